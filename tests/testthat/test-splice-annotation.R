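test_that("canonical transcripts align as the exact mature exon chain", {
  tx <- extract_transcript(fx$model, fx$genomic)
  chain <- align_transcript(tx, fx$genomic, fx$model)
  ex <- fx$model$exons[fx$model$exons$in_mrna, ]
  expect_equal(chain$g_start, ex$start)
  expect_equal(chain$g_end, ex$end)
  expect_equal(nrow(classify_events(chain, fx$model)), 0L)
})

test_that("an exon-9-deleted transcript loses the exon-9 interval", {
  tx <- simulate_isoform(fx$genomic, fx$model, parse_signature("skip9"))
  chain <- align_transcript(tx, fx$genomic, fx$model)
  e9 <- fx$model$exons[fx$model$exons$exon == 9, ]
  covered <- any(chain$g_start <= e9$end & chain$g_end >= e9$start)
  expect_false(covered)
  expect_equal(classify_events(chain, fx$model)$kind, "exon_skip")
})

test_that("transcripts from a different allele raise a no-derivation error", {
  tx <- extract_transcript(fx$model, fx$genomic)
  p <- 1000L
  substr(tx, p, p) <- setdiff(c("A", "C", "G", "T"), substr(tx, p, p))[1]
  expect_error(align_transcript(tx, fx$genomic, fx$model),
               class = "lilr_derivation_error")
})

test_that("event classification matches the constructed boundary shifts", {
  cases <- list(
    list(sig = "alt3ss10+3", kind = "alt_3ss", exon = 10L, delta = 3L),
    list(sig = "skip15", kind = "exon_skip", exon = 15L, delta = 0L),
    list(sig = "ret15+30", kind = "intron_retention", exon = 15L,
         delta = 30L),
    list(sig = "micro10+2", kind = "micro_insertion", exon = 10L,
         delta = 2L),
    list(sig = "alt5ss10-6", kind = "alt_5ss", exon = 10L, delta = -6L),
    list(sig = "alt3ss10-3", kind = "alt_3ss", exon = 10L, delta = -3L)
  )
  for (cs in cases) {
    tx <- simulate_isoform(fx$genomic, fx$model, parse_signature(cs$sig))
    ev <- classify_events(align_transcript(tx, fx$genomic, fx$model),
                          fx$model)
    expect_equal(nrow(ev), 1L, info = cs$sig)
    expect_equal(ev$kind, cs$kind, info = cs$sig)
    expect_equal(ev$exon, cs$exon, info = cs$sig)
    expect_equal(ev$delta_bp, cs$delta, info = cs$sig)
  }
})

test_that("a 30-bp intron-15 retention yields a 156-bp exon-15 block", {
  tx <- simulate_isoform(fx$genomic, fx$model, parse_signature("ret15+30"))
  chain <- align_transcript(tx, fx$genomic, fx$model)
  ael <- annotated_exon_lengths(chain, fx$model)
  expect_equal(ael$obs_length[ael$exon == 15], 156L)
  expect_equal(ael$obs_length[ael$exon == 14], 90L)
})

test_that("transcript length obeys the event-conservation identity", {
  ex <- fx$model$exons[fx$model$exons$in_mrna, ]
  base_len <- sum(ex$length)
  for (lab in event_catalog) {
    sig <- parse_signature(lab)
    tx <- simulate_isoform(fx$genomic, fx$model, sig)
    skipped <- sum(ex$length[ex$exon %in%
                               sig$exon[sig$kind == "exon_skip"]])
    expect_equal(nchar(tx), base_len + sum(sig$delta_bp) - skipped,
                 info = lab)
  }
})

test_that("protein annotation deduces insertions, ITIM loss and stops", {
  a10 <- annotate_protein(parse_signature("alt3ss10+3"), fx$genomic,
                          fx$model)
  expect_true(a10$cds_intact)
  expect_equal(a10$inserted_residues, "A")
  a15 <- annotate_protein(parse_signature("alt3ss15+3"), fx$genomic,
                          fx$model)
  expect_equal(a15$inserted_residues, "Q")
  skip <- annotate_protein(parse_signature("skip15"), fx$genomic,
                           fx$model)
  expect_true(skip$cds_intact)
  expect_equal(skip$itim_count, 3L)
  canon <- annotate_protein(splice_signature(), fx$genomic, fx$model)
  expect_equal(canon$itim_count, 4L)
  for (lab in c("micro10+1", "micro10+2")) {
    m <- annotate_protein(parse_signature(lab), fx$genomic, fx$model)
    expect_false(m$cds_intact)
    expect_false(is.na(m$premature_stop))
    expect_true(m$soluble_candidate, info = lab)
  }
})

test_that("ITIM count never increases when exons are removed", {
  base <- annotate_protein(splice_signature(), fx$genomic,
                           fx$model)$itim_count
  for (e in c(9L, 12L, 13L, 14L, 15L)) {
    skip <- annotate_protein(splice_signature("exon_skip", e, 0L),
                             fx$genomic, fx$model)
    expect_lte(skip$itim_count, base)
  }
})

test_that("splice-motif survey flags GC donors and cryptic stops", {
  motifs <- detect_splice_motifs(fx$genomic, fx$model)
  expect_equal(nrow(motifs), 15L)
  expect_true(all(motifs$donor_canonical))
  expect_false(isTRUE(motifs$cryptic_stop[motifs$intron == 10]))
  expect_true(all(is.na(motifs$cryptic_stop[motifs$intron != 10])))

  gc <- lilrseq:::apply_feature(fx$genomic, fx$model, "gc_donor15")
  m_gc <- detect_splice_motifs(gc$genomic, gc$model)
  expect_false(m_gc$donor_canonical[m_gc$intron == 15])
  expect_equal(m_gc$donor[m_gc$intron == 15], "GC")

  cs <- lilrseq:::apply_feature(fx$genomic, fx$model, "cryptic_stop10")
  m_cs <- detect_splice_motifs(cs$genomic, cs$model)
  expect_true(m_cs$cryptic_stop[m_cs$intron == 10])
  # oracle: translating the read-through past exon 10 hits that stop
  ex10 <- fx$model$exons[fx$model$exons$exon == 10, ]
  upstream_coding <- sum(fx$model$exons$coding_len[
    fx$model$exons$exon <= 10])
  cds_part <- extract_cds(cs$model, cs$genomic)
  readthrough <- paste0(substr(cds_part, 1, upstream_coding),
                        lilrseq:::intron_seq(cs$model, cs$genomic, 10L))
  prot <- translate_dna(readthrough, partial = TRUE)
  first_stop <- regexpr("*", prot, fixed = TRUE)
  expect_equal(as.integer(first_stop), upstream_coding / 3 + 2L)

  tiny <- build_canonical_model("t", c(6L, 6L), first_mrna_exon = 1L,
                                start_codon_exon = 1L, utr5_len = 0L,
                                coding_prefix_len = 6L,
                                intron_lengths = 4L)
  expect_error(detect_splice_motifs(strrep("A", 16), tiny),
               class = "lilr_structural_error")
})

test_that("the shared-event filter demands two animals and two species", {
  events <- tibble::tibble(
    kind = c(rep("exon_skip", 3), "alt_3ss", "alt_3ss",
             "intron_retention"),
    exon = c(15L, 15L, 15L, 10L, 10L, 15L),
    delta_bp = c(0L, 0L, 0L, 3L, 3L, 30L),
    animal = c("a1", "a2", "a3", "b1", "b2", "c1"),
    species = c("SpA", "SpA", "SpA", "SpA", "SpB", "SpA"))
  out <- filter_shared_events(events)
  # skip15: three animals but one species -> excluded
  # alt_3ss10+3: one animal in each of two species -> included
  # retention: single animal -> excluded
  expect_equal(nrow(out), 1L)
  expect_equal(out$kind, "alt_3ss")
  expect_equal(out$n_animals, 2L)
  expect_equal(out$n_species, 2L)
  empty <- filter_shared_events(events[0, ])
  expect_equal(nrow(empty), 0L)
  counts <- shared_event_counts(out)
  expect_equal(counts$n_events, 1L)
})
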