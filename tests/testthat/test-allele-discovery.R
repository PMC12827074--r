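ref_lib <- local({
  tx1 <- extract_transcript(fx$model, fx$genomic)
  # a second allele: one substitution inside exon 5
  g2 <- fx$genomic
  e5 <- fx$model$exons[fx$model$exons$exon == 5, ]
  p <- e5$start + 50L
  substr(g2, p, p) <- if (substr(g2, p, p) == "A") "G" else "A"
  reference_library(tibble::tibble(
    name = c("alleleA", "alleleB"),
    sequence = c(tx1, extract_transcript(fx$model, g2)),
    gene = "LILRB1"))
})

test_that("exact-match assignment follows the mapping contract", {
  txA <- ref_lib$entries$sequence[1]
  reads <- tibble::tibble(
    id = c("full", "sub450", "mismatch1", "oneN", "twoN", "short"),
    seq = c(
      txA,
      substr(txA, 101, 550),                       # exact 450-bp substring
      paste0("T", substr(txA, 2, nchar(txA))),     # if first base not T
      paste0("N", substr(txA, 2, nchar(txA))),
      paste0("NN", substr(txA, 3, nchar(txA))),
      substr(txA, 1, 399)))
  if (substr(txA, 1, 1) == "T") {
    reads$seq[3] <- paste0("A", substr(txA, 2, nchar(txA)))
  }
  res <- match_to_reference(reads, ref_lib)
  expect_setequal(res$assignments$id, c("full", "sub450", "oneN"))
  expect_true(all(res$assignments$allele == "alleleA"))
  expect_setequal(res$unassigned$id, c("mismatch1", "twoN", "short"))
})

test_that("reads matching several references are flagged ambiguous", {
  # both alleles share everything outside exon 5: a read covering only
  # the 3' half matches both
  txA <- ref_lib$entries$sequence[1]
  shared <- substr(txA, nchar(txA) - 799L, nchar(txA))
  res <- match_to_reference(
    tibble::tibble(id = "shared", seq = shared), ref_lib)
  expect_equal(nrow(res$assignments), 2L)
  expect_true(all(res$assignments$ambiguous))
  expect_setequal(res$assignments$allele, c("alleleA", "alleleB"))
})

test_that("assignment is exact-match sound and monotone in the library", {
  truth <- simulate_allele_set(small_sim(), seed = 41L)
  rs <- simulate_ccs_reads(truth, seed = 42L)
  dmx <- demultiplex(filter_by_quality(rs$reads), rs$barcodes) |>
    dplyr::filter(!is.na(sample))
  iso_refs <- purrr::map(seq_len(nrow(truth$alleles)), function(i) {
    tibble::tibble(
      name = paste0(truth$alleles$allele_id[i], "_",
                    truth$config$splice_profile$signature_id),
      sequence = purrr::map_chr(
        truth$config$splice_profile$events,
        ~ simulate_isoform(truth$alleles$genomic[i],
                           truth$alleles$model[[i]], .x)),
      gene = "LILRB1", parent = truth$alleles$allele_id[i])
  }) |> purrr::list_rbind() |> dplyr::distinct(sequence, .keep_all = TRUE)
  full_lib <- reference_library(iso_refs)
  half_lib <- reference_library(
    iso_refs[iso_refs$parent %in% truth$alleles$allele_id[1:6], ])
  res_full <- match_to_reference(dmx, full_lib)
  res_half <- match_to_reference(dmx, half_lib)
  # soundness at error 0: every assigned read is a substring of its ref
  merged <- res_full$assignments |>
    dplyr::left_join(full_lib$entries, by = c(allele = "name"))
  expect_true(all(purrr::map2_lgl(merged$seq, merged$sequence,
                                  ~ grepl(.x, .y, fixed = TRUE) ||
                                    grepl(.y, .x, fixed = TRUE))))
  # truthfulness: assignment agrees with the generating allele
  tr <- rs$truth_reads
  chk <- res_full$assignments |>
    dplyr::filter(!ambiguous) |>
    dplyr::left_join(tr, by = "id")
  expect_true(all(full_lib$entries$parent[
    match(chk$allele, full_lib$entries$name)] == chk$allele_id))
  # monotonicity: enlarging the library never loses assignments
  expect_gte(dplyr::n_distinct(res_full$assignments$id),
             dplyr::n_distinct(res_half$assignments$id))
  expect_true(all(unique(res_half$assignments$id) %in%
                    unique(res_full$assignments$id)))
})

test_that("contig clustering applies the three-read cutoff and majority vote", {
  novel <- substr(extract_transcript(fx$model, fx$genomic), 1, 600)
  five <- tibble::tibble(id = sprintf("r%d", 1:5), seq = novel)
  out5 <- cluster_unassigned(five, min_length = 400L)
  expect_equal(nrow(out5), 1L)
  expect_equal(out5$support, 5L)
  expect_identical(out5$consensus, novel)

  two <- five[1:2, ]
  expect_equal(nrow(cluster_unassigned(two, min_length = 400L)), 0L)

  # three reads, each with a single error at a distinct position:
  # the column-majority consensus recovers the true sequence
  seqs <- rep(novel, 3)
  for (i in 1:3) {
    p <- 100L * i
    substr(seqs[i], p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(novel, p, p))[1]
  }
  out3 <- cluster_unassigned(
    tibble::tibble(id = sprintf("e%d", 1:3), seq = seqs),
    min_length = 400L)
  expect_equal(nrow(out3), 1L)
  expect_identical(out3$consensus, novel)
})

test_that("novel candidates follow the two-runs-or-two-individuals rule", {
  cands <- tibble::tibble(
    consensus = c("AAA", "AAA", "CCC", "GGG", "GGG", "TTT"),
    sample = c("an1", "an2", "an3", "an4", "an4", "an5"),
    run = c("run1", "run1", "run1", "run1", "run2", "run1"),
    support = c(5L, 4L, 3L, 3L, 6L, 3L))
  lib <- reference_library(tibble::tibble(
    name = "known", sequence = "TTT", gene = "LILRB1"))
  out <- confirm_novel(cands, lib)
  expect_equal(out$status[out$consensus == "AAA"], "confirmed") # 2 animals
  expect_equal(out$status[out$consensus == "CCC"], "candidate") # 1/1
  expect_equal(out$status[out$consensus == "GGG"], "confirmed") # 2 runs
  expect_equal(out$status[out$consensus == "TTT"], "known")
})

test_that("library growth deduplicates and bumps the version", {
  lib <- reference_library(tibble::tibble(
    name = "a", sequence = "ACGTACGT", gene = "LILRB1"))
  lib2 <- add_to_library(lib, tibble::tibble(
    name = c("b", "dup"), sequence = c("TTTTAAAA", "ACGTACGT"),
    gene = "LILRB1"))
  expect_equal(lib2$version, 2L)
  expect_equal(nrow(lib2$entries), 2L)
  expect_error(reference_library(tibble::tibble(
    name = c("x", "x"), sequence = c("AA", "CC"), gene = "g")), "unique")
})

test_that("cDNA-gDNA reconciliation links transcripts via splice signatures", {
  g2 <- fx$genomic
  # second genomic allele differing only in intron 3 (same transcript)
  i3 <- fx$model$introns[fx$model$introns$intron == 3, ]
  p <- i3$start + 40L
  substr(g2, p, p) <- if (substr(g2, p, p) == "A") "C" else "A"
  galleles <- tibble::tibble(
    name = c("G1", "G2"), sequence = c(fx$genomic, g2),
    model = list(fx$model, fx$model))

  tx_c <- extract_transcript(fx$model, fx$genomic)
  tx_skip <- simulate_isoform(fx$genomic, fx$model,
                              parse_signature("skip15"))
  foreign <- tx_c
  substr(foreign, 500, 500) <- setdiff(c("A", "C", "G", "T"),
                                       substr(tx_c, 500, 500))[1]
  rec <- reconcile_cdna_gdna(
    tibble::tibble(name = c("tC", "tSkip", "tForeign"),
                   sequence = c(tx_c, tx_skip, foreign)),
    galleles)
  expect_equal(unique(rec$status[rec$transcript == "tC"]), "ambiguous")
  expect_equal(sum(rec$transcript == "tC"), 2L)
  skip_row <- rec[rec$transcript == "tSkip", ]
  expect_equal(unique(skip_row$signature_id), "skip15")
  expect_equal(rec$status[rec$transcript == "tForeign"],
               "transcript_only")
})
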