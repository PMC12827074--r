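#' Transcript-to-genomic spliced alignment and event classification
#'
#' Each transcript is partitioned into maximal exact blocks mapped
#' co-linearly onto its genomic allele; block boundaries are compared with
#' the annotated exon boundaries to call alternative-splicing events, whose
#' protein consequences (stem insertions, premature stops, ITIM loss,
#' soluble-isoform candidates) are then deduced.
#'
#' @name splice_annotation
NULL

#' Spliced alignment of a transcript against its genomic allele
#'
#' Greedy maximal-exact-block chaining: from the current transcript
#' position a 20-mer seed is located in the genomic sequence downstream of
#' the previous block, every occurrence is extended to its maximal exact
#' match, and the longest (leftmost on ties) wins. Junctions are then
#' normalized by left-shifting ambiguous boundary bases so that block ends
#' land on annotated exon ends where the sequence allows it (deterministic
#' canonical form). The transcript must derive exactly from this allele;
#' any residual mismatch raises a no-derivation error.
#'
#' @param transcript Transcript sequence.
#' @param genomic Genomic allele sequence.
#' @param model The allele's `gene_model`.
#' @param min_block Minimum internal block length (guards against chance
#'   matches; default 12).
#' @param seed_len Seed length for block anchoring (default 20).
#' @return A tibble of blocks: `t_start`, `t_end`, `g_start`, `g_end`
#'   (1-based inclusive), co-linear and covering the whole transcript.
#' @export
align_transcript <- function(transcript, genomic, model,
                             min_block = 12L, seed_len = 20L) {
  check_genomic(model, genomic)
  nt <- nchar(transcript)
  ng <- nchar(genomic)
  if (nt < min_block) {
    abort("transcript too short to align", class = "lilr_derivation_error")
  }
  t <- 1L
  gmin <- 1L
  blocks <- list()
  while (t <= nt) {
    if (length(blocks) > 2L * nrow(model$exons) + 10L) {
      abort("transcript does not derive from this allele (fragmented chain)",
            class = "lilr_derivation_error")
    }
    rem <- nt - t + 1L
    sl <- min(seed_len, rem)
    seed <- substr(transcript, t, t + sl - 1L)
    occ <- gregexpr(seed, genomic, fixed = TRUE)[[1]]
    occ <- occ[occ >= gmin]
    if (length(occ) == 0L || occ[1] == -1L) {
      abort(sprintf(
        "transcript does not derive from this allele (no anchor at %d)", t),
        class = "lilr_derivation_error")
    }
    tail_seq <- substr(transcript, t, nt)
    best_ext <- 0L
    best_g <- NA_integer_
    for (g in occ) {
      ext <- lcp_len(tail_seq, substr(genomic, g, ng))
      if (ext > best_ext) {
        best_ext <- ext
        best_g <- g
      }
      if (best_ext == rem) break
    }
    if (best_ext < rem && best_ext < min_block) {
      abort(sprintf(
        "transcript does not derive from this allele (mismatch near %d)",
        t + best_ext),
        class = "lilr_derivation_error")
    }
    blocks[[length(blocks) + 1L]] <- c(t, t + best_ext - 1L,
                                       best_g, best_g + best_ext - 1L)
    t <- t + best_ext
    gmin <- best_g + best_ext + 1L
  }
  chain <- tibble(
    t_start = map_int(blocks, ~ .x[1]), t_end = map_int(blocks, ~ .x[2]),
    g_start = map_int(blocks, ~ .x[3]), g_end = map_int(blocks, ~ .x[4])
  )
  normalize_chain(chain, transcript, genomic, model)
}

# Left-shift ambiguous junction bases so block boundaries land on
# annotated exon boundaries (block end on an exon end, or next block
# start on an exon start) where the sequence allows it.
normalize_chain <- function(chain, transcript, genomic, model) {
  exon_ends <- model$exons$end
  exon_starts <- model$exons$start
  n <- nrow(chain)
  if (n < 2L) return(chain)
  for (i in seq_len(n - 1L)) {
    # maximal left slide of the junction between block i and i+1
    s_max <- 0L
    while (s_max < chain$t_end[i] - chain$t_start[i] + 1L) {
      tpos <- chain$t_end[i] - s_max
      gpos <- chain$g_start[i + 1L] - s_max - 1L
      if (gpos < 1L) break
      if (substr(transcript, tpos, tpos) != substr(genomic, gpos, gpos)) break
      s_max <- s_max + 1L
    }
    if (s_max == 0L) next
    k <- NA_integer_
    for (cand in 0:s_max) {
      if ((chain$g_end[i] - cand) %in% exon_ends ||
          (chain$g_start[i + 1L] - cand) %in% exon_starts) {
        k <- cand
        break
      }
    }
    if (is.na(k) || k == 0L) next
    chain$t_end[i] <- chain$t_end[i] - k
    chain$g_end[i] <- chain$g_end[i] - k
    chain$t_start[i + 1L] <- chain$t_start[i + 1L] - k
    chain$g_start[i + 1L] <- chain$g_start[i + 1L] - k
  }
  chain
}

#' Classify alternative-splicing events from a block chain
#'
#' Compares the aligned block chain with the model's mature exon spans:
#' a missing exon is an `exon_skip`; an acceptor boundary shifted into the
#' preceding intron by 1-2 bp is a `micro_insertion`, by 3..`alt_ss_max`
#' bp an `alt_3ss` (+k; shifts into the exon give negative k); a donor
#' boundary extended contiguously into the following intron is an
#' `intron_retention` (+k retained bases, the reported reading of partial
#' intron retention); a donor boundary pulled into the exon is an
#' `alt_5ss` (-k). Events are reported sorted by exon.
#'
#' @param chain Block chain from [align_transcript()].
#' @param model The `gene_model`.
#' @param alt_ss_max Maximum acceptor shift still called `alt_3ss`
#'   (larger acceptor-side extensions are called retention; default 50).
#' @return A splice-signature tibble (`kind`, `exon`, `delta_bp`).
#' @export
classify_events <- function(chain, model, alt_ss_max = 50L) {
  ex <- model$exons[model$exons$in_mrna, ]
  events <- list()
  push <- function(kind, exon, delta) {
    events[[length(events) + 1L]] <<- tibble(
      kind = kind, exon = as.integer(exon), delta_bp = as.integer(delta))
  }
  # block index overlapping each exon
  overlaps <- map(seq_len(nrow(ex)), function(i) {
    which(chain$g_start <= ex$end[i] & chain$g_end >= ex$start[i])
  })
  covered <- lengths(overlaps) > 0L
  # every block must overlap at least one mature exon
  blk_hit <- unique(unlist(overlaps))
  if (length(setdiff(seq_len(nrow(chain)), blk_hit)) > 0L) {
    abort("chain inconsistent with model: block maps outside mature exons",
          class = "lilr_classification_error")
  }
  for (i in seq_len(nrow(ex))) {
    e <- ex$exon[i]
    if (!covered[i]) {
      push("exon_skip", e, 0L)
      next
    }
    bl <- overlaps[[i]]
    if (length(bl) > 1L) {
      # a split within one exon is not a splice event we can represent
      abort(sprintf("chain inconsistent with model: exon %d fragmented", e),
            class = "lilr_classification_error")
    }
    b <- chain[bl, ]
    prev_end <- if (i > 1L) ex$end[i - 1L] else 0L
    next_start <- if (i < nrow(ex)) ex$start[i + 1L] else
      model$genomic_length + 1L

    # acceptor (5') side; skip if the block flows in from the previous exon
    # (full intron retention, handled as that exon's donor event)
    if (b$g_start > prev_end) {
      d_acc <- ex$start[i] - b$g_start
      if (d_acc != 0L) {
        if (d_acc %in% 1:2) {
          push("micro_insertion", e, d_acc)
        } else if (d_acc > 2L && d_acc <= alt_ss_max) {
          push("alt_3ss", e, d_acc)
        } else if (d_acc > alt_ss_max) {
          push("intron_retention", e, d_acc)
        } else if (-d_acc <= alt_ss_max) {
          push("alt_3ss", e, d_acc)
        } else {
          abort(sprintf("exon %d acceptor truncated beyond %d bp", e,
                        alt_ss_max),
                class = "lilr_classification_error")
        }
      }
    }
    # donor (3') side; skip if the block flows into the next exon
    if (b$g_end < next_start) {
      d_don <- b$g_end - ex$end[i]
      if (d_don > 0L) {
        push("intron_retention", e, d_don)
      } else if (d_don < 0L) {
        push("alt_5ss", e, d_don)
      }
    } else if (i < nrow(ex)) {
      # block runs through the whole following intron
      push("intron_retention", e, next_start - 1L - ex$end[i])
    }
  }
  if (length(events) == 0L) return(splice_signature())
  sig <- list_rbind(events) |> arrange(.data$exon, .data$kind)
  validate_signature(sig)
  sig
}

#' Observed per-exon block lengths of an aligned isoform
#'
#' Reports, for each mature exon covered by the chain, the length of its
#' aligned block (boundary shifts included). A 30-bp partial intron-15
#' retention on a 126-bp exon 15, for example, yields an annotated exon-15
#' length of 156 bp.
#'
#' @param chain Block chain from [align_transcript()].
#' @param model The `gene_model`.
#' @return Tibble: `exon`, `obs_length` (`NA` for skipped exons).
#' @export
annotated_exon_lengths <- function(chain, model) {
  ex <- model$exons[model$exons$in_mrna, ]
  obs <- map_int(seq_len(nrow(ex)), function(i) {
    bl <- which(chain$g_start <= ex$end[i] & chain$g_end >= ex$start[i])
    if (length(bl) == 0L) return(NA_integer_)
    b <- chain[bl[1], ]
    lo <- max(b$g_start, if (i > 1L) ex$end[i - 1L] + 1L else 1L)
    hi <- min(b$g_end, if (i < nrow(ex)) ex$start[i + 1L] - 1L else b$g_end)
    hi - lo + 1L
  })
  tibble(exon = ex$exon, obs_length = obs)
}

# Net change in coding length caused by a signature.
coding_delta <- function(signature, model) {
  if (nrow(signature) == 0L) return(0L)
  sum(map_int(seq_len(nrow(signature)), function(i) {
    e <- signature$exon[i]
    r <- exon_row(model, e)
    if (signature$kind[i] == "exon_skip") -r$coding_len else
      signature$delta_bp[i]
  }))
}

#' Deduce the protein consequences of a splice signature
#'
#' Rebuilds the isoform transcript, translates from the start codon and
#' reports: whether the reading frame and stop position are intact, the
#' position of a premature stop (if any), residues inserted relative to
#' the allele's canonical protein (e.g. the alanine added by the 3-bp
#' alternative 3' splice site at exon 10), the ITIM count of the
#' translated product, and whether the product is a soluble-receptor
#' candidate (premature stop upstream of the transmembrane segment).
#'
#' @param signature Splice-signature tibble.
#' @param genomic Genomic allele sequence.
#' @param model The allele's `gene_model`.
#' @return One-row tibble: `signature_id`, `cds_intact`, `premature_stop`
#'   (aa position or `NA`), `itim_count`, `inserted_residues`,
#'   `soluble_candidate`.
#' @export
annotate_protein <- function(signature, genomic, model) {
  validate_signature(signature)
  transcript <- simulate_isoform(genomic, model, signature)
  blocks <- isoform_blocks(model, signature)

  # transcript coordinate of the start codon
  start_ex <- exon_row(model, model$start_codon_exon)
  start_g <- start_ex$start + model$utr5_len
  bi <- which(blocks$g_start <= start_g & blocks$g_end >= start_g)
  if (length(bi) == 0L) {
    abort("signature removes the start codon", class = "lilr_classification_error")
  }
  tpos <- sum(blocks$g_end[seq_len(bi - 1L)] -
                blocks$g_start[seq_len(bi - 1L)] + 1L) +
    (start_g - blocks$g_start[bi]) + 1L

  coding_part <- substr(transcript, tpos, nchar(transcript))
  prot <- translate_dna(coding_part, partial = TRUE)
  stop_at <- as.integer(regexpr("*", prot, fixed = TRUE))

  canonical_cds <- extract_cds(model, genomic)
  canonical_prot <- translate_dna(canonical_cds)
  canonical_stop <- nchar(canonical_cds) %/% 3L
  delta <- coding_delta(signature, model)
  in_frame <- delta %% 3L == 0L
  expected_stop <- if (in_frame) canonical_stop + delta %/% 3L else
    NA_integer_

  premature <- NA_integer_
  cds_intact <- FALSE
  if (stop_at > 0L) {
    if (in_frame && stop_at == expected_stop) {
      cds_intact <- TRUE
    } else {
      premature <- stop_at
    }
  }

  product <- if (stop_at > 0L) substr(prot, 1L, stop_at - 1L) else
    gsub("\\*.*$", "", prot)
  itims <- length(itim_positions(product))

  inserted <- NA_character_
  if (cds_intact && delta > 0L) {
    inserted <- peptide_insertion(sub("\\*$", "", canonical_prot), product)
  }

  # first TM codon: translation position where the TM region begins
  coding_exons <- model$exons[model$exons$coding_len > 0L, ]
  pre_tm <- sum(coding_exons$coding_len[
    cumsum(coding_exons$region == "TM") == 0L])
  tm_codon <- pre_tm %/% 3L + 1L
  soluble <- !is.na(premature) && premature <= tm_codon

  tibble(
    signature_id = signature_label(signature),
    cds_intact = cds_intact,
    premature_stop = premature,
    itim_count = itims,
    inserted_residues = inserted,
    soluble_candidate = soluble
  )
}

#' Survey splice-site dinucleotides and cryptic stop codons
#'
#' Reports each intron's donor (first two) and acceptor (last two)
#' dinucleotides, flags non-GT donors (e.g. the GT-to-GC donor mutation
#' after exon 15 linked to exon-15 skipping), and checks the intron that
#' follows the stem region for an in-frame cryptic stop codon beginning
#' 3 nt downstream of the donor site (the soluble-isoform mechanism).
#'
#' @param genomic Genomic allele sequence.
#' @param model The `gene_model`.
#' @return Tibble: `intron`, `donor`, `acceptor`, `donor_canonical`,
#'   `cryptic_stop` (`NA` except for the intron after the stem region).
#' @export
detect_splice_motifs <- function(genomic, model) {
  check_genomic(model, genomic)
  if (any(model$introns$length < 6L)) {
    abort("intron shorter than 6 nt", class = "lilr_structural_error")
  }
  stem_exons <- model$exons$exon[model$exons$region == "stem"]
  stem_intron <- if (length(stem_exons) > 0L) max(stem_exons) else NA_integer_
  coding_exons <- model$exons[model$exons$coding_len > 0L, ]

  rows <- map(seq_len(nrow(model$introns)), function(i) {
    intr <- model$introns[i, ]
    iseq <- substr(genomic, intr$start, intr$end)
    donor <- substr(iseq, 1L, 2L)
    acceptor <- substr(iseq, nchar(iseq) - 1L, nchar(iseq))
    cryptic <- NA
    if (!is.na(stem_intron) && intr$intron == stem_intron) {
      # frame at read-through: coding bases upstream of this intron
      upstream <- sum(coding_exons$coding_len[coding_exons$exon <=
                                                intr$intron])
      in_frame <- upstream %% 3L == 0L
      cryptic <- in_frame && substr(iseq, 4L, 6L) %in% STOP_CODONS
    }
    tibble(intron = intr$intron, donor = donor, acceptor = acceptor,
           donor_canonical = donor == "GT", cryptic_stop = cryptic)
  })
  list_rbind(rows)
}

#' Filter splicing events to the shared-event catalog
#'
#' Retains events (identified allele-agnostically by kind, exon and
#' delta_bp) observed in at least two individuals/animals AND present in
#' two or more species, the criterion behind the shared-event
#' catalogs.
#'
#' @param events Tibble with columns `kind`, `exon`, `delta_bp`, `animal`,
#'   `species` (one row per observation).
#' @return Tibble of surviving events with `n_animals`, `n_species` and
#'   total observation counts.
#' @export
filter_shared_events <- function(events) {
  if (nrow(events) == 0L) {
    return(tibble(kind = character(), exon = integer(),
                  delta_bp = integer(), n_animals = integer(),
                  n_species = integer(), n_obs = integer()))
  }
  events |>
    group_by(.data$kind, .data$exon, .data$delta_bp) |>
    summarise(
      n_animals = n_distinct(.data$animal),
      n_species = n_distinct(.data$species),
      n_obs = n(),
      .groups = "drop"
    ) |>
    filter(.data$n_animals >= 2L, .data$n_species >= 2L) |>
    arrange(.data$exon, .data$kind)
}

#' Per-exon stacked event counts for a shared-event catalog
#' @param catalog Output of [filter_shared_events()].
#' @return Tibble of `exon`, `kind`, `n_events` suitable for stacked bars.
#' @export
shared_event_counts <- function(catalog) {
  catalog |>
    count(.data$exon, .data$kind, name = "n_events")
}
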