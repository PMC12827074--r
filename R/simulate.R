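#' Synthetic study generator
#'
#' Generates lineage-structured allele libraries, splice-isoform mixtures
#' and barcoded, error-bearing CCS reads with ground-truth manifests, so
#' the whole pipeline can be exercised and verified without external data.
#' The defaults encode the assay conditions the analysis assumes:
#' multi-allele (diploid) samples, inter-lineage divergence much larger
#' than intra-lineage divergence, an isoform mixture dominated by
#' non-canonical transcripts, 16-bp dual sample barcodes and a low CCS
#' substitution error rate with read qualities mostly >= 0.99.
#'
#' @name synthetic_data
NULL

#' Default splice-isoform mixture
#'
#' The mixture mirrors the dominant observed isoforms: a 3-bp alternative
#' 3' splice site at exon 10 (most common), exon-15 skipping, their
#' combination, a 3-bp alternative 3' splice site at exon 15, a 30-bp
#' partial intron-15 retention and a 1-bp premature-stop micro-insertion at
#' exon 10, with the canonical mature mRNA in the minority.
#'
#' @return A tibble with columns `signature_id`, `weight` and `events`
#'   (list-column of signature tibbles); weights sum to 1.
#' @export
default_splice_profile <- function() {
  tibble(
    signature_id = c("C", "alt3ss10+3", "skip15", "alt3ss10+3,skip15",
                     "alt3ss15+3", "ret15+30", "micro10+1"),
    weight = c(0.15, 0.30, 0.20, 0.15, 0.10, 0.05, 0.05)
  ) |>
    mutate(events = map(.data$signature_id, parse_signature))
}

#' Simulation configuration
#'
#' @param n_lineages Number of allele lineages.
#' @param alleles_per_lineage Alleles per lineage.
#' @param inter_lineage_divergence Substitutions/site between the ancestor
#'   and each lineage founder.
#' @param intra_lineage_divergence Substitutions/site between a founder and
#'   each of its alleles (must be < `inter_lineage_divergence`).
#' @param indel_features Tibble with columns `lineage`, `type`
#'   (`"exon9_insert"`, `"gc_donor15"`, `"cryptic_stop10"`) marking
#'   structural features carried by all alleles of a lineage: the 21-bp
#'   in-frame exon-9 insertion (stem extension PTTGPTS), the GT-to-GC donor
#'   mutation of intron 15 (linked to exon-15 skipping), and a cryptic stop
#'   codon 3 nt into the intron after the stem region (soluble-isoform
#'   candidate).
#' @param splice_profile Isoform mixture, as [default_splice_profile()].
#' @param n_samples Number of samples (individuals).
#' @param n_species Number of species labels the samples are spread over.
#' @param n_runs Number of sequencing runs the samples are spread over.
#' @param max_alleles_per_sample Allele copies per individual (diploid = 2).
#' @param reads_per_sample CCS reads emitted per sample.
#' @param ccs_error_rate Per-base substitution probability.
#' @param barcode_len Barcode length in bp (16 in the assay design).
#' @param rq_pass_frac Fraction of reads drawn from the passing
#'   read-quality stratum (rq >= 0.99); the rest fall in [0.95, 0.99).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lineages = 3L,
                       alleles_per_lineage = 4L,
                       inter_lineage_divergence = 0.05,
                       intra_lineage_divergence = 0.002,
                       indel_features = tibble(
                         lineage = c(3L, 1L, 2L),
                         type = c("exon9_insert", "gc_donor15",
                                  "cryptic_stop10")
                       ),
                       splice_profile = default_splice_profile(),
                       n_samples = 20L,
                       n_species = 2L,
                       n_runs = 2L,
                       max_alleles_per_sample = 2L,
                       reads_per_sample = 500L,
                       ccs_error_rate = 0.001,
                       barcode_len = 16L,
                       rq_pass_frac = 0.9) {
  stopifnot(
    n_lineages >= 1L, alleles_per_lineage >= 1L,
    inter_lineage_divergence > intra_lineage_divergence,
    intra_lineage_divergence >= 0,
    barcode_len > 0L, ccs_error_rate >= 0, ccs_error_rate < 1,
    rq_pass_frac >= 0, rq_pass_frac <= 1
  )
  if (abs(sum(splice_profile$weight) - 1) > 1e-9) {
    abort("splice profile mixture weights must sum to 1")
  }
  if (nrow(indel_features) > 0L &&
      !all(indel_features$type %in%
           c("exon9_insert", "gc_donor15", "cryptic_stop10"))) {
    abort("unknown indel feature type")
  }
  structure(
    list(
      n_lineages = as.integer(n_lineages),
      alleles_per_lineage = as.integer(alleles_per_lineage),
      inter_lineage_divergence = inter_lineage_divergence,
      intra_lineage_divergence = intra_lineage_divergence,
      indel_features = indel_features,
      splice_profile = splice_profile,
      n_samples = as.integer(n_samples),
      n_species = as.integer(n_species),
      n_runs = as.integer(n_runs),
      max_alleles_per_sample = as.integer(max_alleles_per_sample),
      reads_per_sample = as.integer(reads_per_sample),
      ccs_error_rate = ccs_error_rate,
      barcode_len = as.integer(barcode_len),
      rq_pass_frac = rq_pass_frac
    ),
    class = "sim_config"
  )
}

# Positions of the genomic sequence that mutation must not touch:
# splice-site dinucleotides, the engineered intron tails/heads, the start
# and stop codons.
locked_positions <- function(model) {
  intr <- model$introns
  locked <- c(
    outer(intr$start, 0:1, `+`), outer(intr$end, -1:0, `+`)
  )
  tail3 <- function(i) {
    j <- match(i, intr$intron)
    if (is.na(j)) return(integer())
    (intr$end[j] - 2L):intr$end[j]
  }
  head_n <- function(i, n) {
    j <- match(i, intr$intron)
    if (is.na(j)) return(integer())
    intr$start[j]:(intr$start[j] + n - 1L)
  }
  locked <- c(locked, tail3(9L), tail3(14L), head_n(10L, 6L),
              head_n(15L, 30L))
  start_ex <- exon_row(model, model$start_codon_exon)
  locked <- c(locked, (start_ex$start + model$utr5_len) +
                (0:2))
  stop_ex <- exon_row(model, model$stop_codon_exon)
  stop_beg <- stop_ex$start + model$coding_prefix_len - 3L
  locked <- c(locked, stop_beg:(stop_beg + 2L))
  sort(unique(as.integer(locked)))
}

# Map a genomic position to its CDS position (NA if non-coding).
genomic_to_cds_map <- function(model) {
  pos <- rep(NA_integer_, model$genomic_length)
  cum <- 0L
  for (e in mature_mrna_exons(model)) {
    w <- coding_window(model, e)
    if (is.null(w)) next
    r <- exon_row(model, e)
    g <- (r$start + w[1] - 1L):(r$start + w[2] - 1L)
    pos[g] <- cum + seq_along(g)
    cum <- cum + length(g)
  }
  pos
}

# Substitute `n_sub` positions of `genomic`, avoiding locked positions and
# never creating an internal stop codon in the CDS.
mutate_genomic <- function(genomic, model, n_sub, locked, cds_map) {
  if (n_sub == 0L) return(genomic)
  raw <- charToRaw(genomic)
  candidates <- setdiff(seq_len(nchar(genomic)), locked)
  pos <- sample(candidates, min(n_sub, length(candidates)))
  for (p in pos) {
    cur <- rawToChar(raw[p])
    alts <- sample(setdiff(DNA_BASES, cur))
    for (alt in alts) {
      if (!is.na(cds_map[p])) {
        cp <- cds_map[p]
        codon_i <- (cp - 1L) %/% 3L
        off <- (cp - 1L) %% 3L
        # genomic positions of this codon are contiguous only within an
        # exon; rebuild the codon from the map
        codon_pos <- which(cds_map %in% (codon_i * 3L + 1:3))
        codon <- rawToChar(raw[codon_pos])
        substr(codon, off + 1L, off + 1L) <- alt
        if (codon %in% STOP_CODONS) next
      }
      raw[p] <- charToRaw(alt)
      break
    }
  }
  rawToChar(raw)
}

# Apply a structural indel feature to (genomic, model).
apply_feature <- function(genomic, model, type) {
  switch(type,
    exon9_insert = {
      r <- exon_row(model, 9L)
      at <- r$start + EXON9_INSERT_OFFSET - 1L
      genomic <- paste0(substr(genomic, 1L, at), EXON9_INSERT_SEQ,
                        substr(genomic, at + 1L, nchar(genomic)))
      model2 <- lilrb1_model(exon9_insert_len = nchar(EXON9_INSERT_SEQ))
      list(genomic = genomic, model = model2)
    },
    gc_donor15 = {
      j <- match(15L, model$introns$intron)
      p <- model$introns$start[j] + 1L
      substr(genomic, p, p) <- "C"
      list(genomic = genomic, model = model)
    },
    cryptic_stop10 = {
      j <- match(10L, model$introns$intron)
      p <- model$introns$start[j]
      substr(genomic, p, p + 5L) <- "GTATGA"
      list(genomic = genomic, model = model)
    },
    abort(sprintf("unknown feature type: %s", type))
  )
}

#' Simulate a lineage-structured allele set
#'
#' Star-within-star process: a canonical ancestral allele is mutated into
#' `n_lineages` founders at the inter-lineage divergence, and each founder
#' into `alleles_per_lineage` alleles at the intra-lineage divergence.
#' Lineage-level structural features (21-bp exon-9 insertion, GC donor,
#' cryptic stop) are applied to the founder before the intra-lineage step.
#' Splice-site dinucleotides, the start/stop codons and the engineered
#' intron heads/tails are never mutated, and substitutions never create an
#' internal stop codon, so every allele satisfies its gene model.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `lilr_truth` with elements `alleles` (tibble:
#'   `allele_id`, `lineage`, `genomic`, `model` list-column, `features`),
#'   `genotypes` (tibble: `sample`, `species`, `run`, `allele_id`),
#'   `ancestor` (the fixture) and `config`.
#' @export
simulate_allele_set <- function(config = sim_config(), seed = 1L) {
  if (nchar(EXON9_INSERT_SEQ) %% 3L != 0L) {
    abort("in-frame insert feature must have length a multiple of 3")
  }
  anc <- lilrb1_fixture()
  model0 <- anc$model
  locked <- locked_positions(model0)
  cmap <- genomic_to_cds_map(model0)
  L <- nchar(anc$genomic)

  with_rng(seed, {
    alleles <- vector("list", config$n_lineages * config$alleles_per_lineage)
    k <- 0L
    for (lin in seq_len(config$n_lineages)) {
      n_sub <- stats::rbinom(1L, L, config$inter_lineage_divergence)
      founder <- mutate_genomic(anc$genomic, model0, n_sub, locked, cmap)
      fmodel <- model0
      feats <- config$indel_features$type[config$indel_features$lineage == lin]
      for (ft in feats) {
        res <- apply_feature(founder, fmodel, ft)
        founder <- res$genomic
        fmodel <- res$model
      }
      flocked <- if (identical(fmodel, model0)) locked else
        locked_positions(fmodel)
      fcmap <- if (identical(fmodel, model0)) cmap else
        genomic_to_cds_map(fmodel)
      seen <- character()
      for (a in seq_len(config$alleles_per_lineage)) {
        repeat {
          n_sub <- stats::rbinom(1L, nchar(founder),
                                 config$intra_lineage_divergence)
          g <- mutate_genomic(founder, fmodel, n_sub, flocked, fcmap)
          if (config$intra_lineage_divergence == 0 || !g %in% seen) break
        }
        seen <- c(seen, g)
        k <- k + 1L
        alleles[[k]] <- tibble(
          allele_id = sprintf("sim%02d.%02d", lin, a),
          lineage = lin,
          genomic = g,
          model = list(fmodel),
          features = list(feats)
        )
      }
    }
    alleles <- list_rbind(alleles)

    # diploid genotypes; every allele placed in at least one sample
    n_all <- nrow(alleles)
    geno <- map(seq_len(config$n_samples), function(s) {
      n_cp <- min(config$max_alleles_per_sample,
                  if (stats::runif(1) < 0.9) 2L else 1L)
      n_cp <- min(n_cp, n_all)
      pick <- function(x, size) x[sample.int(length(x), size)]
      ids <- if (s <= n_all) {
        # first pass guarantees coverage of every simulated allele
        c(s, pick(setdiff(seq_len(n_all), s), n_cp - 1L))
      } else {
        pick(seq_len(n_all), n_cp)
      }
      tibble(
        sample = sprintf("S%02d", s),
        species = sprintf("Sp%s", LETTERS[(s - 1L) %% config$n_species + 1L]),
        run = sprintf("run%d", (s - 1L) %% config$n_runs + 1L),
        allele_id = alleles$allele_id[ids]
      )
    }) |> list_rbind()

    structure(
      list(alleles = alleles, genotypes = geno, ancestor = anc,
           config = config),
      class = "lilr_truth"
    )
  })
}

#' @export
print.lilr_truth <- function(x, ...) {
  cat(sprintf(
    "<lilr_truth> %d alleles in %d lineages; %d samples, %d reads/sample planned\n",
    nrow(x$alleles), x$config$n_lineages, x$config$n_samples,
    x$config$reads_per_sample
  ))
  invisible(x)
}

# Generate n dual-barcode pairs of the given length with all barcodes
# (fwd and rev pooled) pairwise separated by > 2*max_mismatch mismatches.
generate_barcodes <- function(n, len = 16L, min_dist = 5L) {
  pool <- character(0)
  while (length(pool) < 2L * n) {
    cand <- random_dna(len)
    if (all(vapply(pool, function(b) hamming(b, cand) >= min_dist, TRUE))) {
      pool <- c(pool, cand)
    }
  }
  tibble(
    sample = sprintf("S%02d", seq_len(n)),
    fwd_barcode = pool[seq_len(n)],
    rev_barcode = pool[n + seq_len(n)]
  )
}

# Substitute errors into a read at the given per-base rate.
add_read_errors <- function(seq, rate) {
  n_err <- stats::rbinom(1L, nchar(seq), rate)
  if (n_err == 0L) return(list(seq = seq, n_errors = 0L))
  raw <- charToRaw(seq)
  pos <- sample.int(nchar(seq), n_err)
  for (p in pos) {
    raw[p] <- charToRaw(sample(setdiff(DNA_BASES, rawToChar(raw[p])), 1L))
  }
  list(seq = rawToChar(raw), n_errors = n_err)
}

#' Simulate barcoded CCS reads from a truth set
#'
#' Draws reads per sample from its genotype's isoform mixture, applies
#' substitution errors at the configured CCS error rate, attaches the
#' sample's 16-bp barcodes at both ends (reverse barcode
#' reverse-complemented, as on the opposite strand), flips half of the
#' reads to the reverse orientation, and assigns each read a read-quality
#' value from the configured passing/failing mixture.
#'
#' @param truth A `lilr_truth` from [simulate_allele_set()].
#' @param seed Integer seed; byte-identical output for identical inputs.
#' @return A list of class `lilr_readset`: `reads` (tibble `id`, `seq`,
#'   `rq`), `barcodes` (sample manifest), `truth_reads` (per-read ground
#'   truth: sample, allele, signature, error count, orientation).
#' @export
simulate_ccs_reads <- function(truth, seed = 1L) {
  config <- truth$config
  with_rng(seed, {
    barcodes <- generate_barcodes(config$n_samples, config$barcode_len)

    # precompute isoform transcripts per allele x signature
    prof <- config$splice_profile
    iso <- vector("list", nrow(truth$alleles))
    for (i in seq_len(nrow(truth$alleles))) {
      g <- truth$alleles$genomic[i]
      m <- truth$alleles$model[[i]]
      iso[[i]] <- map_chr(prof$events, ~ simulate_isoform(g, m, .x))
    }
    names(iso) <- truth$alleles$allele_id

    out_reads <- vector("list", config$n_samples)
    out_truth <- vector("list", config$n_samples)
    rid <- 0L
    for (s in seq_len(config$n_samples)) {
      samp <- sprintf("S%02d", s)
      gt <- truth$genotypes[truth$genotypes$sample == samp, ]
      bc <- barcodes[barcodes$sample == samp, ]
      rc_rev <- revcomp(bc$rev_barcode)
      n <- config$reads_per_sample
      allele_pick <- sample(gt$allele_id, n, replace = TRUE)
      sig_pick <- sample.int(nrow(prof), n, replace = TRUE,
                             prob = prof$weight)
      pass <- stats::runif(n) < config$rq_pass_frac
      rq <- ifelse(pass, 0.99 + stats::runif(n) * 0.00999,
                   0.95 + stats::runif(n) * 0.04)
      flip <- stats::runif(n) < 0.5
      seqs <- character(n)
      nerr <- integer(n)
      for (r in seq_len(n)) {
        tx <- iso[[allele_pick[r]]][sig_pick[r]]
        e <- add_read_errors(tx, config$ccs_error_rate)
        nerr[r] <- e$n_errors
        read <- paste0(bc$fwd_barcode, e$seq, rc_rev)
        if (flip[r]) read <- revcomp(read)
        seqs[r] <- read
      }
      ids <- sprintf("ccs%06d", rid + seq_len(n))
      rid <- rid + n
      out_reads[[s]] <- tibble(id = ids, seq = seqs, rq = round(rq, 4))
      out_truth[[s]] <- tibble(
        id = ids, sample = samp, species = gt$species[1], run = gt$run[1],
        allele_id = allele_pick, signature_id = prof$signature_id[sig_pick],
        n_errors = nerr, flipped = flip
      )
    }
    structure(
      list(reads = list_rbind(out_reads), barcodes = barcodes,
           truth_reads = list_rbind(out_truth)),
      class = "lilr_readset"
    )
  })
}

#' @export
print.lilr_readset <- function(x, ...) {
  cat(sprintf("<lilr_readset> %d reads over %d samples\n",
              nrow(x$reads), nrow(x$barcodes)))
  invisible(x)
}
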