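#' CCS read pre-processing
#'
#' Circular consensus reads are filtered for high read quality (0.99 or
#' higher) and demultiplexed on their unique dual 16-bp barcodes.
#'
#' @name read_processing
NULL

#' Write CCS reads to FASTQ
#'
#' The read-quality value is carried as an `rq=` comment tag on the header
#' line; base qualities are a flat Phred score derived from `rq`.
#'
#' @param reads Tibble with columns `id`, `seq`, `rq`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_ccs_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "rq") %in% names(reads)))
  q <- pmin(93L, pmax(2L, round(-10 * log10(pmax(1 - reads$rq, 1e-10)))))
  qual <- Biostrings::BStringSet(vapply(
    seq_len(nrow(reads)),
    function(i) strrep(intToUtf8(q[i] + 33L), nchar(reads$seq[i])),
    character(1)
  ))
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- sprintf("%s rq=%.4f", reads$id, reads$rq)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read CCS reads from FASTQ
#'
#' @param path FASTQ path (headers carrying `rq=` comment tags).
#' @param on_missing_rq What to do with reads lacking an `rq` tag:
#'   `"fail"` (default) or `"na"` (keep with `rq = NA`).
#' @return Tibble with columns `id`, `seq`, `rq`.
#' @export
read_ccs_fastq <- function(path, on_missing_rq = c("fail", "na")) {
  on_missing_rq <- match.arg(on_missing_rq)
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  hdr <- names(dna)
  id <- stringr::str_extract(hdr, "^\\S+")
  rq <- suppressWarnings(
    as.numeric(stringr::str_match(hdr, "\\brq=([0-9.]+)")[, 2])
  )
  if (anyNA(rq) && on_missing_rq == "fail") {
    abort(sprintf("read %s lacks an rq tag", id[which(is.na(rq))[1]]))
  }
  tibble(id = id, seq = unname(as.character(dna)), rq = rq)
}

#' Filter CCS reads by read quality
#'
#' Retains exactly the reads with `rq >= threshold` (default 0.99, the
#' conventional CCS high-quality cutoff), preserving input order.
#'
#' @param reads Tibble with columns `id`, `seq`, `rq`.
#' @param threshold Read-quality threshold in `[0, 1]`.
#' @param on_missing_rq `"fail"` (default) on reads with `NA` rq, or
#'   `"drop"` to discard them.
#' @return The retained rows, with attributes `n_in`/`n_out` recording the
#'   filter tally.
#' @export
filter_by_quality <- function(reads, threshold = 0.99,
                              on_missing_rq = c("fail", "drop")) {
  on_missing_rq <- match.arg(on_missing_rq)
  stopifnot(threshold >= 0, threshold <= 1)
  if (anyNA(reads$rq)) {
    if (on_missing_rq == "fail") abort("reads lacking an rq value")
    reads <- reads[!is.na(reads$rq), ]
  }
  out <- reads[reads$rq >= threshold, ]
  attr(out, "n_in") <- nrow(reads)
  attr(out, "n_out") <- nrow(out)
  out
}

barcode_int_matrix <- function(barcodes) {
  do.call(rbind, lapply(barcodes, utf8ToInt))
}

# Validate a barcode manifest against the uniqueness precondition: for any
# two samples the joint (fwd + rev) barcode distance must exceed
# 2 * max_mismatch, so no read can match two samples within tolerance.
check_barcode_manifest <- function(manifest, max_mismatch) {
  stopifnot(all(c("sample", "fwd_barcode", "rev_barcode") %in%
                  names(manifest)))
  if (anyDuplicated(manifest$sample)) abort("duplicate sample ids")
  lens <- nchar(c(manifest$fwd_barcode, manifest$rev_barcode))
  if (length(unique(lens)) != 1L) abort("barcodes must share one length")
  n <- nrow(manifest)
  if (n < 2L) return(invisible(manifest))
  fm <- barcode_int_matrix(manifest$fwd_barcode)
  rm_ <- barcode_int_matrix(manifest$rev_barcode)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum(fm[i, ] != fm[j, ]) + sum(rm_[i, ] != rm_[j, ])
      if (d <= 2L * max_mismatch) {
        abort(sprintf(
          "samples %s and %s have barcodes within 2*max_mismatch (%d)",
          manifest$sample[i], manifest$sample[j], d))
      }
    }
  }
  invisible(manifest)
}

#' Demultiplex CCS reads on dual barcodes
#'
#' Each read is compared, in both orientations, against every sample's
#' forward/reverse barcode pair; it is assigned to the unique sample
#' matching within `max_mismatch` mismatches at both ends (the orientation
#' with the better joint score wins; joint-score ties between samples or
#' orientations leave the read unassigned). Barcodes are trimmed from
#' assigned reads and reads are normalized to forward orientation.
#'
#' @param reads Tibble with columns `id`, `seq` (and any others, carried
#'   through).
#' @param manifest Barcode manifest: `sample`, `fwd_barcode`, `rev_barcode`.
#' @param max_mismatch Mismatches tolerated per barcode (default 1).
#' @return The input tibble with added columns `sample` (`NA` for
#'   unassigned), `flipped`, and `seq` trimmed for assigned reads.
#' @export
demultiplex <- function(reads, manifest, max_mismatch = 1L) {
  check_barcode_manifest(manifest, max_mismatch)
  L <- nchar(manifest$fwd_barcode[1])
  fm <- barcode_int_matrix(manifest$fwd_barcode)
  rm_ <- barcode_int_matrix(manifest$rev_barcode)
  n_samp <- nrow(manifest)

  assign_one <- function(seq_fwd, seq_rev) {
    # returns c(sample_index or NA, flipped)
    best_d <- Inf; best_i <- NA_integer_; best_flip <- NA; tie <- FALSE
    for (o in 1:2) {
      s <- if (o == 1L) seq_fwd else seq_rev
      f_obs <- utf8ToInt(substr(s, 1L, L))
      r_obs <- utf8ToInt(revcomp(substr(s, nchar(s) - L + 1L, nchar(s))))
      df <- rowSums(fm != matrix(f_obs, n_samp, L, byrow = TRUE))
      dr <- rowSums(rm_ != matrix(r_obs, n_samp, L, byrow = TRUE))
      ok <- df <= max_mismatch & dr <= max_mismatch
      if (!any(ok)) next
      d <- df + dr
      d[!ok] <- Inf
      i <- which.min(d)
      if (d[i] < best_d) {
        tie <- sum(d == d[i]) > 1L
        best_d <- d[i]; best_i <- i; best_flip <- o == 2L
      } else if (d[i] == best_d) {
        tie <- TRUE
      }
    }
    if (is.infinite(best_d) || tie) c(NA_integer_, NA) else
      c(best_i, best_flip)
  }

  n <- nrow(reads)
  sample_out <- rep(NA_character_, n)
  flipped <- rep(NA, n)
  seq_out <- reads$seq
  if (n > 0L) {
    for (r in seq_len(n)) {
      s <- reads$seq[r]
      if (nchar(s) < 2L * L + 1L) next
      rc <- revcomp(s)
      res <- assign_one(s, rc)
      if (!is.na(res[1])) {
        sample_out[r] <- manifest$sample[res[1]]
        flipped[r] <- as.logical(res[2])
        oriented <- if (flipped[r]) rc else s
        seq_out[r] <- substr(oriented, L + 1L, nchar(oriented) - L)
      }
    }
  }
  reads |>
    mutate(seq = seq_out, sample = sample_out, flipped = flipped)
}

#' Per-sample read tally after demultiplexing
#' @param demuxed Output of [demultiplex()].
#' @return Tibble of `sample` (including `"(unassigned)"`) and `n_reads`.
#' @export
demux_counts <- function(demuxed) {
  demuxed |>
    mutate(sample = ifelse(is.na(.data$sample), "(unassigned)",
                           .data$sample)) |>
    count(.data$sample, name = "n_reads")
}
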