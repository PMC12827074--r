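#' Splice events and isoform simulation
#'
#' A splice event is one deviation from the canonical exon chain of a gene
#' model, described allele-agnostically by its kind, the exon it affects and
#' a signed length change:
#'
#' * `exon_skip` - the exon is absent (`delta_bp = 0`; the skipped length
#'   is the exon's own length, kept in the model);
#' * `alt_3ss` - the acceptor (upstream) boundary shifts: positive
#'   `delta_bp` retains the last `delta_bp` bases of the preceding intron,
#'   negative truncates the exon start;
#' * `alt_5ss` - the donor (downstream) boundary shifts into the exon
#'   (negative `delta_bp`, truncation); donor-side extensions are
#'   classified as intron retention;
#' * `intron_retention` - the exon extends `delta_bp` bases contiguously
#'   into the following intron (`delta_bp > 0`);
#' * `micro_insertion` - a 1-2 bp acceptor-side insertion (the premature
#'   stop generator observed at the start of exon 10).
#'
#' An isoform signature is a tibble of such events, one row per event.
#'
#' @name splice_events
NULL

EVENT_KINDS <- c("exon_skip", "alt_3ss", "alt_5ss",
                 "intron_retention", "micro_insertion")

#' Construct a splice-event signature
#'
#' @param kind Character vector of event kinds (see [splice_events]).
#' @param exon Integer vector of affected exon numbers.
#' @param delta_bp Signed length changes in bp (0 for `exon_skip`).
#' @return A tibble with columns `kind`, `exon`, `delta_bp`, ordered by
#'   exon, validated against the per-kind invariants.
#' @export
splice_signature <- function(kind = character(), exon = integer(),
                             delta_bp = integer()) {
  sig <- tibble(kind = as.character(kind), exon = as.integer(exon),
                delta_bp = as.integer(delta_bp)) |>
    arrange(.data$exon, .data$kind)
  validate_signature(sig)
  sig
}

validate_signature <- function(sig) {
  bad <- !sig$kind %in% EVENT_KINDS
  if (any(bad)) abort(sprintf("unknown event kind: %s", sig$kind[bad][1]))
  ok <- with(sig, (kind == "exon_skip" & delta_bp == 0L) |
               (kind == "alt_3ss" & delta_bp != 0L) |
               (kind == "alt_5ss" & delta_bp < 0L) |
               (kind == "intron_retention" & delta_bp > 0L) |
               (kind == "micro_insertion" & delta_bp %in% 1:2))
  if (!all(ok)) {
    abort(sprintf("invalid delta_bp for %s event at exon %d",
                  sig$kind[!ok][1], sig$exon[!ok][1]))
  }
  skipped <- sig$exon[sig$kind == "exon_skip"]
  clash <- sig$kind != "exon_skip" & sig$exon %in% skipped
  if (any(clash)) {
    abort(sprintf("incompatible events: boundary event on skipped exon %d",
                  sig$exon[clash][1]))
  }
  dup <- duplicated(sig[, c("exon", "kind")])
  if (any(dup)) abort("duplicated event for one exon/kind")
  # one acceptor-side and one donor-side event per exon at most
  acceptor <- sig$kind %in% c("alt_3ss", "micro_insertion")
  donor <- sig$kind %in% c("alt_5ss", "intron_retention")
  if (anyDuplicated(sig$exon[acceptor]) ||
      anyDuplicated(sig$exon[donor])) {
    abort("incompatible events: two events on the same splice site")
  }
  invisible(sig)
}

#' Compact labels for splice signatures
#'
#' `signature_label()` renders a signature as a short string (`"C"` for the
#' canonical mRNA, e.g. `"alt3ss10+3,skip15"`); `parse_signature()` parses
#' the same format back (used in configuration files and reports).
#'
#' @param sig A splice-signature tibble.
#' @return `signature_label()` a single string; `parse_signature()` a
#'   signature tibble.
#' @export
signature_label <- function(sig) {
  if (nrow(sig) == 0L) return("C")
  lab <- map_chr(seq_len(nrow(sig)), function(i) {
    k <- sig$kind[i]
    switch(k,
      exon_skip = sprintf("skip%d", sig$exon[i]),
      alt_3ss = sprintf("alt3ss%d%+d", sig$exon[i], sig$delta_bp[i]),
      alt_5ss = sprintf("alt5ss%d%+d", sig$exon[i], sig$delta_bp[i]),
      intron_retention = sprintf("ret%d+%d", sig$exon[i], sig$delta_bp[i]),
      micro_insertion = sprintf("micro%d+%d", sig$exon[i], sig$delta_bp[i])
    )
  })
  paste(lab, collapse = ",")
}

#' @rdname signature_label
#' @param label A signature label string.
#' @export
parse_signature <- function(label) {
  if (identical(label, "C") || label == "") return(splice_signature())
  parts <- strsplit(label, ",", fixed = TRUE)[[1]]
  m <- stringr::str_match(parts,
    "^(skip|alt3ss|alt5ss|ret|micro)(\\d+)([+-]\\d+)?$")
  if (anyNA(m[, 1])) abort(sprintf("cannot parse event label: %s",
                                   parts[is.na(m[, 1])][1]))
  kind <- c(skip = "exon_skip", alt3ss = "alt_3ss", alt5ss = "alt_5ss",
            ret = "intron_retention", micro = "micro_insertion")[m[, 2]]
  delta <- ifelse(is.na(m[, 4]), 0L, as.integer(m[, 4]))
  splice_signature(kind, as.integer(m[, 3]), delta)
}

# Per-exon transcript intervals (genomic 1-based inclusive) after applying
# a signature to a model. Returns tibble(exon, g_start, g_end).
isoform_blocks <- function(model, signature) {
  validate_signature(signature)
  ex <- model$exons[model$exons$in_mrna, ]
  unknown <- setdiff(signature$exon, ex$exon)
  if (length(unknown) > 0L) {
    abort(sprintf("event on exon %d outside the mature mRNA", unknown[1]))
  }
  blocks <- tibble(exon = ex$exon, g_start = ex$start, g_end = ex$end)
  for (i in seq_len(nrow(signature))) {
    e <- signature$exon[i]
    d <- signature$delta_bp[i]
    j <- match(e, blocks$exon)
    switch(signature$kind[i],
      exon_skip = { blocks$g_start[j] <- NA_integer_ },
      alt_3ss = ,
      micro_insertion = { blocks$g_start[j] <- blocks$g_start[j] - d },
      alt_5ss = { blocks$g_end[j] <- blocks$g_end[j] + d },
      intron_retention = { blocks$g_end[j] <- blocks$g_end[j] + d }
    )
  }
  blocks <- blocks[!is.na(blocks$g_start), ]
  if (any(blocks$g_end < blocks$g_start)) {
    abort("event removes more bases than the exon holds")
  }
  if (any(blocks$g_start[-1] <= blocks$g_end[-nrow(blocks)])) {
    abort("incompatible events: adjacent blocks overlap")
  }
  blocks
}

#' Simulate a spliced isoform transcript
#'
#' Applies a splice-event signature to a genomic allele under its gene
#' model and returns the resulting transcript. Deterministic.
#'
#' @param genomic Genomic allele sequence.
#' @param model The allele's `gene_model`.
#' @param signature A signature tibble from [splice_signature()] (empty =
#'   canonical mature mRNA).
#' @return Transcript sequence (character string).
#' @export
simulate_isoform <- function(genomic, model, signature = splice_signature()) {
  check_genomic(model, genomic)
  blocks <- isoform_blocks(model, signature)
  paste(substring(genomic, blocks$g_start, blocks$g_end), collapse = "")
}
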