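#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Broom-style tidiers for lilrseq result objects
#'
#' `tidy()` returns one row per elementary result (pairwise distance,
#' allele-lineage assignment, read-count entry); `glance()` returns a
#' one-row summary of a pipeline run.
#'
#' @param x A `lilr_dist`, `lilr_lineages` or `lilr_report` object.
#' @param ... Unused.
#' @name lilr_tidiers
NULL

#' @rdname lilr_tidiers
#' @export
tidy.lilr_lineages <- function(x, ...) {
  as_tibble(x)
}

#' @rdname lilr_tidiers
#' @export
glance.lilr_report <- function(x, ...) {
  tibble(
    n_reads_in = x$counts$n_reads_in,
    n_reads_pass_rq = x$counts$n_reads_pass_rq,
    n_reads_assigned = x$counts$n_reads_assigned,
    n_samples = x$counts$n_samples,
    library_version = x$library$version,
    n_library_entries = nrow(x$library$entries),
    n_alleles_called = length(unique(x$calls$allele_parent)),
    n_confirmed_variants = x$counts$n_confirmed_variants,
    n_novel_alleles = x$counts$n_novel_alleles,
    n_lineages = length(unique(x$lineages$lineage)),
    n_shared_events = nrow(x$shared_events)
  )
}

#' @rdname lilr_tidiers
#' @export
tidy.lilr_report <- function(x, ...) {
  x$calls
}
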