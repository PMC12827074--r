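#' LILRB allele nomenclature for Old World monkey species
#'
#' Names follow the proposed grammar `Mamu-LILRB1*001:01:01:01`: a
#' four-letter taxon prefix (first two letters of the genus + first two of
#' the species, per the published examples Mamu/Mafa/Paha), a hyphen, the
#' gene name, an asterisk, then colon-separated fields: a 3-digit lineage
#' (a group of alleles clustering together in phylogenetic analyses) and
#' up to three 2-digit fields for allelic (nonsynonymous) variation,
#' synonymous coding variation and non-coding variation. The suffix `Sp`
#' marks an allele described from a splice-variant transcript
#' (e.g. `Paha-LILRB2*013:01Sp`).
#'
#' @name allele_nomenclature
NULL

#' Taxon prefix from genus and species
#' @param genus,species Scientific name parts (e.g. `"Macaca"`,
#'   `"mulatta"`).
#' @return Four-letter prefix, e.g. `"Mamu"`.
#' @export
taxon_prefix <- function(genus, species) {
  stopifnot(nchar(genus) >= 2L, nchar(species) >= 2L)
  paste0(
    toupper(substr(genus, 1L, 1L)), tolower(substr(genus, 2L, 2L)),
    tolower(substr(species, 1L, 2L))
  )
}

#' Construct an allele name object
#'
#' @param prefix Four-letter taxon prefix (or supply `genus`/`species`).
#' @param gene Gene label (e.g. `"LILRB1"`).
#' @param lineage Lineage number (1-999) or 3-digit string.
#' @param allele Allelic-variation field (1-99), or `NA` for absent.
#' @param synonymous Synonymous-variation field, or `NA`.
#' @param noncoding Non-coding-variation field, or `NA`.
#' @param sp_suffix `TRUE` for splice-variant designations.
#' @param genus,species Alternative to `prefix`.
#' @return An object of class `allele_name`.
#' @export
allele_name <- function(prefix = NULL, gene, lineage, allele = NA,
                        synonymous = NA, noncoding = NA, sp_suffix = FALSE,
                        genus = NULL, species = NULL) {
  if (is.null(prefix)) {
    if (is.null(genus) || is.null(species)) {
      abort("supply `prefix` or both `genus` and `species`")
    }
    prefix <- taxon_prefix(genus, species)
  }
  if (!grepl("^[A-Z][a-z]{3}$", prefix)) {
    abort("prefix must be four letters, first capitalized")
  }
  if (is.na(allele) && (!is.na(synonymous) || !is.na(noncoding))) {
    abort("field 3/4 requires field 2")
  }
  if (is.na(synonymous) && !is.na(noncoding)) {
    abort("field 4 requires field 3")
  }
  check2 <- function(x, what) {
    if (is.na(x)) return(NA_integer_)
    x <- as.integer(x)
    if (x < 1L || x > 99L) abort(sprintf("%s field must be in 1..99", what))
    x
  }
  lineage <- as.integer(lineage)
  if (lineage < 1L || lineage > 999L) abort("lineage must be in 1..999")
  structure(
    list(prefix = prefix, gene = gene, lineage = lineage,
         allele = check2(allele, "allele"),
         synonymous = check2(synonymous, "synonymous"),
         noncoding = check2(noncoding, "noncoding"),
         sp_suffix = isTRUE(sp_suffix)),
    class = "allele_name"
  )
}

#' Format an allele name
#' @param x An `allele_name` object.
#' @return The text form, e.g. `"Mamu-LILRB1*001:01:01:01"`.
#' @export
format_name <- function(x) {
  stopifnot(inherits(x, "allele_name"))
  fields <- c(sprintf("%03d", x$lineage),
              sprintf("%02d", c(x$allele, x$synonymous, x$noncoding)))
  fields <- fields[!grepl("NA", fields)]
  paste0(x$prefix, "-", x$gene, "*", paste(fields, collapse = ":"),
         if (x$sp_suffix) "Sp" else "")
}

#' @export
format.allele_name <- function(x, ...) format_name(x)

#' @export
print.allele_name <- function(x, ...) {
  cat(format_name(x), "\n")
  invisible(x)
}

#' Parse an allele name
#'
#' @param text A name such as `"Paha-LILRB2*013:01Sp"`.
#' @return An `allele_name` object; malformed input raises a parse error
#'   reporting the offending position.
#' @export
parse_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  re <- paste0(
    "^([A-Z][a-z]{3})-([A-Za-z0-9]+)\\*",
    "(\\d{3})(?::(\\d{2}))?(?::(\\d{2}))?(?::(\\d{2}))?(Sp)?$"
  )
  m <- stringr::str_match(text, re)
  if (is.na(m[1, 1])) {
    # locate the first position where the name stops conforming
    probe <- function(t) {
      grepl(paste0("^([A-Z]([a-z]([a-z]([a-z](-([A-Za-z0-9]+(\\*(\\d",
                   "[0-9:Sp]*)?)?)?)?)?)?)?)?$"), t)
    }
    pos <- 1L
    while (pos <= nchar(text) && probe(substr(text, 1L, pos))) pos <- pos + 1L
    abort(sprintf("cannot parse allele name %s (near position %d)",
                  text, pos),
          class = "lilr_parse_error")
  }
  toi <- function(s) if (is.na(s)) NA_integer_ else as.integer(s)
  allele_name(
    prefix = m[1, 2], gene = m[1, 3], lineage = as.integer(m[1, 4]),
    allele = toi(m[1, 5]), synonymous = toi(m[1, 6]),
    noncoding = toi(m[1, 7]), sp_suffix = !is.na(m[1, 8])
  )
}

#' Name newly discovered alleles within their lineages
#'
#' Within each lineage the first allele (discovery order) becomes the
#' lineage reference (`*NNN:01`). Every further allele is compared against
#' the reference: any nonsynonymous coding difference opens a new allelic
#' field-2 value; otherwise a synonymous coding difference opens a new
#' field-3 value; otherwise (intron/UTR-only differences) a new field-4
#' value.
#'
#' @param lineages A `lilr_lineages` assignment.
#' @param alleles Tibble with columns `allele_id`, `genomic`, `model`
#'   (list-column), aligned with the assignment's `allele` ids.
#' @param prefix Taxon prefix for the names.
#' @param gene Gene label.
#' @param sp_alleles Character vector of allele ids to be flagged `Sp`
#'   (described from splice-variant transcripts).
#' @return Tibble: `allele_id`, `lineage`, `name`.
#' @export
name_alleles <- function(lineages, alleles, prefix = "Mamu",
                         gene = "LILRB1", sp_alleles = character()) {
  stopifnot(all(lineages$allele %in% alleles$allele_id))
  out <- list()
  for (lin in unique(lineages$lineage)) {
    ids <- lineages$allele[lineages$lineage == lin]
    rows <- alleles[match(ids, alleles$allele_id), ]
    ref_cds <- extract_cds(rows$model[[1]], rows$genomic[1])
    ref_prot <- translate_dna(ref_cds)
    counters <- c(allele = 1L, syn = 1L, nonc = 1L)
    fields <- list(c(1L, 1L, 1L))
    for (i in seq_len(nrow(rows))[-1]) {
      cds <- extract_cds(rows$model[[i]], rows$genomic[i])
      prot <- translate_dna(cds)
      if (nchar(prot) != nchar(ref_prot) || prot != ref_prot) {
        counters["allele"] <- counters["allele"] + 1L
        fields[[i]] <- c(counters[["allele"]], 1L, 1L)
      } else if (cds != ref_cds) {
        counters["syn"] <- counters["syn"] + 1L
        fields[[i]] <- c(fields[[1]][1], counters[["syn"]], 1L)
      } else {
        counters["nonc"] <- counters["nonc"] + 1L
        fields[[i]] <- c(fields[[1]][1], 1L, counters[["nonc"]])
      }
    }
    out[[length(out) + 1L]] <- tibble(
      allele_id = ids,
      lineage = lin,
      name = map_chr(seq_along(ids), function(i) {
        f <- fields[[i]]
        format_name(allele_name(
          prefix = prefix, gene = gene, lineage = as.integer(lin),
          allele = f[1], synonymous = f[2], noncoding = f[3],
          sp_suffix = ids[i] %in% sp_alleles
        ))
      })
    )
  }
  list_rbind(out)
}
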