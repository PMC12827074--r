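#' Reference-library and table I/O
#'
#' Reference libraries travel as FASTA with structured headers
#' `name|gene|species|source`; stage outputs are plain TSV.
#'
#' @name library_io
NULL

#' Write a reference library to FASTA
#' @param lib A `reference_library`.
#' @param path Output FASTA path.
#' @param species Species tag written into the headers.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(lib, path, species = "Mamu") {
  dna <- Biostrings::DNAStringSet(lib$entries$sequence)
  names(dna) <- sprintf("%s|%s|%s|%s", lib$entries$name, lib$entries$gene,
                        species, lib$entries$source)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Load a reference allele library from FASTA
#'
#' Headers must follow `name|gene|species|source`; in strict mode names
#' must additionally parse under the allele-name grammar. Malformed
#' headers are reported with their record number.
#'
#' @param path FASTA path.
#' @param strict Validate names with [parse_name()].
#' @return A `reference_library`; an empty FASTA yields an empty library
#'   with a warning.
#' @export
load_reference_library <- function(path, strict = FALSE) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) {
    warn("empty reference FASTA")
    return(structure(
      list(entries = tibble(name = character(), sequence = character(),
                            gene = character(), source = character(),
                            parent = character()),
           version = 1L),
      class = "reference_library"
    ))
  }
  parts <- stringr::str_split(names(dna), stringr::fixed("|"))
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed FASTA header at record %d: %s",
                  bad[1], names(dna)[bad[1]]))
  }
  entries <- tibble(
    name = map_chr(parts, 1L),
    sequence = unname(as.character(dna)),
    gene = map_chr(parts, 2L),
    source = map_chr(parts, ~ if (length(.x) >= 4L) .x[[4]] else "published")
  )
  if (strict) {
    for (i in seq_len(nrow(entries))) {
      base <- sub("Sp$", "", entries$name[i])
      tryCatch(parse_name(paste0(base, "")), error = function(e) {
        abort(sprintf("record %d: %s", i, conditionMessage(e)),
              class = "lilr_parse_error")
      })
    }
  }
  if (anyDuplicated(entries$name)) abort("duplicate names in library FASTA")
  dup <- duplicated(paste(entries$gene, entries$sequence))
  if (any(dup)) {
    warn(sprintf("duplicate sequence under different names (e.g. %s); both kept",
                 entries$name[which(dup)[1]]))
  }
  structure(list(entries = mutate(entries, parent = .data$name),
                 version = 1L),
            class = "reference_library")
}

#' Write pipeline artifact tables to a directory
#' @param artifacts Named list of data frames.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(artifacts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- map_chr(names(artifacts), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- artifacts[[nm]]
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })
  invisible(paths)
}
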