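#' Exon-intron gene models for LILRB-family genes
#'
#' A `gene_model` records the ordered exon/intron architecture of a
#' LILRB-family gene on a genomic allele sequence, which exons contribute to
#' the mature mRNA, where translation starts and stops, and which structural
#' region of the receptor each exon encodes. LILRB1 has 16 exons of which 14
#' encode the mature mRNA; the start codon lies in exon 3 and the stop codon
#' at the beginning of exon 16, 147 bp into it. The four extracellular
#' Ig-like domains D1-D4 are encoded by exons 5-8, the stem by exons 9-10,
#' the transmembrane segment by exon 11 and the cytoplasmic tail (carrying
#' the ITIMs) by exons 12-16. For LILRB2, exon 1 and intron 1 cannot be
#' resolved in public assemblies, so LILRB2 models begin at exon 2.
#'
#' All coordinates are 1-based inclusive, both internally and in reports.
#'
#' @name gene_model
NULL

# Structural region of each exon under the shared LILRB1/LILRB2 layout
# (genomic exon numbering).
default_domain_map <- function(exon) {
  dplyr::case_when(
    exon <= 2 ~ "UTR",
    exon <= 4 ~ "leader",
    exon == 5 ~ "D1",
    exon == 6 ~ "D2",
    exon == 7 ~ "D3",
    exon == 8 ~ "D4",
    exon <= 10 ~ "stem",
    exon == 11 ~ "TM",
    TRUE ~ "Cyt"
  )
}

#' Build a canonical LILRB-family gene model
#'
#' @param gene_name `"LILRB1"` or `"LILRB2"` (any label is accepted; the
#'   default domain map follows the shared LILRB layout).
#' @param exon_lengths Integer vector of exon lengths in bp, ordered along
#'   the gene. Names are ignored; exon numbers are assigned starting at
#'   `first_exon`.
#' @param first_exon Number of the first modeled exon (1 for LILRB1; 2 for
#'   LILRB2, whose exon 1 is unresolved).
#' @param first_mrna_exon First exon contributing to the mature mRNA.
#' @param start_codon_exon Exon containing the start codon.
#' @param utr5_len Length of the 5' UTR inside the start-codon exon (the
#'   start codon begins at `utr5_len + 1` within that exon).
#' @param coding_prefix_len Coding length of the terminal exon, i.e. the
#'   offset (in bp, including the stop codon) at which translation
#'   terminates inside it; 147 for canonical LILRB1.
#' @param intron_lengths Intron lengths in bp (one fewer than exons).
#' @param domain_map Optional named character vector (names = exon numbers)
#'   overriding the default structural-region map.
#' @return An object of class `gene_model`.
#' @examples
#' m <- build_canonical_model("LILRB1", exon_lengths = c(
#'   100, 80, 78, 36, 294, 294, 294, 294, 63, 51, 108, 69, 90, 90, 126, 447
#' ))
#' sum(m$exons$in_mrna) # 14 exons encode the mature mRNA
#' @export
build_canonical_model <- function(gene_name,
                                  exon_lengths,
                                  first_exon = 1L,
                                  first_mrna_exon = 3L,
                                  start_codon_exon = first_mrna_exon,
                                  utr5_len = 30L,
                                  coding_prefix_len = 147L,
                                  intron_lengths = NULL,
                                  domain_map = NULL) {
  exon_lengths <- as.integer(exon_lengths)
  if (length(exon_lengths) == 0L || any(exon_lengths <= 0L)) {
    abort("`exon_lengths` must be non-empty and positive")
  }
  n <- length(exon_lengths)
  exon_no <- seq.int(first_exon, length.out = n)
  stop_codon_exon <- exon_no[n]
  if (coding_prefix_len > exon_lengths[n]) {
    abort("stop-codon offset exceeds the terminal exon length")
  }
  if (!start_codon_exon %in% exon_no || start_codon_exon < first_mrna_exon) {
    abort("`start_codon_exon` must be a mature-mRNA exon")
  }
  if (utr5_len >= exon_lengths[match(start_codon_exon, exon_no)]) {
    abort("5' UTR longer than the start-codon exon")
  }
  if (is.null(intron_lengths)) intron_lengths <- rep(100L, n - 1L)
  intron_lengths <- as.integer(intron_lengths)
  if (length(intron_lengths) != n - 1L || (n > 1L && any(intron_lengths <= 0L))) {
    abort("`intron_lengths` must have one entry per intron, all positive")
  }

  starts <- cumsum(c(1L, exon_lengths[-n] + intron_lengths))
  ends <- starts + exon_lengths - 1L
  in_mrna <- exon_no >= first_mrna_exon
  region <- default_domain_map(exon_no)
  if (!is.null(domain_map)) {
    hit <- match(as.character(exon_no), names(domain_map))
    region[!is.na(hit)] <- domain_map[hit[!is.na(hit)]]
  }

  coding_len <- ifelse(in_mrna, exon_lengths, 0L)
  i_start <- match(start_codon_exon, exon_no)
  coding_len[exon_no < start_codon_exon] <- 0L
  coding_len[i_start] <- exon_lengths[i_start] - utr5_len
  coding_len[n] <- coding_prefix_len
  if (sum(coding_len) %% 3L != 0L) {
    abort("total coding length is not a multiple of 3")
  }

  model <- structure(
    list(
      gene_name = gene_name,
      exons = tibble(
        exon = exon_no,
        start = starts,
        end = ends,
        length = exon_lengths,
        region = region,
        in_mrna = in_mrna,
        coding_len = as.integer(coding_len),
        itim_count = NA_integer_
      ),
      introns = if (n > 1L) {
        tibble(
          intron = exon_no[-n],
          start = ends[-n] + 1L,
          end = starts[-1L] - 1L,
          length = intron_lengths
        )
      } else {
        tibble(intron = integer(), start = integer(), end = integer(),
               length = integer())
      },
      first_mrna_exon = as.integer(first_mrna_exon),
      start_codon_exon = as.integer(start_codon_exon),
      utr5_len = as.integer(utr5_len),
      stop_codon_exon = as.integer(stop_codon_exon),
      coding_prefix_len = as.integer(coding_prefix_len),
      genomic_length = unname(ends[n])
    ),
    class = "gene_model"
  )
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s: %d exons (%d in mature mRNA), start codon exon %d, stop exon %d (+%d bp)\n",
    x$gene_name, nrow(x$exons), sum(x$exons$in_mrna),
    x$start_codon_exon, x$stop_codon_exon, x$coding_prefix_len
  ))
  print(x$exons, n = nrow(x$exons))
  invisible(x)
}

#' Exon numbers contributing to the mature mRNA
#' @param model A `gene_model`.
#' @return Integer vector of exon numbers.
#' @export
mature_mrna_exons <- function(model) {
  model$exons$exon[model$exons$in_mrna]
}

#' Structural region encoded by an exon
#'
#' @param model A `gene_model`.
#' @param exon_index Exon number (genomic numbering as in the model).
#' @return Region label (`"D1"`..`"D4"`, `"stem"`, `"TM"`, `"Cyt"`,
#'   `"leader"`, `"UTR"`).
#' @export
domain_of <- function(model, exon_index) {
  i <- match(exon_index, model$exons$exon)
  if (anyNA(i)) abort(sprintf("unknown exon index: %s",
                              paste(exon_index[is.na(i)], collapse = ", ")))
  model$exons$region[i]
}

exon_row <- function(model, exon) {
  i <- match(exon, model$exons$exon)
  if (is.na(i)) abort(sprintf("unknown exon index: %s", exon))
  model$exons[i, ]
}

# Substring of the genomic sequence for one exon.
exon_seq <- function(model, genomic, exon) {
  r <- exon_row(model, exon)
  substr(genomic, r$start, r$end)
}

intron_seq <- function(model, genomic, intron) {
  i <- match(intron, model$introns$intron)
  if (is.na(i)) abort(sprintf("unknown intron index: %s", intron))
  substr(genomic, model$introns$start[i], model$introns$end[i])
}

check_genomic <- function(model, genomic) {
  if (nchar(genomic) != model$genomic_length) {
    abort(
      sprintf("genomic sequence length (%d) inconsistent with model (%d)",
              nchar(genomic), model$genomic_length),
      class = "lilr_structural_error"
    )
  }
}

# Coding sub-interval of an exon in exon-local coordinates, or NULL.
coding_window <- function(model, exon) {
  r <- exon_row(model, exon)
  if (r$coding_len == 0L) return(NULL)
  from <- 1L
  if (exon == model$start_codon_exon) from <- model$utr5_len + 1L
  c(from, from + r$coding_len - 1L)
}

#' Extract the coding sequence from a genomic allele
#'
#' Concatenates the coding portions of the mature-mRNA exons, starting at
#' the start codon and ending at the stop codon inside the terminal exon.
#'
#' @param model A `gene_model`.
#' @param genomic Genomic allele sequence consistent with the model spans.
#' @return The CDS as a character string (length divisible by 3, begins with
#'   `ATG`, ends with a stop codon).
#' @export
extract_cds <- function(model, genomic) {
  check_genomic(model, genomic)
  parts <- map_chr(mature_mrna_exons(model), function(e) {
    w <- coding_window(model, e)
    if (is.null(w)) return("")
    es <- exon_seq(model, genomic, e)
    substr(es, w[1], w[2])
  })
  cds <- paste(parts, collapse = "")
  if (nchar(cds) %% 3L != 0L) {
    abort("coding frame not restorable (length mod 3 != 0)",
          class = "lilr_structural_error")
  }
  if (substr(cds, 1L, 3L) != "ATG") {
    abort("CDS does not begin with a start codon",
          class = "lilr_structural_error")
  }
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% STOP_CODONS) {
    abort("CDS does not end with a stop codon",
          class = "lilr_structural_error")
  }
  cds
}

#' Extract the mature mRNA (canonical transcript) from a genomic allele
#'
#' Concatenates the full mature-mRNA exons, including the 5' UTR portion of
#' the start-codon exon and the 3' UTR portion of the terminal exon.
#'
#' @inheritParams extract_cds
#' @return The canonical transcript as a character string.
#' @export
extract_transcript <- function(model, genomic) {
  check_genomic(model, genomic)
  paste(map_chr(mature_mrna_exons(model), ~ exon_seq(model, genomic, .x)),
        collapse = "")
}

#' Assemble a genomic sequence from exon and intron sequences
#'
#' Inverse of taking exon/intron substrings under a model: interleaves the
#' supplied exon and intron sequences. Lengths must match the model spans.
#'
#' @param model A `gene_model`.
#' @param exon_seqs Character vector of exon sequences, in model order.
#' @param intron_seqs Character vector of intron sequences, in model order.
#' @return Genomic sequence string.
#' @export
assemble_genomic <- function(model, exon_seqs, intron_seqs) {
  n <- nrow(model$exons)
  stopifnot(length(exon_seqs) == n, length(intron_seqs) == n - 1L)
  if (!all(nchar(exon_seqs) == model$exons$length) ||
      (n > 1L && !all(nchar(intron_seqs) == model$introns$length))) {
    abort("exon/intron sequence lengths inconsistent with the model",
          class = "lilr_structural_error")
  }
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, 2L)] <- exon_seqs
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, 2L)] <- intron_seqs
  paste(pieces, collapse = "")
}

# Map CDS codon numbers to exon numbers (a codon split across a junction is
# attributed to the exon holding its first base).
codon_exon_map <- function(model) {
  ex <- model$exons[model$exons$coding_len > 0L, ]
  cum <- cumsum(ex$coding_len)
  n_codon <- sum(ex$coding_len) %/% 3L
  first_base <- (seq_len(n_codon) - 1L) * 3L + 1L
  ex$exon[findInterval(first_base - 1L, c(0L, cum), rightmost.closed = FALSE)]
}

#' Count ITIM motifs in the translated cytoplasmic tail
#'
#' Scans the translated CDS with the classical immunoreceptor
#' tyrosine-based inhibitory motif consensus `(S/I/V/L)-x-Y-x-x-(I/V/L)`
#' (overlapping matches counted) and attributes each motif to the exon
#' encoding its first residue. The canonical LILRB1 tail carries four
#' ITIMs, one of them in exon 15, so skipping exon 15 reduces the count
#' from four to three.
#'
#' @param model A `gene_model`.
#' @param genomic Genomic allele sequence.
#' @param protein Optionally, an already-translated protein (overrides
#'   `genomic`).
#' @return A tibble with columns `exon` and `itims` (exons with >= 1 motif).
#' @export
count_itims <- function(model, genomic = NULL, protein = NULL) {
  if (is.null(protein)) {
    cds <- extract_cds(model, genomic)
    protein <- translate_dna(cds)
  }
  hits <- itim_positions(protein)
  if (length(hits) == 0L) {
    return(tibble(exon = integer(), itims = integer()))
  }
  cmap <- codon_exon_map(model)
  exon_at <- cmap[pmin(hits, length(cmap))]
  tibble(exon = exon_at) |>
    count(.data$exon, name = "itims")
}

# 1-based residue positions where an ITIM starts (overlapping allowed).
itim_positions <- function(protein) {
  m <- gregexpr("(?=([SIVL].Y..[IVL]))", protein, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Annotate a model with per-exon ITIM counts from a genomic allele
#' @inheritParams count_itims
#' @return The model with `exons$itim_count` filled (0 where no motif).
#' @export
annotate_itims <- function(model, genomic) {
  tab <- count_itims(model, genomic)
  model$exons$itim_count <- 0L
  i <- match(tab$exon, model$exons$exon)
  model$exons$itim_count[i] <- tab$itims
  model
}

#' Tabular serialization of a gene model
#'
#' @param model A `gene_model`.
#' @return A tibble with columns `exon_index`, `start`, `end`,
#'   `coding_prefix_len`, `region`, `itim_count` (1-based inclusive
#'   coordinates).
#' @export
gene_model_table <- function(model) {
  model$exons |>
    transmute(
      exon_index = .data$exon, start = .data$start, end = .data$end,
      coding_prefix_len = .data$coding_len, region = .data$region,
      itim_count = .data$itim_count
    )
}

#' Write a gene model to TSV (and read it back)
#' @param model A `gene_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_model_tsv <- function(model, path) {
  utils::write.table(gene_model_table(model), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a gene model as GFF3
#'
#' Emits gene, exon and CDS features on a single synthetic contig.
#'
#' @param model A `gene_model`.
#' @param path Output GFF3 path.
#' @param seqid Contig name used in column 1.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff3 <- function(model, path, seqid = model$gene_name) {
  ex <- model$exons
  rows <- c(
    sprintf("%s\tlilrseq\tgene\t%d\t%d\t.\t+\t.\tID=%s",
            seqid, min(ex$start), max(ex$end), model$gene_name),
    sprintf("%s\tlilrseq\texon\t%d\t%d\t.\t+\t.\tID=exon%d;Parent=%s",
            seqid, ex$start, ex$end, ex$exon, model$gene_name)
  )
  cds <- ex[ex$coding_len > 0L, ]
  if (nrow(cds) > 0L) {
    cstart <- cds$start
    cend <- cds$end
    i1 <- which(cds$exon == model$start_codon_exon)
    cstart[i1] <- cstart[i1] + model$utr5_len
    iN <- nrow(cds)
    cend[iN] <- cstart[iN] + model$coding_prefix_len - 1L
    rows <- c(rows, sprintf(
      "%s\tlilrseq\tCDS\t%d\t%d\t.\t+\t.\tID=cds%d;Parent=%s",
      seqid, cstart, cend, cds$exon, model$gene_name
    ))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
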