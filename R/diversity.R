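#' Diversity statistics over allele sets
#'
#' Per-position amino-acid variability (the count of unique residues at
#' each alignment position), per-exon synonymous/non-synonymous mutation
#' density normalized to exon coding length, grouping of alleles by shared
#' D1/D2 peptide identity, and position-wise residue frequency tables.
#'
#' @name diversity_stats
NULL

aa_matrix <- function(aa_alignment) {
  if (length(aa_alignment) == 0L) abort("empty alignment")
  lens <- unique(nchar(aa_alignment))
  if (length(lens) != 1L) abort("sequences must be aligned (equal length)")
  m <- do.call(rbind, strsplit(toupper(aa_alignment), ""))
  rownames(m) <- names(aa_alignment)
  m
}

#' Per-position amino-acid variability profile
#'
#' Counts the number of unique amino acids encountered at each position of
#' a protein alignment. Gap and unknown characters (`-`, `.`, `X`, `*`)
#' are excluded from the count by default.
#'
#' @param aa_alignment Character vector of aligned protein sequences.
#' @param count_gaps Count gap characters as a residue state.
#' @return Tibble: `position`, `n_residues`.
#' @export
variability_profile <- function(aa_alignment, count_gaps = FALSE) {
  m <- aa_matrix(aa_alignment)
  excluded <- c("-", ".", "X", "*")
  counts <- apply(m, 2L, function(col) {
    if (!count_gaps) col <- col[!col %in% excluded]
    length(unique(col))
  })
  tibble(position = seq_along(counts), n_residues = as.integer(counts))
}

#' Per-exon synonymous/non-synonymous mutation density
#'
#' For each variable codon position of a codon-aligned CDS set, every
#' observed alternative codon is classified against the consensus
#' (majority) codon as synonymous (same residue) or non-synonymous;
#' counts are accumulated per exon and normalized to the exon's coding
#' length. A codon altered at several positions counts as one mutation
#' event, classified by its net residue effect.
#'
#' @param cds_alignment Character vector of equal-length CDS sequences in
#'   frame (no gaps; length a multiple of 3).
#' @param model The `gene_model` providing exon coding lengths.
#' @return Tibble: `exon`, `region`, `coding_len`, `S`, `NS`,
#'   `S_density`, `NS_density`.
#' @export
exon_mutation_density <- function(cds_alignment, model) {
  if (length(cds_alignment) == 0L) abort("empty alignment")
  lens <- unique(nchar(cds_alignment))
  if (length(lens) != 1L || lens %% 3L != 0L) {
    abort("CDS set must be codon-aligned (equal length, multiple of 3)")
  }
  cmap <- codon_exon_map(model)
  n_codon <- lens %/% 3L
  if (n_codon != length(cmap)) {
    abort("alignment length inconsistent with the model's coding length")
  }
  code <- Biostrings::GENETIC_CODE
  codon_mat <- do.call(rbind, lapply(cds_alignment, codons_of))
  S <- integer(nrow(model$exons))
  NS <- integer(nrow(model$exons))
  names(S) <- names(NS) <- model$exons$exon
  for (j in seq_len(n_codon)) {
    col <- codon_mat[, j]
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) == 1L) next
    consensus <- names(tab)[1]
    e <- as.character(cmap[j])
    for (alt in setdiff(names(tab), consensus)) {
      if (code[[alt]] == code[[consensus]]) S[e] <- S[e] + 1L
      else NS[e] <- NS[e] + 1L
    }
  }
  model$exons |>
    filter(.data$coding_len > 0L) |>
    transmute(
      exon = .data$exon, region = .data$region,
      coding_len = .data$coding_len,
      S = unname(S[as.character(.data$exon)]),
      NS = unname(NS[as.character(.data$exon)]),
      S_density = .data$S / .data$coding_len,
      NS_density = .data$NS / .data$coding_len
    )
}

# Deduced peptide of a genomic allele over a set of structural regions.
region_peptide <- function(genomic, model, regions) {
  cds <- extract_cds(model, genomic)
  prot <- translate_dna(cds)
  cmap <- codon_exon_map(model)
  keep <- model$exons$exon[model$exons$region %in% regions]
  paste(strsplit(prot, "")[[1]][cmap %in% keep], collapse = "")
}

#' Group alleles sharing identical deduced peptides over domains
#'
#' Partitions an allele set by exact peptide identity over one or more
#' structural regions (e.g. D1 = exon 5, D2 = exon 6, or the combined
#' D1-D2), the comparison behind the domain-sharing analysis. Alleles
#' from different species falling in one group are flagged as
#' cross-species sharing.
#'
#' @param alleles Tibble with columns `allele_id`, `genomic`, `model`
#'   (list-column) and optionally `species`.
#' @param regions Character vector of region labels (e.g. `c("D1","D2")`).
#' @return Tibble: `group`, `peptide`, `allele_id`, `species`,
#'   `cross_species`.
#' @export
domain_identity_groups <- function(alleles, regions = "D1") {
  peptides <- map_chr(seq_len(nrow(alleles)), function(i) {
    tryCatch(
      region_peptide(alleles$genomic[i], alleles$model[[i]], regions),
      error = function(e) {
        warn(sprintf("allele %s untranslatable over %s; excluded",
                     alleles$allele_id[i], paste(regions, collapse = "+")))
        NA_character_
      }
    )
  })
  res <- tibble(
    allele_id = alleles$allele_id,
    species = if ("species" %in% names(alleles)) alleles$species else
      NA_character_,
    peptide = peptides
  ) |>
    filter(!is.na(.data$peptide)) |>
    mutate(group = match(.data$peptide, unique(.data$peptide))) |>
    group_by(.data$group) |>
    mutate(cross_species = n_distinct(.data$species) > 1L) |>
    ungroup() |>
    select("group", "peptide", "allele_id", "species", "cross_species") |>
    arrange(.data$group)
  res
}

#' Position-wise residue frequency table
#'
#' Counts each residue at the requested alignment positions (the basis of
#' the stacked-bar representation of MHC alpha-3 domain variation) and
#' reports which of the requested positions are invariant.
#'
#' @param aa_alignment Character vector of aligned protein sequences.
#' @param positions Integer positions to tabulate (default: all).
#' @return Tibble: `position`, `residue`, `count`, `frequency`,
#'   `invariant`.
#' @export
residue_frequency_table <- function(aa_alignment, positions = NULL) {
  m <- aa_matrix(aa_alignment)
  if (is.null(positions)) positions <- seq_len(ncol(m))
  if (any(positions < 1L | positions > ncol(m))) {
    abort("position out of range")
  }
  rows <- map(positions, function(p) {
    tab <- table(m[, p])
    tibble(
      position = p,
      residue = names(tab),
      count = as.integer(tab),
      frequency = as.integer(tab) / sum(tab),
      invariant = length(tab) == 1L
    )
  })
  list_rbind(rows) |> arrange(.data$position, desc(.data$count))
}
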