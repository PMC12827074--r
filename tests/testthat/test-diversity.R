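test_that("variability counts unique residues per column", {
  aln <- c("LLAK", "LVAK", "LVAE", "LIAK")
  prof <- variability_profile(aln)
  expect_equal(prof$n_residues, c(1L, 3L, 1L, 2L))
  # a single sequence is all ones
  expect_true(all(variability_profile("MKVLA")$n_residues == 1L))
  # gaps are excluded from the count by default
  expect_equal(variability_profile(c("L-", "LV", "LV"))$n_residues,
               c(1L, 1L))
  expect_equal(
    variability_profile(c("L-", "LV", "LV"),
                        count_gaps = TRUE)$n_residues[2], 2L)
  expect_error(variability_profile(character()), "empty")
})

test_that("a near-monomorphic allele set shows exactly its two variable sites", {
  # four alleles differing at two residues (one D3, one tail), as in the
  # Hamadryas baboon LILRB1 set
  base <- sub("\\*$", "", fx$protein)
  cmap <- lilrseq:::codon_exon_map(fx$model)
  d3_pos <- which(cmap == 7L)[10]
  tail_pos <- which(cmap == 14L)[5]
  v <- c(base, base, base, base)
  substr(v[2], d3_pos, d3_pos) <- "W"
  substr(v[3], tail_pos, tail_pos) <- "W"
  substr(v[4], d3_pos, d3_pos) <- "W"
  prof <- variability_profile(v)
  expect_equal(which(prof$n_residues > 1L), c(d3_pos, tail_pos))
  expect_equal(prof$n_residues[c(d3_pos, tail_pos)], c(2L, 2L))
})

test_that("exon mutation density classifies and normalizes per exon", {
  cds <- fx$cds
  cmap <- lilrseq:::codon_exon_map(fx$model)
  # synonymous change in exon 5: third base of an exon-5 codon
  j <- which(cmap == 5L)[4]
  codon <- substr(cds, 3 * j - 2, 3 * j)
  syn_alt <- NULL
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
    cand <- paste0(substr(codon, 1, 2), b)
    if (Biostrings::GENETIC_CODE[[cand]] ==
        Biostrings::GENETIC_CODE[[codon]]) syn_alt <- cand
  }
  mut <- cds
  substr(mut, 3 * j - 2, 3 * j) <- syn_alt
  dens <- exon_mutation_density(c(a = cds, b = mut), fx$model)
  expect_equal(dens$S[dens$exon == 5], 1L)
  expect_equal(dens$NS[dens$exon == 5], 0L)
  expect_true(all(dens$S[dens$exon != 5] == 0L))
  expect_equal(dens$S_density[dens$exon == 5], 1 / 294)

  # one NS mutation each in exons 5 (294 bp) and 9 (63 bp): the shorter
  # exon carries the higher density
  j5 <- which(cmap == 5L)[6]
  j9 <- which(cmap == 9L)[3]
  mut2 <- cds
  for (j2 in c(j5, j9)) {
    codon <- substr(cds, 3 * j2 - 2, 3 * j2)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 1, 1))) {
      cand <- paste0(b, substr(codon, 2, 3))
      if (Biostrings::GENETIC_CODE[[cand]] != "*" &&
          Biostrings::GENETIC_CODE[[cand]] !=
          Biostrings::GENETIC_CODE[[codon]]) {
        substr(mut2, 3 * j2 - 2, 3 * j2 - 2) <- b
        break
      }
    }
  }
  dens2 <- exon_mutation_density(c(a = cds, b = mut2), fx$model)
  expect_equal(dens2$NS[dens2$exon == 5], 1L)
  expect_equal(dens2$NS[dens2$exon == 9], 1L)
  expect_lt(dens2$NS_density[dens2$exon == 5],
            dens2$NS_density[dens2$exon == 9])

  # input order invariance
  dens2b <- exon_mutation_density(c(b = mut2, a = cds), fx$model)
  expect_equal(dens2$NS, dens2b$NS)
  expect_equal(dens2$S, dens2b$S)
})

test_that("mutation counts match an exhaustive per-codon oracle", {
  set.seed(77)
  cds <- fx$cds
  n_codon <- nchar(cds) / 3
  seqs <- c(ref = cds)
  for (k in 1:3) {
    mut <- cds
    for (j in sample(n_codon - 1L, 15)) {
      codon <- substr(mut, 3 * j - 2, 3 * j)
      alt <- sample(lilrseq:::NON_STOP_CODONS, 1)
      substr(mut, 3 * j - 2, 3 * j) <- alt
    }
    seqs[paste0("m", k)] <- mut
  }
  dens <- exon_mutation_density(seqs, fx$model)
  # oracle: direct per-codon majority + classification
  cmap <- lilrseq:::codon_exon_map(fx$model)
  S <- NS <- stats::setNames(integer(16), 1:16)
  for (j in seq_len(n_codon)) {
    col <- substring(seqs, 3 * j - 2, 3 * j)
    tab <- sort(table(col), decreasing = TRUE)
    cons <- names(tab)[1]
    for (alt in setdiff(names(tab), cons)) {
      e <- as.character(cmap[j])
      if (Biostrings::GENETIC_CODE[[alt]] ==
          Biostrings::GENETIC_CODE[[cons]]) S[e] <- S[e] + 1L
      else NS[e] <- NS[e] + 1L
    }
  }
  expect_equal(dens$S, unname(S[as.character(dens$exon)]))
  expect_equal(dens$NS, unname(NS[as.character(dens$exon)]))
})

test_that("domain identity groups partition alleles by deduced peptide", {
  g1 <- fx$genomic
  cmap <- lilrseq:::codon_exon_map(fx$model)
  # synonymous-only D1 change: same D1 peptide
  j <- which(cmap == 5L)[8]
  cds_pos <- 3L * j # third base of the codon
  # map CDS position back to genomic
  gmap <- lilrseq:::genomic_to_cds_map(fx$model)
  gp <- which(gmap == cds_pos)
  g2 <- g1
  codon <- substr(fx$cds, 3 * j - 2, 3 * j)
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
    cand <- paste0(substr(codon, 1, 2), b)
    if (Biostrings::GENETIC_CODE[[cand]] ==
        Biostrings::GENETIC_CODE[[codon]]) {
      substr(g2, gp, gp) <- b
      break
    }
  }
  # D2 nonsynonymous change: differs in D2 but not D1
  j6 <- which(cmap == 6L)[8]
  gp6 <- which(gmap == 3L * j6 - 2L)
  g3 <- g1
  codon6 <- substr(fx$cds, 3 * j6 - 2, 3 * j6)
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon6, 1, 1))) {
    cand <- paste0(b, substr(codon6, 2, 3))
    if (Biostrings::GENETIC_CODE[[cand]] != "*" &&
        Biostrings::GENETIC_CODE[[cand]] !=
        Biostrings::GENETIC_CODE[[codon6]]) {
      substr(g3, gp6, gp6) <- b
      break
    }
  }
  alleles <- tibble::tibble(
    allele_id = c("x", "y", "z"),
    genomic = c(g1, g2, g3),
    model = rep(list(fx$model), 3),
    species = c("SpA", "SpB", "SpA"))
  gD1 <- domain_identity_groups(alleles, "D1")
  expect_equal(dplyr::n_distinct(gD1$group), 1L)
  expect_true(all(gD1$cross_species))
  gD2 <- domain_identity_groups(alleles, "D2")
  expect_equal(gD2$group[gD2$allele_id == "x"],
               gD2$group[gD2$allele_id == "y"])
  expect_false(gD2$group[gD2$allele_id == "z"] ==
                 gD2$group[gD2$allele_id == "x"])
  gBoth <- domain_identity_groups(alleles, c("D1", "D2"))
  expect_equal(dplyr::n_distinct(gBoth$group), 2L)
})

test_that("lineage-conserved D1-D2 yields one group per lineage", {
  truth <- simulate_allele_set(
    sim_config(n_lineages = 3L, alleles_per_lineage = 3L,
               intra_lineage_divergence = 0,
               indel_features = tibble::tibble(lineage = integer(),
                                               type = character()),
               n_samples = 4L, reads_per_sample = 10L),
    seed = 91L)
  grp <- domain_identity_groups(
    truth$alleles |> dplyr::rename(allele_id = allele_id), c("D1", "D2"))
  by_lineage <- split(grp$group,
                      truth$alleles$lineage[match(grp$allele_id,
                                                  truth$alleles$allele_id)])
  for (g in by_lineage) expect_equal(dplyr::n_distinct(g), 1L)
})

test_that("residue frequencies sum to one and flag invariant positions", {
  aln <- c("EAKLCD", "EAKLCD", "KAELCD", "KAQLCD")
  tab <- residue_frequency_table(aln)
  sums <- tab |>
    dplyr::group_by(position) |>
    dplyr::summarise(s = sum(frequency))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  p1 <- tab[tab$position == 1, ]
  expect_setequal(p1$residue, c("E", "K"))
  expect_equal(sort(p1$frequency), c(0.5, 0.5))
  invariant <- unique(tab$position[tab$invariant])
  expect_equal(invariant, c(2L, 4L, 5L, 6L))
  expect_error(residue_frequency_table(aln, positions = 99), "range")
  sel <- residue_frequency_table(aln, positions = c(1, 3))
  expect_setequal(sel$position, c(1L, 3L))
})
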