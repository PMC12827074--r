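test_that("all three distances are zero on identity and symmetric", {
  set.seed(101)
  # codon-safe pair (no internal stops) usable by all three distances
  ca <- sample(lilrseq:::NON_STOP_CODONS, 100, TRUE)
  a <- paste(ca, collapse = "")
  b <- a
  for (p in sample(300, 30)) {
    cand <- b
    substr(cand, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(a, p, p)), 1)
    j <- (p - 1) %/% 3
    if (!substr(cand, 3 * j + 1, 3 * j + 3) %in%
        c("TAA", "TAG", "TGA")) b <- cand
  }
  for (f in list(jc_distance, tamura_nei_distance, nei_gojobori_ns)) {
    expect_equal(as.numeric(f(a, a)), 0)
    expect_equal(as.numeric(f(a, b)), as.numeric(f(b, a)))
  }
})

test_that("Jukes-Cantor matches its closed form and saturates at 3/4", {
  a <- strrep("ACGT", 25)
  b <- a
  for (p in 1:10) {
    substr(b, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[
      substr(a, p, p)]
  }
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 4 * 0.1 / 3))
  expect_equal(jc_distance(a, b), 0.1073256, tolerance = 1e-6)
  # gap columns are excluded pairwise
  a_gap <- paste0("--", substr(a, 3, 100))
  expect_equal(jc_distance(a_gap, b),
               -0.75 * log(1 - 4 * (sum(utf8ToInt(substr(a, 3, 100)) !=
                                          utf8ToInt(substr(b, 3, 100))) / 98) / 3))
  sat <- jc_distance(strrep("A", 100), strrep("C", 100))
  expect_true(is.nan(sat))
  expect_true(attr(sat, "saturated"))
})

test_that("Tamura-Nei agrees with an independent implementation", {
  set.seed(7)
  for (rep in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    b <- a
    for (p in sample(500, 40)) {
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(a, p, p)), 1)
    }
    bin <- ape::as.DNAbin(strsplit(c(x = a, y = b), ""))
    expect_equal(tamura_nei_distance(a, b),
                 as.numeric(ape::dist.dna(bin, "TN93",
                                          pairwise.deletion = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("TN exceeds JC on transition-rich pairs; both approach p as p -> 0", {
  a <- strrep("ACGT", 250)
  b <- a
  for (p in seq(1, 120, 4)) { # A -> G transitions only
    substr(b, p, p) <- "G"
  }
  expect_gte(tamura_nei_distance(a, b), jc_distance(a, b))
  # first-order agreement at tiny divergence
  a2 <- strrep("ACGT", 2500)
  b2 <- a2
  substr(b2, 1, 1) <- "G" # p = 1e-4
  expect_lt(abs(jc_distance(a2, b2) - 1e-4), 1e-6)
  expect_lt(abs(tamura_nei_distance(a2, b2) - 1e-4), 1e-6)
})

test_that("Nei-Gojobori matches brute-force pathway enumeration", {
  # the worked single-codon case: TTT (F) -> TTA (L), one nonsyn path
  d <- lilrseq:::codon_path_diffs("TTT", "TTA")
  expect_equal(unname(d["syn"]), 0)
  expect_equal(unname(d["nonsyn"]), 1)
  # distance on a toy two-codon CDS against the independent oracle
  a <- "TTTGGG"
  b <- "TTAGGC"
  expect_equal(nei_gojobori_ns(a, b), oracle_ng_distance(a, b),
               tolerance = 1e-12)
  # random multi-codon alignments
  set.seed(11)
  sense <- lilrseq:::NON_STOP_CODONS
  for (rep in 1:5) {
    ca <- sample(sense, 30, TRUE)
    cb <- vapply(ca, function(cd) {
      if (stats::runif(1) < 0.5) return(cd)
      repeat {
        mut <- cd
        for (p in sample(3, sample(2, 1))) {
          substr(mut, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        if (!mut %in% c("TAA", "TAG", "TGA")) return(mut)
      }
    }, character(1))
    a <- paste(ca, collapse = "")
    b <- paste(cb, collapse = "")
    expect_equal(nei_gojobori_ns(a, b), oracle_ng_distance(a, b),
                 tolerance = 1e-12)
  }
  expect_error(nei_gojobori_ns("ATGTAAGGG", "ATGTAAGGG"), "stop codon")
})

test_that("NJ recovers the generating quartet on additive matrices", {
  set.seed(23)
  for (rep in 1:10) {
    D <- random_additive_quartet()
    tree <- build_nj_tree(D)
    expect_equal(nj_quartet_split(tree), c("a", "b"))
    expect_equal(oracle_quartet_split(D), c("a", "b"))
    # branch lengths are exact on additive input (after clamping no-ops)
    pd <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
    expect_equal(unname(pd), unname(D), tolerance = 1e-9)
  }
  # permuting labels does not change the topology
  D <- random_additive_quartet()
  perm <- c("c", "a", "d", "b")
  t1 <- build_nj_tree(D)
  t2 <- build_nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
  # three taxa have a unique star resolution
  t3 <- build_nj_tree(D[1:3, 1:3])
  expect_equal(t3$Nnode, 1L)
  expect_error(build_nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("negative NJ branches are clamped with the deficit moved", {
  D <- matrix(c(0, 5, 9, 9.5,
                5, 0, 10, 10.5,
                9, 10, 0, 0.2,
                9.5, 10.5, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- build_nj_tree(D)
  expect_true(all(tree$edge.length >= 0))
})

test_that("bootstrap support is seed-reproducible and near-certain for deep splits", {
  truth <- simulate_allele_set(
    sim_config(n_lineages = 2L, alleles_per_lineage = 3L,
               indel_features = tibble::tibble(lineage = integer(),
                                               type = character()),
               n_samples = 4L, reads_per_sample = 10L),
    seed = 51L)
  cds <- purrr::map_chr(seq_len(nrow(truth$alleles)), function(i) {
    extract_cds(truth$alleles$model[[i]], truth$alleles$genomic[i])
  })
  names(cds) <- truth$alleles$allele_id
  t1 <- bootstrap_support(cds, n_reps = 100L, seed = 9L)
  t2 <- bootstrap_support(cds, n_reps = 100L, seed = 9L)
  expect_identical(t1$node.label, t2$node.label)
  # the lineage split is maximally supported at this divergence
  lin1 <- truth$alleles$allele_id[truth$alleles$lineage == 1]
  D <- distance_matrix(cds, "JC")
  lab <- assign_lineages(t1, D)
  expect_equal(dplyr::n_distinct(lab$lineage), 2L)
  split_support <- stats::na.omit(as.numeric(t1$node.label))
  expect_gte(max(split_support), 99)
  t0 <- bootstrap_support(cds, n_reps = 0L, seed = 9L)
  expect_true(all(is.na(t0$node.label)))
})

test_that("lineage assignment recovers simulated lineages exactly", {
  truth <- simulate_allele_set(sim_config(n_samples = 4L,
                                          reads_per_sample = 10L),
                               seed = 61L)
  cds <- purrr::map_chr(seq_len(nrow(truth$alleles)), function(i) {
    extract_cds(truth$alleles$model[[i]], truth$alleles$genomic[i])
  })
  names(cds) <- truth$alleles$allele_id
  aligned <- align_alleles(cds, "dna")   # lineage 3 carries the insert
  D <- distance_matrix(aligned, "JC")
  tree <- bootstrap_support(aligned, n_reps = 100L, seed = 13L)
  lab <- assign_lineages(tree, D)
  agree <- table(lab$lineage,
                 truth$alleles$lineage[match(lab$allele,
                                             truth$alleles$allele_id)])
  # perfect one-to-one correspondence with the simulated labels
  expect_equal(dplyr::n_distinct(lab$lineage), 3L)
  expect_true(all(rowSums(agree > 0) == 1))
  expect_true(all(colSums(agree > 0) == 1))

  # a legacy map pins ids
  pinned <- lab$allele[lab$lineage == "002"][1]
  lab2 <- assign_lineages(tree, D,
                          legacy_map = stats::setNames("007", pinned))
  expect_equal(unique(lab2$lineage[lab2$allele == pinned]), "007")
  # a tiny divergence ceiling produces singleton lineages
  lab3 <- assign_lineages(tree, D, max_intra = 1e-9)
  expect_equal(nrow(lab3), dplyr::n_distinct(lab3$lineage))
})

test_that("allele names format and parse bijectively", {
  expect_equal(
    format_name(allele_name(genus = "Macaca", species = "mulatta",
                            gene = "LILRB1", lineage = 1, allele = 1,
                            synonymous = 1, noncoding = 1)),
    "Mamu-LILRB1*001:01:01:01")
  expect_equal(taxon_prefix("Papio", "hamadryas"), "Paha")
  expect_equal(taxon_prefix("Macaca", "fascicularis"), "Mafa")
  p <- parse_name("Paha-LILRB2*013:01Sp")
  expect_true(p$sp_suffix)
  expect_equal(p$lineage, 13L)
  expect_equal(p$allele, 1L)
  expect_true(is.na(p$synonymous))
  expect_equal(format_name(p), "Paha-LILRB2*013:01Sp")
  expect_error(parse_name("Mamu-LILRB1*1:01"), class = "lilr_parse_error")
  expect_error(parse_name("MAMU-LILRB1*001"), class = "lilr_parse_error")
  expect_error(allele_name(prefix = "Mamu", gene = "LILRB1", lineage = 1,
                           synonymous = 2), "field 3")
})

test_that("newly named alleles partition fields by difference class", {
  g1 <- fx$genomic
  g2 <- g1 # synonymous-only change: third base of a D1 codon
  e5 <- fx$model$exons[fx$model$exons$exon == 5, ]
  # codon boundary: exon 5 starts in frame 0 in the fixture design
  p <- e5$start + 2L
  repeat {
    codon <- substr(g2, p - 2L, p)
    for (b in setdiff(c("A", "C", "G", "T"), substr(g2, p, p))) {
      cand <- paste0(substr(codon, 1, 2), b)
      if (Biostrings::GENETIC_CODE[[cand]] ==
          Biostrings::GENETIC_CODE[[codon]]) {
        substr(g2, p, p) <- b
        break
      }
    }
    if (g2 != g1) break
    p <- p + 3L
  }
  g3 <- g1 # intron-only change
  i5 <- fx$model$introns[fx$model$introns$intron == 5, ]
  p3 <- i5$start + 20L
  substr(g3, p3, p3) <- setdiff(c("A", "C", "G", "T"),
                                substr(g3, p3, p3))[1]
  g4 <- g1 # nonsynonymous change
  p4 <- e5$start + 30L
  repeat {
    codon_start <- p4 - (p4 - e5$start) %% 3L
    codon <- substr(g4, codon_start, codon_start + 2L)
    alt <- paste0("A", substr(codon, 2, 3))
    if (Biostrings::GENETIC_CODE[[alt]] != "*" &&
        Biostrings::GENETIC_CODE[[alt]] !=
        Biostrings::GENETIC_CODE[[codon]]) {
      substr(g4, codon_start, codon_start) <- "A"
      break
    }
    p4 <- p4 + 3L
  }
  alleles <- tibble::tibble(
    allele_id = c("ref", "syn", "nonc", "nonsyn"),
    genomic = c(g1, g2, g3, g4),
    model = rep(list(fx$model), 4))
  lineages <- structure(
    tibble::tibble(allele = alleles$allele_id, lineage = "001",
                   clade_support = 100),
    class = c("lilr_lineages", class(tibble::tibble())))
  named <- name_alleles(lineages, alleles, prefix = "Mamu",
                        gene = "LILRB1")
  expect_equal(named$name[named$allele_id == "ref"],
               "Mamu-LILRB1*001:01:01:01")
  expect_equal(named$name[named$allele_id == "syn"],
               "Mamu-LILRB1*001:01:02:01")
  expect_equal(named$name[named$allele_id == "nonc"],
               "Mamu-LILRB1*001:01:01:02")
  expect_equal(named$name[named$allele_id == "nonsyn"],
               "Mamu-LILRB1*001:02:01:01")
})
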