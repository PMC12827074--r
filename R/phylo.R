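#' Evolutionary distances, NJ trees, bootstrap and lineages
#'
#' Pairwise evolutionary distances (Jukes-Cantor, Tamura-Nei, and the
#' Nei-Gojobori nonsynonymous distance with Jukes-Cantor correction) are
#' computed on aligned sequences with pairwise deletion of gap columns;
#' neighbor-joining trees with bootstrap support (column resampling) drive
#' the assignment of alleles to lineages, defined as supported clades of
#' bounded internal divergence.
#'
#' @name phylo_nomenclature
NULL

# Split an aligned pair into ungapped comparable columns.
pair_columns <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) abort("sequences must be aligned (equal length)")
  keep <- av %in% DNA_BASES & bv %in% DNA_BASES
  list(a = av[keep], b = bv[keep])
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) * log(1 - (4/3) p)` with `p` the mismatch proportion over
#' ungapped columns (pairwise deletion).
#'
#' @param a,b Aligned nucleotide sequences (equal length; gaps `-`).
#' @return The distance, or `NaN` with attribute `saturated = TRUE` when
#'   `p >= 3/4`.
#' @export
jc_distance <- function(a, b) {
  cols <- pair_columns(a, b)
  n <- length(cols$a)
  if (n == 0L) abort("no comparable columns")
  p <- sum(cols$a != cols$b) / n
  if (p >= 0.75) {
    return(structure(NaN, saturated = TRUE))
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Splits transitions into the purine (A/G) and pyrimidine (C/T) classes
#' and weights them by base frequencies estimated from the pair itself;
#' reduces toward Jukes-Cantor as frequencies become uniform and the
#' transition/transversion ratio approaches 1.
#'
#' @inheritParams jc_distance
#' @return The TN93 distance, or `NaN` flagged `saturated` on logarithm
#'   domain violations.
#' @export
tamura_nei_distance <- function(a, b) {
  cols <- pair_columns(a, b)
  n <- length(cols$a)
  if (n == 0L) abort("no comparable columns")
  av <- cols$a
  bv <- cols$b
  freq <- (table(factor(av, DNA_BASES)) + table(factor(bv, DNA_BASES))) /
    (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG
  gY <- gC + gT
  pair <- paste0(pmin(av, bv), pmax(av, bv))
  P1 <- mean(pair == "AG")          # purine transitions
  P2 <- mean(pair == "CT")          # pyrimidine transitions
  Q <- mean(av != bv) - P1 - P2     # transversions
  sat <- function() structure(NaN, saturated = TRUE)
  if (gA * gG == 0 || gC * gT == 0 || gR * gY == 0) {
    # degenerate composition: fall back to JC on the same columns
    return(jc_distance(a, b))
  }
  x1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  x2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
  x3 <- 1 - Q / (2 * gR * gY)
  if (x1 <= 0 || x2 <= 0 || x3 <= 0) return(sat())
  -2 * gA * gG / gR * log(x1) - 2 * gT * gC / gY * log(x2) -
    2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) * log(x3)
}

# --- Nei-Gojobori (1986) nonsynonymous distance ------------------------

# Fraction of the three possible single-base changes at each codon
# position that are synonymous; changes to stop codons count as
# nonsynonymous. Returns the number of synonymous sites of the codon.
syn_sites_codon <- function(codon, code = Biostrings::GENETIC_CODE) {
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] != "*" && code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over all
# shortest mutational pathways (equally weighted); pathways passing
# through a stop codon are excluded unless all do.
codon_path_diffs <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(pos) else if (nd == 2L) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  eval_path <- function(order) {
    cur <- c1
    s <- 0; n <- 0; via_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") via_stop <- TRUE
      if (code[[nxt]] == code[[cur]] && code[[cur]] != "*") s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    list(s = s, n = n, via_stop = via_stop)
  }
  paths <- map(perms, eval_path)
  ok <- !map_lgl(paths, "via_stop")
  if (any(ok)) paths <- paths[ok]
  c(syn = mean(map_dbl(paths, "s")), nonsyn = mean(map_dbl(paths, "n")))
}

#' Nei-Gojobori nonsynonymous distance (Jukes-Cantor corrected)
#'
#' Counts nonsynonymous sites and differences by codon-pathway averaging
#' (all shortest paths weighted equally, stop-codon paths excluded) and
#' applies the Jukes-Cantor correction to the proportion
#' `pN = Nd / N`. Units: nonsynonymous substitutions per nonsynonymous
#' site.
#'
#' @param a,b Aligned coding sequences (equal length, multiple of 3, no
#'   internal stop codons; codons with gaps or ambiguity are dropped
#'   pairwise).
#' @return The distance, flagged `saturated` when `pN >= 3/4`.
#' @export
nei_gojobori_ns <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences must be aligned (equal length)")
  if (nchar(a) %% 3L != 0L) abort("aligned CDS length must be a multiple of 3")
  ca <- codons_of(toupper(a))
  cb <- codons_of(toupper(b))
  valid <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[valid]
  cb <- cb[valid]
  if (length(ca) == 0L) abort("no comparable codons")
  code <- Biostrings::GENETIC_CODE
  if (any(code[ca] == "*") || any(code[cb] == "*")) {
    abort("internal stop codon in CDS")
  }
  syn_a <- sum(vapply(ca, syn_sites_codon, numeric(1)))
  syn_b <- sum(vapply(cb, syn_sites_codon, numeric(1)))
  S <- (syn_a + syn_b) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca),
                  function(i) codon_path_diffs(ca[i], cb[i]), numeric(2))
  Nd <- sum(diffs["nonsyn", ])
  pN <- Nd / N
  if (pN >= 0.75) return(structure(NaN, saturated = TRUE))
  -0.75 * log(1 - 4 * pN / 3)
}

#' Pairwise distance matrix over a set of aligned sequences
#'
#' @param seqs Named character vector of aligned sequences.
#' @param method `"JC"`, `"TN93"` or `"NG"` (Nei-Gojobori nonsynonymous).
#' @return An object of class `lilr_dist`: labels, symmetric matrix `d`
#'   (substitutions/site), `method`, and a logical `saturated` matrix.
#' @export
distance_matrix <- function(seqs, method = c("JC", "TN93", "NG")) {
  method <- match.arg(method)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("sequences must carry unique names")
  }
  fn <- switch(method, JC = jc_distance, TN93 = tamura_nei_distance,
               NG = nei_gojobori_ns)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- fn(seqs[[i]], seqs[[j]])
        d[i, j] <- d[j, i] <- as.numeric(v)
        sat[i, j] <- sat[j, i] <- isTRUE(attr(v, "saturated"))
      }
    }
  }
  structure(list(labels = names(seqs), d = d, method = method,
                 saturated = sat),
            class = "lilr_dist")
}

#' @export
print.lilr_dist <- function(x, ...) {
  cat(sprintf("<lilr_dist> %s distances over %d sequences\n",
              x$method, length(x$labels)))
  invisible(x)
}

#' @rdname lilr_tidiers
#' @export
tidy.lilr_dist <- function(x, ...) {
  as_tibble(as.data.frame.table(x$d, responseName = "distance")) |>
    rename(item1 = "Var1", item2 = "Var2") |>
    mutate(item1 = as.character(.data$item1),
           item2 = as.character(.data$item2),
           method = x$method) |>
    filter(.data$item1 < .data$item2)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch at
#' the same node, keeping path lengths consistent.
#'
#' @param D A `lilr_dist` or a symmetric numeric matrix.
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(D) {
  m <- if (inherits(D, "lilr_dist")) D$d else D
  if (inherits(D, "lilr_dist") && any(D$saturated)) {
    abort("distance matrix contains saturated entries")
  }
  if (any(!is.finite(m))) abort("distance matrix contains non-finite entries")
  if (nrow(m) < 3L) abort("need at least 3 sequences")
  tree <- ape::nj(stats::as.dist(m))
  # clamp negative branches, moving the deficit to the sister branch
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sisters) > 0L) {
      tree$edge.length[sisters[1L]] <-
        tree$edge.length[sisters[1L]] + deficit
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap clade support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports the frequency (percent) with which each internal
#' clade of the reference tree recurs. Reproducible from `seed`.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param n_reps Number of replicates (conventionally 1,000).
#' @param seed Integer seed.
#' @param method Distance method, as [distance_matrix()].
#' @return The reference tree with `node.label` set to support
#'   percentages (root `NA`); `n_reps = 0` yields all-`NA` labels.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = 1L,
                              method = "JC") {
  ref <- build_nj_tree(distance_matrix(seqs, method))
  if (n_reps == 0L) {
    ref$node.label <- rep(NA_real_, ref$Nnode)
    return(ref)
  }
  len <- unique(nchar(seqs))
  if (length(len) != 1L) abort("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  trees <- with_rng(seed, {
    map(seq_len(n_reps), function(r) {
      cols <- sample.int(len, len, replace = TRUE)
      boot <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
      build_nj_tree(distance_matrix(boot, method))
    })
  })
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / n_reps * 100
  support[1L] <- NA_real_ # root of the unrooted representation
  ref$node.label <- support
  ref
}

#' Assign alleles to lineages from a supported tree
#'
#' Midpoint-roots the tree and takes, top-down, the maximal clades whose
#' bootstrap support meets `min_support` and whose internal divergence
#' does not exceed `max_intra` substitutions/site; singleton lineages are
#' allowed. Lineage ids (3-digit) are assigned in discovery order, unless
#' a legacy map pins ids to named alleles.
#'
#' @param tree A `phylo` with `node.label` support values (percent), as
#'   from [bootstrap_support()].
#' @param D The `lilr_dist` used to build the tree.
#' @param min_support Minimum clade support (percent) to accept a
#'   multi-allele lineage (default 70).
#' @param max_intra Intra-lineage divergence ceiling (substitutions/site;
#'   default 0.04).
#' @param legacy_map Optional named character vector `allele -> "001"`
#'   pinning lineage ids.
#' @return An object of class `lilr_lineages`: tibble `allele`,
#'   `lineage` (3-digit string), `clade_support`.
#' @export
assign_lineages <- function(tree, D, min_support = 70, max_intra = 0.04,
                            legacy_map = NULL) {
  m <- if (inherits(D, "lilr_dist")) D$d else D
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  support_of <- function(node) {
    if (node <= ntip) return(100)
    lab <- rooted$node.label[node - ntip]
    v <- suppressWarnings(as.numeric(lab))
    if (is.na(v)) 100 else v # root/unlabeled nodes do not block descent
  }
  tips_of <- function(node) {
    if (node <= ntip) return(rooted$tip.label[node])
    rooted$tip.label[unlist(phangorn::Descendants(rooted, node, "tips"))]
  }
  children_of <- function(node) rooted$edge[rooted$edge[, 1L] == node, 2L]

  groups <- list()
  visit <- function(node, is_root = FALSE) {
    tips <- tips_of(node)
    ok_div <- length(tips) == 1L ||
      max(m[tips, tips]) <= max_intra
    ok_sup <- length(tips) == 1L || support_of(node) >= min_support
    if (ok_div && (ok_sup || is_root)) {
      groups[[length(groups) + 1L]] <<- list(
        tips = tips,
        support = if (length(tips) == 1L) NA_real_ else support_of(node)
      )
    } else {
      for (ch in children_of(node)) visit(ch)
    }
  }
  root <- ntip + 1L
  visit(root, is_root = TRUE)

  assignment <- list_rbind(imap(groups, function(g, i) {
    tibble(allele = g$tips, group = i, clade_support = g$support)
  }))

  # number lineages: legacy pins first, then discovery order
  ids <- rep(NA_character_, length(groups))
  used <- character()
  if (!is.null(legacy_map)) {
    for (al in names(legacy_map)) {
      gi <- assignment$group[assignment$allele == al]
      if (length(gi) == 1L && is.na(ids[gi]) &&
          !legacy_map[[al]] %in% used) {
        ids[gi] <- legacy_map[[al]]
        used <- c(used, legacy_map[[al]])
      }
    }
  }
  nxt <- 1L
  for (i in seq_along(ids)) {
    if (!is.na(ids[i])) next
    while (sprintf("%03d", nxt) %in% used) nxt <- nxt + 1L
    ids[i] <- sprintf("%03d", nxt)
    used <- c(used, ids[i])
  }
  structure(
    assignment |>
      transmute(allele = .data$allele, lineage = ids[.data$group],
                clade_support = .data$clade_support),
    class = c("lilr_lineages", class(tibble()))
  )
}
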