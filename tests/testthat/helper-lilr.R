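# Shared fixtures and independent oracles, built once per test run.

fx <- lilrb1_fixture()

# A small, fast simulation used by several suites.
small_sim <- function(...) {
  sim_config(n_samples = 6L, reads_per_sample = 60L, ccs_error_rate = 0,
             ...)
}

# The catalog of single splice events exercised throughout (the deduced
# isoforms 1-5 of both genes, plus retention and micro-insertions).
event_catalog <- c(
  "alt3ss10+3", "alt3ss15+3", "skip15", "skip9", "skip9,skip10",
  "ret15+30", "micro10+1", "micro10+2", "alt3ss10-3", "alt5ss10-6",
  "alt3ss10+3,skip15", "skip9,alt3ss10+3", "skip9,alt3ss15+3"
)

# --- independent Nei-Gojobori pathway oracle ---------------------------
# Deliberately naive: explicit permutation enumeration with no shared
# code with the implementation.
oracle_ng_codon <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  d <- which(substring(c1, 1:3, 1:3) != substring(c2, 1:3, 1:3))
  if (length(d) == 0) return(c(0, 0))
  perms <- switch(as.character(length(d)),
    "1" = list(d),
    "2" = list(d, d[2:1]),
    "3" = lapply(list(c(1,2,3),c(1,3,2),c(2,1,3),c(2,3,1),c(3,1,2),
                      c(3,2,1)), function(o) d[o]))
  res <- list()
  for (p in perms) {
    cur <- c1; s <- 0; n <- 0; stopped <- FALSE
    for (pos in p) {
      nxt <- paste0(substr(cur,1,pos-1), substr(c2,pos,pos),
                    substr(cur,pos+1,3))
      if (code[[nxt]] == "*") stopped <- TRUE
      if (code[[nxt]] == code[[cur]] && code[[cur]] != "*") s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    res[[length(res)+1]] <- c(s = s, n = n, stopped = stopped)
  }
  keep <- Filter(function(r) !r[["stopped"]], res)
  if (length(keep) == 0) keep <- res
  c(mean(vapply(keep, `[[`, 0, "s")), mean(vapply(keep, `[[`, 0, "n")))
}

oracle_ng_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  s <- 0
  for (pos in 1:3) {
    for (b in c("A","C","G","T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon,1,pos-1), b, substr(codon,pos+1,3))
      if (code[[mut]] != "*" && code[[mut]] == code[[codon]]) s <- s + 1/3
    }
  }
  s
}

oracle_ng_distance <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- mean(c(sum(sapply(ca, oracle_ng_sites)),
              sum(sapply(cb, oracle_ng_sites))))
  N <- 3 * length(ca) - S
  Nd <- sum(sapply(seq_along(ca),
                   function(i) oracle_ng_codon(ca[i], cb[i])[2]))
  -3/4 * log(1 - 4/3 * Nd / N)
}

# --- brute-force 4-taxon least-squares topology oracle -----------------
# Fits branch lengths of each of the three unrooted quartet topologies by
# ordinary least squares and returns the split of the best fit.
oracle_quartet_split <- function(D) {
  taxa <- rownames(D)
  splits <- list(c(1,2), c(1,3), c(1,4)) # pair grouped with taxon 1
  dvec <- c(D[1,2], D[1,3], D[1,4], D[2,3], D[2,4], D[3,4])
  fit <- sapply(splits, function(sp) {
    other <- setdiff(2:4, sp[2])
    # order: t1..t4 external, t5 internal; path matrix rows follow dvec
    pair <- function(i, j) {
      x <- rep(0, 5)
      x[i] <- 1; x[j] <- 1
      same <- (i %in% sp && j %in% sp) || (i %in% other && j %in% other)
      if (!same) x[5] <- 1
      x
    }
    X <- rbind(pair(1,2), pair(1,3), pair(1,4), pair(2,3), pair(2,4),
               pair(3,4))
    sum(stats::lm.fit(X, dvec)$residuals^2)
  })
  canonical_split(taxa[splits[[which.min(fit)]]], taxa)
}

# Random additive 4-taxon distance matrix with its generating split.
random_additive_quartet <- function() {
  bl <- stats::runif(5, 0.5, 3)  # a,b external pair | c,d pair | internal
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a","b"] <- bl[1] + bl[2]
  D["c","d"] <- bl[3] + bl[4]
  D["a","c"] <- bl[1] + bl[5] + bl[3]
  D["a","d"] <- bl[1] + bl[5] + bl[4]
  D["b","c"] <- bl[2] + bl[5] + bl[3]
  D["b","d"] <- bl[2] + bl[5] + bl[4]
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

# Canonical form of a quartet split: the pair containing the
# alphabetically first taxon ({a,b}|{c,d} == {c,d}|{a,b}).
canonical_split <- function(pair, taxa) {
  first <- sort(taxa)[1]
  if (first %in% pair) sort(pair) else sort(setdiff(taxa, pair))
}

# Split of taxon pair grouped together in an unrooted 4-taxon tree.
nj_quartet_split <- function(tree) {
  tr <- ape::unroot(tree)
  # the two tips hanging off one internal node form the split
  for (node in unique(tr$edge[, 1])) {
    tips <- tr$edge[tr$edge[, 1] == node & tr$edge[, 2] <= 4, 2]
    if (length(tips) == 2) {
      return(canonical_split(tr$tip.label[tips], tr$tip.label))
    }
  }
  NULL
}

random_valid_name <- function() {
  n_fields <- sample(1:4, 1)
  allele_name(
    prefix = paste0(
      paste(sample(LETTERS, 1), collapse = ""),
      paste(sample(letters, 3, TRUE), collapse = "")),
    gene = sample(c("LILRB1", "LILRB2"), 1),
    lineage = sample(999, 1),
    allele = if (n_fields >= 2) sample(99, 1) else NA,
    synonymous = if (n_fields >= 3) sample(99, 1) else NA,
    noncoding = if (n_fields >= 4) sample(99, 1) else NA,
    sp_suffix = stats::runif(1) < 0.3
  )
}
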