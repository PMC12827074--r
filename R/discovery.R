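#' Exact-match allele discovery with iterative reference libraries
#'
#' Reads are assigned to known alleles only on a perfect match (zero
#' mismatches over at least 400 bp of overlap, at most one ambiguous base),
#' the strict mapping settings of the original workflow. Unassigned reads are
#' grouped into contigs (cutoff: three reads per contig), candidate
#' consensus sequences are confirmed when seen in two independent runs for
#' one individual or in at least two individuals, and confirmed alleles are
#' appended to the reference library, which grows iteratively until no new
#' read can be assigned.
#'
#' @name allele_discovery
NULL

#' Construct a reference allele library
#'
#' @param entries Tibble with columns `name`, `sequence`, `gene` and
#'   optionally `source` (`"published"` or `"this-run"`) and `parent`
#'   (parent allele of a splice-variant entry).
#' @return An object of class `reference_library` (entries + version).
#' @export
reference_library <- function(entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("name", "sequence", "gene") %in% names(entries)))
  if (!"source" %in% names(entries)) entries$source <- "published"
  if (!"parent" %in% names(entries)) entries$parent <- entries$name
  if (anyDuplicated(entries$name)) abort("library names must be unique")
  dup <- entries |> count(.data$gene, .data$sequence) |> filter(n > 1L)
  if (nrow(dup) > 0L) abort("duplicate sequence within one gene")
  structure(list(entries = entries, version = 1L),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> v%d: %d entries (%d published, %d this-run)\n",
              x$version, nrow(x$entries),
              sum(x$entries$source == "published"),
              sum(x$entries$source == "this-run")))
  invisible(x)
}

#' Append confirmed entries to a library (version bump)
#' @param lib A `reference_library`.
#' @param entries New entries (same columns as [reference_library()]).
#' @return The updated library; entries whose sequence is already present
#'   for the gene are silently skipped.
#' @export
add_to_library <- function(lib, entries) {
  entries <- as_tibble(entries)
  if (!"source" %in% names(entries)) entries$source <- "this-run"
  if (!"parent" %in% names(entries)) entries$parent <- entries$name
  keep <- !paste(entries$gene, entries$sequence) %in%
    paste(lib$entries$gene, lib$entries$sequence)
  entries <- entries[keep, ]
  if (nrow(entries) == 0L) return(lib)
  entries$name <- make.unique(c(lib$entries$name, entries$name),
                              sep = "_")[nrow(lib$entries) + seq_len(nrow(entries))]
  lib$entries <- bind_rows(lib$entries,
                           entries[, names(lib$entries)])
  lib$version <- lib$version + 1L
  lib
}

# Ambiguous-base count (anything not ACGT).
count_ambiguous <- function(seq) {
  nchar(seq) - vapply(strsplit(chartr("ACGT", "....", seq), ""),
                      function(x) sum(x == "."), integer(1))
}

#' Match reads to a reference library by perfect overlap
#'
#' A read is assigned to a reference iff it aligns with zero mismatches
#' over at least `min_overlap` bases covering the full shorter sequence
#' (100% overlap identity), with at most `max_ambiguity` ambiguous bases.
#' Reads matching several references equally are assigned to all of them
#' and flagged ambiguous.
#'
#' @param reads Tibble with columns `id`, `seq` (plus any carried columns,
#'   e.g. `sample`).
#' @param lib A `reference_library`.
#' @param min_overlap Minimum perfect-overlap length in bp (default 400).
#' @param max_ambiguity Maximum ambiguous bases tolerated in a read.
#' @return A list: `assignments` (tibble `id`, `allele` = reference name,
#'   `ambiguous`, plus carried columns) and `unassigned` (the input rows
#'   with no assignment).
#' @export
match_to_reference <- function(reads, lib, min_overlap = 400L,
                               max_ambiguity = 1L) {
  if (nrow(lib$entries) == 0L) abort("reference library is empty")
  refs <- lib$entries
  ref_len <- nchar(refs$sequence)
  ref_by_seq <- split(refs$name, refs$sequence)

  # anchor index: every reference k-mer -> (ref, position); exact
  # containment of a read implies its leading k-mer occurs in the
  # reference, so the index is a complete prefilter
  k <- 32L
  idx <- new.env(parent = emptyenv(), size = 4L * sum(ref_len))
  for (j in seq_len(nrow(refs))) {
    s <- refs$sequence[j]
    if (nchar(s) < k) next
    starts <- seq_len(nchar(s) - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (q in seq_along(kmers)) {
      key <- kmers[q]
      idx[[key]] <- c(idx[[key]], j * 1e7 + starts[q])
    }
  }

  uniq <- reads |> distinct(.data$seq)
  hit_list <- vector("list", nrow(uniq))
  for (u in seq_len(nrow(uniq))) {
    s <- uniq$seq[u]
    ns <- nchar(s)
    if (ns < min_overlap) next
    n_amb <- count_ambiguous(s)
    if (n_amb > max_ambiguity) next
    exact <- ref_by_seq[[s]]
    if (!is.null(exact)) {
      hit_list[[u]] <- exact
      next
    }
    hits <- character(0)
    if (n_amb == 0L && ns >= k) {
      # read contained in a longer reference: anchor the leading k-mer
      cand <- idx[[substr(s, 1L, k)]]
      for (cd in cand) {
        j <- cd %/% 1e7
        p <- cd %% 1e7
        if (ref_len[j] > ns && ref_len[j] - p + 1L >= ns &&
            substr(refs$sequence[j], p, p + ns - 1L) == s) {
          hits <- c(hits, refs$name[j])
        }
      }
      # reference contained in a longer read
      for (j in which(ref_len < ns & ref_len >= min_overlap)) {
        if (grepl(refs$sequence[j], s, fixed = TRUE)) {
          hits <- c(hits, refs$name[j])
        }
      }
    } else if (n_amb > 0L) {
      # ambiguity-tolerant path (rare): full scan with IUPAC matching
      ref_set <- Biostrings::DNAStringSet(refs$sequence)
      cnt <- Biostrings::vcountPattern(s, ref_set[ref_len > ns],
                                       fixed = "subject")
      hits <- refs$name[ref_len > ns][cnt > 0L]
      for (j in which(ref_len <= ns & ref_len >= min_overlap)) {
        if (Biostrings::countPattern(ref_set[[j]],
                                     Biostrings::DNAString(s),
                                     fixed = "pattern") > 0L) {
          hits <- c(hits, refs$name[j])
        }
      }
    }
    if (length(hits) > 0L) hit_list[[u]] <- unique(hits)
  }

  uniq$hits <- hit_list
  joined <- reads |> left_join(uniq, by = "seq")
  has_hit <- lengths(joined$hits) > 0L
  assignments <- joined[has_hit, ] |>
    mutate(ambiguous = lengths(.data$hits) > 1L) |>
    tidyr::unnest_longer(col = "hits") |>
    rename(allele = "hits")
  list(
    assignments = assignments,
    unassigned = reads[!has_hit, ]
  )
}

#' Cluster unassigned reads into candidate contigs
#'
#' Reads from one sample are grouped by length (the CCS error model is
#' substitution-dominated, so reads from one isoform share a length), then
#' clustered greedily at the identity threshold (Hamming distance). Within
#' a cluster, every exact haplotype supported by at least `min_reads`
#' identical reads becomes its own candidate -- at CCS accuracy, several
#' byte-identical full-length copies cannot be error artifacts, and this
#' keeps co-clustered alleles of one lineage apart -- and the remaining
#' (error-bearing) reads attach to their nearest candidate as extra
#' support. A cluster with no such haplotype falls back to the
#' majority-rule column consensus. Candidates supported by fewer than
#' `min_reads` reads are discarded (the three-reads-per-contig cutoff).
#'
#' @param reads Tibble with columns `id`, `seq` from a single sample.
#' @param min_reads Minimum supporting reads per contig (default 3).
#' @param identity Minimum within-cluster identity (default 0.995).
#' @param min_length Minimum consensus length to span the amplicon window.
#' @return Tibble of candidates: `consensus`, `support`, `read_ids`
#'   (list-column).
#' @export
cluster_unassigned <- function(reads, min_reads = 3L, identity = 0.995,
                               min_length = 400L) {
  if (nrow(reads) == 0L) {
    return(tibble(consensus = character(), support = integer(),
                  read_ids = list()))
  }
  out <- list()
  for (len in unique(nchar(reads$seq))) {
    if (len < min_length) next
    grp <- reads[nchar(reads$seq) == len, ]
    max_d <- floor((1 - identity) * len)
    m <- do.call(rbind, lapply(grp$seq, utf8ToInt))
    left <- seq_len(nrow(grp))
    while (length(left) > 0L) {
      seedi <- left[1]
      d <- rowSums(m[left, , drop = FALSE] !=
                     matrix(m[seedi, ], length(left), len, byrow = TRUE))
      members <- left[d <= max_d]
      left <- setdiff(left, members)
      if (length(members) < min_reads) next
      seqs <- grp$seq[members]
      hap <- sort(table(seqs), decreasing = TRUE)
      anchors <- names(hap)[hap >= min_reads]
      if (length(anchors) == 0L) {
        # error-dominated cluster: majority-rule column consensus,
        # ties to the lexicographically first base
        sub <- m[members, , drop = FALSE]
        cons <- sub[1L, ]
        varying <- which(colSums(sub != matrix(cons, nrow(sub), len,
                                               byrow = TRUE)) > 0L)
        for (cidx in varying) {
          tab <- sort(table(sub[, cidx]), decreasing = TRUE)
          cons[cidx] <- as.integer(names(tab)[1])
        }
        out[[length(out) + 1L]] <- tibble(
          consensus = intToUtf8(cons),
          support = length(members),
          read_ids = list(grp$id[members])
        )
      } else {
        # each well-supported exact haplotype is its own candidate;
        # error-bearing reads attach to the nearest one
        anchor_mat <- do.call(rbind, lapply(anchors, utf8ToInt))
        pick <- vapply(members, function(ri) {
          ad <- rowSums(anchor_mat != matrix(m[ri, ], nrow(anchor_mat),
                                             len, byrow = TRUE))
          which.min(ad)
        }, integer(1))
        for (ai in seq_along(anchors)) {
          grp_members <- members[pick == ai]
          if (length(grp_members) < min_reads) next
          out[[length(out) + 1L]] <- tibble(
            consensus = anchors[ai],
            support = length(grp_members),
            read_ids = list(grp$id[grp_members])
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(consensus = character(), support = integer(),
                  read_ids = list()))
  }
  list_rbind(out)
}

#' Confirm novel candidate alleles across samples and runs
#'
#' A candidate consensus is confirmed iff it was identified in two
#' independent runs for one individual, or in at least two individuals.
#' Candidates whose consensus already equals a library sequence are
#' reported as `known`, not novel.
#'
#' @param candidates Tibble with columns `consensus`, `support`, `sample`
#'   (individual id) and `run`.
#' @param lib A `reference_library` (to recognize already-known sequences).
#' @return Tibble: `consensus`, `status` (`confirmed` / `candidate` /
#'   `known`), `n_samples`, `n_runs`, `support` (total reads).
#' @export
confirm_novel <- function(candidates, lib = NULL) {
  if (nrow(candidates) == 0L) {
    return(tibble(consensus = character(), status = character(),
                  n_samples = integer(), n_runs = integer(),
                  support = integer()))
  }
  stopifnot(all(c("consensus", "sample", "run", "support") %in%
                  names(candidates)))
  known_seqs <- if (is.null(lib)) character() else lib$entries$sequence
  candidates |>
    group_by(.data$consensus) |>
    summarise(
      n_samples = n_distinct(.data$sample),
      n_runs_one_sample = max(tapply(.data$run, .data$sample,
                                     function(r) length(unique(r)))),
      n_runs = n_distinct(.data$run),
      support = sum(.data$support),
      .groups = "drop"
    ) |>
    mutate(
      status = case_when(
        .data$consensus %in% known_seqs ~ "known",
        .data$n_samples >= 2L | .data$n_runs_one_sample >= 2L ~ "confirmed",
        TRUE ~ "candidate"
      )
    ) |>
    select("consensus", "status", "n_samples", "n_runs", "support")
}

#' Reconcile transcript alleles with genomic alleles
#'
#' A transcript links to a genomic allele iff it is derivable from the
#' genomic sequence under the gene model plus a valid splice signature
#' (checked by spliced alignment and event classification). Transcripts
#' derivable from several genomic alleles are flagged ambiguous;
#' transcripts derivable from none are retained and flagged
#' transcript-only.
#'
#' @param transcripts Tibble with columns `name`, `sequence`.
#' @param genomic_alleles Tibble with columns `name`, `sequence` and
#'   `model` (list-column of `gene_model`s).
#' @return Tibble: `transcript`, `genomic_allele` (`NA` if none),
#'   `signature` (list-column), `signature_id`, `status`
#'   (`linked` / `ambiguous` / `transcript_only`).
#' @export
reconcile_cdna_gdna <- function(transcripts, genomic_alleles) {
  rows <- map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts$sequence[i]
    links <- list()
    for (j in seq_len(nrow(genomic_alleles))) {
      sig <- tryCatch({
        chain <- align_transcript(tx, genomic_alleles$sequence[j],
                                  genomic_alleles$model[[j]])
        classify_events(chain, genomic_alleles$model[[j]])
      }, error = function(e) NULL)
      if (!is.null(sig)) {
        links[[length(links) + 1L]] <- list(
          genomic = genomic_alleles$name[j], sig = sig)
      }
    }
    status <- if (length(links) == 0L) "transcript_only"
      else if (length(links) > 1L) "ambiguous" else "linked"
    if (length(links) == 0L) {
      tibble(transcript = transcripts$name[i],
             genomic_allele = NA_character_,
             signature = list(splice_signature()),
             signature_id = NA_character_, status = status)
    } else {
      tibble(transcript = transcripts$name[i],
             genomic_allele = map_chr(links, "genomic"),
             signature = map(links, "sig"),
             signature_id = map_chr(links, ~ signature_label(.x$sig)),
             status = status)
    }
  })
  list_rbind(rows)
}
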