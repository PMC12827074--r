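#' Pipeline configuration and orchestration
#'
#' `run_pipeline()` executes the full workflow behind one call:
#' (optional) simulation -> read-quality filter -> demultiplexing ->
#' exact-match allele calling with iterative library growth ->
#' splice-isoform reconciliation and shared-event cataloguing ->
#' NJ phylogeny, lineage assignment and naming -> diversity statistics.
#' All randomness flows from the single configured seed; identical
#' config + seed give identical outputs.
#'
#' @name cli_report
NULL

#' Build a pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its stream
#'   from it.
#' @param sim A [sim_config()] describing the synthetic study (used when
#'   no external inputs are supplied).
#' @param quality_threshold CCS read-quality cutoff (default 0.99).
#' @param barcode_max_mismatch Mismatches tolerated per barcode end.
#' @param min_overlap Minimum perfect-overlap for reference matching (bp).
#' @param max_ambiguity Ambiguous bases tolerated per read.
#' @param cluster_min_reads Contig support cutoff (default 3).
#' @param cluster_identity Clustering identity threshold.
#' @param max_iterations Library-growth closure iterations (cap 5).
#' @param distance_method Distance model for the phylogeny stage.
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param min_support,max_intra Lineage delimitation thresholds.
#' @param prefix,gene Naming parameters.
#' @param reads_fastq,reference_fasta,barcode_tsv Optional external
#'   inputs; when given, the simulation stage is skipped.
#' @param output_dir Optional directory for stage artifact TSVs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(),
                            quality_threshold = 0.99,
                            barcode_max_mismatch = 1L,
                            min_overlap = 400L,
                            max_ambiguity = 1L,
                            cluster_min_reads = 3L,
                            cluster_identity = 0.995,
                            max_iterations = 5L,
                            distance_method = "JC",
                            bootstrap_reps = 1000L,
                            min_support = 70,
                            max_intra = 0.04,
                            prefix = "Mamu",
                            gene = "LILRB1",
                            reads_fastq = NULL,
                            reference_fasta = NULL,
                            barcode_tsv = NULL,
                            output_dir = NULL) {
  stopifnot(quality_threshold >= 0, quality_threshold <= 1,
            cluster_identity > 0, cluster_identity <= 1,
            max_iterations >= 1L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$splice_profile)) {
    sp <- tibble(
      signature_id = map_chr(sim_args$splice_profile, "signature"),
      weight = map_dbl(sim_args$splice_profile, "weight")
    ) |>
      mutate(events = map(.data$signature_id, parse_signature))
    sim_args$splice_profile <- sp
  }
  if (!is.null(sim_args$indel_features)) {
    sim_args$indel_features <- tibble(
      lineage = map_int(sim_args$indel_features, ~ as.integer(.x$lineage)),
      type = map_chr(sim_args$indel_features, "type")
    )
  }
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  y$sim$splice_profile <- map(seq_len(nrow(config$sim$splice_profile)),
    function(i) list(signature = config$sim$splice_profile$signature_id[i],
                     weight = config$sim$splice_profile$weight[i]))
  y$sim$indel_features <- map(seq_len(nrow(config$sim$indel_features)),
    function(i) list(lineage = config$sim$indel_features$lineage[i],
                     type = config$sim$indel_features$type[i]))
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Align a set of sequences (identity pass-through when already aligned)
#'
#' Sequence sets that share one length (the substitution-only case) are
#' returned unchanged; sets with indels are aligned with the system
#' `mafft` executable.
#'
#' @param seqs Named character vector.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector of aligned sequences.
#' @export
align_alleles <- function(seqs, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  if (Sys.which("mafft") == "") {
    abort("sequences of unequal length need the mafft executable")
  }
  tmp_in <- tempfile(fileext = ".fa")
  tmp_out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", seqs), tmp_in)
  status <- system2("mafft", c("--auto", "--quiet", "--preservecase", tmp_in),
                    stdout = tmp_out)
  if (status != 0L) abort("mafft failed")
  aln <- if (type == "dna") Biostrings::readDNAStringSet(tmp_out) else
    Biostrings::readAAStringSet(tmp_out)
  out <- as.character(aln)
  names(out) <- names(aln)
  out[names(seqs)]
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @return An object of class `lilr_report`; see [glance.lilr_report()]
#'   for the one-row summary.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)),
            class = "lilr_stage_error")
    })
  }
  external <- !is.null(config$reads_fastq)
  for (p in c(config$reads_fastq, config$reference_fasta,
              config$barcode_tsv)) {
    if (!file.exists(p)) {
      abort(sprintf("input path does not exist: %s", p),
            class = "lilr_config_error")
    }
  }

  # --- inputs ----------------------------------------------------------
  truth <- NULL
  if (external) {
    reads <- stage("input", read_ccs_fastq(config$reads_fastq))
    barcodes <- stage("input", as_tibble(utils::read.delim(
      config$barcode_tsv, colClasses = "character")))
    lib <- stage("input", load_reference_library(config$reference_fasta))
    sample_meta <- tibble(sample = barcodes$sample,
                          species = "unknown", run = "run1")
  } else {
    truth <- stage("simulate",
                   simulate_allele_set(config$sim, seed = config$seed))
    readset <- stage("simulate",
                     simulate_ccs_reads(truth, seed = config$seed + 1L))
    reads <- readset$reads
    barcodes <- readset$barcodes
    sample_meta <- truth$genotypes |>
      distinct(.data$sample, .data$species, .data$run)
    lib <- reference_library(tibble(
      name = truth$alleles$allele_id,
      sequence = map_chr(seq_len(nrow(truth$alleles)), function(i) {
        extract_transcript(truth$alleles$model[[i]],
                           truth$alleles$genomic[i])
      }),
      gene = config$gene,
      source = "published"
    ))
  }

  # --- filter + demultiplex -------------------------------------------
  filtered <- stage("filter",
                    filter_by_quality(reads, config$quality_threshold))
  demuxed <- stage("demux",
                   demultiplex(filtered, barcodes,
                               config$barcode_max_mismatch))
  assigned_reads <- demuxed |> filter(!is.na(.data$sample))

  # --- allele calling with library growth ------------------------------
  genomic_refs <- if (!external) {
    truth$alleles |>
      transmute(name = .data$allele_id, sequence = .data$genomic,
                model = .data$model)
  } else {
    NULL
  }

  assignments <- list()
  pending <- assigned_reads
  reconciliation <- list()
  closure_log <- list()
  match_lib <- lib
  for (iter in seq_len(config$max_iterations)) {
    res <- stage("call", match_to_reference(
      pending, match_lib, min_overlap = config$min_overlap,
      max_ambiguity = config$max_ambiguity))
    assignments[[iter]] <- res$assignments
    pending <- res$unassigned
    closure_log[[iter]] <- tibble(
      iteration = iter, library_version = lib$version,
      n_assigned = nrow(res$assignments), n_unassigned = nrow(pending)
    )
    if (iter == config$max_iterations || is.null(genomic_refs)) break

    cands <- pending |>
      group_by(.data$sample) |>
      group_map(function(rows, key) {
        cluster_unassigned(rows, min_reads = config$cluster_min_reads,
                           identity = config$cluster_identity,
                           min_length = config$min_overlap) |>
          mutate(sample = key$sample)
      }) |>
      list_rbind()
    if (nrow(cands) == 0L) break
    cands <- cands |> left_join(sample_meta, by = "sample")
    conf <- confirm_novel(cands |> select("consensus", "sample", "run",
                                          "support"), lib)
    confirmed <- conf |> filter(.data$status == "confirmed")
    if (nrow(confirmed) == 0L) break

    cand_tab <- tibble(
      name = sprintf("iso%02d_%03d", iter, seq_len(nrow(confirmed))),
      sequence = confirmed$consensus
    )
    rec <- stage("splice", reconcile_cdna_gdna(cand_tab, genomic_refs))
    reconciliation[[iter]] <- rec
    seq_of <- stats::setNames(cand_tab$sequence, cand_tab$name)
    linked <- rec |> filter(.data$status == "linked")
    orphans <- rec |> filter(.data$status == "transcript_only")
    new_entries <- bind_rows(
      if (nrow(linked) > 0L) tibble(
        name = sprintf("%s_%sSp", linked$genomic_allele,
                       gsub("[^A-Za-z0-9]+", ".", linked$signature_id)),
        sequence = unname(seq_of[linked$transcript]),
        gene = config$gene, source = "this-run",
        parent = linked$genomic_allele
      ),
      if (nrow(orphans) > 0L) tibble(
        name = sprintf("novel_%02d_%03d", iter, seq_len(nrow(orphans))),
        sequence = unname(seq_of[orphans$transcript]),
        gene = config$gene, source = "this-run", parent = NA_character_
      )
    )
    n_before <- nrow(lib$entries)
    lib <- add_to_library(lib, new_entries)
    n_added <- nrow(lib$entries) - n_before
    if (n_added == 0L) break
    # only newly added entries need matching against still-pending reads
    match_lib <- structure(
      list(entries = utils::tail(lib$entries, n_added),
           version = lib$version),
      class = "reference_library")
  }
  assignments <- list_rbind(assignments)
  reconciliation <- if (length(reconciliation) > 0L) {
    list_rbind(reconciliation)
  } else {
    tibble()
  }

  parent_of <- stats::setNames(lib$entries$parent, lib$entries$name)
  calls <- assignments |>
    mutate(allele_parent = parent_of[.data$allele]) |>
    group_by(.data$sample, .data$allele_parent) |>
    summarise(
      n_reads = sum(!.data$ambiguous),
      n_ambiguous = sum(.data$ambiguous),
      .groups = "drop"
    ) |>
    filter(.data$n_reads > 0L) |>
    left_join(sample_meta, by = "sample") |>
    mutate(status = ifelse(
      .data$allele_parent %in%
        lib$entries$name[lib$entries$source == "published"],
      "known", "novel"))

  # --- shared splice events -------------------------------------------
  shared_events <- tibble()
  event_obs <- tibble()
  if (nrow(reconciliation) > 0L) {
    sig_of <- stats::setNames(
      reconciliation$signature[reconciliation$status == "linked"],
      sprintf("%s_%sSp",
              reconciliation$genomic_allele[reconciliation$status == "linked"],
              gsub("[^A-Za-z0-9]+", ".",
                   reconciliation$signature_id[reconciliation$status == "linked"]))
    )
    obs <- assignments |>
      filter(.data$allele %in% names(sig_of), !.data$ambiguous) |>
      distinct(.data$sample, .data$allele) |>
      left_join(sample_meta, by = "sample")
    if (nrow(obs) > 0L) {
      event_obs <- list_rbind(map(seq_len(nrow(obs)), function(i) {
        sig_of[[obs$allele[i]]] |>
          mutate(animal = obs$sample[i], species = obs$species[i],
                 allele = obs$allele[i])
      }))
      shared_events <- filter_shared_events(event_obs)
    }
  }

  # --- phylogeny, lineages, names -------------------------------------
  tree <- NULL; D <- NULL; lineages <- tibble(); names_tab <- tibble()
  stats_out <- list()
  if (!external) {
    called <- intersect(truth$alleles$allele_id,
                        unique(calls$allele_parent))
    if (length(called) >= 3L) {
      idx <- match(called, truth$alleles$allele_id)
      cds <- stats::setNames(
        map_chr(idx, function(i) extract_cds(truth$alleles$model[[i]],
                                             truth$alleles$genomic[i])),
        called)
      aligned <- stage("phylo", align_alleles(cds, "dna"))
      D <- stage("phylo", distance_matrix(aligned, config$distance_method))
      tree <- stage("phylo", bootstrap_support(
        aligned, n_reps = config$bootstrap_reps, seed = config$seed + 2L,
        method = config$distance_method))
      lineages <- stage("phylo", assign_lineages(
        tree, D, min_support = config$min_support,
        max_intra = config$max_intra))
      # an allele is an "Sp" designation when its transcripts are
      # predominantly spliced: variant reads outnumber canonical reads
      read_mix <- assignments |>
        filter(!.data$ambiguous) |>
        mutate(parent = parent_of[.data$allele],
               canonical = .data$allele == .data$parent) |>
        group_by(.data$parent) |>
        summarise(n_canonical = sum(.data$canonical),
                  n_variant = sum(!.data$canonical), .groups = "drop")
      sp_alleles <- read_mix$parent[read_mix$n_variant >
                                      read_mix$n_canonical]
      names_tab <- stage("name", name_alleles(
        lineages, truth$alleles, prefix = config$prefix,
        gene = config$gene, sp_alleles = sp_alleles))

      prots <- stats::setNames(
        map_chr(idx, function(i) sub("\\*$", "", translate_dna(
          extract_cds(truth$alleles$model[[i]], truth$alleles$genomic[i])))),
        called)
      stats_out$variability <- variability_profile(
        align_alleles(prots, "protein"))
      modal_len <- as.integer(names(sort(table(nchar(cds)),
                                         decreasing = TRUE))[1])
      plain <- cds[nchar(cds) == modal_len]
      plain_model <- truth$alleles$model[[
        idx[which(nchar(cds) == modal_len)[1]]]]
      stats_out$mutation_density <- exon_mutation_density(plain, plain_model)
      stats_out$d1d2_groups <- domain_identity_groups(
        truth$alleles[idx, ], regions = c("D1", "D2"))
    }
  }

  counts <- list(
    n_reads_in = nrow(reads),
    n_reads_pass_rq = nrow(filtered),
    n_reads_demuxed = sum(!is.na(demuxed$sample)),
    n_reads_assigned = length(unique(assignments$id)),
    n_samples = nrow(barcodes),
    n_confirmed_variants = sum(lib$entries$source == "this-run" &
                                 !is.na(lib$entries$parent)),
    n_novel_alleles = sum(lib$entries$source == "this-run" &
                            is.na(lib$entries$parent))
  )

  report <- structure(
    list(
      config = config, truth = truth, library = lib,
      demux = demux_counts(demuxed), closure_log = list_rbind(closure_log),
      assignments = assignments, calls = calls,
      reconciliation = reconciliation,
      event_observations = event_obs, shared_events = shared_events,
      tree = tree, distances = D, lineages = lineages,
      allele_names = names_tab, stats = stats_out, counts = counts
    ),
    class = "lilr_report"
  )
  if (!is.null(config$output_dir)) {
    write_tables(
      list(calls = calls, closure_log = report$closure_log,
           demux_counts = report$demux,
           shared_events = shared_events),
      config$output_dir)
  }
  report
}

#' @export
print.lilr_report <- function(x, ...) {
  g <- glance(x)
  cat("<lilr_report>\n")
  cat(sprintf("  reads: %d in, %d pass rq, %d assigned\n",
              g$n_reads_in, g$n_reads_pass_rq, g$n_reads_assigned))
  cat(sprintf("  library v%d: %d entries (%d confirmed splice variants, %d novel)\n",
              g$library_version, g$n_library_entries,
              x$counts$n_confirmed_variants, x$counts$n_novel_alleles))
  cat(sprintf("  calls: %d alleles over %d samples; %d lineages; %d shared events\n",
              g$n_alleles_called, g$n_samples, g$n_lineages,
              g$n_shared_events))
  invisible(x)
}
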