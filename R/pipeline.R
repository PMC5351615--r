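# Pipeline assembly: declarative config, staged execution, TSV outputs with
# metadata headers, and a machine-readable run summary. Every stage is also
# an exported function, so each step can be run standalone in R.

#' Build a pipeline run configuration
#'
#' All thresholds default to the standard fragment-RRBS analysis settings:
#' 40-220 bp fragments, coverage >= 10 at >= 2 CpG sites, Fisher+Bonferroni
#' at alpha 0.05 with a 25% minimum methylation difference, a 500 bp cohort
#' matching window and 2 kb CpG-island shores.
#'
#' @param outdir Output directory (created).
#' @param simulate Generate the study with the synthetic-data module. When
#'   FALSE, `genome_fasta` and `sample_sheet` must point at existing inputs.
#' @param genome_fasta,sample_sheet Paths for a non-simulated run. The
#'   sample sheet is TSV with columns sample_id, role, pair_id,
#'   replicate_of, path.
#' @param design [study_design()] for a simulated run.
#' @param planted [planted_dmfs()] plan for a simulated run.
#' @param genome_params List of [generate_genome()] arguments.
#' @param cohort Optional [cohort_design()]; enables the validation stage in
#'   a simulated run.
#' @param size_min,size_max Fragment length window, bp.
#' @param cov_min,min_cpgs Analysability gate.
#' @param alpha,delta_min DMF call thresholds.
#' @param window Cohort probe matching window, bp.
#' @param shore_width CpG-island shore width, bp.
#' @param promoter_window Promoter window around the TSS.
#' @param seed Master seed.
#' @export
run_config <- function(outdir, simulate = TRUE,
                       genome_fasta = NULL, sample_sheet = NULL,
                       design = study_design(), planted = default_planted(),
                       genome_params = list(), cohort = NULL,
                       size_min = 40, size_max = 220,
                       cov_min = 10, min_cpgs = 2,
                       alpha = 0.05, delta_min = 0.25,
                       window = 500, shore_width = 2000,
                       promoter_window = c(-2000, 500), seed = 1L) {
  .assert(all(c(size_min, size_max, cov_min, min_cpgs, alpha, delta_min,
                window, shore_width) > 0), "thresholds must be positive")
  if (!simulate) {
    .assert(!is.null(genome_fasta) && !is.null(sample_sheet),
            "non-simulated runs need genome_fasta and sample_sheet")
  }
  structure(list(outdir = outdir, simulate = simulate,
                 genome_fasta = genome_fasta, sample_sheet = sample_sheet,
                 design = design, planted = planted,
                 genome_params = genome_params, cohort = cohort,
                 size_min = size_min, size_max = size_max,
                 cov_min = cov_min, min_cpgs = min_cpgs,
                 alpha = alpha, delta_min = delta_min, window = window,
                 shore_width = shore_width, promoter_window = promoter_window,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields override [run_config()] defaults; `design`, `planted` and
#' `cohort` accept nested maps of the corresponding constructor arguments.
#' A `seed` field is required.
#' @param path YAML file.
#' @param outdir Output directory (overrides any `outdir` in the file).
#' @export
read_run_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  .assert(!is.null(y$seed), "config must set a master seed")
  args <- y
  if (!is.null(y$design)) args$design <- do.call(study_design, y$design)
  if (!is.null(y$planted))
    args$planted <- do.call(rbind, lapply(y$planted, function(p)
      do.call(planted_dmfs, p)))
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_design, y$cohort)
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(run_config, args)
}

.config_hash <- function(config) {
  parts <- c(
    vapply(c("simulate", "size_min", "size_max", "cov_min", "min_cpgs",
             "alpha", "delta_min", "window", "shore_width", "seed"),
           function(k) paste(k, paste(config[[k]], collapse = ",")), ""),
    paste("promoter_window", paste(config$promoter_window, collapse = ",")),
    paste("design", paste(deparse(config$design[
      c("n_pairs", "include_normal", "replicate_samples", "coverage_mean",
        "dispersion", "pair_jitter", "seed")]), collapse = "")),
    paste("planted", paste(deparse(config$planted), collapse = "")),
    if (!is.null(config$genome_fasta)) paste("genome", file_hash(config$genome_fasta)),
    if (!is.null(config$sample_sheet)) paste("sheet", file_hash(config$sample_sheet)))
  str_hash(parts)
}

#' Read a sample sheet and its coverage files
#'
#' Replicate libraries (`replicate_of` set) are merged into their parent
#' sample; replicate Pearson correlations are recorded.
#' @param path Sample sheet TSV: sample_id, role, pair_id, replicate_of,
#'   path (coverage file, relative paths resolved against the sheet).
#' @param cov_min Coverage threshold for the replicate correlation.
#' @return list(samples = named list of merged `sample_methylome`,
#'   replicate_r = data.frame).
#' @export
read_sample_sheet <- function(path, cov_min = 10) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  need <- c("sample_id", "role", "pair_id", "replicate_of", "path")
  .assert(all(need %in% names(sheet)), sprintf(
    "sample sheet must have columns %s", paste(need, collapse = ", ")))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  libs <- lapply(seq_len(nrow(sheet)), function(i)
    read_coverage_file(resolve(sheet$path[i]),
                       sample_id = if (is.na(sheet$replicate_of[i]))
                         sheet$sample_id[i] else sheet$replicate_of[i],
                       role = sheet$role[i], pair_id = sheet$pair_id[i]))
  names(libs) <- sheet$sample_id
  main <- which(is.na(sheet$replicate_of))
  samples <- list()
  rep_r <- list()
  for (i in main) {
    sm <- libs[[i]]
    reps <- which(!is.na(sheet$replicate_of) &
                  sheet$replicate_of == sheet$sample_id[i])
    for (j in reps) {
      rc <- replicate_correlation(sm, libs[[j]], cov_min = cov_min)
      rep_r[[length(rep_r) + 1L]] <- data.frame(
        sample_id = sheet$sample_id[i], replicate = sheet$sample_id[j],
        r = rc$r, n_common = rc$n_common, stringsAsFactors = FALSE)
      sm <- merge_replicates(sm, libs[[j]])
    }
    samples[[sheet$sample_id[i]]] <- sm
  }
  list(samples = samples,
       replicate_r = if (length(rep_r)) do.call(rbind, rep_r) else
         data.frame(sample_id = character(), replicate = character(),
                    r = numeric(), n_common = integer()))
}

.write_sim_inputs <- function(config, dir) {
  gp <- config$genome_params
  gp$seed <- gp$seed %||% config$seed
  gen <- do.call(generate_genome, gp)
  catalog <- build_catalog(gen$sequences, config$size_min, config$size_max)
  truth <- plan_methylation_states(catalog, config$design, config$planted,
                                   seed = config$seed)
  libs <- simulate_counts(truth, catalog, config$design,
                          seed = config$seed + 1L)
  write_fasta(gen$sequences, file.path(dir, "genome.fa"))
  utils::write.table(gen$islands, file.path(dir, "islands.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_truth_table(truth, file.path(dir, "truth.tsv"))
  sheet <- do.call(rbind, lapply(names(libs), function(id) {
    sm <- libs[[id]]
    data.frame(sample_id = id, role = sm$role, pair_id = sm$pair_id,
               replicate_of = if (grepl("_rep2$", id))
                 sub("_rep2$", "", id) else NA_character_,
               path = paste0(id, ".cov"), stringsAsFactors = FALSE)
  }))
  for (id in names(libs))
    write_coverage_file(libs[[id]], file.path(dir, paste0(id, ".cov")))
  utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  list(genome = gen, truth = truth)
}

#' Run the full fragment-RRBS pipeline
#'
#' Stages: (simulate) -> digest -> methylome -> per-pair DMF calling
#' (normal-vs-primary when a normal sample is present, and
#' primary-vs-metastatic) -> shared-DMF screen -> optional cohort validation
#' -> summary. Every output TSV carries `#` metadata headers with the tool
#' version, config hash and seed; reruns with the same config and seed are
#' byte-identical. Stage failures abort with the stage named; outputs written
#' so far are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `summary` (named character vector, also written to
#'   `<outdir>/summary.tsv`).
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  truth <- NULL
  if (config$simulate) {
    indir <- file.path(outdir, "inputs")
    dir.create(indir, showWarnings = FALSE)
    sim <- stage("simulate", .write_sim_inputs(config, indir))
    truth <- sim$truth
    config$genome_fasta <- file.path(indir, "genome.fa")
    config$sample_sheet <- file.path(indir, "sample_sheet.tsv")
    note("simulate: wrote %d libraries to %s", nrow(truth$samples), indir)
  }
  hash <- .config_hash(config)
  meta <- c(paste("dmfscreen", as.character(utils::packageVersion("dmfscreen"))),
            paste("config_hash", hash), paste("seed", config$seed))

  genome <- stage("digest", read_fasta(config$genome_fasta))
  catalog_all <- stage("digest", digest_genome(genome))
  catalog <- stage("digest", assign_cpgs_to_fragments(
    locate_cpgs(genome),
    filter_fragments_by_size(catalog_all, config$size_min, config$size_max)))
  write_catalog_bed(catalog, file.path(outdir, "fragments.bed"))
  note("digest: %d fragments, %d in [%d,%d] bp, %d CpGs on fragments",
       nrow(catalog_all$fragments), nrow(catalog$fragments),
       config$size_min, config$size_max,
       sum(!is.na(catalog$cpgs$fragment_id)))

  sheet <- stage("methylome", read_sample_sheet(config$sample_sheet,
                                                cov_min = config$cov_min))
  samples <- sheet$samples
  frag_tabs <- stage("methylome", lapply(samples, fragment_methylation,
                                         catalog = catalog,
                                         cov_min = config$cov_min,
                                         min_cpgs = config$min_cpgs))
  global <- vapply(samples, global_mean_methylation,
                   cov_min = config$cov_min, numeric(1))
  tree <- stage("methylome", cluster_samples(samples, cov_min = config$cov_min))
  write_newick(tree, file.path(outdir, "clustering.nwk"))
  note("methylome: %d samples; analysable fragments per sample %s",
       length(samples),
       paste(names(frag_tabs), vapply(frag_tabs, nrow, 0L),
             sep = "=", collapse = ", "))

  roles <- vapply(samples, `[[`, "", "role")
  pair_of <- vapply(samples, function(s) s$pair_id %||% NA_character_, "")
  pair_ids <- sort(unique(stats::na.omit(pair_of[roles == "primary"])))
  has_normal <- any(roles == "normal")
  dmfs_pm <- list()
  dmfs_np <- list()
  for (p in pair_ids) {
    pri <- names(samples)[roles == "primary" & pair_of == p]
    met <- names(samples)[roles == "metastatic" & pair_of == p]
    dmfs_pm[[p]] <- stage("dmf", call_dmfs(
      frag_tabs[[pri]], frag_tabs[[met]], pair_id = p,
      comparison = "primary_vs_metastatic",
      alpha = config$alpha, delta_min = config$delta_min))
    write_tsv_meta(dmfs_pm[[p]],
                   file.path(outdir, sprintf("dmf_%s_primary_vs_metastatic.tsv", p)),
                   meta)
    if (has_normal) {
      nrm <- names(samples)[roles == "normal"][1]
      dmfs_np[[p]] <- stage("dmf", call_dmfs(
        frag_tabs[[nrm]], frag_tabs[[pri]], pair_id = p,
        comparison = "normal_vs_primary",
        alpha = config$alpha, delta_min = config$delta_min))
      write_tsv_meta(dmfs_np[[p]],
                     file.path(outdir, sprintf("dmf_%s_normal_vs_primary.tsv", p)),
                     meta)
    }
    note("dmf %s: tested %d, significant %d (pm)", p, nrow(dmfs_pm[[p]]),
         sum(dmfs_pm[[p]]$significant))
  }

  screen <- NULL
  patterns <- NULL
  if (length(dmfs_pm) >= 2) {
    screen <- stage("screen", intersect_dmfs(dmfs_pm))
    write_tsv_meta(screen$shared, file.path(outdir, "shared_dmfs.tsv"), meta)
    if (has_normal)
      patterns <- stage("screen",
                        classify_progression_pattern(dmfs_np, dmfs_pm))
    note("screen: %d shared-in-all", sum(screen$shared$in_all))
  }

  validation <- NULL
  if (config$simulate && !is.null(config$cohort) && !is.null(screen) &&
      any(screen$shared$in_all & screen$shared$direction_consistent)) {
    cohort <- stage("validate", simulate_cohort(truth, catalog, config$cohort,
                                                seed = config$seed + 2L))
    keep <- screen$shared$in_all & screen$shared$direction_consistent
    validation <- stage("validate", cohort_validate(
      screen$shared[keep, , drop = FALSE], cohort, window = config$window,
      alpha = config$alpha))
    write_tsv_meta(validation, file.path(outdir, "cohort_validation.tsv"), meta)
    note("validate: %d matched probes, %d concordant", nrow(validation),
         sum(validation$direction_concordant))
  } else {
    note("validate: skipped (no cohort configured)")
  }

  summary <- c(config_hash = hash, seed = as.character(config$seed),
               n_fragments_total = as.character(nrow(catalog_all$fragments)),
               n_fragments_in_range = as.character(nrow(catalog$fragments)),
               n_samples = as.character(length(samples)))
  for (i in seq_len(nrow(sheet$replicate_r)))
    summary[paste0("replicate_r_", sheet$replicate_r$sample_id[i])] <-
      sprintf("%.6f", sheet$replicate_r$r[i])
  for (s in names(global))
    summary[paste0("global_meth_pct_", s)] <- sprintf("%.4f", global[s])
  for (p in names(dmfs_pm)) {
    sd <- summarize_direction(dmfs_pm[[p]])
    summary[paste0("dmfs_pm_", p)] <- as.character(sum(sd))
    summary[paste0("dmfs_pm_", p, "_hyper")] <- as.character(sd[["hyper"]])
    summary[paste0("dmfs_pm_", p, "_hypo")] <- as.character(sd[["hypo"]])
  }
  for (p in names(dmfs_np))
    summary[paste0("dmfs_np_", p)] <- as.character(sum(dmfs_np[[p]]$significant))
  if (!is.null(screen)) {
    cd <- common_direction_dmfs(screen$shared)
    summary["shared_in_all"] <- as.character(sum(screen$shared$in_all))
    summary["hyper_in_all"] <- as.character(length(cd$hyper_in_all))
    summary["hypo_in_all"] <- as.character(length(cd$hypo_in_all))
  }
  if (!is.null(patterns))
    summary["n_progression_classified"] <- as.character(nrow(patterns))
  if (!is.null(truth)) {
    planted_shared <- truth$labels$fragment_id[truth$labels$label == "dmf_shared" &
                                               is.na(truth$labels$pattern)]
    if (length(planted_shared) && !is.null(screen)) {
      cd <- common_direction_dmfs(screen$shared)
      rec <- intersect(planted_shared, c(cd$hyper_in_all, cd$hypo_in_all))
      summary["planted_shared"] <- as.character(length(planted_shared))
      summary["planted_shared_recovered"] <- as.character(length(rec))
      summary["shared_recovery_sensitivity"] <-
        sprintf("%.6f", length(rec) / length(planted_shared))
    }
  }
  if (!is.null(validation)) {
    summary["validation_probes"] <- as.character(nrow(validation))
    summary["validation_concordant"] <-
      as.character(sum(validation$direction_concordant))
  }
  sm_df <- data.frame(key = names(summary), value = unname(summary),
                      stringsAsFactors = FALSE)
  write_tsv_meta(sm_df, file.path(outdir, "summary.tsv"), meta)
  writeLines(log_lines, file.path(outdir, "pipeline.log"))

  invisible(list(config = config, catalog = catalog, samples = samples,
                 fragment_tables = frag_tabs, replicate_r = sheet$replicate_r,
                 global_methylation = global, tree = tree, truth = truth,
                 dmfs_primary_metastatic = dmfs_pm,
                 dmfs_normal_primary = dmfs_np, screen = screen,
                 patterns = patterns, validation = validation,
                 summary = summary))
}
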