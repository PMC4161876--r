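#' Read a pipeline run configuration from YAML
#'
#' The YAML may contain a `simulate:` mapping (any [simulation_config()]
#' argument) and a `screen:` mapping (any [run_screen()] parameter except the
#' data arguments). Unknown keys are rejected so typos fail before any
#' compute.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `simulate` (a `sim_config`) and `screen`
#'   (named list of screen parameters).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("simulate", "screen"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown config sections: %s", paste(bad, collapse = ", ")))
  }
  sim_args <- raw$simulate %||% list()
  bad <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad) > 0L) {
    abort(sprintf("unknown simulate parameters: %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(sim_args$ct_fold_changes)) {
    sim_args$ct_fold_changes <- unlist(sim_args$ct_fold_changes)
  }
  screen_args <- raw$screen %||% list()
  allowed <- setdiff(
    names(formals(run_screen)),
    c("ctss", "windows", "chains", "annotation", "...")
  )
  bad <- setdiff(names(screen_args), allowed)
  if (length(bad) > 0L) {
    abort(sprintf("unknown screen parameters: %s", paste(bad, collapse = ", ")))
  }
  list(simulate = do.call(simulation_config, sim_args), screen = screen_args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full synthetic screen pipeline
#'
#' Orchestrates simulate -> lift -> quantify -> screen, plus the companion
#' parsimony, delta-delta-Ct and calcium analyses, writing every artifact and
#' a JSON run-metadata file under `out_dir`. All inputs are written to disk
#' and read back through the package's parsers, so the run also exercises
#' every format round trip. Identical config and seed give identical outputs.
#'
#' @param config A [simulation_config()] (or the `simulate` element of
#'   [read_run_config()] output).
#' @param out_dir Output directory.
#' @param screen_params Named list of [run_screen()] parameters
#'   (`library_subset` defaults to all simulated libraries).
#' @return Invisibly, a list with the `or_screen` object (`screen`), the
#'   truth-comparison `report`, the parsimony fit, the ddCt table, the
#'   calcium calls and summary, and all written `paths`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         screen_params = list()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")

  sim <- run_stage("simulate", simulate_dataset(config, in_dir))

  # read everything back through the parsers
  ctss <- run_stage("read", {
    libs <- sort(grep("\\.ctss$", list.files(in_dir, full.names = TRUE),
                      value = TRUE))
    purrr::map_dfr(libs, read_ctss)
  })
  chains <- run_stage("read", read_chain(sim$paths$chain))
  src_ann <- run_stage("read", read_bed(sim$paths$src_bed))
  tgt_ann <- run_stage("read", read_bed(sim$paths$tgt_bed))

  windows <- run_stage("lift", build_tss_windows(
    src_ann |> select(id = "locus_id", "chrom", "tss", "strand"),
    width = config$window_width
  ))

  screen_args <- c(
    list(ctss = ctss, windows = windows, chains = chains,
         annotation = tgt_ann),
    screen_params
  )
  if (is.null(screen_args$library_subset)) {
    screen_args$library_subset <- sort(unique(ctss$library))
  }
  screen <- run_stage("screen", do.call(run_screen, screen_args))

  truth <- sim$genomes$truth
  cand <- screen$candidates
  expressed_ids <- truth$id[truth$expressed & truth$mapped & !truth$collision_second]
  decoy_ids <- truth$id[truth$decoy]
  art_ids <- cand$id[cand$artifact]
  report <- tibble(
    n_expressed = length(expressed_ids),
    n_recovered = sum(cand$verdict[cand$id %in% expressed_ids] == "candidate"),
    sensitivity = n_recovered / n_expressed,
    n_decoys = length(decoy_ids),
    n_decoys_flagged = sum(decoy_ids %in% art_ids),
    decoy_recall = n_decoys_flagged / n_decoys,
    artifact_precision = if (length(art_ids)) {
      mean(art_ids %in% decoy_ids)
    } else NA_real_,
    n_collisions_discarded = length(screen$discarded)
  )

  fit <- run_stage("phylo", mp_search(sim$msa, replicates = 10,
                                      seed = config$seed + 6L))
  qpcr <- run_stage("qpcr", ddct(
    read_ct_table(sim$paths$ct), sim$ct$reference_genes,
    sim$ct$calibrator_samples
  ))
  traces <- run_stage("calcium", read_traces(sim$paths$traces))
  calls <- run_stage("calcium", calcium_calls(
    traces, t_on = config$stim_on, t_off = config$stim_off
  ))
  pop <- summarize_population(calls)

  paths <- list(
    candidates = file.path(out_dir, "candidates.tsv"),
    report = file.path(out_dir, "truth_report.tsv"),
    metadata = file.path(out_dir, "run_metadata.json"),
    tree = file.path(out_dir, "mp_tree.nwk"),
    qpcr = file.path(out_dir, "ddct.tsv"),
    calcium = file.path(out_dir, "calcium_calls.tsv")
  )
  write_candidates(tidy(screen), paths$candidates)
  readr::write_tsv(report, paths$report)
  write_newick(fit$trees[[1]], paths$tree)
  readr::write_tsv(qpcr, paths$qpcr)
  readr::write_tsv(calls, paths$calcium)
  jsonlite::write_json(
    list(
      seed = config$seed,
      config = unclass(config),
      screen_params = screen$params,
      q3 = screen$q3,
      stage_counts = as.list(screen$stage_counts),
      mp_score = fit$score,
      calcium_population = as.list(pop)
    ),
    paths$metadata, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    screen = screen, report = report, mp_fit = fit, qpcr = qpcr,
    calcium_calls = calls, calcium_population = pop,
    truth = truth, paths = c(sim$paths, paths)
  ))
}
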