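# End-to-end pipeline: simulate -> analyze -> summarize -> test -> report.

# cheap stable checksum of a configuration (hex string); good enough to
# spot a changed config in a manifest, not cryptographic
.config_hash <- function(cfg) {
  s <- paste(vapply(unclass(cfg), function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    collapse = ";")
  codes <- utf8ToInt(s)
  h <- 5381
  for (c in codes) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", h)
}

# derive per-stage child seeds from one global seed (kept below 2^31)
.child_seed <- function(seed, stage) {
  (as.numeric(seed) * 1009 + stage * 9176) %% 2147483647
}

#' Run the full analysis pipeline
#'
#' Simulates the configured study, filters non-targeted jumps, analyzes
#' every trajectory, and writes the results table, per-height summary,
#' stratified permutation tests (overall and pairwise) for the take-off
#' velocities, the recovery report against generator truth, a
#' feasibility map for the highest target, and a run manifest.
#'
#' @param cfg a [study_config()].
#' @param out_dir output directory; created if needed.  `NULL` skips all
#'   file output.
#' @param seed optional global seed overriding `cfg$seed`; per-stage
#'   seeds are derived from it by a fixed splitting rule.
#' @param n_permutations permutations for the height-effect tests.
#' @return list of class `katyjump_run` with `manifest`, `results`,
#'   `summary`, `tests`, `pairwise`, `recovery`, `feasibility` and the
#'   simulated `study`, invisibly.
#' @export
run_pipeline <- function(cfg = study_config(), out_dir = NULL, seed = NULL,
                         n_permutations = 999) {
  if (!is.null(seed)) {
    cfg$seed <- as.integer(.child_seed(seed, 1))
  }
  study <- simulate_study(cfg)

  n_total <- nrow(study$assignments)
  keep <- study$assignments$targeted
  excluded <- study$assignments$jump_id[!keep]
  kept_study <- study
  kept_study$trajectories <- study$trajectories[keep]
  kept_study$assignments <- study$assignments[keep, , drop = FALSE]

  results <- tryCatch(analyze_study(kept_study),
                      error = function(e)
                        stop("analysis stage failed: ",
                             conditionMessage(e), call. = FALSE))
  stopifnot(nrow(results) + length(excluded) == n_total)

  summary_tab <- summarize_study(results)
  test_seed <- .child_seed(cfg$seed, 2)
  tests <- lapply(c(lv = "lv", av = "av"), function(resp)
    stratified_permutation_test(results[[resp]], results$target_height,
                                results$animal_id,
                                n_permutations = n_permutations,
                                seed = test_seed))
  pairwise <- pairwise_height_tests(results$av, results$target_height,
                                    results$animal_id,
                                    n_permutations = n_permutations,
                                    seed = test_seed)
  recovery <- recovery_report(results,
                              study$truth[study$truth$jump_id %in%
                                            results$jump_id, , drop = FALSE])
  top <- max(cfg$heights)
  fmap <- feasibility_map(top,
                          speed_grid = seq(0.5, 3, length.out = 26),
                          av_grid = seq(0, 120, length.out = 25),
                          y0 = cfg$y0)

  manifest <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("katyjump")),
                   n_jumps = n_total, n_analyzed = nrow(results),
                   n_excluded = length(excluded),
                   excluded_jumps = excluded,
                   timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(results, file.path(out_dir, "results.csv"))
    write_results_table(summary_tab, file.path(out_dir, "summary.csv"))
    write_results_table(recovery, file.path(out_dir, "recovery.csv"))
    write_results_table(pairwise, file.path(out_dir, "pairwise_tests.csv"))
    utils::write.csv(fmap, file.path(out_dir, "feasibility_map.csv"))
    test_tab <- data.frame(response = names(tests),
                           statistic = vapply(tests, `[[`, 0,
                                              "observed_statistic"),
                           p = vapply(tests, `[[`, 0, "p"))
    write_results_table(test_tab, file.path(out_dir, "height_tests.csv"))
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  message(sprintf("pipeline: %d jumps simulated, %d analyzed, %d excluded",
                  n_total, nrow(results), length(excluded)))
  invisible(structure(list(manifest = manifest, results = results,
                           summary = summary_tab, tests = tests,
                           pairwise = pairwise, recovery = recovery,
                           feasibility = fmap, study = study),
                      class = "katyjump_run"))
}
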