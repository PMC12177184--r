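# Descriptive summaries, the animal-stratified permutation test for
# target-height effects, and recovery reports against generator truth.
#
# Inference here is deliberately design-based: the height effect is tested
# by permuting height labels WITHIN each animal, which conditions on the
# per-animal jump counts and makes the test exact under the null that
# height is exchangeable within animal.  No variance components are
# estimated.

#' Per-height summary of a response
#'
#' @param values numeric response, one value per jump.
#' @param heights target height of each jump.
#' @param animals optional animal id of each jump; when given, an
#'   animal-level (cluster) standard error of the mean is also reported
#'   (SD of per-animal means divided by sqrt of the number of animals),
#'   which respects the repeated sampling of each animal.
#' @return data frame with one row per height: `height`, `n`, `mean`,
#'   `sd`, `se` (sample SD / sqrt(n); `NA`-flagged when `n < 2`), and
#'   `se_animal` when `animals` is supplied.
#' @export
summarize_response <- function(values, heights, animals = NULL) {
  if (length(values) == 0L) stop("no values to summarize")
  hs <- sort(unique(heights))
  out <- do.call(rbind, lapply(hs, function(h) {
    v <- values[heights == h]
    n <- length(v)
    data.frame(height = h, n = n, mean = mean(v),
               sd = if (n >= 2) stats::sd(v) else NA_real_,
               se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_)
  }))
  if (!is.null(animals)) {
    out$se_animal <- vapply(hs, function(h) {
      sel <- heights == h
      am <- tapply(values[sel], animals[sel], mean)
      if (length(am) >= 2) stats::sd(am) / sqrt(length(am)) else NA_real_
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Summary table over several responses of a results data frame
#'
#' @param results per-jump results (rows from [analyze_jump()] /
#'   [analyze_study()]).
#' @param responses column names to summarize.
#' @return long data frame with a `response` column followed by the
#'   [summarize_response()] columns.
#' @export
summarize_study <- function(results,
                            responses = c("lv", "av", "lv_secant",
                                          "av_secant", "ftj_rest",
                                          "ftj_takeoff", "air_time",
                                          "rot_fraction")) {
  responses <- intersect(responses, names(results))
  out <- do.call(rbind, lapply(responses, function(resp) {
    s <- summarize_response(results[[resp]], results$target_height,
                            results$animal_id)
    cbind(response = resp, s, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# test statistic: between-height weighted sum of squared height means of
# within-animal-centred values (invariant to per-animal constants)
.height_stat <- function(vc, heights) {
  m <- tapply(vc, heights, mean)
  n <- tabulate(match(heights, names(m)), nbins = length(m))
  sum(n * m^2)
}

#' Animal-stratified permutation test for a height effect
#'
#' Tests whether a per-jump response differs among target heights while
#' controlling for repeated sampling of the same animals.  The statistic
#' is the between-height weighted sum of squares of height means of
#' within-animal centred values; the null distribution is built by
#' permuting height labels within each animal (upper tail; the add-one
#' rule `(b + 1) / (m + 1)` keeps p in `(0, 1]`).
#'
#' @param values numeric response, one value per jump.
#' @param heights target height labels.
#' @param animals animal id labels.
#' @param n_permutations number of within-animal permutations (>= 99).
#' @param seed integer seed.
#' @return list of class `permutation_result` with `observed_statistic`,
#'   `p`, `n_permutations`, `seed` and `excluded_animals` (animals seen
#'   at fewer than two heights, dropped with a warning).
#' @export
stratified_permutation_test <- function(values, heights, animals,
                                        n_permutations = 999, seed = 1) {
  if (n_permutations < 99) stop("need at least 99 permutations")
  if (length(unique(heights)) < 2) stop("need at least 2 heights")
  n_h <- tapply(heights, animals, function(h) length(unique(h)))
  excluded <- names(n_h)[n_h < 2]
  if (length(excluded) > 0L) {
    warning("excluding animal(s) observed at a single height: ",
            paste(excluded, collapse = ", "))
    keep <- !(animals %in% excluded)
    values <- values[keep]; heights <- heights[keep]
    animals <- animals[keep]
  }
  if (length(values) == 0L) stop("no data left after exclusions")
  vc <- values - stats::ave(values, animals)
  obs <- .height_stat(vc, heights)
  groups <- split(seq_along(values), animals)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  b <- 0L
  hp <- heights
  for (i in seq_len(n_permutations)) {
    for (g in groups) hp[g] <- heights[g][sample.int(length(g))]
    if (.height_stat(vc, hp) >= obs - 1e-12) b <- b + 1L
  }
  structure(list(observed_statistic = obs, p = (b + 1) / (n_permutations + 1),
                 n_permutations = n_permutations, seed = seed,
                 excluded_animals = excluded),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Stratified permutation test: statistic %.4g, ",
                     "p = %.4g (%d permutations)\n"),
              x$observed_statistic, x$p, x$n_permutations))
  if (length(x$excluded_animals) > 0L)
    cat("  excluded animals:", paste(x$excluded_animals, collapse = ", "),
        "\n")
  invisible(x)
}

#' Pairwise height contrasts by stratified permutation, Holm-corrected
#'
#' @inheritParams stratified_permutation_test
#' @return data frame with one row per height pair: `height_a`,
#'   `height_b`, `p`, `p_adjusted` (Holm).
#' @export
pairwise_height_tests <- function(values, heights, animals,
                                  n_permutations = 999, seed = 1) {
  hs <- sort(unique(heights))
  pairs <- utils::combn(hs, 2)
  res <- apply(pairs, 2, function(pr) {
    sel <- heights %in% pr
    t <- suppressWarnings(
      stratified_permutation_test(values[sel], heights[sel], animals[sel],
                                  n_permutations, seed))
    t$p
  })
  out <- data.frame(height_a = pairs[1, ], height_b = pairs[2, ], p = res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Recovery report of pipeline estimates against generator truth
#'
#' Joins per-jump estimates and truth by `jump_id` and reports, per
#' response and target height, the bias (mean estimate minus truth), the
#' RMSE, and the coverage: the fraction of jumps whose absolute error is
#' below a per-response tolerance (three times the tracking-noise
#' propagated error of the estimator under the default study settings).
#'
#' @param estimates per-jump results from [analyze_study()].
#' @param truth generator truth table (`study$truth`).
#' @param responses named estimate columns to compare; values are the
#'   matching truth columns.
#' @param tolerances named per-response coverage tolerances.
#' @return data frame `(response, height, n, bias, rmse, coverage)`.
#' @export
recovery_report <- function(estimates, truth,
                            responses = c(lv = "lv", av = "av",
                                          av_secant = "av",
                                          ftj_rest = "ftj_rest",
                                          ftj_takeoff = "ftj_takeoff",
                                          air_time = "air_time"),
                            tolerances = c(lv = 0.2, av = 20,
                                           av_secant = 3,
                                           ftj_rest = 5, ftj_takeoff = 5,
                                           air_time = 1.5e-3)) {
  i <- match(estimates$jump_id, truth$jump_id)
  if (anyNA(i))
    stop("truth table missing jump(s): ",
         paste(estimates$jump_id[is.na(i)], collapse = ", "))
  truth <- truth[i, , drop = FALSE]
  hs <- sort(unique(estimates$target_height))
  rows <- list()
  for (resp in names(responses)) {
    err <- estimates[[resp]] - truth[[responses[[resp]]]]
    for (h in hs) {
      sel <- estimates$target_height == h
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, height = h, n = sum(sel),
        bias = mean(err[sel]),
        rmse = sqrt(mean(err[sel]^2)),
        coverage = mean(abs(err[sel]) < tolerances[[resp]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
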