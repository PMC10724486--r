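#' Descriptive statistics of a response matrix
#'
#' Total-score mean/SD/range, per-item category frequencies and covariate
#' frequency tables (count and percent), the standard opening table of a
#' bank-evaluation report.
#'
#' @param responses a [response_matrix()].
#' @return List of class `response_description`: `n`, `total_score`
#'   (mean, sd, min, max over listwise-complete rows; sd is `NA` when
#'   fewer than 2 complete rows), `category_freq` (K x J counts),
#'   `covariates` (list of data frames).
#' @export
describe_responses <- function(responses) {
  stopifnot(inherits(responses, "response_matrix"))
  x <- complete_responses(responses)
  total <- rowSums(x)
  freq <- apply(responses$responses, 2L, tabulate, nbins = responses$K)
  rownames(freq) <- paste0("cat", seq_len(responses$K))
  covs <- NULL
  if (!is.null(responses$covariates)) {
    covs <- lapply(responses$covariates, function(v) {
      tb <- table(v, useNA = "no")
      data.frame(level = names(tb), n = as.vector(tb),
                 percent = round(100 * as.vector(tb) / sum(tb), 1L),
                 stringsAsFactors = FALSE)
    })
  }
  structure(list(
    n = nrow(responses$responses), n_complete = nrow(x),
    total_score = c(mean = mean(total),
                    sd = if (length(total) >= 2L) stats::sd(total) else NA_real_,
                    min = suppressWarnings(min(total)),
                    max = suppressWarnings(max(total))),
    category_freq = freq, covariates = covs),
    class = "response_description")
}

#' @export
print.response_description <- function(x, ...) {
  cat(sprintf("n = %d (%d complete); total score mean %.2f, sd %.2f, range %g-%g\n",
              x$n, x$n_complete, x$total_score["mean"], x$total_score["sd"],
              x$total_score["min"], x$total_score["max"]))
  invisible(x)
}

#' Run the full bank-evaluation pipeline
#'
#' Executes, in order: descriptives, classical reliability, GRM
#' assumption checks, MML-EM calibration, item screening, fit indices,
#' information/OCC/TIC tables, and DIF for each requested grouping.
#' Criterion failures (e.g. an eigenvalue ratio below 3) are reported in
#' the summary, never fatal: a screening tool must show the evidence
#' either way. When `out_dir` is given, per-stage CSVs plus one
#' machine-readable `summary.json` (with the full settings echoed for
#' provenance) are written.
#'
#' @param responses a [response_matrix()] (or a path readable by
#'   [read_responses()]).
#' @param groupings character vector of binary covariate columns to test
#'   for DIF (default: all covariates present).
#' @param out_dir optional output directory for the report bundle.
#' @param grid a [theta_grid()].
#' @param tol,max_cycles EM settings passed to [fit_grm()].
#' @param n_bins monotonicity bins.
#' @param min_n minimum sample size for calibration.
#' @param compute_fit if `FALSE`, skip the (relatively expensive) M2 fit
#'   indices.
#' @return List of class `grm_pipeline` with elements `describe`,
#'   `reliability`, `assumptions`, `fit`, `screening`, `fit_indices`,
#'   `information`, `tic`, `dif`, `dif_summary`, `settings`.
#' @export
run_pipeline <- function(responses, groupings = NULL, out_dir = NULL,
                         grid = theta_grid(), tol = 1e-4, max_cycles = 500L,
                         n_bins = 8L, min_n = 100L, compute_fit = TRUE) {
  if (is.character(responses)) responses <- read_responses(responses)
  stopifnot(inherits(responses, "response_matrix"))
  if (is.null(groupings) && !is.null(responses$covariates))
    groupings <- names(responses$covariates)

  desc <- describe_responses(responses)
  rel <- reliability_report(responses)
  fit <- fit_grm(responses, grid = grid, tol = tol, max_cycles = max_cycles,
                 min_n = min_n)
  assum <- check_assumptions(responses, fit)
  screen <- screen_items(fit$bank)
  fi <- if (compute_fit) fit_indices(responses, fit, grid)
  info <- information_summary(fit$bank)
  tic <- test_information(fit$bank, seq(-4, 4, by = 0.1))
  dif <- list()
  for (grp in groupings) dif[[grp]] <- dif_olr(responses, grp)
  difsum <- dif_report(dif)

  settings <- list(quadrature = length(grid$nodes),
                   theta_range = range(grid$nodes), tol = tol,
                   max_cycles = max_cycles, n_bins = n_bins, min_n = min_n,
                   groupings = groupings)
  out <- structure(list(describe = desc, reliability = rel,
                        assumptions = assum, fit = fit, screening = screen,
                        fit_indices = fi, information = info, tic = tic,
                        dif = dif, dif_summary = difsum, settings = settings),
                   class = "grm_pipeline")
  if (!is.null(out_dir)) write_pipeline_bundle(out, out_dir)
  out
}

#' @export
print.grm_pipeline <- function(x, ...) {
  cat("== bank evaluation pipeline ==\n")
  print(x$describe)
  print(x$reliability)
  print(x$assumptions)
  print(x$fit)
  if (!is.null(x$fit_indices)) print(x$fit_indices)
  cat(sprintf("screening: %d/%d items pass all rules\n",
              sum(x$screening$a_ok & x$screening$b_ok & x$screening$interval_ok),
              nrow(x$screening)))
  if (nrow(x$dif_summary)) print(as.data.frame(x$dif_summary))
  invisible(x)
}

write_pipeline_bundle <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$reliability$items, file.path(out_dir, "reliability.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(x$screening), file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(x$information),
                   file.path(out_dir, "information.csv"), row.names = FALSE)
  utils::write.csv(x$tic, file.path(out_dir, "tic.csv"), row.names = FALSE)
  if (!is.null(x$assumptions$q3))
    utils::write.csv(as.data.frame(x$assumptions$q3$q3),
                     file.path(out_dir, "residual_correlations.csv"))
  mono <- x$assumptions$monotonicity$curves
  mono_tab <- do.call(rbind, Map(function(id, cu)
    cbind(item_id = id, cu), names(mono), mono))
  utils::write.csv(mono_tab, file.path(out_dir, "monotonicity.csv"),
                   row.names = FALSE)
  for (grp in names(x$dif))
    utils::write.csv(as.data.frame(x$dif[[grp]]),
                     file.path(out_dir, paste0("dif_", grp, ".csv")),
                     row.names = FALSE)
  write_bank(x$fit$bank, file.path(out_dir, "bank.json"))
  summ <- list(
    n = x$describe$n,
    alpha = x$reliability$alpha,
    kmo = x$assumptions$kmo,
    bartlett_p = x$assumptions$bartlett$p,
    eigenvalue_ratio = x$assumptions$eigen$ratio,
    q3_max_abs = if (!is.null(x$assumptions$q3)) x$assumptions$q3$max_abs,
    verdicts = as.list(x$assumptions$verdicts),
    loglik = x$fit$loglik, converged = x$fit$converged,
    rmsea = if (!is.null(x$fit_indices)) x$fit_indices$rmsea,
    cfi = if (!is.null(x$fit_indices)) x$fit_indices$cfi,
    tli = if (!is.null(x$fit_indices)) x$fit_indices$tli,
    tic_max = max(x$tic$info),
    tic_argmax = x$tic$theta[which.max(x$tic$info)],
    n_high_info = attr(x$information, "n_high"),
    dif = if (nrow(x$dif_summary)) x$dif_summary else NULL,
    settings = x$settings)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
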