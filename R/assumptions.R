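#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO computed from the anti-image (partial) correlations:
#' \eqn{KMO = \sum_{i \ne j} r_{ij}^2 / (\sum_{i \ne j} r_{ij}^2 +
#' \sum_{i \ne j} q_{ij}^2)}, with \eqn{q_{ij} = -s_{ij}/\sqrt{s_{ii}s_{jj}}}
#' from the inverse correlation matrix S. Values close to 1 support
#' component analysis.
#'
#' @param responses a [response_matrix()] (or numeric matrix); Pearson
#'   correlations of the raw ordinal codes, listwise-complete rows.
#' @return KMO statistic in \[0, 1\].
#' @export
kmo_statistic <- function(responses) {
  R <- stats::cor(resp_complete_matrix(responses))
  S <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; consider removing collinear items",
         call. = FALSE))
  q <- -S / sqrt(outer(diag(S), diag(S)))
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' \eqn{\chi^2 = -(n - 1 - (2J + 5)/6)\,\ln|R|} with df = J(J-1)/2,
#' against the identity-correlation null.
#'
#' @inheritParams kmo_statistic
#' @return List: `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(responses) {
  x <- resp_complete_matrix(responses)
  n <- nrow(x); J <- ncol(x)
  if (n <= J) stop("Bartlett's test needs n > J", call. = FALSE)
  detR <- det(stats::cor(x))
  if (detR <= 0) stop("correlation matrix is not positive definite", call. = FALSE)
  chi2 <- -(n - 1 - (2 * J + 5) / 6) * log(detR)
  df <- J * (J - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Eigenvalue ratio check of unidimensionality
#'
#' Principal components of the Pearson correlation matrix of the raw
#' ordinal scores; essential unidimensionality is accepted when the first
#' two roots satisfy lambda1/lambda2 > `cutoff`.
#'
#' @inheritParams kmo_statistic
#' @param cutoff pass threshold on the ratio (default 3).
#' @return List: `eigenvalues` (nonincreasing, summing to J), `ratio`,
#'   `verdict`.
#' @export
eigenvalue_ratio <- function(responses, cutoff = 3) {
  x <- resp_complete_matrix(responses)
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  list(eigenvalues = ev, ratio = ev[1L] / ev[2L],
       verdict = ev[1L] / ev[2L] > cutoff)
}

#' Residual correlations (Yen's Q3) for local independence
#'
#' Per-person item residuals, observed score minus the model-expected
#' score \eqn{\sum_k k P_k(\hat\theta_i)} at the person's EAP theta, are
#' correlated across item pairs. Under local independence Q3 values are
#' small with a slight negative bias (about -1/(J-1)); the pass rule is
#' max |Q3| below `cutoff` over off-diagonal pairs.
#'
#' @param responses a [response_matrix()].
#' @param fit a [fit_grm()] result (or an [item_bank()] taken as already
#'   calibrated).
#' @param grid a [theta_grid()] for EAP scoring.
#' @param cutoff pass threshold on |Q3| (default 0.70).
#' @return List: `q3` (J x J matrix, diagonal `NA`), `max_abs`, `range`,
#'   `verdict`, `method`.
#' @export
residual_correlations <- function(responses, fit, grid = theta_grid(),
                                  cutoff = 0.70) {
  bank <- if (inherits(fit, "grm_fit")) fit$bank else fit
  stopifnot(inherits(bank, "item_bank"))
  x <- responses$responses
  keep <- rowSums(!is.na(x)) >= 2L
  x <- x[keep, , drop = FALSE]
  rm2 <- response_matrix(x, K = responses$K)
  eap <- eap_scores(bank, rm2, grid)$eap_theta
  ids <- item_ids(bank)
  res <- x
  for (j in seq_len(ncol(x))) {
    it <- bank[[match(colnames(x)[j], ids)]]
    expected <- as.vector(category_prob(it, eap) %*% seq_len(bank$K))
    res[, j] <- x[, j] - expected
  }
  q3 <- suppressWarnings(stats::cor(res, use = "pairwise.complete.obs"))
  diag(q3) <- NA_real_
  list(q3 = q3, max_abs = max(abs(q3), na.rm = TRUE),
       range = range(q3, na.rm = TRUE),
       verdict = max(abs(q3), na.rm = TRUE) < cutoff,
       method = "Yen Q3 on GRM residuals at EAP theta")
}

#' Monotonicity check via rest-score conditional means
#'
#' The rest score (total minus the item) is cut into quantile bins (bins
#' merged until each holds at least `min_bin`); the mean item score per
#' bin should be non-decreasing. A bin-to-bin drop larger than
#' `tolerance` flags a violation; the tolerance absorbs binomial noise at
#' the minimum bin size.
#'
#' @param responses a [response_matrix()].
#' @param n_bins target number of rest-score bins (default 8).
#' @param min_bin minimum persons per bin after merging (default 30).
#' @param tolerance allowed bin-to-bin decrease in mean score (default
#'   0.05).
#' @return List of class `monotonicity_report`: `curves` (one data frame
#'   per item: `bin`, `rest_mean`, `item_mean`, `n`), `violations`
#'   (logical per item), `verdict`.
#' @export
monotonicity_curves <- function(responses, n_bins = 8L, min_bin = 30L,
                                tolerance = 0.05) {
  x <- resp_complete_matrix(responses)
  if (n_bins < 3L) stop("need at least 3 bins", call. = FALSE)
  if (nrow(x) < 3L * min_bin)
    stop("too few persons (", nrow(x), ") for ", min_bin, "-person bins",
         call. = FALSE)
  total <- rowSums(x)
  curves <- list(); viol <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    rest <- total - x[, j]
    br <- unique(stats::quantile(rest, probs = seq(0, 1, length.out = n_bins + 1L)))
    bins <- cut(rest, breaks = br, include.lowest = TRUE, labels = FALSE)
    # merge sparse bins with their left neighbour
    repeat {
      cnt <- table(bins)
      small <- which(cnt < min_bin)
      if (!length(small) || length(cnt) <= 2L) break
      s <- as.integer(names(cnt)[small[1L]])
      tgt <- if (s > min(bins)) max(bins[bins < s]) else min(bins[bins > s])
      bins[bins == s] <- tgt
    }
    lev <- sort(unique(bins))
    bins <- match(bins, lev)
    cur <- data.frame(
      bin = seq_along(lev),
      rest_mean = as.vector(tapply(rest, bins, mean)),
      item_mean = as.vector(tapply(x[, j], bins, mean)),
      n = as.vector(table(bins)))
    curves[[colnames(x)[j]]] <- cur
    viol[j] <- any(diff(cur$item_mean) < -tolerance)
  }
  names(viol) <- colnames(x)
  structure(list(curves = curves, violations = viol, verdict = !any(viol),
                 tolerance = tolerance, min_bin = min_bin),
            class = "monotonicity_report")
}

#' Run all three GRM precondition checks
#'
#' Unidimensionality (KMO, Bartlett, eigenvalue ratio), local independence
#' (Q3 residual correlations; requires a calibration) and monotonicity
#' (rest-score conditional means), each with its published decision rule.
#'
#' @param responses a [response_matrix()].
#' @param fit optional [fit_grm()] result or [item_bank()]; if omitted the
#'   Q3 check is skipped.
#' @param ratio_cutoff,q3_cutoff,monotonicity_tolerance decision rules.
#' @return List of class `assumption_report` with elements `kmo`,
#'   `bartlett`, `eigen`, `q3` (or `NULL`), `monotonicity`, `verdicts`.
#' @export
check_assumptions <- function(responses, fit = NULL, ratio_cutoff = 3,
                              q3_cutoff = 0.70, monotonicity_tolerance = 0.05) {
  kmo <- kmo_statistic(responses)
  bart <- bartlett_sphericity(responses)
  eig <- eigenvalue_ratio(responses, cutoff = ratio_cutoff)
  q3 <- if (!is.null(fit)) residual_correlations(responses, fit, cutoff = q3_cutoff)
  mono <- monotonicity_curves(responses, tolerance = monotonicity_tolerance)
  verdicts <- c(unidimensionality = unname(eig$verdict) && bart$p < 0.05,
                local_independence = if (is.null(q3)) NA else unname(q3$verdict),
                monotonicity = unname(mono$verdict))
  structure(list(kmo = kmo, bartlett = bart, eigen = eig, q3 = q3,
                 monotonicity = mono, verdicts = verdicts),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("KMO = %.3f; Bartlett chi2(%d) = %.1f, p = %.3g\n",
              x$kmo, x$bartlett$df, x$bartlett$chi2, x$bartlett$p))
  cat(sprintf("eigenvalue ratio lambda1/lambda2 = %.2f (%s)\n",
              x$eigen$ratio, if (x$eigen$verdict) "pass" else "fail"))
  if (!is.null(x$q3))
    cat(sprintf("Q3 range [%.2f, %.2f], max |Q3| = %.2f (%s)\n",
                x$q3$range[1L], x$q3$range[2L], x$q3$max_abs,
                if (x$q3$verdict) "pass" else "fail"))
  cat(sprintf("monotonicity: %s\n",
              if (x$monotonicity$verdict) "all items non-decreasing"
              else paste("violations:",
                         paste(names(which(x$monotonicity$violations)),
                               collapse = ", "))))
  invisible(x)
}
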