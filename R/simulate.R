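# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Default covariate specification of the study population
#'
#' Proportions for the three dichotomized person covariates: age group
#' (18-59 vs >= 60), gender (male vs female) and education group (junior
#' high school or below vs high school or above).
#'
#' @return Named list of named probability vectors.
#' @export
default_covariate_spec <- function() {
  list(age_group = c("18-59" = 0.645, "60+" = 0.355),
       gender = c(male = 0.380, female = 0.620),
       education = c(junior_high_or_below = 0.470, high_school_or_above = 0.530))
}

# draw one categorical response per person from the item's category
# probabilities at that person's theta, via the boundary representation
draw_item <- function(item, theta) {
  Ps <- boundary_prob(item, theta)           # n x (K-1), decreasing in k
  u <- stats::runif(length(theta))
  1L + rowSums(u < Ps)
}

#' Simulate graded responses from an item bank
#'
#' Persons' traits are drawn from Normal(`theta_mean`, `theta_sd`^2) and
#' each response from the item's GRM category probabilities at the
#' person's theta. Covariates are drawn independently of theta (no
#' impact) unless a group mean shift is requested via `impact`; optional
#' DIF is injected by answering selected items from a modified bank in
#' the focal group (see [inject_dif()]). True thetas are returned as an
#' attribute, never written into the response data.
#'
#' @param bank an [item_bank()].
#' @param n number of persons.
#' @param seed mandatory integer seed; the one seed drives the whole
#'   simulation and the caller's RNG state is left untouched.
#' @param theta_mean,theta_sd latent trait distribution (defaults 0, 1).
#' @param covariate_spec named list of named probability vectors (each
#'   summing to 1), as in [default_covariate_spec()]; `NULL` for no
#'   covariates.
#' @param dif_spec optional data frame with columns `item_id`, `grouping`,
#'   `type` (`"uniform"`/`"nonuniform"`), `magnitude`: the focal group
#'   (second level of the grouping covariate) answers those items from a
#'   shifted bank.
#' @param impact optional named numeric: theta mean shift for the focal
#'   level of the named covariates (distribution impact, distinct from
#'   DIF).
#' @return A [response_matrix()] with attribute `theta` (true traits).
#' @export
simulate_responses <- function(bank, n, seed, theta_mean = 0, theta_sd = 1,
                               covariate_spec = default_covariate_spec(),
                               dif_spec = NULL, impact = NULL) {
  stopifnot(inherits(bank, "item_bank"), n >= 2L)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  with_local_seed(seed, {
    covs <- NULL
    if (!is.null(covariate_spec)) {
      covs <- as.data.frame(lapply(covariate_spec, function(p) {
        stopifnot(abs(sum(p) - 1) < 1e-8)
        sample(names(p), n, replace = TRUE, prob = p)
      }), stringsAsFactors = FALSE)
    }
    theta <- stats::rnorm(n, theta_mean, theta_sd)
    if (!is.null(impact)) {
      for (nm in names(impact)) {
        lev <- names(covariate_spec[[nm]])
        theta <- theta + impact[[nm]] * (covs[[nm]] == lev[2L])
      }
    }
    x <- matrix(NA_integer_, n, length(bank),
                dimnames = list(NULL, item_ids(bank)))
    focal_banks <- list()
    if (!is.null(dif_spec)) {
      for (grp in unique(dif_spec$grouping))
        focal_banks[[grp]] <- inject_dif(bank, dif_spec[dif_spec$grouping == grp, ])
    }
    for (j in seq_len(length(bank))) {
      it <- bank[[j]]
      resp <- draw_item(it, theta)
      if (!is.null(dif_spec)) {
        for (grp in names(focal_banks)) {
          if (it$item_id %in% dif_spec$item_id[dif_spec$grouping == grp]) {
            lev <- names(covariate_spec[[grp]])
            focal <- covs[[grp]] == lev[2L]
            if (any(focal))
              resp[focal] <- draw_item(focal_banks[[grp]][[it$item_id]], theta[focal])
          }
        }
      }
      x[, j] <- resp
    }
    out <- response_matrix(x, K = bank$K, covariates = covs)
    attr(out, "theta") <- theta
    out
  })
}

#' Build a focal-group bank with injected DIF
#'
#' Uniform DIF shifts all thresholds of an item by `+magnitude` (the focal
#' group needs a higher trait level for the same response, so its expected
#' item score is lower at every theta); non-uniform DIF multiplies the
#' discrimination by `1 + magnitude`. The reference bank is untouched.
#'
#' @param bank reference [item_bank()].
#' @param dif_spec data frame with columns `item_id`, `type`
#'   (`"uniform"`/`"nonuniform"`), `magnitude`.
#' @return The focal-group [item_bank()].
#' @export
inject_dif <- function(bank, dif_spec) {
  stopifnot(inherits(bank, "item_bank"))
  items <- bank$items
  ids <- item_ids(bank)
  for (i in seq_len(nrow(dif_spec))) {
    j <- match(dif_spec$item_id[i], ids)
    if (is.na(j)) stop("unknown item id '", dif_spec$item_id[i], "'", call. = FALSE)
    it <- items[[j]]
    mag <- dif_spec$magnitude[i]
    stopifnot(is.finite(mag))
    if (dif_spec$type[i] == "uniform") {
      items[[j]] <- item_params(it$item_id, it$a, it$b + mag, it$wording)
    } else if (dif_spec$type[i] == "nonuniform") {
      items[[j]] <- item_params(it$item_id, it$a * (1 + mag), it$b, it$wording)
    } else stop("unknown DIF type '", dif_spec$type[i], "'", call. = FALSE)
  }
  item_bank(items, K = bank$K, metric = bank$metric)
}

#' Simulate a full study-shaped dataset
#'
#' One call producing the canonical integration fixture: 1075 persons
#' answering the 23 packaged bank items, theta ~ N(0,1), the three
#' dichotomized covariates at the study proportions (age 64.5/35.5,
#' gender 38.0/62.0, education 47.0/53.0), no DIF.
#'
#' @param seed integer seed.
#' @param n number of persons (default 1075).
#' @return A [response_matrix()] (1075 x 23 plus 3 covariates) with
#'   attribute `theta`.
#' @export
simulate_study <- function(seed, n = 1075L) {
  simulate_responses(load_default_bank(), n = n, seed = seed)
}
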