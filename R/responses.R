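#' Construct a response matrix
#'
#' Holds a persons-by-items grid of ordinal category codes in `1..K`
#' (missing entries allowed, stored as `NA`) together with optional
#' person-level categorical covariates (e.g. age group, gender, education
#' group) used by the DIF module. All interfaces speak the instrument's
#' observed coding `1..K`.
#'
#' @param values integer matrix (or data frame) of codes in `1..K`; `NA`
#'   marks a missing response. Column names are taken as item ids.
#' @param K number of response categories (default 5, a five-point Likert
#'   scale).
#' @param covariates optional data frame of per-person categorical columns,
#'   one row per person.
#' @param person_ids optional person identifiers (default `1..n` as
#'   character).
#' @return Object of class `response_matrix` with elements `responses`
#'   (integer matrix), `covariates`, `K`.
#' @export
response_matrix <- function(values, K = 5L, covariates = NULL, person_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 persons and 2 items", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("item", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate item name: ",
         colnames(values)[duplicated(colnames(values))][1L], call. = FALSE)
  storage <- suppressWarnings(as.numeric(values))
  bad <- which(!is.na(storage) & (storage != round(storage) | storage < 1 | storage > K))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "invalid response code '%s' at row %d, column '%s' (must be an integer in 1..%d)",
      as.character(values[bad[1L]]), rc[1L], colnames(values)[rc[2L]], K),
      call. = FALSE)
  }
  m <- matrix(as.integer(storage), nrow(values), ncol(values),
              dimnames = list(NULL, colnames(values)))
  if (is.null(person_ids)) person_ids <- as.character(seq_len(nrow(m)))
  stopifnot(length(person_ids) == nrow(m))
  rownames(m) <- person_ids
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    stopifnot(nrow(covariates) == nrow(m))
    for (nm in names(covariates)) {
      if (all(is.na(covariates[[nm]])))
        stop("covariate '", nm, "' has no observed level", call. = FALSE)
    }
  }
  structure(list(responses = m, covariates = covariates, K = as.integer(K)),
            class = "response_matrix")
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, K = %d, %d missing entries\n",
              nrow(x$responses), ncol(x$responses), x$K, sum(is.na(x$responses))))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Read a response matrix from a delimited text file
#'
#' Expects a header row; one person per row. Columns named in
#' `covariate_cols` (or matching `covariate_prefix`) are split off as
#' person covariates; all remaining columns are taken as item responses
#' and validated against `1..K`. Missing responses are preserved as `NA`,
#' never imputed.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension,
#'   override with `sep`).
#' @param missing_marker token representing a missing response (default
#'   `"NA"`).
#' @param covariate_cols character vector of covariate column names.
#' @param covariate_prefix alternatively, a prefix identifying covariate
#'   columns.
#' @param K number of categories.
#' @param sep field delimiter; `NULL` to infer.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, missing_marker = "NA", covariate_cols = NULL,
                           covariate_prefix = NULL, K = 5L, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = missing_marker, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (anyDuplicated(names(tab)))
    stop("duplicate item name in header: ",
         names(tab)[duplicated(names(tab))][1L], call. = FALSE)
  cov_nms <- covariate_cols
  if (!is.null(covariate_prefix))
    cov_nms <- union(cov_nms, grep(paste0("^", covariate_prefix), names(tab), value = TRUE))
  cov_nms <- intersect(cov_nms, names(tab))
  item_nms <- setdiff(names(tab), cov_nms)
  vals <- tab[item_nms]
  for (nm in item_nms) {
    v <- vals[[nm]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | num != round(num) | num < 1 | num > K))
    if (length(bad))
      stop(sprintf("invalid response code '%s' at row %d, column '%s' (must be an integer in 1..%d)",
                   v[bad[1L]], bad[1L], nm, K), call. = FALSE)
    vals[[nm]] <- as.integer(num)
  }
  response_matrix(as.matrix(vals), K = K,
                  covariates = if (length(cov_nms)) tab[cov_nms] else NULL)
}

#' Write a response matrix to CSV
#'
#' Covariate columns (if any) follow the item columns; missing responses
#' are written as `missing_marker`. Inverse of [read_responses()].
#'
#' @param x a `response_matrix`.
#' @param path output file.
#' @param missing_marker token for missing entries.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, missing_marker = "NA") {
  stopifnot(inherits(x, "response_matrix"))
  out <- as.data.frame(x$responses)
  if (!is.null(x$covariates)) out <- cbind(out, x$covariates)
  utils::write.csv(out, path, row.names = FALSE, na = missing_marker)
  invisible(path)
}

# rows with every item answered; attribute n_dropped records the listwise loss
complete_responses <- function(x) {
  keep <- stats::complete.cases(x$responses)
  structure(x$responses[keep, , drop = FALSE], n_dropped = sum(!keep))
}
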