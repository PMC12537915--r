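#' Normalize a decision matrix
#'
#' Puts all criteria on a common, benefit-oriented scale. Four methods are
#' provided: the model's logistic (sigmoid) standardization, plus the three
#' alternatives used by the robustness harness — fuzzy quantization (linear
#' min-max membership), decimal scaling and vector (Euclidean-norm)
#' normalization. After normalization "larger is better" holds for every
#' column: cost criteria are orientation-flipped by each method.
#'
#' @param X a [decision_matrix()].
#' @param method `"logistic"`, `"fq"` (fuzzy quantization), `"ds"` (decimal
#'   scaling) or `"vector"`.
#' @param ... passed to the method-specific function (e.g.
#'   `standardize_first` for `"logistic"`).
#' @return a `normalized_matrix` (same shape, method recorded).
#' @seealso [normalize_logistic()], [normalize_fuzzy_quantization()],
#'   [normalize_decimal_scaling()], [normalize_vector()]
#' @export
normalize <- function(X, method = c("logistic", "fq", "ds", "vector"), ...) {
  aliases <- c(fuzzy_quantization = "fq", decimal_scaling = "ds",
               vector_norm = "vector")
  m1 <- method[1L]
  if (is.character(m1) && m1 %in% names(aliases)) m1 <- aliases[[m1]]
  if (!is.character(m1) || length(m1) != 1L ||
      !(m1 %in% c("logistic", "fq", "ds", "vector"))) {
    abort_validation(paste0("unknown normalization method: ",
                            paste(method[1L], collapse = ", ")),
                     "mcdm_unknown_method_error")
  }
  switch(m1,
         logistic = normalize_logistic(X, ...),
         fq       = normalize_fuzzy_quantization(X, ...),
         ds       = normalize_decimal_scaling(X, ...),
         vector   = normalize_vector(X, ...))
}

check_dm <- function(X) {
  if (!inherits(X, "decision_matrix")) {
    abort_validation("input must be a decision_matrix")
  }
  invisible(X)
}

#' Logistic (sigmoid) normalization
#'
#' Maps each column through a logistic function: benefit criteria by
#' `1/(1 + exp(-x))` (increasing) and cost criteria by `1/(1 + exp(x))`
#' (decreasing), so that larger normalized values are always better. Because
#' raw criteria can differ by orders of magnitude — a raw sigmoid would
#' saturate at 0 or 1 and destroy discrimination — each column is z-scored
#' (mean 0, sd 1) before the sigmoid by default.
#'
#' @param X a [decision_matrix()].
#' @param standardize_first z-score columns before the sigmoid (default
#'   `TRUE`). With `TRUE`, a zero-variance column raises a degenerate-column
#'   error.
#' @param strict_verbatim apply the decreasing form `1/(1 + exp(x))` to
#'   *every* column regardless of direction. This reproduces the source
#'   formula exactly as printed but inverts merit order for benefit
#'   criteria; default `FALSE`.
#' @return a `normalized_matrix` with values strictly in (0, 1).
#' @export
normalize_logistic <- function(X, standardize_first = TRUE,
                               strict_verbatim = FALSE) {
  check_dm(X)
  V <- X$values
  if (standardize_first) {
    sds <- apply(V, 2, stats::sd)
    if (any(sds == 0)) {
      abort_degenerate(paste0("zero-variance column(s): ",
                              paste(colnames(V)[sds == 0], collapse = ", ")),
                       "mcdm_degenerate_column_error")
    }
    V <- scale(V)[, , drop = FALSE]
  }
  sign_mat <- matrix(rep(ifelse(X$directions == "cost", -1, 1),
                         each = nrow(V)), nrow(V))
  if (strict_verbatim) sign_mat[] <- -1
  out <- stats::plogis(sign_mat * V)
  dimnames(out) <- dimnames(X$values)
  new_normalized_matrix(X, out, "logistic")
}

#' Fuzzy-quantization (linear min-max membership) normalization
#'
#' Benefit: `(x - min)/(max - min)`; cost: `(max - x)/(max - min)`. Outputs
#' lie in \[0, 1\] with both endpoints attained in every column.
#'
#' @param X a [decision_matrix()].
#' @return a `normalized_matrix`.
#' @export
normalize_fuzzy_quantization <- function(X) {
  check_dm(X)
  V <- X$values
  rng <- apply(V, 2, range)
  const <- rng[1, ] == rng[2, ]
  if (any(const)) {
    abort_degenerate(paste0("constant column(s): ",
                            paste(colnames(V)[const], collapse = ", ")),
                     "mcdm_degenerate_column_error")
  }
  out <- sweep(sweep(V, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
  cost <- X$directions == "cost"
  out[, cost] <- 1 - out[, cost, drop = FALSE]
  new_normalized_matrix(X, out, "fuzzy_quantization")
}

#' Decimal-scaling normalization
#'
#' Each column is divided by `10^d`, with `d` the smallest integer such that
#' `max(|x|)/10^d <= 1`. Cost columns are then flipped as `1 - value`. An
#' all-zero column is returned unchanged (`d = 0`). Multiplying a column by
#' 10 leaves its output unchanged (scale equivariance).
#'
#' @param X a [decision_matrix()].
#' @return a `normalized_matrix`.
#' @export
normalize_decimal_scaling <- function(X) {
  check_dm(X)
  V <- X$values
  d <- vapply(seq_len(ncol(V)), function(j) {
    mx <- max(abs(V[, j]))
    if (mx == 0) 0 else max(0, ceiling(log10(mx)))
  }, numeric(1))
  # guard rounding: ensure max|x|/10^d <= 1 and d minimal
  for (j in seq_along(d)) {
    mx <- max(abs(V[, j]))
    while (mx / 10^d[j] > 1) d[j] <- d[j] + 1
    while (d[j] > 0 && mx / 10^(d[j] - 1) <= 1) d[j] <- d[j] - 1
  }
  out <- sweep(V, 2, 10^d, "/")
  cost <- X$directions == "cost"
  out[, cost] <- 1 - out[, cost, drop = FALSE]
  new_normalized_matrix(X, out, "decimal_scaling")
}

#' Vector (Euclidean-norm) normalization
#'
#' Each column is divided by its Euclidean norm, so each normalized column
#' has unit norm; cost columns are then flipped as `1 - value`.
#'
#' @param X a [decision_matrix()].
#' @return a `normalized_matrix`.
#' @export
normalize_vector <- function(X) {
  check_dm(X)
  V <- X$values
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) {
    abort_degenerate(paste0("all-zero column(s): ",
                            paste(colnames(V)[nrm == 0], collapse = ", ")),
                     "mcdm_degenerate_column_error")
  }
  out <- sweep(V, 2, nrm, "/")
  cost <- X$directions == "cost"
  out[, cost] <- 1 - out[, cost, drop = FALSE]
  new_normalized_matrix(X, out, "vector")
}
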