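#' Per-criterion sample standard deviation
#'
#' The contrast (dispersion) term of the DCRITIC weight: the sample standard
#' deviation (denominator `m - 1`) of each normalized column.
#'
#' @param N a `normalized_matrix` (or any `decision_matrix`).
#' @return named numeric vector of column standard deviations.
#' @export
column_sd <- function(N) {
  check_dm(N)
  if (nrow(N$values) < 2L) {
    abort_validation("need at least 2 alternatives to compute a standard deviation")
  }
  apply(N$values, 2, stats::sd)
}

#' Distance correlation between two numeric vectors
#'
#' The (biased, V-statistic) sample distance correlation of Szekely and
#' Rizzo: pairwise absolute-difference matrices are double-centered (row
#' means and column means subtracted, grand mean added back), the distance
#' covariance is the mean elementwise product of the centered matrices, and
#' `dCor = dCov / sqrt(dVar_u * dVar_v)`. Unlike Pearson correlation, dCor
#' lies in \[0, 1\] and is zero (in the population) only under independence,
#' which is what lets the DCRITIC weighting penalize *any* redundancy between
#' criteria, not just linear redundancy. If either marginal distance
#' variance is zero (a constant vector), 0 is returned.
#'
#' @param u,v numeric vectors of equal length `m >= 2`.
#' @return a single number in \[0, 1\].
#' @export
distance_correlation <- function(u, v) {
  if (length(u) != length(v)) {
    abort_validation("`u` and `v` must have the same length",
                     "mcdm_shape_error")
  }
  if (length(u) < 2L) abort_validation("need at least 2 observations")
  A <- dc_center(abs(outer(u, u, "-")))
  B <- dc_center(abs(outer(v, v, "-")))
  dcov2 <- mean(A * B)
  dvar2u <- mean(A * A)
  dvar2v <- mean(B * B)
  if (dvar2u <= 0 || dvar2v <= 0) return(0)
  r2 <- dcov2 / sqrt(dvar2u * dvar2v)
  sqrt(min(max(r2, 0), 1))
}

dc_center <- function(a) {
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, rm) + mean(a)
}

#' Pairwise distance-correlation matrix of criteria columns
#'
#' @param N a `normalized_matrix`.
#' @return symmetric n x n matrix with unit diagonal (0 on the diagonal for
#'   constant columns, by the constant-vector convention of
#'   [distance_correlation()]).
#' @export
dcor_matrix <- function(N) {
  check_dm(N)
  V <- N$values
  n <- ncol(V)
  DC <- diag(nrow = n)
  dimnames(DC) <- list(colnames(V), colnames(V))
  for (j in seq_len(n)) {
    DC[j, j] <- distance_correlation(V[, j], V[, j])
    if (j < n) for (jp in (j + 1L):n) {
      DC[j, jp] <- DC[jp, j] <- distance_correlation(V[, j], V[, jp])
    }
  }
  DC
}

#' DCRITIC information content
#'
#' `I_j = t_j * sum_{j'}(1 - dCor(o_j, o_j'))`: dispersion times total
#' non-redundancy. The sum runs over all `j'` including `j' = j`, whose term
#' is 0 for a non-constant column.
#'
#' @param t per-criterion standard deviations ([column_sd()]).
#' @param DC pairwise distance-correlation matrix ([dcor_matrix()]).
#' @return named numeric vector of information contents (all `>= 0`).
#' @export
information_content <- function(t, DC) {
  if (!is.matrix(DC) || nrow(DC) != ncol(DC) || length(t) != nrow(DC)) {
    abort_validation("`DC` must be n x n and `t` of length n",
                     "mcdm_shape_error")
  }
  stats::setNames(t * rowSums(1 - DC), colnames(DC))
}

new_weight_vector <- function(w, method) {
  structure(w, method = method, class = "mcdm_weights")
}

#' @export
print.mcdm_weights <- function(x, ...) {
  cat(sprintf("<mcdm_weights method=%s>\n", attr(x, "method")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' DCRITIC objective criterion weights
#'
#' The distance-correlation CRITIC weighting: each criterion's weight is its
#' information content (dispersion times distance-correlation-based
#' non-redundancy) normalized to sum to one:
#' `w_j = I_j / sum(I)`. Operates on the normalized matrix so that
#' dispersion is measured on a common scale.
#'
#' @param N a `normalized_matrix` with `n >= 2` criteria.
#' @return an `mcdm_weights` vector (non-negative, sums to 1).
#' @export
dcritic_weights <- function(N) {
  check_dm(N)
  if (ncol(N$values) < 2L) {
    abort_validation("DCRITIC needs at least 2 criteria")
  }
  t <- column_sd(N)
  I <- information_content(t, dcor_matrix(N))
  total <- sum(I)
  # rounding leaves O(eps) residues when columns are mutually affine
  # (dCor = 1 up to ~1e-15); treat those as zero information
  if (total <= sqrt(.Machine$double.eps) * max(t, 1)) {
    abort_degenerate("all information contents are zero (criteria mutually redundant)",
                     "mcdm_degenerate_weights_error")
  }
  new_weight_vector(I / total, "dcritic")
}

#' Entropy objective criterion weights
#'
#' Shannon-entropy weighting: column shares `p_ij = x_ij / sum_i(x_ij)`,
#' entropy `e_j = -(1/ln m) sum_i p_ij ln p_ij` (with `0 ln 0 := 0`),
#' divergence `d_j = 1 - e_j`, weights `w_j = d_j / sum(d)`.
#'
#' @param N a `normalized_matrix` with non-negative values and positive
#'   column sums.
#' @return an `mcdm_weights` vector.
#' @export
entropy_weights <- function(N) {
  check_dm(N)
  V <- N$values
  if (any(V < 0)) abort_validation("entropy weighting needs non-negative values",
                                   "mcdm_negative_value_error")
  cs <- colSums(V)
  if (any(cs == 0)) {
    abort_degenerate(paste0("zero-sum column(s): ",
                            paste(colnames(V)[cs == 0], collapse = ", ")),
                     "mcdm_degenerate_column_error")
  }
  m <- nrow(V)
  P <- sweep(V, 2, cs, "/")
  plogp <- ifelse(P > 0, P * log(P), 0)
  e <- -colSums(plogp) / log(m)
  d <- 1 - e
  if (sum(d) <= 0) {
    abort_degenerate("all columns have maximal entropy; entropy weights undefined",
                     "mcdm_degenerate_weights_error")
  }
  new_weight_vector(d / sum(d), "entropy")
}

#' MEREC objective criterion weights
#'
#' MEthod based on the Removal Effects of Criteria: the overall log-score of
#' each alternative is `S_i = ln(1 + mean_j |ln x_ij|)`; removing criterion
#' `j` gives `S'_ij = ln(1 + mean over j' != j of |ln x_ij'|)` (mean taken
#' with the same denominator `n`); the removal effect is
#' `E_j = sum_i |S'_ij - S_i|` and `w_j = E_j / sum(E)`.
#'
#' @param N a `normalized_matrix` with values strictly in (0, 1\].
#' @param uniform_fallback if every removal effect is zero (e.g. all values
#'   equal 1), return uniform weights instead of raising a degeneracy error.
#' @return an `mcdm_weights` vector.
#' @export
merec_weights <- function(N, uniform_fallback = FALSE) {
  check_dm(N)
  V <- N$values
  if (any(V <= 0)) {
    abort_validation("MEREC needs strictly positive values",
                     "mcdm_nonpositive_value_error")
  }
  n <- ncol(V)
  L <- abs(log(V))
  S <- log(1 + rowSums(L) / n)
  E <- vapply(seq_len(n), function(j) {
    Sp <- log(1 + (rowSums(L) - L[, j]) / n)
    sum(abs(Sp - S))
  }, numeric(1))
  names(E) <- colnames(V)
  if (sum(E) <= 0) {
    if (uniform_fallback) {
      return(new_weight_vector(stats::setNames(rep(1 / n, n), colnames(V)),
                               "merec"))
    }
    abort_degenerate("all removal effects are zero; MEREC weights undefined",
                     "mcdm_degenerate_weights_error")
  }
  new_weight_vector(E / sum(E), "merec")
}

#' Compute criterion weights by a named method
#'
#' @param N a `normalized_matrix`.
#' @param method `"dcritic"`, `"entropy"` or `"merec"`.
#' @param ... passed to the method function.
#' @return an `mcdm_weights` vector.
#' @export
compute_weights <- function(N, method = c("dcritic", "entropy", "merec"), ...) {
  if (!is.character(method) || !(method[1L] %in% c("dcritic", "entropy", "merec"))) {
    abort_validation(paste0("unknown weighting method: ",
                            paste(method[1L], collapse = ", ")),
                     "mcdm_unknown_method_error")
  }
  switch(method[1L],
         dcritic = dcritic_weights(N, ...),
         entropy = entropy_weights(N, ...),
         merec   = merec_weights(N, ...))
}

check_weights <- function(w, N) {
  if (length(w) != ncol(N$values)) {
    abort_validation("weight vector length must match the number of criteria",
                     "mcdm_shape_error")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort_validation("weights must be non-negative and sum to 1")
  }
  invisible(w)
}
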