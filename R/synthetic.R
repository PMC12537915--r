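#' Specify a synthetic dataset
#'
#' A reproducible recipe for synthetic decision matrices and clustered score
#' sets. Defaults mirror the case-study shape: 35 alternatives, 15 criteria,
#' 6 latent groups, with moderate noise. All generators are pure functions
#' of the spec (including its seed): equal specs give bit-identical output.
#'
#' @param m number of alternatives (default 35).
#' @param n number of criteria (default 15).
#' @param k_true number of latent groups for clustered scores (default 6).
#' @param center_positions latent centers. For [generate_clustered_scores()]
#'   a numeric vector of length `k_true` (or a `k_true` x d matrix); for
#'   [generate_decision_matrix()] a numeric vector of length `n` of column
#'   mean levels. Defaults: equally spaced `0..(k_true-1)` and levels
#'   `1..n`.
#' @param noise_sd Gaussian noise standard deviation (default 0.05, small
#'   relative to the unit spacing of the default centers).
#' @param outlier_rate fraction of rows whose noise scale is inflated
#'   (default 0; contaminated rows get noise scale `5 * noise_sd`).
#' @param skew exponential tilt parameter; 0 = symmetric noise.
#' @param inter_criterion_correlation common latent correlation between all
#'   criterion pairs (equicorrelation Gaussian copula), in
#'   `(-1/(n-1), 1)`.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(m = 35L, n = 15L, k_true = 6L,
                           center_positions = NULL,
                           noise_sd = 0.05, outlier_rate = 0,
                           skew = 0, inter_criterion_correlation = 0,
                           seed = 1L) {
  stopifnot_scalar_number(m, "m", 2)
  stopifnot_scalar_number(n, "n", 1)
  stopifnot_scalar_number(k_true, "k_true", 1, m)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  stopifnot_scalar_number(outlier_rate, "outlier_rate", 0, 1)
  stopifnot_scalar_number(skew, "skew")
  stopifnot_scalar_number(seed, "seed")
  rho <- inter_criterion_correlation
  if (n > 1) {
    stopifnot_scalar_number(rho, "inter_criterion_correlation",
                            lower = -1 / (n - 1) + 1e-9, upper = 1 - 1e-12)
  }
  structure(list(m = as.integer(m), n = as.integer(n),
                 k_true = as.integer(k_true),
                 center_positions = center_positions,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 skew = skew, inter_criterion_correlation = rho,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Each generator draws from its own stream: a fixed offset per generator
# keeps streams independent of call order, and the RNG state of the caller
# is restored on exit.
with_spec_seed <- function(spec, offset, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((spec$seed + offset) %% .Machine$integer.max)
  code
}

# exponential tilt: monotone map of a standard normal draw that skews its
# distribution while keeping g(0) = 0, g'(0) = 1
tilt <- function(z, skew) {
  if (skew == 0) z else (exp(skew * z) - 1) / skew
}

#' Generate a synthetic decision matrix
#'
#' Draws criterion columns from an equicorrelated Gaussian copula
#' (correlation `inter_criterion_correlation` between every pair), applies
#' the exponential-tilt skew, scales by `noise_sd`, shifts by the column
#' mean levels, and contaminates `floor(outlier_rate * m)` rows with
#' 5x-inflated noise. All criteria are assigned benefit orientation.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (a [decision_matrix()]) and `metadata`
#'   (column levels, outlier rows, the latent Gaussian draw).
#' @export
generate_decision_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$m; n <- spec$n
  levels <- spec$center_positions
  if (is.null(levels)) levels <- seq_len(n)
  if (length(levels) != n) {
    abort_validation("center_positions must supply one level per criterion",
                     "mcdm_shape_error")
  }
  rho <- spec$inter_criterion_correlation
  R <- matrix(rho, n, n); diag(R) <- 1
  ch <- try(chol(R), silent = TRUE)
  if (inherits(ch, "try-error")) {
    abort_validation("correlation matrix is not positive definite",
                     "mcdm_correlation_error")
  }
  with_spec_seed(spec, 101L, {
    Z <- matrix(stats::rnorm(m * n), m, n) %*% ch
    G <- tilt(Z, spec$skew)
    n_out <- floor(spec$outlier_rate * m)
    outlier_rows <- if (n_out > 0) sort(sample.int(m, n_out)) else integer()
    scale_row <- rep(spec$noise_sd, m)
    scale_row[outlier_rows] <- 5 * spec$noise_sd
    V <- sweep(G * scale_row, 2, levels, "+")
    dimnames(V) <- list(sprintf("A%02d", seq_len(m)),
                        sprintf("C%02d", seq_len(n)))
    list(matrix = decision_matrix(V),
         metadata = list(levels = levels, outlier_rows = outlier_rows,
                         latent = Z))
  })
}

#' Generate synthetic clustered composite scores
#'
#' Gaussian blobs around `k_true` distinct centers: row `i` belongs to a
#' latent group (groups as balanced as possible, order shuffled), its score
#' is the group center plus `noise_sd` Gaussian noise (5x-inflated for
#' contaminated rows). This emulates the one-dimensional composite-score
#' input of the grouping stage.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `scores` (m x d matrix, d = 1 for vector centers),
#'   `labels` (true group per row, integers 0..k_true-1) and `metadata`
#'   (centers, outlier rows).
#' @export
generate_clustered_scores <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$m; k <- spec$k_true
  centers <- spec$center_positions
  if (is.null(centers)) centers <- seq_len(k) - 1
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 1)
  if (nrow(centers) != k) {
    abort_validation("need one center position per latent group",
                     "mcdm_shape_error")
  }
  if (anyDuplicated(as.data.frame(centers))) {
    abort_validation("latent centers must be distinct",
                     "mcdm_duplicate_center_error")
  }
  d <- ncol(centers)
  with_spec_seed(spec, 202L, {
    base <- rep_len(seq_len(k), m)
    labels <- base[sample.int(m)]
    n_out <- floor(spec$outlier_rate * m)
    outlier_rows <- if (n_out > 0) sort(sample.int(m, n_out)) else integer()
    scale_row <- rep(spec$noise_sd, m)
    scale_row[outlier_rows] <- 5 * spec$noise_sd
    noise <- matrix(stats::rnorm(m * d), m, d) * scale_row
    pts <- centers[labels, , drop = FALSE] + tilt(noise, spec$skew)
    rownames(pts) <- sprintf("A%02d", seq_len(m))
    list(scores = pts,
         labels = stats::setNames(labels - 1L, rownames(pts)),
         metadata = list(centers = centers, outlier_rows = outlier_rows))
  })
}

#' Generate a two-period panel of decision matrices
#'
#' Emulates a two-study-year design: period 1 comes from
#' [generate_decision_matrix()]; period 2 adds per-cell drift. `drift` may
#' be a scalar standard deviation of i.i.d. Gaussian drift, or an explicit
#' m x n drift matrix. The drift matrix is returned as ground truth so that
#' change-decomposition output can be checked cell by cell.
#'
#' @param spec a [synthetic_spec()].
#' @param drift scalar sd or m x n matrix (default 0.1).
#' @return list with `t1`, `t2` (decision matrices), `drift` (the m x n
#'   matrix actually applied) and `metadata` from period 1.
#' @export
generate_panel <- function(spec, drift = 0.1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- generate_decision_matrix(spec)
  V1 <- g$matrix$values
  if (is.matrix(drift)) {
    if (!all(dim(drift) == dim(V1))) {
      abort_validation("drift matrix must be m x n", "mcdm_shape_error")
    }
    D <- drift
  } else {
    stopifnot_scalar_number(drift, "drift", 0)
    D <- with_spec_seed(spec, 303L,
                        matrix(stats::rnorm(length(V1), sd = drift),
                               nrow(V1), ncol(V1)))
  }
  dimnames(D) <- dimnames(V1)
  t2 <- decision_matrix(V1 + D, directions = g$matrix$directions)
  list(t1 = g$matrix, t2 = t2, drift = D, metadata = g$metadata)
}
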