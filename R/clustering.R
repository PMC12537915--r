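#' Gaussian similarity graph
#'
#' Builds the fully connected similarity matrix
#' `S_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))`. The bandwidth `sigma`
#' controls how fast similarity decays with distance. Two scale-free
#' heuristics are offered:
#'
#' * `"auto"` (default): the median over points of the distance to the
#'   3rd-nearest neighbour (2nd/1st for very small m) — a single-bandwidth
#'   variant of the local-scaling rule used in self-tuning spectral
#'   clustering. It tracks the *within-cluster* scale, which is what the
#'   spectral embedding needs to separate groups.
#' * `"median"`: the median of all `m(m-1)/2` pairwise Euclidean
#'   distances. This global scale is dominated by *between*-cluster
#'   distances when the data are clustered, and over-smooths the graph;
#'   it is kept as an explicit option.
#'
#' Either heuristic falls back to the mean of the positive pairwise
#' distances if its primary statistic is zero, and raises a degeneracy
#' error when all points coincide.
#'
#' @param points numeric matrix (m x d) or vector (treated as m x 1).
#' @param sigma positive bandwidth, `"auto"`, or `"median"`.
#' @return a `similarity_graph`: list with `S` (m x m, symmetric, unit
#'   diagonal), `sigma`, `d`.
#' @export
similarity_matrix <- function(points, sigma = "auto") {
  points <- as_points(points)
  m <- nrow(points)
  if (m < 2L) abort_validation("need at least 2 points")
  Dm <- as.matrix(stats::dist(points))
  if (identical(sigma, "auto") || identical(sigma, "median")) {
    pw <- Dm[lower.tri(Dm)]
    primary <- if (identical(sigma, "median")) {
      stats::median(pw)
    } else {
      nn <- min(3L, m - 1L)
      stats::median(apply(Dm + diag(Inf, m), 1,
                          function(r) sort(r)[nn]))
    }
    if (primary > 0) {
      sigma <- primary
    } else if (any(pw > 0)) {
      sigma <- mean(pw[pw > 0])
    } else {
      abort_degenerate("all points identical: auto sigma undefined",
                       "mcdm_degenerate_points_error")
    }
  } else {
    stopifnot_scalar_number(sigma, "sigma", lower = 1e-300)
  }
  S <- exp(-Dm^2 / (2 * sigma^2))
  structure(list(S = S, sigma = sigma, d = ncol(points)),
            class = "similarity_graph")
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  if (!is.numeric(points) || anyNA(points) || !all(is.finite(points))) {
    abort_validation("points must be finite numerics")
  }
  as.matrix(points)
}

#' Unnormalized graph Laplacian
#'
#' `D_ii = sum_j S_ij` (self-similarity included) and `L = D - S`. Because
#' the self term appears in both `D` and `S`, it cancels in the difference:
#' `L` does not depend on the diagonal convention of `S`. `L` is symmetric
#' positive semidefinite with zero row sums; its number of (near-)zero
#' eigenvalues equals the number of connected components of the graph.
#'
#' @param G a `similarity_graph`.
#' @return a `laplacian_pair`: list with `D` (diagonal matrix) and `L`.
#' @export
laplacian <- function(G) {
  if (!inherits(G, "similarity_graph")) {
    abort_validation("input must be a similarity_graph")
  }
  deg <- rowSums(G$S)
  L <- diag(deg, nrow = length(deg)) - G$S
  structure(list(D = diag(deg, nrow = length(deg)), L = L),
            class = "laplacian_pair")
}

#' Spectral embedding from the Laplacian
#'
#' Symmetric eigendecomposition of `L`; the eigenvectors of the `k` smallest
#' eigenvalues (ascending) form the columns of the embedding matrix `U`.
#' Eigenvector sign is fixed deterministically: in each column the entry of
#' largest magnitude (ties: lowest index) is made positive. Within a
#' degenerate eigenvalue the eigensolver's ordering is kept as returned,
#' which is deterministic for a fixed input.
#'
#' @param LP a `laplacian_pair`.
#' @param k number of eigenvectors, `1 <= k <= m`.
#' @return a `spectral_embedding`: list with `U` (m x k, orthonormal
#'   columns) and `eigenvalues` (length k, ascending).
#' @export
spectral_embedding <- function(LP, k) {
  if (!inherits(LP, "laplacian_pair")) {
    abort_validation("input must be a laplacian_pair")
  }
  m <- nrow(LP$L)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > m || k != round(k)) {
    abort_validation(sprintf("k must be an integer in 1..%d", m),
                     "mcdm_parameter_error")
  }
  eg <- eigen((LP$L + t(LP$L)) / 2, symmetric = TRUE)
  idx <- seq(m, m - k + 1L)        # eigen() returns decreasing order
  U <- eg$vectors[, idx, drop = FALSE]
  vals <- eg$values[idx]
  for (j in seq_len(ncol(U))) {
    i0 <- which.max(abs(U[, j]))   # ties: which.max takes the lowest index
    if (U[i0, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, eigenvalues = vals), class = "spectral_embedding")
}

# Deterministic farthest-first seeds among rows of M: the first seed is the
# row nearest the centroid, each next seed maximizes the minimum distance to
# the seeds chosen so far; all ties go to the lowest row index.
farthest_first_rows <- function(M, k) {
  m <- nrow(M)
  ctr <- colMeans(M)
  d2ctr <- rowSums(sweep(M, 2, ctr)^2)
  seeds <- which.min(d2ctr)
  if (k > 1L) {
    mind2 <- rowSums(sweep(M, 2, M[seeds, ])^2)
    while (length(seeds) < k) {
      nxt <- which.max(mind2)
      seeds <- c(seeds, nxt)
      mind2 <- pmin(mind2, rowSums(sweep(M, 2, M[nxt, ])^2))
    }
  }
  seeds
}

#' Initial centers from the spectral embedding
#'
#' Runs a fully deterministic k-means (farthest-first seeding, then Lloyd
#' iterations) on the *rows of the embedding* `U`, then transfers the
#' resulting assignment back to the original space: the j-th initial center
#' is the mean of the original-space points whose embedded representatives
#' fell in embedded cluster j. This transfer keeps the subsequent Lloyd
#' iterations well-typed in the original space.
#'
#' @param points original-space points (m x d).
#' @param E a `spectral_embedding`.
#' @param k number of centers.
#' @return k x d matrix of initial centers.
#' @export
initial_centers <- function(points, E, k) {
  points <- as_points(points)
  if (!inherits(E, "spectral_embedding")) {
    abort_validation("E must be a spectral_embedding")
  }
  if (k > nrow(points)) abort_validation("k cannot exceed the number of points")
  U <- E$U
  seeds <- farthest_first_rows(U, k)
  emb <- lloyd(U, U[seeds, , drop = FALSE])
  labs <- emb$labels  # 0-based
  C <- matrix(NA_real_, k, ncol(points))
  for (j in seq_len(k)) {
    C[j, ] <- colMeans(points[labs == (j - 1L), , drop = FALSE])
  }
  C
}

#' Lloyd's k-means iterations
#'
#' Alternates nearest-center assignment (squared Euclidean distance,
#' ties to the lowest center index) and center-mean updates until the
#' assignment is unchanged or the largest center shift falls below `tol`.
#' A cluster left empty after an update is reseeded with the point farthest
#' from its currently assigned center (largest contribution to the inertia;
#' ties to the lowest point index), deterministically.
#'
#' @param points m x d matrix (or vector, treated as m x 1).
#' @param centers k x d matrix of starting centers (or vector for d = 1).
#' @param max_iter maximum number of assign/update sweeps (default 300).
#' @param tol convergence threshold on the maximum center displacement.
#' @return a `grouping_result`: list with `labels` (named integers in
#'   0..k-1), `centers` (k x d), `iterations`, `inertia`, `converged`,
#'   `initial_centers`.
#' @export
lloyd <- function(points, centers, max_iter = 300L, tol = 1e-10) {
  points <- as_points(points)
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = ncol(points))
  centers <- as.matrix(centers)
  if (ncol(centers) != ncol(points)) {
    abort_validation("centers and points must have the same dimension",
                     "mcdm_shape_error")
  }
  k <- nrow(centers)
  if (k < 1L) abort_validation("need at least one center")
  m <- nrow(points)
  C_init <- centers
  converged <- FALSE
  iterations <- 0L
  inertia_history <- numeric()

  dist2 <- function(C) {
    # m x k squared distances (clamped at 0 against rounding)
    pmax(outer(rowSums(points^2), rep(1, k)) - 2 * points %*% t(C) +
           outer(rep(1, m), rowSums(C^2)), 0)
  }
  # ties.method = "first" on the negated distances: lowest center index wins
  assign_step <- function(C) max.col(-dist2(C), ties.method = "first")

  labels <- assign_step(centers)
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    newC <- centers
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (length(members)) {
        newC[j, ] <- colMeans(points[members, , drop = FALSE])
      } else {
        # reseed: point with the largest distance to its assigned center
        d2own <- rowSums((points - newC[labels, , drop = FALSE])^2)
        far <- which.max(d2own)
        newC[j, ] <- points[far, ]
        labels[far] <- j
      }
    }
    shift <- max(sqrt(rowSums((newC - centers)^2)))
    centers <- newC
    newlab <- assign_step(centers)
    inertia_history <- c(inertia_history,
                         sum((points - centers[newlab, , drop = FALSE])^2))
    if (identical(newlab, labels) || shift < tol) {
      labels <- newlab
      converged <- TRUE
      break
    }
    labels <- newlab
  }
  inertia <- sum((points - centers[labels, , drop = FALSE])^2)
  structure(list(labels = stats::setNames(labels - 1L, rownames(points)),
                 centers = centers,
                 iterations = iterations,
                 inertia = inertia,
                 inertia_history = inertia_history,
                 converged = converged,
                 initial_centers = C_init),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf("<grouping_result> k=%d, iterations=%d, inertia=%.6g, converged=%s\n",
              nrow(x$centers), x$iterations, x$inertia, x$converged))
  print(table(x$labels))
  invisible(x)
}

#' Graph-seeded k-means
#'
#' The full deterministic clustering pipeline: Gaussian similarity graph ->
#' unnormalized Laplacian -> spectral embedding of the k smallest
#' eigenvalues -> deterministic embedded-space k-means to pick initial
#' centers -> Lloyd iterations in the original space. Given identical
#' `(points, k, sigma)` the output is bit-identical run to run — the
#' initialization randomness of classical k-means is removed entirely.
#'
#' @inheritParams similarity_matrix
#' @param k number of groups.
#' @param max_iter,tol passed to [lloyd()].
#' @return a `grouping_result` (see [lloyd()]), with the bandwidth actually
#'   used attached as attribute `sigma`.
#' @export
cluster_graph_kmeans <- function(points, k, sigma = "auto",
                                 max_iter = 300L, tol = 1e-10) {
  points <- as_points(points)
  if (k > nrow(points)) abort_validation("k cannot exceed the number of points")
  G <- similarity_matrix(points, sigma)
  E <- spectral_embedding(laplacian(G), k)
  C0 <- initial_centers(points, E, k)
  out <- lloyd(points, C0, max_iter = max_iter, tol = tol)
  attr(out, "sigma") <- G$sigma
  out
}

#' Classical k-means seedings (benchmark comparators)
#'
#' Seeded baseline initializations used to benchmark the graph seeding:
#' `"random"` draws k distinct points uniformly; `"kmeanspp"` is k-means++
#' (squared-distance-proportional sampling); `"farthest_first"` picks a
#' random first seed then grows greedily by maximum minimum distance.
#'
#' @inheritParams lloyd
#' @param k number of centers.
#' @param strategy seeding strategy.
#' @param seed integer seed making the draw reproducible.
#' @return k x d matrix of centers.
#' @export
baseline_init <- function(points, k,
                          strategy = c("random", "kmeanspp", "farthest_first"),
                          seed = 1L) {
  points <- as_points(points)
  m <- nrow(points)
  if (k > m) abort_validation("k cannot exceed the number of points")
  if (!is.character(strategy) ||
      !(strategy[1L] %in% c("random", "kmeanspp", "farthest_first"))) {
    abort_validation(paste0("unknown init strategy: ",
                            paste(strategy[1L], collapse = ", ")),
                     "mcdm_unknown_method_error")
  }
  strategy <- strategy[1L]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- switch(strategy,
    random = sample.int(m, k),
    kmeanspp = {
      ix <- sample.int(m, 1L)
      while (length(ix) < k) {
        d2 <- apply(points, 1, function(p) {
          min(colSums((t(points[ix, , drop = FALSE]) - p)^2))
        })
        if (sum(d2) == 0) {
          ix <- c(ix, setdiff(seq_len(m), ix)[1L])
        } else {
          ix <- c(ix, sample.int(m, 1L, prob = d2 / sum(d2)))
        }
      }
      ix
    },
    farthest_first = {
      ix <- sample.int(m, 1L)
      mind2 <- rowSums(sweep(points, 2, points[ix, ])^2)
      while (length(ix) < k) {
        nxt <- which.max(mind2)
        ix <- c(ix, nxt)
        mind2 <- pmin(mind2, rowSums(sweep(points, 2, points[nxt, ])^2))
      }
      ix
    })
  points[idx, , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
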