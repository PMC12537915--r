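#' Spearman rank correlation between two rankings
#'
#' Tie-corrected Spearman's rho: the Pearson correlation of the rank values.
#' Both rankings must cover the same alternatives; if both are named they
#' are aligned by name first.
#'
#' @param r1,r2 `rank_vector`s or plain numeric rank vectors.
#' @return a single number in \[-1, 1\].
#' @export
spearman_rho <- function(r1, r2) {
  if (length(r1) != length(r2)) {
    abort_validation("rankings must have the same length", "mcdm_shape_error")
  }
  if (!is.null(names(r1)) && !is.null(names(r2))) {
    if (!setequal(names(r1), names(r2))) {
      abort_validation("rankings must cover the same alternatives",
                       "mcdm_shape_error")
    }
    r2 <- r2[names(r1)]
  }
  stats::cor(as.numeric(r1), as.numeric(r2), method = "spearman")
}

#' V-measure between two partitions
#'
#' The entropy-based external clustering agreement score: homogeneity
#' `h = 1 - H(A|B)/H(A)` and completeness `c = 1 - H(B|A)/H(B)` are
#' computed from the contingency table (natural-log entropies; `0/0 := 1`),
#' and `V = 2hc/(h + c)` is their harmonic mean (`V = 0` when `h + c = 0`).
#' V is invariant to label permutation and symmetric in its arguments.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return a single number in \[0, 1\].
#' @export
vmeasure <- function(labels_a, labels_b) {
  if (length(labels_a) == 0L || length(labels_b) == 0L) {
    abort_validation("labelings must be non-empty")
  }
  if (length(labels_a) != length(labels_b)) {
    abort_validation("labelings must have the same length", "mcdm_shape_error")
  }
  ct <- table(labels_a, labels_b)
  n <- sum(ct)
  p <- ct / n
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  Ha <- ent(pa); Hb <- ent(pb)
  # conditional entropies H(A|B), H(B|A)
  Hab <- -sum(p[p > 0] * log((p / rep(pb, each = nrow(p)))[p > 0]))
  Hba <- -sum(p[p > 0] * log((p / pa)[p > 0]))
  h <- if (Ha == 0) 1 else 1 - Hab / Ha
  c_ <- if (Hb == 0) 1 else 1 - Hba / Hb
  if (h + c_ == 0) return(0)
  2 * h * c_ / (h + c_)
}

pairwise_matrix <- function(items, f) {
  n <- length(items)
  M <- diag(nrow = n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) M[i, j] <- M[j, i] <- f(items[[i]], items[[j]])
    }
  }
  dimnames(M) <- list(names(items), names(items))
  M
}

#' Pairwise rank-agreement matrix
#'
#' Spearman's rho between every pair of rank columns.
#'
#' @param ranks a data.frame or matrix whose columns are rankings, or a
#'   named list of rank vectors.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
rank_agreement <- function(ranks) {
  if (is.data.frame(ranks) || is.matrix(ranks)) {
    ranks <- as.list(as.data.frame(ranks))
  }
  pairwise_matrix(ranks, function(a, b) spearman_rho(a, b))
}

#' Pairwise group-agreement matrix
#'
#' V-measure between every pair of labelings.
#'
#' @param labelings data.frame, matrix, or named list of label vectors.
#' @return symmetric matrix with unit diagonal.
#' @export
group_agreement <- function(labelings) {
  if (is.data.frame(labelings) || is.matrix(labelings)) {
    labelings <- as.list(as.data.frame(labelings))
  }
  pairwise_matrix(labelings, vmeasure)
}

#' Robustness comparison across pipeline variants
#'
#' Re-runs the full pipeline on `X` once per variant of one factor
#' (normalization, weighting, or aggregation), holding everything else at
#' the supplied configuration, and quantifies agreement between every pair
#' of variants: Spearman's rho between the rank vectors and V-measure
#' between the groupings.
#'
#' @param X a [decision_matrix()].
#' @param vary which factor to vary.
#' @param config a [pipeline_config()] supplying the fixed factors.
#' @param variants optional character vector restricting the variants.
#' @return a `comparison_report`: list with `varied`, `variants`,
#'   `spearman` and `vmeasure` matrices, `ranks`, `labels`.
#' @export
robustness_matrix <- function(X,
                              vary = c("normalization", "weighting", "aggregation"),
                              config = pipeline_config(),
                              variants = NULL) {
  vary <- match.arg(vary)
  all_variants <- switch(vary,
                         normalization = c("logistic", "fq", "ds", "vector"),
                         weighting = c("dcritic", "entropy", "merec"),
                         aggregation = c("waspas", "topsis", "vikor"))
  if (is.null(variants)) variants <- all_variants
  bad <- setdiff(variants, all_variants)
  if (length(bad)) {
    abort_validation(paste0("unknown variant(s): ", paste(bad, collapse = ", ")),
                     "mcdm_unknown_method_error")
  }
  runs <- lapply(variants, function(v) {
    cfg <- config
    cfg[[vary]] <- v
    run_pipeline(X, cfg)
  })
  names(runs) <- variants
  ranks <- lapply(runs, function(r) r$ranks)
  labels <- lapply(runs, function(r) r$grouping$labels)
  structure(list(varied = vary,
                 variants = variants,
                 spearman = pairwise_matrix(ranks, spearman_rho),
                 vmeasure = pairwise_matrix(labels, vmeasure),
                 ranks = ranks,
                 labels = labels),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report varied=%s>\nSpearman rho:\n", x$varied))
  print(round(x$spearman, 4))
  cat("V-measure:\n")
  print(round(x$vmeasure, 4))
  invisible(x)
}

#' Deconstruct composite scores into per-criterion contributions
#'
#' Splits each alternative's weighted-sum score into additive per-criterion
#' contributions `w_j * x_ij`, which sum exactly to `WS_i`. (The additive
#' weighted-sum convention is used: the geometric WP component is not
#' additively separable.)
#'
#' @inheritParams weighted_sum
#' @return a `decomposition_table`: list with `contributions` (m x n
#'   matrix), `totals` (= WS), `weights`.
#' @export
score_deconstruction <- function(N, w) {
  check_dm(N); check_weights(w, N)
  contrib <- sweep(N$values, 2, as.numeric(w), "*")
  structure(list(contributions = contrib,
                 totals = rowSums(contrib),
                 weights = as.numeric(w)),
            class = "decomposition_table")
}

#' Decompose the change in composite score between two time points
#'
#' For two normalized matrices over the same alternatives and criteria
#' (e.g. two study years) and a single weight vector, the change in each
#' alternative's weighted-sum score decomposes additively as
#' `Delta_ij = w_j (x_ij(t2) - x_ij(t1))`. Each criterion is classified as
#' `"contributing"` (`Delta > tol`), `"regressing"` (`Delta < -tol`) or
#' `"neutral"`. A single weight vector keeps the decomposition exact; the
#' caller decides whether it comes from year 1, year 2 or pooled data.
#'
#' @param N_t1,N_t2 `normalized_matrix` objects with identical alternatives
#'   and criteria.
#' @param w weight vector.
#' @param tol neutrality threshold on `|Delta|` (default 1e-12).
#' @return a `decomposition_table` with `contributions` (the Delta matrix),
#'   `totals` (= Delta WS), and `classification` (character matrix).
#' @export
change_decomposition <- function(N_t1, N_t2, w, tol = 1e-12) {
  check_dm(N_t1); check_dm(N_t2); check_weights(w, N_t1)
  if (!identical(dimnames(N_t1$values), dimnames(N_t2$values))) {
    abort_validation("the two matrices must share alternatives and criteria",
                     "mcdm_shape_error")
  }
  delta <- sweep(N_t2$values - N_t1$values, 2, as.numeric(w), "*")
  cls <- matrix("neutral", nrow(delta), ncol(delta), dimnames = dimnames(delta))
  cls[delta > tol] <- "contributing"
  cls[delta < -tol] <- "regressing"
  structure(list(contributions = delta,
                 totals = rowSums(delta),
                 classification = cls,
                 weights = as.numeric(w)),
            class = "decomposition_table")
}

#' Benchmark k-means initializations
#'
#' For each synthetic clustered dataset and each initialization strategy,
#' runs Lloyd's algorithm and records the iteration count, final inertia,
#' and — over `repeats` seeds — how many distinct label partitions occur
#' (run-to-run stability; the graph seeding is deterministic, so its count
#' is always 1).
#'
#' @param specs list of [synthetic_spec()]s describing the datasets.
#' @param inits subset of `c("graph", "random", "kmeanspp",
#'   "farthest_first")`.
#' @param repeats number of seeded repeats per dataset x init.
#' @param seed base seed for the randomized initializations.
#' @return a data.frame with one row per dataset x init: median iterations,
#'   median inertia, distinct partition count.
#' @export
init_benchmark <- function(specs, inits = c("graph", "random"),
                           repeats = 20L, seed = 1L) {
  ok <- c("graph", "random", "kmeanspp", "farthest_first")
  bad <- setdiff(inits, ok)
  if (length(bad)) abort_validation(paste0("unknown init(s): ",
                                           paste(bad, collapse = ", ")),
                                    "mcdm_unknown_method_error")
  rows <- list()
  for (di in seq_along(specs)) {
    spec <- specs[[di]]
    gen <- generate_clustered_scores(spec)
    pts <- gen$scores
    k <- spec$k_true
    for (init in inits) {
      iters <- integer(repeats)
      inert <- numeric(repeats)
      parts <- character(repeats)
      for (r in seq_len(repeats)) {
        gr <- if (init == "graph") {
          cluster_graph_kmeans(pts, k)
        } else {
          C0 <- baseline_init(pts, k, strategy = init,
                              seed = seed + 1000L * di + r)
          lloyd(pts, C0)
        }
        iters[r] <- gr$iterations
        inert[r] <- gr$inertia
        parts[r] <- canonical_partition(gr$labels)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(dataset = di, init = init,
                   median_iterations = stats::median(iters),
                   median_inertia = stats::median(inert),
                   distinct_partitions = length(unique(parts)))
    }
  }
  do.call(rbind, rows)
}

# label-permutation-invariant fingerprint of a partition
canonical_partition <- function(labels) {
  paste(match(labels, unique(labels)), collapse = ",")
}
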