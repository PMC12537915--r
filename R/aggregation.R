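#' Weighted sum of normalized criteria
#'
#' `WS_i = sum_j w_j x_ij` — the weighted arithmetic mean component of
#' WASPAS.
#'
#' @param N a `normalized_matrix`.
#' @param w an `mcdm_weights` vector (or any non-negative vector summing
#'   to 1) matching the criteria.
#' @return named numeric vector of per-alternative scores.
#' @export
weighted_sum <- function(N, w) {
  check_dm(N); check_weights(w, N)
  drop(N$values %*% as.numeric(w))
}

#' Weighted product of normalized criteria
#'
#' `WP_i = prod_j x_ij^(w_j)` — the weighted geometric mean component of
#' WASPAS, computed in the log domain. Requires strictly positive values.
#'
#' @inheritParams weighted_sum
#' @return named numeric vector of per-alternative scores.
#' @export
weighted_product <- function(N, w) {
  check_dm(N); check_weights(w, N)
  if (any(N$values <= 0)) {
    abort_validation("weighted product needs strictly positive normalized values",
                     "mcdm_nonpositive_value_error")
  }
  exp(drop(log(N$values) %*% as.numeric(w)))
}

#' Competition-rank a score vector
#'
#' Standard competition ranking ("1, 2, 2, 4"): tied scores share the best
#' rank and the next rank is skipped. The returned vector is ordered as the
#' input; the deterministic id tiebreak fixes only the *stored order* of
#' tied alternatives in downstream tables, never the rank value itself.
#'
#' @param scores named numeric vector (names = alternative ids).
#' @param higher_is_better rank 1 goes to the largest score (`TRUE`, default)
#'   or the smallest.
#' @param source tag recording which method produced the scores.
#' @return a `rank_vector` (integer ranks in 1..m, named by alternative).
#' @export
rank_alternatives <- function(scores, higher_is_better = TRUE,
                              source = "scores") {
  if (!is.numeric(scores) || anyNA(scores) || !all(is.finite(scores))) {
    abort_validation("scores must be finite numerics")
  }
  s <- if (higher_is_better) -scores else scores
  new_rank_vector(rank(s, ties.method = "min"),
                  ids = names(scores), source = source)
}

#' WASPAS scores and ranks
#'
#' The weighted aggregated sum-product assessment:
#' `WQ_i = lambda * WS_i + (1 - lambda) * WP_i`, a convex blend of the
#' weighted arithmetic ([weighted_sum()]) and geometric
#' ([weighted_product()]) means. `lambda = 1` recovers the pure weighted
#' sum, `lambda = 0` the pure weighted product; by the AM-GM inequality
#' `WP_i <= WQ_i <= WS_i`, so `WQ` is non-decreasing in `lambda`. Rank 1 is
#' the best (largest `WQ`); ties take competition ranks, with tied rows
#' ordered by alternative id.
#'
#' @inheritParams weighted_sum
#' @param lambda blend parameter in \[0, 1\] (default 0.5, the symmetric
#'   convention).
#' @return a `score_table` data frame with columns `alternative`, `WS`,
#'   `WP`, `WQ`, `rank`, and attribute `lambda`.
#' @export
waspas_score <- function(N, w, lambda = 0.5) {
  stopifnot_scalar_number(lambda, "lambda", 0, 1)
  WS <- weighted_sum(N, w)
  WP <- weighted_product(N, w)
  WQ <- lambda * WS + (1 - lambda) * WP
  ids <- rownames(N$values)
  r <- rank_alternatives(stats::setNames(WQ, ids), source = "waspas")
  ord <- order(r, ids)
  new_score_table(ids[ord], WS[ord], WP[ord], WQ[ord], r[ord], lambda)
}

#' TOPSIS closeness scores and ranks
#'
#' Technique for Order of Preference by Similarity to Ideal Solution, run on
#' the same normalized matrix as WASPAS so that the aggregator is the only
#' varying factor: the weighted matrix is `v_ij = w_j x_ij`; the ideal and
#' anti-ideal points are the column-wise max and min (criterion directions
#' are already folded in by normalization); closeness is
#' `C_i = d-_i / (d+_i + d-_i)` with Euclidean distances to the two poles.
#' Rank 1 is the largest closeness.
#'
#' @inheritParams weighted_sum
#' @return list with `closeness` (named numeric) and `ranks`
#'   (a `rank_vector`).
#' @export
topsis_score <- function(N, w) {
  check_dm(N); check_weights(w, N)
  V <- sweep(N$values, 2, as.numeric(w), "*")
  ideal <- apply(V, 2, max)
  anti  <- apply(V, 2, min)
  dpos <- sqrt(rowSums(sweep(V, 2, ideal)^2))
  dneg <- sqrt(rowSums(sweep(V, 2, anti)^2))
  tot <- dpos + dneg
  if (any(tot == 0)) {
    abort_degenerate("all alternatives identical: ideal and anti-ideal coincide",
                     "mcdm_degenerate_alternatives_error")
  }
  C <- stats::setNames(dneg / tot, rownames(N$values))
  list(closeness = C,
       ranks = rank_alternatives(C, higher_is_better = TRUE, source = "topsis"))
}

#' VIKOR compromise scores and ranks
#'
#' VIKOR on the benefit-oriented normalized matrix: with per-criterion best
#' `f*_j = max_i x_ij` and worst `f-_j = min_i x_ij`, the group utility is
#' `S_i = sum_j w_j (f*_j - x_ij)/(f*_j - f-_j)` and the individual regret
#' `R_i = max_j` of the same terms. The compromise index is
#' `Q_i = v (S_i - S*)/(S- - S*) + (1 - v)(R_i - R*)/(R- - R*)`
#' (`S* = min S`, `S- = max S`, likewise for `R`); a term with zero spread
#' is defined as 0. Rank 1 is the *smallest* `Q`.
#'
#' @inheritParams weighted_sum
#' @param v weight of the group-utility strategy, default 0.5 ("consensus").
#' @return list with `Q`, `S`, `R` (named numerics) and `ranks`
#'   (a `rank_vector`, ascending in `Q`).
#' @export
vikor_score <- function(N, w, v = 0.5) {
  check_dm(N); check_weights(w, N)
  stopifnot_scalar_number(v, "v", 0, 1)
  V <- N$values
  fstar <- apply(V, 2, max)
  fminus <- apply(V, 2, min)
  spread <- fstar - fminus
  if (any(spread == 0)) {
    abort_degenerate(paste0("constant criterion column(s): ",
                            paste(colnames(V)[spread == 0], collapse = ", ")),
                     "mcdm_degenerate_column_error")
  }
  terms <- sweep(sweep(-V, 2, fstar, "+"), 2, spread, "/")  # (f* - x)/(f* - f-)
  wterms <- sweep(terms, 2, as.numeric(w), "*")
  S <- rowSums(wterms)
  R <- apply(wterms, 1, max)
  qterm <- function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0, length(x)) else (x - min(x)) / rng
  }
  Q <- v * qterm(S) + (1 - v) * qterm(R)
  ids <- rownames(V)
  names(Q) <- names(S) <- names(R) <- ids
  list(Q = Q, S = S, R = R,
       ranks = rank_alternatives(Q, higher_is_better = FALSE, source = "vikor"))
}

#' Score and rank alternatives by a named aggregator
#'
#' Dispatch over the three aggregators. All three consume the same
#' normalized matrix and weight vector; only the aggregation rule varies.
#'
#' @inheritParams weighted_sum
#' @param method `"waspas"`, `"topsis"` or `"vikor"`.
#' @param lambda WASPAS blend parameter.
#' @param vikor_v VIKOR strategy weight.
#' @return list with `scores` (named numeric, orientation depends on the
#'   method), `ranks` (a `rank_vector`) and, for WASPAS, `table`
#'   (the full `score_table`).
#' @export
aggregate_scores <- function(N, w, method = c("waspas", "topsis", "vikor"),
                             lambda = 0.5, vikor_v = 0.5) {
  if (!is.character(method) || !(method[1L] %in% c("waspas", "topsis", "vikor"))) {
    abort_validation(paste0("unknown aggregation method: ",
                            paste(method[1L], collapse = ", ")),
                     "mcdm_unknown_method_error")
  }
  switch(method[1L],
         waspas = {
           st <- waspas_score(N, w, lambda)
           sc <- stats::setNames(st$WQ, st$alternative)[rownames(N$values)]
           list(scores = sc,
                ranks = rank_alternatives(sc, source = "waspas"),
                table = st)
         },
         topsis = {
           ts <- topsis_score(N, w)
           list(scores = ts$closeness, ranks = ts$ranks)
         },
         vikor = {
           vk <- vikor_score(N, w, vikor_v)
           list(scores = vk$Q, ranks = vk$ranks)
         })
}
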