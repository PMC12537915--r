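# Independent brute-force oracles: literal transcriptions of the defining
# formulas, written with explicit loops so they share no code with the
# package implementations they check.

oracle_dcor <- function(u, v) {
  m <- length(u)
  a <- matrix(0, m, m); b <- matrix(0, m, m)
  for (k in 1:m) for (l in 1:m) {
    a[k, l] <- abs(u[k] - u[l]); b[k, l] <- abs(v[k] - v[l])
  }
  A <- matrix(0, m, m); B <- matrix(0, m, m)
  for (k in 1:m) for (l in 1:m) {
    A[k, l] <- a[k, l] - mean(a[k, ]) - mean(a[, l]) + mean(a)
    B[k, l] <- b[k, l] - mean(b[k, ]) - mean(b[, l]) + mean(b)
  }
  dcov2 <- sum(A * B) / m^2
  du <- sum(A * A) / m^2
  dv <- sum(B * B) / m^2
  if (du <= 0 || dv <= 0) return(0)
  sqrt(dcov2 / sqrt(du * dv))
}

oracle_dcritic <- function(V) {
  m <- nrow(V); n <- ncol(V)
  t <- numeric(n)
  for (j in 1:n) t[j] <- sqrt(sum((V[, j] - mean(V[, j]))^2) / (m - 1))
  DC <- matrix(0, n, n)
  for (j in 1:n) for (jp in 1:n) DC[j, jp] <- oracle_dcor(V[, j], V[, jp])
  I <- numeric(n)
  for (j in 1:n) I[j] <- t[j] * sum(1 - DC[j, ])
  I / sum(I)
}

oracle_entropy <- function(V) {
  m <- nrow(V); n <- ncol(V)
  d <- numeric(n)
  for (j in 1:n) {
    p <- V[, j] / sum(V[, j])
    e <- 0
    for (i in 1:m) if (p[i] > 0) e <- e - p[i] * log(p[i])
    d[j] <- 1 - e / log(m)
  }
  d / sum(d)
}

oracle_merec <- function(V) {
  m <- nrow(V); n <- ncol(V)
  S <- numeric(m)
  for (i in 1:m) S[i] <- log(1 + sum(abs(log(V[i, ]))) / n)
  E <- numeric(n)
  for (j in 1:n) {
    for (i in 1:m) {
      Sp <- log(1 + sum(abs(log(V[i, -j]))) / n)
      E[j] <- E[j] + abs(Sp - S[i])
    }
  }
  E / sum(E)
}

oracle_topsis <- function(V, w) {
  m <- nrow(V); n <- ncol(V)
  Z <- V
  for (j in 1:n) Z[, j] <- w[j] * V[, j]
  vplus <- apply(Z, 2, max); vminus <- apply(Z, 2, min)
  C <- numeric(m)
  for (i in 1:m) {
    dp <- sqrt(sum((Z[i, ] - vplus)^2))
    dn <- sqrt(sum((Z[i, ] - vminus)^2))
    C[i] <- dn / (dp + dn)
  }
  C
}

oracle_vikor <- function(V, w, v = 0.5) {
  m <- nrow(V); n <- ncol(V)
  fs <- apply(V, 2, max); fm <- apply(V, 2, min)
  S <- numeric(m); R <- numeric(m)
  for (i in 1:m) {
    terms <- numeric(n)
    for (j in 1:n) terms[j] <- w[j] * (fs[j] - V[i, j]) / (fs[j] - fm[j])
    S[i] <- sum(terms); R[i] <- max(terms)
  }
  Q <- numeric(m)
  for (i in 1:m) {
    qs <- if (max(S) - min(S) == 0) 0 else (S[i] - min(S)) / (max(S) - min(S))
    qr <- if (max(R) - min(R) == 0) 0 else (R[i] - min(R)) / (max(R) - min(R))
    Q[i] <- v * qs + (1 - v) * qr
  }
  Q
}

oracle_vmeasure <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  Ha <- 0
  for (x in ua) { p <- sum(a == x) / n; Ha <- Ha - p * log(p) }
  Hb <- 0
  for (y in ub) { p <- sum(b == y) / n; Hb <- Hb - p * log(p) }
  Hab <- 0; Hba <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      Hab <- Hab - pxy * log(pxy / (sum(b == y) / n))
      Hba <- Hba - pxy * log(pxy / (sum(a == x) / n))
    }
  }
  h <- if (Ha == 0) 1 else 1 - Hab / Ha
  cc <- if (Hb == 0) 1 else 1 - Hba / Hb
  if (h + cc == 0) return(0)
  2 * h * cc / (h + cc)
}

# exhaustive minimum-SSE bipartition of a point set (small m only)
oracle_best_2partition <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  m <- nrow(points)
  best <- NULL; best_sse <- Inf
  for (code in 1:(2^(m - 1) - 1)) {
    grp <- c(0L, as.integer(intToBits(code)[1:(m - 1)]))
    sse <- 0
    for (g in 0:1) {
      rows <- points[grp == g, , drop = FALSE]
      ctr <- colMeans(rows)
      sse <- sse + sum(sweep(rows, 2, ctr)^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- grp }
  }
  list(labels = best, sse = best_sse)
}

# convenience: a normalized_matrix wrapper around a plain values matrix
as_norm <- function(V, directions = NULL) {
  rn <- rownames(V)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn))) {
    rownames(V) <- sprintf("a%02d", seq_len(nrow(V)))
  }
  cn <- colnames(V)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn))) {
    colnames(V) <- sprintf("c%02d", seq_len(ncol(V)))
  }
  X <- decision_matrix(V, directions = directions)
  graphMCDM:::new_normalized_matrix(X, X$values, "test")
}

rand_norm_matrix <- function(m, n, seed) {
  set.seed(seed)
  V <- matrix(runif(m * n, 0.05, 0.95), m, n)
  as_norm(V)
}

uw <- function(n) rep(1 / n, n)

new_test_weights <- function(w) {
  graphMCDM:::new_weight_vector(stats::setNames(w, sprintf("c%02d", seq_along(w))),
                                "test")
}
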