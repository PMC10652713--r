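# Independent oracles, deliberately coded from first principles and kept
# separate from the package's implementations.

# Benjamini-Hochberg step-up by the definition: find the largest k with
# p_(k) <= k/m * alpha; adjusted value by the running-minimum construction.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- running
  }
  pmin(adj, 1)
}

# Holm step-down by the definition.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in 1:m) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

# Exact two-sided Mann-Whitney p by direct enumeration of every split of
# the pooled sample into the two groups.
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- combn(N, nx)
  Us <- apply(splits, 2, function(ix) sum(rk[ix]) - nx * (nx + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(Us <= U_obs + eps), mean(Us >= U_obs - eps)))
}

# Untrimmed Johansen-form between-by-within test, written directly from the
# definition with ordinary means and covariance-of-the-mean blocks, and an
# elementwise loop for the df correction term. `effect` picks the contrast.
oracle_johansen <- function(Xg, effect = c("group", "condition", "interaction")) {
  effect <- match.arg(effect)
  J <- length(Xg); K <- ncol(Xg[[1]])
  mu <- unlist(lapply(Xg, colMeans))
  n <- vapply(Xg, nrow, integer(1))
  V <- matrix(0, J * K, J * K)
  for (j in seq_len(J)) {
    rows <- (j - 1) * K + seq_len(K)
    V[rows, rows] <- cov(Xg[[j]]) / n[j]
  }
  # deviation-style contrasts (any row basis spanning the same space works)
  dev <- function(k) {
    C <- matrix(-1 / k, k - 1, k)
    for (i in seq_len(k - 1)) C[i, i] <- C[i, i] + 1
    C
  }
  onesr <- function(k) matrix(1 / k, 1, k)
  C <- switch(effect,
              group = kronecker(dev(J), onesr(K)),
              condition = kronecker(onesr(J), dev(K)),
              interaction = kronecker(dev(J), dev(K)))
  q <- nrow(C)
  W <- solve(C %*% V %*% t(C))
  Tstat <- as.numeric(t(C %*% mu) %*% W %*% (C %*% mu))
  R <- V %*% t(C) %*% W %*% C
  A <- 0
  for (j in seq_len(J)) {
    rows <- (j - 1) * K + seq_len(K)
    M <- matrix(0, J * K, J * K)
    M[rows, ] <- R[rows, ]
    tr1 <- sum(diag(M %*% M))
    tr2 <- sum(diag(M))
    A <- A + (tr1 + tr2^2) / (n[j] - 1)    # untrimmed: h = n
  }
  A <- A / 2
  cval <- q + 2 * A - 6 * A / (q + 2)
  Fstat <- Tstat / cval
  df2 <- q * (q + 2) / (3 * A)
  list(statistic = Fstat, df1 = q, df2 = df2,
       p = pf(Fstat, q, df2, lower.tail = FALSE))
}

# Exhaustive minimal-total-cost full assignment (every row matched) by
# recursion over all injective row -> column mappings. Requires
# nrow(cost) <= ncol(cost).
oracle_assignment_cost <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc)
  best <- Inf
  recurse <- function(i, used, tot) {
    if (tot >= best) return(invisible(NULL))
    if (i > nr) { best <<- tot; return(invisible(NULL)) }
    for (j in which(!used)) {
      used[j] <- TRUE
      recurse(i + 1, used, tot + cost[i, j])
      used[j] <- FALSE
    }
    invisible(NULL)
  }
  recurse(1, rep(FALSE, nc), 0)
  best
}
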