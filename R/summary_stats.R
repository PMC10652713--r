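# Scalar and region-level statistics: extent tables, rank tests,
# multiplicity control, the robust between-by-within ANOVA on trimmed
# means, and Fisher r-to-z correlation contrasts.

#' Per-participant coloured-extent table
#'
#' Computes, for one task, each participant's whole-body and per-region
#' coloured proportions from the (cleaned, binarized) responses. For an
#' emotion name the activation and deactivation silhouettes are overlaid
#' first ([combine_signed()]) and a pixel counts as coloured when either
#' was marked; `component` selects activation- or deactivation-only
#' extents instead. Participants whose response for the task is missing
#' are omitted.
#'
#' @param cohort A preprocessed `cohort`.
#' @param task A task name from [all_tasks()], or an emotion name
#'   (`"anger"`, ..., `"neutral"`).
#' @param component For emotions: `"either"` (default), `"activation"` or
#'   `"deactivation"`.
#' @param per_roi Include the eight per-region rows (default) or only the
#'   whole-body row per participant.
#' @return Long data frame: participant_id, group, task, region
#'   (`"whole"` plus the eight ROI names), proportion.
#' @export
extent_table <- function(cohort, task,
                         component = c("either", "activation", "deactivation"),
                         per_roi = TRUE) {
  component <- match.arg(component)
  is_emotion <- task %in% EMOTIONS
  layout <- if (is_emotion) "one_panel" else task_layout(task)
  mask <- cohort_mask(cohort, layout)
  atlas <- cohort_atlas(cohort, layout)
  roi_sizes <- tabulate(atlas$values, 8L)
  ids <- character(0); grp <- character(0); props <- list()
  for (i in seq_len(nrow(cohort$participants))) {
    pid <- cohort$participants$id[i]
    if (is_emotion) {
      act <- get_response(cohort, pid, paste0(task, "_activation"))
      deact <- get_response(cohort, pid, paste0(task, "_deactivation"))
      if (is.null(act) || is.null(deact)) next
      mp <- combine_signed(binarize(act, mask), binarize(deact, mask), task)
      pos <- switch(component,
                    either = mp$pos,
                    activation = mp$pos[mp$sign > 0L],
                    deactivation = mp$pos[mp$sign < 0L])
    } else {
      resp <- get_response(cohort, pid, task)
      if (is.null(resp)) next
      pos <- binarize(resp, mask)$pos
    }
    ids <- c(ids, pid)
    grp <- c(grp, cohort$participants$group[i])
    props[[length(props) + 1L]] <-
      if (per_roi) c(length(pos) / mask$n_in_mask,
                     tabulate(atlas$values[pos], 8L) / roi_sizes)
      else length(pos) / mask$n_in_mask
  }
  regions <- if (per_roi) c("whole", atlas$names) else "whole"
  k <- length(regions)
  data.frame(participant_id = rep(ids, each = k),
             group = rep(grp, each = k),
             task = task,
             region = rep(regions, times = length(ids)),
             proportion = unlist(props),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum test with signed effect size
#'
#' U is the rank-sum statistic for `x`. The two-sided p value is computed
#' by exact enumeration of all group assignments when `nx + ny <= 12`
#' (ties handled exactly), and by the normal approximation with tie and
#' continuity corrections otherwise. The effect size is the signed
#' `r = z / sqrt(N)` (positive when `x` tends larger), with z taken from
#' the corrected normal approximation in both regimes.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest `nx + ny` for exact enumeration (default 12).
#' @return A `bsm_test` result: statistic (U), z, p, effect size r, nA, nB.
#' @export
mann_whitney <- function(x, y, exact_limit = 12L) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  stopifnot(nx >= 1, ny >= 1)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- nx * ny / 12 * ((N + 1) - tie_term)
  dev <- U - mu
  dev <- sign(dev) * max(0, abs(dev) - 0.5)   # continuity correction
  z <- if (sig2 > 0) dev / sqrt(sig2) else 0
  if (N <= exact_limit) {
    splits <- utils::combn(N, nx)
    Us <- colSums(matrix(rk[splits], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    method <- "exact"
  } else {
    p <- if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal"
  }
  structure(list(name = "Mann-Whitney", statistic = U, z = z, p = p,
                 p_adjusted = NA_real_, effect_r = z / sqrt(N),
                 nA = nx, nB = ny, method = method),
            class = "bsm_test")
}

#' @export
print.bsm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), r = %.3f, n = %d + %d\n",
              x$name, x$statistic, x$p, x$method %||% "", x$effect_r,
              x$nA, x$nB))
  invisible(x)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down familywise-error adjustment used for the scalar test families
#' (the FDR machinery is reserved for the pixel maps).
#'
#' @param pvals Vector of raw p values.
#' @return Adjusted p values (monotone, capped at 1), same order as input.
#' @export
holm_bonferroni <- function(pvals) {
  stats::p.adjust(pvals, method = "holm")
}

# --- robust between-by-within ANOVA on trimmed means --------------------

trimmed_mean <- function(x, gamma) mean(x, trim = gamma)

winsorize <- function(x, gamma) {
  n <- length(x)
  j <- floor(gamma * n)
  s <- sort(x)
  clamp(x, s[j + 1L], s[n - j])
}

# Johansen-type test of C mu = 0 given group trimmed-mean vectors, their
# estimated covariances (block diagonal), and effective sizes h.
johansen_test <- function(C, mu, V, h, block) {
  q <- nrow(C)
  bread <- C %*% V %*% t(C)
  binv <- tryCatch(solve(bread), error = function(e) pinv(bread))
  Tstat <- drop(t(C %*% mu) %*% binv %*% (C %*% mu))
  R <- V %*% t(C) %*% binv %*% C
  A <- 0
  for (j in seq_along(h)) {
    rows <- which(block == j)
    Qj <- matrix(0, length(mu), length(mu))
    Qj[cbind(rows, rows)] <- 1
    M <- Qj %*% R
    A <- A + (sum(diag(M %*% M)) + sum(diag(M))^2) / (h[j] - 1)
  }
  A <- A / 2
  cval <- q + 2 * A - 6 * A / (q + 2)
  Fstat <- Tstat / cval
  df2 <- if (A > 0) q * (q + 2) / (3 * A) else Inf
  p <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  list(statistic = Fstat, df1 = q, df2 = df2, p = p)
}

# successive-difference contrasts for k levels ((k-1) x k)
succ_contrasts <- function(k) {
  C <- matrix(0, k - 1L, k)
  for (i in seq_len(k - 1L)) { C[i, i] <- 1; C[i, i + 1L] <- -1 }
  C
}

#' Robust between-by-within ANOVA on trimmed means
#'
#' A two-way ANOVA for one between-subject factor (e.g. patient/control)
#' crossed with one within-subject factor (e.g. emotion), robust to
#' non-normal data: group-by-condition cells are summarised by
#' `gamma`-trimmed means, their sampling covariance is estimated from the
#' winsorized covariance matrix
#' (`(n - 1) S_w / (h (h - 1))`, `h = n - 2 floor(gamma n)`), and each
#' effect (group, condition, interaction) is tested with a Johansen-type
#' approximate F statistic.
#'
#' With `gamma = 0` this reduces to the untrimmed Johansen procedure.
#'
#' @param data Long data frame with columns `subject`, `group`
#'   (between-subject), `condition` (within-subject) and `value`; every
#'   subject must have exactly one value per condition.
#' @param gamma Trim proportion per tail in `[0, 0.25]` (default 0.2).
#' @return A `trimmed_bw_anova`: data frame of per-effect statistics
#'   (statistic, df1, df2, p) plus `gamma` and the cell trimmed means.
#' @export
trimmed_bw_anova <- function(data, gamma = 0.2) {
  stopifnot(is.data.frame(data),
            all(c("subject", "group", "condition", "value") %in% names(data)))
  if (gamma < 0 || gamma >= 0.5) stopf("gamma must be in [0, 0.5)")
  groups <- sort(unique(as.character(data$group)))
  conds <- unique(as.character(data$condition))
  J <- length(groups); K <- length(conds)
  if (J < 2L) stopf("need at least two between-subject groups")
  # wide matrices per group, subjects x conditions
  Xg <- vector("list", J)
  for (j in seq_len(J)) {
    d <- data[data$group == groups[j], ]
    subj <- factor(as.character(d$subject))
    cond <- factor(as.character(d$condition), levels = conds)
    if (any(table(subj, cond) != 1L))
      stopf("unbalanced within-subject design: missing or duplicated cells in group '%s'",
            groups[j])
    Xg[[j]] <- tapply(d$value, list(subj, cond), mean)
  }
  n <- vapply(Xg, nrow, integer(1))
  h <- n - 2L * floor(gamma * n)
  if (any(h < 2L)) stopf("too few subjects per group after trimming")
  mu <- numeric(0); Vblocks <- vector("list", J)
  for (j in seq_len(J)) {
    mu <- c(mu, apply(Xg[[j]], 2, trimmed_mean, gamma = gamma))
    W <- apply(Xg[[j]], 2, winsorize, gamma = gamma)
    Sw <- stats::cov(as.matrix(W))
    Vblocks[[j]] <- (n[j] - 1) * Sw / (h[j] * (h[j] - 1))
  }
  p <- J * K
  V <- matrix(0, p, p)
  for (j in seq_len(J)) {
    rows <- ((j - 1L) * K + 1L):(j * K)
    V[rows, rows] <- Vblocks[[j]]
  }
  block <- rep(seq_len(J), each = K)
  if (max(abs(V)) < 1e-300) {
    eff <- data.frame(effect = c("group", "condition", "interaction"),
                      statistic = 0, df1 = c(J - 1, K - 1, (J - 1) * (K - 1)),
                      df2 = Inf, p = 1)
    return(structure(list(effects = eff, gamma = gamma,
                          trimmed_means = matrix(mu, J, K, byrow = TRUE,
                                                 dimnames = list(groups, conds)),
                          n = n),
                     class = "trimmed_bw_anova"))
  }
  CJ <- succ_contrasts(J); CK <- succ_contrasts(K)
  oneJ <- matrix(1, 1, J); oneK <- matrix(1, 1, K)
  tests <- list(
    group = johansen_test(kronecker(CJ, oneK / K), mu, V, h, block),
    condition = johansen_test(kronecker(oneJ / J, CK), mu, V, h, block),
    interaction = johansen_test(kronecker(CJ, CK), mu, V, h, block))
  eff <- data.frame(effect = names(tests),
                    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
                    df1 = vapply(tests, `[[`, numeric(1), "df1"),
                    df2 = vapply(tests, `[[`, numeric(1), "df2"),
                    p = vapply(tests, `[[`, numeric(1), "p"),
                    row.names = NULL)
  structure(list(effects = eff, gamma = gamma,
                 trimmed_means = matrix(mu, J, K, byrow = TRUE,
                                        dimnames = list(groups, conds)),
                 n = n),
            class = "trimmed_bw_anova")
}

#' @export
print.trimmed_bw_anova <- function(x, ...) {
  cat(sprintf("between-by-within ANOVA on %.0f%% trimmed means (n = %s)\n",
              100 * x$gamma, paste(x$n, collapse = ", ")))
  df <- x$effects
  df$statistic <- signif(df$statistic, 4)
  df$df2 <- signif(df$df2, 5)
  df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' Tests whether two correlation coefficients estimated in independent
#' groups differ: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`
#' with a two-sided normal p value.
#'
#' @param r1,r2 Correlations (strictly inside (-1, 1)).
#' @param n1,n2 Sample sizes (> 3).
#' @return A `correlation_contrast`: z, p, and the inputs.
#' @examples
#' fisher_z_compare(0.74, 118, 0.40, 118)
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stopf("correlations must be strictly inside (-1, 1)")
  if (n1 <= 3 || n2 <= 3) stopf("need n > 3 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z = z,
                 p = 2 * stats::pnorm(-abs(z)), p_adjusted = NA_real_),
            class = "correlation_contrast")
}

#' @export
print.correlation_contrast <- function(x, ...) {
  cat(sprintf("Fisher z = %.3f (r1 = %.3f, n1 = %d vs r2 = %.3f, n2 = %d), p = %.4g\n",
              x$z, x$r1, x$n1, x$r2, x$n2, x$p))
  invisible(x)
}

#' Correlation panel with between-group contrasts
#'
#' Pearson correlations among a set of variables within each group
#' (pairwise-complete observations), Holm-adjusted p values per group, and
#' a contrast table testing each pairwise correlation across the two
#' groups with [fisher_z_compare()] (contrast p values Holm-adjusted as a
#' family). Zero-variance variables yield `NA` cells.
#'
#' @param data Data frame containing `group_col` and the variables.
#' @param group_col Name of the two-level grouping column.
#' @param vars Character vector of variable columns.
#' @return A `correlation_panel`: per-group `r`, `n`, `p`, `p_adjusted`
#'   matrices and a `contrasts` data frame.
#' @export
correlation_panel <- function(data, group_col, vars) {
  stopifnot(all(c(group_col, vars) %in% names(data)))
  lev <- sort(unique(as.character(data[[group_col]])))
  if (length(lev) != 2L) stopf("correlation_panel needs exactly two groups")
  per_group <- lapply(lev, function(g) {
    d <- as.matrix(data[data[[group_col]] == g, vars, drop = FALSE])
    n <- crossprod(!is.na(d))
    r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
    tt <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), pmax(n - 2, 1))
    diag(p) <- NA
    up <- upper.tri(p)
    padj <- p
    padj[up] <- holm_bonferroni(p[up])
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    list(r = r, n = n, p = p, p_adjusted = padj)
  })
  names(per_group) <- lev
  pairs <- which(upper.tri(diag(length(vars))), arr.ind = TRUE)
  ct <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r1 <- per_group[[1]]$r[i, j]; n1 <- per_group[[1]]$n[i, j]
    r2 <- per_group[[2]]$r[i, j]; n2 <- per_group[[2]]$n[i, j]
    ok <- is.finite(r1) && is.finite(r2) && abs(r1) < 1 && abs(r2) < 1 &&
      n1 > 3 && n2 > 3
    fz <- if (ok) fisher_z_compare(r1, n1, r2, n2) else NULL
    data.frame(var1 = vars[i], var2 = vars[j],
               r1 = r1, n1 = n1, r2 = r2, n2 = n2,
               z = if (ok) fz$z else NA_real_,
               p = if (ok) fz$p else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ct$p_adjusted <- holm_bonferroni(ct$p)
  structure(list(groups = lev, by_group = per_group, contrasts = ct,
                 vars = vars),
            class = "correlation_panel")
}

#' Brief Pain Inventory mean interference
#'
#' Condenses the seven BPI interference items (mood, walking, working,
#' relationships, sleep, joy of life, life in general; each 0-10) to their
#' arithmetic mean. Up to 3 missing items are tolerated (mean of the
#' observed); more yields `NA`.
#'
#' @param items Numeric vector of the 7 items (may contain `NA`), or a
#'   matrix/data frame with 7 columns (one row per participant).
#' @return Scalar (or vector) mean interference.
#' @export
bpi_interference_mean <- function(items) {
  f <- function(v) {
    if (length(v) != 7L) stopf("expected 7 BPI interference items")
    if (any(v < 0 | v > 10, na.rm = TRUE)) stopf("BPI items must be in 0-10")
    if (sum(is.na(v)) > 3L) return(NA_real_)
    mean(v, na.rm = TRUE)
  }
  if (is.matrix(items) || is.data.frame(items))
    apply(as.matrix(items), 1L, f)
  else f(items)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' two-sided p value. Degenerate input (zero variance in both samples) with
#' equal means returns statistic 0, p 1.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return A `bsm_test` result with statistic, df, p.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  d <- mean(x) - mean(y)
  if (se2 <= 0) {
    stat <- if (d == 0) 0 else sign(d) * Inf
    df <- nx + ny - 2
    p <- if (d == 0) 1 else 0
  } else {
    stat <- d / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(stat), df)
  }
  structure(list(name = "Welch t", statistic = stat, df = df, p = p,
                 p_adjusted = NA_real_, effect_r = NA_real_,
                 nA = nx, nB = ny, method = "welch"),
            class = "bsm_test")
}
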