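# Mass-univariate pixel-wise group comparison with FDR thresholding.
#
# Group data are matrices of in-mask pixel values, one row per participant:
# 0/1 for binary (pain/sensitivity) maps, -1/0/1 for signed emotion maps.
# An independent two-sample test runs at every pixel; Benjamini-Hochberg
# correction is then applied over exactly the m in-mask pixels of the
# silhouette, degenerate (constant) pixels included.

#' Stack maps into a participants x pixels matrix
#'
#' @param maps List of `binary_map` or `signed_map` objects on a shared
#'   mask.
#' @return Numeric matrix, one row per map, `m` columns.
#' @export
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  m <- maps[[1L]]$m
  out <- matrix(0, length(maps), m)
  for (i in seq_along(maps)) {
    mp <- maps[[i]]
    if (mp$m != m) stopf("maps use different masks")
    out[i, mp$pos] <- if (is.null(mp$sign)) 1 else mp$sign
  }
  rownames(out) <- vapply(maps, function(x)
    x$participant_id %||% NA_character_, character(1))
  out
}

as_map_matrix <- function(x) {
  if (is.matrix(x)) x else stack_maps(x)
}

#' Group frequency map
#'
#' Per-pixel mean over participants: for binary maps the proportion of the
#' group that coloured the pixel (in `[0, 1]`); for signed maps the mean of
#' the -1/0/1 values (in `[-1, 1]`).
#'
#' @param maps List of maps or a stacked matrix (see [stack_maps()]).
#' @return Numeric vector over the in-mask pixels.
#' @export
group_frequency_map <- function(maps) {
  X <- as_map_matrix(maps)
  colMeans(X)
}

new_pixel_comparison <- function(statistic, p, test, nA, nB, m) {
  structure(list(statistic = statistic, p = p, q = NULL,
                 significant = NULL, test = test, nA = nA, nB = nB,
                 alpha = NA_real_, m = m),
            class = "pixel_comparison")
}

col_var <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  (colSums(X * X) - n * mu * mu) / (n - 1)
}

#' Pixel-wise two-sample t map
#'
#' A two-sample t test of the signed (-1/0/1) values at every in-mask
#' pixel, group A minus group B (positive statistics mean stronger
#' activation in A). Welch's unequal-variance form by default; pooled
#' variance with `var_equal = TRUE`. Pixels with zero variance in both
#' groups get statistic 0 and p 1 but remain part of the pixel family for
#' correction. Two-sided p values.
#'
#' Missing responses are handled listwise: each group matrix contains only
#' participants with a usable map for the task.
#'
#' @param groupA,groupB Lists of `signed_map`s (or stacked matrices).
#' @param var_equal Use the pooled-variance t instead of Welch.
#' @return A `pixel_comparison` (un-thresholded; see [fdr_threshold()]).
#' @export
pixelwise_ttest <- function(groupA, groupB, var_equal = FALSE) {
  A <- as_map_matrix(groupA); B <- as_map_matrix(groupB)
  if (ncol(A) != ncol(B)) stopf("groups use different masks")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2L || nB < 2L) stopf("each group needs at least 2 participants")
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- col_var(A); vB <- col_var(B)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se2 <- sp2 * (1 / nA + 1 / nB)
    df <- rep(nA + nB - 2, ncol(A))
  } else {
    a <- vA / nA; b <- vB / nB
    se2 <- a + b
    df <- se2^2 / (a^2 / (nA - 1) + b^2 / (nB - 1))
  }
  degen <- se2 <= 0 | !is.finite(df)
  stat <- ifelse(degen, 0, (mA - mB) / sqrt(pmax(se2, 1e-300)))
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(stat), df))
  new_pixel_comparison(stat, p, "t", nA, nB, ncol(A))
}

#' Pixel-wise two-proportion z map
#'
#' At every in-mask pixel, the pooled two-proportion z test of the fraction
#' of each group that coloured the pixel:
#' `z = (pA - pB) / sqrt(p(1-p)(1/nA + 1/nB))` with pooled `p`. Positive z
#' means a larger proportion in group A. Pixels coloured by nobody (or by
#' everybody) in both groups get z 0, p 1. Two-sided p values.
#'
#' @param groupA,groupB Lists of `binary_map`s (or stacked 0/1 matrices).
#' @return A `pixel_comparison`.
#' @export
pixelwise_proportion_test <- function(groupA, groupB) {
  A <- as_map_matrix(groupA); B <- as_map_matrix(groupB)
  if (ncol(A) != ncol(B)) stopf("groups use different masks")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 1L || nB < 1L) stopf("empty group")
  pA <- colMeans(A); pB <- colMeans(B)
  pp <- (pA * nA + pB * nB) / (nA + nB)
  se2 <- pp * (1 - pp) * (1 / nA + 1 / nB)
  degen <- se2 <= 0
  stat <- ifelse(degen, 0, (pA - pB) / sqrt(pmax(se2, 1e-300)))
  p <- ifelse(degen, 1, 2 * stats::pnorm(-abs(stat)))
  new_pixel_comparison(stat, p, "proportion_z", nA, nB, ncol(A))
}

#' Benjamini-Hochberg thresholding over the silhouette
#'
#' Step-up FDR correction over exactly the `m` in-mask pixels (degenerate
#' p = 1 pixels included in the family). Adds the adjusted `q` grid and the
#' `significant` mask (`q <= alpha`) to the comparison.
#'
#' @param pmap A `pixel_comparison`.
#' @param alpha FDR level (default 0.05).
#' @return The updated `pixel_comparison`.
#' @export
fdr_threshold <- function(pmap, alpha = 0.05) {
  stopifnot(inherits(pmap, "pixel_comparison"))
  pmap$q <- stats::p.adjust(pmap$p, method = "BH")
  pmap$alpha <- alpha
  pmap$significant <- pmap$q <= alpha
  pmap
}

#' @export
print.pixel_comparison <- function(x, ...) {
  cat(sprintf("pixel_comparison (%s): nA=%d nB=%d over m=%d pixels",
              x$test, x$nA, x$nB, x$m))
  if (!is.null(x$significant))
    cat(sprintf("; %d significant at FDR %.3g", sum(x$significant), x$alpha))
  cat("\n")
  invisible(x)
}
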