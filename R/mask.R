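# Silhouette masks and the eight-region anatomical atlas.
#
# The statistics in this package are mask-agnostic: every map is a vector of
# values over the in-mask pixels of a silhouette_mask, and the atlas labels
# those same pixels 1..8. The procedural fixture below stands in for the
# colouring-tool artwork; a scanned silhouette can be dropped in through
# read_mask() without touching any downstream code.

ROI_NAMES <- c("head", "shoulders", "arms", "hands",
               "upper_torso", "lower_torso", "legs", "feet")

# Label codes follow ROI_NAMES order (1 = head, ..., 8 = feet).
# Geometry is defined in normalised panel coordinates (x, y in [0, 1]) and
# rendered by the left half + reflection so every panel is exactly
# left-right symmetric at pixel level (required for affected-side mirroring).
panel_labels <- function(height, width) {
  y <- (seq_len(height) - 0.5) / height
  x <- (seq_len(width) - 0.5) / width
  Y <- matrix(y, height, width)
  X <- matrix(x, height, width, byrow = TRUE)
  lab <- matrix(0L, height, width)
  put_rect <- function(y0, y1, x0, x1, code) {
    sel <- Y >= y0 & Y < y1 & X >= x0 & X < x1 & lab == 0L
    lab[sel] <<- code
  }
  # head: ellipse
  sel <- ((Y - 0.085) / 0.065)^2 + ((X - 0.5) / 0.16)^2 <= 1
  lab[sel] <- 1L
  put_rect(0.15, 0.23, 0.44, 0.56, 2L)     # neck (counted with shoulders)
  put_rect(0.18, 0.23, 0.20, 0.80, 2L)     # shoulder girdle
  put_rect(0.23, 0.38, 0.26, 0.74, 5L)     # upper torso
  put_rect(0.38, 0.52, 0.28, 0.72, 6L)     # lower torso
  put_rect(0.23, 0.56, 0.06, 0.18, 3L)     # left arm
  put_rect(0.23, 0.56, 0.82, 0.94, 3L)     # right arm
  put_rect(0.56, 0.66, 0.05, 0.19, 4L)     # hands
  put_rect(0.56, 0.66, 0.81, 0.95, 4L)
  put_rect(0.52, 0.90, 0.30, 0.46, 7L)     # legs
  put_rect(0.52, 0.90, 0.54, 0.70, 7L)
  put_rect(0.90, 0.97, 0.26, 0.48, 8L)     # feet
  put_rect(0.90, 0.97, 0.52, 0.74, 8L)
  # enforce exact mirror symmetry: reflect the left half onto the right
  half <- width %/% 2
  lab[, width + 1L - seq_len(half)] <- lab[, seq_len(half)]
  lab
}

new_silhouette_mask <- function(grid, layout, panel_bounds = NULL) {
  idx <- which(grid)
  if (length(idx) == 0L) stopf("mask has no in-body pixels")
  rc <- arrayInd(idx, dim(grid))
  pos_lookup <- integer(length(grid))
  pos_lookup[idx] <- seq_along(idx)
  structure(list(
    grid = grid,
    layout = layout,
    panel_bounds = panel_bounds,
    n_in_mask = length(idx),
    idx = idx,
    row = rc[, 1L],
    col = rc[, 2L],
    pos_lookup = pos_lookup
  ), class = "silhouette_mask")
}

#' Procedural silhouette mask
#'
#' Draws a deterministic human silhouette (stacked ellipse/rectangle
#' primitives: head, shoulders, arms, hands, torso, legs, feet) to serve as
#' the body outline for colouring maps. `"one_panel"` produces a single
#' figure (used by the emotion tasks, which do not distinguish front from
#' back); `"two_panel"` produces two mirror-identical figures side by side
#' (front on the left, back on the right, as used by the pain and
#' sensitivity tasks).
#'
#' Generation is seedless: the same dimensions always give the same grid.
#'
#' @param height,width Frame dimensions in pixels; both must be at least 64
#'   (and `width` even for `"two_panel"`) so all eight anatomical regions
#'   can be drawn.
#' @param layout `"one_panel"` or `"two_panel"`.
#' @return A `silhouette_mask`: logical `grid` (height x width), `layout`,
#'   `panel_bounds` (two_panel only), `n_in_mask`, and cached in-mask pixel
#'   indices/coordinates.
#' @examples
#' m <- make_fixture_mask(128, 64, "one_panel")
#' m$n_in_mask
#' @export
make_fixture_mask <- function(height, width, layout = c("one_panel", "two_panel")) {
  layout <- match.arg(layout)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 64 || width < 64)
    stopf("mask frame must be at least 64x64 pixels (got %dx%d)", height, width)
  key <- sprintf("%d|%d|%s", height, width, layout)
  cached <- .mask_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (layout == "one_panel") {
    lab <- panel_labels(height, width)
    pb <- NULL
  } else {
    if (width %% 2L != 0L) stopf("two_panel layout needs an even width")
    pw <- width %/% 2L
    left <- panel_labels(height, pw)
    lab <- cbind(left, left[, rev(seq_len(pw)), drop = FALSE])
    pb <- list(front = c(1L, pw), back = c(pw + 1L, width))
  }
  if (!all(1:8 %in% lab))
    stopf("frame too small: not all 8 body regions could be drawn")
  out <- new_silhouette_mask(lab > 0L, layout, pb)
  .mask_cache[[key]] <- out
  out
}

# construction is deterministic, so caching is purely a speed-up
.mask_cache <- new.env(parent = emptyenv())

#' @export
print.silhouette_mask <- function(x, ...) {
  cat(sprintf("silhouette_mask: %dx%d, %s, %d in-mask pixels\n",
              nrow(x$grid), ncol(x$grid), x$layout, x$n_in_mask))
  invisible(x)
}

#' Anatomical region atlas for a silhouette mask
#'
#' Partitions the in-mask pixels into the eight anatomical regions of
#' interest used for regional extent summaries: head, shoulders, arms,
#' hands, upper torso, lower torso, legs and feet. For two-panel masks both
#' panels are labelled. In-mask pixels that fall outside the procedural
#' region primitives (possible for drop-in masks) are assigned to the
#' nearest labelled pixel, so the labels always partition the mask exactly.
#'
#' @param mask A `silhouette_mask`.
#' @return A `roi_atlas` with the label `matrix` (0 = background, 1..8 =
#'   region), the ordered region `names`, and `values`, the label of each
#'   in-mask pixel in mask-vector order.
#' @export
make_roi_atlas <- function(mask) {
  stopifnot(inherits(mask, "silhouette_mask"))
  h <- nrow(mask$grid); w <- ncol(mask$grid)
  if (mask$layout == "one_panel") {
    lab <- panel_labels(h, w)
  } else {
    pw <- w %/% 2L
    left <- panel_labels(h, pw)
    lab <- cbind(left, left[, rev(seq_len(pw)), drop = FALSE])
  }
  lab[!mask$grid] <- 0L
  vals <- lab[mask$idx]
  if (any(vals == 0L)) {
    # nearest-label fill for in-mask pixels the primitives missed
    miss <- which(vals == 0L)
    have <- which(vals != 0L)
    if (length(have) == 0L) stopf("mask does not overlap the body regions")
    for (i in miss) {
      d2 <- (mask$row[have] - mask$row[i])^2 + (mask$col[have] - mask$col[i])^2
      vals[i] <- vals[have[which.min(d2)]]
    }
    lab[mask$idx] <- vals
  }
  if (!all(1:8 %in% vals))
    stopf("mask is missing body regions: %s",
          paste(ROI_NAMES[setdiff(1:8, unique(vals))], collapse = ", "))
  structure(list(labels = lab, names = ROI_NAMES, values = vals,
                 dim = c(h, w)),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("roi_atlas:", paste(x$names, collapse = ", "), "\n")
  print(table(factor(x$values, levels = 1:8, labels = x$names)))
  invisible(x)
}

# Positions (in mask-vector order) of the pixels of one region.
roi_positions <- function(atlas, roi) {
  code <- if (is.character(roi)) match(roi, atlas$names) else as.integer(roi)
  if (is.na(code) || code < 1L || code > 8L) stopf("unknown ROI '%s'", roi)
  which(atlas$values == code)
}

# Mask-vector positions after flipping each panel about its own vertical
# midline. For one-panel masks this is an error by contract.
mirror_positions <- function(mask) {
  if (mask$layout != "two_panel")
    stopf("affected-side mirroring is defined for two_panel masks only")
  w <- ncol(mask$grid); pw <- w %/% 2L
  col2 <- ifelse(mask$col <= pw, pw + 1L - mask$col, 3L * pw + 1L - mask$col)
  tgt_idx <- (col2 - 1L) * nrow(mask$grid) + mask$row
  pos <- match(tgt_idx, mask$idx)
  if (anyNA(pos))
    stopf("mask panels are not left-right symmetric; cannot mirror")
  pos
}
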