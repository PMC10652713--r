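# Preprocessing: binary conversion, activation/deactivation overlay,
# outside-outline cleaning, empty-body semantics, the 10% quality-control
# rule, and affected-side mirroring.
#
# Maps are stored sparsely against a silhouette_mask:
#   binary_map: `pos` = coloured in-mask pixel positions (mask-vector order)
#   signed_map: `pos` + `sign` (+1 activation, -1 deactivation)

new_binary_map <- function(pos, m, task = NA_character_,
                           participant_id = NA_character_) {
  structure(list(pos = as.integer(pos), m = as.integer(m), task = task,
                 participant_id = participant_id),
            class = "binary_map")
}

new_signed_map <- function(pos, sgn, m, emotion = NA_character_,
                           participant_id = NA_character_) {
  structure(list(pos = as.integer(pos), sign = as.integer(sgn),
                 m = as.integer(m), emotion = emotion,
                 participant_id = participant_id),
            class = "signed_map")
}

#' Convert a colouring response to a binary map
#'
#' Any colouring counts: a pixel is 1 iff its opacity is strictly positive
#' (opacity depends on device and repeated strokes, so it is discarded).
#' Binarization is idempotent and ignores colouring outside the outline
#' (use [clean_outside()] first to measure it).
#'
#' @param resp A `colouring_response` (or an already binary `binary_map`,
#'   returned unchanged).
#' @param mask The response's `silhouette_mask`.
#' @param threshold Opacity strictly above this value counts as coloured
#'   (default 0).
#' @return A `binary_map`.
#' @export
binarize <- function(resp, mask, threshold = 0) {
  if (inherits(resp, "binary_map")) return(resp)
  stopifnot(inherits(resp, "colouring_response"))
  pos <- resp$in_pos[resp$opacity > threshold]
  new_binary_map(pos, mask$n_in_mask, resp$task, resp$participant_id)
}

#' Overlay activation and deactivation maps into a signed map
#'
#' Emotion tasks produce one silhouette for increased and one for decreased
#' bodily activation. They are combined pixel-wise as
#' `activation - deactivation`, giving +1 (activation), -1 (deactivation)
#' or 0 (uncoloured, or coloured in both - the conflict rule forced by the
#' -1/0/1 coding).
#'
#' @param activation,deactivation `binary_map`s of the same participant,
#'   emotion and mask.
#' @param emotion Optional emotion label stored on the result.
#' @return A `signed_map`.
#' @export
combine_signed <- function(activation, deactivation, emotion = NA_character_) {
  stopifnot(inherits(activation, "binary_map"),
            inherits(deactivation, "binary_map"))
  if (activation$m != deactivation$m)
    stopf("activation and deactivation maps use different masks")
  both <- intersect(activation$pos, deactivation$pos)
  act <- setdiff(activation$pos, both)
  deact <- setdiff(deactivation$pos, both)
  pos <- c(act, deact)
  sgn <- c(rep(1L, length(act)), rep(-1L, length(deact)))
  o <- order(pos)
  new_signed_map(pos[o], sgn[o], activation$m, emotion,
                 activation$participant_id)
}

#' Remove and quantify colouring outside the body outline
#'
#' Mechanises the visual outline screen: out-of-outline pixels are zeroed
#' and their share of the total coloured area is reported, so responses
#' with heavy spill can be flagged (the default pipeline flags, and never
#' auto-excludes, at fraction > 0.5).
#'
#' @param resp A `colouring_response`.
#' @param mask Its `silhouette_mask`.
#' @return List with `response` (cleaned) and `outside_fraction`
#'   (coloured-outside / coloured-total; 0 for an empty map).
#' @export
clean_outside <- function(resp, mask) {
  stopifnot(inherits(resp, "colouring_response"))
  n_out <- length(resp$out_idx)
  n_in <- length(resp$in_pos)
  frac <- if (n_in + n_out == 0L) 0 else n_out / (n_in + n_out)
  resp$out_idx <- integer(0)
  resp$out_val <- numeric(0)
  list(response = resp, outside_fraction = frac)
}

#' Classify empty colouring responses
#'
#' Patients could flag a body as intentionally left empty; controls could
#' not. Empty control bodies are therefore kept as genuine zero maps, while
#' empty patient bodies without the intentional flag are treated as missing
#' data: the response is dropped from that task's analyses (the participant
#' is retained elsewhere) and recorded in `cohort$missing`.
#'
#' @param cohort A `cohort`.
#' @return The cohort with unintentional patient empties removed and listed
#'   in `missing`.
#' @export
resolve_empty <- function(cohort) {
  grp <- setNames(cohort$participants$group, cohort$participants$id)
  drop <- vapply(cohort$responses, function(r) {
    if (!is_empty_response(r)) return(FALSE)
    if (grp[[r$participant_id]] == "control") return(FALSE)
    !isTRUE(r$intentional_empty)
  }, logical(1))
  if (any(drop)) {
    dropped <- cohort$responses[drop]
    cohort$missing <- rbind(cohort$missing, data.frame(
      participant_id = vapply(dropped, `[[`, character(1), "participant_id"),
      task = vapply(dropped, `[[`, character(1), "task"),
      row.names = NULL))
    cohort$responses <- cohort$responses[!drop]
  }
  cohort
}

#' Whole-body and regional coloured proportions
#'
#' The coloured extent of a map as a proportion of the in-mask pixels
#' (1 if the whole silhouette - or both silhouettes, for two-panel tasks -
#' was coloured, 0 if left blank), optionally broken down by the eight
#' anatomical regions (each region's coloured pixels over its own size).
#' For signed maps a pixel counts as coloured when its value is nonzero;
#' activation and deactivation extents are also reported separately.
#'
#' @param map A `binary_map` or `signed_map`.
#' @param mask Its `silhouette_mask`.
#' @param atlas Optional `roi_atlas` for the per-region breakdown.
#' @return List with `whole` and, given an atlas, `roi` (named vector);
#'   signed maps add `whole_activation` / `whole_deactivation`.
#' @export
proportion_coloured <- function(map, mask, atlas = NULL) {
  m <- mask$n_in_mask
  if (!is.null(map$m) && map$m != m)
    stopf("map was built against a different mask (m = %d vs %d)", map$m, m)
  out <- list(whole = length(map$pos) / m)
  if (inherits(map, "signed_map")) {
    out$whole_activation <- sum(map$sign > 0L) / m
    out$whole_deactivation <- sum(map$sign < 0L) / m
  }
  if (!is.null(atlas)) {
    sizes <- tabulate(atlas$values, 8L)
    counts <- tabulate(atlas$values[map$pos], 8L)
    out$roi <- setNames(counts / sizes, atlas$names)
  }
  out
}

#' The 10% colouring quality-control rule
#'
#' Retains a participant iff, in at least one task, they coloured at least
#' `min_fraction` of that task's in-mask pixels (each task is judged
#' against its own mask's pixel count; the boundary is inclusive).
#' Responses should already be cleaned and empties resolved.
#'
#' @param cohort A `cohort`.
#' @param min_fraction Retention threshold (default 0.10).
#' @return List with `cohort` (retained participants) and `report`, a
#'   `qc_report` data frame of per-participant best fractions and exclusion
#'   flags.
#' @export
qc_filter <- function(cohort, min_fraction = 0.10) {
  ids <- cohort$participants$id
  best <- setNames(numeric(length(ids)), ids)
  m1 <- cohort$mask_one_panel$n_in_mask
  m2 <- cohort$mask_two_panel$n_in_mask
  for (r in cohort$responses) {
    m <- if (r$layout == "one_panel") m1 else m2
    f <- length(r$in_pos) / m
    if (f > best[[r$participant_id]]) best[[r$participant_id]] <- f
  }
  report <- data.frame(participant_id = ids,
                       group = cohort$participants$group,
                       max_fraction = unname(best[ids]),
                       excluded = unname(best[ids]) < min_fraction,
                       row.names = NULL)
  class(report) <- c("qc_report", class(report))
  kept <- ids[!report$excluded]
  if (length(kept) == 0L) warning("no participants retained after QC")
  list(cohort = subset_cohort(cohort, kept), report = report)
}

#' Mirror a two-panel map so the affected side faces right
#'
#' Maps of patients whose condition is lateralised (e.g. left-arm CRPS) can
#' be flipped so the affected side always appears on the right-hand side of
#' the drawing. Each panel is flipped about its own vertical midline;
#' `affected_side = "right"` (or `"none"`) is the identity. The operation
#' is an involution and preserves the coloured pixel count.
#'
#' @param map A `binary_map` or `signed_map` on a two-panel mask.
#' @param affected_side `"left"`, `"right"` or `"none"`.
#' @param mask The two-panel `silhouette_mask`.
#' @return The (possibly flipped) map.
#' @export
mirror_affected_side <- function(map, affected_side, mask) {
  stopifnot(affected_side %in% c("left", "right", "none"))
  if (affected_side != "left") return(map)
  mp <- mirror_positions(mask)
  map$pos <- mp[map$pos]
  o <- order(map$pos)
  map$pos <- map$pos[o]
  if (!is.null(map$sign)) map$sign <- map$sign[o]
  map
}

# Dense vector of a binary/signed map over the mask pixels.
map_values <- function(map) {
  v <- numeric(map$m)
  v[map$pos] <- if (is.null(map$sign)) 1 else map$sign
  v
}

#' Lay a map vector out on the image grid
#'
#' @param values Numeric vector over the in-mask pixels.
#' @param mask The `silhouette_mask`.
#' @param fill Value for out-of-mask pixels (default `NA`).
#' @return A `height x width` matrix.
#' @export
map_grid <- function(values, mask, fill = NA_real_) {
  stopifnot(length(values) == mask$n_in_mask)
  g <- matrix(fill, nrow(mask$grid), ncol(mask$grid))
  g[mask$idx] <- values
  g
}
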