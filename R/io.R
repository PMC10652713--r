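# On-disk formats.
#
# A cohort directory contains:
#   participants.csv            one row per participant (documented header)
#   mask_one_panel.png/.json    body outline (0/1 PNG) + sidecar (layout,
#   mask_two_panel.png/.json    panel bounds, n_in_mask, ROI names)
#   atlas_one_panel.png         region labels as grey levels label/255
#   atlas_two_panel.png
#   responses_meta.csv          participant_id, task, intentional_empty
#   responses.csv               sparse full-precision opacities
#     (format = "csv": participant_id, task, index, opacity; `index` is the
#      1-based column-major linear index into the full grid, so outside-
#      outline colouring round-trips too), or
#   maps/<participant>/<task>.png   8-bit greyscale opacity images
#     (format = "png": round-trips within 1/255)

write_mask_files <- function(mask, atlas, dir, stem) {
  png::writePNG(ifelse(mask$grid, 1, 0), file.path(dir, paste0(stem, ".png")))
  side <- list(layout = mask$layout,
               panel_bounds = mask$panel_bounds,
               n_in_mask = mask$n_in_mask,
               roi_names = atlas$names)
  jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, null = "null")
  png::writePNG(atlas$labels / 255,
                file.path(dir, paste0(sub("mask", "atlas", stem), ".png")))
}

read_mask_files <- function(dir, stem) {
  img <- png::readPNG(file.path(dir, paste0(stem, ".png")))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  side <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  pb <- if (!is.null(side$panel_bounds))
    lapply(side$panel_bounds, as.integer)
  mask <- new_silhouette_mask(img > 0.5, side$layout, pb)
  if (mask$n_in_mask != side$n_in_mask)
    stopf("mask %s: pixel count %d does not match sidecar (%d)",
          stem, mask$n_in_mask, side$n_in_mask)
  mask
}

#' Write a cohort to a directory
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (sparse plain text, exact round-trip) or `"png"`
#'   (8-bit greyscale images, round-trip within 1/255).
#' @return `dir`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  write_mask_files(cohort$mask_one_panel, cohort$atlas_one_panel, dir,
                   "mask_one_panel")
  write_mask_files(cohort$mask_two_panel, cohort$atlas_two_panel, dir,
                   "mask_two_panel")
  meta <- data.frame(
    participant_id = vapply(cohort$responses, `[[`, character(1),
                            "participant_id"),
    task = vapply(cohort$responses, `[[`, character(1), "task"),
    intentional_empty = vapply(cohort$responses, function(r)
      if (is.na(r$intentional_empty)) "unknown"
      else as.character(r$intentional_empty), character(1)),
    row.names = NULL)
  utils::write.csv(meta, file.path(dir, "responses_meta.csv"),
                   row.names = FALSE)
  if (format == "csv") {
    chunks <- lapply(cohort$responses, function(r) {
      mask <- if (r$layout == "one_panel") cohort$mask_one_panel
              else cohort$mask_two_panel
      idx <- c(mask$idx[r$in_pos], r$out_idx)
      if (length(idx) == 0L) return(NULL)
      data.frame(participant_id = r$participant_id, task = r$task,
                 index = idx, opacity = c(r$opacity, r$out_val),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
    if (is.null(tab))
      tab <- data.frame(participant_id = character(0), task = character(0),
                        index = integer(0), opacity = numeric(0))
    # full precision so the round trip is exact
    tab$opacity <- sprintf("%.17g", tab$opacity)
    utils::write.csv(tab, file.path(dir, "responses.csv"), row.names = FALSE,
                     quote = FALSE)
  } else {
    for (r in cohort$responses) {
      mask <- if (r$layout == "one_panel") cohort$mask_one_panel
              else cohort$mask_two_panel
      pdir <- file.path(dir, "maps", r$participant_id)
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      png::writePNG(response_matrix(r, mask),
                    file.path(pdir, paste0(r$task, ".png")))
    }
  }
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Reads the formats written by [write_cohort()], validating participant
#' scale ranges, task names, response/mask shape agreement and
#' participant x task uniqueness.
#'
#' @param dir Cohort directory.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  validate_participants(participants)
  mask1 <- read_mask_files(dir, "mask_one_panel")
  mask2 <- read_mask_files(dir, "mask_two_panel")
  meta <- utils::read.csv(file.path(dir, "responses_meta.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  flags <- ifelse(meta$intentional_empty == "unknown", NA,
                  meta$intentional_empty == "TRUE")
  responses <- vector("list", nrow(meta))
  csv_path <- file.path(dir, "responses.csv")
  if (file.exists(csv_path)) {
    tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
    key <- response_key(tab$participant_id, tab$task)
    by_key <- split(seq_len(nrow(tab)), key)
    for (i in seq_len(nrow(meta))) {
      mask <- if (task_layout(meta$task[i]) == "one_panel") mask1 else mask2
      op <- matrix(0, nrow(mask$grid), ncol(mask$grid))
      rows <- by_key[[response_key(meta$participant_id[i], meta$task[i])]]
      if (!is.null(rows)) {
        if (any(tab$index[rows] < 1 | tab$index[rows] > length(op)))
          stopf("response %s/%s: pixel index outside the %dx%d grid",
                meta$participant_id[i], meta$task[i],
                nrow(op), ncol(op))
        op[tab$index[rows]] <- tab$opacity[rows]
      }
      responses[[i]] <- colouring_response(meta$participant_id[i],
                                           meta$task[i], op, mask,
                                           intentional_empty = flags[i])
    }
  } else {
    for (i in seq_len(nrow(meta))) {
      mask <- if (task_layout(meta$task[i]) == "one_panel") mask1 else mask2
      f <- file.path(dir, "maps", meta$participant_id[i],
                     paste0(meta$task[i], ".png"))
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      responses[[i]] <- colouring_response(meta$participant_id[i],
                                           meta$task[i], img, mask,
                                           intentional_empty = flags[i])
    }
  }
  cohort(participants, responses, mask1, mask2)
}
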