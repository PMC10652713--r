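# Cohort plumbing: the colouring task battery, per-response containers and
# participant metadata validation.

EMOTIONS <- c("anger", "fear", "disgust", "happiness", "sadness",
              "surprise", "neutral")

#' The colouring task battery
#'
#' Nineteen tasks: activation and deactivation silhouettes for the six basic
#' emotions plus a neutral state (one-panel), current and chronic pain maps,
#' and nociceptive, tactile and hedonic sensitivity maps (two-panel,
#' front/back).
#'
#' @return Character vector of task names.
#' @export
all_tasks <- function() {
  c(paste0(EMOTIONS, "_activation"),
    paste0(EMOTIONS, "_deactivation"),
    "pain_current", "pain_chronic",
    "sens_nociceptive", "sens_tactile", "sens_hedonic")
}

#' @rdname all_tasks
#' @param task A task name.
#' @export
task_layout <- function(task) {
  if (!all(task %in% all_tasks())) {
    stopf("unknown task name: %s",
          paste(setdiff(task, all_tasks()), collapse = ", "))
  }
  ifelse(grepl("^(pain|sens)_", task), "two_panel", "one_panel")
}

#' A single colouring response
#'
#' Stores one participant x task opacity image against its silhouette mask.
#' Opacities are kept sparsely: `in_pos`/`opacity` hold the coloured in-mask
#' pixels (positions in mask-vector order), and `out_idx`/`out_val` any
#' colouring that spilled outside the body outline (full-grid linear
#' indices), which quality control later measures and removes.
#'
#' `intentional_empty` is `TRUE`/`FALSE`/`NA` (unknown). Patients in the
#' source design could flag a deliberately empty body; controls could not,
#' so their flag is unknown and empty control bodies are treated as
#' intentional downstream (see [resolve_empty()]).
#'
#' @param participant_id Participant identifier.
#' @param task Task name (see [all_tasks()]).
#' @param opacity Either a full `height x width` matrix of opacities in
#'   `[0, 1]`, or a numeric vector of length `mask$n_in_mask` (in-mask
#'   values only).
#' @param mask The task's `silhouette_mask`.
#' @param intentional_empty Logical flag, `NA` when unknown.
#' @return A `colouring_response`.
#' @export
colouring_response <- function(participant_id, task, opacity, mask,
                               intentional_empty = NA) {
  stopifnot(inherits(mask, "silhouette_mask"))
  layout <- task_layout(task)
  if (layout != mask$layout)
    stopf("task '%s' uses a %s mask, got %s", task, layout, mask$layout)
  if (is.matrix(opacity)) {
    if (!identical(dim(opacity), dim(mask$grid)))
      stopf("response grid %dx%d does not match the %dx%d mask",
            nrow(opacity), ncol(opacity), nrow(mask$grid), ncol(mask$grid))
    if (anyNA(opacity) || min(opacity) < 0 || max(opacity) > 1)
      stopf("opacity values must be in [0, 1]")
    vals <- opacity[mask$idx]
    in_pos <- which(vals > 0)
    out_lin <- which(opacity > 0)
    out_lin <- setdiff(out_lin, mask$idx)
    out_val <- opacity[out_lin]
  } else {
    if (length(opacity) != mask$n_in_mask)
      stopf("in-mask opacity vector has length %d, expected %d",
            length(opacity), mask$n_in_mask)
    if (anyNA(opacity) || min(opacity) < 0 || max(opacity) > 1)
      stopf("opacity values must be in [0, 1]")
    vals <- opacity
    in_pos <- which(vals > 0)
    out_lin <- integer(0)
    out_val <- numeric(0)
  }
  structure(list(
    participant_id = as.character(participant_id),
    task = task,
    layout = layout,
    dim = dim(mask$grid),
    in_pos = as.integer(in_pos),
    opacity = unname(vals[in_pos]),
    out_idx = as.integer(out_lin),
    out_val = unname(out_val),
    intentional_empty = intentional_empty
  ), class = "colouring_response")
}

# Dense in-mask opacity vector of a response.
response_values <- function(resp, mask) {
  v <- numeric(mask$n_in_mask)
  v[resp$in_pos] <- resp$opacity
  v
}

#' Reconstruct the full opacity image of a response
#'
#' @param resp A `colouring_response`.
#' @param mask Its `silhouette_mask`.
#' @return A `height x width` numeric matrix (includes any outside-outline
#'   colouring still attached to the response).
#' @export
response_matrix <- function(resp, mask) {
  m <- matrix(0, resp$dim[1], resp$dim[2])
  m[mask$idx[resp$in_pos]] <- resp$opacity
  if (length(resp$out_idx)) m[resp$out_idx] <- resp$out_val
  m
}

is_empty_response <- function(resp) {
  length(resp$in_pos) == 0L && length(resp$out_idx) == 0L
}

PARTICIPANT_SCALES <- c("nrs_now", "bpi_now", "bpi_24h_mean",
                        paste0("bpi_", c("mood", "walking", "working",
                                         "relationships", "sleep", "joy",
                                         "life")),
                        paste0("sr_", c("anger", "fear", "disgust",
                                        "happiness", "sadness", "surprise",
                                        "anxiety", "depression", "pain")))

BPI_ITEMS <- paste0("bpi_", c("mood", "walking", "working", "relationships",
                              "sleep", "joy", "life"))
SELF_RATING_ITEMS <- paste0("sr_", c("anger", "fear", "disgust", "happiness",
                                     "sadness", "surprise", "anxiety",
                                     "depression", "pain"))

#' Validate a participant metadata table
#'
#' Checks the column set, 0-10 scale ranges, group/subgroup consistency
#' (controls carry subgroup `"none"`) and id uniqueness.
#'
#' @param df A data frame, one row per participant.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_participants <- function(df) {
  needed <- c("id", "group", "subgroup", "affected_side", "age", "gender",
              "chronic_pain_flag", PARTICIPANT_SCALES)
  miss <- setdiff(needed, names(df))
  if (length(miss)) stopf("participant table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stopf("duplicate participant ids")
  if (!all(df$group %in% c("patient", "control")))
    stopf("group must be 'patient' or 'control'")
  if (!all(df$subgroup %in% c("CRPS", "NP", "FM", "LBP", "other", "none")))
    stopf("invalid subgroup value")
  if (any(df$group == "control" & df$subgroup != "none"))
    stopf("controls must have subgroup 'none'")
  if (!all(df$affected_side %in% c("left", "right", "none")))
    stopf("invalid affected_side value")
  if (!all(df$gender %in% c("woman", "man", "other")))
    stopf("invalid gender value")
  if (any(df$age < 0 | df$age > 130)) stopf("implausible age")
  for (col in PARTICIPANT_SCALES) {
    v <- df[[col]]
    bad <- !is.na(v) & (v < 0 | v > 10)
    if (any(bad))
      stopf("%s out of the 0-10 range for participant(s) %s",
            col, paste(df$id[bad], collapse = ", "))
  }
  invisible(df)
}

response_key <- function(participant_id, task) paste(participant_id, task, sep = "::")

#' Assemble a cohort
#'
#' A cohort bundles the participant table, the colouring responses and the
#' two silhouette masks (one-panel for emotion tasks, two-panel for pain
#' and sensitivity tasks) with their region atlases. Every response must
#' belong to a listed participant, match its task's mask, and be unique per
#' participant x task.
#'
#' @param participants Validated participant data frame.
#' @param responses List of `colouring_response` objects.
#' @param mask_one_panel,mask_two_panel The two `silhouette_mask`s.
#' @param atlas_one_panel,atlas_two_panel Matching `roi_atlas`es (computed
#'   with [make_roi_atlas()] when omitted).
#' @return A `cohort`.
#' @export
cohort <- function(participants, responses, mask_one_panel, mask_two_panel,
                   atlas_one_panel = NULL, atlas_two_panel = NULL) {
  validate_participants(participants)
  keys <- vapply(responses, function(r) response_key(r$participant_id, r$task),
                 character(1))
  if (anyDuplicated(keys)) stopf("duplicate participant x task response")
  ok <- vapply(responses, function(r) r$participant_id %in% participants$id,
               logical(1))
  if (!all(ok)) stopf("response for unknown participant: %s",
                      paste(unique(vapply(responses[!ok],
                                          `[[`, character(1),
                                          "participant_id")), collapse = ", "))
  for (r in responses) {
    mk <- if (r$layout == "one_panel") mask_one_panel else mask_two_panel
    if (!identical(r$dim, dim(mk$grid)))
      stopf("response %s has grid %dx%d but the %s mask is %dx%d",
            response_key(r$participant_id, r$task), r$dim[1], r$dim[2],
            r$layout, nrow(mk$grid), ncol(mk$grid))
  }
  names(responses) <- keys
  structure(list(
    participants = participants,
    responses = responses,
    mask_one_panel = mask_one_panel,
    mask_two_panel = mask_two_panel,
    atlas_one_panel = atlas_one_panel %||% make_roi_atlas(mask_one_panel),
    atlas_two_panel = atlas_two_panel %||% make_roi_atlas(mask_two_panel),
    missing = data.frame(participant_id = character(0), task = character(0))
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d participants (%d patients, %d controls), %d responses\n",
              nrow(x$participants), sum(x$participants$group == "patient"),
              sum(x$participants$group == "control"), length(x$responses)))
  invisible(x)
}

cohort_mask <- function(cohort, layout) {
  if (layout == "one_panel") cohort$mask_one_panel else cohort$mask_two_panel
}

cohort_atlas <- function(cohort, layout) {
  if (layout == "one_panel") cohort$atlas_one_panel else cohort$atlas_two_panel
}

get_response <- function(cohort, participant_id, task) {
  cohort$responses[[response_key(participant_id, task)]]
}

# Subset a cohort to a set of participant ids (keeps their responses).
subset_cohort <- function(cohort, ids) {
  keep <- cohort$participants$id %in% ids
  out <- cohort
  out$participants <- cohort$participants[keep, , drop = FALSE]
  pid <- vapply(cohort$responses, `[[`, character(1), "participant_id")
  out$responses <- cohort$responses[pid %in% ids]
  out
}
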