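# Synthetic cohort generator.
#
# Emulates the structure the analysis assumes: a patient group of 118 with
# subgroup-specific pain topographies (CRPS -> arms on the affected side,
# LBP -> lower back, NP -> feet, FM -> diffuse), a larger control pool that
# mixes eligible and ineligible members so matching has work to do, 87%
# women, mean age ~44, and colouring maps built from spatially coherent
# blobs (real colouring is autocorrelated, so false-discovery behaviour is
# exercised under dependence, not pixel-iid noise).
#
# Every response stream is derived from (seed, participant id, task), so a
# cohort is reproducible under reordering and a single map can be redrawn
# in isolation.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the package is designed around:
#' 118 patients (42 CRPS, 24 neuropathic, 12 fibromyalgia, 32 low back
#' pain, 8 other), a 3:1 control pool with ~87% women and mean age 44, and
#' blob parameters calibrated so that patients' chronic-pain extent sits
#' near a 0.14 median against ~0.03 for controls, and patients' emotion
#' maps are dampened to 75% of the control extent
#' (`emotion_extent_multiplier_patients`).
#'
#' Blob radii are given in pixels at a reference mask height of 256 and are
#' scaled proportionally for other mask sizes.
#'
#' @param n_patients,n_control_pool Group sizes.
#' @param subgroup_counts Named patient counts for CRPS, NP, FM, LBP,
#'   other; must not exceed `n_patients` (a shortfall is filled with
#'   "other").
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param prop_women Probability a participant is a woman.
#' @param one_panel_dim,two_panel_dim Mask frame sizes (pixels).
#' @param tasks Subset of [all_tasks()] to generate responses for (use
#'   `character(0)` for metadata-only cohorts).
#' @param emotion_extent_multiplier_patients Scalar in (0, 1]; patients'
#'   emotion blob areas are scaled by this factor.
#' @param blob Blob model parameters (Poisson rates, radius ranges in
#'   reference pixels, placement prior weights, opacity range).
#' @param severity_sd,expressiveness_sd Log-scale SDs of the
#'   per-participant factors that couple extents across pain/nociceptive
#'   tasks and across emotion tasks respectively.
#' @param p_accidental_empty Probability a patient response is lost
#'   (empty, not flagged intentional) - exercises missing-data handling.
#' @param p_outside_spill Probability a response adds colouring outside
#'   the outline - exercises the quality-control screen (default 0).
#' @param control_chronic_pain_rate Fraction of the control pool reporting
#'   a chronic pain condition (ineligible for matching).
#' @param self_ratings Named mean vectors (`control`, `patient`) for the
#'   nine 0-10 momentary self-ratings.
#' @param null_mode When `TRUE`, patients' maps are drawn from the control
#'   distributions (multiplier forced to 1): group map distributions are
#'   identical by construction.
#' @param seed Master seed; all randomness descends from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 118L,
                       n_control_pool = 354L,
                       subgroup_counts = c(CRPS = 42L, NP = 24L, FM = 12L,
                                           LBP = 32L, other = 8L),
                       age_mean = 44, age_sd = 12, age_range = c(18, 80),
                       prop_women = 0.87,
                       one_panel_dim = c(176L, 88L),
                       two_panel_dim = c(176L, 176L),
                       tasks = all_tasks(),
                       emotion_extent_multiplier_patients = 0.75,
                       blob = NULL,
                       severity_sd = 0.5,
                       expressiveness_sd = 0.25,
                       p_accidental_empty = 0.02,
                       p_outside_spill = 0,
                       control_chronic_pain_rate = 0.2,
                       self_ratings = NULL,
                       null_mode = FALSE,
                       seed = 1L) {
  blob_default <- list(
    emotion_activation   = list(rate = 6,  radius = c(8, 18)),
    emotion_deactivation = list(rate = 3,  radius = c(8, 18)),
    neutral_scale = 0.35,
    pain_current     = list(patient = list(rate = 6,   radius = c(10, 22)),
                            control = list(rate = 0.45, radius = c(9, 20))),
    pain_chronic     = list(patient = list(rate = 8,   radius = c(10, 24)),
                            control = list(rate = 1.6, radius = c(9, 20))),
    sens_nociceptive = list(patient = list(rate = 9,   radius = c(6, 16)),
                            control = list(rate = 4,   radius = c(6, 16))),
    sens_tactile     = list(patient = list(rate = 15,  radius = c(6, 16)),
                            control = list(rate = 15,  radius = c(6, 16))),
    sens_hedonic     = list(patient = list(rate = 16,  radius = c(6, 16)),
                            control = list(rate = 16,  radius = c(6, 16))),
    prior_weight_pain = 0.6,
    prior_weight_sens = 0.5,
    opacity = c(0.4, 1))
  if (!is.null(blob)) blob_default[names(blob)] <- blob
  sr_default <- list(
    control = c(anger = 0.8, fear = 0.8, disgust = 0.5, happiness = 5.3,
                sadness = 1.2, surprise = 1.5, anxiety = 1.8,
                depression = 1.2, pain = 0.6),
    patient = c(anger = 2.8, fear = 2.6, disgust = 2.0, happiness = 4.5,
                sadness = 3.5, surprise = 2.5, anxiety = 4.5,
                depression = 4.0, pain = 6.0))
  if (!is.null(self_ratings)) sr_default[names(self_ratings)] <- self_ratings

  cfg <- list(n_patients = as.integer(n_patients),
              n_control_pool = as.integer(n_control_pool),
              subgroup_counts = subgroup_counts,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              prop_women = prop_women,
              one_panel_dim = as.integer(one_panel_dim),
              two_panel_dim = as.integer(two_panel_dim),
              tasks = tasks,
              emotion_extent_multiplier_patients =
                emotion_extent_multiplier_patients,
              blob = blob_default,
              severity_sd = severity_sd,
              expressiveness_sd = expressiveness_sd,
              p_accidental_empty = p_accidental_empty,
              p_outside_spill = p_outside_spill,
              control_chronic_pain_rate = control_chronic_pain_rate,
              self_ratings = sr_default,
              null_mode = isTRUE(null_mode),
              seed = as.integer(seed))
  if (cfg$n_patients < 1L || cfg$n_control_pool < 0L)
    stopf("group sizes must be positive")
  if (sum(subgroup_counts) > cfg$n_patients)
    stopf("subgroup counts (%d) exceed n_patients (%d)",
          sum(subgroup_counts), cfg$n_patients)
  if (emotion_extent_multiplier_patients <= 0 ||
      emotion_extent_multiplier_patients > 1)
    stopf("emotion_extent_multiplier_patients must be in (0, 1]")
  if (prop_women < 0 || prop_women > 1) stopf("prop_women must be in [0, 1]")
  if (length(tasks) && !all(tasks %in% all_tasks()))
    stopf("unknown task in config")
  class(cfg) <- "sim_config"
  cfg
}

# Per-participant latent factors (log-normal), shared across that
# participant's tasks. Derived from (seed, id) only, so the null mode keeps
# groups distributionally identical.
participant_factors <- function(config, id) {
  with_seed(substream_seed(config$seed, id, "factors"), {
    z <- stats::rnorm(2)
    c(severity = exp(config$severity_sd * z[1]),
      expressiveness = exp(config$expressiveness_sd * z[2]))
  })
}

# Blob placement prior for a patient's pain/sensitivity maps.
subgroup_prior_positions <- function(participant, mask, atlas) {
  pw <- ncol(mask$grid) %/% 2L
  switch(participant$subgroup,
    CRPS = {
      pos <- roi_positions(atlas, "arms")
      half <- ifelse(mask$col <= pw, mask$col > pw / 2,
                     mask$col - pw > pw / 2)
      want_right <- !identical(participant$affected_side, "left")
      sel <- if (want_right) half[pos] else !half[pos]
      pos[sel]
    },
    LBP = {
      pos <- roi_positions(atlas, "lower_torso")
      pos[mask$col[pos] > pw]          # back panel
    },
    NP = roi_positions(atlas, "feet"),
    seq_len(mask$n_in_mask))           # FM / other: diffuse
}

# Integer disk offsets (dr, dc, squared distance) for a radius bound R,
# cached: blob stamping then costs O(blob area), not O(mask size).
.disk_cache <- new.env(parent = emptyenv())
disk_offsets <- function(R) {
  key <- as.character(R)
  o <- .disk_cache[[key]]
  if (is.null(o)) {
    s <- -R:R
    dr <- rep(s, times = length(s))
    dc <- rep(s, each = length(s))
    d2 <- dr * dr + dc * dc
    keep <- d2 <= R * R
    o <- list(dr = dr[keep], dc = dc[keep], d2 = d2[keep])
    .disk_cache[[key]] <- o
  }
  o
}

# Add k disk blobs to a dense in-mask opacity vector.
add_blobs <- function(v, mask, k, radius_range, pool, opacity_range) {
  centers <- pool[sample.int(length(pool), k, replace = TRUE)]
  radii <- stats::runif(k, radius_range[1], radius_range[2])
  ops <- stats::runif(k, opacity_range[1], opacity_range[2])
  h <- nrow(mask$grid); w <- ncol(mask$grid)
  for (b in seq_len(k)) {
    o <- disk_offsets(ceiling(radii[b]))
    keep <- o$d2 <= radii[b]^2
    rr <- mask$row[centers[b]] + o$dr[keep]
    cc <- mask$col[centers[b]] + o$dc[keep]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    pos <- mask$pos_lookup[(cc[ok] - 1L) * h + rr[ok]]
    pos <- pos[pos > 0L]
    v[pos] <- pmin(1, v[pos] + ops[b])
  }
  v
}

#' Draw one synthetic colouring response
#'
#' Opacity is a clipped sum of disk blobs: blob count is Poisson, radii
#' uniform (scaled to the mask size), and centres follow the participant's
#' placement prior - patients' pain and nociceptive blobs concentrate in
#' their subgroup's region (arms on the affected side for CRPS, the lower
#' back panel for LBP, feet for NP, diffuse for FM), emotion blobs are
#' uniform over the body. A Poisson draw of zero yields an empty body.
#'
#' @param participant One row of the participant table (list or data
#'   frame row).
#' @param task Task name.
#' @param config A [sim_config()].
#' @param mask,atlas The task-layout mask and atlas.
#' @return A `colouring_response`.
#' @export
generate_map <- function(participant, task, config, mask, atlas) {
  stopifnot(inherits(config, "sim_config"))
  if (!task %in% all_tasks()) stopf("unknown task '%s'", task)
  if (task_layout(task) != mask$layout)
    stopf("task '%s' needs a %s mask", task, task_layout(task))
  id <- participant$id
  fac <- participant$.factors %||% participant_factors(config, id)
  is_patient <- identical(participant$group, "patient")
  eff_group <- if (is_patient && !config$null_mode) "patient" else "control"
  scale_px <- nrow(mask$grid) / 256

  with_seed(substream_seed(config$seed, id, task), {
    if (is_patient && stats::runif(1) < config$p_accidental_empty) {
      return(colouring_response(id, task, numeric(mask$n_in_mask), mask,
                                intentional_empty = FALSE))
    }
    bl <- config$blob
    emo <- sub("_(activation|deactivation)$", "", task)
    if (emo %in% EMOTIONS) {
      side <- if (grepl("_activation$", task)) "emotion_activation"
              else "emotion_deactivation"
      rate <- bl[[side]]$rate * fac[["expressiveness"]]
      if (emo == "neutral") rate <- rate * bl$neutral_scale
      radius <- bl[[side]]$radius * scale_px
      if (eff_group == "patient")
        radius <- radius * sqrt(config$emotion_extent_multiplier_patients)
      pool <- seq_len(mask$n_in_mask)
      prior_w <- 0
    } else {
      par <- bl[[task]][[eff_group]]
      rate <- par$rate
      if (task %in% c("pain_current", "pain_chronic", "sens_nociceptive"))
        rate <- rate * fac[["severity"]]
      radius <- par$radius * scale_px
      prior_w <- if (grepl("^pain_", task)) bl$prior_weight_pain
                 else if (task == "sens_nociceptive" ||
                          task == "sens_tactile") bl$prior_weight_sens
                 else 0
      pool <- seq_len(mask$n_in_mask)
      if (eff_group == "patient" && prior_w > 0) {
        prior <- subgroup_prior_positions(participant, mask, atlas)
        if (length(prior) == 0L) prior <- pool
      }
    }
    k <- stats::rpois(1, rate)
    if (k == 0L) {
      flag <- if (is_patient) TRUE else NA
      return(colouring_response(id, task, numeric(mask$n_in_mask), mask,
                                intentional_empty = flag))
    }
    v <- numeric(mask$n_in_mask)
    if (prior_w > 0 && eff_group == "patient") {
      from_prior <- stats::runif(k) < prior_w
      if (any(from_prior))
        v <- add_blobs(v, mask, sum(from_prior), radius, prior, bl$opacity)
      if (any(!from_prior))
        v <- add_blobs(v, mask, sum(!from_prior), radius, pool, bl$opacity)
    } else {
      v <- add_blobs(v, mask, k, radius, pool, bl$opacity)
    }
    resp <- colouring_response(id, task, v, mask,
                               intentional_empty = if (is_patient) FALSE else NA)
    if (config$p_outside_spill > 0 && stats::runif(1) < config$p_outside_spill)
      resp <- add_outside_spill(resp, mask, radius = max(3, 4 * scale_px))
    resp
  })
}

# Colour a small disk just outside the outline (for QC exercises).
add_outside_spill <- function(resp, mask, radius) {
  h <- nrow(mask$grid); w <- ncol(mask$grid)
  # pick a random out-of-mask pixel adjacent-ish to the body
  out_lin <- sample.int(h * w, 50L)
  out_lin <- out_lin[!mask$grid[out_lin]]
  if (length(out_lin) == 0L) return(resp)
  c0 <- arrayInd(out_lin[1L], c(h, w))
  rows <- max(1L, c0[1] - ceiling(radius)):min(h, c0[1] + ceiling(radius))
  cols <- max(1L, c0[2] - ceiling(radius)):min(w, c0[2] + ceiling(radius))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  sel <- (rr - c0[1])^2 + (cc - c0[2])^2 <= radius^2
  lin <- (cc[sel] - 1L) * h + rr[sel]
  lin <- lin[!mask$grid[lin]]
  resp$out_idx <- sort(unique(c(resp$out_idx, lin)))
  resp$out_val <- rep(stats::runif(1, 0.4, 1), length(resp$out_idx))
  resp
}

truncated_normal <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

score_draw <- function(n, mean, sd = 2) as.numeric(clamp(round(stats::rnorm(n, mean, sd)), 0, 10))

#' Generate a synthetic cohort
#'
#' Samples participant metadata (demographics, pain scores, momentary
#' self-ratings) and all requested colouring responses. Patients carry a
#' chronic-pain flag and elevated pain scores; the control pool mixes
#' eligible members with ineligible ones (chronic pain, or acute pain above
#' the matching cut-offs). Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [cohort()].
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  mask1 <- make_fixture_mask(config$one_panel_dim[1], config$one_panel_dim[2],
                             "one_panel")
  mask2 <- make_fixture_mask(config$two_panel_dim[1], config$two_panel_dim[2],
                             "two_panel")
  atlas1 <- make_roi_atlas(mask1)
  atlas2 <- make_roi_atlas(mask2)

  np <- config$n_patients; nc <- config$n_control_pool
  sub <- rep(names(config$subgroup_counts), config$subgroup_counts)
  sub <- c(sub, rep("other", np - length(sub)))

  participants <- with_seed(substream_seed(config$seed, "demographics"), {
    n <- np + nc
    grp <- c(rep("patient", np), rep("control", nc))
    ids <- c(sprintf("P%03d", seq_len(np)), sprintf("C%04d", seq_len(nc)))
    gender <- ifelse(stats::runif(n) < config$prop_women, "woman", "man")
    age <- truncated_normal(n, config$age_mean, config$age_sd,
                            config$age_range)
    subgroup <- c(sub, rep("none", nc))
    affected <- ifelse(subgroup == "CRPS",
                       ifelse(stats::runif(n) < 0.5, "left", "right"),
                       "none")
    chronic <- c(rep(TRUE, np),
                 stats::runif(nc) < config$control_chronic_pain_rate)
    nrs_probs <- c(0.55, 0.15, 0.08, 0.06, 0.05, 0.04, 0.03, 0.02,
                   0.01, 0.005, 0.005)
    ctl_scale <- function() sample(0:10, nc, replace = TRUE, prob = nrs_probs)
    nrs <- c(score_draw(np, 6), ctl_scale())
    bpi_now <- c(score_draw(np, 5.5), ctl_scale())
    bpi_24h <- c(score_draw(np, 5.5), ctl_scale())
    df <- data.frame(id = ids, group = grp, subgroup = subgroup,
                     affected_side = affected, age = age, gender = gender,
                     chronic_pain_flag = chronic, nrs_now = nrs,
                     bpi_now = bpi_now, bpi_24h_mean = bpi_24h,
                     stringsAsFactors = FALSE)
    for (item in BPI_ITEMS)
      df[[item]] <- c(score_draw(np, 5, 2.5), ctl_scale())
    interference <- rowMeans(df[, BPI_ITEMS])
    for (item in SELF_RATING_ITEMS) {
      key <- sub("^sr_", "", item)
      mu <- ifelse(df$group == "patient",
                   config$self_ratings$patient[[key]],
                   config$self_ratings$control[[key]])
      # pain interference depresses patients' momentary happiness
      if (key == "happiness")
        mu <- mu - ifelse(df$group == "patient",
                          interference - mean(interference[1:np]), 0)
      df[[item]] <- score_draw(n, mu)
    }
    df
  })

  responses <- list()
  if (length(config$tasks)) {
    responses <- vector("list", nrow(participants) * length(config$tasks))
    i <- 0L
    for (r in seq_len(nrow(participants))) {
      p <- as.list(participants[r, ])
      p$.factors <- participant_factors(config, p$id)
      for (task in config$tasks) {
        one <- task_layout(task) == "one_panel"
        i <- i + 1L
        responses[[i]] <- generate_map(p, task, config,
                                       if (one) mask1 else mask2,
                                       if (one) atlas1 else atlas2)
      }
    }
  }
  cohort(participants, responses, mask1, mask2, atlas1, atlas2)
}
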