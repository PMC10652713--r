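# End-to-end study pipeline: simulate (or load) -> clean/QC -> match ->
# pixel-wise map comparisons -> extent/ANOVA/correlation tables, with an
# optional report directory (CSV tables, JSON report, rendered PNG maps).

#' Pipeline configuration
#'
#' Bundles everything that determines a run: the simulation settings (or a
#' cohort directory to load instead), matching criteria, the FDR level for
#' pixel maps, the trim proportion for the robust ANOVAs, and the seed.
#'
#' @param sim A [sim_config()]; ignored when `cohort_dir` is given.
#' @param cohort_dir Optional directory to [read_cohort()] from.
#' @param criteria An [eligibility_criteria()].
#' @param alpha FDR level for pixel-wise maps.
#' @param gamma Trim proportion for the robust ANOVAs.
#' @param qc_min_fraction The colouring quality-control threshold.
#' @param outside_flag_threshold Outside-outline fraction above which a
#'   response is flagged (flag only, no exclusion).
#' @param seed Master seed (overrides `sim$seed`).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), cohort_dir = NULL,
                            criteria = eligibility_criteria(),
                            alpha = 0.05, gamma = 0.2,
                            qc_min_fraction = 0.10,
                            outside_flag_threshold = 0.5,
                            seed = 1L) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, cohort_dir = cohort_dir, criteria = criteria,
                 alpha = alpha, gamma = gamma,
                 qc_min_fraction = qc_min_fraction,
                 outside_flag_threshold = outside_flag_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# maps (listwise per task) for one group of participant ids
collect_binary_maps <- function(cohort, ids, task, mask) {
  out <- list()
  for (pid in ids) {
    r <- get_response(cohort, pid, task)
    if (is.null(r)) next
    out[[length(out) + 1L]] <- binarize(r, mask)
  }
  out
}

collect_signed_maps <- function(cohort, ids, emotion, mask) {
  out <- list()
  for (pid in ids) {
    a <- get_response(cohort, pid, paste0(emotion, "_activation"))
    d <- get_response(cohort, pid, paste0(emotion, "_deactivation"))
    if (is.null(a) || is.null(d)) next
    out[[length(out) + 1L]] <- combine_signed(binarize(a, mask),
                                              binarize(d, mask), emotion)
  }
  out
}

#' Run the full case-control analysis
#'
#' Stages, in order: cohort generation (or load), outside-outline cleaning
#' and empty-body resolution, the 10% quality-control filter, control
#' matching, pixel-wise group comparison maps with FDR thresholding
#' (two-proportion z for the pain and sensitivity tasks, two-sample t on
#' the signed maps for each emotion), whole-body extent tests
#' (Mann-Whitney, Holm-adjusted), robust group x emotion and group x
#' sensitivity ANOVAs on trimmed means, the self-rating group x item
#' ANOVA, the correlation panel with Fisher r-to-z group contrasts, and
#' the BPI mean-interference correlations. Identical config + seed gives
#' an identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for qc.csv, matches.csv, tests.csv,
#'   report.json and rendered PNG maps.
#' @return A `bsm_report` list with every computed table and map summary.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(schema = "bsm_report/1", seed = config$seed)

  co <- if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
        else generate_cohort(config$sim)

  # -- preprocessing ------------------------------------------------------
  outside <- numeric(0)
  for (k in names(co$responses)) {
    cl <- clean_outside(co$responses[[k]],
                        cohort_mask(co, co$responses[[k]]$layout))
    co$responses[[k]] <- cl$response
    if (cl$outside_fraction > 0) outside[k] <- cl$outside_fraction
  }
  flagged <- outside[outside > config$outside_flag_threshold]
  co <- resolve_empty(co)
  qc <- qc_filter(co, config$qc_min_fraction)
  co <- qc$cohort
  report$qc <- list(
    n_excluded = sum(qc$report$excluded),
    excluded_ids = qc$report$participant_id[qc$report$excluded],
    outside_flagged = names(flagged),
    n_missing_responses = nrow(co$missing))

  # -- matching -----------------------------------------------------------
  patients <- co$participants[co$participants$group == "patient", ]
  pool <- co$participants[co$participants$group == "control", ]
  mres <- match_controls(patients, pool, config$criteria, seed = config$seed)
  report$matching <- list(n_matched = nrow(mres$pairs),
                          unmatched = mres$unmatched,
                          mean_age_diff = if (nrow(mres$pairs))
                            mean(mres$pairs$age_diff) else NA_real_)
  analysis_ids <- c(mres$pairs$patient_id, mres$pairs$control_id)
  co_a <- subset_cohort(co, analysis_ids)
  pat_ids <- mres$pairs$patient_id
  ctl_ids <- mres$pairs$control_id

  # -- pixel-wise maps ----------------------------------------------------
  mask2 <- co_a$mask_two_panel
  mask1 <- co_a$mask_one_panel
  map_summaries <- list()
  comparisons <- list()
  for (task in c("pain_current", "pain_chronic", "sens_nociceptive",
                 "sens_tactile", "sens_hedonic")) {
    A <- collect_binary_maps(co_a, pat_ids, task, mask2)
    B <- collect_binary_maps(co_a, ctl_ids, task, mask2)
    if (length(A) < 1L || length(B) < 1L) next
    pc <- fdr_threshold(pixelwise_proportion_test(A, B), config$alpha)
    comparisons[[task]] <- list(pc = pc,
                                freq_a = group_frequency_map(A),
                                freq_b = group_frequency_map(B),
                                mask = "two_panel")
    map_summaries[[task]] <- list(
      test = pc$test, nA = pc$nA, nB = pc$nB, m = pc$m,
      n_significant = sum(pc$significant),
      frac_significant = mean(pc$significant))
  }
  for (emo in EMOTIONS) {
    A <- collect_signed_maps(co_a, pat_ids, emo, mask1)
    B <- collect_signed_maps(co_a, ctl_ids, emo, mask1)
    if (length(A) < 2L || length(B) < 2L) next
    pc <- fdr_threshold(pixelwise_ttest(A, B), config$alpha)
    comparisons[[emo]] <- list(pc = pc,
                               freq_a = group_frequency_map(A),
                               freq_b = group_frequency_map(B),
                               mask = "one_panel")
    map_summaries[[emo]] <- list(
      test = pc$test, nA = pc$nA, nB = pc$nB, m = pc$m,
      n_significant = sum(pc$significant),
      frac_significant = mean(pc$significant))
  }
  report$maps <- map_summaries

  # -- whole-body extent tests (Mann-Whitney, Holm family) ---------------
  extents <- list()
  scalar_tests <- list()
  for (task in c("pain_current", "pain_chronic", "sens_nociceptive",
                 "sens_tactile", "sens_hedonic")) {
    et <- extent_table(co_a, task)
    extents[[task]] <- et
    w <- et[et$region == "whole", ]
    x <- w$proportion[w$group == "patient"]
    y <- w$proportion[w$group == "control"]
    if (length(x) && length(y)) {
      mw <- mann_whitney(x, y)
      scalar_tests[[task]] <- data.frame(
        name = paste0("extent_", task), statistic = mw$statistic,
        z = mw$z, p = mw$p, effect_r = mw$effect_r,
        median_patients = stats::median(x), median_controls = stats::median(y),
        nA = mw$nA, nB = mw$nB, stringsAsFactors = FALSE)
    }
  }
  tests_df <- do.call(rbind, scalar_tests)
  if (!is.null(tests_df)) tests_df$p_adjusted <- holm_bonferroni(tests_df$p)
  report$extent_tests <- tests_df

  # -- robust ANOVAs ------------------------------------------------------
  emo_long <- list()
  for (emo in EMOTIONS) {
    et <- extent_table(co_a, emo)
    w <- et[et$region == "whole", ]
    if (nrow(w)) {
      w$condition <- emo
      emo_long[[emo]] <- w[, c("participant_id", "group", "condition",
                               "proportion")]
    }
  }
  emo_long <- do.call(rbind, emo_long)
  report$emotion_anova <- NULL
  if (!is.null(emo_long)) {
    names(emo_long) <- c("subject", "group", "condition", "value")
    # listwise: keep subjects with all emotions
    cnt <- table(emo_long$subject)
    emo_long <- emo_long[emo_long$subject %in%
                           names(cnt)[cnt == length(EMOTIONS)], ]
    if (length(unique(emo_long$group)) == 2L) {
      an <- trimmed_bw_anova(emo_long, config$gamma)
      report$emotion_anova <- an$effects
      report$emotion_group_means <- stats::aggregate(
        value ~ group, emo_long, mean)
    }
  }
  sens_long <- list()
  for (task in c("sens_nociceptive", "sens_tactile", "sens_hedonic")) {
    w <- extents[[task]][extents[[task]]$region == "whole", ]
    w$condition <- task
    sens_long[[task]] <- w[, c("participant_id", "group", "condition",
                               "proportion")]
  }
  sens_long <- do.call(rbind, sens_long)
  names(sens_long) <- c("subject", "group", "condition", "value")
  cnt <- table(sens_long$subject)
  sens_long <- sens_long[sens_long$subject %in% names(cnt)[cnt == 3L], ]
  report$sensitivity_anova <-
    if (length(unique(sens_long$group)) == 2L)
      trimmed_bw_anova(sens_long, config$gamma)$effects else NULL

  # -- self-rating ANOVA --------------------------------------------------
  sr <- co_a$participants[, c("id", "group", SELF_RATING_ITEMS)]
  sr_long <- stats::reshape(sr, direction = "long",
                            varying = SELF_RATING_ITEMS,
                            v.names = "value", timevar = "condition",
                            times = SELF_RATING_ITEMS, idvar = "id")
  names(sr_long)[names(sr_long) == "id"] <- "subject"
  report$self_rating_anova <- trimmed_bw_anova(
    sr_long[, c("subject", "group", "condition", "value")],
    config$gamma)$effects

  # -- correlation panel and contrasts -----------------------------------
  vars <- data.frame(id = co_a$participants$id,
                     group = co_a$participants$group,
                     stringsAsFactors = FALSE)
  whole_of <- function(task) {
    w <- extents[[task]][extents[[task]]$region == "whole", ]
    setNames(w$proportion, w$participant_id)
  }
  pc_ext <- whole_of("pain_current")
  et_chronic <- extent_table(co_a, "pain_chronic")
  wc <- et_chronic[et_chronic$region == "whole", ]
  ch_ext <- setNames(wc$proportion, wc$participant_id)
  vars$extent_pain_current <- unname(pc_ext[vars$id])
  vars$extent_pain_chronic <- unname(ch_ext[vars$id])
  for (task in c("sens_nociceptive", "sens_tactile", "sens_hedonic")) {
    v <- whole_of(task)
    vars[[paste0("extent_", task)]] <- unname(v[vars$id])
  }
  for (item in SELF_RATING_ITEMS)
    vars[[item]] <- co_a$participants[[item]][match(vars$id,
                                                    co_a$participants$id)]
  panel_vars <- setdiff(names(vars), c("id", "group"))
  panel <- correlation_panel(vars, "group", panel_vars)
  report$correlation_contrasts <- panel$contrasts
  # patients-minus-controls orientation for the headline contrast
  gp <- panel$by_group[["patient"]]; gc <- panel$by_group[["control"]]
  report$fisher_z_current_chronic <- tryCatch({
    i <- "extent_pain_current"; j <- "extent_pain_chronic"
    fisher_z_compare(gp$r[i, j], gp$n[i, j], gc$r[i, j], gc$n[i, j])$z
  }, error = function(e) NA_real_)

  # -- BPI mean interference ---------------------------------------------
  pats <- co_a$participants[co_a$participants$group == "patient", ]
  mi <- bpi_interference_mean(pats[, BPI_ITEMS])
  hap <- pats$sr_happiness
  ok <- stats::complete.cases(mi, hap)
  report$bpi_interference <- if (sum(ok) > 3) {
    ct <- stats::cor.test(mi[ok], hap[ok])
    list(r_happiness = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  } else NULL

  out <- structure(list(report = report, cohort = co_a, match = mres,
                        qc = qc$report, comparisons = comparisons,
                        extents = extents, panel = panel,
                        config = config),
                   class = "bsm_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

write_report <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
  utils::write.csv(x$match$pairs, file.path(out_dir, "matches.csv"),
                   row.names = FALSE)
  if (!is.null(x$report$extent_tests))
    utils::write.csv(x$report$extent_tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(x$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    mask <- cohort_mask(x$cohort, cm$mask)
    render_maps(cm$freq_a, cm$freq_b, cm$pc, mask,
                file.path(out_dir, paste0("map_", nm, ".png")))
  }
  invisible(out_dir)
}

#' @export
print.bsm_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("bsm_report (seed %d): %d matched pairs; %d map contrasts\n",
              r$seed, r$matching$n_matched, length(r$maps)))
  invisible(x)
}

# simple colour ramps over [0,1]
ramp_hot <- function(v) {
  cbind(pmin(1, 3 * v), clamp(3 * v - 1, 0, 1), clamp(3 * v - 2, 0, 1))
}

#' Render group frequency maps and the thresholded difference map
#'
#' Writes three PNGs, each with the mask's dimensions: the two group
#' frequency maps (colour intensity is the proportion of the group that
#' coloured each pixel) and the comparison map showing only
#' FDR-significant pixels, red where the statistic is positive (higher in
#' group A) and blue where negative.
#'
#' @param freq_a,freq_b Frequency vectors over the in-mask pixels.
#' @param comparison A thresholded `pixel_comparison`.
#' @param mask The `silhouette_mask`.
#' @param file Base PNG path; `_groupA`, `_groupB` and `_diff` are
#'   inserted before the extension.
#' @return The three file paths, invisibly.
#' @export
render_maps <- function(freq_a, freq_b, comparison, mask, file) {
  h <- nrow(mask$grid); w <- ncol(mask$grid)
  panel <- function(fill_rgb) {
    img <- array(1, c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(1, h, w)
      plane[mask$idx] <- fill_rgb[, ch]
      img[, , ch] <- plane
    }
    img
  }
  base <- function(v) {
    v <- abs(v)
    col <- ramp_hot(clamp(v, 0, 1))
    grey <- 0.88
    mix <- as.numeric(v > 0)
    col * mix + grey * (1 - mix)
  }
  sig <- comparison$significant %||% rep(FALSE, mask$n_in_mask)
  dc <- matrix(0.88, mask$n_in_mask, 3)
  pos <- sig & comparison$statistic > 0
  neg <- sig & comparison$statistic < 0
  dc[pos, ] <- matrix(rep(c(0.85, 0.10, 0.10), each = sum(pos)), ncol = 3)
  dc[neg, ] <- matrix(rep(c(0.10, 0.25, 0.85), each = sum(neg)), ncol = 3)
  paths <- vapply(c("groupA", "groupB", "diff"), function(sfx)
    sub("\\.png$", paste0("_", sfx, ".png"), file), character(1))
  png::writePNG(panel(base(freq_a)), paths[["groupA"]])
  png::writePNG(panel(base(freq_b)), paths[["groupB"]])
  png::writePNG(panel(dc), paths[["diff"]])
  invisible(paths)
}
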