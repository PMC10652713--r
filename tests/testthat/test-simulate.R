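test_that("cohort generation is seed-reproducible, bit for bit", {
  cfg <- tiny_config(tasks = c("pain_chronic", "anger_activation"), seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$responses, b$responses)
  # and different seeds differ
  d <- generate_cohort(tiny_config(tasks = c("pain_chronic",
                                             "anger_activation"), seed = 8))
  expect_false(identical(a$responses, d$responses))
})

test_that("responses are reproducible under participant reordering", {
  cfg <- tiny_config(tasks = "pain_chronic", seed = 7)
  co <- generate_cohort(cfg)
  p <- as.list(co$participants[3, ])
  redraw <- generate_map(p, "pain_chronic", cfg, co$mask_two_panel,
                         co$atlas_two_panel)
  orig <- bodymaps:::get_response(co, p$id, "pain_chronic")
  expect_identical(redraw$in_pos, orig$in_pos)
  expect_identical(redraw$opacity, orig$opacity)
})

test_that("demographics track the configured cohort structure", {
  cfg <- sim_config(n_patients = 500,
                    subgroup_counts = c(CRPS = 178, NP = 102, FM = 51,
                                        LBP = 135, other = 34),
                    n_control_pool = 500, tasks = character(0), seed = 2)
  co <- generate_cohort(cfg)
  p <- co$participants
  expect_equal(mean(p$gender == "woman"), 0.87, tolerance = 0.05)
  expect_true(all(p$age >= 18 & p$age <= 80))
  expect_equal(mean(p$age), 44, tolerance = 2)
  expect_true(all(p$chronic_pain_flag[p$group == "patient"]))
  expect_true(all(p$subgroup[p$group == "control"] == "none"))
  expect_equal(sum(p$subgroup == "CRPS"), 178)
  # patients report more pain, controls are a mixed pool with some
  # ineligible members
  expect_gt(mean(p$nrs_now[p$group == "patient"]),
            mean(p$nrs_now[p$group == "control"]) + 2)
  ctl <- p[p$group == "control", ]
  n_elig <- nrow(eligible_controls(ctl, eligibility_criteria()))
  expect_gt(n_elig, 0)
  expect_lt(n_elig, nrow(ctl))
  validate_participants(p)
})

test_that("patient pain blobs concentrate in the subgroup's region", {
  # CRPS -> arms: the arms ROI coloured fraction should dominate every
  # other region in expectation over repeated draws
  cfg <- tiny_config(tasks = character(0), seed = 13)
  co <- generate_cohort(cfg)
  mask <- co$mask_two_panel; atlas <- co$atlas_two_panel
  crps <- as.list(co$participants[co$participants$subgroup == "CRPS", ][1, ])
  roi_frac <- matrix(0, 100, 8)
  for (i in 1:100) {
    cfg_i <- tiny_config(tasks = character(0), seed = 1000 + i)
    r <- generate_map(crps, "pain_chronic", cfg_i, mask, atlas)
    pr <- proportion_coloured(binarize(r, mask), mask, atlas)
    roi_frac[i, ] <- pr$roi
  }
  avg <- colMeans(roi_frac)
  names(avg) <- atlas$names
  expect_true(all(avg["arms"] > avg[setdiff(atlas$names, "arms")]))
  # LBP -> lower torso, NP -> feet
  for (case in list(c("LBP", "lower_torso"), c("NP", "feet"))) {
    pp <- as.list(co$participants[co$participants$subgroup == case[1], ][1, ])
    roi_frac <- matrix(0, 60, 8)
    for (i in 1:60) {
      cfg_i <- tiny_config(tasks = character(0), seed = 2000 + i)
      r <- generate_map(pp, "pain_chronic", cfg_i, mask, atlas)
      roi_frac[i, ] <- proportion_coloured(binarize(r, mask), mask, atlas)$roi
    }
    avg <- setNames(colMeans(roi_frac), atlas$names)
    expect_true(all(avg[case[2]] > avg[setdiff(atlas$names, case[2])]))
  }
})

test_that("CRPS blobs honour the affected side", {
  cfg <- tiny_config(tasks = character(0), seed = 13)
  co <- generate_cohort(cfg)
  mask <- co$mask_two_panel; atlas <- co$atlas_two_panel
  crps <- as.list(co$participants[co$participants$subgroup == "CRPS", ][1, ])
  pw <- ncol(mask$grid) %/% 2
  drawing_right <- ifelse(mask$col <= pw, mask$col > pw / 2,
                          mask$col - pw > pw / 2)
  arms <- bodymaps:::roi_positions(atlas, "arms")
  count_side <- function(side) {
    crps$affected_side <- side
    right <- 0; left <- 0
    for (i in 1:40) {
      cfg_i <- tiny_config(tasks = character(0), seed = 3000 + i)
      b <- binarize(generate_map(crps, "pain_chronic", cfg_i, mask, atlas),
                    mask)
      in_arms <- intersect(b$pos, arms)
      right <- right + sum(drawing_right[in_arms])
      left <- left + sum(!drawing_right[in_arms])
    }
    c(left = left, right = right)
  }
  r <- count_side("right")
  expect_gt(r[["right"]], r[["left"]])
  l <- count_side("left")
  expect_gt(l[["left"]], l[["right"]])
})

test_that("a zero blob draw yields an intentionally empty body", {
  cfg <- tiny_config(tasks = character(0), seed = 1,
                     blob = list(pain_current = list(
                       patient = list(rate = 0, radius = c(8, 20)),
                       control = list(rate = 0, radius = c(8, 18)))),
                     p_accidental_empty = 0)
  co <- generate_cohort(cfg)
  mask <- co$mask_two_panel; atlas <- co$atlas_two_panel
  pat <- as.list(co$participants[co$participants$group == "patient", ][1, ])
  ctl <- as.list(co$participants[co$participants$group == "control", ][1, ])
  rp <- generate_map(pat, "pain_current", cfg, mask, atlas)
  expect_true(bodymaps:::is_empty_response(rp))
  expect_true(isTRUE(rp$intentional_empty))
  # controls had no flag: unknown
  rc <- generate_map(ctl, "pain_current", cfg, mask, atlas)
  expect_true(bodymaps:::is_empty_response(rc))
  expect_true(is.na(rc$intentional_empty))
})

test_that("null mode equalises patient and control map distributions", {
  ps <- numeric(20)
  for (s in 1:20) {
    cfg <- tiny_config(n_patients = 15, n_control_pool = 15,
                       subgroup_counts = c(CRPS = 5, NP = 3, FM = 3,
                                           LBP = 3, other = 1),
                       tasks = "pain_chronic", null_mode = TRUE,
                       p_accidental_empty = 0, seed = 400 + s)
    co <- generate_cohort(cfg)
    et <- extent_table(co, "pain_chronic", per_roi = FALSE)
    ps[s] <- welch_t(et$proportion[et$group == "patient"],
                     et$proportion[et$group == "control"])$p
  }
  # per-seed two-sample tests behave like null tests
  expect_gte(mean(ps > 0.01), 0.9)
})

test_that("outside spill is generated on demand and caught by cleaning", {
  cfg <- tiny_config(tasks = "sens_tactile", p_outside_spill = 1, seed = 5)
  co <- generate_cohort(cfg)
  n_out <- vapply(co$responses, function(r) length(r$out_idx), integer(1))
  expect_gt(sum(n_out > 0), 0)
  r <- co$responses[[which(n_out > 0)[1]]]
  cl <- clean_outside(r, co$mask_two_panel)
  expect_gt(cl$outside_fraction, 0)
  expect_length(cl$response$out_idx, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(n_patients = 3), "exceed")
  expect_error(sim_config(emotion_extent_multiplier_patients = 0), "0, 1")
  expect_error(sim_config(tasks = "definitely_not_a_task"), "unknown task")
})
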