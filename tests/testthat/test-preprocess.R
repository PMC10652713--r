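test_that("binarize counts any positive opacity and is idempotent", {
  m <- tiny_mask1()
  op <- matrix(0, 96, 64)
  op[m$idx[1:10]] <- 0.3
  op[m$idx[11:20]] <- 1
  b <- binarize(matrix_response(op, m, "anger_activation"), m)
  expect_equal(length(b$pos), 20)
  expect_identical(binarize(b, m), b)
  # all-zero stays all-zero
  b0 <- binarize(matrix_response(matrix(0, 96, 64), m, "anger_activation"), m)
  expect_equal(length(b0$pos), 0)
  # full in-mask colouring gives proportion 1
  op1 <- matrix(0, 96, 64); op1[m$idx] <- 1
  b1 <- binarize(matrix_response(op1, m, "anger_activation"), m)
  expect_equal(proportion_coloured(b1, m)$whole, 1)
})

test_that("signed overlay follows the activation - deactivation rule", {
  m <- tiny_mask1()
  act <- bodymaps:::new_binary_map(c(1L, 2L, 3L), m$n_in_mask)
  deact <- bodymaps:::new_binary_map(c(3L, 4L), m$n_in_mask)
  s <- combine_signed(act, deact, "anger")
  v <- bodymaps:::map_values(s)
  expect_equal(v[1:2], c(1, 1))     # activation only -> +1
  expect_equal(v[4], -1)            # deactivation only -> -1
  expect_equal(v[3], 0)             # both -> conflict -> 0
  expect_true(all(v %in% c(-1, 0, 1)))
  # overlay with an empty deactivation equals the activation as signed
  s2 <- combine_signed(act, bodymaps:::new_binary_map(integer(0), m$n_in_mask))
  expect_equal(bodymaps:::map_values(s2)[1:3], c(1, 1, 1))
  expect_equal(sum(bodymaps:::map_values(s2) != 0), 3)
})

test_that("outside-outline cleaning measures and removes spill", {
  m <- tiny_mask1()
  outside <- which(!m$grid)
  op <- matrix(0, 96, 64)
  op[m$idx[1:30]] <- 0.8
  op[outside[1:10]] <- 0.9
  cl <- clean_outside(matrix_response(op, m, "anger_activation"), m)
  expect_equal(cl$outside_fraction, 10 / 40)
  expect_length(cl$response$out_idx, 0)
  # all outside
  op2 <- matrix(0, 96, 64); op2[outside[1:5]] <- 1
  cl2 <- clean_outside(matrix_response(op2, m, "anger_activation"), m)
  expect_equal(cl2$outside_fraction, 1)
  expect_true(bodymaps:::is_empty_response(cl2$response))
  # empty map: fraction 0 by convention
  cl3 <- clean_outside(matrix_response(matrix(0, 96, 64), m,
                                       "anger_activation"), m)
  expect_equal(cl3$outside_fraction, 0)
})

test_that("empty bodies are kept for controls, dropped for unflagged patients", {
  cfg <- tiny_config(tasks = character(0))
  co <- generate_cohort(cfg)
  m <- co$mask_one_panel
  zero <- matrix(0, nrow(m$grid), ncol(m$grid))
  pid <- co$participants$id[co$participants$group == "patient"][1:3]
  cid <- co$participants$id[co$participants$group == "control"][1]
  co$responses <- list(
    colouring_response(cid, "anger_activation", zero, m, NA),
    colouring_response(pid[1], "anger_activation", zero, m, FALSE),
    colouring_response(pid[2], "anger_activation", zero, m, TRUE),
    colouring_response(pid[3], "anger_activation", zero, m, NA))
  names(co$responses) <- vapply(co$responses, function(r)
    bodymaps:::response_key(r$participant_id, r$task), character(1))
  out <- resolve_empty(co)
  kept <- vapply(out$responses, `[[`, character(1), "participant_id")
  expect_setequal(kept, c(cid, pid[2]))            # control + flagged patient
  expect_setequal(out$missing$participant_id, c(pid[1], pid[3]))
})

test_that("the 10% rule keeps exactly the participants with a sufficient task", {
  cfg <- tiny_config(tasks = character(0), n_patients = 3,
                     n_control_pool = 0,
                     subgroup_counts = c(CRPS = 3, NP = 0, FM = 0, LBP = 0,
                                         other = 0))
  co <- generate_cohort(cfg)
  m <- co$mask_one_panel
  ids <- co$participants$id
  frac_map <- function(f) {
    op <- matrix(0, nrow(m$grid), ncol(m$grid))
    k <- ceiling(f * m$n_in_mask)
    if (k > 0) op[m$idx[seq_len(k)]] <- 1
    op
  }
  co$responses <- list(
    colouring_response(ids[1], "anger_activation", frac_map(0.09), m, FALSE),
    colouring_response(ids[2], "anger_activation", frac_map(0.12), m, FALSE),
    colouring_response(ids[2], "fear_activation", frac_map(0), m, TRUE),
    colouring_response(ids[3], "anger_activation", frac_map(0.10), m, FALSE))
  names(co$responses) <- vapply(co$responses, function(r)
    bodymaps:::response_key(r$participant_id, r$task), character(1))
  qc <- qc_filter(co, 0.10)
  expect_setequal(qc$cohort$participants$id, c(ids[2], ids[3]))  # 0.10 kept
  expect_true(qc$report$excluded[qc$report$participant_id == ids[1]])
  expect_equal(qc$report$max_fraction[qc$report$participant_id == ids[2]],
               ceiling(0.12 * m$n_in_mask) / m$n_in_mask, tolerance = 1e-12)
  # monotone in the threshold: lowering it never excludes anyone new
  qc2 <- qc_filter(co, 0.05)
  expect_true(all(qc$cohort$participants$id %in% qc2$cohort$participants$id))
})

test_that("affected-side mirroring is an involution that relocates blobs", {
  m <- tiny_mask2()
  atlas <- make_roi_atlas(m)
  pw <- ncol(m$grid) %/% 2
  arms <- bodymaps:::roi_positions(atlas, "arms")
  left_front_arm <- arms[m$col[arms] <= pw / 2]    # front panel, drawing-left
  map <- bodymaps:::new_binary_map(left_front_arm, m$n_in_mask)
  flipped <- mirror_affected_side(map, "left", m)
  expect_equal(length(flipped$pos), length(map$pos))   # count preserved
  # now in the drawing-right half of the front panel, still in the arms ROI
  expect_true(all(m$col[flipped$pos] > pw / 2 & m$col[flipped$pos] <= pw))
  expect_true(all(atlas$values[flipped$pos] == match("arms", atlas$names)))
  # involution; affected right is the identity
  twice <- mirror_affected_side(flipped, "left", m)
  expect_equal(sort(twice$pos), sort(map$pos))
  expect_identical(mirror_affected_side(map, "right", m), map)
  expect_error(mirror_affected_side(map, "left", tiny_mask1()), "two_panel")
})

test_that("coloured proportions cover the whole-body and ROI cases", {
  m <- tiny_mask1()
  atlas <- make_roi_atlas(m)
  half <- bodymaps:::new_binary_map(seq_len(m$n_in_mask %/% 2), m$n_in_mask)
  expect_equal(proportion_coloured(half, m)$whole,
               (m$n_in_mask %/% 2) / m$n_in_mask)
  blank <- bodymaps:::new_binary_map(integer(0), m$n_in_mask)
  expect_equal(proportion_coloured(blank, m, atlas)$whole, 0)
  expect_true(all(proportion_coloured(blank, m, atlas)$roi == 0))
  full <- bodymaps:::new_binary_map(seq_len(m$n_in_mask), m$n_in_mask)
  pr <- proportion_coloured(full, m, atlas)
  expect_equal(pr$whole, 1)
  expect_true(all(pr$roi == 1))
  # signed maps report activation/deactivation separately
  s <- bodymaps:::new_signed_map(c(1L, 2L, 3L), c(1L, 1L, -1L), m$n_in_mask)
  ps <- proportion_coloured(s, m)
  expect_equal(ps$whole, 3 / m$n_in_mask)
  expect_equal(ps$whole_activation, 2 / m$n_in_mask)
  expect_equal(ps$whole_deactivation, 1 / m$n_in_mask)
})
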