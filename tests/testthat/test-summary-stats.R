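test_that("Mann-Whitney exact p agrees with enumeration and symmetry holds", {
  # complete separation: U = 0, exact two-sided p = 2 * (1/20)
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$p, oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)))
  # identical samples: no effect
  mw0 <- mann_whitney(c(2, 2, 5), c(2, 2, 5))
  expect_equal(mw0$effect_r, 0)
  expect_equal(mw0$statistic, 3 * 3 / 2)
  # swapping groups reflects U about nx*ny and flips the effect sign
  x <- c(3.2, 1.1, 4.4, 2.0); y <- c(5.0, 0.5, 6.1)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(b$statistic, length(x) * length(y) - a$statistic)
  expect_equal(b$effect_r, -a$effect_r)
  expect_equal(a$p, b$p)
})

test_that("Mann-Whitney normal approximation tracks the exact p", {
  set.seed(21)
  # continuous null data at n = 10 + 10: agreement within 0.01
  for (rep in 1:12) {
    x <- rnorm(10); y <- rnorm(10)
    exact <- mann_whitney(x, y, exact_limit = 20L)$p
    approx <- mann_whitney(x, y, exact_limit = 0L)$p
    expect_lt(abs(exact - approx), 0.01)
  }
  # with heavy ties the exact p still equals brute-force enumeration
  for (rep in 1:15) {
    x <- sample(0:3, 6, replace = TRUE)
    y <- sample(0:3, 6, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p, oracle_mw_exact(x, y))
  }
})

test_that("Holm adjustment matches the hand step-down rule", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(rep(0.03, 3)), rep(0.09, 3))
  expect_equal(holm_bonferroni(c(0.2, 0.01, 0.05)),
               oracle_holm(c(0.2, 0.01, 0.05)))
})

test_that("Holm and BH agree with hand computation over a p-vector grid", {
  grid <- seq(0.005, 0.2, by = 0.005)
  set.seed(17)
  for (len in 2:4) {
    for (rep in 1:40) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(holm_bonferroni(p), oracle_holm(p), tolerance = 1e-12)
      expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    }
  }
})

test_that("Welch t matches the direct formula and stats::t.test", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4, tolerance = 1e-9)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  # identical samples -> 0; affine invariance for positive scale
  expect_equal(welch_t(c(5, 5, 5), c(5, 5, 5))$statistic, 0)
  x <- rnorm(8); y <- rnorm(9)
  expect_equal(welch_t(2 * x + 1, 2 * y + 1)$statistic,
               welch_t(x, y)$statistic, tolerance = 1e-12)
})

test_that("Fisher r-to-z contrast follows the formula and its edge cases", {
  fz <- fisher_z_compare(0.5, 53, 0.0, 53)
  expect_equal(fz$z, atanh(0.5) / 0.2, tolerance = 1e-9)
  expect_equal(fz$z, 2.7465, tolerance = 1e-4)
  expect_equal(fisher_z_compare(0.3, 50, 0.3, 80)$z, 0)
  expect_error(fisher_z_compare(1, 50, 0.2, 50), "inside")
  expect_error(fisher_z_compare(0.5, 3, 0.2, 50), "n > 3")
})

test_that("trimmed ANOVA with no trimming equals the untrimmed Johansen oracle", {
  set.seed(31)
  for (rep in 1:6) {
    J <- 2; K <- sample(2:4, 1); n <- sample(12:20, 2, replace = TRUE)
    Xg <- lapply(1:J, function(j)
      matrix(rnorm(n[j] * K, mean = j / 2), n[j], K))
    long <- do.call(rbind, lapply(1:J, function(j) {
      data.frame(subject = paste0("g", j, "s", rep(seq_len(n[j]), K)),
                 group = paste0("g", j),
                 condition = rep(paste0("c", seq_len(K)), each = n[j]),
                 value = as.vector(Xg[[j]]))
    }))
    fit <- trimmed_bw_anova(long, gamma = 0)
    for (eff in c("group", "condition", "interaction")) {
      o <- oracle_johansen(Xg, eff)
      row <- fit$effects[fit$effects$effect == eff, ]
      expect_equal(row$statistic, o$statistic, tolerance = 1e-6)
      expect_equal(row$df2, o$df2, tolerance = 1e-6)
      expect_equal(row$p, o$p, tolerance = 1e-6)
    }
  }
})

test_that("trimmed ANOVA is location-equivariant and handles constant data", {
  set.seed(8)
  n <- 16; K <- 3
  long <- data.frame(subject = rep(sprintf("s%02d", 1:(2 * n)), each = K),
                     group = rep(c("a", "b"), each = n * K),
                     condition = rep(paste0("c", 1:K), 2 * n),
                     value = rnorm(2 * n * K))
  f1 <- trimmed_bw_anova(long, gamma = 0.2)
  long2 <- long; long2$value <- long2$value + 100
  f2 <- trimmed_bw_anova(long2, gamma = 0.2)
  expect_equal(f1$effects$statistic, f2$effects$statistic, tolerance = 1e-8)
  # identical constant data in both groups: null result, not an error
  long3 <- long; long3$value <- 1
  f3 <- trimmed_bw_anova(long3, gamma = 0.2)
  expect_true(all(f3$effects$statistic == 0))
  expect_true(all(f3$effects$p == 1))
  # malformed designs are rejected
  expect_error(trimmed_bw_anova(long[-1, ], gamma = 0.2), "unbalanced")
  expect_error(trimmed_bw_anova(long, gamma = 0.6), "gamma")
})

test_that("a planted group shift is detected by the trimmed ANOVA", {
  set.seed(99)
  hits <- 0
  for (rep in 1:20) {
    n <- 50; K <- 7
    base <- rnorm(2 * n)                     # subject effects
    val <- rep(base, each = K) + rnorm(2 * n * K)
    shift <- rep(c(1, 0), each = n * K)      # one within-subject SD
    long <- data.frame(subject = rep(sprintf("s%03d", 1:(2 * n)), each = K),
                       group = rep(c("a", "b"), each = n * K),
                       condition = rep(paste0("c", 1:K), 2 * n),
                       value = val + shift)
    fit <- trimmed_bw_anova(long, gamma = 0.2)
    p <- fit$effects$p[fit$effects$effect == "group"]
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("correlation panels are symmetric with exact self-correlations", {
  set.seed(12)
  n <- 30
  df <- data.frame(group = rep(c("patient", "control"), each = n),
                   a = rnorm(2 * n))
  df$b <- 2 * df$a + 1                       # exact linear function
  df$c <- rnorm(2 * n)
  pan <- correlation_panel(df, "group", c("a", "b", "c"))
  for (g in pan$groups) {
    r <- pan$by_group[[g]]$r
    expect_equal(diag(r), c(a = 1, b = 1, c = 1))
    expect_equal(r, t(r))
    expect_equal(r["a", "b"], 1, tolerance = 1e-12)
  }
  # permuting participant order changes nothing
  perm <- sample(nrow(df))
  pan2 <- correlation_panel(df[perm, ], "group", c("a", "b", "c"))
  expect_equal(pan$by_group$patient$r, pan2$by_group$patient$r)
  expect_equal(pan$contrasts$z, pan2$contrasts$z)
})

test_that("BPI mean interference averages items and tolerates few missing", {
  expect_equal(bpi_interference_mean(rep(5, 7)), 5)
  expect_equal(bpi_interference_mean(c(0, 0, 0, 0, 0, 0, 7)), 1)
  expect_equal(bpi_interference_mean(c(2, 2, 2, 2, 2, 2, NA)), 2)
  expect_true(is.na(bpi_interference_mean(c(1, 2, 3, NA, NA, NA, NA))))
  expect_error(bpi_interference_mean(c(1, 2, 3)), "7")
  expect_error(bpi_interference_mean(c(1, 2, 3, 4, 5, 6, 11)), "0-10")
  m <- rbind(rep(5, 7), c(0, 0, 0, 0, 0, 0, 7))
  expect_equal(bpi_interference_mean(m), c(5, 1))
})

test_that("extent tables are bounded with blank cohorts all zero", {
  co <- generate_cohort(tiny_config(tasks = c("pain_current",
                                              "anger_activation",
                                              "anger_deactivation"),
                                    seed = 5))
  et <- extent_table(co, "pain_current")
  expect_true(all(et$proportion >= 0 & et$proportion <= 1))
  expect_setequal(unique(et$region), c("whole", bodymaps:::ROI_NAMES))
  ete <- extent_table(co, "anger")
  expect_true(all(ete$proportion >= 0 & ete$proportion <= 1))
  ea <- extent_table(co, "anger", component = "activation", per_roi = FALSE)
  ed <- extent_table(co, "anger", component = "deactivation", per_roi = FALSE)
  # either-direction extent is at most activation + deactivation
  expect_true(all(ete$proportion[ete$region == "whole"] <=
                    ea$proportion + ed$proportion + 1e-12))
  # blank responses give all-zero extents
  m <- co$mask_two_panel
  zero <- matrix(0, nrow(m$grid), ncol(m$grid))
  co$responses <- lapply(co$participants$id[1:3], function(id)
    colouring_response(id, "pain_current", zero, m, TRUE))
  names(co$responses) <- vapply(co$responses, function(r)
    bodymaps:::response_key(r$participant_id, r$task), character(1))
  et0 <- extent_table(co, "pain_current")
  expect_true(all(et0$proportion == 0))
  expect_equal(nrow(et0), 3 * 9)
})
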