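cfg <- task_config()

# small synthetic metrics/fits fixture built in code
make_metrics_fixture <- function() {
  grid <- expand.grid(rat_id = sprintf("r%02d", 1:6), cod_s = cfg$cod_set,
                      stringsAsFactors = FALSE)
  grid$sex <- ifelse(as.integer(sub("r", "", grid$rat_id)) <= 3,
                     "male", "female")
  set.seed(11)
  grid$pc <- 10 + as.integer(factor(grid$rat_id)) - grid$cod_s / 6
  grid$tip_s <- 4 + grid$cod_s / 3 + as.integer(factor(grid$rat_id)) / 2
  grid$rejection_ul <- 96 - grid$cod_s
  grid$wr_ul_min_kg <- 3000 - 40 * grid$cod_s
  grid$vd_pct <- grid$cod_s / 2 - 5
  grid$td_pct <- ifelse(grid$cod_s == 0, NA_real_, grid$cod_s)
  grid
}

test_that("composite scores sum each measure across delays", {
  metrics <- make_metrics_fixture()
  fits <- data.frame(rat_id = sprintf("r%02d", 1:6),
                     k = seq(0.01, 0.06, by = 0.01), auc = seq(0.9, 0.4, by = -0.1))
  cs <- composite_scores(metrics, fits, cfg)
  expect_identical(nrow(cs), 6L)
  r1 <- cs[cs$rat_id == "r01", ]
  m1 <- metrics[metrics$rat_id == "r01", ]
  expect_equal(r1$pc, sum(m1$pc))
  expect_equal(r1$tip, sum(m1$tip_s))
  expect_equal(r1$wr, sum(m1$wr_ul_min_kg))
  expect_equal(r1$vd, sum(m1$vd_pct))
  expect_equal(r1$td, sum(m1$td_pct[m1$cod_s > 0]))  # TD undefined at COD 0
  expect_equal(r1$k, 0.01)
  # a rat with a missing cell is excluded with a message
  metrics$pc[metrics$rat_id == "r02" & metrics$cod_s == 12] <- NA
  expect_message(cs2 <- composite_scores(metrics, fits, cfg), "excluded")
  expect_false("r02" %in% cs2$rat_id)
  # all-zero metrics give all-zero composites
  mz <- make_metrics_fixture()
  for (v in c("pc", "tip_s", "rejection_ul", "wr_ul_min_kg", "vd_pct"))
    mz[[v]] <- 0
  mz$td_pct <- ifelse(mz$cod_s == 0, NA_real_, 0)
  cz <- composite_scores(mz, fits, cfg)
  expect_true(all(cz[, c("vd", "td", "tip", "pc", "wr")] == 0))
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(3)
  n <- 40
  scores <- data.frame(
    rat_id = sprintf("r%03d", 1:n), sex = "male",
    k = rlnorm(n, log(0.05), 0.4), auc = runif(n, 0.3, 0.9),
    vd = rnorm(n), td = rnorm(n), tip = rnorm(n, 40, 5),
    pc = rnorm(n, 50, 8), wr = rnorm(n, 1e4, 2e3))
  cm <- correlation_matrix(scores, "male")
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 7))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # identical columns correlate at 1
  scores$td <- scores$vd
  cm2 <- correlation_matrix(scores, "male")
  expect_equal(cm2["vd", "td"], 1)
  # zero-variance columns are flagged and set missing
  scores$wr <- 5
  expect_warning(cm3 <- correlation_matrix(scores, "male"), "zero-variance")
  expect_true(all(is.na(cm3["wr", -which(colnames(cm3) == "wr")])))
  expect_error(correlation_matrix(scores[1:3, ], "male"), "at least 4")
})

test_that("sample correlations recover a known latent correlation", {
  set.seed(99)
  n <- 500
  z <- rnorm(n)
  tip <- z
  td <- 0.8 * z + sqrt(1 - 0.8^2) * rnorm(n)
  scores <- data.frame(rat_id = as.character(1:n), sex = "female",
                       k = rnorm(n), auc = rnorm(n), vd = rnorm(n),
                       td = td, tip = tip, pc = rnorm(n), wr = rnorm(n))
  cm <- correlation_matrix(scores, "female")
  expect_equal(cm["tip", "td"], 0.8, tolerance = 0.05)
})

test_that("Meng z-test matches an independent formula transcription", {
  grid <- expand.grid(r1 = c(-0.8, -0.3, 0, 0.25, 0.6, 0.87),
                      r2 = c(-0.5, 0.1, 0.45, 0.9),
                      rx = c(-0.2, 0.1, 0.5, 0.8),
                      n = c(10, 60, 896))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- meng_z_test(g$r1, g$r2, g$rx, g$n)
    expect_equal(res$z, oracle_meng_z(g$r1, g$r2, g$rx, g$n),
                 tolerance = 1e-6,
                 label = sprintf("z at (%g, %g, %g, n=%d)",
                                 g$r1, g$r2, g$rx, g$n))
    expect_equal(res$p, 2 * pnorm(-abs(res$z)))
  }
})

test_that("Meng z-test is antisymmetric and null at equal correlations", {
  res0 <- meng_z_test(0.4, 0.4, 0.2, 50)
  expect_equal(res0$z, 0)
  expect_equal(res0$p, 1)
  expect_true(is.na(res0$stronger))
  a <- meng_z_test(0.7, 0.2, 0.3, 80)
  b <- meng_z_test(0.2, 0.7, 0.3, 80)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_identical(a$stronger, "r_jx")
  expect_identical(b$stronger, "r_jy")
  expect_error(meng_z_test(1, 0.2, 0.3, 50), "\\|r\\| < 1")
  expect_error(meng_z_test(0.5, 0.2, 0.3, 3), "n must exceed 3")
})

test_that("mixed ANOVA matches a hand-computed decomposition on a small fixture", {
  # 4 rats (2 per sex) x 3 delays, values chosen for clean sums of squares
  fx <- data.frame(
    rat_id = rep(c("a", "b", "c", "d"), each = 3),
    sex = rep(c("male", "male", "female", "female"), each = 3),
    cod_s = rep(c(0, 6, 12), 4),
    y = c(10, 12, 14,  12, 14, 16,  16, 18, 20,  18, 20, 22))
  res <- mixed_anova(fx, "y")
  tab <- res$table
  # hand SS: grand mean 16; sex means 13 vs 19 -> SS_sex = 6*(3^2+3^2) = 108
  expect_equal(tab$ss[tab$effect == "sex"], 108)
  # delay means 14, 16, 18 -> SS_delay = 4*(4+0+4) = 32
  expect_equal(tab$ss[tab$effect == "delay"], 32)
  # no interaction, perfectly parallel profiles
  expect_equal(tab$ss[tab$effect == "sex:delay"], 0)
  # subjects within sex: a/b and c/d differ by +-1 -> SS = 3*(1+1+1+1) = 12
  expect_equal(tab$ss[tab$effect == "residuals_between"], 12)
  expect_equal(tab$ss[tab$effect == "residuals_within"], 0)
  # partial eta squared from the same SS
  expect_equal(tab$pes[tab$effect == "sex"], 108 / (108 + 12))
  expect_equal(tab$pes[tab$effect == "delay"], 1)
  # SS additivity against the total
  expect_equal(sum(tab$ss), sum((fx$y - mean(fx$y))^2))
  # F for sex: MS_sex / MS_between-res = 108 / (12/2)
  expect_equal(tab$F[tab$effect == "sex"], 18)
})

test_that("mixed ANOVA degenerate and constructed cases behave", {
  fx <- expand.grid(rat_id = sprintf("r%d", 1:8), cod_s = c(0, 6, 12),
                    stringsAsFactors = FALSE)
  fx$sex <- ifelse(as.integer(sub("r", "", fx$rat_id)) <= 4, "male", "female")
  # identical values everywhere: zero SS for all effects
  fx$y <- 7
  res <- mixed_anova(fx, "y")
  expect_equal(sum(res$table$ss), 0)
  expect_equal(res$table$pes[res$table$effect == "sex"], 0)
  # pure additive sex shift, no delay effect
  set.seed(5)
  fx$y <- ifelse(fx$sex == "male", 10, 0) + rnorm(nrow(fx), sd = 0.1)
  res2 <- mixed_anova(fx, "y")
  t2 <- res2$table
  expect_gt(t2$F[t2$effect == "sex"], 100)
  expect_lt(t2$p[t2$effect == "sex"], 1e-4)
  expect_gt(t2$p[t2$effect == "delay"], 0.01)
  # a rat with a missing cell is dropped with a message
  fx2 <- fx[-1, ]
  expect_message(res3 <- mixed_anova(fx2, "y"), "dropped")
  expect_identical(res3$n_dropped, 1L)
})

test_that("post-hoc t-tests and Cohen's d follow their definitions", {
  fx <- expand.grid(rat_id = sprintf("r%d", 1:10), cod_s = c(0, 6),
                    stringsAsFactors = FALSE)
  fx$sex <- ifelse(as.integer(sub("r", "", fx$rat_id)) <= 5, "male", "female")
  # equal group means -> t = 0, d = 0
  fx$y <- rep(c(1, 2, 3, 4, 5), 4)
  ph <- posthoc_tests(fx, "y")
  expect_equal(ph$between$t, c(0, 0))
  expect_equal(ph$between$cohen_d, c(0, 0))
  expect_equal(ph$between$p_bonferroni, pmin(ph$between$p * 2, 1))
  # two groups with means 0 (males) and 1 (females), common SD 1:
  # |d| = 1 by definition (group 1 is the first factor level, female)
  y1 <- c(-1, -0.5, 0, 0.5, 1); y1 <- (y1 - mean(y1)) / sd(y1)
  fx$y <- c(y1, y1 + 1, y1, y1 + 1)
  ph2 <- posthoc_tests(fx, "y")
  expect_equal(ph2$between$cohen_d, c(1, 1))
  expect_equal(ph2$between$mean_1 - ph2$between$mean_2, c(1, 1))
  # within-subject pairs: one pair, paired t on the differences
  d6 <- fx$y[fx$cod_s == 6] - fx$y[fx$cod_s == 0]
  expect_equal(ph2$within$mean_diff, mean(d6))
  expect_identical(nrow(ph2$within), 1L)
})

test_that("skewness screen separates symmetric from skewed samples", {
  set.seed(21)
  sym <- normality_screen(rnorm(5000))
  expect_lt(abs(sym$skewness), 0.15)
  expect_true(sym$pass)
  ex <- normality_screen(rexp(10000))
  expect_equal(ex$skewness, 2, tolerance = 0.15)
  expect_false(ex$pass)
  cst <- normality_screen(rep(3, 10))
  expect_true(is.na(cst$skewness))
  expect_true(is.na(cst$pass))
  expect_error(normality_screen(c(1, 2)), "at least 3")
  # exact G1 on a tiny fixture against the direct formula
  x <- c(1, 2, 4, 8)
  n <- 4; m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  expect_equal(normality_screen(x)$skewness,
               (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2))
})

test_that("Meng z-test type-I error is calibrated under a simulated null", {
  # equal population correlations sharing a variable; needs only the
  # trivariate normal sampler, not the full simulator
  set.seed(2024)
  r_shared <- 0.4; r_xy <- 0.3; n <- 60; reps <- 2500
  Sig <- matrix(c(1, r_shared, r_shared,
                  r_shared, 1, r_xy,
                  r_shared, r_xy, 1), 3)
  L <- chol(Sig)
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    X <- matrix(rnorm(n * 3), n) %*% L
    R <- cor(X)
    rej[i] <- meng_z_test(R[1, 2], R[1, 3], R[2, 3], n)$p < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})
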