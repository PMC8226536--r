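test_that("CT calling interpolates the first threshold crossing", {
  # crossing exactly at a sampled cycle
  f <- c(rep(0.01, 23), 0.15, 0.8, 1.5)
  expect_equal(ct_from_curve(f)$ct, 24)
  # linear interpolation between bracketing cycles
  r <- ct_from_curve(c(0.10, 0.20), cycles = c(20, 21))
  expect_equal(r$ct, 20.5)
  expect_false(r$censored)
  # flat curve is censored, not an error
  r2 <- ct_from_curve(rep(0.01, 40))
  expect_true(r2$censored)
  expect_true(is.na(r2$ct))
  expect_equal(r2$max_cycle, 40L)
})

test_that("CT from a synthetic logistic curve matches the closed-form inversion", {
  # F(c) = Fmax / (1 + exp(-(c - c0)/s)) crosses th at
  # c = c0 - s log(Fmax/th - 1); with Fmax = 0.3, th = 0.15 the crossing sits
  # at the inflection point c0 = 24.3, where linear interpolation is exact
  # to third order
  cycles <- 1:40
  f <- 0.3 / (1 + exp(-(cycles - 24.3) / 1.5))
  expect_lt(abs(ct_from_curve(f, cycles)$ct - 24.3), 0.01)
})

test_that("delta-CT is the difference of replicate means, no trimming", {
  t1 <- ct_measurement("s1", "tgt", c(25, 25, 25))
  r1 <- ct_measurement("s1", "ref", c(20, 20, 20))
  expect_equal(delta_ct(t1, r1)$delta_ct, 5)
  expect_equal(delta_ct(r1, r1)$delta_ct, 0)
  # an outlier replicate is averaged in, not rejected
  t2 <- ct_measurement("s1", "tgt", c(24.8, 25.1, 31))
  expect_equal(delta_ct(t2, r1)$delta_ct, mean(c(24.8, 25.1, 31)) - 20)
  expect_error(delta_ct(ct_measurement("s2", "tgt", 25), r1), "mismatch")
  expect_error(ct_measurement("s", "a", c(25, 41)), "in \\(0, 40\\]")
})

test_that("fold change follows 2^-ddCT with reciprocal symmetry", {
  expect_equal(fold_change(c(5, 5), c(5, 5))$fc, 1)
  expect_equal(fold_change(c(4, 4), c(5, 5))$fc, 2)
  # -1.3219 cycles is almost exactly 2.5-fold
  expect_equal(fold_change(3.6781, 5)$fc, 2.50, tolerance = 1e-4)
  expect_error(fold_change(numeric(), 1), "empty")
  set.seed(701)
  for (i in 1:10) {
    a <- rnorm(5, 5); b <- rnorm(7, 6)
    expect_equal(fold_change(a, b)$fc * fold_change(b, a)$fc, 1,
                 tolerance = 1e-12)
  }
})

test_that("adding a constant to target replicates shifts delta-CT by that constant", {
  set.seed(702)
  t0 <- rnorm(3, 25, 0.2); r0 <- rnorm(3, 20, 0.2)
  base <- delta_ct(ct_measurement("s", "t", t0),
                   ct_measurement("s", "r", r0))$delta_ct
  for (c0 in c(-2, 0.5, 3)) {
    shifted <- delta_ct(ct_measurement("s", "t", t0 + c0),
                        ct_measurement("s", "r", r0))$delta_ct
    expect_equal(shifted, base + c0, tolerance = 1e-12)
  }
})

test_that("standard-curve efficiency follows 10^(-1/slope) - 1", {
  # ideal doubling: slope -1/log10(2)
  lg <- 0:-4
  e <- efficiency_from_dilution(lg, 20 - lg / log10(2))
  expect_equal(e$efficiency, 1, tolerance = 1e-10)
  expect_equal(e$r_squared, 1)
  # frozen direct evaluation at slope -3.456
  e2 <- efficiency_from_dilution(lg, 20 - 3.456 * lg)
  expect_equal(e2$efficiency, 0.94694, tolerance = 1e-4)
  # round trip through a noiseless series generated at E = 0.92
  slope <- -1 / log10(1.92)
  e3 <- efficiency_from_dilution(lg, 22 + slope * lg)
  expect_equal(e3$efficiency, 0.92, tolerance = 1e-10)
  expect_error(efficiency_from_dilution(c(0, -1), c(20, 23)), ">= 3")
  expect_error(efficiency_from_dilution(rep(1, 4), 20:23), "zero variance")
})

test_that("digital-PCR quantification inverts the Poisson partition model", {
  z <- dpcr_quantify(0L, 10000L, 0.001)
  expect_equal(z$copies_per_ul, 0)
  h <- dpcr_quantify(5000L, 10000L, 0.001)
  expect_equal(h$lambda, log(2), tolerance = 1e-12)
  expect_equal(h$copies_per_ul, log(2) / 0.001, tolerance = 1e-12)
  s <- dpcr_quantify(100L, 100L, 0.001)
  expect_true(s$saturated)
  expect_true(is.infinite(s$lambda))
  expect_error(dpcr_quantify(11L, 10L, 1), "in \\[0, total\\]")
})

test_that("the dPCR interval covers the truth in at least 93 of 100 simulations", {
  covered <- 0L
  for (r in 1:100) {
    sim <- generate_dpcr_partitions(300, partitions = 5000L,
                                    volume_ul = 0.00091, seed = 20100 + r)
    est <- dpcr_quantify(sim$positives, sim$total, sim$volume_ul)
    if (est$ci[["lower"]] <= 300 && 300 <= est$ci[["upper"]])
      covered <- covered + 1L
  }
  expect_gte(covered, 93L)
})

test_that("re-simulating from a dPCR estimate is a statistical fixed point", {
  # maximum-likelihood inverse: estimate -> simulate -> re-estimate stays
  # centered on the original estimate
  first <- dpcr_quantify(generate_dpcr_partitions(400, seed = 71)$positives,
                         26000L)
  again <- vapply(1:40, function(r) {
    sim <- generate_dpcr_partitions(first$copies_per_ul, 26000L,
                                    seed = 7100 + r)
    dpcr_quantify(sim$positives, sim$total)$copies_per_ul
  }, 0)
  expect_lt(abs(mean(again) - first$copies_per_ul),
            3 * stats::sd(again) / sqrt(length(again)) + 1e-9)
})

test_that("pool fractions are concentration ratios", {
  pool <- dpcr_quantify(9000L, 26000L)
  expect_equal(pool_fraction(pool, pool)$fraction, 1)
  zero <- dpcr_quantify(0L, 26000L)
  expect_equal(pool_fraction(zero, pool)$fraction, 0)
  expect_error(pool_fraction(pool, zero), "zero pool")
})

test_that("membrane-potential fold change is the ratio of red/green ratios", {
  expect_equal(mmp_fold_change(300, 100, 600, 200), 1)
  expect_equal(mmp_fold_change(150, 100, 300, 100), 0.5)
  set.seed(703)
  for (i in 1:10) {
    v <- runif(4, 10, 1000)
    expect_equal(mmp_fold_change(v[1], v[2], v[3], v[4]),
                 (v[1] / v[2]) / (v[3] / v[4]))
  }
  expect_error(mmp_fold_change(0, 1, 1, 1), "positive")
})

test_that("group comparison reproduces the textbook two-sample t-test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742, tolerance = 1e-4)
  expect_equal(r$p, 0.02131, tolerance = 1e-3)
  expect_equal(r$df, 4)
  w <- compare_groups(c(1, 2, 3), c(4, 6, 14), variant = "welch")
  expect_lt(w$df, 4)  # unequal variances shrink the Welch df
  expect_error(compare_groups(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("student p broadly agrees with the exhaustive permutation test", {
  set.seed(704)
  for (i in 1:8) {
    a <- rnorm(5, 0); b <- rnorm(5, 1.2)
    p_t <- compare_groups(a, b)$p
    vals <- c(a, b)
    combs <- utils::combn(10L, 5L)
    obs <- abs(mean(a) - mean(b))
    stat <- apply(combs, 2L, function(idx)
      abs(mean(vals[idx]) - mean(vals[-idx])))
    p_perm <- mean(stat >= obs - 1e-12)
    expect_lt(abs(p_t - p_perm), 0.05)
  }
})

test_that("censored replicates are excluded from table-level means", {
  tab <- data.frame(sample = c("s1", "s1"), assay = c("T", "R"),
                    rep1 = c(25, 20), rep2 = c(NA, 20), rep3 = c(25.2, 20),
                    group = "g")
  d <- ct_table_delta(tab, "T", "R")
  expect_equal(d$delta_ct, mean(c(25, 25.2)) - 20)
  expect_equal(attr(d, "censored"), 1L)
})

test_that("the cohort pipeline recovers a planted fold change and detects it", {
  ct <- generate_ct_table(cohort_config(seed = 705))
  rq <- relative_quantification(ct, "IVS9", "ACTB", "AD", "Control")
  expect_gt(rq$fc, 2.2); expect_lt(rq$fc, 2.8)
  expect_lt(rq$test$p, 0.001)
  expect_equal(nrow(rq$delta), 67L)
})

test_that("a planted mitochondrial copy-number loss is recovered through ddCT", {
  ds <- generate_h2o2_dataset(mtdna_effect = 0.4, seed = 706)
  fc <- h2o2_fold_changes(ds)
  expect_equal(unname(fc$mean[["mtdna_fc"]]), 0.4, tolerance = 0.08)
  expect_true(all(fc$per_line$mtdna_fc < 1))
})
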