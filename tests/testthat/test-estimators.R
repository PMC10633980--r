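test_that("Wald ratio follows the delta-method formulas", {
  h <- manual_harmonized(0.1, 0.02, 0.05, 0.01)
  est <- mr_wald(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$nsnp, 1L)

  null <- mr_wald(manual_harmonized(0.1, 0.02, 0, 0.01))
  expect_equal(null$beta, 0)
  expect_equal(null$pvalue, 1)

  expect_error(mr_wald(manual_harmonized(0, 0.02, 0.05, 0.01)),
               class = "mrflow_estimation_error")
})

test_that("first-order Wald SE matches the Monte-Carlo sampling SD", {
  h <- manual_harmonized(0.1, 0.02, 0.05, 0.01)
  est <- mr_wald(h)
  set.seed(11)
  draws <- rnorm(1e5, 0.05, 0.01) / 0.1
  expect_equal(est$se, sd(draws), tolerance = 0.02)
})

test_that("IVW equals the inverse-variance-weighted mean of Wald ratios", {
  set.seed(21)
  h <- sim_harmonized(n_snps = 10, theta = 0.1, seed = 21)
  est <- mr_ivw(h, model = "fixed")
  # independent brute-force loop over per-SNP ratios
  num <- 0; den <- 0
  for (j in seq_len(nrow(h))) {
    ratio <- h$beta_out[j] / h$beta_exp[j]
    wj <- h$beta_exp[j]^2 / h$se_out[j]^2
    num <- num + wj * ratio
    den <- den + wj
  }
  expect_equal(est$beta, num / den, tolerance = 1e-10)
  expect_equal(est$se, 1 / sqrt(den), tolerance = 1e-10)
})

test_that("degenerate heterogeneity and single-instrument consistency", {
  h <- manual_harmonized(c(0.1, 0.2), c(0.02, 0.02),
                         0.7 * c(0.1, 0.2), c(0.01, 0.01))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.7)
  expect_equal(est$q_stat, 0)

  one <- manual_harmonized(0.1, 0.02, 0.05, 0.01)
  dup <- dplyr::bind_rows(one, one)
  expect_equal(mr_ivw(dup)$beta, mr_wald(one)$beta)
  expect_error(mr_ivw(one), class = "mrflow_contract_error")
})

test_that("Egger recovers slope and intercept exactly on noiseless data", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  h <- manual_harmonized(bx, rep(0.02, 4), 0.1 * bx, rep(0.01, 4))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.1, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)

  h2 <- manual_harmonized(bx, rep(0.02, 4), 0.02 + 0.1 * bx,
                          rep(0.01, 4))
  est2 <- mr_egger(h2)
  expect_equal(est2$beta, 0.1, tolerance = 1e-12)
  expect_equal(est2$intercept, 0.02, tolerance = 1e-12)
  expect_error(mr_egger(h[1:2, ]), class = "mrflow_contract_error")
})

test_that("constant directional pleiotropy lands in the Egger intercept", {
  # pleiotropy is directional relative to the fitted orientation, so the
  # constant +0.02 is added after orienting exposure effects positive
  # (Egger's own convention); the mean recovered intercept approaches it
  ints <- vapply(1:300, function(r) {
    dat <- sim_sumstats(sim_config(n_snps = 50, theta = 0.1,
                                   seed = 300 + r))
    h <- harmonized_kept(suppressMessages(
      mr_harmonize(tibble::as_tibble(dat$exposure), dat$outcome)))
    flip <- ifelse(h$beta_exp < 0, -1, 1)
    h$beta_exp <- h$beta_exp * flip
    h$beta_out <- h$beta_out * flip + 0.02
    mr_egger(h)$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.02), 0.002)
})

test_that("weighted median interpolates the cumulative-weight midpoint", {
  h <- manual_harmonized(rep(0.1, 3), rep(0.02, 3),
                         0.1 * c(0.4, 0.5, 0.9), rep(0.01, 3))
  est <- suppressWarnings(mr_weighted_median(h, n_boot = 100, seed = 1))
  expect_equal(est$beta, 0.5)

  # ~98% of the weight on the third SNP drags the estimate to its ratio
  hw <- manual_harmonized(c(0.02, 0.02, 0.4), rep(0.02, 3),
                          c(0.02 * 0.2, 0.02 * 0.3, 0.4 * 0.7),
                          rep(0.01, 3))
  estw <- suppressWarnings(mr_weighted_median(hw, n_boot = 100, seed = 1))
  expect_equal(estw$beta, 0.7, tolerance = 5e-3)
})

test_that("weighted median resists up to half the weight being pleiotropic", {
  hits <- vapply(1:100, function(r) {
    dat <- sim_sumstats(sim_config(n_snps = 20, theta = 0.1, seed = 900 + r))
    h <- harmonized_kept(suppressMessages(
      mr_harmonize(tibble::as_tibble(dat$exposure), dat$outcome)))
    w <- h$beta_exp^2 / h$se_out^2
    # poison instruments holding ~45% of the total weight
    ord <- order(-w)
    bad <- ord[cumsum(w[ord]) / sum(w) <= 0.45]
    h$beta_out[bad] <- h$beta_out[bad] + 0.5 * h$beta_exp[bad]
    est <- mr_weighted_median(h, n_boot = 200, seed = r)
    abs(est$beta - 0.1) <= 2 * est$se
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- manual_harmonized(rep(0.1, 4), rep(0.02, 4),
                         0.1 * c(0.1, 0.1, 0.1, 0.9), rep(0.01, 4))
  est <- suppressWarnings(mr_mode(h, weighted = FALSE, n_boot = 100,
                                  seed = 1))
  # grid oracle: densest point of the equal-weight kernel density
  ratios <- c(0.1, 0.1, 0.1, 0.9)
  # mad is 0 here, so the bandwidth rule falls back to the sd
  bw <- 0.9 * sd(ratios) * 4^(-1 / 5)
  grid <- seq(-0.5, 1.5, length.out = 4001)
  dens <- vapply(grid, function(g) {
    sum(dnorm((g - ratios) / bw))
  }, numeric(1))
  expect_equal(est$beta, grid[which.max(dens)], tolerance = 0.01)
  expect_lt(abs(est$beta - 0.1), 0.05)

  # all-identical ratios collapse to the common value
  hd <- manual_harmonized(rep(0.1, 3), rep(0.02, 3), rep(0.06, 3),
                          rep(0.01, 3))
  estd <- suppressWarnings(mr_mode(hd, n_boot = 100, seed = 1))
  expect_equal(estd$beta, 0.6)
})

test_that("the battery dispatches on instrument count", {
  one <- sim_harmonized(n_snps = 1, theta = 0.1, seed = 41)
  expect_equal(mr_estimate_all(one)$method, "wald")

  two <- sim_harmonized(n_snps = 2, theta = 0.1, seed = 42)
  est2 <- mr_estimate_all(two)
  expect_equal(est2$method, "ivw")

  three <- sim_harmonized(n_snps = 3, theta = 0.1, seed = 43)
  est3 <- suppressWarnings(suppressMessages(
    mr_estimate_all(three, n_boot = 100)))
  expect_setequal(est3$method, c("ivw", "egger", "weighted_median",
                                 "simple_mode", "weighted_mode"))

  ten <- sim_harmonized(n_snps = 10, theta = 0.1, seed = 44)
  est10 <- suppressWarnings(mr_estimate_all(ten, n_boot = 100))
  expect_setequal(est10$method,
                  c("ivw", "egger", "weighted_median", "simple_mode",
                    "weighted_mode", "presso_raw", "presso_corrected"))
  expect_s3_class(attr(est10, "presso"), "mr_presso")
  expect_error(mr_estimate_all(ten[0, ]), class = "mrflow_input_error")
})

test_that("rescaling the exposure rescales every causal estimate", {
  h <- sim_harmonized(n_snps = 10, theta = 0.1, seed = 45)
  c_scale <- 2.5
  h2 <- h
  h2$beta_exp <- h$beta_exp * c_scale
  h2$se_exp <- h$se_exp * c_scale
  for (fn in list(
    function(d) mr_ivw(d)$beta,
    function(d) mr_egger(d)$beta,
    function(d) suppressWarnings(mr_weighted_median(d, n_boot = 100,
                                                    seed = 2))$beta,
    function(d) suppressWarnings(mr_mode(d, n_boot = 100, seed = 2))$beta
  )) {
    expect_equal(fn(h2), fn(h) / c_scale, tolerance = 1e-8)
  }
})
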