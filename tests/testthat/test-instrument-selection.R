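test_that("p-value and MAF filters use strict inequalities", {
  ss <- manual_sumstats(
    variant_id = c("keep", "at_threshold", "rare_major"),
    beta = c(0.1, 0.1, 0.1), se = c(0.02, 0.02, 0.02),
    pvalue = c(9e-6, 1e-5, 9e-6),
    eaf = c(0.30, 0.30, 0.995)
  )
  out <- mr_filter_instruments(ss, p_threshold = 1e-5, eaf_floor = 0.01)
  expect_equal(out$variant_id, "keep")
})

test_that("filter matches a brute-force record-by-record oracle", {
  set.seed(71)
  n <- 100
  ss <- manual_sumstats(
    variant_id = sprintf("rs%03d", 1:n),
    beta = rnorm(n, 0, 0.1), se = runif(n, 0.01, 0.05),
    pvalue = 10^runif(n, -8, 0),
    eaf = runif(n, 0, 1)
  )
  got <- mr_filter_instruments(ss, p_threshold = 1e-4, eaf_floor = 0.05)
  oracle <- ss$variant_id[
    vapply(seq_len(nrow(ss)), function(i) {
      ss$pvalue[i] < 1e-4 && min(ss$eaf[i], 1 - ss$eaf[i]) > 0.05
    }, logical(1))]
  expect_setequal(got$variant_id, oracle)
})

test_that("no-op thresholds return every record with a known frequency", {
  ss <- manual_sumstats(
    variant_id = c("a", "b", "c"),
    beta = c(0.1, 0.2, 0.3), se = rep(0.05, 3),
    pvalue = c(0.9, 0.5, 0.1),
    eaf = c(0.3, NA, 0.5)
  )
  out <- suppressMessages(
    mr_filter_instruments(ss, p_threshold = 1 - 1e-12, eaf_floor = 0))
  expect_setequal(out$variant_id, c("a", "c"))
})

test_that("F-statistics follow the squared z-score and flag strength", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.02), 0)
  expect_error(f_statistic(0.1, 0), class = "mrflow_input_error")
  # at the exposure GWAS regime (true effect 0.15, n = 7,738) nearly all
  # observed instruments clear the F > 19 strength bar
  set.seed(5)
  maf <- runif(1000, 0.05, 0.5)
  se <- 1 / sqrt(2 * maf * (1 - maf) * 7738)
  beta_obs <- rnorm(1000, 0.15, se)
  expect_gte(mean(f_statistic(beta_obs, se) > 19), 0.95)
})

test_that("clumping keeps the stronger of two linked variants", {
  cand <- manual_sumstats(
    variant_id = c("lead", "tag"),
    beta = c(0.2, 0.15), se = c(0.02, 0.02),
    pvalue = c(1e-8, 1e-6),
    position = c(1e6, 1e6 + 5e3)
  )
  ld <- ld_matrix(matrix(c(1, 0.8, 0.8, 1), 2), c("lead", "tag"))
  kept <- mr_clump(cand, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_equal(kept$variant_id, "lead")
  log <- clump_log(kept)
  expect_equal(log$leader[log$variant_id == "tag"], "lead")
})

test_that("variants outside the clump window survive despite LD", {
  cand <- manual_sumstats(
    variant_id = c("far1", "far2"),
    beta = c(0.2, 0.15), se = c(0.02, 0.02),
    pvalue = c(1e-8, 1e-6),
    position = c(1e6, 1e6 + 15000 * 1e3)  # 15,000 kb apart
  )
  ld <- ld_matrix(matrix(c(1, 0.8, 0.8, 1), 2), c("far1", "far2"))
  kept <- mr_clump(cand, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_setequal(kept$variant_id, c("far1", "far2"))
})

# Independent reimplementation of greedy p-rank clumping used as oracle.
brute_clump <- function(cand, r2m, r2_threshold, window_kb) {
  remaining <- cand$variant_id[order(cand$pvalue, cand$variant_id)]
  kept <- character(0)
  while (length(remaining) > 0) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    li <- match(lead, cand$variant_id)
    remaining <- remaining[-1]
    drop <- vapply(remaining, function(v) {
      vi <- match(v, cand$variant_id)
      cand$chromosome[vi] == cand$chromosome[li] &&
        abs(cand$position[vi] - cand$position[li]) <= window_kb * 1000 &&
        r2m[lead, v] >= r2_threshold
    }, logical(1))
    remaining <- remaining[!drop]
  }
  kept
}

test_that("greedy clumping matches a brute-force oracle on LD blocks", {
  set.seed(42)
  n <- 20
  block <- rep(1:3, length.out = n)
  cand <- manual_sumstats(
    variant_id = sprintf("v%02d", 1:n),
    beta = rnorm(n, 0, 0.1), se = rep(0.02, n),
    pvalue = 10^runif(n, -10, -4),
    chromosome = as.character(block),
    position = 1e6 + (seq_len(n) %/% 3) * 1e5
  )
  r2m <- matrix(0, n, n, dimnames = list(cand$variant_id, cand$variant_id))
  for (b in 1:3) {
    idx <- which(block == b)
    r2m[idx, idx] <- runif(1, 0.3, 0.9)
  }
  diag(r2m) <- 1
  ld <- ld_matrix(r2m, cand$variant_id)
  kept <- mr_clump(cand, ld, r2_threshold = 0.1, window_kb = 10000)
  expect_setequal(kept$variant_id,
                  brute_clump(cand, r2m, 0.1, 10000))
  # no kept pair may violate the (chromosome, window, r2) rule
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(nrow(kept))) {
      if (i >= j) next
      violation <- kept$chromosome[i] == kept$chromosome[j] &&
        abs(kept$position[i] - kept$position[j]) <= 1e7 &&
        r2m[kept$variant_id[i], kept$variant_id[j]] >= 0.1
      expect_false(violation)
    }
  }
  # idempotence: clumping the kept set changes nothing
  again <- mr_clump(kept, ld, r2_threshold = 0.1, window_kb = 10000)
  expect_equal(again$variant_id, kept$variant_id)
})

test_that("candidates without LD entry or position are an error", {
  cand <- manual_sumstats(
    variant_id = c("a", "b"), beta = c(0.1, 0.2), se = c(0.02, 0.02),
    pvalue = c(1e-6, 1e-7)
  )
  cand$position <- NA_integer_
  expect_error(mr_clump(cand, NULL), "a, b",
               class = "mrflow_input_error")
})

test_that("proxy search picks the best qualifying substitute", {
  missing <- manual_sumstats("inst", beta = 0.1, se = 0.02, pvalue = 1e-6)
  outcome <- manual_sumstats(c("p1", "p2"), beta = c(0.05, 0.06),
                             se = c(0.01, 0.01), pvalue = c(0.1, 0.1))
  r2m <- matrix(c(1, 0.9, 0.85, 0.9, 1, 0.5, 0.85, 0.5, 1), 3,
                dimnames = list(c("inst", "p1", "p2"),
                                c("inst", "p1", "p2")))
  ld <- ld_matrix(r2m, c("inst", "p1", "p2"))
  map <- mr_find_proxies(missing, outcome, ld, r2_min = 0.8)
  expect_equal(map$proxy_id, "p1")
  expect_equal(map$r2, 0.9)
  # below the r2 bar nothing qualifies
  expect_warning(
    none <- mr_find_proxies(missing, outcome, ld, r2_min = 0.95),
    "no proxy")
  expect_equal(nrow(none), 0)
})

test_that("proxy mapping equals an exhaustive per-instrument argmax scan", {
  set.seed(9)
  n_inst <- 10; n_out <- 15
  inst_ids <- sprintf("i%02d", 1:n_inst)
  out_ids <- sprintf("o%02d", 1:n_out)
  ids <- c(inst_ids, out_ids)
  r2m <- matrix(runif(length(ids)^2, 0, 1), length(ids),
                dimnames = list(ids, ids))
  r2m <- (r2m + t(r2m)) / 2; diag(r2m) <- 1
  ld <- ld_matrix(r2m, ids)
  missing <- manual_sumstats(inst_ids, beta = rnorm(n_inst, 0, 0.1),
                             se = rep(0.02, n_inst),
                             pvalue = rep(1e-6, n_inst))
  outcome <- manual_sumstats(out_ids, beta = rnorm(n_out, 0, 0.05),
                             se = rep(0.01, n_out),
                             pvalue = rep(0.5, n_out))
  map <- suppressWarnings(mr_find_proxies(missing, outcome, ld,
                                          r2_min = 0.8))
  for (id in inst_ids) {
    r2s <- r2m[id, out_ids]
    best <- out_ids[order(-r2s, out_ids)][1]
    if (max(r2s) >= 0.8) {
      expect_equal(map$proxy_id[map$variant_id == id], best)
    } else {
      expect_false(id %in% map$variant_id)
    }
  }
})
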