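test_that("bh_fdr matches brute force, p.adjust, and the worked example", {
  # brute-force step-up oracle over all ranks
  brute_bh <- function(p, m) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    for (i in seq_len(n)) {
      q[o[i]] <- min(1, min(vapply(i:n, function(j) {
        m * p[o[j]] / j
      }, numeric(1))))
    }
    q
  }
  set.seed(55)
  p <- runif(40)
  expect_equal(bh_fdr(p, m = 60), brute_bh(p, 60), tolerance = 1e-12)
  expect_equal(bh_fdr(p), unname(stats::p.adjust(p, "BH")),
               tolerance = 1e-12)

  # p = 1e-4 at rank 1 of m = 207 tests
  q <- bh_fdr(c(1e-4, 0.5, 0.9), m = 207)
  expect_equal(q[1], 207 * 1e-4, tolerance = 1e-12)

  # ties: all q equal m * p / n_obs
  expect_equal(bh_fdr(rep(0.01, 4), m = 10), rep(10 * 0.01 / 4, 4))

  # monotone in sorted order and permutation-equivariant
  q_sorted <- bh_fdr(sort(p), m = 60)
  expect_true(all(diff(q_sorted) >= -1e-15))
  perm <- sample(40)
  expect_equal(bh_fdr(p[perm], m = 60), brute_bh(p, 60)[perm])

  expect_error(bh_fdr(p, m = 10), class = "mrflow_config_error")
  expect_equal(bh_fdr(c(0.1, NA, 0.2), m = 3)[2], NA_real_)
})

test_that("a single-exposure screen reduces to the direct estimate", {
  dat <- sim_sumstats(sim_config(n_snps = 10, theta = 0.1, seed = 201))
  s <- mr_screen(dat$exposure, dat$outcome, methods = "primary")
  inst <- suppressMessages(mr_filter_instruments(dat$exposure))
  h <- harmonized_kept(suppressMessages(mr_harmonize(inst, dat$outcome)))
  direct <- if (nrow(h) >= 2) mr_ivw(h) else mr_wald(h)
  expect_equal(s$beta, direct$beta)
  expect_equal(s$fdr_q, s$pvalue)  # m = 1
  expect_equal(s$method, direct$method)
})

test_that("exposures without instruments still count toward the correction", {
  strong <- sim_sumstats(sim_config(n_snps = 10, theta = 0.2, seed = 202))
  weak <- strong$exposure
  weak$pvalue <- rep(0.5, nrow(weak))  # nothing passes the filter
  attr(weak, "trait_id") <- "no_inst"
  s <- mr_screen(list(strong$exposure, weak), strong$outcome,
                 methods = "primary")
  expect_equal(s$status[2], "no_instruments")
  expect_equal(s$nsnp[2], 0L)
  expect_true(is.na(s$fdr_q[2]))
  expect_equal(attr(s, "m"), 2)
  # the observed p is adjusted with m = 2 despite one failed exposure
  expect_equal(s$fdr_q[1], min(1, s$pvalue[1] * 2))
})

test_that("proxy substitution rescues instruments absent from the outcome", {
  dat <- sim_sumstats(sim_config(n_snps = 6, theta = 0.1, seed = 203))
  expo <- tibble::as_tibble(dat$exposure)
  expo$pvalue <- 1e-8  # all six are unambiguous instruments
  out <- tibble::as_tibble(dat$outcome)
  # rs00001 vanishes from the outcome GWAS; rs00099 is its perfect proxy,
  # present in both GWAS
  proxy_exp <- expo[1, ]
  proxy_exp$variant_id <- "rs00099"
  proxy_exp$pvalue <- 0.5  # the proxy itself is not an instrument
  proxy_out <- out[1, ]
  proxy_out$variant_id <- "rs00099"
  expo2 <- as_sumstats(dplyr::bind_rows(expo, proxy_exp), "taxon")
  out2 <- as_sumstats(dplyr::bind_rows(out[-1, ], proxy_out), "af",
                      "binary")
  ids <- c(expo2$variant_id)
  r2m <- diag(length(ids)); dimnames(r2m) <- list(ids, ids)
  r2m["rs00001", "rs00099"] <- r2m["rs00099", "rs00001"] <- 0.95
  ld <- ld_matrix(r2m, ids)
  s <- mr_screen(expo2, out2, ld = ld, methods = "primary",
                 clump_r2 = 0.999)
  expect_equal(s$status, "ok")
  expect_equal(s$nsnp, 6L)  # 5 direct + 1 via proxy
  s_no_ld <- mr_screen(expo2, out2, methods = "primary")
  expect_equal(s_no_ld$nsnp, 5L)  # without LD data the instrument drops
})

test_that("reverse MR with one instrument dispatches to the Wald ratio", {
  dat <- sim_sumstats(sim_config(n_snps = 1, theta = 0, gamma_sd = 0.3,
                                 seed = 204))
  r <- mr_reverse(dat$exposure, dat$outcome, p_threshold = 1e-4)
  expect_equal(r$method, "wald")
})

test_that("reverse estimates are null when causation is forward-only", {
  hits <- vapply(1:20, function(r) {
    cfg <- sim_config(n_snps = 50, theta = 0, gamma_sd = 0.02,
                      n_exp = 1030836, n_out = 7738, seed = 400 + r)
    dat <- sim_sumstats(cfg)
    rev <- mr_reverse(dat$exposure, dat$outcome, p_threshold = 5e-8,
                      methods = "primary")
    is.na(rev$beta) || abs(rev$beta) <= 2 * rev$se
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("overlap bias follows the first-order approximation", {
  none <- assess_overlap_bias(f_bar = 19, overlap_fraction = 0,
                              confounded_assoc = 0.2)
  expect_equal(none$expected_bias, 0)
  expect_equal(none$type1_error, 0.05, tolerance = 1e-10)

  some <- assess_overlap_bias(f_bar = 19, overlap_fraction = 0.383,
                              confounded_assoc = 0.2)
  expect_equal(some$expected_bias, 0.383 * 0.2 / 19, tolerance = 1e-12)
  expect_gt(some$type1_error, 0.05)

  more <- assess_overlap_bias(f_bar = 19, overlap_fraction = 0.8,
                              confounded_assoc = 0.2)
  expect_gt(more$type1_error, some$type1_error)
})

test_that("a full synthetic study is reproducible and stage-toggleable", {
  cfg <- study_config(
    n_taxa = 6,
    signal_taxa = list(list(id = "taxon_A", theta = log(1.4),
                            n_snps = 10)),
    sim = sim_config(cohort_n = 3000, seed = 99),
    n_boot = 200, methods = "primary", seed = 99
  )
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res1 <- suppressWarnings(suppressMessages(mr_run_study(cfg, dir1)))
  res2 <- suppressWarnings(suppressMessages(mr_run_study(cfg, dir2)))
  expect_identical(readLines(file.path(dir1, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))
  expect_true(file.exists(file.path(dir1, "screen_results.tsv")))
  expect_equal(res1$screen$beta, res2$screen$beta)

  cfg_off <- cfg
  cfg_off$run_cohort <- FALSE
  dir3 <- withr::local_tempdir()
  res3 <- suppressWarnings(suppressMessages(mr_run_study(cfg_off, dir3)))
  expect_false(file.exists(file.path(dir3, "grs_associations.tsv")))
  expect_equal(res3$manifest$stages$grs, "disabled")
})

test_that("file-mode studies run from delimited inputs on disk", {
  dat <- sim_sumstats(sim_config(n_snps = 8, theta = 0.3, seed = 301))
  dir <- withr::local_tempdir()
  expof <- file.path(dir, "taxon.tsv")
  outf <- file.path(dir, "af.tsv")
  readr::write_tsv(
    dplyr::rename(tibble::as_tibble(dat$exposure),
                  base_pair_location = position,
                  effect_allele_frequency = eaf,
                  standard_error = se, p_value = pvalue), expof)
  readr::write_tsv(
    dplyr::rename(tibble::as_tibble(dat$outcome),
                  base_pair_location = position,
                  effect_allele_frequency = eaf,
                  standard_error = se, p_value = pvalue), outf)
  cfg <- study_config(simulate = FALSE,
                      exposure_files = c(taxon = expof),
                      outcome_file = outf,
                      methods = "primary",
                      run_reverse = FALSE, run_mediation = FALSE,
                      run_cohort = FALSE, seed = 3)
  res <- suppressMessages(mr_run_study(cfg, file.path(dir, "out")))
  expect_equal(res$screen$status, "ok")
  expect_true(file.exists(file.path(dir, "out", "screen_results.tsv")))
})
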