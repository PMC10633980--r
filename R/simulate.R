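#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators with defaults
#' fixed to the study conditions the pipeline is designed for: a
#' shotgun-metagenomics exposure GWAS of 7,738 individuals (the scale at
#' which microbial-taxon instruments reach only suggestive significance),
#' a disease outcome meta-GWAS of ~1.03 million (60,620 cases), per-SNP
#' exposure effects of SD 0.15 (the regime in which every instrument's
#' F-statistic comfortably exceeds 19), a mediation triangle with
#' `beta1 = 0.05`, `beta2 = 0.336`, `delta = 0.123` (true proportion
#' mediated 12.0%), and a cohort stage with a true hazard ratio of 1.14
#' per score unit, ~0.5%/year baseline hazard and exponential censoring
#' yielding ~5-6% incident events over ~11.5 years of mean follow-up.
#'
#' @param n_snps Instruments for the (taxon) exposure.
#' @param n_exp,n_out,n_med GWAS sample sizes: exposure, outcome, mediator.
#' @param theta True causal effect of exposure on outcome (log-odds).
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd,pleiotropy_mean Distribution of the direct
#'   (pleiotropic) effects `alpha_j` on the outcome.
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param gamma_sd SD of true per-SNP exposure effects.
#' @param gamma_sd_mediator SD of true per-SNP mediator effects.
#' @param n_snps_mediator Instruments for the mediator.
#' @param beta1,beta2,delta Mediation triangle: taxon -> mediator effect,
#'   mediator -> outcome effect, and direct (unmediated) taxon -> outcome
#'   effect; the total effect is `delta + beta1 * beta2`.
#' @param cohort_n Cohort size for the survival stage.
#' @param hr_per_unit True hazard ratio per unit of weighted GRS.
#' @param baseline_hazard Baseline event hazard (per year).
#' @param censor_rate Hazard of loss to follow-up (per year).
#' @param death_rate Hazard of competing death (per year; coded
#'   `event = 2`, censoring in the primary fit).
#' @param prevalent_frac Fraction flagged prevalent at recruitment.
#' @param ld_blocks,block_size,block_r2 Optional block-LD mode: number of
#'   LD blocks among the candidates, variants per block, and within-block
#'   r-squared (`ld_blocks = 0` simulates LD-independent, post-clumping
#'   instruments).
#' @param seed Mandatory RNG seed; all generators are pure functions of
#'   the configuration including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 10,
                       n_exp = 7738,
                       n_out = 1030836,
                       n_med = 450000,
                       theta = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.003,
                       pleiotropy_mean = 0.002,
                       maf_range = c(0.05, 0.5),
                       gamma_sd = 0.15,
                       gamma_sd_mediator = 0.02,
                       n_snps_mediator = 50,
                       beta1 = 0.05, beta2 = 0.336, delta = 0.123,
                       cohort_n = 50000,
                       hr_per_unit = 1.14,
                       baseline_hazard = 0.005,
                       censor_rate = 0.078,
                       death_rate = 0.004,
                       prevalent_frac = 0.02,
                       ld_blocks = 0, block_size = 5, block_r2 = 0.8,
                       seed) {
  if (missing(seed)) {
    abort("sim_config: a seed is mandatory", class = "mrflow_config_error")
  }
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(
    n_snps >= 1, n_exp > 0, n_out > 0, n_med > 0,
    pleiotropy_sd >= 0, gamma_sd > 0, gamma_sd_mediator > 0,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    cohort_n > 0, hr_per_unit > 0, baseline_hazard > 0,
    censor_rate >= 0, death_rate >= 0,
    prevalent_frac >= 0, prevalent_frac < 1,
    ld_blocks >= 0, block_size >= 2, block_r2 >= 0, block_r2 <= 1
  )
  structure(as.list(environment()), class = "sim_config")
}

# GWAS standard error of a per-allele effect at frequency maf and size n
.gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

.non_palindromic_pairs <- matrix(
  c("A", "G", "A", "C", "T", "G", "T", "C",
    "G", "A", "C", "A", "G", "T", "C", "T"),
  ncol = 2, byrow = TRUE
)

.sim_variants <- function(n_snps, maf_range, prefix = "rs") {
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  pair <- .non_palindromic_pairs[
    sample.int(nrow(.non_palindromic_pairs), n_snps, replace = TRUE), ,
    drop = FALSE]
  idx <- seq_len(n_snps)
  tibble::tibble(
    variant_id = sprintf("%s%05d", prefix, idx),
    chromosome = as.character(rep_len(1:22, n_snps)),
    # successive SNPs on one chromosome sit > 10 Mb apart (outside any
    # realistic clump window); stays well inside 32-bit integer range
    position = as.integer(1e6 + ((idx - 1L) %/% 22L) * 2e7),
    effect_allele = pair[, 1],
    other_allele = pair[, 2],
    eaf = maf
  )
}

.assoc_stats <- function(variants, true_beta, n) {
  se <- .gwas_se(variants$eaf, n)
  beta <- rnorm(nrow(variants), true_beta, se)
  dplyr::mutate(variants,
                beta = beta, se = se,
                pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
                n = n)
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Per SNP `j`: a minor-allele frequency from `maf_range`; a true exposure
#' effect `gamma_j ~ N(0, gamma_sd^2)`; the observed exposure effect drawn
#' around `gamma_j` with the analytic GWAS standard error
#' `1/sqrt(2 maf (1-maf) n_exp)`; a pleiotropic effect `alpha_j` (zero,
#' balanced `N(0, sd^2)`, or directional `N(mean, sd^2)`); the true
#' outcome effect `Gamma_j = theta * gamma_j + alpha_j`; and the observed
#' outcome effect drawn analogously with `n_out`. P-values are two-sided
#' normal. With `ld_blocks > 0` the candidates come in LD blocks (shared
#' true effect within a block, within-block r-squared `block_r2`) and the
#' matching [ld_matrix()] is returned to exercise clumping.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` (`mr_sumstats` tibbles),
#'   `truth` (per-SNP `gamma`, `alpha`, plus `theta`), and `ld` (an
#'   [ld_matrix()], or `NULL` when `ld_blocks = 0`).
#' @export
sim_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    if (config$ld_blocks > 0) {
      n_total <- config$ld_blocks * config$block_size
      variants <- .sim_variants(n_total, config$maf_range)
      block <- rep(seq_len(config$ld_blocks), each = config$block_size)
      # co-locate blocks so they fall inside the clump window
      variants$chromosome <- as.character(rep_len(1:22, config$ld_blocks))[block]
      variants$position <- as.integer(1e6 + block * 3e6 +
                                        (seq_len(n_total) %% config$block_size) * 1e4)
      gamma_block <- rnorm(config$ld_blocks, 0, config$gamma_sd)
      gamma <- gamma_block[block]
      r2 <- matrix(0, n_total, n_total)
      for (b in seq_len(config$ld_blocks)) {
        idx <- which(block == b)
        r2[idx, idx] <- config$block_r2
      }
      diag(r2) <- 1
      ld <- ld_matrix(r2, variants$variant_id,
                      positions = variants[, c("variant_id", "chromosome",
                                               "position")])
    } else {
      variants <- .sim_variants(config$n_snps, config$maf_range)
      gamma <- rnorm(config$n_snps, 0, config$gamma_sd)
      ld <- NULL
    }
    alpha <- switch(config$pleiotropy_mode,
      none = rep(0, length(gamma)),
      balanced = rnorm(length(gamma), 0, config$pleiotropy_sd),
      directional = rnorm(length(gamma), config$pleiotropy_mean,
                          config$pleiotropy_sd)
    )
    exposure <- .assoc_stats(variants, gamma, config$n_exp)
    outcome <- .assoc_stats(variants, config$theta * gamma + alpha,
                            config$n_out)
    list(
      exposure = as_sumstats(exposure, trait_id = "exposure",
                             trait_type = "continuous"),
      outcome = as_sumstats(outcome, trait_id = "outcome",
                            trait_type = "binary"),
      truth = tibble::tibble(variant_id = variants$variant_id,
                             gamma = gamma, alpha = alpha,
                             theta = config$theta),
      ld = ld
    )
  })
}

#' Simulate a mediation triangle with known ground truth
#'
#' Generates the three summary-statistic pairs of a taxon -> mediator ->
#' outcome triangle: taxon instruments with effects `beta1 * gamma_j` on
#' the mediator and `beta3 * gamma_j` on the outcome (where
#' `beta3 = delta + beta1 * beta2` is the total effect), and a disjoint
#' set of mediator instruments with effects `beta2 * eta_k` on the
#' outcome. The observed taxon-exposure effects are shared between the
#' taxon-mediator and taxon-outcome pairs, as when both fits reuse the
#' same exposure GWAS.
#'
#' @param config A [sim_config()]; uses `beta1`, `beta2`, `delta`,
#'   `n_snps`, `n_snps_mediator`, the sample sizes and `gamma_sd`s.
#' @return List of pairs `taxon_mediator`, `mediator_outcome`,
#'   `taxon_outcome` (each `list(exposure, outcome)`), and `truth`
#'   (`beta1`, `beta2`, `beta3`, `delta`, `proportion`).
#' @export
sim_triangle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  beta3 <- config$delta + config$beta1 * config$beta2
  withr::with_seed(config$seed, {
    tax <- .sim_variants(config$n_snps, config$maf_range, prefix = "rst")
    med <- .sim_variants(config$n_snps_mediator, config$maf_range,
                         prefix = "rsm")
    gamma <- rnorm(config$n_snps, 0, config$gamma_sd)
    eta <- rnorm(config$n_snps_mediator, 0, config$gamma_sd_mediator)

    tax_exp <- .assoc_stats(tax, gamma, config$n_exp)
    tax_on_med <- .assoc_stats(tax, config$beta1 * gamma, config$n_med)
    tax_on_out <- .assoc_stats(tax, beta3 * gamma, config$n_out)
    med_exp <- .assoc_stats(med, eta, config$n_med)
    med_on_out <- .assoc_stats(med, config$beta2 * eta, config$n_out)

    list(
      taxon_mediator = list(
        exposure = as_sumstats(tax_exp, "taxon", "continuous"),
        outcome = as_sumstats(tax_on_med, "mediator", "continuous")
      ),
      mediator_outcome = list(
        exposure = as_sumstats(med_exp, "mediator", "continuous"),
        outcome = as_sumstats(med_on_out, "outcome", "binary")
      ),
      taxon_outcome = list(
        exposure = as_sumstats(tax_exp, "taxon", "continuous"),
        outcome = as_sumstats(tax_on_out, "outcome", "binary")
      ),
      truth = list(beta1 = config$beta1, beta2 = config$beta2,
                   beta3 = beta3, delta = config$delta,
                   proportion = config$beta1 * config$beta2 / beta3)
    )
  })
}

#' Simulate an individual-level cohort for the GRS stage
#'
#' Dosages are Binomial(2, maf) per variant; the linear predictor is
#' `log(hr_per_unit) * wt-GRS` plus modest covariate effects (age, sex,
#' four genetic PCs, genotyping batch and assessment centre); incident
#' event times are exponential with that hazard; loss to follow-up and
#' competing death are independent exponentials (`censor_rate`,
#' `death_rate`); a `prevalent_frac` fraction is flagged prevalent.
#'
#' @param config A [sim_config()].
#' @param weights Named numeric vector of per-variant score weights
#'   (typically the exposure-GWAS instrument betas), or a tibble with
#'   `variant_id` and `beta`/`weight` columns.
#' @return A [cohort_table()]; the realized per-individual score and true
#'   log hazard ratio are attached as attributes `"score"` and
#'   `"true_log_hr"`.
#' @export
sim_cohort <- function(config, weights) {
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(weights)) {
    wcol <- if ("weight" %in% names(weights)) "weight" else "beta"
    weights <- setNames(weights[[wcol]], weights$variant_id)
  }
  if (length(weights) == 0) {
    abort("sim_cohort: weights must be non-empty",
          class = "mrflow_config_error")
  }
  n <- config$cohort_n
  J <- length(weights)
  withr::with_seed(config$seed + 1L, {
    maf <- runif(J, config$maf_range[1], config$maf_range[2])
    dosages <- matrix(rbinom(n * J, 2, rep(maf, each = n)), n, J,
                      dimnames = list(NULL, names(weights)))
    score <- as.vector(dosages %*% weights)
    age <- rnorm(n, 56.7, 8)
    sex <- rbinom(n, 1, 0.46)
    pcs <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("pc", 1:4)))
    batch <- sample.int(3, n, replace = TRUE)
    center <- sample.int(5, n, replace = TRUE)
    lp <- log(config$hr_per_unit) * score +
      0.06 * (age - 56.7) + 0.4 * sex +
      pcs %*% rep(0.03, 4) +
      0.05 * (batch - 2) + 0.04 * (center - 3)
    lp <- as.vector(lp)
    t_event <- rexp(n, config$baseline_hazard * exp(lp))
    t_loss <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
      rep(Inf, n)
    t_death <- if (config$death_rate > 0) rexp(n, config$death_rate) else
      rep(Inf, n)
    exit <- pmin(t_event, t_loss, t_death)
    event <- dplyr::case_when(
      t_event <= t_loss & t_event <= t_death ~ 1L,
      t_death < t_event & t_death <= t_loss ~ 2L,
      .default = 0L
    )
    if (all(event != 1)) {
      # degenerate censoring regime: no incident events to analyse
      warn("sim_cohort: no incident events generated")
    }
    prevalent <- runif(n) < config$prevalent_frac
    cohort <- cohort_table(
      tibble::tibble(
        id = sprintf("id%06d", seq_len(n)),
        age = age, sex = sex,
        pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4],
        batch = batch, center = center,
        entry_time = 0, exit_time = exit,
        event = event, prevalent = prevalent
      ),
      dosages
    )
    attr(cohort, "score") <- score
    attr(cohort, "true_log_hr") <- log(config$hr_per_unit)
    cohort
  })
}
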