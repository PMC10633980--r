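Z95 <- qnorm(0.975)

# Common one-row estimate tibble. CIs are Wald-type beta +/- 1.96 se;
# exponentiated columns are the odds-ratio view for binary outcomes.
.est_row <- function(method, nsnp, beta, se, pvalue,
                     q_stat = NA_real_, q_df = NA_real_,
                     q_pvalue = NA_real_,
                     intercept = NA_real_, intercept_se = NA_real_,
                     intercept_p = NA_real_) {
  ci_low <- beta - Z95 * se
  ci_high <- beta + Z95 * se
  tibble::tibble(
    method = method, nsnp = as.integer(nsnp),
    beta = beta, se = se, pvalue = pvalue,
    ci_low = ci_low, ci_high = ci_high,
    or_ = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
    q_stat = q_stat, q_df = q_df, q_pvalue = q_pvalue,
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p
  )
}

.kept <- function(dat) {
  if ("keep" %in% names(dat)) dat <- dat[dat$keep, ]
  tibble::as_tibble(dat)
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect as `beta_out / beta_exp`, with the first-order
#' delta-method standard error `se_out / |beta_exp|` (which ignores the
#' exposure-side uncertainty, matching the weighting used by the IVW
#' regression). The second-order expansion adding the
#' `beta_out^2 se_exp^2 / beta_exp^4` term is available by flag.
#'
#' @param dat One-row harmonized instrument table (columns `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`; a `keep` column is honoured).
#' @param second_order Use the second-order delta-method SE?
#' @return One-row estimate tibble (`method = "wald"`).
#' @export
mr_wald <- function(dat, second_order = FALSE) {
  dat <- .kept(dat)
  if (nrow(dat) != 1) {
    abort("mr_wald takes exactly one instrument; use mr_ivw for several",
          class = "mrflow_contract_error")
  }
  bx <- dat$beta_exp; by <- dat$beta_out
  if (bx == 0) {
    abort("Wald ratio undefined: exposure beta is zero",
          class = "mrflow_estimation_error")
  }
  beta <- by / bx
  se <- if (second_order) {
    sqrt(dat$se_out^2 / bx^2 + by^2 * dat$se_exp^2 / bx^4)
  } else {
    dat$se_out / abs(bx)
  }
  .est_row("wald", 1L, beta, se, 2 * pnorm(-abs(beta / se)))
}

.q_statistic <- function(bx, by, w, slope) {
  sum(w * (by - slope * bx)^2)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin, weights `1/se_out^2`; algebraically the
#' inverse-variance-weighted mean of per-SNP Wald ratios. The default
#' multiplicative random-effects model inflates the fixed-effect SE by
#' `max(1, sqrt(Q/(J-1)))` so heterogeneity widens but never narrows the
#' interval. Cochran's Q (df `J - 1`) is returned alongside.
#'
#' @param dat Harmonized instrument table with at least 2 kept rows.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return One-row estimate tibble (`method = "ivw"`) carrying `q_stat`,
#'   `q_df`, `q_pvalue`.
#' @export
mr_ivw <- function(dat, model = c("random", "fixed")) {
  model <- match.arg(model)
  dat <- .kept(dat)
  if (nrow(dat) < 2) {
    abort("mr_ivw needs at least 2 instruments; use mr_wald for one",
          class = "mrflow_contract_error")
  }
  bx <- dat$beta_exp; by <- dat$beta_out
  w <- 1 / dat$se_out^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- .q_statistic(bx, by, w, beta)
  df <- nrow(dat) - 1L
  se <- if (model == "random") se_fixed * max(1, sqrt(q / df)) else se_fixed
  out <- .est_row("ivw", nrow(dat), beta, se, 2 * pnorm(-abs(beta / se)),
                  q_stat = q, q_df = df,
                  q_pvalue = pchisq(q, df, lower.tail = FALSE))
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights `1/se_out^2`, after orienting every instrument's
#' exposure effect non-negative (both betas of an instrument are
#' sign-flipped together, which leaves the slope and the causal
#' interpretation unchanged). The slope is the causal estimate under the
#' InSIDE assumption; a non-zero intercept indicates directional
#' pleiotropy. SEs use the residual scale floored at 1 (at least
#' fixed-effect precision), with t-distribution p-values on `J - 2`
#' degrees of freedom; Q is the weighted residual sum of squares
#' (df `J - 2`).
#'
#' @param dat Harmonized instrument table with at least 3 kept rows.
#' @return One-row estimate tibble (`method = "egger"`) carrying the
#'   intercept test in `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(dat) {
  dat <- .kept(dat)
  J <- nrow(dat)
  if (J < 3) {
    abort("mr_egger needs at least 3 instruments",
          class = "mrflow_contract_error")
  }
  flip <- sign(dat$beta_exp)
  flip[flip == 0] <- 1
  bx <- dat$beta_exp * flip
  by <- dat$beta_out * flip
  w <- 1 / dat$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  coefs <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  scale <- 1 / min(sigma, 1)  # floor the residual scale at 1
  slope <- coefs["bx", "Estimate"]
  slope_se <- coefs["bx", "Std. Error"] * scale
  inter <- coefs["(Intercept)", "Estimate"]
  inter_se <- coefs["(Intercept)", "Std. Error"] * scale
  q <- sum(w * stats::residuals(fit)^2)
  df <- J - 2L
  .est_row("egger", J, slope, slope_se,
           2 * pt(-abs(slope / slope_se), df),
           q_stat = q, q_df = df,
           q_pvalue = pchisq(q, df, lower.tail = FALSE),
           intercept = inter, intercept_se = inter_se,
           intercept_p = 2 * pt(-abs(inter / inter_se), df))
}

# Weighted median of values x with weights w, cumulative-weight
# convention p_j = (S_j - w_j/2) / S_J, linear interpolation to 0.5.
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  k <- max(which(p < 0.5))
  x[k] + (x[k + 1] - x[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

.boot_draws <- function(dat, n_boot) {
  J <- nrow(dat)
  list(
    bx = matrix(rnorm(n_boot * J, mean = rep(dat$beta_exp, each = n_boot),
                      sd = rep(dat$se_exp, each = n_boot)), n_boot, J),
    by = matrix(rnorm(n_boot * J, mean = rep(dat$beta_out, each = n_boot),
                      sd = rep(dat$se_out, each = n_boot)), n_boot, J)
  )
}

#' Weighted-median estimate
#'
#' Consistent when instruments carrying at least half of the total weight
#' are valid. Per-SNP Wald ratios are sorted and the estimate is the value
#' at cumulative weight one half (weights `beta_exp^2 / se_out^2`, linear
#' interpolation between straddling order statistics). The SE comes from a
#' parametric bootstrap: exposure and outcome effects are redrawn from
#' their sampling distributions and the weighted median recomputed.
#'
#' @param dat Harmonized instrument table with at least 3 kept rows.
#' @param n_boot Bootstrap draws for the SE (default 1000; fewer than 100
#'   draws a configuration warning).
#' @param seed RNG seed for the bootstrap.
#' @return One-row estimate tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = 1) {
  dat <- .kept(dat)
  if (nrow(dat) < 3) {
    abort("mr_weighted_median needs at least 3 instruments",
          class = "mrflow_contract_error")
  }
  if (n_boot < 100) {
    warn("mr_weighted_median: n_boot < 100 gives unreliable SEs")
  }
  beta <- .weighted_median(dat$beta_out / dat$beta_exp,
                           dat$beta_exp^2 / dat$se_out^2)
  draws <- withr::with_seed(seed, .boot_draws(dat, n_boot))
  boot <- vapply(seq_len(n_boot), function(s) {
    bx <- draws$bx[s, ]; by <- draws$by[s, ]
    .weighted_median(by / bx, bx^2 / dat$se_out^2)
  }, numeric(1))
  se <- sd(boot)
  .est_row("weighted_median", nrow(dat), beta, se,
           2 * pnorm(-abs(beta / se)))
}

# Mode of per-SNP ratios via a weighted gaussian kernel density.
# Bandwidth: modified Silverman rule 0.9 * min(sd, mad) * J^(-1/5),
# scaled by bandwidth_factor.
.mode_point <- function(ratios, w, bandwidth_factor) {
  spread <- c(sd(ratios), mad(ratios))
  spread <- spread[spread > 0]
  if (length(spread) == 0) return(ratios[1])  # all ratios identical
  h <- bandwidth_factor * 0.9 * min(spread) * length(ratios)^(-1 / 5)
  d <- density(ratios, weights = w / sum(w), bw = h, n = 1024,
               kernel = "gaussian")
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The estimate is the argmax of a gaussian kernel density over the
#' per-SNP Wald ratios — consistent when the largest group of instruments
#' sharing the same ratio is valid (zero modal pleiotropy). Weights are
#' inverse-variance weights of the ratios (`1/se_ratio^2`, with
#' `se_ratio = se_out/|beta_exp|`) for the weighted mode, equal otherwise.
#' SE by parametric bootstrap as in [mr_weighted_median()]. If all ratios
#' coincide the common ratio is returned with a bootstrap SE.
#'
#' @param dat Harmonized instrument table with at least 3 kept rows.
#' @param weighted Weighted (`TRUE`) or simple (`FALSE`) mode.
#' @param bandwidth_factor Multiplier on the modified Silverman bandwidth
#'   (default 1).
#' @param n_boot,seed Bootstrap control as in [mr_weighted_median()].
#' @return One-row estimate tibble (`method = "weighted_mode"` or
#'   `"simple_mode"`).
#' @export
mr_mode <- function(dat, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  dat <- .kept(dat)
  J <- nrow(dat)
  if (J < 3) {
    abort("mr_mode needs at least 3 instruments",
          class = "mrflow_contract_error")
  }
  if (n_boot < 100) {
    warn("mr_mode: n_boot < 100 gives unreliable SEs")
  }
  weight_of <- function(bx) {
    if (weighted) (bx / dat$se_out)^2 else rep(1, J)
  }
  beta <- .mode_point(dat$beta_out / dat$beta_exp,
                      weight_of(dat$beta_exp), bandwidth_factor)
  draws <- withr::with_seed(seed, .boot_draws(dat, n_boot))
  boot <- vapply(seq_len(n_boot), function(s) {
    bx <- draws$bx[s, ]; by <- draws$by[s, ]
    .mode_point(by / bx, weight_of(bx), bandwidth_factor)
  }, numeric(1))
  se <- sd(boot)
  .est_row(if (weighted) "weighted_mode" else "simple_mode",
           J, beta, se, 2 * pnorm(-abs(beta / se)))
}

#' Run the estimator battery appropriate to the instrument count
#'
#' Dispatch follows standard two-sample MR practice for taxon screens:
#' a single instrument gives the Wald ratio only; two instruments give IVW
#' only; three or more add MR-Egger, weighted median, and the simple and
#' weighted modes; four or more additionally run MR-PRESSO (its raw and
#' outlier-corrected IVW rows carry the global-test p-value in
#' `q_pvalue`, and the full [mr_presso()] object is attached as attribute
#' `"presso"`).
#'
#' @param dat Harmonized instrument table (kept rows are used).
#' @param ivw_model IVW variant, see [mr_ivw()].
#' @param n_boot,seed Bootstrap control for median/mode estimators; the
#'   seed also drives MR-PRESSO.
#' @param presso Run MR-PRESSO when 4+ instruments are available?
#' @param n_sim Simulations for the MR-PRESSO global test.
#' @return Tibble of estimates, one row per method.
#' @export
mr_estimate_all <- function(dat, ivw_model = "random", n_boot = 1000,
                            seed = 1, presso = TRUE, n_sim = 1000) {
  dat <- .kept(dat)
  J <- nrow(dat)
  if (J == 0) {
    abort("no instruments to estimate from", class = "mrflow_input_error")
  }
  if (J == 1) return(mr_wald(dat))
  out <- mr_ivw(dat, model = ivw_model)
  if (J >= 3) {
    out <- dplyr::bind_rows(
      out,
      mr_egger(dat),
      mr_weighted_median(dat, n_boot = n_boot, seed = seed),
      mr_mode(dat, weighted = FALSE, n_boot = n_boot, seed = seed + 1L),
      mr_mode(dat, weighted = TRUE, n_boot = n_boot, seed = seed + 2L)
    )
  }
  if (J >= 4 && presso) {
    pr <- mr_presso(dat, n_sim = n_sim, seed = seed + 3L)
    out <- dplyr::bind_rows(out, tidy(pr))
    attr(out, "presso") <- pr
  } else if (presso && J == 3) {
    inform("mr_estimate_all: MR-PRESSO skipped (needs 4+ instruments)")
  }
  out
}
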