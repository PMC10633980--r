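.primary_estimate <- function(dat, ivw_model = "random") {
  dat <- .kept(dat)
  if (nrow(dat) == 1) mr_wald(dat) else mr_ivw(dat, model = ivw_model)
}

#' Two-step MR coefficients for a mediation triangle
#'
#' Estimates the three legs of the taxon -> risk factor -> outcome
#' triangle: `beta1`, the effect of the taxon on the risk factor (IVW, or
#' Wald with a single instrument); `beta2`, the effect of the risk factor
#' on the outcome; and `beta3`, the taxon's total effect on the outcome,
#' taken from an already-computed estimate so the same total effect used
#' in the screen feeds the mediation stage.
#'
#' @param taxon_mediator Harmonized table of taxon instruments against the
#'   risk-factor GWAS.
#' @param mediator_outcome Harmonized table of risk-factor instruments
#'   against the outcome GWAS.
#' @param taxon_outcome One-row estimate tibble for the taxon's total
#'   effect on the outcome (e.g. from [mr_ivw()]).
#' @return One-row tibble with `beta1`, `se1`, `p1`, `beta2`, `se2`, `p2`,
#'   `beta3`, `se3`, `p3`.
#' @export
mr_two_step <- function(taxon_mediator, mediator_outcome, taxon_outcome) {
  e1 <- .primary_estimate(taxon_mediator)
  e2 <- .primary_estimate(mediator_outcome)
  tibble::tibble(
    beta1 = e1$beta, se1 = e1$se, p1 = e1$pvalue,
    beta2 = e2$beta, se2 = e2$se, p2 = e2$pvalue,
    beta3 = taxon_outcome$beta, se3 = taxon_outcome$se,
    p3 = taxon_outcome$pvalue
  )
}

#' Multivariable MR: direct effects conditional on co-exposures
#'
#' Weighted least squares of the outcome effects on the matrix of exposure
#' effects without intercept, weights `1/se_out^2`. Each coefficient is an
#' exposure's direct effect conditional on the others. SEs use the
#' fixed-effect covariance inflated by `max(1, sqrt(Q/(J-k)))`, matching
#' the univariable IVW convention (with a single exposure column the
#' result equals [mr_ivw()] exactly).
#'
#' @param dat Data frame with one row per instrument: the outcome
#'   association columns and one effect column per exposure.
#' @param exposure_cols Character vector naming the per-exposure effect
#'   columns (at least 2 unless reducing to IVW; `J > k` required).
#' @param outcome_beta,outcome_se Names of the outcome effect/SE columns.
#' @return Tibble with one row per exposure: `exposure`, `beta`, `se`,
#'   `pvalue`, `nsnp`.
#' @export
mr_mvmr <- function(dat, exposure_cols, outcome_beta = "beta_out",
                    outcome_se = "se_out") {
  dat <- .kept(dat)
  missing_cols <- setdiff(c(exposure_cols, outcome_beta, outcome_se),
                          names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0("mr_mvmr: missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrflow_config_error")
  }
  X <- as.matrix(dat[, exposure_cols, drop = FALSE])
  y <- dat[[outcome_beta]]
  w <- 1 / dat[[outcome_se]]^2
  J <- nrow(X); k <- ncol(X)
  if (J <= k) {
    abort("mr_mvmr needs more instruments than exposures",
          class = "mrflow_input_error")
  }
  qr_x <- qr(sqrt(w) * X)
  if (qr_x$rank < k) {
    dropped <- exposure_cols[qr_x$pivot[(qr_x$rank + 1):k]]
    abort(paste0("mr_mvmr: rank-deficient design; collinear exposure(s): ",
                 paste(dropped, collapse = ", ")),
          class = "mrflow_estimation_error")
  }
  xtwx <- crossprod(X, w * X)
  beta <- solve(xtwx, crossprod(X, w * y))
  res <- y - X %*% beta
  q <- sum(w * res^2)
  scale <- max(1, sqrt(q / (J - k)))
  se <- unname(sqrt(diag(solve(xtwx))) * scale)
  beta <- as.vector(beta)
  tibble::tibble(
    exposure = exposure_cols,
    beta = beta,
    se = se,
    pvalue = 2 * pnorm(-abs(beta / se)),
    nsnp = J
  )
}

#' Mediation proportion with parametric bootstrap uncertainty
#'
#' Product-of-coefficients mediation for a taxon -> risk factor -> outcome
#' triangle: the indirect effect is `beta1 * beta2`, and the proportion
#' mediated is `beta1 * beta2 / beta3` where `beta3` is the taxon's total
#' effect on the outcome. Uncertainty comes from a parametric bootstrap
#' treating the three coefficients as independent normals (they arise from
#' non-overlapping two-sample fits): `se_prop` is the SD of the bootstrap
#' proportions, the 95% CI is the percentile interval (ratio distributions
#' are skewed, so percentile is preferred over normal-theory), and the
#' p-value is two-sided normal on `proportion / se_prop`. Draws in which
#' the total effect crosses zero are retained but flagged when they exceed
#' 1% of draws (the ratio is then unstable).
#'
#' @param beta1,se1 Taxon -> risk-factor effect and SE.
#' @param beta2,se2 Risk-factor -> outcome effect and SE.
#' @param beta3,se3 Taxon -> outcome total effect and SE (`beta3 != 0`).
#' @param n_boot Bootstrap draws (>= 1000 recommended; fewer warns).
#' @param seed RNG seed.
#' @return An object of class `mr_mediation` with fields `beta1`, `beta2`,
#'   `beta3`, `indirect`, `proportion`, `se_prop`, `ci_low`, `ci_high`,
#'   `pvalue`, `unstable_frac`, `n_boot`, `seed`. Use `tidy()` for a
#'   one-row tibble.
#' @export
mr_mediation <- function(beta1, se1, beta2, se2, beta3, se3,
                         n_boot = 2000, seed = 1) {
  if (beta3 == 0) {
    abort("mediation proportion undefined: total effect beta3 is zero",
          class = "mrflow_estimation_error")
  }
  if (n_boot < 1000) {
    warn("mr_mediation: n_boot < 1000 gives unreliable intervals")
  }
  indirect <- beta1 * beta2
  proportion <- indirect / beta3
  draws <- withr::with_seed(seed, {
    tibble::tibble(
      b1 = rnorm(n_boot, beta1, se1),
      b2 = rnorm(n_boot, beta2, se2),
      b3 = rnorm(n_boot, beta3, se3)
    )
  })
  prop_boot <- draws$b1 * draws$b2 / draws$b3
  unstable <- mean(sign(draws$b3) != sign(beta3))
  if (unstable > 0.01) {
    warn(paste0("mr_mediation: total effect crosses zero in ",
                round(100 * unstable, 1),
                "% of bootstrap draws; proportion is unstable"))
  }
  ci <- unname(stats::quantile(prop_boot, c(0.025, 0.975)))
  se_prop <- sd(prop_boot)
  structure(
    list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
         indirect = indirect, proportion = proportion,
         se_prop = se_prop, ci_low = ci[1], ci_high = ci[2],
         pvalue = 2 * pnorm(-abs(proportion / se_prop)),
         unstable_frac = unstable,
         prop_draws = prop_boot,
         n_boot = n_boot, seed = seed),
    class = "mr_mediation"
  )
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("Mediation (product of coefficients, parametric bootstrap)\n")
  cat(sprintf("  beta1 = %.4g, beta2 = %.4g, beta3 = %.4g\n",
              x$beta1, x$beta2, x$beta3))
  cat(sprintf("  proportion mediated = %.2f%% (95%% CI %.2f%% - %.2f%%, p = %.3g)\n",
              100 * x$proportion, 100 * x$ci_low, 100 * x$ci_high,
              x$pvalue))
  invisible(x)
}

#' @export
tidy.mr_mediation <- function(x, ...) {
  tibble::tibble(
    beta1 = x$beta1, beta2 = x$beta2, beta3 = x$beta3,
    indirect = x$indirect, proportion = x$proportion,
    se_prop = x$se_prop, ci_low = x$ci_low, ci_high = x$ci_high,
    pvalue = x$pvalue, n_boot = x$n_boot, seed = x$seed
  )
}

#' @export
glance.mr_mediation <- function(x, ...) {
  tibble::tibble(
    proportion = x$proportion, ci_low = x$ci_low, ci_high = x$ci_high,
    pvalue = x$pvalue, unstable_frac = x$unstable_frac,
    n_boot = x$n_boot
  )
}

#' @export
autoplot.mr_mediation <- function(object, ...) {
  df <- tibble::tibble(proportion = object$prop_draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey55", colour = "white") +
    ggplot2::geom_vline(xintercept = object$proportion,
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "bootstrap proportion mediated", y = "draws",
                  title = "Mediation proportion: bootstrap distribution") +
    ggplot2::theme_minimal()
}
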