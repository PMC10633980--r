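#' Benjamini-Hochberg q-values with an explicit test count
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (m p_(j) / j)` capped at
#' 1 and mapped back to input order. The denominator `m` may exceed the
#' number of observed p-values so that exposures attempted but yielding no
#' estimate still count toward the correction (a screen of 207 taxa is
#' corrected for 207 tests even if some taxa had no instruments).
#' `NA` p-values (failed estimates) propagate as `NA` q-values but do not
#' affect the ranks of the others.
#'
#' @param pvalues Numeric vector in (0, 1\]; `NA` allowed.
#' @param m Total number of tests, at least the number of non-`NA`
#'   p-values. Defaults to `length(pvalues)`.
#' @return Numeric vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues, m = length(pvalues)) {
  obs <- which(!is.na(pvalues))
  if (m < length(obs)) {
    abort("bh_fdr: m must be at least the number of observed p-values",
          class = "mrflow_config_error")
  }
  q <- rep(NA_real_, length(pvalues))
  if (length(obs) == 0) return(q)
  p <- pvalues[obs]
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  q_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  q[obs[o]] <- q_sorted
  q
}

#' Screen many exposures against one outcome
#'
#' Runs the full per-exposure pipeline — p-value/EAF instrument filter,
#' greedy LD clumping, proxy substitution for instruments missing from the
#' outcome GWAS, harmonization, estimation — and adjusts the primary
#' p-values (IVW with two or more instruments, Wald ratio with one) across
#' exposures by Benjamini-Hochberg with `m` equal to the number of
#' exposures attempted, including those yielding no instruments.
#'
#' @param exposures List of `mr_sumstats` tibbles (or a single one).
#' @param outcome An `mr_sumstats` tibble.
#' @param ld Optional [ld_matrix()] used for clumping and proxy search.
#' @param p_threshold,eaf_floor Instrument filter, see
#'   [mr_filter_instruments()].
#' @param clump_r2,clump_kb Clumping parameters, see [mr_clump()].
#' @param proxy_r2 Minimum proxy r-squared, see [mr_find_proxies()].
#' @param palindrome_eaf_window See [mr_harmonize()].
#' @param methods `"primary"` computes only the IVW/Wald estimate per
#'   exposure (fast, what the FDR screen needs); `"all"` runs the full
#'   battery of [mr_estimate_all()] and nests it in an `estimates`
#'   list-column.
#' @param alpha FDR significance level applied to the q-values.
#' @param n_boot,seed,ivw_model Passed to the estimators.
#' @return A tibble of class `mr_screen`, one row per exposure:
#'   `exposure_id`, `nsnp`, `method`, `beta`, `se`, `pvalue`, `ci_low`,
#'   `ci_high`, `or_`, `fdr_q`, `significant`, `status`, and (for
#'   `methods = "all"`) `estimates`.
#' @export
mr_screen <- function(exposures, outcome, ld = NULL,
                      p_threshold = 1e-5, eaf_floor = 0.01,
                      clump_r2 = 0.001, clump_kb = 10000,
                      proxy_r2 = 0.8, palindrome_eaf_window = 0.08,
                      methods = c("all", "primary"), alpha = 0.05,
                      n_boot = 1000, seed = 1, ivw_model = "random") {
  methods <- match.arg(methods)
  if (inherits(exposures, "mr_sumstats")) exposures <- list(exposures)
  if (length(exposures) == 0) {
    abort("mr_screen: at least one exposure required",
          class = "mrflow_input_error")
  }
  rows <- purrr::imap(exposures, function(expo, i) {
    id <- trait_id(expo) %||% paste0("exposure_", i)
    empty <- tibble::tibble(
      exposure_id = id, nsnp = 0L, method = NA_character_,
      beta = NA_real_, se = NA_real_, pvalue = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, or_ = NA_real_,
      status = "no_instruments", estimates = list(NULL)
    )
    result <- tryCatch({
      cand <- suppressMessages(
        mr_filter_instruments(expo, p_threshold, eaf_floor))
      if (nrow(cand) == 0) return(empty)
      kept <- mr_clump(cand, ld, clump_r2, clump_kb)
      kept$action_pre <- NA_character_
      missing <- kept[!kept$variant_id %in% outcome$variant_id, ]
      if (nrow(missing) > 0) {
        kept <- kept[kept$variant_id %in% outcome$variant_id, ]
        prox <- suppressWarnings(
          mr_find_proxies(missing, outcome, ld, proxy_r2))
        if (nrow(prox) > 0) {
          # substitute the proxy variant on both sides of the analysis
          sub <- tibble::as_tibble(expo)[
            match(prox$proxy_id, expo$variant_id), ]
          sub <- sub[!is.na(sub$variant_id) &
                       !sub$variant_id %in% kept$variant_id, ]
          if (nrow(sub) > 0) {
            sub$action_pre <- "proxy_substituted"
            kept <- dplyr::bind_rows(kept, sub)
          }
        }
      }
      if (nrow(kept) == 0) return(empty)
      harm <- suppressMessages(
        mr_harmonize(kept, outcome, palindrome_eaf_window))
      harm <- harmonized_kept(harm)
      if (nrow(harm) == 0) {
        empty$status <- "all_instruments_dropped"
        return(empty)
      }
      primary <- .primary_estimate(harm, ivw_model = ivw_model)
      ests <- if (methods == "all") {
        suppressMessages(
          mr_estimate_all(harm, ivw_model = ivw_model, n_boot = n_boot,
                          seed = seed + i))
      } else NULL
      tibble::tibble(
        exposure_id = id, nsnp = primary$nsnp, method = primary$method,
        beta = primary$beta, se = primary$se, pvalue = primary$pvalue,
        ci_low = primary$ci_low, ci_high = primary$ci_high,
        or_ = primary$or_, status = "ok",
        estimates = list(ests)
      )
    }, error = function(e) {
      bad <- empty
      bad$status <- paste0("error: ", conditionMessage(e))
      bad
    })
    result
  })
  out <- dplyr::bind_rows(rows)
  out$fdr_q <- bh_fdr(out$pvalue, m = length(exposures))
  out$significant <- !is.na(out$fdr_q) & out$fdr_q < alpha
  if (methods == "primary") out$estimates <- NULL
  class(out) <- c("mr_screen", class(tibble::tibble()))
  attr(out, "alpha") <- alpha
  attr(out, "m") <- length(exposures)
  out
}

#' Reverse-direction MR
#'
#' Swaps the roles: the disease GWAS becomes the exposure (instrumented at
#' genome-wide significance by default, where such GWAS have many strong
#' hits) and the taxon GWAS the outcome, to check whether the forward
#' finding could be explained by causation in the other direction.
#'
#' @param outcome_as_exposure Disease `mr_sumstats` used as exposure.
#' @param exposure_as_outcome Taxon `mr_sumstats` used as outcome.
#' @param ld Optional [ld_matrix()].
#' @param p_threshold Instrument threshold for the disease GWAS, default
#'   `5e-8`.
#' @param ... Further arguments passed to [mr_screen()].
#' @return One-row `mr_screen` tibble.
#' @export
mr_reverse <- function(outcome_as_exposure, exposure_as_outcome, ld = NULL,
                       p_threshold = 5e-8, ...) {
  mr_screen(list(outcome_as_exposure), exposure_as_outcome, ld = ld,
            p_threshold = p_threshold, ...)
}

#' First-order bias and type-1 error from exposure/outcome sample overlap
#'
#' Two-sample MR assumes non-overlapping GWAS samples; overlap biases the
#' estimate toward the confounded observational association, with
#' magnitude controlled by instrument strength. The expected relative bias
#' is approximated as `overlap_fraction * confounded_assoc / f_bar`, and
#' the type-1 error of a nominal `alpha` test as the rejection probability
#' of a normal test whose mean is shifted by `bias / se_mr`.
#'
#' @param f_bar Mean instrument F-statistic (> 0).
#' @param overlap_fraction Fraction of shared samples, in \[0, 1\].
#' @param confounded_assoc Observational (confounded) association between
#'   exposure and outcome.
#' @param se_mr Standard error of the MR estimate used for the shifted
#'   test; default 0.019, a typical taxon-screen IVW SE (CI width
#'   `(log 1.12 - log 1.04)/3.92`).
#' @param alpha Nominal test level.
#' @return One-row tibble: `expected_bias`, `type1_error`.
#' @export
assess_overlap_bias <- function(f_bar, overlap_fraction, confounded_assoc,
                                se_mr = 0.019, alpha = 0.05) {
  stopifnot(f_bar > 0, overlap_fraction >= 0, overlap_fraction <= 1,
            se_mr > 0)
  bias <- overlap_fraction * confounded_assoc / f_bar
  z <- qnorm(1 - alpha / 2)
  shift <- bias / se_mr
  tibble::tibble(
    expected_bias = bias,
    type1_error = pnorm(-z - shift) + pnorm(-z + shift)
  )
}

#' @export
autoplot.mr_screen <- function(object, label_significant = TRUE, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$beta))
  df$rank <- rank(df$pvalue, ties.method = "first")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = -log10(.data$pvalue),
                                        colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "exposure rank", y = "-log10 p (primary estimate)",
                  colour = "FDR significant",
                  title = "Exposure-wide MR screen") +
    ggplot2::theme_minimal()
  if (label_significant && any(df$significant)) {
    p <- p + ggplot2::geom_text(
      data = df[df$significant, ],
      mapping = ggplot2::aes(label = .data$exposure_id),
      vjust = -0.6, show.legend = FALSE, size = 3)
  }
  p
}
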