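#' Cohort tables for the genetic-risk-score stage
#'
#' A cohort table couples a per-individual phenotype tibble with a dosage
#' matrix. The tibble needs `id`, `entry_time`, `exit_time` (days or years
#' from recruitment, `exit_time >= entry_time >= 0`), `event` (0 censored,
#' 1 incident event, 2 competing death — treated as censoring in the main
#' fit), `prevalent` (logical), and any covariate columns. The dosage
#' matrix has one row per individual (same order) and one column per
#' variant, values in \[0, 2\].
#'
#' @param data Per-individual tibble as described above.
#' @param dosages Numeric matrix `n x J` with variant ids as column names.
#' @return A list of class `cohort_table` with elements `data`, `dosages`.
#' @export
cohort_table <- function(data, dosages) {
  data <- tibble::as_tibble(data)
  need <- c("id", "entry_time", "exit_time", "event", "prevalent")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrflow_config_error")
  }
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == nrow(data), !is.null(colnames(dosages)))
  if (any(data$entry_time < 0) || any(data$exit_time < data$entry_time)) {
    abort("follow-up times must satisfy exit_time >= entry_time >= 0",
          class = "mrflow_input_error")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("dosages must lie in [0, 2]", class = "mrflow_input_error")
  }
  structure(list(data = data, dosages = dosages), class = "cohort_table")
}

#' Weighted genetic risk score
#'
#' Per-individual dosage-weighted sum of instrument effect sizes:
#' `score_i = sum_k w_k dosage_ik`, with weights taken from the exposure
#' GWAS instrument set. Missing dosages are mean-imputed per variant, with
#' a message reporting the count.
#'
#' @param cohort A [cohort_table()].
#' @param weights Named numeric vector (names are variant ids) or a tibble
#'   with columns `variant_id`, `weight` (a `beta` column is accepted).
#' @return Numeric vector of scores, one per individual.
#' @export
grs_score <- function(cohort, weights) {
  if (is.data.frame(weights)) {
    wcol <- if ("weight" %in% names(weights)) "weight" else "beta"
    weights <- setNames(weights[[wcol]], weights$variant_id)
  }
  absent <- setdiff(names(weights), colnames(cohort$dosages))
  if (length(absent) > 0) {
    abort(paste0("weights refer to variant(s) without dosage columns: ",
                 paste(absent, collapse = ", ")),
          class = "mrflow_config_error")
  }
  d <- cohort$dosages[, names(weights), drop = FALSE]
  n_missing <- sum(is.na(d))
  if (n_missing > 0) {
    means <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) {
      d[is.na(d[, j]), j] <- means[j]
    }
    inform(paste0("grs_score: mean-imputed ", n_missing,
                  " missing dosage value(s)"))
  }
  as.vector(d %*% weights)
}

#' Exclude prevalent cases before survival analysis
#'
#' Drops individuals whose event predates or falls on the recruitment
#' visit (the `prevalent` flag); only incident events are analysed.
#'
#' @param cohort A [cohort_table()].
#' @return The cohort restricted to `prevalent == FALSE`; counts are
#'   reported in a message.
#' @export
cohort_exclude_prevalent <- function(cohort) {
  keep <- !cohort$data$prevalent
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(paste0("cohort_exclude_prevalent: excluded ", n_drop,
                  " prevalent case(s), retaining ", sum(keep)))
  }
  cohort_table(cohort$data[keep, ], cohort$dosages[keep, , drop = FALSE])
}

#' Cox proportional-hazards association of a weighted GRS with incident
#' events
#'
#' Fits a Cox model of time-to-incident-event on the score, adjusted for
#' the named covariates, with Efron tie handling (competing deaths,
#' `event == 2`, are treated as censoring in this primary fit). Reports
#' the hazard ratio per unit score (or per SD with `standardize = TRUE`)
#' with Wald CI and p-value, and the global Schoenfeld-residual test of
#' proportional hazards computed on the event-time rank scale.
#'
#' @param cohort A [cohort_table()] with prevalent cases already excluded
#'   (rows still flagged prevalent are dropped with a message).
#' @param score Numeric score vector aligned with the cohort rows (see
#'   [grs_score()]).
#' @param adjust Covariate column names; character/factor columns (and
#'   `batch`/`center` codes) enter as factors.
#' @param standardize Scale the score to unit SD before fitting?
#' @param ph_test Compute the Schoenfeld proportional-hazards test?
#'   Skipping it speeds up replicate simulation loops.
#' @return An object of class `grs_cox`: list with `hr`, `ci_low`,
#'   `ci_high`, `pvalue`, `beta`, `se`, `n`, `n_events`, `ph_test_p`, and
#'   the underlying `survival::coxph` fit. `tidy()`/`glance()` methods
#'   are provided.
#' @export
grs_cox <- function(cohort, score, adjust = character(0),
                    standardize = FALSE, ph_test = TRUE) {
  stopifnot(length(score) == nrow(cohort$data))
  if (any(cohort$data$prevalent)) {
    cohort_full <- cohort
    keep <- !cohort_full$data$prevalent
    score <- score[keep]
    cohort <- cohort_exclude_prevalent(cohort_full)
  }
  df <- cohort$data
  if (standardize && sd(score) > 0) score <- score / sd(score)
  n_events <- sum(df$event == 1)
  if (n_events == 0) {
    abort("grs_cox: no incident events in cohort",
          class = "mrflow_input_error")
  }
  if (n_events < 2) {
    abort("grs_cox: at least 2 incident events required",
          class = "mrflow_input_error")
  }
  if (stats::var(score) == 0) {
    # no variation: the score carries no information, coefficient 0
    warn("grs_cox: score has no variation across individuals")
    return(structure(
      list(hr = 1, ci_low = 0, ci_high = Inf, pvalue = 1,
           beta = 0, se = Inf, n = nrow(df), n_events = n_events,
           ph_test_p = NA_real_, standardized = standardize, fit = NULL),
      class = "grs_cox"
    ))
  }
  mf <- tibble::tibble(
    time = df$exit_time - df$entry_time,
    status = as.integer(df$event == 1),
    score = score
  )
  for (cv in adjust) {
    if (!cv %in% names(df)) {
      abort(paste0("grs_cox: covariate not in cohort: ", cv),
            class = "mrflow_config_error")
    }
    v <- df[[cv]]
    if (is.character(v) || is.factor(v) || cv %in% c("batch", "center")) {
      v <- factor(v)
      if (nlevels(v) < 2) next  # constant factor carries no information
    }
    mf[[cv]] <- v
  }
  rhs <- paste(c("score", setdiff(names(mf), c("time", "status", "score"))),
               collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~", rhs))
  fit <- survival::coxph(fml, data = mf, ties = "efron")
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)["score"])
  se <- sm$coefficients["score", "se(coef)"]
  if (is.na(beta)) {
    abort("grs_cox: score coefficient inestimable",
          class = "mrflow_estimation_error")
  }
  ph_p <- if (ph_test) {
    tryCatch({
      zph <- survival::cox.zph(fit, transform = "rank", global = TRUE)
      unname(zph$table["GLOBAL", "p"])
    }, error = function(e) NA_real_)
  } else NA_real_
  structure(
    list(hr = exp(beta), ci_low = exp(beta - Z95 * se),
         ci_high = exp(beta + Z95 * se),
         pvalue = 2 * pnorm(-abs(beta / se)),
         beta = beta, se = se,
         n = nrow(mf), n_events = n_events,
         ph_test_p = ph_p, standardized = standardize,
         fit = fit),
    class = "grs_cox"
  )
}

#' @export
print.grs_cox <- function(x, ...) {
  cat("Weighted-GRS Cox association\n")
  cat(sprintf("  HR per %s = %.3f (95%% CI %.3f - %.3f), p = %.3g\n",
              if (x$standardized) "SD" else "unit",
              x$hr, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("  n = %d, events = %d, Schoenfeld global p = %.3g\n",
              x$n, x$n_events, x$ph_test_p))
  invisible(x)
}

#' @export
tidy.grs_cox <- function(x, ...) {
  tibble::tibble(
    term = "score", beta = x$beta, se = x$se, hr = x$hr,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue
  )
}

#' @export
glance.grs_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, hr = x$hr,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
    ph_test_p = x$ph_test_p
  )
}
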