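#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based horizontal-pleiotropy diagnostic in three parts.
#'
#' **Global test.** The observed residual sum of squares is
#' `RSS_obs = sum_j w_j (beta_out_j - theta_(-j) beta_exp_j)^2` with
#' leave-one-out IVW slopes `theta_(-j)` and weights `w_j = 1/se_out_j^2`.
#' Its null distribution comes from `n_sim` parametric simulations of the
#' instrument table under the no-pleiotropy model (`beta_exp*` redrawn
#' around the observed exposure effects, `beta_out*` around
#' `theta_(-j) beta_exp_j`), each processed with the same leave-one-out
#' statistic; `global_p = (1 + #\{RSS_sim >= RSS_obs\})/(n_sim + 1)`.
#'
#' **Outlier test.** Each SNP's observed weighted residual is compared to
#' its simulated distribution; the per-SNP simulation p-values are
#' Bonferroni-corrected by the instrument count and flagged below
#' `outlier_alpha`.
#'
#' **Distortion test.** The difference between the raw IVW estimate and
#' the outlier-removed IVW estimate is compared to the distribution of
#' differences obtained by removing the same number of randomly chosen
#' instruments.
#'
#' @param dat Harmonized instrument table with at least 4 kept rows.
#' @param n_sim Number of null simulations, at least 1000.
#' @param outlier_alpha Familywise significance level for outlier flagging
#'   (Bonferroni-corrected by the instrument count), default 0.05.
#' @param n_distortion Random-removal draws for the distortion test.
#' @param seed RNG seed.
#' @param ivw_model IVW variant for the raw and corrected fits.
#' @return An object of class `mr_presso`: a list with `global_rss_obs`,
#'   `global_p`, `outlier_ids`, `outlier_p` (named, Bonferroni-corrected),
#'   `distortion_p`, `raw` and `corrected` estimate rows, `n_sim`, `seed`.
#'   `tidy()` returns the raw/corrected rows as a tibble with the global
#'   p-value in `q_pvalue`.
#' @export
mr_presso <- function(dat, n_sim = 1000, outlier_alpha = 0.05,
                      n_distortion = 1000, seed = 1,
                      ivw_model = "random") {
  dat <- .kept(dat)
  J <- nrow(dat)
  if (J < 4) {
    abort("mr_presso needs at least 4 instruments",
          class = "mrflow_input_error")
  }
  if (n_sim < 1000) {
    abort("mr_presso requires n_sim >= 1000", class = "mrflow_config_error")
  }
  bx <- dat$beta_exp; by <- dat$beta_out
  sx <- dat$se_exp; sy <- dat$se_out
  w <- 1 / sy^2

  loo_slopes <- function(bxm, bym) {
    # rows = datasets, cols = SNPs; slope excluding each column in turn
    sxy <- as.vector((bxm * bym) %*% w)
    sxx <- as.vector((bxm^2) %*% w)
    (sxy - sweep(bxm * bym, 2, w, `*`)) / (sxx - sweep(bxm^2, 2, w, `*`))
  }

  obs <- loo_slopes(matrix(bx, 1), matrix(by, 1))
  res_obs <- w * (by - obs[1, ] * bx)^2
  rss_obs <- sum(res_obs)

  sims <- withr::with_seed(seed, {
    bxs <- matrix(rnorm(n_sim * J, rep(bx, each = n_sim),
                        rep(sx, each = n_sim)), n_sim, J)
    bys <- matrix(rnorm(n_sim * J, rep(obs[1, ] * bx, each = n_sim),
                        rep(sy, each = n_sim)), n_sim, J)
    list(bx = bxs, by = bys,
         removal = matrix(runif(n_distortion * J), n_distortion, J))
  })
  th <- loo_slopes(sims$bx, sims$by)
  res_sim <- sweep((sims$by - th * sims$bx)^2, 2, w, `*`)
  rss_sim <- rowSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_snp <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) / (n_sim + 1)
  p_snp_bonf <- pmin(p_snp * J, 1)
  names(p_snp_bonf) <- dat$variant_id
  outliers <- dat$variant_id[p_snp_bonf < outlier_alpha]

  raw <- mr_ivw(dat, model = ivw_model)
  raw$method <- "presso_raw"
  corrected <- raw
  corrected$method <- "presso_corrected"
  distortion_p <- NA_real_
  if (length(outliers) > 0 && J - length(outliers) >= 2) {
    keep_ids <- !dat$variant_id %in% outliers
    corrected <- mr_ivw(dat[keep_ids, ], model = ivw_model)
    corrected$method <- "presso_corrected"
    d_obs <- corrected$beta - raw$beta
    k <- length(outliers)
    ivw_slope <- function(idx) {
      sum(w[idx] * bx[idx] * by[idx]) / sum(w[idx] * bx[idx]^2)
    }
    d_rand <- apply(sims$removal, 1, function(u) {
      drop <- order(u)[seq_len(k)]
      ivw_slope(setdiff(seq_len(J), drop)) - raw$beta
    })
    distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_distortion + 1)
  } else if (length(outliers) > 0) {
    warn(paste0("mr_presso: too few instruments left after outlier ",
                "removal; corrected estimate kept equal to raw"))
  }
  corrected$q_pvalue <- global_p
  raw$q_pvalue <- global_p

  structure(
    list(global_rss_obs = rss_obs, global_p = global_p,
         outlier_ids = outliers, outlier_p = p_snp_bonf,
         distortion_p = distortion_p,
         raw = raw, corrected = corrected,
         n_sim = n_sim, seed = seed),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO (", x$n_sim, " simulations)\n", sep = "")
  cat("  global RSS ", format(x$global_rss_obs, digits = 4),
      ", p = ", format(x$global_p, digits = 3), "\n", sep = "")
  if (length(x$outlier_ids) > 0) {
    cat("  outliers: ", paste(x$outlier_ids, collapse = ", "),
        " (distortion p = ", format(x$distortion_p, digits = 3), ")\n",
        sep = "")
  } else {
    cat("  no outliers detected\n")
  }
  cat("  corrected estimate: beta = ",
      format(x$corrected$beta, digits = 4), " (se ",
      format(x$corrected$se, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.mr_presso <- function(x, ...) {
  dplyr::bind_rows(x$raw, x$corrected)
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_rss_obs = x$global_rss_obs,
    global_p = x$global_p,
    n_outliers = length(x$outlier_ids),
    distortion_p = x$distortion_p,
    n_sim = x$n_sim
  )
}
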