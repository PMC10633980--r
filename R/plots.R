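#' Scatter plot of harmonized instrument effects with fitted slopes
#'
#' Outcome effects against exposure effects per instrument (error bars are
#' one SE), with one fitted line per estimate supplied: IVW and the other
#' slope-based methods through the origin, MR-Egger with its intercept.
#'
#' @param harmonized Harmonized instrument table (kept rows are plotted).
#' @param estimates Optional estimates tibble from [mr_estimate_all()].
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(harmonized, estimates = NULL) {
  h <- harmonized_kept(harmonized)
  # orient exposure effects positive for display, as Egger fits them
  flip <- ifelse(h$beta_exp < 0, -1, 1)
  df <- tibble::tibble(
    bx = h$beta_exp * flip, by = h$beta_out * flip,
    sx = h$se_exp, sy = h$se_out
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$sy,
                                        ymax = .data$by + .data$sy),
                           width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$sx,
                                         xmax = .data$bx + .data$sx),
                            height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    lines <- dplyr::transmute(
      estimates,
      method = .data$method,
      slope = .data$beta,
      intercept = dplyr::coalesce(.data$intercept, 0)
    )
    p <- p + ggplot2::geom_abline(
      data = lines,
      mapping = ggplot2::aes(slope = .data$slope,
                             intercept = .data$intercept,
                             colour = .data$method)
    ) + ggplot2::labs(colour = "method")
  }
  p
}

#' Forest plot of MR estimates
#'
#' One row per estimate with its 95% CI, on the odds-ratio scale by
#' default (log-spaced axis, reference line at 1).
#'
#' @param estimates Estimates tibble (from [mr_estimate_all()] or a
#'   filtered [mr_screen()] result with `method`, `beta`, `ci_low`,
#'   `ci_high` columns); a `label` column overrides the row labels.
#' @param or_scale Plot odds ratios (`TRUE`) or raw betas.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(estimates, or_scale = TRUE) {
  df <- tibble::as_tibble(estimates)
  df$label <- if ("label" %in% names(df)) df$label else
    if ("exposure_id" %in% names(df)) df$exposure_id else df$method
  df <- dplyr::filter(df, !is.na(.data$beta))
  tf <- if (or_scale) exp else identity
  df <- dplyr::mutate(df,
                      mid = tf(.data$beta),
                      lo = tf(.data$ci_low),
                      hi = tf(.data$ci_high))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid,
                                        y = stats::reorder(.data$label,
                                                           .data$mid))) +
    ggplot2::geom_vline(xintercept = if (or_scale) 1 else 0,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo,
                                         xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = if (or_scale) "odds ratio (95% CI)" else
      "effect (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (or_scale) p <- p + ggplot2::scale_x_log10()
  p
}
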