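.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome effects onto a common effect allele
#'
#' Aligns each instrument's outcome association to the exposure's effect
#' allele. Exposure effects are never altered; all orientation happens on
#' the outcome side:
#'
#' * alleles match as reported: kept unchanged;
#' * alleles match after swapping effect/other: outcome beta negated and
#'   `eaf_out` complemented (`allele_flip`);
#' * alleles match only after strand complementation (A<->T, C<->G): the
#'   outcome record is complemented, then the rule above applies;
#' * palindromic variants (allele pair A/T or C/G), whose strand cannot be
#'   resolved from labels: if both allele frequencies lie outside the
#'   ambiguous zone `0.5 +/- palindrome_eaf_window`, the outcome effect is
#'   oriented so the aligned `eaf_out` falls on the same side of 0.5 as
#'   `eaf_exp` (`palindromic_inferred`); otherwise — including when either
#'   frequency is missing — the variant is dropped (`palindromic_dropped`);
#' * non-reconcilable allele pairs are dropped (`incompatible_dropped`).
#'
#' Dropped rows are returned with `keep = FALSE` so the disposition of
#' every instrument is auditable; estimators must use only `keep == TRUE`
#' rows (see [harmonized_kept()]).
#'
#' @param exposure Tibble of exposure instruments (columns as in
#'   [as_sumstats()]; an optional `action_pre` column, e.g.
#'   `"proxy_substituted"` set by the proxy stage, is carried into
#'   `action_taken` for retained rows).
#' @param outcome An `mr_sumstats` tibble containing every exposure
#'   variant (run the proxy stage first; a missing variant is an error).
#' @param palindrome_eaf_window Half-width of the ambiguous allele
#'   frequency zone around 0.5. Default 0.08 (zone 0.42–0.58), the common
#'   community default.
#' @return Tibble with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`,
#'   `se_out`, `eaf_out`, `action_taken`, `f_stat`, `keep`.
#' @export
mr_harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  w <- palindrome_eaf_window
  stopifnot(w >= 0, w < 0.5)
  exposure <- tibble::as_tibble(exposure)
  idx <- match(exposure$variant_id, outcome$variant_id)
  if (anyNA(idx)) {
    abort(paste0("exposure variant(s) absent from outcome GWAS ",
                 "(resolve proxies first): ",
                 paste(exposure$variant_id[is.na(idx)], collapse = ", ")),
          class = "mrflow_contract_error")
  }
  out <- outcome[idx, ]
  pre <- if ("action_pre" %in% names(exposure)) exposure$action_pre else
    rep(NA_character_, nrow(exposure))

  n <- nrow(exposure)
  beta_out <- out$beta
  eaf_out <- out$eaf
  action <- character(n)
  keep <- rep(TRUE, n)

  ea <- exposure$effect_allele; oa <- exposure$other_allele
  oea <- out$effect_allele; ooa <- out$other_allele
  pal <- .is_palindromic(ea, oa)

  for (i in seq_len(n)) {
    if (pal[i]) {
      same_pair <- setequal(c(oea[i], ooa[i]), c(ea[i], oa[i]))
      if (!same_pair) {
        action[i] <- "incompatible_dropped"; keep[i] <- FALSE; next
      }
      # label alignment first (swap => negate), then frequency decides
      if (oea[i] == oa[i]) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      }
      fe <- exposure$eaf[i]; fo <- eaf_out[i]
      unambiguous <- !is.na(fe) && !is.na(fo) &&
        abs(fe - 0.5) > w && abs(fo - 0.5) > w
      if (!unambiguous) {
        action[i] <- "palindromic_dropped"; keep[i] <- FALSE; next
      }
      if ((fe - 0.5) * (fo - 0.5) < 0) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      action[i] <- "palindromic_inferred"
    } else {
      a1 <- oea[i]; a2 <- ooa[i]
      if (!setequal(c(a1, a2), c(ea[i], oa[i]))) {
        a1 <- .complement(a1); a2 <- .complement(a2)
      }
      if (a1 == ea[i] && a2 == oa[i]) {
        action[i] <- "unchanged"
      } else if (a1 == oa[i] && a2 == ea[i]) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "allele_flip"
      } else {
        action[i] <- "incompatible_dropped"; keep[i] <- FALSE; next
      }
    }
    if (!is.na(pre[i])) action[i] <- pre[i]
  }

  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0("mr_harmonize: dropped ", n_dropped, " instrument(s) (",
                  paste(unique(action[!keep]), collapse = ", "), ")"))
  }
  tibble::tibble(
    variant_id = exposure$variant_id,
    effect_allele = ea,
    other_allele = oa,
    beta_exp = exposure$beta,
    se_exp = exposure$se,
    eaf_exp = exposure$eaf,
    beta_out = beta_out,
    se_out = out$se,
    eaf_out = eaf_out,
    action_taken = action,
    f_stat = f_statistic(exposure$beta, exposure$se),
    keep = keep
  )
}

#' @rdname mr_harmonize
#' @param harmonized A tibble returned by [mr_harmonize()].
#' @export
harmonized_kept <- function(harmonized) {
  dplyr::filter(harmonized, .data$keep)
}

#' Check that harmonization is stable on an already-aligned table
#'
#' Re-harmonizing a retained, aligned instrument table against itself must
#' be the identity: no beta sign changes, no frequency complements, nothing
#' newly dropped. Used as a self-diagnostic.
#'
#' @param harmonized A retained (`keep == TRUE`) harmonized tibble.
#' @param palindrome_eaf_window As in [mr_harmonize()].
#' @return `TRUE` iff the second pass reproduces the table exactly.
#' @export
harmonization_is_stable <- function(harmonized,
                                    palindrome_eaf_window = 0.08) {
  h <- harmonized_kept(harmonized)
  if (nrow(h) == 0) return(TRUE)
  exposure <- tibble::tibble(
    variant_id = h$variant_id,
    effect_allele = h$effect_allele,
    other_allele = h$other_allele,
    eaf = h$eaf_exp,
    beta = h$beta_exp,
    se = h$se_exp,
    pvalue = 2 * pnorm(-abs(h$beta_exp / h$se_exp))
  )
  outcome <- as_sumstats(
    tibble::tibble(
      variant_id = h$variant_id,
      effect_allele = h$effect_allele,
      other_allele = h$other_allele,
      eaf = h$eaf_out,
      beta = h$beta_out,
      se = h$se_out,
      pvalue = pmax(2 * pnorm(-abs(h$beta_out / h$se_out)), 1e-300)
    ),
    trait_id = "self", trait_type = "continuous"
  )
  h2 <- mr_harmonize(exposure, outcome,
                     palindrome_eaf_window = palindrome_eaf_window)
  all(h2$keep) &&
    isTRUE(all.equal(h2$beta_out, h$beta_out, tolerance = 0)) &&
    isTRUE(all.equal(h2$eaf_out, h$eaf_out, tolerance = 0))
}
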