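#' Filter instrument candidates by association p-value and allele frequency
#'
#' Keeps variants with `pvalue` strictly below `p_threshold` and a minor
#' allele frequency strictly above `eaf_floor` (the frequency filter is
#' applied to `min(eaf, 1 - eaf)`, so near-monomorphic variants are removed
#' regardless of which allele is the effect allele). Variants with missing
#' `eaf` are dropped, with a message, since the frequency filter and
#' palindrome resolution both need it on the exposure side.
#'
#' @param stats An `mr_sumstats` tibble (see [as_sumstats()]).
#' @param p_threshold Inclusion p-value threshold, default `1e-5` (the
#'   suggestive threshold commonly used for microbial-taxon GWAS with few
#'   genome-wide-significant hits).
#' @param eaf_floor Minor-allele-frequency floor, default `0.01`.
#' @return Tibble of surviving candidate instruments.
#' @export
mr_filter_instruments <- function(stats, p_threshold = 1e-5,
                                  eaf_floor = 0.01) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            eaf_floor >= 0, eaf_floor < 0.5)
  n_missing <- sum(is.na(stats$eaf))
  if (n_missing > 0) {
    inform(paste0("mr_filter_instruments: dropped ", n_missing,
                  " candidate(s) with missing eaf"))
  }
  dplyr::filter(tibble::as_tibble(stats),
                !is.na(.data$eaf),
                .data$pvalue < p_threshold,
                pmin(.data$eaf, 1 - .data$eaf) > eaf_floor)
}

#' Greedy LD clumping of candidate instruments
#'
#' PLINK-style greedy clumping: candidates are ranked by ascending p-value
#' (ties broken by `variant_id`), the best remaining variant is kept, and
#' every remaining variant on the same chromosome within `window_kb`
#' kilobases whose r-squared with the kept variant is at or above
#' `r2_threshold` is removed and logged against that leader. Pairs absent
#' from `ld` are treated as unlinked.
#'
#' @param candidates Tibble of candidate instruments (needs `variant_id`,
#'   `chromosome`, `position`, `pvalue`).
#' @param ld An [ld_matrix()] or `NULL` (no LD information: all pairs are
#'   treated as unlinked, so only identical positions could clump —
#'   effectively a no-op).
#' @param r2_threshold Removal threshold on r-squared, default `0.001`.
#' @param window_kb Half-window in kilobases, default `10000` (variants
#'   further apart are kept regardless of LD).
#' @return Tibble of kept instruments (rows of `candidates`), with the full
#'   disposition log attached as attribute `"clump_log"` — a tibble with
#'   columns `variant_id`, `disposition` (`"kept"` or
#'   `"removed_by_clump"`), `leader`. Retrieve it with [clump_log()].
#' @export
mr_clump <- function(candidates, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0) {
    abort("no candidates to clump", class = "mrflow_input_error")
  }
  in_ld <- if (is.null(ld)) rep(FALSE, nrow(candidates)) else
    candidates$variant_id %in% rownames(ld)
  no_pos <- is.na(candidates$chromosome) | is.na(candidates$position)
  orphan <- !in_ld & no_pos
  if (any(orphan)) {
    abort(paste0("candidate(s) missing from LD data and lacking position: ",
                 paste(candidates$variant_id[orphan], collapse = ", ")),
          class = "mrflow_input_error")
  }
  ord <- order(candidates$pvalue, candidates$variant_id)
  remaining <- ord
  kept <- integer(0)
  log <- list()
  while (length(remaining) > 0) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      same_chr <- candidates$chromosome[remaining] ==
        candidates$chromosome[lead]
      near <- same_chr & !is.na(same_chr) &
        abs(candidates$position[remaining] - candidates$position[lead]) <=
          window_kb * 1000
      r2 <- ld_r2(ld, candidates$variant_id[remaining],
                  candidates$variant_id[lead])
      drop <- near & r2 >= r2_threshold
      if (any(drop)) {
        log[[length(log) + 1L]] <- tibble::tibble(
          variant_id = candidates$variant_id[remaining[drop]],
          disposition = "removed_by_clump",
          leader = candidates$variant_id[lead]
        )
        remaining <- remaining[!drop]
      }
    }
  }
  kept <- sort(kept)
  log[[length(log) + 1L]] <- tibble::tibble(
    variant_id = candidates$variant_id[kept],
    disposition = "kept",
    leader = NA_character_
  )
  out <- candidates[kept, ]
  attr(out, "clump_log") <-
    dplyr::arrange(dplyr::bind_rows(log), .data$variant_id)
  out
}

#' @rdname mr_clump
#' @param x A clumped instrument tibble returned by [mr_clump()].
#' @export
clump_log <- function(x) attr(x, "clump_log", exact = TRUE)

#' Find LD proxies for instruments absent from the outcome GWAS
#'
#' For each missing instrument, selects the outcome-present variant on the
#' same chromosome with the largest r-squared at or above `r2_min` (ties
#' broken by `variant_id`). Instruments with no qualifying proxy are
#' dropped with a warning; an empty mapping is a valid result.
#'
#' @param missing Tibble of instruments absent from the outcome GWAS.
#' @param outcome An `mr_sumstats` tibble for the outcome.
#' @param ld An [ld_matrix()]; proxies are only found among its variants.
#' @param r2_min Minimum acceptable r-squared, default `0.8`.
#' @return Tibble with columns `variant_id`, `proxy_id`, `r2`; zero rows if
#'   nothing qualifies.
#' @export
mr_find_proxies <- function(missing, outcome, ld, r2_min = 0.8) {
  stopifnot(r2_min > 0, r2_min <= 1)
  if (is.null(ld) || nrow(missing) == 0) {
    if (nrow(missing) > 0) {
      warn(paste0("no LD data supplied; dropping ", nrow(missing),
                  " instrument(s) absent from the outcome GWAS"))
    }
    return(tibble::tibble(variant_id = character(0),
                          proxy_id = character(0), r2 = numeric(0)))
  }
  pos <- attr(ld, "positions", exact = TRUE)
  chrom_of <- function(id) {
    if (!is.null(pos) && id %in% pos$variant_id) {
      pos$chromosome[match(id, pos$variant_id)]
    } else NA_character_
  }
  rows <- purrr::map(seq_len(nrow(missing)), function(i) {
    id <- missing$variant_id[i]
    if (!id %in% rownames(ld)) return(NULL)
    cand <- setdiff(intersect(rownames(ld), outcome$variant_id), id)
    if (length(cand) == 0) return(NULL)
    chr <- chrom_of(id)
    if (!is.na(chr)) {
      cand_chr <- vapply(cand, chrom_of, character(1))
      cand <- cand[is.na(cand_chr) | cand_chr == chr]
      if (length(cand) == 0) return(NULL)
    }
    r2 <- ld[id, cand]
    best <- order(-r2, cand)[1]
    if (r2[best] >= r2_min) {
      tibble::tibble(variant_id = id, proxy_id = cand[best],
                     r2 = unname(r2[best]))
    } else NULL
  })
  out <- dplyr::bind_rows(rows)
  n_dropped <- nrow(missing) - nrow(out)
  if (n_dropped > 0) {
    warn(paste0("mr_find_proxies: ", n_dropped,
                " instrument(s) had no proxy with r2 >= ", r2_min,
                " and were dropped"))
  }
  out
}

#' Single-variant F-statistic
#'
#' Instrument strength as the squared z-score `(beta / se)^2`, the
#' single-SNP approximation to the first-stage F-statistic. Values above
#' ~10 are conventionally taken as strong instruments.
#'
#' @param beta,se Per-allele effect and its standard error (vectorized).
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort("f_statistic requires se > 0", class = "mrflow_input_error")
  }
  (beta / se)^2
}
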