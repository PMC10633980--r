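# Shared fixture builders; everything is generated in code at test time.

# Harmonized instrument table straight from the synthetic generator.
sim_harmonized <- function(n_snps = 10, theta = 0, seed = 1, ...) {
  dat <- sim_sumstats(sim_config(n_snps = n_snps, theta = theta,
                                 seed = seed, ...))
  harmonized_kept(suppressMessages(
    mr_harmonize(tibble::as_tibble(dat$exposure), dat$outcome)))
}

# Hand-built harmonized table with exact values (for formula tests).
manual_harmonized <- function(beta_exp, se_exp, beta_out, se_out) {
  n <- length(beta_exp)
  tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp,
    eaf_exp = 0.3,
    beta_out = beta_out, se_out = se_out, eaf_out = 0.3,
    action_taken = "unchanged",
    f_stat = (beta_exp / se_exp)^2,
    keep = TRUE
  )
}

# Minimal valid summary-stats tibble.
manual_sumstats <- function(variant_id, beta, se, pvalue = NULL,
                            eaf = 0.3, effect_allele = "A",
                            other_allele = "G", chromosome = "1",
                            position = seq_along(variant_id) * 1e6,
                            trait_id = "trait",
                            trait_type = "continuous") {
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  as_sumstats(tibble::tibble(
    variant_id = variant_id, chromosome = chromosome,
    position = as.integer(position),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue
  ), trait_id = trait_id, trait_type = trait_type)
}
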