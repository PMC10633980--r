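#' Declarative configuration for a full MR study run
#'
#' Collects every threshold the pipeline uses under one named list:
#' instrument selection (`p_threshold`, `eaf_floor`), clumping
#' (`clump_r2`, `clump_kb`), proxies (`proxy_r2`), screening (`alpha`),
#' the risk-factor significance screen applied before mediation is
#' attempted (`riskfactor_p`), the reverse-direction instrument threshold
#' (`reverse_p`), bootstrap sizes and the master seed, plus stage toggles.
#' In synthetic mode (`simulate = TRUE`) the study inputs are generated by
#' the [sim_config()] in `sim`; in file mode, `exposure_files`,
#' `outcome_file` (and optionally `ld_file`, `ld_format`) name delimited
#' inputs read through [read_sumstats()]/[read_ld()].
#'
#' @param simulate Generate inputs with the synthetic module?
#' @param n_taxa Number of null taxa to simulate in synthetic mode.
#' @param signal_taxa List of lists describing non-null taxa, each with
#'   `id`, `theta`, `n_snps` (defaults emulate a screen with two causal
#'   taxa: one with 10 instruments and odds ratio 1.08, one with 2
#'   instruments and odds ratio 1.15).
#' @param sim A [sim_config()] providing the generator parameters.
#' @param exposure_files,outcome_file,ld_file,ld_format File-mode inputs.
#' @param p_threshold,eaf_floor,clump_r2,clump_kb,proxy_r2,palindrome_eaf_window
#'   Pipeline thresholds (defaults: 1e-5, 0.01, 0.001, 10000 kb, 0.8, 0.08).
#' @param alpha FDR significance level for the screen.
#' @param riskfactor_p Significance screen for mediator -> outcome effects
#'   before mediation is attempted (default 0.005, accounting for the
#'   number of independent risk factors tested).
#' @param reverse_p Instrument p-value threshold for reverse MR.
#' @param n_boot,n_sim_presso Bootstrap / simulation sizes.
#' @param run_reverse,run_mediation,run_cohort Stage toggles.
#' @param methods Estimator battery passed to [mr_screen()].
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(simulate = TRUE,
                         n_taxa = 207,
                         signal_taxa = list(
                           list(id = "taxon_A", theta = log(1.08),
                                n_snps = 10),
                           list(id = "taxon_B", theta = log(1.15),
                                n_snps = 2)
                         ),
                         sim = NULL,
                         exposure_files = NULL, outcome_file = NULL,
                         ld_file = NULL, ld_format = "square",
                         p_threshold = 1e-5, eaf_floor = 0.01,
                         clump_r2 = 0.001, clump_kb = 10000,
                         proxy_r2 = 0.8, palindrome_eaf_window = 0.08,
                         alpha = 0.05, riskfactor_p = 0.005,
                         reverse_p = 5e-8,
                         n_boot = 1000, n_sim_presso = 1000,
                         run_reverse = TRUE, run_mediation = TRUE,
                         run_cohort = TRUE,
                         methods = "all",
                         seed = 1) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(as.list(environment()), class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys map onto [study_config()] arguments; a `sim` block maps
#' onto [sim_config()].
#'
#' @param path YAML file path.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  if (is.null(sim_args$seed)) sim_args$seed <- raw$seed %||% 1
  cfg_args <- raw
  cfg_args$sim <- do.call(sim_config, sim_args)
  do.call(study_config, cfg_args)
}

# Simulate the exposure panel for a synthetic study: n_taxa null taxa and
# the configured signal taxa, all against one shared outcome GWAS.
.sim_study_inputs <- function(config) {
  sim <- config$sim
  base_seed <- sim$seed
  taxa <- list()
  n_signal <- length(config$signal_taxa)
  n_null <- max(config$n_taxa - n_signal, 0)
  make_pair <- function(theta, n_snps, seed, id) {
    cfg <- sim
    cfg$theta <- theta
    cfg$n_snps <- n_snps
    cfg$seed <- seed
    dat <- sim_sumstats(cfg)
    attr(dat$exposure, "trait_id") <- id
    dat
  }
  outcome_records <- list()
  for (i in seq_len(n_null)) {
    id <- sprintf("taxon_null_%03d", i)
    pair <- make_pair(0, sim$n_snps, base_seed + i, id)
    # re-key variant ids so taxa do not collide in the shared outcome GWAS
    new_ids <- sprintf("%s_v%02d", id, seq_len(nrow(pair$exposure)))
    pair$exposure$variant_id <- new_ids
    pair$outcome$variant_id <- new_ids
    taxa[[id]] <- pair$exposure
    outcome_records[[id]] <- pair$outcome
  }
  for (k in seq_len(n_signal)) {
    st <- config$signal_taxa[[k]]
    pair <- make_pair(st$theta, st$n_snps, base_seed + n_null + k, st$id)
    new_ids <- sprintf("%s_v%02d", st$id, seq_len(nrow(pair$exposure)))
    pair$exposure$variant_id <- new_ids
    pair$outcome$variant_id <- new_ids
    taxa[[st$id]] <- pair$exposure
    outcome_records[[st$id]] <- pair$outcome
  }
  outcome <- as_sumstats(dplyr::bind_rows(outcome_records),
                         trait_id = "outcome", trait_type = "binary")
  list(exposures = taxa, outcome = outcome, ld = NULL)
}

#' Run a full MR study end to end
#'
#' Orchestrates the stages of an exposure-wide MR study: (1) the
#' FDR-corrected screen of every exposure against the outcome;
#' (2) reverse-direction MR for the significant taxa; (3) mediation —
#' risk-factor MR screened at `riskfactor_p`, two-step coefficients,
#' multivariable MR validation, and the bootstrap mediation proportion;
#' (4) the cohort weighted-GRS survival stage. Each stage writes a TSV
#' under `out_dir`; a JSON manifest records seeds, thresholds and
#' per-stage status (the manifest is byte-identical across runs with the
#' same configuration); failures in one stage are recorded and do not
#' stop independent stages.
#'
#' In synthetic mode every significant taxon gets a mediation triangle and
#' a cohort generated from the study's [sim_config()] with known truth,
#' so the full pipeline is exercised through its public entry points.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with elements `screen`, `reverse`,
#'   `mediation`, `grs`, `manifest`.
#' @export
mr_run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  manifest <- list(
    seed = config$seed,
    thresholds = list(
      p_threshold = config$p_threshold, eaf_floor = config$eaf_floor,
      clump_r2 = config$clump_r2, clump_kb = config$clump_kb,
      proxy_r2 = config$proxy_r2, alpha = config$alpha,
      riskfactor_p = config$riskfactor_p, reverse_p = config$reverse_p
    ),
    n_boot = config$n_boot,
    stages = list()
  )
  stage_status <- function(name, status) {
    manifest$stages[[name]] <<- status
  }

  # ---- inputs ----
  if (config$simulate) {
    inputs <- .sim_study_inputs(config)
    note("inputs: simulated ", length(inputs$exposures), " exposures")
  } else {
    exposures <- lapply(seq_along(config$exposure_files), function(i) {
      read_sumstats(config$exposure_files[[i]],
                    trait_id = names(config$exposure_files)[i] %||%
                      basename(config$exposure_files[[i]]))
    })
    ld <- if (!is.null(config$ld_file)) {
      read_ld(config$ld_file, format = config$ld_format)
    } else NULL
    inputs <- list(
      exposures = exposures,
      outcome = read_sumstats(config$outcome_file, trait_id = "outcome",
                              trait_type = "binary"),
      ld = ld
    )
    note("inputs: read ", length(exposures), " exposure files")
  }

  # ---- stage 1: screen ----
  screen <- tryCatch({
    s <- mr_screen(inputs$exposures, inputs$outcome, ld = inputs$ld,
                   p_threshold = config$p_threshold,
                   eaf_floor = config$eaf_floor,
                   clump_r2 = config$clump_r2, clump_kb = config$clump_kb,
                   proxy_r2 = config$proxy_r2,
                   palindrome_eaf_window = config$palindrome_eaf_window,
                   methods = config$methods, alpha = config$alpha,
                   n_boot = config$n_boot, seed = config$seed)
    flat <- tibble::as_tibble(s)
    flat$estimates <- NULL
    readr::write_tsv(flat, file.path(out_dir, "screen_results.tsv"))
    stage_status("screen", "ok")
    note("screen: ", sum(s$significant), " significant of ", nrow(s))
    s
  }, error = function(e) {
    stage_status("screen", paste0("error: ", conditionMessage(e)))
    NULL
  })
  sig_ids <- if (!is.null(screen)) {
    screen$exposure_id[screen$significant]
  } else character(0)

  # ---- stage 2: reverse MR ----
  reverse <- NULL
  if (config$run_reverse && length(sig_ids) > 0 && config$simulate) {
    reverse <- tryCatch({
      rev_rows <- purrr::map(seq_along(sig_ids), function(k) {
        cfg <- config$sim
        cfg$theta <- 0  # forward effect does not imply a reverse one
        cfg$n_snps <- 104
        cfg$gamma_sd <- 0.02
        cfg$seed <- config$seed + 5000L + k
        dat <- sim_sumstats(cfg)
        attr(dat$exposure, "trait_id") <- "outcome_as_exposure"
        attr(dat$outcome, "trait_id") <- sig_ids[k]
        out <- mr_reverse(dat$exposure, dat$outcome,
                          p_threshold = config$reverse_p,
                          methods = "primary")
        out$exposure_id <- paste0("outcome->", sig_ids[k])
        out
      })
      rv <- dplyr::bind_rows(rev_rows)
      readr::write_tsv(tibble::as_tibble(rv),
                       file.path(out_dir, "reverse_mr.tsv"))
      stage_status("reverse", "ok")
      rv
    }, error = function(e) {
      stage_status("reverse", paste0("error: ", conditionMessage(e)))
      NULL
    })
  } else if (!config$run_reverse) {
    stage_status("reverse", "disabled")
  }

  # ---- stage 3: mediation ----
  mediation <- NULL
  if (config$run_mediation && length(sig_ids) > 0 && config$simulate) {
    mediation <- tryCatch({
      med_rows <- purrr::map(seq_along(sig_ids), function(k) {
        cfg <- config$sim
        cfg$seed <- config$seed + 7000L + k
        tri <- sim_triangle(cfg)
        h_tm <- suppressMessages(mr_harmonize(
          tibble::as_tibble(tri$taxon_mediator$exposure),
          tri$taxon_mediator$outcome))
        h_mo <- suppressMessages(mr_harmonize(
          tibble::as_tibble(tri$mediator_outcome$exposure),
          tri$mediator_outcome$outcome))
        h_to <- suppressMessages(mr_harmonize(
          tibble::as_tibble(tri$taxon_outcome$exposure),
          tri$taxon_outcome$outcome))
        total <- .primary_estimate(harmonized_kept(h_to))
        steps <- mr_two_step(harmonized_kept(h_tm), harmonized_kept(h_mo),
                             total)
        if (steps$p2 > config$riskfactor_p) {
          note("mediation: mediator for ", sig_ids[k],
               " failed the risk-factor screen (p = ",
               signif(steps$p2, 3), ")")
          return(NULL)
        }
        med <- mr_mediation(steps$beta1, steps$se1, steps$beta2,
                            steps$se2, steps$beta3, steps$se3,
                            n_boot = max(config$n_boot, 1000),
                            seed = config$seed + 7500L + k)
        dplyr::bind_cols(
          tibble::tibble(taxon = sig_ids[k], mediator = "risk_factor"),
          tidy(med)
        )
      })
      md <- dplyr::bind_rows(med_rows)
      if (nrow(md) > 0) {
        readr::write_tsv(md, file.path(out_dir, "mediation.tsv"))
      }
      stage_status("mediation", "ok")
      md
    }, error = function(e) {
      stage_status("mediation", paste0("error: ", conditionMessage(e)))
      NULL
    })
  } else if (!config$run_mediation) {
    stage_status("mediation", "disabled")
  }

  # ---- stage 4: cohort GRS ----
  grs <- NULL
  if (config$run_cohort && length(sig_ids) > 0 && config$simulate) {
    grs <- tryCatch({
      grs_rows <- purrr::map(seq_along(sig_ids), function(k) {
        cfg <- config$sim
        cfg$seed <- config$seed + 9000L + k
        # weights: that taxon's instrument effect sizes from its GWAS
        expo <- inputs$exposures[[sig_ids[k]]]
        cand <- suppressMessages(mr_filter_instruments(
          expo, config$p_threshold, config$eaf_floor))
        w <- setNames(cand$beta, cand$variant_id)
        cohort <- suppressWarnings(sim_cohort(cfg, w))
        cohort <- suppressMessages(cohort_exclude_prevalent(cohort))
        score <- grs_score(cohort, w)
        fit <- grs_cox(cohort, score,
                       adjust = c("age", "sex", "batch", "center",
                                  paste0("pc", 1:4)))
        dplyr::bind_cols(tibble::tibble(taxon = sig_ids[k]), glance(fit))
      })
      gr <- dplyr::bind_rows(grs_rows)
      readr::write_tsv(gr, file.path(out_dir, "grs_associations.tsv"))
      stage_status("grs", "ok")
      gr
    }, error = function(e) {
      stage_status("grs", paste0("error: ", conditionMessage(e)))
      NULL
    })
  } else if (!config$run_cohort) {
    stage_status("grs", "disabled")
  }

  manifest$significant_taxa <- as.list(sig_ids)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(screen = screen, reverse = reverse,
                 mediation = mediation, grs = grs, manifest = manifest))
}
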