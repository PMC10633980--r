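#' GWAS summary-statistics tables
#'
#' A summary-statistics table is a tibble with one row per variant and the
#' columns `variant_id`, `chromosome`, `position`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, carrying the trait
#' identity as attributes. `as_sumstats()` validates a data frame into this
#' shape; [read_sumstats()] builds one from a delimited file.
#'
#' Validation drops (with a message) rows that violate the per-variant
#' invariants: non-finite or non-positive `se`, `pvalue` outside (0, 1]
#' (zero p-values are floored at 1e-300 rather than dropped, keeping
#' -log10(p) finite), identical effect and other alleles, alleles outside
#' {A,C,G,T}, or `eaf` outside [0, 1]. Missing `eaf` is permitted (needed
#' for outcome GWAS that do not report frequencies); duplicated
#' `variant_id`s keep the first occurrence.
#'
#' @param x A data frame with the columns above (`chromosome`, `position`,
#'   `eaf` and `n` may be absent; they are filled with `NA`).
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"binary"` (effects are log odds ratios) or
#'   `"continuous"`.
#' @return A tibble of class `mr_sumstats` with attributes `trait_id` and
#'   `trait_type`.
#' @examples
#' as_sumstats(
#'   data.frame(
#'     variant_id = "rs1", effect_allele = "a", other_allele = "g",
#'     eaf = 0.3, beta = 0.1, se = 0.02, pvalue = 1e-6
#'   ),
#'   trait_id = "taxon_x", trait_type = "continuous"
#' )
#' @export
as_sumstats <- function(x, trait_id, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "pvalue")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("summary statistics lack mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrflow_config_error")
  }
  x <- tibble::as_tibble(x)
  for (col in c("chromosome", "position", "eaf", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- dplyr::mutate(
    x,
    variant_id    = as.character(.data$variant_id),
    chromosome    = as.character(.data$chromosome),
    position      = as.integer(.data$position),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele  = toupper(as.character(.data$other_allele)),
    eaf           = as.numeric(.data$eaf),
    beta          = as.numeric(.data$beta),
    se            = as.numeric(.data$se),
    pvalue        = pmax(as.numeric(.data$pvalue), 1e-300),
    n             = as.numeric(.data$n)
  )
  ok <- is.finite(x$beta) & is.finite(x$se) & x$se > 0 &
    is.finite(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1 &
    x$effect_allele != x$other_allele &
    x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    inform(paste0("as_sumstats: rejected ", n_bad,
                  " row(s) violating summary-statistic invariants"))
    x <- x[ok, ]
  }
  if (nrow(x) == 0) {
    abort("summary statistics contain no valid records",
          class = "mrflow_input_error")
  }
  dup <- duplicated(x$variant_id)
  if (any(dup)) {
    inform(paste0("as_sumstats: dropped ", sum(dup),
                  " duplicated variant_id row(s), keeping first"))
    x <- x[!dup, ]
  }
  x <- x[, c("variant_id", "chromosome", "position", "effect_allele",
             "other_allele", "eaf", "beta", "se", "pvalue", "n")]
  structure(x,
            trait_id = trait_id,
            trait_type = trait_type,
            class = c("mr_sumstats", class(tibble::tibble())))
}

#' @rdname as_sumstats
#' @export
trait_id <- function(x) attr(x, "trait_id", exact = TRUE)

#' @rdname as_sumstats
#' @export
trait_type <- function(x) attr(x, "trait_type", exact = TRUE) %||% "continuous"

#' Default column mapping for GWAS summary-statistics files
#'
#' The defaults follow the GWAS-SSF convention (`variant_id`, `chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`).
#' Override individual entries for files with other headers, e.g.
#' `sumstats_columns(variant_id = "SNP", pvalue = "P")`.
#'
#' @param ... Named overrides; names are internal field names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`), values are the
#'   column headers in the file.
#' @return Named character vector mapping internal fields to file columns.
#' @export
sumstats_columns <- function(...) {
  map <- c(variant_id = "variant_id",
           chromosome = "chromosome",
           position = "base_pair_location",
           effect_allele = "effect_allele",
           other_allele = "other_allele",
           eaf = "effect_allele_frequency",
           beta = "beta",
           se = "standard_error",
           pvalue = "p_value",
           n = "n")
  override <- c(...)
  if (length(override) > 0) {
    bad <- setdiff(names(override), names(map))
    if (length(bad) > 0) {
      abort(paste0("unknown summary-statistic field(s): ",
                   paste(bad, collapse = ", ")),
            class = "mrflow_config_error")
    }
    map[names(override)] <- override
  }
  map
}

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path Path to a delimited file with a header row. The delimiter is
#'   guessed from the header (tab or comma) unless given.
#' @param trait_id,trait_type Trait identity, see [as_sumstats()].
#' @param column_map Mapping from internal field names to file headers, see
#'   [sumstats_columns()]. Mapped optional columns (`chromosome`,
#'   `position`, `eaf`, `n`) that are absent from the file are filled with
#'   `NA`; absent mandatory columns are an error.
#' @param delim Field delimiter, or `NULL` to guess.
#' @return An `mr_sumstats` tibble; rows with unparseable or invalid
#'   effect/SE fields are rejected with a message.
#' @seealso [as_sumstats()] for the validation rules.
#' @export
read_sumstats <- function(path, trait_id,
                          trait_type = c("continuous", "binary"),
                          column_map = sumstats_columns(),
                          delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mrflow_input_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0) {
      abort(paste0("empty summary-statistics file: ", path),
            class = "mrflow_input_error")
    }
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0("empty summary-statistics file: ", path),
          class = "mrflow_input_error")
  }
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta",
                 "se", "pvalue")
  for (field in mandatory) {
    if (!column_map[[field]] %in% names(raw)) {
      abort(paste0("mapped column '", column_map[[field]], "' for field '",
                   field, "' not present in ", path),
            class = "mrflow_config_error")
    }
  }
  pick <- function(field) {
    col <- column_map[[field]]
    if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  out <- tibble::tibble(
    variant_id = pick("variant_id"),
    chromosome = pick("chromosome"),
    position = suppressWarnings(as.integer(pick("position"))),
    effect_allele = pick("effect_allele"),
    other_allele = pick("other_allele"),
    eaf = suppressWarnings(as.numeric(pick("eaf"))),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    pvalue = suppressWarnings(as.numeric(pick("pvalue"))),
    n = suppressWarnings(as.numeric(pick("n")))
  )
  as_sumstats(out, trait_id = trait_id, trait_type = trait_type)
}

#' Linkage-disequilibrium matrices
#'
#' An LD matrix holds pairwise squared correlations (r-squared) between
#' variants as a symmetric numeric matrix with unit diagonal, dimnames set
#' to the variant ids, and an optional `positions` attribute (a tibble with
#' `variant_id`, `chromosome`, `position`).
#'
#' @param r2 Square numeric matrix of squared correlations in \[0, 1\].
#' @param variant_ids Character vector of ids, one per row/column.
#' @param positions Optional tibble with columns `variant_id`,
#'   `chromosome`, `position`.
#' @return A matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids, positions = NULL) {
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == ncol(r2), length(variant_ids) == nrow(r2))
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    abort("LD r-squared values must lie in [0, 1]",
          class = "mrflow_input_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-6) {
    abort("LD matrix is asymmetric beyond tolerance 1e-6",
          class = "mrflow_input_error")
  }
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(r2, positions = positions, class = c("ld_matrix", "matrix"))
}

#' Look up pairwise r-squared in an LD matrix
#'
#' Pairs absent from the matrix are treated as unlinked (r-squared 0);
#' self-pairs are always 1.
#'
#' @param ld An [ld_matrix()], or `NULL` (all pairs unlinked).
#' @param a,b Variant id vectors (recycled to common length).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  k <- max(length(a), length(b))
  a <- rep_len(as.character(a), k)
  b <- rep_len(as.character(b), k)
  out <- ifelse(a == b, 1, 0)
  if (!is.null(ld)) {
    ids <- rownames(ld)
    hit <- a %in% ids & b %in% ids
    if (any(hit)) out[hit] <- ld[cbind(a[hit], b[hit])]
  }
  out
}

#' Read an LD matrix from delimited text
#'
#' Two layouts are supported. `"square"`: a header row of variant ids
#' followed by the numeric r-squared matrix (first column may repeat the
#' ids). `"long"`: three columns `id_a`, `id_b`, `r2`; pairs are mirrored,
#' absent pairs default to 0 and self-pairs are forced to 1.
#'
#' @param path File path.
#' @param format `"square"` or `"long"`.
#' @return An [ld_matrix()].
#' @export
read_ld <- function(path, format = c("square", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mrflow_input_error")
  }
  if (format == "square") {
    raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    if (is.character(raw[[1]])) {
      ids <- as.character(raw[[1]])
      m <- as.matrix(raw[, -1, drop = FALSE])
    } else {
      ids <- names(raw)
      m <- as.matrix(raw)
    }
    storage.mode(m) <- "double"
    ld_matrix(m, variant_ids = ids)
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    need <- c("id_a", "id_b", "r2")
    if (!all(need %in% names(raw))) {
      abort("long-format LD file needs columns id_a, id_b, r2",
            class = "mrflow_input_error")
    }
    if (any(raw$r2 < 0 | raw$r2 > 1 | !is.finite(raw$r2))) {
      abort("LD r-squared values must lie in [0, 1]",
            class = "mrflow_input_error")
    }
    ids <- sort(unique(c(raw$id_a, raw$id_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(raw$id_a, raw$id_b)] <- raw$r2
    m[cbind(raw$id_b, raw$id_a)] <- raw$r2
    diag(m) <- 1
    ld_matrix(m, variant_ids = ids)
  }
}

#' Write MR estimates to a results TSV
#'
#' Writes one row per estimate with columns `exposure`, `outcome`,
#' `method`, `nsnp`, `beta`, `se`, `or_`, `ci_low`, `ci_high`, `pvalue`,
#' `q_stat`, `q_pvalue`, `egger_intercept_p`. `ci_low`/`ci_high` are on the
#' beta (log-odds) scale; the odds-ratio column `or_ = exp(beta)` is
#' populated only for binary outcomes. Numbers are serialized at full
#' double precision (well beyond 6 significant digits), so a read-back
#' reproduces them.
#'
#' @param estimates Tibble of MR estimates as produced by
#'   [mr_estimate_all()] (or a compatible tibble with at least `method`,
#'   `nsnp`, `beta`, `se`, `pvalue`). Optional columns `exposure`,
#'   `outcome`, `ci_low`, `ci_high`, `q_stat`, `q_pvalue`,
#'   `egger_intercept_p` are carried through when present.
#' @param path Output file path.
#' @param binary_outcome Populate the odds-ratio column? Defaults to `TRUE`
#'   when `estimates` carries an `outcome_type` attribute equal to
#'   `"binary"`, else `TRUE` (disease outcomes are the common case).
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(estimates, path,
                             binary_outcome = NULL) {
  if (is.null(estimates) || nrow(estimates) == 0) {
    abort("no estimates to write", class = "mrflow_input_error")
  }
  if (is.null(binary_outcome)) {
    ot <- attr(estimates, "outcome_type", exact = TRUE)
    binary_outcome <- is.null(ot) || identical(ot, "binary")
  }
  grab <- function(col, default = NA_real_) {
    if (col %in% names(estimates)) estimates[[col]] else
      rep(default, nrow(estimates))
  }
  out <- tibble::tibble(
    exposure = as.character(grab("exposure", NA_character_)),
    outcome = as.character(grab("outcome", NA_character_)),
    method = estimates$method,
    nsnp = estimates$nsnp,
    beta = estimates$beta,
    se = estimates$se,
    or_ = if (binary_outcome) exp(estimates$beta) else NA_real_,
    ci_low = grab("ci_low"),
    ci_high = grab("ci_high"),
    pvalue = estimates$pvalue,
    q_stat = grab("q_stat"),
    q_pvalue = grab("q_pvalue"),
    egger_intercept_p = grab("intercept_p")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
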