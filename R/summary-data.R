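#' Read a per-SNP summary-statistics table
#'
#' Reads a tab- or comma-delimited table of per-SNP association summary
#' statistics (one row per SNP) as published by GWAS consortia. The delimiter
#' is auto-detected from the header line; CRLF line endings are accepted.
#'
#' Required columns are `snp`, `effect_allele`, `other_allele`, `beta`, `se`;
#' an optional `eaf` (effect-allele frequency) column is carried through.
#' Effects must be per effect-allele copy, in SD units of the trait for
#' quantitative traits or log-odds for binary traits.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param trait Trait label attached to every record (e.g. `"urate"`).
#' @param source Optional free-text provenance label.
#'
#' @return A tibble with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `trait`, `source` (and `eaf` if present).
#'
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse",
#'              "rs1\tA\tG\t0.05\t0.01"), path)
#' read_summary_table(path, trait = "urate")
#' @export
read_summary_table <- function(path, trait = "trait", source = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("summary table not found: ", path), class = "mrpipe_io_error")
  }
  header <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_guess()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  names(tab) <- tolower(names(tab))
  required <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "mrpipe_format_error"
    )
  }
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(
      paste0(
        "malformed rows in ", path, " at line(s): ",
        paste(unique(prob$row + 1L), collapse = ", ")
      ),
      class = "mrpipe_format_error"
    )
  }
  out <- tibble(
    snp = as.character(tab$snp),
    effect_allele = toupper(as.character(tab$effect_allele)),
    other_allele = toupper(as.character(tab$other_allele)),
    beta = as.numeric(tab$beta),
    se = as.numeric(tab$se),
    trait = trait,
    source = source
  )
  if ("eaf" %in% names(tab)) out$eaf <- as.numeric(tab$eaf)
  validate_summary(out, label = trait)
  out
}

#' Write a per-SNP summary-statistics table
#'
#' Inverse of [read_summary_table()]; writes the canonical tab-delimited
#' layout (`snp`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf` if
#' present).
#'
#' @param data A summary tibble as returned by [read_summary_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(data, path) {
  keep <- intersect(
    c("snp", "effect_allele", "other_allele", "beta", "se", "eaf"),
    names(data)
  )
  readr::write_tsv(data[keep], path, progress = FALSE)
  invisible(path)
}

# Validates the SnpAssociation invariants, naming offending SNPs.
validate_summary <- function(data, label = "summary") {
  required <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(
      paste0(label, ": missing column(s): ", paste(missing, collapse = ", ")),
      class = "mrpipe_format_error"
    )
  }
  bad_se <- data$snp[!is.finite(data$se) | data$se <= 0]
  if (length(bad_se) > 0) {
    abort(
      paste0(label, ": non-positive or missing SE for SNP(s): ",
             paste(bad_se, collapse = ", ")),
      class = "mrpipe_validation_error"
    )
  }
  bad_beta <- data$snp[!is.finite(data$beta)]
  if (length(bad_beta) > 0) {
    abort(
      paste0(label, ": non-finite beta for SNP(s): ",
             paste(bad_beta, collapse = ", ")),
      class = "mrpipe_validation_error"
    )
  }
  same <- data$snp[data$effect_allele == data$other_allele]
  if (length(same) > 0) {
    abort(
      paste0(label, ": effect and other allele identical for SNP(s): ",
             paste(same, collapse = ", ")),
      class = "mrpipe_validation_error"
    )
  }
  if (anyDuplicated(data$snp)) {
    abort(
      paste0(label, ": duplicated SNP id(s): ",
             paste(unique(data$snp[duplicated(data$snp)]), collapse = ", ")),
      class = "mrpipe_validation_error"
    )
  }
  invisible(data)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) {
  !is.na(.complement[ea]) & .complement[ea] == oa
}

# Orientation of one observed allele pair relative to the reference pair:
# +1 keep the beta, -1 flip its sign, NA irreconcilable (drop).
# Palindromic reference pairs (A/T, G/C) are kept only on an exact letter
# match; any other configuration is strand-ambiguous without frequency data.
.allele_orientation <- function(ref_ea, ref_oa, ea, oa) {
  pal <- .is_palindromic(ref_ea, ref_oa)
  direct <- ea == ref_ea & oa == ref_oa
  swapped <- ea == ref_oa & oa == ref_ea
  cea <- .complement[ea]
  coa <- .complement[oa]
  comp <- !is.na(cea) & !is.na(coa) & cea == ref_ea & coa == ref_oa
  comp_swapped <- !is.na(cea) & !is.na(coa) & cea == ref_oa & coa == ref_ea
  out <- rep(NA_real_, length(ea))
  out[direct] <- 1
  out[!pal & swapped] <- -1
  out[!pal & comp] <- 1
  out[!pal & comp_swapped] <- -1
  out
}

#' Harmonise exposure, outcome, and covariate summary statistics
#'
#' Aligns per-SNP effect estimates from different studies to the exposure
#' study's effect allele, producing the allele-consistent instrument that the
#' MR estimators consume. Where a study reports the opposite allele the beta
#' sign is flipped; strand flips are resolved by base complement.
#' Strand-ambiguous palindromic SNPs (A/T or G/C) whose reported letters do
#' not match the exposure exactly are dropped with a warning, as are SNPs
#' whose allele pairs cannot be reconciled at all.
#'
#' @param exposure Summary tibble for the exposure ([read_summary_table()]).
#' @param outcome Summary tibble for the outcome.
#' @param covariates Named list of summary tibbles, one per measured
#'   pleiotropic phenotype (e.g. `list(SBP = ..., HDL = ...)`).
#' @param allow_missing_covariates If `FALSE` (default) a covariate table
#'   lacking an instrument SNP is an error; if `TRUE` the missing cell is
#'   imputed as beta 0 with infinite SE (no information), which excludes it
#'   from any SE-weighted use.
#'
#' @return An `mr_instrument` tibble with one row per retained SNP and
#'   columns `snp`, `bx`, `se_x`, `by`, `se_y`, then `bc_<label>` and
#'   `se_c_<label>` per covariate. Covariate labels are recorded in the
#'   `covariates` attribute and dropped SNPs (with reasons) in the `dropped`
#'   attribute.
#'
#' @seealso [as_instrument()] to build an instrument from an already-wide
#'   table, [write_instrument()]/[read_instrument()] for file round-trips.
#' @export
harmonise <- function(exposure, outcome, covariates = list(),
                      allow_missing_covariates = FALSE) {
  validate_summary(exposure, "exposure")
  validate_summary(outcome, "outcome")
  if (length(covariates) > 0 &&
      (is.null(names(covariates)) || any(names(covariates) == ""))) {
    abort("covariates must be a named list", class = "mrpipe_parameter_error")
  }
  for (lab in names(covariates)) validate_summary(covariates[[lab]], lab)

  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) {
    abort("no SNPs shared between exposure and outcome tables",
          class = "mrpipe_empty_instrument_error")
  }
  dropped <- tibble(snp = character(), reason = character())
  absent <- setdiff(exposure$snp, outcome$snp)
  if (length(absent) > 0) {
    warn(paste0("SNP(s) absent from outcome dropped: ",
                paste(absent, collapse = ", ")))
    dropped <- dplyr::bind_rows(
      dropped, tibble(snp = absent, reason = "absent from outcome")
    )
  }
  exp_kept <- exposure[exposure$snp %in% shared, , drop = FALSE]
  out_idx <- match(exp_kept$snp, outcome$snp)
  orient <- .allele_orientation(
    exp_kept$effect_allele, exp_kept$other_allele,
    outcome$effect_allele[out_idx], outcome$other_allele[out_idx]
  )
  if (anyNA(orient)) {
    bad <- exp_kept$snp[is.na(orient)]
    warn(paste0("allele pair irreconcilable or palindromic-ambiguous, ",
                "SNP(s) dropped: ", paste(bad, collapse = ", ")))
    dropped <- dplyr::bind_rows(
      dropped, tibble(snp = bad, reason = "irreconcilable alleles vs outcome")
    )
    keep <- !is.na(orient)
    exp_kept <- exp_kept[keep, , drop = FALSE]
    out_idx <- out_idx[keep]
    orient <- orient[keep]
  }
  if (nrow(exp_kept) == 0) {
    abort("no SNPs remain after allele harmonisation",
          class = "mrpipe_empty_instrument_error")
  }

  inst <- tibble(
    snp = exp_kept$snp,
    effect_allele = exp_kept$effect_allele,
    other_allele = exp_kept$other_allele,
    bx = exp_kept$beta,
    se_x = exp_kept$se,
    by = orient * outcome$beta[out_idx],
    se_y = outcome$se[out_idx]
  )

  for (lab in names(covariates)) {
    ctab <- covariates[[lab]]
    cidx <- match(inst$snp, ctab$snp)
    miss <- inst$snp[is.na(cidx)]
    if (length(miss) > 0 && !allow_missing_covariates) {
      abort(
        paste0("covariate '", lab, "' missing SNP(s): ",
               paste(miss, collapse = ", "),
               " (set allow_missing_covariates = TRUE to impute zero weight)"),
        class = "mrpipe_validation_error"
      )
    }
    corient <- rep(NA_real_, nrow(inst))
    has <- !is.na(cidx)
    corient[has] <- .allele_orientation(
      inst$effect_allele[has], inst$other_allele[has],
      ctab$effect_allele[cidx[has]], ctab$other_allele[cidx[has]]
    )
    amb <- inst$snp[has & is.na(corient)]
    if (length(amb) > 0) {
      if (!allow_missing_covariates) {
        abort(
          paste0("covariate '", lab, "' alleles irreconcilable for SNP(s): ",
                 paste(amb, collapse = ", ")),
          class = "mrpipe_validation_error"
        )
      }
      warn(paste0("covariate '", lab, "': irreconcilable alleles treated as ",
                  "missing for SNP(s): ", paste(amb, collapse = ", ")))
    }
    bc <- ifelse(has & !is.na(corient), corient * ctab$beta[cidx], 0)
    sec <- ifelse(has & !is.na(corient), ctab$se[cidx], Inf)
    inst[[paste0("bc_", lab)]] <- bc
    inst[[paste0("se_c_", lab)]] <- sec
  }

  new_instrument(inst, covariates = names(covariates), dropped = dropped)
}

new_instrument <- function(data, covariates = character(), dropped = NULL) {
  out <- as_tibble(data)
  attr(out, "covariates") <- as.character(covariates)
  attr(out, "dropped") <- dropped
  class(out) <- c("mr_instrument", class(tibble()))
  out
}

#' Coerce a wide per-SNP table to an MR instrument
#'
#' Validates and classes a wide table with columns `snp`, `bx`, `se_x`,
#' `by`, `se_y` and optional covariate columns `bc_<label>` / `se_c_<label>`
#' (all effects already aligned to a common effect allele per SNP).
#'
#' @param data A data frame in the wide instrument layout.
#' @param covariates Covariate labels; by default inferred from `bc_*`
#'   column names.
#' @return An `mr_instrument` tibble.
#' @export
as_instrument <- function(data, covariates = NULL) {
  data <- as_tibble(data)
  required <- c("snp", "bx", "se_x", "by", "se_y")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("instrument missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mrpipe_format_error")
  }
  if (is.null(covariates)) {
    covariates <- sub("^bc_", "", grep("^bc_", names(data), value = TRUE))
  }
  for (lab in covariates) {
    for (col in paste0(c("bc_", "se_c_"), lab)) {
      if (!col %in% names(data)) {
        abort(paste0("instrument missing covariate column: ", col),
              class = "mrpipe_format_error")
      }
    }
  }
  if (nrow(data) < 1) {
    abort("instrument has no SNPs", class = "mrpipe_empty_instrument_error")
  }
  for (col in c("se_x", "se_y", paste0("se_c_", covariates))) {
    if (any(!is.na(data[[col]]) & data[[col]] <= 0)) {
      abort(paste0("non-positive values in ", col),
            class = "mrpipe_validation_error")
    }
  }
  new_instrument(data, covariates = covariates,
                 dropped = attr(data, "dropped"))
}

#' Covariate labels carried by an instrument
#' @param instrument An `mr_instrument`.
#' @return Character vector of labels (possibly empty).
#' @export
instrument_covariates <- function(instrument) {
  attr(instrument, "covariates") %||%
    sub("^bc_", "", grep("^bc_", names(instrument), value = TRUE))
}

# J x M matrix of covariate betas (M = 0 gives a 0-column matrix).
.cov_matrix <- function(instrument, labels, prefix = "bc_") {
  cols <- paste0(prefix, labels)
  m <- as.matrix(instrument[, cols, drop = FALSE])
  colnames(m) <- labels
  m
}

#' Write / read a harmonised instrument
#'
#' The on-disk format is a single wide TSV with columns
#' `snp bx se_x by se_y bc_<label> se_c_<label> ...`.
#'
#' @param instrument An `mr_instrument`.
#' @param path File path.
#' @return `write_instrument()` returns `path` invisibly;
#'   `read_instrument()` returns an `mr_instrument`.
#' @export
write_instrument <- function(instrument, path) {
  readr::write_tsv(as_tibble(instrument), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("instrument file not found: ", path),
          class = "mrpipe_io_error")
  }
  as_instrument(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}
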