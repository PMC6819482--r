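# Input readers, validation, expression normalization, mutation-call
# filtering and subgroup assignment.

#' Read a gene-by-sample expression table
#'
#' Expects a TSV whose first column holds gene symbols and whose remaining
#' columns each hold one sample, with a header row of sample identifiers.
#' Values must be non-negative and gene symbols unique.
#'
#' @param path Path to the TSV file.
#' @param units Units of the stored values, `"FPKM"` or `"TPM"`. Recorded on
#'   the returned object and checked by [fpkm_to_tpm()].
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample, carrying a `units` attribute.
#' @export
read_expression_tsv <- function(path, units = c("TPM", "FPKM")) {
  units <- match.arg(units)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "gene"
  as_expression(raw, units = units)
}

#' Validate a data frame as an expression matrix
#'
#' @param x Data frame with a `gene` character column and one numeric column
#'   per sample.
#' @param units `"FPKM"` or `"TPM"`.
#' @return The validated tibble with a `units` attribute.
#' @export
as_expression <- function(x, units = c("TPM", "FPKM")) {
  units <- match.arg(units)
  x <- as_tibble(x)
  if (!"gene" %in% names(x)) {
    abort("expression table must have a 'gene' column")
  }
  x <- relocate(x, "gene")
  if (anyDuplicated(x$gene) > 0) {
    dup <- unique(x$gene[duplicated(x$gene)])
    abort(paste0("duplicated gene symbols: ", paste(head(dup, 5), collapse = ", ")))
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression values must be numeric")
  if (anyNA(vals)) abort("expression values must not be missing")
  if (any(vals < 0)) abort("expression values must be non-negative")
  attr(x, "units") <- units
  x
}

#' Units tag of an expression table
#'
#' @param x An expression tibble from [read_expression_tsv()] or
#'   [as_expression()].
#' @return `"FPKM"` or `"TPM"` (or `NULL` if untagged).
#' @export
expression_units <- function(x) attr(x, "units", exact = TRUE)

#' Convert FPKM expression values to TPM
#'
#' Per sample, TPM rescales FPKM to a fixed library mass of one million:
#' `TPM(g, s) = FPKM(g, s) / sum_g FPKM(g, s) * 1e6`. Each sample column of
#' the result sums to 1e6.
#'
#' @param x Expression tibble tagged as FPKM.
#' @return The same tibble rescaled, tagged as TPM.
#' @export
#' @examples
#' expr <- as_expression(
#'   tibble::tibble(gene = c("A", "B"), s1 = c(2, 8)),
#'   units = "FPKM"
#' )
#' fpkm_to_tpm(expr)
fpkm_to_tpm <- function(x) {
  units <- expression_units(x)
  if (is.null(units)) abort("expression table has no units tag; use as_expression()")
  if (units == "TPM") {
    abort("expression is already in TPM; refusing to renormalize")
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  totals <- colSums(vals)
  if (any(totals == 0)) {
    bad <- colnames(vals)[totals == 0][1]
    abort(paste0("sample '", bad, "' has an all-zero expression column"))
  }
  out <- x
  out[, -1] <- sweep(vals, 2, totals, "/") * 1e6
  attr(out, "units") <- "TPM"
  out
}

#' Read the clinical table
#'
#' Expects columns `patient_id`, `os_days`, `event` (0/1), `stage`, `gender`,
#' `age`, `smoking`, `subtype` and `mutation_burden` (empty allowed).
#' Exactly one row per patient is required; duplicate-aliquot arbitration is
#' assumed done upstream.
#'
#' @param path Path to the TSV file.
#' @return A validated clinical tibble.
#' @export
read_clinical_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           os_days = readr::col_double(),
                           event = readr::col_integer(),
                           stage = readr::col_character(),
                           gender = readr::col_character(),
                           age = readr::col_double(),
                           smoking = readr::col_character(),
                           subtype = readr::col_character(),
                           mutation_burden = readr::col_double()
                         ))
  validate_clinical(raw)
}

#' Validate a clinical table
#'
#' @param x Data frame of per-patient clinical records.
#' @return The validated tibble (`event` coerced to logical, `subtype`
#'   missing values recoded to `"unknown"`).
#' @export
validate_clinical <- function(x) {
  x <- as_tibble(x)
  required <- c("patient_id", "os_days", "event")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$patient_id) > 0) {
    dup <- unique(x$patient_id[duplicated(x$patient_id)])
    abort(paste0("duplicate patient rows (one aliquot per patient expected): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (anyNA(x$os_days) || any(x$os_days <= 0)) {
    abort("os_days must be strictly positive and non-missing")
  }
  if (!all(x$event %in% c(0, 1, TRUE, FALSE))) {
    abort("event must be 0/1")
  }
  x$event <- as.logical(x$event)
  if (!"subtype" %in% names(x)) x$subtype <- "unknown"
  x$subtype[is.na(x$subtype)] <- "unknown"
  bad_subtype <- setdiff(unique(x$subtype), c("PI", "PP", "TRU", "unknown"))
  if (length(bad_subtype) > 0) {
    abort(paste0("unknown transcriptional subtype labels: ",
                 paste(bad_subtype, collapse = ", ")))
  }
  x
}

#' Read a mutation-call table
#'
#' Expects a MAF-compatible subset: columns `patient_id`, `gene`,
#' `vep_impact`, `sift`, `polyphen` (the latter two may be empty).
#'
#' @param path Path to the TSV file.
#' @return Tibble of mutation calls.
#' @export
read_mutations_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "gene", "vep_impact")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mutation table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"sift" %in% names(raw)) raw$sift <- NA_character_
  if (!"polyphen" %in% names(raw)) raw$polyphen <- NA_character_
  as_tibble(raw)
}

#' Filter mutation calls by predicted functional impact
#'
#' A call is retained if its VEP impact is not LOW/MODIFIER, or if SIFT or
#' PolyPhen annotate it as damaging. Low-impact calls with no damaging
#' annotation are excluded, so silent passengers do not flip a patient to
#' mutant status.
#'
#' @param calls Tibble with `vep_impact`, `sift`, `polyphen` columns.
#' @param damaging_sift SIFT categories counted as damaging.
#' @param damaging_polyphen PolyPhen categories counted as damaging.
#' @return The retained subset of `calls`.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   patient_id = c("P1", "P2"), gene = c("KRAS", "KRAS"),
#'   vep_impact = c("LOW", "MODERATE"),
#'   sift = c("tolerated", NA), polyphen = c("benign", NA)
#' )
#' filter_mutation_calls(calls)
filter_mutation_calls <- function(calls,
                                  damaging_sift = c("deleterious",
                                                    "deleterious_low_confidence"),
                                  damaging_polyphen = c("probably_damaging",
                                                        "possibly_damaging")) {
  calls <- as_tibble(calls)
  known <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  bad <- which(!(calls$vep_impact %in% known))
  if (length(bad) > 0) {
    abort(paste0("unknown vep_impact value(s) in row(s) ",
                 paste(head(bad, 5), collapse = ", "), ": ",
                 paste(unique(calls$vep_impact[bad]), collapse = ", ")))
  }
  keep <- !(calls$vep_impact %in% c("LOW", "MODIFIER")) |
    (!is.na(calls$sift) & calls$sift %in% damaging_sift) |
    (!is.na(calls$polyphen) & calls$polyphen %in% damaging_polyphen)
  calls[keep, , drop = FALSE]
}

#' Assign patients to the twelve overlapping subgroups
#'
#' Genotype subgroups (`KRASmut`/`KRASwt`, `TP53mut`/`TP53wt`,
#' `STK11mut`/`STK11wt`, `EGFRmut`) come from the retained mutation calls: a
#' patient is `geneX`-mutant iff at least one retained call hits gene X.
#' `PDL1high` holds samples whose CD274 TPM exceeds twice the cohort mean;
#' the remainder form `PDL1low`. `PI`/`PP`/`TRU` are copied from the clinical
#' `subtype` labels (patients with `subtype == "unknown"` belong to none).
#'
#' @param clinical Validated clinical tibble (defines the analyzed cohort).
#' @param calls Mutation calls already passed through
#'   [filter_mutation_calls()].
#' @param expression Expression tibble in TPM containing CD274.
#' @return Tibble with `patient_id` and one logical column per subgroup.
#' @export
assign_subgroups <- function(clinical, calls, expression) {
  clinical <- validate_clinical(clinical)
  units <- expression_units(expression)
  if (!is.null(units) && units != "TPM") {
    abort("assign_subgroups() requires TPM expression; run fpkm_to_tpm() first")
  }
  if (!"CD274" %in% expression$gene) {
    abort("gene 'CD274' is absent from the expression matrix")
  }
  samples <- setdiff(names(expression), "gene")
  missing_expr <- setdiff(clinical$patient_id, samples)
  if (length(missing_expr) > 0) {
    abort(paste0("patients absent from expression matrix: ",
                 paste(head(missing_expr, 5), collapse = ", ")))
  }

  cd274 <- as.numeric(expression[expression$gene == "CD274", clinical$patient_id])
  pdl1_high <- cd274 > 2 * mean(cd274)

  mutant <- function(gene_symbol) {
    clinical$patient_id %in% calls$patient_id[calls$gene == gene_symbol]
  }

  tibble(
    patient_id = clinical$patient_id,
    KRASmut = mutant("KRAS"),
    KRASwt = !mutant("KRAS"),
    EGFRmut = mutant("EGFR"),
    TP53mut = mutant("TP53"),
    TP53wt = !mutant("TP53"),
    STK11mut = mutant("STK11"),
    STK11wt = !mutant("STK11"),
    PDL1high = pdl1_high,
    PDL1low = !pdl1_high,
    PI = clinical$subtype == "PI",
    PP = clinical$subtype == "PP",
    TRU = clinical$subtype == "TRU"
  )
}
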