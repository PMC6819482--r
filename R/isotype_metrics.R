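# Per-sample immunoglobulin composite metrics and median dichotomization.

#' Per-sample immunoglobulin isotype profiles
#'
#' Computes, for every sample column of a TPM expression table, the nine IGH
#' constant-gene values, the composite sums `IGH` (all nine) and `IgA`
#' (IGHA1 + IGHA2), the marker-gene values, and the derived ratios used in
#' the survival screens. Any ratio whose denominator is zero is missing
#' (`NA`), not zero or infinite, so zero-infiltration samples drop out of
#' that metric's split only.
#'
#' @param expression Expression tibble in TPM containing the nine IGH
#'   constant genes and the five marker genes.
#' @return A tibble with one row per sample: `sample_id`, the 14 gene TPMs,
#'   `IGH`, `IgA`, and columns `IGHG1_over_IGH`, `IGHG4_over_IGH`,
#'   `IgA_over_IGH`, `IGH_over_MS4A1`, `IGHG1_over_MS4A1`,
#'   `IGHG4_over_MS4A1`, `IgA_over_MS4A1`.
#' @export
#' @examples
#' expr <- as_expression(tibble::tibble(
#'   gene = c(igh_constant_genes(), marker_genes()),
#'   s1 = c(rep(1, 9), 2, 1, 1, 1, 1)
#' ))
#' isotype_profiles(expr)
isotype_profiles <- function(expression) {
  units <- expression_units(expression)
  if (!is.null(units) && units != "TPM") {
    abort("isotype_profiles() requires TPM expression; run fpkm_to_tpm() first")
  }
  needed <- c(igh_constant_genes(), marker_genes())
  absent <- setdiff(needed, expression$gene)
  if (length(absent) > 0) {
    abort(paste0("required gene(s) absent from expression matrix: ",
                 paste(absent, collapse = ", ")))
  }

  long <- expression |>
    filter(.data$gene %in% needed) |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "tpm") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "tpm")

  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

  long |>
    mutate(
      IGH = .data$IGHA1 + .data$IGHA2 + .data$IGHG1 + .data$IGHG2 +
        .data$IGHG3 + .data$IGHG4 + .data$IGHM + .data$IGHD + .data$IGHE,
      IgA = .data$IGHA1 + .data$IGHA2,
      IGHG1_over_IGH = safe_ratio(.data$IGHG1, .data$IGH),
      IGHG4_over_IGH = safe_ratio(.data$IGHG4, .data$IGH),
      IgA_over_IGH = safe_ratio(.data$IgA, .data$IGH),
      IGH_over_MS4A1 = safe_ratio(.data$IGH, .data$MS4A1),
      IGHG1_over_MS4A1 = safe_ratio(.data$IGHG1, .data$MS4A1),
      IGHG4_over_MS4A1 = safe_ratio(.data$IGHG4, .data$MS4A1),
      IgA_over_MS4A1 = safe_ratio(.data$IgA, .data$MS4A1)
    ) |>
    relocate("sample_id")
}

#' Split a metric at its median into high and low groups
#'
#' The median is computed over the non-missing values supplied (i.e. within
#' whatever subgroup the caller has subset to). A value is `"high"` iff it
#' is strictly above the median and `"low"` otherwise, so ties at the median
#' fall into the low group; missing values are `"excluded"`.
#'
#' @param x Numeric vector of per-patient metric values (NA allowed).
#' @param min_n Minimum number of non-missing values required (default 4).
#' @return Character vector of labels `"high"`, `"low"`, `"excluded"`,
#'   same length as `x`.
#' @export
#' @examples
#' median_split(c(1, 2, 3, 4))
#' median_split(c(1, 2, 2, 5))       # ties at the median fall low
#' median_split(c(7, NA, 3, 9, 1))   # missing values are excluded
median_split <- function(x, min_n = 4) {
  if (!is.numeric(x)) abort("median_split() expects a numeric vector")
  ok <- !is.na(x)
  if (sum(ok) < min_n) {
    abort(paste0("median_split() needs at least ", min_n,
                 " non-missing values; got ", sum(ok)))
  }
  if (length(unique(x[ok])) == 1) {
    abort("degenerate split: all non-missing values are identical")
  }
  med <- median(x[ok])
  out <- rep("excluded", length(x))
  out[ok] <- ifelse(x[ok] > med, "high", "low")
  out
}
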