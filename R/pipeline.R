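# End-to-end orchestration: normalize inputs, assign subgroups, compute
# metrics, run the survival screen (with multivariable confirmation), the
# clonality analysis, the burden correlation, and the V-J usage signature,
# and assemble a deterministic report bundle.

default_metrics <- function() {
  c("CD19", "IGH", "IGHG1", "IGHG4", "IgA",
    "IGHG1_over_IGH", "IGHG4_over_IGH", "IgA_over_IGH",
    "IGH_over_MS4A1", "IGHG1_over_MS4A1", "IGHG4_over_MS4A1",
    "IgA_over_MS4A1")
}

#' Run the full isotype-survival analysis
#'
#' Orchestrates every stage: FPKM-to-TPM conversion when needed, mutation
#' filtering and subgroup assignment, isotype profiles, the subgroup x
#' metric survival screen with Bonferroni adjustment and multivariable Cox
#' confirmation, per-sample clonality (when clonotype tables are supplied),
#' the Spearman correlation between IGHG1/IGH and mutation burden per
#' subgroup, and the V-J usage signature in the configured subgroup.
#' Identical inputs, parameters and seed yield identical output tables.
#'
#' @param expression Expression tibble (see [as_expression()]); converted
#'   with [fpkm_to_tpm()] if tagged FPKM.
#' @param clinical Clinical tibble (see [read_clinical_tsv()]).
#' @param mutations Mutation-call tibble; filtered internally with
#'   [filter_mutation_calls()].
#' @param clonotypes Optional clonotype tibble spanning samples; enables
#'   the clonality metrics and the V-J signature.
#' @param metrics Metric columns to screen (default [default_metrics()],
#'   plus `clonality_IgG1` / `clonality_IgA` when clonotypes are given).
#' @param subgroups Subgroup columns to screen (default
#'   [subgroup_names()]).
#' @param median_scope `"subgroup"` or `"cohort"` medians for the splits.
#' @param bonferroni_m Bonferroni family size (default: number of
#'   subgroups).
#' @param cox_covariates Covariates of the multivariable confirmation fits
#'   (default stage, gender, smoking, age and infiltration, where
#'   infiltration is `log2(PTPRC TPM + 1)`); `NULL` disables them.
#' @param min_reads Repertoire coverage threshold (strict; default 500).
#' @param downsample_to Downsampling target read count (default 500).
#' @param clonality_replicates Downsampling replicates averaged per sample
#'   (default 10).
#' @param signature_isotype Isotype of the V-J signature (default
#'   `"IgG1"`).
#' @param signature_subgroup Subgroup within which survival labels define
#'   the signature contrast (default `"KRASmut"`).
#' @param seed Integer seed; required when `clonotypes` are supplied.
#' @param output_dir Optional directory to write the report to (see
#'   [write_report()]).
#' @param force Overwrite a non-empty `output_dir`.
#' @return An object of class `ig_report`: list with `profiles`,
#'   `subgroups`, `survival`, `clonality`, `correlation`, `signature`,
#'   `manifest`.
#' @export
run_full_analysis <- function(expression, clinical, mutations,
                              clonotypes = NULL,
                              metrics = NULL,
                              subgroups = subgroup_names(),
                              median_scope = c("subgroup", "cohort"),
                              bonferroni_m = NULL,
                              cox_covariates = c("stage", "gender", "smoking",
                                                 "age", "infiltration"),
                              min_reads = 500, downsample_to = 500,
                              clonality_replicates = 10,
                              signature_isotype = "IgG1",
                              signature_subgroup = "KRASmut",
                              seed = NULL,
                              output_dir = NULL, force = FALSE) {
  median_scope <- match.arg(median_scope)
  clinical <- validate_clinical(clinical)
  if (!is.null(clonotypes) && is.null(seed)) {
    abort("a seed is required when clonotype tables are analyzed")
  }
  units <- expression_units(expression) %||% "TPM"
  if (units == "FPKM") expression <- fpkm_to_tpm(expression)

  filtered <- filter_mutation_calls(mutations)
  sg <- assign_subgroups(clinical, filtered, expression)
  profiles <- isotype_profiles(expression)

  data <- clinical |>
    left_join(profiles, by = c(patient_id = "sample_id")) |>
    left_join(sg, by = "patient_id") |>
    mutate(infiltration = log2(.data$PTPRC + 1))

  metrics <- metrics %||% default_metrics()
  clon <- NULL
  if (!is.null(clonotypes)) {
    clonotypes <- validate_clonotypes(clonotypes)
    clon <- purrr::map(c("IgG1", "IgA"), function(iso) {
      ct <- clonality_table(clonotypes, iso, min_reads = min_reads,
                            n_reads = downsample_to,
                            replicates = clonality_replicates,
                            seed = seed + match(iso, c("IgG1", "IgA")))
      ct$isotype <- iso
      ct
    }) |> purrr::list_rbind()
    clon_wide <- clon |>
      select("sample_id", "isotype", "clonality") |>
      tidyr::pivot_wider(names_from = "isotype", values_from = "clonality",
                         names_prefix = "clonality_")
    data <- left_join(data, clon_wide, by = c(patient_id = "sample_id"))
    for (col in c("clonality_IgG1", "clonality_IgA")) {
      if (!col %in% names(data)) data[[col]] <- NA_real_
    }
    metrics <- union(metrics, c("clonality_IgG1", "clonality_IgA"))
  }

  m <- bonferroni_m %||% length(subgroups)
  screen <- survival_screen(data, metrics, subgroups,
                            median_scope = median_scope, m = m)
  if (!is.null(cox_covariates)) {
    screen <- add_adjusted_cox(screen, data, cox_covariates,
                               median_scope = median_scope)
  }

  correlation <- purrr::map(c("ALL", subgroups), function(sgname) {
    sub <- if (sgname == "ALL") data else data[data[[sgname]], , drop = FALSE]
    res <- tryCatch(
      spearman_corr(sub$IGHG1_over_IGH, sub$mutation_burden),
      error = function(e) tibble(rho = NA_real_, p = NA_real_,
                                 n = sum(complete.cases(
                                   sub[, c("IGHG1_over_IGH",
                                           "mutation_burden")])))
    )
    mutate(res, subgroup = sgname, .before = 1)
  }) |> purrr::list_rbind()

  signature <- NULL
  if (!is.null(clonotypes)) {
    signature <- tryCatch({
      usage <- vj_usage(clonotypes, signature_isotype, min_reads = min_reads)
      members <- if (signature_subgroup == "ALL") {
        clinical$patient_id
      } else {
        sg$patient_id[sg[[signature_subgroup]]]
      }
      keep <- usage$sample_id %in% members
      usage <- usage[keep, , drop = FALSE]
      cohort_clin <- clinical[match(usage$sample_id, clinical$patient_id), ]
      labels <- survival_group_labels(cohort_clin)
      signature_pca(usage, labels)
    }, error = function(e) {
      warn(paste0("V-J signature stage skipped: ", conditionMessage(e)))
      NULL
    })
  }

  manifest <- list(
    package = "igsurv",
    version = as.character(packageVersion("igsurv")),
    seed = seed,
    parameters = list(
      metrics = metrics, subgroups = subgroups,
      median_scope = median_scope, bonferroni_m = m,
      cox_covariates = cox_covariates,
      min_reads = min_reads, downsample_to = downsample_to,
      clonality_replicates = clonality_replicates,
      signature_isotype = signature_isotype,
      signature_subgroup = signature_subgroup
    ),
    n_patients = nrow(clinical),
    input_hash = rlang::hash(list(expression, clinical, mutations,
                                  clonotypes))
  )
  manifest$config_hash <- rlang::hash(manifest$parameters)

  report <- structure(
    list(profiles = profiles, subgroups = sg, survival = screen,
         clonality = clon, correlation = correlation,
         signature = signature, manifest = manifest),
    class = "ig_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir, force = force)
  report
}

# Multivariable Cox confirmation per screen row: high/low indicator plus
# clinical covariates, within the subgroup. Degenerate rows stay NA.
add_adjusted_cox <- function(screen, data, covariates, median_scope) {
  adj <- purrr::pmap(screen[, c("subgroup", "metric")],
                     function(subgroup, metric) {
    out <- tibble(hr_adjusted = NA_real_, p_adjusted_cox = NA_real_)
    sub <- data[data[[subgroup]], , drop = FALSE]
    res <- tryCatch({
      vals <- sub[[metric]]
      labels <- if (median_scope == "cohort") {
        med <- median(data[[metric]], na.rm = TRUE)
        ifelse(is.na(vals), "excluded", ifelse(vals > med, "high", "low"))
      } else {
        median_split(vals)
      }
      sub <- sub[labels != "excluded", , drop = FALSE]
      sub$high <- as.integer(labels[labels != "excluded"] == "high")
      fit <- suppressMessages(
        cox_fit(sub, covariates = c("high", covariates))
      )
      td <- tidy(fit)
      td[td$term == "high", c("hazard_ratio", "p.value")]
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$hr_adjusted <- res$hazard_ratio
      out$p_adjusted_cox <- res$p.value
    }
    out
  }) |> purrr::list_rbind()
  bind_cols(screen, adj)
}

#' @export
print.ig_report <- function(x, ...) {
  cat("igsurv report:", x$manifest$n_patients, "patients;",
      nrow(x$survival), "subgroup x metric comparisons\n")
  hits <- x$survival |>
    filter(!is.na(.data$p.adjusted), .data$p.adjusted < 0.05) |>
    arrange(.data$p.adjusted)
  if (nrow(hits) > 0) {
    cat("Significant after Bonferroni (p.adjusted < 0.05):\n")
    print(select(hits, "subgroup", "metric", "n_high", "n_low",
                 "hazard_ratio", "p.value", "p.adjusted"))
  } else {
    cat("No comparison significant after Bonferroni adjustment.\n")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `metrics.tsv`, `subgroups.tsv`, `survival.tsv`,
#' `clonality.tsv`, `correlation.tsv`, `signature_loadings.tsv` /
#' `signature_scores.tsv` / `signature_group_diff.tsv` (when present) and
#' `manifest.json`. On any failure the partially written directory is
#' removed.
#'
#' @param report An `ig_report` from [run_full_analysis()].
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, force = FALSE) {
  stopifnot(inherits(report, "ig_report"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(paste0("output directory ", dir,
                 " is non-empty; use force = TRUE to overwrite"))
  }
  created <- !dir.exists(dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch({
    readr::write_tsv(report$profiles, file.path(dir, "metrics.tsv"))
    readr::write_tsv(report$subgroups, file.path(dir, "subgroups.tsv"))
    readr::write_tsv(report$survival, file.path(dir, "survival.tsv"))
    if (!is.null(report$clonality)) {
      readr::write_tsv(report$clonality, file.path(dir, "clonality.tsv"))
    }
    readr::write_tsv(report$correlation, file.path(dir, "correlation.tsv"))
    if (!is.null(report$signature)) {
      readr::write_tsv(report$signature$loadings,
                       file.path(dir, "signature_loadings.tsv"))
      readr::write_tsv(report$signature$scores,
                       file.path(dir, "signature_scores.tsv"))
      readr::write_tsv(report$signature$group_diff,
                       file.path(dir, "signature_group_diff.tsv"))
    }
    jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }, error = function(e) {
    if (created) unlink(dir, recursive = TRUE)
    abort(paste0("failed to write report bundle: ", conditionMessage(e)))
  })
  invisible(dir)
}

#' Read an input bundle from disk
#'
#' Counterpart of [write_simulation_bundle()]: reads `expression.tsv`,
#' `clinical.tsv`, `mutations.tsv` and the per-sample clonotype tables
#' under `clonotypes/` from a directory.
#'
#' @param dir Bundle directory.
#' @param expression_units Units tag of the stored expression values.
#' @return A list with `expression`, `clinical`, `mutations`,
#'   `clonotypes` (`NULL` when absent).
#' @export
read_input_bundle <- function(dir, expression_units = "TPM") {
  clon_dir <- file.path(dir, "clonotypes")
  list(
    expression = read_expression_tsv(file.path(dir, "expression.tsv"),
                                     units = expression_units),
    clinical = read_clinical_tsv(file.path(dir, "clinical.tsv")),
    mutations = read_mutations_tsv(file.path(dir, "mutations.tsv")),
    clonotypes = if (dir.exists(clon_dir)) read_clonotype_dir(clon_dir)
  )
}
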