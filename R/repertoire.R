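# BCR repertoire analysis: clonotype table IO, coverage filtering,
# hypergeometric downsampling, clonality, V-family collapsing, V-J usage
# matrices and the PCA usage signature.

#' Read a per-sample clonotype table
#'
#' Reads a VDJtools-style TSV with columns `count`, `freq`, `cdr3nt`,
#' `cdr3aa`, `v`, `d`, `j` plus an `isotype` column; the `d` column may be
#' absent. If the file has no `sample_id` column, the file name (without
#' extension) is used.
#'
#' @param path Path to the TSV file.
#' @param sample_id Optional explicit sample identifier.
#' @return Tibble of clonotypes with a `sample_id` column.
#' @export
read_clonotype_tsv <- function(path, sample_id = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "j", "isotype")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("clonotype table ", path, " lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"d" %in% names(raw)) raw$d <- NA_character_
  if (!"sample_id" %in% names(raw)) {
    raw$sample_id <- sample_id %||%
      sub("\\.[^.]*$", "", basename(path))
  }
  validate_clonotypes(raw)
}

#' Read all clonotype tables in a directory
#'
#' @param dir Directory of per-sample clonotype TSV files (one file per
#'   sample, sample id taken from the file name).
#' @param pattern File pattern (default `"\\.tsv$"`).
#' @return One tibble of clonotypes across all samples.
#' @export
read_clonotype_dir <- function(dir, pattern = "\\.tsv$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) abort(paste0("no clonotype files found in ", dir))
  purrr::map(files, read_clonotype_tsv) |> purrr::list_rbind()
}

#' Validate a clonotype tibble
#'
#' @param x Tibble with `sample_id`, `count`, `cdr3nt`, `cdr3aa`, `v`, `j`,
#'   `isotype` columns.
#' @return The validated tibble.
#' @export
validate_clonotypes <- function(x) {
  x <- as_tibble(x)
  if (any(is.na(x$count)) || any(x$count < 1) || any(x$count != round(x$count))) {
    abort("clonotype counts must be positive integers")
  }
  bad_v <- !startsWith(x$v, "IGHV")
  if (any(bad_v)) {
    abort(paste0("v_call must start with 'IGHV'; offending: ",
                 paste(head(unique(x$v[bad_v]), 3), collapse = ", ")))
  }
  bad_j <- !startsWith(x$j, "IGHJ")
  if (any(bad_j)) {
    abort(paste0("j_call must start with 'IGHJ'; offending: ",
                 paste(head(unique(x$j[bad_j]), 3), collapse = ", ")))
  }
  x
}

#' Collapse an IGHV gene name to its family
#'
#' `IGHV3-11` and `IGHV3-13` both belong to family `IGHV3`: the family is
#' the leading digit block after `IGHV`.
#'
#' @param v_call Character vector of IGHV gene names.
#' @return Character vector of family names (`"IGHV3"`, ...).
#' @export
#' @examples
#' collapse_v_family(c("IGHV3-11", "IGHV6-1"))
collapse_v_family <- function(v_call) {
  m <- stringr::str_match(v_call, "^(IGHV\\d+)([-/*].*)?$")
  bad <- is.na(m[, 2])
  if (any(bad)) {
    abort(paste0("not an IGHV gene name: ",
                 paste(head(unique(v_call[bad]), 3), collapse = ", ")))
  }
  m[, 2]
}

#' Per-sample, per-isotype read totals
#'
#' @param clonotypes Clonotype tibble.
#' @return Tibble `sample_id`, `isotype`, `reads`.
#' @export
isotype_read_totals <- function(clonotypes) {
  clonotypes |>
    group_by(.data$sample_id, .data$isotype) |>
    summarise(reads = sum(.data$count), .groups = "drop")
}

#' Coverage filter for repertoire analyses
#'
#' A sample passes for a given isotype iff it has strictly more than
#' `min_reads` CDR3-covering reads of that isotype; 500 reads is the
#' smallest coverage at which clonality can be assessed reliably, so the
#' default threshold excludes a sample with exactly 500 reads.
#'
#' @param clonotypes Clonotype tibble (may span many samples).
#' @param isotype Isotype to assess, e.g. `"IgG1"` or `"IgA"`.
#' @param min_reads Threshold (default 500; strict inequality).
#' @return Tibble `sample_id`, `reads`, `pass` for every sample present in
#'   `clonotypes` (samples with no reads of the isotype have `reads = 0`).
#' @export
coverage_filter <- function(clonotypes, isotype, min_reads = 500) {
  all_samples <- unique(clonotypes$sample_id)
  clonotypes |>
    filter(.data$isotype == .env$isotype) |>
    group_by(.data$sample_id) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    right_join(tibble(sample_id = all_samples), by = "sample_id") |>
    mutate(reads = tidyr::replace_na(.data$reads, 0L),
           pass = .data$reads > min_reads) |>
    arrange(.data$sample_id)
}

# Multivariate hypergeometric draw: sample n reads without replacement from
# the multiset of reads implied by `counts`. Uses the current RNG state.
downsample_counts <- function(counts, n) {
  total <- sum(counts)
  if (total < n) abort("cannot downsample below the available read total")
  if (total == n) return(counts)
  clone_of_read <- rep.int(seq_along(counts), counts)
  picked <- clone_of_read[sample.int(total, n)]
  tabulate(picked, nbins = length(counts))
}

#' Downsample an isotype repertoire to a fixed read count
#'
#' Draws `n` reads uniformly without replacement from the pool of
#' CDR3-covering reads of the given isotype in each sample (a multivariate
#' hypergeometric draw), so that clonality is comparable across samples of
#' different sequencing depth. Clonotypes downsampled to zero are dropped
#' and frequencies recomputed.
#'
#' @param clonotypes Clonotype tibble.
#' @param isotype Isotype to downsample.
#' @param n Target read count (default 500).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Clonotype tibble of the chosen isotype with new `count` and
#'   `freq`; every sample's counts sum to exactly `n`.
#' @export
downsample_reads <- function(clonotypes, isotype, n = 500, seed) {
  if (missing(seed)) abort("downsample_reads() requires an explicit seed")
  sub <- filter(clonotypes, .data$isotype == .env$isotype)
  totals <- sub |> group_by(.data$sample_id) |> summarise(reads = sum(.data$count))
  low <- totals$sample_id[totals$reads < n]
  if (length(low) > 0) {
    abort(paste0("sample(s) with fewer than ", n, " '", isotype, "' reads: ",
                 paste(head(low, 5), collapse = ", "),
                 "; apply coverage_filter() first"))
  }
  withr::with_seed(seed, {
    sub |>
      group_by(.data$sample_id) |>
      group_modify(function(df, key) {
        df$count <- downsample_counts(df$count, n)
        df <- df[df$count > 0, , drop = FALSE]
        df$freq <- df$count / sum(df$count)
        df
      }) |>
      ungroup()
  })
}

#' Repertoire clonality
#'
#' Clonality is one minus the normalized Shannon-Wiener index of the
#' clonotype frequency distribution: with `p_i = count_i / sum(count)` and
#' `S` clonotypes, `H = -sum(p_i * log(p_i))` and
#' `clonality = 1 - H / log(S)`. It is 0 for a perfectly even repertoire
#' and approaches 1 under the dominance of a single clone; a
#' single-clonotype repertoire is defined to have clonality 1 (the limit of
#' maximal clonal dominance; the raw formula is 0/0 there).
#'
#' @param counts Positive numeric vector of clonotype read counts, intended
#'   to be depth-normalized (see [downsample_reads()]).
#' @return Clonality in `[0, 1]`.
#' @export
#' @examples
#' clonality(rep(5, 100))  # uniform repertoire: 0
#' clonality(c(400, 100))
clonality <- function(counts) {
  if (length(counts) == 0) abort("clonality() needs a non-empty count vector")
  if (any(is.na(counts)) || any(counts <= 0)) {
    abort("clonality() counts must all be positive")
  }
  s <- length(counts)
  if (s == 1) return(1)
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  1 - h / log(s)
}

#' Per-sample clonality with coverage filtering and seeded downsampling
#'
#' For each sample passing the coverage filter, clonotype reads of the given
#' isotype are aggregated by clonotype identity (CDR3 nucleotide sequence +
#' V family + J gene by default), downsampled to `n_reads` reads, and
#' clonality computed; the reported value is the mean over `replicates`
#' seeded downsampling draws (set `replicates = 1` for a single draw).
#'
#' @param clonotypes Clonotype tibble.
#' @param isotype Isotype to analyze.
#' @param min_reads Coverage threshold (strict; default 500).
#' @param n_reads Downsampling target (default 500).
#' @param replicates Number of downsampling replicates (default 10).
#' @param seed Integer seed.
#' @param identity `"nt"` (CDR3 nucleotide + V family + J gene) or `"aa"`
#'   (CDR3 amino acid + V family + J gene) clonotype identity.
#' @return Tibble `sample_id`, `reads`, `n_clonotypes`, `clonality`,
#'   `clonality_sd`, `replicates` for passing samples.
#' @export
clonality_table <- function(clonotypes, isotype, min_reads = 500,
                            n_reads = 500, replicates = 10, seed,
                            identity = c("nt", "aa")) {
  if (missing(seed)) abort("clonality_table() requires an explicit seed")
  identity <- match.arg(identity)
  cov <- coverage_filter(clonotypes, isotype, min_reads)
  passing <- cov$sample_id[cov$pass]
  if (length(passing) == 0) {
    return(tibble(sample_id = character(), reads = integer(),
                  n_clonotypes = integer(), clonality = double(),
                  clonality_sd = double(), replicates = integer()))
  }
  cdr3_col <- if (identity == "nt") "cdr3nt" else "cdr3aa"
  agg <- clonotypes |>
    filter(.data$isotype == .env$isotype, .data$sample_id %in% passing) |>
    mutate(clone_id = paste(.data[[cdr3_col]],
                            collapse_v_family(.data$v), .data$j, sep = "|")) |>
    group_by(.data$sample_id, .data$clone_id) |>
    summarise(count = sum(.data$count), .groups = "drop")

  withr::with_seed(seed, {
    agg |>
      group_by(.data$sample_id) |>
      group_modify(function(df, key) {
        reps <- vapply(seq_len(replicates), function(i) {
          cnt <- downsample_counts(df$count, n_reads)
          clonality(cnt[cnt > 0])
        }, numeric(1))
        tibble(reads = sum(df$count), n_clonotypes = nrow(df),
               clonality = mean(reps),
               clonality_sd = if (replicates > 1) sd(reps) else NA_real_,
               replicates = as.integer(replicates))
      }) |>
      ungroup()
  })
}

#' IGHV-family by IGHJ-gene usage matrix
#'
#' For each sample passing the coverage filter, the read-count-weighted
#' frequency of every observed (V family, J gene) combination within the
#' sample's repertoire of the given isotype. V genes are collapsed to
#' families; J genes are kept at gene level. Feature columns are labelled
#' `IGHV<f>-IGHJ<g>` and every sample row sums to 1.
#'
#' @param clonotypes Clonotype tibble.
#' @param isotype Isotype to analyze (default `"IgG1"`).
#' @param min_reads Coverage threshold (strict; default 500).
#' @return Tibble with `sample_id` and one frequency column per feature.
#' @export
vj_usage <- function(clonotypes, isotype = "IgG1", min_reads = 500) {
  cov <- coverage_filter(clonotypes, isotype, min_reads)
  passing <- cov$sample_id[cov$pass]
  sub <- clonotypes |>
    filter(.data$isotype == .env$isotype, .data$sample_id %in% passing)
  if (nrow(sub) == 0) abort("no clonotypes left after coverage filtering")
  usage <- sub |>
    mutate(feature = paste(collapse_v_family(.data$v), .data$j, sep = "-")) |>
    group_by(.data$sample_id, .data$feature) |>
    summarise(reads = sum(.data$count), .groups = "drop_last") |>
    mutate(freq = .data$reads / sum(.data$reads)) |>
    ungroup() |>
    select("sample_id", "feature", "freq") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "freq",
                       values_fill = 0)
  usage[, c("sample_id", sort(setdiff(names(usage), "sample_id")))]
}

#' Overall-survival group labels relative to the cohort median
#'
#' The reference point is the median of the observed times (event or
#' censoring) in the cohort. A patient is `"high"` if still under
#' observation past the median, `"low"` if they died at or before the
#' median, and `"excluded"` if censored at or before the median (their fate
#' at the median is unknown).
#'
#' @param clinical Clinical tibble with `os_days` and logical `event`.
#' @return Character vector of labels, one per row of `clinical`.
#' @export
survival_group_labels <- function(clinical) {
  clinical <- validate_clinical(clinical)
  med <- median(clinical$os_days)
  dplyr::case_when(
    clinical$os_days > med ~ "high",
    clinical$event ~ "low",
    .default = "excluded"
  )
}

#' PCA signature of V-J usage versus survival
#'
#' Principal component analysis of the mean-centered (not variance-scaled)
#' usage matrix identifies the V-J profiles explaining the most variance
#' across samples; alongside, each feature's mean-frequency difference
#' between long- and short-survival samples is reported. Loading signs are
#' fixed by requiring the largest-magnitude loading of each component to be
#' positive, so results are deterministic.
#'
#' @param usage Usage tibble from [vj_usage()].
#' @param labels Character vector aligned with the rows of `usage`, with
#'   values `"high"`, `"low"` or `"excluded"` (see
#'   [survival_group_labels()]).
#' @return An object of class `ig_vj_signature` with elements `loadings`
#'   (tibble feature x PC), `scores` (tibble sample x PC), `sdev`,
#'   `var_explained`, and `group_diff` (tibble `feature`, `mean_high`,
#'   `mean_low`, `diff`, sorted by decreasing `diff`).
#' @export
signature_pca <- function(usage, labels) {
  if (nrow(usage) < 3) abort("signature_pca() needs at least 3 samples")
  if (length(labels) != nrow(usage)) {
    abort("labels must align with the rows of the usage matrix")
  }
  bad <- setdiff(unique(labels), c("high", "low", "excluded"))
  if (length(bad) > 0) {
    abort(paste0("unknown survival labels: ", paste(bad, collapse = ", ")))
  }
  mat <- as.matrix(usage[, setdiff(names(usage), "sample_id"), drop = FALSE])
  if (all(apply(mat, 2, function(col) diff(range(col))) < .Machine$double.eps)) {
    abort("zero-variance usage matrix: all samples identical")
  }
  pca <- prcomp(mat, center = TRUE, scale. = FALSE)
  # deterministic sign: largest |loading| of each PC made positive
  for (k in seq_len(ncol(pca$rotation))) {
    i <- which.max(abs(pca$rotation[, k]))
    if (pca$rotation[i, k] < 0) {
      pca$rotation[, k] <- -pca$rotation[, k]
      pca$x[, k] <- -pca$x[, k]
    }
  }
  var_explained <- pca$sdev^2 / sum(pca$sdev^2)

  mean_or_na <- function(m) {
    if (nrow(m) == 0) rep(NA_real_, ncol(mat)) else colMeans(m)
  }
  mh <- mean_or_na(mat[labels == "high", , drop = FALSE])
  ml <- mean_or_na(mat[labels == "low", , drop = FALSE])
  group_diff <- tibble(
    feature = colnames(mat),
    mean_high = unname(mh),
    mean_low = unname(ml),
    diff = unname(mh - ml)
  ) |> arrange(desc(.data$diff))

  structure(
    list(
      loadings = bind_cols(tibble(feature = colnames(mat)),
                           as_tibble(pca$rotation)),
      scores = bind_cols(tibble(sample_id = usage$sample_id,
                                label = labels),
                         as_tibble(pca$x)),
      sdev = pca$sdev,
      var_explained = var_explained,
      group_diff = group_diff
    ),
    class = "ig_vj_signature"
  )
}

#' @export
print.ig_vj_signature <- function(x, ...) {
  cat("V-J usage signature:", nrow(x$loadings), "features,",
      nrow(x$scores), "samples\n")
  cat(sprintf("PC1 explains %.1f%% of variance\n", 100 * x$var_explained[1]))
  cat("Top group differences (high - low survival):\n")
  print(head(x$group_diff, 4))
  invisible(x)
}

#' Tidy a V-J usage signature
#'
#' @param x An `ig_vj_signature` object.
#' @param ... Unused.
#' @return Tibble with one row per feature: PC1/PC2 loadings and the
#'   high-minus-low mean frequency difference.
#' @export
tidy.ig_vj_signature <- function(x, ...) {
  pcs <- intersect(c("PC1", "PC2"), names(x$loadings))
  x$group_diff |>
    left_join(x$loadings[, c("feature", pcs)], by = "feature")
}

#' Glance at a V-J usage signature
#'
#' @param x An `ig_vj_signature` object.
#' @param ... Unused.
#' @return One-row tibble with sample/feature counts and PC1/PC2 explained
#'   variance.
#' @export
glance.ig_vj_signature <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_features = nrow(x$loadings),
    var_explained_pc1 = x$var_explained[1],
    var_explained_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
    top_feature = x$group_diff$feature[1]
  )
}

#' Plot a V-J usage signature
#'
#' Bar chart of per-feature mean-frequency differences between high- and
#' low-survival groups, with the strongest features at the top.
#'
#' @param object An `ig_vj_signature` object.
#' @param n_features Number of extreme features to show (default 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ig_vj_signature <- function(object, n_features = 12, ...) {
  gd <- object$group_diff |>
    arrange(.data$diff) |>
    filter(dplyr::row_number() <= n_features / 2 |
             dplyr::row_number() > dplyr::n() - n_features / 2)
  ggplot2::ggplot(gd, ggplot2::aes(
    x = .data$diff, y = stats::reorder(.data$feature, .data$diff),
    fill = .data$diff > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = "mean frequency difference (high - low survival)",
      y = NULL, title = "V-J usage signature"
    ) +
    ggplot2::theme_minimal()
}
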