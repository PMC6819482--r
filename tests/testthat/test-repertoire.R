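test_that("clonality matches the arithmetic oracle and its conventions", {
  # uniform repertoire: H = log S, clonality 0
  expect_equal(clonality(rep(5, 100)), 0)
  # single clonotype: maximal clonal dominance by convention
  expect_equal(clonality(c(123)), 1)
  # direct arithmetic: p = (0.8, 0.2), normalized by log 2
  h <- -(0.8 * log(0.8) + 0.2 * log(0.2))
  expect_equal(clonality(c(400, 100)), 1 - h / log(2), tolerance = 1e-12)
  expect_error(clonality(numeric(0)), "non-empty")
  expect_error(clonality(c(3, 0)), "positive")
})

test_that("clonality is scale-invariant and increases under majorization", {
  set.seed(7)
  for (i in 1:30) {
    counts <- sample(1:500, 3)
    expect_equal(clonality(counts * 7), clonality(counts), tolerance = 1e-12)
    # move one read from the smallest clone to the largest
    if (min(counts) < 2) next
    shifted <- counts
    shifted[which.min(counts)] <- min(counts) - 1
    shifted[which.max(counts)] <- max(counts) + 1
    expect_gt(clonality(shifted), clonality(counts))
  }
})

test_that("collapse_v_family keeps the leading digit block only", {
  expect_equal(collapse_v_family(c("IGHV3-11", "IGHV3-13")),
               c("IGHV3", "IGHV3"))
  expect_equal(collapse_v_family("IGHV6-1"), "IGHV6")
  expect_equal(collapse_v_family("IGHV4"), "IGHV4")
  expect_error(collapse_v_family("TRBV9"), "TRBV9")
})

test_that("coverage filter is strictly greater-than", {
  tab <- dplyr::bind_rows(
    clono_fixture(501, sample_id = "A"),
    clono_fixture(500, sample_id = "B"),
    clono_fixture(100, sample_id = "C", isotype = "IgA")
  )
  cov <- coverage_filter(tab, "IgG1", min_reads = 500)
  expect_equal(cov$pass[cov$sample_id == "A"], TRUE)
  expect_equal(cov$pass[cov$sample_id == "B"], FALSE)
  expect_equal(cov$reads[cov$sample_id == "C"], 0)   # no IgG1 reads at all
  expect_equal(cov$pass[cov$sample_id == "C"], FALSE)
})

test_that("downsampling returns exactly n reads and is seed-reproducible", {
  one <- clono_fixture(1000)
  down <- downsample_reads(one, "IgG1", n = 500, seed = 1)
  expect_equal(down$count, 500L)

  exact <- clono_fixture(c(300, 150, 50))
  expect_equal(downsample_reads(exact, "IgG1", n = 500, seed = 1)$count,
               c(300L, 150L, 50L))

  two <- clono_fixture(c(900, 100))
  d1 <- downsample_reads(two, "IgG1", n = 500, seed = 99)
  d2 <- downsample_reads(two, "IgG1", n = 500, seed = 99)
  expect_identical(d1, d2)
  expect_equal(sum(d1$count), 500)

  expect_error(downsample_reads(clono_fixture(400), "IgG1", n = 500, seed = 1),
               "coverage_filter")
})

test_that("downsampling matches the hypergeometric expectation", {
  two <- clono_fixture(c(900, 100))
  draws <- vapply(1:1000, function(s) {
    d <- downsample_reads(two, "IgG1", n = 500, seed = s)
    small <- d$count[d$cdr3nt == two$cdr3nt[2]]
    if (length(small) == 0) 0L else small
  }, integer(1))
  # E = 50; hypergeometric sd = sqrt(500 * .1 * .9 * 500/999) ~ 4.7
  se <- sqrt(500 * 0.1 * 0.9 * (1000 - 500) / (1000 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - 50), 4 * se)
})

test_that("downsampling preserves expected clone frequencies", {
  set.seed(5)
  counts <- sample(10:400, 8)
  tab <- clono_fixture(counts)
  total <- sum(counts)
  means <- rowMeans(vapply(1:300, function(s) {
    d <- downsample_reads(tab, "IgG1", n = 500, seed = s)
    d$count[match(tab$cdr3nt, d$cdr3nt)] / 500
  }, numeric(nrow(tab))), na.rm = TRUE)
  p <- counts / total
  se <- sqrt(p * (1 - p) / 500 * (total - 500) / (total - 1)) / sqrt(300)
  expect_true(all(abs(means - p) < 3 * se + 1e-3))
})

test_that("vj_usage builds read-weighted frequencies with rows summing to 1", {
  tab <- dplyr::bind_rows(
    clono_fixture(600, sample_id = "A", v = "IGHV3-11", j = "IGHJ4"),
    clono_fixture(c(300, 201), sample_id = "B",
                  v = c("IGHV1-2", "IGHV4-34"), j = c("IGHJ4", "IGHJ6"))
  )
  usage <- vj_usage(tab, "IgG1")
  expect_equal(usage$`IGHV3-IGHJ4`[usage$sample_id == "A"], 1)
  expect_equal(usage$`IGHV1-IGHJ4`[usage$sample_id == "B"], 300 / 501)
  expect_equal(usage$`IGHV4-IGHJ6`[usage$sample_id == "B"], 201 / 501)
  expect_equal(unname(rowSums(usage[, -1])), c(1, 1), tolerance = 1e-9)

  dup <- dplyr::bind_rows(
    clono_fixture(c(400, 200), sample_id = "X",
                  v = c("IGHV1-2", "IGHV3-7"), j = c("IGHJ4", "IGHJ5")),
    clono_fixture(c(400, 200), sample_id = "Y",
                  v = c("IGHV1-2", "IGHV3-7"), j = c("IGHJ4", "IGHJ5"))
  )
  u2 <- vj_usage(dup, "IgG1")
  expect_equal(unlist(u2[1, -1]), unlist(u2[2, -1]))
})

test_that("survival labels compare to the cohort median of observed time", {
  clin <- clinical_fixture(
    n = 5,
    os_days = c(400, 1200, 300, 700, 900),
    event = c(1, 0, 0, 1, 1)
  )
  # median observed time = 700
  expect_equal(survival_group_labels(clin),
               c("low", "high", "excluded", "low", "high"))
})

test_that("signature PCA is deterministic, unit-norm, and flags planted shifts", {
  set.seed(13)
  base <- matrix(rgamma(40 * 6, 2), nrow = 40)
  base <- sweep(base, 1, rowSums(base), "/")
  colnames(base) <- c("IGHV1-IGHJ4", "IGHV3-IGHJ1", "IGHV3-IGHJ2",
                      "IGHV4-IGHJ3", "IGHV6-IGHJ4", "IGHV7-IGHJ6")
  usage <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%02d", 1:40)),
    tibble::as_tibble(base)
  )
  labels <- rep(c("high", "low"), each = 20)
  # plant a shift in the high group
  shifted <- usage
  shifted[1:20, "IGHV6-IGHJ4"] <- shifted[["IGHV6-IGHJ4"]][1:20] + 0.15
  shifted[, -1] <- shifted[, -1] / rowSums(shifted[, -1])

  sig <- signature_pca(shifted, labels)
  expect_equal(sig$group_diff$feature[1], "IGHV6-IGHJ4")
  expect_gt(sig$group_diff$diff[1], 0)
  # loadings unit-norm, largest-magnitude loading positive
  loads <- as.matrix(sig$loadings[, -1])
  expect_equal(unname(colSums(loads^2)), rep(1, ncol(loads)), tolerance = 1e-9)
  for (k in seq_len(ncol(loads))) {
    expect_gt(loads[which.max(abs(loads[, k])), k], 0)
  }

  # duplicated samples get identical scores
  dup_usage <- usage[c(1, 1, 2, 3, 4), ]
  dup_usage$sample_id <- paste0("D", 1:5)
  s2 <- signature_pca(dup_usage, rep("high", 5))
  expect_equal(unlist(s2$scores[1, -(1:2)]), unlist(s2$scores[2, -(1:2)]))

  flat <- usage[c(1, 1, 1), ]
  expect_error(signature_pca(flat, rep("high", 3)), "zero-variance")
})

test_that("clonality_table filters, aggregates identity, and averages replicates", {
  tab <- dplyr::bind_rows(
    # sample A: two rows that are the same clone (same CDR3, same V family)
    clono_fixture(c(600, 300), sample_id = "A",
                  v = c("IGHV3-11", "IGHV3-13"),
                  cdr3nt = c("TGTAAA", "TGTAAA")),
    clono_fixture(400, sample_id = "B")  # below threshold
  )
  ct <- clonality_table(tab, "IgG1", seed = 4)
  expect_equal(ct$sample_id, "A")
  expect_equal(ct$n_clonotypes, 1L)      # aggregated to a single clone
  expect_equal(ct$clonality, 1)          # single clone is maximally clonal
  expect_equal(ct$replicates, 10L)
})
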