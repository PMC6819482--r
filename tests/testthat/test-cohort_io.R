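test_that("fpkm_to_tpm rescales each sample to a million and tags units", {
  one_gene <- as_expression(tibble::tibble(gene = "IGHG1", S1 = 5),
                            units = "FPKM")
  out <- fpkm_to_tpm(one_gene)
  expect_equal(out$S1, 1e6)
  expect_identical(expression_units(out), "TPM")

  two_genes <- as_expression(
    tibble::tibble(gene = c("A", "B"), S1 = c(2, 8)), units = "FPKM"
  )
  expect_equal(fpkm_to_tpm(two_genes)$S1, c(2e5, 8e5))
})

test_that("fpkm_to_tpm rejects all-zero samples and double normalization", {
  bad <- as_expression(
    tibble::tibble(gene = c("A", "B"), S1 = c(1, 2), S2 = c(0, 0)),
    units = "FPKM"
  )
  expect_error(fpkm_to_tpm(bad), "S2")
  tpm <- as_expression(tibble::tibble(gene = "A", S1 = 3), units = "TPM")
  expect_error(fpkm_to_tpm(tpm), "already in TPM")
})

test_that("the TPM transform is idempotent in effect", {
  set.seed(11)
  x <- as_expression(
    tibble::tibble(gene = paste0("G", 1:50),
                   S1 = rexp(50), S2 = rexp(50)),
    units = "FPKM"
  )
  once <- fpkm_to_tpm(x)
  again <- fpkm_to_tpm(as_expression(once, units = "FPKM"))
  expect_equal(as.matrix(again[, -1]), as.matrix(once[, -1]),
               tolerance = 1e-9)
  expect_equal(unname(colSums(as.matrix(once[, -1]))), c(1e6, 1e6))
})

test_that("expression validation catches duplicates and negatives", {
  expect_error(
    as_expression(tibble::tibble(gene = c("A", "A"), S1 = c(1, 2))),
    "duplicated gene symbols"
  )
  expect_error(
    as_expression(tibble::tibble(gene = c("A", "B"), S1 = c(1, -2))),
    "non-negative"
  )
})

test_that("mutation calls are retained by impact or damaging annotation", {
  calls <- tibble::tibble(
    patient_id = paste0("P", 1:4),
    gene = "KRAS",
    vep_impact = c("LOW", "LOW", "HIGH", "MODIFIER"),
    sift = c("tolerated", "deleterious", NA, NA),
    polyphen = c("benign", NA, NA, "possibly_damaging")
  )
  kept <- filter_mutation_calls(calls)
  expect_setequal(kept$patient_id, c("P2", "P3", "P4"))
})

test_that("unknown VEP impact values abort with the offending row", {
  calls <- tibble::tibble(patient_id = "P1", gene = "KRAS",
                          vep_impact = "SEVERE", sift = NA, polyphen = NA)
  expect_error(filter_mutation_calls(calls), "SEVERE")
})

test_that("subgroups follow retained calls, PD-L1 threshold, and subtype labels", {
  clin <- clinical_fixture(n = 5, subtype = c("PI", "PP", "TRU",
                                              "unknown", "unknown"))
  # CD274: cohort mean 10; only P01 exceeds twice the mean
  expr <- expr_fixture(list(
    P01 = c(CD274 = 25), P02 = c(CD274 = 10), P03 = c(CD274 = 5),
    P04 = c(CD274 = 5), P05 = c(CD274 = 5)
  ))
  calls <- filter_mutation_calls(tibble::tibble(
    patient_id = c("P01", "P02", "P02"),
    gene = c("KRAS", "TP53", "KRAS"),
    vep_impact = c("MODERATE", "HIGH", "LOW"),
    sift = c(NA, NA, "tolerated"), polyphen = c(NA, NA, "benign")
  ))
  sg <- assign_subgroups(clin, calls, expr)

  expect_true(sg$KRASmut[sg$patient_id == "P01"])
  expect_false(sg$KRASmut[sg$patient_id == "P02"])  # LOW call filtered out
  expect_true(sg$TP53mut[sg$patient_id == "P02"])
  expect_equal(sg$PDL1high, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(sg$PI, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # unknown subtype belongs to none of PI/PP/TRU
  expect_false(any(sg$PI[4:5] | sg$PP[4:5] | sg$TRU[4:5]))
})

test_that("genotype pairs partition the cohort and PD-L1 split is scale-invariant", {
  bundle <- simulate_cohort(sim_config(n_patients = 60, seed = 5))
  calls <- filter_mutation_calls(bundle$mutations)
  sg <- assign_subgroups(bundle$clinical, calls, bundle$expression)

  n <- nrow(sg)
  expect_equal(sum(sg$KRASmut) + sum(sg$KRASwt), n)
  expect_equal(sum(sg$TP53mut) + sum(sg$TP53wt), n)
  expect_equal(sum(sg$STK11mut) + sum(sg$STK11wt), n)
  expect_equal(sum(sg$PDL1high) + sum(sg$PDL1low), n)
  expect_true(all(rowSums(cbind(sg$PI, sg$PP, sg$TRU)) <= 1))

  scaled <- bundle$expression
  scaled[, -1] <- scaled[, -1] * 37.5
  sg2 <- assign_subgroups(bundle$clinical, calls, as_expression(scaled))
  expect_equal(sg2$PDL1high, sg$PDL1high)
})

test_that("assign_subgroups insists on CD274 and TPM units", {
  clin <- clinical_fixture(n = 4)
  expr <- expr_fixture(list(P01 = c(), P02 = c(), P03 = c(), P04 = c()))
  no_cd274 <- as_expression(dplyr::filter(expr, gene != "CD274"))
  calls <- tibble::tibble(patient_id = character(), gene = character(),
                          vep_impact = character(), sift = character(),
                          polyphen = character())
  expect_error(assign_subgroups(clin, calls, no_cd274), "CD274")
  fpkm <- as_expression(expr, units = "FPKM")
  expect_error(assign_subgroups(clin, calls, fpkm), "TPM")
})

test_that("clinical validation enforces one row per patient and positive times", {
  clin <- clinical_fixture(n = 4)
  expect_silent(validate_clinical(clin))
  dup <- dplyr::bind_rows(clin, clin[1, ])
  expect_error(validate_clinical(dup), "duplicate")
  neg <- clin; neg$os_days[2] <- 0
  expect_error(validate_clinical(neg), "positive")
})

test_that("TSV round trip preserves the tables", {
  dir <- withr::local_tempdir()
  bundle <- simulate_cohort_bundle(sim_config(n_patients = 12, seed = 9),
                                   dir = dir)
  inputs <- read_input_bundle(dir)
  expect_equal(as.data.frame(inputs$clinical),
               as.data.frame(dplyr::mutate(bundle$clinical,
                                           event = as.logical(event))))
  expect_equal(as.matrix(inputs$expression[, -1]),
               as.matrix(bundle$expression[, -1]), tolerance = 1e-12)
  expect_equal(nrow(inputs$mutations), nrow(bundle$mutations))
  expect_setequal(unique(inputs$clonotypes$sample_id),
                  unique(bundle$clonotypes$sample_id))
})
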