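# Fixture builders and independent oracles shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expression fixture: named gene values per sample, padded with the full
# 14-gene panel so isotype_profiles() accepts it.
expr_fixture <- function(samples, units = "TPM", fill = 1) {
  genes <- c(igh_constant_genes(), marker_genes())
  cols <- lapply(samples, function(vals) {
    out <- rep(fill, length(genes))
    names(out) <- genes
    out[names(vals)] <- vals
    unname(out)
  })
  names(cols) <- names(samples)
  as_expression(
    tibble::tibble(gene = genes, !!!cols),
    units = units
  )
}

clinical_fixture <- function(n = 8, os_days = NULL, event = NULL,
                             subtype = "unknown", seed = 42) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    os_days = os_days %||% sample(100:2000, n),
    event = event %||% rbinom(n, 1, 0.6),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    gender = sample(c("female", "male"), n, replace = TRUE),
    age = sample(45:85, n, replace = TRUE),
    smoking = sample(c("current", "former", "never"), n, replace = TRUE),
    subtype = subtype,
    mutation_burden = runif(n, 0.5, 20)
  )
}

# Minimal clonotype tibble: one row per clone.
clono_fixture <- function(counts, sample_id = "S1", isotype = "IgG1",
                          v = "IGHV3-11", j = "IGHJ4", cdr3nt = NULL) {
  k <- length(counts)
  tibble::tibble(
    sample_id = sample_id,
    count = as.integer(counts),
    freq = counts / sum(counts),
    cdr3nt = cdr3nt %||% sprintf("TGTGCG%04d", seq_len(k)),
    cdr3aa = sprintf("CAR%04d", seq_len(k)),
    v = rep_len(v, k),
    d = NA_character_,
    j = rep_len(j, k),
    isotype = isotype
  )
}

# Independent product-limit oracle: survival at each distinct event time by
# direct risk-set counting.
km_oracle <- function(times, events, at) {
  ev_times <- sort(unique(times[as.logical(events)]))
  s <- 1
  for (t in ev_times[ev_times <= at]) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & as.logical(events))
    s <- s * (1 - d / n_risk)
  }
  s
}

# Independent log-rank oracle: brute-force summation of observed minus
# hypergeometric-expected events with the exact hypergeometric variance.
logrank_oracle <- function(times, events, in_a) {
  events <- as.logical(events)
  o <- e <- v <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    d <- sum(times == t & events)
    o <- o + sum(times == t & events & in_a)
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}
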