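# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small planted cohort used by several modules: clear signal, fast stats.
small_cohort <- function() {
  cached_fixture("small_cohort",
                 simulate_cohort(sim_config(n_probes = 3000L, n_cases = 20L,
                                            n_controls = 30L,
                                            n_true_dmps = 80L, seed = 11L)))
}

# Same scale with three planted episignature-negative cases.
negative_cohort <- function() {
  cached_fixture("negative_cohort",
                 simulate_cohort(sim_config(n_probes = 3000L, n_cases = 20L,
                                            n_controls = 30L,
                                            n_true_dmps = 80L,
                                            n_negative_cases = 3L,
                                            seed = 12L)))
}

# Write a CpG-island BED file (0-based half-open) and return its path.
write_cgi_bed <- function(islands) {
  path <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\tCpG", islands$chrom, islands$start,
                     islands$end), path)
  path
}

# Independent oracle: two-sided Fisher exact p by full hypergeometric
# enumeration over the support of the 2x2 table with fixed margins.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# Independent oracle: BH step-up q-values straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q[ord[i]] <- min(p[ord[js]] * m / js)
  }
  pmin(q, 1)
}

# The default-scale discovery run shared by the acceptance checks:
# 60 cases vs 85 controls on 20,000 probes with 200 planted DMPs at a mean
# shift of 0.10 (hyper fraction 0.7), iterative case pruning, a 75/25
# stratified split, SVM training and scoring of held-out controls,
# retained discovery cases and a frozen-classifier validation series.
default_run <- function() {
  cached_fixture("default_run", {
    sim <- simulate_cohort(sim_config(seed = 1L))
    pr <- iterative_case_pruning(sim$beta, sim$sample_sheet, seed = 1L)
    split <- split_train_test(pr$retained_sheet, fraction = 0.75, seed = 2L)
    train_sheet <- pr$retained_sheet[pr$retained_sheet$sample_id %in%
                                       split$train, ]
    clf <- train_svm(sim$beta[, split$train], pr$probe_set, train_sheet,
                     seed = 3L)
    test_sheet <- pr$retained_sheet[pr$retained_sheet$sample_id %in%
                                      split$test, ]
    test_controls <- test_sheet$sample_id[test_sheet$group == "control"]
    disc_cases <- pr$retained_sheet$sample_id[pr$retained_sheet$group ==
                                                "case"]
    val <- simulate_cases(sim, 11L, seed = 2L)
    list(sim = sim, pruned = pr, split = split, classifier = clf,
         test_controls = test_controls, disc_cases = disc_cases, val = val)
  })
}
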