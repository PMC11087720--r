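make_sheet <- function(groups, ids = sprintf("s%02d", seq_along(groups))) {
  data.frame(sample_id = ids, group = groups, stringsAsFactors = FALSE)
}

test_that("per-probe OLS matches the normal-equations oracle", {
  # exact separation: cases at M = 1, controls at M = 0
  M <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = 1), nrow = 1, byrow = TRUE,
              dimnames = list("cg1", sprintf("s%02d", 1:6)))
  sheet <- make_sheet(c("case", "case", "case", "control", "control", "control"))
  fit <- fit_probe_models(M, sheet)
  expect_equal(unname(fit$coef), 1)
  expect_equal(unname(fit$s2), 0)
  expect_equal(fit$df, 4L)

  # random data vs brute-force normal equations, probe by probe
  set.seed(101)
  M2 <- matrix(rnorm(5 * 8), nrow = 5,
               dimnames = list(paste0("cg", 1:5), sprintf("s%02d", 1:8)))
  sheet2 <- make_sheet(rep(c("case", "control"), each = 4))
  fit2 <- fit_probe_models(M2, sheet2)
  X <- cbind(1, rep(c(1, 0), each = 4))
  for (i in 1:5) {
    b <- solve(t(X) %*% X, t(X) %*% M2[i, ])
    expect_equal(unname(fit2$coef[i]), b[2, 1], tolerance = 1e-10)
    res <- M2[i, ] - X %*% b
    expect_equal(unname(fit2$s2[i]), sum(res^2) / (8 - 2), tolerance = 1e-10)
  }

  # a covariate orthogonal to the group contrast leaves the effect unchanged
  age <- rep(c(-1, 0, 1, 0), 2)  # same pattern in both groups
  sheet3 <- make_sheet(rep(c("case", "control"), each = 4))
  sheet3$age <- age
  fit3 <- fit_probe_models(M2, sheet3, covariates = "age")
  expect_equal(fit3$coef, fit2$coef, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  set.seed(5)
  M <- matrix(rnorm(3 * 6), nrow = 3,
              dimnames = list(paste0("cg", 1:3), sprintf("s%02d", 1:6)))
  sheet <- make_sheet(rep(c("case", "control"), each = 3))
  sheet$dup <- as.numeric(sheet$group == "case")  # duplicates the group column
  expect_error(fit_probe_models(M, sheet, covariates = "dup"), "dup",
               class = "model_error")
})

test_that("variance moderation attains the ordinary-t and full-shrinkage limits", {
  set.seed(202)
  n <- 120; ns <- 10
  sds <- sqrt(stats::rchisq(n, 4) / 4)
  M <- matrix(rnorm(n * ns), n, dimnames = list(paste0("cg", 1:n),
                                                sprintf("s%02d", 1:ns))) * sds
  sheet <- make_sheet(rep(c("case", "control"), each = 5))
  fit <- fit_probe_models(M, sheet)

  # d0 = 0: moderated t equals the ordinary t statistic
  mod0 <- ebayes_moderate(fit$coef, fit$s2, fit$df, fit$se_unit, d0 = 0)
  t_ordinary <- fit$coef / (sqrt(fit$s2) * fit$se_unit)
  expect_equal(mod0$t_mod, t_ordinary, tolerance = 1e-8)

  # d0 = Inf: every posterior variance collapses onto the prior
  modInf <- ebayes_moderate(fit$coef, fit$s2, fit$df, fit$se_unit, d0 = Inf)
  expect_true(all(modInf$s2_post == modInf$prior$s0_sq))

  # sign(t_mod) = sign(coef)
  mod <- ebayes_moderate(fit$coef, fit$s2, fit$df, fit$se_unit)
  expect_identical(sign(mod$t_mod), sign(fit$coef))
  expect_true(all(mod$p > 0 & mod$p <= 1))

  expect_error(ebayes_moderate(c(1, 1), c(0, 0), 4, 0.5),
               class = "degenerate_variance_error")
})

test_that("null moderated p-values are uniform", {
  set.seed(303)
  n <- 200; ns <- 20
  M <- matrix(rnorm(n * ns), n, dimnames = list(paste0("cg", 1:n),
                                                sprintf("s%02d", 1:ns)))
  sheet <- make_sheet(rep(c("case", "control"), each = 10))
  fit <- fit_probe_models(M, sheet)
  mod <- ebayes_moderate(fit$coef, fit$s2, fit$df, fit$se_unit)
  ks <- suppressWarnings(stats::ks.test(mod$p, "punif")$statistic)
  expect_lt(as.numeric(ks), 0.1)
})

test_that("moderated statistics agree with an independent reference implementation", {
  skip_if_not_installed("limma")
  set.seed(404)
  n <- 400; ns <- 12
  sds <- sqrt(stats::rchisq(n, 5) / 5)
  M <- matrix(rnorm(n * ns), n, dimnames = list(paste0("cg", 1:n),
                                                sprintf("s%02d", 1:ns))) * sds
  grp <- rep(c("case", "control"), each = 6)
  fit <- fit_probe_models(M, make_sheet(grp))
  mod <- ebayes_moderate(fit$coef, fit$s2, fit$df, fit$se_unit)
  eb <- limma::eBayes(limma::lmFit(M, cbind(1, as.numeric(grp == "case"))))
  expect_equal(mod$prior$d0, eb$df.prior, tolerance = 1e-10)
  expect_equal(mod$prior$s0_sq, eb$s2.prior, tolerance = 1e-10)
  expect_equal(unname(mod$t_mod), unname(eb$t[, 2]), tolerance = 1e-10)
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.04, 0.90)), c(0.03, 0.06, 0.90))
  expect_error(bh_fdr(numeric(0)), class = "argument_error")
  expect_error(bh_fdr(c(0.5, 0)), class = "argument_error")

  # property: random vectors against the exhaustive oracle
  set.seed(99)
  for (len in c(1, 3, 5, 8)) {
    p <- runif(len)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("delta-beta equals the direct group-mean difference", {
  beta <- matrix(c(rep(0.6, 6), rep(0.5, 6)), nrow = 2, byrow = FALSE,
                 dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  beta["a", ] <- c(0.6, 0.6, 0.6, 0.5, 0.5, 0.5)
  beta["b", ] <- 0.5
  grp <- rep(c("case", "control"), each = 3)
  db <- compute_delta_beta(beta, grp)
  expect_equal(unname(db["a"]), 0.1)
  expect_equal(unname(db["b"]), 0)

  set.seed(17)
  beta2 <- matrix(runif(24), nrow = 4,
                  dimnames = list(paste0("cg", 1:4), paste0("s", 1:6)))
  grp2 <- c("case", "control", "case", "control", "case", "control")
  oracle <- apply(beta2, 1, function(x) mean(x[grp2 == "case"]) -
                    mean(x[grp2 == "control"]))
  expect_equal(compute_delta_beta(beta2, grp2), oracle)
  expect_error(compute_delta_beta(beta2, rep("case", 6)),
               class = "argument_error")
})

test_that("probe selection filters, ranks, truncates and prunes duplicates", {
  sim <- small_cohort()
  tab <- dmp_table(sim$beta, sim$sample_sheet)
  groups <- sim$sample_sheet$group

  # duplicated probe rows: only one survives the correlation pruning
  beta_dup <- rbind(sim$beta, dup_probe = sim$beta[sim$truth$planted_set[1], ])
  tab_dup <- dmp_table(beta_dup, sim$sample_sheet)
  ps_dup <- select_probes(tab_dup, beta_dup, groups)
  expect_equal(sum(c(sim$truth$planted_set[1], "dup_probe") %in%
                     ps_dup$probe_ids), 1L)

  # truncation-only mode returns exactly the top-ranked probes
  ps3 <- select_probes(tab, sim$beta, groups, q_max = 1, min_abs_delta = 0,
                       top_n = 3, corr_max = 1)
  top3 <- tab$probe_id[order(-tab$rank_score, tab$probe_id)][1:3]
  expect_identical(ps3$probe_ids, top3)

  # impossible filters raise a selection error reporting attained values
  expect_error(select_probes(tab, sim$beta, groups, min_abs_delta = 0.9),
               class = "selection_error")

  # invariance to row and column permutations (same ordered output)
  ps <- select_probes(tab, sim$beta, groups)
  set.seed(8)
  perm_cols <- sample(ncol(sim$beta))
  perm_rows <- sample(nrow(sim$beta))
  beta_perm <- sim$beta[perm_rows, perm_cols]
  tab_perm <- dmp_table(beta_perm, sim$sample_sheet)
  ps_perm <- select_probes(tab_perm, beta_perm,
                           sim$sample_sheet$group[match(colnames(beta_perm),
                                                        sim$sample_sheet$sample_id)])
  expect_identical(ps$probe_ids, ps_perm$probe_ids)

  # stored training stats are on the beta scale and match the groups
  i <- ps$stats$probe_id[1]
  expect_equal(ps$stats$case_mean[1],
               mean(sim$beta[i, groups == "case"]))
  expect_equal(ps$stats$control_sd[1],
               sd(sim$beta[i, groups == "control"]))
})

test_that("case pruning removes exactly the planted negatives and is idempotent", {
  sim <- negative_cohort()
  pr <- iterative_case_pruning(sim$beta, sim$sample_sheet, seed = 4)
  expect_setequal(pr$removed_case_ids, sim$truth$negative_case_ids)

  # idempotence: pruning the retained cohort removes nothing
  retained <- pr$retained_sheet
  pr2 <- iterative_case_pruning(sim$beta[, retained$sample_id], retained,
                                seed = 4)
  expect_length(pr2$removed_case_ids, 0L)

  # a clean cohort loses no cases
  clean <- small_cohort()
  pr3 <- iterative_case_pruning(clean$beta, clean$sample_sheet, seed = 4)
  expect_length(pr3$removed_case_ids, 0L)
})

test_that("pruning an all-negative cohort reports signature instability", {
  cfg <- sim_config(n_probes = 2000L, n_cases = 12L, n_controls = 12L,
                    n_true_dmps = 50L, n_negative_cases = 12L, seed = 44L)
  sim <- simulate_cohort(cfg)
  expect_error(iterative_case_pruning(sim$beta, sim$sample_sheet, seed = 4),
               class = "instability_error")
})
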