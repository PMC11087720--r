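# Build a DMP table data.frame directly, for signature-rule tests.
fake_dmp <- function(n_pass, n_fail = 50, q_pass = 0.01) {
  n <- n_pass + n_fail
  data.frame(probe_id = sprintf("cg%05d", seq_len(n)),
             delta_beta = c(runif(n_pass, 0.05, 0.2), runif(n_fail, 0, 0.02)),
             p = c(seq_len(n_pass) * 1e-6, runif(n_fail, 0.5, 1)),
             q = c(rep(q_pass, n_pass), runif(n_fail, 0.5, 1)),
             stringsAsFactors = FALSE)
}

sig_from_ids <- function(name, ids, delta = 0.1) {
  structure(list(name = name,
                 probes = data.frame(probe_id = ids, delta_beta = delta,
                                     p = 1e-6, q = 1e-4,
                                     stringsAsFactors = FALSE),
                 rule = "manual"), class = "cohort_signature")
}

test_that("cohort signatures apply the FDR cutoff and the top-500 cap", {
  set.seed(1)
  sig600 <- build_cohort_signature(fake_dmp(600), "big")
  expect_equal(nrow(sig600$probes), 500L)

  sig120 <- build_cohort_signature(fake_dmp(120), "small")
  expect_equal(nrow(sig120$probes), 120L)

  # q exactly at the threshold is excluded (strict <)
  boundary <- fake_dmp(10)
  boundary$q[1] <- 0.05
  sigb <- build_cohort_signature(boundary, "boundary")
  expect_false(boundary$probe_id[1] %in% sigb$probes$probe_id)
  expect_equal(nrow(sigb$probes), 9L)

  # sorted by ascending p
  expect_true(!is.unsorted(sig600$probes$p))

  # no passing probe: empty signature with a warning, not an error
  null_tab <- fake_dmp(0)
  expect_warning(sig0 <- build_cohort_signature(null_tab, "empty"), "empty")
  expect_equal(nrow(sig0$probes), 0L)
})

test_that("overlap percentages are directional set arithmetic", {
  A <- sig_from_ids("A", sprintf("p%04d", 1:500))
  B <- sig_from_ids("B", c(sprintf("p%04d", 1:20), sprintf("x%04d", 1:180)))
  m <- overlap_matrix(list(A, B))
  expect_equal(m["A", "B"], 4.0)    # 100 * 20 / 500
  expect_equal(m["B", "A"], 10.0)   # 100 * 20 / 200
  expect_equal(diag(m), c(A = 100, B = 100))

  A2 <- sig_from_ids("A2", A$probes$probe_id)
  m2 <- overlap_matrix(list(A, A2))
  expect_true(all(m2 == 100))

  expect_error(overlap_matrix(list(A, A)), class = "argument_error")
  expect_error(overlap_matrix(list(A)), class = "argument_error")
})

test_that("planted multi-cohort overlap is recovered exactly", {
  base <- sim_config(n_probes = 20000L, n_cases = 4L, n_controls = 4L,
                     n_true_dmps = 100L, seed = 61L)
  sims <- simulate_multi_cohort(base, k_cohorts = 3L, overlap_fraction = 0.3)
  sigs <- lapply(seq_along(sims), function(i) {
    tr <- sims[[i]]$truth$probe_truths
    sig_from_ids(sprintf("cohort%d", i), tr$probe_id[tr$is_dmp],
                 delta = tr$delta[tr$is_dmp])
  })
  m <- overlap_matrix(sigs)
  expect_equal(m["cohort1", "cohort2"], 100 * round(0.3 * 100) / 100)
  expect_equal(m["cohort1", "cohort3"], 30)
})

test_that("cohort trees aggregate over the union feature space", {
  A <- sig_from_ids("A", sprintf("p%03d", 1:40), delta = 0.1)
  B <- sig_from_ids("B", sprintf("p%03d", 1:40), delta = 0.1)
  C <- sig_from_ids("C", sprintf("q%03d", 1:25), delta = -0.1)
  tree <- cohort_tree(list(A, B, C))

  # identical signatures merge first at height zero
  expect_equal(tree$hclust$height[1], 0)
  expect_setequal(tree$hclust$labels[-tree$hclust$merge[1, ]], c("A", "B"))

  # leaf size equals the signature probe count; colors carry the sign
  expect_equal(tree$leaf_stats$n_dmps, c(40L, 40L, 25L))
  expect_equal(tree$leaf_stats$mean_delta, c(0.1, 0.1, -0.1))

  # probes absent from a signature contribute 0 to its vector
  expect_equal(unname(tree$matrix["C", "p001"]), 0)
  expect_equal(dim(tree$matrix), c(3L, 65L))

  # input order invariance up to the leaf-order tie-break
  tree2 <- cohort_tree(list(C, B, A))
  expect_equal(tree2$hclust$height, tree$hclust$height)
  expect_identical(tree2$hclust$labels[tree2$hclust$order],
                   tree$hclust$labels[tree$hclust$order])

  # hyper- vs hypo-dominant planted cohorts carry opposite-sign means
  base <- sim_config(n_probes = 4000L, n_cases = 10L, n_controls = 10L,
                     n_true_dmps = 60L, hyper_fraction = 1, seed = 62L)
  sims <- simulate_multi_cohort(base, 2L, overlap_fraction = 0,
                                hyper_fractions = c(1, 0))
  sigs <- lapply(1:2, function(i) {
    tab <- dmp_table(sims[[i]]$beta, sims[[i]]$sample_sheet)
    build_cohort_signature(tab, sprintf("c%d", i))
  })
  tr2 <- cohort_tree(sigs)
  expect_gt(tr2$leaf_stats$mean_delta[1], 0)
  expect_lt(tr2$leaf_stats$mean_delta[2], 0)
})

test_that("CpG-island annotation bins probes by boundary distance", {
  # island spanning 1-based positions 10001-11000
  bed <- write_cgi_bed(data.frame(chrom = "chr1", start = 10000L,
                                  end = 11000L))
  ann <- data.frame(
    probe_id = sprintf("cg%d", 1:8),
    chrom = "chr1",
    pos = c(10500L,        # inside the island
            12500L,        # 1500 bp from the edge -> shore
            13000L,        # exactly 2000 bp -> shore
            13001L,        # 2001 bp -> shelf
            14000L,        # 3000 bp -> shelf
            15000L,        # exactly 4000 bp -> shelf
            15001L,        # 4001 bp -> open sea
            21000L),       # 10 kb -> open sea
    gene_region = c("promoter", "gene_body", "promoter_plus", "intergenic",
                    "gene_body", "promoter", "intergenic", "gene_body"),
    stringsAsFactors = FALSE)
  ctx <- annotate_probes(ann$probe_id, ann, bed)
  expect_identical(ctx$cgi_relation,
                   c("island", "shore", "shore", "shelf", "shelf", "shelf",
                     "open_sea", "open_sea"))
  expect_identical(ctx$gene_region, ann$gene_region)

  # the left boundary behaves symmetrically
  left <- data.frame(probe_id = "cgL", chrom = "chr1", pos = 9500L,
                     gene_region = "promoter", stringsAsFactors = FALSE)
  expect_identical(annotate_probes("cgL", left, bed)$cgi_relation, "shore")

  # a probe on a CGI-free chromosome is open sea
  far <- data.frame(probe_id = "cgF", chrom = "chr9", pos = 100L,
                    gene_region = "intergenic", stringsAsFactors = FALSE)
  expect_identical(annotate_probes("cgF", far, bed)$cgi_relation, "open_sea")

  # categories partition the probes
  expect_equal(sum(table(ctx$cgi_relation)), nrow(ctx))

  expect_error(annotate_probes(c("cg1", "nope"), ann, bed), "nope",
               class = "annotation_error")
})

test_that("context enrichment builds exact Fisher tables with BH across categories", {
  sig <- data.frame(probe_id = paste0("s", 1:10), gene_region = "promoter",
                    cgi_relation = "island", stringsAsFactors = FALSE)
  bg <- data.frame(probe_id = paste0("b", 1:100),
                   gene_region = rep(c("promoter", "gene_body"), each = 50),
                   cgi_relation = rep(c("island", "open_sea"), 50),
                   stringsAsFactors = FALSE)
  enr <- context_enrichment(sig, bg)
  prom <- enr[enr$axis == "gene_region" & enr$category == "promoter", ]
  expect_equal(prom$proportion_signature, 1.0)
  expect_equal(prom$proportion_background, 0.5)
  expect_identical(prom$or_flag, "infinite")
  expect_equal(prom$p, fisher_p_oracle(10, 0, 50, 50), tolerance = 1e-12)
  expect_true(all(enr$q >= enr$p - 1e-12))

  # a category absent from the background is reported, flagged undefined
  sig2 <- sig; sig2$gene_region <- "enhancer"
  enr2 <- context_enrichment(sig2, bg)
  enh <- enr2[enr2$category == "enhancer", ]
  expect_identical(enh$or_flag, "undefined")
  expect_true(is.na(enh$odds_ratio))

  # a signature drawn uniformly from the background shows no enrichment
  set.seed(77)
  big_bg <- data.frame(
    probe_id = sprintf("u%05d", 1:2000),
    gene_region = sample(c("promoter", "promoter_plus", "gene_body",
                           "intergenic"), 2000, TRUE),
    cgi_relation = sample(c("island", "shore", "shelf", "open_sea"), 2000,
                          TRUE), stringsAsFactors = FALSE)
  hit_rates <- vapply(1:10, function(s) {
    set.seed(700 + s)
    draw <- big_bg[sample(2000, 100), ]
    e <- context_enrichment(draw, big_bg)
    mean(e$q <= 0.05)
  }, numeric(1))
  expect_lt(mean(hit_rates), 0.1)

  expect_error(context_enrichment(big_bg, sig), class = "argument_error")
})

test_that("loss-of-function transcript fractions sum the aberrant classes", {
  expect_equal(lof_transcript_fraction(15, 27, 8, 50), 42)
  expect_equal(lof_transcript_fraction(0, 0, 50, 50), 0)
  expect_equal(lof_transcript_fraction(50, 50, 0, 0), 100)
  expect_error(lof_transcript_fraction(15, 27, 8, 40),
               class = "consistency_error")
  expect_error(lof_transcript_fraction(-5, 27, 8, 70),
               class = "argument_error")
})
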