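# End-to-end orchestration: a single run configuration drives
# discovery (statistics -> pruning -> selection -> training -> CV ->
# clustering/MDS) and validation scoring, with structured logging and a
# provenance manifest.

log_stage <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  paste0(...)))
}

#' Run configuration for the discovery pipeline
#'
#' @param beta Path to the beta matrix TSV (or an in-memory matrix).
#' @param sample_sheet Path to the sample sheet CSV (or a data.frame).
#' @param outdir Output directory for artifacts.
#' @param annotation,cgi_bed Optional probe annotation TSV and CpG-island
#'   BED paths for the comparative stage.
#' @param covariates Covariate columns for the per-probe models.
#' @param select_params,svm_params,pruning,cv Per-module parameter blocks:
#'   `pruning` is a list (`enabled`, `mvp_cutoff`, `max_rounds`), `cv` a
#'   list (`n_rounds`, `holdout_fraction`).
#' @param match_ratio If not `NULL`, controls are reduced to an age/sex
#'   matched subset with up to this many controls per case.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(beta, sample_sheet, outdir,
                       annotation = NULL, cgi_bed = NULL,
                       covariates = NULL,
                       select_params = list(), svm_params = list(),
                       pruning = list(enabled = TRUE, mvp_cutoff = 0.25,
                                      max_rounds = 3L),
                       cv = list(n_rounds = 20L, holdout_fraction = 0.25),
                       match_ratio = NULL, seed = 1L) {
  cfg <- list(beta = beta, sample_sheet = sample_sheet, outdir = outdir,
              annotation = annotation, cgi_bed = cgi_bed,
              covariates = covariates, select_params = select_params,
              svm_params = svm_params, pruning = pruning, cv = cv,
              match_ratio = match_ratio, seed = as.integer(seed))
  for (p in c("beta", "sample_sheet", "annotation", "cgi_bed")) {
    v <- cfg[[p]]
    if (is.character(v) && !file.exists(v))
      stop_episign("config_error", "%s path does not exist: %s", p, v)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML path with fields matching [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

load_inputs <- function(config) {
  beta <- if (is.character(config$beta)) read_beta_matrix(config$beta) else
    check_beta_matrix(config$beta)
  sheet <- if (is.character(config$sample_sheet))
    read_sample_sheet(config$sample_sheet) else
      check_sample_sheet(config$sample_sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(beta), , drop = FALSE]
  list(beta = beta[, sheet$sample_id, drop = FALSE], sheet = sheet)
}

#' Run the episignature discovery pipeline
#'
#' Executes the full sequence on a case/control cohort: optional
#' age/sex-matched control selection, M-value statistics with
#' empirical-Bayes moderation and BH FDR, iterative removal of
#' episignature-negative cases, probe selection, stratified 75/25
#' train/test split with SVM training and held-out specificity,
#' leave-25%-out cross-validation, and hierarchical clustering plus MDS on
#' the signature probes. Every artifact is written under `outdir` together
#' with a manifest recording stage counts and file checksums.
#'
#' @param config A [run_config()] (or a list coercible to one).
#' @return Invisibly, a list with the in-memory artifacts: `dmp`,
#'   `probe_set`, `removed_case_ids`, `classifier`, `split`,
#'   `specificity`, `cv`, `hclust`, `mds`, `manifest`.
#' @export
run_discovery <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  inputs <- load_inputs(config)
  beta <- inputs$beta; sheet <- inputs$sheet
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  counts <- list(probes_in = nrow(beta), samples_in = ncol(beta))
  log_stage("input probes=", nrow(beta), " samples=", ncol(beta))

  beta <- drop_incomplete_probes(beta)
  counts$probes_complete <- nrow(beta)

  if (!is.null(config$match_ratio)) {
    cases <- sheet[sheet$group == "case", ]
    pool <- sheet[sheet$group == "control", ]
    sel <- match_controls(cases, pool, ratio = config$match_ratio)
    keep <- c(cases$sample_id, sel$selected)
    sheet <- sheet[sheet$sample_id %in% keep, , drop = FALSE]
    beta <- beta[, sheet$sample_id, drop = FALSE]
    log_stage("matched controls kept=", length(sel$selected))
  }
  counts$samples_analyzed <- ncol(beta)

  disc <- sheet[sheet$group %in% c("case", "control"), , drop = FALSE]
  beta_disc <- beta[, disc$sample_id, drop = FALSE]

  if (isTRUE(config$pruning$enabled %||% TRUE)) {
    pr <- iterative_case_pruning(
      beta_disc, disc, covariates = config$covariates,
      select_params = config$select_params, svm_params = config$svm_params,
      mvp_cutoff = config$pruning$mvp_cutoff %||% 0.25,
      max_rounds = config$pruning$max_rounds %||% 3L,
      seed = config$seed)
    removed <- pr$removed_case_ids
    disc <- pr$retained_sheet
    beta_disc <- beta_disc[, disc$sample_id, drop = FALSE]
    dmp <- pr$dmp; ps <- pr$probe_set
    log_stage("pruning removed=", length(removed))
  } else {
    removed <- character(0)
    dmp <- dmp_table(beta_disc, disc, covariates = config$covariates)
    ps <- do.call(select_probes,
                  c(list(dmp = dmp, beta = beta_disc, groups = disc$group),
                    config$select_params))
  }
  counts$dmps_q05 <- sum(dmp$q < 0.05)
  counts$probes_selected <- length(ps$probe_ids)
  counts$cases_removed <- length(removed)
  log_stage("selected probes=", length(ps$probe_ids))

  split <- split_train_test(disc, fraction = 0.75,
                            seed = derive_seed(config$seed, 101L))
  clf <- do.call(train_svm,
                 c(list(beta = beta_disc[, split$train, drop = FALSE],
                        probe_set = ps,
                        sample_sheet = disc[disc$sample_id %in% split$train, ],
                        seed = derive_seed(config$seed, 102L)),
                   config$svm_params))
  test_sheet <- disc[disc$sample_id %in% split$test, ]
  test_controls <- test_sheet$sample_id[test_sheet$group == "control"]
  specificity <- if (length(test_controls))
    assess_specificity(clf, beta_disc[ps$probe_ids, test_controls, drop = FALSE])
  else NA_real_
  log_stage("held-out control specificity=", format(specificity))

  cv <- cross_validate(beta_disc, disc,
                       n_rounds = config$cv$n_rounds %||% 20L,
                       holdout_fraction = config$cv$holdout_fraction %||% 0.25,
                       seed = derive_seed(config$seed, 103L),
                       covariates = config$covariates,
                       select_params = config$select_params,
                       svm_params = config$svm_params)

  sig_beta <- beta_disc[ps$probe_ids, , drop = FALSE]
  hc <- hierarchical_cluster(sig_beta)
  mds <- mds_embed(sig_beta)

  paths <- c(dmp = file.path(config$outdir, "dmp_table.tsv"),
             probe_set = file.path(config$outdir, "probe_set.json"),
             removed = file.path(config$outdir, "removed_cases.txt"),
             classifier = file.path(config$outdir, "classifier.json"),
             scores = file.path(config$outdir, "discovery_scores.tsv"),
             cv = file.path(config$outdir, "cv_report.tsv"),
             dendrogram = file.path(config$outdir, "dendrogram.nwk"),
             mds = file.path(config$outdir, "mds.tsv"))
  write_dmp_table(dmp, paths[["dmp"]])
  write_probe_set(ps, paths[["probe_set"]])
  writeLines(removed, paths[["removed"]])
  write_classifier(clf, paths[["classifier"]])
  data.table::fwrite(mvp_report(clf, sig_beta), paths[["scores"]],
                     sep = "\t", quote = FALSE)
  data.table::fwrite(as.data.frame(cv), paths[["cv"]], sep = "\t",
                     quote = FALSE)
  write_newick(hc, paths[["dendrogram"]])
  data.table::fwrite(data.frame(sample_id = rownames(mds), mds),
                     paths[["mds"]], sep = "\t", quote = FALSE)

  manifest <- list(counts = counts, seed = config$seed,
                   specificity_held_out = specificity,
                   files = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dmp = dmp, probe_set = ps, removed_case_ids = removed,
                 classifier = clf, split = split, specificity = specificity,
                 cv = cv, hclust = hc, mds = mds, manifest = manifest,
                 retained_sheet = disc, beta = beta_disc))
}

#' Score a validation cohort against a frozen classifier
#'
#' Scores new samples with a previously trained classifier and re-clusters
#' the combined cohort on the signature probes; optionally re-derives the
#' episignature with the validation cases folded into the discovery
#' cohort (the paper-style final round that refreshes the probe list).
#'
#' @param classifier A frozen `episign_classifier`.
#' @param probe_set The `probe_set` behind the classifier.
#' @param new_beta Probes x samples beta matrix of validation samples
#'   (must share the probe universe).
#' @param train_beta,train_sheet The discovery cohort (for the combined
#'   clustering and optional re-derivation).
#' @param rederive If `TRUE`, also re-runs probe selection with validation
#'   cases added as cases.
#' @param select_params,svm_params,seed Forwarded to the re-derivation.
#' @return A list with `report` (per-sample MVP + call), `hclust`
#'   (combined clustering) and optionally `rederived` (`probe_set`,
#'   `classifier`).
#' @export
run_validation <- function(classifier, probe_set, new_beta, train_beta,
                           train_sheet, rederive = FALSE,
                           select_params = list(), svm_params = list(),
                           seed = 1L) {
  if (is.null(new_beta) || ncol(new_beta) == 0L) {
    warning("empty validation set; nothing to score")
    return(list(report = data.frame(sample_id = character(0),
                                    mvp = numeric(0), call = character(0)),
                hclust = NULL))
  }
  missing <- setdiff(probe_set$probe_ids, rownames(new_beta))
  if (length(missing))
    stop_episign("scoring_error",
                 "validation samples missing %d signature probe(s): %s",
                 length(missing), paste(utils::head(missing, 10L), collapse = ", "))
  report <- mvp_report(classifier, new_beta)
  combined <- cbind(train_beta[probe_set$probe_ids, , drop = FALSE],
                    new_beta[probe_set$probe_ids, , drop = FALSE])
  hc <- hierarchical_cluster(combined)
  out <- list(report = report, hclust = hc)
  if (rederive) {
    val_sheet <- data.frame(sample_id = colnames(new_beta), group = "case",
                            age = NA_real_, sex = NA_character_,
                            cohort = "validation", stringsAsFactors = FALSE)
    sheet_all <- rbind(train_sheet[, c("sample_id", "group", "age", "sex",
                                       "cohort")], val_sheet)
    beta_all <- cbind(train_beta, new_beta[rownames(train_beta), , drop = FALSE])
    out$rederived <- derive_and_train(beta_all, sheet_all,
                                      select_params = select_params,
                                      svm_params = svm_params, seed = seed)
  }
  out
}
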