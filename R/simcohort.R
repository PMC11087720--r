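# Synthetic EPIC-like cohort generator with planted episignatures,
# covariate structure, episignature-negative cases, mosaic attenuation and
# machine-readable ground truth.

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. The defaults
#' emulate a rare-disorder discovery study on an EPIC-like array: 60 cases
#' against 85 age- and sex-matched controls, 20,000 probes of which 200
#' carry a planted, predominantly hypermethylated episignature with a mean
#' absolute beta shift of 0.10 (per-probe shifts are drawn uniformly from
#' `delta * [0.5, 1.5]`, i.e. 0.05-0.15 at the default).
#'
#' @param n_probes Number of array probes.
#' @param n_cases,n_controls Cohort sizes.
#' @param n_true_dmps Number of planted differentially methylated probes.
#' @param delta Mean planted absolute beta shift.
#' @param hyper_fraction Fraction of planted probes shifted towards
#'   hypermethylation in cases.
#' @param mosaic_fractions Optional named numeric vector mapping case
#'   sample ids to a mosaic cell fraction `m` in `[0, 1]`; the bulk effect
#'   at a planted probe is `m * delta` (linear dilution).
#' @param n_negative_cases Number of cases carrying no episignature
#'   (equivalent to `m = 0` on every planted probe).
#' @param age_range Length-2 numeric, uniform sampling range for ages.
#' @param noise_precision Concentration of the per-observation beta noise:
#'   each measured beta is drawn from `Beta(mu * k, (1 - mu) * k)` with
#'   `k = noise_precision` and `mu` the (effect-shifted) probe mean.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_probes = 20000L, n_cases = 60L, n_controls = 85L,
                       n_true_dmps = 200L, delta = 0.10, hyper_fraction = 0.7,
                       mosaic_fractions = NULL, n_negative_cases = 0L,
                       age_range = c(2, 40), noise_precision = 100,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_true_dmps = as.integer(n_true_dmps), delta = delta,
              hyper_fraction = hyper_fraction,
              mosaic_fractions = mosaic_fractions,
              n_negative_cases = as.integer(n_negative_cases),
              age_range = as.numeric(age_range),
              noise_precision = noise_precision, seed = as.integer(seed))
  if (cfg$n_probes < 1L) stop_episign("argument_error", "n_probes must be >= 1")
  if (cfg$n_cases < 1L || cfg$n_controls < 1L)
    stop_episign("argument_error", "n_cases and n_controls must be >= 1")
  if (cfg$n_true_dmps > cfg$n_probes)
    stop_episign("argument_error", "n_true_dmps (%d) exceeds n_probes (%d)",
                 cfg$n_true_dmps, cfg$n_probes)
  if (cfg$n_true_dmps < 0L || cfg$delta < 0)
    stop_episign("argument_error", "n_true_dmps and delta must be non-negative")
  if (cfg$hyper_fraction < 0 || cfg$hyper_fraction > 1)
    stop_episign("argument_error", "hyper_fraction must lie in [0,1]")
  if (!is.null(cfg$mosaic_fractions)) {
    if (is.null(names(cfg$mosaic_fractions)) ||
        any(cfg$mosaic_fractions < 0 | cfg$mosaic_fractions > 1))
      stop_episign("argument_error",
                   "mosaic_fractions must be a named vector with values in [0,1]")
  }
  if (cfg$n_negative_cases > cfg$n_cases)
    stop_episign("argument_error", "n_negative_cases exceeds n_cases")
  if (cfg$noise_precision <= 0)
    stop_episign("argument_error", "noise_precision must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate baseline probe methylation means
#'
#' Baseline per-probe means are drawn from a three-component mixture that
#' reproduces the characteristic bimodality of array beta values: 45%
#' low-methylated (around 0.1), 45% high-methylated (around 0.9) and 10%
#' intermediate. Means are clipped to (0.01, 0.99).
#'
#' @param n_probes Number of probes (>= 1).
#' @param seed Integer seed.
#' @param mixture List with numeric vectors `weights`, `means`,
#'   `concentration` (one entry per component).
#' @return A data.frame of probe truth records: `probe_id`,
#'   `baseline_mean`, `precision`, `is_dmp`, `direction`, `delta`.
#' @export
simulate_baseline <- function(n_probes, seed = 1L,
                              mixture = list(weights = c(0.45, 0.45, 0.10),
                                             means = c(0.10, 0.90, 0.50),
                                             concentration = c(40, 40, 10))) {
  n_probes <- as.integer(n_probes)
  if (is.na(n_probes) || n_probes < 1L)
    stop_episign("argument_error", "n_probes must be a positive integer")
  stopifnot(length(mixture$weights) == length(mixture$means),
            length(mixture$means) == length(mixture$concentration))
  withr::with_seed(as.integer(seed), {
    comp <- sample.int(length(mixture$weights), n_probes, replace = TRUE,
                       prob = mixture$weights)
    k <- mixture$concentration[comp]
    mu <- mixture$means[comp]
    means <- stats::rbeta(n_probes, mu * k, (1 - mu) * k)
  })
  means <- pmin(pmax(means, 0.011), 0.989)
  data.frame(probe_id = sprintf("cg%08d", seq_len(n_probes)),
             baseline_mean = means,
             precision = NA_real_,
             is_dmp = FALSE,
             direction = "none",
             delta = 0,
             stringsAsFactors = FALSE)
}

#' Shift a probe mean by a (possibly mosaic-diluted) case effect
#'
#' In a bulk sample where only a fraction `m` of cells carries the variant,
#' the cell-level methylation shift `delta` is diluted linearly, so the
#' expected bulk mean is `baseline + s * m * delta` with `s = +1` for
#' hypermethylation and `s = -1` for hypomethylation. The result is clipped
#' to `[0.01, 0.99]`.
#'
#' @param baseline_mean Baseline probe mean(s) in (0, 1).
#' @param delta Non-negative planted absolute shift.
#' @param direction `"hyper"`, `"hypo"` or `"none"` (recycled).
#' @param m Mosaic cell fraction in `[0, 1]` (default 1, fully affected).
#' @return Shifted mean(s).
#' @export
apply_case_effect <- function(baseline_mean, delta, direction, m = 1) {
  if (any(baseline_mean <= 0 | baseline_mean >= 1))
    stop_episign("argument_error", "baseline_mean must lie in (0, 1)")
  if (any(m < 0 | m > 1))
    stop_episign("argument_error", "mosaic fraction m must lie in [0, 1]")
  if (any(delta < 0))
    stop_episign("argument_error", "delta must be non-negative")
  dir <- rep_len(as.character(direction), length(baseline_mean))
  if (!all(dir %in% c("hyper", "hypo", "none")))
    stop_episign("argument_error", "direction must be hyper, hypo or none")
  if (any(dir == "none" & rep_len(delta, length(dir)) > 0))
    stop_episign("consistency_error", "direction 'none' with delta > 0")
  s <- ifelse(dir == "hyper", 1, ifelse(dir == "hypo", -1, 0))
  pmin(pmax(baseline_mean + s * m * delta, 0.01), 0.99)
}

# Plant an episignature into a baseline truth table. Planted probes are
# restricted to baselines with headroom for the shift so the clip at
# 0.01/0.99 never truncates the planted effect.
plant_signature <- function(truth, n_true_dmps, delta, hyper_fraction,
                            forced = NULL, exclude = character(0)) {
  if (n_true_dmps == 0L && is.null(forced)) return(truth)
  n_forced <- if (is.null(forced)) 0L else length(forced$probe_id)
  n_new <- n_true_dmps - n_forced
  eligible <- which(truth$baseline_mean >= 0.15 & truth$baseline_mean <= 0.80 &
                      !(truth$probe_id %in% c(exclude,
                                              if (n_forced) forced$probe_id)))
  if (length(eligible) < n_new)
    stop_episign("argument_error",
                 "only %d probes have headroom for planting %d DMPs",
                 length(eligible), n_new)
  new_idx <- if (n_new > 0L) sample(eligible, n_new) else integer(0)
  n_hyper <- round(hyper_fraction * n_new)
  dirs <- rep("hypo", n_new)
  if (n_new > 0L) dirs[sample.int(n_new, n_hyper)] <- "hyper"
  deltas <- if (n_new > 0L) stats::runif(n_new, 0.5 * delta, 1.5 * delta) else numeric(0)
  truth$is_dmp[new_idx] <- TRUE
  truth$direction[new_idx] <- dirs
  truth$delta[new_idx] <- deltas
  if (n_forced) {
    fi <- match(forced$probe_id, truth$probe_id)
    truth$is_dmp[fi] <- TRUE
    truth$direction[fi] <- forced$direction
    truth$delta[fi] <- forced$delta
    truth$baseline_mean[fi] <- forced$baseline_mean
  }
  truth
}

# Expected beta mean matrix (probes x samples) for a cohort given truth,
# sample metadata and mosaic map; covariate effects act on the M scale.
cohort_mean_matrix <- function(truth, sheet, mosaic, age_effects, sex_effects,
                               age_center) {
  n_probes <- nrow(truth)
  n_samples <- nrow(sheet)
  mu <- matrix(rep(truth$baseline_mean, n_samples), nrow = n_probes)
  planted <- which(truth$is_dmp)
  is_case <- sheet$group == "case"
  for (j in which(is_case)) {
    m <- mosaic[[sheet$sample_id[j]]]
    if (m > 0)
      mu[planted, j] <- apply_case_effect(truth$baseline_mean[planted],
                                          truth$delta[planted],
                                          truth$direction[planted], m = m)
  }
  # covariates on the M scale, then back to beta
  cov_idx <- c(age_effects$idx, sex_effects$idx)
  if (length(cov_idx)) {
    mm <- beta_to_m(mu[cov_idx, , drop = FALSE], epsilon = 0.001)
    if (length(age_effects$idx)) {
      rows <- seq_along(age_effects$idx)
      mm[rows, ] <- mm[rows, ] +
        outer(age_effects$slope, sheet$age - age_center)
    }
    if (length(sex_effects$idx)) {
      rows <- length(age_effects$idx) + seq_along(sex_effects$idx)
      mm[rows, ] <- mm[rows, ] +
        outer(sex_effects$shift, as.numeric(sheet$sex == "F"))
    }
    mu[cov_idx, ] <- m_to_beta(mm)
  }
  pmin(pmax(mu, 0.01), 0.99)
}

# Draw beta observations around a mean matrix with the configured
# concentration; values are kept strictly inside (0, 1).
draw_betas <- function(mu, precision) {
  vals <- stats::rbeta(length(mu), mu * precision, (1 - mu) * precision)
  vals <- pmin(pmax(vals, 1e-6), 1 - 1e-6)
  matrix(vals, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate a synthetic methylation cohort with a planted episignature
#'
#' Generates a beta matrix, sample sheet and ground-truth record for a
#' case/control cohort. Cases carry the planted shift at every
#' episignature probe, attenuated per sample by its mosaic fraction;
#' episignature-negative cases receive no shift at all (`m = 0`). A random
#' 1% of non-planted probes drift linearly with age on the M scale and a
#' small labeled block responds to sex, so covariate adjustment is
#' exercised downstream.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_cohort` with elements `beta` (probes x
#'   samples matrix), `sample_sheet` (data.frame) and `truth` (list with
#'   `probe_truths`, `planted_set`, `negative_case_ids`, `mosaic_map`,
#'   `age_probes`, `sexlike_probes`, `config`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, {
    truth <- simulate_baseline(config$n_probes, seed = derive_seed(config$seed, 1L))
    truth$precision <- config$noise_precision
    truth <- plant_signature(truth, config$n_true_dmps, config$delta,
                             config$hyper_fraction)
    planted_ids <- truth$probe_id[truth$is_dmp]

    free <- which(!truth$is_dmp)
    n_age <- max(0L, round(0.01 * length(free)))
    age_idx <- if (n_age) sample(free, n_age) else integer(0)
    free2 <- setdiff(free, age_idx)
    n_sex <- max(0L, round(0.005 * length(free)))
    sex_idx <- if (n_sex) sample(free2, n_sex) else integer(0)
    age_effects <- list(idx = age_idx, slope = stats::rnorm(n_age, 0, 0.01))
    sex_effects <- list(idx = sex_idx, shift = stats::rnorm(n_sex, 0, 0.5))

    sheet <- data.frame(
      sample_id = c(sprintf("case_%03d", seq_len(config$n_cases)),
                    sprintf("ctrl_%03d", seq_len(config$n_controls))),
      group = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
      age = round(stats::runif(config$n_cases + config$n_controls,
                               config$age_range[1L], config$age_range[2L]), 1),
      sex = sample(c("F", "M"), config$n_cases + config$n_controls,
                   replace = TRUE),
      cohort = "synthetic",
      stringsAsFactors = FALSE)

    case_ids <- sheet$sample_id[sheet$group == "case"]
    mosaic <- stats::setNames(rep(1, length(case_ids)), case_ids)
    if (!is.null(config$mosaic_fractions)) {
      unknown <- setdiff(names(config$mosaic_fractions), case_ids)
      if (length(unknown))
        stop_episign("argument_error", "mosaic_fractions for unknown case(s): %s",
                     paste(unknown, collapse = ", "))
      mosaic[names(config$mosaic_fractions)] <- config$mosaic_fractions
    }
    negative_ids <- character(0)
    if (config$n_negative_cases > 0L) {
      negative_ids <- sample(case_ids, config$n_negative_cases)
      mosaic[negative_ids] <- 0
    }

    mu <- cohort_mean_matrix(truth, sheet, as.list(mosaic), age_effects,
                             sex_effects, mean(config$age_range))
    dimnames(mu) <- list(truth$probe_id, sheet$sample_id)
    beta <- draw_betas(mu, config$noise_precision)
  })
  structure(list(
    beta = beta,
    sample_sheet = sheet,
    truth = list(probe_truths = truth,
                 planted_set = planted_ids,
                 negative_case_ids = negative_ids,
                 mosaic_map = mosaic,
                 age_probes = truth$probe_id[age_effects$idx],
                 sexlike_probes = truth$probe_id[sex_effects$idx],
                 age_effects = age_effects,
                 sex_effects = sex_effects,
                 config = config)
  ), class = "sim_cohort")
}

#' Simulate additional case samples from an existing cohort's ground truth
#'
#' Draws new case samples against the same baseline, planted probe set and
#' noise model as a previously simulated cohort — e.g. a validation series
#' carrying the same episignature, or mosaic cases with an attenuated
#' effect.
#'
#' @param sim A `sim_cohort` object.
#' @param n Number of new case samples.
#' @param seed Integer seed.
#' @param m Mosaic fraction applied to every new sample (scalar, default 1).
#' @param prefix Sample id prefix.
#' @return A list with `beta` (probes x n matrix) and `sample_sheet`.
#' @export
simulate_cases <- function(sim, n, seed, m = 1, prefix = "val") {
  stopifnot(inherits(sim, "sim_cohort"))
  config <- sim$truth$config
  truth <- sim$truth$probe_truths
  withr::with_seed(as.integer(seed), {
    sheet <- data.frame(
      sample_id = sprintf("%s_%03d", prefix, seq_len(n)),
      group = "validation",
      age = round(stats::runif(n, config$age_range[1L], config$age_range[2L]), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      cohort = "synthetic_validation",
      stringsAsFactors = FALSE)
    sheet$group <- "case"  # planted effect applies to cases
    mosaic <- stats::setNames(rep(m, n), sheet$sample_id)
    mu <- cohort_mean_matrix(truth, sheet, as.list(mosaic),
                             sim$truth$age_effects, sim$truth$sex_effects,
                             mean(config$age_range))
    dimnames(mu) <- list(truth$probe_id, sheet$sample_id)
    beta <- draw_betas(mu, config$noise_precision)
  })
  sheet$group <- "validation"
  list(beta = beta, sample_sheet = sheet)
}

#' Simulate related cohorts with a controlled episignature overlap
#'
#' Cohort 1 is generated from `base_config`; each further cohort shares
#' exactly `round(overlap_fraction * n_true_dmps)` planted probes with
#' cohort 1 (same direction and shift) and plants the remainder on probes
#' disjoint from cohort 1's signature. All cohorts share the same probe
#' universe and baseline means, as disorder cohorts profiled on the same
#' array do.
#'
#' @param base_config A [sim_config()].
#' @param k_cohorts Number of cohorts (>= 2).
#' @param overlap_fraction Fraction of cohort 1's planted set shared by
#'   each other cohort, in `[0, 1]`.
#' @param hyper_fractions Optional numeric vector (length `k_cohorts`) of
#'   per-cohort hypermethylation fractions; defaults to the base config's.
#' @return A list of `sim_cohort` objects.
#' @export
simulate_multi_cohort <- function(base_config, k_cohorts, overlap_fraction,
                                  hyper_fractions = NULL) {
  if (!inherits(base_config, "sim_config"))
    base_config <- do.call(sim_config, base_config)
  if (k_cohorts < 2L)
    stop_episign("argument_error", "k_cohorts must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop_episign("argument_error", "overlap_fraction must lie in [0, 1]")
  if (is.null(hyper_fractions))
    hyper_fractions <- rep(base_config$hyper_fraction, k_cohorts)

  first <- simulate_cohort(base_config)
  cohorts <- vector("list", k_cohorts)
  cohorts[[1L]] <- first
  t1 <- first$truth$probe_truths
  planted1 <- which(t1$is_dmp)
  n_shared <- round(overlap_fraction * base_config$n_true_dmps)

  for (i in 2:k_cohorts) {
    seed_i <- derive_seed(base_config$seed, i)
    cfg_i <- base_config
    cfg_i$seed <- seed_i
    cfg_i$hyper_fraction <- hyper_fractions[i]
    withr::with_seed(seed_i, {
      truth_i <- t1
      truth_i$is_dmp <- FALSE
      truth_i$direction <- "none"
      truth_i$delta <- 0
      shared_idx <- if (n_shared > 0L) sample(planted1, n_shared) else integer(0)
      forced <- if (n_shared > 0L)
        list(probe_id = t1$probe_id[shared_idx],
             direction = t1$direction[shared_idx],
             delta = t1$delta[shared_idx],
             baseline_mean = t1$baseline_mean[shared_idx])
      truth_i <- plant_signature(truth_i,
                                 cfg_i$n_true_dmps, cfg_i$delta,
                                 cfg_i$hyper_fraction, forced = forced,
                                 exclude = t1$probe_id[planted1])
      sheet_i <- data.frame(
        sample_id = sprintf("c%d_%s_%03d", i,
                            rep(c("case", "ctrl"), c(cfg_i$n_cases, cfg_i$n_controls)),
                            c(seq_len(cfg_i$n_cases), seq_len(cfg_i$n_controls))),
        group = rep(c("case", "control"), c(cfg_i$n_cases, cfg_i$n_controls)),
        age = round(stats::runif(cfg_i$n_cases + cfg_i$n_controls,
                                 cfg_i$age_range[1L], cfg_i$age_range[2L]), 1),
        sex = sample(c("F", "M"), cfg_i$n_cases + cfg_i$n_controls, TRUE),
        cohort = sprintf("synthetic_%d", i),
        stringsAsFactors = FALSE)
      mosaic_i <- stats::setNames(rep(1, cfg_i$n_cases),
                                  sheet_i$sample_id[sheet_i$group == "case"])
      mu <- cohort_mean_matrix(truth_i, sheet_i, as.list(mosaic_i),
                               list(idx = integer(0), slope = numeric(0)),
                               list(idx = integer(0), shift = numeric(0)),
                               mean(cfg_i$age_range))
      dimnames(mu) <- list(truth_i$probe_id, sheet_i$sample_id)
      beta_i <- draw_betas(mu, cfg_i$noise_precision)
    })
    cohorts[[i]] <- structure(list(
      beta = beta_i, sample_sheet = sheet_i,
      truth = list(probe_truths = truth_i,
                   planted_set = truth_i$probe_id[truth_i$is_dmp],
                   negative_case_ids = character(0),
                   mosaic_map = mosaic_i,
                   age_probes = character(0), sexlike_probes = character(0),
                   age_effects = list(idx = integer(0), slope = numeric(0)),
                   sex_effects = list(idx = integer(0), shift = numeric(0)),
                   config = cfg_i)), class = "sim_cohort")
  }
  cohorts
}

#' Write a simulated cohort to disk
#'
#' Writes the beta matrix (TSV), sample sheet (CSV), probe-level ground
#' truth (TSV: `probe_id`, `is_dmp`, `direction`, `delta`) and the
#' configuration (YAML) into a directory.
#'
#' @param sim A `sim_cohort` object.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             sample_sheet = file.path(dir, "sample_sheet.csv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  write_beta_matrix(sim$beta, paths[["beta"]])
  write_sample_sheet(sim$sample_sheet, paths[["sample_sheet"]])
  tr <- sim$truth$probe_truths[, c("probe_id", "is_dmp", "direction", "delta")]
  data.table::fwrite(tr, paths[["truth"]], sep = "\t", quote = FALSE)
  cfg <- unclass(sim$truth$config)
  cfg$mosaic_fractions <- as.list(cfg$mosaic_fractions)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
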