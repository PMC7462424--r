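#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: the task design,
#' the planted model (for synthetic cohorts), the gamma grid, iteration
#' and permutation counts, thresholds, and a master seed from which each
#' stochastic stage derives its own seed. Every stochastic stage must
#' have an explicit seed; construction fails otherwise. The configuration
#' round-trips losslessly through YAML or JSON (see [write_config()]).
#'
#' Defaults are sized for a workstation-scale synthetic analysis (20
#' subjects, 60 regions, 25-step grid, reduced permutation counts); the
#' full analysis scale used on real cohorts (1000 Louvain iterations,
#' 50,000 / 10,000 permutations, 100-step grid) is reachable by raising
#' the corresponding fields.
#'
#' @param seed master integer seed.
#' @param cohort `"connectivity"` (direct network sampling, fast) or
#'   `"timeseries"` (full LS-S path).
#' @param n_subjects,n_regions cohort dimensions.
#' @param n_communities planted number of communities.
#' @param n_changed planted number of membership-changing regions.
#' @param rho_within,rho_between,censor_rate planted-model parameters (see
#'   [planted_model()]).
#' @param sigma_noise planted-model noise scale. For connectivity cohorts
#'   this is edge noise on the z-score scale (default 4, roughly
#'   two-thirds of the planted within-community weight, giving realistic
#'   subject-to-subject partition variability); for timeseries cohorts it
#'   is volume noise relative to unit trial amplitudes (about 1 is
#'   realistic).
#' @param design list of [generate_task_design()] arguments (used by the
#'   timeseries cohort).
#' @param grid gamma grid.
#' @param sweep_repeats,n_iter_sweep,n_iter_final iteration counts for the
#'   sweep and final partitioning.
#' @param consensus_reps Louvain repartitions per consensus iteration.
#' @param tau consensus threshold.
#' @param n_null,percentile community-selection settings.
#' @param n_perm_community,n_perm_region Monte Carlo iteration counts.
#' @param alpha per-step significance level for region counting.
#' @param fdr_q Benjamini-Hochberg level for community comparisons.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed,
                            cohort = c("connectivity", "timeseries"),
                            n_subjects = 20,
                            n_regions = 60,
                            n_communities = 4,
                            n_changed = 6,
                            rho_within = 0.6,
                            rho_between = 0.1,
                            sigma_noise = 4,
                            censor_rate = 0.04,
                            design = list(n_trials_per_condition = 80,
                                          numerosities = c(2, 4, 6, 8),
                                          isi_set = seq(3300, 7300, 1000),
                                          tr = 2, max_run = 3),
                            grid = gamma_grid(0.2, 5, 0.2),
                            sweep_repeats = 5,
                            n_iter_sweep = 50,
                            n_iter_final = 250,
                            consensus_reps = 50,
                            tau = 0.5,
                            n_null = 500,
                            percentile = 99,
                            n_perm_community = 1000,
                            n_perm_region = 200,
                            alpha = 0.05,
                            fdr_q = 0.05) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("pipeline_config requires an explicit master seed")
  }
  cohort <- match.arg(cohort)
  cfg <- list(
    seed = as.integer(seed), cohort = cohort,
    n_subjects = n_subjects, n_regions = n_regions,
    n_communities = n_communities, n_changed = n_changed,
    rho_within = rho_within, rho_between = rho_between,
    sigma_noise = sigma_noise, censor_rate = censor_rate,
    design = design,
    grid = list(start = min(grid), stop = max(grid),
                step = attr(grid, "step")),
    sweep_repeats = sweep_repeats, n_iter_sweep = n_iter_sweep,
    n_iter_final = n_iter_final, consensus_reps = consensus_reps,
    tau = tau, n_null = n_null, percentile = percentile,
    n_perm_community = n_perm_community, n_perm_region = n_perm_region,
    alpha = alpha, fdr_q = fdr_q
  )
  # stage seeds, all derived from the master seed and logged in the report
  cfg$stage_seeds <- as.list(cfg$seed + c(design = 1L, cohort = 2L,
                                          sweep = 3L, final = 4L,
                                          communities = 5L, compare = 6L,
                                          regions = 7L))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML or JSON)
#'
#' @param config a `pipeline_config`.
#' @param path destination; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$design$numerosities <- as.numeric(x$design$numerosities)
  x$design$isi_set <- as.numeric(x$design$isi_set)
  structure(x, class = "pipeline_config")
}

# planted partitions implied by a config: communities of near-equal size;
# the first n_changed regions move to the next community in condition B
.config_partitions <- function(config) {
  n <- config$n_regions
  k <- config$n_communities
  pA <- sort(rep_len(seq_len(k), n))
  pB <- pA
  if (config$n_changed > 0) {
    chg <- seq_len(config$n_changed)
    pB[chg] <- (pA[chg] %% k) + 1L
  }
  list(A = pA, B = pB)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> (betas -> connect) -> sweep -> select-gamma ->
#' partition -> communities -> compare -> regions, entirely determined by
#' the configuration (identical configs give bit-identical reports). The
#' connectivity cohort path samples subject networks directly from the
#' planted block model; the timeseries path simulates volumes, estimates
#' LS-S betas, scrubs, normalizes and correlates.
#'
#' @param config a `pipeline_config`.
#' @return object of class `run_report`: per-stage summaries (selected
#'   gamma, community tables, comparison tables, flagged regions), the
#'   configuration, its hash, and a report hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$stage_seeds)) stop("config is missing stage seeds")
  grid <- gamma_grid(config$grid$start, config$grid$stop, config$grid$step)
  parts <- .config_partitions(config)
  model <- planted_model(parts$A, parts$B,
                         rho_within = config$rho_within,
                         rho_between = config$rho_between,
                         sigma_noise = config$sigma_noise,
                         censor_rate = config$censor_rate,
                         n_subjects = config$n_subjects,
                         seed = config$stage_seeds$cohort)

  # --- simulate + connect ---------------------------------------------
  if (config$cohort == "connectivity") {
    nets <- generate_connectivity_cohort(model)
    design <- NULL
    retained <- NULL
  } else {
    design <- do.call(generate_task_design,
                      c(config$design,
                        list(seed = config$stage_seeds$design)))
    cohort <- generate_cohort(design, model)
    nets <- vector("list", config$n_subjects)
    retained <- matrix(NA_integer_, config$n_subjects, 2,
                       dimnames = list(NULL, c("A", "B")))
    for (s in seq_len(config$n_subjects)) {
      subj <- cohort$subjects[[s]]
      bs <- estimate_beta_series(subj$roi_timeseries, design,
                                 censor = subj$censor_mask)
      bs <- scrub_trials(bs, design, subj$censor_mask)
      bs <- normalize_within_condition(bs)
      nets[[s]] <- list(A = compute_connectivity(bs, "A"),
                        B = compute_connectivity(bs, "B"))
      retained[s, ] <- bs$n_retained[c("A", "B")]
    }
  }

  # --- sweep + gamma selection ----------------------------------------
  sweep <- run_gamma_sweep(nets, grid,
                           n_repeats = config$sweep_repeats,
                           n_iter_subject = config$n_iter_sweep,
                           tau = config$tau,
                           seed = config$stage_seeds$sweep,
                           consensus_reps = config$consensus_reps)
  sel <- select_gamma(sweep)
  gamma_star <- sel$gamma_star

  # --- final partitioning at gamma* -----------------------------------
  set.seed(config$stage_seeds$final)
  final_parts <- list(A = vector("list", config$n_subjects),
                      B = vector("list", config$n_subjects))
  for (s in seq_len(config$n_subjects)) {
    for (cond in c("A", "B")) {
      final_parts[[cond]][[s]] <- subject_consensus(
        nets[[s]][[cond]], gamma = gamma_star,
        n_iter = config$n_iter_final, tau = config$tau,
        consensus_reps = config$consensus_reps)$partition
    }
  }
  groupA <- group_consensus(final_parts$A, tau = config$tau,
                            consensus_reps = config$consensus_reps)
  groupB <- group_consensus(final_parts$B, tau = config$tau,
                            consensus_reps = config$consensus_reps)
  gB_matched <- match_labels(groupA$partition, groupB$partition)

  # --- community selection + allegiance comparison --------------------
  selection <- list(
    A = select_communities(lapply(nets, `[[`, "A"), groupA$partition,
                           gamma = gamma_star, n_null = config$n_null,
                           percentile = config$percentile,
                           seed = config$stage_seeds$communities),
    B = select_communities(lapply(nets, `[[`, "B"), gB_matched,
                           gamma = gamma_star, n_null = config$n_null,
                           percentile = config$percentile,
                           seed = config$stage_seeds$communities + 1L)
  )
  compare <- list(
    A = community_allegiance_difference(
      groupA$allegiance, groupB$allegiance, groupA$partition,
      final_parts$A, final_parts$B, n_perm = config$n_perm_community,
      seed = config$stage_seeds$compare, fdr_q = config$fdr_q),
    B = community_allegiance_difference(
      groupA$allegiance, groupB$allegiance, gB_matched,
      final_parts$A, final_parts$B, n_perm = config$n_perm_community,
      seed = config$stage_seeds$compare + 1L, fdr_q = config$fdr_q)
  )

  # --- region-level sweep ---------------------------------------------
  regions <- region_sweep(lapply(sweep$subject_partitions, `[[`, "A"),
                          lapply(sweep$subject_partitions, `[[`, "B"),
                          grid, n_perm = config$n_perm_region,
                          alpha = config$alpha,
                          seed = config$stage_seeds$regions)
  count_fit <- fit_negative_binomial(regions$counts)
  outliers <- detect_outlier_regions(regions$counts, count_fit)

  report <- list(
    package_version = as.character(utils::packageVersion("betanet")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    gamma_star = gamma_star,
    flex_sd_curve = sel$curve,
    n_communities = c(A = max(groupA$partition), B = max(gB_matched)),
    n_singletons = c(A = sum(table(groupA$partition) == 1),
                     B = sum(table(gB_matched) == 1)),
    retained_trials = retained,
    group_partition = list(A = groupA$partition, B = gB_matched),
    community_selection = selection,
    allegiance_comparison = compare,
    region_counts = regions$counts,
    count_fit_type = count_fit$type,
    flagged_regions = outliers$region[outliers$flagged],
    planted_changed_regions = model$changed_regions
  )
  report$report_hash <- rlang::hash(report)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (config", substr(x$config_hash, 1, 8), ")\n")
  cat("  gamma* =", x$gamma_star, "\n")
  cat("  communities (A/B):", x$n_communities["A"], "/",
      x$n_communities["B"], "\n")
  cat("  selected communities (A/B):",
      sum(x$community_selection$A$selected), "/",
      sum(x$community_selection$B$selected), "\n")
  cat("  flagged regions:", if (length(x$flagged_regions))
    paste(x$flagged_regions, collapse = ", ") else "none", "\n")
  cat("  report hash:", x$report_hash, "\n")
  invisible(x)
}

#' Write a run report as JSON (plus a Markdown summary)
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return invisibly the JSON path.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  md <- c(
    "# Pipeline run report",
    paste0("- config hash: ", report$config_hash),
    paste0("- report hash: ", report$report_hash),
    paste0("- gamma*: ", report$gamma_star),
    paste0("- communities (A/B): ", report$n_communities["A"], " / ",
           report$n_communities["B"]),
    paste0("- flagged regions: ",
           if (length(report$flagged_regions))
             paste(report$flagged_regions, collapse = ", ") else "none")
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(json_path)
}
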