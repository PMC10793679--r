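#' Configuration for a full pipeline run
#'
#' @param rank taxonomic rank for community-level analyses (default genus)
#' @param factors metadata columns tested one at a time by PERMANOVA on the
#'   baseline fecal samples (each accompanied by a dispersion-homogeneity
#'   check)
#' @param min_reads per-sample read-count threshold (strict-below excluded)
#' @param rare_frac dataset-wide relative-abundance threshold for taxa
#' @param min_count per-sample presence threshold for the OTU set logic
#' @param min_prevalence prevalence filter for per-taxon testing
#' @param n_perm permutations for PERMANOVA / dispersion tests
#' @param donor_rule `"any"` or `"all"` donor-presence pooling
#' @param donor_reference `"pairwise_mean"` or `"profile_mean"` (see
#'   [donor_dissimilarity_trajectory()])
#' @param exclude_post_relapse drop samples taken after relapse from the
#'   donor-similarity and engraftment analyses
#' @param seed RNG seed for every stochastic stage
#' @return a `run_config` list
#' @export
run_config <- function(rank = "genus",
                       factors = c("arm", "antibiotic_type",
                                   "antibiotic_pattern"),
                       min_reads = 10000,
                       rare_frac = 1e-5,
                       min_count = 1,
                       min_prevalence = 0.1,
                       n_perm = 999,
                       donor_rule = "any",
                       donor_reference = "pairwise_mean",
                       exclude_post_relapse = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full study-shaped analysis pipeline
#'
#' Executes, in fixed order: the rarity filter, the read-count filter,
#' per-sample diversity, the genus-level Bray-Curtis distance matrix on
#' baseline fecal samples with one PERMANOVA + dispersion check per
#' configured factor, dissimilarity-to-donor trajectories, engraftment
#' trajectories, and per-taxon group tests (baseline patients vs donor).
#' All outputs are deterministic for identical `(table, meta, config)`.
#'
#' @param table a [count_table()] covering patient and donor samples
#' @param meta sample metadata (one row per table sample)
#' @param config a [run_config()]
#' @param out_dir optional directory; when given, stage outputs (TSVs) and
#'   the summary report (`report.json`) are written there
#' @return a `run_report` list: `provenance`, `attrition`, `diversity`,
#'   `permanova`, `trajectory`, `engraftment`, `taxon_tests`
#' @export
run_pipeline <- function(table, meta, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(table, "count_table"), inherits(config, "run_config"))
  meta_all <- check_table_metadata(table, meta)
  missing_factors <- setdiff(config$factors, names(meta_all))
  if (length(missing_factors)) {
    stop("pipeline config references missing metadata column: ",
         missing_factors[1])
  }

  n0_samples <- n_samples(table); n0_taxa <- n_taxa(table)
  filtered <- filter_min_relative_abundance(table, config$rare_frac)
  dropped_taxa <- attr(filtered, "dropped_taxa")
  filtered <- filter_min_reads(filtered, config$min_reads)
  dropped_samples <- attr(filtered, "dropped_samples")
  meta <- meta_all[meta_all$sample_id %in% sample_ids(filtered), ,
                   drop = FALSE]
  attrition <- list(
    taxa_in = n0_taxa, taxa_dropped_rare = length(dropped_taxa),
    taxa_out = n_taxa(filtered),
    samples_in = n0_samples, samples_dropped_low_depth = length(dropped_samples),
    samples_out = n_samples(filtered),
    dropped_samples = dropped_samples)

  div <- diversity_by_group(filtered, meta)

  # Baseline fecal community: per-factor PERMANOVA with dispersion check.
  base_ids <- meta$sample_id[meta$site == "fecal" & meta$week == 0 &
                               meta$arm != "donor"]
  perm_results <- list()
  if (length(base_ids) >= 4) {
    base_tab <- subset_table(filtered, samples = base_ids)
    dm <- distance_matrix(base_tab, rank = config$rank)
    bm <- meta[match(base_ids, meta$sample_id), , drop = FALSE]
    for (fac in config$factors) {
      vals <- bm[[fac]]
      ok <- !is.na(vals)
      g <- factor(vals[ok])
      g <- droplevels(g)
      sizes <- table(g)
      if (nlevels(g) < 2 || any(sizes < 2)) {
        perm_results[[fac]] <- list(skipped = TRUE,
                                    reason = "fewer than 2 usable groups")
        next
      }
      sub_dm <- dm[ok, ok, drop = FALSE]
      pv <- permanova(sub_dm, g, n_perm = config$n_perm, seed = config$seed)
      bd <- beta_dispersion(sub_dm, g, n_perm = config$n_perm,
                            seed = config$seed)
      perm_results[[fac]] <- list(
        skipped = FALSE, n = sum(ok), n_dropped_na = sum(!ok),
        r_squared = pv$r_squared, pseudo_f = pv$pseudo_f,
        p_value = pv$p_value, dispersion_p = bd$p_value)
    }
  }

  traj <- donor_dissimilarity_trajectory(
    filtered, meta, rank = config$rank,
    exclude_post_relapse = config$exclude_post_relapse,
    donor_reference = config$donor_reference)
  traj_summary <- stats::aggregate(dissimilarity ~ arm + week, data = traj,
                                   FUN = mean)

  engraft <- engraftment_trajectories(
    filtered, meta, donor_presence_rule = config$donor_rule,
    min_count = config$min_count,
    exclude_post_relapse = config$exclude_post_relapse)
  engraft_summary <- if (nrow(engraft)) {
    ok <- !is.na(engraft$fraction)
    stats::aggregate(fraction ~ arm + week, data = engraft[ok, , drop = FALSE],
                     FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                         n = length(x)))
  } else NULL

  contrast <- baseline_vs_donor_contrast(filtered, meta, rank = config$rank,
                                         min_prevalence = config$min_prevalence)

  report <- list(
    provenance = list(package_version = as.character(
                        utils::packageVersion("pouchtrack")),
                      seed = config$seed,
                      config = config[setdiff(names(config), "factors")],
                      factors = config$factors),
    attrition = attrition,
    diversity = div,
    permanova = perm_results,
    trajectory = traj,
    trajectory_summary = traj_summary,
    engraftment = engraft,
    engraftment_summary = engraft_summary,
    taxon_tests = contrast$tests,
    diversity_contrast_p = contrast$diversity_p)
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(div, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(traj, file.path(out_dir, "donor_dissimilarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(engraft, file.path(out_dir, "engraftment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(contrast$tests, file.path(out_dir, "taxon_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(provenance = report$provenance, attrition = attrition,
           permanova = perm_results,
           trajectory_summary = traj_summary,
           diversity_contrast_p = contrast$diversity_p,
           n_significant_taxa = sum(contrast$tests$q_value < 0.05 &
                                      contrast$tests$p_value < 0.05)),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  samples: %d in, %d out (%d below read threshold)\n",
              x$attrition$samples_in, x$attrition$samples_out,
              x$attrition$samples_dropped_low_depth))
  cat(sprintf("  taxa: %d in, %d out\n", x$attrition$taxa_in,
              x$attrition$taxa_out))
  for (fac in names(x$permanova)) {
    pr <- x$permanova[[fac]]
    if (isTRUE(pr$skipped)) next
    cat(sprintf("  PERMANOVA %s: R2 = %.3f, p = %.4g (dispersion p = %.4g)\n",
                fac, pr$r_squared, pr$p_value, pr$dispersion_p))
  }
  cat(sprintf("  significant taxa (baseline vs donor): %d\n",
              sum(x$taxon_tests$q_value < 0.05 & x$taxon_tests$p_value < 0.05)))
  invisible(x)
}

#' Baseline patients versus donor contrast
#'
#' Genus-level per-taxon tests of the patients' baseline fecal samples
#' against the donor samples, plus a rank-sum comparison of inverse
#' Simpson diversity between the two groups.
#'
#' @param table a filtered [count_table()]
#' @param meta sample metadata
#' @param rank rank for the per-taxon tests
#' @param min_prevalence prevalence filter
#' @return list with `tests` (a [taxon_group_test()] result over groups
#'   donor/patient) and `diversity_p` (rank-sum p-value, donor vs patient)
#' @export
baseline_vs_donor_contrast <- function(table, meta, rank = "genus",
                                       min_prevalence = 0.1) {
  meta <- check_table_metadata(table, meta)
  donor_ids <- meta$sample_id[meta$arm == "donor"]
  patient_ids <- meta$sample_id[meta$arm != "donor" & meta$site == "fecal" &
                                  meta$week == 0]
  if (length(donor_ids) < 2) stop("need at least 2 donor samples")
  if (!length(patient_ids)) stop("no patient baseline samples")
  ids <- c(donor_ids, patient_ids)
  sub <- subset_table(table, samples = ids)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  m$contrast_group <- ifelse(m$arm == "donor", "donor", "patient")
  tests <- taxon_group_test(sub, m, rank = rank, grouping = "contrast_group",
                            min_prevalence = min_prevalence)
  div <- diversity_by_group(sub, m)
  is_donor <- div$arm == "donor"
  dp <- rank_sum_test(div$inverse_simpson[is_donor],
                      div$inverse_simpson[!is_donor])$p.value
  list(tests = tests, diversity_p = dp)
}

#' Pouch versus ileum mucosal contrast
#'
#' Pairs the two mucosal sites within subject at a given week and applies
#' the signed-rank test per taxon to the paired differences of per-sample
#' fractions, BH-corrected. Subjects lacking either site are dropped with
#' a message.
#'
#' @param table a filtered [count_table()]
#' @param meta sample metadata
#' @param week which mucosal sampling week to use (default 0)
#' @param rank rank for the per-taxon tests (default genus)
#' @param min_prevalence prevalence filter across the paired samples
#' @return data.frame with `taxon_id`, `mean_diff` (pouch minus ileum),
#'   `statistic`, `p_value`, `q_value`
#' @export
site_contrast <- function(table, meta, week = 0, rank = "genus",
                          min_prevalence = 0.1) {
  meta <- check_table_metadata(table, meta)
  muc <- meta[meta$site %in% c("pouch", "ileum") & meta$week == week, ,
              drop = FALSE]
  subjects <- unique(muc$subject_id)
  pairs <- list()
  for (subj in subjects) {
    pouch <- muc$sample_id[muc$subject_id == subj & muc$site == "pouch"]
    ileum <- muc$sample_id[muc$subject_id == subj & muc$site == "ileum"]
    if (length(pouch) == 1 && length(ileum) == 1) {
      pairs[[subj]] <- c(pouch, ileum)
    } else {
      message("site_contrast: subject '", subj, "' lacks a site pair; dropped")
    }
  }
  if (length(pairs) < 2) stop("fewer than 2 subjects with both mucosal sites")
  ids <- unlist(pairs, use.names = FALSE)
  sub <- subset_table(table, samples = ids)
  agg <- if (is.null(rank)) sub else aggregate_taxa(sub, rank)
  frac <- to_relative(agg)
  pouch_ids <- vapply(pairs, `[`, character(1), 1)
  ileum_ids <- vapply(pairs, `[`, character(1), 2)
  diffs <- frac[, pouch_ids, drop = FALSE] - frac[, ileum_ids, drop = FALSE]
  prevalent <- rowMeans(frac > 0) >= min_prevalence
  if (!any(prevalent)) stop("no taxa pass the prevalence filter")
  res <- lapply(rownames(frac)[prevalent], function(tx) {
    d <- diffs[tx, ]
    if (sum(d != 0) < 2) {
      # too few informative pairs to rank: no evidence either way
      return(data.frame(taxon_id = tx, mean_diff = mean(d),
                        statistic = NA_real_, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    ht <- suppressWarnings(signed_rank_test(d))
    data.frame(taxon_id = tx, mean_diff = mean(d),
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$q_value, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
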