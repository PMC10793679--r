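#' Configuration for the synthetic FMT cohort generator
#'
#' Bundles every tunable of the generator. Defaults emulate a single-donor
#' chronic pouchitis FMT trial: one healthy donor sampled six times, 26
#' patients with dysbiotic baselines (Proteobacteria-enriched, low
#' diversity), five fecal timepoints at 0/4/12/26/52 weeks, mucosal (pouch
#' and ileum) samples at weeks 0 and 52, relapse events followed by
#' antibiotic perturbation, and sequencing depths drawn from a negative
#' binomial whose left tail places roughly 5% of samples below the
#' 10,000-read inclusion filter.
#'
#' @param n_taxa number of OTUs in the donor community (>= 10)
#' @param n_private_taxa size of the patient-associated OTU pool absent from
#'   the donor
#' @param n_patients number of patients
#' @param n_donor_samples longitudinal donor samples (default 6)
#' @param depth_mean mean sequencing depth (reads per sample)
#' @param depth_dispersion negative-binomial size parameter for depth
#' @param engraftment_rate per-patient donor-mixture weight `e` in `[0, 1]`;
#'   each donor-only OTU transfers independently with probability `e`
#' @param dysbiosis_strength log-scale multiplier applied to
#'   Proteobacteria in patient baselines; the patient-private taxon pool is
#'   itself Proteobacteria-rich, so even 0 leaves baselines dysbiotic
#' @param zero_fraction probability that a donor OTU is absent from a
#'   patient's baseline (these absences create the transferable OTU pool)
#' @param private_fraction probability that a pool OTU is present in a
#'   patient's baseline
#' @param patient_variation_sd log-normal sd of per-taxon inter-patient
#'   heterogeneity at baseline
#' @param jitter_sd log-normal sd of per-timepoint temporal drift of fecal
#'   communities
#' @param donor_jitter_sd log-normal sd between the donor's six samples
#' @param mucosal_jitter_sd log-normal sd between a fecal sample and the
#'   same-week mucosal communities
#' @param antibiotic_factor multiplicative boost of Gammaproteobacteria
#'   after relapse (antibiotic perturbation)
#' @param relapse_pullback weight pulling post-relapse communities back
#'   toward the dysbiotic baseline
#' @param relapse_prob per-patient relapse probability when no explicit
#'   schedule is given
#' @param relapse_schedule optional named list/vector mapping subject id to
#'   relapse week (`NA` = never); overrides `relapse_prob`
#' @param fmt_fraction fraction of patients randomized to the FMT arm
#' @param timepoints_weeks fecal sampling weeks, ascending, starting at 0
#' @param lognormal_sigma sd of the log-normal OTU abundance distribution
#' @param seed master seed; every random draw is a pure function of
#'   (config, seed)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_taxa = 300,
                       n_private_taxa = 120,
                       n_patients = 26,
                       n_donor_samples = 6,
                       depth_mean = 45000,
                       depth_dispersion = 2.5,
                       engraftment_rate = 0.3,
                       dysbiosis_strength = 0.5,
                       zero_fraction = 0.45,
                       private_fraction = 0.5,
                       patient_variation_sd = 0.8,
                       jitter_sd = 0.6,
                       donor_jitter_sd = 0.3,
                       mucosal_jitter_sd = 0.6,
                       antibiotic_factor = 3,
                       relapse_pullback = 0.75,
                       relapse_prob = 0.65,
                       relapse_schedule = NULL,
                       fmt_fraction = 0.5,
                       timepoints_weeks = c(0L, 4L, 12L, 26L, 52L),
                       lognormal_sigma = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (n_taxa < 10) stop("n_taxa must be >= 10")
  if (engraftment_rate < 0 || engraftment_rate > 1) {
    stop("engraftment_rate must be in [0, 1]")
  }
  if (is.unsorted(timepoints_weeks, strictly = TRUE) ||
      timepoints_weeks[1] != 0) {
    stop("timepoints_weeks must be strictly ascending and start at 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Phylum composition of the simulated communities. Donor masses follow the
# profile of a healthy high-diversity donor (Proteobacteria well under 1%,
# Bacteroidetes in the 10-25% band); the patient pool is dominated by
# facultative anaerobes.
.donor_phyla <- data.frame(
  phylum = c("Firmicutes", "Bacteroidetes", "Actinobacteria",
             "Proteobacteria", "Fusobacteria", "Verrucomicrobia"),
  taxa_frac = c(0.55, 0.18, 0.12, 0.08, 0.04, 0.03),
  mass = c(0.700, 0.165, 0.120, 0.004, 0.0005, 0.0105),
  stringsAsFactors = FALSE)

.pool_phyla <- data.frame(
  phylum = c("Proteobacteria", "Firmicutes", "Fusobacteria", "Actinobacteria"),
  taxa_frac = c(0.50, 0.25, 0.10, 0.15),
  stringsAsFactors = FALSE)

.families <- list(
  Firmicutes = list(Lachnospiraceae = c("Blautia", "Roseburia", "Coprococcus",
                                        "Dorea", "Anaerostipes",
                                        "Pseudobutyrivibrio"),
                    Ruminococcaceae = c("Faecalibacterium", "Oscillibacter",
                                        "Ruminococcus", "ClostridiumIV"),
                    Veillonellaceae = c("Veillonella", "Dialister"),
                    Streptococcaceae = c("Streptococcus"),
                    Enterococcaceae = c("Enterococcus")),
  Bacteroidetes = list(Bacteroidaceae = c("Bacteroides"),
                       Prevotellaceae = c("Prevotella"),
                       Rikenellaceae = c("Alistipes")),
  Actinobacteria = list(Bifidobacteriaceae = c("Bifidobacterium"),
                        Coriobacteriaceae = c("Collinsella"),
                        Actinomycetaceae = c("Actinomyces")),
  Proteobacteria = list(Enterobacteriaceae = c("Escherichia/Shigella",
                                               "Klebsiella", "Kluyvera",
                                               "Erwinia", "Enterobacter"),
                        Pasteurellaceae = c("Haemophilus"),
                        Sutterellaceae = c("Sutterella")),
  Fusobacteria = list(Fusobacteriaceae = c("Fusobacterium")),
  Verrucomicrobia = list(Akkermansiaceae = c("Akkermansia")))

# Gammaproteobacteria proxy: the antibiotic perturbation targets these
# families (the simulated Proteobacteria classes with enteric/facultative
# lifestyle).
.gamma_families <- c("Enterobacteriaceae", "Pasteurellaceae")

# Deterministic integer split of n into parts proportional to frac.
.split_counts <- function(n, frac) {
  cum <- round(cumsum(frac) / sum(frac) * n)
  diff(c(0L, cum))
}

# Build the shared taxon universe: donor-community OTUs followed by the
# patient-associated pool. Pure function of the config seed.
make_taxa_universe <- function(config) {
  with_seed(stable_seed(config$seed, "universe"), {
    assign_block <- function(n, phyla_df, offset, origin) {
      counts <- .split_counts(n, phyla_df$taxa_frac)
      phylum <- rep(phyla_df$phylum, counts)
      family <- character(n)
      genus <- character(n)
      for (i in seq_len(n)) {
        fams <- .families[[phylum[i]]]
        fam <- sample(names(fams), 1L)
        family[i] <- fam
        genus[i] <- sample(fams[[fam]], 1L)
      }
      data.frame(taxon_id = sprintf("OTU_%04d", offset + seq_len(n)),
                 phylum = phylum, family = family, genus = genus,
                 origin = origin, stringsAsFactors = FALSE)
    }
    rbind(assign_block(config$n_taxa, .donor_phyla, 0L, "donor"),
          assign_block(config$n_private_taxa, .pool_phyla,
                       config$n_taxa, "pool"))
  })
}

community_profile <- function(taxa, proportions) {
  stopifnot(length(proportions) == nrow(taxa), all(proportions >= 0))
  s <- sum(proportions)
  if (abs(s - 1) > 1e-12) proportions <- proportions / s
  names(proportions) <- taxa$taxon_id
  structure(list(taxa = taxa, proportions = proportions),
            class = "community_profile")
}

#' Generate the donor community profile
#'
#' Draws log-normal OTU abundances within each phylum and rescales phylum
#' masses to a healthy high-diversity profile: Proteobacteria below 1% and
#' Bacteroidetes between 10% and 25% of the community. Patient-pool OTUs
#' get proportion zero. Deterministic under a fixed config seed.
#'
#' @param config a [sim_config()]
#' @return a `community_profile`: list with `taxa` (lineage data.frame over
#'   the full taxon universe) and `proportions` (named, summing to 1)
#' @export
make_donor_profile <- function(config) {
  taxa <- make_taxa_universe(config)
  with_seed(stable_seed(config$seed, "donor-profile"), {
    w <- numeric(nrow(taxa))
    donor_rows <- taxa$origin == "donor"
    raw <- exp(stats::rnorm(sum(donor_rows), 0, config$lognormal_sigma))
    w[donor_rows] <- raw
    for (i in seq_len(nrow(.donor_phyla))) {
      ph <- .donor_phyla$phylum[i]
      idx <- donor_rows & taxa$phylum == ph
      if (any(idx)) w[idx] <- w[idx] / sum(w[idx]) * .donor_phyla$mass[i]
    }
    community_profile(taxa, w / sum(w))
  })
}

#' Generate a dysbiotic patient baseline profile
#'
#' Starts from the donor community, (i) zeroes a random subset of donor
#' OTUs (creating the donor-only taxa that engraftment bookkeeping relies
#' on), (ii) switches on a random subset of the patient-associated pool,
#' (iii) adds per-taxon log-normal heterogeneity, and (iv) multiplies
#' Proteobacteria by `exp(dysbiosis_strength)` before renormalizing. With
#' `zero_fraction = 0`, `private_fraction = 0`, `patient_variation_sd = 0`
#' and `dysbiosis_strength = 0` the result equals the donor profile.
#'
#' @param donor a donor `community_profile` from [make_donor_profile()]
#' @param config a [sim_config()]
#' @param subject_seed integer seed for this subject's draws
#' @return a `community_profile` over the same taxon universe
#' @export
make_patient_baseline <- function(donor, config, subject_seed) {
  taxa <- donor$taxa
  with_seed(subject_seed, {
    w <- unname(donor$proportions)
    donor_support <- which(w > 0)
    zeroed <- donor_support[stats::runif(length(donor_support)) <
                              config$zero_fraction]
    w[zeroed] <- 0
    pool_rows <- which(taxa$origin == "pool")
    active <- pool_rows[stats::runif(length(pool_rows)) <
                          config$private_fraction]
    if (length(active)) {
      scale <- mean(donor$proportions[donor$proportions > 0])
      w[active] <- scale * exp(stats::rnorm(length(active), 0,
                                            config$lognormal_sigma))
    }
    if (config$patient_variation_sd > 0) {
      pos <- w > 0
      w[pos] <- w[pos] * exp(stats::rnorm(sum(pos), 0,
                                          config$patient_variation_sd))
    }
    prot <- taxa$phylum == "Proteobacteria"
    w[prot] <- w[prot] * exp(config$dysbiosis_strength)
    community_profile(taxa, w / sum(w))
  })
}

# Normalized multiplicative log-normal jitter of a composition (support
# preserved: zero stays zero).
.jitter <- function(p, sd) {
  if (sd <= 0) return(p)
  pos <- p > 0
  p[pos] <- p[pos] * exp(stats::rnorm(sum(pos), 0, sd))
  p / sum(p)
}

.draw_depth <- function(config) {
  stats::rnbinom(1L, size = config$depth_dispersion, mu = config$depth_mean)
}

#' Simulate one subject's longitudinal samples
#'
#' FMT-arm composition at follow-up weeks is the mixture
#' `(1 - e) * baseline + e * donor'`, where `donor'` is the donor profile
#' restricted to shared taxa plus those donor-only taxa whose independent
#' Bernoulli(`e`) transfer indicator fired, renormalized; the placebo arm
#' uses `e = 0`. Each follow-up timepoint receives independent log-normal
#' temporal jitter. After a relapse at week `r`, samples with `week > r`
#' are pulled back toward baseline and Gammaproteobacteria are boosted by
#' `antibiotic_factor` (antibiotic perturbation). Counts are multinomial
#' draws at a negative-binomial depth.
#'
#' @param donor donor `community_profile`
#' @param baseline subject baseline `community_profile`
#' @param config a [sim_config()]
#' @param subject subject id (used for sample ids and seed streams)
#' @param arm `"fmt"` or `"placebo"`
#' @param relapse_week relapse week or `NA`
#' @param antibiotic_type,antibiotic_pattern metadata passthrough
#' @param include_mucosal also emit pouch/ileum samples at weeks 0 and 52
#'   (jittered copies of the same-week fecal composition)
#' @return list with `counts` (taxa x samples integer matrix), `meta`
#'   (metadata rows), `transfers` (per donor-only taxon transfer
#'   indicators) and `depths` (per-sample realized depth)
#' @export
simulate_timecourse <- function(donor, baseline, config, subject,
                                arm, relapse_week = NA_integer_,
                                antibiotic_type = "none",
                                antibiotic_pattern = "none",
                                include_mucosal = FALSE) {
  if (missing(arm) || is.na(arm) || !arm %in% c("fmt", "placebo")) {
    stop("subject '", subject, "' has no study arm assigned")
  }
  e <- if (arm == "fmt") config$engraftment_rate else 0
  taxa <- donor$taxa
  nt <- nrow(taxa)
  d <- unname(donor$proportions)
  b <- unname(baseline$proportions)
  donor_only <- which(d > 0 & b == 0)
  gamma <- taxa$phylum == "Proteobacteria" & taxa$family %in% .gamma_families

  with_seed(stable_seed(config$seed, "timecourse", subject), {
    fired <- stats::runif(length(donor_only)) < e
    donor_r <- d
    donor_r[donor_only[!fired]] <- 0
    donor_r <- donor_r / sum(donor_r)

    weeks <- config$timepoints_weeks
    comps <- matrix(0, nrow = nt, ncol = length(weeks))
    counts <- matrix(0L, nrow = nt, ncol = length(weeks))
    depths <- integer(length(weeks))
    for (k in seq_along(weeks)) {
      t <- weeks[k]
      if (t == 0) {
        comp <- b
      } else {
        comp <- .jitter((1 - e) * b + e * donor_r, config$jitter_sd)
      }
      if (!is.na(relapse_week) && t > relapse_week) {
        comp <- (1 - config$relapse_pullback) * comp +
          config$relapse_pullback * b
        comp[gamma] <- comp[gamma] * config$antibiotic_factor
        comp <- comp / sum(comp)
      }
      comps[, k] <- comp
      depths[k] <- .draw_depth(config)
      counts[, k] <- stats::rmultinom(1L, depths[k], comp)[, 1]
    }
    ids <- sprintf("%s_fec_w%02d", subject, weeks)
    meta <- data.frame(sample_id = ids, subject_id = subject, arm = arm,
                       week = as.integer(weeks), site = "fecal",
                       relapse_week = as.integer(relapse_week),
                       antibiotic_type = antibiotic_type,
                       antibiotic_pattern = antibiotic_pattern,
                       stringsAsFactors = FALSE)

    if (include_mucosal) {
      muc_weeks <- intersect(c(0L, 52L), weeks)
      for (t in muc_weeks) {
        base_comp <- comps[, match(t, weeks)]
        for (site in c("pouch", "ileum")) {
          comp <- .jitter(base_comp, config$mucosal_jitter_sd)
          depth <- .draw_depth(config)
          cnt <- stats::rmultinom(1L, depth, comp)[, 1]
          id <- sprintf("%s_%s_w%02d", subject, substr(site, 1, 3), t)
          counts <- cbind(counts, cnt)
          depths <- c(depths, depth)
          ids <- c(ids, id)
          meta <- rbind(meta, data.frame(
            sample_id = id, subject_id = subject, arm = arm,
            week = as.integer(t), site = site,
            relapse_week = as.integer(relapse_week),
            antibiotic_type = antibiotic_type,
            antibiotic_pattern = antibiotic_pattern,
            stringsAsFactors = FALSE))
        }
      }
    }
    colnames(counts) <- ids
    rownames(counts) <- taxa$taxon_id
    transfers <- data.frame(subject_id = subject,
                            taxon_id = taxa$taxon_id[donor_only],
                            fired = fired, stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, transfers = transfers,
         depths = data.frame(sample_id = ids, depth = depths,
                             stringsAsFactors = FALSE))
  })
}

#' Generate a full synthetic FMT cohort
#'
#' Emits one count table covering the donor's longitudinal samples, all
#' patients at all fecal timepoints, and pouch/ileum mucosal samples at
#' weeks 0 and 52, together with sample metadata and the generator's ground
#' truth. Fully reproducible from the config seed; per-subject random
#' streams are derived by stable hashing, so adding a patient never
#' reshuffles the draws of existing patients.
#'
#' @param config a [sim_config()]
#' @return an `fmt_cohort`: list with `table` (a [count_table()]), `meta`
#'   (sample metadata) and `truth` (list with `patients`, `transfers`,
#'   `depths`)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  donor <- make_donor_profile(config)
  taxa <- donor$taxa

  counts_list <- list()
  meta_list <- list()
  depths_list <- list()
  transfers_list <- list()

  for (k in seq_len(config$n_donor_samples)) {
    with_seed(stable_seed(config$seed, "donor-sample", k), {
      comp <- .jitter(unname(donor$proportions), config$donor_jitter_sd)
      depth <- .draw_depth(config)
      cnt <- stats::rmultinom(1L, depth, comp)[, 1]
      id <- sprintf("donor_s%02d", k)
      counts_list[[id]] <- cnt
      depths_list[[id]] <- data.frame(sample_id = id, depth = depth,
                                       stringsAsFactors = FALSE)
      meta_list[[id]] <- data.frame(
        sample_id = id, subject_id = "donor", arm = "donor",
        week = as.integer(k), site = "fecal",
        relapse_week = NA_integer_, antibiotic_type = "none",
        antibiotic_pattern = "none", stringsAsFactors = FALSE)
    })
  }
  donor_counts <- do.call(cbind, counts_list)
  colnames(donor_counts) <- names(counts_list)

  subjects <- sprintf("P%02d", seq_len(config$n_patients))
  n_fmt <- round(config$fmt_fraction * config$n_patients)
  arm <- rep("placebo", config$n_patients)
  ord <- c(seq(1, config$n_patients, by = 2),
           seq_len(config$n_patients)[-seq(1, config$n_patients, by = 2)])
  if (n_fmt > 0) arm[ord[seq_len(n_fmt)]] <- "fmt"

  patient_counts <- vector("list", config$n_patients)
  patients_truth <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    subj <- subjects[i]
    clin <- with_seed(stable_seed(config$seed, "clinical", subj), {
      if (!is.null(config$relapse_schedule)) {
        rw <- config$relapse_schedule[[subj]]
        rw <- if (is.null(rw) || is.na(rw)) NA_integer_ else as.integer(rw)
      } else {
        rw <- if (stats::runif(1) < config$relapse_prob) {
          cand <- config$timepoints_weeks[config$timepoints_weeks > 0]
          as.integer(sample(cand, 1L))
        } else NA_integer_
      }
      list(relapse_week = rw,
           abx_type = sample(c("ciprofloxacin", "metronidazole", "other"),
                             1L, prob = c(0.50, 0.35, 0.15)),
           abx_pattern = sample(c("continuous", "repeated"), 1L,
                                prob = c(0.46, 0.54)))
    })
    baseline <- make_patient_baseline(
      donor, config, stable_seed(config$seed, "baseline", subj))
    tc <- simulate_timecourse(donor, baseline, config, subj, arm[i],
                              relapse_week = clin$relapse_week,
                              antibiotic_type = clin$abx_type,
                              antibiotic_pattern = clin$abx_pattern,
                              include_mucosal = TRUE)
    patient_counts[[i]] <- tc$counts
    meta_list[[subj]] <- tc$meta
    depths_list[[subj]] <- tc$depths
    transfers_list[[subj]] <- tc$transfers
    patients_truth[[i]] <- data.frame(
      subject_id = subj, arm = arm[i],
      engraftment_rate = if (arm[i] == "fmt") config$engraftment_rate else 0,
      relapse_week = clin$relapse_week, stringsAsFactors = FALSE)
  }

  counts <- cbind(donor_counts, do.call(cbind, patient_counts))
  lineage <- taxa[, c("taxon_id", "phylum", "family", "genus")]
  table <- count_table(counts, lineage)
  meta <- validate_metadata(do.call(rbind, c(meta_list,
                                             make.row.names = FALSE)))
  truth <- list(patients = do.call(rbind, c(patients_truth,
                                            make.row.names = FALSE)),
                transfers = do.call(rbind, c(transfers_list,
                                             make.row.names = FALSE)),
                depths = do.call(rbind, c(depths_list,
                                          make.row.names = FALSE)))
  structure(list(table = table, meta = meta, truth = truth),
            class = "fmt_cohort")
}

#' @export
print.fmt_cohort <- function(x, ...) {
  cat(sprintf("fmt_cohort: %d taxa, %d samples, %d patients\n",
              n_taxa(x$table), n_samples(x$table), nrow(x$truth$patients)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `counts.tsv`, `metadata.tsv` and `truth.json` into `dir`.
#' Byte-identical across runs for the same cohort object.
#'
#' @param cohort an `fmt_cohort` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fmt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(cohort$table, file.path(dir, "counts.tsv"))
  write_sample_metadata(cohort$meta, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA,
                       auto_unbox = FALSE)
  invisible(dir)
}
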