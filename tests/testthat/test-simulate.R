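test_that("generator is a pure function of (config, seed)", {
  cfg <- small_config(seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$table$counts, c2$table$counts)
  expect_identical(c1$meta, c2$meta)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(small_config(seed = 12))
  expect_false(identical(c1$table$counts, c3$table$counts))
  # adding a patient never reshuffles existing patients' samples
  c4 <- generate_cohort(small_config(seed = 11, n_patients = 7))
  shared <- intersect(sample_ids(c1$table), sample_ids(c4$table))
  expect_identical(c1$table$counts[, shared], c4$table$counts[, shared])
})

test_that("cohort covers the designed sample grid", {
  cfg <- small_config(seed = 13)
  coh <- generate_cohort(cfg)
  expect_equal(n_samples(coh$table), 6 + 6 * 5 + 6 * 4)
  expect_equal(sum(coh$meta$arm == "donor"), 6)
  muc <- coh$meta[coh$meta$site != "fecal", ]
  expect_setequal(unique(muc$week), c(0, 52))
  expect_setequal(unique(muc$site), c("pouch", "ileum"))
  # metadata covers every sample exactly once
  expect_setequal(coh$meta$sample_id, sample_ids(coh$table))
})

test_that("donor profile satisfies its constructed phylum constraints", {
  cfg <- small_config(seed = 14)
  d1 <- make_donor_profile(cfg)
  d2 <- make_donor_profile(cfg)
  expect_identical(d1$proportions, d2$proportions)
  prot <- sum(d1$proportions[d1$taxa$phylum == "Proteobacteria"])
  bact <- sum(d1$proportions[d1$taxa$phylum == "Bacteroidetes"])
  expect_lt(prot, 0.01)
  expect_gt(bact, 0.10)
  expect_lt(bact, 0.25)
  expect_equal(sum(d1$proportions), 1, tolerance = 1e-12)
})

test_that("patient baseline reduces to the donor in the identity limit", {
  cfg <- small_config(seed = 15, zero_fraction = 0, private_fraction = 0,
                      patient_variation_sd = 0, dysbiosis_strength = 0)
  donor <- make_donor_profile(cfg)
  b <- make_patient_baseline(donor, cfg, 999)
  expect_equal(unname(b$proportions), unname(donor$proportions),
               tolerance = 1e-12)
})

test_that("patient baselines are Proteobacteria-enriched with donor-only taxa", {
  cfg <- small_config(seed = 16, dysbiosis_strength = 2)
  donor <- make_donor_profile(cfg)
  donor_prot <- sum(donor$proportions[donor$taxa$phylum == "Proteobacteria"])
  prots <- vapply(1:20, function(i) {
    b <- make_patient_baseline(donor, cfg, 3000 + i)
    sum(b$proportions[b$taxa$phylum == "Proteobacteria"])
  }, numeric(1))
  expect_gt(mean(prots), donor_prot)
  b <- make_patient_baseline(donor, cfg, 3001)
  donor_only <- donor$proportions > 0 & b$proportions == 0
  expect_gt(sum(donor_only), 0)
})

test_that("timecourse identity limits: placebo stasis and full engraftment", {
  cfg0 <- small_config(seed = 17, jitter_sd = 0, engraftment_rate = 0)
  donor <- make_donor_profile(cfg0)
  base <- make_patient_baseline(donor, cfg0, 4001)
  tc <- simulate_timecourse(donor, base, cfg0, "P01", "placebo")
  frac <- sweep(tc$counts, 2, colSums(tc$counts), "/")
  # all fecal timepoints drawn from the same baseline composition:
  # expected fractions identical, so supports must agree with baseline
  for (k in seq_len(ncol(frac))) {
    expect_true(all(tc$counts[base$proportions == 0, k] == 0))
  }
  expect_false(any(tc$transfers$fired))

  cfg1 <- small_config(seed = 17, jitter_sd = 0, engraftment_rate = 1,
                       relapse_prob = 0)
  base1 <- make_patient_baseline(donor, cfg1, 4001)
  tc1 <- simulate_timecourse(donor, base1, cfg1, "P01", "fmt")
  expect_true(all(tc1$transfers$fired))
  # with e = 1 and no jitter the week-4 composition equals the donor
  w4 <- tc1$counts[, grepl("w04", colnames(tc1$counts))]
  p_hat <- w4 / sum(w4)
  expect_lt(bc_oracle(p_hat + 1e-12, donor$proportions + 1e-12), 0.05)
  expect_error(simulate_timecourse(donor, base1, cfg1, "P01", NA),
               "no study arm")
})

test_that("dissimilarity to donor decreases in expectation with engraftment rate", {
  rates <- c(0, 0.25, 0.5, 0.75)
  mean_bc <- numeric(length(rates))
  for (ri in seq_along(rates)) {
    vals <- numeric(0)
    for (seed in 1:8) {
      cfg <- small_config(seed = 700 + seed, engraftment_rate = rates[ri],
                          n_patients = 2, relapse_prob = 0, fmt_fraction = 1)
      donor <- make_donor_profile(cfg)
      for (p in 1:2) {
        base <- make_patient_baseline(
          donor, cfg, stable_seed(cfg$seed, "baseline", sprintf("P%02d", p)))
        tc <- simulate_timecourse(donor, base, cfg, sprintf("P%02d", p), "fmt")
        w4 <- tc$counts[, grepl("w04", colnames(tc$counts))]
        vals <- c(vals, bc_oracle(w4 / sum(w4), donor$proportions))
      }
    }
    mean_bc[ri] <- mean(vals)
  }
  expect_true(all(diff(mean_bc) < 0))
})

test_that("relapse perturbs post-relapse samples toward Gammaproteobacteria", {
  cfg <- small_config(seed = 18, relapse_schedule = list(P01 = 4),
                      antibiotic_factor = 10, jitter_sd = 0.1)
  donor <- make_donor_profile(cfg)
  base <- make_patient_baseline(donor, cfg, 5001)
  tc <- simulate_timecourse(donor, base, cfg, "P01", "fmt", relapse_week = 4L)
  gamma <- donor$taxa$phylum == "Proteobacteria" &
    donor$taxa$family %in% c("Enterobacteriaceae", "Pasteurellaceae")
  frac <- sweep(tc$counts, 2, colSums(tc$counts), "/")
  pre <- sum(frac[gamma, "P01_fec_w04"])
  post <- sum(frac[gamma, "P01_fec_w12"])
  expect_gt(post, pre)
})

test_that("cohort files are byte-identical across two writes", {
  cfg <- small_config(seed = 19)
  coh <- generate_cohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(coh, d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("counts.tsv", "metadata.tsv", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # round-trip through the readers
  tab <- read_count_table(file.path(d1, "counts.tsv"))
  expect_identical(tab$counts, coh$table$counts)
  meta <- read_sample_metadata(file.path(d1, "metadata.tsv"))
  expect_equal(meta$sample_id, coh$meta$sample_id)
})

test_that("truth transfer indicators only reference donor-only taxa", {
  cfg <- small_config(seed = 20)
  coh <- generate_cohort(cfg)
  donor <- make_donor_profile(cfg)
  for (subj in unique(coh$truth$transfers$subject_id)) {
    base <- make_patient_baseline(donor, cfg,
                                  stable_seed(cfg$seed, "baseline", subj))
    donor_only <- donor$taxa$taxon_id[donor$proportions > 0 &
                                        base$proportions == 0]
    tr <- coh$truth$transfers[coh$truth$transfers$subject_id == subj, ]
    expect_setequal(tr$taxon_id, donor_only)
  }
  # placebo patients never fire
  placebo <- coh$truth$patients$subject_id[coh$truth$patients$arm == "placebo"]
  pt <- coh$truth$transfers[coh$truth$transfers$subject_id %in% placebo, ]
  expect_false(any(pt$fired))
})
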