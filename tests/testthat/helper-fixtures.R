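# Shared fixture builders: everything is generated in code at test time.

make_table <- function(counts, phylum = NULL, family = NULL, genus = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("t%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  }
  lin <- data.frame(taxon_id = rownames(counts),
                    phylum = phylum %||% "unclassified",
                    family = family %||% "unclassified",
                    genus = genus %||% "unclassified",
                    stringsAsFactors = FALSE)
  count_table(counts, lin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(n_taxa, n_samples, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, max_count / 2), nrow = n_taxa,
              dimnames = list(sprintf("otu%03d", seq_len(n_taxa)),
                              sprintf("S%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  genera <- sprintf("g%02d", sample(ceiling(n_taxa / 3), n_taxa, replace = TRUE))
  make_table(m, phylum = "Firmicutes", family = "F1", genus = genera)
}

simple_meta <- function(table, arm = "fmt", week = 0, site = "fecal",
                        subject = NULL) {
  n <- n_samples(table)
  data.frame(sample_id = sample_ids(table),
             subject_id = subject %||% sample_ids(table),
             arm = rep_len(arm, n), week = rep_len(week, n),
             site = rep_len(site, n), relapse_week = NA_integer_,
             antibiotic_type = "none", antibiotic_pattern = "none",
             stringsAsFactors = FALSE)
}

# A small cohort config that keeps module tests fast; study-scale defaults
# are exercised in the acceptance suite.
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_taxa = 80, n_private_taxa = 30, n_patients = 6,
         depth_mean = 8000, depth_dispersion = 20, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Independent Bray-Curtis oracle: the textbook min-sum formula, written
# separately from the package's implementation.
bc_oracle <- function(x, y) {
  x <- x / sum(x); y <- y / sum(y)
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}
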