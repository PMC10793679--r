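#' Inverse Simpson diversity index
#'
#' The effective number of equally abundant taxa, `1 / sum(p_i^2)` with
#' `p_i = count_i / total`. Scale-invariant in the counts, bounded below by
#' 1 (single taxon) and above by the number of taxa present, with equality
#' at a perfectly even community.
#'
#' @param counts non-negative numeric vector with at least one positive entry
#' @return the inverse Simpson index, a real `>= 1`
#' @examples
#' inverse_simpson(c(5, 5, 5, 5))  # 4: four equally abundant taxa
#' @export
inverse_simpson <- function(counts) {
  if (any(counts < 0) || !length(counts)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all counts are zero; diversity undefined")
  p <- counts / total
  1 / sum(p^2)
}

#' Per-sample diversity with grouping columns attached
#'
#' Computes the inverse Simpson index for every sample and joins the
#' metadata columns used for downstream group comparisons (arm, week, site,
#' relapse status).
#'
#' @param table a [count_table()], typically already filtered
#' @param meta sample metadata (see [validate_metadata()])
#' @return data.frame with columns `sample_id`, `inverse_simpson`,
#'   `subject_id`, `arm`, `week`, `site`, `relapsed`
#' @export
diversity_by_group <- function(table, meta) {
  meta <- check_table_metadata(table, meta)
  values <- apply(table$counts, 2, inverse_simpson)
  data.frame(sample_id = sample_ids(table),
             inverse_simpson = unname(values),
             subject_id = meta$subject_id,
             arm = meta$arm,
             week = meta$week,
             site = meta$site,
             relapsed = !is.na(meta$relapse_week),
             stringsAsFactors = FALSE)
}

#' Mean relative abundance by group and taxon
#'
#' Aggregates counts to a rank, converts to per-sample fractions, and
#' summarizes each group x taxon cell by the mean and sample standard
#' deviation (n - 1) of the fractions. Within any group the means sum to 1
#' across taxa.
#'
#' @param table a [count_table()]
#' @param meta sample metadata
#' @param rank taxonomic rank to aggregate to
#' @param grouping character vector of metadata column names defining the
#'   groups
#' @return data.frame with columns `group`, `taxon_id`, `mean_fraction`,
#'   `sd_fraction`, `n_samples`
#' @export
mean_relative_abundance <- function(table, meta,
                                    rank = c("phylum", "family", "genus"),
                                    grouping = "arm") {
  rank <- match.arg(rank)
  meta <- check_table_metadata(table, meta)
  bad <- setdiff(grouping, names(meta))
  if (length(bad)) stop("unknown metadata column: ", bad[1])
  agg <- aggregate_taxa(table, rank)
  frac <- to_relative(agg)
  group <- interaction(meta[grouping], drop = TRUE, sep = ":", lex.order = TRUE)
  if (any(table(group) == 0)) {
    stop("empty group: ", names(which(table(group) == 0))[1])
  }
  out <- lapply(levels(group), function(g) {
    cols <- frac[, group == g, drop = FALSE]
    data.frame(group = g,
               taxon_id = rownames(frac),
               mean_fraction = rowMeans(cols),
               sd_fraction = if (ncol(cols) > 1) apply(cols, 1, stats::sd)
                             else NA_real_,
               n_samples = ncol(cols),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
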