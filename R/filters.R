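#' Exclude low-depth samples
#'
#' Drops samples whose total read count falls below a threshold. The rule is
#' a strict inequality: a sample with exactly `min_reads` reads is retained
#' ("under 10,000 reads" excludes 9,999 but keeps 10,000). The taxon list is
#' unchanged. Dropped sample ids are recorded in the `"dropped_samples"`
#' attribute of the result.
#'
#' @param table a [count_table()]
#' @param min_reads minimum per-sample read count (default 10000)
#' @return the filtered `count_table`; `attr(, "dropped_samples")` holds the
#'   ids of excluded samples (possibly empty)
#' @export
filter_min_reads <- function(table, min_reads = 10000) {
  stopifnot(inherits(table, "count_table"))
  depth <- colSums(table$counts)
  keep <- depth >= min_reads
  dropped <- sample_ids(table)[!keep]
  out <- count_table(table$counts[, keep, drop = FALSE], table$lineage)
  if (n_samples(out) == 0L) {
    message("filter_min_reads: all samples dropped (min_reads = ",
            min_reads, ")")
  }
  attr(out, "dropped_samples") <- dropped
  out
}

#' Discard rare taxa by dataset-wide relative abundance
#'
#' Removes taxa whose share of the grand total read count is strictly below
#' `min_frac` (default 1e-5, i.e. 0.001%). The fraction is computed over the
#' whole dataset, not per sample; counts of retained taxa are unchanged.
#' A taxon sitting exactly at the threshold is retained. Dropped taxon ids
#' are recorded in the `"dropped_taxa"` attribute.
#'
#' @param table a [count_table()]
#' @param min_frac minimum dataset-wide relative abundance (default 1e-5)
#' @return the filtered `count_table`; `attr(, "dropped_taxa")` holds the ids
#'   of discarded taxa
#' @export
filter_min_relative_abundance <- function(table, min_frac = 1e-5) {
  stopifnot(inherits(table, "count_table"))
  totals <- rowSums(table$counts)
  grand <- sum(as.numeric(totals))
  if (grand == 0) stop("grand total of counts is zero; cannot compute relative abundance")
  keep <- totals / grand >= min_frac
  dropped <- taxon_ids(table)[!keep]
  out <- count_table(table$counts[keep, , drop = FALSE],
                     table$lineage[keep, , drop = FALSE])
  attr(out, "dropped_taxa") <- dropped
  out
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums counts over taxa sharing the same label at the requested rank
#' (phylum, family or genus). Labels are kept in order of first appearance;
#' all `"unclassified"` taxa at that rank aggregate into a single bucket.
#' Per-sample column sums are conserved exactly (integer arithmetic).
#'
#' @param table a [count_table()]
#' @param rank one of `"phylum"`, `"family"`, `"genus"`
#' @return a `count_table` whose taxon ids are the rank labels
#' @export
aggregate_taxa <- function(table, rank = c("genus", "family", "phylum")) {
  stopifnot(inherits(table, "count_table"))
  rank <- match.arg(rank)
  labels <- table$lineage[[rank]]
  f <- factor(labels, levels = unique(labels))
  counts <- rowsum(table$counts, f, reorder = FALSE)
  storage.mode(counts) <- "integer"
  rownames(counts) <- levels(f)
  first <- match(levels(f), labels)
  lin <- data.frame(taxon_id = levels(f),
                    phylum = table$lineage$phylum[first],
                    family = table$lineage$family[first],
                    genus = table$lineage$genus[first],
                    stringsAsFactors = FALSE)
  # ranks below the aggregation level are no longer meaningful
  if (rank == "phylum") lin$family <- lin$genus <- "unclassified"
  if (rank == "family") lin$genus <- "unclassified"
  lin[[rank]] <- levels(f)
  count_table(counts, lin)
}

#' Convert counts to per-sample fractions
#'
#' @param table a [count_table()]
#' @return a numeric matrix (taxa x samples) in which every column sums to 1
#'   within 1e-12
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  depth <- colSums(table$counts)
  if (any(depth == 0)) {
    stop("sample '", sample_ids(table)[which(depth == 0)[1]],
         "' has zero total count")
  }
  sweep(table$counts, 2, depth, "/")
}
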