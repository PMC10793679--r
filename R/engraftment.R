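#' Taxa present in a sample
#'
#' Presence is defined as a count of at least `min_count` reads in that
#' sample (applied after the global rarity filter in the default pipeline).
#'
#' @param table a [count_table()]
#' @param sample sample id
#' @param min_count minimum count to call a taxon present (default 1)
#' @return character vector of taxon ids
#' @export
presence_set <- function(table, sample, min_count = 1) {
  stopifnot(inherits(table, "count_table"))
  if (!sample %in% sample_ids(table)) stop("unknown sample id: ", sample)
  taxon_ids(table)[table$counts[, sample] >= min_count]
}

otu_set <- function(ids, provenance, reference_samples = character(0)) {
  structure(list(ids = sort(unique(ids)), provenance = provenance,
                 reference_samples = reference_samples),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("otu_set (%s): %d taxa\n", x$provenance, length(x$ids)))
  invisible(x)
}

#' Transferable OTUs: present in the donor, absent at patient baseline
#'
#' The engraftment denominator. Donor presence pools the longitudinal
#' donor samples either as a union (`donor_presence_rule = "any"`, the
#' default) or an intersection (`"all"`); the patient's baseline presence
#' set is then subtracted.
#'
#' @param table a [count_table()]
#' @param donor_samples donor sample ids (non-empty)
#' @param baseline_sample the patient's pre-FMT sample id
#' @param donor_presence_rule `"any"` (union over donor samples) or
#'   `"all"` (intersection)
#' @param min_count presence threshold passed to [presence_set()]
#' @return an `otu_set` with provenance `"donor_only"`
#' @export
transferable_otus <- function(table, donor_samples, baseline_sample,
                              donor_presence_rule = c("any", "all"),
                              min_count = 1) {
  donor_presence_rule <- match.arg(donor_presence_rule)
  if (!length(donor_samples)) stop("donor_samples must be non-empty")
  if (baseline_sample %in% donor_samples) {
    stop("baseline sample '", baseline_sample,
         "' is listed among the donor samples")
  }
  sets <- lapply(donor_samples, presence_set, table = table,
                 min_count = min_count)
  donor_ids <- if (donor_presence_rule == "any") {
    Reduce(union, sets)
  } else {
    Reduce(intersect, sets)
  }
  base_ids <- presence_set(table, baseline_sample, min_count)
  otu_set(setdiff(donor_ids, base_ids), "donor_only",
          reference_samples = c(donor_samples, baseline_sample))
}

#' Donor-derived OTUs detected at a follow-up timepoint
#'
#' The engraftment numerator: transferable OTUs that are present in the
#' patient's post-FMT sample.
#'
#' @param transferable an `otu_set` with provenance `"donor_only"`
#' @param followup_presence character vector of taxon ids present at the
#'   follow-up sample (from [presence_set()])
#' @return an `otu_set` with provenance `"donor_derived"`
#' @export
donor_derived_otus <- function(transferable, followup_presence) {
  stopifnot(inherits(transferable, "otu_set"))
  if (transferable$provenance != "donor_only") {
    stop("`transferable` must have provenance 'donor_only'")
  }
  otu_set(intersect(transferable$ids, followup_presence), "donor_derived",
          reference_samples = transferable$reference_samples)
}

#' Engraftment fraction (percent)
#'
#' `100 * |detected| / |transferable|`. Undefined when the transferable set
#' is empty: returns `NA` with a warning (such patients are excluded from
#' group means rather than counted as zero).
#'
#' @param transferable `otu_set` (denominator)
#' @param detected `otu_set` (numerator); must be a subset of `transferable`
#' @return percentage in `[0, 100]`, or `NA` if the denominator is empty
#' @export
engraftment_fraction <- function(transferable, detected) {
  stopifnot(inherits(transferable, "otu_set"), inherits(detected, "otu_set"))
  if (length(setdiff(detected$ids, transferable$ids))) {
    stop("detected set is not a subset of the transferable set")
  }
  if (!length(transferable$ids)) {
    warning("no transferable OTUs; engraftment fraction undefined")
    return(NA_real_)
  }
  100 * length(detected$ids) / length(transferable$ids)
}

#' Engraftment trajectories for every patient
#'
#' For each patient with a baseline (week 0) fecal sample surviving the
#' filters, classifies transferable OTUs against the donor samples and
#' counts the detected donor-derived OTUs at every retained follow-up
#' fecal timepoint. With `exclude_post_relapse = TRUE`, samples taken
#' strictly after the relapse week are omitted. Patients whose baseline
#' sample was filtered out are skipped with a message. Runs at the
#' unaggregated OTU level by default; set `rank` to aggregate first.
#'
#' @param table a filtered [count_table()]
#' @param meta sample metadata
#' @param donor_samples donor sample ids (default: all `arm == "donor"`
#'   rows present in the table)
#' @param donor_presence_rule `"any"` or `"all"` (see [transferable_otus()])
#' @param min_count presence threshold
#' @param exclude_post_relapse drop follow-up samples after relapse
#' @param rank optional rank to aggregate to before classification
#' @return data.frame with columns `subject_id`, `arm`, `week`,
#'   `relapsed`, `n_transferable`, `n_detected`, `fraction`
#' @export
engraftment_trajectories <- function(table, meta, donor_samples = NULL,
                                     donor_presence_rule = "any",
                                     min_count = 1,
                                     exclude_post_relapse = TRUE,
                                     rank = NULL) {
  meta <- check_table_metadata(table, meta)
  if (!is.null(rank)) table <- aggregate_taxa(table, rank)
  if (is.null(donor_samples)) {
    donor_samples <- meta$sample_id[meta$arm == "donor"]
  }
  if (!length(donor_samples)) stop("no donor samples available")
  fm <- meta[meta$arm != "donor" & meta$site == "fecal", , drop = FALSE]
  records <- list()
  for (subj in unique(fm$subject_id)) {
    sm <- fm[fm$subject_id == subj, , drop = FALSE]
    base <- sm$sample_id[sm$week == 0]
    if (!length(base)) {
      message("engraftment: patient '", subj,
              "' has no baseline fecal sample after filtering; skipped")
      next
    }
    transferable <- transferable_otus(table, donor_samples, base[1],
                                      donor_presence_rule = donor_presence_rule,
                                      min_count = min_count)
    follow <- sm[sm$week > 0, , drop = FALSE]
    if (exclude_post_relapse && nrow(follow)) {
      keep <- is.na(follow$relapse_week) | follow$week <= follow$relapse_week
      follow <- follow[keep, , drop = FALSE]
    }
    for (j in seq_len(nrow(follow))) {
      detected <- donor_derived_otus(
        transferable, presence_set(table, follow$sample_id[j], min_count))
      frac <- if (length(transferable$ids)) {
        100 * length(detected$ids) / length(transferable$ids)
      } else NA_real_
      records[[length(records) + 1L]] <- data.frame(
        subject_id = subj, arm = follow$arm[j], week = follow$week[j],
        relapsed = !is.na(follow$relapse_week[j]),
        n_transferable = length(transferable$ids),
        n_detected = length(detected$ids),
        fraction = frac, stringsAsFactors = FALSE)
    }
  }
  if (!length(records)) {
    return(data.frame(subject_id = character(0), arm = character(0),
                      week = integer(0), relapsed = logical(0),
                      n_transferable = integer(0), n_detected = integer(0),
                      fraction = numeric(0)))
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
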