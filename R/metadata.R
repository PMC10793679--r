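#' Validate a sample metadata table
#'
#' Sample metadata carries the clinical/design annotations used throughout
#' the pipeline: subject id, study arm (`fmt`, `placebo`, `donor`), timepoint
#' in weeks (donor samples use a collection index), sample site (`fecal`,
#' `pouch`, `ileum`), relapse week (NA when the subject never relapsed),
#' antibiotic type (`ciprofloxacin`, `metronidazole`, `other`, `none`) and
#' antibiotic usage pattern (`continuous`, `repeated`, `none`).
#'
#' @param meta a data.frame with columns `sample_id`, `subject_id`, `arm`,
#'   `week`, `site`, `relapse_week`, `antibiotic_type`, `antibiotic_pattern`
#' @return the validated data.frame (invisibly unchanged apart from
#'   type coercion of `week`/`relapse_week` to integer)
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "subject_id", "arm", "week", "site", "relapse_week",
            "antibiotic_type", "antibiotic_pattern")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[anyDuplicated(meta$sample_id)])
  }
  check_enum <- function(col, allowed) {
    bad <- setdiff(unique(meta[[col]]), allowed)
    if (length(bad)) {
      stop(sprintf("invalid %s value '%s' (allowed: %s)", col, bad[1],
                   paste(allowed, collapse = ", ")))
    }
  }
  check_enum("arm", c("fmt", "placebo", "donor"))
  check_enum("site", c("fecal", "pouch", "ileum"))
  check_enum("antibiotic_type", c("ciprofloxacin", "metronidazole", "other", "none"))
  check_enum("antibiotic_pattern", c("continuous", "repeated", "none"))
  meta$week <- as.integer(meta$week)
  meta$relapse_week <- as.integer(meta$relapse_week)
  if (any(meta$week < 0, na.rm = TRUE)) stop("negative week in metadata")
  donor_relapse <- meta$arm == "donor" & !is.na(meta$relapse_week)
  if (any(donor_relapse)) {
    stop("donor sample '", meta$sample_id[which(donor_relapse)[1]],
         "' has a relapse_week; donors cannot relapse")
  }
  meta
}

#' Read sample metadata from a tab-separated file
#'
#' `relapse_week` is empty or `NA` for subjects who never relapsed; enum
#' columns are lower-case. CRLF and trailing newlines are tolerated.
#'
#' @param path path to a TSV file
#' @return a validated metadata data.frame
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "",
                            stringsAsFactors = FALSE, encoding = "UTF-8",
                            na.strings = c("NA", ""))
  validate_metadata(meta)
}

#' Write sample metadata to a tab-separated file
#'
#' @param meta a metadata data.frame (see [validate_metadata()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_sample_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(meta), collapse = "\t"),
             do.call(paste, c(lapply(meta, function(x) {
               x <- as.character(x)
               x[is.na(x)] <- "NA"
               x
             }), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Check that every sample in the table has exactly one metadata row; used at
# pipeline entry.
check_table_metadata <- function(table, meta) {
  meta <- validate_metadata(meta)
  missing_meta <- setdiff(sample_ids(table), meta$sample_id)
  if (length(missing_meta)) {
    stop("sample '", missing_meta[1], "' has no metadata row")
  }
  meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
}
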