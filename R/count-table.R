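#' Construct a taxon-by-sample count table
#'
#' The `count_table` is the pipeline's universal currency: an integer matrix
#' of sequence counts (rows = taxa, columns = samples) together with a
#' lineage annotation (phylum / family / genus) for every taxon. Lineage
#' ranks that are unknown carry the label `"unclassified"`.
#'
#' @param counts integer matrix, taxa x samples, with unique rownames
#'   (taxon ids) and unique colnames (sample ids). All entries must be
#'   non-negative integers.
#' @param lineage data.frame with columns `taxon_id`, `phylum`, `family`,
#'   `genus`, one row per taxon, in any order. If `NULL`, all ranks are set
#'   to `"unclassified"`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `lineage` (data.frame aligned to the rows of
#'   `counts`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(c("otu1", "otu2", "otu3"), c("S1", "S2")))
#' ct <- count_table(m)
#' n_taxa(ct)
#' @export
count_table <- function(counts, lineage = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("`counts` must have taxon rownames and sample colnames")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon id: ",
         rownames(counts)[anyDuplicated(rownames(counts))])
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample id: ",
         colnames(counts)[anyDuplicated(colnames(counts))])
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("count for taxon '%s' in sample '%s' is not a non-negative integer",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(lineage)) {
    # a zero-row matrix reports NULL rownames even after assignment
    lineage <- data.frame(taxon_id = rownames(counts) %||% character(0),
                          phylum = rep("unclassified", nrow(counts)),
                          family = rep("unclassified", nrow(counts)),
                          genus = rep("unclassified", nrow(counts)),
                          stringsAsFactors = FALSE)
  }
  need <- c("taxon_id", "phylum", "family", "genus")
  if (!all(need %in% names(lineage))) {
    stop("`lineage` must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(lineage$taxon_id, rownames(counts))) {
    stop("`lineage` taxon ids do not match the rows of `counts`")
  }
  lineage <- lineage[match(rownames(counts), lineage$taxon_id), need]
  rownames(lineage) <- NULL
  for (r in c("phylum", "family", "genus")) {
    v <- as.character(lineage[[r]])
    v[is.na(v) | v == ""] <- "unclassified"
    lineage[[r]] <- v
  }
  structure(list(counts = counts, lineage = lineage), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @rdname count_table
#' @param table a `count_table`
#' @export
n_taxa <- function(table) nrow(table$counts)

#' @rdname count_table
#' @export
n_samples <- function(table) ncol(table$counts)

#' @rdname count_table
#' @export
sample_ids <- function(table) colnames(table$counts)

#' @rdname count_table
#' @export
taxon_ids <- function(table) rownames(table$counts)

#' Subset a count table by sample and/or taxon ids
#'
#' @param table a `count_table`
#' @param samples character vector of sample ids to keep (default all)
#' @param taxa character vector of taxon ids to keep (default all)
#' @return a `count_table` restricted to the requested ids, in the order given
#' @export
subset_table <- function(table, samples = sample_ids(table),
                         taxa = taxon_ids(table)) {
  stopifnot(inherits(table, "count_table"))
  missing_s <- setdiff(samples, sample_ids(table))
  if (length(missing_s)) stop("unknown sample id: ", missing_s[1])
  missing_t <- setdiff(taxa, taxon_ids(table))
  if (length(missing_t)) stop("unknown taxon id: ", missing_t[1])
  counts <- table$counts[taxa, samples, drop = FALSE]
  lin <- table$lineage[match(taxa, table$lineage$taxon_id), , drop = FALSE]
  count_table(counts, lin)
}

# Parse one "p__X;f__Y;g__Z" lineage string into the three tracked ranks.
# Ranks may be omitted; unknown or malformed fields become "unclassified".
parse_lineage <- function(s) {
  out <- c(phylum = "unclassified", family = "unclassified",
           genus = "unclassified")
  if (is.na(s) || s == "") return(out)
  prefix <- c(p = "phylum", f = "family", g = "genus")
  for (part in strsplit(s, ";", fixed = TRUE)[[1]]) {
    part <- trimws(part)
    if (grepl("^[pfg]__", part)) {
      rank <- prefix[[substr(part, 1, 1)]]
      val <- substring(part, 4)
      if (nzchar(val)) out[[rank]] <- val
    }
  }
  out
}

format_lineage <- function(lineage_row) {
  paste0("p__", lineage_row$phylum,
         ";f__", lineage_row$family,
         ";g__", lineage_row$genus)
}

#' Read a count table from a tab-separated file
#'
#' Expects UTF-8 TSV with header `taxon_id`, `lineage`, then one column per
#' sample. The lineage column uses semicolon-separated rank-prefixed labels
#' (`p__X;f__Y;g__Z`); ranks may be omitted and malformed ranks become
#' `"unclassified"`. CRLF line endings and a trailing newline are tolerated.
#'
#' @param path path to a TSV file
#' @return a validated [count_table()] preserving the file's taxon and
#'   sample order
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(sub("\r$", "", readLines(path, n = 1L)), "\t",
                     fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "taxon_id" || header[2] != "lineage") {
    stop("count table header must start with 'taxon_id\tlineage'")
  }
  samples <- header[-(1:2)]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in header: ", samples[anyDuplicated(samples)])
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", encoding = "UTF-8")
  taxa <- raw[[1]]
  if (anyDuplicated(taxa)) stop("duplicate taxon id: ", taxa[anyDuplicated(taxa)])
  if (length(samples)) {
    cnt <- as.matrix(raw[, -(1:2), drop = FALSE])
    ok <- matrix(grepl("^[0-9]+$", cnt), nrow = nrow(cnt))
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer or negative count for taxon '%s' in sample '%s'",
                   taxa[bad[1]], samples[bad[2]]))
    }
    counts <- matrix(as.integer(cnt), nrow = length(taxa),
                     ncol = length(samples), dimnames = list(taxa, samples))
  } else {
    counts <- matrix(integer(0), nrow = length(taxa), ncol = 0,
                     dimnames = list(taxa, character(0)))
  }
  parsed <- t(vapply(raw[[2]], parse_lineage, character(3), USE.NAMES = FALSE))
  lineage <- data.frame(taxon_id = taxa, phylum = parsed[, 1],
                        family = parsed[, 2], genus = parsed[, 3],
                        stringsAsFactors = FALSE)
  if (length(taxa) == 0L) {
    lineage <- data.frame(taxon_id = character(0), phylum = character(0),
                          family = character(0), genus = character(0))
  }
  count_table(counts, lineage)
}

#' Write a count table to a tab-separated file
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(t))`
#' reproduces `t` exactly (ids, lineages, counts, order). Output is LF-
#' terminated UTF-8 and byte-stable across repeated writes.
#'
#' @param table a `count_table`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  lin <- vapply(seq_len(n_taxa(table)),
                function(i) format_lineage(table$lineage[i, ]), character(1))
  header <- paste(c("taxon_id", "lineage", sample_ids(table)), collapse = "\t")
  if (n_taxa(table) > 0) {
    body <- paste(taxon_ids(table), lin,
                  apply(table$counts, 1, paste, collapse = "\t"),
                  sep = "\t")
    if (n_samples(table) == 0L) {
      body <- paste(taxon_ids(table), lin, sep = "\t")
    }
  } else {
    body <- character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
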