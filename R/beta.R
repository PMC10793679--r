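#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, computed by default on
#' per-sample fractions (each vector scaled to sum 1), matching ordination
#' on relative abundances. Set `normalize = FALSE` to compute on raw
#' counts. The value lies in `[0, 1]`: 0 for identical compositions, 1 for
#' disjoint supports.
#'
#' @param x,y non-negative numeric vectors over the same taxon index
#' @param normalize scale each vector to sum 1 first (default TRUE)
#' @return the dissimilarity, a real in `[0, 1]`
#' @export
bray_curtis <- function(x, y, normalize = TRUE) {
  if (length(x) != length(y)) stop("x and y must share the same taxon index")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 && sy == 0) stop("both vectors are all-zero")
  if (normalize) {
    if (sx == 0 || sy == 0) stop("cannot normalize an all-zero vector")
    x <- x / sx; y <- y / sy
    sx <- sy <- 1
  }
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

#' All-pairwise Bray-Curtis distance matrix
#'
#' Aggregates the table to `rank` (if given), converts to per-sample
#' fractions, and returns the symmetric matrix of pairwise Bray-Curtis
#' dissimilarities. On fractions the index equals half the Manhattan
#' distance, which is used for speed; it is exactly the pairwise
#' [bray_curtis()] double loop.
#'
#' @param table a [count_table()]
#' @param rank optional rank to aggregate to before computing distances
#'   (`NULL` = use taxa as-is; the study design uses `"genus"`)
#' @return symmetric numeric matrix with sample ids as dimnames, zero
#'   diagonal, entries in `[0, 1]`
#' @export
distance_matrix <- function(table, rank = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (!is.null(rank)) table <- aggregate_taxa(table, rank)
  frac <- to_relative(table)
  d <- as.matrix(stats::dist(t(frac), method = "manhattan")) / 2
  dimnames(d) <- list(sample_ids(table), sample_ids(table))
  d
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square")
  }
  if (is.null(rownames(dm))) stop("distance matrix must carry sample ids")
  dm
}

#' Average dissimilarity of one sample to the donor samples
#'
#' The donor reference is the arithmetic mean of the pairwise distances to
#' each longitudinal donor sample.
#'
#' @param patient_sample sample id
#' @param donor_samples character vector of donor sample ids (non-empty)
#' @param dm distance matrix from [distance_matrix()]
#' @return mean of `dm[patient_sample, donor_samples]`
#' @export
donor_dissimilarity <- function(patient_sample, donor_samples, dm) {
  check_distance_matrix(dm)
  if (!length(donor_samples)) stop("donor_samples must be non-empty")
  ids <- c(patient_sample, donor_samples)
  unknown <- setdiff(ids, rownames(dm))
  if (length(unknown)) stop("unknown sample id: ", unknown[1])
  mean(dm[patient_sample, donor_samples])
}

#' Dissimilarity-to-donor trajectories
#'
#' For every patient fecal sample, the average genus-level Bray-Curtis
#' dissimilarity to the donor's longitudinal samples. With
#' `exclude_post_relapse = TRUE` (the default), samples taken strictly
#' after the patient's relapse week are omitted — the week-of-relapse
#' sample itself is retained. `donor_reference = "profile_mean"` measures
#' distance to the mean donor fraction profile instead of averaging the
#' pairwise distances.
#'
#' @param table a filtered [count_table()] containing patient fecal and
#'   donor samples
#' @param meta sample metadata
#' @param donor_samples donor sample ids (default: all `arm == "donor"`
#'   samples present in the table)
#' @param rank rank for the underlying distance matrix (default genus)
#' @param exclude_post_relapse drop samples with `week > relapse_week`
#' @param donor_reference `"pairwise_mean"` (default) or `"profile_mean"`
#' @return data.frame with columns `sample_id`, `subject_id`, `arm`,
#'   `week`, `relapsed`, `dissimilarity`
#' @export
donor_dissimilarity_trajectory <- function(table, meta, donor_samples = NULL,
                                           rank = "genus",
                                           exclude_post_relapse = TRUE,
                                           donor_reference = c("pairwise_mean",
                                                               "profile_mean")) {
  donor_reference <- match.arg(donor_reference)
  meta <- check_table_metadata(table, meta)
  if (is.null(donor_samples)) {
    donor_samples <- meta$sample_id[meta$arm == "donor"]
  }
  if (!length(donor_samples)) stop("no donor samples available")
  patient <- meta$arm != "donor" & meta$site == "fecal"
  if (exclude_post_relapse) {
    patient <- patient & (is.na(meta$relapse_week) |
                            meta$week <= meta$relapse_week)
  }
  pm <- meta[patient, , drop = FALSE]
  keep <- c(pm$sample_id, donor_samples)
  sub <- subset_table(table, samples = keep)

  if (donor_reference == "pairwise_mean") {
    dm <- distance_matrix(sub, rank = rank)
    vals <- vapply(pm$sample_id, donor_dissimilarity, numeric(1),
                   donor_samples = donor_samples, dm = dm)
  } else {
    agg <- if (is.null(rank)) sub else aggregate_taxa(sub, rank)
    frac <- to_relative(agg)
    ref <- rowMeans(frac[, donor_samples, drop = FALSE])
    vals <- vapply(pm$sample_id,
                   function(s) bray_curtis(frac[, s], ref, normalize = FALSE),
                   numeric(1))
  }
  data.frame(sample_id = pm$sample_id, subject_id = pm$subject_id,
             arm = pm$arm, week = pm$week,
             relapsed = !is.na(pm$relapse_week),
             dissimilarity = unname(vals), stringsAsFactors = FALSE)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and scales the
#' eigenvectors of positive eigenvalues by the square root of their
#' eigenvalue. Axes are ordered by descending eigenvalue; each axis's sign
#' is fixed so that its largest-magnitude loading is positive. Negative
#' eigenvalues (common for Bray-Curtis input) are dropped; their ids are
#' kept in the `n_negative` field and excluded from `prop_explained`,
#' which is computed over positive eigenvalues only.
#'
#' @param dm symmetric distance matrix with sample ids
#' @param n_axes number of axes requested (>= 2); if fewer positive
#'   eigenvalues exist, the available axes are returned with a warning
#' @return an object of class `pcoa_ord`: list with `coordinates` (samples
#'   x axes), `eigenvalues` (all, descending), `prop_explained` (positive
#'   eigenvalues only) and `n_negative`
#' @export
pcoa_ord <- function(dm, n_axes = 2) {
  check_distance_matrix(dm)
  if (n_axes < 2) stop("n_axes must be >= 2")
  n <- nrow(dm)
  a <- -0.5 * dm^2
  centered <- a - rowMeans(a)[row(a)] - colMeans(a)[col(a)] + mean(a)
  eig <- eigen((centered + t(centered)) / 2, symmetric = TRUE)
  values <- eig$values
  tol <- max(abs(values)) * 1e-9
  pos <- which(values > tol)
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axes",
                    length(pos), k))
  }
  coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(values[pos[seq_len(k)]]), k)
  for (j in seq_len(k)) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  dimnames(coords) <- list(rownames(dm), paste0("PCo", seq_len(k)))
  structure(list(coordinates = coords,
                 eigenvalues = values,
                 prop_explained = values[pos] / sum(values[pos]),
                 n_negative = sum(values < -tol)),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("pcoa_ord: %d samples, %d axes (PCo1 %.1f%%, PCo2 %.1f%%)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$prop_explained[1],
              100 * if (length(x$prop_explained) > 1) x$prop_explained[2] else NA))
  invisible(x)
}

# All distinct arrangements of a label vector (multiset permutations),
# returned as an integer matrix of level codes, one arrangement per column.
# Used for exact PERMANOVA p-values on small designs.
.label_arrangements <- function(codes) {
  n <- length(codes)
  lev <- sort(unique(codes))
  rec <- function(positions, remaining) {
    if (length(remaining) == 1L) {
      m <- matrix(0L, nrow = n, ncol = 1L)
      m[positions, 1L] <- remaining[1L]
      return(m)
    }
    l <- remaining[1L]
    k <- sum(codes == l)
    picks <- utils::combn(positions, k)
    out <- lapply(seq_len(ncol(picks)), function(j) {
      sub <- rec(setdiff(positions, picks[, j]), remaining[-1L])
      sub[picks[, j], ] <- l
      sub
    })
    do.call(cbind, out)
  }
  rec(seq_len(n), lev)
}

.permanova_ss <- function(d2, codes, levels) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (l in levels) {
    idx <- which(codes == l)
    ss_within <- ss_within +
      sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
  }
  c(total = ss_total, within = ss_within)
}

#' One-way PERMANOVA (permutational multivariate analysis of variance)
#'
#' Anderson's distance-based one-way PERMANOVA: total sum of squares
#' `sum_{i<j} d_ij^2 / n`, within-group sum of squares from within-group
#' pairs, pseudo-F `= (SS_between / (a - 1)) / (SS_within / (n - a))`, and
#' `R^2 = SS_between / SS_total`. The p-value comes from permuting group
#' labels: when the number of distinct label arrangements is at most
#' `n_perm` the full enumeration is used (exact p); otherwise `n_perm`
#' random permutations with the add-one estimator
#' `p = (1 + #[F* >= F]) / (1 + n_perm)`.
#'
#' @param dm symmetric distance matrix
#' @param grouping group label per sample (>= 2 groups, each >= 2 samples)
#' @param n_perm number of permutations (default 999)
#' @param seed RNG seed for the permutation stream
#' @return object of class `permanova`: list with `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`, `method` (`"exact"` or `"sampled"`) and
#'   `seed`
#' @export
permanova <- function(dm, grouping, n_perm = 999, seed = 1L) {
  check_distance_matrix(dm)
  g <- factor(grouping)
  n <- nrow(dm)
  if (length(g) != n) stop("grouping length must match the distance matrix")
  sizes <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("group '", names(sizes)[which(sizes < 2)[1]], "' has fewer than 2 samples")
  }
  a <- nlevels(g)
  codes <- as.integer(g)
  d2 <- dm^2
  ss <- .permanova_ss(d2, codes, seq_len(a))
  ss_between <- ss["total"] - ss["within"]
  f_obs <- (ss_between / (a - 1)) / (ss["within"] / (n - a))
  r2 <- unname(ss_between / ss["total"])

  n_distinct <- round(exp(lgamma(n + 1) - sum(lgamma(sizes + 1))))
  f_of <- function(codes_perm) {
    ssp <- .permanova_ss(d2, codes_perm, seq_len(a))
    ((ss["total"] - ssp["within"]) / (a - 1)) / (ssp["within"] / (n - a))
  }
  eps <- 1e-12
  if (n_distinct <= n_perm) {
    arr <- .label_arrangements(codes)
    f_all <- apply(arr, 2, f_of)
    p <- mean(f_all >= f_obs - eps)
    method <- "exact"
    n_used <- ncol(arr)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) f_of(codes[sample.int(n)]),
             numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - eps)) / (1 + n_perm)
    method <- "sampled"
    n_used <- n_perm
  }
  structure(list(r_squared = r2, pseudo_f = unname(f_obs), p_value = p,
                 n_permutations = n_used, method = method, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.3f, pseudo-F = %.3f, p = %.4g (%s, %d permutations)\n",
              x$r_squared, x$pseudo_f, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' Homogeneity of multivariate group dispersions
#'
#' Embeds the distance matrix by principal coordinates (positive
#' eigenvalues only), computes each sample's Euclidean distance to its
#' group centroid in that space, and tests equality of mean dispersions
#' with a one-way F statistic whose null distribution is obtained by
#' permuting group labels over the distances (add-one p-value). Negative
#' PCoA axes are not retained, and the group center is the centroid, not
#' the spatial median.
#'
#' @inheritParams permanova
#' @return object of class `beta_dispersion`: list with `group_means`
#'   (mean distance to centroid per group), `distances` (per sample),
#'   `f_statistic`, `p_value`, `n_permutations`, `seed`
#' @export
beta_dispersion <- function(dm, grouping, n_perm = 999, seed = 1L) {
  check_distance_matrix(dm)
  g <- factor(grouping)
  n <- nrow(dm)
  if (length(g) != n) stop("grouping length must match the distance matrix")
  sizes <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("group '", names(sizes)[which(sizes < 2)[1]], "' has fewer than 2 samples")
  }
  ord <- suppressWarnings(pcoa_ord(dm, n_axes = n))
  coords <- ord$coordinates
  dist_to_centroid <- function(gf) {
    out <- numeric(n)
    for (lev in levels(gf)) {
      idx <- which(gf == lev)
      centroid <- colMeans(coords[idx, , drop = FALSE])
      out[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2,
                                     centroid)^2))
    }
    out
  }
  z <- dist_to_centroid(g)
  f_of <- function(zv, gf) {
    gm <- tapply(zv, gf, mean)
    ssb <- sum(tabulate(gf) * (gm - mean(zv))^2)
    ssw <- sum((zv - gm[as.integer(gf)])^2)
    (ssb / (nlevels(gf) - 1)) / (ssw / (n - nlevels(gf)))
  }
  f_obs <- f_of(z, g)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_of(z[sample.int(n)], g), numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  structure(list(group_means = tapply(z, g, mean),
                 distances = stats::setNames(z, rownames(dm)),
                 f_statistic = f_obs, p_value = p,
                 n_permutations = n_perm, seed = seed),
            class = "beta_dispersion")
}

#' @export
print.beta_dispersion <- function(x, ...) {
  cat("Multivariate dispersion homogeneity\n")
  cat("  mean distance to centroid:",
      paste(sprintf("%s = %.4f", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  cat(sprintf("  F = %.3f, p = %.4g (%d permutations)\n",
              x$f_statistic, x$p_value, x$n_permutations))
  invisible(x)
}
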