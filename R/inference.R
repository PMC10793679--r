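# Midranks of a pooled vector.
.midranks <- function(x) rank(x, ties.method = "average")

# Sum over tie groups of (t^3 - t), used in tie corrections.
.tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test for a location difference between two independent
#' samples. The statistic is the rank sum `W` of the first sample over the
#' pooled midranks. For `length(a) + length(b) <= 12` the p-value is exact,
#' enumerating all assignments of the pooled values to the two groups;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. When every pooled value is tied the test is
#' degenerate and p = 1 is returned with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @return a list of class `htest` with `statistic` (W), `p.value`, and
#'   `method` noting whether the p-value is exact
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  m <- length(a); n2 <- length(b); n <- m + n2
  pooled <- c(a, b)
  r <- .midranks(pooled)
  w_obs <- sum(r[seq_len(m)])
  mu <- m * (n + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(structure(list(statistic = c(W = w_obs), p.value = 1,
                          method = "Wilcoxon rank-sum test (degenerate)",
                          alternative = "two.sided"), class = "htest"))
  }
  eps <- 1e-9
  if (n <= 12) {
    combos <- utils::combn(n, m)
    w_all <- colSums(matrix(r[combos], nrow = m))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
    method <- "Wilcoxon rank-sum test (exact enumeration)"
  } else {
    sigma2 <- m * n2 / 12 * ((n + 1) - .tie_term(r) / (n * (n - 1)))
    dev <- max(abs(w_obs - mu) - 0.5, 0)  # continuity correction
    z <- dev / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  structure(list(statistic = c(W = w_obs), p.value = p, method = method,
                 alternative = "two.sided"), class = "htest")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided test that the paired differences are symmetric about zero.
#' Zero differences are dropped (standard convention). The statistic is
#' `V`, the sum of the ranks of `|d|` over the positive differences. Exact
#' by enumeration of all sign assignments when the number of nonzero
#' differences is at most 12; otherwise normal approximation with tie
#' correction and continuity correction.
#'
#' @param paired_diffs numeric vector of paired differences with at least
#'   2 nonzero entries (all-zero input returns p = 1 with a warning)
#' @return a list of class `htest` with `statistic` (V), `p.value`, `method`
#' @export
signed_rank_test <- function(paired_diffs) {
  d <- paired_diffs[paired_diffs != 0]
  if (!length(d)) {
    warning("all differences are zero; p = 1")
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed-rank test (degenerate)",
                          alternative = "two.sided"), class = "htest"))
  }
  if (length(d) < 2) stop("need >= 2 nonzero differences")
  n <- length(d)
  r <- .midranks(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  eps <- 1e-9
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - eps)
    method <- "Wilcoxon signed-rank test (exact enumeration)"
  } else {
    sigma2 <- sum(r^2) / 4
    dev <- max(abs(v_obs - mu) - 0.5, 0)
    z <- dev / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  structure(list(statistic = c(V = v_obs), p.value = p, method = method,
                 alternative = "two.sided"), class = "htest")
}

#' Kruskal-Wallis rank test for two or more groups
#'
#' H statistic on pooled midranks with tie correction, compared to a
#' chi-square distribution on `k - 1` degrees of freedom. If every pooled
#' value is tied, H = 0 and p = 1.
#'
#' @param groups list of numeric vectors, each of length >= 2
#' @return a list of class `htest` with `statistic` (H), `parameter` (df),
#'   `p.value`
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values")
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- .midranks(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  rsums <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsums^2 / lengths(groups)) - 3 * (n + 1)
  correction <- 1 - .tie_term(r) / (n^3 - n)
  if (correction <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- h / correction
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  structure(list(statistic = c(H = h), parameter = c(df = k - 1),
                 p.value = p, method = "Kruskal-Wallis rank sum test"),
            class = "htest")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH q-values with monotonicity enforcement; order-preserving
#' (`q[i]` corresponds to `p[i]`).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @return q-values, same length and order as the input
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Per-taxon differential abundance testing between groups
#'
#' Aggregates counts to `rank`, converts to per-sample fractions, drops
#' taxa present in fewer than `min_prevalence` of the samples, and tests
#' each remaining taxon for a group difference: the rank-sum test for two
#' groups, Kruskal-Wallis for more. P-values are corrected to q-values by
#' Benjamini-Hochberg over the tested family. The log2 fold change (two
#' groups only) compares group mean fractions with a pseudo-fraction of
#' half the smallest nonzero observed fraction. The conventional
#' significance call is p < 0.05 and q < 0.05.
#'
#' @param table a filtered [count_table()]
#' @param meta sample metadata
#' @param rank taxonomic rank to aggregate to (default genus)
#' @param grouping metadata column name defining the groups; samples with
#'   `NA` in that column are dropped
#' @param min_prevalence minimum fraction of samples in which a taxon must
#'   be present to be tested (default 0.1)
#' @return data.frame with columns `taxon_id`, per-group mean fractions,
#'   `log2_fc`, `statistic`, `p_value`, `q_value`, ordered by `q_value`
#' @export
taxon_group_test <- function(table, meta, rank = "genus", grouping = "arm",
                             min_prevalence = 0.1) {
  meta <- check_table_metadata(table, meta)
  if (!grouping %in% names(meta)) stop("unknown metadata column: ", grouping)
  gvals <- meta[[grouping]]
  keep <- !is.na(gvals)
  g <- factor(gvals[keep])
  if (nlevels(g) < 2) stop("grouping defines fewer than 2 groups")
  if (any(table(g) == 0)) {
    stop("empty group: ", levels(g)[which(table(g) == 0)[1]])
  }
  sub <- subset_table(table, samples = sample_ids(table)[keep])
  agg <- if (is.null(rank)) sub else aggregate_taxa(sub, rank)
  frac <- to_relative(agg)
  prevalent <- rowMeans(frac > 0) >= min_prevalence
  if (!any(prevalent)) stop("no taxa pass the prevalence filter")
  frac <- frac[prevalent, , drop = FALSE]

  pseudo <- min(frac[frac > 0]) / 2
  two_groups <- nlevels(g) == 2
  res <- lapply(rownames(frac), function(tx) {
    v <- frac[tx, ]
    by_group <- split(v, g)
    means <- vapply(by_group, mean, numeric(1))
    if (two_groups) {
      ht <- rank_sum_test(by_group[[1]], by_group[[2]])
      fc <- log2((means[1] + pseudo) / (means[2] + pseudo))
    } else {
      ht <- kruskal_wallis(by_group)
      fc <- NA_real_
    }
    cbind(data.frame(taxon_id = tx, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(
            means, paste0("mean_", names(means))))),
          data.frame(log2_fc = unname(fc),
                     statistic = unname(ht$statistic),
                     p_value = ht$p.value, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$q_value, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
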