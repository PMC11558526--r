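# Interval-overlap discrimination and supporting statistics. The discrimination
# criterion of the method is geometric (non-overlapping value intervals), not
# statistical significance; rank-sum and chi-square tests are reported alongside.

#' Interval overlap index between two samples
#'
#' Represents each group's feature values by the interval between two sample
#' quantiles (the full min-max range when `trim = c(0, 1)`) and measures how
#' much the shorter interval is covered by the other one:
#' `length(intersection) / min(length(A), length(B))`, in `[0, 1]`. Zero
#' means disjoint intervals — the personalized-discrimination criterion. A
#' degenerate (zero-length) interval scores 1 if its point lies inside the
#' other interval, else 0.
#'
#' @param a,b numeric samples, each of size >= 2, no missing values.
#' @param trim quantile pair `c(qlo, qhi)` with `0 <= qlo < qhi <= 1`
#'   defining the interval (e.g. `c(0.025, 0.975)` for robust trimming).
#' @param feature,groups optional labels carried into the report.
#' @return Object of class `overlap_report`: list with `overlap_index`,
#'   `non_overlap`, the two interval bounds, sample sizes, and the trim used.
#' @export
overlap_index <- function(a, b, trim = c(0, 1), feature = NA_character_,
                          groups = c("a", "b")) {
  if (length(a) < 2 || length(b) < 2)
    stopf("overlap_index: each sample needs >= 2 values")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    stopf("overlap_index: samples must be finite and complete")
  if (length(trim) != 2 || trim[1] < 0 || trim[2] > 1 || trim[1] >= trim[2])
    stopf("overlap_index: trim must satisfy 0 <= qlo < qhi <= 1")
  ia <- unname(stats::quantile(a, trim, names = FALSE))
  ib <- unname(stats::quantile(b, trim, names = FALSE))
  la <- diff(ia); lb <- diff(ib)
  inter <- max(0, min(ia[2], ib[2]) - max(ia[1], ib[1]))
  idx <- if (min(la, lb) == 0) {
    pt  <- if (la <= lb) ia[1] else ib[1]
    box <- if (la <= lb) ib else ia
    as.numeric(pt >= box[1] & pt <= box[2])
  } else inter / min(la, lb)
  structure(list(feature = feature, groups = groups, overlap_index = idx,
                 non_overlap = idx == 0, interval_a = ia, interval_b = ib,
                 n = c(length(a), length(b)), trim = trim),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap %s [%s vs %s]: index %.3f%s\n",
              if (is.na(x$feature)) "" else x$feature,
              x$groups[1], x$groups[2], x$overlap_index,
              if (x$non_overlap) " (non-overlapping)" else ""))
  invisible(x)
}

#' Scan a DI matrix for discriminating features
#'
#' Scores every feature x group-pair by the interval overlap index, with the
#' rank-sum comparison (and Benjamini-Hochberg adjusted p-values) reported
#' alongside. Ranked ascending by overlap index — non-overlapping features
#' first — with ties broken by larger rank-sum effect size, then by feature
#' identifier; the ordering is deterministic. Pairs where a group has fewer
#' than 2 observations are skipped with a warning entry.
#'
#' @param di_matrix numeric matrix, observations x features (named columns).
#' @param groups group label per observation (>= 2 groups).
#' @param trim quantile pair passed to [overlap_index()].
#' @return data.frame of class `overlap_scan`, one row per feature and group
#'   pair, plus a `skipped` attribute listing skipped pairs.
#' @export
scan_discriminators <- function(di_matrix, groups, trim = c(0, 1)) {
  di_matrix <- as.matrix(di_matrix)
  if (is.null(colnames(di_matrix)))
    colnames(di_matrix) <- paste0("di", seq_len(ncol(di_matrix)))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(di_matrix))
  glev <- sort(unique(groups))
  if (length(glev) < 2) stopf("scan_discriminators: need >= 2 groups")
  pairs <- utils::combn(glev, 2)
  sizes <- table(groups)
  ok_pair <- sizes[pairs[1, ]] >= 2 & sizes[pairs[2, ]] >= 2
  skipped <- character(0)
  if (any(!ok_pair)) {
    skipped <- paste(pairs[1, !ok_pair], pairs[2, !ok_pair], sep = " vs ")
    warnf("scan_discriminators: skipping pair(s) with < 2 observations: %s",
          paste(skipped, collapse = "; "))
    pairs <- pairs[, ok_pair, drop = FALSE]
  }
  rows <- list()
  for (j in seq_len(ncol(di_matrix))) {
    feat <- colnames(di_matrix)[j]
    for (p in seq_len(ncol(pairs))) {
      g1 <- pairs[1, p]; g2 <- pairs[2, p]
      a <- di_matrix[groups == g1, j]; b <- di_matrix[groups == g2, j]
      ov <- overlap_index(a, b, trim, feature = feat, groups = c(g1, g2))
      rc <- rank_compare(a, b)
      effect <- abs(2 * rc$statistic / (length(a) * length(b)) - 1)
      rows[[length(rows) + 1]] <- data.frame(
        feature = feat, group1 = g1, group2 = g2,
        n1 = length(a), n2 = length(b),
        overlap_index = ov$overlap_index, non_overlap = ov$non_overlap,
        lo1 = ov$interval_a[1], hi1 = ov$interval_a[2],
        lo2 = ov$interval_b[1], hi2 = ov$interval_b[2],
        statistic = rc$statistic, p_value = rc$p_value, effect = effect,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$overlap_index, -out$effect, out$feature,
                   out$group1, out$group2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "trim") <- trim
  class(out) <- c("overlap_scan", "data.frame")
  out
}

#' Two-sided rank-sum (Mann-Whitney) comparison
#'
#' Compares the locations of two samples with the Mann-Whitney U statistic
#' on midranks. For `n_a + n_b <= 12` the p-value is computed by exhaustive
#' enumeration of all rank splits (exact, valid under ties); above that, the
#' continuity-corrected normal approximation with tie-corrected variance is
#' used.
#'
#' @param a,b numeric samples (size >= 1).
#' @return List: `median_a`, `median_b`, `statistic` (U for sample `a`),
#'   `p_value`, `method`, and `tied` (`TRUE` when every value is identical,
#'   in which case the p-value is 1).
#' @export
rank_compare <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stopf("rank_compare: empty sample")
  if (anyNA(a) || anyNA(b)) stopf("rank_compare: missing values")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  out <- list(median_a = stats::median(a), median_b = stats::median(b),
              statistic = u, tied = length(unique(c(a, b))) == 1)
  if (out$tied) {
    out$p_value <- 1
    out$method <- "degenerate (all values tied)"
    return(out)
  }
  if (n <= 12) {
    splits <- utils::combn(n, na)
    us <- colSums(matrix(r[splits], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
    out$p_value <- min(1, p)
    out$method <- "exact enumeration"
  } else {
    ties <- table(r)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)   # continuity-corrected
    out$p_value <- 2 * stats::pnorm(-max(0, z))
    out$method <- "normal approximation, tie- and continuity-corrected"
  }
  out
}

#' Pearson chi-square test of association
#'
#' Association between the rows and columns of a contingency table of
#' nonnegative counts (e.g. group x outcome), without continuity correction
#' by default, with per-row proportions.
#'
#' @param table matrix of nonnegative integer counts (2x2 or k x 2); all
#'   row and column margins must be positive.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return List: `chi2`, `df`, `p_value`, `proportions` (cells divided by
#'   their row totals).
#' @export
contingency_test <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || anyNA(tab)) stopf("contingency_test: counts must be >= 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("contingency_test: zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), proportions = tab / rowSums(tab))
}

#' Excess kurtosis
#'
#' Fourth standardized central moment minus 3 (the normal distribution
#' scores 0); a measure of peakedness/tail weight.
#'
#' @param x numeric sample, size >= 4, positive variance.
#' @return Excess kurtosis of `x`.
#' @export
excess_kurtosis <- function(x) {
  if (anyNA(x)) stopf("excess_kurtosis: missing values")
  if (length(x) < 4) stopf("excess_kurtosis: need >= 4 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stopf("excess_kurtosis: zero variance")
  mean((x - m)^4) / m2^2 - 3
}
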