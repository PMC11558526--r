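# Operationalization of the visual pattern-recognition step: thin line-like
# point clouds in 3D indicator space, ordered along their principal curve,
# segmented at perpendicular direction inflections.

angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Thinness of a point cloud
#'
#' From the principal-axis variances `lambda1 >= lambda2 >= lambda3` of the
#' centered cloud, `thinness = 1 - (lambda2 + lambda3) / sum(lambda)`.
#' A perfectly collinear set scores 1; an isotropic 3D cloud about 1/3; an
#' isotropic planar cloud about 1/2. Invariant to rotation, translation and
#' uniform scaling.
#'
#' @param points numeric matrix (n x 3, n >= 3) of coordinates.
#' @return Thinness in `[0, 1]`.
#' @export
thinness <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stopf("thinness: need >= 3 points")
  if (anyNA(points)) stopf("thinness: missing coordinates")
  lam <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (sum(lam) == 0) stopf("degenerate cloud: all points coincident")
  1 - (sum(lam) - lam[1]) / sum(lam)
}

#' Order observations along a thin curve
#'
#' Orders the points of a thin (line-like) cloud along the curve they trace:
#' the chain starts at the extreme point of the first principal axis and
#' greedily appends the nearest unvisited point, so bent (L- or Z-shaped)
#' lines are walked arm by arm without interleaving. The reversed ordering
#' is an equivalent answer.
#'
#' @param points numeric matrix (n x d, n >= 3).
#' @param thinness_threshold minimal [thinness()] required before curve
#'   ordering is meaningful (error below it).
#' @return Integer index sequence along the curve.
#' @export
order_along_curve <- function(points, thinness_threshold = 0.9) {
  points <- as.matrix(points)
  th <- thinness(points)
  if (th < thinness_threshold)
    stopf("cloud thinness %.3f below threshold %.3f: not line-like, curve ordering not advised",
          th, thinness_threshold)
  n <- nrow(points)
  ctr <- scale(points, center = TRUE, scale = FALSE)
  pc1 <- eigen(stats::cov(points), symmetric = TRUE)$vectors[, 1]
  proj <- drop(ctr %*% pc1)
  ord <- integer(n)
  ord[1] <- which.min(proj)
  left <- setdiff(seq_len(n), ord[1])
  for (i in seq_len(n - 1)) {
    d2 <- colSums((t(points[left, , drop = FALSE]) - points[ord[i], ])^2)
    nxt <- left[which.min(d2)]
    ord[i + 1] <- nxt
    left <- setdiff(left, nxt)
  }
  ord
}

#' Detect direction inflections along an ordered point sequence
#'
#' At each interior position, measures the angle between the mean direction
#' of the preceding `window` steps and the mean direction of the following
#' `window` steps. Positions where the angle reaches `angle_threshold` and
#' is a local maximum (one per run of super-threshold positions) are
#' reported; angles within `perpendicular_band` of 90 degrees are tagged
#' "perpendicular" — the hallmark geometry of the partitioned structures.
#'
#' @param points numeric matrix of coordinates, already in curve order.
#' @param window half-window size in points.
#' @param angle_threshold minimal turn angle in degrees (default 60).
#' @param perpendicular_band the perpendicular tag applies within
#'   `90 +/- perpendicular_band` degrees.
#' @return data.frame with `position`, `angle`, `perpendicular`; empty (with
#'   a warning) when the sequence is shorter than `2 * window + 1`.
#' @export
detect_inflections <- function(points, window = 5, angle_threshold = 60,
                               perpendicular_band = 15) {
  points <- as.matrix(points)
  n <- nrow(points)
  empty <- data.frame(position = integer(0), angle = numeric(0),
                      perpendicular = logical(0))
  if (n < 2 * window + 1) {
    warnf("detect_inflections: sequence of %d points too short for window %d",
          n, window)
    return(empty)
  }
  dirs <- diff(points)
  ang <- rep(NA_real_, n)
  for (i in (window + 1):(n - window)) {
    v1 <- colMeans(dirs[(i - window):(i - 1), , drop = FALSE])
    v2 <- colMeans(dirs[i:(i + window - 1), , drop = FALSE])
    ang[i] <- angle_deg(v1, v2)
  }
  cand <- which(!is.na(ang) & ang >= angle_threshold)
  if (length(cand) == 0) return(empty)
  runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
  pos <- vapply(runs, function(r) r[which.max(ang[r])], integer(1))
  data.frame(position = unname(pos), angle = ang[pos],
             perpendicular = abs(ang[pos] - 90) <= perpendicular_band)
}

#' Partition ordered observations at inflection points
#'
#' `k` inflections split the ordered sequence into `k + 1` contiguous
#' segments, labeled `A`, `B`, `C`, ... Subset `A` is by convention the end
#' with the lower mortality (ties broken by lower mean N/L ratio; with no
#' metadata, the start of the given ordering). Per-subset mortality and
#' septic proportions are computed from the observation metadata.
#'
#' @param order integer index sequence from [order_along_curve()].
#' @param inflections data.frame from [detect_inflections()], or an integer
#'   vector of strictly increasing positions along the ordering.
#' @param outcome,septic_status,nl optional per-observation metadata
#'   (indexed like the original observations): `"survived"`/`"died"`,
#'   septic status, and N/L ratio values.
#' @return Object of class `subset_assignment`: list with `labels`
#'   (per original observation), `order`, `positions` (inflection positions)
#'   and `summary` (per-subset n, mortality and septic proportions).
#' @export
partition_by_inflections <- function(order, inflections, outcome = NULL,
                                     septic_status = NULL, nl = NULL) {
  pos <- if (is.data.frame(inflections)) inflections$position else inflections
  pos <- as.integer(pos)
  if (is.unsorted(pos, strictly = TRUE))
    stopf("inflection positions must be strictly increasing")
  n <- length(order)
  seg <- findInterval(seq_len(n), pos + 0.5) + 1L   # segment per position
  k <- length(pos) + 1L

  reverse <- FALSE
  if (!is.null(outcome) && k > 1) {
    mort <- function(s) {
      o <- outcome[order[seg == s]]
      if (length(o) == 0) NA_real_ else mean(o == "died")
    }
    m1 <- mort(1); mk <- mort(k)
    if (!is.na(m1) && !is.na(mk)) {
      if (m1 > mk) reverse <- TRUE
      else if (m1 == mk && !is.null(nl)) {
        nl1 <- mean(nl[order[seg == 1]]); nlk <- mean(nl[order[seg == k]])
        if (isTRUE(nl1 > nlk)) reverse <- TRUE
      }
    }
  }
  lab_of_seg <- if (reverse) rev(LETTERS[seq_len(k)]) else LETTERS[seq_len(k)]
  labels <- rep(NA_character_, max(order))
  labels[order] <- lab_of_seg[seg]

  summ <- do.call(rbind, lapply(sort(unique(lab_of_seg)), function(L) {
    idx <- order[lab_of_seg[seg] == L]
    data.frame(
      subset = L, n = length(idx),
      mortality = if (!is.null(outcome)) mean(outcome[idx] == "died") else NA_real_,
      septic = if (!is.null(septic_status)) mean(septic_status[idx] == "septic") else NA_real_,
      stringsAsFactors = FALSE)
  }))
  structure(list(labels = labels, order = order, positions = pos,
                 summary = summ),
            class = "subset_assignment")
}

#' @export
print.subset_assignment <- function(x, ...) {
  cat("Subset assignment:", length(x$positions), "inflection(s),",
      nrow(x$summary), "subset(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Search DI triplets for line-like spatial patterns
#'
#' Enumerates (exhaustively up to `max_triplets`, otherwise by seeded
#' sampling) triplets of indicator columns, standardizes each coordinate,
#' and scores the triplet by the [thinness()] of the 3D cloud and — for
#' triplets thin enough to order — by the mortality contrast between the
#' subsets its inflections induce. Triplets below the thinness threshold
#' are dropped; the result is ranked by thinness, then contrast, and is
#' deterministic for a fixed seed.
#'
#' @param di_matrix numeric matrix, observations x indicators (>= 3 columns).
#' @param outcome optional `"survived"`/`"died"` per observation.
#' @param top_k number of patterns to return.
#' @param thinness_threshold minimal thinness for a reported pattern.
#' @param max_triplets above this, triplets are sampled rather than
#'   enumerated (seed required).
#' @param window,angle_threshold passed to [detect_inflections()].
#' @param seed RNG seed for triplet sampling.
#' @return data.frame of class `pattern_search`: `di1`, `di2`, `di3`,
#'   `thinness`, `n_inflections`, `mortality_contrast`, ranked best first.
#' @export
search_patterns <- function(di_matrix, outcome = NULL, top_k = 5,
                            thinness_threshold = 0.9, max_triplets = 2000,
                            window = 5, angle_threshold = 60, seed = 1) {
  di_matrix <- as.matrix(di_matrix)
  if (ncol(di_matrix) < 3) stopf("search_patterns: need >= 3 indicators")
  if (is.null(colnames(di_matrix)))
    colnames(di_matrix) <- paste0("di", seq_len(ncol(di_matrix)))
  empty <- data.frame(di1 = character(0), di2 = character(0),
                      di3 = character(0), thinness = numeric(0),
                      n_inflections = integer(0),
                      mortality_contrast = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("pattern_search", "data.frame")
  if (top_k <= 0) return(empty)

  n_trip <- choose(ncol(di_matrix), 3)
  trips <- if (n_trip <= max_triplets) {
    utils::combn(ncol(di_matrix), 3)
  } else {
    set.seed(seed)
    matrix(replicate(max_triplets, sort(sample.int(ncol(di_matrix), 3))),
           nrow = 3)
  }
  Z <- scale(di_matrix)
  rows <- list()
  for (t in seq_len(ncol(trips))) {
    ix <- trips[, t]
    pts <- Z[, ix, drop = FALSE]
    th <- thinness(pts)
    if (th < thinness_threshold) next
    contrast <- NA_real_
    n_inf <- NA_integer_
    ordd <- order_along_curve(pts, thinness_threshold)
    infl <- suppressWarnings(
      detect_inflections(pts[ordd, , drop = FALSE], window, angle_threshold))
    n_inf <- nrow(infl)
    if (!is.null(outcome)) {
      pa <- partition_by_inflections(ordd, infl, outcome = outcome)
      m <- pa$summary$mortality
      contrast <- if (all(is.na(m))) NA_real_ else
        diff(range(m, na.rm = TRUE))
    }
    rows[[length(rows) + 1]] <- data.frame(
      di1 = colnames(di_matrix)[ix[1]], di2 = colnames(di_matrix)[ix[2]],
      di3 = colnames(di_matrix)[ix[3]], thinness = th,
      n_inflections = n_inf, mortality_contrast = contrast,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$thinness, -ifelse(is.na(out$mortality_contrast), -Inf,
                                          out$mortality_contrast),
                   out$di1, out$di2, out$di3), , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  class(out) <- c("pattern_search", "data.frame")
  out
}

#' Full spatial-pattern analysis of one DI triplet
#'
#' Runs the complete geometry pipeline on one indicator triplet:
#' standardization, thinness, curve ordering, inflection detection, and
#' subset partitioning with outcome metadata.
#'
#' @param di_matrix numeric matrix, observations x indicators.
#' @param triplet three column names (or indices) of `di_matrix`.
#' @param outcome,septic_status,nl optional observation metadata, see
#'   [partition_by_inflections()].
#' @param window,angle_threshold,thinness_threshold geometry parameters.
#' @return Object of class `spatial_pattern`: list with `triplet`, `coords`
#'   (standardized), `thinness`, `order`, `inflections`, `assignment`.
#' @export
spatial_pattern <- function(di_matrix, triplet, outcome = NULL,
                            septic_status = NULL, nl = NULL, window = 5,
                            angle_threshold = 60, thinness_threshold = 0.9) {
  di_matrix <- as.matrix(di_matrix)
  raw <- di_matrix[, triplet, drop = FALSE]
  pts <- scale(raw)
  if (ncol(pts) != 3) stopf("spatial_pattern: triplet must select 3 columns")
  th <- thinness(pts)
  ordd <- order_along_curve(pts, thinness_threshold)
  infl <- suppressWarnings(
    detect_inflections(pts[ordd, , drop = FALSE], window, angle_threshold))
  asg <- partition_by_inflections(ordd, infl, outcome = outcome,
                                  septic_status = septic_status, nl = nl)
  structure(list(triplet = colnames(pts) %||% triplet, coords = pts,
                 raw = raw, thinness = th, order = ordd, inflections = infl,
                 assignment = asg),
            class = "spatial_pattern")
}

#' @export
print.spatial_pattern <- function(x, ...) {
  cat("Spatial pattern over (", paste(x$triplet, collapse = ", "),
      "): thinness ", sprintf("%.3f", x$thinness), ", ",
      nrow(x$inflections), " inflection(s)\n", sep = "")
  print(x$assignment$summary, row.names = FALSE)
  invisible(x)
}
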