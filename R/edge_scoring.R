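#' Mutual information between two sample partitions
#'
#' Given two partitions of the same N samples into modules \eqn{U_1..U_{|U|}}
#' and \eqn{V_1..V_{|V|}}, the mutual information is the double sum
#' \deqn{MI(U,V) = \sum_i \sum_j \frac{|U_i \cap V_j|}{N}
#'   \log \frac{N |U_i \cap V_j|}{|U_i| |V_j|}}
#' in nats, with empty intersections contributing zero. MI is symmetric,
#' non-negative, invariant under module relabeling, and bounded above by the
#' smaller of the two partition entropies.
#'
#' @param u,v Equal-length label vectors (any type usable as a factor); each
#'   distinct label is one module.
#' @return Mutual information in nats (non-negative scalar).
#' @export
mutual_information <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have the same length")
  if (length(u) == 0) stop("partitions must be non-empty")
  tab <- table(u, v)
  n <- sum(tab)
  p_ij <- tab / n
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  terms <- p_ij * log(p_ij / outer(p_i, p_j))
  mi <- sum(terms[tab > 0])
  max(mi, 0) # clamp float noise on independent partitions
}

entropy_nats <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Rescales [mutual_information()] into `[0, 1]` — 0 meaning no correlation
#' and 1 perfect correlation — by dividing by a mean of the two partition
#' entropies. The arithmetic mean is the default normalization; geometric,
#' min and max are available for comparability with older tooling. When
#' either partition has zero entropy (a single module), the score is defined
#' as 0: a constant gene carries no information about its partner.
#'
#' @inheritParams mutual_information
#' @param norm Which mean of the two entropies to divide by.
#' @return NMI in `[0, 1]`.
#' @export
normalized_mi <- function(u, v, norm = c("arithmetic", "geometric", "min", "max")) {
  norm <- match.arg(norm)
  if (length(u) != length(v)) stop("`u` and `v` must have the same length")
  h_u <- entropy_nats(u)
  h_v <- entropy_nats(v)
  if (h_u == 0 || h_v == 0) return(0)
  mi <- mutual_information(u, v)
  denom <- switch(norm,
    arithmetic = (h_u + h_v) / 2,
    geometric = sqrt(h_u * h_v),
    min = min(h_u, h_v),
    max = max(h_u, h_v)
  )
  min(1, max(0, mi / denom))
}

#' @rdname normalized_mi
#' @return `mi_result()`: a one-row tibble with `mi_raw`, `nmi`, `h_u`, `h_v`.
#' @export
mi_result <- function(u, v, norm = "arithmetic") {
  tibble::tibble(
    mi_raw = mutual_information(u, v),
    nmi = normalized_mi(u, v, norm),
    h_u = entropy_nats(u),
    h_v = entropy_nats(v)
  )
}

#' Discretize one gene's expression for MI scoring
#'
#' The MI estimator uses the same bin grid as the imaging step, so the image
#' and the score describe one and the same quantization of the data. Each
#' sample's module is its expression bin; out-of-range or missing samples get
#' `NA` and are excluded pairwise together with the partner gene.
#'
#' @param expr Numeric expression vector.
#' @param grid A [bin_grid()].
#' @return Integer module labels (0-based bin indices), `NA` where dropped.
#' @export
discretize_for_mi <- function(expr, grid) {
  bin_value(expr, grid)
}

#' Normalized MI score of one gene pair
#'
#' The default (`mode = "all_samples"`) scores the pair with the NMI of the
#' two bin-discretized expression vectors over all pairwise-complete samples
#' — the straightforward approach, adopted because averaging MI over detected
#' modes did not materially change the resulting network. `mode = "per_blob"`
#' retains that alternative: every sample is assigned to the strongest-
#' response blob whose disk (radius `sqrt(2) * sigma`, or `sigma` for DoH
#' blobs) contains its binned coordinate, ties going to the nearest center;
#' blobs holding fewer than `min_blob_samples` samples are skipped, and the
#' edge score is the unweighted mean of the per-blob NMIs. If no blob
#' qualifies the function falls back to the all-samples score with a warning.
#'
#' @param expr_a,expr_b Paired expression vectors.
#' @param grid A [bin_grid()].
#' @param mode `"all_samples"` (default) or `"per_blob"`.
#' @param blobs Blob tibble from [detect_blobs()] (required for
#'   `"per_blob"`); `row`/`col` are in 0-based bin units.
#' @param norm NMI normalization, see [normalized_mi()].
#' @param min_blob_samples Minimum samples for a blob to contribute.
#' @return NMI in `[0, 1]`.
#' @export
edge_nmi <- function(expr_a, expr_b, grid,
                     mode = c("all_samples", "per_blob"), blobs = NULL,
                     norm = "arithmetic", min_blob_samples = 10L) {
  mode <- match.arg(mode)
  if (length(expr_a) != length(expr_b)) stop("expression vectors must be paired")
  if (length(expr_a) == 0) stop("empty input")
  la <- discretize_for_mi(expr_a, grid)
  lb <- discretize_for_mi(expr_b, grid)
  keep <- !is.na(la) & !is.na(lb)
  if (!any(keep)) stop("no pairwise-complete in-range samples")
  la <- la[keep]
  lb <- lb[keep]
  if (mode == "all_samples") {
    return(normalized_mi(la, lb, norm))
  }
  if (is.null(blobs)) stop("`per_blob` mode requires a blob set")
  if (nrow(blobs) == 0) {
    warning("no blobs supplied; falling back to all-samples NMI")
    return(normalized_mi(la, lb, norm))
  }
  fac <- ifelse(blobs$method == "doh", 1, sqrt(2))
  rad2 <- (fac * blobs$sigma)^2
  assign_blob <- function(r, c) {
    d2 <- (blobs$row - r)^2 + (blobs$col - c)^2
    inside <- which(d2 <= rad2)
    if (length(inside) == 0) return(NA_integer_)
    best <- inside[order(-blobs$response[inside], d2[inside])]
    best[1]
  }
  # sample coordinates in image space: row = partner gene bin, col = gene a bin
  assignment <- mapply(assign_blob, lb, la)
  scores <- c()
  for (b in seq_len(nrow(blobs))) {
    in_b <- which(assignment == b)
    if (length(in_b) >= min_blob_samples) {
      scores <- c(scores, normalized_mi(la[in_b], lb[in_b], norm))
    }
  }
  if (length(scores) == 0) {
    warning("no blob held enough samples; falling back to all-samples NMI")
    return(normalized_mi(la, lb, norm))
  }
  mean(scores)
}

#' Mean silhouette coefficient
#'
#' Cluster-separation score of a labeled point set under Euclidean distance.
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to any other cluster; the
#' point's score is `(b - a) / max(a, b)`, a singleton cluster's member
#' scoring 0 by convention. The returned `S` is the mean over all points and
#' lies in `[-1, 1]`.
#'
#' @param points Numeric matrix or data frame, one row per sample (any
#'   dimensionality; for a bigenic edge, the two genes' expressions).
#' @param labels Cluster assignment, one label per row.
#' @return Mean silhouette `S` in `[-1, 1]`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (length(labels) != n) stop("one label per point required")
  labels <- as.character(labels)
  clusters <- unique(labels)
  if (length(clusters) < 2) stop("silhouette requires at least 2 clusters")
  d <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1) { s[i] <- 0; next } # singleton convention
    a <- sum(d[i, own]) / (n_own - 1) # excludes self (d[i,i] = 0)
    b <- min(vapply(setdiff(clusters, labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
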