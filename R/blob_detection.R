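#' Detector configuration
#'
#' Collects the tunable parameters of the three scale-space blob detectors.
#' All scales are in bin units. The defaults are the conventional choices for
#' isotropic blob detection on small images: scales from 1 bin up to a
#' quarter of the image side, 10 scale samples for LoG/DoH, a geometric ratio
#' of 1.6 between successive Gaussian widths for DoG, an absolute response
#' threshold of 0.05 (appropriate for max-normalized intensities), and 50%
#' disk-overlap pruning. `min_blobs` and `k_required` parameterize the edge
#' inclusion rule: a gene pair passes when at least `k_required` of the three
#' detectors each find `min_blobs` or more subpopulations (default: 2 or more
#' blobs within at least 2 of the detectors).
#'
#' @param min_sigma Smallest Gaussian scale considered, in bins.
#' @param max_sigma Largest scale; `NULL` means `n_bins / 4`, resolved when an
#'   image is seen.
#' @param num_sigma Number of linearly spaced scales for LoG and DoH.
#' @param sigma_ratio Geometric ratio between successive DoG scales (> 1).
#' @param threshold Absolute minimum scale-space response for a blob
#'   candidate.
#' @param overlap Maximum allowed fractional disk overlap between two kept
#'   blobs, in `[0, 1]`; of an overlapping pair, the weaker response is
#'   pruned.
#' @param min_blobs Blob count a detector must reach to call an image
#'   multimodal.
#' @param k_required Number of detectors that must call the image multimodal
#'   for the pair to pass.
#' @return A `detector_config` list.
#' @export
detector_config <- function(min_sigma = 1, max_sigma = NULL, num_sigma = 10,
                            sigma_ratio = 1.6, threshold = 0.05, overlap = 0.5,
                            min_blobs = 2L, k_required = 2L) {
  stopifnot(min_sigma > 0, num_sigma >= 2, sigma_ratio > 1,
            threshold >= 0, overlap >= 0, overlap <= 1,
            min_blobs >= 1, k_required >= 0, k_required <= 3)
  if (!is.null(max_sigma) && max_sigma <= min_sigma) {
    stop("`max_sigma` must exceed `min_sigma`")
  }
  structure(
    list(
      min_sigma = min_sigma, max_sigma = max_sigma, num_sigma = as.integer(num_sigma),
      sigma_ratio = sigma_ratio, threshold = threshold, overlap = overlap,
      min_blobs = as.integer(min_blobs), k_required = as.integer(k_required)
    ),
    class = "detector_config"
  )
}

blob_methods <- function() c("log", "dog", "doh")

# --- Gaussian kernels and separable convolution ------------------------------
#
# Smoothing and derivatives are sampled 1-D Gaussian kernels (radius 4 sigma)
# applied separably with symmetric (edge-repeating) boundary reflection. Each
# 1-D pass is a dense n x n convolution matrix; these are cached per
# (n, sigma) since one grid serves every edge of a run.

.kernel_cache <- new.env(parent = emptyenv())

# Sampled Gaussian and its first/second derivatives on -r..r, all normalized
# by the sum of the plain Gaussian so smoothing preserves a constant image.
gauss_kernels_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  t <- (-r):r
  g0 <- exp(-t^2 / (2 * sigma^2))
  z <- sum(g0)
  list(
    g = g0 / z,
    gx = (-t / sigma^2) * g0 / z,
    gxx = ((t^2 - sigma^2) / sigma^4) * g0 / z
  )
}

# Fold an out-of-range index into 1..n by symmetric reflection with edge
# repetition (... 2 1 | 1 2 ... n | n n-1 ...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j >= n, 2L * n - 1L - j, j) + 1L)
}

# Dense matrix realizing 1-D convolution with `kernel` under reflection; the
# convolution of column vectors of length n is M %*% x.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    src <- reflect_index(seq_len(n) + off, n)
    m[cbind(seq_len(n), src)] <- m[cbind(seq_len(n), src)] + kernel[k]
  }
  m
}

conv_matrices <- function(n, sigma) {
  key <- sprintf("%d_%.10g", n, sigma)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  ks <- gauss_kernels_1d(sigma)
  out <- list(
    g = conv_matrix(n, ks$g),
    gx = conv_matrix(n, ks$gx),
    gxx = conv_matrix(n, ks$gxx)
  )
  .kernel_cache[[key]] <- out
  out
}

# --- Scale-space responses ----------------------------------------------------
#
# All three responses are defined to be positive over bright blobs and are
# scale-normalized so that response magnitude is comparable across sigma:
#   LoG:  -sigma^2 * Laplacian(G_sigma * I)
#   DoG:  (G_sigma * I - G_{k sigma} * I) / (k - 1)   (approximates the LoG)
#   DoH:   sigma^4 * det(Hessian(G_sigma * I))

log_response <- function(image, sigma) {
  n <- nrow(image)
  m <- conv_matrices(n, sigma)
  d_rows <- m$gxx %*% image %*% t(m$g)
  d_cols <- m$g %*% image %*% t(m$gxx)
  -sigma^2 * (d_rows + d_cols)
}

doh_response <- function(image, sigma) {
  n <- nrow(image)
  m <- conv_matrices(n, sigma)
  h_rr <- m$gxx %*% image %*% t(m$g)
  h_cc <- m$g %*% image %*% t(m$gxx)
  h_rc <- m$gx %*% image %*% t(m$gx)
  sigma^4 * (h_rr * h_cc - h_rc * h_rc)
}

smooth_image <- function(image, sigma) {
  m <- conv_matrices(nrow(image), sigma)
  m$g %*% image %*% t(m$g)
}

# Scale samples per detector.
log_sigma_list <- function(cfg, n_bins) {
  max_sigma <- if (is.null(cfg$max_sigma)) n_bins / 4 else cfg$max_sigma
  if (max_sigma <= cfg$min_sigma) max_sigma <- cfg$min_sigma * 2
  seq(cfg$min_sigma, max_sigma, length.out = cfg$num_sigma)
}

dog_sigma_list <- function(cfg, n_bins) {
  max_sigma <- if (is.null(cfg$max_sigma)) n_bins / 4 else cfg$max_sigma
  if (max_sigma <= cfg$min_sigma) max_sigma <- cfg$min_sigma * 2
  k <- max(1L, as.integer(floor(log(max_sigma / cfg$min_sigma) / log(cfg$sigma_ratio))) + 1L)
  cfg$min_sigma * cfg$sigma_ratio^(0:k)
}

# --- Scale-space peak search --------------------------------------------------

shift_matrix <- function(m, dr, dc, fill = -Inf) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  rs <- seq_len(n1) - dr
  cs <- seq_len(n2) - dc
  ok_r <- rs >= 1 & rs <= n1
  ok_c <- cs >= 1 & cs <= n2
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Local maxima of a response stack over (row, col, sigma): a voxel is a
# candidate when its response exceeds `threshold` and is >= all of its (up to)
# 26 neighbors. Plateaus yield several candidates; overlap pruning with the
# deterministic tie-break collapses them.
stack_peaks <- function(stack, sigmas, threshold) {
  n_s <- length(stack)
  peaks <- vector("list", n_s)
  for (s in seq_len(n_s)) {
    cur <- stack[[s]]
    mask <- cur > threshold
    if (!any(mask)) next
    for (ds in (-1):1) {
      si <- s + ds
      if (si < 1 || si > n_s) next
      ref <- stack[[si]]
      for (dr in (-1):1) {
        for (dc in (-1):1) {
          if (ds == 0 && dr == 0 && dc == 0) next
          mask <- mask & (cur >= shift_matrix(ref, dr, dc))
          if (!any(mask)) break
        }
        if (!any(mask)) break
      }
      if (!any(mask)) break
    }
    if (any(mask)) {
      idx <- which(mask, arr.ind = TRUE)
      peaks[[s]] <- tibble::tibble(
        row = idx[, 1] - 1L, col = idx[, 2] - 1L,
        sigma = sigmas[s], response = cur[idx]
      )
    }
  }
  out <- dplyr::bind_rows(peaks)
  if (nrow(out) == 0) {
    out <- tibble::tibble(row = integer(), col = integer(),
                          sigma = numeric(), response = numeric())
  }
  out
}

# Fraction of the smaller disk covered by the intersection of two disks.
disk_overlap <- function(r1, c1, rad1, r2, c2, rad2) {
  d <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
  lo <- min(rad1, rad2); hi <- max(rad1, rad2)
  if (d >= rad1 + rad2) return(0)
  if (d <= hi - lo) return(1)
  # circular lens area
  a1 <- rad1^2 * acos(pmin(1, pmax(-1, (d^2 + rad1^2 - rad2^2) / (2 * d * rad1))))
  a2 <- rad2^2 * acos(pmin(1, pmax(-1, (d^2 + rad2^2 - rad1^2) / (2 * d * rad2))))
  a3 <- 0.5 * sqrt(max(0, (-d + rad1 + rad2) * (d + rad1 - rad2) *
                          (d - rad1 + rad2) * (d + rad1 + rad2)))
  (a1 + a2 - a3) / (pi * lo^2)
}

# Greedy pruning: strongest responses are kept first; ties broken by
# (row, col, sigma) order for determinism.
prune_overlaps <- function(cand, radius_factor, overlap) {
  if (nrow(cand) <= 1) return(cand)
  ord <- order(-cand$response, cand$row, cand$col, cand$sigma)
  cand <- cand[ord, ]
  rad <- radius_factor * cand$sigma
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- disk_overlap(cand$row[i], cand$col[i], rad[i],
                         cand$row[j], cand$col[j], rad[j])
      if (ov > overlap) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  cand[keep, ]
}

#' Detect expression subpopulations in an edge image
#'
#' Runs one of three scale-space blob detectors over a max-normalized edge
#' image and returns the surviving blobs. Bright, roughly circular regions of
#' the image — each a subpopulation ("mode") of samples with a distinct
#' bivariate expression regime — appear as local maxima of the detector's
#' response over position and scale:
#'
#' * `"log"` — maxima of the scale-normalized negative Laplacian of Gaussian;
#' * `"dog"` — maxima of normalized differences of successively
#'   Gaussian-smoothed images (geometric scale ladder), the classic LoG
#'   approximation;
#' * `"doh"` — maxima of the scale-normalized determinant of the Hessian of
#'   the smoothed image. Note DoH is insensitive to blobs much smaller than
#'   about 3 bins, which is one reason the edge rule asks for agreement of
#'   only 2 of the 3 detectors.
#'
#' Candidates below `cfg$threshold` are discarded, and of two blobs whose
#' disks (radius `sqrt(2) * sigma` for LoG/DoG, `sigma` for DoH) overlap by
#' more than `cfg$overlap`, only the stronger response is kept (equal
#' responses are broken by `(row, col, sigma)` order so output is
#' deterministic). Smoothing uses symmetric boundary reflection; blob centers
#' may lie on the image border.
#'
#' @param image Square numeric matrix of finite intensities, normally from
#'   [normalize_image()].
#' @param method One of `"log"`, `"dog"`, `"doh"`.
#' @param cfg A [detector_config()].
#' @return A tibble with columns `method`, `row`, `col` (blob center, 0-based
#'   bin units), `sigma` (scale, bins) and `response`, sorted by
#'   `(row, col, sigma)`.
#' @export
detect_blobs <- function(image, method = c("log", "dog", "doh"),
                         cfg = detector_config()) {
  method <- match.arg(method)
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    stop("`image` must be a square matrix")
  }
  if (!all(is.finite(image))) stop("`image` must be finite")
  n <- nrow(image)
  if (method %in% c("log", "doh")) {
    sigmas <- log_sigma_list(cfg, n)
    resp_fun <- if (method == "log") log_response else doh_response
    stack <- lapply(sigmas, function(s) resp_fun(image, s))
    blob_sigmas <- sigmas
  } else {
    ladder <- dog_sigma_list(cfg, n)
    smoothed <- lapply(ladder, function(s) smooth_image(image, s))
    stack <- lapply(seq_len(length(ladder) - 1L), function(i) {
      (smoothed[[i]] - smoothed[[i + 1L]]) / (cfg$sigma_ratio - 1)
    })
    blob_sigmas <- ladder[-length(ladder)]
  }
  cand <- stack_peaks(stack, blob_sigmas, cfg$threshold)
  radius_factor <- if (method == "doh") 1 else sqrt(2)
  kept <- prune_overlaps(cand, radius_factor, cfg$overlap)
  kept <- dplyr::arrange(kept, .data$row, .data$col, .data$sigma)
  dplyr::bind_cols(tibble::tibble(method = rep(method, nrow(kept))), kept)
}

#' @rdname detect_blobs
#' @return `detect_all_blobs()`: one tibble covering all three methods, with
#'   attribute `methods` recording which detectors ran.
#' @export
detect_all_blobs <- function(image, cfg = detector_config()) {
  out <- dplyr::bind_rows(lapply(blob_methods(), function(m) {
    detect_blobs(image, m, cfg)
  }))
  attr(out, "methods") <- blob_methods()
  out
}

#' Count detectors that report a multimodal image
#'
#' Tallies blobs per detector and counts how many detectors found at least
#' `min_blobs` subpopulations (after overlap pruning). All three detectors
#' must be represented — either via the `methods` attribute set by
#' [detect_all_blobs()] or by passing `methods` explicitly; a detector that
#' ran but found nothing counts as zero blobs.
#'
#' @param blobs Blob tibble as from [detect_all_blobs()].
#' @param min_blobs Blob count at which a detector's image counts as
#'   multimodal (default 2, i.e. "more than 1 subpopulation").
#' @param methods Character vector of detectors that were run.
#' @return List with `counts` (named integer vector over methods) and
#'   `n_methods_multimodal`.
#' @export
count_multimodal_methods <- function(blobs, min_blobs = 2L,
                                     methods = attr(blobs, "methods")) {
  if (is.null(methods)) methods <- unique(blobs$method)
  missing_m <- setdiff(blob_methods(), methods)
  if (length(missing_m) > 0) {
    stop("blob sets missing for method(s): ", paste(missing_m, collapse = ", "))
  }
  unknown <- setdiff(unique(blobs$method), blob_methods())
  if (length(unknown) > 0) {
    stop("unknown blob detection method(s): ", paste(unknown, collapse = ", "))
  }
  counts <- vapply(blob_methods(), function(m) sum(blobs$method == m), integer(1))
  list(
    counts = counts,
    n_methods_multimodal = as.integer(sum(counts >= min_blobs))
  )
}

#' Apply the multimodality inclusion rule
#'
#' A gene pair qualifies for the network only when at least `k_required` of
#' the three detectors each report multiple subpopulations — the default rule
#' being 2 or more blobs within at least 2 of the blob detection approaches.
#'
#' @param n_methods_multimodal Integer in 0..3.
#' @param k_required Detectors required (default 2).
#' @return Logical.
#' @export
passes_blob_criterion <- function(n_methods_multimodal, k_required = 2L) {
  stopifnot(all(n_methods_multimodal >= 0), all(n_methods_multimodal <= 3))
  n_methods_multimodal >= k_required
}
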