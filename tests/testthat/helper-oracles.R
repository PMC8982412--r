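# Independent oracles: literal formula evaluations and brute-force scans,
# deliberately written over different computational paths than the package
# (nested loops and dense 2-D kernels instead of contingency tables and
# separable convolution matrices).

# Term-by-term evaluation of the mutual-information double sum over modules.
oracle_mi <- function(u, v) {
  n <- length(u)
  mi <- 0
  for (ui in unique(u)) {
    for (vj in unique(v)) {
      nij <- sum(u == ui & v == vj)
      if (nij > 0) {
        mi <- mi + (nij / n) * log(n * nij / (sum(u == ui) * sum(v == vj)))
      }
    }
  }
  mi
}

oracle_entropy <- function(u) {
  n <- length(u)
  h <- 0
  for (ui in unique(u)) {
    p <- sum(u == ui) / n
    h <- h - p * log(p)
  }
  h
}

# --- Brute-force scale-space blob detection ----------------------------------

oracle_reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i else i <- 2 * n + 1 - i
  }
  i
}

# Direct 2-D convolution with a dense kernel under symmetric reflection.
oracle_conv2d <- function(img, k2d) {
  n <- nrow(img)
  r <- (nrow(k2d) - 1) %/% 2
  out <- matrix(0, n, n)
  offs <- (-r):r
  for (i in seq_len(n)) {
    ri <- vapply(i + offs, oracle_reflect1, numeric(1), n = n)
    for (j in seq_len(n)) {
      rj <- vapply(j + offs, oracle_reflect1, numeric(1), n = n)
      out[i, j] <- sum(k2d * img[ri, rj])
    }
  }
  out
}

oracle_g1 <- function(sigma) {
  r <- max(1, ceiling(4 * sigma))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  list(t = t, g = g, z = sum(g))
}

# Dense 2-D response kernels built from the continuous Gaussian formulas.
oracle_kernel <- function(sigma, kind) {
  k <- oracle_g1(sigma)
  g <- k$g / k$z
  gx <- (-k$t / sigma^2) * k$g / k$z
  gxx <- ((k$t^2 - sigma^2) / sigma^4) * k$g / k$z
  switch(kind,
    smooth = outer(g, g),
    log = -sigma^2 * (outer(gxx, g) + outer(g, gxx)),
    hrr = outer(gxx, g),
    hcc = outer(g, gxx),
    hrc = outer(gx, gx)
  )
}

oracle_response_stack <- function(image, method, cfg) {
  n <- nrow(image)
  max_sigma <- if (is.null(cfg$max_sigma)) n / 4 else cfg$max_sigma
  if (method %in% c("log", "doh")) {
    sigmas <- seq(cfg$min_sigma, max_sigma, length.out = cfg$num_sigma)
    stack <- lapply(sigmas, function(s) {
      if (method == "log") {
        oracle_conv2d(image, oracle_kernel(s, "log"))
      } else {
        hrr <- oracle_conv2d(image, oracle_kernel(s, "hrr"))
        hcc <- oracle_conv2d(image, oracle_kernel(s, "hcc"))
        hrc <- oracle_conv2d(image, oracle_kernel(s, "hrc"))
        s^4 * (hrr * hcc - hrc * hrc)
      }
    })
  } else {
    k <- max(1, floor(log(max_sigma / cfg$min_sigma) / log(cfg$sigma_ratio)) + 1)
    ladder <- cfg$min_sigma * cfg$sigma_ratio^(0:k)
    sm <- lapply(ladder, function(s) oracle_conv2d(image, oracle_kernel(s, "smooth")))
    stack <- lapply(seq_len(k), function(i) {
      (sm[[i]] - sm[[i + 1]]) / (cfg$sigma_ratio - 1)
    })
    sigmas <- ladder[seq_len(k)]
  }
  list(stack = stack, sigmas = sigmas)
}

# Exhaustive scan: every (row, col, sigma) voxel is compared against its up
# to 26 neighbors by explicit loops.
oracle_scan_peaks <- function(stack, sigmas, threshold) {
  n <- nrow(stack[[1]])
  n_s <- length(stack)
  hits <- list()
  for (s in seq_len(n_s)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        v <- stack[[s]][i, j]
        if (v <= threshold) next
        is_max <- TRUE
        for (ds in -1:1) {
          for (di in -1:1) {
            for (dj in -1:1) {
              if (ds == 0 && di == 0 && dj == 0) next
              ss <- s + ds; ii <- i + di; jj <- j + dj
              if (ss < 1 || ss > n_s || ii < 1 || ii > n || jj < 1 || jj > n) next
              if (stack[[ss]][ii, jj] > v) { is_max <- FALSE; break }
            }
            if (!is_max) break
          }
          if (!is_max) break
        }
        if (is_max) {
          hits[[length(hits) + 1]] <- data.frame(
            row = i - 1, col = j - 1, sigma = sigmas[s], response = v
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(row = numeric(), col = numeric(),
                      sigma = numeric(), response = numeric()))
  }
  do.call(rbind, hits)
}

oracle_disk_overlap <- function(r1, c1, rad1, r2, c2, rad2) {
  d <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
  if (d >= rad1 + rad2) return(0)
  if (d <= abs(rad1 - rad2)) return(1)
  a1 <- rad1^2 * acos(min(1, max(-1, (d^2 + rad1^2 - rad2^2) / (2 * d * rad1))))
  a2 <- rad2^2 * acos(min(1, max(-1, (d^2 + rad2^2 - rad1^2) / (2 * d * rad2))))
  a3 <- 0.5 * sqrt(max(0, (-d + rad1 + rad2) * (d + rad1 - rad2) *
                          (d - rad1 + rad2) * (d + rad1 + rad2)))
  (a1 + a2 - a3) / (pi * min(rad1, rad2)^2)
}

oracle_detect <- function(image, method, cfg) {
  rs <- oracle_response_stack(image, method, cfg)
  cand <- oracle_scan_peaks(rs$stack, rs$sigmas, cfg$threshold)
  fac <- if (method == "doh") 1 else sqrt(2)
  if (nrow(cand) > 1) {
    cand <- cand[order(-cand$response, cand$row, cand$col, cand$sigma), ]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ok <- TRUE
      for (j in which(keep)) {
        ov <- oracle_disk_overlap(cand$row[i], cand$col[i], fac * cand$sigma[i],
                                  cand$row[j], cand$col[j], fac * cand$sigma[j])
        if (ov > cfg$overlap) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    cand <- cand[keep, ]
  }
  cand[order(cand$row, cand$col, cand$sigma), , drop = FALSE]
}
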