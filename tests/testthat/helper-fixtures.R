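# Shared in-code fixtures.

# Image holding one isotropic Gaussian bump per row of `centers` (0-based
# coordinates), unit amplitude unless given.
make_bump_image <- function(n, centers, sigma, amplitude = NULL) {
  if (is.null(amplitude)) amplitude <- rep(1, nrow(centers))
  sigma <- rep_len(sigma, nrow(centers))
  rc <- expand.grid(row = 0:(n - 1), col = 0:(n - 1))
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    img <- img + amplitude[k] * matrix(
      exp(-((rc$row - centers[k, 1])^2 + (rc$col - centers[k, 2])^2) /
            (2 * sigma[k]^2)),
      n, n
    )
  }
  img
}

# Small deterministic GEM with named genes and samples.
make_toy_gem <- function(values, genes = NULL, samples = NULL) {
  g <- nrow(values)
  s <- ncol(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(g))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(s))
  dimnames(values) <- list(genes, samples)
  values
}

# Fast detector settings for pipeline-level tests (fewer scales).
fast_detector <- function(...) {
  detector_config(num_sigma = 6, ...)
}
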