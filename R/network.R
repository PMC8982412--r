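#' Enumerate candidate gene pairs
#'
#' Yields every unordered pair of genes exactly once, canonically
#' (lexicographically) ordered: G genes give `G * (G - 1) / 2` pairs. An
#' optional predicate filters genes by their expression profile before
#' pairing.
#'
#' @param gem GEM matrix (genes x samples) or a character vector of gene ids.
#' @param gene_filter Optional predicate `function(expr_row)` returning
#'   `TRUE` to keep a gene (only usable when `gem` is a matrix).
#' @return Tibble with columns `gene_a`, `gene_b`, sorted.
#' @export
enumerate_pairs <- function(gem, gene_filter = NULL) {
  genes <- if (is.matrix(gem)) rownames(gem) else as.character(gem)
  if (!is.null(gene_filter)) {
    if (!is.matrix(gem)) stop("`gene_filter` requires an expression matrix")
    keep <- vapply(genes, function(g) isTRUE(gene_filter(gem[g, ])), logical(1))
    genes <- genes[keep]
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (length(genes) < 2) stop("need at least 2 genes to enumerate pairs")
  genes <- sort(genes, method = "radix")
  idx <- utils::combn(length(genes), 2)
  tibble::tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]])
}

#' Prefilter genes by variance and expression prevalence
#'
#' Optional scale control for large matrices: drops genes whose expression
#' variance falls below `min_variance` or that exceed `expression_floor` in
#' fewer than `min_fraction` of samples. Both filters default to off so small
#' matrices run exhaustively.
#'
#' @param gem GEM matrix.
#' @param min_variance Minimum per-gene variance (missing values ignored).
#' @param min_fraction Minimum fraction of samples above `expression_floor`.
#' @param expression_floor Expression level a sample must exceed to count as
#'   expressing the gene.
#' @return The filtered GEM matrix.
#' @export
filter_genes <- function(gem, min_variance = 0, min_fraction = 0,
                         expression_floor = 0) {
  validate_gem(gem)
  v <- apply(gem, 1, stats::var, na.rm = TRUE)
  frac <- rowMeans(gem > expression_floor, na.rm = TRUE)
  keep <- frac >= min_fraction
  if (min_variance > 0) keep <- keep & !is.na(v) & v >= min_variance
  keep[is.na(keep)] <- FALSE
  gem[keep, , drop = FALSE]
}

#' Evaluate one candidate edge
#'
#' The per-pair unit of the pipeline: the pair is put into canonical
#' orientation, its pairwise-complete samples binned into an image on the
#' shared grid, the image max-normalized, all three blob detectors run, and
#' the pair scored with NMI over the same discretization. Because evaluation
#' always happens in canonical orientation, the result is a pure, symmetric
#' function of the unordered pair and the configuration — the orientation of
#' the input axes cannot influence edge selection.
#'
#' Pairs with fewer than `min_samples` pairwise-complete samples are not
#' scored; their record carries `skipped = TRUE` and a reason.
#'
#' @param gem GEM matrix.
#' @param gene_a,gene_b Gene identifiers (single pair).
#' @param grid A [bin_grid()]; defaults to the grid of the whole matrix at
#'   resolution 0.5.
#' @param detector A [detector_config()].
#' @param mi_threshold Minimum NMI for the pair to pass (default 0.97).
#' @param min_samples Minimum pairwise-complete samples (default 30).
#' @param mi_mode,nmi_norm,min_blob_samples Scoring options, see
#'   [edge_nmi()]. In `per_blob` mode the LoG blob set provides the modes.
#' @param log_compress Intensity compression before detection, see
#'   [normalize_image()].
#' @return One-row tibble: `gene_a`, `gene_b`, `nmi`, `blobs_log`,
#'   `blobs_dog`, `blobs_doh`, `n_methods_multimodal`, `passed_blob`,
#'   `passed_mi`, `n_samples_used`, `skipped`, `skip_reason`.
#' @export
evaluate_edge <- function(gem, gene_a, gene_b, grid = NULL,
                          detector = detector_config(),
                          mi_threshold = 0.97, min_samples = 30L,
                          mi_mode = "all_samples", nmi_norm = "arithmetic",
                          min_blob_samples = 10L, log_compress = FALSE) {
  stopifnot(length(gene_a) == 1, length(gene_b) == 1)
  if (!all(c(gene_a, gene_b) %in% rownames(gem))) {
    stop("gene(s) not present in the GEM: ",
         paste(setdiff(c(gene_a, gene_b), rownames(gem)), collapse = ", "))
  }
  cp <- canonical_pair(gene_a, gene_b)
  if (is.null(grid)) grid <- bin_grid_from_gem(gem)
  expr_a <- gem[cp$gene_a, ]
  expr_b <- gem[cp$gene_b, ]

  rec <- tibble::tibble(
    gene_a = cp$gene_a, gene_b = cp$gene_b, nmi = NA_real_,
    blobs_log = NA_integer_, blobs_dog = NA_integer_, blobs_doh = NA_integer_,
    n_methods_multimodal = NA_integer_, passed_blob = FALSE, passed_mi = FALSE,
    n_samples_used = 0L, skipped = TRUE, skip_reason = NA_character_
  )

  complete <- !is.na(bin_value(expr_a, grid)) & !is.na(bin_value(expr_b, grid))
  if (sum(complete) < min_samples) {
    rec$skip_reason <- sprintf("only %d pairwise-complete samples (< %d)",
                               sum(complete), min_samples)
    return(rec)
  }

  img <- bin_edge(expr_a, expr_b, grid)
  norm <- normalize_image(img, log_compress = log_compress)
  blobs <- detect_all_blobs(norm, detector)
  mm <- count_multimodal_methods(blobs, min_blobs = detector$min_blobs)
  nmi <- edge_nmi(
    expr_a, expr_b, grid, mode = mi_mode,
    blobs = blobs[blobs$method == "log", , drop = FALSE],
    norm = nmi_norm, min_blob_samples = min_blob_samples
  )

  rec$nmi <- nmi
  rec$blobs_log <- mm$counts[["log"]]
  rec$blobs_dog <- mm$counts[["dog"]]
  rec$blobs_doh <- mm$counts[["doh"]]
  rec$n_methods_multimodal <- mm$n_methods_multimodal
  rec$passed_blob <- passes_blob_criterion(mm$n_methods_multimodal, detector$k_required)
  rec$passed_mi <- nmi >= mi_threshold
  rec$n_samples_used <- img$n_samples_used
  rec$skipped <- FALSE
  rec
}

#' Assemble the network from evaluated edge records
#'
#' Keeps the records that satisfy both printed criteria — the blob rule
#' (`passed_blob`) and the score threshold (`passed_mi`) — and collects the
#' incident genes as nodes. Records must be canonical and unique; skipped
#' records are excluded from the edge set but tallied.
#'
#' @param records Tibble of [evaluate_edge()] rows.
#' @param grid,config Optional metadata stored on the network object.
#' @return An `ec_network`: list with `edges` (passing records), `nodes`,
#'   `records` (all records), `grid`, `config`.
#' @export
build_network <- function(records, grid = NULL, config = list()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0) {
    cp <- canonical_pair(records$gene_a, records$gene_b)
    if (!identical(cp$gene_a, records$gene_a) || !identical(cp$gene_b, records$gene_b)) {
      stop("records must be canonically ordered")
    }
    if (anyDuplicated(paste(records$gene_a, records$gene_b, sep = "\r"))) {
      stop("duplicate gene pair in records")
    }
  }
  records <- dplyr::arrange(records, .data$gene_a, .data$gene_b)
  passing <- dplyr::filter(records, !.data$skipped, .data$passed_blob, .data$passed_mi)
  structure(
    list(
      edges = passing,
      nodes = sort(unique(c(passing$gene_a, passing$gene_b)), method = "radix"),
      records = records,
      grid = grid,
      config = config
    ),
    class = "ec_network"
  )
}

#' @export
print.ec_network <- function(x, ...) {
  n_eval <- sum(!x$records$skipped)
  cat(sprintf(
    "<ec_network> %d edge(s) over %d gene(s); %d pair(s) evaluated, %d skipped\n",
    nrow(x$edges), length(x$nodes), n_eval, sum(x$records$skipped)
  ))
  invisible(x)
}

#' Construct a gene relationship network from a GEM
#'
#' The end-to-end pipeline: build the shared bin grid from the matrix's
#' global maximum, enumerate every unordered gene pair, evaluate each pair
#' (binning, three-detector blob counting, NMI scoring) and keep the pairs in
#' which at least `k_required` detectors find `min_blobs` or more
#' subpopulations and whose NMI reaches `mi_threshold`. The result is
#' deterministic and independent of evaluation order and worker count.
#'
#' @param gem GEM matrix, e.g. from [read_gem()] or [generate_gem()].
#' @param resolution Bin width in expression units (default 0.5); ignored if
#'   `grid` is given.
#' @param grid Optional pre-built [bin_grid()] (reusable across matrices).
#' @param detector A [detector_config()]; `min_blobs`/`k_required` live here.
#' @param mi_threshold Edge inclusion threshold on NMI (default 0.97).
#' @param min_samples Minimum pairwise-complete samples per pair.
#' @param mi_mode,nmi_norm,min_blob_samples,log_compress See
#'   [evaluate_edge()].
#' @param gene_filter Optional predicate on expression rows, see
#'   [enumerate_pairs()].
#' @param flip_axes Present the pairs in reversed axis orientation. Because
#'   evaluation canonicalizes each pair first, the output is identical either
#'   way; the flag exists to demonstrate exactly that (see
#'   [verify_orientation_invariance()]).
#' @param threads Workers for pair evaluation (forked; results are
#'   independent of `threads`).
#' @return An `ec_network` (see [build_network()]).
#' @examples
#' sim <- generate_gem(planted_gem_spec(2, 2, 2, n_genes = 12,
#'                                      groups = c(a = 40, b = 40), seed = 7))
#' net <- craft_network(sim$gem, mi_threshold = 0.2)
#' glance(net)
#' @export
craft_network <- function(gem, resolution = 0.5, grid = NULL,
                          detector = detector_config(),
                          mi_threshold = 0.97, min_samples = 30L,
                          mi_mode = "all_samples", nmi_norm = "arithmetic",
                          min_blob_samples = 10L, log_compress = FALSE,
                          gene_filter = NULL, flip_axes = FALSE, threads = 1L) {
  validate_gem(gem)
  stopifnot(mi_threshold >= 0, mi_threshold <= 1)
  if (is.null(grid)) grid <- bin_grid_from_gem(gem, resolution)
  pairs <- enumerate_pairs(gem, gene_filter)
  if (flip_axes) pairs <- pairs[c("gene_b", "gene_a")] # undone by canonicalization

  eval_one <- function(i) {
    evaluate_edge(
      gem, pairs[[1]][i], pairs[[2]][i], grid = grid, detector = detector,
      mi_threshold = mi_threshold, min_samples = min_samples,
      mi_mode = mi_mode, nmi_norm = nmi_norm,
      min_blob_samples = min_blob_samples, log_compress = log_compress
    )
  }
  idx <- seq_len(nrow(pairs))
  records <- if (threads > 1L && .Platform$OS.type == "unix") {
    dplyr::bind_rows(parallel::mclapply(idx, eval_one, mc.cores = threads))
  } else {
    dplyr::bind_rows(lapply(idx, eval_one))
  }

  config <- list(
    resolution = grid$resolution, detector = detector,
    mi_threshold = mi_threshold, min_samples = min_samples,
    mi_mode = mi_mode, nmi_norm = nmi_norm,
    min_blob_samples = min_blob_samples, log_compress = log_compress,
    flip_axes = flip_axes
  )
  build_network(records, grid = grid, config = config)
}

#' Compare two networks record by record
#'
#' Two runs are considered identical when they evaluated the same canonical
#' pairs and agree on every pass flag, blob count, and NMI (to `tolerance`).
#'
#' @param net1,net2 `ec_network` objects.
#' @param tolerance Absolute NMI tolerance.
#' @return Logical.
#' @export
compare_networks <- function(net1, net2, tolerance = 1e-9) {
  r1 <- dplyr::arrange(net1$records, .data$gene_a, .data$gene_b)
  r2 <- dplyr::arrange(net2$records, .data$gene_a, .data$gene_b)
  if (nrow(r1) != nrow(r2)) return(FALSE)
  same_ids <- identical(r1$gene_a, r2$gene_a) && identical(r1$gene_b, r2$gene_b)
  if (!same_ids) return(FALSE)
  flags <- c("blobs_log", "blobs_dog", "blobs_doh", "n_methods_multimodal",
             "passed_blob", "passed_mi", "skipped")
  for (f in flags) {
    if (!identical(r1[[f]], r2[[f]])) return(FALSE)
  }
  nmi_ok <- (is.na(r1$nmi) & is.na(r2$nmi)) |
    (!is.na(r1$nmi) & !is.na(r2$nmi) & abs(r1$nmi - r2$nmi) <= tolerance)
  all(nmi_ok)
}

#' Confirm that axis orientation does not affect edge selection
#'
#' Re-runs the validation experiment of the method: the pipeline is executed
#' twice on the same matrix, the second time with the x/y axes of every gene
#' pair flipped, and the two runs' edge records (canonical pairs, pass flags,
#' blob counts, NMIs to `tolerance`) are compared.
#'
#' @param gem GEM matrix.
#' @param ... Passed to [craft_network()] (must not include `flip_axes`).
#' @param tolerance Absolute NMI tolerance for the comparison.
#' @return `TRUE` when the two runs select identical edges.
#' @export
verify_orientation_invariance <- function(gem, ..., tolerance = 1e-9) {
  normal <- craft_network(gem, ..., flip_axes = FALSE)
  flipped <- craft_network(gem, ..., flip_axes = TRUE)
  compare_networks(normal, flipped, tolerance = tolerance)
}
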