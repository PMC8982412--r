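#' Read a gene expression matrix from TSV
#'
#' Expects the plain exchange format used for unified bulk RNA-seq
#' compendia: a tab-separated table whose header row holds sample identifiers
#' and whose first column holds gene identifiers, with every other cell a
#' non-negative expression value (e.g. log-scale FPKM) or an NA token.
#' Negative values are rejected — the whole pipeline assumes a minimum
#' expression of zero. Missing values are allowed and handled per edge by
#' pairwise deletion.
#'
#' @param path Path to a tab-separated file.
#' @param na Strings interpreted as missing values.
#' @return A numeric matrix (genes x samples) with gene identifiers as
#'   rownames and sample identifiers as colnames.
#' @export
read_gem <- function(path, na = c("", "NA", "NaN")) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = na, progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed GEM file '%s': %d parsing problem(s), e.g. row %d: %s",
                 path, nrow(probs), probs$row[1], probs$expected[1]))
  }
  if (ncol(raw) < 2) stop("GEM must have a gene-id column and at least one sample column")
  gene_ids <- raw[[1]]
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers in GEM: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in GEM header")
  }
  vals <- suppressWarnings(vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(sample_ids))
  bad <- is.na(vals) & !is.na(as.matrix(raw[-1]))
  if (any(bad)) {
    stop(sprintf("non-numeric expression value(s) in GEM, first at gene '%s'",
                 gene_ids[which(rowSums(bad) > 0)[1]]))
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  validate_gem(vals)
}

#' Validate a gene expression matrix
#'
#' Checks the container invariants: a numeric matrix with unique, non-empty
#' gene rownames and sample colnames, and no negative value (only positive
#' expression levels are considered; missing values are allowed).
#'
#' @param gem Numeric matrix, genes in rows, samples in columns.
#' @return The matrix, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_gem <- function(gem) {
  if (!is.matrix(gem) || !is.numeric(gem)) stop("GEM must be a numeric matrix")
  if (is.null(rownames(gem)) || is.null(colnames(gem))) {
    stop("GEM must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(gem))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(gem))) stop("duplicate sample identifiers")
  if (any(gem < 0, na.rm = TRUE)) {
    stop("negative expression value(s) found; only positive expression levels are considered")
  }
  gem
}

#' Write a gene expression matrix to TSV
#'
#' Inverse of [read_gem()]: header row of sample identifiers, first column
#' `gene_id`, tab-separated. Reading the file back yields an identical matrix.
#'
#' @param gem Validated GEM matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(gem, path) {
  validate_gem(gem)
  df <- tibble::as_tibble(gem, rownames = "gene_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a sample phenotype label table
#'
#' Two tab-separated columns, `sample_id` and `group`, with an optional
#' header. Labels are used only for diagnostics and synthetic-data
#' generation — the network construction itself never sees them. Exact
#' duplicate rows are collapsed; the same sample listed with two different
#' groups is an error.
#'
#' @param path Path to a two-column TSV.
#' @param header `"auto"` (default) sniffs for a header line whose fields look
#'   like column names; `"yes"`/`"no"` force the interpretation.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_labels <- function(path, header = c("auto", "yes", "no")) {
  header <- match.arg(header)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty label file: ", path)
    return(tibble::tibble(sample_id = character(), group = character()))
  }
  first <- tolower(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  looks_header <- length(first) >= 2 &&
    (first[1] %in% c("sample", "sample_id", "id") ||
       first[2] %in% c("group", "label", "phenotype", "condition"))
  drop_first <- switch(header, auto = looks_header, yes = TRUE, no = FALSE)
  if (drop_first) lines <- lines[-1]
  if (length(lines) == 0) {
    warning("label file has a header but no rows: ", path)
    return(tibble::tibble(sample_id = character(), group = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("label file rows must have two tab-separated fields (sample_id, group)")
  }
  out <- tibble::tibble(
    sample_id = vapply(parts, `[[`, character(1), 1),
    group = vapply(parts, `[[`, character(1), 2)
  )
  out <- dplyr::distinct(out)
  if (anyDuplicated(out$sample_id)) {
    dup <- unique(out$sample_id[duplicated(out$sample_id)])
    stop("sample(s) labeled with conflicting groups: ", paste(dup, collapse = ", "))
  }
  out
}

#' @rdname read_labels
#' @param labels Tibble with columns `sample_id` and `group`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("sample_id", "group") %in% names(labels)))
  readr::write_tsv(labels[c("sample_id", "group")], path, progress = FALSE)
  invisible(path)
}

#' Canonically order a gene pair
#'
#' Every unordered gene pair is evaluated exactly once, under the canonical
#' (lexicographically sorted) orientation — this is what detaches axis
#' orientation from edge selection. Comparison uses C-locale (radix) ordering
#' so results do not depend on the session locale. Vectorized; self-pairs are
#' an error because self-edges are excluded from the network.
#'
#' @param gene_a,gene_b Character vectors of gene identifiers (recycled to a
#'   common length).
#' @return A tibble with columns `gene_a` and `gene_b`, `gene_a <= gene_b`
#'   lexicographically in every row.
#' @examples
#' canonical_pair("XAF1", "NDUFA4L2")
#' @export
canonical_pair <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  n <- max(length(gene_a), length(gene_b))
  gene_a <- rep_len(gene_a, n)
  gene_b <- rep_len(gene_b, n)
  if (any(gene_a == gene_b)) {
    stop("self-pairs are not allowed (self-edges are excluded): ",
         paste(unique(gene_a[gene_a == gene_b]), collapse = ", "))
  }
  lev <- sort(unique(c(gene_a, gene_b)), method = "radix")
  swap <- match(gene_a, lev) > match(gene_b, lev)
  first <- ifelse(swap, gene_b, gene_a)
  second <- ifelse(swap, gene_a, gene_b)
  tibble::tibble(gene_a = first, gene_b = second)
}

# Network edge-list columns, in output order.
network_columns <- function() {
  c("gene_a", "gene_b", "nmi", "blobs_log", "blobs_dog", "blobs_doh",
    "n_passing_methods")
}

#' Write a gene relationship network
#'
#' Writes the passing edges either as a TSV edge list with fixed columns
#' (`gene_a`, `gene_b`, `nmi`, `blobs_log`, `blobs_dog`, `blobs_doh`,
#' `n_passing_methods`), rows sorted by `(gene_a, gene_b)`, or as GraphML
#' with the same quantities as edge attributes. An empty network yields a
#' header-only TSV.
#'
#' @param network An `ec_network` from [craft_network()] /
#'   [build_network()], or an edge tibble with the columns above (where
#'   `n_passing_methods` may be named `n_methods_multimodal`).
#' @param path Output path.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  edges <- if (inherits(network, "ec_network")) network$edges else tibble::as_tibble(network)
  if ("n_methods_multimodal" %in% names(edges) && !"n_passing_methods" %in% names(edges)) {
    edges <- dplyr::rename(edges, n_passing_methods = "n_methods_multimodal")
  }
  missing_cols <- setdiff(network_columns(), names(edges))
  if (length(missing_cols) > 0) {
    stop("edge table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges <- edges[network_columns()]
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  if (format == "edge_list_tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_a = readr::col_character(),
      gene_b = readr::col_character(),
      nmi = readr::col_double(),
      blobs_log = readr::col_integer(),
      blobs_dog = readr::col_integer(),
      blobs_doh = readr::col_integer(),
      n_passing_methods = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
}
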