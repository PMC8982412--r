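#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the edges of a gene relationship network
#'
#' @param x An `ec_network` from [craft_network()].
#' @param all Return every evaluated record instead of only the passing
#'   edges.
#' @param ... Unused.
#' @return A tibble, one row per edge (or per evaluated pair with
#'   `all = TRUE`).
#' @method tidy ec_network
#' @export
tidy.ec_network <- function(x, all = FALSE, ...) {
  if (all) x$records else x$edges
}

#' One-row summary of a network run
#'
#' @param x An `ec_network`.
#' @param ... Unused.
#' @return A tibble with pair counts, pass counts, grid and threshold
#'   settings.
#' @method glance ec_network
#' @export
glance.ec_network <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$records),
    n_evaluated = sum(!x$records$skipped),
    n_skipped = sum(x$records$skipped),
    n_passed_blob = sum(x$records$passed_blob, na.rm = TRUE),
    n_passed_mi = sum(x$records$passed_mi, na.rm = TRUE),
    n_edges = nrow(x$edges),
    n_nodes = length(x$nodes),
    n_bins = if (!is.null(x$grid)) x$grid$n_bins else NA_integer_,
    resolution = if (!is.null(x$grid)) x$grid$resolution else NA_real_,
    mi_threshold = x$config$mi_threshold %||% NA_real_
  )
}
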