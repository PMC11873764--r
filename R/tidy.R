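#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a connectome into a long edge table
#'
#' @param x A `connectome` matrix.
#' @param ... Unused.
#' @return A tibble: `region_1`, `region_2`, `accordance`.
#' @method tidy connectome
#' @export
tidy.connectome <- function(x, ...) connectome_edges(x)

#' One-row summary of a connectome
#'
#' @param x A `connectome` matrix.
#' @param ... Unused.
#' @return A tibble: `n_networks`, `n_edges`, `n_undefined`,
#'   `mean_accordance`, `min_accordance`, `max_accordance`.
#' @method glance connectome
#' @export
glance.connectome <- function(x, ...) {
  e <- connectome_edges(x)$accordance
  tibble::tibble(n_networks = ncol(x), n_edges = length(e),
                 n_undefined = sum(is.na(e)),
                 mean_accordance = mean(e, na.rm = TRUE),
                 min_accordance = min(e, na.rm = TRUE),
                 max_accordance = max(e, na.rm = TRUE))
}

#' Tidy an edge-stats table
#'
#' @param x An `edge_stats` object from [paired_edge_ttest()].
#' @param ... Unused.
#' @return The underlying tibble (class attributes stripped).
#' @method tidy edge_stats
#' @export
tidy.edge_stats <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of an edge-stats table
#'
#' @param x An `edge_stats` object.
#' @param ... Unused.
#' @return A tibble: `n_edges`, `n_coi`, `alpha`, `m`, `sides`,
#'   `n_edges_dropped`.
#' @method glance edge_stats
#' @export
glance.edge_stats <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x), n_coi = sum(x$in_coi),
                 alpha = attr(x, "alpha"), m = attr(x, "m"),
                 sides = attr(x, "sides"),
                 n_edges_dropped = attr(x, "n_edges_dropped"))
}

#' Tidy a group-difference table
#'
#' @param x A `group_diff` object from [music_effect_test()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy group_diff
#' @export
tidy.group_diff <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of a group-difference table
#'
#' @param x A `group_diff` object.
#' @param ... Unused.
#' @return A tibble: `n_edges`, `n_significant`, `z_threshold`,
#'   `max_z_diff`.
#' @method glance group_diff
#' @export
glance.group_diff <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x), n_significant = sum(x$significant),
                 z_threshold = attr(x, "z_threshold"),
                 max_z_diff = max(x$z_diff))
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("edge_stats", "group_diff"))
  x
}
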