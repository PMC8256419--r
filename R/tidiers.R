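#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a function ranking
#'
#' @param x A `rwhn_ranking`.
#' @param retained_only Keep only retained rows.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.rwhn_ranking <- function(x, retained_only = FALSE, ...) {
  out <- tibble::as_tibble(unclass(x)[names(x)])
  if (retained_only) out <- out[out$retained, ]
  out
}

#' @rdname tidy.rwhn_ranking
#' @export
glance.rwhn_ranking <- function(x, ...) {
  tibble::tibble(
    n_clusters = dplyr::n_distinct(x$seed_cluster),
    n_terms = dplyr::n_distinct(x$term_id),
    n_constant_rank = dplyr::n_distinct(x$term_id[x$constant_rank]),
    n_retained = sum(x$retained))
}

#' Tidy a permutation test
#'
#' @param x A `rwhn_permtest`.
#' @param ... Unused.
#' @return A plain tibble of per-term statistics.
#' @export
tidy.rwhn_permtest <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.rwhn_permtest
#' @export
glance.rwhn_permtest <- function(x, ...) {
  tibble::tibble(
    n_perm = attr(x, "n_perm"),
    n_terms = dplyr::n_distinct(x$term_id),
    n_significant = sum(x$p_adjusted < 0.05))
}

#' Tidy a multilayer network into an edge table
#'
#' @param x A `multilayer_net`.
#' @param ... Unused.
#' @return Tibble `from`, `to`, `block` with one row per undirected edge.
#' @export
tidy.multilayer_net <- function(x, ...) {
  block_edges <- function(a, block, directed_pair = FALSE) {
    s <- Matrix::summary(methods::as(a, "TsparseMatrix"))
    if (!nrow(s)) return(NULL)
    keep <- if (directed_pair) rep(TRUE, nrow(s)) else s$i < s$j
    s <- s[keep, , drop = FALSE]
    tibble::tibble(from = rownames(a)[s$i], to = colnames(a)[s$j],
                   block = block)
  }
  dplyr::bind_rows(
    block_edges(x$a_rr, "site-site"),
    block_edges(x$a_pp, "protein-protein"),
    block_edges(x$a_ff, "function-function"),
    block_edges(x$a_rp, "site-protein", directed_pair = TRUE),
    block_edges(x$a_pf, "protein-function", directed_pair = TRUE))
}

#' @rdname tidy.multilayer_net
#' @export
glance.multilayer_net <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$sites), n_proteins = length(x$proteins),
    n_functions = length(x$functions),
    site_site_edges = Matrix::nnzero(x$a_rr) / 2,
    protein_protein_edges = Matrix::nnzero(x$a_pp) / 2,
    function_function_edges = Matrix::nnzero(x$a_ff) / 2,
    site_protein_edges = Matrix::nnzero(x$a_rp),
    protein_function_edges = Matrix::nnzero(x$a_pf))
}

#' Tidy a cluster assignment
#'
#' @param x A `site_clusters`.
#' @param ... Unused.
#' @return Tibble `site_id`, `protein`, `cluster` (plus `membership` of the
#'   hard label in fuzzy mode).
#' @export
tidy.site_clusters <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x)[names(x)])
  memb <- attr(x, "memberships")
  if (!is.null(memb)) {
    out$membership <- memb[cbind(seq_len(nrow(out)), out$cluster)]
  }
  out
}
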