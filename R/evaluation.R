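#' Permute a multilayer network for the significance null
#'
#' Shuffles node labels independently within each intra-layer subnetwork
#' (sites, proteins, functions) while keeping both bipartite blocks fixed.
#' Each entity thus inherits the intra-layer connectivity of a random peer:
#' layer sizes and intra-layer degree multisets are preserved exactly, but
#' the routing from seeds to function terms is randomized, which is the null
#' of interest for rank significance.
#'
#' @param net A `multilayer_net`.
#' @param seed Integer seed.
#' @return A permuted `multilayer_net` over the same node lists.
#' @export
permute_multilayer <- function(net, seed = 1L) {
  set.seed(as.integer(seed))
  shuffle <- function(a) {
    perm <- sample(nrow(a))
    a[perm, perm, drop = FALSE]
  }
  a_rr <- shuffle(net$a_rr); a_pp <- shuffle(net$a_pp); a_ff <- shuffle(net$a_ff)
  # restore original dimnames: the labels stay put, the connectivity moves
  dimnames(a_rr) <- dimnames(net$a_rr)
  dimnames(a_pp) <- dimnames(net$a_pp)
  dimnames(a_ff) <- dimnames(net$a_ff)
  new_multilayer_net(sites = net$sites, proteins = net$proteins,
                     functions = net$functions,
                     a_rr = a_rr, a_pp = a_pp, a_ff = a_ff,
                     a_rp = net$a_rp, a_pf = net$a_pf,
                     term_names = net$term_names, modules = net$modules,
                     enrichment = net$enrichment)
}

#' Permutation significance of term ranks
#'
#' Runs the walk on `n_perm` label-permuted networks (default 100) and
#' compares each term's observed rank, per seed cluster, against its null
#' ranks. The primary statistic is the add-one empirical p-value
#' `(1 + #[null rank <= observed rank]) / (n_perm + 1)` (small when the term
#' ranks better than its permutation null), Benjamini-Hochberg adjusted
#' across terms within each cluster. When a term has observed ranks in two
#' or more clusters, a Mann-Whitney U comparison of the observed rank sample
#' against the pooled null ranks is additionally reported. A Gaussian kernel
#' density estimate of the null ranks (Silverman bandwidth) is attached for
#' plotting.
#'
#' @param net A `multilayer_net`.
#' @param clusters `site_clusters` used for seeding.
#' @param params [rwhn_params()] bundle.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; permutation i uses `seed + i`.
#' @return A `rwhn_permtest` tibble: `seed_cluster`, `term_id`,
#'   `observed_rank`, `p_empirical`, `p_adjusted`, `p_mwu`, `p_mwu_adjusted`,
#'   with the null rank matrix and densities as attributes.
#' @export
permutation_significance <- function(net, clusters, params = rwhn_params(),
                                     n_perm = 100, seed = 1L) {
  if (n_perm < 1) rwhn_abort("bad_perm_count", "n_perm must be >= 1")
  observed <- run_rwhn(net, clusters, params)
  obs <- observed[, c("seed_cluster", "term_id", "rank")]
  null_ranks <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    pnet <- permute_multilayer(net, seed = as.integer(seed) + i)
    res <- run_rwhn(pnet, clusters, params)
    null_ranks[[i]] <- tibble::tibble(perm = i,
                                      seed_cluster = res$seed_cluster,
                                      term_id = res$term_id,
                                      rank = res$rank)
  }
  nulls <- dplyr::bind_rows(null_ranks)

  key <- paste(nulls$seed_cluster, nulls$term_id)
  null_by_key <- split(nulls$rank, key)
  obs$p_empirical <- vapply(seq_len(nrow(obs)), function(i) {
    nr <- null_by_key[[paste(obs$seed_cluster[i], obs$term_id[i])]]
    (1 + sum(nr <= obs$rank[i])) / (n_perm + 1)
  }, 1.0)
  obs <- dplyr::mutate(dplyr::group_by(obs, .data$seed_cluster),
                       p_adjusted = stats::p.adjust(.data$p_empirical, "BH"))
  obs <- dplyr::ungroup(obs)

  # MWU variant: observed ranks across clusters vs pooled null ranks per term
  n_clusters <- dplyr::n_distinct(obs$seed_cluster)
  mwu <- tibble::tibble(term_id = unique(obs$term_id), p_mwu = NA_real_)
  if (n_clusters >= 2) {
    mwu$p_mwu <- vapply(mwu$term_id, function(t) {
      o <- obs$rank[obs$term_id == t]
      nr <- nulls$rank[nulls$term_id == t]
      if (length(o) < 2 || !length(nr)) return(NA_real_)
      suppressWarnings(stats::wilcox.test(o, nr)$p.value)
    }, 1.0)
    mwu$p_mwu_adjusted <- stats::p.adjust(mwu$p_mwu, "BH")
  } else {
    mwu$p_mwu_adjusted <- NA_real_
  }
  out <- dplyr::left_join(
    dplyr::rename(obs, observed_rank = "rank"), mwu, by = "term_id")

  dens <- lapply(split(nulls$rank, nulls$seed_cluster), function(r) {
    if (length(unique(r)) < 2) NULL else stats::density(r, bw = "nrd0")
  })
  structure(out,
            null_ranks = nulls, densities = dens, n_perm = n_perm,
            class = c("rwhn_permtest", class(tibble::tibble())))
}

#' @export
print.rwhn_permtest <- function(x, ...) {
  cat("# Permutation test: ", attr(x, "n_perm"), " permutations, ",
      dplyr::n_distinct(x$term_id), " terms, ",
      sum(x$p_adjusted < 0.05), " rows with adjusted p < 0.05\n", sep = "")
  NextMethod()
}

#' Over-representation analysis baseline
#'
#' Standard gene-centric ORA: the proteins of one regulation cluster are
#' tested for enrichment of every library term with an upper-tail
#' hypergeometric test against the universe, Benjamini-Hochberg adjusted
#' across all tested terms, keeping `q < alpha`.
#'
#' @param cluster_proteins Non-empty character vector of proteins.
#' @param lib Annotation library tibble.
#' @param universe Character vector of universe genes.
#' @param alpha FDR cutoff (default 0.05).
#' @return Tibble `term`, `name`, `overlap`, `size`, `p`, `q`, sorted by `p`,
#'   filtered to `q < alpha`.
#' @export
ora <- function(cluster_proteins, lib, universe, alpha = 0.05) {
  cluster_proteins <- unique(cluster_proteins)
  if (!length(cluster_proteins)) rwhn_abort("empty_cluster", "empty protein set")
  universe <- unique(universe)
  if (!length(universe)) rwhn_abort("empty_universe", "empty gene universe")
  members <- intersect(cluster_proteins, universe)
  gs <- lapply(gene_sets(lib), intersect, universe)
  rows <- purrr::imap(gs, function(set, term) {
    k <- length(intersect(set, members))
    if (k == 0) return(NULL)
    tibble::tibble(term = term, overlap = k, size = length(set),
                   p = stats::phyper(k - 1, length(set),
                                     length(universe) - length(set),
                                     length(members), lower.tail = FALSE))
  })
  tab <- dplyr::bind_rows(rows)
  if (!nrow(tab)) {
    return(tibble::tibble(term = character(), name = character(),
                          overlap = integer(), size = integer(),
                          p = numeric(), q = numeric()))
  }
  tab$q <- stats::p.adjust(tab$p, "BH")
  tab$name <- lib$name[match(tab$term, lib$term)]
  tab <- tab[tab$q < alpha, c("term", "name", "overlap", "size", "p", "q")]
  dplyr::arrange(tab, .data$p)
}

#' Weighted Kendall tau between two rankings
#'
#' Top-weighted rank correlation: each item pair contributes its
#' concordance sign weighted by the additive hyperbolic weight
#' `1/(1 + rank_i) + 1/(1 + rank_j)`, so exchanges near the top of the list
#' matter more than exchanges in the tail. The statistic is symmetrized by
#' averaging the values computed with weights taken from each ranking in
#' turn.
#'
#' @param rank_a,rank_b Named numeric vectors of ranks (1 = best) over the
#'   same item set.
#' @return Correlation in \[-1, 1\]; 1 for identical rankings.
#' @export
weighted_tau <- function(rank_a, rank_b) {
  if (is.null(names(rank_a)) || is.null(names(rank_b)) ||
      !setequal(names(rank_a), names(rank_b)) ||
      length(rank_a) != length(rank_b)) {
    rwhn_abort("item_mismatch", "rankings must cover the same item set")
  }
  b <- rank_b[names(rank_a)]
  a <- rank_a
  one_sided <- function(w_rank) {
    n <- length(a)
    da <- outer(a, a, "-"); db <- outer(b, b, "-")
    sgn <- sign(da) * sign(db)
    w <- outer(1 / (1 + w_rank), 1 / (1 + w_rank), "+")
    up <- upper.tri(sgn)
    sum(w[up] * sgn[up]) / sum(w[up])
  }
  (one_sided(a) + one_sided(b)) / 2
}

#' Ranks of one cluster's terms as a named vector
#'
#' Convenience accessor for comparing rankings with [weighted_tau()].
#'
#' @param ranking A `rwhn_ranking`.
#' @param cluster Seed-cluster id (default: first).
#' @return Named integer vector of ranks keyed by term id.
#' @export
ranking_vector <- function(ranking, cluster = NULL) {
  if (is.null(cluster)) cluster <- ranking$seed_cluster[1]
  sub <- ranking[ranking$seed_cluster == cluster, ]
  stats::setNames(sub$rank, sub$term_id)
}
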