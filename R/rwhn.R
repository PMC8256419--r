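#' Random-walk parameters
#'
#' Bundles the tunable parameters of the heterogeneous random walk. The
#' defaults follow established practice for walks with restart on
#' heterogeneous biological networks: inter-layer transition probability
#' `lambda = 0.7`, restart probability `r = 0.7`, initial-vector layer
#' weights `eta_p = 0.7` (protein layer) and `eta_f = 0.3` (function layer),
#' L1 convergence tolerance `1e-10`, iteration cap `10000`, and retention of
#' the top 5 percent of ranked function terms.
#'
#' @param lambda Probability mass moved across layers per step, in (0, 1).
#' @param r Restart probability, in (0, 1].
#' @param eta_p,eta_f Initial-probability weights of the protein and
#'   function layers, in \[0, 1\].
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @param top_fraction Fraction of ranked function terms retained.
#' @param protein_split How protein nodes adjacent to both bipartite layers
#'   split the cross-layer mass: `"half"` (lambda/2 each, default) or
#'   `"degree"` (proportional to bipartite degree).
#' @return A list of class `rwhn_params`.
#' @export
rwhn_params <- function(lambda = 0.7, r = 0.7, eta_p = 0.7, eta_f = 0.3,
                        tol = 1e-10, max_iter = 10000, top_fraction = 0.05,
                        protein_split = c("half", "degree")) {
  protein_split <- match.arg(protein_split)
  stopifnot(lambda > 0, lambda < 1, r > 0, r <= 1,
            eta_p >= 0, eta_p <= 1, eta_f >= 0, eta_f <= 1,
            tol > 0, max_iter >= 1, top_fraction > 0, top_fraction <= 1)
  structure(list(lambda = lambda, r = r, eta_p = eta_p, eta_f = eta_f,
                 tol = tol, max_iter = max_iter, top_fraction = top_fraction,
                 protein_split = protein_split),
            class = "rwhn_params")
}

# Row-normalize a block restricted to given rows; zero rows stay zero.
row_norm <- function(block) {
  rs <- Matrix::rowSums(block)
  pos <- rs > 0
  if (any(pos)) block[pos, ] <- block[pos, , drop = FALSE] / rs[pos]
  block
}

#' Transition matrix of the multilayer network
#'
#' Converts the binary block adjacency into the row-stochastic transition
#' matrix of the walk. For every node, probability mass `lambda` goes to
#' cross-layer moves (row-normalized within each bipartite block) and
#' `1 - lambda` to intra-layer moves (row-normalized within the intra
#' block). A node with no intra-layer edges sends its full mass across
#' layers, and vice versa; protein nodes adjacent to both the site and the
#' function layer split the cross-layer mass between them (half/half by
#' default, or proportionally to their bipartite degrees). Fully isolated
#' nodes keep an all-zero row.
#'
#' @param net A `multilayer_net`.
#' @param lambda Inter-layer transition probability.
#' @param protein_split `"half"` or `"degree"` (see [rwhn_params()]).
#' @return List of class `rwhn_transition` with the sparse matrix `m` over
#'   `[sites; proteins; functions]` and the layer index map.
#' @export
build_transition_matrix <- function(net, lambda = 0.7,
                                    protein_split = c("half", "degree")) {
  protein_split <- match.arg(protein_split)
  nr <- length(net$sites); np <- length(net$proteins); nf <- length(net$functions)

  rr <- row_norm(net$a_rr); pp <- row_norm(net$a_pp); ff <- row_norm(net$a_ff)
  rp <- row_norm(net$a_rp); pf <- row_norm(net$a_pf)
  pr <- row_norm(Matrix::t(net$a_rp)); fp <- row_norm(Matrix::t(net$a_pf))

  deg <- function(a) Matrix::rowSums(a) > 0

  # sites: bipartite partner is the protein layer only
  s_intra <- deg(net$a_rr); s_cross <- deg(net$a_rp)
  w_rr <- ifelse(s_intra & s_cross, 1 - lambda, ifelse(s_intra, 1, 0))
  w_rp <- ifelse(s_intra & s_cross, lambda, ifelse(s_cross, 1, 0))

  # functions: bipartite partner is the protein layer only
  f_intra <- deg(net$a_ff); f_cross <- deg(Matrix::t(net$a_pf))
  w_ff <- ifelse(f_intra & f_cross, 1 - lambda, ifelse(f_intra, 1, 0))
  w_fp <- ifelse(f_intra & f_cross, lambda, ifelse(f_cross, 1, 0))

  # proteins: possibly adjacent to both bipartite layers
  p_intra <- deg(net$a_pp)
  p_to_r <- deg(Matrix::t(net$a_rp)); p_to_f <- deg(net$a_pf)
  cross_total <- ifelse(p_intra & (p_to_r | p_to_f), lambda,
                        ifelse(p_to_r | p_to_f, 1, 0))
  if (protein_split == "half") {
    share_r <- ifelse(p_to_r & p_to_f, 0.5, ifelse(p_to_r, 1, 0))
  } else {
    dr <- Matrix::rowSums(Matrix::t(net$a_rp)); df <- Matrix::rowSums(net$a_pf)
    tot <- dr + df
    share_r <- ifelse(tot > 0, dr / pmax(tot, 1), 0)
  }
  share_f <- ifelse(p_to_r | p_to_f, 1 - share_r, 0)
  w_pp <- ifelse(p_intra & (p_to_r | p_to_f), 1 - lambda,
                 ifelse(p_intra, 1, 0))
  w_pr <- cross_total * share_r
  w_pf <- cross_total * share_f

  zero_rf <- empty_adjacency(net$sites, net$functions)
  m <- rbind(
    cbind(w_rr * rr, w_rp * rp, zero_rf),
    cbind(w_pr * pr, w_pp * pp, w_pf * pf),
    cbind(Matrix::t(zero_rf), w_fp * fp, w_ff * ff)
  )
  structure(list(m = m,
                 layers = list(sites = seq_len(nr),
                               proteins = nr + seq_len(np),
                               functions = nr + np + seq_len(nf)),
                 nodes = c(net$sites, net$proteins, net$functions)),
            class = "rwhn_transition")
}

#' Initial probability vector for a seed set
#'
#' Seed sites share probability 1 equally; all other sites get 0. Protein
#' and function nodes receive uniform within-layer mass weighted by `eta_p`
#' and `eta_f` respectively, and the whole vector is normalized by
#' `1 + eta_p + eta_f` so it sums to 1. Because the walk is linear in the
#' initial vector, this normalization never changes the ranking.
#'
#' @param net A `multilayer_net`.
#' @param seeds Character vector of seed site ids (non-empty, all in the
#'   site layer).
#' @param eta_p,eta_f Layer weights.
#' @return Named numeric vector over `[sites; proteins; functions]`.
#' @export
make_initial_vector <- function(net, seeds, eta_p = 0.7, eta_f = 0.3) {
  if (!length(seeds)) rwhn_abort("empty_seeds", "seed set is empty")
  if (!all(seeds %in% net$sites)) {
    rwhn_abort("empty_seeds", "seeds must be site-layer nodes")
  }
  p_sites <- stats::setNames(rep(0, length(net$sites)), net$sites)
  p_sites[unique(seeds)] <- 1 / length(unique(seeds))
  np <- length(net$proteins); nf <- length(net$functions)
  p <- c(p_sites,
         stats::setNames(rep(if (np) eta_p / np else 0, np), net$proteins),
         stats::setNames(rep(if (nf) eta_f / nf else 0, nf), net$functions))
  p / (1 + (if (np) eta_p else 0) + (if (nf) eta_f else 0))
}

#' Random walk with restart
#'
#' Iterates `p_{s+1} = (1 - r) * t(M) %*% p_s + r * p_0` until the L1 change
#' drops below `tol`, returning the steady-state probability vector. Rows of
#' `M` are out-transition distributions, so the update acts with the
#' transpose on a probability column vector.
#'
#' @param m A `rwhn_transition` (or a row-stochastic matrix).
#' @param p0 Initial probability vector.
#' @param r Restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   final residual.
#' @return Named steady-state vector.
#' @export
random_walk <- function(m, p0, r = 0.7, tol = 1e-10, max_iter = 10000) {
  mat <- if (inherits(m, "rwhn_transition")) m$m else m
  stopifnot(nrow(mat) == length(p0))
  if (r == 1) return(p0)
  mt <- Matrix::t(mat)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_next <- as.numeric((1 - r) * (mt %*% p)) + r * p0
    delta <- sum(abs(p_next - p))
    p <- p_next
    if (delta < tol) {
      names(p) <- names(p0)
      return(p)
    }
  }
  rwhn_abort("no_convergence", paste0(
    "random walk did not converge in ", max_iter,
    " iterations (final L1 residual ", format(delta), ")"))
}

#' Rank function terms from per-cluster steady states
#'
#' Restricts each steady-state vector to the function layer, ranks terms by
#' descending probability (ties broken lexicographically by term id, ranks
#' reported as integers), removes terms whose integer rank is identical for
#' every seed cluster (only meaningful with two or more clusters), and
#' retains the top `ceiling(top_fraction * n_remaining)` terms per cluster.
#'
#' @param steady_states Named list of steady-state vectors, one per seed
#'   cluster.
#' @param net The `multilayer_net` the walks ran on.
#' @param top_fraction Retained fraction (default 0.05).
#' @return A `rwhn_ranking` tibble: `seed_cluster`, `term_id`, `term_name`,
#'   `probability`, `rank`, `retained`.
#' @export
extract_function_ranking <- function(steady_states, net, top_fraction = 0.05) {
  stopifnot(length(steady_states) >= 1)
  terms <- net$functions
  per_cluster <- purrr::imap(steady_states, function(p, cl) {
    pf <- p[net$functions]
    ord <- order(-pf, terms)
    tibble::tibble(seed_cluster = cl,
                   term_id = terms[ord],
                   term_name = unname(net$term_names[terms[ord]]),
                   probability = unname(pf[ord]),
                   rank = seq_along(ord))
  })
  tab <- dplyr::bind_rows(per_cluster)
  if (length(steady_states) >= 2 && length(terms)) {
    const <- dplyr::summarise(dplyr::group_by(tab, .data$term_id),
                              constant = dplyr::n_distinct(.data$rank) == 1,
                              .groups = "drop")
    constant_terms <- const$term_id[const$constant]
  } else {
    constant_terms <- character()
  }
  tab <- dplyr::mutate(
    dplyr::group_by(tab, .data$seed_cluster),
    constant_rank = .data$term_id %in% constant_terms,
    # re-rank after removal so the retention cut is over surviving terms
    rank_kept = ifelse(.data$constant_rank, NA_integer_,
                       rank(replace(.data$rank, .data$constant_rank, NA),
                            na.last = "keep")),
    retained = !is.na(.data$rank_kept) &
      .data$rank_kept <= ceiling(top_fraction * sum(!.data$constant_rank)))
  tab <- dplyr::ungroup(tab)
  tab$rank_kept <- NULL
  new_rwhn_ranking(tab)
}

new_rwhn_ranking <- function(tbl) {
  structure(tbl, class = c("rwhn_ranking", class(tibble::tibble())))
}

#' Run the full heterogeneous random walk per seed cluster
#'
#' Builds the transition matrix once, then for each regulation cluster seeds
#' the walk with that cluster's sites and extracts the per-cluster function
#' ranking. Fully deterministic.
#'
#' @param net A `multilayer_net`.
#' @param clusters `site_clusters` covering the network's sites (sites of
#'   the table absent from the network are ignored; every cluster must keep
#'   at least one site in the network).
#' @param params A [rwhn_params()] bundle.
#' @return A `rwhn_ranking` tibble (see [extract_function_ranking()]).
#' @export
run_rwhn <- function(net, clusters, params = rwhn_params()) {
  m <- build_transition_matrix(net, lambda = params$lambda,
                               protein_split = params$protein_split)
  cl_ids <- sort(unique(clusters$cluster))
  steady <- stats::setNames(lapply(cl_ids, function(cl) {
    seeds <- intersect(clusters$site_id[clusters$cluster == cl], net$sites)
    if (!length(seeds)) {
      rwhn_abort("empty_seeds", paste0("cluster ", cl,
                                       " has no sites in the network"))
    }
    p0 <- make_initial_vector(net, seeds, eta_p = params$eta_p,
                              eta_f = params$eta_f)
    random_walk(m, p0, r = params$r, tol = params$tol,
                max_iter = params$max_iter)
  }), as.character(cl_ids))
  extract_function_ranking(steady, net, top_fraction = params$top_fraction)
}

#' @export
print.rwhn_ranking <- function(x, ...) {
  cat("# RWHN function ranking: ", dplyr::n_distinct(x$seed_cluster),
      " seed cluster(s), ", dplyr::n_distinct(x$term_id), " terms (",
      sum(x$retained), " retained rows)\n", sep = "")
  NextMethod()
}
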