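#' Temporal archetype profiles
#'
#' Five canonical regulation shapes on the log2-ratio scale, evaluated on a
#' unit time grid: early transient (fast rise, fast decay), sustained
#' (saturating rise), late (sigmoidal late rise), decreasing (saturating
#' loss) and cycling (one full oscillation). Amplitude 2 on the log2 scale,
#' so peak ratios reach 4 (or 0.25), comfortably beyond the two-fold
#' regulation bounds.
#'
#' @param n_timepoints Number of conditions in the profile.
#' @return Matrix `archetype x time` of log2 ratios, rownames naming the
#'   shapes.
#' @export
archetype_profiles <- function(n_timepoints = 8) {
  t <- seq(0, 1, length.out = n_timepoints)
  shapes <- rbind(
    early_transient = (t / 0.15) * exp(1 - t / 0.15),
    sustained       = 1 - exp(-t / 0.2),
    late            = 1 / (1 + exp(-(t - 0.7) / 0.08)),
    decreasing      = -(1 - exp(-t / 0.25)),
    cycling         = sin(2 * pi * t) * 0.8
  )
  2 * shapes
}

#' Generate a planted-truth synthetic study
#'
#' Builds a fully self-contained study in which the true cluster-to-function
#' mapping is known by construction. Each regulation cluster follows one
#' temporal archetype (plus Gaussian noise on the log2 scale); its sites sit
#' on a group of host proteins that form, together with a few
#' non-phosphorylated interactors, a dense interaction module. The module's
#' interactors are annotated to the cluster's distinctive term and to a few
#' overlapping satellite terms (emulating the annotation redundancy of real
#' libraries); routing from seeds to these terms therefore runs through the
#' interaction topology, which is what the walk is supposed to exploit.
#' Decoy terms are annotated to background proteins arranged in cliques;
#' each background protein also has one confident interaction with a host
#' protein, placing it in the first interaction shell the protein layer is
#' built from (as decoy annotations sit in a real interactome). A toy
#' ontology places every term under one root, with satellites as children
#' of their distinctive term.
#'
#' @param n_clusters Number of planted clusters (>= 2, <= 5 archetypes).
#' @param sites_per_cluster Sites per cluster (>= 3).
#' @param n_background_proteins Background proteins carrying decoy
#'   annotations (grouped into cliques of 6).
#' @param n_decoy_terms Decoy terms (round-robin over background cliques).
#' @param noise_sd Gaussian noise sd on the log2-ratio scale (default 0.1,
#'   tight co-regulation within an archetype).
#' @param n_timepoints Conditions per profile (default 8).
#' @param satellites_per_cluster Satellite terms per planted module
#'   (default 4).
#' @param decoy_set_size Genes per decoy term, drawn from its background
#'   clique (default 2).
#' @param seed Integer seed; the study is bit-reproducible given it.
#' @return A `synthetic_study` list: `quant`, `clusters` (planted labels),
#'   `ppi` (confidence-filtered), `ppi_raw` (unfiltered STRING-scale table),
#'   `lib`, `dag`, `truth` (cluster id -> distinctive term), `archetypes`.
#' @export
generate_planted_study <- function(n_clusters = 3, sites_per_cluster = 30,
                                   n_background_proteins = 60,
                                   n_decoy_terms = 5,
                                   noise_sd = 0.1, n_timepoints = 8,
                                   satellites_per_cluster = 4,
                                   decoy_set_size = 2,
                                   seed = 1L) {
  if (n_clusters < 2 || n_clusters > 5 || sites_per_cluster < 3 ||
      n_background_proteins < 6 || n_decoy_terms < 1 || n_timepoints < 3) {
    rwhn_abort("bad_config", "inconsistent synthetic-study sizes")
  }
  set.seed(as.integer(seed))
  arch <- archetype_profiles(n_timepoints)[seq_len(n_clusters), , drop = FALSE]
  n_hosts <- max(2, ceiling(sites_per_cluster / 5))
  n_inter <- 6

  hosts <- lapply(seq_len(n_clusters), function(c)
    sprintf("C%d_HOST%d", c, seq_len(n_hosts)))
  inters <- lapply(seq_len(n_clusters), function(c)
    sprintf("C%d_INT%d", c, seq_len(n_inter)))
  bg <- sprintf("BG%02d", seq_len(n_background_proteins))

  # quant table: sites round-robin over their cluster's hosts
  residues <- c("S", "T", "Y")
  rows <- list()
  for (c in seq_len(n_clusters)) {
    for (s in seq_len(sites_per_cluster)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein = hosts[[c]][((s - 1) %% n_hosts) + 1],
        residue = residues[((s - 1) %% 3) + 1],
        position = 10L + 7L * ((s - 1) %/% n_hosts),
        cluster = c)
    }
  }
  info <- dplyr::bind_rows(rows)
  vals <- t(vapply(info$cluster, function(c)
    arch[c, ] + stats::rnorm(n_timepoints, 0, noise_sd),
    numeric(n_timepoints)))
  colnames(vals) <- sprintf("t%d", seq_len(n_timepoints))
  qt <- quant_tbl(dplyr::bind_cols(info[, c("protein", "residue", "position")],
                                   tibble::as_tibble(2^vals)))
  clusters <- new_site_clusters(tibble::tibble(site_id = site_ids(qt),
                                               protein = qt$protein,
                                               cluster = info$cluster))

  # PPI: one dense module per cluster (hosts + interactors), background
  # cliques of 6, plus sub-threshold noise edges exercising the score filter
  clique_edges <- function(nodes) {
    if (length(nodes) < 2) return(NULL)
    idx <- utils::combn(length(nodes), 2)
    tibble::tibble(protein_a = nodes[idx[1, ]], protein_b = nodes[idx[2, ]],
                   score = stats::runif(ncol(idx), 0.401, 1))
  }
  # module = host-interactor bipartite shell plus an interactor complex:
  # phosphorylated hosts each bind all module interactors, which form a
  # dense complex among themselves; hosts do not interact directly, so seed
  # mass is transmitted outward into the module rather than circulating
  # among hosts
  modules <- lapply(seq_len(n_clusters), function(c) {
    hi <- expand.grid(a = hosts[[c]], b = inters[[c]],
                      stringsAsFactors = FALSE)
    dplyr::bind_rows(
      tibble::tibble(protein_a = hi$a, protein_b = hi$b,
                     score = stats::runif(nrow(hi), 0.401, 1)),
      clique_edges(inters[[c]]))
  })
  bg_cliques <- split(bg, ceiling(seq_along(bg) / 6))
  bg_edges <- lapply(bg_cliques, clique_edges)
  # each background protein interacts confidently with a hub host (the
  # first host of each cluster, round-robin), placing it in the first
  # interaction shell of the data proteins as the wider interactome would;
  # hub-dominated attachment mirrors the skewed degree distributions of
  # real interactomes, and each clique then enters as an induced module
  hubs <- vapply(hosts, `[[`, "", 1L)
  attach_edges <- tibble::tibble(
    protein_a = bg,
    protein_b = hubs[(seq_along(bg) - 1L) %% length(hubs) + 1L],
    score = stats::runif(length(bg), 0.401, 1))
  all_prot <- c(unlist(hosts), unlist(inters), bg)
  noise_pairs <- matrix(sample(all_prot, 2 * 3 * n_clusters, replace = TRUE),
                        ncol = 2)
  noise_pairs <- noise_pairs[noise_pairs[, 1] != noise_pairs[, 2], ,
                             drop = FALSE]
  noise_edges <- tibble::tibble(protein_a = noise_pairs[, 1],
                                protein_b = noise_pairs[, 2],
                                score = stats::runif(nrow(noise_pairs),
                                                     0.05, 0.39))
  ppi_raw <- dplyr::bind_rows(c(modules, bg_edges,
                                list(attach_edges, noise_edges)))

  # annotation library: distinctive + satellite terms on module interactors,
  # decoys on background cliques; decoy genes carry one annotation each
  # (undivided mass), so label-shuffled nulls systematically favour them,
  # giving the permutation test a null with a known direction
  lib_rows <- list()
  truth <- character(n_clusters)
  for (c in seq_len(n_clusters)) {
    main <- sprintf("TERM_C%d_MAIN", c)
    truth[c] <- main
    lib_rows[[length(lib_rows) + 1L]] <- tibble::tibble(
      term = main, name = sprintf("planted process %d", c),
      genes = list(inters[[c]]))
    for (s in seq_len(satellites_per_cluster)) {
      # leave-one-out subsets: satellites share most of the distinctive
      # term's annotation profile, as related processes do in real libraries
      keep <- setdiff(seq_len(n_inter), ((s - 1) %% n_inter) + 1)
      lib_rows[[length(lib_rows) + 1L]] <- tibble::tibble(
        term = sprintf("TERM_C%d_S%d", c, s),
        name = sprintf("planted satellite %d.%d", c, s),
        genes = list(inters[[c]][keep]))
    }
  }
  for (d in seq_len(n_decoy_terms)) {
    cl <- bg_cliques[[((d - 1) %% length(bg_cliques)) + 1]]
    lib_rows[[length(lib_rows) + 1L]] <- tibble::tibble(
      term = sprintf("TERM_BG%02d", d),
      name = sprintf("decoy process %d", d),
      genes = list(cl[seq_len(min(decoy_set_size, length(cl)))]))
  }
  lib <- dplyr::bind_rows(lib_rows)

  # toy ontology: satellites under their distinctive term, all under a root
  edges <- list()
  for (c in seq_len(n_clusters)) {
    edges[[length(edges) + 1L]] <-
      tibble::tibble(child = sprintf("TERM_C%d_MAIN", c),
                     parent = "TERM_ROOT", relation = "is_a")
    for (s in seq_len(satellites_per_cluster)) {
      edges[[length(edges) + 1L]] <-
        tibble::tibble(child = sprintf("TERM_C%d_S%d", c, s),
                       parent = sprintf("TERM_C%d_MAIN", c),
                       relation = "is_a")
    }
  }
  for (d in seq_len(n_decoy_terms)) {
    edges[[length(edges) + 1L]] <-
      tibble::tibble(child = sprintf("TERM_BG%02d", d),
                     parent = "TERM_ROOT", relation = "is_a")
  }
  edge_tbl <- dplyr::bind_rows(edges)
  dag <- onto_dag(terms = c("TERM_ROOT", lib$term), edges = edge_tbl,
                  names = stats::setNames(c("root process", lib$name),
                                          c("TERM_ROOT", lib$term)))

  structure(list(quant = qt, clusters = clusters,
                 ppi = ppi_network(ppi_raw, threshold = 0.4),
                 ppi_raw = ppi_raw, lib = lib, dag = dag,
                 truth = stats::setNames(truth, seq_len(n_clusters)),
                 archetypes = stats::setNames(rownames(arch),
                                              seq_len(n_clusters))),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("# Synthetic planted study: ", nrow(x$quant), " sites, ",
      length(unique(x$clusters$cluster)), " clusters, ",
      nrow(x$lib), " terms (", length(x$truth), " planted)\n", sep = "")
  invisible(x)
}

#' A small curated-dynamics-style dataset
#'
#' Generates a compact table shaped like hand-curated growth-factor
#' signalling dynamics: 19 sites on 8 proteins following 5 temporal
#' archetypes over a 5-point time course. Values are synthetic draws around
#' the archetype shapes, not measurements.
#'
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @return List with `quant` (19 x 5 [quant_tbl]) and `clusters`
#'   (`site_clusters` with 5 labels).
#' @export
generate_validation_like_dataset <- function(seed = 1L, noise_sd = 0.1) {
  set.seed(as.integer(seed))
  arch <- archetype_profiles(5)
  sizes <- c(4, 4, 4, 4, 3)
  proteins <- sprintf("PROT%d", 1:8)
  lab <- rep(seq_len(5), sizes)
  host <- proteins[(seq_len(19) - 1) %% 8 + 1]
  vals <- t(vapply(lab, function(c) arch[c, ] + stats::rnorm(5, 0, noise_sd),
                   numeric(5)))
  colnames(vals) <- sprintf("t%d", 1:5)
  qt <- quant_tbl(dplyr::bind_cols(
    tibble::tibble(protein = host,
                   residue = c("S", "T", "Y")[(seq_len(19) - 1) %% 3 + 1],
                   position = 5L * seq_len(19)),
    tibble::as_tibble(2^vals)))
  list(quant = qt,
       clusters = new_site_clusters(tibble::tibble(site_id = site_ids(qt),
                                                   protein = qt$protein,
                                                   cluster = lab)))
}

#' Generate a toy ontology with annotations
#'
#' Random rooted DAG: terms are added in order, each choosing one or two
#' parents among earlier terms (`is_a` with probability 0.7, else
#' `part_of`), so acyclicity and root reachability hold by construction.
#' Each term is annotated to a random handful of genes from a small pool.
#'
#' @param n_terms Number of terms including the root (>= 2).
#' @param max_parents Maximum parents per term (default 2).
#' @param n_genes Gene-pool size (default `5 * n_terms`).
#' @param seed Integer seed.
#' @return List with `dag` (an `onto_dag`) and `lib` (annotation tibble).
#' @export
generate_toy_ontology <- function(n_terms = 10, max_parents = 2,
                                  n_genes = 5 * n_terms, seed = 1L) {
  if (n_terms < 2) rwhn_abort("bad_config", "need at least 2 terms")
  set.seed(as.integer(seed))
  ids <- sprintf("TOY:%04d", seq_len(n_terms))
  edges <- list()
  for (i in 2:n_terms) {
    n_par <- sample(seq_len(min(max_parents, i - 1)), 1)
    parents <- sample(seq_len(i - 1), n_par)
    for (p in parents) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        child = ids[i], parent = ids[p],
        relation = sample(c("is_a", "part_of"), 1, prob = c(0.7, 0.3)))
    }
  }
  dag <- onto_dag(ids, dplyr::bind_rows(edges),
                  names = stats::setNames(sprintf("toy term %d",
                                                  seq_len(n_terms)), ids))
  pool <- sprintf("G%03d", seq_len(n_genes))
  lib <- tibble::tibble(
    term = ids, name = unname(dag$names[ids]),
    genes = lapply(seq_len(n_terms), function(i)
      sample(pool, sample(1:5, 1))))
  list(dag = dag, lib = lib)
}

#' Random multilayer network
#'
#' A structureless null network for solver and calibration checks:
#' Erdos-Renyi intra-layer blocks, one uniformly chosen host protein per
#' site, and Bernoulli protein-function edges. Carries no planted signal.
#'
#' @param n_sites,n_proteins,n_functions Layer sizes.
#' @param p_rr,p_pp,p_ff,p_pf Edge probabilities per block.
#' @param seed Integer seed.
#' @return A `multilayer_net`.
#' @export
generate_random_multilayer <- function(n_sites = 20, n_proteins = 25,
                                       n_functions = 15,
                                       p_rr = 0.1, p_pp = 0.15, p_ff = 0.1,
                                       p_pf = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  sites <- sprintf("S%03d", seq_len(n_sites))
  proteins <- sprintf("P%03d", seq_len(n_proteins))
  functions <- sprintf("F%03d", seq_len(n_functions))
  sym_block <- function(nodes, p) {
    n <- length(nodes)
    a <- matrix(stats::rbinom(n * n, 1, p), n, n,
                dimnames = list(nodes, nodes))
    a[lower.tri(a, diag = TRUE)] <- 0
    methods::as(a + t(a), "CsparseMatrix")
  }
  a_rp <- empty_adjacency(sites, proteins)
  a_rp[cbind(seq_len(n_sites), sample(n_proteins, n_sites, replace = TRUE))] <- 1
  a_pf <- empty_adjacency(proteins, functions)
  hits <- which(matrix(stats::rbinom(n_proteins * n_functions, 1, p_pf),
                       n_proteins) == 1, arr.ind = TRUE)
  if (nrow(hits)) a_pf[hits] <- 1
  new_multilayer_net(sites = sites, proteins = proteins, functions = functions,
                     a_rr = sym_block(sites, p_rr),
                     a_pp = sym_block(proteins, p_pp),
                     a_ff = sym_block(functions, p_ff),
                     a_rp = a_rp, a_pf = a_pf)
}

#' Write a synthetic study to fixture files
#'
#' Serialises the four inputs in their standard on-disk formats: the quant
#' table as TSV, the raw interaction table in STRING flat-file dialect
#' (scores on the 0--1000 integer scale, `experimental` and `combined_score`
#' channels), the annotation library as GMT, and the ontology as OBO 1.2.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(quant = file.path(dir, "quant.tsv"),
             ppi = file.path(dir, "ppi_links.txt"),
             gmt = file.path(dir, "library.gmt"),
             obo = file.path(dir, "ontology.obo"))
  write_quant_table(study$quant, paths["quant"])
  ppi <- study$ppi_raw
  string_tbl <- data.frame(protein1 = ppi$protein_a, protein2 = ppi$protein_b,
                           experimental = as.integer(round(ppi$score * 1000)),
                           combined_score = as.integer(round(ppi$score * 1000)))
  utils::write.table(string_tbl, paths["ppi"], sep = " ", quote = FALSE,
                     row.names = FALSE)
  write_gmt(study$lib, paths["gmt"])
  write_obo(study$dag, paths["obo"])
  paths
}
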