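#' Site-site subnetwork from co-clustered, correlated profiles
#'
#' Draws a binary edge between two sites when they belong to the same
#' regulation cluster and the squared Pearson correlation of their
#' per-condition profiles is at least `threshold` (default 0.99). With
#' `square = FALSE` the threshold is applied to the plain correlation r
#' instead. Constant (zero-variance) profiles correlate with nothing and
#' yield isolated nodes.
#'
#' @param qt A complete [quant_tbl].
#' @param clusters A `site_clusters` assignment covering every site.
#' @param threshold Correlation cutoff (inclusive).
#' @param square Apply the cutoff to r^2 (default) rather than r.
#' @return Sparse symmetric binary adjacency over the site ids.
#' @export
build_site_subnetwork <- function(qt, clusters, threshold = 0.99,
                                  square = TRUE) {
  m <- quant_matrix(qt)
  if (anyNA(m)) rwhn_abort("missing_data", "profiles must be complete")
  ids <- rownames(m)
  if (!all(ids %in% clusters$site_id)) {
    rwhn_abort("bad_config", "every site must carry a cluster label")
  }
  lab <- clusters$cluster[match(ids, clusters$site_id)]
  a <- empty_adjacency(ids, ids)
  for (cl in unique(lab)) {
    members <- which(lab == cl)
    if (length(members) < 2) next
    prof <- t(m[members, , drop = FALSE])
    sds <- apply(prof, 2, stats::sd)
    ok <- which(sds > 0)
    if (length(ok) < 2) next
    r <- suppressWarnings(stats::cor(prof[, ok, drop = FALSE]))
    stat <- if (square) r^2 else r
    hit <- which(stat >= threshold & upper.tri(stat), arr.ind = TRUE)
    if (nrow(hit)) {
      i <- members[ok[hit[, 1]]]; j <- members[ok[hit[, 2]]]
      a[cbind(c(i, j), c(j, i))] <- 1
    }
  }
  a
}

#' Protein layer: data proteins plus their first interaction shell
#'
#' The protein node set is the phosphorylated (data) proteins together with
#' all their direct interactors in the confidence-filtered PPI network; the
#' edge set is every PPI edge with both endpoints inside that node set
#' (including edges among interactors). Data proteins absent from the PPI
#' remain as isolated nodes.
#'
#' @param ppi Confidence-filtered edge tibble (see [ppi_network()]).
#' @param data_proteins Character vector of proteins carrying measured sites.
#' @return Sparse symmetric binary adjacency over the protein node set.
#' @export
build_protein_subnetwork <- function(ppi, data_proteins) {
  data_proteins <- unique(data_proteins)
  touch <- ppi$protein_a %in% data_proteins | ppi$protein_b %in% data_proteins
  interactors <- unique(c(ppi$protein_a[touch], ppi$protein_b[touch]))
  nodes <- sort(unique(c(data_proteins, interactors)))
  keep <- ppi$protein_a %in% nodes & ppi$protein_b %in% nodes
  e <- ppi[keep, ]
  a <- empty_adjacency(nodes, nodes)
  if (nrow(e)) {
    i <- match(e$protein_a, nodes); j <- match(e$protein_b, nodes)
    a[cbind(c(i, j), c(j, i))] <- 1
  }
  a
}

#' Louvain modules of the protein subnetwork
#'
#' @param app Symmetric protein adjacency.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed Integer seed making the greedy optimisation reproducible.
#' @return Tibble with columns `protein`, `module` (1-based integer).
#' @export
detect_modules <- function(app, resolution = 1, seed = 1L) {
  g <- igraph::graph_from_adjacency_matrix(
    methods::as(app, "CsparseMatrix"), mode = "undirected")
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  tibble::tibble(protein = rownames(app),
                 module = as.integer(igraph::membership(comm)))
}

#' Hypergeometric enrichment of annotation terms per module
#'
#' For each Louvain module, each library term sharing at least one gene with
#' the module is tested with the upper-tail hypergeometric test against the
#' gene universe; p-values are Benjamini-Hochberg adjusted within the module
#' and terms with `q < alpha` retained. The protein-function bipartite block
#' connects each retained term to the module proteins annotated to it; a
#' term enriched in several modules appears once, with its edges unioned.
#'
#' @param modules Tibble `protein`, `module` (see [detect_modules()]).
#' @param lib Annotation library tibble.
#' @param universe Character vector of universe genes (must cover the module
#'   proteins present in the library).
#' @param alpha FDR cutoff (default 0.05).
#' @return List with `table` (tibble `module`, `term`, `overlap`, `p`, `q`)
#'   and `a_pf` (sparse binary protein x term adjacency).
#' @export
enrich_modules <- function(modules, lib, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) rwhn_abort("empty_universe", "empty gene universe")
  gs <- lapply(gene_sets(lib), intersect, universe)
  n_u <- length(universe)
  rows <- list()
  for (mod in sort(unique(modules$module))) {
    members <- intersect(modules$protein[modules$module == mod], universe)
    if (!length(members)) next
    ps <- purrr::imap(gs, function(set, term) {
      k <- length(intersect(set, members))
      if (k == 0) return(NULL)
      tibble::tibble(module = mod, term = term, overlap = k,
                     p = stats::phyper(k - 1, length(set),
                                       n_u - length(set),
                                       length(members),
                                       lower.tail = FALSE))
    })
    tab <- dplyr::bind_rows(ps)
    if (!nrow(tab)) next
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    rows[[length(rows) + 1L]] <- tab
  }
  table <- dplyr::bind_rows(rows)
  if (!nrow(table)) {
    table <- tibble::tibble(module = integer(), term = character(),
                            overlap = integer(), p = numeric(), q = numeric())
  }
  hits <- table[table$q < alpha, ]
  terms <- sort(unique(hits$term))
  a_pf <- empty_adjacency(sort(unique(modules$protein)), terms)
  gsets <- gene_sets(lib)
  for (i in seq_len(nrow(hits))) {
    members <- modules$protein[modules$module == hits$module[i]]
    annotated <- intersect(members, gsets[[hits$term[i]]])
    if (length(annotated)) {
      a_pf[cbind(match(annotated, rownames(a_pf)),
                 match(hits$term[i], colnames(a_pf)))] <- 1
    }
  }
  list(table = table, a_pf = a_pf)
}

#' Drop broad and redundant ontology terms
#'
#' Removes terms annotated (after child-to-ancestor propagation) to more
#' than `freq_cutoff` of the universe, then collapses semantically redundant
#' pairs: whenever two surviving terms have Wang similarity above
#' `redundancy_cutoff`, the higher-frequency (broader) term of the pair is
#' dropped, keeping the more specific one. Ties are broken by keeping the
#' lexicographically smaller id.
#'
#' @param terms Character vector of candidate term ids.
#' @param dag An `onto_dag` covering the terms.
#' @param lib Annotation library tibble.
#' @param universe Character vector of universe genes.
#' @param freq_cutoff Annotation-frequency cutoff (default 0.05, strict).
#' @param redundancy_cutoff Wang-similarity cutoff (default 0.9, strict).
#' @return The filtered term id vector (original order preserved).
#' @export
filter_function_terms <- function(terms, dag, lib, universe,
                                  freq_cutoff = 0.05,
                                  redundancy_cutoff = 0.9) {
  if (!length(terms)) return(terms)
  freq <- vapply(terms, function(t) term_frequency(lib, dag, t, universe), 1.0)
  keep <- terms[freq <= freq_cutoff]
  freq <- freq[match(keep, terms)]
  if (length(keep) < 2) return(keep)
  drop <- rep(FALSE, length(keep))
  for (i in seq_len(length(keep) - 1)) {
    for (j in (i + 1):length(keep)) {
      if (drop[i] || drop[j]) next
      if (wang_similarity(dag, keep[i], keep[j]) > redundancy_cutoff) {
        if (freq[i] > freq[j]) drop[i] <- TRUE
        else if (freq[j] > freq[i]) drop[j] <- TRUE
        else drop[max(i, j)] <- TRUE
      }
    }
  }
  keep[!drop]
}

#' Function-function subnetwork
#'
#' Wires the function layer: for ontology (`mode = "go"`) terms an edge is
#' drawn when Wang similarity is strictly above `threshold`; for pathway
#' (`mode = "kegg"`) terms when the annotation-profile similarity (overlap
#' coefficient by default) is strictly above it. Default threshold 0.7.
#'
#' @param terms Character vector of term ids.
#' @param mode `"go"` or `"kegg"`.
#' @param dag `onto_dag`, required in go mode.
#' @param lib Annotation library, required in kegg mode.
#' @param threshold Similarity cutoff (strict).
#' @param metric Profile-similarity metric for kegg mode.
#' @return Sparse symmetric binary adjacency over `terms`.
#' @export
build_function_subnetwork <- function(terms, mode = c("go", "kegg"),
                                      dag = NULL, lib = NULL,
                                      threshold = 0.7,
                                      metric = c("overlap", "jaccard")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  a <- empty_adjacency(terms, terms)
  if (length(terms) < 2) return(a)
  simfun <- if (mode == "go") {
    if (is.null(dag)) rwhn_abort("bad_config", "go mode needs an ontology DAG")
    function(x, y) wang_similarity(dag, x, y)
  } else {
    if (is.null(lib)) rwhn_abort("bad_config", "kegg mode needs a gene-set library")
    function(x, y) annotation_profile_similarity(lib, x, y, metric = metric)
  }
  for (i in seq_len(length(terms) - 1)) {
    for (j in (i + 1):length(terms)) {
      if (simfun(terms[i], terms[j]) > threshold) {
        a[i, j] <- 1; a[j, i] <- 1
      }
    }
  }
  a
}

#' Assemble the three-layer heterogeneous network
#'
#' Runs the five construction rules and packs their blocks into one
#' multilayer network over ordered node lists (sites, proteins, functions):
#' site-site edges from co-clustered correlated profiles, the protein
#' interaction layer with its first shell, function-function similarity
#' edges, the one-edge-per-site site-protein block, and protein-function
#' edges from Louvain-module enrichment (after frequency/redundancy
#' filtering in go mode).
#'
#' @param qt Complete, clustered [quant_tbl].
#' @param clusters `site_clusters` for `qt`.
#' @param ppi Confidence-filtered PPI edge tibble.
#' @param lib Annotation library tibble.
#' @param dag `onto_dag` (go mode only).
#' @param mode `"go"` or `"kegg"`.
#' @param universe Gene universe for enrichment; defaults to the union of
#'   protein-layer nodes and all library genes.
#' @param site_cor_threshold,fun_sim_threshold,freq_cutoff,redundancy_cutoff,alpha
#'   Construction thresholds (defaults 0.99, 0.7, 0.05, 0.9, 0.05).
#' @param resolution,seed Louvain parameters.
#' @return A `multilayer_net`: node vectors `sites`, `proteins`, `functions`,
#'   sparse blocks `a_rr`, `a_pp`, `a_ff`, `a_rp`, `a_pf`, plus the module
#'   table, enrichment table and term names.
#' @export
assemble_multilayer <- function(qt, clusters, ppi, lib, dag = NULL,
                                mode = c("go", "kegg"),
                                universe = NULL,
                                site_cor_threshold = 0.99,
                                fun_sim_threshold = 0.7,
                                freq_cutoff = 0.05,
                                redundancy_cutoff = 0.9,
                                alpha = 0.05,
                                resolution = 1, seed = 1L) {
  mode <- match.arg(mode)
  a_rr <- build_site_subnetwork(qt, clusters, threshold = site_cor_threshold)
  a_pp <- build_protein_subnetwork(ppi, unique(qt$protein))
  proteins <- rownames(a_pp)
  orphan <- setdiff(unique(qt$protein), proteins)
  if (length(orphan)) {
    rwhn_abort("orphan_site", paste0("site protein missing from protein layer: ",
                                     orphan[1]))
  }
  if (is.null(universe)) {
    universe <- unique(c(proteins, unlist(lib$genes, use.names = FALSE)))
  }
  modules <- detect_modules(a_pp, resolution = resolution, seed = seed)
  enr <- enrich_modules(modules, lib, universe, alpha = alpha)
  terms <- colnames(enr$a_pf)
  if (mode == "go" && length(terms)) {
    terms <- filter_function_terms(terms, dag, lib, universe,
                                   freq_cutoff = freq_cutoff,
                                   redundancy_cutoff = redundancy_cutoff)
  }
  a_pf <- enr$a_pf[, terms, drop = FALSE]
  a_ff <- build_function_subnetwork(terms, mode = mode, dag = dag, lib = lib,
                                    threshold = fun_sim_threshold)
  sites <- rownames(a_rr)
  a_rp <- empty_adjacency(sites, proteins)
  a_rp[cbind(seq_along(sites), match(qt$protein, proteins))] <- 1
  term_names <- if (mode == "go" && !is.null(dag)) {
    stats::setNames(unname(dag$names[terms]), terms)
  } else {
    stats::setNames(lib$name[match(terms, lib$term)], terms)
  }
  term_names[is.na(term_names)] <- terms[is.na(term_names)]
  new_multilayer_net(sites = sites, proteins = proteins, functions = terms,
                     a_rr = a_rr, a_pp = a_pp, a_ff = a_ff,
                     a_rp = a_rp, a_pf = a_pf,
                     term_names = term_names,
                     modules = modules, enrichment = enr$table)
}

new_multilayer_net <- function(sites, proteins, functions,
                               a_rr, a_pp, a_ff, a_rp, a_pf,
                               term_names = NULL, modules = NULL,
                               enrichment = NULL) {
  stopifnot(nrow(a_rr) == length(sites), ncol(a_rr) == length(sites),
            nrow(a_pp) == length(proteins), ncol(a_pp) == length(proteins),
            nrow(a_ff) == length(functions), ncol(a_ff) == length(functions),
            nrow(a_rp) == length(sites), ncol(a_rp) == length(proteins),
            nrow(a_pf) == length(proteins), ncol(a_pf) == length(functions))
  if (is.null(term_names)) term_names <- stats::setNames(functions, functions)
  structure(list(sites = sites, proteins = proteins, functions = functions,
                 a_rr = a_rr, a_pp = a_pp, a_ff = a_ff,
                 a_rp = a_rp, a_pf = a_pf,
                 term_names = term_names, modules = modules,
                 enrichment = enrichment),
            class = "multilayer_net")
}

#' @export
print.multilayer_net <- function(x, ...) {
  cat("# Multilayer heterogeneous network\n",
      "  sites:     ", length(x$sites), " nodes, ",
      Matrix::nnzero(x$a_rr) / 2, " edges\n",
      "  proteins:  ", length(x$proteins), " nodes, ",
      Matrix::nnzero(x$a_pp) / 2, " edges\n",
      "  functions: ", length(x$functions), " nodes, ",
      Matrix::nnzero(x$a_ff) / 2, " edges\n",
      "  site-protein: ", Matrix::nnzero(x$a_rp), " edges;",
      " protein-function: ", Matrix::nnzero(x$a_pf), " edges\n", sep = "")
  invisible(x)
}

#' Full block adjacency of a multilayer network
#'
#' Stacks the five blocks (and the transposes of the bipartite ones) into
#' the single symmetric adjacency over `[sites; proteins; functions]`.
#'
#' @param net A `multilayer_net`.
#' @return Sparse symmetric matrix with all node ids as dimnames.
#' @export
full_adjacency <- function(net) {
  rbind(
    cbind(net$a_rr, net$a_rp, empty_adjacency(net$sites, net$functions)),
    cbind(Matrix::t(net$a_rp), net$a_pp, net$a_pf),
    cbind(empty_adjacency(net$functions, net$sites), Matrix::t(net$a_pf),
          net$a_ff)
  )
}

empty_adjacency <- function(rows, cols) {
  Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                       dims = c(length(rows), length(cols)),
                       dimnames = list(rows, cols))
}
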