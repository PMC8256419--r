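#' Wang semantic similarity between ontology terms
#'
#' Topology-based similarity on the ontology DAG. For a term A, every
#' ancestor t (including A itself) receives an S-value: `S_A(A) = 1` and
#' `S_A(t) = max { w_e * S_A(c) }` over the children c of t inside A's
#' ancestor graph, where `w_e` is the semantic contribution factor of the
#' edge relation (`is_a` 0.8, `part_of` 0.6 by default). The similarity is
#'
#' `sim(A, B) = sum_{t in T_A intersect T_B} (S_A(t) + S_B(t)) / (SV(A) + SV(B))`
#'
#' with `SV(X) = sum_{t in T_X} S_X(t)`. Only `is_a` and `part_of` edges are
#' traversed.
#'
#' @param dag An `onto_dag`.
#' @param t1,t2 Term ids present in `dag`.
#' @param weights Named contribution factors in (0, 1) per relation.
#' @return Similarity in \[0, 1\]; 1 for identical terms, 0 for terms with
#'   disjoint ancestor sets.
#' @export
wang_similarity <- function(dag, t1, t2,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(weights > 0 & weights < 1))
  s1 <- wang_svalues(dag, t1, weights)
  if (t1 == t2) return(1)
  s2 <- wang_svalues(dag, t2, weights)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

# S-values of a term over its ancestor graph (term included, S = 1).
wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!term %in% dag$terms) {
    rwhn_abort("unknown_term", paste0("term not in ontology: ", term))
  }
  anc <- ontology_ancestors(dag, term)
  sub <- dag$edges[dag$edges$child %in% anc & dag$edges$parent %in% anc, ]
  s <- stats::setNames(rep(-Inf, length(anc)), anc)
  s[term] <- 1
  # relax child->parent edges to a fixpoint; the DAG guarantees termination
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(sub))) {
      cand <- unname(weights[sub$relation[i]]) * s[sub$child[i]]
      if (cand > s[sub$parent[i]]) {
        s[sub$parent[i]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  s[is.finite(s)]
}

# A term plus all its is_a/part_of ancestors.
ontology_ancestors <- function(dag, term) {
  out <- term
  frontier <- term
  while (length(frontier)) {
    parents <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    frontier <- setdiff(parents, out)
    out <- c(out, frontier)
  }
  out
}

# A term plus all its descendants.
ontology_descendants <- function(dag, term) {
  out <- term
  frontier <- term
  while (length(frontier)) {
    children <- unique(dag$edges$child[dag$edges$parent %in% frontier])
    frontier <- setdiff(children, out)
    out <- c(out, frontier)
  }
  out
}

#' Similarity of two terms' annotation profiles
#'
#' Set similarity of the gene sets annotated to two terms, used to wire the
#' function layer for pathway (gene-set) annotations where no ontology DAG
#' exists. The default is the overlap coefficient
#' `|A intersect B| / min(|A|, |B|)`; Jaccard `|A intersect B| / |A union B|`
#' is available.
#'
#' @param lib Annotation library tibble (`term`, `name`, `genes`).
#' @param t1,t2 Term ids present in `lib`.
#' @param metric `"overlap"` (default) or `"jaccard"`.
#' @return Similarity in \[0, 1\].
#' @export
annotation_profile_similarity <- function(lib, t1, t2,
                                          metric = c("overlap", "jaccard")) {
  metric <- match.arg(metric)
  gs <- gene_sets(lib)
  if (!t1 %in% names(gs) || !t2 %in% names(gs)) {
    rwhn_abort("unknown_term", "term has no gene set in the library")
  }
  a <- gs[[t1]]; b <- gs[[t2]]
  inter <- length(intersect(a, b))
  if (metric == "overlap") inter / min(length(a), length(b))
  else inter / length(union(a, b))
}

#' Annotation frequency of a term
#'
#' Fraction of the gene universe annotated to a term or any of its
#' descendants (annotations are propagated child-to-ancestor before
#' counting, as in standard GO practice). High-frequency terms are broad,
#' uninformative ones.
#'
#' @param lib Annotation library tibble.
#' @param dag An `onto_dag` containing `term`.
#' @param term Term id.
#' @param universe Character vector of universe genes.
#' @return Frequency in \[0, 1\].
#' @export
term_frequency <- function(lib, dag, term, universe) {
  if (!term %in% dag$terms) {
    rwhn_abort("unknown_term", paste0("term not in ontology: ", term))
  }
  fam <- ontology_descendants(dag, term)
  gs <- gene_sets(lib)
  genes <- unique(unlist(gs[intersect(names(gs), fam)], use.names = FALSE))
  length(intersect(genes, universe)) / length(universe)
}
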