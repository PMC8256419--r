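# Small fixtures and independent oracles, built in code at test time.

tiny_quant <- function() {
  quant_tbl(tibble::tibble(
    protein = c("P1", "P1", "P2"),
    residue = c("S", "T", "Y"),
    position = c(12L, 40L, 7L),
    t1 = c(1.0, 0.4, 2.5),
    t2 = c(1.1, 0.5, 2.6),
    t3 = c(1.2, 0.6, 2.4),
    t4 = c(1.3, 0.7, 2.7)))
}

# root R with is_a children A and B: the documented Wang toy
toy_dag <- function() {
  onto_dag(terms = c("R", "A", "B"),
           edges = tibble::tibble(child = c("A", "B"), parent = c("R", "R"),
                                  relation = c("is_a", "is_a")))
}

hard_clusters <- function(site_id, cluster, protein = NULL) {
  if (is.null(protein)) protein <- sub("_.*$", "", site_id)
  structure(tibble::tibble(site_id = site_id, protein = protein,
                           cluster = cluster),
            class = c("site_clusters", class(tibble::tibble())))
}

# independent Wang oracle: enumerate every directed path from the term to
# each ancestor; S-value = max over paths of the product of edge factors
wang_oracle <- function(dag, t1, t2, w = c(is_a = 0.8, part_of = 0.6)) {
  svals <- function(term) {
    s <- c()
    recurse <- function(node, value) {
      s[node] <<- max(s[node], value, na.rm = TRUE)
      e <- dag$edges[dag$edges$child == node, ]
      for (i in seq_len(nrow(e))) {
        recurse(e$parent[i], value * unname(w[e$relation[i]]))
      }
    }
    recurse(term, 1)
    s
  }
  s1 <- svals(t1); s2 <- svals(t2)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

# independent weighted-tau oracle: explicit loop over all item pairs with
# additive hyperbolic weights from each ranking in turn, then averaged
weighted_tau_oracle <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  one <- function(w_rank) {
    num <- 0; den <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        w <- 1 / (1 + w_rank[i]) + 1 / (1 + w_rank[j])
        num <- num + w * sign(a[i] - a[j]) * sign(b[i] - b[j])
        den <- den + w
      }
    }
    unname(num / den)
  }
  (one(a) + one(b)) / 2
}

# map planted cluster ids to fitted labels by majority vote
align_labels <- function(planted, fitted) {
  vapply(sort(unique(planted)), function(g) {
    as.integer(names(which.max(table(fitted[planted == g]))))
  }, 1L)
}

# seed clusters over a random multilayer network's sites
random_net_clusters <- function(net, k = 3) {
  hard_clusters(net$sites,
                rep_len(seq_len(k), length(net$sites)),
                protein = rep("X", length(net$sites)))
}

direct_steady_state <- function(m, p0, r) {
  mat <- if (inherits(m, "rwhn_transition")) m$m else m
  n <- nrow(mat)
  as.numeric(solve(diag(n) - (1 - r) * Matrix::t(mat), r * p0))
}
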