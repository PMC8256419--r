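make_profiles <- function(values, clusters) {
  n <- nrow(values)
  qt <- quant_tbl(dplyr::bind_cols(
    tibble::tibble(protein = paste0("P", seq_len(n)), residue = "S",
                   position = seq_len(n)),
    tibble::as_tibble(values)))
  list(qt = qt, cl = hard_clusters(site_ids(qt), clusters, qt$protein))
}

test_that("site edges require co-membership and near-perfect correlation", {
  vals <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(1, 2, 3, 6), c(1, 2, 3, 4),
                c(5, 5, 5, 5))
  colnames(vals) <- paste0("t", 1:4)
  fx <- make_profiles(vals, c(1, 1, 1, 2, 1))
  a <- build_site_subnetwork(fx$qt, fx$cl, threshold = 0.99)
  ids <- site_ids(fx$qt)
  expect_equal(a[ids[1], ids[2]], 1)  # r^2 = 1, same cluster
  expect_equal(a[ids[1], ids[3]], 0)  # r^2 ~ 0.878 < 0.99
  expect_equal(a[ids[1], ids[4]], 0)  # identical profile, other cluster
  expect_equal(sum(a[ids[5], ]), 0)   # constant profile: no edges
  expect_true(Matrix::isSymmetric(a))
  expect_true(all(Matrix::diag(a) == 0))
  # plain-r option applies the cutoff to r rather than r^2
  ar <- build_site_subnetwork(fx$qt, fx$cl, threshold = 0.93, square = FALSE)
  expect_equal(ar[ids[1], ids[3]], 1)
})

test_that("site edges depend only on cluster co-membership, not labels", {
  st <- generate_planted_study(n_clusters = 2, sites_per_cluster = 8,
                               seed = 31)
  relabeled <- st$clusters
  relabeled$cluster <- 3L - relabeled$cluster   # swap 1 <-> 2
  a1 <- build_site_subnetwork(st$quant, st$clusters)
  a2 <- build_site_subnetwork(st$quant, relabeled)
  expect_equal(a1, a2)
})

test_that("protein layer is the data proteins plus their first shell", {
  ppi <- ppi_network(tibble::tibble(
    protein_a = c("A", "B", "A", "B2", "D"),
    protein_b = c("B", "C", "B2", "B", "E"),
    score = c(0.9, 0.8, 0.7, 0.7, 0.9)))
  a <- build_protein_subnetwork(ppi, data_proteins = c("A", "Z"))
  # A's interactor B in; C only reachable through B: out; isolated data
  # protein Z kept; D-E disconnected from data: out
  expect_setequal(rownames(a), c("A", "B", "B2", "Z"))
  expect_equal(sum(a["Z", ]), 0)
  expect_equal(a["B", "B2"], 1)  # edge among included interactors retained
})

test_that("Louvain modules resolve disconnected cliques deterministically", {
  nodes <- c(paste0("a", 1:5), paste0("b", 1:5))
  a <- rwhn:::empty_adjacency(nodes, nodes)
  for (g in list(1:5, 6:10)) {
    for (i in g) for (j in g) if (i != j) a[i, j] <- 1
  }
  mod <- detect_modules(a, seed = 2)
  expect_equal(dplyr::n_distinct(mod$module), 2)
  expect_equal(dplyr::n_distinct(mod$module[1:5]), 1)
  expect_equal(dplyr::n_distinct(mod$module[6:10]), 1)
  expect_identical(mod, detect_modules(a, seed = 2))
})

test_that("module enrichment matches the closed-form hypergeometric", {
  universe <- paste0("g", 1:20)
  lib <- tibble::tibble(term = c("hit", "offset", "nohit"),
                        name = c("h", "o", "n"),
                        genes = list(paste0("g", 1:5), paste0("g", 4:9),
                                     paste0("g", 11:12)))
  modules <- tibble::tibble(protein = paste0("g", 1:5), module = 1L)
  enr <- enrich_modules(modules, lib, universe, alpha = 0.05)
  hit <- enr$table[enr$table$term == "hit", ]
  expect_equal(hit$p, 1 / choose(20, 5), tolerance = 1e-12)
  # zero-overlap terms are never tested
  expect_false("nohit" %in% enr$table$term)
  # BH within the module
  expect_equal(enr$table$q, stats::p.adjust(enr$table$p, "BH"))
  # bipartite edges only to annotated module proteins of retained terms
  expect_true("hit" %in% colnames(enr$a_pf))
  expect_equal(sum(enr$a_pf[, "hit"]), 5)
  expect_error(enrich_modules(modules, lib, character()),
               class = "rwhn_error_empty_universe")
})

test_that("broad and redundant terms are filtered", {
  dag <- onto_dag(terms = c("root", "broad", "s1", "s2"),
                  edges = tibble::tibble(child = c("broad", "s1", "s2"),
                                         parent = c("root", "broad", "s1"),
                                         relation = "is_a"))
  universe <- paste0("g", 1:100)
  lib <- tibble::tibble(term = c("broad", "s1", "s2"),
                        name = c("b", "s1", "s2"),
                        genes = list(paste0("g", 1:6), paste0("g", 1:3),
                                     paste0("g", 1)))
  # broad: 6% > 5% -> removed; sim(s1, s2) = 0.8145 < 0.9 -> both kept
  kept <- filter_function_terms(c("broad", "s1", "s2"), dag, lib, universe)
  expect_setequal(kept, c("s1", "s2"))
  # with a lenient redundancy cutoff the higher-frequency term of the
  # similar pair is dropped
  kept2 <- filter_function_terms(c("s1", "s2"), dag, lib, universe,
                                 redundancy_cutoff = 0.8)
  expect_equal(kept2, "s2")
  # identity when nothing exceeds either cutoff
  expect_equal(filter_function_terms(c("s1", "s2"), dag, lib, universe),
               c("s1", "s2"))
})

test_that("function subnetwork applies strict similarity thresholds", {
  chain <- onto_dag(terms = c("A", "B", "C"),
                    edges = tibble::tibble(child = c("B", "C"),
                                           parent = c("A", "B"),
                                           relation = "is_a"))
  a <- build_function_subnetwork(c("A", "B", "C"), mode = "go", dag = chain)
  # sim(B, C) = 0.764 > 0.7 -> edge; sim(A, B) = 0.643 -> none; no loops
  expect_equal(a["B", "C"], 1)
  expect_equal(a["A", "B"], 0)
  expect_true(all(Matrix::diag(a) == 0))

  lib <- tibble::tibble(term = c("K1", "K2"), name = c("k1", "k2"),
                        genes = list(paste0("g", 1:4), paste0("g", 2:5)))
  ak <- build_function_subnetwork(c("K1", "K2"), mode = "kegg", lib = lib)
  expect_equal(ak["K1", "K2"], 1)  # overlap 3/4 = 0.75 > 0.7
})

test_that("assembled multilayer networks satisfy the block contracts", {
  st <- generate_planted_study(seed = 17)
  net <- assemble_multilayer(st$quant, st$clusters, st$ppi, st$lib,
                             dag = st$dag, mode = "kegg", seed = 2)
  full <- full_adjacency(net)
  expect_true(Matrix::isSymmetric(full))
  expect_equal(nrow(full),
               length(net$sites) + length(net$proteins) +
                 length(net$functions))
  expect_true(all(Matrix::rowSums(net$a_rp) == 1))  # one host per site
  expect_true(all(net$a_rr@x %in% c(0, 1)))
  expect_true(all(colnames(net$a_pf) == net$functions))
})
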