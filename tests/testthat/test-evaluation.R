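test_that("network permutation keeps bipartite blocks and degree multisets", {
  st <- generate_planted_study(n_clusters = 2, sites_per_cluster = 8,
                               n_background_proteins = 12, seed = 6)
  net <- assemble_multilayer(st$quant, st$clusters, st$ppi, st$lib,
                             dag = st$dag, mode = "kegg", seed = 1)
  perm <- permute_multilayer(net, seed = 11)
  expect_identical(as.matrix(perm$a_rp), as.matrix(net$a_rp))
  expect_identical(as.matrix(perm$a_pf), as.matrix(net$a_pf))
  for (b in c("a_rr", "a_pp", "a_ff")) {
    expect_equal(unname(sort(Matrix::rowSums(perm[[b]]))),
                 unname(sort(Matrix::rowSums(net[[b]]))))
    expect_equal(Matrix::nnzero(perm[[b]]), Matrix::nnzero(net[[b]]))
    expect_identical(dimnames(perm[[b]]), dimnames(net[[b]]))
  }
  expect_identical(as.matrix(permute_multilayer(net, seed = 11)$a_pp),
                   as.matrix(perm$a_pp))
})

test_that("permutation significance reports calibrated add-one p-values", {
  net <- generate_random_multilayer(n_sites = 15, n_proteins = 12,
                                    n_functions = 10, seed = 21)
  cl <- random_net_clusters(net, k = 2)
  ps <- permutation_significance(net, cl, n_perm = 19, seed = 2)
  tp <- tidy(ps)
  n_rows <- dplyr::n_distinct(tp$term_id) * dplyr::n_distinct(tp$seed_cluster)
  expect_equal(nrow(tp), n_rows)
  expect_true(all(tp$p_empirical >= 1 / 20))   # never zero
  expect_true(all(tp$p_empirical <= 1))
  expect_true(all(tp$p_adjusted >= tp$p_empirical))
  expect_equal(nrow(attr(ps, "null_ranks")),
               19 * n_rows)
  expect_error(permutation_significance(net, cl, n_perm = 0, seed = 1),
               class = "rwhn_error_bad_perm_count")
})

test_that("over-representation analysis matches the closed form", {
  universe <- paste0("g", 1:20)
  lib <- tibble::tibble(term = c("hit", "miss"), name = c("h", "m"),
                        genes = list(paste0("g", 1:5), paste0("g", 18:20)))
  res <- ora(paste0("g", 1:5), lib, universe, alpha = 0.05)
  expect_equal(res$term, "hit")
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_lt(res$q, 0.05)

  none <- ora("g17", lib, universe)  # g17 is not annotated anywhere
  expect_equal(nrow(none), 0)
  expect_error(ora(character(), lib, universe),
               class = "rwhn_error_empty_cluster")

  # single-module enrichment and ORA share the same hypergeometric core
  modules <- tibble::tibble(protein = paste0("g", 1:5), module = 1L)
  enr <- enrich_modules(modules, lib, universe)
  expect_equal(enr$table$p[enr$table$term == "hit"], res$p)
})

test_that("weighted tau matches brute-force pair enumeration", {
  items <- paste0("i", 1:5)
  ident <- stats::setNames(1:5, items)
  expect_equal(weighted_tau(ident, ident), 1)
  expect_lt(weighted_tau(ident, stats::setNames(5:1, items)), 0)
  set.seed(31)
  for (rep in 1:20) {
    a <- stats::setNames(sample(5), items)
    b <- stats::setNames(sample(5), items)
    expect_equal(weighted_tau(a, b), weighted_tau_oracle(a, b),
                 tolerance = 1e-12)
    expect_gte(weighted_tau(a, b), -1)
    expect_lte(weighted_tau(a, b), 1)
  }
  expect_error(weighted_tau(ident, stats::setNames(1:5, paste0("j", 1:5))),
               class = "rwhn_error_item_mismatch")
})
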