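# a hand-checkable network: two co-clustered sites on one protein, the
# protein linked to a second protein annotated to one of two terms
hand_net <- function() {
  sites <- c("s1", "s2"); proteins <- c("p1", "p2"); funs <- c("f1", "f2")
  a_rr <- rwhn:::empty_adjacency(sites, sites)
  a_rr["s1", "s2"] <- 1; a_rr["s2", "s1"] <- 1
  a_pp <- rwhn:::empty_adjacency(proteins, proteins)
  a_pp["p1", "p2"] <- 1; a_pp["p2", "p1"] <- 1
  a_ff <- rwhn:::empty_adjacency(funs, funs)
  a_ff["f1", "f2"] <- 1; a_ff["f2", "f1"] <- 1
  a_rp <- rwhn:::empty_adjacency(sites, proteins)
  a_rp["s1", "p1"] <- 1; a_rp["s2", "p1"] <- 1
  a_pf <- rwhn:::empty_adjacency(proteins, funs)
  a_pf["p2", "f1"] <- 1
  rwhn:::new_multilayer_net(sites = sites, proteins = proteins,
                            functions = funs, a_rr = a_rr, a_pp = a_pp,
                            a_ff = a_ff, a_rp = a_rp, a_pf = a_pf)
}

test_that("transition rows allocate lambda across layers as specified", {
  net <- hand_net()
  tm <- build_transition_matrix(net, lambda = 0.5)
  m <- as.matrix(tm$m)
  # site with one intra neighbour and its host: lambda to the host,
  # 1 - lambda to the neighbour
  expect_equal(m["s1", "s2"], 0.5)
  expect_equal(m["s1", "p1"], 0.5)
  # p1 carries sites but no annotations: cross mass all to the site layer,
  # split equally between its two sites
  expect_equal(m["p1", "s1"], 0.25)
  expect_equal(m["p1", "s2"], 0.25)
  expect_equal(m["p1", "p2"], 0.5)
  # p2 is annotated but has no sites: cross mass all to functions
  expect_equal(m["p2", "f1"], 0.5)
  expect_equal(m["p2", "p1"], 0.5)
  # f1 has an intra edge and its protein; f2 intra only
  expect_equal(m["f1", "p2"], 0.5)
  expect_equal(m["f1", "f2"], 0.5)
  expect_equal(m["f2", "f1"], 1)
})

test_that("a site without site-site edges sends all mass to its host", {
  net <- hand_net()
  net$a_rr[] <- 0
  m <- as.matrix(build_transition_matrix(net, lambda = 0.5)$m)
  expect_equal(m["s1", "p1"], 1)
  expect_equal(sum(m["s1", ]), 1)
})

test_that("proteins touching both bipartite layers split lambda", {
  net <- hand_net()
  net$a_pf["p1", "f2"] <- 1   # p1 now adjacent to sites AND functions
  m <- as.matrix(build_transition_matrix(net, lambda = 0.6)$m)
  expect_equal(m["p1", "s1"], 0.15)  # lambda/2 split over two sites
  expect_equal(m["p1", "f2"], 0.3)   # lambda/2 to its one function
  expect_equal(m["p1", "p2"], 0.4)
  # proportional-to-degree alternative: 2 site edges vs 1 function edge
  md <- as.matrix(build_transition_matrix(net, lambda = 0.6,
                                          protein_split = "degree")$m)
  expect_equal(md["p1", "s1"], 0.6 * (2 / 3) / 2)
  expect_equal(md["p1", "f2"], 0.6 * (1 / 3))
})

test_that("every connected row of the transition matrix is stochastic", {
  for (s in 1:20) {
    net <- generate_random_multilayer(n_sites = 12, n_proteins = 10,
                                      n_functions = 8, seed = s)
    m <- build_transition_matrix(net, lambda = 0.7)$m
    rs <- Matrix::rowSums(m)
    connected <- Matrix::rowSums(full_adjacency(net)) > 0
    expect_true(all(abs(rs[connected] - 1) < 1e-12))
    expect_true(all(rs[!connected] == 0))
  }
})

test_that("initial vectors place mass on seeds and weighted layers", {
  net <- hand_net()
  p0 <- make_initial_vector(net, seeds = c("s1", "s2"), eta_p = 0,
                            eta_f = 0)
  expect_equal(unname(p0), c(0.5, 0.5, 0, 0, 0, 0))
  for (ep in c(0, 0.3, 0.7)) {
    for (ef in c(0, 0.3, 1)) {
      p <- make_initial_vector(net, "s1", eta_p = ep, eta_f = ef)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(unname(p["s2"]), 0)   # non-seed sites stay at zero
    }
  }
  expect_error(make_initial_vector(net, character()),
               class = "rwhn_error_empty_seeds")
  expect_error(make_initial_vector(net, "p1"),
               class = "rwhn_error_empty_seeds")
})

test_that("the walk matches the direct linear solve and its limits", {
  for (s in 1:5) {
    net <- generate_random_multilayer(n_sites = 20, n_proteins = 18,
                                      n_functions = 12, p_rr = 0.2,
                                      p_pp = 0.25, p_ff = 0.2, p_pf = 0.2,
                                      seed = 100 + s)
    tm <- build_transition_matrix(net, lambda = 0.7)
    p0 <- make_initial_vector(net, net$sites[1:4])
    ss <- random_walk(tm, p0, r = 0.7)
    expect_lt(max(abs(ss - direct_steady_state(tm, p0, 0.7))), 1e-8)
    # restart-only limit
    expect_identical(random_walk(tm, p0, r = 1), p0)
    # linearity: scaling the initial vector scales the steady state
    expect_equal(random_walk(tm, 2 * p0, r = 0.7), 2 * ss,
                 tolerance = 1e-9)
  }
  net <- generate_random_multilayer(n_sites = 10, n_proteins = 8,
                                    n_functions = 6, p_rr = 0.6, p_pp = 0.6,
                                    p_ff = 0.6, p_pf = 0.5, seed = 9)
  tm <- build_transition_matrix(net, lambda = 0.7)
  p0 <- make_initial_vector(net, net$sites[1:2])
  if (all(Matrix::rowSums(tm$m) > 0)) {
    expect_equal(sum(random_walk(tm, p0, r = 0.7)), 1, tolerance = 1e-9)
  }
  expect_error(random_walk(tm, p0, r = 0.7, max_iter = 2),
               class = "rwhn_error_no_convergence")
})

test_that("ranking extraction is deterministic with lexicographic ties", {
  net <- generate_random_multilayer(n_sites = 4, n_proteins = 4,
                                    n_functions = 6, seed = 5)
  nodes <- c(net$sites, net$proteins, net$functions)
  make_ss <- function(fvals) {
    p <- stats::setNames(rep(0.01, length(nodes)), nodes)
    p[net$functions] <- fvals
    p
  }
  # ties between F002 and F003 resolved by term id
  ss <- list(`1` = make_ss(c(0.5, 0.3, 0.3, 0.2, 0.1, 0.05)),
             `2` = make_ss(c(0.5, 0.1, 0.2, 0.3, 0.25, 0.05)))
  rk <- extract_function_ranking(ss, net, top_fraction = 0.5)
  r1 <- rk[rk$seed_cluster == "1", ]
  expect_equal(r1$term_id[1:3], c("F001", "F002", "F003"))
  expect_equal(r1$rank, 1:6)
  # F001 and F006 hold the same rank in both clusters: removed before the
  # cut, and the retained count is over the surviving terms
  expect_true(all(rk$constant_rank[rk$term_id %in% c("F001", "F006")]))
  expect_false(any(rk$retained[rk$term_id == "F001"]))
  expect_equal(sum(rk$retained[rk$seed_cluster == "1"]), ceiling(0.5 * 4))
  # a single seed cluster skips constant-rank removal
  rk1 <- extract_function_ranking(ss[1], net, top_fraction = 0.5)
  expect_false(any(rk1$constant_rank))
  expect_equal(sum(rk1$retained), 3)
})

test_that("the full walk is deterministic and order-invariant", {
  st <- generate_planted_study(n_clusters = 2, sites_per_cluster = 8,
                               n_background_proteins = 12, seed = 3)
  net <- assemble_multilayer(st$quant, st$clusters, st$ppi, st$lib,
                             dag = st$dag, mode = "kegg", seed = 4)
  rk1 <- run_rwhn(net, st$clusters)
  rk2 <- run_rwhn(net, st$clusters)
  expect_identical(rk1, rk2)

  # permuting the input row order leaves the rankings unchanged
  perm <- sample(nrow(st$quant))
  qt_p <- quant_tbl(tibble::as_tibble(st$quant)[perm, ],
                    conditions = quant_conditions(st$quant))
  cl_p <- st$clusters[perm, ]
  net_p <- assemble_multilayer(qt_p, cl_p, st$ppi, st$lib,
                               dag = st$dag, mode = "kegg", seed = 4)
  rk_p <- run_rwhn(net_p, cl_p)
  key <- function(x) {
    tb <- tidy(x)
    tb[order(tb$seed_cluster, tb$term_id), ]
  }
  expect_equal(key(rk_p)$rank, key(rk1)$rank)
  expect_equal(key(rk_p)$probability, key(rk1)$probability,
               tolerance = 1e-9)
})
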