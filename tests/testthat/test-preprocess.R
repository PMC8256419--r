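test_that("regulation filter keeps responsive, well-quantified sites", {
  qt <- quant_tbl(tibble::tibble(
    protein = c("A", "B", "C"), residue = "S", position = c(1L, 2L, 3L),
    t1 = c(1.0, 1.0, 0.4), t2 = c(1.1, 1.1, NA),
    t3 = c(2.5, 1.2, NA), t4 = c(NA, 1.3, 1.0)))
  out <- filter_regulated_sites(qt)
  # A: one ratio > 2 with one missing -> kept; B: all within [0.5, 2] ->
  # dropped; C: regulated but two missing -> dropped
  expect_equal(out$protein, "A")
  # idempotence
  expect_equal(filter_regulated_sites(out), out)
})

test_that("regulation bounds are strict", {
  qt <- quant_tbl(tibble::tibble(protein = "A", residue = "S", position = 1L,
                                 t1 = 2.0, t2 = 0.5, t3 = 1.0))
  expect_equal(nrow(filter_regulated_sites(qt)), 0)
})

test_that("left-censored imputation fills low values deterministically", {
  set.seed(99)
  base <- matrix(2^stats::rnorm(120, 0, 1), 30, 4,
                 dimnames = list(NULL, paste0("t", 1:4)))
  qt <- quant_tbl(dplyr::bind_cols(
    tibble::tibble(protein = paste0("P", 1:30), residue = "S",
                   position = seq_len(30)),
    tibble::as_tibble(base)))
  miss <- qt
  miss$t2[c(3, 7)] <- NA; miss$t4[10] <- NA

  out <- impute_left_censored(miss, seed = 5)
  expect_false(anyNA(quant_matrix(out)))
  # observed cells untouched
  obs_mask <- !is.na(quant_matrix(miss))
  expect_equal(quant_matrix(out)[obs_mask], quant_matrix(miss)[obs_mask])
  # imputed values never exceed the truncation bound, recomputed here
  for (cc in c("t2", "t4")) {
    obs_log <- log2(miss[[cc]][!is.na(miss[[cc]])])
    bound <- stats::quantile(obs_log, 0.01, names = FALSE)
    imputed <- log2(out[[cc]][is.na(miss[[cc]])])
    expect_true(all(imputed <= bound))
  }
  # determinism and identity on complete tables
  expect_identical(out, impute_left_censored(miss, seed = 5))
  expect_identical(impute_left_censored(qt, seed = 5), qt)

  short <- quant_tbl(tibble::tibble(protein = c("A", "B", "C"), residue = "S",
                                    position = 1:3, t1 = c(1, NA, NA)))
  expect_error(impute_left_censored(short, seed = 1),
               class = "rwhn_error_insufficient_data")
})

test_that("quantile normalization equalises column distributions", {
  qt <- quant_tbl(tibble::tibble(protein = c("A", "B"), residue = "S",
                                 position = 1:2, c1 = c(1, 3), c2 = c(2, 4)))
  out <- quant_matrix(quantile_normalize(qt))
  expect_equal(unname(out[, "c1"]), c(1.5, 3.5))   # hand-computed rank means
  expect_equal(unname(out[, "c2"]), c(1.5, 3.5))

  set.seed(4)
  qt2 <- quant_tbl(dplyr::bind_cols(
    tibble::tibble(protein = paste0("P", 1:20), residue = "S",
                   position = 1:20),
    tibble::as_tibble(matrix(2^stats::rnorm(60), 20, 3,
                             dimnames = list(NULL, paste0("t", 1:3))))))
  m <- quant_matrix(quantile_normalize(qt2))
  expect_equal(unname(sort(m[, 1])), unname(sort(m[, 2])))
  expect_equal(unname(sort(m[, 2])), unname(sort(m[, 3])))
  # within-column order preserved
  expect_equal(order(m[, 1]), order(quant_matrix(qt2)[, 1]))

  with_na <- qt2; with_na$t1[1] <- NA
  expect_error(quantile_normalize(with_na), class = "rwhn_error_missing_data")
})

test_that("profile clustering recovers planted archetypes", {
  st <- generate_planted_study(n_clusters = 2, sites_per_cluster = 10,
                               seed = 12)
  cl <- cluster_profiles(st$quant, k = 2, method = "fcm", seed = 3)
  tab <- table(st$clusters$cluster, cl$cluster)
  expect_equal(unname(sort(apply(tab, 1, max))), c(10, 10))  # pure up to relabeling
  memb <- attr(cl, "memberships")
  expect_true(all(abs(rowSums(memb) - 1) < 1e-9))
  expect_equal(cl$cluster, unname(apply(memb, 1, which.max)))

  km <- cluster_profiles(st$quant, k = 2, method = "kmeans", seed = 3)
  expect_null(attr(km, "memberships"))
  expect_identical(cluster_profiles(st$quant, k = 2, seed = 3),
                   cluster_profiles(st$quant, k = 2, seed = 3))

  one <- cluster_profiles(st$quant, k = 1, method = "fcm", seed = 1)
  expect_true(all(one$cluster == 1L))
  expect_error(cluster_profiles(st$quant, k = 0, seed = 1),
               class = "rwhn_error_bad_k")
  expect_error(cluster_profiles(st$quant, k = 1000, seed = 1),
               class = "rwhn_error_bad_k")
})

test_that("cluster-number selection finds the planted k", {
  st <- generate_planted_study(n_clusters = 3, sites_per_cluster = 12,
                               seed = 8)
  expect_equal(select_k(st$quant, 2:6, method = "silhouette", seed = 2), 3)
  expect_equal(select_k(st$quant, 2:6, method = "elbow", seed = 2), 3)
  expect_equal(select_k(st$quant, 4, seed = 2), 4)  # length-1 range
  expect_error(select_k(st$quant, 2:1000, seed = 2),
               class = "rwhn_error_bad_k")
})
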