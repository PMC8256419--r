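#' Keep regulated, well-quantified sites
#'
#' Applies the two standard regulation filters to a SILAC-style ratio table:
#' a site is kept when it has at most `max_missing` missing ratios (the
#' default removes sites with two or more) and at least one observed ratio
#' strictly greater than `hi` or strictly lower than `lo` (defaults 2 and
#' 0.5, i.e. a two-fold change in either direction). The operation is
#' idempotent.
#'
#' @param qt A [quant_tbl].
#' @param max_missing Maximum number of missing ratios tolerated per site.
#' @param lo,hi Regulation bounds on the ratio scale; `lo < hi`.
#' @return The filtered [quant_tbl].
#' @export
filter_regulated_sites <- function(qt, max_missing = 1, lo = 0.5, hi = 2) {
  stopifnot(lo < hi)
  m <- quant_matrix(qt)
  n_miss <- rowSums(is.na(m))
  regulated <- apply(m, 1, function(v) any(v > hi | v < lo, na.rm = TRUE))
  keep <- n_miss <= max_missing & regulated
  quant_tbl(tibble::as_tibble(qt)[keep, , drop = FALSE],
            conditions = quant_conditions(qt))
}

#' Impute left-censored missing ratios
#'
#' Missing phosphoproteomics quantifications are predominantly
#' left-censored: low-abundance signals fall below the detection limit. Each
#' condition column is imputed independently with draws from a normal
#' distribution fitted to the observed log2 ratios of that column and
#' truncated from above at the column's `censor_quantile` quantile, so
#' imputed values land in the low tail (a QRILC-style scheme). Draws are
#' made on the log2 scale and back-transformed; observed cells are never
#' altered and the result is deterministic given `seed`.
#'
#' @param qt A [quant_tbl] (ratios must be positive).
#' @param seed Integer seed for the truncated draws.
#' @param censor_quantile Upper truncation point, as a quantile of the
#'   observed log2 values per column (default 0.01).
#' @return A [quant_tbl] with no missing values.
#' @export
impute_left_censored <- function(qt, seed = 1L, censor_quantile = 0.01) {
  m <- quant_matrix(qt)
  if (!anyNA(m)) return(qt)
  if (any(m <= 0, na.rm = TRUE)) {
    rwhn_abort("parse_error", "ratios must be positive for log-scale imputation")
  }
  lm2 <- log2(m)
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(lm2))) {
    obs <- lm2[!is.na(lm2[, j]), j]
    if (length(obs) < 3) {
      rwhn_abort("insufficient_data", paste0(
        "condition ", colnames(lm2)[j], " has fewer than 3 observed values"))
    }
    miss <- which(is.na(lm2[, j]))
    if (!length(miss)) next
    mu <- mean(obs); sd <- stats::sd(obs)
    if (sd == 0) sd <- 1e-8
    bound <- stats::quantile(obs, censor_quantile, names = FALSE)
    # inverse-CDF sampling from N(mu, sd) truncated above at `bound`
    p_hi <- stats::pnorm(bound, mu, sd)
    u <- stats::runif(length(miss), min = 0, max = p_hi)
    lm2[miss, j] <- stats::qnorm(u, mu, sd)
  }
  set_quant_matrix(qt, 2^lm2)
}

#' Quantile-normalize condition columns
#'
#' Forces every condition column onto the identical distribution (the
#' per-rank mean of the input columns) while preserving within-column
#' ordering, via [limma::normalizeQuantiles()]. Requires a complete matrix.
#'
#' @param qt A [quant_tbl] without missing values.
#' @return The normalized [quant_tbl].
#' @export
quantile_normalize <- function(qt) {
  m <- quant_matrix(qt)
  if (anyNA(m)) {
    rwhn_abort("missing_data", "quantile normalization requires a complete matrix; impute first")
  }
  set_quant_matrix(qt, limma::normalizeQuantiles(m))
}

#' Cluster site regulation profiles
#'
#' Groups sites by the shape of their per-condition profile with fuzzy
#' C-means (via [e1071::cmeans()]) or k-means. Fuzzy clustering returns the
#' full membership matrix; hard labels are the argmax memberships.
#'
#' @param qt A complete [quant_tbl].
#' @param k Number of clusters, `1 <= k <=` number of sites.
#' @param method `"fcm"` (default) or `"kmeans"`.
#' @param fuzzifier Fuzziness exponent m for FCM (default 2).
#' @param seed Integer seed (k-means uses 25 restarts under it).
#' @return A `site_clusters` tibble with columns `site_id`, `protein`,
#'   `cluster`; FCM memberships in the `"memberships"` attribute.
#' @export
cluster_profiles <- function(qt, k, method = c("fcm", "kmeans"),
                             fuzzifier = 2, seed = 1L) {
  method <- match.arg(method)
  m <- quant_matrix(qt)
  if (anyNA(m)) rwhn_abort("missing_data", "clustering requires a complete matrix")
  if (k < 1 || k > nrow(m)) {
    rwhn_abort("bad_k", paste0("k must be in [1, ", nrow(m), "]"))
  }
  set.seed(as.integer(seed))
  memberships <- NULL
  if (k == 1) {
    labels <- rep(1L, nrow(m))
    if (method == "fcm") {
      memberships <- matrix(1, nrow(m), 1, dimnames = list(rownames(m), NULL))
    }
  } else if (method == "fcm") {
    fit <- e1071::cmeans(m, centers = k, m = fuzzifier,
                         iter.max = 1000, method = "cmeans")
    labels <- as.integer(fit$cluster)
    memberships <- fit$membership
    rownames(memberships) <- rownames(m)
  } else {
    fit <- stats::kmeans(m, centers = k, nstart = 25, iter.max = 100)
    labels <- as.integer(fit$cluster)
  }
  new_site_clusters(tibble::tibble(site_id = rownames(m),
                                   protein = qt$protein,
                                   cluster = labels),
                    memberships = memberships)
}

new_site_clusters <- function(tbl, memberships = NULL) {
  structure(tbl,
            memberships = memberships,
            class = c("site_clusters", class(tibble::tibble())))
}

#' @export
print.site_clusters <- function(x, ...) {
  cat("# Site clusters: ", nrow(x), " sites in ",
      length(unique(x$cluster)), " cluster(s)",
      if (!is.null(attr(x, "memberships"))) " (fuzzy)", "\n", sep = "")
  NextMethod()
}

#' Choose the number of clusters
#'
#' `"elbow"` picks the k maximising the second difference of the
#' within-cluster sum of squares across `k_range` (the sharpest knee);
#' `"silhouette"` picks the k maximising the mean silhouette width
#' ([cluster::silhouette()]). Clustering at each k uses k-means under the
#' given seed for both scores.
#'
#' @param qt A complete [quant_tbl].
#' @param k_range Integer vector of candidate k (within `[2, n_sites - 1]`).
#' @param method `"silhouette"` (default) or `"elbow"`.
#' @param seed Integer seed.
#' @return The selected k (integer).
#' @export
select_k <- function(qt, k_range = 2:8, method = c("silhouette", "elbow"),
                     seed = 1L) {
  method <- match.arg(method)
  m <- quant_matrix(qt)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0 || min(k_range) < 1 || max(k_range) > nrow(m) - 1) {
    rwhn_abort("bad_k", "k_range must lie within [1, n_sites - 1]")
  }
  if (length(k_range) == 1) return(k_range)
  set.seed(as.integer(seed))
  fits <- lapply(k_range, function(k)
    stats::kmeans(m, centers = k, nstart = 25, iter.max = 100))
  if (method == "elbow") {
    wss <- vapply(fits, function(f) f$tot.withinss, 1.0)
    if (length(k_range) < 3) return(k_range[which.min(wss)])
    d2 <- wss[-c(length(wss) - 1, length(wss))] -
      2 * wss[-c(1, length(wss))] + wss[-(1:2)]
    k_range[which.max(d2) + 1L]
  } else {
    d <- stats::dist(m)
    sil <- vapply(fits, function(f) {
      if (length(unique(f$cluster)) < 2) return(-1)
      mean(cluster::silhouette(f$cluster, d)[, "sil_width"])
    }, 1.0)
    k_range[which.max(sil)]
  }
}
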