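#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent named list) with input paths,
#' the annotation mode and the numeric parameters of every stage. Every
#' parameter has the method's default, so a minimal config only names the
#' inputs and the output directory.
#'
#' @param path Path to a YAML file.
#' @return Validated config list of class `rwhn_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    rwhn_abort("config_error", paste0("config file not found: ", path))
  }
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param x Named list of config entries (see Details).
#' @details Recognised entries: `quant`, `ppi`, `gmt`, `obo` (input paths),
#'   `mode` (`"go"`/`"kegg"`), `out_dir`, `seed`, `k` (integer, or `"auto"`
#'   with `k_range` and `k_method`), `cluster_method`, `max_missing`, `lo`,
#'   `hi`, `censor_quantile`, `ppi_channel`, `string_threshold`,
#'   `site_cor_threshold`, `fun_sim_threshold`, `freq_cutoff`,
#'   `redundancy_cutoff`, `enrich_alpha`, `resolution`, `lambda`, `r`,
#'   `eta_p`, `eta_f`, `tol`, `max_iter`, `top_fraction`, `protein_split`,
#'   `n_perm`, `ora_alpha`.
#' @export
pipeline_config <- function(x) {
  defaults <- list(
    quant = NULL, ppi = NULL, gmt = NULL, obo = NULL,
    mode = "go", out_dir = ".", seed = 1L,
    k = "auto", k_range = 2:8, k_method = "silhouette",
    cluster_method = "fcm", fuzzifier = 2,
    max_missing = 1, lo = 0.5, hi = 2, censor_quantile = 0.01,
    ppi_channel = "experimental", string_threshold = 0.4,
    site_cor_threshold = 0.99, fun_sim_threshold = 0.7,
    freq_cutoff = 0.05, redundancy_cutoff = 0.9, enrich_alpha = 0.05,
    resolution = 1,
    lambda = 0.7, r = 0.7, eta_p = 0.7, eta_f = 0.3,
    tol = 1e-10, max_iter = 10000, top_fraction = 0.05,
    protein_split = "half",
    n_perm = 0, ora_alpha = 0.05)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    rwhn_abort("config_error", paste0("unknown config field(s): ",
                                      paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, x)
  for (f in c("quant", "ppi", "gmt")) {
    if (is.null(cfg[[f]])) {
      rwhn_abort("config_error", paste0("missing required config field: ", f))
    }
  }
  if (identical(cfg$mode, "go") && is.null(cfg$obo)) {
    rwhn_abort("config_error", "missing required config field: obo (go mode)")
  }
  for (f in c("quant", "ppi", "gmt", "obo")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      rwhn_abort("config_error", paste0("input file not found (", f, "): ",
                                        cfg[[f]]))
    }
  }
  structure(cfg, class = "rwhn_config")
}

#' Run the full site-to-function pipeline
#'
#' Orchestrates preprocessing (regulation filter, left-censored imputation,
#' quantile normalization, clustering), multilayer network construction, the
#' per-cluster random walk, the ORA baseline and (optionally) the
#' permutation significance test, writing all outputs plus a JSON manifest
#' recording parameters, input checksums, the seed and per-stage node/edge
#' counts. One global seed derives all stage seeds by a fixed offset, so
#' every stage is individually reproducible and two runs with the same
#' config are byte-identical.
#'
#' @param config A `rwhn_config`, a named list, or a YAML path.
#' @return Invisibly, a list with `ranking`, `ora`, `permutation` (or NULL),
#'   `network`, `clusters`, `manifest` and the output file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "rwhn_config")) config
         else if (is.character(config)) read_pipeline_config(config)
         else pipeline_config(config)
  seed <- as.integer(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  qt <- read_quant_table(cfg$quant)
  ppi <- read_ppi_edges(cfg$ppi, channel = cfg$ppi_channel,
                        threshold = cfg$string_threshold)
  lib <- read_gmt(cfg$gmt)
  dag <- if (!is.null(cfg$obo)) read_obo(cfg$obo) else NULL

  qt <- filter_regulated_sites(qt, max_missing = cfg$max_missing,
                               lo = cfg$lo, hi = cfg$hi)
  if (nrow(qt) == 0) rwhn_abort("config_error", "no regulated sites survive filtering")
  qt <- impute_left_censored(qt, seed = seed + 1L,
                             censor_quantile = cfg$censor_quantile)
  qt <- quantile_normalize(qt)

  k <- if (identical(cfg$k, "auto")) {
    select_k(qt, k_range = cfg$k_range, method = cfg$k_method,
             seed = seed + 2L)
  } else as.integer(cfg$k)
  clusters <- cluster_profiles(qt, k = k, method = cfg$cluster_method,
                               fuzzifier = cfg$fuzzifier, seed = seed + 3L)

  net <- assemble_multilayer(qt, clusters, ppi, lib, dag = dag,
                             mode = cfg$mode,
                             site_cor_threshold = cfg$site_cor_threshold,
                             fun_sim_threshold = cfg$fun_sim_threshold,
                             freq_cutoff = cfg$freq_cutoff,
                             redundancy_cutoff = cfg$redundancy_cutoff,
                             alpha = cfg$enrich_alpha,
                             resolution = cfg$resolution, seed = seed + 4L)
  params <- rwhn_params(lambda = cfg$lambda, r = cfg$r,
                        eta_p = cfg$eta_p, eta_f = cfg$eta_f,
                        tol = cfg$tol, max_iter = cfg$max_iter,
                        top_fraction = cfg$top_fraction,
                        protein_split = cfg$protein_split)
  ranking <- run_rwhn(net, clusters, params)

  universe <- unique(c(net$proteins, unlist(lib$genes, use.names = FALSE)))
  ora_tab <- dplyr::bind_rows(lapply(sort(unique(clusters$cluster)),
    function(cl) {
      prot <- unique(clusters$protein[clusters$cluster == cl])
      res <- ora(prot, lib, universe, alpha = cfg$ora_alpha)
      if (nrow(res)) dplyr::mutate(res, cluster = cl, .before = 1) else NULL
    }))

  perm <- NULL
  if (cfg$n_perm > 0) {
    perm <- permutation_significance(net, clusters, params,
                                     n_perm = cfg$n_perm, seed = seed + 5L)
  }

  paths <- c(rankings = file.path(cfg$out_dir, "rankings.tsv"),
             ora = file.path(cfg$out_dir, "ora.tsv"),
             manifest = file.path(cfg$out_dir, "manifest.json"))
  write_rankings(ranking, paths["rankings"])
  readr::write_tsv(if (nrow(ora_tab)) ora_tab else
    tibble::tibble(cluster = integer(), term = character()),
    paths["ora"], progress = FALSE)
  if (!is.null(perm)) {
    paths["permutation"] <- file.path(cfg$out_dir, "permutation.tsv")
    readr::write_tsv(tibble::as_tibble(perm), paths["permutation"],
                     progress = FALSE)
  }

  inputs <- Filter(Negate(is.null), cfg[c("quant", "ppi", "gmt", "obo")])
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("quant", "ppi", "gmt", "obo",
                                           "out_dir"))],
    seed = seed,
    k_used = k,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    network = list(
      sites = length(net$sites),
      proteins = length(net$proteins),
      functions = length(net$functions),
      site_site_edges = Matrix::nnzero(net$a_rr) / 2,
      protein_protein_edges = Matrix::nnzero(net$a_pp) / 2,
      function_function_edges = Matrix::nnzero(net$a_ff) / 2,
      site_protein_edges = Matrix::nnzero(net$a_rp),
      protein_function_edges = Matrix::nnzero(net$a_pf)),
    outputs = as.list(paths))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(ranking = ranking, ora = ora_tab, permutation = perm,
                 network = net, clusters = clusters, quant = qt,
                 manifest = manifest, paths = paths))
}

#' Parameter sweeps against the default run
#'
#' Reruns the walk over a grid of one parameter and reports, per grid value,
#' the mean (across seed clusters) weighted Kendall tau between the sweep
#' ranking and the default-parameter ranking. For `string_threshold` the
#' protein layer itself changes, so the tau is computed over the shared term
#' set and the number of connected components of the protein layer is
#' reported alongside.
#'
#' @param config Pipeline config (list, `rwhn_config` or YAML path); used to
#'   load inputs and set defaults.
#' @param parameter One of `"lambda"`, `"r"`, `"eta_p"`, `"eta_f"`,
#'   `"string_threshold"`.
#' @param grid Numeric vector of values to test.
#' @return Tibble with `parameter`, `value`, `tau`, `n_components` (protein
#'   layer; NA except for string-threshold sweeps).
#' @export
sweep_parameters <- function(config, parameter, grid) {
  allowed <- c("lambda", "r", "eta_p", "eta_f", "string_threshold")
  if (!parameter %in% allowed) {
    rwhn_abort("unknown_parameter", paste0(
      "parameter must be one of: ", paste(allowed, collapse = ", ")))
  }
  cfg <- if (inherits(config, "rwhn_config")) config
         else if (is.character(config)) read_pipeline_config(config)
         else pipeline_config(config)
  base_dir <- cfg$out_dir
  cfg$out_dir <- file.path(tempdir(), "rwhn_sweep_base")
  base <- run_pipeline(cfg)

  mean_tau <- function(rank_a, rank_b) {
    cls <- intersect(unique(rank_a$seed_cluster), unique(rank_b$seed_cluster))
    taus <- vapply(cls, function(cl) {
      va <- ranking_vector(rank_a, cl); vb <- ranking_vector(rank_b, cl)
      shared <- intersect(names(va), names(vb))
      if (length(shared) < 2) return(NA_real_)
      weighted_tau(rank(va[shared], ties.method = "first"),
                   rank(vb[shared], ties.method = "first"))
    }, 1.0)
    mean(taus, na.rm = TRUE)
  }

  rows <- lapply(seq_along(grid), function(i) {
    cfg_i <- cfg
    cfg_i[[parameter]] <- grid[i]
    cfg_i$out_dir <- file.path(tempdir(), sprintf("rwhn_sweep_%02d", i))
    res <- run_pipeline(cfg_i)
    n_comp <- if (parameter == "string_threshold") {
      g <- igraph::graph_from_adjacency_matrix(
        methods::as(res$network$a_pp, "CsparseMatrix"), mode = "undirected")
      igraph::components(g)$no
    } else NA_integer_
    tibble::tibble(parameter = parameter, value = grid[i],
                   tau = mean_tau(res$ranking, base$ranking),
                   n_components = n_comp)
  })
  cfg$out_dir <- base_dir
  dplyr::bind_rows(rows)
}
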