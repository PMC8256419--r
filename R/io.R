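#' Read a quantitative phosphosite table
#'
#' Parses a delimited text file (TSV or CSV, autodetected from the header
#' line) with one row per phosphorylation site into a [quant_tbl]. Missing
#' ratios may be encoded as empty cells, `NA`, `NaN` (any case); they are
#' kept as `NA` and flagged by the missing mask implicit in the tibble.
#'
#' @param path Path to the delimited file.
#' @param id_columns Length-3 character vector naming the columns holding the
#'   protein accession, residue letter and 1-based position, in that order.
#' @param condition_columns Columns holding the ratios; default every other
#'   column.
#' @return A [quant_tbl] with row order preserved.
#' @export
read_quant_table <- function(path,
                             id_columns = c("protein", "residue", "position"),
                             condition_columns = NULL) {
  stopifnot(length(id_columns) == 3)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(id_columns, names(raw))
  if (length(missing_cols) > 0) {
    rwhn_abort("parse_error", paste0("id column(s) not found: ",
                                     paste(missing_cols, collapse = ", ")))
  }
  if (is.null(condition_columns)) {
    condition_columns <- setdiff(names(raw), id_columns)
  }
  out <- tibble::tibble(
    protein  = raw[[id_columns[1]]],
    residue  = raw[[id_columns[2]]],
    position = raw[[id_columns[3]]]
  )
  if (anyNA(suppressWarnings(as.integer(out$position)))) {
    rwhn_abort("parse_error", "malformed `position` value in quant table")
  }
  for (cc in condition_columns) {
    v <- trimws(raw[[cc]])
    v[v == "" | toupper(v) %in% c("NA", "NAN")] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) {
      rwhn_abort("parse_error", paste0("non-numeric ratio in column ", cc))
    }
    out[[cc]] <- num
  }
  quant_tbl(out, conditions = condition_columns)
}

#' Write a quant table
#'
#' @param qt A [quant_tbl].
#' @param path Output path; written as TSV at full precision.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(qt, path) {
  readr::write_tsv(tibble::as_tibble(qt), path, progress = FALSE)
  invisible(path)
}

#' Read a STRING-dialect protein interaction file
#'
#' Expects a whitespace- or tab-delimited flat file with a header naming at
#' least two protein id columns (`protein1`, `protein2`) and one or more
#' score channels on the STRING 0--1000 integer scale. Edges whose selected
#' channel score, divided by 1000, is strictly greater than `threshold` are
#' kept; self-loops are dropped and duplicate pairs merged keeping the
#' maximum score.
#'
#' @param path Path to the flat file.
#' @param channel Name of the score column to use (default `"experimental"`;
#'   pass `"combined_score"` for combined-score files).
#' @param threshold Confidence cutoff on the 0--1 scale (default 0.4; the
#'   inequality is strict).
#' @return Tibble with columns `protein_a`, `protein_b`, `score`, pairs
#'   stored canonically (`protein_a` < `protein_b`), scores in \[0, 1\].
#' @export
read_ppi_edges <- function(path, channel = "experimental", threshold = 0.4) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  cols <- names(raw)
  if (!channel %in% cols) {
    rwhn_abort("parse_error", paste0("score channel not found: ", channel))
  }
  sc <- suppressWarnings(as.numeric(raw[[channel]]))
  if (anyNA(sc)) rwhn_abort("parse_error", "non-numeric interaction score")
  ppi_network(tibble::tibble(
    protein_a = as.character(raw[[1]]),
    protein_b = as.character(raw[[2]]),
    score = sc / 1000
  ), threshold = threshold)
}

#' Construct a protein interaction network from an edge table
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`, `score`
#'   (scores already on the 0--1 scale).
#' @param threshold Keep edges with score strictly greater than this.
#' @return Canonicalised tibble of confident, de-duplicated, loop-free edges.
#' @export
ppi_network <- function(edges, threshold = 0) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(edges)))
  if (any(edges$score < 0 | edges$score > 1)) {
    rwhn_abort("parse_error", "interaction scores must lie in [0, 1]")
  }
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  out <- tibble::tibble(protein_a = a, protein_b = b, score = edges$score)
  out <- dplyr::filter(out, .data$protein_a != .data$protein_b,
                       .data$score > threshold)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$protein_a, .data$protein_b),
    score = max(.data$score), .groups = "drop")
  out
}

#' Read a GMT annotation library
#'
#' GMT lines are tab-delimited: term id, description, then one gene per
#' field. Gene sets are de-duplicated; a line with zero genes is an error.
#'
#' @param path Path to the GMT file.
#' @return An annotation library: tibble with columns `term`, `name` and a
#'   list-column `genes` of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    rwhn_abort("empty_term", paste0(
      "GMT line with no genes: ", strsplit(lines[bad][1], "\t")[[1]][1]))
  }
  tibble::tibble(
    term = vapply(parts, `[[`, "", 1L),
    name = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write an annotation library as GMT
#'
#' @param lib Annotation library tibble (`term`, `name`, `genes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  lines <- vapply(seq_len(nrow(lib)), function(i) {
    paste(c(lib$term[i], lib$name[i], lib$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene sets of an annotation library as a named list
#'
#' @param lib Annotation library tibble.
#' @return Named list of character vectors keyed by term id.
#' @export
gene_sets <- function(lib) {
  stats::setNames(lib$genes, lib$term)
}

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas keeping non-obsolete terms and the `is_a` and
#' `relationship: part_of` edges only. The result must be acyclic.
#'
#' @param path Path to the OBO file.
#' @return An `onto_dag`: list with `terms` (character), `names` (named
#'   character), `edges` (tibble `child`, `parent`, `relation`), `roots`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  stanza_starts <- which(grepl("^\\[", lines))
  ids <- character(); nms <- character()
  edges <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1):e]
    get1 <- function(key) {
      m <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(m)) sub(paste0("^", key, ": "), "", m) else character()
    }
    id <- get1("id")[1]
    if (is.na(id) || is.null(id)) next
    if (any(grepl("^is_obsolete: true", block))) next
    ids <- c(ids, id)
    nm <- get1("name")
    nms <- c(nms, stats::setNames(if (length(nm)) nm[1] else id, id))
    for (p in get1("is_a")) {
      edges[[length(edges) + 1L]] <-
        c(id, trimws(sub("!.*$", "", p)), "is_a")
    }
    rel <- grep("^relationship: part_of ", block, value = TRUE)
    for (p in rel) {
      tgt <- trimws(sub("!.*$", "", sub("^relationship: part_of ", "", p)))
      edges[[length(edges) + 1L]] <- c(id, tgt, "part_of")
    }
  }
  edge_tbl <- if (length(edges)) {
    m <- do.call(rbind, edges)
    tibble::tibble(child = m[, 1], parent = m[, 2], relation = m[, 3])
  } else {
    tibble::tibble(child = character(), parent = character(),
                   relation = character())
  }
  edge_tbl <- dplyr::filter(edge_tbl, .data$parent %in% ids)
  onto_dag(terms = ids, edges = edge_tbl, names = nms)
}

#' Construct an ontology DAG
#'
#' @param terms Character vector of term ids.
#' @param edges Tibble with `child`, `parent`, `relation` (`is_a`/`part_of`)
#'   columns; edges are directed child to parent.
#' @param names Optional named character vector of term names.
#' @return An `onto_dag` object; errors if the relations contain a cycle.
#' @export
onto_dag <- function(terms, edges, names = NULL) {
  terms <- unique(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(edges$relation %in% c("is_a", "part_of")))
  if (!all(edges$child %in% terms) || !all(edges$parent %in% terms)) {
    rwhn_abort("unknown_term", "ontology edge references an unknown term")
  }
  # Kahn topological sort doubles as the acyclicity check
  deg <- table(factor(edges$child, levels = terms))
  queue <- terms[deg == 0]
  remaining <- edges
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    drop <- remaining$parent == t
    kids <- remaining$child[drop]
    remaining <- remaining[!drop, ]
    for (k in kids) {
      if (!any(remaining$child == k)) queue <- c(queue, k)
    }
  }
  if (seen < length(terms)) {
    rwhn_abort("cycle_detected", "ontology relations contain a cycle")
  }
  roots <- setdiff(terms, unique(edges$child))
  if (is.null(names)) names <- stats::setNames(terms, terms)
  structure(list(terms = terms, names = names, edges = edges, roots = roots),
            class = "onto_dag")
}

#' @export
print.onto_dag <- function(x, ...) {
  cat("# Ontology DAG: ", length(x$terms), " terms, ", nrow(x$edges),
      " edges, ", length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' Write an ontology as OBO 1.2
#'
#' @param dag An `onto_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", unname(dag$names[t])))
    e <- dag$edges[dag$edges$child == t, ]
    for (i in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[i] == "is_a") {
        paste0("is_a: ", e$parent[i])
      } else {
        paste0("relationship: part_of ", e$parent[i])
      })
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write per-cluster function rankings
#'
#' Serialises a ranking (see [run_rwhn()]) as TSV with columns
#' `seed_cluster`, `term_id`, `term_name`, `steady_state_probability`,
#' `rank`, `retained_flag`, grouped by seed cluster in input order and at
#' full numeric precision. Clusters whose retained set is empty still emit
#' their rows with `retained_flag` FALSE.
#'
#' @param result A `rwhn_ranking` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rankings <- function(result, path) {
  if (nrow(result) == 0) rwhn_abort("parse_error", "empty ranking result")
  out <- tibble::tibble(
    seed_cluster = result$seed_cluster,
    term_id = result$term_id,
    term_name = result$term_name,
    steady_state_probability = sprintf("%.17g", result$probability),
    rank = result$rank,
    retained_flag = result$retained
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a rankings TSV written by [write_rankings()]
#'
#' @param path Path to the TSV.
#' @return A `rwhn_ranking` tibble.
#' @export
read_rankings <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_rwhn_ranking(tibble::tibble(
    seed_cluster = raw$seed_cluster,
    term_id = raw$term_id,
    term_name = raw$term_name,
    probability = as.numeric(raw$steady_state_probability),
    rank = as.integer(raw$rank),
    retained = as.logical(raw$retained_flag)
  ))
}
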