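#' Quantitative phosphosite tables
#'
#' A quant table is a tibble with one row per phosphorylation site. The first
#' three columns identify the site (`protein`, `residue`, `position`); the
#' remaining *condition* columns hold dimensionless abundance ratios
#' (SILAC-style), with `NA` marking missing quantifications. The condition
#' column names are carried in the `"conditions"` attribute so that id and
#' measurement columns never have to be re-guessed downstream.
#'
#' @param x A data frame with `protein`, `residue`, `position` columns and
#'   numeric ratio columns.
#' @param conditions Character vector naming the ratio columns. Defaults to
#'   every column that is not an id column.
#'
#' @return A tibble of class `quant_tbl`.
#' @export
quant_tbl <- function(x, conditions = NULL) {
  x <- tibble::as_tibble(x)
  id_cols <- c("protein", "residue", "position")
  if (!all(id_cols %in% names(x))) {
    rwhn_abort("parse_error",
               "a quant table needs `protein`, `residue` and `position` columns")
  }
  if (is.null(conditions)) {
    conditions <- setdiff(names(x), id_cols)
  }
  x$protein <- as.character(x$protein)
  x$residue <- toupper(as.character(x$residue))
  pos <- suppressWarnings(as.integer(x$position))
  if (anyNA(pos) || any(pos < 1L)) {
    rwhn_abort("parse_error", "`position` must be a positive integer for every site")
  }
  x$position <- pos
  bad_res <- setdiff(unique(x$residue), c("S", "T", "Y"))
  if (length(bad_res) > 0) {
    rwhn_abort("parse_error", paste0(
      "phosphosite residues must be S, T or Y; found: ",
      paste(bad_res, collapse = ", ")))
  }
  key <- paste(x$protein, x$position)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rwhn_abort("duplicate_site", paste0(
      "duplicated site (protein, position): ", dup))
  }
  for (cc in conditions) x[[cc]] <- as.numeric(x[[cc]])
  x <- x[, c(id_cols, conditions)]
  structure(x,
            conditions = conditions,
            class = c("quant_tbl", class(tibble::tibble())))
}

#' @describeIn quant_tbl Names of the condition (ratio) columns.
#' @export
quant_conditions <- function(x) {
  cond <- attr(x, "conditions")
  if (is.null(cond)) setdiff(names(x), c("protein", "residue", "position")) else cond
}

#' Site identifiers
#'
#' Canonical `PROTEIN_R123`-style identifiers (protein accession, residue
#' letter, 1-based position), used as node ids in the site layer.
#'
#' @param x A quant table.
#' @return Character vector, one id per row.
#' @export
site_ids <- function(x) {
  paste0(x$protein, "_", x$residue, x$position)
}

#' @describeIn quant_tbl Ratio values as a numeric matrix (sites x conditions),
#'   rownames set to the site ids.
#' @export
quant_matrix <- function(x) {
  m <- as.matrix(x[, quant_conditions(x), drop = FALSE])
  rownames(m) <- site_ids(x)
  m
}

# Rebuild a quant_tbl after its value matrix was modified in place.
set_quant_matrix <- function(x, m) {
  for (j in seq_along(quant_conditions(x))) {
    x[[quant_conditions(x)[j]]] <- m[, j]
  }
  x
}

#' @export
print.quant_tbl <- function(x, ...) {
  cond <- quant_conditions(x)
  cat("# Quant table: ", nrow(x), " sites x ", length(cond), " conditions (",
      sum(is.na(as.matrix(x[, cond]))), " missing cells)\n", sep = "")
  NextMethod()
}

rwhn_abort <- function(kind, message) {
  rlang::abort(message, class = paste0("rwhn_error_", kind))
}
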