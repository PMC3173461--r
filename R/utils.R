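#' @keywords internal
"_PACKAGE"

## Symbols used for expression-profile symbolization.
sym_up <- "↑"
sym_down <- "↓"
sym_flat <- "-"

abort_pistatus <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pistatus_error"), ...)
}

#' @importFrom rlang .data
NULL

## An expression table is a tibble whose first column is `gene_id` and whose
## remaining columns are numeric sample/channel signals. The value kind
## ("raw_two_channel", "one_colour", "ratio", "median_scaled") travels as an
## attribute; helpers below tolerate its loss through dplyr verbs.
set_value_kind <- function(x, kind) {
  attr(x, "value_kind") <- kind
  x
}

#' Value kind of an expression table
#'
#' Expression tables carry a `value_kind` attribute recording whether their
#' signals are raw two-channel intensities, one-colour signals, per-array
#' ratios, or median-scaled values. Returns `NA` when the attribute has been
#' dropped (e.g. by a dplyr verb).
#'
#' @param x An expression tibble.
#' @return A string or `NA`.
#' @export
value_kind <- function(x) {
  k <- attr(x, "value_kind", exact = TRUE)
  if (is.null(k)) NA_character_ else k
}

check_expr_tbl <- function(x, arg = "matrix") {
  if (!is.data.frame(x) || !identical(names(x)[1], "gene_id")) {
    abort_pistatus(
      sprintf("`%s` must be a data frame with first column `gene_id`.", arg),
      "pistatus_data_error"
    )
  }
  invisible(x)
}

expr_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

expr_tbl <- function(values, gene_id, kind = NULL) {
  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), out)
  if (!is.null(kind)) out <- set_value_kind(out, kind)
  out
}

align_columns_to_meta <- function(x, meta, arg = "matrix") {
  check_expr_tbl(x, arg)
  ids <- setdiff(names(x), "gene_id")
  if (!all(meta$sample_id %in% ids)) {
    abort_pistatus(
      sprintf("`%s` is missing columns for some samples in `meta`.", arg),
      "pistatus_alignment_error"
    )
  }
  x[, c("gene_id", meta$sample_id)]
}

## Derive a stream-specific 32-bit seed from a master seed, so independent
## stages draw independent but reproducible streams.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

#' Write a table as TSV with a provenance header
#'
#' Writes tab-separated UTF-8 text with a header row; missing values are
#' written as `"."`. Optional `provenance` entries become `#`-prefixed comment
#' lines above the header.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param provenance Named character vector written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_pistatus_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), as.character(provenance)), con)
  }
  utils::write.table(
    as.data.frame(x), con,
    sep = "\t", quote = FALSE, row.names = FALSE, na = ".",
    fileEncoding = ""
  )
  invisible(path)
}

#' Read a TSV written by [write_pistatus_tsv()]
#'
#' @param path File path.
#' @return A tibble; `#` comment lines are skipped and `"."` is read as `NA`.
#' @export
read_pistatus_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_pistatus(sprintf("Input file does not exist: %s", path), "pistatus_data_error")
  }
  readr::read_tsv(
    path,
    comment = "#", na = ".", show_col_types = FALSE, progress = FALSE
  )
}
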