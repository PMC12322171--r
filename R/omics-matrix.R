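#' Construct an omics matrix
#'
#' A genes x samples numeric matrix on a log2-like scale, tagged with the
#' data layer it represents. Missing values are permitted except on the
#' residual layer, where a gene either covers a sample (numeric value) or
#' does not appear in that sample's residual row at all (`NA` is the absence
#' marker and is allowed there for samples the gene does not cover; the
#' invariant checked is structural validity, uniqueness, and minimum size).
#'
#' @param values Numeric matrix with rownames (gene symbols) and colnames
#'   (sample ids).
#' @param layer One of `"protein"`, `"mrna"`, `"residual"`.
#' @return An `omics_matrix` (numeric matrix with a `layer` attribute).
#' @export
omics_matrix <- function(values, layer = c("protein", "mrna", "residual")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("omics matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    rlang::abort("duplicate gene ids in omics matrix")
  }
  if (anyDuplicated(colnames(values))) {
    rlang::abort("duplicate sample ids in omics matrix")
  }
  if (nrow(values) < 1 || ncol(values) < 2) {
    rlang::abort("omics matrix needs at least 1 gene and 2 samples")
  }
  structure(values, layer = layer, class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix[%s]> %d genes x %d samples, %.1f%% missing\n",
              attr(x, "layer"), nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

layer_of <- function(x) attr(x, "layer")

#' Read an abundance matrix from TSV/CSV
#'
#' Expects gene rows and sample columns with a header row; the first column
#' holds gene symbols. Empty cells become missing values. Duplicated gene
#' rows and non-numeric cells are load errors.
#'
#' @param path File path (`.tsv`/`.txt` tab-delimited, `.csv` comma).
#' @param layer Data layer tag, see [omics_matrix()].
#' @return An `omics_matrix`.
#' @export
read_matrix <- function(path, layer = c("protein", "mrna", "residual")) {
  layer <- match.arg(layer)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 3) rlang::abort("matrix file needs a gene column and >= 2 samples")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicated gene row(s) in %s: %s", path,
                         paste(unique(dup), collapse = ", ")))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      col[col == ""] <- NA_character_
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        rlang::abort(sprintf(
          "malformed numeric cell at gene '%s', sample '%s' in %s",
          genes[bad[1]], names(vals)[j], path))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  omics_matrix(m, layer)
}

#' Write an abundance matrix to TSV
#'
#' Missing values are written as empty cells, the inverse of
#' [read_matrix()]; numbers use full precision so read/write round-trips.
#'
#' @param x An `omics_matrix` (or plain named numeric matrix).
#' @param path Output path.
#' @param gene_col Name of the gene-symbol column (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, gene_col = "gene") {
  df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(!!gene_col := rownames(x)), df)
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Construct a copy-number call matrix
#'
#' Gene-level thresholded (GISTIC-style) calls: -2 homozygous deletion, -1
#' hemizygous loss, 0 neutral, 1 gain, 2 amplification. Missing calls are
#' allowed; any value outside -2..2 is rejected.
#'
#' @param values Integer matrix with gene rownames and sample colnames.
#' @return A `copy_state_matrix`.
#' @export
copy_state_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("copy-state matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    rlang::abort("duplicate gene or sample ids in copy-state matrix")
  }
  obs <- values[!is.na(values)]
  if (length(obs) > 0 && (any(obs != round(obs)) || any(abs(obs) > 2))) {
    rlang::abort("copy-number calls must be integers in {-2,-1,0,1,2}")
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("copy_state_matrix", class(values)))
}

#' Read a gene-level copy-number call matrix
#'
#' @inheritParams read_matrix
#' @return A `copy_state_matrix`.
#' @export
read_copy_states <- function(path) {
  m <- read_matrix(path, layer = "protein")
  copy_state_matrix(structure(unclass(m), layer = NULL))
}

#' Read a sample table
#'
#' Two mandatory columns: `sample_id` and `study` (cancer type / lineage).
#'
#' @param path TSV path.
#' @return A tibble with unique `sample_id` and a `study` label per sample.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  validate_sample_table(df)
}

validate_sample_table <- function(df) {
  need <- c("sample_id", "study")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("sample table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) rlang::abort("duplicate sample ids")
  if (any(is.na(df$study))) rlang::abort("every sample needs a study label")
  tibble::as_tibble(df[, need])
}
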