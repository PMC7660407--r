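#' Core data types and readers
#'
#' All drug-response statistics operate on natural-log IC50 values as
#' provided (GDSC convention); the package never exponentiates them. A
#' measurement is "extrapolated" when its modeled ln(IC50) lies strictly
#' above the natural log of the maximum screened concentration, i.e. the
#' fitted IC50 was never actually reached in the assay.
#'
#' @name data_model
NULL

.default_drug_response_dialect <- list(
  cell_line = "cell_line", drug = "drug", ln_ic50 = "ln_ic50",
  max_conc = "max_conc", extrapolated = "extrapolated")

#' Validate an in-memory drug-response table
#'
#' @param df Data frame with columns `cell_line`, `drug`, `ln_ic50` and
#'   optionally `max_conc` (maximum screened concentration, uM) and/or a
#'   logical `extrapolated` flag. If the flag is absent it is computed as
#'   `ln_ic50 > log(max_conc)` (strict); if neither is present all rows are
#'   treated as non-extrapolated with a warning.
#' @return A validated `unres_drug_response` data frame.
#' @export
as_drug_response <- function(df) {
  for (f in c("cell_line", "drug", "ln_ic50"))
    if (is.null(df[[f]])) stop_schema(sprintf("missing required column '%s'", f))
  df$cell_line <- trimws(as.character(df$cell_line))
  df$drug <- trimws(as.character(df$drug))
  df$ln_ic50 <- as.numeric(df$ln_ic50)
  if (any(!is.finite(df$ln_ic50)))
    stop_integrity(sprintf("non-finite ln_ic50 in %d row(s)", sum(!is.finite(df$ln_ic50))))
  key <- paste(df$cell_line, df$drug, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_integrity(sprintf("duplicate (cell_line, drug) pair(s): %s",
                           paste(gsub("\r", "/", utils::head(dup, 5)), collapse = ", ")))
  }
  if (is.null(df$extrapolated)) {
    if (!is.null(df$max_conc)) {
      df$max_conc <- as.numeric(df$max_conc)
      if (any(!is.na(df$max_conc) & df$max_conc <= 0))
        stop_integrity("max_conc must be positive")
      df$extrapolated <- !is.na(df$max_conc) & df$ln_ic50 > log(df$max_conc)
    } else {
      warning("no extrapolation flag or maximum screened concentration supplied; ",
              "treating all measurements as within the tested range")
      df$extrapolated <- FALSE
    }
  } else {
    df$extrapolated <- parse_logical(df$extrapolated)
  }
  rownames(df) <- NULL
  class(df) <- c("unres_drug_response", "data.frame")
  df
}

#' Read a drug-response table
#'
#' @param path CSV/TSV file with a header row; delimiter auto-detected
#'   unless `sep` is given.
#' @param dialect Named list mapping canonical names (`cell_line`, `drug`,
#'   `ln_ic50`, `max_conc`, `extrapolated`) to the file's column names.
#' @param sep Optional field separator override.
#' @return An `unres_drug_response` data frame.
#' @export
read_drug_response <- function(path, dialect = NULL, sep = NULL) {
  dia <- utils::modifyList(.default_drug_response_dialect, as.list(dialect %||% list()))
  raw <- read_table_auto(path, sep)
  for (f in c("cell_line", "drug", "ln_ic50"))
    if (!dia[[f]] %in% names(raw))
      stop_schema(sprintf("missing required column '%s'", dia[[f]]))
  df <- data.frame(cell_line = raw[[dia$cell_line]], drug = raw[[dia$drug]],
                   ln_ic50 = raw[[dia$ln_ic50]], stringsAsFactors = FALSE)
  if (dia$max_conc %in% names(raw)) df$max_conc <- raw[[dia$max_conc]]
  if (dia$extrapolated %in% names(raw)) df$extrapolated <- raw[[dia$extrapolated]]
  as_drug_response(df)
}

#' Construct a binary cancer-functional-event (CFE) matrix
#'
#' @param mat Numeric matrix, cell lines in rows, CFEs in columns, values
#'   strictly 0/1.
#' @param metadata Data frame with columns `cfe_id`, `alteration_class`
#'   (one of mutation/cna/methylation), `genes` (list column or
#'   semicolon-joined string of member gene symbols) and logical
#'   `has_driver_gene`.
#' @return An `unres_cfe_matrix` object (list with `$matrix`, `$metadata`).
#' @export
cfe_matrix <- function(mat, metadata) {
  mat <- as.matrix(mat)
  mode(mat) <- "numeric"
  bad <- which(!(mat %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(mat))
    stop_integrity(sprintf(
      "non-binary CFE value %s at row %s ('%s'), column %s ('%s')",
      format(mat[bad[1]]), rc[1], rownames(mat)[rc[1]], rc[2], colnames(mat)[rc[2]]))
  }
  rownames(mat) <- trimws(rownames(mat))
  colnames(mat) <- trimws(colnames(mat))
  if (anyDuplicated(rownames(mat))) stop_integrity("duplicate cell_line_id in CFE matrix")
  if (anyDuplicated(colnames(mat))) stop_integrity("duplicate cfe_id in CFE matrix")
  for (f in c("cfe_id", "alteration_class", "genes", "has_driver_gene"))
    if (is.null(metadata[[f]])) stop_schema(sprintf("CFE metadata lacks column '%s'", f))
  metadata$cfe_id <- trimws(as.character(metadata$cfe_id))
  if (!is.list(metadata$genes))
    metadata$genes <- lapply(strsplit(as.character(metadata$genes), ";", fixed = TRUE),
                             function(g) trimws(g[nzchar(trimws(g))]))
  metadata$has_driver_gene <- parse_logical(metadata$has_driver_gene)
  bad_class <- setdiff(unique(metadata$alteration_class), c("mutation", "cna", "methylation"))
  if (length(bad_class))
    stop_integrity(sprintf("unknown alteration_class: %s", paste(bad_class, collapse = ", ")))
  missing_meta <- setdiff(colnames(mat), metadata$cfe_id)
  if (length(missing_meta))
    stop_schema(sprintf("CFE id(s) without metadata: %s", paste(missing_meta, collapse = ", ")))
  no_genes <- lengths(metadata$genes) == 0 & metadata$has_driver_gene
  if (any(no_genes))
    stop_integrity(sprintf("CFE(s) flagged has_driver_gene but without genes: %s",
                           paste(metadata$cfe_id[no_genes], collapse = ", ")))
  metadata <- metadata[match(colnames(mat), metadata$cfe_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(matrix = mat, metadata = metadata), class = "unres_cfe_matrix")
}

#' Read a CFE matrix and its metadata
#'
#' @param matrix_path CSV/TSV; first column is the cell-line id, remaining
#'   columns one CFE each with 0/1 values.
#' @param metadata_path CSV/TSV with columns `cfe_id`, `alteration_class`,
#'   `genes` (semicolon-joined symbols, may be empty), `has_driver_gene`.
#' @param sep Optional separator override for both files.
#' @return An `unres_cfe_matrix` object.
#' @export
read_cfe_matrix <- function(matrix_path, metadata_path, sep = NULL) {
  m <- read_table_auto(matrix_path, sep)
  cells <- trimws(as.character(m[[1]]))
  mat <- as.matrix(m[-1])
  rownames(mat) <- cells
  meta <- read_table_auto(metadata_path, sep)
  cfe_matrix(mat, meta)
}

#' @export
print.unres_cfe_matrix <- function(x, ...) {
  cat(sprintf("CFE matrix: %d cell lines x %d CFEs (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", names(table(x$metadata$alteration_class)),
                            table(x$metadata$alteration_class)), collapse = ", ")))
  invisible(x)
}

#' Read per-cell-line annotations
#'
#' @param path CSV/TSV with columns `cell_line`, `tissue`, `msi_status`,
#'   `medium`, `growth_property`.
#' @param sep Optional separator override.
#' @return An `unres_annotations` data frame, one row per cell line.
#' @export
read_annotations <- function(path, sep = NULL) {
  df <- read_table_auto(path, sep)
  as_annotations(df)
}

#' @rdname read_annotations
#' @param df In-memory annotation data frame to validate.
#' @export
as_annotations <- function(df) {
  for (f in c("cell_line", "tissue", "msi_status", "medium", "growth_property"))
    if (is.null(df[[f]])) stop_schema(sprintf("annotation table lacks column '%s'", f))
  df$cell_line <- trimws(as.character(df$cell_line))
  df$tissue <- trimws(as.character(df$tissue))
  if (anyDuplicated(df$cell_line))
    stop_integrity(sprintf("duplicated cell_line id(s): %s",
                           paste(unique(df$cell_line[duplicated(df$cell_line)]), collapse = ", ")))
  if (any(!nzchar(df$tissue) | is.na(df$tissue)))
    stop_integrity("empty tissue field in annotation table")
  rownames(df) <- NULL
  class(df) <- c("unres_annotations", "data.frame")
  df
}

#' Read a CRISPR gene-effect (essentiality) matrix
#'
#' Scores are unitless CERES-style gene effects: negative means the gene is
#' essential in that cell line. Missing values stay missing (never zero).
#'
#' @param path CSV/TSV; first column holds row identifiers.
#' @param orientation `"genes_in_rows"` (default) or `"cells_in_rows"`; the
#'   returned matrix is always gene x cell line.
#' @param sep Optional separator override.
#' @return A numeric matrix, genes in rows, cell lines in columns.
#' @export
read_essentiality <- function(path, orientation = c("genes_in_rows", "cells_in_rows"),
                              sep = NULL) {
  orientation <- match.arg(orientation)
  raw <- read_table_auto(path, sep)
  ids <- trimws(as.character(raw[[1]]))
  body <- raw[-1]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      chr <- trimws(as.character(col))
      num <- suppressWarnings(as.numeric(chr))
      bad <- which(!is.na(chr) & nzchar(chr) & chr != "NA" & is.na(num))
      if (length(bad))
        stop_parse(sprintf("non-numeric gene-effect value '%s' at row %d, column '%s'",
                           chr[bad[1]], bad[1], names(body)[j]))
      num[chr == "" | chr == "NA"] <- NA
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (orientation == "cells_in_rows") mat <- t(mat)
  rownames(mat) <- trimws(rownames(mat))
  colnames(mat) <- trimws(colnames(mat))
  if (anyDuplicated(rownames(mat)))
    stop_integrity(sprintf("duplicate gene symbol(s): %s",
                           paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", ")))
  if (any(is.infinite(mat))) stop_integrity("infinite gene-effect value")
  mat
}

#' Read a cancer gene list
#'
#' One gene symbol per line; symbols are trimmed and upper-cased
#' (gene-symbol comparisons in this package are case-insensitive).
#'
#' @param path Text file, one symbol per line.
#' @return A character vector of unique upper-case symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  g <- unique(toupper(trimws(readLines(path))))
  g <- g[nzchar(g)]
  if (!length(g)) stop_integrity("cancer gene list is empty")
  g
}
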