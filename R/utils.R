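`%||%` <- function(a, b) if (is.null(a)) b else a

.MOD31 <- 2147483647  # 2^31 - 1; keeps derived seeds valid R integers

#' Derive a deterministic substream seed
#'
#' Mixes the run seed with an arbitrary key (e.g. tissue, drug, CFE, i) so
#' every (association, i) pair gets its own reproducible random stream,
#' independent of iteration order.
#'
#' @param seed Integer run seed.
#' @param ... Key components; coerced to character and hashed.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
stream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "\r")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% .MOD31
  s <- as.numeric(seed) %% .MOD31
  as.integer((h + s * 48271 + 1) %% .MOD31)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Classed error constructors. Everything user-input related inherits
# "unres_validation_error" so the CLI can map it to exit status 2.
unres_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "unres_validation_error", "unres_error")))
}
stop_schema    <- function(msg) unres_stop(msg, "unres_schema_error")
stop_integrity <- function(msg) unres_stop(msg, "unres_integrity_error")
stop_parse     <- function(msg) unres_stop(msg, "unres_parse_error")
stop_config    <- function(msg) unres_stop(msg, "unres_config_error")
stop_argument  <- function(msg) unres_stop(msg, "unres_argument_error")
stop_input     <- function(msg) unres_stop(msg, "unres_input_error")
stop_degenerate <- function(msg) unres_stop(msg, "unres_degenerate_error")

# Delimiter sniffing: tab wins over comma if present in the header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) && grepl("\t", header)) "\t" else ","
}

read_table_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  sep <- sep %||% detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    colClasses = NA)
}

#' Write a result table as TSV
#'
#' @param df A data frame. List columns are flattened by joining with ";".
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  flat <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(x, collapse = ";"), character(1))
    else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(flat) <- names(df)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- v %in% c("TRUE", "T", "1", "YES")
  bad <- !v %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO", "NA")
  if (any(bad)) stop_parse(sprintf("cannot parse logical value(s): %s",
                                   paste(unique(v[bad]), collapse = ", ")))
  out[v == "NA"] <- NA
  out
}

# Sample SD (n-1 denominator) of each column of a numeric matrix with m rows.
col_sd <- function(x, m = nrow(x)) {
  s1 <- .colSums(x, m, ncol(x))
  s2 <- .colSums(x * x, m, ncol(x))
  sqrt(pmax((s2 - s1 * s1 / m) / (m - 1), 0))
}
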