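#' Leave-top-i SD decrease
#'
#' For a sensitive subpopulation of n ln-IC50 values, `sigma0` is the sample
#' SD of the full set and `sigma_i` the sample SD after removing the i
#' largest values (the most resistant lines); the statistic is
#' `delta_sigma = sigma_i - sigma0`. i ranges over 1..min(n/2, i_max).
#' Ties at the removal boundary are broken by cell-line id (names of
#' `values`) for reproducibility, with a warning.
#'
#' @param values Named numeric vector of ln-IC50 values (n >= 4).
#' @param i Number of top values to remove.
#' @param i_max Upper bound on i (default 5).
#' @param half How to round n/2 for odd n: `"floor"` (default) or
#'   `"ceiling"`.
#' @return List with `sigma0`, `sigma_i`, `delta_sigma` and `removed`
#'   (cell ids ordered by descending ln-IC50).
#' @export
sd_decrease <- function(values, i, i_max = 5, half = c("floor", "ceiling")) {
  half <- match.arg(half)
  n <- length(values)
  if (n < 4) stop_argument("need at least 4 values")
  bound <- min(if (half == "floor") floor(n / 2) else ceiling(n / 2), i_max)
  if (!is.numeric(i) || length(i) != 1 || i != round(i) || i < 1 || i > bound || n - i < 2)
    stop_argument(sprintf("i must be an integer in 1..%d", bound))
  nm <- names(values) %||% sprintf("obs%04d", seq_len(n))
  ord <- order(-values, nm)
  if (values[ord[i]] == values[ord[i + 1]])
    warning("tie at the removal boundary; broken by cell-line id")
  keep <- ord[-seq_len(i)]
  list(sigma0 = stats::sd(values),
       sigma_i = stats::sd(values[keep]),
       delta_sigma = stats::sd(values[keep]) - stats::sd(values),
       removed = nm[ord[seq_len(i)]])
}

#' Bootstrap null distribution of the SD-decrease statistic
#'
#' Samples n ln-IC50 values with replacement from the pool of all measured
#' cell lines of the tissue for the drug (ignoring CFE status) and computes
#' `delta_sigma_i` for each of B resamples. The median of the distribution
#' is retained as the expected SD change `E[delta_sigma_i]`.
#'
#' @param pool Numeric vector of ln-IC50 values for the drug within the
#'   tissue; must have at least n members.
#' @param n Subpopulation size to resample.
#' @param i Number of top values removed.
#' @param B Bootstrap iterations (default 10000).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of length B with attribute `"median"`.
#' @export
bootstrap_null <- function(pool, n, i, B = 10000, seed = 1L) {
  if (length(pool) < n) stop_input("bootstrap pool smaller than subpopulation size n")
  if (n < 4) stop_argument("n must be at least 4")
  if (i < 1 || n - i < 2) stop_argument("i out of range for n")
  if (B < 1) stop_argument("B must be positive")
  m <- with_seed(seed, matrix(sample(pool, n * B, replace = TRUE), nrow = n))
  # sort each column ascending in one radix pass; top-i values are the last rows
  srt <- matrix(m[order(col(m), m)], nrow = n)
  sigma0 <- col_sd(srt)
  sigma_i <- col_sd(srt[seq_len(n - i), , drop = FALSE])
  null <- sigma_i - sigma0
  attr(null, "median") <- stats::median(null)
  null
}

#' Add-one bootstrap p-value
#'
#' `p = (1 + #\{null <= observed\}) / (B + 1)`: the fraction of bootstrap
#' SD decreases at least as extreme (as negative) as the observed one, with
#' the add-one convention so p is never below `1/(B+1)`.
#'
#' @param delta_sigma Observed SD decrease.
#' @param null Bootstrap null distribution (vector of B values).
#' @param B Number of bootstrap members (defaults to `length(null)`).
#' @return The p-value.
#' @export
bootstrap_pvalue <- function(delta_sigma, null, B = length(null)) {
  if (length(null) != B) stop_argument("null must have B members")
  (1 + sum(null <= delta_sigma)) / (B + 1)
}

#' Normalized SD decrease
#'
#' `-(delta_sigma - E) / (sigma0 - E)` with `E` the bootstrap-null median.
#' Centers the observed SD change on what removal of the top i values does
#' by chance and scales by the null-adjusted spread, giving a magnitude
#' measure in roughly \[0, 1\] for genuine outliers; cases above 0.5 are
#' conventionally labeled as strong.
#'
#' @param delta_sigma Observed SD decrease.
#' @param sigma0 SD of the full subpopulation.
#' @param bootstrap_median Median of the bootstrap null (`E`).
#' @return The normalized decrease, or `NA` with attribute
#'   `undefined = TRUE` (and a warning) when `sigma0 - E` is within 1e-12
#'   of zero.
#' @export
normalized_sd_decrease <- function(delta_sigma, sigma0, bootstrap_median) {
  denom <- sigma0 - bootstrap_median
  if (abs(denom) < 1e-12) {
    warning("sigma0 - E[delta_sigma] is numerically zero; magnitude undefined")
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -(delta_sigma - bootstrap_median) / denom
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted p-values (monotone, capped at 1) with
#' significance flags at level `alpha`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.15).
#' @return List with `adjusted` (same order as input) and `significant`
#'   (`adjusted < alpha`).
#' @export
bh_adjust <- function(p_values, alpha = 0.15) {
  p <- as.numeric(p_values)
  if (any(is.na(p) | p <= 0 | p > 1)) stop_argument("p-values must lie in (0, 1]")
  m <- length(p)
  adj <- numeric(m)
  if (m) {
    o <- order(p)
    adj[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  }
  list(adjusted = adj, significant = adj < alpha)
}

#' Detect UNRES cases for one sensitivity association
#'
#' For the association's CFE-altered cell lines with a measured response in
#' the tissue, computes one UNRES case per i in 1..min(n/2, `i_max`): the
#' leave-top-i SD decrease, its bootstrap p-value against the within-tissue
#' pool (all measured lines for the drug, ignoring CFE status), and the
#' normalized magnitude. Adjusted p-values (`p_adjusted`, `selected`) are
#' filled by the pooled BH pass of [hfdr_select()] across all children of
#' all significant parents; here they are `NA`.
#'
#' @param association One-row data frame (or list) with `tissue`, `drug`,
#'   `cfe`.
#' @param resp,ann,cfe Screen tables.
#' @param B Bootstrap iterations (default 10000).
#' @param seed Run seed; each i gets its own substream via [stream_seed()].
#' @param i_max Upper bound on i (default 5).
#' @param half Rounding of n/2 (see [sd_decrease()]).
#' @return `unres_cases` data frame, one row per i.
#' @export
detect_unres <- function(association, resp, ann, cfe, B = 10000, seed = 1L,
                         i_max = 5, half = "floor") {
  tissue <- association$tissue; drug <- association$drug; cfe_id <- association$cfe
  cells_t <- ann$cell_line[ann$tissue == tissue]
  rd <- resp[resp$drug == drug & resp$cell_line %in% cells_t, , drop = FALSE]
  pool <- rd$ln_ic50
  rd <- rd[rd$cell_line %in% rownames(cfe$matrix), , drop = FALSE]
  status <- cfe$matrix[rd$cell_line, cfe_id]
  vals <- stats::setNames(rd$ln_ic50[status == 1], rd$cell_line[status == 1])
  n <- length(vals)
  if (n < 4) stop_input(sprintf("association %s/%s/%s has fewer than 4 altered lines",
                                tissue, drug, cfe_id))
  bound <- min(if (half == "floor") floor(n / 2) else ceiling(n / 2), i_max)
  rows <- vector("list", bound)
  for (i in seq_len(bound)) {
    dec <- sd_decrease(vals, i, i_max = i_max, half = half)
    null <- bootstrap_null(pool, n, i, B = B,
                           seed = stream_seed(seed, tissue, drug, cfe_id, i))
    med <- attr(null, "median")
    rows[[i]] <- data.frame(
      tissue = tissue, drug = drug, cfe = cfe_id, n = n, i = i,
      removed_cells = paste(dec$removed, collapse = ";"),
      sigma0 = dec$sigma0, sigma_i = dec$sigma_i, delta_sigma = dec$delta_sigma,
      p_value = bootstrap_pvalue(dec$delta_sigma, null, B),
      p_adjusted = NA_real_, selected = NA,
      bootstrap_median = med,
      normalized_sd_decrease = as.numeric(normalized_sd_decrease(
        dec$delta_sigma, dec$sigma0, med)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  class(res) <- c("unres_cases", "data.frame")
  res
}

.empty_unres_cases <- function() {
  res <- data.frame(tissue = character(), drug = character(), cfe = character(),
                    n = integer(), i = integer(), removed_cells = character(),
                    sigma0 = numeric(), sigma_i = numeric(), delta_sigma = numeric(),
                    p_value = numeric(), p_adjusted = numeric(), selected = logical(),
                    bootstrap_median = numeric(), normalized_sd_decrease = numeric(),
                    stringsAsFactors = FALSE)
  class(res) <- c("unres_cases", "data.frame")
  res
}

#' Detect UNRES cases for every retained association
#'
#' @param associations `unres_associations` data frame; only rows with
#'   `retained == TRUE` are analysed.
#' @inheritParams detect_unres
#' @return `unres_cases` data frame with a `parent` id column
#'   (`tissue|drug|cfe`).
#' @export
detect_unres_all <- function(associations, resp, ann, cfe, B = 10000, seed = 1L,
                             i_max = 5, half = "floor") {
  ret <- associations[associations$retained %||% rep(TRUE, nrow(associations)), ,
                      drop = FALSE]
  if (!nrow(ret)) {
    res <- .empty_unres_cases()
    res$parent <- character()
    return(res)
  }
  out <- lapply(seq_len(nrow(ret)), function(r)
    detect_unres(ret[r, ], resp, ann, cfe, B = B, seed = seed,
                 i_max = i_max, half = half))
  res <- do.call(rbind, out)
  res$parent <- paste(res$tissue, res$drug, res$cfe, sep = "|")
  class(res) <- c("unres_cases", "data.frame")
  res
}
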