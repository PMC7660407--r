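#' Per-comparison z-scores of gene-effect differences
#'
#' For one comparison between the index (e.g. UNRES) cell line and another
#' line, the raw differences `diff_g = ess_out_g - ess_other_g` over the
#' shared genes are standardized: `z_g = (diff_g - mean(diff)) / sd(diff)`
#' (sample SD, n-1 denominator). Standardizing per comparison damps noisy
#' cell lines before averaging across comparisons.
#'
#' @param ess_out Named numeric vector: gene effects of the index cell line.
#' @param ess_other Named numeric vector: gene effects of the comparator.
#' @param min_shared Minimum shared genes with values in both profiles
#'   (default 100).
#' @return Named z vector over the shared genes. When the difference vector
#'   is constant (profiles identical up to a shift) the result is all zeros
#'   with attribute `degenerate = TRUE`.
#' @export
pairwise_z <- function(ess_out, ess_other, min_shared = 100) {
  shared <- intersect(names(ess_out)[!is.na(ess_out)],
                      names(ess_other)[!is.na(ess_other)])
  if (length(shared) < min_shared)
    stop_input(sprintf("only %d shared genes with values in both profiles (need >= %d)",
                       length(shared), min_shared))
  diff <- ess_out[shared] - ess_other[shared]
  s <- stats::sd(diff)
  if (!is.finite(s) || s < 1e-12) {
    z <- stats::setNames(rep(0, length(shared)), shared)
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (diff - mean(diff)) / s
}

#' Differential essentiality of an index cell line
#'
#' `delta_ess_g` is the average over the k comparisons of the
#' per-comparison z-score of [pairwise_z()]. Genes missing in some
#' comparisons are averaged over the comparisons where they are defined,
#' with the per-gene count reported. Positive values mean the gene is less
#' essential in the index line than in the comparators; strongly negative
#' values mark vulnerabilities unique to the index line.
#'
#' @param ess_out Named numeric vector for the index cell line.
#' @param comparators Named list of named numeric vectors (one per
#'   comparator cell line), or a gene x cell matrix.
#' @param min_shared Minimum shared genes per comparison (default 100).
#' @return `unres_delta_ess` data frame: `gene`, `delta_ess`, `k` and one
#'   `z.<comparator>` column per comparison.
#' @export
delta_essentiality <- function(ess_out, comparators, min_shared = 100) {
  if (is.matrix(comparators))
    comparators <- stats::setNames(
      lapply(seq_len(ncol(comparators)), function(j) comparators[, j]),
      colnames(comparators))
  if (!length(comparators)) stop_argument("need at least one comparator")
  nm <- names(comparators) %||% sprintf("cmp%d", seq_along(comparators))
  zs <- vector("list", length(comparators))
  for (j in seq_along(comparators)) {
    if (!length(intersect(names(ess_out), names(comparators[[j]]))))
      stop_input(sprintf("no shared genes with comparator '%s'", nm[j]))
    zs[[j]] <- pairwise_z(ess_out, comparators[[j]], min_shared = min_shared)
  }
  genes <- sort(unique(unlist(lapply(zs, names))))
  zmat <- matrix(NA_real_, nrow = length(genes), ncol = length(zs),
                 dimnames = list(genes, paste0("z.", nm)))
  for (j in seq_along(zs)) zmat[names(zs[[j]]), j] <- zs[[j]]
  k <- rowSums(!is.na(zmat))
  res <- data.frame(gene = genes,
                    delta_ess = rowMeans(zmat, na.rm = TRUE),
                    k = as.integer(k),
                    zmat, check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(res) <- c("unres_delta_ess", "data.frame")
  res
}

#' Label genes as wt-like
#'
#' A gene is wt-like when its differential essentiality against the
#' biomarker-wild-type population is near zero (`|delta_ess_wt| < tau`): its
#' dependency in the index line matches the wild-type background, so the
#' vulnerability is not specific to the resistant context.
#'
#' @param delta_vs_sensitive `unres_delta_ess` table contrasting the index
#'   line with the sensitive population (the table labels are attached to).
#' @param delta_vs_wildtype `unres_delta_ess` table contrasting the index
#'   line with wild-type lines, same gene universe.
#' @param tau Positive threshold on `|delta_ess|` versus wild type.
#' @return `delta_vs_sensitive` with an added logical `wt_like` column (NA
#'   for genes absent from the wild-type contrast).
#' @export
classify_wt_like <- function(delta_vs_sensitive, delta_vs_wildtype, tau) {
  if (!is.numeric(tau) || tau <= 0) stop_argument("tau must be positive")
  idx <- match(delta_vs_sensitive$gene, delta_vs_wildtype$gene)
  delta_vs_sensitive$wt_like <- abs(delta_vs_wildtype$delta_ess[idx]) < tau
  delta_vs_sensitive
}

#' Highlight strongly differential genes
#'
#' @param table `unres_delta_ess` data frame.
#' @param threshold Positive cut (default 4); strict inequalities.
#' @return List with `less_essential` (`delta_ess > threshold`, the index
#'   line does not depend on these genes) and `uniquely_essential`
#'   (`delta_ess < -threshold`, index-line-specific vulnerabilities).
#' @export
highlight_genes <- function(table, threshold = 4) {
  if (!is.numeric(threshold) || threshold <= 0) stop_argument("threshold must be positive")
  ok <- is.finite(table$delta_ess)
  list(less_essential = table$gene[ok & table$delta_ess > threshold],
       uniquely_essential = table$gene[ok & table$delta_ess < -threshold])
}
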