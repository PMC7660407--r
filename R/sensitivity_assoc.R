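#' Enumerate candidate (tissue, drug, CFE) associations
#'
#' A candidate is a cancer-type-specific triple where the CFE involves an
#' established driver gene, at least `min_mut` CFE-altered cell lines have a
#' measured response for the drug in that tissue, and at most
#' `max_extrapolated_frac` of those altered lines carry extrapolated IC50s.
#' A minimum wild-type group size of `min_wt` keeps the downstream ANOVA and
#' Cohen's d defined.
#'
#' @param cfe An `unres_cfe_matrix`.
#' @param resp An `unres_drug_response` table.
#' @param ann An `unres_annotations` table.
#' @param min_mut Minimum altered cell lines with a measurement (default 4).
#' @param max_extrapolated_frac Maximum tolerated fraction of altered lines
#'   with extrapolated IC50s (default 0.5).
#' @param min_wt Minimum wild-type lines with a measurement (default 2).
#' @return Data frame with columns tissue, drug, cfe, n_mut, n_wt,
#'   frac_mut_extrapolated.
#' @export
enumerate_candidates <- function(cfe, resp, ann, min_mut = 4,
                                 max_extrapolated_frac = 0.5, min_wt = 2) {
  shared <- Reduce(intersect, list(rownames(cfe$matrix), unique(resp$cell_line),
                                   ann$cell_line))
  if (!length(shared))
    stop_input("no cell line shared between CFE matrix, responses and annotations")
  driver <- cfe$metadata$cfe_id[cfe$metadata$has_driver_gene]
  if (!length(driver)) return(.empty_candidates())
  mat <- cfe$matrix[, driver, drop = FALSE]
  tissue_of <- stats::setNames(ann$tissue, ann$cell_line)
  out <- list()
  for (t in unique(ann$tissue)) {
    cells_t <- intersect(shared, ann$cell_line[ann$tissue == t])
    if (!length(cells_t)) next
    rt <- resp[resp$cell_line %in% cells_t, , drop = FALSE]
    for (d in unique(rt$drug)) {
      rd <- rt[rt$drug == d, , drop = FALSE]
      sub <- mat[rd$cell_line, , drop = FALSE]
      n_mut <- .colSums(sub, nrow(sub), ncol(sub))
      n_wt <- nrow(sub) - n_mut
      n_ex <- .colSums(sub * rd$extrapolated, nrow(sub), ncol(sub))
      frac <- ifelse(n_mut > 0, n_ex / n_mut, 0)
      keep <- n_mut >= min_mut & frac <= max_extrapolated_frac & n_wt >= min_wt
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          tissue = t, drug = d, cfe = colnames(sub)[keep],
          n_mut = as.integer(n_mut[keep]), n_wt = as.integer(n_wt[keep]),
          frac_mut_extrapolated = frac[keep],
          stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(out)) return(.empty_candidates())
  res <- do.call(rbind, out)
  class(res) <- c("unres_candidates", "data.frame")
  res
}

.empty_candidates <- function() {
  res <- data.frame(tissue = character(), drug = character(), cfe = character(),
                    n_mut = integer(), n_wt = integer(),
                    frac_mut_extrapolated = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("unres_candidates", "data.frame")
  res
}

#' Signed Cohen's d effect size
#'
#' `d = (mean(alt) - mean(wt)) / s_pooled`, with the pooled SD computed with
#' n-1 denominators. Group 1 is always the CFE-altered group, so a
#' sensitising alteration gives a negative d.
#'
#' @param group_alt Numeric vector, CFE-altered group (>= 2 values).
#' @param group_wt Numeric vector, wild-type group (>= 2 values).
#' @return Signed effect size.
#' @export
cohens_d <- function(group_alt, group_wt) {
  n1 <- length(group_alt); n2 <- length(group_wt)
  if (n1 < 2 || n2 < 2) stop_argument("both groups need at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(group_alt) + (n2 - 1) * stats::var(group_wt)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop_degenerate("pooled SD is zero; effect size undefined")
  (mean(group_alt) - mean(group_wt)) / sqrt(sp2)
}

#' ANOVA p-value for the CFE term
#'
#' Fits an ordinary-least-squares model `ln_ic50 ~ covariates + cfe` within
#' one tissue and returns the partial (type-II) F-test p-value of the CFE
#' term. Covariates are treated as unordered factors with reference coding;
#' covariates constant within the tissue are dropped, and rows with missing
#' covariate values are dropped with a message.
#'
#' @param ln_ic50 Numeric response vector.
#' @param cfe_status Binary (0/1) alteration status, same length.
#' @param covariates Named list of categorical vectors (e.g. msi, medium,
#'   growth), each the same length as `ln_ic50`.
#' @return The p-value, or `NA` with attribute `untestable = TRUE` when the
#'   CFE term is perfectly collinear with a covariate.
#' @export
anova_pvalue <- function(ln_ic50, cfe_status, covariates = list()) {
  if (length(unique(cfe_status)) < 2) stop_argument("CFE status is constant")
  if (min(table(cfe_status)) < 2)
    stop_argument("each CFE group needs at least 2 observations")
  d <- data.frame(.y = as.numeric(ln_ic50), stringsAsFactors = FALSE)
  kept <- character()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) >= 2) {
      d[[nm]] <- factor(v)
      kept <- c(kept, nm)
    }
  }
  d$.cfe <- factor(cfe_status)
  cc <- stats::complete.cases(d)
  if (!all(cc)) {
    message(sprintf("dropping %d row(s) with missing covariate values", sum(!cc)))
    d <- d[cc, , drop = FALSE]
    if (length(unique(d$.cfe)) < 2 || min(table(d$.cfe)) < 2)
      stop_argument("CFE groups degenerate after dropping incomplete rows")
  }
  rhs <- paste(c(kept, ".cfe"), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  cf <- stats::coef(full)
  cfe_coef <- cf[grep("^\\.cfe", names(cf))]
  if (any(is.na(cfe_coef))) {
    out <- NA_real_
    attr(out, "untestable") <- TRUE
    return(out)
  }
  reduced <- stats::lm(
    stats::as.formula(paste(".y ~", if (length(kept)) paste(kept, collapse = " + ") else "1")),
    data = d)
  stats::anova(reduced, full)[2, "Pr(>F)"]
}

#' Discover drug-sensitivity associations
#'
#' Tests every candidate with [anova_pvalue()] and [cohens_d()] and flags
#' associations with `p_value < p_threshold` and `cohens_d < d_threshold`
#' as retained. All tested candidates are reported.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param resp,ann,cfe Screen tables (see [enumerate_candidates()]).
#' @param p_threshold Parent p-value gate (default 0.001).
#' @param d_threshold Signed effect-size gate (default -1).
#' @return `unres_associations` data frame: candidates plus `p_value`,
#'   `cohens_d`, `untestable`, `retained`.
#' @export
discover_associations <- function(candidates, resp, ann, cfe,
                                  p_threshold = 0.001, d_threshold = -1) {
  n <- nrow(candidates)
  p <- rep(NA_real_, n)
  dval <- rep(NA_real_, n)
  untest <- logical(n)
  tissue_cells <- split(ann$cell_line, ann$tissue)
  for (r in seq_len(n)) {
    cells_t <- tissue_cells[[candidates$tissue[r]]]
    rd <- resp[resp$drug == candidates$drug[r] & resp$cell_line %in% cells_t, , drop = FALSE]
    rd <- rd[rd$cell_line %in% rownames(cfe$matrix), , drop = FALSE]
    status <- cfe$matrix[rd$cell_line, candidates$cfe[r]]
    ia <- match(rd$cell_line, ann$cell_line)
    covs <- list(msi = ann$msi_status[ia], medium = ann$medium[ia],
                 growth = ann$growth_property[ia])
    pv <- tryCatch(anova_pvalue(rd$ln_ic50, status, covs),
                   unres_validation_error = function(e) NA_real_)
    untest[r] <- isTRUE(attr(pv, "untestable"))
    p[r] <- as.numeric(pv)
    dval[r] <- tryCatch(cohens_d(rd$ln_ic50[status == 1], rd$ln_ic50[status == 0]),
                        unres_validation_error = function(e) NA_real_)
  }
  res <- candidates
  res$p_value <- as.numeric(p)
  res$cohens_d <- dval
  res$untestable <- untest
  res$retained <- !is.na(res$p_value) & !is.na(res$cohens_d) &
    res$p_value < p_threshold & res$cohens_d < d_threshold
  class(res) <- c("unres_associations", "data.frame")
  res
}
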