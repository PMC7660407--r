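#' Hierarchical FDR selection (Yekutieli two-level procedure)
#'
#' Level L0 holds the sensitivity-association (parent) hypotheses, level L1
#' the UNRES (child) hypotheses, each child keyed to its parent. Parents are
#' significant under a fixed threshold `alpha_parent`; children of
#' significant parents are then tested jointly with Benjamini-Hochberg at
#' `alpha_child` (pooled across all considered children by default, with a
#' per-parent option). Children of non-significant parents are never tested.
#'
#' @param parent_pvalues Named numeric vector of parent p-values.
#' @param child_pvalues Named list (by parent id) of named numeric vectors
#'   of child p-values.
#' @param alpha_parent Parent p-value threshold (default 0.001).
#' @param alpha_child BH level for the children (default 0.15).
#' @param pool_children Pool children of all significant parents into one
#'   BH pass (default `TRUE`; `FALSE` adjusts within each parent).
#' @return `unres_hfdr` list: `significant_parents`, `children` (data frame
#'   with parent, child, p_value, p_adjusted, selected) and
#'   `n_discoveries` (significant parents + selected children).
#' @export
hfdr_select <- function(parent_pvalues, child_pvalues, alpha_parent = 0.001,
                        alpha_child = 0.15, pool_children = TRUE) {
  orphans <- setdiff(names(child_pvalues), names(parent_pvalues))
  if (length(orphans))
    stop_integrity(sprintf("child hypotheses without a parent: %s",
                           paste(orphans, collapse = ", ")))
  sig_parents <- names(parent_pvalues)[parent_pvalues < alpha_parent]
  considered <- child_pvalues[intersect(names(child_pvalues), sig_parents)]
  children <- data.frame(parent = character(), child = character(),
                         p_value = numeric(), p_adjusted = numeric(),
                         selected = logical(), stringsAsFactors = FALSE)
  if (length(considered)) {
    children <- do.call(rbind, lapply(names(considered), function(pa)
      data.frame(parent = pa,
                 child = names(considered[[pa]]) %||%
                   sprintf("%s#%d", pa, seq_along(considered[[pa]])),
                 p_value = as.numeric(considered[[pa]]),
                 stringsAsFactors = FALSE)))
    if (pool_children) {
      bh <- bh_adjust(children$p_value, alpha_child)
      children$p_adjusted <- bh$adjusted
      children$selected <- bh$significant
    } else {
      children$p_adjusted <- NA_real_
      children$selected <- NA
      for (pa in unique(children$parent)) {
        idx <- children$parent == pa
        bh <- bh_adjust(children$p_value[idx], alpha_child)
        children$p_adjusted[idx] <- bh$adjusted
        children$selected[idx] <- bh$significant
      }
    }
    rownames(children) <- NULL
  }
  structure(list(significant_parents = sig_parents, children = children,
                 n_discoveries = length(sig_parents) + sum(children$selected)),
            class = "unres_hfdr")
}

#' Closed-form bound on the overall FDR of the hierarchy
#'
#' `FDR <= ((D + F) / (D + 1)) * alpha * delta`, where D is the number of
#' discoveries (significant parents plus selected children), F the number of
#' hypothesis families (unique tested drug-tissue combinations), alpha the
#' testing level and delta an inflation factor assumed 1.
#'
#' @param n_discoveries Number of discoveries (>= 0).
#' @param n_families Number of families (>= 1).
#' @param alpha Testing level.
#' @param delta Inflation factor (default 1).
#' @return The FDR bound.
#' @export
fdr_bound <- function(n_discoveries, n_families, alpha, delta = 1) {
  if (n_discoveries < 0 || n_families < 1 || alpha < 0 || delta < 0)
    stop_argument("fdr_bound: negative input or n_families < 1")
  ((n_discoveries + n_families) / (n_discoveries + 1)) * alpha * delta
}

# Permute the measurement columns (ln_ic50 together with its extrapolation
# flag and screened concentration) among the cell lines of each
# (drug, tissue) group; the multiset of values per group is preserved.
permute_responses <- function(resp, tissue_of, seed) {
  grp <- split(seq_len(nrow(resp)), paste(resp$drug, tissue_of[resp$cell_line], sep = "\r"))
  value_cols <- intersect(c("ln_ic50", "max_conc", "extrapolated"), names(resp))
  shuffled <- resp
  with_seed(seed, {
    for (g in grp) shuffled[g, value_cols] <- resp[g[sample.int(length(g))], value_cols]
  })
  shuffled
}

#' Within-tissue permutation study
#'
#' Permutes the ln-IC50 measurements (together with their extrapolation
#' flags and screened concentrations) among the cell lines of each
#' (drug, tissue) group, reruns the full discovery + UNRES + HFDR pipeline
#' with the original thresholds, and summarises per replicate: the number of
#' sensitivity associations, the number with at least one significant UNRES
#' case, and the maximum number of UNRES cell lines per association.
#'
#' @param resp,ann,cfe Screen tables.
#' @param n_perm Number of permutation replicates (default 100).
#' @param seed Run seed; replicate r uses substream `stream_seed(seed,
#'   "perm", r)`.
#' @param opts Analysis options, see [unres_options()].
#' @return `unres_permutation` list with `$replicates` (one row each) and
#'   `$summary` (means and ranges).
#' @export
permute_within_tissue <- function(resp, ann, cfe, n_perm = 100, seed = 1L,
                                  opts = unres_options()) {
  if (n_perm < 1) stop_argument("n_perm must be at least 1")
  tissue_of <- stats::setNames(ann$tissue, ann$cell_line)
  known <- resp$cell_line %in% names(tissue_of)
  if (!all(known)) {
    message(sprintf("dropping %d response row(s) for unannotated cell lines", sum(!known)))
    resp <- resp[known, , drop = FALSE]
  }
  reps <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    sub_seed <- stream_seed(seed, "perm", r)
    shuffled <- permute_responses(resp, tissue_of, sub_seed)
    ana <- analyse_screen(shuffled, cfe, ann,
                          opts = utils::modifyList(opts, list(seed = sub_seed)))
    uc <- ana$unres_cases
    sel <- uc[!is.na(uc$selected) & uc$selected, , drop = FALSE]
    reps[[r]] <- data.frame(
      replicate = r, substream = sub_seed,
      n_sensitivity_associations = sum(ana$associations$retained),
      n_assoc_with_unres = length(unique(sel$parent)),
      max_unres_cells = if (nrow(sel)) max(sel$i) else 0L,
      stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, reps)
  agg <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  structure(list(
    replicates = replicates,
    summary = list(n_sensitivity_associations = agg(replicates$n_sensitivity_associations),
                   n_assoc_with_unres = agg(replicates$n_assoc_with_unres),
                   max_unres_cells = agg(replicates$max_unres_cells))),
    class = "unres_permutation")
}
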