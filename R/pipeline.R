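#' Analysis options
#'
#' Defaults are the framework's published operating point: parent p-value
#' gate 0.001 with Cohen's d < -1, minimum of four mutant lines, exclusion
#' of associations with more than 50% extrapolated mutant IC50s, B = 10,000
#' bootstrap iterations, child BH level 0.15, at most i = 5 removed lines,
#' 100 within-tissue permutations, enrichment p < 0.05, |delta_ess| > 4
#' highlights and a 0.5 label threshold on the normalized SD decrease.
#'
#' @param p_parent Parent (sensitivity-association) p-value threshold.
#' @param d_threshold Signed Cohen's d gate.
#' @param min_mut Minimum CFE-altered cell lines with a measurement.
#' @param max_extrapolated_frac Maximum fraction of extrapolated mutant IC50s.
#' @param alpha_child BH level for UNRES child hypotheses.
#' @param B Bootstrap iterations.
#' @param i_max Upper bound on removed top-IC50 lines per case.
#' @param half Rounding of n/2 for odd n (`"floor"` or `"ceiling"`).
#' @param n_perm Permutation replicates for the permutation study.
#' @param fisher_p Enrichment significance threshold.
#' @param delta_ess_highlight |delta_ess| highlight cut.
#' @param normalized_label Label threshold on the normalized SD decrease.
#' @param tau wt-like threshold on |delta_ess| versus wild type (free
#'   parameter; default 2).
#' @param min_shared_genes Minimum shared genes per essentiality comparison.
#' @param pool_children Pool child hypotheses across parents in the BH pass.
#' @param seed Integer run seed.
#' @return Named list of validated options.
#' @export
unres_options <- function(p_parent = 0.001, d_threshold = -1, min_mut = 4,
                          max_extrapolated_frac = 0.5, alpha_child = 0.15,
                          B = 10000, i_max = 5, half = "floor", n_perm = 100,
                          fisher_p = 0.05, delta_ess_highlight = 4,
                          normalized_label = 0.5, tau = 2,
                          min_shared_genes = 100, pool_children = TRUE,
                          seed = 1L) {
  opts <- list(p_parent = p_parent, d_threshold = d_threshold,
               min_mut = as.integer(min_mut),
               max_extrapolated_frac = max_extrapolated_frac,
               alpha_child = alpha_child, B = as.integer(B),
               i_max = as.integer(i_max), half = half,
               n_perm = as.integer(n_perm), fisher_p = fisher_p,
               delta_ess_highlight = delta_ess_highlight,
               normalized_label = normalized_label, tau = tau,
               min_shared_genes = as.integer(min_shared_genes),
               pool_children = isTRUE(pool_children), seed = as.integer(seed))
  if (opts$p_parent <= 0 || opts$p_parent > 1) stop_config("p_parent out of (0,1]")
  if (opts$alpha_child <= 0 || opts$alpha_child >= 1) stop_config("alpha_child out of (0,1)")
  if (opts$max_extrapolated_frac < 0 || opts$max_extrapolated_frac > 1)
    stop_config("max_extrapolated_frac out of [0,1]")
  if (opts$B < 1 || opts$i_max < 1 || opts$min_mut < 4 || opts$n_perm < 1)
    stop_config("B, i_max, n_perm must be positive and min_mut >= 4")
  if (!opts$half %in% c("floor", "ceiling")) stop_config("half must be floor or ceiling")
  if (opts$fisher_p <= 0 || opts$fisher_p >= 1) stop_config("fisher_p out of (0,1)")
  if (opts$tau <= 0 || opts$delta_ess_highlight <= 0)
    stop_config("tau and delta_ess_highlight must be positive")
  opts
}

#' Run discovery, UNRES detection and HFDR on in-memory tables
#'
#' The computational core of the pipeline: enumerates candidates, discovers
#' sensitivity associations, detects UNRES cases under every retained
#' association, fills their adjusted p-values through the pooled BH pass of
#' [hfdr_select()], and computes the global FDR bound with the number of
#' families taken as the unique tested (drug, tissue) combinations.
#'
#' @param resp,cfe,ann Screen tables.
#' @param opts See [unres_options()].
#' @return List: `candidates`, `associations`, `unres_cases`, `hfdr`,
#'   `n_families`, `fdr_bound`.
#' @export
analyse_screen <- function(resp, cfe, ann, opts = unres_options()) {
  cand <- enumerate_candidates(cfe, resp, ann, min_mut = opts$min_mut,
                               max_extrapolated_frac = opts$max_extrapolated_frac)
  assoc <- discover_associations(cand, resp, ann, cfe,
                                 p_threshold = opts$p_parent,
                                 d_threshold = opts$d_threshold)
  cases <- detect_unres_all(assoc, resp, ann, cfe, B = opts$B, seed = opts$seed,
                            i_max = opts$i_max, half = opts$half)
  ret <- assoc[assoc$retained, , drop = FALSE]
  parent_p <- stats::setNames(ret$p_value, paste(ret$tissue, ret$drug, ret$cfe, sep = "|"))
  child_p <- if (nrow(cases))
    lapply(split(stats::setNames(cases$p_value, paste0("i=", cases$i)), cases$parent),
           identity)
  else list()
  hfdr <- hfdr_select(parent_p, child_p, alpha_parent = opts$p_parent,
                      alpha_child = opts$alpha_child,
                      pool_children = opts$pool_children)
  if (nrow(cases)) {
    key <- paste(cases$parent, paste0("i=", cases$i))
    ckey <- paste(hfdr$children$parent, hfdr$children$child)
    idx <- match(key, ckey)
    cases$p_adjusted <- hfdr$children$p_adjusted[idx]
    cases$selected <- hfdr$children$selected[idx]
    cases$labeled <- !is.na(cases$normalized_sd_decrease) &
      cases$normalized_sd_decrease > opts$normalized_label
  }
  n_fam <- nrow(unique(cand[, c("tissue", "drug")]))
  bound <- if (n_fam >= 1)
    fdr_bound(hfdr$n_discoveries, n_fam, opts$alpha_child) else NA_real_
  list(candidates = cand, associations = assoc, unres_cases = cases,
       hfdr = hfdr, n_families = n_fam, fdr_bound = bound)
}

# Carrier cells of an association with measured responses, in the tissue.
.association_carriers <- function(association, resp, ann, cfe) {
  cells_t <- ann$cell_line[ann$tissue == association$tissue]
  rd <- resp[resp$drug == association$drug & resp$cell_line %in% cells_t, , drop = FALSE]
  rd <- rd[rd$cell_line %in% rownames(cfe$matrix), , drop = FALSE]
  rd$cell_line[cfe$matrix[rd$cell_line, association$cfe] == 1]
}

#' Run the full pipeline and write a results directory
#'
#' Stages: read inputs -> discover associations -> detect UNRES cases ->
#' HFDR selection -> resistance biomarkers per selected case -> optional
#' differential essentiality (when a gene-effect matrix is supplied).
#' Writes one TSV per stage plus `manifest.json` (inputs with MD5 digests,
#' options, seed, package version, skipped stages).
#'
#' @param drug_response,cfe_matrix_path,cfe_metadata,annotations Input file
#'   paths (see the corresponding `read_*` functions).
#' @param out Output directory (created if needed).
#' @param gene_effect Optional gene-effect CSV path.
#' @param gene_effect_orientation Orientation of the gene-effect matrix.
#' @param cancer_genes Optional cancer-gene-list path.
#' @param opts See [unres_options()].
#' @return Invisibly, the analysis list of [analyse_screen()] augmented
#'   with `biomarkers`, `delta_ess` and `manifest`.
#' @export
run_pipeline <- function(drug_response, cfe_matrix_path, cfe_metadata, annotations,
                         out, gene_effect = NULL,
                         gene_effect_orientation = "genes_in_rows",
                         cancer_genes = NULL, opts = unres_options()) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(drug_response = drug_response, cfe_matrix = cfe_matrix_path,
              cfe_metadata = cfe_metadata, annotations = annotations,
              gene_effect = gene_effect, cancer_genes = cancer_genes)
  resp <- read_drug_response(drug_response)
  cfe <- read_cfe_matrix(cfe_matrix_path, cfe_metadata)
  ann <- read_annotations(annotations)
  genes <- if (!is.null(cancer_genes)) read_gene_list(cancer_genes)
  message(sprintf("inputs: %d response rows, %d cell lines x %d CFEs, %d annotated lines",
                  nrow(resp), nrow(cfe$matrix), ncol(cfe$matrix), nrow(ann)))
  ana <- analyse_screen(resp, cfe, ann, opts)
  message(sprintf("funnel: %d candidates -> %d tested -> %d retained -> %d UNRES cases (%d selected)",
                  nrow(ana$candidates), sum(!is.na(ana$associations$p_value)),
                  sum(ana$associations$retained), nrow(ana$unres_cases),
                  sum(ana$unres_cases$selected %in% TRUE)))
  write_tsv(ana$candidates, file.path(out, "candidates.tsv"))
  write_tsv(ana$associations, file.path(out, "associations.tsv"))
  write_tsv(ana$unres_cases, file.path(out, "unres_cases.tsv"))

  sel <- ana$unres_cases[ana$unres_cases$selected %in% TRUE, , drop = FALSE]
  bm <- list()
  for (r in seq_len(nrow(sel))) {
    case <- sel[r, ]
    carriers <- .association_carriers(case, resp, ann, cfe)
    unres_cells <- strsplit(case$removed_cells, ";", fixed = TRUE)[[1]]
    sens <- setdiff(carriers, unres_cells)
    cand <- propose_biomarkers(unres_cells, sens, cfe, case$cfe,
                               gene_list = genes, fisher_threshold = opts$fisher_p)
    if (nrow(cand)) {
      cand <- cbind(data.frame(tissue = case$tissue, drug = case$drug,
                               association_cfe = case$cfe, i = case$i,
                               unres_cells = case$removed_cells,
                               stringsAsFactors = FALSE),
                    cand)
      bm[[length(bm) + 1L]] <- cand
    }
  }
  biomarkers <- if (length(bm)) do.call(rbind, bm) else NULL
  if (!is.null(biomarkers)) write_tsv(biomarkers, file.path(out, "biomarkers.tsv"))

  delta_tabs <- list()
  skipped <- character()
  if (!is.null(gene_effect)) {
    ess <- read_essentiality(gene_effect, orientation = gene_effect_orientation)
    for (r in seq_len(nrow(sel))) {
      case <- sel[r, ]
      carriers <- .association_carriers(case, resp, ann, cfe)
      unres_cells <- intersect(strsplit(case$removed_cells, ";", fixed = TRUE)[[1]],
                               colnames(ess))
      sens <- intersect(setdiff(carriers, unres_cells), colnames(ess))
      if (!length(unres_cells) || !length(sens)) next
      cells_t <- ann$cell_line[ann$tissue == case$tissue]
      in_mat <- intersect(cells_t, rownames(cfe$matrix))
      wt <- intersect(in_mat[cfe$matrix[in_mat, case$cfe] == 0], colnames(ess))
      for (idx_cell in unres_cells) {
        tab <- delta_essentiality(ess[, idx_cell],
                                  ess[, sens, drop = FALSE],
                                  min_shared = opts$min_shared_genes)
        if (length(wt)) {
          tab_wt <- delta_essentiality(ess[, idx_cell], ess[, wt, drop = FALSE],
                                       min_shared = opts$min_shared_genes)
          tab <- classify_wt_like(tab, tab_wt, tau = opts$tau)
        }
        hi <- highlight_genes(tab, opts$delta_ess_highlight)
        tab$highlight <- ifelse(tab$gene %in% hi$uniquely_essential, "uniquely_essential",
                                ifelse(tab$gene %in% hi$less_essential, "less_essential", ""))
        fn <- file.path(out, sprintf("delta_ess_%s_%s_i%d.tsv", idx_cell, case$drug, case$i))
        write_tsv(tab, fn)
        delta_tabs[[sprintf("%s|%s|i=%d", idx_cell, case$drug, case$i)]] <- tab
      }
    }
  } else {
    skipped <- "diff_essentiality (no gene-effect matrix supplied)"
    message("skipping essentiality stage: no gene-effect matrix supplied")
  }

  manifest <- list(
    package = "unresscreen",
    version = as.character(utils::packageVersion("unresscreen")),
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    options = opts, seed = opts$seed,
    n_families = ana$n_families, fdr_bound = ana$fdr_bound,
    n_discoveries = ana$hfdr$n_discoveries,
    skipped_stages = as.list(skipped))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(ana, list(biomarkers = biomarkers, delta_ess = delta_tabs,
                        manifest = manifest)))
}

#' Run the within-tissue permutation study and write its reports
#'
#' @inheritParams run_pipeline
#' @param n_perm Number of permutation replicates (defaults to
#'   `opts$n_perm`).
#' @return Invisibly, the `unres_permutation` object.
#' @export
run_permutation_study <- function(drug_response, cfe_matrix_path, cfe_metadata,
                                  annotations, out, n_perm = NULL,
                                  opts = unres_options()) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  resp <- read_drug_response(drug_response)
  cfe <- read_cfe_matrix(cfe_matrix_path, cfe_metadata)
  ann <- read_annotations(annotations)
  perm <- permute_within_tissue(resp, ann, cfe, n_perm = n_perm %||% opts$n_perm,
                                seed = opts$seed, opts = opts)
  write_tsv(perm$replicates, file.path(out, "permutation_replicates.tsv"))
  jsonlite::write_json(perm$summary, file.path(out, "permutation_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(perm)
}
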