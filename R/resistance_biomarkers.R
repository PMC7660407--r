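.empty_biomarkers <- function() {
  df <- data.frame(cfe_id = character(), evidence = character(),
                   direction = character(), fisher_p = numeric(),
                   stringsAsFactors = FALSE)
  df$genes <- list()
  df
}

.candidate_df <- function(ids, evidence, direction, cfe, fisher_p = NA_real_) {
  if (!length(ids)) return(.empty_biomarkers())
  df <- data.frame(cfe_id = ids, evidence = evidence,
                   direction = direction,
                   fisher_p = fisher_p, stringsAsFactors = FALSE)
  df$genes <- cfe$metadata$genes[match(ids, cfe$metadata$cfe_id)]
  rownames(df) <- NULL
  df
}

#' Second mutations in the sensitivity-biomarker gene(s) unique to UNRES lines
#'
#' The classic pattern is a secondary mutation in the drug's target gene
#' (e.g. a gatekeeper mutation) found in the resistant line but in none of
#' the sensitive carriers. Candidates are mutation-class CFEs whose member
#' genes overlap the association CFE's genes, present in at least one UNRES
#' cell and absent from every sensitive cell.
#'
#' @param unres_cells,sensitive_cells Cell-line id vectors partitioning the
#'   association's carriers.
#' @param cfe An `unres_cfe_matrix`.
#' @param association_cfe The association's own cfe_id (supplies the target
#'   genes; excluded from the candidates).
#' @return Biomarker-candidate data frame.
#' @export
unique_target_mutations <- function(unres_cells, sensitive_cells, cfe,
                                    association_cfe) {
  meta <- cfe$metadata
  idx <- match(association_cfe, meta$cfe_id)
  if (is.na(idx)) stop_input(sprintf("unknown CFE id: %s", association_cfe))
  target_genes <- meta$genes[[idx]]
  if (!length(target_genes)) {
    message(sprintf("association CFE %s has no gene annotation; skipping unique-mutation search",
                    association_cfe))
    return(.empty_biomarkers())
  }
  in_target <- vapply(meta$genes, function(g)
    any(toupper(g) %in% toupper(target_genes)), logical(1))
  pool <- setdiff(meta$cfe_id[meta$alteration_class == "mutation" & in_target],
                  association_cfe)
  mat <- cfe$matrix
  hits <- pool[vapply(pool, function(id)
    any(mat[unres_cells, id] == 1) && all(mat[sensitive_cells, id] == 0), logical(1))]
  .candidate_df(hits, "unique_target_mutation", "present_in_unres", cfe)
}

#' Mutually exclusive CFEs between UNRES and sensitive cells
#'
#' A CFE is a candidate when it is altered in all UNRES cells and wild type
#' in all sensitive cells (`present_in_unres`) or the reverse
#' (`absent_in_unres`).
#'
#' @inheritParams unique_target_mutations
#' @return Biomarker-candidate data frame.
#' @export
mutually_exclusive_cfes <- function(unres_cells, sensitive_cells, cfe) {
  if (!length(unres_cells) || !length(sensitive_cells))
    stop_argument("need at least one UNRES and one sensitive cell line")
  mat <- cfe$matrix
  u <- mat[unres_cells, , drop = FALSE]
  s <- mat[sensitive_cells, , drop = FALSE]
  all_u <- .colSums(u, nrow(u), ncol(u)) == nrow(u)
  none_u <- .colSums(u, nrow(u), ncol(u)) == 0
  all_s <- .colSums(s, nrow(s), ncol(s)) == nrow(s)
  none_s <- .colSums(s, nrow(s), ncol(s)) == 0
  present <- colnames(mat)[all_u & none_s]
  absent <- colnames(mat)[none_u & all_s]
  rbind(.candidate_df(present, "mutually_exclusive", "present_in_unres", cfe),
        .candidate_df(absent, "mutually_exclusive", "absent_in_unres", cfe))
}

#' CFEs enriched in UNRES cells (Fisher's exact test)
#'
#' Applied only when there are multiple UNRES cell lines. Each CFE is tested
#' two-sided on the 2x2 table (UNRES/sensitive x altered/wild-type); every
#' CFE is reported with its p-value and candidates are flagged at
#' `p_threshold`.
#'
#' @inheritParams unique_target_mutations
#' @param p_threshold Enrichment significance threshold (default 0.05).
#' @return Data frame of all CFEs with `fisher_p`, `direction` and a
#'   `candidate` flag; empty (with a message) when fewer than 2 UNRES cells.
#' @export
enriched_cfes <- function(unres_cells, sensitive_cells, cfe, p_threshold = 0.05) {
  if (length(unres_cells) < 2) {
    message("fewer than 2 UNRES cell lines; skipping enrichment test")
    out <- .empty_biomarkers()
    out$candidate <- logical()
    return(out)
  }
  mat <- cfe$matrix
  u <- mat[unres_cells, , drop = FALSE]
  s <- mat[sensitive_cells, , drop = FALSE]
  a <- .colSums(u, nrow(u), ncol(u))          # UNRES altered
  cc <- .colSums(s, nrow(s), ncol(s))         # sensitive altered
  p <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- matrix(c(a[j], nrow(u) - a[j], cc[j], nrow(s) - cc[j]), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  frac_u <- a / nrow(u)
  frac_s <- cc / nrow(s)
  out <- .candidate_df(colnames(mat), "enriched",
                       ifelse(frac_u >= frac_s, "present_in_unres", "absent_in_unres"),
                       cfe, fisher_p = p)
  out$candidate <- p < p_threshold
  out
}

#' Filter biomarker candidates to a cancer gene list
#'
#' Flags each candidate by whether at least one member gene is in the list
#' (comparison is case-insensitive). The full candidate set is returned with
#' the flag, so callers can keep both the filtered and unfiltered views.
#'
#' @param candidates Biomarker-candidate data frame with a `genes` list
#'   column.
#' @param genes Character vector of cancer gene symbols (see
#'   [read_gene_list()]).
#' @return `candidates` with an added logical `in_cancer_gene_list` column.
#' @export
filter_cancer_genes <- function(candidates, genes) {
  if (!length(genes)) stop_config("cancer gene list is empty")
  genes <- toupper(genes)
  candidates$in_cancer_gene_list <- vapply(candidates$genes, function(g)
    any(toupper(g) %in% genes), logical(1))
  candidates
}

#' Propose putative resistance biomarkers for one UNRES case
#'
#' Runs the three evidence routes (unique target mutations, mutual
#' exclusivity, Fisher enrichment), concatenates and de-duplicates by CFE,
#' keeping the strongest evidence class in the order
#' unique_target_mutation > mutually_exclusive > enriched, and annotates
#' candidates against the cancer gene list when one is supplied.
#'
#' @inheritParams unique_target_mutations
#' @param gene_list Optional cancer gene list.
#' @param fisher_threshold Enrichment significance threshold (default 0.05).
#' @return Biomarker-candidate data frame.
#' @export
propose_biomarkers <- function(unres_cells, sensitive_cells, cfe, association_cfe,
                               gene_list = NULL, fisher_threshold = 0.05) {
  enr <- enriched_cfes(unres_cells, sensitive_cells, cfe, fisher_threshold)
  enr <- enr[which(enr$candidate), setdiff(names(enr), "candidate"), drop = FALSE]
  out <- rbind(
    unique_target_mutations(unres_cells, sensitive_cells, cfe, association_cfe),
    mutually_exclusive_cfes(unres_cells, sensitive_cells, cfe),
    enr)
  out <- out[!duplicated(out$cfe_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(gene_list)) out <- filter_cancer_genes(out, gene_list)
  out
}
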