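#' Simulation configuration for synthetic screens
#'
#' The defaults describe the reference world used throughout the test suite:
#' tissues of 25 cell lines, planted sensitivity associations with exactly 10
#' CFE carriers shifted by -6 ln-IC50 units (i.e. -6 noise SDs at the default
#' `noise_sd = 1`), and one planted UNRES line per association that carries
#' the CFE but reverts fully to the non-responder baseline.
#'
#' @param n_tissues Number of tissues (cancer types).
#' @param cells_per_tissue Cell lines per tissue (>= 8).
#' @param n_drugs Number of drugs screened on every cell line.
#' @param n_cfes Number of CFE columns.
#' @param cfe_frequency Bernoulli alteration frequency for non-planted CFEs.
#' @param sensitivity_shift Mean ln-IC50 shift of carriers of a planted
#'   association's CFE (negative = sensitising).
#' @param n_planted_associations Number of planted (tissue, drug, CFE)
#'   sensitivity associations; each uses a distinct CFE.
#' @param n_planted_unres_per_association Carriers per planted association
#'   that revert to the baseline mean (the planted UNRES lines); may be 0.
#' @param n_carriers_per_association Exact carrier count assigned to each
#'   planted CFE within its tissue.
#' @param noise_sd SD of the baseline ln-IC50 noise.
#' @param max_screened_conc Maximum screened concentration (uM), constant
#'   across measurements.
#' @param n_genes,n_differential,differential_shift Gene-effect simulation:
#'   total genes, planted differentially essential genes, and their score
#'   shift in the index cell line(s).
#' @param seed Integer master seed.
#' @return An `unres_sim_config` list.
#' @export
sim_config <- function(n_tissues = 4, cells_per_tissue = 25, n_drugs = 5, n_cfes = 8,
                       cfe_frequency = 0.4, sensitivity_shift = -6,
                       n_planted_associations = 4, n_planted_unres_per_association = 1,
                       n_carriers_per_association = 10,
                       noise_sd = 1, max_screened_conc = 100,
                       n_genes = 2000, n_differential = 5, differential_shift = -6,
                       seed = 1L) {
  cfg <- list(n_tissues = as.integer(n_tissues),
              cells_per_tissue = as.integer(cells_per_tissue),
              n_drugs = as.integer(n_drugs), n_cfes = as.integer(n_cfes),
              cfe_frequency = cfe_frequency, sensitivity_shift = sensitivity_shift,
              n_planted_associations = as.integer(n_planted_associations),
              n_planted_unres_per_association = as.integer(n_planted_unres_per_association),
              n_carriers_per_association = as.integer(n_carriers_per_association),
              noise_sd = noise_sd, max_screened_conc = max_screened_conc,
              n_genes = as.integer(n_genes), n_differential = as.integer(n_differential),
              differential_shift = differential_shift, seed = as.integer(seed))
  if (cfg$cells_per_tissue < 8) stop_config("cells_per_tissue must be >= 8")
  if (cfg$sensitivity_shift >= 0) stop_config("sensitivity_shift must be negative")
  if (cfg$noise_sd <= 0) stop_config("noise_sd must be positive")
  if (cfg$cfe_frequency <= 0 || cfg$cfe_frequency >= 1)
    stop_config("cfe_frequency must be in (0, 1)")
  if (cfg$n_planted_associations > cfg$n_cfes)
    stop_config("need one distinct CFE per planted association")
  if (cfg$n_planted_associations > cfg$n_tissues * cfg$n_drugs)
    stop_config("more planted associations than (tissue, drug) slots")
  if (cfg$n_carriers_per_association > cfg$cells_per_tissue)
    stop_config("n_carriers_per_association exceeds cells_per_tissue")
  if (cfg$n_planted_unres_per_association >= cfg$n_carriers_per_association)
    stop_config("n_planted_unres_per_association must be below the carrier count")
  if (cfg$n_differential > cfg$n_genes)
    stop_config("n_differential exceeds n_genes")
  structure(cfg, class = "unres_sim_config")
}

#' Generate a complete synthetic screen with planted ground truth
#'
#' Baseline ln-IC50 values are Normal(0, `noise_sd`) for every (cell line,
#' drug) pair. Carriers of a planted association's CFE are shifted by
#' `sensitivity_shift` for that drug; planted UNRES lines carry the CFE but
#' keep the baseline distribution, so they sit intermingled with the
#' non-responders. Covariates are drawn independently of CFE status.
#'
#' @param config An [sim_config()] object.
#' @return List with `$drug_response`, `$cfe`, `$annotations`,
#'   `$ground_truth` (planted associations, carriers and UNRES lines).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "unres_sim_config"))
  with_seed(stream_seed(config$seed, "screen"), {
    tissues <- sprintf("TISSUE%02d", seq_len(config$n_tissues))
    cells <- unlist(lapply(tissues, function(t)
      sprintf("%s_C%02d", t, seq_len(config$cells_per_tissue))))
    tissue_of <- rep(tissues, each = config$cells_per_tissue)
    names(tissue_of) <- cells
    drugs <- sprintf("DRUG%02d", seq_len(config$n_drugs))
    cfes <- sprintf("CFE%02d", seq_len(config$n_cfes))

    mat <- matrix(stats::rbinom(length(cells) * config$n_cfes, 1, config$cfe_frequency),
                  nrow = length(cells), dimnames = list(cells, cfes))

    k <- config$n_planted_associations
    planted <- if (k > 0) {
      data.frame(
        tissue = tissues[((seq_len(k) - 1) %% config$n_tissues) + 1],
        drug = drugs[(((seq_len(k) - 1) %/% config$n_tissues) %% config$n_drugs) + 1],
        cfe = cfes[seq_len(k)], stringsAsFactors = FALSE)
    } else {
      data.frame(tissue = character(), drug = character(), cfe = character(),
                 stringsAsFactors = FALSE)
    }

    carriers <- vector("list", k)
    unres <- vector("list", k)
    for (j in seq_len(k)) {
      cells_t <- cells[tissue_of == planted$tissue[j]]
      mat[cells_t, planted$cfe[j]] <- 0
      carr <- sort(sample(cells_t, config$n_carriers_per_association))
      mat[carr, planted$cfe[j]] <- 1
      carriers[[j]] <- carr
      unres[[j]] <- if (config$n_planted_unres_per_association > 0)
        sort(sample(carr, config$n_planted_unres_per_association)) else character()
    }

    resp <- expand.grid(cell_line = cells, drug = drugs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    resp$ln_ic50 <- stats::rnorm(nrow(resp), 0, config$noise_sd)
    for (j in seq_len(k)) {
      shifted <- setdiff(carriers[[j]], unres[[j]])
      hit <- resp$drug == planted$drug[j] & resp$cell_line %in% shifted
      resp$ln_ic50[hit] <- resp$ln_ic50[hit] + config$sensitivity_shift
    }
    resp$max_conc <- config$max_screened_conc

    ann <- data.frame(
      cell_line = cells, tissue = tissue_of,
      msi_status = sample(c("MSS", "MSI"), length(cells), replace = TRUE, prob = c(0.85, 0.15)),
      medium = sample(c("DMEM", "RPMI"), length(cells), replace = TRUE),
      growth_property = sample(c("Adherent", "Semi-Adherent"), length(cells), replace = TRUE),
      stringsAsFactors = FALSE)

    classes <- rep("mutation", config$n_cfes)
    if (config$n_cfes > k)
      classes[(k + 1):config$n_cfes] <-
        sample(c("mutation", "cna", "methylation"), config$n_cfes - k, replace = TRUE)
    meta <- data.frame(cfe_id = cfes, alteration_class = classes,
                       stringsAsFactors = FALSE)
    meta$genes <- lapply(cfes, function(id) paste0("GENE_", id))
    meta$has_driver_gene <- TRUE

    gt <- list(associations = planted, carriers = carriers, unres = unres,
               config = unclass(config))
    list(drug_response = as_drug_response(resp),
         cfe = cfe_matrix(mat, meta),
         annotations = as_annotations(ann),
         ground_truth = gt)
  })
}

#' Generate a synthetic CRISPR gene-effect matrix
#'
#' Scores are standard normal per (gene, cell line); the first
#' `n_differential` genes are shifted by `differential_shift` in the index
#' cell line(s) only, planting a differential-essentiality signal.
#'
#' @param config An [sim_config()] object (uses the `n_genes`,
#'   `n_differential`, `differential_shift` and `seed` fields).
#' @param index_cells Character vector of index (e.g. UNRES) cell lines.
#' @param comparator_cells Character vector of comparator cell lines.
#' @return List with `$matrix` (gene x cell line) and `$ground_truth`
#'   (`$differential_genes`).
#' @export
generate_essentiality <- function(config, index_cells, comparator_cells) {
  stopifnot(inherits(config, "unres_sim_config"))
  if (config$n_genes < 100) stop_config("need at least 100 genes")
  cells <- c(index_cells, comparator_cells)
  if (anyDuplicated(cells)) stop_config("index and comparator cells overlap")
  with_seed(stream_seed(config$seed, "essentiality"), {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    mat <- matrix(stats::rnorm(config$n_genes * length(cells)),
                  nrow = config$n_genes, dimnames = list(genes, cells))
    diff_genes <- genes[seq_len(config$n_differential)]
    mat[diff_genes, index_cells] <- mat[diff_genes, index_cells] + config$differential_shift
    list(matrix = mat,
         ground_truth = list(differential_genes = diff_genes,
                             index_cells = index_cells,
                             comparator_cells = comparator_cells))
  })
}

#' Write a synthetic screen to a fixture-bundle directory
#'
#' Produces `drug_response.csv`, `cfe_matrix.csv`, `cfe_metadata.csv`,
#' `annotations.csv`, optionally `gene_effect.csv`, and `ground_truth.json`,
#' all readable by the `read_*` functions.
#'
#' @param screen Output of [generate_screen()].
#' @param dir Target directory (created if needed).
#' @param essentiality Optional output of [generate_essentiality()].
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture_bundle <- function(screen, dir, essentiality = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0)
    stop_input(sprintf("cannot write to directory: %s", dir))
  paths <- c(drug_response = file.path(dir, "drug_response.csv"),
             cfe_matrix = file.path(dir, "cfe_matrix.csv"),
             cfe_metadata = file.path(dir, "cfe_metadata.csv"),
             annotations = file.path(dir, "annotations.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(as.data.frame(screen$drug_response), paths["drug_response"],
                   row.names = FALSE, quote = FALSE)
  mat_df <- data.frame(cell_line = rownames(screen$cfe$matrix),
                       screen$cfe$matrix, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.csv(mat_df, paths["cfe_matrix"], row.names = FALSE, quote = FALSE)
  meta <- screen$cfe$metadata
  meta$genes <- vapply(meta$genes, paste, character(1), collapse = ";")
  utils::write.csv(meta, paths["cfe_metadata"], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(screen$annotations), paths["annotations"],
                   row.names = FALSE, quote = FALSE)
  gt <- screen$ground_truth
  if (!is.null(essentiality)) {
    paths <- c(paths, gene_effect = file.path(dir, "gene_effect.csv"))
    ge <- data.frame(gene = rownames(essentiality$matrix), essentiality$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(ge, paths["gene_effect"], row.names = FALSE, quote = FALSE)
    gt$essentiality <- essentiality$ground_truth
  }
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
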