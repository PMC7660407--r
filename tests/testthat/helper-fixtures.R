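# Shared in-code fixtures. Everything is generated at test time; nothing is
# stored on disk.

# A hand-sized CFE matrix: cells A..F, four CFEs with mixed classes.
tiny_cfe <- function() {
  mat <- rbind(
    A = c(CFE_A = 1, CFE_B = 0, CFE_C = 1, CFE_D = 0),
    B = c(1, 1, 0, 0),
    C = c(1, 0, 0, 1),
    D = c(0, 1, 0, 1),
    E = c(0, 0, 1, 1),
    F = c(0, 1, 1, 0))
  meta <- data.frame(
    cfe_id = c("CFE_A", "CFE_B", "CFE_C", "CFE_D"),
    alteration_class = c("mutation", "mutation", "cna", "methylation"),
    genes = c("EGFR", "TP53", "", "MLH1"),
    has_driver_gene = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  cfe_matrix(mat, meta)
}

# One-tissue screen assembled by hand: `carriers` get `shift` added for drug
# DRUG1, everything else is baseline Normal(0, sd).
hand_screen <- function(n_cells = 20, carriers = 1:8, shift = -6, sd = 1,
                        seed = 42, n_cfes = 2) {
  withr_seed <- function(code) { set.seed(seed); code }
  cells <- sprintf("C%02d", seq_len(n_cells))
  withr_seed({
    y <- rnorm(n_cells, 0, sd)
    y[carriers] <- y[carriers] + shift
    resp <- as_drug_response(data.frame(
      cell_line = cells, drug = "DRUG1", ln_ic50 = y, max_conc = 100,
      stringsAsFactors = FALSE))
    mat <- matrix(0, n_cells, n_cfes,
                  dimnames = list(cells, sprintf("CFE%d", seq_len(n_cfes))))
    mat[carriers, 1] <- 1
    mat[, -1] <- rbinom(n_cells * (n_cfes - 1), 1, 0.3)
    meta <- data.frame(cfe_id = colnames(mat), alteration_class = "mutation",
                       genes = paste0("G_", colnames(mat)),
                       has_driver_gene = TRUE, stringsAsFactors = FALSE)
    ann <- as_annotations(data.frame(
      cell_line = cells, tissue = "LUNG",
      msi_status = sample(c("MSS", "MSI"), n_cells, TRUE, prob = c(.85, .15)),
      medium = sample(c("DMEM", "RPMI"), n_cells, TRUE),
      growth_property = sample(c("Adherent", "Semi-Adherent"), n_cells, TRUE),
      stringsAsFactors = FALSE))
    list(resp = resp, cfe = cfe_matrix(mat, meta), ann = ann, cells = cells)
  })
}

expect_unres_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
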