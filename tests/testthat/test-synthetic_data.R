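test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "unres_sim_config")
  expect_error(sim_config(cells_per_tissue = 5), class = "unres_config_error")
  expect_error(sim_config(sensitivity_shift = 1), class = "unres_config_error")
  expect_error(sim_config(noise_sd = 0), class = "unres_config_error")
  expect_error(sim_config(n_planted_unres_per_association = 10,
                          n_carriers_per_association = 10),
               class = "unres_config_error")
  expect_error(sim_config(n_differential = 5000), class = "unres_config_error")
})

test_that("generate_screen is deterministic and respects type invariants", {
  cfg <- sim_config(seed = 123)
  a <- generate_screen(cfg)
  b <- generate_screen(cfg)
  expect_identical(a, b)
  expect_true(all(a$cfe$matrix %in% 0:1))
  expect_false(anyDuplicated(paste(a$drug_response$cell_line, a$drug_response$drug)) > 0)
  # every planted UNRES cell carries the association's CFE
  gt <- a$ground_truth
  for (j in seq_len(nrow(gt$associations)))
    expect_true(all(a$cfe$matrix[gt$unres[[j]], gt$associations$cfe[j]] == 1))
})

test_that("null screens produce no discoveries at the parent thresholds", {
  cfg <- sim_config(n_planted_associations = 0, seed = 5)
  s <- generate_screen(cfg)
  cand <- enumerate_candidates(s$cfe, s$drug_response, s$annotations)
  assoc <- discover_associations(cand, s$drug_response, s$annotations, s$cfe)
  expect_gt(nrow(assoc), 50)
  expect_equal(sum(assoc$retained), 0)
})

test_that("planted UNRES line has the maximum ln-IC50 among carriers", {
  # Monte-Carlo check of the generator: with shift -6 * noise_sd the reverted
  # line should top the carriers in > 99% of replicates (300 here, scaled
  # down from the 1,000 of a full run; the true rate is ~1 - 1e-4).
  hits <- 0L
  reps <- 300L
  for (s in seq_len(reps)) {
    cfg <- sim_config(n_tissues = 1, n_drugs = 1, n_cfes = 1,
                      n_planted_associations = 1,
                      n_carriers_per_association = 10,
                      n_planted_unres_per_association = 1, seed = s)
    sc <- generate_screen(cfg)
    gt <- sc$ground_truth
    carr <- gt$carriers[[1]]
    resp <- sc$drug_response
    vals <- resp$ln_ic50[match(carr, resp$cell_line)]
    if (carr[which.max(vals)] == gt$unres[[1]]) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.99)
})

test_that("non-carrier ln-IC50 marginals match the configured normal", {
  cfg <- sim_config(n_tissues = 4, cells_per_tissue = 100, n_drugs = 25,
                    n_cfes = 2, n_planted_associations = 0, seed = 77)
  s <- generate_screen(cfg)
  y <- s$drug_response$ln_ic50  # 10,000 baseline draws
  expect_gte(length(y), 10000)
  expect_lt(abs(mean(y)), 0.05)
  expect_lt(abs(sd(y) - cfg$noise_sd), 0.05)
  skw <- mean((y - mean(y))^3) / sd(y)^3
  expect_lt(abs(skw), 0.1)
})

test_that("generate_essentiality plants a recoverable differential signal", {
  cfg <- sim_config(seed = 9)
  ge1 <- generate_essentiality(cfg, "IDX", c("A", "B", "C"))
  ge2 <- generate_essentiality(cfg, "IDX", c("A", "B", "C"))
  expect_identical(ge1, ge2)
  expect_error(generate_essentiality(cfg, "A", c("A", "B")),
               class = "unres_config_error")
  expect_no_error(generate_essentiality(sim_config(n_genes = 150, seed = 1), "I", "C"))

  # null construction: no shift -> planted genes centred at zero across seeds
  means <- vapply(1:20, function(s) {
    cfg0 <- sim_config(differential_shift = 0, seed = s)
    # differential_shift = 0 still passes sim_config (only sensitivity_shift
    # must be negative); the planted genes then carry no signal
    ge <- generate_essentiality(cfg0, "IDX", c("A", "B"))
    tab <- delta_essentiality(ge$matrix[, "IDX"], ge$matrix[, c("A", "B")])
    mean(tab$delta_ess[tab$gene %in% ge$ground_truth$differential_genes])
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.5)

  # planted -6 genes land deep in the left tail (bottom 1% of 2,000 genes)
  for (s in 1:10) {
    ge <- generate_essentiality(sim_config(seed = s), "IDX", c("A", "B", "C"))
    tab <- delta_essentiality(ge$matrix[, "IDX"], ge$matrix[, c("A", "B", "C")])
    bottom <- tab$gene[order(tab$delta_ess)][1:20]
    expect_true(all(ge$ground_truth$differential_genes %in% bottom))
  }
})

test_that("fixture bundles round-trip through the readers", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 31)
  s <- generate_screen(cfg)
  gt <- s$ground_truth
  ess <- generate_essentiality(cfg, gt$unres[[1]],
                               setdiff(gt$carriers[[1]], gt$unres[[1]]))
  paths <- write_fixture_bundle(s, d, essentiality = ess)
  expect_true(all(file.exists(paths)))

  resp <- read_drug_response(paths["drug_response"])
  expect_equal(resp$ln_ic50, s$drug_response$ln_ic50, tolerance = 1e-12)
  expect_identical(resp$cell_line, s$drug_response$cell_line)
  cfe <- read_cfe_matrix(paths["cfe_matrix"], paths["cfe_metadata"])
  expect_identical(cfe$matrix, s$cfe$matrix)
  ann <- read_annotations(paths["annotations"])
  expect_identical(as.data.frame(ann), as.data.frame(s$annotations))
  m <- read_essentiality(paths["gene_effect"])
  expect_equal(m, ess$matrix, tolerance = 1e-12)

  js <- jsonlite::read_json(paths["ground_truth"], simplifyVector = TRUE)
  expect_equal(nrow(js$associations), cfg$n_planted_associations)
})
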