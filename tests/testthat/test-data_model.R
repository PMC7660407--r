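test_that("read_drug_response parses, computes extrapolation, honours dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cl,cmpd,logic50,conc",
               "A,D1,0.5,10",
               "B,D1,3.4,10",      # ln(10) = 2.303 < 3.4 -> extrapolated
               sprintf("C,D1,%.17g,10", log(10)),  # exactly ln(max): strict, so FALSE
               sprintf("D,D1,%.10f,10", log(10) + 1)),
             f)
  tab <- read_drug_response(f, dialect = list(cell_line = "cl", drug = "cmpd",
                                              ln_ic50 = "logic50", max_conc = "conc"))
  expect_s3_class(tab, "unres_drug_response")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$extrapolated, c(FALSE, TRUE, FALSE, TRUE))

  # missing column is a schema error naming the column
  expect_error(read_drug_response(f), class = "unres_schema_error",
               regexp = "cell_line")
})

test_that("drug-response integrity: duplicates and non-finite values rejected", {
  df <- data.frame(cell_line = c("A", "A"), drug = c("D1", "D1"),
                   ln_ic50 = c(1, 2), max_conc = 10)
  expect_error(as_drug_response(df), class = "unres_integrity_error",
               regexp = "A/D1")
  df2 <- data.frame(cell_line = c("A", "B"), drug = "D1", ln_ic50 = c(1, Inf))
  expect_error(as_drug_response(df2), class = "unres_integrity_error")
  # no flag and no concentration: all non-extrapolated, with a warning
  df3 <- data.frame(cell_line = c("A", "B"), drug = "D1", ln_ic50 = c(1, 2))
  expect_warning(tab <- as_drug_response(df3), regexp = "extrapolat")
  expect_false(any(tab$extrapolated))
})

test_that("read_cfe_matrix joins matrix and metadata, validates both", {
  d <- withr::local_tempdir()
  mpath <- file.path(d, "m.csv"); gpath <- file.path(d, "g.csv")
  writeLines(c("cell_line,CFE1,CFE2", "A,1,0", "B,0,1", "C,1,1"), mpath)
  writeLines(c("cfe_id,alteration_class,genes,has_driver_gene",
               "CFE1,mutation,KRAS,TRUE", "CFE2,cna,,FALSE"), gpath)
  x <- read_cfe_matrix(mpath, gpath)
  expect_s3_class(x, "unres_cfe_matrix")
  expect_equal(dim(x$matrix), c(3L, 2L))
  expect_equal(x$metadata$genes[[1]], "KRAS")
  expect_length(x$metadata$genes[[2]], 0)

  writeLines(c("cell_line,CFE1,CFE2", "A,1,0", "B,0,2", "C,1,1"), mpath)
  expect_error(read_cfe_matrix(mpath, gpath), class = "unres_integrity_error",
               regexp = "CFE2")
  writeLines(c("cell_line,CFE1,CFE2", "A,1,0", "B,0,1", "C,1,1"), mpath)
  writeLines(c("cfe_id,alteration_class,genes,has_driver_gene",
               "CFE1,mutation,KRAS,TRUE"), gpath)
  expect_error(read_cfe_matrix(mpath, gpath), class = "unres_schema_error",
               regexp = "CFE2")
})

test_that("annotation reader validates one row per cell line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_line,tissue,msi_status,medium,growth_property",
               sprintf("C%d,LUNG,MSS,DMEM,Adherent", 1:5)), f)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 5)

  writeLines(c("cell_line,tissue,msi_status,medium,growth_property",
               "C1,LUNG,MSS,DMEM,Adherent", "C1,LUNG,MSS,DMEM,Adherent"), f)
  expect_error(read_annotations(f), class = "unres_integrity_error")
  writeLines(c("cell_line,tissue,msi_status,medium,growth_property",
               "C1,,MSS,DMEM,Adherent"), f)
  expect_error(read_annotations(f), class = "unres_integrity_error",
               regexp = "tissue")
})

test_that("essentiality reader normalizes orientation and missingness", {
  f <- withr::local_tempfile(fileext = ".csv")
  # cells in rows: 3 cells x 4 genes
  writeLines(c("cell,G1,G2,G3,G4",
               "A,-1,0.5,,2", "B,0,1,1,-2", "C,2,NA,0,-0.5"), f)
  m <- read_essentiality(f, orientation = "cells_in_rows")
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(rownames(m), c("G1", "G2", "G3", "G4"))
  expect_true(is.na(m["G3", "A"]))  # missing stays missing, not zero
  expect_true(is.na(m["G2", "C"]))
  expect_equal(m["G4", "B"], -2)

  writeLines(c("gene,A,B", "G1,1,2", "G1,3,4"), f)
  expect_error(read_essentiality(f), class = "unres_integrity_error",
               regexp = "G1")
  writeLines(c("gene,A,B", "G1,1,x"), f)
  expect_error(read_essentiality(f), class = "unres_parse_error", regexp = "B")
})

test_that("result tables round-trip through TSV to 12 significant digits", {
  set.seed(11)
  df <- data.frame(id = sprintf("row%02d", 1:20), n = 1:20,
                   value = rnorm(20) * 10^sample(-6:6, 20, TRUE),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(df, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_identical(back$id, df$id)
  expect_identical(back$n, df$n)
  expect_equal(back$value, df$value, tolerance = 1e-12)
  # reading the same file twice yields identical objects
  expect_identical(back, utils::read.table(f, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE))
})
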