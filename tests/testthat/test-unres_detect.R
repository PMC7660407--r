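test_that("sd_decrease matches hand computation and enforces the i bound", {
  v <- c(a = 0, b = 0, c = 0, d = 10)
  dec <- sd_decrease(v, 1)
  expect_equal(dec$sigma0, 5)       # sd of (0,0,0,10), n-1 denominator
  expect_equal(dec$sigma_i, 0)
  expect_equal(dec$delta_sigma, -5)
  expect_identical(dec$removed, "d")

  expect_equal(suppressWarnings(sd_decrease(rep(3, 6), 1)$delta_sigma), 0)
  expect_error(sd_decrease(v, 3), class = "unres_argument_error")  # > floor(4/2)
  expect_error(sd_decrease(v, 0), class = "unres_argument_error")
  expect_error(sd_decrease(v[1:3], 1), class = "unres_argument_error")
  # upper bound of 5 even for large n, and configurable ceiling for odd n
  expect_error(sd_decrease(rnorm(20), 6), class = "unres_argument_error")
  expect_no_error(sd_decrease(stats::setNames(rnorm(9), letters[1:9]), 5,
                              half = "ceiling"))
  expect_error(sd_decrease(stats::setNames(rnorm(9), letters[1:9]), 5,
                           half = "floor"), class = "unres_argument_error")
})

test_that("sd_decrease removal order and tie handling are deterministic", {
  v <- c(x = 1, y = 5, z = 5, w = 0, q = -1, r = 2)
  expect_warning(dec <- sd_decrease(v, 1), regexp = "tie")
  expect_identical(dec$removed, "y")  # lexicographic id breaks the 5/5 tie
  dec2 <- suppressWarnings(sd_decrease(v, 2))
  expect_identical(dec2$removed, c("y", "z"))
})

test_that("sd_decrease equals the brute-force oracle on random vectors", {
  set.seed(10)
  for (r in 1:1000) {
    n <- sample(4:14, 1)
    v <- stats::setNames(rnorm(n), sprintf("c%02d", sample(n)))
    i <- sample(min(floor(n / 2), 5), 1)
    dec <- suppressWarnings(sd_decrease(v, i))
    keep <- sort(v, decreasing = TRUE)[(i + 1):n]  # oracle: sort then drop top i
    expect_equal(dec$delta_sigma, sd(keep) - sd(v), tolerance = 1e-12)
  }
})

test_that("bootstrap_null is deterministic, validated, and matches its oracle", {
  expect_true(all(bootstrap_null(rep(2, 10), 5, 1, B = 200, seed = 1) == 0))
  pool0 <- rnorm(20)
  expect_identical(bootstrap_null(pool0, 8, 2, B = 500, seed = 42),
                   bootstrap_null(pool0, 8, 2, B = 500, seed = 42))
  expect_error(bootstrap_null(rnorm(5), 10, 1), class = "unres_input_error")

  # median against an independent brute-force simulation (1e5 replicates,
  # scaled down from 1e6 for runtime; compared within 3 Monte-Carlo SEs)
  set.seed(99)
  pool <- rnorm(200)
  null <- bootstrap_null(pool, 10, 1, B = 10000, seed = 7)
  oracle <- replicate(1e5, {
    x <- sample(pool, 10, replace = TRUE)
    sd(sort(x)[1:9]) - sd(x)
  })
  se_med <- 1.2533 * sd(oracle) / sqrt(1e4)  # SE of the B=1e4 median
  expect_lt(abs(attr(null, "median") - median(oracle)), 3 * se_med)
})

test_that("bootstrap_pvalue implements the add-one formula", {
  null <- c(-3, -2, 0, 1)
  expect_equal(bootstrap_pvalue(-10, null, 4), 1 / 5)
  expect_equal(bootstrap_pvalue(5, null, 4), 1)
  expect_equal(bootstrap_pvalue(-2, null, 4), 3 / 5)  # two values <= -2
  expect_error(bootstrap_pvalue(0, null, 7), class = "unres_argument_error")
  # monotone: smaller (more negative) observed value, smaller p; bound holds
  set.seed(5)
  null <- rnorm(1000)
  obs <- sort(rnorm(50))
  p <- vapply(obs, bootstrap_pvalue, numeric(1), null = null)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 1 / 1001))
})

test_that("normalized_sd_decrease matches hand values and flags degeneracy", {
  expect_equal(normalized_sd_decrease(-4, 5, -1), 0.5)   # -(-4+1)/(5+1)
  expect_equal(normalized_sd_decrease(-1, 1, 0), 1)
  expect_equal(normalized_sd_decrease(-0.7, 3, -0.7), 0) # centred on E
  expect_warning(out <- normalized_sd_decrease(-1, 0.5, 0.5))
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "undefined")))
})

test_that("bh_adjust matches hand computations and the reference oracle", {
  res <- bh_adjust(c(0.01, 0.02, 0.03))
  expect_equal(res$adjusted, c(0.03, 0.03, 0.03))
  expect_true(all(res$significant))
  expect_equal(bh_adjust(0.2)$adjusted, 0.2)
  allone <- bh_adjust(rep(1, 5))
  expect_equal(allone$adjusted, rep(1, 5))
  expect_false(any(allone$significant))
  expect_error(bh_adjust(c(0.5, 0)), class = "unres_argument_error")

  set.seed(6)
  for (r in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p)$adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("detect_unres recovers a planted resistant line", {
  # 8 carriers at -6, one reverted to baseline; pool is the whole tissue
  s <- hand_screen(n_cells = 25, carriers = 1:10, shift = -6, seed = 13)
  resp <- s$resp
  unres_cell <- "C10"
  resp$ln_ic50[resp$cell_line == unres_cell] <-
    resp$ln_ic50[resp$cell_line == unres_cell] + 6  # revert to baseline
  assoc <- list(tissue = "LUNG", drug = "DRUG1", cfe = "CFE1")
  cases <- detect_unres(assoc, resp, s$ann, s$cfe, B = 2000, seed = 17)
  expect_equal(nrow(cases), 5)          # n = 10 -> i = 1..5
  expect_equal(cases$i, 1:5)
  c1 <- cases[cases$i == 1, ]
  expect_identical(strsplit(c1$removed_cells, ";")[[1]], unres_cell)
  expect_equal(c1$delta_sigma, c1$sigma_i - c1$sigma0, tolerance = 1e-12)
  # the bootstrap pool contains the outlier itself, so the exact 1/(B+1)
  # floor is not attainable; the case is still far in the null tail
  expect_gte(c1$p_value, 1 / 2001)
  expect_lt(c1$p_value, 0.01)
  expect_true(all(cases$p_value >= 1 / 2001))

  # determinism of the full per-association detection
  cases2 <- detect_unres(assoc, resp, s$ann, s$cfe, B = 2000, seed = 17)
  expect_identical(cases, cases2)
})

test_that("detect_unres_all returns an empty, well-typed frame when nothing is retained", {
  s <- hand_screen()
  assoc <- data.frame(tissue = "LUNG", drug = "DRUG1", cfe = "CFE1",
                      retained = FALSE, stringsAsFactors = FALSE)
  out <- detect_unres_all(assoc, s$resp, s$ann, s$cfe, B = 100)
  expect_equal(nrow(out), 0)
  expect_true(all(c("p_value", "p_adjusted", "parent") %in% names(out)))
})
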