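test_that("experimental measurements convert to DDG by RT ln ratio", {
  expect_equal(experimental_ddg("Ki", 5, 5), 0)
  # 10-fold affinity loss at 300 K
  expect_equal(experimental_ddg("IC50", 1, 10, temperature = 300),
               0.0019872041 * 300 * log(10), tolerance = 1e-12)
  expect_equal(experimental_ddg("dG", -8.0, -6.5), 1.5)
  # antisymmetric under wt/mut swap
  expect_equal(experimental_ddg("Ki", 2, 7), -experimental_ddg("Ki", 7, 2))
  # log10 unit option
  expect_equal(experimental_ddg("Ki", 1, 100, units = "log10"), 2)
  expect_error(experimental_ddg("Ki", 0, 1), class = "fepddg_input_error")
  expect_error(experimental_ddg("EC50", 1, 2), class = "fepddg_input_error")
})

test_that("regression reports OLS fit and R^2 with oracle-checked values", {
  # collinear points
  expect_equal(fit_regression(1:5, 2 * (1:5) - 1)$r_squared, 1)
  # constant response explains nothing
  flat <- fit_regression(c(0, 1, 2), c(3, 3, 3))
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$slope, 0)
  # hand-computed Pearson oracle: x=(0,1,2,3), y=(0,2,1,3)
  # centered sums: Sxy = 4, Sxx = 5, Syy = 5 -> r^2 = 16/25
  r <- fit_regression(c(0, 1, 2, 3), c(0, 2, 1, 3))
  expect_equal(r$r_squared, 0.64, tolerance = 1e-12)
  expect_equal(r$n_points, 4)
  expect_equal(r$slope, 4 / 5, tolerance = 1e-12)
  expect_equal(length(r$residuals), 4)
  expect_error(fit_regression(c(1, 1, 1), c(1, 2, 3)),
               class = "fepddg_input_error")
  expect_error(fit_regression(1, 2), class = "fepddg_input_error")
})

test_that("R^2 is invariant under affine rescaling of either axis", {
  set.seed(66)
  x <- rnorm(12)
  y <- 1.4 * x + rnorm(12, sd = 0.5)
  base <- fit_regression(x, y)$r_squared
  expect_equal(fit_regression(3 * x - 2, y)$r_squared, base, tolerance = 1e-12)
  expect_equal(fit_regression(x, -0.5 * y + 7)$r_squared, base,
               tolerance = 1e-12)
})

test_that("experimental tables round-trip through the reader with ddg_exp attached", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(system = c("NA", "ALK"), mutation = c("H275Y", "L1196M"),
                   measure_type = c("Ki", "IC50"), wt_value = c(1.0, 10),
                   mut_value = c(250, 120), temperature_K = c(300, 310))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_experimental_table(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$ddg_exp,
               experimental_ddg(df$measure_type, df$wt_value, df$mut_value,
                                df$temperature_K))
  # wrong headers -> schema error naming the expectation
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(a = 1), bad, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_experimental_table(bad), class = "fepddg_schema_error")
})
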