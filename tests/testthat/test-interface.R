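test_that("observation tables round-trip through delimited text", {
  d <- simulate_gratitude(120, seed = 4)
  csv <- tempfile(fileext = ".csv")
  write.csv(d, csv, row.names = FALSE)
  back <- read_observations(csv, items = paste0("gq_", 1:5),
                            aux = "agegroup")
  expect_identical(nrow(back), nrow(d))
  expect_equal(back[paste0("gq_", 1:5)], d[paste0("gq_", 1:5)],
               ignore_attr = TRUE)
  # missing cells are dropped with a reported count
  d2 <- d
  d2$gq_2[3:6] <- NA
  write.csv(d2, csv, row.names = FALSE)
  expect_message(back2 <- read_observations(csv,
                                            items = paste0("gq_", 1:5)),
                 "4 incomplete")
  expect_identical(attr(back2, "n_dropped"), 4L)
  # structural errors
  expect_error(read_observations(csv, items = "gq_9"), "missing column")
  d3 <- d
  d3$gq_1 <- "x"
  write.csv(d3, csv, row.names = FALSE)
  expect_error(read_observations(csv, items = paste0("gq_", 1:5)),
               "not numeric")
  expect_error(read_observations("no/such/file.csv"), "not found")
})

test_that("score test JSON is schema-stable and deterministic", {
  s <- fit_small_sim()
  r <- score_test(s$fit, s$data$level, parm = "f1=~y1",
                  functional = "maxLMo", nrep = 2000, seed = 7)
  j1 <- score_test_json(r)
  j2 <- score_test_json(r)
  expect_identical(as.character(j1), as.character(j2))
  parsed <- jsonlite::fromJSON(j1)
  expect_identical(parsed$schema_version, 1L)
  expect_equal(parsed$statistic, r$statistic)
  expect_equal(parsed$p_value, r$p.value)
  expect_identical(parsed$critical_values$seed, 7L)
})

test_that("instability plots are produced for ordinal functionals only", {
  s <- fit_small_sim()
  r <- score_test(s$fit, s$data$level, parm = "f1=~y1",
                  functional = "WDMo")
  png_file <- tempfile(fileext = ".png")
  contrib <- instability_plot(r, file = png_file)
  expect_true(file.exists(png_file) && file.size(png_file) > 0)
  expect_length(contrib, r$m - 1L)
  rdm <- suppressWarnings(score_test(s$fit, s$data$level, parm = 1,
                                     functional = "DM"))
  expect_error(instability_plot(rdm), "ordinal")
})

test_that("an injected level shift shows up at and after the changepoint", {
  dgp <- cfa_dgp()
  d <- generate_dataset(dgp, n = 960, m = 8, violate = "y1~1", d = 10,
                        seed = 13)
  fit <- cfa_fit(sim_model(), d, identification = "variance")
  r <- score_test(fit, d$level, parm = "y1~1", functional = "WDMo")
  contrib <- instability_plot(r, file = tempfile(fileext = ".png"))
  expect_gte(which.max(contrib), 4L)
})

test_that("the command-line interface mirrors the library results", {
  skip_on_os("windows")
  cli <- system.file("cli", "scoremiv.R", package = "scoremiv")
  expect_true(nzchar(cli))
  d <- simulate_gratitude(240, seed = 5)
  csv <- tempfile(fileext = ".csv")
  write.csv(d, csv, row.names = FALSE)
  mod <- tempfile(fileext = ".txt")
  writeLines("f1 =~ gq_1 + gq_2 + gq_3 + gq_4 + gq_5", mod)
  out <- tempfile(fileext = ".json")
  res <- system2("Rscript", c(cli, "sctest", "--data", csv, "--model", mod,
                              "--group", "agegroup",
                              "--group-equal", "loadings",
                              "--order-by", "agegroup",
                              "--functional", "LMuo", "--parm", "1:4",
                              "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  parsed <- jsonlite::fromJSON(out)
  fit <- cfa_fit("f1 =~ gq_1 + gq_2 + gq_3 + gq_4 + gq_5", d,
                 group = "agegroup", group_equal = "loadings")
  ref <- score_test(fit, d$agegroup, parm = 1:4, functional = "LMuo")
  expect_equal(parsed$statistic, ref$statistic, tolerance = 1e-6)
  expect_equal(parsed$p_value, ref$p.value, tolerance = 1e-6)
})
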