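test_that("expression TSV reading echoes the declared design and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t1\t2\t3\t4\t5\t6",
               "B\t0.5\t0.25\t0\t-1\t-2\t-3",
               "C\t1\t1\t2\t2\t3\t3"), path)
  ds <- read_expression(path, n_times = 3, n_replicates = 2)
  expect_equal(ds$n_times, 3L)
  expect_equal(ds$n_replicates, 2L)
  expect_equal(ds$gene_names, c("A", "B", "C"))
  expect_equal(unname(ds$values["A", ]), 1:6 + 0)

  expect_error(read_expression(path, n_times = 4, n_replicates = 2),
               class = "bmanet_dimension_error")

  writeLines(c("A\t1\t2", "A\t3\t4"), path)
  expect_error(read_expression(path, 1, 2, is_time_series = FALSE),
               "Duplicate", class = "bmanet_read_error")

  writeLines(c("A\t1\tx2"), path)
  err <- expect_error(read_expression(path, 1, 2, is_time_series = FALSE),
                      class = "bmanet_read_error")
  expect_match(conditionMessage(err), "row 1")
  expect_match(conditionMessage(err), "column 2")
})

test_that("write/read round trip reproduces random datasets to full precision", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(rnorm(8 * 12) * 10^sample(-6:6, 96, TRUE), 8, 12)
    rownames(vals) <- paste0("G", 1:8)
    ds <- expression_dataset(vals, n_times = 4, n_replicates = 3)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_expression(ds, path)
    back <- read_expression(path, 4, 3)
    expect_identical(back$values, ds$values)
  }
})

test_that("network edge lists round-trip through TSV", {
  set.seed(9)
  net <- grn_network(tibble::tibble(
    regulator = paste0("G", 1:20), target = paste0("G", 21:40),
    weight = runif(20)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$regulator, net$regulator)
  expect_equal(back$weight, net$weight, tolerance = 1e-8)
})

test_that("prior files apply fallbacks, restrict to known genes, and validate bounds", {
  ds <- expression_dataset(matrix(rnorm(12), 3, 4,
                                  dimnames = list(c("A", "B", "C"), NULL)),
                           n_times = 2, n_replicates = 2)
  path <- withr::local_tempfile(fileext = ".tsv")

  file.create(path)
  pm <- read_priors(path, ds, default_prior = 0.01)
  expect_equal(bmanet:::prior_vector(pm, "B", c("A", "C")), c(0.01, 0.01))

  writeLines("A\tB\t0.9", path)
  pm <- read_priors(path, ds, default_prior = 0.01)
  expect_equal(bmanet:::prior_vector(pm, "B", c("A", "C")), c(0.9, 0.01))
  expect_equal(bmanet:::prior_vector(pm, "A", c("B", "C")), c(0.01, 0.01))

  writeLines(c("A\tB\t0.5", "Z\tB\t0.5"), path)
  expect_warning(pm <- read_priors(path, ds, 0.01), "1 prior rows")
  expect_equal(attr(pm, "n_skipped"), 1L)

  writeLines(c("A\tB\t0.5", "A\tC\t1.7"), path)
  err <- expect_error(read_priors(path, ds, 0.01), class = "bmanet_read_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("the uninformative default prior is 1/p, clamped away from 0 and 1", {
  pm <- prior_matrix()
  expect_equal(bmanet:::prior_vector(pm, "T", paste0("G", 1:16)),
               rep(1 / 16, 16))
  strong <- prior_matrix(tibble::tibble(regulator = "A", target = "T",
                                        probability = 1))
  expect_equal(bmanet:::prior_vector(strong, "T", c("A", "B"))[1], 1 - 1e-6)
})

test_that("lagged designs have R*(T-1) rows and steady-state designs R*T", {
  # yeast-scale shape: 6 time points, 97 replicates -> 485 lagged rows
  set.seed(1)
  ds <- expression_dataset(matrix(rnorm(5 * 582), 5, 582), 6, 97)
  d <- build_design(ds, 1)
  expect_equal(d$n, 97 * 5)
  expect_equal(nrow(d$X), 485)
  expect_equal(ncol(d$X), 4)  # target excluded

  # a T = 2, R = 1 series yields a single lag pair: too few rows to
  # center and scale, so it is rejected
  ds2 <- expression_dataset(matrix(rnorm(3 * 2) + 1:6, 3, 2), 2, 1)
  expect_error(build_design(ds2, 1), class = "bmanet_design_error")
})

test_that("design construction validates shapes and flags degenerate input", {
  set.seed(2)
  ds <- expression_dataset(matrix(rnorm(4 * 12), 4, 12), 1, 12,
                           is_time_series = FALSE)
  expect_error(build_design(ds, 1, time_series = TRUE),
               class = "bmanet_design_error")

  vals <- matrix(rnorm(4 * 12), 4, 12)
  vals[3, ] <- 7  # constant gene
  ds <- expression_dataset(vals, 1, 12, is_time_series = FALSE)
  d <- build_design(ds, 1, time_series = FALSE)
  expect_equal(d$dropped, 3L)
  expect_false(3L %in% d$candidate_indices)

  vals[1, ] <- 2  # constant target
  ds <- expression_dataset(vals, 1, 12, is_time_series = FALSE)
  expect_error(build_design(ds, 1, time_series = FALSE),
               class = "bmanet_degenerate_target")
})

test_that("design rows pair lag-1 predictors with responses, replicate-major", {
  # deterministic 2-gene series, T = 3, R = 2: values chosen so each lagged
  # pair is identifiable by eye
  vals <- rbind(c(1, 2, 3, 10, 20, 30),
                c(4, 5, 6, 40, 50, 60))
  rownames(vals) <- c("A", "B")
  ds <- expression_dataset(vals, n_times = 3, n_replicates = 2)
  d <- build_design(ds, "A", self_edges = TRUE)
  expect_equal(d$n, 4)
  # raw responses are A at t = 2,3 per replicate: 2,3,20,30
  expect_equal(d$y * d$y_scale + mean(c(2, 3, 20, 30)), c(2, 3, 20, 30))
})

test_that("standardized design columns have mean 0 and unit variance", {
  for (seed in 1:10) {
    d <- random_design(seed, p = sample(3:10, 1), nobs = sample(10:60, 1))
    expect_lt(max(abs(colMeans(d$X))), 1e-10)
    expect_lt(max(abs(apply(d$X, 2, stats::sd) - 1)), 1e-10)
    expect_lt(abs(mean(d$y)), 1e-10)
  }
})
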