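test_that("imputation fills exactly the missing entries and nothing else", {
  x <- toy_expression()
  expect_identical(impute_missing(x), x)           # nothing missing: identity
  x[1, 2] <- NA
  y <- impute_missing(x, "row_mean")
  expect_equal(y[1, 2], mean(x[1, -2]))
  expect_identical(y[-1, ], x[-1, ])
  z <- impute_missing(x, "zero")
  expect_equal(z[1, 2], 0)
  x2 <- matrix(c(1, NA, 3), 1, 3,
               dimnames = list("tf1", c("a", "b", "c")))
  expect_equal(unname(impute_missing(x2, "row_mean")[1, ]), c(1, 2, 3))
  x2[1, ] <- NA
  expect_error(impute_missing(x2, "row_mean"), "tf1")
})

test_that("zero-strategy imputation restores exactly a known mask", {
  sim <- generate_expression(synthetic_spec(missing_rate = 0.1, seed = 21))
  mask <- is.na(sim$expression)
  y <- impute_missing(sim$expression, "zero")
  expect_true(all(y[mask] == 0))
  expect_identical(y[!mask], sim$expression[!mask])
})

test_that("PCA matches a direct covariance eigendecomposition oracle", {
  set.seed(101)
  x <- matrix(rnorm(500), 50, 10,
              dimnames = list(sprintf("r%02d", 1:50), sprintf("c%02d", 1:10)))
  model <- fit_pca(x)
  ev <- eigen(cov(x), symmetric = TRUE)          # independent oracle
  expect_equal(model$sdev^2, ev$values, tolerance = 1e-8)
  for (j in 1:10)                                 # loadings up to sign
    expect_equal(abs(model$loadings[, j]), abs(ev$vectors[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  # scores reproduce centered data through the loadings
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_lt(max(abs(model$scores %*% t(model$loadings) - xc)), 1e-8)
})

test_that("two perfectly correlated columns put all variance on one component", {
  set.seed(3)
  v <- rnorm(30)
  x <- cbind(a = v, b = 2 * v)
  rownames(x) <- sprintf("r%02d", 1:30)
  model <- fit_pca(x)
  expect_equal(cumulative_variance(model)[1], 1)
})

test_that("cumulative variance is non-decreasing and ends at 1", {
  sim <- generate_expression(synthetic_spec(missing_rate = 0, seed = 31))
  cv <- cumulative_variance(fit_pca(sim$expression))
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 1)
  expect_true(all(cv > 0 & cv <= 1 + 1e-12))
})

test_that("scaling with a zero-variance column errors", {
  x <- toy_expression()
  x[, 2] <- 5
  expect_error(fit_pca(x, scale. = TRUE), "zero-variance")
})

test_that("attribute projections equal covariances with unit-variance scores", {
  set.seed(7)
  x <- matrix(rnorm(240), 30, 8,
              dimnames = list(sprintf("r%02d", 1:30), sprintf("c%02d", 1:8)))
  model <- fit_pca(x)
  proj <- attribute_projections(model, 5)
  std_scores <- sweep(model$scores, 2, model$sdev, `/`)
  for (j in 1:8)
    for (i in 1:5)
      expect_equal(proj[j, i],
                   cov(x[, j], std_scores[, i]) * (29 / 29),  # sample cov
                   tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(attribute_projections(model, 99), "components")
})

test_that("duplicated attributes get identical projection vectors", {
  set.seed(8)
  v <- matrix(rnorm(90), 30, 3)
  x <- cbind(v, v[, 1])
  dimnames(x) <- list(sprintf("r%02d", 1:30), c("a", "b", "c", "a_copy"))
  proj <- attribute_projections(fit_pca(x), 3)
  expect_equal(proj["a", ], proj["a_copy", ], tolerance = 1e-10)
})

test_that("selection keeps exactly one representative per correlated block", {
  # three blocks of near-duplicated informative attributes plus attributes
  # whose projections sit below the candidate threshold
  set.seed(17)
  base <- list(c(0.9, 0.1, 0, 0.05, 0), c(0, 0.8, 0.3, 0, 0.1),
               c(0.2, 0, 0, 0.7, 0.4))
  rows <- list()
  for (j in 1:3)
    for (r in 1:4)                         # 4 near-copies per block
      rows[[paste0("blk", j, "_", r)]] <- base[[j]] + rnorm(5, sd = 0.005)
  for (u in 1:10)                          # uninformative, below threshold
    rows[[paste0("noise", u)]] <- rnorm(5, sd = 0.03)
  proj <- do.call(rbind, rows)
  sel <- select_attributes(proj, tau_candidate = 0.15, tau_decorrelate = 0.9)
  expect_length(sel$selected_ids, 3)
  for (j in 1:3)
    expect_equal(sum(startsWith(sel$selected_ids, paste0("blk", j))), 1)
})

test_that("no two selected attributes come from the same duplicate block", {
  sim <- generate_expression(synthetic_spec(missing_rate = 0, seed = 17))
  model <- fit_pca(sim$expression)
  sel <- select_attributes(attribute_projections(model, 5))
  expect_gt(length(sel$selected_ids), 0)
  block_of <- sub("_[0-9]+$", "", sel$selected_ids)       # dupXX_Y -> dupXX
  block_of <- sub("^dup", "inf", block_of)                # source column
  dup_members <- block_of[grepl("^inf0[123]$", block_of)]
  expect_equal(anyDuplicated(dup_members), 0)
})

test_that("a correlation ceiling of 1 admits every mutually uncorrelated candidate", {
  proj <- diag(4) * 0.5
  rownames(proj) <- letters[1:4]
  sel <- select_attributes(proj, tau_candidate = 0.15, tau_decorrelate = 1)
  expect_setequal(sel$selected_ids, letters[1:4])
})

test_that("selected sets always satisfy the pairwise-correlation ceiling", {
  for (s in 1:5) {
    sim <- generate_expression(synthetic_spec(seed = s))
    model <- fit_pca(impute_missing(sim$expression))
    sel <- select_attributes(attribute_projections(model, 5))
    pm <- sel$projection_matrix[sel$selected_ids, , drop = FALSE]
    cm <- abs(cor(t(pm)))
    expect_lt(max(cm[upper.tri(cm)]), 0.9)
  }
})

test_that("selection is invariant to attribute order", {
  sim <- generate_expression(synthetic_spec(missing_rate = 0, seed = 23))
  model <- fit_pca(sim$expression)
  proj <- attribute_projections(model, 4)
  sel1 <- select_attributes(proj)
  set.seed(1)
  perm <- sample(nrow(proj))
  sel2 <- select_attributes(proj[perm, , drop = FALSE])
  expect_setequal(sel1$selected_ids, sel2$selected_ids)
})

test_that("an unreachable candidate threshold gives an advisory error", {
  proj <- matrix(0.01, 3, 2, dimnames = list(letters[1:3], NULL))
  expect_error(select_attributes(proj, tau_candidate = 0.15), "lower")
})
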