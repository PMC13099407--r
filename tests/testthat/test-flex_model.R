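test_that("the published coefficient set is complete and correctly placed", {
  m <- published_model()
  expect_length(m$beta, 15)
  expect_equal(m$intercept, 0)
  expect_equal(unname(m$beta["O0"]), -1.91)
  expect_equal(unname(m$beta["O2"]), 2.98)
  expect_equal(unname(m$beta["O14"]), -1.48)
})

test_that("feature transform is log1p plus per-column sample z-score", {
  gdv <- matrix(5L, 4, 15, dimnames = list(NULL, paste0("O", 0:14)))
  expect_equal(unname(transform_features(gdv)), matrix(0, 4, 15))

  gdv2 <- matrix(0, 2, 15)
  gdv2[2, ] <- exp(1) - 1
  f <- transform_features(gdv2)
  expect_equal(unname(f[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(40)
  counts <- matrix(rpois(20 * 15, 9), 20, 15)
  f2 <- transform_features(counts)
  direct <- apply(log1p(counts), 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  expect_equal(unname(f2), unname(direct), tolerance = 1e-12)
  expect_true(all(abs(colMeans(f2)) < 1e-9))
  expect_error(transform_features(counts[1, , drop = FALSE]), "two atoms")
})

test_that("target transform is log plus sample z-score on positive values", {
  expect_equal(as.numeric(transform_target(rep(2.5, 6))), rep(0, 6))
  expect_equal(as.numeric(transform_target(c(1, exp(1)))),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(41)
  v <- exp(rnorm(50))
  expect_equal(as.numeric(transform_target(v)),
               (log(v) - mean(log(v))) / sd(log(v)), tolerance = 1e-12)
  expect_true(attr(transform_target(v), "normalized"))
  expect_error(transform_target(c(1, -0.2)), "positive")
  expect_error(transform_target(c(1, 0)), "positive")
})

test_that("prediction is the linear form intercept + features . beta", {
  m <- published_model()
  z <- matrix(0, 1, 15)
  expect_equal(as.numeric(predict(m, z)), 0)
  z[1, 3] <- 1 # O2
  expect_equal(as.numeric(predict(m, z)), 2.98)
  set.seed(42)
  F1 <- matrix(rnorm(50 * 15), 50, 15)
  expect_equal(as.numeric(predict(m, F1)),
               drop(F1 %*% unname(m$beta)), tolerance = 1e-12)
  # linearity with zero intercept
  F2 <- matrix(rnorm(50 * 15), 50, 15)
  expect_equal(as.numeric(predict(m, 2 * F1 + 3 * F2)),
               2 * as.numeric(predict(m, F1)) + 3 * as.numeric(predict(m, F2)),
               tolerance = 1e-10)
  expect_error(predict(m, F1[, 1:14]), "15 columns")
})

test_that("noiseless synthetic data identifies the generating coefficients", {
  tr <- synth_flex_dataset(6, noise_sd = 0, seed = 3, n_res_range = c(50, 80))
  fit <- fit_flex_model(tr)
  expect_lt(max(abs(fit$beta - published_model()$beta)), 1e-8)
  expect_lt(abs(fit$intercept), 1e-8)
})

test_that("the OLS fit equals the closed-form normal-equations solution", {
  tr <- synth_flex_dataset(4, noise_sd = 0.3, seed = 13,
                           n_res_range = c(40, 60))
  fit <- fit_flex_model(tr)
  pool <- gdvflex:::pool_training(tr)
  D <- cbind(1, pool$X)
  ne <- solve(crossprod(D), crossprod(D, pool$y))
  expect_equal(unname(c(fit$intercept, fit$beta)), unname(drop(ne)),
               tolerance = 1e-8)
})

test_that("a rank-deficient design warns and returns the min-norm solution", {
  gdv <- matrix(rpois(30 * 15, 6), 30, 15)
  gdv[, 2] <- gdv[, 1] # exact duplicate orbit column
  y <- rnorm(30)
  entry <- training_entry("dup", gdv, rmsf_profile(y, normalized = TRUE),
                          rep(TRUE, 30))
  expect_warning(fit <- fit_flex_model(list(entry)), "rank-deficient")
  # min-norm solution still reproduces the fitted values of lm
  D <- cbind(1, transform_features(gdv))
  pred <- drop(D %*% c(fit$intercept, fit$beta))
  lmfit <- lm.fit(D, y)
  expect_equal(pred, unname(lmfit$fitted.values), tolerance = 1e-8)
})

test_that("cross-validation groups whole proteins and scores at Ca", {
  tr <- synth_flex_dataset(8, noise_sd = 0, seed = 6, n_res_range = c(40, 60))
  cv <- cross_validate(tr, k = 4, seed = 2)
  expect_equal(nrow(cv$scores), 8) # every protein scored exactly once
  expect_equal(sort(unique(cv$scores$fold)), 1:4)
  expect_true(all(cv$scores$rho > 0.999)) # noiseless self-consistency
  expect_error(cross_validate(tr, k = 9), "fewer proteins")

  # negating a held-out protein's reference flips its score sign exactly:
  # its own training pool excludes it, so the fitted model is unchanged
  flipped <- tr
  flipped[[1]] <- training_entry(
    tr[[1]]$id, tr[[1]]$gdv,
    rmsf_profile(-as.numeric(tr[[1]]$rmsf), normalized = TRUE),
    tr[[1]]$ca_mask)
  cvf <- cross_validate(flipped, k = 4, seed = 2)
  rho1 <- cvf$scores$rho[cvf$scores$id == tr[[1]]$id]
  rho1_orig <- cv$scores$rho[cv$scores$id == tr[[1]]$id]
  expect_equal(rho1, -rho1_orig)
  expect_lt(rho1, -0.999)
})

test_that("fold assignment is deterministic in the seed", {
  tr <- synth_flex_dataset(6, noise_sd = 0.2, seed = 10,
                           n_res_range = c(40, 50))
  a <- cross_validate(tr, k = 3, seed = 7)
  b <- cross_validate(tr, k = 3, seed = 7)
  expect_identical(a, b)
})

test_that("model JSON serialization round-trips with its conventions", {
  m <- flex_model(0.25, seq(-0.7, 0.7, length.out = 15))
  path <- withr::local_tempfile(fileext = ".json")
  write_flex_model(m, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$orbit_order, paste0("O", 0:14))
  expect_equal(doc$transform$log_offset_features, 1)
  expect_equal(doc$transform$sd, "sample")
  back <- read_flex_model(path)
  expect_equal(back$beta, m$beta)
  expect_equal(back$intercept, m$intercept)
})
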