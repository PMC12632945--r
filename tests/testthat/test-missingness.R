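test_that("profile extraction returns per-site fully-missing proportions in order", {
  m <- matrix_from_gt(rbind(c("./.", "0/1", "0/0", "1/1"),
                            c("0/0", "0/1", "1/1", "0/1")))
  expect_equal(extract_profile(m), c(0.25, 0))
  clean <- matrix_from_gt(rbind("0/1", "1/1"))
  expect_equal(extract_profile(clean), c(0, 0))
  set.seed(31)
  m2 <- make_template(25, 8, shape = "beta")
  expect_length(extract_profile(m2), 25)
  expect_error(extract_profile(m2[integer(0), ]), "empty")
})

test_that("dispersal replication with M = N is the identity for any seed", {
  for (s in c(1, 99, 12345)) {
    set.seed(s)
    x <- runif(37)
    set.seed(s + 1)
    expect_identical(replicate_dispersal(x, 37), x)
  }
})

test_that("downsampling draws each target from its own contiguous template block", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  for (s in 1:25) {
    set.seed(s)
    y <- replicate_dispersal(x, 2)
    expect_true(y[1] %in% c(0.1, 0.2))
    expect_true(y[2] %in% c(0.3, 0.4))
  }
})

test_that("constant profiles are preserved for every (N, M) pair", {
  for (N in 1:12) {
    for (M in 1:12) {
      set.seed(N * 100 + M)
      x <- rep(0.37, N)
      expect_equal(replicate_dispersal(x, M), rep(0.37, M))
    }
  }
})

test_that("upsampled targets match uniform-interval moments and support", {
  set.seed(32)
  y <- replicate_dispersal(c(0.0, 1.0), 1000)
  expect_true(all(y >= 0 & y < 1))
  expect_lt(abs(mean(y) - 0.5), 0.05)
  # single-site template broadcasts its value
  expect_equal(replicate_dispersal(0.3, 7), rep(0.3, 7))
  expect_error(replicate_dispersal(numeric(0), 3), "empty")
  expect_error(replicate_dispersal(c(0.1, 0.2), 0), "positive")
})

test_that("a monotone template yields block means that trend upward on average", {
  set.seed(33)
  x <- seq(0, 0.9, length.out = 20)
  y <- replicate_dispersal(x, 4000)
  block_means <- colMeans(matrix(y, ncol = 20))
  expect_true(all(diff(block_means) > -0.05))
  expect_lt(block_means[1], block_means[20])
})

test_that("beta moment matching recovers closed-form shapes and rejects infeasible moments", {
  unif <- beta_model_from_moments(0.5, sqrt(1 / 12))
  expect_equal(unif$alpha, 1, tolerance = 1e-12)
  expect_equal(unif$beta, 1, tolerance = 1e-12)
  b <- beta_model_from_moments(0.56, 0.21)
  expect_equal(b$alpha, 0.56 * (0.56 * 0.44 / 0.21^2 - 1), tolerance = 1e-12)
  expect_equal(b$beta, 0.44 * (0.56 * 0.44 / 0.21^2 - 1), tolerance = 1e-12)
  expect_equal(b$alpha, 2.5689, tolerance = 1e-4)
  expect_equal(b$beta, 2.0184, tolerance = 1e-4)
  expect_error(beta_model_from_moments(0.5, 0.5), "infeasible")
  expect_error(beta_model_from_moments(0, 0.1), "mean")
})

test_that("beta fitting from a template uses population moments and flags degeneracy", {
  m <- matrix_from_gt(rbind(c("./.", "0/1", "1/1", "0/0"),
                            c("./.", "./.", "./.", "0/0")))
  # profile [0.25, 0.75]: mean 0.5, population sd 0.25
  fit <- beta_model_from_template(m)
  expect_equal(fit$mean, 0.5)
  expect_equal(fit$sd, 0.25)
  const <- matrix_from_gt(rbind(c("./.", "0/1"), c("./.", "1/1")))
  expect_error(beta_model_from_template(const), "zero variance")
  set.seed(34)
  big <- make_template(3000, 50, shape = "beta", shape1 = 2, shape2 = 2)
  expect_lt(abs(beta_model_from_template(big)$mean - 0.5), 0.03)
})

test_that("beta plans have the model's moments and are seed-reproducible", {
  model <- beta_model_from_moments(0.5, sqrt(1 / 12))
  set.seed(35)
  y <- plan_from_beta(model, 10000)
  expect_lt(abs(mean(y) - 0.5), 0.015)
  expect_true(all(y > 0 & y < 1))
  set.seed(36)
  a <- plan_from_beta(model, 50)
  set.seed(36)
  expect_identical(plan_from_beta(model, 50), a)
})

test_that("plans are applied per site with already-missing calls preserved", {
  set.seed(37)
  m <- make_clean_segment(500, 20)
  expect_equal(apply_plan(m, rep(0, 500)), m)
  gone <- apply_plan(m, rep(1, 500))
  expect_true(all(fully_missing(gone)))
  part <- apply_plan(m, rep(0.3, 500))
  expect_lt(abs(mean(fully_missing(part)) - 0.3), 0.02)
  # applying again never resurrects a missing genotype
  again <- apply_plan(part, rep(0, 500))
  expect_equal(again, part)
  expect_error(apply_plan(m, rep(0.1, 3)), "sites")
  # exact-count realization hits round(y * n) samples per site
  exact <- apply_plan(m, rep(0.25, 500), exact_count = TRUE)
  expect_true(all(rowSums(fully_missing(exact)) == 5))
})
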