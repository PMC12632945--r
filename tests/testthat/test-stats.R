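test_that("missingness summaries count full and half calls like PLINK tables", {
  m <- matrix_from_gt(rbind(c("./.", "0/1"),
                            c("0/0", "1/1")))
  s <- summarize_missingness(m)
  expect_equal(s$per_site$proportion, c(0.5, 0))
  expect_equal(s$per_sample$proportion, c(0.5, 0))
  expect_equal(s$overall_mean, 0.25)
  half <- matrix_from_gt(rbind(c("./0", "0/1", "./.", "1/1")))
  sh <- summarize_missingness(half)
  expect_equal(sh$per_site$n_fully_missing, 1)
  expect_equal(sh$per_site$n_half_missing, 1)
  expect_equal(sh$per_site$proportion, 0.25)
  clean <- matrix_from_gt(rbind("0/1", "0/0"))
  sc <- summarize_missingness(clean)
  expect_equal(sc$overall_mean, 0)
  expect_equal(sc$overall_sd, 0)
  expect_error(summarize_missingness(clean[integer(0), ]), "empty")
})

test_that("summary double-count identity holds on random fixtures", {
  set.seed(61)
  for (r in 1:5) {
    m <- make_template(40, 11, shape = "beta", shape1 = 1, shape2 = 3)
    s <- summarize_missingness(m)
    expect_equal(sum(s$per_site$n_fully_missing),
                 sum(s$per_sample$n_missing_sites))
    expect_equal(s$overall_mean, mean(s$per_site$proportion))
  }
})

test_that("summary TSV tables mirror the in-memory summary", {
  set.seed(62)
  m <- make_template(15, 6, shape = "constant", value = 0.4)
  s <- summarize_missingness(m)
  prefix <- tempfile()
  paths <- write_missingness_summary(s, prefix)
  lmiss <- read.delim(paths[1])
  imiss <- read.delim(paths[2])
  expect_equal(names(lmiss), c("CHROM", "POS", "N_MISS", "N_HALF", "F_MISS"))
  expect_equal(lmiss$F_MISS, s$per_site$proportion)
  expect_equal(imiss$N_MISS, s$per_sample$n_missing_sites)
})

test_that("histogram binning is left-closed with the last bin closed on both ends", {
  h <- missingness_histogram(c(0, 0.5, 1), bins = 2)
  expect_equal(h$mass, c(1 / 3, 2 / 3))
  h0 <- missingness_histogram(rep(0, 10))
  expect_equal(h0$mass, c(1, rep(0, 49)))
  expect_equal(length(h0$breaks), 51)
  set.seed(63)
  hr <- missingness_histogram(runif(997), bins = 13)
  expect_equal(sum(hr$mass), 1)
  expect_error(missingness_histogram(numeric(0)), "empty")
  expect_error(missingness_histogram(c(0.2), bins = 0), "positive")
})

test_that("KL divergence matches the closed form and Gibbs' inequality", {
  p <- missingness_histogram(c(0.1, 0.6), bins = 2)   # mass (1/2, 1/2)
  q <- missingness_histogram(c(0.1, 0.6, 0.7, 0.8), bins = 2)  # (1/4, 3/4)
  expect_equal(kl_divergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-12)
  expect_equal(kl_divergence(p, p), 0)
  set.seed(64)
  for (r in 1:20) {
    a <- missingness_histogram(runif(60), bins = 8)
    b <- missingness_histogram(runif(60), bins = 8)
    expect_gte(kl_divergence(a, b), 0)
    expect_equal(kl_divergence(a, a), 0)
  }
  expect_error(kl_divergence(p, missingness_histogram(runif(5), bins = 3)),
               "bin")
})

test_that("empty bins are handled by pseudocount regularization", {
  p <- missingness_histogram(c(0.1, 0.1, 0.9), bins = 4)
  q <- missingness_histogram(c(0.3, 0.3, 0.3), bins = 4)
  d <- kl_divergence(p, q)
  expect_true(is.finite(d) && d > 0)
  expect_equal(kl_divergence(p, p), 0)
})

test_that("dispersal replication tracks a structured template more closely than the beta model", {
  set.seed(65)
  template <- make_template(1000, 60, shape = "ramp", from = 0, to = 0.9)
  profile <- extract_profile(template)
  h_template <- missingness_histogram(profile)
  clean <- make_clean_segment(1000, 60)
  eggs <- extract_profile(apply_plan(clean, replicate_dispersal(profile, 1000)))
  beta <- extract_profile(apply_plan(clean,
                                     plan_from_beta(beta_model_from_template(template), 1000)))
  expect_lt(kl_divergence(h_template, missingness_histogram(eggs)),
            kl_divergence(h_template, missingness_histogram(beta)))
})
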