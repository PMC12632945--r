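#' Extract the per-site missingness profile of a template
#'
#' For each site, the proportion of samples whose genotype is fully
#' missing (both allele calls absent). The vector keeps the template's
#' site order: the positional arrangement ("dispersal") of missingness
#' along the segment is exactly what [replicate_dispersal()] preserves.
#'
#' @param m a nonempty `genotype_matrix`.
#' @return numeric vector `x_1..x_N` of fractions in `[0, 1]`, one per
#'   site, in site order.
#' @export
extract_profile <- function(m) {
  if (n_sites(m) == 0) stop("cannot extract a missingness profile from an empty matrix")
  if (n_samples(m) == 0) stop("genotype matrix has zero samples")
  rowMeans(fully_missing(m))
}

# Contiguous block partition of 1..n into m non-empty blocks:
# block j covers indices (j-1)*n %/% m + 1 .. j*n %/% m.
# Reduces to runs of n/m consecutive indices when m divides n.
#' @keywords internal
dispersal_blocks <- function(n, m) {
  j <- seq_len(m)
  cbind(lo = ((j - 1L) * n) %/% m + 1L, hi = (j * n) %/% m)
}

#' Replicate the dispersal of a missingness profile onto M target sites
#'
#' The core resampling step: given template proportions `x_1..x_N`,
#' produce target proportions `y_1..y_M` that reproduce both the
#' aggregate distribution and the positional trend of the template.
#'
#' When `M <= N`, the template indices `1..N` are partitioned into `M`
#' contiguous non-empty blocks (block `j` covers
#' `floor((j-1)N/M)+1 .. floor(jN/M)`) and `y_j` is drawn uniformly
#' from the template values in block `j`. When `M > N`, the target
#' indices `1..M` are partitioned into `N` contiguous blocks by the
#' mirror rule; each `y` in target block `j < N` is an independent draw
#' from `U(min(x_j, x_{j+1}), max(x_j, x_{j+1}))`, and the last block
#' draws from the interval spanned by `x_{N-1}` and `x_N` — i.e. the
#' trend at the end of the template is assumed to extend. With `N = 1`
#' every `y_j = x_1`. `M = N` returns the profile verbatim.
#'
#' Uses the session RNG; call `set.seed()` first for reproducibility.
#'
#' @param profile numeric vector of template proportions in `[0, 1]`
#'   (see [extract_profile()]).
#' @param M number of target sites (>= 1).
#' @return numeric vector of length `M` of target proportions.
#' @export
replicate_dispersal <- function(profile, M) {
  N <- length(profile)
  if (N < 1) stop("empty missingness profile")
  if (any(profile < 0 | profile > 1)) stop("profile values must lie in [0, 1]")
  M <- as.integer(M)
  if (is.na(M) || M < 1) stop("M must be a positive integer")
  if (M <= N) {
    b <- dispersal_blocks(N, M)
    picked <- b[, "lo"] +
      vapply(b[, "hi"] - b[, "lo"] + 1L, function(k) sample.int(k, 1L),
             integer(1)) - 1L
    return(profile[picked])
  }
  if (N == 1) return(rep(profile, M))
  b <- dispersal_blocks(M, N)
  y <- numeric(M)
  for (j in seq_len(N)) {
    pj <- min(j, N - 1L)  # last block extends the final template interval
    a <- min(profile[pj], profile[pj + 1L])
    z <- max(profile[pj], profile[pj + 1L])
    k <- b[j, "hi"] - b[j, "lo"] + 1L
    y[b[j, "lo"]:b[j, "hi"]] <- if (a == z) rep(a, k) else stats::runif(k, a, z)
  }
  y
}

#' Moment-matched beta model for random missingness
#'
#' Parameterizes a beta distribution from the mean and standard
#' deviation of per-site missingness proportions, the random
#' alternative to dispersal replication: shape parameters are obtained
#' by the method of moments,
#' `alpha = mean * (mean(1-mean)/sd^2 - 1)`,
#' `beta = (1-mean) * (mean(1-mean)/sd^2 - 1)`.
#'
#' @param mean mean missingness proportion, in (0, 1).
#' @param sd standard deviation of the proportions; must satisfy
#'   `sd^2 < mean * (1 - mean)` for a beta distribution to exist.
#' @return an object of class `beta_missingness_model`: list with
#'   `mean`, `sd`, `alpha`, `beta`.
#' @export
beta_model_from_moments <- function(mean, sd) {
  if (!(mean > 0 && mean < 1)) stop("mean must lie strictly between 0 and 1")
  if (!(sd > 0)) stop("sd must be positive")
  if (!(sd^2 < mean * (1 - mean))) {
    stop(sprintf("infeasible moments: need sd^2 < mean*(1-mean), but %.6g >= %.6g",
                 sd^2, mean * (1 - mean)))
  }
  k <- mean * (1 - mean) / sd^2 - 1
  structure(list(mean = mean, sd = sd, alpha = mean * k,
                 beta = (1 - mean) * k),
            class = "beta_missingness_model")
}

#' @export
print.beta_missingness_model <- function(x, ...) {
  cat(sprintf("beta missingness model: mean %.4g, sd %.4g -> Beta(alpha = %.4g, beta = %.4g)\n",
              x$mean, x$sd, x$alpha, x$beta))
  invisible(x)
}

#' Fit the beta model to a template's missingness profile
#'
#' Computes the mean and (population) standard deviation of the
#' template's per-site missingness proportions and hands them to
#' [beta_model_from_moments()].
#'
#' @param m a `genotype_matrix` with at least two sites.
#' @return a `beta_missingness_model`.
#' @export
beta_model_from_template <- function(m) {
  profile <- extract_profile(m)
  if (length(profile) < 2) stop("need at least two sites to fit a beta model")
  mu <- mean(profile)
  sd_pop <- sqrt(mean((profile - mu)^2))
  if (sd_pop == 0) stop("template profile has zero variance; beta model is degenerate")
  beta_model_from_moments(mu, sd_pop)
}

#' Draw a per-site missingness plan from a beta model
#'
#' @param model a `beta_missingness_model`.
#' @param M number of target sites.
#' @return numeric vector of `M` independent `Beta(alpha, beta)` draws.
#' @export
plan_from_beta <- function(model, M) {
  stopifnot(inherits(model, "beta_missingness_model"))
  M <- as.integer(M)
  if (is.na(M) || M < 1) stop("M must be a positive integer")
  stats::rbeta(M, model$alpha, model$beta)
}

#' Introduce missing genotypes according to a per-site plan
#'
#' At site `j`, samples become fully missing with target proportion
#' `plan[j]`. By default each sample is knocked out independently with
#' probability `plan[j]` (Bernoulli realization); with
#' `exact_count = TRUE`, exactly `round(plan[j] * n_samples)` randomly
#' chosen samples are knocked out instead, so the realized per-site
#' proportion is deterministic up to 1/n quantization. Genotypes that
#' are already missing stay missing; all site metadata is untouched.
#'
#' @param m a `genotype_matrix`.
#' @param plan numeric vector of target proportions, one per site of
#'   `m` (see [replicate_dispersal()], [plan_from_beta()]).
#' @param exact_count logical; see above.
#' @return a `genotype_matrix` with the plan applied.
#' @export
apply_plan <- function(m, plan, exact_count = FALSE) {
  validate_genotype_matrix(m)
  if (length(plan) != n_sites(m)) {
    stop(sprintf("plan has %d entries but the matrix has %d sites",
                 length(plan), n_sites(m)))
  }
  if (any(plan < 0 | plan > 1)) stop("plan values must lie in [0, 1]")
  ns <- n_sites(m)
  np <- n_samples(m)
  if (exact_count) {
    hit <- matrix(FALSE, ns, np)
    k <- as.integer(round(plan * np))
    for (j in which(k > 0)) hit[j, sample.int(np, k[j])] <- TRUE
  } else {
    hit <- matrix(stats::runif(ns * np), ns, np) < plan
  }
  m$left[hit] <- NA_integer_
  m$right[hit] <- NA_integer_
  m$phased[hit] <- FALSE
  m
}
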