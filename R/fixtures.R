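#' Target missingness profile for a synthetic template
#'
#' Evaluates one of the built-in spatial missingness shapes over
#' `n_sites` positions. Shapes emulate the kinds of positional
#' structure seen in empirical (especially ancient-DNA) callsets:
#' * `constant`: flat missingness `value` everywhere.
#' * `ramp`: linear trend `from` -> `to` along the segment.
#' * `sinusoid`: `center + amplitude * sin(2*pi*cycles*t)`, `t` in
#'   `[0, 1]` — periodic pockets of low callability.
#' * `blocks`: piecewise-constant `values` switching at site-index
#'   `breakpoints` — mappability-block-like structure.
#' * `beta`: i.i.d. `Beta(shape1, shape2)` draws — no spatial
#'   structure, the null case.
#'
#' @param n_sites number of sites.
#' @param shape one of `"constant"`, `"ramp"`, `"sinusoid"`,
#'   `"blocks"`, `"beta"`.
#' @param value constant level (shape `"constant"`).
#' @param from,to ramp endpoints (shape `"ramp"`).
#' @param center,amplitude,cycles sinusoid parameters; must keep the
#'   profile inside `[0, 1]`.
#' @param breakpoints,values for `"blocks"`: `values[k]` applies to
#'   sites in `(breakpoints[k-1], breakpoints[k]]` with an implicit
#'   final breakpoint at `n_sites`.
#' @param shape1,shape2 beta shapes (shape `"beta"`; uses the session
#'   RNG).
#' @return numeric vector of length `n_sites` with values in `[0, 1]`.
#' @export
profile_shape <- function(n_sites,
                          shape = c("constant", "ramp", "sinusoid",
                                    "blocks", "beta"),
                          value = 0.5, from = 0, to = 0.9,
                          center = 0.45, amplitude = 0.35, cycles = 2,
                          breakpoints = NULL, values = NULL,
                          shape1 = 2, shape2 = 2) {
  shape <- match.arg(shape)
  x <- switch(shape,
    constant = rep(value, n_sites),
    ramp = seq(from, to, length.out = n_sites),
    sinusoid = {
      t <- if (n_sites == 1) 0 else (seq_len(n_sites) - 1) / (n_sites - 1)
      center + amplitude * sin(2 * pi * cycles * t)
    },
    blocks = {
      if (is.null(values)) stop("shape 'blocks' needs 'values'")
      edges <- c(0, breakpoints, n_sites)
      if (length(values) != length(edges) - 1) {
        stop("'values' must have one entry per block")
      }
      rep(values, times = diff(edges))
    },
    beta = stats::rbeta(n_sites, shape1, shape2))
  if (any(x < 0 | x > 1)) stop("profile shape leaves [0, 1]; adjust parameters")
  x
}

#' Generate a synthetic template with controlled missingness structure
#'
#' Stands in for an empirical (e.g. ancient-DNA) template VCF: a
#' biallelic, unphased, unpolarized matrix whose per-site missingness
#' follows a prescribed spatial shape. Missingness is realized by
#' exact counts — `round(x_i * n_samples)` randomly chosen samples per
#' site — so [extract_profile()] recovers the requested profile
#' deterministically up to `1/n_samples` quantization, making the
#' template a usable oracle in tests. Non-missing genotypes draw each
#' allele independently with a per-site ALT frequency uniform on
#' (0.05, 0.95).
#'
#' Uses the session RNG; call `set.seed()` first for reproducibility.
#'
#' @param n_sites,n_samples dimensions (>= 1).
#' @param shape,... passed to [profile_shape()].
#' @param chrom chromosome label.
#' @param segment_length positions are drawn without replacement from
#'   `1..segment_length` (default `100 * n_sites`).
#' @return a `genotype_matrix`.
#' @export
make_template <- function(n_sites, n_samples, shape = "ramp", ...,
                          chrom = "1", segment_length = NULL) {
  stopifnot(n_sites >= 1, n_samples >= 1)
  if (is.null(segment_length)) segment_length <- 100 * n_sites
  x <- profile_shape(n_sites, shape, ...)
  pos <- sort(sample.int(segment_length, n_sites))
  nucs <- c("A", "C", "G", "T")
  ref <- sample(nucs, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
  freq <- stats::runif(n_sites, 0.05, 0.95)
  left <- matrix(as.integer(stats::runif(n_sites * n_samples) <
                              freq), n_sites, n_samples)
  right <- matrix(as.integer(stats::runif(n_sites * n_samples) <
                               freq), n_sites, n_samples)
  k <- as.integer(round(x * n_samples))
  for (j in which(k > 0)) {
    hit <- sample.int(n_samples, k[j])
    left[j, hit] <- NA_integer_
    right[j, hit] <- NA_integer_
  }
  genotype_matrix(chrom = rep(chrom, n_sites), pos = pos, ref = ref,
                  alt = as.list(alt), left = left, right = right,
                  phased = matrix(FALSE, n_sites, n_samples),
                  samples = sprintf("template_%d", seq_len(n_samples)),
                  polarized = FALSE)
}

#' Generate a clean, idealized simulated segment
#'
#' A desk-scale stand-in for coalescent simulator output: fully
#' phased, polarized, missing-free, biallelic. Per site, the number of
#' derived-allele copies `i` among the `2 * n_samples` haplotypes is
#' drawn from the neutral site-frequency spectrum (probability
#' proportional to `1/i`, `i = 1 .. 2*n_samples - 1`) and assigned to
#' a uniformly random subset of haplotypes. The output satisfies
#' [write_ms()]'s preconditions.
#'
#' Uses the session RNG; call `set.seed()` first for reproducibility.
#'
#' @param n_sites,n_samples dimensions (>= 1).
#' @param chrom chromosome label.
#' @param segment_length bp span positions are drawn from (default
#'   `100 * n_sites`).
#' @return a phased, polarized `genotype_matrix`.
#' @export
make_clean_segment <- function(n_sites, n_samples, chrom = "1",
                               segment_length = NULL) {
  stopifnot(n_sites >= 1, n_samples >= 1)
  if (is.null(segment_length)) segment_length <- 100 * n_sites
  pos <- sort(sample.int(segment_length, n_sites))
  n_hap <- 2L * n_samples
  sfs_support <- seq_len(max(n_hap - 1L, 1L))
  dac <- sample(sfs_support, n_sites, replace = TRUE,
                prob = 1 / sfs_support)
  hap <- matrix(0L, n_sites, n_hap)
  for (j in seq_len(n_sites)) {
    hap[j, sample.int(n_hap, dac[j])] <- 1L
  }
  nucs <- c("A", "C", "G", "T")
  ref <- sample(nucs, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
  genotype_matrix(chrom = rep(chrom, n_sites), pos = pos, ref = ref,
                  alt = as.list(alt),
                  left = hap[, 2 * seq_len(n_samples) - 1, drop = FALSE],
                  right = hap[, 2 * seq_len(n_samples), drop = FALSE],
                  phased = matrix(TRUE, n_sites, n_samples),
                  samples = sprintf("sim_%d", seq_len(n_samples)),
                  polarized = TRUE)
}
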