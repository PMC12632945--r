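#' PLINK-style missingness summary
#'
#' Per-site and per-sample tallies of missing genotypes, analogous to
#' PLINK's `.lmiss` / `.imiss` reports, plus the overall mean and
#' (population) standard deviation of per-site missingness proportions
#' — the two moments that parameterize [beta_model_from_moments()].
#' Fully-missing ("./.") and half-missing (one absent call) genotypes
#' are counted separately; only fully-missing ones enter the
#' proportions.
#'
#' @param m a nonempty `genotype_matrix`.
#' @return an object of class `missingness_summary`: list with
#'   `per_site` (data.frame `chrom`, `pos`, `n_fully_missing`,
#'   `n_half_missing`, `proportion`), `per_sample` (data.frame
#'   `sample`, `n_missing_sites`, `proportion`), `overall_mean`,
#'   `overall_sd`.
#' @export
summarize_missingness <- function(m) {
  if (n_sites(m) == 0 || n_samples(m) == 0) {
    stop("cannot summarize an empty genotype matrix")
  }
  fm <- fully_missing(m)
  hm <- half_missing(m)
  prop <- rowMeans(fm)
  per_site <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                         n_fully_missing = rowSums(fm),
                         n_half_missing = rowSums(hm),
                         proportion = prop, stringsAsFactors = FALSE)
  per_sample <- data.frame(sample = m$samples,
                           n_missing_sites = colSums(fm),
                           proportion = colMeans(fm),
                           stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL
  structure(list(per_site = per_site, per_sample = per_sample,
                 overall_mean = mean(prop),
                 overall_sd = sqrt(mean((prop - mean(prop))^2))),
            class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat(sprintf("missingness summary: %d site(s), %d sample(s)\n",
              nrow(x$per_site), nrow(x$per_sample)))
  cat(sprintf("  per-site missingness: mean %.4f, sd %.4f\n",
              x$overall_mean, x$overall_sd))
  invisible(x)
}

#' Write a missingness summary as TSV tables
#'
#' Writes `<prefix>.lmiss.tsv` (columns CHROM, POS, N_MISS, N_HALF,
#' F_MISS) and `<prefix>.imiss.tsv` (columns SAMPLE, N_MISS, F_MISS),
#' deliberately close to PLINK's `.lmiss` / `.imiss` column meanings.
#'
#' @param s a `missingness_summary`.
#' @param prefix output path prefix.
#' @return character vector of the two paths written, invisibly.
#' @export
write_missingness_summary <- function(s, prefix) {
  stopifnot(inherits(s, "missingness_summary"))
  site_path <- paste0(prefix, ".lmiss.tsv")
  sample_path <- paste0(prefix, ".imiss.tsv")
  site_tab <- data.frame(CHROM = s$per_site$chrom, POS = s$per_site$pos,
                         N_MISS = s$per_site$n_fully_missing,
                         N_HALF = s$per_site$n_half_missing,
                         F_MISS = s$per_site$proportion)
  sample_tab <- data.frame(SAMPLE = s$per_sample$sample,
                           N_MISS = s$per_sample$n_missing_sites,
                           F_MISS = s$per_sample$proportion)
  utils::write.table(site_tab, site_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sample_tab, sample_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(site_path, sample_path))
}

#' Histogram of a missingness profile
#'
#' Bins per-site missingness proportions into `bins` equal-width bins
#' on `[0, 1]` (left-closed; the last bin is closed on both ends, so a
#' proportion of exactly 1 lands in the final bin). The 50-bin default
#' is the resolution used to compare a degraded dataset's missingness
#' distribution with its template's.
#'
#' @param profile numeric vector of proportions in `[0, 1]`
#'   (see [extract_profile()]).
#' @param bins number of bins (default 50).
#' @return an object of class `missingness_histogram`: list with
#'   `breaks` (length `bins + 1`), `counts`, `mass`
#'   (normalized to sum 1), `n`, `bins`.
#' @export
missingness_histogram <- function(profile, bins = 50) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1) stop("bins must be a positive integer")
  if (length(profile) == 0) stop("empty missingness profile")
  if (any(profile < 0 | profile > 1)) stop("profile values must lie in [0, 1]")
  idx <- pmin(floor(profile * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  structure(list(breaks = seq(0, 1, length.out = bins + 1L),
                 counts = counts, mass = counts / length(profile),
                 n = length(profile), bins = bins),
            class = "missingness_histogram")
}

#' @export
print.missingness_histogram <- function(x, ...) {
  cat(sprintf("missingness histogram: %d bin(s) over [0, 1], %d site(s)\n",
              x$bins, x$n))
  invisible(x)
}

#' @export
plot.missingness_histogram <- function(x, ...) {
  graphics::barplot(x$mass, names.arg = NULL, space = 0, border = NA,
                    xlab = "per-site missingness proportion",
                    ylab = "fraction of sites", ...)
  graphics::axis(1, at = c(0, x$bins / 2, x$bins), labels = c(0, 0.5, 1))
  invisible(x)
}

#' Kullback-Leibler divergence between two missingness histograms
#'
#' `KL(p || q) = sum_i p_i * ln(p_i / q_i)` over bins, natural log. KL
#' is undefined whenever a bin with `q_i = 0` has `p_i > 0`; when
#' either histogram has an empty bin, both are regularized by adding a
#' pseudocount of half an observation to every bin before normalizing
#' (identical histograms therefore still give 0). Histograms without
#' empty bins are compared exactly.
#'
#' @param p,q `missingness_histogram` objects with identical binning;
#'   `p` is conventionally the template, `q` the replicate.
#' @return non-negative divergence in nats; 0 iff the (regularized)
#'   distributions coincide.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "missingness_histogram"),
            inherits(q, "missingness_histogram"))
  if (p$bins != q$bins || !isTRUE(all.equal(p$breaks, q$breaks))) {
    stop("histograms must share bin count and edges")
  }
  pm <- p$mass
  qm <- q$mass
  if (any(p$counts == 0) || any(q$counts == 0)) {
    pm <- (p$counts + 0.5) / (p$n + 0.5 * p$bins)
    qm <- (q$counts + 0.5) / (q$n + 0.5 * q$bins)
  }
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / qm[nz]))
}
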