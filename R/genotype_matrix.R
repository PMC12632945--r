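#' Construct a diploid genotype matrix
#'
#' The central in-memory container shared by all readers, degradation
#' operators and summaries. Sites are rows, samples are columns; each
#' diploid genotype is stored as a left and a right allele index
#' (0 = reference/ancestral, 1.. = alternative/derived, `NA` = missing
#' call) plus a per-genotype phase flag. All samples are assumed diploid.
#'
#' Sites are sorted by (chrom, pos) on construction. A genotype is
#' "fully missing" only when both of its allele slots are `NA`; a
#' genotype with exactly one `NA` slot is "half missing" and is treated
#' as observed by the missingness machinery (but reported separately by
#' [summarize_missingness()]).
#'
#' @param chrom character vector of chromosome labels, one per site.
#' @param pos integer vector of 1-based positions, one per site.
#' @param ref character vector of reference alleles.
#' @param alt list of character vectors of alternative alleles (may be
#'   empty for monomorphic records; more than one entry marks a
#'   multiallelic site).
#' @param left,right integer matrices (sites x samples) of allele
#'   indices, `NA` for a missing call.
#' @param phased logical matrix (sites x samples); `TRUE` renders the
#'   genotype with `|`, `FALSE` with `/`. Fully-missing genotypes are
#'   normalized to unphased.
#' @param samples character vector of sample names.
#' @param id optional character vector of site identifiers (default ".").
#' @param polarized logical; `TRUE` when allele index 0 is known to be
#'   the ancestral allele (simulator output); dropped by [depolarize()].
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `sites` (data.frame `chrom`, `pos`, `id`, `ref`), `alt`,
#'   `left`, `right`, `phased`, `polarized`.
#' @seealso [read_vcf()], [ms_to_matrix()], [make_clean_segment()]
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, left, right, phased,
                            samples, id = NULL, polarized = FALSE) {
  left <- as.matrix(left)
  right <- as.matrix(right)
  phased <- as.matrix(phased)
  storage.mode(left) <- "integer"
  storage.mode(right) <- "integer"
  storage.mode(phased) <- "logical"
  n_sites <- length(chrom)
  if (is.null(id)) id <- rep(".", n_sites)
  if (!is.list(alt)) alt <- as.list(alt)
  alt <- unname(lapply(alt, function(a) unname(as.character(a))))
  sites <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                      id = as.character(id), ref = as.character(ref),
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
    alt <- alt[ord]
    left <- left[ord, , drop = FALSE]
    right <- right[ord, , drop = FALSE]
    phased <- phased[ord, , drop = FALSE]
  }
  # "./." carries no phase information
  fm <- is.na(left) & is.na(right)
  phased[fm] <- FALSE
  m <- structure(list(samples = as.character(samples), sites = sites,
                      alt = alt, left = left, right = right,
                      phased = phased, polarized = isTRUE(polarized)),
                 class = "genotype_matrix")
  validate_genotype_matrix(m)
  m
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants: matching dimensions, allele indices
#' within each site's allele count, and diploid storage.
#'
#' @param m a `genotype_matrix`.
#' @return `m`, invisibly; stops on violation.
#' @export
validate_genotype_matrix <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  ns <- nrow(m$sites)
  np <- length(m$samples)
  for (comp in c("left", "right", "phased")) {
    d <- dim(m[[comp]])
    if (d[1] != ns || d[2] != np) {
      stop(sprintf("'%s' must be a %d x %d matrix, got %d x %d",
                   comp, ns, np, d[1], d[2]))
    }
  }
  if (length(m$alt) != ns) stop("'alt' must have one entry per site")
  if (ns > 0 && np > 0) {
    n_alleles <- 1L + lengths(m$alt)
    mx <- pmax(suppressWarnings(apply(m$left, 1, max, na.rm = TRUE)),
               suppressWarnings(apply(m$right, 1, max, na.rm = TRUE)))
    mx[!is.finite(mx)] <- 0
    bad <- which(mx >= n_alleles)
    if (length(bad) > 0) {
      stop(sprintf("allele index out of range at site %d (%s:%d): index %d with %d allele(s)",
                   bad[1], m$sites$chrom[bad[1]], m$sites$pos[bad[1]],
                   mx[bad[1]], n_alleles[bad[1]]))
    }
    if (any(m$left < 0, na.rm = TRUE) || any(m$right < 0, na.rm = TRUE)) {
      stop("negative allele index")
    }
  }
  invisible(m)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d site(s) x %d diploid sample(s)\n",
              n_sites(x), n_samples(x)))
  cat(sprintf("  polarized: %s; phased genotypes: %d; fully missing: %d; half missing: %d\n",
              x$polarized, sum(x$phased), sum(fully_missing(x)),
              sum(half_missing(x))))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param m a `genotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(m) nrow(m$sites)

#' @rdname n_sites
#' @export
n_samples <- function(m) length(m$samples)

#' Fully-missing and half-missing genotype masks
#'
#' `fully_missing()` marks genotypes with both allele calls absent
#' ("./."); these are the unit the missingness model counts.
#' `half_missing()` marks genotypes with exactly one absent call
#' (e.g. "./0"); they do not count towards per-site missingness
#' proportions but are tallied by [summarize_missingness()].
#'
#' @param m a `genotype_matrix`.
#' @return logical sites x samples matrix.
#' @export
fully_missing <- function(m) is.na(m$left) & is.na(m$right)

#' @rdname fully_missing
#' @export
half_missing <- function(m) xor(is.na(m$left), is.na(m$right))

#' Proportion of fully-missing samples at one site
#'
#' @param m a `genotype_matrix` with at least one sample.
#' @param i site index (1-based).
#' @return fraction in `[0, 1]`: the share of samples whose genotype at
#'   site `i` has both alleles missing. Half-missing genotypes do not
#'   count.
#' @export
site_missing_proportion <- function(m, i) {
  if (n_samples(m) == 0) stop("genotype matrix has zero samples")
  if (i < 1 || i > n_sites(m)) stop("site index out of range")
  mean(is.na(m$left[i, ]) & is.na(m$right[i, ]))
}

#' Which sites are biallelic?
#'
#' Degradation operators restricted to biallelic sites ([depolarize()],
#' [deaminate()], [pseudohaploidize()]) use this gate; monomorphic
#' (no ALT) and multiallelic records are skipped.
#'
#' @param m a `genotype_matrix`.
#' @return logical vector, one entry per site.
#' @export
is_biallelic <- function(m) lengths(m$alt) == 1L

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i site indices.
#' @param j sample indices.
#' @param ... ignored.
#' @return a `genotype_matrix` restricted to the selected sites/samples.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_sites(x))
  if (missing(j)) j <- seq_len(n_samples(x))
  genotype_matrix(chrom = x$sites$chrom[i], pos = x$sites$pos[i],
                  ref = x$sites$ref[i], alt = x$alt[i],
                  left = x$left[i, j, drop = FALSE],
                  right = x$right[i, j, drop = FALSE],
                  phased = x$phased[i, j, drop = FALSE],
                  samples = x$samples[j], id = x$sites$id[i],
                  polarized = x$polarized)
}
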