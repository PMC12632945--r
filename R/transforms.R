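#' Remove phase from all genotypes
#'
#' Each genotype's left and right alleles are exchanged with
#' probability 1/2 (so any residual left/right ordering carries no
#' information) and every phase flag is cleared: the output VCF renders
#' all genotypes with `/`. Allele values are never changed, only their
#' order.
#'
#' Uses the session RNG; call `set.seed()` first for reproducibility.
#'
#' @param m a `genotype_matrix`.
#' @return the unphased `genotype_matrix`.
#' @export
unphase <- function(m) {
  validate_genotype_matrix(m)
  swap <- matrix(stats::runif(n_sites(m) * n_samples(m)) < 0.5,
                 n_sites(m), n_samples(m))
  tmp <- m$left[swap]
  m$left[swap] <- m$right[swap]
  m$right[swap] <- tmp
  m$phased[] <- FALSE
  m
}

#' Remove ancestral/derived polarization
#'
#' At each biallelic site, with probability 1/2 the REF and ALT strings
#' are exchanged and every genotype's allele indices are flipped
#' (0 <-> 1, missing preserved), so the site is a pure relabeling: the
#' nucleotides each sample carries are unchanged. The ancestral-allele
#' annotation is dropped either way, since after this step index 0 no
#' longer means "ancestral". Monomorphic and multiallelic sites are
#' passed through untouched (a message reports the skip count).
#'
#' @param m a `genotype_matrix`.
#' @return the depolarized `genotype_matrix`.
#' @export
depolarize <- function(m) {
  validate_genotype_matrix(m)
  bi <- is_biallelic(m)
  if (any(!bi)) {
    message(sprintf("depolarize: skipped %d non-biallelic site(s)", sum(!bi)))
  }
  flip <- bi & stats::runif(n_sites(m)) < 0.5
  if (any(flip)) {
    new_ref <- vapply(m$alt[flip], `[`, character(1), 1L)
    m$alt[flip] <- as.list(m$sites$ref[flip])
    m$sites$ref[flip] <- new_ref
    m$left[flip, ] <- 1L - m$left[flip, , drop = FALSE]
    m$right[flip, ] <- 1L - m$right[flip, , drop = FALSE]
  }
  m$polarized <- FALSE
  m
}

#' Introduce post-mortem deamination damage
#'
#' A two-parameter per-site, per-allele model of ancient-DNA damage:
#' each biallelic site is independently designated a transition site
#' with probability `p_transition`; at transition sites every
#' reference-allele copy (index 0) independently converts to the
#' alternative allele (index 1) with probability `p_deaminate`. A
#' heterozygote can therefore lose one or both reference copies.
#' Non-reference and missing alleles are never touched, so the per-site
#' ALT allele count can only increase. Non-biallelic sites are skipped
#' (message reports the count). The expected fraction of reference
#' copies converted overall is `p_transition * p_deaminate`.
#'
#' @param m a `genotype_matrix`.
#' @param p_transition probability in `[0, 1]` that a site is a
#'   transition site.
#' @param p_deaminate probability in `[0, 1]` that a reference-allele
#'   copy at a transition site deaminates to the alternative allele.
#' @return the damaged `genotype_matrix`.
#' @export
deaminate <- function(m, p_transition, p_deaminate) {
  validate_genotype_matrix(m)
  if (p_transition < 0 || p_transition > 1 || p_deaminate < 0 || p_deaminate > 1) {
    stop("deamination probabilities must lie in [0, 1]")
  }
  bi <- is_biallelic(m)
  if (any(!bi)) {
    message(sprintf("deaminate: skipped %d non-biallelic site(s)", sum(!bi)))
  }
  transition <- bi & stats::runif(n_sites(m)) < p_transition
  rows <- which(transition)
  np <- n_samples(m)
  for (comp in c("left", "right")) {
    a <- m[[comp]][rows, , drop = FALSE]
    convert <- !is.na(a) & a == 0L &
      matrix(stats::runif(length(rows) * np), length(rows), np) < p_deaminate
    a[convert] <- 1L
    m[[comp]][rows, ] <- a
  }
  m
}

#' Pseudohaploidize genotypes
#'
#' Emulates pseudohaploid genotype calling, the standard representation
#' for low-coverage ancient DNA: at each biallelic site, each sample is
#' reported homozygous for one of its own two allele calls, chosen with
#' equal probability (heterozygotes become `0/0` or `1/1` with
#' probability 1/2 each; homozygotes are unchanged; fully-missing
#' genotypes stay missing). If a half-missing genotype's missing slot
#' is drawn, the genotype becomes fully missing. The result is
#' unphased. Non-biallelic sites are skipped (message reports the
#' count). Because the retained allele is drawn uniformly from the
#' sample's own calls, expected allele frequencies are preserved.
#'
#' @param m a `genotype_matrix`.
#' @return the pseudohaploidized `genotype_matrix`.
#' @export
pseudohaploidize <- function(m) {
  validate_genotype_matrix(m)
  bi <- is_biallelic(m)
  if (any(!bi)) {
    message(sprintf("pseudohaploidize: skipped %d non-biallelic site(s)", sum(!bi)))
  }
  rows <- which(bi)
  np <- n_samples(m)
  take_right <- matrix(stats::runif(length(rows) * np), length(rows), np) < 0.5
  kept <- m$left[rows, , drop = FALSE]
  r <- m$right[rows, , drop = FALSE]
  kept[take_right] <- r[take_right]
  m$left[rows, ] <- kept
  m$right[rows, ] <- kept
  m$phased[rows, ] <- FALSE
  m
}
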