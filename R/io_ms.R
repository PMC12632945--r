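#' Read ms-style simulator output
#'
#' Parses Hudson-style simulator text: replicates delimited by `//`,
#' each with a `segsites: S` line, a `positions:` line of fractional
#' coordinates in (0, 1), and one row of 0/1 characters per haploid
#' genome. Anything before the first `//` (command line, RNG seeds) is
#' ignored.
#'
#' @param path path to an ms/msms-style text file.
#' @return a list of replicates, each a list with elements `segsites`
#'   (integer), `positions` (numeric, non-decreasing) and `haplotypes`
#'   (character vector of 0/1 strings; an even number, since consecutive
#'   pairs are combined into diploid samples downstream).
#' @export
read_ms <- function(path) {
  lines <- readLines(path)
  starts <- which(trimws(lines) == "//")
  if (length(starts) == 0) format_error("no '//' replicate delimiter found in '%s'", path)
  ends <- c(starts[-1] - 1L, length(lines))
  reps <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    seg_line <- grep("^segsites:", trimws(block), value = TRUE)
    if (length(seg_line) != 1) {
      format_error("replicate %d: expected exactly one 'segsites:' line", k)
    }
    segsites <- as.integer(sub("^segsites:\\s*", "", trimws(seg_line)))
    positions <- numeric(0)
    haps <- character(0)
    if (segsites > 0) {
      pos_line <- grep("^positions:", trimws(block), value = TRUE)
      if (length(pos_line) != 1) {
        format_error("replicate %d: expected a 'positions:' line", k)
      }
      positions <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "",
                                                  trimws(pos_line))),
                                       "\\s+")[[1]])
      if (length(positions) != segsites) {
        format_error("replicate %d: %d positions for %d segregating sites",
                     k, length(positions), segsites)
      }
      if (is.unsorted(positions)) {
        format_error("replicate %d: positions are not non-decreasing", k)
      }
      haps <- trimws(block[grepl("^[01]+$", trimws(block))])
      if (any(nchar(haps) != segsites)) {
        format_error("replicate %d: haplotype length differs from segsites (%d)",
                     k, segsites)
      }
    }
    if (length(haps) %% 2 != 0) {
      format_error("replicate %d: odd number of haplotypes (%d); cannot pair into diploids",
                   k, length(haps))
    }
    reps[[k]] <- list(segsites = segsites, positions = positions,
                      haplotypes = haps)
  }
  reps
}

# Map fractional ms positions in (0,1) onto 1-based integer coordinates:
# pos = floor(fraction * L) + 1, with collisions bumped to the next free
# integer so site order is preserved.
#' @keywords internal
map_ms_positions <- function(fractions, segment_length) {
  if (segment_length < length(fractions)) {
    format_error("segment length %d is smaller than the number of sites (%d); cannot place distinct integer positions",
                 segment_length, length(fractions))
  }
  pos <- floor(fractions * segment_length) + 1
  if (length(pos) > 1) {
    for (i in 2:length(pos)) {
      if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
    }
  }
  if (length(pos) > 0 && pos[length(pos)] > segment_length) {
    format_error("collision bumping pushed a position past the segment length (%d)",
                 segment_length)
  }
  as.integer(pos)
}

#' Convert one ms replicate to a genotype matrix
#'
#' Consecutive haplotype pairs (1, 2), (3, 4), ... become diploid
#' samples. Allele 0 is the ancestral allele and becomes REF; allele 1
#' is derived and becomes ALT, so the result is polarized, and every
#' genotype is phased. Fractional positions are mapped to 1-based
#' integers as `floor(fraction * segment_length) + 1`, with ties bumped
#' upward to the next free integer.
#'
#' @param rep one element of the list returned by [read_ms()].
#' @param segment_length length in bp of the simulated segment that the
#'   fractional positions refer to (default 1e6).
#' @param chrom_label chromosome name for the output records.
#' @param ref,alt nucleotides used for the ancestral and derived allele
#'   (ms carries none; defaults "A"/"T").
#' @return a phased, polarized `genotype_matrix` with
#'   `segsites` sites and `length(haplotypes) / 2` samples.
#' @export
ms_to_matrix <- function(rep, segment_length = 1e6, chrom_label = "1",
                         ref = "A", alt = "T") {
  n_hap <- length(rep$haplotypes)
  if (n_hap %% 2 != 0) format_error("odd haplotype count (%d)", n_hap)
  n_dip <- n_hap %/% 2
  s <- rep$segsites
  pos <- map_ms_positions(rep$positions, segment_length)
  hap <- matrix(0L, nrow = s, ncol = n_hap)
  if (s > 0 && n_hap > 0) {
    for (h in seq_len(n_hap)) {
      hap[, h] <- as.integer(strsplit(rep$haplotypes[h], "")[[1]])
    }
  }
  genotype_matrix(chrom = rep(chrom_label, s), pos = pos,
                  ref = rep(ref, s), alt = rep(list(alt), s),
                  left = hap[, 2 * seq_len(n_dip) - 1, drop = FALSE],
                  right = hap[, 2 * seq_len(n_dip), drop = FALSE],
                  phased = matrix(TRUE, s, n_dip),
                  samples = if (n_dip > 0) sprintf("sample_%d", seq_len(n_dip)) else character(0),
                  polarized = TRUE)
}

#' Write a genotype matrix as ms-style output
#'
#' ms-style text cannot represent missing calls, unphased genotypes or
#' multiallelic sites, so writing is only permitted for fully phased,
#' biallelic, missing-free matrices (i.e. before any degradation that
#' introduces missingness). Positions are written as
#' `(pos - 0.5) / segment_length` so that [ms_to_matrix()] recovers the
#' integer coordinates exactly.
#'
#' @param m a phased, biallelic, missing-free `genotype_matrix`.
#' @param path output path.
#' @param segment_length segment length used to rescale positions into
#'   (0, 1); defaults to the largest position in `m`.
#' @return `path`, invisibly.
#' @export
write_ms <- function(m, path, segment_length = NULL) {
  validate_genotype_matrix(m)
  if (any(is.na(m$left)) || any(is.na(m$right))) {
    stop("ms-style output cannot represent missing genotypes; write VCF instead")
  }
  if (n_sites(m) > 0) {
    if (!all(m$phased)) stop("ms-style output requires fully phased genotypes")
    if (!all(is_biallelic(m))) stop("ms-style output requires biallelic sites")
    if (any(m$left > 1) || any(m$right > 1)) {
      stop("ms-style output requires 0/1 alleles")
    }
  }
  s <- n_sites(m)
  if (is.null(segment_length)) {
    segment_length <- if (s > 0) max(m$sites$pos) else 1
  }
  lines <- c(sprintf("genodegrade-ms %d 1", 2L * n_samples(m)), "", "//",
             sprintf("segsites: %d", s))
  if (s > 0) {
    frac <- (m$sites$pos - 0.5) / segment_length
    lines <- c(lines,
               paste("positions:", paste(sprintf("%.10f", frac), collapse = " ")))
    hap <- matrix("", 2L * n_samples(m), s)
    hap[2 * seq_len(n_samples(m)) - 1, ] <- t(m$left)
    hap[2 * seq_len(n_samples(m)), ] <- t(m$right)
    lines <- c(lines, apply(hap, 1, paste, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}
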