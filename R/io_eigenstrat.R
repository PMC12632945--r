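#' Read an EIGENSTRAT triplet into a genotype matrix
#'
#' EIGENSTRAT (the format used by the Allen Ancient DNA Resource)
#' stores genotypes as one digit per sample per line of the `.geno`
#' file: the number of copies of the reference allele (column 5 of the
#' `.snp` file), with 9 for missing. Codes map to VCF genotypes as
#' 0 -> `1/1`, 1 -> `0/1`, 2 -> `0/0`, 9 -> `./.`. EIGENSTRAT carries
#' no phase, so all genotypes are read unphased, and no ancestral
#' allele, so the result is unpolarized.
#'
#' @param geno path to the `.geno` genotype file.
#' @param snp path to the `.snp` site table (columns: id, chrom,
#'   genetic position, physical position, reference allele, alternative
#'   allele).
#' @param ind path to the `.ind` sample table (columns: id, sex,
#'   population); only the id is used.
#' @return a `genotype_matrix`.
#' @export
read_eigenstrat <- function(geno, snp, ind) {
  snp_tab <- utils::read.table(snp, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(snp_tab) < 6) {
    format_error(".snp file '%s' must have 6 columns (id, chrom, genetic pos, physical pos, ref, alt)",
                 snp)
  }
  ind_tab <- utils::read.table(ind, header = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(ind_tab[[1]])
  rows <- readLines(geno)
  rows <- rows[nzchar(rows)]
  if (length(rows) != nrow(snp_tab)) {
    format_error(".geno has %d line(s) but .snp has %d row(s)",
                 length(rows), nrow(snp_tab))
  }
  if (any(nchar(rows) != length(samples))) {
    bad <- which(nchar(rows) != length(samples))[1]
    format_error(".geno line %d has %d character(s) but .ind lists %d sample(s)",
                 bad, nchar(rows[bad]), length(samples))
  }
  n <- length(rows)
  p <- length(samples)
  codes <- matrix(unlist(strsplit(rows, ""), use.names = FALSE),
                  nrow = n, ncol = p, byrow = TRUE)
  ok <- codes %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    format_error("invalid .geno code '%s' at line %d, column %d (expected 0, 1, 2 or 9)",
                 codes[bad], (bad - 1) %% n + 1, (bad - 1) %/% n + 1)
  }
  # code = number of reference-allele copies
  left <- matrix(NA_integer_, n, p)
  right <- matrix(NA_integer_, n, p)
  left[codes == "0"] <- 1L; right[codes == "0"] <- 1L
  left[codes == "1"] <- 0L; right[codes == "1"] <- 1L
  left[codes == "2"] <- 0L; right[codes == "2"] <- 0L
  genotype_matrix(chrom = as.character(snp_tab[[2]]),
                  pos = as.integer(snp_tab[[4]]),
                  ref = as.character(snp_tab[[5]]),
                  alt = as.list(as.character(snp_tab[[6]])),
                  left = left, right = right,
                  phased = matrix(FALSE, n, p),
                  samples = samples, id = as.character(snp_tab[[1]]),
                  polarized = FALSE)
}

#' Convert an EIGENSTRAT triplet to a VCF file
#'
#' Thin wrapper: [read_eigenstrat()] followed by [write_vcf()].
#'
#' @inheritParams read_eigenstrat
#' @param out output VCF path.
#' @return the path of the written VCF, invisibly.
#' @export
eigenstrat_to_vcf <- function(geno, snp, ind, out) {
  write_vcf(read_eigenstrat(geno, snp, ind), out)
}
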