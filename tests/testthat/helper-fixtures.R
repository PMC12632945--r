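# Small hand-built genotype matrices used across test files.

# Build a genotype_matrix from VCF-style GT strings given as a character
# matrix (sites x samples), e.g. rbind(c("0|1", "./."), c("1/1", "0/0")).
matrix_from_gt <- function(gt, chrom = "1", pos = NULL, ref = NULL,
                           alt = NULL, polarized = FALSE) {
  gt <- as.matrix(gt)
  ns <- nrow(gt)
  np <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(ns) * 10L
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep(list("T"), ns)
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  a1[a1 == "."] <- NA
  a2[a2 == "."] <- NA
  genotype_matrix(chrom = rep(chrom, ns), pos = pos, ref = ref, alt = alt,
                  left = matrix(as.integer(a1), ns, np),
                  right = matrix(as.integer(a2), ns, np),
                  phased = matrix(grepl("|", gt, fixed = TRUE), ns, np),
                  samples = sprintf("s%d", seq_len(np)),
                  polarized = polarized)
}

# Write lines to a temp file and return its path.
write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A tiny handwritten 3-site, 2-sample VCF body.
tiny_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "1\t100\trs1\tA\tT\t.\t.\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tG\t.\t.\t.\tGT\t./.\t0/1",
    "1\t300\t.\tG\tA,C\t.\t.\t.\tGT\t1/2\t0/0")
}

# Independent oracle for the dispersal block partition: instead of the
# per-block floor boundaries, assign each index i in 1..n to a block by
# the per-index closed form ceil(i*m/n) (block of i = least j with
# i/n <= j/m).
oracle_block_of <- function(i, n, m) as.integer(ceiling(i * m / n))

oracle_blocks <- function(n, m) {
  split(seq_len(n), vapply(seq_len(n), oracle_block_of, integer(1), n, m))
}
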