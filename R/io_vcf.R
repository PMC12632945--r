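#' @keywords internal
format_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("genodegrade_format_error", "error")))
}

#' Read a VCF file into a genotype matrix
#'
#' Parses the GT field of a VCF 4.x file (plain or gzipped) into a
#' [genotype_matrix()]. Separators determine the phase flag (`|` phased,
#' `/` unphased); `.`, `./.` and `.|.` all map to a fully-missing
#' genotype. All FORMAT fields other than GT are dropped. A matrix is
#' considered polarized when every record carries an `AA=` INFO tag
#' (the convention [write_vcf()] uses for simulator-derived data).
#'
#' @param path path to a `.vcf` or `.vcf.gz` file with at least one
#'   sample column.
#' @return a `genotype_matrix`.
#' @details Non-diploid GT strings (haploid calls, triploid calls) are
#'   an error: the degradation model assumes diploid samples
#'   throughout. Records whose FORMAT lacks GT are read as fully
#'   missing, with a warning.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt_block <- v@gt
  if (is.null(gt_block) || ncol(gt_block) < 2) {
    format_error("VCF '%s' has no sample genotype columns", path)
  }
  samples <- colnames(gt_block)[-1]
  n <- nrow(fix)
  fmt <- gt_block[, 1]
  g <- gt_block[, -1, drop = FALSE]
  # pull the GT subfield where FORMAT carries extra fields
  if (n > 0 && !all(fmt == "GT")) {
    keys <- strsplit(fmt, ":", fixed = TRUE)
    gt_idx <- vapply(keys, function(k) {
      w <- which(k == "GT")
      if (length(w) == 0) NA_integer_ else w[1]
    }, integer(1))
    no_gt <- is.na(gt_idx)
    if (any(no_gt)) {
      warning(sprintf("%d VCF record(s) without a GT FORMAT field read as fully missing",
                      sum(no_gt)))
      g[no_gt, ] <- "."
      gt_idx[no_gt] <- 1L
    }
    multi <- which(gt_idx > 1L | grepl(":", g[, 1], fixed = TRUE) |
                     fmt != "GT")
    for (r in multi) {
      g[r, ] <- vapply(strsplit(g[r, ], ":", fixed = TRUE),
                       `[`, character(1), gt_idx[r])
    }
  }
  g[is.na(g)] <- "."
  parsed <- parse_gt_strings(g, fix)
  alt <- strsplit(ifelse(is.na(fix[, "ALT"]) | fix[, "ALT"] == ".",
                         "", fix[, "ALT"]), ",", fixed = TRUE)
  info <- fix[, "INFO"]
  polarized <- n > 0 && all(!is.na(info) & grepl("(^|;)AA=", info))
  genotype_matrix(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = alt,
                  left = parsed$left, right = parsed$right,
                  phased = parsed$phased, samples = samples,
                  id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                  polarized = polarized)
}

# Split a character matrix of GT strings into allele/phase matrices.
# Fast path for the ubiquitous single-character-allele case.
#' @keywords internal
parse_gt_strings <- function(g, fix) {
  dm <- dim(g)
  gv <- as.vector(g)
  lone <- gv == "."
  gv[lone] <- "./."
  if (all(nchar(gv) == 3L)) {
    a1 <- substr(gv, 1, 1)
    sep <- substr(gv, 2, 2)
    a2 <- substr(gv, 3, 3)
    ok <- (a1 == "." | (a1 >= "0" & a1 <= "9")) &
      (a2 == "." | (a2 >= "0" & a2 <= "9")) & (sep == "/" | sep == "|")
  } else {
    ok <- grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", gv)
    a1 <- sub("[/|].*$", "", gv)
    a2 <- sub("^.*[/|]", "", gv)
    sep <- ifelse(grepl("|", gv, fixed = TRUE), "|", "/")
  }
  if (!all(ok)) {
    bad <- which(!ok)[1]
    r <- (bad - 1) %% dm[1] + 1
    format_error("malformed or non-diploid GT '%s' at record %d (%s:%s); diploid samples are required",
                 gv[bad], r, fix[r, "CHROM"], fix[r, "POS"])
  }
  a1[a1 == "."] <- NA
  a2[a2 == "."] <- NA
  list(left = matrix(as.integer(a1), dm[1], dm[2]),
       right = matrix(as.integer(a2), dm[1], dm[2]),
       phased = matrix(sep == "|", dm[1], dm[2]))
}

#' Write a genotype matrix to a VCF file
#'
#' Emits VCF 4.2 with a minimal header (fileformat, source, inferred
#' contig lines, GT as the only FORMAT field). Phased genotypes use
#' `|`, unphased `/`; fully-missing genotypes are written `./.`. While
#' the matrix is still polarized, every record carries an `AA=<REF>`
#' INFO tag so that downstream tools (and [read_vcf()]) can see that
#' allele index 0 is ancestral; [depolarize()] drops the tag.
#'
#' @param m a `genotype_matrix`.
#' @param path output path; a `.gz` suffix gzip-compresses the output.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  validate_genotype_matrix(m)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##fileDate=%s", format(Sys.Date(), "%Y%m%d")),
              sprintf("##source=genodegrade_v%s",
                      as.character(utils::packageVersion("genodegrade"))),
              sprintf("##contig=<ID=%s>", unique(m$sites$chrom)))
  if (m$polarized) {
    header <- c(header,
                "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">")
  }
  header <- c(header,
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", m$samples),
                    collapse = "\t"))
  a1 <- ifelse(is.na(m$left), ".", as.character(m$left))
  a2 <- ifelse(is.na(m$right), ".", as.character(m$right))
  sep <- ifelse(m$phased & !(is.na(m$left) & is.na(m$right)), "|", "/")
  gt <- matrix(paste0(a1, sep, a2), n_sites(m), n_samples(m))
  altstr <- vapply(m$alt, function(a) {
    if (length(a) == 0) "." else paste(a, collapse = ",")
  }, character(1))
  info <- if (m$polarized) paste0("AA=", m$sites$ref) else rep(".", n_sites(m))
  fixed <- paste(m$sites$chrom, m$sites$pos, m$sites$id, m$sites$ref,
                 altstr, ".", ".", info, "GT", sep = "\t")
  body <- do.call(paste, c(list(fixed), asplit(gt, 2), list(sep = "\t")))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
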