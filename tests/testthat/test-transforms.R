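test_that("unphase preserves allele multisets and clears every phase flag", {
  set.seed(41)
  m <- make_clean_segment(200, 25)
  u <- unphase(m)
  expect_false(any(u$phased))
  sorted_pair <- function(mm) {
    array(c(pmin(mm$left, mm$right), pmax(mm$left, mm$right)),
          c(n_sites(mm), n_samples(mm), 2))
  }
  expect_equal(sorted_pair(u), sorted_pair(m))
  # homozygotes are fixed points; hets land in either order about half the time
  set.seed(42)
  het <- matrix_from_gt(matrix("0|1", 1, 10000), alt = list("T"))
  swapped <- unphase(het)
  expect_lt(abs(mean(swapped$left[1, ] == 1) - 0.5), 0.02)
  f <- tempfile(fileext = ".vcf")
  write_vcf(swapped, f)
  body <- grep("^#", readLines(f), invert = TRUE, value = TRUE)
  expect_false(any(grepl("|", body, fixed = TRUE)))
})

test_that("depolarize relabels sites without changing carried nucleotides", {
  set.seed(43)
  m <- make_clean_segment(2000, 10)
  d <- depolarize(m)
  expect_false(d$polarized)
  nuc_of <- function(mm, allele) {
    alleles <- cbind(mm$sites$ref, vapply(mm$alt, `[`, character(1), 1))
    matrix(alleles[cbind(rep(seq_len(n_sites(mm)), n_samples(mm)),
                         as.vector(allele) + 1L)],
           n_sites(mm), n_samples(mm))
  }
  expect_equal(nuc_of(d, d$left), nuc_of(m, m$left))
  expect_equal(nuc_of(d, d$right), nuc_of(m, m$right))
  flipped <- d$sites$ref != m$sites$ref
  expect_lt(abs(mean(flipped) - 0.5), 0.03)
  # flipped sites exchange REF/ALT and complement the genotype indices
  expect_equal(m$sites$ref[flipped],
               vapply(d$alt[flipped], `[`, character(1), 1))
  expect_equal(d$left[flipped, ], 1L - m$left[flipped, ])
  # non-biallelic sites are skipped with a message
  mono <- matrix_from_gt(rbind("0/0", "0/1"), alt = list(character(0), "T"))
  expect_message(depolarize(mono), "skipped 1")
})

test_that("depolarize keeps missing calls missing and is frequency-neutral twice over", {
  m <- matrix_from_gt(rbind(c("0|1", "./.", "1|1")), polarized = TRUE)
  set.seed(44)
  d <- suppressMessages(depolarize(depolarize(m)))
  expect_true(is.na(d$left[1, 2]) && is.na(d$right[1, 2]))
  count_nuc <- function(mm) {
    alleles <- c(mm$sites$ref[1], mm$alt[[1]])
    table(factor(alleles[c(mm$left[1, ], mm$right[1, ]) + 1L],
                 levels = c("A", "C", "G", "T")))
  }
  expect_equal(count_nuc(d), count_nuc(m))
})

test_that("deamination converts only reference copies at transition sites", {
  set.seed(45)
  m <- make_clean_segment(3000, 10)
  expect_equal(deaminate(m, 0, 0.9), m)
  expect_equal(deaminate(m, 0.9, 0), m)
  sat <- deaminate(m, 1, 1)
  expect_true(all(sat$left == 1L) && all(sat$right == 1L))
  # ALT counts can only grow
  set.seed(46)
  dmg <- deaminate(m, 0.5, 0.4)
  expect_true(all(rowSums(dmg$left + dmg$right) >=
                    rowSums(m$left + m$right)))
  # overall conversion fraction approximates p_t * p_d
  n_ref <- sum(m$left == 0) + sum(m$right == 0)
  converted <- (sum(dmg$left) + sum(dmg$right)) -
    (sum(m$left) + sum(m$right))
  expect_lt(abs(converted / n_ref - 0.2), 0.02)
  # missing alleles stay missing
  hole <- apply_plan(m, rep(0.2, 3000))
  set.seed(47)
  dmg2 <- deaminate(hole, 1, 1)
  expect_equal(fully_missing(dmg2), fully_missing(hole))
})

test_that("pseudohaploidization eliminates heterozygotes without biasing frequencies", {
  set.seed(48)
  m <- make_clean_segment(300, 20)
  ph <- pseudohaploidize(m)
  expect_true(all(ph$left == ph$right, na.rm = TRUE))
  expect_false(any(ph$phased))
  # homozygotes and fully-missing genotypes are fixed points
  hom <- m$left == m$right
  expect_equal(ph$left[hom], m$left[hom])
  hole <- apply_plan(m, rep(0.3, 300))
  set.seed(49)
  ph2 <- pseudohaploidize(hole)
  expect_equal(fully_missing(ph2)[fully_missing(hole)],
               rep(TRUE, sum(fully_missing(hole))))
  # het outcomes are balanced and allele frequency is preserved in expectation
  set.seed(50)
  het <- matrix_from_gt(matrix("0/1", 1, 10000), alt = list("T"))
  out <- pseudohaploidize(het)
  expect_lt(abs(mean(out$left[1, ] == 1) - 0.5), 0.02)
  big_freq_in <- mean(c(m$left, m$right))
  big_freq_out <- mean(c(ph$left, ph$right))
  expect_lt(abs(big_freq_out - big_freq_in), 0.02)
})

test_that("depolarization commutes exactly with sample reordering", {
  # site-level coin flips do not depend on sample order
  set.seed(51)
  m <- make_clean_segment(50, 8)
  perm <- sample(8)
  set.seed(52)
  a <- depolarize(m[, perm])
  set.seed(52)
  b <- depolarize(m)[, perm]
  expect_equal(a, b)
})
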