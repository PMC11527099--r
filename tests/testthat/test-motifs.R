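test_that("loadKmers normalizes, deduplicates and validates", {
  f <- tempfile()
  writeLines(c("atcg", "ATCG", "", "ccg"), f)
  expect_setequal(kmers(loadKmers(f)), c("ATCG", "CCG"))
  writeLines("AT-CG", f)
  expect_error(loadKmers(f), "outside \\{A,C,G,T\\}")
})

test_that("parseJaspar reads bracketed and bare layouts, counts or probs", {
  f <- tempfile()
  writeLines(c(">M1 example",
               "A [ 0.2 0.1 0.4 0.3 ]",
               "C [ 0.3 0.5 0.1 0.2 ]",
               "G [ 0.4 0.3 0.4 0.5 ]",
               "T [ 0.1 0.1 0.1 0.0 ]"), f)
  pw <- parseJaspar(f)
  expect_length(pw, 1L)
  expect_equal(ncol(probs(pw[[1]])), 4L)
  expect_equal(unname(probs(pw[[1]])["G", 4]), 0.5)
  expect_equal(unname(colSums(probs(pw[[1]]))), rep(1, 4))

  # counts, bare rows, no labels: columns renormalized
  writeLines(c(">M2", "3 6", "1 2", "4 1", "2 1"), f)
  pw2 <- parseJaspar(f)[[1]]
  expect_equal(unname(probs(pw2)["A", 1]), 0.3)
  expect_equal(unname(probs(pw2)["A", 2]), 0.6)

  # single column
  writeLines(c(">M3", "A [1]", "C [0]", "G [0]", "T [0]"), f)
  expect_equal(ncol(probs(parseJaspar(f)[[1]])), 1L)

  # missing nucleotide row
  writeLines(c(">M4", "A [1]", "C [0]", "G [0]"), f)
  expect_error(parseJaspar(f), "expected 4 nucleotide rows")
  # unequal row lengths
  writeLines(c(">M5", "A [1 2]", "C [1]", "G [1 2]", "T [1 2]"), f)
  expect_error(parseJaspar(f), "unequal lengths")
})

test_that("reverse complement of k-mers matches the worked example", {
  expect_equal(reverseComplement("CCG"), "CGG")
  expect_equal(reverseComplement("A"), "T")
  expect_equal(reverseComplement("ACGT"), "ACGT")
  set.seed(5)
  for (i in 1:20) {
    s <- randomSeq(sample(1:12, 1))
    expect_equal(reverseComplement(s), naiveRevComp(s))
  }
})

test_that("reverse complement of a PWM follows the stated rule and is an involution", {
  pwm <- tablePwm()
  rc <- reverseComplement(pwm)
  # rc column 1 comes from original column 4 with complemented rows:
  # original col 4 is (A=.3, C=.2, G=.5, T=0) -> rc col 1 (A=0, C=.5, G=.2, T=.3)
  expect_equal(unname(probs(rc)[, 1]), c(0.0, 0.5, 0.2, 0.3))
  # full matrix relation rc[b, i] = p[comp(b), L - 1 - i]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- ncol(probs(pwm))
  for (b in rownames(probs(pwm))) for (i in seq_len(L))
    expect_equal(unname(probs(rc)[b, i]),
                 unname(probs(pwm)[comp[[b]], L + 1 - i]))
  # involution
  expect_equal(probs(reverseComplement(rc)), probs(pwm))
  # symmetry fixed point: uniform matrix maps to itself
  uni <- new("PwmMotif", motifId = "U", name = "U",
             probs = matrix(0.25, 4, 3,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(probs(reverseComplement(uni)), probs(uni))
  # single-column pure-A complements to pure-T
  a1 <- new("PwmMotif", motifId = "A1", name = "A1",
            probs = matrix(c(1, 0, 0, 0), 4, 1,
                           dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(unname(probs(reverseComplement(a1))[, 1]), c(0, 0, 0, 1))
})

test_that("log-odds scores follow log2(p/bg) with pseudocount regularization", {
  # closed form without pseudocount influence: p = 0.5 vs bg = 0.25 -> 1 bit
  m <- matrix(c(0.5, 0.5, 0, 0), 4, 1,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  lo <- pwmLogOdds(new("PwmMotif", motifId = "x", name = "x", probs = m),
                   pseudocount = 0)
  expect_equal(unname(lo@scores["A", 1]), 1)
  # identity: p == bg everywhere -> all-zero matrix
  uni <- matrix(0.25, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  lo2 <- pwmLogOdds(new("PwmMotif", motifId = "u", name = "u", probs = uni))
  expect_equal(unname(lo2@scores), matrix(0, 4, 2))
  expect_equal(lo2@minScore, 0)
  expect_equal(lo2@maxScore, 0)
  # pseudocount rule, hand-computed for the worked-example column 1
  lo3 <- pwmLogOdds(tablePwm(), pseudocount = 0.01)
  expect_equal(unname(lo3@scores["A", 1]), log2((0.21 / 1.04) / 0.25))
  expect_equal(unname(lo3@scores["T", 4]), log2((0.01 / 1.04) / 0.25))
  expect_false(any(is.infinite(lo3@scores)))
  # zero background rejected
  expect_error(pwmLogOdds(tablePwm(), background = c(0.5, 0.5, 0, 0)),
               "strictly positive")
  # min/max bookkeeping
  expect_equal(lo3@maxScore, sum(apply(lo3@scores, 2, max)))
  expect_equal(lo3@minScore, sum(apply(lo3@scores, 2, min)))
})

test_that("threshold calibration is deterministic, monotone and accurate", {
  lo <- pwmLogOdds(tablePwm())
  c1 <- calibrateThreshold(lo, pValue = 0.05, nSamples = 20000, seed = 9)
  c2 <- calibrateThreshold(lo, pValue = 0.05, nSamples = 20000, seed = 9)
  expect_identical(threshold(c1), threshold(c2))

  # monotone: larger p-value -> lower threshold (same seed and samples)
  ps <- c(0.01, 0.05, 0.2, 0.5)
  thr <- vapply(ps, function(p)
    threshold(calibrateThreshold(lo, pValue = p, nSamples = 20000,
                                 seed = 9)), 0)
  expect_true(all(diff(thr) <= 0))

  # degenerate p = 1: every window passes
  cAll <- calibrateThreshold(lo, pValue = 1, nSamples = 1000, seed = 1)
  expect_lte(threshold(cAll), lo@minScore)

  # under-resolved tail warns
  expect_warning(calibrateThreshold(lo, pValue = 1e-4, nSamples = 100,
                                    seed = 1),
                 "cannot resolve")

  # Monte-Carlo threshold close to the exact 95th-percentile score from
  # exhaustive enumeration of all 256 length-4 sequences
  exact <- exhaustiveQuantile(lo@scores, rep(0.25, 4), 0.05)
  mc <- threshold(calibrateThreshold(lo, pValue = 0.05, nSamples = 1e5,
                                     seed = 42))
  expect_lt(abs(mc - exact), 0.15)
})

test_that("exact tail mass at the calibrated threshold is within 3 SE of p", {
  set.seed(21)
  for (L in c(3L, 5L)) {
    pwm <- randomPwm(L)
    bg <- rep(0.25, 4)
    lo <- pwmLogOdds(pwm, background = bg)
    p <- 0.05
    n <- 1e5
    thr <- threshold(calibrateThreshold(lo, pValue = p, nSamples = n,
                                        seed = 42))
    exact <- exhaustiveTail(lo@scores, bg, thr)
    se <- sqrt(p * (1 - p) / n)
    atom <- 0.25^L  # quantization of the discrete score distribution
    expect_lt(abs(exact - p), 3 * se + atom)
  }
})
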