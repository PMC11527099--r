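test_that("k-mer engine reproduces the reverse-complement worked example", {
  h <- scanKmers("ATCGGCA", kmerSet("CCG"), includeRevComp = TRUE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$matchedSeq, "CGG")
  expect_equal(c(h$start, h$end), c(2L, 4L))
  # source coordinates (3, 5) when the record starts at 1
  rec <- list(start = 1, size = 7)
  expect_equal(unname(ungappedToSource(rec, h$start, 3)), c(3, 5))
})

test_that("k-mer engine reports overlapping and nested occurrences", {
  h <- scanKmers("AAAA", kmerSet("AA"))
  expect_equal(h$start, c(0L, 1L, 2L))
  # nested: one k-mer inside another
  h2 <- scanKmers("GATCGA", kmerSet(c("ATCG", "TC")))
  expect_equal(h2$motifId, c("ATCG", "TC"))
  expect_equal(h2$start, c(1L, 2L))
  expect_error(scanKmers("ACGT", new("KmerSet", kmers = character(0))),
               "non-empty")
})

test_that("k-mer engine equals the sliding-window oracle on random cases", {
  set.seed(31)
  for (i in 1:40) {
    seq <- randomSeq(sample(50:200, 1))
    kms <- unique(vapply(1:10, function(j) randomSeq(4), ""))
    rc <- sample(c(TRUE, FALSE), 1)
    got <- scanKmers(seq, kmerSet(kms), includeRevComp = rc)
    want <- naiveKmerScan(seq, kms, includeRevComp = rc)
    expect_equal(got[, c("motifId", "start", "end", "strand", "matchedSeq")],
                 want, ignore_attr = TRUE)
  }
})

test_that("N in the sequence never matches a k-mer base", {
  expect_equal(nrow(scanKmers("ATNCG", kmerSet(c("ATC", "TCG")))), 0L)
  expect_equal(scanKmers("ANATCG", kmerSet("ATCG"))$start, 2L)
  # k-mers themselves may not contain N or gaps
  expect_error(kmerSet("AT-G"), "outside \\{A,C,G,T\\}")
})

test_that("regex engine finds reverse-strand matches via sequence reversal", {
  h <- scanRegex("ATCGGCA", regexSet("C{2}G"), includeRevComp = TRUE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(c(h$start, h$end), c(2L, 4L))
  expect_equal(h$matchedSeq, "CGG")  # forward-frame slice
  rec <- list(start = 1, size = 7)
  expect_equal(unname(ungappedToSource(rec, h$start, 3)), c(3, 5))
})

test_that("regex engine enumerates overlaps and handles empty results", {
  expect_equal(scanRegex("AAA", regexSet("A"))$start, c(0L, 1L, 2L))
  # overlapping matches found by restarting one position after each start
  expect_equal(scanRegex("AAAA", regexSet("AA"))$start, c(0L, 1L, 2L))
  expect_equal(nrow(scanRegex("ACGT", regexSet("TTTT"))), 0L)
  # comma-separated construction
  h <- scanRegex("ACGTACGT", regexSet("ACG,CGT"))
  expect_setequal(h$motifId, c("ACG", "CGT"))
  expect_equal(nrow(h), 4L)
})

test_that("regex and k-mer engines agree on literal patterns", {
  set.seed(37)
  for (i in 1:20) {
    seq <- randomSeq(150)
    pat <- randomSeq(3)
    rc <- sample(c(TRUE, FALSE), 1)
    a <- scanKmers(seq, kmerSet(pat), includeRevComp = rc)
    b <- scanRegex(seq, regexSet(pat), includeRevComp = rc)
    expect_equal(a[, c("start", "end", "strand", "matchedSeq")],
                 b[, c("start", "end", "strand", "matchedSeq")],
                 ignore_attr = TRUE)
  }
})

test_that("PWM engine equals the per-window rescoring oracle", {
  set.seed(41)
  lo <- pwmLogOdds(randomPwm(4))
  cal <- calibrateThreshold(lo, pValue = 0.2, nSamples = 5000, seed = 2)
  thr <- threshold(cal)
  tol <- 1e-9  # exclude exact threshold ties (long-double vs double sums)
  for (i in 1:15) {
    seq <- randomSeq(300)
    got <- scanPwm(seq, lo, cal)
    want <- naivePwmScan(seq, lo@scores, thr)
    expect_equal(got$start[abs(got$score - thr) > tol],
                 want$start[abs(want$score - thr) > tol])
    common <- intersect(got$start, want$start)
    expect_equal(got$score[match(common, got$start)],
                 want$score[match(common, want$start)], tolerance = 1e-12)
    # reverse strand against the reverse-complement matrix
    gotRc <- scanPwm(seq, lo, cal, includeRevComp = TRUE)
    rcM <- gotRc[gotRc$strand == "-", ]
    wantRc <- naivePwmScan(seq, lo@rcScores, thr)
    expect_equal(rcM$start[abs(rcM$score - thr) > tol],
                 wantRc$start[abs(wantRc$score - thr) > tol])
  }
})

test_that("PWM boundary and degenerate behaviour", {
  # threshold comparison is inclusive: calibrate at p = 1 on a uniform
  # matrix where every window scores exactly 0 = threshold
  uni <- new("PwmMotif", motifId = "u", name = "u",
             probs = matrix(0.25, 4, 2,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  lo <- pwmLogOdds(uni, pseudocount = 0)
  cal <- calibrateThreshold(lo, pValue = 1, nSamples = 100, seed = 1)
  h <- scanPwm("ACGTA", lo, cal)
  expect_equal(nrow(h), 4L)          # every window is a hit
  expect_true(all(h$score == 0))
  expect_true(all(h$score >= threshold(cal)))
  # windows containing N are skipped (only windows AC and TA remain)
  hN <- scanPwm("ACNTA", lo, cal)
  expect_equal(hN$start, c(0L, 3L))
  # sequence shorter than the motif: no hits
  expect_equal(nrow(scanPwm("A", lo, cal)), 0L)
})

test_that("PWM empirical p-values are tail fractions of the calibration sample", {
  lo <- pwmLogOdds(tablePwm())
  cal <- calibrateThreshold(lo, pValue = 0.5, nSamples = 10000, seed = 3)
  h <- scanPwm("ATCGGCATGGT", lo, cal)
  expect_gt(nrow(h), 0L)
  for (i in seq_len(nrow(h))) {
    frac <- mean(cal@sampleScores >= h$score[i] - 1e-12)
    expect_equal(h$pValue[i], max(frac, 1 / (cal@nSamples + 1)))
    expect_gt(h$pValue[i], 0)
    expect_lte(h$pValue[i], 1)
  }
  # a higher score never gets a larger empirical p-value
  o <- order(h$score)
  expect_true(all(diff(h$pValue[o]) <= 0))
})

test_that("strand symmetry: hits reflect onto revcomp(motif) on revcomp(seq)", {
  set.seed(47)
  for (i in 1:15) {
    seq <- randomSeq(120)
    km <- randomSeq(4)
    n <- nchar(seq)
    fwd <- scanKmers(seq, kmerSet(km), includeRevComp = TRUE)
    mirr <- scanKmers(reverseComplement(seq), kmerSet(reverseComplement(km)),
                      includeRevComp = TRUE)
    # a '+' hit of km at [s, e] is a '+' hit of revcomp(km) at
    # [n-e-1, n-s-1] in the reverse-complemented sequence; '-' hits
    # reflect onto '-' hits likewise
    reflS <- sort(n - fwd$end[fwd$strand == "+"] - 1L)
    expect_equal(sort(mirr$start[mirr$strand == "+"]), reflS)
    reflS2 <- sort(n - fwd$end[fwd$strand == "-"] - 1L)
    expect_equal(sort(mirr$start[mirr$strand == "-"]), reflS2)
  }
})

test_that("mapHitToAlignment fills gapped spans consistent with the row", {
  h <- scanKmers("ATCG", kmerSet("TCG"))
  m <- mapHitToAlignment(h, buildGapMap("A-TCG"))
  expect_equal(c(m$gappedStart, m$gappedEnd), c(2L, 4L))
  # gap-free row: spans coincide
  m2 <- mapHitToAlignment(scanKmers("ATCG", kmerSet("TCG")),
                          buildGapMap("ATCG"))
  expect_equal(c(m2$gappedStart, m2$gappedEnd), c(1L, 3L))
  # hit spanning a 3-gap run: gapped span longer than the motif by 3
  txt <- "AC---GT"
  m3 <- mapHitToAlignment(scanKmers("ACGT", kmerSet("CG")), buildGapMap(txt))
  expect_equal(m3$gappedEnd - m3$gappedStart + 1L, 2L + 3L)
  ch <- strsplit(txt, "")[[1]]
  span <- ch[(m3$gappedStart + 1):(m3$gappedEnd + 1)]
  expect_equal(paste(span[span != "-"], collapse = ""), m3$matchedSeq)
  # out-of-range offsets rejected
  expect_error(mapHitToAlignment(scanKmers("ATCGG", kmerSet("CGG")),
                                 buildGapMap("A-TCG")),
               "outside")
})

test_that("gapped slice minus gaps always equals matchedSeq (random fixtures)", {
  set.seed(53)
  for (i in 1:25) {
    ch <- sample(c("A", "C", "G", "T", "-"), 80, replace = TRUE,
                 prob = c(rep(0.22, 4), 0.12))
    txt <- paste(ch, collapse = "")
    seq <- gsub("-", "", txt, fixed = TRUE)
    if (nchar(seq) < 6) next
    km <- substring(seq, 3, 5)
    hits <- mapHitToAlignment(scanKmers(seq, kmerSet(km)), buildGapMap(txt))
    for (j in seq_len(nrow(hits))) {
      span <- ch[(hits$gappedStart[j] + 1):(hits$gappedEnd[j] + 1)]
      expect_equal(paste(span[span != "-"], collapse = ""),
                   hits$matchedSeq[j])
    }
  }
})
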