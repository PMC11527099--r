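#' @useDynLib mafconserve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical empty hit table; offsets are 0-based and ungapped
.emptyHits <- function() {
  data.frame(motifId = character(0), motifType = character(0),
             start = integer(0), end = integer(0),
             strand = character(0), matchedSeq = character(0),
             score = numeric(0), pValue = numeric(0),
             stringsAsFactors = FALSE)
}

.orderHits <- function(hits) {
  hits[order(hits$start, hits$motifId, hits$strand), , drop = FALSE]
}

#' Scan a sequence for literal k-mer motifs
#'
#' Locates every occurrence of every k-mer in one pass of an
#' Aho-Corasick multi-pattern automaton over the ungapped sequence.
#' Overlapping and nested occurrences are all reported. With
#' `includeRevComp = TRUE` the reverse complement of each k-mer is
#' searched on the forward text and reported with strand `'-'`; the
#' `matchedSeq` field always holds the forward-frame text (i.e. the
#' reverse complement of the k-mer for a `'-'` hit).
#'
#' @param seq uppercase, gap-free sequence string.
#' @param kmerSet a [KmerSet][KmerSet-class].
#' @param includeRevComp also search each k-mer's reverse complement
#'   (default `FALSE`).
#' @return data.frame of hits ordered by start then motif identifier,
#'   with columns `motifId`, `motifType`, `start`, `end` (0-based
#'   inclusive ungapped offsets), `strand`, `matchedSeq`, `score`,
#'   `pValue` (the last two `NA` for k-mer hits).
#' @examples
#' scanKmers("ATCGGCA", kmerSet("CCG"), includeRevComp = TRUE)
#' @export
scanKmers <- function(seq, kmerSet, includeRevComp = FALSE) {
  if (!is(kmerSet, "KmerSet")) kmerSet <- kmerSet(kmerSet)
  km <- kmers(kmerSet)
  pat <- data.frame(motifId = km, strand = "+", text = km,
                    stringsAsFactors = FALSE)
  if (includeRevComp) {
    pat <- rbind(pat, data.frame(motifId = km, strand = "-",
                                 text = .revCompChar(km)))
  }
  uniq <- unique(pat$text)
  m <- .acSearch(seq, uniq)
  if (!nrow(m)) return(.emptyHits())
  # expand matches of each unique string to all (k-mer, strand) carriers
  carrier <- split(seq_len(nrow(pat)), match(pat$text, uniq))
  rows <- carrier[as.character(m$pattern)]
  nrep <- lengths(rows)
  pidx <- unlist(rows, use.names = FALSE)
  starts <- rep(m$start, nrep)
  hits <- data.frame(
    motifId = pat$motifId[pidx], motifType = "kmer",
    start = starts, end = starts + nchar(pat$text[pidx]) - 1L,
    strand = pat$strand[pidx], matchedSeq = pat$text[pidx],
    score = NA_real_, pValue = NA_real_, stringsAsFactors = FALSE)
  .orderHits(hits)
}

#' Scan a sequence with regular-expression motifs
#'
#' Forward hits come from scanning the sequence itself. Because a regex
#' cannot be reverse complemented symbolically, reverse-strand hits are
#' found by scanning the reverse complement of the sequence and mapping
#' match coordinates back to the original frame
#' (`start' = len - end - 1`, `end' = len - start - 1`, 0-based).
#' Overlapping matches are enumerated by restarting the search one
#' position after each match start. Zero-length matches are skipped.
#' `matchedSeq` holds the forward-frame text of the matched span.
#'
#' @param seq uppercase, gap-free sequence string.
#' @param regexSet a [RegexSet][RegexSet-class] (or character vector of
#'   patterns).
#' @param includeRevComp also scan the reverse complement of the
#'   sequence (default `FALSE`).
#' @return data.frame of hits as in [scanKmers()], `motifType = "regex"`.
#' @examples
#' scanRegex("ATCGGCA", regexSet("C{2}G"), includeRevComp = TRUE)
#' @export
scanRegex <- function(seq, regexSet, includeRevComp = FALSE) {
  if (!is(regexSet, "RegexSet")) regexSet <- regexSet(regexSet)
  pats <- patterns(regexSet)
  n <- nchar(seq)
  res <- list()
  for (pat in pats) {
    fwd <- .regexAll(seq, pat)
    if (nrow(fwd)) {
      res[[length(res) + 1L]] <- data.frame(
        motifId = pat, motifType = "regex", start = fwd$start,
        end = fwd$end, strand = "+",
        matchedSeq = substring(seq, fwd$start + 1L, fwd$end + 1L),
        score = NA_real_, pValue = NA_real_, stringsAsFactors = FALSE)
    }
    if (includeRevComp) {
      rc <- .regexAll(.revCompChar(seq), pat)
      if (nrow(rc)) {
        os <- n - rc$end - 1L
        oe <- n - rc$start - 1L
        res[[length(res) + 1L]] <- data.frame(
          motifId = pat, motifType = "regex", start = os, end = oe,
          strand = "-", matchedSeq = substring(seq, os + 1L, oe + 1L),
          score = NA_real_, pValue = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(.emptyHits())
  .orderHits(do.call(rbind, res))
}

# all (overlapping) matches of one pattern; 0-based inclusive coordinates
.regexAll <- function(seq, pat) {
  starts <- integer(0); ends <- integer(0)
  pos <- 1L
  n <- nchar(seq)
  while (pos <= n) {
    m <- tryCatch(regexpr(pat, substring(seq, pos), perl = TRUE),
                  error = function(e)
                    stop(sprintf("pattern '%s' failed to compile: %s", pat,
                                 conditionMessage(e)), call. = FALSE))
    if (m == -1L) break
    len <- attr(m, "match.length")
    s <- pos + as.integer(m) - 1L  # 1-based absolute
    if (len > 0L) {
      starts <- c(starts, s - 1L)
      ends <- c(ends, s + len - 2L)
    }
    pos <- s + 1L
  }
  data.frame(start = starts, end = ends)
}

#' Scan a sequence with a calibrated position weight matrix
#'
#' Scores every length-L window of the sequence with the log-odds
#' matrix and reports windows scoring at or above the calibrated
#' threshold (the comparison is inclusive). The reverse strand is
#' scanned with the reverse-complement matrix against the same
#' threshold. Windows containing any non-ACGT character (e.g. `N`) are
#' skipped. Each hit carries its score and the empirical p-value (tail
#' fraction of the calibration sample at or above the score).
#'
#' @param seq uppercase, gap-free sequence string.
#' @param logodds a [LogOddsMatrix][LogOddsMatrix-class].
#' @param calib a [CalibratedThreshold][CalibratedThreshold-class] from
#'   [calibrateThreshold()].
#' @param includeRevComp also scan the reverse strand (default `FALSE`).
#' @return data.frame of hits as in [scanKmers()], `motifType = "pwm"`,
#'   with `score` and `pValue` populated.
#' @export
scanPwm <- function(seq, logodds, calib, includeRevComp = FALSE) {
  L <- ncol(logodds@scores)
  n <- nchar(seq)
  if (n < L) return(.emptyHits())
  base <- match(strsplit(seq, "", fixed = TRUE)[[1]], .DNA_BASES)
  nw <- n - L + 1L
  # window x position matrix of base indices
  idx <- outer(seq_len(nw), 0:(L - 1L), `+`)
  bmat <- matrix(base[idx], nrow = nw)
  valid <- !apply(is.na(bmat), 1L, any)
  strands <- if (includeRevComp) c("+", "-") else "+"
  res <- list()
  for (st in strands) {
    sc <- if (st == "+") logodds@scores else logodds@rcScores
    wscore <- rep(NA_real_, nw)
    if (any(valid)) {
      cell <- matrix(sc[cbind(as.vector(bmat[valid, , drop = FALSE]),
                              rep(seq_len(L), each = sum(valid)))],
                     nrow = sum(valid))
      wscore[valid] <- rowSums(cell)
    }
    pass <- which(valid & wscore >= calib@threshold)
    if (length(pass)) {
      res[[length(res) + 1L]] <- data.frame(
        motifId = logodds@motifId, motifType = "pwm",
        start = pass - 1L, end = pass + L - 2L, strand = st,
        matchedSeq = substring(seq, pass, pass + L - 1L),
        score = wscore[pass], pValue = .empiricalP(wscore[pass], calib),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(.emptyHits())
  .orderHits(do.call(rbind, res))
}

#' Map an ungapped hit to gapped alignment columns
#'
#' Fills the gapped column span of a hit: `gappedStart` is the column of
#' the first matched base and `gappedEnd` the column of the last matched
#' base (0-based, inclusive). The span contains exactly the hit's bases
#' as non-gap characters.
#'
#' @param hits data.frame of hits from a scan function (columns `start`,
#'   `end` as 0-based ungapped offsets).
#' @param gapMap a [GapIndexMap][GapIndexMap-class] for the searched row.
#' @return the hit data.frame with `gappedStart` and `gappedEnd` columns
#'   added.
#' @examples
#' h <- scanKmers("ATCG", kmerSet("TCG"))
#' mapHitToAlignment(h, buildGapMap("A-TCG"))
#' @export
mapHitToAlignment <- function(hits, gapMap) {
  u2g <- ungappedToGapped(gapMap)
  if (nrow(hits)) {
    if (any(hits$start < 0L) || any(hits$end >= length(u2g)))
      stop("hit offsets outside the record's ungapped length", call. = FALSE)
    hits$gappedStart <- u2g[hits$start + 1L]
    hits$gappedEnd <- u2g[hits$end + 1L]
  } else {
    hits$gappedStart <- integer(0)
    hits$gappedEnd <- integer(0)
  }
  hits
}
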