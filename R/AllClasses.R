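#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.MAF_ALPHABET <- c("A", "C", "G", "T", "N", "-")
.DNA_BASES <- c("A", "C", "G", "T")

#' MafBlock: one alignment block of a MAF file
#'
#' A single block of a Multiple Alignment Format (MAF) file: the optional
#' score from the `a` line plus an ordered table of gapped sequence
#' records (the `s` lines). Coordinates follow the MAF convention: the
#' `start` field is the 0-based, strand-relative offset of the first
#' aligned base in the source sequence and `size` counts non-gap
#' characters.
#'
#' @slot score numeric(1), the `a score=` value (`NA` if absent).
#' @slot records a [S4Vectors::DataFrame] with columns `src`, `start`,
#'   `size`, `strand`, `srcSize`, `text`. The first record is the block's
#'   reference row by default.
#' @slot blockIndex integer(1), 0-based ordinal of the block in its file.
#'
#' @seealso [parseMaf()], [mafBlockFromTexts()]
#' @exportClass MafBlock
setClass("MafBlock",
  slots = c(score = "numeric", records = "DataFrame", blockIndex = "integer")
)

setValidity("MafBlock", function(object) {
  rec <- object@records
  need <- c("src", "start", "size", "strand", "srcSize", "text")
  if (!all(need %in% colnames(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(rec) == 0L)
    return("a MafBlock must contain at least one sequence record")
  txt <- rec$text
  if (length(unique(nchar(txt))) != 1L)
    return("all records in a block must have equal gapped text length")
  bad <- grepl(paste0("[^", paste(.MAF_ALPHABET, collapse = ""), "]"), txt)
  if (any(bad))
    return(sprintf("record %d: text contains characters outside {A,C,G,T,N,-}",
                   which(bad)[1]))
  ungapped <- nchar(gsub("-", "", txt, fixed = TRUE))
  if (any(ungapped != rec$size))
    return(sprintf("record %d ('%s'): stated size %d != non-gap count %d",
                   which(ungapped != rec$size)[1],
                   rec$src[ungapped != rec$size][1],
                   rec$size[ungapped != rec$size][1],
                   ungapped[ungapped != rec$size][1]))
  if (any(rec$start + rec$size > rec$srcSize))
    return("start + size exceeds srcSize for at least one record")
  if (!all(rec$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  TRUE
})

#' GapIndexMap: gapped/ungapped coordinate map for one alignment row
#'
#' Bidirectional map between the 0-based ungapped offsets of a sequence
#' and the 0-based gapped column indices of its aligned (gap-containing)
#' text.
#'
#' @slot ungappedToGapped integer vector; entry `u + 1` holds the column
#'   index of the u-th (0-based) non-gap character. Strictly increasing.
#' @slot gappedToUngapped integer vector over all columns; entry `c + 1`
#'   holds the ungapped offset of column `c`, or `NA` for gap columns.
#'
#' @seealso [buildGapMap()]
#' @exportClass GapIndexMap
setClass("GapIndexMap",
  slots = c(ungappedToGapped = "integer", gappedToUngapped = "integer")
)

setValidity("GapIndexMap", function(object) {
  u2g <- object@ungappedToGapped
  g2u <- object@gappedToUngapped
  if (length(u2g) && any(diff(u2g) <= 0L))
    return("ungappedToGapped must be strictly increasing")
  if (length(u2g) != sum(!is.na(g2u)))
    return("map sizes disagree on the number of non-gap columns")
  ok <- is.na(g2u[u2g + 1L]) | g2u[u2g + 1L] != seq_along(u2g) - 1L
  if (length(u2g) && any(ok))
    return("round-trip identity violated for a non-gap column")
  TRUE
})

#' KmerSet: a set of literal k-mer motifs
#'
#' Uppercase DNA words over {A,C,G,T}; each k-mer is its own identifier.
#'
#' @slot kmers character vector of unique uppercase k-mers.
#' @seealso [loadKmers()]
#' @exportClass KmerSet
setClass("KmerSet", slots = c(kmers = "character"))

setValidity("KmerSet", function(object) {
  k <- object@kmers
  if (length(k) == 0L) return("k-mer set must be non-empty")
  if (anyDuplicated(k)) return("k-mers must be unique")
  bad <- grepl("[^ACGT]", k)
  if (any(bad))
    return(sprintf("k-mer '%s' contains characters outside {A,C,G,T}",
                   k[bad][1]))
  TRUE
})

#' RegexSet: an ordered set of regular-expression motifs
#'
#' @slot patterns character vector of regular expressions (PCRE dialect);
#'   the pattern text is its identifier.
#' @seealso [regexSet()]
#' @exportClass RegexSet
setClass("RegexSet", slots = c(patterns = "character"))

setValidity("RegexSet", function(object) {
  p <- object@patterns
  if (length(p) == 0L) return("regex set must be non-empty")
  for (pat in p) {
    ok <- tryCatch({ regexpr(pat, "ACGT", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(sprintf("pattern '%s' does not compile", pat))
  }
  TRUE
})

#' PwmMotif: a position weight matrix motif
#'
#' Per-position nucleotide probabilities for a motif of length L, stored
#' as a 4 x L matrix with rows A, C, G, T. JASPAR count matrices are
#' column-normalized to probabilities on load.
#'
#' @slot motifId character(1) motif identifier (e.g. a JASPAR accession).
#' @slot name character(1) motif name.
#' @slot probs numeric 4 x L matrix, rownames `c("A","C","G","T")`,
#'   columns summing to 1.
#' @seealso [parseJaspar()], [pwmLogOdds()]
#' @exportClass PwmMotif
setClass("PwmMotif",
  slots = c(motifId = "character", name = "character", probs = "matrix")
)

setValidity("PwmMotif", function(object) {
  m <- object@probs
  if (!identical(rownames(m), .DNA_BASES))
    return("probs must have rownames A, C, G, T in that order")
  if (ncol(m) < 1L) return("motif length must be >= 1")
  if (any(m < 0)) return("probabilities must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    return("probability columns must sum to 1")
  TRUE
})

#' LogOddsMatrix: a PWM converted to log-odds scores against a background
#'
#' Cell (b, i) holds `log2(p[b, i] / bg[b])` after pseudocount
#' regularization of the probabilities. The reverse-complement score
#' matrix (reversed positions, complemented rows, same background) is
#' kept alongside so both strands can be scanned against one calibrated
#' threshold.
#'
#' @slot motifId character(1) identifier carried from the source PWM.
#' @slot scores numeric 4 x L log-odds matrix (bits), rows A, C, G, T.
#' @slot rcScores numeric 4 x L log-odds matrix of the reverse-complement
#'   motif against the same background.
#' @slot background numeric(4) background probabilities for A, C, G, T.
#' @slot minScore,maxScore numeric(1): sums over positions of the
#'   column-wise minima / maxima of `scores`.
#' @seealso [pwmLogOdds()], [calibrateThreshold()], [scanPwm()]
#' @exportClass LogOddsMatrix
setClass("LogOddsMatrix",
  slots = c(motifId = "character", scores = "matrix", rcScores = "matrix",
            background = "numeric", minScore = "numeric", maxScore = "numeric")
)

setValidity("LogOddsMatrix", function(object) {
  if (!identical(rownames(object@scores), .DNA_BASES))
    return("scores must have rownames A, C, G, T")
  if (!identical(dim(object@scores), dim(object@rcScores)))
    return("scores and rcScores must have identical dimensions")
  # all.equal rather than a plain difference: min/max may be -Inf when a
  # probability cell is exactly zero and no pseudocount was applied
  if (!isTRUE(all.equal(object@maxScore, sum(apply(object@scores, 2, max)))))
    return("maxScore must equal the sum of column maxima")
  if (!isTRUE(all.equal(object@minScore, sum(apply(object@scores, 2, min)))))
    return("minScore must equal the sum of column minima")
  TRUE
})

#' CalibratedThreshold: a Monte-Carlo calibrated PWM score cutoff
#'
#' The score threshold whose exceedance probability under the background
#' model is the target p-value, estimated as the empirical (1 - p)
#' quantile of the scores of random background sequences. The sorted
#' calibration sample is retained so each hit can be assigned an
#' empirical p-value (tail fraction of the sample at or above its score).
#'
#' @slot threshold numeric(1) score cutoff in the same units as the
#'   log-odds matrix (bits).
#' @slot pValue numeric(1) target p-value in (0, 1].
#' @slot nSamples integer(1) Monte-Carlo sample size.
#' @slot seed integer(1) RNG seed used for the calibration draw.
#' @slot sampleScores numeric vector of the calibration scores, sorted
#'   ascending.
#' @seealso [calibrateThreshold()]
#' @exportClass CalibratedThreshold
setClass("CalibratedThreshold",
  slots = c(threshold = "numeric", pValue = "numeric", nSamples = "integer",
            seed = "integer", sampleScores = "numeric")
)

setValidity("CalibratedThreshold", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  if (is.unsorted(object@sampleScores))
    return("sampleScores must be sorted ascending")
  TRUE
})

#' MotifScanResult: hits and conservation records from one scan run
#'
#' @slot hits data.frame with one row per motif instance (see
#'   [mafMotifScan()] for the column dictionary).
#' @slot conservation data.frame with one row per hit x compared genome,
#'   carrying the similarity vector, the conservation percentage, and
#'   the block-level average.
#' @slot summary list of run-level statistics (hit counts per motif,
#'   mean conservation).
#' @seealso [mafMotifScan()], [writeHitsJson()], [writeHitsCsv()]
#' @exportClass MotifScanResult
setClass("MotifScanResult",
  slots = c(hits = "data.frame", conservation = "data.frame",
            summary = "list")
)
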