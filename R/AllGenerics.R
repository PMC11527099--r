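#' @importFrom Biostrings reverseComplement DNAString DNAStringSet
NULL

#' Accessors for MafBlock objects
#'
#' @param x a [MafBlock][MafBlock-class] object.
#' @return `mafScore()` the numeric `a`-line score (`NA` if absent);
#'   `mafRecords()` the [S4Vectors::DataFrame] of sequence records;
#'   `blockIndex()` the 0-based block ordinal.
#' @examples
#' blk <- mafBlockFromTexts(c("A-TCG", "A-TCG"))
#' mafRecords(blk)$src
#' blockIndex(blk)
#' @name MafBlock-accessors
#' @export
setGeneric("mafScore", function(x) standardGeneric("mafScore"))

#' @rdname MafBlock-accessors
#' @export
setGeneric("mafRecords", function(x) standardGeneric("mafRecords"))

#' @rdname MafBlock-accessors
#' @export
setGeneric("blockIndex", function(x) standardGeneric("blockIndex"))

#' @rdname MafBlock-accessors
setMethod("mafScore", "MafBlock", function(x) x@score)

#' @rdname MafBlock-accessors
setMethod("mafRecords", "MafBlock", function(x) x@records)

#' @rdname MafBlock-accessors
setMethod("blockIndex", "MafBlock", function(x) x@blockIndex)

#' Accessors for GapIndexMap objects
#'
#' @param x a [GapIndexMap][GapIndexMap-class] object.
#' @return `ungappedToGapped()`: integer vector mapping 0-based ungapped
#'   offsets to 0-based gapped column indices; `gappedToUngapped()`:
#'   integer vector mapping columns back to offsets (`NA` at gap columns).
#' @examples
#' gm <- buildGapMap("A-TCG")
#' ungappedToGapped(gm)   # 0 2 3 4
#' @name GapIndexMap-accessors
#' @export
setGeneric("ungappedToGapped", function(x) standardGeneric("ungappedToGapped"))

#' @rdname GapIndexMap-accessors
#' @export
setGeneric("gappedToUngapped", function(x) standardGeneric("gappedToUngapped"))

#' @rdname GapIndexMap-accessors
setMethod("ungappedToGapped", "GapIndexMap", function(x) x@ungappedToGapped)

#' @rdname GapIndexMap-accessors
setMethod("gappedToUngapped", "GapIndexMap", function(x) x@gappedToUngapped)

#' Accessors for motif objects
#'
#' @param x a [KmerSet][KmerSet-class], [RegexSet][RegexSet-class],
#'   [PwmMotif][PwmMotif-class] or
#'   [CalibratedThreshold][CalibratedThreshold-class] object.
#' @return `kmers()` the character vector of k-mers; `patterns()` the
#'   regular expressions; `motifId()` the motif identifier; `probs()` the
#'   4 x L probability matrix; `threshold()` the calibrated score cutoff.
#' @name motif-accessors
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))

#' @rdname motif-accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname motif-accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @rdname motif-accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname motif-accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname motif-accessors
setMethod("kmers", "KmerSet", function(x) x@kmers)

#' @rdname motif-accessors
setMethod("patterns", "RegexSet", function(x) x@patterns)

#' @rdname motif-accessors
setMethod("motifId", "PwmMotif", function(x) x@motifId)

#' @rdname motif-accessors
setMethod("motifId", "LogOddsMatrix", function(x) x@motifId)

#' @rdname motif-accessors
setMethod("probs", "PwmMotif", function(x) x@probs)

#' @rdname motif-accessors
setMethod("threshold", "CalibratedThreshold", function(x) x@threshold)

#' Accessors for MotifScanResult objects
#'
#' @param x a [MotifScanResult][MotifScanResult-class] object.
#' @return `scanHits()` the per-instance hit table; `conservationTable()`
#'   the long table of per-hit, per-compared-genome conservation records;
#'   `scanSummary()` the run-level summary list.
#' @name MotifScanResult-accessors
#' @export
setGeneric("scanHits", function(x) standardGeneric("scanHits"))

#' @rdname MotifScanResult-accessors
#' @export
setGeneric("conservationTable",
           function(x) standardGeneric("conservationTable"))

#' @rdname MotifScanResult-accessors
#' @export
setGeneric("scanSummary", function(x) standardGeneric("scanSummary"))

#' @rdname MotifScanResult-accessors
setMethod("scanHits", "MotifScanResult", function(x) x@hits)

#' @rdname MotifScanResult-accessors
setMethod("conservationTable", "MotifScanResult", function(x) x@conservation)

#' @rdname MotifScanResult-accessors
setMethod("scanSummary", "MotifScanResult", function(x) x@summary)

setMethod("show", "MafBlock", function(object) {
  rec <- object@records
  cat(sprintf("MafBlock #%d: %d records, %d columns, score %s\n",
              object@blockIndex, nrow(rec), nchar(rec$text[1]),
              format(object@score)))
  for (i in seq_len(min(nrow(rec), 6L))) {
    cat(sprintf("  s %-20s %8d %5d %s %9d %s\n", rec$src[i], rec$start[i],
                rec$size[i], rec$strand[i], rec$srcSize[i],
                if (nchar(rec$text[i]) > 40)
                  paste0(substr(rec$text[i], 1, 37), "...")
                else rec$text[i]))
  }
  if (nrow(rec) > 6L) cat(sprintf("  ... and %d more records\n", nrow(rec) - 6L))
})

setMethod("show", "PwmMotif", function(object) {
  cat(sprintf("PwmMotif %s (%s), length %d\n", object@motifId, object@name,
              ncol(object@probs)))
  print(round(object@probs, 3))
})

setMethod("show", "CalibratedThreshold", function(object) {
  cat(sprintf(
    "CalibratedThreshold: %.4f bits at p = %g (%d samples, seed %d)\n",
    object@threshold, object@pValue, object@nSamples, object@seed))
})

setMethod("show", "MotifScanResult", function(object) {
  cat(sprintf("MotifScanResult: %d hits, %d conservation records\n",
              nrow(object@hits), nrow(object@conservation)))
  s <- object@summary
  if (!is.null(s$meanConservation) && !is.na(s$meanConservation))
    cat(sprintf("  mean block-average conservation: %.2f%%\n",
                s$meanConservation))
  if (!is.null(s$hitsPerMotif) && length(s$hitsPerMotif)) {
    cat("  hits per motif:\n")
    for (m in names(s$hitsPerMotif))
      cat(sprintf("    %s: %d\n", m, s$hitsPerMotif[[m]]))
  }
})
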