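#' Gap-aware similarity vector between two aligned spans
#'
#' Walks the aligned columns of the hit's span in the searched
#' (reference) row and a compared row, and emits one binary entry per
#' scored column: 1 when the two characters are identical (and neither
#' is `N`), 0 otherwise. Columns gapped in *both* rows are skipped.
#'
#' Two column rules are provided:
#' \describe{
#'   \item{`"truncating"` (default)}{every column that is not a
#'     double-gap is scored — including columns where only one row has a
#'     gap — and the emitted entries are then truncated to the first
#'     `motifLen` values. This reproduces the worked perfect-match and
#'     mismatch-with-gaps examples bit-exactly (e.g. `A-TCG` vs `AT-CG`
#'     gives `[1,0,0,1]`, 50\%).}
#'   \item{`"refbase"`}{only columns where the reference row has a base
#'     are scored, so entry i corresponds to motif base i (`A-TCG` vs
#'     `AT-CG` gives `[1,0,1,1]`, 75\%).}
#' }
#'
#' @param refSpan gapped column slice of the searched row covering the
#'   hit (must contain exactly `motifLen` non-gap characters).
#' @param cmpSpan equal-length column slice of the compared row.
#' @param motifLen ungapped motif length.
#' @param mode `"truncating"` or `"refbase"`.
#' @return integer vector of 0/1 of length `motifLen`.
#' @examples
#' similarityVector("A-TCG", "A-TCG", 4)  # 1 1 1 1
#' similarityVector("A-TCG", "AT-CG", 4)  # 1 0 0 1
#' similarityVector("A-TCG", "AT-CG", 4, mode = "refbase")  # 1 0 1 1
#' @export
similarityVector <- function(refSpan, cmpSpan, motifLen,
                             mode = c("truncating", "refbase")) {
  mode <- match.arg(mode)
  if (nchar(refSpan) != nchar(cmpSpan))
    stop("refSpan and cmpSpan must be equal-length column slices",
         call. = FALSE)
  rc <- strsplit(toupper(refSpan), "", fixed = TRUE)[[1]]
  cc <- strsplit(toupper(cmpSpan), "", fixed = TRUE)[[1]]
  nRefBases <- sum(rc != "-")
  if (nRefBases != motifLen)
    stop(sprintf("refSpan has %d non-gap characters, expected motifLen = %d",
                 nRefBases, motifLen), call. = FALSE)
  if (mode == "truncating") {
    keep <- !(rc == "-" & cc == "-")
  } else {
    keep <- rc != "-"
  }
  r <- rc[keep]; c <- cc[keep]
  bits <- as.integer(r == c & r != "-" & r != "N" & c != "N")
  bits[seq_len(motifLen)]
}

#' Conservation percentage of a similarity vector
#'
#' @param bits integer/logical vector of 0/1 similarity entries.
#' @return `100 * sum(bits) / length(bits)`; an empty vector returns 0
#'   with a warning.
#' @examples
#' conservationPercent(c(1, 0, 0, 1))  # 50
#' @export
conservationPercent <- function(bits) {
  if (!length(bits)) {
    warning("empty similarity vector; conservation undefined, returning 0")
    return(0)
  }
  100 * sum(bits) / length(bits)
}

#' Block-level average conservation of one motif instance
#'
#' @param pcts numeric vector of per-compared-genome conservation
#'   percentages for a hit.
#' @return their unweighted arithmetic mean; `NA` with a warning when no
#'   genome was compared.
#' @examples
#' blockConservation(c(100, 50))  # 75
#' @export
blockConservation <- function(pcts) {
  if (!length(pcts)) {
    warning("no compared genomes in block; block average undefined")
    return(NA_real_)
  }
  mean(pcts)
}

#' Score the conservation of hits against the other rows of their block
#'
#' For each hit, slices the searched row's gapped span
#' `[gappedStart, gappedEnd]` out of every other record of the block and
#' computes the similarity vector and conservation percentage against
#' each, plus the per-hit block average.
#'
#' @param block a [MafBlock][MafBlock-class].
#' @param hits hit data.frame with `gappedStart`/`gappedEnd` columns (see
#'   [mapHitToAlignment()]).
#' @param searchedRow 1-based index of the record the hits were found in.
#' @param genomeIds optional character vector of genome identifiers (the
#'   `src` prefix before the first `.`); when given, only matching rows
#'   are compared. Unmatched identifiers trigger a warning.
#' @param mode conservation column rule (see [similarityVector()]).
#' @param dropAllGapRows when `TRUE`, compared rows whose slice is
#'   entirely gaps are omitted instead of contributing an all-zero
#'   vector (default `FALSE`; silence would bias block averages upward).
#' @return data.frame, one row per hit x compared genome: the hit
#'   columns plus `comparedSrc`, `similarityVector` (e.g. `"1001"`),
#'   `conservationPct` and `blockAvgPct`.
#' @examples
#' blk <- mafBlockFromTexts(c("A-TCG", "AT-CG"), starts = c(1000, 0))
#' h <- mapHitToAlignment(scanKmers("ATCG", kmerSet("ATCG")),
#'                        buildGapMap("A-TCG"))
#' scoreConservation(blk, h)[, c("comparedSrc", "similarityVector",
#'                               "conservationPct")]
#' @export
scoreConservation <- function(block, hits, searchedRow = 1L,
                              genomeIds = NULL,
                              mode = c("truncating", "refbase"),
                              dropAllGapRows = FALSE) {
  mode <- match.arg(mode)
  rec <- mafRecords(block)
  cmpRows <- setdiff(seq_len(nrow(rec)), searchedRow)
  if (!is.null(genomeIds)) {
    genome <- sub("\\..*$", "", rec$src)
    unmatched <- setdiff(genomeIds, genome)
    if (length(unmatched))
      warning(sprintf("genome IDs not present in block %d: %s",
                      blockIndex(block), paste(unmatched, collapse = ", ")))
    cmpRows <- cmpRows[genome[cmpRows] %in% genomeIds]
  }
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    refSpan <- substring(rec$text[searchedRow], h$gappedStart + 1L,
                         h$gappedEnd + 1L)
    motifLen <- h$end - h$start + 1L
    vecs <- character(0); pcts <- numeric(0); srcs <- character(0)
    for (j in cmpRows) {
      cmpSpan <- substring(rec$text[j], h$gappedStart + 1L,
                           h$gappedEnd + 1L)
      if (dropAllGapRows && !grepl("[^-]", cmpSpan)) next
      bits <- similarityVector(refSpan, cmpSpan, motifLen, mode = mode)
      srcs <- c(srcs, rec$src[j])
      vecs <- c(vecs, paste(bits, collapse = ""))
      pcts <- c(pcts, conservationPercent(bits))
    }
    avg <- if (length(pcts)) mean(pcts) else {
      warning(sprintf("hit %s at %d: no compared genomes in block %d",
                      h$motifId, h$start, blockIndex(block)))
      NA_real_
    }
    n <- max(length(srcs), 1L)
    rowRep <- h[rep(1L, n), , drop = FALSE]
    rowRep$comparedSrc <- if (length(srcs)) srcs else NA_character_
    rowRep$similarityVector <- if (length(vecs)) vecs else NA_character_
    rowRep$conservationPct <- if (length(pcts)) pcts else NA_real_
    rowRep$blockAvgPct <- avg
    out[[length(out) + 1L]] <- rowRep
  }
  if (!length(out)) {
    e <- hits[0, , drop = FALSE]
    e$comparedSrc <- character(0)
    e$similarityVector <- character(0)
    e$conservationPct <- numeric(0)
    e$blockAvgPct <- numeric(0)
    return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
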