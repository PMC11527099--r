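#' Scan a MAF file for motifs and score their conservation
#'
#' The end-to-end pipeline: parses the MAF file in block-aligned chunks
#' distributed over `processes` workers, locates motif instances in the
#' target row(s) of every block with the engine matching the motif
#' source (Aho-Corasick automaton for k-mers, overlapping regex search,
#' or calibrated PWM scanning), maps each hit to source coordinates and
#' gapped alignment columns, and computes per-compared-genome similarity
#' vectors, conservation percentages and block averages. Results are
#' merged in a deterministic order (`blockIndex`, `sourceStart`,
#' `motifId`), so output is identical for any number of processes.
#'
#' Exactly one of `kmerFile`/`kmers`, `jasparFile`/`pwms`, `regexes`
#' must be supplied.
#'
#' Hit table columns: `motifId`, `motifType` (`kmer`/`regex`/`pwm`),
#' `src`, `sourceStart`/`sourceEnd` (inclusive, in the strand-relative
#' frame of the MAF `start` field), `strand` (strand searched),
#' `matchedSeq` (forward-frame matched text), `ungappedStart`/
#' `ungappedEnd` (0-based row offsets), `gappedStart`/`gappedEnd`
#' (0-based block columns), `blockIndex`, and for PWM hits `score`,
#' `pValue` and the Benjamini-Hochberg `qValue` across all PWM hits of
#' the run.
#'
#' @param mafFile path to the MAF file.
#' @param kmerFile,kmers path to a k-mer list file, or a character
#'   vector / [KmerSet][KmerSet-class] of k-mers.
#' @param jasparFile,pwms path to a JASPAR PWM file, or a list of
#'   [PwmMotif][PwmMotif-class] objects.
#' @param regexes comma-separated string, character vector or
#'   [RegexSet][RegexSet-class] of regular expressions.
#' @param searchIn `"reference"` (row 1 of each block, the default) or a
#'   genome identifier: every row whose `src` prefix before the first
#'   `.` equals it is searched.
#' @param genomeIds optional character vector (or path to a file, one ID
#'   per line) restricting which genomes are compared for conservation.
#' @param reverseComplement also search the reverse strand
#'   (default `FALSE`).
#' @param processes number of worker processes (>= 1).
#' @param pValue PWM threshold p-value (default 1e-4).
#' @param backgroundFrequencies numeric(4) background frequencies for
#'   A, C, G, T (default uniform).
#' @param nSamples Monte-Carlo sample size for PWM calibration.
#' @param seed RNG seed for PWM calibration.
#' @param conservationMode column rule for similarity vectors (see
#'   [similarityVector()]).
#' @param dropAllGapRows omit all-gap compared slices instead of scoring
#'   them as all-zero vectors.
#' @param outputPrefix when given, writes `<prefix>.json` and
#'   `<prefix>.csv` (see [writeHitsJson()], [writeHitsCsv()]).
#' @return a [MotifScanResult][MotifScanResult-class].
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(formatMaf(mafBlockFromTexts(c("A-TCG", "A-TCG"),
#'                                        starts = c(1000, 0))), maf)
#' res <- mafMotifScan(maf, kmers = "ATCG")
#' scanHits(res)[, c("src", "sourceStart", "sourceEnd")]
#' @export
mafMotifScan <- function(mafFile,
                         kmerFile = NULL, kmers = NULL,
                         jasparFile = NULL, pwms = NULL,
                         regexes = NULL,
                         searchIn = "reference",
                         genomeIds = NULL,
                         reverseComplement = FALSE,
                         processes = 1L,
                         pValue = 1e-4,
                         backgroundFrequencies = NULL,
                         nSamples = 1e5,
                         seed = 42L,
                         conservationMode = c("truncating", "refbase"),
                         dropAllGapRows = FALSE,
                         outputPrefix = NULL) {
  conservationMode <- match.arg(conservationMode)
  nSources <- (!is.null(kmerFile) || !is.null(kmers)) +
    (!is.null(jasparFile) || !is.null(pwms)) + (!is.null(regexes))
  if (nSources != 1L)
    stop("exactly one motif source (k-mers, JASPAR PWMs, or regexes) ",
         "must be supplied", call. = FALSE)
  if (processes < 1L) stop("processes must be >= 1", call. = FALSE)
  if (!file.exists(mafFile))
    stop(sprintf("MAF file not found: %s", mafFile), call. = FALSE)
  if (is.character(genomeIds) && length(genomeIds) == 1L &&
      file.exists(genomeIds))
    genomeIds <- trimws(readLines(genomeIds, warn = FALSE))
  if (!is.null(genomeIds)) genomeIds <- genomeIds[nzchar(genomeIds)]

  motifs <- .prepareMotifs(kmerFile, kmers, jasparFile, pwms, regexes,
                           backgroundFrequencies, pValue, nSamples, seed)

  chunks <- chunkBlocks(mafFile, processes)
  worker <- function(i) {
    blocks <- readMafChunk(mafFile, chunks[i, ])
    res <- lapply(blocks, .scanBlock, motifs = motifs, searchIn = searchIn,
                  reverseComplement = reverseComplement,
                  genomeIds = genomeIds, mode = conservationMode,
                  dropAllGapRows = dropAllGapRows)
    do.call(rbind, res)
  }
  parts <- if (nrow(chunks) == 0L) {
    list()
  } else if (processes > 1L) {
    parallel::mclapply(seq_len(nrow(chunks)), worker,
                       mc.cores = processes, mc.preschedule = FALSE)
  } else {
    lapply(seq_len(nrow(chunks)), worker)
  }
  err <- vapply(parts, function(p) inherits(p, "try-error"), TRUE)
  if (any(err)) stop("worker failed: ", parts[[which(err)[1]]])
  cons <- if (length(parts)) do.call(rbind, parts) else NULL
  if (is.null(cons) || !nrow(cons)) cons <- .emptyConservation()
  cons <- cons[order(cons$blockIndex, cons$sourceStart, cons$motifId,
                     cons$strand, cons$comparedSrc), , drop = FALSE]
  rownames(cons) <- NULL

  hits <- .dedupeHits(cons)
  hits <- .addQValues(hits)
  if (nrow(hits)) {
    key <- paste(cons$blockIndex, cons$motifId, cons$sourceStart,
                 cons$strand, cons$src)
    hkey <- paste(hits$blockIndex, hits$motifId, hits$sourceStart,
                  hits$strand, hits$src)
    cons$qValue <- hits$qValue[match(key, hkey)]
  } else {
    cons$qValue <- numeric(0)
  }

  summ <- list(
    nHits = nrow(hits),
    hitsPerMotif = as.list(table(hits$motifId)),
    meanConservation = if (nrow(hits)) mean(hits$blockAvgPct, na.rm = TRUE)
                       else NA_real_)
  message(sprintf("scanned %d chunk(s): %d hit(s), mean block conservation %s",
                  max(nrow(chunks), 1L), summ$nHits,
                  ifelse(is.na(summ$meanConservation), "NA",
                         sprintf("%.2f%%", summ$meanConservation))))
  res <- new("MotifScanResult", hits = hits, conservation = cons,
             summary = summ)
  if (!is.null(outputPrefix)) {
    writeHitsJson(res, paste0(outputPrefix, ".json"))
    writeHitsCsv(res, paste0(outputPrefix, ".csv"))
  }
  res
}

# resolve the motif source into a single engine descriptor
.prepareMotifs <- function(kmerFile, kmers, jasparFile, pwms, regexes,
                           background, pValue, nSamples, seed) {
  if (!is.null(kmerFile) || !is.null(kmers)) {
    ks <- if (!is.null(kmerFile)) loadKmers(kmerFile)
          else if (is(kmers, "KmerSet")) kmers else kmerSet(kmers)
    return(list(type = "kmer", kmerSet = ks))
  }
  if (!is.null(regexes)) {
    rs <- if (is(regexes, "RegexSet")) regexes else regexSet(regexes)
    return(list(type = "regex", regexSet = rs))
  }
  pw <- if (!is.null(jasparFile)) parseJaspar(jasparFile) else pwms
  if (is(pw, "PwmMotif")) pw <- list(pw)
  bg <- if (is.null(background)) rep(0.25, 4) else background
  engines <- lapply(pw, function(p) {
    lo <- pwmLogOdds(p, background = bg)
    list(logodds = lo,
         calib = calibrateThreshold(lo, pValue = pValue,
                                    nSamples = nSamples, seed = seed))
  })
  list(type = "pwm", engines = engines)
}

# scan one block's target rows and score conservation
.scanBlock <- function(block, motifs, searchIn, reverseComplement,
                       genomeIds, mode, dropAllGapRows) {
  rec <- mafRecords(block)
  rows <- if (identical(searchIn, "reference")) 1L else
    which(sub("\\..*$", "", rec$src) == searchIn)
  out <- list()
  for (r in rows) {
    seq <- .ungappedText(rec$text[r])
    hits <- switch(motifs$type,
      kmer = scanKmers(seq, motifs$kmerSet, includeRevComp = reverseComplement),
      regex = scanRegex(seq, motifs$regexSet,
                        includeRevComp = reverseComplement),
      pwm = {
        hs <- lapply(motifs$engines, function(e)
          scanPwm(seq, e$logodds, e$calib,
                  includeRevComp = reverseComplement))
        hs <- do.call(rbind, hs)
        if (is.null(hs) || !nrow(hs)) .emptyHits() else .orderHits(hs)
      })
    if (!nrow(hits)) next
    hits <- mapHitToAlignment(hits, buildGapMap(rec$text[r]))
    hits$sourceStart <- rec$start[r] + hits$start
    hits$sourceEnd <- rec$start[r] + hits$end
    hits$src <- rec$src[r]
    hits$blockIndex <- blockIndex(block)
    cons <- scoreConservation(
      block, hits, searchedRow = r, genomeIds = genomeIds, mode = mode,
      dropAllGapRows = dropAllGapRows)
    names(cons)[names(cons) == "start"] <- "ungappedStart"
    names(cons)[names(cons) == "end"] <- "ungappedEnd"
    out[[length(out) + 1L]] <- cons
  }
  if (!length(out)) return(.emptyConservation())
  do.call(rbind, out)
}

.emptyConservation <- function() {
  h <- .emptyHits()
  names(h)[names(h) == "start"] <- "ungappedStart"
  names(h)[names(h) == "end"] <- "ungappedEnd"
  h$gappedStart <- integer(0)
  h$gappedEnd <- integer(0)
  h$sourceStart <- numeric(0)
  h$sourceEnd <- numeric(0)
  h$src <- character(0)
  h$blockIndex <- integer(0)
  h$comparedSrc <- character(0)
  h$similarityVector <- character(0)
  h$conservationPct <- numeric(0)
  h$blockAvgPct <- numeric(0)
  h
}

# one row per hit (collapsing the per-compared-genome long table)
.dedupeHits <- function(cons) {
  key <- paste(cons$blockIndex, cons$motifId, cons$sourceStart,
               cons$strand, cons$src)
  hits <- cons[!duplicated(key),
               setdiff(colnames(cons),
                       c("comparedSrc", "similarityVector",
                         "conservationPct")),
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Benjamini-Hochberg q-values over all PWM hits of the run
.addQValues <- function(hits) {
  hits$qValue <- rep(NA_real_, nrow(hits))
  isPwm <- which(hits$motifType == "pwm" & !is.na(hits$pValue))
  if (length(isPwm))
    hits$qValue[isPwm] <- stats::p.adjust(hits$pValue[isPwm], method = "BH")
  hits
}

#' Write a motif scan result as a JSON report
#'
#' One top-level JSON object keyed by hit identifier
#' `"<src>:<start>-<end>:<motifId>:<strand>"`. Each value records the
#' source genome and chromosome (the `src` split at its first `.`),
#' inclusive source coordinates, strand, motif type/length/sequence,
#' 0-based gapped and ungapped block-relative spans, per-compared-genome
#' similarity vectors and conservation percentages, the block average,
#' and for PWM hits the score, empirical p-value and BH q-value.
#'
#' @param result a [MotifScanResult][MotifScanResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHitsJson <- function(result, path) {
  hits <- scanHits(result)
  cons <- conservationTable(result)
  recs <- list()
  hkey <- paste(hits$blockIndex, hits$motifId, hits$sourceStart,
                hits$strand, hits$src)
  ckey <- paste(cons$blockIndex, cons$motifId, cons$sourceStart,
                cons$strand, cons$src)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    cv <- cons[ckey == hkey[i] & !is.na(cons$comparedSrc), , drop = FALSE]
    conserv <- list()
    for (j in seq_len(nrow(cv))) {
      conserv[[cv$comparedSrc[j]]] <- list(
        similarity_vector = as.integer(strsplit(cv$similarityVector[j],
                                                "")[[1]]),
        conservation_pct = cv$conservationPct[j])
    }
    dot <- regexpr(".", h$src, fixed = TRUE)
    rec <- list(
      source_name = if (dot > 0) substr(h$src, 1, dot - 1) else h$src,
      chromosome = if (dot > 0) substring(h$src, dot + 1) else NA,
      start = h$sourceStart, end = h$sourceEnd, strand = h$strand,
      motif_type = h$motifType, motif_id = h$motifId,
      motif_length = h$ungappedEnd - h$ungappedStart + 1L,
      motif_sequence = h$matchedSeq,
      block_index = h$blockIndex,
      ungapped_start = h$ungappedStart, ungapped_end = h$ungappedEnd,
      gapped_start = h$gappedStart, gapped_end = h$gappedEnd,
      conservation = conserv,
      block_avg_pct = h$blockAvgPct)
    if (identical(h$motifType, "pwm")) {
      rec$score <- h$score
      rec$p_value <- h$pValue
      rec$q_value <- h$qValue
    }
    key <- sprintf("%s:%.0f-%.0f:%s:%s", h$src, h$sourceStart, h$sourceEnd,
                   h$motifId, h$strand)
    recs[[key]] <- rec
  }
  if (!length(recs)) recs <- stats::setNames(list(), character(0))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Write a motif scan result as a CSV report
#'
#' RFC-4180 CSV with a header row and one row per hit x compared genome.
#' Columns: `block_index`, `motif_id`, `motif_type`, `src`, `start`,
#' `end`, `strand`, `matched_seq`, `compared_src`, `similarity_vector`
#' (e.g. `"1001"`), `conservation_pct`, `block_avg_pct`, `score`,
#' `p_value`, `q_value` (the last three empty for non-PWM hits).
#'
#' @param result a [MotifScanResult][MotifScanResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHitsCsv <- function(result, path) {
  cons <- conservationTable(result)
  df <- data.frame(
    block_index = cons$blockIndex, motif_id = cons$motifId,
    motif_type = cons$motifType, src = cons$src,
    start = cons$sourceStart, end = cons$sourceEnd,
    strand = cons$strand, matched_seq = cons$matchedSeq,
    compared_src = cons$comparedSrc,
    similarity_vector = cons$similarityVector,
    conservation_pct = cons$conservationPct,
    block_avg_pct = cons$blockAvgPct,
    score = cons$score, p_value = cons$pValue, q_value = cons$qValue,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
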