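#' Parse a MAF file into alignment blocks
#'
#' Reads Multiple Alignment Format text (UCSC dialect: an `a` line with an
#' optional `score=` field, followed by `s` lines of the form
#' `s src start size strand srcSize text`). Files produced by `hal2maf`
#' (blank-line separated blocks, optional `##maf version=1` header) are
#' accepted. `i`, `e` and `q` lines are tolerated and skipped; comment
#' (`#`) and blank lines are ignored. Sequence text is uppercased on load.
#'
#' @param file path to a MAF file, or a connection.
#' @param text optional character scalar/vector of MAF text, used instead
#'   of `file`.
#' @param firstBlockIndex 0-based index assigned to the first block parsed
#'   (used when parsing a chunk of a larger file).
#' @return a list of [MafBlock][MafBlock-class] objects in file order.
#' @examples
#' maf <- c("##maf version=1", "a score=0",
#'          "s hg38.chr1 1000 4 + 248956422 A-TCG",
#'          "s mm39.chr4 2000 4 + 156860686 A-TCG")
#' blocks <- parseMaf(text = maf)
#' mafRecords(blocks[[1]])$text
#' @export
parseMaf <- function(file, text = NULL, firstBlockIndex = 0L) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    readLines(file, warn = FALSE)
  }
  blocks <- list()
  curScore <- NA_real_
  cur <- list()   # list of s-line record lists
  inBlock <- FALSE
  idx <- firstBlockIndex

  flush <- function() {
    if (!length(cur)) return(invisible())
    rec <- DataFrame(
      src = vapply(cur, `[[`, "", "src"),
      start = vapply(cur, `[[`, 0, "start"),
      size = vapply(cur, `[[`, 0, "size"),
      strand = vapply(cur, `[[`, "", "strand"),
      srcSize = vapply(cur, `[[`, 0, "srcSize"),
      text = vapply(cur, `[[`, "", "text")
    )
    blk <- tryCatch(
      new("MafBlock", score = curScore, records = rec, blockIndex = idx),
      error = function(e) stop(sprintf("structural error in block %d: %s",
                                       idx, conditionMessage(e)), call. = FALSE)
    )
    blocks[[length(blocks) + 1L]] <<- blk
    idx <<- idx + 1L
    cur <<- list()
    curScore <<- NA_real_
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) { flush(); inBlock <- FALSE; next }
    first <- substr(trimws(line), 1L, 1L)
    if (first == "#") next
    if (first == "a") {
      flush()
      inBlock <- TRUE
      m <- regmatches(line, regexec("score=([-0-9.eE+]+)", line))[[1]]
      curScore <- if (length(m) == 2L) as.numeric(m[2]) else NA_real_
      next
    }
    if (first == "s") {
      fields <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(fields) != 7L)
        stop(sprintf("line %d: malformed 's' line (%d fields, expected 7)",
                     ln, length(fields)), call. = FALSE)
      nums <- suppressWarnings(as.numeric(fields[c(3, 4, 6)]))
      if (anyNA(nums) || any(nums != floor(nums)))
        stop(sprintf("line %d: non-integer start/size/srcSize in 's' line",
                     ln), call. = FALSE)
      if (!fields[5] %in% c("+", "-"))
        stop(sprintf("line %d: strand must be '+' or '-'", ln), call. = FALSE)
      cur[[length(cur) + 1L]] <- list(
        src = fields[2], start = nums[1], size = nums[2],
        strand = fields[5], srcSize = nums[3], text = toupper(fields[7])
      )
      inBlock <- TRUE
      next
    }
    if (first %in% c("i", "e", "q")) {
      if (isTRUE(getOption("mafconserve.verbose")))
        message(sprintf("skipping '%s' line %d", first, ln))
      next
    }
    # unknown line types are tolerated and skipped
  }
  flush()
  blocks
}

#' Build the gapped/ungapped coordinate map of one alignment row
#'
#' @param text gapped sequence string over \{A,C,G,T,N,-\} (case
#'   insensitive).
#' @return a [GapIndexMap][GapIndexMap-class]; all offsets and column
#'   indices are 0-based, matching the MAF `start` convention.
#' @examples
#' ungappedToGapped(buildGapMap("A-TCG"))  # 0 2 3 4
#' @export
buildGapMap <- function(text) {
  ch <- strsplit(toupper(text), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% .MAF_ALPHABET)
  if (any(bad))
    stop(sprintf("illegal character '%s' at column %d", ch[bad][1],
                 which(bad)[1]), call. = FALSE)
  nonGap <- which(ch != "-")
  g2u <- rep(NA_integer_, length(ch))
  g2u[nonGap] <- seq_along(nonGap) - 1L
  new("GapIndexMap",
      ungappedToGapped = as.integer(nonGap - 1L),
      gappedToUngapped = g2u)
}

#' Map an ungapped motif span to source-sequence coordinates
#'
#' Converts a 0-based ungapped offset/length within a record to the
#' inclusive source coordinate range `[start + offset,
#' start + offset + length - 1]`, in the same strand-relative frame as
#' the record's MAF `start` field.
#'
#' @param record one row of a block's record table (any list-like with
#'   `start` and `size` fields), or a [MafBlock][MafBlock-class] together
#'   with `row`.
#' @param offset 0-based ungapped offset of the first motif base.
#' @param length motif length in bases (>= 1).
#' @param row when `record` is a MafBlock: 1-based record row to use.
#' @return numeric(2): inclusive `(start, end)` source coordinates.
#' @examples
#' blk <- mafBlockFromTexts(c("A-TCG", "A-TCG"), starts = c(1000, 0))
#' ungappedToSource(blk, offset = 0, length = 4)  # 1000 1003
#' @export
ungappedToSource <- function(record, offset, length, row = 1L) {
  if (is(record, "MafBlock")) record <- as.list(mafRecords(record)[row, ])
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (offset < 0L || offset + length > record$size)
    stop(sprintf("offset %d + length %d out of range for record of size %d",
                 offset, length, record$size), call. = FALSE)
  start <- record$start + offset
  c(start = start, end = start + length - 1)
}

#' Partition a MAF file into block-aligned byte-range chunks
#'
#' Splits a MAF file into at most `nChunks` contiguous byte ranges, each
#' beginning at an `a` line, so that no block is ever split across
#' chunks. Concatenating per-chunk parses in order reproduces the
#' single-pass parse exactly.
#'
#' @param path path to a MAF file.
#' @param nChunks requested number of chunks (>= 1); fewer are returned
#'   when the file has fewer blocks.
#' @return a data.frame with one row per non-empty chunk: `start` and
#'   `end` (0-based inclusive byte offsets) and `firstBlockIndex`.
#' @seealso [readMafChunk()]
#' @export
chunkBlocks <- function(path, nChunks) {
  if (nChunks < 1L) stop("nChunks must be >= 1", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nbytes <- nchar(lines, type = "bytes") + 1L  # assumes \n line endings
  offs <- cumsum(c(0L, nbytes[-length(nbytes)]))
  aLines <- grep("^[ \t]*a( |\t|$)", lines)
  if (!length(aLines)) {
    # headerless dialect: treat first s-line of each blank-separated run
    sLines <- grep("^[ \t]*s[ \t]", lines)
    if (!length(sLines))
      return(data.frame(start = integer(0), end = integer(0),
                        firstBlockIndex = integer(0)))
    starts <- sLines[c(TRUE, diff(sLines) > 1L)]
    aLines <- starts
  }
  nb <- length(aLines)
  k <- min(nChunks, nb)
  grp <- ceiling(seq_len(nb) * k / nb)
  firsts <- aLines[!duplicated(grp)]
  chunkStart <- offs[firsts]
  fileSize <- sum(nbytes)
  chunkEnd <- c(chunkStart[-1] - 1L, fileSize - 1L)
  data.frame(start = chunkStart, end = chunkEnd,
             firstBlockIndex = c(0L, cumsum(tabulate(grp, k))[-k]))
}

#' Parse one byte-range chunk of a MAF file
#'
#' @param path path to the MAF file.
#' @param chunk one row of the data.frame returned by [chunkBlocks()]
#'   (or any list with `start`, `end`, `firstBlockIndex`).
#' @return a list of [MafBlock][MafBlock-class] objects with block
#'   indices continuing the whole-file numbering.
#' @export
readMafChunk <- function(path, chunk) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = chunk$start)
  raw <- readChar(con, nchars = chunk$end - chunk$start + 1L,
                  useBytes = TRUE)
  parseMaf(text = raw, firstBlockIndex = as.integer(chunk$firstBlockIndex))
}

#' Construct a MafBlock from gapped row texts
#'
#' Convenience constructor for desk-scale blocks: the `size` field is
#' derived from the non-gap count of each text and `srcSize` is padded to
#' be consistent.
#'
#' @param texts character vector of equal-length gapped row texts.
#' @param srcs source identifiers (`genome.chromosome`); defaults to
#'   `g1.chr1`, `g2.chr1`, ...
#' @param starts 0-based strand-relative start offsets (default all 0).
#' @param strands `'+'`/`'-'` per row (default all `'+'`).
#' @param srcSizes total source lengths; default `starts + size + 1000`.
#' @param score optional `a`-line score.
#' @param blockIndex 0-based block ordinal.
#' @return a [MafBlock][MafBlock-class].
#' @examples
#' mafBlockFromTexts(c("A-TCG", "AT-CG"), starts = c(1000, 500))
#' @export
mafBlockFromTexts <- function(texts, srcs = NULL, starts = NULL,
                              strands = NULL, srcSizes = NULL,
                              score = NA_real_, blockIndex = 0L) {
  n <- length(texts)
  texts <- toupper(texts)
  if (is.null(srcs)) srcs <- paste0("g", seq_len(n), ".chr1")
  if (is.null(starts)) starts <- rep(0, n)
  if (is.null(strands)) strands <- rep("+", n)
  sizes <- nchar(gsub("-", "", texts, fixed = TRUE))
  if (is.null(srcSizes)) srcSizes <- starts + sizes + 1000
  new("MafBlock", score = score,
      records = DataFrame(src = srcs, start = starts, size = sizes,
                          strand = strands, srcSize = srcSizes,
                          text = texts),
      blockIndex = as.integer(blockIndex))
}

#' Serialize MafBlock objects to MAF text
#'
#' @param blocks a [MafBlock][MafBlock-class] or list of them.
#' @param version version string for the `##maf` header.
#' @return character vector of MAF lines (one element per line).
#' @export
formatMaf <- function(blocks, version = "1") {
  if (is(blocks, "MafBlock")) blocks <- list(blocks)
  out <- c(sprintf("##maf version=%s", version), "")
  for (blk in blocks) {
    aline <- if (is.na(mafScore(blk))) "a" else
      sprintf("a score=%s", format(mafScore(blk), scientific = FALSE))
    rec <- mafRecords(blk)
    slines <- sprintf("s %s %.0f %.0f %s %.0f %s", rec$src, rec$start,
                      rec$size, rec$strand, rec$srcSize, rec$text)
    out <- c(out, aline, slines, "")
  }
  out
}

# ungapped row text of one record
.ungappedText <- function(text) gsub("-", "", text, fixed = TRUE)
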