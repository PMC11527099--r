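#' Generate a synthetic MAF file with planted motifs and known truth
#'
#' Builds an alignment of `length(genomes)` rows per block. The first
#' genome is the reference: a uniform-random sequence of `blockLen`
#' bases into which the requested motifs are planted at fixed ungapped
#' offsets (reverse-strand plants insert the motif's reverse
#' complement). Every other row is derived from the reference by i.i.d.
#' substitution at `mutationRate` (to a uniformly chosen different
#' base), then mutated structurally at `gapRate`: per position and
#' non-reference row, either a deletion run (`-` replacing 1-3 bases of
#' that row) or an insertion (a new column holding a random base in
#' that row and `-` in all others, which creates reference-gap columns).
#' Column padding keeps all row texts equal length, so the emitted
#' blocks satisfy the MAF invariants by construction. Deterministic for
#' a given seed.
#'
#' @param nBlocks number of alignment blocks.
#' @param genomes character vector of genome names (>= 1; first is the
#'   reference). Row sources are `<genome>.chr1`.
#' @param blockLen ungapped reference length of each block.
#' @param mutationRate per-base substitution probability in non-reference
#'   rows, in `[0, 1]`.
#' @param gapRate per-position probability of a structural (indel) event
#'   in each non-reference row, in `[0, 1]`.
#' @param planted optional data.frame with columns `motif`, `block`
#'   (0-based block index), `offset` (0-based ungapped offset in the
#'   reference), `strand` (`'+'`/`'-'`).
#' @param seed RNG seed.
#' @param refStart 0-based source start of the reference row in each
#'   block (recycled over blocks).
#' @param file optional path; when given the MAF text is written there.
#' @return list with elements `text` (character vector of MAF lines),
#'   `blocks` (list of [MafBlock][MafBlock-class]) and `truth`
#'   (data.frame of planted instances with their expected source
#'   coordinates: `motif`, `block`, `offset`, `strand`, `sourceStart`,
#'   `sourceEnd`).
#' @examples
#' fx <- generateMaf(nBlocks = 2, genomes = c("hg38", "mm39"),
#'                   blockLen = 40, mutationRate = 0, gapRate = 0,
#'                   planted = data.frame(motif = "ATCGAT", block = 0:1,
#'                                        offset = 5, strand = "+"),
#'                   seed = 7)
#' fx$truth
#' @export
generateMaf <- function(nBlocks = 1L, genomes = c("hg38", "mm39"),
                        blockLen = 100L, mutationRate = 0.05,
                        gapRate = 0.02, planted = NULL, seed = 1L,
                        refStart = 0L, file = NULL) {
  stopifnot(nBlocks >= 1L, length(genomes) >= 1L, blockLen >= 1L,
            mutationRate >= 0, mutationRate <= 1,
            gapRate >= 0, gapRate <= 1)
  if (!is.null(planted)) {
    need <- c("motif", "block", "offset")
    if (!all(need %in% colnames(planted)))
      stop("planted needs columns motif, block, offset (and optional strand)",
           call. = FALSE)
    if (is.null(planted$strand)) planted$strand <- "+"
    over <- planted$offset + nchar(planted$motif) > blockLen
    if (any(over))
      stop(sprintf("planted motif '%s' overflows block length %d",
                   planted$motif[over][1], blockLen), call. = FALSE)
    if (any(planted$block < 0 | planted$block >= nBlocks))
      stop("planted block index out of range", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  refStart <- rep_len(refStart, nBlocks)

  blocks <- vector("list", nBlocks)
  truth <- list()
  for (b in seq_len(nBlocks)) {
    ref <- sample(.DNA_BASES, blockLen, replace = TRUE)
    if (!is.null(planted)) {
      pb <- planted[planted$block == b - 1L, , drop = FALSE]
      for (k in seq_len(nrow(pb))) {
        mot <- toupper(pb$motif[k])
        ins <- if (pb$strand[k] == "-") .revCompChar(mot) else mot
        at <- pb$offset[k]
        ref[(at + 1L):(at + nchar(ins))] <- strsplit(ins, "")[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          motif = mot, block = b - 1L, offset = at, strand = pb$strand[k],
          sourceStart = refStart[b] + at,
          sourceEnd = refStart[b] + at + nchar(ins) - 1L)
      }
    }
    rows <- list(ref)
    ng <- length(genomes)
    for (g in seq_len(ng - 1L)) {
      row <- ref
      mut <- which(stats::runif(blockLen) < mutationRate)
      for (p in mut) {
        row[p] <- sample(setdiff(.DNA_BASES, row[p]), 1L)
      }
      rows[[g + 1L]] <- row
    }
    # structural events: deletions gap the derived row; insertions add a
    # column that is a base in the derived row and '-' everywhere else
    if (gapRate > 0 && ng > 1L) {
      for (g in 2L:ng) {
        ev <- which(stats::runif(length(rows[[g]])) < gapRate)
        for (p in rev(ev)) {
          if (stats::runif(1) < 0.5) {
            len <- sample(1:3, 1L)
            span <- p:min(p + len - 1L, length(rows[[g]]))
            cur <- rows[[g]][span]
            rows[[g]][span] <- ifelse(cur == "-", cur, "-")
          } else {
            base <- sample(.DNA_BASES, 1L)
            for (r in seq_len(ng)) {
              rows[[r]] <- append(rows[[r]], if (r == g) base else "-",
                                  after = p)
            }
          }
        }
      }
    }
    texts <- vapply(rows, paste, "", collapse = "")
    sizes <- nchar(gsub("-", "", texts, fixed = TRUE))
    starts <- c(refStart[b], rep(0, ng - 1L))
    blocks[[b]] <- new("MafBlock", score = 0,
      records = DataFrame(
        src = paste0(genomes, ".chr1"), start = starts, size = sizes,
        strand = rep("+", ng), srcSize = starts + sizes + 10000,
        text = texts),
      blockIndex = b - 1L)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(motif = character(0), block = integer(0),
               offset = integer(0), strand = character(0),
               sourceStart = numeric(0), sourceEnd = numeric(0))
  text <- formatMaf(blocks)
  if (!is.null(file)) writeLines(text, file)
  list(text = text, blocks = blocks, truth = truth)
}
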