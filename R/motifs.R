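#' Load a k-mer motif list
#'
#' Reads a plain-text file with one k-mer per line (blank lines ignored),
#' uppercases and deduplicates.
#'
#' @param path path to the k-mer file.
#' @return a [KmerSet][KmerSet-class].
#' @export
loadKmers <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  km <- toupper(trimws(lines[keep]))
  bad <- grepl("[^ACGT]", km)
  if (any(bad))
    stop(sprintf("line %d: k-mer '%s' contains characters outside {A,C,G,T}",
                 which(keep)[bad][1], km[bad][1]), call. = FALSE)
  kmerSet(km)
}

#' Construct a KmerSet from character k-mers
#'
#' @param x character vector of DNA words; uppercased and deduplicated.
#' @return a [KmerSet][KmerSet-class].
#' @export
kmerSet <- function(x) new("KmerSet", kmers = unique(toupper(x)))

#' Construct a RegexSet from pattern strings
#'
#' @param x character vector of regular expressions (PCRE dialect), or a
#'   single comma-separated string.
#' @return a [RegexSet][RegexSet-class].
#' @export
regexSet <- function(x) {
  if (length(x) == 1L && grepl(",", x, fixed = TRUE))
    x <- strsplit(x, ",", fixed = TRUE)[[1]]
  new("RegexSet", patterns = trimws(x))
}

#' Parse a JASPAR-format PWM file
#'
#' Accepts the JASPAR PFM text layout: a `>ID NAME` header followed by
#' four rows for A, C, G and T, either bracketed
#' (`A [ 3 5 ... ]`) or as bare numbers. Counts and probabilities are
#' both accepted; every column is renormalized to probabilities.
#'
#' @param path path to the JASPAR file.
#' @return a list of [PwmMotif][PwmMotif-class] objects.
#' @export
parseJaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads))
    stop("no '>' header found in JASPAR file", call. = FALSE)
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    hdr <- trimws(sub("^>", "", lines[heads[i]]))
    parts <- strsplit(hdr, "[ \t]+")[[1]]
    id <- parts[1]
    nm <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else id
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop(sprintf("motif '%s': expected 4 nucleotide rows, found %d",
                   id, length(body)), call. = FALSE)
    rows <- lapply(body, .parseJasparRow)
    labels <- vapply(rows, `[[`, "", "base")
    if (all(labels %in% .DNA_BASES) && !anyDuplicated(labels)) {
      vals <- lapply(rows, `[[`, "values")[match(.DNA_BASES, labels)]
    } else if (all(!nzchar(labels))) {
      vals <- lapply(rows, `[[`, "values")  # unlabeled: assume A,C,G,T order
    } else {
      stop(sprintf("motif '%s': nucleotide rows must be labeled A,C,G,T or unlabeled",
                   id), call. = FALSE)
    }
    lens <- lengths(vals)
    if (length(unique(lens)) != 1L)
      stop(sprintf("motif '%s': nucleotide rows have unequal lengths", id),
           call. = FALSE)
    m <- do.call(rbind, vals)
    rownames(m) <- .DNA_BASES
    cs <- colSums(m)
    if (any(cs <= 0))
      stop(sprintf("motif '%s': column with zero total count", id),
           call. = FALSE)
    m <- sweep(m, 2, cs, "/")
    out[[i]] <- new("PwmMotif", motifId = id, name = nm, probs = m)
  }
  out
}

.parseJasparRow <- function(line) {
  line <- trimws(line)
  base <- ""
  m <- regexec("^([ACGTacgt])\\s*\\[(.*)\\]\\s*$", line)
  hit <- regmatches(line, m)[[1]]
  if (length(hit) == 3L) {
    base <- toupper(hit[2])
    nums <- hit[3]
  } else {
    m2 <- regexec("^([ACGTacgt])\\s+([-0-9. \teE+]+)$", line)
    hit2 <- regmatches(line, m2)[[1]]
    if (length(hit2) == 3L) {
      base <- toupper(hit2[2])
      nums <- hit2[3]
    } else {
      nums <- line
    }
  }
  values <- suppressWarnings(as.numeric(strsplit(trimws(nums), "[ \t]+")[[1]]))
  if (anyNA(values))
    stop(sprintf("cannot parse JASPAR matrix row: '%s'", line), call. = FALSE)
  list(base = base, values = values)
}

# reverse complement for plain character DNA (vectorized)
.revCompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname reverseComplement-methods
#' @export
setMethod("reverseComplement", "character", function(x, ...) .revCompChar(x))

#' Reverse complement methods for motif objects
#'
#' For a [PwmMotif][PwmMotif-class] the reverse complement reverses the
#' order of the positions and replaces each nucleotide row with its
#' complement: `rc[b, i] = p[complement(b), L - 1 - i]` (0-based
#' positions). The operation is an involution. For character vectors the
#' standard DNA reverse complement is returned.
#'
#' @param x a [PwmMotif][PwmMotif-class] or character vector of DNA
#'   strings.
#' @param ... ignored.
#' @return an object of the same class as `x`.
#' @examples
#' reverseComplement("CCG")  # "CGG"
#' @name reverseComplement-methods
NULL

#' @rdname reverseComplement-methods
#' @export
setMethod("reverseComplement", "PwmMotif", function(x, ...) {
  m <- x@probs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- m[comp[.DNA_BASES], rev(seq_len(ncol(m))), drop = FALSE]
  rownames(rc) <- .DNA_BASES
  colnames(rc) <- NULL
  new("PwmMotif", motifId = x@motifId, name = x@name, probs = rc)
})

#' Convert a PWM to a log-odds score matrix
#'
#' Adds a pseudocount to every probability cell, renormalizes each
#' column, and computes per-cell log-odds `log2(p / bg)` against the
#' background model. The reverse-complement motif's log-odds against the
#' same background are precomputed alongside so both strands can be
#' scanned.
#'
#' @param pwm a [PwmMotif][PwmMotif-class].
#' @param background numeric(4) background probabilities for A, C, G, T;
#'   each must be strictly positive and they must sum to 1 (default
#'   uniform).
#' @param pseudocount value added to each probability cell before column
#'   renormalization (default 0.01); guards against `-Inf` scores from
#'   zero entries.
#' @return a [LogOddsMatrix][LogOddsMatrix-class].
#' @examples
#' pwm <- new("PwmMotif", motifId = "m1", name = "m1",
#'            probs = matrix(c(1, 0, 0, 0), 4, 1,
#'                           dimnames = list(c("A", "C", "G", "T"), NULL)))
#' pwmLogOdds(pwm)
#' @export
pwmLogOdds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  bg <- .checkBackground(background)
  lo <- .logOddsCore(pwm@probs, bg, pseudocount)
  rc <- .logOddsCore(reverseComplement(pwm)@probs, bg, pseudocount)
  new("LogOddsMatrix", motifId = pwm@motifId, scores = lo, rcScores = rc,
      background = bg,
      minScore = sum(apply(lo, 2, min)), maxScore = sum(apply(lo, 2, max)))
}

.logOddsCore <- function(p, bg, pseudocount) {
  p <- p + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  log2(p / bg)
}

.checkBackground <- function(bg) {
  bg <- as.numeric(bg)
  if (length(bg) != 4L)
    stop("background must be four frequencies for A, C, G, T", call. = FALSE)
  if (any(bg <= 0))
    stop("background frequencies must be strictly positive", call. = FALSE)
  if (abs(sum(bg) - 1) > 1e-6)
    stop("background frequencies must sum to 1", call. = FALSE)
  names(bg) <- .DNA_BASES
  bg
}

#' Calibrate a PWM score threshold for a target p-value
#'
#' Draws `nSamples` i.i.d. random sequences of the motif length from the
#' background nucleotide model, scores each with the log-odds matrix,
#' and returns the empirical `(1 - pValue)` quantile of the score
#' distribution as the threshold. A window then passes at score >=
#' threshold, so that the probability of a background window passing is
#' approximately `pValue`. Deterministic for a given seed. The sorted
#' sample is stored so each later hit can be assigned an empirical
#' p-value.
#'
#' @param logodds a [LogOddsMatrix][LogOddsMatrix-class] from
#'   [pwmLogOdds()].
#' @param pValue target p-value in (0, 1]; `1` makes every window pass.
#' @param nSamples Monte-Carlo sample size (default 100000); a warning is
#'   issued when `nSamples < 1 / pValue`, where the tail is unresolved.
#' @param seed RNG seed (default 42).
#' @return a [CalibratedThreshold][CalibratedThreshold-class].
#' @export
calibrateThreshold <- function(logodds, pValue = 1e-4, nSamples = 1e5,
                               seed = 42L) {
  if (pValue <= 0 || pValue > 1)
    stop("pValue must lie in (0, 1]", call. = FALSE)
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L) stop("nSamples must be >= 1", call. = FALSE)
  if (nSamples < 1 / pValue)
    warning(sprintf(
      "nSamples = %d cannot resolve pValue = %g; recommend >= %.0f samples",
      nSamples, pValue, 1 / pValue))
  L <- ncol(logodds@scores)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  bases <- sample.int(4L, nSamples * L, replace = TRUE,
                      prob = logodds@background)
  cell <- matrix(logodds@scores[cbind(bases, rep(seq_len(L), each = nSamples))],
                 nrow = nSamples, ncol = L)
  scores <- sort(rowSums(cell))
  thr <- if (pValue >= 1) logodds@minScore else
    unname(stats::quantile(scores, probs = 1 - pValue, type = 1))
  new("CalibratedThreshold", threshold = thr, pValue = pValue,
      nSamples = nSamples, seed = as.integer(seed), sampleScores = scores)
}

# empirical tail p-value of a score against the calibration sample;
# resolution 1/nSamples, floored at 1/(nSamples + 1)
.empiricalP <- function(score, calib) {
  n <- calib@nSamples
  nGE <- n - findInterval(score - 1e-12, calib@sampleScores)
  pmax(nGE / n, 1 / (n + 1))
}
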