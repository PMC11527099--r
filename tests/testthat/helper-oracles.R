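# Independent brute-force oracles. These deliberately avoid the package's
# engines (automaton, vectorized PWM scoring, gap-map arithmetic) so each
# test is a genuine dual-route check.

# reverse complement without Biostrings
naiveRevComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(comp[ch], collapse = "")
  }, "", USE.NAMES = FALSE)
}

# sliding-window literal search; returns 0-based starts
naiveFind <- function(seq, pattern) {
  n <- nchar(seq); k <- nchar(pattern)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - k)) {
    if (substring(seq, s + 1, s + k) == pattern) hits <- c(hits, s)
  }
  hits
}

# full k-mer scan oracle mirroring the hit-table contract
naiveKmerScan <- function(seq, kmers, includeRevComp = FALSE) {
  rows <- list()
  for (km in kmers) {
    for (s in naiveFind(seq, km)) {
      rows[[length(rows) + 1L]] <- data.frame(
        motifId = km, start = s, end = s + nchar(km) - 1L, strand = "+",
        matchedSeq = km, stringsAsFactors = FALSE)
    }
    if (includeRevComp) {
      rc <- naiveRevComp(km)
      for (s in naiveFind(seq, rc)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motifId = km, start = s, end = s + nchar(km) - 1L, strand = "-",
          matchedSeq = rc, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(motifId = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matchedSeq = character(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$motifId, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# per-window PWM rescoring oracle (explicit loops, no matrix indexing tricks)
naivePwmScore <- function(window, scores) {
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  total <- 0
  for (i in seq_along(ch)) {
    r <- match(ch[i], c("A", "C", "G", "T"))
    if (is.na(r)) return(NA_real_)
    total <- total + scores[r, i]
  }
  total
}

naivePwmScan <- function(seq, scores, thr) {
  L <- ncol(scores); n <- nchar(seq)
  out <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      sc <- naivePwmScore(substring(seq, s + 1, s + L), scores)
      if (!is.na(sc) && sc >= thr)
        out[[length(out) + 1L]] <- data.frame(start = s, score = sc)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), score = numeric(0)))
  do.call(rbind, out)
}

randomSeq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

randomPwm <- function(L, id = "M0001") {
  m <- matrix(stats::runif(4 * L), 4, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- sweep(m, 2, colSums(m), "/")
  new("PwmMotif", motifId = id, name = id, probs = m)
}

# the worked-example PWM (positions 1-4)
tablePwm <- function() {
  m <- matrix(c(0.2, 0.1, 0.4, 0.3,
                0.3, 0.5, 0.1, 0.2,
                0.4, 0.3, 0.4, 0.5,
                0.1, 0.1, 0.1, 0.0),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  new("PwmMotif", motifId = "T5", name = "example", probs = m)
}

# exact tail probability of score >= thr over all 4^L sequences under bg
exhaustiveTail <- function(scores, bg, thr) {
  L <- ncol(scores)
  grid <- expand.grid(rep(list(1:4), L))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    b <- as.integer(grid[i, ])
    sc <- sum(scores[cbind(b, seq_len(L))])
    if (sc >= thr) tot <- tot + prod(bg[b])
  }
  tot
}

# exact score quantile over all 4^L sequences under bg
exhaustiveQuantile <- function(scores, bg, p) {
  L <- ncol(scores)
  grid <- expand.grid(rep(list(1:4), L))
  sc <- numeric(nrow(grid))
  w <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    b <- as.integer(grid[i, ])
    sc[i] <- sum(scores[cbind(b, seq_len(L))])
    w[i] <- prod(bg[b])
  }
  o <- order(sc)
  cw <- cumsum(w[o])
  sc[o][which(cw >= 1 - p)[1]]
}

writeTempMaf <- function(blocks) {
  f <- tempfile(fileext = ".maf")
  writeLines(formatMaf(blocks), f)
  f
}
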