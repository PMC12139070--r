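## Independent reference implementations used as oracles. They share only the
## problem definition with the package code, not its implementation.

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## --- expectation scoring: memoised top-down recursion over alignment states
oracleDuplexScore <- function(srna, window, scheme = scoringScheme()) {
  s <- strsplit(chartr("Uu", "Tt", toupper(srna)), "", fixed = TRUE)[[1]]
  u <- rev(strsplit(chartr("Uu", "Tt", toupper(window)), "", fixed = TRUE)[[1]])
  n <- length(s); m <- length(u)
  B <- scheme@maxBulges
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  mult <- function(i) if (i >= scheme@seedStart && i <= scheme@seedEnd)
    scheme@seedMultiplier else 1
  colCost <- function(i, j) {
    if (wc[[s[i]]] == u[j]) 0
    else if ((s[i] == "G" && u[j] == "T") || (s[i] == "T" && u[j] == "G"))
      scheme@wobblePenalty * mult(i)
    else scheme@mismatchPenalty * mult(i)
  }
  memo <- new.env(hash = TRUE)
  ## f(i, j, b, last): min cost to consume s[1..i], u[1..j] with b gap events,
  ## the final column being of type `last` ("M" aligned, "X" sRNA bulge,
  ## "Y" target bulge). (0, 0, 0, "M") is the start.
  f <- function(i, j, b, last) {
    if (i == 0 && j == 0) return(if (b == 0 && last == "M") 0 else Inf)
    if (i < 0 || j < 0 || b < 0) return(Inf)
    key <- paste(i, j, b, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- Inf
    if (last == "M" && i >= 1 && j >= 1) {
      below <- min(f(i - 1, j - 1, b, "M"), f(i - 1, j - 1, b, "X"),
                   f(i - 1, j - 1, b, "Y"))
      val <- below + colCost(i, j)
    } else if (last == "X" && i >= 1) {
      val <- min(f(i - 1, j, b - 1, "M") + scheme@gapOpenPenalty * mult(i),
                 f(i - 1, j, b, "X") + scheme@gapExtendPenalty * mult(i))
    } else if (last == "Y" && j >= 1) {
      adj <- min(i + 1, n)
      val <- min(f(i, j - 1, b - 1, "M") + scheme@gapOpenPenalty * mult(adj),
                 f(i, j - 1, b, "Y") + scheme@gapExtendPenalty * mult(adj))
    }
    memo[[key]] <- val
    val
  }
  best <- Inf
  for (b in 0:B) for (last in c("M", "X", "Y"))
    best <- min(best, f(n, m, b, last))
  best
}

## exhaustive window scan + the same reporting rule, via the oracle scorer
oracleTargetScan <- function(srna, transcript, scheme = scoringScheme()) {
  n <- nchar(srna); L <- nchar(transcript)
  rows <- list()
  for (start in 1:L) {
    best <- Inf; bestEnd <- NA
    for (w in (n - scheme@maxBulges):(n + scheme@maxBulges)) {
      end <- start + w - 1
      if (w < 1 || end > L) next
      e <- oracleDuplexScore(srna, substr(transcript, start, end), scheme)
      if (e < best - 1e-12) { best <- e; bestEnd <- end }
    }
    if (!is.na(bestEnd) && best <= scheme@maxExpectation + 1e-9)
      rows[[length(rows) + 1L]] <- data.frame(start = start, end = bestEnd,
                                              expectation = best)
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer(),
                                       expectation = numeric()))
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$expectation, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand)); taken <- NULL
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (is.null(taken) || all(e < taken[, 1] | s > taken[, 2])) {
      keep[i] <- TRUE; taken <- rbind(taken, c(s, e))
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$expectation, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- read mapping: exhaustive window comparison on both strands
oracleMapReads <- function(reads, transcripts) {
  rows <- list()
  for (r in seq_len(nrow(reads))) {
    rs <- chartr("U", "T", toupper(reads$sequence[r]))
    rc <- revComp(rs)
    w <- nchar(rs)
    for (tid in names(transcripts)) {
      tx <- chartr("U", "T", toupper(transcripts[[tid]]))
      L <- nchar(tx)
      if (w > L) next
      for (start in 1:(L - w + 1)) {
        win <- substr(tx, start, start + w - 1)
        for (strand in c("+", "-")) {
          if ((strand == "+" && win == rs) || (strand == "-" && win == rc))
            rows[[length(rows) + 1L]] <- data.frame(
              read_sequence = reads$sequence[r], transcript_id = tid,
              start = start, end = start + w - 1L, strand = strand,
              count = reads$count[r], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(read_sequence = character(), transcript_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      count = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$transcript_id, res$start, res$strand,
                   res$read_sequence), ]
  rownames(res) <- NULL
  res
}

## --- maximum nested base pairing by brute-force recursion on the first
## position (no memoisation; for short sequences only)
oracleMaxPairs <- function(seq, minLoop = 3) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "", fixed = TRUE)[[1]]
  canPair <- function(a, b) {
    wc <- c(A = "T", C = "G", G = "C", T = "A")
    wc[[a]] == b || (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  go <- function(i, j) {
    if (i >= j) return(0L)
    best <- go(i + 1L, j)  # i unpaired
    if (j - i > minLoop) {
      for (k in (i + minLoop + 1L):j) {
        if (canPair(s[i], s[k]))
          best <- max(best, 1L + go(i + 1L, k - 1L) + go(k + 1L, j))
      }
    }
    best
  }
  go(1L, length(s))
}

## --- hypergeometric register p-value by exhaustive subset enumeration
oraclePhasingPvalue <- function(k, n, period, cycles) {
  m <- period * cycles
  inPhase <- seq(1, m, by = period)  # q = cycles positions
  sets <- utils::combn(m, n)
  hits <- apply(sets, 2, function(ss) sum(ss %in% inPhase) >= k)
  mean(hits)
}

## small helper: a scheme with tight bounds for quick scans
fastScheme <- function(...) scoringScheme(...)
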