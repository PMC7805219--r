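#' Detect tandemly repetitive content with a bounded-period self-match
#' scan
#'
#' For every period \code{p <= maxPeriod} the sequence is compared to
#' itself shifted by \code{p}; maximal runs where the windowed match
#' fraction reaches \code{minIdentity} and whose span covers at least
#' \code{minCopies} repeat units become tandem intervals (each run is
#' extended left by one period to include the seed copy). Periods above
#' \code{maxPeriod} are invisible by construction, which preserves long
#' and complex satellite repeats. Overlapping intervals are merged for
#' the coverage statistics.
#'
#' @param seq DNA string.
#' @param maxPeriod Largest repeat period considered (default 20 bp).
#' @param minIdentity Minimum within-run match fraction (default 0.8).
#' @param minCopies Minimum repeat copies spanned (default 3).
#' @return A \linkS4class{TandemAnnotation}.
#' @examples
#' detectTandem(strrep("AC", 100))
#' @export
detectTandem <- function(seq, maxPeriod = 20L, minIdentity = 0.8,
                         minCopies = 3.0) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  stopifnot2(n >= 1L, "sequence must be non-empty")
  ch <- splitChars(seq)
  iv <- list()
  for (p in seq_len(min(maxPeriod, n - 1L))) {
    match <- c(rep(FALSE, p), ch[(p + 1L):n] == ch[seq_len(n - p)])
    w <- max(p, 10L)
    if (n < p + w) next
    # windowed match fraction over positions p+1..n
    cs <- cumsum(match)
    starts <- (p + 1L):(n - w + 1L)
    if (!length(starts)) next
    frac <- (cs[starts + w - 1L] - c(0, cs)[starts]) / w
    good <- frac >= minIdentity
    r <- rle(good)
    pos <- cumsum(c(0L, r$lengths))
    for (j in which(r$values)) {
      a <- starts[pos[j] + 1L]           # first window start in the run
      b <- starts[pos[j + 1L]] + w - 1L  # last window end
      a <- max(1L, a - p)                # include the seed copy
      if (b - a + 1L >= minCopies * p) {
        id <- mean(match[max(a + p, 1L):b])
        iv[[length(iv) + 1L]] <- c(a, b, p, id)
      }
    }
  }
  if (length(iv)) {
    m <- do.call(rbind, iv)
    intervals <- data.frame(start = as.integer(m[, 1L]),
                            end = as.integer(m[, 2L]),
                            period = as.integer(m[, 3L]),
                            identity = m[, 4L])
  } else {
    intervals <- data.frame(start = integer(), end = integer(),
                            period = integer(), identity = numeric())
  }
  covered <- logical(n)
  for (k in seq_len(nrow(intervals)))
    covered[intervals$start[k]:intervals$end[k]] <- TRUE
  runs <- rle(covered)
  clear <- if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0L
  new("TandemAnnotation", intervals = intervals,
      tandemFraction = mean(covered), longestClearRun = as.integer(clear),
      seqLength = as.integer(n))
}

#' Uncurated-library import filter for tandemly repetitive consensi
#'
#' Applies the pre-import rule for de novo family libraries: a family
#' is dropped if and only if more than 80 percent of its consensus is
#' tandemly repetitive AND it contains less than 100 bp of contiguous
#' non-tandem sequence. Both inequalities are strict, so a family at
#' exactly 80 percent, or with exactly 100 bp clear, is kept.
#'
#' @param consensus Family consensus DNA string.
#' @param maxPeriod Passed to \code{\link{detectTandem}} (default 20
#'   bp, preserving common and complex satellites).
#' @param ... Further arguments to \code{\link{detectTandem}}.
#' @return List with \code{keep} (logical), \code{tandemFraction},
#'   \code{longestClearRun}, and \code{reasons} (character).
#' @examples
#' tandemImportFilter(strrep("TA", 200))$keep
#' @export
tandemImportFilter <- function(consensus, maxPeriod = 20L, ...) {
  ann <- detectTandem(consensus, maxPeriod = maxPeriod, ...)
  highTandem <- ann@tandemFraction > 0.80
  shortClear <- ann@longestClearRun < 100L
  keep <- !(highTandem && shortClear)
  reasons <- c(
    sprintf("tandem fraction %.3f %s 0.80", ann@tandemFraction,
            if (highTandem) ">" else "<="),
    sprintf("longest clear run %d bp %s 100 bp", ann@longestClearRun,
            if (shortClear) "<" else ">="))
  list(keep = keep, tandemFraction = ann@tandemFraction,
       longestClearRun = ann@longestClearRun, reasons = reasons,
       annotation = ann)
}

#' Filter a FASTA consensus library and write a TSV report
#'
#' @param fastaPath Input FASTA of family consensi.
#' @param reportPath Optional output TSV (family, fraction, clear run,
#'   decision).
#' @return data.frame of per-family decisions, invisibly written to
#'   \code{reportPath} when given.
#' @export
filterConsensusLibrary <- function(fastaPath, reportPath = NULL) {
  lib <- Biostrings::readDNAStringSet(fastaPath)
  rows <- lapply(seq_along(lib), function(i) {
    r <- tandemImportFilter(as.character(lib[[i]]))
    data.frame(family = names(lib)[i],
               tandem_fraction = round(r$tandemFraction, 4),
               longest_clear_run = r$longestClearRun,
               decision = if (r$keep) "keep" else "drop")
  })
  out <- do.call(rbind, rows)
  if (!is.null(reportPath))
    utils::write.table(out, reportPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
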