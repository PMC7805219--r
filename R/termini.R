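#' Extract the terminal sequences of a consensus
#'
#' Returns the first and last \code{L} bases of a consensus; sequences
#' shorter than \code{L} are N-padded (on the right for the 5' end, on
#' the left for the 3' end) so that terminal positions stay anchored at
#' the element boundary.
#'
#' @param consensus DNA string.
#' @param L Terminus length in bp (default 60; the informative range
#'   for class II termini is roughly 30-60 bp).
#' @return List with \code{five} and \code{three}, both length-L
#'   strings.
#' @examples
#' extractTermini(strrep("ACGT", 25), L = 60)
#' @export
extractTermini <- function(consensus, L = 60L) {
  consensus <- toupper(as.character(consensus))
  n <- nchar(consensus)
  stopifnot2(n >= 1L, "empty sequence")
  stopifnot2(L >= 1L, "L must be >= 1")
  k <- min(L, n)
  five <- paste0(substr(consensus, 1L, k), strrep("N", L - k))
  three <- paste0(strrep("N", L - k), substr(consensus, n - k + 1L, n))
  list(five = five, three = three)
}

#' Build a terminus pile-up for one classification category
#'
#' Anchors each family's terminus at the element boundary, then refines
#' the stack with an exhaustive small-offset search (0-\code{maxShift}
#' bp, toward the interior) choosing per row the shift that maximizes
#' total column information content -- a deterministic stand-in for
#' hand-aligning the pile-up.
#'
#' @param termini Character vector of length-L terminus strings (one
#'   per family; see \code{\link{extractTermini}}).
#' @param category Classification path of the category.
#' @param end One of \code{"five_prime"}, \code{"three_prime"}.
#' @param familyIds Source family identifiers.
#' @param maxShift Maximum anchoring shift in bp (default 3).
#' @return List with \code{category}, \code{end}, \code{rows},
#'   \code{familyIds}.
#' @export
buildTerminusPileup <- function(termini, category, end,
                                familyIds = names(termini), maxShift = 3L) {
  stopifnot2(end %in% c("five_prime", "three_prime"), "invalid end")
  L <- unique(nchar(termini))
  stopifnot2(length(L) == 1L, "termini must share one length")
  rows <- toupper(termini)
  if (maxShift > 0L && length(rows) > 2L) {
    shift1 <- function(s, by) {   # shift toward the interior, N-fill
      if (by == 0L) return(s)
      if (end == "five_prime")
        paste0(substr(s, by + 1L, L), strrep("N", by))
      else
        paste0(strrep("N", by), substr(s, 1L, L - by))
    }
    totalIC <- function(rws)
      sum(profileIC(profileFromRows(rws, 0.5)$p))
    for (r in seq_along(rows)) {
      cand <- vapply(0:maxShift, function(by) {
        tmp <- rows; tmp[r] <- shift1(rows[r], by)
        totalIC(tmp)
      }, numeric(1))
      rows[r] <- shift1(rows[r], (0:maxShift)[which.max(cand)])
    }
  }
  list(category = category, end = end, rows = rows,
       familyIds = if (is.null(familyIds)) paste0("fam", seq_along(rows))
                   else familyIds)
}

# position probability matrix from equal-length rows; N excluded
profileFromRows <- function(rows, pseudocount) {
  L <- nchar(rows[1L])
  m <- matrix(unlist(strsplit(rows, ""), use.names = FALSE),
              nrow = length(rows), byrow = TRUE)
  p <- matrix(NA_real_, L, 4L, dimnames = list(NULL, DNA_BASES))
  for (b in DNA_BASES) p[, b] <- colSums(m == b)
  tot <- rowSums(p)
  p <- (p + pseudocount / 4) / (tot + pseudocount)
  list(p = p, counts = tot)
}

# per-column information content, 2 + sum p log2 p, in bits
profileIC <- function(p) {
  pmax(0, pmin(2, 2 + rowSums(ifelse(p > 0, p * log2(p), 0))))
}

#' Build a termini signature from 5' and 3' pile-ups
#'
#' Per-column pseudocounted base probabilities for each end, plus the
#' combined profile (5' rows pooled with reverse-complemented 3' rows)
#' used for terminal-inverted-repeat categories, and per-column
#' information content \eqn{IC = 2 + \sum_b p_b \log_2 p_b}.
#'
#' @param pileup5,pileup3 Pile-ups from
#'   \code{\link{buildTerminusPileup}} for the same category.
#' @param makeCombined Also build the pooled 5' + revcomp(3') profile.
#' @param pseudocount Per-column pseudocount mass (default 0.5).
#' @param tsdExpectation List with \code{min}, \code{max},
#'   \code{motif} describing the category's expected TSD.
#' @return A \linkS4class{TerminiSignature}.
#' @export
terminiSignature <- function(pileup5, pileup3, makeCombined = FALSE,
                             pseudocount = 0.5,
                             tsdExpectation = list(min = NA_integer_,
                                                   max = NA_integer_,
                                                   motif = NA_character_)) {
  stopifnot2(identical(pileup5$category, pileup3$category),
             "pile-ups must share one category")
  if (length(pileup5$rows) < 2L || length(pileup3$rows) < 2L)
    warning("singleton pile-up: signature unreliable", call. = FALSE)
  profiles <- list(
    five_prime = profileFromRows(pileup5$rows, pseudocount)$p,
    three_prime = profileFromRows(pileup3$rows, pseudocount)$p)
  if (makeCombined) {
    pooled <- c(pileup5$rows, vapply(pileup3$rows, revComp, character(1)))
    profiles$combined <- profileFromRows(pooled, pseudocount)$p
  }
  new("TerminiSignature", category = pileup5$category, profiles = profiles,
      informationContent = lapply(profiles, profileIC),
      tsdExpectation = tsdExpectation,
      nFamilies = length(unique(c(pileup5$familyIds, pileup3$familyIds))))
}

# ungapped log-odds of a terminus string against a profile, best
# placement over offsets -slack..slack; N positions score 0
scoreTerminus <- function(term, profile, slack) {
  L <- nrow(profile)
  ch <- splitChars(term)
  lo <- log2(pmax(profile, 1e-9) / 0.25)
  best <- -Inf; bestOff <- 0L
  for (off in -slack:slack) {
    cols <- seq_len(L) + off          # profile column for each query pos
    ok <- cols >= 1L & cols <= L
    bi <- baseIndex(ch)
    idx <- which(ok & !is.na(bi))
    s <- sum(lo[cbind(cols[idx], bi[idx])])
    if (s > best) { best <- s; bestOff <- off }
  }
  list(score = best, offset = bestOff)
}

#' Classify a consensus by its terminal sequences
#'
#' Scores the query's 5' and 3' termini against every signature in the
#' library, in both orientations, as ungapped log-odds sums over
#' placements within \code{slack} bp of the terminus. A category is
#' reported only when its 5' and 3' matches are consistent in
#' orientation and each end exceeds \code{minBits} -- the positional and
#' orientation filtering that makes short terminal homologies
#' trustworthy. An empty result is a valid "unclassified" outcome.
#'
#' @param queryConsensus DNA string of the model to classify.
#' @param library List of \linkS4class{TerminiSignature}.
#' @param slack Maximum placement offset in bp (default 3).
#' @param minBits Minimum bits per end (default 8, about one chance hit
#'   per 256 placements).
#' @return data.frame of hits, ranked by combined score, with columns
#'   \code{category}, \code{orientation}, \code{scoreFive},
#'   \code{scoreThree}, \code{score}, \code{offsetFive},
#'   \code{offsetThree}.
#' @export
classifyByTermini <- function(queryConsensus, library, slack = 3L,
                              minBits = 8) {
  stopifnot2(length(library) > 0L, "signature library is empty")
  L <- nrow(library[[1L]]@profiles$five_prime)
  t0 <- extractTermini(queryConsensus, L)
  rc <- extractTermini(revComp(queryConsensus), L)
  hits <- list()
  for (sig in library) {
    p5 <- sig@profiles$five_prime
    p3 <- sig@profiles$three_prime
    for (orient in c("+", "-")) {
      five <- if (orient == "+") t0$five else rc$five
      three <- if (orient == "+") t0$three else rc$three
      s5 <- scoreTerminus(five, p5, slack)
      s3 <- scoreTerminus(three, p3, slack)
      if (s5$score >= minBits && s3$score >= minBits)
        hits[[length(hits) + 1L]] <- data.frame(
          category = sig@category, orientation = orient,
          scoreFive = s5$score, scoreThree = s3$score,
          score = s5$score + s3$score,
          offsetFive = s5$offset, offsetThree = s3$offset)
    }
  }
  if (!length(hits))
    return(data.frame(category = character(), orientation = character(),
                      scoreFive = numeric(), scoreThree = numeric(),
                      score = numeric(), offsetFive = integer(),
                      offsetThree = integer()))
  out <- do.call(rbind, hits)
  out[order(-out$score), , drop = FALSE]
}

#' Detect a target site duplication between insertion flanks
#'
#' Looks for the longest \code{k} in \code{kRange} such that the last
#' \code{k} bases of the left flank equal the first \code{k} bases of
#' the right flank; one mismatch is tolerated for \code{k >= 8}.
#'
#' @param flankLeft,flankRight Flanking sequences (>= 20 bp each).
#' @param kRange Length-2 integer vector of TSD lengths to consider.
#' @return List with \code{length} and \code{motif}, or \code{NULL}
#'   when no duplication of length >= kRange[1] is found.
#' @examples
#' detectTSD(paste0(strrep("G", 20), "ACGTT"),
#'           paste0("ACGTT", strrep("G", 20)))
#' @export
detectTSD <- function(flankLeft, flankRight, kRange = c(2L, 20L)) {
  flankLeft <- toupper(flankLeft); flankRight <- toupper(flankRight)
  stopifnot2(nchar(flankLeft) >= 20L && nchar(flankRight) >= 20L,
             "flanks must be at least 20 bp")
  nl <- nchar(flankLeft)
  for (k in seq(min(kRange[2L], nl), kRange[1L])) {
    a <- splitChars(substr(flankLeft, nl - k + 1L, nl))
    b <- splitChars(substr(flankRight, 1L, k))
    mm <- sum(a != b)
    if (mm == 0L || (k >= 8L && mm <= 1L))
      return(list(length = k, motif = substr(flankRight, 1L, k)))
  }
  NULL
}

#' Heuristic solo-LTR check
#'
#' Flags a consensus as a candidate solitary LTR when it starts with
#' \code{TG}, ends with \code{CA}, contains the poly-adenylation signal
#' \code{AATAAA}, and (when flanks are given) is bracketed by a 4-6 bp
#' TSD.
#'
#' @param consensus DNA string.
#' @param flankLeft,flankRight Optional insertion flanks for the TSD
#'   check.
#' @return Logical.
#' @export
isSoloLTRCandidate <- function(consensus, flankLeft = NULL,
                               flankRight = NULL) {
  s <- toupper(consensus)
  n <- nchar(s)
  structural <- startsWith(s, "TG") && substr(s, n - 1L, n) == "CA" &&
    grepl("AATAAA", s, fixed = TRUE)
  if (!structural) return(FALSE)
  if (is.null(flankLeft) || is.null(flankRight)) return(TRUE)
  tsd <- detectTSD(flankLeft, flankRight, kRange = c(2L, 20L))
  !is.null(tsd) && tsd$length >= 4L && tsd$length <= 6L
}

#' Render a sequence logo of one signature end as SVG
#'
#' Standard logo convention: at each column the letters are stacked
#' with heights \eqn{p_b \times IC(column)} bits, most probable letter
#' on top.
#'
#' @param sig A \linkS4class{TerminiSignature}.
#' @param end Which profile to draw (\code{"five_prime"},
#'   \code{"three_prime"}, \code{"combined"}).
#' @param path Output SVG path.
#' @param colWidth Column width in px; the y axis spans 2 bits.
#' @return \code{path}, invisibly.
#' @export
renderLogo <- function(sig, end, path, colWidth = 12) {
  p <- sig@profiles[[end]]
  if (is.null(p)) stop("signature has no '", end, "' profile",
                       call. = FALSE)
  ic <- sig@informationContent[[end]]
  L <- nrow(p)
  H <- 120  # px for 2 bits
  letterCol <- c(A = "#109648", C = "#255c99", G = "#f7b32b", T = "#d62839")
  elems <- character()
  for (j in seq_len(L)) {
    ord <- order(p[j, ])  # draw small letters first (bottom of stack)
    y <- H
    for (b in DNA_BASES[ord]) {
      h <- p[j, b] * ic[j] / 2 * H
      if (h < 0.5) next
      y <- y - h
      elems <- c(elems, sprintf(
        paste0('<text x="%.1f" y="%.1f" font-family="monospace" ',
               'font-size="%.2fpx" textLength="%d" ',
               'lengthAdjust="spacingAndGlyphs" fill="%s" ',
               'transform="translate(0,%.2f) scale(1,%.4f) translate(0,%.2f)"',
               '>%s</text>'),
        (j - 1) * colWidth + 1, 0, colWidth * 1.4, colWidth - 2,
        letterCol[b], y + h, h / (colWidth * 1.4), -(y + h), b))
    }
  }
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    L * colWidth, H + 10), elems, "</svg>")
  writeLines(svg, path)
  invisible(path)
}
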