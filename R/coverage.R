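#' Coverage and alignment-quality summary of a seed alignment
#'
#' Computes per-column coverage (number of non-gap residues) and, for
#' every instance, fraction identity to the consensus over non-overlapping
#' windows of consensus positions. This is the data behind the seed
#' alignment heatmap view: coverage as a silhouette, quality as a
#' red-to-blue gradient per 10 bp window.
#'
#' @param aln A \linkS4class{SeedAlignment}.
#' @param consensus A \linkS4class{ConsensusCall} (its column map ties
#'   consensus positions to alignment columns), or a plain consensus
#'   string with one base per alignment column.
#' @param window Window width in consensus positions (default 10).
#' @return A list with \code{perColumnDepth} (integer per alignment
#'   column), \code{perWindowQuality} (instances x windows matrix of
#'   fraction identity; \code{NA} where the instance has no aligned
#'   residue in the window), \code{windowStarts} (1-based consensus
#'   position starting each window), and \code{consensusLength}.
#' @examples
#' aln <- SeedAlignment(c("ACGTACGTAC", "ACGTACGTAC"))
#' cq <- coverageQuality(aln, "ACGTACGTAC", window = 5)
#' cq$perWindowQuality
#' @export
coverageQuality <- function(aln, consensus, window = 10L) {
  stopifnot2(window >= 1L, "window must be >= 1")
  m <- alignmentMatrix(aln)
  if (is(consensus, "ConsensusCall")) {
    cseq <- splitChars(toupper(consensus@sequence))
    cmap <- consensus@columnMap
  } else {
    cseq0 <- splitChars(toupper(as.character(consensus)))
    if (length(cseq0) != ncol(m))
      stop("consensus length inconsistent with alignment columns; ",
           "pass a ConsensusCall or a per-column consensus string",
           call. = FALSE)
    keep <- cseq0 != "-"
    cseq <- cseq0[keep]
    cmap <- which(keep)
  }
  depth <- as.integer(colSums(m != "-"))
  npos <- length(cseq)
  nwin <- ceiling(npos / window)
  starts <- seq(1L, npos, by = window)
  sub <- m[, cmap, drop = FALSE]         # instance chars at consensus columns
  ng <- sub != "-"
  eq <- ng & (sub == matrix(cseq, nrow(m), npos, byrow = TRUE))
  q <- matrix(NA_real_, nInstances(aln), nwin,
              dimnames = list(aln@ids, NULL))
  for (w in seq_len(nwin)) {
    idx <- starts[w]:min(starts[w] + window - 1L, npos)
    al <- rowSums(ng[, idx, drop = FALSE])
    qw <- rowSums(eq[, idx, drop = FALSE]) / al
    qw[al == 0L] <- NA_real_
    q[, w] <- qw
  }
  list(perColumnDepth = depth, perWindowQuality = q,
       windowStarts = starts, consensusLength = npos)
}

# red (low) -> white -> blue (high) quality colour; NA cells grey
qualityColour <- function(q) {
  out <- rep("#dddddd", length(q))
  ok <- !is.na(q)
  if (any(ok)) {
    ramp <- grDevices::colorRamp(c("#d73027", "#fee090", "#4575b4"))
    m <- ramp(pmin(pmax(q[ok], 0), 1))
    out[ok] <- grDevices::rgb(m[, 1L], m[, 2L], m[, 3L],
                              maxColorValue = 255)
  }
  out
}

#' Render the seed-alignment coverage/quality view as SVG
#'
#' Draws a filled coverage silhouette over the alignment columns and,
#' below it, one row per instance sorted ascending by start column, with
#' one cell per window coloured red (low identity) to blue (high).
#'
#' @param prof Result of \code{\link{coverageQuality}} on \code{aln}.
#' @param aln The \linkS4class{SeedAlignment} the profile was computed
#'   from.
#' @param path Output SVG path.
#' @param cellWidth,cellHeight Cell size in px.
#' @return \code{path}, invisibly.
#' @export
renderAlignmentPlot <- function(prof, aln, path, cellWidth = 4,
                                cellHeight = 3) {
  q <- prof$perWindowQuality
  if (nrow(q) != nInstances(aln))
    stop("profile was not computed from this alignment", call. = FALSE)
  ord <- order(instanceRanges(aln)$startCol)
  nwin <- ncol(q)
  covH <- 40
  width <- nwin * cellWidth + 20
  height <- covH + 10 + nrow(q) * cellHeight + 10
  # coverage silhouette, averaged per window over consensus columns
  depth <- prof$perColumnDepth
  maxd <- max(depth, 1L)
  ws <- prof$windowStarts
  wwid <- if (length(ws) > 1L) ws[2L] - ws[1L] else prof$consensusLength
  winDepth <- vapply(seq_len(nwin), function(w) {
    idx <- ws[w]:min(ws[w] + wwid - 1L, prof$consensusLength)
    mean(depth[pmin(idx, length(depth))])
  }, numeric(1))
  xs <- (seq_len(nwin) - 0.5) * cellWidth + 10
  ys <- covH - (winDepth / maxd) * (covH - 2)
  poly <- paste(c(sprintf("%.1f,%.0f", xs[1], covH),
                  sprintf("%.1f,%.1f", xs, ys),
                  sprintf("%.1f,%.0f", xs[nwin], covH)), collapse = " ")
  rows <- character()
  y0 <- covH + 10
  cols <- matrix(qualityColour(as.vector(q[ord, , drop = FALSE])),
                 nrow = length(ord))
  for (i in seq_along(ord)) {
    present <- which(!is.na(q[ord[i], ]))
    if (!length(present)) next
    rows <- c(rows, sprintf(
      '<rect x="%.1f" y="%.1f" width="%d" height="%d" fill="%s"/>',
      10 + (present - 1L) * cellWidth, y0 + (i - 1L) * cellHeight,
      cellWidth, cellHeight, cols[i, present]))
  }
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   ceiling(width), ceiling(height)),
           sprintf('<polygon points="%s" fill="#1a9850" opacity="0.8"/>', poly),
           rows,
           '</svg>')
  writeLines(svg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
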