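#' Build a profile HMM from a seed alignment
#'
#' Columns whose occupancy is at least \code{symfrac} become match
#' states (the boundary is inclusive). Match and insert emissions are
#' pseudocounted against the uniform background,
#' \eqn{(counts + pc \cdot 0.25) / (total + pc)}; transitions are
#' estimated from the observed state path of each row with Laplace
#' smoothing. Rows are treated as fragments: leading and trailing gaps
#' contribute neither delete states nor begin/end transitions, matching
#' the glocal alignment semantics in which instances are fragments of a
#' full-length model. Sequence weighting is uniform.
#'
#' A consensus is called over the same alignment (match columns forced
#' into the consensus) so that every match state maps to exactly one
#' consensus position; the bijection is stored in the model.
#'
#' @param aln A \linkS4class{SeedAlignment}.
#' @param symfrac Occupancy threshold for match columns (default 0.5).
#' @param pseudocount Emission pseudocount mass (default 1.0).
#' @param matrix \linkS4class{SubstitutionMatrix} used for the paired
#'   consensus call; defaults to
#'   \code{neutralSubstitutionMatrix(0.2)}.
#' @param consensus Optional precomputed \linkS4class{ConsensusCall};
#'   it must cover every match column (build it with
#'   \code{forceColumns}).
#' @param name Model name.
#' @return A \linkS4class{ProfileHMM}.
#' @examples
#' aln <- SeedAlignment(rep("ACGT", 4))
#' hmm <- buildHMM(aln)
#' modelLength(hmm)
#' @export
buildHMM <- function(aln, symfrac = 0.5, pseudocount = 1.0,
                     matrix = neutralSubstitutionMatrix(0.2),
                     consensus = NULL, name = aln@familyName) {
  m <- alignmentMatrix(aln)
  nrow_ <- nrow(m)
  occ <- colSums(m != "-") / nrow_
  matchCols <- which(occ >= symfrac)
  if (!length(matchCols)) stop("zero match columns", call. = FALSE)
  L <- length(matchCols)
  bg <- rep(0.25, 4L)

  if (is.null(consensus))
    consensus <- callConsensus(aln, matrix, forceColumns = matchCols)
  cmap <- match(matchCols, consensus@columnMap)
  if (anyNA(cmap))
    stop("consensus does not cover every match column; ",
         "rebuild it with forceColumns = match columns", call. = FALSE)

  countBases <- function(cols) {
    if (!length(cols)) return(matrix(0, 4L, 1L, dimnames = list(DNA_BASES)))
    sub <- m[, cols, drop = FALSE]
    vapply(DNA_BASES, function(b) sum(sub == b), numeric(1))
  }
  mE <- t(vapply(matchCols, function(cl) {
    cnt <- vapply(DNA_BASES, function(b) sum(m[, cl] == b), numeric(1))
    (cnt + pseudocount * bg) / (sum(cnt) + pseudocount)
  }, numeric(4L)))
  colnames(mE) <- DNA_BASES

  # insert emissions: pooled over non-match columns between match k, k+1
  iE <- matrix(0.25, L, 4L, dimnames = list(NULL, DNA_BASES))
  for (k in seq_len(max(L - 1L, 0L))) {
    lo <- matchCols[k] + 1L
    hi <- matchCols[k + 1L] - 1L
    if (lo <= hi) {
      cnt <- countBases(lo:hi)
      if (sum(cnt) > 0)
        iE[k, ] <- (cnt + pseudocount * bg) / (sum(cnt) + pseudocount)
    }
  }

  # transition counts from per-row state paths within each row's span
  cM <- matrix(0, L, 3L, dimnames = list(NULL, c("MM", "MI", "MD")))
  cB <- c(BM = 0, BD = 0)
  cI <- matrix(0, L, 2L, dimnames = list(NULL, c("IM", "II")))
  cD <- matrix(0, L, 2L, dimnames = list(NULL, c("DM", "DD")))
  isMatch <- logical(ncol(m)); isMatch[matchCols] <- TRUE
  stateOf <- integer(ncol(m))          # match-state index per column
  stateOf[matchCols] <- seq_len(L)
  lastBefore <- cumsum(isMatch)        # match state at or before column
  rng <- instanceRanges(aln)
  for (r in seq_len(nrow_)) {
    span <- rng$startCol[r]:rng$endCol[r]
    prevKind <- "B"; prevK <- 0L
    firstMatchSeen <- FALSE
    for (cl in span) {
      ch <- m[r, cl]
      if (isMatch[cl]) {
        k <- stateOf[cl]
        kind <- if (ch == "-") "D" else "M"
        if (!firstMatchSeen) {
          firstMatchSeen <- TRUE
          if (k == 1L)  # row covers the model start: count B transition
            cB[if (kind == "M") "BM" else "BD"] <- cB[if (kind == "M") "BM" else "BD"] + 1
          prevKind <- kind; prevK <- k
          next
        }
        key <- paste0(prevKind, kind)
        if (prevKind == "M") cM[prevK, key] <- cM[prevK, key] + 1
        else if (prevKind == "I") {
          # I -> D is not representable in the Plan7-like graph; only
          # the I -> M transition is counted
          if (kind == "M") cI[prevK, "IM"] <- cI[prevK, "IM"] + 1
        } else cD[prevK, key] <- cD[prevK, key] + 1
        prevKind <- kind; prevK <- k
      } else if (ch != "-") {
        if (!firstMatchSeen) next  # residues before the first match column
        k <- lastBefore[cl]
        if (k >= L) next           # residues after the last match column
        if (prevKind == "I" && prevK == k) {
          cI[k, "II"] <- cI[k, "II"] + 1
        } else if (prevKind == "M" && prevK == k) {
          cM[k, "MI"] <- cM[k, "MI"] + 1
        } else next  # insert after a delete: not representable, skipped
        prevKind <- "I"; prevK <- k
      }
    }
  }

  # smoothing toward a sparse transition prior (one pseudo-observation
  # split 0.9/0.05/0.05): keeps match-to-match dominant even for
  # single-sequence models while still learning indel propensities
  smooth <- function(cnt, prior) (cnt + prior) / (sum(cnt) + sum(prior))
  tMat <- matrix(0, L + 1L, 3L, dimnames = list(NULL, c("MM", "MI", "MD")))
  b <- smooth(cB, c(0.9, 0.1))
  tMat[1L, ] <- c(b["BM"], 0, b["BD"])
  for (k in seq_len(L - 1L))
    tMat[k + 1L, ] <- smooth(cM[k, ], c(0.9, 0.05, 0.05))
  tMat[L + 1L, ] <- c(1, 0, 0)  # M_L -> E
  tIns <- matrix(0.5, L, 2L, dimnames = list(NULL, c("IM", "II")))
  tDel <- matrix(0.5, L, 2L, dimnames = list(NULL, c("DM", "DD")))
  for (k in seq_len(max(L - 1L, 0L))) {
    tIns[k, ] <- smooth(cI[k, ], c(0.5, 0.5))
    tDel[k, ] <- smooth(cD[k, ], c(0.5, 0.5))
  }
  tIns[L, ] <- c(1, 0)
  tDel[L, ] <- c(1, 0)  # D_L -> E

  new("ProfileHMM", modelLength = L, matchEmissions = mE,
      insertEmissions = iE, matchTransitions = tMat,
      insertTransitions = tIns, deleteTransitions = tDel,
      background = bg, consensusMap = as.integer(cmap),
      name = if (is.null(name) || !length(name)) NA_character_ else name)
}

#' Align a sequence to a profile HMM (Viterbi)
#'
#' Maximum log-odds glocal decoding: the model is traversed globally
#' (every match state visited or deleted) while the sequence is matched
#' locally; flanking sequence is emitted at background frequency and
#' contributes zero bits. \code{N} residues score zero bits in every
#' state.
#'
#' @param hmm A \linkS4class{ProfileHMM}.
#' @param seq DNA string over \code{A,C,G,T,N}.
#' @return A \linkS4class{ModelAlignment}.
#' @examples
#' aln <- SeedAlignment(rep("ACGTACGT", 5))
#' hmm <- buildHMM(aln)
#' viterbiAlign(hmm, "TTACGTACGTTT")
#' @export
viterbiAlign <- function(hmm, seq, .tables = NULL) {
  seq <- toupper(as.character(seq))
  stopifnot2(nchar(seq) > 0L, "sequence must be non-empty")
  si <- baseIndex(splitChars(seq))
  si[is.na(si)] <- 0L
  tb <- if (is.null(.tables)) hmmScoreTables(hmm) else .tables
  res <- .viterbi_cpp(as.integer(si), tb$mE, tb$iE, tb$tBM, tb$tBD,
                      tb$tM, tb$tI, tb$tD)
  kinds <- c("M", "I", "D")[res$kind]
  path <- data.frame(kind = kinds,
                     model = ifelse(kinds == "I", NA_integer_, res$model),
                     seqPos = res$seqpos)
  emitted <- path$seqPos[!is.na(path$seqPos)]
  new("ModelAlignment", path = path, score = res$score,
      seqStart = if (length(emitted)) min(emitted) else NA_integer_,
      seqEnd = if (length(emitted)) max(emitted) else NA_integer_,
      hmmName = hmm@name)
}

# precomputed log2-odds tables for repeated Viterbi calls on one model
hmmScoreTables <- function(hmm) {
  L <- hmm@modelLength
  log2s <- function(p) pmax(log2(p), SCORE_FLOOR)
  list(
    mE = log2s(sweep(hmm@matchEmissions, 2L, hmm@background, "/")),
    iE = log2s(sweep(hmm@insertEmissions, 2L, hmm@background, "/")),
    # rows of tM: out of M_k -> (M_{k+1}, I_k, D_{k+1})
    tM = log2s(cbind(hmm@matchTransitions[2:(L + 1L), 1L],
                     hmm@matchTransitions[1:L + 1L, 2L],
                     hmm@matchTransitions[1:L + 1L, 3L])),
    tI = log2s(hmm@insertTransitions),
    tD = log2s(hmm@deleteTransitions),
    tBM = log2s(hmm@matchTransitions[1L, 1L]),
    tBD = log2s(hmm@matchTransitions[1L, 3L]))
}

#' Project a model alignment onto consensus coordinates
#'
#' Maps every match-state visit through the model's consensus map,
#' yielding (consensus position, sequence position) pairs. Insert
#' states pair a sequence position with no consensus position; delete
#' states the converse. This is the correspondence that lets HMM and
#' consensus alignments of the same family be compared directly.
#'
#' @param hmm The \linkS4class{ProfileHMM} that produced \code{ma}.
#' @param ma A \linkS4class{ModelAlignment}.
#' @return data.frame with columns \code{consensusPos}, \code{seqPos}.
#' @export
projectAlignment <- function(hmm, ma) {
  if (!identical(ma@hmmName, hmm@name))
    stop("alignment was produced by a different model ('", ma@hmmName,
         "' vs '", hmm@name, "')", call. = FALSE)
  mi <- ma@path$model
  if (any(!is.na(mi) & (mi < 1L | mi > hmm@modelLength)))
    stop("alignment state indices exceed this model", call. = FALSE)
  cons <- ifelse(is.na(mi), NA_integer_, hmm@consensusMap[mi])
  data.frame(consensusPos = as.integer(cons), seqPos = ma@path$seqPos)
}

#' Write / read a profile HMM as text
#'
#' A documented HMMER3-like text layout (probabilities stored as
#' negative natural logs, one match state per block) for interchange
#' and storage. The layout is this package's own and is not bit-exact
#' HMMER; the format line says so.
#'
#' @param hmm A \linkS4class{ProfileHMM}.
#' @param path File path.
#' @param append Append to an existing file (for concatenated exports).
#' @return \code{path} (write) or a \linkS4class{ProfileHMM} (read).
#' @export
writeProfileHMM <- function(hmm, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  nl <- function(p) ifelse(p <= 0, "*", sprintf("%.17g", -log(p)))
  w <- function(...) writeLines(paste0(...), con)
  w("TEFAMKIT-HMM 1.0 [HMMER3-like layout; approximate interchange]")
  w("NAME  ", if (is.na(hmm@name)) "unnamed" else hmm@name)
  w("LENG  ", hmm@modelLength)
  w("ALPH  DNA")
  w("CMAP  ", paste(hmm@consensusMap, collapse = ","))
  w("HMM          A        C        G        T")
  L <- hmm@modelLength
  w("  COMPO  ", paste(nl(hmm@background), collapse = "  "))
  w("  BEGIN  ", paste(nl(hmm@matchTransitions[1L, c(1L, 3L)]),
                       collapse = "  "))
  for (k in seq_len(L)) {
    w(sprintf("%7d  %s", k, paste(nl(hmm@matchEmissions[k, ]),
                                  collapse = "  ")))
    w("         ", paste(nl(hmm@insertEmissions[k, ]), collapse = "  "))
    w("         ", paste(c(nl(hmm@matchTransitions[k + 1L, ]),
                           nl(hmm@insertTransitions[k, ]),
                           nl(hmm@deleteTransitions[k, ])), collapse = "  "))
  }
  w("//")
  invisible(path)
}

#' @rdname writeProfileHMM
#' @export
readProfileHMM <- function(path) {
  lines <- readLines(path, warn = FALSE)
  readProfileHMMLines(lines)
}

# parse one model from a character vector of lines
readProfileHMMLines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!grepl("^TEFAMKIT-HMM", lines[1L]))
    stop("not a tefamkit HMM file", call. = FALSE)
  field <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)[1L]
    trimws(sub(paste0("^", tag, "\\s+"), "", ln))
  }
  name <- field("NAME")
  L <- as.integer(field("LENG"))
  cmap <- as.integer(strsplit(field("CMAP"), ",")[[1L]])
  un <- function(tok) {
    v <- numeric(length(tok))
    num <- tok != "*"
    v[num] <- exp(-as.numeric(tok[num]))
    v
  }
  toks <- function(ln) strsplit(trimws(ln), "\\s+")[[1L]]
  i0 <- grep("^HMM\\s", lines)
  bg <- un(toks(lines[i0 + 1L])[-1L])
  beg <- un(toks(lines[i0 + 2L])[-1L])
  mE <- iE <- matrix(0, L, 4L, dimnames = list(NULL, DNA_BASES))
  tMat <- matrix(0, L + 1L, 3L, dimnames = list(NULL, c("MM", "MI", "MD")))
  tMat[1L, ] <- c(beg[1L], 0, beg[2L])
  tIns <- matrix(0, L, 2L, dimnames = list(NULL, c("IM", "II")))
  tDel <- matrix(0, L, 2L, dimnames = list(NULL, c("DM", "DD")))
  ln <- i0 + 3L
  for (k in seq_len(L)) {
    mE[k, ] <- un(toks(lines[ln])[-1L]); ln <- ln + 1L
    iE[k, ] <- un(toks(lines[ln])); ln <- ln + 1L
    tr <- un(toks(lines[ln])); ln <- ln + 1L
    tMat[k + 1L, ] <- tr[1:3]
    tIns[k, ] <- tr[4:5]
    tDel[k, ] <- tr[6:7]
  }
  new("ProfileHMM", modelLength = L, matchEmissions = mE,
      insertEmissions = iE, matchTransitions = tMat,
      insertTransitions = tIns, deleteTransitions = tDel,
      background = bg, consensusMap = cmap, name = name)
}
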