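# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results by exhaustive enumeration or
# direct arithmetic, sharing no code with the implementation paths they
# check.

# exhaustive argmax over the four candidate ancestral bases
oracleCallColumn <- function(counts, mat) {
  bases <- c("A", "C", "G", "T")
  sc <- vapply(bases, function(b) {
    s <- 0
    for (obs in names(counts)) s <- s + counts[[obs]] * mat@scores[b, obs]
    s
  }, numeric(1))
  list(base = bases[which.max(sc)], score = max(sc), all = sc)
}

# tie-aware comparison of a column call against the oracle: bases must
# agree unless the top two oracle scores tie to numerical precision, in
# which case score agreement suffices
expectColumnCallMatches <- function(cnt, mat) {
  got <- callColumn(cnt, mat)
  want <- oracleCallColumn(as.list(cnt), mat)
  gap <- diff(sort(want$all, decreasing = TRUE)[2:1])
  testthat::expect_equal(got$score, want$score, tolerance = 1e-9)
  if (abs(gap) > 1e-9) testthat::expect_identical(got$base, want$base)
}

# closed-form Kimura-style probabilities -> log-odds, written directly
# from the model definition: substitution mass d per site, transition:
# transversion weights 4:1:1, C->T / G->A transition weight multiplied
# by the bias with the per-site substitution mass held at d
oracleKimuraScores <- function(d, bias = 1) {
  bases <- c("A", "C", "G", "T")
  tsOf <- c(A = "G", C = "T", G = "A", T = "C")
  p <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (b in bases) {
    w <- if (b %in% c("C", "G")) bias else 1
    for (o in bases) p[b, o] <- d / (4 * w + 2)
    p[b, tsOf[b]] <- d * 4 * w / (4 * w + 2)
    p[b, b] <- 1 - d
  }
  pmax(log2(p / 0.25), -30)
}

# exhaustive argmax over all 16 ancestral dimers for a column pair;
# the (C,G) dimer is scored with CpG-elevated (renormalized) rows
oracleBestDimer <- function(colX, colY, mat) {
  bases <- c("A", "C", "G", "T")
  m <- mat@cpgMultiplier
  elevRow <- function(row, hot) {
    row[hot] <- row[hot] * m
    row <- row / sum(row)
    pmax(log2(row / 0.25), -30)
  }
  eC <- elevRow(mat@probs["C", ], "T")
  eG <- elevRow(mat@probs["G", ], "A")
  best <- -Inf; bestDimer <- NULL
  for (b1 in bases) for (b2 in bases) {
    s <- 0
    for (x in colX) if (x %in% bases)
      s <- s + if (b1 == "C" && b2 == "G") eC[x] else mat@scores[b1, x]
    for (y in colY) if (y %in% bases)
      s <- s + if (b1 == "C" && b2 == "G") eG[y] else mat@scores[b2, y]
    if (s > best) { best <- s; bestDimer <- c(b1, b2) }
  }
  list(dimer = bestDimer, score = best)
}

# exhaustive enumeration of every legal glocal path through a small
# profile HMM, sharing nothing with the dynamic program
oracleViterbi <- function(hmm, seq) {
  si <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  n <- length(si)
  L <- hmm@modelLength
  lg <- function(p) max(log2(p), -30)
  em <- function(k, i) if (is.na(si[i])) 0 else
    lg(hmm@matchEmissions[k, si[i]] / 0.25)
  ie <- function(k, i) if (is.na(si[i])) 0 else
    lg(hmm@insertEmissions[k, si[i]] / 0.25)
  tM <- hmm@matchTransitions; tI <- hmm@insertTransitions
  tD <- hmm@deleteTransitions
  best <- -Inf
  # recurse over (state kind, state index, next unconsumed seq position)
  rec <- function(kind, k, i, sc) {
    if (k == L) {
      # exit to E from M_L or D_L; trailing flank free
      best <<- max(best, sc)
      return(invisible())
    }
    if (kind == "M") {
      if (i <= n) rec("M", k + 1, i + 1,
                      sc + lg(tM[k + 1, "MM"]) + em(k + 1, i))
      rec("D", k + 1, i, sc + lg(tM[k + 1, "MD"]))
      if (k < L && i <= n)  # enter I_k
        recI(k, i, sc + lg(tM[k + 1, "MI"]) + ie(k, i))
    } else if (kind == "D") {
      if (i <= n) rec("M", k + 1, i + 1,
                      sc + lg(tD[k, "DM"]) + em(k + 1, i))
      rec("D", k + 1, i, sc + lg(tD[k, "DD"]))
    }
  }
  recI <- function(k, i, sc) {
    # currently in I_k having just emitted position i
    if (i + 1 <= n)
      recI(k, i + 1, sc + lg(tI[k, "II"]) + ie(k, i + 1))
    if (i + 1 <= n)
      rec("M", k + 1, i + 2, sc + lg(tI[k, "IM"]) + em(k + 1, i + 1))
  }
  for (start in 0:n) {
    # B after consuming `start` flank characters
    if (start + 1 <= n)
      rec("M", 1, start + 2, lg(tM[1, "MM"]) + em(1, start + 1))
    rec("D", 1, start + 1, lg(tM[1, "MD"]))
  }
  best
}

# random proper profile HMM for oracle comparisons
randomProfileHMM <- function(L) {
  rdist <- function(n) { x <- stats::runif(n) + 0.05; x / sum(x) }
  mE <- t(vapply(seq_len(L), function(k) rdist(4), numeric(4)))
  iE <- t(vapply(seq_len(L), function(k) rdist(4), numeric(4)))
  colnames(mE) <- colnames(iE) <- c("A", "C", "G", "T")
  tM <- matrix(0, L + 1, 3, dimnames = list(NULL, c("MM", "MI", "MD")))
  b <- rdist(2)
  tM[1, ] <- c(b[1], 0, b[2])
  for (k in seq_len(L - 1)) tM[k + 1, ] <- rdist(3)
  tM[L + 1, ] <- c(1, 0, 0)
  tI <- matrix(0.5, L, 2, dimnames = list(NULL, c("IM", "II")))
  tD <- matrix(0.5, L, 2, dimnames = list(NULL, c("DM", "DD")))
  for (k in seq_len(L - 1)) { tI[k, ] <- rdist(2); tD[k, ] <- rdist(2) }
  tI[L, ] <- c(1, 0); tD[L, ] <- c(1, 0)
  new("ProfileHMM", modelLength = as.integer(L), matchEmissions = mE,
      insertEmissions = iE, matchTransitions = tM,
      insertTransitions = tI, deleteTransitions = tD,
      background = rep(0.25, 4),
      consensusMap = seq_len(L), name = "random")
}

# per-base identity of two equal-length strings
strIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y)
}

# reconstruct a called consensus in ancestor coordinates using the
# simulator's RF annotation (ancestor columns marked 'x')
reconstructOnAncestor <- function(call, aln, ancestorLength) {
  rf <- strsplit(aln@referenceAnnotation, "")[[1]]
  ancCols <- which(rf == "x")
  c2a <- match(call@columnMap, ancCols)
  s <- strsplit(consensusSequence(call), "")[[1]]
  rec <- rep("-", ancestorLength)
  rec[c2a[!is.na(c2a)]] <- s[!is.na(c2a)]
  rec
}

# CpG dinucleotide start positions of a sequence string
cpgPositions <- function(s) {
  ch <- strsplit(s, "")[[1]]
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}
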