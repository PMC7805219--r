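SCORE_FLOOR <- -30  # bits; caps log-odds of vanishing probabilities

#' Neutral log-odds substitution matrix
#'
#' Builds a Kimura-style single-branch substitution probability matrix
#' at the given expected divergence with transition/transversion ratio
#' 2, applies the mammalian-style GC->AT transition asymmetry by
#' multiplying the C->T and G->A probabilities by \code{gcToAtBias} and
#' renormalizing those rows, and returns per-cell log2-odds against a
#' uniform 0.25 background. Scores are capped below at -30 bits so the
#' matrix stays finite.
#'
#' @param divergence Expected substitutions per site, in (0, 0.6].
#' @param gcToAtBias Multiplier (>= 1) on the C->T / G->A probabilities.
#' @param cpgMultiplier Elevation factor (>= 1) for transitions in CpG
#'   context; stored for use by the ancestral-CpG inference of
#'   \code{\link{callConsensus}}.
#' @return A \linkS4class{SubstitutionMatrix}.
#' @examples
#' neutralSubstitutionMatrix(0.2)
#' @export
neutralSubstitutionMatrix <- function(divergence, gcToAtBias = 2,
                                      cpgMultiplier = 10) {
  if (!is.numeric(divergence) || divergence <= 0 || divergence > 0.6)
    stop("divergence must be in (0, 0.6]", call. = FALSE)
  if (gcToAtBias < 1) stop("gcToAtBias must be >= 1", call. = FALSE)
  if (cpgMultiplier < 1) stop("cpgMultiplier must be >= 1", call. = FALSE)
  # substitution mass d per row split ts:tv = 2:1 (weights 4:1:1); the
  # GC->AT bias multiplies the C->T / G->A transition weight, keeping
  # the per-site substitution probability at the configured divergence
  transitionOf <- c(A = "G", C = "T", G = "A", T = "C")
  p <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (b in DNA_BASES) {
    w <- gcToAtBias^(b %in% c("C", "G"))
    p[b, ] <- divergence / (4 * w + 2)
    p[b, transitionOf[b]] <- divergence * 4 * w / (4 * w + 2)
    p[b, b] <- 1 - divergence
  }
  # keep the matrix diagonally dominant at extreme divergence
  p["C", "T"] <- min(p["C", "T"], p["C", "C"])
  p["G", "A"] <- min(p["G", "A"], p["G", "G"])
  p <- p / rowSums(p)
  sc <- pmax(log2(p / 0.25), SCORE_FLOOR)
  new("SubstitutionMatrix", scores = sc, probs = p, divergence = divergence,
      gcToAtBias = gcToAtBias, cpgMultiplier = cpgMultiplier)
}

# CpG-elevated substitution scores: the C->T (resp. G->A) probability
# is multiplied by the CpG factor and the whole row renormalized, so
# retained ancestral bases are penalized exactly as much as the decay
# model predicts.
cpgElevatedScores <- function(mat) {
  m <- mat@cpgMultiplier
  rowC <- mat@probs["C", ]
  rowC["T"] <- rowC["T"] * m
  rowC <- rowC / sum(rowC)
  rowG <- mat@probs["G", ]
  rowG["A"] <- rowG["A"] * m
  rowG <- rowG / sum(rowG)
  list(C = pmax(log2(rowC / 0.25), SCORE_FLOOR),
       G = pmax(log2(rowG / 0.25), SCORE_FLOOR))
}

#' Call the ancestral base of one alignment column
#'
#' Scores every candidate ancestral base b as
#' \eqn{\sum_{obs} counts[obs] \cdot S[b, obs]} and returns the argmax;
#' ties are broken in the fixed order A < C < G < T.
#'
#' @param counts Named integer vector of observed base counts
#'   (\code{A,C,G,T}; missing names count as 0).
#' @param matrix A \linkS4class{SubstitutionMatrix}.
#' @return List with \code{base} and \code{score} (bits).
#' @examples
#' m <- neutralSubstitutionMatrix(0.2)
#' callColumn(c(C = 3, T = 3), m)
#' @export
callColumn <- function(counts, matrix) {
  cnt <- setNames(numeric(4L), DNA_BASES)
  cnt[names(counts)[names(counts) %in% DNA_BASES]] <-
    counts[names(counts) %in% DNA_BASES]
  if (sum(cnt) <= 0)
    stop("empty column: no counted residues", call. = FALSE)
  sc <- as.vector(matrix@scores %*% cnt)
  # ties (to numerical precision) break in the fixed order A < C < G < T
  best <- which(sc >= max(sc) - 1e-9)[1L]
  list(base = DNA_BASES[best], score = sc[best])
}

#' Call a CpG-aware consensus from a seed alignment
#'
#' Columns with occupancy (fraction of rows with a non-gap residue)
#' below \code{minOccupancy} are excluded. Each retained column is
#' called independently with \code{\link{callColumn}}; a second pass
#' then infers ancestral CpG sites: for each pair of adjacent retained
#' columns the joint score of an ancestral \code{CG} dimer is computed
#' in which the deamination outcomes (observed \code{TG} and \code{CA}
#' dimers, i.e. C->T on the plus strand and G->A on the minus strand)
#' are scored at CpG-elevated transition rates (the multiplied rows
#' are renormalized, so retained ancestral bases are penalized exactly
#' as the decay model predicts). When the joint score exceeds the sum
#' of the two independent calls the pair is emitted as \code{C,G} and
#' recorded as a CpG site. A largely intact CpG cannot beat its own
#' independent \code{C,G} calls, so pairs already called \code{C,G}
#' are also recorded whenever at least one intact \code{CG} dimer is
#' observed -- any ancestral \code{CG} is a CpG site.
#'
#' @param aln A \linkS4class{SeedAlignment}.
#' @param matrix A \linkS4class{SubstitutionMatrix}; its
#'   \code{cpgMultiplier} drives the elevated rates.
#' @param minOccupancy Occupancy threshold for consensus columns
#'   (default 0.3; deliberately below the HMM match-state threshold so
#'   the consensus extends into lower-coverage flanks).
#' @param forceColumns Alignment columns retained regardless of
#'   occupancy (used to keep HMM match columns and consensus positions
#'   in one-to-one correspondence).
#' @return A \linkS4class{ConsensusCall}.
#' @examples
#' aln <- SeedAlignment(rep("ACGT", 10))
#' cc <- callConsensus(aln, neutralSubstitutionMatrix(0.2))
#' consensusSequence(cc); cpgSites(cc)
#' @export
callConsensus <- function(aln, matrix, minOccupancy = 0.3,
                          forceColumns = integer()) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  occ <- colSums(m != "-") / n
  # 4 x nCols base-count matrix, N and gaps excluded
  cnt <- t(vapply(DNA_BASES, function(b) colSums(m == b),
                  numeric(ncol(m))))
  keep <- which((occ >= minOccupancy |
                   seq_len(ncol(m)) %in% forceColumns) & colSums(cnt) > 0)
  if (!length(keep))
    stop("empty consensus: all columns below occupancy threshold",
         call. = FALSE)
  # all candidate-ancestor scores at once: 4 x npos
  allScores <- matrix@scores %*% cnt[, keep, drop = FALSE]
  bestIdx <- apply(allScores, 2L, function(s)
    which(s >= max(s) - 1e-9)[1L])  # ties: A < C < G < T
  base <- DNA_BASES[bestIdx]
  score <- allScores[cbind(bestIdx, seq_along(keep))]

  elev <- cpgElevatedScores(matrix)
  elevC <- as.vector(elev$C[DNA_BASES] %*% cnt[, keep, drop = FALSE])
  elevG <- as.vector(elev$G[DNA_BASES] %*% cnt[, keep, drop = FALSE])
  npos <- length(keep)
  cpg <- integer()
  i <- 1L
  while (i < npos) {
    ci <- keep[i]; cj <- keep[i + 1L]
    jointC <- elevC[i]
    jointG <- elevG[i + 1L]
    joint <- jointC + jointG
    indep <- score[i] + score[i + 1L]
    nCG <- sum(m[, ci] == "C" & m[, cj] == "G")
    if (joint > indep + 1e-9) {
      # decayed ancestral CpG recovered over the independent calls
      base[i] <- "C"; base[i + 1L] <- "G"
      score[i] <- jointC; score[i + 1L] <- jointG
      cpg <- c(cpg, i)
      i <- i + 2L
    } else if (base[i] == "C" && base[i + 1L] == "G" && nCG > 0) {
      # largely intact CpG: the joint hypothesis cannot beat the
      # independent C,G calls, but an observed CG dimer marks the site
      cpg <- c(cpg, i)
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  new("ConsensusCall", sequence = pasteChars(base),
      perPositionScore = as.numeric(score), cpgSites = as.integer(cpg),
      columnMap = as.integer(keep))
}

#' Plain majority-vote consensus (baseline)
#'
#' Per-column plurality call over the same retained columns as
#' \code{\link{callConsensus}}, with no substitution model and no CpG
#' inference. Ties go to the alphabetically first base. Provided as the
#' naive baseline a model-aware caller is compared against.
#'
#' @inheritParams callConsensus
#' @return A \linkS4class{ConsensusCall} with zero scores and no CpG
#'   sites.
#' @export
majorityConsensus <- function(aln, minOccupancy = 0.3) {
  m <- alignmentMatrix(aln)
  occ <- colSums(m != "-") / nrow(m)
  keep <- which(occ >= minOccupancy)
  keep <- keep[vapply(keep, function(cl) any(m[, cl] %in% DNA_BASES),
                      logical(1))]
  if (!length(keep))
    stop("empty consensus: all columns below occupancy threshold",
         call. = FALSE)
  base <- vapply(keep, function(cl) {
    cnt <- table(factor(m[, cl][m[, cl] %in% DNA_BASES], levels = DNA_BASES))
    DNA_BASES[which.max(cnt)]
  }, character(1))
  new("ConsensusCall", sequence = pasteChars(base),
      perPositionScore = numeric(length(keep)), cpgSites = integer(),
      columnMap = as.integer(keep))
}

#' Write a consensus report
#'
#' \code{writeConsensusFasta} writes the consensus as single-record
#' FASTA; \code{writeConsensusReport} writes a TSV of per-position
#' scores and CpG annotation for curator QC.
#'
#' @param cc A \linkS4class{ConsensusCall}.
#' @param path Output path.
#' @param name Record name.
#' @return \code{path}, invisibly.
#' @export
writeConsensusFasta <- function(cc, path, name = "consensus") {
  x <- Biostrings::DNAStringSet(cc@sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname writeConsensusFasta
#' @export
writeConsensusReport <- function(cc, path) {
  n <- nchar(cc@sequence)
  df <- data.frame(position = seq_len(n),
                   base = splitChars(cc@sequence),
                   column = cc@columnMap,
                   score_bits = round(cc@perPositionScore, 4),
                   cpg = seq_len(n) %in%
                     c(cc@cpgSites, cc@cpgSites + 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
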