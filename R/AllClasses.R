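#' @import methods
#' @importFrom stats setNames
#' @useDynLib tefamkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' SeedAlignment: a gap-aware multiple alignment of TE family instances
#'
#' The seed alignment is the single source of provenance for a family:
#' both the consensus sequence and the profile HMM are derived from it.
#' Rows are gapped strings over \code{A,C,G,T,N,-} of equal length; row
#' order is preserved exactly as read (sorting is a rendering concern).
#'
#' @slot familyName Family name.
#' @slot ids Character vector of instance identifiers, typically
#'   \code{genome:start-end:strand}.
#' @slot sequences Character vector of gapped rows, all of equal length.
#' @slot referenceAnnotation Optional RF-style column annotation string
#'   (same length as the rows) or \code{NA_character_}.
#' @export
setClass("SeedAlignment",
  representation(
    familyName = "character",
    ids = "character",
    sequences = "character",
    referenceAnnotation = "character"
  ),
  prototype(familyName = NA_character_, referenceAnnotation = NA_character_)
)

setValidity("SeedAlignment", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n < 1L) msg <- c(msg, "alignment must contain at least one instance")
  if (length(object@ids) != n)
    msg <- c(msg, "ids and sequences differ in length")
  w <- unique(nchar(object@sequences))
  if (length(w) > 1L)
    msg <- c(msg, "rows differ in length (ragged alignment)")
  if (n >= 1L) {
    bad <- grepl("[^ACGTNacgtn.-]", object@sequences)
    if (any(bad))
      msg <- c(msg, paste0("invalid characters in row(s): ",
                           paste(object@ids[bad], collapse = ", ")))
  }
  if (!is.na(object@referenceAnnotation) && length(w) == 1L &&
      nchar(object@referenceAnnotation) != w)
    msg <- c(msg, "reference annotation length differs from row length")
  if (length(msg)) msg else TRUE
})

#' Construct a SeedAlignment
#'
#' @param sequences Character vector of gapped rows (equal length;
#'   alphabet \code{A,C,G,T,N,-}; \code{.} is normalized to \code{-}).
#' @param ids Instance identifiers; defaults to \code{seq1, seq2, ...}.
#' @param familyName Optional family name.
#' @param referenceAnnotation Optional RF-style column string.
#' @return A \linkS4class{SeedAlignment}.
#' @examples
#' aln <- SeedAlignment(c("AC-T", "ACGT"))
#' nCols(aln)
#' @export
SeedAlignment <- function(sequences, ids = NULL, familyName = NA_character_,
                          referenceAnnotation = NA_character_) {
  sequences <- gsub(".", "-", as.character(sequences), fixed = TRUE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  new("SeedAlignment", familyName = familyName, ids = as.character(ids),
      sequences = sequences,
      referenceAnnotation = as.character(referenceAnnotation))
}

#' @describeIn SeedAlignment Number of alignment columns.
#' @param x,object A \code{SeedAlignment}.
#' @export
nCols <- function(x) nchar(x@sequences[1L])

#' @describeIn SeedAlignment Number of instances (rows).
#' @export
nInstances <- function(x) length(x@sequences)

#' @describeIn SeedAlignment Instance identifiers.
#' @export
instanceIds <- function(x) x@ids

#' @describeIn SeedAlignment Gapped row strings, named by id.
#' @export
alignedRows <- function(x) setNames(x@sequences, x@ids)

setMethod("show", "SeedAlignment", function(object) {
  cat("SeedAlignment",
      if (!is.na(object@familyName)) paste0(" '", object@familyName, "'"),
      ": ", nInstances(object), " instances x ", nCols(object),
      " columns\n", sep = "")
})

#' Per-instance span and character-matrix helpers
#'
#' \code{instanceRanges} reports, for every row, the first and last
#' aligned (non-gap) column as a 1-based closed interval.
#'
#' @param aln A \linkS4class{SeedAlignment}.
#' @return \code{instanceRanges}: data.frame with \code{id},
#'   \code{startCol}, \code{endCol} (1-based, inclusive).
#' @export
instanceRanges <- function(aln) {
  m <- alignmentMatrix(aln)
  ng <- m != "-"
  start <- apply(ng, 1L, function(r) which(r)[1L])
  end <- apply(ng, 1L, function(r) { w <- which(r); w[length(w)] })
  data.frame(id = aln@ids, startCol = as.integer(start),
             endCol = as.integer(end), stringsAsFactors = FALSE)
}

#' @describeIn instanceRanges Upper-case character matrix (rows x columns)
#'   view of the alignment.
#' @export
alignmentMatrix <- function(aln) {
  m <- matrix(unlist(strsplit(toupper(aln@sequences), "", fixed = FALSE),
                     use.names = FALSE),
              nrow = length(aln@sequences), byrow = TRUE)
  rownames(m) <- aln@ids
  m
}

#' SubstitutionMatrix: neutral log-odds substitution scores
#'
#' Log-odds (bits) scores for each (ancestral base, observed base) pair
#' under a neutral decay model, plus the underlying substitution
#' probabilities so that CpG-elevated variants can be derived from the
#' same parameterization.
#'
#' @slot scores 4x4 numeric matrix of log2-odds (rows ancestral, columns
#'   observed), dimnames \code{A,C,G,T}.
#' @slot probs 4x4 row-stochastic substitution probability matrix.
#' @slot divergence Expected substitutions per site used to build it.
#' @slot gcToAtBias Multiplier applied to C->T and G->A probabilities.
#' @slot cpgMultiplier Elevation factor for CpG-context transitions.
#' @export
setClass("SubstitutionMatrix",
  representation(scores = "matrix", probs = "matrix", divergence = "numeric",
                 gcToAtBias = "numeric", cpgMultiplier = "numeric"))

setValidity("SubstitutionMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (!all(dim(s) == c(4L, 4L))) msg <- c(msg, "scores must be 4x4")
  if (any(!is.finite(s))) msg <- c(msg, "scores must be finite")
  if (all(dim(s) == c(4L, 4L))) {
    d <- diag(s)
    if (any(d < apply(s, 1L, max)))
      msg <- c(msg, "diagonal must be the per-row maximum")
  }
  p <- object@probs
  if (any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "probability rows must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubstitutionMatrix", function(object) {
  cat("SubstitutionMatrix (bits): divergence=", object@divergence,
      ", GC->AT bias=", object@gcToAtBias,
      ", CpG multiplier=", object@cpgMultiplier, "\n", sep = "")
  print(round(object@scores, 3))
})

#' ConsensusCall: a called consensus with provenance
#'
#' @slot sequence Ungapped consensus string.
#' @slot perPositionScore Bits of the winning call at each position.
#' @slot cpgSites 1-based positions of the C of each inferred ancestral
#'   CpG dinucleotide.
#' @slot columnMap 1-based alignment column backing each consensus
#'   position.
#' @export
setClass("ConsensusCall",
  representation(sequence = "character", perPositionScore = "numeric",
                 cpgSites = "integer", columnMap = "integer"))

setValidity("ConsensusCall", function(object) {
  msg <- character()
  n <- nchar(object@sequence)
  if (length(object@columnMap) != n)
    msg <- c(msg, "columnMap length must equal consensus length")
  if (length(object@perPositionScore) != n)
    msg <- c(msg, "perPositionScore length must equal consensus length")
  if (length(object@cpgSites)) {
    ch <- strsplit(object@sequence, "")[[1L]]
    ok <- object@cpgSites >= 1L & object@cpgSites < n &
      ch[object@cpgSites] == "C" & ch[object@cpgSites + 1L] == "G"
    if (!all(ok)) msg <- c(msg, "cpgSites must point at C of a CG dimer")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusCall", function(object) {
  cat("ConsensusCall: ", nchar(object@sequence), " bp, ",
      length(object@cpgSites), " inferred ancestral CpG site(s)\n", sep = "")
})

#' @describeIn ConsensusCall The consensus string.
#' @param x A \code{ConsensusCall}.
#' @export
consensusSequence <- function(x) x@sequence

#' @describeIn ConsensusCall Inferred ancestral CpG positions (1-based,
#'   position of the C).
#' @export
cpgSites <- function(x) x@cpgSites

#' @describeIn ConsensusCall Alignment column behind each consensus
#'   position.
#' @export
consensusColumnMap <- function(x) x@columnMap

#' ProfileHMM: profile hidden Markov model of a TE family
#'
#' Plan7-like nucleotide profile HMM without the multi-hit (J) state:
#' model-global, sequence-local ("glocal") alignment semantics, matching
#' how fragmentary TE instances relate to a full-length family model.
#' A bijective map between match states and consensus positions is kept
#' so alignments against the HMM and against the consensus can be
#' compared directly.
#'
#' @slot modelLength Number of match states L.
#' @slot matchEmissions L x 4 row-stochastic emission table.
#' @slot insertEmissions L x 4 row-stochastic emission table (insert
#'   state after each match state; the final row is unused).
#' @slot matchTransitions (L+1) x 3 matrix, columns \code{MM,MI,MD}; row
#'   1 holds the begin-state transitions (B->M1 / B->D1, MI unused), row
#'   k+1 the transitions out of match state k. Row L+1 column MM is the
#'   exit M_L -> E.
#' @slot insertTransitions L x 2 matrix, columns \code{IM,II}.
#' @slot deleteTransitions L x 2 matrix, columns \code{DM,DD}; row L
#'   column DM is the exit D_L -> E.
#' @slot background Length-4 background distribution.
#' @slot consensusMap Integer vector: consensus position of each match
#'   state (1-based).
#' @slot name Model name.
#' @export
setClass("ProfileHMM",
  representation(modelLength = "integer", matchEmissions = "matrix",
                 insertEmissions = "matrix", matchTransitions = "matrix",
                 insertTransitions = "matrix", deleteTransitions = "matrix",
                 background = "numeric", consensusMap = "integer",
                 name = "character"))

setValidity("ProfileHMM", function(object) {
  msg <- character()
  L <- object@modelLength
  tol <- 1e-9
  if (nrow(object@matchEmissions) != L || nrow(object@insertEmissions) != L)
    msg <- c(msg, "emission tables must have L rows")
  if (any(abs(rowSums(object@matchEmissions) - 1) > tol))
    msg <- c(msg, "match emission rows must sum to 1")
  if (any(abs(rowSums(object@insertEmissions) - 1) > tol))
    msg <- c(msg, "insert emission rows must sum to 1")
  if (nrow(object@matchTransitions) != L + 1L)
    msg <- c(msg, "matchTransitions must have L+1 rows")
  else {
    if (abs(sum(object@matchTransitions[1L, c(1L, 3L)]) - 1) > tol)
      msg <- c(msg, "begin transitions must sum to 1")
    if (L > 1L &&
        any(abs(rowSums(object@matchTransitions[2:L, , drop = FALSE]) - 1) >
            tol))
      msg <- c(msg, "match transition rows must sum to 1")
    if (abs(object@matchTransitions[L + 1L, 1L] - 1) > tol)
      msg <- c(msg, "final match state must exit to E")
  }
  if (L > 1L) {
    it <- object@insertTransitions[seq_len(L - 1L), , drop = FALSE]
    if (any(abs(rowSums(it) - 1) > tol))
      msg <- c(msg, "insert transition rows must sum to 1")
    dt <- object@deleteTransitions[seq_len(L - 1L), , drop = FALSE]
    if (any(abs(rowSums(dt) - 1) > tol))
      msg <- c(msg, "delete transition rows must sum to 1")
  }
  if (length(object@consensusMap) != L)
    msg <- c(msg, "consensusMap must cover all match states")
  else if (anyDuplicated(object@consensusMap))
    msg <- c(msg, "consensusMap must be injective")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM",
      if (!is.na(object@name)) paste0(" '", object@name, "'"), ": ",
      object@modelLength, " match states\n", sep = "")
})

#' @describeIn ProfileHMM Number of match states.
#' @param x A \code{ProfileHMM}.
#' @export
modelLength <- function(x) x@modelLength

#' @describeIn ProfileHMM Match-state to consensus-position map.
#' @export
consensusMap <- function(x) x@consensusMap

#' ModelAlignment: one sequence aligned to a ProfileHMM
#'
#' @slot path data.frame with columns \code{kind} ("M","I","D"),
#'   \code{model} (match-state index; NA for I), \code{seqPos}
#'   (1-based sequence position; NA for D).
#' @slot score Bit score of the alignment.
#' @slot seqStart,seqEnd First/last aligned sequence positions (1-based).
#' @slot hmmName Name of the model that produced the alignment.
#' @export
setClass("ModelAlignment",
  representation(path = "data.frame", score = "numeric",
                 seqStart = "integer", seqEnd = "integer",
                 hmmName = "character"))

setMethod("show", "ModelAlignment", function(object) {
  cat("ModelAlignment: score ", round(object@score, 2), " bits, sequence ",
      object@seqStart, "-", object@seqEnd, "\n", sep = "")
})

#' TerminiSignature: terminal-sequence profile of a class II category
#'
#' Ungapped position probability profiles of the 5' and 3' termini (and
#' optionally the combined profile: 5' rows pooled with
#' reverse-complemented 3' rows) of the family consensi in one
#' classification category, with per-column information content and the
#' category's expected target site duplication.
#'
#' @slot category Classification path of the category.
#' @slot profiles Named list (\code{five_prime}, \code{three_prime},
#'   optionally \code{combined}) of L x 4 probability matrices.
#' @slot informationContent Named list of per-column bits, same names.
#' @slot tsdExpectation List with \code{min}, \code{max}, \code{motif}.
#' @slot nFamilies Number of source families behind the profiles.
#' @export
setClass("TerminiSignature",
  representation(category = "character", profiles = "list",
                 informationContent = "list", tsdExpectation = "list",
                 nFamilies = "integer"))

setValidity("TerminiSignature", function(object) {
  msg <- character()
  for (end in names(object@profiles)) {
    p <- object@profiles[[end]]
    if (any(abs(rowSums(p) - 1) > 1e-9))
      msg <- c(msg, paste0(end, ": profile rows must sum to 1"))
    ic <- object@informationContent[[end]]
    if (is.null(ic) || length(ic) != nrow(p))
      msg <- c(msg, paste0(end, ": information content length mismatch"))
    else if (any(ic < -1e-9 | ic > 2 + 1e-9))
      msg <- c(msg, paste0(end, ": information content outside [0,2] bits"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TerminiSignature", function(object) {
  cat("TerminiSignature ", object@category, ": ends {",
      paste(names(object@profiles), collapse = ", "), "}, ",
      object@nFamilies, " families\n", sep = "")
})

#' ClassificationTree: unranked TE classification with path strings
#'
#' Nodes are addressed by concatenating names along the path from the
#' (virtual) root, joined with \code{';'}. Node names may repeat in
#' different subtrees, so resolution always uses the full path. The tree
#' is unranked: no node carries a rank label.
#'
#' @slot nodes data.frame with \code{id}, \code{name}, \code{parent}
#'   (id; NA for the virtual root), \code{path}.
#' @slot aliases data.frame with \code{id}, \code{system}, \code{label}
#'   mapping nodes to equivalent labels in other classification systems.
#' @export
setClass("ClassificationTree",
  representation(nodes = "data.frame", aliases = "data.frame"))

setMethod("show", "ClassificationTree", function(object) {
  cat("ClassificationTree: ", nrow(object@nodes) - 1L, " nodes, ",
      nrow(object@aliases), " cross-system aliases\n", sep = "")
})

#' TEFamily: a TE family record
#'
#' @slot accession DF (curated) or DR (uncurated) accession with
#'   version, e.g. \code{DR0000001.1}.
#' @slot name Family name.
#' @slot consensus Ungapped consensus sequence.
#' @slot hmm A \linkS4class{ProfileHMM} or \code{NULL}.
#' @slot classification Classification path string.
#' @slot cladeTaxa Integer taxonomy ids the family is assigned to.
#' @slot curated Logical; must agree with the accession prefix.
#' @slot metadata Named list (description, citations, date, ...).
#' @export
setClass("TEFamily",
  representation(accession = "character", name = "character",
                 consensus = "character", hmm = "ANY",
                 classification = "character", cladeTaxa = "integer",
                 curated = "logical", metadata = "list"))

ACCESSION_RE <- "^D[FR][0-9]{7}\\.[0-9]+$"

setValidity("TEFamily", function(object) {
  msg <- character()
  if (!is.na(object@accession)) {
    if (!grepl(ACCESSION_RE, object@accession))
      msg <- c(msg, "accession must match D[FR]NNNNNNN.V")
    else {
      pre <- substr(object@accession, 1L, 2L)
      if ((pre == "DF") != object@curated)
        msg <- c(msg, "accession prefix inconsistent with curated flag")
    }
  }
  if (!nzchar(object@consensus) || is.na(object@consensus))
    msg <- c(msg, "consensus must be non-empty")
  if (!is.null(object@hmm) && !is(object@hmm, "ProfileHMM"))
    msg <- c(msg, "hmm must be a ProfileHMM or NULL")
  if (length(msg)) msg else TRUE
})

#' Construct a TEFamily
#'
#' @param consensus Ungapped consensus sequence (required).
#' @param name Family name.
#' @param accession Accession (\code{DFnnnnnnn.v} / \code{DRnnnnnnn.v});
#'   \code{NA} to let the store auto-assign the next DR number.
#' @param hmm Optional \linkS4class{ProfileHMM}.
#' @param classification Classification path string.
#' @param cladeTaxa Taxonomy ids.
#' @param curated Curated (DF) or uncurated (DR) family.
#' @param metadata Named list of free metadata.
#' @return A \linkS4class{TEFamily}.
#' @export
TEFamily <- function(consensus, name = NA_character_,
                     accession = NA_character_, hmm = NULL,
                     classification = "Interspersed_Repeat;Unknown",
                     cladeTaxa = integer(), curated = FALSE,
                     metadata = list()) {
  new("TEFamily", accession = accession, name = name,
      consensus = toupper(consensus), hmm = hmm,
      classification = classification,
      cladeTaxa = as.integer(cladeTaxa), curated = curated,
      metadata = metadata)
}

setMethod("show", "TEFamily", function(object) {
  cat("TEFamily ", object@accession, " (", object@name, "): ",
      nchar(object@consensus), " bp consensus, ",
      if (is.null(object@hmm)) "no HMM" else "with HMM",
      "; ", object@classification, "\n", sep = "")
})

#' TandemAnnotation: tandemly repetitive content of a sequence
#'
#' @slot intervals data.frame with \code{start}, \code{end} (1-based,
#'   inclusive), \code{period}, \code{identity}.
#' @slot tandemFraction Fraction of positions covered by any interval.
#' @slot longestClearRun Longest run (bp) free of tandem annotation.
#' @slot seqLength Length of the annotated sequence.
#' @export
setClass("TandemAnnotation",
  representation(intervals = "data.frame", tandemFraction = "numeric",
                 longestClearRun = "integer", seqLength = "integer"))

setMethod("show", "TandemAnnotation", function(object) {
  cat("TandemAnnotation: ", nrow(object@intervals), " interval(s), ",
      round(100 * object@tandemFraction, 1), "% tandem, clear run ",
      object@longestClearRun, " bp of ", object@seqLength, "\n", sep = "")
})

#' FamDB: taxonomy-indexed family store backed by HDF5
#'
#' An offline container holding TE families (consensus, optional profile
#' HMM, classification, metadata) together with an embedded organismal
#' taxonomy, indexed for fast clade queries. The live handle keeps its
#' tables in an environment; \code{\link{famdbFlush}} persists them to
#' the HDF5 file.
#'
#' @slot path Path of the backing HDF5 file.
#' @slot env Environment holding the in-memory tables and indexes.
#' @export
setClass("FamDB", representation(path = "character", env = "environment"))

setMethod("show", "FamDB", function(object) {
  cat("FamDB <", object@path, ">: ", object@env$nFamilies,
      " families, ", nrow(object@env$taxonomy), " taxa\n", sep = "")
})
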