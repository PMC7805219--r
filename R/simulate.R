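#' Specify one simulated TE family
#'
#' Defaults describe a typical young class II (TIR) family: a 1000 bp
#' ancestor, 50 genomic copies related to it by a star phylogeny, 15
#' percent mean divergence with transition/transversion ratio 2,
#' 10-fold elevated CpG transitions and a 2-fold GC->AT transition
#' bias.
#'
#' @param name Family name.
#' @param kind One of \code{"class2_tir"}, \code{"class1_line"},
#'   \code{"ltr"}, \code{"solo_ltr"}.
#' @param ancestralLength Ancestor length in bp.
#' @param copyNumber Number of genomic copies.
#' @param meanDivergence Expected substitutions per site per copy.
#' @param cpgMultiplier Fold elevation of CpG-context transitions.
#' @param gcToAtBias Fold elevation of C->T / G->A transitions.
#' @param tsdLength Target site duplication length; \code{NA} for the
#'   kind's default (fixed 8 for TIR, variable 5-15 for LINEs, 4-6 for
#'   LTR kinds).
#' @param truncation \code{"none"} or \code{"five_prime_geometric"}
#'   (LINE-style 5' truncation).
#' @param truncationP Geometric parameter of the truncated-length
#'   distribution (mean truncation 1/p bp).
#' @param subfamilyCount Number of subfamily clusters (class I master
#'   lineage); 1 means a pure star.
#' @param indelRate Indel events per substitution (default 0.1).
#' @param tirLength Terminal inverted repeat length for
#'   \code{class2_tir}.
#' @return A validated family spec (list).
#' @export
familySpec <- function(name, kind = c("class2_tir", "class1_line", "ltr",
                                      "solo_ltr"),
                       ancestralLength = 1000L, copyNumber = 50L,
                       meanDivergence = 0.15, cpgMultiplier = 10,
                       gcToAtBias = 2, tsdLength = NA_integer_,
                       truncation = c("none", "five_prime_geometric"),
                       truncationP = 0.005, subfamilyCount = 1L,
                       indelRate = 0.1, tirLength = 15L) {
  kind <- match.arg(kind)
  truncation <- match.arg(truncation)
  stopifnot2(meanDivergence >= 0 && meanDivergence <= 0.6,
             "meanDivergence must be in [0, 0.6]")
  stopifnot2(copyNumber >= 1L, "copyNumber must be >= 1")
  stopifnot2(ancestralLength >= 50L, "ancestralLength must be >= 50")
  list(name = name, kind = kind, ancestralLength = ancestralLength,
       copyNumber = copyNumber, meanDivergence = meanDivergence,
       cpgMultiplier = cpgMultiplier, gcToAtBias = gcToAtBias,
       tsdLength = tsdLength, truncation = truncation,
       truncationP = truncationP, subfamilyCount = subfamilyCount,
       indelRate = indelRate, tirLength = tirLength)
}

#' Simulation configuration
#'
#' The default configuration holds five families of 50 copies each --
#' two TIR transposons, a 5'-truncating LINE with two subfamilies, a
#' full-length LTR element and a solo LTR -- inserted into a neutral
#' background genome.
#'
#' @param seed Integer seed fixing all randomness.
#' @param genomeLength Background genome length in bp.
#' @param families List of \code{\link{familySpec}}.
#' @return A validated config (list).
#' @export
simConfig <- function(seed = 1L,
                      genomeLength = 300000L,
                      families = list(
                        familySpec("TIR1", "class2_tir",
                                   ancestralLength = 600L,
                                   meanDivergence = 0.10, tsdLength = 8L),
                        familySpec("TIR2", "class2_tir",
                                   ancestralLength = 500L,
                                   meanDivergence = 0.15, tsdLength = 4L),
                        familySpec("LINE1", "class1_line",
                                   ancestralLength = 1200L,
                                   meanDivergence = 0.12,
                                   truncation = "five_prime_geometric",
                                   subfamilyCount = 2L),
                        familySpec("LTR1", "ltr", ancestralLength = 800L,
                                   meanDivergence = 0.12),
                        familySpec("SOLO1", "solo_ltr",
                                   ancestralLength = 350L,
                                   meanDivergence = 0.10))) {
  stopifnot2(is.numeric(seed) && length(seed) == 1L, "seed must be scalar")
  list(seed = as.integer(seed), genomeLength = as.integer(genomeLength),
       families = families)
}

# ancestor with kind-specific structural features
makeAncestor <- function(spec) {
  L <- spec$ancestralLength
  s <- randomDNA(L)
  sub <- function(s, at, what)
    paste0(substr(s, 1L, at - 1L), what,
           substr(s, at + nchar(what), nchar(s)))
  if (spec$kind == "class2_tir") {
    tir <- randomDNA(spec$tirLength)
    s <- sub(s, 1L, tir)
    s <- sub(s, L - spec$tirLength + 1L, revComp(tir))
  } else if (spec$kind == "class1_line") {
    s <- sub(s, L - 11L, strrep("A", 12L))       # poly-A tail
  } else if (spec$kind == "solo_ltr") {
    s <- sub(s, 1L, "TG")
    s <- sub(s, L - 1L, "CA")
    s <- sub(s, max(3L, L - 40L), "AATAAA")      # poly-adenylation signal
  } else if (spec$kind == "ltr") {
    ltr <- paste0("TG", randomDNA(146L), "CA")   # identical 150 bp LTRs
    core <- randomDNA(max(L - 300L, 20L))
    s <- paste0(ltr, core, ltr)
    s <- sub(s, nchar(s) - 40L, "AATAAA")
  }
  s
}

# substitution outcome probabilities per ancestor position:
# Kimura-style ts/tv = 2, GC->AT bias, CpG-context transitions at a
# hazard-elevated rate q = 1 - exp(-mult * r_ts)
mutationProbs <- function(anc, spec) {
  d <- spec$meanDivergence
  L <- nchar(anc)
  ch <- splitChars(anc)
  bi <- baseIndex(ch)
  base <- neutralSubstitutionMatrix(max(d, 1e-6), spec$gcToAtBias, 1)@probs
  P <- base[ifelse(is.na(bi), 1L, bi), , drop = FALSE]  # L x 4
  isCpG <- c(ch[-L] == "C" & ch[-1L] == "G", FALSE)     # C of CpG
  isGpC <- c(FALSE, isCpG[-L])                          # G of CpG
  # CpG transitions: the baseline (unbiased) transition rate elevated
  # by the multiplier on the hazard scale, so the probability
  # saturates below 1; the multiplier is defined against baseline
  # transitions, not on top of the GC->AT bias, to avoid
  # double-counting deamination
  b <- spec$gcToAtBias
  pTs0 <- 2 / 3 * d
  tv <- d / (4 * b + 2)
  q <- 1 - exp(-spec$cpgMultiplier * -log(max(1 - pTs0, 1e-12)))
  q <- min(q, 0.95, 1 - 2 * tv - 0.02)
  P[isCpG, ] <- matrix(c(tv, 1 - q - 2 * tv, tv, q), sum(isCpG), 4L,
                       byrow = TRUE)                    # C row: A C G T
  P[isGpC, ] <- matrix(c(q, tv, 1 - q - 2 * tv, tv), sum(isGpC), 4L,
                       byrow = TRUE)                    # G row
  P[is.na(bi), ] <- 0
  P[is.na(bi), 1L] <- 1  # N treated as A for mutation bookkeeping
  list(P = P, chars = ch)
}

# one mutated copy; returns chars (possibly '-') per ancestor position,
# insertions as list(position -> string), and the subs count
mutateCopy <- function(probs, spec, protect = integer()) {
  L <- nrow(probs$P)
  cum <- t(apply(probs$P, 1L, cumsum))
  u <- stats::runif(L)
  out <- DNA_BASES[max.col(u <= cum, ties.method = "first")]
  out[protect] <- probs$chars[protect]
  nonACGT <- is.na(baseIndex(probs$chars))
  out[nonACGT] <- probs$chars[nonACGT]
  # indels: geometric lengths (mean 1.7), rate indelRate per substitution
  nIndel <- stats::rpois(1L, spec$indelRate * spec$meanDivergence * L)
  ins <- list()
  if (nIndel > 0L) {
    at <- sample.int(L, nIndel, replace = FALSE)
    for (k in seq_len(nIndel)) {
      len <- stats::rgeom(1L, 1 / 1.7) + 1L
      if (stats::runif(1L) < 0.5) {
        lo <- at[k]; hi <- min(L, at[k] + len - 1L)
        del <- setdiff(lo:hi, protect)
        out[del] <- "-"
      } else {
        ins[[as.character(at[k])]] <- randomDNA(len)
      }
    }
  }
  list(chars = out, ins = ins)
}

# assemble star/subfamily copies of one family into a ground-truth MSA
simulateFamily <- function(spec) {
  anc <- makeAncestor(spec)
  L <- nchar(anc)
  nSub <- max(1L, spec$subfamilyCount)
  # class I: master lineage accumulates diagnostic mutations shared by
  # all later subfamilies; those sites are protected from re-mutation so
  # they co-segregate perfectly with the subfamily labels
  subAncestors <- list(anc)
  diagnostic <- integer()
  if (spec$kind == "class1_line" && nSub > 1L) {
    cur <- anc
    for (s in 2:nSub) {
      nDiag <- max(3L, round(0.005 * L))
      at <- sample(setdiff(seq_len(L), diagnostic), nDiag)
      ch <- splitChars(cur)
      for (i in at) {
        alt <- setdiff(DNA_BASES, ch[i])
        ch[i] <- sample(alt, 1L)
      }
      cur <- pasteChars(ch)
      diagnostic <- c(diagnostic, at)
      subAncestors[[s]] <- cur
    }
  }
  subfamilyOf <- sort(rep_len(seq_len(nSub), spec$copyNumber))
  copies <- vector("list", spec$copyNumber)
  for (i in seq_len(spec$copyNumber)) {
    src <- subAncestors[[subfamilyOf[i]]]
    probs <- mutationProbs(src, spec)
    cp <- mutateCopy(probs, spec, protect = diagnostic)
    if (spec$truncation == "five_prime_geometric") {
      t <- min(stats::rgeom(1L, spec$truncationP), L - 30L)
      if (t > 0L) cp$chars[seq_len(t)] <- "-"
      cp$ins <- cp$ins[as.integer(names(cp$ins)) > t]
    }
    copies[[i]] <- cp
  }
  # MSA columns: one per ancestor position plus per-anchor insert blocks
  insLens <- integer(L + 1L)  # insert block width after position k
  for (cp in copies)
    for (k in names(cp$ins)) {
      ki <- as.integer(k)
      insLens[ki + 1L] <- max(insLens[ki + 1L], nchar(cp$ins[[k]]))
    }
  rows <- character(spec$copyNumber)
  for (i in seq_len(spec$copyNumber)) {
    cp <- copies[[i]]
    parts <- character(L)
    for (p in seq_len(L)) {
      insHere <- cp$ins[[as.character(p)]]
      blk <- if (insLens[p + 1L] > 0L) {
        istr <- if (is.null(insHere)) "" else insHere
        paste0(istr, strrep("-", insLens[p + 1L] - nchar(istr)))
      } else ""
      parts[p] <- paste0(cp$chars[p], blk)
    }
    rows[i] <- paste(parts, collapse = "")
  }
  rf <- paste(vapply(seq_len(L), function(p)
    paste0("x", strrep(".", insLens[p + 1L])), character(1)),
    collapse = "")
  list(ancestor = anc, rows = rows, subfamilyOf = subfamilyOf,
       diagnostic = sort(diagnostic), rf = rf)
}

#' Simulate a genome with TE families and ground truth
#'
#' Generates each family's ancestor with its kind's structural
#' features (terminal inverted repeats; LINE poly-A tail and 5'
#' truncation; identical 150 bp LTRs; solo LTRs with TG...CA termini
#' and a poly-adenylation signal), evolves copies under neutral decay
#' -- class II copies independently from the ancestor (star phylogeny),
#' class I along a master lineage with co-segregating diagnostic
#' mutations -- and inserts them into an i.i.d. background genome with
#' kind-appropriate target site duplications on random strands.
#'
#' @param config A \code{\link{simConfig}}.
#' @return List with \code{genome} (DNA string) and \code{truth},
#'   itself a list: \code{ancestralSequences} (named character),
#'   \code{seedAlignments} (named list of
#'   \linkS4class{SeedAlignment}, rows in ancestor orientation),
#'   \code{insertions} (data.frame with family, start, end (1-based
#'   inclusive), strand, subfamily, tsd), \code{subfamilyOf},
#'   \code{diagnosticSites}.
#' @examples
#' sim <- simulateTE(simConfig(seed = 42, genomeLength = 20000L,
#'   families = list(familySpec("toy", ancestralLength = 200L,
#'                              copyNumber = 5L))))
#' nchar(sim$genome)
#' @export
simulateTE <- function(config) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  fams <- lapply(config$families, simulateFamily)
  names(fams) <- vapply(config$families, `[[`, character(1), "name")

  # per-copy ungapped sequences and TSD lengths
  pieces <- list()
  for (fi in seq_along(fams)) {
    spec <- config$families[[fi]]
    fam <- fams[[fi]]
    for (ci in seq_along(fam$rows)) {
      seqc <- gsub("-", "", fam$rows[ci], fixed = TRUE)
      tsdLen <- if (!is.na(spec$tsdLength)) spec$tsdLength
        else switch(spec$kind,
                    class2_tir = 8L,
                    class1_line = sample(5:15, 1L),
                    ltr = sample(4:6, 1L),
                    solo_ltr = sample(4:6, 1L))
      pieces[[length(pieces) + 1L]] <- list(
        family = names(fams)[fi], copy = ci, seq = seqc,
        strand = sample(c("+", "-"), 1L), tsdLen = tsdLen,
        subfamily = fam$subfamilyOf[ci])
    }
  }
  totalTE <- sum(vapply(pieces, function(p)
    nchar(p$seq) + p$tsdLen, numeric(1)))
  bgLen <- config$genomeLength - totalTE
  minGap <- 30L
  if (bgLen < (length(pieces) + 1L) * minGap)
    stop("infeasible packing: genome too short for the requested ",
         "insertions", call. = FALSE)
  # insertion points in background coordinates, then assemble
  pieces <- pieces[sample.int(length(pieces))]
  cuts <- sort(sample.int(bgLen - 2L * minGap, length(pieces))) + minGap
  if (anyDuplicated(cuts) || any(diff(cuts) < 1L))
    cuts <- cumsum(rep(floor(bgLen / (length(pieces) + 1L)),
                       length(pieces)))
  bg <- randomDNA(bgLen)
  out <- character()
  ins <- list()
  prev <- 0L
  offset <- 0L  # accumulated inserted length
  for (k in seq_along(pieces)) {
    p <- pieces[[k]]
    left <- substr(bg, prev + 1L, cuts[k])
    tsd <- substr(bg, cuts[k] - p$tsdLen + 1L, cuts[k])
    body <- if (p$strand == "+") p$seq else revComp(p$seq)
    out <- c(out, left, body, tsd)
    start <- cuts[k] + offset + 1L
    ins[[k]] <- data.frame(family = p$family, copy = p$copy,
                           start = start,
                           end = start + nchar(body) - 1L,
                           strand = p$strand, subfamily = p$subfamily,
                           tsd = tsd, tsdLength = p$tsdLen)
    offset <- offset + nchar(body) + p$tsdLen
    prev <- cuts[k]
  }
  out <- c(out, substr(bg, prev + 1L, bgLen))
  genome <- paste(out, collapse = "")
  insertions <- do.call(rbind, ins)
  insertions <- insertions[order(insertions$start), , drop = FALSE]
  rownames(insertions) <- NULL

  seedAlignments <- lapply(names(fams), function(fn) {
    fam <- fams[[fn]]
    idx <- which(insertions$family == fn)
    ids <- sprintf("genome:%d-%d:%s",
                   insertions$start[idx][order(insertions$copy[idx])],
                   insertions$end[idx][order(insertions$copy[idx])],
                   insertions$strand[idx][order(insertions$copy[idx])])
    SeedAlignment(fam$rows, ids = ids, familyName = fn,
                  referenceAnnotation = gsub(".", "-", fam$rf,
                                             fixed = TRUE))
  })
  names(seedAlignments) <- names(fams)

  list(genome = genome,
       truth = list(
         ancestralSequences = vapply(fams, `[[`, character(1), "ancestor"),
         seedAlignments = seedAlignments,
         insertions = insertions,
         subfamilyOf = lapply(fams, `[[`, "subfamilyOf"),
         diagnosticSites = lapply(fams, `[[`, "diagnostic")))
}

#' Write simulation fixtures to disk
#'
#' Emits the genome (FASTA), instance intervals (BED, 0-based
#' half-open, with strand), one Stockholm seed alignment per family,
#' the ancestors (FASTA) and the insertion truth table (TSV).
#'
#' @param sim Result of \code{\link{simulateTE}}.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
emitFixtures <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  g <- Biostrings::DNAStringSet(sim$genome)
  names(g) <- "genome"
  paths$genome <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(g, paths$genome)
  a <- Biostrings::DNAStringSet(sim$truth$ancestralSequences)
  paths$ancestors <- file.path(outdir, "ancestors.fa")
  Biostrings::writeXStringSet(a, paths$ancestors)
  ins <- sim$truth$insertions
  bed <- data.frame(chrom = "genome", start = ins$start - 1L,
                    end = ins$end,
                    name = paste0(ins$family, "_", ins$copy),
                    score = 0L, strand = ins$strand)
  paths$bed <- file.path(outdir, "instances.bed")
  utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$truth <- file.path(outdir, "insertions.tsv")
  utils::write.table(ins, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (fn in names(sim$truth$seedAlignments)) {
    p <- file.path(outdir, paste0(fn, ".stk"))
    writeStockholm(sim$truth$seedAlignments[[fn]], p)
    paths[[paste0("seed_", fn)]] <- p
  }
  invisible(paths)
}

#' Simulate class II termini categories for classification experiments
#'
#' Draws \code{nCategories} unrelated TIR-style terminus pairs (3'
#' terminus = reverse complement of the first \code{tirLength} bp of
#' the 5' terminus, then independent sequence), and for each category
#' \code{familiesPerCategory} family consensi whose termini are the
#' category termini mutated at \code{terminusDivergence} around a
#' random internal core.
#'
#' @param nCategories Number of categories.
#' @param familiesPerCategory Families per category.
#' @param terminusDivergence Per-family terminus divergence.
#' @param L Terminus length (default 60).
#' @param coreLength Internal core length of each family consensus.
#' @param tirLength TIR length within the termini.
#' @return List with \code{categories} (character) and \code{families}
#'   (data.frame: \code{category}, \code{family}, \code{consensus}).
#' @export
simulateTerminiLibrary <- function(nCategories = 5L,
                                   familiesPerCategory = 20L,
                                   terminusDivergence = 0.10, L = 60L,
                                   coreLength = 150L, tirLength = 15L) {
  mutateStr <- function(s, d) {
    ch <- splitChars(s)
    hit <- stats::runif(length(ch)) < d
    ch[hit] <- vapply(which(hit), function(i)
      sample(setdiff(DNA_BASES, ch[i]), 1L), character(1))
    pasteChars(ch)
  }
  cats <- sprintf(
    "Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;SimCat%02d",
    seq_len(nCategories))
  fams <- list()
  for (c in seq_len(nCategories)) {
    five <- randomDNA(L)
    tir <- substr(five, 1L, tirLength)
    three <- paste0(randomDNA(L - tirLength), revComp(tir))
    for (f in seq_len(familiesPerCategory)) {
      cons <- paste0(mutateStr(five, terminusDivergence),
                     randomDNA(coreLength),
                     mutateStr(three, terminusDivergence))
      fams[[length(fams) + 1L]] <- data.frame(
        category = cats[c], family = sprintf("sim%02d_%02d", c, f),
        consensus = cons)
    }
  }
  list(categories = cats, families = do.call(rbind, fams))
}
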