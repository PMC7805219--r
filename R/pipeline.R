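# scan both strands of a genome against one model in overlapping
# windows, returning candidate hits (genome plus-strand coordinates)
# with their model alignments and the oriented window text
gatherInstances <- function(hmm, genome, minBits) {
  Lc <- max(consensusMap(hmm))
  win <- 2L * Lc + 100L
  stride <- Lc + 50L
  n <- nchar(genome)
  hits <- list()
  tables <- hmmScoreTables(hmm)
  scan <- function(seqStr, strand) {
    starts <- unique(c(seq(1L, max(n - win + 1L, 1L), by = stride),
                       max(n - win + 1L, 1L)))
    for (s in starts) {
      chunk <- substr(seqStr, s, min(s + win - 1L, n))
      ma <- viterbiAlign(hmm, chunk, .tables = tables)
      if (is.na(ma@seqStart) || ma@score < minBits) next
      a <- s + ma@seqStart - 1L  # oriented coordinates
      b <- s + ma@seqEnd - 1L
      hits[[length(hits) + 1L]] <<- list(
        start = if (strand == "+") a else n - b + 1L,
        end = if (strand == "+") b else n - a + 1L,
        strand = strand, score = ma@score, ma = ma, chunk = chunk)
    }
  }
  scan(genome, "+")
  scan(revComp(genome), "-")
  if (!length(hits)) return(hits)
  # windows overlap: drop duplicate detections of the same locus
  ord <- order(vapply(hits, `[[`, numeric(1), "score"), decreasing = TRUE)
  kept <- list()
  for (h in hits[ord]) {
    dup <- any(vapply(kept, function(k)
      min(k$end, h$end) - max(k$start, h$start) >= 0.5 * (h$end - h$start),
      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- h
  }
  kept
}

# seed alignment in consensus coordinates from accepted hits; rows are
# model-oriented, ids carry genome coordinates and strand
seedFromHits <- function(hmm, hits, familyName) {
  Lc <- max(consensusMap(hmm))
  rows <- character(0)
  ids <- character(0)
  for (h in hits) {
    pr <- projectAlignment(hmm, h$ma)
    pr <- pr[!is.na(pr$consensusPos) & !is.na(pr$seqPos), , drop = FALSE]
    row <- rep("-", Lc)
    row[pr$consensusPos] <- splitChars(h$chunk)[pr$seqPos]
    rows <- c(rows, pasteChars(row))
    ids <- c(ids, sprintf("genome:%d-%d:%s", h$start, h$end, h$strand))
  }
  SeedAlignment(rows, ids = ids, familyName = familyName)
}

#' Uncurated-library import pipeline
#'
#' Runs the intake steps applied to de novo family libraries before
#' they enter the store as uncurated (DR) families: the tandem-repeat
#' import filter; optionally, instance gathering against a genome by
#' glocal profile-HMM alignment with single assignment (each genome
#' interval is given to its best-scoring family only; ties go to the
#' lexicographically first family name) and seed-alignment
#' construction; CpG-aware consensus and profile HMM building from the
#' seed alignment; optional termini classification; and persistence.
#' Per-family failures are logged in the report and skipped; the batch
#' never aborts.
#'
#' @param libraryFasta FASTA of candidate family consensi.
#' @param genomeFasta Optional genome FASTA for instance gathering;
#'   \code{NULL} uses each library consensus as a single-row seed.
#' @param storePath Path for the FamDB HDF5 store (created).
#' @param taxonomy Taxonomy for the store (default: a minimal 1-node
#'   taxonomy).
#' @param cladeTaxa Taxonomy ids assigned to imported families.
#' @param terminiLibrary Optional list of
#'   \linkS4class{TerminiSignature} for classification.
#' @param divergence Divergence of the consensus-calling substitution
#'   model.
#' @param minBitsPerPosition Instance acceptance threshold in bits per
#'   model position (default 0.2).
#' @param reportPath Optional TSV report path.
#' @return List with \code{store} (a \linkS4class{FamDB}),
#'   \code{report} (data.frame, one row per input family) and
#'   \code{seeds} (the seed alignment built for each processed family;
#'   instance ids carry genome coordinates and strand).
#' @export
pipelineUncuratedImport <- function(libraryFasta, genomeFasta = NULL,
                                    storePath,
                                    taxonomy = data.frame(
                                      tax_id = 1L,
                                      parent_id = NA_integer_,
                                      name = "root",
                                      rank = "no_rank"),
                                    cladeTaxa = taxonomy$tax_id[1L],
                                    terminiLibrary = NULL,
                                    divergence = 0.2,
                                    minBitsPerPosition = 0.2,
                                    reportPath = NULL) {
  lib <- Biostrings::readDNAStringSet(libraryFasta)
  stopifnot2(length(lib) > 0L, "library is empty")
  genome <- if (!is.null(genomeFasta))
    as.character(Biostrings::readDNAStringSet(genomeFasta)[[1L]])
  else NULL
  mat <- neutralSubstitutionMatrix(divergence)
  store <- famdbCreate(storePath, taxonomy)
  report <- list()
  note <- function(family, decision, ...) {
    extra <- list(...)
    data.frame(family = family, decision = decision,
               tandem_fraction = extra$tf %||% NA_real_,
               clear_run = extra$cr %||% NA_integer_,
               n_instances = extra$ni %||% NA_integer_,
               accession = extra$acc %||% NA_character_,
               classification = extra$cls %||% NA_character_,
               stringsAsFactors = FALSE)
  }

  # pass 1: tandem filter + models from library consensi
  kept <- list()
  for (i in seq_along(lib)) {
    nm <- strsplit(names(lib)[i], "\\s+")[[1L]][1L]
    cons <- as.character(lib[[i]])
    tf <- tryCatch(tandemImportFilter(cons), error = function(e) NULL)
    if (is.null(tf)) {
      report[[nm]] <- note(nm, "error_tandem_filter")
      next
    }
    if (!tf$keep) {
      report[[nm]] <- note(nm, "dropped_tandem", tf = tf$tandemFraction,
                           cr = tf$longestClearRun)
      next
    }
    kept[[nm]] <- list(consensus = cons, tf = tf)
  }

  # pass 2: instance gathering with single assignment
  assigned <- list()
  if (!is.null(genome) && length(kept)) {
    allHits <- list()
    for (nm in names(kept)) {
      hmm0 <- tryCatch(
        buildHMM(SeedAlignment(kept[[nm]]$consensus, ids = nm,
                               familyName = nm),
                 matrix = mat, name = nm),
        error = function(e) NULL)
      if (is.null(hmm0)) next
      kept[[nm]]$hmm0 <- hmm0
      hs <- gatherInstances(hmm0, genome,
                            minBits = minBitsPerPosition *
                              modelLength(hmm0))
      for (h in hs) {
        h$family <- nm
        allHits[[length(allHits) + 1L]] <- h
      }
    }
    if (length(allHits)) {
      sc <- vapply(allHits, `[[`, numeric(1), "score")
      fm <- vapply(allHits, `[[`, character(1), "family")
      ord <- order(-sc, fm)  # ties: lexicographically first family
      accepted <- list()
      for (h in allHits[ord]) {
        clash <- any(vapply(accepted, function(a)
          min(a$end, h$end) >= max(a$start, h$start), logical(1)))
        if (!clash) accepted[[length(accepted) + 1L]] <- h
      }
      assigned <- split(accepted,
                        vapply(accepted, `[[`, character(1), "family"))
    }
  }

  # pass 3: seed, consensus, HMM, classification, store
  seeds <- list()
  for (nm in names(kept)) {
    res <- tryCatch({
      hits <- assigned[[nm]]
      aln <- if (!is.null(hits) && length(hits) >= 2L)
        seedFromHits(kept[[nm]]$hmm0, hits, nm)
      else
        SeedAlignment(kept[[nm]]$consensus, ids = nm, familyName = nm)
      seeds[[nm]] <- aln
      m <- alignmentMatrix(aln)
      matchCols <- which(colSums(m != "-") / nrow(m) >= 0.5)
      cc <- callConsensus(aln, mat, forceColumns = matchCols)
      hmm <- buildHMM(aln, matrix = mat, consensus = cc, name = nm)
      cls <- "Interspersed_Repeat;Unknown"
      if (!is.null(terminiLibrary)) {
        th <- classifyByTermini(consensusSequence(cc), terminiLibrary)
        if (nrow(th)) cls <- th$category[1L]
      }
      fam <- TEFamily(consensusSequence(cc), name = nm,
                      classification = cls, cladeTaxa = cladeTaxa,
                      curated = FALSE,
                      metadata = list(
                        description = "uncurated import",
                        n_seed_instances = nInstances(aln)))
      fam@hmm <- hmm
      acc <- famdbAddFamily(store, fam)
      note(nm, "stored", tf = kept[[nm]]$tf$tandemFraction,
           cr = kept[[nm]]$tf$longestClearRun, ni = nInstances(aln),
           acc = acc, cls = cls)
    }, error = function(e)
      note(nm, paste0("error: ", conditionMessage(e))))
    report[[nm]] <- res
  }
  famdbFlush(store)
  rep <- do.call(rbind, report)
  rownames(rep) <- NULL
  rep <- rep[order(rep$family), , drop = FALSE]
  if (!is.null(reportPath))
    utils::write.table(rep, reportPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(store = store, report = rep, seeds = seeds)
}
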