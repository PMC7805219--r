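FAMDB_LAYOUT_VERSION <- "tefamkit-famdb-1.0"

validateTaxonomy <- function(taxonomy) {
  need <- c("tax_id", "parent_id", "name")
  stopifnot2(all(need %in% names(taxonomy)),
             "taxonomy needs tax_id, parent_id, name columns")
  if (!"rank" %in% names(taxonomy)) taxonomy$rank <- NA_character_
  if (anyDuplicated(taxonomy$tax_id))
    stop("invalid taxonomy: duplicate tax_id", call. = FALSE)
  roots <- taxonomy$tax_id[is.na(taxonomy$parent_id) |
                             taxonomy$parent_id == taxonomy$tax_id]
  if (length(roots) != 1L)
    stop("invalid taxonomy: expected exactly one root, found ",
         length(roots), call. = FALSE)
  if (!all(taxonomy$parent_id[!is.na(taxonomy$parent_id)] %in%
             taxonomy$tax_id))
    stop("invalid taxonomy: parent_id not in taxonomy", call. = FALSE)
  # integer-indexed ancestry of every node; also proves acyclicity
  n <- nrow(taxonomy)
  pidx <- match(taxonomy$parent_id, taxonomy$tax_id)  # NA at the root
  pidx[!is.na(pidx) & pidx == seq_len(n)] <- NA_integer_
  anc <- vector("list", n)
  state <- integer(n)  # 0 unvisited, 1 in progress, 2 done
  for (s in seq_len(n)) {
    if (state[s] == 2L) next
    stack <- s
    while (length(stack)) {
      i <- stack[length(stack)]
      p <- pidx[i]
      if (is.na(p)) {
        anc[[i]] <- taxonomy$tax_id[i]
        state[i] <- 2L
        stack <- stack[-length(stack)]
      } else if (state[p] == 2L) {
        anc[[i]] <- c(taxonomy$tax_id[i], anc[[p]])
        state[i] <- 2L
        stack <- stack[-length(stack)]
      } else {
        if (state[p] == 1L)
          stop("invalid taxonomy: cycle detected at tax_id ",
               taxonomy$tax_id[i], call. = FALSE)
        state[i] <- 1L
        stack <- c(stack, p)
      }
    }
  }
  names(anc) <- as.character(taxonomy$tax_id)
  list(taxonomy = taxonomy, ancestors = anc)
}

newFamdbEnv <- function(taxonomy) {
  v <- validateTaxonomy(taxonomy)
  e <- new.env(parent = emptyenv())
  e$taxonomy <- v$taxonomy
  # hashed lookups keep query time independent of store size
  e$ancestors <- list2env(v$ancestors, hash = TRUE,
                          parent = emptyenv())
  kids <- split(v$taxonomy$tax_id,
                factor(v$taxonomy$parent_id, levels = v$taxonomy$tax_id))
  names(kids) <- as.character(v$taxonomy$tax_id)
  e$children <- list2env(kids, hash = TRUE, parent = emptyenv())
  e$families <- new.env(hash = TRUE, parent = emptyenv())
  e$taxIndex <- new.env(hash = TRUE, parent = emptyenv())
  e$nFamilies <- 0L
  e$nameIndex <- NULL          # built lazily from taxon names
  e$nextDR <- 1L
  e
}

envGet <- function(env, key) {
  if (exists(key, envir = env, inherits = FALSE))
    get(key, envir = env, inherits = FALSE) else NULL
}

#' Create a FamDB store
#'
#' Creates a new taxonomy-indexed family store. The taxonomy is
#' immutable per store; root paths are precomputed at creation so that
#' ancestor queries cost O(depth). The on-disk HDF5 layout (groups for
#' families, taxonomy, and the taxon-to-accession and
#' name-token-to-taxon indexes, versioned in a root attribute) is this
#' package's own; it honors the FamDB contracts -- offline, HDF5,
#' taxonomy-aware, query time independent of store size -- without
#' copying any external layout.
#'
#' @param path Path of the HDF5 file to create (overwritten).
#' @param taxonomy data.frame with \code{tax_id}, \code{parent_id},
#'   \code{name} and optional \code{rank}; exactly one root (parent
#'   missing or self-referential); acyclic.
#' @return A \linkS4class{FamDB} handle.
#' @seealso \code{\link{famdbAddFamily}}, \code{\link{famdbFlush}},
#'   \code{\link{famdbOpen}}
#' @export
famdbCreate <- function(path, taxonomy) {
  store <- new("FamDB", path = path, env = newFamdbEnv(taxonomy))
  famdbFlush(store)
  store
}

#' Add a family to a FamDB store
#'
#' When the family has no accession, the next free DR (uncurated)
#' number is auto-assigned with version .1; explicit accessions must
#' be unused. Every taxon in \code{cladeTaxa} must exist in the
#' store's taxonomy; the taxon index is updated for each. Call
#' \code{\link{famdbFlush}} to persist.
#'
#' @param store A \linkS4class{FamDB}.
#' @param fam A \linkS4class{TEFamily}.
#' @return The accession actually used.
#' @export
famdbAddFamily <- function(store, fam) {
  e <- store@env
  if (is.na(fam@accession)) {
    acc <- sprintf("DR%07d.1", e$nextDR)
    e$nextDR <- e$nextDR + 1L
    fam@accession <- acc
    fam@curated <- FALSE
  } else {
    acc <- fam@accession
    if (!grepl(ACCESSION_RE, acc))
      stop("invalid accession '", acc, "'", call. = FALSE)
    if (!is.null(envGet(e$families, acc)))
      stop("duplicate accession '", acc, "'", call. = FALSE)
    num <- as.integer(substr(acc, 3L, 9L))
    if (startsWith(acc, "DR")) e$nextDR <- max(e$nextDR, num + 1L)
  }
  validObject(fam)
  missing <- setdiff(fam@cladeTaxa, e$taxonomy$tax_id)
  if (length(missing))
    stop("taxon ", paste(missing, collapse = ","),
         " absent from taxonomy", call. = FALSE)
  assign(acc, fam, envir = e$families)
  e$nFamilies <- e$nFamilies + 1L
  for (t in as.character(fam@cladeTaxa))
    assign(t, c(envGet(e$taxIndex, t), acc), envir = e$taxIndex)
  acc
}

#' @describeIn famdbAddFamily Fetch one family by accession.
#' @param accession Family accession.
#' @export
famdbGetFamily <- function(store, accession) {
  f <- envGet(store@env$families, accession)
  if (is.null(f)) stop("no family '", accession, "'", call. = FALSE)
  f
}

#' Query families by taxon
#'
#' Returns the families indexed on a taxonomy node, optionally
#' including those indexed on its root-path ancestors (repeats that
#' predate the clade) and/or on its whole subtree. Results are
#' duplicate-free and in deterministic accession order.
#'
#' @param store A \linkS4class{FamDB}.
#' @param taxId Taxonomy id to query.
#' @param includeAncestors Include families of root-path ancestors.
#' @param includeDescendants Include families of the subtree.
#' @return List of \linkS4class{TEFamily}.
#' @export
familiesForTaxon <- function(store, taxId, includeAncestors = FALSE,
                             includeDescendants = FALSE) {
  e <- store@env
  key <- as.character(taxId)
  if (is.null(envGet(e$ancestors, key)))
    stop("unknown tax_id ", taxId, call. = FALSE)
  nodes <- taxId
  if (includeAncestors) nodes <- c(nodes, envGet(e$ancestors, key))
  if (includeDescendants) {
    stack <- taxId
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      kids <- setdiff(envGet(e$children, as.character(cur)), cur)
      nodes <- c(nodes, kids)
      stack <- c(stack, kids)
    }
  }
  hits <- lapply(as.character(unique(nodes)), envGet, env = e$taxIndex)
  accs <- sort(unique(as.character(unlist(hits, use.names = FALSE))))
  setNames(lapply(accs, famdbGetFamily, store = store), accs)
}

#' Look up taxa by name token
#'
#' Case-insensitive whole-token search over taxonomy names (the
#' name-token index of the store).
#'
#' @param store A \linkS4class{FamDB}.
#' @param token Name token, e.g. \code{"homo"}.
#' @return Integer tax_ids.
#' @export
taxaByName <- function(store, token) {
  e <- store@env
  if (is.null(e$nameIndex)) {
    toks <- strsplit(tolower(e$taxonomy$name), "[^a-z0-9]+")
    e$nameIndex <- data.frame(
      token = unlist(toks),
      tax_id = rep(e$taxonomy$tax_id, lengths(toks)))
    e$nameIndex <- e$nameIndex[nzchar(e$nameIndex$token), ]
  }
  sort(unique(e$nameIndex$tax_id[e$nameIndex$token == tolower(token)]))
}

hmmToList <- function(h) {
  list(modelLength = h@modelLength, matchEmissions = h@matchEmissions,
       insertEmissions = h@insertEmissions,
       matchTransitions = h@matchTransitions,
       insertTransitions = h@insertTransitions,
       deleteTransitions = h@deleteTransitions,
       background = h@background, consensusMap = h@consensusMap,
       name = if (is.na(h@name)) "unnamed" else h@name)
}

hmmFromList <- function(x) {
  dimn <- function(m, cn) { colnames(m) <- cn; m }
  new("ProfileHMM", modelLength = as.integer(x$modelLength),
      matchEmissions = dimn(x$matchEmissions, DNA_BASES),
      insertEmissions = dimn(x$insertEmissions, DNA_BASES),
      matchTransitions = dimn(x$matchTransitions, c("MM", "MI", "MD")),
      insertTransitions = dimn(x$insertTransitions, c("IM", "II")),
      deleteTransitions = dimn(x$deleteTransitions, c("DM", "DD")),
      background = as.numeric(x$background),
      consensusMap = as.integer(x$consensusMap),
      name = as.character(x$name))
}

#' Persist / reopen a FamDB store
#'
#' \code{famdbFlush} writes the in-memory tables to the backing HDF5
#' file (layout version in the root attribute \code{famdb_layout});
#' \code{famdbOpen} reads a store back into memory.
#'
#' @param store A \linkS4class{FamDB}.
#' @param path HDF5 file path.
#' @return \code{famdbFlush}: the store, invisibly. \code{famdbOpen}:
#'   a \linkS4class{FamDB}.
#' @export
famdbFlush <- function(store) {
  e <- store@env
  path <- store@path
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(FAMDB_LAYOUT_VERSION, fid, "famdb_layout")
  rhdf5::h5createGroup(fid, "taxonomy")
  tx <- e$taxonomy
  rhdf5::h5write(as.integer(tx$tax_id), fid, "taxonomy/tax_id")
  rhdf5::h5write(as.integer(ifelse(is.na(tx$parent_id), tx$tax_id,
                                   tx$parent_id)),
                 fid, "taxonomy/parent_id")
  rhdf5::h5write(as.character(tx$name), fid, "taxonomy/name")
  rhdf5::h5write(as.character(ifelse(is.na(tx$rank), "", tx$rank)),
                 fid, "taxonomy/rank")
  rhdf5::h5createGroup(fid, "families")
  accs <- sort(ls(e$families))
  fams <- mget(accs, envir = e$families)
  col <- function(f) vapply(fams, f, character(1), USE.NAMES = FALSE)
  if (length(fams)) {
    rhdf5::h5write(accs, fid, "families/accession")
    rhdf5::h5write(col(function(f) f@name %||% ""), fid, "families/name")
    rhdf5::h5write(col(function(f) f@consensus), fid, "families/consensus")
    rhdf5::h5write(col(function(f) f@classification %||% ""), fid,
                   "families/classification")
    rhdf5::h5write(vapply(fams, function(f) f@curated, logical(1),
                          USE.NAMES = FALSE),
                   fid, "families/curated")
    rhdf5::h5write(col(function(f)
      jsonlite::toJSON(f@metadata, auto_unbox = TRUE)), fid,
      "families/metadata")
    rhdf5::h5write(col(function(f)
      paste(f@cladeTaxa, collapse = ",")), fid, "families/clade_taxa")
    withHmm <- accs[vapply(fams, function(f) !is.null(f@hmm), logical(1),
                           USE.NAMES = FALSE)]
    rhdf5::h5createGroup(fid, "hmms")
    for (acc in withHmm)
      rhdf5::h5write(hmmToList(fams[[acc]]@hmm), fid, paste0("hmms/", acc))
  }
  # indexes: taxon -> accessions and lowercase name token -> tax_ids
  rhdf5::h5createGroup(fid, "index")
  ti <- as.list(e$taxIndex)
  it <- rep(names(ti), lengths(ti))
  ia <- unlist(ti, use.names = FALSE)
  rhdf5::h5write(as.integer(it), fid, "index/taxon")
  rhdf5::h5write(if (is.null(ia)) character(0) else ia,
                 fid, "index/taxon_accession")
  toks <- strsplit(tolower(tx$name), "[^a-z0-9]+")
  keep <- nzchar(unlist(toks))
  rhdf5::h5write(unlist(toks)[keep], fid, "index/name_token")
  rhdf5::h5write(rep(as.integer(tx$tax_id), lengths(toks))[keep], fid,
                 "index/token_tax_id")
  rhdf5::h5write(e$nextDR, fid, "meta_next_dr")
  invisible(store)
}

#' @rdname famdbFlush
#' @export
famdbOpen <- function(path) {
  stopifnot2(file.exists(path), paste0("no such store: ", path))
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  ver <- rhdf5::h5readAttributes(fid, "/")$famdb_layout
  if (!identical(as.character(ver), FAMDB_LAYOUT_VERSION))
    stop("unsupported famdb layout: ", ver, call. = FALSE)
  rd <- function(name) tryCatch(rhdf5::h5read(fid, name),
                                error = function(e) NULL)
  tx <- data.frame(tax_id = as.integer(rd("taxonomy/tax_id")),
                   parent_id = as.integer(rd("taxonomy/parent_id")),
                   name = as.character(rd("taxonomy/name")),
                   rank = as.character(rd("taxonomy/rank")))
  tx$parent_id[tx$parent_id == tx$tax_id] <- NA_integer_
  e <- newFamdbEnv(tx)
  accs <- rd("families/accession")
  if (!is.null(accs) && length(accs)) {
    nm <- rd("families/name"); cons <- rd("families/consensus")
    cls <- rd("families/classification"); cur <- rd("families/curated")
    meta <- rd("families/metadata"); ct <- rd("families/clade_taxa")
    hmmAccs <- tryCatch(rhdf5::h5ls(fid)$name[
      rhdf5::h5ls(fid)$group == "/hmms"], error = function(e) character())
    for (i in seq_along(accs)) {
      hmm <- NULL
      if (accs[i] %in% hmmAccs)
        hmm <- hmmFromList(rd(paste0("hmms/", accs[i])))
      taxa <- if (nzchar(ct[i]))
        as.integer(strsplit(ct[i], ",")[[1L]]) else integer()
      fam <- new("TEFamily", accession = accs[i], name = nm[i],
                 consensus = cons[i], hmm = hmm, classification = cls[i],
                 cladeTaxa = taxa, curated = as.logical(cur[i]),
                 metadata = as.list(jsonlite::fromJSON(meta[i])))
      assign(accs[i], fam, envir = e$families)
      for (t in as.character(taxa))
        assign(t, c(envGet(e$taxIndex, t), accs[i]), envir = e$taxIndex)
    }
    e$nFamilies <- length(accs)
  }
  ndr <- rd("meta_next_dr")
  if (!is.null(ndr)) e$nextDR <- as.integer(ndr)
  new("FamDB", path = path, env = e)
}

#' Export families from a FamDB store
#'
#' Writes the selected families as multi-record FASTA, EMBL flat
#' entries (1-based coordinates in the SQ block), or concatenated HMM
#' text. Families without an HMM are skipped from HMM export with a
#' per-family warning.
#'
#' @param store A \linkS4class{FamDB}.
#' @param selection Character vector of accessions, or a list of
#'   \linkS4class{TEFamily} (e.g. from
#'   \code{\link{familiesForTaxon}}).
#' @param format One of \code{"fasta"}, \code{"embl"}, \code{"hmm"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
famdbExport <- function(store, selection, format = c("fasta", "embl",
                                                     "hmm"), path) {
  format <- match.arg(format)
  if (is.character(selection))
    selection <- lapply(selection, famdbGetFamily, store = store)
  stopifnot2(length(selection) > 0L, "empty selection")
  if (format == "fasta") {
    x <- Biostrings::DNAStringSet(vapply(selection, function(f)
      f@consensus, character(1)))
    names(x) <- vapply(selection, function(f)
      paste0(f@accession, " ", f@name %||% ""), character(1))
    Biostrings::writeXStringSet(x, path)
  } else if (format == "embl") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in selection) {
      n <- nchar(f@consensus)
      writeLines(c(
        sprintf("ID   %s; SV %s; linear; DNA; STD; UNC; %d BP.",
                sub("\\..*$", "", f@accession),
                sub("^.*\\.", "", f@accession), n),
        "XX",
        sprintf("DE   %s", f@name %||% ""),
        "XX",
        sprintf("OC   %s", f@classification %||% ""),
        "XX",
        sprintf("SQ   Sequence %d BP;", n)), con)
      s <- tolower(f@consensus)
      for (st in seq(1L, n, by = 60L)) {
        chunk <- substr(s, st, min(st + 59L, n))
        grp <- gsub("(.{10})", "\\1 ", chunk)
        writeLines(sprintf("     %-66s%9d", trimws(grp),
                           min(st + 59L, n)), con)
      }
      writeLines("//", con)
    }
  } else {
    first <- TRUE
    wrote <- FALSE
    for (f in selection) {
      if (is.null(f@hmm)) {
        warning("family ", f@accession, " has no HMM; skipped",
                call. = FALSE)
        next
      }
      writeProfileHMM(f@hmm, path, append = !first)
      first <- FALSE; wrote <- TRUE
    }
    if (!wrote) stop("no family in the selection has an HMM",
                     call. = FALSE)
  }
  invisible(path)
}

#' Generate a toy taxonomy for testing and demonstrations
#'
#' Random rooted tree in NCBI-like node/parent/name triples: node 1 is
#' the root; every other node's parent is drawn uniformly among
#' earlier nodes.
#'
#' @param n Number of nodes.
#' @return data.frame with \code{tax_id}, \code{parent_id},
#'   \code{name}, \code{rank}.
#' @export
makeToyTaxonomy <- function(n) {
  stopifnot2(n >= 1L, "n must be >= 1")
  parent <- c(NA_integer_,
              if (n > 1L) vapply(2:n, function(i)
                if (i == 2L) 1L else sample.int(i - 1L, 1L), integer(1)))
  data.frame(tax_id = seq_len(n), parent_id = parent,
             name = paste0("taxon_", seq_len(n)),
             rank = rep(NA_character_, n))
}
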