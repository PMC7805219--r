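#' Read a Stockholm 1.0 seed alignment
#'
#' Reads single- or multi-block Stockholm; blocks are concatenated per
#' sequence in order of first appearance. \code{.} gaps are normalized
#' to \code{-}; case is preserved in memory (comparisons elsewhere are
#' case-insensitive). The \code{#=GC RF} column annotation is retained
#' when present; other annotation lines are ignored.
#'
#' @param path Path to a Stockholm file.
#' @return A \linkS4class{SeedAlignment}.
#' @seealso \code{\link{writeStockholm}}
#' @examples
#' f <- tempfile(fileext = ".stk")
#' writeStockholm(SeedAlignment(c("AC-T", "ACGT")), f)
#' readStockholm(f)
#' @export
readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("Stockholm format error: empty file: ", path, call. = FALSE)
  if (!grepl("^#\\s*STOCKHOLM", lines[1L]))
    stop("Stockholm format error: missing '# STOCKHOLM 1.0' header in ",
         path, call. = FALSE)
  seqs <- list()
  order <- character()
  rf <- character()
  for (ln in lines[-1L]) {
    t <- trimws(ln)
    if (!nzchar(t) || t == "//") next
    if (startsWith(t, "#")) {
      if (grepl("^#=GC\\s+RF\\s+", t))
        rf <- c(rf, sub("^#=GC\\s+RF\\s+", "", t))
      next
    }
    f <- strsplit(t, "\\s+")[[1L]]
    if (length(f) != 2L)
      stop("Stockholm format error: malformed alignment line: ", t,
           call. = FALSE)
    id <- f[1L]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- f[2L]
      order <- c(order, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], f[2L])
    }
  }
  if (!length(seqs))
    stop("Stockholm format error: no sequences in ", path, call. = FALSE)
  rows <- unlist(seqs[order], use.names = FALSE)
  w <- nchar(rows)
  if (length(unique(w)) > 1L) {
    bad <- order[w != max(w)][1L]
    stop("Stockholm format error: row length mismatch for sequence '",
         bad, "'", call. = FALSE)
  }
  fam <- sub("\\.(stk|sto|stockholm)$", "", basename(path))
  SeedAlignment(rows, ids = order, familyName = fam,
                referenceAnnotation = if (length(rf))
                  gsub(".", "-", paste(rf, collapse = ""), fixed = TRUE)
                else NA_character_)
}

#' Write a Stockholm 1.0 seed alignment
#'
#' Emits a single-block Stockholm file with the \code{# STOCKHOLM 1.0}
#' header and \code{//} terminator; the \code{#=GC RF} line is written
#' when the alignment carries a reference annotation. Gaps are written
#' as \code{-}.
#'
#' @param aln A \linkS4class{SeedAlignment}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeStockholm <- function(aln, path) {
  validObject(aln)
  wid <- max(nchar(aln@ids), if (!is.na(aln@referenceAnnotation)) 8L else 0L)
  body <- sprintf("%-*s %s", wid, aln@ids,
                  gsub(".", "-", aln@sequences, fixed = TRUE))
  out <- c("# STOCKHOLM 1.0",
           if (!is.na(aln@familyName))
             paste0("#=GF ID ", aln@familyName),
           body,
           if (!is.na(aln@referenceAnnotation))
             sprintf("%-*s %s", wid, "#=GC RF", aln@referenceAnnotation),
           "//")
  writeLines(out, path)
  invisible(path)
}

#' Export ungapped instance sequences as FASTA
#'
#' @param aln A \linkS4class{SeedAlignment}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeInstanceFasta <- function(aln, path) {
  ungapped <- gsub("-", "", aln@sequences, fixed = TRUE)
  x <- Biostrings::DNAStringSet(toupper(ungapped))
  names(x) <- aln@ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
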