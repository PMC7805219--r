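CLASSIFICATION_SYSTEMS <- c("repeatmasker", "repbase", "wicker",
                            "curcio_derbyshire")

#' Load a TE classification tree
#'
#' Reads a tab-separated tree definition with columns \code{path}
#' (full \code{';'}-joined path of the node) and optional alias columns
#' named after the supported foreign systems
#' (\code{repeatmasker}, \code{repbase}, \code{wicker},
#' \code{curcio_derbyshire}). Parents must be defined before children.
#' Node names may not contain \code{';'} or whitespace; sibling names
#' must be unique. The tree is unranked: nodes carry no rank labels.
#'
#' @param config Path to the tree definition; defaults to the curated
#'   subset shipped with the package (a faithful skeleton spanning the
#'   class I / class II divisions, not a clone of any full online
#'   tree).
#' @return A \linkS4class{ClassificationTree}.
#' @examples
#' tree <- loadClassificationTree()
#' resolveClassification("Interspersed_Repeat;Unknown", tree)
#' @export
loadClassificationTree <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "classification_tree.tsv",
                          package = "tefamkit", mustWork = TRUE)
  df <- utils::read.delim(config, stringsAsFactors = FALSE,
                          comment.char = "#")
  stopifnot2("path" %in% names(df), "tree config must have a 'path' column")
  extra <- setdiff(names(df), c("path", CLASSIFICATION_SYSTEMS))
  if (length(extra))
    stop("classification format error: unsupported column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  nodes <- data.frame(id = 1L, name = "", parent = NA_integer_, path = "",
                      stringsAsFactors = FALSE)  # virtual root, path ""
  aliases <- data.frame(id = integer(), system = character(),
                        label = character(), stringsAsFactors = FALSE)
  pathId <- c("<root>" = 1L)
  for (i in seq_len(nrow(df))) {
    p <- df$path[i]
    parts <- strsplit(p, ";", fixed = TRUE)[[1L]]
    name <- parts[length(parts)]
    if (grepl("[;[:space:]]", name))
      stop("classification format error: invalid node name '", name, "'",
           call. = FALSE)
    parentPath <- paste(parts[-length(parts)], collapse = ";")
    pid <- pathId[if (nzchar(parentPath)) parentPath else "<root>"]
    if (is.na(pid))
      stop("classification format error: parent of '", p,
           "' is not defined before it", call. = FALSE)
    pid <- as.integer(pid)
    sibs <- nodes$name[!is.na(nodes$parent) & nodes$parent == pid]
    if (name %in% sibs)
      stop("classification format error: duplicate sibling '", name,
           "' under '", parentPath, "'", call. = FALSE)
    id <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = id, name = name, parent = pid,
                                     path = p, stringsAsFactors = FALSE))
    pathId[p] <- id
    for (sys in intersect(names(df), CLASSIFICATION_SYSTEMS)) {
      lab <- df[[sys]][i]
      if (!is.na(lab) && nzchar(lab))
        aliases <- rbind(aliases,
                         data.frame(id = id, system = sys, label = lab,
                                    stringsAsFactors = FALSE))
    }
  }
  new("ClassificationTree", nodes = nodes, aliases = aliases)
}

#' Resolve a classification path string to a node
#'
#' Resolution always uses the full path from the root, since node
#' names may repeat across subtrees; a prefix of a full path resolves
#' to the corresponding internal node, enabling partial
#' classifications. The empty string resolves to the virtual root.
#'
#' @param path Classification path string (\code{';'}-joined names).
#' @param tree A \linkS4class{ClassificationTree}.
#' @return One-row data.frame (\code{id}, \code{name}, \code{parent},
#'   \code{path}).
#' @export
resolveClassification <- function(path, tree) {
  i <- match(path, tree@nodes$path)
  if (is.na(i)) {
    parts <- strsplit(path, ";", fixed = TRUE)[[1L]]
    best <- ""
    for (k in rev(seq_along(parts))) {
      pref <- paste(parts[seq_len(k)], collapse = ";")
      if (pref %in% tree@nodes$path) { best <- pref; break }
    }
    stop("unresolvable classification '", path,
         "'; nearest valid prefix: '", best, "'", call. = FALSE)
  }
  tree@nodes[i, , drop = FALSE]
}

#' Map a classification node to a foreign system's label
#'
#' @param node A node row from \code{\link{resolveClassification}} (or
#'   a path string, resolved against \code{tree}).
#' @param system One of \code{"repeatmasker"}, \code{"repbase"},
#'   \code{"wicker"}, \code{"curcio_derbyshire"}.
#' @param tree A \linkS4class{ClassificationTree}.
#' @return The foreign label, or \code{NA_character_} when the foreign
#'   system has no equivalent.
#' @export
mapClassification <- function(node, system, tree) {
  if (!system %in% CLASSIFICATION_SYSTEMS)
    stop("unknown classification system '", system, "'", call. = FALSE)
  if (is.character(node)) node <- resolveClassification(node, tree)
  hit <- tree@aliases[tree@aliases$id == node$id &
                        tree@aliases$system == system, "label"]
  if (length(hit)) hit[1L] else NA_character_
}

#' @describeIn mapClassification Find nodes carrying a given foreign
#'   label (reverse lookup).
#' @param label Foreign label to search for.
#' @export
findByAlias <- function(label, system, tree) {
  if (!system %in% CLASSIFICATION_SYSTEMS)
    stop("unknown classification system '", system, "'", call. = FALSE)
  ids <- tree@aliases$id[tree@aliases$system == system &
                           tree@aliases$label == label]
  tree@nodes[tree@nodes$id %in% ids, , drop = FALSE]
}
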