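.TRACK_HEADER <- c("t", "x", "y", "z", "cell_id", "parent_id", "name", "rid")

#' Read a tracked-embryo table into a lineage tree
#'
#' Reads the tab-separated track dialect used throughout the package: one
#' row per cell per timepoint, with columns \code{t, x, y, z, cell_id,
#' parent_id, name, rid} (empty string for a missing parent, name or
#' reference ID).  Birth and end times are taken as the first and last
#' recorded timepoint of each cell; a cell with two children is recorded as
#' divided, a cell ending before the final frame as terminal, and a cell
#' present in the final frame as censored by the end of the recording.
#'
#' @param file path or connection to a track TSV.
#' @param embryoId identifier for the resulting tree (defaults to the file
#'   name).
#' @return a [LineageTree-class].
#' @export
readTracks <- function(file, embryoId = NULL) {
  header <- strsplit(readLines(file, n = 1L), "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(.TRACK_HEADER, header)
  if (length(missing_cols))
    stop("track file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c(t = "numeric", x = "numeric",
                                         y = "numeric", z = "numeric",
                                         cell_id = "character",
                                         parent_id = "character",
                                         name = "character",
                                         rid = "character"),
                          quote = "", comment.char = "", na.strings = NULL)
  if (is.null(embryoId))
    embryoId <- if (is.character(file)) basename(file) else "tracks"
  df <- df[order(df$cell_id, df$t), ]
  blank2na <- function(x) ifelse(nzchar(x), x, NA_character_)

  first <- !duplicated(df$cell_id)
  uids <- df$cell_id[first]
  birth <- tapply(df$t, df$cell_id, min)[uids]
  end <- tapply(df$t, df$cell_id, max)[uids]
  parent <- blank2na(df$parent_id[first])
  name <- blank2na(df$name[first])
  rid <- blank2na(df$rid[first])

  bad <- !is.na(parent) & !(parent %in% uids)
  if (any(bad))
    stop("orphan parent reference for cell(s): ",
         paste(df$cell_id[first][bad], collapse = ", "),
         " (row ", which(first)[which(bad)[1]], ")")
  pend <- end[match(parent, uids)]
  off <- !is.na(pend) & (birth < pend - 0.01)
  if (any(off))
    stop("cell ", uids[which(off)[1]], " is born at ", birth[which(off)[1]],
         " before its parent's last timepoint ", pend[which(off)[1]],
         " (row ", which(first)[which(off)[1]], ")")
  # snap births to the parent division time within the format tolerance
  birth[!is.na(pend)] <- pmax(birth[!is.na(pend)], pend[!is.na(pend)])

  nkids <- table(factor(parent, levels = uids))
  t_last <- max(df$t)
  fate <- ifelse(nkids[uids] == 2L, "divided",
                 ifelse(end >= t_last - .TIME_TOL, "censored", "terminal"))
  nodes <- data.frame(uid = uids, rid = rid, name = name, parent = parent,
                      birth = as.numeric(birth), end = as.numeric(end),
                      fate = unname(fate), mode = NA_character_,
                      tag = NA_character_, stringsAsFactors = FALSE)
  positions <- data.frame(uid = df$cell_id, t = df$t, x = df$x, y = df$y,
                          z = df$z, stringsAsFactors = FALSE)
  lineageTree(embryoId, nodes, positions,
              recordingWindow = c(min(df$t), t_last))
}

#' Write a lineage tree as a track table
#'
#' Inverse of [readTracks()]: one row per recorded (cell, timepoint), sorted
#' canonically by cell id then time, times printed with 3 decimals.
#' Reading the output back reproduces the tree (up to row order), and
#' writing a freshly read file reproduces it byte for byte.
#'
#' @param tree a [LineageTree-class].
#' @param file path or connection.
#' @export
writeTracks <- function(tree, file) {
  pos <- tree@positions
  nd <- tree@nodes
  i <- match(pos$uid, nd$uid)
  na2blank <- function(x) ifelse(is.na(x), "", x)
  out <- data.frame(t = sprintf("%.3f", pos$t),
                    x = sprintf("%.4f", pos$x),
                    y = sprintf("%.4f", pos$y),
                    z = sprintf("%.4f", pos$z),
                    cell_id = pos$uid,
                    parent_id = na2blank(nd$parent[i]),
                    name = na2blank(nd$name[i]),
                    rid = na2blank(nd$rid[i]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, as.numeric(out$t)), ]
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}
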