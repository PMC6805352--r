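.NODE_COLS <- c("uid", "rid", "name", "parent", "birth", "end", "fate",
                "mode", "tag")
.FATES <- c("divided", "terminal", "apoptotic", "migrated_out", "censored")
.TIME_TOL <- 1e-6

#' @keywords internal
.validLineageTree <- function(object) {
  nd <- object@nodes
  if (!all(.NODE_COLS %in% names(nd)))
    return(paste("nodes must have columns",
                 paste(.NODE_COLS, collapse = ", ")))
  if (anyDuplicated(nd$uid))
    return("duplicate cell uids")
  if (nrow(nd) == 0L) return(TRUE)
  if (!all(nd$fate %in% .FATES))
    return("unknown end fate")
  if (any(nd$end < nd$birth - .TIME_TOL))
    return("cell end time before birth time")
  has_parent <- !is.na(nd$parent)
  if (any(has_parent & !(nd$parent %in% nd$uid)))
    return(paste("orphan parent reference:",
                 paste(unique(nd$uid[has_parent &
                                     !(nd$parent %in% nd$uid)]),
                       collapse = ", ")))
  # acyclic because birth equals the parent's (strictly later) division time
  pi_ <- match(nd$parent, nd$uid)
  pe <- nd$end[pi_]
  if (any(!is.na(pe) & abs(nd$birth - pe) > 0.01 + .TIME_TOL))
    return("child birth time does not equal parent division time")
  nkids <- table(nd$parent[has_parent])
  div <- nd$uid[nd$fate == "divided"]
  if (!all(div %in% names(nkids)) ||
      !all(nkids[div] == 2L))
    return("divided cells must have exactly 2 children")
  extra <- setdiff(names(nkids), div)
  if (length(extra))
    return("non-divided cells must not have children")
  TRUE
}

#' Construct a lineage tree from a node table
#'
#' @param embryoId single string identifying the embryo.
#' @param nodes data.frame with columns \code{uid}, \code{rid}, \code{name},
#'   \code{parent}, \code{birth}, \code{end}, \code{fate}, \code{mode},
#'   \code{tag} (missing optional columns are filled with NA).
#' @param positions data.frame with columns \code{uid}, \code{t}, \code{x},
#'   \code{y}, \code{z} (may be empty).
#' @param recordingWindow numeric(2), recording start and end (hpf).
#' @param frame coordinate-convention list; by default the apical axis is
#'   +z, the dorsal (D-quadrant) azimuth is +y and the sagittal plane x = 0.
#' @return a [LineageTree-class] object.
#' @export
lineageTree <- function(embryoId, nodes,
                        positions = data.frame(uid = character(),
                                               t = numeric(), x = numeric(),
                                               y = numeric(), z = numeric()),
                        recordingWindow = range(c(nodes$birth, nodes$end)),
                        frame = list(apical = "+z", dorsalAzimuth = pi / 2,
                                     sagittal = "x=0")) {
  for (col in .NODE_COLS) {
    if (!col %in% names(nodes))
      nodes[[col]] <- if (col %in% c("birth", "end")) NA_real_
                      else NA_character_
    nodes[[col]] <- if (col %in% c("birth", "end"))
      as.numeric(nodes[[col]]) else as.character(nodes[[col]])
  }
  nodes <- nodes[.NODE_COLS]
  rownames(nodes) <- NULL
  new("LineageTree", embryoId = embryoId, nodes = nodes,
      positions = positions, recordingWindow = as.numeric(recordingWindow),
      frame = frame)
}

#' @describeIn lineageTree embryo identifier accessor
#' @param tree a [LineageTree-class].
#' @export
embryoId <- function(tree) tree@embryoId

#' @describeIn lineageTree node-table accessor
#' @export
treeNodes <- function(tree) tree@nodes

#' @describeIn lineageTree position-table accessor
#' @export
treePositions <- function(tree) tree@positions

#' @describeIn lineageTree recording-window accessor
#' @export
recordingWindow <- function(tree) tree@recordingWindow

setMethod("show", "LineageTree", function(object) {
  nd <- object@nodes
  cat("LineageTree", sQuote(object@embryoId), "\n")
  cat("  cells:", nrow(nd),
      " divisions:", sum(nd$fate == "divided"),
      " roots:", sum(is.na(nd$parent)), "\n")
  cat(sprintf("  recording window: %.2f - %.2f hpf\n",
              object@recordingWindow[1], object@recordingWindow[2]))
})

#' Children lookup for a tree
#' @return named list uid -> character vector of child uids.
#' @keywords internal
.childrenMap <- function(tree) {
  nd <- tree@nodes
  has <- !is.na(nd$parent)
  split(nd$uid[has], factor(nd$parent[has], levels = nd$uid))
}

#' Cells alive at a developmental time
#'
#' A cell is alive at \code{t} from its birth up to (but excluding) its end
#' time; cells whose fate is \code{terminal} or \code{censored} (present
#' when the recording ends) are additionally alive at their end time.
#'
#' @param tree a [LineageTree-class].
#' @param t time (hpf).
#' @return character vector of uids.
#' @export
aliveAt <- function(tree, t) {
  nd <- tree@nodes
  keep <- nd$birth <= t + .TIME_TOL &
    (t < nd$end - .TIME_TOL |
       (nd$fate %in% c("terminal", "censored") & t <= nd$end + .TIME_TOL))
  nd$uid[keep]
}

#' Interpolated cell position at a time
#'
#' Nearest recorded timepoint at or before \code{t} (falling back to the
#' first recorded point).
#' @keywords internal
.positionAt <- function(tree, uids, t) {
  pos <- tree@positions
  out <- matrix(NA_real_, nrow = length(uids), ncol = 3,
                dimnames = list(uids, c("x", "y", "z")))
  for (i in seq_along(uids)) {
    p <- pos[pos$uid == uids[i], , drop = FALSE]
    if (nrow(p) == 0L) next
    k <- findInterval(t + .TIME_TOL, p$t)
    if (k < 1L) k <- 1L
    out[i, ] <- c(p$x[k], p$y[k], p$z[k])
  }
  out
}

#' Mean position over an early-life window
#'
#' Positions averaged over the first \code{window} hours after birth, the
#' reference position used when testing mirror correspondence of newborn
#' cells.
#' @keywords internal
.birthPosition <- function(tree, uids, window = 0.5) {
  pos <- tree@positions
  nd <- tree@nodes
  birth <- nd$birth[match(uids, nd$uid)]
  out <- matrix(NA_real_, nrow = length(uids), ncol = 3,
                dimnames = list(uids, c("x", "y", "z")))
  idx <- split(seq_len(nrow(pos)), pos$uid)
  for (i in seq_along(uids)) {
    rows <- idx[[uids[i]]]
    if (is.null(rows)) next
    p <- pos[rows, , drop = FALSE]
    sel <- p$t <= birth[i] + window + .TIME_TOL
    if (!any(sel)) sel <- seq_len(min(1L, nrow(p)))
    out[i, ] <- c(mean(p$x[sel]), mean(p$y[sel]), mean(p$z[sel]))
  }
  out
}

#' Ancestor uids of a cell (nearest first)
#' @keywords internal
.ancestors <- function(nodes, uid) {
  par <- nodes$parent
  names(par) <- nodes$uid
  out <- character()
  u <- par[[uid]]
  while (!is.na(u)) {
    out <- c(out, u)
    u <- par[[u]]
  }
  out
}

#' Descendant uids of a set of cells
#' @keywords internal
.descendants <- function(tree, uids, children = .childrenMap(tree)) {
  out <- character()
  frontier <- uids
  while (length(frontier)) {
    kids <- unlist(children[frontier], use.names = FALSE)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}
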