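#' Lineage depth of a cell
#'
#' The number of cell divisions separating a cell from the zygote at a
#' given time.  Trees rooted below the zygote (e.g. at the first micromere
#' quartet) add a fixed root offset: 3 divisions separate the zygote from
#' a 1m micromere (zygote -> AB/CD -> quadrants -> first micromeres).
#'
#' @param tree a [LineageTree-class].
#' @param uid a cell alive at \code{t}.
#' @param t developmental time (hpf).
#' @param rootOffset divisions from the zygote to the tracked roots
#'   (default 3 for 1m-rooted trees).
#' @return integer division count.
#' @examples
#' emb <- simulateEmbryo(canonicalProgram(), zeroVariability(), 1, tEnd = 12)
#' lineageDepth(simTree(emb), "1a-1122", 9)   # 3 + 4
#' @export
lineageDepth <- function(tree, uid, t, rootOffset = 3L) {
  .assertAlive(tree, uid, t)
  length(.ancestors(tree@nodes, uid)) + as.integer(rootOffset)
}

#' Cell age: time since the last division
#'
#' @inheritParams lineageDepth
#' @return age in hours, \code{t - birth_time}.
#' @export
cellAge <- function(tree, uid, t) {
  .assertAlive(tree, uid, t)
  t - tree@nodes$birth[match(uid, tree@nodes$uid)]
}

#' Cell-cycle length of a divided cell
#'
#' @param tree a [LineageTree-class].
#' @param uid a divided cell.
#' @return cycle length in hours (division time minus birth).
#' @export
cycleLength <- function(tree, uid) {
  i <- match(uid, tree@nodes$uid)
  if (is.na(i)) stop("unknown cell ", uid)
  if (tree@nodes$fate[i] != "divided")
    stop("cell ", uid, " did not divide")
  tree@nodes$end[i] - tree@nodes$birth[i]
}

#' @keywords internal
.assertAlive <- function(tree, uid, t) {
  if (!uid %in% tree@nodes$uid) stop("unknown cell ", uid)
  if (!uid %in% aliveAt(tree, t))
    stop("cell ", uid, " is not alive at ", t, " hpf")
  invisible(TRUE)
}

#' Clonal projection of a labelled cell set
#'
#' Projects a set of cells labelled at stage \code{s} (e.g. an expression
#' pattern mapped onto the lineage) forward to its theoretical clonal
#' offspring at stage \code{sTarget}: every labelled cell still alive is
#' kept, every divided one is replaced by its descendants alive at the
#' target stage.
#'
#' @param tree a [LineageTree-class].
#' @param labeled character vector of labelled cell uids, all alive at
#'   \code{s}.
#' @param s,sTarget source and target stages (hpf), \code{s <= sTarget}.
#' @return character vector of uids alive at \code{sTarget}.
#' @export
projectClone <- function(tree, labeled, s, sTarget) {
  stopifnot(s <= sTarget)
  unknown <- setdiff(labeled, tree@nodes$uid)
  if (length(unknown))
    stop("unknown labelled cell(s): ", paste(unknown, collapse = ", "))
  for (u in labeled) .assertAlive(tree, u, s)
  alive <- aliveAt(tree, sTarget)
  fam <- unique(c(labeled, .descendants(tree, labeled)))
  intersect(fam, alive)
}

#' Clonality score of an expression pattern
#'
#' Compares an observed labelled cell set with the theoretical clonal
#' projection of an earlier pattern (both at the same stage) by the
#' Jaccard index: 1 means perfectly clonal inheritance of the label, 0
#' means no overlap (dynamic switching of expression between cell
#' cycles).
#'
#' @param observed,projected character vectors of cell uids at one stage.
#' @return list with \code{score} (Jaccard index, NA when both sets are
#'   empty), \code{gained} (observed only) and \code{lost} (projected
#'   only).
#' @export
clonalityScore <- function(observed, projected) {
  observed <- unique(observed); projected <- unique(projected)
  u <- union(observed, projected)
  if (!length(u))
    return(list(score = NA_real_, gained = character(),
                lost = character()))
  list(score = length(intersect(observed, projected)) / length(u),
       gained = setdiff(observed, projected),
       lost = setdiff(projected, observed))
}
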