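#' Estimate the sagittal mirror plane of a tracked embryo
#'
#' Finds the plane through the apical axis that minimises the mean
#' symmetric nearest-neighbour distance between the alive-cell point set
#' and its mirror image: a coarse 1-degree azimuth scan refined by
#' golden-section search.  With \code{method = "metadata"} the frame
#' convention plane x = 0 is returned without fitting.
#'
#' @param tree a [LineageTree-class].
#' @param t developmental time (hpf); at least 10 cells must be alive.
#' @param method \code{"fit"} (default) or \code{"metadata"}.
#' @return a [MirrorPlane-class].
#' @export
estimateMirrorPlane <- function(tree, t, method = c("fit", "metadata")) {
  method <- match.arg(method)
  if (method == "metadata")
    return(new("MirrorPlane", azimuth = 0, fitted = FALSE,
               objective = NA_real_))
  uids <- aliveAt(tree, t)
  if (length(uids) < 10)
    stop("need at least 10 alive cells to fit a mirror plane")
  P <- .positionAt(tree, uids, t)
  P <- P[stats::complete.cases(P), , drop = FALSE]
  .fitMirrorAzimuth(P)
}

#' @keywords internal
.mirrorObjective <- function(P, azimuth) {
  # reflect across the plane with normal (cos a, sin a, 0)
  n <- c(cos(azimuth), sin(azimuth), 0)
  Q <- P - 2 * (P %*% n) %*% t(n)
  dd <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  dd <- sqrt(pmax(dd, 0))
  (mean(apply(dd, 1, min)) + mean(apply(dd, 2, min))) / 2
}

#' @keywords internal
.fitMirrorAzimuth <- function(P) {
  if (max(abs(P[, 1:2])) < 1e-9)
    stop("degenerate point set: all cells on the apical axis")
  grid <- seq(0, pi, length.out = 181L)[-181L]
  obj <- vapply(grid, function(a) .mirrorObjective(P, a), 0)
  a0 <- grid[which.min(obj)]
  lo <- a0 - pi / 180
  hi <- a0 + pi / 180
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- .mirrorObjective(P, x1); f2 <- .mirrorObjective(P, x2)
  for (i in 1:40) {
    if (f1 < f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- .mirrorObjective(P, x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- .mirrorObjective(P, x2)
    }
  }
  a <- ((x1 + x2) / 2) %% pi
  new("MirrorPlane", azimuth = a, fitted = TRUE,
      objective = .mirrorObjective(P, a))
}

setMethod("show", "MirrorPlane", function(object) {
  cat(sprintf("MirrorPlane: normal azimuth %.2f deg (%s)\n",
              object@azimuth * 180 / pi,
              if (object@fitted) "fitted" else "metadata"))
})

#' @keywords internal
.reflectAcross <- function(P, plane) {
  n <- c(cos(plane@azimuth), sin(plane@azimuth), 0)
  if (is.matrix(P)) P - 2 * (P %*% n) %*% t(n)
  else P - 2 * sum(P * n) * n
}

# ---------------------------------------------------------------------

#' Topological similarity of two clones
#'
#' Scores how similar the lineage-tree topologies of two clones are: a
#' division in one clone can match a division in the other when their
#' clone-relative birth times differ by at most \code{dtTol} and their
#' parent divisions matched (recursive best daughter assignment).  The
#' score is 2 * matched / (divisions_u + divisions_v); two terminal cells
#' score 1.
#'
#' @param tree a [LineageTree-class].
#' @param uidU,uidV clone root cells.
#' @param dtTol tolerance (h) on clone-relative division times.
#' @param horizon optional common horizon (hpf); divisions after it are
#'   ignored.
#' @return similarity in [0, 1].
#' @export
cloneTopologySimilarity <- function(tree, uidU, uidV, dtTol = 1.0,
                                    horizon = tree@recordingWindow[2]) {
  ctx <- list(idx = stats::setNames(seq_len(nrow(tree@nodes)),
                                    tree@nodes$uid),
              nodes = tree@nodes, children = .childrenMap(tree))
  .cloneTopoScore(ctx, ctx, uidU, uidV, dtTol, horizon)
}

# division counter within horizon
#' @keywords internal
.cloneDivCount <- function(ctx, uid, horizon) {
  i <- ctx$idx[[uid]]
  if (ctx$nodes$fate[i] != "divided" || ctx$nodes$end[i] > horizon)
    return(0L)
  kids <- ctx$children[[uid]]
  1L + .cloneDivCount(ctx, kids[1], horizon) +
    .cloneDivCount(ctx, kids[2], horizon)
}

# matched divisions between clones rooted at u (in cu) and v (in cv),
# times taken relative to the clone roots' births
#' @keywords internal
.cloneMatchedDiv <- function(cu, cv, u, v, off_u, off_v, dtTol, horizon) {
  iu <- cu$idx[[u]]; iv <- cv$idx[[v]]
  du <- cu$nodes$fate[iu] == "divided" && cu$nodes$end[iu] <= horizon
  dv <- cv$nodes$fate[iv] == "divided" && cv$nodes$end[iv] <= horizon
  if (!du || !dv) return(0L)
  tu <- cu$nodes$end[iu] - off_u
  tv <- cv$nodes$end[iv] - off_v
  if (abs(tu - tv) > dtTol) return(0L)
  ku <- cu$children[[u]]; kv <- cv$children[[v]]
  straight <- .cloneMatchedDiv(cu, cv, ku[1], kv[1], off_u, off_v, dtTol,
                               horizon) +
    .cloneMatchedDiv(cu, cv, ku[2], kv[2], off_u, off_v, dtTol, horizon)
  swapped <- .cloneMatchedDiv(cu, cv, ku[1], kv[2], off_u, off_v, dtTol,
                              horizon) +
    .cloneMatchedDiv(cu, cv, ku[2], kv[1], off_u, off_v, dtTol, horizon)
  1L + max(straight, swapped)
}

#' @keywords internal
.cloneTopoScore <- function(cu, cv, u, v, dtTol, horizon) {
  nu <- .cloneDivCount(cu, u, horizon)
  nv <- .cloneDivCount(cv, v, horizon)
  if (nu + nv == 0L) return(1.0)
  off_u <- cu$nodes$birth[cu$idx[[u]]]
  off_v <- cv$nodes$birth[cv$idx[[v]]]
  m <- .cloneMatchedDiv(cu, cv, u, v, off_u, off_v, dtTol, horizon)
  2 * m / (nu + nv)
}

# ---------------------------------------------------------------------

#' Detect bilateral founder cells
#'
#' Applies the three bilateral-founder criteria to every cross-side cell
#' pair: (i) a bilateral counterpart in position (mirror distance at birth,
#' positions averaged over the first 30 min, at most \code{mirrorEps});
#' (ii) bilaterally symmetrical clonal progeny with similar lineage-tree
#' topology (score at least \code{topoMin}); (iii) origin at roughly the
#' same developmental time (birth times within \code{dtTol}).  Candidate
#' pairs are pruned to founders: a pair is a founder only if no ancestor
#' pair of both members is itself a candidate (the earliest qualifying
#' generation), and each cell joins at most one pair (greedy by descending
#' topology score, then smaller mirror distance, then lexicographic uid).
#'
#' @param tree a [LineageTree-class].
#' @param plane a [MirrorPlane-class] (e.g. [estimateMirrorPlane()], or the
#'   metadata plane x = 0).
#' @param dtTol birth-time tolerance in hours (default 1.0).
#' @param mirrorEps mirror-distance tolerance as a distance (default 10
#'   percent of the hemisphere radius, taken as 1).
#' @param topoMin minimum clone-topology score (default 0.8).
#' @param horizon clone comparison horizon (default recording end).
#' @return data.frame of founder pairs sorted by origin time, with columns
#'   \code{left_uid}, \code{right_uid}, \code{left_name},
#'   \code{right_name}, \code{birth_left}, \code{birth_right},
#'   \code{mirror_distance}, \code{topology_score}, \code{symmetry_class}.
#' @export
detectBilateralFounders <- function(tree, plane = NULL, dtTol = 1.0,
                                    mirrorEps = 0.10, topoMin = 0.8,
                                    horizon = tree@recordingWindow[2]) {
  if (is.null(plane))
    plane <- new("MirrorPlane", azimuth = 0, fitted = FALSE,
                 objective = NA_real_)
  nd <- tree@nodes
  # signed distance from the mirror plane
  pos <- .birthPosition(tree, nd$uid, window = 0.5)
  n <- c(cos(plane@azimuth), sin(plane@azimuth), 0)
  side <- as.numeric(pos %*% n)
  mirrored <- .reflectAcross(pos, plane)

  left <- which(side < 0)
  right <- which(side > 0)
  if (!length(left) || !length(right)) return(.emptyFounders())

  # cheap criteria first: birth-time and mirror-position windows
  cand <- list()
  ctx <- list(idx = stats::setNames(seq_len(nrow(nd)), nd$uid),
              nodes = nd, children = .childrenMap(tree))
  md <- outer(rowSums(mirrored[left, , drop = FALSE]^2),
              rowSums(pos[right, , drop = FALSE]^2), "+") -
    2 * mirrored[left, , drop = FALSE] %*%
        t(pos[right, , drop = FALSE])
  md <- sqrt(pmax(md, 0))
  dt <- abs(outer(nd$birth[left], nd$birth[right], "-"))
  hits <- which(md <= mirrorEps & dt <= dtTol, arr.ind = TRUE)
  if (!nrow(hits)) return(.emptyFounders())
  for (h in seq_len(nrow(hits))) {
    i <- left[hits[h, 1]]; j <- right[hits[h, 2]]
    ts <- .cloneTopoScore(ctx, ctx, nd$uid[i], nd$uid[j], dtTol, horizon)
    if (ts >= topoMin)
      cand[[length(cand) + 1L]] <- list(i = i, j = j,
                                        md = md[hits[h, 1], hits[h, 2]],
                                        ts = ts)
  }
  if (!length(cand)) return(.emptyFounders())

  # prune to the earliest qualifying generation: drop a pair when an
  # ancestor of the left and an ancestor of the right member form a
  # candidate pair themselves
  candKey <- vapply(cand, function(x) paste(x$i, x$j), "")
  anc <- lapply(nd$uid, function(u) .ancestors(nd, u))
  names(anc) <- nd$uid
  isCand <- new.env(parent = emptyenv())
  for (k in candKey) assign(k, TRUE, envir = isCand)
  keep <- vapply(cand, function(x) {
    ai <- match(anc[[nd$uid[x$i]]], nd$uid)
    aj <- match(anc[[nd$uid[x$j]]], nd$uid)
    for (a in ai) for (b in aj)
      if (!is.null(get0(paste(a, b), envir = isCand))) return(FALSE)
    TRUE
  }, TRUE)
  cand <- cand[keep]
  if (!length(cand)) return(.emptyFounders())

  # greedy disjoint selection
  ord <- order(-vapply(cand, `[[`, 0, "ts"),
               vapply(cand, `[[`, 0, "md"),
               vapply(cand, function(x) nd$uid[x$i], ""),
               vapply(cand, function(x) nd$uid[x$j], ""))
  used <- logical(nrow(nd))
  sel <- list()
  for (k in ord) {
    x <- cand[[k]]
    if (used[x$i] || used[x$j]) next
    used[x$i] <- used[x$j] <- TRUE
    sel[[length(sel) + 1L]] <- x
  }

  out <- data.frame(
    left_uid = vapply(sel, function(x) nd$uid[x$i], ""),
    right_uid = vapply(sel, function(x) nd$uid[x$j], ""),
    left_name = vapply(sel, function(x) nd$name[x$i], ""),
    right_name = vapply(sel, function(x) nd$name[x$j], ""),
    birth_left = vapply(sel, function(x) nd$birth[x$i], 0),
    birth_right = vapply(sel, function(x) nd$birth[x$j], 0),
    mirror_distance = vapply(sel, `[[`, 0, "md"),
    topology_score = vapply(sel, `[[`, 0, "ts"),
    stringsAsFactors = FALSE)
  out$symmetry_class <- mapply(function(l, r) {
    if (is.na(l) || is.na(r)) "UNNAMED"
    else classifyFounderPair(l, r)
  }, out$left_name, out$right_name)
  out <- out[order(pmin(out$birth_left, out$birth_right), out$left_uid), ]
  rownames(out) <- NULL
  out
}

#' @keywords internal
.emptyFounders <- function() {
  data.frame(left_uid = character(), right_uid = character(),
             left_name = character(), right_name = character(),
             birth_left = numeric(), birth_right = numeric(),
             mirror_distance = numeric(), topology_score = numeric(),
             symmetry_class = character(), stringsAsFactors = FALSE)
}

#' Symmetry class of a bilateral founder pair
#'
#' Classifies how a founder pair relates to the spiral-cleavage lineage:
#' identical division index under the A-B / C-D quadrant swap is the
#' common quadrant-homolog symmetry; identical index under the A-C swap is
#' the rarer A|C symmetry; two cells of one quadrant form single-quadrant
#' symmetry; anything else is a pair of non-corresponding lineages.
#'
#' @param left,right lineage names (strings or [LineageName-class]).
#' @return one of \code{"QUADRANT_HOMOLOG_ABCD"}, \code{"AC_HOMOLOG"},
#'   \code{"SINGLE_QUADRANT"}, \code{"NON_CORRESPONDING"}.
#' @examples
#' classifyFounderPair("1a-1122", "1b-1122")
#' @export
classifyFounderPair <- function(left, right) {
  l <- if (is(left, "LineageName")) left else parseLineageName(left)
  r <- if (is(right, "LineageName")) right else parseLineageName(right)
  if (l@quadrant == "M" || r@quadrant == "M")
    stop("cannot classify the quadrant shorthand")
  pAB <- bilateralPartnerName(l, "AB_CD")
  if (pAB@quadrant == r@quadrant && l@tier == r@tier &&
      l@index == r@index)
    return("QUADRANT_HOMOLOG_ABCD")
  pAC <- bilateralPartnerName(l, "AC")
  if (pAC@quadrant == r@quadrant && l@quadrant != r@quadrant &&
      l@tier == r@tier && l@index == r@index)
    return("AC_HOMOLOG")
  if (l@quadrant == r@quadrant) return("SINGLE_QUADRANT")
  "NON_CORRESPONDING"
}
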