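#' Feature weights for the corresponding-cell similarity score
#'
#' The similarity score combines three division features (daughter
#' positions, daughter cycle lengths, descendant counts) with weighting
#' coefficients.  The original procedure's coefficients were chosen
#' arbitrarily and never published; the defaults here weight the three
#' features equally.
#'
#' @param w_pos,w_cycle,w_desc non-negative feature weights.
#' @param tau_cycle scale (hours) of the cycle-length similarity kernel.
#' @return a \code{FeatureWeights} list.
#' @export
featureWeights <- function(w_pos = 1, w_cycle = 1, w_desc = 1,
                           tau_cycle = 2.0) {
  stopifnot(w_pos >= 0, w_cycle >= 0, w_desc >= 0, tau_cycle > 0,
            w_pos + w_cycle + w_desc > 0)
  structure(list(w_pos = w_pos, w_cycle = w_cycle, w_desc = w_desc,
                 tau_cycle = tau_cycle), class = "FeatureWeights")
}

# ---------------------------------------------------------------------
# Per-tree match context: fast lookups for positions, children and
# horizon-limited descendant-division counts.
#' @keywords internal
.matchContext <- function(tree, horizon) {
  nd <- tree@nodes
  pos <- tree@positions
  first <- !duplicated(pos$uid)
  firstPos <- as.matrix(pos[first, c("x", "y", "z")])
  rownames(firstPos) <- pos$uid[first]
  last <- !duplicated(pos$uid, fromLast = TRUE)
  lastPos <- as.matrix(pos[last, c("x", "y", "z")])
  rownames(lastPos) <- pos$uid[last]
  children <- .childrenMap(tree)
  # descendant divisions with division time <= horizon, per cell
  ndesc <- stats::setNames(rep(NA_real_, nrow(nd)), nd$uid)
  ord <- order(nd$birth, decreasing = TRUE)   # children before parents
  div <- stats::setNames(nd$fate == "divided" & nd$end <= horizon, nd$uid)
  for (u in nd$uid[ord]) {
    kids <- children[[u]]
    ndesc[u] <- if (div[[u]])
      1 + sum(ndesc[kids]) else 0
  }
  list(nodes = nd, idx = stats::setNames(seq_len(nrow(nd)), nd$uid),
       children = children, firstPos = firstPos, lastPos = lastPos,
       ndesc = ndesc, recEnd = tree@recordingWindow[2])
}

#' Division features of a tracked cell division
#'
#' Extracts the features used to identify corresponding cells across
#' embryos: the unit displacement of each daughter from the mother at
#' division, each daughter's subsequent cell-cycle length (censored with a
#' lower bound when the daughter has not divided by the end of the
#' recording), and each daughter's number of descendant divisions within
#' the comparison horizon.
#'
#' @param tree a [LineageTree-class].
#' @param uid a divided cell.
#' @param horizon hpf; descendant divisions after this time are not counted.
#' @return list with elements \code{daughters}, \code{offsets} (2 x 3 unit
#'   matrix), \code{cycles}, \code{censored}, \code{ndesc}.
#' @export
divisionFeatures <- function(tree, uid, horizon = tree@recordingWindow[2]) {
  ctx <- .matchContext(tree, horizon)
  .divisionFeatures(ctx, uid)
}

#' @keywords internal
.divisionFeatures <- function(ctx, uid) {
  i <- ctx$idx[[uid]]
  if (ctx$nodes$fate[i] != "divided")
    stop("cell ", uid, " did not divide")
  kids <- ctx$children[[uid]]
  mpos <- ctx$lastPos[uid, ]
  off <- ctx$firstPos[kids, , drop = FALSE] - rep(mpos, each = 2)
  nrm <- sqrt(rowSums(off^2))
  nrm[nrm < 1e-12] <- 1
  off <- off / nrm
  ki <- ctx$idx[kids]
  divided <- ctx$nodes$fate[ki] == "divided"
  cycles <- ifelse(divided,
                   ctx$nodes$end[ki] - ctx$nodes$birth[ki],
                   ctx$recEnd - ctx$nodes$birth[ki])
  list(daughters = kids, offsets = off, cycles = cycles,
       censored = !divided, ndesc = unname(ctx$ndesc[kids]))
}

#' @keywords internal
.cycleTerm <- function(ca, cb, censA, censB, tau) {
  gap <- if (!censA && !censB) abs(ca - cb)
         else if (censA && censB) 0
         else if (censA) max(0, ca - cb)
         else max(0, cb - ca)
  exp(-gap / tau)
}

#' Similarity of two cell divisions across embryos
#'
#' Compares the division features of two cells from different (registered)
#' embryos.  Both possible daughter assignments (straight and swapped) are
#' scored as the weighted mean of a position kernel \code{(1 + cos theta)/2},
#' a cycle kernel \code{exp(-|dcycle|/tau)} (using the censoring bound for
#' unobserved cycles) and a descendant-count kernel
#' \code{1 - |n1 - n2| / max(n1, n2, 1)}, and the higher-scoring assignment
#' is returned.  Scores lie in [0, 1]; identical features score 1.  Exact
#' ties are broken towards the assignment with the smaller summed angular
#' offset distance, then towards the straight assignment.
#'
#' @param fa,fb feature lists from [divisionFeatures()].
#' @param w a [featureWeights()] list.
#' @return list with \code{score}, \code{pairing} ("straight" or
#'   "swapped") and both assignment scores.
#' @export
pairingSimilarity <- function(fa, fb, w = featureWeights()) {
  one <- function(perm) {
    s_pos <- s_cyc <- s_desc <- 0
    for (k in 1:2) {
      j <- perm[k]
      s_pos <- s_pos + (1 + sum(fa$offsets[k, ] * fb$offsets[j, ])) / 2
      s_cyc <- s_cyc + .cycleTerm(fa$cycles[k], fb$cycles[j],
                                  fa$censored[k], fb$censored[j],
                                  w$tau_cycle)
      n1 <- fa$ndesc[k]; n2 <- fb$ndesc[j]
      s_desc <- s_desc + 1 - abs(n1 - n2) / max(n1, n2, 1)
    }
    (w$w_pos * s_pos + w$w_cycle * s_cyc + w$w_desc * s_desc) /
      (2 * (w$w_pos + w$w_cycle + w$w_desc))
  }
  ang <- function(perm) {
    sum(acos(pmin(1, pmax(-1, c(sum(fa$offsets[1, ] * fb$offsets[perm[1], ]),
                                sum(fa$offsets[2, ] * fb$offsets[perm[2], ]))))))
  }
  s1 <- one(1:2)
  s2 <- one(2:1)
  pairing <- if (abs(s1 - s2) > 1e-12) {
    if (s1 >= s2) "straight" else "swapped"
  } else if (ang(1:2) <= ang(2:1)) "straight" else "swapped"
  list(score = max(s1, s2), pairing = pairing,
       straight = s1, swapped = s2)
}

#' Rigid registration between two tracked embryos
#'
#' Embryos are mounted apically, so registration reduces to a rotation
#' about the apical (+z) axis.  With frame metadata the rotation aligns
#' the dorsal azimuths; otherwise it is fitted in closed form (2-D
#' orthogonal Procrustes) from >= 3 landmark cells named in both trees.
#'
#' @param treeA,treeB [LineageTree-class] objects.
#' @param method \code{"metadata"}, \code{"landmarks"} or \code{"auto"}.
#' @param t time at which landmark positions are taken (default: earliest
#'   common time).
#' @return list with the rotation \code{angle} (radians, applied to B to
#'   align with A) and the \code{method} used.
#' @export
registerFrames <- function(treeA, treeB,
                           method = c("auto", "metadata", "landmarks"),
                           t = NULL) {
  method <- match.arg(method)
  hasMeta <- !is.null(treeA@frame$dorsalAzimuth) &&
    !is.null(treeB@frame$dorsalAzimuth)
  if (method == "auto") method <- if (hasMeta) "metadata" else "landmarks"
  if (method == "metadata") {
    if (!hasMeta) stop("frame metadata missing; use landmarks")
    return(list(angle = treeA@frame$dorsalAzimuth -
                  treeB@frame$dorsalAzimuth, method = "metadata"))
  }
  common <- intersect(stats::na.omit(treeA@nodes$name),
                      stats::na.omit(treeB@nodes$name))
  if (length(common) < 3)
    stop("need at least 3 common named landmark cells (found ",
         length(common), ") and no frame metadata path was requested")
  ua <- treeA@nodes$uid[match(common, treeA@nodes$name)]
  ub <- treeB@nodes$uid[match(common, treeB@nodes$name)]
  if (is.null(t))
    t <- max(treeA@nodes$birth[match(ua, treeA@nodes$uid)],
             treeB@nodes$birth[match(ub, treeB@nodes$uid)])
  A <- .positionAt(treeA, ua, t)
  B <- .positionAt(treeB, ub, t)
  keep <- stats::complete.cases(A) & stats::complete.cases(B)
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  if (nrow(A) < 3) stop("fewer than 3 landmarks with positions at t")
  num <- sum(B[, 1] * A[, 2] - B[, 2] * A[, 1])
  den <- sum(B[, 1] * A[, 1] + B[, 2] * A[, 2])
  list(angle = atan2(num, den), method = "landmarks")
}

#' @describeIn registerFrames apply a registration to a point matrix.
#' @param points n x 3 matrix.
#' @param transform result of [registerFrames()].
#' @export
applyRegistration <- function(points, transform) {
  a <- transform$angle
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  points %*% t(R)
}

# ---------------------------------------------------------------------

#' Identify corresponding cells between two tracked embryos
#'
#' The recursive corresponding-cell procedure: starting from manually (or
#' programmatically) assigned root pairs, each matched pair whose members
#' both divide before the comparison point has its divisions compared by
#' [pairingSimilarity()]; the best daughter assignment provides the new
#' rooting points and the recursion continues.  When only one member
#' divides before the comparison point, the other member's remaining
#' frames up to \code{tCompare + guard} are searched for the division to
#' come; if the recording ends first the subtree is flagged censored,
#' otherwise it is a real lineage difference.
#'
#' @param treeA,treeB [LineageTree-class] objects.
#' @param rootPairs two-column matrix/data.frame of (uid in A, uid in B)
#'   root assignments, or NULL to pair roots by lineage name.
#' @param tCompare comparison point (hpf), default 30.
#' @param guard guard window (h) of "known divisions to come", default 3.
#' @param w a [featureWeights()] list.
#' @return a [CorrespondenceMap-class].
#' @export
matchLineages <- function(treeA, treeB, rootPairs = NULL, tCompare = 30,
                          guard = 3, w = featureWeights()) {
  if (tCompare + guard > min(treeA@recordingWindow[2],
                             treeB@recordingWindow[2]) + .TIME_TOL)
    stop("tCompare + guard must not exceed the shorter recording")
  if (is.null(rootPairs)) {
    ra <- treeA@nodes[is.na(treeA@nodes$parent), c("uid", "name")]
    rb <- treeB@nodes[is.na(treeB@nodes$parent), c("uid", "name")]
    common <- intersect(ra$name, rb$name)
    if (!length(common))
      stop("no root pairs given and no shared root names")
    rootPairs <- cbind(ra$uid[match(common, ra$name)],
                       rb$uid[match(common, rb$name)])
  }
  rootPairs <- as.matrix(rootPairs)
  if (!all(rootPairs[, 1] %in% treeA@nodes$uid) ||
      !all(rootPairs[, 2] %in% treeB@nodes$uid))
    stop("root uid absent from its tree")
  horizon <- tCompare + guard
  ca <- .matchContext(treeA, horizon)
  cb <- .matchContext(treeB, horizon)

  pairs <- list(); unA <- list(); unB <- list()
  flagSubtree <- function(side, kids, reason) {
    for (u in kids) {
      rec <- list(uid = u, reason = reason)
      if (side == "a") unA[[length(unA) + 1L]] <<- rec
      else unB[[length(unB) + 1L]] <<- rec
    }
  }
  recurse <- function(ua, ub, score, pairing) {
    pairs[[length(pairs) + 1L]] <<- list(uid_a = ua, uid_b = ub,
                                         score = score, pairing = pairing)
    ia <- ca$idx[[ua]]; ib <- cb$idx[[ub]]
    divA <- ca$nodes$fate[ia] == "divided" &&
      ca$nodes$end[ia] <= tCompare + .TIME_TOL
    divB <- cb$nodes$fate[ib] == "divided" &&
      cb$nodes$end[ib] <= tCompare + .TIME_TOL
    if (divA && divB) {
      fa <- .divisionFeatures(ca, ua)
      fb <- .divisionFeatures(cb, ub)
      ps <- pairingSimilarity(fa, fb, w)
      perm <- if (ps$pairing == "straight") 1:2 else 2:1
      for (k in 1:2)
        recurse(fa$daughters[k], fb$daughters[perm[k]], ps$score,
                ps$pairing)
    } else if (divA && !divB) {
      fateB <- cb$nodes$fate[ib]
      endB <- cb$nodes$end[ib]
      if (fateB == "divided" && endB <= horizon + .TIME_TOL) {
        # known division to come: matched, beyond the comparison horizon
      } else if (fateB == "censored") {
        flagSubtree("a", ca$children[[ua]], "censored")
      } else {
        flagSubtree("a", ca$children[[ua]], "real_difference")
      }
    } else if (divB && !divA) {
      fateA <- ca$nodes$fate[ia]
      endA <- ca$nodes$end[ia]
      if (fateA == "divided" && endA <= horizon + .TIME_TOL) {
      } else if (fateA == "censored") {
        flagSubtree("b", cb$children[[ub]], "censored")
      } else {
        flagSubtree("b", cb$children[[ub]], "real_difference")
      }
    }
  }
  for (r in seq_len(nrow(rootPairs)))
    recurse(rootPairs[r, 1], rootPairs[r, 2], NA_real_, NA_character_)

  pairDf <- data.frame(
    uid_a = vapply(pairs, `[[`, "", "uid_a"),
    uid_b = vapply(pairs, `[[`, "", "uid_b"),
    score = vapply(pairs, `[[`, 0, "score"),
    pairing = vapply(pairs, `[[`, "", "pairing"),
    stringsAsFactors = FALSE)
  unDf <- function(x) data.frame(
    uid = vapply(x, `[[`, "", "uid"),
    reason = vapply(x, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  new("CorrespondenceMap",
      embryoA = treeA@embryoId, embryoB = treeB@embryoId,
      pairs = pairDf, unmatchedA = unDf(unA), unmatchedB = unDf(unB),
      tCompare = tCompare, guard = guard)
}

setMethod("show", "CorrespondenceMap", function(object) {
  cat("CorrespondenceMap", object@embryoA, "<->", object@embryoB, "\n")
  cat("  matched pairs:", nrow(object@pairs),
      " unmatched A:", nrow(object@unmatchedA),
      " unmatched B:", nrow(object@unmatchedB), "\n")
  cat("  compared at", object@tCompare, "hpf with", object@guard,
      "h guard\n")
})

# cells of `tree` flagged as real differences against the partner embryo,
# expanded to whole subtrees (a differing division marks its progeny)
#' @keywords internal
.rdCells <- function(map, tree) {
  un <- if (map@embryoA == tree@embryoId) map@unmatchedA
        else if (map@embryoB == tree@embryoId) map@unmatchedB
        else stop("map does not involve embryo ", tree@embryoId)
  roots <- un$uid[un$reason == "real_difference"]
  unique(c(roots, .descendants(tree, roots)))
}

#' Quantify lineage differences across an embryo cohort
#'
#' A cell alive at \code{t} counts as a difference when it (or the
#' division that created it) is flagged as a real lineage difference
#' against \emph{both} other cohort members; censored subtrees never
#' count.  Returns per-embryo counts and the pooled percentage.
#'
#' @param trees list of [LineageTree-class] (>= 3 embryos).
#' @param maps list of pairwise [CorrespondenceMap-class] covering every
#'   embryo pair.
#' @param t developmental time (hpf).
#' @return data.frame with one row per embryo (columns \code{embryo},
#'   \code{different}, \code{total}) plus attribute \code{percent}.
#' @export
countDifferences <- function(trees, maps, t) {
  ids <- vapply(trees, embryoId, "")
  if (length(ids) < 3) stop("need a cohort of at least 3 embryos")
  win <- vapply(trees, function(x) x@recordingWindow, numeric(2))
  if (t < min(win[1, ]) - .TIME_TOL || t > max(win[2, ]) + .TIME_TOL)
    stop("t is outside every recording window")
  findMap <- function(i, j) {
    for (m in maps)
      if ((m@embryoA == ids[i] && m@embryoB == ids[j]) ||
          (m@embryoA == ids[j] && m@embryoB == ids[i])) return(m)
    stop("no correspondence map for pair ", ids[i], " / ", ids[j])
  }
  out <- data.frame(embryo = ids, different = 0L, total = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    alive <- aliveAt(trees[[i]], t)
    others <- setdiff(seq_along(ids), i)
    rd <- lapply(others, function(j) .rdCells(findMap(i, j), trees[[i]]))
    rdAll <- Reduce(intersect, rd)
    out$different[i] <- sum(alive %in% rdAll)
    out$total[i] <- length(alive)
  }
  attr(out, "percent") <- 100 * sum(out$different) / max(1, sum(out$total))
  out
}

# ---------------------------------------------------------------------
# union-find over (embryo, uid) keys, tracking the embryos represented in
# each cluster so that inconsistent merges (two cells of one embryo in
# one cluster) can be refused or reported
#' @keywords internal
.unionFind <- function() {
  parent <- new.env(parent = emptyenv())
  embs <- new.env(parent = emptyenv())
  find <- function(x) {
    p <- get0(x, envir = parent, ifnotfound = x)
    if (identical(p, x)) return(x)
    r <- find(p)
    assign(x, r, envir = parent)
    r
  }
  clusterEmbryos <- function(r) {
    get0(r, envir = embs,
         ifnotfound = sub("\r.*$", "", r))
  }
  list(find = find,
       clusterEmbryos = clusterEmbryos,
       union = function(x, y, force = TRUE) {
         rx <- find(x); ry <- find(y)
         if (identical(rx, ry)) return(TRUE)
         ex <- clusterEmbryos(rx); ey <- clusterEmbryos(ry)
         if (length(intersect(ex, ey))) {
           if (!force) return(FALSE)
         }
         assign(rx, ry, envir = parent)
         assign(ry, union(ex, ey), envir = embs)
         TRUE
       })
}

# cluster the cohort's cells by correspondence; map pairs are applied in
# descending similarity-score order and, when strict = FALSE, a pairing
# that would place two cells of one embryo in the same cluster (an
# inconsistent correspondence triangle) is dropped
#' @keywords internal
.cohortClusters <- function(ids, maps, strict = FALSE) {
  uf <- .unionFind()
  key <- function(e, u) paste0(e, "\r", u)
  allPairs <- do.call(rbind, lapply(maps, function(m)
    data.frame(a = key(m@embryoA, m@pairs$uid_a),
               b = key(m@embryoB, m@pairs$uid_b),
               score = m@pairs$score, stringsAsFactors = FALSE)))
  if (is.null(allPairs) || !nrow(allPairs)) return(uf)
  sc <- ifelse(is.na(allPairs$score), Inf, allPairs$score)
  allPairs <- allPairs[order(-sc), ]
  for (r in seq_len(nrow(allPairs)))
    uf$union(allPairs$a[r], allPairs$b[r], force = strict)
  uf
}

#' Build the consensus lineage tree of a cohort
#'
#' Groups cells across the cohort by correspondence and keeps the
#' divisions supported by more than half of the embryos (2 of 3 for the
#' standard cohort).  Each consensus node records its support count, the
#' minimal and maximal observed division time, a low-support flag, and a
#' deterministic reference ID ("r" + breadth-first birth-order rank).
#' Lineage names are propagated when all named members agree.
#'
#' @param trees list of [LineageTree-class] objects.
#' @param maps pairwise [CorrespondenceMap-class] list covering the cohort.
#' @param strict if TRUE, an inconsistent correspondence cycle (a cluster
#'   with two cells of one embryo) is an error listing the conflicting
#'   cells; by default the weakest-scoring pairings of such cycles are
#'   dropped instead.
#' @return a [ConsensusTree-class].
#' @export
buildConsensus <- function(trees, maps, strict = FALSE) {
  ids <- vapply(trees, embryoId, "")
  n <- length(ids)
  if (n < 2) stop("need at least 2 embryos")
  uf <- .cohortClusters(ids, maps, strict = strict)
  key <- function(e, u) paste0(e, "\r", u)
  # cluster membership for every cell in every tree
  members <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    nd <- trees[[i]]@nodes
    for (u in nd$uid) {
      root <- uf$find(key(ids[i], u))
      lst <- get0(root, envir = members, ifnotfound = list())
      lst[[length(lst) + 1L]] <- c(embryo = ids[i], uid = u)
      assign(root, lst, envir = members)
    }
  }
  ctx <- lapply(trees, function(tr) {
    list(idx = stats::setNames(seq_len(nrow(tr@nodes)), tr@nodes$uid),
         nodes = tr@nodes, children = .childrenMap(tr))
  })
  names(ctx) <- ids
  clusterInfo <- function(root) {
    lst <- get(root, envir = members)
    emb <- vapply(lst, `[[`, "", "embryo")
    if (anyDuplicated(emb))
      stop("inconsistent correspondence: cluster with several cells of ",
           "one embryo: ",
           paste(vapply(lst, function(x) paste0(x[["embryo"]], ":",
                                                x[["uid"]]),
                        ""), collapse = ", "))
    lst
  }
  out <- list()
  ridCounter <- new.env(parent = emptyenv()); ridCounter$n <- 0L
  visit <- function(root, parentRid) {
    lst <- clusterInfo(root)
    info <- lapply(lst, function(m) {
      cc <- ctx[[m[["embryo"]]]]
      i <- cc$idx[[m[["uid"]]]]
      list(embryo = m[["embryo"]], uid = m[["uid"]],
           fate = cc$nodes$fate[i], end = cc$nodes$end[i],
           birth = cc$nodes$birth[i], name = cc$nodes$name[i],
           kids = cc$children[[m[["uid"]]]])
    })
    divs <- Filter(function(x) x$fate == "divided", info)
    support <- length(divs)
    nm <- unique(stats::na.omit(vapply(info, `[[`, "", "name")))
    ridCounter$n <- ridCounter$n + 1L
    rid <- paste0("r", ridCounter$n)
    retainDiv <- support > n / 2
    out[[length(out) + 1L]] <<- data.frame(
      rid = rid, parent_rid = parentRid,
      name = if (length(nm) == 1L) nm else NA_character_,
      support = support,
      t_min = if (support) min(vapply(divs, `[[`, 0, "end")) else NA_real_,
      t_max = if (support) max(vapply(divs, `[[`, 0, "end")) else NA_real_,
      low_support = retainDiv && support < n,
      members = paste(vapply(info, function(x)
        paste0(x$embryo, ":", x$uid), ""), collapse = ";"),
      stringsAsFactors = FALSE)
    if (!retainDiv) return(invisible())
    # children clusters, visited in birth order for deterministic rIDs
    kidRoots <- unique(unlist(lapply(divs, function(x)
      vapply(x$kids, function(u) uf$find(key(x$embryo, u)), ""))))
    kb <- vapply(kidRoots, function(r) {
      lst <- get(r, envir = members)
      min(vapply(lst, function(m)
        ctx[[m[["embryo"]]]]$nodes$birth[
          ctx[[m[["embryo"]]]]$idx[[m[["uid"]]]]], 0))
    }, 0)
    for (r in kidRoots[order(kb)]) visit(r, rid)
  }
  rootClusters <- unique(unlist(lapply(seq_along(trees), function(i) {
    nd <- trees[[i]]@nodes
    vapply(nd$uid[is.na(nd$parent)], function(u)
      uf$find(key(ids[i], u)), "")
  })))
  rb <- vapply(rootClusters, function(r) {
    lst <- get(r, envir = members)
    nm <- vapply(lst, `[[`, "", "uid")
    min(nm)
  }, "")
  for (r in rootClusters[order(rb)]) visit(r, NA_character_)
  new("ConsensusTree", nodes = do.call(rbind, out),
      cohortSize = as.integer(n))
}

setMethod("show", "ConsensusTree", function(object) {
  nd <- object@nodes
  cat("ConsensusTree over", object@cohortSize, "embryos:",
      nrow(nd), "nodes,",
      sum(nd$support == object@cohortSize), "full-support divisions,",
      sum(nd$low_support), "low-support divisions\n")
})

#' Write a consensus tree as JSON
#'
#' @param consensus a [ConsensusTree-class].
#' @param file output path.
#' @export
writeConsensus <- function(consensus, file) {
  jsonlite::write_json(
    list(schema = "spiralineage/consensus/1",
         cohort_size = consensus@cohortSize,
         nodes = consensus@nodes),
    file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' Mean maximal division-time asynchrony in a time window
#'
#' For every corresponding division observed in all cohort members, the
#' asynchrony is the difference between the earliest and the latest member
#' division time; the statistic is the mean over the corresponding
#' divisions whose mean time falls inside the window.
#'
#' @param trees cohort [LineageTree-class] list.
#' @param maps pairwise correspondence maps.
#' @param window numeric(2), time window in hpf.
#' @return mean asynchrony in hours, or NA when the window contains no
#'   corresponding division.
#' @export
maxTimingAsynchrony <- function(trees, maps, window) {
  ids <- vapply(trees, embryoId, "")
  n <- length(ids)
  uf <- .cohortClusters(ids, maps)
  key <- function(e, u) paste0(e, "\r", u)
  divTimes <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    nd <- trees[[i]]@nodes
    dv <- nd$fate == "divided"
    for (j in which(dv)) {
      root <- uf$find(key(ids[i], nd$uid[j]))
      v <- get0(root, envir = divTimes, ifnotfound = numeric())
      assign(root, c(v, nd$end[j]), envir = divTimes)
    }
  }
  spans <- numeric()
  for (root in ls(divTimes)) {
    v <- get(root, envir = divTimes)
    if (length(v) != n) next          # division must occur in all members
    if (mean(v) >= window[1] && mean(v) <= window[2])
      spans <- c(spans, max(v) - min(v))
  }
  if (!length(spans)) return(NA_real_)
  mean(spans)
}
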