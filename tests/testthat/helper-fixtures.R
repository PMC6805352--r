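# Shared fixtures: simulations are cached per test run because several
# files interrogate the same canonical embryo / cohorts.

.fixtures <- new.env(parent = emptyenv())

canonicalEmbryo <- function(tEnd = 32) {
  key <- paste0("canon", tEnd)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulateEmbryo(canonicalProgram(),
                                       zeroVariability(), 1L, tEnd = tEnd)
  .fixtures[[key]]
}

zeroVarCohort <- function(tEnd = 20) {
  key <- paste0("zcohort", tEnd)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulateCohort(3, 1L,
                                       variability = zeroVariability(),
                                       tEnd = tEnd)
  .fixtures[[key]]
}

# a small hand-built tree: one mother dividing into two daughters
tinyTree <- function() {
  nodes <- data.frame(
    uid = c("m", "d1", "d2"),
    rid = NA_character_,
    name = c("1a", "1a-1", "1a-2"),
    parent = c(NA, "m", "m"),
    birth = c(2, 4, 4), end = c(4, 8, 8),
    fate = c("divided", "terminal", "terminal"),
    mode = c("spiral_cw", NA, NA), tag = NA_character_,
    stringsAsFactors = FALSE)
  pos <- data.frame(
    uid = c("m", "m", "d1", "d2"),
    t = c(2, 4, 4, 4),
    x = c(0.5, 0.5, 0.45, 0.55),
    y = c(0.5, 0.5, 0.55, 0.45),
    z = c(0.70, 0.70, 0.70, 0.70), stringsAsFactors = FALSE)
  lineageTree("tiny", nodes, pos, recordingWindow = c(2, 8))
}

# random binary tree with n leaves over a fixed time span; division times
# and daughter geometry drawn from the supplied RNG stream
randomTree <- function(nLeaves, seed, embryoId = "rnd", jitterSd = 0) {
  set.seed(seed)
  nodes <- list()
  positions <- list()
  addCell <- function(uid, parent, birth, pos, depth) {
    divide <- length(nodes) < (2 * nLeaves - 1) - 1 &&
      depth < ceiling(log2(nLeaves)) + 1 && stats::runif(1) < 0.75
    if (divide) {
      # draw the deviate unconditionally so the RNG stream (and hence
      # the topology) is identical across jitter settings
      cycle <- stats::runif(1, 2, 5) + jitterSd * stats::rnorm(1)
      cycle <- max(0.5, cycle)
      end <- birth + cycle
      nodes[[length(nodes) + 1L]] <<- data.frame(
        uid = uid, rid = NA, name = NA, parent = parent, birth = birth,
        end = end, fate = "divided", mode = NA, tag = NA,
        stringsAsFactors = FALSE)
      positions[[length(positions) + 1L]] <<- data.frame(
        uid = uid, t = c(birth, end), x = pos[1], y = pos[2], z = pos[3],
        stringsAsFactors = FALSE)
      ang <- stats::runif(1, 0, 2 * pi)
      off <- 0.1 * c(cos(ang), sin(ang), 0)
      addCell(paste0(uid, "1"), uid, end, pos + off, depth + 1)
      addCell(paste0(uid, "2"), uid, end, pos - off, depth + 1)
    } else {
      end <- 30
      nodes[[length(nodes) + 1L]] <<- data.frame(
        uid = uid, rid = NA, name = NA, parent = parent, birth = birth,
        end = end, fate = "censored", mode = NA, tag = NA,
        stringsAsFactors = FALSE)
      positions[[length(positions) + 1L]] <<- data.frame(
        uid = uid, t = c(birth, end), x = pos[1], y = pos[2], z = pos[3],
        stringsAsFactors = FALSE)
    }
  }
  addCell("r", NA_character_, 2, c(0.3, 0.3, 0.9), 0)
  lineageTree(embryoId, do.call(rbind, nodes), do.call(rbind, positions),
              recordingWindow = c(2, 30))
}

# brute-force optimal recursive assignment: enumerates both daughter
# pairings at every matched division and maximises the total similarity
bruteForceMatchScore <- function(treeA, treeB, rootA, rootB, tCompare,
                                 guard, w = featureWeights()) {
  ca <- spiralineage:::.matchContext(treeA, tCompare + guard)
  cb <- spiralineage:::.matchContext(treeB, tCompare + guard)
  best <- function(ua, ub) {
    ia <- ca$idx[[ua]]; ib <- cb$idx[[ub]]
    divA <- ca$nodes$fate[ia] == "divided" && ca$nodes$end[ia] <= tCompare
    divB <- cb$nodes$fate[ib] == "divided" && cb$nodes$end[ib] <= tCompare
    if (!divA || !divB) return(0)
    fa <- spiralineage:::.divisionFeatures(ca, ua)
    fb <- spiralineage:::.divisionFeatures(cb, ub)
    ps <- pairingSimilarity(fa, fb, w)
    straight <- ps$straight +
      best(fa$daughters[1], fb$daughters[1]) +
      best(fa$daughters[2], fb$daughters[2])
    swapped <- ps$swapped +
      best(fa$daughters[1], fb$daughters[2]) +
      best(fa$daughters[2], fb$daughters[1])
    max(straight, swapped)
  }
  best(rootA, rootB)
}

# total score realised by the greedy matcher, on the same scale
greedyMatchScore <- function(map, treeA, tCompare) {
  nd <- treeA@nodes
  divided <- nd$uid[nd$fate == "divided" & nd$end <= tCompare]
  p <- map@pairs
  kids <- nd$uid[!is.na(nd$parent) & nd$parent %in% divided]
  # each matched division contributed its chosen pairing score once per
  # daughter pair; pair rows store the score of the division that created
  # them, so sum one score per matched divided mother
  matchedMothers <- p$uid_a[p$uid_a %in% divided]
  total <- 0
  for (m in matchedMothers) {
    ka <- nd$uid[!is.na(nd$parent) & nd$parent == m]
    sc <- p$score[p$uid_a %in% ka]
    if (length(sc)) total <- total + sc[1]
  }
  total
}
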