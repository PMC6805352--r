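test_that("frame registration recovers rotations about the apical axis", {
  tr <- simTree(canonicalEmbryo(tEnd = 12))
  # identical trees: identity
  tf <- registerFrames(tr, tr, method = "metadata")
  expect_equal(tf$angle, 0)

  # rotate embryo B by 30 degrees and recover the rotation by landmarks
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0,
                0, 0, 1), 3)
  pos <- treePositions(tr)
  rot <- as.matrix(pos[, c("x", "y", "z")]) %*% t(R)
  posB <- data.frame(uid = pos$uid, t = pos$t, x = rot[, 1],
                     y = rot[, 2], z = rot[, 3])
  trB <- lineageTree("rotated", treeNodes(tr), posB,
                     recordingWindow = recordingWindow(tr))
  tfL <- registerFrames(tr, trB, method = "landmarks", t = 5)
  expect_equal(tfL$angle, -ang, tolerance = 1e-6)
  # applying the registration restores the original positions
  back <- applyRegistration(rot, tfL)
  expect_equal(back, unname(as.matrix(pos[, c("x", "y", "z")])),
               tolerance = 1e-9, ignore_attr = TRUE)

  # landmark fit on 4 quadrant cells agrees with the metadata path
  trB2 <- lineageTree("same-frame", treeNodes(tr), pos,
                      recordingWindow = recordingWindow(tr))
  tf4 <- registerFrames(tr, trB2, method = "landmarks", t = 2.4)
  expect_lt(abs(tf4$angle - registerFrames(tr, trB2,
                                           method = "metadata")$angle),
            pi / 180)
})

test_that("division features capture offsets, cycles and censoring", {
  tr <- simTree(canonicalEmbryo(tEnd = 12))
  f <- divisionFeatures(tr, "1a-112")
  expect_setequal(f$daughters, c("1a-1121", "1a-1122"))
  expect_equal(rowSums(f$offsets^2), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # 1a-1121 divides at 8 (cycle 2); 1a-1122 divides at 9.6, after the
  # 12 hpf recording end in the short fixture -> censored with bound
  i1 <- match("1a-1121", f$daughters)
  expect_false(f$censored[i1])
  expect_equal(f$cycles[i1], 2.0)
  emb8 <- simulateEmbryo(canonicalProgram(), zeroVariability(), 1,
                         tEnd = 9)
  f8 <- divisionFeatures(simTree(emb8), "1a-112")
  i2 <- match("1a-1122", f8$daughters)
  expect_true(f8$censored[i2])
  expect_equal(f8$cycles[i2], 9 - 6)   # recording end minus birth

  # horizon before any grandchild division: zero descendant counts
  fh <- divisionFeatures(tr, "1a-112", horizon = 7)
  expect_equal(fh$ndesc, c(0, 0))
  expect_error(divisionFeatures(tr, "1a-221"), "did not divide")

  # mirrored mothers (a founder pair) have mirror-equal features
  fl <- divisionFeatures(tr, "1d-1122")
  fr <- divisionFeatures(tr, "1c-1122")
  expect_equal(sort(fl$cycles), sort(fr$cycles), tolerance = 1e-9)
  expect_equal(sort(fl$ndesc), sort(fr$ndesc))
})

test_that("pairing similarity matches the hand-evaluated formula", {
  # identical features: perfect straight pairing
  f <- list(daughters = c("x", "y"),
            offsets = rbind(c(1, 0, 0), c(0, 1, 0)),
            cycles = c(2, 3), censored = c(FALSE, FALSE),
            ndesc = c(2, 4))
  ps <- pairingSimilarity(f, f)
  expect_equal(ps$score, 1.0)
  expect_equal(ps$pairing, "straight")

  # swapped daughters: perfect swapped pairing
  fsw <- list(daughters = c("y", "x"),
              offsets = f$offsets[2:1, ], cycles = f$cycles[2:1],
              censored = c(FALSE, FALSE), ndesc = f$ndesc[2:1])
  ps2 <- pairingSimilarity(f, fsw)
  expect_equal(ps2$score, 1.0)
  expect_equal(ps2$pairing, "swapped")

  # hand-built case evaluated independently: orthogonal first offsets,
  # cycle gap equal to tau on daughter 1, descendant counts 2 vs 4
  g <- list(daughters = c("x", "y"),
            offsets = rbind(c(0, 1, 0), c(0, 1, 0)),
            cycles = c(4, 3), censored = c(FALSE, FALSE),
            ndesc = c(4, 4))
  w <- featureWeights()    # equal weights, tau = 2
  s_pos <- (1 + 0) / 2 + (1 + 1) / 2          # cos 90 deg, cos 0
  s_cyc <- exp(-2 / 2) + exp(-0 / 2)          # |4-2| = tau, |3-3| = 0
  s_desc <- (1 - 2 / 4) + (1 - 0 / 4)         # 2 vs 4, 4 vs 4
  expected <- (s_pos + s_cyc + s_desc) / 6
  ps3 <- pairingSimilarity(f, g, w)
  expect_equal(ps3$straight, expected, tolerance = 1e-9)

  # censored bounds contribute through the consistency gap
  cens <- list(daughters = c("x", "y"),
               offsets = f$offsets, cycles = c(5, 3),
               censored = c(TRUE, FALSE), ndesc = c(2, 4))
  term <- spiralineage:::.cycleTerm(5, 2, TRUE, FALSE, 2)
  expect_equal(term, exp(-3 / 2))     # bound 5 vs observed 2
  expect_equal(spiralineage:::.cycleTerm(5, 6, TRUE, FALSE, 2), 1)
  expect_equal(spiralineage:::.cycleTerm(5, 7, TRUE, TRUE, 2), 1)
})

test_that("matching an embryo against itself is the identity", {
  tr <- simTree(canonicalEmbryo(tEnd = 20))
  m <- matchLineages(tr, tr, tCompare = 16, guard = 3)
  expect_identical(m@pairs$uid_a, m@pairs$uid_b)
  sc <- m@pairs$score[!is.na(m@pairs$score)]
  # identical divisions score 1; the budding division contributes a
  # zero-length offset whose position kernel is neutral (0.5)
  expect_true(all(sc > 0.8))
  expect_gt(mean(sc > 0.999), 0.98)
  expect_equal(nrow(m@unmatchedA), 0L)
  expect_equal(nrow(m@unmatchedB), 0L)
})

test_that("a skipped division is flagged as exactly that subtree", {
  co <- zeroVarCohort(tEnd = 20)
  trA <- simTree(co[[1]])
  # remove the 16.0 hpf eye-forming division from embryo B
  ndB <- treeNodes(simTree(co[[2]]))
  drop <- c("1a-1211211", "1a-1211212")
  ndB <- ndB[!(ndB$uid %in% drop), ]
  i <- match("1a-121121", ndB$uid)
  ndB$fate[i] <- "terminal"; ndB$end[i] <- 20; ndB$mode[i] <- NA
  posB <- treePositions(simTree(co[[2]]))
  posB <- posB[!(posB$uid %in% drop), ]
  trB <- lineageTree("edited", ndB, posB, recordingWindow = c(2, 20))
  m <- matchLineages(trA, trB, tCompare = 16, guard = 3)
  rd <- m@unmatchedA[m@unmatchedA$reason == "real_difference", ]
  expect_setequal(rd$uid, drop)
  expect_equal(nrow(m@unmatchedB), 0L)
})

test_that("zero-variability cohorts match without differences", {
  co <- zeroVarCohort(tEnd = 20)
  trees <- lapply(co, simTree)
  maps <- list(matchLineages(trees[[1]], trees[[2]], tCompare = 16),
               matchLineages(trees[[1]], trees[[3]], tCompare = 16),
               matchLineages(trees[[2]], trees[[3]], tCompare = 16))
  for (m in maps) {
    expect_equal(nrow(m@unmatchedA), 0L)
    expect_equal(nrow(m@unmatchedB), 0L)
  }
  for (tt in c(8, 12, 16))
    expect_equal(sum(countDifferences(trees, maps, tt)$different), 0L)
  # ground-truth recovery: matched pairs agree with canonical identity
  for (m in maps)
    expect_identical(m@pairs$uid_a, m@pairs$uid_b)
  expect_error(countDifferences(trees, maps, 50), "outside")
})

test_that("difference counts are symmetric in cohort order", {
  co <- simulateCohort(3, 31, variability = variabilityModel(),
                       tEnd = 20)
  trees <- lapply(co, simTree)
  maps <- list(matchLineages(trees[[1]], trees[[2]], tCompare = 16),
               matchLineages(trees[[1]], trees[[3]], tCompare = 16),
               matchLineages(trees[[2]], trees[[3]], tCompare = 16))
  d1 <- countDifferences(trees, maps, 16)
  perm <- c(3, 1, 2)
  d2 <- countDifferences(trees[perm], maps, 16)
  expect_equal(d2$different[match(d1$embryo, d2$embryo)], d1$different)
  expect_equal(attr(d2, "percent"), attr(d1, "percent"))
})

test_that("an extra division contributes its two cells only after it
          happens", {
  co <- zeroVarCohort(tEnd = 20)
  trees <- lapply(co, simTree)
  # graft an extra division at 17 hpf onto a terminal cell of embryo 1
  nd <- treeNodes(trees[[1]])
  u <- "1a-122"                      # accessory prototroch, terminal
  i <- match(u, nd$uid)
  nd$fate[i] <- "divided"; nd$end[i] <- 17
  kids <- data.frame(uid = c("xx1", "xx2"), rid = NA, name = NA,
                     parent = u, birth = 17, end = 20,
                     fate = "terminal", mode = NA, tag = NA,
                     stringsAsFactors = FALSE)
  nd <- rbind(nd, kids)
  pos <- treePositions(trees[[1]])
  pos <- pos[!(pos$uid == u & pos$t > 17), ]
  base <- pos[pos$uid == u, ][1, ]
  pos <- rbind(pos,
               data.frame(uid = c("xx1", "xx2"), t = 17,
                          x = base$x + c(-0.03, 0.03), y = base$y,
                          z = base$z))
  trees[[1]] <- lineageTree(embryoId(trees[[1]]), nd, pos,
                            recordingWindow = c(2, 20))
  maps <- list(matchLineages(trees[[1]], trees[[2]], tCompare = 16),
               matchLineages(trees[[1]], trees[[3]], tCompare = 16),
               matchLineages(trees[[2]], trees[[3]], tCompare = 16))
  expect_equal(sum(countDifferences(trees, maps, 16)$different), 0L)
  maps2 <- list(matchLineages(trees[[1]], trees[[2]], tCompare = 17,
                              guard = 3),
                matchLineages(trees[[1]], trees[[3]], tCompare = 17,
                              guard = 3),
                matchLineages(trees[[2]], trees[[3]], tCompare = 17,
                              guard = 3))
  d <- countDifferences(trees, maps2, 18)
  expect_equal(sum(d$different), 2L)
  expect_equal(d$different[1], 2L)
})

test_that("censoring a recording never creates real differences", {
  long <- simulateCohort(2, 11, variability = zeroVariability(),
                         tEnd = 26)
  trA <- simTree(long[[1]])
  trBfull <- simTree(long[[2]])
  # truncate embryo B's recording to 22.9 hpf
  cut <- 22.9
  ndB <- treeNodes(trBfull)
  posB <- treePositions(trBfull)
  ndB <- ndB[ndB$birth < cut, ]
  over <- ndB$end >= cut
  ndB$end[over] <- cut
  ndB$fate[over] <- "censored"
  posB <- posB[posB$uid %in% ndB$uid & posB$t <= cut, ]
  trB <- lineageTree("truncated", ndB, posB,
                     recordingWindow = c(2, cut))
  m <- matchLineages(trA, trB, tCompare = 19, guard = 3)
  expect_equal(sum(m@unmatchedA$reason == "real_difference"), 0L)
  expect_equal(sum(m@unmatchedB$reason == "real_difference"), 0L)
  # against the untruncated recording nothing is censored either
  m0 <- matchLineages(trA, trBfull, tCompare = 19, guard = 3)
  expect_gte(sum(m@unmatchedA$reason == "censored"),
             sum(m0@unmatchedA$reason == "censored"))
})

test_that("greedy matching equals the brute-force optimum on small
          trees", {
  worst <- 1
  for (i in 1:200) {
    trA <- randomTree(sample(4:8, 1), seed = 1000 + i, embryoId = "A")
    trB <- lineageTree("B", treeNodes(trA), treePositions(trA),
                       recordingWindow = recordingWindow(trA))
    m <- matchLineages(trA, trB, rootPairs = cbind("r", "r"),
                       tCompare = 25, guard = 3)
    g <- greedyMatchScore(m, trA, 25)
    b <- bruteForceMatchScore(trA, trB, "r", "r", 25, 3)
    expect_equal(g, b, tolerance = 1e-9)
  }
  # jittered copies: greedy stays within 5 percent of the optimum
  for (i in 1:50) {
    nl <- sample(4:8, 1)
    trA <- randomTree(nl, seed = 3000 + i, embryoId = "A")
    trB <- randomTree(nl, seed = 3000 + i, embryoId = "B",
                      jitterSd = 0.5)
    m <- matchLineages(trA, trB, rootPairs = cbind("r", "r"),
                       tCompare = 25, guard = 3)
    g <- greedyMatchScore(m, trA, 25)
    b <- bruteForceMatchScore(trA, trB, "r", "r", 25, 3)
    if (b > 0) worst <- min(worst, g / b)
  }
  expect_gte(worst, 0.95)
})

test_that("consensus of identical trees is the tree at full support", {
  co <- zeroVarCohort(tEnd = 20)
  trees <- lapply(co, simTree)
  maps <- list(matchLineages(trees[[1]], trees[[2]], tCompare = 16),
               matchLineages(trees[[1]], trees[[3]], tCompare = 16),
               matchLineages(trees[[2]], trees[[3]], tCompare = 16))
  cons <- buildConsensus(trees, maps, strict = TRUE)
  nd <- cons@nodes
  # retained divisions (support beyond half the cohort) all have full
  # support and zero-width time ranges in an identical cohort
  div <- nd[nd$support * 2 > cons@cohortSize, ]
  expect_true(all(div$support == 3))
  expect_false(any(nd$low_support))
  expect_equal(max(div$t_max - div$t_min), 0)
  expect_match(nd$rid, "^r[0-9]+$")
  # retained divisions are exactly the divisions of cells created by
  # the matched part of the tree (roots or divisions before the
  # comparison point)
  ndA <- treeNodes(trees[[1]])
  expect_equal(nrow(div),
               sum(ndA$fate == "divided" &
                     (is.na(ndA$parent) | ndA$birth <= 16)))
})

test_that("a division in 2 of 3 embryos is retained and flagged", {
  co <- zeroVarCohort(tEnd = 20)
  trees <- lapply(co, simTree)
  # drop one leaf division (the right eye pair) from embryo 3
  nd <- treeNodes(trees[[3]])
  drop <- c("1c-121121a", "1c-121121b")
  nd <- nd[!(nd$uid %in% drop), ]
  i <- match("1c-121121", nd$uid)
  nd$fate[i] <- "terminal"; nd$end[i] <- 20
  pos <- treePositions(trees[[3]])
  pos <- pos[!(pos$uid %in% drop), ]
  trees[[3]] <- lineageTree(embryoId(trees[[3]]), nd, pos,
                            recordingWindow = c(2, 20))
  maps <- list(matchLineages(trees[[1]], trees[[2]], tCompare = 16),
               matchLineages(trees[[1]], trees[[3]], tCompare = 16),
               matchLineages(trees[[2]], trees[[3]], tCompare = 16))
  cons <- buildConsensus(trees, maps)
  ndc <- cons@nodes
  hit <- ndc[!is.na(ndc$name) & ndc$name == "1c-121121", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$support, 2L)
  expect_true(hit$low_support)
})

test_that("inconsistent correspondence cycles error in strict mode", {
  tiny <- function(id) {
    lineageTree(id, data.frame(
      uid = c("p", "q"), rid = NA, name = NA, parent = NA_character_,
      birth = 2, end = 10, fate = "censored", mode = NA, tag = NA,
      stringsAsFactors = FALSE), recordingWindow = c(2, 10))
  }
  mk <- function(a, b, ua, ub) {
    new("CorrespondenceMap", embryoA = a, embryoB = b,
        pairs = data.frame(uid_a = ua, uid_b = ub, score = 1,
                           pairing = "straight",
                           stringsAsFactors = FALSE),
        unmatchedA = data.frame(uid = character(),
                                reason = character()),
        unmatchedB = data.frame(uid = character(),
                                reason = character()),
        tCompare = 8, guard = 1)
  }
  trees <- list(tiny("e1"), tiny("e2"), tiny("e3"))
  maps <- list(mk("e1", "e2", c("p", "q"), c("p", "q")),
               mk("e2", "e3", c("p", "q"), c("p", "q")),
               mk("e1", "e3", c("p", "q"), c("q", "p")))  # crossed
  expect_error(buildConsensus(trees, maps, strict = TRUE),
               "inconsistent")
  expect_no_error(buildConsensus(trees, maps))
})

test_that("division asynchrony follows its definition", {
  co <- zeroVarCohort(tEnd = 20)
  trees <- lapply(co, simTree)
  maps <- list(matchLineages(trees[[1]], trees[[2]], tCompare = 16),
               matchLineages(trees[[1]], trees[[3]], tCompare = 16),
               matchLineages(trees[[2]], trees[[3]], tCompare = 16))
  expect_equal(maxTimingAsynchrony(trees, maps, c(2, 16)), 0)
  expect_true(is.na(maxTimingAsynchrony(trees, maps, c(0, 1))))

  # two embryos, one corresponding division at 10 vs 11 hpf
  mk1 <- function(id, tdiv) {
    nodes <- data.frame(
      uid = c("r", "a", "b"), rid = NA, name = NA,
      parent = c(NA, "r", "r"), birth = c(2, tdiv, tdiv),
      end = c(tdiv, 20, 20), fate = c("divided", "censored", "censored"),
      mode = NA, tag = NA, stringsAsFactors = FALSE)
    lineageTree(id, nodes, recordingWindow = c(2, 20))
  }
  t1 <- mk1("x", 10); t2 <- mk1("y", 11)
  mp <- new("CorrespondenceMap", embryoA = "x", embryoB = "y",
            pairs = data.frame(uid_a = c("r", "a", "b"),
                               uid_b = c("r", "a", "b"), score = 1,
                               pairing = "straight",
                               stringsAsFactors = FALSE),
            unmatchedA = data.frame(uid = character(),
                                    reason = character()),
            unmatchedB = data.frame(uid = character(),
                                    reason = character()),
            tCompare = 16, guard = 3)
  expect_equal(maxTimingAsynchrony(list(t1, t2), list(mp), c(8, 12)),
               1.0)
})
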