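test_that("the fitted mirror plane recovers the sagittal plane", {
  # bilateral symmetry dominates the cell arrangement once the founder
  # clones have grown; fit at a late stage of the canonical embryo
  tr <- simTree(canonicalEmbryo(tEnd = 32))
  pl <- estimateMirrorPlane(tr, 30)
  # the frame convention puts the plane at x = 0 (normal azimuth 0)
  off <- min(pl@azimuth, pi - pl@azimuth) * 180 / pi
  expect_lt(off, 2)

  # equivariance: rotating the embryo rotates the recovered azimuth
  ang <- 25 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0,
                0, 0, 1), 3)
  pos <- treePositions(tr)
  rot <- as.matrix(pos[, c("x", "y", "z")]) %*% t(R)
  trR <- lineageTree("rot", treeNodes(tr),
                     data.frame(uid = pos$uid, t = pos$t, x = rot[, 1],
                                y = rot[, 2], z = rot[, 3]),
                     recordingWindow = recordingWindow(tr))
  plR <- estimateMirrorPlane(trR, 30)
  shift <- abs(((plR@azimuth - pl@azimuth) - ang + pi / 2) %% pi -
                 pi / 2)
  expect_lt(shift * 180 / pi, 2)
})

test_that("the plane fit matches an exhaustive 0.1-degree scan", {
  set.seed(99)
  for (rep in 1:3) {
    # 10 mirrored point pairs about a random azimuth
    a0 <- runif(1, 0, pi)
    n <- c(cos(a0), sin(a0), 0)
    P0 <- cbind(runif(10, -1, 1), runif(10, -1, 1), runif(10, 0.2, 1))
    M <- P0 - 2 * (P0 %*% n) %*% t(n)
    P <- rbind(P0, M) + matrix(rnorm(60, 0, 0.01), ncol = 3)
    fit <- spiralineage:::.fitMirrorAzimuth(P)
    grid <- seq(0, pi, by = 0.1 * pi / 180)
    obj <- vapply(grid, function(a)
      spiralineage:::.mirrorObjective(P, a), 0)
    best <- grid[which.min(obj)]
    d <- abs((fit@azimuth - best + pi / 2) %% pi - pi / 2)
    expect_lt(d, 0.1 * pi / 180 + 1e-6)
    expect_lte(fit@objective, min(obj) + 1e-9)
  }
  expect_error(spiralineage:::.fitMirrorAzimuth(
    cbind(0, 0, c(1, 2, 3))), "degenerate")
})

test_that("clone topology similarity scores match hand enumeration", {
  tr <- simTree(canonicalEmbryo(tEnd = 32))
  # a clone against itself is perfect
  expect_equal(cloneTopologySimilarity(tr, "1d-1122", "1d-1122"), 1.0)
  # mirrored founder clones are perfect
  expect_equal(cloneTopologySimilarity(tr, "1d-1122", "1c-1122"), 1.0)
  expect_equal(cloneTopologySimilarity(tr, "1a-1121121",
                                       "1a-1121211"), 1.0)
  # two terminal cells are trivially similar
  expect_equal(cloneTopologySimilarity(tr, "1a-221", "1b-222"), 1.0)

  # balanced 4-leaf clone vs 2-leaf clone with matching times: the root
  # divisions match, the deeper ones cannot: 2 * 1 / (3 + 1) = 0.5
  nodes <- data.frame(
    uid = c("u", "u1", "u2", "u11", "u12", "u21", "u22",
            "v", "v1", "v2"),
    rid = NA, name = NA,
    parent = c(NA, "u", "u", "u1", "u1", "u2", "u2", NA, "v", "v"),
    birth = c(2, 5, 5, 8, 8, 8, 8, 2, 5, 5),
    end = c(5, 8, 8, 20, 20, 20, 20, 5, 20, 20),
    fate = c("divided", "divided", "divided", rep("terminal", 4),
             "divided", "terminal", "terminal"),
    mode = NA, tag = NA, stringsAsFactors = FALSE)
  tr2 <- lineageTree("hand", nodes, recordingWindow = c(2, 20))
  expect_equal(cloneTopologySimilarity(tr2, "u", "v"), 0.5)
})

test_that("the canonical embryo yields exactly the 11 registered founder
          pairs", {
  tr <- simTree(canonicalEmbryo(tEnd = 32))
  fp <- detectBilateralFounders(tr)
  reg <- founderRegistry(canonicalProgram())
  expect_equal(nrow(fp), 11L)
  expect_setequal(paste(fp$left_name, fp$right_name),
                  paste(reg$left, reg$right))
  expect_true(all(fp$topology_score >= 0.999))
  expect_true(all(pmin(fp$birth_left, fp$birth_right) >= 6))
  expect_true(all(pmin(fp$birth_left, fp$birth_right) <= 18))
  # classes agree with the registry's lineage relationship
  classMap <- c(quadrant_homolog = "QUADRANT_HOMOLOG_ABCD",
                ac_homolog = "AC_HOMOLOG",
                single_quadrant = "SINGLE_QUADRANT",
                non_corresponding = "NON_CORRESPONDING")
  got <- fp$symmetry_class[match(paste(reg$left, reg$right),
                                 paste(fp$left_name, fp$right_name))]
  expect_identical(got, unname(classMap[reg$class]))
})

test_that("prototroch and apical-rosette cells never join founder
          pairs", {
  tr <- simTree(canonicalEmbryo(tEnd = 32))
  fp <- detectBilateralFounders(tr)
  nd <- treeNodes(tr)
  excluded <- c(nd$uid[nd$tag %in% c("primary_prototroch",
                                     "accessory_prototroch")],
                grep("^1[abcd]-111$", nd$uid, value = TRUE))
  expect_equal(length(intersect(c(fp$left_uid, fp$right_uid),
                                excluded)), 0L)
})

test_that("founder detection is mirror-equivariant", {
  tr <- simTree(canonicalEmbryo(tEnd = 32))
  pos <- treePositions(tr)
  trM <- lineageTree("mirrored", treeNodes(tr),
                     data.frame(uid = pos$uid, t = pos$t, x = -pos$x,
                                y = pos$y, z = pos$z),
                     recordingWindow = recordingWindow(tr))
  fp <- detectBilateralFounders(tr)
  fpM <- detectBilateralFounders(trM)
  expect_setequal(paste(fpM$left_uid, fpM$right_uid),
                  paste(fp$right_uid, fp$left_uid))
})

test_that("a hand-built tree with one mirrored clone yields exactly that
          pair", {
  tr <- plantedFounderTree(1)
  fp <- detectBilateralFounders(tr)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$left_uid, "fL")
  expect_equal(fp$right_uid, "fR")
})

test_that("detection equals brute-force pair enumeration on small
          trees", {
  for (i in 1:50) {
    tr <- plantedFounderTree(100 + i, nBackground = sample(5:12, 1))
    fp <- detectBilateralFounders(tr)
    got <- sort(paste(fp$left_uid, fp$right_uid))
    expect_identical(got, bruteForceFounders(tr), label = paste("seed",
                                                                100 + i))
  }
  # and on small canonical embryos (every cross-side pair enumerated)
  emb <- simulateEmbryo(canonicalProgram(), zeroVariability(), 1,
                        tEnd = 9)
  tr <- simTree(emb)
  fp <- detectBilateralFounders(tr)
  expect_identical(sort(paste(fp$left_uid, fp$right_uid)),
                   bruteForceFounders(tr))
})

test_that("founder pairs classify by quadrant relationship", {
  expect_equal(classifyFounderPair("1a-1122", "1b-1122"),
               "QUADRANT_HOMOLOG_ABCD")
  expect_equal(classifyFounderPair("1a-1121211", "1a-1121121"),
               "SINGLE_QUADRANT")
  expect_equal(classifyFounderPair("1c-12111", "1a-12111"),
               "AC_HOMOLOG")
  expect_equal(classifyFounderPair("1d-112111", "1c-112121"),
               "NON_CORRESPONDING")
  expect_error(classifyFounderPair("1m-1122", "1b-1122"), "shorthand")
})

test_that("rotational symmetry scoring follows its definition", {
  # perfect 12-point ring
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  mkRing <- function(disp = 0) {
    xy <- cbind(cos(ang), sin(ang)) * 0.9
    xy[1, ] <- xy[1, ] + disp
    nodes <- data.frame(uid = paste0("c", 1:12), rid = NA, name = NA,
                        parent = NA_character_, birth = 2, end = 10,
                        fate = "terminal", mode = NA, tag = NA,
                        stringsAsFactors = FALSE)
    pos <- data.frame(uid = paste0("c", 1:12), t = 2, x = xy[, 1],
                      y = xy[, 2], z = 0.43)
    lineageTree("ring", nodes, pos, recordingWindow = c(2, 10))
  }
  ring <- mkRing()
  expect_equal(rotationalSymmetryScore(ring, paste0("c", 1:12), 4, 2),
               1.0)
  expect_error(rotationalSymmetryScore(ring, paste0("c", 1:3), 4, 2),
               "at least")

  # one cell displaced by one spacing: evaluate the definition on the
  # explicit points independently
  d <- 2 * 0.9 * sin(pi / 12)
  ringD <- mkRing(disp = d)
  P <- as.matrix(treePositions(ringD)[, c("x", "y", "z")])
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  Q <- P %*% t(R)
  nn <- function(A, B) {
    dd <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(pmax(dd, 0))
  }
  drot <- mean(apply(nn(P, Q), 1, min))
  spac <- nn(P, P); diag(spac) <- Inf
  expected <- max(0, min(1, 1 - drot / mean(apply(spac, 1, min))))
  expect_equal(rotationalSymmetryScore(ringD, paste0("c", 1:12), 4, 2),
               expected, tolerance = 1e-6)
})
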