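# Independent brute-force founder detection: applies the three criteria
# directly to every cross-side cell pair, prunes to the earliest
# qualifying generation and selects disjoint pairs greedily — mirroring
# the documented contract without sharing the implementation's candidate
# generation or pruning code paths.
bruteForceFounders <- function(tree, dtTol = 1.0, mirrorEps = 0.10,
                               topoMin = 0.8,
                               horizon = recordingWindow(tree)[2]) {
  nd <- treeNodes(tree)
  pos <- spiralineage:::.birthPosition(tree, nd$uid, window = 0.5)
  cand <- list()
  for (i in seq_len(nrow(nd))) for (j in seq_len(nrow(nd))) {
    if (pos[i, 1] >= 0 || pos[j, 1] <= 0) next
    if (abs(nd$birth[i] - nd$birth[j]) > dtTol) next
    mp <- pos[i, ]; mp[1] <- -mp[1]
    md <- sqrt(sum((mp - pos[j, ])^2))
    if (md > mirrorEps) next
    ts <- cloneTopologySimilarity(tree, nd$uid[i], nd$uid[j],
                                  dtTol = dtTol, horizon = horizon)
    if (ts < topoMin) next
    cand[[length(cand) + 1L]] <- list(i = i, j = j, md = md, ts = ts)
  }
  if (!length(cand)) return(character())
  candSet <- vapply(cand, function(x) paste(x$i, x$j), "")
  ancIdx <- function(i) match(spiralineage:::.ancestors(nd, nd$uid[i]),
                              nd$uid)
  keep <- vapply(cand, function(x) {
    for (a in ancIdx(x$i)) for (b in ancIdx(x$j))
      if (paste(a, b) %in% candSet) return(FALSE)
    TRUE
  }, TRUE)
  cand <- cand[keep]
  ord <- order(-vapply(cand, `[[`, 0, "ts"),
               vapply(cand, `[[`, 0, "md"),
               vapply(cand, function(x) nd$uid[x$i], ""),
               vapply(cand, function(x) nd$uid[x$j], ""))
  used <- logical(nrow(nd))
  out <- character()
  for (k in ord) {
    x <- cand[[k]]
    if (used[x$i] || used[x$j]) next
    used[x$i] <- used[x$j] <- TRUE
    out <- c(out, paste(nd$uid[x$i], nd$uid[x$j]))
  }
  sort(out)
}

# small embryo-like tree with a planted mirrored founder pair plus
# asymmetric background cells, for detector/brute-force comparisons
plantedFounderTree <- function(seed, nBackground = 8) {
  set.seed(seed)
  rows <- list(); prows <- list()
  addCell <- function(uid, parent, birth, end, fate, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      uid = uid, rid = NA, name = NA, parent = parent, birth = birth,
      end = end, fate = fate, mode = NA, tag = NA,
      stringsAsFactors = FALSE)
    prows[[length(prows) + 1L]] <<- data.frame(
      uid = uid, t = c(birth, end), x = x, y = y, z = z,
      stringsAsFactors = FALSE)
  }
  addCell("root", NA_character_, 2, 6, "divided", 0.02, 0.4, 0.9)
  # mirrored pair: founders born at 6, each dividing once at 10 into
  # two terminal daughters (identical clone topology)
  fx <- runif(1, 0.3, 0.6); fy <- runif(1, -0.4, 0.4)
  fz <- sqrt(max(0.05, 1 - fx^2 - fy^2))
  addCell("fL", "root", 6, 10, "divided", -fx, fy, fz)
  addCell("fR", "root", 6, 10, "divided", fx, fy, fz)
  for (s in c("L", "R")) {
    sx <- if (s == "L") -1 else 1
    addCell(paste0("f", s, "1"), paste0("f", s), 10, 20, "terminal",
            sx * (fx + 0.05), fy + 0.05, fz)
    addCell(paste0("f", s, "2"), paste0("f", s), 10, 20, "terminal",
            sx * (fx - 0.05), fy - 0.05, fz)
  }
  # asymmetric background: untracked-origin (root) terminal cells at
  # scattered positions and staggered birth times
  for (k in seq_len(nBackground)) {
    ang <- runif(1, 0, 2 * pi)
    r <- runif(1, 0.3, 0.9)
    b <- 3 + k * 1.3
    addCell(paste0("bg", k), NA_character_, b, 20, "terminal",
            r * cos(ang), r * sin(ang), sqrt(max(0.02, 1 - r^2)))
  }
  nodes <- do.call(rbind, rows)
  pos <- do.call(rbind, prows)
  lineageTree(paste0("planted", seed), nodes, pos,
              recordingWindow = c(2, 20))
}
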