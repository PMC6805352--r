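#' Inter-embryo variability model
#'
#' Parameters of the stochastic deviations applied on top of the canonical
#' program.  With the defaults, division-time jitter grows linearly with
#' developmental time (calibrated so the 3-embryo mean max-minus-min
#' division-time difference reaches about 2.5 h between 30 and 34 hpf),
#' lineage deviations (extra or skipped divisions, in equal proportion)
#' occur after a 16 hpf onset at a per-division rate calibrated to give
#' roughly 10 percent differing cells at 30 hpf, nuclear positions carry
#' 2 percent-of-radius measurement noise, and the variable ventral rosette
#' cell 1b-111 divides not at all (p = 3/6), once (2/6) or twice (1/6),
#' with a first-division time drawn uniformly from its characteristic
#' window (clipped at the deviation onset, before which embryos are
#' indistinguishable).
#'
#' @param jitterSlope division-time jitter SD growth per hour (SD is
#'   \code{jitterSlope * (t - 2)}).
#' @param deviationOnset hpf after which lineage deviations occur.
#' @param deviationRate per-division probability of a lineage deviation.
#' @param positionNoise positional noise SD, fraction of hemisphere radius.
#' @param b111Probs probabilities of \{no, one, more\} divisions of 1b-111.
#' @param b111Window first-division window of 1b-111 (hpf).
#' @return a [VariabilityModel-class].
#' @export
variabilityModel <- function(jitterSlope = 0.060,
                             deviationOnset = 16,
                             deviationRate = 0.40,
                             positionNoise = 0.02,
                             b111Probs = c(3, 2, 1) / 6,
                             b111Window = c(12, 24)) {
  new("VariabilityModel", jitterSlope = jitterSlope,
      deviationOnset = deviationOnset, deviationRate = deviationRate,
      positionNoise = positionNoise, b111Probs = b111Probs,
      b111Window = b111Window)
}

#' @describeIn variabilityModel the deterministic no-variability model: the
#'   simulated embryo is exactly the canonical embryo for every seed.
#' @export
zeroVariability <- function() {
  new("VariabilityModel", jitterSlope = 0, deviationOnset = Inf,
      deviationRate = 0, positionNoise = 0, b111Probs = c(1, 0, 0),
      b111Window = c(12, 24))
}

setMethod("show", "VariabilityModel", function(object) {
  cat("VariabilityModel: jitter slope", signif(object@jitterSlope, 4),
      "SD/h, deviation rate", object@deviationRate, "after",
      object@deviationOnset, "hpf, position noise",
      object@positionNoise, "\n")
})

.TERMINAL_TAGS <- c("primary_prototroch", "accessory_prototroch",
                    "apical_organ", "terminal")

# nominal inter-daughter separation at developmental time t
.sepAt <- function(t) max(0.13, 0.55 * exp(-(t - 2) / 6))

#' Simulate one tracked episphere embryo
#'
#' Deterministically realises the canonical program under a variability
#' model: a given (program, variability, seed) triple always produces the
#' identical embryo, and with [zeroVariability()] the output is the
#' canonical embryo for any seed.  The stereotypic phase follows the
#' scripted events; from each bilateral founder onwards the clone grows by
#' parametric proliferation (per-clone cycle length and division depth,
#' lateral clones fastest), mirrored exactly between the left and right
#' pair members.  The tracked positions sample each cell every 0.5 h plus
#' at its end time, with optional per-timepoint measurement noise.
#'
#' @param program a [CanonicalProgram-class].
#' @param variability a [VariabilityModel-class].
#' @param seed integer master seed; all randomness is derived from it,
#'   namespaced per embryo and per event.
#' @param tEnd end of the recording (hpf, in (2, 34]).
#' @param embryoId identifier for the simulated recording.
#' @return a [SimulatedEmbryo-class].
#' @examples
#' emb <- simulateEmbryo(canonicalProgram(), zeroVariability(), 1, tEnd = 8)
#' length(aliveAt(simTree(emb), 8))
#' @export
simulateEmbryo <- function(program = canonicalProgram(),
                           variability = variabilityModel(),
                           seed = 1L, tEnd = 32,
                           embryoId = paste0("sim", seed)) {
  stopifnot(is(program, "CanonicalProgram"),
            is(variability, "VariabilityModel"))
  if (tEnd < 2) stop("tEnd must be at least 2 hpf (first micromeres)")
  if (tEnd > 34) stop("tEnd must not exceed 34 hpf")
  v <- variability
  ex <- .expandEvents(program@events)
  eventIdx <- split(seq_len(nrow(ex)), ex$mother)
  reg <- program@founders
  regMember <- c(stats::setNames(seq_len(nrow(reg)), reg$left),
                 stats::setNames(-seq_len(nrow(reg)), reg$right))
  overrides <- .scriptedPositions(program)

  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  emit <- function(uid, name, parent, birth, cbirth, end, fate, mode, tag,
                   pos) {
    acc$rows[[length(acc$rows) + 1L]] <-
      list(uid = uid, name = name, parent = parent, birth = birth,
           cbirth = cbirth, end = end, fate = fate, mode = mode,
           tag = tag, pos = pos)
  }

  jitter <- function(uid, tc) {
    if (v@jitterSlope == 0) return(tc)
    s <- v@jitterSlope * max(0, tc - 2)
    tc + .eventDraw(seed, paste(embryoId, "jit", uid), function()
      stats::rnorm(1, 0, s))
  }
  skips <- function(uid, tc) {
    v@deviationRate > 0 && tc > v@deviationOnset &&
      .eventDraw(seed, paste(embryoId, "skip", uid),
                 function() stats::runif(1)) < v@deviationRate / 2
  }

  # ---- scripted / growth recursion -----------------------------------
  develop <- function(uid, name, parent, birth, cbirth, tag, pos) {
    terminalTag <- !is.na(tag) && tag %in% c("apoptotic", "migrates_out")
    if (terminalTag) {
      dwell <- if (tag == "apoptotic") 4 else 1.5
      tend <- birth + dwell
      if (tend <= tEnd) {
        emit(uid, name, parent, birth, cbirth, tend,
             if (tag == "apoptotic") "apoptotic" else "migrated_out",
             NA_character_, tag, pos)
      } else {
        emit(uid, name, parent, birth, cbirth, tEnd, "censored",
             NA_character_, tag, pos)
      }
      return(invisible())
    }
    if (!is.na(tag) && tag %in% .TERMINAL_TAGS) {
      .maybeExtra(uid, name, parent, birth, cbirth, tag, pos)
      return(invisible())
    }
    idx <- if (!is.na(name)) eventIdx[[name]] else NULL
    if (!is.null(idx)) {
      .runScripted(uid, name, parent, birth, cbirth, tag, pos, ex[idx[1], ])
      return(invisible())
    }
    if (!is.na(name) && !is.na(regMember[name])) {
      m <- unname(regMember[name])
      row <- reg[abs(m), ]
      if (!is.na(row$cycle_h)) {
        .growClone(uid, name, parent, birth, cbirth, pos, row, m > 0)
        return(invisible())
      }
    }
    if (!is.na(name) && name == "1b-111") {
      .runB111(uid, name, parent, birth, cbirth, pos)
      return(invisible())
    }
    .maybeExtra(uid, name, parent, birth, cbirth,
                if (is.na(tag)) "none" else tag, pos)
  }

  # a division may be skipped only when it is the final (leaf-producing)
  # division of its branch: observed inter-embryo differences are local
  # missing/extra terminal divisions, not wholesale loss of clones
  .daughterIsLeaf <- function(name, tag) {
    (!is.na(tag) && tag %in% c(.TERMINAL_TAGS, "apoptotic",
                               "migrates_out")) ||
      (is.null(eventIdx[[name]]) && is.na(regMember[name]) &&
         name != "1b-111")
  }

  .runScripted <- function(uid, name, parent, birth, cbirth, tag, pos, evt) {
    tc <- evt$time
    d1n <- .childName(name, evt$d1)
    d2n <- .childName(name, evt$d2)
    leafDiv <- .daughterIsLeaf(d1n, .na2none(evt$d1_tag)) &&
      .daughterIsLeaf(d2n, .na2none(evt$d2_tag))
    if (leafDiv && skips(uid, tc)) {
      emit(uid, name, parent, birth, cbirth, tEnd, "terminal",
           NA_character_, "skipped_division", pos)
      return(invisible())
    }
    td <- max(birth + 0.25, jitter(uid, tc))
    if (td >= tEnd) {
      emit(uid, name, parent, birth, cbirth, tEnd, "censored",
           NA_character_, tag, pos)
      return(invisible())
    }
    d1 <- d1n
    d2 <- d2n
    dp <- placeDaughters(pos, evt$mode, separation = .sepAt(tc))
    p1 <- .placedPosition(d1, dp[1, ], overrides, reg, regMember)
    p2 <- .placedPosition(d2, dp[2, ], overrides, reg, regMember)
    emit(uid, name, parent, birth, cbirth, td, "divided", evt$mode, tag, pos)
    develop(d1, d1, uid, td, tc, .na2none(evt$d1_tag), p1)
    develop(d2, d2, uid, td, tc, .na2none(evt$d2_tag), p2)
  }

  .growClone <- function(uid, name, parent, birth, cbirth, pos, row,
                         isLeft) {
    cycle <- row$cycle_h
    layout <- .cloneLayout(row, isLeft)
    recurse <- function(uid, name, parent, birth, cbirth, depth, path,
                        pos) {
      if (depth >= row$depth) {
        .maybeExtra(uid, name, parent, birth, cbirth, "none", pos)
        return(invisible())
      }
      tc <- cbirth + cycle
      if (depth == row$depth - 1L && skips(uid, tc)) {
        emit(uid, name, parent, birth, cbirth, tEnd, "terminal",
             NA_character_, "skipped_division", pos)
        return(invisible())
      }
      td <- max(birth + 0.25, jitter(uid, tc))
      if (tc > tEnd || td >= tEnd) {
        emit(uid, name, parent, birth, cbirth, tEnd, "censored",
             NA_character_, "none", pos)
        return(invisible())
      }
      emit(uid, name, parent, birth, cbirth, td, "divided", "clone_growth",
           "none", pos)
      for (d in 1:2) {
        cpath <- paste0(path, d)
        cuid <- paste0(sub("\\..*$", "", uid), ".", cpath)
        recurse(cuid, NA_character_, uid, td, tc, depth + 1L, cpath,
                layout(cpath, pos))
      }
    }
    recurse(uid, name, parent, birth, cbirth, 0L, "", pos)
  }

  # deterministic mirrored clone layout: directions are fixed in the
  # tangent frame of the right member's scripted position and mirrored
  # wholesale for the left member
  .cloneLayout <- function(row, isLeft) {
    p0 <- .sphPoint(row$az_deg, row$pol_deg)
    b <- .tangentBasis(p0)
    function(path, parentPos) {
      k <- nchar(path)
      ang <- k * 2.399963               # golden-angle direction schedule
      dir <- cos(ang) * b$e_theta + sin(ang) * b$e_phi
      if (isLeft) dir <- .mirrorX(dir)
      # separations stay near the late-stage internuclear distance so
      # that daughter-offset directions remain informative against the
      # positional measurement noise
      s <- max(0.07, 0.09 * 0.8^(k - 1))
      sgn <- if (substr(path, k, k) == "1") -0.5 else 0.5
      p <- .projectHemisphere(parentPos + sgn * s * dir)
      # clones do not cross the midline: clamp to the founder's side
      xside <- if (isLeft) -1 else 1
      if (sign(p[1]) != xside) {
        p[1] <- xside * 0.02
        p <- .projectHemisphere(p)
      }
      p
    }
  }

  .runB111 <- function(uid, name, parent, birth, cbirth, pos) {
    cat_ <- .eventDraw(seed, paste(embryoId, "b111"), function()
      sample.int(3, 1, prob = v@b111Probs)) - 1L
    if (cat_ == 0L) {
      # 1b-111 variability is fully described by its own behaviour
      # distribution; it is not additionally exposed to the generic
      # deviation channel
      emit(uid, name, parent, birth, cbirth, tEnd, "terminal",
           NA_character_, "none", pos)
      return(invisible())
    }
    lo <- max(v@b111Window[1], v@deviationOnset)
    t1 <- .eventDraw(seed, paste(embryoId, "b111t"), function()
      stats::runif(1, lo, max(lo + 0.1, v@b111Window[2])))
    if (t1 >= tEnd) {
      emit(uid, name, parent, birth, cbirth, tEnd, "censored",
           NA_character_, "none", pos)
      return(invisible())
    }
    dp <- placeDaughters(pos, "bilateral", separation = .sepAt(t1))
    emit(uid, name, parent, birth, cbirth, t1, "divided", "bilateral",
         "none", pos)
    d1 <- paste0(name, "a"); d2 <- paste0(name, "b")
    if (cat_ == 2L && t1 + 3 < tEnd) {
      dp2 <- placeDaughters(dp[1, ], "bilateral", separation = 0.1)
      emit(d1, d1, uid, t1, t1, t1 + 3, "divided", "bilateral", "none",
           dp[1, ])
      emit(paste0(d1, "a"), paste0(d1, "a"), d1, t1 + 3, t1 + 3, tEnd,
           "terminal", NA_character_, "none", dp2[1, ])
      emit(paste0(d1, "b"), paste0(d1, "b"), d1, t1 + 3, t1 + 3, tEnd,
           "terminal", NA_character_, "none", dp2[2, ])
    } else {
      emit(d1, d1, uid, t1, t1, tEnd, "terminal", NA_character_, "none",
           dp[1, ])
    }
    emit(d2, d2, uid, t1, t1, tEnd, "terminal", NA_character_, "none",
         dp[2, ])
  }

  # terminal cell that may undergo an extra (deviant) division
  .maybeExtra <- function(uid, name, parent, birth, cbirth, tag, pos) {
    doExtra <- v@deviationRate > 0 &&
      .eventDraw(seed, paste(embryoId, "extra", uid), function()
        stats::runif(1)) < v@deviationRate / 2
    if (doExtra) {
      t0 <- max(birth + 0.5, v@deviationOnset)
      tx <- if (t0 < tEnd - 0.1)
        t0 + (tEnd - 0.1 - t0) *
          .eventDraw(seed, paste(embryoId, "extrat", uid), function()
            stats::runif(1))^2 else tEnd
      if (tx < tEnd - 0.1) {
        emit(uid, name, parent, birth, cbirth, tx, "divided",
             NA_character_, paste0(tag, "|extra_division"), pos)
        # the deviant daughters re-enter the cycle and proliferate
        deviantClone <- function(cuid, parentUid, birth, pos) {
          td <- birth + 4.5
          if (td < tEnd - 0.1) {
            dp <- placeDaughters(pos, "radial", separation = 0.06)
            emit(cuid, NA_character_, parentUid, birth, birth, td,
                 "divided", NA_character_, "deviant", pos)
            deviantClone(paste0(cuid, "1"), cuid, td, dp[1, ])
            deviantClone(paste0(cuid, "2"), cuid, td, dp[2, ])
          } else {
            emit(cuid, NA_character_, parentUid, birth, birth, tEnd,
                 "terminal", NA_character_, "deviant", pos)
          }
        }
        dp <- placeDaughters(pos, "radial", separation = 0.08)
        deviantClone(paste0(uid, ".x1"), uid, tx, dp[1, ])
        deviantClone(paste0(uid, ".x2"), uid, tx, dp[2, ])
        return(invisible())
      }
    }
    emit(uid, name, parent, birth, cbirth, tEnd, "terminal",
         NA_character_, tag, pos)
  }

  # ---- run ------------------------------------------------------------
  # quadrant azimuths carry the rotational (spiral) offset of the cleavage
  # pattern: the quadrant arrangement is fourfold rotationally symmetric
  # but not mirror symmetric about the future sagittal plane
  for (q in c("a", "b", "c", "d")) {
    nm <- paste0("1", q)
    az <- c(a = 237, b = 327, c = 57, d = 147)[[q]]
    develop(nm, nm, NA_character_, 2.0, 2.0, "none",
            .sphPoint(az, 60))
  }

  rows <- acc$rows
  nodes <- data.frame(
    uid = vapply(rows, `[[`, "", "uid"),
    rid = NA_character_,
    name = vapply(rows, `[[`, "", "name"),
    parent = vapply(rows, `[[`, "", "parent"),
    birth = vapply(rows, `[[`, 0, "birth"),
    end = vapply(rows, `[[`, 0, "end"),
    fate = vapply(rows, `[[`, "", "fate"),
    mode = vapply(rows, `[[`, "", "mode"),
    tag = vapply(rows, `[[`, "", "tag"),
    stringsAsFactors = FALSE)
  base <- t(vapply(rows, `[[`, numeric(3), "pos"))

  # ---- sampled positions ---------------------------------------------
  plist <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    tg <- seq(nodes$birth[i], nodes$end[i], by = 0.5)
    if (tg[length(tg)] < nodes$end[i] - 1e-9)
      tg <- c(tg, nodes$end[i])
    m <- length(tg)
    xyz <- matrix(rep(base[i, ], each = m), nrow = m)
    if (v@positionNoise > 0) {
      noise <- .eventDraw(seed, paste(embryoId, "noise", nodes$uid[i]),
                          function() stats::rnorm(3 * m, 0,
                                                  v@positionNoise))
      xyz <- xyz + matrix(noise, nrow = m)
    }
    plist[[i]] <- data.frame(uid = nodes$uid[i], t = tg, x = xyz[, 1],
                             y = xyz[, 2], z = xyz[, 3],
                             stringsAsFactors = FALSE)
  }
  positions <- do.call(rbind, plist)

  tree <- lineageTree(embryoId, nodes, positions,
                      recordingWindow = c(2, tEnd))
  truth <- stats::setNames(ifelse(nodes$tag %in% "deviant",
                                  NA_character_, nodes$uid), nodes$uid)
  ft <- reg[reg$left %in% nodes$uid & reg$right %in% nodes$uid, ,
            drop = FALSE]
  new("SimulatedEmbryo", tree = tree, truth = truth, founderTruth = ft)
}

#' @keywords internal
.na2none <- function(x) if (is.na(x) || x == "none") "none" else x

#' @keywords internal
.scriptedPositions <- function(program) {
  pl <- program@placements
  out <- lapply(seq_len(nrow(pl)), function(i)
    .sphPoint(pl$az_deg[i], pl$pol_deg[i]))
  names(out) <- pl$name
  out
}

#' @keywords internal
.placedPosition <- function(name, default, overrides, reg, regMember) {
  if (!is.null(overrides[[name]])) return(overrides[[name]])
  m <- regMember[name]
  if (!is.na(m)) {
    row <- reg[abs(m), ]
    p <- .sphPoint(row$az_deg, row$pol_deg)
    if (m > 0) p <- .mirrorX(p)   # left member mirrors the scripted right
    return(p)
  }
  default
}

#' @describeIn simulateEmbryo the simulated [LineageTree-class].
#' @param embryo a [SimulatedEmbryo-class].
#' @export
simTree <- function(embryo) embryo@tree

#' @describeIn simulateEmbryo ground-truth map uid -> canonical identity.
#' @export
simTruth <- function(embryo) embryo@truth

#' @describeIn simulateEmbryo realized founder-pair registry.
#' @export
simFounderTruth <- function(embryo) embryo@founderTruth

setMethod("show", "SimulatedEmbryo", function(object) {
  cat("SimulatedEmbryo", sQuote(object@tree@embryoId), "with",
      nrow(object@tree@nodes), "cells and",
      nrow(object@founderTruth), "realized founder pairs\n")
})

#' Simulate a cohort of embryos from a shared program
#'
#' @param n number of embryos (>= 2).
#' @param baseSeed integer; embryo i uses seed \code{baseSeed + i - 1}.
#' @param program,variability,tEnd as in [simulateEmbryo()].
#' @return list of [SimulatedEmbryo-class] objects.
#' @export
simulateCohort <- function(n, baseSeed = 1L,
                           program = canonicalProgram(),
                           variability = variabilityModel(), tEnd = 32) {
  if (n < 2) stop("a cohort needs at least 2 embryos")
  lapply(seq_len(n), function(i)
    simulateEmbryo(program, variability, seed = baseSeed + i - 1L,
                   tEnd = tEnd, embryoId = paste0("embryo", i)))
}

#' Time of the first (or last) division of a given geometric mode
#'
#' @param embryo a [SimulatedEmbryo-class].
#' @param mode a division mode (\code{"bilateral"}, \code{"radial"},
#'   \code{"budding"}, \code{"spiral_cw"}, \code{"spiral_ccw"}, or
#'   \code{"spiral"} to match either chirality).
#' @param which \code{"first"} (default) or \code{"last"}.
#' @return event time in hpf; \code{Inf} (or \code{-Inf} for
#'   \code{which = "last"}) when no such division exists.
#' @export
firstDivisionOfMode <- function(embryo, mode, which = c("first", "last")) {
  which <- match.arg(which)
  nd <- simTree(embryo)@nodes
  hit <- nd$fate == "divided" & !is.na(nd$mode) &
    (nd$mode == mode | (mode == "spiral" &
                          nd$mode %in% c("spiral_cw", "spiral_ccw")))
  tt <- nd$end[hit]
  if (which == "first") {
    if (length(tt)) min(tt) else Inf
  } else {
    if (length(tt)) max(tt) else -Inf
  }
}
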