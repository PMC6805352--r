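# The canonical episphere division program.
#
# The stereotypic phase (2-12 hpf and a few later scripted events) is given
# as explicit division events; where all four quadrants behave identically
# an event is written once against the collective 1m name and expanded at
# simulation time.  The late phase (towards 32 hpf) grows the clone of each
# bilateral founder parametrically (cycle length + division depth), since
# late development is proliferative rather than stereotypically scripted.

.evt <- function(mother, quadrants, time, mode, d1, d2, t1, t2) {
  data.frame(mother = mother, quadrants = quadrants, time = time,
             mode = mode, d1 = d1, d2 = d2, d1_tag = t1, d2_tag = t2,
             stringsAsFactors = FALSE)
}

#' @keywords internal
.buildCanonicalProgram <- function() {
  e <- rbind(
    # -- spiral cleavage of the first micromere quartet ------------------
    .evt("1m",      "abcd", 3.0, "spiral_cw",  "1", "2", "none", "none"),
    .evt("1m-2",    "abcd", 4.0, "spiral_ccw", "1", "2", "none", "none"),
    .evt("1m-1",    "abcd", 4.5, "spiral_ccw", "1", "2", "none", "none"),
    .evt("1m-11",   "abcd", 5.0, "spiral_cw",  "1", "2", "none", "none"),
    # primary prototroch: 1m-21 / 1m-22 divide radially, daughters exit
    .evt("1m-21",   "abcd", 6.5, "radial", "1", "2",
         "accessory_prototroch", "primary_prototroch"),
    .evt("1m-22",   "abcd", 7.0, "radial", "1", "2",
         "primary_prototroch", "primary_prototroch"),
    # accessory prototroch from 1m-12 (two spiral rounds); the 1d-12 clone
    # instead migrates out of the episphere through the prototroch gap
    .evt("1m-12",   "abc",  7.0, "spiral_cw", "1", "2",
         "none", "accessory_prototroch"),
    .evt("1d-12",   "-",    7.0, "spiral_cw", "1", "2",
         "migrates_out", "none"),
    .evt("1m-121",  "abc",  8.0, "spiral_ccw", "1", "2",
         "none", "accessory_prototroch"),
    .evt("1d-122",  "-",    8.0, "spiral_ccw", "1", "2",
         "accessory_prototroch", "migrates_out"),
    # -- first bilateral divisions ---------------------------------------
    .evt("1m-112",  "abcd", 6.0, "bilateral", "1", "2", "none", "none"),
    .evt("1m-1121", "abcd", 8.0, "bilateral", "1", "2", "none", "none"),
    # -- apical rosette / apical organ -----------------------------------
    .evt("1c-111",  "-",  9.0, "radial", "1", "2",
         "apical_organ", "apical_organ"),          # ampullary cells
    .evt("1d-111",  "-", 10.0, "radial", "1", "2",
         "apical_organ", "apical_organ"),  # large dorsal apical + flask
    .evt("1a-111",  "-",  9.0, "budding", "1", "2", "none", "apical_organ"),
    .evt("1a-1111", "-", 12.0, "radial", "1", "2", "apical_organ", "none"),
    .evt("1a-11112",  "-", 17.5, "bilateral", "a", "b", "none", "none"),
    .evt("1a-11112a", "-", 23.0, "bilateral", "a", "b", "none", "none"),
    .evt("1a-11112b", "-", 23.0, "bilateral", "a", "b", "none", "none"),
    # -- dorso-medial founders (C/D quadrants, non-corresponding) --------
    .evt("1d-11211",  "-", 10.6, "bilateral", "1", "2", "none", "none"),
    .evt("1d-11212",  "-", 12.6, "bilateral", "1", "2", "none", "none"),
    .evt("1c-11212",  "-", 10.0, "bilateral", "1", "2", "none", "none"),
    .evt("1c-112122", "-", 11.4, "bilateral", "1", "2", "none", "terminal"),
    .evt("1c-11211",  "-", 12.0, "bilateral", "1", "2", "none", "none"),
    .evt("1c-112112", "-", 13.4, "bilateral", "1", "2", "none", "terminal"),
    # -- ventro-medial founders (A/B quadrants, non-corresponding) -------
    .evt("1a-11211",  "-", 10.2, "bilateral", "1", "2", "none", "none"),
    .evt("1a-112112", "-", 12.0, "bilateral", "1", "2", "none", "terminal"),
    .evt("1a-11212",  "-", 10.6, "bilateral", "1", "2", "none", "none"),
    .evt("1a-112121", "-", 12.2, "bilateral", "1", "2", "none", "terminal"),
    .evt("1b-11212",  "-", 10.8, "bilateral", "1", "2", "none", "terminal"),
    .evt("1b-11211",  "-", 11.2, "bilateral", "1", "2", "terminal", "none"),
    # -- the A|C clone: bilateral divisions inside 1a-12 / 1c-12 ---------
    .evt("1m-1211",   "ac", 10.5, "bilateral", "1", "2",
         "apoptotic", "none"),
    .evt("1m-12112",  "ac", 13.0, "bilateral", "1", "2", "none", "terminal"),
    .evt("1a-121121", "-",  16.0, "bilateral", "1", "2",
         "terminal", "terminal"),                   # left eye pair
    .evt("1c-121121", "-",  16.0, "bilateral", "a", "b",
         "terminal", "terminal"),                   # right eye pair
    # -- single-quadrant founder chain inside the 1b-121 clone -----------
    .evt("1b-1211",   "-", 10.5, "bilateral", "1", "2", "none", "none"),
    .evt("1b-12111",  "-", 13.0, "bilateral", "a", "b", "none", "terminal"),
    .evt("1b-12111a", "-", 15.5, "bilateral", "a", "b", "none", "terminal"),
    .evt("1b-12112",  "-", 13.0, "bilateral", "1", "2", "none", "terminal"),
    .evt("1b-121121", "-", 15.5, "bilateral", "a", "b", "terminal", "none"))

  f <- data.frame(
    pair_id = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
    left = c("1d-112111", "1d-112112", "1d-112121", "1d-1122",
             "1d-112122", "1a-1211", "1a-112111", "1a-112122",
             "1a-1122", "1a-1121121", "1b-12111aa"),
    right = c("1c-112121", "1c-1121221", "1c-112111", "1c-1122",
              "1c-1121121", "1c-1211", "1b-112121", "1b-112112",
              "1b-1122", "1a-1121211", "1b-121121b"),
    origin = c(10.0, 10.6, 12.0, 6.0, 12.6, 8.0, 10.2, 10.6, 6.0,
               12.0, 15.5),
    cycle_h = c(5.0, 5.2, 4.8, 3.4, 5.0, NA, 5.4, 5.6, 3.6, 5.8, 4.6),
    depth = c(4L, 3L, 4L, 7L, 3L, 0L, 3L, 3L, 6L, 3L, 3L),
    az_deg = c(80, 35, 60, 80, 25, 0, -75, -40, -80, -60, -25),
    pol_deg = c(22, 32, 45, 62, 52, 58, 25, 32, 62, 45, 52),
    class = c("non_corresponding", "non_corresponding",
              "non_corresponding", "quadrant_homolog",
              "non_corresponding", "ac_homolog", "non_corresponding",
              "non_corresponding", "quadrant_homolog", "single_quadrant",
              "single_quadrant"),
    verified = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                 TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)

  # scripted position overrides (azimuth/polar in degrees) for the
  # asymmetric medial terminals and the mirrored A|C (p6) clone interior
  pl <- data.frame(
    name = c("1a-2", "1b-2", "1c-2", "1d-2",
             "1a-21", "1b-21", "1c-21", "1d-21",
             "1a-22", "1b-22", "1c-22", "1d-22",
             "1c-1121222", "1c-1121122", "1a-1121122", "1a-1121212",
             "1b-112111", "1b-112122",
             "1c-12111", "1c-12112", "1c-121121", "1c-121122",
             "1c-121121a", "1c-121121b",
             "1a-12111", "1a-12112", "1a-121121", "1a-121122",
             "1a-1211212", "1a-1211211",
             "1b-1211", "1b-12111", "1b-12112", "1b-12111a",
             "1b-121121", "1b-12111b", "1b-12111ab", "1b-121122",
             "1b-121121a"),
    az_deg = c(230.1, 320.1, 50.1, 140.1,
               218.0, 308.0, 38.0, 128.0,
               239.3, 329.3, 59.3, 149.3,
               85, 50, 242, 200, 320, 290,
               12, 15, 10, 22, 18, 6,
               168, 165, 170, 158, 162, 174,
               295, 305, 283, 303, 278, 310, 300, 285, 275),
    pol_deg = c(67.7, 67.7, 67.7, 67.7,
                58.5, 58.5, 58.5, 58.5,
                77.1, 77.1, 77.1, 77.1,
                30, 28, 20, 34, 26, 45,
                64, 62, 66, 68, 70, 72,
                64, 62, 66, 68, 70, 72,
                50, 54, 55, 57, 50, 58, 55, 60, 52),
    stringsAsFactors = FALSE)

  new("CanonicalProgram", events = e, founders = f, placements = pl)
}

#' @keywords internal
.validProgram <- function(object) {
  f <- object@founders
  if (nrow(f)) {
    if (any(f$origin < 6 - 1e-9 | f$origin > 18 + 1e-9))
      return("founder origin times must lie in [6, 18] hpf")
    if (anyDuplicated(c(f$left, f$right)))
      return("a cell may appear in only one founder pair")
  }
  ex <- try(.expandEvents(object@events), silent = TRUE)
  if (inherits(ex, "try-error"))
    return("event table cannot be expanded")
  for (q in c("a", "b", "c")) {
    if (.countTag(ex, q, "primary_prototroch") != 3L)
      return(paste0("quadrant ", q, " must contribute 3 primary ",
                    "prototroch cells"))
    if (.countTag(ex, q, "accessory_prototroch") != 3L)
      return(paste0("quadrant ", q, " must contribute 3 accessory ",
                    "prototroch cells"))
  }
  if (.countTag(ex, "d", "primary_prototroch") != 3L)
    return("quadrant d must contribute 3 primary prototroch cells")
  if (.countTag(ex, "d", "accessory_prototroch") != 2L)
    return("quadrant d must contribute 2 accessory prototroch cells")
  TRUE
}

#' @keywords internal
.countTag <- function(expanded, quadrant, tag) {
  hit <- (expanded$d1_tag == tag | expanded$d2_tag == tag)
  d <- expanded[hit, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(d))) {
    if (.nameQuadrant(d$mother[i]) != quadrant) next
    n <- n + (d$d1_tag[i] == tag) + (d$d2_tag[i] == tag)
  }
  n
}

# Expand quadrant-shorthand events to concrete per-quadrant events.
#' @keywords internal
.expandEvents <- function(events) {
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    row <- events[i, ]
    if (row$quadrants == "-") {
      out[[i]] <- row
    } else {
      qs <- strsplit(row$quadrants, "")[[1]]
      reps <- lapply(qs, function(q) {
        r <- row
        r$mother <- .swapQuadrant(row$mother, "m", q)
        r$quadrants <- "-"
        r
      })
      out[[i]] <- do.call(rbind, reps)
    }
  }
  ex <- do.call(rbind, out)
  ex$d1_name <- .childName(ex$mother, ex$d1)
  ex$d2_name <- .childName(ex$mother, ex$d2)
  rownames(ex) <- NULL
  ex
}

#' @keywords internal
.childName <- function(mother, suffix) {
  ifelse(grepl("-", mother), paste0(mother, suffix),
         paste0(mother, "-", suffix))
}

#' The canonical episphere division program
#'
#' Returns the packaged canonical program: the scripted stereotypic-phase
#' division events for all four quadrants, the registry of the 11 bilateral
#' founder pairs with their clone growth parameters, and the scripted
#' position overrides.  The registry identities that are not printed in
#' full in the source material carry \code{verified = FALSE} and are
#' consistent placeholders, not biological claims.
#'
#' @return a [CanonicalProgram-class].
#' @examples
#' prog <- canonicalProgram()
#' nrow(founderRegistry(prog))   # 11
#' @export
canonicalProgram <- function() .buildCanonicalProgram()

#' @describeIn canonicalProgram the founder-pair registry data.frame.
#' @param program a [CanonicalProgram-class].
#' @export
founderRegistry <- function(program) program@founders

#' @describeIn canonicalProgram the scripted event table (with shorthand
#'   rows).
#' @export
programEvents <- function(program) program@events

#' Prototroch complement of one quadrant under the canonical program
#'
#' @param program a [CanonicalProgram-class].
#' @param quadrant one of \code{"a","b","c","d"}.
#' @param type \code{"accessory"} or \code{"primary"}.
#' @return character vector of cell names carrying that prototroch fate.
#' @export
prototrochCells <- function(program, quadrant,
                            type = c("accessory", "primary")) {
  type <- match.arg(type)
  tag <- paste0(type, "_prototroch")
  ex <- .expandEvents(program@events)
  out <- character()
  for (i in seq_len(nrow(ex))) {
    if (.nameQuadrant(ex$mother[i]) != quadrant) next
    if (ex$d1_tag[i] == tag) out <- c(out, ex$d1_name[i])
    if (ex$d2_tag[i] == tag) out <- c(out, ex$d2_name[i])
  }
  sort(out)
}

setMethod("show", "CanonicalProgram", function(object) {
  cat("CanonicalProgram:",
      nrow(object@events), "scripted event rows,",
      nrow(object@founders), "founder pairs\n")
})

#' Write / read a canonical program as TSV fixtures
#'
#' @param program a [CanonicalProgram-class].
#' @param dir directory receiving (or containing) \code{events.tsv},
#'   \code{founders.tsv} and \code{placements.tsv}.
#' @export
writeProgram <- function(program, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(program@events, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(program@founders, file.path(dir, "founders.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(program@placements, file.path(dir, "placements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeProgram
#' @export
readProgram <- function(dir) {
  rd <- function(f, cls) utils::read.table(file.path(dir, f), header = TRUE,
                                           sep = "\t", colClasses = cls,
                                           quote = "", na.strings = "NA")
  new("CanonicalProgram",
      events = rd("events.tsv",
                  c(mother = "character", quadrants = "character",
                    time = "numeric", mode = "character", d1 = "character",
                    d2 = "character", d1_tag = "character",
                    d2_tag = "character")),
      founders = rd("founders.tsv",
                    c(pair_id = "integer", left = "character",
                      right = "character", origin = "numeric",
                      cycle_h = "numeric", depth = "integer",
                      az_deg = "numeric", pol_deg = "numeric",
                      class = "character", verified = "logical")),
      placements = rd("placements.tsv",
                      c(name = "character", az_deg = "numeric",
                        pol_deg = "numeric")))
}
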