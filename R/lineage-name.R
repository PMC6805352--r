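#' Parse a spiralian blastomere name
#'
#' Parses names in the standard spiralian nomenclature, e.g. \code{"1a-1122"}
#' or the collective quadrant shorthand \code{"1m-112"}.  Commas and
#' whitespace inside the division index (as printed in annotation tables,
#' e.g. \code{"1d-11,221"}) are stripped.  The index alphabet is exactly
#' \{1, 2, a, b\}: \code{"1"}/\code{"a"} label the more anterior daughter of
#' a division and \code{"2"}/\code{"b"} the more posterior one (letters are
#' conventionally used once the divisions are no longer spiral).
#'
#' @param text a single non-empty character string.
#' @return a [LineageName-class] object.
#' @examples
#' parseLineageName("1a-1122")
#' parseLineageName("1d-11,221")   # comma-normalised to 1d-11221
#' @export
parseLineageName <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("lineage name must be a single non-empty string")
  s <- gsub("[ ,]", "", text)
  m <- regmatches(s, regexec("^([0-9]+)([A-Za-z])(?:-(.*))?$", s))[[1]]
  if (length(m) == 0L)
    stop("cannot parse lineage name ", sQuote(text),
         ": expected <tier><quadrant>[-<index>]")
  tier <- suppressWarnings(as.integer(m[2]))
  if (is.na(tier) || tier < 1L)
    stop("missing or invalid tier in ", sQuote(text))
  q <- toupper(m[3])
  if (!q %in% c("A", "B", "C", "D", "M"))
    stop("unknown quadrant letter ", sQuote(m[3]), " in ", sQuote(text))
  idx <- m[4]
  if (is.na(idx)) idx <- ""
  if (nzchar(idx)) {
    bad <- regmatches(idx, regexpr("[^12ab]", idx))
    if (length(bad) && nzchar(bad))
      stop("illegal index character ", sQuote(bad), " in ", sQuote(text),
           " (alphabet is {1,2,a,b})")
  }
  new("LineageName", quadrant = q, tier = tier, index = idx)
}

#' Render a blastomere name to its standard printed form
#'
#' @param name a [LineageName-class] object.
#' @return a string, \code{"<tier><quadrant letter>[-<index>]"} with a
#'   lowercase quadrant letter; parsing the result round-trips.
#' @export
renderLineageName <- function(name) {
  stopifnot(is(name, "LineageName"))
  base <- paste0(name@tier, tolower(name@quadrant))
  if (nzchar(name@index)) paste0(base, "-", name@index) else base
}

setMethod("show", "LineageName", function(object) {
  cat("LineageName:", renderLineageName(object), "\n")
})

#' Expand the collective quadrant shorthand
#'
#' The shorthand \code{1m-xyz} refers collectively to the four quadrant
#' homologs \code{1a-xyz}, \code{1b-xyz}, \code{1c-xyz}, \code{1d-xyz}.
#'
#' @param name a [LineageName-class] with quadrant \code{"M"}.
#' @return a list of 4 [LineageName-class] objects in quadrant order
#'   A, B, C, D with the same tier and index.
#' @examples
#' vapply(expandShorthand(parseLineageName("1m-111")), renderLineageName, "")
#' @export
expandShorthand <- function(name) {
  stopifnot(is(name, "LineageName"))
  if (name@quadrant != "M")
    stop("not a quadrant shorthand: ", renderLineageName(name))
  lapply(c("A", "B", "C", "D"), function(q)
    new("LineageName", quadrant = q, tier = name@tier, index = name@index))
}

#' Bilateral partner of a blastomere name under a quadrant-swap scheme
#'
#' Mirror-image clones normally come from swapped quadrants: the sagittal
#' plane maps the A quadrant to B and C to D (\code{scheme = "AB_CD"}).  In
#' rarer cases bilateral pairs relate the A and C quadrants
#' (\code{scheme = "AC"}; B and D map to themselves).  Tier and index are
#' preserved, and either map is an involution.
#'
#' @param name a concrete (non-shorthand) [LineageName-class].
#' @param scheme \code{"AB_CD"} or \code{"AC"}.
#' @return the partner [LineageName-class].
#' @examples
#' renderLineageName(bilateralPartnerName(parseLineageName("1d-11221")))
#' @export
bilateralPartnerName <- function(name, scheme = c("AB_CD", "AC")) {
  stopifnot(is(name, "LineageName"))
  scheme <- match.arg(scheme)
  if (name@quadrant == "M")
    stop("cannot take the bilateral partner of the quadrant shorthand")
  map <- if (scheme == "AB_CD") {
    c(A = "B", B = "A", C = "D", D = "C")
  } else {
    c(A = "C", B = "B", C = "A", D = "D")
  }
  new("LineageName", quadrant = unname(map[name@quadrant]),
      tier = name@tier, index = name@index)
}

# Internal string-level helpers used throughout the simulator, where names
# are carried as plain strings for speed.
.nameQuadrant <- function(s) sub("^[0-9]+([a-z]).*$", "\\1", s)
.nameIndex <- function(s) ifelse(grepl("-", s), sub("^[^-]*-", "", s), "")
.swapQuadrant <- function(s, from, to) {
  sub(paste0("^([0-9]+)", from), paste0("\\1", to), s)
}
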