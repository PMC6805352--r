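#' @import methods
NULL

#' Spiralian blastomere name
#'
#' A blastomere name in the standard spiralian nomenclature: a micromere-tier
#' number, a quadrant letter and a division-index string over the alphabet
#' \{1, 2, a, b\}.  The quadrant \code{"M"} is the collective shorthand
#' (printed \code{1m-xyz}) referring to all four quadrant homologs at once.
#'
#' @slot quadrant single character, one of \code{"A","B","C","D","M"}.
#' @slot tier positive integer, the leading micromere-quartet number.
#' @slot index character string over \code{\{1,2,a,b\}}, possibly empty.
#'
#' @seealso [parseLineageName()], [expandShorthand()], [bilateralPartnerName()]
#' @export
setClass("LineageName",
  representation(quadrant = "character", tier = "integer", index = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@quadrant) != 1L ||
        !object@quadrant %in% c("A", "B", "C", "D", "M"))
      msg <- c(msg, "quadrant must be one of A, B, C, D, M")
    if (length(object@tier) != 1L || is.na(object@tier) || object@tier < 1L)
      msg <- c(msg, "tier must be a positive integer")
    if (length(object@index) != 1L || is.na(object@index))
      msg <- c(msg, "index must be a single string")
    else if (nzchar(object@index) &&
             !grepl("^[12ab]+$", object@index))
      msg <- c(msg, "index characters must be drawn from {1,2,a,b}")
    if (length(msg)) msg else TRUE
  })

#' Tracked cell-lineage tree of one embryo
#'
#' Container for the tracked cells of one episphere recording: one row per
#' cell in \code{nodes}, a time series of 3-D nuclear positions in
#' \code{positions}, the recording window in hours post fertilization, and
#' the spatial frame convention (apical axis = +z, dorsal azimuth = +y,
#' sagittal mirror plane = \{x = 0\}).
#'
#' @slot embryoId single string naming the recording.
#' @slot nodes data.frame with columns \code{uid}, \code{rid}, \code{name},
#'   \code{parent}, \code{birth}, \code{end}, \code{fate}, \code{mode},
#'   \code{tag}.  \code{fate} is one of \code{divided}, \code{terminal},
#'   \code{apoptotic}, \code{migrated_out}, \code{censored}.
#' @slot positions data.frame with columns \code{uid}, \code{t}, \code{x},
#'   \code{y}, \code{z}.
#' @slot recordingWindow numeric(2), start and end of the recording (hpf).
#' @slot frame list with entries \code{apical}, \code{dorsalAzimuth} (radians)
#'   and \code{sagittal}, fixing the coordinate convention.
#'
#' @export
setClass("LineageTree",
  representation(embryoId = "character", nodes = "data.frame",
                 positions = "data.frame", recordingWindow = "numeric",
                 frame = "list"),
  validity = function(object) .validLineageTree(object))

#' Nuclei-count to developmental-time calibration curve
#'
#' Piecewise-linear calibration from episphere nuclei counts to hours post
#' fertilization, anchored at counted fixed stages.
#'
#' @slot counts integer vector of nuclei counts, strictly increasing.
#' @slot times numeric vector of stage times (hpf), strictly increasing.
#' @export
setClass("CalibrationCurve",
  representation(counts = "numeric", times = "numeric"),
  validity = function(object) {
    if (length(object@counts) < 2L)
      return("at least 2 anchors are required")
    if (length(object@counts) != length(object@times))
      return("counts and times must have equal length")
    if (any(diff(object@counts) <= 0))
      return("anchor counts must be strictly increasing")
    if (any(diff(object@times) <= 0))
      return("anchor times must be strictly increasing")
    TRUE
  })

#' Canonical episphere division program
#'
#' The scripted canonical development of the episphere: quadrant-expandable
#' division events for the stereotypic phase, the registry of bilateral
#' founder pairs, per-founder-clone growth parameters for the late phase,
#' and scripted position overrides for founders and asymmetric medial cells.
#'
#' @slot events data.frame of scripted division events (columns
#'   \code{mother}, \code{quadrants}, \code{time}, \code{mode}, \code{d1},
#'   \code{d2}, \code{d1_tag}, \code{d2_tag}).
#' @slot founders data.frame registry of bilateral founder pairs (columns
#'   \code{pair_id}, \code{left}, \code{right}, \code{origin}, \code{cycle_h},
#'   \code{depth}, \code{az_deg}, \code{pol_deg}, \code{class},
#'   \code{verified}).
#' @slot placements data.frame of scripted position overrides (columns
#'   \code{name}, \code{az_deg}, \code{pol_deg}).
#' @export
setClass("CanonicalProgram",
  representation(events = "data.frame", founders = "data.frame",
                 placements = "data.frame"),
  validity = function(object) .validProgram(object))

#' Inter-embryo variability model
#'
#' Stochastic deviation parameters applied on top of the canonical program:
#' developmental-time jitter of division events, a per-division probability
#' of an extra or skipped division after the deviation onset, positional
#' measurement noise, and the categorical behaviour of the variable ventral
#' rosette cell 1b-111.
#'
#' @slot jitterSlope numeric; the division-time jitter SD grows linearly from
#'   0 at 2 hpf with this SD-per-hour slope.
#' @slot deviationOnset hpf after which lineage deviations may occur.
#' @slot deviationRate per-division probability of a deviation (split evenly
#'   between extra and skipped divisions).
#' @slot positionNoise spatial noise SD as a fraction of hemisphere radius.
#' @slot b111Probs numeric(3), probabilities of \{no division, one division,
#'   more divisions\} for 1b-111.
#' @slot b111Window numeric(2), window (hpf) of the 1b-111 first division.
#' @export
setClass("VariabilityModel",
  representation(jitterSlope = "numeric", deviationOnset = "numeric",
                 deviationRate = "numeric", positionNoise = "numeric",
                 b111Probs = "numeric", b111Window = "numeric"),
  validity = function(object) {
    if (abs(sum(object@b111Probs) - 1) > 1e-9)
      return("b111Probs must sum to 1")
    if (object@jitterSlope < 0 || object@deviationRate < 0 ||
        object@positionNoise < 0)
      return("variability parameters must be non-negative")
    if (object@deviationRate > 1)
      return("deviationRate is a probability")
    TRUE
  })

#' Simulated episphere embryo
#'
#' A [LineageTree] together with its ground truth: the canonical identity of
#' every cell and the realized founder registry.
#'
#' @slot tree the simulated [LineageTree].
#' @slot truth named character vector, uid -> canonical identity (NA for
#'   cells created by a lineage deviation).
#' @slot founderTruth data.frame, the realized bilateral founder pairs.
#' @export
setClass("SimulatedEmbryo",
  representation(tree = "LineageTree", truth = "character",
                 founderTruth = "data.frame"))

#' Cross-embryo cell correspondence map
#'
#' Result of the recursive corresponding-cell identification between two
#' tracked embryos: matched cell pairs with similarity scores, plus the
#' unmatched cells of either embryo with the reason (a real lineage
#' difference, or censoring by the end of the recording).
#'
#' @slot embryoA,embryoB ids of the two embryos.
#' @slot pairs data.frame with columns \code{uid_a}, \code{uid_b},
#'   \code{score}, \code{pairing} (straight/swapped at the division that
#'   created the pair, NA for roots).
#' @slot unmatchedA,unmatchedB data.frame with columns \code{uid},
#'   \code{reason} (\code{real_difference} or \code{censored}); each row is
#'   the root of an unmatched subtree.
#' @slot tCompare,guard the comparison point and guard window (hpf).
#' @export
setClass("CorrespondenceMap",
  representation(embryoA = "character", embryoB = "character",
                 pairs = "data.frame", unmatchedA = "data.frame",
                 unmatchedB = "data.frame", tCompare = "numeric",
                 guard = "numeric"))

#' Consensus lineage tree of an embryo cohort
#'
#' Divisions grouped by cross-embryo correspondence, retained when supported
#' by more than half of the cohort, with per-division support counts,
#' observed division-time ranges, and deterministic reference IDs.
#'
#' @slot nodes data.frame with columns \code{rid}, \code{parent_rid},
#'   \code{name}, \code{support}, \code{t_min}, \code{t_max},
#'   \code{low_support}, \code{members} (semicolon-joined embryo:uid).
#' @slot cohortSize integer, number of embryos.
#' @export
setClass("ConsensusTree",
  representation(nodes = "data.frame", cohortSize = "integer"))

#' Sagittal mirror plane estimate
#'
#' A candidate plane of bilateral symmetry: a plane containing the apical
#' (+z) axis whose normal lies in the x-y plane at the given azimuth.
#'
#' @slot azimuth angle (radians, in [0, pi)) of the plane normal in x-y.
#' @slot fitted logical; FALSE when taken from frame metadata.
#' @slot objective mean symmetric nearest-neighbour mismatch at the optimum
#'   (NA for metadata planes).
#' @export
setClass("MirrorPlane",
  representation(azimuth = "numeric", fitted = "logical",
                 objective = "numeric"),
  validity = function(object) {
    if (object@azimuth < 0 || object@azimuth >= pi)
      return("azimuth must lie in [0, pi)")
    TRUE
  })
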