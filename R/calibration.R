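#' Build a nuclei-count calibration curve
#'
#' Live-imaging frame times drift with imaging conditions, so recordings
#' are calibrated against episphere nuclei counts of precisely staged fixed
#' embryos.  The curve interpolates piecewise-linearly between anchors.
#'
#' @param counts nuclei counts at the anchor stages (strictly increasing).
#' @param times anchor stage times in hpf (strictly increasing).
#' @return a [CalibrationCurve-class].
#' @export
calibrationCurve <- function(counts, times) {
  new("CalibrationCurve", counts = as.numeric(counts),
      times = as.numeric(times))
}

#' Calibrated developmental time for an observed nuclei count
#'
#' Piecewise-linear interpolation in (count -> hpf); exact at the anchors
#' and monotone non-decreasing.  Counts outside the anchored range are
#' clamped to the terminal anchor times, with a warning.
#'
#' @param curve a [CalibrationCurve-class].
#' @param count observed nuclei count(s), positive.
#' @return developmental time(s) in hpf.
#' @examples
#' cc <- calibrationCurve(c(100, 200), c(20, 24))
#' calibrateTime(cc, 150)   # 22
#' @export
calibrateTime <- function(curve, count) {
  stopifnot(is(curve, "CalibrationCurve"), all(count > 0))
  if (any(count < min(curve@counts) | count > max(curve@counts)))
    warning("nuclei count outside the anchored range; ",
            "clamping to the terminal anchor time")
  stats::approx(curve@counts, curve@times, xout = count, rule = 2)$y
}

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve with", length(object@counts), "anchors:\n")
  print(data.frame(count = object@counts, hpf = object@times),
        row.names = FALSE)
})
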