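.MARKER_VOCAB <- c("chat", "phc2", "syt", "5HT", "vacht", "none")

#' Load the annotated differentiated cell types
#'
#' Reads the packaged transcription of the 62 differentiated cell types
#' identified in the 30 hpf episphere: cell-type label, consensus lineage
#' name, observation support (recordings with the lineage / recordings
#' analysed, plus a literature flag), approximate cell-cycle exit time,
#' consensus-tree reference ID, expression markers and multiplicity (one
#' table row covers two anterior prototroch cells).  Lineage names are
#' normalised (printed commas stripped) and all invariants are validated.
#'
#' @param file path to an annotation TSV; defaults to the packaged fixture.
#' @return data.frame of annotation records with a parsed
#'   \code{lineage_norm} column.
#' @examples
#' ann <- loadAnnotations()
#' nrow(ann)   # 62
#' @export
loadAnnotations <- function(file = system.file("extdata",
                                               "annotations_table1.tsv",
                                               package = "spiralineage")) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(index = "integer",
                                         cell_type = "character",
                                         lineage = "character",
                                         support_k = "integer",
                                         support_n = "integer",
                                         refs = "logical",
                                         last_division_hpf = "numeric",
                                         rid = "character",
                                         markers = "character",
                                         multiplicity = "integer"))
  if (anyDuplicated(df$rid))
    stop("duplicate reference ID at row ",
         which(duplicated(df$rid))[1])
  norm <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    ln <- try(parseLineageName(df$lineage[i]), silent = TRUE)
    if (inherits(ln, "try-error"))
      stop("unparseable lineage ", sQuote(df$lineage[i]), " at row ", i)
    norm[i] <- renderLineageName(ln)
  }
  df$lineage_norm <- norm
  mk <- strsplit(df$markers, ";", fixed = TRUE)
  bad <- !vapply(mk, function(x) all(x %in% .MARKER_VOCAB), TRUE)
  if (any(bad))
    stop("unknown marker(s) at row ", which(bad)[1],
         "; valid markers: ", paste(.MARKER_VOCAB, collapse = ", "))
  if (any(df$support_k > df$support_n))
    stop("support k exceeds n at row ",
         which(df$support_k > df$support_n)[1])
  if (any(df$multiplicity < 1L))
    stop("multiplicity must be >= 1")
  if (nrow(df) != 62L)
    warning("annotation fixture has ", nrow(df),
            " records; 62 expected for the full table")
  df
}

#' Select annotation records by expression marker
#'
#' @param records data.frame from [loadAnnotations()].
#' @param marker one of \code{"chat"}, \code{"phc2"}, \code{"syt"},
#'   \code{"5HT"}, \code{"vacht"}, \code{"none"}.
#' @return the matching records; the attribute \code{"cellCount"} gives
#'   the multiplicity-expanded number of cells.
#' @examples
#' nrow(markerCells(loadAnnotations(), "chat"))   # 9 cholinergic cells
#' @export
markerCells <- function(records, marker) {
  if (!marker %in% .MARKER_VOCAB)
    stop("unknown marker ", sQuote(marker), "; valid markers: ",
         paste(.MARKER_VOCAB, collapse = ", "))
  hit <- vapply(strsplit(records$markers, ";", fixed = TRUE),
                function(x) marker %in% x, TRUE)
  out <- records[hit, , drop = FALSE]
  attr(out, "cellCount") <- sum(out$multiplicity)
  out
}
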