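#' Export a lineage tree in Newick format
#'
#' Branch lengths are cell lifetimes in hours.  Trees with several tracked
#' roots (e.g. the four first micromeres) are joined under an unlabelled
#' zero-age root so the output is a single valid Newick tree.
#'
#' @param tree a [LineageTree-class].
#' @param label which node attribute to use as label: lineage \code{name},
#'   reference id (\code{rid}) or \code{uid}.
#' @param strict if TRUE (default), duplicate or missing labels are an
#'   error; if FALSE they are disambiguated by suffixing the uid.
#' @return a single Newick string.
#' @export
toNewick <- function(tree, label = c("name", "rid", "uid"), strict = TRUE) {
  label <- match.arg(label)
  nd <- tree@nodes
  lab <- nd[[if (label == "uid") "uid" else label]]
  if (anyNA(lab) || anyDuplicated(lab)) {
    if (strict)
      stop("missing or duplicate ", label,
           " labels; use strict = FALSE to suffix uids")
    lab <- ifelse(is.na(lab), nd$uid, lab)
    dup <- duplicated(lab) | duplicated(lab, fromLast = TRUE)
    lab[dup] <- paste0(lab[dup], "_", nd$uid[dup])
  }
  lab <- gsub("[ ,:;()\\[\\]]", "_", lab)
  names(lab) <- nd$uid
  children <- .childrenMap(tree)
  len <- nd$end - nd$birth
  names(len) <- nd$uid
  fmt <- function(uid) {
    kids <- children[[uid]]
    body <- if (length(kids)) {
      paste0("(", paste(vapply(kids, fmt, ""), collapse = ","), ")")
    } else {
      ""
    }
    paste0(body, lab[[uid]], ":", format(len[[uid]], digits = 10))
  }
  roots <- nd$uid[is.na(nd$parent)]
  if (length(roots) == 1L) {
    paste0(fmt(roots), ";")
  } else {
    paste0("(", paste(vapply(roots, fmt, ""), collapse = ","), ");")
  }
}
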