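# SideVolumes construction and helpers.

.matchSide <- function(side) {
  side <- tolower(side)
  if (length(side) != 1L || !side %in% .SIDES) {
    stop("side must be 'right' or 'left'", call. = FALSE)
  }
  side
}

#' Normalize a sequence tag
#'
#' Accepts the canonical tags \code{"T2_TSE"} and \code{"T2_TSE_DRB"} as
#' well as the shorthands \code{"tse"} and \code{"drb"} (case-insensitive).
#'
#' @param sequence sequence tag or shorthand.
#' @return canonical sequence tag.
#' @export
matchSequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single tag", call. = FALSE)
  }
  key <- toupper(gsub("[- ]", "_", sequence))
  tag <- switch(key,
    T2_TSE = , TSE = "T2_TSE",
    T2_TSE_DRB = , DRB = "T2_TSE_DRB",
    NA_character_
  )
  if (is.na(tag)) {
    stop(sprintf("unknown sequence tag '%s' (expected %s)", sequence,
                 paste(.SEQUENCES, collapse = " or ")), call. = FALSE)
  }
  tag
}

#' Construct per-hemisphere subfield volumes
#'
#' @param volumes named numeric vector of volumes (mm^3); names are
#'   canonicalized via [resolveRegions()].
#' @param subjectID subject identifier.
#' @param side \code{"right"} or \code{"left"}.
#' @param sequence sequence tag (see [matchSequence()]).
#' @param hierarchy a [RegionHierarchy-class].
#' @return a [SideVolumes-class].
#' @examples
#' SideVolumes(c(`CA1-head` = 251.1, HATA = 44.7),
#'             subjectID = "pat01", side = "right", sequence = "drb")
#' @export
SideVolumes <- function(volumes, subjectID, side, sequence,
                        hierarchy = canonicalHierarchy()) {
  if (!is.numeric(volumes) || is.null(names(volumes))) {
    stop("volumes must be a named numeric vector", call. = FALSE)
  }
  canon <- resolveRegions(names(volumes), hierarchy)
  dup <- unique(canon[duplicated(canon)])
  if (length(dup)) {
    stop("duplicate region(s) after alias resolution: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  new("SideVolumes",
      subjectID = as.character(subjectID),
      side = .matchSide(side),
      sequence = matchSequence(sequence),
      volumes = stats::setNames(as.numeric(volumes), canon))
}

#' @rdname SideVolumes
#' @param x a \code{SideVolumes} object.
#' @export
volumes <- function(x) {
  stopifnot(is(x, "SideVolumes"))
  x@volumes
}

setMethod("show", "SideVolumes", function(object) {
  cat(sprintf("SideVolumes: subject '%s', %s hemisphere, %s\n",
              object@subjectID, object@side, object@sequence))
  cat(sprintf("  %d regions, total %.1f mm^3\n",
              length(object@volumes), sum(object@volumes)))
})
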