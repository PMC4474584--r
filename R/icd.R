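#' @keywords internal
# ICD-10 code shapes in scope: chapter letter + 2-digit category + optional
# decimal subcategory, matched on whole tokens, case-insensitively.
icd_pattern <- "^[A-Za-z][0-9]{2}(\\.[0-9]+)?$"

is_icd_token <- function(tokens) grepl(icd_pattern, tokens)

#' Segment an ICD-10 code into its weighted taxonomy chain
#'
#' An ICD-10 code is decomposed one character at a time (the decimal point is
#' not a level of its own), from the chapter letter down to the full code:
#' `"J21.1"` yields the chain J, J2, J21, J21.1. The full code carries weight
#' 1 and the weight is halved at each step up the hierarchy, so sibling codes
#' share progressively down-weighted ancestor components.
#'
#' @param raw Code string such as `"J21.1"` or `"I50"` (case-insensitive).
#' @return An object of class `icd_code` with fields `raw` and `segments`, a
#'   data.frame of `segment` (general to specific) and `weight`.
#' @examples
#' segment_icd("J21.1")$segments
#' @export
segment_icd <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  code <- toupper(trimws(raw))
  if (!grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", code))
    stop("not a valid ICD-10 code: '", raw, "'")
  chars <- strsplit(gsub(".", "", code, fixed = TRUE), "")[[1L]]
  segs <- vapply(seq_along(chars), function(k) {
    s <- paste(chars[seq_len(k)], collapse = "")
    if (k > 3L) paste0(substr(s, 1L, 3L), ".", substr(s, 4L, k)) else s
  }, character(1))
  n <- length(segs)
  structure(list(raw = code,
                 segments = data.frame(segment = segs,
                                       weight = 0.5 ^ ((n - 1L):0),
                                       stringsAsFactors = FALSE)),
            class = "icd_code")
}

#' @export
print.icd_code <- function(x, ...) {
  cat("<icd_code> ", x$raw, ": ",
      paste(sprintf("%s (%g)", x$segments$segment, x$segments$weight),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Remove sentences mentioning ICD-10 codes from a note
#'
#' Sentences containing any whole token that looks like an ICD-10 code are
#' dropped; the remaining sentences are untouched. Used when constructing
#' query episodes so that diagnosis codes leaking into the free text cannot
#' trivially identify relevant episodes.
#'
#' @param note A [clinical_note()].
#' @return A new `clinical_note`; may have zero sentences.
#' @export
strip_icd_sentences <- function(note) {
  keep <- vapply(note$sentences, function(s) !any(is_icd_token(s)),
                 logical(1))
  note$sentences <- note$sentences[keep]
  note
}

#' Construct a query episode
#'
#' Discharge summaries are assumed unavailable at query time: the summary
#' note is removed, every remaining note has its ICD-mentioning sentences
#' stripped, and the primary code label is cleared. Notes left without text
#' are dropped and positions renumbered.
#'
#' @param ep A `care_episode`.
#' @return A `care_episode` with attribute `usable` (`FALSE` when no textual
#'   content survives, in which case the episode cannot serve as a query).
#' @export
build_query_episode <- function(ep) {
  notes <- ep$notes[!vapply(ep$notes, `[[`, logical(1), "is_summary")]
  notes <- lapply(notes, strip_icd_sentences)
  notes <- notes[vapply(notes, function(n) length(n$sentences) > 0L,
                        logical(1))]
  if (!length(notes)) {
    out <- structure(list(episode_id = ep$episode_id, notes = list(),
                          primary_icd = NULL),
                     class = "care_episode")
    attr(out, "usable") <- FALSE
    return(out)
  }
  for (i in seq_along(notes)) notes[[i]]$position <- i - 1L
  out <- care_episode(ep$episode_id, notes, NULL)
  attr(out, "usable") <- TRUE
  out
}

#' @rdname build_query_episode
#' @export
is_usable_query <- function(ep) isTRUE(attr(ep, "usable"))
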