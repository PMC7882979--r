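#' Flag a 15-s clip as containing chimpanzees
#'
#' A clip counts as a chimpanzee clip when at least two distinct annotators
#' classified it as "chimp" (a single classification could be erroneous) or
#' when a moderator captioned it with a `#chimp` hashtag. A moderator
#' `#omit` hashtag overrides everything and forces the flag off.
#'
#' @param verdicts Character vector of per-annotator verdicts
#'   (`"chimp"`, `"blank"`, or another species label).
#' @param annotators Annotator identifiers parallel to `verdicts`; must be
#'   unique within a clip.
#' @param hashtags Character vector of hashtag captions on the clip.
#' @return Logical scalar.
#' @export
#' @examples
#' chimp_clip_flag(c("chimp", "chimp", "blank"))       # TRUE
#' chimp_clip_flag("chimp")                             # FALSE: one vote
#' chimp_clip_flag(character(0), hashtags = "#chimp")   # TRUE
chimp_clip_flag <- function(verdicts, annotators = seq_along(verdicts),
                            hashtags = character(0)) {
  if (anyDuplicated(annotators)) {
    stop("annotator ids must be unique within a clip", call. = FALSE)
  }
  if ("#omit" %in% hashtags) return(FALSE)
  sum(verdicts == "chimp") >= 2L || "#chimp" %in% hashtags
}

#' Select videos eligible for between-channel comparison
#'
#' A 1-min video enters the comparison set only when (a) all four of its
#' 15-s clips were viewed (at least one classification each; expert viewing
#' of the full minute is assumed), and (b) at least one clip is
#' chimpanzee-flagged while every non-flagged clip is unanimously blank in at
#' least three independent classifications. This guarantees both channels
#' saw the full minute and agreed it contains at least one chimpanzee.
#'
#' @param clips Data frame of per-classification rows with columns
#'   `clip_id`, `video_id`, `position` (1-4), `annotator_id`, `verdict`.
#' @param hashtags Optional data frame with columns `clip_id`, `tag`.
#' @return Character vector of included `video_id`s.
#' @export
video_inclusion_filter <- function(clips, hashtags = NULL) {
  stopifnot(all(c("clip_id", "video_id", "position", "annotator_id",
                  "verdict") %in% names(clips)))
  tags_for <- function(cid) {
    if (is.null(hashtags) || !nrow(hashtags)) character(0)
    else hashtags$tag[hashtags$clip_id == cid]
  }
  included <- character(0)
  for (vid in unique(clips$video_id)) {
    vc <- clips[clips$video_id == vid, , drop = FALSE]
    pos <- sort(unique(vc$position))
    if (!identical(pos, 1:4) && !identical(pos, c(1L, 2L, 3L, 4L))) {
      # a video is structurally four clips; fewer means it was not fully
      # viewed (criterion a) -- treat missing positions as unviewed
      next
    }
    flag <- blank_ok <- logical(4L)
    for (p in 1:4) {
      cc <- vc[vc$position == p, , drop = FALSE]
      if (!nrow(cc)) { flag[p] <- NA; next }
      flag[p] <- chimp_clip_flag(cc$verdict, cc$annotator_id,
                                 tags_for(cc$clip_id[1L]))
      blank_ok[p] <- nrow(cc) >= 3L && all(cc$verdict == "blank")
    }
    if (anyNA(flag)) next
    if (any(flag) && all(flag | blank_ok)) included <- c(included, vid)
  }
  included
}

#' Link the four clips of one minute into a single detection tally
#'
#' The four 15-s clips of a video are merged back into the 1-min unit of
#' comparison. With per-clip individual tokens (identified IDs and
#' producer-linked anonymous tokens alike), the minute's individual set is
#' the union over clips and the count its size. With only per-clip counts and
#' no linking, the max over clips is used -- a lower bound, since the same
#' animal may span clips.
#'
#' @param x Either a list of per-clip character vectors of individual tokens,
#'   or a numeric vector of per-clip counts.
#' @return List with `individuals` (character, possibly empty; `NULL` for
#'   counts-only input) and `count`.
#' @export
#' @examples
#' link_minute(list(c("A", "B"), c("B", "C"), character(0), character(0)))
#' link_minute(c(2, 1, 0, 0))  # counts-only: max convention, count 2
link_minute <- function(x) {
  if (is.list(x)) {
    ind <- unique(unlist(x, use.names = FALSE))
    ind <- ind[!is.na(ind)]
    list(individuals = ind, count = length(ind))
  } else if (is.numeric(x)) {
    list(individuals = NULL, count = if (length(x)) max(x) else 0)
  } else {
    stop("x must be a list of token sets or a numeric count vector",
         call. = FALSE)
  }
}

#' Apply the consensus rule to a prospective individual ID
#'
#' A prospective ID is promoted to confirmed only when at least three
#' annotators agree, the individual was seen in at least two temporally and
#' spatially independent clips, and nobody dissents. Two sightings are
#' independent when they come from different cameras, or from the same
#' camera more than 60 s apart (same-camera sightings within 60 s are
#' consecutive clips of the same minute and carry no new information).
#'
#' @param n_agree Number of agreeing annotators.
#' @param sightings Data frame with columns `clip_id`, `camera_id`,
#'   `timestamp` (ISO 8601 UTC or POSIXct).
#' @param n_dissent Number of dissenting annotators.
#' @return `"confirmed"` or `"prospective"`.
#' @export
confirm_id <- function(n_agree, sightings, n_dissent = 0L) {
  if (n_dissent > 0L || n_agree < 3L || nrow(sightings) < 2L) {
    return("prospective")
  }
  t <- sightings$timestamp
  if (!inherits(t, "POSIXct")) t <- parse_timestamp(t)
  n <- nrow(sightings)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      independent <- sightings$camera_id[i] != sightings$camera_id[j] ||
        abs(as.numeric(difftime(t[i], t[j], units = "secs"))) > 60
      if (independent) return("confirmed")
    }
  }
  "prospective"
}
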