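#' Group videos at the same camera into events
#'
#' Videos recorded at one camera location are chained into a single event
#' whenever consecutive start times are at most `window` minutes apart
#' (inclusive: a gap of exactly 15 min still merges). Chaining is
#' transitive, so an event can span more than `window` minutes end to end.
#' Events at different cameras never merge.
#'
#' @param videos Data frame with columns `video_id`, `camera_id`,
#'   `start_timestamp` (ISO 8601 UTC or POSIXct).
#' @param window Grouping window in minutes (default 15).
#' @return Data frame with one row per event: `event_id`, `camera_id`,
#'   `t_start`, `t_end` (first and last member start), `n_videos`, and
#'   `video_ids` (semicolon-joined, in time order).
#' @export
group_events <- function(videos, window = 15) {
  req <- c("video_id", "camera_id", "start_timestamp")
  stopifnot(all(req %in% names(videos)))
  if (any(is.na(videos$start_timestamp) | videos$start_timestamp == "")) {
    bad <- videos$video_id[is.na(videos$start_timestamp) |
                             videos$start_timestamp == ""]
    stop("missing start_timestamp for video(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  t <- videos$start_timestamp
  if (!inherits(t, "POSIXct")) t <- parse_timestamp(t)
  o <- order(videos$camera_id, t, videos$video_id)
  v <- videos[o, , drop = FALSE]
  tt <- t[o]
  gap_min <- c(Inf, as.numeric(difftime(tt[-1L], tt[-length(tt)],
                                        units = "mins")))
  new_event <- gap_min > window |
    c(TRUE, v$camera_id[-1L] != v$camera_id[-nrow(v)])
  eid <- cumsum(new_event)
  out <- do.call(rbind, lapply(split(seq_len(nrow(v)), eid), function(ix) {
    data.frame(
      camera_id = v$camera_id[ix[1L]],
      t_start = format_timestamp(tt[ix[1L]]),
      t_end = format_timestamp(tt[ix[length(ix)]]),
      n_videos = length(ix),
      video_ids = paste(v$video_id[ix], collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$t_start, out$camera_id), , drop = FALSE]
  out <- cbind(event_id = sprintf("ev%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Party composition of each event under the gambit of the group
#'
#' All individuals identified in any video of an event are treated as one
#' associating party. Unidentified detections contribute nothing here (they
#' affect counts, not networks).
#'
#' @param events Data frame from [group_events()].
#' @param detections Detection table (see [simulate_community()] for the
#'   schema); rows with `individual_id` present are used.
#' @param channel `"expert"` or `"citizen"`.
#' @return Named list (by `event_id`) of character vectors of individual IDs.
#' @export
gambit_party <- function(events, detections, channel) {
  stopifnot(channel %in% c("expert", "citizen"))
  d <- detections[detections$channel == channel &
                    !is.na(detections$individual_id), , drop = FALSE]
  vid2ind <- split(d$individual_id, d$video_id)
  parties <- lapply(strsplit(events$video_ids, ";", fixed = TRUE),
                    function(vs) {
                      sort(unique(unlist(vid2ind[vs], use.names = FALSE)))
                    })
  stats::setNames(parties, events$event_id)
}

#' Shared weaned roster across the two observation channels
#'
#' The network roster comprises all weaned individuals with at least one
#' identified detection in each channel, after mapping citizen IDs onto
#' expert IDs. Citizen IDs with no mapping entry are an error.
#'
#' @param detections Detection table covering both channels.
#' @param weaned Named logical vector of weaned flags by (expert) individual
#'   ID; taken from the `weaned` column when `NULL`.
#' @param id_map Optional data frame `(citizen_id, expert_id)` standardizing
#'   citizen IDs; identity mapping assumed when `NULL` (synthetic data).
#' @return Sorted character vector of roster IDs (expert naming).
#' @export
select_shared_roster <- function(detections, weaned = NULL, id_map = NULL) {
  d <- detections[!is.na(detections$individual_id), , drop = FALSE]
  cz <- d$individual_id[d$channel == "citizen"]
  if (!is.null(id_map)) {
    hit <- match(cz, id_map$citizen_id)
    if (anyNA(hit)) {
      stop("unmapped citizen ID(s): ",
           paste(unique(cz[is.na(hit)]), collapse = ", "), call. = FALSE)
    }
    cz <- id_map$expert_id[hit]
  }
  ex <- d$individual_id[d$channel == "expert"]
  shared <- intersect(unique(ex), unique(cz))
  if (is.null(weaned)) {
    weaned <- tapply(d$weaned == 1L, d$individual_id, any)
  }
  sort(shared[shared %in% names(weaned)[weaned %in% TRUE]])
}

#' Simple ratio index for one dyad
#'
#' SRI(A, B) = x / (x + yAB + yA + yB), where x counts events with both A
#' and B, yA / yB events with exactly one of them, and yAB events where both
#' were seen but apart (structurally zero when a sampling unit is a single
#' camera's event). Only events containing at least one roster member are
#' eligible sampling units; events containing neither A nor B contribute
#' nothing either way.
#'
#' @param parties List of per-event ID vectors (see [gambit_party()]).
#' @param pair Character vector of two individual IDs.
#' @param roster Roster the pair must belong to; defaults to all IDs seen.
#' @return Association weight in `[0, 1]` (0 when the pair was never
#'   sampled).
#' @export
simple_ratio_index <- function(parties, pair, roster = NULL) {
  stopifnot(length(pair) == 2L)
  if (is.null(roster)) roster <- unique(unlist(parties, use.names = FALSE))
  if (!all(pair %in% roster)) {
    stop("pair not in roster: ",
         paste(setdiff(pair, roster), collapse = ", "), call. = FALSE)
  }
  a <- vapply(parties, function(p) pair[1L] %in% p, TRUE)
  b <- vapply(parties, function(p) pair[2L] %in% p, TRUE)
  x <- sum(a & b)
  denom <- x + sum(a & !b) + sum(!a & b)
  if (denom == 0L) 0 else x / denom
}

#' Build a simple-ratio-index association network
#'
#' Computes the symmetric SRI weight matrix over all unordered roster pairs
#' from the event parties of one channel. The number of qualifying events
#' (those containing at least one roster member) is attached as attribute
#' `n_events`.
#'
#' @param parties List of per-event ID vectors.
#' @param roster Character vector of individuals to include (the matrix
#'   order).
#' @return An `"assoc_matrix"`: a symmetric numeric matrix with zero
#'   diagonal, `dimnames` the roster, and attribute `n_events`.
#' @export
build_network <- function(parties, roster) {
  stopifnot(length(roster) >= 1L, !anyDuplicated(roster))
  inc <- vapply(parties, function(p) roster %in% p,
                logical(length(roster)))
  if (length(parties) == 0L || is.null(dim(inc))) {
    inc <- matrix(as.logical(inc), nrow = length(roster))
  }
  qualifying <- colSums(inc) > 0L
  if (!any(qualifying)) {
    warning("no qualifying events; returning empty network")
  }
  m <- inc[, qualifying, drop = FALSE]
  storage.mode(m) <- "double"
  x <- tcrossprod(m)                    # joint occurrences
  npr <- rowSums(m)
  denom <- outer(npr, npr, "+") - x     # events with A or B
  w <- ifelse(denom > 0, x / denom, 0)
  diag(w) <- 0
  dimnames(w) <- list(roster, roster)
  structure(w, n_events = sum(qualifying), class = c("assoc_matrix",
                                                     "matrix"))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat("simple-ratio-index association network:", nrow(x), "individuals,",
      attr(x, "n_events"), "qualifying events\n")
  print(unclass(x), ...)
  invisible(x)
}
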