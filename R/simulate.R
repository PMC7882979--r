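#' Configuration for the fission-fusion community simulator
#'
#' Builds and validates the parameter set for [simulate_community()]. The
#' defaults emulate the observation regime of a habituated chimpanzee
#' community monitored by motion-triggered cameras: roughly three dozen
#' individuals in a community with latent subgroup structure, 60-s videos
#' quartered into four 15-s clips, a mean of 1.8 videos per event, an expert
#' channel that identifies about 85% of detected animals and a citizen
#' channel that confirms IDs for about 46%, with citizen count errors skewed
#' roughly 69:31 toward undercounting.
#'
#' @param n_individuals Number of individuals in the community.
#' @param n_communities Number of latent subgroups (K) planted in the roster.
#' @param p_within Probability that an individual joins a party whose seed is
#'   in its own latent community.
#' @param p_between Same for a seed from another community; must be strictly
#'   less than `p_within`.
#' @param n_events Number of camera-trap events to simulate.
#' @param n_cameras Number of camera locations.
#' @param videos_per_event_mean Mean number of videos per event (>= 1); video
#'   counts are drawn as 1 + Poisson(mean - 1).
#' @param expert_id_prob Probability an expert detection carries its true ID.
#' @param citizen_id_prob Probability a citizen detection carries a confirmed
#'   ID.
#' @param citizen_undercount_prob Per-video probability that the citizen
#'   channel misses one present individual (applied only when at least two
#'   are present).
#' @param citizen_overcount_prob Per-video probability that the citizen
#'   channel reports one extra anonymous animal.
#' @param weaned_fraction Fraction of individuals flagged as weaned (the unit
#'   of network analysis).
#' @param seed Integer seed; identical configurations yield byte-identical
#'   datasets.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_events = 50, seed = 7)
#' dat <- simulate_community(cfg)
#' head(dat$detections)
sim_config <- function(n_individuals = 36L,
                       n_communities = 3L,
                       p_within = 0.7,
                       p_between = 0.05,
                       n_events = 500L,
                       n_cameras = 25L,
                       videos_per_event_mean = 1.8,
                       expert_id_prob = 0.85,
                       citizen_id_prob = 0.46,
                       citizen_undercount_prob = 0.09,
                       citizen_overcount_prob = 0.04,
                       weaned_fraction = 2 / 3,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_communities = as.integer(n_communities),
    p_within = p_within, p_between = p_between,
    n_events = as.integer(n_events), n_cameras = as.integer(n_cameras),
    videos_per_event_mean = videos_per_event_mean,
    expert_id_prob = expert_id_prob, citizen_id_prob = citizen_id_prob,
    citizen_undercount_prob = citizen_undercount_prob,
    citizen_overcount_prob = citizen_overcount_prob,
    weaned_fraction = weaned_fraction, seed = as.integer(seed)
  )
  probs <- c("p_within", "p_between", "expert_id_prob", "citizen_id_prob",
             "citizen_undercount_prob", "citizen_overcount_prob",
             "weaned_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid sim_config: ", p, " must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$p_between >= cfg$p_within) {
    stop("invalid sim_config: p_between must be < p_within", call. = FALSE)
  }
  if (cfg$n_communities > cfg$n_individuals) {
    stop("invalid sim_config: n_communities must be <= n_individuals",
         call. = FALSE)
  }
  if (cfg$videos_per_event_mean < 1) {
    stop("invalid sim_config: videos_per_event_mean must be >= 1",
         call. = FALSE)
  }
  if (cfg$n_events < 1L || cfg$n_cameras < 1L || cfg$n_individuals < 1L) {
    stop("invalid sim_config: counts must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# the 15 non-empty subsets of the four clip positions
.clip_subsets <- local({
  s <- list()
  for (m in 1:15) s[[m]] <- which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
  s
})

#' Simulate a fission-fusion community observed through two channels
#'
#' Generates ground truth (latent community labels, true party per event) and
#' the two imperfect observation channels. Party formation follows a
#' seed-plus-independent-inclusion model under the gambit of the group: one
#' uniformly chosen seed individual starts each party and every other
#' individual joins independently with probability `p_within` or `p_between`
#' according to whether it shares the seed's latent community. Each event is
#' placed at a random camera; events are spaced an hour apart so they never
#' merge under the 15-minute grouping rule, while videos within an event are
#' 1-10 min apart and always chain. Every present individual appears in a
#' uniformly chosen non-empty subset of the video's four clips.
#'
#' The expert channel records every truly present animal and attaches its
#' true ID with probability `expert_id_prob` (else the detection is an
#' anonymous count contribution). The citizen channel additionally perturbs
#' per-video counts: with probability `citizen_undercount_prob` one present
#' individual's detection is dropped (only when at least two are present, so
#' the video is still recognized as containing chimpanzees), and with
#' probability `citizen_overcount_prob` one extra anonymous detection is
#' added; surviving true detections carry a confirmed ID with probability
#' `citizen_id_prob`. Detections of the same animal instance in the two
#' channels share a `token`, standing in for the manual cross-clip linking a
#' data producer performs.
#'
#' @param config A [sim_config()].
#' @return A list of class `"ctsna_dataset"` with elements `truth` (community
#'   assignment, weaned flags, party per event), `videos`, `detections`
#'   (both channels, long format), `clips` (per-clip classification verdicts)
#'   and `hashtags` (empty by default), plus the `config`.
#' @export
simulate_community <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("ind%02d", seq_len(n))
  community <- sort(rep_len(seq_len(config$n_communities), n))
  names(community) <- ids
  n_weaned <- max(1L, round(config$weaned_fraction * n))
  weaned <- stats::setNames(rep(FALSE, n), ids)
  weaned[sample(ids, n_weaned)] <- TRUE
  asc <- stats::setNames(character(n), ids)
  asc[weaned] <- sample(c("adult_female", "adult_male", "adolescent_female",
                          "adolescent_male"), sum(weaned), replace = TRUE)
  asc[!weaned] <- sample(c("juvenile", "infant"), sum(!weaned),
                         replace = TRUE)

  ne <- config$n_events
  seeds <- sample(ids, ne, replace = TRUE)
  # inclusion probability by community match with the event's seed
  pmat <- matrix(config$p_between, ne, n)
  pmat[community[seeds][row(pmat)] == community[col(pmat)]] <- config$p_within
  member <- matrix(stats::runif(ne * n), ne, n) < pmat
  member[cbind(seq_len(ne), match(seeds, ids))] <- TRUE

  cameras <- sprintf("cam%02d", sample(config$n_cameras, ne, replace = TRUE))
  origin <- as.POSIXct("2016-06-13 06:00:00", tz = "UTC")
  event_base <- origin + (seq_len(ne) - 1L) * 3600
  nvid <- 1L + stats::rpois(ne, config$videos_per_event_mean - 1)

  parties <- apply(member, 1L, function(m) ids[m], simplify = FALSE)
  names(parties) <- sprintf("ev%04d", seq_len(ne))

  # video table: offsets within an event are 1-10 min, so videos chain
  vid_event <- rep(seq_len(ne), nvid)
  n_videos <- length(vid_event)
  offset <- round(stats::runif(n_videos, 60, 600))
  first <- !duplicated(vid_event)
  offset[first] <- 0
  start <- event_base[vid_event] +
    as.vector(unlist(tapply(offset, vid_event, cumsum), use.names = FALSE))
  videos <- data.frame(
    video_id = sprintf("vid%05d", seq_len(n_videos)),
    camera_id = cameras[vid_event],
    start_timestamp = format_timestamp(start),
    stringsAsFactors = FALSE
  )

  # one true-detection row per (video, present individual)
  psize <- rowSums(member)
  det_ind <- unlist(parties[vid_event], use.names = FALSE)
  det_vid <- rep(videos$video_id, psize[vid_event])
  nr <- length(det_ind)
  within_vid <- stats::ave(seq_len(nr), det_vid, FUN = seq_along)
  truth_det <- data.frame(
    video_id = det_vid,
    individual = det_ind,
    token = paste0(det_vid, ":", within_vid),
    clip_idx = sample(15L, nr, replace = TRUE),
    stringsAsFactors = FALSE
  )

  vid_meta <- videos[match(truth_det$video_id, videos$video_id), ]
  make_channel <- function(base, channel, ided, extra = NULL) {
    d <- data.frame(
      video_id = base$video_id,
      camera_id = vid_meta$camera_id[match(base$video_id, truth_det$video_id)],
      start_timestamp = videos$start_timestamp[match(base$video_id,
                                                     videos$video_id)],
      channel = channel,
      clip_positions = join_positions(.clip_subsets[base$clip_idx]),
      individual_id = ifelse(ided, base$individual, NA_character_),
      age_sex_class = unname(asc[base$individual]),
      weaned = as.integer(unname(weaned[base$individual])),
      token = base$token,
      stringsAsFactors = FALSE
    )
    rbind(d, extra)
  }

  ex_ided <- stats::runif(nr) < config$expert_id_prob
  expert <- make_channel(truth_det, "expert", ex_ided)

  # citizen perturbations operate per video before ID assignment
  cz <- truth_det
  per_vid <- table(cz$video_id)
  uc_vids <- videos$video_id[stats::runif(n_videos) <
                               config$citizen_undercount_prob]
  uc_vids <- uc_vids[per_vid[uc_vids] >= 2L]
  drop_rows <- integer(0)
  for (v in uc_vids) {
    rows <- which(cz$video_id == v)
    drop_rows <- c(drop_rows, rows[sample.int(length(rows), 1L)])
  }
  if (length(drop_rows)) cz <- cz[-drop_rows, , drop = FALSE]
  oc_vids <- videos$video_id[stats::runif(n_videos) <
                               config$citizen_overcount_prob]
  extra <- NULL
  if (length(oc_vids)) {
    src <- vapply(oc_vids, function(v) {
      rows <- which(cz$video_id == v)
      if (length(rows)) rows[sample.int(length(rows), 1L)] else NA_integer_
    }, 1L)
    src <- src[!is.na(src)]
    if (length(src)) {
      ex <- cz[src, , drop = FALSE]
      extra <- data.frame(
        video_id = ex$video_id,
        camera_id = videos$camera_id[match(ex$video_id, videos$video_id)],
        start_timestamp = videos$start_timestamp[match(ex$video_id,
                                                       videos$video_id)],
        channel = "citizen",
        clip_positions = join_positions(.clip_subsets[ex$clip_idx]),
        individual_id = NA_character_,
        age_sex_class = "unknown",
        weaned = NA_integer_,
        token = paste0(ex$video_id, ":x", seq_along(src)),
        stringsAsFactors = FALSE
      )
    }
  }
  cz_ided <- stats::runif(nrow(cz)) < config$citizen_id_prob
  citizen <- make_channel(cz, "citizen", cz_ided, extra)

  detections <- rbind(expert, citizen)
  rownames(detections) <- NULL

  # clip classification table: 3 annotators per clip; a clip is "chimp" iff
  # some truly present animal appears in it, else unanimously blank
  clip_pos <- rep(1:4, times = n_videos)
  clip_vid <- rep(videos$video_id, each = 4L)
  occ <- matrix(FALSE, n_videos, 4L,
                dimnames = list(videos$video_id, NULL))
  for (k in seq_len(nr)) {
    occ[truth_det$video_id[k], .clip_subsets[[truth_det$clip_idx[k]]]] <- TRUE
  }
  verdict <- ifelse(t(occ)[cbind(clip_pos, match(clip_vid,
                                                 videos$video_id))],
                    "chimp", "blank")
  clips <- data.frame(
    clip_id = rep(paste0(clip_vid, "_c", clip_pos), each = 3L),
    video_id = rep(clip_vid, each = 3L),
    position = rep(clip_pos, each = 3L),
    annotator_id = rep(c("ann1", "ann2", "ann3"), times = 4L * n_videos),
    verdict = rep(verdict, each = 3L),
    stringsAsFactors = FALSE
  )

  structure(list(
    truth = list(community = community, weaned = weaned,
                 age_sex_class = asc, parties = parties,
                 event_camera = stats::setNames(cameras, names(parties)),
                 event_start = stats::setNames(format_timestamp(event_base),
                                               names(parties))),
    videos = videos,
    detections = detections,
    clips = clips,
    hashtags = data.frame(clip_id = character(0), tag = character(0),
                          stringsAsFactors = FALSE),
    config = config
  ), class = "ctsna_dataset")
}

#' @export
print.ctsna_dataset <- function(x, ...) {
  cat("camera-trap dataset:", x$config$n_individuals, "individuals,",
      x$config$n_events, "events,", nrow(x$videos), "videos,",
      nrow(x$detections), "detections (both channels)\n")
  invisible(x)
}

#' Write a simulated dataset to delimited-text files
#'
#' Emits `videos.csv`, `detections.csv`, `clips.csv`, `hashtags.csv`,
#' `truth.json` and `config.json` under `path`. The files round-trip
#' losslessly through [read_dataset()].
#'
#' @param dataset A `"ctsna_dataset"` from [simulate_community()].
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "ctsna_dataset"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(path, f),
                                         row.names = FALSE, quote = FALSE,
                                         na = "")
  wr(dataset$videos, "videos.csv")
  wr(dataset$detections, "detections.csv")
  wr(dataset$clips, "clips.csv")
  wr(dataset$hashtags, "hashtags.csv")
  tr <- dataset$truth
  jsonlite::write_json(list(
    community = as.list(tr$community), weaned = as.list(tr$weaned),
    age_sex_class = as.list(tr$age_sex_class),
    parties = tr$parties,
    event_camera = as.list(tr$event_camera),
    event_start = as.list(tr$event_start)
  ), file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Directory containing the dataset files.
#' @return A `"ctsna_dataset"`.
#' @export
read_dataset <- function(path) {
  rd <- function(f, ...) utils::read.csv(file.path(path, f),
                                         stringsAsFactors = FALSE, ...)
  detections <- rd("detections.csv",
                   colClasses = c(individual_id = "character",
                                  clip_positions = "character"))
  detections$individual_id[detections$individual_id == ""] <- NA_character_
  detections$weaned[is.na(detections$weaned)] <- NA_integer_
  tr <- jsonlite::read_json(file.path(path, "truth.json"))
  cfgl <- jsonlite::read_json(file.path(path, "config.json"))
  truth <- list(
    community = unlist(tr$community),
    weaned = unlist(tr$weaned),
    age_sex_class = unlist(tr$age_sex_class),
    parties = lapply(tr$parties, function(p) unlist(p)),
    event_camera = unlist(tr$event_camera),
    event_start = unlist(tr$event_start)
  )
  structure(list(
    truth = truth,
    videos = rd("videos.csv"),
    detections = detections,
    clips = rd("clips.csv"),
    hashtags = rd("hashtags.csv", colClasses = c("character", "character")),
    config = do.call(sim_config, cfgl)
  ), class = "ctsna_dataset")
}
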