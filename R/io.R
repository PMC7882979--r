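# file formats: plain CSV with fixed column orders, strict UTC timestamps

.detection_cols <- c("video_id", "camera_id", "start_timestamp", "channel",
                     "clip_positions", "individual_id", "age_sex_class",
                     "weaned", "token")

#' Read and write detection tables
#'
#' Detections are stored as CSV with the fixed column order `video_id,
#' camera_id, start_timestamp, channel, clip_positions, individual_id,
#' age_sex_class, weaned, token`; an empty `individual_id` means
#' unidentified, `clip_positions` is semicolon-joined, and `token` links
#' detections of the same animal instance across channels.
#'
#' @param detections Detection data frame.
#' @param path File path.
#' @return `read_detections` returns the data frame; `write_detections`
#'   returns `path` invisibly.
#' @export
write_detections <- function(detections, path) {
  stopifnot(all(.detection_cols %in% names(detections)))
  utils::write.csv(detections[, .detection_cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing <- setdiff(.detection_cols, names(d))
  if (length(missing)) {
    stop("malformed detections CSV, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parse_timestamp(d$start_timestamp)    # validates; stored as text
  bad <- !d$channel %in% c("expert", "citizen")
  if (any(bad)) {
    stop("malformed detections CSV, bad channel in row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  d$individual_id[d$individual_id == ""] <- NA_character_
  d$weaned <- suppressWarnings(as.integer(d$weaned))
  d
}

#' Read and write event tables
#'
#' Events are stored as CSV with columns `event_id, camera_id, t_start,
#' t_end, n_videos, video_ids` (`video_ids` semicolon-joined, time order).
#'
#' @param events Event data frame from [group_events()].
#' @param path File path.
#' @return `read_events` returns the data frame; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(video_ids = "character"))
  parse_timestamp(e$t_start)
  parse_timestamp(e$t_end)
  e
}

#' Export an association network
#'
#' Three interchange formats: a tab-delimited square matrix, an edge list
#' (`indiv_a, indiv_b, weight` with weights printed to 6 decimals, lower
#' triangle only), and GraphML for standard graph viewers.
#'
#' @param m An `"assoc_matrix"` (or plain symmetric matrix with dimnames).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_matrix <- function(m, path) {
  utils::write.table(unclass(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_network_matrix
#' @export
write_network_edges <- function(m, path) {
  ix <- which(lower.tri(m), arr.ind = TRUE)
  edges <- data.frame(indiv_a = rownames(m)[ix[, 2L]],
                      indiv_b = rownames(m)[ix[, 1L]],
                      weight = sprintf("%.6f", m[ix]),
                      stringsAsFactors = FALSE)
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_matrix
#' @export
write_network_graphml <- function(m, path) {
  g <- igraph::graph_from_adjacency_matrix(unclass(m), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge list written by [write_network_edges()]
#'
#' @param path Edge-list CSV.
#' @param roster Optional roster fixing matrix order; inferred otherwise.
#' @return An `"assoc_matrix"`.
#' @export
read_network_edges <- function(path, roster = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(roster)) roster <- sort(unique(c(e$indiv_a, e$indiv_b)))
  m <- matrix(0, length(roster), length(roster),
              dimnames = list(roster, roster))
  m[cbind(e$indiv_a, e$indiv_b)] <- e$weight
  m[cbind(e$indiv_b, e$indiv_a)] <- e$weight
  structure(m, class = c("assoc_matrix", "matrix"))
}

#' Read an ID-standardization map
#'
#' The map aligns citizen-channel ID names with expert names, one row per
#' citizen ID (`citizen_id, expert_id` plus optional `note`). A citizen ID
#' the expert associated with two distinct expert IDs (a chimeric ID) may
#' appear on multiple rows; it is collapsed to its first expert ID and
#' flagged in the returned `chimera` column.
#'
#' @param path CSV file path.
#' @return Data frame `citizen_id, expert_id, note, chimera` with unique
#'   `citizen_id`.
#' @export
read_id_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  stopifnot(all(c("citizen_id", "expert_id") %in% names(m)))
  if (is.null(m$note)) m$note <- ""
  chim <- tapply(m$expert_id, m$citizen_id,
                 function(x) length(unique(x)) > 1L)
  out <- m[!duplicated(m$citizen_id), c("citizen_id", "expert_id", "note")]
  out$chimera <- unname(chim[out$citizen_id])
  rownames(out) <- NULL
  out
}

# per-video minute-linked counts for one channel, via producer tokens
.minute_counts <- function(detections, channel, video_ids) {
  d <- detections[detections$channel == channel &
                    detections$video_id %in% video_ids, , drop = FALSE]
  cnt <- vapply(split(d$token, d$video_id),
                function(tok) link_minute(list(tok))$count, 1L)
  out <- stats::setNames(integer(length(video_ids)), video_ids)
  out[names(cnt)] <- cnt
  out
}

#' Run the full pipeline and emit a results summary
#'
#' End-to-end driver: simulates (or takes) a two-channel dataset, applies
#' the video-inclusion filter, links minutes, computes detection-count and
#' ID agreement statistics, groups events, builds per-channel SRI networks
#' on the shared weaned roster, detects communities, compares node metrics
#' (Spearman), runs MRQAP with double semi-partialling, and estimates a
#' subsampling robustness curve for the sparser channel. Every stochastic
#' stage is seeded from the dataset's configuration seed, so a fixed
#' configuration yields a byte-identical report.
#'
#' @param x A `"sim_config"` or a `"ctsna_dataset"`.
#' @param n_permutations MRQAP permutations (default 1000).
#' @param n_replicates Robustness replicates per grid size (default 1000).
#' @param grid Robustness sample-size grid; default 15 to 170 by 5,
#'   truncated to the available event count.
#' @param mrqap_response Which channel's network is the MRQAP response
#'   (default `"expert"`: does the citizen network predict the expert one).
#' @param out_dir Optional directory; when given, writes `report.json` plus
#'   events, networks (edge list, matrix, GraphML), node metrics and the
#'   robustness curve as text files.
#' @return The report as a nested list (invisibly the same list written to
#'   JSON).
#' @export
run_report <- function(x = sim_config(), n_permutations = 1000L,
                       n_replicates = 1000L, grid = NULL,
                       mrqap_response = c("expert", "citizen"),
                       out_dir = NULL) {
  mrqap_response <- match.arg(mrqap_response)
  dat <- if (inherits(x, "ctsna_dataset")) x else simulate_community(x)
  cfg <- dat$config

  included <- video_inclusion_filter(dat$clips, dat$hashtags)
  cnt_ex <- .minute_counts(dat$detections, "expert", included)
  cnt_cz <- .minute_counts(dat$detections, "citizen", included)
  det <- detection_agreement(cnt_ex, cnt_cz)

  din <- dat$detections[dat$detections$video_id %in% included, ,
                        drop = FALSE]
  rate_ex <- id_assignment_rate(din, "expert")
  rate_cz <- id_assignment_rate(din, "citizen")

  ex <- din[din$channel == "expert", , drop = FALSE]
  cz <- din[din$channel == "citizen", , drop = FALSE]
  key <- intersect(ex$token[!is.na(ex$individual_id)],
                   cz$token[!is.na(cz$individual_id)])
  ida <- id_agreement(ex$individual_id[match(key, ex$token)],
                      cz$individual_id[match(key, cz$token)],
                      ex$age_sex_class[match(key, ex$token)],
                      cz$age_sex_class[match(key, cz$token)])

  n_known <- cfg$n_individuals
  under_ex <- underestimate_pct(
    length(unique(stats::na.omit(ex$individual_id))), n_known)
  under_cz <- underestimate_pct(
    length(unique(stats::na.omit(cz$individual_id))), n_known)

  events <- group_events(dat$videos)
  roster <- select_shared_roster(din)
  parties_ex <- gambit_party(events, din, "expert")
  parties_cz <- gambit_party(events, din, "citizen")
  net_ex <- build_network(parties_ex, roster)
  net_cz <- build_network(parties_cz, roster)

  part_ex <- leading_eigenvector_communities(net_ex)
  part_cz <- leading_eigenvector_communities(net_cz)
  agree <- membership_agreement(part_ex, part_cz, roster)

  cen_ex <- eigenvector_centrality(net_ex)
  cen_cz <- eigenvector_centrality(net_cz)
  str_ex <- node_strength(net_ex)
  str_cz <- node_strength(net_cz)

  yx <- if (mrqap_response == "expert") list(net_ex, net_cz) else
    list(net_cz, net_ex)
  qr_ <- mrqap_dsp(yx[[1L]], stats::setNames(list(unclass(yx[[2L]])),
                                             "other_channel"),
                   n_permutations = n_permutations,
                   seed = cfg$seed + 1000L)

  # robustness on the sparser (citizen) network's qualifying events
  qual_cz <- parties_cz[vapply(parties_cz,
                               function(p) any(p %in% roster), TRUE)]
  if (is.null(grid)) {
    top <- min(170L, length(qual_cz))
    grid <- seq(15L, top, 5L)
  }
  rob <- robustness_curve(qual_cz, roster, grid = grid,
                          n_replicates = n_replicates,
                          seed = cfg$seed + 2000L)

  report <- list(
    package = "camtrapnets",
    version = as.character(utils::packageVersion("camtrapnets")),
    seed = cfg$seed,
    config = unclass(cfg),
    n_permutations = n_permutations,
    n_replicates = n_replicates,
    detection = list(
      n_videos_included = length(included),
      n_count_agree = det$n_count_agree,
      pct_count_agree = det$pct_count_agree,
      n_under = det$n_under, n_over = det$n_over,
      pct_under = det$pct_under,
      mean_abs_disagreement = det$mean_abs_disagreement
    ),
    identification = list(
      expert = rate_ex, citizen = rate_cz,
      id_agreement = ida[c("n_total", "n_agree", "pct_agree")],
      roster_underestimate_pct = list(expert = under_ex,
                                      citizen = under_cz),
      n_known = n_known
    ),
    network = list(
      roster_size = length(roster),
      n_events_total = nrow(events),
      n_events_qualifying = list(expert = attr(net_ex, "n_events"),
                                 citizen = attr(net_cz, "n_events")),
      n_communities = list(expert = part_ex$n_communities,
                           citizen = part_cz$n_communities),
      modularity = list(expert = part_ex$modularity,
                        citizen = part_cz$modularity),
      membership_agreement_pct = agree$pct_same,
      mrqap = list(response = mrqap_response,
                   coefficient = unname(qr_$coefficients[2L]),
                   adj_r_squared = qr_$adj_r_squared,
                   p_value = unname(qr_$p_values[1L])),
      spearman = list(
        eigenvector_centrality = spearman_rho(cen_ex[roster],
                                              cen_cz[roster]),
        strength = spearman_rho(str_ex[roster], str_cz[roster])
      )
    ),
    robustness = list(
      channel = "citizen",
      grid = rob$n,
      mean = rob$mean,
      ci_low = rob$ci_low,
      ci_high = rob$ci_high,
      final_mean = rob$mean[nrow(rob)],
      plateau_n = plateau_size(rob)
    )
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_events(events, file.path(out_dir, "events.csv"))
    for (ch in c("expert", "citizen")) {
      net <- if (ch == "expert") net_ex else net_cz
      write_network_edges(net, file.path(out_dir,
                                         paste0("network_", ch, ".csv")))
      write_network_matrix(net, file.path(out_dir,
                                          paste0("network_", ch, ".tsv")))
      write_network_graphml(net, file.path(out_dir,
                                           paste0("network_", ch,
                                                  ".graphml")))
    }
    metrics <- data.frame(
      individual = roster,
      strength_expert = unname(str_ex[roster]),
      strength_citizen = unname(str_cz[roster]),
      centrality_expert = unname(cen_ex[roster]),
      centrality_citizen = unname(cen_cz[roster]),
      community_expert = unname(part_ex$membership[roster]),
      community_citizen = unname(part_cz$membership[roster])
    )
    utils::write.csv(metrics, file.path(out_dir, "node_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(rob),
                     file.path(out_dir, "robustness_curve.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
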