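#' Per-video detection-count agreement between two observer channels
#'
#' Compares the number of animals each channel tallied per 1-min video.
#' Disagreements are split into undercounts and overcounts of channel B
#' relative to channel A, and the undercount share is reported as a percent
#' of disagreements. All percentages are rounded half-up to integers.
#'
#' @param counts_a,counts_b Named numeric vectors of per-video counts (names
#'   are video IDs); the two video sets must coincide.
#' @return List: `n_videos`, `n_count_agree`, `pct_count_agree`, `n_under`,
#'   `n_over`, `pct_under` (share of disagreements), `mean_abs_disagreement`,
#'   `range_under`, `range_over`.
#' @export
detection_agreement <- function(counts_a, counts_b) {
  if (!setequal(names(counts_a), names(counts_b))) {
    d <- c(setdiff(names(counts_a), names(counts_b)),
           setdiff(names(counts_b), names(counts_a)))
    stop("video sets differ between channels: ",
         paste(utils::head(d, 5L), collapse = ", "), call. = FALSE)
  }
  b <- counts_b[names(counts_a)]
  diff_ <- b - counts_a
  n <- length(diff_)
  n_agree <- sum(diff_ == 0)
  n_under <- sum(diff_ < 0)
  n_over <- sum(diff_ > 0)
  dis <- abs(diff_[diff_ != 0])
  list(
    n_videos = n,
    n_count_agree = n_agree,
    pct_count_agree = pct_round(100 * n_agree / n),
    n_under = n_under,
    n_over = n_over,
    pct_under = if (n_under + n_over > 0) {
      pct_round(100 * n_under / (n_under + n_over))
    } else NA_integer_,
    mean_abs_disagreement = if (length(dis)) mean(dis) else 0,
    range_under = if (n_under) range(abs(diff_[diff_ < 0])) else c(0L, 0L),
    range_over = if (n_over) range(diff_[diff_ > 0]) else c(0L, 0L)
  )
}

#' Share of detected animals that received an individual ID
#'
#' A detection is one animal in one 1-min video (after minute linking). The
#' rate is the share carrying a (confirmed) individual ID, as a half-up
#' integer percent.
#'
#' @param detections Detection table, or a count `n_with_id` when `n_total`
#'   is given.
#' @param channel Channel to tally when `detections` is a table.
#' @param n_total Total detections (numeric interface).
#' @return List: `n_with_id`, `n_total`, `pct_with_id`.
#' @export
id_assignment_rate <- function(detections, channel = NULL, n_total = NULL) {
  if (is.data.frame(detections)) {
    d <- detections
    if (!is.null(channel)) d <- d[d$channel == channel, , drop = FALSE]
    n_with <- sum(!is.na(d$individual_id))
    n_tot <- nrow(d)
  } else {
    n_with <- detections
    n_tot <- n_total
  }
  if (is.null(n_tot) || n_tot == 0) {
    warning("no detections: assignment rate undefined")
    return(list(n_with_id = n_with, n_total = n_tot %||% 0L,
                pct_with_id = NA_integer_))
  }
  list(n_with_id = n_with, n_total = n_tot,
       pct_with_id = pct_round(100 * n_with / n_tot))
}

#' Agreement between the two channels' IDs for co-identified detections
#'
#' For detections of the same animal instance that carry an ID in both
#' channels (after ID standardization), reports how often the IDs match.
#' When age-sex classes are supplied, disagreements are additionally
#' classified by whether the mismatching IDs fall in the same class.
#'
#' @param ids_a,ids_b Character vectors of standardized IDs for matched
#'   detections.
#' @param class_a,class_b Optional age-sex class vectors parallel to the
#'   IDs.
#' @return List: `n_total`, `n_agree`, `pct_agree`, and (with classes) a
#'   `mismatch_pattern` table of disagreements by same/different class.
#' @export
id_agreement <- function(ids_a, ids_b, class_a = NULL, class_b = NULL) {
  stopifnot(length(ids_a) == length(ids_b))
  agree <- ids_a == ids_b
  out <- list(n_total = length(agree), n_agree = sum(agree),
              pct_agree = if (length(agree)) {
                pct_round(100 * mean(agree))
              } else NA_integer_)
  if (!is.null(class_a) && !is.null(class_b)) {
    mis <- !agree
    out$mismatch_pattern <- c(
      same_class = sum(mis & class_a == class_b),
      different_class = sum(mis & class_a != class_b)
    )
  }
  out
}

#' Roster underestimate of a channel
#'
#' How far short a channel's set of uniquely identified individuals falls of
#' the known population, as a half-up integer percent.
#'
#' @param n_identified_unique Number of distinct individuals the channel
#'   identified.
#' @param n_known Number of individuals known to be present.
#' @return Integer percent.
#' @export
#' @examples
#' underestimate_pct(36, 37)  # 3
#' underestimate_pct(29, 37)  # 22
underestimate_pct <- function(n_identified_unique, n_known) {
  if (n_known == 0) stop("n_known must be positive", call. = FALSE)
  stopifnot(n_identified_unique >= 0, n_identified_unique <= n_known)
  pct_round(100 * (1 - n_identified_unique / n_known))
}

#' Cohen's kappa from a square contingency table
#'
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o the diagonal
#' share and chance agreement p_e the sum of products of marginal shares --
#' agreement corrected for chance concordance between two raters.
#'
#' @param table Square matrix of non-negative category counts (raters on the
#'   two dimensions).
#' @return Kappa coefficient.
#' @export
cohens_kappa <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == ncol(m), nrow(m) >= 2L, all(m >= 0))
  tot <- sum(m)
  if (tot == 0) stop("empty contingency table", call. = FALSE)
  po <- sum(diag(m)) / tot
  pe <- sum(rowSums(m) * colSums(m)) / tot^2
  if (1 - pe <= 0) {
    warning("chance agreement is 1: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Resolve prospective IDs against an expert mapping
#'
#' Prospective IDs are the candidate labels that never achieved consensus.
#' Given each one's expert adjudication, reports the three-way partition
#' (resolved to an existing confirmed ID, unresolvable or non-member,
#' genuinely unique but unconfirmed) and the resolved share as an integer
#' percent.
#'
#' @param status Character vector with one entry per prospective ID, each
#'   one of `"resolved_to_confirmed"`, `"unresolvable_or_nonmember"`,
#'   `"unique_unconfirmed"`.
#' @return List of the three counts plus `n_total` and `pct_resolved`.
#' @export
prospective_id_resolution <- function(status) {
  lv <- c("resolved_to_confirmed", "unresolvable_or_nonmember",
          "unique_unconfirmed")
  if (!all(status %in% lv)) {
    stop("statuses must partition into: ", paste(lv, collapse = ", "),
         call. = FALSE)
  }
  ct <- table(factor(status, lv))
  n <- length(status)
  list(resolved_to_confirmed = as.integer(ct[[1L]]),
       unresolvable_or_nonmember = as.integer(ct[[2L]]),
       unique_unconfirmed = as.integer(ct[[3L]]),
       n_total = n,
       pct_resolved = if (n) pct_round(100 * ct[[1L]] / n) else 0L)
}
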