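# Contact-episode detection: frames where two standing pigs are in close
# physical contact, segmented into maximal runs of sufficient duration.

#' Per-frame contact pairs
#'
#' A pair of tracks is in contact at a frame when both are observed there
#' and either (a) their barycenter distance is at most `contact_dist_px`, or
#' (b) both are flagged as sharing a merged blob. Groups of three or more
#' pigs in mutual contact decompose into all pairwise contacts.
#'
#' @param tracks List of tracks from [track_regions].
#' @param contact_dist_px Contact distance threshold in pixels.
#' @return Data frame with columns `frame`, `id_a`, `id_b` (id_a < id_b),
#'   `dist`, `merged`; one row per contact pair per frame.
#' @export
contact_pairs <- function(tracks, contact_dist_px) {
  stopifnot(contact_dist_px > 0)
  empty <- data.frame(frame = integer(), id_a = integer(), id_b = integer(),
                      dist = numeric(), merged = logical())
  if (length(tracks) < 2) return(empty)
  obs <- do.call(rbind, lapply(tracks, function(t)
    data.frame(id = t$id, frame = t$frames, row = t$rows, col = t$cols,
               merged = t$merged)))
  out <- lapply(split(obs, obs$frame), function(fr) {
    n <- nrow(fr)
    if (n < 2) return(NULL)
    pr <- utils::combn(n, 2)
    d <- sqrt((fr$row[pr[1, ]] - fr$row[pr[2, ]])^2 +
              (fr$col[pr[1, ]] - fr$col[pr[2, ]])^2)
    both_merged <- fr$merged[pr[1, ]] & fr$merged[pr[2, ]] & d < 1e-9
    hit <- d <= contact_dist_px | both_merged
    if (!any(hit)) return(NULL)
    data.frame(frame = fr$frame[1],
               id_a = pmin(fr$id[pr[1, hit]], fr$id[pr[2, hit]]),
               id_b = pmax(fr$id[pr[1, hit]], fr$id[pr[2, hit]]),
               dist = d[hit], merged = both_merged[hit])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$frame, out$id_a, out$id_b), ]
}

#' Segment contact frames into interaction episodes
#'
#' For each track pair, maximal runs of contact frames become episodes;
#' runs separated by at most `max_gap_frames` missing frames are bridged
#' (momentary tracking dropouts), and a run survives only if its duration
#' `(end - start + 1) / fps` reaches `min_duration_s` (inclusive). With the
#' defaults this encodes the rule that an interaction is close physical
#' contact lasting at least one second.
#'
#' @param contacts Data frame from [contact_pairs].
#' @param meta A [sequence_meta] (for fps).
#' @param min_duration_s Minimum episode duration in seconds (default 1).
#' @param max_gap_frames Largest bridged gap in frames (default 5).
#' @return Data frame of episodes: `episode_id`, `track_a`, `track_b`,
#'   `start_frame`, `end_frame`, `duration_s`.
#' @export
segment_episodes <- function(contacts, meta, min_duration_s = 1.0,
                             max_gap_frames = 5) {
  stopifnot(min_duration_s > 0)
  empty <- data.frame(episode_id = integer(), track_a = integer(),
                      track_b = integer(), start_frame = integer(),
                      end_frame = integer(), duration_s = numeric())
  if (nrow(contacts) == 0) return(empty)
  key <- paste(contacts$id_a, contacts$id_b, sep = ":")
  eps <- lapply(split(contacts, key), function(cc) {
    fr <- sort(unique(cc$frame))
    run <- cumsum(c(1, diff(fr) > max_gap_frames + 1))
    do.call(rbind, lapply(split(fr, run), function(r) {
      dur <- (max(r) - min(r) + 1) / meta$fps
      if (dur < min_duration_s) return(NULL)
      data.frame(track_a = cc$id_a[1], track_b = cc$id_b[1],
                 start_frame = min(r), end_frame = max(r), duration_s = dur)
    }))
  })
  eps <- do.call(rbind, eps)
  if (is.null(eps) || nrow(eps) == 0) return(empty)
  eps <- eps[order(eps$start_frame, eps$track_a, eps$track_b), ]
  rownames(eps) <- NULL
  cbind(episode_id = seq_len(nrow(eps)), eps)
}
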