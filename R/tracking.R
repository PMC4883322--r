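# Identity maintenance across frames: greedy Euclidean matching of region
# barycenters against active track heads, with a bounded miss gap and a
# merged-blob rule for pigs in full body contact.

#' Match segmented regions to active tracks in one frame
#'
#' Greedy one-to-one assignment in ascending order of pairwise Euclidean
#' barycenter distance; only pairs at distance `max_dist_px` or less are
#' eligible. Ties in distance are broken by lower track id, then lower
#' region index, so the assignment is deterministic. Regions left unmatched
#' are reported so the caller can open new tracks.
#'
#' @param track_pos Numeric matrix (n_tracks x 2, columns row/col) of the
#'   last known barycenter of each active track.
#' @param track_ids Integer vector of track ids, parallel to `track_pos`.
#' @param region_pos Numeric matrix (n_regions x 2) of region barycenters.
#' @param max_dist_px Matching threshold in pixels; either a scalar or one
#'   value per track (a track emerging from a merged blob gets a wider
#'   radius, since the blob barycenter sat between the two bodies).
#' @return List with `assignment` (data frame of track_id, region, dist) and
#'   `new_regions` (indices of regions that matched no track).
#' @export
match_regions <- function(track_pos, track_ids, region_pos, max_dist_px = 30) {
  stopifnot(max_dist_px > 0)
  nt <- nrow(track_pos); nr <- nrow(region_pos)
  if (is.null(nt)) nt <- 0L
  if (is.null(nr)) nr <- 0L
  if (nt == 0 || nr == 0)
    return(list(assignment = data.frame(track_id = integer(),
                                        region = integer(), dist = numeric()),
                new_regions = seq_len(nr)))
  d <- outer(track_pos[, 1], region_pos[, 1], "-")^2 +
       outer(track_pos[, 2], region_pos[, 2], "-")^2
  d <- sqrt(d)
  lim <- rep_len(max_dist_px, nt)
  cand <- which(d <= matrix(lim, nt, nr), arr.ind = TRUE)
  assignment <- data.frame(track_id = integer(), region = integer(),
                           dist = numeric())
  if (nrow(cand) > 0) {
    ord <- order(d[cand], track_ids[cand[, 1]], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used_t <- logical(nt); used_r <- logical(nr)
    for (k in seq_len(nrow(cand))) {
      ti <- cand[k, 1]; ri <- cand[k, 2]
      if (used_t[ti] || used_r[ri]) next
      used_t[ti] <- TRUE; used_r[ri] <- TRUE
      assignment <- rbind(assignment,
                          data.frame(track_id = track_ids[ti], region = ri,
                                     dist = d[ti, ri]))
    }
    new_regions <- which(!used_r)
  } else new_regions <- seq_len(nr)
  list(assignment = assignment, new_regions = new_regions)
}

#' Track pigs across a sequence of segmented frames
#'
#' Maintains identities by per-frame greedy barycenter matching
#' ([match_regions]). A track unmatched for more than `max_gap` consecutive
#' frames deactivates; a pig reappearing later receives a fresh id. When two
#' pigs press into full contact their blobs merge into one large region
#' (area above `merge_area_factor` times the running median region area);
#' tracks that lose their own region but lie close to such a region are
#' attached to it, all attached tracks receive the merged barycenter, and
#' those frames are flagged `merged` for the episode detector. The attach
#' radius is widened by half the blob's equivalent-circle radius because a
#' merged barycenter sits mid-way between the two bodies.
#'
#' @param regions_by_frame List (one element per frame) of region lists from
#'   [segment_pigs].
#' @param max_dist_px Matching threshold in pixels (default 30).
#' @param max_gap Consecutive misses tolerated before deactivation
#'   (default 5).
#' @param merge_area_factor Area multiple of the running median region area
#'   above which a region is considered a merged blob (default 1.5).
#' @return List of tracks, each with `id`, `frames` (0-based), `rows`,
#'   `cols`, `merged` (logical per observation).
#' @export
track_regions <- function(regions_by_frame, max_dist_px = 30, max_gap = 5,
                          merge_area_factor = 1.5) {
  tracks <- list()       # finished + live track records
  live <- integer(0)     # indices into `tracks` of active tracks
  missed <- integer(0)   # consecutive misses per live track
  next_id <- 1L
  areas_seen <- numeric(0)

  for (f in seq_along(regions_by_frame)) {
    regions <- regions_by_frame[[f]]
    frame0 <- f - 1L
    npos <- length(regions)
    pos <- if (npos) t(vapply(regions, function(r) r$barycenter,
                              numeric(2))) else matrix(numeric(0), 0, 2)
    areas <- vapply(regions, function(r) r$area, numeric(1))
    areas_seen <- c(areas_seen, areas)
    med_area <- if (length(areas_seen)) stats::median(areas_seen) else Inf

    tpos <- if (length(live))
      t(vapply(tracks[live], function(t) c(t$rows[length(t$rows)],
                                           t$cols[length(t$cols)]),
               numeric(2))) else matrix(numeric(0), 0, 2)
    tids <- vapply(tracks[live], function(t) t$id, integer(1))

    # a track last seen on a merged blob sat at the blob barycenter, up to
    # half a blob radius away from its own body: widen its match radius
    eff_dist <- vapply(tracks[live], function(t) {
      n <- length(t$merged)
      if (n && t$merged[n]) max_dist_px + 0.5 * sqrt(t$last_area / pi)
      else max_dist_px
    }, numeric(1))

    m <- match_regions(tpos, tids, pos, eff_dist)
    matched_live <- match(m$assignment$track_id, tids)
    attach <- rep(NA_integer_, length(live))        # region index per live track
    attach[matched_live] <- m$assignment$region

    # merged-blob pass: unmatched live tracks may join a nearby large region
    big <- which(areas > merge_area_factor * med_area)
    if (length(big) && any(is.na(attach))) {
      for (li in which(is.na(attach))) {
        dd <- sqrt((pos[big, 1] - tpos[li, 1])^2 +
                   (pos[big, 2] - tpos[li, 2])^2)
        radius <- max_dist_px + 0.5 * sqrt(areas[big] / pi)
        ok <- which(dd <= radius)
        if (length(ok)) attach[li] <- big[ok[which.min(dd[ok])]]
      }
    }
    merged_region <- as.integer(names(which(table(attach) >= 2)))

    for (li in seq_along(live)) {
      ri <- attach[li]
      if (is.na(ri)) { missed[li] <- missed[li] + 1L; next }
      ti <- live[li]
      tracks[[ti]]$frames <- c(tracks[[ti]]$frames, frame0)
      tracks[[ti]]$rows <- c(tracks[[ti]]$rows, unname(pos[ri, 1]))
      tracks[[ti]]$cols <- c(tracks[[ti]]$cols, unname(pos[ri, 2]))
      tracks[[ti]]$merged <- c(tracks[[ti]]$merged, ri %in% merged_region)
      tracks[[ti]]$last_area <- areas[ri]
      missed[li] <- 0L
    }

    keep <- missed <= max_gap
    live <- live[keep]; missed <- missed[keep]

    taken <- unique(attach[!is.na(attach)])
    for (ri in setdiff(seq_len(npos), taken)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, frames = frame0,
        rows = unname(pos[ri, 1]), cols = unname(pos[ri, 2]), merged = FALSE,
        last_area = areas[ri])
      live <- c(live, length(tracks)); missed <- c(missed, 0L)
      next_id <- next_id + 1L
    }
  }
  lapply(tracks, function(t) structure(t, class = "pig_track"))
}

#' Per-step speeds along a track
#'
#' The speed between consecutive observations is the Euclidean barycenter
#' displacement divided by the frame gap, times the frame rate: pixels per
#' second. When `meta$px_per_cm` is set, speeds are additionally returned in
#' cm/s.
#'
#' @param track A track from [track_regions] (fields `frames`, `rows`,
#'   `cols`).
#' @param meta A [sequence_meta].
#' @return Data frame with one row per step: `frame_from`, `frame_to`,
#'   `speed_px_s` and, when calibrated, `speed_cm_s`. Tracks with fewer than
#'   two observations yield zero rows.
#' @export
compute_speeds <- function(track, meta) {
  n <- length(track$frames)
  if (n < 2)
    return(data.frame(frame_from = integer(), frame_to = integer(),
                      speed_px_s = numeric()))
  dr <- diff(track$rows); dc <- diff(track$cols)
  gap <- diff(track$frames)
  sp <- sqrt(dr^2 + dc^2) / gap * meta$fps
  out <- data.frame(frame_from = track$frames[-n],
                    frame_to = track$frames[-1],
                    speed_px_s = sp)
  if (!is.null(meta$px_per_cm)) out$speed_cm_s <- sp / meta$px_per_cm
  out
}

#' Tabulate tracks
#'
#' @param tracks List of tracks from [track_regions].
#' @param meta A [sequence_meta] used for speeds.
#' @return Data frame: track_id, frame, row, col, speed_px_s (speed of the
#'   step ending at this frame; NA for the first observation), merged_flag.
#' @export
tracks_to_df <- function(tracks, meta) {
  if (length(tracks) == 0)
    return(data.frame(track_id = integer(), frame = integer(),
                      row = numeric(), col = numeric(),
                      speed_px_s = numeric(), merged_flag = logical()))
  do.call(rbind, lapply(tracks, function(t) {
    sp <- compute_speeds(t, meta)
    data.frame(track_id = t$id, frame = t$frames, row = t$rows, col = t$cols,
               speed_px_s = c(NA_real_, sp$speed_px_s),
               merged_flag = t$merged)
  }))
}
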