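# Five-dimensional activity descriptor of one interaction episode:
# minimum, maximum, mean and standard deviation of velocity, pooled over
# both interacting pigs, plus the mean inter-pig distance.

#' Extract the five-feature activity descriptor for an episode
#'
#' Per-step speeds of *both* pigs are pooled into one sample over the
#' episode interval (steps whose two endpoint frames both lie inside the
#' interval). `v_min`, `v_max`, `v_mean` are the minimum, maximum and mean
#' of the pooled sample and `v_std` its population (divide-by-n) standard
#' deviation. `dist` is the mean barycenter distance between the two pigs
#' over the episode frames where both are observed; during merged-blob
#' frames both tracks carry the blob barycenter, so those frames contribute
#' distance 0.
#'
#' @param episode One row of the data frame from [segment_episodes] (or any
#'   list with `track_a`, `track_b`, `start_frame`, `end_frame`).
#' @param tracks List of tracks from [track_regions].
#' @param meta A [sequence_meta]; speeds are px/s, or cm/s when
#'   `px_per_cm` is set.
#' @return A `feature_vector`: list with `v_min`, `v_max`, `v_mean`,
#'   `v_std`, `dist`, `episode_id`, `label` (NA until classified).
#' @export
extract_features <- function(episode, tracks, meta) {
  s <- episode$start_frame; e <- episode$end_frame
  if (e - s < 1)
    stop("episode spans fewer than 2 frames: insufficient data",
         call. = FALSE)
  ids <- vapply(tracks, function(t) t$id, integer(1))
  ta <- tracks[[match(episode$track_a, ids)]]
  tb <- tracks[[match(episode$track_b, ids)]]
  if (is.null(ta) || is.null(tb))
    stop("episode references unknown track ids", call. = FALSE)

  step_speeds <- function(t) {
    sp <- compute_speeds(t, meta)
    sp$speed_px_s[sp$frame_from >= s & sp$frame_to <= e]
  }
  unit_speed <- function(sp) {
    if (!is.null(meta$px_per_cm)) sp / meta$px_per_cm else sp
  }
  pooled <- unit_speed(c(step_speeds(ta), step_speeds(tb)))
  if (length(pooled) == 0)
    stop("no speed samples inside the episode interval", call. = FALSE)

  ia <- ta$frames >= s & ta$frames <= e
  ib <- tb$frames >= s & tb$frames <= e
  common <- intersect(ta$frames[ia], tb$frames[ib])
  da <- match(common, ta$frames); db <- match(common, tb$frames)
  dists <- sqrt((ta$rows[da] - tb$rows[db])^2 +
                (ta$cols[da] - tb$cols[db])^2)
  if (!is.null(meta$px_per_cm)) dists <- dists / meta$px_per_cm

  structure(
    list(v_min = min(pooled), v_max = max(pooled), v_mean = mean(pooled),
         v_std = sqrt(mean((pooled - mean(pooled))^2)),
         dist = mean(dists),
         episode_id = if (!is.null(episode$episode_id))
           episode$episode_id else NA_integer_,
         label = NA_character_),
    class = "feature_vector")
}

#' Assemble feature vectors into a tabular dataset
#'
#' @param fvs List of `feature_vector` objects from [extract_features].
#' @return Data frame with columns `episode_id`, `v_min`, `v_max`, `v_mean`,
#'   `v_std`, `dist`, `label`; one row per episode, header-only when `fvs`
#'   is empty. Round-trips through CSV.
#' @export
features_to_table <- function(fvs) {
  if (length(fvs) == 0)
    return(data.frame(episode_id = integer(), v_min = numeric(),
                      v_max = numeric(), v_mean = numeric(),
                      v_std = numeric(), dist = numeric(),
                      label = character()))
  do.call(rbind, lapply(fvs, function(f)
    data.frame(episode_id = f$episode_id, v_min = f$v_min, v_max = f$v_max,
               v_mean = f$v_mean, v_std = f$v_std, dist = f$dist,
               label = f$label)))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(
    "<feature_vector> v_min=%.3g v_max=%.3g v_mean=%.3g v_std=%.3g dist=%.3g\n",
    x$v_min, x$v_max, x$v_mean, x$v_std, x$dist))
  invisible(x)
}
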