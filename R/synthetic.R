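# Synthetic top-view depth-video simulator. Pigs are rigid ellipses at
# standing or lying height on a flat pen floor; behaviors differ only in
# their kinematics, which is exactly the information the five-feature
# activity descriptor can see. Every episode carries ground-truth tracks
# and a labelled contact interval.

#' Simulator configuration
#'
#' Defaults mirror the recording conditions the pipeline targets (512 x 424
#' px at 30 fps) and pen geometry plausible for ~25-30 kg weaner pigs under
#' a ceiling-mounted depth camera: a 2.5 m camera-to-floor distance, body
#' ellipses of 70 x 36 px, shoulder height 400 mm standing and 150 mm
#' lying. Behavior kinematics are parameterised per class; the default
#' corpus composition is 215 normal, 61 knocking and 54 chasing episodes.
#'
#' @param ... Named overrides of any default listed below.
#' @return A `sim_config` list with fields:
#' \describe{
#'   \item{arena_w, arena_h}{frame size in px (512, 424)}
#'   \item{fps}{frames per second (30)}
#'   \item{floor_depth_mm}{camera-to-floor distance (2500)}
#'   \item{pig_semi_major, pig_semi_minor}{body ellipse semi-axes in px
#'     (35, 18)}
#'   \item{standing_height_mm, lying_height_mm}{body height above floor
#'     (400, 150)}
#'   \item{standing_mm}{segmentation threshold the geometry must straddle
#'     (250)}
#'   \item{noise_sd_mm, dropout_frac}{i.i.d. Gaussian depth noise sd (10)
#'     and fraction of no-return pixels (0.01)}
#'   \item{contact_dist_px}{contact threshold, 1.2 x body length (84)}
#'   \item{walk_speed, walk_sep}{normal walking speed range in px/s
#'     (20-50) and side-by-side separation (75)}
#'   \item{knock_gap, knock_burst_px, knock_burst_frames,
#'     knock_recoil_frames, knock_burst_prob, knock_drift_speed}{knocking:
#'     head-to-head barycenter gap (85), lunge amplitude range in px
#'     (12-20), lunge/recoil durations in frames, per-frame lunge start
#'     probability (0.12), drift speed of the pair (5 px/s)}
#'   \item{chase_speed, chase_gap}{chasing: sustained pursuit speed range
#'     in px/s (100-140) and along-path pursuer gap (80)}
#'   \item{contact_s, pad_s}{contact-interval duration range in seconds
#'     (1.2-2.4) and approach/depart padding (0.3)}
#'   \item{approach_extra_px}{extra separation at episode start/end (40)}
#'   \item{counts}{named episode counts for [generate_corpus]
#'     (normal 215, knocking 61, chasing 54)}
#'   \item{seed}{master seed for [generate_corpus] (1)}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    arena_w = 512L, arena_h = 424L, fps = 30, floor_depth_mm = 2500,
    pig_semi_major = 35, pig_semi_minor = 18,
    standing_height_mm = 400, lying_height_mm = 150, standing_mm = 250,
    noise_sd_mm = 10, dropout_frac = 0.01,
    contact_dist_px = 84,
    walk_speed = c(20, 50), walk_sep = 75,
    knock_gap = 78, knock_burst_px = c(12, 20),
    knock_burst_frames = 2:3, knock_recoil_frames = 3:5,
    knock_burst_prob = 0.12, knock_drift_speed = 5,
    chase_speed = c(100, 140), chase_gap = 80,
    contact_s = c(1.2, 2.4), pad_s = 0.3, approach_extra_px = 40,
    counts = c(normal = 215, knocking = 61, chasing = 54),
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  stopifnot(cfg$standing_height_mm > cfg$standing_mm,
            cfg$standing_mm > cfg$lying_height_mm,
            cfg$fps > 0, cfg$floor_depth_mm > 0)
  structure(cfg, class = "sim_config")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

angdiff <- function(a, b) atan2(sin(a - b), cos(a - b))

# smooth speed profile: clamped random walk inside [lo, hi]
smooth_speeds <- function(n, range) {
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) return(rep(lo, n))
  s <- numeric(n)
  s[1] <- stats::runif(1, lo, hi)
  step <- (hi - lo) * 0.08
  for (t in seq_len(n - 1))
    s[t + 1] <- min(hi, max(lo, s[t] + stats::rnorm(1, 0, step)))
  s
}

# random smooth path with wall-avoiding steering; returns x, y, heading
gen_path <- function(n, speeds, cfg, margin = 70, turn_sd = 0.05,
                     steer_gain = 0.25, steer_max = Inf,
                     start = NULL, heading0 = NULL) {
  W <- cfg$arena_w; H <- cfg$arena_h
  if (is.null(start))
    start <- c(stats::runif(1, margin + 60, W - margin - 60),
               stats::runif(1, margin + 50, H - margin - 50))
  if (is.null(heading0)) heading0 <- stats::runif(1, 0, 2 * pi)
  x <- numeric(n); y <- numeric(n); h <- numeric(n)
  x[1] <- start[1]; y[1] <- start[2]; h[1] <- heading0
  for (t in seq_len(n - 1)) {
    steer <- 0
    if (x[t] < margin || x[t] > W - margin ||
        y[t] < margin || y[t] > H - margin) {
      to_center <- atan2(H / 2 - y[t], W / 2 - x[t])
      steer <- steer_gain * angdiff(to_center, h[t])
      steer <- sign(steer) * min(abs(steer), steer_max)
    }
    h[t + 1] <- h[t] + stats::rnorm(1, 0, turn_sd) + steer
    step <- speeds[t] / cfg$fps
    x[t + 1] <- x[t] + step * cos(h[t + 1])
    y[t + 1] <- y[t] + step * sin(h[t + 1])
  }
  list(x = x, y = y, heading = h)
}

# piecewise-linear approach/depart profile: extra separation beyond the
# in-contact value during the pad frames at both ends
pad_profile <- function(n, n_pad, extra) {
  prof <- numeric(n)
  if (n_pad > 0) {
    ramp <- seq(extra, 0, length.out = n_pad + 1)[seq_len(n_pad)]
    prof[seq_len(n_pad)] <- ramp
    prof[n - seq_len(n_pad) + 1] <- ramp
  }
  prof
}

# lunge displacement series for one knocking pig
burst_series <- function(n, cfg) {
  d <- numeric(n)
  t <- 1L
  while (t <= n) {
    if (stats::runif(1) < cfg$knock_burst_prob) {
      amp <- stats::runif(1, cfg$knock_burst_px[1], cfg$knock_burst_px[2])
      nf <- sample(cfg$knock_burst_frames, 1)
      nr <- sample(cfg$knock_recoil_frames, 1)
      shape <- c(seq(0, amp, length.out = nf + 1)[-1],
                 seq(amp, 0, length.out = nr + 1)[-1])
      len <- min(length(shape), n - t)
      d[t + seq_len(len)] <- shape[seq_len(len)]
      t <- t + len + 1L
    } else t <- t + 1L
  }
  d
}

# behavior kinematics: ground-truth barycenter paths for each pig.
# Returns list(pigs = list of (x, y, heading, posture), n)
behavior_paths <- function(behavior, cfg, n_contact, n_pad) {
  n <- n_contact + 2L * n_pad
  extra <- pad_profile(n, n_pad, cfg$approach_extra_px)
  if (behavior == "rest") {
    cx <- stats::runif(1, 180, cfg$arena_w - 180)
    cy <- stats::runif(1, 150, cfg$arena_h - 150)
    th <- stats::runif(1, 0, 2 * pi)
    off <- 75
    p1 <- list(x = rep(cx - off * cos(th), n), y = rep(cy - off * sin(th), n),
               heading = rep(th, n), posture = "lying")
    p2 <- list(x = rep(cx + off * cos(th), n), y = rep(cy + off * sin(th), n),
               heading = rep(th + pi, n), posture = "lying")
    return(list(pigs = list(p1, p2), n = n))
  }
  if (behavior == "walk_alone") {
    sp <- smooth_speeds(n, cfg$walk_speed)
    p <- gen_path(n, sp, cfg)
    p$posture <- "standing"
    return(list(pigs = list(p), n = n))
  }
  if (behavior == "walk_together") {
    sp <- smooth_speeds(n, cfg$walk_speed)
    sep <- cfg$walk_sep + extra
    # steer the shared path with room for the lateral pair offset
    base <- gen_path(n, sp, cfg, margin = 70 + max(sep) / 2)
    orth <- base$heading[1] + pi / 2        # fixed offset axis: parallel paths
    p1 <- list(x = base$x + cos(orth) * sep / 2,
               y = base$y + sin(orth) * sep / 2,
               heading = base$heading, posture = "standing")
    p2 <- list(x = base$x - cos(orth) * sep / 2,
               y = base$y - sin(orth) * sep / 2,
               heading = base$heading, posture = "standing")
    return(list(pigs = list(p1, p2), n = n))
  }
  if (behavior == "knocking") {
    sp <- smooth_speeds(n, c(0, cfg$knock_drift_speed))
    mid <- gen_path(n, sp, cfg, turn_sd = 0.02, margin = 120)
    phi <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(n, 0, 0.004))
    d1 <- burst_series(n, cfg)
    d2 <- burst_series(n, cfg)
    half <- (cfg$knock_gap + extra) / 2
    p1 <- list(x = mid$x - cos(phi) * (half - d1),
               y = mid$y - sin(phi) * (half - d1),
               heading = phi, posture = "standing")
    p2 <- list(x = mid$x + cos(phi) * (half - d2),
               y = mid$y + sin(phi) * (half - d2),
               heading = phi + pi, posture = "standing")
    return(list(pigs = list(p1, p2), n = n))
  }
  if (behavior == "chasing") {
    # leader path long enough that the pursuer's delayed arc position exists
    gap <- cfg$chase_gap + extra
    n_pre <- ceiling(max(gap) / (cfg$chase_speed[1] / cfg$fps)) + 5L
    # gentle turns: a tight curve would shorten the chord between pursuer
    # and leader below body length and force the blobs to merge
    sp <- smooth_speeds(n + n_pre, cfg$chase_speed)
    path <- gen_path(n + n_pre, sp, cfg, margin = 120, turn_sd = 0.02,
                     steer_gain = 0.15, steer_max = 0.08)
    arc <- c(0, cumsum(sqrt(diff(path$x)^2 + diff(path$y)^2)))
    idx <- n_pre + seq_len(n)
    s_target <- arc[idx] - gap
    fx <- stats::approx(arc, path$x, xout = s_target, rule = 2)$y
    fy <- stats::approx(arc, path$y, xout = s_target, rule = 2)$y
    fh <- stats::approx(arc, path$heading, xout = s_target, rule = 2)$y
    leader <- list(x = path$x[idx], y = path$y[idx],
                   heading = path$heading[idx], posture = "standing")
    follower <- list(x = fx, y = fy, heading = fh, posture = "standing")
    return(list(pigs = list(follower, leader), n = n))
  }
  stop("unknown behavior: ", behavior, call. = FALSE)
}

# paint one frame: flat floor, elliptical pig bodies, sensor noise, dropout
render_frame <- function(pigs, t, cfg) {
  H <- cfg$arena_h; W <- cfg$arena_w
  depth <- matrix(cfg$floor_depth_mm, H, W)
  a <- cfg$pig_semi_major; b <- cfg$pig_semi_minor
  pad <- ceiling(a) + 1L
  for (p in pigs) {
    cx <- p$x[t]; cy <- p$y[t]; th <- p$heading[t]
    height <- if (p$posture == "standing") cfg$standing_height_mm
              else cfg$lying_height_mm
    rows <- max(1L, floor(cy - pad)):min(H, ceiling(cy + pad))
    cols <- max(1L, floor(cx - pad)):min(W, ceiling(cx + pad))
    if (!length(rows) || !length(cols)) next
    dy <- rows - cy; dx <- cols - cx
    u <- outer(dy, dx, function(yy, xx) xx * cos(th) + yy * sin(th))
    v <- outer(dy, dx, function(yy, xx) -xx * sin(th) + yy * cos(th))
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- depth[rows, cols]
    sub[inside] <- cfg$floor_depth_mm - height
    depth[rows, cols] <- sub
  }
  depth <- depth + stats::rnorm(H * W) * cfg$noise_sd_mm
  if (cfg$dropout_frac > 0) {
    ndrop <- round(cfg$dropout_frac * H * W)
    depth[sample.int(H * W, ndrop)] <- 0
  }
  depth <- round(depth)
  depth[depth < 0] <- 0
  storage.mode(depth) <- "integer"
  depth
}

#' Simulate one behavior episode
#'
#' Generates ground-truth barycenter paths for the requested behavior,
#' optionally renders them to depth frames, and derives the true contact
#' interval (frames where the designed inter-pig distance is at most
#' `contact_dist_px`). Behaviors: `rest` (two lying pigs, no motion),
#' `walk_alone` (one standing pig), `walk_together` (two standing pigs on
#' parallel paths at stable moderate separation - a normal interaction),
#' `knocking` (two facing pigs trading short high-amplitude lunges) and
#' `chasing` (one pig pursuing another at high sustained speed and small
#' gap). Paths straying outside the arena are clipped with a warning.
#'
#' @param behavior One of `"rest"`, `"walk_alone"`, `"walk_together"`,
#'   `"knocking"`, `"chasing"`.
#' @param config A [sim_config].
#' @param seed Integer seed; the same seed reproduces the episode exactly.
#' @param render Render depth frames (`TRUE`) or return ground truth only
#'   (`FALSE`, much faster, for kinematics-level work).
#' @return List with `behavior`, `frames` (list of [depth_frame] or NULL),
#'   `meta` ([sequence_meta]), and `truth`: `tracks` (data frame pig,
#'   frame, row, col, posture) and `episodes` (data frame label,
#'   start_frame, end_frame; empty for non-contact behaviors).
#' @export
simulate_episode <- function(behavior, config = sim_config(), seed = 1,
                             render = TRUE) {
  with_seed(seed, {
    n_contact <- round(stats::runif(1, config$contact_s[1],
                                    config$contact_s[2]) * config$fps)
    n_pad <- round(config$pad_s * config$fps)
    bp <- behavior_paths(behavior, config, n_contact, n_pad)
    n <- bp$n

    # clip to arena (steering should prevent this; warn if it fires)
    a <- config$pig_semi_major
    clipped <- FALSE
    bp$pigs <- lapply(bp$pigs, function(p) {
      xc <- pmin(pmax(p$x, a + 1), config$arena_w - a - 1)
      yc <- pmin(pmax(p$y, a + 1), config$arena_h - a - 1)
      if (any(xc != p$x | yc != p$y)) clipped <<- TRUE
      p$x <- xc; p$y <- yc
      p
    })
    if (clipped) warning("path left the arena and was clipped")

    truth_tracks <- do.call(rbind, lapply(seq_along(bp$pigs), function(i) {
      p <- bp$pigs[[i]]
      data.frame(pig = i, frame = seq_len(n) - 1L, row = p$y, col = p$x,
                 posture = p$posture)
    }))

    truth_eps <- data.frame(label = character(), start_frame = integer(),
                            end_frame = integer())
    if (length(bp$pigs) == 2 && bp$pigs[[1]]$posture == "standing") {
      d <- sqrt((bp$pigs[[1]]$x - bp$pigs[[2]]$x)^2 +
                (bp$pigs[[1]]$y - bp$pigs[[2]]$y)^2)
      inc <- which(d <= config$contact_dist_px)
      if (length(inc)) {
        lab <- switch(behavior, walk_together = "normal",
                      knocking = "knocking", chasing = "chasing", "normal")
        truth_eps <- data.frame(label = lab,
                                start_frame = min(inc) - 1L,
                                end_frame = max(inc) - 1L)
      }
    }

    meta <- sequence_meta(fps = config$fps, depth_scale = 1,
                          floor_depth_mm = config$floor_depth_mm)
    frames <- NULL
    if (render)
      frames <- lapply(seq_len(n), function(t)
        depth_frame(render_frame(bp$pigs, t, config), index = t - 1L))

    list(behavior = behavior, frames = frames, meta = meta,
         truth = list(tracks = truth_tracks, episodes = truth_eps))
  })
}

#' Generate a labelled corpus of simulated episodes
#'
#' Emits `counts` episodes per class (normal episodes are simulated as
#' `walk_together`), each with its own seed derived deterministically from
#' the master seed, so two corpora built from the same configuration are
#' identical.
#'
#' @param config A [sim_config]; `config$counts` and `config$seed` control
#'   composition and reproducibility.
#' @param render Render depth frames per episode (see [simulate_episode]).
#' @param dir Optional directory: when given, each episode's frames are
#'   written via [write_depth_sequence] under `dir/ep_NNNN/` and
#'   `ground_truth_tracks.csv` / `ground_truth_episodes.csv` are written at
#'   the top level.
#' @param progress Print a dot every 25 episodes.
#' @return List of episodes (as from [simulate_episode], each with an extra
#'   `episode` index) plus attribute `labels`: data frame (episode, label,
#'   seed).
#' @export
generate_corpus <- function(config = sim_config(), render = TRUE,
                            dir = NULL, progress = FALSE) {
  counts <- config$counts
  stopifnot(all(counts >= 1))
  behaviors <- rep(names(counts), counts)
  behaviors[behaviors == "normal"] <- "walk_together"
  n <- length(behaviors)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ep <- simulate_episode(behaviors[i], config, seed = seeds[i],
                           render = render)
    ep$episode <- i
    out[[i]] <- ep
    if (!is.null(dir) && render) {
      write_depth_sequence(ep$frames, ep$meta,
                           file.path(dir, sprintf("ep_%04d", i)))
    }
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  labels <- data.frame(
    episode = seq_len(n),
    label = vapply(out, function(e)
      if (nrow(e$truth$episodes)) e$truth$episodes$label[1]
      else NA_character_, character(1)),
    seed = seeds)
  if (!is.null(dir)) {
    tr <- do.call(rbind, lapply(out, function(e)
      cbind(episode = e$episode, e$truth$tracks)))
    eps <- do.call(rbind, lapply(out, function(e)
      if (nrow(e$truth$episodes)) cbind(episode = e$episode,
                                        e$truth$episodes) else NULL))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tr, file.path(dir, "ground_truth_tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(eps, file.path(dir, "ground_truth_episodes.csv"),
                     row.names = FALSE)
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  attr(out, "labels") <- labels
  out
}
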