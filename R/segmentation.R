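# Standing-pig segmentation: height-above-floor thresholding of a top-view
# depth frame, 8-connected component labelling, and per-region statistics.

#' Convert a depth frame to a height-above-floor map
#'
#' Heights are `floor_depth_mm - depth` clipped below at 0; dropout pixels
#' (depth 0, i.e. no sensor return) map to height 0 so they never enter a
#' segmented region.
#'
#' @param frame A [depth_frame].
#' @param meta A [sequence_meta] carrying `floor_depth_mm`.
#' @return Numeric matrix of heights in mm, same dimensions as the frame.
#' @export
height_map <- function(frame, meta) {
  h <- meta$floor_depth_mm - frame$values
  h[h < 0] <- 0
  h[frame$values == 0] <- 0
  h
}

#' Segment standing pigs from a height map
#'
#' Thresholds the height map at `standing_mm` and labels the 8-connected
#' components of the resulting mask; components smaller than `min_area_px`
#' pixels are discarded as noise. Each surviving region carries its pixel
#' set, barycenter (arithmetic mean of pixel coordinates), minimum
#' circumscribed rectangle (tight axis-aligned bounding box), area, median
#' height and posture. Because lying animals fall below the standing
#' threshold they are excluded here and never reach tracking.
#'
#' @param heights Height matrix from [height_map] (mm).
#' @param standing_mm Height threshold separating standing from lying
#'   animals; default 250 mm.
#' @param min_area_px Minimum component area in pixels; default 100.
#' @return List of `pig_region` objects, each with fields `pixels` (n x 2
#'   matrix of row, col), `barycenter` (row, col), `rect`
#'   (min_row, min_col, max_row, max_col), `area`, `median_height_mm`,
#'   `posture`.
#' @export
segment_pigs <- function(heights, standing_mm = 250, min_area_px = 100) {
  stopifnot(standing_mm > 0, min_area_px >= 1)
  mask <- heights >= standing_mm
  on <- which(mask)
  if (length(on) == 0) return(list())
  # label only the bounding box of foreground pixels (frames are mostly floor)
  nr_full <- nrow(heights)
  on_r <- (on - 1L) %% nr_full + 1L
  on_c <- (on - 1L) %/% nr_full + 1L
  r0 <- min(on_r); r1 <- max(on_r); c0 <- min(on_c); c1 <- max(on_c)
  lab <- label_components8(mask[r0:r1, c0:c1, drop = FALSE])
  idx_sub <- which(lab > 0L)
  labs <- lab[idx_sub]
  nr <- r1 - r0 + 1L
  rows <- (idx_sub - 1L) %% nr + r0
  cols <- (idx_sub - 1L) %/% nr + c0
  idx <- (cols - 1L) * nr_full + rows
  regions <- list()
  for (l in sort(unique(labs))) {
    sel <- labs == l
    if (sum(sel) < min_area_px) next
    r <- rows[sel]; c <- cols[sel]
    med_h <- stats::median(heights[idx[sel]])
    regions[[length(regions) + 1L]] <- structure(
      list(pixels = cbind(row = r, col = c),
           barycenter = c(row = mean(r), col = mean(c)),
           rect = c(min_row = min(r), min_col = min(c),
                    max_row = max(r), max_col = max(c)),
           area = length(r),
           median_height_mm = med_h,
           posture = classify_posture(med_h, standing_mm)),
      class = "pig_region")
  }
  regions
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally get distinct labels; a union-find pass over the four
# diagonal neighbour shifts merges them exactly.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2) return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  shifts <- list(c(1, 1), c(1, -1))  # down-right, down-left cover all diagonals
  for (s in shifts) {
    r0 <- max(1, 1 + s[1]):min(nr, nr + s[1])
    a <- lab[r0 - s[1], , drop = FALSE]
    b <- lab[r0, , drop = FALSE]
    if (s[2] > 0) { a <- a[, -nc, drop = FALSE]; b <- b[, -1, drop = FALSE] }
    else          { a <- a[, -1, drop = FALSE];  b <- b[, -nc, drop = FALSE] }
    hit <- which(a > 0 & b > 0 & a != b)
    for (k in hit) union_(a[k], b[k])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

#' Classify posture from region height
#'
#' A region is standing when its median height above the floor reaches the
#' standing threshold (inclusive), lying otherwise.
#'
#' @param median_height_mm Median height of the region in mm.
#' @param standing_mm Standing threshold in mm.
#' @return `"standing"` or `"lying"`.
#' @export
classify_posture <- function(median_height_mm, standing_mm = 250) {
  if (median_height_mm >= standing_mm) "standing" else "lying"
}

#' Tabulate segmented regions
#'
#' @param regions List of regions from [segment_pigs].
#' @param frame_index Frame ordinal recorded in the output.
#' @return Data frame with one row per region: frame, region_id, barycenter
#'   and rectangle coordinates, area, median height and posture.
#' @export
regions_to_df <- function(regions, frame_index = 0L) {
  if (length(regions) == 0)
    return(data.frame(frame = integer(), region_id = integer(),
                      barycenter_row = numeric(), barycenter_col = numeric(),
                      min_row = integer(), min_col = integer(),
                      max_row = integer(), max_col = integer(),
                      area = integer(), median_height_mm = numeric(),
                      posture = character()))
  do.call(rbind, lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    data.frame(frame = as.integer(frame_index), region_id = i,
               barycenter_row = r$barycenter[["row"]],
               barycenter_col = r$barycenter[["col"]],
               min_row = r$rect[["min_row"]], min_col = r$rect[["min_col"]],
               max_row = r$rect[["max_row"]], max_col = r$rect[["max_col"]],
               area = r$area, median_height_mm = r$median_height_mm,
               posture = r$posture)
  }))
}
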