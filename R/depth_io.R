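# Depth-frame sequence I/O: 16-bit binary PGM (P5) frames plus a JSON
# metadata sidecar. This is the pipeline's only contact with on-disk imagery.

#' Construct a depth frame
#'
#' A depth frame holds one top-view depth image as a numeric matrix of
#' camera-to-surface distances in millimetres. A value of 0 encodes "no
#' reading" (sensor shadow or dropout); every downstream operation ignores
#' zero-valued pixels.
#'
#' @param values Numeric matrix (rows x cols) of depth readings in mm, all
#'   values >= 0.
#' @param index 0-based frame ordinal within its sequence.
#' @return An object of class `depth_frame` with fields `values`, `index`,
#'   `width` (columns) and `height` (rows).
#' @export
depth_frame <- function(values, index = 0L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (any(values < 0))
    stop("depth values must be >= 0", call. = FALSE)
  structure(
    list(values = values, index = as.integer(index),
         width = ncol(values), height = nrow(values)),
    class = "depth_frame"
  )
}

#' Construct sequence metadata
#'
#' @param fps Frames per second of the recording (> 0).
#' @param depth_scale Millimetres per stored file unit (> 0). Stored pixel
#'   values are multiplied by this on read.
#' @param floor_depth_mm Camera-to-floor distance in mm (> 0); heights above
#'   the floor are computed against this reference.
#' @param px_per_cm Optional ground-plane scale (pixels per centimetre); when
#'   present, speeds and distances can be reported in cm.
#' @return An object of class `sequence_meta`.
#' @export
sequence_meta <- function(fps = 30, depth_scale = 1, floor_depth_mm = 2500,
                          px_per_cm = NULL) {
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (depth_scale <= 0) stop("depth_scale must be > 0", call. = FALSE)
  if (floor_depth_mm <= 0) stop("floor_depth_mm must be > 0", call. = FALSE)
  if (!is.null(px_per_cm) && px_per_cm <= 0)
    stop("px_per_cm must be > 0 when given", call. = FALSE)
  structure(
    list(fps = fps, depth_scale = depth_scale,
         floor_depth_mm = floor_depth_mm, px_per_cm = px_per_cm),
    class = "sequence_meta"
  )
}

# -- raw PGM (P5, 16-bit, big-endian) ----------------------------------------

write_pgm16 <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(values), nrow(values)), "65535"), con)
  # PGM is row-major; R matrices are column-major
  writeBin(as.integer(round(t(values))), con, size = 2, endian = "big")
  invisible(path)
}

read_pgm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "P5"))
    stop("not a binary PGM (P5) file: ", path, call. = FALSE)
  # header tokens may be split across lines; comments start with '#'
  tokens <- character(0)
  while (length(tokens) < 3) {
    line <- readLines(con, n = 1)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
  }
  dims <- as.integer(tokens[1:3])
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  if (maxval > 65535) stop("PGM maxval exceeds 16 bits: ", path, call. = FALSE)
  size <- if (maxval > 255) 2L else 1L
  raw <- readBin(con, "integer", n = w * h, size = size,
                 signed = FALSE, endian = "big")
  if (length(raw) != w * h)
    stop("truncated PGM payload: ", path, call. = FALSE)
  matrix(raw, nrow = h, ncol = w, byrow = TRUE)
}

# -- sequence read/write -----------------------------------------------------

#' Write a depth-frame sequence to a directory
#'
#' Frames are written as zero-padded `frame_NNNNNN.pgm` files (16-bit binary
#' PGM) whose filenames define the replay order, alongside a `meta.json`
#' sidecar with keys `fps`, `depth_scale`, `floor_depth_mm` and (optionally)
#' `px_per_cm`. Values are divided by `depth_scale` before storage; any value
#' that does not fit in 16 bits after scaling is an error.
#'
#' @param frames List of [depth_frame] objects with identical dimensions.
#' @param meta A [sequence_meta].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_depth_sequence <- function(frames, meta, path) {
  stopifnot(length(frames) >= 1)
  dims <- vapply(frames, function(f) c(f$height, f$width), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    stored <- frames[[i]]$values / meta$depth_scale
    if (any(stored > 65535))
      stop("depth value exceeds 16-bit range after scaling", call. = FALSE)
    write_pgm16(stored, file.path(path, sprintf("frame_%06d.pgm", i - 1L)))
  }
  side <- list(fps = meta$fps, depth_scale = meta$depth_scale,
               floor_depth_mm = meta$floor_depth_mm)
  if (!is.null(meta$px_per_cm)) side$px_per_cm <- meta$px_per_cm
  jsonlite::write_json(side, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a depth-frame sequence from a directory
#'
#' Reads every `*.pgm` frame (sorted by filename, which defines the frame
#' ordinal) and the `meta.json` sidecar; stored units are converted to
#' millimetres via `depth_scale`.
#'
#' @param path Directory written by [write_depth_sequence] (or following the
#'   same layout).
#' @return A list with elements `frames` (list of [depth_frame]) and
#'   `meta` ([sequence_meta]).
#' @export
read_depth_sequence <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("missing meta.json sidecar in ", path, call. = FALSE)
  side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("fps", "depth_scale", "floor_depth_mm"))
    if (is.null(side[[key]]))
      stop("meta.json lacks required key: ", key, call. = FALSE)
  meta <- sequence_meta(side$fps, side$depth_scale, side$floor_depth_mm,
                        side$px_per_cm)
  files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0)
    stop("no .pgm frames found in ", path, call. = FALSE)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    vals <- read_pgm16(files[i]) * meta$depth_scale
    frames[[i]] <- depth_frame(vals, index = i - 1L)
    if (i > 1 && (frames[[i]]$width != frames[[1]]$width ||
                  frames[[i]]$height != frames[[1]]$height))
      stop("inconsistent frame dimensions in sequence", call. = FALSE)
  }
  list(frames = frames, meta = meta)
}
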