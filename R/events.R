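# Event-stream input/output and conversion to frame sequences.
#
# Events are address-event records (x, y, t, p) from a dynamic vision
# sensor: pixel coordinates (0-based, x = column, y = row), a timestamp in
# microseconds and an ON/OFF polarity. Streams are ordinary tibbles with
# sensor geometry attached, so all dplyr verbs apply.

#' Construct an event stream
#'
#' @param x,y Integer pixel coordinates, 0-based (`0 <= x < width`,
#'   `0 <= y < height`; `x` is the column, `y` the row).
#' @param t Numeric timestamps in microseconds, sorted on construction.
#' @param p Polarity: `"ON"`/`"OFF"` (or 1/0, TRUE/FALSE).
#' @param width,height Sensor size in pixels.
#' @param duration Stream duration in microseconds; defaults to the final
#'   timestamp.
#' @return A tibble of class `event_stream` with columns `x`, `y`, `t`, `p`
#'   and attributes `width`, `height`, `duration`.
#' @examples
#' ev <- event_stream(x = c(0, 1), y = c(0, 0), t = c(10, 20), p = c("ON", "OFF"),
#'                    width = 2, height = 1)
#' events_to_frames(ev, n_frames = 2, mode = "sum")
#' @export
event_stream <- function(x, y, t, p, width, height, duration = NULL) {
  t <- as.numeric(t)
  n <- length(t)
  x <- rep_len(as.integer(x), n)
  y <- rep_len(as.integer(y), n)
  p <- normalize_polarity(p)
  p <- p[rep_len(seq_along(p), n)]
  if (length(x) && (any(x < 0L) || any(x >= width)))
    stop("x out of range [0, width)")
  if (length(y) && (any(y < 0L) || any(y >= height)))
    stop("y out of range [0, height)")
  ord <- order(t)
  out <- tibble::tibble(x = x[ord], y = y[ord], t = t[ord], p = p[ord])
  attr(out, "width") <- as.integer(width)
  attr(out, "height") <- as.integer(height)
  attr(out, "duration") <-
    if (is.null(duration)) (if (nrow(out)) max(out$t) else 0) else as.numeric(duration)
  class(out) <- c("event_stream", class(out))
  out
}

normalize_polarity <- function(p) {
  if (is.factor(p)) p <- as.character(p)
  if (is.logical(p)) p <- ifelse(p, "ON", "OFF")
  if (is.numeric(p)) p <- ifelse(p > 0, "ON", "OFF")
  p <- toupper(p)
  if (length(p) && !all(p %in% c("ON", "OFF")))
    stop("polarity must map to ON/OFF")
  factor(p, levels = c("ON", "OFF"))
}

#' Read / write event streams
#'
#' Native dialects: `"csv"` (plain text, header `x,y,t,p`), `"rds"` (R
#' serialized stream) and `"packed40"`, a 40-bit packed binary record layout
#' common for event-camera exports: per event five bytes
#' `[x | y | p<<7 + t22..16 | t15..8 | t7..0]` with a 23-bit microsecond
#' timestamp.
#'
#' @param path File path.
#' @param dialect One of `"csv"`, `"rds"`, `"packed40"`.
#' @param width,height Sensor size (required for `csv`/`packed40`, which do
#'   not carry geometry).
#' @param duration Optional stream duration in microseconds.
#' @return `read_events()` returns an [event_stream()]; `write_events()`
#'   returns `path` invisibly.
#' @export
read_events <- function(path, dialect = c("csv", "rds", "packed40"),
                        width = NULL, height = NULL, duration = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "rds") {
    out <- readRDS(path)
    if (!inherits(out, "event_stream")) stop("not an event_stream rds: ", path)
    return(out)
  }
  if (dialect == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(
      x = readr::col_integer(), y = readr::col_integer(),
      t = readr::col_double(), p = readr::col_character()))
    if (!all(c("x", "y", "t", "p") %in% names(df)))
      stop("malformed CSV event file (need header x,y,t,p): ", path)
    if (is.null(width) || is.null(height))
      stop("width and height are required for the csv dialect")
    return(event_stream(df$x, df$y, df$t, df$p, width, height, duration))
  }
  # packed40
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) %% 5L != 0L)
    stop("malformed packed40 file (size not a multiple of 5 bytes) at byte ",
         length(raw))
  n <- length(raw) %/% 5L
  m <- matrix(as.integer(raw), nrow = 5L)
  x <- m[1, ]; y <- m[2, ]
  p <- ifelse(bitwAnd(m[3, ], 128L) > 0L, "ON", "OFF")
  t <- bitwAnd(m[3, ], 127L) * 65536 + m[4, ] * 256 + m[5, ]
  if (is.null(width) || is.null(height))
    stop("width and height are required for the packed40 dialect")
  event_stream(x, y, t, p, width, height, duration)
}

#' @rdname read_events
#' @param stream An [event_stream()].
#' @export
write_events <- function(stream, path, dialect = c("csv", "rds", "packed40")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(stream, "event_stream"))
  if (dialect == "rds") { saveRDS(stream, path); return(invisible(path)) }
  if (dialect == "csv") {
    readr::write_csv(tibble::tibble(x = stream$x, y = stream$y, t = stream$t,
                                    p = as.character(stream$p)), path)
    return(invisible(path))
  }
  t <- round(stream$t)
  if (length(t) && max(t) >= 2^23)
    stop("packed40 supports 23-bit timestamps (< 8388608 us)")
  pbit <- ifelse(stream$p == "ON", 128L, 0L)
  b3 <- pbit + (t %/% 65536)
  b4 <- (t %/% 256) %% 256
  b5 <- t %% 256
  bytes <- as.raw(rbind(stream$x, stream$y, b3, b4, b5))
  writeBin(bytes, path)
  invisible(path)
}

#' Cut an event stream at a fixed duration
#'
#' Explicitly drops all events with `t > t_max` and sets the stream duration
#' to `t_max`, e.g. keeping only the first part of each recording before
#' frame binning. Dropping is deliberate and reported via a message.
#'
#' @param stream An [event_stream()].
#' @param t_max Cut time in microseconds.
#' @return An [event_stream()] of duration `t_max`.
#' @export
cut_events <- function(stream, t_max) {
  stopifnot(inherits(stream, "event_stream"), t_max > 0)
  keep <- stream$t <= t_max
  if (any(!keep))
    message(sum(!keep), " events beyond ", t_max, " us dropped by cut")
  event_stream(stream$x[keep], stream$y[keep], stream$t[keep],
               stream$p[keep], attr(stream, "width"), attr(stream, "height"),
               duration = t_max)
}

#' Construct a frame sequence
#'
#' A frame sequence is an `N x C x H x W` array of non-negative values: `N`
#' frames, `C` channels (two per stacked source frame: ON then OFF), spatial
#' size `H x W`, with the frame interval `T_F` (ms) attached.
#'
#' @param data Numeric array with `dim = c(N, C, H, W)`.
#' @param t_f Frame interval in milliseconds.
#' @return An array of class `frame_sequence`.
#' @export
frame_sequence <- function(data, t_f) {
  stopifnot(is.array(data), length(dim(data)) == 4, all(data >= 0))
  structure(data, t_f = as.numeric(t_f), class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_sequence> %d frames x %d channels x %dx%d, T_F = %.4g ms\n",
              d[1], d[2], d[3], d[4], attr(x, "t_f")))
  invisible(x)
}

#' Bin an event stream into input frames
#'
#' Divides the stream duration into `n_frames` equal intervals of length
#' `T_F = duration / N` and accumulates ON and OFF events into two separate
#' channels per frame. Intervals are half-open `[k*T_F, (k+1)*T_F)` with the
#' final interval closed so the last event is kept. `mode = "sum"` yields
#' event counts; `mode = "average"` yields rates in events per millisecond
#' (counts divided by `T_F` in ms).
#'
#' @param stream An [event_stream()].
#' @param n_frames Number of frames `N` (>= 1).
#' @param mode `"average"` (default) or `"sum"`.
#' @return A [frame_sequence()] with `dim = c(N, 2, H, W)` and `T_F` in ms.
#' @examples
#' ev <- gen_random_events(8, 8, rate = 1e-4, duration = 1e5, seed = 1)
#' fr <- events_to_frames(ev, 16)
#' attr(fr, "t_f") # 100 ms / 16 = 6.25 ms
#' @export
events_to_frames <- function(stream, n_frames, mode = c("average", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stream, "event_stream"), n_frames >= 1)
  n_frames <- as.integer(n_frames)
  H <- attr(stream, "height"); W <- attr(stream, "width")
  dur <- attr(stream, "duration")
  out <- array(0, dim = c(n_frames, 2L, H, W))
  if (nrow(stream) && dur > 0) {
    t_f_us <- dur / n_frames
    bin <- pmin(floor(stream$t / t_f_us) + 1L, n_frames)
    chan <- ifelse(stream$p == "ON", 1L, 2L)
    # column-major linear index into (N, 2, H, W)
    idx <- bin + (chan - 1L) * n_frames +
      stream$y * (n_frames * 2L) + stream$x * (n_frames * 2L * H)
    counts <- tabulate(idx, nbins = length(out))
    out[] <- counts
    if (mode == "average") out <- out / (t_f_us / 1000)
  }
  t_f_ms <- if (dur > 0) dur / n_frames / 1000 else 0
  frame_sequence(out, t_f = t_f_ms)
}

# 1-D bilinear interpolation matrix mapping `n_src` samples to `n_dst`,
# pixel centers aligned; rows sum to one so constants are preserved.
bilinear_matrix <- function(n_dst, n_src) {
  pos <- (seq_len(n_dst) - 0.5) * n_src / n_dst + 0.5
  pos <- pmin(pmax(pos, 1), n_src)
  lo <- pmin(floor(pos), n_src - ifelse(n_src > 1, 1, 0))
  lo <- pmax(lo, 1)
  hi <- pmin(lo + 1, n_src)
  w_hi <- ifelse(hi > lo, pos - lo, 0)
  m <- matrix(0, n_dst, n_src)
  m[cbind(seq_len(n_dst), lo)] <- 1 - w_hi
  m[cbind(seq_len(n_dst), hi)] <- m[cbind(seq_len(n_dst), hi)] + w_hi
  m
}

#' Downscale a frame sequence by bilinear interpolation
#'
#' Resamples every frame and channel to `height x width` with
#' center-aligned bilinear interpolation. Interpolation weights are convex,
#' so non-negativity and constants are preserved. Upscaling is permitted but
#' flagged with a warning.
#'
#' @param frames A [frame_sequence()].
#' @param height,width Target spatial size (>= 1).
#' @return A [frame_sequence()] with the new spatial size.
#' @export
downscale <- function(frames, height, width) {
  stopifnot(inherits(frames, "frame_sequence"), height >= 1, width >= 1)
  d <- dim(frames)
  if (height > d[3] || width > d[4])
    warning("target larger than source: upscaling by bilinear interpolation")
  Rh <- bilinear_matrix(height, d[3])
  Rw <- bilinear_matrix(width, d[4])
  out <- array(0, dim = c(d[1], d[2], height, width))
  for (n in seq_len(d[1])) for (c in seq_len(d[2])) {
    img <- matrix(frames[n, c, , ], d[3], d[4])
    out[n, c, , ] <- Rh %*% img %*% t(Rw)
  }
  frame_sequence(out, t_f = attr(frames, "t_f"))
}

#' Normalize frame values to a fixed range
#'
#' Divides all frame values by `scale` (default: the maximum over the
#' sequence, so values land in `[0, 1]`). When preparing a dataset, pass
#' the maximum over the *training* set as `scale` to every split so train
#' and test share one scale. Returns the scale used as attribute `scale`.
#'
#' @param frames A [frame_sequence()].
#' @param scale Positive divisor; default `max(frames)` (1 if all zero).
#' @return A [frame_sequence()] with values divided by `scale`.
#' @export
normalize_frames <- function(frames, scale = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (is.null(scale)) scale <- max(max(frames), 1e-12)
  stopifnot(scale > 0)
  out <- frame_sequence(frames / scale, t_f = attr(frames, "t_f"))
  attr(out, "scale") <- scale
  out
}

#' Stack consecutive frames into multi-channel inputs
#'
#' Groups `s` consecutive frames into one input of `s * C` channels,
#' enabling temporal integration over longer horizons without motion blur in
#' the individual frames. The channel order is frame-within-stack major,
#' polarity minor: output channel `(f - 1) * C + c` holds source frame `f`
#' of the stack, channel `c`. If `N` is not divisible by `s` the trailing
#' remainder frames are truncated (reported via a message).
#'
#' @param frames A [frame_sequence()] with `N` frames and `C` channels.
#' @param s Stack size (>= 1).
#' @return A [frame_sequence()] with `N %/% s` frames, `s * C` channels and
#'   frame interval `s * T_F`.
#' @examples
#' fr <- frame_sequence(array(0, c(240, 2, 4, 4)), t_f = 6.25)
#' dim(stack_frames(fr, 10)) # 24 frames x 20 channels
#' @export
stack_frames <- function(frames, s) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (s <= 0) stop("stack size must be positive")
  s <- as.integer(s)
  if (s == 1L) return(frames)
  d <- dim(frames)
  n_out <- d[1] %/% s
  if (n_out < 1L) stop("fewer frames than stack size")
  if (d[1] %% s != 0L)
    message(d[1] %% s, " trailing frames truncated by stacking")
  out <- array(0, dim = c(n_out, s * d[2], d[3], d[4]))
  for (g in seq_len(n_out)) for (f in seq_len(s)) {
    src <- (g - 1L) * s + f
    out[g, ((f - 1L) * d[2] + 1L):(f * d[2]), , ] <- frames[src, , , ]
  }
  frame_sequence(out, t_f = s * attr(frames, "t_f"))
}
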