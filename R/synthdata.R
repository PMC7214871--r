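# Synthetic data generators: the moving-rectangles task, random sparse
# event streams, and small random network fixtures. All generators are
# deterministic under their seed argument.

#' Generate the moving-rectangles dataset
#'
#' Each sample is a pair of binary images containing one rectangle; in the
#' second image the rectangle is shifted horizontally by `shift` pixels,
#' left or right, and the class is the movement direction. No single image
#' is informative - the direction can only be inferred from the sequence -
#' which makes this the minimal temporal-integration task. Each image is
#' repeated `n_repeats` times, giving `2 * n_repeats` input frames per
#' sample (first half image A, second half image B). Rectangles are
#' delivered directly as frames: ON channel holds the pixel intensity, OFF
#' channel is zero.
#'
#' @param n Number of samples; classes are exactly balanced (`n` even
#'   recommended).
#' @param height,width Image size in pixels.
#' @param shift Horizontal shift magnitude in pixels (>= 1).
#' @param size_range Inclusive range of rectangle edge lengths in pixels.
#' @param n_repeats Repeats per image (default 3: six input frames).
#' @param seed Integer seed.
#' @return A list of class `frame_dataset`: `x` an array
#'   `(n, 2 * n_repeats, 2, height, width)`, `y` integer labels (1 = left,
#'   2 = right), `classes = c("left", "right")`, and a `meta` tibble with
#'   the sampled geometry.
#' @examples
#' d <- gen_rectangles(10, seed = 1)
#' table(d$classes[d$y])
#' @export
gen_rectangles <- function(n, height = 16L, width = 16L, shift = 2L,
                           size_range = c(3L, 8L), n_repeats = 3L, seed = 1L) {
  stopifnot(n >= 1, shift >= 1, n_repeats >= 1,
            size_range[1] >= 1, size_range[2] >= size_range[1])
  old <- new_seed_scope(seed); on.exit(restore_seed_scope(old))
  if (size_range[2] + 2L * shift > width || size_range[2] > height)
    stop(sprintf("geometry impossible: %dx%d rectangles shifted by %d do not fit in %dx%d",
                 size_range[2], size_range[2], shift, height, width))
  N <- 2L * n_repeats
  x <- array(0, dim = c(n, N, 2L, height, width))
  y <- rep(c(1L, 2L), length.out = n)[sample.int(n)] # balanced, shuffled
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    s <- if (y[i] == 2L) shift else -shift
    rh <- sample(size_range[1]:size_range[2], 1L)
    rw <- sample(size_range[1]:size_range[2], 1L)
    # the first image's position is drawn from the same range for both
    # classes (room for a shift in either direction), so no single first
    # image carries label information
    x_lo <- 1L + shift
    x_hi <- width - rw + 1L - shift
    if (x_hi < x_lo) stop("geometry impossible for sampled rectangle")
    x0 <- if (x_hi > x_lo) sample(x_lo:x_hi, 1L) else x_lo
    y0 <- if (height > rh) sample(seq_len(height - rh + 1L), 1L) else 1L
    imgA <- matrix(0, height, width)
    imgA[y0:(y0 + rh - 1L), x0:(x0 + rw - 1L)] <- 1
    imgB <- matrix(0, height, width)
    imgB[y0:(y0 + rh - 1L), (x0 + s):(x0 + s + rw - 1L)] <- 1
    for (r in seq_len(n_repeats)) {
      x[i, r, 1L, , ] <- imgA
      x[i, n_repeats + r, 1L, , ] <- imgB
    }
    meta[[i]] <- tibble::tibble(sample = i, label = c("left", "right")[y[i]],
                                x0 = x0, y0 = y0, h = rh, w = rw)
  }
  structure(list(x = x, y = y, classes = c("left", "right"),
                 meta = dplyr::bind_rows(meta)),
            class = "frame_dataset")
}

#' @export
print.frame_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<frame_dataset> %d samples x %d frames x %d channels x %dx%d, %d classes\n",
              d[1], d[2], d[3], d[4], d[5], length(x$classes)))
  invisible(x)
}

#' Generate a random sparse event stream
#'
#' Homogeneous Poisson events: the total event count is Poisson with mean
#' `rate * duration * height * width`, positions and timestamps uniform,
#' polarity ON/OFF with equal probability.
#'
#' @param height,width Sensor size in pixels.
#' @param rate Per-pixel event rate in events per microsecond (ON and OFF
#'   combined).
#' @param duration Stream duration in microseconds.
#' @param seed Integer seed.
#' @return An [event_stream()] with `duration` set explicitly.
#' @export
gen_random_events <- function(height, width, rate, duration, seed = 1L) {
  stopifnot(rate >= 0, duration > 0)
  old <- new_seed_scope(seed); on.exit(restore_seed_scope(old))
  n <- stats::rpois(1L, rate * duration * height * width)
  event_stream(x = sample.int(width, n, replace = TRUE) - 1L,
               y = sample.int(height, n, replace = TRUE) - 1L,
               t = stats::runif(n, 0, duration),
               p = sample(c("ON", "OFF"), n, replace = TRUE),
               width = width, height = height, duration = duration)
}

#' Generate a small random network fixture
#'
#' A chain rollout model (`input -> depth - 1 dense ReLU layers -> linear
#' readout`) with random weights and non-negative biases, used by the
#' conversion and simulation equivalence tests. Deterministic under `seed`.
#'
#' @param depth Number of parameterised layers including the readout
#'   (2..5).
#' @param width Units per hidden layer (<= 32).
#' @param n_features Flat input feature count.
#' @param n_classes Readout size.
#' @param seed Integer seed.
#' @return A [build_rollout_model()] model over a [graph_chain()].
#' @export
gen_fixture_network <- function(depth = 3L, width = 8L, n_features = 6L,
                                n_classes = 3L, seed = 1L) {
  stopifnot(depth >= 2, depth <= 5, width >= 1, width <= 32)
  g <- graph_chain(l_s = depth, width = width, n_features = n_features,
                   n_classes = n_classes)
  model <- build_rollout_model(g, seed = seed)
  old <- new_seed_scope(seed + 1L); on.exit(restore_seed_scope(old))
  for (key in names(model$params)) {
    p <- model$params[[key]]
    fan_in <- nrow(p$W)
    model$params[[key]]$W <- matrix(stats::rnorm(length(p$W), sd = sqrt(1 / fan_in)),
                                    nrow(p$W), ncol(p$W))
    model$params[[key]]$b <- stats::runif(length(p$b), 0, 0.2)
  }
  model
}
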