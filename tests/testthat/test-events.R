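# Event-stream input/output and frame preprocessing.

test_that("CSV and packed binary dialects round-trip an event stream", {
  ev <- gen_random_events(12, 10, rate = 2e-4, duration = 5e4, seed = 3)
  ev$t <- round(ev$t) # binary dialect stores integer microseconds

  csv <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, csv, "csv")
  back <- read_events(csv, "csv", width = 10, height = 12,
                      duration = attr(ev, "duration"))
  expect_equal(back$x, ev$x)
  expect_equal(back$y, ev$y)
  expect_equal(back$t, ev$t)
  expect_equal(as.character(back$p), as.character(ev$p))

  bin <- withr::local_tempfile(fileext = ".bin")
  write_events(ev, bin, "packed40")
  back2 <- read_events(bin, "packed40", width = 10, height = 12)
  expect_equal(back2$x, ev$x)
  expect_equal(back2$y, ev$y)
  expect_equal(back2$t, ev$t)
  expect_equal(as.character(back2$p), as.character(ev$p))
})

test_that("a small CSV fixture parses field by field", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,t,p", "3,1,100,ON", "0,2,250,OFF", "1,0,50,ON"), path)
  ev <- read_events(path, "csv", width = 4, height = 3)
  expect_identical(nrow(ev), 3L)
  expect_identical(ev$t, c(50, 100, 250)) # sorted on load
  expect_identical(ev$x, c(1L, 3L, 0L))
  expect_identical(as.character(ev$p), c("ON", "ON", "OFF"))
  expect_error(read_events(path, "unknown-dialect"), "arg")
})

test_that("malformed binary files are rejected with an offset", {
  path <- withr::local_tempfile(fileext = ".bin")
  writeBin(as.raw(1:7), path) # not a multiple of 5 bytes
  expect_error(read_events(path, "packed40", width = 8, height = 8),
               "byte")
})

test_that("frame binning conserves event counts and separates polarities", {
  ev <- gen_random_events(8, 6, rate = 5e-4, duration = 8e4, seed = 9)
  for (N in c(1L, 4L, 16L)) {
    fr <- events_to_frames(ev, N, mode = "sum")
    expect_identical(dim(fr), c(N, 2L, 8L, 6L))
    expect_equal(sum(fr), nrow(ev))
    expect_equal(sum(fr[, 1, , ]), sum(ev$p == "ON"))
    expect_equal(sum(fr[, 2, , ]), sum(ev$p == "OFF"))
    # per-pixel totals equal per-pixel counts
    tab <- dplyr::count(tibble::as_tibble(ev), x, y, p)
    for (r in seq_len(nrow(tab))) {
      ch <- if (tab$p[r] == "ON") 1L else 2L
      expect_equal(sum(fr[, ch, tab$y[r] + 1L, tab$x[r] + 1L]), tab$n[r])
    }
    # average mode is sum / T_F (in ms)
    fa <- events_to_frames(ev, N, mode = "average")
    expect_equal(as.numeric(fa), as.numeric(fr) / attr(fr, "t_f"))
  }
})

test_that("frame interval arithmetic matches the worked examples", {
  ev100 <- gen_random_events(4, 4, rate = 1e-5, duration = 1e5, seed = 1)
  expect_equal(attr(events_to_frames(ev100, 16), "t_f"), 6.25) # 100 ms / 16
  ev13 <- gen_random_events(4, 4, rate = 1e-6, duration = 1.3e6, seed = 1)
  expect_equal(attr(events_to_frames(ev13, 48), "t_f"), 1300 / 48,
               tolerance = 1e-12) # 27.08 ms
})

test_that("empty streams produce all-zero frames", {
  ev <- gen_random_events(5, 5, rate = 0, duration = 1e4, seed = 1)
  fr <- events_to_frames(ev, 4)
  expect_identical(dim(fr), c(4L, 2L, 5L, 5L))
  expect_true(all(fr == 0))
})

test_that("binning uses half-open intervals with a closed final interval", {
  # events exactly on bin edges go to the later bin; the final edge is kept
  ev <- event_stream(x = c(0, 0, 0), y = c(0, 0, 0), t = c(0, 50, 100),
                     p = "ON", width = 1, height = 1, duration = 100)
  fr <- events_to_frames(ev, 2, mode = "sum")
  expect_equal(fr[1, 1, 1, 1], 1) # t = 0
  expect_equal(fr[2, 1, 1, 1], 2) # t = 50 (edge -> bin 2) and t = 100 (kept)
})

test_that("binning is translation-consistent by one frame interval", {
  ev <- gen_random_events(6, 6, rate = 3e-4, duration = 6e4, seed = 21)
  N <- 6L
  t_f <- attr(ev, "duration") / N
  fr <- events_to_frames(ev, N, mode = "sum")
  shifted <- event_stream(ev$x, ev$y, ev$t + t_f, ev$p, 6, 6,
                          duration = attr(ev, "duration") + t_f)
  fr2 <- events_to_frames(shifted, N + 1L, mode = "sum")
  # interior frames shift by exactly one
  expect_equal(fr2[2:(N), , , ], fr[1:(N - 1L), , , ])
})

test_that("explicit cut drops late events and fixes the duration", {
  ev <- gen_random_events(4, 4, rate = 1e-3, duration = 2e4, seed = 5)
  expect_message(cut <- cut_events(ev, 1e4), "dropped by cut")
  expect_true(all(cut$t <= 1e4))
  expect_equal(attr(cut, "duration"), 1e4)
})

test_that("bilinear downscaling preserves constants and averages blocks", {
  const <- frame_sequence(array(3.5, c(2, 2, 8, 8)), t_f = 1)
  for (target in c(8L, 5L, 3L)) {
    dn <- downscale(const, target, target)
    expect_true(all(abs(dn - 3.5) < 1e-12))
  }
  # 2x2 checkerboard to 1x1 -> mean of the four pixels
  cb <- array(0, c(1, 1, 2, 2))
  cb[1, 1, , ] <- matrix(c(1, 0, 0, 1), 2, 2)
  dn <- downscale(frame_sequence(cb, t_f = 1), 1, 1)
  expect_equal(as.numeric(dn), 0.5)
  # shape contract 128 -> 32 and non-negativity
  big <- frame_sequence(array(stats::runif(1 * 2 * 128 * 128), c(1, 2, 128, 128)),
                        t_f = 1)
  small <- downscale(big, 32, 32)
  expect_identical(dim(small), c(1L, 2L, 32L, 32L))
  expect_true(all(small >= 0))
  expect_warning(downscale(small, 64, 64), "upscaling")
})

test_that("frame stacking reorders channels exactly and rescales T_F", {
  # indexed frames: value encodes (frame, channel) so the bookkeeping is
  # checkable per output channel
  N <- 12L; s <- 4L
  arr <- array(0, c(N, 2, 3, 3))
  for (f in 1:N) for (c in 1:2) arr[f, c, , ] <- 100 * f + c
  fr <- frame_sequence(arr, t_f = 2)
  st <- stack_frames(fr, s)
  expect_identical(dim(st), c(N %/% s, 2L * s, 3L, 3L))
  expect_equal(attr(st, "t_f"), 2 * s)
  for (g in seq_len(N %/% s)) for (f in 1:s) for (c in 1:2) {
    expect_equal(unique(as.numeric(st[g, (f - 1L) * 2L + c, , ])),
                 100 * ((g - 1L) * s + f) + c)
  }
  # s = 1 is the identity
  expect_equal(as.numeric(stack_frames(fr, 1)), as.numeric(fr))
  # 240 frames by 10 -> 24 inputs of 20 channels
  big <- frame_sequence(array(0, c(240, 2, 2, 2)), t_f = 6.25)
  st10 <- stack_frames(big, 10)
  expect_identical(dim(st10)[1:2], c(24L, 20L))
  expect_equal(attr(st10, "t_f"), 62.5)
  expect_error(stack_frames(fr, 0), "positive")
  expect_message(stack_frames(fr, 5), "truncated")
})

test_that("frame normalization divides by a shared scale", {
  fr <- frame_sequence(array(stats::runif(4 * 2 * 3 * 3, 0, 8), c(4, 2, 3, 3)),
                       t_f = 1)
  nf <- normalize_frames(fr)
  expect_equal(max(nf), 1)
  expect_equal(attr(nf, "scale"), max(fr))
  nf2 <- normalize_frames(fr, scale = 16)
  expect_equal(as.numeric(nf2), as.numeric(fr) / 16)
})

test_that("out-of-range coordinates are rejected", {
  expect_error(event_stream(x = 5, y = 0, t = 1, p = "ON", width = 4, height = 4),
               "x out of range")
  expect_error(event_stream(x = 0, y = -1, t = 1, p = "ON", width = 4, height = 4),
               "y out of range")
})
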