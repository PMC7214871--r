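# Rollout ANN: forward semantics, loss weighting, gradients, training.

test_that("loss weight schemes match their definitions and normalise to one", {
  expect_equal(make_loss_weights("uniform", 3:6)$weight, rep(0.25, 4))
  expect_equal(make_loss_weights("first-only", 5:21)$weight,
               c(1, rep(0, 16)))
  expect_equal(make_loss_weights("last-only", 5:21)$weight,
               c(rep(0, 16), 1))
  k <- 3:6
  expect_equal(make_loss_weights("exp-decreasing", k)$weight,
               exp(-k) / sum(exp(-k)))
  expect_equal(make_loss_weights("exp-increasing", k)$weight,
               exp(k) / sum(exp(k)))
  expect_equal(make_loss_weights("linear-increasing", k)$weight,
               (k + 1) / sum(k + 1))
  expect_equal(make_loss_weights("inverse", k)$weight,
               (1 / (k + 1)) / sum(1 / (k + 1)))
  expect_error(make_loss_weights("quadratic", k))
  for (s in c("uniform", "linear-increasing", "exp-increasing", "inverse",
              "exp-decreasing"))
    expect_equal(sum(make_loss_weights(s, 5:21)$weight), 1)
})

test_that("rollout loss matches closed forms and a term-by-term oracle", {
  # single output, full confidence -> zero loss
  expect_equal(rollout_loss(matrix(c(1, 0), 1, 2), 1, weights = 1), 0)
  # two outputs, uniform weights, p(true) = 0.5 both -> log 2
  probs <- matrix(0.5, 2, 2)
  expect_equal(rollout_loss(probs, 1, weights = c(0.5, 0.5)), log(2))
  # last-only weights equal plain cross entropy on the final output
  set.seed(4)
  P <- matrix(stats::runif(5 * 3), 5, 3); P <- P / rowSums(P)
  w_last <- c(0, 0, 0, 0, 1)
  expect_equal(rollout_loss(P, 2, w_last), -log(P[5, 2]))
  # random outputs and weights vs explicit summation
  w <- stats::runif(5); w <- w / sum(w)
  expect_equal(rollout_loss(P, 3, w), sum(-w * log(P[, 3])))
  # uniform weights with identical outputs reduce to single-output CE
  P1 <- matrix(rep(P[1, ], 5), 5, 3, byrow = TRUE)
  expect_equal(rollout_loss(P1, 1, rep(1 / 5, 5)), -log(P[1, 1]))
  # zero probability is clamped, not -Inf
  expect_true(is.finite(rollout_loss(matrix(c(0, 1), 1, 2), 1, 1)))
})

test_that("all-zero input yields identical bias-driven outputs past the warm-up", {
  g <- graph_skip_example(channels = 3, input_shape = c(2, 6, 6))
  m <- build_rollout_model(g, seed = 2)
  for (key in names(m$params)) m$params[[key]]$b <- stats::runif(length(m$params[[key]]$b))
  x <- array(0, dim = c(1, 4, 2, 6, 6))
  fwd <- forward_rollout(m, x)
  # beyond the warm-up cone (frame >= l_max + 1) all outputs are equal
  ps <- path_stats(g)
  late <- which(fwd$output_frames >= ps$l_max + 1L)
  ref <- fwd$probs[1, late[1], ]
  for (i in late) expect_equal(fwd$probs[1, i, ], ref, tolerance = 1e-12)
})

test_that("perturbing input frame j changes output k iff j is in its cone", {
  for (seed in 1:4) {
    g <- random_dag(sample(5:8, 1), seed = 300 + seed)
    m <- build_rollout_model(g, seed = seed)
    N <- path_stats(g)$tau + 2L
    sched <- rollout(g, N)
    set.seed(seed)
    x <- array(stats::runif(1 * N * g$input_shape), dim = c(1, N, g$input_shape))
    base <- forward_rollout(m, x, sched)$logits
    for (j in seq_len(N)) {
      xp <- x
      xp[1, j, ] <- xp[1, j, ] + 3 # perturb frame j
      pert <- forward_rollout(m, xp, sched)$logits
      for (i in seq_along(sched$output_frames)) {
        k <- sched$output_frames[i]
        changed <- any(abs(pert[1, i, ] - base[1, i, ]) > 1e-9)
        in_cone <- j %in% dependency_cone(sched, k)
        if (changed) expect_true(in_cone)
        if (!in_cone) expect_false(changed)
      }
    }
  }
})

test_that("the example topology emits one output per input frame", {
  g <- graph_skip_example(channels = 2, input_shape = c(2, 6, 6))
  m <- build_rollout_model(g, seed = 1)
  x <- array(stats::runif(2 * 4 * 2 * 6 * 6), dim = c(2, 4, 2, 6, 6))
  fwd <- forward_rollout(m, x)
  expect_identical(dim(fwd$probs), c(2L, 4L, 2L))
  expect_identical(fwd$output_frames, 3:6)
  expect_equal(apply(fwd$probs, c(1, 2), sum), matrix(1, 2, 4))
  # shape mismatch carries the offending node information
  bad <- array(0, dim = c(2, 4, 2, 5, 5))
  expect_error(forward_rollout(m, bad), "input")
})

test_that("analytic gradients agree with central finite differences", {
  # dense chain (covers weight sharing across frames)
  m <- gen_fixture_network(depth = 3, width = 4, n_features = 3,
                           n_classes = 2, seed = 7)
  for (key in names(m$params)) # move off ReLU kinks for the FD window
    m$params[[key]]$b <- m$params[[key]]$b + 0.05
  set.seed(42)
  N <- 3L
  x <- array(stats::runif(2 * N * 3), dim = c(2, N, 3))
  y <- c(1L, 2L)
  sched <- rollout(m$graph, N)
  w <- make_loss_weights("uniform", sched$output_frames)
  res <- streamsnn:::rollout_grads(m, x, y, w, sched, act_decay = 0.01)
  eps <- 1e-6
  for (key in names(m$params)) for (part in c("W", "b")) {
    P <- m$params[[key]][[part]]
    for (i in unique(round(seq(1, length(P), length.out = 5)))) {
      m2 <- m; m2$params[[key]][[part]][i] <- P[i] + eps
      lp <- streamsnn:::rollout_grads(m2, x, y, w, sched, act_decay = 0.01)$loss
      m2$params[[key]][[part]][i] <- P[i] - eps
      lm <- streamsnn:::rollout_grads(m2, x, y, w, sched, act_decay = 0.01)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- res$grads[[key]][[part]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
  # conv + transition + head model (covers every spatial layer type)
  g <- build_densenet_graph(2, 1, 3, c(2, 8, 8), 2)
  mc <- build_rollout_model(g, seed = 3)
  for (key in names(mc$params)) mc$params[[key]]$b <- mc$params[[key]]$b + 0.05
  xc <- array(stats::runif(2 * 4 * 2 * 8 * 8), dim = c(2, 4, 2, 8, 8))
  sc <- rollout(g, 4)
  wc <- make_loss_weights("linear-increasing", sc$output_frames)
  resc <- streamsnn:::rollout_grads(mc, xc, c(2L, 1L), wc, sc, act_decay = 3e-3)
  for (key in names(mc$params)) for (part in c("W", "b")) {
    P <- mc$params[[key]][[part]]
    for (i in unique(round(seq(1, length(P), length.out = 4)))) {
      m2 <- mc; m2$params[[key]][[part]][i] <- P[i] + eps
      lp <- streamsnn:::rollout_grads(m2, xc, c(2L, 1L), wc, sc, act_decay = 3e-3)$loss
      m2$params[[key]][[part]][i] <- P[i] - eps
      lm <- streamsnn:::rollout_grads(m2, xc, c(2L, 1L), wc, sc, act_decay = 3e-3)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- resc$grads[[key]][[part]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-3)
    }
  }
})

test_that("weight sharing: one parameter set drives all rollout frames", {
  g <- graph_chain(2, width = 4, n_features = 3)
  m <- gen_fixture_network(depth = 2, width = 4, n_features = 3, seed = 5)
  x <- array(1, dim = c(1, 4, 3))
  base <- forward_rollout(m, x)
  m$params[["2"]]$W <- m$params[["2"]]$W * 0 # mutate the single shared copy
  killed <- forward_rollout(m, x)
  # every output frame is affected identically (logit differences equal)
  d <- base$logits[1, , ] - killed$logits[1, , ]
  expect_true(max(abs(sweep(d, 2, d[nrow(d), ]))) < 1e-9)
})

test_that("zero training epochs return the model unchanged", {
  m <- gen_fixture_network(depth = 2, width = 4, n_features = 3, seed = 5)
  x <- array(stats::runif(8 * 3 * 3), dim = c(8, 3, 3))
  y <- rep(1:2, 4)
  m2 <- train_rollout(m, x, y, epochs = 0)
  expect_identical(m2$params, m$params)
})

test_that("forward conv layers agree with the naive convolution oracle", {
  set.seed(8)
  X <- array(stats::runif(3 * 6 * 7 * 2), dim = c(3, 6, 7, 2))
  W <- matrix(stats::rnorm(9 * 2 * 3), 18, 3)
  b <- stats::rnorm(3)
  Z <- streamsnn:::conv_forward_pre(X, W, b)
  for (i in 1:3)
    expect_equal(Z[i, , , ], naive_conv(X[i, , , ], W, b), tolerance = 1e-12)
})
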