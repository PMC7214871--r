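# Independent oracles used across the test suite. Each deliberately avoids
# the implementation path it checks: path statistics by exhaustive
# enumeration, convolution by a naive triple loop, percentiles by explicit
# sort-and-interpolate.

# All simple input->output paths of a network_graph, as total delays.
enumerate_path_lengths <- function(graph) {
  lens <- integer(0)
  walk <- function(v, acc) {
    if (v == graph$output_id) {
      lens[length(lens) + 1L] <<- acc
      return(invisible())
    }
    out <- graph$edges[graph$edges$from == v, ]
    for (i in seq_len(nrow(out))) walk(out$to[i], acc + out$delay[i])
  }
  walk(graph$input_id, 0L)
  sort(unique(lens))
}

# Random layered DAG with one input, dense hidden nodes and an fc sink;
# guaranteed to satisfy the reachability invariants.
random_dag <- function(n_nodes, seed, edge_prob = 0.4, n_features = 3L,
                       width = 4L, n_classes = 2L) {
  set.seed(seed)
  stopifnot(n_nodes >= 3, n_nodes <= 12)
  nodes <- tibble::tibble(
    id = seq_len(n_nodes),
    kind = c("input", rep("dense", n_nodes - 2L), "fc"),
    channels = as.integer(c(n_features, rep(width, n_nodes - 2L), n_classes)))
  edges <- list()
  for (i in 1:(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    if (j == i + 1L || stats::runif(1) < edge_prob)
      edges[[length(edges) + 1L]] <- tibble::tibble(from = i, to = j, delay = 1L)
  }
  network_graph(nodes, dplyr::bind_rows(edges),
                input_shape = n_features, n_classes = n_classes)
}

# Naive direct convolution (stride 1, zero padding) for a single image
# (H, W, C); weights in the package layout (k*k*C_in, C_out),
# offset-major / channel-minor rows.
naive_conv <- function(X, W, b, k = 3L) {
  H <- dim(X)[1]; Wd <- dim(X)[2]; C <- dim(X)[3]
  Cout <- ncol(W)
  r <- (k - 1L) %/% 2L
  off <- expand.grid(dy = -r:r, dx = -r:r)
  out <- array(0, dim = c(H, Wd, Cout))
  for (p in 1:H) for (q in 1:Wd) for (co in 1:Cout) {
    acc <- b[co]
    for (o in seq_len(nrow(off))) for (ci in 1:C) {
      sy <- p + off$dy[o]; sx <- q + off$dx[o]
      if (sy >= 1 && sy <= H && sx >= 1 && sx <= Wd)
        acc <- acc + W[(o - 1L) * C + ci, co] * X[sy, sx, ci]
    }
    out[p, q, co] <- acc
  }
  out
}

# Sort-and-interpolate percentile (linear interpolation between order
# statistics), written independently of stats::quantile.
manual_percentile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

# Structural fan-out of one neuron by explicit enumeration over target
# neurons of all outgoing edges (oracle for snn_fanout / count_snn_ops).
enumerate_fanout <- function(snn, node_key, i, j = NULL, c = NULL) {
  model <- snn$model
  g <- snn$graph
  succ <- g$edges$to[g$edges$from == as.integer(node_key)]
  total <- 0L
  for (v in succ) {
    sv <- model$shape[[as.character(v)]]
    if (sv$kind %in% c("conv", "transition")) {
      r <- (sv$kernel - 1L) %/% 2L
      H <- model$shape[[node_key]]$H; W <- model$shape[[node_key]]$W
      tg <- 0L
      seen <- character(0)
      for (dy in -r:r) for (dx in -r:r) {
        p <- i + dy; q <- j + dx
        if (p < 1 || p > H || q < 1 || q > W) next
        cell <- if (sv$kind == "transition")
          paste(ceiling(p / 2), ceiling(q / 2)) else paste(p, q)
        if (!cell %in% seen) { seen <- c(seen, cell); tg <- tg + 1L }
      }
      total <- total + tg * sv$C
    } else {
      total <- total + sv$C
    }
  }
  total
}

# Single IF neuron driven through a one-edge network: input -> dense(1) ->
# readout, identity weights on class 1 so the dynamics are hand-computable.
single_neuron_net <- function(w = 1, bias = 0) {
  nodes <- tibble::tibble(id = 1:3, kind = c("input", "dense", "fc"),
                          channels = c(1L, 1L, 2L))
  edges <- tibble::tibble(from = c(1, 2), to = c(2, 3), delay = 1L)
  g <- network_graph(nodes, edges, input_shape = 1L, n_classes = 2L)
  m <- build_rollout_model(g, seed = 1)
  m$params[["2"]]$W <- matrix(w, 1, 1)
  m$params[["2"]]$b <- bias
  m$params[["3"]]$W <- matrix(c(1, 0), 1, 2)
  m$params[["3"]]$b <- c(0, 0)
  m
}

# The moving-rectangles study model, trained once per test run and cached:
# 2000 samples, N_l = 1 / N_b = 3 rollout DenseNet, trained to convergence.
trained_rect_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    d <- gen_rectangles(2000, seed = 101)
    g <- build_densenet_graph(3, 1, 8, c(2, 16, 16), 2)
    m <- build_rollout_model(g, seed = 7)
    m <- train_rollout(m, d$x, d$y, epochs = 15, batch_size = 64, lr = 3e-3,
                       weight_decay = 1e-4, act_decay = 1e-6, seed = 3)
    cache <<- list(model = m, train = d,
                   test = gen_rectangles(300, seed = 202))
    cache
  }
})
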