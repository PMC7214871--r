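# Layered network graphs and their streaming rollouts.
#
# A network graph is a DAG whose nodes are layers (not single neurons) and
# whose edges carry an integer delay in rollout frames (d_ANN, here always 1
# unless constructed otherwise).  Under a streaming rollout every edge spans
# time, so path lengths through the graph translate directly into latencies
# and the spread between shortest and longest input->output path sets the
# temporal receptive field.

#' Construct a layered network graph
#'
#' Builds a validated directed acyclic graph of layer nodes. Nodes are layers
#' of a neural network (input, convolution, transition, dense hidden or
#' classifier head); edges are dependencies between layers, each carrying a
#' positive integer delay measured in rollout frames.
#'
#' @param nodes A data frame with columns `id` (unique integer), `kind` (one
#'   of `"input"`, `"conv"`, `"transition"`, `"dense"`, `"fc"`), and
#'   optionally `channels` (output channels / units), `kernel` (spatial kernel
#'   size for conv-like nodes) and `pool` (pooling factor for transitions).
#' @param edges A data frame with columns `from`, `to` (node ids) and
#'   optionally `delay` (positive integer rollout frames, default 1).
#' @param input_shape Integer vector, either `c(channels, height, width)` for
#'   image input or a single length for flat input.
#' @param n_classes Number of output classes.
#' @param depth Optional conventional depth of the architecture (number of
#'   parameterised block layers plus classifier); when `NULL` it is derived
#'   from the longest path by [path_stats()].
#'
#' @return An object of class `network_graph`: a list with tibbles `nodes`
#'   and `edges` plus shape metadata.
#' @examples
#' g <- graph_skip_example()
#' path_stats(g)
#' @seealso [build_densenet_graph()], [path_stats()], [rollout()]
#' @export
network_graph <- function(nodes, edges, input_shape = NULL, n_classes = NULL,
                          depth = NULL) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "kind") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (!"delay" %in% names(edges)) edges$delay <- 1L
  if (!"channels" %in% names(nodes)) nodes$channels <- NA_integer_
  if (!"kernel" %in% names(nodes)) nodes$kernel <- NA_integer_
  if (!"pool" %in% names(nodes)) nodes$pool <- NA_integer_
  nodes$id <- as.integer(nodes$id)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  edges$delay <- as.integer(edges$delay)

  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (any(edges$delay < 0L)) stop("edge delays must be non-negative")
  kinds <- c("input", "conv", "transition", "dense", "fc")
  bad <- setdiff(unique(nodes$kind), kinds)
  if (length(bad)) stop("unknown node kind(s): ", paste(bad, collapse = ", "))
  if (sum(nodes$kind == "input") != 1L) stop("exactly one input node required")
  if (!all(edges$from %in% nodes$id) || !all(edges$to %in% nodes$id))
    stop("edge endpoints must reference node ids")

  g <- structure(
    list(nodes = nodes, edges = edges,
         input_shape = input_shape, n_classes = n_classes, depth = depth),
    class = "network_graph")

  ord <- topo_order(g) # errors on cycles
  # output node: unique sink
  sinks <- setdiff(nodes$id, edges$from)
  if (length(sinks) != 1L) stop("exactly one output (sink) node required")
  g$output_id <- sinks
  g$input_id <- nodes$id[nodes$kind == "input"]
  # reachability: every node reachable from input, output reachable from all
  fwd <- reachable_from(g, g$input_id)
  bwd <- reachable_from(reverse_graph(g), g$output_id)
  if (!all(nodes$id %in% fwd)) stop("every node must be reachable from the input")
  if (!all(nodes$id %in% bwd)) stop("the output must be reachable from every node")
  g$topo <- ord
  g
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  ps <- path_stats(x)
  cat(sprintf("  l_s = %d, l_max = %d, tau = %d, depth D = %d\n",
              ps$l_s, ps$l_max, ps$tau, ps$depth))
  invisible(x)
}

# Kahn topological sort; ties broken by node id (deterministic ordering).
topo_order <- function(graph) {
  ids <- sort(graph$nodes$id)
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (to in graph$edges$to) indeg[as.character(to)] <- indeg[as.character(to)] + 1L
  out <- integer(0)
  avail <- ids[indeg[as.character(ids)] == 0L]
  while (length(avail)) {
    v <- min(avail)
    avail <- setdiff(avail, v)
    out <- c(out, v)
    succ <- graph$edges$to[graph$edges$from == v]
    for (s in succ) {
      key <- as.character(s)
      indeg[key] <- indeg[key] - 1L
      if (indeg[key] == 0L) avail <- c(avail, s)
    }
  }
  if (length(out) != length(ids)) stop("graph has a cycle")
  out
}

reverse_graph <- function(graph) {
  g <- graph
  g$edges <- tibble::tibble(from = graph$edges$to, to = graph$edges$from,
                            delay = graph$edges$delay)
  g
}

reachable_from <- function(graph, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(graph$edges$to[graph$edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

# Set of realized input->output path delays (each path's summed edge delays).
# Dynamic programme over the topological order; the result drives
# dependency_cone(), which must reflect paths that actually exist rather
# than the [l_s, l_max] interval (identical for dense blocks, not for
# arbitrary DAGs).
path_length_set <- function(graph) {
  sets <- list()
  sets[[as.character(graph$input_id)]] <- 0L
  for (v in graph$topo) {
    if (v == graph$input_id) next
    inc <- graph$edges[graph$edges$to == v, ]
    acc <- integer(0)
    for (i in seq_len(nrow(inc))) {
      src <- sets[[as.character(inc$from[i])]]
      if (!is.null(src)) acc <- c(acc, src + inc$delay[i])
    }
    sets[[as.character(v)]] <- sort(unique(acc))
  }
  sets[[as.character(graph$output_id)]]
}

#' Temporal path statistics of a network graph
#'
#' Computes the shortest (`l_s`) and longest (`l_max`) input-to-output path
#' length, where a path's length is the sum of its edge delays (with all
#' delays equal to one this is the edge count). The spatio-temporal receptive
#' field spans `tau = l_max - l_s + 1` input frames: under a streaming
#' rollout an output at frame `k` merges information that entered the network
#' between frames `k - l_max` and `k - l_s`.
#'
#' @param graph A [network_graph()].
#' @return An object of class `path_stats`: list with `l_s`, `l_max`, `tau`,
#'   `depth`, and `lengths` (the set of realized path lengths).
#' @examples
#' path_stats(graph_skip_example()) # l_s = 2, l_max = 4, tau = 3
#' @export
path_stats <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  lens <- path_length_set(graph)
  if (!length(lens)) stop("no input->output path")
  depth <- graph$depth
  if (is.null(depth)) {
    # conventional depth: parameterised layers on the longest chain
    depth <- longest_param_chain(graph)
  }
  structure(list(l_s = min(lens), l_max = max(lens),
                 tau = max(lens) - min(lens) + 1L,
                 depth = as.integer(depth), lengths = lens),
            class = "path_stats")
}

#' @export
print.path_stats <- function(x, ...) {
  cat(sprintf("path stats: l_s = %d, l_max = %d, tau = %d, D = %d\n",
              x$l_s, x$l_max, x$tau, x$depth))
  invisible(x)
}

#' @rdname path_stats
#' @param x A `path_stats` object.
#' @param ... Unused.
#' @export
tidy.path_stats <- function(x, ...) {
  tibble::tibble(l_s = x$l_s, l_max = x$l_max, tau = x$tau, depth = x$depth)
}

longest_param_chain <- function(graph) {
  param <- graph$nodes$kind %in% c("conv", "transition", "dense", "fc")
  names(param) <- graph$nodes$id
  best <- stats::setNames(rep(-Inf, nrow(graph$nodes)), graph$nodes$id)
  best[as.character(graph$input_id)] <- 0
  for (v in graph$topo) {
    if (v == graph$input_id) next
    inc <- graph$edges[graph$edges$to == v, ]
    prev <- max(best[as.character(inc$from)])
    best[as.character(v)] <- prev + as.integer(param[as.character(v)])
  }
  as.integer(best[as.character(graph$output_id)])
}

#' Streaming rollout schedule
#'
#' Unrolls a network graph over time. Every edge transports information to a
#' later rollout frame (by its delay), so all layers can update in parallel
#' within a frame. With `N` input frames and shortest path `l_s` the rollout
#' spans `K = N + l_s` frames: the last output is connected to the last input
#' via the shortest path. Outputs are emitted at frames `l_s + 1, ..., K`,
#' one per input frame. If `N` is smaller than the receptive field `tau`,
#' the rollout keeps its `tau` input slots (`K = tau + l_s`) and the `N`
#' frames are spread evenly over them (slot `round(i * tau / N)` for frame
#' `i`), empty slots receiving zero input.
#'
#' @param graph A [network_graph()].
#' @param n_frames Number of input frames `N` (>= 1).
#' @return An object of class `rollout_schedule`: list with `K`, `N`, `l_s`,
#'   `output_frames`, `input_assignment` (length-`K` integer vector mapping
#'   rollout frame to input frame index, 0 = no input) and the graph.
#' @examples
#' sched <- rollout(graph_skip_example(), n_frames = 4)
#' sched$K               # 6
#' sched$output_frames   # 3 4 5 6
#' @export
rollout <- function(graph, n_frames) {
  stopifnot(inherits(graph, "network_graph"), n_frames >= 1)
  n_frames <- as.integer(n_frames)
  ps <- path_stats(graph)
  if (n_frames >= ps$tau) {
    K <- n_frames + ps$l_s
    assign <- integer(K)
    assign[seq_len(n_frames)] <- seq_len(n_frames)
  } else {
    K <- ps$tau + ps$l_s
    assign <- integer(K)
    slots <- pmax(1L, as.integer(round(seq_len(n_frames) * ps$tau / n_frames)))
    assign[slots] <- seq_len(n_frames)
  }
  structure(list(K = K, N = n_frames, l_s = ps$l_s, l_max = ps$l_max,
                 tau = ps$tau, lengths = ps$lengths,
                 output_frames = (ps$l_s + 1L):K,
                 input_assignment = assign, graph = graph),
            class = "rollout_schedule")
}

#' @export
print.rollout_schedule <- function(x, ...) {
  cat(sprintf("<rollout_schedule> K = %d frames (N = %d inputs, l_s = %d), outputs at %d..%d\n",
              x$K, x$N, x$l_s, min(x$output_frames), max(x$output_frames)))
  invisible(x)
}

#' Input frames feeding a given output frame
#'
#' Returns the set of input frames on which the network output at rollout
#' frame `k` depends. An input at rollout slot `s` reaches the output at
#' frame `k` iff `k - s` is a realized input-to-output path length; with a
#' dense block every length in `l_s..l_max` is realized and the cone is the
#' interval `{k - l_max, ..., k - l_s}` clipped to existing frames.
#'
#' @param schedule A [rollout()] schedule.
#' @param k An output frame index.
#' @return Sorted integer vector of input frame indices.
#' @examples
#' sched <- rollout(graph_skip_example(), 4)
#' dependency_cone(sched, 6) # 2 3 4
#' @export
dependency_cone <- function(schedule, k) {
  stopifnot(inherits(schedule, "rollout_schedule"))
  k <- as.integer(k)
  if (!(k %in% schedule$output_frames))
    stop("k = ", k, " is not an output frame (outputs at ",
         min(schedule$output_frames), "..", max(schedule$output_frames), ")")
  slots <- k - schedule$lengths
  slots <- slots[slots >= 1L & slots <= schedule$K]
  frames <- schedule$input_assignment[slots]
  sort(unique(frames[frames > 0L]))
}

#' Build a DenseNet-style network graph
#'
#' Constructs the standard architecture used throughout: an initial 3x3
#' convolution, `n_blocks` dense blocks of `layers_per_block` convolutional
#' layers in which every layer receives the block input and all previous
#' layers of the block, transition layers (3x3 convolution + 2x2 average
#' pooling) between blocks fed by the full block concatenation, and a
#' classifier head (global average pooling + fully connected) fed by the
#' concatenation of the last block. All edges carry a delay of one rollout
#' frame, so under a streaming rollout the dense connectivity provides
#' temporal skip connections and an output update at every frame.
#'
#' @param n_blocks Number of dense blocks `N_b` (>= 1).
#' @param layers_per_block Layers per block `N_l` (>= 1).
#' @param growth Growth factor `g`: output channels of each block layer.
#' @param input_shape `c(channels, height, width)` of one input frame.
#' @param n_classes Number of classes.
#' @return A [network_graph()] with depth metadata `D = N_l * N_b + 1`.
#' @examples
#' g <- build_densenet_graph(3, 5, 12, c(2, 32, 32), 2)
#' path_stats(g)$depth # 16
#' @export
build_densenet_graph <- function(n_blocks, layers_per_block, growth,
                                 input_shape, n_classes) {
  stopifnot(n_blocks >= 1, layers_per_block >= 1, growth >= 1,
            length(input_shape) == 3, n_classes >= 2)
  H <- input_shape[2]; W <- input_shape[3]
  # spatial size after the (n_blocks - 1) pooling transitions must stay >= 1
  for (b in seq_len(n_blocks - 1L)) {
    if (H %% 2L != 0L || W %% 2L != 0L)
      stop(sprintf("spatial size underflow: %dx%d not divisible by 2 at transition %d",
                   H, W, b))
    H <- H %/% 2L; W <- W %/% 2L
  }
  nodes <- list(); edges <- list()
  nid <- 0L
  add_node <- function(kind, channels = NA, kernel = NA, pool = NA) {
    nid <<- nid + 1L
    nodes[[nid]] <<- tibble::tibble(id = nid, kind = kind,
                                    channels = as.integer(channels),
                                    kernel = as.integer(kernel),
                                    pool = as.integer(pool))
    nid
  }
  add_edge <- function(from, to)
    edges[[length(edges) + 1L]] <<- tibble::tibble(from = from, to = to, delay = 1L)

  input <- add_node("input", channels = input_shape[1])
  conv1 <- add_node("conv", channels = 2L * growth, kernel = 3L)
  add_edge(input, conv1)
  block_in <- conv1
  for (b in seq_len(n_blocks)) {
    members <- block_in # block input participates in the dense connectivity
    for (l in seq_len(layers_per_block)) {
      lay <- add_node("conv", channels = growth, kernel = 3L)
      for (m in members) add_edge(m, lay)
      members <- c(members, lay)
    }
    if (b < n_blocks) {
      tr <- add_node("transition", channels = growth, kernel = 3L, pool = 2L)
      for (m in members) add_edge(m, tr)
      block_in <- tr
    } else {
      head <- add_node("fc", channels = n_classes)
      for (m in members) add_edge(m, head)
    }
  }
  network_graph(dplyr::bind_rows(nodes), dplyr::bind_rows(edges),
                input_shape = as.integer(input_shape),
                n_classes = as.integer(n_classes),
                depth = as.integer(layers_per_block * n_blocks + 1L))
}

#' Example network graph with temporal skip connections
#'
#' A small feed-forward graph: input, an initial convolution, and one block
#' of three densely connected layers of which the third is the classifier
#' head (global pool + fully connected). Every layer in the block receives
#' the initial convolution and all previous block layers, so paths of length
#' 2, 3 and 4 connect input to output: `l_s = 2`, `l_max = 4`, receptive
#' field `tau = 3` input frames. Rolled out over `N = 4` input frames this
#' gives `K = 6` rollout frames with outputs at frames 3..6, and the final
#' output merges input frames 2, 3 and 4.
#'
#' @param channels Channels of the convolutional layers (default 4).
#' @param input_shape `c(channels, height, width)` of one input frame.
#' @param n_classes Number of classes (default 2).
#' @return A [network_graph()].
#' @examples
#' unlist(tidy(path_stats(graph_skip_example())))
#' @export
graph_skip_example <- function(channels = 4L, input_shape = c(2L, 8L, 8L),
                               n_classes = 2L) {
  nodes <- tibble::tibble(
    id = 1:5,
    kind = c("input", "conv", "conv", "conv", "fc"),
    channels = as.integer(c(input_shape[1], channels, channels, channels,
                            n_classes)),
    kernel = c(NA, 3L, 3L, 3L, NA),
    pool = NA_integer_)
  edges <- tibble::tibble(
    from = c(1L, 2L, 2L, 2L, 3L, 3L, 4L),
    to   = c(2L, 3L, 4L, 5L, 4L, 5L, 5L),
    delay = 1L)
  network_graph(nodes, edges, input_shape = as.integer(input_shape),
                n_classes = as.integer(n_classes), depth = 4L)
}

#' Chain network graph
#'
#' A plain chain `input -> h_1 -> ... -> h_m -> output` with `l_s = l_max =
#' m + 1` (no skips, receptive field of one frame). Useful for delay
#' bookkeeping and for rollout-length arithmetic with a prescribed `l_s`.
#'
#' @param l_s Desired shortest (= longest) path length in edges (>= 1).
#' @param width Units per hidden layer.
#' @param n_features Flat input feature count.
#' @param n_classes Number of classes.
#' @return A [network_graph()].
#' @examples
#' path_stats(graph_chain(5))$l_s # 5
#' rollout(graph_chain(5), 16)$K  # 21
#' @export
graph_chain <- function(l_s, width = 8L, n_features = 4L, n_classes = 2L) {
  stopifnot(l_s >= 1)
  n_hidden <- l_s - 1L
  ids <- seq_len(n_hidden + 2L)
  nodes <- tibble::tibble(
    id = ids,
    kind = c("input", rep("dense", n_hidden), "fc"),
    channels = as.integer(c(n_features, rep(width, n_hidden), n_classes)),
    kernel = NA_integer_, pool = NA_integer_)
  edges <- tibble::tibble(from = ids[-length(ids)], to = ids[-1], delay = 1L)
  network_graph(nodes, edges, input_shape = as.integer(n_features),
                n_classes = as.integer(n_classes))
}

#' Serialize a network graph to JSON
#'
#' Writes nodes (in deterministic topological order, ties by id), edges and
#' shape metadata as a JSON document readable by [read_graph_json()].
#'
#' @param graph A [network_graph()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  ord <- match(graph$topo, graph$nodes$id)
  doc <- list(
    nodes = graph$nodes[ord, ],
    edges = graph$edges,
    input_shape = graph$input_shape,
    n_classes = graph$n_classes,
    depth = graph$depth)
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  network_graph(doc$nodes, doc$edges,
                input_shape = if (!is.null(doc$input_shape)) as.integer(doc$input_shape),
                n_classes = if (!is.null(doc$n_classes)) as.integer(doc$n_classes),
                depth = if (!is.null(doc$depth)) as.integer(doc$depth))
}
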