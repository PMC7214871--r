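# Operation accounting and the accuracy ratio rho.
#
# ANN cost is counted in multiply-add operations, fixed by the
# architecture and input size (identical across samples and, after
# warm-up, across rollout frames). SNN cost is counted in synaptic
# operations: every spike contributes one operation per structural target
# synapse (its source neuron's fan-out). Analog input-current injections
# and bias currents are not spikes and are not counted.

valid_span <- function(i, r, n) pmin(n, i + r) - pmax(1L, i - r) + 1L

pooled_span <- function(i, r, n) {
  ceiling(pmin(n, i + r) / 2) - ceiling(pmax(1L, i - r) / 2) + 1L
}

# Per-neuron synaptic fan-out of every (potentially spiking) node, summed
# over outgoing connections. Spatial nodes: array (H, W, C); flat nodes:
# numeric vector.
snn_fanout <- function(snn) {
  model <- snn$model
  g <- snn$graph
  out <- list()
  for (key in as.character(g$topo)) {
    if (key == as.character(g$input_id)) next
    s <- model$shape[[key]]
    base <- if (isTRUE(s$spatial)) array(0, dim = c(s$H, s$W, s$C)) else numeric(s$C)
    succ <- g$edges$to[g$edges$from == as.integer(key)]
    for (v in succ) {
      sv <- model$shape[[as.character(v)]]
      if (sv$kind %in% c("conv", "transition")) {
        r <- (sv$kernel - 1L) %/% 2L
        rows <- valid_span(seq_len(s$H), r, s$H)
        cols <- valid_span(seq_len(s$W), r, s$W)
        if (sv$kind == "transition") {
          rows <- pooled_span(seq_len(s$H), r, s$H)
          cols <- pooled_span(seq_len(s$W), r, s$W)
        }
        per_pos <- outer(rows, cols) * sv$C
        base <- base + array(rep(per_pos, s$C), dim = dim(base))
      } else { # dense or fc readout: all-to-all on the flat/GAP features
        base <- base + sv$C
      }
    }
    out[[key]] <- base
  }
  out
}

#' Count ANN multiply-add operations
#'
#' Operations per layer equal fan-in times number of output units
#' (convolutions: `k^2 * C_in * C_out * H_out * W_out`; dense layers:
#' `F_in * F_out`; average pooling: 4 per pooled unit; global average
#' pooling: one per input position). The count is a property of the
#' architecture and input size only - identical for every sample. Per
#' rollout frame, all nodes past their warm-up (a node first computes at
#' frame `1 + shortest distance from the input`) are summed; the
#' cumulative cost at output frame `k` counts all node updates in frames
#' `1..k`.
#'
#' @param model A [build_rollout_model()] model.
#' @param n_frames Number of input frames `N` for the rollout.
#' @return A list of class `ann_ops`: `per_node` tibble, `per_frame`
#'   numeric (length `K`), `cumulative_at_output` (named by output frame),
#'   `total`.
#' @examples
#' ops <- count_ann_ops(gen_fixture_network(depth = 2, seed = 1), n_frames = 2)
#' ops$per_node
#' @export
count_ann_ops <- function(model, n_frames) {
  stopifnot(inherits(model, "rollout_model"))
  schedule <- rollout(model$graph, n_frames)
  g <- model$graph
  rows <- list()
  for (key in as.character(g$topo)) {
    if (key == as.character(g$input_id)) next
    s <- model$shape[[key]]
    ops <- if (s$kind == "conv") {
      s$kernel^2 * s$in_C * s$C * s$H * s$W
    } else if (s$kind == "transition") {
      s$kernel^2 * s$in_C * s$C * s$in_H * s$in_W + 4 * s$C * s$H * s$W
    } else if (s$kind == "dense") {
      s$in_C * s$C
    } else if (isTRUE(s$gap)) {
      s$in_H * s$in_W * s$in_C + s$in_C * s$C
    } else {
      s$in_C * s$C
    }
    rows[[key]] <- tibble::tibble(node = as.integer(key), kind = s$kind,
                                  ops = ops)
  }
  per_node <- dplyr::bind_rows(rows)
  # warm-up: shortest input->node distance
  dist <- stats::setNames(rep(Inf, nrow(g$nodes)), g$nodes$id)
  dist[as.character(g$input_id)] <- 0
  for (v in g$topo) {
    if (v == g$input_id) next
    inc <- g$edges[g$edges$to == v, ]
    dist[as.character(v)] <- min(dist[as.character(inc$from)] + inc$delay)
  }
  per_frame <- vapply(seq_len(schedule$K), function(k)
    sum(per_node$ops[k >= 1 + dist[as.character(per_node$node)]]), numeric(1))
  cum <- cumsum(per_frame)
  structure(list(per_node = per_node, per_frame = per_frame,
                 cumulative_at_output = stats::setNames(
                   cum[schedule$output_frames], schedule$output_frames),
                 total = sum(per_frame), schedule = schedule),
            class = "ann_ops")
}

#' @export
print.ann_ops <- function(x, ...) {
  cat(sprintf("<ann_ops> %.3g multiply-adds over %d rollout frames (%.3g steady-state per frame)\n",
              x$total, length(x$per_frame), max(x$per_frame)))
  invisible(x)
}

#' Count SNN synaptic operations from a spike record
#'
#' Every spike is charged its source neuron's fan-out: the number of
#' structural synapses it is delivered across (all target neurons over all
#' outgoing connections of its node).
#'
#' @param snn A [build_snn()] spiking network.
#' @param record A spike record tibble `(node, neuron, step)` as returned
#'   by `snn_run(..., record_spikes = TRUE)`.
#' @return A tibble `(step, ops, cum_ops)` covering steps `1..max(step)`.
#' @export
count_snn_ops <- function(snn, record) {
  stopifnot(all(c("node", "neuron", "step") %in% names(record)))
  fan <- snn_fanout(snn)
  if (!nrow(record))
    return(tibble::tibble(step = integer(), ops = numeric(), cum_ops = numeric()))
  bad <- setdiff(unique(record$node), as.integer(names(fan)))
  if (length(bad)) stop("spike from unknown node: ", paste(bad, collapse = ", "))
  per_spike <- numeric(nrow(record))
  for (key in names(fan)) {
    sel <- record$node == as.integer(key)
    if (!any(sel)) next
    fv <- as.numeric(fan[[key]])
    if (any(record$neuron[sel] < 1L | record$neuron[sel] > length(fv)))
      stop("spike from unknown neuron in node ", key)
    per_spike[sel] <- fv[record$neuron[sel]]
  }
  steps <- seq_len(max(record$step))
  ops <- vapply(steps, function(t) sum(per_spike[record$step == t]), numeric(1))
  tibble::tibble(step = steps, ops = ops, cum_ops = cumsum(ops))
}

#' Accuracy ratio between SNN and ANN
#'
#' The ratio of the areas under the two accuracy-over-simulation-step
#' curves, `rho = AUC(SNN) / AUC(ANN)`, by rectangular integration on the
#' common per-step grid. The ANN curve is piecewise constant: each output
#' frame's accuracy held for that frame's `n_sf` steps. `rho` close to 1
#' means the SNN tracks the ANN's anytime accuracy; `rho = 1` would
#' require instantaneous rate approximation.
#'
#' @param ann_curve,snn_curve Per-step accuracy vectors on the same step
#'   grid (typically steps `l_s * n_sf + 1, ..., K * n_sf`).
#' @return Scalar `rho`.
#' @export
accuracy_ratio <- function(ann_curve, snn_curve) {
  stopifnot(length(ann_curve) == length(snn_curve))
  a <- sum(ann_curve)
  if (a <= 0) stop("ANN curve has zero area under the curve")
  sum(snn_curve) / a
}

# Expand a per-output-frame ANN accuracy curve onto the simulation-step
# axis: steps l_s*n_sf + 1 .. K*n_sf, piecewise constant per frame.
ann_curve_steps <- function(ann_curve, n_sf) {
  rep(ann_curve$accuracy, each = n_sf)
}

#' Literature energy estimates per operation
#'
#' Reported hardware energy ranges per operation, as metadata for
#' converting operation counts into rough energy figures: real-valued
#' multiply-adds on a recent FPGA architecture versus synaptic operations
#' on neuromorphic devices. These are cited estimates, never asserted by
#' any computation in this package; the trade-off varies strongly between
#' accelerators.
#'
#' @return A tibble with columns `operation`, `platform`, `pj_min`,
#'   `pj_max` (picojoules).
#' @export
energy_per_op_estimates <- function() {
  tibble::tibble(
    operation = c("multiply-add", "synaptic op"),
    platform = c("FPGA", "neuromorphic"),
    pj_min = c(555, 2.8),
    pj_max = c(1295.4, 360))
}

#' Sweep simulation steps per frame
#'
#' For each value of `n_sf`: convert the model (single percentile
#' calibration shared across the sweep), simulate the SNN over the
#' dataset, and compute the accuracy ratio `rho` and the operation counts.
#' Used to pick the smallest `n_sf` at which `rho` saturates - the
#' accuracy/energy trade-off.
#'
#' @param model A trained [build_rollout_model()] model.
#' @param x,y Evaluation inputs and labels (typically a random
#'   subset of the training set).
#' @param n_sf Integer vector of simulation-steps-per-frame values.
#' @param percentile Calibration percentile (see
#'   [calibrate_percentiles()]).
#' @param calib_x Calibration inputs (default: `x`).
#' @param batch_size Simulation batch size.
#' @return A tibble of class `nsf_sweep` with columns `n_sf`, `rho`,
#'   `ann_mops`, `snn_mops` (millions of operations for a full rollout,
#'   per sample), sorted by `n_sf`.
#' @export
sweep_nsf <- function(model, x, y, n_sf = c(5L, 15L, 35L), percentile = 99.9,
                      calib_x = NULL, batch_size = 64L) {
  stopifnot(inherits(model, "rollout_model"))
  x <- as_input_tensor(model, x)
  if (is.null(calib_x)) calib_x <- x
  lambda <- calibrate_percentiles(model, calib_x, p = percentile)
  ann <- ann_accuracy_curve(model, x, y)
  ann_ops <- count_ann_ops(model, dim(x)[2])
  rows <- lapply(sort(as.integer(n_sf)), function(nsf) {
    snn <- build_snn(model, lambda, n_sf = nsf)
    snn_curve <- snn_accuracy_curve(snn, x, y, batch_size = batch_size,
                                    count_ops = TRUE)
    sched <- ann_ops$schedule
    grid <- (sched$l_s * nsf + 1L):(sched$K * nsf)
    rho <- accuracy_ratio(ann_curve_steps(ann, nsf),
                          snn_curve$accuracy[grid])
    ops <- attr(snn_curve, "ops_per_step")
    tibble::tibble(n_sf = nsf, rho = rho,
                   ann_mops = ann_ops$total / 1e6,
                   snn_mops = ops[length(ops)] / 1e6)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nsf_sweep", class(out))
  out
}
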