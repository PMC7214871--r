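# Time-stepped simulation of the converted integrate-and-fire network.
#
# Dynamics per neuron and step: add all delayed weighted presynaptic
# spikes plus the constant bias current (input-layer targets additionally
# receive the analog frame value as a constant current); if V >= V_th emit
# one spike and subtract V_th; clamp V at V_min. At most one spike per
# neuron per step - neurons driven beyond rate 1 saturate. Membrane
# potentials persist across rollout-frame boundaries, which carries
# information forward and speeds up re-convergence when the input changes
# slowly.

#' Simulate a spiking network on a frame sequence
#'
#' Runs the converted IF network for `T_tot = n_sf * K` steps, where `K`
#' is the rollout length for `N` input frames: frame `k` drives steps
#' `(k-1) * n_sf + 1, ..., k * n_sf` as a constant analog input current
#' (divided by the input node's `lambda`). All membrane potentials start
#' at `V(0) = 0`. Spikes travel along every connection with the axonal
#' delay `d = n_sf` set at conversion; the prediction at each step is the
#' argmax of the readout node's weighted input summed over the trailing
#' `min(t, n_sf)` steps (ties broken toward the lowest class index).
#'
#' @param snn A [build_snn()] spiking network.
#' @param x Input frames as for [forward_rollout()] (same preprocessing as
#'   ANN training).
#' @param record_spikes Return the full spike record as a tibble
#'   `(node, neuron, step)`; single-sample input only.
#' @param count_ops Accumulate synaptic operations per step (one op per
#'   spike per structural target synapse; analog input currents and bias
#'   currents are not spikes and are not counted).
#' @return An object of class `snn_run`: list with `predictions`
#'   (batch x steps), `readout` (steps x classes, windowed sums, batch
#'   mean), per-node total `spike_counts`, `ops_per_step` (per-sample mean
#'   cumulative synaptic ops) if requested, `spike_record` if requested,
#'   plus `n_sf`, `K`, `T` and the schedule.
#' @export
snn_run <- function(snn, x, record_spikes = FALSE, count_ops = FALSE) {
  stopifnot(inherits(snn, "spiking_network"))
  model <- snn$model
  x <- as_input_tensor(model, x)
  B <- dim(x)[1]
  if (record_spikes && B != 1L)
    stop("record_spikes requires a single sample")
  schedule <- rollout(snn$graph, dim(x)[2])
  n_sf <- snn$n_sf
  T_tot <- schedule$K * n_sf
  g <- snn$graph
  in_key <- as.character(g$input_id)
  out_key <- as.character(g$output_id)
  lam_in <- snn$lambda[in_key]
  if (is.na(lam_in)) lam_in <- 1

  max_delay <- max(snn$delays)
  if (max_delay != n_sf * max(g$edges$delay))
    stop("n_sf mismatch between network delays and simulation")
  hidden_keys <- setdiff(as.character(g$topo), c(in_key, out_key))

  V <- list(); ring <- list()
  L <- as.integer(max_delay)
  for (key in c(in_key, hidden_keys)) {
    s <- model$shape[[key]]
    if (key != in_key) V[[key]] <- zero_act(s, B)
    ring[[key]] <- vector("list", L)
  }
  fan <- if (count_ops) snn_fanout(snn) else NULL
  spike_counts <- stats::setNames(
    lapply(hidden_keys, function(key) zero_act(model$shape[[key]], B)),
    hidden_keys)
  ops <- if (count_ops) numeric(T_tot) else NULL
  rec <- if (record_spikes) list() else NULL

  window <- matrix(0, B, model$n_classes) # running readout window sum
  zring <- vector("list", n_sf)
  predictions <- matrix(0L, B, T_tot)
  readout_mean <- matrix(0, T_tot, model$n_classes)

  delay_of <- stats::setNames(as.integer(snn$delays), names(snn$delays))
  gather_delayed <- function(s, t) {
    parts <- vector("list", nrow(s$preds))
    for (i in seq_len(nrow(s$preds))) {
      pid <- as.character(s$preds$id[i])
      d <- delay_of[paste0(s$preds$id[i], "->", s$node_id)]
      src <- NULL
      if (t - d >= 1L) src <- ring[[pid]][[((t - d - 1L) %% L) + 1L]]
      parts[[i]] <- if (is.null(src)) zero_act(model$shape[[pid]], B) else src
    }
    if (is.matrix(parts[[1L]])) do.call(cbind, parts) else concat_spatial(parts)
  }

  # cache node_id inside shapes for edge lookup
  for (key in names(model$shape)) model$shape[[key]]$node_id <- as.integer(key)

  for (t in seq_len(T_tot)) {
    frame <- schedule$input_assignment[ceiling(t / n_sf)]
    input_act <- input_slice(model, x, frame)
    input_act <- input_act / lam_in
    new_spikes <- list()
    for (key in hidden_keys) {
      s <- model$shape[[key]]
      p <- model$params[[key]]
      Xin <- gather_delayed(s, t)
      current <- if (s$kind == "conv") conv_forward_pre(Xin, p$W, p$b, s$kernel)
        else if (s$kind == "transition") avgpool2(conv_forward_pre(Xin, p$W, p$b, s$kernel))
        else sweep(Xin %*% p$W, 2L, p$b, "+")
      if (any(!is.finite(current)))
        stop("non-finite membrane input at node ", key, ", step ", t)
      Vk <- V[[key]] + current
      sp <- (Vk >= snn$v_th) * 1
      Vk <- Vk - snn$v_th * sp
      Vk[Vk < snn$v_min] <- snn$v_min
      V[[key]] <- Vk
      new_spikes[[key]] <- sp
      spike_counts[[key]] <- spike_counts[[key]] + sp
      if (count_ops) ops[t] <- ops[t] + sum_spike_ops(sp, fan[[key]])
      if (record_spikes) {
        idx <- which(as.numeric(sp) > 0)
        if (length(idx))
          rec[[length(rec) + 1L]] <- tibble::tibble(node = as.integer(key),
                                                    neuron = idx, step = t)
      }
    }
    # readout: non-spiking accumulator of delayed weighted input
    s <- model$shape[[out_key]]
    p <- model$params[[out_key]]
    Xin <- gather_delayed(s, t)
    G <- if (isTRUE(s$gap)) gap_forward(Xin) else Xin
    z <- sweep(G %*% p$W, 2L, p$b, "+")
    slot <- ((t - 1L) %% n_sf) + 1L
    old <- zring[[slot]]
    window <- window + z - (if (is.null(old)) 0 else old)
    zring[[slot]] <- z
    predictions[, t] <- max.col(window, ties.method = "first")
    readout_mean[t, ] <- colMeans(window)
    # advance delay lines (input carries the analog frame value)
    wslot <- ((t - 1L) %% L) + 1L
    ring[[in_key]][[wslot]] <- input_act
    for (key in hidden_keys) ring[[key]][[wslot]] <- new_spikes[[key]]
  }
  res <- list(predictions = predictions, readout = readout_mean,
              spike_counts = spike_counts,
              total_spikes = vapply(spike_counts, sum, numeric(1)) / B,
              n_sf = n_sf, K = schedule$K, T = T_tot, schedule = schedule)
  if (count_ops) res$ops_per_step <- cumsum(ops) / B
  if (record_spikes)
    res$spike_record <- if (length(rec)) dplyr::bind_rows(rec)
      else tibble::tibble(node = integer(), neuron = integer(), step = integer())
  class(res) <- "snn_run"
  res
}

sum_spike_ops <- function(sp, fanout) {
  if (is.null(fanout)) return(0)
  if (is.matrix(sp)) sum(sp %*% fanout)
  else {
    d <- dim(sp)
    spm <- sp; dim(spm) <- c(d[1], prod(d[-1]))
    sum(spm %*% as.numeric(fanout))
  }
}

#' @export
print.snn_run <- function(x, ...) {
  cat(sprintf("<snn_run> %d samples, %d steps (%d frames x n_sf = %d), %.0f spikes/sample\n",
              nrow(x$predictions), x$T, x$K, x$n_sf, sum(x$total_spikes)))
  invisible(x)
}

#' @rdname snn_run
#' @param x An `snn_run` object.
#' @param ... Unused.
#' @export
tidy.snn_run <- function(x, ...) {
  tibble::tibble(step = seq_len(x$T),
                 frame = ceiling(seq_len(x$T) / x$n_sf),
                 prediction = if (nrow(x$predictions) == 1L)
                   as.integer(x$predictions[1L, ]) else NA_integer_)
}

#' Per-step (and per-frame) accuracy of the spiking network
#'
#' Simulates the SNN over a labelled dataset and averages per-step
#' prediction correctness over samples; the per-frame accuracy is the mean
#' over that frame's `n_sf` steps (equivalently, predictions averaged over
#' the last `n_sf` steps of the frame window).
#'
#' @param snn A [build_snn()] spiking network.
#' @param x,y Dataset inputs and 1-based labels.
#' @param batch_size Simulation batch size (memory scales with
#'   `batch_size * n_sf`).
#' @param count_ops Also accumulate mean cumulative synaptic operations
#'   per step (attached as attribute `ops_per_step`).
#' @return A tibble of class `accuracy_curve` with columns `step`,
#'   `frame`, `accuracy`, `n`.
#' @export
snn_accuracy_curve <- function(snn, x, y, batch_size = 64L, count_ops = FALSE) {
  x <- as_input_tensor(snn$model, x)
  y <- as.integer(y)
  B_all <- dim(x)[1]
  correct <- NULL; ops <- NULL
  for (start in seq(1L, B_all, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B_all)
    xs <- if (snn$model$spatial_input) x[idx, , , , , drop = FALSE]
      else x[idx, , , drop = FALSE]
    run <- snn_run(snn, xs, count_ops = count_ops)
    hit <- sweep(run$predictions, 1L, y[idx], "==")
    correct <- if (is.null(correct)) colSums(hit) else correct + colSums(hit)
    if (count_ops)
      ops <- if (is.null(ops)) run$ops_per_step * length(idx)
        else ops + run$ops_per_step * length(idx)
    T_tot <- run$T; n_sf <- run$n_sf
  }
  out <- tibble::tibble(step = seq_len(T_tot),
                        frame = ceiling(seq_len(T_tot) / n_sf),
                        accuracy = correct / B_all, n = B_all)
  class(out) <- c("accuracy_curve", class(out))
  attr(out, "kind") <- "snn"
  if (count_ops) attr(out, "ops_per_step") <- ops / B_all
  out
}

#' Summarise an accuracy curve per frame
#'
#' @param curve An `accuracy_curve` tibble from [snn_accuracy_curve()] or
#'   [ann_accuracy_curve()].
#' @return A tibble with one row per frame.
#' @export
frame_accuracy <- function(curve) {
  if (!"frame" %in% names(curve)) return(curve)
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(curve), .data$frame),
                   accuracy = mean(.data$accuracy), .groups = "drop")
}
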