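# ANN-to-SNN conversion: percentile calibration of activations, parameter
# rescaling, and construction of the spiking network with matched axonal
# delays.
#
# Conversion maps ReLU activations to integrate-and-fire spike rates.
# Because a rate is bounded by one spike per simulation step, each layer's
# parameters are rescaled so that a chosen percentile of its training-set
# activations maps to rate 1: weights into node l are multiplied by
# lambda_source / lambda_l (each concatenated input branch by its own
# source lambda), biases by 1 / lambda_l. The rescaled network computes
# exactly a_l / lambda_l, so the readout argmax is unchanged.

#' Calibrate per-layer activation percentiles
#'
#' Runs the rollout forward over a calibration set and computes, for every
#' node separately, the `p`-th percentile of all its activation values
#' pooled across calibration samples and across all rollout frames (one
#' pass). Pooling over rollout frames is required because activations
#' change over time in a rollout. The input node's percentile is computed
#' from the raw input frame values; transition (average-pooling) nodes are
#' calibrated like any other layer. The readout node is assigned
#' `lambda = 1`: it is converted to a non-spiking accumulator, so its
#' scores stay on the ANN scale (and may be negative). A node whose pooled
#' activations are all zero gets `lambda = 1` with a warning.
#'
#' @param model A trained [build_rollout_model()] model.
#' @param x Calibration inputs (see [forward_rollout()]); the typical
#'   choice is a subset of the training set.
#' @param p Percentile in `(0, 100]` (default 99.9, the robust default of
#'   the conversion literature).
#' @param batch_size Forward batch size.
#' @return Named numeric vector of scale factors `lambda`, one per node id.
#' @export
calibrate_percentiles <- function(model, x, p = 99.9, batch_size = 64L) {
  stopifnot(inherits(model, "rollout_model"), p > 0, p <= 100)
  x <- as_input_tensor(model, x)
  B_all <- dim(x)[1]
  stopifnot(B_all >= 1)
  schedule <- rollout(model$graph, dim(x)[2])
  g <- model$graph
  keys <- as.character(g$topo)
  pool <- stats::setNames(vector("list", length(keys)), keys)
  for (start in seq(1L, B_all, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B_all)
    xs <- if (model$spatial_input) x[idx, , , , , drop = FALSE]
      else x[idx, , , drop = FALSE]
    fwd <- forward_rollout(model, xs, schedule, keep_activations = TRUE)
    for (k in seq_len(schedule$K)) for (key in names(fwd$activations[[k]])) {
      v <- as.numeric(fwd$activations[[k]][[key]])
      pool[[key]] <- c(pool[[key]], v)
    }
  }
  lambda <- stats::setNames(rep(1, length(keys)), keys)
  out_key <- as.character(g$output_id)
  for (key in keys) {
    if (key == out_key) next # readout stays on the ANN scale
    v <- pool[[key]]
    lam <- stats::quantile(v, p / 100, names = FALSE, type = 7)
    if (!is.finite(lam) || lam <= 0) {
      warning("node ", key, ": all-zero activations, lambda set to 1")
      lam <- 1
    }
    lambda[key] <- lam
  }
  lambda
}

#' Rescale model parameters by per-layer scale factors
#'
#' Applies the linear conversion map: for every non-input node `l`, each
#' weight row is multiplied by the `lambda` of the source channel's node
#' and the whole weight matrix and bias are divided by `lambda_l`.
#' Concatenated (dense) inputs are scaled branch-wise by their own source
#' `lambda`. If the input is also divided by `lambda_input`, every
#' activation of the rescaled network equals the original activation
#' divided by that node's `lambda` - an exact per-layer linear map, so
#' with `lambda = 1` everywhere the model is unchanged and the readout
#' argmax is always preserved.
#'
#' @param model A [build_rollout_model()] model.
#' @param lambda Named numeric vector of per-node scale factors (names =
#'   node ids); missing nodes default to 1.
#' @return The model with rescaled parameters and `lambda` attached.
#' @export
rescale_model <- function(model, lambda) {
  stopifnot(inherits(model, "rollout_model"))
  lam <- function(id) {
    v <- lambda[as.character(id)]
    if (is.na(v)) 1 else unname(v)
  }
  for (key in names(model$params)) {
    s <- model$shape[[key]]
    chan_scale <- unlist(lapply(seq_len(nrow(s$preds)), function(i)
      rep(lam(s$preds$id[i]), s$preds$C[i])))
    row_scale <- if (s$kind %in% c("conv", "transition"))
      rep(chan_scale, times = s$kernel^2) else chan_scale
    model$params[[key]]$W <- model$params[[key]]$W * row_scale / lam(key)
    model$params[[key]]$b <- model$params[[key]]$b / lam(key)
  }
  model$lambda <- lambda
  model
}

#' Build a spiking network from a trained rollout model
#'
#' Converts the (percentile-rescaled) ANN into an integrate-and-fire
#' network that mirrors the network graph. Every neuron is a non-leaky IF
#' unit with threshold `v_th = 1`, subtractive reset and a lower membrane
#' bound `v_min`; every connection's axonal delay is set to
#' `d = n_sf * d_ANN` simulation steps, so information propagates exactly
#' as prescribed by the streaming rollout when each input frame is held
#' for `n_sf` steps. The readout node is a non-spiking accumulator whose
#' windowed weighted input drives the argmax prediction. Simulating `K`
#' rollout frames takes `T_tot = n_sf * K` steps.
#'
#' @param model A trained [build_rollout_model()] model.
#' @param lambda Per-node scale factors from [calibrate_percentiles()]
#'   (or `NULL` for no rescaling).
#' @param n_sf Simulation steps per rollout frame (>= 1).
#' @param v_th Firing threshold (default 1).
#' @param v_min Membrane lower bound (default 0).
#' @return An object of class `spiking_network`.
#' @examples
#' m <- gen_fixture_network(depth = 2, seed = 1)
#' snn <- build_snn(m, lambda = NULL, n_sf = 15)
#' snn$delays
#' @export
build_snn <- function(model, lambda, n_sf, v_th = 1, v_min = 0) {
  stopifnot(inherits(model, "rollout_model"), n_sf >= 1)
  n_sf <- as.integer(n_sf)
  if (is.null(lambda))
    lambda <- stats::setNames(rep(1, nrow(model$graph$nodes)),
                              as.character(model$graph$nodes$id))
  rescaled <- rescale_model(model, lambda)
  delays <- stats::setNames(n_sf * model$graph$edges$delay,
                            paste0(model$graph$edges$from, "->",
                                   model$graph$edges$to))
  structure(list(model = rescaled, graph = model$graph,
                 lambda = lambda, n_sf = n_sf,
                 delays = delays, v_th = v_th, v_min = v_min),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("<spiking_network> %d nodes, n_sf = %d (all delays = %d steps), V_th = %g, V_min = %g\n",
              nrow(x$graph$nodes), x$n_sf, x$n_sf, x$v_th, x$v_min))
  invisible(x)
}
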