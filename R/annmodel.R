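# Weight-shared streaming-rollout ANN: model construction, forward pass,
# multi-output loss, and backpropagation-through-time training.
#
# One parameter set exists per graph node and is reused at every rollout
# frame; gradients from all frames therefore accumulate into the same
# weights. All hidden activations are ReLU and all pooling is average
# pooling, the assumptions under which conversion to integrate-and-fire
# spiking neurons is exact in the rate limit.

new_seed_scope <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  old
}
restore_seed_scope <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build a weight-shared rollout model from a network graph
#'
#' Resolves layer shapes along the graph (channel concatenation of all
#' predecessors, spatial halving at transitions) and initialises one shared
#' parameter set per node (He-scaled Gaussian weights, zero biases).
#'
#' @param graph A [network_graph()] with `input_shape` and `n_classes` set.
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `rollout_model`.
#' @examples
#' m <- build_rollout_model(graph_skip_example(), seed = 1)
#' @export
build_rollout_model <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "network_graph"))
  old <- new_seed_scope(seed); on.exit(restore_seed_scope(old))
  spatial_input <- length(graph$input_shape) == 3L
  shape <- list(); params <- list()
  for (id in graph$topo) {
    node <- graph$nodes[graph$nodes$id == id, ]
    key <- as.character(id)
    if (node$kind == "input") {
      shape[[key]] <- if (spatial_input)
        list(kind = "input", spatial = TRUE, H = graph$input_shape[2],
             W = graph$input_shape[3], C = graph$input_shape[1])
      else list(kind = "input", spatial = FALSE, C = graph$input_shape[1])
      next
    }
    inc <- graph$edges[graph$edges$to == id, ]
    inc <- inc[order(inc$from), ]
    preds <- lapply(as.character(inc$from), function(p) shape[[p]])
    pred_spatial <- vapply(preds, `[[`, logical(1), "spatial")
    in_C <- sum(vapply(preds, `[[`, numeric(1), "C"))
    s <- list(kind = node$kind,
              preds = tibble::tibble(id = inc$from, delay = inc$delay,
                                     C = vapply(preds, `[[`, numeric(1), "C")),
              in_C = in_C)
    if (node$kind %in% c("conv", "transition")) {
      if (!all(pred_spatial)) stop("node ", id, ": conv inputs must be spatial")
      Hs <- unique(vapply(preds, `[[`, numeric(1), "H"))
      Ws <- unique(vapply(preds, `[[`, numeric(1), "W"))
      if (length(Hs) != 1L || length(Ws) != 1L)
        stop("node ", id, ": predecessor spatial sizes differ")
      k <- if (is.na(node$kernel)) 3L else node$kernel
      s$spatial <- TRUE; s$kernel <- k; s$in_H <- Hs; s$in_W <- Ws
      if (node$kind == "transition") {
        if (Hs %% 2L || Ws %% 2L)
          stop("node ", id, ": spatial size ", Hs, "x", Ws,
               " not divisible by pooling factor 2")
        s$H <- Hs %/% 2L; s$W <- Ws %/% 2L
      } else { s$H <- Hs; s$W <- Ws }
      s$C <- node$channels
      params[[key]] <- list(
        W = matrix(stats::rnorm(k * k * in_C * s$C, sd = sqrt(2 / (k * k * in_C))),
                   k * k * in_C, s$C),
        b = numeric(s$C))
    } else if (node$kind == "dense") {
      if (any(pred_spatial)) stop("node ", id, ": dense inputs must be flat")
      s$spatial <- FALSE; s$C <- node$channels
      params[[key]] <- list(
        W = matrix(stats::rnorm(in_C * s$C, sd = sqrt(2 / in_C)), in_C, s$C),
        b = numeric(s$C))
    } else { # fc head: GAP + linear readout (spatial) or linear (flat)
      s$spatial <- FALSE
      s$gap <- all(pred_spatial)
      if (s$gap) {
        Hs <- unique(vapply(preds, `[[`, numeric(1), "H"))
        Ws <- unique(vapply(preds, `[[`, numeric(1), "W"))
        if (length(Hs) != 1L || length(Ws) != 1L)
          stop("node ", id, ": predecessor spatial sizes differ")
        s$in_H <- Hs; s$in_W <- Ws
      }
      s$C <- graph$n_classes
      params[[key]] <- list(
        W = matrix(stats::rnorm(in_C * s$C, sd = sqrt(1 / in_C)), in_C, s$C),
        b = numeric(s$C))
    }
    shape[[key]] <- s
  }
  structure(list(graph = graph, shape = shape, params = params,
                 n_classes = graph$n_classes, spatial_input = spatial_input,
                 history = NULL),
            class = "rollout_model")
}

#' @export
print.rollout_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<rollout_model> %d nodes, %d parameters%s\n",
              nrow(x$graph$nodes), np,
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

n_parameters <- function(model)
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))

zero_act <- function(s, B) {
  if (isTRUE(s$spatial)) array(0, dim = c(B, s$H, s$W, s$C))
  else matrix(0, B, s$C)
}

apply_channel_mask <- function(Y, m) {
  if (is.matrix(Y)) return(Y * m)
  for (c in seq_len(dim(Y)[4])) Y[, , , c] <- Y[, , , c] * m[, c]
  Y
}

gather_input <- function(model, acts, s, k, B) {
  parts <- vector("list", nrow(s$preds))
  for (i in seq_len(nrow(s$preds))) {
    kk <- k - s$preds$delay[i]
    key <- as.character(s$preds$id[i])
    parts[[i]] <- if (kk >= 1L && !is.null(acts[[kk]][[key]]))
      acts[[kk]][[key]] else zero_act(model$shape[[key]], B)
  }
  if (is.matrix(parts[[1L]])) do.call(cbind, parts) else concat_spatial(parts)
}

node_forward <- function(s, p, Xin) {
  if (s$kind == "conv") {
    relu(conv_forward_pre(Xin, p$W, p$b, s$kernel))
  } else if (s$kind == "transition") {
    relu(avgpool2(conv_forward_pre(Xin, p$W, p$b, s$kernel)))
  } else if (s$kind == "dense") {
    relu(sweep(Xin %*% p$W, 2L, p$b, "+"))
  } else { # fc: linear readout
    G <- if (isTRUE(s$gap)) gap_forward(Xin) else Xin
    sweep(G %*% p$W, 2L, p$b, "+")
  }
}

#' Forward pass of the streaming rollout
#'
#' Computes all node activations over the `K` rollout frames. At frame `k`
#' every node reads only activations from frame `k - d` of its predecessors
#' (d = edge delay), so the whole frame updates in parallel; frames before
#' the first input and unreachable predecessors contribute zeros. Class
#' scores are emitted by the readout node at frames `l_s + 1, ..., K` and
#' returned as post-softmax probabilities.
#'
#' @param model A [build_rollout_model()] model.
#' @param x Input frames: array `(batch, N, C, H, W)` for image input (or a
#'   single sample `(N, C, H, W)` / a [frame_sequence()]), `(batch, N, F)`
#'   for flat input.
#' @param schedule Optional [rollout()] schedule; derived from `N` otherwise.
#' @param keep_activations Keep all node activations (needed for
#'   calibration and training).
#' @param dropout_masks Optional per-node channel masks (training only).
#' @return List with `probs` (batch x outputs x classes), `logits`,
#'   `output_frames`, `schedule`, and `activations` if requested.
#' @export
forward_rollout <- function(model, x, schedule = NULL,
                            keep_activations = FALSE, dropout_masks = NULL) {
  stopifnot(inherits(model, "rollout_model"))
  x <- as_input_tensor(model, x)
  B <- dim(x)[1]; N <- dim(x)[2]
  if (is.null(schedule)) schedule <- rollout(model$graph, N)
  g <- model$graph
  in_key <- as.character(g$input_id)
  acts <- vector("list", schedule$K)
  for (k in seq_len(schedule$K)) {
    acts[[k]] <- list()
    f <- schedule$input_assignment[k]
    acts[[k]][[in_key]] <- input_slice(model, x, f)
    for (id in g$topo) {
      if (id == g$input_id) next
      key <- as.character(id)
      s <- model$shape[[key]]
      Xin <- gather_input(model, acts, s, k, B)
      Y <- node_forward(s, model$params[[key]], Xin)
      if (!is.null(dropout_masks[[key]]))
        Y <- apply_channel_mask(Y, dropout_masks[[key]])
      acts[[k]][[key]] <- Y
    }
  }
  out_key <- as.character(g$output_id)
  n_out <- length(schedule$output_frames)
  logits <- array(0, dim = c(B, n_out, model$n_classes))
  for (i in seq_along(schedule$output_frames))
    logits[, i, ] <- acts[[schedule$output_frames[i]]][[out_key]]
  probs <- logits
  for (i in seq_len(n_out)) {
    Z <- logits[, i, ]
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = B)
    probs[, i, ] <- softmax_rows(Z)
  }
  res <- list(probs = probs, logits = logits,
              output_frames = schedule$output_frames, schedule = schedule)
  if (keep_activations) res$activations <- acts
  res
}

as_input_tensor <- function(model, x) {
  if (inherits(x, "frame_sequence")) {
    d <- dim(x)
    x <- array(x, dim = c(1L, d))
    return(x)
  }
  nd_expect <- if (model$spatial_input) 5L else 3L
  if (length(dim(x)) == nd_expect - 1L) {
    x <- array(x, dim = c(1L, dim(x)))
  }
  if (length(dim(x)) != nd_expect)
    stop("input tensor must have ", nd_expect, " dimensions (batch, frames, ...)")
  if (model$spatial_input) {
    ins <- model$graph$input_shape
    if (!all(dim(x)[3:5] == ins))
      stop(sprintf("input shape mismatch at input node: got %s, expected %s",
                   paste(dim(x)[3:5], collapse = "x"),
                   paste(ins, collapse = "x")))
  } else if (dim(x)[3] != model$graph$input_shape[1]) {
    stop(sprintf("input shape mismatch at input node: got %d features, expected %d",
                 dim(x)[3], model$graph$input_shape[1]))
  }
  x
}

input_slice <- function(model, x, f) {
  B <- dim(x)[1]
  s <- model$shape[[as.character(model$graph$input_id)]]
  if (f == 0L) return(zero_act(s, B))
  if (model$spatial_input) {
    sl <- x[, f, , , , drop = FALSE]
    dim(sl) <- dim(x)[-2]
    aperm(sl, c(1L, 3L, 4L, 2L)) # (B, C, H, W) -> (B, H, W, C)
  } else {
    sl <- x[, f, , drop = FALSE]
    dim(sl) <- dim(x)[-2]
    sl
  }
}

#' Loss weighting schemes over output frames
#'
#' Builds the per-output weights `a_k` that trade off early against late
#' accuracy in the multi-output loss, normalised so that `sum(a_k) = 1`.
#' Schemes (`k` the absolute output frame index): `uniform` (`a_k = 1`),
#' `linear-increasing` (`a_k = k + 1`), `exp-increasing` (`a_k = exp(k)`),
#' `first-only` (all mass on the first output), `inverse`
#' (`a_k = 1 / (k + 1)`), `exp-decreasing` (`a_k = exp(-k)`), `last-only`
#' (all mass on the last output).
#'
#' @param scheme Scheme name (see above).
#' @param output_frames Integer vector of output frame indices.
#' @return A tibble with columns `frame` and `weight` (`sum(weight) == 1`).
#' @examples
#' make_loss_weights("uniform", 3:6)
#' @export
make_loss_weights <- function(scheme = c("uniform", "linear-increasing",
                                         "exp-increasing", "first-only",
                                         "inverse", "exp-decreasing",
                                         "last-only"),
                              output_frames) {
  scheme <- match.arg(scheme)
  k <- as.numeric(output_frames)
  w <- switch(scheme,
    "uniform" = rep(1, length(k)),
    "linear-increasing" = k + 1,
    "exp-increasing" = exp(k - max(k)),
    "first-only" = as.numeric(seq_along(k) == 1L),
    "inverse" = 1 / (k + 1),
    "exp-decreasing" = exp(-(k - min(k))),
    "last-only" = as.numeric(seq_along(k) == length(k)))
  tibble::tibble(frame = as.integer(output_frames), weight = w / sum(w))
}

#' Weighted multi-output cross-entropy loss
#'
#' `L = sum_k -a_k * log(y_k[true class])`, the categorical cross entropy
#' summed over all rollout outputs with trade-off weights `a_k`; the target
#' class is the same at every output. Probabilities are clamped at `eps`
#' before the log. For a batch the mean over samples is returned.
#'
#' @param probs Probabilities: matrix (outputs x classes) or array
#'   (batch x outputs x classes), e.g. `forward_rollout(...)$probs`.
#' @param label True class index (1-based), length 1 or batch.
#' @param weights A [make_loss_weights()] tibble or numeric vector of
#'   per-output weights.
#' @param eps Clamp for `log` (default 1e-12).
#' @return Scalar loss.
#' @export
rollout_loss <- function(probs, label, weights, eps = 1e-12) {
  if (is.data.frame(weights)) weights <- weights$weight
  if (is.matrix(probs)) probs <- array(probs, dim = c(1L, dim(probs)))
  B <- dim(probs)[1]; n_out <- dim(probs)[2]
  stopifnot(length(weights) == n_out)
  label <- rep_len(as.integer(label), B)
  total <- 0
  for (i in seq_len(n_out)) {
    p <- probs[cbind(seq_len(B), i, label)]
    total <- total - weights[i] * sum(log(pmax(p, eps)))
  }
  total / B
}

# Forward + backward pass: loss and parameter gradients for one batch.
# Activation decay adds an L2 penalty on all hidden (post-ReLU) activations
# summed over rollout frames; weight decay is handled by the optimizer.
rollout_grads <- function(model, x, y, weights, schedule = NULL,
                          act_decay = 0, dropout_masks = NULL, eps = 1e-12) {
  fwd <- forward_rollout(model, x, schedule, keep_activations = TRUE,
                         dropout_masks = dropout_masks)
  schedule <- fwd$schedule
  x <- as_input_tensor(model, x)
  B <- dim(x)[1]
  g <- model$graph
  acts <- fwd$activations
  out_key <- as.character(g$output_id)
  y <- rep_len(as.integer(y), B)

  grads <- lapply(model$params, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b))))
  gacts <- vector("list", schedule$K)
  for (k in seq_len(schedule$K)) gacts[[k]] <- list()

  loss <- rollout_loss(fwd$probs, y, weights, eps)
  if (act_decay > 0) {
    assq <- 0
    for (k in seq_len(schedule$K)) for (key in names(acts[[k]]))
      if (key != as.character(g$input_id) && key != out_key)
        assq <- assq + sum(acts[[k]][[key]]^2)
    loss <- loss + act_decay * assq / B
  }

  # seed gradients at the readout frames: a_k * (softmax - onehot) / B
  wv <- if (is.data.frame(weights)) weights$weight else weights
  for (i in seq_along(schedule$output_frames)) {
    k <- schedule$output_frames[i]
    P <- fwd$probs[, i, , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, nrow = B)
    P[cbind(seq_len(B), y)] <- P[cbind(seq_len(B), y)] - 1
    seed <- wv[i] * P / B
    gacts[[k]][[out_key]] <- if (is.null(gacts[[k]][[out_key]])) seed
      else gacts[[k]][[out_key]] + seed
  }

  rev_topo <- rev(g$topo)
  for (k in rev(seq_len(schedule$K))) {
    for (id in rev_topo) {
      if (id == g$input_id) next
      key <- as.character(id)
      s <- model$shape[[key]]
      G <- gacts[[k]][[key]]
      hidden <- s$kind %in% c("conv", "transition", "dense")
      if (act_decay > 0 && hidden) {
        pen <- 2 * act_decay * acts[[k]][[key]] / B
        G <- if (is.null(G)) pen else G + pen
      }
      if (is.null(G)) next
      if (!is.null(dropout_masks[[key]]))
        G <- apply_channel_mask(G, dropout_masks[[key]])
      p <- model$params[[key]]
      Xin <- gather_input(model, acts, s, k, B)
      if (s$kind == "conv") {
        dZ <- G * (acts[[k]][[key]] > 0)
        bk <- conv_backward(Xin, dZ, p$W, s$kernel)
      } else if (s$kind == "transition") {
        dZp <- G * (acts[[k]][[key]] > 0)
        dZc <- avgpool2_backward(dZp, s$in_H, s$in_W)
        bk <- conv_backward(Xin, dZc, p$W, s$kernel)
      } else if (s$kind == "dense") {
        dZ <- G * (acts[[k]][[key]] > 0)
        bk <- list(dW = crossprod(Xin, dZ), db = colSums(dZ),
                   dX = dZ %*% t(p$W))
      } else { # fc (linear readout)
        Gin <- if (isTRUE(s$gap)) gap_forward(Xin) else Xin
        dX <- G %*% t(p$W)
        if (isTRUE(s$gap)) dX <- gap_backward(dX, s$in_H, s$in_W)
        bk <- list(dW = crossprod(Gin, G), db = colSums(G), dX = dX)
      }
      grads[[key]]$W <- grads[[key]]$W + bk$dW
      grads[[key]]$b <- grads[[key]]$b + bk$db
      # route input gradient to predecessors at frame k - delay
      sizes <- s$preds$C
      parts <- if (is.matrix(bk$dX)) {
        at <- 0L
        lapply(sizes, function(sz) {
          out <- bk$dX[, at + seq_len(sz), drop = FALSE]; at <<- at + sz; out })
      } else split_channels(bk$dX, sizes)
      for (i in seq_len(nrow(s$preds))) {
        kk <- k - s$preds$delay[i]
        pid <- s$preds$id[i]
        if (kk < 1L || pid == g$input_id) next
        pk <- as.character(pid)
        gacts[[kk]][[pk]] <- if (is.null(gacts[[kk]][[pk]])) parts[[i]]
          else gacts[[kk]][[pk]] + parts[[i]]
      }
    }
  }
  list(loss = loss, grads = grads, probs = fwd$probs)
}

#' Train a rollout model by backpropagation through time
#'
#' Minimises the weighted multi-output cross entropy ([rollout_loss()]) over
#' the streaming rollout with Adam, sharing weights across rollout frames
#' (gradients from all frames accumulate into the single per-node parameter
#' set). Regularisation: L2 weight decay, optional L2 activation decay (for
#' sparser activations, which reduces spiking cost after conversion) and
#' spatial dropout (per-channel masks, shared across rollout frames of a
#' sample, training only). After every epoch the accuracy of the final
#' output on a held-out validation split is evaluated and the best-scoring
#' parameters are kept.
#'
#' @param model A [build_rollout_model()] model.
#' @param x,y Training inputs (see [forward_rollout()]) and 1-based labels.
#' @param loss_weights Scheme name for [make_loss_weights()] or a weights
#'   tibble/vector.
#' @param epochs,batch_size,lr Optimisation budget and Adam learning rate.
#' @param weight_decay L2 penalty on weights.
#' @param act_decay L2 penalty on hidden activations (summed over frames).
#' @param dropout Spatial dropout rate in `[0, 1)`.
#' @param val_fraction Fraction of samples held out for validation.
#' @param seed Seed controlling shuffling, dropout and the split.
#' @param stop_at_val_acc Stop early once validation accuracy reaches this
#'   value (default 1 = stop at perfect validation accuracy).
#' @param verbose Print per-epoch progress.
#' @return The trained `rollout_model` with a `history` tibble
#'   (`epoch`, `train_loss`, `val_accuracy`) and `best_epoch` attached.
#' @export
train_rollout <- function(model, x, y, loss_weights = "uniform",
                          epochs = 20L, batch_size = 64L, lr = 1e-3,
                          weight_decay = 1e-4, act_decay = 0,
                          dropout = 0, val_fraction = 0.15, seed = 1L,
                          stop_at_val_acc = 1, verbose = FALSE) {
  stopifnot(inherits(model, "rollout_model"))
  old <- new_seed_scope(seed); on.exit(restore_seed_scope(old))
  x <- as_input_tensor(model, x)
  y <- as.integer(y)
  B_all <- dim(x)[1]
  stopifnot(length(y) == B_all)
  schedule <- rollout(model$graph, dim(x)[2])
  weights <- if (is.character(loss_weights))
    make_loss_weights(loss_weights, schedule$output_frames) else loss_weights
  if (epochs < 1L) { model$history <- tibble::tibble(); return(model) }

  n_val <- max(1L, round(val_fraction * B_all))
  val_idx <- sample.int(B_all, n_val)
  tr_idx <- setdiff(seq_len(B_all), val_idx)

  adam <- list()
  adam_step <- function(key, part, grad, t) {
    k2 <- paste0(key, ".", part)
    st <- adam[[k2]]
    if (is.null(st)) st <- list(m = grad * 0, v = grad * 0)
    st$m <- 0.9 * st$m + 0.1 * grad
    st$v <- 0.999 * st$v + 0.001 * grad^2
    adam[[k2]] <<- st
    mh <- st$m / (1 - 0.9^t); vh <- st$v / (1 - 0.999^t)
    lr * mh / (sqrt(vh) + 1e-8)
  }

  take <- function(idx) {
    xs <- if (model$spatial_input) x[idx, , , , , drop = FALSE]
      else x[idx, , , drop = FALSE]
    xs
  }
  val_accuracy <- function() {
    fwd <- forward_rollout(model, take(val_idx), schedule)
    P <- fwd$probs[, dim(fwd$probs)[2], ]
    if (is.null(dim(P))) P <- matrix(P, nrow = length(val_idx))
    mean(max.col(P, ties.method = "first") == y[val_idx])
  }

  hidden_keys <- names(model$shape)[vapply(model$shape, function(s)
    isTRUE(s$kind %in% c("conv", "transition", "dense")), logical(1))]

  history <- list(); best <- list(acc = -Inf, params = model$params, epoch = 0L)
  t_global <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      masks <- NULL
      if (dropout > 0) {
        masks <- list()
        for (key in hidden_keys) {
          C <- model$shape[[key]]$C
          keep <- matrix(stats::rbinom(length(idx) * C, 1L, 1 - dropout),
                         length(idx), C)
          masks[[key]] <- keep / (1 - dropout)
        }
      }
      res <- rollout_grads(model, take(idx), y[idx], weights, schedule,
                           act_decay = act_decay, dropout_masks = masks)
      if (!is.finite(res$loss))
        stop("divergent loss (non-finite) at epoch ", ep, "; lower the learning rate")
      t_global <- t_global + 1L
      for (key in names(model$params)) {
        gW <- res$grads[[key]]$W + 2 * weight_decay * model$params[[key]]$W
        model$params[[key]]$W <- model$params[[key]]$W - adam_step(key, "W", gW, t_global)
        model$params[[key]]$b <- model$params[[key]]$b -
          adam_step(key, "b", res$grads[[key]]$b, t_global)
      }
      ep_loss <- ep_loss + res$loss; nb <- nb + 1L
    }
    acc <- val_accuracy()
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / nb,
                                    val_accuracy = acc)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val acc %.3f", ep, ep_loss / nb, acc))
    if (acc > best$acc) best <- list(acc = acc, params = model$params, epoch = ep)
    if (acc >= stop_at_val_acc) break
  }
  model$params <- best$params
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- best$epoch
  model
}

#' @rdname train_rollout
#' @export
glance.rollout_model <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history))
    return(tibble::tibble(trained = FALSE, n_parameters = n_parameters(x)))
  tibble::tibble(trained = TRUE,
                 epochs = max(x$history$epoch),
                 best_epoch = x$best_epoch,
                 val_accuracy = x$history$val_accuracy[x$history$epoch == x$best_epoch][1],
                 final_train_loss = x$history$train_loss[nrow(x$history)],
                 n_parameters = n_parameters(x))
}

#' Per-output-frame accuracy of the rollout ANN
#'
#' Accuracy of `argmax y_k` at every output frame, averaged over a labelled
#' dataset. Early outputs see only the head of the input sequence (their
#' dependency cone), so the curve typically rises from near chance to the
#' late-output accuracy as deeper paths start contributing.
#'
#' @param model A trained [build_rollout_model()] model.
#' @param x,y Dataset inputs and 1-based labels.
#' @param batch_size Evaluation batch size.
#' @return A tibble of class `accuracy_curve` with columns `frame`,
#'   `accuracy`, `n`.
#' @export
ann_accuracy_curve <- function(model, x, y, batch_size = 256L) {
  x <- as_input_tensor(model, x)
  y <- as.integer(y)
  B_all <- dim(x)[1]
  schedule <- rollout(model$graph, dim(x)[2])
  n_out <- length(schedule$output_frames)
  correct <- numeric(n_out)
  for (start in seq(1L, B_all, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B_all)
    xs <- if (model$spatial_input) x[idx, , , , , drop = FALSE]
      else x[idx, , , drop = FALSE]
    fwd <- forward_rollout(model, xs, schedule)
    for (i in seq_len(n_out)) {
      P <- fwd$probs[, i, , drop = TRUE]
      if (is.null(dim(P))) P <- matrix(P, nrow = length(idx))
      pred <- max.col(P, ties.method = "first")
      correct[i] <- correct[i] + sum(pred == y[idx])
    }
  }
  out <- tibble::tibble(frame = schedule$output_frames,
                        accuracy = correct / B_all, n = B_all)
  class(out) <- c("accuracy_curve", class(out))
  attr(out, "kind") <- "ann"
  out
}
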