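# streamsnn

Sequence classification on event-camera data streams with spiking neural
networks (SNNs) obtained by converting conventionally trained artificial
neural networks (ANNs) — for researchers in neuromorphic computing and
event-based vision who want accurate, low-latency, energy-efficient
spiking inference without training SNNs directly.

## The idea

An SNN executing on neuromorphic hardware is fully model-parallel: every
connection has a non-zero axonal delay and every neuron updates from
incoming spikes only. A conventional ANN is not — feed-forward edges act
instantaneously. `streamsnn` closes that gap with **streaming rollouts**:
the network graph is unrolled in time with *every* edge carrying a delay
of one rollout frame, so layer `l` at frame `k` reads only frame `k - 1`.
Skip connections then become *temporal* skip connections: paths of
different lengths from input to output meet at the same output frame and
integrate information across time.

For a graph with shortest input–output path `l_s` and longest path
`l_max`:

- the first (approximate) prediction appears after `l_s` frames,
- one output is emitted per input frame: `K = N + l_s` rollout frames for
  `N` input frames,
- the spatio-temporal receptive field spans `tau = l_max - l_s + 1` input
  frames.

The rollout ANN (weights shared across frames) is trained by
backpropagation through time on the weighted multi-output cross entropy

    L = sum_k  -a_k * y_hat_k' log(y_k),     sum_k a_k = 1,

where the weights `a_k` trade off early against late accuracy. The trained
ANN is converted to a network of non-leaky integrate-and-fire neurons
(threshold `V_th = 1`, subtractive reset, lower membrane bound): each
layer's parameters are rescaled by a percentile `lambda_l` of its
training-set activations pooled over all rollout frames, so spike rates
approximate `a_l / lambda_l`; every connection gets axonal delay
`d = n_sf * d_ANN`, where `n_sf` is the number of simulation steps per
rollout frame. Predictions are read out as the argmax of the output
layer's weighted input summed over a trailing `n_sf`-step window.
Efficiency is compared in operations: multiply-adds for the ANN versus
synaptic operations (one per spike per target synapse) for the SNN, and
the accuracy ratio `rho = AUC(SNN) / AUC(ANN)` over simulation steps
guides the choice of `n_sf`.

## Worked example

Path analytics of the small example graph (initial convolution plus one
block of three densely connected layers, the third being the classifier):

```r
library(streamsnn)
g <- graph_skip_example()
tidy(path_stats(g))
#> # A tibble: 1 x 4
#>     l_s l_max   tau depth
#>   <int> <int> <int> <int>
#> 1     2     4     3     4
sched <- rollout(g, n_frames = 4)
sched$K                    # 6 rollout frames
dependency_cone(sched, 6)  # 2 3 4  — the last output merges frames 2..4
```

The moving-rectangles study end to end — two binary images per sample, the
rectangle shifts left or right, and only the pair reveals the direction:

```r
train <- gen_rectangles(2000, seed = 11)
graph <- build_densenet_graph(n_blocks = 3, layers_per_block = 1, growth = 8,
                              input_shape = c(2, 16, 16), n_classes = 2)
model <- build_rollout_model(graph, seed = 5) |>
  train_rollout(train$x, train$y, epochs = 15, batch_size = 64, lr = 3e-3,
                weight_decay = 1e-4, act_decay = 1e-6, seed = 2)

test <- gen_rectangles(400, seed = 99)
ann_accuracy_curve(model, test$x, test$y)
#>   frame accuracy   n
#> 1     5   0.4825 400   # sees only the first image: chance
#> 2     6   0.4975 400
#> 3     7   0.5150 400
#> 4     8   0.8325 400   # first output that sees both images
#> 5     9   1.0000 400
#> 6    10   1.0000 400
```

Outputs at frames 5–7 depend only on the first image (their dependency
cone) and sit at chance; once paths from both images meet, accuracy goes
to 100 %. Conversion and simulation:

```r
lambda <- calibrate_percentiles(model, train$x[1:256, , , , , drop = FALSE],
                                p = 99.9)
snn <- build_snn(model, lambda, n_sf = 15)
curve <- snn_accuracy_curve(snn, test$x, test$y, count_ops = TRUE)
frame_accuracy(curve)      # rises to 1.00 on the final frame,
                           # lagging the ANN by about one rollout frame
```

On this run the SNN needed 1.74 MOps (synaptic operations) against
7.41 MOps (multiply-adds) for the ANN — about 4x cheaper at equal peak
accuracy. Choosing `n_sf` via the accuracy-ratio sweep:

```r
sweep_nsf(model, train$x[1:256, , , , , drop = FALSE], train$y[1:256],
          n_sf = c(5, 15, 35))
#>   n_sf   rho ann_mops snn_mops
#> 1    5 0.950     7.41    0.525
#> 2   15 0.963     7.41    1.710
#> 3   35 0.956     7.41    4.079
```

`rho` saturates around `n_sf = 15`: a good accuracy/energy trade-off.
`autoplot()` methods exist for accuracy curves and sweeps, and a thin CLI
(`inst/exec/streamsnn`) wraps the preprocessing, training, conversion and
simulation steps for shell use.

## Scope

Loaders exist for a packed 40-bit binary event dialect and plain CSV/RDS
streams, but full-scale published event-camera benchmarks (they require
large downloads and GPU-scale training) are out of scope; the synthetic
generators and property suites stand in for them. Neuron models beyond
non-leaky integrate-and-fire, spike-timing codes, and adaptive threshold
rescaling are likewise out of scope.
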