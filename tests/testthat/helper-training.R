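# Shared desk-scale training runs for the trend tests: the synthetic
# benchmark (200 images, 64x64), the tiny network, fixed-epoch Adam training,
# combined loss with pixel-normalized CAL and background excluded from it.

desk_benchmark <- function(seed, n_foreground = 3, n_samples = 200) {
  synth_dataset(synth_config(n_samples = n_samples,
                             n_foreground = n_foreground, seed = seed))
}

desk_train_eval <- function(ds, seed, rho = 0, drop_classes = NULL,
                            alpha = 0.4, epochs = 8, lr = 5e-3,
                            sampler = NULL, view = NULL) {
  C <- ds$n_classes
  if (is.null(drop_classes)) drop_classes <- seq_len(C - 1L)
  if (is.null(view) && rho > 0)
    view <- heterogeneous_view(ds$ids[ds$split == "train"], C,
                               drop_spec(drop_classes, rho, seed = seed + 3L,
                                         persistence = "whole_training"),
                               background_index = C)
  net <- build_network(tiny_network_config(num_classes = C, seed = seed + 1L))
  fit <- train_network(net, ds,
                       train_config(batch_size = 10, learning_rate = lr,
                                    max_epochs = epochs,
                                    validation_fraction = 0, seed = seed + 2L),
                       loss_config(alpha = alpha, background_index = C,
                                   cal_normalize = TRUE),
                       view = view, sampler = sampler)
  test_ids <- ds$ids[ds$split == "test"]
  ev <- evaluate_dataset(lapply(ds$samples[test_ids], `[[`, "gt"),
                         predict_network(fit$net,
                                         lapply(ds$samples[test_ids], `[[`, "image")),
                         class_names = c(ds$class_names, "background"),
                         background_index = C)
  list(eval = ev, history = fit$history, net = fit$net)
}
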