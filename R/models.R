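#' Model family specification
#'
#' Eight families share one training protocol: two feature-based
#' classifiers (logistic regression and a 128-unit single-hidden-layer
#' perceptron on the 192 handcrafted features), three window-based
#' convolutional networks (CNN-simple: two conv layers with a linear
#' classifier on the flattened maps; CNN-base: three conv/max-pool blocks
#' and a 128-unit dense stage; ResNet: a conv stem plus two residual
#' blocks and a 128-unit dense stage), and a hybrid variant of each
#' network that concatenates the scaled handcrafted features with the
#' backbone representation and passes them through a fusion layer
#' (128 units for CNN-simple/CNN-base hybrids, 256 for the ResNet
#' hybrid) before classification. Convolutions use stride 1 and no
#' padding; max-pooling defaults to stride 1 as well (`pool_stride`
#' switches to conventional stride-k pooling). All hidden activations
#' are ReLU.
#'
#' @param family One of `"LR"`, `"MLP"`, `"CNN-simple"`, `"CNN-base"`,
#'   `"ResNet"`, `"CNN-simple-hybrid"`, `"CNN-base-hybrid"`,
#'   `"ResNet-hybrid"`.
#' @param n_features Width of the handcrafted representation.
#' @param window_len,window_ch Window geometry (250 samples x 4 channels).
#' @param kernel Convolution kernel size.
#' @param filters Filter counts for the successive conv stages.
#' @param dense_width Width of the dense stage in CNN-base/ResNet.
#' @param pool_stride Max-pool stride (1 as captioned; set to the kernel
#'   size for conventional pooling).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, n_features = 192, window_len = 250,
                       window_ch = 4, kernel = 5, filters = c(16, 32, 64),
                       dense_width = 128, pool_stride = 1) {
  families <- c("LR", "MLP", "CNN-simple", "CNN-base", "ResNet",
                "CNN-simple-hybrid", "CNN-base-hybrid", "ResNet-hybrid")
  family <- match.arg(family, families)
  hybrid <- grepl("-hybrid$", family)
  backbone <- sub("-hybrid$", "", family)
  input_kind <- if (backbone %in% c("LR", "MLP")) "features-192"
  else if (hybrid) "both" else "window"
  fusion_width <- if (!hybrid) NA_integer_
  else if (backbone == "ResNet") 256L else 128L
  structure(list(family = family, backbone = backbone, hybrid = hybrid,
                 input_kind = input_kind, n_features = n_features,
                 window_len = window_len, window_ch = window_ch,
                 kernel = kernel, filters = filters,
                 dense_width = dense_width, fusion_width = fusion_width,
                 mlp_hidden = 128L, pool_stride = pool_stride),
            class = "model_spec")
}

#' Build an untrained model from a specification
#'
#' @param spec A [model_spec()].
#' @param n_classes Number of activity classes.
#' @return An object of class `har_model` (untrained; parameters are
#'   drawn when [train_model()] initializes it under the run seed).
#' @export
build_model <- function(spec, n_classes = 5) {
  stopifnot(inherits(spec, "model_spec"))
  k <- spec$kernel
  fl <- spec$filters
  tensor <- list(); mat <- list()
  L <- spec$window_len
  backbone_width <- NULL
  if (spec$backbone == "LR") {
    head <- list(nn_dense(spec$n_features, n_classes))
    backbone_width <- spec$n_features
  } else if (spec$backbone == "MLP") {
    head <- list(nn_dense(spec$n_features, spec$mlp_hidden), nn_relu(),
                 nn_dense(spec$mlp_hidden, n_classes))
    backbone_width <- spec$mlp_hidden
  } else if (spec$backbone == "CNN-simple") {
    tensor <- list(nn_conv(k, spec$window_ch, fl[1]), nn_relu(),
                   nn_conv(k, fl[1], fl[2]), nn_relu())
    for (ly in tensor) L <- conv_out_len(L, ly)
    backbone_width <- L * fl[2]
    head <- list(nn_dense(backbone_width, n_classes))
  } else if (spec$backbone == "CNN-base") {
    in_ch <- spec$window_ch
    for (f in fl) {
      tensor <- c(tensor, list(nn_conv(k, in_ch, f), nn_relu(),
                               nn_pool(2, spec$pool_stride)))
      in_ch <- f
    }
    for (ly in tensor) L <- conv_out_len(L, ly)
    mat <- list(nn_dense(L * fl[length(fl)], spec$dense_width), nn_relu())
    backbone_width <- spec$dense_width
    head <- list(nn_dense(spec$dense_width, n_classes))
  } else if (spec$backbone == "ResNet") {
    tensor <- list(nn_conv(k, spec$window_ch, fl[1]), nn_relu(),
                   nn_resblock(k, fl[1], fl[2]), nn_resblock(k, fl[2], fl[3]))
    for (ly in tensor) L <- conv_out_len(L, ly)
    mat <- list(nn_dense(L * fl[3], spec$dense_width), nn_relu())
    backbone_width <- spec$dense_width
    head <- list(nn_dense(spec$dense_width, n_classes))
  }
  if (spec$hybrid) {
    head <- list(nn_dense(backbone_width + spec$n_features, spec$fusion_width),
                 nn_relu(),
                 nn_dense(spec$fusion_width, n_classes))
  }
  flat_ch <- if (length(tensor)) {
    last_f <- fl[if (spec$backbone == "CNN-simple") 2 else length(fl)]
    last_f
  } else 0
  net <- list(tensor_layers = tensor, matrix_layers = mat, head_layers = head,
              hybrid = spec$hybrid, flat_len = L, flat_ch = flat_ch,
              spec = spec, n_classes = n_classes, trained = FALSE)
  class(net) <- "har_model"
  net
}

#' Number of trainable parameters
#'
#' @param model A `har_model`.
#' @return Integer count of all weights and biases.
#' @export
n_params <- function(model) {
  count <- function(p) {
    if (is.null(p)) 0
    else if (is.numeric(p)) length(p)
    else sum(vapply(p, count, numeric(1)))
  }
  count(net_get_params(model))
}

#' Embedding width of a model family
#'
#' Width of the activation vector feeding the final classification layer:
#' the scaled 192 features for LR, the 128 hidden units for MLP, the
#' flattened feature maps for CNN-simple, the dense stage for
#' CNN-base/ResNet, and the fusion layer for hybrids.
#'
#' @param model A `har_model`.
#' @return Integer width.
#' @export
embedding_width <- function(model) {
  nh <- length(model$head_layers)
  model$head_layers[[nh]]$n_in
}

#' Class weights for the cross-entropy loss
#'
#' Default mode `"inverse-frequency"` gives class c weight N/(K n_c)
#' (upweights rare classes, the usual correction for imbalance). Mode
#' `"proportional"` gives n_c/N — the per-class share of training
#' instances used verbatim as its weight (a reading of "class shares as
#' weights" that up-weights majority classes; kept selectable so both
#' conventions are runnable). Classes absent from the
#' training labels are excluded from the returned vector (and hence from
#' the loss), with a warning.
#'
#' @param train_labels Character or factor vector of training labels.
#' @param mode `"inverse-frequency"` (default) or `"proportional"`.
#' @param classes Full class vocabulary (to detect absences).
#' @return Named numeric vector of weights over the present classes.
#' @export
class_weights <- function(train_labels,
                          mode = c("inverse-frequency", "proportional"),
                          classes = canonical_activities()) {
  mode <- match.arg(mode)
  tab <- table(factor(as.character(train_labels), levels = classes))
  absent <- names(tab)[tab == 0]
  if (length(absent)) {
    warning(sprintf("class(es) absent from training set excluded from loss: %s",
                    paste(absent, collapse = ", ")))
  }
  n_c <- tab[tab > 0]
  N <- sum(n_c); K <- length(n_c)
  w <- if (mode == "inverse-frequency") N / (K * n_c) else n_c / N
  stats::setNames(as.numeric(w), names(n_c))
}

#' Training configuration
#'
#' The shared protocol for every family: Adam, class-weighted
#' cross-entropy, a seeded 10% validation split drawn without
#' replacement, a 140-epoch cap, early stopping after 30 epochs without
#' a new validation-loss minimum, and restoration of the checkpoint with
#' the best validation loss.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs.
#' @param validation_fraction Fraction of training data held out for
#'   validation.
#' @param class_weight_mode Passed to [class_weights()].
#' @param seed Run seed (fixes initialization, the validation split and
#'   batch shuffling).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128,
                         max_epochs = 140, patience = 30,
                         validation_fraction = 0.10,
                         class_weight_mode = "inverse-frequency", seed = 1) {
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 validation_fraction = validation_fraction,
                 class_weight_mode = class_weight_mode, seed = seed),
            class = "train_config")
}

#' The 3 x 3 hyperparameter grid
#'
#' Three learning rates crossed with three batch sizes; per-task results
#' are averaged over these nine runs.
#'
#' @return data.frame with columns `learning_rate` and `batch_size`,
#'   9 rows.
#' @export
hyper_grid <- function() {
  expand.grid(learning_rate = c(0.0008, 0.001, 0.003),
              batch_size = c(64, 128, 256), KEEP.OUT.ATTRS = FALSE)
}

#' Global Z-score normalization for window inputs
#'
#' One (mean, sd) pair computed over all entries of all training windows
#' jointly (set `per_channel = TRUE` for per-channel statistics), applied
#' to any window tensor with the train statistics.
#'
#' @param train_windows Array `[n, len, ch]` of training windows.
#' @param per_channel Compute one pair per channel instead of globally.
#' @return `fit_window_scaler`: object of class `window_scaler`.
#' @export
fit_window_scaler <- function(train_windows, per_channel = FALSE) {
  if (per_channel) {
    m <- apply(train_windows, 3, mean)
    s <- apply(train_windows, 3, stats::sd)
  } else {
    m <- mean(train_windows)
    s <- stats::sd(as.vector(train_windows))
  }
  s[s == 0] <- 1
  structure(list(mean = m, sd = s, per_channel = per_channel),
            class = "window_scaler")
}

#' @rdname fit_window_scaler
#' @param scaler A `window_scaler`.
#' @param windows Array `[n, len, ch]`.
#' @export
apply_window_scaler <- function(scaler, windows) {
  stopifnot(inherits(scaler, "window_scaler"))
  if (scaler$per_channel) {
    for (c_ in seq_len(dim(windows)[3])) {
      windows[, , c_] <- (windows[, , c_] - scaler$mean[c_]) / scaler$sd[c_]
    }
    windows
  } else {
    (windows - scaler$mean) / scaler$sd
  }
}

# Assemble the (Xw, Xf) inputs a model consumes from a training-data list.
model_inputs <- function(model, data, idx = NULL) {
  kind <- model$spec$input_kind
  Xw <- NULL; Xf <- NULL
  if (kind %in% c("window", "both")) {
    w <- data$windows
    if (is.null(w)) stop_cfg("model expects window input but none supplied")
    if (!is.null(idx)) w <- w[idx, , , drop = FALSE]
    Xw <- aperm(w, c(2, 1, 3))  # [len, batch, ch]
  }
  if (kind %in% c("features-192", "both")) {
    f <- data$features
    if (is.null(f)) stop_cfg("model expects feature input but none supplied")
    if (!is.null(idx)) f <- f[idx, , drop = FALSE]
    Xf <- as.matrix(f)
  }
  list(Xw = Xw, Xf = Xf)
}

#' Train a model under the shared protocol
#'
#' Initializes parameters under the run seed, draws the seeded
#' validation split, then runs Adam on class-weighted cross-entropy
#' minibatches. After every epoch the validation loss is evaluated; each
#' new minimum is checkpointed, training stops after `patience` epochs
#' without improvement or at the epoch cap, and the returned model
#' carries the checkpointed parameters.
#'
#' @param model An untrained `har_model` from [build_model()].
#' @param data List with `labels` (character vector), and `windows`
#'   (`[n, len, ch]` array, already normalized) and/or `features`
#'   (`[n, p]` matrix, already scaled) as the family requires, plus
#'   optionally `classes` (full label vocabulary).
#' @param config A [train_config()].
#' @return A `har_trained_model`: the checkpointed model plus `history`
#'   (per-epoch train/validation loss), `checkpoint_epoch`, `stop_epoch`,
#'   `classes`, and the config.
#' @export
train_model <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "har_model"), inherits(config, "train_config"))
  classes <- data$classes %||% sort(unique(as.character(data$labels)))
  y_all <- match(as.character(data$labels), classes)
  if (anyNA(y_all)) stop_cfg("labels outside the class vocabulary")
  n <- length(y_all)
  if (n == 0) stop_cfg("empty training data")
  n_val <- round(config$validation_fraction * n)
  if (n_val < 1 || n_val >= n) stop_cfg("validation split empty or degenerate")

  with_seed(config$seed, {
    model <- net_init(model, seed = NULL)
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    w_named <- suppressWarnings(
      class_weights(classes[y_all[tr_idx]], mode = config$class_weight_mode,
                    classes = classes))
    weights <- stats::setNames(numeric(length(classes)), classes)
    weights[names(w_named)] <- w_named

    val_in <- model_inputs(model, data, val_idx)
    y_val <- y_all[val_idx]
    eval_loss <- function(net) {
      out <- net_forward(net, val_in$Xw, val_in$Xf)
      weighted_ce(out$logits, y_val, weights)$loss
    }

    params <- net_get_params(model)
    state <- NULL
    t_step <- 0
    best_val <- Inf; best_params <- params; checkpoint_epoch <- 0
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    stop_epoch <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        inp <- model_inputs(model, data, b)
        fw <- net_forward(model, inp$Xw, inp$Xf, need_cache = TRUE)
        ce <- weighted_ce(fw$logits, y_all[b], weights)
        ep_loss <- ep_loss + ce$loss * length(b)
        grads <- net_backward(model, fw$cache, ce$dlogits)
        t_step <- t_step + 1
        upd <- adam_update(net_get_params(model), grads, state,
                           config$learning_rate, t_step)
        state <- upd$s
        model <- net_set_params(model, upd$p)
      }
      vl <- eval_loss(model)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / length(tr_idx), val_loss = vl))
      if (vl < best_val) {
        best_val <- vl
        best_params <- net_get_params(model)
        checkpoint_epoch <- epoch
      } else if (epoch - checkpoint_epoch >= config$patience) {
        stop_epoch <- epoch
        break
      }
      stop_epoch <- epoch
    }
    model <- net_set_params(model, best_params)
    model$trained <- TRUE
    structure(list(model = model, spec = model$spec, history = history,
                   checkpoint_epoch = checkpoint_epoch,
                   stop_epoch = stop_epoch, classes = classes,
                   config = config),
              class = "har_trained_model")
  })
}

#' @export
print.har_trained_model <- function(x, ...) {
  cat(sprintf("<har_trained_model> %s: stopped at epoch %d (checkpoint %d), val loss %.4f\n",
              x$spec$family, x$stop_epoch, x$checkpoint_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Predict activity labels
#'
#' Argmax of the logits from the checkpointed parameters; exact ties go
#' to the lowest class index.
#'
#' @param object A `har_trained_model`.
#' @param data Input list as in [train_model()] (labels not required).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.har_trained_model <- function(object, data, ...) {
  inp <- model_inputs(object$model, data)
  out <- net_forward(object$model, inp$Xw, inp$Xf)
  object$classes[apply(out$logits, 1, which.max)]
}

#' Extract penultimate-layer embeddings
#'
#' Returns, per sample, the activation vector feeding the final
#' classification layer (the representation on which the
#' distribution-shift metrics operate).
#'
#' @param trained A `har_trained_model`.
#' @param data Input list as in [train_model()].
#' @return Numeric matrix `[n x embedding_width]` with attribute
#'   `source = "embedding"`.
#' @export
embed <- function(trained, data) {
  stopifnot(inherits(trained, "har_trained_model"))
  if (!isTRUE(trained$model$trained)) stop_cfg("model is not trained")
  inp <- model_inputs(trained$model, data)
  out <- net_forward(trained$model, inp$Xw, inp$Xf)
  emb <- out$embedding
  attr(emb, "source") <- "embedding"
  emb
}
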