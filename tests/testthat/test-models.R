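# shorthand for internals used by the engine-level checks
nf <- harshift:::net_forward
nb <- harshift:::net_backward
ni <- harshift:::net_init
ngp <- harshift:::net_get_params
nsp <- harshift:::net_set_params
wce <- harshift:::weighted_ce

all_families <- c("LR", "MLP", "CNN-simple", "CNN-base", "ResNet",
                  "CNN-simple-hybrid", "CNN-base-hybrid", "ResNet-hybrid")

test_that("class weights implement both imbalance conventions", {
  labs <- c(rep("walk", 80), rep("run", 20))
  w <- class_weights(labs, "inverse-frequency", classes = c("walk", "run"))
  expect_equal(unname(w[c("walk", "run")]), c(0.625, 2.5))
  w2 <- class_weights(labs, "proportional", classes = c("walk", "run"))
  expect_equal(unname(w2[c("walk", "run")]), c(0.8, 0.2))
  # balanced counts: equal weights under both modes
  bal <- rep(canonical_activities(), each = 10)
  expect_true(all(class_weights(bal, "inverse-frequency") == 1))
  expect_true(all(class_weights(bal, "proportional") == 0.2))
  # absent classes are excluded with a warning
  expect_warning(w3 <- class_weights(labs), "absent")
  expect_setequal(names(w3), c("walk", "run"))
})

test_that("architectures expose the contracted shapes and widths", {
  expect_equal(n_params(build_model(model_spec("LR"), 5)), 5 * 192 + 5)
  widths <- c("LR" = 192, "MLP" = 128,
              "CNN-simple" = (250 - 4 - 4) * 32, "CNN-base" = 128,
              "ResNet" = 128, "CNN-simple-hybrid" = 128,
              "CNN-base-hybrid" = 128, "ResNet-hybrid" = 256)
  for (fam in names(widths)) {
    expect_equal(embedding_width(build_model(model_spec(fam), 5)),
                 unname(widths[fam]), info = fam)
  }
  # hybrid fusion layer consumes backbone width + 192 features
  hb <- build_model(model_spec("CNN-simple-hybrid"), 5)
  expect_equal(hb$head_layers[[1]]$n_in, (250 - 4 - 4) * 32 + 192)
  hb2 <- build_model(model_spec("CNN-base-hybrid"), 5)
  expect_equal(hb2$head_layers[[1]]$n_in, 128 + 192)
})

test_that("forward passes produce one logit row per sample, 5 classes", {
  set.seed(3)
  Xw <- aperm(array(rnorm(2 * 250 * 4), c(2, 250, 4)), c(2, 1, 3))
  Xf <- matrix(rnorm(2 * 192), 2)
  for (fam in c("CNN-simple", "ResNet-hybrid")) {
    net <- ni(build_model(model_spec(fam), 5), seed = 1)
    out <- nf(net, Xw, Xf)
    expect_equal(dim(out$logits), c(2, 5), info = fam)
  }
  net <- ni(build_model(model_spec("CNN-base-hybrid"), 5), seed = 1)
  expect_error(nf(net, Xw, NULL), "feature input")
})

test_that("analytic gradients match numerical differentiation everywhere", {
  set.seed(5)
  B <- 4
  Xw <- array(rnorm(30 * B * 2), c(30, B, 2))
  Xf <- matrix(rnorm(B * 7), B)
  y <- c(1, 2, 3, 1)
  w <- c(1, 2, 0.5)
  rand_bias <- function(p) {
    # perturb biases away from 0 so no ReLU preactivation sits exactly at
    # its kink (where the numerical derivative is one-sided)
    if (is.null(p)) return(p)
    if (!is.null(p$b)) p$b <- stats::rnorm(length(p$b), 0, 0.1)
    for (nm in names(p)) if (is.list(p[[nm]])) p[[nm]] <- rand_bias(p[[nm]])
    p
  }
  for (fam in all_families) {
    s <- model_spec(fam, n_features = 7, window_len = 30, window_ch = 2,
                    kernel = 3, filters = c(3, 4, 5), dense_width = 6)
    net <- ni(build_model(s, 3), seed = 2)
    pp <- lapply(ngp(net), function(lst) lapply(lst, rand_bias))
    net <- nsp(net, pp)
    lossfn <- function(n) wce(nf(n, Xw, Xf)$logits, y, w)$loss
    fw <- nf(net, Xw, Xf, need_cache = TRUE)
    gr <- nb(net, fw$cache, wce(fw$logits, y, w)$dlogits)
    cur <- ngp(net)
    maxerr <- 0
    eps <- 1e-6
    check <- function(pget, pset, g) {
      p <- pget()
      for (i in sample(length(p), min(4, length(p)))) {
        p2 <- p
        p2[i] <- p[i] + eps
        n1 <- lossfn(pset(p2))
        p2[i] <- p[i] - eps
        n2 <- lossfn(pset(p2))
        maxerr <<- max(maxerr, abs((n1 - n2) / (2 * eps) - g[i]))
      }
    }
    walk <- function(pget, pset, gsub) {
      if (is.null(gsub)) return()
      if (is.numeric(gsub)) {
        check(pget, pset, gsub)
        return()
      }
      for (k in seq_along(gsub)) local({
        kk <- k
        walk(function() pget()[[kk]],
             function(v) {
               p <- pget()
               p[[kk]] <- v
               pset(p)
             }, gsub[[kk]])
      })
    }
    walk(function() cur, function(v) {
      cur <<- v
      nsp(net, cur)
    }, gr)
    expect_lt(maxerr, 1e-4)
  }
})

test_that("the early-stopping scan obeys cap, patience and checkpointing", {
  # strictly decreasing history runs to the cap
  h <- harshift:::early_stop_epoch(seq(1, 0.01, length.out = 140))
  expect_equal(h$stop_epoch, 140)
  expect_equal(h$checkpoint_epoch, 140)
  # minimum at epoch 5 then flat: patience 30 stops at 35
  h2 <- harshift:::early_stop_epoch(c(seq(1, 0.5, length.out = 5),
                                      rep(0.6, 200)))
  expect_equal(h2$checkpoint_epoch, 5)
  expect_equal(h2$stop_epoch, 35)
  # property: stop_epoch <= min(140, checkpoint_epoch + 30) on random walks
  set.seed(13)
  for (i in 1:50) {
    v <- cumsum(rnorm(200)) + seq(0, -2, length.out = 200)
    r <- harshift:::early_stop_epoch(v)
    expect_lte(r$stop_epoch, min(140, r$checkpoint_epoch + 30))
    expect_equal(r$checkpoint_epoch,
                 which.min(v[seq_len(r$stop_epoch)]))
  }
})

test_that("training is deterministic and restores the checkpoint", {
  d <- separable_features()
  cfg <- train_config(learning_rate = 0.05, batch_size = 16, max_epochs = 25,
                      patience = 30, seed = 7)
  m1 <- train_model(build_model(model_spec("LR", n_features = 6), 2), d, cfg)
  m2 <- train_model(build_model(model_spec("LR", n_features = 6), 2), d, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$checkpoint_epoch, which.min(m1$history$val_loss))
  # a rerun capped at the checkpoint epoch reproduces the returned model:
  # the restored parameters are exactly those of the best epoch
  cfg3 <- train_config(learning_rate = 0.05, batch_size = 16,
                       max_epochs = m1$checkpoint_epoch, patience = 30,
                       seed = 7)
  m3 <- train_model(build_model(model_spec("LR", n_features = 6), 2), d, cfg3)
  expect_equal(harshift:::net_get_params(m3$model),
               harshift:::net_get_params(m1$model), tolerance = 1e-12)
})

test_that("logistic regression separates a separable problem perfectly", {
  d <- separable_features(n_per = 40)
  cfg <- train_config(learning_rate = 0.05, batch_size = 16,
                      max_epochs = 140, patience = 140, seed = 1)
  tr <- train_model(build_model(model_spec("LR", n_features = 6), 2), d, cfg)
  pred <- predict(tr, d)
  expect_equal(mean(pred == d$labels), 1)
})

test_that("prediction breaks logit ties toward the lowest class index", {
  d <- separable_features(n_per = 5)
  net <- build_model(model_spec("LR", n_features = 6), 2)
  # zero weights -> all logits equal -> every prediction is class 1
  trained <- structure(list(model = ni(net, 1), spec = net$spec,
                            classes = d$classes),
                       class = "har_trained_model")
  trained$model$trained <- TRUE
  zero <- lapply(harshift:::net_get_params(trained$model), function(lst) {
    lapply(lst, function(p) if (is.null(p)) NULL else lapply(p, function(x) x * 0))
  })
  trained$model <- harshift:::net_set_params(trained$model, zero)
  expect_true(all(predict(trained, d) == d$classes[1]))
})

test_that("embeddings come from the layer feeding the classifier", {
  d <- separable_features(n_per = 10)
  cfg <- train_config(learning_rate = 0.05, batch_size = 8, max_epochs = 3,
                      patience = 30, seed = 2)
  tr <- train_model(build_model(model_spec("MLP", n_features = 6), 2), d, cfg)
  e <- embed(tr, d)
  expect_equal(dim(e), c(20, 128))
  expect_identical(attr(e, "source"), "embedding")
  lr <- train_model(build_model(model_spec("LR", n_features = 6), 2), d, cfg)
  # for LR the embedding is its (scaled) feature input
  e_lr <- embed(lr, d)
  attr(e_lr, "source") <- NULL
  expect_equal(unname(e_lr), unname(d$features))
  un <- build_model(model_spec("LR", n_features = 6), 2)
  expect_error(embed(structure(list(model = un), class = "har_trained_model"),
                     d), "not trained")
})

test_that("window normalization uses one global train statistic pair", {
  set.seed(8)
  w <- array(rnorm(5 * 20 * 4, mean = 3, sd = 2), c(5, 20, 4))
  sc <- fit_window_scaler(w)
  out <- apply_window_scaler(sc, w)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.vector(out)), 1, tolerance = 1e-12)
  scc <- fit_window_scaler(w, per_channel = TRUE)
  outc <- apply_window_scaler(scc, w)
  expect_equal(mean(outc[, , 2]), 0, tolerance = 1e-12)
})
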