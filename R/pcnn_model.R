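#' Block mask specification for the partially connected layers
#'
#' The first two hidden layers of the model are partially connected: a
#' hidden unit receives input only from columns of its own feature block,
#' i.e. the weight matrix is masked block-diagonally. The spec records, per
#' block, the input width `n_i` and the hidden widths `m_i` of the two
#' partial layers; a partial layer trains exactly `sum(n_i * m_i)` weights
#' instead of the fully connected `sum(n_i) * sum(m_i)`.
#'
#' @param input_widths Named integer vector of block input widths (order
#'   defines the mask's block order and must match the assembled features).
#' @param hidden1_widths Hidden widths of the first partial layer, same
#'   names/order.
#' @param hidden2_widths Hidden widths of the second partial layer; defaults
#'   to `hidden1_widths`.
#' @return Object of class `pcnn_mask_spec`.
#' @export
pcnn_mask_spec <- function(input_widths, hidden1_widths,
                           hidden2_widths = hidden1_widths) {
  stopifnot(length(input_widths) == length(hidden1_widths),
            length(input_widths) == length(hidden2_widths),
            all(input_widths >= 1L), all(hidden1_widths >= 1L),
            all(hidden2_widths >= 1L))
  if (is.null(names(input_widths))) {
    names(input_widths) <- paste0("block", seq_along(input_widths))
  }
  structure(list(blocks = names(input_widths),
                 input = as.integer(input_widths),
                 hidden1 = as.integer(hidden1_widths),
                 hidden2 = as.integer(hidden2_widths)),
            class = "pcnn_mask_spec")
}

#' Default full-scale mask specification
#'
#' Per-block first-layer hidden widths 200/160/68 for the latent (300),
#' interaction (285) and chemical (101) blocks, giving
#' (300*200) + (285*160) + (101*68) = 112,468 trainable partial-layer
#' weights; the second partial layer reuses the same per-block widths.
#'
#' @return A [pcnn_mask_spec()].
#' @export
default_mask_spec <- function() {
  w <- default_block_widths()
  pcnn_mask_spec(w, c(latent = 200L, interaction = 160L, chemical = 68L))
}

#' Build a block-diagonal binary mask
#'
#' @param input_widths Integer vector of per-block input widths.
#' @param hidden_widths Integer vector of per-block hidden widths.
#' @return Binary matrix of size `sum(input_widths)` x `sum(hidden_widths)`
#'   with exactly `sum(input_widths * hidden_widths)` ones.
#' @export
build_mask <- function(input_widths, hidden_widths) {
  stopifnot(length(input_widths) == length(hidden_widths),
            all(input_widths >= 1L), all(hidden_widths >= 1L))
  mask <- matrix(0, nrow = sum(input_widths), ncol = sum(hidden_widths))
  r0 <- c(0L, cumsum(input_widths))
  c0 <- c(0L, cumsum(hidden_widths))
  for (i in seq_along(input_widths)) {
    mask[(r0[i] + 1L):r0[i + 1L], (c0[i] + 1L):c0[i + 1L]] <- 1
  }
  mask
}

#' Edge accounting for the partial layers
#'
#' Counts trainable weights of both partial layers under the block mask and
#' under full connection, and reports both the ratio partial/full (what the
#' masked model trains *relative to* a dense one) and its complement (the
#' share of edges removed).
#'
#' @param spec A [pcnn_mask_spec()].
#' @return List with `partial` (named per-layer counts), `full`,
#'   `partial_total`, `full_total`, `ratio_to_full`, `reduction_by`.
#' @export
count_partial_edges <- function(spec) {
  stopifnot(inherits(spec, "pcnn_mask_spec"))
  p1 <- sum(spec$input * spec$hidden1)
  p2 <- sum(spec$hidden1 * spec$hidden2)
  f1 <- sum(spec$input) * sum(spec$hidden1)
  f2 <- sum(spec$hidden1) * sum(spec$hidden2)
  list(partial = c(layer1 = p1, layer2 = p2),
       full = c(layer1 = f1, layer2 = f2),
       partial_total = p1 + p2, full_total = f1 + f2,
       ratio_to_full = (p1 + p2) / (f1 + f2),
       reduction_by = 1 - (p1 + p2) / (f1 + f2))
}

#' He-style weight initialization
#'
#' Draws i.i.d. zero-mean Gaussian weights with standard deviation
#' `sqrt(2 / n_l)`, the scaling that preserves activation variance under the
#' ReLU nonlinearity. For masked layers `n_l` is the *unmasked* fan-in of
#' each hidden unit, and masked entries are returned as exact zeros.
#'
#' @param n_in,n_out Layer dimensions.
#' @param mask Optional binary mask (`n_in` x `n_out`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Weight matrix `n_in` x `n_out`.
#' @export
init_params <- function(n_in, n_out, mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fan_in <- if (is.null(mask)) rep(n_in, n_out) else colSums(mask)
  w <- matrix(stats::rnorm(n_in * n_out), nrow = n_in)
  w <- sweep(w, 2L, sqrt(2 / pmax(fan_in, 1)), "*")
  if (!is.null(mask)) w <- w * mask
  w
}

#' Class weights inversely proportional to class frequencies
#'
#' `w_c = N / (2 * N_c)`, so balanced labels give (1, 1) and the identity
#' `w0 * N0 == w1 * N1` always holds.
#'
#' @param labels Binary vector containing both classes.
#' @return Named vector `c(w0 = , w1 = )`: weights for class 0 and class 1.
#' @export
class_weights <- function(labels) {
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0L || n1 == 0L) stop("labels contain a single class")
  n <- n0 + n1
  c(w0 = n / (2 * n0), w1 = n / (2 * n1))
}

#' Class-weighted binary cross-entropy
#'
#' `L = -sum_i [ w0 * y_i * log(p_i) + w1 * (1 - y_i) * log(1 - p_i) ]`,
#' with predicted probabilities clipped to `[clip, 1 - clip]` to avoid
#' `log(0)`. Note the argument convention follows the loss equation: `w0`
#' multiplies the positive (y = 1) term and `w1` the negative term, so for
#' imbalance correction pass the *positive-class* weight as `w0`.
#'
#' @param y Binary target vector.
#' @param yhat Predicted probabilities, same length.
#' @param w0 Weight on the positive term (default 1).
#' @param w1 Weight on the negative term (default 1).
#' @param clip Probability clipping bound (default 1e-7).
#' @return Scalar loss (a sum, not a mean).
#' @export
weighted_bce <- function(y, yhat, w0 = 1, w1 = 1, clip = 1e-7) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  p <- pmin(pmax(yhat, clip), 1 - clip)
  -sum(w0 * y * log(p) + w1 * (1 - y) * log(1 - p))
}

bn_eps <- 1e-5
bn_momentum <- 0.9

new_hidden_layer <- function(n_in, n_out, mask = NULL) {
  # run_mean / run_var hold *bias-corrected* exponential moving averages:
  # the raw EMA starts at zero and is divided by (1 - momentum^t) at use,
  # so inference statistics are meaningful from the very first update.
  list(W = init_params(n_in, n_out, mask = mask),
       b = numeric(n_out),
       gamma = rep(1, n_out), beta = numeric(n_out),
       run_mean = numeric(n_out), run_var = numeric(n_out),
       bn_count = 0L,
       mask = mask)
}

#' Initialize a partially connected disease model
#'
#' Layer stack: two masked (partially connected) hidden layers, each an
#' affine transform followed by batch normalization and ReLU, whose
#' per-block outputs are concatenated; then fully connected hidden layers
#' of widths `fc_widths` (same affine+BN+ReLU pattern); then a single
#' sigmoid output unit.
#'
#' @param spec A [pcnn_mask_spec()]; `sum(spec$input)` must equal the model
#'   input width.
#' @param fc_widths Widths of the fully connected hidden layers
#'   (default `c(256, 64)`).
#' @param seed Optional seed for reproducible initialization.
#' @return Object of class `pcnn_model`.
#' @export
pcnn_init <- function(spec, fc_widths = c(256L, 64L), seed = NULL) {
  stopifnot(inherits(spec, "pcnn_mask_spec"))
  if (!is.null(seed)) set.seed(seed)
  m1 <- build_mask(spec$input, spec$hidden1)
  m2 <- build_mask(spec$hidden1, spec$hidden2)
  layers <- list(new_hidden_layer(sum(spec$input), sum(spec$hidden1), m1),
                 new_hidden_layer(sum(spec$hidden1), sum(spec$hidden2), m2))
  prev <- sum(spec$hidden2)
  for (h in fc_widths) {
    layers[[length(layers) + 1L]] <- new_hidden_layer(prev, h)
    prev <- h
  }
  out <- list(W = init_params(prev, 1L), b = 0)
  structure(list(spec = spec, fc_widths = fc_widths,
                 layers = layers, out = out,
                 history = NULL, best_epoch = NA_integer_),
            class = "pcnn_model")
}

# Forward pass. training = TRUE uses batch statistics (and updates running
# statistics in the returned model); otherwise running statistics are used.
# Returns list(prob, cache, model).
pcnn_forward_full <- function(model, x, training = FALSE) {
  a <- x
  cache <- list()
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    z <- a %*% ly$W + matrix(ly$b, nrow(a), length(ly$b), byrow = TRUE)
    if (training) {
      mu <- colMeans(z)
      v <- colMeans(sweep(z, 2L, mu)^2)
      m <- nrow(z)
      unb <- if (m > 1L) v * m / (m - 1) else v
      model$layers[[li]]$run_mean <- bn_momentum * ly$run_mean + (1 - bn_momentum) * mu
      model$layers[[li]]$run_var <- bn_momentum * ly$run_var + (1 - bn_momentum) * unb
      model$layers[[li]]$bn_count <- ly$bn_count + 1L
    } else if (ly$bn_count > 0L) {
      correct <- 1 - bn_momentum^ly$bn_count
      mu <- ly$run_mean / correct
      v <- ly$run_var / correct
    } else {
      mu <- numeric(length(ly$b))
      v <- rep(1, length(ly$b))
    }
    sdv <- sqrt(v + bn_eps)
    xhat <- sweep(sweep(z, 2L, mu), 2L, sdv, "/")
    y <- sweep(sweep(xhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    a_next <- pmax(y, 0)
    cache[[li]] <- list(a_prev = a, xhat = xhat, sdv = sdv, y = y)
    a <- a_next
  }
  z_out <- as.numeric(a %*% model$out$W + model$out$b)
  prob <- 1 / (1 + exp(-z_out))
  if (any(!is.finite(prob))) stop("non-finite activations in forward pass")
  list(prob = prob, a_last = a, cache = cache, model = model)
}

#' Predict probabilities with a trained model
#'
#' Inference-mode forward pass (running batch-norm statistics), so scores
#' are deterministic and invariant to how rows are batched.
#'
#' @param model A `pcnn_model`.
#' @param x Feature matrix with `sum(spec$input)` columns.
#' @return Numeric vector of probabilities in (0, 1), named by rownames.
#' @export
pcnn_predict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != sum(model$spec$input)) {
    stop(sprintf("input width %d does not match model input width %d",
                 ncol(x), sum(model$spec$input)))
  }
  p <- pcnn_forward_full(model, x, training = FALSE)$prob
  names(p) <- rownames(x)
  p
}

# Backward pass for the mean weighted BCE; returns gradients shaped like
# the model parameters. w_pos multiplies the y = 1 term.
pcnn_backward <- function(model, fwd, y, w_pos, w_neg) {
  n <- length(y)
  p <- fwd$prob
  dz_out <- matrix((-w_pos * y * (1 - p) + w_neg * (1 - y) * p) / n, ncol = 1L)
  g_out <- list(W = crossprod(fwd$a_last, dz_out), b = sum(dz_out))
  da <- dz_out %*% t(model$out$W)
  g_layers <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cc <- fwd$cache[[li]]
    dy <- da * (cc$y > 0)
    dgamma <- colSums(dy * cc$xhat)
    dbeta <- colSums(dy)
    dxhat <- sweep(dy, 2L, ly$gamma, "*")
    m <- nrow(dy)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cc$xhat)
    dz <- sweep(m * dxhat -
                  matrix(s1, m, length(s1), byrow = TRUE) -
                  cc$xhat * matrix(s2, m, length(s2), byrow = TRUE),
                2L, 1 / (m * cc$sdv), "*")
    dw <- crossprod(cc$a_prev, dz)
    if (!is.null(ly$mask)) dw <- dw * ly$mask
    g_layers[[li]] <- list(W = dw, b = colSums(dz),
                           gamma = dgamma, beta = dbeta)
    da <- dz %*% t(ly$W)
  }
  list(layers = g_layers, out = g_out)
}

adam_state_like <- function(model) {
  zero_of <- function(p) lapply(p, function(v) v * 0)
  list(m = list(layers = lapply(model$layers, function(ly)
                  zero_of(ly[c("W", "b", "gamma", "beta")])),
                out = zero_of(model$out[c("W", "b")])),
       v = list(layers = lapply(model$layers, function(ly)
                  zero_of(ly[c("W", "b", "gamma", "beta")])),
                out = zero_of(model$out[c("W", "b")])),
       t = 0L)
}

adam_step_param <- function(p, g, m, v, lr, b1, b2, t, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Training configuration
#'
#' Optimization settings of the per-disease models: Adam with learning rate
#' 1e-4, beta1 = 0.9, beta2 = 0.999, batch size 64, at most 3000 epochs,
#' early stopping on validation loss with patience 30 (best-epoch weights
#' restored).
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param beta1,beta2 Adam moment decays (defaults 0.9, 0.999).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Epoch cap (default 3000).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param validation_fraction Fraction of training rows held out for
#'   validation when no explicit validation set is given (default 0.25,
#'   i.e. the 2:6 validation:train proportion of a 6:2:2 split).
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 64L, max_epochs = 3000L,
                         patience = 30L, validation_fraction = 0.25,
                         seed = 1L) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1L, max_epochs >= 1L, patience >= 1L,
            patience < max_epochs,
            validation_fraction > 0, validation_fraction < 1)
  structure(as.list(environment()), class = "train_config")
}

snapshot_params <- function(model) {
  list(layers = lapply(model$layers, function(ly)
         ly[c("W", "b", "gamma", "beta", "run_mean", "run_var", "bn_count")]),
       out = model$out)
}

restore_params <- function(model, snap) {
  for (li in seq_along(model$layers)) {
    model$layers[[li]][names(snap$layers[[li]])] <- snap$layers[[li]]
  }
  model$out <- snap$out
  model
}

#' Train one per-disease model
#'
#' Minimizes the mean class-weighted binary cross-entropy by Adam. The
#' positive class receives the larger weight `N/(2*N1)` so that rare
#' indications are not drowned out. Block masks are re-applied after every
#' update, so masked weight entries are exactly zero at every checkpoint.
#' Training stops when the validation loss has not improved for
#' `config$patience` epochs and the best-epoch parameters are restored.
#'
#' @param x Feature matrix (rows = compounds).
#' @param y Binary label vector, one element per row of `x`.
#' @param spec A [pcnn_mask_spec()] matching `ncol(x)`.
#' @param config A [train_config()].
#' @param fc_widths Fully connected hidden widths (default `c(256, 64)`).
#' @param val_idx Row indices used for validation; when `NULL`, a stratified
#'   `config$validation_fraction` split is drawn.
#' @param train_idx Row indices used for optimization; defaults to all rows
#'   not in `val_idx` (pass explicitly to hold out a test set).
#' @param swap_class_weights If `TRUE`, pair the class-0 weight with the
#'   positive loss term instead (the reversed pairing; default `FALSE`).
#' @return A trained `pcnn_model` with `history` (per-epoch train and
#'   validation loss) and `best_epoch`.
#' @export
pcnn_train <- function(x, y, spec, config = train_config(),
                       fc_widths = c(256L, 64L), val_idx = NULL,
                       train_idx = NULL, swap_class_weights = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (ncol(x) != sum(spec$input)) {
    stop(sprintf("feature width %d does not match mask spec input width %d",
                 ncol(x), sum(spec$input)))
  }
  set.seed(config$seed)
  if (is.null(val_idx)) {
    plan <- make_split(seq_len(nrow(x)),
                       ratios = c(1 - config$validation_fraction,
                                  config$validation_fraction),
                       seed = config$seed, labels = y)
    train_idx <- plan$splits[[1]]
    val_idx <- plan$splits[[2]]
  } else if (is.null(train_idx)) {
    train_idx <- setdiff(seq_len(nrow(x)), val_idx)
  }
  if (length(unique(y[train_idx])) < 2L) stop("training labels are single-class")
  cw <- class_weights(y[train_idx])
  w_pos <- unname(if (swap_class_weights) cw["w0"] else cw["w1"])
  w_neg <- unname(if (swap_class_weights) cw["w1"] else cw["w0"])

  model <- pcnn_init(spec, fc_widths = fc_widths)
  opt <- adam_state_like(model)
  x_tr <- x[train_idx, , drop = FALSE]
  y_tr <- y[train_idx]
  x_val <- x[val_idx, , drop = FALSE]
  y_val <- y[val_idx]

  best_val <- Inf
  best_snap <- snapshot_params(model)
  best_epoch <- 0L
  wait <- 0L
  hist_train <- hist_val <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(y_tr))
    starts <- seq(1L, length(ord), by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      fwd <- pcnn_forward_full(model, x_tr[idx, , drop = FALSE], training = TRUE)
      model <- fwd$model  # running BN statistics advanced
      grads <- pcnn_backward(model, fwd, y_tr[idx], w_pos, w_neg)
      opt$t <- opt$t + 1L
      for (li in seq_along(model$layers)) {
        for (pn in c("W", "b", "gamma", "beta")) {
          upd <- adam_step_param(model$layers[[li]][[pn]],
                                 grads$layers[[li]][[pn]],
                                 opt$m$layers[[li]][[pn]],
                                 opt$v$layers[[li]][[pn]],
                                 config$learning_rate, config$beta1,
                                 config$beta2, opt$t)
          model$layers[[li]][[pn]] <- upd$p
          opt$m$layers[[li]][[pn]] <- upd$m
          opt$v$layers[[li]][[pn]] <- upd$v
        }
        if (!is.null(model$layers[[li]]$mask)) {
          model$layers[[li]]$W <- model$layers[[li]]$W * model$layers[[li]]$mask
        }
      }
      for (pn in c("W", "b")) {
        upd <- adam_step_param(model$out[[pn]], grads$out[[pn]],
                               opt$m$out[[pn]], opt$v$out[[pn]],
                               config$learning_rate, config$beta1,
                               config$beta2, opt$t)
        model$out[[pn]] <- upd$p
        opt$m$out[[pn]] <- upd$m
        opt$v$out[[pn]] <- upd$v
      }
      epoch_loss <- epoch_loss +
        weighted_bce(y_tr[idx], fwd$prob, w_pos, w_neg)
    }
    if (!is.finite(epoch_loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
    }
    hist_train[epoch] <- epoch_loss / length(y_tr)
    p_val <- pcnn_forward_full(model, x_val, training = FALSE)$prob
    val_loss <- weighted_bce(y_val, p_val, w_pos, w_neg) / length(y_val)
    hist_val[epoch] <- val_loss
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_snap <- snapshot_params(model)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model <- restore_params(model, best_snap)
  model$history <- data.frame(epoch = seq_along(hist_train),
                              train_loss = hist_train, val_loss = hist_val)
  model$best_epoch <- best_epoch
  model$class_weights <- c(w_pos = w_pos, w_neg = w_neg)
  model
}

#' Train one model per disease
#'
#' Fits an independent binary model for every column of the label matrix
#' (one disease at a time, as in the per-disease modelling design), sharing
#' the feature matrix, mask spec and training configuration.
#'
#' @param features Feature matrix (rows = compounds; a `feature_matrix`
#'   from [assemble_features()] or a plain matrix).
#' @param labels Binary label matrix with matching rownames.
#' @param spec A [pcnn_mask_spec()].
#' @param config A [train_config()].
#' @param ... Passed to [pcnn_train()].
#' @return Named list of `pcnn_model` objects, one per disease.
#' @export
train_disease_models <- function(features, labels, spec,
                                 config = train_config(), ...) {
  x <- as.matrix(features)
  stopifnot(!is.null(rownames(x)), !is.null(rownames(labels)))
  labels <- labels[rownames(x), , drop = FALSE]
  models <- lapply(colnames(labels), function(dz) {
    pcnn_train(x, labels[, dz], spec, config = config, ...)
  })
  names(models) <- colnames(labels)
  models
}

#' Score compounds with trained per-disease models
#'
#' @param models Named list of `pcnn_model` objects.
#' @param features Feature matrix.
#' @return Score matrix in (0, 1), compounds x diseases.
#' @export
predict_disease_models <- function(models, features) {
  x <- as.matrix(features)
  scores <- vapply(models, function(m) pcnn_predict(m, x), numeric(nrow(x)))
  rownames(scores) <- rownames(x)
  scores
}
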