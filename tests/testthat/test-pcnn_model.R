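test_that("block masks are block-diagonal with the closed-form edge count", {
  m <- build_mask(c(2L, 3L), c(1L, 2L))
  expect_equal(dim(m), c(5L, 3L))
  expect_equal(sum(m), 2 * 1 + 3 * 2)
  expect_equal(m[1:2, 1], c(1, 1))
  expect_equal(sum(m[1:2, 2:3]), 0)
  expect_equal(sum(m[3:5, 1]), 0)

  # single block: fully connected limit
  expect_true(all(build_mask(4L, 3L) == 1))

  spec <- default_mask_spec()
  m_full <- build_mask(spec$input, spec$hidden1)
  expect_equal(sum(m_full), 112468)
})

test_that("edge accounting matches the per-block products", {
  spec <- default_mask_spec()
  acc <- count_partial_edges(spec)
  expect_equal(unname(acc$partial["layer1"]),
               300 * 200 + 285 * 160 + 101 * 68)
  expect_equal(unname(acc$full["layer1"]), 686 * 428)
  expect_lt(acc$ratio_to_full, 0.40)
  expect_gt(acc$ratio_to_full, 0.33)

  one <- pcnn_mask_spec(c(b = 10L), c(b = 7L))
  acc1 <- count_partial_edges(one)
  expect_equal(unname(acc1$partial["layer1"]), 10 * 7)
  expect_equal(acc1$ratio_to_full, 1)

  set.seed(3)
  for (i in 1:5) {
    nb <- sample(2:4, 1)
    sp <- pcnn_mask_spec(sample(2:9, nb), sample(2:9, nb), sample(2:9, nb))
    expect_equal(sum(build_mask(sp$input, sp$hidden1)),
                 sum(sp$input * sp$hidden1))
    expect_equal(sum(build_mask(sp$hidden1, sp$hidden2)),
                 sum(sp$hidden1 * sp$hidden2))
  }
})

test_that("initialization is He-scaled over the unmasked fan-in", {
  w <- init_params(100L, 1000L, seed = 5L)
  expect_lt(abs(mean(w)), 3 * sqrt(2 / 100) / sqrt(length(w)))
  expect_lt(abs(stats::sd(w) - sqrt(2 / 100)), 0.002)
  expect_identical(init_params(10L, 4L, seed = 9L), init_params(10L, 4L, seed = 9L))

  mask <- build_mask(c(40L, 160L), c(500L, 500L))
  wm <- init_params(200L, 1000L, mask = mask, seed = 6L)
  expect_true(all(wm[mask == 0] == 0))
  sd_block1 <- stats::sd(wm[1:40, 1:500])
  sd_block2 <- stats::sd(wm[41:200, 501:1000])
  expect_lt(abs(sd_block1 - sqrt(2 / 40)), 0.01)
  expect_lt(abs(sd_block2 - sqrt(2 / 160)), 0.005)
})

test_that("class weights are inverse class frequencies", {
  expect_equal(class_weights(rep(c(0, 1), 25)), c(w0 = 1, w1 = 1))
  expect_equal(unname(class_weights(c(rep(0, 90), rep(1, 10)))["w1"]), 5.0)
  y <- c(rep(0, 37), rep(1, 13))
  cw <- class_weights(y)
  expect_equal(cw[["w0"]] * 37, cw[["w1"]] * 13)
  expect_error(class_weights(rep(1, 5)), "single class")
})

test_that("weighted cross-entropy matches hand values and the textbook form", {
  expect_equal(weighted_bce(c(1, 0), c(1, 0)), 0, tolerance = 1e-6)
  expect_equal(weighted_bce(1, 0.5, w0 = 2), 2 * log(2))
  set.seed(8)
  y <- rbinom(20, 1, 0.5)
  p <- runif(20, 0.05, 0.95)
  textbook <- -sum(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce(y, p), textbook, tolerance = 1e-10)
  expect_error(weighted_bce(c(1, 0), 0.5), "lengths differ")
})

tiny_spec <- function() pcnn_mask_spec(c(a = 2L), c(a = 1L))

test_that("an untrained network with zeroed weights outputs 0.5", {
  model <- pcnn_init(tiny_spec(), fc_widths = integer(0), seed = 1L)
  for (li in seq_along(model$layers)) {
    model$layers[[li]]$W[] <- 0
    model$layers[[li]]$b[] <- 0
  }
  model$out$W[] <- 0
  model$out$b <- 0
  p <- pcnn_predict(model, matrix(rnorm(10), 5, 2))
  expect_equal(unname(p), rep(0.5, 5))
})

test_that("a hand-computed two-feature network matches the closed form", {
  model <- pcnn_init(tiny_spec(), fc_widths = integer(0), seed = 2L)
  # fresh model: batch-norm falls back to identity statistics (mean 0, var 1)
  model$layers[[1]]$W <- matrix(c(0.5, -0.25), 2, 1)
  model$layers[[1]]$b <- 0.1
  model$layers[[2]]$W <- matrix(2, 1, 1)
  model$layers[[2]]$b <- -0.05
  model$out$W <- matrix(1.5, 1, 1)
  model$out$b <- 0.2
  x <- matrix(c(1, -2, 0.3, 0.4), 2, 2, byrow = TRUE)
  eps <- 1e-5
  h1 <- pmax((x %*% model$layers[[1]]$W + 0.1) / sqrt(1 + eps), 0)
  h2 <- pmax((h1 * 2 - 0.05) / sqrt(1 + eps), 0)
  expected <- 1 / (1 + exp(-(h2 * 1.5 + 0.2)))
  expect_equal(unname(pcnn_predict(model, x)), as.numeric(expected),
               tolerance = 1e-12)
})

test_that("masked entries cannot influence the output", {
  spec <- pcnn_mask_spec(c(a = 3L, b = 3L), c(a = 2L, b = 2L))
  model <- pcnn_init(spec, fc_widths = 4L, seed = 3L)
  x <- matrix(rnorm(30), 5, 6)
  base <- pcnn_predict(model, x)
  corrupted <- model
  for (li in 1:2) {
    w <- corrupted$layers[[li]]$W
    w[corrupted$layers[[li]]$mask == 0] <- 1e6
    corrupted$layers[[li]]$W <- w
  }
  expect_false(isTRUE(all.equal(pcnn_predict(corrupted, x), base)))
  for (li in 1:2) {
    corrupted$layers[[li]]$W <- corrupted$layers[[li]]$W *
      corrupted$layers[[li]]$mask
  }
  expect_equal(pcnn_predict(corrupted, x), base)
})

separable_data <- function(n = 60, seed = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  y <- as.integer(x[, 1] + x[, 4] + rnorm(n, sd = 0.3) > 0)
  list(x = x, y = y)
}

fast_config <- function(seed = 1L) {
  train_config(learning_rate = 5e-3, max_epochs = 150L, patience = 30L,
               batch_size = 16L, seed = seed)
}

test_that("training beats the coin-flip baseline and preserves the mask", {
  d <- separable_data()
  spec <- pcnn_mask_spec(c(a = 3L, b = 3L), c(a = 3L, b = 3L))
  model <- pcnn_train(d$x, d$y, spec, config = fast_config(),
                      fc_widths = 4L)
  cw <- model$class_weights
  baseline <- weighted_bce(d$y, rep(0.5, length(d$y)),
                           cw["w_pos"], cw["w_neg"]) / length(d$y)
  expect_lt(utils::tail(model$history$train_loss, 1), baseline)
  expect_equal(mask_violation(model), 0)
  expect_gt(model$best_epoch, 0L)
  expect_true(all(diff(model$history$epoch) == 1))
})

test_that("training is deterministic under a fixed seed", {
  d <- separable_data(n = 40, seed = 4)
  spec <- pcnn_mask_spec(c(a = 3L, b = 3L), c(a = 2L, b = 2L))
  m1 <- pcnn_train(d$x, d$y, spec, config = fast_config(7L), fc_widths = 4L)
  m2 <- pcnn_train(d$x, d$y, spec, config = fast_config(7L), fc_widths = 4L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
})

test_that("prediction is deterministic, duplicate-consistent and batch-invariant", {
  d <- separable_data(n = 50, seed = 6)
  spec <- pcnn_mask_spec(c(a = 3L, b = 3L), c(a = 2L, b = 2L))
  model <- pcnn_train(d$x, d$y, spec, config = fast_config(2L), fc_widths = 4L)
  dup <- d$x[c(1, 1, 2), ]
  p <- pcnn_predict(model, dup)
  expect_equal(unname(p[1]), unname(p[2]))
  whole <- pcnn_predict(model, d$x)
  halves <- c(pcnn_predict(model, d$x[1:20, ]),
              pcnn_predict(model, d$x[21:50, ]))
  expect_equal(whole, halves)
  expect_true(all(whole > 0 & whole < 1))
})

test_that("per-disease training scores positives above negatives", {
  d <- separable_data(n = 80, seed = 12)
  labels <- cbind(D01 = d$y, D02 = as.integer(d$x[, 2] > 0))
  rownames(labels) <- rownames(d$x)
  spec <- pcnn_mask_spec(c(a = 3L, b = 3L), c(a = 3L, b = 3L))
  models <- train_disease_models(d$x, labels, spec, config = fast_config(3L),
                                 fc_widths = 4L)
  expect_named(models, c("D01", "D02"))
  scores <- predict_disease_models(models, d$x)
  expect_equal(dim(scores), c(80L, 2L))
  for (dz in colnames(labels)) {
    w <- stats::wilcox.test(scores[labels[, dz] == 1, dz],
                            scores[labels[, dz] == 0, dz],
                            alternative = "greater", exact = FALSE)
    expect_lt(w$p.value, 0.01)
  }
})

test_that("feature width mismatches are rejected", {
  d <- separable_data(n = 30)
  spec <- pcnn_mask_spec(c(a = 4L, b = 4L), c(a = 2L, b = 2L))
  expect_error(pcnn_train(d$x, d$y, spec, config = fast_config()),
               "does not match")
  model <- pcnn_init(tiny_spec(), seed = 1L)
  expect_error(pcnn_predict(model, matrix(0, 2, 5)), "does not match")
})
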