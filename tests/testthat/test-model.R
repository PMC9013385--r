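tiny_cfg <- function(...) {
  model_config(levels = 2, base_filters = 2, input_shape = c(4L, 8L, 8L, 1L), ...)
}

test_that("configuration validates divisibility and level count", {
  expect_error(model_config(levels = 1), ">= 2")
  expect_error(model_config(levels = 4, input_shape = c(4L, 8L, 8L, 1L)),
               "divisible")
  expect_s3_class(tiny_cfg(), "model_config")
})

test_that("toggles only ever add name-scoped parameters (ablation nesting)", {
  cfgs <- ablation_configs(levels = 2, base_filters = 2,
                           input_shape = c(4L, 8L, 8L, 1L))
  nets <- lapply(cfgs, build_dalunet, init_seed = 1)
  nm <- lapply(nets, function(n) names(n$params))
  expect_false(any(grepl("^(ag|clstm|ds)", nm$unet3d)))
  expect_true(any(grepl("^ag", nm$aunet)))
  expect_false(any(grepl("^(clstm|ds)", nm$aunet)))
  expect_true(any(grepl("^ds", nm$aunet_ds)))
  expect_true(any(grepl("^clstm", nm$dalunet)))
  # strict nesting of the parameter-name sets along the ladder
  expect_true(all(nm$unet3d %in% nm$aunet) && length(nm$aunet) > length(nm$unet3d))
  expect_true(all(nm$aunet %in% nm$aunet_ds) && length(nm$aunet_ds) > length(nm$aunet))
  expect_true(all(nm$aunet_ds %in% nm$dalunet) &&
                length(nm$dalunet) > length(nm$aunet_ds))
  counts <- vapply(nets, n_params, 1L)
  expect_true(all(diff(counts) > 0))
})

test_that("building twice from one seed gives identical parameters", {
  cfg <- tiny_cfg(use_attention = TRUE, use_deep_supervision = TRUE,
                  use_clstm = TRUE)
  expect_identical(build_dalunet(cfg, init_seed = 42)$params,
                   build_dalunet(cfg, init_seed = 42)$params)
})

test_that("forward pass honours the shape contract and the sigmoid range", {
  cfg <- model_config(levels = 3, base_filters = 2,
                      use_deep_supervision = TRUE, use_attention = TRUE,
                      input_shape = c(16L, 64L, 64L, 1L))
  net <- build_dalunet(cfg, init_seed = 2)
  set.seed(1)
  x <- array(runif(16 * 64 * 64), c(16, 64, 64, 1))
  out <- forward(net, x)
  expect_equal(dim(out$final_prob), c(16L, 64L, 64L))
  expect_true(all(out$final_prob >= 0 & out$final_prob <= 1))
  expect_length(out$ds_probs, 3)  # one head per level with levels = 3
  expect_error(forward(net, array(0, c(8, 64, 64, 1))), "does not match")
})

test_that("inference is deterministic run-to-run", {
  cfg <- tiny_cfg(use_attention = TRUE, use_clstm = TRUE)
  net <- build_dalunet(cfg, init_seed = 3)
  set.seed(2)
  x <- array(runif(4 * 8 * 8), c(4, 8, 8, 1))
  expect_identical(forward(net, x)$final_prob, forward(net, x)$final_prob)
})

test_that("attention coefficients are sigmoid-bounded and 0.5 at zero weights", {
  set.seed(4)
  s <- array(rnorm(4 * 8 * 8 * 2), c(4, 8, 8, 2))
  g <- array(rnorm(4 * 8 * 8 * 2), c(4, 8, 8, 2))
  zero_par <- list(Ws = matrix(0, 2, 2), Wg = matrix(0, 2, 2), b = numeric(2),
                   psi_W = matrix(0, 2, 1), psi_b = 0)
  ag0 <- attention_gate(s, g, zero_par)
  expect_true(all(ag0$alpha == 0.5))
  expect_equal(ag0$gated, 0.5 * s)
  ran_par <- list(Ws = matrix(rnorm(4), 2), Wg = matrix(rnorm(4), 2),
                  b = rnorm(2), psi_W = matrix(rnorm(2), 2, 1), psi_b = 0.3)
  ag <- attention_gate(s, g, ran_par)
  expect_true(all(ag$alpha > 0 & ag$alpha < 1))
  ag_zero_skip <- attention_gate(0 * s, g, ran_par)
  expect_true(all(ag_zero_skip$gated == 0))  # multiplicative gating
  expect_error(attention_gate(s, g, list(Ws = matrix(0, 3, 2), Wg = matrix(0, 2, 2),
                                         b = numeric(2), psi_W = matrix(0, 2, 1),
                                         psi_b = 0)),
               "channel")
})

test_that("ConvLSTM gate algebra: zero weights give zero output", {
  set.seed(5)
  x <- array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2))
  par0 <- list(Wx = array(0, c(3, 3, 2, 8)), Wh = array(0, c(3, 3, 2, 8)),
               b = numeric(8))
  expect_true(all(clstm_block(x, par0) == 0))  # h = sigmoid(0) * tanh(0)
})

test_that("a single-slice ConvLSTM step matches a hand-rolled recurrence", {
  set.seed(6)
  x <- array(rnorm(1 * 2 * 2 * 1), c(1, 2, 2, 1))
  Wx <- array(rnorm(3 * 3 * 1 * 4, sd = 0.5), c(3, 3, 1, 4))
  Wh <- array(rnorm(3 * 3 * 1 * 4, sd = 0.5), c(3, 3, 1, 4))
  b <- rnorm(4)
  out <- clstm_block(x, list(Wx = Wx, Wh = Wh, b = b))
  # oracle: one explicit recurrence step from zero state with loop convs
  z <- bf_conv2d(array(x[1, , , ], c(2, 2, 1)), Wx)  # h_prev = 0
  sig <- function(u) 1 / (1 + exp(-u))
  i <- sig(z[, , 1] + b[1]); f <- sig(z[, , 2] + b[2])
  o <- sig(z[, , 3] + b[3]); g <- tanh(z[, , 4] + b[4])
  h <- o * tanh(f * 0 + i * g)
  expect_equal(array(out[1, , , ], c(2, 2)), h, tolerance = 1e-12)
})

test_that("ConvLSTM output depends on slice order (causal recurrence)", {
  set.seed(7)
  x <- array(rnorm(3 * 4 * 4 * 1), c(3, 4, 4, 1))
  par <- list(Wx = array(rnorm(36, sd = 0.4), c(3, 3, 1, 4)),
              Wh = array(rnorm(36, sd = 0.4), c(3, 3, 1, 4)), b = rnorm(4))
  fwd <- clstm_block(x, par)
  rev_out <- clstm_block(x[3:1, , , , drop = FALSE], par)
  expect_false(isTRUE(all.equal(fwd, rev_out[3:1, , , , drop = FALSE])))
  # causality: the first slice's output ignores later slices
  x2 <- x
  x2[3, , , ] <- x2[3, , , ] + 5
  fwd2 <- clstm_block(x2, par)
  expect_equal(fwd2[1, , , ], fwd[1, , , ])
  expect_equal(fwd2[2, , , ], fwd[2, , , ])
  expect_error(clstm_block(array(0, c(0, 4, 4, 1)), par), "non-empty")
})

test_that("analytic gradients of every layer match finite differences", {
  cfg <- model_config(levels = 2, base_filters = 2, use_attention = TRUE,
                      use_deep_supervision = TRUE, use_clstm = TRUE,
                      input_shape = c(4L, 8L, 8L, 1L))
  net <- build_dalunet(cfg, init_seed = 3)
  set.seed(42)
  x <- array(runif(4 * 8 * 8), c(4, 8, 8, 1))
  gt <- array(rbinom(4 * 8 * 8, 1, 0.3), c(4, 8, 8))
  loss_of <- function(net) {
    f <- forward(net, x, training = TRUE)
    hepavol:::case_loss_grads(net, f, gt)$total
  }
  fwd <- forward(net, x, training = TRUE)
  lg <- hepavol:::case_loss_grads(net, fwd, gt)
  g <- hepavol:::backward(net, fwd, lg$dfinal, lg$dds)
  expect_setequal(names(g), names(net$params))
  eps <- 1e-5
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    ii <- max(1L, length(p) %/% 2L)
    net_p <- net; net_p$params[[nm]][ii] <- p[ii] + eps
    net_m <- net; net_m$params[[nm]][ii] <- p[ii] - eps
    num <- (loss_of(net_p) - loss_of(net_m)) / (2 * eps)
    expect_equal(g[[nm]][ii], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("predict_mask thresholds, unpads and stays monotone in threshold", {
  cfg <- tiny_cfg()
  net <- build_dalunet(cfg, init_seed = 1)
  # zero the output head and set its bias to logit(0.6): prob = 0.6 everywhere
  net$params[["out.W"]][] <- 0
  net$params[["out.b"]][] <- log(0.6 / 0.4)
  vol <- ct_volume(array(runif(6 * 8 * 8), c(6, 8, 8)), c(5, 1, 1),
                   windowed = TRUE)  # 6 slices: forces padding of the 4-block
  pred <- predict_mask(net, vol, threshold = 0.5)
  expect_equal(dim(pred), c(6L, 8L, 8L))
  expect_true(all(pred$masks$whole == 1))
  expect_true(all(predict_mask(net, vol, threshold = 1.0)$masks$whole == 0))

  net2 <- build_dalunet(cfg, init_seed = 8)
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1.01),
                   function(th) sum(predict_mask(net2, vol, th)$masks$whole), 1.0)
  expect_true(all(diff(counts) <= 0))
})

test_that("a small block forward-passes in under a second", {
  cfg <- model_config(levels = 2, base_filters = 4, use_attention = TRUE,
                      use_deep_supervision = TRUE, use_clstm = TRUE,
                      input_shape = c(8L, 32L, 32L, 1L))
  net <- build_dalunet(cfg, init_seed = 1)
  x <- array(runif(8 * 32 * 32), c(8, 32, 32, 1))
  forward(net, x)  # warm the index caches
  elapsed <- system.time(forward(net, x))[["elapsed"]]
  expect_lt(elapsed, 1)
})

test_that("checkpoints are self-describing", {
  cfg <- tiny_cfg(use_attention = TRUE)
  net <- build_dalunet(cfg, init_seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  expect_identical(net2$cfg, cfg)
  expect_identical(net2$params, net$params)
})
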