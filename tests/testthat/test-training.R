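test_that("config invariants are enforced", {
  expect_error(train_config(lr_factor = 1.5), "\\(0, 1\\)")
  expect_error(train_config(lr_patience = 0), "patiences")
  expect_error(train_config(lr_patience = 10, stop_patience = 10), "exceed")
})

test_that("an always-improving loss stream never reduces the learning rate", {
  tc <- train_config(max_epochs = 100)
  st <- schedule_init(tc)
  for (loss in seq(1, 0.01, length.out = 60)) {
    expect_false(early_stop_check(st, loss))
    st <- lr_schedule_step(st, loss)
  }
  expect_equal(st$lr, 0.01)
})

test_that("a constant loss stream compounds LR reductions at the patience cadence", {
  tc <- train_config()
  st <- schedule_init(tc)
  lrs <- numeric(25)
  for (e in 1:25) {
    st <- lr_schedule_step(st, 0.5)
    lrs[e] <- st$lr
  }
  expect_equal(lrs[10], 0.01)    # patience not yet exhausted at epoch 10
  expect_equal(lrs[11], 0.001)   # first reduction: 0.01 x 0.1
  expect_equal(lrs[20], 0.001)
  expect_equal(lrs[21], 1e-4)    # second reduction compounds
  expect_error(lr_schedule_step(st, NaN), "non-finite")
})

test_that("early stopping fires exactly at best + stop_patience", {
  tc <- train_config()
  st <- schedule_init(tc)
  fired_at <- NA
  for (e in 1:40) {
    if (early_stop_check(st, 0.5)) { fired_at <- e; break }
    st <- lr_schedule_step(st, 0.5)
  }
  expect_equal(fired_at, 31)  # best at epoch 1, 30 non-improving epochs after

  # an improvement inside the window resets the counter
  st <- schedule_init(tc)
  losses <- rep(0.5, 40)
  losses[1] <- 0.6
  losses[29] <- 0.4
  fired_at <- NA
  for (e in seq_along(losses)) {
    if (early_stop_check(st, losses[e])) { fired_at <- e; break }
    st <- lr_schedule_step(st, losses[e])
  }
  expect_true(is.na(fired_at) || fired_at > 31)
})

tiny_train_setup <- function(ds = TRUE) {
  cfg <- model_config(levels = 2, base_filters = 2, use_attention = TRUE,
                      use_deep_supervision = ds, use_clstm = FALSE,
                      input_shape = c(4L, 8L, 8L, 1L))
  set.seed(99)
  cases <- lapply(1:2, function(i) {
    y <- array(0, c(4, 8, 8))
    y[, 3:6, 3:6] <- 1
    list(x = array(runif(4 * 8 * 8), c(4, 8, 8, 1)) * 0.5 + 0.5 * rep(y, 1), y = y)
  })
  list(cfg = cfg, cases = cases)
}

test_that("zero-epoch training returns an untrained network and empty history", {
  s <- tiny_train_setup()
  res <- train(s$cfg, train_config(max_epochs = 0), s$cases)
  expect_equal(nrow(res$history), 0)
  expect_equal(res$stop_reason, "max_epochs")
  expect_identical(res$net$params,
                   build_dalunet(s$cfg, init_seed = hepavol:::derive_seed(1, 1))$params)
  expect_error(train(s$cfg, train_config(max_epochs = 1), list()), "empty")
})

test_that("training histories are bit-reproducible for a fixed seed", {
  s <- tiny_train_setup()
  tc <- train_config(max_epochs = 3, seed = 21)
  r1 <- train(s$cfg, tc, s$cases)
  r2 <- train(s$cfg, tc, s$cases)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("logged total loss equals final-head loss plus the DS sum", {
  s <- tiny_train_setup(ds = TRUE)
  res <- train(s$cfg, train_config(max_epochs = 3, seed = 2), s$cases)
  h <- res$history
  expect_equal(h$train_loss, h$train_final_loss + h$train_ds_loss,
               tolerance = 1e-6)
  expect_true(all(h$train_ds_loss > 0))  # DS heads contribute
  no_ds <- tiny_train_setup(ds = FALSE)
  h2 <- train(no_ds$cfg, train_config(max_epochs = 2, seed = 2), no_ds$cases)$history
  expect_true(all(h2$train_ds_loss == 0))
})

test_that("history learning rates are exactly initial_lr x factor^k and non-increasing", {
  s <- tiny_train_setup(ds = FALSE)
  tc <- train_config(max_epochs = 8, lr_patience = 2, stop_patience = 6, seed = 3)
  h <- train(s$cfg, tc, s$cases)$history
  k <- log(h$lr / tc$initial_lr) / log(tc$lr_factor)
  expect_equal(k, round(k), tolerance = 1e-9)
  expect_true(all(diff(h$lr) <= 1e-15))
  expect_true(all(diff(h$epoch) == 1) && h$epoch[1] == 1)
})

test_that("training and validation losses are finite and in [0, 1 + levels]", {
  s <- tiny_train_setup()
  h <- train(s$cfg, train_config(max_epochs = 2, seed = 4), s$cases)$history
  expect_true(all(is.finite(h$train_loss)) && all(is.finite(h$val_loss)))
  expect_true(all(h$val_loss >= 0 & h$val_loss <= 1))
})

test_that("tidy and glance expose the history and run summary", {
  s <- tiny_train_setup()
  res <- train(s$cfg, train_config(max_epochs = 2, seed = 5), s$cases)
  expect_identical(generics::tidy(res), res$history)
  gl <- generics::glance(res)
  expect_equal(gl$epochs, 2)
  expect_true(gl$stop_reason %in% c("max_epochs", "early_stop", "stop_loss"))
})
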