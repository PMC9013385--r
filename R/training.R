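#' Training configuration
#'
#' Adam on the dice loss with reduce-on-plateau scheduling and early
#' stopping: when the monitored loss has not improved (strict decrease beyond
#' `1e-8`) for `lr_patience` consecutive epochs the learning rate is
#' multiplied by `lr_factor` (reductions compound, per plateau-scheduler
#' convention), and training stops after `stop_patience` consecutive
#' non-improving epochs. Defaults: initial LR 0.01, factor 0.1, patience 10,
#' stop patience 30. The monitored quantity is the validation dice loss.
#'
#' @param initial_lr Starting learning rate.
#' @param lr_factor Multiplicative LR reduction factor in `(0, 1)`.
#' @param lr_patience Epochs of no improvement before an LR reduction.
#' @param stop_patience Epochs of no improvement before stopping; must
#'   exceed `lr_patience`.
#' @param max_epochs Epoch budget.
#' @param batch_size Cases per gradient step (3D blocks are large; default 1).
#' @param seed Seed for shuffling and any stochastic choice in the loop.
#' @param monitor Name of the monitored loss (informational).
#' @param stop_loss Optional floor: stop once the training loss drops below
#'   it (off by default).
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, lr_factor = 0.1, lr_patience = 10L,
                         stop_patience = 30L, max_epochs = 100L,
                         batch_size = 1L, seed = 1L,
                         monitor = "val_dice_loss", stop_loss = NULL) {
  if (lr_factor <= 0 || lr_factor >= 1) abort("`lr_factor` must be in (0, 1).")
  if (lr_patience < 1L || stop_patience < 1L) abort("patiences must be >= 1.")
  if (stop_patience <= lr_patience) abort("`stop_patience` must exceed `lr_patience`.")
  if (max_epochs < 0L) abort("`max_epochs` must be >= 0.")
  structure(list(
    initial_lr = initial_lr, lr_factor = lr_factor,
    lr_patience = as.integer(lr_patience),
    stop_patience = as.integer(stop_patience),
    max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed), monitor = monitor, stop_loss = stop_loss
  ), class = "train_config")
}

#' Initialise plateau-scheduler state
#'
#' @param tc A [train_config()].
#' @return Schedule state: best loss so far, epochs since improvement (for
#'   the LR rule and for early stopping separately), current LR, epoch count.
#' @export
schedule_init <- function(tc) {
  structure(list(
    best = Inf, wait_lr = 0L, wait_stop = 0L, lr = tc$initial_lr,
    epoch = 0L, lr_patience = tc$lr_patience, lr_factor = tc$lr_factor,
    stop_patience = tc$stop_patience
  ), class = "schedule_state")
}

#' Advance the LR schedule by one epoch
#'
#' An improvement is a strict decrease of the monitored loss beyond `1e-8`.
#' After `lr_patience` consecutive non-improving epochs the LR is multiplied
#' by `lr_factor` and the LR patience counter resets; the early-stop counter
#' keeps running.
#'
#' @param state A `schedule_state`.
#' @param epoch_loss Monitored loss for the epoch just finished.
#' @return Updated state.
#' @export
lr_schedule_step <- function(state, epoch_loss) {
  stopifnot(inherits(state, "schedule_state"))
  if (!is.finite(epoch_loss)) {
    abort(sprintf("non-finite monitored loss (%s) at epoch %d; training aborted.",
                  format(epoch_loss), state$epoch + 1L))
  }
  state$epoch <- state$epoch + 1L
  if (state$best - epoch_loss > 1e-8) {
    state$best <- epoch_loss
    state$wait_lr <- 0L
    state$wait_stop <- 0L
  } else {
    state$wait_lr <- state$wait_lr + 1L
    state$wait_stop <- state$wait_stop + 1L
    if (state$wait_lr >= state$lr_patience) {
      state$lr <- state$lr * state$lr_factor
      state$wait_lr <- 0L
    }
  }
  state
}

#' Early-stopping predicate
#'
#' Called with the same `(state, epoch_loss)` pair *before*
#' [lr_schedule_step()]: returns `TRUE` exactly when this epoch completes
#' `stop_patience` consecutive non-improving epochs.
#'
#' @param state A `schedule_state` (not yet advanced for this epoch).
#' @param epoch_loss Monitored loss for the epoch just finished.
#' @return Logical.
#' @export
early_stop_check <- function(state, epoch_loss) {
  stopifnot(inherits(state, "schedule_state"))
  improved <- state$best - epoch_loss > 1e-8
  !improved && (state$wait_stop + 1L) >= state$stop_patience
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

# total loss and head gradients for one case; gt is the full-resolution
# binary target for the block
case_loss_grads <- function(net, fwd, gt) {
  cfg <- net$cfg
  final_loss <- dice_loss(fwd$final_prob, gt)
  dfinal <- dice_loss_grad(fwd$final_prob, gt)
  ds_losses <- numeric(0)
  dds <- list()
  if (cfg$use_deep_supervision) {
    L <- cfg$levels
    keys <- names(fwd$ds_probs)
    for (key in keys) {
      k <- if (key == "bott") L - 1L else as.integer(sub("lvl", "", key)) - 1L
      gt_k <- downsample_mask(gt, k)
      ds_losses[key] <- dice_loss(fwd$ds_probs[[key]], gt_k)
      dds[[key]] <- dice_loss_grad(fwd$ds_probs[[key]], gt_k)
    }
  }
  list(final_loss = final_loss, ds_losses = ds_losses,
       total = final_loss + if (length(ds_losses)) ds_total_loss(ds_losses) else 0,
       dfinal = dfinal, dds = dds)
}

#' Train a segmentation network
#'
#' Minimises the dice loss (plus, with deep supervision, the summed
#' per-level dice losses) with Adam. Each case supplies one input block and
#' its binary target. Per epoch the training set is reshuffled
#' deterministically from the seed, the validation dice loss of the final
#' head (inference mode) is monitored, the LR plateau rule and early-stop
#' rule are applied, and the epoch is appended to the history.
#'
#' @param cfg A [model_config()].
#' @param tc A [train_config()].
#' @param train_cases,val_cases Lists of cases, each `list(x = , y = )` with
#'   `x` an input block of shape `cfg$input_shape` and `y` the binary target
#'   `(depth, H, W)`. `val_cases` defaults to the training cases.
#' @param init_seed Weight-initialisation seed (default derived from
#'   `tc$seed`).
#' @return Object of class `train_result`: `net` (weights at the
#'   best-validation epoch), `history` (tibble: epoch, train/val losses, lr),
#'   `stop_reason` (`"early_stop"`, `"stop_loss"` or `"max_epochs"`).
#' @export
train <- function(cfg, tc, train_cases, val_cases = train_cases,
                  init_seed = NULL) {
  stopifnot(inherits(cfg, "model_config"), inherits(tc, "train_config"))
  if (length(train_cases) == 0L) abort("empty training set.")
  if (is.null(init_seed)) init_seed <- derive_seed(tc$seed, 1)
  net <- build_dalunet(cfg, init_seed = init_seed)
  opt <- adam_init(net$params)
  state <- schedule_init(tc)
  history <- list()
  stop_reason <- "max_epochs"
  best_net <- net
  best_val <- Inf
  n <- length(train_cases)
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- with_seed(derive_seed(tc$seed, 1000 + epoch), sample.int(n))
    final_losses <- numeric(n)
    ds_sums <- numeric(n)
    batch_grads <- NULL
    in_batch <- 0L
    for (i in seq_along(ord)) {
      case <- train_cases[[ord[i]]]
      fwd <- forward(net, case$x, training = TRUE)
      net$bn <- fwd$bn
      lg <- case_loss_grads(net, fwd, case$y)
      final_losses[i] <- lg$final_loss
      ds_sums[i] <- if (length(lg$ds_losses)) ds_total_loss(lg$ds_losses) else 0
      g <- backward(net, fwd, lg$dfinal, lg$dds)
      if (is.null(batch_grads)) {
        batch_grads <- g
      } else {
        for (nm in names(g)) batch_grads[[nm]] <- batch_grads[[nm]] + g[[nm]]
      }
      in_batch <- in_batch + 1L
      if (in_batch == tc$batch_size || i == n) {
        for (nm in names(batch_grads)) {
          batch_grads[[nm]] <- batch_grads[[nm]] / in_batch
        }
        upd <- adam_step(net$params, batch_grads, opt, state$lr)
        net$params <- upd$params
        opt <- upd$st
        batch_grads <- NULL
        in_batch <- 0L
      }
    }
    train_final <- mean(final_losses)
    train_ds <- mean(ds_sums)
    train_total <- train_final + train_ds
    val_loss <- mean(vapply(val_cases, function(case) {
      dice_loss(forward(net, case$x, training = FALSE)$final_prob, case$y)
    }, 1.0))
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_total, train_final_loss = train_final,
      train_ds_loss = train_ds, val_loss = val_loss, lr = state$lr
    )
    if (val_loss < best_val) {
      best_val <- val_loss
      best_net <- net
    }
    stop_now <- early_stop_check(state, val_loss)
    state <- lr_schedule_step(state, val_loss)
    if (stop_now) {
      stop_reason <- "early_stop"
      break
    }
    if (!is.null(tc$stop_loss) && train_total < tc$stop_loss) {
      stop_reason <- "stop_loss"
      break
    }
  }
  history <- if (length(history)) dplyr::bind_rows(history) else
    tibble::tibble(epoch = integer(), train_loss = numeric(),
                   train_final_loss = numeric(), train_ds_loss = numeric(),
                   val_loss = numeric(), lr = numeric())
  structure(list(net = best_net, final_net = net, history = history,
                 stop_reason = stop_reason, config = tc),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs, stop: %s", nrow(x$history), x$stop_reason))
  if (nrow(x$history)) {
    cat(sprintf(", best val loss %.4f", min(x$history$val_loss)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname train
#' @param x A `train_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.train_result <- function(x, ...) x$history

#' @rdname train
#' @exportS3Method generics::glance
glance.train_result <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    best_val_loss = if (nrow(h)) min(h$val_loss) else NA_real_,
    final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    final_lr = if (nrow(h)) h$lr[nrow(h)] else NA_real_,
    stop_reason = x$stop_reason
  )
}

#' Loss-curve plot for a training run
#' @param object A `train_result`.
#' @param ... Unused.
#' @return A ggplot of train and validation loss by epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.train_result <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Dice loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Preprocess a phantom or CT case into training blocks
#'
#' Windows, resizes and blocks the image, and pairs each block with the
#' matching slices of the chosen structure's mask (nearest-neighbour resized
#' on the same grid, zero-padded like the image).
#'
#' @param image A [ct_volume()] in HU.
#' @param labels A [label_volume()] on the same grid.
#' @param structure Target structure.
#' @param target In-plane size after resizing.
#' @param depth Block depth.
#' @param w A [window_spec()].
#' @return List of cases `list(x, y)` suitable for [train()].
#' @export
prepare_case <- function(image, labels, structure = "whole", target = 256L,
                         depth = 64L, w = window_spec()) {
  vol <- apply_window(image, w)
  vol <- resize_inplane(vol, target)
  lab <- resize_inplane(labels, target)
  blocked <- to_model_blocks(vol, depth)
  m <- lab$masks[[structure]]
  if (is.null(m)) abort(paste0("structure `", structure, "` missing."))
  lapply(seq_along(blocked$blocks), function(b) {
    i0 <- (b - 1L) * depth + 1L
    y <- array(0, c(depth, dim(m)[2], dim(m)[3]))
    y[seq_len(blocked$valid[b]), , ] <- m[i0:(i0 + blocked$valid[b] - 1L), , ]
    list(x = blocked$blocks[[b]], y = y)
  })
}
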