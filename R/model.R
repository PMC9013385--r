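#' Segmentation network configuration
#'
#' Architecture toggles for the 3D encoder-decoder family. All toggles off is
#' the plain 3D U-Net baseline; `use_attention` adds attention gates on the
#' skip connections (AU-Net); `use_deep_supervision` adds per-level sigmoid
#' heads whose dice losses are summed into the objective (AU-Net w/ DS); and
#' `use_clstm` additionally runs a convolutional LSTM along the slice axis on
#' the gated skip features in the decoder — the full model. The four
#' combinations reproduce the ablation ladder.
#'
#' @param levels Number of resolution levels (`>= 2`); spatial dims of
#'   `input_shape` must be divisible by `2^(levels - 1)`.
#' @param base_filters Filters at the finest level; doubled per level.
#' @param use_attention,use_deep_supervision,use_clstm Architecture toggles.
#' @param input_shape `(depth, height, width, 1)` of one model block.
#' @return An object of class `model_config`.
#' @export
model_config <- function(levels = 3L, base_filters = 8L,
                         use_attention = FALSE, use_deep_supervision = FALSE,
                         use_clstm = FALSE,
                         input_shape = c(64L, 256L, 256L, 1L)) {
  levels <- as.integer(levels); base_filters <- as.integer(base_filters)
  if (levels < 2L) abort("`levels` must be >= 2.")
  if (base_filters < 1L) abort("`base_filters` must be >= 1.")
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 4L || input_shape[4] != 1L) {
    abort("`input_shape` must be (depth, height, width, 1).")
  }
  div <- 2L^(levels - 1L)
  if (any(input_shape[1:3] %% div != 0L)) {
    abort(sprintf("spatial dims must be divisible by 2^(levels-1) = %d.", div))
  }
  structure(list(
    levels = levels, base_filters = base_filters,
    use_attention = isTRUE(use_attention),
    use_deep_supervision = isTRUE(use_deep_supervision),
    use_clstm = isTRUE(use_clstm),
    input_shape = input_shape
  ), class = "model_config")
}

#' The four ablation configurations
#'
#' @param ... Passed to [model_config()] (e.g. `levels`, `base_filters`,
#'   `input_shape`).
#' @return Named list of [model_config()]s: `unet3d`, `aunet`, `aunet_ds`,
#'   `dalunet`.
#' @export
ablation_configs <- function(...) {
  list(
    unet3d = model_config(...),
    aunet = model_config(use_attention = TRUE, ...),
    aunet_ds = model_config(use_attention = TRUE, use_deep_supervision = TRUE, ...),
    dalunet = model_config(use_attention = TRUE, use_deep_supervision = TRUE,
                           use_clstm = TRUE, ...)
  )
}

level_filters <- function(cfg) cfg$base_filters * 2L^(seq_len(cfg$levels) - 1L)

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

#' Build a segmentation network from a configuration
#'
#' Allocates and seeds every parameter tensor the configuration calls for:
#' two 3x3x3 conv + batch-norm + ReLU blocks per level, 2x2x2 max pooling,
#' 2x2x2 transposed-conv upsampling, and — per toggle — attention gates,
#' deep-supervision heads and decoder convolutional LSTMs. The parameter set
#' is a pure function of the configuration, and toggles only ever add
#' name-scoped parameters, so the ablation ladder is nested by construction.
#'
#' @param cfg A [model_config()].
#' @param init_seed Seed for weight initialisation (He for convolutions).
#' @return Object of class `dalunet` holding `cfg`, `params` (named list) and
#'   `bn` (running statistics).
#' @export
build_dalunet <- function(cfg, init_seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  L <- cfg$levels
  f <- level_filters(cfg)
  params <- list()
  bn <- list()
  with_seed(init_seed, {
    add_conv <- function(name, cin, cout) {
      params[[paste0(name, ".W")]] <<- he_init(c(3, 3, 3, cin, cout), 27 * cin)
      params[[paste0(name, ".b")]] <<- numeric(cout)
    }
    add_bn <- function(name, c) {
      params[[paste0(name, ".gamma")]] <<- rep(1, c)
      params[[paste0(name, ".beta")]] <<- numeric(c)
      bn[[name]] <<- list(mean = numeric(c), var = rep(1, c))
    }
    add_block <- function(name, cin, cout) {
      add_conv(paste0(name, ".conv1"), cin, cout)
      add_bn(paste0(name, ".bn1"), cout)
      add_conv(paste0(name, ".conv2"), cout, cout)
      add_bn(paste0(name, ".bn2"), cout)
    }
    for (l in seq_len(L)) {
      cin <- if (l == 1L) 1L else f[l - 1L]
      add_block(paste0("enc", l), cin, f[l])
    }
    for (l in rev(seq_len(L - 1L))) {
      nm <- paste0("dec", l)
      params[[paste0(nm, ".up.W")]] <- he_init(c(2, 2, 2, f[l + 1L], f[l]), 8 * f[l + 1L])
      params[[paste0(nm, ".up.b")]] <- numeric(f[l])
      if (cfg$use_attention) {
        ag <- paste0("ag", l)
        params[[paste0(ag, ".Ws")]] <- he_init(c(f[l], f[l]), f[l])
        params[[paste0(ag, ".Wg")]] <- he_init(c(f[l], f[l]), f[l])
        params[[paste0(ag, ".b")]] <- numeric(f[l])
        params[[paste0(ag, ".psi.W")]] <- he_init(c(f[l], 1), f[l])
        params[[paste0(ag, ".psi.b")]] <- numeric(1)
      }
      if (cfg$use_clstm) {
        cl <- paste0("clstm", l)
        params[[paste0(cl, ".Wx")]] <- he_init(c(3, 3, f[l], 4 * f[l]), 9 * f[l])
        params[[paste0(cl, ".Wh")]] <- he_init(c(3, 3, f[l], 4 * f[l]), 9 * f[l])
        b <- numeric(4 * f[l])
        b[f[l] + seq_len(f[l])] <- 1  # forget-gate bias opens the cell path
        params[[paste0(cl, ".b")]] <- b
      }
      if (cfg$use_deep_supervision) {
        ds <- paste0("ds", l)
        params[[paste0(ds, ".W")]] <- he_init(c(f[l], 1), f[l])
        params[[paste0(ds, ".b")]] <- numeric(1)
      }
      add_block(nm, 2L * f[l], f[l])
    }
    if (cfg$use_deep_supervision) {
      params[["ds.bott.W"]] <- he_init(c(f[L], 1), f[L])
      params[["ds.bott.b"]] <- numeric(1)
    }
    params[["out.W"]] <- he_init(c(f[1], 1), f[1])
    params[["out.b"]] <- numeric(1)
  })
  structure(list(cfg = cfg, params = params, bn = bn), class = "dalunet")
}

#' @export
print.dalunet <- function(x, ...) {
  cfg <- x$cfg
  tag <- if (cfg$use_clstm) "DALU-Net"
  else if (cfg$use_deep_supervision) "AU-Net w/ DS"
  else if (cfg$use_attention) "AU-Net"
  else "3D U-Net"
  cat(sprintf(
    "<dalunet> %s: %d levels, base %d filters, input %s, %s parameters\n",
    tag, cfg$levels, cfg$base_filters,
    paste(cfg$input_shape, collapse = "x"),
    format(n_params(x), big.mark = ",")
  ))
  invisible(x)
}

#' Total trainable parameter count
#' @param net A `dalunet`.
#' @return Integer count.
#' @export
n_params <- function(net) sum(vapply(net$params, length, 1L))

ag_param_names <- function(name) {
  paste0(name, c(".Ws", ".Wg", ".b", ".psi.W", ".psi.b"))
}

convblock_fwd <- function(x, name, net, training, tape) {
  p <- net$params
  c1 <- conv3d_forward(x, p[[paste0(name, ".conv1.W")]], p[[paste0(name, ".conv1.b")]])
  b1 <- bn_forward(c1$y, p[[paste0(name, ".bn1.gamma")]], p[[paste0(name, ".bn1.beta")]],
                   tape$bn[[paste0(name, ".bn1")]]$mean,
                   tape$bn[[paste0(name, ".bn1")]]$var, training)
  tape$bn[[paste0(name, ".bn1")]] <- list(mean = b1$run_mean, var = b1$run_var)
  r1 <- relu_forward(b1$y)
  c2 <- conv3d_forward(r1$y, p[[paste0(name, ".conv2.W")]], p[[paste0(name, ".conv2.b")]])
  b2 <- bn_forward(c2$y, p[[paste0(name, ".bn2.gamma")]], p[[paste0(name, ".bn2.beta")]],
                   tape$bn[[paste0(name, ".bn2")]]$mean,
                   tape$bn[[paste0(name, ".bn2")]]$var, training)
  tape$bn[[paste0(name, ".bn2")]] <- list(mean = b2$run_mean, var = b2$run_var)
  r2 <- relu_forward(b2$y)
  tape$caches[[name]] <- list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2)
  r2$y
}

convblock_bwd <- function(dy, name, net, tape, grads) {
  p <- net$params
  cc <- tape$caches[[name]]
  d <- relu_backward(dy, cc$r2)
  bb <- bn_backward(d, p[[paste0(name, ".bn2.gamma")]], cc$b2)
  grads[[paste0(name, ".bn2.gamma")]] <- bb$dgamma
  grads[[paste0(name, ".bn2.beta")]] <- bb$dbeta
  cb <- conv3d_backward(bb$dx, p[[paste0(name, ".conv2.W")]], cc$c2)
  grads[[paste0(name, ".conv2.W")]] <- cb$dW
  grads[[paste0(name, ".conv2.b")]] <- cb$db
  d <- relu_backward(cb$dx, cc$r1)
  bb <- bn_backward(d, p[[paste0(name, ".bn1.gamma")]], cc$b1)
  grads[[paste0(name, ".bn1.gamma")]] <- bb$dgamma
  grads[[paste0(name, ".bn1.beta")]] <- bb$dbeta
  cb <- conv3d_backward(bb$dx, p[[paste0(name, ".conv1.W")]], cc$c1)
  grads[[paste0(name, ".conv1.W")]] <- cb$dW
  grads[[paste0(name, ".conv1.b")]] <- cb$db
  cb$dx
}

#' Forward pass of the network on one input block
#'
#' @param net A `dalunet` from [build_dalunet()].
#' @param block 4D array matching `cfg$input_shape`.
#' @param training Use batch statistics and record a tape for [backward()]
#'   (`TRUE`), or the frozen running statistics for deterministic inference
#'   (`FALSE`).
#' @return List: `final_prob` (3D array in `[0,1]` at input resolution),
#'   `ds_probs` (list of per-level probability maps, deepest first; empty
#'   when deep supervision is off), and when `training = TRUE` a `tape` for
#'   the backward pass plus updated `bn` running statistics.
#' @export
forward <- function(net, block, training = FALSE) {
  stopifnot(inherits(net, "dalunet"))
  cfg <- net$cfg
  if (!identical(as.integer(dim(block)), cfg$input_shape)) {
    abort(sprintf("block shape (%s) does not match configured input (%s).",
                  paste(dim(block), collapse = "x"),
                  paste(cfg$input_shape, collapse = "x")))
  }
  L <- cfg$levels
  p <- net$params
  tape <- new.env(parent = emptyenv())
  tape$bn <- net$bn
  tape$caches <- list()
  enc <- vector("list", L - 1L)
  cur <- block
  for (l in seq_len(L - 1L)) {
    enc[[l]] <- convblock_fwd(cur, paste0("enc", l), net, training, tape)
    pl <- maxpool_forward(enc[[l]])
    tape$caches[[paste0("pool", l)]] <- pl
    cur <- pl$y
  }
  bott <- convblock_fwd(cur, paste0("enc", L), net, training, tape)
  ds_probs <- list()
  if (cfg$use_deep_supervision) {
    h <- conv1x1_forward(bott, p[["ds.bott.W"]], p[["ds.bott.b"]])
    pr <- sigmoid(h$y)
    tape$caches[["ds.bott"]] <- list(h = h, prob = pr)
    ds_probs[["bott"]] <- array(pr, dim(pr)[1:3])
  }
  cur <- bott
  for (l in rev(seq_len(L - 1L))) {
    up <- upconv_forward(cur, p[[paste0("dec", l, ".up.W")]],
                         p[[paste0("dec", l, ".up.b")]])
    tape$caches[[paste0("dec", l, ".up")]] <- up
    skip <- enc[[l]]
    if (cfg$use_attention) {
      ag <- attention_forward(skip, up$y, list(
        Ws = p[[paste0("ag", l, ".Ws")]], Wg = p[[paste0("ag", l, ".Wg")]],
        b = p[[paste0("ag", l, ".b")]], psi_W = p[[paste0("ag", l, ".psi.W")]],
        psi_b = p[[paste0("ag", l, ".psi.b")]]))
      tape$caches[[paste0("ag", l)]] <- ag
      skip2 <- ag$y
    } else {
      skip2 <- skip
    }
    if (cfg$use_deep_supervision) {
      h <- conv1x1_forward(skip2, p[[paste0("ds", l, ".W")]],
                           p[[paste0("ds", l, ".b")]])
      pr <- sigmoid(h$y)
      tape$caches[[paste0("ds", l)]] <- list(h = h, prob = pr)
      ds_probs[[paste0("lvl", l)]] <- array(pr, dim(pr)[1:3])
    }
    if (cfg$use_clstm) {
      cl <- clstm_forward(skip2, list(
        Wx = p[[paste0("clstm", l, ".Wx")]], Wh = p[[paste0("clstm", l, ".Wh")]],
        b = p[[paste0("clstm", l, ".b")]]))
      tape$caches[[paste0("clstm", l)]] <- cl
      skip3 <- cl$y
    } else {
      skip3 <- skip2
    }
    dd <- dim(up$y)
    cat_ <- array(0, c(dd[1:3], 2L * dd[4]))
    cat_[, , , seq_len(dd[4])] <- up$y
    cat_[, , , dd[4] + seq_len(dd[4])] <- skip3
    cur <- convblock_fwd(cat_, paste0("dec", l), net, training, tape)
  }
  h <- conv1x1_forward(cur, p[["out.W"]], p[["out.b"]])
  prob <- sigmoid(h$y)
  tape$caches[["out"]] <- list(h = h, prob = prob)
  out <- list(final_prob = array(prob, dim(prob)[1:3]), ds_probs = ds_probs)
  if (training) {
    out$tape <- tape
    out$bn <- tape$bn
  }
  out
}

# Backward pass: head gradients (w.r.t. each head's probability map) to
# parameter gradients. `dfinal` matches final_prob; `dds` matches ds_probs.
backward <- function(net, fwd, dfinal, dds = list()) {
  cfg <- net$cfg
  L <- cfg$levels
  p <- net$params
  tape <- fwd$tape
  grads <- new.env(parent = emptyenv())
  oc <- tape$caches[["out"]]
  dpre <- array(dfinal, dim(oc$prob)) * oc$prob * (1 - oc$prob)
  ob <- conv1x1_backward(dpre, p[["out.W"]], oc$h)
  grads[["out.W"]] <- ob$dW; grads[["out.b"]] <- ob$db
  dcur <- ob$dx
  ds_head_grad <- function(name, key) {
    # gradient flowing into the head's input features
    if (!cfg$use_deep_supervision || is.null(dds[[key]])) return(NULL)
    hc <- tape$caches[[name]]
    dp <- array(dds[[key]], dim(hc$prob)) * hc$prob * (1 - hc$prob)
    hb <- conv1x1_backward(dp, p[[paste0(name, ".W")]], hc$h)
    grads[[paste0(name, ".W")]] <- hb$dW
    grads[[paste0(name, ".b")]] <- hb$db
    hb$dx
  }
  for (l in seq_len(L - 1L)) {
    dcat <- convblock_bwd(dcur, paste0("dec", l), net, tape, grads)
    dd <- dim(dcat)
    half <- dd[4] %/% 2L
    dup <- dcat[, , , seq_len(half), drop = FALSE]
    dskip3 <- dcat[, , , half + seq_len(half), drop = FALSE]
    if (cfg$use_clstm) {
      clp <- list(Wx = p[[paste0("clstm", l, ".Wx")]],
                  Wh = p[[paste0("clstm", l, ".Wh")]],
                  b = p[[paste0("clstm", l, ".b")]])
      cb <- clstm_backward(dskip3, clp, tape$caches[[paste0("clstm", l)]])
      grads[[paste0("clstm", l, ".Wx")]] <- cb$dWx
      grads[[paste0("clstm", l, ".Wh")]] <- cb$dWh
      grads[[paste0("clstm", l, ".b")]] <- cb$db
      dskip2 <- cb$dx
    } else {
      dskip2 <- dskip3
    }
    hg <- ds_head_grad(paste0("ds", l), paste0("lvl", l))
    if (!is.null(hg)) dskip2 <- dskip2 + hg
    if (cfg$use_attention) {
      agp <- list(Ws = p[[paste0("ag", l, ".Ws")]], Wg = p[[paste0("ag", l, ".Wg")]],
                  b = p[[paste0("ag", l, ".b")]], psi_W = p[[paste0("ag", l, ".psi.W")]],
                  psi_b = p[[paste0("ag", l, ".psi.b")]])
      ab <- attention_backward(dskip2, agp, tape$caches[[paste0("ag", l)]])
      grads[[paste0("ag", l, ".Ws")]] <- ab$dWs
      grads[[paste0("ag", l, ".Wg")]] <- ab$dWg
      grads[[paste0("ag", l, ".b")]] <- ab$db
      grads[[paste0("ag", l, ".psi.W")]] <- ab$dpsi_W
      grads[[paste0("ag", l, ".psi.b")]] <- ab$dpsi_b
      dskip <- ab$ds
      dup <- dup + ab$dg
    } else {
      dskip <- dskip2
    }
    ub <- upconv_backward(dup, p[[paste0("dec", l, ".up.W")]],
                          tape$caches[[paste0("dec", l, ".up")]])
    grads[[paste0("dec", l, ".up.W")]] <- ub$dW
    grads[[paste0("dec", l, ".up.b")]] <- ub$db
    dcur <- ub$dx
    # encoder skip gradient deferred to the encoder sweep
    tape$caches[[paste0("skipgrad", l)]] <- dskip
  }
  dbott <- dcur
  hg <- ds_head_grad("ds.bott", "bott")
  if (!is.null(hg)) dbott <- dbott + hg
  dcur <- convblock_bwd(dbott, paste0("enc", L), net, tape, grads)
  for (l in rev(seq_len(L - 1L))) {
    dpool <- maxpool_backward(dcur, tape$caches[[paste0("pool", l)]])
    denc <- dpool + tape$caches[[paste0("skipgrad", l)]]
    dcur <- convblock_bwd(denc, paste0("enc", l), net, tape, grads)
  }
  as.list(grads)
}

#' Standalone attention gate
#'
#' Gates skip-connection features by learned coefficients
#' `alpha = sigmoid(psi(relu(Ws s + Wg g + b)))` computed from 1x1x1
#' projections of the skip (`s`) and gating (`g`) features — a multiplicative
#' mask in `(0, 1)` that suppresses background regions of the skip path.
#' Exposed for inspection; inside the network the same computation runs on
#' each decoder level.
#'
#' @param skip,gating Feature arrays `(D, H, W, C)` with equal spatial dims.
#' @param par List `Ws` (Cs x Ci), `Wg` (Cg x Ci), `b` (Ci), `psi_W`
#'   (Ci x 1), `psi_b` (1).
#' @return List `gated` (same shape as `skip`) and `alpha` (3D coefficient
#'   map, strictly inside `(0, 1)`).
#' @export
attention_gate <- function(skip, gating, par) {
  if (!identical(dim(skip)[1:3], dim(gating)[1:3])) {
    abort("skip and gating features must share spatial dimensions.")
  }
  if (nrow(par$Ws) != dim(skip)[4] || nrow(par$Wg) != dim(gating)[4]) {
    abort("projection channel counts do not match the input features.")
  }
  f <- attention_forward(skip, gating, par)
  list(gated = f$y, alpha = f$alpha)
}

#' Standalone convolutional LSTM over a slice sequence
#'
#' Runs the standard ConvLSTM recurrence (3x3 convolutional input and
#' recurrent transforms; sigmoid input/forget/output gates, tanh candidate)
#' along the slice axis, ascending. The output at slice `k` depends only on
#' slices `<= k`.
#'
#' @param features Array `(D, H, W, C)`, slices first.
#' @param par List `Wx` (3 x 3 x C x 4C), `Wh` (3 x 3 x C x 4C), `b` (4C).
#' @return Array of the hidden-state sequence, same shape as `features`.
#' @export
clstm_block <- function(features, par) {
  if (length(dim(features)) != 4L || dim(features)[1] < 1L) {
    abort("`features` must be a non-empty (slices, H, W, C) array.")
  }
  clstm_forward(features, par)$y
}

#' Segment a preprocessed volume
#'
#' Blocks the volume to the configured depth, runs deterministic inference on
#' each block, un-pads and reassembles the probability map, and thresholds it
#' into a whole-structure mask. (Per-lobe models are trained separately, so a
#' single network predicts a single structure.)
#'
#' @param net A trained `dalunet`.
#' @param vol A windowed, resized [ct_volume()].
#' @param threshold Probability cut for the binary mask (default 0.5).
#' @return A [label_volume()] with structure `whole`.
#' @export
predict_mask <- function(net, vol, threshold = 0.5) {
  stopifnot(inherits(net, "dalunet"), inherits(vol, "ct_volume"))
  if (!vol$windowed) abort("volume must be windowed before prediction.")
  shp <- net$cfg$input_shape
  d <- dim(vol$voxels)
  if (d[2] != shp[2] || d[3] != shp[3]) {
    abort(sprintf("in-plane size %dx%d does not match the model's %dx%d.",
                  d[2], d[3], shp[2], shp[3]))
  }
  blocked <- to_model_blocks(vol, depth = shp[1])
  preds <- lapply(blocked$blocks, function(b) {
    pr <- forward(net, b, training = FALSE)$final_prob
    array(pr, c(dim(pr), 1L))
  })
  blocked$blocks <- preds
  prob <- blocks_to_volume(blocked)
  if (!identical(dim(prob), d)) abort("internal error: un-padding bookkeeping mismatch.")
  label_volume(list(whole = (prob >= threshold) * 1), vol$spacing)
}

#' Save / load a self-describing checkpoint
#'
#' The configuration travels with the weights, so a checkpoint can be
#' restored without external metadata.
#'
#' @param net A `dalunet`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the restored `dalunet` (load).
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "dalunet"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "dalunet")) abort("not a dalunet checkpoint.")
  net
}
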