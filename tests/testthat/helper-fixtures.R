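# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use plain loops so they share no code path with the implementation.

tiny_phantom_spec <- function(seed = 11, shape = c(16L, 64L, 64L),
                              spacing = c(5, 2.8, 2.8)) {
  phantom_spec(
    shape = shape, spacing = spacing,
    liver_semi_axes = c(30, 50, 60),
    lobe_plane = list(normal = c(0, 0, 1), offset_mm = 19),
    caudate_semi_axes = c(8, 10, 12),
    seed = seed
  )
}

iso_phantom_spec <- function(seed = 5) {
  # 1 mm isotropic grid for analytic-volume checks
  phantom_spec(
    shape = c(32L, 40L, 44L), spacing = c(1, 1, 1),
    liver_semi_axes = c(10, 13, 15),
    lobe_plane = list(normal = c(0, 0, 1), offset_mm = 5),
    caudate_semi_axes = c(4, 4, 5),
    caudate_center = c(16.5, 36, 16),
    seed = seed
  )
}

rand_mask <- function(dims, p = 0.3) array(rbinom(prod(dims), 1, p), dims)

# exhaustive voxel-loop confusion counts
bf_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1) fp <- fp + 1
    else if (truth[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# loop-based 6-connectivity boundary extraction
bf_boundary <- function(mask) {
  d <- dim(mask)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else 0, if (i < d[1]) mask[i + 1, j, k] else 0,
      if (j > 1) mask[i, j - 1, k] else 0, if (j < d[2]) mask[i, j + 1, k] else 0,
      if (k > 1) mask[i, j, k - 1] else 0, if (k < d[3]) mask[i, j, k + 1] else 0
    )
    if (length(nb) < 6 || any(nb == 0)) pts <- rbind(pts, c(i, j, k))
  }
  pts
}

# O(n^2) all-pairs symmetric Hausdorff on boundary voxel centres
bf_hausdorff <- function(a, b, spacing) {
  pa <- bf_boundary(a); pb <- bf_boundary(b)
  h_dir <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        dv <- (p[i, ] - q[j, ]) * spacing
        best <- min(best, sum(dv^2))
      }
      worst <- max(worst, best)
    }
    sqrt(worst)
  }
  max(h_dir(pa, pb), h_dir(pb, pa))
}

# loop-based same-padding 3x3 2D convolution (oracle for the ConvLSTM step)
bf_conv2d <- function(x, W) {
  # x: (H, W, Cin), W: (3, 3, Cin, Cout)
  d <- dim(x); co <- dim(W)[4]
  y <- array(0, c(d[1], d[2], co))
  for (oc in seq_len(co)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    acc <- 0
    for (ci in seq_len(dim(W)[3])) for (a in 1:3) for (b in 1:3) {
      ii <- i + a - 2; jj <- j + b - 2
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
        acc <- acc + x[ii, jj, ci] * W[a, b, ci, oc]
      }
    }
    y[i, j, oc] <- acc
  }
  y
}

expect_binary <- function(x) expect_true(all(x %in% c(0, 1)))
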