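test_that("dice loss limits and hand value", {
  m <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  expect_lt(dice_loss(m, m), 1e-5)                      # perfect overlap
  disjoint_pred <- array(0, c(4, 4, 4)); disjoint_pred[1, 1, 1] <- 1
  disjoint_truth <- array(0, c(4, 4, 4)); disjoint_truth[4, 4, 4] <- 1
  expect_gt(dice_loss(disjoint_pred, disjoint_truth), 1 - 1e-5)
  pred <- array(0, c(2, 2, 2)) + 1                      # 8 predicted voxels
  truth <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)) # 4 true, all covered
  expect_equal(dice_loss(pred, truth), 1 / 3, tolerance = 1e-6)  # 1 - 8/12
  expect_error(dice_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))), "shape")
  expect_error(dice_loss(array(2, c(2, 2, 2)), array(1, c(2, 2, 2))), "\\[0, 1\\]")
})

test_that("dice loss is continuous in the prediction", {
  set.seed(1)
  pred <- array(runif(4^3), c(4, 4, 4))
  truth <- rand_mask(c(4, 4, 4))
  bumped <- pmin(pred + 1e-6, 1)
  expect_lt(abs(dice_loss(bumped, truth) - dice_loss(pred, truth)), 1e-4)
})

test_that("deep-supervision total is the plain sum", {
  expect_equal(ds_total_loss(c(0.2, 0.3, 0.1)), 0.6)
  expect_equal(ds_total_loss(list(0.42)), 0.42)
  set.seed(2)
  xs <- runif(5)
  expect_equal(ds_total_loss(xs), ds_total_loss(sample(xs)))
  expect_error(ds_total_loss(numeric(0)), "non-empty")
})

test_that("confusion counts equal an exhaustive voxel loop", {
  set.seed(3)
  for (rep in 1:5) {
    p <- rand_mask(c(8, 8, 8)); t <- rand_mask(c(8, 8, 8))
    cc <- confusion_counts(p, t)
    expect_identical(cc, bf_confusion(p, t))
    expect_equal(sum(cc), 512)
  }
  expect_error(confusion_counts(array(0.5, c(2, 2, 2)), rand_mask(c(2, 2, 2))),
               "binary")
})

test_that("segmentation metrics: identity, hand case and the DSC-IoU identity", {
  sp <- c(5, 0.7, 0.7)
  m <- rand_mask(c(6, 6, 6))
  lv <- function(x) label_volume(list(whole = x), sp)
  same <- seg_metrics(lv(m), lv(m))
  expect_equal(same$recall, 1); expect_equal(same$precision, 1)
  expect_equal(same$dsc, 1); expect_equal(same$iou, 1)
  expect_equal(same$hd_mm, 0)

  # |pred| = |truth| = 4, overlap 2
  p <- array(0, c(2, 2, 2)); p[c(1, 2, 3, 4)] <- 1
  t <- array(0, c(2, 2, 2)); t[c(3, 4, 5, 6)] <- 1
  hand <- seg_metrics(lv(p), lv(t))
  expect_equal(hand$dsc, 0.5)
  expect_equal(hand$iou, 1 / 3)
  expect_equal(hand$recall, 0.5)
  expect_equal(hand$precision, 0.5)

  set.seed(4)
  for (rep in 1:100) {
    a <- rand_mask(c(5, 5, 5)); b <- rand_mask(c(5, 5, 5))
    sm <- seg_metrics(lv(a), lv(b))
    expect_equal(sm$dsc, 2 * sm$iou / (1 + sm$iou), tolerance = 1e-9)
    expect_gte(sm$dsc, sm$iou)
    expect_true(all(unlist(sm[, c("recall", "precision", "dsc", "iou")]) >= 0))
    expect_true(all(unlist(sm[, c("recall", "precision", "dsc", "iou")]) <= 1))
  }
  expect_error(seg_metrics(lv(p), label_volume(list(left_lobe = t), sp), "left_lobe"),
               "absent")
})

test_that("empty-mask conventions are explicit", {
  sp <- c(5, 1, 1)
  e <- array(0, c(3, 3, 3))
  m <- e; m[2, 2, 2] <- 1
  lv <- function(x) label_volume(list(whole = x), sp)
  both <- seg_metrics(lv(e), lv(e))
  expect_equal(unlist(both[, c("recall", "precision", "dsc", "iou")]),
               c(recall = 1, precision = 1, dsc = 1, iou = 1))
  expect_equal(both$hd_mm, 0)
  one <- seg_metrics(lv(e), lv(m))
  expect_equal(one$dsc, 0); expect_equal(one$iou, 0)
  expect_equal(one$precision, 0)  # empty prediction: vacuous precision is 0
  expect_true(is.na(one$hd_mm))   # undefined distance surfaced, not defaulted
})

test_that("Hausdorff distance: hand case, symmetry, zero on identity", {
  d <- c(8, 4, 4)
  a <- array(0, d); a[2, 2, 2] <- 1
  b <- array(0, d); b[5, 2, 2] <- 1      # 3 slices apart
  expect_equal(hausdorff_mm(a, b, c(5, 0.7, 0.7)), 15)   # 3 x 5 mm
  expect_equal(hausdorff_mm(a, a, c(5, 0.7, 0.7)), 0)
  set.seed(5)
  for (rep in 1:5) {
    x <- rand_mask(c(5, 5, 5), 0.2); y <- rand_mask(c(5, 5, 5), 0.2)
    if (sum(x) == 0 || sum(y) == 0) next
    sp <- c(5, 0.7, 0.7)
    expect_equal(hausdorff_mm(x, y, sp), hausdorff_mm(y, x, sp))
    expect_equal(hausdorff_mm(x, y, sp), bf_hausdorff(x, y, sp), tolerance = 1e-12)
  }
  expect_error(hausdorff_mm(array(0, d), b, c(5, 1, 1)), "empty")
})

test_that("metric tables aggregate to mean and SD per group", {
  tbl <- tibble::tibble(
    model = rep(c("a", "b"), each = 3),
    structure = "whole",
    dsc = c(0.8, 0.9, 1.0, 0.5, 0.6, 0.7)
  )
  agg <- summarise_metrics(tbl)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$dsc_mean, c(0.9, 0.6))
  expect_equal(agg$dsc_sd, c(0.1, 0.1), tolerance = 1e-12)
})
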