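test_that("rotated IoU: identity, disjoint, and the offset-square case", {
  b <- oriented_box(3, 4, 2, 5, 37)
  expect_equal(rotated_iou(b, b), 1)
  expect_equal(rotated_iou(b, oriented_box(100, 100, 2, 5, 80)), 0)
  expect_equal(rotated_iou(oriented_box(0, 0, 1, 1, 0),
                           oriented_box(0.5, 0, 1, 1, 0)), 1 / 3,
               tolerance = 1e-12)
  # symmetry
  a <- oriented_box(1, 1, 3, 2, 20)
  expect_equal(rotated_iou(a, b), rotated_iou(b, a), tolerance = 1e-12)
})

test_that("rotated IoU agrees with the polygon oracle and the AABB closed form", {
  set.seed(41)
  for (i in 1:200) {
    a <- rand_obb(4); b <- rand_obb(4)
    expect_equal(rotated_iou(a, b), rotated_iou_oracle(a, b), tolerance = 1e-9)
  }
  for (i in 1:50) {
    # h > w keeps theta = 0 under the canonical box representation, so the
    # stored w/h are the x/y extents the closed form expects
    a <- oriented_box(runif(1, -3, 3), runif(1, -3, 3), runif(1, 1, 2), runif(1, 2.5, 4), 0)
    b <- oriented_box(runif(1, -3, 3), runif(1, -3, 3), runif(1, 1, 2), runif(1, 2.5, 4), 0)
    expect_equal(rotated_iou(a, b), aabb_iou(a, b), tolerance = 1e-9)
  }
})

test_that("greedy one-to-one matching yields the documented confusion counts", {
  gt <- oriented_box(0, 0, 4, 6, 15)
  m1 <- match_detections(list(detection(gt, 0, 0.9)), list(gt), 0.5)
  expect_equal(unclass(m1$counts)[c("tp", "fp", "fn")], list(tp = 1, fp = 0, fn = 0))

  m2 <- match_detections(list(), list(gt, oriented_box(10, 10, 4, 6, 0)), 0.5)
  expect_equal(m2$counts$fn, 2)

  near <- oriented_box(0.2, 0, 4, 6, 15)   # IoU < 1 but > 0.5
  m3 <- match_detections(list(detection(gt, 0, 0.9), detection(near, 0, 0.8)),
                         list(gt), 0.5)
  expect_equal(unclass(m3$counts)[c("tp", "fp", "fn")], list(tp = 1, fp = 1, fn = 0))
  expect_equal(m3$matches$det, 1)          # higher confidence claims the gt
})

test_that("precision/recall/accuracy are exact fractions with NA sentinels", {
  m <- precision_recall_accuracy(confusion_counts(tp = 9, tn = 0, fp = 1, fn = 2))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11)
  expect_equal(m$accuracy, 9 / 12)

  expect_true(is.na(precision_recall_accuracy(confusion_counts(fn = 3))$precision))
  m2 <- precision_recall_accuracy(confusion_counts(tp = 5, tn = 5))
  expect_equal(unlist(m2), c(precision = 1, recall = 1, accuracy = 1))

  # scale-free in the counts
  m3 <- precision_recall_accuracy(confusion_counts(tp = 27, tn = 0, fp = 3, fn = 6))
  expect_equal(unlist(m3), unlist(m))
})

test_that("average precision covers the sanity and staircase cases", {
  g1 <- oriented_box(0, 0, 2, 3, 0); g2 <- oriented_box(10, 0, 2, 3, 40)
  perfect <- list(detection(g1, 0, 0.9), detection(g2, 0, 0.8))
  expect_equal(average_precision(perfect, list(g1, g2)), 1)
  expect_equal(average_precision(list(), list(g1, g2)), 0)
  expect_true(is.na(average_precision(perfect, list())))

  # conf 0.9 TP, 0.8 FP, 0.7 TP over 2 gts: all-points 5/6, 11-point 28/33
  dets <- list(detection(g1, 0, 0.9),
               detection(oriented_box(50, 50, 2, 3, 0), 0, 0.8),
               detection(g2, 0, 0.7))
  expect_equal(average_precision(dets, list(g1, g2)), 5 / 6, tolerance = 1e-12)
  expect_equal(average_precision(dets, list(g1, g2), interpolation = "elevenpoint"),
               28 / 33, tolerance = 1e-12)

  # invariant to monotone confidence rescaling
  dets2 <- lapply(dets, function(d) detection(d$box, d$class_id, d$confidence^3))
  expect_equal(average_precision(dets2, list(g1, g2)),
               average_precision(dets, list(g1, g2)))

  # mAP averages per-class APs
  gts <- list(list(box = g1, class_id = 0L), list(box = g2, class_id = 1L))
  dets3 <- list(detection(g1, 0, 0.9),
                detection(oriented_box(50, 50, 2, 3, 0), 1, 0.8))
  expect_equal(map50(dets3, gts), mean(c(1, 0)))
})

test_that("angular deviation reports average unsigned line angles", {
  lines <- lapply(c(10, 40, 90), function(d) line_from_point_direction(c(0, 0), d))
  r0 <- angular_deviation_report(lines, lines)
  expect_equal(r0$per_image_deviation_deg, c(0, 0, 0))
  expect_equal(r0$mean_deviation_deg, 0)

  rot <- lapply(c(10, 40, 90), function(d) line_from_point_direction(c(3, 1), d + 2))
  r2 <- angular_deviation_report(rot, lines)
  expect_equal(r2$mean_deviation_deg, 2, tolerance = 1e-9)

  devs <- c(3.59, 1.29, 1.01, 0.41, 0.80, 2.12)
  r <- angular_deviation_report(deviations = devs)
  expect_equal(r$mean_deviation_deg, mean(devs))
  expect_equal(angular_deviation_report(deviations = sample(devs))$mean_deviation_deg,
               r$mean_deviation_deg)                 # permutation invariance
  expect_true(all(r$per_image_deviation_deg >= 0 & r$per_image_deviation_deg <= 90))

  expect_error(angular_deviation_report(lines, lines[1:2]), "pairing")
})
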