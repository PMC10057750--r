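disc_image <- function(nr, nc, specs) {
  # specs: list of c(cx, cy, r, value)
  img <- matrix(0L, nr, nc)
  for (s in specs) {
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    img[(rows - s[1])^2 + (cols - s[2])^2 <= s[3]^2] <- as.integer(s[4])
  }
  img
}

test_that("intensity classes are discovered as the sorted distinct non-zero values", {
  img <- matrix(c(0L, 100L, 200L, 100L), 2, 2)
  cl <- intensity_classes(img)
  expect_identical(as.integer(cl), c(100L, 200L))
  expect_identical(attr(cl, "n_pixels"), c(2L, 1L))

  expect_identical(as.integer(intensity_classes(matrix(255L, 3, 3))), 255L)

  # hand-segmentation values need no particular magnitudes
  img4 <- matrix(sample(c(13L, 77L, 145L, 9000L), 100, replace = TRUE), 10, 10)
  expect_identical(as.integer(intensity_classes(img4)), sort(unique(as.integer(img4))))

  expect_error(intensity_classes(matrix(0L, 4, 4)), "no ground-truth objects")
  expect_warning(intensity_classes(img, min_pixels = 2), "fewer than 2 pixels")
})

test_that("objects are the per-class connected components, ids in class-then-scan order", {
  # two disjoint discs of one intensity: 2 objects
  two <- disc_image(30, 30, list(c(8, 8, 4, 100), c(22, 22, 4, 100)))
  expect_equal(label_objects(two)$n, 2L)

  # touching discs of different intensities stay separate despite adjacency
  touch <- disc_image(30, 40, list(c(15, 12, 5, 100), c(15, 23, 5, 200)))
  expect_true(any(adjacent_labels(touch)))  # sanity: they do touch
  map <- label_objects(touch)
  expect_equal(map$n, 2L)
  expect_identical(map$source_class, c(100L, 200L))

  # checkerboard: 4-connectivity isolates every cell, 8-connectivity joins all
  ck <- matrix(0L, 6, 6)
  ck[(row(ck) + col(ck)) %% 2 == 0] <- 100L
  expect_equal(label_objects(ck, connectivity = 4)$n, sum(ck > 0))
  expect_equal(label_objects(ck, connectivity = 8)$n, 1L)

  # canonical id order: ascending class first, then column-major scan order
  img <- matrix(0L, 6, 6)
  img[5:6, 1:2] <- 200L   # earliest in scan order but higher class
  img[1:2, 3:4] <- 100L
  img[5:6, 5:6] <- 100L
  map2 <- label_objects(img)
  expect_identical(map2$source_class, c(100L, 100L, 200L))
  expect_equal(map2$labels[1, 3], 1L)  # first 100-class component by scan order
  expect_equal(map2$labels[5, 5], 2L)
  expect_equal(map2$labels[5, 1], 3L)
  expect_equal(sum(map2$sizes), sum(img > 0))
})

test_that("component labeling agrees with flood fill and with EBImage at 4-connectivity", {
  set.seed(99)
  for (rep in 1:20) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    mask <- matrix(rbinom(nr * nc, 1, 0.45), nr, nc) > 0
    for (conn in c(4, 8)) {
      got <- segmetrics:::connected_components(mask, as.integer(conn))
      ref <- oracle_flood_fill(mask, conn)
      expect_identical(unname(got[seq_along(ref)]), as.integer(ref))
    }
    # EBImage's bwlabel is 4-connected: same partition up to relabeling
    eb <- EBImage::bwlabel(mask * 1)
    got4 <- segmetrics:::connected_components(mask, 4L)
    expect_equal(max(got4), max(eb))
    fg <- which(mask)
    expect_true(all(tapply(eb[fg], got4[fg], function(v) length(unique(v))) == 1))
  }
})

test_that("modal overlap matching picks the dominant test object deterministically", {
  test <- matrix(0L, 10, 10)
  test[2:9, 2:4] <- 1L
  test[2:9, 5:7] <- 2L
  test[2:9, 9] <- 3L

  inside <- matrix(0L, 10, 10); inside[3:5, 9] <- 1L
  expect_equal(match_object(inside, test), 3L)

  # 30 px on label 1 vs 20 px on label 2
  straddle <- matrix(0L, 10, 10)
  straddle[1:10, 2:4] <- 1L; straddle[1:10, 5:6] <- 1L
  expect_equal(sum(test[straddle == 1] == 1), 24)
  expect_equal(sum(test[straddle == 1] == 2), 16)
  expect_equal(match_object(straddle, test), 1L)

  # exact tie resolves to the smallest label
  tie <- matrix(0L, 10, 10); tie[2:9, 4:5] <- 1L  # 8 px on each of labels 1, 2
  expect_equal(sum(test[tie == 1] == 1), sum(test[tie == 1] == 2))
  expect_equal(match_object(tie, test), 1L)

  over_bg <- matrix(0L, 10, 10); over_bg[1, 1] <- 1L
  expect_true(is.na(match_object(over_bg, test)))

  expect_error(match_object(matrix(0L, 10, 10), test), "empty")
})

test_that("per-object counts follow the size-minus-TP bookkeeping", {
  gt <- matrix(0L, 10, 10)
  gt[1:5, 1:10] <- 100L                      # one 50-px object
  test_same <- matrix(0L, 10, 10); test_same[1:5, 1:10] <- 1L
  gt_map <- label_objects(gt)
  tm <- segmetrics:::canonicalize_labels(test_same)
  cnt <- per_object_counts(gt_map, 1L, match_object(binarize(gt), tm), tm)
  expect_equal(unclass(cnt)[1:3], list(tp = 50, fp = 0, fn = 0))

  # matched test object of 70 px containing all 50 gt px
  test_big <- matrix(0L, 10, 10); test_big[1:7, 1:10] <- 1L
  tm2 <- segmetrics:::canonicalize_labels(test_big)
  cnt2 <- per_object_counts(gt_map, 1L, 1L, tm2)
  expect_equal(unclass(cnt2)[1:3], list(tp = 50, fp = 20, fn = 0))

  # unmatched object keeps all pixels as FN
  cnt3 <- per_object_counts(gt_map, 1L, NA_integer_, tm2)
  expect_equal(unclass(cnt3)[1:3], list(tp = 0, fp = 0, fn = 50))

  expect_error(per_object_counts(gt_map, 5L, 1L, tm2), "out of range")
})

test_that("image-level aggregation charges unmatched test pixels once", {
  # 10x10 all-foreground, gt split at column 5, test split at column 7
  pr <- make_adjacent_pair(10, 10, shape_rect(1, 10, 1, 10),
                           split_vertical(5), split_vertical(7))
  ev <- evaluate_segmentation(pr$a, pr$b)
  expect_equal(unclass(ev$object$counts)[1:3], list(tp = 80, fp = 20, fn = 20))
  expect_equal(ev$object$metrics$precision, 0.8)
  expect_equal(ev$object$metrics$recall, 0.8)
  expect_equal(ev$object$metrics$f_measure, 0.8)
  expect_equal(ev$pixel$metrics$precision, 1)

  # spurious 25-px test object enters image-level FP
  gt <- matrix(0L, 12, 12); gt[2:6, 2:6] <- 100L
  test <- matrix(0L, 12, 12); test[2:6, 2:6] <- 1L; test[8:12, 8:12] <- 2L
  ev2 <- evaluate_segmentation(gt, test)
  expect_equal(ev2$object$counts$fp, 25)
  expect_equal(ev2$n_unmatched_test, 1L)
})

test_that("full evaluation handles self-comparison, shared footprints and empty tests", {
  touch <- disc_image(40, 60, list(c(20, 20, 8, 100), c(20, 37, 8, 200)))
  ev <- evaluate_segmentation(touch, touch)
  expect_equal(ev$n_gt_objects, 2L)
  po <- tidy(ev)
  expect_true(all(po$precision == 1, po$recall == 1, po$f_measure == 1))

  pr <- make_adjacent_pair()
  ev2 <- evaluate_segmentation(pr$a, pr$b)
  expect_equal(ev2$pixel$metrics$precision, 1)
  expect_lt(ev2$object$metrics$precision, 1)

  empty <- matrix(0L, 40, 60)
  ev3 <- evaluate_segmentation(touch, empty)
  expect_equal(ev3$pixel$metrics$precision, 0)
  expect_equal(ev3$object$metrics$f_measure, 0)
  expect_true(all(is.na(tidy(ev3)$matched_test_id)))

  expect_error(evaluate_segmentation(touch, matrix(0L, 10, 10)), "dimensions differ")
  expect_error(evaluate_segmentation(empty, empty), "no ground-truth objects")
})

test_that("per-object counts equal brute-force enumeration on random scenes", {
  set.seed(11)
  for (rep in 1:30) {
    sc <- random_scene()
    ev <- evaluate_segmentation(sc$gt, sc$test)
    ref <- oracle_evaluate(sc$gt, sc$test)
    po <- tidy(ev)
    expect_equal(po$tp, ref$per_object$tp)
    expect_equal(po$fp, ref$per_object$fp)
    expect_equal(po$fn, ref$per_object$fn)
    expect_equal(po$matched_test_id, ref$per_object$matched,
                 ignore_attr = TRUE)
    # sum of per-object TP is the image-level object TP, itself <= pixel TP
    expect_equal(sum(po$tp), ev$object$counts$tp)
    expect_equal(ev$object$counts$fp, ref$totals$fp)
    expect_lte(ev$object$counts$tp, ev$pixel$counts$tp)
  }
})

test_that("metrics are invariant to relabeling, translation and scene duplication", {
  set.seed(23)
  base_gt <- disc_image(30, 30, list(c(9, 9, 5, 100), c(22, 20, 5, 200)))
  base_test <- disc_image(30, 30, list(c(9, 10, 5, 1), c(22, 19, 5, 2)))
  ref <- glance(evaluate_segmentation(base_gt, base_test))[, -1]

  # permute test labels, remap gt classes to arbitrary distinct values
  perm_test <- matrix(c(0L, 9L, 4L)[base_test + 1L], 30, 30)
  remap_gt <- base_gt
  remap_gt[base_gt == 100L] <- 7131L
  remap_gt[base_gt == 200L] <- 12L
  expect_equal(glance(evaluate_segmentation(remap_gt, perm_test))[, -1], ref)

  # translate the whole scene
  pad <- function(img) {
    out <- matrix(0L, 40, 40); out[9:38, 6:35] <- img; out
  }
  expect_equal(glance(evaluate_segmentation(pad(base_gt), pad(base_test)))[, -1],
               ref)

  # duplicate the scene disjointly: metrics unchanged, counts doubled
  dup <- function(img) rbind(img, matrix(0L, 3, 30), img)
  ev_dup <- evaluate_segmentation(dup(base_gt), dup(base_test))
  g <- glance(ev_dup)
  expect_equal(g[, 2:7], ref[, 1:6])
  expect_equal(g$n_gt_objects, 2L * ref$n_gt_objects)
})

test_that("bijective matching transposes per-object precision and recall", {
  pr <- make_adjacent_pair(10, 10, shape_rect(1, 10, 1, 10),
                           split_vertical(5), split_vertical(7))
  fwd <- tidy(evaluate_segmentation(pr$a, pr$b))
  rev <- tidy(evaluate_segmentation(pr$b, pr$a))
  expect_equal(fwd$precision, rev$recall)
  expect_equal(fwd$recall, rev$precision)
  expect_equal(fwd$f_measure, rev$f_measure)
})
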