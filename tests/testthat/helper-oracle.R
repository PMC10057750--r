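# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals: explicit per-pixel loops and
# stack-based flood fill.

oracle_pixel_counts <- function(gt_mask, test_mask) {
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(gt_mask))) {
    for (j in seq_len(ncol(gt_mask))) {
      g <- gt_mask[i, j]; t <- test_mask[i, j]
      if (g == 1 && t == 1) tp <- tp + 1
      if (g == 0 && t == 1) fp <- fp + 1
      if (g == 1 && t == 0) fn <- fn + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) {          # column-major scan order
    for (i in seq_len(nr)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        stack <- list(c(i, j))
        lab[i, j] <- nxt
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (o in offs) {
            r <- p[1] + o[1]; c <- p[2] + o[2]
            if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
                mask[r, c] && lab[r, c] == 0L) {
              lab[r, c] <- nxt
              stack[[length(stack) + 1]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  lab
}

# Enumerate ground-truth objects (per intensity class, flood fill) and score
# each against every test label by direct pixel-overlap counting.
oracle_evaluate <- function(gt, test, connectivity = 8) {
  classes <- sort(unique(gt[gt > 0]))
  gt_lab <- matrix(0L, nrow(gt), ncol(gt))
  gt_class <- integer(0)
  k <- 0L
  for (v in classes) {
    comp <- oracle_flood_fill(gt == v, connectivity)
    m <- max(comp)
    gt_lab[comp > 0] <- comp[comp > 0] + k
    gt_class <- c(gt_class, rep(v, m))
    k <- k + m
  }
  test_vals <- sort(unique(test[test > 0]))
  test_lab <- matrix(0L, nrow(test), ncol(test))
  for (t in seq_along(test_vals)) test_lab[test == test_vals[t]] <- t
  n_test <- length(test_vals)
  test_sizes <- vapply(seq_len(n_test), function(t) sum(test_lab == t), numeric(1))

  rows <- data.frame(gt_id = integer(0), matched = integer(0),
                     tp = numeric(0), fp = numeric(0), fn = numeric(0))
  for (id in seq_len(k)) {
    overlap <- rep(0, n_test)
    for (i in seq_len(nrow(gt))) {
      for (j in seq_len(ncol(gt))) {
        if (gt_lab[i, j] == id && test_lab[i, j] > 0) {
          overlap[test_lab[i, j]] <- overlap[test_lab[i, j]] + 1
        }
      }
    }
    gt_size <- sum(gt_lab == id)
    if (n_test == 0 || all(overlap == 0)) {
      rows[id, ] <- list(id, NA_integer_, 0, 0, gt_size)
    } else {
      best <- which(overlap == max(overlap))[1]   # smallest label on ties
      tp <- overlap[best]
      rows[id, ] <- list(id, best, tp, test_sizes[best] - tp, gt_size - tp)
    }
  }
  tp_total <- sum(rows$tp)
  list(per_object = rows,
       totals = list(tp = tp_total,
                     fp = sum(test_sizes) - tp_total,
                     fn = sum(gt_lab > 0) - tp_total))
}

# Small random scene: up to `max_objects` rectangles per image, ground truth
# using few intensity classes, test using arbitrary labels.
random_scene <- function(max_dim = 20, max_objects = 5) {
  nr <- sample(6:max_dim, 1); nc <- sample(6:max_dim, 1)
  draw_rects <- function(values) {
    img <- matrix(0L, nr, nc)
    for (v in values) {
      r0 <- sample(1:(nr - 1), 1); r1 <- sample(r0:min(nr, r0 + 6), 1)
      c0 <- sample(1:(nc - 1), 1); c1 <- sample(c0:min(nc, c0 + 6), 1)
      img[r0:r1, c0:c1] <- v
    }
    img
  }
  n_gt <- sample(1:max_objects, 1)
  n_test <- sample(0:max_objects, 1)
  gt <- draw_rects(sample(c(50L, 100L, 150L, 200L), n_gt, replace = TRUE))
  if (all(gt == 0L)) gt[sample(nr, 1), sample(nc, 1)] <- 100L
  test <- if (n_test == 0) matrix(0L, nr, nc) else
    draw_rects(sample(1:40, n_test))
  list(gt = gt, test = test)
}

adjacent_labels <- function(img) {
  # TRUE when two distinct positive values touch under 8-connectivity
  nr <- nrow(img); nc <- ncol(img)
  hits <- logical(0)
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    rs <- max(1, 1 - o[1]):min(nr, nr - o[1])
    cs <- max(1, 1 - o[2]):min(nc, nc - o[2])
    a <- img[rs, cs]; b <- img[rs + o[1], cs + o[2]]
    hits <- c(hits, any(a > 0 & b > 0 & a != b))
  }
  hits
}

new_map_from_labels <- function(labels) {
  sizes <- tabulate(labels[labels > 0L], max(labels))
  segmetrics:::new_object_map(labels, sizes, rep(NA_integer_, max(labels)), 8L)
}
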