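#' Constant validation image
#'
#' All-foreground or all-background fields used to pin down the output range
#' of the evaluation (all-ones vs all-ones scores Precision 1; all-zeros vs
#' all-zeros scores 0 under the 0/0 convention).
#'
#' @param height,width Positive dimensions in pixels.
#' @param value 0 or 1.
#' @return An integer matrix.
#' @export
make_constant <- function(height = 256, width = 256, value = 1) {
  stopifnot(height >= 1, width >= 1, value %in% c(0, 1))
  matrix(as.integer(value), height, width)
}

#' Half-white/half-black validation image
#'
#' One rectangular half of the image is foreground (1), the other background
#' (0). The four (orientation, side) combinations pair into horizontal
#' complements and vertical complements; any two orthogonal halves share
#' exactly one quadrant, so their Precision is 0.5.
#'
#' @param height,width Dimensions; the split dimension must be even.
#' @param orientation `"horizontal"` (split into top/bottom halves) or
#'   `"vertical"` (left/right).
#' @param white_side `"first"` (top or left half is white) or `"second"`.
#' @return An integer 0/1 matrix with exactly `height * width / 2` ones.
#' @export
make_half <- function(height = 256, width = 256,
                      orientation = c("horizontal", "vertical"),
                      white_side = c("first", "second")) {
  orientation <- match.arg(orientation)
  white_side <- match.arg(white_side)
  split_dim <- if (orientation == "horizontal") height else width
  if (split_dim %% 2L != 0L) {
    stop(sprintf("cannot split %s dimension %d into equal halves", orientation, split_dim),
         call. = FALSE)
  }
  img <- matrix(0L, height, width)
  if (orientation == "horizontal") {
    rows <- if (white_side == "first") 1:(height / 2) else (height / 2 + 1):height
    img[rows, ] <- 1L
  } else {
    cols <- if (white_side == "first") 1:(width / 2) else (width / 2 + 1):width
    img[, cols] <- 1L
  }
  img
}

#' Shape and split descriptors for synthetic scenes
#'
#' `shape_disc()` and `shape_rect()` describe footprints; `split_vertical()`
#' and `split_horizontal()` describe where the internal boundary between two
#' adjacent objects lies (part 1 is the side at or before `at`).
#'
#' @param cx,cy Disc center (row, column), possibly fractional.
#' @param r Disc radius in pixels.
#' @return A descriptor list consumed by [make_adjacent_pair()].
#' @export
shape_disc <- function(cx, cy, r) {
  list(type = "disc", cx = cx, cy = cy, r = r)
}

#' @rdname shape_disc
#' @param row0,row1,col0,col1 Inclusive rectangle bounds.
#' @export
shape_rect <- function(row0, row1, col0, col1) {
  list(type = "rect", row0 = row0, row1 = row1, col0 = col0, col1 = col1)
}

#' @rdname shape_disc
#' @param at Last column (for vertical splits) or row (horizontal) of part 1.
#' @export
split_vertical <- function(at) list(type = "vertical", at = at)

#' @rdname shape_disc
#' @export
split_horizontal <- function(at) list(type = "horizontal", at = at)

rasterize_shape <- function(shape, height, width) {
  if (is.matrix(shape)) return(shape > 0)
  switch(shape$type,
    disc = {
      rows <- matrix(seq_len(height), height, width)
      cols <- matrix(seq_len(width), height, width, byrow = TRUE)
      (rows - shape$cx)^2 + (cols - shape$cy)^2 <= shape$r^2
    },
    rect = {
      m <- matrix(FALSE, height, width)
      m[shape$row0:shape$row1, shape$col0:shape$col1] <- TRUE
      m
    },
    stop("unknown shape type", call. = FALSE))
}

split_predicate <- function(split, height, width) {
  if (is.function(split)) {
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    return(matrix(mapply(split, rows, cols), height, width))
  }
  switch(split$type,
    vertical = matrix(seq_len(width) <= split$at, height, width, byrow = TRUE),
    horizontal = matrix(seq_len(height) <= split$at, height, width),
    stop("unknown split type", call. = FALSE))
}

#' Adjacent-object image pair with a shared footprint
#'
#' Generates two grayscale images whose two adjacent objects cover the same
#' overall foreground footprint but are divided by differently placed
#' internal boundaries — the configuration where pixel-level evaluation
#' scores a perfect 1 while the per-object evaluation exposes the
#' misassigned pixels. In each image, part 1 takes `intensities[1]` and part
#' 2 `intensities[2]`.
#'
#' @param height,width Image dimensions.
#' @param footprint A shape descriptor ([shape_disc()], [shape_rect()]) or a
#'   logical/0-1 matrix.
#' @param split_a,split_b Split descriptors ([split_vertical()],
#'   [split_horizontal()]) or predicates `function(row, col)` returning
#'   `TRUE` for part 1. Each must divide the footprint into exactly two
#'   non-empty connected parts.
#' @param intensities Two distinct positive intensities (default 100 and
#'   200, matching adjacent circles of those values).
#' @return List with integer images `a` and `b`.
#' @examples
#' pr <- make_adjacent_pair(10, 10, shape_rect(1, 10, 1, 10),
#'                          split_vertical(5), split_vertical(7))
#' evaluate_segmentation(pr$a, pr$b)$object$metrics
#' @export
make_adjacent_pair <- function(height = 256, width = 256,
                               footprint = shape_disc(128.5, 128.5, 80),
                               split_a = split_vertical(128),
                               split_b = split_vertical(148),
                               intensities = c(100L, 200L)) {
  stopifnot(length(intensities) == 2L, all(intensities > 0),
            intensities[1] != intensities[2])
  fp <- rasterize_shape(footprint, height, width)
  if (!any(fp)) stop("footprint is empty", call. = FALSE)
  build <- function(split, which) {
    pred <- split_predicate(split, height, width)
    img <- matrix(0L, height, width)
    for (part in 1:2) {
      sel <- if (part == 1L) fp & pred else fp & !pred
      if (!any(sel)) {
        stop(sprintf("split_%s leaves part %d of the footprint empty", which, part),
             call. = FALSE)
      }
      comp <- connected_components(sel, 8L)
      if (attr(comp, "n") != 1L) {
        stop(sprintf("split_%s does not divide the footprint into two connected parts", which),
             call. = FALSE)
      }
      img[sel] <- as.integer(intensities[part])
    }
    img
  }
  list(a = build(split_a, "a"), b = build(split_b, "b"))
}

#' Scene specification for randomized cell fields
#'
#' Describes a field of non-overlapping discs emulating segmented cells:
#' mostly isolated objects plus optional touching pairs, with controlled
#' perturbations applied to the test labeling so the per-object TP/FP/FN
#' truth is known analytically.
#'
#' @param height,width Field dimensions (default 256 x 256, a typical
#'   microscopy frame).
#' @param n_objects Total number of discs, including touching-pair members.
#' @param radius Inclusive integer radius range, in pixels.
#' @param n_touching_pairs Number of disc pairs placed in pixel adjacency
#'   (exercising the four-color separation); their test objects are left
#'   unperturbed.
#' @param gap Minimum clearance in pixels between non-touching discs (at
#'   least 3, so 1-pixel dilations cannot collide).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param perturb Named list of perturbation counts applied to distinct
#'   isolated objects: `dilate` (grow by a 1-pixel ring into background),
#'   `erode` (shrink by the 1-pixel boundary), `delete` (remove from the
#'   test image), `merge` (pairs of objects sharing one test label).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height = 256, width = 256, n_objects = 12,
                       radius = c(6, 14), n_touching_pairs = 1, gap = 4,
                       seed = 1,
                       perturb = list(dilate = 2, erode = 2, delete = 1, merge = 0)) {
  stopifnot(height >= 16, width >= 16, n_objects >= 1,
            length(radius) == 2L, radius[1] >= 3, radius[2] >= radius[1],
            n_touching_pairs >= 0, 2 * n_touching_pairs <= n_objects, gap >= 3)
  perturb <- utils::modifyList(list(dilate = 0, erode = 0, delete = 0, merge = 0),
                               as.list(perturb))
  structure(list(height = height, width = width, n_objects = n_objects,
                 radius = radius, n_touching_pairs = n_touching_pairs,
                 gap = gap, seed = seed, perturb = perturb),
            class = "scene_spec")
}

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  sr <- seq_len(nrow(m)); sc <- seq_len(ncol(m))
  src_r <- sr - dr; src_c <- sc - dc
  ok_r <- src_r >= 1L & src_r <= nrow(m)
  ok_c <- src_c >= 1L & src_c <= ncol(m)
  out[sr[ok_r], sc[ok_c]] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

neighborhood8 <- expand.grid(dr = -1:1, dc = -1:1)

dilate8 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(neighborhood8))) {
    out <- out | shift_mask(mask, neighborhood8$dr[i], neighborhood8$dc[i])
  }
  out
}

erode8 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(neighborhood8))) {
    out <- out & shift_mask(mask, neighborhood8$dr[i], neighborhood8$dc[i])
  }
  out
}

#' Randomized cell field with analytically known per-object truth
#'
#' Places the discs described by `spec`, four-colors the ground truth so
#' touching objects take different intensities, derives the test labeling by
#' applying the requested perturbations, and records the exact per-object
#' TP/FP/FN each perturbation implies. The truth table rows are ordered by
#' the canonical ground-truth object ids that [evaluate_segmentation()] will
#' assign (ascending intensity class, then scan order), so
#' `evaluate_segmentation(gt, test)$per_object` must reproduce `truth`
#' exactly.
#'
#' @param spec A [scene_spec()].
#' @return List with `gt` (four-colored ground-truth image), `test`
#'   (perturbed label image), `truth` (tibble: `gt_id`, `class`, `size`,
#'   `tp`, `fp`, `fn`) and `spec`.
#' @export
make_cell_field <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    placement <- place_discs(spec)
    labels <- placement$labels
    k <- placement$n

    map <- new_object_map(labels, placement$sizes, rep(NA_integer_, k), 8L)
    gt <- four_color_relabel(map, connectivity = 8L)
    colors <- attr(gt, "colors")

    eligible <- setdiff(seq_len(k), placement$touching_ids)
    p <- spec$perturb
    need <- p$dilate + p$erode + p$delete + 2 * p$merge
    if (need > length(eligible)) {
      stop(sprintf("perturbations need %d isolated objects but only %d are available",
                   need, length(eligible)), call. = FALSE)
    }
    chosen <- if (need > 0) sample(eligible, need) else integer(0)
    take <- function(n) {
      out <- chosen[seq_len(n)]
      chosen <<- chosen[-seq_len(n)]
      out
    }
    dilate_ids <- take(p$dilate)
    erode_ids <- take(p$erode)
    delete_ids <- take(p$delete)
    merge_ids <- take(2 * p$merge)

    test <- labels
    sizes <- placement$sizes
    truth <- tibble::tibble(placement_id = seq_len(k), size = sizes,
                            tp = as.numeric(sizes), fp = 0, fn = 0)
    for (id in dilate_ids) {
      ring <- dilate8(labels == id) & labels == 0L
      test[ring] <- id
      truth$fp[id] <- sum(ring)
    }
    for (id in erode_ids) {
      mask <- labels == id
      er <- erode8(mask)
      stopifnot(any(er))  # radius >= 3 guarantees a non-empty core
      test[mask & !er] <- 0L
      truth$tp[id] <- sum(er)
      truth$fn[id] <- sum(mask & !er)
    }
    for (id in delete_ids) {
      test[labels == id] <- 0L
      truth$tp[id] <- 0
      truth$fn[id] <- truth$size[id]
    }
    if (length(merge_ids) > 0) {
      for (i in seq_len(length(merge_ids) / 2)) {
        a <- merge_ids[2 * i - 1]; b <- merge_ids[2 * i]
        test[test == b] <- a
        truth$fp[a] <- truth$fp[a] + sizes[b]
        truth$fp[b] <- truth$fp[b] + sizes[a]
      }
    }

    # Reorder truth into the canonical gt-id order evaluate_segmentation uses:
    # ascending intensity class, then column-major scan order of first pixel.
    first_px <- vapply(seq_len(k), function(id) min(which(labels == id)), integer(1))
    ord <- order(colors, first_px)
    truth <- truth[ord, ]
    truth <- tibble::tibble(gt_id = seq_len(k), class = colors[ord],
                            size = truth$size, tp = truth$tp, fp = truth$fp,
                            fn = truth$fn)
    list(gt = gt, test = test, truth = truth, spec = spec)
  })
}

# Rejection-sampled disc placement honoring the clearance and touching-pair
# constraints of a scene_spec. Returns placement-order labels.
place_discs <- function(spec) {
  h <- spec$height; w <- spec$width
  rmin <- spec$radius[1]; rmax <- spec$radius[2]
  labels <- matrix(0L, h, w)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  touching_ids <- integer(0)
  margin <- rmax + 2

  clear_of_others <- function(cx, cy, r, skip = integer(0)) {
    if (nrow(centers) == 0) return(TRUE)
    keep <- setdiff(seq_len(nrow(centers)), skip)
    if (length(keep) == 0) return(TRUE)
    d <- sqrt((centers[keep, 1] - cx)^2 + (centers[keep, 2] - cy)^2)
    all(d >= radii[keep] + r + spec$gap)
  }
  draw <- function(cx, cy, r, id) {
    sel <- rasterize_shape(shape_disc(cx, cy, r), h, w)
    if (any(labels[sel] > 0L)) {
      stop("internal error: overlapping ground-truth shapes", call. = FALSE)
    }
    labels[sel] <<- id
    centers <<- rbind(centers, c(cx, cy))
    radii <<- c(radii, r)
  }

  id <- 0L
  for (pair in seq_len(spec$n_touching_pairs)) {
    placed <- FALSE
    for (try in 1:500) {
      r1 <- sample(rmin:rmax, 1); r2 <- sample(rmin:rmax, 1)
      # integer centers so the discs are exactly pixel-adjacent at the equator
      cx <- sample(ceiling(margin):floor(h - margin), 1)
      cy <- sample(ceiling(margin):floor(w - margin - (r1 + r2 + 1)), 1)
      cy2 <- cy + r1 + r2 + 1
      if (clear_of_others(cx, cy, r1) && clear_of_others(cx, cy2, r2)) {
        draw(cx, cy, r1, id + 1L)
        draw(cx, cy2, r2, id + 2L)
        touching_ids <- c(touching_ids, id + 1L, id + 2L)
        id <- id + 2L
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place touching pair; field too crowded", call. = FALSE)
  }
  while (id < spec$n_objects) {
    placed <- FALSE
    for (try in 1:1000) {
      r <- sample(rmin:rmax, 1)
      cx <- stats::runif(1, margin, h - margin)
      cy <- stats::runif(1, margin, w - margin)
      if (clear_of_others(cx, cy, r)) {
        draw(cx, cy, r, id + 1L)
        id <- id + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place object; reduce n_objects or radii", call. = FALSE)
  }
  sizes <- tabulate(labels[labels > 0L], spec$n_objects)
  list(labels = labels, sizes = sizes, n = spec$n_objects,
       touching_ids = touching_ids)
}

#' Four-color an object map into a ground-truth image
#'
#' Greedy coloring of the object-adjacency graph (objects are adjacent when
#' any two of their pixels touch under the chosen connectivity) onto the
#' intensity palette, guaranteeing that touching objects receive different
#' intensities — the encoding the evaluation expects of a ground-truth
#' image. Coloring order is descending object size, ties by id; if greedy
#' coloring ever needs more than the palette offers, additional intensity
#' levels are appended.
#'
#' @param map An `object_map`.
#' @param palette Intensity values to color with (default 50/100/150/200).
#' @param connectivity 4 or 8 (default: the map's own connectivity, else 8).
#' @return An integer ground-truth image with attribute `colors` giving the
#'   intensity assigned to each object id.
#' @export
four_color_relabel <- function(map, palette = c(50L, 100L, 150L, 200L),
                               connectivity = NULL) {
  stopifnot(inherits(map, "object_map"))
  if (is.null(connectivity)) {
    connectivity <- if (!is.na(map$connectivity)) map$connectivity else 8L
  }
  connectivity <- check_connectivity(connectivity)
  labels <- map$labels
  k <- map$n
  adj <- adjacency_pairs(labels, connectivity)
  neighbors <- vector("list", k)
  for (i in seq_len(nrow(adj))) {
    a <- adj[i, 1]; b <- adj[i, 2]
    neighbors[[a]] <- c(neighbors[[a]], b)
    neighbors[[b]] <- c(neighbors[[b]], a)
  }
  colors <- integer(k)
  extended <- as.integer(palette)
  for (id in order(-map$sizes, seq_len(k))) {
    used <- colors[neighbors[[id]]]
    avail <- setdiff(extended, used[used > 0L])
    while (length(avail) == 0L) {
      extended <- c(extended, max(extended) + 50L)
      avail <- setdiff(extended, used[used > 0L])
    }
    colors[id] <- avail[1L]
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0L] <- colors[labels[labels > 0L]]
  structure(out, colors = colors)
}

# Unique pairs of distinct object ids with touching pixels.
adjacency_pairs <- function(labels, connectivity) {
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- matrix(integer(0), 0, 2)
  for (o in offs) {
    r_src <- max(1L, 1L - o[1L]):min(nr, nr - o[1L])
    c_src <- max(1L, 1L - o[2L]):min(nc, nc - o[2L])
    a <- labels[r_src, c_src]
    b <- labels[r_src + o[1L], c_src + o[2L]]
    hit <- a > 0L & b > 0L & a != b
    if (any(hit)) {
      p <- cbind(pmin(a[hit], b[hit]), pmax(a[hit], b[hit]))
      pairs <- rbind(pairs, p)
    }
  }
  unique(pairs)
}
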