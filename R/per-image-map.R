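#' The standard IoU threshold grid
#'
#' Ten thresholds from 0.50 to 0.95 in steps of 0.05, as used by the COCO
#' mAP 50:95 protocol. Built from integer arithmetic so threshold
#' comparisons are exact for rational IoU values.
#'
#' @return Numeric vector of length 10.
#' @export
iou_thresholds <- function() seq(50L, 95L, by = 5L) / 100

#' Intersection-over-union of two boxes
#'
#' Boxes use the COCO `[x, y, w, h]` convention. Returns
#' `area(a intersect b) / area(a union b)`, 0 for disjoint boxes.
#'
#' @param a,b Numeric vectors `c(x, y, w, h)` with positive `w`, `h`.
#' @return IoU in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 1/3
#' @export
box_iou <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L, a[3] > 0, a[4] > 0,
            b[3] > 0, b[4] > 0)
  iw <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  ih <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# IoU matrix between detection and ground-truth box tables (rows: dets).
iou_matrix <- function(dets, gts) {
  nd <- nrow(dets); ng <- nrow(gts)
  m <- matrix(0, nd, ng)
  for (i in seq_len(nd)) {
    for (j in seq_len(ng)) {
      m[i, j] <- box_iou(c(dets$x[i], dets$y[i], dets$w[i], dets$h[i]),
                         c(gts$x[j], gts$y[j], gts$w[j], gts$h[j]))
    }
  }
  m
}

#' Greedy confidence-ordered matching of detections to ground truth
#'
#' Detections of a single image and category are processed in descending
#' confidence (ties keep input order). Each detection is matched to the
#' still-unmatched ground-truth box with the highest IoU at or above the
#' threshold; if none qualifies it is a false positive. Each ground-truth
#' box is matched at most once.
#'
#' @param dets Detection tibble for one image and category (columns `x`,
#'   `y`, `w`, `h`, `score`).
#' @param gts Ground-truth box tibble for the same image and category
#'   (columns `x`, `y`, `w`, `h`).
#' @param iou_thr IoU threshold for a match.
#' @return A list with `matches` (tibble in descending-confidence order:
#'   `det_index` into the input, `score`, `tp`) and `fn`, the count of
#'   unmatched ground-truth boxes.
#' @export
match_image <- function(dets, gts, iou_thr) {
  dets <- tibble::as_tibble(dets); gts <- tibble::as_tibble(gts)
  nd <- nrow(dets); ng <- nrow(gts)
  ord <- order(-dets$score)  # stable: ties keep input order
  tp <- logical(nd)
  if (nd > 0L && ng > 0L) {
    iou <- iou_matrix(dets, gts)
    gt_taken <- logical(ng)
    for (k in ord) {
      cand <- which(!gt_taken & iou[k, ] >= iou_thr)
      if (length(cand) > 0L) {
        best <- cand[which.max(iou[k, cand])]
        gt_taken[best] <- TRUE
        tp[k] <- TRUE
      }
    }
  }
  list(
    matches = tibble::tibble(det_index = ord,
                             score = dets$score[ord],
                             tp = tp[ord]),
    fn = ng - sum(tp)
  )
}

# AP from a confidence-ordered TP/FP label sequence and the GT count.
ap_from_labels <- function(tp_ordered, n_gt,
                           interpolation = c("coco101", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  stopifnot(n_gt >= 1L)
  n <- length(tp_ordered)
  if (n == 0L) return(0)
  cum_tp <- cumsum(tp_ordered)
  precision <- cum_tp / seq_len(n)
  recall <- cum_tp / n_gt
  # precision envelope: best precision achievable at recall >= r
  envelope <- rev(cummax(rev(precision)))
  if (interpolation == "coco101") {
    grid <- 0:100 / 100
    p_at <- vapply(grid, function(r) {
      i <- which(recall >= r - 1e-12)
      if (length(i) == 0L) 0 else envelope[i[1]]
    }, numeric(1))
    mean(p_at)
  } else {
    r_prev <- c(0, recall[-n])
    sum((recall - r_prev) * envelope)
  }
}

#' Average precision of a single image and category
#'
#' Builds the precision-recall curve from the predictions and ground-truth
#' boxes of one image only, using greedy IoU matching, and integrates it
#' with COCO's 101-point interpolated precision (a trapezoid variant over
#' all recall breakpoints is available for sensitivity checks).
#'
#' @inheritParams match_image
#' @param interpolation `"coco101"` (default) or `"trapezoid"`.
#' @return AP in `[0, 1]`.
#' @export
per_image_ap <- function(dets, gts, iou_thr,
                         interpolation = c("coco101", "trapezoid")) {
  gts <- tibble::as_tibble(gts)
  if (nrow(gts) < 1L) {
    stop("per-image AP is undefined without ground-truth boxes", call. = FALSE)
  }
  m <- match_image(dets, gts, iou_thr)
  ap_from_labels(m$matches$tp, nrow(gts), match.arg(interpolation))
}

#' Per-image mAP 50:95
#'
#' The single-image analogue of COCO mAP: for each IoU threshold in
#' [iou_thresholds()], AP is computed per category and averaged over the
#' categories present in this image's ground truth (a category with
#' ground-truth boxes but no detections contributes 0); the score is the
#' mean over the ten thresholds. An image with no ground-truth boxes has
#' no recall axis, so its score is undefined (`defined = FALSE`) and it is
#' excluded from set-level means.
#'
#' @param dets Detection tibble for one image (columns `category_id`, `x`,
#'   `y`, `w`, `h`, `score`).
#' @param gts Ground-truth tibble for the same image (columns
#'   `category_id`, `x`, `y`, `w`, `h`).
#' @param image_id,variant_id Labels carried into the result.
#' @param thresholds IoU thresholds (default the 0.50:0.95 grid).
#' @param interpolation Passed to [per_image_ap()].
#' @return A `per_image_score`: list with `image_id`, `variant_id`,
#'   `map5095`, `per_threshold` (named AP vector), `per_category` (tibble
#'   `category_id`, `ap5095`), and `defined`.
#' @export
per_image_map5095 <- function(dets, gts, image_id = NA_character_,
                              variant_id = NA_integer_,
                              thresholds = iou_thresholds(),
                              interpolation = c("coco101", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  dets <- tibble::as_tibble(dets); gts <- tibble::as_tibble(gts)
  if (nrow(gts) == 0L) {
    return(structure(list(image_id = image_id, variant_id = variant_id,
                          map5095 = NA_real_,
                          per_threshold = setNames(rep(NA_real_, length(thresholds)),
                                                   format(thresholds)),
                          per_category = tibble::tibble(category_id = integer(),
                                                        ap5095 = double()),
                          defined = FALSE),
                     class = "per_image_score"))
  }
  cats <- sort(unique(gts$category_id))
  ap <- matrix(0, length(cats), length(thresholds),
               dimnames = list(cats, format(thresholds)))
  for (ci in seq_along(cats)) {
    gts_c <- gts[gts$category_id == cats[ci], , drop = FALSE]
    dets_c <- dets[dets$category_id == cats[ci], , drop = FALSE]
    for (ti in seq_along(thresholds)) {
      ap[ci, ti] <- per_image_ap(dets_c, gts_c, thresholds[ti], interpolation)
    }
  }
  per_threshold <- colMeans(ap)
  structure(list(image_id = image_id, variant_id = variant_id,
                 map5095 = mean(per_threshold),
                 per_threshold = per_threshold,
                 per_category = tibble::tibble(category_id = as.integer(cats),
                                               ap5095 = rowMeans(ap)),
                 defined = TRUE),
            class = "per_image_score")
}

#' @export
print.per_image_score <- function(x, ...) {
  cat(sprintf("<per_image_score %s / variant %s: mAP50:95 = %s>\n",
              x$image_id, x$variant_id,
              if (x$defined) sprintf("%.4f", x$map5095) else "undefined"))
  invisible(x)
}

#' Conventional pooled dataset-level mAP
#'
#' The standard COCO-style evaluation for comparison with the per-image
#' protocol: per category, detections are matched greedily within each
#' image, then pooled across all images in descending confidence to build
#' one precision-recall curve; AP is averaged over categories with at
#' least one ground-truth box and over the IoU thresholds.
#'
#' @param dets Detection tibble (columns `image_id`, `category_id`, `x`,
#'   `y`, `w`, `h`, `score`); typically one variant's detections.
#' @param gt A `gt_set`, or a ground-truth tibble with `image_id` and
#'   `category_id` columns.
#' @inheritParams per_image_map5095
#' @return A list with `map50`, `map5095`, `per_threshold` (category-
#'   averaged AP per threshold) and `per_category` (tibble `category_id`,
#'   `ap50`, `ap5095`).
#' @export
dataset_map <- function(dets, gt, thresholds = iou_thresholds(),
                        interpolation = c("coco101", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  anns <- if (inherits(gt, "gt_set")) gt$annotations else tibble::as_tibble(gt)
  dets <- tibble::as_tibble(dets)
  cats <- sort(unique(anns$category_id))
  if (length(cats) == 0L) stop("ground truth has no annotated boxes", call. = FALSE)
  ap <- matrix(0, length(cats), length(thresholds))
  for (ci in seq_along(cats)) {
    anns_c <- anns[anns$category_id == cats[ci], , drop = FALSE]
    dets_c <- dets[dets$category_id == cats[ci], , drop = FALSE]
    n_gt <- nrow(anns_c)
    for (ti in seq_along(thresholds)) {
      # match per image, then pool labels under the global confidence ranking
      labels <- purrr::map(unique(dets_c$image_id), function(id) {
        m <- match_image(dets_c[dets_c$image_id == id, , drop = FALSE],
                         anns_c[anns_c$image_id == id, , drop = FALSE],
                         thresholds[ti])
        tibble::tibble(score = m$matches$score, tp = m$matches$tp)
      }) |> dplyr::bind_rows()
      if (nrow(labels) == 0L) { ap[ci, ti] <- 0; next }
      ord <- order(-labels$score)
      ap[ci, ti] <- ap_from_labels(labels$tp[ord], n_gt, interpolation)
    }
  }
  per_threshold <- setNames(colMeans(ap), format(thresholds))
  i50 <- which(abs(thresholds - 0.5) < 1e-9)
  list(map50 = if (length(i50) == 1L) per_threshold[[i50]] else NA_real_,
       map5095 = mean(colMeans(ap)),
       per_threshold = per_threshold,
       per_category = tibble::tibble(
         category_id = as.integer(cats),
         ap50 = if (length(i50) == 1L) ap[, i50] else NA_real_,
         ap5095 = rowMeans(ap)))
}

#' Per-image score matrix over all variants
#'
#' Computes [per_image_map5095()] for every image in the ground truth and
#' every variant, yielding the N x (V+1) matrix that drives the mixed-set
#' construction. Variant 0 is the original imagery.
#'
#' @param dets Detection tibble covering all variants (must include a
#'   `variant_id` column).
#' @param gt A `gt_set`.
#' @param variants Optional integer vector of expected variant ids; an
#'   expected variant with no detections at all triggers a coverage error.
#' @inheritParams per_image_map5095
#' @return A `uw_score_matrix`: list with `scores` (long tibble:
#'   `image_id`, `variant_id`, `map5095`, `defined`), `images`,
#'   `variants`. `as.matrix()` gives the wide images x variants matrix;
#'   [tidy()] returns the long tibble.
#' @export
score_matrix <- function(dets, gt, variants = NULL,
                         thresholds = iou_thresholds(),
                         interpolation = c("coco101", "trapezoid")) {
  stopifnot(inherits(gt, "gt_set"))
  interpolation <- match.arg(interpolation)
  dets <- tibble::as_tibble(dets)
  present <- sort(unique(dets$variant_id))
  if (is.null(variants)) {
    variants <- present
  } else {
    missing <- setdiff(variants, present)
    if (length(missing) > 0L) {
      stop("no detections at all for expected variant id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (length(variants) == 0L) stop("no variants to score", call. = FALSE)
  images <- gt$images$image_id
  grid <- tidyr::expand_grid(image_id = images, variant_id = as.integer(variants))
  scores <- purrr::pmap(grid, function(image_id, variant_id) {
    s <- per_image_map5095(
      dets[dets$image_id == image_id & dets$variant_id == variant_id, , drop = FALSE],
      gt$annotations[gt$annotations$image_id == image_id, , drop = FALSE],
      image_id = image_id, variant_id = variant_id,
      thresholds = thresholds, interpolation = interpolation)
    tibble::tibble(image_id = image_id, variant_id = variant_id,
                   map5095 = s$map5095, defined = s$defined)
  }) |> dplyr::bind_rows()
  structure(list(scores = scores, images = images,
                 variants = as.integer(variants)),
            class = "uw_score_matrix")
}

#' @export
print.uw_score_matrix <- function(x, ...) {
  cat(sprintf("<uw_score_matrix: %d images x %d variants (%d undefined rows)>\n",
              length(x$images), length(x$variants),
              sum(!x$scores$defined) %/% max(1L, length(x$variants))))
  invisible(x)
}

#' @export
as.matrix.uw_score_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$scores[c("image_id", "variant_id", "map5095")],
                             names_from = "variant_id", values_from = "map5095")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$image_id
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

#' @rdname score_matrix
#' @param x A `uw_score_matrix`.
#' @param ... Unused.
#' @export
tidy.uw_score_matrix <- function(x, ...) x$scores
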