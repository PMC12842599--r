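# Independent, deliberately naive implementation of the COCO-style
# evaluation protocol (greedy confidence-ordered matching, 101-point
# interpolated AP, category and threshold averaging), written with explicit
# loops and no shared code with the package.

oracle_iou <- function(a, b) {
  ax2 <- a[1] + a[3]; ay2 <- a[2] + a[4]
  bx2 <- b[1] + b[3]; by2 <- b[2] + b[4]
  iw <- min(ax2, bx2) - max(a[1], b[1])
  ih <- min(ay2, by2) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Greedy matching replay: detections in descending score (ties: input
# order); each picks the best still-free GT with IoU >= thr.
oracle_match <- function(dets, gts, thr) {
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd)
  free <- rep(TRUE, ng)
  ord <- order(-dets$score)
  for (k in ord) {
    best_iou <- -1; best_j <- 0
    for (j in seq_len(ng)) {
      if (!free[j]) next
      v <- oracle_iou(c(dets$x[k], dets$y[k], dets$w[k], dets$h[k]),
                      c(gts$x[j], gts$y[j], gts$w[j], gts$h[j]))
      if (v >= thr && v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0) { free[best_j] <- FALSE; tp[k] <- TRUE }
  }
  list(tp = tp, order = ord)
}

oracle_ap101 <- function(tp_sorted, n_gt) {
  n <- length(tp_sorted)
  if (n == 0) return(0)
  prec <- numeric(n); rec <- numeric(n)
  hits <- 0
  for (k in seq_len(n)) {
    if (tp_sorted[k]) hits <- hits + 1
    prec[k] <- hits / k
    rec[k] <- hits / n_gt
  }
  total <- 0
  for (r in 0:100 / 100) {
    # best precision achievable at any operating point with recall >= r
    best <- 0
    for (k in seq_len(n)) {
      if (rec[k] >= r - 1e-12) best <- max(best, max(prec[k:n]))
    }
    total <- total + best
  }
  total / 101
}

oracle_per_image_map <- function(dets, gts, thresholds = 0:9 * 0.05 + 0.5) {
  cats <- sort(unique(gts$category_id))
  if (length(cats) == 0) return(NA_real_)
  acc <- 0
  for (thr in thresholds) {
    cat_sum <- 0
    for (cc in cats) {
      g <- gts[gts$category_id == cc, , drop = FALSE]
      d <- dets[dets$category_id == cc, , drop = FALSE]
      if (nrow(d) == 0) { next }
      m <- oracle_match(d, g, thr)
      cat_sum <- cat_sum + oracle_ap101(m$tp[m$order], nrow(g))
    }
    acc <- acc + cat_sum / length(cats)
  }
  acc / length(thresholds)
}

oracle_dataset_map <- function(dets, gts, thresholds = 0:9 * 0.05 + 0.5) {
  cats <- sort(unique(gts$category_id))
  per_thr <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    cat_sum <- 0
    for (cc in cats) {
      g_all <- gts[gts$category_id == cc, , drop = FALSE]
      d_all <- dets[dets$category_id == cc, , drop = FALSE]
      n_gt <- nrow(g_all)
      scores <- c(); tps <- c()
      for (id in unique(d_all$image_id)) {
        d <- d_all[d_all$image_id == id, , drop = FALSE]
        g <- g_all[g_all$image_id == id, , drop = FALSE]
        m <- oracle_match(d, g, thresholds[ti])
        scores <- c(scores, d$score[m$order])
        tps <- c(tps, m$tp[m$order])
      }
      if (length(scores) > 0) {
        ord <- order(-scores)
        cat_sum <- cat_sum + oracle_ap101(tps[ord], n_gt)
      }
    }
    per_thr[ti] <- cat_sum / length(cats)
  }
  mean(per_thr)
}

# Small random detection fixtures -----------------------------------------

random_gt_fixture <- function(n_images, seed, n_categories = 2) {
  set.seed(seed)
  ids <- sprintf("f%03d", seq_len(n_images))
  rows <- do.call(rbind, lapply(seq_len(n_images), function(i) {
    k <- sample(1:4, 1)
    w <- runif(k, 10, 80); h <- runif(k, 10, 80)
    data.frame(image_id = ids[i],
               category_id = sample(seq_len(n_categories), k, replace = TRUE),
               x = runif(k, 0, 200), y = runif(k, 0, 200), w = w, h = h)
  }))
  tibble::as_tibble(rows)
}

random_det_fixture <- function(gts, seed, miss_p = 0.2, jitter = 6, n_fp = 8) {
  set.seed(seed)
  kept <- gts[runif(nrow(gts)) > miss_p, , drop = FALSE]
  kept$x <- kept$x + rnorm(nrow(kept), 0, jitter)
  kept$y <- kept$y + rnorm(nrow(kept), 0, jitter)
  kept$w <- pmax(4, kept$w + rnorm(nrow(kept), 0, jitter))
  kept$h <- pmax(4, kept$h + rnorm(nrow(kept), 0, jitter))
  kept$score <- runif(nrow(kept), 0.3, 0.99)
  ids <- unique(gts$image_id)
  fp <- tibble::tibble(
    image_id = sample(ids, n_fp, replace = TRUE),
    category_id = sample(unique(gts$category_id), n_fp, replace = TRUE),
    x = runif(n_fp, 0, 220), y = runif(n_fp, 0, 220),
    w = runif(n_fp, 10, 60), h = runif(n_fp, 10, 60),
    score = runif(n_fp, 0.05, 0.8))
  dplyr::bind_rows(tibble::as_tibble(kept), fp)
}
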