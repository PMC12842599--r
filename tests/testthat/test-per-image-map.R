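box <- function(x, y, w, h) tibble::tibble(x = x, y = y, w = w, h = h)
det <- function(x, y, w, h, score, category_id = 1L) {
  tibble::tibble(category_id = category_id, x = x, y = y, w = w, h = h,
                 score = score)
}

test_that("IoU matches hand geometry", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 5, 5)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 10, 10)), 1 / 3)
  # touching edges do not intersect
  expect_equal(box_iou(c(0, 0, 10, 10), c(10, 0, 10, 10)), 0)
})

test_that("greedy matching follows the single-assignment rule", {
  gts <- box(0, 0, 10, 10)
  d <- det(c(0, 1), c(0, 1), c(10, 10), c(10, 10), score = c(0.9, 0.6))
  m <- match_image(d, gts, 0.5)
  expect_equal(m$matches$tp, c(TRUE, FALSE))  # higher confidence wins the GT
  expect_equal(m$fn, 0L)

  # one detection, one GT above threshold
  m1 <- match_image(det(0, 0, 10, 10, 0.8), gts, 0.5)
  expect_equal(m1$matches$tp, TRUE)
  expect_equal(m1$fn, 0L)

  # no detections: everything is a miss
  m0 <- match_image(det(numeric(0), numeric(0), numeric(0), numeric(0),
                        numeric(0)), gts, 0.5)
  expect_equal(nrow(m0$matches), 0L)
  expect_equal(m0$fn, 1L)
})

test_that("greedy matching equals an independent replay on adversarial cases", {
  # a 3x3 IoU pattern where greedy and globally optimal assignment differ
  gts <- box(c(0, 12, 24), c(0, 0, 0), c(10, 10, 10), c(10, 10, 10))
  d <- det(c(5, 1, 23), c(0, 0, 0), c(12, 10, 11), c(10, 10, 10),
           score = c(0.9, 0.8, 0.7))
  for (thr in c(0.3, 0.5)) {
    m <- match_image(d, gts, thr)
    o <- oracle_match(d, gts, thr)
    expect_equal(m$matches$tp, o$tp[o$order])
  }

  # randomized cases
  for (seed in 1:10) {
    set.seed(seed)
    ng <- sample(1:5, 1); nd <- sample(0:6, 1)
    gts <- box(runif(ng, 0, 60), runif(ng, 0, 60), runif(ng, 8, 30), runif(ng, 8, 30))
    d <- det(runif(nd, 0, 60), runif(nd, 0, 60), runif(nd, 8, 30),
             runif(nd, 8, 30), score = round(runif(nd), 2))
    m <- match_image(d, gts, 0.3)
    o <- oracle_match(d, gts, 0.3)
    expect_equal(m$matches$tp, o$tp[o$order])
    expect_equal(m$fn, ng - sum(o$tp))
  }
})

test_that("101-point AP reproduces the hand-computed PR fixture", {
  # 2 GT; ranked labels (TP, FP, TP): PR points (1, .5), (.5, .5), (2/3, 1)
  # 51 recall grid points at precision 1, 50 at 2/3 -> AP = 253/303
  gts <- box(c(0, 100), c(0, 0), c(10, 10), c(10, 10))
  d <- det(c(0, 50, 100), c(0, 0, 0), c(10, 10, 10), c(10, 10, 10),
           score = c(0.9, 0.8, 0.7))
  ap <- per_image_ap(d, gts, 0.5)
  expect_equal(ap, 253 / 303)

  # perfect ranking -> 1; no detections -> 0
  expect_equal(per_image_ap(det(c(0, 100), c(0, 0), c(10, 10), c(10, 10),
                                c(0.9, 0.8)), gts, 0.5), 1)
  expect_equal(per_image_ap(det(numeric(0), numeric(0), numeric(0),
                                numeric(0), numeric(0)), gts, 0.5), 0)
  expect_error(per_image_ap(d, box(numeric(0), numeric(0), numeric(0),
                                   numeric(0)), 0.5), "undefined")
})

test_that("AP never increases when a lowest-ranked detection is appended", {
  set.seed(21)
  for (i in 1:10) {
    gts <- box(runif(3, 0, 80), runif(3, 0, 80), runif(3, 10, 30), runif(3, 10, 30))
    d <- det(runif(4, 0, 80), runif(4, 0, 80), runif(4, 10, 30),
             runif(4, 10, 30), score = runif(4, 0.5, 1))
    extra <- dplyr::bind_rows(d, det(runif(1, 0, 80), runif(1, 0, 80),
                                     runif(1, 10, 30), runif(1, 10, 30),
                                     score = 0.01))
    expect_lte(per_image_ap(extra, gts, 0.5), per_image_ap(d, gts, 0.5) + 1e-12)
  }
})

test_that("AP depends on confidence ranks only", {
  set.seed(5)
  gts <- box(runif(4, 0, 80), runif(4, 0, 80), runif(4, 10, 30), runif(4, 10, 30))
  d <- det(runif(6, 0, 80), runif(6, 0, 80), runif(6, 10, 30), runif(6, 10, 30),
           score = runif(6, 0.2, 1))
  scaled <- dplyr::mutate(d, score = score * 0.5)
  for (thr in c(0.3, 0.5, 0.75)) {
    expect_equal(per_image_ap(scaled, gts, thr), per_image_ap(d, gts, thr))
  }
})

test_that("the threshold sweep yields the step-function per-image score", {
  # detection fully inside the GT with IoU exactly 0.60: passes 0.50/0.55/0.60
  gts <- tibble::tibble(category_id = 1L, x = 0, y = 0, w = 10, h = 10)
  d <- det(0, 0, 10, 6, score = 0.9)
  s <- per_image_map5095(d, gts)
  expect_equal(s$map5095, 0.30)
  expect_equal(unname(s$per_threshold), c(1, 1, 1, rep(0, 7)))

  # identity detections -> 1.0
  ident <- dplyr::mutate(gts, score = 1.0)
  expect_equal(per_image_map5095(ident, gts)$map5095, 1)

  # no detections -> 0.0
  none <- det(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(per_image_map5095(none, gts)$map5095, 0)

  # no ground truth -> undefined
  u <- per_image_map5095(d, gts[0, ])
  expect_false(u$defined)
  expect_true(is.na(u$map5095))
})

test_that("per-image scores average over categories present in the GT", {
  gts <- tibble::tibble(category_id = c(1L, 2L), x = c(0, 100), y = 0,
                        w = 10, h = 10)
  # perfect on category 1, nothing on category 2 -> mean (1 + 0) / 2
  d <- det(0, 0, 10, 10, 0.9, category_id = 1L)
  expect_equal(per_image_map5095(d, gts)$map5095, 0.5)
  # detections for a category absent from this image's GT are ignored
  d2 <- dplyr::bind_rows(d, det(300, 300, 10, 10, 0.9, category_id = 3L))
  expect_equal(per_image_map5095(d2, gts)$map5095, 0.5)
})

test_that("per-image and pooled dataset scores match the protocol oracle", {
  gts <- random_gt_fixture(20, seed = 301)
  dets <- random_det_fixture(gts, seed = 302)
  gt <- uwbench:::new_gt_set(gts, tibble::tibble(image_id = unique(gts$image_id)),
                             tibble::tibble(category_id = 1:2,
                                            name = c("c1", "c2")))
  for (id in unique(gts$image_id)[1:8]) {
    s <- per_image_map5095(dets[dets$image_id == id, ],
                           gts[gts$image_id == id, ])
    expect_equal(s$map5095,
                 oracle_per_image_map(dets[dets$image_id == id, ],
                                      gts[gts$image_id == id, ]),
                 tolerance = 1e-6)
  }
  dm <- dataset_map(dets, gt)
  expect_equal(dm$map5095, oracle_dataset_map(dets, gts), tolerance = 1e-6)
  expect_true(dm$map50 >= dm$map5095)
})

test_that("dataset mAP hits the trivial extremes", {
  gts <- random_gt_fixture(5, seed = 77)
  gt <- uwbench:::new_gt_set(gts, tibble::tibble(image_id = unique(gts$image_id)),
                             tibble::tibble(category_id = 1:2,
                                            name = c("c1", "c2")))
  perfect <- dplyr::mutate(gts, score = 0.99)
  expect_equal(dataset_map(perfect, gt)$map5095, 1)
  none <- perfect[0, ]
  expect_equal(dataset_map(none, gt)$map5095, 0)
})

test_that("single-image datasets collapse dataset mAP onto the per-image score", {
  gts <- random_gt_fixture(1, seed = 55)
  dets <- random_det_fixture(gts, seed = 56, n_fp = 3)
  gt <- uwbench:::new_gt_set(gts, tibble::tibble(image_id = unique(gts$image_id)),
                             tibble::tibble(category_id = 1:2,
                                            name = c("c1", "c2")))
  s <- per_image_map5095(dets, gts)
  # category-averaging convention is identical on a one-image dataset when
  # the image contains every annotated category
  if (setequal(unique(gts$category_id), unique(gt$annotations$category_id))) {
    expect_equal(dataset_map(dets, gt)$map5095, s$map5095)
  }
})

test_that("the score matrix recomputes element-wise and flags coverage", {
  sc <- generate_scenario(scenario_config(n_images = 8, n_variants = 2, seed = 13))
  sm <- score_matrix(sc$detections, sc$gt)
  expect_equal(sort(unique(sm$scores$variant_id)), 0:2)
  for (k in sample(nrow(sm$scores), 5)) {
    row <- sm$scores[k, ]
    direct <- per_image_map5095(
      sc$detections[sc$detections$image_id == row$image_id &
                      sc$detections$variant_id == row$variant_id, ],
      sc$gt$annotations[sc$gt$annotations$image_id == row$image_id, ])
    expect_equal(row$map5095, direct$map5095)
  }

  # duplicating a variant gives identical columns
  dup <- dplyr::mutate(sc$detections[sc$detections$variant_id == 1L, ],
                       variant_id = 9L)
  sm2 <- score_matrix(dplyr::bind_rows(sc$detections, dup), sc$gt)
  m <- as.matrix(sm2)
  expect_equal(unname(m[, "9"]), unname(m[, "1"]))

  expect_error(score_matrix(sc$detections, sc$gt, variants = 0:5),
               "no detections at all for expected variant")

  # single-variant matrix is a single column
  sm1 <- score_matrix(sc$detections[sc$detections$variant_id == 0L, ], sc$gt)
  expect_equal(ncol(as.matrix(sm1)), 1L)
})
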