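# A small record table with easy numbers: values chosen so rescaling and
# aggregation can be verified by hand.
make_records <- function(values, variants = NULL, metric = "uiqm") {
  n <- length(values)
  tibble::tibble(
    image_id = sprintf("im%02d", seq_len(n)),
    variant_id = variants %||% rep(0L, n),
    uiqm = if (metric == "uiqm") values else seq(0, 1, length.out = n),
    uciqe = if (metric == "uciqe") values else seq(0, 1, length.out = n),
    ccf = if (metric == "ccf") values else seq(0, 1, length.out = n),
    entropy = if (metric == "entropy") values else seq(0, 8, length.out = n)
  )
}

test_that("the 3-scaled-MAD rule removes exactly the hand-computed outliers", {
  # median 3, raw MAD 1, threshold 3 * 1.4826 ~ 4.45, so only 100 exceeds it
  res <- remove_outliers(c(1, 2, 3, 4, 100))
  expect_equal(res$kept, c(1, 2, 3, 4))
  expect_equal(res$removed_mask, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  expect_equal(remove_outliers(c(5, 5, 5, 5))$kept, c(5, 5, 5, 5))
  expect_equal(remove_outliers(7)$kept, 7)
  expect_error(remove_outliers(numeric(0)), "non-empty")
  expect_error(remove_outliers(c(1, NA)), "finite")
})

test_that("global rescaling maps cleaned min/max to 0/1 and preserves order", {
  recs <- make_records(c(2, 4, 6))
  qt <- global_rescale(recs, outlier_removal = FALSE)
  expect_equal(qt$scores$uiqm, c(0, 0.5, 1))
  expect_true(all(diff(qt$scores$uiqm) > 0))

  # outliers do not set the bounds: with 100 excluded, 4 rescales to 1
  recs <- make_records(c(1, 2, 3, 4, 100))
  qt <- global_rescale(recs)
  expect_equal(nrow(qt$scores), 4L)
  expect_equal(max(qt$scores$uiqm), 1)
  expect_equal(qt$scores$uiqm, (c(1, 2, 3, 4) - 1) / 3)
  expect_equal(qt$excluded$image_id, "im05")
  expect_equal(qt$excluded$metric, "uiqm")
  b <- qt$bounds[qt$bounds$metric == "uiqm", ]
  expect_equal(c(b$min, b$max), c(1, 4))
})

test_that("a constant metric raises a degenerate-scale error naming it", {
  recs <- make_records(rep(3, 4), metric = "ccf")
  expect_error(global_rescale(recs), "degenerate scale.*'ccf'")
})

test_that("aggregation is a weighted mean with the documented conventions", {
  recs <- make_records(c(0, 1))
  qt <- global_rescale(recs, outlier_removal = FALSE)
  # plant exact rescaled values, then aggregate
  qt$scores[1, c("uiqm", "uciqe", "ccf", "entropy")] <- as.list(c(0.2, 0.4, 0.6, 0.8))
  qt2 <- aggregate_qindex(qt)
  expect_equal(qt2$scores$qindex[1], 0.5)

  # all metrics equal q -> qindex q, any weights (convexity fixed point)
  qt$scores[1, c("uiqm", "uciqe", "ccf", "entropy")] <- as.list(rep(0.37, 4))
  expect_equal(aggregate_qindex(qt, c(0.1, 0.5, 0.2, 0.2))$scores$qindex[1], 0.37)

  # basis vector with unequal weights
  qt$scores[1, c("uiqm", "uciqe", "ccf", "entropy")] <- as.list(c(1, 0, 0, 0))
  expect_equal(aggregate_qindex(qt, c(0.4, 0.2, 0.2, 0.2))$scores$qindex[1], 0.4)

  expect_error(aggregate_qindex(qt, c(-0.1, 0.4, 0.4, 0.3)), "nonnegative")
})

test_that("equal-weight qindex is invariant under metric permutation and monotone", {
  set.seed(101)
  recs <- tibble::tibble(
    image_id = sprintf("im%02d", 1:12), variant_id = 0L,
    uiqm = runif(12), uciqe = runif(12), ccf = runif(12), entropy = runif(12, 0, 8)
  )
  qt <- qindex_pipeline(recs, outlier_removal = FALSE)
  permuted <- recs
  names(permuted)[3:6] <- c("entropy", "ccf", "uciqe", "uiqm")
  qp <- qindex_pipeline(permuted, outlier_removal = FALSE)
  expect_equal(sort(qp$scores$qindex), sort(qt$scores$qindex))

  # increasing one rescaled metric never decreases qindex
  bumped <- qt
  bumped$scores$uciqe <- pmin(1, bumped$scores$uciqe + 0.05)
  bumped <- aggregate_qindex(bumped)
  expect_true(all(bumped$scores$qindex >= qt$scores$qindex - 1e-12))
})

test_that("delta against the original follows the subtraction identity", {
  recs <- dplyr::bind_rows(
    make_records(c(0.1, 0.5, 0.9)),
    make_records(c(0.3, 0.5, 0.7), variants = rep(1L, 3))
  )
  qt <- qindex_pipeline(recs, outlier_removal = FALSE)
  d <- delta_qindex(qt)
  expect_equal(nrow(d), 3L)
  expect_equal(d$delta, d$qindex - d$qindex_original)
  # the original against itself is identically zero
  self <- qt
  self$scores$variant_id[self$scores$variant_id == 1L] <- 2L
  self$scores <- dplyr::bind_rows(
    self$scores,
    dplyr::mutate(dplyr::filter(qt$scores, variant_id == 0L), variant_id = 1L))
  expect_equal(dplyr::filter(delta_qindex(self), variant_id == 1L)$delta,
               rep(0, 3))

  # a missing original is a hard error listing the image
  qt$scores <- qt$scores[qt$scores$image_id != "im01" | qt$scores$variant_id != 0L, ]
  expect_error(delta_qindex(qt), "im01")
})

test_that("an additive enhancement shows up as the median delta", {
  set.seed(7)
  q0 <- runif(40, 0.1, 0.4)
  recs <- dplyr::bind_rows(
    tibble::tibble(image_id = sprintf("im%02d", 1:40), variant_id = 0L,
                   uiqm = q0, uciqe = q0, ccf = q0, entropy = q0 * 8),
    tibble::tibble(image_id = sprintf("im%02d", 1:40), variant_id = 1L,
                   uiqm = q0 + 0.2, uciqe = q0 + 0.2, ccf = q0 + 0.2,
                   entropy = (q0 + 0.2) * 8)
  )
  qt <- qindex_pipeline(recs, outlier_removal = FALSE)
  d <- delta_qindex(qt)
  # +0.2 on every raw metric maps through the shared rescale to a constant
  # positive shift; the median delta reflects it
  expect_gt(median(d$delta), 0.15)
  summ <- distribution_summary(qt)
  expect_equal(summ$summary$frac_improved[summ$summary$variant_id == 1L], 1)
})

test_that("weight sensitivity is null at zero perturbation and bounded", {
  set.seed(33)
  recs <- dplyr::bind_rows(
    make_records(runif(6)),
    make_records(runif(6), variants = rep(1L, 6))
  )
  qt <- qindex_pipeline(recs)
  s0 <- weight_sensitivity(qt, perturbation = 0)
  expect_equal(s0$max_abs_change, 0)
  base <- qt$scores |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(m = median(qindex))
  expect_equal(unique(s0$report$median_qindex[s0$report$variant_id == 0L]),
               base$m[base$variant_id == 0L])

  # all-equal metrics per record are a fixed point of any reweighting
  fx <- global_rescale(make_records(c(0.2, 0.8)), outlier_removal = FALSE)
  fx$scores[, c("uiqm", "uciqe", "ccf", "entropy")] <-
    tibble::tibble(a = c(0.3, 0.6), b = c(0.3, 0.6), c = c(0.3, 0.6),
                   d = c(0.3, 0.6))
  fx <- aggregate_qindex(fx)
  sfx <- weight_sensitivity(fx, 0.25)
  expect_equal(sfx$max_abs_change, 0)

  # two-record table: perturbed qindex equals the hand-computed weighted sum
  m <- c(uiqm = 0.2, uciqe = 0.4, ccf = 0.6, entropy = 0.8)
  hand <- global_rescale(make_records(c(0, 1)), outlier_removal = FALSE)
  hand$scores[1, names(m)] <- as.list(m)
  hand <- aggregate_qindex(hand)
  sh <- weight_sensitivity(hand, 0.25)
  w <- c(0.25 * 1.25, 0.25, 0.25, 0.25); w <- w / sum(w)
  expect_equal(sh$max_abs_change >= 0, TRUE)
  # direct check of one perturbed setting on record 1
  expected <- sum(w * m)
  got <- sh$report[sh$report$metric == "uiqm" & sh$report$direction == "up" &
                     sh$report$variant_id == 0L, ]
  # two records in variant 0: median of the two perturbed values
  other <- sum(w * unlist(hand$scores[2, names(m)]))
  expect_equal(got$median_qindex, median(c(expected, other)))

  expect_error(weight_sensitivity(qt, 1.2), "perturbation")
})

test_that("quality bins follow the left-closed, last-bin-closed convention", {
  qt <- global_rescale(make_records(c(0, 1)), outlier_removal = FALSE)
  qt$scores$qindex <- c(0.55, 1.0)
  qt$weights <- setNames(rep(0.25, 4), c("uiqm", "uciqe", "ccf", "entropy"))
  b <- bin_by_quality(qt, 10)
  expect_equal(b$bins$bin, c(5L, 9L))
  expect_equal(nrow(b$counts), 10L)
  expect_equal(sum(b$counts$n), 2L)
  expect_true(all(b$counts$n[c(1:5, 7:9)] == 0))

  # a uniform grid of 100 values spreads 10 per bin
  qt$scores <- qt$scores[rep(1, 100), ]
  qt$scores$qindex <- (0:99) / 100 + 0.005
  expect_equal(bin_by_quality(qt, 10)$counts$n, rep(10L, 10))
  expect_error(bin_by_quality(qt, 0), "positive")
})

test_that("distribution summary reports medians and improvement fractions", {
  recs <- dplyr::bind_rows(
    make_records(seq(0.1, 0.9, length.out = 8)),
    make_records(seq(0.1, 0.9, length.out = 8), variants = rep(1L, 8))
  )
  qt <- qindex_pipeline(recs, outlier_removal = FALSE)
  # symmetric +-0.1 deltas in equal numbers -> median 0, positive fraction .5
  d <- rep(c(0.1, -0.1), 4)
  qt$scores$qindex[qt$scores$variant_id == 1L] <-
    qt$scores$qindex[qt$scores$variant_id == 0L] + d
  summ <- distribution_summary(qt)
  row <- summ$summary[summ$summary$variant_id == 1L, ]
  expect_equal(row$median_delta, 0)
  expect_equal(row$frac_improved, 0.5)

  # all positive deltas -> fraction 1
  qt$scores$qindex[qt$scores$variant_id == 1L] <-
    qt$scores$qindex[qt$scores$variant_id == 0L] + 0.05
  expect_equal(
    distribution_summary(qt)$summary$frac_improved[
      summ$summary$variant_id == 1L], 1)
})
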