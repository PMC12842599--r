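#' Flag outliers by the 3-scaled-MAD rule
#'
#' A value `x` is an outlier when `|x - median| > 3 * 1.4826 * MAD_raw`,
#' where `MAD_raw = median(|x - median|)` and 1.4826 is the consistency
#' constant that makes the scaled MAD estimate the standard deviation for
#' normal data. The median itself can never be flagged, so at least one
#' value is always kept.
#'
#' @param values Numeric vector of finite values (length >= 1).
#' @param n_mad Multiplier on the scaled MAD (default 3).
#' @return A list with `kept` (the retained values) and `removed_mask`
#'   (logical, aligned with the input, `TRUE` where removed).
#' @examples
#' remove_outliers(c(1, 2, 3, 4, 100))$kept
#' @export
remove_outliers <- function(values, n_mad = 3) {
  if (length(values) < 1L) stop("`values` must be non-empty", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  med <- median(values)
  mad_scaled <- 1.4826 * median(abs(values - med))
  mask <- abs(values - med) > n_mad * mad_scaled
  list(kept = values[!mask], removed_mask = mask)
}

quality_metrics <- c("uiqm", "uciqe", "ccf", "entropy")

as_quality_records <- function(records) {
  if (inherits(records, "iqa_collection")) records <- records$records
  records <- tibble::as_tibble(records)
  missing <- setdiff(c("image_id", "variant_id", quality_metrics), names(records))
  if (length(missing) > 0L) {
    stop("quality records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records
}

#' Globally rescale quality metrics to \[0, 1\]
#'
#' Step 1 and 2 of the composite-index construction: per metric, outliers
#' are flagged over the pooled values of all variants (original included) by
#' the 3-scaled-MAD rule, then the surviving values set the min-max bounds
#' and every kept value is rescaled as `(x - min) / (max - min)`. A record
#' that loses any metric to the outlier filter is dropped from the rescaled
#' table and listed in `excluded`.
#'
#' @param records Quality records: a data frame with columns `image_id`,
#'   `variant_id` and the four metrics `uiqm`, `uciqe`, `ccf`, `entropy`
#'   (an `iqa_collection` is accepted directly).
#' @param outlier_removal Set `FALSE` to skip the outlier filter.
#' @return A `qindex_table`: list with `scores` (rescaled metrics, `qindex`
#'   column `NA` until [aggregate_qindex()]), `bounds` (per-metric min/max
#'   actually used), `excluded` (tibble of `image_id`, `variant_id`,
#'   `metric` dropped as outliers) and `weights` (`NULL` until aggregation).
#' @export
global_rescale <- function(records, outlier_removal = TRUE) {
  records <- as_quality_records(records)

  excluded <- tibble::tibble(image_id = character(), variant_id = integer(),
                             metric = character())
  bounds <- list()
  rescaled <- records
  for (m in quality_metrics) {
    v <- records[[m]]
    mask <- if (outlier_removal) remove_outliers(v)$removed_mask
            else rep(FALSE, length(v))
    kept <- v[!mask]
    if (length(kept) < 2L) {
      stop("fewer than 2 values left for metric '", m, "' after outlier removal",
           call. = FALSE)
    }
    lo <- min(kept); hi <- max(kept)
    if (hi <= lo) {
      stop("degenerate scale for metric '", m, "': min equals max (", lo, ")",
           call. = FALSE)
    }
    bounds[[m]] <- c(min = lo, max = hi)
    rescaled[[m]] <- (v - lo) / (hi - lo)
    rescaled[[m]][mask] <- NA_real_
    if (any(mask)) {
      excluded <- dplyr::bind_rows(excluded, tibble::tibble(
        image_id = as.character(records$image_id[mask]),
        variant_id = as.integer(records$variant_id[mask]),
        metric = m
      ))
    }
  }

  complete <- stats::complete.cases(rescaled[quality_metrics])
  scores <- rescaled[complete, , drop = FALSE]
  scores$qindex <- NA_real_

  structure(
    list(scores = tibble::as_tibble(scores),
         bounds = dplyr::bind_rows(purrr::imap(
           bounds, ~tibble::tibble(metric = .y, min = .x[["min"]], max = .x[["max"]]))),
         excluded = excluded,
         weights = NULL),
    class = "qindex_table"
  )
}

#' Aggregate rescaled metrics into the composite quality index
#'
#' Step 3: the per-record index is the weighted mean of the four rescaled
#' metrics, `qindex = sum(w_m * metric_m)`. Weights must be nonnegative and
#' are normalised internally to sum to 1; the default is equal weighting,
#' which avoids bias toward any individual metric.
#'
#' @param table A `qindex_table` from [global_rescale()].
#' @param weights Four nonnegative weights, in the order `uiqm`, `uciqe`,
#'   `ccf`, `entropy`.
#' @return The `qindex_table` with the `qindex` column filled and `weights`
#'   recorded.
#' @export
aggregate_qindex <- function(table, weights = rep(0.25, 4)) {
  stopifnot(inherits(table, "qindex_table"))
  if (length(weights) != 4L || anyNA(weights)) {
    stop("`weights` must be four finite numbers", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  w <- weights / sum(weights)
  m <- as.matrix(table$scores[quality_metrics])
  table$scores$qindex <- as.vector(m %*% w)
  table$weights <- setNames(w, quality_metrics)
  table
}

#' Run the full composite-index construction
#'
#' Convenience wrapper chaining [global_rescale()] (3-scaled-MAD outlier
#' removal, then global min-max rescaling pooled over all variants) and
#' [aggregate_qindex()] (weighted aggregation, equal weights by default).
#'
#' @inheritParams global_rescale
#' @inheritParams aggregate_qindex
#' @return A `qindex_table` with `qindex` in `[0, 1]` per record.
#' @examples
#' recs <- tibble::tibble(
#'   image_id = rep(sprintf("im%02d", 1:5), 2),
#'   variant_id = rep(0:1, each = 5),
#'   uiqm = runif(10), uciqe = runif(10), ccf = runif(10), entropy = runif(10, 0, 8)
#' )
#' qt <- qindex_pipeline(recs)
#' range(qt$scores$qindex)
#' @export
qindex_pipeline <- function(records, weights = rep(0.25, 4),
                            outlier_removal = TRUE) {
  records |>
    global_rescale(outlier_removal = outlier_removal) |>
    aggregate_qindex(weights = weights)
}

#' @export
print.qindex_table <- function(x, ...) {
  cat(sprintf("<qindex_table: %d records, %d variants, %d excluded values>\n",
              nrow(x$scores), dplyr::n_distinct(x$scores$variant_id),
              nrow(x$excluded)))
  invisible(x)
}

#' @rdname qindex_pipeline
#' @param x A `qindex_table`.
#' @param ... Unused.
#' @export
tidy.qindex_table <- function(x, ...) x$scores

#' @rdname qindex_pipeline
#' @export
glance.qindex_table <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$scores),
    n_variants = dplyr::n_distinct(x$scores$variant_id),
    n_excluded = nrow(x$excluded),
    qindex_mean = mean(x$scores$qindex),
    qindex_min = min(x$scores$qindex),
    qindex_max = max(x$scores$qindex)
  )
}

#' Per-image change in the composite index after enhancement
#'
#' For every enhanced record, the difference between its index and the
#' index of the original variant of the same image:
#' `delta = qindex(variant) - qindex(original)`.
#'
#' @param table A `qindex_table` with `qindex` computed.
#' @return A tibble with `image_id`, `variant_id` (>= 1), `qindex`,
#'   `qindex_original` and `delta` in `[-1, 1]`.
#' @export
delta_qindex <- function(table) {
  stopifnot(inherits(table, "qindex_table"))
  scores <- table$scores
  if (anyNA(scores$qindex)) stop("run aggregate_qindex() first", call. = FALSE)
  originals <- scores |>
    dplyr::filter(.data$variant_id == 0L) |>
    dplyr::select("image_id", qindex_original = "qindex")
  enhanced <- dplyr::filter(scores, .data$variant_id >= 1L)
  orphans <- setdiff(enhanced$image_id, originals$image_id)
  if (length(orphans) > 0L) {
    # an original lost to the outlier filter is recorded in `excluded`;
    # its enhanced records simply have no delta. Anything else is a
    # missing baseline in the input.
    excluded_orig <- unique(table$excluded$image_id[table$excluded$variant_id == 0L])
    unknown <- setdiff(orphans, excluded_orig)
    if (length(unknown) > 0L) {
      stop("no original (variant 0) record for image(s): ",
           paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)
    }
    message(length(orphans),
            " image(s) dropped from deltas: original excluded as outlier")
  }
  enhanced |>
    dplyr::inner_join(originals, by = "image_id") |>
    dplyr::mutate(delta = .data$qindex - .data$qindex_original) |>
    dplyr::select("image_id", "variant_id", "qindex", "qindex_original", "delta")
}

#' Sensitivity of the composite index to single-metric weight changes
#'
#' Scales each metric's weight by `(1 - perturbation)` and `(1 +
#' perturbation)` in turn (renormalising the four weights to sum to 1),
#' recomputes the index, and summarises each perturbed setting by the
#' per-variant median index and median delta against the original variant.
#' The default perturbation of 0.25 probes a +/-25% band around equal
#' weighting.
#'
#' @param table A `qindex_table` with `qindex` computed.
#' @param perturbation Fractional weight change, in `[0, 1)`.
#' @return A list with `report` (tibble: `metric`, `direction`,
#'   `variant_id`, `median_qindex`, `median_delta`) and `max_abs_change`,
#'   the largest absolute change of any record's index across all
#'   perturbed settings relative to the baseline weights.
#' @export
weight_sensitivity <- function(table, perturbation = 0.25) {
  stopifnot(inherits(table, "qindex_table"))
  if (anyNA(table$scores$qindex)) stop("run aggregate_qindex() first", call. = FALSE)
  if (!is.numeric(perturbation) || length(perturbation) != 1L ||
      perturbation < 0 || perturbation >= 1) {
    stop("`perturbation` must be a single number in [0, 1)", call. = FALSE)
  }
  base_w <- table$weights %||% setNames(rep(0.25, 4), quality_metrics)
  m <- as.matrix(table$scores[quality_metrics])

  variant_summary <- function(q) {
    scratch <- table
    scratch$scores$qindex <- q
    d <- if (any(table$scores$variant_id == 0L) &&
             any(table$scores$variant_id >= 1L)) delta_qindex(scratch) else NULL
    out <- table$scores |>
      dplyr::mutate(q = q) |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::summarise(median_qindex = median(.data$q), .groups = "drop")
    if (!is.null(d)) {
      med_d <- d |>
        dplyr::group_by(.data$variant_id) |>
        dplyr::summarise(median_delta = median(.data$delta), .groups = "drop")
      out <- dplyr::left_join(out, med_d, by = "variant_id")
    } else {
      out$median_delta <- NA_real_
    }
    out
  }

  settings <- tidyr::expand_grid(metric = quality_metrics,
                                 direction = c("down", "up"))
  max_change <- 0
  baseline_q <- as.vector(m %*% base_w)
  report <- purrr::pmap(settings, function(metric, direction) {
    w <- base_w
    w[metric] <- w[metric] * (1 + ifelse(direction == "up", 1, -1) * perturbation)
    w <- w / sum(w)
    q <- as.vector(m %*% w)
    max_change <<- max(max_change, max(abs(q - baseline_q)))
    variant_summary(q) |>
      dplyr::mutate(metric = metric, direction = direction, .before = 1L)
  }) |> dplyr::bind_rows()

  list(report = report, max_abs_change = max_change)
}

#' Assign records to equal-width quality bins
#'
#' Partitions `[0, 1]` into `n_bins` equal-width intervals, left-closed and
#' right-open except for the last bin, which is right-closed so an index of
#' exactly 1 lands in the top bin. Bin indices are 0-based (bin `k` covers
#' `[k/n, (k+1)/n)`), and empty bins are reported with a zero count.
#'
#' @param table A `qindex_table` with `qindex` computed.
#' @param n_bins Number of bins (default 10).
#' @return A list with `bins` (per-record: `image_id`, `variant_id`,
#'   `qindex`, `bin`) and `counts` (per bin: `bin`, `lower`, `upper`, `n`,
#'   empty bins included).
#' @export
bin_by_quality <- function(table, n_bins = 10L) {
  stopifnot(inherits(table, "qindex_table"))
  if (!is.numeric(n_bins) || n_bins < 1L) {
    stop("`n_bins` must be a positive integer", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  q <- table$scores$qindex
  if (anyNA(q)) stop("run aggregate_qindex() first", call. = FALSE)
  bin <- pmin(floor(q * n_bins), n_bins - 1L)
  bins <- table$scores |>
    dplyr::select("image_id", "variant_id", "qindex") |>
    dplyr::mutate(bin = as.integer(bin))
  counts <- tibble::tibble(
    bin = 0:(n_bins - 1L),
    lower = (0:(n_bins - 1L)) / n_bins,
    upper = (1:n_bins) / n_bins
  ) |>
    dplyr::left_join(dplyr::count(bins, .data$bin), by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  list(bins = bins, counts = counts)
}

#' Per-variant summary of the quality distribution
#'
#' Summarises, for each variant, the distribution of the composite index
#' and of its per-image change against the original: median, quartiles and
#' the fraction of images whose index improved. The raw per-record values
#' are returned alongside so violin-style plots can be drawn from the same
#' object.
#'
#' @param table A `qindex_table` with `qindex` computed.
#' @return A list with `summary` (per variant: `variant_id`, `n`,
#'   `median_qindex`, `q25`, `q75`, `median_delta`, `frac_improved`) and
#'   `deltas` (the [delta_qindex()] tibble; empty when only the original
#'   variant is present).
#' @export
distribution_summary <- function(table) {
  stopifnot(inherits(table, "qindex_table"))
  scores <- table$scores
  if (anyNA(scores$qindex)) stop("run aggregate_qindex() first", call. = FALSE)
  has_deltas <- any(scores$variant_id == 0L) && any(scores$variant_id >= 1L)
  deltas <- if (has_deltas) delta_qindex(table) else
    tibble::tibble(image_id = character(), variant_id = integer(),
                   qindex = double(), qindex_original = double(), delta = double())
  summary <- scores |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_qindex = median(.data$qindex),
      q25 = quantile(.data$qindex, 0.25, names = FALSE),
      q75 = quantile(.data$qindex, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      deltas |>
        dplyr::group_by(.data$variant_id) |>
        dplyr::summarise(median_delta = median(.data$delta),
                         frac_improved = mean(.data$delta > 0), .groups = "drop"),
      by = "variant_id"
    )
  list(summary = summary, deltas = deltas)
}

#' Violin plot of the quality distribution per variant
#'
#' Shows the composite-index distribution of the original variant and the
#' per-image change distribution of each enhanced variant, mirroring the
#' usual violin presentation of enhancement effects.
#'
#' @param object A `qindex_table` with `qindex` computed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qindex_table <- function(object, ...) {
  scores <- object$scores
  has_deltas <- any(scores$variant_id == 0L) && any(scores$variant_id >= 1L)
  if (has_deltas) {
    d <- delta_qindex(object)
    ggplot2::ggplot(d, ggplot2::aes(
      x = factor(.data$variant_id), y = .data$delta)) +
      ggplot2::geom_violin(fill = "steelblue", alpha = 0.6) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "variant", y = "change in quality index")
  } else {
    ggplot2::ggplot(scores, ggplot2::aes(
      x = factor(.data$variant_id), y = .data$qindex)) +
      ggplot2::geom_violin(fill = "steelblue", alpha = 0.6) +
      ggplot2::labs(x = "variant", y = "quality index")
  }
}
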