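#' Read a run configuration from YAML
#'
#' A run config names the inputs and parameters of a full evaluation:
#' `image_root` (directory of per-variant image folders), `original`
#' (name of the unenhanced variant folder), `ground_truth` (COCO
#' annotation JSON), `variants` (list of `name` / `variant_id` /
#' `detections` entries), `weights` (four aggregation weights), `n_bins`,
#' `interpolation` (`coco101` or `trapezoid`), `out_dir` and `seed`.
#' Missing entries fall back to the documented defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(list(weights = rep(0.25, 4), n_bins = 10L,
                         interpolation = "coco101", seed = 1L,
                         original = "original"),
                    cfg)
}

#' Run the image-quality half of the pipeline
#'
#' Scores every image of every variant with the four quality metrics,
#' builds the composite index (outlier removal, global rescaling,
#' weighted aggregation), computes per-image deltas, the weight
#' sensitivity report and the quality bins, and writes all artifacts as
#' CSV/JSON under `out_dir`.
#'
#' @param config A list (or YAML path, read via [read_run_config()]) with
#'   at least `image_root`; alternatively supply `quality_records` (a
#'   data frame of precomputed metric values) to skip image scoring.
#' @return Invisibly, a list with `collection` (or `NULL`), `qindex`
#'   (`qindex_table`), `deltas`, `sensitivity`, `bins` and `paths` of the
#'   written files.
#' @export
run_quality <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$quality_records)) {
    collection <- NULL
    records <- tibble::as_tibble(config$quality_records)
  } else {
    collection <- score_directory(config$image_root,
                                  original = config$original %||% "original")
    records <- collection$records
    if (nrow(collection$errors) > 0L) {
      message(nrow(collection$errors), " image(s) failed to score")
    }
  }

  qt <- qindex_pipeline(records, weights = config$weights %||% rep(0.25, 4))
  message("outliers removed per metric: ",
          paste(sprintf("%s=%d", quality_metrics,
                        vapply(quality_metrics,
                               function(m) sum(qt$excluded$metric == m),
                               integer(1))),
                collapse = ", "))
  multi <- any(qt$scores$variant_id >= 1L) && any(qt$scores$variant_id == 0L)
  deltas <- if (multi) delta_qindex(qt) else
    tibble::tibble(image_id = character(), variant_id = integer(),
                   qindex = double(), qindex_original = double(), delta = double())
  sens <- weight_sensitivity(qt, perturbation = 0.25)
  bins <- bin_by_quality(qt, n_bins = config$n_bins %||% 10L)

  paths <- list(
    quality = file.path(out_dir, "quality.csv"),
    quality_summary = file.path(out_dir, "quality_summary.csv"),
    qindex = file.path(out_dir, "qindex.csv"),
    delta = file.path(out_dir, "delta_qindex.csv"),
    sensitivity = file.path(out_dir, "sensitivity.json"),
    bins = file.path(out_dir, "bins.csv")
  )
  utils::write.csv(records, paths$quality, row.names = FALSE)
  if (!is.null(collection)) {
    utils::write.csv(collection$summary, paths$quality_summary, row.names = FALSE)
  }
  utils::write.csv(qt$scores, paths$qindex, row.names = FALSE)
  utils::write.csv(deltas, paths$delta, row.names = FALSE)
  jsonlite::write_json(list(max_abs_change = sens$max_abs_change,
                            report = sens$report),
                       paths$sensitivity, auto_unbox = TRUE, digits = NA)
  utils::write.csv(bins$bins, paths$bins, row.names = FALSE)

  invisible(list(collection = collection, qindex = qt, deltas = deltas,
                 sensitivity = sens, bins = bins, paths = paths))
}

#' Run the detection half of the pipeline
#'
#' Reads the ground truth and the per-variant detection files (or takes
#' in-memory tables), computes the per-image score matrix, the mixed-set
#' selection, the set comparison table and the composition statistics,
#' and writes them under `out_dir`.
#'
#' @param config A list (or YAML path) with `ground_truth` and `variants`
#'   (each `name` / `variant_id` / `detections` path), or in-memory `gt`
#'   (a `gt_set`) and `detections` (tibble with `variant_id`).
#' @return Invisibly, a list with `matrix` (`uw_score_matrix`),
#'   `selection` (`mixed_selection`), `comparison`, `composition` and
#'   `paths`.
#' @export
run_detection_eval <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$gt)) {
    gt <- config$gt
    dets <- tibble::as_tibble(config$detections)
  } else {
    gt <- read_ground_truth(config$ground_truth)
    dets <- purrr::map(config$variants, function(v) {
      read_detections(v$detections, v$variant_id, gt = gt)
    }) |> dplyr::bind_rows()
  }

  sm <- score_matrix(dets, gt,
                     interpolation = config$interpolation %||% "coco101")
  sel <- build_mixed_set(sm)
  comp <- compare_sets(sm, sel)
  stats <- composition_stats(sel)

  paths <- list(
    scores = file.path(out_dir, "per_image_scores.csv"),
    selection = file.path(out_dir, "mixed_selection.csv"),
    comparison = file.path(out_dir, "set_comparison.csv"),
    composition = file.path(out_dir, "composition.json")
  )
  utils::write.csv(sm$scores, paths$scores, row.names = FALSE)
  utils::write.csv(sel$selections, paths$selection, row.names = FALSE)
  utils::write.csv(comp$table, paths$comparison, row.names = FALSE)
  jsonlite::write_json(
    list(fractions = stats$fractions,
         original_plurality = stats$original_plurality,
         mixed_mean = sel$mixed_mean,
         relative_improvement_pct = comp$relative_improvement_pct),
    paths$composition, auto_unbox = TRUE, digits = NA)

  invisible(list(matrix = sm, selection = sel, comparison = comp,
                 composition = stats, paths = paths))
}

#' Pair quality scores with detection outcomes
#'
#' Joins the composite-index table with the per-image score matrix on
#' (image, variant) and reports: per-variant means (mean index vs. mean
#' per-image mAP), per-image pairs (index, per-image mAP, and for
#' enhanced variants the change in both against the original), Pearson
#' and Spearman correlations (descriptive; `NA` with a warning when a
#' side is constant), and the frequency of detection improvement
#' stratified by the original image's quality bin.
#'
#' @param qindex_table A `qindex_table` with `qindex` computed.
#' @param matrix A `uw_score_matrix` over the same images/variants.
#' @param n_bins Number of quality bins for the stratified summary.
#' @return A list with `per_variant`, `per_image`, `correlations` and
#'   `by_bin` tibbles.
#' @export
quality_detection_pairs <- function(qindex_table, matrix, n_bins = 10L) {
  stopifnot(inherits(qindex_table, "qindex_table"),
            inherits(matrix, "uw_score_matrix"))
  q <- qindex_table$scores[c("image_id", "variant_id", "qindex")]
  s <- matrix$scores[matrix$scores$defined,
                     c("image_id", "variant_id", "map5095")]
  joined <- dplyr::inner_join(q, s, by = c("image_id", "variant_id"))
  if (nrow(joined) == 0L) {
    stop("quality table and score matrix share no (image, variant) keys",
         call. = FALSE)
  }

  per_variant <- joined |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(mean_qindex = mean(.data$qindex),
                     mean_map5095 = mean(.data$map5095),
                     n = dplyr::n(), .groups = "drop")

  originals <- joined |>
    dplyr::filter(.data$variant_id == 0L) |>
    dplyr::select("image_id", qindex_original = "qindex",
                  map_original = "map5095")
  per_image <- joined |>
    dplyr::left_join(originals, by = "image_id") |>
    dplyr::mutate(delta_qindex = .data$qindex - .data$qindex_original,
                  delta_map = .data$map5095 - .data$map_original)

  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("degenerate variance; ", method, " correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y, method = method)
  }
  correlations <- tibble::tibble(
    level = c("per_image", "per_image", "per_variant", "per_variant"),
    method = rep(c("pearson", "spearman"), 2),
    estimate = c(
      safe_cor(joined$qindex, joined$map5095, "pearson"),
      safe_cor(joined$qindex, joined$map5095, "spearman"),
      safe_cor(per_variant$mean_qindex, per_variant$mean_map5095, "pearson"),
      safe_cor(per_variant$mean_qindex, per_variant$mean_map5095, "spearman")
    ))

  enhanced <- per_image |>
    dplyr::filter(.data$variant_id >= 1L, !is.na(.data$delta_map))
  by_bin <- enhanced |>
    dplyr::mutate(bin = pmin(floor(.data$qindex_original * n_bins),
                             n_bins - 1L)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     improve_freq = mean(.data$delta_map > 0),
                     mean_delta_map = mean(.data$delta_map),
                     .groups = "drop")

  list(per_variant = per_variant, per_image = per_image,
       correlations = correlations, by_bin = by_bin)
}

#' Scatter plot of per-image quality against detection score
#'
#' @param pairs The result of [quality_detection_pairs()].
#' @return A ggplot object.
#' @export
plot_quality_detection <- function(pairs) {
  ggplot2::ggplot(pairs$per_image, ggplot2::aes(
    x = .data$qindex, y = .data$map5095,
    colour = factor(.data$variant_id))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "quality index", y = "per-image mAP 50:95",
                  colour = "variant")
}
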