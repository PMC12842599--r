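#' Pick the best-scoring variant of one image
#'
#' Argmax over a row of per-image scores indexed by variant (0 = the
#' original). Ties are broken in favour of the original, then the lowest
#' variant index: enhancement is an intervention, so a tie means no
#' intervention.
#'
#' @param scores Numeric vector of per-image mAP values; names (or
#'   `variant_ids`) give the variant ids, defaulting to `0:(V)`.
#' @param variant_ids Optional integer vector of variant ids aligned with
#'   `scores`.
#' @return The selected variant id (integer), or `NA` with a warning when
#'   every score is undefined.
#' @examples
#' select_best_variant(c(0.2, 0.5, 0.4))  # 1
#' select_best_variant(c(0.4, 0.4, 0.3))  # 0 (tie kept original)
#' @export
select_best_variant <- function(scores, variant_ids = NULL) {
  if (is.null(variant_ids)) {
    variant_ids <- if (!is.null(names(scores))) as.integer(names(scores))
                   else seq_along(scores) - 1L
  }
  stopifnot(length(variant_ids) == length(scores))
  ord <- order(variant_ids)
  scores <- scores[ord]; variant_ids <- variant_ids[ord]
  ok <- !is.na(scores)
  if (!any(ok)) {
    warning("all scores undefined; row excluded")
    return(NA_integer_)
  }
  variant_ids[ok][which.max(scores[ok])]
}

#' Build the oracle mixed set from a per-image score matrix
#'
#' For every image, selects the variant (original or enhanced) with the
#' highest per-image mAP; the mixed set is the collection of these
#' selections and its mean per-image mAP is the oracle upper bound for any
#' selective enhancement strategy. Images whose score is undefined for all
#' variants (no ground-truth boxes) are excluded from the set size N.
#'
#' @param matrix A `uw_score_matrix` from [score_matrix()], or a plain
#'   numeric matrix (rows = images, columns = variants; column names taken
#'   as variant ids, else `0:(V)`).
#' @return A `mixed_selection`: list with `selections` (tibble:
#'   `image_id`, `variant_id`, `map5095`), `n`, `mixed_mean`,
#'   `composition` (tibble: `variant_id`, `n`, `fraction`, fractions sum
#'   to 1) and `column_means` (per-variant mean over the same N images).
#' @examples
#' m <- rbind(c(0.5, 0.7), c(0.4, 0.2))
#' build_mixed_set(m)$mixed_mean  # 0.55
#' @export
build_mixed_set <- function(matrix) {
  if (inherits(matrix, "uw_score_matrix")) {
    long <- matrix$scores
    variants <- matrix$variants
  } else {
    matrix <- as.matrix(matrix)
    if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
      stop("empty score matrix", call. = FALSE)
    }
    variants <- if (!is.null(colnames(matrix))) as.integer(colnames(matrix))
                else seq_len(ncol(matrix)) - 1L
    ids <- rownames(matrix) %||% sprintf("img_%04d", seq_len(nrow(matrix)))
    long <- tibble::tibble(
      image_id = rep(ids, times = ncol(matrix)),
      variant_id = rep(variants, each = nrow(matrix)),
      map5095 = as.vector(matrix),
      defined = !is.na(as.vector(matrix))
    )
  }
  if (nrow(long) == 0L) stop("empty score matrix", call. = FALSE)

  picks <- long |>
    dplyr::group_by(.data$image_id) |>
    dplyr::filter(any(.data$defined)) |>
    dplyr::summarise(
      chosen = select_best_variant(
        ifelse(.data$defined, .data$map5095, NA_real_), .data$variant_id),
      .groups = "drop")
  rows <- picks |>
    dplyr::inner_join(long, by = c("image_id", chosen = "variant_id")) |>
    dplyr::select("image_id", variant_id = "chosen", "map5095")
  n_dropped <- dplyr::n_distinct(long$image_id) - nrow(rows)
  if (nrow(rows) == 0L) stop("no image has a defined score", call. = FALSE)
  if (n_dropped > 0L) {
    message(n_dropped, " image(s) excluded: score undefined for every variant")
  }

  composition <- tibble::tibble(variant_id = sort(unique(variants))) |>
    dplyr::left_join(dplyr::count(rows, .data$variant_id), by = "variant_id") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = .data$n / sum(.data$n))

  column_means <- long |>
    dplyr::filter(.data$image_id %in% rows$image_id, .data$defined) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(mean_map = mean(.data$map5095), .groups = "drop")

  structure(list(selections = rows, n = nrow(rows),
                 mixed_mean = mean(rows$map5095),
                 composition = composition,
                 column_means = column_means),
            class = "mixed_selection")
}

#' @export
print.mixed_selection <- function(x, ...) {
  cat(sprintf("<mixed_selection: N = %d, mean per-image mAP = %.4f>\n",
              x$n, x$mixed_mean))
  invisible(x)
}

#' @rdname build_mixed_set
#' @param x A `mixed_selection`.
#' @param ... Unused.
#' @export
tidy.mixed_selection <- function(x, ...) x$selections

#' @rdname build_mixed_set
#' @export
glance.mixed_selection <- function(x, ...) {
  orig <- x$column_means$mean_map[x$column_means$variant_id == 0L]
  tibble::tibble(
    n = x$n,
    mixed_mean = x$mixed_mean,
    original_mean = if (length(orig) == 1L) orig else NA_real_,
    original_fraction = x$composition$fraction[x$composition$variant_id == 0L],
    original_plurality = composition_stats(x)$original_plurality
  )
}

#' Compare the mixed set against the original and single-variant sets
#'
#' Tabulates the mean per-image mAP of the original column, of each
#' single-variant column, and of the mixed set, together with the absolute
#' and relative improvement of the mixed set over the original
#' (`(mixed - original) / original * 100`, also reported rounded to an
#' integer percent). A zero original mean leaves the relative improvement
#' undefined.
#'
#' @param matrix A `uw_score_matrix` or plain score matrix (see
#'   [build_mixed_set()]).
#' @param selection Optional `mixed_selection` already built from the same
#'   matrix (rebuilt when omitted).
#' @return A list with `table` (tibble: `set`, `variant_id`, `mean_map`),
#'   `absolute_improvement`, `relative_improvement_pct` and
#'   `relative_improvement_pct_rounded`.
#' @export
compare_sets <- function(matrix, selection = NULL) {
  selection <- selection %||% build_mixed_set(matrix)
  stopifnot(inherits(selection, "mixed_selection"))
  cm <- selection$column_means
  tab <- dplyr::bind_rows(
    cm |>
      dplyr::mutate(set = ifelse(.data$variant_id == 0L, "original",
                                 paste0("variant_", .data$variant_id))) |>
      dplyr::select("set", "variant_id", mean_map = "mean_map"),
    tibble::tibble(set = "mixed", variant_id = NA_integer_,
                   mean_map = selection$mixed_mean)
  )
  orig <- cm$mean_map[cm$variant_id == 0L]
  if (length(orig) != 1L) {
    abs_imp <- NA_real_; rel <- NA_real_
  } else {
    abs_imp <- selection$mixed_mean - orig
    rel <- if (orig > 0) abs_imp / orig * 100 else NA_real_
  }
  list(table = tab,
       absolute_improvement = abs_imp,
       relative_improvement_pct = rel,
       relative_improvement_pct_rounded = if (is.na(rel)) NA_real_ else round(rel))
}

#' Composition of the mixed set by source variant
#'
#' The fraction of images each variant contributes to the mixed set (the
#' pie-chart quantities), plus whether the original is the plurality
#' source.
#'
#' @param selection A `mixed_selection`, or an integer vector of selected
#'   variant ids.
#' @return A list with `fractions` (tibble: `variant_id`, `n`, `fraction`)
#'   and `original_plurality` (logical).
#' @examples
#' composition_stats(c(0L, 0L, 1L, 2L))
#' @export
composition_stats <- function(selection) {
  fr <- if (inherits(selection, "mixed_selection")) {
    selection$composition
  } else {
    if (length(selection) == 0L) stop("empty selection", call. = FALSE)
    tibble::tibble(variant_id = as.integer(selection)) |>
      dplyr::count(.data$variant_id) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n))
  }
  orig <- fr$fraction[fr$variant_id == 0L]
  orig <- if (length(orig) == 1L) orig else 0
  list(fractions = fr,
       original_plurality = all(orig >= fr$fraction[fr$variant_id != 0L]) &&
         orig > 0)
}

#' Composition plot of the mixed set
#'
#' Bar chart of the fraction of images each variant contributes to the
#' mixed set.
#'
#' @param object A `mixed_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixed_selection <- function(object, ...) {
  ggplot2::ggplot(object$composition, ggplot2::aes(
    x = factor(.data$variant_id), y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "source variant (0 = original)",
                  y = "fraction of mixed set")
}
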