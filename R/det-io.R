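#' Ground-truth and detection tables in the COCO box conventions
#'
#' Boxes follow the COCO convention throughout: `[x, y, w, h]` with the
#' origin at the top-left corner, `x` rightward, `y` downward, pixel units,
#' and strictly positive width and height. No coordinate transformation is
#' applied on I/O.
#'
#' A ground-truth set (`gt_set`) is a list with `annotations` (tibble:
#' `image_id`, `category_id`, `x`, `y`, `w`, `h`), `images` (tibble of all
#' `image_id`s, including those with zero annotations) and `categories`
#' (tibble: `category_id`, `name`). A detection set is a plain tibble with
#' columns `image_id`, `variant_id`, `category_id`, `x`, `y`, `w`, `h`,
#' `score`.
#'
#' @name det_io
NULL

new_gt_set <- function(annotations, images, categories) {
  structure(list(annotations = tibble::as_tibble(annotations),
                 images = tibble::as_tibble(images),
                 categories = tibble::as_tibble(categories)),
            class = "gt_set")
}

#' @export
print.gt_set <- function(x, ...) {
  cat(sprintf("<gt_set: %d images, %d boxes, %d categories>\n",
              nrow(x$images), nrow(x$annotations), nrow(x$categories)))
  invisible(x)
}

validate_box <- function(bbox, where) {
  if (is.null(bbox) || length(bbox) != 4L || anyNA(bbox) ||
      any(!is.finite(unlist(bbox)))) {
    stop("malformed bbox in ", where, ": need 4 finite numbers [x, y, w, h]",
         call. = FALSE)
  }
  bbox <- as.numeric(bbox)
  if (bbox[3] <= 0 || bbox[4] <= 0) {
    stop("non-positive box width/height in ", where, call. = FALSE)
  }
  bbox
}

#' Read COCO-style ground-truth annotations
#'
#' Parses the COCO annotation dialect (`images`, `annotations`,
#' `categories` arrays; `bbox = [x, y, width, height]`). Images with zero
#' annotations are retained with empty entries. Crowd regions are not
#' supported: any annotation with `iscrowd = 1` is rejected.
#'
#' @param path Path to a COCO annotation JSON file.
#' @return A `gt_set` (see [det_io]).
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("images", "annotations", "categories")) {
    if (is.null(doc[[field]])) {
      stop("COCO annotation file lacks the '", field, "' array: ", path,
           call. = FALSE)
    }
  }
  images <- tibble::tibble(
    image_id = purrr::map_chr(doc$images, ~as.character(.x$id))
  )
  if (anyDuplicated(images$image_id)) {
    stop("duplicate image ids in ", path, call. = FALSE)
  }
  categories <- tibble::tibble(
    category_id = purrr::map_int(doc$categories, ~as.integer(.x$id)),
    name = purrr::map_chr(doc$categories, ~as.character(.x$name %||% .x$id))
  )
  annotations <- purrr::imap(doc$annotations, function(a, i) {
    where <- paste0("annotation #", i)
    if (!is.null(a$iscrowd) && as.integer(a$iscrowd) == 1L) {
      stop("crowd annotations (iscrowd = 1) are not supported (", where, ")",
           call. = FALSE)
    }
    bbox <- validate_box(a$bbox, where)
    tibble::tibble(image_id = as.character(a$image_id),
                   category_id = as.integer(a$category_id),
                   x = bbox[1], y = bbox[2], w = bbox[3], h = bbox[4])
  }) |> dplyr::bind_rows()
  if (nrow(annotations) == 0L) {
    annotations <- tibble::tibble(image_id = character(),
                                  category_id = integer(),
                                  x = double(), y = double(),
                                  w = double(), h = double())
  }
  bad_cat <- setdiff(annotations$category_id, categories$category_id)
  if (length(bad_cat) > 0L) {
    stop("annotation category id(s) not in the catalogue: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  bad_img <- setdiff(annotations$image_id, images$image_id)
  if (length(bad_img) > 0L) {
    stop("annotation(s) reference unknown image id(s): ",
         paste(utils::head(bad_img, 10L), collapse = ", "), call. = FALSE)
  }
  new_gt_set(annotations, images, categories)
}

#' Write COCO-style ground-truth annotations
#'
#' @param gt A `gt_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "gt_set"))
  doc <- list(
    images = purrr::map(gt$images$image_id, ~list(id = .x)),
    annotations = purrr::pmap(
      cbind(gt$annotations, ann_id = seq_len(nrow(gt$annotations))),
      function(image_id, category_id, x, y, w, h, ann_id) {
        list(id = ann_id, image_id = image_id, category_id = category_id,
             bbox = c(x, y, w, h), area = w * h, iscrowd = 0L)
      }),
    categories = purrr::pmap(gt$categories, function(category_id, name) {
      list(id = category_id, name = name)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style detection results
#'
#' Parses the COCO results dialect: a JSON array of records
#' `{image_id, category_id, bbox, score}`. Scores must lie in `[0, 1]`.
#' When a ground-truth set is supplied, detections for images absent from
#' it are an error by default (downgradeable to a warning).
#'
#' @param path Path to a COCO results JSON file.
#' @param variant_id Integer variant label stored with every detection
#'   (0 = original imagery, 1..V = enhancer variants).
#' @param gt Optional `gt_set` used to check image-id coverage.
#' @param unknown_images `"error"` (default) or `"warn"` for detections on
#'   images the ground truth does not list.
#' @return A detection tibble (see [det_io]); empty input yields an empty
#'   tibble with the right columns.
#' @export
read_detections <- function(path, variant_id, gt = NULL,
                            unknown_images = c("error", "warn")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  unknown_images <- match.arg(unknown_images)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dets <- purrr::imap(doc, function(d, i) {
    where <- paste0("detection #", i)
    bbox <- validate_box(d$bbox, where)
    score <- as.numeric(d$score)
    if (is.na(score) || score < 0 || score > 1) {
      stop("score outside [0, 1] in ", where, ": ", d$score, call. = FALSE)
    }
    tibble::tibble(image_id = as.character(d$image_id),
                   variant_id = as.integer(variant_id),
                   category_id = as.integer(d$category_id),
                   x = bbox[1], y = bbox[2], w = bbox[3], h = bbox[4],
                   score = score)
  }) |> dplyr::bind_rows()
  if (nrow(dets) == 0L) {
    dets <- tibble::tibble(image_id = character(), variant_id = integer(),
                           category_id = integer(), x = double(), y = double(),
                           w = double(), h = double(), score = double())
  }
  if (!is.null(gt)) {
    unknown <- setdiff(dets$image_id, gt$images$image_id)
    if (length(unknown) > 0L) {
      msg <- paste0("detections reference image id(s) absent from the ground truth: ",
                    paste(utils::head(unknown, 10L), collapse = ", "))
      if (unknown_images == "error") stop(msg, call. = FALSE) else warning(msg)
    }
  }
  dets
}

#' Write COCO-style detection results
#'
#' @param detections A detection tibble (see [det_io]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  detections <- tibble::as_tibble(detections)
  doc <- purrr::pmap(
    detections[c("image_id", "category_id", "x", "y", "w", "h", "score")],
    function(image_id, category_id, x, y, w, h, score) {
      list(image_id = image_id, category_id = category_id,
           bbox = c(x, y, w, h), score = score)
    })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
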