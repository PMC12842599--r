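#' Canonical coefficients of the composite quality metrics
#'
#' Returns the exact coefficient values the package uses for UIQM, UCIQE and
#' CCF, in machine-readable form. The same values ship as
#' `inst/extdata/iqa-coefficients.yaml` so an analysis can audit them without
#' loading the package.
#'
#' @return A nested named list with one entry per metric.
#' @examples
#' iqa_coefficients()$uiqm
#' @export
iqa_coefficients <- function() {
  list(
    uiqm = c(uicm = 0.0282, uism = 0.2953, uiconm = 3.5753),
    uicm = c(mu = -0.0268, sigma = 0.1586, trim = 0.1),
    uciqe = c(sigma_chroma = 0.4680, con_luminance = 0.2745, mu_saturation = 0.2576),
    ccf = c(colorfulness = 0.17593, contrast = 0.61759, clarity = 0.33988),
    block_size = 10,
    luma = c(r = 0.299, g = 0.587, b = 0.114)
  )
}

new_iqa_score <- function(total, components, coefficients) {
  structure(
    list(total = total, components = components, coefficients = coefficients),
    class = "iqa_score"
  )
}

#' @export
print.iqa_score <- function(x, ...) {
  cat(sprintf("<iqa_score total = %.6g>\n", x$total))
  print(x$components)
  invisible(x)
}

# ---- block machinery ---------------------------------------------------

# Per-block min/max over non-overlapping block_size x block_size tiles,
# truncating partial border tiles. Returns list(min =, max =) matrices
# (k1 x k2) or NULL when no full block fits.
block_extrema <- function(mat, block_size) {
  k1 <- nrow(mat) %/% block_size
  k2 <- ncol(mat) %/% block_size
  if (k1 < 1L || k2 < 1L) return(NULL)
  bmin <- matrix(0, k1, k2)
  bmax <- matrix(0, k1, k2)
  for (i in seq_len(k1)) {
    rows <- ((i - 1L) * block_size + 1L):(i * block_size)
    for (j in seq_len(k2)) {
      cols <- ((j - 1L) * block_size + 1L):(j * block_size)
      blk <- mat[rows, cols]
      bmin[i, j] <- min(blk)
      bmax[i, j] <- max(blk)
    }
  }
  list(min = bmin, max = bmax, k1 = k1, k2 = k2)
}

# Enhancement-measure-of-entropy style block contrast:
# (2 / (k1 k2)) * sum log(max/min); blocks with a non-positive extreme
# contribute 0.
eme <- function(mat, block_size) {
  bx <- block_extrema(mat, block_size)
  if (is.null(bx)) {
    stop("image region (", nrow(mat), " x ", ncol(mat), ") smaller than one ",
         block_size, " x ", block_size, " analysis block", call. = FALSE)
  }
  ok <- bx$min > 0 & bx$max > 0
  2 / (bx$k1 * bx$k2) * sum(log(bx$max[ok] / bx$min[ok]))
}

# log-AMEE block contrast on an intensity map: mean over blocks of
# -w * log(w) with Michelson contrast w = (max - min) / (max + min).
log_amee <- function(mat, block_size) {
  bx <- block_extrema(mat, block_size)
  if (is.null(bx)) {
    stop("image region (", nrow(mat), " x ", ncol(mat), ") smaller than one ",
         block_size, " x ", block_size, " analysis block", call. = FALSE)
  }
  w <- (bx$max - bx$min) / (bx$max + bx$min)
  w[!is.finite(w) | w <= 0] <- NA_real_
  terms <- -w * log(w)
  terms[is.na(terms)] <- 0
  sum(terms) / (bx$k1 * bx$k2)
}

# Sobel gradient magnitude on the valid interior ((h-2) x (w-2)).
sobel_magnitude <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  gx <- (mat[ri - 1L, ci + 1L] + 2 * mat[ri, ci + 1L] + mat[ri + 1L, ci + 1L]) -
        (mat[ri - 1L, ci - 1L] + 2 * mat[ri, ci - 1L] + mat[ri + 1L, ci - 1L])
  gy <- (mat[ri + 1L, ci - 1L] + 2 * mat[ri + 1L, ci] + mat[ri + 1L, ci + 1L]) -
        (mat[ri - 1L, ci - 1L] + 2 * mat[ri - 1L, ci] + mat[ri - 1L, ci + 1L])
  sqrt(gx^2 + gy^2)
}

# Asymmetric trimmed mean: drop floor(trim * n) values from each tail.
trimmed_mean <- function(x, trim) {
  x <- sort(x)
  n <- length(x)
  t <- floor(trim * n)
  mean(x[(t + 1L):(n - t)])
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# ---- the four metrics --------------------------------------------------

#' Shannon entropy of the grayscale histogram
#'
#' Information content of an image in bits: the base-2 Shannon entropy of
#' the 256-bin histogram of the luma grayscale (weights 0.299, 0.587, 0.114,
#' rounded to the nearest integer level). Depends on the histogram only, so
#' it is invariant under any permutation of pixel positions.
#'
#' @param image An [rgb_image] (or an array coercible to one).
#' @return Entropy in `[0, 8]` bits.
#' @examples
#' compute_entropy(rgb_image(array(128, dim = c(16, 16, 3))))  # 0 bits
#' @export
compute_entropy <- function(image) {
  image <- assert_rgb_image(image)
  g <- rgb_to_gray(image, round_levels = TRUE)
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(g)
  -sum(p * log2(p))
}

#' Underwater image quality measure (UIQM)
#'
#' Weighted sum of a colorfulness term (UICM), a sharpness term (UISM) and a
#' contrast term (UIConM):
#' \deqn{UIQM = c_1\,UICM + c_2\,UISM + c_3\,UIConM}
#' with the canonical coefficients `c = (0.0282, 0.2953, 3.5753)`.
#'
#' UICM uses the red-green and yellow-blue opponent channels: an
#' asymmetric trimmed mean (10% per tail) of each channel and the second
#' moment about that trimmed mean, combined as
#' `-0.0268 * sqrt(mu_RG^2 + mu_YB^2) + 0.1586 * sqrt(s_RG^2 + s_YB^2)`.
#' UISM applies a Sobel gradient to each channel and measures block
#' contrast of the gradient magnitude (10 x 10 blocks, partial border
#' blocks truncated), combined with luma weights. UIConM is a log-AMEE
#' block contrast of the luma image.
#'
#' @param image An [rgb_image].
#' @param coefficients Named weights for the three components.
#' @param block_size Side of the square analysis blocks (pixels).
#' @return An `iqa_score`: list with `total`, named `components`
#'   (`uicm`, `uism`, `uiconm`) and the `coefficients` used.
#' @export
compute_uiqm <- function(image,
                         coefficients = iqa_coefficients()$uiqm,
                         block_size = 10L) {
  image <- assert_rgb_image(image)
  stopifnot(length(coefficients) == 3L)
  co <- iqa_coefficients()

  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  rg <- as.vector(r - g)
  yb <- as.vector((r + g) / 2 - b)
  trim <- unname(co$uicm["trim"])
  mu_rg <- trimmed_mean(rg, trim); mu_yb <- trimmed_mean(yb, trim)
  s2_rg <- mean((rg - mu_rg)^2);   s2_yb <- mean((yb - mu_yb)^2)
  uicm <- unname(co$uicm["mu"]) * sqrt(mu_rg^2 + mu_yb^2) +
          unname(co$uicm["sigma"]) * sqrt(s2_rg + s2_yb)

  lw <- co$luma
  uism <- unname(lw["r"]) * eme(sobel_magnitude(r), block_size) +
          unname(lw["g"]) * eme(sobel_magnitude(g), block_size) +
          unname(lw["b"]) * eme(sobel_magnitude(b), block_size)

  uiconm <- log_amee(rgb_to_gray(image), block_size)

  comps <- c(uicm = uicm, uism = uism, uiconm = uiconm)
  new_iqa_score(sum(unname(coefficients) * comps), comps, coefficients)
}

#' Underwater color image quality evaluation (UCIQE)
#'
#' Linear combination of the chroma standard deviation, the luminance
#' contrast, and the mean saturation, computed in CIELab (sRGB in, D65):
#' \deqn{UCIQE = c_1\,\sigma_c + c_2\,con_l + c_3\,\mu_s}
#' with coefficients `(0.4680, 0.2745, 0.2576)`. Chroma is
#' `sqrt(a^2 + b^2)`; `sigma_c` is its population standard deviation
#' divided by 100, `con_l` the difference between the 99th and 1st
#' percentile of `L` divided by 100, and `mu_s` the mean of the
#' saturation `C / sqrt(C^2 + L^2)` (0 where both vanish).
#'
#' @inheritParams compute_uiqm
#' @return An `iqa_score` with components `sigma_chroma`,
#'   `con_luminance`, `mu_saturation`.
#' @export
compute_uciqe <- function(image, coefficients = iqa_coefficients()$uciqe) {
  image <- assert_rgb_image(image)
  stopifnot(length(coefficients) == 3L)
  srgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3])) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  L <- lab[, 1]
  chroma <- sqrt(lab[, 2]^2 + lab[, 3]^2)
  sigma_c <- pop_sd(chroma) / 100
  q <- stats::quantile(L, c(0.01, 0.99), names = FALSE, type = 7)
  con_l <- (q[2] - q[1]) / 100
  denom <- sqrt(chroma^2 + L^2)
  sat <- ifelse(denom > 0, chroma / denom, 0)
  mu_s <- mean(sat)

  comps <- c(sigma_chroma = sigma_c, con_luminance = con_l, mu_saturation = mu_s)
  new_iqa_score(sum(unname(coefficients) * comps), comps, coefficients)
}

#' Colorfulness-contrast-fog composite (CCF)
#'
#' Weighted combination of a colorfulness index, a global luminance
#' contrast, and a clarity (inverse fog density) term:
#' \deqn{CCF = w_1\,CF + w_2\,contrast + w_3\,clarity}
#' with weights `(0.17593, 0.61759, 0.33988)`. Colorfulness is the
#' opponent-channel statistic `sqrt(s_rg^2 + s_yb^2) +
#' 0.3 sqrt(mu_rg^2 + mu_yb^2)` divided by 85.59; contrast is the
#' population standard deviation of the luma in `[0, 1]` units; clarity is
#' one minus the mean per-pixel channel minimum (the dark channel at
#' 1 x 1 patch size) over 255, so a dense uniform veil scores near 0.
#'
#' @inheritParams compute_uiqm
#' @param weights Named weights for the three components.
#' @return An `iqa_score` with components `colorfulness`, `contrast`,
#'   `clarity`.
#' @export
compute_ccf <- function(image, weights = iqa_coefficients()$ccf) {
  image <- assert_rgb_image(image)
  stopifnot(length(weights) == 3L)
  r <- as.vector(image[, , 1]); g <- as.vector(image[, , 2])
  b <- as.vector(image[, , 3])
  rg <- r - g
  yb <- (r + g) / 2 - b
  cf <- (sqrt(pop_sd(rg)^2 + pop_sd(yb)^2) +
         0.3 * sqrt(mean(rg)^2 + mean(yb)^2)) / 85.59
  contrast <- pop_sd(rgb_to_gray(image)) / 255
  clarity <- 1 - mean(pmin(r, g, b)) / 255

  comps <- c(colorfulness = cf, contrast = contrast, clarity = clarity)
  new_iqa_score(sum(unname(weights) * comps), comps, weights)
}

# ---- batch scoring -----------------------------------------------------

#' Score a collection of images with all four quality metrics
#'
#' Computes UIQM, UCIQE, CCF and entropy for every (image, variant) pair and
#' summarises each variant by the mean and standard deviation of each metric.
#' Unreadable or invalid entries are collected as record-level errors rather
#' than aborting the batch.
#'
#' @param images A data frame (or tibble) with columns `image_id`,
#'   `variant_id`, and either `image` (a list column of [rgb_image]s) or
#'   `path` (image file paths). An optional `variant_name` column is carried
#'   through.
#' @return An `iqa_collection`: list with `records` (one row per scored
#'   pair: `image_id`, `variant_id`, `uiqm`, `uciqe`, `ccf`, `entropy`),
#'   `summary` (per-variant mean and sd of each metric) and `errors`
#'   (tibble of failed records, possibly empty). [tidy()] returns the
#'   records, [glance()] the per-variant summary.
#' @export
score_collection <- function(images) {
  images <- tibble::as_tibble(images)
  stopifnot(nrow(images) >= 1L,
            all(c("image_id", "variant_id") %in% names(images)))
  if (!"image" %in% names(images) && !"path" %in% names(images)) {
    stop("`images` needs an `image` list column or a `path` column", call. = FALSE)
  }

  scored <- purrr::pmap(images, function(...) {
    row <- list(...)
    tryCatch({
      img <- if (!is.null(row[["image"]])) assert_rgb_image(row[["image"]])
             else read_rgb_image(row[["path"]])
      tibble::tibble(
        image_id = row$image_id, variant_id = row$variant_id,
        variant_name = row[["variant_name"]] %||% as.character(row$variant_id),
        uiqm = compute_uiqm(img)$total, uciqe = compute_uciqe(img)$total,
        ccf = compute_ccf(img)$total, entropy = compute_entropy(img),
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(
        image_id = row$image_id, variant_id = row$variant_id,
        variant_name = row[["variant_name"]] %||% as.character(row$variant_id),
        uiqm = NA_real_, uciqe = NA_real_, ccf = NA_real_, entropy = NA_real_,
        error = conditionMessage(e)
      )
    })
  })
  scored <- dplyr::bind_rows(scored)
  errors <- dplyr::filter(scored, !is.na(.data$error))
  records <- scored |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::select(-"error")

  summary <- records |>
    tidyr::pivot_longer(c("uiqm", "uciqe", "ccf", "entropy"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$variant_id, .data$variant_name, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )

  structure(list(records = records, summary = summary, errors = errors),
            class = "iqa_collection")
}

#' @export
print.iqa_collection <- function(x, ...) {
  cat(sprintf("<iqa_collection: %d records, %d variants, %d errors>\n",
              nrow(x$records), dplyr::n_distinct(x$records$variant_id),
              nrow(x$errors)))
  invisible(x)
}

#' @rdname score_collection
#' @param x An `iqa_collection`.
#' @param ... Unused.
#' @export
tidy.iqa_collection <- function(x, ...) x$records

#' @rdname score_collection
#' @export
glance.iqa_collection <- function(x, ...) x$summary

#' Score a directory tree of image variants
#'
#' Expects the layout `<root>/<variant_name>/<image_id>.<ext>`: one
#' subdirectory per variant holding identically named image files. The
#' directory named by `original` becomes variant 0; the remaining variants
#' are numbered 1..V in the given (or sorted) order.
#'
#' @param root Directory containing one subdirectory per variant.
#' @param original Name of the subdirectory holding the unenhanced images.
#' @param variants Optional character vector restricting / ordering the
#'   enhanced variant directories.
#' @return An `iqa_collection` (see [score_collection()]).
#' @export
score_directory <- function(root, original = "original", variants = NULL) {
  stopifnot(dir.exists(root))
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (!original %in% dirs) {
    stop("no '", original, "' variant directory under ", root, call. = FALSE)
  }
  variants <- variants %||% sort(setdiff(dirs, original))
  plan <- purrr::imap(c(original, variants), function(vn, i) {
    files <- list.files(file.path(root, vn), full.names = TRUE,
                        pattern = "\\.(png|jpg|jpeg|tif|tiff)$", ignore.case = TRUE)
    tibble::tibble(
      image_id = tools::file_path_sans_ext(basename(files)),
      variant_id = i - 1L, variant_name = vn, path = files
    )
  }) |> dplyr::bind_rows()
  if (nrow(plan) == 0L) stop("no image files found under ", root, call. = FALSE)
  score_collection(plan)
}
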