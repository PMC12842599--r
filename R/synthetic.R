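# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic degraded underwater image
#'
#' Builds a smooth textured base image (a seeded mixture of oriented
#' sinusoids per channel), then applies three degradations typical of
#' underwater optics: a per-channel attenuation cast (red absorbed most,
#' blue least), an affine contrast compression toward a veil level
#' (haze), and additive Gaussian noise, clipped to `[0, 255]`. With all
#' strengths zero the base image is returned unchanged; with
#' `haze_strength = 1` every pixel equals the veil level.
#'
#' @param seed Integer seed; the output is bit-identical per seed.
#' @param width,height Image size in pixels (>= 8).
#' @param cast_strength,haze_strength Degradation strengths in `[0, 1]`.
#' @param noise_sigma Standard deviation of the additive noise (intensity
#'   levels, >= 0).
#' @return An [rgb_image].
#' @export
generate_degraded_image <- function(seed, width = 64L, height = 64L,
                                    cast_strength = 0, haze_strength = 0,
                                    noise_sigma = 0) {
  stopifnot(cast_strength >= 0, cast_strength <= 1,
            haze_strength >= 0, haze_strength <= 1, noise_sigma >= 0)
  with_seed(seed, {
    xg <- matrix(rep(seq_len(width), each = height), height, width) / width
    yg <- matrix(rep(seq_len(height), times = width), height, width) / height
    channel <- function() {
      f <- matrix(0, height, width)
      for (k in 1:5) {
        fr <- runif(1, 1.5, 9)
        th <- runif(1, 0, pi)
        ph <- runif(1, 0, 2 * pi)
        amp <- runif(1, 0.3, 1)
        f <- f + amp * sin(2 * pi * fr * (cos(th) * xg + sin(th) * yg) + ph)
      }
      f
    }
    base <- array(0, dim = c(height, width, 3))
    for (c in 1:3) {
      f <- channel()
      base[, , c] <- round(107.5 + 100 * f / max(abs(f)))
    }
    # wavelength-dependent attenuation: red fades first, blue persists
    atten <- c(0.75, 0.35, 0.10) * cast_strength
    veil <- 160
    out <- base
    for (c in 1:3) {
      ch <- base[, , c] * (1 - atten[c])
      out[, , c] <- veil + (1 - haze_strength) * (ch - veil)
    }
    if (noise_sigma > 0) {
      out <- out + rnorm(length(out), 0, noise_sigma)
    }
    rgb_image(round(clamp(out, 0, 255)))
  })
}

#' Configuration of a synthetic detection scenario
#'
#' Encodes the statistical structure the generator emulates:
#' \describe{
#'   \item{quality_law}{Latent original quality `q0` per image is drawn
#'     from a two-component normal mixture (the roughly bimodal quality
#'     distribution of real underwater survey data), clamped to
#'     `[0.02, 0.98]`.}
#'   \item{response_law}{Enhancement shifts quality piecewise-linearly
#'     toward a crossover point: images below it improve
#'     (`improve_slope`), images above it degrade (`degrade_slope`), so
#'     low-quality inputs benefit and high-quality inputs over-enhance.
#'     Each enhancer `v` applies the shift at its own intensity
#'     (`variant_gain[v]`), with per-image response noise.}
#'   \item{detection_law}{Detection behaviour depends on the variant
#'     quality `q`: each ground-truth box is missed with probability
#'     `p_miss(q)` (linear from `miss_at_q0` at `q = 0` to `miss_at_q1`
#'     at `q = 1`, clamped into `[0, 1]`, so endpoints outside the range
#'     give saturation), surviving boxes are localised with Gaussian
#'     jitter of scale `sigma(q)` pixels, and `Poisson(lambda(q))` false
#'     positives are added per image (both laws clamped at 0).
#'     Confidences decrease with the realised jitter.}
#' }
#'
#' @param n_images Number of annotated images.
#' @param n_variants Number of enhanced variants V (variant 0 is the
#'   original).
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @param width,height Canvas size in pixels.
#' @param quality_law,response_law,detection_law Named lists overriding
#'   individual default parameters (see Details).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_images = 120L, n_variants = 4L, seed = 1L,
                            width = 800L, height = 600L,
                            quality_law = list(), response_law = list(),
                            detection_law = list()) {
  ql <- utils::modifyList(list(
    means = c(0.40, 0.56), sds = c(0.05, 0.06), weights = c(0.35, 0.65)
  ), quality_law)
  rl <- utils::modifyList(list(
    crossover = 0.5, improve_slope = 0.8, degrade_slope = 0.6,
    variant_gain = NULL, response_noise = 0.03
  ), response_law)
  if (is.null(rl$variant_gain)) {
    rl$variant_gain <- if (n_variants > 1L) {
      seq(0.85, 1.0, length.out = n_variants)
    } else 1.0
  }
  # the *_at_q0 / *_at_q1 pairs define straight lines in q; evaluations are
  # clamped into the valid range, so endpoints outside it are allowed and
  # yield saturation (e.g. a miss probability that reaches 0 before q = 1)
  dl <- utils::modifyList(list(
    miss_at_q0 = 1.0, miss_at_q1 = -2 / 3,
    jitter_at_q0 = 12, jitter_at_q1 = -6,
    fp_at_q0 = 1.5, fp_at_q1 = -0.5,
    n_categories = 3L, boxes_per_image = c(1L, 6L),
    box_size = c(20, 150)
  ), detection_law)
  stopifnot(n_images >= 1L, n_variants >= 0L,
            all(ql$weights >= 0), sum(ql$weights) > 0,
            all(is.finite(unlist(dl[c("miss_at_q0", "miss_at_q1",
                                      "jitter_at_q0", "jitter_at_q1",
                                      "fp_at_q0", "fp_at_q1")]))))
  structure(list(n_images = as.integer(n_images),
                 n_variants = as.integer(n_variants),
                 seed = as.integer(seed),
                 width = width, height = height,
                 quality_law = ql, response_law = rl, detection_law = dl),
            class = "scenario_config")
}

p_miss_at <- function(q, dl) clamp(dl$miss_at_q0 + (dl$miss_at_q1 - dl$miss_at_q0) * q, 0, 1)
sigma_at <- function(q, dl) pmax(0, dl$jitter_at_q0 + (dl$jitter_at_q1 - dl$jitter_at_q0) * q)
lambda_at <- function(q, dl) pmax(0, dl$fp_at_q0 + (dl$fp_at_q1 - dl$fp_at_q0) * q)

#' Generate a full synthetic detection scenario
#'
#' Draws latent original qualities from the bimodal quality law, derives
#' each variant's quality through the response law, builds ground-truth
#' boxes, and simulates per-variant detection sets through the detection
#' law (misses, localisation jitter, false positives, jitter-dependent
#' confidences). Pseudo quality-metric records (four noisy monotone
#' transforms of the latent quality) are emitted alongside so the
#' composite-index pipeline can be exercised on the same cohort. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A `uw_scenario`: list with `gt` (a `gt_set`), `detections`
#'   (tibble over all variants), `qualities` (tibble: `image_id`,
#'   `variant_id`, `q`), `quality_records` (pseudo-metric tibble for
#'   [qindex_pipeline()]), `oracle` (tibble: `image_id`, `best_variant`,
#'   the variant with the highest latent quality, ties to the original)
#'   and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ql <- config$quality_law; rl <- config$response_law; dl <- config$detection_law
  n <- config$n_images; V <- config$n_variants
  with_seed(config$seed, {
    ids <- sprintf("img_%04d", seq_len(n))

    comp <- sample.int(length(ql$weights), n, replace = TRUE,
                       prob = ql$weights / sum(ql$weights))
    q0 <- clamp(rnorm(n, ql$means[comp], ql$sds[comp]), 0.02, 0.98)

    qualities <- tibble::tibble(image_id = rep(ids, V + 1L),
                                variant_id = rep(0:V, each = n),
                                q = NA_real_)
    qualities$q[qualities$variant_id == 0L] <- q0
    for (v in seq_len(V)) {
      shift <- ifelse(q0 < rl$crossover,
                      rl$improve_slope * (rl$crossover - q0),
                      -rl$degrade_slope * (q0 - rl$crossover))
      qv <- clamp(q0 + rl$variant_gain[v] * shift +
                    rnorm(n, 0, rl$response_noise), 0.02, 0.98)
      qualities$q[qualities$variant_id == v] <- qv
    }

    # ground truth: 1-6 boxes per image, sizes >= 8 px, inside the canvas
    gt_rows <- purrr::map(seq_len(n), function(i) {
      k <- sample(dl$boxes_per_image[1]:dl$boxes_per_image[2], 1L)
      w <- runif(k, dl$box_size[1], dl$box_size[2])
      h <- runif(k, dl$box_size[1], dl$box_size[2])
      tibble::tibble(
        image_id = ids[i],
        category_id = sample.int(dl$n_categories, k, replace = TRUE),
        x = runif(k, 0, config$width - w), y = runif(k, 0, config$height - h),
        w = w, h = h)
    }) |> dplyr::bind_rows()
    gt <- new_gt_set(
      gt_rows,
      tibble::tibble(image_id = ids),
      tibble::tibble(category_id = seq_len(dl$n_categories),
                     name = paste0("class_", seq_len(dl$n_categories))))

    detections <- purrr::map(0:V, function(v) {
      qv <- qualities$q[qualities$variant_id == v]
      purrr::map(seq_len(n), function(i) {
        boxes <- gt_rows[gt_rows$image_id == ids[i], , drop = FALSE]
        p <- p_miss_at(qv[i], dl); s <- sigma_at(qv[i], dl)
        lam <- lambda_at(qv[i], dl)
        hit <- runif(nrow(boxes)) >= p
        tp <- boxes[hit, , drop = FALSE]
        if (nrow(tp) > 0L) {
          jx <- rnorm(nrow(tp), 0, s); jy <- rnorm(nrow(tp), 0, s)
          jw <- rnorm(nrow(tp), 0, s); jh <- rnorm(nrow(tp), 0, s)
          jitter_mag <- sqrt(jx^2 + jy^2 + jw^2 + jh^2)
          tp$x <- tp$x + jx; tp$y <- tp$y + jy
          tp$w <- pmax(4, tp$w + jw); tp$h <- pmax(4, tp$h + jh)
          tp$score <- clamp(0.95 - 0.02 * jitter_mag + rnorm(nrow(tp), 0, 0.02),
                            0.01, 0.99)
        } else {
          tp$score <- double()
        }
        n_fp <- rpois(1L, lam)
        fp <- if (n_fp > 0L) {
          wf <- runif(n_fp, dl$box_size[1], dl$box_size[2])
          hf <- runif(n_fp, dl$box_size[1], dl$box_size[2])
          tibble::tibble(
            image_id = ids[i],
            category_id = sample.int(dl$n_categories, n_fp, replace = TRUE),
            x = runif(n_fp, 0, config$width - wf),
            y = runif(n_fp, 0, config$height - hf),
            w = wf, h = hf, score = runif(n_fp, 0.05, 0.55))
        } else NULL
        dplyr::bind_rows(tp, fp)
      }) |> dplyr::bind_rows() -> dd
      if (nrow(dd) == 0L) {
        tibble::tibble(image_id = character(), variant_id = integer(),
                       category_id = integer(), x = double(), y = double(),
                       w = double(), h = double(), score = double())
      } else {
        dplyr::mutate(dd, variant_id = v, .after = "image_id")
      }
    }) |> dplyr::bind_rows()
    if (nrow(detections) == 0L) {
      detections <- tibble::tibble(image_id = character(), variant_id = integer(),
                                   category_id = integer(), x = double(),
                                   y = double(), w = double(), h = double(),
                                   score = double())
    }

    # pseudo metric records: noisy monotone transforms of the latent quality
    nq <- nrow(qualities)
    quality_records <- tibble::tibble(
      image_id = qualities$image_id,
      variant_id = qualities$variant_id,
      uiqm = -0.5 + 5.5 * qualities$q + rnorm(nq, 0, 0.10),
      uciqe = 0.30 + 0.35 * qualities$q + rnorm(nq, 0, 0.01),
      ccf = 5 + 28 * qualities$q + rnorm(nq, 0, 0.5),
      entropy = clamp(3.5 + 4.2 * qualities$q + rnorm(nq, 0, 0.08), 0, 8))

    oracle <- qualities |>
      dplyr::group_by(.data$image_id) |>
      dplyr::summarise(
        best_variant = select_best_variant(.data$q, .data$variant_id),
        .groups = "drop")

    structure(list(gt = gt, detections = detections, qualities = qualities,
                   quality_records = quality_records, oracle = oracle,
                   config = config),
              class = "uw_scenario")
  })
}

#' @export
print.uw_scenario <- function(x, ...) {
  cat(sprintf("<uw_scenario: %d images, %d variants, %d GT boxes, %d detections>\n",
              x$config$n_images, x$config$n_variants,
              nrow(x$gt$annotations), nrow(x$detections)))
  invisible(x)
}

#' Write a scenario to COCO-style files
#'
#' Emits the ground-truth annotation JSON, one COCO results JSON per
#' variant, the pseudo quality-record CSV, and a YAML manifest mapping
#' variant names to files. The files round-trip through
#' [read_ground_truth()] / [read_detections()].
#'
#' @param scenario A `uw_scenario`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (`gt`, `detections` (named by
#'   variant), `quality`, `manifest`), invisibly.
#' @export
scenario_to_files <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "uw_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt_path <- file.path(out_dir, "ground_truth.json")
  write_ground_truth(scenario$gt, gt_path)
  variants <- 0:scenario$config$n_variants
  det_paths <- setNames(
    file.path(out_dir, sprintf("detections_variant_%d.json", variants)),
    sprintf("variant_%d", variants))
  for (v in variants) {
    write_detections(
      scenario$detections[scenario$detections$variant_id == v, , drop = FALSE],
      det_paths[[sprintf("variant_%d", v)]])
  }
  quality_path <- file.path(out_dir, "quality_records.csv")
  utils::write.csv(scenario$quality_records, quality_path, row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(
    ground_truth = basename(gt_path),
    quality_records = basename(quality_path),
    variants = purrr::imap(as.list(det_paths),
                           ~list(name = .y,
                                 variant_id = as.integer(sub("variant_", "", .y)),
                                 detections = basename(.x)))),
    manifest_path)
  invisible(list(gt = gt_path, detections = det_paths,
                 quality = quality_path, manifest = manifest_path))
}

#' Read a scenario manifest back into memory
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [scenario_to_files()].
#' @return A list with `gt` (a `gt_set`) and `detections` (tibble over all
#'   variants).
#' @export
read_scenario_files <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  gt <- read_ground_truth(file.path(dir, man$ground_truth))
  detections <- purrr::map(man$variants, function(v) {
    read_detections(file.path(dir, v$detections), v$variant_id, gt = gt)
  }) |> dplyr::bind_rows()
  list(gt = gt, detections = detections)
}
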