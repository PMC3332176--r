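# Deterministic generator of dermoscopy-like RGB fixtures with exact
# ground-truth masks: an irregular, darker lesion (ellipse with a low-order
# random Fourier perturbation of its radius, radially graded interior) on a
# lighter skin background with smooth texture, plus optional per-pixel
# Gaussian noise. All randomness flows from one Mersenne-Twister seed, so
# fixtures are reproducible across platforms.

#' Specification of a synthetic lesion fixture
#'
#' @param size Image side in pixels (square image, default 128).
#' @param skin_rgb Skin base color, length-3 in `[0, 255]` (light tan).
#' @param contrast Gap between mean skin and mean lesion gray intensity, in
#'   gray levels (`> 0`).
#' @param noise_sigma Per-pixel, per-channel Gaussian noise scale.
#' @param irregularity Boundary perturbation amplitude as a fraction of the
#'   base radius, in `[0, 0.5]`.
#' @param radius Base lesion radius as a fraction of the image side.
#' @param eccentricity Ellipse axis ratio in `(0, 1]` (1 = circle).
#' @param grade_amp Amplitude of the radial interior shading, gray levels.
#' @param texture_amp Amplitude of the smooth skin texture, gray levels.
#' @param seed Integer seed; the single source of randomness.
#' @return List of class `lesion_spec`.
#' @export
lesion_spec <- function(size = 128L, skin_rgb = c(205, 170, 145),
                        contrast = 60, noise_sigma = 10, irregularity = 0.25,
                        radius = 0.28, eccentricity = 0.8, grade_amp = 8,
                        texture_amp = 4, seed = 0L) {
  stopifnot(size >= 16L, contrast > 0, noise_sigma >= 0,
            irregularity >= 0, irregularity <= 0.5,
            radius > 0, radius < 0.5, eccentricity > 0, eccentricity <= 1,
            length(skin_rgb) == 3L, all(skin_rgb >= 0), all(skin_rgb <= 255))
  structure(list(size = as.integer(size), skin_rgb = as.numeric(skin_rgb),
                 contrast = contrast, noise_sigma = noise_sigma,
                 irregularity = irregularity, radius = radius,
                 eccentricity = eccentricity, grade_amp = grade_amp,
                 texture_amp = texture_amp, seed = as.integer(seed)),
            class = "lesion_spec")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a synthetic lesion image with its ground-truth mask
#'
#' The lesion region is an ellipse whose polar radius is modulated by a
#' low-order random Fourier series (irregular border); the interior is
#' darker than the skin by exactly `contrast` in mean gray intensity (the
#' radial shading and the skin texture are centered within their regions,
#' so they do not move the means); Gaussian noise is added last and values
#' are clipped to `[0, 255]`. The mask is the exact pre-noise region.
#'
#' @param spec A [lesion_spec()].
#' @return List with `image` (`size x size x 3` array in `[0, 255]`),
#'   `mask` (`size x size`, `1` = lesion) and the `spec`.
#' @export
generate_lesion <- function(spec = lesion_spec()) {
  stopifnot(inherits(spec, "lesion_spec"))
  n <- spec$size
  with_local_seed(spec$seed, {
    # lesion geometry
    cx <- 0.5 + stats::runif(1L, -0.08, 0.08)
    cy <- 0.5 + stats::runif(1L, -0.08, 0.08)
    phi <- stats::runif(1L, 0, pi)
    n_harm <- 4L
    amp <- spec$irregularity * stats::runif(n_harm, 0, 1) / seq_len(n_harm)
    pha <- stats::runif(n_harm, 0, 2 * pi)
    xs <- (col(matrix(0, n, n)) - 0.5) / n - cx
    ys <- (row(matrix(0, n, n)) - 0.5) / n - cy
    xr <- cos(phi) * xs + sin(phi) * ys
    yr <- -sin(phi) * xs + cos(phi) * ys
    r <- sqrt(xr^2 + (yr / spec$eccentricity)^2)
    theta <- atan2(yr, xr)
    rb <- spec$radius * (1 + Reduce(`+`, lapply(seq_len(n_harm), function(h)
      amp[h] * cos(h * theta + pha[h]))))
    mask <- (r <= rb) * 1L
    frac <- mean(mask)
    if (frac < 0.05 || frac > 0.6)
      stop("lesion area fraction ", format(frac, digits = 3),
           " outside [0.05, 0.6]; adjust radius/irregularity", call. = FALSE)
    # smooth skin texture, centered per region so region means are exact
    fx <- stats::runif(2L, 1.5, 3.5); fy <- stats::runif(2L, 1.5, 3.5)
    ph2 <- stats::runif(2L, 0, 2 * pi)
    tex <- spec$texture_amp *
      (sin(2 * pi * fx[1L] * (xs + cx) + ph2[1L]) *
         cos(2 * pi * fy[1L] * (ys + cy) + ph2[2L]) +
       0.5 * sin(2 * pi * fx[2L] * (xs + cx) + 2 * pi * fy[2L] * (ys + cy)))
    inside <- mask == 1
    tex[inside] <- tex[inside] - mean(tex[inside])
    tex[!inside] <- tex[!inside] - mean(tex[!inside])
    # radial interior shading (darker core), centered over the lesion
    grade <- matrix(0, n, n)
    grade[inside] <- -spec$grade_amp * (1 - (r[inside] / rb[inside])^2)
    grade[inside] <- grade[inside] - mean(grade[inside])
    base_gray <- tex + grade - spec$contrast * (mask == 1)
    img <- array(0, dim = c(n, n, 3L))
    for (ci in 1:3) img[, , ci] <- spec$skin_rgb[ci] + base_gray
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(3L * n * n, 0, spec$noise_sigma),
                         dim = dim(img))
    img[img < 0] <- 0
    img[img > 255] <- 255
    list(image = img, mask = mask, spec = spec)
  })
}

#' Generate the standard fixture suite
#'
#' A parameter grid of `contrast x noise_sigma` fixtures (defaults: contrast
#' 30, 60, 100 by noise 5, 15, 25 at 128 x 128), each with its own seed
#' derived from `base_seed`. Optionally written to disk as PNG image/mask
#' pairs with parameter-encoding names.
#'
#' @param contrasts,noises Numeric grids.
#' @param base_seed Integer; fixture `i` uses `base_seed + i`.
#' @param size Image side.
#' @param dir Optional output directory (created if needed).
#' @return Invisible list of [generate_lesion()] results, named
#'   `contrast<em>_noise<em>`.
#' @export
generate_lesion_suite <- function(contrasts = c(30, 60, 100),
                                  noises = c(5, 15, 25),
                                  base_seed = 0L, size = 128L, dir = NULL) {
  grid <- expand.grid(contrast = contrasts, noise = noises)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    generate_lesion(lesion_spec(size = size, contrast = grid$contrast[i],
                                noise_sigma = grid$noise[i],
                                seed = base_seed + i))
  })
  names(out) <- sprintf("contrast%g_noise%g", grid$contrast, grid$noise)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      write_image(out[[nm]]$image, file.path(dir, paste0(nm, "_image.png")))
      write_mask(out[[nm]]$mask, file.path(dir, paste0(nm, "_mask.png")))
    }
  }
  invisible(out)
}
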