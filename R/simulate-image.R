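#' Parameters for the synthetic gastruloid image generator
#'
#' Describes an elliptical gastruloid-like body with Gaussian-blob nuclei
#' (DAPI channel) and an optional posterior-polarized reporter gradient.
#' All lengths are in micrometres.
#'
#' @param body_semi_axes numeric length-2, semi-axes `(a, b)` of the body
#'   ellipse in µm, with `a >= b > 0`; the major axis runs left to right.
#' @param pixel_size µm per pixel.
#' @param n_nuclei number of nuclei to place uniformly inside the body.
#' @param nucleus_radius_mean,nucleus_radius_sd mean and SD (µm) of nucleus
#'   radii; the Gaussian blob sigma is radius / 2.
#' @param reporter_polarized if `TRUE` the reporter follows a logistic
#'   gradient along the major axis; if `FALSE` it is flat on the body.
#' @param gradient_midpoint relative axial position in [0, 1] where the
#'   logistic reaches half maximum.
#' @param gradient_steepness dimensionless logistic steepness (> 0).
#' @param noise_sd SD of additive Gaussian intensity noise (clipped at 0).
#' @param seed integer RNG seed; identical params + seed give bit-identical
#'   output.
#' @param dapi_amplitude,reporter_amplitude peak intensities of a nucleus
#'   blob and of the reporter plateau (arbitrary units).
#' @param body_background diffuse DAPI intensity over the whole body,
#'   emulating the dense out-of-focus signal of a projected 3D aggregate
#'   (this is what whole-structure segmentation picks up).
#' @param margin border of background pixels around the body, in µm.
#' @return A list of class `image_sim_params`.
#' @export
image_sim_params <- function(body_semi_axes = c(150, 50), pixel_size = 2,
                             n_nuclei = 150, nucleus_radius_mean = 5,
                             nucleus_radius_sd = 1, reporter_polarized = TRUE,
                             gradient_midpoint = 0.7, gradient_steepness = 20,
                             noise_sd = 10, seed = 1,
                             dapi_amplitude = 600, reporter_amplitude = 1000,
                             body_background = 500, margin = 20) {
  a <- body_semi_axes[1]; b <- body_semi_axes[2]
  if (!(is.numeric(body_semi_axes) && length(body_semi_axes) == 2L && a >= b && b > 0))
    stop("body_semi_axes must satisfy a >= b > 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (n_nuclei < 0) stop("n_nuclei must be >= 0", call. = FALSE)
  if (nucleus_radius_mean <= 0) stop("nucleus_radius_mean must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (gradient_steepness <= 0) stop("gradient_steepness must be > 0", call. = FALSE)
  if (gradient_midpoint < 0 || gradient_midpoint > 1)
    stop("gradient_midpoint must lie in [0, 1]", call. = FALSE)
  structure(list(body_semi_axes = c(a = a, b = b), pixel_size = pixel_size,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 reporter_polarized = isTRUE(reporter_polarized),
                 gradient_midpoint = gradient_midpoint,
                 gradient_steepness = gradient_steepness,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 dapi_amplitude = dapi_amplitude,
                 reporter_amplitude = reporter_amplitude,
                 body_background = body_background, margin = margin),
            class = "image_sim_params")
}

#' Simulate a two-channel gastruloid-like image with ground truth
#'
#' Renders an axis-aligned elliptical body. The DAPI channel is a sum of
#' Gaussian nucleus blobs placed uniformly inside the ellipse; the reporter
#' channel is either a logistic gradient of the relative position along the
#' major axis (posterior-high), or flat, restricted to the body. Additive
#' Gaussian noise (clipped at zero) is applied to both channels last.
#'
#' The RNG is consumed in a documented order: nucleus positions, nucleus
#' radii, DAPI noise, reporter noise — so that identical parameters and seed
#' reproduce the image exactly.
#'
#' @param params an [image_sim_params()] object.
#' @return A list with elements `image` (a [labeled_image()] with channels
#'   `dapi` and `reporter`) and `truth`, a list holding `body_mask` (logical
#'   matrix), `true_area` (µm², \eqn{\pi a b}), `true_feret_max` (= 2a, µm),
#'   `true_feret_min` (= 2b, µm), `nucleus_centers` ((row, col), 0-based px)
#'   and `per_pixel_true_reporter` (noise-free reporter raster).
#' @export
simulate_gastruloid_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  a_px <- p$body_semi_axes["a"] / p$pixel_size
  b_px <- p$body_semi_axes["b"] / p$pixel_size
  m_px <- ceiling(p$margin / p$pixel_size)
  nr <- as.integer(ceiling(2 * b_px) + 2 * m_px)
  nc <- as.integer(ceiling(2 * a_px) + 2 * m_px)
  r0 <- (nr - 1) / 2; c0 <- (nc - 1) / 2
  rr <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  body <- ((cc - c0) / a_px)^2 + ((rr - r0) / b_px)^2 <= 1
  if (2 * b_px < 1 || !any(body))
    stop("body smaller than one pixel at this pixel_size", call. = FALSE)

  out <- with_seed(p$seed, {
    # nuclei: uniform in ellipse as affine image of the uniform unit disk
    n <- p$n_nuclei
    dapi <- matrix(0, nr, nc)
    dapi[body] <- p$body_background
    centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    if (n > 0) {
      ang <- runif(n, 0, 2 * pi)
      rad <- sqrt(runif(n))
      cx <- c0 + rad * cos(ang) * a_px
      cy <- r0 + rad * sin(ang) * b_px
      centers <- cbind(row = cy, col = cx)
      radii <- pmax(rnorm(n, p$nucleus_radius_mean, p$nucleus_radius_sd),
                    p$pixel_size / 2)
      sig <- radii / 2 / p$pixel_size
      for (i in seq_len(n)) {
        w <- ceiling(4 * sig[i])
        ri <- max(0, floor(cy[i]) - w):min(nr - 1, ceiling(cy[i]) + w)
        ci <- max(0, floor(cx[i]) - w):min(nc - 1, ceiling(cx[i]) + w)
        g <- p$dapi_amplitude *
          exp(-outer((ri - cy[i])^2, (ci - cx[i])^2, "+") / (2 * sig[i]^2))
        dapi[ri + 1, ci + 1] <- dapi[ri + 1, ci + 1] + g
      }
    }
    # reporter: relative axial position over the body's major-axis extent
    relpos <- clamp((cc - (c0 - a_px)) / (2 * a_px), 0, 1)
    reporter_true <- if (p$reporter_polarized) {
      p$reporter_amplitude /
        (1 + exp(-p$gradient_steepness * (relpos - p$gradient_midpoint)))
    } else matrix(p$reporter_amplitude, nr, nc)
    reporter_true[!body] <- 0
    dapi_noisy <- dapi
    reporter <- reporter_true
    if (p$noise_sd > 0) {
      dapi_noisy <- pmax(dapi + rnorm(nr * nc, 0, p$noise_sd), 0)
      reporter <- pmax(reporter_true + rnorm(nr * nc, 0, p$noise_sd), 0)
    }
    list(dapi = dapi_noisy, reporter = reporter,
         reporter_true = reporter_true, centers = centers)
  })

  img <- labeled_image(list(dapi = out$dapi, reporter = out$reporter),
                       pixel_size = p$pixel_size,
                       image_id = sprintf("sim_seed%d", p$seed))
  truth <- list(body_mask = body,
                true_area = pi * p$body_semi_axes[["a"]] * p$body_semi_axes[["b"]],
                true_feret_max = 2 * p$body_semi_axes[["a"]],
                true_feret_min = 2 * p$body_semi_axes[["b"]],
                nucleus_centers = out$centers,
                per_pixel_true_reporter = out$reporter_true)
  list(image = img, truth = truth)
}
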