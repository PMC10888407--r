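#' Configuration for the synthetic two-stain cohort generator
#'
#' The generator emulates the statistical structure the separation model
#' assumes: each pixel's OD vector is a non-negative mixture of two fixed
#' stain directions, plus acquisition noise and a near-white background
#' region. Hematoxylin concentrations form Gaussian nuclear blobs; DAB
#' concentrations form a smooth random field whose overall level rises
#' across five cohort tiers, emulating increasing biomarker expression.
#'
#' @param n_images cohort size (default 50).
#' @param n_tiers number of expression tiers (default 5).
#' @param image_size `(height, width)` in pixels (default 64 x 64).
#' @param h_vec,d_vec ground-truth OD unit 3-vectors for hematoxylin and
#'   DAB (defaults: the classical reference directions).
#' @param tier_dab_scale mean DAB concentration per tier, strictly
#'   increasing (default `c(0.05, 0.3, 0.8, 1.5, 2.5)`).
#' @param nucleus_density nuclear blobs per image (default 60, giving the
#'   dense nuclear coverage of a tumor field at x20).
#' @param noise_sd OD-space additive Gaussian noise sd (default 0.02).
#' @param background_fraction fraction of the image covered by an
#'   unstained (near-white) band (default 0.15).
#' @param seed RNG seed making the cohort fully reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_images = 50L, n_tiers = 5L,
                         image_size = c(64L, 64L),
                         h_vec = c(0.650, 0.704, 0.286),
                         d_vec = c(0.269, 0.568, 0.778),
                         tier_dab_scale = c(0.05, 0.3, 0.8, 1.5, 2.5),
                         nucleus_density = 60L, noise_sd = 0.02,
                         background_fraction = 0.15, seed = 1L) {
  h_vec <- h_vec / sqrt(sum(h_vec^2))
  d_vec <- d_vec / sqrt(sum(d_vec^2))
  if (any(h_vec < 0) || any(d_vec < 0)) stop("stain vectors must be non-negative")
  sep_deg <- acos(min(1, sum(h_vec * d_vec))) * 180 / pi
  if (sep_deg < 10) stop("stain vectors must be separated by >= 10 degrees")
  if (length(tier_dab_scale) != n_tiers || any(diff(tier_dab_scale) <= 0)) {
    stop("tier_dab_scale must be strictly increasing with one entry per tier")
  }
  if (n_images < n_tiers) stop("need at least one image per tier")
  structure(
    list(n_images = as.integer(n_images), n_tiers = as.integer(n_tiers),
         image_size = as.integer(image_size), h_vec = h_vec, d_vec = d_vec,
         tier_dab_scale = tier_dab_scale,
         nucleus_density = as.integer(nucleus_density),
         noise_sd = noise_sd, background_fraction = background_fraction,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Bilinear upsampling of a coarse grid to (height, width): the cheap way
# to get a spatially smooth random field.
bilinear_field <- function(coarse, height, width) {
  gy <- nrow(coarse); gx <- ncol(coarse)
  yy <- seq(1, gy, length.out = height)
  xx <- seq(1, gx, length.out = width)
  y0 <- pmin(floor(yy), gy - 1L); x0 <- pmin(floor(xx), gx - 1L)
  fy <- yy - y0; fx <- xx - x0
  a <- coarse[cbind(rep(y0, times = width), rep(x0, each = height))]
  b <- coarse[cbind(rep(y0 + 1, times = width), rep(x0, each = height))]
  cc <- coarse[cbind(rep(y0, times = width), rep(x0 + 1, each = height))]
  d <- coarse[cbind(rep(y0 + 1, times = width), rep(x0 + 1, each = height))]
  wy <- rep(fy, times = width); wx <- rep(fx, each = height)
  matrix((1 - wy) * (1 - wx) * a + wy * (1 - wx) * b +
           (1 - wy) * wx * cc + wy * wx * d, height, width)
}

#' Ground-truth concentration fields for one synthetic image
#'
#' Hematoxylin: a sum of Gaussian nuclear blobs at uniform random centers
#' with lognormal amplitudes; values below 0.2 are floored to zero so
#' that nuclei have the crisp boundaries they show at this magnification
#' rather than faint sub-quantization halos. DAB: a smooth random field
#' (bilinear interpolation of a coarse Gaussian grid) thresholded at zero
#' — so part of the tissue is DAB-free — with its dynamic range
#' compressed onto a stained plateau (real sections vary in expression
#' smoothly but moderately; the tier level, not the within-field range,
#' carries the score). DAB is excluded from nuclear pixels, emulating a
#' cytoplasmic/membrane chromogen displaced by the nucleus; this gives
#' the stain-dominant pixel population the separation method assumes. A
#' contiguous background band on one randomly chosen side has both
#' concentrations zero. The field is normalized so its mean over tissue
#' is 1 before scaling, making `tier_dab_scale` the mean DAB
#' concentration per tissue pixel. Consumes the current RNG stream.
#'
#' @param config a `synth_config`.
#' @param tier tier index (1 = lowest DAB expression).
#' @return 2 x N matrix (row 1 = hematoxylin, row 2 = DAB), with
#'   attribute `background` (logical N-vector).
#' @export
make_concentration_fields <- function(config, tier) {
  h <- config$image_size[1]; w <- config$image_size[2]
  n <- h * w
  row_i <- rep(seq_len(h), times = w)
  col_i <- rep(seq_len(w), each = h)

  # background band on one side
  bg <- rep(FALSE, n)
  if (config$background_fraction > 0) {
    side <- sample(4L, 1L)
    frac <- config$background_fraction
    bg <- switch(side,
      col_i <= w * frac,
      col_i > w * (1 - frac),
      row_i <= h * frac,
      row_i > h * (1 - frac)
    )
  }

  hem <- rep(0, n)
  if (config$nucleus_density > 0) {
    cx <- stats::runif(config$nucleus_density, 1, w)
    cy <- stats::runif(config$nucleus_density, 1, h)
    amp <- stats::rlnorm(config$nucleus_density, meanlog = log(1.5), sdlog = 0.3)
    blob_sd <- 1.5
    for (b in seq_len(config$nucleus_density)) {
      hem <- hem + amp[b] *
        exp(-((col_i - cx[b])^2 + (row_i - cy[b])^2) / (2 * blob_sd^2))
    }
    hem[hem < 0.2] <- 0
  }

  coarse <- matrix(stats::rnorm(64, mean = 1, sd = 1), 8, 8)
  f <- pmax(as.vector(bilinear_field(coarse, h, w)) - 0.3, 0)
  f <- (0.7 + 0.3 * pmin(f, 2)) * (f > 0)   # stained plateau, OD kept unsaturated
  f[hem > 0] <- 0                           # nuclei displace the chromogen
  f[bg] <- 0
  hem[bg] <- 0
  mu <- mean(f[!bg])
  if (is.finite(mu) && mu > 0) f <- f / mu
  dab <- f * config$tier_dab_scale[tier]
  structure(rbind(hem, dab), background = bg)
}

#' Render a synthetic image from ground-truth stains
#'
#' Forward model of the Beer-Lambert mixture: `X = W H` plus OD-space
#' Gaussian noise (clipped at zero), then `I = round(Io * exp(-X))`
#' clipped to `[0, Io]`. Consumes the current RNG stream.
#'
#' @param true_w 3 x 2 stain matrix (columns hematoxylin, DAB).
#' @param true_h 2 x N concentration matrix.
#' @param noise_sd OD noise standard deviation.
#' @param width,height image dimensions.
#' @param io_level maximum intensity (default 255).
#' @return An `rgb_image`.
#' @export
render_image <- function(true_w, true_h, noise_sd, width, height,
                         io_level = 255) {
  x <- true_w %*% true_h
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), sd = noise_sd)
  }
  x <- pmax(x, 0)
  px <- pmin(pmax(round(io_level * exp(-x)), 0), io_level)
  rgb_image(px, width = width, height = height, io_level = io_level)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Images are assigned to tiers round-robin and rendered reproducibly
#' from the config seed.
#'
#' @param config a `synth_config`.
#' @return List of class `synth_cohort`: `images` (named list of
#'   `rgb_image`s), `truth` (tibble: image_id, tier), `true_w` (3 x 2),
#'   `true_h` (list of 2 x N matrices), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  true_w <- cbind(config$h_vec, config$d_vec)
  h <- config$image_size[1]; w <- config$image_size[2]
  tiers <- ((seq_len(config$n_images) - 1L) %% config$n_tiers) + 1L
  ids <- sprintf("synthetic_%03d", seq_len(config$n_images))
  fields <- vector("list", config$n_images)
  images <- vector("list", config$n_images)
  for (i in seq_len(config$n_images)) {
    fields[[i]] <- make_concentration_fields(config, tiers[i])
    images[[i]] <- render_image(true_w, fields[[i]], config$noise_sd,
                                width = w, height = h)
  }
  names(images) <- ids
  structure(
    list(images = images,
         truth = tibble(image_id = ids, tier = tiers),
         true_w = true_w, true_h = fields, config = config),
    class = "synth_cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' Renders each image as a PNG, plus a ground-truth CSV (image_id, tier)
#' and a JSON echo of the true stain matrix and configuration.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$images)) {
    write_rgb_image(cohort$images[[id]], file.path(dir, paste0(id, ".png")))
  }
  write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(
    list(true_w = cohort$true_w,
         config = cfg[setdiff(names(cfg), c("h_vec", "d_vec"))]),
    file.path(dir, "ground_truth.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
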