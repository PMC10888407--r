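# Shared fixtures: small controlled images and separation objects built in
# code, so expected values can be derived by hand.

# flat-colour image: every pixel the same RGB triple
flat_image <- function(rgb, width = 4, height = 3, io_level = 255) {
  rgb_image(matrix(rep(rgb, width * height), nrow = 3),
            width = width, height = height, io_level = io_level)
}

# a noiseless two-stain image with known W and H drawn in code
two_stain_od <- function(n = 400, seed = 1,
                         w = cbind(c(0.650, 0.704, 0.286),
                                   c(0.269, 0.568, 0.778))) {
  set.seed(seed)
  w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
  h <- rbind(ifelse(stats::runif(n) < 0.5, stats::rgamma(n, 2, 2), 0),
             ifelse(stats::runif(n) < 0.5, stats::rgamma(n, 2, 2), 0))
  list(od = w %*% h, w = w, h = h)
}

# hand-built cohort separation object with fully controlled contents, for
# exact feature arithmetic
fake_separation <- function(w_bar, conc_bar, fits = NULL, n_pixels = NULL) {
  n <- length(conc_bar)
  ids <- sprintf("img%02d", seq_len(n))
  if (is.null(n_pixels)) n_pixels <- vapply(conc_bar, ncol, integer(1))
  if (is.null(fits)) {
    fits <- lapply(seq_len(n), function(i) {
      structure(list(basis = w_bar, conc = conc_bar[[i]],
                     degenerate = FALSE, excluded = FALSE,
                     angles = c(0, 1), clip_fraction = 0),
                class = "stain_fit")
    })
  }
  structure(
    list(fits = fits, w_bar = structure(w_bar, class = c("stain_basis", "matrix", "array")),
         conc_bar = conc_bar, ods = NULL, image_ids = ids,
         n_pixels = as.integer(n_pixels),
         summary = tibble::tibble(image_id = ids)),
    class = "ihc_separation"
  )
}

small_synth <- function(n_images = 10, seed = 1, noise_sd = 0.02, ...) {
  synth_config(n_images = n_images, seed = seed, noise_sd = noise_sd,
               image_size = c(48L, 48L), ...)
}

max_basis_error <- function(basis, true_w) {
  max(angle_between(unclass(basis)[, 1], true_w[, 1]),
      angle_between(unclass(basis)[, 2], true_w[, 2]))
}
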