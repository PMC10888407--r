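test_that("uncentered PCA matches an SVD oracle and handles rank deficiency", {
  # rank-1 cloud
  x <- matrix(rep(c(1, 0, 0), 10), nrow = 3)
  p <- uncentered_pca(x)
  expect_equal(p$eigvals, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(p$eigvecs[, 1]), c(1, 0, 0), tolerance = 1e-12)

  # exact rank-2 cloud: third eigenvalue vanishes
  set.seed(4)
  w <- cbind(c(0.6, 0.7, 0.3), c(0.2, 0.5, 0.8))
  x <- w %*% matrix(stats::rgamma(400, 2), nrow = 2)
  p <- uncentered_pca(x)
  expect_lt(p$eigvals[3], 1e-12 * p$eigvals[1])

  # oracle: SVD of X / sqrt(N)
  for (i in 1:20) {
    set.seed(i)
    x <- matrix(stats::rexp(3 * 200), nrow = 3)
    p <- uncentered_pca(x)
    sv <- svd(x / sqrt(ncol(x)))
    expect_equal(p$eigvals, sv$d^2, tolerance = 1e-10)
    for (j in 1:3) {
      expect_equal(abs(sum(p$eigvecs[, j] * sv$u[, j])), 1, tolerance = 1e-8)
    }
    expect_equal(p$eigvecs %*% diag(p$eigvals) %*% t(p$eigvecs),
                 tcrossprod(x) / ncol(x), tolerance = 1e-10)
    expect_true(all(colSums(p$eigvecs) >= 0))
  }
  expect_error(uncentered_pca(matrix(0, 3, 5)), "blank")
})

test_that("unit-power projection has mean-square-one rows and reconstructs rank-2 data", {
  s <- two_stain_od(seed = 2)
  p <- uncentered_pca(s$od)
  z <- project_unit_power(s$od, p)
  expect_equal(rowMeans(z^2), c(1, 1), tolerance = 1e-8)
  recon <- (p$eigvecs[, 1:2] %*% diag(sqrt(p$eigvals[1:2]))) %*% z
  expect_equal(recon, s$od, tolerance = 1e-8, ignore_attr = TRUE)
  # rank-1 cloud is flagged degenerate
  x1 <- outer(c(0.6, 0.7, 0.3), stats::rgamma(50, 2))
  expect_error(project_unit_power(x1, uncentered_pca(x1)), "degenerate")
})

test_that("unit-power scaling widens the angular spread of a narrow wedge", {
  # cloud spanning a 30-degree wedge between two directions
  set.seed(9)
  a <- c(1, 0, 0); b <- c(cos(pi / 6), sin(pi / 6), 0)
  mix <- stats::runif(500)
  x <- outer(a, mix) + outer(b, 1 - mix) + 1e-3 * abs(matrix(stats::rnorm(1500), 3))
  p <- uncentered_pca(x)
  z_power <- project_unit_power(x, p)
  z_plain <- crossprod(p$eigvecs[, 1:2], x)   # unit-norm loadings
  spread <- function(z) diff(range(atan2(z[2, ], z[1, ])))
  expect_gt(spread(z_power), spread(z_plain))
})

test_that("angular profile bins mean norms over the occupied range", {
  # all points at one angle: mass in a single bin, value = mean norm
  th <- 0.2
  z <- rbind(cos(th) * c(1, 3), sin(th) * c(1, 3)) + 0
  z <- cbind(z, 1e-9 * c(cos(1), sin(1)))  # second distinct angle so range > 0
  prof <- angular_profile(z, n_bins = 10)
  expect_equal(max(prof$raw_mean_norm), 2)    # mean of norms 1 and 3
  expect_equal(sum(prof$raw_mean_norm > 0), 2)

  # two clusters: largest bins within one bin width of the true angles
  set.seed(5)
  ang <- c(rep(0.3, 300), rep(1.0, 200)) + stats::rnorm(500, sd = 1e-4)
  r <- stats::rgamma(500, 3)
  z <- rbind(r * cos(ang), r * sin(ang))
  prof <- angular_profile(z, n_bins = 100)
  top2 <- prof$bin_centers[order(prof$raw_mean_norm, decreasing = TRUE)[1:2]]
  wd <- diff(prof$bin_centers[1:2])
  expect_true(any(abs(top2 - 0.3) < wd) && any(abs(top2 - 1.0) < wd))

  expect_error(angular_profile(rbind(c(1, 2), c(1, 2))), "one angle")
})

test_that("profile smoothing is zero-phase with unit DC gain and strong Nyquist rejection", {
  mk <- function(v) structure(list(bin_centers = seq_along(v), raw_mean_norm = v,
                                   smoothed = NULL), class = "angular_profile")
  const <- smooth_profile(mk(rep(3.7, 1000)))
  expect_equal(const$smoothed, rep(3.7, 1000), tolerance = 1e-4)

  nyq <- smooth_profile(mk(rep(c(1, -1), 500)))
  expect_lt(max(abs(nyq$smoothed)), 0.01)   # > 100x attenuation

  imp <- rep(0, 1000); imp[437] <- 1
  sm <- smooth_profile(mk(imp))
  expect_equal(which.max(sm$smoothed), 437)  # no phase lag
})

test_that("basis angles come from the global peak and the opposite-half maximum", {
  mkprof <- function(v, centers = seq(0, 1, length.out = length(v))) {
    structure(list(bin_centers = centers, raw_mean_norm = v, smoothed = v),
              class = "angular_profile")
  }
  v <- rep(0, 100); v[10] <- 5; v[90] <- 4
  pb <- find_basis_angles(mkprof(v))
  expect_equal(sort(pb$angles), sort(c(9.5 / 99 * 1, 89.5 / 99)), tolerance = 0.02)

  # spurious bump larger than the true second peak but in the same half
  v <- rep(0, 100); v[10] <- 5; v[30] <- 4.5; v[80] <- 1
  pb <- find_basis_angles(mkprof(v))
  expect_equal(max(pb$angles), (80 - 0.5) / 99, tolerance = 0.02)

  # symmetric bimodal picks the two symmetric peaks
  cent <- seq(-1, 1, length.out = 200)
  v <- exp(-((cent - 0.8) / 0.1)^2) + exp(-((cent + 0.8) / 0.1)^2)
  pb <- find_basis_angles(mkprof(v, cent))
  expect_equal(sort(pb$angles), c(-0.8, 0.8), tolerance = 0.02)

  # all mass in one half: single-stain error
  v <- rep(0, 100); v[5] <- 3; v[20] <- 2
  expect_error(find_basis_angles(mkprof(v)), "single-stain")
  expect_true(all(abs(colSums(pb$matrix^2) - 1) < 1e-12))
})

test_that("lifting a planar angle back to 3-D inverts the projection", {
  s <- two_stain_od(seed = 3)
  p <- uncentered_pca(s$od)
  proj <- diag(1 / sqrt(p$eigvals[1:2])) %*% t(p$eigvecs[, 1:2])
  b <- proj %*% s$w
  planar <- structure(list(angles = atan2(b[2, ], b[1, ]),
                           matrix = sweep(b, 2, sqrt(colSums(b^2)), "/")),
                      class = "planar_basis")
  w_hat <- lift_basis(planar, p, assign_stains = FALSE)
  for (k in 1:2) {
    expect_lt(angle_between(unclass(w_hat)[, k], s$w[, k]), 1e-4)
  }
  # identity planar basis returns the scaled principal directions
  planar_id <- structure(list(angles = c(0, pi / 2), matrix = diag(2)),
                         class = "planar_basis")
  w_id <- suppressWarnings(lift_basis(planar_id, p, assign_stains = FALSE))
  expect_equal(unclass(w_id)[, 1], pmax(p$eigvecs[, 1] * sqrt(p$eigvals[1]), 0),
               tolerance = 1e-10)
})

test_that("stain columns are ordered hematoxylin first, DAB second", {
  h_ref <- c(0.650, 0.704, 0.286); d_ref <- c(0.269, 0.568, 0.778)
  s <- two_stain_od(seed = 6, w = cbind(d_ref, h_ref))  # deliberately swapped
  p <- uncentered_pca(s$od)
  proj <- diag(1 / sqrt(p$eigvals[1:2])) %*% t(p$eigvecs[, 1:2])
  b <- proj %*% s$w
  planar <- structure(list(angles = atan2(b[2, ], b[1, ]),
                           matrix = sweep(b, 2, sqrt(colSums(b^2)), "/")),
                      class = "planar_basis")
  w_hat <- unclass(lift_basis(planar, p, assign_stains = TRUE))
  expect_lt(angle_between(w_hat[, 1], h_ref), 1)
  expect_lt(angle_between(w_hat[, 2], d_ref), 1)
})

test_that("color deconvolution recovers consistent systems exactly and clips impossibles", {
  s <- two_stain_od(seed = 7)
  h_hat <- color_deconvolve(s$od, s$w)
  expect_equal(h_hat, s$h, tolerance = 1e-10, ignore_attr = TRUE)

  # physically impossible column: clipped then recalculated per stain
  x <- cbind(-s$w[, 1])
  h1 <- color_deconvolve(x, s$w)
  expect_equal(h1[1, 1], 0)
  expect_gte(h1[2, 1], 0)

  # LS oracle: brute-force grid never beats the pre-clipping solution
  set.seed(11)
  w <- matrix(stats::runif(6, 0.1, 1), 3, 2)
  x <- matrix(stats::runif(3), 3, 1)
  h_ls <- solve(crossprod(w), crossprod(w, x))
  grid <- as.matrix(expand.grid(h1 = seq(0, 10, 0.05), h2 = seq(0, 10, 0.05)))
  obj <- colSums((as.vector(x) - w %*% t(grid))^2)
  expect_lte(sum((x - w %*% h_ls)^2), min(obj) + 1e-12)

  expect_error(color_deconvolve(x, cbind(w[, 1], 2 * w[, 1])), "rank")
})

test_that("single-positive columns are recalculated by single-vector least squares", {
  w <- cbind(c(1, 0, 0), c(0, 1, 0))
  # x = (0.5, -0.2, 0): naive solution (0.5, -0.2) -> clip -> recalc h1
  x <- cbind(c(0.5, -0.2, 0))
  h <- color_deconvolve(x, w)
  expect_equal(h[, 1], c(0.5, 0))
  # exactly-one-positive test is strict: all-zero columns stay zero
  h0 <- color_deconvolve(cbind(c(-1, -1, 0)), w)
  expect_equal(h0[, 1], c(0, 0))
})

test_that("dominance refinement keeps exact bases and improves noisy ones", {
  # disjoint supports: refined planar columns equal each set's mean direction
  s <- two_stain_od(seed = 8)
  set.seed(8)
  half <- ncol(s$od) / 2
  h_disjoint <- rbind(c(stats::rgamma(half, 2, 2), rep(0, half)),
                      c(rep(0, half), stats::rgamma(half, 2, 2)))
  od <- s$w %*% h_disjoint
  p <- uncentered_pca(od)
  z <- project_unit_power(od, p)
  conc <- color_deconvolve(od, s$w)
  ref <- refine_basis(od, p, z, structure(s$w, class = c("stain_basis", "matrix", "array")),
                      conc)
  expect_lt(max_basis_error(ref$basis, s$w), 0.1)

  # dominance threshold is strict: ratios of 9.9 select nothing
  conc99 <- rbind(rep(9.9, ncol(od)), rep(1, ncol(od)))
  expect_message(
    ref2 <- refine_basis(od, p, z, structure(s$w, class = c("stain_basis", "matrix", "array")),
                         conc99),
    "no dominant"
  )
  expect_equal(unclass(ref2$basis), s$w, ignore_attr = TRUE)

  # with OD noise, refinement does not worsen the estimate (median over seeds)
  deltas <- vapply(1:20, function(i) {
    co <- generate_cohort(small_synth(n_images = 5, seed = 100 + i, noise_sd = 0.05))
    od <- rgb_to_od(co$images[[3]])
    pca <- uncentered_pca(od)
    z <- project_unit_power(od, pca)
    prof <- smooth_profile(angular_profile(z, mask = background_mask(od)))
    planar <- find_basis_angles(prof)
    b0 <- suppressWarnings(lift_basis(planar, pca))
    c0 <- color_deconvolve(od, b0)
    r <- suppressMessages(refine_basis(od, pca, z, b0, c0))
    max_basis_error(b0, co$true_w) - max_basis_error(r$basis, co$true_w)
  }, numeric(1))
  expect_gte(stats::median(deltas), 0)
})

test_that("per-image pipeline is permutation-equivariant and scale-invariant", {
  co <- generate_cohort(small_synth(n_images = 5, seed = 21))
  od <- rgb_to_od(co$images[[3]])
  fit <- estimate_image_basis(od)
  set.seed(1)
  perm <- sample(ncol(od))
  fit_p <- estimate_image_basis(unclass(od)[, perm])
  expect_equal(unclass(fit_p$basis), unclass(fit$basis), tolerance = 1e-10)
  expect_equal(fit_p$conc, fit$conc[, perm], tolerance = 1e-10)

  # scaling all concentrations leaves estimated directions unchanged
  s <- two_stain_od(seed = 12)
  f1 <- estimate_image_basis(s$od, tau_bg = 0)
  f2 <- estimate_image_basis(3 * s$od, tau_bg = 0)
  for (j in 1:2) {
    expect_lt(angle_between(unclass(f1$basis)[, j], unclass(f2$basis)[, j]), 0.2)
  }
})

test_that("unclipped concentration columns reproduce the orthogonal projection", {
  s <- two_stain_od(seed = 13)
  set.seed(13)
  noisy <- s$od + abs(matrix(stats::rnorm(length(s$od), sd = 0.05), nrow = 3))
  h <- color_deconvolve(noisy, s$w)
  proj <- s$w %*% solve(crossprod(s$w)) %*% t(s$w)   # brute-force projector
  raw <- solve(crossprod(s$w), crossprod(s$w, noisy))
  unclipped <- which(apply(raw > 0, 2, all))
  expect_gt(length(unclipped), 10)
  expect_equal(s$w %*% h[, unclipped], proj %*% noisy[, unclipped],
               tolerance = 1e-10)
})

test_that("average basis is the entry-wise mean and cohort deconvolution is consistent", {
  b1 <- matrix(1:6 / 10, 3, 2); b2 <- matrix(2:7 / 10, 3, 2)
  expect_equal(unclass(average_basis(list(b1, b2))), (b1 + b2) / 2)
  expect_equal(unclass(average_basis(list(b1))), b1)
  expect_error(average_basis(list()), "no usable")

  # noiseless cohort from one true W: shared-basis concentrations match truth
  co <- generate_cohort(small_synth(n_images = 5, seed = 31, noise_sd = 0))
  ods <- lapply(co$true_h, function(h) co$true_w %*% h)
  hbar <- cohort_deconvolve(ods, structure(co$true_w, class = c("stain_basis", "matrix", "array")))
  for (i in seq_along(hbar)) {
    denom <- sqrt(sum(co$true_h[[i]]^2))
    expect_lt(sqrt(sum((hbar[[i]] - co$true_h[[i]])^2)) / denom, 1e-6)
  }
  # blank image deconvolves to ~0
  blank <- matrix(0, 3, 20)
  expect_equal(cohort_deconvolve(list(blank), co$true_w)[[1]], matrix(0, 2, 20),
               ignore_attr = TRUE)
})

test_that("noiseless synthetic images are separated to within two degrees with exact concentrations", {
  # exact OD mixtures (no 8-bit quantization): rank-2 exactness of the
  # full per-image chain
  co <- generate_cohort(small_synth(n_images = 5, seed = 41, noise_sd = 0))
  for (i in seq_along(co$images)) {
    od <- co$true_w %*% co$true_h[[i]]
    fit <- estimate_image_basis(od)
    expect_false(fit$degenerate)
    expect_lt(max_basis_error(fit$basis, co$true_w), 2)
    # concentrations within 1% relative Frobenius error (basis rescaled to truth)
    scale <- colSums(unclass(fit$basis) * co$true_w) / colSums(co$true_w^2)
    h_adj <- fit$conc * scale
    expect_lt(sqrt(sum((h_adj - co$true_h[[i]])^2)) / sqrt(sum(co$true_h[[i]]^2)),
              0.01)
  }
})
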