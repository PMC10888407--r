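#' Uncentered PCA of an OD point cloud
#'
#' Eigendecomposition of the second-moment matrix `R = X X^T / N` (no mean
#' subtraction, preserving the non-negative cone geometry of optical
#' densities). Eigenvalues are returned in descending order; each
#' eigenvector is sign-flipped so that its entry sum is non-negative,
#' pinning the angular frame of the downstream projections.
#'
#' @param od 3 x N OD matrix.
#' @return List with `eigvecs` (3 x 3 orthonormal, columns q1..q3) and
#'   `eigvals` (length 3, descending, >= 0).
#' @export
uncentered_pca <- function(od) {
  od <- unclass(od)
  n <- ncol(od)
  if (is.null(n) || n < 3L) stop("need at least 3 pixels")
  if (all(od == 0)) stop("blank image: OD matrix is all zero")
  r <- tcrossprod(od) / n
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  flip <- colSums(vecs) < 0
  vecs[, flip] <- -vecs[, flip]
  list(eigvecs = vecs, eigvals = vals)
}

#' Unit-power projection onto the principal plane
#'
#' Projects the OD columns onto the first two principal directions with
#' each component scaled by the inverse square root of its eigenvalue:
#' `Z = diag(L1^-1/2, L2^-1/2) [q1, q2]^T X`. Each row of Z then has mean
#' square 1 ("unit power"), which widens the angular spread between the
#' two stain directions in the plane compared to a plain projection.
#'
#' @param od 3 x N OD matrix.
#' @param pca result of [uncentered_pca()].
#' @param eps_rank relative eigenvalue threshold: `L2 <= eps_rank * L1`
#'   flags the cloud as effectively rank one (single stain).
#' @return 2 x N matrix of projections.
#' @export
project_unit_power <- function(od, pca, eps_rank = 1e-4) {
  l <- pca$eigvals
  if (l[2] <= eps_rank * l[1]) {
    stop("degenerate image: OD cloud is effectively rank one (single stain)")
  }
  diag(1 / sqrt(l[1:2])) %*% crossprod(pca$eigvecs[, 1:2], unclass(od))
}

#' Angular density profile of the planar projections
#'
#' For each foreground projection column, the angle `theta = atan2(z2, z1)`
#' and norm `r = sqrt(z1^2 + z2^2)` are computed. The occupied angle range
#' is split into `n_bins` equal bins and each bin holds the mean norm of
#' its members (0 if empty). Pixels with one stain dominant concentrate
#' mass near that stain's angle, so the stain directions appear as peaks.
#'
#' @param projections 2 x N matrix from [project_unit_power()].
#' @param mask logical vector: `TRUE` marks background pixels to exclude.
#' @param n_bins number of angle bins (default 1000).
#' @return List of class `angular_profile` with `bin_centers`,
#'   `raw_mean_norm`, and (after [smooth_profile()]) `smoothed`.
#' @export
angular_profile <- function(projections, mask = NULL, n_bins = 1000L) {
  z <- unclass(projections)
  if (!is.null(mask)) z <- z[, !mask, drop = FALSE]
  if (ncol(z) < 2L) stop("fewer than 2 foreground pixels")
  theta <- atan2(z[2, ], z[1, ])
  r <- sqrt(colSums(z^2))
  lo <- min(theta); hi <- max(theta)
  if (hi - lo < .Machine$double.eps * 8) {
    stop("degenerate angular profile: all foreground pixels at one angle")
  }
  wd <- (hi - lo) / n_bins
  idx <- pmin(floor((theta - lo) / wd) + 1L, n_bins)
  mean_r <- rep(0, n_bins)
  agg <- tapply(r, idx, mean)
  mean_r[as.integer(names(agg))] <- agg
  structure(
    list(bin_centers = lo + (seq_len(n_bins) - 0.5) * wd,
         raw_mean_norm = mean_r, smoothed = NULL),
    class = "angular_profile"
  )
}

# Zero-phase low-pass filtering with symmetric-reflection padding, so that
# boundary transients of the IIR filter do not contaminate the profile and
# peak positions are not shifted.
zero_phase_filter <- function(coef, x, pad = 500L) {
  n <- length(x)
  p <- min(pad, n - 1L)
  padded <- c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
  y <- signal::filtfilt(coef, padded)
  y[(p + 1L):(p + n)]
}

#' Smooth an angular profile
#'
#' Applies an eighth-order low-pass Butterworth filter (digital cutoff
#' 0.035, as a fraction of the Nyquist frequency) to the binned mean-norm
#' profile, forward and backward so the filtering is zero-phase.
#'
#' @param profile an `angular_profile`.
#' @param order,cutoff Butterworth filter order and normalized cutoff.
#' @return The profile with its `smoothed` field filled in.
#' @export
smooth_profile <- function(profile, order = 8L, cutoff = 0.035) {
  stopifnot(inherits(profile, "angular_profile"))
  coef <- signal::butter(order, cutoff)
  profile$smoothed <- zero_phase_filter(coef, profile$raw_mean_norm)
  profile
}

#' Locate the two stain angles in a smoothed profile
#'
#' The global maximum of the smoothed profile gives the first stain angle.
#' Because spurious secondary bumps can occur near the first peak, the
#' second angle is taken as the maximum of the profile restricted to the
#' half of the occupied angle range that does not contain the first peak.
#'
#' @param profile a smoothed `angular_profile`.
#' @return List of class `planar_basis` with `angles` (radians) and
#'   `matrix` (2 x 2, columns `(cos phi, sin phi)`).
#' @export
find_basis_angles <- function(profile) {
  v <- profile$smoothed
  if (is.null(v)) stop("profile not smoothed; call smooth_profile() first")
  phi <- profile$bin_centers
  mid <- (min(phi) + max(phi)) / 2
  k1 <- which.max(v)
  in_first_half <- phi < mid
  opposite <- if (in_first_half[k1]) !in_first_half else in_first_half
  v_opp <- v[opposite]
  if (length(v_opp) == 0L || all(v_opp <= 0)) {
    stop("no density in the opposite angular half: single-stain image")
  }
  k2 <- which(opposite)[which.max(v_opp)]
  ang <- c(phi[k1], phi[k2])
  structure(
    list(angles = ang, matrix = rbind(cos(ang), sin(ang))),
    class = "planar_basis"
  )
}

# Assign the two columns of a 3 x 2 stain matrix to (hematoxylin, DAB) by
# maximal total cosine similarity against the classical reference OD
# directions; ties broken by blue-channel OD (larger -> DAB).
assign_stain_columns <- function(w) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  keep <- cosine(w[, 1], HEMATOXYLIN_REF) + cosine(w[, 2], DAB_REF)
  swap <- cosine(w[, 1], DAB_REF) + cosine(w[, 2], HEMATOXYLIN_REF)
  if (abs(keep - swap) < 1e-12) {
    if (w[3, 1] > w[3, 2]) w[, 2:1] else w
  } else if (keep >= swap) w else w[, 2:1]
}

#' Lift a planar basis back to 3-D stain vectors
#'
#' Reverses the unit-power projection: `W = [q1 sqrt(L1), q2 sqrt(L2)] B`,
#' the exact inverse of the projection on the principal plane. Columns are
#' then ordered (hematoxylin, DAB) by cosine similarity to the classical
#' reference OD directions, and small negative entries (projection
#' leakage) are clipped to zero.
#'
#' @param planar a `planar_basis`.
#' @param pca result of [uncentered_pca()].
#' @param assign_stains reorder columns by stain identity (default TRUE).
#' @return 3 x 2 non-negative stain matrix of class `stain_basis`, column
#'   1 = hematoxylin, column 2 = DAB. Attribute `large_negative` flags a
#'   physically implausible estimate (entry below -0.05 of the column
#'   norm before clipping).
#' @export
lift_basis <- function(planar, pca, assign_stains = TRUE) {
  w <- (pca$eigvecs[, 1:2] %*% diag(sqrt(pca$eigvals[1:2]))) %*% planar$matrix
  cos_ang <- abs(sum(w[, 1] * w[, 2])) /
    sqrt(sum(w[, 1]^2) * sum(w[, 2]^2))
  if (!is.finite(cos_ang) || cos_ang > 1 - 1e-10) {
    stop("lifted stain vectors are collinear")
  }
  large_neg <- FALSE
  for (j in 1:2) {
    cn <- sqrt(sum(w[, j]^2))
    if (any(w[, j] < -0.05 * cn)) {
      warning("stain column ", j, " has a large negative entry; ",
              "estimate is physically implausible")
      large_neg <- TRUE
    }
  }
  w <- pmax(w, 0)
  if (assign_stains) w <- assign_stain_columns(w)
  structure(w, large_negative = large_neg, class = c("stain_basis", "matrix", "array"))
}

#' Least-squares color deconvolution
#'
#' Solves `X = W H` for the 2 x N concentration matrix by the left
#' pseudoinverse `H = (W^T W)^-1 W^T X`, then clips negative
#' concentrations to zero. Columns left with exactly one strictly
#' positive entry are recomputed by single-vector least squares against
#' the corresponding stain column, `h = max(0, w^T x / ||w||^2)`, which
#' removes the bias the discarded negative component would leave behind.
#'
#' @param od 3 x N OD matrix.
#' @param basis 3 x 2 stain matrix (full rank).
#' @return 2 x N non-negative concentration matrix (row 1 = hematoxylin,
#'   row 2 = DAB).
#' @export
color_deconvolve <- function(od, basis) {
  w <- unclass(basis)
  x <- unclass(od)
  gram <- crossprod(w)
  if (abs(det(gram)) < 1e-12 * (gram[1, 1] * gram[2, 2] + 1e-300)) {
    stop("rank-deficient stain basis")
  }
  h <- solve(gram, crossprod(w, x))
  h[h < 0] <- 0
  for (s in 1:2) {
    other <- 3L - s
    j <- which(h[s, ] > 0 & h[other, ] == 0)
    if (length(j)) {
      h[s, j] <- pmax(0, colSums(w[, s] * x[, j, drop = FALSE]) / sum(w[, s]^2))
    }
  }
  h
}

#' Refine a stain basis from stain-dominant pixels
#'
#' For each stain, the planar projections of pixels where that stain's
#' concentration is at least `dominance` times the other's (and positive)
#' are averaged and renormalized to give a new planar direction; the
#' refined basis is lifted back to 3-D and the concentrations are
#' re-deconvolved. A stain with no dominant pixels keeps its previous
#' column.
#'
#' @param od 3 x N OD matrix.
#' @param pca result of [uncentered_pca()].
#' @param projections 2 x N unit-power projections.
#' @param basis current 3 x 2 stain basis.
#' @param conc current 2 x N concentrations from [color_deconvolve()].
#' @param dominance dominance ratio threshold (default 10).
#' @return List with refined `basis` and `conc`.
#' @export
refine_basis <- function(od, pca, projections, basis, conc, dominance = 10) {
  z <- unclass(projections)
  # recover the current planar columns of the basis so a stain without
  # dominant pixels keeps its direction
  proj_mat <- diag(1 / sqrt(pca$eigvals[1:2])) %*% t(pca$eigvecs[, 1:2])
  b <- proj_mat %*% unclass(basis)
  changed <- FALSE
  for (s in 1:2) {
    other <- 3L - s
    dom <- conc[s, ] >= dominance * conc[other, ] & conc[s, ] > 0
    if (any(dom)) {
      m <- rowMeans(z[, dom, drop = FALSE])
      nm <- sqrt(sum(m^2))
      if (nm > 0) {
        b[, s] <- m / nm
        changed <- TRUE
      }
    } else {
      message("refine_basis: stain ", s, " has no dominant pixels; column kept")
    }
  }
  if (!changed) return(list(basis = basis, conc = conc))
  b <- sweep(b, 2, sqrt(colSums(b^2)), "/")
  planar <- structure(list(angles = atan2(b[2, ], b[1, ]), matrix = b),
                      class = "planar_basis")
  new_basis <- lift_basis(planar, pca, assign_stains = FALSE)
  list(basis = new_basis, conc = color_deconvolve(od, new_basis))
}

#' Entry-wise average of per-image stain bases
#'
#' @param bases list of 3 x 2 `stain_basis` matrices (degenerate or
#'   excluded images should not be passed in).
#' @return 3 x 2 `stain_basis`, the entry-wise mean.
#' @export
average_basis <- function(bases) {
  if (length(bases) == 0L) stop("no usable per-image bases to average")
  w <- Reduce(`+`, lapply(bases, function(b) {
    b <- unclass(b); attributes(b) <- list(dim = dim(b)); b
  })) / length(bases)
  structure(w, class = c("stain_basis", "matrix", "array"))
}

#' Re-deconvolve a cohort with the average stain basis
#'
#' @param ods list of 3 x N OD matrices.
#' @param w_bar cohort-average 3 x 2 stain basis.
#' @return List of 2 x N concentration matrices.
#' @export
cohort_deconvolve <- function(ods, w_bar) {
  lapply(ods, color_deconvolve, basis = w_bar)
}

#' Estimate the stain basis and concentrations of one image
#'
#' Runs the full per-image chain: background masking, uncentered PCA,
#' unit-power projection, angular density profile, Butterworth smoothing,
#' opposite-half peak selection, basis lift, color deconvolution, and one
#' dominance-based refinement pass. Images whose OD cloud is effectively
#' rank one (single stain), or whose angular profile collapses, are
#' flagged degenerate rather than failing: the caller substitutes the
#' cohort-average basis for them.
#'
#' @param od 3 x N OD matrix.
#' @param tau_bg background OD threshold for the angular profile
#'   (0 disables masking).
#' @param n_bins number of angle bins.
#' @param butter_order,butter_cutoff smoothing filter parameters.
#' @param dominance refinement dominance ratio.
#' @param eps_rank rank-degeneracy threshold on `L2 / L1`.
#' @return List of class `stain_fit`: `basis`, `conc`, `pca`,
#'   `projections`, `angles`, `profile`, `degenerate` (logical),
#'   `excluded` (logical: implausible basis, kept out of the average),
#'   `clip_fraction`.
#' @export
estimate_image_basis <- function(od, tau_bg = 0.05, n_bins = 1000L,
                                 butter_order = 8L, butter_cutoff = 0.035,
                                 dominance = 10, eps_rank = 1e-4) {
  pca <- uncentered_pca(od)
  degenerate_fit <- function(reason) {
    structure(list(basis = NULL, conc = NULL, pca = pca, projections = NULL,
                   angles = c(NA_real_, NA_real_), profile = NULL,
                   degenerate = TRUE, excluded = TRUE, reason = reason,
                   clip_fraction = NA_real_),
              class = "stain_fit")
  }
  if (pca$eigvals[2] <= eps_rank * pca$eigvals[1]) {
    return(degenerate_fit("rank-one OD cloud"))
  }
  z <- project_unit_power(od, pca, eps_rank = eps_rank)
  mask <- if (tau_bg > 0) background_mask(od, tau_bg) else NULL
  prof <- tryCatch({
    p <- angular_profile(z, mask = mask, n_bins = n_bins)
    smooth_profile(p, order = butter_order, cutoff = butter_cutoff)
  }, error = function(e) e)
  if (inherits(prof, "error")) return(degenerate_fit(conditionMessage(prof)))
  planar <- tryCatch(find_basis_angles(prof), error = function(e) e)
  if (inherits(planar, "error")) return(degenerate_fit(conditionMessage(planar)))
  basis <- lift_basis(planar, pca)
  raw_h <- solve(crossprod(unclass(basis)),
                 crossprod(unclass(basis), unclass(od)))
  clip_fraction <- mean(raw_h < 0)
  conc <- color_deconvolve(od, basis)
  refined <- refine_basis(od, pca, z, basis, conc, dominance = dominance)
  structure(
    list(basis = refined$basis, conc = refined$conc, pca = pca,
         projections = z, angles = planar$angles, profile = prof,
         degenerate = FALSE,
         excluded = isTRUE(attr(refined$basis, "large_negative")),
         reason = NULL, clip_fraction = clip_fraction),
    class = "stain_fit"
  )
}

#' Separate a cohort of two-stain IHC images
#'
#' Estimates a stain basis per image, averages the usable per-image bases
#' into a cohort basis, and re-deconvolves every image with the average
#' basis. Degenerate images (single-stain OD clouds) are scored against
#' the cohort basis only.
#'
#' @param images list of `rgb_image` objects, or a character vector of
#'   image paths; optionally named (names become image ids).
#' @param tau_bg,n_bins,butter_order,butter_cutoff,dominance,eps_rank
#'   passed to [estimate_image_basis()].
#' @param eps_floor intensity clip floor for the OD transform.
#' @return Object of class `ihc_separation`: `fits` (per-image
#'   `stain_fit`s), `w_bar` (average basis), `conc_bar` (per-image
#'   cohort-basis concentrations), `ods`, `image_ids`, `n_pixels`, and a
#'   `summary` tibble (image_id, n_pixels, degenerate, excluded, angles,
#'   clip fraction).
#' @export
separate_cohort <- function(images, tau_bg = 0.05, n_bins = 1000L,
                            butter_order = 8L, butter_cutoff = 0.035,
                            dominance = 10, eps_rank = 1e-4, eps_floor = 1) {
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, read_rgb_image)
    if (is.null(names(paths))) {
      names(images) <- tools::file_path_sans_ext(basename(paths))
    } else {
      names(images) <- names(paths)
    }
  }
  if (length(images) == 0L) stop("empty cohort")
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
  ods <- lapply(images, function(im) {
    if (inherits(im, "rgb_image")) rgb_to_od(im, eps_floor = eps_floor) else im
  })
  fits <- lapply(ods, estimate_image_basis,
                 tau_bg = tau_bg, n_bins = n_bins,
                 butter_order = butter_order, butter_cutoff = butter_cutoff,
                 dominance = dominance, eps_rank = eps_rank)
  usable <- !vapply(fits, function(f) f$degenerate || f$excluded, logical(1))
  if (!any(usable)) stop("no image yielded a usable stain basis")
  w_bar <- average_basis(lapply(fits[usable], `[[`, "basis"))
  conc_bar <- cohort_deconvolve(ods, w_bar)
  structure(
    list(fits = fits, w_bar = w_bar, conc_bar = conc_bar, ods = ods,
         image_ids = ids,
         n_pixels = vapply(ods, ncol, integer(1)),
         summary = tibble(
           image_id = ids,
           n_pixels = vapply(ods, ncol, integer(1)),
           degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
           excluded = vapply(fits, `[[`, logical(1), "excluded"),
           angle_1 = vapply(fits, function(f) f$angles[1], numeric(1)),
           angle_2 = vapply(fits, function(f) f$angles[2], numeric(1)),
           clip_fraction = vapply(fits, `[[`, numeric(1), "clip_fraction")
         )),
    class = "ihc_separation"
  )
}

#' @export
print.ihc_separation <- function(x, ...) {
  cat("<ihc_separation> ", length(x$fits), " images, ",
      sum(x$summary$degenerate), " degenerate\n", sep = "")
  cat("average stain basis (columns H, DAB):\n")
  w <- unclass(x$w_bar)
  attributes(w) <- list(dim = dim(w), dimnames = list(c("R", "G", "B"), c("H", "DAB")))
  print(round(w, 4))
  invisible(x)
}
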