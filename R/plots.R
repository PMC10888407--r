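#' Angle between two 3-vectors, in degrees
#'
#' Handy diagnostic for comparing estimated stain directions against a
#' reference (e.g. ground truth of a synthetic cohort).
#'
#' @param a,b numeric vectors of equal length.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_between <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

#' Plot an angular density profile
#'
#' Raw binned mean norms with the smoothed curve overlaid; the two
#' selected stain angles (if the fit succeeded) are marked by vertical
#' lines.
#'
#' @param fit a `stain_fit` from [estimate_image_basis()].
#' @return A ggplot object.
#' @export
plot_angular_profile <- function(fit) {
  stopifnot(inherits(fit, "stain_fit"))
  if (is.null(fit$profile)) stop("degenerate fit: no angular profile")
  df <- tibble(angle = fit$profile$bin_centers,
               raw = fit$profile$raw_mean_norm,
               smoothed = fit$profile$smoothed)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$raw), width = diff(df$angle[1:2]),
                      fill = "grey75") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::labs(x = "planar angle (rad)", y = "mean projection norm",
                  title = "Angular density profile")
  if (!anyNA(fit$angles)) {
    p <- p + ggplot2::geom_vline(xintercept = fit$angles, linetype = "dashed")
  }
  p
}

#' Plot cohort scores against the feature-vector norms
#'
#' Sorted feature norms colored by assigned score; a well-behaved cohort
#' shows a monotone staircase (high norm-score correlation).
#'
#' @param object an `ihc_scores` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ihc_scores <- function(object, ...) {
  df <- object$table
  df <- df[order(df$norm), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$norm,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "image rank (by feature norm)",
                  y = sprintf("feature %s-norm", format(object$p)),
                  colour = "score",
                  title = "Feature-vector norm vs assigned score")
}

#' Plot estimated per-image stain vectors
#'
#' Shows the per-image hematoxylin and DAB OD directions (usable fits
#' only) together with the cohort average; consistent estimates cluster
#' tightly around the average.
#'
#' @param sep an `ihc_separation` object.
#' @return A ggplot object (red vs blue OD coordinates of unit-normalized
#'   stain columns).
#' @export
plot_stain_vectors <- function(sep) {
  stopifnot(inherits(sep, "ihc_separation"))
  rows <- list()
  unitcol <- function(w, j) w[, j] / sqrt(sum(w[, j]^2))
  for (i in seq_along(sep$fits)) {
    f <- sep$fits[[i]]
    if (f$degenerate) next
    for (j in 1:2) {
      u <- unitcol(unclass(f$basis), j)
      rows[[length(rows) + 1]] <- tibble(
        image_id = sep$image_ids[i],
        stain = c("hematoxylin", "DAB")[j],
        od_red = u[1], od_blue = u[3], kind = "per-image")
    }
  }
  for (j in 1:2) {
    u <- unitcol(unclass(sep$w_bar), j)
    rows[[length(rows) + 1]] <- tibble(
      image_id = "average", stain = c("hematoxylin", "DAB")[j],
      od_red = u[1], od_blue = u[3], kind = "cohort average")
  }
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$od_red, y = .data$od_blue,
                                   colour = .data$stain,
                                   shape = .data$kind,
                                   size = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_manual(values = c(`per-image` = 2, `cohort average` = 4)) +
    ggplot2::labs(x = "OD (red channel)", y = "OD (blue channel)",
                  title = "Estimated stain directions across the cohort")
}
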