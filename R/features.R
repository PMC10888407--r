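#' Per-image scalar features of DAB expression
#'
#' Computes the four per-image features used for scoring, from a cohort
#' separation result. All features increase, in general, with the DAB
#' stain concentration:
#'
#' * `f1` — mean DAB intensity under the cohort-average basis,
#'   `M1 = (1/3N) ||w_DAB||_1 ||h_DAB||_1`, normalized by its cohort
#'   maximum (so `f1` lies in `[0, 1]` with maximum 1).
#' * `f2` — ratio of cohort-normalized robust maxima (99th percentile of
#'   the entries of the rank-one per-stain intensity matrix) of DAB over
#'   hematoxylin, both referenced to the image with the largest DAB
#'   robust maximum.
#' * `f3` — root-mean-square DAB intensity under the cohort-average
#'   basis, `M3 = (1/3N) ||w_DAB||_2 ||h_DAB||_2`, normalized by its
#'   cohort maximum.
#' * `f4` — root of the mean DAB intensity power under each image's own
#'   basis, `(1/sqrt(3N)) ||w_DAB||_2 ||h_DAB||_2` (OD units, not
#'   cohort-normalized). Images with a degenerate per-image basis fall
#'   back to the cohort-average basis and are flagged.
#'
#' @param sep an `ihc_separation` from [separate_cohort()].
#' @param percentile robust-maximum percentile (default 0.99).
#' @param eps_r floor applied to the hematoxylin robust maximum in the
#'   `f2` denominator, guarding hematoxylin-free edge cases.
#' @return A tibble with one row per image: `image_id`, `f1`..`f4`,
#'   intermediates `M1`, `M3`, `R1`, `R2`, `n_pixels`, and
#'   `f4_surrogate` (TRUE where `f4` used the cohort basis).
#' @export
extract_features <- function(sep, percentile = 0.99, eps_r = 1e-9) {
  stopifnot(inherits(sep, "ihc_separation"))
  w_bar <- unclass(sep$w_bar)
  n_img <- length(sep$conc_bar)
  n_pix <- sep$n_pixels

  m1 <- vapply(seq_len(n_img), function(m) {
    sum(abs(w_bar[, 2])) * sum(sep$conc_bar[[m]][2, ]) / (3 * n_pix[m])
  }, numeric(1))
  if (max(m1) == 0) stop("no DAB signal anywhere in the cohort: unscorable")
  f1 <- m1 / max(m1)

  robust_max <- function(w_col, h_row) {
    quantile(outer(w_col, h_row), probs = percentile, names = FALSE)
  }
  r1 <- vapply(seq_len(n_img), function(m) {
    robust_max(w_bar[, 1], sep$conc_bar[[m]][1, ])
  }, numeric(1))
  r2 <- vapply(seq_len(n_img), function(m) {
    robust_max(w_bar[, 2], sep$conc_bar[[m]][2, ])
  }, numeric(1))
  m_star <- which.max(r2)
  if (r1[m_star] == 0) {
    stop("reference image (largest DAB robust maximum) has no hematoxylin")
  }
  r2_bar <- r2 / r2[m_star]
  r1_bar <- pmax(r1, eps_r) / r1[m_star]
  f2 <- r2_bar / r1_bar

  m3 <- vapply(seq_len(n_img), function(m) {
    sqrt(sum(w_bar[, 2]^2)) * sqrt(sum(sep$conc_bar[[m]][2, ]^2)) / (3 * n_pix[m])
  }, numeric(1))
  f3 <- m3 / max(m3)

  f4_surrogate <- vapply(sep$fits, `[[`, logical(1), "degenerate")
  f4 <- vapply(seq_len(n_img), function(m) {
    if (f4_surrogate[m]) {
      w <- w_bar; h <- sep$conc_bar[[m]]
    } else {
      w <- unclass(sep$fits[[m]]$basis); h <- sep$fits[[m]]$conc
    }
    sqrt(sum(w[, 2]^2)) * sqrt(sum(h[2, ]^2)) / sqrt(3 * n_pix[m])
  }, numeric(1))

  tibble(
    image_id = sep$image_ids,
    f1 = f1, f2 = f2, f3 = f3, f4 = f4,
    M1 = m1, M3 = m3, R1 = r1, R2 = r2,
    n_pixels = n_pix, f4_surrogate = f4_surrogate
  )
}
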