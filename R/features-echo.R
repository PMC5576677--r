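#' Echointensity features of muscle and subcutaneous fat
#'
#' The five first-order features: mean and sample standard deviation of the
#' muscle and fat region intensities, and the ratio of the two means.
#' Elevated muscle echointensity (absolute or relative to fat) marks fibrotic
#' or fatty-replaced muscle.
#'
#' @param muscle,fat \code{\link{RegionPixels-class}} bags (>= 2 pixels each).
#' @return named numeric: \code{echo_mean_muscle, echo_sd_muscle,
#'   echo_mean_fat, echo_sd_fat, echo_ratio}.
#' @export
echoFeatures <- function(muscle, fat) {
  mv <- regionValues(muscle); fv <- regionValues(fat)
  if (length(mv) < 2L || length(fv) < 2L)
    .err("echo features need at least 2 pixels per region (sample SD)",
         "insufficient_data_error")
  mf <- mean(fv)
  if (mf == 0)
    .err("mean fat echointensity is 0; muscle/fat ratio undefined",
         "degenerate_ratio_error")
  c(echo_mean_muscle = mean(mv), echo_sd_muscle = stats::sd(mv),
    echo_mean_fat = mf, echo_sd_fat = stats::sd(fv),
    echo_ratio = mean(mv) / mf)
}

#' Fit the Nakagami speckle distribution by the method of moments
#'
#' Pixel intensities are treated as amplitude samples of a Nakagami(m, omega)
#' distribution (shape m >= 0.5, scale omega = E[X^2]). The
#' inverse-normalized-variance moment estimator is used:
#' \eqn{\hat\omega = \overline{x^2}} and
#' \eqn{\hat m = \hat\omega^2 / \mathrm{var}(x^2)}. Estimates of m below the
#' distribution's support bound 0.5 are clamped there with a warning.
#'
#' @param region a \code{\link{RegionPixels-class}} with >= 10 pixels.
#' @return named numeric \code{c(m =, omega =)}.
#' @export
fitNakagami <- function(region) {
  x <- if (is(region, "RegionPixels")) regionValues(region) else as.numeric(region)
  if (length(x) < 10L)
    .err(sprintf("Nakagami fit needs >= 10 pixels, got %d", length(x)),
         "insufficient_data_error")
  x2 <- x^2
  v <- stats::var(x2)
  if (v == 0)
    .err("constant region: var(x^2) = 0, Nakagami shape undefined",
         "degenerate_texture_error")
  omega <- mean(x2)
  m <- omega^2 / v
  if (m < 0.5) {
    warning(sprintf("Nakagami shape estimate %.3f below support bound; clamped to 0.5", m))
    m <- 0.5
  }
  c(m = m, omega = omega)
}
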