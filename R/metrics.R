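# Scalar figures of merit: Gaussian-fitted FWHM and the minimisation
# statistic Omega.

#' Least-squares Gaussian fit to a binned profile
#'
#' Fits counts ~ A exp(-(x - mu)^2 / (2 s^2)) by nonlinear least squares
#' (Levenberg-Marquardt), starting from the weighted moments of the profile.
#' Used both on histogrammed particle samples and on analytic dose profiles.
#'
#' @param x Bin centres (mm).
#' @param counts Non-negative bin values.
#' @return List with \code{sigma}, \code{sigma_se}, \code{mu}, \code{amp}.
#' @keywords internal
fit_gaussian_profile <- function(x, counts) {
  stopifnot(length(x) == length(counts), all(counts >= 0))
  tot <- sum(counts)
  if (tot <= 0) stop("profile is empty")
  mu0 <- sum(x * counts) / tot
  s0 <- sqrt(sum((x - mu0)^2 * counts) / tot)
  if (!is.finite(s0) || s0 <= 0) stop("degenerate profile: zero spread")
  df <- data.frame(x = x, c = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(c ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = list(A = max(counts), mu = mu0, s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the moment estimate; its SE is the usual large-n value
    return(list(sigma = s0, sigma_se = s0 / sqrt(2 * max(tot - 1, 1)),
                mu = mu0, amp = max(counts)))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["s"]], error = function(e) NA_real_)
  list(sigma = abs(cf[["s"]]), sigma_se = se, mu = cf[["mu"]], amp = cf[["A"]])
}

#' Gaussian-fitted beam width of a 1-D sample
#'
#' Bins the sampled transverse positions (Freedman-Diaconis bin width),
#' fits a Gaussian to the bin counts and reports FWHM = 2 sqrt(2 log 2)
#' sigma (approximately 2.355 sigma) with the propagated fit error.
#'
#' @param positions Sampled positions, mm (>= 10 values with nonzero
#'   spread).
#' @param plane Optional plane label (\code{"horizontal"}/\code{"vertical"}).
#' @param z Optional plane position, cm.
#' @return Object of class \code{beam_profile} with fields \code{sigma},
#'   \code{sigma_se}, \code{fwhm}, \code{fwhm_se}, \code{n}, \code{plane},
#'   \code{z}.
#' @export
fit_gaussian_fwhm <- function(positions, plane = NA_character_, z = NA_real_) {
  positions <- positions[is.finite(positions)]
  if (length(positions) < 10) stop("need at least 10 samples to fit a profile")
  if (stats::sd(positions) == 0) stop("degenerate profile: zero spread")
  h <- graphics::hist(positions, breaks = "FD", plot = FALSE)
  f <- fit_gaussian_profile(h$mids, h$counts)
  structure(list(plane = plane, z = z, sigma = f$sigma, sigma_se = f$sigma_se,
                 fwhm = FWHM_CONST * f$sigma,
                 fwhm_se = FWHM_CONST * f$sigma_se,
                 mu = f$mu, n = length(positions)),
            class = "beam_profile")
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf("Beam profile (%s%s): FWHM = %.4g +/- %.2g mm (sigma = %.4g mm, n = %d)\n",
              ifelse(is.na(x$plane), "?", x$plane),
              ifelse(is.na(x$z), "", sprintf(", z = %g cm", x$z)),
              x$fwhm, x$fwhm_se, x$sigma, x$n))
  invisible(x)
}

#' Combined beam-size statistic Omega
#'
#' Omega = (h v) (h/v + v/h) = h^2 + v^2 (mm^2), the scalar minimised by the
#' quadrupole grid search. For a fixed product h v it is smallest at h = v,
#' which drives the minimisation towards symmetric focal spots.
#'
#' @param h_fwhm,v_fwhm Horizontal and vertical FWHM, mm (> 0; the product
#'   form is undefined at 0).
#' @return Omega in mm^2.
#' @export
omega <- function(h_fwhm, v_fwhm) {
  if (any(h_fwhm <= 0) || any(v_fwhm <= 0)) {
    stop("omega requires strictly positive FWHM values")
  }
  h_fwhm^2 + v_fwhm^2
}

#' Minibeam criterion
#'
#' TRUE iff both transverse FWHM are <= 1 mm (boundary inclusive).
#'
#' @param h,v Horizontal/vertical \code{beam_profile}s or FWHM values (mm).
#' @return Logical.
#' @export
is_minibeam <- function(h, v) {
  val <- function(p) if (inherits(p, "beam_profile")) p$fwhm else p
  val(h) <= 1 && val(v) <= 1
}
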