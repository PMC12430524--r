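#' Wrap angles into the canonical interval
#'
#' Maps arbitrary angles (degrees) to the half-open interval (-180, 180].
#' This is the canonical representation used for every dihedral in the
#' package: cis = 0, trans = 180 (never -180).
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each value in (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -190, 360, 180, -180))
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor() maps 180 to -180; fold back onto the closed upper end
  w[w == -180] <- 180
  w
}

#' Signed circular difference
#'
#' Shortest signed difference `a - b` on the circle, in degrees,
#' wrapped to (-180, 180].
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return numeric vector of signed differences in (-180, 180].
#' @export
wrap_difference <- function(a, b) {
  wrap_angle(a - b)
}

#' Circular summary statistics of angles
#'
#' Mean direction, mean resultant length and circular standard deviation of
#' a sample of angles. The mean is the direction of the vector mean of the
#' unit vectors (atan2 of mean sine over mean cosine); the circular SD is
#' \code{sqrt(-2 log R)} converted to degrees. For nearly uniform samples
#' (resultant length below \code{tol}) the mean direction is undefined and
#' returned as \code{NA} with \code{defined = FALSE} rather than an
#' arbitrary direction.
#'
#' @param x numeric vector of angles in degrees; must be nonempty.
#' @param tol resultant length below which the mean is flagged undefined.
#' @return list with components \code{mean} (degrees in (-180, 180] or NA),
#'   \code{sd} (degrees), \code{resultant} (in [0, 1]) and \code{defined}.
#' @export
#' @examples
#' circular_stats(c(170, -170))$mean   # 180, not the naive 0
#' circular_stats(c(10, 20))$mean      # 15
circular_stats <- function(x, tol = 1e-8) {
  if (length(x) == 0L || !is.numeric(x)) {
    stop("circular_stats(): 'x' must be a nonempty numeric vector")
  }
  if (anyNA(x)) stop("circular_stats(): 'x' contains NA")
  rad <- x * pi / 180
  s <- mean(sin(rad))
  c <- mean(cos(rad))
  r <- sqrt(s^2 + c^2)
  if (r < tol) {
    return(list(mean = NA_real_, sd = Inf, resultant = r, defined = FALSE))
  }
  m <- wrap_angle(atan2(s, c) * 180 / pi)
  sd_deg <- sqrt(-2 * log(min(r, 1))) * 180 / pi
  list(mean = m, sd = sd_deg, resultant = r, defined = TRUE)
}

#' Column-wise circular mean of an angle matrix
#'
#' @param m numeric matrix of angles in degrees (rows = observations).
#' @return numeric vector of circular means per column (NA where undefined).
#' @export
circular_col_means <- function(m) {
  rad <- m * pi / 180
  s <- colMeans(sin(rad))
  c <- colMeans(cos(rad))
  r <- sqrt(s^2 + c^2)
  out <- wrap_angle(atan2(s, c) * 180 / pi)
  out[r < 1e-8] <- NA_real_
  out
}

#' Column-wise circular standard deviation of an angle matrix
#'
#' @param m numeric matrix of angles in degrees (rows = observations).
#' @return numeric vector of circular SDs (degrees) per column.
#' @export
circular_col_sds <- function(m) {
  rad <- m * pi / 180
  s <- colMeans(sin(rad))
  c <- colMeans(cos(rad))
  r <- pmin(sqrt(s^2 + c^2), 1)
  sqrt(-2 * log(r)) * 180 / pi
}

#' Draw from the von Mises distribution
#'
#' Vectorised Best–Fisher (1979) rejection sampler. Used by the synthetic
#' ensemble generator: a unimodal circular analogue of the normal
#' distribution, appropriate for equilibrated single-basin dihedral
#' sampling.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees (scalar or length-n).
#' @param kappa concentration parameter (> 0); larger is tighter. A circular
#'   SD of roughly \code{1/sqrt(kappa)} radians.
#' @return numeric vector of n angles in degrees, wrapped to (-180, 180].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0)
  if (n == 0L) return(numeric(0))
  if (!all(is.finite(mu)) || !is.finite(kappa) || kappa <= 0) {
    stop("rvonmises(): 'mu' must be finite and 'kappa' finite and > 0")
  }
  mu_rad <- rep_len(mu, n) * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  theta <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    m <- length(todo)
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r0 * z) / (r0 + z)
    cc <- kappa * (r0 - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      u3 <- stats::runif(sum(ok))
      theta[todo[ok]] <- sign(u3 - 0.5) * acos(f[ok])
    }
    todo <- todo[!ok]
  }
  wrap_angle((theta + mu_rad) * 180 / pi)
}
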