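#' Wrap angles to (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to the half-open interval (-pi, pi].
#' @export
#' @examples
#' wrap_pi(c(0, pi, -pi, 3 * pi / 2))
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi)
  # map 0 back to 2*pi so that +pi stays +pi and -pi maps to +pi
  y[y == 0] <- 2 * pi
  y - pi
}

#' Circular mean direction and mean resultant length
#'
#' Unweighted circular summary of a sample of angles: the mean direction is
#' the argument of the average unit phasor, and the mean resultant length
#' (MRL) its modulus, between 0 (uniform) and 1 (perfectly concentrated).
#'
#' @param phases Numeric vector of angles in radians.
#' @param weights Optional non-negative weights (defaults to equal weights).
#' @return A list with `mrl`, `mean_direction` (radians in (-pi, pi]), and
#'   `n` (number of angles, or sum of weights when weighted).
#' @export
circ_stats <- function(phases, weights = NULL) {
  if (length(phases) == 0L) {
    stop("cannot compute circular statistics of an empty sample", call. = FALSE)
  }
  if (is.null(weights)) {
    z <- mean(exp(1i * phases))
    n <- length(phases)
  } else {
    stopifnot(length(weights) == length(phases))
    if (any(weights < 0) || all(weights == 0)) {
      stop("weights must be non-negative with a positive sum", call. = FALSE)
    }
    z <- sum(weights * exp(1i * phases)) / sum(weights)
    n <- sum(weights)
  }
  list(mrl = Mod(z), mean_direction = Arg(z), n = n)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that a sample of angles is uniformly
#' distributed on the circle. The statistic is Z = n * R^2 with R the mean
#' resultant length; the p-value uses the standard series approximation,
#' accurate for n >= 10.
#'
#' @param phases Numeric vector of angles in radians, length >= 10.
#' @return A tibble with one row: `n`, `mrl`, `z` and `p_value`.
#' @export
#' @examples
#' set.seed(1)
#' rayleigh_test(runif(50, -pi, pi))
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 10L) {
    stop("Rayleigh test requires at least 10 angles, got ", n, call. = FALSE)
  }
  R <- Mod(mean(exp(1i * phases)))
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  tibble::tibble(n = n, mrl = R, z = Z, p_value = p)
}

#' Watson-Williams test for equality of mean directions
#'
#' Circular analogue of a one-way ANOVA: tests whether two or more groups of
#' angles share a common mean direction, assuming comparable concentration
#' across groups. Uses the standard F statistic with the 1 + 3/(8*kappa)
#' correction factor; a warning is issued when the pooled concentration
#' estimate is below 1, where the approximation degrades.
#'
#' @param groups A list of numeric vectors of angles (radians), each of
#'   length >= 10, or a data frame with columns `phase` and `group`.
#' @return A tibble with one row: `f`, `df1`, `df2`, `p_value`, `kappa`.
#' @export
watson_williams_test <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("phase", "group") %in% names(groups)))
    groups <- split(groups$phase, groups$group)
  }
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 10L)) {
    stop("every group must contain at least 10 angles", call. = FALSE)
  }
  N <- sum(n_i)
  # per-group and pooled resultant lengths (unnormalized)
  r_i <- vapply(groups, function(g) Mod(sum(exp(1i * g))), numeric(1))
  r_all <- Mod(sum(vapply(groups, function(g) sum(exp(1i * g)), complex(1))))
  rw <- sum(r_i) / N
  kappa <- kappa_from_mrl(rw)
  if (kappa < 1) {
    warning("pooled concentration estimate kappa < 1; ",
      "Watson-Williams approximation may be unreliable",
      call. = FALSE
    )
  }
  Fstat <- (1 + 3 / (8 * kappa)) *
    ((N - k) * (sum(r_i) - r_all)) / ((k - 1) * (N - sum(r_i)))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  tibble::tibble(
    f = Fstat, df1 = k - 1, df2 = N - k, p_value = p, kappa = kappa
  )
}

#' Invert the mean resultant length to a von Mises concentration
#'
#' Maximum-likelihood inversion of R = A1(kappa) = I1(kappa)/I0(kappa) using
#' Fisher's piecewise approximation.
#'
#' @param r Mean resultant length in \[0, 1).
#' @return Estimated concentration parameter kappa (>= 0).
#' @export
kappa_from_mrl <- function(r) {
  stopifnot(r >= 0, r <= 1)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else if (r < 1) {
    1 / (r^3 - 4 * r^2 + 3 * r)
  } else {
    Inf
  }
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. With `kappa = 0` the draw is
#' uniform on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (kappa < 1e-9) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(out + mu)
}
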