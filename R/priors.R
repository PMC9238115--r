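#' Specify a parameter prior by its first two moments
#'
#' A prior for one uncertain model input, identified by its distribution
#' family and by the mean and standard deviation on the natural scale of the
#' parameter. Shape parameters are derived later by [moment_match()], so a
#' configuration file only ever carries the quantities that are actually
#' reported in source studies.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet_row"`. Beta is used for probabilities and utilities, gamma
#'   for costs, lognormal for relative risks; `"dirichlet_row"` marks a
#'   transition-matrix row sampled jointly (see [dirichlet_row_params()]).
#' @param mean Central value on the natural scale.
#' @param sd Standard deviation on the natural scale. `sd = 0` denotes a
#'   degenerate (point-mass) prior; draws then return `mean` exactly.
#' @param bounds Optional length-2 numeric truncation interval.
#' @return An object of class `"prior_spec"`.
#' @examples
#' prior_spec("beta", 0.70, 0.072)
#' prior_spec("gamma", 9.14, 4.09)
#' @export
prior_spec <- function(family = c("beta", "gamma", "lognormal", "dirichlet_row"),
                       mean, sd, bounds = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(sd), length(sd) == 1L, sd >= 0)
  if (!is.null(bounds)) {
    stopifnot(is.numeric(bounds), length(bounds) == 2L, bounds[1] <= bounds[2])
  }
  structure(list(family = family, mean = mean, sd = sd, bounds = bounds),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> %s(mean = %g, sd = %g)%s\n", x$family, x$mean,
              x$sd, if (is.null(x$bounds)) "" else
                sprintf(" truncated to [%g, %g]", x$bounds[1], x$bounds[2])))
  invisible(x)
}

#' Method-of-moments distribution parameters for a prior
#'
#' Converts a `(mean, sd)` prior specification into the family's natural
#' shape parameters so that the distribution reproduces the two moments
#' exactly:
#' \itemize{
#'   \item beta: \eqn{\alpha = m(m(1-m)/s^2 - 1)}, \eqn{\beta = \alpha(1-m)/m};
#'   \item gamma: shape \eqn{(m/s)^2}, scale \eqn{s^2/m};
#'   \item lognormal: \eqn{\sigma^2 = \log(1 + s^2/m^2)},
#'     \eqn{\mu = \log m - \sigma^2/2}.
#' }
#' A zero-sd prior is returned as a point mass in every family.
#'
#' @param prior A [prior_spec()].
#' @param label Parameter name used in error messages.
#' @return A list with `family`, the family-specific parameters, and
#'   `degenerate` (logical; `TRUE` for point masses).
#' @examples
#' moment_match(prior_spec("beta", 0.70, 0.072))   # alpha ~ 27.66, beta ~ 11.85
#' moment_match(prior_spec("gamma", 95.05, 8.53))  # shape ~ 124.2, scale ~ 0.766
#' @export
moment_match <- function(prior, label = "parameter") {
  stopifnot(inherits(prior, "prior_spec"))
  m <- prior$mean; s <- prior$sd
  if (s == 0) {
    return(list(family = prior$family, degenerate = TRUE, value = m))
  }
  out <- switch(prior$family,
    beta = {
      if (m <= 0 || m >= 1)
        stop(sprintf("beta prior for '%s': mean must lie in (0,1), got %g",
                     label, m), call. = FALSE)
      if (s^2 >= m * (1 - m))
        stop(sprintf(
          "beta prior for '%s' is infeasible: sd^2 = %g >= mean(1-mean) = %g",
          label, s^2, m * (1 - m)), call. = FALSE)
      alpha <- m * (m * (1 - m) / s^2 - 1)
      list(family = "beta", degenerate = FALSE,
           shape1 = alpha, shape2 = alpha * (1 - m) / m)
    },
    gamma = {
      if (m <= 0)
        stop(sprintf("gamma prior for '%s': mean must be > 0", label),
             call. = FALSE)
      list(family = "gamma", degenerate = FALSE,
           shape = (m / s)^2, scale = s^2 / m)
    },
    lognormal = {
      if (m <= 0)
        stop(sprintf("lognormal prior for '%s': mean must be > 0", label),
             call. = FALSE)
      sigma2 <- log(1 + s^2 / m^2)
      list(family = "lognormal", degenerate = FALSE,
           meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    dirichlet_row = stop(
      "dirichlet_row priors are parameterised by dirichlet_row_params()",
      call. = FALSE)
  )
  out
}

#' Concentration parameters of a Dirichlet prior for a transition-matrix row
#'
#' A transition row has one printed standard deviation per off-diagonal
#' probability but a Dirichlet needs a single concentration scale. The
#' effective sample size is anchored to the component with the largest
#' reported SD: its marginal-beta SD under the Dirichlet,
#' \eqn{\sqrt{m(1-m)/(N+1)}}, is matched exactly, giving
#' \eqn{N = m(1-m)/s^2 - 1} and \eqn{\alpha_i = m_i N}.
#'
#' @param means Probabilities of the full row (summing to 1).
#' @param sds Standard deviations, positionally matching `means`; use `NA`
#'   (or 0) for components without a printed SD (typically the diagonal).
#' @param label Row name used in error messages.
#' @return A list with `alpha` (concentration vector), `n_eff`, and
#'   `degenerate` (`TRUE` when the row is a point mass, e.g. means `(1,0,0)`
#'   or all SDs zero).
#' @examples
#' dirichlet_row_params(c(0.899, 0.097, 0.004), c(NA, 0.029, 0.002))
#' @export
dirichlet_row_params <- function(means, sds, label = "row") {
  stopifnot(length(means) == length(sds))
  if (abs(sum(means) - 1) > 1e-9)
    stop(sprintf("transition row '%s': probabilities sum to %.12g, not 1",
                 label, sum(means)), call. = FALSE)
  if (any(means < 0))
    stop(sprintf("transition row '%s': negative probability", label),
         call. = FALSE)
  sds[is.na(sds)] <- 0
  if (all(sds == 0) || any(means >= 1 - 1e-12)) {
    if (!all(sds == 0) )
      warning(sprintf("transition row '%s' is degenerate; returning point mass",
                      label))
    return(list(alpha = means, n_eff = Inf, degenerate = TRUE, means = means))
  }
  k <- which.max(sds)
  m <- means[k]; s <- sds[k]
  if (s^2 >= m * (1 - m))
    stop(sprintf(
      "transition row '%s': SD %g too large for marginal mean %g", label, s, m),
      call. = FALSE)
  n_eff <- m * (1 - m) / s^2 - 1
  list(alpha = means * n_eff, n_eff = n_eff, degenerate = FALSE, means = means)
}

#' Draw from a moment-matched prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @param label Name used in error messages.
#' @return Numeric vector of length `n`; draws use R's global RNG stream.
#' @export
draw_prior <- function(prior, n = 1L, label = "parameter") {
  mm <- moment_match(prior, label)
  if (isTRUE(mm$degenerate)) return(rep(mm$value, n))
  x <- switch(mm$family,
    beta = stats::rbeta(n, mm$shape1, mm$shape2),
    gamma = stats::rgamma(n, shape = mm$shape, scale = mm$scale),
    lognormal = stats::rlnorm(n, mm$meanlog, mm$sdlog))
  if (!is.null(prior$bounds)) x <- pmin(pmax(x, prior$bounds[1]), prior$bounds[2])
  x
}

#' Draw transition-matrix rows from a Dirichlet prior
#'
#' Uses the standard gamma construction: independent
#' \eqn{G_i \sim \mathrm{Gamma}(\alpha_i, 1)} normalised to sum to one, so
#' every sampled row is exactly row-stochastic. Zero-probability components
#' are structural zeros and stay zero.
#'
#' @param dpar Result of [dirichlet_row_params()].
#' @param n Number of rows to draw.
#' @return An `n` x `length(alpha)` matrix of probabilities.
#' @export
draw_dirichlet_row <- function(dpar, n = 1L) {
  if (isTRUE(dpar$degenerate))
    return(matrix(rep(dpar$means, each = n), nrow = n))
  k <- length(dpar$alpha)
  g <- matrix(0, n, k)
  pos <- dpar$alpha > 0
  g[, pos] <- matrix(stats::rgamma(n * sum(pos), shape = rep(dpar$alpha[pos],
                                                             each = n)),
                     nrow = n)
  g / rowSums(g)
}
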