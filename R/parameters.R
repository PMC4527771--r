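PAR_NAMES <- c("theta1", "theta2", "thetaA", "m1", "m2", "t")

#' The six scaled IM model parameters
#'
#' All parameters are scaled by the neutral mutation rate u: the population
#' mutation parameters `theta = 4*N*u` for the two descendant populations and
#' the ancestral population, the backward-in-time migration rates `m/u`
#' (`m1` moves lineages currently in population 1 into population 2), and the
#' divergence time `t/u` in expected-mutations units.
#'
#' @param theta1,theta2,thetaA Nonnegative population mutation parameters.
#' @param m1,m2 Nonnegative scaled migration rates.
#' @param t Nonnegative scaled divergence time.
#' @return Named numeric vector of class `im_parameters`.
#' @export
im_parameters <- function(theta1 = 1, theta2 = 1, thetaA = 1,
                          m1 = 0, m2 = 0, t = 1) {
  p <- c(theta1 = theta1, theta2 = theta2, thetaA = thetaA,
         m1 = m1, m2 = m2, t = t)
  if (any(!is.finite(p)) || any(p < 0))
    stop("all IM parameters must be finite and nonnegative")
  structure(p, class = "im_parameters")
}

#' @export
print.im_parameters <- function(x, ...) {
  cat("<im_parameters>\n")
  print(unclass(round(x, 6)))
  invisible(x)
}

#' Uniform prior bounds for the six IM parameters
#'
#' Independent Uniform(0, bound) priors; all bounds default to 10.
#'
#' @param theta1,theta2,thetaA,m1,m2,t Positive upper bounds.
#' @return Named numeric vector of class `im_priors`.
#' @export
im_priors <- function(theta1 = 10, theta2 = 10, thetaA = 10,
                      m1 = 10, m2 = 10, t = 10) {
  b <- c(theta1 = theta1, theta2 = theta2, thetaA = thetaA,
         m1 = m1, m2 = m2, t = t)
  if (any(!is.finite(b)) || any(b <= 0)) stop("all prior bounds must be > 0")
  structure(b, class = "im_priors")
}

#' Log prior density of a parameter vector
#'
#' @param params [im_parameters()].
#' @param priors [im_priors()].
#' @return `sum(-log(bounds))` when every parameter lies in `[0, bound]`,
#'   `-Inf` otherwise.
#' @export
log_prior <- function(params, priors = im_priors()) {
  p <- unclass(params)[PAR_NAMES]
  b <- unclass(priors)[PAR_NAMES]
  if (any(p < 0) || any(p > b)) return(-Inf)
  -sum(log(b))
}

#' Draw a parameter vector from the prior
#'
#' @param priors [im_priors()].
#' @return [im_parameters()] with each component uniform on `[0, bound]`.
#' @export
sample_prior <- function(priors = im_priors()) {
  b <- unclass(priors)[PAR_NAMES]
  do.call(im_parameters, as.list(runif(6L) * b))
}

# reflect a value into [0, b]
reflect01 <- function(x, b) {
  if (b <= 0) stop("bound must be positive")
  x <- x %% (2 * b)
  ifelse(x > b, 2 * b - x, x)
}

#' Sliding-window proposal for one scalar parameter
#'
#' Adds a Uniform(-window/2, window/2) perturbation to the chosen parameter,
#' reflecting at 0 and at the prior upper bound so the move is symmetric
#' (log-Hastings ratio 0).
#'
#' @param params Current [im_parameters()].
#' @param which One of `"theta1"`, `"theta2"`, `"thetaA"`, `"m1"`, `"m2"`,
#'   `"t"`.
#' @param window Positive window width.
#' @param priors [im_priors()].
#' @return List with elements `params` (proposed vector) and `log_hastings`
#'   (always 0).
#' @export
propose_scalar_update <- function(params, which, window, priors = im_priors()) {
  if (!which %in% PAR_NAMES) stop("unknown parameter name: ", which)
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  b <- unclass(priors)[[which]]
  new <- reflect01(unclass(params)[[which]] + runif(1L, -window / 2, window / 2),
                   b)
  out <- params
  out[[which]] <- new
  list(params = out, log_hastings = 0)
}

# default proposal windows: bound / 5 per parameter
default_windows <- function(priors) {
  w <- unclass(priors)[PAR_NAMES] / 5
  as.list(w)
}
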