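# Stochastic samplers for caste sizes and event proportions.
#
# Most functions that take a number of individuals (or a proportion of
# workers) also accept a sampler created here, so that caste sizes and event
# proportions vary stochastically between calls.

#' Create a count sampler
#'
#' Returns a function that draws a non-negative integer count each time it is
#' called. Such samplers can be passed wherever a number of individuals is
#' expected (e.g. [createWorkers()], [buildUp()], [pullDroneGroupsFromDCA()]),
#' making those operations stochastic.
#'
#' Kinds:
#' * `"fixed"`: always returns `mean` (degenerate distribution),
#' * `"poisson"`: Poisson with the given mean,
#' * `"truncPoisson"`: zero-truncated Poisson (values >= 1), with
#'   expectation `mean / (1 - exp(-mean))`.
#'
#' @param kind one of `"fixed"`, `"poisson"`, `"truncPoisson"`.
#' @param mean non-negative mean parameter (the Poisson rate; for
#'   `"truncPoisson"` it must be positive).
#' @return A function of no required arguments returning one integer.
#' @examples
#' s <- makeCountSampler("truncPoisson", mean = 15)
#' s()
#' @export
makeCountSampler <- function(kind = c("fixed", "poisson", "truncPoisson"),
                             mean) {
  kind <- match.arg(kind)
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean < 0) {
    stopf("'mean' must be a single non-negative number")
  }
  f <- switch(kind,
    fixed = function() as.integer(round(mean)),
    poisson = function() stats::rpois(1L, lambda = mean),
    truncPoisson = {
      if (mean <= 0) stopf("a zero-truncated Poisson needs mean > 0")
      function() {
        # inverse-CDF draw conditional on X >= 1
        u <- stats::runif(1L, min = stats::dpois(0L, mean), max = 1)
        stats::qpois(u, lambda = mean)
      }
    }
  )
  structure(f, class = c("countSampler", "function"), kind = kind, mean = mean)
}

#' Create a proportion sampler
#'
#' Returns a function drawing a proportion in `[0, 1]`, usable wherever an
#' event proportion `p` is expected (e.g. [swarm()], [split()], [downsize()]).
#'
#' Kinds:
#' * `"fixed"`: always returns `p`,
#' * `"uniform"`: uniform on `[low, high]`,
#' * `"betaStrength"`: a beta draw whose mean increases with colony strength
#'   (number of workers): the mean is `strength / (strength + refStrength)`,
#'   so a colony at the reference strength swarms with half of its workers on
#'   average and stronger colonies leave with a larger share. `precision` is
#'   the beta sum-of-shapes parameter (larger = less variable).
#'
#' @param kind one of `"fixed"`, `"uniform"`, `"betaStrength"`.
#' @param p fixed proportion (kind `"fixed"`).
#' @param low,high uniform bounds within `[0, 1]` (kind `"uniform"`).
#' @param refStrength reference colony strength in workers (kind
#'   `"betaStrength"`); default 100, the default full-size worker count.
#' @param precision positive beta precision (kind `"betaStrength"`).
#' @return A function; for `"betaStrength"` it takes a `strength` argument.
#' @examples
#' u <- makeProportionSampler("uniform", low = 0.4, high = 0.6)
#' u()
#' b <- makeProportionSampler("betaStrength")
#' b(strength = 200) # tends to exceed b(strength = 50)
#' @export
makeProportionSampler <- function(kind = c("fixed", "uniform", "betaStrength"),
                                  p = 0.5, low = 0, high = 1,
                                  refStrength = 100, precision = 10) {
  kind <- match.arg(kind)
  f <- switch(kind,
    fixed = {
      if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
        stopf("'p' must lie within [0, 1]")
      }
      function() p
    },
    uniform = {
      if (low < 0 || high > 1 || low > high) {
        stopf("uniform bounds must satisfy 0 <= low <= high <= 1")
      }
      function() stats::runif(1L, low, high)
    },
    betaStrength = {
      if (refStrength <= 0 || precision <= 0) {
        stopf("'refStrength' and 'precision' must be positive")
      }
      function(strength = refStrength) {
        mu <- strength / (strength + refStrength)
        if (mu <= 0) return(0)
        stats::rbeta(1L, shape1 = mu * precision, shape2 = (1 - mu) * precision)
      }
    }
  )
  structure(f, class = c("proportionSampler", "function"), kind = kind)
}

# Mean of the betaStrength sampler at a given strength; used for tests and
# documentation of the monotonicity contract.
#' @noRd
betaStrengthMean <- function(strength, refStrength = 100) {
  strength / (strength + refStrength)
}
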