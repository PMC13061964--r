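#' Declarative sampling distributions for exposure parameters
#'
#' A `dist_spec` describes how one input of the probabilistic risk model is
#' sampled: a point mass (constant), a uniform range, a normal (optionally
#' truncated to a physical range), or a lognormal. Lognormals may be given
#' directly on the log scale or fitted from arithmetic moments with
#' [fit_lognormal()].
#'
#' @param value Constant returned for every draw.
#' @return A `dist_spec` object.
#' @name dist_spec
NULL

new_dist_spec <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  stopifnot(is.finite(value))
  new_dist_spec("point", list(value = value))
}

#' @param low,high Bounds of the uniform range (`low <= high`).
#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high) {
  if (!(is.finite(low) && is.finite(high) && low <= high)) {
    stop("uniform requires finite low <= high", call. = FALSE)
  }
  new_dist_spec("uniform", list(low = low, high = high))
}

#' @param mean,sd Normal mean and standard deviation (`sd >= 0`).
#' @param lower,upper Optional truncation bounds; draws are restricted to
#'   `[lower, upper]` by inverse-CDF sampling.
#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    stop("normal requires finite mean and sd >= 0", call. = FALSE)
  }
  if (!(lower <= upper)) {
    stop("truncation bounds must be ordered", call. = FALSE)
  }
  new_dist_spec("normal",
                list(mean = mean, sd = sd, lower = lower, upper = upper))
}

#' @param meanlog,sdlog Lognormal parameters on the log scale
#'   (`sdlog >= 0`).
#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog < 0) {
    stop("lognormal requires finite meanlog and sdlog >= 0", call. = FALSE)
  }
  new_dist_spec("lognormal", list(meanlog = meanlog, sdlog = sdlog))
}

#' Fit a lognormal to an arithmetic mean and standard deviation
#'
#' Concentration tables report arithmetic mean +/- SD, which does not pin
#' down a lognormal uniquely; two conventions are supported.
#' `"moment_matched"` preserves the arithmetic moments:
#' \deqn{\sigma^2 = \ln(1 + (sd/mean)^2), \quad
#'       \mu = \ln(mean) - \sigma^2/2,}
#' so the fitted distribution has exactly the stated mean and SD.
#' `"median_anchored"` pins the median to the reported mean
#' (\eqn{\mu = \ln(mean)}) with the same \eqn{\sigma}; the arithmetic mean
#' of that distribution is then larger than the reported value by
#' \eqn{e^{\sigma^2/2}}. With `sd = 0` both collapse to a point mass at
#' `mean`.
#'
#' @param arith_mean Arithmetic mean (> 0).
#' @param arith_sd Arithmetic standard deviation (>= 0).
#' @param mode `"median_anchored"` or `"moment_matched"`.
#' @return A [dist_lognormal()] spec.
#' @export
fit_lognormal <- function(arith_mean, arith_sd,
                          mode = c("median_anchored", "moment_matched")) {
  mode <- match.arg(mode)
  if (!is.finite(arith_mean) || arith_mean <= 0) {
    stop("arithmetic mean must be strictly positive", call. = FALSE)
  }
  if (!is.finite(arith_sd) || arith_sd < 0) {
    stop("arithmetic sd must be non-negative", call. = FALSE)
  }
  sigma2 <- log(1 + (arith_sd / arith_mean)^2)
  meanlog <- switch(mode,
    moment_matched = log(arith_mean) - sigma2 / 2,
    median_anchored = log(arith_mean)
  )
  dist_lognormal(meanlog = meanlog, sdlog = sqrt(sigma2))
}

#' Draw samples from a distribution spec
#'
#' Uses R's current RNG stream, so results are reproducible after
#' `set.seed()`. Truncated normals are drawn by the inverse-CDF method
#' (quantile of a uniform restricted to the CDF mass inside the bounds),
#' so every draw respects the bounds exactly.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws.
#' @return A numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' range(sample_dist(dist_uniform(350, 365), 1000)) # within [350, 365]
#' @export
sample_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) {
    stop("spec must be a dist_spec", call. = FALSE)
  }
  stopifnot(n >= 1)
  p <- spec$params
  switch(spec$kind,
    point = rep(p$value, n),
    uniform = stats::runif(n, p$low, p$high),
    normal = {
      if (is.infinite(p$lower) && is.infinite(p$upper)) {
        stats::rnorm(n, p$mean, p$sd)
      } else if (p$sd == 0) {
        if (p$mean < p$lower || p$mean > p$upper) {
          stop("truncation region has zero probability mass", call. = FALSE)
        }
        rep(p$mean, n)
      } else {
        plo <- stats::pnorm(p$lower, p$mean, p$sd)
        phi <- stats::pnorm(p$upper, p$mean, p$sd)
        if (phi - plo <= 0) {
          stop("truncation region has zero probability mass", call. = FALSE)
        }
        stats::qnorm(stats::runif(n, plo, phi), p$mean, p$sd)
      }
    },
    lognormal = {
      if (p$sdlog == 0) rep(exp(p$meanlog), n)
      else stats::rlnorm(n, p$meanlog, p$sdlog)
    },
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec: %s> %s\n", x$kind,
              paste(names(x$params), signif(unlist(x$params), 6),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
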