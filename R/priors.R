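#' Offset fossil-calibration prior on a node age
#'
#' A fossil dates the minimum age of a node; the prior places that hard
#' minimum at `offset` (Ma) and models the exceedance — how much older
#' the node may be — as either a lognormal or an exponential
#' distribution. For the lognormal, `mean` and `sd` are the *real-space*
#' mean and standard deviation of the exceedance, mapped internally to
#' log-scale parameters `sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`. For the exponential, `mean` is the
#' exceedance mean.
#'
#' @param kind `"offset_lognormal"` or `"offset_exponential"`.
#' @param offset Hard minimum age, Ma, `>= 0`.
#' @param mean Real-space mean of the part above the offset, `> 0`.
#' @param sd Real-space standard deviation (lognormal only), `> 0`.
#' @return An object of class `"calibration_prior"`.
#' @examples
#' pr <- calibration_prior("offset_lognormal", offset = 34, mean = 7, sd = 5)
#' quantile(pr, 0.5)   # ~39.7 Ma
#' summary(pr)
#' @export
calibration_prior <- function(kind = c("offset_lognormal", "offset_exponential"),
                              offset, mean, sd = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(offset), offset >= 0, is.numeric(mean), mean > 0)
  if (kind == "offset_lognormal") {
    if (is.null(sd) || !is.numeric(sd) || sd <= 0)
      stopf("offset_lognormal requires sd > 0")
    sigma2 <- log(1 + sd^2 / mean^2)
    pars <- list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
  } else {
    if (!is.null(sd)) warnf("sd is ignored for offset_exponential")
    pars <- list(rate = 1 / mean)
  }
  structure(list(kind = kind, offset = offset, mean = mean, sd = sd,
                 pars = pars),
            class = "calibration_prior")
}

#' @param x A `"calibration_prior"`.
#' @param probs Probabilities in `(0, 1)`.
#' @param ... Unused.
#' @rdname calibration_prior
#' @export
quantile.calibration_prior <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  if (any(probs <= 0 | probs >= 1)) stopf("probs must lie in (0, 1)")
  q <- if (x$kind == "offset_lognormal")
    qlnorm(probs, x$pars$meanlog, x$pars$sdlog)
  else
    qexp(probs, x$pars$rate)
  setNames(x$offset + q, paste0("q", probs))
}

#' Cumulative distribution function of a calibration prior
#' @param prior A `"calibration_prior"`.
#' @param x Ages in Ma.
#' @return `P(age <= x)`.
#' @export
prior_cdf <- function(prior, x) {
  y <- pmax(x - prior$offset, 0)
  if (prior$kind == "offset_lognormal")
    plnorm(y, prior$pars$meanlog, prior$pars$sdlog)
  else
    pexp(y, prior$pars$rate)
}

#' Draw random ages from a calibration prior
#' @inheritParams prior_cdf
#' @param n Number of draws.
#' @param seed Optional integer seed (drawn via an isolated RNG state).
#' @export
prior_sample <- function(prior, n, seed = NULL) {
  draw <- function() {
    if (prior$kind == "offset_lognormal")
      prior$offset + rlnorm(n, prior$pars$meanlog, prior$pars$sdlog)
    else
      prior$offset + rexp(n, prior$pars$rate)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @param object A `"calibration_prior"`.
#' @rdname calibration_prior
#' @export
summary.calibration_prior <- function(object, ...) {
  q <- quantile(object, c(0.025, 0.05, 0.5, 0.95, 0.975))
  out <- list(kind = object$kind, offset = object$offset,
              median = unname(q["q0.5"]),
              ci95 = unname(q[c("q0.025", "q0.975")]),
              quantiles = q)
  class(out) <- "summary.calibration_prior"
  out
}

#' @export
print.summary.calibration_prior <- function(x, ...) {
  cat(sprintf("%s prior: offset %.2f Ma\n", x$kind, x$offset))
  cat(sprintf("  median  %.2f Ma\n", x$median))
  cat(sprintf("  95%% CI  [%.2f, %.2f] Ma\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
print.calibration_prior <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Quantile table for one or more calibration priors
#' @param ... `"calibration_prior"` objects.
#' @return Data frame with one row per prior: kind, offset, mean, sd,
#'   median and 2.5/5/95/97.5% quantiles (Ma, reported to 0.01 Ma).
#' @export
prior_table <- function(...) {
  priors <- list(...)
  if (length(priors) == 1 && !inherits(priors[[1]], "calibration_prior"))
    priors <- priors[[1]]
  do.call(rbind, lapply(priors, function(p) {
    q <- quantile(p, c(0.025, 0.05, 0.5, 0.95, 0.975))
    data.frame(kind = p$kind, offset = p$offset, mean = p$mean,
               sd = if (is.null(p$sd)) NA_real_ else p$sd,
               q025 = round(q[["q0.025"]], 2), q05 = round(q[["q0.05"]], 2),
               median = round(q[["q0.5"]], 2), q95 = round(q[["q0.95"]], 2),
               q975 = round(q[["q0.975"]], 2), stringsAsFactors = FALSE)
  }))
}
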