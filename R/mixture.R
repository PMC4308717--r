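# Two-component Gaussian mixture for the dynamic-range (DNR) distribution.
# The DNR of orthologous genes is bimodal: a low-DNR component of genes whose
# expression varies little across tissues and species, and a high-DNR
# component of regulated genes. The constrained/unconstrained threshold is
# the intersection of the two weighted component densities between the means.

#' Fit a two-Gaussian mixture to dynamic-range values
#'
#' Maximum-likelihood EM fit of \eqn{w_1 N(\mu_1,\sigma_1^2) + w_2
#' N(\mu_2,\sigma_2^2)} with deterministic seeded k-means++ initialisation
#' (several restarts, best log-likelihood kept) and a variance floor guarding
#' against degenerate components. The classification threshold is the root of
#' \eqn{w_1 \phi(x;\mu_1,\sigma_1) = w_2 \phi(x;\mu_2,\sigma_2)} inside
#' \eqn{(\mu_1,\mu_2)}, located by bisection.
#'
#' @param x numeric vector of defined DNR values (log10 units); at least 50.
#' @param seed RNG seed for the initialisation draws.
#' @param tol EM convergence tolerance on the log-likelihood and bisection
#'   tolerance for the threshold (default `1e-6`).
#' @param max_iter maximum EM iterations per restart.
#' @param n_init number of k-means++ restarts (default 10).
#' @param var_floor lower bound on component variances (default `1e-4`).
#' @return object of class `dnr_mixture` with components `w`, `mu`, `sigma`
#'   (component 1 is the lower-mean component), `threshold`, `loglik`,
#'   `n_iter`, `n`, and the input summary used by [plot.dnr_mixture()].
#' @seealso [classify_constraint()] which applies the threshold to a DNR
#'   table.
#' @examples
#' x <- c(rnorm(200, 1, 0.4), rnorm(300, 3, 0.8))
#' fit <- fit_dnr_mixture(x, seed = 1)
#' fit
#' coef(fit)
#' @export
fit_dnr_mixture <- function(x, seed = 1L, tol = 1e-6, max_iter = 500L,
                            n_init = 10L, var_floor = 1e-4) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 50L) stop("need at least 50 defined DNR values to fit the mixture")

  best <- NULL
  local_seed(seed, {
    for (r in seq_len(n_init)) {
      centers <- kmeanspp_centers(x, 2L)
      fit <- em_gauss2(x, centers, tol = tol, max_iter = max_iter,
                       var_floor = var_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (min(best$sigma) <= sqrt(var_floor) + 1e-12 &&
      diff(range(x)) > 10 * sqrt(var_floor)) {
    stop("degenerate EM solution (sigma collapsed to the variance floor); ",
         "consider raising 'var_floor'")
  }
  thr <- mixture_intersection(best$w, best$mu, best$sigma, tol = tol)
  structure(c(best, list(threshold = thr, n = n,
                         data_summary = quantile(x, c(0, 0.25, 0.5, 0.75, 1)),
                         breaks = pretty(x, 50), x = x)),
            class = "dnr_mixture")
}

# k-means++ seeding for 1-D data: first centre uniform, second with
# probability proportional to squared distance from the first.
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1L] <- x[sample.int(length(x), 1L)]
  for (j in 2:k) {
    d2 <- (x - centers[j - 1L])^2
    if (all(d2 == 0)) d2 <- rep(1, length(x))
    centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
  }
  sort(centers)
}

em_gauss2 <- function(x, centers, tol, max_iter, var_floor) {
  n <- length(x)
  assign1 <- abs(x - centers[1L]) <= abs(x - centers[2L])
  w <- c(mean(assign1), mean(!assign1))
  w <- pmax(w, 1 / n)
  w <- w / sum(w)
  mu <- c(mean(x[assign1]), mean(x[!assign1]))
  sg <- c(sd(x[assign1]), sd(x[!assign1]))
  sg[!is.finite(sg) | sg < sqrt(var_floor)] <- max(sd(x) / 2, sqrt(var_floor))

  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d1 <- w[1L] * dnorm(x, mu[1L], sg[1L])
    d2 <- w[2L] * dnorm(x, mu[2L], sg[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    v1 <- sum(g1 * (x - mu[1L])^2) / n1
    v2 <- sum((1 - g1) * (x - mu[2L])^2) / n2
    sg <- sqrt(pmax(c(v1, v2), var_floor))
    if (!is.finite(ll)) break
    if (abs(ll - ll_old) < tol || iter >= max_iter) break
    ll_old <- ll
  }
  if (mu[1L] > mu[2L]) {
    w <- rev(w); mu <- rev(mu); sg <- rev(sg)
  }
  list(w = w, mu = mu, sigma = sg, loglik = ll, n_iter = iter)
}

# Root of w1*phi(x;mu1,s1) - w2*phi(x;mu2,s2) in (mu1, mu2) by bisection.
# The log-density difference is quadratic, so there are at most two roots;
# if none lies between the means both are reported in the error.
mixture_intersection <- function(w, mu, sigma, tol = 1e-6) {
  f <- function(x) {
    (log(w[1L]) - log(sigma[1L]) - (x - mu[1L])^2 / (2 * sigma[1L]^2)) -
      (log(w[2L]) - log(sigma[2L]) - (x - mu[2L])^2 / (2 * sigma[2L]^2))
  }
  lo <- mu[1L]; hi <- mu[2L]
  if (hi - lo < tol) return((lo + hi) / 2)
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    # solve the quadratic a x^2 + b x + c = 0 explicitly to report roots
    a <- 1 / (2 * sigma[2L]^2) - 1 / (2 * sigma[1L]^2)
    b <- mu[1L] / sigma[1L]^2 - mu[2L] / sigma[2L]^2
    cc <- (mu[2L]^2 / (2 * sigma[2L]^2) - mu[1L]^2 / (2 * sigma[1L]^2)) +
      log(w[1L] / sigma[1L]) - log(w[2L] / sigma[2L])
    disc <- b^2 - 4 * a * cc
    roots <- if (abs(a) < 1e-12) -cc / b else if (disc >= 0) {
      c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
    } else numeric(0)
    stop("no density intersection between the component means (roots: ",
         paste(sprintf("%.4f", roots), collapse = ", "), ")")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.dnr_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture of DNR values\n")
  cat(sprintf("  n = %d, log-likelihood = %.2f (%d EM iterations)\n",
              x$n, x$loglik, x$n_iter))
  cat(sprintf("  component 1 (constrained-like):   w = %.3f, mu = %.3f, sigma = %.3f\n",
              x$w[1L], x$mu[1L], x$sigma[1L]))
  cat(sprintf("  component 2 (unconstrained-like): w = %.3f, mu = %.3f, sigma = %.3f\n",
              x$w[2L], x$mu[2L], x$sigma[2L]))
  cat(sprintf("  density-intersection threshold: DNR = %.4f\n", x$threshold))
  invisible(x)
}

#' @export
summary.dnr_mixture <- function(object, ...) {
  print(object)
  cat("  DNR quartiles:\n")
  print(round(object$data_summary, 3))
  invisible(object)
}

#' @export
coef.dnr_mixture <- function(object, ...) {
  c(w1 = object$w[1L], w2 = object$w[2L],
    mu1 = object$mu[1L], mu2 = object$mu[2L],
    sigma1 = object$sigma[1L], sigma2 = object$sigma[2L],
    threshold = object$threshold)
}

#' @export
logLik.dnr_mixture <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n, class = "logLik")
}

#' Posterior component membership for new DNR values
#'
#' @param object `dnr_mixture` fit.
#' @param newdata numeric DNR values (defaults to the training values).
#' @param type `"class"` for the hard low/high component call implied by the
#'   threshold, `"posterior"` for the probability of the low-DNR component.
#' @param ... unused.
#' @export
predict.dnr_mixture <- function(object, newdata = NULL,
                                type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else newdata
  if (type == "class") {
    return(factor(ifelse(x <= object$threshold, "low", "high"),
                  levels = c("low", "high")))
  }
  d1 <- object$w[1L] * dnorm(x, object$mu[1L], object$sigma[1L])
  d2 <- object$w[2L] * dnorm(x, object$mu[2L], object$sigma[2L])
  d1 / (d1 + d2)
}

#' Histogram of DNR values with the fitted mixture overlaid
#'
#' @param x `dnr_mixture` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.dnr_mixture <- function(x, ...) {
  h <- graphics::hist(x$x, breaks = x$breaks, freq = FALSE,
                      main = "DNR mixture fit", xlab = "DNR (log10 units)", ...)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 400L)
  graphics::lines(xs, x$w[1L] * dnorm(xs, x$mu[1L], x$sigma[1L]), col = "steelblue", lwd = 2)
  graphics::lines(xs, x$w[2L] * dnorm(xs, x$mu[2L], x$sigma[2L]), col = "firebrick", lwd = 2)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}
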