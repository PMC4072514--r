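#' Fit the undivided CFSE peak in pooled resting wells
#'
#' The resting (unstimulated) wells contain only undivided cells, so their
#' log10 CFSE intensities form a single Gaussian peak. Its mean and SD seed
#' the constrained dilution mixture fitted to the stimulated wells. If the
#' input is multimodal the pooled mean/SD are still returned (documented
#' behaviour, no error).
#'
#' @param intensities Numeric vector of log10 CFSE intensities (pooled
#'   resting wells).
#' @param min_events Event floor (default 100).
#' @return List: `mu0`, `sigma0`, `n`.
#' @export
fit_resting_peak <- function(intensities, min_events = 100) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < min_events) {
    abort(sprintf("need at least %d events (%d supplied).",
                  min_events, length(x)),
          class = "temqtl_insufficient_data")
  }
  s <- sd(x)
  if (s == 0) {
    abort("degenerate resting peak: zero variance.",
          class = "temqtl_degenerate_peak")
  }
  list(mu0 = mean(x), sigma0 = s, n = length(x))
}

#' Constrained CFSE dilution mixture fit
#'
#' Deconvolves stimulated-well log10 CFSE intensities into division
#' generations with a one-dimensional Gaussian mixture constrained to the
#' dye-dilution geometry: component k (k = 0..`max_divisions`) has mean
#' `mu0 - k * d` (equal peak-to-peak spacing) and all components share one
#' SD. The undivided-peak location is initialized at the resting estimate
#' `mu0` and constrained to `mu0 +/- sigma0`; the spacing is initialized at
#' `log10(2)` (CFSE halves per division) and bounded in
#' `[0.7, 1.3] * log10(2)`; weights live on the simplex with zeros allowed.
#'
#' Optimization is a constrained EM: responsibilities give closed-form
#' weight updates, and `(mu0, d)` solve a weighted least-squares system,
#' projected into their boxes by coordinate passes, with the shared variance
#' re-estimated from the aligned residuals. Iteration stops when the
#' log-likelihood gain falls below `tol` or after `max_iter` iterations;
#' random restarts (re-initializing the weights) guard against local
#' optima and the best log-likelihood is kept.
#'
#' @param intensities Stimulated-well log10 CFSE intensities (>= 200
#'   events).
#' @param mu0,sigma0 Resting-peak estimates from [fit_resting_peak()].
#' @param max_divisions Maximum divisions modelled (default 5, i.e. at most
#'   six components).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @param n_restarts Additional random restarts (default 2).
#' @param seed Seed for restart initialization.
#' @return A `cfse_fit`: `mu0`, `d`, `sigma`, `w` (length 6, `w0..w5`),
#'   `loglik`, `loglik_trace`, `converged`, `n_events`.
#' @export
fit_cfse_mixture <- function(intensities, mu0, sigma0, max_divisions = 5,
                             tol = 1e-6, max_iter = 500, n_restarts = 2,
                             seed = 1L) {
  x <- intensities[is.finite(intensities)]
  if (length(x) == 0) {
    abort("no events supplied.", class = "temqtl_insufficient_data")
  }
  if (length(x) < 200) {
    abort("need at least 200 events for a stable dilution fit.",
          class = "temqtl_insufficient_data")
  }
  K <- max_divisions + 1L
  if (K > 6L) abort("at most 5 divisions (6 components) are supported.",
                    class = "temqtl_invalid_config")
  d0 <- log10(2)
  d_box <- c(0.7, 1.3) * d0
  mu_box <- c(mu0 - sigma0, mu0 + sigma0)
  ks <- 0:(K - 1L)
  n <- length(x)

  run_em <- function(w_init) {
    mu <- mu0; d <- d0; sig <- sigma0; w <- w_init
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      M <- outer(x, mu - ks * d, "-")            # n x K residuals
      L <- dnorm(M, sd = sig, log = TRUE)
      L <- sweep(L, 2, log(pmax(w, 1e-300)), "+")
      ll_row <- row_logsumexp(L)
      ll <- sum(ll_row)
      if (length(trace) && ll < tail(trace, 1) - 1e-8) break
      trace <- c(trace, ll)
      if (length(trace) > 1 &&
          trace[length(trace)] - trace[length(trace) - 1] < tol) {
        converged <- TRUE
        break
      }
      z <- exp(L - ll_row)
      w <- colSums(z) / n
      zk <- colSums(z)
      zk_k <- sum(zk * ks)
      # coordinate passes on (mu, d) with box projection
      for (pass in 1:2) {
        mu <- (sum(z * x) + d * zk_k) / n
        mu <- min(max(mu, mu_box[1]), mu_box[2])
        sk2 <- sum(zk * ks^2)
        if (sk2 > 0) {
          d <- (mu * zk_k - sum(sweep(z, 1, x, "*") %*% ks)) / sk2
          d <- min(max(d, d_box[1]), d_box[2])
        }
      }
      resid2 <- sum(z * (outer(x, mu - ks * d, "-"))^2) / n
      sig <- sqrt(max(resid2, 1e-8))
    }
    list(mu = mu, d = d, sig = sig, w = w, trace = trace,
         converged = converged)
  }

  inits <- list(rep(1 / K, K))
  if (n_restarts > 0) {
    extra <- with_seed(derive_seed(seed, "cfse_restarts"), {
      lapply(seq_len(n_restarts), function(i) {
        g <- -log(runif(K))
        g / sum(g)
      })
    })
    inits <- c(inits, extra)
  }
  fits <- lapply(inits, run_em)
  best <- fits[[which.max(vapply(fits, function(f) tail(f$trace, 1),
                                 numeric(1)))]]
  w6 <- c(best$w, rep(0, 6 - K))
  structure(list(mu0 = best$mu, d = best$d, sigma = best$sig, w = w6,
                 loglik = tail(best$trace, 1), loglik_trace = best$trace,
                 converged = best$converged, n_events = n),
            class = "cfse_fit")
}

#' Division and proliferation indices from a dilution fit
#'
#' The division index (DI) is the average number of divisions undergone by
#' all cells, `sum(k * w_k)`; the proliferation index (PI) is the average
#' over cells that divided at least once,
#' `sum(k * w_k, k >= 1) / sum(w_k, k >= 1)`. PI is flagged undefined when
#' essentially no cell divided (divided mass below `tol`).
#'
#' @param fit A `cfse_fit`, or a numeric vector of division weights
#'   (length <= 6, sum 1).
#' @param tol Divided-mass threshold below which PI is undefined (default
#'   1e-6).
#' @return Tibble: `di`, `pi`, `pi_defined`.
#' @examples
#' proliferation_metrics(c(0.5, 0.25, 0.25))  # DI 0.75, PI 1.5
#' @export
proliferation_metrics <- function(fit, tol = 1e-6) {
  w <- if (inherits(fit, "cfse_fit")) fit$w else check_division_weights(fit)
  ks <- 0:5
  di <- sum(ks * w)
  divided <- sum(w[-1])
  pi_defined <- divided >= tol
  tibble(di = di,
         pi = if (pi_defined) sum(ks[-1] * w[-1]) / divided else NA_real_,
         pi_defined = pi_defined)
}

#' Quantify proliferation for a full CFSE well set
#'
#' Pools the resting wells to estimate the undivided peak, fits the
#' constrained dilution mixture to each stimulated well separately, and
#' averages DI and PI across replicate wells.
#'
#' @param wellset A `cfse_well_set`.
#' @param ... Passed to [fit_cfse_mixture()].
#' @return List: `fits` (per stimulated well), `per_well` (tibble of
#'   per-well metrics), `di`, `pi`, `resting` (peak estimates).
#' @export
quantify_proliferation <- function(wellset, ...) {
  stopifnot(inherits(wellset, "cfse_well_set"))
  pooled <- unlist(wellset$resting)
  peak <- fit_resting_peak(pooled)
  fits <- lapply(wellset$stimulated, function(x) {
    fit_cfse_mixture(x, peak$mu0, peak$sigma0, ...)
  })
  per_well <- purrr::map_dfr(seq_along(fits), function(i) {
    m <- proliferation_metrics(fits[[i]])
    dplyr::mutate(m, well = i, converged = fits[[i]]$converged,
                  .before = 1)
  })
  list(fits = fits, per_well = per_well,
       di = mean(per_well$di), pi = mean(per_well$pi, na.rm = TRUE),
       resting = peak)
}

#' @export
print.cfse_fit <- function(x, ...) {
  m <- proliferation_metrics(x)
  cat(sprintf("<cfse_fit> %d events: mu0 = %.3f, spacing = %.3f, sigma = %.3f\n",
              x$n_events, x$mu0, x$d, x$sigma))
  cat(sprintf("  weights: %s\n", paste(sprintf("%.3f", x$w), collapse = " ")))
  cat(sprintf("  DI = %.3f, PI = %s (%s)\n", m$di,
              ifelse(m$pi_defined, sprintf("%.3f", m$pi), "undefined"),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
tidy.cfse_fit <- function(x, ...) {
  tibble(division = 0:5, mean = x$mu0 - (0:5) * x$d, sd = x$sigma,
         weight = x$w)
}

#' @export
glance.cfse_fit <- function(x, ...) {
  m <- proliferation_metrics(x)
  tibble(mu0 = x$mu0, spacing = x$d, sigma = x$sigma, loglik = x$loglik,
         converged = x$converged, n_events = x$n_events, di = m$di,
         pi = m$pi)
}
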