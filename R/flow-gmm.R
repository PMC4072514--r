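# Row-wise log density of a trivariate Gaussian via the Cholesky factor.
dmvnorm_log <- function(X, mean, cov) {
  R <- chol(cov)
  V <- sweep(X, 2, mean)
  W <- t(forwardsolve(t(R), t(V)))
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(R))) + rowSums(W^2))
}

# log-sum-exp over rows of a matrix of component log densities
row_logsumexp <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

#' Template-guided gating by a 7-component Gaussian mixture
#'
#' Fits a full-covariance trivariate Gaussian mixture to flow events by EM,
#' initialized at the supplied population template so that components keep
#' their biological identity (automated template-guided gating). After
#' convergence each fitted component is relabeled by the nearest template
#' component (Mahalanobis distance between means under the template
#' covariance, matched one-to-one). The per-iteration log-likelihood trace
#' is retained and is non-decreasing.
#'
#' @param sample A `flow_sample` (events x 3 matrix of transformed
#'   intensities).
#' @param template A `population_template` with exactly one `TEM` and one
#'   `debris` component.
#' @param max_iter EM iteration cap (default 200). `max_iter = 0` returns
#'   the template unchanged with posteriors computed under it.
#' @param tol Stop when the log-likelihood gain drops below this (default
#'   1e-6).
#' @param min_events Event floor (default 350, i.e. 50 per component).
#' @param cov_det_floor Covariance determinant below which a component is
#'   declared collapsed; it is re-seeded from the template once, then the
#'   fit is flagged failed.
#' @return A `population_fit`: fitted `labels`, `weights`, `means`, `covs`,
#'   the n x 7 `posterior` matrix, hard `assignments`, `loglik_trace`,
#'   `converged`, `collapsed`, `n_events`.
#' @export
fit_population_model <- function(sample, template, max_iter = 200,
                                 tol = 1e-6, min_events = 350,
                                 cov_det_floor = 1e-12) {
  stopifnot(inherits(template, "population_template"))
  X <- sample$events
  n <- nrow(X)
  if (n < min_events) {
    abort(sprintf("need at least %d events (%d supplied).", min_events, n),
          class = "temqtl_insufficient_data")
  }
  K <- 7L
  w <- template$weights
  means <- template$means
  covs <- template$covs

  e_step <- function(w, means, covs) {
    L <- vapply(seq_len(K), function(k) {
      log(w[k]) + dmvnorm_log(X, means[[k]], covs[[k]])
    }, numeric(n))
    ll_row <- row_logsumexp(L)
    list(post = exp(L - ll_row), loglik = sum(ll_row))
  }

  es <- e_step(w, means, covs)
  trace <- es$loglik
  collapsed <- FALSE
  reseeded <- rep(FALSE, K)
  iter <- 0
  converged <- max_iter == 0
  while (iter < max_iter) {
    iter <- iter + 1
    z <- es$post
    nk <- colSums(z)
    w_new <- nk / n
    means_new <- lapply(seq_len(K), function(k) colSums(z[, k] * X) / nk[k])
    covs_new <- lapply(seq_len(K), function(k) {
      V <- sweep(X, 2, means_new[[k]])
      S <- crossprod(V * z[, k], V) / nk[k]
      (S + t(S)) / 2 + diag(1e-8, 3)
    })
    for (k in seq_len(K)) {
      if (det(covs_new[[k]]) < cov_det_floor || nk[k] < 1e-8) {
        if (!reseeded[k]) {
          reseeded[k] <- TRUE
          means_new[[k]] <- template$means[[k]]
          covs_new[[k]] <- template$covs[[k]]
          w_new[k] <- 1e-3
          w_new <- w_new / sum(w_new)
        } else {
          collapsed <- TRUE
        }
      }
    }
    if (collapsed) break
    es_new <- e_step(w_new, means_new, covs_new)
    if (es_new$loglik < tail(trace, 1) - 1e-8) break  # numerical guard
    w <- w_new; means <- means_new; covs <- covs_new
    es <- es_new
    trace <- c(trace, es$loglik)
    if (length(trace) > 1 &&
        trace[length(trace)] - trace[length(trace) - 1] < tol) {
      converged <- TRUE
      break
    }
  }
  if (iter >= max_iter && !converged) converged <- FALSE

  # relabel: one-to-one match of fitted means to template means by
  # Mahalanobis distance under the template covariances
  D <- matrix(Inf, K, K)
  for (k in seq_len(K)) {
    for (j in seq_len(K)) {
      v <- means[[k]] - template$means[[j]]
      D[k, j] <- drop(v %*% solve(template$covs[[j]], v))
    }
  }
  labels <- character(K)
  Dw <- D
  for (step in seq_len(K)) {
    idx <- arrayInd(which.min(Dw), dim(Dw))
    labels[idx[1]] <- template$labels[idx[2]]
    Dw[idx[1], ] <- Inf
    Dw[, idx[2]] <- Inf
  }
  assignments <- labels[max.col(es$post)]
  structure(list(labels = labels, weights = w, means = means, covs = covs,
                 posterior = es$post, assignments = assignments,
                 loglik_trace = trace, converged = converged,
                 collapsed = collapsed, n_events = n),
            class = "population_fit")
}

#' TEM abundance from a fitted population model
#'
#' Relative abundance of the effector-memory population as a percentage of
#' all CD4 T cells: the posterior mass of the `TEM` component divided by the
#' total posterior mass of all non-`debris` components, times 100.
#'
#' @param fit A `population_fit` from [fit_population_model()].
#' @return Percentage in [0, 100].
#' @export
quantify_tem_abundance <- function(fit) {
  stopifnot(inherits(fit, "population_fit"))
  mass <- colSums(fit$posterior)
  tem <- sum(mass[fit$labels == "TEM"])
  denom <- sum(mass[fit$labels != "debris"])
  if (denom <= 0) {
    abort("all posterior mass assigned to debris; abundance undefined.",
          class = "temqtl_undefined_abundance")
  }
  100 * tem / denom
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> %d events, %d EM iterations, %s\n",
              x$n_events, length(x$loglik_trace) - 1,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
tidy.population_fit <- function(x, ...) {
  tibble(
    component = seq_along(x$labels), label = x$labels,
    weight = x$weights,
    mean_CD45RA = vapply(x$means, `[`, numeric(1), 1),
    mean_CD45RO = vapply(x$means, `[`, numeric(1), 2),
    mean_CD62L = vapply(x$means, `[`, numeric(1), 3)
  )
}

#' @export
glance.population_fit <- function(x, ...) {
  tibble(n_events = x$n_events, loglik = tail(x$loglik_trace, 1),
         n_iter = length(x$loglik_trace) - 1, converged = x$converged,
         collapsed = x$collapsed)
}
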