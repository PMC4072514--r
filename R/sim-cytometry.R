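#' Simulate a CFSE dye-dilution experiment
#'
#' CFSE intensity halves at each cell division, so on a log10 axis divided
#' generations appear as equally spaced peaks below the undivided peak.
#' The resting well is a single Gaussian at `mu0`; each stimulated well is a
#' mixture whose k-th component (k = 0..5 divisions) sits at
#' `mu0 - k * spacing` with shared SD `sigma` and the supplied weights.
#'
#' @param weights Per-division proportions (length <= 6, nonnegative, sum 1).
#' @param config A [sim_cohort_config()]; its `cfse` entry supplies `mu0`,
#'   `spacing`, `sigma` and the default `n_events`.
#' @param n_wells_stim Number of replicate stimulated wells.
#' @param n_events Events per well; 0 gives an empty, flagged well.
#' @param seed Seed; defaults to a stream derived from `config$seed`.
#' @return A `cfse_well_set`: list with `resting` and `stimulated` (lists of
#'   log10-intensity vectors), `scale = "log10"`, and a `truth` list
#'   (weights, mu0, spacing, sigma). Empty wells carry attribute
#'   `empty = TRUE`.
#' @export
simulate_cfse_experiment <- function(weights, config,
                                     n_wells_stim = 2,
                                     n_events = config$cfse$n_events,
                                     seed = derive_seed(config$seed, "cfse")) {
  weights <- check_division_weights(weights)
  p <- config$cfse
  with_seed(seed, {
    draw_well <- function(w) {
      if (n_events == 0) {
        return(structure(numeric(0), empty = TRUE))
      }
      k <- sample.int(6L, n_events, replace = TRUE, prob = w) - 1L
      rnorm(n_events, p$mu0 - k * p$spacing, p$sigma)
    }
    resting <- list(draw_well(c(1, rep(0, 5))))
    stimulated <- lapply(seq_len(n_wells_stim), function(i) draw_well(weights))
  })
  structure(list(resting = resting, stimulated = stimulated, scale = "log10",
                 truth = list(weights = weights, mu0 = p$mu0,
                              spacing = p$spacing, sigma = p$sigma)),
            class = "cfse_well_set")
}

check_division_weights <- function(weights) {
  if (length(weights) > 6 || any(weights < 0)) {
    abort("division weights must be nonnegative with length <= 6.",
          class = "temqtl_invalid_weights")
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    abort("division weights must sum to 1.", class = "temqtl_invalid_weights")
  }
  c(weights, rep(0, 6 - length(weights)))
}

#' Seven-population template for CD4 T-cell flow cytometry
#'
#' Builds the gating template used by [fit_population_model()]: seven
#' trivariate Gaussian components on transformed CD45RA / CD45RO / CD62L
#' intensities. The `TEM` component is CD45RA-, CD45RO+, CD62L-low; the
#' `debris` component sits low in all three channels and is excluded from
#' abundance denominators.
#'
#' @param tem_weight Share of the TEM population among non-debris events
#'   (default 0.0957, the cohort mean relative abundance).
#' @param debris_weight Share of debris among all events.
#' @return A `population_template`: list with `labels`, `weights`, `means`
#'   (list of 3-vectors) and `covs` (list of 3x3 matrices).
#' @export
default_population_template <- function(tem_weight = 0.0957,
                                        debris_weight = 0.08) {
  labels <- c("naive", "TCM", "TEM", "TEMRA", "transitional", "activated",
              "debris")
  means <- list(
    naive        = c(3.0, 1.0, 3.0),
    TCM          = c(1.0, 3.0, 3.0),
    TEM          = c(1.0, 3.0, 1.0),
    TEMRA        = c(3.0, 1.0, 1.0),
    transitional = c(2.0, 2.0, 2.2),
    activated    = c(1.2, 3.2, 2.1),
    debris       = c(0.3, 0.3, 0.3)
  )
  covs <- lapply(c(0.06, 0.06, 0.05, 0.06, 0.08, 0.06, 0.1), function(v) {
    diag(v, 3)
  })
  share <- c(naive = 0.38, TCM = 0.26, TEM = NA, TEMRA = 0.06,
             transitional = 0.12, activated = 0.0843)
  rest <- 1 - tem_weight
  share[is.na(share)] <- tem_weight
  share[names(share) != "TEM"] <-
    share[names(share) != "TEM"] / sum(share[names(share) != "TEM"]) * rest
  weights <- c(share * (1 - debris_weight), debris = debris_weight)
  new_population_template(labels, unname(weights), means, covs)
}

new_population_template <- function(labels, weights, means, covs) {
  if (length(labels) != 7 || length(weights) != 7 ||
      length(means) != 7 || length(covs) != 7) {
    abort("a population template must have exactly 7 components.",
          class = "temqtl_invalid_template")
  }
  if (sum(labels == "TEM") != 1 || sum(labels == "debris") != 1) {
    abort("template must contain exactly one `TEM` and one `debris` label.",
          class = "temqtl_invalid_template")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("template weights must be nonnegative and sum to 1.",
          class = "temqtl_invalid_template")
  }
  for (S in covs) {
    if (!isSymmetric(unname(S)) || inherits(try(chol(S), silent = TRUE), "try-error")) {
      abort("template covariances must be symmetric positive-definite.",
            class = "temqtl_invalid_template")
    }
  }
  structure(list(labels = labels, weights = weights,
                 means = means, covs = covs),
            class = "population_template")
}

#' Simulate a flow-cytometry sample from a population template
#'
#' @param template A `population_template` (7 components).
#' @param weights Mixing proportions over the 7 components (sum 1); defaults
#'   to the template's own weights.
#' @param n_events Number of events to draw.
#' @param seed Integer seed.
#' @return A `flow_sample`: list with `events` (n x 3 matrix, columns
#'   CD45RA, CD45RO, CD62L), `transform = "log10"` and `labels` (true
#'   component label per event, kept for testing).
#' @export
simulate_flow_sample <- function(template, weights = template$weights,
                                 n_events = 20000, seed = 1L) {
  stopifnot(inherits(template, "population_template"))
  if (length(weights) != 7 || abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must have length 7 and sum to 1.",
          class = "temqtl_invalid_weights")
  }
  with_seed(seed, {
    comp <- sample.int(7L, n_events, replace = TRUE, prob = weights)
    z <- matrix(rnorm(n_events * 3), n_events, 3)
    events <- matrix(0, n_events, 3,
                     dimnames = list(NULL, c("CD45RA", "CD45RO", "CD62L")))
    for (k in seq_len(7)) {
      idx <- comp == k
      if (!any(idx)) next
      R <- chol(template$covs[[k]])
      events[idx, ] <- z[idx, , drop = FALSE] %*% R +
        matrix(template$means[[k]], sum(idx), 3, byrow = TRUE)
    }
  })
  structure(list(events = events, transform = "log10",
                 labels = template$labels[comp]),
            class = "flow_sample")
}
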