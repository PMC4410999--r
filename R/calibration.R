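#' Calibration objective: mean square error against field biomass
#'
#' Runs the simulator with a candidate parameter table, averages the
#' equilibrium aboveground biomass (census threshold, total and per PFT)
#' over the evaluation window, and returns the weighted mean square error
#' against the field targets — the misfit minimised by the inverse
#' parameterization.
#'
#' @param params Candidate PFT parameter table.
#' @param targets A `field_targets` object ([field_statistics()]).
#' @param config Global configuration.
#' @param years,window,replicates,area_ha Simulation settings per evaluation.
#' @param seed Seed for the evaluation (the objective is deterministic given
#'   the seed).
#' @param weight_total,weight_pft Weights of the total-AGB and per-PFT-AGB
#'   error terms.
#' @return Scalar MSE (>= 0); non-finite simulation output returns a large
#'   penalty value with a warning.
#' @export
calibration_objective <- function(params, targets, config = forest_config(),
                                  years = 300, window = c(150, 300),
                                  replicates = 2, area_ha = 1, seed = 1,
                                  weight_total = 1, weight_pft = 1) {
  sim <- try(simulate_forest(params, config, years = years,
                             area_ha = area_ha, replicates = replicates,
                             seed = seed), silent = TRUE)
  if (inherits(sim, "try-error")) {
    warning("simulation failed during calibration; penalty applied",
            call. = FALSE)
    return(1e12)
  }
  es <- equilibrium_stats(sim, window)
  sim_tot <- es$mean[es$variable == "agb10" & is.na(es$pft)]
  per <- es[es$variable == "agb10" & !is.na(es$pft), ]
  obs_per <- targets$by_pft$agb[match(per$pft, targets$by_pft$pft)]
  err <- c(sim_tot - targets$total$agb, per$mean - obs_per)
  w <- c(weight_total, rep(weight_pft, nrow(per)))
  if (any(!is.finite(err))) {
    warning("non-finite simulated biomass; penalty applied", call. = FALSE)
    return(1e12)
  }
  sum(w * err^2) / sum(w)
}

mse_components <- function(simulated, observed, weights = NULL) {
  stopifnot(length(simulated) == length(observed))
  if (is.null(weights)) weights <- rep(1, length(simulated))
  sum(weights * (simulated - observed)^2) / sum(weights)
}

apply_free_values <- function(params, free, values) {
  for (i in seq_len(nrow(free))) {
    par <- free$parameter[i]
    if (!par %in% names(params)) {
      stop("unknown free parameter: ", par, call. = FALSE)
    }
    if (is.na(free$pft[i])) {
      params[[par]] <- rep(values[i], nrow(params))
    } else {
      params[[par]][params$pft == free$pft[i]] <- values[i]
    }
  }
  params
}

#' Inverse parameterization of growth and mortality parameters
#'
#' Searches a box of free parameters (Latin-hypercube, uniform-random or
#' grid sampling) to minimise [calibration_objective()]: the mean square
#' error between simulated equilibrium aboveground biomass (total and per
#' PFT) and the field inventory targets. Every evaluation is recorded in a
#' ledger; the best parameter vector is the ledger's argmin.
#'
#' @param targets A `field_targets` object.
#' @param free A tibble `parameter, pft, lower, upper`; `pft = NA` varies
#'   the parameter for all PFTs at once.
#' @param params Base PFT parameter table.
#' @param config Global configuration.
#' @param n_evaluations Number of sampled parameter vectors.
#' @param sampler `"lhs"`, `"random"` or `"grid"`.
#' @param years,window,replicates,area_ha Simulation settings per evaluation.
#' @param seed Master seed (sampling plan and evaluation seeds derive from
#'   it; rerunning reproduces the ledger exactly).
#' @param weight_total,weight_pft Objective weights.
#' @return An object of class `forest_calibration`: list with `best_params`
#'   (full PFT table at the optimum), `best` (one-row tibble of free values
#'   + mse), `ledger` (tibble: eval, free values, mse), `free`, and the
#'   settings. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
calibrate_forest <- function(targets, free, params = pft_parameters(),
                             config = forest_config(),
                             n_evaluations = 500, sampler = c("lhs", "random",
                                                             "grid"),
                             years = 300, window = c(150, 300),
                             replicates = 2, area_ha = 1, seed = 1,
                             weight_total = 1, weight_pft = 1) {
  sampler <- match.arg(sampler)
  if (n_evaluations < 1) stop("n_evaluations must be >= 1", call. = FALSE)
  stopifnot(all(free$lower < free$upper), all(is.finite(free$lower)),
            all(is.finite(free$upper)))
  k <- nrow(free)
  set.seed(seed)
  U <- switch(sampler,
    lhs = lhs::randomLHS(n_evaluations, k),
    random = matrix(stats::runif(n_evaluations * k), n_evaluations, k),
    grid = {
      m <- ceiling(n_evaluations^(1 / k))
      g <- as.matrix(expand.grid(rep(list(seq(0, 1, length.out = m)), k)))
      g[seq_len(min(nrow(g), n_evaluations)), , drop = FALSE]
    })
  X <- sweep(sweep(U, 2, free$upper - free$lower, "*"), 2, free$lower, "+")
  eval_seeds <- sample.int(.Machine$integer.max - 1, nrow(X))

  mse <- vapply(seq_len(nrow(X)), function(i) {
    p_i <- apply_free_values(params, free, X[i, ])
    calibration_objective(p_i, targets, config, years = years,
                          window = window, replicates = replicates,
                          area_ha = area_ha, seed = eval_seeds[i],
                          weight_total = weight_total,
                          weight_pft = weight_pft)
  }, numeric(1))

  colnames(X) <- free_names <- paste0(
    free$parameter, ifelse(is.na(free$pft), "", paste0("_pft", free$pft)))
  ledger <- dplyr::bind_cols(tibble::tibble(eval = seq_len(nrow(X))),
                             tibble::as_tibble(X),
                             tibble::tibble(mse = mse))
  ibest <- which.min(mse)
  best <- ledger[ibest, ]
  structure(
    list(best_params = apply_free_values(params, free, X[ibest, ]),
         best = best, ledger = ledger, free = free,
         settings = list(n_evaluations = n_evaluations, sampler = sampler,
                         years = years, window = window,
                         replicates = replicates, area_ha = area_ha,
                         seed = seed)),
    class = "forest_calibration")
}

#' @export
print.forest_calibration <- function(x, ...) {
  cat("Inverse parameterization: ", nrow(x$ledger), " evaluations (",
      x$settings$sampler, " sampling)\n", sep = "")
  cat("Best MSE:", format(x$best$mse, digits = 5), "\n")
  print(x$best, ...)
  invisible(x)
}

#' @export
tidy.forest_calibration <- function(x, ...) x$ledger

#' @export
glance.forest_calibration <- function(x, ...) {
  dplyr::mutate(x$best,
                n_evaluations = nrow(x$ledger),
                sampler = x$settings$sampler)
}
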