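# Extended-least-squares calibration of selected fixture parameters
# against mean blood-BHB concentration data at two dose levels, local
# sensitivity analysis, and the prediction/data overlay.

#' Define an extended-least-squares estimation problem
#'
#' @param fixture the `keto_fixture` holding all fixed parameter values;
#'   free parameters are overridden during estimation.
#' @param dataset a dataset data frame (columns `dose_mg_per_kg`,
#'   `time_h`, `mean_mM`, `sem_mM`, `n`), e.g. from
#'   [generate_dataset()] or [read_dataset()].
#' @param free named list: free parameter name -> `c(lower, upper)`
#'   bounds (finite, positive where the parameter is a rate or
#'   capacity).
#' @param start optional named numeric start values (defaults to the
#'   geometric mid-point of the bounds).
#' @param var_a,var_b residual-variance model parameters: the variance
#'   of an observation with prediction `yhat` is `(var_a + var_b *
#'   yhat)^2` (additive + proportional combined error). `var_a` should
#'   not be set below the assay LLOQ scale.
#' @param lloq observations with mean below this are excluded from the
#'   objective (default: the fixture's `lloq_mM`).
#' @param multistart number of optimizer starts (first start is `start`,
#'   the rest are seeded log-uniform draws within the bounds).
#' @param seed RNG seed making the multistart deterministic.
#' @param maxit iteration cap per start.
#' @param rtol,atol solver tolerances used inside the objective.
#' @return An `keto_estimation` problem object.
#' @export
estimation_problem <- function(fixture, dataset, free, start = NULL,
                               var_a = 1, var_b = 0, lloq = NULL,
                               multistart = 5L, seed = 1L, maxit = 200L,
                               rtol = 1e-6, atol = 1e-8) {
  if (!length(free)) stop("the free parameter set must be non-empty")
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(upper <= lower))
    stop("bounds must be finite, positive and ordered")
  fixture_value(fixture, names(free))  # all free names must exist
  if (is.null(start)) start <- sqrt(lower * upper)
  start <- stats::setNames(pmin(pmax(start, lower), upper), names(free))
  check_nonneg(var_a, "var_a"); check_nonneg(var_b, "var_b")
  if (var_a + var_b <= 0) stop("variance model must be positive")
  structure(list(
    fixture = fixture, dataset = dataset, free = free,
    lower = lower, upper = upper, start = start,
    var_a = var_a, var_b = var_b,
    lloq = lloq %||% unname(fixture_value(fixture, "lloq_mM")),
    multistart = as.integer(multistart), seed = as.integer(seed),
    maxit = as.integer(maxit), rtol = rtol, atol = atol,
    cache = new.env(parent = emptyenv())
  ), class = "keto_estimation")
}

# Predict mean blood BHB at the dataset's (dose, time) points for the
# fixture with `params` applied. The equilibrated baseline is reused as
# a warm start between objective evaluations.
predict_dataset <- function(params, problem) {
  fix <- fixture_set(problem$fixture, names(params), unname(params))
  model <- build_ketone_model(fix, check_monotonicity = FALSE)
  base <- equilibrate(model, init = problem$cache$baseline,
                      rtol = problem$rtol, atol = problem$atol)
  problem$cache$baseline <- base
  out <- problem$dataset
  out$pred_mM <- NA_real_
  for (dose in unique(out$dose_mg_per_kg)) {
    idx <- out$dose_mg_per_kg == dose
    tt <- out$time_h[idx]
    grid <- sort(unique(c(0, tt)))
    sim <- run_dose(model, dose, baseline = base, t_grid = grid,
                    rtol = problem$rtol, atol = problem$atol)
    out$pred_mM[idx] <- sim$conc[match(tt, sim$time)]
  }
  out
}

#' Extended-least-squares objective
#'
#' `sum((y - yhat)^2 / g + log(g))` over all retained (dose, time)
#' observations, with variance model `g = (var_a + var_b * yhat)^2`.
#' Observations whose mean is below the LLOQ are excluded. A failed
#' simulation yields a large finite penalty (recorded on the problem)
#' rather than an error, so bounded optimisation can continue.
#'
#' @param params named numeric vector of free parameter values (within
#'   bounds).
#' @param problem an [estimation_problem()].
#' @return Scalar objective value.
#' @export
els_objective <- function(params, problem) {
  pred <- tryCatch(predict_dataset(params, problem), error = function(e) e)
  if (inherits(pred, "error")) {
    problem$cache$failures <- c(problem$cache$failures,
                                conditionMessage(pred))
    return(1e10)
  }
  keep <- pred$mean_mM >= problem$lloq
  y <- pred$mean_mM[keep]
  yhat <- pred$pred_mM[keep]
  g <- (problem$var_a + problem$var_b * yhat)^2
  sum((y - yhat)^2 / g + log(g))
}

#' Fit the free parameters by bounded multistart minimisation
#'
#' Runs L-BFGS-B from `multistart` seeded start points and returns the
#' best local minimum. Deterministic given the problem seed.
#'
#' @param problem an [estimation_problem()].
#' @return A `keto_fit` list: `estimates`, `objective`, `convergence`
#'   (0 = converged), `starts` (per-start trace), `seed`.
#' @export
fit_els <- function(problem) {
  np <- length(problem$start)
  starts <- matrix(NA_real_, problem$multistart, np)
  starts[1, ] <- problem$start
  if (problem$multistart > 1) {
    rng <- local({
      set.seed(problem$seed)
      matrix(stats::runif((problem$multistart - 1) * np),
             problem$multistart - 1, np)
    })
    for (j in seq_len(np))
      starts[-1, j] <- exp(log(problem$lower[j]) +
                             rng[, j] * (log(problem$upper[j]) -
                                           log(problem$lower[j])))
  }
  runs <- lapply(seq_len(problem$multistart), function(i) {
    par0 <- stats::setNames(starts[i, ], names(problem$start))
    fit <- stats::optim(
      par0, function(p) els_objective(stats::setNames(p, names(par0)),
                                      problem),
      method = "L-BFGS-B", lower = problem$lower, upper = problem$upper,
      control = list(maxit = problem$maxit, factr = 1e7,
                     parscale = par0))
    list(start = par0, par = fit$par, value = fit$value,
         convergence = fit$convergence, message = fit$message,
         counts = fit$counts)
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  if (all(values >= 1e10))
    stop("no optimizer start converged; traces: ",
         paste(sprintf("start %d: %.4g", seq_along(values), values),
               collapse = "; "))
  best <- runs[[which.min(values)]]
  structure(list(
    estimates = best$par, objective = best$value,
    convergence = best$convergence, starts = runs, seed = problem$seed,
    failures = problem$cache$failures
  ), class = "keto_fit")
}

#' @export
print.keto_fit <- function(x, ...) {
  cat("keto_fit: objective", format(x$objective), "\n")
  print(x$estimates)
  invisible(x)
}

#' Normalised local sensitivity of the blood BHB curve
#'
#' Central finite-difference elasticities
#' `S_p(t) = (dC(t)/dp) * p / C(t)` with a relative step (default 1% of
#' the parameter), summarised as root-mean-square over the simulation
#' grid and returned in descending order. A parameter with value zero
#' gets a one-sided difference and a warning.
#'
#' @param fixture a `keto_fixture`.
#' @param param_names fixture parameters to perturb.
#' @param dose dose (mg/kg) of the probing simulation.
#' @param rel_step relative finite-difference step.
#' @param t_grid simulation grid (h).
#' @param rtol,atol solver tolerances.
#' @return Data frame (`parameter`, `rms_sensitivity`), ranked.
#' @export
sensitivity_analysis <- function(fixture, param_names, dose = 192,
                                 rel_step = 0.01,
                                 t_grid = seq(0, 6, by = 0.05),
                                 rtol = 1e-8, atol = 1e-10) {
  curve_for <- function(fix) {
    model <- build_ketone_model(fix, check_monotonicity = FALSE)
    run_dose(model, dose, t_grid = t_grid, rtol = rtol, atol = atol)$conc
  }
  c0 <- curve_for(fixture)
  rms <- vapply(param_names, function(pn) {
    p <- unname(fixture_value(fixture, pn))
    if (p == 0) {
      warning(sprintf("parameter '%s' is zero; using one-sided difference", pn))
      h <- rel_step
      cp <- curve_for(fixture_set(fixture, pn, h))
      dcdp <- (cp - c0) / h
      return(sqrt(mean((dcdp * h / c0)^2)))
    }
    h <- rel_step * p
    cp <- curve_for(fixture_set(fixture, pn, p + h))
    cm <- curve_for(fixture_set(fixture, pn, p - h))
    s <- (cp - cm) / (2 * h) * p / c0
    sqrt(mean(s^2))
  }, numeric(1))
  out <- data.frame(parameter = param_names, rms_sensitivity = unname(rms),
                    stringsAsFactors = FALSE)
  out[order(-out$rms_sensitivity), ]
}

#' Overlay model predictions on a mean +/- SEM dataset
#'
#' Reproduces the calibration diagnostic: per-dose overlay of the
#' predicted blood BHB curve on the empirical means with SEM bars and
#' the LLOQ line, plus a residual table and the fraction of points whose
#' prediction falls within mean +/- SEM.
#'
#' @param model a built `keto_model`.
#' @param dataset dataset data frame (see [estimation_problem()]).
#' @param t_grid dense curve grid for the plot (h).
#' @return List with `plot` (ggplot), `residuals` (data frame with
#'   `within_sem` flag) and `within_sem_fraction`.
#' @export
calibration_overlay <- function(model, dataset,
                                t_grid = seq(0, 6, by = 0.02)) {
  baseline <- equilibrate(model)
  lloq <- model$metadata$lloq_mM %||% 0
  res <- dataset
  res$pred_mM <- NA_real_
  curves <- list()
  for (dose in unique(dataset$dose_mg_per_kg)) {
    idx <- dataset$dose_mg_per_kg == dose
    grid <- sort(unique(c(t_grid, dataset$time_h[idx])))
    sim <- run_dose(model, dose, baseline = baseline, t_grid = grid)
    res$pred_mM[idx] <- sim$conc[match(dataset$time_h[idx], sim$time)]
    curves[[as.character(dose)]] <- data.frame(
      dose_mg_per_kg = dose, time_h = sim$time, pred_mM = sim$conc)
  }
  res$residual <- res$pred_mM - res$mean_mM
  res$within_sem <- abs(res$residual) <= res$sem_mM + 1e-9
  curve_df <- do.call(rbind, curves)
  p <- ggplot2::ggplot(res, ggplot2::aes(x = time_h)) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(y = pred_mM), colour = "blue",
                       linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = mean_mM, ymin = mean_mM - sem_mM,
      ymax = mean_mM + sem_mM), colour = "red") +
    ggplot2::geom_hline(yintercept = lloq, colour = "darkgreen",
                        linetype = "dashed") +
    ggplot2::facet_wrap(~dose_mg_per_kg, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (h)", y = "Blood BHB (mM)")
  list(plot = p, residuals = res,
       within_sem_fraction = mean(res$within_sem))
}
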