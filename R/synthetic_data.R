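# Generator of clinical-study-shaped datasets: mean +/- SEM blood BHB
# concentration-time curves at two dose levels, emulating a balanced
# design in which every subject at every dose level is sampled at every
# time point.

#' Describe a synthetic study design
#'
#' Defaults mirror the two-extreme-dose oral study the model is
#' calibrated against: 192 and 573 mg/kg of the monoester with dense
#' early sampling to resolve the single early peak. The noise model has
#' three components: a subject-level proportional effect (`cv_between`,
#' shared by all samples of one subject, emulating between-subject
#' variability in a repeated-measures design), an observation-level
#' proportional component (`cv_within`) and an additive assay component
#' (`sd_add`). Individual draws below the LLOQ are censored before means
#' and SEMs are formed.
#'
#' @param doses dose levels (mg/kg), default `c(192, 573)`.
#' @param n_subjects subjects per dose level (`>= 2` so the SEM is
#'   defined).
#' @param times sampling times (h) within the simulation window.
#' @param lloq lower limit of quantification (mM).
#' @param cv_between between-subject proportional CV.
#' @param cv_within within-subject (residual) proportional CV.
#' @param sd_add additive noise SD (mM).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A `keto_design` list.
#' @export
study_design <- function(doses = c(192, 573), n_subjects = 8L,
                         times = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6),
                         lloq = 0.02, cv_between = 0.15, cv_within = 0.1,
                         sd_add = 0.02, seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects for a SEM")
  check_nonneg(doses, "doses")
  check_nonneg(times, "times")
  check_nonneg(c(cv_between, cv_within, sd_add), "noise parameters")
  structure(list(doses = doses, n_subjects = as.integer(n_subjects),
                 times = sort(unique(times)), lloq = lloq,
                 cv_between = cv_between, cv_within = cv_within,
                 sd_add = sd_add, seed = as.integer(seed)),
            class = "keto_design")
}

#' Generate a synthetic mean +/- SEM dataset from a fixture
#'
#' Simulates the deterministic truth curve per dose from the
#' equilibrated baseline, draws `n_subjects` noisy realisations per
#' time point (`truth * (1 + eta_subject) * (1 + eps) + eps_add`),
#' censors individual draws below the LLOQ, and returns per-time mean
#' and SEM over the uncensored draws with the retained n. Time points
#' at which every draw is censored are dropped with a warning.
#'
#' @param design a [study_design()].
#' @param fixture a `keto_fixture` defining the generating truth.
#' @param rtol,atol solver tolerances of the truth simulation.
#' @return Data frame with columns `dose_mg_per_kg`, `time_h`,
#'   `mean_mM`, `sem_mM`, `n`, plus attributes `truth` (the noise-free
#'   curve) and `design`.
#' @export
generate_dataset <- function(design, fixture, rtol = 1e-8, atol = 1e-10) {
  model <- build_ketone_model(fixture)
  baseline <- equilibrate(model)
  rows <- list()
  truth_rows <- list()
  set.seed(design$seed)
  for (dose in design$doses) {
    grid <- sort(unique(c(0, design$times)))
    sim <- run_dose(model, dose, baseline = baseline, t_grid = grid,
                    rtol = rtol, atol = atol)
    truth <- sim$conc[match(design$times, sim$time)]
    truth_rows[[as.character(dose)]] <- data.frame(
      dose_mg_per_kg = dose, time_h = design$times, truth_mM = truth)
    eta <- stats::rnorm(design$n_subjects, 0, design$cv_between)
    for (i in seq_along(design$times)) {
      eps <- stats::rnorm(design$n_subjects, 0, design$cv_within)
      add <- stats::rnorm(design$n_subjects, 0, design$sd_add)
      y <- truth[i] * (1 + eta) * (1 + eps) + add
      y <- y[y >= design$lloq]
      if (!length(y)) {
        warning(sprintf(
          "all draws censored at dose %g, t = %g h; point omitted",
          dose, design$times[i]))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dose_mg_per_kg = dose, time_h = design$times[i],
        mean_mM = mean(y),
        sem_mM = if (length(y) > 1) stats::sd(y) / sqrt(length(y)) else 0,
        n = length(y))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth_rows)
  attr(out, "design") <- design
  rownames(out) <- NULL
  out
}

#' Qualitative structure checks on a generated dataset
#'
#' Verifies the features the generator is meant to emulate: a nonzero
#' pre-dose baseline below 0.5 mM, a single post-dose peak per dose
#' (monotone rise then fall within a 2-SEM noise band), peaks that
#' increase with dose, and all reported means at or above the LLOQ.
#'
#' @param dataset data frame from [generate_dataset()].
#' @param lloq LLOQ (mM); defaults to the generating design's.
#' @return A `keto_checks` list of named logicals plus a `pass` flag;
#'   printing lists any failures.
#' @export
qualitative_checks <- function(dataset, lloq = NULL) {
  design <- attr(dataset, "design")
  lloq <- lloq %||% (if (!is.null(design)) design$lloq else 0)
  doses <- sort(unique(dataset$dose_mg_per_kg))
  checks <- list()
  peaks <- numeric(0)
  for (dose in doses) {
    d <- dataset[dataset$dose_mg_per_kg == dose, ]
    d <- d[order(d$time_h), ]
    key <- paste0("dose_", dose)
    pre <- d$mean_mM[d$time_h == min(d$time_h)]
    checks[[paste0(key, "_baseline_below_0.5_mM")]] <-
      length(pre) == 1 && pre > 0 && pre < 0.5
    if (dose > 0) {
      i <- which.max(d$mean_mM)
      slack <- 2 * d$sem_mM
      single_peak <- i > 1 && i < nrow(d) &&
        all(diff(d$mean_mM[1:i]) > -slack[2:i]) &&
        all(diff(d$mean_mM[i:nrow(d)]) < slack[(i + 1):nrow(d)])
      checks[[paste0(key, "_single_post_dose_peak")]] <- single_peak
      peaks[key] <- max(d$mean_mM)
    } else {
      flat <- diff(range(d$mean_mM)) <= 4 * max(d$sem_mM, 1e-12)
      checks[[paste0(key, "_flat_profile")]] <- flat
    }
    checks[[paste0(key, "_means_at_or_above_lloq")]] <- all(d$mean_mM >= lloq)
  }
  if (length(peaks) > 1)
    checks[["peaks_increase_with_dose"]] <- !is.unsorted(peaks, strictly = TRUE)
  structure(list(checks = checks, pass = all(unlist(checks))),
            class = "keto_checks")
}

#' @export
print.keto_checks <- function(x, ...) {
  status <- ifelse(unlist(x$checks), "ok", "FAIL")
  cat(sprintf("%-40s %s\n", names(x$checks), status), sep = "")
  cat(if (x$pass) "all checks passed\n" else "some checks FAILED\n")
  invisible(x)
}

#' Read / write the dataset CSV schema
#'
#' Columns: `dose_mg_per_kg`, `time_h`, `mean_mM`, `sem_mM`, `n`.
#'
#' @param dataset dataset data frame.
#' @param path CSV path.
#' @return `read_dataset()` returns the data frame; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(
    dataset[c("dose_mg_per_kg", "time_h", "mean_mM", "sem_mM", "n")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path)
  need <- c("dose_mg_per_kg", "time_h", "mean_mM", "sem_mM", "n")
  if (!all(need %in% names(d)))
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  if (any(d$sem_mM < 0) || any(d$mean_mM < 0))
    stop("means and SEMs must be non-negative")
  d
}
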