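# State/process containers, strict assembly-time validation, and the
# compiled right-hand side of the indicator-gated compartmental network.

#' Compartment, substance and process vocabularies
#'
#' Controlled vocabularies used by [species_state()] and [flux_process()].
#' Sink compartments are absorbing: no process may take mass out of them.
#' @name vocabularies
#' @export
COMPARTMENTS <- c(
  "upper_proximal_lumen", "lower_proximal_lumen",
  "upper_distal_lumen", "lower_distal_lumen",
  "lower_proximal_enterocyte", "upper_distal_enterocyte",
  "lower_distal_enterocyte",
  "portal", "liver", "blood", "tissues",
  "faeces_sink", "excretion_sink", "consumption_sink"
)

#' @rdname vocabularies
#' @export
SINK_COMPARTMENTS <- c("faeces_sink", "excretion_sink", "consumption_sink")

#' @rdname vocabularies
#' @export
SUBSTANCES <- c("ester", "butanediol", "BHB", "AcAc", "acetone",
                "acetylCoA", "other")

PROCESS_KINDS <- c("first_order", "saturable", "saturable_competitive",
                   "zero_order")

#' Declare one amount-valued state variable
#'
#' @param id integer state index (states of a model must be numbered
#'   `1..n` contiguously).
#' @param compartment one of [COMPARTMENTS].
#' @param substance one of [SUBSTANCES].
#' @param amount initial amount (mmol), `>= 0`.
#' @return A `keto_state` list.
#' @export
species_state <- function(id, compartment, substance, amount = 0) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  substance <- match.arg(substance, SUBSTANCES)
  check_nonneg(amount, "amount")
  structure(list(id = as.integer(id), compartment = compartment,
                 substance = substance, amount = amount),
            class = "keto_state")
}

#' Declare one directed mass-transfer or reaction process
#'
#' A process removes `fraction * rate` from its source state and adds the
#' product-mapped amounts to its targets. The default product map sends
#' coefficient 1 to `target`; reactions with several products (e.g.
#' hydrolysis of 1 mmol ester into 1 mmol butanediol plus 1 mmol BHB) pass
#' an explicit `products` vector. Zero-order production processes have no
#' source. Setting `indicator = 0` gates the process off: it then
#' contributes exactly zero flux, which is how in silico knockouts are
#' realised.
#'
#' @param name unique process name.
#' @param kind one of `"first_order"`, `"saturable"`,
#'   `"saturable_competitive"`, `"zero_order"`.
#' @param source source state id (omit for `zero_order`).
#' @param target target state id (used for the default product map).
#' @param products named numeric vector, names = target state ids,
#'   values = stoichiometric coefficients; overrides `target`.
#' @param fraction fractional millimoles of the source undertaking this
#'   process, in `[0, 1]`.
#' @param rate_constant first-order rate constant (1/h).
#' @param vmax,km saturable-process parameters (mmol/h, mmol).
#' @param competitor state id of the competing substrate
#'   (`saturable_competitive` only).
#' @param km_comp Michaelis constant (mmol) of the competitor.
#' @param base_rate zero-order production rate (mmol/h).
#' @param feedback optional [feedback_law()] (`zero_order` only).
#' @param indicator 0 (not operational) or 1 (operational).
#' @param knockout_tags character vector of knockout-variant ids this
#'   process belongs to.
#' @param partition optional label; processes sharing a source and a
#'   partition label form one physical fate split and their fractions
#'   must sum to 1 (checked by [validate_model()]).
#' @return A `keto_process` list.
#' @export
flux_process <- function(name, kind, source = NULL, target = NULL,
                         products = NULL, fraction = 1,
                         rate_constant = NULL, vmax = NULL, km = NULL,
                         competitor = NULL, km_comp = NULL,
                         base_rate = NULL, feedback = NULL,
                         indicator = 1L, knockout_tags = character(),
                         partition = NULL) {
  kind <- match.arg(kind, PROCESS_KINDS)
  check_fraction(fraction, "fraction")
  if (!indicator %in% c(0L, 1L)) stop("`indicator` must be 0 or 1")
  if (kind == "zero_order") {
    if (!is.null(source)) stop("zero-order processes have no source state")
    check_nonneg(base_rate, "base_rate")
    if (!is.null(feedback) && !inherits(feedback, "keto_feedback"))
      stop("`feedback` must be a feedback_law()")
  } else {
    if (is.null(source)) stop(sprintf("process '%s' needs a source", name))
    if (!is.null(feedback)) stop("feedback is only defined for zero_order")
  }
  if (kind == "first_order") check_nonneg(rate_constant, "rate_constant")
  if (kind %in% c("saturable", "saturable_competitive")) {
    check_nonneg(vmax, "vmax")
    check_pos(km, "km")
  }
  if (kind == "saturable_competitive") {
    if (is.null(competitor)) stop("competitive process needs a competitor")
    check_pos(km_comp, "km_comp")
  }
  if (is.null(products)) {
    if (is.null(target)) stop(sprintf("process '%s' needs a target", name))
    products <- stats::setNames(1, as.character(as.integer(target)))
  }
  if (is.null(names(products)) || any(products < 0))
    stop("`products` must be a named vector of non-negative coefficients")
  structure(list(
    name = name, kind = kind,
    source = if (is.null(source)) NULL else as.integer(source),
    products = products, fraction = fraction,
    rate_constant = rate_constant, vmax = vmax, km = km,
    competitor = if (is.null(competitor)) NULL else as.integer(competitor),
    km_comp = km_comp, base_rate = base_rate, feedback = feedback,
    indicator = as.integer(indicator),
    knockout_tags = as.character(knockout_tags),
    partition = partition
  ), class = "keto_process")
}

#' Assemble a model instance from states and processes
#'
#' @param states list of [species_state()] objects, ids `1..n`.
#' @param processes list of [flux_process()] objects with unique names.
#' @param parameters optional data frame (`name`, `value`, `unit`,
#'   `provenance`) retained for reporting.
#' @param metadata named list; the ketone-model builder stores component
#'   labels, segment labels, volumes and key state indices here.
#' @return A validated object of class `keto_model`.
#' @export
model_instance <- function(states, processes, parameters = NULL,
                           metadata = list()) {
  st <- data.frame(
    id = vapply(states, function(s) s$id, integer(1)),
    compartment = vapply(states, function(s) s$compartment, character(1)),
    substance = vapply(states, function(s) s$substance, character(1)),
    initial = vapply(states, function(s) s$amount, numeric(1)),
    stringsAsFactors = FALSE
  )
  names(processes) <- vapply(processes, function(p) p$name, character(1))
  model <- structure(list(states = st, processes = processes,
                          parameters = parameters, metadata = metadata),
                     class = "keto_model")
  validate_model(model)
  model
}

#' Validate a model instance
#'
#' Strict assembly-time validation: contiguous unique state ids, no
#' dangling state references (sources, products, competitors, feedback
#' inhibitors), absorbing sinks, and fate-partition fractions summing
#' to 1. Simulation never runs on an invalid model.
#'
#' @param model a `keto_model`.
#' @return `TRUE` invisibly, or an error listing every offender.
#' @export
validate_model <- function(model) {
  st <- model$states
  n <- nrow(st)
  bad <- character()
  if (anyDuplicated(st$id) || !identical(sort(st$id), seq_len(n)))
    bad <- c(bad, "state ids must be unique and contiguous 1..n")
  known <- function(i) !is.null(i) && all(i >= 1L & i <= n)
  sink_ids <- st$id[st$compartment %in% SINK_COMPARTMENTS]
  if (anyDuplicated(names(model$processes)))
    bad <- c(bad, "process names must be unique")
  for (p in model$processes) {
    if (!is.null(p$source)) {
      if (!known(p$source))
        bad <- c(bad, sprintf("process '%s': dangling source %d", p$name, p$source))
      else if (p$source %in% sink_ids)
        bad <- c(bad, sprintf("process '%s': sink state %d must be absorbing",
                              p$name, p$source))
    }
    tgt <- as.integer(names(p$products))
    if (!known(tgt))
      bad <- c(bad, sprintf("process '%s': dangling product state", p$name))
    if (!is.null(p$competitor) && !known(p$competitor))
      bad <- c(bad, sprintf("process '%s': dangling competitor %d",
                            p$name, p$competitor))
    if (!is.null(p$feedback) && !known(p$feedback$inhibitor_states))
      bad <- c(bad, sprintf("process '%s': dangling feedback state", p$name))
  }
  # fate partitions: fractions of co-partitioned processes must sum to 1
  has_part <- Filter(function(p) !is.null(p$partition), model$processes)
  if (length(has_part)) {
    key <- vapply(has_part, function(p)
      paste(p$source %||% 0L, p$partition, sep = "/"), character(1))
    fr <- vapply(has_part, function(p) p$fraction, numeric(1))
    sums <- tapply(fr, key, sum)
    off <- names(sums)[abs(sums - 1) > 1e-9]
    if (length(off))
      bad <- c(bad, sprintf("fate partition '%s' fractions sum to %g, not 1",
                            off, sums[off]))
  }
  if (length(bad))
    stop("invalid model:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

#' Clone a model, optionally overriding process indicators
#'
#' The clone is fully independent: mutating it never touches the
#' original. Indicator overrides are given as a named vector
#' (process name -> 0/1) or applied to every process carrying one of
#' `tags`.
#'
#' @param model a `keto_model`.
#' @param indicators named integer vector of indicator overrides.
#' @param tags character vector of knockout tags; every process carrying
#'   any of these tags gets indicator `tag_value`.
#' @param tag_value indicator assigned to tagged processes (default 0).
#' @return A new `keto_model`.
#' @export
model_clone <- function(model, indicators = NULL, tags = NULL,
                        tag_value = 0L) {
  clone <- model
  if (!is.null(indicators)) {
    unknown <- setdiff(names(indicators), names(clone$processes))
    if (length(unknown))
      stop("unknown process name(s): ", paste(unknown, collapse = ", "))
    for (nm in names(indicators))
      clone$processes[[nm]]$indicator <- as.integer(indicators[[nm]])
  }
  if (!is.null(tags)) {
    for (nm in names(clone$processes)) {
      if (length(intersect(clone$processes[[nm]]$knockout_tags, tags)))
        clone$processes[[nm]]$indicator <- as.integer(tag_value)
    }
  }
  clone
}

state_names <- function(model) paste0("s", model$states$id)

#' Look up state ids by compartment and/or substance
#'
#' @param model a `keto_model`.
#' @param compartment,substance optional filters.
#' @return Integer vector of state ids.
#' @export
state_index <- function(model, compartment = NULL, substance = NULL) {
  keep <- rep(TRUE, nrow(model$states))
  if (!is.null(compartment))
    keep <- keep & model$states$compartment %in% compartment
  if (!is.null(substance))
    keep <- keep & model$states$substance %in% substance
  model$states$id[keep]
}

# Compile the process network into indexed vectors plus an incidence
# matrix so the ODE right-hand side is a handful of vectorised
# operations. Amounts are clamped at zero inside the RHS so saturable
# terms stay well defined against solver under/overshoot.
compile_network <- function(model) {
  validate_model(model)
  n <- nrow(model$states)
  procs <- unname(model$processes)
  np <- length(procs)
  kind <- vapply(procs, function(p) p$kind, character(1))
  coef <- vapply(procs, function(p) p$fraction * p$indicator, numeric(1))
  src <- vapply(procs, function(p) p$source %||% 1L, integer(1))

  i_fo <- which(kind == "first_order")
  i_sat <- which(kind == "saturable")
  i_cmp <- which(kind == "saturable_competitive")
  i_zo <- which(kind == "zero_order")

  k_fo <- vapply(procs[i_fo], function(p) p$rate_constant, numeric(1))
  v_sat <- vapply(procs[i_sat], function(p) p$vmax, numeric(1))
  km_sat <- vapply(procs[i_sat], function(p) p$km, numeric(1))
  v_cmp <- vapply(procs[i_cmp], function(p) p$vmax, numeric(1))
  km_cmp <- vapply(procs[i_cmp], function(p) p$km, numeric(1))
  ratio_cmp <- vapply(procs[i_cmp], function(p) p$km / p$km_comp, numeric(1))
  comp_cmp <- vapply(procs[i_cmp], function(p) p$competitor, integer(1))
  zo <- procs[i_zo]

  M <- matrix(0, n, np)
  for (j in seq_len(np)) {
    p <- procs[[j]]
    if (!is.null(p$source)) M[p$source, j] <- M[p$source, j] - 1
    tgt <- as.integer(names(p$products))
    M[cbind(tgt, j)] <- M[cbind(tgt, j)] + p$products
  }

  src_fo <- src[i_fo]; src_sat <- src[i_sat]; src_cmp <- src[i_cmp]

  rhs <- function(t, A) {
    A <- pmax(A, 0)
    r <- numeric(np)
    if (length(i_fo)) r[i_fo] <- k_fo * A[src_fo]
    if (length(i_sat)) {
      As <- A[src_sat]
      r[i_sat] <- v_sat * As / (km_sat + As)
    }
    if (length(i_cmp)) {
      Ai <- A[src_cmp]
      r[i_cmp] <- v_cmp * Ai / (km_cmp + Ai + ratio_cmp * A[comp_cmp])
    }
    for (z in seq_along(i_zo)) {
      p <- zo[[z]]
      r[i_zo[z]] <- if (is.null(p$feedback)) p$base_rate else
        p$base_rate * feedback_multiplier(p$feedback,
                                          A[p$feedback$inhibitor_states])
    }
    drop(M %*% (coef * r))
  }
  list(rhs = rhs, n = n, sink_ids = model$states$id[
    model$states$compartment %in% SINK_COMPARTMENTS])
}

#' Assemble the ODE right-hand side of a model
#'
#' Compiles the validated process network into a function
#' `f(t, A) -> dA/dt` (mmol/h). Gated processes (`indicator = 0`)
#' contribute exactly zero.
#'
#' @param model a `keto_model` (validated on assembly; assembly fails
#'   loudly on an invalid model).
#' @return A function of `(t, A)` returning the derivative vector.
#' @export
assemble_rhs <- function(model) compile_network(model)$rhs

#' Mole-equivalent weights for mass bookkeeping
#'
#' The ester hydrolyses into one butanediol plus one BHB, so it carries
#' two mole-equivalents; every other substance carries one. Processes
#' into sink states already deposit mole-equivalents (ester entering the
#' faeces sink carries coefficient 2), so sink states take weight 1 and
#' the weighted total is conserved whenever zero-order production is off.
#'
#' @param model a `keto_model`.
#' @return Numeric weight per state.
#' @export
mole_equivalents <- function(model) {
  ifelse(model$states$substance == "ester", 2, 1)
}

#' @export
print.keto_model <- function(x, ...) {
  comp <- x$metadata$components
  cat(sprintf("keto_model: %d states, %d processes", nrow(x$states),
              length(x$processes)))
  if (!is.null(comp))
    cat(sprintf(", %d components (%s)", length(unique(comp)),
                paste(unique(comp), collapse = ", ")))
  cat("\n")
  gated <- sum(vapply(x$processes, function(p) p$indicator == 0L, logical(1)))
  if (gated) cat(sprintf("  %d process(es) gated off\n", gated))
  invisible(x)
}

# ---- serialization ---------------------------------------------------

process_to_list <- function(p) {
  out <- p[!vapply(p, is.null, logical(1))]
  out$products <- list(targets = as.integer(names(p$products)),
                       coefficients = unname(p$products))
  if (!is.null(p$feedback)) out$feedback <- unclass(p$feedback)
  out
}

process_from_list <- function(x) {
  fb <- if (!is.null(x$feedback))
    feedback_law(x$feedback$inhibitor_states, x$feedback$imax,
                 x$feedback$ic50, x$feedback$weights)
  flux_process(
    name = x$name, kind = x$kind, source = x$source,
    products = stats::setNames(x$products$coefficients,
                               x$products$targets),
    fraction = x$fraction, rate_constant = x$rate_constant,
    vmax = x$vmax, km = x$km, competitor = x$competitor,
    km_comp = x$km_comp, base_rate = x$base_rate, feedback = fb,
    indicator = x$indicator, knockout_tags = x$knockout_tags %||% character(),
    partition = x$partition
  )
}

#' Save / load a model configuration
#'
#' The full model (states, processes with parameters and knockout tags,
#' parameter table, metadata) is serialized as JSON (`.json`) or YAML
#' (`.yaml`/`.yml`). Round-trip load -> save -> load is value-identical.
#'
#' @param model a `keto_model`.
#' @param path file path; format chosen by extension.
#' @return `load_model_config()` returns a validated `keto_model`;
#'   `save_model_config()` returns `path` invisibly.
#' @export
save_model_config <- function(model, path) {
  obj <- list(
    states = as.list(model$states),
    processes = lapply(unname(model$processes), process_to_list),
    parameters = if (!is.null(model$parameters)) as.list(model$parameters),
    metadata = model$metadata
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 17)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_model_config
#' @export
load_model_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  st <- lapply(obj$states, unlist)
  states <- lapply(seq_along(st$id), function(i)
    species_state(st$id[[i]], st$compartment[[i]], st$substance[[i]],
                  st$initial[[i]]))
  procs <- lapply(obj$processes, function(x) {
    x$products$targets <- unlist(x$products$targets)
    x$products$coefficients <- unlist(x$products$coefficients)
    if (!is.null(x$feedback))
      x$feedback <- lapply(x$feedback, unlist)
    x$knockout_tags <- unlist(x$knockout_tags)
    x
  })
  params <- if (!is.null(obj$parameters))
    data.frame(lapply(obj$parameters, unlist), stringsAsFactors = FALSE)
  meta <- obj$metadata
  for (nm in c("components", "segments"))
    if (!is.null(meta[[nm]])) meta[[nm]] <- unlist(meta[[nm]])
  model_instance(states, lapply(procs, process_from_list),
                 parameters = params, metadata = meta)
}
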