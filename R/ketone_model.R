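# Builder for the ketone monoester absorption/catabolism model: four gut
# lumen segments chained by first-order transit, enterocyte BHB states
# with apical MCT1 + SMCT1 uptake and basolateral MCT4 export, portal,
# liver, blood (with the lumped "other" feedback state) and tissues, plus
# faeces / consumption / excretion sinks.

GUT_SEGMENTS <- c("upper_proximal", "lower_proximal", "upper_distal",
                  "lower_distal")
ACTIVE_SEGMENTS <- c("lower_proximal", "upper_distal", "lower_distal")

# knockout-variant tags: 4 passive (one per segment) + apical/basolateral
# pairs for the three active segments
PASSIVE_TAG <- stats::setNames(c("1", "2", "5", "8"), GUT_SEGMENTS)
APICAL_TAG <- stats::setNames(c("3", "6", "9"), ACTIVE_SEGMENTS)
BASOLATERAL_TAG <- stats::setNames(c("4", "7", "10"), ACTIVE_SEGMENTS)

required_parameters <- function() {
  gut <- unlist(lapply(GUT_SEGMENTS, function(s) paste0(
    "gut.", s, c(".transit_k", ".hydrolysis_k",
                 ".passive_k.ester", ".passive_k.butanediol",
                 ".passive_k.bhb"))))
  active <- unlist(lapply(ACTIVE_SEGMENTS, function(s) paste0(
    "gut.", s, ".", rep(c("mct1", "smct1", "mct4"), each = 2),
    c(".vmax", ".km"))))
  liver <- c(
    "liver.ester_hydrolysis_k", "liver.butanediol_to_bhb_k",
    "liver.bhb_to_acac_k", "liver.acac_to_bhb_k", "liver.acac_to_acetone_k",
    "liver.endogenous.base_rate", "liver.endogenous.imax",
    "liver.endogenous.ic50", "liver.endogenous.w_bhb",
    "liver.endogenous.w_acac", "liver.endogenous.w_other",
    paste0("liver.", rep(c("mct1_bhb_out", "mct1_bhb_in", "mct1_acac_out",
                           "mct1_acac_in"), each = 2), c(".vmax", ".km")),
    paste0("liver.passive.", rep(c("ester", "butanediol", "acetone"),
                                 each = 2), c(".out", ".in")))
  blood <- c("blood.ester_hydrolysis_k", "blood.butanediol_to_bhb_k",
             "blood.acac_to_acetone_k", "blood.other.production_rate",
             "blood.other.loss_k")
  tissues <- c(
    paste0("tissues.", rep(c("mct1_bhb_in", "mct1_bhb_out", "mct2_bhb_in",
                             "mct2_bhb_out", "mct1_acac_in", "mct1_acac_out",
                             "mct2_acac_in", "mct2_acac_out"), each = 2),
           c(".vmax", ".km")),
    paste0("tissues.passive.", rep(c("ester", "butanediol", "acetone"),
                                   each = 2), c(".in", ".out")),
    "tissues.bhb_consumption_k", "tissues.acac_consumption_k",
    "tissues.bhb_renal_k", "tissues.acac_renal_k",
    "tissues.acetone_exhalation_k")
  c("body_weight_kg", "blood_volume_L", "liver_volume_L",
    "ester_molar_mass_g_mol", "lloq_mM", gut, active, "portal.outflow_k",
    liver, blood, tissues)
}

#' Load a parameter fixture
#'
#' A fixture is a named parameter table (name, value, unit, provenance)
#' serialized as JSON or YAML. Provenance is one of `literature`,
#' `scaled`, `estimated`, `fixture-default`. The same schema accepts
#' externally supplied parameter tables (e.g. a published supplementary
#' parameter listing) for exact reproduction runs.
#'
#' @param path path to a `.json` / `.yaml` fixture file.
#' @return Object of class `keto_fixture` (a data frame with a value
#'   lookup).
#' @export
load_fixture <- function(path) {
  if (!nzchar(path) || !file.exists(path))
    stop("fixture file not found: '", path, "'", call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  tab <- data.frame(lapply(obj$parameters, unlist), stringsAsFactors = FALSE)
  stopifnot(all(c("name", "value", "unit", "provenance") %in% names(tab)))
  if (anyDuplicated(tab$name))
    stop("duplicated parameter name(s) in fixture")
  structure(tab, class = c("keto_fixture", "data.frame"),
            meta = obj$meta)
}

#' Write a fixture to disk
#' @param fixture a `keto_fixture`.
#' @param path output path (`.json` or `.yaml`).
#' @export
save_fixture <- function(fixture, path) {
  obj <- list(meta = attr(fixture, "meta"),
              parameters = as.list(as.data.frame(fixture)))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' The default parameter fixture shipped with the package
#'
#' Transit constants, volumes and Michaelis constants are plausible
#' physiological values from the transporter and gut-physiology
#' literature; carrier capacities are scaled so that expression (and
#' hence `vmax`) increases from proximal to distal gut; the remaining
#' rate constants were calibrated against the package's reference
#' concentration-time behaviour (early single peak, dose-dependent
#' nonlinearity, endogenous baseline below 0.5 mM).
#'
#' @return A `keto_fixture`.
#' @export
default_fixture <- function() {
  load_fixture(system.file("extdata", "fixture_default.json",
                           package = "ketoabsorb", mustWork = TRUE))
}

#' Read or override fixture values
#'
#' @param fixture a `keto_fixture`.
#' @param name parameter name(s).
#' @param value replacement value(s) for `fixture_set`.
#' @return `fixture_value` returns numeric value(s); `fixture_set`
#'   returns the modified fixture.
#' @export
fixture_value <- function(fixture, name) {
  i <- match(name, fixture$name)
  if (anyNA(i))
    stop("fixture is missing parameter(s): ",
         paste(name[is.na(i)], collapse = ", "))
  stats::setNames(fixture$value[i], name)
}

#' @rdname fixture_value
#' @export
fixture_set <- function(fixture, name, value) {
  i <- match(name, fixture$name)
  if (anyNA(i))
    stop("fixture is missing parameter(s): ",
         paste(name[is.na(i)], collapse = ", "))
  fixture$value[i] <- value
  fixture$provenance[i] <- "estimated"
  fixture
}

#' Build the ketone monoester systems model from a fixture
#'
#' Assembles the full network: gut lumen segments (ester, butanediol,
#' BHB) chained by first-order transit ending in the faeces sink;
#' luminal hydrolysis of ester into butanediol + BHB in every segment;
#' passive absorption of all three species into the portal compartment;
#' for the three active segments an enterocyte BHB state with apical
#' saturable uptake (MCT1 and SMCT1 in parallel) and basolateral MCT4
#' export into portal; portal to liver transfer; hepatic ester
#' hydrolysis, butanediol conversion, BHB/AcAc interconversion, AcAc
#' decarboxylation to acetone, and feedback-inhibited zero-order
#' endogenous AcAc production; liver/blood and blood/tissue BHB and AcAc
#' exchange through shared saturable carriers with mutual competitive
#' inhibition; blood-side metabolism; tissue consumption of BHB/AcAc to
#' acetyl-CoA (consumption sink) and renal/pulmonary excretion
#' (excretion sink).
#'
#' @param fixture a `keto_fixture`; all required parameters must be
#'   present (a build error names any that are missing).
#' @param check_monotonicity assert that carrier capacity increases down
#'   the gut and that SMCT1 is higher-affinity than MCT1 (default TRUE;
#'   disable for deliberately perturbed fixtures).
#' @return A validated `keto_model`.
#' @export
build_ketone_model <- function(fixture, check_monotonicity = TRUE) {
  missing <- setdiff(required_parameters(), fixture$name)
  if (length(missing))
    stop("fixture is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  P <- function(name) unname(fixture_value(fixture, name))

  if (check_monotonicity) {
    for (tr in c("mct1", "smct1", "mct4")) {
      v <- vapply(ACTIVE_SEGMENTS, function(s)
        P(paste0("gut.", s, ".", tr, ".vmax")), numeric(1))
      if (is.unsorted(v))
        stop(sprintf("gut %s vmax must be non-decreasing from proximal to distal", tr))
    }
    for (s in ACTIVE_SEGMENTS)
      if (P(paste0("gut.", s, ".smct1.km")) >= P(paste0("gut.", s, ".mct1.km")))
        stop("SMCT1 must be higher affinity (smaller km) than MCT1")
  }

  # ---- states --------------------------------------------------------
  lumen <- paste0(GUT_SEGMENTS, "_lumen")
  spec <- list()
  add_state <- function(compartment, substance) {
    spec[[length(spec) + 1L]] <<- list(compartment = compartment,
                                       substance = substance)
    length(spec)
  }
  lum <- list()
  for (seg in GUT_SEGMENTS)
    lum[[seg]] <- c(ester = add_state(paste0(seg, "_lumen"), "ester"),
                    butanediol = add_state(paste0(seg, "_lumen"), "butanediol"),
                    BHB = add_state(paste0(seg, "_lumen"), "BHB"))
  ent <- stats::setNames(vapply(ACTIVE_SEGMENTS, function(seg)
    add_state(paste0(seg, "_enterocyte"), "BHB"), numeric(1)), ACTIVE_SEGMENTS)
  portal <- c(ester = add_state("portal", "ester"),
              butanediol = add_state("portal", "butanediol"),
              BHB = add_state("portal", "BHB"))
  liver <- c(ester = add_state("liver", "ester"),
             butanediol = add_state("liver", "butanediol"),
             BHB = add_state("liver", "BHB"),
             AcAc = add_state("liver", "AcAc"),
             acetone = add_state("liver", "acetone"))
  blood <- c(ester = add_state("blood", "ester"),
             butanediol = add_state("blood", "butanediol"),
             BHB = add_state("blood", "BHB"),
             AcAc = add_state("blood", "AcAc"),
             acetone = add_state("blood", "acetone"),
             other = add_state("blood", "other"))
  tiss <- c(ester = add_state("tissues", "ester"),
            butanediol = add_state("tissues", "butanediol"),
            BHB = add_state("tissues", "BHB"),
            AcAc = add_state("tissues", "AcAc"),
            acetone = add_state("tissues", "acetone"))
  faeces <- add_state("faeces_sink", "other")
  consumption <- add_state("consumption_sink", "acetylCoA")
  excretion <- add_state("excretion_sink", "other")

  states <- lapply(seq_along(spec), function(i)
    species_state(i, spec[[i]]$compartment, spec[[i]]$substance))

  # ---- processes -----------------------------------------------------
  pr <- list()
  add <- function(p) pr[[length(pr) + 1L]] <<- p
  fo <- function(name, src, tgt, k, products = NULL, tags = character())
    add(flux_process(name, "first_order", source = src, target = tgt,
                     products = products, rate_constant = k,
                     knockout_tags = tags))
  sat <- function(name, src, tgt, vmax, km, tags = character())
    add(flux_process(name, "saturable", source = src, target = tgt,
                     vmax = vmax, km = km, knockout_tags = tags))
  cmp <- function(name, src, tgt, vmax, km, competitor, km_comp)
    add(flux_process(name, "saturable_competitive", source = src,
                     target = tgt, vmax = vmax, km = km,
                     competitor = competitor, km_comp = km_comp))

  subs <- c("ester", "butanediol", "BHB")
  # gut transit down the chain, last segment into the faeces sink (ester
  # enters the sink as 2 mole-equivalents)
  for (i in seq_along(GUT_SEGMENTS)) {
    seg <- GUT_SEGMENTS[i]
    k <- P(paste0("gut.", seg, ".transit_k"))
    for (s in subs) {
      if (i < length(GUT_SEGMENTS)) {
        fo(paste0("transit.", seg, ".", s), lum[[seg]][s],
           lum[[GUT_SEGMENTS[i + 1]]][s], k)
      } else {
        coefs <- stats::setNames(if (s == "ester") 2 else 1, faeces)
        fo(paste0("transit.", seg, ".", s), lum[[seg]][s], NULL, k,
           products = coefs)
      }
    }
  }
  # luminal hydrolysis: 1 ester -> 1 butanediol + 1 BHB
  for (seg in GUT_SEGMENTS) {
    prod <- stats::setNames(c(1, 1),
                            c(lum[[seg]]["butanediol"], lum[[seg]]["BHB"]))
    fo(paste0("hydrolysis.", seg), lum[[seg]]["ester"], NULL,
       P(paste0("gut.", seg, ".hydrolysis_k")), products = prod)
  }
  # passive absorption into portal (knockout tags 1/2/5/8)
  pk <- c(ester = "ester", butanediol = "butanediol", BHB = "bhb")
  for (seg in GUT_SEGMENTS) {
    for (s in subs)
      fo(paste0("passive.", seg, ".", s), lum[[seg]][s], portal[s],
         P(paste0("gut.", seg, ".passive_k.", pk[s])),
         tags = PASSIVE_TAG[seg])
  }
  # apical MCT1 + SMCT1 uptake into the enterocyte, basolateral MCT4
  # export into portal (tags 3/4, 6/7, 9/10)
  for (seg in ACTIVE_SEGMENTS) {
    for (tr in c("mct1", "smct1"))
      sat(paste0("apical.", tr, ".", seg), lum[[seg]]["BHB"], ent[seg],
          P(paste0("gut.", seg, ".", tr, ".vmax")),
          P(paste0("gut.", seg, ".", tr, ".km")), tags = APICAL_TAG[seg])
    sat(paste0("basolateral.mct4.", seg), ent[seg], portal["BHB"],
        P(paste0("gut.", seg, ".mct4.vmax")),
        P(paste0("gut.", seg, ".mct4.km")), tags = BASOLATERAL_TAG[seg])
  }
  # portal -> liver
  for (s in subs)
    fo(paste0("portal_to_liver.", s), portal[s], liver[s],
       P("portal.outflow_k"))
  # liver metabolism
  fo("liver.hydrolysis", liver["ester"], NULL, P("liver.ester_hydrolysis_k"),
     products = stats::setNames(c(1, 1),
                                c(liver["butanediol"], liver["BHB"])))
  fo("liver.butanediol_to_bhb", liver["butanediol"], liver["BHB"],
     P("liver.butanediol_to_bhb_k"))
  fo("liver.bhb_to_acac", liver["BHB"], liver["AcAc"],
     P("liver.bhb_to_acac_k"))
  fo("liver.acac_to_bhb", liver["AcAc"], liver["BHB"],
     P("liver.acac_to_bhb_k"))
  fo("liver.acac_to_acetone", liver["AcAc"], liver["acetone"],
     P("liver.acac_to_acetone_k"))
  # endogenous ketogenesis with saturable feedback from circulating
  # BHB, AcAc and the lumped "other" state
  add(flux_process("liver.endogenous_production", "zero_order",
                   target = liver["AcAc"],
                   base_rate = P("liver.endogenous.base_rate"),
                   feedback = feedback_law(
                     c(blood["BHB"], blood["AcAc"], blood["other"]),
                     imax = P("liver.endogenous.imax"),
                     ic50 = P("liver.endogenous.ic50"),
                     weights = c(P("liver.endogenous.w_bhb"),
                                 P("liver.endogenous.w_acac"),
                                 P("liver.endogenous.w_other")))))
  # liver <-> blood: BHB and AcAc share hepatic MCT1 (mutual competition)
  cmp("liver_to_blood.mct1.BHB", liver["BHB"], blood["BHB"],
      P("liver.mct1_bhb_out.vmax"), P("liver.mct1_bhb_out.km"),
      liver["AcAc"], P("liver.mct1_acac_out.km"))
  cmp("blood_to_liver.mct1.BHB", blood["BHB"], liver["BHB"],
      P("liver.mct1_bhb_in.vmax"), P("liver.mct1_bhb_in.km"),
      blood["AcAc"], P("liver.mct1_acac_in.km"))
  cmp("liver_to_blood.mct1.AcAc", liver["AcAc"], blood["AcAc"],
      P("liver.mct1_acac_out.vmax"), P("liver.mct1_acac_out.km"),
      liver["BHB"], P("liver.mct1_bhb_out.km"))
  cmp("blood_to_liver.mct1.AcAc", blood["AcAc"], liver["AcAc"],
      P("liver.mct1_acac_in.vmax"), P("liver.mct1_acac_in.km"),
      blood["BHB"], P("liver.mct1_bhb_in.km"))
  for (s in c("ester", "butanediol", "acetone")) {
    fo(paste0("liver_to_blood.passive.", s), liver[s], blood[s],
       P(paste0("liver.passive.", s, ".out")))
    fo(paste0("blood_to_liver.passive.", s), blood[s], liver[s],
       P(paste0("liver.passive.", s, ".in")))
  }
  # blood metabolism and the lumped feedback state
  fo("blood.hydrolysis", blood["ester"], NULL, P("blood.ester_hydrolysis_k"),
     products = stats::setNames(c(1, 1),
                                c(blood["butanediol"], blood["BHB"])))
  fo("blood.butanediol_to_bhb", blood["butanediol"], blood["BHB"],
     P("blood.butanediol_to_bhb_k"))
  fo("blood.acac_to_acetone", blood["AcAc"], blood["acetone"],
     P("blood.acac_to_acetone_k"))
  add(flux_process("blood.other_production", "zero_order",
                   target = blood["other"],
                   base_rate = P("blood.other.production_rate")))
  fo("blood.other_loss", blood["other"], excretion, P("blood.other.loss_k"))
  # blood <-> tissues: MCT1 and MCT2 in parallel, mutual BHB/AcAc
  # competition on each carrier and direction
  for (tr in c("mct1", "mct2")) {
    cmp(paste0("blood_to_tissues.", tr, ".BHB"), blood["BHB"], tiss["BHB"],
        P(paste0("tissues.", tr, "_bhb_in.vmax")),
        P(paste0("tissues.", tr, "_bhb_in.km")),
        blood["AcAc"], P(paste0("tissues.", tr, "_acac_in.km")))
    cmp(paste0("tissues_to_blood.", tr, ".BHB"), tiss["BHB"], blood["BHB"],
        P(paste0("tissues.", tr, "_bhb_out.vmax")),
        P(paste0("tissues.", tr, "_bhb_out.km")),
        tiss["AcAc"], P(paste0("tissues.", tr, "_acac_out.km")))
    cmp(paste0("blood_to_tissues.", tr, ".AcAc"), blood["AcAc"], tiss["AcAc"],
        P(paste0("tissues.", tr, "_acac_in.vmax")),
        P(paste0("tissues.", tr, "_acac_in.km")),
        blood["BHB"], P(paste0("tissues.", tr, "_bhb_in.km")))
    cmp(paste0("tissues_to_blood.", tr, ".AcAc"), tiss["AcAc"], blood["AcAc"],
        P(paste0("tissues.", tr, "_acac_out.vmax")),
        P(paste0("tissues.", tr, "_acac_out.km")),
        tiss["BHB"], P(paste0("tissues.", tr, "_bhb_out.km")))
  }
  for (s in c("ester", "butanediol", "acetone")) {
    fo(paste0("blood_to_tissues.passive.", s), blood[s], tiss[s],
       P(paste0("tissues.passive.", s, ".in")))
    fo(paste0("tissues_to_blood.passive.", s), tiss[s], blood[s],
       P(paste0("tissues.passive.", s, ".out")))
  }
  # terminal fates: Krebs-cycle consumption via acetyl-CoA, renal loss,
  # exhaled acetone
  fo("tissues.bhb_consumption", tiss["BHB"], consumption,
     P("tissues.bhb_consumption_k"))
  fo("tissues.acac_consumption", tiss["AcAc"], consumption,
     P("tissues.acac_consumption_k"))
  fo("tissues.bhb_renal", tiss["BHB"], excretion, P("tissues.bhb_renal_k"))
  fo("tissues.acac_renal", tiss["AcAc"], excretion, P("tissues.acac_renal_k"))
  fo("tissues.acetone_exhalation", tiss["acetone"], excretion,
     P("tissues.acetone_exhalation_k"))

  components <- c(rep("gut", 15), rep("portal", 3), rep("liver", 5),
                  rep("blood", 6), rep("tissues", 5),
                  "gut", "tissues", "tissues")
  segments <- character(length(spec))
  for (seg in GUT_SEGMENTS) segments[lum[[seg]]] <- seg
  for (seg in ACTIVE_SEGMENTS) segments[ent[seg]] <- seg

  model_instance(
    states, pr,
    parameters = as.data.frame(fixture)[c("name", "value", "unit",
                                          "provenance")],
    metadata = list(
      components = components, segments = segments,
      blood_volume_L = P("blood_volume_L"),
      liver_volume_L = P("liver_volume_L"),
      body_weight_kg = P("body_weight_kg"),
      ester_molar_mass_g_mol = P("ester_molar_mass_g_mol"),
      lloq_mM = P("lloq_mM"),
      dose_state = unname(lum[["upper_proximal"]]["ester"]),
      blood_bhb_state = unname(blood["BHB"])
    ))
}

#' Number of physiological components of a model
#'
#' Counts the distinct component labels (gut, portal, liver, blood,
#' tissues) recorded at build time; sink states are attributed to the
#' component whose mass they collect.
#'
#' @param model a `keto_model` built by [build_ketone_model()].
#' @return Integer count.
#' @export
n_components <- function(model) {
  length(unique(model$metadata$components))
}

#' List the competitively coupled transport processes
#'
#' BHB and AcAc share the hepatic and peripheral monocarboxylate
#' carriers, so each direction of saturable BHB transport between
#' liver/blood/tissues names AcAc as its competitor and vice versa. Gut
#' apical and basolateral BHB transport has no competing substrate.
#'
#' @param model a `keto_model`.
#' @return Data frame with process name, transported substance and
#'   competitor substance.
#' @export
competitive_links <- function(model) {
  procs <- Filter(function(p) p$kind == "saturable_competitive",
                  model$processes)
  data.frame(
    name = vapply(procs, function(p) p$name, character(1)),
    source = vapply(procs, function(p) p$source, integer(1)),
    substance = model$states$substance[
      vapply(procs, function(p) p$source, integer(1))],
    competitor = vapply(procs, function(p) p$competitor, integer(1)),
    competitor_substance = model$states$substance[
      vapply(procs, function(p) p$competitor, integer(1))],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Replace every saturable process by its first-order limit
#'
#' Each saturable or competitive carrier is replaced by a first-order
#' process with rate constant `vmax / km` (the low-occupancy limit) and
#' the endogenous-production feedback is switched off (`imax = 0`). The
#' resulting model is linear and satisfies dose superposition, which is
#' used as a structural check on the simulator.
#'
#' @param model a `keto_model`.
#' @return A new linear `keto_model`.
#' @export
linearize_model <- function(model) {
  out <- model
  for (nm in names(out$processes)) {
    p <- out$processes[[nm]]
    if (p$kind %in% c("saturable", "saturable_competitive")) {
      out$processes[[nm]] <- flux_process(
        p$name, "first_order", source = p$source, products = p$products,
        fraction = p$fraction, rate_constant = p$vmax / p$km,
        indicator = p$indicator, knockout_tags = p$knockout_tags,
        partition = p$partition)
    } else if (p$kind == "zero_order" && !is.null(p$feedback)) {
      p$feedback$imax <- 0
      out$processes[[nm]] <- p
    }
  }
  out
}

#' Gate all zero-order production off
#'
#' Used by the mass-bookkeeping checks: with production disabled the
#' mole-equivalent total (see [mole_equivalents()]) is conserved along
#' any trajectory.
#'
#' @param model a `keto_model`.
#' @return A clone with every zero-order process gated off.
#' @export
disable_production <- function(model) {
  zo <- names(model$processes)[vapply(model$processes, function(p)
    p$kind == "zero_order", logical(1))]
  model_clone(model, indicators = stats::setNames(rep(0L, length(zo)), zo))
}
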