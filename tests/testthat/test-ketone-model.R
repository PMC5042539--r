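test_that("the built model has the expected anatomy and tagging", {
  m <- model_default
  expect_equal(n_components(m), 5)
  expect_equal(nrow(m$states), 37)
  tags <- sort(unique(unlist(lapply(m$processes, function(p) p$knockout_tags))))
  expect_setequal(tags, as.character(1:10))
  # passive variants gate 3 processes (ester, butanediol, BHB) per segment;
  # apical variants gate MCT1 + SMCT1; basolateral variants gate MCT4
  n_tagged <- function(tag) sum(vapply(m$processes, function(p)
    tag %in% p$knockout_tags, logical(1)))
  for (tag in c("1", "2", "5", "8")) expect_equal(n_tagged(tag), 3)
  for (tag in c("3", "6", "9")) expect_equal(n_tagged(tag), 2)
  for (tag in c("4", "7", "10")) expect_equal(n_tagged(tag), 1)
  # transit and hydrolysis carry no knockout tags (they are not absorption)
  for (nm in grep("^(transit|hydrolysis)\\.", names(m$processes), value = TRUE))
    expect_length(m$processes[[nm]]$knockout_tags, 0)
})

test_that("BHB and AcAc compete on shared systemic carriers but not in the gut", {
  links <- competitive_links(model_default)
  bhb <- links[links$substance == "BHB", ]
  acac <- links[links$substance == "AcAc", ]
  expect_true(all(bhb$competitor_substance == "AcAc"))
  expect_true(all(acac$competitor_substance == "BHB"))
  # every saturable liver/blood/tissue ketone flux is competitive (6 BHB + 6 AcAc
  # directions over MCT1 liver<->blood and MCT1/MCT2 blood<->tissues)
  expect_equal(nrow(links), 12)
  # gut carriers are plain saturable processes without a competitor
  gut <- Filter(function(p) p$kind == "saturable", model_default$processes)
  expect_gt(length(gut), 0)
  expect_true(all(vapply(gut, function(p) is.null(p$competitor), logical(1))))
  expect_true(all(grepl("^(apical|basolateral)\\.", names(gut))))
})

test_that("pinning the competitor at zero reproduces the plain saturable flux", {
  p <- model_default$processes[["liver_to_blood.mct1.BHB"]]
  for (a in c(0.5, 5, 50))
    expect_identical(competitive_rate(p$vmax, p$km, a, p$km_comp, 0),
                     saturable_rate(p$vmax, p$km, a))
})

test_that("builder enforces distal capacity monotonicity and SMCT1 affinity ordering", {
  bad <- fixture_set(fix_default, "gut.lower_distal.mct1.vmax", 1)
  expect_error(build_ketone_model(bad), "non-decreasing")
  bad2 <- fixture_set(fix_default, "gut.upper_distal.smct1.km", 1e5)
  expect_error(build_ketone_model(bad2), "higher affinity")
  # both build fine when the check is explicitly disabled
  expect_s3_class(build_ketone_model(bad, check_monotonicity = FALSE),
                  "keto_model")
})

test_that("a missing fixture parameter is reported by name", {
  fix <- fix_default[fix_default$name != "portal.outflow_k", ]
  class(fix) <- class(fix_default)
  expect_error(build_ketone_model(fix), "portal\\.outflow_k")
})

test_that("zeroing all active-transport capacity equals the all-active knockout", {
  fix0 <- fix_default
  for (seg in c("lower_proximal", "upper_distal", "lower_distal"))
    for (tr in c("mct1", "smct1", "mct4"))
      fix0 <- fixture_set(fix0, paste0("gut.", seg, ".", tr, ".vmax"), 0)
  m0 <- build_ketone_model(fix0)
  m13 <- ko_apply(model_default, set = 13)
  s0 <- run_dose(m0, 192, baseline = baseline_default)
  s13 <- run_dose(m13, 192, baseline = baseline_default)
  expect_equal(s0$amounts, s13$amounts, tolerance = 1e-12)
})

test_that("zero basolateral capacity traps BHB inside the enterocyte", {
  seg <- "lower_proximal"
  fix0 <- fixture_set(fix_default, paste0("gut.", seg, ".mct4.vmax"), 0)
  m0 <- build_ketone_model(fix0, check_monotonicity = FALSE)
  sim <- run_dose(m0, 192, baseline = baseline_default)
  ent <- state_index(m0, paste0(seg, "_enterocyte"), "BHB")
  # material accumulates intracellularly with no way out
  expect_gt(sim$amounts[nrow(sim$amounts), ent], 0)
  expect_true(all(diff(sim$amounts[, ent]) >= -1e-10))
  # zero capacity is trajectory-equivalent to gating the basolateral
  # process off (variant 4)
  sim_ko <- run_dose(ko_apply(model_default, variants = 4L), 192,
                     baseline = baseline_default)
  expect_equal(sim$amounts, sim_ko$amounts, tolerance = 1e-12)
})

test_that("the undosed default model settles below 0.5 mM blood BHB", {
  conc <- baseline_default[paste0("s", state_index(model_default, "blood", "BHB"))] /
    model_default$metadata$blood_volume_L
  expect_gt(conc, 0)
  expect_lt(conc, 0.5)
})
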