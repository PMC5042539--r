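test_that("a two-state first-order chain yields dA/dt = (-kA, +kA)", {
  m <- chain_model(k = 1)
  rhs <- assemble_rhs(m)
  expect_equal(rhs(0, c(10, 0)), c(-10, 10))
  rhs_half <- assemble_rhs(chain_model(k = 1, fraction = 0.5))
  expect_equal(rhs_half(0, c(10, 0)), c(-5, 5))
})

test_that("an indicator-0 process is exactly equivalent to an absent process", {
  with_gate <- model_instance(
    states = list(species_state(1, "blood", "BHB", 10),
                  species_state(2, "tissues", "BHB", 0),
                  species_state(3, "liver", "BHB", 4)),
    processes = list(
      flux_process("keep", "first_order", source = 1, target = 2,
                   rate_constant = 0.3),
      flux_process("gated", "saturable", source = 3, target = 2,
                   vmax = 5, km = 2, indicator = 0L))
  )
  without <- model_instance(
    states = with_gate$states |> split(seq_len(3)) |> lapply(function(r)
      species_state(r$id, r$compartment, r$substance, r$initial)),
    processes = with_gate$processes["keep"]
  )
  r1 <- assemble_rhs(with_gate); r2 <- assemble_rhs(without)
  set.seed(21)
  for (i in 1:10) {
    a <- runif(3, 0, 20)
    expect_identical(r1(0, a), r2(0, a))
  }
})

test_that("assembled derivatives match a direct process-by-process bookkeeping oracle", {
  m <- model_default
  rhs <- assemble_rhs(m)
  # independent route: loop over processes calling the public rate laws
  oracle <- function(A) {
    dA <- numeric(nrow(m$states))
    for (p in m$processes) {
      if (p$indicator == 0L) next
      r <- switch(p$kind,
        first_order = first_order_rate(p$rate_constant, max(A[p$source], 0)),
        saturable = saturable_rate(p$vmax, p$km, max(A[p$source], 0)),
        saturable_competitive = competitive_rate(
          p$vmax, p$km, max(A[p$source], 0), p$km_comp,
          max(A[p$competitor], 0)),
        zero_order = zero_order_with_feedback(
          p$base_rate, p$feedback,
          if (!is.null(p$feedback))
            pmax(A[p$feedback$inhibitor_states], 0)))
      r <- r * p$fraction
      if (!is.null(p$source)) dA[p$source] <- dA[p$source] - r
      tgt <- as.integer(names(p$products))
      dA[tgt] <- dA[tgt] + p$products * r
    }
    dA
  }
  set.seed(22)
  for (i in 1:5) {
    A <- runif(nrow(m$states), 0, 30)
    expect_equal(rhs(0, A), oracle(A), tolerance = 1e-12)
  }
})

test_that("the mole-equivalent derivative equals the instantaneous production rate", {
  m <- model_default
  rhs <- assemble_rhs(m)
  w <- mole_equivalents(m)
  production_rate <- function(A) {
    sum(vapply(Filter(function(p) p$kind == "zero_order" && p$indicator == 1L,
                      m$processes), function(p)
      p$fraction * zero_order_with_feedback(
        p$base_rate, p$feedback,
        if (!is.null(p$feedback)) pmax(A[p$feedback$inhibitor_states], 0)),
      numeric(1)))
  }
  set.seed(23)
  for (i in 1:5) {
    A <- runif(nrow(m$states), 0, 30)
    expect_equal(sum(w * rhs(0, A)), production_rate(A), tolerance = 1e-10)
  }
  m0 <- disable_production(m)
  rhs0 <- assemble_rhs(m0)
  A <- runif(nrow(m$states), 0, 30)
  expect_equal(sum(w * rhs0(0, A)), 0, tolerance = 1e-10)
})

test_that("validation rejects dangling references, leaky sinks and broken fate partitions", {
  states <- list(species_state(1, "blood", "BHB", 1),
                 species_state(2, "faeces_sink", "other", 0))
  expect_error(model_instance(states, list(
    flux_process("bad", "first_order", source = 5, target = 1,
                 rate_constant = 1))), "dangling source")
  expect_error(model_instance(states, list(
    flux_process("bad", "first_order", source = 1, target = 9,
                 rate_constant = 1))), "dangling product")
  expect_error(model_instance(states, list(
    flux_process("leak", "first_order", source = 2, target = 1,
                 rate_constant = 1))), "absorbing")
  expect_error(model_instance(states, list(
    flux_process("half1", "first_order", source = 1, target = 2,
                 rate_constant = 1, fraction = 0.5, partition = "fate"),
    flux_process("half2", "first_order", source = 1, target = 2,
                 rate_constant = 1, fraction = 0.2, partition = "fate"))),
    "fractions sum")
  # complete partition passes
  expect_silent(model_instance(states, list(
    flux_process("half1", "first_order", source = 1, target = 2,
                 rate_constant = 1, fraction = 0.5, partition = "fate"),
    flux_process("half2", "first_order", source = 1, target = 2,
                 rate_constant = 1, fraction = 0.5, partition = "fate"))))
})

test_that("cloning with indicator overrides leaves the original untouched", {
  m <- chain_model()
  clone <- model_clone(m, indicators = c(a_to_b = 0L))
  expect_identical(m$processes$a_to_b$indicator, 1L)
  expect_identical(clone$processes$a_to_b$indicator, 0L)
  expect_error(model_clone(m, indicators = c(nope = 0L)), "unknown process")
})

test_that("model configuration survives a JSON round-trip value-identically", {
  path1 <- withr::local_tempfile(fileext = ".json")
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model_config(model_default, path1)
  m1 <- load_model_config(path1)
  save_model_config(m1, path2)
  m2 <- load_model_config(path2)
  expect_identical(m1$states, m2$states)
  expect_identical(m1$processes, m2$processes)
  expect_identical(m1$parameters, m2$parameters)
  # and the reloaded model is dynamically identical to the in-memory one
  r0 <- assemble_rhs(model_default); r1 <- assemble_rhs(m1)
  A <- model_default$states$initial + 1
  expect_equal(r0(0, A), r1(0, A), tolerance = 1e-12)
})
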