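test_that("toy network optima match the hand calculation and the LP oracle", {
  b <- 0.1
  model <- apply_biomass(make_toy_hepatocyte_gsmn(biomass_demand = b), b)

  # 25 mM glucose via the default transport law: uptake magnitude 25/6
  u <- 5 * 25 / (5 + 25)
  glc <- set_bounds(model, data.frame(reaction = c("EX_glc", "EX_fru"),
                                      lb = c(-u, 0), ub = c(u, 0)))
  s <- solve_fba(glc, "TAGS", "max")
  expect_equal(s$objective, toy_tag_optimum(u, 5, b), tolerance = 1e-8)
  expect_equal(s$objective, (2 * u - b) / 13, tolerance = 1e-8)

  # and against the independent vertex-enumeration oracle
  oracle <- oracle_lp(replace(numeric(length(glc$reactions)),
                              match("TAGS", glc$reactions), 1),
                      as.matrix(glc$S), glc$lb, glc$ub, maximize = TRUE)
  expect_equal(s$objective, oracle$objective, tolerance = 1e-6)

  # empty medium: zero TAG (biomass relaxed so the model stays feasible)
  empty <- apply_biomass(apply_medium(model, c()), 0)
  expect_equal(solve_fba(empty, "TAGS", "max")$objective, 0, tolerance = 1e-9)

  # equal uptake caps on glucose and fructose media give equal TAG optima:
  # the committed-step cap is not binding below it, and fructolysis
  # bypasses it entirely
  for (u_eq in c(2, 3.5)) {
    glc_m <- set_bounds(model, data.frame(reaction = c("EX_glc", "EX_fru"),
                                          lb = c(-u_eq, 0), ub = c(u_eq, 0)))
    fru_m <- set_bounds(model, data.frame(reaction = c("EX_glc", "EX_fru"),
                                          lb = c(0, -u_eq), ub = c(0, u_eq)))
    expect_equal(solve_fba(glc_m, "TAGS", "max")$objective,
                 solve_fba(fru_m, "TAGS", "max")$objective, tolerance = 1e-8)
  }

  # the GK cap binds for glucose but the KHK bypass does not for fructose
  big <- 8
  glc_b <- set_bounds(model, data.frame(reaction = c("EX_glc", "EX_fru"),
                                        lb = c(-big, 0), ub = c(big, 0)))
  fru_b <- set_bounds(model, data.frame(reaction = c("EX_glc", "EX_fru"),
                                        lb = c(0, -big), ub = c(0, big)))
  expect_equal(solve_fba(glc_b, "TAGS", "max")$objective,
               toy_tag_optimum(big, 5, b), tolerance = 1e-8)   # capped at 5
  expect_equal(solve_fba(fru_b, "TAGS", "max")$objective,
               toy_tag_optimum(big, 10, b), tolerance = 1e-8)  # cap 10 > 8
})

test_that("contradictory caps make the generator fail loudly", {
  expect_error(make_toy_hepatocyte_gsmn(gk_cap = 0.01, khk_cap = 0.01,
                                        biomass_demand = 5),
               "unreachable")
  expect_error(make_toy_hepatocyte_gsmn(gk_cap = -1), "> 0")
})

test_that("toy regulome counts, gating and freezing behave as specified", {
  reg <- make_toy_regulome(n_genes = 2, treatment_tokens = 4)
  expect_equal(nrow(reg$map), 2)
  expect_setequal(reg$map$reaction, c("TAGS", "DNL"))
  expect_equal(reg$net$marking[["treatment"]], 4)
  expect_error(make_toy_regulome(n_genes = 10), "between 1 and")

  # induction is necessary: across every gene-level combination, TAG
  # capability exceeds baseline only when g1 is induced
  model <- apply_biomass(reg$model)
  cpl <- coupling_map(genes = as.data.frame(reg$map))
  base <- flux_variability(model, "TAGS")[["vmax"]]
  for (g1 in 0:2) for (g2 in 0:2) {
    m <- c(treatment = 0, TF = 1, g1 = g1, g2 = g2)
    b <- bounds_from_marking(cpl, m, model)
    cap <- flux_variability(set_bounds(model, b), "TAGS")[["vmax"]]
    if (g1 == 2 && g2 >= 1) {
      expect_gt(cap, base + 1e-6)        # TAGS cap released, DNL open
    } else if (g2 == 0) {
      expect_lt(cap, 1e-9)               # lipogenesis shut entirely
    } else {
      expect_lte(cap, base + 1e-9)       # basal TAGS cap still binding
    }
  }

  # frozen (naive) counterpart: capability equals baseline in all states
  naive <- make_regulatory_naive(reg)
  expect_true(all(vapply(naive$net$places[c("TF", "g1", "g2")],
                         `[[`, 0, "marking") == 1))
  expect_length(enabled_transitions(naive$net,
                                    baseline_marking(naive)), 0)
})

test_that("enumerated success probability responds to the token budget", {
  # more agonist tokens make full induction more likely; the default
  # budget puts the toy deep in the induced regime
  p <- vapply(c(1, 2, 4, 8), function(tk) {
    enumerate_success_probability(make_toy_regulome(treatment_tokens = tk))
  }, 0)
  expect_true(all(diff(p) > 0))
  expect_gt(p[4], 0.95)
})

test_that("synthetic uptake observations follow the integrated MM model", {
  times <- seq(0, 24, 2)
  clean <- simulate_uptake_observations(Vmax = 2, Km = 5, S0 = 25,
                                        noise_sd = 0, times = times)
  expect_equal(clean$concentration, mm_depletion(times, 25, 2, 5))

  # insulin scaling strictly accelerates depletion at every positive time
  ins <- simulate_uptake_observations(Vmax = 2, Km = 5, S0 = 25,
                                      insulin_scale = 1.25, noise_sd = 0,
                                      times = times)
  expect_true(all(ins$concentration[-1] < clean$concentration[-1]))

  # seeded reproducibility and tidy shape
  a <- simulate_uptake_observations(2, 5, noise_sd = 0.02, replicates = 3,
                                    times = times, seed = 42)
  b <- simulate_uptake_observations(2, 5, noise_sd = 0.02, replicates = 3,
                                    times = times, seed = 42)
  expect_identical(a, b)
  expect_named(a, c("time", "replicate", "concentration"))
  expect_equal(nrow(a), 3 * length(times))
  expect_true(all(a$concentration >= 0))
  expect_error(simulate_uptake_observations(-1, 5), "non-negative")
})

test_that("generated fixtures satisfy their structural invariants", {
  model <- make_toy_hepatocyte_gsmn()
  expect_true(all(model$lb <= model$ub))
  expect_true(all(model$exchange %in% model$reactions))
  # every exchange reaction touches exactly one metabolite
  for (rx in model$exchange) {
    expect_equal(sum(model$S[, rx] != 0), 1)
  }
  reg <- make_toy_regulome(n_genes = 3)
  expect_silent(validate_marking(reg$net, reg$net$marking))
  expect_false(anyDuplicated(paste(reg$map$gene, reg$map$reaction)) > 0)
  expect_true(all(reg$map$reaction %in% reg$model$reactions))
})
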