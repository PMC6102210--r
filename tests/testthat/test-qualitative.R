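reg_setup <- function(n_genes = 1) {
  reg <- make_toy_regulome(n_genes = n_genes)
  list(reg = reg,
       model = apply_biomass(reg$model),
       cpl = coupling_map(genes = as.data.frame(reg$map)))
}

test_that("untreated trajectories stay at baseline with zero events", {
  s <- reg_setup()
  tr <- run_trajectory(s$model, s$cpl, s$reg, treatment = 0, seed = 1)
  expect_equal(nrow(tr$events), 0)
  expect_equal(unname(tr$fluxes[1, "TAGS"]), tr$baseline$fluxes[["TAGS"]])
  ph <- detect_phases(tr)
  expect_null(ph$acute)
  expect_null(ph$reconstitutive)
  expect_true(ph$returned_to_baseline)
})

test_that("trajectories are bit-reproducible given a seed", {
  s <- reg_setup()
  tr1 <- run_trajectory(s$model, s$cpl, s$reg, seed = 123)
  tr2 <- run_trajectory(s$model, s$cpl, s$reg, seed = 123)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$markings, tr2$markings)
  expect_identical(tr1$fluxes, tr2$fluxes)
  # the process is genuinely stochastic: different seeds explore
  # different event orders (over a batch, not any fixed pair)
  seqs <- vapply(1:10, function(s2) {
    paste(run_trajectory(s$model, s$cpl, s$reg, seed = s2)$events$transition,
          collapse = ">")
  }, "")
  expect_gt(length(unique(seqs)), 1)
})

test_that("every recorded event was enabled at its predecessor marking", {
  s <- reg_setup(n_genes = 2)
  for (seed in 1:10) {
    tr <- run_trajectory(s$model, s$cpl, s$reg, seed = seed)
    for (k in seq_len(nrow(tr$events))) {
      m_prev <- tr$markings[k, ]
      expect_true(tr$events$transition[k] %in%
                    enabled_transitions(s$reg$net, m_prev))
      expect_identical(unname(fire(s$reg$net, m_prev, tr$events$transition[k])),
                       unname(tr$markings[k + 1, ]))
    }
  }
})

test_that("the scheduler draws uniformly among enabled transitions", {
  # four independently enabled clearance-style transitions; check the first
  # draw over many trajectories against exact binomial bounds at n = 10000
  places <- lapply(1:4, function(i) {
    pn_place(paste0("t", i), "treatment", marking = 1, discrete = TRUE,
             level_range = c(0L, 1L))
  })
  trans <- lapply(1:4, function(i) {
    pn_transition(paste0("c", i), "rule", pn_arcs(paste0("t", i), 1, "consume"))
  })
  net <- petri_net(places, trans)
  reg <- structure(list(net = net, map = tibble::tibble(
    gene = character(0), reaction = character(0), effect = character(0)),
    model = NULL, tf = NULL, treatment_place = "t1", frozen = FALSE),
    class = "regulome_model")
  model <- apply_biomass(make_toy_hepatocyte_gsmn())
  cpl <- coupling_map()
  cache <- new.env(parent = emptyenv())
  n <- 10000
  firsts <- vapply(seq_len(n), function(s) {
    run_trajectory(model, cpl, reg, monitored = "TAGS", max_steps = 1,
                   seed = s, cache = cache)$events$transition[1]
  }, "")
  counts <- table(factor(firsts, levels = paste0("c", 1:4)))
  # exact 99.9% binomial band per transition at p = 1/4
  band <- qbinom(c(5e-4, 1 - 5e-4), n, 0.25)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("ensembles reproduce from the master seed and wrap n = 1 cleanly", {
  s <- reg_setup()
  e1 <- run_ensemble(s$model, s$cpl, s$reg, n = 5, master_seed = 77)
  e2 <- run_ensemble(s$model, s$cpl, s$reg, n = 5, master_seed = 77)
  expect_identical(lapply(e1$trajectories, `[[`, "events"),
                   lapply(e2$trajectories, `[[`, "events"))
  single <- run_ensemble(s$model, s$cpl, s$reg, n = 1, master_seed = 3)
  expect_equal(single$n, 1)
  expect_length(single$trajectories, 1)
  expect_error(run_ensemble(s$model, s$cpl, s$reg, n = 0), "n must be")
})

test_that("fraction statistics carry exact binomial confidence intervals", {
  s <- reg_setup()
  ens <- run_ensemble(s$model, s$cpl, s$reg, n = 30, master_seed = 5)
  fs <- fraction_increased_flux(ens, "TAGS")
  expect_gte(fs$conf_low, 0); expect_lte(fs$conf_high, 1)
  expect_true(fs$conf_low <= fs$fraction && fs$fraction <= fs$conf_high)
  expect_equal(fs$n, 30)
  expect_error(fraction_increased_flux(ens, "NOT_MONITORED"), "not monitored")

  # degenerate edges: all increased / none increased
  naive <- make_regulatory_naive(s$reg)
  ens0 <- run_ensemble(s$model, s$cpl, naive, n = 10, master_seed = 2)
  fs0 <- fraction_increased_flux(ens0, "TAGS")
  expect_identical(fs0$fraction, 0)
})

test_that("the empirical fraction matches the enumerated success probability", {
  s <- reg_setup()
  p_star <- enumerate_success_probability(s$reg)
  ens <- run_ensemble(s$model, s$cpl, s$reg, n = 1000, master_seed = 11)
  fs <- fraction_increased_flux(ens, "TAGS")
  band <- binom_band(1000, p_star)
  expect_gte(fs$fraction, band[1])
  expect_lte(fs$fraction, band[2])
})

test_that("enumeration agrees with the hand-computed single-token case", {
  # one agonist token: success requires TF induction before clearance and
  # target induction before TF relaxes; by hand the probability is 3/8
  reg <- make_toy_regulome(treatment_tokens = 1)
  expect_equal(enumerate_success_probability(reg, "g1"), 3 / 8)
  # and the TF itself is induced in exactly half of all runs
  expect_equal(enumerate_success_probability(reg, "TF"), 1 / 2)
})

test_that("regulatory-naive models show no regulatory events and no induction", {
  s <- reg_setup()
  naive <- make_regulatory_naive(s$reg)
  expect_true(naive$frozen)
  gene_ids <- c("TF", "g1")
  for (seed in 1:5) {
    tr <- run_trajectory(s$model, s$cpl, naive, seed = seed)
    # only clearance events remain; gene levels never move
    expect_true(all(tr$events$transition == "treatment_clear"))
    expect_true(all(tr$markings[, gene_ids] == 1))
    expect_true(all(abs(tr$fluxes[, "TAGS"] -
                          tr$baseline$fluxes[["TAGS"]]) < 1e-9))
  }
})

test_that("naive-vs-competent contrast and phase structure hold on the toy", {
  s <- reg_setup()
  ens_c <- run_ensemble(s$model, s$cpl, s$reg, n = 100, master_seed = 42)
  fs_c <- fraction_increased_flux(ens_c, "TAGS")
  expect_gte(fs_c$fraction, 0.9)

  naive <- make_regulatory_naive(s$reg)
  ens_n <- run_ensemble(s$model, s$cpl, naive, n = 100, master_seed = 42)
  expect_identical(fraction_increased_flux(ens_n, "TAGS")$fraction, 0)

  # competent trajectories that responded show a reconstitutive phase;
  # naive trajectories never do
  ph_c <- detect_phases(ens_c$trajectories[[1]])
  expect_false(is.null(ph_c$reconstitutive))
  for (tr in ens_n$trajectories[1:10]) {
    expect_null(detect_phases(tr)$reconstitutive)
  }
})

test_that("detect_phases finds constructed square-pulse boundaries", {
  # hand-built trajectory (step = row - 1): tokens hit 0 at step 2, flux
  # and marking return to baseline at step 4 and stay there
  markings <- rbind(c(treatment = 2, g = 1), c(1, 1), c(0, 2),
                    c(0, 2), c(0, 1), c(0, 1))
  colnames(markings) <- c("treatment", "g")
  fluxes <- matrix(c(1, 1, 2, 2, 1, 1), ncol = 1,
                   dimnames = list(NULL, "R"))
  tr <- structure(list(
    events = tibble::tibble(step = 1:5, transition = letters[1:5]),
    markings = markings, fluxes = fluxes, monitored = "R", seed = 1,
    treatment_place = "treatment",
    baseline = list(marking = c(treatment = 0, g = 1), fluxes = c(R = 1))),
    class = "trajectory")
  ph <- detect_phases(tr, window = 2)
  expect_equal(ph$acute, c(0L, 2L))
  expect_equal(ph$reconstitutive, c(2L, 4L))
  expect_true(ph$returned_to_baseline)
})

test_that("flux matrices are event-ordered with the declared dimensions", {
  s <- reg_setup(n_genes = 2)
  tr <- run_trajectory(s$model, s$cpl, s$reg, seed = 9)
  M <- flux_heatmap_matrix(tr)
  expect_equal(ncol(M), nrow(tr$events))
  expect_equal(rownames(M), tr$monitored)
  expect_error(flux_heatmap_matrix(tr, character(0)), "empty")
  expect_error(flux_heatmap_matrix(tr, "bogus"), "not monitored")

  # all-zero fluxes give an all-neutral matrix; a sign flip shows as one
  # row changing class at the flip index
  tr$fluxes[] <- 0
  expect_true(all(flux_heatmap_matrix(tr) == 0))
  tr$fluxes[, 1] <- c(rep(-1, 3), rep(1, nrow(tr$fluxes) - 3))
  M2 <- flux_heatmap_matrix(tr)
  expect_equal(unname(sign(M2[1, ])), sign(tr$fluxes[-1, 1]))
})

test_that("regulome tables parse with deduplication and validation", {
  f <- write_regulome_csv(data.frame(
    gene_id = "PPARA_T1", reaction_id = c("r1", "r2"),
    effect = "activates"))
  expect_message(map <- parse_regulome(f), "1 genes regulating 2 reactions")
  expect_equal(nrow(map), 2)

  fdup <- write_regulome_csv(data.frame(
    gene_id = "g", reaction_id = c("r1", "r1"), effect = "activates"))
  expect_warning(expect_message(m2 <- parse_regulome(fdup)), "duplicate")
  expect_equal(nrow(m2), 1)

  fbad <- write_regulome_csv(data.frame(
    gene_id = "g", reaction_id = "r", effect = "boosts"))
  expect_error(parse_regulome(fbad), "unknown effect .* line 2")
  fcol <- write_regulome_csv(data.frame(gene = "g", reaction = "r"))
  expect_error(parse_regulome(fcol), "missing column")

  # a synthetic table at the full regulome's scale: 91 genes, 233 reactions
  set.seed(1)
  genes <- sprintf("G%02d", 1:91)
  rxns <- sprintf("r%03d", 1:233)
  tab <- data.frame(gene_id = rep(genes, length.out = 233),
                    reaction_id = rxns,
                    effect = sample(c("activates", "represses"), 233, TRUE))
  fbig <- write_regulome_csv(tab)
  expect_message(big <- parse_regulome(fbig), "91 genes regulating 233 reactions")
  expect_equal(length(unique(big$gene)), 91)
  expect_equal(length(unique(big$reaction)), 233)
})
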