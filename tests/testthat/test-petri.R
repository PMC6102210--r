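test_that("enabled_transitions matches brute-force guard evaluation", {
  # empty net
  empty <- petri_net(list(pn_place("p", "species", 1)))
  expect_identical(enabled_transitions(empty), character(0))

  # single gene motif with its activator marked: only induce is enabled
  act <- pn_place("act", "treatment", marking = 1, discrete = TRUE,
                  level_range = c(0L, 1L))
  motif <- gene_motif("g", activator = "act")
  net <- petri_net(c(list(act, motif$place)), motif$transitions)
  expect_identical(enabled_transitions(net), "g_induce")

  # 3-transition toy net across its reachable markings
  net3 <- toy_rule_net()
  markings <- list(
    net3$marking,
    c(buf = 0, out = 2, sig = 0),
    c(buf = 1, out = 1, sig = 0.5),
    c(buf = 0, out = 0, sig = 1))
  for (m in markings) {
    expect_identical(enabled_transitions(net3, m), brute_force_enabled(net3, m))
  }
})

test_that("fire applies arc arithmetic and rejects disabled transitions", {
  act <- pn_place("act", "treatment", marking = 1, discrete = TRUE,
                  level_range = c(0L, 1L))
  motif <- gene_motif("g", activator = "act")
  net <- petri_net(c(list(act, motif$place)), motif$transitions)
  m2 <- fire(net, net$marking, "g_induce")
  expect_equal(m2[["g"]], 2)

  # treatment token cleared by a consume arc of weight 1
  net3 <- toy_rule_net()
  m <- fire(net3, net3$marking, "move")
  expect_equal(m[["buf"]], 1)
  expect_equal(m[["out"]], 1)

  # disabled: gated requires sig present
  expect_error(fire(net3, net3$marking, "gated"), "not enabled")

  # random firing sequences agree with direct arc arithmetic
  for (seed in 1:20) {
    withr::with_seed(seed, {
      m <- net3$marking
      for (step in 1:6) {
        en <- enabled_transitions(net3, m)
        if (!length(en)) break
        id <- sample(en, 1)
        tr <- net3$transitions[[id]]
        expected <- m
        for (i in seq_len(nrow(tr$arcs))) {
          a <- tr$arcs[i, ]
          if (a$kind == "consume") expected[[a$place]] <- expected[[a$place]] - a$weight
          if (a$kind == "produce") expected[[a$place]] <- expected[[a$place]] + a$weight
        }
        m <- fire(net3, m, id)
        expect_identical(m, expected)
      }
    })
  }
})

test_that("firing is deterministic and never violates place invariants", {
  net <- toy_rule_net()
  m1 <- fire(net, net$marking, "move")
  m2 <- fire(net, net$marking, "move")
  expect_identical(m1, m2)
  # exhaustive reachability: every reachable marking satisfies invariants
  seen <- new.env(parent = emptyenv())
  frontier <- list(net$marking)
  while (length(frontier)) {
    m <- frontier[[1]]; frontier <- frontier[-1]
    key <- paste(m, collapse = "|")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    expect_silent(validate_marking(net, m))
    for (id in enabled_transitions(net, m)) {
      frontier <- c(frontier, list(fire(net, m, id)))
    }
  }
})

test_that("gene motif is reversible: basal level reachable once regulators absent", {
  act <- pn_place("act", "treatment", marking = 1, discrete = TRUE,
                  level_range = c(0L, 1L))
  inh <- pn_place("inh", "treatment", marking = 0, discrete = TRUE,
                  level_range = c(0L, 1L))
  motif <- gene_motif("g", activator = "act", inhibitor = "inh")
  net <- petri_net(list(act, inh, motif$place), motif$transitions)

  # drive to induced, drop the activator, relax restores basal in one firing
  m <- fire(net, net$marking, "g_induce")
  expect_equal(m[["g"]], 2)
  m[["act"]] <- 0
  expect_true("g_relax_down" %in% enabled_transitions(net, m))
  m <- fire(net, m, "g_relax_down")
  expect_equal(m[["g"]], 1)
  expect_false(any(grepl("relax", enabled_transitions(net, m))))

  # and from the repressed side
  m[["inh"]] <- 1
  m <- fire(net, m, "g_repress")
  expect_equal(m[["g"]], 0)
  m[["inh"]] <- 0
  m <- fire(net, m, "g_relax_up")
  expect_equal(m[["g"]], 1)
})

test_that("kinetic_step performs an explicit-Euler update with clipping", {
  # all rates zero: marking unchanged
  still <- petri_net(
    list(pn_place("x", "species", 1)),
    list(pn_transition("dx", "kinetic", pn_arcs("x", 1, "consume"),
                       rate_law = kinetic_law("constant", rate = 0))))
  expect_identical(kinetic_step(still, dt = 0.1), still$marking)

  # first-order decay, k = 1/h, x0 = 1, dt = 0.1 -> 0.9
  decay <- petri_net(
    list(pn_place("x", "species", 1)),
    list(pn_transition("dx", "kinetic", pn_arcs("x", 1, "consume"),
                       rate_law = kinetic_law("mass_action", k = 1))))
  expect_equal(kinetic_step(decay, dt = 0.1)[["x"]], 0.9)
  expect_error(kinetic_step(decay, dt = -0.1), "dt")

  # clipping at zero warns
  fast <- petri_net(
    list(pn_place("x", "species", 0.1)),
    list(pn_transition("dx", "kinetic", pn_arcs("x", 1, "consume"),
                       rate_law = kinetic_law("constant", rate = 10))))
  expect_warning(m <- kinetic_step(fast, dt = 1), "clipped")
  expect_equal(m[["x"]], 0)
})

test_that("two-step kinetic cascade converges to the fine-step reference", {
  cascade <- petri_net(
    list(pn_place("a", "species", 1), pn_place("b", "species", 0),
         pn_place("c", "species", 0)),
    list(pn_transition("v1", "kinetic",
                       rbind(pn_arcs("a", 1, "consume"), pn_arcs("b", 1, "produce")),
                       rate_law = kinetic_law("mass_action", k = 2)),
         pn_transition("v2", "kinetic",
                       rbind(pn_arcs("b", 1, "consume"), pn_arcs("c", 1, "produce")),
                       rate_law = kinetic_law("mass_action", k = 1))))
  run <- function(dt, t_end = 1) {
    m <- cascade$marking
    for (i in seq_len(round(t_end / dt))) m <- kinetic_step(cascade, m, dt)
    m
  }
  coarse <- run(0.05)
  fine <- run(0.0005)
  # explicit Euler is first order: error at dt = 0.05 stays O(dt)
  expect_lt(max(abs(coarse - fine)), 5 * 0.05)
  # and shrinks roughly linearly with dt
  mid <- run(0.005)
  expect_lt(max(abs(mid - fine)), 0.5 * max(abs(coarse - fine)))
})
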