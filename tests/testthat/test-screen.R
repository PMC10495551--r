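test_that("perturbation enumeration flips exactly one fixed node per condition", {
  net <- boolean_network(list(A = NULL, B = NULL, C = NULL, D = "A"))
  base <- initial_conditions(c(A = 1L, B = 0L, C = 1L), "curated")
  perts <- enumerate_perturbations(base, net)
  expect_length(perts, 3L)
  expect_identical(vapply(perts, `[[`, character(1), "id"), c("C1", "C2", "C3"))
  for (p in perts) {
    diffs <- names(which(p$conditions$values != base$values[names(p$conditions$values)]))
    expect_identical(diffs, p$node)
    expect_identical(p$conditions$values[[p$node]], p$flipped_to)
    expect_identical(p$flipped_to, 1L - base$values[[p$node]])
  }
  # scope=inputs drops fixed non-input nodes
  base2 <- initial_conditions(c(A = 1L, D = 1L), "curated")
  expect_length(enumerate_perturbations(base2, net, scope = "inputs"), 1L)
  expect_error(enumerate_perturbations(initial_conditions(), net), "empty")
})

test_that("profile classification uses a strict glycolytic threshold", {
  expect_identical(classify_profile(c(glycolytic = 85.05, oxidative = 14.95)),
                   "glycolytic")
  expect_identical(classify_profile(c(glycolytic = 4, oxidative = 96)),
                   "oxidative")
  expect_identical(classify_profile(c(glycolytic = 50, oxidative = 50)),
                   "oxidative") # boundary goes to oxidative
  expect_identical(classify_profile(NULL), "infeasible")
})

test_that("the screen reproduces the planted switch and finds the driver", {
  sys <- make_toy_coupled_model(seed = 4)
  scr <- run_screen(sys$net, sys$baseline, sys$map, sys$model, sys$objective)
  expect_identical(attr(scr, "control_class"), "oxidative")
  expect_identical(scr$class[scr$id == "baseline"], "glycolytic")
  expect_equal(scr$glycolytic[scr$id == "baseline"], 100)
  hyp <- scr[!is.na(scr$node) & scr$node == "Hypoxia", ]
  expect_identical(hyp$class, "oxidative")
  expect_equal(hyp$oxidative, 100 * 100 / 140, tolerance = 1e-9)
  # decoys stay glycolytic
  dec <- scr[!is.na(scr$node) & scr$node != "Hypoxia", ]
  expect_true(all(dec$class == "glycolytic"))
  expect_identical(identify_drivers(scr), "Hypoxia")
})

test_that("the screen result includes the baseline and is deterministic", {
  sys <- make_toy_coupled_model(seed = 9)
  a <- run_screen(sys$net, sys$baseline, sys$map, sys$model, sys$objective)
  b <- run_screen(sys$net, sys$baseline, sys$map, sys$model, sys$objective)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(a$id[1], "baseline")
  expect_identical(nrow(a), length(sys$baseline$values) + 1L)
})

test_that("per-condition failures are recorded without aborting the screen", {
  sys <- make_toy_coupled_model(seed = 1)
  rxns <- sys$model$reactions
  rxns$lb[rxns$id == "EX_lac"] <- 5 # forced lactate secretion in every run
  model <- metabolic_model(sys$model$metabolites, rxns, sys$model$stoichiometry)
  # second mapped component keeps LDH open only while HIF1 is on, so the
  # hypoxia knock-out blocks the only lactate source and becomes infeasible
  net <- boolean_network(
    c(sys$net$functions, list(LDHN = "HIF1")),
    annotations = sys$net$annotations
  )
  map <- component_map(c("PDH", "LDHN"), c("enzyme", "enzyme"),
                       list("TCA", "LDH"))
  base <- initial_conditions(c(Hypoxia = 1L), "curated")
  scr <- run_screen(net, base, map, model, sys$objective)
  expect_identical(scr$class[scr$id == "baseline"], "glycolytic")
  hyp <- scr[!is.na(scr$node) & scr$node == "Hypoxia", ]
  expect_identical(hyp$status, "infeasible")
  expect_identical(hyp$class, "infeasible")
  expect_false("Hypoxia" %in% identify_drivers(scr))
})

test_that("an empty flip-to-control screen yields no drivers", {
  sys <- make_toy_coupled_model(seed = 1)
  # remove the planted driver from the baseline: only decoys get flipped
  vals <- sys$baseline$values[setdiff(names(sys$baseline$values), "Hypoxia")]
  base <- initial_conditions(vals, "data-driven")
  # clamp hypoxia on permanently via the network instead
  net <- boolean_network(
    c(list(Hypoxia = TRUE),
      sys$net$functions[setdiff(sys$net$nodes, "Hypoxia")]),
    annotations = sys$net$annotations
  )
  scr <- run_screen(net, base, sys$map, sys$model, sys$objective)
  expect_length(identify_drivers(scr), 0L)
})
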