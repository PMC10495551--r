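test_that("FBA solves a single linear pathway", {
  model <- metabolic_model(
    metabolites = data.frame(id = c("A", "B"), compartment = "c",
                             formula = c("C1", "C1")),
    reactions = data.frame(id = c("EX_A", "R1", "EX_B"),
                           lb = c(-4, 0, 0), ub = c(0, 100, 100),
                           exchange = c(TRUE, FALSE, TRUE)),
    stoichiometry = data.frame(
      reaction = c("EX_A", "R1", "R1", "EX_B"),
      metabolite = c("A", "A", "B", "B"),
      coefficient = c(-1, -1, 1, -1))
  )
  obj <- objective_spec(glycolytic = "R1", oxidative = character(0))
  f <- run_fba(model, obj)
  expect_identical(f$status, "optimal")
  expect_equal(f$objective_value, 4)
})

test_that("toy model optimum routes pyruvate oxidatively when open", {
  sys <- make_toy_coupled_model(seed = 1)
  f <- run_fba(sys$model, sys$objective)
  expect_equal(f$objective_value, 140)      # 20 PGK + 20 PYK + 100 CV
  expect_equal(unname(f$fluxes[c("PGK", "PYK", "CV", "LDH")]),
               c(20, 20, 100, 0))
  sh <- atp_shares(f)
  expect_equal(unname(sh), c(100 * 40 / 140, 100 * 100 / 140))
  expect_equal(sum(sh), 100, tolerance = 1e-6)
})

test_that("blocking the TCA lump diverts all pyruvate to lactate", {
  sys <- make_toy_coupled_model(seed = 1)
  blocked <- apply_constraints(sys$model, structure(
    data.frame(reaction = "TCA", lb = 0, ub = 0),
    class = c("flux_constraints", "data.frame")))
  f <- run_fba(blocked, sys$objective)
  expect_equal(f$objective_value, 40)
  expect_equal(unname(f$fluxes[c("LDH", "TCA", "CV")]), c(20, 0, 0))
  sh <- atp_shares(f)
  expect_equal(unname(sh), c(100, 0))
})

test_that("returned distributions satisfy steady state and bounds", {
  sys <- make_toy_coupled_model(seed = 1)
  for (block in list(character(0), "TCA", "CV", c("LDH"))) {
    cs <- structure(
      data.frame(reaction = block, lb = numeric(length(block)),
                 ub = numeric(length(block))),
      class = c("flux_constraints", "data.frame"))
    m <- apply_constraints(sys$model, cs)
    f <- run_fba(m, sys$objective)
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% f$fluxes)), 1e-6)
    expect_true(all(f$fluxes >= m$reactions$lb - 1e-9))
    expect_true(all(f$fluxes <= m$reactions$ub + 1e-9))
  }
})

test_that("the optimum certifies against feasible comparison points", {
  # any feasible scaled-down copy of the optimum must not beat it
  sys <- make_toy_coupled_model(seed = 1)
  f <- run_fba(sys$model, sys$objective)
  cc <- as.numeric(sys$model$reactions$id %in% sys$objective$reaction)
  for (lambda in c(0, 0.25, 0.5, 0.9)) {
    v <- lambda * f$fluxes # feasible: S v = 0 and 0 is inside all bounds
    expect_lte(sum(cc * v), f$objective_value + 1e-9)
  }
})

test_that("infeasible models are reported, not fabricated", {
  sys <- make_toy_coupled_model(seed = 1)
  rxns <- sys$model$reactions
  rxns$lb[rxns$id == "EX_lac"] <- 5   # force lactate secretion
  rxns$lb[rxns$id == "LDH"] <- 0
  rxns$ub[rxns$id == "LDH"] <- 0      # ... while blocking its only source
  m <- metabolic_model(sys$model$metabolites, rxns, sys$model$stoichiometry)
  f <- run_fba(m, sys$objective)
  expect_identical(f$status, "infeasible")
  expect_true(is.na(f$objective_value))
  expect_error(atp_shares(f), "undefined")
})

test_that("carbon flux shares weight fluxes by carbon count", {
  # uptake of glucose (C6) at 2 and acetate (C2) at 3: shares 12/18 and 6/18
  model <- metabolic_model(
    metabolites = data.frame(id = c("glc", "ac", "x"), compartment = "c",
                             formula = c("C6H12O6", "C2H3O2", "C8")),
    reactions = data.frame(id = c("EX_glc", "EX_ac", "MK", "EX_x"),
                           lb = c(-2, -3, 0, 0), ub = c(0, 0, 100, 100),
                           exchange = c(TRUE, TRUE, FALSE, TRUE)),
    stoichiometry = data.frame(
      reaction = c("EX_glc", "EX_ac", "MK", "MK", "MK", "EX_x"),
      metabolite = c("glc", "ac", "glc", "ac", "x", "x"),
      coefficient = c(-1, -1, -1, -1.5, 1, -1)) # 1 glc + 1.5 ac -> x
  )
  f <- run_fba(model, objective_spec("MK", character(0)))
  up <- carbon_flux_shares(model, f, "uptake")
  expect_equal(up$share[up$reaction == "EX_glc"], 100 * 12 / 18, tolerance = 1e-9)
  expect_equal(up$share[up$reaction == "EX_ac"], 100 * 6 / 18, tolerance = 1e-9)
  expect_equal(sum(up$share), 100, tolerance = 1e-9)
  sec <- carbon_flux_shares(model, f, "secretion")
  expect_identical(sec$reaction, "EX_x") # single secreted carbon: 100%
  expect_equal(sec$share, 100)
})

test_that("carbon-free exchanges are excluded and formulas are required", {
  sys <- make_toy_coupled_model(seed = 1)
  f <- run_fba(sys$model, sys$objective)
  up <- carbon_flux_shares(sys$model, f, "uptake")
  expect_false("EX_o2" %in% up$reaction)    # O2 carries no carbon
  expect_identical(up$reaction, "EX_glc")
  expect_equal(up$share, 100)
  mets <- sys$model$metabolites
  mets$formula[mets$id == "glc"] <- NA
  m2 <- metabolic_model(mets, sys$model$reactions, sys$model$stoichiometry)
  expect_error(carbon_flux_shares(m2, f, "uptake"), "without a chemical formula.*glc")
  expect_error(formula_element_count("C2R"), "not countable")
})

test_that("carbon is conserved across the boundary at steady state", {
  sys <- make_toy_coupled_model(seed = 1)
  for (block in list(character(0), "TCA")) {
    cs <- structure(
      data.frame(reaction = block, lb = numeric(length(block)),
                 ub = numeric(length(block))),
      class = c("flux_constraints", "data.frame"))
    m <- apply_constraints(sys$model, cs)
    f <- run_fba(m, sys$objective)
    ex <- boolfba:::exchange_metabolites(m)
    carbons <- formula_element_count(
      m$metabolites$formula[match(ex$metabolite, m$metabolites$id)])
    net_in <- sum(carbons * ex$coefficient * f$fluxes[ex$reaction])
    expect_equal(net_in, 0, tolerance = 1e-6)
  }
})

test_that("flux comparison reports fold changes and activation classes", {
  mk <- function(v) structure(list(fluxes = v, objective_value = sum(v),
                                   status = "optimal"),
                              class = "flux_distribution")
  ctrl <- mk(c(R1 = 10, R2 = 10, R3 = 0, R4 = 5, R5 = -8))
  dis <- mk(c(R1 = 25, R2 = 10, R3 = 5, R4 = 0, R5 = -3))
  cmp <- compare_fluxes(ctrl, dis)
  expect_identical(cmp$change[cmp$reaction == "R1"], "increased")
  expect_equal(cmp$ratio[cmp$reaction == "R1"], 2.5)
  expect_false("R2" %in% cmp$reaction)                 # unchanged
  expect_identical(cmp$change[cmp$reaction == "R3"], "activated")
  expect_identical(cmp$change[cmp$reaction == "R4"], "silenced")
  expect_identical(cmp$change[cmp$reaction == "R5"], "decreased") # magnitudes
  expect_error(compare_fluxes(ctrl, mk(c(A = 1))), "different reaction sets")
})

test_that("objective specifications round-trip through YAML", {
  obj <- objective_spec(glycolytic = c("PGK", "PYK"), oxidative = "CV")
  f <- tempfile(fileext = ".yaml")
  write_objective_yaml(obj, f)
  back <- read_objective_yaml(f)
  expect_identical(back$reaction, obj$reaction)
  expect_identical(back$role, obj$role)
  expect_error(objective_spec("A", "A"), "both roles")
})
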