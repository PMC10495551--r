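test_that("asymptotic maximum is 0 only when fixed at 0 everywhere", {
  spaces <- list(c(A = 0L, B = 1L), c(A = 0L, B = 0L))
  expect_identical(component_asymptotic_max(spaces, "A"), 0L)
  expect_identical(component_asymptotic_max(spaces, "B"), 1L)
  # free in one space counts as potentially active
  spaces2 <- list(c(A = 0L), c(B = 1L))
  expect_identical(component_asymptotic_max(spaces2, "A"), 1L)
  net <- toy_core_net()
  expect_error(component_asymptotic_max(spaces, "Nope", net), "absent")
  expect_error(component_asymptotic_max(list(), "A"), "no trap spaces")
})

test_that("hypoxic trap spaces constrain the PDH-linked reaction", {
  sys <- make_toy_coupled_model(seed = 1)
  clamped <- apply_clamping(sys$net, clamping(c(Hypoxia = 1)))
  spaces <- compute_minimal_trap_spaces(clamped)
  cs <- derive_constraints(spaces, sys$map, net = sys$net, model = sys$model)
  expect_identical(cs$reaction, "TCA")
  expect_identical(cs$justification[[1]], "PDH")
  expect_equal(cs$lb, 0)
  expect_equal(cs$ub, 0)
})

test_that("active components contribute no constraints", {
  sys <- make_toy_coupled_model(seed = 1)
  clamped <- apply_clamping(sys$net, clamping(c(Hypoxia = 0)))
  spaces <- compute_minimal_trap_spaces(clamped)
  cs <- derive_constraints(spaces, sys$map, net = sys$net, model = sys$model)
  expect_identical(nrow(cs), 0L)
})

test_that("a reaction reached through two components is listed once with both justifications", {
  net <- boolean_network(list(E = FALSE, M = FALSE)) # both asymptotically off
  spaces <- compute_minimal_trap_spaces(net)
  map <- component_map(c("E", "M"), c("enzyme", "metabolite"),
                       list("R1", "R1"))
  cs <- derive_constraints(spaces, map)
  expect_identical(cs$reaction, "R1")
  expect_setequal(cs$justification[[1]], c("E", "M"))
})

test_that("applying constraints is pure, idempotent and validated", {
  sys <- make_toy_coupled_model(seed = 1)
  cs <- structure(data.frame(reaction = "TCA", lb = 0, ub = 0),
                  class = c("flux_constraints", "data.frame"))
  m2 <- apply_constraints(sys$model, cs)
  expect_equal(m2$reactions$ub[m2$reactions$id == "TCA"], 0)
  # original untouched
  expect_equal(sys$model$reactions$ub[sys$model$reactions$id == "TCA"], 1000)
  # idempotent
  m3 <- apply_constraints(m2, cs)
  expect_identical(m3$reactions, m2$reactions)
  # empty set: identity
  empty <- structure(data.frame(reaction = character(), lb = numeric(),
                                ub = numeric()),
                     class = c("flux_constraints", "data.frame"))
  expect_identical(apply_constraints(sys$model, empty), sys$model)
  bad <- structure(data.frame(reaction = "NOPE", lb = 0, ub = 0),
                   class = c("flux_constraints", "data.frame"))
  expect_error(apply_constraints(sys$model, bad), "NOPE")
})

test_that("constraints only ever tighten the optimum", {
  sys <- make_toy_coupled_model(seed = 1)
  base <- run_fba(sys$model, sys$objective)$objective_value
  for (block in list("TCA", "CV", "LDH", c("TCA", "LDH"))) {
    cs <- structure(
      data.frame(reaction = block, lb = numeric(length(block)),
                 ub = numeric(length(block))),
      class = c("flux_constraints", "data.frame"))
    f <- run_fba(apply_constraints(sys$model, cs), sys$objective)
    if (f$status == "optimal") expect_lte(f$objective_value, base + 1e-9)
  }
})

test_that("constraint derivation is monotone in the trap-space set", {
  map <- component_map(c("A", "B"), c("enzyme", "enzyme"), list("R1", "R2"))
  s1 <- list(c(A = 0L, B = 0L))
  s2 <- c(s1, list(c(A = 0L, B = 1L)))
  c1 <- derive_constraints(s1, map)
  c2 <- derive_constraints(s2, map)
  expect_true(all(c2$reaction %in% c1$reaction)) # more spaces, fewer constraints
})

test_that("metabolite map entries must name producible reactions", {
  sys <- make_toy_coupled_model(seed = 1)
  ok <- component_map("LacNode", "metabolite", list("LDH"), metabolite = "lac")
  expect_silent(validate_component_map(ok, sys$model))
  # lac has negative stoichiometry in its irreversible exchange: not producing
  bad <- component_map("LacNode", "metabolite", list("EX_lac"), metabolite = "lac")
  expect_error(validate_component_map(bad, sys$model), "cannot produce")
  # but a reversible consumer counts (it can run backwards)
  rxns <- sys$model$reactions
  rxns$lb[rxns$id == "EX_lac"] <- -1000
  m2 <- metabolic_model(sys$model$metabolites, rxns, sys$model$stoichiometry)
  expect_silent(validate_component_map(bad, m2))
  unknown <- component_map("X", "enzyme", list("NOPE"))
  expect_error(validate_component_map(unknown, sys$model), "unknown reaction")
})

test_that("component maps and constraints round-trip through TSV", {
  map <- component_map(c("PDH", "Lac"), c("enzyme", "metabolite"),
                       list("TCA", c("LDH", "ALT")),
                       metabolite = c(NA, "lac"))
  f <- tempfile(fileext = ".tsv")
  write_component_map_tsv(map, f)
  back <- read_component_map_tsv(f)
  expect_identical(back$node, map$node)
  expect_identical(back$kind, map$kind)
  expect_identical(back$reactions, map$reactions)
  expect_identical(back$metabolite, map$metabolite)
  cs <- structure(data.frame(reaction = "TCA", lb = 0, ub = 0),
                  class = c("flux_constraints", "data.frame"))
  cs$justification <- list(c("PDH", "Lac"))
  f2 <- tempfile(fileext = ".tsv")
  write_constraints_tsv(cs, f2)
  back2 <- read_constraints_tsv(f2)
  expect_identical(back2$reaction, cs$reaction)
  expect_identical(back2$justification, cs$justification)
})
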