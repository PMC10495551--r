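test_that("a self-activating node yields the two fixed points", {
  net <- boolean_network(list(A = "A"))
  expect_identical(space_keys(compute_minimal_trap_spaces(net)),
                   c("A=0", "A=1"))
})

test_that("a negative loop yields a single all-free trap space", {
  net <- boolean_network(list(A = "!B", B = "A"))
  # brute force over the 9 subspaces of 2 nodes gives the same answer
  expect_identical(space_keys(compute_minimal_trap_spaces(net)), "<empty>")
  expect_identical(space_keys(brute_force_trap_spaces(net)), "<empty>")
})

test_that("hypoxia core trap spaces match hand enumeration", {
  net <- toy_core_net()
  # the input is bistable; each value percolates down the chain
  expect_identical(
    space_keys(compute_minimal_trap_spaces(net)),
    c("Hypoxia=0,HIF1=0,PDK1=0,PDH=1", "Hypoxia=1,HIF1=1,PDK1=1,PDH=0")
  )
})

test_that("clamping is honoured: all trap spaces carry the clamped value", {
  net <- toy_core_net()
  clamped <- apply_clamping(net, clamping(c(HIF1 = 0)))
  spaces <- compute_minimal_trap_spaces(clamped)
  expect_true(length(spaces) > 0)
  for (sp in spaces) expect_identical(sp[["HIF1"]], 0L)
  expect_identical(space_keys(spaces), space_keys(brute_force_trap_spaces(clamped)))
})

test_that("every returned trap space satisfies the closure property", {
  for (s in 1:25) {
    net <- make_random_boolean_network(s, 7)
    for (sp in compute_minimal_trap_spaces(net)) {
      expect_true(is_trap_space(net, sp))
    }
  }
})

test_that("solver and brute-force oracle agree on random networks", {
  for (s in 1:30) {
    net <- make_random_boolean_network(1000 + s, 4 + s %% 5)
    expect_identical(space_keys(compute_minimal_trap_spaces(net)),
                     space_keys(brute_force_trap_spaces(net)),
                     info = paste("seed", 1000 + s))
  }
})

test_that("propagated values are sound for the asynchronous attractors", {
  skip_if_not_installed("igraph")
  for (s in 1:12) {
    net <- make_random_boolean_network(2000 + s, 6)
    nd <- net$nodes[s %% 6 + 1]
    cl <- clamping(setNames(s %% 2, nd))
    p <- propagate_values(net, cl)
    clamped <- apply_clamping(net, cl)
    for (att in async_attractor_states(clamped)) {
      for (nm in names(p$values)) {
        expect_true(all(att[, nm] == p$values[[nm]]),
                    info = paste("seed", 2000 + s, "node", nm))
      }
    }
  }
})

test_that("trap-space output order and serialization are deterministic", {
  net <- make_random_boolean_network(42, 7)
  a <- compute_minimal_trap_spaces(net)
  b <- compute_minimal_trap_spaces(net)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_trap_spaces(a, net$nodes, f1)
  write_trap_spaces(b, net$nodes, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_trap_spaces(f1)
  expect_identical(space_keys(back), space_keys(a))
  expect_identical(attr(back, "nodes"), net$nodes)
})

test_that("the solver refuses oversized residual problems instead of truncating", {
  funs <- setNames(rep(list(NULL), 20), paste0("I", 1:20))
  net <- boolean_network(funs)
  expect_error(compute_minimal_trap_spaces(net, max_free_nodes = 10),
               "solver limit exceeded")
  expect_error(brute_force_trap_spaces(net), "refuses networks")
})

test_that("projection restricts, deduplicates and handles the empty subset", {
  net <- toy_core_net()
  spaces <- compute_minimal_trap_spaces(net)
  pr <- project_trap_spaces(spaces, "PDH")
  expect_identical(space_keys(pr), c("PDH=0", "PDH=1"))
  # project on a node with a single shared value after clamping
  clamped <- apply_clamping(net, clamping(c(Hypoxia = 1)))
  pr2 <- project_trap_spaces(compute_minimal_trap_spaces(clamped), "PDH")
  expect_identical(space_keys(pr2), "PDH=0")
  pr3 <- project_trap_spaces(spaces, character(0))
  expect_length(pr3, 1L)
  expect_length(pr3[[1L]], 0L)
})

test_that("scenario evaluation reports asymptotic readouts", {
  net <- toy_core_net()
  expect_identical(evaluate_scenario(net, clamping(c(Hypoxia = 1)), "PDH"),
                   c(PDH = "0"))
  # clamping the readout itself pins it
  expect_identical(evaluate_scenario(net, clamping(c(PDH = 1)), "PDH"),
                   c(PDH = "1"))
  # bistable unclamped readout varies
  bi <- boolean_network(list(A = "A"))
  expect_identical(evaluate_scenario(bi, clamping(), "A"), c(A = "varies"))
})
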