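test_that("DEG calling applies both thresholds with strict inequalities", {
  tab <- expression_contrast(
    c("G1", "G2", "G3", "G4", "G5"),
    fc = c(2.0, -1.8, 3.0, 1.5, -1.5),
    adj_p = c(0.01, 0.02, 0.2, 0.01, 0.01)
  )
  degs <- call_degs(tab)
  expect_identical(degs$up, "G1")     # G3 fails the p cut
  expect_identical(degs$down, "G2")
  # G4/G5 sit exactly at the fold-change threshold: excluded
  expect_false(any(c("G4", "G5") %in% c(degs$up, degs$down)))
  expect_length(intersect(degs$up, degs$down), 0L)
})

test_that("empty tables yield empty DEG sets", {
  tab <- expression_contrast(character(), numeric(), numeric())
  degs <- call_degs(tab)
  expect_length(degs$up, 0L)
  expect_length(degs$down, 0L)
})

test_that("the log2 convention rescales the fold-change cut", {
  tab <- expression_contrast(c("A", "B", "C"), fc = c(0.7, 1.0, -0.7),
                             adj_p = c(0.01, 0.01, 0.01),
                             fc_convention = "log2")
  degs <- call_degs(tab, fc_threshold = 1.5) # log2(1.5) ~ 0.585
  expect_identical(degs$up, c("A", "B"))
  expect_identical(degs$down, "C")
})

test_that("an undeclared fold-change convention is an error", {
  tab <- expression_contrast(c("A"), 2, 0.01)
  attr(tab, "fc_convention") <- NULL
  expect_error(call_degs(tab), "convention")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tfc\tadj_p", "A\t2\t0.01"), f)
  expect_error(read_contrast_tsv(f), "convention")
})

test_that("contrast tables round-trip through TSV", {
  tab <- make_toy_expression_table(seed = 7, n_genes = 30, n_up = 4, n_down = 3)
  f <- tempfile(fileext = ".tsv")
  write_contrast_tsv(tab$contrast, f)
  back <- read_contrast_tsv(f)
  expect_equal(back$gene, tab$contrast$gene)
  expect_equal(back$fc, tab$contrast$fc)
  expect_equal(back$adj_p, tab$contrast$adj_p)
  expect_identical(attr(back, "fc_convention"), "linear")
})

test_that("DEGs map onto nodes through aliases; unmapped genes are reported", {
  sys <- make_toy_coupled_model(seed = 2)
  ic <- map_and_discretize(up = c("HIF1A", "NOTAGENE"), down = "PDK1",
                           net = sys$net)
  expect_identical(ic$values, c(HIF1 = 1L, PDK1 = 0L))
  expect_identical(unname(ic$provenance), rep("data-driven", 2))
  expect_identical(attr(ic, "unmapped"), "NOTAGENE")
  # matching is case-insensitive
  ic2 <- map_and_discretize(up = "hif1a", down = character(), net = sys$net)
  expect_identical(ic2$values, c(HIF1 = 1L))
})

test_that("conflicting directions on one node raise an error", {
  net <- boolean_network(
    list(N = NULL),
    annotations = list(N = list(name = "SHARED"))
  )
  expect_error(
    map_and_discretize(up = "SHARED", down = "N", net = net),
    "contradictory"
  )
})

test_that("curation fills only what the contrast left unfixed", {
  net <- toy_core_net()
  dd <- initial_conditions(c(HIF1 = 0L), "data-driven")
  cur <- initial_conditions(c(HIF1 = 1L, Hypoxia = 1L), "curated")
  merged <- merge_with_curation(dd, cur, net)
  expect_identical(merged$values[["HIF1"]], 0L)     # data-driven precedence
  expect_identical(merged$values[["Hypoxia"]], 1L)  # curation fills the input
  expect_identical(attr(merged, "conflicts"), "HIF1")
  expect_identical(attr(merged, "unfixed_inputs"), character(0))
  expect_identical(merged$provenance[["Hypoxia"]], "curated")
  # empty curation: identity
  merged2 <- merge_with_curation(dd, initial_conditions(), net)
  expect_identical(merged2$values, dd$values)
  expect_identical(attr(merged2, "unfixed_inputs"), "Hypoxia")
})

test_that("initial conditions round-trip through TSV", {
  ic <- initial_conditions(c(A = 1L, B = 0L), c("data-driven", "curated"))
  f <- tempfile(fileext = ".tsv")
  write_conditions_tsv(ic, f)
  back <- read_conditions_tsv(f)
  expect_identical(back$values, ic$values)
  expect_identical(back$provenance, ic$provenance)
})

test_that("up/down sets stay disjoint over generated tables and thresholds", {
  for (s in 1:10) {
    tab <- make_toy_expression_table(seed = s, n_genes = 60, n_up = 8, n_down = 6)
    for (fc in c(1.2, 1.5, 2.5)) {
      degs <- call_degs(tab$contrast, p_threshold = 0.05, fc_threshold = fc)
      expect_length(intersect(degs$up, degs$down), 0L)
    }
  }
})
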