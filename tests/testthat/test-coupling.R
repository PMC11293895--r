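# Identifier matching, constraint extraction from trap-space projections,
# model contextualization and the ATP pathway ratios.

test_that("enzymes and metabolites match by exact identifier", {
  net <- parse_bnet("PGK, PGK\npyr_c, pyr_c\nNOPE, NOPE")
  model <- toy_core_metabolism()
  suppressWarnings(mapping <- match_components(net, model))
  enz <- mapping[mapping$component == "PGK", ]
  expect_identical(enz$role, "enzyme")
  expect_identical(enz$reaction, "PGK")
  met <- mapping[mapping$component == "pyr_c", ]
  expect_identical(unique(met$role), "metabolite")
  expect_setequal(met$reaction, "PYK")   # the only producer of pyr_c
  expect_identical(unique(met$direction), "forward")
  expect_false("NOPE" %in% mapping$component)
  expect_true("HEX1" %in% attr(mapping, "unmatched"))
})

test_that("matching is case-sensitive; synonyms bridge explicitly", {
  net <- parse_bnet("Pgk, Pgk")
  model <- toy_core_metabolism()
  expect_warning(mapping <- match_components(net, model), "no regulatory")
  expect_identical(nrow(mapping), 0L)
  syn <- tibble::tibble(network_name = "Pgk", model_id = "PGK",
                        role = "enzyme")
  mapping2 <- match_components(net, model, synonyms = syn)
  expect_identical(mapping2$component, "Pgk")
  expect_identical(mapping2$reaction, "PGK")
})

test_that("reversible reactions count as reverse producers of their reactants", {
  m <- chain_model()
  m$reactions$lb[m$reactions$id == "CONV"] <- -5   # CONV reversible
  net <- parse_bnet("A_c, A_c")
  suppressWarnings(mapping <- match_components(net, m))
  conv <- mapping[mapping$reaction == "CONV", ]
  expect_identical(conv$direction, "reverse")   # A_c reproduced by reverse CONV
})

test_that("only projected-0 components induce constraints, per role", {
  m <- chain_model()
  m$reactions$lb[m$reactions$id == "CONV"] <- -5
  net <- parse_bnet("CONV, CONV\nA_c, A_c\natp_c, atp_c")
  suppressWarnings(mapping <- match_components(net, m))
  # enzyme CONV inactive: both bounds zeroed
  proj <- tibble::tibble(component = "CONV", value = 0L)
  cs <- extract_constraints(mapping, proj, m)
  expect_identical(cs$reaction, "CONV")
  expect_identical(cs$lb, 0)
  expect_identical(cs$ub, 0)
  # metabolite A_c inactive: forward producer EX_A gets ub 0, reverse
  # producer CONV gets lb raised to 0
  proj2 <- tibble::tibble(component = "A_c", value = 0L)
  cs2 <- extract_constraints(mapping, proj2, m)
  cs2 <- cs2[order(cs2$reaction), ]
  expect_identical(cs2$reaction, c("CONV", "EX_A"))
  expect_identical(cs2$lb, c(0, 0))
  expect_identical(cs2$ub, c(1000, 0))
  # value 1 induces nothing
  proj3 <- tibble::tibble(component = c("CONV", "A_c"), value = 1L)
  expect_identical(nrow(extract_constraints(mapping, proj3, m)), 0L)
  # projections over unmapped components are ignored with a warning
  proj4 <- tibble::tibble(component = "GHOST", value = 0L)
  expect_warning(cs4 <- extract_constraints(mapping, proj4, m), "ignored")
  expect_identical(nrow(cs4), 0L)
})

test_that("zero net production is enforced for inactive metabolites", {
  m <- chain_model()
  net <- parse_bnet("A_c, A_c")
  suppressWarnings(mapping <- match_components(net, m))
  cs <- extract_constraints(mapping, tibble::tibble(component = "A_c",
                                                    value = 0L), m)
  m2 <- apply_constraints(m, cs)
  r <- fba(m2)
  expect_identical(attr(r, "status"), "optimal")
  # no route produces A_c any more, so nothing flows
  expect_equal(attr(r, "objective_value"), 0, tolerance = 1e-9)
})

test_that("apply_constraints is pure and validates reaction ids", {
  m <- toy_core_metabolism()
  empty <- tibble::tibble(reaction = character(), lb = numeric(),
                          ub = numeric(), components = character())
  expect_identical(apply_constraints(m, empty), m)
  bad <- tibble::tibble(reaction = "NOT_THERE", lb = 0, ub = 0,
                        components = "x")
  expect_error(apply_constraints(m, bad), "unknown reaction")
  cs <- tibble::tibble(reaction = "ATPS4m", lb = 0, ub = 0, components = "x")
  m2 <- apply_constraints(m, cs)
  expect_identical(m$reactions$ub[m$reactions$id == "ATPS4m"], 1000)
  expect_identical(m2$reactions$ub[m2$reactions$id == "ATPS4m"], 0)
})

test_that("knocking out the sole ATP route zeroes the optimum", {
  m <- chain_model()
  cs <- tibble::tibble(reaction = "CONV", lb = 0, ub = 0, components = "x")
  r <- fba(apply_constraints(m, cs))
  expect_equal(attr(r, "objective_value"), 0, tolerance = 1e-12)
})

test_that("constrained optima never exceed the control optimum", {
  m <- toy_core_metabolism()
  base <- attr(fba(m), "objective_value")
  for (seed in 1:50) {
    cs <- random_constraint_set(m, seed)
    r <- fba(apply_constraints(m, cs))
    if (attr(r, "status") != "optimal") next
    expect_lte(attr(r, "objective_value"), base + 1e-9)
  }
})

test_that("constraint soundness: zeroed reactions carry no flux", {
  m <- toy_core_metabolism()
  cs <- tibble::tibble(reaction = c("ATPS4m", "PDH"), lb = 0, ub = 0,
                       components = "x")
  m2 <- apply_constraints(m, cs)
  r <- fba(m2)
  expect_identical(r$flux[r$reaction %in% cs$reaction], c(0, 0))
})

test_that("ATP ratios follow the positive-production arithmetic", {
  m <- toy_core_metabolism()
  r <- fba(m)
  rep <- atp_ratio(r, m, toy_atp_classification())
  expect_equal(rep$total_atp, 120, tolerance = 1e-9)
  expect_equal(rep$glycolytic_atp, 20, tolerance = 1e-9)
  expect_equal(rep$oxidative_atp, 100, tolerance = 1e-9)
  expect_equal(rep$ratio_glycolytic, 1 / 6, tolerance = 1e-9)
  expect_equal(rep$ratio_oxidative, 5 / 6, tolerance = 1e-9)
  expect_false(rep$zero_production)
  # ratios stay normalized
  expect_true(rep$ratio_glycolytic + rep$ratio_oxidative <= 1 + 1e-12)
})

test_that("hand-set fluxes give the stated class ratios", {
  m <- toy_core_metabolism()
  fluxes <- tibble::tibble(reaction = m$reactions$id, flux = 0)
  fluxes$flux[fluxes$reaction == "PGK"] <- 3      # 3 glycolytic ATP
  fluxes$flux[fluxes$reaction == "ATPS4m"] <- 2.8 # 7 oxidative ATP
  rep <- atp_ratio(fluxes, m, toy_atp_classification())
  expect_equal(rep$ratio_glycolytic, 0.3, tolerance = 1e-12)
  expect_equal(rep$ratio_oxidative, 0.7, tolerance = 1e-12)
})

test_that("degenerate classification and zero production are handled", {
  m <- toy_core_metabolism()
  expect_error(atp_classification(c("PGK"), c("PGK", "ATPS4m")), "overlap")
  fluxes <- tibble::tibble(reaction = m$reactions$id, flux = 0)
  rep <- atp_ratio(fluxes, m, toy_atp_classification())
  expect_true(rep$zero_production)
  expect_identical(rep$ratio_glycolytic, 0)
  expect_identical(rep$ratio_oxidative, 0)
})

test_that("FVA envelopes flag solution-dependent ratios", {
  # two equivalent branches, only one classified glycolytic: the class sum
  # depends on the vertex FBA returns
  m <- parallel_model()
  # make B the "ATP" carrier so production is countable
  m$metabolites$id[m$metabolites$id == "B_c"] <- "atp_c"
  m$stoichiometry$metabolite[m$stoichiometry$metabolite == "B_c"] <- "atp_c"
  r <- fba(m)
  env <- fva(m)
  rep <- atp_ratio(r, m, atp_classification("BR1", "BR2"), envelope = env)
  expect_true(rep$solution_dependent)
  # the rigid chain shows no degeneracy
  m2 <- chain_model()
  rep2 <- atp_ratio(fba(m2), m2, atp_classification("CONV", character()),
                    envelope = fva(m2))
  expect_false(rep2$solution_dependent)
})
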