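# SBML flux-model I/O and the FBA/FVA linear programs, checked against
# hand-solved optima.

test_that("the toy core model has the expected stoichiometric matrix", {
  m <- toy_core_metabolism()
  S <- stoich_matrix(m)
  expect_identical(dim(S), c(10L, 13L))
  expect_identical(S["atp_c", "PGK"], 1)
  expect_identical(S["atp_c", "ATPS4m"], 2.5)
  expect_identical(S["atp_c", "DM_atp"], -1)
  expect_identical(S["o2_m", "ATPS4m"], -0.5)
  expect_identical(sum(S != 0), 24L)
})

test_that("SBML-fbc round trips preserve S, bounds, objective and genes", {
  m <- toy_core_metabolism()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_fbc(m, f)
  back <- read_sbml_fbc(f)
  expect_identical(sort(back$reactions$id), sort(m$reactions$id))
  S1 <- stoich_matrix(m)
  S2 <- stoich_matrix(back)
  expect_equal(S1[rownames(S2), colnames(S2)], S2)
  expect_equal(
    back$reactions[order(back$reactions$id), c("lb", "ub")],
    m$reactions[order(m$reactions$id), c("lb", "ub")])
  expect_equal(back$objective, m$objective)
  expect_identical(
    lapply(back$reactions$genes[order(back$reactions$id)], sort),
    lapply(m$reactions$genes[order(m$reactions$id)], sort))
})

test_that("reversible reactions keep negative lower bounds through the file", {
  m <- chain_model()
  m$reactions$lb[m$reactions$id == "CONV"] <- -5
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_fbc(m, f)
  back <- read_sbml_fbc(f)
  lb <- back$reactions$lb[back$reactions$id == "CONV"]
  ub <- back$reactions$ub[back$reactions$id == "CONV"]
  expect_identical(lb, -5)
  expect_true(lb < 0 && 0 <= ub)
})

test_that("missing bounds fall back to defaults with a warning", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false"><model id="m">',
    '<listOfSpecies><species id="a_c" compartment="c" constant="false" ',
    'boundaryCondition="false" hasOnlySubstanceUnits="false"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="true" fast="false">',
    '<listOfProducts><speciesReference species="a_c" stoichiometry="1" ',
    'constant="true"/></listOfProducts></reaction>',
    '<reaction id="R2" reversible="false" fast="false">',
    '<listOfReactants><speciesReference species="a_c" stoichiometry="1" ',
    'constant="true"/></listOfReactants></reaction>',
    '</listOfReactions></model></sbml>'), f)
  ws <- capture_warnings(m <- read_sbml_fbc(f))
  expect_length(ws, 4)   # both bounds of both reactions defaulted
  expect_match(ws, "default applied", all = TRUE)
  expect_identical(m$reactions$lb, c(-1000, 0))
  expect_identical(m$reactions$ub, c(1000, 1000))
})

test_that("legacy Level 2 COBRA-style models are read", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version1" ',
    'level="2" version="1"><model id="m"><listOfSpecies>',
    '<species id="a_c" compartment="c"/></listOfSpecies><listOfReactions>',
    '<reaction id="R1" reversible="false">',
    '<listOfProducts><speciesReference species="a_c"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="7"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="R2" reversible="false">',
    '<listOfReactants><speciesReference species="a_c"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="100"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '</listOfReactions></model></sbml>'), f)
  m <- read_sbml_fbc(f)
  expect_identical(m$reactions$ub, c(7, 100))
  expect_identical(m$objective, c(R2 = 1))
  expect_equal(unname(attr(fba(m), "objective_value")), 7)
})

test_that("FBA solves hand-computable chains exactly", {
  m <- chain_model(uptake_ub = 10)
  r <- fba(m)
  expect_equal(attr(r, "objective_value"), 10, tolerance = 1e-9)
  expect_equal(r$flux[r$reaction == "CONV"], 10, tolerance = 1e-9)
  expect_identical(attr(r, "status"), "optimal")
  # all exchanges closed: zero flux is feasible and optimal
  m0 <- chain_model(uptake_ub = 0)
  expect_equal(attr(fba(m0), "objective_value"), 0, tolerance = 1e-12)
  # knocked-out intermediate kills the objective
  mk <- chain_model()
  mk$reactions$ub[mk$reactions$id == "CONV"] <- 0
  expect_equal(attr(fba(mk), "objective_value"), 0, tolerance = 1e-12)
})

test_that("optimal flux distributions satisfy mass balance and bounds", {
  models <- list(chain_model(), parallel_model(), toy_core_metabolism())
  for (m in models) {
    r <- fba(m)
    v <- stats::setNames(r$flux, r$reaction)[colnames(stoich_matrix(m))]
    residual <- stoich_matrix(m) %*% v
    expect_lt(max(abs(residual)), 1e-9)
    expect_true(all(v >= m$reactions$lb - 1e-9))
    expect_true(all(v <= m$reactions$ub + 1e-9))
  }
})

test_that("an FBA without declared objective demands one explicitly", {
  m <- chain_model()
  m$objective <- numeric()
  expect_error(fba(m), "no objective")
  r <- fba(m, objective = "DM_atp")
  expect_equal(attr(r, "objective_value"), 10, tolerance = 1e-9)
})

test_that("FVA on a rigid chain returns point intervals", {
  r <- fva(chain_model(), fraction_of_optimum = 1)
  for (i in seq_len(nrow(r))) {
    expect_equal(r$min[[i]], 10, tolerance = 1e-6)
    expect_equal(r$max[[i]], 10, tolerance = 1e-6)
  }
})

test_that("FVA exposes the degeneracy of parallel equivalent branches", {
  r <- fva(parallel_model(), fraction_of_optimum = 1)
  for (br in c("BR1", "BR2")) {
    expect_equal(r$min[r$reaction == br], 0, tolerance = 1e-6)
    expect_equal(r$max[r$reaction == br], 10, tolerance = 1e-6)
  }
  expect_equal(r$min[r$reaction == "DM_B"], 10, tolerance = 1e-6)
})

test_that("FVA intervals bracket FBA fluxes on every fixture", {
  models <- list(chain_model(), parallel_model(), toy_core_metabolism())
  for (seed in 1:10) {
    m <- toy_core_metabolism()
    cs <- random_constraint_set(m, seed)
    models <- c(models, list(apply_constraints(m, cs)))
  }
  for (m in models) {
    r <- fba(m)
    if (attr(r, "status") != "optimal") next
    env <- fva(m, fraction_of_optimum = 1)
    hit <- match(r$reaction, env$reaction)
    expect_true(all(env$min[hit] <= r$flux + 1e-6))
    expect_true(all(env$max[hit] >= r$flux - 1e-6))
  }
})

test_that("tightening bounds never increases the optimum", {
  m <- toy_core_metabolism()
  base <- attr(fba(m), "objective_value")
  for (seed in 1:15) {
    cs <- random_constraint_set(m, seed)
    r <- fba(apply_constraints(m, cs))
    if (attr(r, "status") != "optimal") next
    expect_lte(attr(r, "objective_value"), base + 1e-9)
  }
})

test_that("infeasible problems are reported in the status, not raised", {
  m <- chain_model()
  # force consumption that production cannot match
  m$reactions$lb[m$reactions$id == "EX_B"] <- 50
  r <- fba(m)
  expect_identical(attr(r, "status"), "infeasible")
  expect_true(is.na(attr(r, "objective_value")))
  expect_error(fva(m), "infeasible")
})
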