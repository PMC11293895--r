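# CellDesigner parsing, Boolean inference from process-description maps,
# subnetwork extraction and forced initial conditions.

test_that("a toy map parses with species, reaction and classified modifier", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_celldesigner(toy_pd_map(), f)
  map <- parse_celldesigner(f)
  expect_identical(nrow(map$species), 4L)
  expect_identical(length(map$reactions), 1L)
  expect_identical(map$reactions[[1]]$modifiers$species, "s4")
  expect_identical(map$reactions[[1]]$modifiers$class, "INHIBITION")
  expect_identical(sort(map$species$name), c("A", "B", "C", "I"))
})

test_that("species duplicated across compartments stay distinct", {
  map <- pd_map(
    species = tibble::tibble(
      id = c("s1", "s2"), name = c("glc", "glc"),
      compartment = c("cyt", "mito"), class = "SIMPLE_MOLECULE"),
    reactions = list()
  )
  f <- withr::local_tempfile(fileext = ".xml")
  write_celldesigner(map, f)
  back <- parse_celldesigner(f)
  expect_identical(nrow(back$species), 2L)
  net <- infer_boolean(back)
  expect_setequal(net$variables, c("glc_cyt", "glc_mito"))
})

test_that("species count equals an independent XML query of listOfSpecies", {
  fx <- coupled_fixture("all_active", dir = withr::local_tempdir())
  map <- parse_celldesigner(fx$paths$map)
  doc <- xml2::read_xml(fx$paths$map)
  n_species <- length(xml2::xml_find_all(
    doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']"))
  expect_identical(nrow(map$species), n_species)
})

test_that("files without the CellDesigner namespace are rejected", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines('<sbml xmlns="http://www.sbml.org/sbml/level2/version4"/>', f)
  expect_error(parse_celldesigner(f), "celldesigner namespace")
})

test_that("dangling reaction references are an integrity error", {
  expect_error(pd_map(
    species = tibble::tibble(id = "s1", name = "A", compartment = "c",
                             class = NA),
    reactions = list(list(id = "re1", reactants = "s9", products = "s1",
                          modifiers = tibble::tibble(species = character(),
                                                     class = character())))),
    "integrity")
})

test_that("inference composes reactants, modifiers and producers correctly", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_celldesigner(toy_pd_map(), f)
  net <- infer_boolean(parse_celldesigner(f))
  # reaction A+B -> C inhibited by I
  expect_same_truth_tables(
    paste0("A, A\nB, B\nI, I\nC, ", format(net$functions$C)),
    "A, A\nB, B\nI, I\nC, A & B & !I")
  # inputs get the identity update
  expect_identical(format(net$functions$A), "A")
})

test_that("multiple producing reactions combine by disjunction", {
  map <- pd_map(
    species = tibble::tibble(id = c("sA", "sB", "sC"),
                             name = c("A", "B", "C"),
                             compartment = "c", class = "PROTEIN"),
    reactions = list(
      list(id = "r1", reactants = "sA", products = "sC",
           modifiers = tibble::tibble(species = character(),
                                      class = character())),
      list(id = "r2", reactants = "sB", products = "sC",
           modifiers = tibble::tibble(species = character(),
                                      class = character())))
  )
  net <- infer_boolean(map)
  expect_identical(format(net$functions$C), "A | B")
})

test_that("unknown modifier classes are rejected, polarity is configurable", {
  map <- toy_pd_map()
  map$reactions[[1]]$modifiers$class <- "MYSTERY"
  expect_error(infer_boolean(map), "unknown modifier class")
  net <- infer_boolean(map, polarity = c(MYSTERY = "positive"))
  expect_identical(format(net$functions$C), "A & B & I")
})

test_that("subnetwork extraction follows influence reachability", {
  net <- parse_bnet("A, A\nB, A\nC, B")
  down <- extract_subnetwork(net, "B", "downstream")
  expect_setequal(down$variables, c("A", "B", "C"))  # A re-added as input
  expect_identical(format(down$functions$A), "A")
  up <- extract_subnetwork(net, "B", "upstream")
  expect_setequal(up$variables, c("A", "B"))
  expect_error(extract_subnetwork(net, "Q"), "nearest matches")
  # case-insensitive unique fallback
  expect_setequal(extract_subnetwork(net, "b", "upstream")$variables,
                  c("A", "B"))
})

test_that("extraction with all variables as seeds is the identity", {
  net <- random_boolean_network(n = 8, max_in_degree = 3, seed = 5)
  sub <- extract_subnetwork(net, net$variables, "both")
  expect_same_truth_tables(write_bnet(net), write_bnet(sub))
})

test_that("retained variables match an igraph reachability oracle", {
  for (seed in 1:10) {
    net <- random_boolean_network(n = 20, max_in_degree = 3, seed = seed)
    edges <- do.call(rbind, lapply(net$variables, function(w) {
      regs <- setdiff(expr_vars(net$functions[[w]]), character())
      if (!length(regs)) return(NULL)
      cbind(regs, w)
    }))
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges), vertices = data.frame(name = net$variables))
    seed_var <- net$variables[[1 + seed %% 20]]
    for (dir in c("downstream", "upstream")) {
      mode <- if (dir == "downstream") "out" else "in"
      want <- names(igraph::subcomponent(g, seed_var, mode = mode))
      sub <- extract_subnetwork(net, seed_var, dir)
      core <- sub$variables[vapply(sub$variables, function(v) {
        f <- sub$functions[[v]]
        !(f$op == "var" && f$name == v) || v %in% want
      }, logical(1))]
      expect_setequal(core, want)
      # every non-core variable is a boundary input with identity update
      for (v in setdiff(sub$variables, core)) {
        expect_identical(format(sub$functions[[v]]), v)
      }
    }
  }
})

test_that("initial conditions replace update functions by constants", {
  net <- parse_bnet("A, !B\nB, A")
  fixed <- apply_initial_conditions(net, c(A = 1))
  expect_identical(format(fixed$functions$A), "1")
  expect_identical(format(fixed$functions$B), "A")
  expect_identical(write_bnet(apply_initial_conditions(net, c())),
                   write_bnet(net))
  expect_error(apply_initial_conditions(net, c(Z = 1)), "unknown component")
  expect_error(apply_initial_conditions(net, c(A = 2)), "must be 0 or 1")
})

test_that("initial-conditions CSVs are parsed and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("component,value", "A,1", "B-x,0"), f)
  ic <- read_initial_conditions(f)
  expect_identical(ic, c(A = 1L, B_x = 0L))
  writeLines("component,value", f)
  expect_identical(length(read_initial_conditions(f)), 0L)
  writeLines(c("component,value", "A,2"), f)
  expect_error(read_initial_conditions(f), "0 or 1")
  writeLines(c("who,what", "A,1"), f)
  expect_error(read_initial_conditions(f), "header")
})

test_that("conditioned networks only keep trap spaces consistent with the fix", {
  for (seed in 1:12) {
    net <- random_boolean_network(n = 5, max_in_degree = 3, seed = seed)
    v <- net$variables[[1 + seed %% 5]]
    b <- seed %% 2
    fixed <- apply_initial_conditions(net, stats::setNames(b, v))
    traps <- minimal_trap_spaces(fixed)
    expect_true(all(traps[[v]] == as.character(b)), label = paste(seed))
    # and agrees with the brute-force oracle on the conditioned network
    want <- trap_keys(oracle_minimal(oracle_trap_spaces_fast(fixed)))
    expect_identical(trap_keys(as.matrix(traps)), want)
  }
})

test_that("components_table lists formulae and aliases", {
  fx <- coupled_fixture("all_active", dir = withr::local_tempdir())
  map <- parse_celldesigner(fx$paths$map)
  net <- infer_boolean(map)
  tab <- components_table(net, map)
  expect_identical(tab$component, sort(net$variables))
  expect_identical(tab$formula[tab$component == "PDH"], "PGC1A & !HIF1A")
  expect_false(any(is.na(tab$alias)))
})
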