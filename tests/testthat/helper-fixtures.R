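# Small builders shared across test files.

toy_pd_map <- function() {
  pd_map(
    species = tibble::tibble(
      id = c("s1", "s2", "s3", "s4"),
      name = c("A", "B", "C", "I"),
      compartment = "cyt",
      class = "PROTEIN"
    ),
    reactions = list(list(
      id = "re1", reactants = c("s1", "s2"), products = "s3",
      modifiers = tibble::tibble(species = "s4", class = "INHIBITION")
    )),
    aliases = tibble::tibble(species = paste0("s", 1:4),
                             alias = paste0("sa", 1:4))
  )
}

# three-reaction chain: uptake (ub 10) -> A; A -> B + atp; atp demand
chain_model <- function(uptake_ub = 10) {
  metabolic_network(
    metabolites = tibble::tibble(
      id = c("A_c", "B_c", "atp_c"),
      name = c("A", "B", "ATP"), compartment = "c"),
    reactions = tibble::tibble(
      id = c("EX_A", "CONV", "EX_B", "DM_atp"),
      name = id, lb = 0, ub = c(uptake_ub, 1000, 1000, 1000),
      genes = list(character(), "CONV", character(), character())),
    stoichiometry = tibble::tribble(
      ~reaction, ~metabolite, ~coef,
      "EX_A", "A_c", 1,
      "CONV", "A_c", -1,
      "CONV", "B_c", 1,
      "CONV", "atp_c", 1,
      "EX_B", "B_c", -1,
      "DM_atp", "atp_c", -1),
    objective = c(DM_atp = 1)
  )
}

# two equivalent parallel branches feeding one demand of 10
parallel_model <- function() {
  metabolic_network(
    metabolites = tibble::tibble(
      id = c("A_c", "B_c"), name = c("A", "B"), compartment = "c"),
    reactions = tibble::tibble(
      id = c("EX_A", "BR1", "BR2", "DM_B"),
      name = id, lb = 0, ub = c(10, 1000, 1000, 1000),
      genes = list(character(), "BR1", "BR2", character())),
    stoichiometry = tibble::tribble(
      ~reaction, ~metabolite, ~coef,
      "EX_A", "A_c", 1,
      "BR1", "A_c", -1,
      "BR1", "B_c", 1,
      "BR2", "A_c", -1,
      "BR2", "B_c", 1,
      "DM_B", "B_c", -1),
    objective = c(DM_B = 1)
  )
}

# random bound tightenings of the toy core model, reproducible
random_constraint_set <- function(model, seed) {
  set.seed(seed)
  k <- sample(1:4, 1)
  picks <- sample(model$reactions$id, k)
  tibble::tibble(
    reaction = picks,
    lb = 0,
    ub = vapply(picks, function(r) {
      ub0 <- model$reactions$ub[model$reactions$id == r]
      stats::runif(1, 0, ub0)
    }, 0),
    components = "synthetic"
  )
}

# Hand-written SBML-qual source for the two-node network A = !B, B = A,
# with switchable default-term level (the else branch), maxLevel and a
# missing-default variant. Kept as literal XML so the reader is tested
# against text the package writer never produced.
sbml_qual_fixture <- function(default_level = 0, max_level = 1,
                              drop_default = FALSE) {
  term <- function(level, math) {
    paste0('<qual:functionTerm qual:resultLevel="', level, '">',
           '<math xmlns="http://www.w3.org/1998/Math/MathML">', math,
           "</math></qual:functionTerm>")
  }
  dflt <- if (drop_default) "" else
    paste0('<qual:defaultTerm qual:resultLevel="', default_level,
           '"/>')
  # default 0: list the states giving 1; default 1: list the states giving 0
  a_math <- if (default_level == 0) {
    "<apply><eq/><ci>B</ci><cn type='integer'>0</cn></apply>"
  } else {
    "<apply><eq/><ci>B</ci><cn type='integer'>1</cn></apply>"
  }
  b_math <- if (default_level == 0) {
    "<apply><eq/><ci>A</ci><cn type='integer'>1</cn></apply>"
  } else {
    "<apply><eq/><ci>A</ci><cn type='integer'>0</cn></apply>"
  }
  a_level <- if (default_level == 0) 1 else 0
  transition <- function(id, target, math, level) {
    paste0('<qual:transition qual:id="', id, '">',
           '<qual:listOfOutputs><qual:output qual:qualitativeSpecies="',
           target,
           '" qual:transitionEffect="assignmentLevel"/></qual:listOfOutputs>',
           "<qual:listOfFunctionTerms>", dflt, term(level, math),
           "</qual:listOfFunctionTerms></qual:transition>")
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" ',
    'level="3" version="1" qual:required="true"><model id="twin">',
    "<listOfCompartments><compartment id='c' constant='true'/>",
    "</listOfCompartments>",
    "<qual:listOfQualitativeSpecies>",
    '<qual:qualitativeSpecies qual:id="A" qual:compartment="c" ',
    'qual:constant="false" qual:maxLevel="', max_level, '"/>',
    '<qual:qualitativeSpecies qual:id="B" qual:compartment="c" ',
    'qual:constant="false" qual:maxLevel="1"/>',
    "</qual:listOfQualitativeSpecies>",
    "<qual:listOfTransitions>",
    transition("tr_A", "A", a_math, a_level),
    transition("tr_B", "B", b_math, a_level),
    "</qual:listOfTransitions>",
    "</model></sbml>"
  )
}

expect_same_truth_tables <- function(text_a, text_b) {
  net_a <- parse_bnet(text_a)
  vars <- sort(net_a$variables)
  states <- oracle_states(vars)
  tt_a <- oracle_truth_tables(oracle_formulas(net_a), states)
  tt_b <- oracle_truth_tables(oracle_formulas(parse_bnet(text_b)), states)
  for (v in vars) testthat::expect_identical(tt_a[[v]], tt_b[[v]])
}
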