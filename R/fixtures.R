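#' Random Boolean networks
#'
#' Seeded generator of random networks for property testing: each variable
#' gets up to `max_in_degree` regulators and a random DNF update function
#' (1-3 terms of random literals over its regulators). With `max_in_degree`
#' 0 every variable becomes a random constant.
#'
#' @param n Number of variables.
#' @param max_in_degree Maximal regulators per function.
#' @param seed Integer seed; the same seed always reproduces the same
#'   network.
#' @return A [boolean_network] with variables `v1..vn`.
#' @export
random_boolean_network <- function(n, max_in_degree = 3L, seed = 1L) {
  stopifnot(n >= 1L, max_in_degree >= 0L)
  vars <- paste0("v", seq_len(n))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
    code
  }
  withr_seed({
    funs <- lapply(vars, function(v) {
      k <- sample(0:min(max_in_degree, n), 1L)
      if (k == 0L) return(bx_const(sample(0:1, 1L)))
      regs <- sample(vars, k)
      n_terms <- sample(1:3, 1L)
      terms <- lapply(seq_len(n_terms), function(i) {
        tk <- sample(seq_len(k), 1L)
        lits <- sample(regs, tk)
        signs <- sample(c(TRUE, FALSE), tk, replace = TRUE)
        bx_and(lapply(seq_len(tk), function(j) {
          if (signs[[j]]) bx_var(lits[[j]]) else bx_not(bx_var(lits[[j]]))
        }))
      })
      bx_or(terms)
    })
    boolean_network(stats::setNames(funs, vars))
  })
}

#' Toy core-metabolism model
#'
#' A hand-solvable 13-reaction caricature of central energy metabolism with
#' both ATP routes: glucose uptake feeding glycolysis (two substrate-level
#' phosphorylation steps, `PGK` and `PYK`, one ATP each per unit flux),
#' pyruvate either reduced to lactate or oxidized via a lumped TCA step to
#' NADH, a lumped ATP synthase (`ATPS4m`, 2.5 ATP per NADH, consuming
#' oxygen), a fatty-acid beta-oxidation feed into the oxidative branch, and
#' an ATP demand reaction (`DM_atp`) as the maximization objective.
#' Identifiers follow BiGG-like conventions (lowercase
#' `metabolite_compartment`, uppercase reaction ids); every enzymatic
#' reaction carries its enzyme label as gene association so exact-identifier
#' coupling is exercised realistically.
#'
#' With the shipped bounds (glucose uptake at most 10, fatty-acid uptake at
#' most 5) the unconstrained optimum is 120 ATP flux units: 20 glycolytic
#' (ratio 1/6) and 100 oxidative (ratio 5/6).
#'
#' @return A [metabolic_network].
#' @export
toy_core_metabolism <- function() {
  metabolites <- tibble::tibble(
    id = c("glc_c", "g6p_c", "pg3_c", "pyr_c", "lac_c", "fa_c",
           "accoa_m", "nadh_m", "o2_m", "atp_c"),
    name = c("glucose", "glucose 6-phosphate", "3-phosphoglycerate",
             "pyruvate", "lactate", "fatty acid", "acetyl-CoA (mito)",
             "NADH (mito)", "oxygen (mito)", "ATP"),
    compartment = c(rep("c", 6), rep("m", 3), "c")
  )
  rx <- function(id, name, lb, ub, genes) {
    tibble::tibble(id = id, name = name, lb = lb, ub = ub,
                   genes = list(genes))
  }
  reactions <- dplyr::bind_rows(
    rx("EX_glc", "glucose uptake", 0, 10, character()),
    rx("HEX1", "hexokinase", 0, 1000, "HEX1"),
    rx("PGK", "phosphoglycerate kinase (lumped upper glycolysis)", 0, 1000,
       "PGK"),
    rx("PYK", "pyruvate kinase", 0, 1000, "PYK"),
    rx("LDH", "lactate dehydrogenase", 0, 1000, "LDH"),
    rx("EX_lac", "lactate secretion", 0, 1000, character()),
    rx("PDH", "pyruvate dehydrogenase", 0, 1000, "PDH"),
    rx("CS", "citrate synthase (lumped TCA)", 0, 1000, "CS"),
    rx("EX_fa", "fatty-acid uptake", 0, 5, character()),
    rx("FAO", "beta-oxidation (lumped)", 0, 1000, "FAO"),
    rx("EX_o2", "oxygen uptake", 0, 1000, character()),
    rx("ATPS4m", "ATP synthase (lumped oxphos)", 0, 1000, "ATPS4m"),
    rx("DM_atp", "ATP demand", 0, 1000, character())
  )
  st <- tibble::tribble(
    ~reaction, ~metabolite, ~coef,
    "EX_glc", "glc_c", 1,
    "HEX1", "glc_c", -1,
    "HEX1", "g6p_c", 1,
    "PGK", "g6p_c", -1,
    "PGK", "pg3_c", 1,
    "PGK", "atp_c", 1,
    "PYK", "pg3_c", -1,
    "PYK", "pyr_c", 1,
    "PYK", "atp_c", 1,
    "LDH", "pyr_c", -1,
    "LDH", "lac_c", 1,
    "EX_lac", "lac_c", -1,
    "PDH", "pyr_c", -1,
    "PDH", "accoa_m", 1,
    "CS", "accoa_m", -1,
    "CS", "nadh_m", 2,
    "EX_fa", "fa_c", 1,
    "FAO", "fa_c", -1,
    "FAO", "accoa_m", 2,
    "EX_o2", "o2_m", 1,
    "ATPS4m", "nadh_m", -1,
    "ATPS4m", "o2_m", -0.5,
    "ATPS4m", "atp_c", 2.5,
    "DM_atp", "atp_c", -1
  )
  metabolic_network(metabolites, reactions, st, c(DM_atp = 1))
}

#' Classification for the toy model
#'
#' @return The `flx_classification` matching [toy_core_metabolism()]:
#'   `PGK`/`PYK` glycolytic, `ATPS4m` oxidative.
#' @export
toy_atp_classification <- function() {
  atp_classification(glycolytic = c("PGK", "PYK"), oxidative = "ATPS4m")
}

toy_regulatory_map <- function() {
  sp <- tibble::tibble(
    id = paste0("s", 1:9),
    name = c("GF", "OX", "HIF1A", "PGC1A", "PGK", "PYK", "ATPS4m", "FAO",
             "PDH"),
    compartment = "cyt",
    class = c("PROTEIN", "SIMPLE_MOLECULE", "PROTEIN", "PROTEIN", "PROTEIN",
              "PROTEIN", "PROTEIN", "PROTEIN", "PROTEIN")
  )
  id_of <- stats::setNames(sp$id, sp$name)
  mk <- function(id, reactants, products, mods = character(),
                 classes = character()) {
    list(id = id, reactants = unname(id_of[reactants]),
         products = unname(id_of[products]),
         modifiers = tibble::tibble(species = unname(id_of[mods]),
                                    class = classes))
  }
  reactions <- list(
    mk("re1", "GF", "HIF1A"),
    mk("re2", "OX", "PGC1A"),
    mk("re3", "HIF1A", "PGK"),
    mk("re4", "HIF1A", "PYK"),
    mk("re5", "PGC1A", "ATPS4m"),
    mk("re6", "PGC1A", "FAO"),
    mk("re7", "PGC1A", "PDH", "HIF1A", "INHIBITION")
  )
  aliases <- tibble::tibble(species = sp$id, alias = paste0("sa", 1:9))
  new_pd_map(sp, reactions, aliases)
}

#' Coupled regulatory/metabolic toy fixtures
#'
#' Writes a complete, self-consistent toy instance of the whole pipeline into
#' a directory: a CellDesigner process-description map of a small signaling
#' layer (growth-factor branch activating the glycolytic kinases via HIF1A;
#' an oxidative branch activating ATP synthase, beta-oxidation and PDH via
#' PGC1A, with HIF1A inhibiting PDH), the matching
#' [toy_core_metabolism()] SBML-fbc model sharing enzyme identifiers, a
#' scenario-specific initial-conditions CSV, and a machine-readable
#' ground-truth sidecar with the constraint set the scenario provably
#' induces:
#'
#' * `all_active` — no initial conditions; every enzyme reaches 1 in some
#'   minimal trap space, so the constraint set is empty and the
#'   contextualized optimum equals the control optimum (120).
#' * `glycolytic_only` — the oxidative input is switched off; `ATPS4m`,
#'   `FAO` and `PDH` are 0 in every minimal trap space, the oxidative route
#'   closes and the glycolytic ATP ratio becomes 1 (optimum 20).
#' * `oxidative_only` — the growth-factor input is switched off; `PGK` and
#'   `PYK` are 0 in every minimal trap space and the glycolytic ratio drops
#'   to 0 (optimum 50, all from beta-oxidation-fed oxphos).
#'
#' @param scenario One of `"all_active"`, `"glycolytic_only"`,
#'   `"oxidative_only"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed kept for interface symmetry with the random
#'   generators; the coupled fixture itself is deterministic.
#' @return A list (class `flx_fixture`): `paths` (map, metabolism, init_csv,
#'   ground_truth), `map`, `model`, `init` (named vector), `ground_truth`
#'   (tibble `reaction,lb,ub,components`), `classification` and `scenario`.
#' @export
coupled_fixture <- function(scenario = c("all_active", "glycolytic_only",
                                         "oxidative_only"),
                            dir = tempfile("fixture"), seed = 1L) {
  scenario <- match.arg(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- toy_regulatory_map()
  model <- toy_core_metabolism()
  paths <- list(
    map = file.path(dir, "map.xml"),
    metabolism = file.path(dir, "metabolism.xml"),
    init_csv = file.path(dir, "init.csv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  write_celldesigner(map, paths$map)
  write_sbml_fbc(model, paths$metabolism)
  init <- switch(scenario,
    all_active = stats::setNames(integer(), character()),
    glycolytic_only = c(OX = 0L),
    oxidative_only = c(GF = 0L)
  )
  utils::write.csv(
    data.frame(component = names(init), value = as.integer(init)),
    paths$init_csv, row.names = FALSE, quote = FALSE)
  gt <- switch(scenario,
    all_active = tibble::tibble(reaction = character(), lb = numeric(),
                                ub = numeric(), components = character()),
    glycolytic_only = tibble::tibble(
      reaction = c("ATPS4m", "FAO", "PDH"), lb = 0, ub = 0,
      components = c("ATPS4m", "FAO", "PDH")),
    oxidative_only = tibble::tibble(
      reaction = c("PGK", "PYK"), lb = 0, ub = 0,
      components = c("PGK", "PYK"))
  )
  readr::write_csv(gt, paths$ground_truth)
  structure(
    list(paths = paths, map = map, model = model, init = init,
         ground_truth = gt, classification = toy_atp_classification(),
         scenario = scenario, seed = seed),
    class = "flx_fixture")
}
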