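test_that("joint FBA recovers the stoichiometrically forced community growth", {
  # fibre 5 -> degrader growth 5 + 10 monomer -> consumer growth 10
  toy <- toy_fixture("toy_3")
  fba <- joint_fba(toy$comm)
  expect_equal(fba$growth, 15, tolerance = 1e-9)
  expect_equal(sum(fba$theta_k), fba$growth, tolerance = 1e-9)
  expect_equal(unname(fba$theta_k["deg"]), 5, tolerance = 1e-9)
})

test_that("a closed empty diet gives zero growth for all members", {
  toy <- toy_fixture("toy_3")
  comm <- apply_diet(toy$comm, diet(), policy = "closed")
  fba <- joint_fba(comm)
  expect_equal(fba$growth, 0, tolerance = 1e-9)
  expect_true(all(abs(fba$theta_k) < 1e-9))
})

test_that("joint FBA matches an independently assembled dense LP", {
  toy <- random_toy(7, 4)
  fba <- joint_fba(toy$comm)
  eng <- minicom:::oracle_engine(toy$comm)
  act <- toy$comm$members
  bio <- toy$comm$biomass[act]
  r <- minicom:::oracle_lp(eng, stats::setNames(rep(1, length(bio)), bio),
                           eng$lb, eng$ub)
  expect_equal(fba$growth, r$objective_value, tolerance = 1e-6)
})

test_that("zero SCFA weights give zero attainable SCFA", {
  toy <- toy_fixture("toy_3")
  spec0 <- functionality_spec(1, weights = c(0, 0, 0))
  fba <- joint_fba(toy$comm)
  fva <- scfa_fva_max(toy$comm, spec0, fba$theta_k, 0.99)
  expect_equal(fva$value, 0)
})

test_that("attainable SCFA is non-increasing in gr_opt_frac", {
  spec <- functionality_spec(3)
  for (seed in c(2, 5, 11)) {
    toy <- random_toy(seed, 5)
    fba <- joint_fba(toy$comm)
    vals <- vapply(c(0.5, 0.9, 0.99),
                   function(f) scfa_fva_max(toy$comm, spec, fba$theta_k, f)$value,
                   numeric(1))
    expect_true(all(diff(vals) <= 1e-9))
  }
})

test_that("producer-only community attains full joint butyrate production", {
  # CONV makes butyrate and biomass jointly, so the growth floor does not
  # trade off against butyrate: max butyrate = all monomer through CONV
  toy <- make_toy_community(c(deg = "degrader", but = "butyrate"))
  spec <- functionality_spec(3)
  fba <- joint_fba(toy$comm)
  fva <- scfa_fva_max(toy$comm, spec, fba$theta_k, 0.99)
  expect_equal(fva$value, 10, tolerance = 1e-9)
  expect_equal(unname(fva$scfa_fluxes["EX_but(e)"]), 10, tolerance = 1e-9)
})

test_that("targets are plain threshold arithmetic", {
  th <- c(a = 1, b = 2)
  tg <- build_targets(th, 5, algo_params(gr_frac = 0.8, scfa_frac = 0.8))
  expect_equal(tg$theta_total, 3)
  expect_equal(tg$gr_frac * tg$theta_total, 2.4)
  expect_equal(tg$scfa_frac * tg$scfa_max, 4)
  tg0 <- build_targets(th, 5, algo_params(gr_frac = 0, scfa_frac = 0))
  expect_equal(tg0$gr_frac * tg0$theta_total, 0)
  tg1 <- build_targets(th, 5, algo_params(gr_frac = 1, scfa_frac = 1))
  expect_equal(tg1$gr_frac * tg1$theta_total, tg1$theta_total)
  expect_equal(tg1$scfa_frac * tg1$scfa_max, 5)
})

test_that("feasibility check accepts the full community and rejects a gutted one", {
  toy <- toy_fixture("toy_3")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  expect_true(check_reduced_feasible(toy$comm, spec, tt$targets))
  gutted <- delete_species(toy$comm, "but")
  expect_false(check_reduced_feasible(gutted, spec, tt$targets))
  zero <- build_targets(tt$fba$theta_k, tt$fva$value,
                        algo_params(gr_frac = 0, scfa_frac = 0))
  expect_true(check_reduced_feasible(gutted, spec, zero))
})

test_that("sequential deletion removes only expendable members", {
  toy <- make_toy_community(c(deg = "degrader", but = "butyrate",
                              f1 = "freeloader", f2 = "freeloader",
                              f3 = "freeloader"))
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  for (seed in c(1, 2)) {
    red <- sequential_reduce(toy$comm, spec, tt$targets,
                             algo_params(milp_size = 2, seed = seed))
    expect_setequal(red$final_active, c("deg", "but"))
    expect_true(check_reduced_feasible(red$comm, spec, tt$targets))
  }
})

test_that("a large milp_size leaves the community untouched", {
  toy <- toy_fixture("toy_3")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  red <- sequential_reduce(toy$comm, spec, tt$targets,
                           algo_params(milp_size = 10))
  expect_equal(nrow(red$trace), 0)
  expect_setequal(red$final_active, toy$comm$members)
})

test_that("interchangeable producers: any seed yields a feasible final set", {
  toy <- toy_fixture("toy_5_redundant")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  finals <- lapply(c(3, 4, 8), function(seed) {
    red <- sequential_reduce(toy$comm, spec, tt$targets,
                             algo_params(milp_size = 2, seed = seed))
    expect_true(check_reduced_feasible(red$comm, spec, tt$targets))
    red$final_active
  })
  expect_true(all(vapply(finals, function(f) "deg" %in% f, logical(1))))
  expect_true(all(vapply(finals, function(f)
    any(c("butA", "butB") %in% f), logical(1))))
})

test_that("the membership MILP finds the cross-feeding pair", {
  toy <- make_toy_community(c(A = "degrader", B = "butyrate",
                              C = "freeloader", D = "freeloader"))
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  mm <- minimize_membership(toy$comm, spec, tt$targets)
  orc <- brute_force_minimal(toy$comm, spec, tt$targets)
  expect_equal(length(mm$members), orc$min_cardinality)
  expect_true(set_key(mm$members) %in%
                vapply(orc$minimal_supports, set_key, character(1)))
  expect_true(all(c("A", "B") %in% mm$members))
})

test_that("zero thresholds give the documented empty-community optimum", {
  toy <- toy_fixture("toy_3")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec, algo_params(gr_frac = 0, scfa_frac = 0))
  expect_warning(mm <- minimize_membership(toy$comm, spec, tt$targets),
                 "empty community")
  expect_length(mm$members, 0)
})

test_that("a single-member community meeting its own thresholds returns itself", {
  m <- tiny_model("solo")
  comm <- build_community(list(m))
  comm <- apply_diet(comm, diet(list("EX_glc(e)" = c(-10, 1000))))
  comm <- add_coupling(comm)
  fba <- joint_fba(comm)
  spec <- functionality_spec(3)   # no SCFA reactions: threshold is trivially 0
  tg <- build_targets(fba$theta_k, 0, algo_params())
  mm <- suppressWarnings(minimize_membership(comm, spec, tg))
  expect_identical(mm$members, "solo")
})

test_that("enumeration with one solution allowed equals the plain MILP", {
  toy <- toy_fixture("toy_5_redundant")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  one <- enumerate_minimal(toy$comm, spec, tt$targets, max_solutions = 1)
  mm <- minimize_membership(toy$comm, spec, tt$targets)
  expect_length(one, 1)
  expect_identical(sort(one[[1]]$members), sort(mm$members))
})

test_that("per-species growth mode gates each member's own threshold", {
  toy <- toy_fixture("toy_3")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec,
                    algo_params(growth_constraint_mode = "per_species"))
  mm <- minimize_membership(toy$comm, spec, tt$targets)
  expect_gt(length(mm$members), 0)
  for (s in mm$members)
    expect_gte(mm$per_species_growth[[s]],
               0.8 * tt$targets$theta_k[[s]] - 1e-6)
  v <- verify_solution(toy$comm, mm, spec, tt$targets)
  expect_true(v$ok)
})

test_that("coupling-only gating still finds a minimal community", {
  toy <- toy_fixture("toy_3")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  strict <- minimize_membership(toy$comm, spec, tt$targets, gate = "all")
  legacy <- minimize_membership(toy$comm, spec, tt$targets,
                                gate = "coupling_only")
  # the legacy formulation only relaxes exclusion, so it can never need more
  expect_lte(length(legacy$members), length(strict$members))
})

test_that("max SCFA of a support respects and can exceed the threshold", {
  toy <- toy_fixture("toy_3")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  mm <- minimize_membership(toy$comm, spec, tt$targets)
  v <- max_scfa_of_minimal(toy$comm, mm$members, spec, tt$targets)
  expect_gte(v, tt$targets$scfa_frac * tt$targets$scfa_max - 1e-9)
  # per-species mode at gr_frac = gr_opt_frac makes the full-community value
  # exactly the Step-2 maximum
  ttp <- toy_targets(toy, spec,
                     algo_params(gr_frac = 0.99, gr_opt_frac = 0.99,
                                 growth_constraint_mode = "per_species"))
  vfull <- max_scfa_of_minimal(toy$comm, toy$comm$members, spec, ttp$targets)
  expect_equal(vfull, ttp$targets$scfa_max, tolerance = 1e-6)
  expect_error(max_scfa_of_minimal(toy$comm, character(0), spec, tt$targets),
               "empty support")
})

test_that("the pipeline keeps the keystone degrader in every solution", {
  toy <- toy_fixture("toy_9_demo")
  res <- find_minimal_microbiomes(toy$models, toy$diet, functionality_spec(3),
                                  algo_params(iterations = 3, milp_size = 5,
                                              seed = 11))
  expect_gt(length(res$solutions), 0)
  for (s in res$solutions) {
    expect_true("deg" %in% s$members)
    expect_true(any(startsWith(s$members, "but")))
  }
})

test_that("iterations with different seeds recover both redundant supports", {
  toy <- toy_fixture("toy_5_redundant")
  res <- find_minimal_microbiomes(toy$models, toy$diet, functionality_spec(3),
                                  algo_params(iterations = 6, milp_size = 2,
                                              seed = 1))
  keys <- vapply(res$solutions, function(s) set_key(s$members), character(1))
  expect_setequal(keys, c("butA|deg", "butB|deg"))
})

test_that("identical seeds replay to identical solution lists", {
  toy <- toy_fixture("toy_9_demo")
  run <- function() find_minimal_microbiomes(
    toy$models, toy$diet, functionality_spec(3),
    algo_params(iterations = 2, milp_size = 4, seed = 5))
  r1 <- run(); r2 <- run()
  expect_identical(lapply(r1$solutions, `[[`, "members"),
                   lapply(r2$solutions, `[[`, "members"))
  expect_identical(vapply(r1$solutions, `[[`, numeric(1), "growth"),
                   vapply(r2$solutions, `[[`, numeric(1), "growth"))
})
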