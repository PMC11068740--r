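# Shared builders for the test suite.  All fixtures are constructed in code;
# yields are small rationals so LP optima are exact.

# a 3-reaction chemostat-style model: imports substrate, grows with yield y
tiny_model <- function(id = "solo", y = 1, uptake = 10) {
  S <- matrix(0, 2, 3, dimnames = list(c("glc[e]", "prec[c]"),
                                       c("EX_glc(e)", "GROW", "biomassA")))
  S["glc[e]", "EX_glc(e)"] <- -1
  S["glc[e]", "GROW"] <- -1
  S["prec[c]", "GROW"] <- y
  S["prec[c]", "biomassA"] <- -1
  microbe_model(id, S, lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
                biomass_rxn = "biomassA", exchange_rxns = "EX_glc(e)")
}

# Step 1 + Step 2 + targets in one go
toy_targets <- function(toy, spec, params = algo_params()) {
  fba <- joint_fba(toy$comm)
  fva <- scfa_fva_max(toy$comm, spec, fba$theta_k, params$gr_opt_frac)
  list(fba = fba, fva = fva,
       targets = build_targets(fba$theta_k, fva$value, params))
}

# cardinality reported by the MILP, Inf when no sub-community is feasible
milp_cardinality <- function(comm, spec, targets, ...) {
  mm <- tryCatch(suppressWarnings(minimize_membership(comm, spec, targets, ...)),
                 error = function(e) NULL)
  if (is.null(mm)) Inf else length(mm$members)
}

# subsets of the active members as bitmask -> character vector
mask_members <- function(act, mask) {
  act[bitwAnd(mask, bitwShiftL(1L, seq_along(act) - 1L)) > 0L]
}

set_key <- function(members) paste(sort(members), collapse = "|")
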