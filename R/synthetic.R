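# Synthetic cross-feeding communities with analytically known structure, and
# the exhaustive brute-force oracle used to certify MILP solutions.
#
# The toy metabolism is a two-level chain: a degrader converts fibre into a
# monomer plus biomass precursor; producers convert the monomer into one SCFA
# plus precursor; freeloaders grow on the monomer without producing anything;
# cross-feeders condense monomer with acetate into butyrate.  All yields are
# small integers or halves so every LP optimum is an exact rational.

toy_roles <- c("degrader", "acetate", "butyrate", "propionate",
               "cross_feeder", "freeloader")

scfa_met <- c(acetate = "ac[e]", butyrate = "but[e]", propionate = "ppa[e]")
scfa_ex <- c(acetate = "EX_ac(e)", butyrate = "EX_but(e)",
             propionate = "EX_ppa(e)")

#' Build one toy community member
#'
#' @param role one of `"degrader"`, `"acetate"`, `"butyrate"`,
#'   `"propionate"` (SCFA producers), `"cross_feeder"` (condenses monomer
#'   and acetate into butyrate) or `"freeloader"` (grows on the monomer,
#'   produces nothing).
#' @param id species id.
#' @param yields named list overriding the stoichiometric yields:
#'   `mono` (monomer per fibre, degrader, default 2), `scfa` (SCFA per
#'   monomer, producers, default 1), `bio` (biomass precursor per substrate,
#'   default 1).
#' @param uptake substrate uptake bound (mmol/gDW-h, default 10).
#' @return a [microbe_model] with 3-6 reactions.
#' @export
make_toy_member <- function(role, id, yields = list(), uptake = 10) {
  role <- match.arg(role, toy_roles)
  y <- function(nm, def) if (!is.null(yields[[nm]])) yields[[nm]] else def
  bio <- y("bio", 1)
  mk <- function(mets, rxns, stoich, lb, ub) {
    S <- matrix(0, length(mets), length(rxns),
                dimnames = list(mets, rxns))
    for (e in stoich) S[e[[1]], e[[2]]] <- as.numeric(e[[3]])
    microbe_model(id, S, lb, ub, biomass_rxn = "biomass",
                  exchange_rxns = rxns[startsWith(rxns, "EX_")])
  }
  if (role == "degrader") {
    ym <- y("mono", 2)
    return(mk(c("fib[e]", "mono[e]", "prec[c]"),
              c("EX_fib(e)", "EX_mono(e)", "DEGRADE", "biomass"),
              list(list("fib[e]", "EX_fib(e)", -1),
                   list("mono[e]", "EX_mono(e)", -1),
                   list("fib[e]", "DEGRADE", -1),
                   list("mono[e]", "DEGRADE", ym),
                   list("prec[c]", "DEGRADE", bio),
                   list("prec[c]", "biomass", -1)),
              lb = c(-uptake, -1000, 0, 0), ub = c(1000, 1000, 1000, 1000)))
  }
  if (role %in% names(scfa_met)) {
    ys <- y("scfa", 1)
    met <- scfa_met[[role]]
    ex <- scfa_ex[[role]]
    return(mk(c("mono[e]", met, "prec[c]"),
              c("EX_mono(e)", ex, "CONV", "biomass"),
              list(list("mono[e]", "EX_mono(e)", -1),
                   list(met, ex, -1),
                   list("mono[e]", "CONV", -1),
                   list(met, "CONV", ys),
                   list("prec[c]", "CONV", bio),
                   list("prec[c]", "biomass", -1)),
              lb = c(-uptake, 0, 0, 0), ub = c(1000, 1000, 1000, 1000)))
  }
  if (role == "cross_feeder") {
    ys <- y("scfa", 1)
    return(mk(c("mono[e]", "ac[e]", "but[e]", "prec[c]"),
              c("EX_mono(e)", "EX_ac(e)", "EX_but(e)", "CONDENSE", "biomass"),
              list(list("mono[e]", "EX_mono(e)", -1),
                   list("ac[e]", "EX_ac(e)", -1),
                   list("but[e]", "EX_but(e)", -1),
                   list("mono[e]", "CONDENSE", -1),
                   list("ac[e]", "CONDENSE", -1),
                   list("but[e]", "CONDENSE", ys),
                   list("prec[c]", "CONDENSE", bio),
                   list("prec[c]", "biomass", -1)),
              lb = c(-uptake, -uptake, 0, 0, 0),
              ub = c(1000, 1000, 1000, 1000, 1000)))
  }
  # freeloader
  mk(c("mono[e]", "prec[c]"),
     c("EX_mono(e)", "GROW", "biomass"),
     list(list("mono[e]", "EX_mono(e)", -1),
          list("mono[e]", "GROW", -1),
          list("prec[c]", "GROW", bio),
          list("prec[c]", "biomass", -1)),
     lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000))
}

#' The fibre-only toy diet
#'
#' @param fibre_supply maximum fibre uptake (mmol/gDW-h, default 5).
#' @return a [diet] supplying only fibre.
#' @export
toy_diet <- function(fibre_supply = 5) {
  diet(list("EX_fib(e)" = c(-fibre_supply, 1000)), name = "fibre_only")
}

#' Build a toy cross-feeding community
#'
#' Members are built with [make_toy_member()], merged with
#' [build_community()], put on a fibre-only diet (closed policy, so only
#' fibre enters from the environment and all cross-feeding happens through
#' the shared pool) and coupled.
#'
#' @param roles character vector of member roles; names (if any) become
#'   species ids, otherwise ids are `<role><position>`.
#' @param yields optional list (per member) of yield overrides.
#' @param fibre_supply community fibre uptake bound (default 5).
#' @param coupling_c,coupling_u coupling constants (defaults 400, 0.01).
#' @return a list with `comm` (ready for [joint_fba()]), `models`, `diet`
#'   and `annotations` (data frame of member roles and the SCFA each can
#'   contribute to).
#' @export
make_toy_community <- function(roles, yields = NULL, fibre_supply = 5,
                               coupling_c = 400, coupling_u = 0.01) {
  ids <- names(roles)
  if (is.null(ids)) ids <- paste0(roles, seq_along(roles))
  models <- lapply(seq_along(roles), function(i)
    make_toy_member(roles[[i]], ids[[i]],
                    yields = if (is.null(yields)) list() else yields[[i]]))
  comm <- build_community(models)
  comm <- apply_diet(comm, toy_diet(fibre_supply), policy = "closed")
  comm <- add_coupling(comm, c = coupling_c, u = coupling_u)
  scfa_of <- c(acetate = "acetate", butyrate = "butyrate",
               propionate = "propionate", cross_feeder = "butyrate",
               degrader = NA_character_, freeloader = NA_character_)
  structure(list(comm = comm, models = models,
                 diet = toy_diet(fibre_supply),
                 annotations = data.frame(id = ids, role = unname(unlist(roles)),
                                          scfa = unname(scfa_of[unlist(roles)]),
                                          stringsAsFactors = FALSE)),
            class = "toy_community")
}

#' Named regression fixtures
#'
#' `toy_3`: degrader + butyrate producer + freeloader (unique minimal
#' butyrate support of size 2).  `toy_5_redundant`: two interchangeable
#' butyrate producers (two minimal supports).  `toy_9_demo`: a 9-member
#' community with four butyrate producers of decreasing yield and five
#' non-producers, mirroring a demonstration-scale gut community design.
#'
#' @param name fixture name.
#' @return a [make_toy_community()] result.
#' @export
toy_fixture <- function(name = c("toy_3", "toy_5_redundant", "toy_9_demo")) {
  name <- match.arg(name)
  switch(name,
    toy_3 = make_toy_community(
      c(deg = "degrader", but = "butyrate", free = "freeloader")),
    toy_5_redundant = make_toy_community(
      c(deg = "degrader", butA = "butyrate", butB = "butyrate",
        freeA = "freeloader", freeB = "freeloader")),
    toy_9_demo = make_toy_community(
      c(deg = "degrader",
        but1 = "butyrate", but2 = "butyrate", but3 = "butyrate",
        but4 = "butyrate", ac1 = "acetate", ac2 = "acetate",
        free1 = "freeloader", free2 = "freeloader"),
      yields = list(list(), list(scfa = 1), list(scfa = 1), list(scfa = 0.5),
                    list(scfa = 0.5), list(), list(scfa = 0.5), list(),
                    list())))
}

#' Random toy community
#'
#' Draws `n` member roles (always at least one degrader and one SCFA
#' producer) and small rational yields under a fixed seed.
#'
#' @param seed integer seed.
#' @param n member count (3-12).
#' @return a [make_toy_community()] result.
#' @export
random_toy <- function(seed, n) {
  stopifnot(n >= 3, n <= 12)
  with_seed(seed, {
    roles <- c("degrader",
               sample(c("acetate", "butyrate", "propionate"), 1),
               sample(toy_roles, n - 2, replace = TRUE,
                      prob = c(0.15, 0.2, 0.2, 0.15, 0.1, 0.2)))
    roles <- sample(roles)  # shuffle positions
    yields <- lapply(roles, function(r) {
      if (r == "degrader") list(mono = sample(c(1.5, 2, 2.5), 1),
                                bio = sample(c(0.5, 1), 1))
      else list(scfa = sample(c(0.5, 1, 1.5), 1), bio = sample(c(0.5, 1), 1))
    })
    names(roles) <- paste0(substr(roles, 1, 3), seq_along(roles))
    make_toy_community(roles, yields = yields)
  })
}

# ---- brute-force oracle ---------------------------------------------------
# Deliberately independent of community_lp()/check_reduced_feasible(): the
# constraint system is re-derived here with its own dense assembly so that
# oracle agreement is evidence rather than tautology.

oracle_engine <- function(comm) {
  A <- as.matrix(comm$S)
  rs <- rep("E", nrow(A))
  rhs <- numeric(nrow(A))
  if (!is.null(comm$coupling)) {
    cc <- comm$coupling$c
    uu <- comm$coupling$u
    for (j in colnames(comm$S)) {
      k <- comm$rxn_species[[j]]
      if (k == 0L) next
      if (j %in% comm$biomass) next
      if (!comm$coupling$couple_exchanges && comm$rxn_is_exchange[[j]]) next
      bio <- comm$biomass[[k]]
      r1 <- numeric(ncol(A)); names(r1) <- colnames(A)
      r1[j] <- 1; r1[bio] <- r1[bio] - cc
      r2 <- numeric(ncol(A)); names(r2) <- colnames(A)
      r2[j] <- -1; r2[bio] <- r2[bio] - cc
      A <- rbind(A, r1, r2)
      rs <- c(rs, "L", "L")
      rhs <- c(rhs, uu, uu)
    }
  }
  rownames(A) <- NULL
  list(A = A, rs = rs, rhs = rhs, vars = colnames(comm$S),
       lb = comm$lb, ub = comm$ub, members = comm$members,
       active = comm$active, biomass = comm$biomass,
       rxn_species = comm$rxn_species)
}

oracle_lp <- function(eng, obj, lb, ub, extra = NULL) {
  A <- eng$A; rs <- eng$rs; rhs <- eng$rhs
  if (!is.null(extra)) {
    A <- rbind(A, extra$A)
    rs <- c(rs, extra$rs)
    rhs <- c(rhs, extra$rhs)
  }
  solve_lp(lp_problem(objective = obj, sense = "max", A = A, row_sense = rs,
                      rhs = rhs, lb = lb, ub = ub, vars = eng$vars))
}

# bounds with every member not in `subset` zeroed out
oracle_bounds <- function(eng, subset) {
  lb <- eng$lb; ub <- eng$ub
  owner <- ifelse(eng$rxn_species > 0,
                  eng$members[pmax(eng$rxn_species, 1L)], NA_character_)
  out <- !is.na(owner) & !(owner %in% subset)
  lb[out] <- 0; ub[out] <- 0
  list(lb = lb, ub = ub)
}

# max growth of a subset, and max weighted SCFA at each growth threshold
oracle_eval_subset <- function(eng, subset, w, gr_thresholds, mode, theta_k,
                               gr_fracs = NULL) {
  b <- oracle_bounds(eng, subset)
  bio <- eng$biomass[subset]
  gobj <- stats::setNames(rep(1, length(bio)), bio)
  if (mode == "community") {
    rg <- oracle_lp(eng, gobj, b$lb, b$ub)
    gmax <- if (rg$status == "optimal") rg$objective_value else -Inf
    smax <- vapply(gr_thresholds, function(thr) {
      if (gmax < thr - THR_TOL) return(-Inf)
      if (!length(w)) return(0)
      row <- numeric(length(eng$vars)); names(row) <- eng$vars
      row[bio] <- 1
      r <- oracle_lp(eng, w, b$lb, b$ub,
                     extra = list(A = matrix(row, 1), rs = "G", rhs = thr))
      if (r$status == "optimal") r$objective_value else -Inf
    }, numeric(1))
    return(list(max_growth = gmax, max_scfa = smax))
  }
  # per-species mode: thresholds are per-member biomass lower bounds
  smax <- vapply(gr_fracs, function(fr) {
    lb <- b$lb
    lb[bio] <- pmax(lb[bio], fr * theta_k[subset])
    obj <- if (length(w)) w else gobj
    r <- oracle_lp(eng, obj, lb, b$ub)
    if (r$status != "optimal") return(-Inf)
    if (length(w)) r$objective_value else 0
  }, numeric(1))
  rg <- oracle_lp(eng, gobj, b$lb, b$ub)
  list(max_growth = if (rg$status == "optimal") rg$objective_value else -Inf,
       max_scfa = smax)
}

#' Exhaustive minimal-subset oracle
#'
#' Tests every nonempty subset of the active members by direct LP (growth
#' check, then SCFA check) against the targets, using its own dense
#' constraint assembly, and reports all feasible subsets and the
#' minimum-cardinality ones.  When both thresholds are zero the empty
#' community is feasible by convention and the minimum cardinality is 0.
#'
#' @param comm a [community_model] with coupling added.
#' @param spec a [functionality_spec].
#' @param targets a [build_targets()] result.
#' @param max_members guard: refuse communities with more than this many
#'   active members (default 12).
#' @return a list of class `oracle_report` with `feasible_subsets`,
#'   `minimal_supports`, `min_cardinality` and `degenerate`.
#' @export
brute_force_minimal <- function(comm, spec, targets, max_members = 12) {
  act <- comm$members[comm$active]
  if (length(act) > max_members)
    stop("oracle guard: ", length(act), " active members exceeds ",
         max_members)
  eng <- oracle_engine(comm)
  w <- scfa_objective(comm, spec)
  gr_thr <- targets$gr_frac * targets$theta_total
  scfa_thr <- targets$scfa_frac * targets$scfa_max
  degenerate <- gr_thr <= THR_TOL && scfa_thr <= THR_TOL &&
    (targets$mode == "community" ||
       all(targets$gr_frac * targets$theta_k <= THR_TOL))
  feas <- list()
  n <- length(act)
  for (mask in seq_len(2^n - 1)) {
    subset <- act[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
    ev <- oracle_eval_subset(eng, subset, w,
                             gr_thresholds = gr_thr, mode = targets$mode,
                             theta_k = targets$theta_k,
                             gr_fracs = targets$gr_frac)
    ok <- if (targets$mode == "community") {
      ev$max_growth >= gr_thr - THR_TOL && ev$max_scfa[1] >= scfa_thr - THR_TOL
    } else {
      is.finite(ev$max_scfa[1]) && ev$max_scfa[1] >= scfa_thr - THR_TOL
    }
    if (ok) feas[[length(feas) + 1L]] <-
        list(members = subset, max_growth = ev$max_growth,
             max_scfa = ev$max_scfa[1])
  }
  cards <- vapply(feas, function(f) length(f$members), integer(1))
  min_card <- if (degenerate) 0L else if (length(cards)) min(cards) else NA_integer_
  minimal <- if (degenerate) list(character(0)) else
    lapply(feas[cards == min_card], `[[`, "members")
  structure(list(feasible_subsets = feas, minimal_supports = minimal,
                 min_cardinality = min_card, degenerate = degenerate),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat("<oracle_report> ", length(x$feasible_subsets),
      " feasible subsets; minimum cardinality ", x$min_cardinality,
      " (", length(x$minimal_supports), " minimal supports)\n", sep = "")
  invisible(x)
}

#' Independent feasibility certificate for a solution
#'
#' Re-checks a returned `minimal_microbiome` against a dense re-assembly of
#' the mass-balance, bound, coupling, membership-gating and threshold
#' constraints.
#'
#' @param comm the [community_model] the solution was computed on.
#' @param sol a `minimal_microbiome` with recorded fluxes.
#' @param spec a [functionality_spec].
#' @param targets a [build_targets()] result.
#' @param tol feasibility tolerance (default 1e-6).
#' @return a list with `ok` and `max_violation`.
#' @export
verify_solution <- function(comm, sol, spec, targets, tol = 1e-6) {
  v <- sol$fluxes
  if (is.null(v)) stop("solution carries no fluxes")
  eng <- oracle_engine(comm)
  v <- v[eng$vars]
  viol <- c(balance = max(abs(eng$A[eng$rs == "E", , drop = FALSE] %*% v)),
            rows = max(c(0, (eng$A[eng$rs == "L", , drop = FALSE] %*% v) -
                           eng$rhs[eng$rs == "L"])))
  b <- oracle_bounds(eng, sol$members)
  viol["bounds"] <- max(c(0, b$lb - v, v - b$ub))
  w <- scfa_objective(comm, spec)
  scfa <- if (length(w)) sum(w * v[names(w)]) else 0
  viol["scfa"] <- max(0, targets$scfa_frac * targets$scfa_max - scfa - THR_TOL)
  if (targets$mode == "community") {
    viol["growth"] <- max(0, targets$gr_frac * targets$theta_total -
                            sum(v[eng$biomass[sol$members]]) - THR_TOL)
  } else {
    thr <- targets$gr_frac * targets$theta_k[sol$members]
    viol["growth"] <- max(c(0, thr - v[eng$biomass[sol$members]] - THR_TOL))
  }
  list(ok = max(viol) < tol, max_violation = max(viol), detail = viol)
}
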