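# The three-step minimal-community algorithm:
#   Step 1  joint FBA: maximise the sum of member biomass fluxes.
#   Step 2  SCFA FVA:  maximise the weighted SCFA exchange sum with each
#           member's growth lower-bounded at gr_opt_frac of its Step-1 rate.
#   Step 3  sequential deletion to a tractable size, then a MILP minimising
#           the L1-norm of the binary membership vector subject to retaining
#           gr_frac of the growth and scfa_frac of the SCFA production.

#' Functionality specification
#'
#' Which SCFA production objective constrains the minimal community.
#' Constraint 1 maximises the weighted sum of the three SCFA exchange fluxes;
#' constraints 2, 3 and 4 are the single-metabolite versions for acetate,
#' butyrate and propionate (weight triples (1,0,0), (0,1,0), (0,0,1)).
#'
#' @param constraint integer 1-4.
#' @param scfa_exchange_ids named character triple of community
#'   exchange-reaction ids, AGORA naming by default.
#' @param weights nonnegative weight triple `(w_ac, w_bu, w_pr)` used by
#'   constraint 1 (default `c(1, 1, 1)`).
#' @return an object of class `functionality_spec`.
#' @export
functionality_spec <- function(constraint = 1,
                               scfa_exchange_ids = c(acetate = "EX_ac(e)",
                                                     butyrate = "EX_but(e)",
                                                     propionate = "EX_ppa(e)"),
                               weights = c(1, 1, 1)) {
  if (!(constraint %in% 1:4)) stop("constraint must be 1, 2, 3 or 4")
  if (length(scfa_exchange_ids) != 3) stop("need exactly three SCFA exchange ids")
  if (length(weights) != 3 || any(weights < 0))
    stop("weights must be three nonnegative reals")
  w <- if (constraint == 1) weights else as.numeric(1:3 == (constraint - 1))
  structure(list(constraint = as.integer(constraint),
                 scfa_exchange_ids = scfa_exchange_ids,
                 weights = weights,
                 effective_weights = stats::setNames(w, scfa_exchange_ids)),
            class = "functionality_spec")
}

#' @export
print.functionality_spec <- function(x, ...) {
  cat("<functionality_spec> constraint ", x$constraint, "; weights ",
      paste(x$effective_weights, collapse = ":"), " on ",
      paste(x$scfa_exchange_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Algorithm parameters
#'
#' @param gr_opt_frac fraction of each member's joint-FBA growth rate used as
#'   its lower bound during the SCFA maximisation step (default 0.99).
#' @param gr_frac growth-retention fraction for the minimal community
#'   (default 0.8).
#' @param scfa_frac SCFA-retention fraction (default 0.8).
#' @param milp_size sequential deletion stops once the community has at most
#'   this many members (default 8).
#' @param deletion_sequence optional ordered species vector; when `NULL` a
#'   seeded random permutation is drawn.
#' @param seed integer seed for random deletion sequences.
#' @param growth_constraint_mode `"community"` (default): total biomass of
#'   the minimal community must reach `gr_frac` of the full community's
#'   total; `"per_species"`: each retained member must reach `gr_frac` of its
#'   own full-community rate (membership-gated).
#' @param iterations number of independently seeded reduction + MILP rounds.
#' @return an object of class `algo_params`.
#' @export
algo_params <- function(gr_opt_frac = 0.99, gr_frac = 0.8, scfa_frac = 0.8,
                        milp_size = 8L, deletion_sequence = NULL, seed = 1L,
                        growth_constraint_mode = c("community", "per_species"),
                        iterations = 1L) {
  stopifnot(gr_opt_frac > 0, gr_opt_frac <= 1, gr_frac >= 0, gr_frac <= 1,
            scfa_frac >= 0, scfa_frac <= 1, milp_size >= 1, iterations >= 1)
  structure(list(gr_opt_frac = gr_opt_frac, gr_frac = gr_frac,
                 scfa_frac = scfa_frac, milp_size = as.integer(milp_size),
                 deletion_sequence = deletion_sequence,
                 seed = as.integer(seed),
                 growth_constraint_mode = match.arg(growth_constraint_mode),
                 iterations = as.integer(iterations)),
            class = "algo_params")
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Step 1: joint flux balance analysis
#'
#' Maximises the unweighted sum of the active members' biomass fluxes subject
#' to community mass balance, flux bounds and any coupling constraints.
#'
#' @param comm a [community_model] (diet applied, coupling added).
#' @return a list with `growth` (community growth rate, h^-1), `theta_k`
#'   (named per-species growth rates, 0 for inactive members), `fluxes` and
#'   `status`.
#' @export
joint_fba <- function(comm) {
  stopifnot(inherits(comm, "community_model"))
  bio <- comm$biomass[comm$active]
  obj <- stats::setNames(rep(1, length(bio)), bio)
  r <- solve_lp(community_lp(comm, obj, sense = "max"))
  if (r$status != "optimal")
    stop("joint FBA ", r$status,
         ": community cannot grow on this diet (growth 0 is feasible, so ",
         "this signals malformed constraints)")
  theta <- stats::setNames(numeric(length(comm$members)), comm$members)
  theta[names(bio)] <- r$fluxes[bio]
  names(theta) <- comm$members
  list(growth = r$objective_value, theta_k = theta, fluxes = r$fluxes,
       status = r$status)
}

# objective over the SCFA exchange reactions actually present in `comm`
scfa_objective <- function(comm, spec) {
  w <- spec$effective_weights
  present <- names(w) %in% colnames(comm$S)
  if (!any(present)) {
    warning("none of the SCFA exchange reactions (",
            paste(names(w), collapse = ", "), ") exist in the community")
  }
  w[present]
}

# bounds with each active member's biomass lower-bounded at frac * theta_k
growth_floored_bounds <- function(comm, theta_k, frac) {
  lb <- comm$lb
  act <- comm$members[comm$active]
  bio <- comm$biomass[act]
  lb[bio] <- pmax(lb[bio], frac * theta_k[act])
  lb
}

#' Step 2: maximum SCFA production at near-optimal growth
#'
#' Solves one LP: maximise the weighted community SCFA exchange sum subject
#' to the community constraints plus `v_bio_k >= gr_opt_frac * theta_k` for
#' every active member.
#'
#' @param comm a [community_model].
#' @param spec a [functionality_spec].
#' @param theta_k per-species growth rates from [joint_fba()] on `comm`.
#' @param gr_opt_frac growth fraction kept during the maximisation.
#' @return a list with `value` (maximum weighted SCFA flux, mmol/gDW-h),
#'   `scfa_fluxes` (the optimal triple) and `fluxes`.
#' @export
scfa_fva_max <- function(comm, spec, theta_k, gr_opt_frac = 0.99) {
  stopifnot(inherits(comm, "community_model"),
            inherits(spec, "functionality_spec"))
  w <- scfa_objective(comm, spec)
  lb <- growth_floored_bounds(comm, theta_k, gr_opt_frac)
  if (!length(w)) {
    triple <- stats::setNames(numeric(3), spec$scfa_exchange_ids)
    return(list(value = 0, scfa_fluxes = triple, fluxes = NULL))
  }
  r <- solve_lp(community_lp(comm, w, sense = "max", lb = lb))
  if (r$status != "optimal")
    stop("SCFA FVA ", r$status, " (unexpected for gr_opt_frac <= 1; ",
         "signals numerical trouble)")
  triple <- stats::setNames(numeric(3), spec$scfa_exchange_ids)
  triple[names(w)] <- r$fluxes[names(w)]
  list(value = r$objective_value, scfa_fluxes = triple, fluxes = r$fluxes)
}

#' Assemble the functionality targets
#'
#' Pure bookkeeping: stores the Step-1 growth rates, the Step-2 maximum SCFA
#' flux and the retention fractions that become the lower bounds of the
#' membership MILP.
#'
#' @param theta_k named per-species growth rates (h^-1).
#' @param scfa_max maximum weighted SCFA flux of the full community.
#' @param params an [algo_params].
#' @return an object of class `community_targets`.
#' @export
build_targets <- function(theta_k, scfa_max, params) {
  structure(list(theta_k = theta_k, theta_total = sum(theta_k),
                 scfa_max = scfa_max,
                 gr_frac = params$gr_frac, scfa_frac = params$scfa_frac,
                 gr_opt_frac = params$gr_opt_frac,
                 mode = params$growth_constraint_mode),
            class = "community_targets")
}

#' @export
print.community_targets <- function(x, ...) {
  cat("<community_targets> total growth ", format(x$theta_total),
      " h^-1, max SCFA ", format(x$scfa_max),
      " mmol/gDW-h; thresholds: growth >= ", format(x$gr_frac * x$theta_total),
      " (", x$mode, "), SCFA >= ", format(x$scfa_frac * x$scfa_max),
      "\n", sep = "")
  invisible(x)
}

# boundary comparisons use threshold - 1e-9 to avoid flapping
THR_TOL <- 1e-9

#' Does a (reduced) community still meet the targets?
#'
#' Two LPs: a growth check (joint FBA) and an SCFA check (maximum weighted
#' SCFA subject to the growth threshold).
#'
#' @param comm a [community_model] with at least one active member.
#' @param spec a [functionality_spec].
#' @param targets a [build_targets()] result.
#' @return `TRUE` iff the active community meets both thresholds (an
#'   infeasible LP counts as `FALSE`).
#' @export
check_reduced_feasible <- function(comm, spec, targets) {
  act <- comm$members[comm$active]
  if (!length(act)) return(FALSE)
  bio <- comm$biomass[act]
  w <- scfa_objective(comm, spec)
  scfa_thr <- targets$scfa_frac * targets$scfa_max

  if (targets$mode == "community") {
    gr_thr <- targets$gr_frac * targets$theta_total
    obj <- stats::setNames(rep(1, length(bio)), bio)
    r1 <- solve_lp(community_lp(comm, obj, sense = "max"))
    if (r1$status != "optimal" || r1$objective_value < gr_thr - THR_TOL)
      return(FALSE)
    if (!length(w)) return(0 >= scfa_thr - THR_TOL)
    grow_row <- matrix(0, 1, ncol(comm$S), dimnames = list(NULL, colnames(comm$S)))
    grow_row[1, bio] <- 1
    r2 <- solve_lp(community_lp(comm, w, sense = "max",
                                extra_A = grow_row, extra_sense = "G",
                                extra_rhs = gr_thr))
    return(r2$status == "optimal" && r2$objective_value >= scfa_thr - THR_TOL)
  }
  # per-species mode: the growth thresholds are bounds
  lb <- growth_floored_bounds(comm, targets$theta_k, targets$gr_frac)
  if (!length(w)) {
    obj <- stats::setNames(rep(1, length(bio)), bio)
    r <- solve_lp(community_lp(comm, obj, sense = "max", lb = lb))
    return(r$status == "optimal" && 0 >= scfa_thr - THR_TOL)
  }
  r <- solve_lp(community_lp(comm, w, sense = "max", lb = lb))
  r$status == "optimal" && r$objective_value >= scfa_thr - THR_TOL
}

#' Step 3a: sequential deletion
#'
#' Walks a deletion sequence (user-supplied or a seeded random permutation),
#' tentatively deleting each species and keeping the deletion iff the reduced
#' community still meets the targets.  The pass repeats until the community
#' is no larger than `milp_size` or a full pass deletes nothing.
#'
#' @param comm a [community_model].
#' @param spec a [functionality_spec].
#' @param targets a [build_targets()] result.
#' @param params an [algo_params]; `milp_size`, `deletion_sequence` and
#'   `seed` are used.
#' @return a list of class `reduction_trace` with `trace` (data frame of
#'   species, action, reason), `sequence`, and `comm` (the reduced model).
#' @export
sequential_reduce <- function(comm, spec, targets, params) {
  stopifnot(inherits(params, "algo_params"))
  act0 <- comm$members[comm$active]
  seqn <- params$deletion_sequence
  if (is.null(seqn)) {
    seqn <- with_seed(params$seed, sample(act0))
  } else {
    seqn <- intersect(seqn, act0)
  }
  trace <- list()
  repeat {
    if (sum(comm$active) <= params$milp_size) break
    deleted_this_pass <- FALSE
    for (s in seqn) {
      if (sum(comm$active) <= params$milp_size) break
      if (!comm$active[[s]]) next
      if (sum(comm$active) == 1L) break
      comm2 <- delete_species(comm, s)
      if (check_reduced_feasible(comm2, spec, targets)) {
        comm <- comm2
        deleted_this_pass <- TRUE
        trace[[length(trace) + 1L]] <-
          data.frame(species = s, action = "deleted",
                     reason = "targets met without it")
      } else {
        trace[[length(trace) + 1L]] <-
          data.frame(species = s, action = "kept",
                     reason = "deletion violates targets")
      }
    }
    if (!deleted_this_pass) break
  }
  structure(list(trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(species = character(), action = character(),
                              reason = character()),
                 sequence = seqn,
                 final_active = comm$members[comm$active],
                 comm = comm),
            class = "reduction_trace")
}

#' @export
print.reduction_trace <- function(x, ...) {
  ndel <- sum(x$trace$action == "deleted")
  cat("<reduction_trace> ", ndel, " deletions; final community: ",
      paste(x$final_active, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# MILP over the active members: binary X_k per member, all member fluxes
# gated by X_k (gate = "all") or only the biomass bounds (gate =
# "coupling_only", the literal printed formulation, which lets an excluded
# member leak up to the coupling threshold u through each reaction).
build_membership_milp <- function(comm, spec, targets,
                                  gate = c("all", "coupling_only"),
                                  cuts = list()) {
  gate <- match.arg(gate)
  act <- comm$members[comm$active]
  xvars <- paste0("X_", act)
  rvars <- colnames(comm$S)
  nv <- length(rvars)
  base <- community_lp(comm, stats::setNames(numeric(0), character(0)),
                       sense = "min")
  A <- cbind(base$A, matrix(0, nrow(base$A), length(xvars)))
  colnames(A) <- c(rvars, xvars)
  row_sense <- base$row_sense
  rhs <- base$rhs

  add_row <- function(cols, vals, sense, b) {
    row <- numeric(ncol(A))
    row[match(cols, colnames(A))] <- vals
    A <<- rbind(A, row)
    row_sense <<- c(row_sense, sense)
    rhs <<- c(rhs, b)
  }

  for (k in seq_along(act)) {
    id <- act[k]
    xk <- xvars[k]
    rx <- if (gate == "all") member_reactions(comm, id) else comm$biomass[[id]]
    for (r in rx) {
      if (comm$ub[[r]] != 0)  # v_r <= ub_r * X_k
        add_row(c(r, xk), c(1, -comm$ub[[r]]), "L", 0)
      if (comm$lb[[r]] != 0)  # v_r >= lb_r * X_k
        add_row(c(r, xk), c(1, -comm$lb[[r]]), "G", 0)
    }
  }

  # functionality constraints
  w <- scfa_objective(comm, spec)
  scfa_thr <- targets$scfa_frac * targets$scfa_max
  if (length(w)) add_row(names(w), unname(w), "G", scfa_thr - THR_TOL)
  bio <- comm$biomass[act]
  if (targets$mode == "community") {
    add_row(bio, rep(1, length(bio)), "G",
            targets$gr_frac * targets$theta_total - THR_TOL)
  } else {
    for (k in seq_along(act)) {
      thr <- targets$gr_frac * targets$theta_k[[act[k]]]
      add_row(c(bio[k], xvars[k]), c(1, -thr), "G", -THR_TOL)
    }
  }
  for (cut in cuts) {  # integer cut: sum_{k in S} X_k <= |S| - 1
    xs <- paste0("X_", cut)
    add_row(xs, rep(1, length(xs)), "L", length(xs) - 1)
  }
  lp_problem(objective = stats::setNames(rep(1, length(xvars)), xvars),
             sense = "min", A = A, row_sense = row_sense, rhs = rhs,
             lb = c(comm$lb, stats::setNames(numeric(length(xvars)), xvars)),
             ub = c(comm$ub, stats::setNames(rep(1, length(xvars)), xvars)),
             vars = c(rvars, xvars), integers = xvars)
}

# wrap a MILP/LP solution into a minimal_microbiome record
as_minimal_microbiome <- function(comm, spec, members, fluxes, status,
                                  provenance = list()) {
  bio <- comm$biomass[members]
  w <- scfa_objective(comm, spec)
  scfa <- if (length(w) && !is.null(fluxes)) sum(w * fluxes[names(w)]) else 0
  per <- if (length(bio) && !is.null(fluxes))
    stats::setNames(unname(fluxes[bio]), members) else
      stats::setNames(numeric(0), character(0))
  structure(list(members = members,
                 growth = sum(per),
                 scfa_flux = scfa,
                 per_species_growth = per,
                 fluxes = if (is.null(fluxes)) NULL else
                   fluxes[colnames(comm$S)],
                 provenance = c(list(universe = comm$members, status = status),
                                provenance)),
            class = "minimal_microbiome")
}

#' @export
print.minimal_microbiome <- function(x, ...) {
  cat("<minimal_microbiome> ", length(x$members), " members: {",
      paste(x$members, collapse = ", "), "}; growth ",
      format(x$growth), " h^-1, SCFA ", format(x$scfa_flux),
      " mmol/gDW-h\n", sep = "")
  invisible(x)
}

#' Step 3b: minimal membership by MILP
#'
#' Minimises the number of retained species subject to community mass
#' balance, coupling, membership-gated flux bounds and the growth and SCFA
#' retention thresholds.  When both thresholds are zero the optimum is the
#' empty community, which is reported (with a warning) as the documented
#' degenerate convention.
#'
#' @param comm the (reduced) [community_model]; only active members enter as
#'   binaries.
#' @param spec a [functionality_spec].
#' @param targets a [build_targets()] result.
#' @param gate `"all"` (default; excluded members carry exactly zero flux) or
#'   `"coupling_only"` (only the biomass bounds are membership-gated).
#' @return a `minimal_microbiome`.
#' @export
minimize_membership <- function(comm, spec, targets,
                                gate = c("all", "coupling_only")) {
  gate <- match.arg(gate)
  p <- build_membership_milp(comm, spec, targets, gate = gate)
  r <- solve_milp(p)
  if (r$status != "optimal")
    stop("membership MILP ", r$status,
         ": no sub-community satisfies the functionality constraints")
  act <- comm$members[comm$active]
  members <- act[r$membership[paste0("X_", act)] > 0.5]
  if (!length(members))
    warning("both thresholds are zero: the empty community is optimal")
  as_minimal_microbiome(comm, spec, members, r$fluxes, r$status,
                        provenance = list(gate = gate,
                                          objective = r$objective_value))
}

#' Enumerate alternative minimal communities by integer cuts
#'
#' Re-solves the membership MILP, excluding each found support `S` with the
#' cut `sum_{k in S} X_k <= |S| - 1`, until `max_solutions` solutions are
#' found, the MILP goes infeasible, or (by default) the optimum's cardinality
#' exceeds the first optimum's.
#'
#' @inheritParams minimize_membership
#' @param max_solutions maximum number of supports to return.
#' @param same_cardinality_only stop when a larger support appears (default
#'   `TRUE`).
#' @return a list of `minimal_microbiome` objects.
#' @export
enumerate_minimal <- function(comm, spec, targets, max_solutions = 10L,
                              same_cardinality_only = TRUE,
                              gate = c("all", "coupling_only")) {
  gate <- match.arg(gate)
  stopifnot(max_solutions >= 1)
  act <- comm$members[comm$active]
  out <- list()
  cuts <- list()
  first_card <- NULL
  repeat {
    p <- build_membership_milp(comm, spec, targets, gate = gate, cuts = cuts)
    r <- solve_milp(p)
    if (r$status != "optimal") break
    members <- act[r$membership[paste0("X_", act)] > 0.5]
    if (is.null(first_card)) first_card <- length(members)
    if (same_cardinality_only && length(members) > first_card) break
    out[[length(out) + 1L]] <-
      as_minimal_microbiome(comm, spec, members, r$fluxes, r$status,
                            provenance = list(gate = gate, cut_index = length(cuts)))
    if (length(out) >= max_solutions) break
    if (!length(members)) break  # empty support: the only optimum
    cuts[[length(cuts) + 1L]] <- members
  }
  out
}

#' Maximum SCFA production of a fixed support
#'
#' Fixes the membership to `members` (all other members deleted) and
#' maximises the weighted SCFA sum subject to the growth and SCFA thresholds.
#'
#' @inheritParams minimize_membership
#' @param members character vector, a feasible support.
#' @return the maximum weighted SCFA flux (mmol/gDW-h).
#' @export
max_scfa_of_minimal <- function(comm, members, spec, targets) {
  act <- comm$members[comm$active]
  bad <- setdiff(members, act)
  if (length(bad)) stop("support contains inactive/unknown species: ",
                        paste(bad, collapse = ", "))
  if (!length(members)) stop("empty support")
  for (s in setdiff(act, members)) comm <- delete_species(comm, s)
  w <- scfa_objective(comm, spec)
  if (!length(w)) return(0)
  scfa_thr <- targets$scfa_frac * targets$scfa_max
  bio <- comm$biomass[members]
  scfa_row <- matrix(0, 1, ncol(comm$S), dimnames = list(NULL, colnames(comm$S)))
  scfa_row[1, names(w)] <- w
  if (targets$mode == "community") {
    grow_row <- matrix(0, 1, ncol(comm$S), dimnames = list(NULL, colnames(comm$S)))
    grow_row[1, bio] <- 1
    r <- solve_lp(community_lp(comm, w, sense = "max",
                               extra_A = rbind(grow_row, scfa_row),
                               extra_sense = c("G", "G"),
                               extra_rhs = c(targets$gr_frac * targets$theta_total - THR_TOL,
                                             scfa_thr - THR_TOL)))
  } else {
    lb <- growth_floored_bounds(comm, targets$theta_k, targets$gr_frac)
    r <- solve_lp(community_lp(comm, w, sense = "max", lb = lb,
                               extra_A = scfa_row, extra_sense = "G",
                               extra_rhs = scfa_thr - THR_TOL))
  }
  if (r$status != "optimal")
    stop("support {", paste(members, collapse = ", "),
         "} is infeasible at the targets")
  r$objective_value
}

#' Find minimal microbiomes: the full pipeline
#'
#' Builds the community, applies the diet and coupling, computes the growth
#' (joint FBA) and SCFA (constrained FVA) targets, then runs `iterations`
#' rounds of seeded sequential deletion followed by the membership MILP
#' (optionally with integer-cut enumeration), and returns the deduplicated
#' solutions.
#'
#' @param models list of [microbe_model] objects.
#' @param diet a [diet].
#' @param spec a [functionality_spec].
#' @param params an [algo_params].
#' @param coupling_c,coupling_u coupling constants (see [add_coupling()]).
#' @param diet_policy passed to [apply_diet()].
#' @param max_solutions per-iteration enumeration cap (1 = plain MILP).
#' @param gate membership gating mode, see [minimize_membership()].
#' @return an object of class `minimal_microbiome_set`.
#' @export
find_minimal_microbiomes <- function(models, diet, spec = functionality_spec(),
                                     params = algo_params(),
                                     coupling_c = 400, coupling_u = 0.01,
                                     diet_policy = "closed",
                                     max_solutions = 1L,
                                     gate = c("all", "coupling_only")) {
  gate <- match.arg(gate)
  comm <- build_community(models)
  comm <- apply_diet(comm, diet, policy = diet_policy)
  comm <- add_coupling(comm, c = coupling_c, u = coupling_u)

  fba <- joint_fba(comm)
  fva <- scfa_fva_max(comm, spec, fba$theta_k, params$gr_opt_frac)
  targets <- build_targets(fba$theta_k, fva$value, params)

  solutions <- list()
  seen <- character(0)
  for (it in seq_len(params$iterations)) {
    pit <- params
    pit$seed <- params$seed + it - 1L
    red <- sequential_reduce(comm, spec, targets, pit)
    sols <- if (max_solutions > 1L) {
      enumerate_minimal(red$comm, spec, targets,
                        max_solutions = max_solutions, gate = gate)
    } else {
      list(minimize_membership(red$comm, spec, targets, gate = gate))
    }
    for (s in sols) {
      key <- paste(sort(s$members), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      s$provenance$iteration <- it
      s$provenance$seed <- pit$seed
      s$provenance$deletion_sequence <- red$sequence
      s$provenance$trace <- red$trace
      solutions[[length(solutions) + 1L]] <- s
    }
  }
  structure(list(solutions = solutions, targets = targets, spec = spec,
                 params = params, growth = fba$growth, scfa_max = fva$value,
                 members = comm$members),
            class = "minimal_microbiome_set")
}

#' @export
print.minimal_microbiome_set <- function(x, ...) {
  cat("<minimal_microbiome_set> ", length(x$solutions),
      " distinct minimal communities from ", length(x$members),
      " species\n", sep = "")
  cat("  full community: growth ", format(x$growth), " h^-1, max SCFA ",
      format(x$scfa_max), " mmol/gDW-h\n", sep = "")
  for (i in seq_along(x$solutions)) {
    s <- x$solutions[[i]]
    cat(sprintf("  [%d] {%s}  growth %s, SCFA %s\n", i,
                paste(s$members, collapse = ", "),
                format(s$growth), format(s$scfa_flux)))
  }
  invisible(x)
}

#' @export
summary.minimal_microbiome_set <- function(object, ...) {
  sols <- object$solutions
  mat <- vapply(sols, function(s) as.integer(object$members %in% s$members),
                integer(length(object$members)))
  mat <- matrix(mat, nrow = length(object$members),
                dimnames = list(object$members,
                                paste0("sol", seq_along(sols))))
  out <- list(presence = mat,
              stats = data.frame(
                solution = paste0("sol", seq_along(sols)),
                size = vapply(sols, function(s) length(s$members), integer(1)),
                growth = vapply(sols, `[[`, numeric(1), "growth"),
                scfa_flux = vapply(sols, `[[`, numeric(1), "scfa_flux")),
              targets = object$targets)
  class(out) <- "summary.minimal_microbiome_set"
  out
}

#' @export
print.summary.minimal_microbiome_set <- function(x, ...) {
  print(x$targets)
  print(x$stats, row.names = FALSE)
  cat("\npresence/absence:\n")
  print(x$presence)
  invisible(x)
}
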