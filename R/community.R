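# Compartmentalised community model: each member keeps its own copy of its
# metabolites and reactions (suffixed "_org<k>", 1-based), member exchange
# reactions are rewired to move the exchanged metabolite between the member
# and a shared pool compartment ("[u]"), and one community-level exchange
# reaction per pooled metabolite connects the pool to the environment.  The
# pool mass-balance rows make the community exchange flux of every metabolite
# equal the sum of the member exchange fluxes.

pool_met_id <- function(met) {
  if (grepl("\\[[A-Za-z0-9]+\\]$", met)) return(sub("\\[[A-Za-z0-9]+\\]$", "[u]", met))
  if (grepl("\\([A-Za-z0-9]+\\)$", met)) return(sub("\\(([A-Za-z0-9]+)\\)$", "(u)", met))
  if (grepl("_[a-z]$", met)) return(sub("_[a-z]$", "_u", met))
  paste0(met, "[u]")
}

#' Build a community model from species models
#'
#' Merges the member models into one stoichiometric system.  Internal
#' metabolites and reactions are suffixed `"_org<k>"`; each member exchange
#' reaction becomes a transfer into a shared pool compartment; one community
#' exchange reaction per pooled metabolite carries the environment bounds
#' (the most permissive bounds over the members that exchange it).  Positive
#' exchange flux is secretion throughout.
#'
#' @param models a list of [microbe_model] objects with unique ids.
#' @return an object of class `community_model` with all members active.
#' @export
build_community <- function(models) {
  if (!length(models)) stop("need at least one model")
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate species ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  lapply(models, validate_microbe_model)
  n <- length(models)
  tags <- paste0("_org", seq_len(n))

  met_ids <- character(0)
  rxn_ids <- character(0)
  rxn_species <- integer(0)
  rxn_is_exchange <- logical(0)
  lb <- numeric(0); ub <- numeric(0)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  biomass <- character(n)
  pool_of <- character(0)        # pool met id per member-exchange column
  comm_exch_lb <- list(); comm_exch_ub <- list()  # pool met -> env bounds
  exch_src <- list()             # pool met -> untagged exchange rxn id

  for (k in seq_len(n)) {
    m <- models[[k]]
    mets <- rownames(m$S)
    rxns <- colnames(m$S)
    tmets <- paste0(mets, tags[k])
    moff <- length(met_ids)
    met_ids <- c(met_ids, tmets)
    exmet <- exchanged_metabolites(m)
    sm <- Matrix::summary(m$S)
    for (j in seq_along(rxns)) {
      r <- rxns[j]
      col_rows <- sm$i[sm$j == j]
      col_x <- sm$x[sm$j == j]
      jcol <- length(rxn_ids) + 1L
      rxn_ids <- c(rxn_ids, paste0(r, tags[k]))
      rxn_species <- c(rxn_species, k)
      is_ex <- r %in% m$exchange_rxns
      rxn_is_exchange <- c(rxn_is_exchange, is_ex)
      lb <- c(lb, unname(m$lb[r])); ub <- c(ub, unname(m$ub[r]))
      ii <- c(ii, moff + col_rows); jj <- c(jj, rep(jcol, length(col_rows)))
      xx <- c(xx, col_x)
      if (is_ex) {
        pm <- pool_met_id(exmet[[r]])
        pool_of <- c(pool_of, stats::setNames(pm, paste0(r, tags[k])))
        if (is.null(comm_exch_lb[[pm]])) {
          comm_exch_lb[[pm]] <- unname(m$lb[r])
          comm_exch_ub[[pm]] <- unname(m$ub[r])
          exch_src[[pm]] <- r
        } else {
          comm_exch_lb[[pm]] <- min(comm_exch_lb[[pm]], m$lb[r])
          comm_exch_ub[[pm]] <- max(comm_exch_ub[[pm]], m$ub[r])
        }
      }
      if (r == m$biomass_rxn) biomass[k] <- paste0(r, tags[k])
    }
  }

  pool_mets <- names(exch_src)
  moff <- length(met_ids)
  met_ids <- c(met_ids, pool_mets)
  # member exchange columns gain a +1 entry for their pool metabolite
  ex_cols <- which(rxn_is_exchange)
  ii <- c(ii, moff + match(pool_of[rxn_ids[ex_cols]], pool_mets))
  jj <- c(jj, ex_cols)
  xx <- c(xx, rep(1, length(ex_cols)))
  # community exchange reactions: pool -> environment, entry -1
  comm_rxns <- vapply(pool_mets, function(pm) exch_src[[pm]], character(1))
  if (anyDuplicated(comm_rxns))
    stop("inconsistent exchange naming: one exchange reaction id maps to ",
         "multiple pooled metabolites")
  for (q in seq_along(pool_mets)) {
    jcol <- length(rxn_ids) + 1L
    rxn_ids <- c(rxn_ids, comm_rxns[q])
    rxn_species <- c(rxn_species, 0L)
    rxn_is_exchange <- c(rxn_is_exchange, TRUE)
    lb <- c(lb, comm_exch_lb[[pool_mets[q]]])
    ub <- c(ub, comm_exch_ub[[pool_mets[q]]])
    ii <- c(ii, moff + q); jj <- c(jj, jcol); xx <- c(xx, -1)
  }

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  structure(list(
    members = ids,
    tag = stats::setNames(tags, ids),
    S = S,
    lb = stats::setNames(lb, rxn_ids),
    ub = stats::setNames(ub, rxn_ids),
    rxn_species = stats::setNames(rxn_species, rxn_ids),
    rxn_is_exchange = stats::setNames(rxn_is_exchange, rxn_ids),
    biomass = stats::setNames(biomass, ids),
    pool_mets = stats::setNames(pool_mets, comm_rxns),
    active = stats::setNames(rep(TRUE, n), ids),
    archived = list(),
    coupling = NULL), class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$members), " members (",
      sum(x$active), " active), ", nrow(x$S), " metabolites (",
      length(x$pool_mets), " pooled), ", ncol(x$S), " reactions",
      if (!is.null(x$coupling))
        sprintf(", coupled (c = %g, u = %g)", x$coupling$c, x$coupling$u),
      "\n", sep = "")
  invisible(x)
}

species_index <- function(comm, k) {
  if (is.character(k)) {
    idx <- match(k, comm$members)
    if (is.na(idx)) stop("unknown species: ", k)
    return(idx)
  }
  if (k < 1 || k > length(comm$members)) stop("species index out of range")
  as.integer(k)
}

member_reactions <- function(comm, k) {
  names(comm$rxn_species)[comm$rxn_species == species_index(comm, k)]
}

#' Add biomass coupling constraints
#'
#' Records, for every non-biomass reaction `j` of every member `k`, the pair
#' of rows `v_j - c v_bio_k <= u` and `-v_j - c v_bio_k <= u`, tying both
#' flux directions of a member's reactions to its growth so that a member
#' growing at zero rate cannot carry more than `u` flux.
#'
#' @param comm a [build_community] result.
#' @param c coupling coefficient (> 0, dimensionless; default 400, the
#'   convention for AGORA-style community models).
#' @param u coupling threshold (>= 0, mmol/gDW-h; default 0.01).
#' @param couple_exchanges couple the member pool-transfer reactions too
#'   (default `TRUE`); with `FALSE` only internal reactions are coupled.
#' @return the community with coupling recorded.
#' @export
add_coupling <- function(comm, c = 400, u = 0.01, couple_exchanges = TRUE) {
  stopifnot(inherits(comm, "community_model"))
  if (c <= 0) stop("coupling coefficient c must be > 0")
  if (u < 0) stop("coupling threshold u must be >= 0")
  keep <- comm$rxn_species > 0 & !(names(comm$rxn_species) %in% comm$biomass)
  if (!couple_exchanges) keep <- keep & !comm$rxn_is_exchange
  rows <- data.frame(rxn = names(comm$rxn_species)[keep],
                     species = unname(comm$rxn_species[keep]),
                     c = c, u = u, stringsAsFactors = FALSE)
  comm$coupling <- list(c = c, u = u, couple_exchanges = couple_exchanges,
                        rows = rows)
  comm
}

#' Delete a species from the community
#'
#' Deletion zeroes the lower and upper bounds of every reaction of the
#' member, including its biomass and pool transfers; the matrix shape is
#' unchanged and the previous bounds are archived so the deletion can be
#' undone with [restore_species()].
#'
#' @param comm a [community_model].
#' @param k species index (1-based) or id.
#' @return the community with member `k` inactive.
#' @export
delete_species <- function(comm, k) {
  k <- species_index(comm, k)
  id <- comm$members[k]
  if (!comm$active[[id]]) stop("species ", id, " is already deleted")
  if (sum(comm$active) == 1L)
    stop("community must retain at least one active member")
  rx <- member_reactions(comm, k)
  comm$archived[[id]] <- list(lb = comm$lb[rx], ub = comm$ub[rx])
  comm$lb[rx] <- 0
  comm$ub[rx] <- 0
  comm$active[[id]] <- FALSE
  comm
}

#' Restore a previously deleted species
#'
#' @param comm a [community_model].
#' @param k species index or id.
#' @return the community with member `k` active and its bounds restored.
#' @export
restore_species <- function(comm, k) {
  k <- species_index(comm, k)
  id <- comm$members[k]
  if (comm$active[[id]]) stop("species ", id, " is not deleted")
  a <- comm$archived[[id]]
  comm$lb[names(a$lb)] <- a$lb
  comm$ub[names(a$ub)] <- a$ub
  comm$archived[[id]] <- NULL
  comm$active[[id]] <- TRUE
  comm
}

#' Apply a diet to the community exchanges
#'
#' Sets the bounds of community exchange reactions listed in the diet.  Under
#' the default `"closed"` policy every community exchange *not* listed gets
#' lower bound 0 (nothing supplied by the environment; secretion unchanged);
#' under `"open"` unlisted exchanges keep their current bounds.  Non-exchange
#' bounds are never touched.  Diet entries naming exchanges absent from the
#' community produce a warning, not an error.
#'
#' @param comm a [community_model].
#' @param d a [diet].
#' @param policy `"closed"` (default) or `"open"`.
#' @return the updated community.
#' @export
apply_diet <- function(comm, d, policy = c("closed", "open")) {
  stopifnot(inherits(comm, "community_model"), inherits(d, "diet"))
  policy <- match.arg(policy)
  comm_ex <- names(comm$pool_mets)
  unknown <- setdiff(names(d$bounds), comm_ex)
  if (length(unknown))
    warning("diet entries not present in community: ",
            paste(unknown, collapse = ", "))
  if (policy == "closed") {
    closed <- setdiff(comm_ex, names(d$bounds))
    comm$lb[closed] <- pmin(0, comm$ub[closed])
  }
  for (id in intersect(names(d$bounds), comm_ex)) {
    comm$lb[[id]] <- d$bounds[[id]][1]
    comm$ub[[id]] <- d$bounds[[id]][2]
  }
  comm
}

# ---- LP assembly ----------------------------------------------------------

# Mass-balance (S v = 0) plus coupling rows for the current community state.
# `objective` is a named coefficient vector over reaction ids.
community_lp <- function(comm, objective, sense = "max",
                         extra_A = NULL, extra_sense = NULL, extra_rhs = NULL,
                         lb = comm$lb, ub = comm$ub) {
  A <- as.matrix(comm$S)
  row_sense <- rep("E", nrow(A))
  rhs <- numeric(nrow(A))
  if (!is.null(comm$coupling) && nrow(comm$coupling$rows)) {
    cp <- comm$coupling$rows
    nc <- nrow(cp)
    C <- matrix(0, 2L * nc, ncol(A), dimnames = list(NULL, colnames(A)))
    bio <- comm$biomass[cp$species]
    jr <- match(cp$rxn, colnames(A))
    jb <- match(bio, colnames(A))
    C[cbind(seq_len(nc), jr)] <- 1
    C[cbind(nc + seq_len(nc), jr)] <- -1
    # both rows share the -c * v_biomass term (accumulate: jr may equal jb never)
    C[cbind(seq_len(nc), jb)] <- C[cbind(seq_len(nc), jb)] - cp$c
    C[cbind(nc + seq_len(nc), jb)] <- C[cbind(nc + seq_len(nc), jb)] - cp$c
    A <- rbind(A, C)
    row_sense <- c(row_sense, rep("L", 2L * nc))
    rhs <- c(rhs, rep(cp$u, 2L))
  }
  if (!is.null(extra_A)) {
    A <- rbind(A, extra_A)
    row_sense <- c(row_sense, extra_sense)
    rhs <- c(rhs, extra_rhs)
  }
  lp_problem(objective = objective, sense = sense, A = A,
             row_sense = row_sense, rhs = rhs,
             lb = lb, ub = ub, vars = colnames(comm$S))
}
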