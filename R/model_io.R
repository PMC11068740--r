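#' Single-species metabolic model
#'
#' A minimal COBRA-style container: a sparse stoichiometric matrix
#' (metabolites x reactions), flux bounds in mmol/gDW-h, one biomass reaction
#' and the set of exchange reactions.  Exchange fluxes follow the standard
#' COBRA sign convention: positive flux = secretion, negative = uptake, i.e.
#' every exchange reaction has a single stoichiometric entry of -1 for the
#' exchanged extracellular metabolite.
#'
#' @param id species identifier.
#' @param S stoichiometric matrix with metabolite row names and reaction
#'   column names (coerced to a sparse `Matrix`).
#' @param lb,ub per-reaction flux bounds, recycled/named by reaction.
#' @param biomass_rxn id of the biomass reaction.
#' @param exchange_rxns character vector of exchange reaction ids.
#' @return an object of class `microbe_model`.
#' @export
microbe_model <- function(id, S, lb, ub, biomass_rxn, exchange_rxns) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  rxns <- colnames(S)
  if (is.null(rxns) || is.null(rownames(S)))
    stop("S must have metabolite row names and reaction column names")
  lb <- stats::setNames(rep_len(lb, length(rxns)), rxns)
  ub <- stats::setNames(rep_len(ub, length(rxns)), rxns)
  m <- structure(list(id = id, S = S, lb = lb, ub = ub,
                      biomass_rxn = biomass_rxn,
                      exchange_rxns = exchange_rxns),
                 class = "microbe_model")
  validate_microbe_model(m)
}

#' @export
print.microbe_model <- function(x, ...) {
  cat("<microbe_model> ", x$id, ": ", nrow(x$S), " metabolites, ",
      ncol(x$S), " reactions (", length(x$exchange_rxns),
      " exchanges), biomass = ", x$biomass_rxn, "\n", sep = "")
  invisible(x)
}

validate_microbe_model <- function(m) {
  rxns <- colnames(m$S)
  if (length(m$biomass_rxn) != 1L || !(m$biomass_rxn %in% rxns))
    stop("model ", m$id, ": biomass_rxn must name exactly one reaction in S")
  if (!all(m$exchange_rxns %in% rxns))
    stop("model ", m$id, ": unknown exchange reactions")
  if (any(m$lb > m$ub + 1e-12))
    stop("model ", m$id, ": lb > ub for some reaction")
  for (r in m$exchange_rxns) {
    col <- m$S[, r]
    nz <- which(col != 0)
    if (length(nz) != 1L || col[nz] != -1)
      stop("model ", m$id, ": exchange reaction ", r,
           " must have a single stoichiometric entry of -1 ",
           "(secretion-positive convention)")
  }
  m
}

#' Metabolites exchanged by each exchange reaction
#'
#' @param m a [microbe_model].
#' @return named character vector, exchange reaction id -> metabolite id.
#' @export
exchanged_metabolites <- function(m) {
  vapply(m$exchange_rxns,
         function(r) rownames(m$S)[which(m$S[, r] != 0)], character(1))
}

# compartment tag from a metabolite id: glc[e], glc(e), glc_e -> "e"
compartment_of <- function(met) {
  m <- regmatches(met, regexec("\\[([A-Za-z0-9]+)\\]$", met))[[1]]
  if (length(m) == 2) return(m[2])
  m <- regmatches(met, regexec("\\(([A-Za-z0-9]+)\\)$", met))[[1]]
  if (length(m) == 2) return(m[2])
  m <- regmatches(met, regexec("_([a-z])$", met))[[1]]
  if (length(m) == 2) return(m[2])
  "c"
}

# classify reactions once raw S/bounds are parsed (shared by JSON and SBML)
finalize_model <- function(id, S, lb, ub, biomass_pattern, exchange_prefix) {
  rxns <- colnames(S)
  cand <- rxns[grepl(biomass_pattern, rxns, ignore.case = TRUE)]
  if (length(cand) == 0L)
    stop("model ", id, ": no reaction matches biomass pattern '",
         biomass_pattern, "'")
  if (length(cand) > 1L)
    stop("model ", id, ": ambiguous biomass reaction, candidates: ",
         paste(cand, collapse = ", "))
  ex <- setdiff(rxns[startsWith(rxns, exchange_prefix)], cand)
  microbe_model(id, S, lb, ub, biomass_rxn = cand, exchange_rxns = ex)
}

#' Read a species model from COBRA JSON or SBML
#'
#' The biomass reaction is identified by a configurable regular expression
#' (default: any reaction id containing "biomass", case-insensitive; AGORA
#' reconstructions have exactly one) and exchange reactions by the id prefix
#' `"EX_"`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` (COBRA JSON) or `"sbml"`
#'   (SBML Level 3 with the fbc package).
#' @param biomass_pattern regular expression for the biomass reaction id.
#' @param exchange_prefix reaction-id prefix marking exchange reactions.
#' @return a [microbe_model].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       biomass_pattern = "biomass", exchange_prefix = "EX_") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  raw <- switch(format,
                json = read_model_json(path),
                sbml = read_model_sbml(path))
  finalize_model(raw$id, raw$S, raw$lb, raw$ub, biomass_pattern,
                 exchange_prefix)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("COBRA JSON parse failure in ",
                                           path, ": ", conditionMessage(e)))
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("COBRA JSON in ", path, " lacks 'reactions'/'metabolites'")
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxns <- vapply(doc$reactions, function(r) r$id, character(1))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    st <- r$metabolites
    if (length(st)) {
      idx <- match(names(st), mets)
      if (anyNA(idx)) stop("reaction ", r$id, " references unknown metabolite")
      ii <- c(ii, idx); jj <- c(jj, rep(j, length(idx)))
      xx <- c(xx, as.numeric(unlist(st)))
    }
    lb[j] <- if (!is.null(r$lower_bound)) r$lower_bound else -1000
    ub[j] <- if (!is.null(r$upper_bound)) r$upper_bound else 1000
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  list(id = if (!is.null(doc$id)) doc$id else sub("\\.json$", "", basename(path)),
       S = S, lb = lb, ub = ub)
}

#' Write a species model to COBRA JSON or SBML
#'
#' @param m a [microbe_model].
#' @param path output file.
#' @param format `"json"` or `"sbml"`.
#' @return invisibly, `path`.
#' @export
write_model <- function(m, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  switch(format, json = write_model_json(m, path),
         sbml = write_model_sbml(m, path))
  invisible(path)
}

write_model_json <- function(m, path) {
  mets <- rownames(m$S)
  doc <- list(
    id = m$id,
    metabolites = lapply(mets, function(x)
      list(id = x, compartment = compartment_of(x))),
    reactions = lapply(colnames(m$S), function(r) {
      col <- m$S[, r]
      nz <- which(col != 0)
      list(id = r,
           metabolites = as.list(stats::setNames(as.numeric(col[nz]), mets[nz])),
           lower_bound = unname(m$lb[r]), upper_bound = unname(m$ub[r]),
           objective_coefficient = if (r == m$biomass_rxn) 1 else 0)
    }),
    genes = list(),
    compartments = as.list(stats::setNames(
      unique(vapply(mets, compartment_of, character(1))),
      unique(vapply(mets, compartment_of, character(1)))))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- SBML L3 + fbc --------------------------------------------------------

# COBRA-style SId escaping: characters outside [A-Za-z0-9_] become __<code>__
sbml_escape <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- !grepl("[A-Za-z0-9_]", ch)
    ch[bad] <- vapply(ch[bad],
                      function(k) sprintf("__%d__", utf8ToInt(k)), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sbml_unescape <- function(x) {
  vapply(x, function(s) {
    while (grepl("__([0-9]+)__", s)) {
      m <- regmatches(s, regexpr("__([0-9]+)__", s))
      code <- as.integer(sub("__([0-9]+)__", "\\1", m))
      s <- sub("__([0-9]+)__", intToUtf8(code), s)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

write_model_sbml <- function(m, path) {
  mets <- rownames(m$S)
  rxns <- colnames(m$S)
  comps <- unique(vapply(mets, compartment_of, character(1)))
  bounds <- sort(unique(c(m$lb, m$ub)))
  bid <- function(v) sprintf("bnd_%d", match(v, bounds))
  esc_m <- stats::setNames(paste0("M_", sbml_escape(mets)), mets)
  esc_r <- stats::setNames(paste0("R_", sbml_escape(rxns)), rxns)

  xml_attr_line <- function(tag, attrs, close = TRUE) {
    paste0("<", tag, " ",
           paste(names(attrs), paste0('"', attrs, '"'), sep = "=", collapse = " "),
           if (close) "/>" else ">")
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('<model id="%s" fbc:strict="true">', sbml_escape(m$id)),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>', comps),
    "</listOfCompartments>",
    "<listOfSpecies>",
    vapply(mets, function(x) xml_attr_line("species", c(
      id = esc_m[[x]], compartment = compartment_of(x),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")), character(1)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="%s" value="%s" constant="true"/>',
            bid(bounds), format(bounds, digits = 17)),
    "</listOfParameters>",
    "<listOfReactions>",
    unlist(lapply(rxns, function(r) {
      col <- m$S[, r]
      nz <- which(col != 0)
      reac <- nz[col[nz] < 0]
      prod <- nz[col[nz] > 0]
      c(xml_attr_line("reaction", c(
          id = esc_r[[r]], reversible = tolower(m$lb[r] < 0), fast = "false",
          "fbc:lowerFluxBound" = bid(unname(m$lb[r])),
          "fbc:upperFluxBound" = bid(unname(m$ub[r]))), close = FALSE),
        if (length(reac)) c("<listOfReactants>",
          sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  esc_m[mets[reac]], format(-col[reac], digits = 17)),
          "</listOfReactants>"),
        if (length(prod)) c("<listOfProducts>",
          sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  esc_m[mets[prod]], format(col[prod], digits = 17)),
          "</listOfProducts>"),
        "</reaction>")
    })),
    "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc_r[[m$biomass_rxn]]),
    "</fbc:listOfFluxObjectives>",
    "</fbc:objective>",
    "</fbc:listOfObjectives>",
    "</model>",
    "</sbml>")
  writeLines(out, path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(model))) stop("SBML in ", path, " has no model node")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met_sid <- xml2::xml_attr(sp, "id")
  mets <- sbml_unescape(sub("^M_", "", met_sid))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_sid <- xml2::xml_attr(rx, "id")
  rxns <- sbml_unescape(sub("^R_", "", rxn_sid))
  nr <- length(rxns)
  lb <- numeric(nr); ub <- numeric(nr)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nr)) {
    node <- rx[[j]]
    lbp <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    ubp <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    if (is.na(lbp)) lbp <- xml2::xml_attr(node, "lowerFluxBound")
    if (is.na(ubp)) ubp <- xml2::xml_attr(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (identical(xml2::xml_attr(node, "reversible"), "true")) -1000 else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0("./s:", side, "/s:speciesReference"), ns)
      if (!length(refs)) next
      sid <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      if (side == "listOfReactants") st <- -st
      idx <- match(sid, met_sid)
      if (anyNA(idx)) stop("reaction ", rxns[j], " references unknown species")
      ii <- c(ii, idx); jj <- c(jj, rep(j, length(idx))); xx <- c(xx, st)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), nr),
                            dimnames = list(mets, rxns))
  id <- sbml_unescape(xml2::xml_attr(model, "id"))
  if (is.na(id)) id <- sub("\\.(xml|sbml)$", "", basename(path))
  list(id = id, S = S, lb = lb, ub = ub)
}

# ---- diets ----------------------------------------------------------------

#' Construct a diet
#'
#' A diet is a table of bounds on community exchange reactions.  Uptake is
#' encoded as a negative lower bound (e.g. acetate available at up to
#' 1 mmol/gDW-h means `lb = -1`).
#'
#' @param bounds named list or two-column matrix/data.frame of `(lb, ub)`
#'   keyed by community exchange-reaction id.
#' @param name diet label.
#' @return an object of class `diet`.
#' @export
diet <- function(bounds = list(), name = "diet") {
  if (is.matrix(bounds) || is.data.frame(bounds)) {
    ids <- rownames(bounds)
    bounds <- stats::setNames(
      lapply(seq_len(nrow(bounds)), function(i) as.numeric(bounds[i, 1:2])), ids)
  }
  for (id in names(bounds)) {
    b <- bounds[[id]]
    if (length(b) != 2 || b[1] > b[2])
      stop("diet entry ", id, ": need lb <= ub")
  }
  structure(list(bounds = bounds, name = name), class = "diet")
}

#' @export
print.diet <- function(x, ...) {
  cat("<diet> ", x$name, ": ", length(x$bounds), " exchange bounds\n", sep = "")
  invisible(x)
}

#' Load a diet table
#'
#' Reads a tab- or comma-separated table with columns `exchange_id`, `lb` and
#' optional `ub`.  A missing `ub` defaults to the open secretion bound.
#' Lines starting with `#` and an optional header row are skipped.
#'
#' @param path file path.
#' @param default_ub upper bound used when the `ub` column is absent or empty
#'   (default 1000 mmol/gDW-h, the COBRA open bound).
#' @return a [diet].
#' @export
load_diet <- function(path, default_ub = 1000) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep))
    return(diet(name = sub("\\.[^.]*$", "", basename(path))))
  sep <- if (grepl("\t", lines[keep[1]])) "\t" else ","
  bounds <- list()
  first <- TRUE
  for (i in keep) {
    f <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
    f <- f[nzchar(f) | seq_along(f) <= 3]
    if (first && length(f) >= 2 && is.na(suppressWarnings(as.numeric(f[2])))) {
      first <- FALSE  # header row
      next
    }
    first <- FALSE
    if (length(f) < 2) stop("diet parse error at line ", i,
                            ": need at least exchange_id and lb")
    lb <- suppressWarnings(as.numeric(f[2]))
    if (is.na(lb)) stop("diet parse error at line ", i, ": lb '", f[2],
                        "' is not numeric")
    ub <- if (length(f) >= 3 && nzchar(f[3])) suppressWarnings(as.numeric(f[3])) else default_ub
    if (is.na(ub)) stop("diet parse error at line ", i, ": ub '", f[3],
                        "' is not numeric")
    if (lb > ub) stop("diet validation error at line ", i, ": lb (", lb,
                      ") > ub (", ub, ") for ", f[1])
    bounds[[f[1]]] <- c(lb, ub)
  }
  diet(bounds, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a diet table
#'
#' @param d a [diet].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_diet <- function(d, path) {
  lines <- c("exchange_id\tlb\tub",
             vapply(names(d$bounds), function(id)
               sprintf("%s\t%s\t%s", id,
                       format(d$bounds[[id]][1], digits = 15),
                       format(d$bounds[[id]][2], digits = 15)),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

# ---- results --------------------------------------------------------------

#' Write minimal-community solutions
#'
#' Writes a presence/absence TSV matrix (rows = species, columns = solutions,
#' entries 0/1) plus a JSON sidecar (`<path>.json`) recording per-solution
#' growth, SCFA fluxes and provenance.  Solutions with identical membership
#' are written as identical columns under distinct solution ids.
#'
#' @param results a nonempty list of `minimal_microbiome` objects (or a
#'   `minimal_microbiome_set`).
#' @param path output TSV path.
#' @param species optional row ordering; defaults to the union of the
#'   solutions' species universes.
#' @return invisibly, `path`.
#' @export
write_result <- function(results, path, species = NULL) {
  if (inherits(results, "minimal_microbiome_set")) results <- results$solutions
  if (inherits(results, "minimal_microbiome")) results <- list(results)
  if (!length(results)) stop("empty result list")
  if (is.null(species)) {
    uni <- unlist(lapply(results, function(r) r$provenance$universe))
    species <- if (length(uni)) unique(uni) else
      unique(unlist(lapply(results, `[[`, "members")))
  }
  mat <- vapply(results, function(r) as.integer(species %in% r$members),
                integer(length(species)))
  mat <- matrix(mat, nrow = length(species),
                dimnames = list(species, paste0("sol", seq_along(results))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("species", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(c(species[i], mat[i, ]), collapse = "\t"), con)
  side <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    list(id = paste0("sol", i), members = as.list(r$members),
         growth = r$growth, scfa_flux = r$scfa_flux,
         per_species_growth = as.list(r$per_species_growth),
         provenance = r$provenance[setdiff(names(r$provenance), "universe")])
  })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
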