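# Model exchange (SBML), parameter/profile/config serialization and unit
# conversion.

#' Convert tissue contents to cellular concentrations
#'
#' Converts metabolite contents reported per gram wet weight into millimolar
#' concentrations: division by the cell-water fraction 0.46 mL/g and
#' correction for the liver density of 1.067 g/mL.
#'
#' @param value_umol_per_g Content in umol per g wet weight (>= 0; vectorized).
#' @return Concentration in mM.
#' @export
#' @examples
#' convert_tissue_units(0.46)  # 1.067 mM
convert_tissue_units <- function(value_umol_per_g) {
  if (any(value_umol_per_g < 0)) stop("tissue content must be >= 0")
  value_umol_per_g / 0.46 * 1.067
}

#' Write a parameter set to YAML or JSON
#'
#' @param params Parameter list as returned by [default_parameters()].
#' @param path Output path; format chosen by extension (.yaml/.yml or .json).
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- strip_classes(params)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(params, path)
  }
  invisible(path)
}

# Drop S3 classes (e.g. allosteric_term) and turn named atomic vectors into
# maps for serialization (yaml drops names of atomic vectors); restored by
# normalize_parameters() on read.
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    x <- as.list(x)
  }
  x
}

#' Read a parameter set from YAML or JSON
#'
#' @param path Parameter file written by [write_parameters()] (or hand-edited
#'   in the same schema).
#' @return Parameter list suitable for [build_network()].
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else yaml::read_yaml(path)
  normalize_parameters(raw)
}

# Restore numeric types and classes lost in serialization.
normalize_parameters <- function(raw) {
  raw$reactions <- lapply(raw$reactions, function(r) {
    r$stoich <- unlist(r$stoich)
    if (!is.null(r$law$allosteric))
      r$law$allosteric <- lapply(r$law$allosteric, function(a)
        structure(list(effector = a$effector, p = as.numeric(a$p),
                       h = as.numeric(a$h), mode = a$mode,
                       beta = if (is.null(a$beta)) NA_real_
                              else suppressWarnings(as.numeric(a$beta))),
                  class = "allosteric_term"))
    for (side in c("subs", "prods"))
      if (!is.null(r$law[[side]]))
        r$law[[side]] <- lapply(r$law[[side]], function(b) {
          b$K <- as.numeric(b$K)
          if (!is.null(b$h)) b$h <- as.numeric(b$h)
          b
        })
    if (!is.null(r$law$keq)) r$law$keq <- as.numeric(r$law$keq)
    r$law$vmax <- as.numeric(r$law$vmax)
    r
  })
  names(raw$reactions) <- vapply(raw$reactions, `[[`, character(1), "id")
  raw$capacity <- as.numeric(raw$capacity)
  raw$kappa <- as.numeric(raw$kappa)
  raw
}

#' Read / write a diurnal glucose profile CSV
#'
#' CSV dialect: two columns, \code{time_h} (hours) and \code{glucose_mM}.
#'
#' @param path File path.
#' @return data.frame with \code{time_h}, \code{glucose_mM}.
#' @export
read_glucose_profile <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "glucose_mM") %in% names(df)))
    stop("profile CSV needs columns time_h, glucose_mM")
  if (any(df$glucose_mM <= 0)) stop("profile contains nonpositive glucose")
  df
}

#' @rdname read_glucose_profile
#' @param profile data.frame with \code{time_h}, \code{glucose_mM}.
#' @export
write_glucose_profile <- function(profile, path) {
  utils::write.csv(profile[, c("time_h", "glucose_mM")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML/JSON)
#'
#' A run configuration bundles a physiological state, clamp settings, a
#' profile path or synthetic profile condition, ensemble size, seed and
#' tolerances.
#'
#' @param path Config file.
#' @return Validated list with class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg$state <- match.arg(cfg$state, physiological_states())
  if (!is.null(cfg$profile_path) && !file.exists(cfg$profile_path))
    stop("profile path does not exist: ", cfg$profile_path)
  if (!is.null(cfg$tol) && any(unlist(cfg$tol) <= 0))
    stop("tolerances must be positive")
  if (is.null(cfg$n_replicates)) cfg$n_replicates <- 1
  if (is.null(cfg$seed)) cfg$seed <- 1
  structure(cfg, class = "run_config")
}

# --------------------------------------------------------------------------
# SBML Level 3 Version 2 exchange.
#
# Species and reactions (ids, compartments, stoichiometry, clamp flags) are
# written as plain SBML; kinetic laws are written both as MathML generated
# from the rate-law templates and as a lossless JSON annotation that the
# importer uses to reconstruct the exact law objects. Foreign SBML without
# that annotation is reported (per reaction) rather than silently dropped.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
HFX_NS <- "https://hepatoflux.invalid/ratelaw"

sbml_sid <- function(id) paste0("M_", gsub("[^A-Za-z0-9_]", "_", id))

# Minimal MathML builders.
mml_cn <- function(x) sprintf("<cn> %.15g </cn>", x)
mml_ci <- function(s) sprintf("<ci> %s </ci>", s)
mml_op <- function(op, ...) {
  args <- unlist(list(...))
  paste0("<apply><", op, "/>", paste0(args, collapse = ""), "</apply>")
}

# MathML for one rate law (full expression including allosteric and store
# factors; gamma enters through a global parameter "gamma").
law_mathml <- function(law, capacity) {
  sat <- function(b) {   # s^h / (K^h + s^h)
    h <- if (is.null(b$h)) 1 else b$h
    s <- mml_ci(sbml_sid(b$id))
    sh <- if (h == 1) s else mml_op("power", s, mml_cn(h))
    mml_op("divide", sh, mml_op("plus", mml_cn(b$K^h), sh))
  }
  core <- switch(law$form,
    mm_irrev = Reduce(function(a, b) mml_op("times", a, b),
                      lapply(law$subs, sat)),
    mm_rev = {
      ps <- Reduce(function(a, b) mml_op("times", a, b),
                   lapply(law$subs, function(b) mml_ci(sbml_sid(b$id))))
      pp <- Reduce(function(a, b) mml_op("times", a, b),
                   lapply(law$prods, function(b) mml_ci(sbml_sid(b$id))))
      ks <- prod(vapply(law$subs, `[[`, numeric(1), "K"))
      den1 <- Reduce(function(a, b) mml_op("times", a, b),
                     lapply(law$subs, function(b)
                       mml_op("plus", mml_cn(1),
                              mml_op("divide", mml_ci(sbml_sid(b$id)),
                                     mml_cn(b$K)))))
      den2 <- Reduce(function(a, b) mml_op("times", a, b),
                     lapply(law$prods, function(b)
                       mml_op("plus", mml_cn(1),
                              mml_op("divide", mml_ci(sbml_sid(b$id)),
                                     mml_cn(b$K)))))
      mml_op("divide",
             mml_op("divide",
                    mml_op("minus", ps, mml_op("divide", pp, mml_cn(law$keq))),
                    mml_cn(ks)),
             mml_op("minus", mml_op("plus", den1, den2), mml_cn(1)))
    },
    carrier = {
      s <- mml_ci(sbml_sid(law$subs[[1]]$id))
      p <- mml_ci(sbml_sid(law$prods[[1]]$id))
      mml_op("divide", mml_op("minus", s, p),
             mml_op("plus", mml_cn(law$subs[[1]]$K), s, p))
    },
    antiport = {
      s1 <- mml_ci(sbml_sid(law$subs[[1]]$id)); s2 <- mml_ci(sbml_sid(law$subs[[2]]$id))
      p1 <- mml_ci(sbml_sid(law$prods[[1]]$id)); p2 <- mml_ci(sbml_sid(law$prods[[2]]$id))
      mml_op("divide",
             mml_op("minus", mml_op("times", s1, s2), mml_op("times", p1, p2)),
             mml_op("times",
                    mml_op("plus", mml_cn(law$subs[[1]]$K), s1, p1),
                    mml_op("plus", mml_cn(law$subs[[2]]$K), s2, p2)))
    })
  factors <- list(mml_ci("vmax"), core)
  if (!is.null(law$pair))
    factors <- c(factors, list(
      mml_op("plus",
             mml_op("times", mml_ci("gamma"), mml_cn(law$pair$phos)),
             mml_op("times",
                    mml_op("minus", mml_cn(1), mml_ci("gamma")),
                    mml_cn(law$pair$dephos)))))
  if (!is.null(law$allosteric))
    for (a in law$allosteric) {
      x <- mml_op("power",
                  mml_op("divide", mml_ci(sbml_sid(a$effector)), mml_cn(a$p)),
                  mml_cn(a$h))
      factors <- c(factors, list(
        if (a$mode == "activator")
          mml_op("divide",
                 mml_op("plus", mml_cn(1), mml_op("times", mml_cn(a$beta), x)),
                 mml_op("plus", mml_cn(1), x))
        else mml_op("divide", mml_cn(1), mml_op("plus", mml_cn(1), x))))
    }
  if (!is.null(law$store)) {
    fill <- mml_op("divide", mml_ci(sbml_sid("Glyc")), mml_cn(capacity))
    factors <- c(factors, list(
      if (law$store$type == "phosphorolysis")
        mml_op("divide", fill, mml_op("plus", fill, mml_cn(law$store$Kf)))
      else mml_op("minus", mml_cn(1), fill)))
  }
  expr <- Reduce(function(a, b) mml_op("times", a, b), factors)
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', expr, "</math>")
}

#' Export a network as SBML Level 3 Version 2
#'
#' Species (with compartments, initial concentrations, clamped species as
#' boundary species), reactions with stoichiometry and kinetic laws (MathML
#' generated from the rate-law templates, local parameter \code{vmax}), and a
#' lossless rate-law annotation used by [import_sbml()] for exact round-trips.
#'
#' @param network A [build_network()] object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_sbml <- function(network, path) {
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  sp_xml <- apply(network$species, 1, function(s) {
    sprintf(paste0('<species id="%s" name="%s" compartment="%s" ',
                   'initialConcentration="%s" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="%s" constant="%s"/>'),
            sbml_sid(s[["id"]]), esc(s[["id"]]), s[["compartment"]],
            format(as.numeric(s[["conc"]]), digits = 15),
            tolower(s[["clamped"]]), tolower(s[["clamped"]]))
  })
  comp_xml <- sprintf(
    '<compartment id="%s" spatialDimensions="3" size="1" constant="true"/>',
    c("cytosol", "mitochondrion", "ER", "external"))
  rxn_xml <- vapply(network$reactions, function(r) {
    if (is.null(r$law$vmax)) stop("incomplete rate law for ", r$id)
    neg <- r$stoich[r$stoich < 0]; pos <- r$stoich[r$stoich > 0]
    refs <- function(v) paste(sprintf(
      '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
      sbml_sid(names(v)), abs(v)), collapse = "")
    anno <- jsonlite::toJSON(strip_classes(r$law), auto_unbox = TRUE,
                             digits = NA, null = "null")
    sprintf(paste0(
      '<reaction id="R_%s" name="%s" reversible="%s">',
      '<annotation><hfx:ratelaw xmlns:hfx="%s">%s</hfx:ratelaw></annotation>',
      "<listOfReactants>%s</listOfReactants>",
      "<listOfProducts>%s</listOfProducts>",
      "<kineticLaw>%s<listOfLocalParameters>",
      '<localParameter id="vmax" value="%.15g"/>',
      "</listOfLocalParameters></kineticLaw></reaction>"),
      r$id, r$id, tolower(r$reversible), HFX_NS, esc(as.character(anno)),
      refs(neg), refs(pos), law_mathml(r$law, network$capacity), r$law$vmax)
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<sbml xmlns="%s" level="3" version="2">', SBML_NS),
    '<model id="hepatocyte_glucose_metabolism" name="hepatocyte glucose metabolism">',
    "<listOfCompartments>", paste(comp_xml, collapse = ""),
    "</listOfCompartments>",
    "<listOfSpecies>", paste(sp_xml, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="glycogen_capacity" value="%.15g" constant="true"/>',
            network$capacity),
    sprintf('<parameter id="tissue_to_mM" value="%.15g" constant="true"/>',
            network$kappa),
    '<parameter id="gamma" value="0.32" constant="false"/>',
    "</listOfParameters>",
    "<listOfReactions>", paste(rxn_xml, collapse = ""), "</listOfReactions>",
    "</model></sbml>")
  # parse before writing: guarantees well-formed output
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

#' Import a network from SBML
#'
#' Reads species, compartments, stoichiometry and clamp flags from SBML
#' (Level 2 or Level 3). Kinetic laws are reconstructed from the rate-law
#' annotation written by [export_sbml()]; reactions carrying kinetic laws in
#' any other vocabulary are reported by id and the import fails rather than
#' silently dropping them.
#'
#' @param path SBML file.
#' @return A [build_network()] object.
#' @export
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("invalid SBML: ", conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) stop("invalid SBML: no model element")

  strip <- function(id) sub("^M_", "", id)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) stop("invalid SBML: no species")
  species <- lapply(sp_nodes, function(n) {
    nm <- xml2::xml_attr(n, "name")
    id <- if (!is.na(nm)) nm else strip(xml2::xml_attr(n, "id"))
    list(id = id,
         compartment = xml2::xml_attr(n, "compartment"),
         conc = as.numeric(xml2::xml_attr(n, "initialConcentration")),
         clamped = identical(xml2::xml_attr(n, "boundaryCondition"), "true"))
  })
  id_of <- setNames(vapply(species, `[[`, character(1), "id"),
                    vapply(sp_nodes, function(n) xml2::xml_attr(n, "id"),
                           character(1)))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  unsupported <- character(0)
  reactions <- list()
  for (n in rx_nodes) {
    rid <- sub("^R_", "", xml2::xml_attr(n, "id"))
    anno <- xml2::xml_find_first(
      n, ".//*[local-name() = 'ratelaw']")
    if (inherits(anno, "xml_missing")) {
      unsupported <- c(unsupported, rid)
      next
    }
    law <- jsonlite::fromJSON(xml2::xml_text(anno), simplifyVector = FALSE)
    law <- normalize_parameters(list(reactions = list(list(
      id = rid, stoich = c(x = 1), law = law)), capacity = 1,
      kappa = 1))$reactions[[1]]$law
    stoich <- numeric(0)
    for (sr in xml2::xml_find_all(n, ".//s:listOfReactants/s:speciesReference", ns))
      stoich[id_of[[xml2::xml_attr(sr, "species")]]] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(n, ".//s:listOfProducts/s:speciesReference", ns))
      stoich[id_of[[xml2::xml_attr(sr, "species")]]] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    reactions[[rid]] <- list(
      id = rid, stoich = stoich,
      reversible = identical(xml2::xml_attr(n, "reversible"), "true"),
      law = law)
  }
  if (length(unsupported))
    stop("unsupported kinetic-law constructs in reactions: ",
         paste(unsupported, collapse = ", "),
         " (no hepatoflux rate-law annotation)")

  par_val <- function(id, default) {
    node <- xml2::xml_find_first(
      doc, sprintf(".//s:listOfParameters/s:parameter[@id='%s']", id), ns)
    if (inherits(node, "xml_missing")) default
    else as.numeric(xml2::xml_attr(node, "value"))
  }
  build_network(list(species = species, reactions = reactions,
                     capacity = par_val("glycogen_capacity", 900),
                     kappa = par_val("tissue_to_mM", TISSUE_TO_MM)))
}
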