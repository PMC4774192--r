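# The metabolic network container and its compiled rate evaluator.

#' Build the hepatocyte carbohydrate network
#'
#' Assembles the reaction network of hepatic glycolysis, gluconeogenesis and
#' glycogen turnover: 32 reactions (including the mitochondrial variants and
#' the ER glucose-6-phosphatase system), species with compartment assignments
#' and clamp flags, and fully parameterized rate laws.
#'
#' @param parameter_source \code{NULL} for the bundled default
#'   parameterization, a parameter list of the shape returned by
#'   [default_parameters()], or the path of a YAML/JSON parameter file written
#'   by [write_parameters()].
#' @return An object of class \code{metabolic_network}: a list with
#'   \code{species} (data.frame: id, compartment, conc, clamped),
#'   \code{reactions} (named list), \code{S} (stoichiometric matrix, species x
#'   reactions), \code{capacity} (glycogen storage capacity, mM glucosyl
#'   units), \code{kappa} (umol/g to mM conversion) and \code{freeze}
#'   (\code{NULL}, or a regulation-mode freeze, see [freeze_mode()]).
#' @export
#' @examples
#' net <- build_network()
#' length(net$reactions)            # 32
#' sum(!net$species$clamped)        # dynamic species
build_network <- function(parameter_source = NULL) {
  pars <- if (is.null(parameter_source)) {
    default_parameters()
  } else if (is.character(parameter_source)) {
    read_parameters(parameter_source)
  } else if (is.list(parameter_source)) {
    parameter_source
  } else stop("parameter_source must be NULL, a list, or a file path")

  species <- do.call(rbind, lapply(pars$species, function(s)
    data.frame(id = s$id, compartment = s$compartment, conc = s$conc,
               clamped = isTRUE(s$clamped), stringsAsFactors = FALSE)))
  if (anyDuplicated(species$id)) stop("duplicate species ids")
  if (any(species$conc < 0)) stop("negative default concentration")
  ok <- species$compartment %in% c("cytosol", "mitochondrion", "ER", "external")
  if (!all(ok)) stop("unknown compartment for: ",
                     paste(species$id[!ok], collapse = ", "))

  reactions <- pars$reactions
  ids <- species$id
  S <- matrix(0, nrow = length(ids), ncol = length(reactions),
              dimnames = list(ids, names(reactions)))
  for (r in reactions) {
    law <- r$law
    if (is.null(law$vmax) || !is.numeric(law$vmax))
      stop("missing rate-law parameter (vmax) for reaction ", r$id)
    if (law$form %in% c("mm_rev") && is.null(law$keq))
      stop("missing rate-law parameter (keq) for reaction ", r$id)
    refs <- unique(c(names(r$stoich),
                     vapply(law$subs, `[[`, character(1), "id"),
                     vapply(law$prods, `[[`, character(1), "id"),
                     if (!is.null(law$allosteric))
                       vapply(law$allosteric, `[[`, character(1), "effector")))
    missing <- setdiff(refs, ids)
    if (length(missing))
      stop("reaction ", r$id, " references unknown species: ",
           paste(missing, collapse = ", "))
    S[names(r$stoich), r$id] <- r$stoich
  }

  net <- structure(list(species = species, reactions = reactions, S = S,
                        capacity = pars$capacity, kappa = pars$kappa,
                        freeze = NULL),
                   class = "metabolic_network")
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$species), "species (",
      sum(!x$species$clamped), "dynamic ),", length(x$reactions),
      "reactions\n")
  if (!is.null(x$freeze))
    cat("  frozen regulation mode(s):", paste(x$freeze$mode, collapse = ", "),
        "\n")
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param network A [build_network()] object.
#' @param dynamic_only Restrict rows to the dynamic (non-clamped) species.
#' @return Numeric matrix, species x reactions.
#' @export
stoichiometric_matrix <- function(network, dynamic_only = FALSE) {
  if (dynamic_only) network$S[!network$species$clamped, , drop = FALSE]
  else network$S
}

#' Default concentration vector of a network
#'
#' @param network A [build_network()] object.
#' @return Named numeric vector over all species (mM).
#' @export
species_concentrations <- function(network)
  setNames(network$species$conc, network$species$id)

# ---------------------------------------------------------------------------
# Compiled evaluator: per-reaction closures over integer indices, for speed in
# the ODE right-hand side. Honors an allosteric freeze baked in at compile
# time. Returns list(rates = function(cc) core rates, vmax, phos, dephos).
compile_network <- function(network) {
  ids <- network$species$id
  capacity <- network$capacity
  glyc_i <- match("Glyc", ids)
  frozen_allo <- if (!is.null(network$freeze) &&
                     "allosteric" %in% network$freeze$mode)
    network$freeze$allo_ref else NULL

  cores <- lapply(network$reactions, function(r) {
    law <- r$law
    si <- vapply(law$subs, function(s) match(s$id, ids), integer(1))
    pi <- vapply(law$prods, function(p) match(p$id, ids), integer(1))
    sK <- vapply(law$subs, `[[`, numeric(1), "K")
    pK <- if (length(law$prods)) vapply(law$prods, `[[`, numeric(1), "K") else numeric(0)
    sH <- vapply(law$subs, function(s) if (is.null(s$h)) 1 else s$h, numeric(1))
    keq <- law$keq
    prodK <- prod(sK)
    allo <- law$allosteric
    ai <- if (!is.null(allo))
      vapply(allo, function(a) match(a$effector, ids), integer(1)) else integer(0)
    allo_const <- if (!is.null(frozen_allo)) frozen_allo[[r$id]] else NULL
    store <- law$store
    form <- law$form

    function(cc) {
      v <- switch(form,
        mm_irrev = {
          x <- cc[si]
          prod(x^sH / (sK^sH + x^sH))
        },
        mm_rev = {
          s <- cc[si]; p <- cc[pi]
          ((prod(s) - prod(p) / keq) / prodK) /
            (prod(1 + s / sK) + prod(1 + p / pK) - 1)
        },
        carrier = {
          s <- cc[si[1L]]; p <- cc[pi[1L]]
          (s - p) / (sK[1L] + s + p)
        },
        antiport = {
          s1 <- cc[si[1L]]; s2 <- cc[si[2L]]
          p1 <- cc[pi[1L]]; p2 <- cc[pi[2L]]
          (s1 * s2 - p1 * p2) / ((sK[1L] + s1 + p1) * (sK[2L] + s2 + p2))
        })
      if (length(ai)) {
        if (!is.null(allo_const)) v <- v * allo_const
        else for (k in seq_along(ai)) {
          a <- allo[[k]]
          x <- (cc[ai[k]] / a$p)^a$h
          v <- v * if (a$mode == "activator") (1 + a$beta * x) / (1 + x)
                   else 1 / (1 + x)
        }
      }
      if (!is.null(store)) {
        fill <- cc[glyc_i] / capacity
        if (fill < 0) fill <- 0 else if (fill > 1) fill <- 1
        v <- v * if (store$type == "phosphorolysis") fill / (fill + store$Kf)
                 else 1 - fill
      }
      v
    }
  })

  vmax <- vapply(network$reactions, function(r) r$law$vmax, numeric(1))
  phos <- vapply(network$reactions, function(r)
    if (is.null(r$law$pair)) 1 else r$law$pair$phos, numeric(1))
  dephos <- vapply(network$reactions, function(r)
    if (is.null(r$law$pair)) 1 else r$law$pair$dephos, numeric(1))

  n <- length(cores)
  rates <- function(cc) {
    v <- numeric(n)
    for (j in seq_len(n)) v[j] <- cores[[j]](cc)
    v
  }
  list(rates = rates, vmax = vmax, phos = phos, dephos = dephos,
       ids = names(network$reactions))
}

#' Reaction rates of the whole network at a metabolic state
#'
#' @param network A [build_network()] object.
#' @param conc Named concentration vector over all species (mM); defaults to
#'   the network's default concentrations.
#' @param gamma Phosphorylated enzyme fraction in [0, 1] (respecting a
#'   phosphorylation freeze if present).
#' @param alpha Named abundance scaling vector over reactions (default all 1);
#'   see [alpha_vector()].
#' @return Named vector of reaction rates (umol/g/h).
#' @export
network_rates <- function(network, conc = species_concentrations(network),
                          gamma = 0, alpha = NULL) {
  if (any(conc < 0)) stop("negative concentration")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (!is.null(network$freeze)) {
    if ("phosphorylation" %in% network$freeze$mode)
      gamma <- network$freeze$gamma_ref
    if ("abundance" %in% network$freeze$mode)
      alpha <- network$freeze$alpha_ref
  }
  comp <- compile_network(network)
  a <- rep(1, length(comp$ids))
  if (!is.null(alpha)) a <- alpha[comp$ids]
  cc <- conc[network$species$id]
  w <- gamma * comp$phos + (1 - gamma) * comp$dephos
  setNames(comp$vmax * a * w * comp$rates(cc), comp$ids)
}
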