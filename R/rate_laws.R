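# Rate-law vocabulary
#
# Every reaction carries a `law` list:
#   form        "mm_rev" | "mm_irrev" | "carrier" | "antiport"
#   vmax        reference (fed-state) maximal rate, umol/g/h
#   subs/prods  lists of list(id, K [, h]) binding terms (clamped cofactors
#               appear here like any other species)
#   keq         equilibrium constant for reversible forms (concentration units)
#   allosteric  list of allosteric_term()
#   pair        NULL, or list(phos =, dephos =): relative activities of the
#               phosphorylated / dephosphorylated enzyme forms; the overall
#               rate is gamma * v_phos + (1 - gamma) * v_dephos
#   store       NULL, or list(type = "phosphorolysis"|"synthesis", Kf =):
#               saturation of the glycogen store (filling state in [0, 1])

#' Construct an allosteric term
#'
#' An allosteric term multiplies a rate law by a positive saturation factor
#' that depends on the effector concentration E only through X = E / p, where
#' p is the binding constant:
#' activators give (1 + beta * X^h) / (1 + X^h) (rising from 1 to beta),
#' inhibitors give 1 / (1 + X^h) (falling from 1 to 0).
#'
#' @param effector Species id of the effector.
#' @param p Binding constant (mM), > 0.
#' @param h Hill exponent.
#' @param mode "activator" or "inhibitor".
#' @param beta Saturating fold-activation (activators only, > 1).
#' @return A list of class "allosteric_term".
#' @export
allosteric_term <- function(effector, p, h = 1,
                            mode = c("activator", "inhibitor"), beta = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || p <= 0) stop("binding constant p must be > 0")
  if (mode == "activator") {
    if (is.null(beta) || beta <= 1) stop("activator needs beta > 1")
  } else beta <- NA_real_
  structure(list(effector = effector, p = p, h = h, mode = mode, beta = beta),
            class = "allosteric_term")
}

#' Evaluate an allosteric saturation factor
#'
#' @param term An [allosteric_term()].
#' @param effector_conc Effector concentration (mM), >= 0.
#' @return Positive multiplicative factor.
#' @export
#' @examples
#' tm <- allosteric_term("Fru26P2", p = 0.005, h = 2, mode = "activator", beta = 20)
#' allosteric_factor(tm, 0)      # 1: empty-site limit
#' allosteric_factor(tm, 0.01)
allosteric_factor <- function(term, effector_conc) {
  if (any(effector_conc < 0)) stop("effector concentration must be >= 0")
  if (term$p <= 0) stop("binding constant p must be > 0")
  x <- (effector_conc / term$p)^term$h
  if (term$mode == "activator") (1 + term$beta * x) / (1 + x) else 1 / (1 + x)
}

# Core (vmax-free) rate of a law at a named concentration vector.
# Returns the saturation/driving part; multiply by vmax (x alpha x pair weight).
law_core <- function(law, conc, capacity = NULL, allo_override = NULL) {
  v <- switch(law$form,
    mm_irrev = {
      f <- 1
      for (s in law$subs) {
        x <- conc[[s$id]]
        h <- if (is.null(s$h)) 1 else s$h
        f <- f * x^h / (s$K^h + x^h)
      }
      f
    },
    mm_rev = {
      num_s <- 1; num_p <- 1; den_s <- 1; den_p <- 1
      for (s in law$subs) {
        x <- conc[[s$id]]
        num_s <- num_s * x
        den_s <- den_s * (1 + x / s$K)
      }
      ks <- prod(vapply(law$subs, function(s) s$K, numeric(1)))
      for (p in law$prods) {
        x <- conc[[p$id]]
        num_p <- num_p * x
        den_p <- den_p * (1 + x / p$K)
      }
      ((num_s - num_p / law$keq) / ks) / (den_s + den_p - 1)
    },
    carrier = {
      s <- conc[[law$subs[[1]]$id]]
      p <- conc[[law$prods[[1]]$id]]
      (s - p) / (law$subs[[1]]$K + s + p)
    },
    antiport = {
      s1 <- conc[[law$subs[[1]]$id]]   # counter-species side A (in)
      s2 <- conc[[law$subs[[2]]$id]]   # co-species side B (in)
      p1 <- conc[[law$prods[[1]]$id]]  # species A (out)
      p2 <- conc[[law$prods[[2]]$id]]  # species B (out)
      (s1 * s2 - p1 * p2) /
        ((law$subs[[1]]$K + s1 + p1) * (law$subs[[2]]$K + s2 + p2))
    },
    stop("unknown rate-law form: ", law$form)
  )
  if (!is.null(law$allosteric) && length(law$allosteric)) {
    if (!is.null(allo_override)) {
      v <- v * allo_override
    } else {
      for (tm in law$allosteric) v <- v * allosteric_factor(tm, conc[[tm$effector]])
    }
  }
  if (!is.null(law$store)) {
    fill <- conc[["Glyc"]] / capacity
    fill <- min(max(fill, 0), 1)
    v <- v * switch(law$store$type,
                    phosphorolysis = fill / (fill + law$store$Kf),
                    synthesis      = 1 - fill,
                    stop("unknown store type"))
  }
  v
}

#' Rate of a single reaction at a given metabolic state
#'
#' For enzymes regulated by reversible phosphorylation the overall rate is the
#' weighted linear combination \code{gamma * v_phos + (1 - gamma) * v_dephos}
#' of the rates of the phosphorylated and dephosphorylated enzyme forms; for
#' all other reactions \code{gamma} is ignored.
#'
#' @param reaction A reaction of a [build_network()] object.
#' @param conc Named concentration vector (mM) covering every species the rate
#'   law references (clamped cofactors included).
#' @param gamma Phosphorylated fraction in [0, 1].
#' @param alpha Abundance scaling factor (default 1 = fed reference).
#' @param capacity Glycogen storage capacity (mM glucosyl units); required for
#'   the glycogen store reactions.
#' @return Reaction rate in umol/g/h (signed by the written direction).
#' @export
reaction_rate <- function(reaction, conc, gamma = 0, alpha = 1,
                          capacity = NULL) {
  if (any(conc < 0)) stop("negative concentration in rate evaluation")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]")
  law <- reaction$law
  w <- if (is.null(law$pair)) 1 else gamma * law$pair$phos + (1 - gamma) * law$pair$dephos
  alpha * law$vmax * w * law_core(law, as.list(conc), capacity = capacity)
}

# Enumerate the kinetic parameters of one reaction for elasticity analysis.
# Returns a data.frame: name, category, value.
enumerate_parameters <- function(reaction) {
  law <- reaction$law
  out <- data.frame(name = "vmax", category = "abundance", value = law$vmax,
                    stringsAsFactors = FALSE)
  for (i in seq_along(law$subs))
    out <- rbind(out, data.frame(name = paste0("K_", law$subs[[i]]$id),
                                 category = "reactant", value = law$subs[[i]]$K))
  for (i in seq_along(law$prods))
    out <- rbind(out, data.frame(name = paste0("K_", law$prods[[i]]$id),
                                 category = "reactant", value = law$prods[[i]]$K))
  if (!is.null(law$allosteric))
    for (i in seq_along(law$allosteric))
      out <- rbind(out, data.frame(
        name = paste0("p_", law$allosteric[[i]]$effector),
        category = "allosteric", value = law$allosteric[[i]]$p))
  if (!is.null(law$pair))
    out <- rbind(out, data.frame(name = "gamma", category = "gamma", value = NA_real_))
  out
}

# Apply a relative bump to one named parameter of a reaction (helper for
# elasticity finite differences). Returns the modified reaction.
bump_parameter <- function(reaction, name, factor) {
  law <- reaction$law
  if (name == "vmax") {
    law$vmax <- law$vmax * factor
  } else if (startsWith(name, "K_")) {
    id <- sub("^K_", "", name)
    done <- FALSE
    for (i in seq_along(law$subs)) if (law$subs[[i]]$id == id && !done) {
      law$subs[[i]]$K <- law$subs[[i]]$K * factor; done <- TRUE
    }
    if (!done) for (i in seq_along(law$prods)) if (law$prods[[i]]$id == id && !done) {
      law$prods[[i]]$K <- law$prods[[i]]$K * factor; done <- TRUE
    }
    if (!done) stop("no binding constant named ", name)
  } else if (startsWith(name, "p_")) {
    id <- sub("^p_", "", name)
    done <- FALSE
    for (i in seq_along(law$allosteric))
      if (law$allosteric[[i]]$effector == id && !done) {
        law$allosteric[[i]]$p <- law$allosteric[[i]]$p * factor; done <- TRUE
      }
    if (!done) stop("no allosteric constant named ", name)
  } else stop("unknown parameter ", name)
  reaction$law <- law
  reaction
}
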