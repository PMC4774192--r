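# Metabolic control analysis: flux control coefficients of the glucose
# exchange flux, pi- and epsilon-elasticities, response coefficients, and
# time-resolved control along diurnal trajectories.

# Descriptor used to assert that two tables were computed at the same state.
state_descriptor <- function(state, clamps)
  sprintf("%s|glc=%g|lac=%g|glyc=%s", state, clamps$glucose, clamps$lactate,
          if (is.null(clamps$glycogen)) "free" else format(clamps$glycogen))

#' Flux control coefficients of the glucose exchange flux
#'
#' The control coefficient of reaction i is the relative change of the
#' stationary glucose exchange flux per relative change of the amount of the
#' catalyzing enzyme. Computed by finite differences: each enzyme amount is
#' varied by \code{perturbation} (default 5 \%), the perturbed system is
#' re-solved to steady state, and C_i = (dv_ex / v_ex) / (dE / E). By the
#' summation theorem the coefficients add up to 1.
#'
#' Coefficients diverge by definition where the exchange flux is zero; a
#' reference state with |v_ex| below \code{floor} is rejected.
#'
#' @param network A [build_network()] object.
#' @param state Physiological state.
#' @param clamps A [clamp_set()]; the canonical states clamp the glycogen
#'   store (low in the fasted, high in the fed state).
#' @param perturbation Relative enzyme-amount perturbation (default 0.05).
#' @param floor Minimal |v_ex| (umol/g/h) at which coefficients are reported.
#' @param scheme "central" (default; the 5 \% variation is applied in both
#'   directions, cancelling the leading finite-difference bias) or "forward".
#' @return Object of class \code{control_table}: data.frame (\code{reaction},
#'   \code{C}), with attributes \code{v_ex}, \code{sum}, \code{perturbation},
#'   \code{descriptor}.
#' @export
#' @examples
#' \donttest{
#' net <- build_network()
#' ct <- control_coefficients(net, "fasted",
#'                            clamp_set(glucose = 4, glycogen = 0.1))
#' attr(ct, "sum")   # ~1 (summation theorem)
#' }
control_coefficients <- function(network, state, clamps,
                                 perturbation = 0.05, floor = 1,
                                 scheme = c("central", "forward")) {
  scheme <- match.arg(scheme)
  ref <- steady_state(network, state, clamps)
  if (abs(ref$v_ex) < floor)
    stop("reference |v_ex| = ", signif(abs(ref$v_ex), 3),
         " umol/g/h is below the divergence floor (", floor,
         "): control coefficients diverge near the set point")
  base_alpha <- ref$alpha
  ids <- names(network$reactions)
  C <- setNames(rep(NA_real_, length(ids)), ids)
  solve_at <- function(a) tryCatch(
    steady_state(network, state, clamps, alpha = a, conc0 = ref$conc),
    error = function(e) NULL)
  for (id in ids) {
    up <- base_alpha; up[id] <- up[id] * (1 + perturbation)
    ss_up <- solve_at(up)
    if (scheme == "central") {
      dn <- base_alpha; dn[id] <- dn[id] * (1 - perturbation)
      ss_dn <- solve_at(dn)
      if (!is.null(ss_up) && !is.null(ss_dn)) {
        C[id] <- ((ss_up$v_ex - ss_dn$v_ex) / ref$v_ex) / (2 * perturbation)
      } else if (!is.null(ss_up)) {
        # one-sided fallback where the downward system sits past a stability
        # boundary and cannot be solved
        C[id] <- ((ss_up$v_ex - ref$v_ex) / ref$v_ex) / perturbation
      } else if (!is.null(ss_dn)) {
        C[id] <- ((ref$v_ex - ss_dn$v_ex) / ref$v_ex) / perturbation
      }
    } else if (!is.null(ss_up)) {
      C[id] <- ((ss_up$v_ex - ref$v_ex) / ref$v_ex) / perturbation
    }
  }
  out <- data.frame(reaction = ids, C = unname(C), stringsAsFactors = FALSE)
  structure(out, class = c("control_table", "data.frame"),
            v_ex = ref$v_ex, sum = sum(C, na.rm = TRUE),
            perturbation = perturbation,
            descriptor = state_descriptor(state, clamps))
}

#' pi-elasticity of an isolated rate law with respect to one parameter
#'
#' pi_ik = (p_k / v_i) * dv_i/dp_k, evaluated by central finite differences on
#' the isolated rate law at a fixed local state (all concentrations and the
#' phosphorylation fraction gamma held constant). By construction the
#' elasticity with respect to the enzyme's abundance (Vmax) is exactly 1, and
#' for a binding constant p_k entering only through X_k = E_k/p_k it equals
#' minus the common elasticity with respect to the effector concentration.
#'
#' @param network A [build_network()] object.
#' @param reaction Reaction id.
#' @param parameter Parameter name as listed by the \code{parameters} element
#'   of [elasticity_table()]: "vmax", "K_<species>", "p_<effector>", "gamma".
#' @param conc Named concentration vector of the local state.
#' @param gamma Phosphorylation fraction of the local state.
#' @param alpha Abundance factor of the local state.
#' @param rel_step Relative step of the central difference.
#' @return The scalar pi-elasticity.
#' @export
pi_elasticity <- function(network, reaction, parameter, conc, gamma = 0.32,
                          alpha = 1, rel_step = 1e-4) {
  rxn <- network$reactions[[reaction]]
  if (is.null(rxn)) stop("unknown reaction ", reaction)
  v0 <- reaction_rate(rxn, conc, gamma, alpha, network$capacity)
  if (abs(v0) < .Machine$double.eps^0.5)
    stop("rate of ", reaction, " is zero at the local state: ",
         "pi-elasticity undefined")
  if (parameter == "gamma") {
    h <- rel_step
    vp <- reaction_rate(rxn, conc, min(gamma * (1 + h), 1), alpha, network$capacity)
    vm <- reaction_rate(rxn, conc, gamma * (1 - h), alpha, network$capacity)
    return((gamma / v0) * (vp - vm) / (gamma * 2 * h))
  }
  vp <- reaction_rate(bump_parameter(rxn, parameter, 1 + rel_step), conc,
                      gamma, alpha, network$capacity)
  vm <- reaction_rate(bump_parameter(rxn, parameter, 1 - rel_step), conc,
                      gamma, alpha, network$capacity)
  (vp - vm) / (2 * rel_step * v0)
}

#' Common (concentration) elasticity of an isolated rate law
#'
#' epsilon_ik = (E_k / v_i) * dv_i/dE_k for an effector/reactant
#' concentration E_k, by central differences at the local state.
#'
#' @inheritParams pi_elasticity
#' @param species Species id whose concentration is varied.
#' @return The scalar elasticity.
#' @export
epsilon_elasticity <- function(network, reaction, species, conc, gamma = 0.32,
                               alpha = 1, rel_step = 1e-4) {
  rxn <- network$reactions[[reaction]]
  v0 <- reaction_rate(rxn, conc, gamma, alpha, network$capacity)
  if (abs(v0) < .Machine$double.eps^0.5)
    stop("rate is zero at the local state")
  cp <- conc; cp[species] <- conc[species] * (1 + rel_step)
  cm <- conc; cm[species] <- conc[species] * (1 - rel_step)
  vp <- reaction_rate(rxn, cp, gamma, alpha, network$capacity)
  vm <- reaction_rate(rxn, cm, gamma, alpha, network$capacity)
  (vp - vm) / (2 * rel_step * v0)
}

#' Table of pi-elasticities for one or more enzymes at a steady state
#'
#' Enumerates every kinetic parameter of each rate law (abundance, reactant
#' binding constants, allosteric binding constants, gamma where the enzyme is
#' interconvertible) and computes pi_ik at the given steady state.
#'
#' @param network A [build_network()] object.
#' @param ss A [steady_state()] result providing the local state.
#' @param reactions Reaction ids (default: all with nonzero flux).
#' @return Object of class \code{elasticity_table}: data.frame with
#'   \code{reaction}, \code{parameter}, \code{category}, \code{pi};
#'   attribute \code{descriptor}.
#' @export
elasticity_table <- function(network, ss, reactions = NULL) {
  if (is.null(reactions)) {
    reactions <- names(network$reactions)[
      abs(ss$fluxes[names(network$reactions)]) > 1e-9]
  }
  rows <- list()
  for (id in reactions) {
    pars <- enumerate_parameters(network$reactions[[id]])
    # skip binding constants of clamped constant cofactor pools? keep all:
    for (i in seq_len(nrow(pars))) {
      pi_v <- tryCatch(
        pi_elasticity(network, id, pars$name[i], ss$conc, ss$gamma,
                      alpha = unname(ss$alpha[id])),
        error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        reaction = id, parameter = pars$name[i], category = pars$category[i],
        pi = pi_v, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("elasticity_table", "data.frame"),
            descriptor = state_descriptor(ss$state, ss$clamps))
}

#' Response coefficients from control and elasticity tables
#'
#' R_ik = C_i * pi_ik: the system-level sensitivity of the glucose exchange
#' flux to a kinetic parameter is the product of the enzyme's flux control
#' coefficient and the parameter's pi-elasticity. Both tables must have been
#' computed at the same state.
#'
#' @param control_table From [control_coefficients()].
#' @param elasticity_table From [elasticity_table()].
#' @return data.frame with \code{reaction}, \code{parameter}, \code{category},
#'   \code{pi}, \code{C}, \code{R}.
#' @export
response_coefficients <- function(control_table, elasticity_table) {
  if (!identical(attr(control_table, "descriptor"),
                 attr(elasticity_table, "descriptor")))
    stop("control and elasticity tables were computed at different states")
  C <- setNames(control_table$C, control_table$reaction)
  out <- elasticity_table
  out$C <- unname(C[out$reaction])
  out$R <- out$C * out$pi
  class(out) <- "data.frame"
  out
}

#' Relative elasticity shares of one enzyme
#'
#' Each |pi_ik| of the enzyme divided by the sum of all |pi_ik|; the shares
#' add up to one and quantify the relative weight of abundance, reactant,
#' allosteric and phosphorylation control of that enzyme.
#'
#' @param elasticity_table From [elasticity_table()].
#' @param reaction Reaction id.
#' @return data.frame with \code{parameter}, \code{category}, \code{share}.
#' @export
relative_elasticities <- function(elasticity_table, reaction) {
  et <- elasticity_table[elasticity_table$reaction == reaction, ]
  et <- et[is.finite(et$pi), ]
  if (!nrow(et)) stop("no elasticities for reaction ", reaction)
  tot <- sum(abs(et$pi))
  if (tot < .Machine$double.eps^0.5)
    stop("all elasticities of ", reaction, " are zero")
  data.frame(parameter = et$parameter, category = et$category,
             share = abs(et$pi) / tot, stringsAsFactors = FALSE)
}

#' Time-resolved flux control coefficients along a diurnal profile
#'
#' Re-computes the control coefficients of selected enzymes at sampled time
#' points of a diurnal glucose profile, clamping plasma glucose and the
#' glycogen filling state at their instantaneous values. Points where the
#' exchange flux is within \code{floor} of zero (the set-point crossings,
#' where coefficients diverge by definition) are flagged as divergent and not
#' reported.
#'
#' @param network A [build_network()] object.
#' @param state Physiological state.
#' @param profile Diurnal glucose profile (data.frame time_h, glucose_mM).
#' @param enzymes Reaction ids to follow (default: the key regulatory set).
#' @param times_h Sample times (h).
#' @param floor Divergence floor on |v_ex| (umol/g/h).
#' @param ... Passed to [run_diurnal()].
#' @return data.frame with \code{time_h}, \code{v_ex}, \code{divergent}, and
#'   one column of C values per enzyme (NA where divergent).
#' @export
diurnal_control <- function(network, state, profile,
                            enzymes = c("GK", "GlcT", "G6P", "FBP2", "PFK2",
                                        "PC", "LacT"),
                            times_h = seq(0, 23, by = 2), floor = 1, ...) {
  day <- run_diurnal(network, profile, state = state, n_replicates = 1, ...)
  g_fun <- periodic_profile(profile)
  out <- vector("list", length(times_h))
  for (k in seq_along(times_h)) {
    tk <- times_h[k]
    i <- which.min(abs(day$time - tk))
    clamps <- clamp_set(glucose = g_fun(tk), glycogen = day$fill[i, 1])
    row <- data.frame(time_h = tk, v_ex = NA_real_, divergent = FALSE)
    for (e in enzymes) row[[e]] <- NA_real_
    ss <- tryCatch(steady_state(network, state, clamps),
                   error = function(e) NULL)
    if (!is.null(ss)) row$v_ex <- ss$v_ex
    if (is.null(ss) || abs(row$v_ex) < floor) {
      row$divergent <- TRUE
    } else {
      ref <- ss
      for (e in enzymes) {
        a <- ref$alpha
        a[e] <- a[e] * 1.05
        ssp <- tryCatch(steady_state(network, state, clamps, alpha = a,
                                     conc0 = ref$conc),
                        error = function(e) NULL)
        if (!is.null(ssp))
          row[[e]] <- ((ssp$v_ex - ref$v_ex) / ref$v_ex) / 0.05
      }
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}

#' Key regulatory enzymes of the exchange flux
#'
#' Enzymes whose flux control coefficient exceeds \code{threshold} in absolute
#' value in at least one of the supplied control tables.
#'
#' @param ... One or more \code{control_table}s.
#' @param threshold Absolute control-coefficient threshold (default 0.1).
#' @return Character vector of reaction ids.
#' @export
key_enzymes <- function(..., threshold = 0.1) {
  tabs <- list(...)
  hits <- unique(unlist(lapply(tabs, function(ct)
    ct$reaction[!is.na(ct$C) & abs(ct$C) > threshold])))
  sort(hits)
}
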