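test_that("pi-elasticity with respect to abundance is exactly one", {
  net <- hf_net()
  ss <- hf_ss_fed()
  for (id in c("GK", "GlcT", "PC", "GPI", "GP")) {
    pi_v <- pi_elasticity(net, id, "vmax", ss$conc, ss$gamma,
                          alpha = unname(ss$alpha[id]))
    expect_equal(pi_v, 1, tolerance = 1e-10)
  }
})

test_that("epsilon = -pi for parameters entering through X = E/p", {
  net <- hf_net()
  ss <- hf_ss_fed()
  cases <- list(c("PFK1", "Fru26P2"), c("FBP1", "Fru26P2"),
                c("GK", "Fru6P"), c("PK", "Fru16P2"),
                c("GP", "Glc"), c("GS", "Glc6P"))
  for (cs in cases) {
    rxn <- cs[1]; eff <- cs[2]
    pi_p <- pi_elasticity(net, rxn, paste0("p_", eff), ss$conc, ss$gamma,
                          alpha = unname(ss$alpha[rxn]))
    # oracle: vary the effector concentration in the isolated factor only
    r <- net$reactions[[rxn]]
    term <- Filter(function(a) a$effector == eff, r$law$allosteric)[[1]]
    h <- 1e-5; E <- ss$conc[[eff]]
    f0 <- allosteric_factor(term, E)
    eps <- (allosteric_factor(term, E * (1 + h)) -
              allosteric_factor(term, E * (1 - h))) / (2 * h * f0)
    expect_equal(pi_p, -eps, tolerance = 1e-5,
                 label = paste("pi vs -eps for", rxn, eff))
    # and against the full-rate epsilon where the effector is a pure modifier
    if (!(eff %in% vapply(r$law$subs, `[[`, character(1), "id"))) {
      eps_full <- epsilon_elasticity(net, rxn, eff, ss$conc, ss$gamma,
                                     alpha = unname(ss$alpha[rxn]))
      expect_equal(pi_p, -eps_full, tolerance = 1e-5)
    }
  }
})

test_that("central differences match the closed-form derivative of a toy law", {
  # single-substrate saturable law v = V s / (K + s):
  #   pi_V = 1,  pi_K = (K/v) dv/dK = -K / (K + s)
  pars <- default_parameters()
  pars$reactions[["toy"]] <- list(
    id = "toy", stoich = c(Glc = -1, Glc6P = 1), reversible = FALSE,
    law = list(form = "mm_irrev", vmax = 10,
               subs = list(list(id = "Glc", K = 0.5)), prods = list()))
  net <- build_network(pars)
  cc <- species_concentrations(net)
  s <- cc[["Glc"]]; K <- 0.5
  expect_equal(pi_elasticity(net, "toy", "vmax", cc), 1, tolerance = 1e-10)
  expect_equal(pi_elasticity(net, "toy", "K_Glc", cc), -K / (K + s),
               tolerance = 1e-6)
  # and the substrate elasticity: (s/v) dv/ds = K / (K + s)
  expect_equal(epsilon_elasticity(net, "toy", "Glc", cc), K / (K + s),
               tolerance = 1e-6)
})

test_that("elasticity shares per enzyme sum to one and ignore signs", {
  net <- hf_net()
  ss <- hf_ss_fed()
  et <- elasticity_table(net, ss, reactions = c("GK", "PFK1", "GP", "GS",
                                                "PK", "GlcT", "PC", "FBP2"))
  for (id in unique(et$reaction)) {
    sh <- relative_elasticities(et, id)
    expect_equal(sum(sh$share), 1, tolerance = 1e-9)
    expect_true(all(sh$share >= 0))
  }
  # single-parameter reaction: share = 1
  et1 <- et[et$reaction == "GlcT" & et$parameter == "vmax", ]
  expect_equal(relative_elasticities(et1, "GlcT")$share, 1)
  # flipping the sign of individual pi values leaves shares unchanged
  et2 <- et[et$reaction == "GK", ]
  sh1 <- relative_elasticities(et2, "GK")
  et2$pi <- et2$pi * sample(c(-1, 1), nrow(et2), replace = TRUE)
  sh2 <- relative_elasticities(et2, "GK")
  expect_equal(sh1$share, sh2$share)
})

test_that("response coefficients compose control and elasticity", {
  net <- hf_net()
  ct <- hf_control_fed()
  ss <- hf_ss_fed()
  et <- elasticity_table(net, ss, reactions = c("GK", "GlcT", "GP", "PC"))
  rt <- response_coefficients(ct, et)
  # R = C for the abundance parameter (pi = 1)
  ab <- rt[rt$parameter == "vmax", ]
  C <- setNames(ct$C, ct$reaction)
  expect_equal(ab$R, unname(C[ab$reaction]), tolerance = 1e-9)
  # C_i = 0 implies R_ik = 0
  zero_rows <- rt[!is.na(rt$C) & rt$C == 0, ]
  if (nrow(zero_rows)) expect_true(all(zero_rows$R == 0))
  # state mismatch is rejected
  ct2 <- hf_control_fasted()
  expect_error(response_coefficients(ct2, et), "different states")
})

test_that("response coefficients match whole-system finite differences", {
  # R_ik from C_i * pi_ik against a direct perturbation of the parameter in
  # the full system, for a few informative (enzyme, parameter) pairs.
  net <- hf_net()
  ct <- hf_control_fed()
  ss <- hf_ss_fed()
  cases <- list(c("GK", "K_Glc"), c("PFK1", "p_Fru26P2"), c("GP", "p_Glc"))
  et <- elasticity_table(net, ss, reactions = vapply(cases, `[`, "", 1))
  rt <- response_coefficients(ct, et)
  for (cs in cases) {
    rid <- cs[1]; pname <- cs[2]
    R_pred <- rt$R[rt$reaction == rid & rt$parameter == pname]
    h <- 0.02
    pars_up <- default_parameters()
    pars_up$reactions[[rid]] <- bump_up <-
      hepatoflux:::bump_parameter(pars_up$reactions[[rid]], pname, 1 + h)
    net_up <- build_network(pars_up)
    ss_up <- steady_state(net_up, "fed", hf_clamps_fed(), conc0 = ss$conc)
    pars_dn <- default_parameters()
    pars_dn$reactions[[rid]] <-
      hepatoflux:::bump_parameter(pars_dn$reactions[[rid]], pname, 1 - h)
    net_dn <- build_network(pars_dn)
    ss_dn <- steady_state(net_dn, "fed", hf_clamps_fed(), conc0 = ss$conc)
    R_direct <- ((ss_up$v_ex - ss_dn$v_ex) / ss$v_ex) / (2 * h)
    expect_equal(R_pred, R_direct, tolerance = max(0.05, 0.05 * abs(R_direct)),
                 label = paste("system response for", rid, pname))
  }
})

test_that("control coefficients diverge at the set point and are refused there", {
  net <- hf_net()
  sp <- set_point(net, "fed", glycogen_fill = 0.5)
  expect_error(
    control_coefficients(net, "fed",
                         clamp_set(glucose = sp$glucose, glycogen = 0.5)),
    "floor")
})

test_that("forward and backward perturbations agree for proportional laws", {
  net <- hf_net()
  clamps <- hf_clamps_fasted()
  ct_f <- control_coefficients(net, "fasted", clamps, perturbation = 0.05,
                               scheme = "forward")
  ct_b <- control_coefficients(net, "fasted", clamps, perturbation = -0.05,
                               scheme = "forward")
  for (id in c("PC", "LacT", "GK")) {
    cf <- ct_f$C[ct_f$reaction == id]
    cb <- ct_b$C[ct_b$reaction == id]
    # agreement up to the O(perturbation) curvature term
    expect_lt(abs(cf - cb), max(0.15 * abs(cf), 0.03))
  }
})

test_that("diurnal control: summation holds off the set point, crossings are flagged", {
  net <- hf_net()
  prof <- gen_diurnal_glucose("fed")
  dc <- diurnal_control(net, "fed", prof, times_h = c(2, 8, 14),
                        dt = 0.5, burn_in_days = 0)
  enz <- c("GK", "GlcT", "G6P", "FBP2", "PFK2", "PC", "LacT")
  for (i in seq_len(nrow(dc))) {
    if (dc$divergent[i]) {
      expect_lt(abs(dc$v_ex[i]), 1)
    } else {
      expect_true(all(is.finite(unlist(dc[i, enz]))))
    }
  }
})
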