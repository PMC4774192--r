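TABLE3_ROSTER <- c(
  "ALD", "EN", "FBP1", "FBP2", "GAPDH", "GK", "GlcT", "GlcT_ER", "GP", "G6P",
  "GPI", "G6PT_ER", "GS", "LacT", "LDH", "MDH", "MDH_mito", "NDK_UTP",
  "NDK_GTP", "NDK_mito_GTP", "PC", "PEPCK", "PEPCK_mito", "PEPT", "PFK1",
  "PFK2", "PGK", "PGM", "PK", "PyrT", "PyrMalT", "TPI")

FIG1_METABOLITES <- c("DHAP", "Fru6P", "Fru16P2", "Fru26P2", "GAP", "Glc",
                      "Glc1P", "Glc6P", "Glyc", "Lac", "Mal", "OA", "P",
                      "PEP", "13P2G", "2PG", "3PG", "PP", "Pyr", "UDP_Glc")

test_that("default network has the full reaction roster and metabolite set", {
  net <- hf_net()
  expect_length(net$reactions, 32)
  expect_setequal(names(net$reactions), TABLE3_ROSTER)
  expect_true(all(FIG1_METABOLITES %in% net$species$id))
  # fixed cofactors are clamped, excluded from the dynamic state
  cof <- c("ATP", "ADP", "NAD", "NADH", "GTP", "UTP")
  expect_true(all(net$species$clamped[net$species$id %in% cof]))
  expect_true(all(net$species$compartment %in%
                    c("cytosol", "mitochondrion", "ER", "external")))
  expect_true(all(net$species$conc >= 0))
})

test_that("dynamic stoichiometric matrix has no all-zero row", {
  # brute-force scan over all dynamic species and reactions
  net <- hf_net()
  S <- stoichiometric_matrix(net, dynamic_only = TRUE)
  for (i in seq_len(nrow(S))) {
    touched <- FALSE
    for (r in net$reactions)
      if (rownames(S)[i] %in% names(r$stoich) &&
          r$stoich[[rownames(S)[i]]] != 0) touched <- TRUE
    expect_true(touched, label = paste("species", rownames(S)[i], "touched"))
    expect_true(any(S[i, ] != 0))
  }
})

test_that("a network with all species clamped has an empty dynamic state", {
  pars <- default_parameters()
  pars$species <- lapply(pars$species, function(s) { s$clamped <- TRUE; s })
  net <- build_network(pars)
  expect_equal(nrow(stoichiometric_matrix(net, dynamic_only = TRUE)), 0)
})

test_that("parameter validation fails with the offending reaction id", {
  pars <- default_parameters()
  pars$reactions[["GK"]]$law$vmax <- NULL
  expect_error(build_network(pars), "GK")
  pars <- default_parameters()
  pars$reactions[["PC"]]$stoich <- c(Pyr_mito = -1, Unobtainium = 1)
  expect_error(build_network(pars), "Unobtainium")
})

test_that("network rates match an independent per-species flux accounting", {
  net <- hf_net()
  m <- hepatoflux:::make_model(net, "normal", clamp_set(glucose = 6))
  for (seed in 1:5) {
    cc <- hf_random_conc(net, seed)
    cc[["Glc_ext"]] <- 6; cc[["Lac_ext"]] <- 1
    gamma <- m$gamma_const
    v <- network_rates(net, cc, gamma = gamma,
                       alpha = alpha_vector(net, "normal"))
    dydt <- m$rhs(0, cc[names(m$cc0[m$dyn_idx])], NULL)[[1]]
    # brute force: accumulate stoichiometry * rate per dynamic species
    for (k in seq_along(m$dyn_idx)) {
      sp_id <- net$species$id[m$dyn_idx[k]]
      acc <- 0
      for (r in net$reactions)
        if (sp_id %in% names(r$stoich))
          acc <- acc + r$stoich[[sp_id]] * v[[r$id]]
      expect_equal(dydt[k], net$kappa * acc, tolerance = 1e-10)
    }
  }
})

test_that("phospho-pair rates are affine in gamma; boundaries are the sub-laws", {
  net <- hf_net()
  cc <- species_concentrations(net)
  for (id in c("GP", "GS", "PK", "PFK2", "FBP2")) {
    r <- net$reactions[[id]]
    expect_false(is.null(r$law$pair))
    v0 <- reaction_rate(r, cc, gamma = 0, capacity = net$capacity)
    v1 <- reaction_rate(r, cc, gamma = 1, capacity = net$capacity)
    vh <- reaction_rate(r, cc, gamma = 0.5, capacity = net$capacity)
    expect_equal(vh, (v0 + v1) / 2, tolerance = 1e-12)
    # gamma = 1 is the phosphorylated sub-law alone (and 0 the dephospho one)
    r_phos <- r; r_phos$law$pair <- list(phos = r$law$pair$phos,
                                         dephos = r$law$pair$phos)
    expect_equal(v1, reaction_rate(r_phos, cc, gamma = 0,
                                   capacity = net$capacity))
    v37 <- reaction_rate(r, cc, gamma = 0.37, capacity = net$capacity)
    expect_equal(v37, v0 + 0.37 * (v1 - v0), tolerance = 1e-12)
  }
  # non-interconvertible enzymes ignore gamma
  vA <- reaction_rate(net$reactions[["GK"]], cc, gamma = 0)
  vB <- reaction_rate(net$reactions[["GK"]], cc, gamma = 1)
  expect_identical(vA, vB)
  expect_error(reaction_rate(net$reactions[["GK"]], cc, gamma = 1.2),
               "gamma")
  cc2 <- cc; cc2[["Glc"]] <- -1
  expect_error(reaction_rate(net$reactions[["GK"]], cc2, gamma = 0.5),
               "negative")
})

test_that("allosteric factors: empty-site limit, scale invariance, elasticity antisymmetry", {
  act <- allosteric_term("Fru26P2", p = 0.005, h = 2, mode = "activator",
                         beta = 20)
  inh <- allosteric_term("Glc", p = 12, h = 2, mode = "inhibitor")
  expect_equal(allosteric_factor(inh, 0), 1)
  expect_equal(allosteric_factor(act, 0), 1)
  # doubling effector and binding constant together leaves the factor unchanged
  act2 <- act; act2$p <- 2 * act$p
  expect_equal(allosteric_factor(act, 0.01), allosteric_factor(act2, 0.02))
  # monotone: increasing for activators, decreasing for inhibitors
  e_grid <- seq(0, 0.05, length.out = 30)
  expect_true(all(diff(vapply(e_grid, allosteric_factor, numeric(1),
                              term = act)) > 0))
  expect_true(all(diff(vapply(seq(0, 30, length.out = 30),
                              allosteric_factor, numeric(1), term = inh)) < 0))
  expect_error(allosteric_term("X", p = -1, mode = "inhibitor"))
  # numeric elasticity wrt p equals minus the elasticity wrt E (X = E/p)
  set.seed(42)
  for (i in 1:10) {
    tm <- if (i %% 2) act else inh
    E <- stats::runif(1, 1e-4, 10 * tm$p)
    h <- 1e-5
    f0 <- allosteric_factor(tm, E)
    dE <- (allosteric_factor(tm, E * (1 + h)) -
             allosteric_factor(tm, E * (1 - h))) / (2 * h * f0)
    tp <- tm; tp$p <- tm$p * (1 + h)
    tmn <- tm; tmn$p <- tm$p * (1 - h)
    dp <- (allosteric_factor(tp, E) - allosteric_factor(tmn, E)) / (2 * h * f0)
    expect_equal(dp, -dE, tolerance = 1e-6)
  }
})

test_that("rates scale strictly proportionally with enzyme abundance", {
  net <- hf_net()
  cc <- hf_random_conc(net, 7)
  v1 <- network_rates(net, cc, gamma = 0.4)
  a <- setNames(rep(1.73, length(net$reactions)), names(net$reactions))
  v2 <- network_rates(net, cc, gamma = 0.4, alpha = a)
  expect_equal(v2, 1.73 * v1, tolerance = 1e-12)
})

test_that("reversible rates are finite and sign-consistent at extreme ratios", {
  net <- hf_net()
  cc <- species_concentrations(net)
  gpi <- net$reactions[["GPI"]]
  # far below equilibrium: forward; far above: backward
  cc1 <- cc; cc1[["Glc6P"]] <- 10;   cc1[["Fru6P"]] <- 1e-9
  cc2 <- cc; cc2[["Glc6P"]] <- 1e-9; cc2[["Fru6P"]] <- 10
  expect_gt(reaction_rate(gpi, cc1), 0)
  expect_lt(reaction_rate(gpi, cc2), 0)
  for (ccx in list(cc1, cc2)) {
    v <- network_rates(net, ccx, gamma = 0.5)
    expect_true(all(is.finite(v)))
  }
})
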