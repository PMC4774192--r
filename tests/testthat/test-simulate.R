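test_that("a converged state is a fixed point of the solver", {
  net <- hf_net()
  ss <- hf_ss_fasted()
  expect_lt(ss$residual, 1e-6)
  again <- steady_state(net, "fasted", hf_clamps_fasted(), conc0 = ss$conc)
  expect_lt(again$residual, 1e-6)
  expect_equal(again$conc, ss$conc, tolerance = 1e-7)
  expect_equal(again$v_ex, ss$v_ex, tolerance = 1e-7)
})

test_that("flux balance holds at every dynamic species at steady state", {
  net <- hf_net()
  for (ss in list(hf_ss_fasted(), hf_ss_fed())) {
    S <- stoichiometric_matrix(net, dynamic_only = TRUE)
    S <- S[rownames(S) != "Glyc", , drop = FALSE]  # store is clamped here
    imbalance <- S %*% ss$fluxes[colnames(S)]
    expect_lt(max(abs(imbalance)), 1e-6 / net$kappa + 1e-8)
  }
})

test_that("hormone-free perfusion with lactate yields net glucose production", {
  net <- hf_net()
  ss <- steady_state(net, "fasted",
                     clamp_set(glucose = 0, lactate = 5, glycogen = 0,
                               hormones = "zero"))
  expect_lt(ss$v_ex, 0)
  expect_equal(ss$hormones$insulin, 0)
})

test_that("steady state agrees with an independent least-squares root solve", {
  net <- hf_net()
  clamps <- clamp_set(glucose = 5, lactate = 1, glycogen = 0.4)
  m <- hepatoflux:::make_model(net, "normal", clamps)
  y0 <- m$cc0[m$dyn_idx]
  # oracle: damped Levenberg-Marquardt root solve of dc/dt = 0 from the same
  # start, in log-concentration space (keeps the iterates positive and the
  # residual smooth)
  fr <- function(z) m$rhs(0, exp(z), NULL)[[1]]
  lm_fit <- minpack.lm::nls.lm(par = log(y0), fn = fr,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 1000, ftol = 0, ptol = 0,
                                 gtol = 0, maxfev = 50000))
  root <- exp(lm_fit$par)
  expect_lt(max(abs(fr(lm_fit$par))), 1e-5)
  ss <- steady_state(net, "normal", clamps)
  expect_equal(unname(ss$conc[names(y0)]), unname(root), tolerance = 1e-4)
})

test_that("set point: root property and agreement with a fine grid scan", {
  net <- hf_net()
  sp <- set_point(net, "fed", glycogen_fill = 0.5)
  expect_lt(abs(sp$v_ex), 0.05)
  # oracle: 0.01-mM grid scan of v_ex around the root
  g_grid <- seq(sp$glucose - 0.05, sp$glucose + 0.05, by = 0.01)
  warm <- NULL
  v <- vapply(g_grid, function(g) {
    ss <- steady_state(net, "fed", clamp_set(glucose = g, glycogen = 0.5),
                       conc0 = warm)
    warm <<- ss$conc
    ss$v_ex
  }, numeric(1))
  crossing <- g_grid[which(diff(sign(v)) != 0)[1]]
  expect_lt(abs(sp$glucose - crossing), 0.011)
})

test_that("set point search reports a liver that never crosses zero", {
  net <- hf_net()
  expect_error(set_point(net, "fed", glycogen_fill = 0.5,
                         interval = c(10, 14)),
               "pure")
})

test_that("v_ex is monotone nondecreasing in plasma glucose (3-12 mM)", {
  net <- hf_net()
  for (state in physiological_states()) {
    warm <- NULL
    v <- vapply(seq(3, 12, by = 1), function(g) {
      ss <- steady_state(net, state, clamp_set(glucose = g, glycogen = 0.5),
                         conc0 = warm)
      warm <<- ss$conc
      ss$v_ex
    }, numeric(1))
    expect_true(all(diff(v) > 0), label = paste("monotone v_ex in", state))
  }
})

test_that("lactate titration saturates and matches an extended-range oracle", {
  net <- hf_net()
  ti <- lactate_titration(net, lactate_range = seq(0, 10, by = 1))
  # production increases (v_ex nonincreasing) with lactate supply
  expect_true(all(diff(ti$v_ex) < 1e-6))
  # no-substrate limit: without lactate or glucose only a small residual flux
  expect_lt(abs(ti$v_ex[1]), 15)
  # extended-range oracle: the curve approaches a genuine asymptote (the
  # 30 mM point sits within 2% of the 50 mM one) and the 10 mM plateau is
  # within the carrier affinity of that asymptote
  far <- lactate_titration(net, lactate_range = c(30, 50))
  expect_lt(abs(far$v_ex[1] - far$v_ex[2]), 0.02 * abs(far$v_ex[2]))
  expect_lt(abs(ti$v_ex[ti$lactate_mM == 10] - far$v_ex[2]),
            0.06 * abs(far$v_ex[2]))
  expect_error(lactate_titration(net, lactate_range = -1), "")
})

test_that("constant glucose at the set point keeps the liver idle all day", {
  net <- hf_net()
  sp <- set_point(net, "normal", glycogen_fill = NULL)
  ss <- steady_state(net, "normal",
                     clamp_set(glucose = sp$glucose, glycogen = NULL))
  flat <- data.frame(time_h = seq(0, 24, by = 1),
                     glucose_mM = rep(sp$glucose, 25))
  day <- run_diurnal(net, flat, state = "normal",
                     glycogen_init = unname(ss$conc["Glyc"]) / net$capacity,
                     burn_in_days = 1)
  expect_lt(max(abs(day$v_ex)), 1.5)
})

test_that("seeded diurnal ensembles are exactly reproducible", {
  net <- hf_net()
  prof <- gen_diurnal_glucose("fasted")
  d1 <- run_diurnal(net, prof, "fasted", n_replicates = 3, seed = 42,
                    dt = 0.25)
  d2 <- run_diurnal(net, prof, "fasted", n_replicates = 3, seed = 42,
                    dt = 0.25)
  expect_identical(d1$v_ex, d2$v_ex)
  expect_identical(d1$fill, d2$fill)
  expect_identical(d1$alpha, d2$alpha)
  d3 <- run_diurnal(net, prof, "fasted", n_replicates = 3, seed = 43,
                    dt = 0.25)
  expect_false(identical(d1$alpha, d3$alpha))
  expect_error(run_diurnal(net, data.frame(time_h = c(0, 24),
                                           glucose_mM = c(5, -1)),
                           "fed"), "nonpositive")
})

test_that("starvation-refeeding fills then drains the glycogen store", {
  net <- hf_net()
  tr <- starvation_refeeding(net, dt = 0.25)
  expect_equal(tr$fill[1], 0)
  refeed <- tr$time_h >= 4 & tr$time_h <= 20      # after initial transients
  fast <- tr$time_h >= 24
  expect_true(all(diff(tr$glycogen_mM[refeed]) >= -1e-6))
  expect_true(all(diff(tr$glycogen_mM[fast]) <= 1e-6))
  expect_gt(max(tr$fill), 0.15)
  # bookkeeping: net glycogen change equals the integral of (GS - GP) flux
  for (win in list(c(2, 18), c(25, 45))) {
    i <- tr$time_h >= win[1] & tr$time_h <= win[2]
    lhs <- tr$glycogen_mM[i][sum(i)] - tr$glycogen_mM[i][1]
    rhs <- net$kappa *
      hepatoflux:::trapz(tr$time_h[i], tr$v_gs[i] - tr$v_gp[i])
    expect_equal(lhs, rhs, tolerance = 0.02 * max(abs(lhs), 1))
  }
})

test_that("bolus response: null perturbation and state ordering", {
  net <- hf_net()
  prof <- gen_diurnal_glucose("fasted")
  # zero-amplitude bolus (peak below the base profile) leaves the day unchanged
  null_b <- bolus_response(net, prof, peak_mM = 0.1, states = "normal",
                           dt = 0.5)
  expect_equal(null_b$v_bolus[, "normal"], null_b$v_base[, "normal"],
               tolerance = 1e-8)
  expect_lt(abs(null_b$extra_uptake[["normal"]]), 1e-6)
  # genuine bolus: extra uptake matches an independent trapezoid quadrature
  b <- bolus_response(net, prof, peak_mM = 10, states = c("fasted", "fed"),
                      dt = 0.5)
  i <- b$time >= 12 & b$time <= 18
  x <- b$time[i]
  y <- b$v_bolus[i, "fed"] - b$v_base[i, "fed"]
  riemann <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  expect_equal(unname(b$extra_uptake[["fed"]]), riemann, tolerance = 1e-9)
})
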