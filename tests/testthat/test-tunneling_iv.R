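# independent constant-level evaluation of the two WKB branches
oracle_tunnel_p <- function(l, phi_ev, v) {
  phiJ <- phi_ev * phys$e
  evJ <- abs(v) * phys$e
  if (evJ <= phiJ) {
    exp(-(2 * l / phys$hbar) * sqrt(2 * phys$m_e * (phiJ - evJ)))
  } else {
    exp(-(4 * l * sqrt(2 * phys$m_e) * phiJ^1.5) / (3 * phys$hbar * evJ))
  }
}

two_node_elements <- function(d = 3.8, rc = 6) {
  ch <- calpha_chain("A", 1:2, "ALA", c(0, d), c(0, 0), c(0, 0))
  assign_elements(build_graph(ch, rc), material_params())
}

test_that("tunnel probability matches the independent WKB oracle", {
  grid <- expand.grid(l = c(2e-10, 3.8e-10, 6e-10),
                      phi = c(53e-3, 59e-3, 69e-3, 0.5),
                      v = c(0, 0.01, 0.059, 0.2, 1, 5))
  for (k in seq_len(nrow(grid))) {
    expect_equal(
      tunnel_probability(grid$l[k], grid$phi[k], grid$v[k]),
      oracle_tunnel_p(grid$l[k], grid$phi[k], grid$v[k]),
      tolerance = 1e-12)
  }
  # frozen reference point: l = 3.8 A, Phi = 59 meV, zero bias
  expect_equal(tunnel_probability(3.8e-10, 59e-3, 0), 0.38839, tolerance = 1e-4)
  # barrier exactly cancelled on the direct branch
  expect_identical(tunnel_probability(3.8e-10, 59e-3, 59e-3), 1)
})

test_that("tunnel probability monotonicities and blend matching", {
  l <- 3.8e-10; phi <- 59e-3
  v_direct <- seq(0, phi, length.out = 20)
  p <- tunnel_probability(l, phi, v_direct)
  expect_true(all(diff(p) > 0))
  v_inj <- seq(phi * 1.01, 1, length.out = 20)
  expect_true(all(diff(tunnel_probability(l, phi, v_inj)) > 0))
  expect_true(all(diff(tunnel_probability(seq(1, 8, 1) * 1e-10, phi, 0.01)) < 0))
  expect_true(all(diff(tunnel_probability(l, seq(0.02, 0.2, 0.02), 0.01)) < 0))
  expect_true(all(p > 0 & p <= 1))

  # hard switch is discontinuous at eV = Phi; blend joins continuously at 1
  just_above <- phi * (1 + 1e-9)
  expect_lt(tunnel_probability(l, phi, just_above), 1)
  expect_equal(tunnel_probability(l, phi, just_above, matching = "blend"), 1,
               tolerance = 1e-6)
  expect_error(tunnel_probability(-1e-10, phi, 0), class = "inpa_bad_input")
  expect_error(tunnel_probability(l, 0, 0), class = "inpa_bad_input")
})

test_that("huge barrier freezes the network onto the linear law V = Z(0) I", {
  el <- assign_elements(build_graph(make_helix(12), 6), material_params())
  ct <- point_contacts(1, 12)
  z0 <- Re(solve_impedance(el, ct, 0))
  iv <- mc_iv_sweep(el, ct, tunneling_params(phi_mean = 10, phi_sigma = 0,
                                             seed = 2),
                    voltages = c(0, 0.5, 1), n_realizations = 5, max_iter = 30)
  ref <- linear_iv(z0, c(0, 0.5, 1))
  expect_equal(iv$current_mean, ref$current_mean, tolerance = 1e-12)
  expect_equal(iv$current_sd, rep(0, 3))
  expect_equal(iv$injection_fraction, rep(0, 3))
})

test_that("rho_low = rho_high makes state changes electrically invisible", {
  el <- two_node_elements()
  ct <- point_contacts(1, 2)
  z0 <- Re(solve_impedance(el, ct, 0))
  iv <- mc_iv_sweep(el, ct,
                    tunneling_params(phi_mean = 59e-3, phi_sigma = 0,
                                     rho_low = 1e10, seed = 5),
                    voltages = c(0, 0.02, 0.04), n_realizations = 5,
                    max_iter = 30)
  expect_equal(iv$current_mean, c(0, 0.02, 0.04) / z0, tolerance = 1e-12)
  expect_equal(iv$current_sd, rep(0, 3))
})

test_that("identical seed gives bit-identical sweeps; seeds differ otherwise", {
  el <- assign_elements(build_graph(make_helix(10), 6), material_params())
  ct <- point_contacts(1, 10)
  pars <- tunneling_params(phi_mean = 59e-3, phi_sigma = 44e-3, seed = 42)
  iv1 <- mc_iv_sweep(el, ct, pars, c(0.5, 1), n_realizations = 4, max_iter = 20)
  iv2 <- mc_iv_sweep(el, ct, pars, c(0.5, 1), n_realizations = 4, max_iter = 20)
  expect_identical(iv1$current_mean, iv2$current_mean)
  expect_identical(iv1$injection_fraction, iv2$injection_fraction)
  iv3 <- mc_iv_sweep(el, ct, tunneling_params(phi_mean = 59e-3,
                                              phi_sigma = 44e-3, seed = 43),
                     c(0.5, 1), n_realizations = 4, max_iter = 20)
  expect_false(identical(iv1$current_mean, iv3$current_mean))
})

test_that("zero-sigma sweep equals a from-scratch single-barrier re-implementation", {
  d <- 3.8
  el <- two_node_elements(d)
  ct <- point_contacts(1, 2)
  pars <- tunneling_params(phi_mean = 59e-3, phi_sigma = 0, seed = 9)
  voltages <- c(0, 0.02, 0.05)
  n_real <- 6; max_iter <- 40
  iv <- mc_iv_sweep(el, ct, pars, voltages, n_realizations = n_real,
                    max_iter = max_iter)

  # oracle: replay the documented scheme (quenched barrier, synchronous
  # redraw, record-then-redraw, 20% burn-in) with the same RNG stream
  g_high <- el$A / el$l / el$rho
  g_low <- el$A / el$l / (el$rho * 1e-6)
  burn <- ceiling(0.2 * max_iter)
  phi <- 59e-3
  cur <- matrix(0, n_real, length(voltages))
  inpa:::with_seed(9, {
    for (r in seq_len(n_real)) {
      for (vi in seq_along(voltages)) {
        V <- voltages[vi]
        if (V == 0) next
        state <- FALSE
        csum <- 0; cnt <- 0
        for (t in seq_len(max_iter)) {
          g <- if (state) g_low else g_high
          z <- solve(matrix(g, 1, 1), 1)[1]
          current <- V / z
          dropv <- abs(z) * current
          if (t > burn) { csum <- csum + current; cnt <- cnt + 1 }
          p <- tunnel_probability(el$l, phi, dropv)
          state <- stats::runif(1) < p
        }
        cur[r, vi] <- csum / cnt
      }
    }
  })
  expect_identical(iv$current_mean, colMeans(cur))
})

test_that("sequential tunneling produces a superlinear I-V when links activate", {
  # near-1D chain: R_C below the next-nearest helix distance
  el <- assign_elements(build_graph(make_helix(20), 4), material_params())
  ct <- point_contacts(1, 20)
  iv <- mc_iv_sweep(el, ct, tunneling_params(phi_mean = 59e-3, phi_sigma = 0,
                                             seed = 21),
                    voltages = c(0.6, 1.2), n_realizations = 30, max_iter = 60)
  expect_gt(iv$injection_fraction[2], 0)  # activation did occur
  expect_gt(iv$current_mean[2] / iv$current_mean[1], 2)
  expect_true(all(iv$current_sd > 0))
})

test_that("crossover sits at the barrier voltage for a single-link toy", {
  el <- two_node_elements(d = 2)
  ct <- point_contacts(1, 2)
  pars <- tunneling_params(phi_mean = 59e-3, phi_sigma = 0, seed = 3)
  volts <- c(0.03, 0.045, 0.0591, 0.075, 0.09)
  iv <- mc_iv_sweep(el, ct, pars, volts, n_realizations = 10, max_iter = 200)
  expect_equal(crossover_voltage(iv), 0.0591)  # first point with eV >= Phi

  capped <- mc_iv_sweep(el, ct, pars, c(0.01, 0.02), n_realizations = 5,
                        max_iter = 50)
  expect_true(is.na(crossover_voltage(capped)))
})

test_that("global leakage: open-circuit identity, additivity, ohmic dominance", {
  el <- assign_elements(build_graph(make_helix(10), 6), material_params())
  ct <- point_contacts(1, 10)
  z0 <- Re(solve_impedance(el, ct, 0))
  pars <- tunneling_params(phi_mean = 59e-3, phi_sigma = 0, seed = 8)
  iv <- mc_iv_sweep(el, ct, pars, c(0, 0.5, 1), n_realizations = 5,
                    max_iter = 30)
  expect_equal(iv_with_leakage(iv, Inf)$current_mean, iv$current_mean)

  # setting leakage in params equals adding the branch afterwards
  pars_lk <- tunneling_params(phi_mean = 59e-3, phi_sigma = 0, seed = 8,
                              leakage_R = z0 / 10)
  iv_lk <- mc_iv_sweep(el, ct, pars_lk, c(0, 0.5, 1), n_realizations = 5,
                       max_iter = 30)
  expect_equal(iv_lk$current_mean,
               iv_with_leakage(iv, z0 / 10)$current_mean, tolerance = 1e-12)

  # dominant leakage: slope ~ 1/leakage_R at low V
  lk <- z0 * 1e-9
  iv_dom <- iv_with_leakage(iv, lk)
  expect_equal(iv_dom$current_mean[2] / 0.5, 1 / lk, tolerance = 1e-3)
  expect_error(iv_with_leakage(iv, 0), class = "inpa_bad_input")
})

test_that("deeper tip indentation raises currents and lowers the crossover", {
  bundle <- make_helix_bundle(3, 14, spacing = 6)
  mat <- material_params()
  run_depth <- function(depth) {
    ct <- make_planar_contacts(bundle, axis = c(0, 0, 1),
                               depth_in = depth, depth_out = 0)
    el <- assign_elements(build_graph(bundle, 6), mat)
    mc_iv_sweep(el, ct, tunneling_params(phi_mean = 59e-3, phi_sigma = 0,
                                         seed = 17),
                voltages = c(0.2, 0.5, 1, 1.5), n_realizations = 20,
                max_iter = 60)
  }
  shallow <- run_depth(5)   # 0.5 nm
  deep <- run_depth(10)     # 1.0 nm
  expect_true(all(deep$current_mean > shallow$current_mean))
  cross_s <- crossover_voltage(shallow)
  cross_d <- crossover_voltage(deep)
  if (!is.na(cross_s) && !is.na(cross_d)) expect_lte(cross_d, cross_s)
})

test_that("sweep input validation", {
  el <- two_node_elements()
  ct <- point_contacts(1, 2)
  expect_error(mc_iv_sweep(el, ct, tunneling_params(), c(1, 0.5)),
               class = "inpa_bad_input")
  expect_error(mc_iv_sweep(el, ct, tunneling_params(), c(-1, 0)),
               class = "inpa_bad_input")
  expect_error(tunneling_params(phi_mean = -1), class = "inpa_bad_input")
})
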