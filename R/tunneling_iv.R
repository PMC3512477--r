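#' Sequential-tunneling model parameters
#'
#' Parameters of the stochastic sequential-tunneling mechanism: links flip
#' to a low-resistivity state with a voltage-dependent barrier-penetration
#' probability ([tunnel_probability()]), and the resistive network is
#' re-solved after every synchronous redraw. Per-link barrier heights are
#' quenched disorder: drawn once per Monte-Carlo realization from a
#' Gaussian truncated at zero (rejection sampling; negative barriers are
#' unphysical), `phi_sigma = 0` meaning a single shared barrier with no
#' random draw at all.
#'
#' Reference barrier values for bacteriorhodopsin-like modelling: a single
#' barrier of 53 or 59 meV, or a Gaussian with mean 69 meV and standard
#' deviation 44 meV.
#'
#' @param phi_mean mean barrier height, eV (> 0). Default 69e-3.
#' @param phi_sigma barrier standard deviation, eV (>= 0). Default 44e-3;
#'   0 switches the Gaussian machinery off entirely.
#' @param m_eff electron effective mass, kg; default the bare electron
#'   mass, length-independent.
#' @param rho_low resistivity of the activated (low-resistive) link state,
#'   Ohm m. Default `NULL` = 1e-6 times each link's high-state resistivity.
#'   This contrast is a model knob: only its being many orders of magnitude
#'   below the high state matters qualitatively.
#' @param leakage_R optional global leakage resistor (Ohm) in parallel with
#'   the whole two-terminal network, emulating conduction through contact
#'   regions (trimers, lipids); its ohmic current is added to every point.
#' @param seed integer RNG seed; runs are bit-reproducible given the seed.
#' @param injection_matching `"hard"` (default: switch formulas exactly at
#'   `e V = Phi`, with the documented discontinuity) or `"blend"` (shift
#'   the Fowler-Nordheim exponent so the branches meet continuously at the
#'   crossover, capped at 1).
#' @param burn_in_frac fraction of iterations discarded before averaging
#'   (default 0.2).
#' @return A `tunneling_params` list.
#' @export
tunneling_params <- function(phi_mean = 69e-3, phi_sigma = 44e-3,
                             m_eff = .phys$m_electron, rho_low = NULL,
                             leakage_R = NULL, seed = 1L,
                             injection_matching = c("hard", "blend"),
                             burn_in_frac = 0.2) {
  injection_matching <- match.arg(injection_matching)
  if (phi_mean <= 0) abort_inpa("phi_mean must be positive")
  if (phi_sigma < 0) abort_inpa("phi_sigma must be >= 0")
  if (!is.null(leakage_R) && leakage_R <= 0) abort_inpa("leakage_R must be positive")
  structure(list(phi_mean = phi_mean, phi_sigma = phi_sigma, m_eff = m_eff,
                 rho_low = rho_low, leakage_R = leakage_R,
                 seed = as.integer(seed),
                 injection_matching = injection_matching,
                 burn_in_frac = burn_in_frac),
            class = "tunneling_params")
}

#' Barrier-penetration probability of a link
#'
#' WKB transmission through the inter-residue barrier. In the direct
#' regime (`e V <= Phi`) the rectangular-barrier form applies:
#' `P = exp(-(2 l / hbar) * sqrt(2 m (Phi - e V)))`, reaching `P = 1` when
#' the drop equals the barrier. Above the barrier (`e V > Phi`) the
#' barrier is tilted into a triangle and the Fowler-Nordheim transmission
#' applies: `P = exp(-(4 l sqrt(2 m) Phi^{3/2}) / (3 hbar e V))`. The two
#' approximations do not meet continuously at `e V = Phi`; the default is
#' the hard switch, `matching = "blend"` rescales the injection branch to
#' join continuously (capped at 1). The drop enters as a magnitude:
#' transmission does not depend on its sign.
#'
#' @param l barrier (link) length in metres (> 0). Vectorized.
#' @param phi barrier height in eV (> 0). Vectorized.
#' @param v_drop potential drop magnitude across the link, V. Vectorized.
#' @param m_eff electron effective mass, kg.
#' @param matching `"hard"` or `"blend"` (see [tunneling_params()]).
#' @return Probabilities in (0, 1].
#' @examples
#' tunnel_probability(3.8e-10, 59e-3, 0)   # ~0.39
#' tunnel_probability(3.8e-10, 59e-3, 59e-3)  # exactly 1
#' @export
tunnel_probability <- function(l, phi, v_drop, m_eff = .phys$m_electron,
                               matching = c("hard", "blend")) {
  matching <- match.arg(matching)
  if (any(l <= 0)) abort_inpa("barrier length must be positive")
  if (any(phi <= 0)) abort_inpa("barrier height must be positive")
  hbar <- .phys$hbar
  e <- .phys$e_charge
  phiJ <- phi * e
  evJ <- abs(v_drop) * e
  n <- max(length(l), length(phi), length(evJ))
  l <- rep_len(l, n); phiJ <- rep_len(phiJ, n); evJ <- rep_len(evJ, n)
  p <- numeric(n)
  direct <- evJ <= phiJ
  p[direct] <- exp(-(2 * l[direct] / hbar) *
                     sqrt(2 * m_eff * (phiJ[direct] - evJ[direct])))
  if (any(!direct)) {
    fn_exp <- -(4 * l[!direct] * sqrt(2 * m_eff) * phiJ[!direct]^1.5) /
      (3 * hbar * evJ[!direct])
    if (matching == "blend") {
      # shift so the FN branch equals the direct branch's value (1) at eV = Phi
      fn_exp <- fn_exp + (4 * l[!direct] * sqrt(2 * m_eff * phiJ[!direct])) /
        (3 * hbar)
      p[!direct] <- pmin(1, exp(fn_exp))
    } else {
      p[!direct] <- exp(fn_exp)
    }
  }
  p
}

# Quenched per-link barrier draw (eV). sigma = 0 consumes no RNG so the
# single-barrier model is reproduced bit-for-bit.
draw_barriers <- function(m, phi_mean, phi_sigma) {
  if (phi_sigma == 0) return(rep(phi_mean, m))
  phi <- stats::rnorm(m, phi_mean, phi_sigma)
  bad <- which(phi <= 0)
  while (length(bad)) {
    phi[bad] <- stats::rnorm(length(bad), phi_mean, phi_sigma)
    bad <- bad[phi[bad] <= 0]
  }
  phi
}

#' Monte-Carlo sequential-tunneling I-V sweep
#'
#' For each realization and voltage: (1) draw quenched per-link barriers;
#' (2) starting from the all-high-resistivity state, iterate the
#' sequential-tunneling loop — solve the resistive network (`omega = 0`)
#' under the applied bias for the self-consistent node potentials, record
#' the terminal current, compute every link's drop, and synchronously
#' redraw every link's state (low resistivity with probability
#' [tunnel_probability()], high otherwise); (3) after the burn-in, average
#' the current and the injection-regime fraction over iterations. Means
#' and standard deviations are reported across realizations. Voltage
#' points start afresh (no hysteresis between sweep points). If
#' `leakage_R` is set, the ohmic current of a resistor in parallel with
#' the whole network is added.
#'
#' The per-iteration record is taken from the configuration being solved
#' (states drawn at the end of iteration t are solved at t+1). The
#' injection fraction classifies the activation draws: among links drawn
#' into the low state, the share whose drop at draw time satisfied
#' `e V_ij >= Phi_ij`, i.e. that tunneled via the Fowler-Nordheim branch
#' (0 when no link is activated).
#'
#' @param elements a `link_elements` data frame ([assign_elements()]).
#' @param contact a `contact_spec`.
#' @param params a [tunneling_params()].
#' @param voltages non-negative, sorted voltage sweep in V.
#' @param n_realizations Monte-Carlo realizations (>= 1).
#' @param max_iter iterations of the solve/redraw loop per voltage point.
#' @return An `iv_result` data frame with columns `voltage`,
#'   `current_mean`, `current_sd`, `injection_fraction`, and attributes
#'   `n_realizations` and `params`.
#' @export
mc_iv_sweep <- function(elements, contact, params = tunneling_params(),
                        voltages, n_realizations = 100L, max_iter = 200L) {
  if (any(voltages < 0) || is.unsorted(voltages))
    abort_inpa("voltages must be non-negative and sorted")
  if (n_realizations < 1L) abort_inpa("n_realizations must be >= 1")
  ctx <- solve_context(elements, contact)
  if (!ctx$connected)
    abort_inpa("contacts are not connected: impedance tends to infinite",
               class = "inpa_disconnected")
  m_all <- nrow(elements)
  rho_high <- elements$rho
  rho_low <- params$rho_low %||% (rho_high * 1e-6)
  # equality is allowed as the degenerate limit where state changes are
  # electrically invisible and the sweep must be exactly linear
  if (any(rho_low > rho_high))
    abort_inpa("rho_low must not exceed the high-state resistivity")
  g_high <- elements$A / elements$l / rho_high
  g_low <- elements$A / elements$l / rho_low
  burn <- ceiling(params$burn_in_frac * max_iter)
  if (burn >= max_iter)
    abort_inpa("burn-in leaves no iterations to average; increase max_iter")
  nV <- length(voltages)
  cur <- matrix(0, n_realizations, nV)
  injfr <- matrix(0, n_realizations, nV)

  with_seed(params$seed, {
    for (r in seq_len(n_realizations)) {
      phi <- draw_barriers(m_all, params$phi_mean, params$phi_sigma)
      for (vi in seq_len(nV)) {
        V <- voltages[vi]
        if (V == 0) next
        state <- rep(FALSE, m_all)
        csum <- 0; fsum <- 0; cnt <- 0L
        for (t in seq_len(max_iter)) {
          g <- ifelse(state, g_low, g_high)
          sol <- solve_reduced(ctx, g[ctx$rows])
          current <- V / sol$z
          drops <- rep(0, m_all)
          drops[ctx$rows] <- sol$drops_unit * current
          p <- tunnel_probability(elements$l, phi, drops,
                                  m_eff = params$m_eff,
                                  matching = params$injection_matching)
          state <- stats::runif(m_all) < p
          if (t > burn) {
            csum <- csum + current
            # classify the activation draws: a link activated while its
            # drop satisfied e V_ij >= Phi_ij tunneled via the injection
            # (Fowler-Nordheim) branch; e*drop >= e*phi compares in V/eV
            if (any(state)) fsum <- fsum + mean(drops[state] >= phi[state])
            cnt <- cnt + 1L
          }
        }
        cur[r, vi] <- csum / cnt
        injfr[r, vi] <- fsum / cnt
      }
    }
  })
  current_mean <- colMeans(cur)
  if (!is.null(params$leakage_R))
    current_mean <- current_mean + voltages / params$leakage_R
  structure(
    data.frame(voltage = voltages,
               current_mean = current_mean,
               current_sd = if (n_realizations > 1L) apply(cur, 2, stats::sd)
                            else rep(0, nV),
               injection_fraction = colMeans(injfr)),
    n_realizations = n_realizations, params = params,
    class = c("iv_result", "data.frame"))
}

#' Add a global leakage branch to an I-V curve
#'
#' Places a fixed resistor in parallel with the whole two-terminal
#' network: `V / leakage_R` is added to every current point. (The
#' per-link leakage variant is handled inside [mc_iv_sweep()] through an
#' effective resistivity.) With `leakage_R = Inf` the curve is unchanged;
#' when the leakage dominates the I-V is ohmic with slope `1/leakage_R`.
#'
#' @param iv an `iv_result`.
#' @param leakage_R leakage resistance in Ohm (> 0; may be `Inf`).
#' @return The modified `iv_result`.
#' @export
iv_with_leakage <- function(iv, leakage_R) {
  if (leakage_R <= 0) abort_inpa("leakage_R must be positive")
  iv$current_mean <- iv$current_mean + iv$voltage / leakage_R
  iv
}

#' Crossover voltage from direct to injection tunneling
#'
#' The smallest sweep voltage at which, among activated links, the
#' injection-regime fraction exceeds the direct-regime fraction (i.e. the
#' recorded `injection_fraction` exceeds 1/2). Deeper extended contacts
#' leave fewer residues in series, raise per-link drops, and shift this
#' crossover to lower voltages.
#'
#' @param iv an `iv_result` from [mc_iv_sweep()].
#' @return The crossover voltage in V, or `NA` if the sweep never reaches
#'   it.
#' @export
crossover_voltage <- function(iv) {
  hit <- which(iv$injection_fraction > 0.5)
  if (length(hit) == 0L) return(NA_real_)
  iv$voltage[hit[1L]]
}
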