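#' Settings for a native-vs-active electrical comparison
#'
#' @param material a [material_params()].
#' @param tunneling `NULL` for the linear (ohmic) I-V, or a
#'   [tunneling_params()] for the stochastic sequential-tunneling I-V.
#' @param voltages voltage sweep, V.
#' @param f_min,f_max,points_per_decade frequency grid (see [spectrum()]).
#' @param n_realizations,max_iter Monte-Carlo controls when tunneling is on.
#' @param contact_fn function(chain) -> `contact_spec`; default endpoint
#'   point contacts (first and last residue).
#' @return A `contrast_settings` list.
#' @export
contrast_settings <- function(material = material_params(), tunneling = NULL,
                              voltages = seq(0, 1, by = 0.25),
                              f_min = 0.1, f_max = 1e5, points_per_decade = 10L,
                              n_realizations = 50L, max_iter = 100L,
                              contact_fn = NULL) {
  structure(list(material = material, tunneling = tunneling,
                 voltages = voltages, f_min = f_min, f_max = f_max,
                 points_per_decade = points_per_decade,
                 n_realizations = n_realizations, max_iter = max_iter,
                 contact_fn = contact_fn %||%
                   function(chain) point_contacts(1L, nrow(chain))),
            class = "contrast_settings")
}

run_one_state <- function(chain, r_c, settings) {
  g <- build_graph(chain, r_c)
  el <- assign_elements(g, settings$material)
  contact <- settings$contact_fn(chain)
  sp <- spectrum(el, contact, settings$f_min, settings$f_max,
                 settings$points_per_decade)
  z0 <- Re(solve_impedance(el, contact, omega = 0))
  iv <- if (is.null(settings$tunneling)) {
    linear_iv(z0, settings$voltages)
  } else {
    mc_iv_sweep(el, contact, settings$tunneling, settings$voltages,
                n_realizations = settings$n_realizations,
                max_iter = settings$max_iter)
  }
  list(spectrum = sp, z0 = z0, iv = iv)
}

#' Electrical contrast between native and active conformers
#'
#' Runs the full pipeline (graph, elements, Kirchhoff solve, I-V)
#' independently on the two conformers of a pair — each with its own
#' interaction radius, since structure-function calibration can assign
#' different radii to the two states (e.g. 70 Angstrom native vs 46
#' Angstrom active for an olfactory receptor) — and reports per-frequency
#' impedance-magnitude ratios and per-voltage current ratios
#' (active/native). Identical conformers under identical settings give
#' ratio 1 everywhere. The unequal radii, when used, are recorded in the
#' result metadata and in every exported header.
#'
#' @param pair a [make_conformer_pair()] result (or any list with
#'   `native`, `active`, `label`).
#' @param r_c_native,r_c_active interaction radii in Angstrom.
#' @param settings a [contrast_settings()].
#' @return A `conformer_contrast` list: `impedance` (data frame `freq_hz`,
#'   `z_mod_native`, `z_mod_active`, `ratio`), `iv` (data frame `voltage`,
#'   `i_native`, `i_active`, `ratio`; ratios reported for V > 0),
#'   `z0_native`, `z0_active`, and run metadata `meta`.
#' @export
conformer_contrast <- function(pair, r_c_native, r_c_active,
                               settings = contrast_settings()) {
  nat <- run_one_state(pair$native, r_c_native, settings)
  act <- run_one_state(pair$active, r_c_active, settings)
  stopifnot(identical(nat$spectrum$freq, act$spectrum$freq))
  imp <- data.frame(freq_hz = nat$spectrum$freq,
                    z_mod_native = Mod(nat$spectrum$Z),
                    z_mod_active = Mod(act$spectrum$Z))
  imp$ratio <- imp$z_mod_active / imp$z_mod_native
  iv <- data.frame(voltage = nat$iv$voltage,
                   i_native = nat$iv$current_mean,
                   i_active = act$iv$current_mean)
  iv$ratio <- ifelse(iv$voltage > 0, iv$i_active / iv$i_native, NA_real_)
  structure(list(impedance = imp, iv = iv,
                 z0_native = nat$z0, z0_active = act$z0,
                 spectrum_native = nat$spectrum, spectrum_active = act$spectrum,
                 meta = list(label = pair$label,
                             r_c_native = r_c_native, r_c_active = r_c_active,
                             table_name = settings$material$table_name,
                             phi_mean = settings$tunneling$phi_mean,
                             seed = settings$tunneling$seed)),
            class = "conformer_contrast")
}

#' @export
print.conformer_contrast <- function(x, ...) {
  cat(sprintf("Conformer contrast '%s': R_C %g vs %g Angstrom; Z0 ratio %.4g\n",
              x$meta$label, x$meta$r_c_native, x$meta$r_c_active,
              x$z0_active / x$z0_native))
  invisible(x)
}

#' Fit the single-protein to macroscopic current scaling
#'
#' A macroscopic sample contains a macroscopic number of proteins; to
#' compare with experiment, the single-protein current in the native state
#' at an anchor voltage (typically 1 V) is normalized to the measured
#' macroscopic current, giving one multiplicative factor. The same factor
#' is then applied unchanged to the activated-state curve, so all
#' active/native ratios are invariant under the scaling (it is a pure
#' gauge). For bacteriorhodopsin-like magnitudes the factor comes out at
#' 1e8 to 1e9.
#'
#' @param single_iv an `iv_result` for the single protein (native state).
#' @param anchor_voltage voltage at which to anchor; must be a sweep point.
#' @param macroscopic_current measured current at that voltage, A (> 0).
#' @return A `scaling_spec` list: `factor`, `anchor_voltage`,
#'   `anchor_current_single`, `anchor_current_macroscopic`.
#' @export
fit_scaling <- function(single_iv, anchor_voltage, macroscopic_current) {
  k <- which(single_iv$voltage == anchor_voltage)
  if (length(k) != 1L)
    abort_inpa("anchor_voltage must match exactly one sweep point")
  i_single <- single_iv$current_mean[k]
  if (i_single <= 0)
    abort_inpa("zero single-protein current at the anchor voltage")
  if (macroscopic_current <= 0)
    abort_inpa("macroscopic current must be positive")
  structure(list(factor = macroscopic_current / i_single,
                 anchor_voltage = anchor_voltage,
                 anchor_current_single = i_single,
                 anchor_current_macroscopic = macroscopic_current),
            class = "scaling_spec")
}

#' Apply (or undo) a current scaling
#'
#' @param iv an `iv_result`.
#' @param scaling a [fit_scaling()] result.
#' @param invert divide instead of multiply, recovering the original curve.
#' @return The scaled `iv_result`.
#' @export
apply_scaling <- function(iv, scaling, invert = FALSE) {
  f <- if (invert) 1 / scaling$factor else scaling$factor
  iv$current_mean <- iv$current_mean * f
  iv$current_sd <- iv$current_sd * f
  iv
}

#' Write a conformer comparison report
#'
#' CSV with `#`-prefixed metadata header lines (pair label, radii,
#' dielectric table, barrier and seed when tunneling was used), followed
#' by the per-frequency impedance ratios and the per-voltage current
#' ratios.
#'
#' @param contrast a [conformer_contrast()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contrast_csv <- function(contrast, path) {
  m <- contrast$meta
  hdr <- c(
    sprintf("# pair: %s", m$label),
    sprintf("# r_c_native_angstrom: %g", m$r_c_native),
    sprintf("# r_c_active_angstrom: %g", m$r_c_active),
    sprintf("# eps_table: %s", m$table_name),
    if (!is.null(m$phi_mean)) sprintf("# phi_mean_ev: %g", m$phi_mean),
    if (!is.null(m$seed)) sprintf("# seed: %d", m$seed),
    sprintf("# z0_native_ohm: %.10g", contrast$z0_native),
    sprintf("# z0_active_ohm: %.10g", contrast$z0_active)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("# impedance ratios", con)
  utils::write.table(contrast$impedance, con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  writeLines("# current ratios", con)
  utils::write.table(contrast$iv, con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
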