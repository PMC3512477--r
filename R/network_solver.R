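#' Contact specifications
#'
#' Contacts are ideal: each contact set is merged into one equipotential
#' supernode with zero internal impedance. `point_contacts` places the
#' terminals on explicit node sets (the default protein configuration uses
#' the first and last residue of the chain); [make_planar_contacts()]
#' builds extended contacts from a slab of nodes at each end of an axis,
#' emulating e.g. an AFM tip indented into a monolayer.
#'
#' @param input_nodes,output_nodes non-empty, disjoint node index vectors.
#' @return A `contact_spec` list with elements `kind`, `input`, `output`.
#' @examples
#' point_contacts(1, 20)
#' @export
point_contacts <- function(input_nodes, output_nodes) {
  input_nodes <- as.integer(input_nodes)
  output_nodes <- as.integer(output_nodes)
  if (length(input_nodes) == 0L || length(output_nodes) == 0L)
    abort_inpa("contact sets must be non-empty")
  if (length(intersect(input_nodes, output_nodes)))
    abort_inpa("input and output contact sets must be disjoint")
  structure(list(kind = "point", input = input_nodes, output = output_nodes),
            class = "contact_spec")
}

#' Planar (extended) contacts along an axis
#'
#' The input set contains every node within `depth_in` of the maximal
#' projection onto `axis` (the "top", e.g. the indented tip side); the
#' output set every node within `depth_out` of the minimal projection.
#' With `depth = 0` each set reduces to the extreme node(s): a point
#' contact. Deeper contacts short more nodes together, which can only
#' decrease the static impedance, and leave fewer residues in series —
#' hence larger per-link voltage drops.
#'
#' @param chain a [calpha_chain()].
#' @param axis unit 3-vector; default the structure's principal axis
#'   (largest-variance eigenvector of the coordinate covariance).
#' @param depth_in,depth_out slab depths in Angstrom (>= 0); their sum must
#'   be smaller than the protein extent along the axis.
#' @return A `contact_spec` with `kind = "planar"` and the axis/depths kept
#'   as metadata.
#' @export
make_planar_contacts <- function(chain, axis = NULL, depth_in, depth_out) {
  if (depth_in < 0 || depth_out < 0) abort_inpa("contact depths must be >= 0")
  xyz <- coords(chain)
  if (is.null(axis)) {
    axis <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors[, 1L]
  }
  axis <- axis / sqrt(sum(axis^2))
  proj <- drop(xyz %*% axis)
  extent <- max(proj) - min(proj)
  if (depth_in + depth_out >= extent)
    abort_inpa("depth_in + depth_out must be smaller than the extent along axis")
  tol <- 1e-9
  input <- which(proj >= max(proj) - depth_in - tol)
  output <- which(proj <= min(proj) + depth_out + tol)
  if (length(intersect(input, output)))
    abort_inpa("planar contact sets overlap")
  structure(list(kind = "planar", input = input, output = output,
                 axis = axis, depth_in = depth_in, depth_out = depth_out),
            class = "contact_spec")
}

# Precompute the reduced incidence structure for a (elements, contact)
# pair. Contact sets are merged into supernodes; links internal to a
# contact set are electrically invisible (zero drop) and excluded from the
# incidence matrix; components not touching the contacts float and are
# excluded from the solve. Returns the dense incidence matrix B
# (kept links x solved nodes, output supernode grounded/removed).
solve_context <- function(elements, contact) {
  n <- attr(elements, "n_nodes")
  if (is.null(n)) n <- max(elements$i, elements$j)
  if (max(contact$input, contact$output) > n)
    abort_inpa("contact node index out of range")
  grp <- seq_len(n)
  grp[contact$input] <- n + 1L
  grp[contact$output] <- n + 2L
  ids <- match(grp, unique(grp))
  K <- max(ids)
  in_id <- ids[contact$input[1L]]
  out_id <- ids[contact$output[1L]]

  a <- ids[elements$i]
  b <- ids[elements$j]
  keep <- a != b
  if (!any(keep))
    return(list(n = n, ids = ids, K = K, in_id = in_id, out_id = out_id,
                connected = FALSE))
  ig <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, K - igraph::vcount(ig)))
  memb <- igraph::components(ig)$membership
  connected <- memb[in_id] == memb[out_id]

  ctx <- list(n = n, ids = ids, K = K, in_id = in_id, out_id = out_id,
              connected = connected)
  if (!connected) return(ctx)

  live_nodes <- which(memb == memb[in_id] & seq_len(K) != out_id)
  col_of <- rep(NA_integer_, K)
  col_of[live_nodes] <- seq_along(live_nodes)
  live_link <- keep & memb[a] == memb[in_id]
  rows <- which(live_link)
  B <- matrix(0, length(rows), length(live_nodes))
  ar <- a[rows]; br <- b[rows]
  has_a <- ar != out_id
  has_b <- br != out_id
  B[cbind(which(has_a), col_of[ar[has_a]])] <- 1
  B[cbind(which(has_b), col_of[br[has_b]])] <- -1
  ctx$B <- B
  ctx$rows <- rows              # element rows entering the solve
  ctx$live_nodes <- live_nodes  # merged-node index of each B column
  ctx$in_col <- col_of[in_id]
  ctx
}

# Solve the reduced Kirchhoff system for a per-kept-link admittance vector
# y (real or complex) under unit injected current. Returns the two-terminal
# impedance, node potentials (solved columns) and per-element voltage-drop
# magnitudes for unit current (zero for merged/floating links).
solve_reduced <- function(ctx, y) {
  L <- t(ctx$B) %*% (y * ctx$B)
  rhs <- rep(if (is.complex(y)) 0 + 0i else 0, ncol(ctx$B))
  rhs[ctx$in_col] <- 1
  v <- tryCatch(solve(L, rhs),
                error = function(e)
                  abort_inpa(sprintf("singular Kirchhoff system: %s",
                                     conditionMessage(e)),
                             class = "inpa_solver_failure"))
  list(z = v[ctx$in_col], v = v, drops_unit = abs(drop(ctx$B %*% v)))
}

#' Two-terminal impedance of the network at one frequency
#'
#' Assembles the complex node-admittance (Laplacian) matrix of the link
#' elements, merges each contact set into an equipotential supernode,
#' grounds the output supernode and injects unit current at the input: the
#' resulting input potential is the global impedance `Z(omega)`.
#' Disconnected contacts mean the impedance tends to infinity; by default
#' that is an error, in scan contexts it is reported as `Inf`.
#'
#' @param elements a `link_elements` data frame ([assign_elements()]).
#' @param contact a `contact_spec`.
#' @param omega circular frequency, rad/s (`omega = 2*pi*f`).
#' @param on_disconnect `"error"` (condition class `inpa_disconnected`) or
#'   `"inf"` (return `Inf + 0i`).
#' @return Complex impedance in Ohm.
#' @export
solve_impedance <- function(elements, contact, omega,
                            on_disconnect = c("error", "inf")) {
  on_disconnect <- match.arg(on_disconnect)
  ctx <- solve_context(elements, contact)
  if (!ctx$connected) {
    if (on_disconnect == "inf") return(complex(real = Inf, imaginary = 0))
    abort_inpa("contacts are not connected: impedance tends to infinite",
               class = "inpa_disconnected")
  }
  y <- link_admittance(elements, omega)[ctx$rows]
  solve_reduced(ctx, y)$z
}

#' Kirchhoff current residuals at internal nodes
#'
#' Recomputes, from the solved potentials and the raw per-link admittances,
#' the net current entering every merged node. For a valid solution the
#' residual at every non-contact node is at machine-precision level
#' relative to the injected unit current.
#'
#' @inheritParams solve_impedance
#' @return Named list: `max_internal` (largest absolute net current at a
#'   non-contact node, per unit injected current) and `z` (the impedance).
#' @export
current_residuals <- function(elements, contact, omega) {
  ctx <- solve_context(elements, contact)
  if (!ctx$connected)
    abort_inpa("contacts are not connected", class = "inpa_disconnected")
  y <- link_admittance(elements, omega)
  sol <- solve_reduced(ctx, y[ctx$rows])
  # full merged-node potentials: grounded output = 0, floating nodes 0
  vfull <- rep(0 + 0i, ctx$K)
  vfull[ctx$live_nodes] <- sol$v
  a <- ctx$ids[elements$i]; b <- ctx$ids[elements$j]
  ilink <- y * (vfull[a] - vfull[b])
  net <- rep(0 + 0i, ctx$K)
  for (k in seq_along(ilink)) {
    net[a[k]] <- net[a[k]] - ilink[k]
    net[b[k]] <- net[b[k]] + ilink[k]
  }
  internal <- setdiff(seq_len(ctx$K), c(ctx$in_id, ctx$out_id))
  list(max_internal = if (length(internal)) max(Mod(net[internal])) else 0,
       z = sol$z)
}

#' Impedance spectrum over a log-spaced frequency grid
#'
#' Computes `Z(omega)` on a logarithmic frequency grid inclusive of both
#' endpoints. The default range 0.1 Hz to 1e5 Hz is the standard range for
#' this model; impedance-spectroscopy comparisons may extend it (e.g.
#' 1 mHz to 100 kHz) via the arguments.
#'
#' @inheritParams solve_impedance
#' @param f_min,f_max frequency range in Hz, `0 < f_min < f_max`.
#' @param points_per_decade grid density (default 10, standard EIS
#'   practice).
#' @return A `spectrum_result`: list with `freq` (Hz), `Z` (complex Ohm),
#'   `contact`, `r_c`.
#' @export
spectrum <- function(elements, contact, f_min = 0.1, f_max = 1e5,
                     points_per_decade = 10L) {
  if (f_min <= 0 || f_max <= f_min) abort_inpa("need 0 < f_min < f_max")
  if (points_per_decade < 1L) abort_inpa("points_per_decade must be >= 1")
  ex <- seq(log10(f_min), log10(f_max), by = 1 / points_per_decade)
  if (ex[length(ex)] < log10(f_max) - 1e-12) ex <- c(ex, log10(f_max))
  freq <- 10^ex
  ctx <- solve_context(elements, contact)
  if (!ctx$connected)
    abort_inpa("contacts are not connected: impedance tends to infinite",
               class = "inpa_disconnected")
  Z <- vapply(freq, function(f) {
    y <- link_admittance(elements, 2 * pi * f)[ctx$rows]
    solve_reduced(ctx, y)$z
  }, complex(1))
  structure(list(freq = freq, Z = Z, contact = contact,
                 r_c = attr(elements, "r_c")),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d points, %g-%g Hz, Z(0) ~ %.4g Ohm\n",
              length(x$freq), min(x$freq), max(x$freq), Re(x$Z[which.min(x$freq)])))
  invisible(x)
}

#' Nyquist representation of a spectrum
#'
#' Returns `-Im Z` against `Re Z`, both normalized to a reference
#' resistance. The default reference is the spectrum's own low-frequency
#' real part, so a self-normalized curve starts at abscissa 1; passing the
#' native state's static value instead (as done when comparing conformers)
#' makes curve diameters directly comparable across states. A network with
#' a uniform time constant traces the semicircle
#' `(x - 1/2)^2 + y^2 = 1/4` with apex at `omega * tau = 1`.
#'
#' @param spec a [spectrum()] result.
#' @param normalize_to optional positive reference resistance in Ohm;
#'   default `Re Z` at the lowest frequency of this spectrum.
#' @return Data frame `z_real_norm`, `z_imag_neg_norm` (one row per
#'   frequency, ordered as the spectrum), with the reference kept as
#'   attribute `z_ref`.
#' @export
nyquist <- function(spec, normalize_to = NULL) {
  z_ref <- normalize_to %||% Re(spec$Z[which.min(spec$freq)])
  if (z_ref <= 0) abort_inpa("normalization reference must be positive")
  structure(data.frame(z_real_norm = Re(spec$Z) / z_ref,
                       z_imag_neg_norm = -Im(spec$Z) / z_ref),
            z_ref = z_ref)
}

#' Linear (ohmic) I-V characteristic
#'
#' The static response of the linear network: `V = Z(0) * I`, i.e.
#' `I = V / Z(0)` with zero variance. This is the limit the stochastic
#' tunneling sweep must reproduce when no link ever activates.
#'
#' @param z0 static impedance in Ohm (> 0, real).
#' @param voltages voltage sweep in V.
#' @return An `iv_result` data frame (`voltage`, `current_mean`,
#'   `current_sd`, `injection_fraction`).
#' @export
linear_iv <- function(z0, voltages) {
  z0 <- Re(z0)
  if (z0 <= 0) abort_inpa("z0 must be positive")
  structure(data.frame(voltage = voltages, current_mean = voltages / z0,
                       current_sd = 0, injection_fraction = 0),
            n_realizations = 1L,
            class = c("iv_result", "data.frame"))
}

#' Export spectrum / Nyquist / I-V tables as CSV
#'
#' Headers: spectrum `freq_hz,z_real_ohm,z_imag_ohm`; Nyquist
#' `z_real_norm,z_imag_neg_norm`; I-V
#' `voltage_v,current_mean_a,current_sd_a,injection_fraction`.
#'
#' @param spec,ny,iv objects from [spectrum()], [nyquist()],
#'   [mc_iv_sweep()]/[linear_iv()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  df <- data.frame(freq_hz = spec$freq, z_real_ohm = Re(spec$Z),
                   z_imag_ohm = Im(spec$Z))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
write_nyquist_csv <- function(ny, path) {
  utils::write.table(as.data.frame(ny), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
write_iv_csv <- function(iv, path) {
  df <- data.frame(voltage_v = iv$voltage, current_mean_a = iv$current_mean,
                   current_sd_a = iv$current_sd,
                   injection_fraction = iv$injection_fraction)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
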