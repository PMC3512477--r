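#' Electrical material parameters
#'
#' Bundles the quantities that turn geometry into impedance: the link
#' resistivity `rho` (indicative protein value 1e10 Ohm m; the microscopic
#' conduction mechanism is not specified at this level), a per-residue
#' relative dielectric table, the default dielectric used for residues
#' missing from the table, and the rule combining the two endpoint values
#' of a link into its `eps_rel`.
#'
#' @param rho resistivity in Ohm m (> 0), identical for every link.
#' @param eps_table named numeric vector mapping 3-letter residue codes to
#'   relative dielectric constants (all >= 1). Defaults to the packaged
#'   flat table (eps = 4 for every standard residue).
#' @param eps_default dielectric used, with a message, for residues absent
#'   from the table; set to `NULL` to make unknown residues an error.
#' @param combine `"arithmetic"` (default) or `"geometric"` mean of the two
#'   endpoint dielectrics.
#' @param eps0 vacuum permittivity, F/m (CODATA).
#' @return A `material_params` list.
#' @export
material_params <- function(rho = 1e10, eps_table = default_eps_table(),
                            eps_default = 4,
                            combine = c("arithmetic", "geometric"),
                            eps0 = .phys$eps0) {
  combine <- match.arg(combine)
  if (rho <= 0) abort_inpa("rho must be positive")
  if (length(eps_table) && any(eps_table < 1))
    abort_inpa("relative dielectric constants must be >= 1")
  structure(list(rho = rho, eps_table = eps_table, eps_default = eps_default,
                 combine = combine, eps0 = eps0,
                 table_name = attr(eps_table, "table_name") %||% "default"),
            class = "material_params")
}

#' Packaged flat dielectric table
#'
#' @return Named numeric vector, eps = 4 for the 20 standard residues.
#' @export
default_eps_table <- function() {
  path <- system.file("extdata", "dielectric_default.txt", package = "inpa")
  read_eps_table(path)
}

#' Read a per-residue dielectric table
#'
#' Two-column whitespace-separated text, `RESNAME eps`; `#` starts a
#' comment.
#'
#' @param path file path.
#' @return Named numeric vector, with the file name kept as attribute
#'   `table_name` so results can report which table was used.
#' @export
read_eps_table <- function(path) {
  if (!file.exists(path)) abort_inpa(sprintf("dielectric table not found: %s", path))
  df <- utils::read.table(path, comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("resname", "eps"))
  tab <- stats::setNames(as.numeric(df$eps), toupper(df$resname))
  attr(tab, "table_name") <- basename(path)
  tab
}

#' Assign elemental RC impedances to every link
#'
#' Each link of the graph becomes an elemental impedance: a resistance in
#' parallel with a capacitance, `Z = (l/A) / (1/rho + 1i * eps_rel * eps0 * omega)`,
#' where `l` and `A` are the link's length and cross-sectional area and
#' `eps_rel` combines the dielectric constants of its two residues.
#' Geometry is converted from Angstrom to SI here, once, so all electrical
#' arithmetic downstream is in SI units.
#'
#' @param graph a [build_graph()] result.
#' @param params a [material_params()].
#' @return A `link_elements` data frame with columns `i, j, l, A`
#'   (SI: m, m^2), `rho`, `eps_rel`, carrying attributes `n_nodes`, `r_c`,
#'   `eps0` and `table_name`.
#' @export
assign_elements <- function(graph, params = material_params()) {
  resn <- graph$nodes$resname
  eps_node <- unname(params$eps_table[resn])
  unknown <- is.na(eps_node)
  if (any(unknown)) {
    if (is.null(params$eps_default))
      abort_inpa(sprintf("no dielectric value for residue(s): %s",
                         paste(unique(resn[unknown]), collapse = ", ")))
    message(sprintf("assign_elements: default eps = %g used for residue(s): %s",
                    params$eps_default,
                    paste(unique(resn[unknown]), collapse = ", ")))
    eps_node[unknown] <- params$eps_default
  }
  li <- graph$links
  e1 <- eps_node[li$i]; e2 <- eps_node[li$j]
  eps_rel <- if (params$combine == "arithmetic") (e1 + e2) / 2 else sqrt(e1 * e2)
  structure(
    data.frame(i = li$i, j = li$j,
               l = li$l * .phys$ang, A = li$A * .phys$ang^2,
               rho = rep_len(params$rho, nrow(li)), eps_rel = eps_rel),
    n_nodes = nrow(graph$nodes), r_c = graph$r_c, eps0 = params$eps0,
    table_name = params$table_name, combine = params$combine,
    class = c("link_elements", "data.frame"))
}

#' Build uniform elements from an imported edge list
#'
#' For solver-only workflows starting from [read_graph_csv()], where no
#' residue identities are available: every link gets the same resistivity
#' and dielectric constant.
#'
#' @param links data frame `i, j, l, A` in Angstrom units (e.g. from
#'   [read_graph_csv()]).
#' @param rho resistivity, Ohm m.
#' @param eps_rel relative dielectric constant applied to all links.
#' @param n_nodes total node count.
#' @param eps0 vacuum permittivity, F/m.
#' @return A `link_elements` data frame (see [assign_elements()]).
#' @export
elements_from_links <- function(links, rho = 1e10, eps_rel = 4,
                                n_nodes = max(links$i, links$j),
                                eps0 = .phys$eps0) {
  structure(
    data.frame(i = links$i, j = links$j,
               l = links$l * .phys$ang, A = links$A * .phys$ang^2,
               rho = rep_len(rho, nrow(links)),
               eps_rel = rep_len(eps_rel, nrow(links))),
    n_nodes = n_nodes, r_c = attr(links, "r_c") %||% NA_real_, eps0 = eps0,
    table_name = "uniform", combine = "arithmetic",
    class = c("link_elements", "data.frame"))
}

#' Elemental link impedance
#'
#' Complex impedance of each elemental RC link at circular frequency
#' `omega`: `Z = (l/A) / (1/rho + 1i * eps_rel * eps0 * omega)`. At
#' `omega = 0` this is the purely real `rho * l / A`; as `omega` grows the
#' capacitance shorts the link and `|Z| -> 0`.
#'
#' @param elements a `link_elements` data frame ([assign_elements()]).
#' @param omega circular frequency in rad/s (>= 0).
#' @return Complex vector, one impedance per link, in Ohm.
#' @export
link_impedance <- function(elements, omega) {
  if (omega < 0) abort_inpa("omega must be >= 0")
  if (any(elements$l <= 0) || any(elements$A <= 0))
    abort_inpa("link geometry must be positive")
  1 / link_admittance(elements, omega)
}

# Per-link complex admittance Y = (A/l) * (1/rho + i eps eps0 omega), Siemens.
link_admittance <- function(elements, omega) {
  eps0 <- attr(elements, "eps0") %||% .phys$eps0
  (elements$A / elements$l) *
    complex(real = 1 / elements$rho,
            imaginary = elements$eps_rel * eps0 * omega)
}
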