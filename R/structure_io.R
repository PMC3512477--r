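#' Construct a C-alpha chain
#'
#' A `calpha_chain` is the geometric skeleton of a protein: one node per
#' residue at its C-alpha position, with residue identity attached. It is a
#' plain data frame with columns `chain`, `seq`, `resname`, `x`, `y`, `z`
#' (coordinates in Angstrom) and class `calpha_chain`.
#'
#' @param chain_id character vector of chain identifiers.
#' @param seq_index integer residue sequence numbers, strictly increasing
#'   within each chain.
#' @param resname three-letter residue codes.
#' @param x,y,z numeric coordinates in Angstrom; must be finite.
#' @return A `calpha_chain` data frame.
#' @examples
#' calpha_chain("A", 1:2, c("ALA", "GLY"), c(0, 3.8), c(0, 0), c(0, 0))
#' @export
calpha_chain <- function(chain_id, seq_index, resname, x, y, z) {
  df <- data.frame(
    chain = as.character(chain_id),
    seq = as.integer(seq_index),
    resname = toupper(as.character(resname)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  validate_calpha_chain(df)
}

validate_calpha_chain <- function(df) {
  if (nrow(df) < 2L)
    abort_inpa("a C-alpha chain needs at least 2 residues (two contact nodes)")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    abort_inpa("non-finite C-alpha coordinates")
  for (ch in unique(df$chain)) {
    s <- df$seq[df$chain == ch]
    if (any(diff(s) <= 0))
      abort_inpa(sprintf("seq_index not strictly increasing within chain '%s'", ch))
  }
  class(df) <- c("calpha_chain", "data.frame")
  df
}

#' C-alpha coordinate matrix
#'
#' @param chain a [calpha_chain()].
#' @return n x 3 numeric matrix of positions in Angstrom.
#' @export
coords <- function(chain) {
  as.matrix(chain[, c("x", "y", "z"), drop = FALSE])
}

#' @export
print.calpha_chain <- function(x, ...) {
  cat(sprintf("C-alpha chain: %d residues, %d chain(s) [%s]\n",
              nrow(x), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts one node per residue from the ATOM records of a PDB file. Only
#' atoms named `CA` are used; HETATM records are ignored. When a residue has
#' alternate locations, the highest-occupancy one is kept (ties: first
#' listed). Residues are ordered by (chain, resSeq, insertion code); by
#' default all chains of the selected model are concatenated and
#' `chain_filter` narrows the selection. Missing residues (chain breaks) are
#' accepted silently: connectivity is decided by the graph builder, not the
#' reader.
#'
#' @param path path to a PDB file containing ATOM records.
#' @param chain_filter optional character vector of chain ids to keep.
#' @param model_index 1-based model number for multi-model files; an error
#'   is raised when it exceeds the models present.
#' @return A [calpha_chain()].
#' @export
read_calpha_pdb <- function(path, chain_filter = NULL, model_index = 1L) {
  if (!file.exists(path))
    abort_inpa(sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort_inpa(sprintf("failed to parse PDB '%s': %s",
                                           path, conditionMessage(e)))
  )
  nmod <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > nmod)
    abort_inpa(sprintf("model_index %d out of range: file has %d model(s)",
                       model_index, nmod))
  at <- pdb$atom
  sel <- at$type == "ATOM" & at$elety == "CA"
  if (!is.null(chain_filter))
    sel <- sel & at$chain %in% as.character(chain_filter)
  idx <- which(sel)
  if (length(idx) == 0L)
    abort_inpa("no CA atoms after filtering")

  sub <- at[idx, , drop = FALSE]
  icode <- sub$insert
  icode[is.na(icode)] <- ""
  key <- paste(sub$chain, sub$resno, icode, sep = "\r")
  # Alternate locations: keep highest occupancy; which.max keeps the first
  # listed on ties.
  occ <- sub$o
  occ[is.na(occ)] <- 1
  pick <- vapply(split(seq_along(idx), factor(key, levels = unique(key))),
                 function(rows) rows[which.max(occ[rows])], integer(1))
  pick <- unname(pick)
  idx <- idx[pick]
  sub <- at[idx, , drop = FALSE]
  icode <- sub$insert
  icode[is.na(icode)] <- ""

  xyz <- pdb$xyz[model_index, ]
  px <- xyz[3L * (idx - 1L) + 1L]
  py <- xyz[3L * (idx - 1L) + 2L]
  pz <- xyz[3L * (idx - 1L) + 3L]
  if (!all(is.finite(px)) || !all(is.finite(py)) || !all(is.finite(pz)))
    abort_inpa("malformed coordinate fields in PDB file")

  ord <- order(sub$chain, sub$resno, icode)
  df <- data.frame(
    chain = sub$chain[ord], seq = as.integer(sub$resno[ord]),
    resname = toupper(sub$resid[ord]),
    x = px[ord], y = py[ord], z = pz[ord],
    stringsAsFactors = FALSE
  )
  validate_calpha_chain(df)
}

#' Write a C-alpha chain as a minimal PDB file
#'
#' Emits one CA ATOM record per residue using fixed wwPDB v3.3 columns
#' (coordinates to 0.001 Angstrom). Useful for round-tripping skeletons and
#' feeding other structure tools.
#'
#' @param chain a [calpha_chain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(chain, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(chain)), substr(chain$resname, 1, 3),
    substr(chain$chain, 1, 1), chain$seq,
    chain$x, chain$y, chain$z, 1, 0
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Export / import a C-alpha table as CSV
#'
#' Plain CSV with header `chain,seq,resname,x,y,z`, coordinates in Angstrom.
#'
#' @param chain a [calpha_chain()].
#' @param path file path.
#' @return `write_calpha_csv`: `path` invisibly; `read_calpha_csv`: a
#'   [calpha_chain()].
#' @export
write_calpha_csv <- function(chain, path) {
  utils::write.table(as.data.frame(chain)[, c("chain", "seq", "resname", "x", "y", "z")],
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calpha_csv
#' @export
read_calpha_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chain = "character"))
  validate_calpha_chain(df)
}

#' Generate an ideal helical C-alpha chain
#'
#' Deterministic synthetic structure used in place of downloaded PDB
#' entries for desk-scale studies. Defaults are the ideal alpha-helix
#' parameters (rise 1.5 Angstrom, radius 2.3 Angstrom, twist 100 degrees),
#' which give a constant consecutive C-alpha spacing of about 3.8 Angstrom
#' — the mean spacing of real backbone traces.
#'
#' @param n_residues number of residues (>= 2).
#' @param rise per-residue translation along the helix axis, Angstrom.
#' @param radius helix radius, Angstrom.
#' @param twist per-residue rotation, degrees.
#' @param resname residue code applied to every node.
#' @return A [calpha_chain()] along the z axis.
#' @examples
#' h <- make_helix(10)
#' dist(coords(h)[1:2, ])  # ~3.83 Angstrom
#' @export
make_helix <- function(n_residues, rise = 1.5, radius = 2.3, twist = 100,
                       resname = "ALA") {
  if (n_residues < 2L) abort_inpa("n_residues must be >= 2")
  if (rise <= 0 || radius <= 0 || twist <= 0)
    abort_inpa("helix geometry parameters must be positive")
  k <- seq_len(n_residues) - 1L
  th <- k * twist * pi / 180
  calpha_chain("A", seq_len(n_residues), resname,
               radius * cos(th), radius * sin(th), k * rise)
}

#' Build a synthetic native/active conformer pair
#'
#' Emulates the paired deposited structures of a receptor before and after
#' activation: the active conformer is the base chain deformed either by a
#' rigid hinge rotation of its C-terminal half (`mode = "hinge"`, the
#' angle chosen so the RMS displacement of the moved residues equals
#' `displacement`) or by i.i.d. Gaussian coordinate noise with per-atom RMS
#' displacement `displacement` (`mode = "random"`). Deterministic given
#' `seed`; `displacement = 0` returns identical copies.
#'
#' @param base a [calpha_chain()] for the native state.
#' @param displacement target RMS displacement in Angstrom (>= 0).
#' @param mode `"hinge"` or `"random"`.
#' @param seed RNG seed (used by `mode = "random"`).
#' @param label free-text label for the pair.
#' @return A `conformer_pair`: list with elements `native`, `active`,
#'   `label`.
#' @export
make_conformer_pair <- function(base, displacement, mode = c("hinge", "random"),
                                seed = 1L, label = "synthetic") {
  mode <- match.arg(mode)
  if (displacement < 0) abort_inpa("displacement must be >= 0")
  xyz <- coords(base)
  n <- nrow(xyz)
  active <- base
  if (displacement > 0) {
    if (mode == "random") {
      # 3D per-atom RMS displacement d => per-coordinate sigma = d/sqrt(3)
      noise <- with_seed(seed, matrix(stats::rnorm(3L * n, sd = displacement / sqrt(3)),
                                      ncol = 3L))
      xyz <- xyz + noise
    } else {
      h <- floor(n / 2)
      moved <- (h + 1L):n
      pivot <- xyz[h, ]
      rel <- sweep(xyz[moved, , drop = FALSE], 2, pivot)
      dirv <- colMeans(rel)
      dirv <- dirv / sqrt(sum(dirv^2))
      # axis through the pivot, perpendicular to the moved half's mean direction
      ref <- diag(3)[, which.min(abs(dirv))]
      axis <- c(dirv[2] * ref[3] - dirv[3] * ref[2],
                dirv[3] * ref[1] - dirv[1] * ref[3],
                dirv[1] * ref[2] - dirv[2] * ref[1])
      axis <- axis / sqrt(sum(axis^2))
      along <- drop(rel %*% axis)
      perp <- rel - outer(along, axis)
      rms_r <- sqrt(mean(rowSums(perp^2)))
      ang <- 2 * asin(min(1, displacement / (2 * rms_r)))
      K <- matrix(c(0, -axis[3], axis[2],
                    axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      xyz[moved, ] <- sweep(rel %*% t(R), 2, pivot, `+`)
    }
  }
  active$x <- xyz[, 1]; active$y <- xyz[, 2]; active$z <- xyz[, 3]
  structure(list(native = base, active = validate_calpha_chain(as.data.frame(active)),
                 label = label),
            class = "conformer_pair")
}

#' @export
print.conformer_pair <- function(x, ...) {
  cat(sprintf("Conformer pair '%s': native %d residues, active %d residues\n",
              x$label, nrow(x$native), nrow(x$active)))
  invisible(x)
}
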