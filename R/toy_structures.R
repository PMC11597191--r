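# Place atom D from reference atoms A, B, C given bond length |C-D|, bond
# angle B-C-D (degrees) and torsion A-B-C-D (degrees): the standard
# internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(ang), length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# idealized fully extended (phi = psi = omega = 180) poly-Ala backbone with
# O and CB; returns a matrix of coordinates and parallel atom/residue labels
build_extended_chain <- function(n_res, resid = "ALA") {
  coords <- list()
  elety <- character(0); resno <- integer(0)
  # first residue backbone placed explicitly
  N1 <- c(0, 0, 0)
  CA1 <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C1 <- CA1 + c(1.525 * cos(pi - ang), 1.525 * sin(pi - ang), 0)
  bb <- list(list(N = N1, CA = CA1, C = C1))
  for (i in seq_len(n_res - 1) + 1) {
    p <- bb[[i - 1]]
    N <- place_atom(p$N, p$CA, p$C, 1.329, 116.2, 180)   # psi
    CA <- place_atom(p$CA, p$C, N, 1.458, 121.7, 180)    # omega
    C <- place_atom(p$C, N, CA, 1.525, 111.2, 180)       # phi
    bb[[i]] <- list(N = N, CA = CA, C = C)
  }
  for (i in seq_len(n_res)) {
    p <- bb[[i]]
    # carbonyl O opposite the next N (psi + 180); CB off the backbone plane
    O <- place_atom(p$N, p$CA, p$C, 1.231, 120.5, 0)
    atoms <- list(N = p$N, CA = p$CA, C = p$C, O = O)
    if (resid != "GLY") {
      atoms$CB <- place_atom(p$C, p$N, p$CA, 1.521, 110.4, 122.7)
    }
    for (nm in names(atoms)) {
      coords[[length(coords) + 1]] <- atoms[[nm]]
      elety <- c(elety, nm)
      resno <- c(resno, i)
    }
  }
  list(xyz = do.call(rbind, coords), elety = elety, resno = resno,
       resid = rep(resid, length(elety)))
}

chain_tibble <- function(ch, chain_id, resid = NULL, resno_offset = 0L) {
  tibble::tibble(
    chain = chain_id,
    resno = ch$resno + resno_offset,
    insert = "",
    resid = resid %||% ch$resid,
    elety = ch$elety,
    element = substr(ch$elety, 1, 1),
    x = ch$xyz[, 1], y = ch$xyz[, 2], z = ch$xyz[, 3],
    o = 1)
}

#' Generate a toy structure fixture
#'
#' Builds idealized poly-alanine geometries used to exercise the exposure
#' classifier without external structure files:
#' \describe{
#'   \item{`extended_peptide`}{a fully extended chain of `n_res` residues;
#'     every residue is solvent-exposed.}
#'   \item{`packed_lattice`}{an `n_cells^3` cubic lattice of alanine
#'     residues at `spacing` Angstroms; the central residue is buried.}
#'   \item{`beta_arch_fibril`}{`n_layers` copies of a serpentine layer
#'     (three antiparallel extended strands of `strand_len` residues,
#'     `gap` apart) stacked at a `rise` of 4.8 Angstroms, mimicking
#'     cross-beta stacking; middle-strand residues face the packed
#'     interior, outer-strand residues the solvent. Layers are chains
#'     `A`, `B`, ...}
#' }
#'
#' @param kind One of `"extended_peptide"`, `"packed_lattice"`,
#'   `"beta_arch_fibril"`.
#' @param n_res Residues in the extended peptide.
#' @param n_cells Lattice cells per edge.
#' @param spacing Lattice spacing in Angstroms.
#' @param strand_len,gap Serpentine strand length (residues) and
#'   inter-strand spacing (Angstroms).
#' @param n_layers Fibril layers.
#' @param rise Inter-layer rise in Angstroms (default 4.8).
#' @param path Optional output path; when given, a PDB file is written via
#'   [bio3d::write.pdb] and the path returned invisibly.
#' @return A `structure_atoms` tibble (or `path` invisibly).
#' @export
generate_toy_structure <- function(kind = c("extended_peptide",
                                            "packed_lattice",
                                            "beta_arch_fibril"),
                                   n_res = 5L, n_cells = 7L, spacing = 5.0,
                                   strand_len = 7L, gap = 5.0,
                                   n_layers = 5L, rise = 4.8,
                                   path = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_res >= 1, n_cells >= 1, n_layers >= 1, spacing > 0, gap > 0)
  atoms <- switch(kind,
    extended_peptide = chain_tibble(build_extended_chain(n_res), "A"),
    packed_lattice = {
      unit <- build_extended_chain(1L)
      cells <- expand.grid(ix = seq_len(n_cells), iy = seq_len(n_cells),
                           iz = seq_len(n_cells))
      parts <- lapply(seq_len(nrow(cells)), function(k) {
        ch <- unit
        ch$xyz <- sweep(ch$xyz, 2,
                        c(cells$ix[k], cells$iy[k], cells$iz[k]) * spacing,
                        "+")
        chain_tibble(ch, "A", resno_offset = k - 1L)
      })
      dplyr::bind_rows(parts)
    },
    beta_arch_fibril = {
      strand <- build_extended_chain(strand_len)
      layer <- lapply(1:3, function(s) {
        ch <- strand
        if (s == 2) {  # antiparallel middle strand
          ch$xyz[, 1] <- max(strand$xyz[, 1]) - ch$xyz[, 1]
        }
        ch$xyz[, 2] <- ch$xyz[, 2] + (s - 1) * gap
        chain_tibble(ch, "X", resno_offset = (s - 1L) * strand_len)
      })
      layer <- dplyr::bind_rows(layer)
      parts <- lapply(seq_len(n_layers), function(l) {
        lt <- layer
        lt$z <- lt$z + (l - 1) * rise
        lt$chain <- LETTERS[l]
        lt
      })
      dplyr::bind_rows(parts)
    })
  atoms <- structure(atoms, structure_id = paste0("toy_", kind),
                     class = c("structure_atoms", class(atoms)))
  if (!is.null(path)) {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     resno = atoms$resno, resid = atoms$resid,
                     chain = atoms$chain, elety = atoms$elety,
                     o = atoms$o, b = rep(0, nrow(atoms)))
    return(invisible(path))
  }
  atoms
}
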