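AA3_STANDARD <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# van der Waals radii by element (A)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Reference maximal solvent-accessible surface areas
#'
#' Theoretical maximum SASA per residue type in an extended Gly-X-Gly
#' reference peptide (Tien et al. 2013, theoretical values), in square
#' Angstroms, used to normalise residue SASA to relative exposure. The
#' table is replaceable.
#'
#' @return Named numeric vector, names are 3-letter residue codes.
#' @export
max_sasa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

# heavy-atom counts per residue type, used to flag incomplete residues
HEAVY_ATOMS_EXPECTED <- c(ALA = 5, ARG = 11, ASN = 8, ASP = 8, CYS = 6,
                          GLN = 9, GLU = 9, GLY = 4, HIS = 10, ILE = 8,
                          LEU = 8, LYS = 9, MET = 8, PHE = 11, PRO = 7,
                          SER = 6, THR = 7, TRP = 14, TYR = 12, VAL = 7)

#' Read a protein structure (PDB or mmCIF)
#'
#' Parses atom records via bio3d, keeping author residue numbering and
#' insertion codes. Alternate locations are resolved to the highest
#' occupancy conformer (ties break to the first listed). Non-protein
#' residues are dropped; chains left without protein residues are skipped
#' with a warning.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return A `structure_atoms` tibble: `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`, `o`; attribute `structure_id` is the
#'   file name without extension.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    switch(ext,
           pdb = bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
           cif = bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
           stop("unsupported structure format: .", ext, call. = FALSE)),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains_all <- unique(at$chain)
  at <- at[at$resid %in% AA3_STANDARD, , drop = FALSE]
  dropped <- setdiff(chains_all, unique(at$chain))
  if (length(dropped) > 0) {
    warning("chain(s) without protein residues skipped: ",
            paste(dropped, collapse = ", "))
  }
  if (nrow(at) == 0) stop("no protein atoms in '", path, "'", call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest occupancy per atom site
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
           drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert), , drop = FALSE]
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(gsub("[0-9]", "", trimws(at$elety)), 1, 1)
  }
  out <- tibble::tibble(chain = at$chain, resno = at$resno,
                        insert = at$insert, resid = at$resid,
                        elety = trimws(at$elety),
                        element = toupper(trimws(element)),
                        x = at$x, y = at$y, z = at$z, o = at$o)
  structure(out,
            structure_id = tools::file_path_sans_ext(basename(path)),
            class = c("structure_atoms", class(out)))
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-sampling SASA: each atom is inflated by the probe radius and
#' covered with a deterministic quasi-uniform point lattice; the accessible
#' area is the fraction of points not inside any neighbouring inflated
#' atom.
#'
#' @param atoms A `structure_atoms` tibble (or any tibble with `element`,
#'   `x`, `y`, `z`).
#' @param probe Probe radius in Angstroms (default 1.4, a water molecule).
#' @param n_points Sample points per atom (default 960).
#' @return Numeric vector of per-atom areas in square Angstroms.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  n <- nrow(atoms)
  radii <- unname(VDW_RADII[atoms$element])
  radii[is.na(radii)] <- 1.70
  rp <- radii + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  pts <- fibonacci_sphere(n_points)
  # neighbour lists from the full distance matrix (structures here are small)
  d2 <- as.matrix(stats::dist(xyz))^2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (rp[i] + rp)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    p_i <- pts * rp[i]
    p_i <- sweep(p_i, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p_i[acc, 1] - xyz[j, 1]
      dy <- p_i[acc, 2] - xyz[j, 2]
      dz <- p_i[acc, 3] - xyz[j, 3]
      acc[acc] <- (dx * dx + dy * dy + dz * dz) >= rp[j]^2
    }
    areas[i] <- 4 * pi * rp[i]^2 * sum(acc) / n_points
  }
  areas
}

#' Relative solvent exposure per residue
#'
#' Computes residue SASA for one chain, optionally in the occluding context
#' of neighbouring chains (which are not themselves reported), and
#' normalises to a relative exposure. The default reference
#' (`"isolated"`) divides by the SASA of the same residue's atoms computed
#' in isolation, which bounds relative exposure in \[0, 1\] and is exact
#' for incomplete residues; alternatively a named per-residue-type maximum
#' table such as [max_sasa_reference()] can be supplied. Residues with
#' missing heavy atoms are flagged low-confidence but still computed.
#'
#' @param atoms A `structure_atoms` tibble.
#' @param chain Chain identifier to report.
#' @param context_chains Chains that occlude but are not reported
#'   (character vector, or `"all"` for every other chain; default none).
#' @param probe Probe radius (default 1.4 A).
#' @param n_points Sample points per atom.
#' @param reference `"isolated"` (default) or a named numeric vector of
#'   reference maxima by 3-letter residue code.
#' @return Tibble of per-residue exposures: `structure_id`, `chain`,
#'   `resno`, `insert`, `resid`, `sasa`, `relative_exposure`, `n_atoms`,
#'   `low_confidence`.
#' @export
compute_relative_exposure <- function(atoms, chain,
                                      context_chains = character(0),
                                      probe = 1.4, n_points = 960L,
                                      reference = "isolated") {
  if (!chain %in% atoms$chain) stop("chain '", chain, "' not in structure",
                                    call. = FALSE)
  if (identical(context_chains, "all")) {
    context_chains <- setdiff(unique(atoms$chain), chain)
  }
  sel <- atoms$chain %in% c(chain, context_chains)
  sub <- atoms[sel, , drop = FALSE]
  areas <- shrake_rupley_sasa(sub, probe = probe, n_points = n_points)
  own <- which(sub$chain == chain)
  df <- tibble::tibble(resno = sub$resno[own], insert = sub$insert[own],
                       resid = sub$resid[own], area = areas[own],
                       atom_row = own)
  res <- df |>
    dplyr::group_by(.data$resno, .data$insert, .data$resid) |>
    dplyr::summarise(sasa = sum(.data$area), n_atoms = dplyr::n(),
                     rows = list(.data$atom_row), .groups = "drop") |>
    dplyr::arrange(.data$resno, .data$insert)
  if (identical(reference, "isolated")) {
    res$reference_sasa <- vapply(res$rows, function(rr) {
      sum(shrake_rupley_sasa(sub[rr, , drop = FALSE], probe = probe,
                             n_points = n_points))
    }, numeric(1))
  } else {
    stopifnot(is.numeric(reference), !is.null(names(reference)))
    res$reference_sasa <- unname(reference[res$resid])
  }
  res$relative_exposure <- res$sasa / res$reference_sasa
  res$low_confidence <- res$n_atoms <
    unname(HEAVY_ATOMS_EXPECTED[res$resid])
  res$low_confidence[is.na(res$low_confidence)] <- TRUE
  tibble::tibble(structure_id = attr(atoms, "structure_id") %||% "structure",
                 chain = chain, res[, c("resno", "insert", "resid", "sasa",
                                        "reference_sasa", "relative_exposure",
                                        "n_atoms", "low_confidence")])
}

#' Classify residues as surface, core or interface
#'
#' Positions in `interface_positions` (by default the conserved
#' heavy-chain-contact set, IMGT 42, 44, 49, 52, 55, 103 and 118) are
#' classified `interface` regardless of exposure; otherwise residues with
#' relative exposure at or above `threshold` (default 10%) are `surface`,
#' below it `core`. Residues within 2 percentage points of the threshold
#' get the `low_confidence` flag (replacing the manual review of borderline
#' residues with a deterministic rule).
#'
#' @param exposure Tibble from [compute_relative_exposure()], optionally
#'   with an `imgt_num` column added by [map_structure_numbering()].
#' @param interface_positions Integer set of interface IMGT positions.
#' @param threshold Relative-exposure threshold (default 0.10).
#' @return The input with `classification` (and updated `low_confidence`).
#' @export
classify_residues <- function(exposure,
                              interface_positions = c(42L, 44L, 49L, 52L,
                                                      55L, 103L, 118L),
                              threshold = 0.10) {
  pos <- if ("imgt_num" %in% names(exposure)) exposure$imgt_num
         else exposure$resno
  cls <- ifelse(exposure$relative_exposure >= threshold, "surface", "core")
  cls[!is.na(pos) & pos %in% interface_positions] <- "interface"
  exposure$classification <- cls
  exposure$low_confidence <- exposure$low_confidence |
    abs(exposure$relative_exposure - threshold) < 0.02
  exposure
}

#' Attach IMGT numbering to a structure chain's residues
#'
#' Maps the i-th residue of the exposure table (in residue order) to the
#' i-th residue of the numbered sequence for that chain; the two must have
#' the same length.
#'
#' @param exposure Tibble from [compute_relative_exposure()].
#' @param ns A `numbered_sequence` for the chain's sequence.
#' @return The exposure tibble with `imgt_position` and `imgt_num` columns.
#' @export
map_structure_numbering <- function(exposure, ns) {
  if (nrow(exposure) != nrow(ns)) {
    stop("numbering failure: structure chain has ", nrow(exposure),
         " residues but the numbered sequence has ", nrow(ns), call. = FALSE)
  }
  exposure$imgt_position <- ns$imgt
  exposure$imgt_num <- ns$imgt_num
  exposure
}

#' Map sequon positions onto a structure
#'
#' Labels every sequon position of a positional histogram as surface, core,
#' interface or unresolved for one structure. Positions without coordinates
#' in the structure are `unresolved`. For fibrils, exposures should be
#' computed in assembly context (the chain plus stacked neighbour layers).
#'
#' @param histogram Named count vector from [position_histogram()].
#' @param exposure Classified exposure tibble (with `imgt_num`), from
#'   [classify_residues()].
#' @param structure_id Identifier for the report (defaults to the
#'   exposure's).
#' @param positions Which positions to report: `"observed"` (count > 0,
#'   default) or `"all"`.
#' @return Tibble: `structure_id`, `imgt_position`, `sequon_count`,
#'   `classification`, `relative_exposure` (`NA` when unresolved).
#' @export
map_positions_to_structure <- function(histogram, exposure,
                                       structure_id = NULL,
                                       positions = c("observed", "all")) {
  positions <- match.arg(positions)
  if (!"classification" %in% names(exposure)) {
    stop("exposure must be classified first (see classify_residues)",
         call. = FALSE)
  }
  pos <- as.integer(names(histogram))
  if (positions == "observed") pos <- pos[histogram > 0]
  sid <- structure_id %||% exposure$structure_id[1]
  m <- match(pos, exposure$imgt_num)
  tibble::tibble(
    structure_id = sid,
    imgt_position = pos,
    sequon_count = as.integer(histogram[as.character(pos)]),
    classification = ifelse(is.na(m), "unresolved", exposure$classification[m]),
    relative_exposure = ifelse(is.na(m), NA_real_,
                               exposure$relative_exposure[m]))
}
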