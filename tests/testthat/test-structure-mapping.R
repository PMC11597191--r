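atom_row <- function(x, y, z, elety = "CA", element = "C", resno = 1L,
                     chain = "A", resid = "ALA") {
  tibble::tibble(chain = chain, resno = resno, insert = "", resid = resid,
                 elety = elety, element = element, x = x, y = y, z = z, o = 1)
}

test_that("sampled SASA matches closed-form sphere areas", {
  # isolated atom: full inflated sphere
  one <- atom_row(0, 0, 0)
  expect_equal(shrake_rupley_sasa(one), 4 * pi * 3.1^2, tolerance = 1e-6)
  # two equal spheres: analytic spherical-cap areas
  for (d in c(1.5, 2.5, 4.0, 6.5)) {
    two <- dplyr::bind_rows(atom_row(0, 0, 0), atom_row(d, 0, 0, resno = 2L))
    got <- shrake_rupley_sasa(two)
    exact <- oracle_two_sphere_area(3.1, 3.1, d)
    expect_equal(got[1], exact, tolerance = 0.01 * 4 * pi * 3.1^2)
    expect_equal(got[2], exact, tolerance = 0.01 * 4 * pi * 3.1^2)
  }
  # unequal radii (C vs O)
  two <- dplyr::bind_rows(atom_row(0, 0, 0),
                          atom_row(2, 0, 0, elety = "O", element = "O",
                                   resno = 2L))
  got <- shrake_rupley_sasa(two)
  expect_equal(got[1], oracle_two_sphere_area(3.1, 2.92, 2),
               tolerance = 0.01 * 4 * pi * 3.1^2)
})

test_that("an isolated residue has relative exposure one by construction", {
  ep <- generate_toy_structure("extended_peptide", n_res = 1)
  ex <- compute_relative_exposure(ep, "A")
  expect_equal(ex$relative_exposure, 1, tolerance = 1e-9)
})

test_that("extended peptide residues are surface at the 10% threshold", {
  ep <- generate_toy_structure("extended_peptide", n_res = 5)
  ex <- classify_residues(compute_relative_exposure(ep, "A"))
  expect_gt(ex$relative_exposure[3], 0.4)
  expect_true(all(ex$classification == "surface"))
})

test_that("packed-lattice centre is core; classification is threshold-monotone", {
  lat <- generate_toy_structure("packed_lattice", n_cells = 5, spacing = 5.0)
  ex <- compute_relative_exposure(lat, "A")
  centre <- 3 + 2 * 5 + 2 * 25  # middle cell of the 5^3 grid
  rel <- ex$relative_exposure[ex$resno == centre]
  expect_lt(rel, 0.10)
  cls <- classify_residues(ex)
  expect_identical(cls$classification[cls$resno == centre], "core")
  # raising the threshold never moves a residue from core to surface
  for (thr in c(0.05, 0.10, 0.20, 0.40)) {
    lo <- classify_residues(ex, threshold = thr)
    hi <- classify_residues(ex, threshold = thr + 0.1)
    expect_false(any(lo$classification == "core" &
                       hi$classification == "surface"))
  }
})

test_that("assembly context can only reduce per-residue SASA", {
  fib <- generate_toy_structure("beta_arch_fibril", strand_len = 5,
                                n_layers = 3)
  iso <- compute_relative_exposure(fib, "B")
  ctx <- compute_relative_exposure(fib, "B", context_chains = "all")
  expect_true(all(ctx$sasa <= iso$sasa + 1e-6))
})

test_that("fibril interior faces are core, outer faces surface", {
  fib <- generate_toy_structure("beta_arch_fibril", strand_len = 7,
                                gap = 5.0, n_layers = 5)
  ex <- classify_residues(
    compute_relative_exposure(fib, "C", context_chains = "all"))
  # middle strand of the serpentine (residues 8-14), interior residues
  expect_true(all(ex$classification[ex$resno %in% 9:12] == "core"))
  # outer strand termini face the solvent
  expect_identical(ex$classification[ex$resno == 1], "surface")
  expect_identical(ex$classification[ex$resno == 21], "surface")
})

test_that("interface positions are classified interface regardless of exposure", {
  ep <- generate_toy_structure("extended_peptide", n_res = 7)
  ex <- compute_relative_exposure(ep, "A")
  ex$imgt_num <- c(42L, 44L, 49L, 52L, 55L, 103L, 118L)
  cls <- classify_residues(ex)
  expect_true(all(cls$classification == "interface"))
  # position 86 classified by exposure alone
  ex$imgt_num <- rep(86L, 7)
  ex$relative_exposure <- c(0.02, 0.5, 0.10, 0.099, 0.8, 0.0, 1.0)
  cls <- classify_residues(ex)
  expect_identical(cls$classification,
                   c("core", "surface", "surface", "core", "surface",
                     "core", "surface"))
})

test_that("PDB round-trip preserves residues; sequon mapping reports unresolved", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure("extended_peptide", n_res = 3, path = tmp)
  st <- read_structure(tmp)
  expect_identical(unique(st$chain), "A")
  expect_identical(sort(unique(st$resno)), 1:3)
  expect_identical(nrow(st), 15L)  # 5 heavy atoms per alanine
  ex <- classify_residues(compute_relative_exposure(st, "A"))
  ex$imgt_num <- c(85L, 86L, 87L)
  hist <- setNames(integer(125), as.character(1:125))
  hist[c("86", "90")] <- c(3L, 1L)
  rep <- map_positions_to_structure(hist, ex)
  expect_identical(rep$classification[rep$imgt_position == 86], "surface")
  expect_identical(rep$classification[rep$imgt_position == 90], "unresolved")
  expect_identical(rep$sequon_count, c(3L, 1L))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60 10.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "END"), tmp)
  st <- read_structure(tmp)
  expect_identical(nrow(st), 2L)
  expect_equal(st$x[st$elety == "N"], 5.0)
})
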