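test_that("detectable-position rule", {
  expect_identical(count_detectable_positions(127, 3), 125L)
  expect_identical(count_detectable_positions(127, 1), 127L)
  expect_identical(count_detectable_positions(3, 3), 1L)
  expect_error(count_detectable_positions(2, 3), "scaffold_size")
  expect_error(count_detectable_positions(3, 0), "scaffold_size")
})

test_that("region and strand maps tile without overlap and label correctly", {
  rm <- default_region_map()
  expect_setequal(rm$region, c("FR1", "CDR1", "FR2", "CDR2", "FR3",
                               "CDR3", "FR4"))
  covered <- unlist(Map(seq, rm$start, rm$end))
  expect_setequal(covered, 1:127)
  expect_identical(position_label(86L, rm), "FR3")
  expect_identical(position_label(109L, rm), "CDR3")
  expect_identical(position_label(1L, rm), "FR1")
  sm <- default_strand_map()
  expect_identical(position_label(c(75L, 86L, 88L), sm), c("D", "E", "E"))
})

test_that("germline self-numbering is the identity", {
  set <- bundled_set()
  for (g in c("IGKV1-33", "IGLV2-14", "IGLV6-57")) {
    v <- get_germline(set, g)
    ref <- concat_germline(v, default_j_gene(set, v$locus))
    ns <- number_sequence(ref$sequence, g, set, sequence_id = g)
    expect_identical(ns$imgt_num, ref$imgt_positions)
    expect_identical(paste(ns$aa, collapse = ""), ref$sequence)
    expect_false(any(ns$insertion))
  }
})

test_that("identical query aligns with zero gaps and mismatches", {
  set <- bundled_set()
  v <- get_germline(set, "IGKV1-33")
  aln <- align_to_germline(v$sequence, v)
  expect_false(grepl("-", aln$query_aligned))
  expect_false(grepl("-", aln$germline_aligned))
  expect_identical(aln$identity, 1)
})

test_that("deletions leave the germline position unoccupied", {
  set <- bundled_set()
  v <- get_germline(set, "IGKV1-33")
  ref <- concat_germline(v, default_j_gene(set, "IGK"))
  i75 <- match(75L, ref$imgt_positions)
  qdel <- paste(strsplit(ref$sequence, "")[[1]][-i75], collapse = "")
  ns <- number_sequence(qdel, "IGKV1-33", set)
  expect_false(75L %in% ns$imgt_num)
  expect_identical(paste(ns$aa, collapse = ""), qdel)
})

test_that("insertions get markers anchored to the preceding position", {
  set <- bundled_set()
  v <- get_germline(set, "IGKV1-33")
  ref <- concat_germline(v, default_j_gene(set, "IGK"))
  res <- strsplit(ref$sequence, "")[[1]]
  i50 <- match(50L, ref$imgt_positions)
  qins <- paste(c(res[1:i50], "G", "G", "G", res[(i50 + 1):length(res)]),
                collapse = "")
  ns <- number_sequence(qins, "IGKV1-33", set)
  ins <- ns[ns$insertion, ]
  expect_identical(nrow(ins), 3L)
  expect_identical(ins$imgt, c("50.1", "50.2", "50.3"))
  expect_identical(unique(ins$region), "FR2")
  expect_identical(paste(ns$aa, collapse = ""), qins)
})

test_that("CDR3 length variants fill canonical positions inward", {
  set <- bundled_set()
  v <- get_germline(set, "IGLV2-14")
  j <- default_j_gene(set, "IGL")
  res_v <- strsplit(v$sequence, "")[[1]]
  fr3_end <- match(104L, v$imgt_positions)
  for (k in 5:15) {
    cdr3 <- strrep("G", k - 2)  # plus the two J-encoded CDR3 residues
    q <- paste0(paste(res_v[1:fr3_end], collapse = ""), cdr3, j$sequence)
    ns <- number_sequence(q, "IGLV2-14", set, sequence_id = paste0("len", k))
    expect_identical(paste(ns$aa, collapse = ""), q)
    got <- ns$imgt_num[!is.na(ns$imgt_num) & ns$imgt_num >= 105 &
                         ns$imgt_num <= 117]
    n_can <- min(k, 13)
    expected <- sort(c(104 + seq_len(min(ceiling(k / 2), 7)),
                       117 - rev(seq_len(min(floor(k / 2), 6))) + 1))
    expect_identical(got, as.integer(expected))
    expect_identical(sum(ns$insertion), max(0L, as.integer(k - 13)))
    # canonical positions unique and increasing
    can <- ns$imgt_num[!is.na(ns$imgt_num)]
    expect_false(is.unsorted(can, strictly = TRUE))
    expect_identical(nrow(ns), nchar(q))
  }
})

test_that("alignment scores equal the brute-force DP oracle", {
  mat <- blosum62()
  set.seed(11)
  for (t in 1:60) {
    a <- paste(sample(c("A", "C", "D", "G", "N", "S", "T", "W"),
                      sample(3:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "G", "N", "S", "T", "W"),
                      sample(3:30, 1), replace = TRUE), collapse = "")
    germ <- structure(list(gene = "g", locus = "IGK", sequence = b,
                           imgt_positions = seq_len(nchar(b)),
                           encoded_sequons = integer(0),
                           progenitor_sites = integer(0)),
                      class = "germline_record")
    aln <- suppressWarnings(align_to_germline(a, germ))
    expect_equal(aln$score, oracle_align_score(a, b, mat))
  }
})

test_that("non-standard residues and empty queries are rejected", {
  set <- bundled_set()
  v <- get_germline(set, "IGKV1-33")
  expect_error(align_to_germline("DIQX", v, sequence_id = "bad1"), "bad1")
  expect_error(align_to_germline("", v, sequence_id = "bad2"), "empty")
})

test_that("low-identity alignments are flagged dubious", {
  set <- bundled_set()
  v <- get_germline(set, "IGKV1-33")
  expect_warning(
    aln <- align_to_germline(strrep("W", 40), v, sequence_id = "junk"),
    "dubious")
  expect_true(aln$dubious)
})
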