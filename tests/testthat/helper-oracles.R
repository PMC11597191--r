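# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force affine-gap global alignment score (Gotoh), gap of length L
# costing open + ext * L -- the same convention as the implementation's
# alignment engine, but computed by explicit dynamic programming
oracle_align_score <- function(a, b, mat, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force sequon scan: test every index explicitly
oracle_scan <- function(s, kind = "NxST") {
  res <- strsplit(s, "")[[1]]
  L <- length(res)
  hits <- integer(0)
  if (L >= 3) {
    for (i in 1:(L - 2)) {
      ok <- res[i] == "N" && res[i + 1] != "P" &&
        (if (kind == "NxST") res[i + 2] %in% c("S", "T")
         else res[i + 2] == "C")
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# exact accessible area of two intersecting spheres of equal radius R at
# distance d (area of sphere 1 outside sphere 2)
oracle_two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}

# the BLOSUM62 matrix, loaded once
local({
  env <- new.env(parent = emptyenv())
  blosum62 <<- function() {
    if (is.null(env$mat)) {
      data("BLOSUM62", package = "Biostrings", envir = env)
      env$mat <- env$BLOSUM62
    }
    env$mat
  }
})

# cached, progenitor-annotated bundled germline set
local({
  env <- new.env(parent = emptyenv())
  bundled_set <<- function() {
    if (is.null(env$set)) {
      env$set <- annotate_progenitor_sites(read_germline_set())
    }
    env$set
  }
})

# IMGT positions of detected first sequons for indel-free synthetic
# sequences: with indels off, the i-th residue of a generated sequence sits
# at the i-th position of its V+J reference, so no alignment is needed
truth_aligned_histogram <- function(repertoire, set) {
  counts <- setNames(integer(125), as.character(1:125))
  refs <- list()
  for (i in seq_len(nrow(repertoire))) {
    v <- repertoire$v_call[i]
    if (is.null(refs[[v]])) {
      vg <- get_germline(set, v)
      refs[[v]] <- concat_germline(vg, default_j_gene(set, vg$locus))
    }
    idx <- oracle_scan(repertoire$sequence_aa[i])
    if (length(idx) == 0) next
    p <- refs[[v]]$imgt_positions[idx[1]]
    if (!is.na(p) && p >= 1 && p <= 125) {
      counts[as.character(p)] <- counts[as.character(p)] + 1L
    }
  }
  counts
}

# uniform usage over a few kappa or lambda genes from the bundled set
usage_kappa <- function() setNames(rep(0.25, 4),
  c("IGKV1-33", "IGKV1-39", "IGKV1-16", "IGKV3-20"))
usage_lambda <- function() setNames(rep(0.25, 4),
  c("IGLV2-14", "IGLV1-44", "IGLV1-51", "IGLV3-1"))
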