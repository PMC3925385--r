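# Shared in-code fixtures: a tiny hand-built reference library and a
# brute-force alignment-score oracle.

rand_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else barcodediet:::with_seed(seed, draw())
}

# substitute k positions of a sequence (deterministic positions, any-base swap)
mutate_at <- function(seq, pos, to = NULL) {
  x <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  x[pos] <- if (is.null(to)) rot[x[pos]] else to
  paste(x, collapse = "")
}

# two families in one order, two genera each, two species per genus
tiny_db <- function(seq_length = 60, seed = 7) {
  base <- rand_seq(seq_length, seed)
  fam <- c("Asellidae", "Palaemonidae")
  recs <- list()
  k <- 0
  for (fi in 1:2) for (gi in 1:2) for (si in 1:2) {
    k <- k + 1
    # carve divergence blocks so families > genera > species differences
    s <- base
    if (fi == 2) s <- mutate_at(s, 1:12)
    if (gi == 2) s <- mutate_at(s, 16:21)
    if (si == 2) s <- mutate_at(s, 25:27)
    g <- paste0("Genus", fi, gi)
    recs[[k]] <- data.frame(
      accession = sprintf("ACC%02d", k), sequence = s,
      phylum = "Arthropoda", class = "Malacostraca", order = "Isopoda",
      family = fam[fi], genus = g,
      species = paste0(g, " species", si), stringsAsFactors = FALSE)
  }
  reference_db(do.call(rbind, recs))
}

# exhaustive enumeration of all global alignments of a and b, scored with
# the same affine convention as the aligner (each gap run costs
# gap_open + length * gap_extend); independent of any DP implementation
brute_force_align_score <- function(a, b, params = alignment_params()) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  score_cols <- function(ca, cb) {
    s <- 0
    run_a <- 0; run_b <- 0
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        run_a <- run_a + 1
        s <- s - params$gap_extend - if (run_a == 1) params$gap_open else 0
      } else run_a <- 0
      if (cb[k] == "-") {
        run_b <- run_b + 1
        s <- s - params$gap_extend - if (run_b == 1) params$gap_open else 0
      } else run_b <- 0
      if (ca[k] != "-" && cb[k] != "-") {
        s <- s + if (ca[k] == cb[k]) params$match else params$mismatch
      }
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score_cols(ca, cb)); return(invisible())
    }
    if (i <= length(a) && j <= length(b)) rec(i + 1, j + 1, c(ca, a[i]), c(cb, b[j]))
    if (i <= length(a)) rec(i + 1, j, c(ca, a[i]), c(cb, "-"))
    if (j <= length(b)) rec(i, j + 1, c(ca, "-"), c(cb, b[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}
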