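test_that("p-distance and K2P match their closed forms", {
  a <- paste(rep("A", 100), collapse = "")
  ts1 <- paste(c("G", rep("A", 99)), collapse = "")     # one transition
  tv1 <- paste(c("C", rep("A", 99)), collapse = "")     # one transversion
  expect_equal(p_distance(a, a), 0)
  expect_equal(p_distance(a, ts1), 0.01)
  expect_equal(k2p_distance(a, a), 0)
  expect_equal(k2p_distance(a, ts1), -0.5 * log(0.98), tolerance = 1e-12)
  expect_equal(k2p_distance(a, tv1), -0.5 * log(0.99) - 0.25 * log(0.98),
               tolerance = 1e-12)
  sat <- paste(rep(c("G", "C"), 50), collapse = "")
  expect_error(k2p_distance(a, sat), "saturated")
})

test_that("K2P agrees with an independent distance implementation", {
  skip_if_not_installed("ape")
  barcodediet:::with_seed(17, {
    for (i in 1:5) {
      a <- rand_seq(300)
      b <- mutate_at(a, sample(300, 30))
      bin <- ape::as.DNAbin(rbind(a = strsplit(tolower(a), "")[[1]],
                                  b = strsplit(tolower(b), "")[[1]]))
      expect_equal(k2p_distance(a, b),
                   as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-10)
      expect_gte(k2p_distance(a, b), p_distance(a, b))
    }
  })
})

test_that("NJ solves the three-taxon case in closed form", {
  m <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))
  expect_error(nj_tree(m[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive four-taxon trees exactly", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  m <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(m)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr0)), 0,
               ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(m), colnames(m)] - m)), 1e-9)
})

test_that("NJ recovers random additive trees and matches an independent NJ", {
  barcodediet:::with_seed(23, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      tr0 <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
      m <- ape::cophenetic.phylo(tr0)
      m <- m[sort(rownames(m)), sort(rownames(m))]
      tr <- nj_tree(m)
      expect_equal(ape::dist.topo(ape::unroot(tr), tr0), 0, ignore_attr = TRUE)
      expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(m), colnames(m)] - m)),
                1e-9)
      # noisy matrix: same topology as ape's NJ (independent implementation)
      m2 <- m + matrix(runif(n * n, 0, 0.02), n, n)
      m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
      expect_equal(ape::dist.topo(ape::unroot(nj_tree(m2)),
                                  ape::unroot(ape::nj(m2))), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("an all-zero matrix yields a zero-length star-like tree", {
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(m)
  expect_equal(sum(tr$edge.length), 0)
  expect_setequal(tr$tip.label, LETTERS[1:4])
})

test_that("negative NJ branch lengths are clamped and logged", {
  m <- matrix(c(0, 1, 5, 4,
                1, 0, 6, 5,
                5, 6, 0, 1,
                4, 5, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 0.01   # force a negative pendant estimate
  tr <- nj_tree(m)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped_deficit"), 0)
})

test_that("bootstrap supports are deterministic under seed and lie in [0,100]", {
  seqs <- c(A = rand_seq(200, seed = 41))
  seqs["B"] <- mutate_at(seqs[["A"]], 1:4)
  seqs["C"] <- mutate_at(seqs[["A"]], 41:90)
  seqs["D"] <- mutate_at(seqs[["C"]], 5:8)
  t1 <- bootstrap_supports(seqs, bootstrap_config(n_replicates = 100, seed = 5))
  t2 <- bootstrap_supports(seqs, bootstrap_config(n_replicates = 100, seed = 5))
  expect_identical(t1$node.label, t2$node.label)
  sup <- attr(t1, "support")
  expect_true(all(sup >= 0 & sup <= 100, na.rm = TRUE))
  expect_error(bootstrap_supports(seqs[1:3], bootstrap_config(10)), "at least 4")
})

test_that("an unambiguous split gets ~100% support, label order irrelevant", {
  # 200 columns uniformly supporting AB|CD, none conflicting
  block <- function(ab, cd) c(A = ab, B = ab, C = cd, D = cd)
  cols <- replicate(200, block("A", "G"))
  seqs <- apply(cols, 1, paste, collapse = "")
  # pendant-only variation so tips are distinct
  seqs["B"] <- mutate_at(seqs[["B"]], 1:3)
  seqs["D"] <- mutate_at(seqs[["D"]], 7:9)
  tr <- bootstrap_supports(seqs, bootstrap_config(n_replicates = 200, seed = 1))
  key <- barcodediet:::tree_splits(tr)
  sup <- attr(tr, "support")[names(key)]
  expect_equal(as.numeric(sup[key == "C|D"]), 100)
  # permuting the input leaves the split's support unchanged
  tr2 <- bootstrap_supports(seqs[c("D", "B", "C", "A")],
                            bootstrap_config(n_replicates = 200, seed = 1))
  key2 <- barcodediet:::tree_splits(tr2)
  expect_equal(as.numeric(attr(tr2, "support")[names(key2)[key2 == "C|D"]]), 100)
})

test_that("newick round-trip preserves topology, lengths and supports", {
  seqs <- c(A = rand_seq(120, seed = 43))
  seqs["B"] <- mutate_at(seqs[["A"]], 1:3)
  seqs["C"] <- mutate_at(seqs[["A"]], 30:60)
  seqs["D"] <- mutate_at(seqs[["C"]], 5:7)
  tr <- bootstrap_supports(seqs, bootstrap_config(n_replicates = 50, seed = 2))
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length), tolerance = 1e-9)
})

test_that("sequences project onto reference coordinates at reference length", {
  ref <- rand_seq(80, seed = 47)
  ins <- paste0(substr(ref, 1, 40), "TTTTT", substr(ref, 41, 80))  # insertion
  del <- paste0(substr(ref, 1, 30), substr(ref, 36, 80))           # deletion
  al <- align_to_reference(c(q1 = ins, q2 = del), ref)
  expect_true(all(nchar(al) == 80))
  expect_identical(al[["reference"]], ref)
  expect_true(grepl("-", al[["q2"]], fixed = TRUE))
})
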