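test_that("identical sequences align without gaps at full identity", {
  aln <- global_align("ACGT", "ACGT")
  expect_identical(aln$a, "ACGT")
  expect_identical(aln$b, "ACGT")
  expect_equal(percent_identity("ACGT", "ACGT")$percent_identity, 100)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment scores match a brute-force enumeration oracle", {
  cases <- list(c("ACGT", "ACT"), c("AAGG", "AGG"), c("ACGTAC", "ACTAC"),
                c("TTTT", "TATA"), c("GATTAC", "GATACA"))
  for (ps in list(alignment_params(),
                  alignment_params(match = 1, mismatch = -1,
                                   gap_open = 0, gap_extend = 1))) {
    for (cs in cases) {
      expect_equal(global_align(cs[1], cs[2], ps)$score,
                   brute_force_align_score(cs[1], cs[2], ps),
                   info = paste(cs, collapse = " vs "))
    }
  }
  # and on random short pairs
  barcodediet:::with_seed(11, {
    for (i in 1:10) {
      a <- rand_seq(sample(3:6, 1)); b <- rand_seq(sample(3:6, 1))
      expect_equal(global_align(a, b)$score, brute_force_align_score(a, b))
    }
  })
})

test_that("low-divergence equal-length pairs align without gaps", {
  a <- rand_seq(658, seed = 3)
  b <- mutate_at(a, 50 * (1:13))
  aln <- global_align(a, b)
  expect_equal(nchar(aln$a), 658)
  expect_false(grepl("-", aln$a, fixed = TRUE) || grepl("-", aln$b, fixed = TRUE))
})

test_that("identity arithmetic brackets the 98% species threshold", {
  a <- rand_seq(658, seed = 5)
  b13 <- mutate_at(a, 50 * (1:13))
  b14 <- mutate_at(a, 45 * (1:14))
  expect_equal(percent_identity(a, b13)$percent_identity, 100 * 645 / 658)
  expect_gte(percent_identity(a, b13)$percent_identity, 98)
  expect_equal(percent_identity(a, b14)$percent_identity, 100 * 644 / 658)
  expect_lt(percent_identity(a, b14)$percent_identity, 98)
})

test_that("identity excludes N and gap columns from both sides of the fraction", {
  r <- percent_identity("ACGTN", "ACCTA")
  expect_equal(r$aligned_columns, 4)
  expect_equal(r$identical_columns, 3)
  expect_equal(r$percent_identity, 75)
  expect_error(percent_identity("NNNN", "NNNN"), "usable")
})

test_that("percent identity is symmetric and 100 iff identical after masking", {
  barcodediet:::with_seed(13, {
    for (i in 1:8) {
      a <- rand_seq(40); b <- mutate_at(a, sample(40, sample(0:6, 1)))
      expect_equal(percent_identity(a, b)$percent_identity,
                   percent_identity(b, a)$percent_identity)
      expect_equal(percent_identity(a, b)$percent_identity == 100, a == b)
    }
  })
  expect_equal(percent_identity("ACNGT", "ACAGT")$percent_identity, 100)
})

test_that("best hit maximizes identity with lexicographic tie-breaking", {
  db <- tiny_db()
  q <- db$records$sequence[3]
  bh <- best_hit(q, db)
  expect_identical(bh$best_hit, db$records$accession[3])
  expect_equal(bh$percent_identity, 100)

  # 1% vs 10% divergence: exhaustive scan must find the close one
  a <- rand_seq(300, seed = 21)
  rec <- data.frame(accession = c("R_FAR", "R_NEAR"),
                    sequence = c(mutate_at(a, 1:30), mutate_at(a, 1:3)),
                    phylum = "P", class = "C", order = "O", family = "F",
                    genus = "G", species = c("G far", "G near"),
                    stringsAsFactors = FALSE)
  expect_identical(best_hit(a, reference_db(rec))$best_hit, "R_NEAR")

  # exact tie -> lexicographically smaller accession
  rec2 <- rec; rec2$sequence <- c(a, a); rec2$accession <- c("ZZZ", "AAA")
  expect_identical(best_hit(a, reference_db(rec2))$best_hit, "AAA")
})

test_that("dereplication groups clones and conserves counts", {
  one <- data.frame(sample_id = "s1", clone_id = paste0("c", 1:10),
                    sequence = rand_seq(100, seed = 31), stringsAsFactors = FALSE)
  otus <- dereplicate_clones(one)
  expect_length(otus, 1)
  expect_equal(sum(otus[[1]]$per_sample_counts), 10)

  # two groups at ~90% identity, 100% within -> 2 OTUs at threshold 98
  a <- rand_seq(200, seed = 32); b <- mutate_at(a, 1:20)
  two <- data.frame(sample_id = rep(c("s1", "s2"), each = 4),
                    clone_id = paste0("c", 1:8),
                    sequence = rep(c(a, b), 4), stringsAsFactors = FALSE)
  otus2 <- dereplicate_clones(two, threshold = 98)
  expect_length(otus2, 2)
  expect_equal(sum(vapply(otus2, function(o) sum(o$per_sample_counts), 0L)), 8)
})

test_that("dereplication conserves per-sample clone counts on random libraries", {
  p <- sim_params(shape = c(phyla = 1, classes = 1, orders = 1, families = 2,
                            genera = 2, species = 2), seq_length = 200)
  for (seed in 1:3) {
    p$seed <- seed
    ref <- make_reference_db(p)
    menu <- default_menu(ref$db, n_samples = 6, seed = seed)
    gut <- make_gut_samples(ref$db, menu, p)
    otus <- dereplicate_clones(gut$clones)
    counts <- Reduce(`+`, lapply(otus, function(o) {
      v <- setNames(integer(length(unique(gut$clones$sample_id))),
                    sort(unique(gut$clones$sample_id)))
      v[names(o$per_sample_counts)] <- o$per_sample_counts
      v
    }))
    expect_equal(counts, table(gut$clones$sample_id)[names(counts)],
                 ignore_attr = TRUE)
    for (o in otus) expect_true(o$representative %in%
                                  gut$clones$sequence[gut$clones$clone_id %in% o$member_clone_ids])
  }
})
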