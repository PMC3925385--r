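# hand-built reference set for clade-walk tests: genus Gen1 (2 species),
# confamilial Gen2, plus one record from another family (outgroup)
clade_db <- function() {
  recs <- data.frame(
    accession = c("R1", "R2", "R3", "R4", "OG"),
    sequence = "ACGTACGT",
    phylum = "Arthropoda", class = "Insecta",
    order = c("Diptera", "Diptera", "Diptera", "Diptera", "Ephemeroptera"),
    family = c("Chironomidae", "Chironomidae", "Chironomidae", "Chironomidae",
               "Caenidae"),
    genus = c("Gen1", "Gen1", "Gen2", "Gen1", "Gen9"),
    species = c("Gen1 alpha", "Gen1 beta", "Gen2 gamma", "Gen1 beta",
                "Gen9 omega"),
    stringsAsFactors = FALSE)
  reference_db(recs)
}

test_that("a supported conspecific sister clade yields a species-level rank", {
  tr <- ape::read.tree(
    text = "(((query:0.01,R1:0.01)100:0.05,R2:0.06)95:0.1,(R3:0.05,OG:0.3)80:0.1);")
  res <- clade_rank(tr, "query", clade_db(), outgroups = "OG")
  expect_identical(res$rank, "species")
  expect_identical(res$taxon, "Gen1 alpha")
  expect_setequal(res$supporting_clade, c("query", "R1"))
})

test_that("a multi-species genus clade yields a genus-level rank", {
  tr <- ape::read.tree(
    text = "(((query:0.01,R1:0.01)40:0.02,(R2:0.01,R4:0.01)90:0.02)100:0.05,(R3:0.05,OG:0.3):0.1);")
  res <- clade_rank(tr, "query", clade_db(), outgroups = "OG", min_support = 50)
  expect_identical(res$rank, "genus")   # species clade exists but support 40
  expect_identical(res$taxon, "Gen1")
  # with a laxer support floor the species clade qualifies
  res2 <- clade_rank(tr, "query", clade_db(), outgroups = "OG", min_support = 30)
  expect_identical(res2$rank, "species")
})

test_that("a query between family clades resolves at family, or not at all", {
  # query attaches between the two Gen1/Gen2 (one family) subtrees
  tr <- ape::read.tree(
    text = "(((R1:0.02,R2:0.02)90:0.03,(query:0.02,(R3:0.01,R4:0.01)85:0.02)70:0.03)95:0.1,OG:0.3);")
  res <- clade_rank(tr, "query", clade_db(), outgroups = "OG")
  expect_identical(res$rank, "family")
  expect_identical(res$taxon, "Chironomidae")
  # demanding more support than any clade has leaves the query unresolved
  res2 <- clade_rank(tr, "query", clade_db(), outgroups = "OG", min_support = 99)
  expect_identical(res2$rank, "unresolved")
  expect_error(clade_rank(tr, "absent", clade_db(), outgroups = "OG"), "not in tree")
  expect_error(clade_rank(tr, "query", clade_db(), outgroups = character(0)),
               "outgroup")
})

test_that("the identification rule reproduces its decision table", {
  # (identity, clade rank) -> assigned rank
  expect_identical(apply_identification_rule(100, "species"), "species")
  expect_identical(apply_identification_rule(99, "genus"), "genus")
  expect_identical(apply_identification_rule(98, "genus"), "genus")
  expect_identical(apply_identification_rule(89, "genus"), "genus")
  expect_identical(apply_identification_rule(82, "family"), "family")
  expect_identical(apply_identification_rule(98, "family"), "family")
  expect_identical(apply_identification_rule(97.9, "species"), "genus")
  expect_identical(apply_identification_rule(50, "unresolved"), "unresolved")
})

test_that("raising the identity threshold never sharpens an assignment", {
  lvl <- function(r) match(r, c("unresolved", "order", "family", "genus", "species"))
  for (clade in c("species", "genus", "family", "order", "unresolved")) {
    for (id in c(80, 90, 97.9, 98, 99, 100)) {
      r_low <- apply_identification_rule(id, clade, threshold = 95)
      r_high <- apply_identification_rule(id, clade, threshold = 99)
      expect_lte(lvl(r_high), lvl(r_low))
    }
  }
})

test_that("the full engine makes a species call when both criteria hold", {
  p <- sim_params(shape = c(phyla = 1, classes = 1, orders = 1, families = 2,
                            genera = 2, species = 2), seq_length = 400, seed = 3)
  db <- make_reference_db(p)$db
  q <- evolve_sequence(db$records$sequence[1], 0.005, p, seed = 9)
  otu <- list(otu_id = "OTU01", representative = q)
  cfg <- assignment_config(bootstrap = bootstrap_config(n_replicates = 100))
  a <- assign_taxon(otu, db, cfg, seed = 4)
  expect_identical(a$assigned_rank, "species")
  expect_identical(a$assigned_taxon, db$records$species[1])
  expect_true(a$identity_pass)
  expect_identical(a$clade_conclusive_rank, "species")
})

test_that("an ambiguous >=98% best hit is demoted to genus", {
  base <- rand_seq(300, seed = 61)
  far <- mutate_at(base, 1:60)
  recs <- data.frame(
    accession = c("RA", "RB", "RC", "OG1"),
    sequence = c(base, base, mutate_at(base, 1:18), far),
    phylum = "P", class = "C", order = "O",
    family = c("Fam1", "Fam1", "Fam1", "Fam2"),
    genus = c("GenX", "GenX", "GenX", "GenZ"),
    species = c("GenX one", "GenX two", "GenX three", "GenZ out"),
    stringsAsFactors = FALSE)
  db <- reference_db(recs)
  a <- assign_taxon(list(otu_id = "OTU01", representative = base), db,
                    assignment_config(bootstrap = bootstrap_config(50)), seed = 1)
  expect_identical(a$assigned_rank, "genus")
  expect_match(a$assigned_taxon, "^GenX sp\\.")
})

test_that("assign_all numbers genus calls and survives per-OTU failures", {
  expect_identical(assign_all(list(), tiny_db()), list())
  base <- rand_seq(300, seed = 62)
  recs <- data.frame(
    accession = c("RA", "RB", "OG1"),
    sequence = c(base, mutate_at(base, 1:15), mutate_at(base, 1:75)),
    phylum = "P", class = "C", order = "O",
    family = c("Fam1", "Fam1", "Fam2"),
    genus = c("GenX", "GenX", "GenZ"),
    species = c("GenX one", "GenX two", "GenZ out"), stringsAsFactors = FALSE)
  db <- reference_db(recs)
  # two distinct queries ~3% from either species: identity fails, genus clade
  q1 <- mutate_at(base, seq(5, 300, by = 15))
  q2 <- mutate_at(base, seq(7, 300, by = 15))
  otus <- list(list(otu_id = "OTU01", representative = q1),
               list(otu_id = "OTU02", representative = q2),
               list(otu_id = "OTU03", representative = NA_character_))
  out <- assign_all(otus, db, assignment_config(bootstrap = bootstrap_config(50)))
  genus_labels <- vapply(out[1:2], function(a) a$assigned_taxon, "")
  ranks <- vapply(out[1:2], function(a) a$assigned_rank, "")
  if (all(ranks == "genus")) {
    expect_setequal(genus_labels, c("GenX sp. 1", "GenX sp. 2"))
  }
  expect_identical(out[[3]]$assigned_rank, "error")
  expect_length(out, 3)
})
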