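## Seeded simulator of COI-like reference libraries and gut clone samples
## with known truth. Sequences evolve under a two-parameter (Kimura)
## substitution process so the K2P distance estimator is consistent for
## simulated divergences; the taxonomy is generated hierarchically so that
## reference relationships are tree-congruent by construction.

BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

#' Simulation parameters
#'
#' @param seq_length barcode fragment length in bp (default 658, the
#'   standard Folmer COI fragment).
#' @param ts_tv_ratio transitions per transversion (kappa-style ratio,
#'   default 2).
#' @param shape named integer vector: number of children per node at each
#'   taxonomy rank, `c(phyla=, classes=, orders=, families=, genera=,
#'   species=)`.
#' @param divergence_between_species expected substitutions/site separating
#'   sibling species (default 0.05, i.e. ~95% identity).
#' @param divergence_between_genera,divergence_between_families expected
#'   substitutions/site separating sibling genera / families (defaults 0.10
#'   and 0.18, bracketing the identity bands at which genus- and
#'   family-level calls occur).
#' @param divergence_higher_ranks per-branch divergence at order, class and
#'   phylum nodes (default 0.06 each; kept moderate to stay clear of K2P
#'   saturation across the library).
#' @param divergence_within_species expected substitutions/site between a
#'   gut clone and its species' reference (default 0.005, inside the 2%
#'   intraspecific band).
#' @param clones_per_sample clones sequenced per gut (default 10).
#' @param seed integer RNG seed.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(seq_length = 658, ts_tv_ratio = 2,
                       shape = c(phyla = 2, classes = 2, orders = 1,
                                 families = 2, genera = 2, species = 2),
                       divergence_between_species = 0.05,
                       divergence_between_genera = 0.10,
                       divergence_between_families = 0.18,
                       divergence_higher_ranks = 0.06,
                       divergence_within_species = 0.005,
                       clones_per_sample = 10, seed = 1) {
  stopifnot(seq_length > 0, ts_tv_ratio > 0, all(shape >= 1),
            divergence_within_species >= 0,
            divergence_within_species < divergence_between_species,
            divergence_between_species < 0.75,
            divergence_between_genera < 0.75,
            divergence_between_families < 0.75)
  structure(list(seq_length = seq_length, ts_tv_ratio = ts_tv_ratio,
                 shape = shape,
                 divergence_between_species = divergence_between_species,
                 divergence_between_genera = divergence_between_genera,
                 divergence_between_families = divergence_between_families,
                 divergence_higher_ranks = divergence_higher_ranks,
                 divergence_within_species = divergence_within_species,
                 clones_per_sample = clones_per_sample, seed = seed),
            class = "sim_params")
}

random_sequence <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Evolve a sequence under a two-parameter substitution process
#'
#' Each site substitutes with the exact Kimura two-parameter transition
#' probabilities for total expected divergence `divergence`
#' (substitutions/site), with transitions favored by `ts_tv_ratio`. `N`
#' sites are left untouched. The realized p-distance is binomial around
#' the (slightly smaller, multiple-hit-corrected) expected proportion.
#'
#' @param ref nucleotide string over `{A,C,G,T,N}`.
#' @param divergence expected substitutions/site in `[0, 0.75)`.
#' @param params a [sim_params()] (only `ts_tv_ratio` is used).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return mutated sequence, same length as `ref`.
#' @export
evolve_sequence <- function(ref, divergence, params = sim_params(), seed = NULL) {
  if (divergence < 0) stop("divergence must be >= 0")
  if (divergence >= 0.75) stop("divergence ", divergence, " >= 0.75: saturated")
  run <- function() {
    x <- strsplit(toupper(ref), "")[[1]]
    kappa <- params$ts_tv_ratio
    B <- divergence / (2 * (kappa + 1))
    A <- kappa * divergence / (kappa + 1)
    p_ts <- 0.25 + 0.25 * exp(-4 * B) - 0.5 * exp(-2 * (A + B))
    p_tv <- 0.5 - 0.5 * exp(-4 * B)
    u <- runif(length(x))
    mutable <- x %in% BASES
    do_ts <- mutable & u < p_ts
    do_tv <- mutable & u >= p_ts & u < p_ts + p_tv
    x[do_ts] <- TS_PARTNER[x[do_ts]]
    if (any(do_tv)) {
      pick <- runif(sum(do_tv)) < 0.5
      x[do_tv] <- mapply(function(b, first) TV_PARTNERS[[b]][if (first) 1 else 2],
                         x[do_tv], pick)
    }
    paste(x, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a hierarchical reference barcode library
#'
#' Evolves sequences down a balanced taxonomy of the requested shape:
#' larger divergences accumulate at higher ranks, so the reference set is
#' congruent with its own taxonomy (each genus, family, ... monophyletic
#' in expectation). One reference record per species.
#'
#' @param params a [sim_params()].
#' @return list with `db` (a [reference_db()]) and `ancestors` (named list
#'   of internal-node sequences, keyed by taxon name).
#' @export
make_reference_db <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  sh <- params$shape
  branch <- c(phylum = params$divergence_higher_ranks,
              class = params$divergence_higher_ranks,
              order = params$divergence_higher_ranks,
              family = params$divergence_between_families / 2,
              genus = params$divergence_between_genera / 2,
              species = params$divergence_between_species / 2)
  with_seed(params$seed, {
    root <- random_sequence(params$seq_length)
    counters <- new.env()
    nm <- function(prefix) {
      k <- (get0(prefix, envir = counters, ifnotfound = 0L)) + 1L
      assign(prefix, k, envir = counters)
      sprintf("%s%02d", prefix, k)
    }
    records <- list(); ancestors <- list()
    for (ip in seq_len(sh[["phyla"]])) {
      p_name <- nm("Phylum"); p_seq <- evolve_sequence(root, branch[["phylum"]], params)
      ancestors[[p_name]] <- p_seq
      for (ic in seq_len(sh[["classes"]])) {
        c_name <- nm("Class"); c_seq <- evolve_sequence(p_seq, branch[["class"]], params)
        ancestors[[c_name]] <- c_seq
        for (io in seq_len(sh[["orders"]])) {
          o_name <- nm("Order"); o_seq <- evolve_sequence(c_seq, branch[["order"]], params)
          ancestors[[o_name]] <- o_seq
          for (ifam in seq_len(sh[["families"]])) {
            f_name <- nm("Family"); f_seq <- evolve_sequence(o_seq, branch[["family"]], params)
            ancestors[[f_name]] <- f_seq
            for (ig in seq_len(sh[["genera"]])) {
              g_name <- nm("Genus"); g_seq <- evolve_sequence(f_seq, branch[["genus"]], params)
              ancestors[[g_name]] <- g_seq
              for (is in seq_len(sh[["species"]])) {
                s_seq <- evolve_sequence(g_seq, branch[["species"]], params)
                s_name <- paste0(g_name, "_sp", sprintf("%02d", is))
                records[[length(records) + 1]] <- data.frame(
                  accession = sprintf("REF%04d", length(records) + 1),
                  sequence = s_seq, phylum = p_name, class = c_name,
                  order = o_name, family = f_name, genus = g_name,
                  species = s_name, stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }
    list(db = reference_db(do.call(rbind, records)), ancestors = ancestors)
  })
}

#' Default gut-sample menu emulating the study design
#'
#' 30 gut samples in three size classes of 10. Each sample receives 1 to
#' `max_species` prey species drawn from the library; clone multiplicities
#' follow a truncated-geometric pattern (a few species dominate each gut),
#' allocated so every sample yields exactly `clones_per_sample` clones.
#'
#' @param db a [reference_db()].
#' @param n_samples number of gut samples (default 30).
#' @param clones_per_sample clones sequenced per gut (default 10).
#' @param max_species maximum prey species per gut (default 4).
#' @param seed RNG seed.
#' @return data frame (`sample_id`, `size_class`, `species`, `n_clones`).
#' @export
default_menu <- function(db, n_samples = 30, clones_per_sample = 10,
                         max_species = 4, seed = 1) {
  species_pool <- sort(unique(db$records$species))
  with_seed(seed, {
    out <- lapply(seq_len(n_samples), function(i) {
      k <- sample.int(min(max_species, length(species_pool)), 1)
      sp <- sample(species_pool, k)
      wt <- 0.5 ^ (seq_len(k) - 1)
      counts <- as.integer(rmultinom(1, clones_per_sample, wt))
      keep <- counts > 0
      data.frame(sample_id = sprintf("G%02d", i),
                 size_class = SIZE_CLASSES[((i - 1) %/% (n_samples / 3)) %% 3 + 1],
                 species = sp[keep], n_clones = counts[keep],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate gut clone libraries from a menu, with truth
#'
#' Each menu row yields `n_clones` clones evolved from that species'
#' reference sequence at the within-species divergence; the truth table
#' records every clone's sample, true species lineage, and realized
#' p-distance to its reference. Optional predator self-DNA contamination
#' adds clones of a designated species to every sample.
#'
#' @param db a [reference_db()].
#' @param menu data frame (`sample_id`, `species`, `n_clones`), e.g. from
#'   [default_menu()].
#' @param params a [sim_params()].
#' @param self_species optional species name whose clones contaminate
#'   every sample.
#' @param self_clones clones of `self_species` added per sample.
#' @return list with `clones` (data frame `sample_id`, `clone_id`,
#'   `sequence`) and `truth` (one row per clone: lineage + realized
#'   divergence).
#' @export
make_gut_samples <- function(db, menu, params = sim_params(),
                             self_species = NULL, self_clones = 0) {
  stopifnot(inherits(db, "reference_db"))
  unknown <- setdiff(menu$species, db$records$species)
  if (length(unknown)) stop("menu species not in reference DB: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(self_species) && self_clones > 0) {
    if (!self_species %in% db$records$species) stop("self species not in DB")
    extra <- data.frame(sample_id = unique(menu$sample_id),
                        species = self_species, n_clones = self_clones,
                        stringsAsFactors = FALSE)
    menu <- rbind(menu[c("sample_id", "species", "n_clones")], extra)
  }
  with_seed(params$seed, {
    rows <- vector("list", nrow(menu))
    for (i in seq_len(nrow(menu))) {
      sp <- menu$species[i]
      rec <- db$records[match(sp, db$records$species), ]
      n <- menu$n_clones[i]
      seqs <- vapply(seq_len(n), function(j)
        evolve_sequence(rec$sequence, params$divergence_within_species, params), "")
      rows[[i]] <- data.frame(
        sample_id = menu$sample_id[i],
        species = sp, sequence = seqs,
        realized_divergence = vapply(seqs, p_distance, 0, b = rec$sequence),
        rec[rep(1, n), c("phylum", "class", "order", "family", "genus")],
        stringsAsFactors = FALSE, row.names = NULL)
    }
    all <- do.call(rbind, rows)
    ord <- order(all$sample_id)
    all <- all[ord, , drop = FALSE]
    # rows are sorted by sample_id, so per-group ids concatenate in row order
    all$clone_id <- unlist(lapply(split(seq_len(nrow(all)), all$sample_id),
                                  function(ix) sprintf("%s:cl%02d",
                                                       all$sample_id[ix[1]],
                                                       seq_along(ix))),
                           use.names = FALSE)
    list(clones = data.frame(sample_id = all$sample_id, clone_id = all$clone_id,
                             sequence = all$sequence, stringsAsFactors = FALSE),
         truth = all[c("sample_id", "clone_id", "species", "genus", "family",
                       "order", "class", "phylum", "realized_divergence")])
  })
}

#' Write gut samples to per-sample FASTA files plus a truth TSV
#' @param samples list from [make_gut_samples()].
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_gut_fastas <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(split(samples$clones, samples$clones$sample_id), function(df) {
    path <- file.path(dir, paste0(df$sample_id[1], ".fasta"))
    seqs <- Biostrings::DNAStringSet(setNames(df$sequence, sub("^.*:", "", df$clone_id)))
    Biostrings::writeXStringSet(seqs, path)
    path
  }, "")
  truth_path <- file.path(dir, "truth.tsv")
  write.table(samples$truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, truth_path))
}

#' End-to-end species recovery experiment
#'
#' Generates a reference library and gut clone samples with known truth,
#' runs dereplication and the two-criterion assignment engine, and scores
#' each OTU against the majority true species of its member clones.
#'
#' @param seed experiment seed (drives the simulator and the bootstraps).
#' @param params a [sim_params()] (its `seed` is overridden by `seed`).
#' @param cfg an [assignment_config()].
#' @param n_samples,clones_per_sample study design passed to
#'   [default_menu()].
#' @return list: `accuracy` (fraction of OTUs assigned at species rank to
#'   their true species), `n_otus`, `results` (per-OTU data frame).
#' @export
run_recovery_experiment <- function(seed = 1, params = sim_params(),
                                    cfg = assignment_config(),
                                    n_samples = 30, clones_per_sample = 10) {
  params$seed <- seed
  ref <- make_reference_db(params)
  menu <- default_menu(ref$db, n_samples = n_samples,
                       clones_per_sample = clones_per_sample, seed = seed + 1)
  gut <- make_gut_samples(ref$db, menu, params)
  otus <- dereplicate_clones(gut$clones, threshold = cfg$species_identity_threshold)
  assignments <- assign_all(otus, ref$db, cfg, seed = seed + 2)
  truth_by_clone <- setNames(gut$truth$species, gut$truth$clone_id)
  results <- do.call(rbind, lapply(seq_along(otus), function(i) {
    true_sp <- names(sort(table(truth_by_clone[otus[[i]]$member_clone_ids]),
                          decreasing = TRUE))[1]
    a <- assignments[[i]]
    data.frame(otu_id = a$otu_id, true_species = true_sp,
               assigned_rank = a$assigned_rank,
               assigned_taxon = a$assigned_taxon %||% NA_character_,
               identity_percent = a$identity_percent,
               correct_species = identical(a$assigned_rank, "species") &&
                 identical(a$assigned_taxon, true_sp),
               stringsAsFactors = FALSE)
  }))
  list(accuracy = mean(results$correct_species), n_otus = nrow(results),
       results = results)
}
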