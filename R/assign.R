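## The two-criterion taxonomic identification rule:
##   (1) percent identity to the best reference hit >= threshold (default 98%)
##   (2) the query clusters conclusively (monophyly with adequate bootstrap
##       support) with references of a single taxon on the NJ tree.
## Species-level calls require both; otherwise the OTU is identified at the
## most specific conclusive clade rank (genus, family, order) or left
## unresolved.

ASSIGN_RANKS <- c("unresolved", "order", "family", "genus", "species")

rank_level <- function(r) match(r, ASSIGN_RANKS) - 1L

#' Assignment configuration
#'
#' @param species_identity_threshold percent identity required for a
#'   species-level call (default 98).
#' @param n_reference_hits number of top reference hits put on the tree
#'   (default 10).
#' @param n_outgroups outgroups drawn from the nearest other families
#'   (default 3).
#' @param min_support minimum bootstrap support (percent) for a clade to
#'   count as conclusive (default 50).
#' @param bootstrap a [bootstrap_config()].
#' @return list of class `"assignment_config"`.
#' @export
assignment_config <- function(species_identity_threshold = 98,
                              n_reference_hits = 10,
                              n_outgroups = 3,
                              min_support = 50,
                              bootstrap = bootstrap_config()) {
  stopifnot(species_identity_threshold > 0, species_identity_threshold <= 100)
  structure(list(species_identity_threshold = species_identity_threshold,
                 n_reference_hits = n_reference_hits,
                 n_outgroups = n_outgroups,
                 min_support = min_support,
                 bootstrap = bootstrap),
            class = "assignment_config")
}

#' The identification rule on (identity, clade rank)
#'
#' Pure decision logic, reusable when identity and the conclusive clade
#' rank are already known (e.g. fixture mode): a species-level call
#' requires identity at/above the threshold AND a species-conclusive
#' clade; identity at/above threshold with a less specific clade demotes
#' to that clade's rank; identity below threshold can never yield species
#' (a species-conclusive clade is demoted to genus).
#'
#' @param identity_percent percent identity to the best hit (0-100).
#' @param clade_rank conclusive clade rank: one of
#'   `"species"`, `"genus"`, `"family"`, `"order"`, `"unresolved"`.
#' @param threshold species identity threshold (default 98).
#' @return assigned rank (same vocabulary as `clade_rank`).
#' @export
apply_identification_rule <- function(identity_percent, clade_rank, threshold = 98) {
  stopifnot(clade_rank %in% ASSIGN_RANKS)
  if (identity_percent >= threshold) {
    clade_rank
  } else if (identical(clade_rank, "species")) {
    "genus"
  } else {
    clade_rank
  }
}

node_path_to_root <- function(tree, tip) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- integer(0)
  nd <- tip
  while (parent[nd] != 0) {
    nd <- parent[nd]
    path <- c(path, nd)
  }
  path
}

tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  todo <- node; tips <- integer(0)
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- c(tips, ch[ch <= n_tip])
    todo <- c(todo, ch[ch > n_tip])
  }
  tree$tip.label[sort(tips)]
}

#' Conclusive clade rank of a query leaf
#'
#' Roots the tree on the edge to the designated outgroups, then walks from
#' the query leaf rootward. At each nested clade containing the query, the
#' reference leaves in the clade are tested for a single shared taxon name
#' at species, then genus, then family, then order; a clade counts only if
#' its bootstrap support (node label) is at least `min_support` (clades
#' without a support value pass). The most specific rank achieved by any
#' qualifying clade is returned, with its supporting leaf set.
#'
#' @param tree `ape::phylo` with bootstrap supports as node labels (e.g.
#'   from [bootstrap_supports()]).
#' @param query_leaf tip label of the query.
#' @param db a [reference_db()] covering every non-query leaf.
#' @param outgroups accessions to root on (must be tips of `tree`).
#' @param min_support minimum support percent (default 50).
#' @return list of class `"clade_rank_result"`: `rank` (one of species/
#'   genus/family/order/unresolved), `taxon` (shared name at `rank`, `NA`
#'   if unresolved), `supporting_clade` (leaf labels), `per_rank` (named
#'   list rank -> shared taxon for every rank achieved).
#' @export
clade_rank <- function(tree, query_leaf, db, outgroups, min_support = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!query_leaf %in% tree$tip.label) stop("query leaf not in tree: ", query_leaf)
  outgroups <- intersect(outgroups, tree$tip.label)
  outgroups <- setdiff(outgroups, query_leaf)
  if (length(outgroups) == 0) stop("no outgroup to root on")
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroups, resolve.root = TRUE, edgelabel = TRUE),
    error = function(e)
      # outgroup set not monophyletic in this tree: root on its first tip
      ape::root(tree, outgroup = outgroups[1], resolve.root = TRUE,
                edgelabel = TRUE))
  n_tip <- length(rooted$tip.label)
  tip <- match(query_leaf, rooted$tip.label)
  path <- node_path_to_root(rooted, tip)

  supports <- suppressWarnings(as.numeric(rooted$node.label %||% character(0)))
  ref_lineages <- lapply(setNames(nm = setdiff(rooted$tip.label, query_leaf)),
                         function(acc) db_lineage(db, acc))

  best <- list(rank = "unresolved", taxon = NA_character_,
               supporting_clade = character(0), per_rank = list())
  for (nd in path) {
    sup <- supports[nd - n_tip]
    if (!is.na(sup) && sup < min_support) next
    leaves <- tips_below(rooted, nd)
    refs <- setdiff(leaves, query_leaf)
    if (length(refs) == 0) next
    for (r in c("species", "genus", "family", "order")) {
      vals <- vapply(ref_lineages[refs], function(l) l[[r]], "")
      if (all(nzchar(vals)) && length(unique(vals)) == 1) {
        if (is.null(best$per_rank[[r]])) best$per_rank[[r]] <- unique(vals)
        if (rank_level(r) > rank_level(best$rank)) {
          best$rank <- r
          best$taxon <- unique(vals)
          best$supporting_clade <- leaves
        }
        break   # most specific rank for this clade found
      }
    }
  }
  structure(best, class = "clade_rank_result")
}

#' Assign a taxon to one OTU
#'
#' Runs the full two-criterion engine: exhaustive best-hit identity scan,
#' NJ + bootstrap tree over the query, its top reference hits, and
#' outgroups from the nearest other families, clade-rank traversal, then
#' the identification rule. An at/above-threshold identity shared by
#' references of two different species (ambiguous best hit) blocks a
#' species call and demotes to genus.
#'
#' @param otu an OTU (list with `otu_id` and `representative`), e.g. from
#'   [dereplicate_clones()].
#' @param db a [reference_db()].
#' @param cfg an [assignment_config()].
#' @param seed RNG seed for the bootstrap.
#' @param params an [alignment_params()].
#' @return list of class `"taxon_assignment"`: `otu_id`, `assigned_taxon`,
#'   `assigned_rank`, `identity_percent`, `best_hit`, `identity_pass`,
#'   `clade_conclusive_rank`, `supporting_clade`.
#' @export
assign_taxon <- function(otu, db, cfg = assignment_config(), seed = 1,
                         params = alignment_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$records) == 0) stop("empty reference DB")
  query <- otu$representative
  bh <- best_hit(query, db, params)
  bh_lineage <- db_lineage(db, bh$best_hit)

  top <- names(bh$all_identities)[seq_len(min(cfg$n_reference_hits,
                                              length(bh$all_identities)))]
  og <- outgroup_candidates(db, bh_lineage, cfg$n_outgroups)$accession
  leaves <- union(top, og)
  seqs <- setNames(db$records$sequence[match(leaves, db$records$accession)], leaves)
  aligned <- align_to_reference(c(setNames(query, "query"), seqs[setdiff(leaves, bh$best_hit)]),
                                ref = seqs[[bh$best_hit]], ref_name = bh$best_hit,
                                params = params)
  boot <- cfg$bootstrap
  boot$seed <- seed
  tree <- bootstrap_supports(aligned, boot)
  cr <- if (length(og)) {
    clade_rank(tree, "query", db, outgroups = og, min_support = cfg$min_support)
  } else {
    structure(list(rank = "unresolved", taxon = NA_character_,
                   supporting_clade = character(0), per_rank = list()),
              class = "clade_rank_result")
  }

  id_pass <- bh$percent_identity >= cfg$species_identity_threshold
  # ambiguous best hit: >= threshold identity to two different species
  top_ids <- bh$all_identities
  at_top <- names(top_ids)[top_ids >= max(cfg$species_identity_threshold,
                                          bh$percent_identity - 1e-9)]
  top_species <- unique(vapply(at_top, function(a) db_lineage(db, a)[["species"]], ""))
  ambiguous <- id_pass && length(top_species) > 1

  eff_clade <- cr$rank
  if (ambiguous && identical(eff_clade, "species")) eff_clade <- "genus"
  assigned_rank <- apply_identification_rule(bh$percent_identity, eff_clade,
                                             cfg$species_identity_threshold)

  taxon <- switch(assigned_rank,
    species = bh_lineage[["species"]],
    genus = cr$per_rank[["genus"]] %||% bh_lineage[["genus"]],
    family = cr$per_rank[["family"]] %||% bh_lineage[["family"]],
    order = cr$per_rank[["order"]] %||% bh_lineage[["order"]],
    unresolved = NA_character_)
  if (identical(assigned_rank, "genus") && !is.na(taxon)) {
    taxon <- paste(taxon, "sp.")
  }
  structure(list(otu_id = otu$otu_id,
                 assigned_taxon = taxon,
                 assigned_rank = assigned_rank,
                 identity_percent = bh$percent_identity,
                 best_hit = bh$best_hit,
                 identity_pass = id_pass,
                 clade_conclusive_rank = cr$rank,
                 supporting_clade = cr$supporting_clade,
                 tree = tree),
            class = "taxon_assignment")
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("%s -> %s [%s] (%.2f%% to %s; clade %s)\n", x$otu_id,
              x$assigned_taxon %||% "unidentified", x$assigned_rank,
              x$identity_percent, x$best_hit, x$clade_conclusive_rank))
  invisible(x)
}

#' Assign taxa to a batch of OTUs
#'
#' Maps [assign_taxon()] over OTUs with a per-OTU seed derived from `seed`;
#' per-OTU errors are captured (rank `"error"`) without aborting the batch.
#' Genus-level labels are numbered when several distinct OTUs land in one
#' genus (`"Asellus sp. 1"`, `"Asellus sp. 2"`); a lone genus-level OTU
#' keeps the plain `"<Genus> sp."` label.
#'
#' @inheritParams assign_taxon
#' @param otus list of OTUs.
#' @return list of `"taxon_assignment"` objects in input order.
#' @export
assign_all <- function(otus, db, cfg = assignment_config(), seed = 1,
                       params = alignment_params()) {
  out <- lapply(seq_along(otus), function(i) {
    tryCatch(assign_taxon(otus[[i]], db, cfg, seed = seed + i, params = params),
             error = function(e) {
               structure(list(otu_id = otus[[i]]$otu_id, assigned_taxon = NA_character_,
                              assigned_rank = "error", identity_percent = NA_real_,
                              best_hit = NA_character_, identity_pass = NA,
                              clade_conclusive_rank = NA_character_,
                              supporting_clade = character(0),
                              error = conditionMessage(e)),
                         class = "taxon_assignment")
             })
  })
  genus_calls <- which(vapply(out, function(a) identical(a$assigned_rank, "genus") &&
                                !is.na(a$assigned_taxon), TRUE))
  if (length(genus_calls)) {
    genera <- vapply(out[genus_calls], function(a) a$assigned_taxon, "")
    for (g in unique(genera)) {
      idx <- genus_calls[genera == g]
      if (length(idx) > 1) {
        for (k in seq_along(idx)) {
          out[[idx[k]]]$assigned_taxon <- paste(g, k)
        }
      }
    }
  }
  out
}

#' Tabulate a batch of assignments
#' @param assignments list from [assign_all()].
#' @return data frame, one row per OTU.
#' @export
assignment_report <- function(assignments) {
  do.call(rbind, lapply(assignments, function(a) {
    data.frame(otu_id = a$otu_id,
               assigned_taxon = a$assigned_taxon %||% NA_character_,
               assigned_rank = a$assigned_rank,
               identity_percent = a$identity_percent,
               best_hit = a$best_hit,
               clade_rank = a$clade_conclusive_rank,
               stringsAsFactors = FALSE)
  }))
}
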