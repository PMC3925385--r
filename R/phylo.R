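## Evolutionary distances, neighbor-joining, bootstrap supports.
## Trees are ape "phylo" objects throughout; Newick I/O goes through ape.

seq_char_matrix <- function(seqs) {
  labs <- names(seqs)
  seqs <- toupper(as.character(seqs))   # toupper drops names
  names(seqs) <- labs
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must be equal-length (aligned)")
  m <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs) %||% sprintf("S%02d", seq_along(seqs))
  m
}

PURINES <- c("A", "G"); PYRIMIDINES <- c("C", "T")

# per-column substitution classes for one aligned pair
pair_site_classes <- function(x, y) {
  usable <- x %in% c(PURINES, PYRIMIDINES) & y %in% c(PURINES, PYRIMIDINES)
  diff <- usable & x != y
  ts <- diff & ((x %in% PURINES & y %in% PURINES) |
                (x %in% PYRIMIDINES & y %in% PYRIMIDINES))
  list(use = usable, ts = ts, tv = diff & !ts)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among usable columns; columns with a gap
#' or `N` in either sequence are excluded.
#'
#' @param a,b equal-length aligned nucleotide strings.
#' @return proportion in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  cls <- pair_site_classes(strsplit(toupper(a), "")[[1]], strsplit(toupper(b), "")[[1]])
  n <- sum(cls$use)
  if (n == 0) stop("no usable columns for distance")
  (sum(cls$ts) + sum(cls$tv)) / n
}

k2p_from_counts <- function(n_use, n_ts, n_tv, cap = FALSE, who = "pair") {
  P <- n_ts / n_use; Q <- n_tv / n_use
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (!cap && (any(a1 <= 0) || any(a2 <= 0))) {
    stop("K2P distance saturated (log argument <= 0) for ", who)
  }
  if (cap) { a1 <- pmax(a1, 1e-10); a2 <- pmax(a2, 1e-10) }
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' observed transition and transversion proportions over usable columns.
#'
#' @inheritParams p_distance
#' @return K2P distance (substitutions/site).
#' @export
k2p_distance <- function(a, b) {
  cls <- pair_site_classes(strsplit(toupper(a), "")[[1]], strsplit(toupper(b), "")[[1]])
  n <- sum(cls$use)
  if (n == 0) stop("no usable columns for distance")
  k2p_from_counts(n, sum(cls$ts), sum(cls$tv),
                  who = paste(names(a) %||% "a", names(b) %||% "b"))
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x

# pairwise per-column class matrices (n_pairs x L logical), for fast
# column-resampled distance recomputation during bootstrap
pairwise_site_classes <- function(seqs) {
  m <- seq_char_matrix(seqs)
  n <- nrow(m)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  L <- ncol(m)
  cls <- apply(pairs, 1, function(ij) {
    c3 <- pair_site_classes(m[ij[1], ], m[ij[2], ])
    c(c3$use, c3$ts, c3$tv)
  })
  cls <- matrix(cls, nrow = 3 * L)
  list(labels = rownames(m), pairs = pairs,
       use = t(matrix(cls[seq_len(L), ], nrow = L)),
       ts  = t(matrix(cls[L + seq_len(L), ], nrow = L)),
       tv  = t(matrix(cls[2 * L + seq_len(L), ], nrow = L)),
       L = L)
}

classes_to_dist <- function(sc, w = NULL, model = "k2p", cap = FALSE) {
  if (is.null(w)) w <- rep(1, sc$L)
  n_use <- as.numeric(sc$use %*% w)
  n_ts  <- as.numeric(sc$ts %*% w)
  n_tv  <- as.numeric(sc$tv %*% w)
  if (any(n_use == 0)) stop("pair with no usable columns")
  d <- if (model == "k2p") {
    k2p_from_counts(n_use, n_ts, n_tv, cap = cap,
                    who = paste(sc$labels[sc$pairs[which(1 - 2 * n_ts / n_use - n_tv / n_use <= 0)[1], ]],
                                collapse = " vs "))
  } else (n_ts + n_tv) / n_use
  n <- length(sc$labels)
  m <- matrix(0, n, n, dimnames = list(sc$labels, sc$labels))
  m[sc$pairs] <- d
  m + t(m)
}

#' Pairwise distance matrix for an aligned sequence set
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param model `"k2p"` (default) or `"p"` for the uncorrected p-distance.
#' @return symmetric labeled distance matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, model = c("k2p", "p")) {
  model <- match.arg(model)
  classes_to_dist(pairwise_site_classes(seqs), model = model)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the Q
#' criterion `(n-2) d_ij - r_i - r_j` is joined; ties are broken by the
#' smallest `(i, j)` index pair in the current matrix for cross-platform
#' determinism. Negative branch lengths are clamped to zero and the total
#' clamped deficit recorded in `attr(tree, "clamped_deficit")`.
#'
#' @param m symmetric distance matrix with unique dimnames (>= 3 labels),
#'   or a `dist` object.
#' @return unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labels <- rownames(m)
  if (is.null(labels) || anyDuplicated(labels)) stop("distance matrix needs unique labels")
  n_tip <- nrow(m)
  if (n_tip < 3) stop("neighbor joining needs at least 3 labels")
  if (max(abs(m - t(m))) > 1e-12 || any(diag(m) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }

  children <- vector("list", 2 * n_tip)   # internal node id -> list of c(child, len)
  active <- seq_len(n_tip)                # node ids of active clusters
  next_id <- n_tip + 1
  D <- m
  clamped <- 0
  clamp <- function(x) { clamped <<- clamped + sum(pmin(x, 0)); pmax(x, 0) }

  while (length(active) > 3) {
    n <- length(active)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    qmin <- min(Q[upper.tri(Q)])
    cand <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    children[[next_id]] <- list(c(active[i], clamp(li)), c(active[j], clamp(lj)))
    dnew <- 0.5 * (D[i, -c(i, j)] + D[j, -c(i, j)] - dij)
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    D <- D2
    active <- c(active[keep], next_id)
    next_id <- next_id + 1
  }

  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  children[[next_id]] <- list(c(active[1], clamp(l1)), c(active[2], clamp(l2)),
                              c(active[3], clamp(l3)))
  root <- next_id

  # renumber nodes into ape's convention (tips 1..n, internals preorder),
  # emitting edges parent-before-children (cladewise)
  edge <- matrix(0L, 2 * n_tip - 3, 2)
  edge_len <- numeric(2 * n_tip - 3)
  new_internal <- n_tip + 1L
  e <- 0
  emit <- function(parent_new, old, len) {
    if (old <= n_tip) {
      child_new <- old
    } else {
      new_internal <<- new_internal + 1L
      child_new <- new_internal
    }
    e <<- e + 1
    edge[e, ] <<- c(parent_new, child_new)
    edge_len[e] <<- len
    if (old > n_tip) {
      for (ch in children[[old]]) emit(child_new, ch[1], ch[2])
    }
  }
  for (ch in children[[root]]) emit(n_tip + 1L, ch[1], ch[2])
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = labels, Nnode = n_tip - 2L),
                    class = "phylo", order = "cladewise")
  attr(tree, "clamped_deficit") <- -clamped
  tree
}

## ---- bipartitions -------------------------------------------------------

# canonical keys for the internal splits of an unrooted tree: each split is
# keyed by the sorted tip labels of the side NOT containing the
# lexicographically smallest label
tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  anchor <- min(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- post$edge[nrow(post$edge), 1]
  internal <- setdiff(unique(post$edge[, 1]), root)
  keys <- vapply(internal, function(nd) {
    side <- below[[nd]]
    if (length(side) < 2 || length(side) > n_tip - 2) return(NA_character_)
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, "")
  setNames(keys[!is.na(keys)], internal[!is.na(keys)])
}

#' Bootstrap configuration
#' @param n_replicates number of pseudoreplicate data sets (default 1000).
#' @param seed RNG seed.
#' @param support_scale scale of reported supports (default 100 = percent).
#' @return list of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(n_replicates = 1000, seed = 1, support_scale = 100) {
  stopifnot(n_replicates >= 1)
  structure(list(n_replicates = n_replicates, seed = seed,
                 support_scale = support_scale), class = "bootstrap_config")
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree on the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilds the NJ tree on
#' each pseudoreplicate, and scores every internal bipartition of the
#' reference tree by the percentage of replicate trees containing it.
#' Supports are stored as integer node labels (root unlabeled) and as the
#' numeric attribute `"support"` (named by internal node id).
#'
#' Replicate distance matrices use a saturation-capped K2P so that extreme
#' column resamples cannot abort a replicate.
#'
#' @param seqs named character vector of >= 4 equal-length aligned sequences.
#' @param cfg a [bootstrap_config()].
#' @param model distance model passed to the resampler (`"k2p"` or `"p"`).
#' @return `ape::phylo` tree with node labels carrying supports.
#' @export
bootstrap_supports <- function(seqs, cfg = bootstrap_config(), model = "k2p") {
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (length(seqs) < 4) stop("bootstrap supports need at least 4 sequences")
  sc <- pairwise_site_classes(seqs)
  ref <- nj_tree(classes_to_dist(sc, model = model, cap = TRUE))
  ref_keys <- tree_splits(ref)
  hits <- setNames(numeric(length(ref_keys)), ref_keys)
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$n_replicates)) {
      w <- tabulate(sample.int(sc$L, sc$L, replace = TRUE), nbins = sc$L)
      rep_tree <- nj_tree(classes_to_dist(sc, w = w, model = model, cap = TRUE))
      present <- intersect(tree_splits(rep_tree), ref_keys)
      hits[present] <- hits[present] + 1
    }
  })
  support <- cfg$support_scale * hits / cfg$n_replicates
  n_tip <- length(ref$tip.label)
  node_support <- setNames(rep(NA_real_, ref$Nnode), n_tip + seq_len(ref$Nnode))
  node_support[names(ref_keys)] <- support
  ref$node.label <- ifelse(is.na(node_support), "", as.character(round(node_support)))
  attr(ref, "support") <- node_support
  ref
}

#' Project sequences onto a reference's coordinates
#'
#' Pairwise-aligns each sequence to the reference and keeps the residue (or
#' gap) facing each reference position, yielding an equal-length pseudo-MSA
#' in reference coordinates. Insertions relative to the reference are
#' dropped. Adequate for near-equal-length barcode fragments; not a full
#' progressive MSA.
#'
#' @param seqs named character vector of sequences.
#' @param ref reference sequence (string); its own row is included under
#'   `ref_name`.
#' @param ref_name label for the reference row.
#' @param params an [alignment_params()].
#' @return named character vector of aligned sequences, all `nchar(ref)` long.
#' @export
align_to_reference <- function(seqs, ref, ref_name = "reference",
                               params = alignment_params()) {
  aln <- align_batch(unname(seqs), ref, params)
  out <- vapply(seq_along(seqs), function(i) {
    pa <- strsplit(aln$a[i], "")[[1]]; pb <- strsplit(aln$b[i], "")[[1]]
    paste(pa[pb != "-"], collapse = "")
  }, "")
  names(out) <- names(seqs)
  c(setNames(ref, ref_name), out)
}

#' Write a tree to a Newick file
#' @param tree `ape::phylo` object (node labels, e.g. bootstrap supports,
#'   are preserved).
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)
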