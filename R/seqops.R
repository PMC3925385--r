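#' Alignment scoring parameters
#'
#' Scoring scheme for pairwise global (Needleman-Wunsch, affine gap)
#' alignment of barcode fragments. Defaults favor ungapped alignments for
#' near-equal-length COI fragments.
#'
#' @param match match score (default 1).
#' @param mismatch mismatch score (default -1; must be < `match`).
#' @param gap_open,gap_extend nonnegative gap penalties (defaults 5 and 2).
#' @return list with class `"alignment_params"`.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = 5, gap_extend = 2) {
  stopifnot(gap_open >= 0, gap_extend >= 0, match > mismatch)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

.submat_cache <- new.env(parent = emptyenv())

submat_for <- function(params) {
  key <- paste(params$match, params$mismatch, sep = "/")
  m <- get0(key, envir = .submat_cache)
  if (is.null(m)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch,
                                                  baseOnly = FALSE, type = "DNA")
    assign(key, m, envir = .submat_cache)
  }
  m
}

# one global alignment call for many patterns against one subject; gapped
# strings extracted via pattern()/subject(), which for type = "global" are
# the full aligned sequences
align_batch <- function(patterns, subject, params) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(patterns),
                                       Biostrings::DNAString(subject),
                                       type = "global",
                                       substitutionMatrix = submat_for(params),
                                       gapOpening = params$gap_open,
                                       gapExtension = params$gap_extend)
  list(a = as.character(Biostrings::pattern(aln)),
       b = as.character(Biostrings::subject(aln)),
       score = Biostrings::score(aln))
}

#' Optimal global pairwise alignment
#'
#' @param a,b nucleotide strings over `{A,C,G,T,N}` (non-empty).
#' @param params an [alignment_params()].
#' @return list with gapped strings `a` and `b` (equal length) and the
#'   optimal alignment `score`.
#' @export
global_align <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  a <- validate_sequence(a, "a"); b <- validate_sequence(b, "b")
  out <- align_batch(a, b, params)
  list(a = out$a, b = out$b, score = out$score)
}

# identity over aligned columns; gap and N columns excluded from both
# numerator and denominator
identity_from_aligned <- function(pa, pb) {
  ra <- charToRaw(pa); rb <- charToRaw(pb)
  stopifnot(length(ra) == length(rb))
  skip <- charToRaw("-N")
  usable <- !(ra %in% skip | rb %in% skip)
  n <- sum(usable)
  list(aligned_columns = n, identical_columns = sum(ra[usable] == rb[usable]))
}

#' Percent identity between two sequences
#'
#' Sequences are globally aligned; identity is computed over aligned
#' columns, excluding any column where either symbol is a gap or `N` from
#' both numerator and denominator. Errors if no usable column remains.
#'
#' @inheritParams global_align
#' @return list of class `"identity_result"`: `percent_identity` (0-100),
#'   `aligned_columns`, `identical_columns`, `best_hit` (`NA` here; filled
#'   by [best_hit()]).
#' @export
percent_identity <- function(a, b, params = alignment_params()) {
  aln <- global_align(a, b, params)
  cols <- identity_from_aligned(aln$a, aln$b)
  if (cols$aligned_columns == 0) stop("no usable (non-gap, non-N) aligned columns")
  structure(list(percent_identity = 100 * cols$identical_columns / cols$aligned_columns,
                 aligned_columns = cols$aligned_columns,
                 identical_columns = cols$identical_columns,
                 best_hit = NA_character_),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("%.2f%% identity (%d/%d columns)%s\n", x$percent_identity,
              x$identical_columns, x$aligned_columns,
              if (is.na(x$best_hit)) "" else paste0(" to ", x$best_hit)))
  invisible(x)
}

#' Best reference hit by exhaustive identity scan
#'
#' Aligns the query against every record in the reference library and
#' returns the maximizer of percent identity; ties are broken
#' lexicographically by accession. This exhaustive scan replaces a
#' heuristic database search: at barcode-library scale it is exact and fast.
#'
#' @param query nucleotide string.
#' @param db a [reference_db()].
#' @param params an [alignment_params()].
#' @return an `"identity_result"` with `best_hit` set to the winning
#'   accession, plus `all_identities` (named vector, one entry per record).
#' @export
best_hit <- function(query, db, params = alignment_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$records) == 0) stop("empty reference DB")
  query <- validate_sequence(query, "query")
  aln <- align_batch(db$records$sequence, query, params)
  cols <- mapply(function(x, y) unlist(identity_from_aligned(x, y)), aln$a, aln$b)
  pid <- 100 * cols["identical_columns", ] / pmax(cols["aligned_columns", ], 1)
  pid[cols["aligned_columns", ] == 0] <- -Inf
  names(pid) <- db$records$accession
  ord <- order(-pid, names(pid))
  win <- ord[1]
  structure(list(percent_identity = pid[[win]],
                 aligned_columns = cols["aligned_columns", win],
                 identical_columns = cols["identical_columns", win],
                 best_hit = names(pid)[win],
                 all_identities = pid[ord]),
            class = "identity_result")
}

#' Read per-sample clone FASTA files
#'
#' One FASTA per gut sample; the sample ID is the file stem. Clone IDs are
#' prefixed with the sample ID when not already unique.
#'
#' @param paths character vector of FASTA paths.
#' @return data frame with columns `sample_id`, `clone_id`, `sequence`.
#' @export
read_clone_fastas <- function(paths) {
  out <- lapply(paths, function(p) {
    seqs <- Biostrings::readDNAStringSet(p)
    sid <- sub("\\.[^.]*$", "", basename(p))
    data.frame(sample_id = sid,
               clone_id = paste0(sid, ":", sub("\\s.*$", "", names(seqs))),
               sequence = as.character(seqs), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Dereplicate clone sequences into OTUs
#'
#' Greedy centroid clustering in descending clone-abundance order: unique
#' sequences are visited from most to least abundant (ties broken by
#' sequence string for determinism); each joins the first existing centroid
#' with percent identity at or above the threshold, otherwise it founds a
#' new OTU whose representative it becomes. Per-sample clone counts are
#' conserved exactly.
#'
#' @param clones data frame with columns `sample_id`, `clone_id`,
#'   `sequence` (e.g. from [read_clone_fastas()]).
#' @param threshold percent identity threshold in (0, 100] (default 98, the
#'   species-delimitation threshold of the identification rule).
#' @param params an [alignment_params()].
#' @return list of OTUs, each a list with `otu_id`, `representative`,
#'   `member_clone_ids`, `per_sample_counts` (named integer vector).
#' @export
dereplicate_clones <- function(clones, threshold = 98, params = alignment_params()) {
  stopifnot(is.data.frame(clones),
            all(c("sample_id", "clone_id", "sequence") %in% names(clones)),
            threshold > 0, threshold <= 100)
  if (nrow(clones) == 0) return(list())
  clones$sequence <- vapply(clones$sequence, validate_sequence, "", USE.NAMES = FALSE)
  uniq <- aggregate(rep(1L, nrow(clones)), by = list(sequence = clones$sequence), FUN = sum)
  names(uniq)[2] <- "abundance"
  uniq <- uniq[order(-uniq$abundance, uniq$sequence), ]
  # ungapped identity of an equal-length pair (lower bound on the aligned
  # identity under the gap-averse defaults); -1 when lengths differ
  hamming_identity <- function(x, y) {
    rx <- charToRaw(x); ry <- charToRaw(y)
    if (length(rx) != length(ry)) return(-1)
    usable <- rx != charToRaw("N") & ry != charToRaw("N")
    if (!any(usable)) return(-1)
    100 * sum(rx[usable] == ry[usable]) / sum(usable)
  }
  centroids <- character(0)
  membership <- integer(nrow(uniq))   # OTU index per unique sequence
  for (i in seq_len(nrow(uniq))) {
    s <- uniq$sequence[i]
    k <- NA_integer_
    # fast path: first centroid whose ungapped identity already passes
    for (j in seq_along(centroids)) {
      if (hamming_identity(s, centroids[j]) >= threshold) { k <- j; break }
    }
    if (is.na(k) && length(centroids)) {
      # full alignment against all centroids, joined in founding order
      aln <- align_batch(centroids, s, params)
      pid <- vapply(seq_along(centroids), function(j) {
        cc <- identity_from_aligned(aln$a[j], aln$b[j])
        if (cc$aligned_columns == 0) -1 else
          100 * cc$identical_columns / cc$aligned_columns
      }, 0)
      k <- which(pid >= threshold)[1]
    }
    if (is.na(k)) {
      centroids <- c(centroids, s)
      k <- length(centroids)
    }
    membership[i] <- k
  }
  otu_of_seq <- setNames(membership, uniq$sequence)
  sample_ids <- unique(clones$sample_id)
  lapply(seq_along(centroids), function(k) {
    members <- clones[otu_of_seq[clones$sequence] == k, , drop = FALSE]
    counts <- table(factor(members$sample_id, levels = sample_ids))
    counts <- counts[counts > 0]
    list(otu_id = sprintf("OTU%02d", k),
         representative = centroids[k],
         member_clone_ids = members$clone_id,
         per_sample_counts = setNames(as.integer(counts), names(counts)))
  })
}
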