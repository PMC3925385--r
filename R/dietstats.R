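## Size-class diet composition and bookkeeping over the OTU x sample clone
## table. Composition is presence-based (OTU counts, not clone abundance):
## cloned PCR products give presence/absence data.

SIZE_CLASSES <- c("I", "II", "III")

#' Predator size class from total length
#'
#' Half-open bins on total length (TL): I = \[0, 100) mm, II = \[100, 200)
#' mm, III = \[200, Inf) mm. TL, not body length, is the binning variable.
#'
#' @param tl_mm total length(s) in mm (> 0).
#' @return factor with levels `"I"`, `"II"`, `"III"`.
#' @export
size_class_of <- function(tl_mm) {
  if (any(!is.finite(tl_mm)) || any(tl_mm <= 0)) stop("total length must be positive")
  cut(tl_mm, breaks = c(0, 100, 200, Inf), labels = SIZE_CLASSES, right = FALSE)
}

#' Construct a clone table
#'
#' @param otus data frame with one row per OTU: `otu_id`, `taxon`, the six
#'   lineage ranks, `identity`, `level`, `clade_rank` (extra columns kept).
#' @param counts nonnegative integer matrix, OTUs x samples (rownames =
#'   `otu_id`, colnames matching `samples$sample_key`).
#' @param samples data frame of predator records: `no`, `id`, `tl_mm`,
#'   `bl_mm`, `wt_g`, `pcr_status` (`success`/`failed`/`empty_stomach`),
#'   `n_clones`; a `size_class` column is derived from `tl_mm`.
#' @param validate_subtotals optional named numeric `c(I=, II=, III=)` of
#'   expected per-size-class clone subtotals (from `n_clones`); mismatches
#'   are a validation error.
#' @return object of class `"clone_table"`.
#' @export
clone_table <- function(otus, counts, samples, validate_subtotals = NULL) {
  stopifnot(is.data.frame(otus), is.matrix(counts), is.data.frame(samples))
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("clone counts must be nonnegative integers")
  }
  if (nrow(counts) != nrow(otus)) stop("counts rows != OTU rows")
  if (ncol(counts) != nrow(samples)) stop("counts columns != sample rows")
  if (!all(samples$pcr_status %in% c("success", "failed", "empty_stomach"))) {
    stop("pcr_status must be success/failed/empty_stomach")
  }
  bad_zero <- samples$pcr_status != "success" & samples$n_clones != 0
  if (any(bad_zero)) {
    stop("failed/empty-stomach samples must have zero clones: ",
         paste(samples$id[bad_zero], collapse = ", "))
  }
  nonempty_cols <- colSums(counts) > 0
  if (any(nonempty_cols & samples$pcr_status != "success")) {
    stop("count matrix has clones in a failed/empty-stomach sample column")
  }
  if (any(samples$tl_mm < samples$bl_mm)) {
    warning("record(s) with TL < BL kept verbatim: ",
            paste(samples$id[samples$tl_mm < samples$bl_mm], collapse = ", "))
  }
  samples$size_class <- size_class_of(samples$tl_mm)
  if (!is.null(validate_subtotals)) {
    got <- tapply(samples$n_clones, samples$size_class, sum)
    bad <- names(which(got[SIZE_CLASSES] != validate_subtotals[SIZE_CLASSES]))
    if (length(bad)) {
      stop("clone subtotal mismatch for size class(es) ",
           paste(bad, collapse = ", "), ": got ",
           paste(got[bad], collapse = ", "), ", expected ",
           paste(validate_subtotals[bad], collapse = ", "))
    }
  }
  structure(list(otus = otus, counts = counts, samples = samples,
                 accounting = list(clone_total = sum(samples$n_clones),
                                   matrix_total = sum(counts))),
            class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  cat("Clone table:", nrow(x$otus), "OTUs x", nrow(x$samples), "samples;",
      x$accounting$clone_total, "clones sequenced")
  if (x$accounting$matrix_total != x$accounting$clone_total) {
    cat(" (matrix cells sum to", x$accounting$matrix_total,
        "- tabulated counts and sequencing totals differ)")
  }
  cat("\n")
  invisible(x)
}

#' Load the packaged (or a compatible) clone table
#'
#' Reads the OTU x sample clone-count table and the predator sample table,
#' validates internal consistency, and checks per-size-class clone
#' subtotals against their expected values (defaulting to the packaged
#' study's printed subtotals 85/142/81, total 308). The clone-count matrix
#' cells are tabulated per OTU and are known not to reconcile exactly with
#' the sequencing totals; the discrepancy is kept in `$accounting`, not
#' silently repaired.
#'
#' @param table2_tsv path to the OTU table TSV (lineage + identity + level
#'   + clade_rank + one count column per sample, `s1` ...).
#' @param table1_tsv path to the predator sample TSV.
#' @param expected_subtotals named numeric `c(I=, II=, III=)` or `NULL` to
#'   skip the checksum.
#' @return a [clone_table()].
#' @export
load_clone_table <- function(table2_tsv = barcodediet_example("table2.tsv"),
                             table1_tsv = barcodediet_example("table1.tsv"),
                             expected_subtotals = c(I = 85, II = 142, III = 81)) {
  samples <- read.delim(table1_tsv, stringsAsFactors = FALSE)
  t2 <- read.delim(table2_tsv, stringsAsFactors = FALSE,
                   na.strings = NULL, colClasses = NA)
  count_cols <- grep("^s[0-9]+$", names(t2), value = TRUE)
  if (length(count_cols) != nrow(samples)) {
    stop("count columns (", length(count_cols), ") != sample rows (", nrow(samples), ")")
  }
  counts <- as.matrix(t2[count_cols])
  rownames(counts) <- t2$otu_id
  meta_cols <- setdiff(names(t2), count_cols)
  otus <- t2[meta_cols]
  for (col in c("genus", "species")) otus[[col]][is.na(otus[[col]])] <- ""
  clone_table(otus, counts, samples, validate_subtotals = expected_subtotals)
}

#' OTUs from a clone table (fixture bypass mode)
#'
#' When only tabulated clone counts are available (no raw sequences), OTUs
#' are constructed directly from the table rows: one OTU per row, with
#' per-sample counts from the matrix cells and no representative sequence.
#'
#' @param t a [clone_table()].
#' @return list of OTUs in row order (`representative` is `NA`).
#' @export
otus_from_clone_table <- function(t) {
  stopifnot(inherits(t, "clone_table"))
  lapply(seq_len(nrow(t$otus)), function(i) {
    cnt <- t$counts[i, ]
    cnt <- cnt[cnt > 0]
    list(otu_id = t$otus$otu_id[i], representative = NA_character_,
         member_clone_ids = character(0),
         per_sample_counts = setNames(as.integer(cnt), names(cnt)))
  })
}

#' Path to a packaged example data file
#' @param file file name under the package's `extdata` (empty to list).
#' @export
barcodediet_example <- function(file = "") {
  if (!nzchar(file)) {
    return(dir(system.file("extdata", package = "barcodediet")))
  }
  path <- system.file("extdata", file, package = "barcodediet")
  if (!nzchar(path)) stop("no packaged file: ", file)
  path
}

drop_self <- function(t, exclude_self, predator_species = "Micropterus salmoides") {
  if (!exclude_self) return(t)
  keep <- t$otus$species != predator_species
  t$otus <- t$otus[keep, , drop = FALSE]
  t$counts <- t$counts[keep, , drop = FALSE]
  t
}

scope_columns <- function(t, scope) {
  ok <- t$samples$pcr_status == "success"
  if (!identical(scope, "all")) ok <- ok & t$samples$size_class == scope
  which(ok)
}

#' PCR success rate over non-empty gut samples
#'
#' `100 * successes / (successes + failures)`; empty stomachs are excluded
#' from the denominator. The exact fraction is returned; display rounds to
#' one decimal.
#'
#' @param samples predator record data frame (see [clone_table()]).
#' @return percent (exact fraction, not rounded).
#' @export
pcr_success_rate <- function(samples) {
  n_succ <- sum(samples$pcr_status == "success")
  n_fail <- sum(samples$pcr_status == "failed")
  if (n_succ + n_fail == 0) stop("no amplifiable (non-empty) samples")
  100 * n_succ / (n_succ + n_fail)
}

#' Per-sample OTU richness
#'
#' Number of OTU rows with a nonzero clone count in each successfully
#' amplified sample (failed and empty-stomach samples get no entry). All
#' OTU rows count, including any predator self-DNA row, matching the
#' tabulated convention; use `exclude_self = TRUE` to drop it.
#'
#' @param t a [clone_table()].
#' @param exclude_self drop the predator's own OTU first.
#' @return named integer vector (names = sample numbers).
#' @export
per_sample_richness <- function(t, exclude_self = FALSE) {
  t <- drop_self(t, exclude_self)
  cols <- scope_columns(t, "all")
  setNames(colSums(t$counts[, cols, drop = FALSE] > 0), t$samples$no[cols])
}

#' Taxon-class composition of the diet
#'
#' OTU presence (not clone abundance) grouped by the class rank of each
#' OTU's lineage; percent = 100 * count / total OTUs in scope.
#'
#' @param t a [clone_table()].
#' @param scope `"all"` or a size class `"I"`/`"II"`/`"III"` (OTUs present
#'   in at least one sample of that class).
#' @param exclude_self drop the predator's own OTU first.
#' @return data frame (`class`, `n_otus`, `percent`), descending by count
#'   then name.
#' @export
class_composition <- function(t, scope = "all", exclude_self = FALSE) {
  stopifnot(scope %in% c("all", SIZE_CLASSES))
  t <- drop_self(t, exclude_self)
  cols <- scope_columns(t, scope)
  present <- rowSums(t$counts[, cols, drop = FALSE] > 0) > 0
  cls <- t$otus$class[present]
  if (length(cls) == 0) {
    return(data.frame(class = character(0), n_otus = integer(0), percent = numeric(0)))
  }
  tab <- sort(table(cls), decreasing = TRUE)
  tab <- tab[order(-tab, names(tab))]
  data.frame(class = names(tab), n_otus = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Distinct-taxon richness rollup
#'
#' Counts of distinct filled names at the phylum, class, order, and family
#' ranks over all OTUs of the table.
#'
#' @inheritParams per_sample_richness
#' @return named integer vector `c(phyla=, classes=, orders=, families=)`.
#' @export
richness_rollup <- function(t, exclude_self = FALSE) {
  t <- drop_self(t, exclude_self)
  cnt <- function(v) length(unique(v[nzchar(v)]))
  c(phyla = cnt(t$otus$phylum), classes = cnt(t$otus$class),
    orders = cnt(t$otus$order), families = cnt(t$otus$family))
}

#' Size-class overlap partition of the OTU sets
#'
#' Places every observed OTU into exactly one of the seven cells of the
#' three-set partition (I only, II only, III only, the three pairwise
#' overlaps, and the center) by its presence pattern across size classes.
#'
#' @inheritParams per_sample_richness
#' @return named integer vector over cells `I`, `II`, `III`, `I&II`,
#'   `I&III`, `II&III`, `I&II&III`; cells sum to the number of OTUs
#'   observed in any class.
#' @export
size_class_overlap <- function(t, exclude_self = FALSE) {
  t <- drop_self(t, exclude_self)
  pres <- sapply(SIZE_CLASSES, function(k) {
    rowSums(t$counts[, scope_columns(t, k), drop = FALSE] > 0) > 0
  })
  pres <- matrix(pres, ncol = 3, dimnames = list(NULL, SIZE_CLASSES))
  cells <- c("I", "II", "III", "I&II", "I&III", "II&III", "I&II&III")
  key <- apply(pres, 1, function(p) paste(SIZE_CLASSES[p], collapse = "&"))
  out <- setNames(integer(length(cells)), cells)
  tab <- table(key[nzchar(key)])
  out[names(tab)] <- as.integer(tab)
  out
}

#' Full diet summary
#'
#' Bundles the bookkeeping and composition statistics: PCR success rate,
#' clone and OTU totals, identification-level counts, taxon richness
#' rollup, overall and per-size-class class composition, per-sample
#' richness, and the size-class overlap partition.
#'
#' @inheritParams per_sample_richness
#' @return list of class `"diet_summary"`.
#' @export
diet_summary <- function(t, exclude_self = FALSE) {
  td <- drop_self(t, exclude_self)
  comp <- setNames(lapply(c("all", SIZE_CLASSES), class_composition, t = t,
                          exclude_self = exclude_self), c("all", SIZE_CLASSES))
  structure(list(
    pcr_success_rate = pcr_success_rate(t$samples),
    clone_total = t$accounting$clone_total,
    matrix_total = td$accounting$matrix_total,
    n_otus = nrow(td$otus),
    level_counts = table(factor(td$otus$level,
                                levels = c("species", "genus", "family", "order"))),
    rollup = richness_rollup(t, exclude_self),
    composition = comp,
    classes_consumed = vapply(SIZE_CLASSES,
                              function(k) nrow(comp[[k]]), 0L),
    per_sample_richness = per_sample_richness(t, exclude_self),
    overlap = size_class_overlap(t, exclude_self),
    exclude_self = exclude_self), class = "diet_summary")
}

#' @export
print.diet_summary <- function(x, ...) {
  cat(sprintf("PCR success rate: %.1f%%\n", x$pcr_success_rate))
  cat(sprintf("%d clones sequenced; %d prey OTUs (%d species-level, %.1f%%)\n",
              x$clone_total, x$n_otus, x$level_counts[["species"]],
              100 * x$level_counts[["species"]] / x$n_otus))
  r <- x$rollup
  cat(sprintf("Taxa: %d phyla / %d classes / %d orders / %d families\n",
              r[["phyla"]], r[["classes"]], r[["orders"]], r[["families"]]))
  top <- head(x$composition$all, 3)
  cat("Top classes:",
      paste(sprintf("%s %d OTUs (%.2f%%)", top$class, top$n_otus, top$percent),
            collapse = ", "), "\n")
  cat("Classes consumed by size class:",
      paste(sprintf("%s=%d", names(x$classes_consumed), x$classes_consumed),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a diet summary report
#'
#' Deterministically writes TSV tables (composition per scope, rollup,
#' per-sample richness, overlap partition, headline numbers) to a
#' directory.
#'
#' @param summary a [diet_summary()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
render_report <- function(summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    w(do.call(rbind, lapply(names(summary$composition), function(s) {
      df <- summary$composition[[s]]
      if (nrow(df)) cbind(scope = s, df) else
        data.frame(scope = character(0), class = character(0),
                   n_otus = integer(0), percent = numeric(0))
    })), "composition.tsv"),
    w(data.frame(rank = names(summary$rollup), n = as.integer(summary$rollup)),
      "richness_rollup.tsv"),
    w(data.frame(sample_no = names(summary$per_sample_richness),
                 n_otus = as.integer(summary$per_sample_richness)),
      "per_sample_richness.tsv"),
    w(data.frame(cell = names(summary$overlap), n_otus = as.integer(summary$overlap)),
      "size_class_overlap.tsv"),
    w(data.frame(
      metric = c("pcr_success_rate", "clone_total", "n_otus", "n_species_level",
                 "pct_species_level", paste0("classes_consumed_", SIZE_CLASSES)),
      value = c(round(summary$pcr_success_rate, 1), summary$clone_total,
                summary$n_otus, summary$level_counts[["species"]],
                round(100 * summary$level_counts[["species"]] / max(summary$n_otus, 1), 1),
                summary$classes_consumed)), "headline.tsv"))
  invisible(files)
}
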