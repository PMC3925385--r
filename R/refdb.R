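#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head
NULL

LINEAGE_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Construct a Linnean lineage
#'
#' A lineage is a named character vector over the six ranks
#' phylum/class/order/family/genus/species, filled top-down: a filled rank
#' implies every higher rank is filled. Genus and species may be empty
#' (e.g. for a family-level reference or assignment). Subspecies names are
#' stored verbatim in the species slot; no subspecies rank is modeled.
#'
#' @param phylum,class,order,family,genus,species rank names (character
#'   scalars; `""` for unfilled lower ranks).
#' @return named character vector of length 6 with class `"lineage"`.
#' @examples
#' lineage("Arthropoda", "Insecta", "Diptera", "Chironomidae",
#'         "Chironomus", "Chironomus plumosus")
#' @export
lineage <- function(phylum = "", class = "", order = "", family = "",
                    genus = "", species = "") {
  x <- c(phylum = phylum, class = class, order = order, family = family,
         genus = genus, species = species)
  x[is.na(x)] <- ""
  filled <- nzchar(x)
  if (any(filled) && any(diff(filled) > 0)) {
    stop("lineage must be filled top-down (a filled rank implies all higher ranks filled): ",
         paste(x[filled], collapse = "/"))
  }
  structure(x, class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  filled <- x[nzchar(x)]
  cat(if (length(filled)) paste(filled, collapse = " / ") else "<empty lineage>", "\n")
  invisible(x)
}

lineage_from_row <- function(row) {
  do.call(lineage, as.list(setNames(as.character(row[LINEAGE_RANKS]), LINEAGE_RANKS)))
}

#' Most specific filled rank of a lineage
#' @param lin a [lineage()] or a named vector/list with the six rank names.
#' @return one of `"phylum"`, ..., `"species"`, or `NA` if empty.
#' @export
lowest_rank <- function(lin) {
  filled <- nzchar(as.character(lin[LINEAGE_RANKS]))
  if (!any(filled)) return(NA_character_)
  LINEAGE_RANKS[max(which(filled))]
}

validate_sequence <- function(seq, id = "<sequence>") {
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty sequence for record ", id)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    stop("record ", id, " contains symbols outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  s
}

#' Build a reference barcode database
#'
#' @param records data frame with columns `accession`, `sequence`, and the
#'   six lineage ranks (`phylum` ... `species`). Every record must have a
#'   species-level lineage and a sequence over `{A,C,G,T,N}`.
#' @return object of class `"reference_db"`: the validated record table plus
#'   a taxonomy index (rank -> name -> accessions).
#' @export
reference_db <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("accession", "sequence", LINEAGE_RANKS)
  missing <- setdiff(needed, names(records))
  if (length(missing)) stop("records lack columns: ", paste(missing, collapse = ", "))
  records <- as.data.frame(records)[, needed]
  rownames(records) <- NULL
  if (anyDuplicated(records$accession)) {
    stop("duplicate accessions: ",
         paste(unique(records$accession[duplicated(records$accession)]), collapse = ", "))
  }
  records$sequence <- mapply(validate_sequence, records$sequence, records$accession,
                             USE.NAMES = FALSE)
  for (i in seq_len(nrow(records))) {
    lin <- lineage_from_row(records[i, ])
    if (!identical(lowest_rank(lin), "species")) {
      stop("reference record ", records$accession[i], " is not resolved to species")
    }
  }
  index <- lapply(setNames(LINEAGE_RANKS, LINEAGE_RANKS), function(r) {
    split(records$accession, records[[r]])
  })
  structure(list(records = records, index = index), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Reference barcode DB:", nrow(x$records), "records;",
      length(x$index$species), "species,",
      length(x$index$genus), "genera,",
      length(x$index$family), "families\n")
  invisible(x)
}

#' @export
length.reference_db <- function(x) nrow(x$records)

db_record <- function(db, accession) {
  i <- match(accession, db$records$accession)
  if (is.na(i)) stop("accession not in reference DB: ", accession)
  db$records[i, ]
}

db_lineage <- function(db, accession) lineage_from_row(db_record(db, accession))

#' Read a reference library from FASTA plus a taxonomy table
#'
#' The taxonomy table is a 7-column TSV (`id`, then the six ranks
#' phylum...species) mapping every FASTA record ID to its lineage.
#'
#' @param fasta_path FASTA file of reference sequences (IDs = accessions).
#' @param taxonomy_path TSV taxonomy table.
#' @return a [reference_db()].
#' @export
read_reference_fasta <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  names(tax) <- tolower(names(tax))
  if (!identical(names(tax)[1], "id")) names(tax)[1] <- "id"
  missing <- setdiff(ids, tax$id)
  if (length(missing)) {
    stop("FASTA records without a taxonomy row: ", paste(missing, collapse = ", "))
  }
  rows <- tax[match(ids, tax$id), ]
  reference_db(data.frame(accession = ids,
                          sequence = as.character(seqs),
                          rows[LINEAGE_RANKS],
                          stringsAsFactors = FALSE))
}

#' Write a reference library back to FASTA + taxonomy TSV
#' @param db a [reference_db()].
#' @param fasta_path,taxonomy_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference_fasta <- function(db, fasta_path, taxonomy_path) {
  seqs <- Biostrings::DNAStringSet(setNames(db$records$sequence, db$records$accession))
  Biostrings::writeXStringSet(seqs, fasta_path)
  tax <- data.frame(id = db$records$accession, db$records[LINEAGE_RANKS],
                    stringsAsFactors = FALSE)
  write.table(tax, taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, taxonomy_path))
}

#' Outgroup candidates from the nearest other families
#'
#' Returns up to `n` reference records from families other than the query
#' lineage's family, preferring records that share the lowest possible
#' higher rank (same order, then same class, then same phylum, then any),
#' ordered lexicographically by accession within each tier.
#'
#' @param db a [reference_db()].
#' @param lin query [lineage()] (family rank must be filled).
#' @param n maximum number of outgroups (the tree-based identification
#'   protocol uses two or three).
#' @return data frame of up to `n` reference records (possibly 0 rows if no
#'   record lies outside the query family).
#' @export
outgroup_candidates <- function(db, lin, n = 3) {
  stopifnot(inherits(db, "reference_db"), n >= 1)
  if (nrow(db$records) == 0) stop("empty reference DB")
  rec <- db$records
  outside <- rec[rec$family != lin[["family"]], , drop = FALSE]
  if (nrow(outside) == 0) return(outside)
  tier <- rep(4L, nrow(outside))
  tier[nzchar(lin[["phylum"]]) & outside$phylum == lin[["phylum"]]] <- 3L
  tier[nzchar(lin[["class"]])  & outside$class  == lin[["class"]]]  <- 2L
  tier[nzchar(lin[["order"]])  & outside$order  == lin[["order"]]]  <- 1L
  picked <- outside[order(tier, outside$accession), , drop = FALSE]
  head(picked, n)
}
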