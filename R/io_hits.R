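#' Read a tabular alignment hit table
#'
#' Parses the standard 12-column tab-separated alignment output dialect
#' (query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score). Only the query,
#' subject, E-value and bit score drive downstream orthology calls; the
#' remaining columns are retained as opaque payload.
#'
#' @param path Path to a tab-separated hit file. An empty file yields a
#'   zero-row table.
#' @param species_id Optional species identifier attached to every record
#'   (the subject proteome the search was run against).
#' @return A `data.frame` with columns `query_id`, `subject_id`, `e_value`,
#'   `bit_score`, `species_id` and the eight payload columns, one row per
#'   input line, in file order.
#' @examples
#' f <- tempfile()
#' writeLines("q1\ts1\t35.2\t100\t60\t2\t1\t100\t5\t104\t1e-05\t200", f)
#' read_hit_table(f, species_id = "spA")
#' @export
read_hit_table <- function(path, species_id = NA_character_) {
  if (!file.exists(path)) stopf("hit file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hit_table(species_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stopf("malformed hit line %d in %s: %d column(s), expected 12", bad, path, nf[bad])
  }
  if (any(nf > 12L))
    warning(sprintf("%s: extra columns beyond 12 ignored", path), call. = FALSE)
  get <- function(i) vapply(fields, `[[`, "", i)
  ev <- suppressWarnings(as.numeric(get(11L)))
  bs <- suppressWarnings(as.numeric(get(12L)))
  if (anyNA(ev) || anyNA(bs)) {
    bad <- which(is.na(ev) | is.na(bs))[1L]
    stopf("malformed hit line %d in %s: non-numeric E-value or bit score", bad, path)
  }
  if (any(ev < 0) || any(bs < 0)) {
    bad <- which(ev < 0 | bs < 0)[1L]
    stopf("malformed hit line %d in %s: negative E-value or bit score", bad, path)
  }
  q <- get(1L); s <- get(2L)
  if (any(!nzchar(q)) || any(!nzchar(s))) {
    bad <- which(!nzchar(q) | !nzchar(s))[1L]
    stopf("malformed hit line %d in %s: empty identifier", bad, path)
  }
  data.frame(
    query_id = q, subject_id = s, e_value = ev, bit_score = bs,
    species_id = species_id,
    pident = get(3L), length = get(4L), mismatch = get(5L), gapopen = get(6L),
    qstart = get(7L), qend = get(8L), sstart = get(9L), send = get(10L),
    stringsAsFactors = FALSE
  )
}

empty_hit_table <- function(species_id = NA_character_) {
  data.frame(
    query_id = character(), subject_id = character(),
    e_value = numeric(), bit_score = numeric(),
    species_id = character(),
    pident = character(), length = character(), mismatch = character(),
    gapopen = character(), qstart = character(), qend = character(),
    sstart = character(), send = character(),
    stringsAsFactors = FALSE
  )
}

#' Write a hit table in the 12-column tabular dialect
#'
#' Inverse of [read_hit_table()]: `read_hit_table(write_hit_table(x, f))`
#' reproduces `query_id`, `subject_id`, `e_value` and `bit_score` losslessly
#' and in order.
#'
#' @param hits A hit table as returned by [read_hit_table()] or
#'   [fabricate_hit_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  payload <- c("pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send")
  for (p in payload) if (is.null(hits[[p]])) hits[[p]] <- "0"
  out <- cbind(
    hits$query_id, hits$subject_id,
    hits$pident, hits$length, hits$mismatch, hits$gapopen,
    hits$qstart, hits$qend, hits$sstart, hits$send,
    formatC(hits$e_value, format = "g", digits = 6),
    formatC(hits$bit_score, format = "g", digits = 6)
  )
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Construct a protein-to-gene map
#'
#' A gene map ties every protein identifier appearing in hit tables to its
#' gene and designates one representative protein per gene (the query used in
#' the forward search). Reciprocal hits are established at the gene level, so
#' a reverse best hit landing on any isoform of the same gene counts.
#'
#' @param protein_to_gene Named character vector: names are protein ids,
#'   values gene ids.
#' @param representative Named character vector: names are gene ids, values
#'   the representative protein id of that gene.
#' @return An object of class `gene_map`.
#' @export
gene_map <- function(protein_to_gene, representative) {
  if (is.null(names(protein_to_gene)) || is.null(names(representative)))
    stopf("gene_map inputs must be named vectors")
  miss <- setdiff(representative, names(protein_to_gene))
  if (length(miss))
    stopf("representative protein(s) missing from protein_to_gene: %s",
          paste(miss, collapse = ", "))
  bad <- names(representative)[protein_to_gene[representative] != names(representative)]
  if (length(bad))
    stopf("representative protein does not map back to its gene: %s",
          paste(bad, collapse = ", "))
  structure(list(protein_to_gene = protein_to_gene,
                 representative = representative),
            class = "gene_map")
}

#' Read a gene map from CSV
#'
#' Expects columns `protein_id`, `gene_id`, `is_representative` (0/1 or
#' TRUE/FALSE; exactly one representative per gene).
#'
#' @param path CSV path.
#' @return A [gene_map()] object.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "gene_id", "is_representative")
  if (!all(need %in% names(df)))
    stopf("gene map CSV needs columns: %s", paste(need, collapse = ", "))
  p2g <- stats::setNames(df$gene_id, df$protein_id)
  rep_rows <- df[as.logical(df$is_representative), , drop = FALSE]
  if (anyDuplicated(rep_rows$gene_id))
    stopf("multiple representative proteins for gene(s): %s",
          paste(unique(rep_rows$gene_id[duplicated(rep_rows$gene_id)]), collapse = ", "))
  gene_map(p2g, stats::setNames(rep_rows$protein_id, rep_rows$gene_id))
}

#' Write a gene map to CSV
#' @param gmap A [gene_map()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gmap, path) {
  df <- data.frame(
    protein_id = names(gmap$protein_to_gene),
    gene_id = unname(gmap$protein_to_gene),
    stringsAsFactors = FALSE
  )
  df$is_representative <- as.integer(
    gmap$representative[df$gene_id] == df$protein_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
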