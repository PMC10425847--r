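#' Read a binary presence/absence profile matrix
#'
#' The on-disk format is TSV: header row `gene_id` followed by species ids,
#' one row per gene, cells strictly 0/1.
#'
#' @param path TSV path.
#' @return Integer matrix, genes in rows (row names), species in columns
#'   (column names).
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("profile matrix needs a gene_id column plus species columns")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stopf("duplicate gene_id in %s: %s", path,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stopf("non-binary cell value in %s", path)
  rownames(m) <- genes
  assert_profile_matrix(m)
  m
}

#' Write a profile matrix
#'
#' Round-trip identity holds: [read_profile_matrix()] on the written file
#' reproduces the matrix bit-exactly.
#'
#' @param matrix Binary integer matrix with gene row names and species
#'   column names.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  assert_profile_matrix(matrix)
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read species annotations
#'
#' CSV with columns `species_id`, `major_group`, `is_ciliated`,
#' `has_motile_cilia`, optional `reduced_complement` and `display_name`.
#' Flags may be 0/1 or logical. Enforces the biological invariants that
#' prokaryotes are non-ciliated and motile cilia imply cilia.
#'
#' @param path CSV path.
#' @return A `data.frame` of per-species annotations.
#' @export
read_species_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (fl in c("is_ciliated", "has_motile_cilia", "reduced_complement")) {
    if (!is.null(ann[[fl]])) ann[[fl]] <- as.logical(ann[[fl]])
  }
  if (is.null(ann$reduced_complement)) ann$reduced_complement <- FALSE
  if (is.null(ann$display_name)) ann$display_name <- ann$species_id
  assert_annotations(ann)
  ann
}

#' Write species annotations
#' @param annotations Annotation `data.frame` (see [read_species_annotations()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_annotations <- function(annotations, path) {
  assert_annotations(annotations)
  out <- annotations
  for (fl in c("is_ciliated", "has_motile_cilia", "reduced_complement"))
    if (!is.null(out[[fl]])) out[[fl]] <- as.integer(out[[fl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line, `#` comments, blank lines ignored.
#' Values are parsed as logical (`true`/`false`), numeric when they look
#' numeric, otherwise strings (quotes stripped); comma-separated values
#' become vectors.
#'
#' @param path Config file path.
#' @return Named list of parsed values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stopf("config line lacks '=': %s", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    parse1 <- function(v) {
      if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) return(num)
      gsub('^"|"$', "", v)
    }
    parsed <- lapply(parts, parse1)
    out[[key]] <- if (length(parsed) == 1L) parsed[[1L]] else unlist(parsed)
  }
  out
}
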