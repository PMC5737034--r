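#' Read an OTU count table from TSV
#'
#' Accepts both common layouts. The OTUs-as-rows dialect has a header of the
#' form `#OTU_ID<TAB>sample1<TAB>...` (the leading `#` is part of the id
#' column name, not a comment); the samples-as-rows dialect is its
#' transpose.
#'
#' @param path Path to a tab-separated file with one header row and one
#'   leading id column.
#' @param orientation `"otus_as_rows"` (default, the classic OTU-table
#'   dialect) or `"samples_as_rows"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path,
                           orientation = c("otus_as_rows",
                                           "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one value ",
                          "column in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- colnames(mat)[!vapply(as.data.frame(mat), is.numeric, logical(1))]
    stop("non-numeric value column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(mat) <- ids
  if (orientation == "otus_as_rows") mat <- t(mat)
  otu_table(mat)
}

#' Write an OTU table as TSV (OTUs-as-rows dialect)
#'
#' @param x An [otu_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  x <- as_otu_table(x)
  out <- tibble::as_tibble(t(unclass(x)), rownames = "#OTU_ID")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

#' Read a taxonomy table from TSV
#'
#' Expects two columns: `otu_id` and a semicolon-separated lineage of up to
#' seven ranks (kingdom through species). Greengenes-style rank prefixes
#' (`k__`, `p__`, ...) are accepted and stripped. Missing or empty ranks
#' become the explicit placeholder `"unclassified"`.
#'
#' @param path Path to the TSV file (header optional for the lineage
#'   column; the first column is taken as the OTU id).
#' @return A tibble with columns `otu_id`, `kingdom`, ..., `species`.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) stop("expected otu_id and lineage columns", call. = FALSE)
  parse_lineages(as.character(df[[1L]]), as.character(df[[2L]]))
}

#' Parse semicolon-separated lineage strings into a taxonomy tibble
#'
#' @param otu_id Character vector of OTU identifiers.
#' @param lineage Character vector of lineages (up to 7 ranks, optional
#'   Greengenes `k__` prefixes).
#' @return A taxonomy tibble ([read_taxonomy()] format).
#' @export
parse_lineages <- function(otu_id, lineage) {
  dup <- unique(otu_id[duplicated(otu_id)])
  if (length(dup)) {
    stop("duplicate OTU id(s) in taxonomy: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  parts <- strsplit(lineage, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[kpcofgs]__", "", p)
    p[p == "" | is.na(p)] <- "unclassified"
    length(p) <- 7L
    p[is.na(p)] <- "unclassified"
    p
  }, character(7)))
  colnames(mat) <- .tax_ranks
  dplyr::bind_cols(tibble::tibble(otu_id = otu_id),
                   tibble::as_tibble(mat))
}

#' Write a taxonomy table as TSV
#' @param taxonomy A taxonomy tibble ([read_taxonomy()] format).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lineage <- apply(as.matrix(taxonomy[, .tax_ranks]), 1L, paste,
                   collapse = ";")
  readr::write_tsv(tibble::tibble(otu_id = taxonomy$otu_id,
                                  lineage = lineage),
                   path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `habitat`, `season`,
#'   `latitude`, `longitude` and any number of numeric environmental
#'   covariate columns (e.g. pH, salinity, TC, TN, TS, TP, NH4.N, NOx.N).
#' @return A tibble with `habitat` and `season` as factors.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "habitat", "season")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  df$habitat <- factor(df$habitat)
  df$season <- factor(df$season)
  df
}

#' Write sample metadata as TSV
#' @param meta Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

check_samples_match <- function(x, meta) {
  x <- as_otu_table(x)
  miss <- setdiff(rownames(x), meta$sample_id)
  if (length(miss)) {
    stop("sample(s) missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta[match(rownames(x), meta$sample_id), , drop = FALSE]
}

#' Write a distance matrix as square labeled TSV
#' @param dm A `dist` object with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  readr::write_tsv(tibble::as_tibble(m, rownames = "id"), path,
                   progress = FALSE)
  invisible(path)
}
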