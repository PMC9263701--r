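#' Construct an OTU count table
#'
#' An `otu_table` is an integer matrix of sequence counts with samples as
#' rows and taxa (OTUs or families) as columns. Counts are always stored as
#' raw integers; relative abundances are derived views (see
#' [relative_abundance()]), never stored.
#'
#' @param counts numeric matrix of non-negative integers, samples x taxa.
#' @param sample_ids,taxon_ids optional identifier vectors; default to the
#'   dimnames of `counts`. Must be unique and non-empty.
#' @param rarefied_depth even depth the table was rarefied to, or `NA` if
#'   the table has not been rarefied.
#' @return an `otu_table`: an integer matrix with class attribute and a
#'   `rarefied_depth` attribute.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      taxon_ids = colnames(counts), rarefied_depth = NA) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(taxon_ids)) {
    stop("counts must have sample and taxon identifiers (dimnames)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicated taxon id: ", taxon_ids[duplicated(taxon_ids)][1L])
  }
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at sample '%s', taxon '%s': %s",
                 sample_ids[bad[1L, 1L]], taxon_ids[bad[1L, 2L]],
                 counts[bad[1L, , drop = FALSE]]))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(counts, class = c("otu_table", "matrix", "array"),
            rarefied_depth = rarefied_depth)
}

#' @export
print.otu_table <- function(x, ...) {
  d <- attr(x, "rarefied_depth")
  cat(sprintf("otu_table: %d samples x %d taxa%s\n", nrow(x), ncol(x),
              if (!is.na(d)) sprintf(" (rarefied to %d)", d) else ""))
  cat("sample totals:", paste(utils::head(sample_totals(x), 6L),
                              collapse = ", "),
      if (nrow(x) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Per-sample read totals
#' @param x an [otu_table()].
#' @return named integer vector of per-sample totals.
#' @export
sample_totals <- function(x) rowSums(unclass(x))

#' Relative abundance view of a count table
#' @param x an [otu_table()] or count matrix (samples x taxa).
#' @return numeric matrix whose rows sum to 1 (all-zero rows stay zero).
#' @export
relative_abundance <- function(x) {
  m <- unclass(as.matrix(x))
  storage.mode(m) <- "double"
  tot <- rowSums(m)
  sweep(m, 1L, pmax(tot, 1), "/")
}

#' Read / write an OTU table (classic QIIME-style TSV)
#'
#' The on-disk format is tab-separated with taxa as rows and samples as
#' columns (the classic layout), or the transpose; orientation is
#' auto-detected by matching the header against `sample_ids` when given. A
#' trailing `taxonomy` column holding a semicolon-separated lineage is split
#' off into a [taxonomy_table()].
#'
#' @param path file path.
#' @param orientation `"auto"`, `"taxa_rows"` or `"samples_rows"`.
#' @param sample_ids known sample ids used for auto-detection (optional).
#' @return for the reader, a list with elements `otu` ([otu_table()]) and
#'   `taxonomy` (a [taxonomy_table()] or `NULL`).
#' @export
read_otu_table <- function(path, orientation = c("auto", "taxa_rows",
                                                 "samples_rows"),
                           sample_ids = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated identifier '%s' at line %d of %s",
                 ids[duplicated(ids)][1L],
                 which(duplicated(ids))[1L] + 1L, path))
  }
  tax <- NULL
  tax_col <- which(tolower(names(df)) == "taxonomy")
  if (length(tax_col)) {
    tax <- parse_lineage_strings(ids, df[[tax_col[1L]]])
    df <- df[, -tax_col, drop = FALSE]
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "auto") {
    orientation <- if (!is.null(sample_ids) &&
                       all(rownames(m) %in% sample_ids))
      "samples_rows" else "taxa_rows"
  }
  if (orientation == "taxa_rows") m <- t(m)
  list(otu = otu_table(m), taxonomy = tax)
}

#' @rdname read_otu_table
#' @param x an [otu_table()].
#' @param taxonomy optional [taxonomy_table()] written as a trailing
#'   semicolon-separated `taxonomy` column.
#' @export
write_otu_table <- function(x, path, taxonomy = NULL) {
  m <- t(unclass(x))  # classic layout: taxa as rows
  df <- data.frame("#OTU ID" = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    tax <- taxonomy[match(rownames(m), taxonomy$taxon_id), tax_ranks(),
                    drop = FALSE]
    df$taxonomy <- apply(tax, 1L, paste, collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus")
}

#' Construct a taxonomy table
#'
#' Maps each taxon id to a ranked lineage (kingdom ... genus); any rank may
#' be `"unclassified"`.
#'
#' @param taxon_id character vector of unique taxon ids.
#' @param ... one character vector per rank, in the order kingdom, phylum,
#'   class, order, family, genus (missing trailing ranks filled with
#'   `"unclassified"`). Alternatively pass a single data frame.
#' @return a data.frame of class `taxonomy_table` with columns `taxon_id`,
#'   `kingdom` ... `genus`.
#' @export
taxonomy_table <- function(taxon_id, ...) {
  args <- list(...)
  if (length(args) == 1L && is.data.frame(args[[1L]])) {
    ranks <- args[[1L]]
  } else {
    ranks <- as.data.frame(args, stringsAsFactors = FALSE)
  }
  taxon_id <- as.character(taxon_id)
  if (anyDuplicated(taxon_id)) {
    stop("duplicated taxon id: ", taxon_id[duplicated(taxon_id)][1L])
  }
  out <- data.frame(taxon_id = taxon_id, stringsAsFactors = FALSE)
  for (i in seq_along(tax_ranks())) {
    r <- tax_ranks()[i]
    v <- if (i <= ncol(ranks)) as.character(ranks[[i]]) else
      rep("unclassified", length(taxon_id))
    v[is.na(v) | v == ""] <- "unclassified"
    out[[r]] <- v
  }
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

parse_lineage_strings <- function(taxon_id, lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  ranks <- lapply(seq_along(tax_ranks()), function(i) {
    vapply(parts, function(p) {
      v <- if (length(p) >= i) trimws(p[i]) else ""
      v <- sub("^[kpcofg]__", "", v)  # greengenes-style prefixes
      if (v == "" || is.na(v)) "unclassified" else v
    }, character(1L))
  })
  names(ranks) <- tax_ranks()
  do.call(taxonomy_table, c(list(taxon_id = taxon_id), ranks))
}

#' Read / write a taxonomy table (TSV: taxon_id + one column per rank)
#' @param path file path.
#' @export
read_taxonomy_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  taxonomy_table(df[[1L]], df[, -1L, drop = FALSE])
}

#' @rdname read_taxonomy_table
#' @param taxonomy a [taxonomy_table()].
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
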