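#' Rarefy an OTU table to an even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, the standard correction for unequal sequencing effort before
#' diversity and network analysis. A single seeded draw is used (no
#' averaging over repeated draws), which keeps every downstream statistic
#' deterministic given the seed.
#'
#' @param x an [otu_table()].
#' @param depth target even depth (reads per sample); default 7000.
#' @param seed integer seed for the subsampling draw.
#' @return an [otu_table()] in which every retained sample totals exactly
#'   `depth`; samples with fewer than `depth` reads are dropped with a
#'   warning. The `rarefied_depth` attribute records `depth`.
#' @export
rarefy <- function(x, depth = 7000, seed = 1L) {
  if (!is.numeric(depth) || depth <= 0) stop("depth must be positive")
  depth <- as.integer(depth)
  tot <- sample_totals(x)
  keep <- tot >= depth
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(names(tot)[!keep], collapse = ", "))
  }
  m <- unclass(x)[keep, , drop = FALSE]
  out <- m
  set.seed(seed)
  for (i in seq_len(nrow(m))) {
    counts <- m[i, ]
    if (sum(counts) == depth) next
    drawn <- sample.int(sum(counts), depth)
    # map draw positions back to taxa via the cumulative count layout
    out[i, ] <- tabulate(findInterval(drawn - 1L, cumsum(counts),
                                      left.open = FALSE) + 1L,
                         nbins = ncol(m))
  }
  otu_table(out, rarefied_depth = depth)
}

#' Observed richness (number of OTUs detected per sample)
#' @param x an [otu_table()].
#' @return named integer vector.
#' @export
observed_richness <- function(x) {
  rowSums(unclass(x) > 0)
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums counts over all OTUs sharing a rank value (e.g. phylum or family)
#' and converts to relative abundance. Taxa outside the `top_k` by mean
#' relative abundance are merged into an `"others"` bucket;
#' `"unclassified"` is always kept as its own category.
#'
#' @param x an [otu_table()].
#' @param taxonomy a [taxonomy_table()]; OTUs it does not cover are
#'   treated as `"unclassified"`.
#' @param rank one of `kingdom, phylum, class, order, family, genus`.
#' @param top_k number of most abundant taxa kept; `Inf` keeps all.
#' @param relative return relative abundances (default) or summed counts.
#' @return matrix samples x rank values of class `aggregated_table`, with
#'   attributes `rank` and `others` (whether a bucket was formed). Rows of
#'   the relative form sum to 1.
#' @export
aggregate_by_rank <- function(x, taxonomy, rank = "phylum", top_k = 10,
                              relative = TRUE) {
  if (!rank %in% tax_ranks()) {
    stop("unknown rank '", rank, "'; must be one of ",
         paste(tax_ranks(), collapse = ", "))
  }
  lab <- taxonomy[[rank]][match(colnames(x), taxonomy$taxon_id)]
  lab[is.na(lab)] <- "unclassified"
  m <- unclass(x)
  storage.mode(m) <- "double"
  agg <- t(rowsum(t(m), group = lab))
  rel <- relative_abundance(agg)
  ord <- order(colMeans(rel), decreasing = TRUE)
  agg <- agg[, ord, drop = FALSE]
  named <- setdiff(colnames(agg), "unclassified")
  merged <- FALSE
  if (is.finite(top_k) && length(named) > top_k) {
    drop <- setdiff(named, named[seq_len(top_k)])
    others <- rowSums(agg[, drop, drop = FALSE])
    agg <- agg[, !colnames(agg) %in% drop, drop = FALSE]
    agg <- cbind(agg, others = others)
    merged <- TRUE
  }
  out <- if (relative) relative_abundance(agg) else agg
  structure(out, class = c("aggregated_table", "matrix", "array"),
            rank = rank, others = merged)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between every
#' pair of samples, on counts (typically rarefied, so counts are
#' proportional to relative abundance) or on relative abundances.
#'
#' @param x an [otu_table()] or non-negative numeric matrix (samples x
#'   taxa).
#' @return a [stats::dist] object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- unclass(as.matrix(x))
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (any(m < 0)) stop("abundances must be non-negative")
  tot <- rowSums(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- tot[i] + tot[j]
      if (denom == 0) {
        stop("Bray-Curtis undefined for all-zero sample pair: ",
             rownames(m)[i], ", ", rownames(m)[j])
      }
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  stats::as.dist(d)
}
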