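#' Remove OTUs with low total counts
#'
#' Drops OTUs whose summed count across all samples is below `min_total`
#' (default 2, i.e. global singletons are discarded). The sample set is
#' never changed; an empty result is allowed and logged.
#'
#' @param table an [otu_table()].
#' @param min_total minimum summed count for an OTU to be retained.
#' @return filtered [otu_table()].
#' @export
filter_low_count_otus <- function(table, min_total = 2L) {
  stopifnot(min_total >= 0)
  keep <- colSums(unclass(table)) >= min_total
  out <- otu_table(unclass(table)[, keep, drop = FALSE])
  log_stage("filter_low_count_otus", input_dims = dim(table),
            params = list(min_total = min_total), output_dims = dim(out))
  out
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each retained sample's counts are replaced by a uniform random subsample
#' of its reads, without replacement, summing exactly to `depth`
#' (via [vegan::rrarefy()]). Samples whose total is below `depth` are
#' dropped (not scaled) and logged, matching subsample-to-lowest-coverage
#' practice. Deterministic under a fixed seed.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (> 0).
#' @param seed integer seed.
#' @return rarefied [otu_table()]; possibly with fewer samples.
#' @export
rarefy <- function(table, depth = 16365L, seed = 1L) {
  stopifnot(depth > 0)
  depths <- sample_depths(table)
  keep <- depths >= depth
  if (!any(keep))
    stop("rarefy: all samples are below depth ", depth, call. = FALSE)
  m <- unclass(table)[keep, , drop = FALSE]
  # depths are validated above; rrarefy's heuristic "observed counts"
  # warning is a false alarm on high-count fixtures
  out <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  out <- otu_table(out)
  log_stage("rarefy", input_dims = dim(table),
            params = list(depth = depth,
                          dropped = rownames(table)[!keep]),
            output_dims = dim(out), seed = seed)
  out
}

#' Number of observed OTUs in one sample
#' @param row one sample's counts (numeric vector).
#' @return integer count of OTUs with count > 0.
#' @export
observed_otus <- function(row) {
  sum(row > 0)
}

#' Chao1 richness estimate for one sample
#'
#' The bias-corrected form (default, as computed by mothur and vegan) is
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1` and `F2` are singleton
#' and doubleton counts. The classical form `S_obs + F1^2 / (2 F2)` is
#' available via `bias_corrected = FALSE`; when `F2 = 0` it falls back to
#' the bias-corrected expression (the classical estimator is undefined
#' there). Always `>= S_obs`.
#'
#' @param row one sample's counts.
#' @param bias_corrected logical, see Details.
#' @return numeric richness estimate.
#' @export
chao1 <- function(row, bias_corrected = TRUE) {
  stopifnot(all(row >= 0))
  s_obs <- sum(row > 0)
  f1 <- sum(row == 1)
  f2 <- sum(row == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Inverse Simpson diversity for one sample
#'
#' `1 / sum(p_i^2)` with `p_i` the within-sample proportions. Ranges from 1
#' (single dominant OTU) to the number of observed OTUs (perfect evenness).
#'
#' @param row one sample's counts; must sum to > 0.
#' @return numeric diversity index.
#' @export
inverse_simpson <- function(row) {
  tot <- sum(row)
  if (tot <= 0) stop("inverse_simpson: zero-sum sample", call. = FALSE)
  p <- row / tot
  1 / sum(p^2)
}

#' Per-sample alpha-diversity table
#'
#' Computes observed OTUs, Chao1 and inverse Simpson for every sample of a
#' (typically rarefied) table.
#'
#' @param table an [otu_table()].
#' @param bias_corrected passed to [chao1()].
#' @return data frame with one row per sample.
#' @export
alpha_diversity <- function(table, bias_corrected = TRUE) {
  m <- unclass(table)
  data.frame(sample_id = rownames(m),
             observed_otus = apply(m, 1, observed_otus),
             chao1 = apply(m, 1, chao1, bias_corrected = bias_corrected),
             inverse_simpson = apply(m, 1, inverse_simpson),
             depth_used = rowSums(m),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table()] whose samples all have total reads > 0.
#' @return numeric matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero))
    stop("relative_abundance: zero-total sample(s): ",
         paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
  sweep(m, 1, tot, "/")
}

GI_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Aggregate an OTU table by taxonomic rank
#'
#' Sums counts per taxon at the requested rank. OTUs lacking an assignment
#' at that rank are pooled under an explicit `"unclassified"` bucket. With
#' `other_below` set, taxa whose average relative abundance across samples
#' falls below the threshold are pooled into `"other"` (the convention used
#' for composition bar plots, e.g. pooling phyla averaging < 5%).
#'
#' @param table an [otu_table()].
#' @param taxonomy data frame with column `otu_id` plus rank columns
#'   (`domain` ... `genus`); missing values or empty-placeholder ranks count
#'   as unclassified.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param other_below optional proportion threshold for pooling into
#'   `"other"` (e.g. 0.05), or `NULL` for no pooling.
#' @return an [otu_table()] keyed by taxon names; per-sample totals are
#'   preserved.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank = "phylum",
                              other_below = NULL) {
  if (!rank %in% GI_RANKS)
    stop("aggregate_by_rank: unknown rank '", rank, "'; use one of ",
         paste(GI_RANKS, collapse = ", "), call. = FALSE)
  m <- unclass(table)
  taxa <- taxonomy[[rank]][match(colnames(m), taxonomy$otu_id)]
  taxa[is.na(taxa) | taxa == "" | grepl("^unclassified", taxa)] <- "unclassified"
  agg <- t(rowsum(t(m), group = taxa))
  if (!is.null(other_below)) {
    prop <- sweep(agg, 1, rowSums(m), "/")
    minor <- colMeans(prop) < other_below & colnames(agg) != "unclassified"
    if (any(minor)) {
      other <- rowSums(agg[, minor, drop = FALSE])
      agg <- cbind(agg[, !minor, drop = FALSE], other = other)
    }
  }
  otu_table(agg)
}
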