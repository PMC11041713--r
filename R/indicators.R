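#' Kruskal-Wallis screening test for one OTU
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p-value (via
#' [stats::kruskal.test()]), comparing one OTU's per-sample abundances
#' between two classes. When every value is tied (the statistic is
#' undefined) the test is uninformative and p = 1 by convention.
#'
#' @param values per-sample abundances (proportions or counts) for one OTU.
#' @param labels class label per sample; exactly the two-class case is
#'   supported and both classes must be non-empty.
#' @return the p-value.
#' @export
kruskal_wallis_per_otu <- function(values, labels) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2 || any(table(labels) == 0))
    stop("kruskal_wallis_per_otu: need exactly two non-empty classes", call. = FALSE)
  if (length(unique(values)) == 1) return(1)
  stats::kruskal.test(values, factor(labels))$p.value
}

# H statistic alone (used by tests comparing against a permutation oracle)
kw_statistic <- function(values, labels) {
  if (length(unique(values)) == 1) return(0)
  unname(stats::kruskal.test(values, factor(labels))$statistic)
}

#' LEfSe-style LDA effect size for one OTU
#'
#' Abundance proportions are scaled to parts-per-million. For each of
#' `n_bootstrap` resamples — two-thirds of each class, drawn with
#' replacement — a one-dimensional linear discriminant is fit between the
#' classes and the log10 absolute difference of the class means on the
#' discriminant axis is recorded (for a single feature the discriminant
#' axis is the feature itself, so this is the log10 absolute difference of
#' resampled class means in ppm). Zero differences are floored at a small
#' positive epsilon before the log. The score is the mean across bootstraps;
#' scores above 2 mark biologically meaningful separation on this scale.
#'
#' @param values per-sample proportions for one OTU.
#' @param labels two-class labels; each class needs >= 2 samples.
#' @param n_bootstrap number of bootstrap resamples (default 30).
#' @param seed integer seed; fixed seed gives an identical score.
#' @param scale multiplier taking proportions to the scoring scale
#'   (default 1e6 = ppm).
#' @param epsilon floor for the absolute mean difference.
#' @return the LDA effect-size score (log10 scale).
#' @export
lda_effect_size <- function(values, labels, n_bootstrap = 30L, seed = 1L,
                            scale = 1e6, epsilon = 1e-30) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("lda_effect_size: need exactly two classes", call. = FALSE)
  i1 <- which(labels == lv[1]); i2 <- which(labels == lv[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("lda_effect_size: each class needs >= 2 samples", call. = FALSE)
  x <- values * scale
  m1 <- ceiling(2 / 3 * length(i1)); m2 <- ceiling(2 / 3 * length(i2))
  withr::with_seed(seed, {
    scores <- vapply(seq_len(n_bootstrap), function(b) {
      a <- x[sample(i1, m1, replace = TRUE)]
      bb <- x[sample(i2, m2, replace = TRUE)]
      log10(max(abs(mean(a) - mean(bb)), epsilon))
    }, numeric(1))
  })
  mean(scores)
}

# vectorized bootstrap LDA scores for a proportion matrix (samples x OTUs);
# one set of bootstrap draws shared across OTUs, as LEfSe resamples samples
lda_scores_matrix <- function(prop, labels, n_bootstrap = 30L, seed = 1L,
                              scale = 1e6, epsilon = 1e-30) {
  lv <- sort(unique(labels))
  i1 <- which(labels == lv[1]); i2 <- which(labels == lv[2])
  m1 <- ceiling(2 / 3 * length(i1)); m2 <- ceiling(2 / 3 * length(i2))
  x <- prop * scale
  acc <- matrix(0, n_bootstrap, ncol(prop))
  withr::with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      a <- x[sample(i1, m1, replace = TRUE), , drop = FALSE]
      bb <- x[sample(i2, m2, replace = TRUE), , drop = FALSE]
      acc[b, ] <- log10(pmax(abs(colMeans(a) - colMeans(bb)), epsilon))
    }
  })
  stats::setNames(colMeans(acc), colnames(prop))
}

#' Two-class indicator-species analysis (LEfSe-style)
#'
#' Screens every OTU with a Kruskal-Wallis test at `kw_alpha`, scores the
#' survivors with the bootstrapped LDA effect size, and reports OTUs whose
#' score exceeds `lda_threshold` as indicators. Direction is `"enriched"`
#' when the positive class (treatment / on-deposit) has the higher mean
#' proportion, `"depleted"` otherwise; both directions are reported.
#' Abundances are within-sample proportions, so results are invariant to
#' sequencing depth.
#'
#' @param table an [otu_table()].
#' @param metadata metadata with one record per sample and exactly two
#'   group labels among the table's samples.
#' @param config a [run_config()] (supplies `kw_alpha`, `lda_threshold`,
#'   `n_bootstrap`, `rng_seed`).
#' @param positive_class the treatment / on-deposit label; by default
#'   `"amended"` or `"above_kimberlite"`, whichever is present.
#' @param source label recorded per record (defaults to the samples' site).
#' @return data frame of indicator records: `otu_id`, `source`, `kw_p`,
#'   `lda_score`, `direction`; one row per significant OTU.
#' @export
run_indicator_analysis <- function(table, metadata, config = run_config(),
                                   positive_class = NULL, source = NULL) {
  validate_metadata(metadata, table)
  meta <- metadata[match(rownames(table), metadata$sample_id), ]
  labels <- meta$group
  lv <- unique(labels)
  if (length(lv) != 2)
    stop("run_indicator_analysis: need exactly two group labels, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (is.null(positive_class)) {
    positive_class <- intersect(c("amended", "above_kimberlite"), lv)
    if (length(positive_class) != 1)
      stop("run_indicator_analysis: cannot infer positive class from labels ",
           paste(lv, collapse = ", "), call. = FALSE)
  }
  if (is.null(source)) source <- unique(meta$site)[1]
  prop <- relative_abundance(table)
  kw_p <- apply(prop, 2, kruskal_wallis_per_otu, labels = labels)
  surv <- which(kw_p <= config$kw_alpha)
  rec <- data.frame(otu_id = character(0), source = character(0),
                    kw_p = numeric(0), lda_score = numeric(0),
                    direction = character(0), stringsAsFactors = FALSE)
  if (length(surv)) {
    scores <- lda_scores_matrix(prop[, surv, drop = FALSE], labels,
                                n_bootstrap = config$n_bootstrap,
                                seed = config$rng_seed)
    pos_mean <- colMeans(prop[labels == positive_class, surv, drop = FALSE])
    neg_mean <- colMeans(prop[labels != positive_class, surv, drop = FALSE])
    sig <- scores > config$lda_threshold
    if (any(sig)) {
      rec <- data.frame(
        otu_id = colnames(prop)[surv][sig],
        source = source,
        kw_p = unname(kw_p[surv][sig]),
        lda_score = unname(scores[sig]),
        direction = ifelse(pos_mean[sig] >= neg_mean[sig], "enriched", "depleted"),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  log_stage("run_indicator_analysis", input_dims = dim(table),
            params = list(kw_alpha = config$kw_alpha,
                          lda_threshold = config$lda_threshold,
                          n_bootstrap = config$n_bootstrap,
                          positive_class = positive_class),
            output_dims = c(nrow(rec), ncol(rec)), seed = config$rng_seed)
  rec
}

#' Census of an indicator record set
#'
#' Counts and percentages of enriched vs depleted indicators — the headline
#' summary of an indicator analysis (e.g. "65 of 375 (17%) increased in
#' relative abundance").
#'
#' @param records indicator record data frame.
#' @return list with `n_total`, `n_enriched`, `n_depleted`, `pct_enriched`,
#'   `pct_depleted` (percent, rounded to integers as conventionally printed)
#'   and the unrounded `pct_enriched_raw` / `pct_depleted_raw`.
#' @export
indicator_census <- function(records) {
  n <- nrow(records)
  n_up <- sum(records$direction == "enriched")
  n_dn <- sum(records$direction == "depleted")
  list(n_total = n, n_enriched = n_up, n_depleted = n_dn,
       pct_enriched = if (n) round(100 * n_up / n) else NA_real_,
       pct_depleted = if (n) round(100 * n_dn / n) else NA_real_,
       pct_enriched_raw = if (n) 100 * n_up / n else NA_real_,
       pct_depleted_raw = if (n) 100 * n_dn / n else NA_real_)
}

#' Overlap between the most abundant taxa of two sites
#'
#' Ranks OTUs by mean relative abundance at each site and reports how many
#' of the top `n` are shared — a quick check of whether two soil terrains
#' are similar in their dominant community members.
#'
#' @param table_a,table_b OTU tables sharing an OTU id space.
#' @param n number of top taxa to compare (default 20).
#' @return list with `shared_ids`, `n_shared`, `pct_shared`.
#' @export
shared_top_taxa <- function(table_a, table_b, n = 20L) {
  top <- function(tab) {
    mu <- colMeans(relative_abundance(tab))
    names(sort(mu, decreasing = TRUE))[seq_len(min(n, length(mu)))]
  }
  shared <- intersect(top(table_a), top(table_b))
  list(shared_ids = shared, n_shared = length(shared),
       pct_shared = 100 * length(shared) / n)
}
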