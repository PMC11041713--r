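# Independent reference implementations and small fixture builders shared
# across test files. These deliberately use naive algorithms so they stay
# independent of the package code paths they check.

# naive O(n^3) average-linkage agglomeration over the raw distance matrix;
# ties broken by lowest index pair. Returns sorted merge heights.
upgma_oracle_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d_ij <- mean(D[clusters[[i]], clusters[[j]]])
        if (d_ij < best_d - 1e-12) {
          best_d <- d_ij; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Kruskal-Wallis H computed from the textbook rank formula (tie-corrected),
# independent of stats::kruskal.test
kw_h_oracle <- function(values, labels) {
  r <- rank(values)
  N <- length(values)
  groups <- split(r, labels)
  h <- 12 / (N * (N + 1)) * sum(vapply(groups, function(g)
    length(g) * (mean(g) - (N + 1) / 2)^2, numeric(1)))
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}

# exact permutation distribution of H for a two-class labeling
kw_h_permutations <- function(values, n1) {
  N <- length(values)
  combos <- utils::combn(N, n1)
  apply(combos, 2, function(idx) {
    labels <- rep("b", N)
    labels[idx] <- "a"
    kw_h_oracle(values, labels)
  })
}

# small deterministic OTU table fixture
toy_table <- function() {
  otu_table(matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2", "S3"), c("Otu1", "Otu2"))))
}

# random valid OTU table with a fixed seed
random_table <- function(n_samples, n_otus, seed, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
                dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                                sprintf("Otu%04d", seq_len(n_otus))))
  })
  otu_table(m)
}

# metadata for a two-arm incubation final timepoint
incubation_meta <- function(sample_ids, groups, timepoint = 85) {
  data.frame(sample_id = sample_ids, site = "incubation", group = groups,
             timepoint_days = timepoint, easting_m = NA_real_,
             northing_m = NA_real_, surficial_class = NA_character_,
             stringsAsFactors = FALSE)
}

# restrict a simulate_incubation() result to its final timepoint
final_timepoint <- function(inc) {
  tF <- max(inc$metadata$timepoint_days)
  meta <- inc$metadata[inc$metadata$timepoint_days == tF, , drop = FALSE]
  list(table = otu_table(unclass(inc$table)[meta$sample_id, , drop = FALSE]),
       metadata = meta)
}

# planted-effect model used by the recovery suites: 20 responders at the
# detection boundary with factor 50, 50 mid-abundance decliners at 0.1;
# responder gains and decliner losses roughly balance so bystander taxa
# stay near the null
planted_model <- function(n_otus = 2000L, dispersion = 0.05) {
  ids <- sprintf("Otu%04d", seq_len(n_otus))
  rare_start <- n_otus - floor(0.3 * n_otus) + 1L
  responders <- ids[rare_start:(rare_start + 19L)]
  mid_start <- round(0.15 * n_otus)
  decliners <- ids[mid_start:(mid_start + 49L)]
  community_model(n_otus = n_otus, dispersion = dispersion,
                  responder_ids = responders,
                  responder_factors = rep(50, 20),
                  decliner_ids = decliners,
                  decliner_factors = rep(0.1, 50))
}

# null model: no planted effects at all
null_model <- function(n_otus = 800L, dispersion = 0.05, depth = 25000L) {
  community_model(n_otus = n_otus, dispersion = dispersion, depth = depth,
                  responder_ids = character(0), responder_factors = numeric(0),
                  decliner_ids = character(0), decliner_factors = numeric(0))
}
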