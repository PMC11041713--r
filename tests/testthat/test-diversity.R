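test_that("low-count filter removes OTUs below the total-read threshold", {
  m <- matrix(c(1L, 2L, 2L, 0L, 0L, 3L), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("OtuA", "OtuB", "OtuC")))
  tab <- otu_table(m)   # OTU totals 1, 2, 5
  filt <- filter_low_count_otus(tab, min_total = 2)
  expect_equal(colnames(filt), c("OtuB", "OtuC"))
  expect_equal(rownames(filt), rownames(tab))
  # identity at zero threshold; degenerate all-singleton case keeps samples
  expect_identical(unclass(filter_low_count_otus(tab, 0)), unclass(tab))
  single <- otu_table(diag(1L, 3), sample_ids = paste0("S", 1:3),
                      otu_ids = paste0("O", 1:3))
  empty <- filter_low_count_otus(single, 2)
  expect_equal(ncol(empty), 0)
  expect_equal(nrow(empty), 3)
})

test_that("rarefaction subsamples to exact depth, drops shallow samples, and is seeded", {
  m <- matrix(c(100L, 0L, 5L, 3L, 600L, 400L), nrow = 3, byrow = TRUE,
              dimnames = list(c("deep1", "shallow", "deep2"), c("O1", "O2")))
  tab <- otu_table(m)
  rar <- rarefy(tab, depth = 10, seed = 4)
  expect_equal(rownames(rar), c("deep1", "deep2"))
  expect_true(all(sample_depths(rar) == 10))
  expect_equal(unname(unclass(rar)["deep1", ]), c(10, 0))  # single-taxon sample
  # identity when total equals depth
  exact <- otu_table(matrix(c(4L, 6L), 1, dimnames = list("S", c("O1", "O2"))))
  expect_identical(unclass(rarefy(exact, 10, seed = 1)), unclass(exact))
  # determinism
  expect_identical(unclass(rarefy(tab, 10, seed = 4)), unclass(rar))
  expect_error(rarefy(tab, depth = 10000), "below depth")
})

test_that("rarefied counts follow the hypergeometric subsampling law", {
  tab <- otu_table(matrix(c(5000L, 5000L), 1, dimnames = list("S", c("O1", "O2"))))
  draws <- vapply(1:1000, function(s) unclass(rarefy(tab, 1000, seed = s))[1, 1],
                  numeric(1))
  # every draw inside the central 99.9% hypergeometric interval, sums exact
  lo <- qhyper(0.0005, 5000, 5000, 1000)
  hi <- qhyper(0.9995, 5000, 5000, 1000)
  expect_true(all(draws >= lo & draws <= hi))
  # moment check: mean and variance near hypergeometric expectation
  expect_equal(mean(draws), 500, tolerance = 0.01)
  v_exp <- 1000 * 0.5 * 0.5 * (10000 - 1000) / (10000 - 1)
  expect_equal(var(draws), v_exp, tolerance = 0.15)
})

test_that("chao1 matches its closed form and dominates observed richness", {
  # F1 = 0 collapses to observed richness
  expect_equal(chao1(c(3, 2, 5, 0)), 3)
  # hand evaluation: S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/(2*3) = 12
  row <- c(rep(1, 4), rep(2, 2), rep(3, 4))
  expect_equal(chao1(row), 12)
  # classical variant: 10 + 16/4 = 14; falls back when F2 = 0
  expect_equal(chao1(row, bias_corrected = FALSE), 14)
  expect_equal(chao1(c(1, 1, 3), bias_corrected = FALSE), chao1(c(1, 1, 3)))
  # property: chao1 >= observed, and agrees with vegan's estimator
  for (s in 1:20) {
    r <- withr::with_seed(s, rpois(50, 2))
    expect_gte(chao1(r), observed_otus(r))
    expect_equal(chao1(r), unname(vegan::estimateR(r)["S.chao1"]))
  }
})

test_that("inverse Simpson has its closed forms and vegan agreement", {
  expect_equal(inverse_simpson(c(10, 0, 0)), 1)
  expect_equal(inverse_simpson(c(50, 50)), 2)
  for (k in c(3, 7, 12))
    expect_equal(inverse_simpson(rep(5, k)), k)
  expect_error(inverse_simpson(c(0, 0)), "zero-sum")
  for (s in 1:10) {
    r <- withr::with_seed(s, rpois(30, 5)) + 1
    expect_equal(inverse_simpson(r),
                 unname(vegan::diversity(r, index = "invsimpson")))
    expect_gte(inverse_simpson(r), 1)
    expect_lte(inverse_simpson(r), observed_otus(r) + 1e-9)
  }
})

test_that("relative abundances are proper per-sample proportions", {
  tab <- toy_table()
  prop <- relative_abundance(tab)
  expect_equal(unname(rowSums(prop)), rep(1, 3))
  expect_equal(unname(prop["S1", ]), c(1, 0))
  expect_equal(unname(prop["S2", ]), c(1 / 3, 2 / 3))
  zero <- otu_table(matrix(c(1L, 0L, 0L, 0L), 2, byrow = TRUE,
                           dimnames = list(c("ok", "empty"), c("O1", "O2"))))
  expect_error(relative_abundance(zero), "empty")
})

test_that("rank aggregation conserves totals and pools unassigned taxa", {
  tab <- random_table(5, 8, seed = 9)
  taxonomy <- data.frame(
    otu_id = colnames(tab),
    domain = "Bacteria",
    phylum = c("Proteobacteria", "Proteobacteria", "Acidobacteria",
               "Chloroflexi", NA, "", "Bacteroidetes", "Chloroflexi"),
    stringsAsFactors = FALSE)
  agg <- aggregate_by_rank(tab, taxonomy, rank = "phylum")
  expect_setequal(colnames(agg), c("Proteobacteria", "Acidobacteria",
                                   "Chloroflexi", "Bacteroidetes", "unclassified"))
  expect_equal(unname(sample_depths(agg)), unname(sample_depths(tab)))
  expect_equal(unname(unclass(agg)[, "Proteobacteria"]),
               unname(rowSums(unclass(tab)[, 1:2])))
  # all-unassigned collapses to a single unclassified bucket
  tax_none <- data.frame(otu_id = colnames(tab), domain = NA, phylum = NA)
  agg0 <- aggregate_by_rank(tab, tax_none, rank = "phylum")
  expect_equal(colnames(agg0), "unclassified")
  expect_error(aggregate_by_rank(tab, taxonomy, rank = "species"), "unknown rank")
  # minor-taxon pooling into "other"
  agg_other <- aggregate_by_rank(tab, taxonomy, rank = "phylum", other_below = 0.2)
  expect_true("other" %in% colnames(agg_other))
  expect_equal(unname(sample_depths(agg_other)), unname(sample_depths(tab)))
})

test_that("amendment lowers observed richness and Chao1 at the final timepoint", {
  model <- community_model()
  inc <- simulate_incubation(model, n_replicates = 5, seed = 21)
  rar <- rarefy(filter_low_count_otus(inc$table), 16365, seed = 21)
  ad <- alpha_diversity(rar)
  meta <- inc$metadata[match(ad$sample_id, inc$metadata$sample_id), ]
  fin <- meta$timepoint_days == max(meta$timepoint_days)
  obs <- tapply(ad$observed_otus[fin], meta$group[fin], mean)
  ch <- tapply(ad$chao1[fin], meta$group[fin], mean)
  expect_lt(obs[["amended"]], obs[["control"]])
  expect_lt(ch[["amended"]], ch[["control"]])
})
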