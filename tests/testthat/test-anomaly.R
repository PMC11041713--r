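test_that("response ratio follows its percent definition and is unit-free", {
  labels <- c("above_kimberlite", "above_kimberlite", "background", "background")
  expect_equal(response_ratio(c(2, 2, 1, 1), labels), 100)
  expect_equal(response_ratio(c(1, 1, 1, 1), labels), 0)
  expect_equal(response_ratio(c(1.5, 1.5, 1, 1), labels), 50)
  # uniform rescaling leaves the ratio unchanged
  v <- c(3.2, 1.8, 2.4, 0.9)
  expect_equal(response_ratio(v * 1e6, labels), response_ratio(v, labels))
  expect_error(response_ratio(c(1, 1, 0, 0), labels), "undefined")
  expect_error(response_ratio(c(1, 1), c("background", "background")), "non-empty")
})

test_that("incubation indicators are curated by count, presence and field ratio", {
  rec <- data.frame(otu_id = c("OtuA", "OtuB", "OtuC", "OtuD"),
                    source = "incubation", kw_p = 0.01, lda_score = 3,
                    direction = c("enriched", "enriched", "enriched", "depleted"),
                    stringsAsFactors = FALSE)
  # incubation means: OtuA 10 reads (keep), OtuB 0.5 (fail rule a), OtuC 10
  inc <- otu_table(matrix(c(10L, 10L, 0L, 1L, 10L, 10L, 5L, 5L), 2,
                          dimnames = list(c("I1", "I2"),
                                          c("OtuA", "OtuB", "OtuC", "OtuD"))))
  # field table lacks OtuC (rule b); OtuA enriched on-deposit (rule c)
  fld <- otu_table(matrix(c(40L, 5L, 30L, 30L, 30L, 65L), 2, byrow = TRUE,
                          dimnames = list(c("F1", "F2"),
                                          c("OtuA", "OtuB", "OtuD"))))
  fmeta <- data.frame(sample_id = c("F1", "F2"), site = "field:DO18",
                      group = c("above_kimberlite", "background"),
                      timepoint_days = NA_real_, easting_m = 0, northing_m = 0,
                      surficial_class = NA_character_, stringsAsFactors = FALSE)
  cur <- curate_incubation_indicators(rec, inc, fld, fmeta)
  expect_equal(cur$otu_id, "OtuA")
  expect_equal(cur$mean_incubation_count, 10)
  expect_gt(cur$field_response_ratio_pct, 0)
  # empty input stays empty
  empty <- curate_incubation_indicators(rec[0, ], inc, fld, fmeta)
  expect_equal(nrow(empty), 0)
})

test_that("indicator set combination is a union with enriched precedence", {
  mk <- function(ids, source, dir = "enriched")
    data.frame(otu_id = ids, source = source, kw_p = 0.01, lda_score = 3,
               direction = dir, stringsAsFactors = FALSE)
  # disjoint 19 + 59 -> 78
  a <- mk(sprintf("A%02d", 1:19), "incubation")
  b <- mk(sprintf("B%02d", 1:59), "field:DO18")
  expect_equal(nrow(combine_indicator_sets(list(a, b))), 78)
  # idempotence
  expect_equal(nrow(combine_indicator_sets(list(a, a))), 19)
  # inclusion-exclusion: 3 and 4 sharing 2 -> 5
  x <- mk(c("O1", "O2", "O3"), "s1")
  y <- mk(c("O2", "O3", "O4", "O5"), "s2")
  comb <- combine_indicator_sets(list(x, y))
  expect_equal(nrow(comb), 5)
  # provenance of shared records lists both sources
  expect_true(any(grepl("s1\\+s2|s2\\+s1", comb$source)))
  # conflicting direction warns and keeps the enriched record
  z <- mk("O1", "s3", dir = "depleted")
  expect_warning(out <- combine_indicator_sets(list(x, z)), "conflicting")
  expect_equal(out$direction[out$otu_id == "O1"], "enriched")
})

test_that("anomaly surfaces conserve mean-normalization and class monotonicity", {
  meta <- data.frame(sample_id = paste0("S", 1:20), site = "field:X",
                     group = "background", timepoint_days = NA_real_,
                     easting_m = 1:20, northing_m = 1, surficial_class = NA,
                     stringsAsFactors = FALSE)
  vars <- withr::with_seed(10, matrix(rexp(20 * 4), 20, 4,
                                      dimnames = list(paste0("S", 1:20),
                                                      paste0("V", 1:4))))
  surf <- anomaly_surface(vars, meta)
  # after divide-by-mean each variable has mean 1, so the summed-score mean
  # equals the number of variables
  expect_equal(mean(surf$summed_score), 4, tolerance = 1e-12)
  # classes are monotone in score
  ord <- order(surf$summed_score)
  expect_true(all(diff(surf$anomaly_class[ord]) >= 0))
  # reordering samples never changes a sample's class
  surf2 <- anomaly_surface(vars[20:1, ], meta)
  m <- match(surf$sample_id, surf2$sample_id)
  expect_equal(surf2$anomaly_class[m], surf$anomaly_class)
  # constant single variable: flat surface, one class
  flat <- anomaly_surface(matrix(5, 20, 1, dimnames = list(paste0("S", 1:20), "V")),
                          meta)
  expect_true(all(flat$summed_score == 1))
  expect_equal(length(unique(flat$anomaly_class)), 1)
  # zero-mean variables are dropped with a warning
  vars0 <- cbind(vars, Z = 0)
  expect_warning(sz <- anomaly_surface(vars0, meta), "zero-mean")
  expect_equal(sz$summed_score, surf$summed_score)
})

test_that("geochemical anomaly applies the same pipeline to element columns", {
  meta <- data.frame(sample_id = paste0("S", 1:10), site = "field:X",
                     group = "background", timepoint_days = NA_real_,
                     easting_m = 1:10, northing_m = 1, surficial_class = NA,
                     stringsAsFactors = FALSE)
  geo <- data.frame(sample_id = paste0("S", 1:10),
                    Cr = rep(15, 10), Ni = rep(7, 10),
                    Nb = rep(2, 10), Mg = rep(0.24, 10))
  flat <- geochemical_anomaly(geo, metadata = meta)
  expect_true(all(flat$summed_score == 4))
  expect_equal(length(unique(flat$anomaly_class)), 1)
  expect_error(geochemical_anomaly(geo[, -2], metadata = meta), "Cr")
  # single element: surface proportional to concentration / mean
  geo$Cr <- seq(10, 100, 10)
  one <- geochemical_anomaly(geo, elements = "Cr", metadata = meta)
  expect_equal(one$summed_score, geo$Cr / mean(geo$Cr))
})

test_that("map export writes GeoJSON + CSV twins that round-trip", {
  meta <- data.frame(sample_id = paste0("S", 1:5), site = "field:X",
                     group = "background", timepoint_days = NA_real_,
                     easting_m = 100 * (1:5), northing_m = 7e6,
                     surficial_class = "till", stringsAsFactors = FALSE)
  vars <- matrix(c(1, 2, 3, 4, 10), 5, 1,
                 dimnames = list(paste0("S", 1:5), "V"))
  surf <- anomaly_surface(vars, meta, quantile_breaks = c(0.5, 0.9))
  path <- withr::local_tempfile(fileext = ".geojson")
  export_map(surf, stats::setNames(meta$surficial_class, meta$sample_id), path)
  back <- read_map(path)
  expect_equal(back$sample_id, surf$sample_id)
  expect_equal(back$summed_score, surf$summed_score)
  expect_equal(back$anomaly_class, surf$anomaly_class)
  expect_equal(back$easting_m, surf$easting_m)
  # CSV twin carries the same rows plus the surficial class
  csv <- utils::read.csv(sub("\\.geojson$", ".csv", path))
  expect_equal(nrow(csv), 5)
  expect_equal(csv$surficial_class, rep("till", 5))
  # empty surface still yields a valid FeatureCollection
  export_map(surf[0, ], path = path)
  fc <- jsonlite::read_json(path)
  expect_equal(fc$type, "FeatureCollection")
  expect_length(fc$features, 0)
  # missing coordinates refuse to export
  surf$easting_m[1] <- NA
  expect_error(export_map(surf, path = path), "coordinates")
})

test_that("randomization null is deterministic and distinct from true labels", {
  model <- community_model(n_otus = 300, dispersion = 0.2, depth = 8000)
  design <- survey_design(grid_shape = c(5, 5), footprint_radius_m = 60)
  svy_a <- simulate_survey(model, design, indicator_effect = 30,
                           site_name = "A", seed = 41)
  svy_b <- simulate_survey(model, design, indicator_effect = 30,
                           site_name = "B", seed = 42)
  cfg <- run_config()
  n1 <- randomization_null(svy_a$table, svy_a$metadata,
                           svy_b$table, svy_b$metadata,
                           n_reps = 3, config = cfg, seed = 5)
  n2 <- randomization_null(svy_a$table, svy_a$metadata,
                           svy_b$table, svy_b$metadata,
                           n_reps = 3, config = cfg, seed = 5)
  expect_identical(n1, n2)
  expect_length(n1$ratios, 3)
  expect_error(randomization_null(svy_a$table, svy_a$metadata,
                                  svy_b$table, svy_b$metadata,
                                  n_reps = 0, config = cfg, seed = 1),
               "n_reps")
  # the true-label transfer beats the permuted replicates
  rec <- run_indicator_analysis(svy_a$table, svy_a$metadata, cfg)
  comb <- combine_indicator_sets(list(rec[rec$direction == "enriched", ]))
  prop_b <- relative_abundance(svy_b$table)
  ids <- intersect(comb$otu_id, colnames(prop_b))
  v <- prop_b[, ids, drop = FALSE]
  score <- rowSums(sweep(v, 2, colMeans(v), "/"))
  labels_b <- svy_b$metadata$group[match(rownames(prop_b),
                                         svy_b$metadata$sample_id)]
  true_rr <- response_ratio(score, labels_b)
  expect_gt(true_rr, max(n1$ratios, na.rm = TRUE))
})
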