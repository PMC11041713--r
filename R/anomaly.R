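#' Response ratio of a variable between on- and off-deposit samples
#'
#' The percent excess of the on-deposit mean over the off-deposit mean:
#' `(mean(on) / mean(off) - 1) * 100`. A ratio-of-means (not a mean of
#' per-sample ratios, which would require a pairing that does not exist).
#' Unit-free: rescaling the variable uniformly leaves the ratio unchanged.
#'
#' @param values per-sample values of the variable.
#' @param labels per-sample labels; `positive_class` marks on-deposit.
#' @param positive_class label of the on-deposit / treatment group.
#' @return the response ratio in percent.
#' @export
response_ratio <- function(values, labels, positive_class = "above_kimberlite") {
  on <- values[labels == positive_class]
  off <- values[labels != positive_class]
  if (length(on) == 0 || length(off) == 0)
    stop("response_ratio: both label groups must be non-empty", call. = FALSE)
  m_off <- mean(off)
  if (m_off <= 0)
    stop("response_ratio: off-deposit mean is zero; ratio undefined", call. = FALSE)
  (mean(on) / m_off - 1) * 100
}

#' Curate incubation-derived indicators for use at a field site
#'
#' Keeps enriched incubation indicators that (a) averaged more than
#' `min_mean_count` raw reads per sample in the incubation experiment,
#' (b) are present in the field OTU table, and (c) have a positive response
#' ratio (relative abundance, on- vs off-deposit) at the field site. This
#' is the transfer rule that turns laboratory responders into mappable
#' field indicators.
#'
#' @param records enriched-direction incubation indicator records.
#' @param incubation_table the (unrarefied) incubation [otu_table()].
#' @param field_table the field-site [otu_table()] sharing the OTU id space.
#' @param field_metadata field metadata (groups `background` /
#'   `above_kimberlite`).
#' @param min_mean_count threshold for rule (a), default 1.
#' @return curated record data frame with added `mean_incubation_count` and
#'   `field_response_ratio_pct` columns; empty curation is allowed (logged).
#' @export
curate_incubation_indicators <- function(records, incubation_table, field_table,
                                         field_metadata, min_mean_count = 1) {
  records <- records[records$direction == "enriched", , drop = FALSE]
  if (nrow(records) == 0) return(cbind(records,
    mean_incubation_count = numeric(0), field_response_ratio_pct = numeric(0)))
  mean_cnt <- colMeans(unclass(incubation_table))[records$otu_id]
  present <- records$otu_id %in% colnames(field_table)
  prop <- relative_abundance(field_table)
  labels <- field_metadata$group[match(rownames(field_table),
                                       field_metadata$sample_id)]
  rr <- rep(NA_real_, nrow(records))
  for (i in which(present)) {
    v <- prop[, records$otu_id[i]]
    rr[i] <- if (mean(v[labels != "above_kimberlite"]) > 0)
      response_ratio(v, labels) else NA_real_
  }
  keep <- !is.na(mean_cnt) & mean_cnt > min_mean_count & present &
    !is.na(rr) & rr > 0
  out <- records[keep, , drop = FALSE]
  out$mean_incubation_count <- unname(mean_cnt[keep])
  out$field_response_ratio_pct <- rr[keep]
  log_stage("curate_incubation_indicators", input_dims = c(nrow(records), 1),
            params = list(min_mean_count = min_mean_count),
            output_dims = c(nrow(out), 1))
  rownames(out) <- NULL
  out
}

#' Combine indicator sets from several sources into one collection
#'
#' Union by OTU id, keeping enriched-direction records only (exploration
#' targets are positive anomalies); when the same OTU appears with
#' conflicting directions a warning is raised and the enriched record kept.
#' Provenance of every source is retained in a comma-joined `source` field.
#'
#' @param sets list of indicator record data frames.
#' @return deduplicated record data frame.
#' @export
combine_indicator_sets <- function(sets) {
  all <- do.call(rbind, lapply(sets, function(s)
    s[, c("otu_id", "source", "kw_p", "lda_score", "direction"), drop = FALSE]))
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(otu_id = character(0), source = character(0),
                      kw_p = numeric(0), lda_score = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  conflicted <- unique(all$otu_id[all$direction == "depleted" &
    all$otu_id %in% all$otu_id[all$direction == "enriched"]])
  if (length(conflicted))
    warning("combine_indicator_sets: conflicting directions for ",
            paste(conflicted, collapse = ", "), "; keeping enriched",
            call. = FALSE)
  all <- all[all$direction == "enriched", , drop = FALSE]
  out <- do.call(rbind, lapply(split(all, all$otu_id), function(g) {
    g1 <- g[which.max(g$lda_score), , drop = FALSE]
    g1$source <- paste(unique(g$source), collapse = "+")
    g1
  }))
  out <- out[order(-out$lda_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean-normalized summed anomaly surface
#'
#' Each variable (an indicator species' relative abundance, or an element
#' concentration) is divided by its mean across all survey samples, making
#' heterogeneous variables commensurable while keeping zeros at zero; the
#' normalized values are summed per sample. Anomaly classes are ordinal
#' intervals from empirical quantiles of the summed score (a deterministic
#' stand-in for analyst-picked probability-plot thresholds): class 0 below
#' the first break, up to `length(quantile_breaks)` above the last.
#'
#' @param variables numeric matrix, samples x variables (rownames are
#'   sample ids). Zero-mean variables are dropped with a warning.
#' @param metadata metadata providing coordinates per sample.
#' @param quantile_breaks strictly increasing probabilities in (0,1).
#' @return data frame of class `anomaly_surface`: `sample_id`, `easting_m`,
#'   `northing_m`, `summed_score`, `anomaly_class`.
#' @export
anomaly_surface <- function(variables, metadata,
                            quantile_breaks = c(0.5, 0.75, 0.9, 0.95, 0.98)) {
  variables <- as.matrix(variables)
  mu <- colMeans(variables)
  drop <- mu == 0
  if (all(drop))
    stop("anomaly_surface: all variables have zero mean", call. = FALSE)
  if (any(drop)) {
    warning("anomaly_surface: dropping zero-mean variable(s): ",
            paste(colnames(variables)[drop], collapse = ", "), call. = FALSE)
    variables <- variables[, !drop, drop = FALSE]
    mu <- mu[!drop]
  }
  norm <- sweep(variables, 2, mu, "/")
  score <- rowSums(norm)
  breaks <- unique(stats::quantile(score, probs = quantile_breaks,
                                   names = FALSE, type = 7))
  cls <- findInterval(score, breaks, left.open = TRUE)
  idx <- match(rownames(variables), metadata$sample_id)
  out <- data.frame(sample_id = rownames(variables),
                    easting_m = metadata$easting_m[idx],
                    northing_m = metadata$northing_m[idx],
                    summed_score = unname(score),
                    anomaly_class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("anomaly_surface", class(out))
  out
}

#' Indicator-species anomaly surface
#'
#' Convenience wrapper: selects the indicator OTUs present in the survey
#' table, takes their relative abundances, and calls [anomaly_surface()].
#'
#' @param records combined indicator records (enriched direction).
#' @param table survey [otu_table()].
#' @param metadata survey metadata.
#' @param quantile_breaks passed through.
#' @return an `anomaly_surface` data frame.
#' @export
indicator_anomaly <- function(records, table, metadata,
                              quantile_breaks = c(0.5, 0.75, 0.9, 0.95, 0.98)) {
  ids <- intersect(records$otu_id, colnames(table))
  if (length(ids) == 0)
    stop("indicator_anomaly: no indicator OTUs present in the survey table",
         call. = FALSE)
  prop <- relative_abundance(table)[, ids, drop = FALSE]
  anomaly_surface(prop, metadata, quantile_breaks)
}

#' Pathfinder-element geochemical anomaly surface
#'
#' Applies the same normalize-to-mean-and-sum pipeline to element
#' concentrations (classically Cr, Ni, Nb and Mg for kimberlite).
#' Normalization makes ppm and wt% elements commensurable.
#'
#' @param geochem geochemistry data frame (`sample_id` + element columns).
#' @param elements elements to sum; all must be present.
#' @param metadata survey metadata.
#' @param quantile_breaks passed through.
#' @return an `anomaly_surface` data frame.
#' @export
geochemical_anomaly <- function(geochem, elements = c("Cr", "Ni", "Nb", "Mg"),
                                metadata,
                                quantile_breaks = c(0.5, 0.75, 0.9, 0.95, 0.98)) {
  miss <- setdiff(elements, names(geochem))
  if (length(miss))
    stop("geochemical_anomaly: missing element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(geochem[, elements, drop = FALSE])
  rownames(m) <- geochem$sample_id
  anomaly_surface(m, metadata, quantile_breaks)
}

#' Label-randomization null for indicator transfer
#'
#' Asks whether indicators as "predictive" as the real ones could arise by
#' chance: for each replicate, the on/off labels of the training site are
#' permuted (group sizes preserved), the indicator analysis re-run on the
#' permuted labels, and the enriched "indicators" transferred to the test
#' site, where the response ratio of their mean-normalized summed abundance
#' is computed. Genuine indicator sets give consistently positive transfer
#' ratios; random ones scatter around zero, with roughly half negative.
#'
#' @param table_a,metadata_a training-site table and metadata.
#' @param table_b,metadata_b test-site table and metadata (shared OTU ids).
#' @param n_reps number of label permutations (default 10).
#' @param config a [run_config()].
#' @param seed integer; replicate seeds are derived from it.
#' @return list with `ratios` (length `n_reps`, NA when a permutation
#'   yields no transferable indicators), `n_negative`, and `n_indicators`
#'   per replicate.
#' @export
randomization_null <- function(table_a, metadata_a, table_b, metadata_b,
                               n_reps = 10L, config = run_config(), seed = 1L) {
  if (n_reps < 1) stop("randomization_null: n_reps must be >= 1", call. = FALSE)
  labels_b <- metadata_b$group[match(rownames(table_b), metadata_b$sample_id)]
  prop_b <- relative_abundance(table_b)
  ratios <- rep(NA_real_, n_reps)
  n_ind <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- (seed + 7919L * r) %% .Machine$integer.max
    meta_perm <- metadata_a
    meta_perm$group <- withr::with_seed(rep_seed, sample(metadata_a$group))
    cfg <- config
    cfg$rng_seed <- rep_seed
    rec <- run_indicator_analysis(table_a, meta_perm, cfg)
    rec <- rec[rec$direction == "enriched", , drop = FALSE]
    ids <- intersect(rec$otu_id, colnames(table_b))
    n_ind[r] <- length(ids)
    if (length(ids) == 0) next
    v <- prop_b[, ids, drop = FALSE]
    mu <- colMeans(v)
    v <- v[, mu > 0, drop = FALSE]
    if (ncol(v) == 0) next
    score <- rowSums(sweep(v, 2, colMeans(v), "/"))
    ratios[r] <- response_ratio(score, labels_b)
  }
  log_stage("randomization_null", params = list(n_reps = n_reps),
            output_dims = n_reps, seed = seed)
  list(ratios = ratios, n_negative = sum(ratios < 0, na.rm = TRUE),
       n_indicators = n_ind)
}

#' Export an anomaly surface as GeoJSON (with a CSV twin)
#'
#' Writes point features with `summed_score`, `anomaly_class` and (when
#' given) `surficial_class` properties; coordinates are the planar
#' easting/northing of the survey grid. A CSV with the same rows is written
#' alongside (same path with extension `.csv`).
#'
#' @param surface an [anomaly_surface()] data frame with coordinates.
#' @param surficial optional named character vector, surficial class per
#'   sample id.
#' @param path output GeoJSON path.
#' @return `path`, invisibly.
#' @export
export_map <- function(surface, surficial = NULL, path) {
  if (nrow(surface) > 0 &&
      (anyNA(surface$easting_m) || anyNA(surface$northing_m)))
    stop("export_map: missing coordinates", call. = FALSE)
  feats <- lapply(seq_len(nrow(surface)), function(i) {
    props <- list(sample_id = surface$sample_id[i],
                  summed_score = surface$summed_score[i],
                  anomaly_class = surface$anomaly_class[i])
    if (!is.null(surficial))
      props$surficial_class <- unname(surficial[surface$sample_id[i]])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(surface$easting_m[i],
                                         surface$northing_m[i])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  csv_path <- sub("\\.[^.]*$", ".csv", path)
  if (csv_path == path) csv_path <- paste0(path, ".csv")
  df <- as.data.frame(surface)
  if (!is.null(surficial))
    df$surficial_class <- unname(surficial[surface$sample_id])
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(path)
}

#' Read back a GeoJSON anomaly surface
#' @param path GeoJSON file written by [export_map()].
#' @return an `anomaly_surface` data frame.
#' @export
read_map <- function(path) {
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  out <- data.frame(
    sample_id = vapply(feats, function(f) f$properties$sample_id, character(1)),
    easting_m = vapply(feats, function(f) as.numeric(f$geometry$coordinates[[1]]), numeric(1)),
    northing_m = vapply(feats, function(f) as.numeric(f$geometry$coordinates[[2]]), numeric(1)),
    summed_score = vapply(feats, function(f) as.numeric(f$properties$summed_score), numeric(1)),
    anomaly_class = vapply(feats, function(f) as.integer(f$properties$anomaly_class), integer(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("anomaly_surface", class(out))
  out
}
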