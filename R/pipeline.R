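#' Run the full analysis pipeline from a declarative config
#'
#' Executes the requested stages in order — `simulate`, `diversity`,
#' `cluster`, `indicators`, `curate`, `anomaly`, `null-test` — writing every
#' intermediate as plain text under `outdir` and recording a manifest
#' (stage list, parameter hash, input/output paths, md5 checksums, seed,
#' package version). Reruns with an identical config and seed reproduce
#' identical outputs bit for bit.
#'
#' The config is a YAML file. Required fields: `outdir`, `seed`,
#' `rarefaction_depth`, `min_total_reads_per_otu`, `lda_threshold`,
#' `kw_alpha`, `n_bootstrap`, `quantile_breaks`. Optional: `stages`
#' (default all), `simulate` (a block with `n_otus`, `n_replicates`,
#' `grid_shape`, `indicator_effect`, ...), or `inputs` pointing at existing
#' OTU/metadata/geochemistry files instead of simulation.
#'
#' @param config_path path to the YAML run configuration.
#' @return the manifest (also written to `<outdir>/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config_path) {
  raw <- yaml::read_yaml(config_path)
  required <- c("outdir", "seed", "rarefaction_depth", "min_total_reads_per_otu",
                "lda_threshold", "kw_alpha", "n_bootstrap", "quantile_breaks")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("run_pipeline: config missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cfg <- run_config(rarefaction_depth = raw$rarefaction_depth,
                    min_total_reads_per_otu = raw$min_total_reads_per_otu,
                    lda_threshold = raw$lda_threshold,
                    kw_alpha = raw$kw_alpha,
                    n_bootstrap = raw$n_bootstrap,
                    quantile_breaks = unlist(raw$quantile_breaks),
                    rng_seed = raw$seed)
  stages <- raw$stages
  if (is.null(stages))
    stages <- c("simulate", "diversity", "cluster", "indicators",
                "curate", "anomaly", "null-test")
  outdir <- raw$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  old_log <- getOption("geoindicate.run_log")
  options(geoindicate.run_log = file.path(outdir, "run_log.jsonl"))
  on.exit(options(geoindicate.run_log = old_log), add = TRUE)

  manifest <- list(package_version = as.character(utils::packageVersion("geoindicate")),
                   config = config_path, seed = raw$seed, stages = list())
  md5_str <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)), f)
    unname(tools::md5sum(f))
  }
  note <- function(name, params, inputs, outputs) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, params_hash = md5_str(params),
      inputs = inputs, outputs = outputs,
      output_md5 = as.list(tools::md5sum(outputs)), seed = raw$seed)
  }

  state <- list()
  for (stage in stages) {
    if (stage == "simulate") {
      sim <- raw$simulate
      if (is.null(sim)) sim <- list()
      model <- community_model(
        n_otus = sim$n_otus %||% 2000L,
        n_responders = sim$n_responders %||% 65L,
        n_decliners = sim$n_decliners %||% 310L,
        depth = sim$depth %||% 25000L)
      inc <- simulate_incubation(model,
                                 n_replicates = sim$n_replicates %||% 5L,
                                 seed = raw$seed)
      design <- survey_design(grid_shape = unlist(sim$grid_shape %||% c(10L, 10L)))
      svy_a <- simulate_survey(model, design,
                               indicator_effect = sim$indicator_effect %||% 30,
                               site_name = "DO18", seed = raw$seed + 1L)
      svy_b <- simulate_survey(model, design,
                               indicator_effect = sim$indicator_effect %||% 30,
                               site_name = "Kelvin", seed = raw$seed + 2L)
      paths <- file.path(outdir, c("incubation_otu.tsv", "incubation_meta.csv",
                                   "do18_otu.tsv", "do18_meta.csv", "do18_geochem.csv",
                                   "kelvin_otu.tsv", "kelvin_meta.csv", "kelvin_geochem.csv"))
      write_otu_table(inc$table, paths[1]); write_metadata(inc$metadata, paths[2])
      write_otu_table(svy_a$table, paths[3]); write_metadata(svy_a$metadata, paths[4])
      write_geochem(svy_a$geochem, paths[5])
      write_otu_table(svy_b$table, paths[6]); write_metadata(svy_b$metadata, paths[7])
      write_geochem(svy_b$geochem, paths[8])
      state <- list(inc = inc, svy_a = svy_a, svy_b = svy_b)
      note("simulate", sim, character(0), paths)
    } else if (stage == "diversity") {
      load_inputs_if_needed(state, raw) -> state
      out <- file.path(outdir, "alpha_diversity.csv")
      filt <- filter_low_count_otus(state$inc$table, cfg$min_total_reads_per_otu)
      rar <- rarefy(filt, cfg$rarefaction_depth, seed = raw$seed)
      utils::write.csv(alpha_diversity(rar), out, row.names = FALSE)
      note("diversity", cfg[c("rarefaction_depth", "min_total_reads_per_otu")],
           file.path(outdir, "incubation_otu.tsv"), out)
    } else if (stage == "cluster") {
      load_inputs_if_needed(state, raw) -> state
      tree <- upgma(euclidean_distance_matrix(state$svy_a$table))
      nwk <- file.path(outdir, "do18_upgma.nwk")
      dendrogram_newick(tree, nwk)
      summ <- file.path(outdir, "do18_clusters.csv")
      utils::write.csv(cut_and_summarize(tree, metadata = state$svy_a$metadata),
                       summ, row.names = FALSE)
      note("cluster", list(linkage = "average"),
           file.path(outdir, "do18_otu.tsv"), c(nwk, summ))
    } else if (stage == "indicators") {
      load_inputs_if_needed(state, raw) -> state
      inc_final <- subset_final_timepoint(state$inc)
      state$rec_inc <- run_indicator_analysis(inc_final$table, inc_final$metadata, cfg)
      state$rec_a <- run_indicator_analysis(state$svy_a$table, state$svy_a$metadata, cfg)
      p1 <- file.path(outdir, "indicators_incubation.csv")
      p2 <- file.path(outdir, "indicators_do18.csv")
      utils::write.csv(state$rec_inc, p1, row.names = FALSE)
      utils::write.csv(state$rec_a, p2, row.names = FALSE)
      note("indicators", cfg[c("kw_alpha", "lda_threshold", "n_bootstrap")],
           character(0), c(p1, p2))
    } else if (stage == "curate") {
      state$curated <- curate_incubation_indicators(
        state$rec_inc, state$inc$table, state$svy_a$table, state$svy_a$metadata)
      state$combined <- combine_indicator_sets(list(state$curated, state$rec_a))
      p <- file.path(outdir, "indicators_combined.csv")
      utils::write.csv(state$combined, p, row.names = FALSE)
      note("curate", list(min_mean_count = 1), character(0), p)
    } else if (stage == "anomaly") {
      surf <- indicator_anomaly(state$combined, state$svy_b$table,
                                state$svy_b$metadata, cfg$quantile_breaks)
      geo <- geochemical_anomaly(state$svy_b$geochem,
                                 metadata = state$svy_b$metadata,
                                 quantile_breaks = cfg$quantile_breaks)
      p1 <- file.path(outdir, "kelvin_microbial_anomaly.geojson")
      p2 <- file.path(outdir, "kelvin_geochem_anomaly.geojson")
      surficial <- stats::setNames(state$svy_b$metadata$surficial_class,
                                   state$svy_b$metadata$sample_id)
      export_map(surf, surficial, p1)
      export_map(geo, surficial, p2)
      note("anomaly", list(quantile_breaks = cfg$quantile_breaks), character(0),
           c(p1, p2, sub("\\.geojson$", ".csv", c(p1, p2))))
    } else if (stage == "null-test") {
      nul <- randomization_null(state$svy_a$table, state$svy_a$metadata,
                                state$svy_b$table, state$svy_b$metadata,
                                n_reps = raw$null_reps %||% 10L,
                                config = cfg, seed = raw$seed)
      p <- file.path(outdir, "null_response_ratios.csv")
      utils::write.csv(data.frame(replicate = seq_along(nul$ratios),
                                  response_ratio_pct = nul$ratios,
                                  n_indicators = nul$n_indicators),
                       p, row.names = FALSE)
      note("null-test", list(n_reps = raw$null_reps %||% 10L), character(0), p)
    } else {
      stop("run_pipeline: unknown stage '", stage, "'", call. = FALSE)
    }
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# restrict an incubation run to its final timepoint (the two-arm contrast
# used for indicator derivation)
subset_final_timepoint <- function(inc) {
  tF <- max(inc$metadata$timepoint_days)
  keep <- inc$metadata$timepoint_days == tF
  meta <- inc$metadata[keep, , drop = FALSE]
  tab <- otu_table(unclass(inc$table)[meta$sample_id, , drop = FALSE])
  list(table = tab, metadata = meta)
}

load_inputs_if_needed <- function(state, raw) {
  if (length(state) > 0 || is.null(raw$inputs)) return(state)
  ins <- raw$inputs
  state$inc <- list(table = read_otu_table(ins$incubation_otu),
                    metadata = read_metadata(ins$incubation_meta))
  state$svy_a <- list(table = read_otu_table(ins$site_a_otu),
                      metadata = read_metadata(ins$site_a_meta),
                      geochem = read_geochem(ins$site_a_geochem))
  state$svy_b <- list(table = read_otu_table(ins$site_b_otu),
                      metadata = read_metadata(ins$site_b_meta),
                      geochem = read_geochem(ins$site_b_geochem))
  state
}
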