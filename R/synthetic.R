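#' Parametric model of a soil microbial community
#'
#' Expected abundances follow a lognormal rank-abundance curve (deterministic
#' quantiles of a lognormal, so the curve itself carries no randomness): a
#' few dominant taxa and a long tail of rare ones, spanning several orders of
#' magnitude as soil communities do. A configurable fraction of the tail is
#' additionally suppressed below detection ("rare biosphere"), which is where
#' responders are drawn from by default — amendment selects for ingrowth of
#' taxa that are nearly undetectable at baseline.
#'
#' Responders carry multiplicative enrichment factors > 1 under treatment,
#' decliners factors < 1; the two sets are disjoint. Defaults are calibrated
#' to the share arithmetic typical of strong amendment responses: responders
#' are the most abundant members of the sub-detection rare tail (roughly
#' 0.5 expected reads each, ~0.1-0.6% of the community collectively) with
#' factors log-spaced over `responder_factor_range`, so that after
#' renormalization they grow to a dominant share of the amended community;
#' decliners default to the abundant bulk (the top `n_decliners` taxa, ~80%
#' of baseline reads) with factors log-spaced over
#' `decliner_factor_range`, collapsing to a few percent. Because the bloom
#' concentrates a fixed sequencing depth into few taxa, the detection-
#' marginal tail loses reads and observed richness declines under treatment.
#'
#' Counts are sampled as gamma-Poisson (negative binomial) around
#' `depth * p_i`, reproducing the overdispersion of amplicon counts. The
#' default dispersion (0.05, i.e. ~22% replicate CV for abundant taxa)
#' reflects replicate jars of homogenized soil; spatially distributed field
#' samples warrant a larger value (~0.3).
#'
#' @param n_otus number of OTUs.
#' @param sdlog lognormal shape of the rank-abundance curve.
#' @param dispersion negative-binomial overdispersion (counts have
#'   `size = 1/dispersion`); 0 gives Poisson counts.
#' @param rare_fraction fraction of OTUs forming the rare tail; at the
#'   default depth and `sdlog` the bottom 30% of the curve sits below ~0.6
#'   expected reads per sample, i.e. below detection.
#' @param rare_suppression optional extra multiplier (< 1) pushing the rare
#'   tail further down; default 1 (the lognormal tail is already
#'   sub-detection at typical depths).
#' @param n_responders,n_decliners sizes of the default responder/decliner
#'   sets (ignored when explicit ids are given).
#' @param responder_ids,responder_factors explicit responder set; factors
#'   must be > 1. Defaults pick the shallowest rare-tail OTUs with factors
#'   log-spaced in `responder_factor_range`.
#' @param decliner_ids,decliner_factors explicit decliner set; factors in
#'   (0,1). Defaults pick the most abundant taxa with factors log-spaced in
#'   `decliner_factor_range` (the dominant taxon collapses hardest).
#' @param responder_factor_range,decliner_factor_range numeric length-2.
#' @param depth expected sequencing depth per sample (mean total reads);
#'   default 25000 keeps samples above the usual 16365 rarefaction depth.
#' @return a list of class `community_model`.
#' @export
community_model <- function(n_otus = 2000L,
                            sdlog = 2,
                            dispersion = 0.05,
                            rare_fraction = 0.3,
                            rare_suppression = 1,
                            n_responders = 65L,
                            n_decliners = 310L,
                            responder_ids = NULL, responder_factors = NULL,
                            decliner_ids = NULL, decliner_factors = NULL,
                            responder_factor_range = c(200, 3000),
                            decliner_factor_range = c(0.05, 0.5),
                            depth = 25000L) {
  n_otus <- as.integer(n_otus)
  stopifnot(n_otus >= 1, sdlog > 0, dispersion >= 0,
            rare_fraction >= 0, rare_fraction < 1, depth > 0)
  otu_ids <- sprintf("Otu%04d", seq_len(n_otus))
  # abundance is monotone decreasing in OTU index: Otu0001 is the dominant
  base <- stats::qlnorm(rev(stats::ppoints(n_otus)), meanlog = 0, sdlog = sdlog)
  n_rare <- floor(rare_fraction * n_otus)
  rare_idx <- if (n_rare > 0) seq(n_otus - n_rare + 1L, n_otus) else integer(0)
  base[rare_idx] <- base[rare_idx] * rare_suppression
  names(base) <- otu_ids

  log_seq <- function(range, n) {
    if (n == 0) return(numeric(0))
    if (n == 1) return(sqrt(range[1] * range[2]))
    exp(seq(log(range[1]), log(range[2]), length.out = n))
  }
  if (is.null(responder_ids)) {
    n_responders <- min(as.integer(n_responders), length(rare_idx))
    # shallowest members of the rare tail: just below detection at baseline
    responder_ids <- otu_ids[rare_idx][seq_len(n_responders)]
    responder_factors <- log_seq(responder_factor_range, n_responders)
  }
  if (is.null(decliner_ids)) {
    pool <- setdiff(otu_ids[seq_len(n_otus - n_rare)], responder_ids)
    n_decliners <- min(as.integer(n_decliners), length(pool))
    # decliners are the abundant bulk; their collapse frees reads for responders
    decliner_ids <- pool[seq_len(n_decliners)]
    decliner_factors <- log_seq(decliner_factor_range, n_decliners)
  }
  if (is.null(responder_factors)) responder_factors <- rep(50, length(responder_ids))
  if (is.null(decliner_factors)) decliner_factors <- rep(0.1, length(decliner_ids))
  if (length(intersect(responder_ids, decliner_ids)))
    stop("community_model: responder and decliner sets must be disjoint", call. = FALSE)
  if (any(responder_factors <= 0) || any(decliner_factors <= 0))
    stop("community_model: enrichment factors must be > 0", call. = FALSE)
  structure(list(n_otus = n_otus, otu_ids = otu_ids,
                 base_abundance = base,
                 dispersion = dispersion,
                 rare_ids = otu_ids[rare_idx],
                 responder_ids = responder_ids,
                 responder_factors = stats::setNames(responder_factors, responder_ids),
                 decliner_ids = decliner_ids,
                 decliner_factors = stats::setNames(decliner_factors, decliner_ids),
                 depth = as.integer(depth)),
            class = "community_model")
}

#' Gridded field-survey design over a buried deposit
#'
#' Stations form a regular `nx x ny` grid. The deposit footprint is the set
#' of stations whose soils directly overlie the (drill-defined) body;
#' by default a compact block around a configurable center. Pathfinder-element
#' plumes are smeared down-ice along `ice_flow_azimuth_deg` (degrees
#' clockwise from grid north) with decay length `dispersion_length_m`,
#' peaking `plume_offset_m` down-ice of the source — glacial transport moves
#' eroded deposit material away from the bedrock source, so the geochemical
#' anomaly is spatially offset while the microbial one is coincident.
#'
#' @param grid_shape integer length-2 `(nx, ny)`.
#' @param station_spacing_m station spacing in meters.
#' @param deposit_footprint integer station indices (row-major over the
#'   grid) on-deposit; default: stations within `footprint_radius_m` of the
#'   grid center.
#' @param footprint_radius_m radius used for the default footprint.
#' @param ice_flow_azimuth_deg direction of past ice flow, degrees clockwise
#'   from north (290 is the westward flow typical of the study terrain).
#' @param dispersion_length_m decay length of the down-ice train.
#' @param plume_offset_m down-ice displacement of the plume maximum.
#' @param cross_width_m Gaussian cross-axis width of the train.
#' @param origin easting/northing of the grid's first station.
#' @return a list of class `survey_design` with station coordinates.
#' @export
survey_design <- function(grid_shape = c(10L, 10L),
                          station_spacing_m = 50,
                          deposit_footprint = NULL,
                          footprint_radius_m = 80,
                          ice_flow_azimuth_deg = 290,
                          dispersion_length_m = 200,
                          plume_offset_m = 75,
                          cross_width_m = 100,
                          origin = c(510000, 7140000)) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), station_spacing_m > 0)
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  easting <- origin[1] + (g$ix - 1) * station_spacing_m
  northing <- origin[2] + (g$iy - 1) * station_spacing_m
  n <- nx * ny
  if (is.null(deposit_footprint)) {
    cx <- mean(range(easting)); cy <- mean(range(northing))
    d <- sqrt((easting - cx)^2 + (northing - cy)^2)
    deposit_footprint <- which(d <= footprint_radius_m)
  }
  deposit_footprint <- as.integer(deposit_footprint)
  if (length(deposit_footprint) == 0)
    stop("survey_design: deposit footprint must not be empty", call. = FALSE)
  if (any(deposit_footprint < 1 | deposit_footprint > n))
    stop("survey_design: deposit footprint indices outside the grid", call. = FALSE)
  structure(list(grid_shape = c(nx, ny),
                 station_spacing_m = station_spacing_m,
                 easting_m = easting, northing_m = northing,
                 deposit_footprint = deposit_footprint,
                 ice_flow_azimuth_deg = ice_flow_azimuth_deg,
                 dispersion_length_m = dispersion_length_m,
                 plume_offset_m = plume_offset_m,
                 cross_width_m = cross_width_m),
            class = "survey_design")
}

# expected relative abundances under a treatment: multiply responder/decliner
# expectations by factor^frac (log-linear interpolation) and renormalize
treatment_profile <- function(model, frac = 1, responder_factors = NULL,
                              apply_decliners = TRUE) {
  ab <- model$base_abundance
  rf <- if (is.null(responder_factors)) model$responder_factors else responder_factors
  if (length(rf)) ab[names(rf)] <- ab[names(rf)] * rf^frac
  if (apply_decliners) {
    df <- model$decliner_factors
    if (length(df)) ab[names(df)] <- ab[names(df)] * df^frac
  }
  ab / sum(ab)
}

# gamma-Poisson counts for one sample around depth * p
sample_counts <- function(p, depth, dispersion) {
  mu <- depth * p / sum(p)
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
}

#' Simulate a two-arm kimberlite-amendment incubation time series
#'
#' Control-arm samples are drawn from the baseline community at every
#' timepoint. In the amended arm, responder and decliner expectations are
#' multiplied by their factors raised to `t / t_final` (linear in
#' log-factor: no effect at the first timepoint, full effect at the last),
#' then renormalized; counts are overdispersed gamma-Poisson draws. The
#' default timepoints 0, 15, 55 and 85 days follow standard amendment
#' sampling schedules.
#'
#' @param model a [community_model()].
#' @param n_replicates replicate jars per arm per timepoint.
#' @param timepoints strictly increasing sampling days.
#' @param seed integer; the simulation is bit-identical under a fixed seed.
#' @return list with elements `table` ([otu_table()]) and `metadata`.
#' @export
simulate_incubation <- function(model, n_replicates = 5L,
                                timepoints = c(0L, 15L, 55L, 85L),
                                seed = 1L) {
  stopifnot(inherits(model, "community_model"), n_replicates >= 1)
  if (any(diff(timepoints) <= 0))
    stop("simulate_incubation: timepoints must be strictly increasing", call. = FALSE)
  t0 <- timepoints[1]; tF <- timepoints[length(timepoints)]
  arms <- c("control", "amended")
  rows <- list(); meta <- list(); k <- 0L
  withr::with_seed(seed, {
    for (tp in timepoints) {
      frac <- if (tF > t0) (tp - t0) / (tF - t0) else 1
      for (arm in arms) {
        p <- if (arm == "amended") treatment_profile(model, frac)
             else model$base_abundance / sum(model$base_abundance)
        for (r in seq_len(n_replicates)) {
          k <- k + 1L
          rows[[k]] <- sample_counts(p, model$depth, model$dispersion)
          meta[[k]] <- data.frame(
            sample_id = sprintf("INC_T%03d_%s_%02d", tp, arm, r),
            site = "incubation", group = arm, timepoint_days = tp,
            easting_m = NA_real_, northing_m = NA_real_,
            surficial_class = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  })
  meta <- do.call(rbind, meta)
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(meta$sample_id, model$otu_ids)
  tab <- otu_table(counts)
  log_stage("simulate_incubation", input_dims = NULL,
            params = list(n_replicates = n_replicates, timepoints = timepoints,
                          n_otus = model$n_otus, depth = model$depth),
            output_dims = dim(tab), seed = seed)
  list(table = tab, metadata = meta)
}

# closed-form plume surface for a design: double-exponential along-ice peaked
# plume_offset_m down-ice of each source station, Gaussian across-ice
plume_surface <- function(design) {
  az <- design$ice_flow_azimuth_deg * pi / 180
  ex <- sin(az); ey <- cos(az)   # unit vector pointing down-ice
  x <- design$easting_m; y <- design$northing_m
  out <- numeric(length(x))
  for (d in design$deposit_footprint) {
    dx <- x - x[d]; dy <- y - y[d]
    u <- dx * ex + dy * ey          # down-ice displacement
    v <- -dx * ey + dy * ex         # cross-ice displacement
    out <- out + exp(-abs(u - design$plume_offset_m) / design$dispersion_length_m) *
      exp(-v^2 / (2 * design$cross_width_m^2))
  }
  out / length(design$deposit_footprint)
}

#' Simulate a gridded field survey over a buried deposit
#'
#' Microbial counts are drawn as in [simulate_incubation()], but the only
#' treatment effect is the responder enrichment (`indicator_effect`),
#' applied at on-deposit stations at full strength — field anomalies are a
#' subtle species-level signal on an otherwise homogeneous community, not
#' the wholesale restructuring seen in amendment experiments.
#' Geochemistry is a per-element background plus a plume term that
#' decays with distance down-ice from the deposit footprint (maximal
#' strictly down-ice, not directly on top), times lognormal noise — so the
#' geochemical anomaly is spatially offset from the deposit while the
#' microbial anomaly is coincident with it.
#'
#' Default element backgrounds (Cr 15 ppm, Mg 0.24 wt%, Ni 7 ppm, Nb 2 ppm)
#' are typical background-soil concentrations for this terrain.
#'
#' @param model a [community_model()].
#' @param design a [survey_design()].
#' @param indicator_effect multiplicative enrichment of responder OTUs at
#'   on-deposit stations (> 0; 1 = no microbial signal).
#' @param site_name used in metadata as `field:<site_name>`.
#' @param geochem_background named per-element background concentrations.
#' @param geochem_amplitude plume amplitude as a multiple of background.
#' @param geochem_noise_sdlog lognormal noise sd (log scale); 0 = noiseless.
#' @param seed integer; fixed seed gives an identical triplet.
#' @return list with `table`, `metadata`, `geochem`.
#' @export
simulate_survey <- function(model, design, indicator_effect = 30,
                            site_name = "DO18",
                            geochem_background = c(Cr = 15, Ni = 7, Nb = 2, Mg = 0.24),
                            geochem_amplitude = 3,
                            geochem_noise_sdlog = 0.4,
                            seed = 1L) {
  stopifnot(inherits(model, "community_model"), inherits(design, "survey_design"))
  if (indicator_effect <= 0)
    stop("simulate_survey: indicator_effect must be > 0", call. = FALSE)
  n <- length(design$easting_m)
  on_dep <- seq_len(n) %in% design$deposit_footprint
  rf <- stats::setNames(rep(indicator_effect, length(model$responder_ids)),
                        model$responder_ids)
  # field anomalies are subtle: only the responder enrichment distinguishes
  # on-deposit stations; the abundant bulk stays homogeneous across the grid
  p_on <- treatment_profile(model, 1, responder_factors = rf,
                            apply_decliners = FALSE)
  p_off <- model$base_abundance / sum(model$base_abundance)
  plume <- plume_surface(design)
  sample_ids <- sprintf("%s_ST%03d", site_name, seq_len(n))
  counts <- matrix(0L, n, model$n_otus,
                   dimnames = list(sample_ids, model$otu_ids))
  geo <- matrix(0, n, length(geochem_background),
                dimnames = list(sample_ids, names(geochem_background)))
  withr::with_seed(seed, {
    for (i in seq_len(n))
      counts[i, ] <- sample_counts(if (on_dep[i]) p_on else p_off,
                                   model$depth, model$dispersion)
    for (j in seq_along(geochem_background)) {
      mu <- geochem_background[j] * (1 + geochem_amplitude * plume)
      noise <- if (geochem_noise_sdlog > 0)
        stats::rlnorm(n, -geochem_noise_sdlog^2 / 2, geochem_noise_sdlog)
      else rep(1, n)
      geo[, j] <- mu * noise
    }
  })
  meta <- data.frame(
    sample_id = sample_ids, site = paste0("field:", site_name),
    group = ifelse(on_dep, "above_kimberlite", "background"),
    timepoint_days = NA_real_,
    easting_m = design$easting_m, northing_m = design$northing_m,
    surficial_class = "till", stringsAsFactors = FALSE)
  geochem <- data.frame(sample_id = sample_ids, geo,
                        stringsAsFactors = FALSE, row.names = NULL)
  attr(geochem, "units") <- c(Cr = "ppm", Ni = "ppm", Nb = "ppm", Mg = "wt%")[
    intersect(c("Cr", "Ni", "Nb", "Mg"), names(geochem_background))]
  tab <- otu_table(counts)
  log_stage("simulate_survey",
            params = list(site = site_name, indicator_effect = indicator_effect,
                          n_stations = n,
                          n_on_deposit = sum(on_dep)),
            output_dims = dim(tab), seed = seed)
  list(table = tab, metadata = meta, geochem = geochem)
}
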