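#' Construct a validated OTU count table
#'
#' An OTU table is stored as an integer matrix with one row per sample and
#' one column per OTU; row names are sample ids and column names OTU ids.
#' Counts are always raw reads: relative abundances are derived on demand
#' (see [relative_abundance()]) and never stored, which prevents
#' double-normalization bugs downstream.
#'
#' @param counts numeric matrix of non-negative integers, samples x OTUs.
#' @param sample_ids,otu_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an object of class `otu_table` (an integer matrix).
#' @examples
#' m <- matrix(c(5, 0, 1, 2, 0, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("S1", "S2", "S3"), c("Otu001", "Otu002")))
#' tab <- otu_table(m)
#' sample_depths(tab)
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(sample_ids)) stop("otu_table: sample ids are required", call. = FALSE)
  if (is.null(otu_ids) && ncol(counts) > 0)
    stop("otu_table: OTU ids are required", call. = FALSE)
  rownames(counts) <- sample_ids
  colnames(counts) <- otu_ids
  validate_otu_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(matrix()))
  counts
}

validate_otu_table <- function(counts) {
  if (anyDuplicated(rownames(counts)))
    stop("otu_table: duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (ncol(counts) > 0 && anyDuplicated(colnames(counts)))
    stop("otu_table: duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "otu_table: invalid count at sample '%s', OTU '%s' (must be a non-negative integer)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]), call. = FALSE)
  invisible(counts)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs; depth %s-%s reads\n",
              nrow(x), ncol(x),
              if (ncol(x)) min(rowSums(x)) else 0,
              if (ncol(x)) max(rowSums(x)) else 0))
  invisible(x)
}

#' Per-sample coverage depth (row sums) of an OTU table
#'
#' @param table an [otu_table()].
#' @return named integer vector of total reads per sample.
#' @export
sample_depths <- function(table) {
  rowSums(unclass(table))
}

#' Read an OTU count table from disk
#'
#' Two tab-separated dialects are supported. `tsv_wide` has the sample id in
#' the first column and one integer column per OTU. `mothur_shared` is the
#' mothur "shared" layout (`label`, `Group`, `numOtus`, then one column per
#' OTU); the bookkeeping columns are dropped on read.
#'
#' Readers reject rather than coerce: a non-integer or negative cell is an
#' error naming the offending sample and OTU.
#'
#' @param path path to an existing file with a header row.
#' @param dialect `"tsv_wide"` (default) or `"mothur_shared"`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, dialect = c("tsv_wide", "mothur_shared")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_otu_table: no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("read_otu_table: malformed header in ", path, call. = FALSE)
  if (dialect == "mothur_shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(df)))
      stop("read_otu_table: mothur_shared file must have columns ",
           paste(need, collapse = ", "), " (line 1)", call. = FALSE)
    ids <- df[["Group"]]
    df <- df[, setdiff(names(df), need), drop = FALSE]
  } else {
    ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  if (nrow(df) == 0)
    stop("read_otu_table: empty data section in ", path, call. = FALSE)
  counts <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
           dimnames = list(ids, names(df))))
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("read_otu_table: non-numeric count at sample '%s', OTU '%s'",
                 ids[bad[1]], names(df)[bad[2]]), call. = FALSE)
  }
  otu_table(counts)
}

#' Write an OTU count table as wide TSV
#'
#' The on-disk format round-trips bit-exactly through [read_otu_table()].
#'
#' @param table an [otu_table()].
#' @param path destination file path.
#' @export
write_otu_table <- function(table, path) {
  validate_otu_table(table)
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

GI_GROUP_SETS <- list(incubation = c("control", "amended"),
                      field = c("background", "above_kimberlite"))

#' Read per-sample metadata
#'
#' Expects a CSV with columns `sample_id`, `site`, `group` and optionally
#' `timepoint_days`, `easting_m`, `northing_m`, `surficial_class`. Sites are
#' either `"incubation"` or `"field:<name>"`. Group labels must come from
#' `control`/`amended` (incubation) or `background`/`above_kimberlite`
#' (field). Field samples must carry planar coordinates (projected meters);
#' incubation samples must carry a timepoint.
#'
#' @param path path to the CSV file.
#' @return a `data.frame`, one validated record per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("read_metadata: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_metadata: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("site", "surficial_class"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  for (col in c("timepoint_days", "easting_m", "northing_m"))
    df[[col]] <- if (is.null(df[[col]])) NA_real_ else suppressWarnings(as.numeric(df[[col]]))
  df$surficial_class[!is.na(df$surficial_class) & df$surficial_class == ""] <- NA_character_
  validate_metadata(df)
  df
}

#' Validate a metadata data frame (optionally against an OTU table)
#'
#' @param meta metadata data frame as returned by [read_metadata()].
#' @param table optional [otu_table()] whose samples must each have exactly
#'   one metadata record.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, table = NULL) {
  if (anyDuplicated(meta$sample_id))
    stop("metadata: duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
         call. = FALSE)
  allowed <- unlist(GI_GROUP_SETS, use.names = FALSE)
  bad <- setdiff(unique(meta$group), allowed)
  if (length(bad))
    stop("metadata: unknown group label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  is_field <- startsWith(ifelse(is.na(meta$site), "", meta$site), "field:")
  no_xy <- is_field & (is.na(meta$easting_m) | is.na(meta$northing_m))
  if (any(no_xy))
    stop("metadata: field sample(s) missing coordinates: ",
         paste(meta$sample_id[no_xy], collapse = ", "), call. = FALSE)
  is_inc <- !is.na(meta$site) & meta$site == "incubation"
  no_t <- is_inc & is.na(meta$timepoint_days)
  if (any(no_t))
    stop("metadata: incubation sample(s) missing timepoint: ",
         paste(meta$sample_id[no_t], collapse = ", "), call. = FALSE)
  if (!is.null(table)) {
    missing <- setdiff(rownames(table), meta$sample_id)
    if (length(missing))
      stop("metadata: no record for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(meta)
}

#' Write sample metadata as CSV
#' @param meta metadata data frame.
#' @param path destination path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}

#' Read a geochemistry table
#'
#' A CSV with a `sample_id` column and one numeric column per element
#' (e.g. Cr, Ni, Nb in ppm; Mg in wt%). Units are attached as a named
#' character attribute `units`, defaulting to the conventional pathfinder
#' units; normalization downstream makes elements commensurable regardless.
#'
#' @param path path to the CSV file.
#' @param units named character vector of units per element column.
#' @return data frame with attribute `units`.
#' @export
read_geochem <- function(path, units = c(Cr = "ppm", Ni = "ppm",
                                         Nb = "ppm", Mg = "wt%")) {
  if (!file.exists(path)) stop("read_geochem: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("read_geochem: missing sample_id column", call. = FALSE)
  elems <- setdiff(names(df), "sample_id")
  for (e in elems) {
    v <- suppressWarnings(as.numeric(df[[e]]))
    if (anyNA(v) || any(v < 0))
      stop("read_geochem: negative or non-numeric concentration in column ", e,
           call. = FALSE)
    df[[e]] <- v
  }
  attr(df, "units") <- units[intersect(names(units), elems)]
  df
}

#' Write a geochemistry table as CSV
#' @param geochem geochemistry data frame.
#' @param path destination path.
#' @export
write_geochem <- function(geochem, path) {
  utils::write.csv(geochem, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Run configuration shared across pipeline stages
#'
#' Defaults follow common practice for 16S survey analysis of this kind:
#' rarefaction to 16365 reads (lowest coverage depth convention), removal of
#' OTUs with fewer than 2 reads in total, Kruskal-Wallis screening at
#' alpha = 0.05, 30 bootstrap resamples for the LDA effect size with
#' significance threshold 2 (log10 scale), and empirical quantile breaks
#' for anomaly classes.
#'
#' @param rarefaction_depth integer > 0, reads per sample after rarefaction.
#' @param min_total_reads_per_otu integer, low-count filter threshold.
#' @param lda_threshold log10 effect-size threshold for significance.
#' @param kw_alpha Kruskal-Wallis screening level.
#' @param n_bootstrap bootstrap resamples for the LDA effect size.
#' @param quantile_breaks strictly increasing probabilities in (0,1) defining
#'   anomaly class intervals.
#' @param rng_seed integer seed used by stochastic stages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(rarefaction_depth = 16365L,
                       min_total_reads_per_otu = 2L,
                       lda_threshold = 2.0,
                       kw_alpha = 0.05,
                       n_bootstrap = 30L,
                       quantile_breaks = c(0.5, 0.75, 0.9, 0.95, 0.98),
                       rng_seed = 1L) {
  cfg <- list(rarefaction_depth = as.integer(rarefaction_depth),
              min_total_reads_per_otu = as.integer(min_total_reads_per_otu),
              lda_threshold = lda_threshold,
              kw_alpha = kw_alpha,
              n_bootstrap = as.integer(n_bootstrap),
              quantile_breaks = quantile_breaks,
              rng_seed = as.integer(rng_seed))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$rarefaction_depth <= 0)
    stop("run_config: rarefaction_depth must be > 0", call. = FALSE)
  qb <- cfg$quantile_breaks
  if (length(qb) && (any(qb <= 0 | qb >= 1) || any(diff(qb) <= 0)))
    stop("run_config: quantile_breaks must be strictly increasing in (0,1)",
         call. = FALSE)
  invisible(cfg)
}

#' Stage logging contract
#'
#' Every pipeline stage emits one structured record: stage name, input
#' dimensions, parameters, output dimensions and the seed used. Records are
#' appended as JSON lines to the file named by
#' `options(geoindicate.run_log = ...)`; with no log file set the record is
#' discarded silently (interactive use).
#'
#' @param stage stage name.
#' @param input_dims,output_dims numeric vectors (e.g. `dim()` of a table).
#' @param params named list of the parameters the stage actually used.
#' @param seed seed used, or NA for deterministic stages.
#' @return the record, invisibly.
#' @export
log_stage <- function(stage, input_dims = NULL, params = list(),
                      output_dims = NULL, seed = NA) {
  rec <- list(stage = stage, input_dims = input_dims, params = params,
              output_dims = output_dims, seed = seed,
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- getOption("geoindicate.run_log", NULL)
  if (!is.null(path)) {
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
    cat(line, "\n", sep = "", file = path, append = TRUE)
  }
  invisible(rec)
}
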