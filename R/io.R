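## Canonical on-disk dialect: tab-separated, UTF-8, "." decimal, no
## thousands separators. Doubles are written with "%.17g" so that numeric
## columns round-trip bit-exactly.

#' Write a data frame as a lossless TSV
#'
#' Numeric (double) columns are formatted with 17 significant digits so the
#' written file parses back to bit-identical doubles; integers and strings
#' are written verbatim.
#'
#' @param df Data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input file.
#' @param required Optional character vector of column names that must be
#'   present; a missing column raises an error naming it.
#' @return A data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "", fileEncoding = "UTF-8"),
    error = function(e) {
      stop("malformed table '", path, "': ", conditionMessage(e))
    }
  )
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop("schema mismatch in '", path, "': missing column ",
           paste(miss, collapse = ", "))
    }
  }
  df
}

#' Write a screen hit table
#'
#' Mirrors the single-metabolite table layout (AUC, P1, LogFCh, P2,
#' endpoint, factor constraints, class sizes). Sentinel fold changes are
#' written exactly as `99.000` / `-99.000`; all other numeric columns keep
#' full precision.
#'
#' @param hits Hit data frame from [screen_blocks()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  out <- hits
  if (nrow(out)) {
    sentinel <- !is.na(out$lfc) & abs(out$lfc) == 99
    lfc <- sprintf("%.17g", out$lfc)
    lfc[sentinel] <- sprintf("%.3f", out$lfc[sentinel])
    lfc[is.na(out$lfc)] <- "NA"
    out$lfc <- lfc
  }
  write_tsv(out, path)
}

#' Default run configuration
#'
#' All thresholds of the pipeline with their standard values: consistency
#' 0.8, imputation missingness cap 0.25, fold-change gate 2, level-1
#' significance 0.05 with tendencies up to 0.10, ROC-AUC gate 0.700,
#' small-sample AUC exception 0.850 (blocks under 12 samples), single
#' coverage gate 70, combined coverage gate 80, Bonferroni family level
#' 0.10, precursor/MS2 tolerances 10/5 ppm with 3 matching MS2 ions, and a
#' minimum of 3 samples per outcome class in a block.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    consistency_threshold = 0.8,
    consistency_group = "d40",
    max_missing_fraction = 0.25,
    impute_ntree = 100L,
    fc_gate = 2,
    alpha_significant = 0.05,
    alpha_tendency = 0.10,
    auc_gate = 0.700,
    small_n = 12L,
    small_n_auc = 0.850,
    small_n_alpha = 0.15,
    min_predicted = 70,
    min_combined = 80,
    bonferroni_level = 0.10,
    precursor_ppm = 10,
    ms2_ppm = 5,
    min_ms2 = 3L,
    min_class = 3L,
    stage0h_sets = c("M", "EB", "B", "EB+B", "free"),
    stage24h_sets = c("ExB", "FEB", "free"),
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key: ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  validate_run_config(cfg)
  structure(cfg, class = "run_config", overridden = names(ov))
}

validate_run_config <- function(cfg) {
  in01 <- c("alpha_significant", "alpha_tendency", "small_n_alpha")
  for (k in in01) {
    if (cfg[[k]] <= 0 || cfg[[k]] > 1) stop("invalid ", k, ": ", cfg[[k]])
  }
  if (cfg$consistency_threshold <= 0 || cfg$consistency_threshold > 1) {
    stop("invalid consistency_threshold")
  }
  if (cfg$max_missing_fraction < 0 || cfg$max_missing_fraction > 1) {
    stop("invalid max_missing_fraction")
  }
  if (cfg$auc_gate < 0.5 || cfg$auc_gate > 1) stop("invalid auc_gate")
  if (cfg$fc_gate <= 1) stop("invalid fc_gate")
  if (cfg$min_class < 1) stop("invalid min_class")
  invisible(cfg)
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline on a fixture directory
#'
#' Executes the fixed stage order (preprocess, screen, coverage, report) on
#' inputs in `indir` (as written by [write_fixtures()]) and writes all
#' output tables plus a run manifest into `outdir`. Reruns with the same
#' inputs and configuration are byte-identical.
#'
#' @param indir Directory with `features.tsv`, `blanks.tsv`, `samples.tsv`,
#'   `impact.tsv`.
#' @param outdir Output directory (created if absent).
#' @param config A [run_config()] object.
#' @param taxonomy Optional data frame (`metabolite`, `class`) for the tally
#'   report.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(indir, outdir, config = run_config(),
                         taxonomy = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  bundle <- read_fixtures_for_run(indir)
  samples <- bundle$samples

  prep <- preprocess_features(bundle$raw, bundle$blanks, samples,
                              config = config)
  net_df <- cbind(data.frame(feature_id = rownames(prep$net)),
                  as.data.frame(prep$net, optional = TRUE))
  write_tsv(net_df, file.path(outdir, "net_matrix.tsv"))
  jsonlite::write_json(
    list(drop_reasons = prep$flags, scale_factors = prep$scale_factors,
         blank_scale_factors = prep$blank_scale_factors,
         stage_order = prep$log),
    file.path(outdir, "preprocess_sidecar.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  screen <- screen_blocks(prep$net, samples, config = config)
  write_hits(screen$hits, file.path(outdir, "hits.tsv"))

  singles <- select_single_biomarkers(screen$hits, bundle$impact,
                                      min_predicted = config$min_predicted)
  write_tsv(singles, file.path(outdir, "singles.tsv"))
  series <- best_combination_per_series(screen$hits, bundle$impact,
                                        min_combined = config$min_combined)
  write_tsv(series, file.path(outdir, "series.tsv"))

  rates <- pregnancy_rate_table(samples)
  write_tsv(rates, file.path(outdir, "pregnancy_rates.tsv"))
  if (nrow(screen$hits)) {
    summ <- auc_vs_n_summary(screen$hits)
    write_tsv(summ$bins, file.path(outdir, "auc_vs_n.tsv"))
    if (is.null(taxonomy)) {
      taxonomy <- data.frame(metabolite = unique(screen$hits$feature_id),
                             class = "unknown")
    }
    tally <- tally_by_class(screen$hits, taxonomy)
    write_tsv(tally$table, file.path(outdir, "tally.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("embryoscreen")),
    config = unclass(config),
    config_hash = config_hash(config),
    overridden_keys = attr(config, "overridden"),
    seed = config$seed,
    rows = list(samples = nrow(samples),
                features_in = nrow(bundle$raw$intensity),
                features_retained = nrow(prep$net),
                blocks = nrow(screen$blocks),
                level1_passers = attr(screen$hits, "n_level1"),
                hits = nrow(screen$hits),
                singles = nrow(singles),
                series_members = nrow(series))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(preprocess = prep, screen = screen, singles = singles,
                 series = series, rates = rates, manifest = manifest))
}

read_fixtures_for_run <- function(indir) {
  for (f in c("features.tsv", "blanks.tsv", "samples.tsv", "impact.tsv")) {
    if (!file.exists(file.path(indir, f))) {
      stop("missing input: ", file.path(indir, f))
    }
  }
  read_fixtures_partial(indir)
}

read_fixtures_partial <- function(dir) {
  feat <- read_tsv(file.path(dir, "features.tsv"),
                   required = c("feature_id", "rt_min", "mz"))
  meta_cols <- c("feature_id", "rt_min", "mz")
  features <- feat[, meta_cols]
  raw <- as.matrix(feat[, setdiff(names(feat), meta_cols), drop = FALSE])
  rownames(raw) <- features$feature_id
  injections <- data.frame(
    column_id = colnames(raw),
    sample_id = sub("_r[0-9]+$", "", colnames(raw)),
    replicate = as.integer(sub("^.*_r", "", colnames(raw)))
  )
  blk <- read_tsv(file.path(dir, "blanks.tsv"), required = "feature_id")
  blanks <- as.matrix(blk[, -1, drop = FALSE])
  rownames(blanks) <- blk$feature_id
  batches <- data.frame(
    blank_id = colnames(blanks),
    round = as.integer(sub("^R([0-9]+)_.*$", "\\1", colnames(blanks))),
    culture = sub("^R[0-9]+_", "", colnames(blanks))
  )
  samples <- read_tsv(file.path(dir, "samples.tsv"),
                      required = c("sample_id", "cryo", "breed", "culture",
                                   "stage0h", "stage24h", "age",
                                   "d40", "d62", "birth"))
  impact <- read_tsv(file.path(dir, "impact.tsv"),
                     required = c("culture", "stage0h", "stage24h",
                                  "percent", "culture_share"))
  list(raw = list(intensity = raw, injections = injections),
       blanks = list(intensity = blanks, batches = batches),
       samples = samples, features = features, impact = impact)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
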