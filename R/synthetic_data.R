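#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults emulate a single-culture embryo-transfer
#' study: 84 transfers (28 fresh Day-7, 48 frozen Day-7, 8 frozen Day-8),
#' two bull breeds, two culture conditions (BSA with or without serum),
#' seven bulls as a random factor, and nested pregnancy endpoints at
#' Day-40, Day-62 and birth.
#'
#' @param n_samples Total number of embryo transfers. Ignored when `margins`
#'   is supplied; otherwise the default cryo-by-age margins are rescaled to
#'   this total.
#' @param margins Data frame with columns `cryo`, `age`, `n` giving the exact
#'   number of samples per cryopreservation-by-embryo-age cell.
#' @param factor_levels Named list of factor levels (`cryo`, `breed`,
#'   `culture`, `bull`, `stage0h`, `stage24h`, `age`).
#' @param endpoint_model Named numeric vector of baseline pregnancy
#'   probabilities for `D40`, `D62`, `Birth`. Must be non-increasing so that
#'   per-sample endpoint indicators are monotone (birth implies Day-62
#'   implies Day-40).
#' @param n_features Number of spectral features to simulate.
#' @param planted_effects List of [planted_effect()] objects.
#' @param noise Log2-scale SD of the biological (per-sample) noise on the
#'   embryo contribution.
#' @param missing List with `lod_quantile` (global detection-limit quantile
#'   below which observed intensities are censored) and `mcar` (additional
#'   missing-completely-at-random rate).
#' @param bull_sd Log2-scale SD of the per-bull random intercept.
#' @param bull_frac Fraction of features carrying the bull effect.
#' @param injection_cv Coefficient of variation of the technical duplicate
#'   injections.
#' @param constituent_frac Fraction of features that are medium constituents
#'   (present in the blank; embryos may consume them, so net intensities can
#'   be negative after blank subtraction).
#' @param consumed_frac Among medium constituents, fraction consumed (rather
#'   than released) by the embryo.
#' @param n_rounds Number of embryo-transfer rounds (blank batches are one
#'   per round-by-culture combination).
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration and seed.
#' @return A list of class `generator_config`.
#' @seealso [generate_cohort()], [planted_effect()]
#' @export
generator_config <- function(n_samples = NULL,
                             margins = NULL,
                             factor_levels = list(
                               cryo = c("Fresh", "Frozen"),
                               breed = c("AV", "H"),
                               culture = c("BSA", "FCS"),
                               bull = sprintf("bull%d", 1:7),
                               stage0h = c("M", "EB", "B"),
                               stage24h = c("ExB", "FEB"),
                               age = c(7L, 8L)
                             ),
                             endpoint_model = c(D40 = 0.607, D62 = 0.583,
                                                Birth = 0.464),
                             n_features = 120L,
                             planted_effects = list(),
                             noise = 1.0,
                             missing = list(lod_quantile = 0.05, mcar = 0.02),
                             bull_sd = 0.5,
                             bull_frac = 0.25,
                             injection_cv = 0.02,
                             constituent_frac = 0.4,
                             consumed_frac = 0.5,
                             n_rounds = 21L,
                             seed = 1L) {
  if (is.null(margins)) {
    margins <- data.frame(
      cryo = c("Fresh", "Frozen", "Frozen"),
      age = c(7L, 7L, 8L),
      n = c(28L, 48L, 8L)
    )
    if (!is.null(n_samples)) {
      n_samples <- as.integer(n_samples)
      raw <- margins$n / sum(margins$n) * n_samples
      margins$n <- floor(raw)
      rem <- n_samples - sum(margins$n)
      if (rem > 0) {
        ord <- order(raw - floor(raw), decreasing = TRUE)
        margins$n[ord[seq_len(rem)]] <- margins$n[ord[seq_len(rem)]] + 1L
      }
    }
  }
  cfg <- list(
    margins = margins, factor_levels = factor_levels,
    endpoint_model = endpoint_model, n_features = as.integer(n_features),
    planted_effects = planted_effects, noise = noise, missing = missing,
    bull_sd = bull_sd, bull_frac = bull_frac, injection_cv = injection_cv,
    constituent_frac = constituent_frac, consumed_frac = consumed_frac,
    n_rounds = as.integer(n_rounds), seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  fl <- cfg$factor_levels
  needed <- c("cryo", "breed", "culture", "bull", "stage0h", "stage24h", "age")
  for (f in needed) {
    if (is.null(fl[[f]]) || length(fl[[f]]) == 0) {
      stop("configuration error: empty factor level list for '", f, "'")
    }
  }
  ep <- cfg$endpoint_model
  if (!all(names(ep) == c("D40", "D62", "Birth"))) {
    stop("configuration error: endpoint_model must be named D40, D62, Birth")
  }
  if (any(ep < 0 | ep > 1)) {
    stop("configuration error: endpoint probability outside [0,1]")
  }
  if (is.unsorted(rev(ep))) {
    stop("configuration error: endpoint probabilities must be non-increasing ",
         "(D40 >= D62 >= Birth)")
  }
  if (any(unlist(cfg$missing) < 0) || any(unlist(cfg$missing) > 1)) {
    stop("configuration error: missingness rates must lie in [0,1]")
  }
  if (!all(cfg$margins$cryo %in% fl$cryo) ||
      !all(cfg$margins$age %in% fl$age)) {
    stop("configuration error: margins reference unknown factor levels")
  }
  for (pe in cfg$planted_effects) {
    for (f in names(pe$stratum)) {
      if (!f %in% needed) {
        stop("configuration error: planted stratum has unknown factor '",
             f, "'")
      }
      if (!all(pe$stratum[[f]] %in% fl[[f]])) {
        stop("configuration error: planted stratum references unknown level ",
             "of '", f, "'")
      }
    }
    if (!all(pe$endpoints %in% c("D40", "D62", "Birth"))) {
      stop("configuration error: planted effect references unknown endpoint")
    }
  }
  invisible(cfg)
}

#' Describe one planted biomarker effect
#'
#' A planted effect makes one simulated feature differential between
#' pregnant and open samples inside a stratum of fixed factors, either as a
#' log2 shift of the embryo contribution (`mode = "shift"`) or as a
#' qualitative effect (`mode = "qualitative"`) in which one outcome class
#' stays at blank level (net intensity about zero after blank subtraction)
#' so the downstream +/-99 fold-change sentinel fires.
#'
#' @param feature Index (1-based) of the affected feature.
#' @param stratum Named list of factor constraints, e.g.
#'   `list(cryo = "Frozen", breed = "AV")`; factors not named are free.
#' @param endpoints Character vector among `"D40"`, `"D62"`, `"Birth"`.
#'   When several endpoints are given the effect is driven by their union
#'   indicator; because the endpoints are nested per sample, contrasts at
#'   endpoints not listed are only partially differential.
#' @param mode `"shift"` or `"qualitative"`.
#' @param effect Log2 effect size of the pregnant/open contrast (shift mode).
#' @param direction Sign of the pregnant-minus-open contrast (+1 or -1).
#' @return A list of class `planted_effect`.
#' @export
planted_effect <- function(feature, stratum = list(),
                           endpoints = "D40",
                           mode = c("shift", "qualitative"),
                           effect = 3, direction = -1) {
  mode <- match.arg(mode)
  stopifnot(direction %in% c(-1, 1), effect > 0)
  structure(list(feature = as.integer(feature), stratum = stratum,
                 endpoints = endpoints, mode = mode, effect = effect,
                 direction = direction),
            class = "planted_effect")
}

samples_in_stratum <- function(samples, stratum) {
  sel <- rep(TRUE, nrow(samples))
  for (f in names(stratum)) {
    sel <- sel & samples[[f]] %in% stratum[[f]]
  }
  sel
}

#' Generate a complete synthetic study bundle
#'
#' Simulates the full set of inputs the analysis pipeline expects: a raw
#' feature-intensity table with technical duplicate injections, one blank
#' record per transfer-round-by-culture batch, per-embryo annotations with
#' nested pregnancy endpoints, a stage-abundance impact table, and a
#' planted-truth ledger listing where each planted biomarker is differential.
#'
#' Intensities are log-normal on the log2 scale. Medium-constituent features
#' carry a blank level; consumed constituents yield net-negative values after
#' blank subtraction. Bull effects are random intercepts on a feature subset.
#' Observed values below a global detection-limit quantile are censored, plus
#' a small MCAR rate.
#'
#' @param config A [generator_config()] object.
#' @return A list of class `synthetic_bundle` with elements `raw`
#'   (`intensity` features-by-injections matrix and `injections` map),
#'   `blanks` (`intensity` features-by-batches matrix and `batches` map),
#'   `samples`, `features`, `impact`, `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  fl <- config$factor_levels
  withr::local_seed(config$seed)

  ## --- sample annotations -------------------------------------------------
  n <- sum(config$margins$n)
  samples <- do.call(rbind, lapply(seq_len(nrow(config$margins)), function(i) {
    m <- config$margins[i, ]
    data.frame(cryo = rep(m$cryo, m$n), age = rep(m$age, m$n))
  }))
  samples$sample_id <- sprintf("S%03d", seq_len(n))
  samples$breed <- sample(fl$breed, n, replace = TRUE)
  samples$culture <- sample(fl$culture, n, replace = TRUE)
  samples$bull <- sample(fl$bull, n, replace = TRUE)
  samples$stage0h <- sample(fl$stage0h, n, replace = TRUE,
                            prob = c(0.3, 0.3, 0.4)[seq_along(fl$stage0h)])
  samples$stage24h <- sample(fl$stage24h, n, replace = TRUE)
  samples$round <- sample(seq_len(config$n_rounds), n, replace = TRUE)
  ep <- config$endpoint_model
  u <- stats::runif(n)
  samples$d40 <- u < ep["D40"]
  samples$d62 <- u < ep["D62"]
  samples$birth <- u < ep["Birth"]
  samples$excluded_from <- NA_character_
  samples <- samples[, c("sample_id", "cryo", "breed", "culture", "bull",
                         "stage0h", "stage24h", "age", "round",
                         "d40", "d62", "birth", "excluded_from")]

  ## --- features -----------------------------------------------------------
  p <- config$n_features
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(p)),
    rt_min = round(stats::runif(p, 0.5, 13), 3),
    mz = round(stats::runif(p, 100, 1500), 4)
  )
  constituent <- stats::runif(p) < config$constituent_frac
  consumed <- constituent & (stats::runif(p) < config$consumed_frac)
  ## planted biomarkers are drawn from quantifiable, released
  ## medium-constituent features: a qualitative effect needs blank-level
  ## signal in its suppressed class to stay detectable, and a shifted
  ## consumption would saturate at complete depletion of the constituent
  ## (which is the qualitative regime, not a fold change)
  for (pe in config$planted_effects) {
    constituent[pe$feature] <- TRUE
    consumed[pe$feature] <- FALSE
  }
  mu <- stats::runif(p, 14, 22)            # log2 blank level for constituents
  ## embryo contribution: a quarter of the blank level for medium
  ## constituents, and low-abundance for genuinely embryo-derived features,
  ## so spent-medium totals stay close to blank totals (as in real data)
  delta_mu <- mu - ifelse(constituent, 2, 5)
  sgn <- ifelse(consumed, -1, 1)
  bull_feat <- stats::runif(p) < config$bull_frac
  bull_int <- stats::rnorm(length(fl$bull), 0, config$bull_sd)
  names(bull_int) <- fl$bull

  ## --- blank batches ------------------------------------------------------
  batches <- unique(samples[, c("round", "culture")])
  batches <- batches[order(batches$round, batches$culture), , drop = FALSE]
  batches$blank_id <- sprintf("R%02d_%s", batches$round, batches$culture)
  rownames(batches) <- NULL
  blank_level <- matrix(0, p, nrow(batches),
                        dimnames = list(features$feature_id, batches$blank_id))
  for (b in seq_len(nrow(batches))) {
    lev <- ifelse(constituent, 2^(mu + stats::rnorm(p, 0, 0.1)), 0)
    blank_level[, b] <- lev
  }
  blank_obs <- blank_level *
    (1 + matrix(stats::rnorm(length(blank_level), 0, config$injection_cv),
                nrow = p))
  blank_obs[blank_obs < 0] <- 0

  ## --- planted truth ledger ----------------------------------------------
  truth <- data.frame(feature_id = character(), endpoint = character(),
                      cryo = character(), breed = character(),
                      culture = character(), stage0h = character(),
                      stage24h = character(), age = character(),
                      mode = character(), direction = numeric(),
                      effect = numeric())
  constraint_of <- function(stratum, f) {
    if (is.null(stratum[[f]])) "free" else paste(stratum[[f]], collapse = "+")
  }
  for (pe in config$planted_effects) {
    for (e in pe$endpoints) {
      truth <- rbind(truth, data.frame(
        feature_id = features$feature_id[pe$feature], endpoint = e,
        cryo = constraint_of(pe$stratum, "cryo"),
        breed = constraint_of(pe$stratum, "breed"),
        culture = constraint_of(pe$stratum, "culture"),
        stage0h = constraint_of(pe$stratum, "stage0h"),
        stage24h = constraint_of(pe$stratum, "stage24h"),
        age = constraint_of(pe$stratum, "age"),
        mode = pe$mode, direction = pe$direction, effect = pe$effect
      ))
    }
  }

  ## --- true (noise-free-injection) sample intensities ---------------------
  endpoint_col <- c(D40 = "d40", D62 = "d62", Birth = "birth")
  eta <- matrix(stats::rnorm(p * n, 0, config$noise), p, n) + delta_mu
  if (any(bull_feat)) {
    eta[bull_feat, ] <- eta[bull_feat, ] +
      matrix(bull_int[samples$bull], sum(bull_feat), n, byrow = TRUE)
  }
  delta <- sgn * 2^eta
  suppressed <- matrix(FALSE, p, n)
  for (pe in config$planted_effects) {
    in_str <- samples_in_stratum(samples, pe$stratum)
    preg <- Reduce(`|`, lapply(pe$endpoints,
                               function(e) samples[[endpoint_col[e]]]))
    j <- pe$feature
    if (pe$mode == "shift") {
      shifted <- in_str & preg
      delta[j, shifted] <- sgn[j] *
        2^(eta[j, shifted] + pe$direction * pe$effect)
    } else {
      ## qualitative: the suppressed class sits near blank level with a
      ## small opposite-sign net (release flips to slight consumption or
      ## vice versa), so the two group means take opposite signs and the
      ## +/-99 sentinel fires downstream
      low_class <- if (pe$direction < 0) preg else !preg
      supp <- in_str & low_class
      delta[j, supp] <- -sgn[j] * 2^(eta[j, supp] - 1)
      suppressed[j, supp] <- TRUE
    }
  }
  blank_of <- batches$blank_id[match(paste(samples$round, samples$culture),
                                     paste(batches$round, batches$culture))]
  truth_mat <- blank_level[, blank_of, drop = FALSE] + delta
  truth_mat[truth_mat < 0] <- 0
  colnames(truth_mat) <- samples$sample_id

  ## --- duplicate injections, detection limit, MCAR ------------------------
  injections <- data.frame(
    column_id = c(sprintf("%s_r1", samples$sample_id),
                  sprintf("%s_r2", samples$sample_id)),
    sample_id = rep(samples$sample_id, 2),
    replicate = rep(1:2, each = n)
  )
  injections <- injections[order(injections$sample_id,
                                 injections$replicate), ]
  rownames(injections) <- NULL
  raw <- truth_mat[, injections$sample_id, drop = FALSE] *
    (1 + matrix(stats::rnorm(p * nrow(injections), 0, config$injection_cv),
                nrow = p))
  raw[raw < 0] <- 0
  colnames(raw) <- injections$column_id
  pos_vals <- raw[raw > 0]
  lod <- stats::quantile(pos_vals, config$missing$lod_quantile, names = FALSE)
  raw[raw < lod] <- NA
  mcar <- matrix(stats::runif(length(raw)) < config$missing$mcar,
                 nrow = nrow(raw))
  raw[mcar] <- NA

  ## --- impact table (deterministic reference stage-abundance) -------------
  impact <- make_impact_table(fl, samples)

  bundle <- list(
    raw = list(intensity = raw, injections = injections),
    blanks = list(intensity = blank_obs, batches = batches),
    samples = samples, features = features, impact = impact,
    truth = truth, config = config
  )
  class(bundle) <- "synthetic_bundle"
  bundle
}

## Reference stage-abundance proportions per culture. Emulates an external
## metadatabase: fixed cell probabilities over stage0h x stage24h, normalised
## to sum to exactly 100 within each culture.
make_impact_table <- function(fl, samples) {
  cell_prob <- c(M_ExB = 0.20, M_FEB = 0.235, EB_ExB = 0.13, EB_FEB = 0.29,
                 B_ExB = 0.065, B_FEB = 0.08)
  grid <- expand.grid(stage0h = fl$stage0h, stage24h = fl$stage24h,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(fl$culture, function(cu) {
    g <- grid
    g$culture <- cu
    pr <- cell_prob[paste(g$stage0h, g$stage24h, sep = "_")]
    # mild culture dependence of stage progression
    if (cu == "FCS") pr <- pr * c(0.6, 0.7, 1.1, 1.2, 1.2, 1.3)
    pct <- 100 * pr / sum(pr)
    pct <- round(pct, 3)
    pct[which.max(pct)] <- pct[which.max(pct)] + (100 - sum(pct))
    g$percent <- pct
    g
  }))
  share <- 100 * as.vector(table(factor(samples$culture, fl$culture))) /
    nrow(samples)
  out$culture_share <- share[match(out$culture, fl$culture)]
  out[, c("culture", "stage0h", "stage24h", "percent", "culture_share")]
}

#' Match a planted-truth ledger against screen results
#'
#' A planted biomarker counts as recovered when some screen hit exists for
#' its feature and endpoint whose block resolves to exactly the pregnant
#' and open sample sets of the planted stratum (constraint tuples that
#' relabel the same sample sets still match).
#'
#' @param truth Planted-truth ledger from [generate_cohort()].
#' @param screen Result of [screen_blocks()].
#' @param samples Sample annotation data frame.
#' @return `truth` with a logical `recovered` column.
#' @export
match_planted_truth <- function(truth, screen, samples) {
  hits <- screen$hits
  blocks <- screen$blocks
  block_key <- vapply(seq_len(nrow(blocks)), function(i) {
    paste(blocks$endpoint[i],
          paste(sort(blocks$pos_ids[[i]]), collapse = ","),
          paste(sort(blocks$neg_ids[[i]]), collapse = ","), sep = "|")
  }, character(1))
  names(block_key) <- as.character(blocks$block_id)
  truth$recovered <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    sel <- rep(TRUE, nrow(samples))
    for (f in c("cryo", "breed", "culture", "stage0h", "stage24h", "age")) {
      if (tr[[f]] != "free") {
        lev <- strsplit(tr[[f]], "+", fixed = TRUE)[[1]]
        sel <- sel & as.character(samples[[f]]) %in% lev
      }
    }
    status <- endpoint_status(samples, tr$endpoint)
    key <- paste(tr$endpoint,
                 paste(sort(samples$sample_id[sel & !is.na(status) &
                                                status]), collapse = ","),
                 paste(sort(samples$sample_id[sel & !is.na(status) &
                                                !status]), collapse = ","),
                 sep = "|")
    cand <- hits[hits$feature_id == tr$feature_id &
                   hits$endpoint == tr$endpoint, , drop = FALSE]
    any(block_key[as.character(cand$block_id)] == key)
  }, logical(1))
  truth
}

#' Construct two outcome-class value vectors with a given discordance
#'
#' Deterministically builds `pregnant` and `open` vectors with exactly
#' `discordant` of the `n_pos * n_neg` cross-pairs discordant and no ties,
#' so the empirical rank ROC-AUC equals
#' `1 - discordant / (n_pos * n_neg)`. Useful for reconstructing blocks with
#' a prescribed AUC.
#'
#' @param n_pos,n_neg Class sizes.
#' @param discordant Number of discordant (open above pregnant) cross-pairs.
#' @return List with numeric vectors `pregnant` and `open`.
#' @export
block_values_with_discordance <- function(n_pos, n_neg, discordant = 0) {
  stopifnot(n_pos >= 1, n_neg >= 1, discordant >= 0,
            discordant <= n_pos * n_neg)
  neg <- as.numeric(seq_len(n_neg))
  pos <- as.numeric(n_neg + seq_len(n_pos))
  k <- discordant
  i <- 1
  while (k > 0) {
    if (k >= n_neg) {
      pos[i] <- -i          # below every open value: n_neg discordant pairs
      k <- k - n_neg
    } else {
      pos[i] <- n_neg - k + 0.5   # below exactly the top k open values
      k <- 0
    }
    i <- i + 1
  }
  list(pregnant = pos, open = neg)
}

#' Write a synthetic bundle to disk as plain-text fixtures
#'
#' Emits `features.tsv` (feature metadata plus one intensity column per
#' injection), `blanks.tsv`, `samples.tsv`, `impact.tsv`, `truth.tsv` and
#' `config.yaml` into `dir`. The files round-trip losslessly through
#' [read_fixtures()].
#'
#' @param bundle A `synthetic_bundle` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
write_fixtures <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("unwritable path: ", dir)
  }
  paths <- c(
    features = file.path(dir, "features.tsv"),
    blanks = file.path(dir, "blanks.tsv"),
    samples = file.path(dir, "samples.tsv"),
    impact = file.path(dir, "impact.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  feat <- cbind(bundle$features,
                as.data.frame(bundle$raw$intensity, optional = TRUE))
  write_tsv(feat, paths["features"])
  blk <- cbind(data.frame(feature_id = rownames(bundle$blanks$intensity)),
               as.data.frame(bundle$blanks$intensity, optional = TRUE))
  write_tsv(blk, paths["blanks"])
  write_tsv(bundle$samples, paths["samples"])
  write_tsv(bundle$impact, paths["impact"])
  write_tsv(bundle$truth, paths["truth"])
  cfg <- bundle$config
  cfg$planted_effects <- lapply(cfg$planted_effects, unclass)
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture files.
#' @return A list with the same structure as a `synthetic_bundle` except
#'   `config`, which is returned as a plain list.
#' @export
read_fixtures <- function(dir) {
  feat <- read_tsv(file.path(dir, "features.tsv"))
  meta_cols <- c("feature_id", "rt_min", "mz")
  features <- feat[, meta_cols]
  raw <- as.matrix(feat[, setdiff(names(feat), meta_cols), drop = FALSE])
  rownames(raw) <- features$feature_id
  injections <- data.frame(
    column_id = colnames(raw),
    sample_id = sub("_r[0-9]+$", "", colnames(raw)),
    replicate = as.integer(sub("^.*_r", "", colnames(raw)))
  )
  blk <- read_tsv(file.path(dir, "blanks.tsv"))
  blanks <- as.matrix(blk[, -1, drop = FALSE])
  rownames(blanks) <- blk$feature_id
  batches <- data.frame(
    blank_id = colnames(blanks),
    round = as.integer(sub("^R([0-9]+)_.*$", "\\1", colnames(blanks))),
    culture = sub("^R[0-9]+_", "", colnames(blanks))
  )
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  list(
    raw = list(intensity = raw, injections = injections),
    blanks = list(intensity = blanks, batches = batches),
    samples = samples, features = features,
    impact = read_tsv(file.path(dir, "impact.tsv")),
    truth = read_tsv(file.path(dir, "truth.tsv")),
    config = yaml::read_yaml(file.path(dir, "config.yaml"))
  )
}
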