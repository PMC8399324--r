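#' Log2 pregnant/open fold change with qualitative sentinel
#'
#' On blank-subtracted (net) intensities, group means can be negative
#' (consumption) or about zero (blank level). When both group means are
#' positive the value is `log2(mean_P / mean_O)`; when both are negative it
#' is `log2(|mean_P| / |mean_O|)`; when the means have opposite signs, or
#' exactly one is zero, the difference is qualitative and the sentinel
#' `+/-99` is returned with the sign of `mean_P - mean_O`. Both means
#' exactly zero is undefined and returns `NA`.
#'
#' @param pregnant_values,open_values Non-empty numeric vectors of net
#'   intensities.
#' @param sentinel Magnitude of the qualitative sentinel (99).
#' @return A single numeric log2 fold change.
#' @export
log_fold_change <- function(pregnant_values, open_values, sentinel = 99) {
  stopifnot(length(pregnant_values) > 0, length(open_values) > 0)
  mp <- mean(pregnant_values)
  mo <- mean(open_values)
  if (mp == 0 && mo == 0) return(NA_real_)
  if (mp > 0 && mo > 0) return(log2(mp / mo))
  if (mp < 0 && mo < 0) return(log2(abs(mp) / abs(mo)))
  sign(mp - mo) * sentinel
}

#' Empirical rank ROC-AUC
#'
#' Concordant-pair (Mann-Whitney) formulation with half credit for ties,
#' made direction-free by returning `max(A, 1 - A)`, so the value always
#' lies in [0.5, 1] whichever class has the higher intensities.
#'
#' @param pregnant_values,open_values Non-empty numeric vectors.
#' @return AUC in [0.5, 1].
#' @export
roc_auc <- function(pregnant_values, open_values) {
  n1 <- length(pregnant_values)
  n0 <- length(open_values)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(c(pregnant_values, open_values))
  a <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

## All level-1/level-2 statistics for one feature in one block, computed in
## closed form (equal-variance two-sample t == one-way ANOVA with 2 groups;
## Kruskal-Wallis chi-square approximation with tie correction; rank AUC).
## Verified against stats::t.test, stats::kruskal.test and pROC in the test
## suite.
screen_stats <- function(pos, neg) {
  n1 <- length(pos)
  n0 <- length(neg)
  N <- n1 + n0
  m1 <- mean(pos)
  m0 <- mean(neg)
  ss <- sum((pos - m1)^2) + sum((neg - m0)^2)
  df <- N - 2
  sp2 <- ss / df
  if (sp2 <= 0) {
    p_t <- if (m1 == m0) 1 else 0
  } else {
    tstat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    p_t <- 2 * stats::pt(-abs(tstat), df)
  }
  r <- rank(c(pos, neg))
  R1 <- sum(r[seq_len(n1)])
  a <- (R1 - n1 * (n1 + 1) / 2) / (n1 * n0)
  auc <- max(a, 1 - a)
  H <- 12 / (N * (N + 1)) * (R1^2 / n1 + (sum(r) - R1)^2 / n0) - 3 * (N + 1)
  ties <- tabulate(match(r, unique(r)))
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  p_kw <- if (C <= 0) 1 else stats::pchisq(H / C, df = 1, lower.tail = FALSE)
  lfc <- log_fold_change(pos, neg)
  c(mean_pos = m1, mean_neg = m0, lfc = lfc, p_t = p_t, p_kw = p_kw,
    auc = auc)
}

#' Level-1 volcano screen for one feature in one block
#'
#' Pass iff the fold-change gate holds (|log2 FCh| >= log2(`fc_gate`), or
#' the qualitative sentinel) and the smaller of the parametric (two-sample
#' t, equivalent to one-way ANOVA with two groups) and non-parametric
#' (Kruskal-Wallis) p-values is below the tendency level. The record is
#' classed `"significant"` below `alpha_significant` and `"tendency"` in
#' [`alpha_significant`, `alpha_tendency`).
#'
#' @param pregnant_values,open_values Net intensities of the two outcome
#'   classes.
#' @param fc_gate Fold-change gate on the natural scale (default 2).
#' @param alpha_significant,alpha_tendency Significance and tendency levels
#'   (defaults 0.05 and 0.10).
#' @return A list: `pass`, `class` (`"significant"`, `"tendency"` or `NA`),
#'   `lfc`, `sentinel`, `p_t`, `p_kw`, `p_min`, `auc`.
#' @export
volcano_level1 <- function(pregnant_values, open_values, fc_gate = 2,
                           alpha_significant = 0.05, alpha_tendency = 0.10) {
  s <- screen_stats(pregnant_values, open_values)
  sentinel <- !is.na(s[["lfc"]]) && abs(s[["lfc"]]) == 99
  fc_ok <- sentinel ||
    (!is.na(s[["lfc"]]) && abs(s[["lfc"]]) >= log2(fc_gate))
  p_min <- min(s[["p_t"]], s[["p_kw"]])
  pass <- fc_ok && p_min < alpha_tendency
  cls <- if (!pass) NA_character_
         else if (p_min < alpha_significant) "significant" else "tendency"
  list(pass = pass, class = cls, lfc = unname(s[["lfc"]]),
       sentinel = sentinel, p_t = unname(s[["p_t"]]),
       p_kw = unname(s[["p_kw"]]), p_min = p_min, auc = unname(s[["auc"]]))
}

#' Level-2 ROC gate
#'
#' A level-1 passer becomes a hit iff its direction-free AUC exceeds
#' `auc_gate` and its t-test p-value is below 0.10. Small blocks (total
#' samples below `small_n`) with AUC of at least `small_n_auc` are admitted
#' with `small_n_exception = TRUE` even when the t-test p-value lies in
#' [0.10, `small_n_alpha`).
#'
#' @param auc Direction-free AUC.
#' @param p_t t-test p-value.
#' @param n_total Total samples in the block.
#' @param auc_gate,small_n,small_n_auc,small_n_alpha Gates; see
#'   [run_config()].
#' @return List with `hit` and `small_n_exception` logicals.
#' @export
roc_level2 <- function(auc, p_t, n_total, auc_gate = 0.700, small_n = 12,
                       small_n_auc = 0.850, small_n_alpha = 0.15) {
  if (auc > auc_gate && p_t < 0.10) {
    return(list(hit = TRUE, small_n_exception = FALSE))
  }
  if (n_total < small_n && auc >= small_n_auc && p_t < small_n_alpha) {
    return(list(hit = TRUE, small_n_exception = TRUE))
  }
  list(hit = FALSE, small_n_exception = FALSE)
}

stage_set <- function(code, levels) {
  if (code == "free") levels else strsplit(code, "+", fixed = TRUE)[[1]]
}

endpoint_column <- c(D40 = "d40", D62 = "d62", Birth = "birth")

endpoint_status <- function(samples, endpoint) {
  status <- samples[[endpoint_column[[endpoint]]]]
  excl_col <- as.character(samples$excluded_from)
  excl <- !is.na(excl_col) &
    vapply(strsplit(excl_col, ","),
           function(x) endpoint %in% x, logical(1))
  status[excl] <- NA
  status
}

#' Enumerate fixed-factor blocks
#'
#' Builds the Cartesian product of endpoint and per-factor constraints
#' (every level plus "free"; embryonic-stage constraints over the allowed
#' subset whitelist), resolves each to its pregnant and open sample lists,
#' keeps blocks with at least `min_class` samples in both classes, and
#' collapses constraint tuples that resolve to identical sample sets to the
#' coarsest tuple (most free factors, then largest stage sets).
#'
#' @param samples Annotated sample data frame.
#' @param min_class Minimum samples per outcome class (default 3).
#' @param endpoints Endpoints to screen.
#' @param stage0h_sets,stage24h_sets Stage-constraint whitelists (strings,
#'   `+`-joined unions or `"free"`).
#' @return Data frame of blocks (`block_id`, `endpoint`, constraint columns,
#'   `n_pos`, `n_neg`) with list columns `pos_ids`, `neg_ids`.
#' @export
enumerate_blocks <- function(samples, min_class = 3,
                             endpoints = c("D40", "D62", "Birth"),
                             stage0h_sets = c("M", "EB", "B", "EB+B", "free"),
                             stage24h_sets = c("ExB", "FEB", "free")) {
  if (is.null(samples$excluded_from)) samples$excluded_from <- NA_character_
  lv <- list(
    cryo = c(unique(samples$cryo), "free"),
    breed = c(unique(samples$breed), "free"),
    culture = c(unique(samples$culture), "free"),
    stage0h = stage0h_sets,
    stage24h = stage24h_sets,
    age = c(as.character(sort(unique(samples$age))), "free")
  )
  grid <- expand.grid(c(list(endpoint = endpoints), lv),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)

  lv0 <- unique(samples$stage0h)
  lv24 <- unique(samples$stage24h)
  match_block <- function(b) {
    sel <- rep(TRUE, nrow(samples))
    if (b$cryo != "free") sel <- sel & samples$cryo == b$cryo
    if (b$breed != "free") sel <- sel & samples$breed == b$breed
    if (b$culture != "free") sel <- sel & samples$culture == b$culture
    if (b$stage0h != "free") {
      sel <- sel & samples$stage0h %in% stage_set(b$stage0h, lv0)
    }
    if (b$stage24h != "free") {
      sel <- sel & samples$stage24h %in% stage_set(b$stage24h, lv24)
    }
    if (b$age != "free") sel <- sel & samples$age == as.integer(b$age)
    sel
  }

  status_by_endpoint <- lapply(stats::setNames(endpoints, endpoints),
                               function(e) endpoint_status(samples, e))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    b <- grid[i, ]
    sel <- match_block(b)
    status <- status_by_endpoint[[b$endpoint]]
    pos <- samples$sample_id[sel & !is.na(status) & status]
    neg <- samples$sample_id[sel & !is.na(status) & !status]
    if (length(pos) >= min_class && length(neg) >= min_class) {
      b$n_pos <- length(pos)
      b$n_neg <- length(neg)
      b$pos_ids <- list(pos)
      b$neg_ids <- list(neg)
      rows[[i]] <- b
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- grid[0, ]
    out$n_pos <- integer(0)
    out$n_neg <- integer(0)
    out$pos_ids <- list()
    out$neg_ids <- list()
    out$block_id <- integer(0)
    return(out)
  }
  blocks <- do.call(rbind, rows)

  # deduplicate by resolved sample sets, keeping the coarsest constraint
  key <- vapply(seq_len(nrow(blocks)), function(i) {
    paste(blocks$endpoint[i],
          paste(sort(blocks$pos_ids[[i]]), collapse = ","),
          paste(sort(blocks$neg_ids[[i]]), collapse = ","), sep = "|")
  }, character(1))
  coarseness <- rowSums(blocks[, c("cryo", "breed", "culture", "stage0h",
                                   "stage24h", "age")] == "free") * 10 +
    vapply(blocks$stage0h, function(s) length(stage_set(s, lv0)),
           numeric(1)) +
    vapply(blocks$stage24h, function(s) length(stage_set(s, lv24)),
           numeric(1))
  ord <- order(key, -coarseness)
  blocks <- blocks[ord[!duplicated(key[ord])], , drop = FALSE]
  rownames(blocks) <- NULL
  blocks$block_id <- seq_len(nrow(blocks))
  blocks
}

#' Two-level screen of every block-by-feature combination
#'
#' Runs [volcano_level1()] and [roc_level2()] for each feature inside each
#' enumerated block. Blocks are screened independently, so the hit set does
#' not depend on evaluation order. No multiple-testing correction is
#' applied inside the screen; the total number of tests and level-1 passers
#' are attached as attributes for transparency.
#'
#' @param net Blank-subtracted features-by-samples matrix.
#' @param samples Annotated sample data frame.
#' @param blocks Optional precomputed [enumerate_blocks()] result.
#' @param config A [run_config()].
#' @return List with `hits` (one row per screen hit: feature, block
#'   constraints, `auc`, `p1` t-test p, `lfc`, `p2` Kruskal-Wallis p,
#'   `level1_class`, `small_n_exception`, class sizes, `block_id`) and
#'   `blocks`. `attr(hits, "n_tests")` and `attr(hits, "n_level1")` give the
#'   screen size.
#' @export
screen_blocks <- function(net, samples, blocks = NULL,
                          config = run_config()) {
  if (is.null(blocks)) {
    blocks <- enumerate_blocks(samples, min_class = config$min_class,
                               stage0h_sets = config$stage0h_sets,
                               stage24h_sets = config$stage24h_sets)
  }
  lthr <- log2(config$fc_gate)
  hit_rows <- vector("list", nrow(blocks))
  n_level1 <- 0L
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    xp <- net[, b$pos_ids[[1]], drop = FALSE]
    xn <- net[, b$neg_ids[[1]], drop = FALSE]
    n_total <- b$n_pos + b$n_neg
    stats_mat <- vapply(seq_len(nrow(net)), function(j) {
      screen_stats(xp[j, ], xn[j, ])
    }, numeric(6))
    lfc <- stats_mat["lfc", ]
    p_min <- pmin(stats_mat["p_t", ], stats_mat["p_kw", ])
    sentinel <- !is.na(lfc) & abs(lfc) == 99
    pass1 <- (sentinel | (!is.na(lfc) & abs(lfc) >= lthr)) &
      p_min < config$alpha_tendency
    n_level1 <- n_level1 + sum(pass1)
    if (!any(pass1)) next
    idx <- which(pass1)
    auc <- stats_mat["auc", idx]
    p_t <- stats_mat["p_t", idx]
    hit <- auc > config$auc_gate & p_t < 0.10
    exc <- !hit & n_total < config$small_n & auc >= config$small_n_auc &
      p_t < config$small_n_alpha
    keep <- hit | exc
    if (!any(keep)) next
    idx <- idx[keep]
    hit_rows[[i]] <- data.frame(
      feature_id = rownames(net)[idx],
      auc = stats_mat["auc", idx],
      p1 = stats_mat["p_t", idx],
      lfc = stats_mat["lfc", idx],
      p2 = stats_mat["p_kw", idx],
      endpoint = b$endpoint, cryo = b$cryo, breed = b$breed,
      culture = b$culture, stage0h = b$stage0h, stage24h = b$stage24h,
      age = b$age, n_pos = b$n_pos, n_neg = b$n_neg,
      level1_class = ifelse(p_min[idx] < config$alpha_significant,
                            "significant", "tendency"),
      small_n_exception = exc[keep],
      block_id = b$block_id
    )
  }
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits)) {
    hits <- data.frame(
      feature_id = character(0), auc = numeric(0), p1 = numeric(0),
      lfc = numeric(0), p2 = numeric(0), endpoint = character(0),
      cryo = character(0), breed = character(0), culture = character(0),
      stage0h = character(0), stage24h = character(0), age = character(0),
      n_pos = integer(0), n_neg = integer(0), level1_class = character(0),
      small_n_exception = logical(0), block_id = integer(0)
    )
  }
  rownames(hits) <- NULL
  attr(hits, "n_tests") <- nrow(blocks) * nrow(net)
  attr(hits, "n_level1") <- n_level1
  list(hits = hits, blocks = blocks)
}

#' Match screened features against a spectral reference library
#'
#' An identification is validated only when the precursor mass agrees
#' within `precursor_ppm` and at least `min_ms2` library MS2 ions are each
#' matched by an observed fragment within `ms2_ppm`.
#'
#' @param features Data frame with `feature_id`, `mz` and optionally `ms2`
#'   (observed fragment m/z values, `;`-separated string).
#' @param library Data frame with `compound`, `exact_mass` (expected
#'   precursor m/z) and `ms2_mz` (`;`-separated reference fragment m/z).
#' @param precursor_ppm,ms2_ppm Mass tolerances in parts per million.
#' @param min_ms2 Minimum matched MS2 ions for validation.
#' @return Data frame: `feature_id`, `compound`, `precursor_ppm_error`,
#'   `n_ms2_matched`, `validated`. One row per feature; unannotated
#'   features carry `NA` compound and `validated = FALSE`.
#' @export
annotate_features <- function(features, library, precursor_ppm = 10,
                              ms2_ppm = 5, min_ms2 = 3) {
  parse_mz <- function(s) {
    if (is.null(s) || is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  empty <- data.frame(feature_id = features$feature_id,
                      compound = NA_character_,
                      precursor_ppm_error = NA_real_,
                      n_ms2_matched = 0L, validated = FALSE)
  if (is.null(library) || nrow(library) == 0) return(empty)
  lib_ions <- lapply(library$ms2_mz, parse_mz)
  out <- empty
  for (i in seq_len(nrow(features))) {
    mz <- features$mz[i]
    ppm <- abs(mz - library$exact_mass) / library$exact_mass * 1e6
    cand <- which(ppm < precursor_ppm)
    if (!length(cand)) next
    obs_ions <- if ("ms2" %in% names(features)) {
      parse_mz(features$ms2[i])
    } else numeric(0)
    n_matched <- vapply(cand, function(k) {
      ref <- lib_ions[[k]]
      if (!length(ref) || !length(obs_ions)) return(0L)
      sum(vapply(ref, function(m) {
        any(abs(obs_ions - m) / m * 1e6 < ms2_ppm)
      }, logical(1)))
    }, integer(1))
    best <- cand[order(-n_matched, ppm[cand])][1]
    out$compound[i] <- library$compound[best]
    out$precursor_ppm_error[i] <- ppm[best]
    out$n_ms2_matched[i] <- n_matched[order(-n_matched, ppm[cand])][1]
    out$validated[i] <- ppm[best] < precursor_ppm &&
      out$n_ms2_matched[i] >= min_ms2
  }
  out
}
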