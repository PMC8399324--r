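#' Whole-dataset endpoint model for one metabolite
#'
#' Ordinary least squares of net intensity on the fixed factors
#' (cryopreservation, culture, breed, stage at 0 h and 24 h, embryo age)
#' plus the endpoint term. The reported p-value is the F test of the
#' endpoint term. The `"Miscarriage"` endpoint contrasts three groups:
#' pregnant to term, post-Day-40 loss, and open at Day-40.
#'
#' @param feature_values Numeric vector of net intensities, one per sample.
#' @param samples Annotated sample data frame.
#' @param endpoint One of `"D40"`, `"D62"`, `"Birth"`, `"Miscarriage"`.
#' @return List: `p` (endpoint-term p-value), `degenerate` (constant
#'   response), `aliased` (rank-deficient design, aliased levels dropped
#'   with a warning).
#' @export
fit_endpoint_model <- function(feature_values, samples, endpoint) {
  stopifnot(length(feature_values) == nrow(samples))
  if (stats::var(feature_values) == 0) {
    return(list(p = 1, degenerate = TRUE, aliased = FALSE))
  }
  if (endpoint == "Miscarriage") {
    outcome <- ifelse(samples$birth, "term",
                      ifelse(samples$d40, "loss", "open"))
  } else {
    outcome <- endpoint_status(samples, endpoint)
  }
  dat <- data.frame(
    y = feature_values,
    cryo = factor(samples$cryo), culture = factor(samples$culture),
    breed = factor(samples$breed), stage0h = factor(samples$stage0h),
    stage24h = factor(samples$stage24h), age = factor(samples$age),
    outcome = factor(outcome)
  )
  dat <- dat[!is.na(dat$outcome), , drop = FALSE]
  if (nlevels(droplevels(dat$outcome)) < 2) {
    return(list(p = NA_real_, degenerate = FALSE, aliased = FALSE))
  }
  # drop constant covariates so the design stays full rank on small cohorts
  keep <- vapply(dat[-1], function(v) nlevels(droplevels(v)) > 1, logical(1))
  form <- stats::reformulate(names(dat)[-1][keep], response = "y")
  fit <- stats::lm(form, data = dat)
  aliased <- anyNA(stats::coef(fit))
  if (aliased) {
    warning("rank-deficient design; aliased levels dropped")
  }
  an <- stats::drop1(fit, scope = ~outcome, test = "F")
  list(p = an[["Pr(>F)"]][2], degenerate = FALSE, aliased = aliased)
}

#' Endpoint models with Bonferroni flags for a candidate metabolite set
#'
#' Fits [fit_endpoint_model()] for every candidate metabolite and endpoint
#' and flags Bonferroni passes at family levels 0.05 and 0.10, where the
#' family size is the number of candidate metabolites tested (the
#' block-identified candidates, not all features).
#'
#' @param net Features-by-samples net intensity matrix.
#' @param samples Annotated sample data frame.
#' @param metabolites Feature ids to test (rows of `net`).
#' @param endpoints Endpoints to test.
#' @return Data frame: `metabolite`, `endpoint`, `p`, `bonferroni_05`,
#'   `bonferroni_10`.
#' @export
endpoint_models <- function(net, samples, metabolites = rownames(net),
                            endpoints = c("D40", "D62", "Birth",
                                          "Miscarriage")) {
  m <- length(metabolites)
  rows <- list()
  for (met in metabolites) {
    for (e in endpoints) {
      res <- fit_endpoint_model(net[met, ], samples, e)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = met, endpoint = e, p = res$p,
        bonferroni_05 = !is.na(res$p) & res$p <= 0.05 / m,
        bonferroni_10 = !is.na(res$p) & res$p <= 0.10 / m
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "family_size") <- m
  out
}

#' Tally predictive blocks by taxonomy class, endpoint and cryo status
#'
#' Cross-tabulates screen hits per metabolite: counts of blocks by
#' endpoint and cryopreservation status of the block (its cryo constraint:
#' frozen, fresh, or `"FF"` for cryo-independent blocks), with class and
#' endpoint totals, plus a metabolite-by-endpoint heatmap matrix of total
#' block counts.
#'
#' @param hits Screen hits from [screen_blocks()].
#' @param taxonomy Data frame mapping `metabolite` (feature id) to `class`;
#'   unmapped metabolites are tallied as class `"unknown"`.
#' @return List: `table` (per-metabolite counts per endpoint-by-cryo cell
#'   and totals), `heatmap` (metabolite-by-endpoint matrix, rows ranked by
#'   total blocks), `class_totals`, `total`.
#' @export
tally_by_class <- function(hits, taxonomy) {
  endpoints <- c("D40", "D62", "Birth")
  cryo_status <- function(cryo) {
    ifelse(cryo == "Frozen", "Fz", ifelse(cryo == "Fresh", "Fh", "FF"))
  }
  mets <- sort(unique(hits$feature_id))
  cls <- taxonomy$class[match(mets, taxonomy$metabolite)]
  cls[is.na(cls)] <- "unknown"
  cols <- as.vector(outer(c("Fz", "Fh", "FF"), endpoints,
                          function(s, e) paste(e, s, sep = "_")))
  tab <- matrix(0L, length(mets), length(cols),
                dimnames = list(mets, cols))
  if (nrow(hits)) {
    cell <- paste(hits$endpoint, cryo_status(hits$cryo), sep = "_")
    cnt <- table(factor(hits$feature_id, mets), factor(cell, cols))
    tab[] <- as.integer(cnt)
  }
  df <- data.frame(metabolite = mets, class = cls, tab,
                   check.names = FALSE)
  for (s in c("Fz", "Fh", "FF")) {
    df[[paste0("Total_", s)]] <-
      rowSums(tab[, paste(endpoints, s, sep = "_"), drop = FALSE])
  }
  df$Total <- rowSums(tab)
  heat <- matrix(0, length(mets), length(endpoints),
                 dimnames = list(mets, endpoints))
  for (e in endpoints) {
    heat[, e] <- rowSums(tab[, paste(e, c("Fz", "Fh", "FF"), sep = "_"),
                             drop = FALSE])
  }
  heat <- heat[order(-df$Total, mets), , drop = FALSE]
  class_totals <- if (nrow(df)) {
    ct <- stats::aggregate(df$Total, list(class = df$class), sum)
    names(ct)[2] <- "blocks"
    ct
  } else {
    data.frame(class = character(0), blocks = numeric(0))
  }
  list(table = df, heatmap = heat, class_totals = class_totals,
       total = sum(tab))
}

#' AUC and p-value summaries by sample-number category
#'
#' Bins screen hits by total block sample number and reports per-bin mean
#' and standard error of the AUC and of the t-test p-value on a x10 scale,
#' plus Pearson correlations of AUC and p with the sample number across
#' hits. Empty bins are reported with `NA` summaries.
#'
#' @param hits Screen hits.
#' @param bin_edges Right-closed bin edges over total sample number; the
#'   default gives seven categories.
#' @return List: `bins` data frame and `cor` (named Pearson r for
#'   `auc_vs_n` and `p_vs_n`).
#' @export
auc_vs_n_summary <- function(hits,
                             bin_edges = c(0, 9, 12, 15, 18, 21, 27, Inf)) {
  n <- hits$n_pos + hits$n_neg
  if (length(unique(n)) < 2) {
    stop("need at least two distinct sample counts")
  }
  bin <- cut(n, bin_edges)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  bins <- data.frame(
    bin = levels(bin),
    n_hits = as.integer(table(bin)),
    auc_mean = as.numeric(tapply(hits$auc, bin, mean)),
    auc_sem = as.numeric(tapply(hits$auc, bin, sem)),
    p10_mean = as.numeric(tapply(hits$p1 * 10, bin, mean)),
    p10_sem = as.numeric(tapply(hits$p1 * 10, bin, sem))
  )
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  list(bins = bins,
       cor = c(auc_vs_n = safe_cor(hits$auc, n),
               p_vs_n = safe_cor(hits$p1, n)))
}

#' Descriptive pregnancy-rate table
#'
#' Counts and percentages of pregnancies at Day-40, Day-62 and birth per
#' cryopreservation-by-culture-by-embryo-age group. Samples excluded from
#' an endpoint (e.g. a recipient deceased before term) are removed from
#' that endpoint's denominator; cells whose denominator differs from the
#' group size are printed as `k/denominator (pct)`, otherwise `k (pct)`.
#'
#' @param samples Annotated sample data frame (optionally with an
#'   `excluded_from` column of comma-separated endpoint names).
#' @return Data frame with group columns, `n`, one formatted cell per
#'   endpoint, and numeric companion columns (`*_k`, `*_denom`, `*_pct`).
#' @export
pregnancy_rate_table <- function(samples) {
  if (is.null(samples$excluded_from)) samples$excluded_from <- NA_character_
  groups <- unique(samples[, c("cryo", "culture", "age")])
  groups <- groups[order(groups$cryo, groups$culture, groups$age), ,
                   drop = FALSE]
  endpoints <- c(D40 = "d40", D62 = "d62", Birth = "birth")
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- samples$cryo == g$cryo & samples$culture == g$culture &
      samples$age == g$age
    row <- data.frame(cryo = g$cryo, culture = g$culture, age = g$age,
                      n = sum(sel))
    for (e in names(endpoints)) {
      status <- endpoint_status(samples[sel, , drop = FALSE], e)
      denom <- sum(!is.na(status))
      k <- sum(status, na.rm = TRUE)
      pct <- if (denom > 0) 100 * k / denom else NA_real_
      row[[e]] <- if (denom == row$n) {
        sprintf("%d (%.1f)", k, pct)
      } else {
        sprintf("%d/%d (%.1f)", k, denom, pct)
      }
      row[[paste0(e, "_k")]] <- k
      row[[paste0(e, "_denom")]] <- denom
      row[[paste0(e, "_pct")]] <- round(pct, 1)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
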