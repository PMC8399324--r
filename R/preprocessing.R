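#' Average technical duplicate injections
#'
#' Collapses a features-by-injections matrix to one column per sample. Each
#' cell becomes the arithmetic mean of its non-missing replicates and stays
#' missing only when every replicate is missing.
#'
#' @param mat Features-by-injections intensity matrix (NA = missing).
#' @param sample_ids Character vector, one sample id per column of `mat`.
#' @return Features-by-samples matrix, columns ordered by first appearance.
#' @export
average_replicates <- function(mat, sample_ids) {
  stopifnot(ncol(mat) == length(sample_ids))
  ids <- unique(sample_ids)
  out <- vapply(ids, function(s) {
    rowMeans(mat[, sample_ids == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat)))
  out[is.nan(out)] <- NA
  dimnames(out) <- list(rownames(mat), ids)
  out
}

#' Consistency filter
#'
#' Retains a feature iff, in at least one level of the grouping factor, the
#' fraction of non-missing values reaches `threshold`.
#'
#' @param mat Features-by-samples matrix.
#' @param groups Grouping vector (one value per sample), typically the
#'   pregnancy outcome classes.
#' @param threshold Required fraction of non-missing values in some group;
#'   in (0, 1].
#' @return List with `mat` (retained features) and `flags`, a data frame
#'   (`feature_id`, `retained`, `reason`).
#' @export
consistency_filter <- function(mat, groups, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1, ncol(mat) == length(groups))
  if (any(is.na(groups))) stop("consistency groups contain missing values")
  lv <- unique(groups)
  if (length(lv) == 0) stop("empty group")
  frac <- vapply(lv, function(g) {
    rowMeans(!is.na(mat[, groups == g, drop = FALSE]))
  }, numeric(nrow(mat)))
  frac <- matrix(frac, nrow = nrow(mat))
  keep <- apply(frac, 1, max) >= threshold
  flags <- data.frame(
    feature_id = rownames(mat),
    retained = keep,
    reason = ifelse(keep, "", "consistency")
  )
  list(mat = mat[keep, , drop = FALSE], flags = flags)
}

#' Random-forest imputation of missing intensities
#'
#' Features still missing in more than `max_missing_fraction` of samples are
#' dropped. Remaining missing cells are imputed with an iterative
#' random-forest scheme: cells start at the feature mean, then each
#' incomplete feature is regressed on all other features and its missing
#' cells replaced by forest predictions, sweeping features in order of
#' increasing missingness until the total change in imputed values stops
#' decreasing. Imputed values are clipped to the observed range of their
#' feature. Deterministic given `seed`.
#'
#' @param mat Features-by-samples matrix (already consistency-filtered).
#' @param max_missing_fraction Per-feature missingness cap; default 0.25.
#' @param seed Integer seed.
#' @param ntree Trees per forest.
#' @param max_iter Maximum sweeps.
#' @return List with `mat` (complete matrix) and `flags` data frame for
#'   dropped features (`reason = "missingness"`).
#' @export
impute_missing <- function(mat, max_missing_fraction = 0.25, seed = 1L,
                           ntree = 100L, max_iter = 10L) {
  miss_frac <- rowMeans(is.na(mat))
  if (any(miss_frac == 1)) {
    stop("all-missing feature reached imputation: ",
         paste(rownames(mat)[miss_frac == 1], collapse = ", "))
  }
  keep <- miss_frac <= max_missing_fraction
  flags <- data.frame(
    feature_id = rownames(mat),
    retained = keep,
    reason = ifelse(keep, "", "missingness")
  )
  m <- mat[keep, , drop = FALSE]
  if (!anyNA(m)) return(list(mat = m, flags = flags))

  withr::local_seed(seed)
  x <- t(m)                              # samples x features for regression
  na_mask <- is.na(x)
  col_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[na_mask[, j], j] <- col_means[j]
  incomplete <- which(colSums(na_mask) > 0)
  incomplete <- incomplete[order(colSums(na_mask)[incomplete])]
  prev_change <- Inf
  best <- x
  for (iter in seq_len(max_iter)) {
    x_old <- x
    for (j in incomplete) {
      obs <- !na_mask[, j]
      fit <- randomForest::randomForest(
        x = x[obs, -j, drop = FALSE], y = x[obs, j], ntree = ntree
      )
      x[!obs, j] <- stats::predict(fit, x[!obs, -j, drop = FALSE])
    }
    change <- sum((x[na_mask] - x_old[na_mask])^2) /
      max(sum(x[na_mask]^2), .Machine$double.eps)
    if (change > prev_change) { x <- x_old; break }
    best <- x
    prev_change <- change
    if (change < 1e-6) break
  }
  x <- best
  # clip imputed cells to each feature's observed range
  for (j in incomplete) {
    obs_rng <- range(t(m)[!na_mask[, j], j])
    x[na_mask[, j], j] <- pmin(pmax(x[na_mask[, j], j], obs_rng[1]),
                               obs_rng[2])
  }
  out <- t(x)
  dimnames(out) <- dimnames(m)
  list(mat = out, flags = flags)
}

#' Total-intensity normalization
#'
#' Scales every sample by (grand mean of sample totals) / (its own total),
#' so all post-scaling sample totals equal the grand mean of the
#' pre-scaling totals.
#'
#' @param mat Complete features-by-samples matrix.
#' @param target Optional fixed total to scale to; defaults to the grand
#'   mean of the sample totals of `mat` (supply the samples' target when
#'   normalizing blanks alongside samples).
#' @return List with `mat`, `scale_factors` (named per sample) and `target`.
#' @export
normalize_total_intensity <- function(mat, target = NULL) {
  if (anyNA(mat)) stop("normalization requires a complete matrix")
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    stop("non-positive sample total: ",
         paste(colnames(mat)[totals <= 0], collapse = ", "))
  }
  if (is.null(target)) target <- mean(totals)
  sf <- target / totals
  list(mat = sweep(mat, 2, sf, `*`), scale_factors = sf, target = target)
}

#' Blank subtraction
#'
#' Subtracts from every sample the blank record of its culture batch,
#' feature by feature. Negative net values are preserved: they represent
#' consumption of medium constituents by the embryo.
#'
#' @param mat Features-by-samples matrix.
#' @param blank_mat Features-by-blanks matrix (same feature order).
#' @param pairing Named character vector mapping sample id to blank id.
#' @return Net features-by-samples matrix.
#' @export
subtract_blank <- function(mat, blank_mat, pairing) {
  unmatched <- setdiff(colnames(mat), names(pairing))
  if (length(unmatched)) {
    stop("samples without a matched blank: ",
         paste(unmatched, collapse = ", "))
  }
  bid <- pairing[colnames(mat)]
  missing_blank <- setdiff(unique(bid), colnames(blank_mat))
  if (length(missing_blank)) {
    stop("blank record absent: ", paste(missing_blank, collapse = ", "))
  }
  stopifnot(identical(rownames(mat), rownames(blank_mat)))
  mat - blank_mat[, bid, drop = FALSE]
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: average duplicate injections, consistency filter,
#' random-forest imputation, total-intensity normalization (samples and
#' blanks to the same grand-mean target), blank subtraction. Reruns with the
#' same inputs and seed are bit-reproducible.
#'
#' @param raw List with `intensity` (features-by-injections matrix) and
#'   `injections` (data frame with `column_id`, `sample_id`).
#' @param blanks List with `intensity` (features-by-blanks matrix) and
#'   `batches` (data frame with `blank_id`, `round`, `culture`).
#' @param samples Sample annotation data frame (needs `sample_id`, `round`,
#'   `culture` for blank pairing and the consistency grouping column).
#' @param config A [run_config()].
#' @return List with `net` (blank-subtracted features-by-samples matrix),
#'   `flags` (per-feature drop reasons), `scale_factors`,
#'   `blank_scale_factors` and `log` (ordered stage names).
#' @export
preprocess_features <- function(raw, blanks, samples, config = run_config()) {
  avg <- average_replicates(raw$intensity, raw$injections$sample_id)
  avg <- avg[, samples$sample_id, drop = FALSE]

  groups <- samples[[config$consistency_group]]
  cons <- consistency_filter(avg, groups,
                             threshold = config$consistency_threshold)
  imp <- impute_missing(cons$mat,
                        max_missing_fraction = config$max_missing_fraction,
                        seed = config$seed, ntree = config$impute_ntree)
  flags <- cons$flags
  flags$reason[match(imp$flags$feature_id[!imp$flags$retained],
                     flags$feature_id)] <- "missingness"
  flags$retained <- flags$feature_id %in% rownames(imp$mat)

  norm <- normalize_total_intensity(imp$mat)
  blank_mat <- blanks$intensity[rownames(imp$mat), , drop = FALSE]
  blank_mat[is.na(blank_mat)] <- 0   # blank below detection = nothing to subtract
  bnorm <- normalize_total_intensity(blank_mat, target = norm$target)

  pairing <- stats::setNames(
    sprintf("R%02d_%s", samples$round, samples$culture), samples$sample_id
  )
  net <- subtract_blank(norm$mat, bnorm$mat, pairing)
  list(net = net, flags = flags, scale_factors = norm$scale_factors,
       blank_scale_factors = bnorm$scale_factors,
       log = c("average_replicates", "consistency_filter", "impute_missing",
               "normalize_total_intensity", "subtract_blank"))
}
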