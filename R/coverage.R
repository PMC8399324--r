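## stage cells covered by a (stage0h, stage24h) constraint pair
stratum_cells <- function(stage0h, stage24h,
                          lv0 = c("M", "EB", "B"),
                          lv24 = c("ExB", "FEB")) {
  s0 <- stage_set(stage0h, lv0)
  s24 <- stage_set(stage24h, lv24)
  as.vector(outer(s0, s24, paste, sep = "|"))
}

#' Look up the population impact of a block
#'
#' The impact of a block is the percentage of the embryo population falling
#' in its culture-by-stage stratum, summed over the impact-table cells the
#' block's stage constraints cover. Within one culture the cell percentages
#' sum to 100, so a block free of stage constraints has impact 100.
#' Culture-free blocks combine the per-culture sums weighted by each
#' culture's population share.
#'
#' @param block List or one-row data frame with `culture`, `stage0h`,
#'   `stage24h` constraint strings (`"free"` or `+`-joined level unions).
#' @param impact Impact table: `culture`, `stage0h`, `stage24h`, `percent`
#'   (within culture), `culture_share` (percent of population per culture).
#' @return Impact percentage in [0, 100].
#' @export
impact_lookup <- function(block, impact) {
  lv0 <- unique(impact$stage0h)
  lv24 <- unique(impact$stage24h)
  s0 <- stage_set(block$stage0h, lv0)
  s24 <- stage_set(block$stage24h, lv24)
  cultures <- if (block$culture == "free") unique(impact$culture)
              else block$culture
  total <- 0
  for (cu in cultures) {
    sub <- impact[impact$culture == cu, , drop = FALSE]
    if (!nrow(sub)) {
      stop("impact table does not cover culture stratum '", cu, "'")
    }
    have <- paste(sub$stage0h, sub$stage24h, sep = "|")
    want <- as.vector(outer(s0, s24, paste, sep = "|"))
    missing <- setdiff(want, have)
    if (length(missing)) {
      stop("impact table lacks stratum ", cu, ":",
           paste(missing, collapse = ","))
    }
    val <- sum(sub$percent[have %in% want])
    if (block$culture == "free") {
      total <- total + sub$culture_share[1] / 100 * val
    } else {
      total <- val
    }
  }
  total
}

#' Impact-weighted predicted coverage
#'
#' The fraction of the embryo population for which a single biomarker
#' predicts the outcome correctly: ROC-AUC times the block's population
#' impact, on the percent scale.
#'
#' @param auc Direction-free AUC in [0.5, 1].
#' @param impact Population impact percentage in [0, 100].
#' @return Predicted coverage percentage.
#' @export
predicted_coverage <- function(auc, impact) {
  stopifnot(all(auc >= 0.5 - 1e-12), all(auc <= 1 + 1e-12),
            all(impact >= 0), all(impact <= 100 + 1e-9))
  auc * impact
}

add_coverage <- function(hits, impact) {
  if (!nrow(hits)) {
    hits$impact <- numeric(0)
    hits$predicted <- numeric(0)
    return(hits)
  }
  hits$impact <- vapply(seq_len(nrow(hits)), function(i) {
    impact_lookup(hits[i, ], impact)
  }, numeric(1))
  hits$predicted <- predicted_coverage(hits$auc, hits$impact)
  hits
}

#' Select single-biomarker blocks by predicted coverage
#'
#' Computes impact and predicted coverage for every screen hit and keeps
#' those whose predicted coverage reaches `min_predicted` percent, sorted by
#' decreasing predicted coverage (ties: larger block, then feature id).
#'
#' @param hits Screen hits from [screen_blocks()].
#' @param impact Impact table (see [impact_lookup()]).
#' @param min_predicted Coverage gate in percent (default 70).
#' @return The filtered, sorted hits with `impact` and `predicted` columns.
#' @export
select_single_biomarkers <- function(hits, impact, min_predicted = 70) {
  cov <- add_coverage(hits, impact)
  cov <- cov[cov$predicted >= min_predicted, , drop = FALSE]
  ord <- order(-cov$predicted, -(cov$n_pos + cov$n_neg), cov$feature_id)
  cov <- cov[ord, , drop = FALSE]
  rownames(cov) <- NULL
  cov
}

## enumerate all non-empty sets of pairwise-disjoint strata (indices)
disjoint_subsets <- function(cells_list) {
  n <- length(cells_list)
  compat <- matrix(TRUE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      compat[i, j] <- length(intersect(cells_list[[i]],
                                       cells_list[[j]])) == 0
    }
  }
  out <- list()
  recurse <- function(chosen, candidates) {
    for (k in candidates) {
      new_chosen <- c(chosen, k)
      out[[length(out) + 1]] <<- new_chosen
      nxt <- candidates[candidates > k & compat[k, candidates]]
      if (length(chosen)) {
        nxt <- nxt[vapply(nxt, function(m) all(compat[m, chosen]),
                          logical(1))]
      }
      if (length(nxt)) recurse(new_chosen, nxt)
    }
  }
  recurse(integer(0), seq_len(n))
  out
}

#' Build candidate biomarker series
#'
#' A series shares one endpoint and one value (possibly free) of
#' cryopreservation, breed, culture and embryo age, and is supported by one
#' or more stage-disjoint member blocks. For every such signature present in
#' the hits, all sets of pairwise stage-disjoint member strata are
#' enumerated exhaustively, together with the candidate metabolites (hits)
#' available in each member.
#'
#' @param hits Screen hits from [screen_blocks()].
#' @param impact Impact table.
#' @return List of candidate series; each has `signature` (one-row data
#'   frame), `members` (data frame of member strata with their impact) and
#'   `candidates` (list of hit data frames, one per member, with
#'   `predicted`).
#' @export
build_series <- function(hits, impact) {
  if (!nrow(hits)) return(list())
  cov <- add_coverage(hits, impact)
  lv0 <- unique(impact$stage0h)
  lv24 <- unique(impact$stage24h)
  sig_cols <- c("endpoint", "cryo", "breed", "culture", "age")
  sigs <- unique(cov[, sig_cols, drop = FALSE])
  sigs <- sigs[order(sigs$endpoint, sigs$cryo, sigs$breed, sigs$culture,
                     sigs$age), , drop = FALSE]
  out <- list()
  for (s in seq_len(nrow(sigs))) {
    sig <- sigs[s, , drop = FALSE]
    h <- cov[Reduce(`&`, lapply(sig_cols,
                                function(cc) cov[[cc]] == sig[[cc]])), ,
             drop = FALSE]
    strata <- unique(h[, c("stage0h", "stage24h"), drop = FALSE])
    rownames(strata) <- NULL
    cells <- lapply(seq_len(nrow(strata)), function(i) {
      stratum_cells(strata$stage0h[i], strata$stage24h[i], lv0, lv24)
    })
    for (subset in disjoint_subsets(cells)) {
      members <- strata[subset, , drop = FALSE]
      members$impact <- vapply(subset, function(i) {
        impact_lookup(list(culture = sig$culture,
                           stage0h = strata$stage0h[i],
                           stage24h = strata$stage24h[i]), impact)
      }, numeric(1))
      candidates <- lapply(subset, function(i) {
        h[h$stage0h == strata$stage0h[i] &
            h$stage24h == strata$stage24h[i], , drop = FALSE]
      })
      out[[length(out) + 1]] <- list(signature = sig, members = members,
                                     candidates = candidates)
    }
  }
  out
}

#' Combined coverage of a series
#'
#' Sum over the member blocks of AUC times impact. Member stage strata must
#' be pairwise disjoint; overlap is an error.
#'
#' @param members Data frame with one chosen metabolite per member block:
#'   columns `stage0h`, `stage24h`, `auc`, `impact`.
#' @param lv0,lv24 Full stage level sets used to resolve `"free"`.
#' @return Combined coverage percentage.
#' @export
combined_coverage <- function(members, lv0 = c("M", "EB", "B"),
                              lv24 = c("ExB", "FEB")) {
  cells <- lapply(seq_len(nrow(members)), function(i) {
    stratum_cells(members$stage0h[i], members$stage24h[i], lv0, lv24)
  })
  all_cells <- unlist(cells)
  if (anyDuplicated(all_cells)) {
    stop("series members overlap in stage stratum ",
         all_cells[duplicated(all_cells)][1])
  }
  sum(predicted_coverage(members$auc, members$impact))
}

#' Best metabolite combination per series
#'
#' For every series signature, picks the member-metabolite assignment and
#' disjoint member set that maximises the combined coverage (within each
#' member block the metabolite with the highest predicted coverage is
#' optimal, so the search reduces to the exhaustive disjoint-subset
#' enumeration of [build_series()]). Ties are broken by fewer members, then
#' lexicographic metabolite ids. Only series whose combined coverage
#' exceeds `min_combined` percent are reported.
#'
#' @param hits Screen hits.
#' @param impact Impact table.
#' @param min_combined Reporting gate in percent (default 80).
#' @return Data frame with one row per member of each winning combination:
#'   `series` id, hit columns, `impact`, `predicted` and the series
#'   `combined` coverage.
#' @export
best_combination_per_series <- function(hits, impact, min_combined = 80) {
  empty <- data.frame(series = integer(0), feature_id = character(0),
                      endpoint = character(0), cryo = character(0),
                      breed = character(0), culture = character(0),
                      stage0h = character(0), stage24h = character(0),
                      age = character(0), n_pos = integer(0),
                      n_neg = integer(0), auc = numeric(0),
                      impact = numeric(0), predicted = numeric(0),
                      combined = numeric(0))
  candidates <- build_series(hits, impact)
  if (!length(candidates)) return(empty)

  pick_best <- function(h) {
    h[order(-h$predicted, h$feature_id)[1], , drop = FALSE]
  }
  sig_key <- vapply(candidates, function(ser) {
    paste(unlist(ser$signature), collapse = "|")
  }, character(1))
  rows <- list()
  series_id <- 0L
  for (key in unique(sig_key)) {
    group <- candidates[sig_key == key]
    best <- NULL
    for (ser in group) {
      chosen <- do.call(rbind, lapply(ser$candidates, pick_best))
      comb <- sum(chosen$predicted)
      ids <- paste(sort(chosen$feature_id), collapse = ",")
      cand <- list(chosen = chosen, combined = comb,
                   n_members = nrow(chosen), ids = ids)
      if (is.null(best) ||
          cand$combined > best$combined + 1e-9 ||
          (abs(cand$combined - best$combined) <= 1e-9 &&
             (cand$n_members < best$n_members ||
                (cand$n_members == best$n_members && cand$ids < best$ids)))) {
        best <- cand
      }
    }
    if (best$combined > min_combined) {
      series_id <- series_id + 1L
      chosen <- best$chosen
      chosen$combined <- best$combined
      chosen$series <- series_id
      rows[[length(rows) + 1]] <- chosen
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  keep <- c("series", "feature_id", "endpoint", "cryo", "breed", "culture",
            "stage0h", "stage24h", "age", "n_pos", "n_neg", "auc",
            "impact", "predicted", "combined")
  out <- out[, intersect(keep, names(out)), drop = FALSE]
  rownames(out) <- NULL
  out
}
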