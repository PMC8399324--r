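# Shared fixture builders; everything is generated in code.

# minimal annotated cohort with explicit factor assignments
tiny_samples <- function(n, cryo = "Frozen", breed = "AV", culture = "BSA",
                         stage0h = "B", stage24h = "FEB", age = 7L,
                         d40 = rep(c(TRUE, FALSE), length.out = n)) {
  data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    cryo = rep_len(cryo, n), breed = rep_len(breed, n),
    culture = rep_len(culture, n), bull = "bull1",
    stage0h = rep_len(stage0h, n), stage24h = rep_len(stage24h, n),
    age = rep_len(age, n), round = 1L,
    d40 = d40, d62 = d40, birth = d40,
    excluded_from = NA_character_
  )
}

# a small impact table with known cell values (percent within culture)
toy_impact <- function() {
  grid <- expand.grid(stage0h = c("M", "EB", "B"),
                      stage24h = c("ExB", "FEB"),
                      stringsAsFactors = FALSE)
  bsa <- grid
  bsa$culture <- "BSA"
  bsa$percent <- c(10, 15, 5, 18.51, 23.49, 28)   # sums to 100
  fcs <- grid
  fcs$culture <- "FCS"
  fcs$percent <- c(20, 10, 10, 25, 15, 20)        # sums to 100
  out <- rbind(bsa, fcs)
  out$culture_share <- ifelse(out$culture == "BSA", 60, 40)
  out[, c("culture", "stage0h", "stage24h", "percent", "culture_share")]
}

# brute-force AUC: explicit double loop over all cross-pairs
brute_auc <- function(pos, neg) {
  conc <- 0
  for (x in pos) {
    for (y in neg) {
      conc <- conc + (x > y) + 0.5 * (x == y)
    }
  }
  a <- conc / (length(pos) * length(neg))
  max(a, 1 - a)
}

# strata of a default cohort with at least min_n samples per outcome class
strata_with_classes <- function(samples, min_n, endpoint_col = "d40") {
  cand <- list(list(cryo = "Frozen"), list(cryo = "Fresh"),
               list(culture = "BSA"), list(culture = "FCS"),
               list(breed = "AV"), list(breed = "H"),
               list(cryo = "Frozen", culture = "BSA"),
               list(cryo = "Frozen", breed = "AV"))
  Filter(function(st) {
    sel <- rep(TRUE, nrow(samples))
    for (f in names(st)) sel <- sel & samples[[f]] == st[[f]]
    sum(sel & samples[[endpoint_col]]) >= min_n &&
      sum(sel & !samples[[endpoint_col]]) >= min_n
  }, cand)
}
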