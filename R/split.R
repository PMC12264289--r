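#' Stratified train/validation/test split
#'
#' Partitions subjects into train/validation/test sets at the given ratios,
#' stratified by group label so each split preserves the cohort's group
#' proportions to within one subject. Validation and test sizes are
#' `round(ratio * n)` and the training set takes the remainder, so the
#' 3818-subject cohort at 60/20/20 yields exactly 2290/764/764. Per-stratum
#' counts are allocated by largest remainder. Deterministic given `seed`.
#'
#' @param labels stratification label per subject (the hemodynamic group).
#' @param ratios length-3 numeric, positive except possibly the last two,
#'   summing to 1.
#' @param seed integer seed.
#' @return list of class `split_assignment` with integer index vectors
#'   `train`, `validation`, `test` (disjoint, exhaustive) and `labels`.
#' @export
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9 ||
      ratios[1] <= 0)
    stop("split error: ratios must be non-negative, positive train share, sum 1")
  labels <- factor(labels)
  n <- length(labels)
  if (all(ratios[2:3] == 0)) {
    warning("degenerate ratios: all subjects assigned to train")
    return(structure(list(train = seq_len(n), validation = integer(0),
                          test = integer(0), labels = labels),
                     class = "split_assignment"))
  }
  if (min(table(labels)) < 3) stop("split error: a stratum has fewer than 3 subjects")
  n_test <- round(ratios[3] * n)
  n_val <- round(ratios[2] * n)
  strata <- levels(labels)
  take_stratified <- function(avail_by_stratum, total) {
    # largest-remainder allocation of `total` across strata, capped by
    # availability
    sizes <- vapply(avail_by_stratum, length, integer(1))
    q <- total * sizes / sum(sizes)
    cnt <- floor(q)
    rem <- total - sum(cnt)
    if (rem > 0) {
      ord <- order(q - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    pmin(cnt, sizes)
  }
  with_seed(seed, {
    avail <- lapply(strata, function(s) sample(which(labels == s)))
    names(avail) <- strata
    cnt_test <- take_stratified(avail, n_test)
    test <- integer(0)
    for (s in strata) {
      test <- c(test, avail[[s]][seq_len(cnt_test[[s]])])
      avail[[s]] <- avail[[s]][-seq_len(cnt_test[[s]])]
    }
    cnt_val <- take_stratified(avail, n_val)
    val <- integer(0)
    for (s in strata) {
      if (cnt_val[[s]] > 0) {
        val <- c(val, avail[[s]][seq_len(cnt_val[[s]])])
        avail[[s]] <- avail[[s]][-seq_len(cnt_val[[s]])]
      }
    }
    train <- unlist(avail, use.names = FALSE)
    structure(list(train = sort(train), validation = sort(val),
                   test = sort(test), labels = labels),
              class = "split_assignment")
  })
}

#' Stratified k-fold assignment
#'
#' Assigns each subject to exactly one validation fold, keeping group
#' proportions balanced across folds.
#'
#' @param labels stratification label per subject.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- factor(labels)
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    for (s in levels(labels)) {
      idx <- sample(which(labels == s))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
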