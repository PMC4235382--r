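# SVM discrimination of origin windows from immediately-upstream windows:
# instance construction, per-feature-family vectors, and stratified k-fold
# cross-validation reporting sensitivity, specificity and accuracy.

FEATURE_FAMILIES <- c("gc_profile", "gc_skew", "d2", "nucleosome")

#' Build labelled positive/negative window instances
#'
#' The positive window is the 300 bp centred on each ORI midpoint; the
#' negative window is the 300 bp immediately upstream (abutting, lower
#' coordinates; origins are unstranded). Feature vectors per family:
#' `gc_profile` and `gc_skew` are the per-window values in 50-bp sliding
#' windows at 1-bp step (251 dimensions over a 300-bp instance); `d2` is the
#' adjacent-lag redundancy in 150-bp windows at 1-bp step (151 dimensions);
#' `nucleosome` is the per-base occupancy (300 dimensions). Instances whose
#' windows exceed chromosome bounds, and negative windows overlapping another
#' ORI's positive window, are dropped with a warning.
#'
#' @param genome Named character vector of sequences.
#' @param oris Interval data.frame of origins.
#' @param family Feature family: `"gc_profile"`, `"gc_skew"`, `"d2"` or
#'   `"nucleosome"`.
#' @param track Per-base occupancy track (required for `"nucleosome"`).
#' @param instance_window Instance width in bp (default 300).
#' @param feat_window Sliding-window width for gc families (default 50).
#' @param d2_window Sliding-window width for the d2 family (default 150).
#' @return List of class `ori_instances`: `features` (matrix, instances x
#'   dims), `labels` (factor positive/negative), `intervals`, `family`.
#' @export
build_instance_sets <- function(genome, oris,
                                family = c("gc_profile", "gc_skew", "d2",
                                           "nucleosome"),
                                track = NULL, instance_window = 300L,
                                feat_window = 50L, d2_window = 150L) {
  family <- match.arg(family)
  if (family == "nucleosome" && is.null(track)) {
    stop("track required for family 'nucleosome'")
  }
  half <- instance_window %/% 2L
  mids <- interval_midpoint(oris)
  pos <- data.frame(chrom = oris$chrom, start = mids - half,
                    end = mids - half + instance_window,
                    stringsAsFactors = FALSE)
  neg <- data.frame(chrom = pos$chrom, start = pos$start - instance_window,
                    end = pos$start, stringsAsFactors = FALSE)
  lens <- vapply(pos$chrom, function(ch) chrom_length(genome, ch), numeric(1L))
  usable <- neg$start >= 0L & pos$end <= lens
  # negatives sliding into another ORI's positive window are label noise
  clash <- vapply(seq_len(nrow(neg)), function(i) {
    any(pos$chrom == neg$chrom[i] & pos$start < neg$end[i] &
          neg$start[i] < pos$end & seq_len(nrow(pos)) != i)
  }, logical(1L))
  dropped <- sum(!usable | clash)
  if (dropped > 0L) {
    warning(dropped, " ORI(s) dropped (window out of bounds or negative",
            " window overlapping another positive window)")
  }
  keep <- usable & !clash
  if (sum(keep) < 20L) stop("fewer than 20 usable ORIs; cross-validation infeasible")
  pos <- pos[keep, , drop = FALSE]
  neg <- neg[keep, , drop = FALSE]
  featurize <- function(w) {
    switch(family,
      gc_profile = sliding_stat(subseq0(genome, w$chrom, w$start, w$end),
                                feat_window, 1L, "gc_profile"),
      gc_skew = sliding_stat(subseq0(genome, w$chrom, w$start, w$end),
                             feat_window, 1L, "gc_skew"),
      d2 = sliding_redundancy(subseq0(genome, w$chrom, w$start, w$end),
                              d2_window, 1L, k = 0L),
      nucleosome = get_chrom_track(track, w$chrom)[(w$start + 1L):w$end])
  }
  all_w <- rbind(pos, neg)
  feats <- t(vapply(seq_len(nrow(all_w)),
                    function(i) featurize(all_w[i, , drop = FALSE]),
                    numeric(switch(family,
                      gc_profile = , gc_skew =
                        floor((instance_window - feat_window)) + 1L,
                      d2 = floor((instance_window - d2_window)) + 1L,
                      nucleosome = instance_window))))
  labels <- factor(rep(c("positive", "negative"), each = nrow(pos)),
                   levels = c("positive", "negative"))
  structure(list(features = feats, labels = labels,
                 intervals = intervals(all_w$chrom, all_w$start, all_w$end),
                 family = family),
            class = "ori_instances")
}

# Standardisation fitted on the training fold only; returned parameters are a
# function of the training matrix alone (anti-leakage).
fit_standardizer <- function(train) {
  mu <- colMeans(train, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  centred <- sweep(train, 2L, mu)
  sdev <- apply(centred, 2L, stats::sd, na.rm = TRUE)
  list(mu = mu, sd = sdev, keep = !is.na(sdev) & sdev > 0)
}

apply_standardizer <- function(std, x) {
  x <- sweep(x, 2L, std$mu)
  # impute missing values with the training-fold mean (0 after centring)
  x[is.na(x)] <- 0
  x <- sweep(x, 2L, ifelse(std$keep, std$sd, 1), "/")
  x[, std$keep, drop = FALSE]
}

# Stratified fold assignment: within each class, a seeded shuffle followed by
# round-robin labelling keeps the class ratio per fold within one instance.
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated SVM discrimination of origin windows
#'
#' Radial-basis SVM (cost 1; kernel width 1 / (dims x mean feature variance)
#' of the standardised training fold). Folds are stratified with a fixed
#' seed; features are standardised per fold on the training instances only,
#' missing values imputed with the training-fold mean, and zero-variance
#' training features dropped for that fold. Confusion totals are accumulated
#' over held-out folds.
#'
#' @param instances An `ori_instances` object from [build_instance_sets()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param cost SVM regularisation constant (default 1).
#' @return List of class `ori_cv_report`: family, folds, seed, TP, FP, TN,
#'   FN, Sn, Sp, Acc.
#' @export
cross_validate_svm <- function(instances, folds = 10L, seed = 1L, cost = 1) {
  stopifnot(inherits(instances, "ori_instances"))
  labels <- instances$labels
  x <- instances$features
  if (min(table(labels)) < 2L) stop("need >= 2 instances per class")
  if (folds > min(table(labels))) stop("folds exceed the smaller class size")
  fold <- stratified_folds(labels, folds, seed)
  tp <- fp <- tn <- fn <- 0L
  dropped_any <- FALSE
  for (f in seq_len(folds)) {
    tr <- fold != f
    std <- fit_standardizer(x[tr, , drop = FALSE])
    if (!all(std$keep)) dropped_any <- TRUE
    if (!any(std$keep)) stop("all features degenerate in a training fold")
    xtr <- apply_standardizer(std, x[tr, , drop = FALSE])
    xte <- apply_standardizer(std, x[!tr, , drop = FALSE])
    gamma <- 1 / (ncol(xtr) * mean(apply(xtr, 2L, stats::var)))
    fit <- e1071::svm(x = xtr, y = labels[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, xte)
    truth <- labels[!tr]
    tp <- tp + sum(pred == "positive" & truth == "positive")
    fp <- fp + sum(pred == "positive" & truth == "negative")
    tn <- tn + sum(pred == "negative" & truth == "negative")
    fn <- fn + sum(pred == "negative" & truth == "positive")
  }
  if (dropped_any) {
    warning("zero-variance training feature(s) dropped in at least one fold")
  }
  structure(list(family = instances$family, folds = folds, seed = seed,
                 TP = tp, FP = fp, TN = tn, FN = fn,
                 Sn = tp / (tp + fn), Sp = tn / (tn + fp),
                 Acc = (tp + tn) / (tp + tn + fp + fn)),
            class = "ori_cv_report")
}

#' Tabulate cross-validation reports
#'
#' One row per feature family with sensitivity, specificity and accuracy at
#' four decimals.
#'
#' @param reports List of `ori_cv_report` objects.
#' @return Data frame: family, Sn, Sp, Acc.
#' @export
report_table <- function(reports) {
  stopifnot(length(reports) >= 1L)
  do.call(rbind, lapply(reports, function(r) {
    stopifnot(inherits(r, "ori_cv_report"))
    data.frame(family = r$family,
               Sn = round(r$Sn, 4L), Sp = round(r$Sp, 4L),
               Acc = round(r$Acc, 4L), stringsAsFactors = FALSE)
  }))
}

#' @export
print.ori_cv_report <- function(x, ...) {
  cat(sprintf(
    "SVM %d-fold CV [%s]: Sn %.4f  Sp %.4f  Acc %.4f  (TP %d FP %d TN %d FN %d)\n",
    x$folds, x$family, x$Sn, x$Sp, x$Acc, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
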