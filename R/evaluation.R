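#' ROC curve and AUC
#'
#' Builds the full ROC curve and its trapezoidal area for a score vector
#' and binary labels. By package convention a lower score (more negative
#' z) indicates disease, so `direction = "lower"` (the default) treats
#' small scores as positive calls; the returned AUC equals the
#' Mann-Whitney pairwise probability that a random positive scores more
#' "positive" than a random negative, with ties counted one half.
#'
#' @param scores numeric vector.
#' @param labels logical (or coercible) vector, `TRUE` = positive class.
#' @param direction `"lower"` if low scores indicate the positive class,
#'   `"higher"` otherwise.
#' @return list with `roc` (data frame `fpr`, `tpr`, `threshold`, the
#'   threshold on the original score scale) and `auc`.
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  s <- if (direction == "lower") -scores else scores
  o <- order(s, decreasing = TRUE)
  s_sorted <- s[o]
  l_sorted <- labels[o]
  tps <- cumsum(l_sorted)
  fps <- cumsum(!l_sorted)
  # collapse tied scores: one operating point per distinct threshold
  keep <- c(s_sorted[-1L] != s_sorted[-length(s_sorted)], TRUE)
  tpr <- c(0, tps[keep] / n_pos)
  fpr <- c(0, fps[keep] / n_neg)
  thr <- c(Inf, s_sorted[keep])
  if (direction == "lower") thr <- -thr
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

#' Cutoff achieving a target specificity on a reference population
#'
#' With the parametric (normal) option, the cutoff is the lower normal
#' quantile of the reference scores at probability `1 - target`; for a
#' standard-normal reference and target 0.95 this is z = -1.6449, the
#' classification rule "call positive when z < -1.65". The empirical
#' option returns the midpoint between the k-th and (k+1)-th smallest
#' reference scores with `k = floor(n * (1 - target))`, so at most a
#' `1 - target` fraction of reference subjects falls below the cutoff.
#'
#' @param reference_scores scores of known-negative (reference) subjects.
#' @param target_specificity target in (0, 1), default 0.95.
#' @param method `"parametric"` (default) or `"empirical"`.
#' @return the cutoff; positives are scores strictly below it.
#' @export
cutoff_for_specificity <- function(reference_scores,
                                   target_specificity = 0.95,
                                   method = c("parametric", "empirical")) {
  method <- match.arg(method)
  if (!is.finite(target_specificity) || target_specificity <= 0 ||
      target_specificity >= 1) {
    stop("target specificity must lie strictly between 0 and 1",
         call. = FALSE)
  }
  x <- reference_scores[is.finite(reference_scores)]
  n <- length(x)
  if (n < 20L) {
    warning("fewer than 20 reference scores; cutoff estimate is unstable",
            call. = FALSE)
  }
  if (method == "parametric") {
    mean(x) + stats::sd(x) * stats::qnorm(1 - target_specificity)
  } else {
    k <- floor(n * (1 - target_specificity))
    xs <- sort(x)
    if (k == 0L) xs[1L] else (xs[k] + xs[k + 1L]) / 2
  }
}

#' Cutoff maximizing the average of sensitivity and specificity
#'
#' Scans the midpoints between adjacent distinct scores (plus one
#' candidate below the minimum and one above the maximum) under the rule
#' "positive when score < cutoff" and returns the cutoff maximizing
#' `(sensitivity + specificity) / 2`. Ties are resolved toward the more
#' specific (smaller) cutoff. Used for subtype comparisons where the
#' high-specificity constraint is relaxed.
#'
#' @param scores numeric score vector.
#' @param labels logical vector, `TRUE` = positive class.
#' @return list with `cutoff`, `sensitivity`, `specificity`,
#'   `youden_mean` (the achieved average).
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  xs <- sort(unique(scores))
  candidates <- c(xs[1L] - 1,
                  if (length(xs) > 1L) (xs[-length(xs)] + xs[-1L]) / 2,
                  xs[length(xs)] + 1)
  best <- NULL
  for (cand in candidates) {
    sens <- mean(scores[labels] < cand)
    spec <- mean(scores[!labels] >= cand)
    avg <- (sens + spec) / 2
    if (is.null(best) || avg > best$youden_mean + 1e-12 ||
        (abs(avg - best$youden_mean) <= 1e-12 &&
           spec > best$specificity)) {
      best <- list(cutoff = cand, sensitivity = sens,
                   specificity = spec, youden_mean = avg)
    }
  }
  best
}

#' Diagnostic likelihood ratios from an operating point
#'
#' `LR+ = sensitivity / (1 - specificity)` and
#' `LR- = (1 - sensitivity) / specificity`. At specificity 1 the positive
#' ratio is undefined (returned as `NA`), and at specificity 0 the
#' negative ratio is undefined.
#'
#' @param sensitivity,specificity values in `[0, 1]`.
#' @return list with `lr_pos` and `lr_neg` (`NA` when undefined).
#' @examples
#' likelihood_ratios(0.59, 0.95) # LR+ = 11.8, LR- ~ 0.43
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  if (!is.finite(sensitivity) || sensitivity < 0 || sensitivity > 1 ||
      !is.finite(specificity) || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  lr_pos <- if (specificity == 1) NA_real_ else {
    sensitivity / (1 - specificity)
  }
  lr_neg <- if (specificity == 0) NA_real_ else {
    (1 - sensitivity) / specificity
  }
  list(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Evaluate index z-scores against a diagnostic comparison
#'
#' Computes the ROC curve, AUC, and the operating point (sensitivity,
#' specificity, LR+, LR-) at a fixed z cutoff for a set of scored
#' subjects.
#'
#' @param z numeric vector of index z-scores.
#' @param labels logical vector, `TRUE` = positive (disease) class.
#' @param cutoff classification cutoff, positive when `z < cutoff`.
#' @param comparison optional label describing the contrast (for printing).
#' @return object of class `ftd_eval`: `auc`, `roc`, `operating_point`,
#'   `n_pos`, `n_neg`, `comparison`.
#' @export
evaluate_scores <- function(z, labels, cutoff = -1.65, comparison = "") {
  labels <- as.logical(labels)
  rc <- roc_auc(z, labels, direction = "lower")
  sens <- mean(z[labels] < cutoff)
  spec <- mean(z[!labels] >= cutoff)
  lrs <- likelihood_ratios(sens, spec)
  structure(list(
    comparison = comparison,
    n_pos = sum(labels), n_neg = sum(!labels),
    roc = rc$roc, auc = rc$auc,
    operating_point = list(cutoff = cutoff, sensitivity = sens,
                           specificity = spec, lr_pos = lrs$lr_pos,
                           lr_neg = lrs$lr_neg)
  ), class = "ftd_eval")
}

#' @export
print.ftd_eval <- function(x, ...) {
  cat("Diagnostic evaluation",
      if (nzchar(x$comparison)) paste0("(", x$comparison, ")"), "\n")
  cat("  n =", x$n_pos, "positive /", x$n_neg, "negative\n")
  cat(sprintf("  AUC = %.3f\n", x$auc))
  op <- x$operating_point
  cat(sprintf("  at cutoff z < %.3f: sens = %.3f, spec = %.3f\n",
              op$cutoff, op$sensitivity, op$specificity))
  cat(sprintf("  LR+ = %s, LR- = %s\n",
              if (is.na(op$lr_pos)) "undefined" else
                sprintf("%.2f", op$lr_pos),
              if (is.na(op$lr_neg)) "undefined" else
                sprintf("%.2f", op$lr_neg)))
  invisible(x)
}

#' Stratified k-fold cross-validated index evaluation
#'
#' Splits the cohort into k folds stratified by diagnosis label. For every
#' fold the entire learning chain — normalization, region weights, and the
#' z-score calibration (mu, sigma) — is refitted on the training folds
#' only and applied to the held-out subjects, so no test subject ever
#' influences any fitted parameter. Held-out z-scores are pooled across
#' folds and evaluated against the requested comparison.
#'
#' @param cohort an [ftd_cohort()].
#' @param index_type `"API"`, `"ASI"` or `"TPL"`.
#' @param k number of folds (default 10).
#' @param seed integer seed making the fold assignment reproducible.
#' @param positive_group,negative_group label sets defining the evaluated
#'   comparison (defaults: FTD vs. all non-FTD groups).
#' @param cutoff classification z cutoff (default -1.65, fixed from
#'   calibration rather than re-tuned per fold).
#' @param ... further arguments passed to [fit_index()].
#' @return object of class `ftd_cv`: pooled `scores` (with fold ids),
#'   the pooled `report` ([evaluate_scores()]), `fold_auc`, `k`, `seed`.
#' @export
crossvalidate <- function(cohort, index_type = "API", k = 10, seed = 1,
                          positive_group = "FTD",
                          negative_group = "non-FTD",
                          cutoff = -1.65, ...) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  n <- nrow(cohort$subjects)
  fold <- integer(n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (dx in unique(cohort$subjects$diagnosis)) {
    idx <- which(cohort$subjects$diagnosis == dx)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  z <- numeric(n)
  raw <- numeric(n)
  for (f in seq_len(k)) {
    train <- subset_cohort(cohort, fold != f)
    if (sum(diagnosis_in(train, "FTD")) < 2L ||
        sum(diagnosis_in(train, "AD")) < 2L) {
      stop("training folds lack FTD or AD subjects; use fewer folds ",
           "or a larger cohort", call. = FALSE)
    }
    model <- fit_index(train, index_type, cutoff = cutoff, ...)
    test <- subset_cohort(cohort, fold == f)
    sc <- predict(model, test)
    z[fold == f] <- sc$z
    raw[fold == f] <- sc$raw
  }
  pos <- diagnosis_in(cohort, positive_group)
  neg <- diagnosis_in(cohort, negative_group) & !pos
  keep <- pos | neg
  report <- evaluate_scores(z[keep], pos[keep], cutoff = cutoff,
                            comparison = paste(
                              paste(positive_group, collapse = "+"),
                              "vs",
                              paste(negative_group, collapse = "+")))
  fold_auc <- vapply(seq_len(k), function(f) {
    sel <- keep & fold == f
    if (length(unique(pos[sel])) < 2L) return(NA_real_)
    roc_auc(z[sel], pos[sel], direction = "lower")$auc
  }, numeric(1))
  structure(list(
    scores = data.frame(subject_id = cohort$subjects$subject_id,
                        diagnosis = cohort$subjects$diagnosis,
                        fold = fold, raw = raw, z = z,
                        stringsAsFactors = FALSE),
    report = report, fold_auc = fold_auc, k = k, seed = seed,
    index_type = index_type
  ), class = "ftd_cv")
}

#' @export
print.ftd_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation of ", x$index_type,
      " (seed ", x$seed, ")\n", sep = "")
  print(x$report)
  cat("  per-fold AUC: ",
      paste(sprintf("%.2f", x$fold_auc), collapse = " "), "\n")
  invisible(x)
}

#' Split a cohort into age strata
#'
#' Partitions subjects at an age threshold (strictly below vs. at/above,
#' default 70 years) so every analysis can be repeated per stratum.
#'
#' @param cohort an [ftd_cohort()].
#' @param threshold age threshold in years.
#' @return named list of two cohorts, `below` and `at_or_above`; an empty
#'   stratum is returned as `NULL` with a warning.
#' @export
stratify_age <- function(cohort, threshold = 70) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  below <- cohort$subjects$age < threshold
  out <- list(below = NULL, at_or_above = NULL)
  if (any(below)) out$below <- subset_cohort(cohort, below) else {
    warning("empty stratum: no subjects below ", threshold, call. = FALSE)
  }
  if (any(!below)) out$at_or_above <- subset_cohort(cohort, !below) else {
    warning("empty stratum: no subjects at/above ", threshold,
            call. = FALSE)
  }
  out
}
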