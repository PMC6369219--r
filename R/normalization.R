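#' Fit the regional volume normalization model
#'
#' Removes nuisance variation from regional volumes before index
#' computation, calibrated on a reference group. The chain is applied in a
#' fixed order: (1) head size — proportional scaling of every volume to a
#' common intracranial volume, `v' = v * reference_tiv / tiv`, with
#' `reference_tiv` the mean TIV of the reference group; (2) age and sex —
#' per-region linear regression of the head-size-corrected volume on age
#' (centred at the reference mean) and a male indicator, fitted within the
#' reference group, whose fitted effects are subtracted when the model is
#' applied; (3) optionally, additive MRI field-strength offsets (off by
#' default — field strength had no appreciable effect on accuracy in the
#' setting this models).
#'
#' @param cohort an [ftd_cohort()].
#' @param reference_group character vector of diagnosis labels defining
#'   the reference population (default: all non-FTD groups).
#' @param covariates subset of `c("headsize", "age", "sex",
#'   "field_strength")` to correct for.
#' @return an object of class `ftd_norm` with per-region coefficients.
#'   Apply it with [predict.ftd_norm()] / [apply_normalization()].
#' @examples
#' cohort <- generate_cohort(simulation_config(preset = "small"), seed = 1)
#' nm <- fit_normalization(cohort)
#' normed <- apply_normalization(nm, cohort)
#' @export
fit_normalization <- function(cohort,
                              reference_group = c("SCD", "MCI", "AD",
                                                  "VaD", "DLB", "Other"),
                              covariates = c("headsize", "age", "sex")) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  covariates <- match.arg(covariates,
                          c("headsize", "age", "sex", "field_strength"),
                          several.ok = TRUE)
  ref_idx <- diagnosis_in(cohort, reference_group)
  n_ref <- sum(ref_idx)
  if (n_ref == 0L) stop("reference group is empty", call. = FALSE)
  s <- cohort$subjects[ref_idx, , drop = FALSE]
  v <- cohort$volumes[ref_idx, , drop = FALSE]

  reference_tiv <- if ("headsize" %in% covariates) mean(s$tiv) else NA_real_
  v_scaled <- if ("headsize" %in% covariates) {
    v * (reference_tiv / s$tiv)
  } else v

  ref_mean_age <- mean(s$age)
  age_c <- s$age - ref_mean_age
  male <- as.numeric(s$sex == "male")

  design <- cbind(intercept = rep(1, n_ref))
  use_age <- "age" %in% covariates && stats::var(age_c) > 0
  use_sex <- "sex" %in% covariates && stats::var(male) > 0
  if ("age" %in% covariates && !use_age) {
    warning("zero variance in age within reference group; ",
            "age coefficients fixed at 0", call. = FALSE)
  }
  if ("sex" %in% covariates && !use_sex) {
    warning("zero variance in sex within reference group; ",
            "sex coefficients fixed at 0", call. = FALSE)
  }
  if (use_age) design <- cbind(design, age = age_c)
  if (use_sex) design <- cbind(design, male = male)
  if (ncol(design) > 1L && n_ref < 10L * (ncol(design) - 1L)) {
    warning("fewer than 10 reference subjects per fitted coefficient",
            call. = FALSE)
  }

  fit <- stats::lm.fit(design, v_scaled)
  cf <- fit$coefficients
  regions <- cohort$atlas$name
  age_coef <- if (use_age) cf["age", ] else stats::setNames(
    rep(0, length(regions)), regions)
  sex_coef <- if (use_sex) cf["male", ] else stats::setNames(
    rep(0, length(regions)), regions)

  fs_offsets <- NULL
  fs_reference <- NA_real_
  if ("field_strength" %in% covariates) {
    fs <- s$field_strength
    if (all(is.na(fs)) || length(unique(stats::na.omit(fs))) < 2L) {
      warning("zero variance in field strength; offsets fixed at 0",
              call. = FALSE)
    } else {
      resid <- v_scaled -
        design %*% cf
      fs_levels <- sort(unique(stats::na.omit(fs)))
      fs_reference <- fs_levels[which.max(tabulate(match(fs, fs_levels)))]
      fs_offsets <- sapply(fs_levels, function(l) {
        colMeans(resid[which(fs == l), , drop = FALSE]) -
          colMeans(resid[which(fs == fs_reference), , drop = FALSE])
      })
      colnames(fs_offsets) <- as.character(fs_levels)
    }
  }

  structure(list(
    covariates = covariates,
    reference_group = reference_group,
    regions = regions,
    reference_tiv = reference_tiv,
    ref_mean_age = ref_mean_age,
    age_coef = age_coef,
    sex_coef = sex_coef,
    fs_offsets = fs_offsets,
    fs_reference = fs_reference,
    fitted_on = n_ref,
    epsilon = 0.001
  ), class = "ftd_norm")
}

#' Apply a fitted normalization model to a cohort
#'
#' Computes, per subject and region,
#' `v_norm = v * reference_tiv / tiv - age_coef * (age - ref_mean_age)
#'  - sex_coef * male - field_strength_offset`,
#' flooring the result at a small positive epsilon (0.001 ml) so that
#' downstream log-ratios stay defined. Deterministic.
#'
#' @param object,model an `ftd_norm` from [fit_normalization()].
#' @param cohort an [ftd_cohort()] over the same atlas regions.
#' @param ... unused.
#' @return the cohort with normalized volumes.
#' @export
apply_normalization <- function(model, cohort) {
  stopifnot(inherits(model, "ftd_norm"), inherits(cohort, "ftd_cohort"))
  missing_r <- setdiff(model$regions, cohort$atlas$name)
  if (length(missing_r) > 0L) {
    stop("normalization model is incompatible with cohort atlas; ",
         "missing region(s): ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }
  s <- cohort$subjects
  bad_tiv <- s$subject_id[!is.finite(s$tiv) | s$tiv <= 0]
  if (length(bad_tiv) > 0L) {
    stop("non-positive TIV for subject(s): ",
         paste(bad_tiv, collapse = ", "), call. = FALSE)
  }
  v <- cohort$volumes[, model$regions, drop = FALSE]
  if ("headsize" %in% model$covariates) {
    v <- v * (model$reference_tiv / s$tiv)
  }
  age_adj <- outer(s$age - model$ref_mean_age, model$age_coef)
  sex_adj <- outer(as.numeric(s$sex == "male"), model$sex_coef)
  v <- v - age_adj - sex_adj
  if (!is.null(model$fs_offsets)) {
    lev <- colnames(model$fs_offsets)
    idx <- match(as.character(s$field_strength), lev)
    for (i in which(!is.na(idx))) {
      v[i, ] <- v[i, ] - model$fs_offsets[, idx[i]]
    }
  }
  n_floored <- sum(v < model$epsilon)
  if (n_floored > 0L) {
    message(n_floored, " normalized volume(s) floored at ",
            model$epsilon, " ml")
  }
  v[v < model$epsilon] <- model$epsilon
  out <- cohort
  out$volumes[, model$regions] <- v
  out$provenance <- paste0(cohort$provenance, "; normalized (",
                           paste(model$covariates, collapse = "+"), ")")
  out
}

#' @rdname apply_normalization
#' @export
predict.ftd_norm <- function(object, cohort, ...) {
  apply_normalization(object, cohort)
}

#' @export
print.ftd_norm <- function(x, ...) {
  cat("Volume normalization model (", paste(x$covariates, collapse = " + "),
      ")\n", sep = "")
  cat("  reference group:", paste(x$reference_group, collapse = ","),
      "(n =", x$fitted_on, ")\n")
  if ("headsize" %in% x$covariates) {
    cat("  reference TIV:", round(x$reference_tiv, 1), "ml\n")
  }
  cat("  reference mean age:", round(x$ref_mean_age, 1), "years\n")
  cat("  regions:", length(x$regions), "\n")
  invisible(x)
}

#' @export
coef.ftd_norm <- function(object, ...) {
  cbind(age_coef = object$age_coef, sex_coef = object$sex_coef)
}
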