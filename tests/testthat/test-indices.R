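# cohort with exactly controlled group means for weight arithmetic:
# anterior regions (front/temp) and posterior regions (par/occ)
weight_cohort <- function(ad_ant = 10, ftd_ant = 8, ref_extra_ant = NULL,
                          ad_post = 5, ftd_post = 5) {
  # 2 AD, 2 FTD, 2 SCD; SCD chosen so mean_nonFTD is easy to control
  mk <- function(ant, post) rep(c(ant, post), each = 4)
  scd_ant <- if (is.null(ref_extra_ant)) ad_ant else ref_extra_ant
  v <- rbind(mk(ad_ant, ad_post), mk(ad_ant, ad_post),
             mk(ftd_ant, ftd_post), mk(ftd_ant, ftd_post),
             mk(scd_ant, ad_post), mk(scd_ant, ad_post))
  tiny_cohort(v, c("AD", "AD", "FTD", "FTD", "SCD", "SCD"))
}

test_that("region weights follow the AD/FTD contrast scaled by the non-FTD mean", {
  co <- weight_cohort(ad_ant = 10, ftd_ant = 8) # mean_nonFTD anterior = 10
  a <- tiny_atlas()
  w <- compute_region_weights(co, anterior_regions(a),
                              posterior_regions(a))
  # anterior: (10 - 8) / 10 = 0.2
  expect_equal(unname(w[anterior_regions(a)]), rep(0.2, 4))
  # posterior: (mean_FTD - mean_AD) = 0 -> 0
  expect_equal(unname(w[posterior_regions(a)]), rep(0, 4))
})

test_that("negative weights are clamped to zero and excluded regions forced to zero", {
  co <- weight_cohort(ad_ant = 8, ftd_ant = 10) # anterior contrast negative
  a <- tiny_atlas()
  w <- compute_region_weights(co, anterior_regions(a),
                              posterior_regions(a))
  expect_true(all(w >= 0))
  expect_equal(unname(w[anterior_regions(a)]), rep(0, 4))
  co2 <- weight_cohort()
  w2 <- compute_region_weights(co2, anterior_regions(a),
                               posterior_regions(a),
                               excluded_regions = "L_front_a")
  expect_equal(unname(w2["L_front_a"]), 0)
  expect_gt(w2["R_front_a"], 0)
})

test_that("raw ratio index is the natural log of weighted sums and scale invariant", {
  model <- structure(list(
    index_type = "API",
    numerator_regions = c("L_front_a", "R_front_a"),
    denominator_regions = c("L_par_a", "R_par_a"),
    weights = c(L_front_a = 1, R_front_a = 1, L_par_a = 1, R_par_a = 1),
    mu = 0, sigma = 1
  ), class = "ftd_index")
  v <- c(L_front_a = 60, R_front_a = 40, L_temp_a = 1, R_temp_a = 1,
         L_par_a = 30, R_par_a = 20, L_occ_a = 1, R_occ_a = 1)
  expect_equal(compute_raw_index(v, model), log(2)) # 100 / 50
  expect_equal(compute_raw_index(v, model), 0.6931, tolerance = 1e-4)
  # equal sums -> log(1) = 0
  v0 <- v; v0[c("L_par_a", "R_par_a")] <- c(60, 40)
  expect_equal(compute_raw_index(v0, model), 0)
  # global rescaling of the subject cancels
  expect_equal(compute_raw_index(3 * v, model),
               compute_raw_index(v, model))
  # non-positive weighted sums are named by side
  vneg <- v; vneg[c("L_par_a", "R_par_a")] <- 0
  expect_error(compute_raw_index(vneg, model), "denominator")
  model0 <- model; model0$weights[] <- 0
  expect_error(compute_raw_index(v, model0), "all region weights")
})

test_that("z calibration uses the sample mean and n-1 SD of the reference", {
  cal <- calibrate_zscore(c(1, 3))
  expect_equal(cal$mu, 2)
  expect_equal(cal$sigma, sqrt(2))
  expect_error(calibrate_zscore(c(2, 2, 2)), "degenerate")
  set.seed(1)
  raw <- rnorm(50, 3, 2)
  cal2 <- calibrate_zscore(raw)
  z <- (raw - cal2$mu) / cal2$sigma
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("classification is strictly below the cutoff, optionally two-sided", {
  expect_true(classify_index(-2.0, cutoff = -1.65))
  expect_false(classify_index(-1.65, cutoff = -1.65)) # boundary negative
  expect_false(classify_index(-1.0, cutoff = -1.65))
  expect_equal(classify_index(c(-2, 2, 0), cutoff = -1.65,
                              two_sided = TRUE),
               c(TRUE, TRUE, FALSE))
  # standard-normal reference: ~95% classified negative at -1.65
  set.seed(2)
  z <- rnorm(2e4)
  expect_equal(mean(!classify_index(z)), 0.95, tolerance = 0.01)
})

test_that("fit_index composes weights and calibration per index type", {
  cfg <- simulation_config(preset = "small")
  co <- generate_cohort(cfg, seed = 3)
  fit_tpl <- fit_index(co, "TPL")
  expect_equal(fit_tpl$weights, c(L_temporal_pole = 1))
  expect_length(fit_tpl$denominator_regions, 0)
  expect_gt(fit_tpl$sigma, 0)

  fit_api <- fit_index(co, "API")
  expect_true(all(coef(fit_api) >= 0))
  expect_true(all(coef(fit_api)[fit_api$excluded_regions] == 0))
  # the two anatomical-outlier gyri are excluded by default, both sides
  expect_setequal(fit_api$excluded_regions,
                  c("L_parahippocampal_gyrus", "R_parahippocampal_gyrus",
                    "L_inferior_temporal_gyrus",
                    "R_inferior_temporal_gyrus"))
  sc <- predict(fit_api, co)
  ftd <- diagnosis_in(co, "FTD")
  expect_lt(median(sc$z[ftd]), median(sc$z[!ftd]))
  # calibration population has mean-0, sd-1 z-scores by construction
  ref <- diagnosis_in(co, "non-FTD")
  expect_equal(mean(sc$z[ref]), 0, tolerance = 1e-10)
  expect_equal(sd(sc$z[ref]), 1, tolerance = 1e-10)
})

test_that("ASI is antisymmetric under a left/right mirror swap", {
  cfg <- simulation_config(preset = "small")
  co <- generate_cohort(cfg, seed = 4)
  fit <- fit_index(co, "ASI", normalization = NULL)
  pairs <- region_pairs(co$atlas)
  mirrored <- co
  mirrored$volumes[, c(pairs$left, pairs$right)] <-
    co$volumes[, c(pairs$right, pairs$left)]
  raw <- compute_raw_index(co$volumes, fit)
  raw_m <- compute_raw_index(mirrored$volumes, fit)
  expect_equal(raw_m, -raw, tolerance = 1e-12)
  # weights are hemisphere-symmetric by construction
  expect_equal(unname(coef(fit)[pairs$left[pairs$left %in%
                                             fit$numerator_regions]]),
               unname(coef(fit)[pairs$right[pairs$right %in%
                                              fit$denominator_regions]]))
})

test_that("a perfectly mirrored cohort has degenerate (zero-variance) ASI", {
  set.seed(6)
  v <- matrix(runif(6 * 8, 4, 8), nrow = 6)
  v[, c(2, 4, 6, 8)] <- v[, c(1, 3, 5, 7)] # right = left exactly
  co <- tiny_cohort(v, c("AD", "AD", "FTD", "FTD", "SCD", "SCD"))
  expect_error(fit_index(co, "ASI", normalization = NULL),
               "degenerate|zero variance")
})

test_that("single-region screening ranks the left temporal pole first for svPPA", {
  cfg <- simulation_config(
    preset = "small",
    group_sizes = c(SCD = 60, svPPA = 25),
    atrophy_effects = list(SCD = numeric(0),
                           svPPA = c(left_temporal_pole = 0.30))
  )
  co <- generate_cohort(cfg, seed = 5)
  nm <- fit_normalization(co, reference_group = "SCD")
  ranked <- screen_single_regions(apply_normalization(nm, co),
                                  "svPPA", "SCD")
  expect_equal(ranked$region[1], "L_temporal_pole")
  expect_gt(ranked$auc[1], 0.9)
})

test_that("screening is null at AUC ~ 0.5 for identical distributions and monotone in effect", {
  cfg0 <- simulation_config(preset = "small",
                            group_sizes = c(SCD = 80, svPPA = 40),
                            atrophy_effects = list(SCD = numeric(0),
                                                   svPPA = numeric(0)))
  co0 <- generate_cohort(cfg0, seed = 6)
  ranked0 <- screen_single_regions(co0, "svPPA", "SCD")
  expect_true(all(abs(ranked0$auc - 0.5) < 0.2))
  expect_lt(abs(mean(ranked0$auc) - 0.5), 0.1)
  # doubling a region's group deficit does not decrease its AUC
  aucs <- sapply(c(0.1, 0.2), function(eff) {
    cfg <- simulation_config(preset = "small",
                             group_sizes = c(SCD = 80, svPPA = 40),
                             atrophy_effects = list(
                               SCD = numeric(0),
                               svPPA = c(left_temporal_pole = eff)))
    co <- generate_cohort(cfg, seed = 7)
    r <- screen_single_regions(co, "svPPA", "SCD")
    r$auc[r$region == "L_temporal_pole"]
  })
  expect_gte(aucs[2], aucs[1])
})

test_that("index models survive a JSON round-trip and score identically", {
  cfg <- simulation_config(preset = "small")
  co <- generate_cohort(cfg, seed = 8)
  fit <- fit_index(co, "API")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model(fit, tmp)
  back <- read_model(tmp, atlas = co$atlas)
  expect_equal(back$weights, fit$weights, tolerance = 0)
  expect_equal(back$mu, fit$mu)
  expect_equal(back$sigma, fit$sigma)
  expect_equal(predict(back, co)$z, predict(fit, co)$z, tolerance = 1e-12)
  # loading against an atlas lacking a weighted region is an explicit
  # incompatibility
  small <- tiny_atlas()
  expect_error(read_model(tmp, atlas = small), "incompatible")
  # normalization models round-trip to full precision too
  nm <- fit_normalization(co)
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_model(nm, tmp2)
  nm2 <- read_model(tmp2)
  expect_equal(nm2$age_coef, nm$age_coef, tolerance = 0)
  expect_equal(nm2$reference_tiv, nm$reference_tiv)
  expect_equal(apply_normalization(nm2, co)$volumes,
               apply_normalization(nm, co)$volumes, tolerance = 1e-12)
})
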