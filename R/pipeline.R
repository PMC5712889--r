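# End-to-end experiment driver: simulate (or load) paired spectra,
# preprocess, split by Kennard-Stone, train the master model, choose the
# master instrument by Passing-Bablok, select standardization samples,
# build the transfer, and evaluate every requested transfer method on the
# same prediction samples.
#
# Preprocessing is staged deliberately. Per-instrument smoothing (a linear,
# channel-local operation) is applied before the transfer is estimated:
# between two instruments observing the same samples the response map is
# channel-wise linear in this space, which is exactly PDS's model class.
# Per-sample scatter correction (SNV), whose scale factor differs between
# instruments sample by sample and therefore breaks channel-wise linearity,
# is applied after transfer, to master spectra and transferred slave
# spectra alike, immediately before modelling.

#' Experiment configuration
#'
#' Collects every knob of the transfer experiment with defaults matching
#' the package's standard synthetic scenario: 700 berries observed by the
#' default grating (master role) and Fourier-transform (slave role)
#' profiles, cropped to the shared 1000-1800 nm range, smoothed per
#' instrument, SNV-corrected for modelling, split 550/150 by
#' Kennard-Stone, modelled by LS-SVM with LOOCV-tuned parameters, and
#' transferred with 45 standardization samples.
#'
#' @param n,seed Simulated sample count and RNG seed.
#' @param master_profile,slave_profile [instrument_profile()]s for the
#'   simulation.
#' @param analyte [analyte_model()] for the simulation.
#' @param chem_sd Chemistry-noise SD passed to [generate_paired_dataset()].
#' @param master_data,slave_data Optional pre-made [spectra_set()]s (same
#'   samples on both); when supplied the simulator is skipped.
#' @param crop_range Shared modelling range in nm (further clipped to the
#'   intersection of the two instruments' spans).
#' @param master_plan,slave_plan Per-instrument pre-transfer
#'   [preprocess_plan()]s (smoothing; applied before the transfer is
#'   estimated).
#' @param model_plan Post-transfer [preprocess_plan()] (scatter
#'   correction; applied to master spectra and to transferred slave
#'   spectra immediately before modelling).
#' @param n_calibration Calibration-set size.
#' @param model `"lssvm"` or `"pls"`.
#' @param gamma,sigma2 Fixed LS-SVM parameters; `NULL` means tune by LOOCV
#'   over `gamma_grid` x `sigma2_grid`.
#' @param gamma_grid,sigma2_grid LS-SVM tuning grids.
#' @param max_components PLS component ceiling.
#' @param master `"auto"` (Passing-Bablok choice), `"master"`, or
#'   `"slave"`: which dataset plays the master role.
#' @param n_standardization Standardization-set size.
#' @param methods Transfer methods to evaluate, from `"none"`,
#'   `"interp_only"`, `"common_pds"`, `"linear_interp_pds"`.
#' @param half_width PDS window half-width in channels, or `"auto"` to
#'   search `hw_candidates` for the lowest prediction RMSEP.
#' @param hw_candidates Candidate half-widths for the search.
#' @param pds_ncomp PLS components per PDS window.
#' @param pds_intercept Additive term in the PDS regressions.
#' @param common_tolerance Matching tolerance (nm) for
#'   [common_wavelengths()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n = 700, seed = 1,
                              master_profile = default_master_profile(),
                              slave_profile = default_slave_profile(),
                              analyte = analyte_model(),
                              chem_sd = 0.45,
                              master_data = NULL, slave_data = NULL,
                              crop_range = c(1000, 1800),
                              master_plan = preprocess_plan(ma(3)),
                              slave_plan = preprocess_plan(ma(18)),
                              model_plan = preprocess_plan("snv"),
                              n_calibration = 550,
                              model = c("lssvm", "pls"),
                              gamma = NULL, sigma2 = NULL,
                              gamma_grid = 10^(0:6),
                              sigma2_grid = 10^(-1:5),
                              max_components = 15,
                              master = c("auto", "master", "slave"),
                              n_standardization = 45,
                              methods = c("none", "interp_only",
                                          "common_pds", "linear_interp_pds"),
                              half_width = "auto",
                              hw_candidates = 1:20,
                              pds_ncomp = 2,
                              pds_intercept = TRUE,
                              common_tolerance = 0.05) {
  model <- match.arg(model)
  master <- match.arg(master)
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_standardization > n_calibration) {
    stop("n_standardization must be <= n_calibration")
  }
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  cfg
}

# fit the configured model type; hyper overrides tuning
.fit_model <- function(X, y, cfg, hyper = NULL) {
  if (cfg$model == "lssvm") {
    if (is.null(hyper)) {
      if (!is.null(cfg$gamma) && !is.null(cfg$sigma2)) {
        hyper <- list(gamma = cfg$gamma, sigma2 = cfg$sigma2)
      } else {
        tuned <- lssvm_tune(X, y, cfg$gamma_grid, cfg$sigma2_grid)
        hyper <- list(gamma = tuned$gamma, sigma2 = tuned$sigma2)
      }
    }
    list(model = lssvm_fit(X, y, hyper$gamma, hyper$sigma2), hyper = hyper)
  } else {
    m <- pls_fit(X, y, cfg$max_components)
    if (!is.null(hyper)) {
      fit <- .pls1(X, y, hyper$n_components)
      m$n_components <- fit$ncomp
      m$coefficients <- fit$coef_path[, fit$ncomp]
      m$x_mean <- fit$x_mean; m$y_mean <- fit$y_mean
      m$n_train <- nrow(X)
    }
    list(model = m, hyper = list(n_components = m$n_components))
  }
}

# split + fit + evaluate one instrument on its own (model-space) spectra;
# the split indices are equally valid for the raw (pre-transfer) spectra
.instrument_model <- function(s_model, cfg) {
  split <- ks_split(s_model, cfg$n_calibration)
  fit <- .fit_model(split$calibration$absorbance,
                    split$calibration$reference, cfg)
  pred <- predict(fit$model, split$prediction)
  list(split = split, model = fit$model, hyper = fit$hyper,
       prediction = pred,
       report = evaluate(pred, split$prediction$reference, "prediction"),
       pb = passing_bablok(split$prediction$reference, pred))
}

#' Search the PDS window half-width
#'
#' Builds the transfer at each candidate half-width and returns the one
#' with the lowest RMSEP of the transferred slave prediction set under the
#' master model.
#'
#' @param master_std,slave_std Standardization [spectra_set()]s in the
#'   space the transfer is estimated in (per-instrument smoothed spectra).
#' @param model Fitted master model (`lssvm_model` or `pls_model`).
#' @param slave_pred Slave prediction-set spectra (same space as
#'   `slave_std`).
#' @param reference Prediction-set reference values.
#' @param candidates Integer half-widths to try.
#' @param method `"linear_interp_pds"` or `"common_pds"`.
#' @param master_grid Target grid for `linear_interp_pds`.
#' @param tolerance Matching tolerance for `common_pds`.
#' @param n_window_components,intercept As in [build_pds()].
#' @param post_plan [preprocess_plan()] applied to the transferred spectra
#'   before prediction (the pipeline's scatter-correction stage).
#' @return A list with `half_width` (the argmin) and `rmsep` per candidate.
#' @export
select_half_width <- function(master_std, slave_std, model, slave_pred,
                              reference, candidates = 1:20,
                              method = c("linear_interp_pds", "common_pds"),
                              master_grid = NULL, tolerance = 0.1,
                              n_window_components = 2, intercept = TRUE,
                              post_plan = NULL) {
  method <- match.arg(method)
  rmsep <- vapply(candidates, function(hw) {
    t <- if (method == "linear_interp_pds") {
      linear_interp_pds(master_std, slave_std, master_grid, hw,
                        n_window_components, intercept)
    } else {
      common_pds(master_std, slave_std, tolerance, hw,
                 n_window_components, intercept)
    }
    out <- apply_plan(apply_transfer(t, slave_pred), post_plan)
    evaluate(predict(model, out), reference)$rmse
  }, numeric(1))
  list(half_width = candidates[which.min(rmsep)],
       rmsep = stats::setNames(rmsep, candidates))
}

# Simulate or pass through, crop to the shared range, per-instrument
# pre-transfer smoothing. Each instrument is prepared in two versions:
# `as_slave` keeps every channel in the shared range (a slave needs its
# full grid to bracket master wavelengths for interpolation), `as_master`
# is additionally restricted to the other instrument's span (a master
# wavelength outside the slave span could never be interpolated).
.prepare_data <- function(cfg) {
  if (is.null(cfg$master_data)) {
    pair <- generate_paired_dataset(cfg$n, cfg$master_profile,
                                    cfg$slave_profile, cfg$analyte,
                                    seed = cfg$seed, chem_sd = cfg$chem_sd)
  } else {
    pair <- list(master = cfg$master_data, slave = cfg$slave_data)
  }
  cropped <- lapply(pair, crop_wavelengths,
                    lower = cfg$crop_range[1], upper = cfg$crop_range[2])
  spans <- lapply(cropped, function(s) range(s$wavelengths))
  lapply(stats::setNames(c("master", "slave"), c("master", "slave")),
         function(k) {
    other <- spans[[setdiff(c("master", "slave"), k)]]
    plan <- cfg[[paste0(k, "_plan")]]
    list(as_slave = apply_plan(cropped[[k]], plan),
         as_master = apply_plan(
           crop_wavelengths(cropped[[k]], other[1], other[2]), plan))
  })
}

# common-channel master model: raw master calibration restricted to the
# matched channels, scatter-corrected on that grid, refit with the master
# model's hyperparameters
.common_model <- function(cfg, M_cal_raw, S_grid, mfit) {
  pairs <- common_wavelengths(M_cal_raw$wavelengths, S_grid,
                              cfg$common_tolerance)
  Xc <- apply_plan(M_cal_raw[, pairs$a], cfg$model_plan)
  .fit_model(Xc$absorbance, Xc$reference, cfg, hyper = mfit$hyper)$model
}

#' Run the full calibration-transfer experiment
#'
#' Executes the whole chain on one configuration: data preparation,
#' master-role assignment (Passing-Bablok on each instrument's own
#' predictions when `master = "auto"`), Kennard-Stone splitting on the
#' master's model-space spectra, master-model training, standardization
#' sample selection, transfer construction in the smoothed response
#' space, scatter correction, and evaluation of every requested method on
#' the same prediction samples.
#'
#' When no instrument's H0 is accepted the run continues with the
#' instrument whose own prediction RMSEP is lowest and flags
#' `no_acceptable_master`.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_result`: `reports` (one
#'   [evaluate()] report per method), `transfer_models`, `master_model`,
#'   `master_instrument`, `master_choice`, `half_width`, `split`,
#'   `std_selection`, `hyper`, and the `config`.
#' @export
run_experiment <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "experiment_config"))
  data <- .prepare_data(cfg)
  model_space <- lapply(data, function(d) {
    apply_plan(d$as_master, cfg$model_plan)
  })
  choice <- NULL
  fits <- list()
  if (cfg$master == "auto") {
    fits$master <- .instrument_model(model_space$master, cfg)
    fits$slave <- .instrument_model(model_space$slave, cfg)
    choice <- choose_master(list(master = fits$master$pb,
                                 slave = fits$slave$pb))
    role <- choice$instrument
    if (is.na(role)) {
      role <- names(which.min(vapply(fits, function(f) f$report$rmse,
                                     numeric(1))))
    }
  } else {
    role <- cfg$master
    fits[[role]] <- .instrument_model(model_space[[role]], cfg)
  }
  other <- setdiff(c("master", "slave"), role)
  M_raw <- data[[role]]$as_master
  S_raw <- data[[other]]$as_slave
  mfit <- fits[[role]]
  split <- mfit$split
  cal_idx <- split$selection$selected
  pred_idx <- split$selection$remaining
  S_pred_raw <- S_raw[pred_idx, ]
  std_sel <- select_standardization(split$calibration, cfg$n_standardization)
  M_std_raw <- M_raw[cal_idx[std_sel$selected], ]
  S_std_raw <- S_raw[cal_idx[std_sel$selected], ]

  reports <- list()
  models <- list()
  hw_used <- NULL
  for (meth in cfg$methods) {
    if (meth == "none") {
      reports$none <- evaluate(mfit$prediction, split$prediction$reference,
                               "master")
      next
    }
    model_for <- mfit$model
    if (meth == "interp_only") {
      t <- interp_only_transfer(S_raw$wavelengths, M_raw$wavelengths)
    } else if (meth == "linear_interp_pds") {
      hw <- cfg$half_width
      if (identical(hw, "auto")) {
        hw <- select_half_width(M_std_raw, S_std_raw, mfit$model, S_pred_raw,
                                S_pred_raw$reference, cfg$hw_candidates,
                                "linear_interp_pds", M_raw$wavelengths,
                                n_window_components = cfg$pds_ncomp,
                                intercept = cfg$pds_intercept,
                                post_plan = cfg$model_plan)$half_width
      }
      hw_used <- hw
      t <- linear_interp_pds(M_std_raw, S_std_raw, M_raw$wavelengths, hw,
                             cfg$pds_ncomp, cfg$pds_intercept)
    } else { # common_pds
      model_for <- .common_model(cfg, M_raw[cal_idx, ], S_raw$wavelengths,
                                 mfit)
      hw <- cfg$half_width
      if (identical(hw, "auto")) {
        hw <- select_half_width(M_std_raw, S_std_raw, model_for, S_pred_raw,
                                S_pred_raw$reference, cfg$hw_candidates,
                                "common_pds",
                                tolerance = cfg$common_tolerance,
                                n_window_components = cfg$pds_ncomp,
                                intercept = cfg$pds_intercept,
                                post_plan = cfg$model_plan)$half_width
      }
      t <- common_pds(M_std_raw, S_std_raw, cfg$common_tolerance, hw,
                      cfg$pds_ncomp, cfg$pds_intercept)
    }
    models[[meth]] <- t
    transferred <- apply_plan(apply_transfer(t, S_pred_raw), cfg$model_plan)
    reports[[meth]] <- evaluate(predict(model_for, transferred),
                                S_pred_raw$reference, meth)
  }
  structure(
    list(reports = reports, transfer_models = models,
         master_model = mfit$model, master_instrument = role,
         master_choice = choice,
         no_acceptable_master = !is.null(choice) &&
           isTRUE(choice$no_acceptable_master),
         half_width = hw_used, split = split, std_selection = std_sel,
         hyper = mfit$hyper, config = cfg),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Calibration-transfer experiment (master role: ",
      x$master_instrument, ")\n", sep = "")
  for (r in x$reports) print(r)
  if (!is.null(x$half_width)) {
    cat(sprintf("PDS half-width: %d\n", x$half_width))
  }
  invisible(x)
}

#' Sweep the number of standardization samples
#'
#' Rebuilds the linear-interpolation PDS transfer for each standardization
#' size (Kennard-Stone subsets of the fixed calibration set) and evaluates
#' the transferred slave prediction set under the master model. Two
#' variants are reported: `"keep"` trains the master model once on the
#' full calibration set (standards included), `"remove"` refits it per
#' size on the calibration set minus the standards (same hyperparameters,
#' coefficients refit). The prediction set is identical for every row.
#'
#' @param config An [experiment_config()]; when `half_width` is `"auto"`
#'   it is selected once at `n_standardization` standards and then held
#'   fixed across sizes.
#' @param sizes Standardization sizes to sweep.
#' @param variants Subset of `c("keep", "remove")`.
#' @return An object of class `sweep_result`: a data frame with columns
#'   `size`, `variant`, `r2`, `rmsep`, `rpd`, `rc2`, `rmsec`, plus
#'   attributes `argmin` (per variant) and `half_width`.
#' @export
sweep_standardization <- function(config,
                                  sizes = sort(unique(c(seq(10, 75, by = 5),
                                                        42:47))),
                                  variants = c("keep", "remove")) {
  cfg <- config
  stopifnot(inherits(cfg, "experiment_config"))
  variants <- match.arg(variants, several.ok = TRUE)
  if (any(sizes > cfg$n_calibration)) {
    stop("all sizes must be <= n_calibration")
  }
  data <- .prepare_data(cfg)
  role <- if (cfg$master == "auto") "master" else cfg$master
  other <- setdiff(c("master", "slave"), role)
  M_raw <- data[[role]]$as_master
  S_raw <- data[[other]]$as_slave
  M_model <- apply_plan(M_raw, cfg$model_plan)
  mfit <- .instrument_model(M_model, cfg)
  split <- mfit$split
  cal_idx <- split$selection$selected
  pred_idx <- split$selection$remaining
  S_pred_raw <- S_raw[pred_idx, ]
  ref_pred <- S_pred_raw$reference

  hw <- cfg$half_width
  if (identical(hw, "auto")) {
    std0 <- select_standardization(split$calibration, cfg$n_standardization)
    hw <- select_half_width(M_raw[cal_idx[std0$selected], ],
                            S_raw[cal_idx[std0$selected], ],
                            mfit$model, S_pred_raw, ref_pred,
                            cfg$hw_candidates, "linear_interp_pds",
                            M_raw$wavelengths,
                            n_window_components = cfg$pds_ncomp,
                            intercept = cfg$pds_intercept,
                            post_plan = cfg$model_plan)$half_width
  }

  cal_report <- evaluate(predict(mfit$model, split$calibration),
                         split$calibration$reference, "calibration")
  rows <- list()
  for (size in sizes) {
    std <- select_standardization(split$calibration, size)
    t <- linear_interp_pds(M_raw[cal_idx[std$selected], ],
                           S_raw[cal_idx[std$selected], ],
                           M_raw$wavelengths, hw,
                           cfg$pds_ncomp, cfg$pds_intercept)
    transferred <- apply_plan(apply_transfer(t, S_pred_raw), cfg$model_plan)
    for (variant in variants) {
      if (variant == "keep") {
        mdl <- mfit$model
        rc <- cal_report
      } else {
        keep_idx <- setdiff(seq_len(cfg$n_calibration), std$selected)
        Mr <- split$calibration[keep_idx, ]
        mdl <- .fit_model(Mr$absorbance, Mr$reference, cfg,
                          hyper = mfit$hyper)$model
        rc <- evaluate(predict(mdl, Mr), Mr$reference, "calibration")
      }
      ev <- evaluate(predict(mdl, transferred), ref_pred, "prediction")
      rows[[length(rows) + 1]] <-
        data.frame(size = size, variant = variant, r2 = ev$r2,
                   rmsep = ev$rmse, rpd = ev$rpd,
                   rc2 = rc$r2, rmsec = rc$rmse)
    }
  }
  out <- do.call(rbind, rows)
  argmin <- vapply(variants, function(v) {
    sub <- out[out$variant == v, ]
    sub$size[which.min(sub$rmsep)]
  }, numeric(1))
  structure(out, class = c("sweep_result", "data.frame"),
            argmin = argmin, half_width = hw)
}
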