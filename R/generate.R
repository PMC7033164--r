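## Synthetic factorial greenhouse experiment generator.
##
## Emulates a multi-factor gas-exchange + chlorophyll-fluorescence experiment on
## young cucumber canopy leaves: a full temperature x CO2 x light (PAR) grid with
## replicated measurements of net photosynthetic rate (Pn) and the fluorescence
## parameters qP, ETR, PhiPS2, Fv'/Fm', NPQ and qN.

#' Ground-truth parameters of the net photosynthetic rate surface
#'
#' The noise-free Pn surface is a modified rectangular hyperbola in light with a
#' linear photoinhibition term, multiplied by separable Gaussian temperature and
#' Michaelis-Menten CO2 modifiers:
#' \deqn{Pn = \frac{\alpha I (1 - \beta I)}{1 + \gamma I}
#'   \exp\!\left(-\left(\frac{T - T_{opt}}{\sigma_T}\right)^2\right)
#'   \frac{C}{C + K_C} - R_d}
#' where `I` is PAR, `T` temperature and `C` the CO2 mole fraction.
#'
#' The defaults were calibrated once (grid search over the light axis) so that
#' the light saturation point — the PAR value maximising Pn at 18 degC and
#' 600 umol mol-1 CO2 — falls at 989 umol m-2 s-1, i.e. within the
#' \[900, 1100\] band around the ~990 umol m-2 s-1 saturation point typical of
#' young cucumber leaves.
#'
#' @param alpha Initial (apparent) quantum yield slope, umol CO2 per umol photons.
#' @param beta Photoinhibition coefficient, per umol m-2 s-1.
#' @param gamma Light saturation coefficient, per umol m-2 s-1.
#' @param t_opt Optimal temperature, degC.
#' @param t_sigma Temperature response breadth, degC.
#' @param k_c CO2 half-saturation constant, umol mol-1.
#' @param r_d Dark respiration rate, umol m-2 s-1.
#' @return An object of class `pn_surface_params`.
#' @export
#' @examples
#' pn_surface_params()
pn_surface_params <- function(alpha = 0.10, beta = 2.54e-4, gamma = 2e-3,
                              t_opt = 30, t_sigma = 15, k_c = 200, r_d = 0.8) {
  stopifnot(alpha > 0, gamma > 0, beta >= 0, t_sigma > 0, k_c > 0, r_d >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, t_opt = t_opt,
                 t_sigma = t_sigma, k_c = k_c, r_d = r_d),
            class = "pn_surface_params")
}

#' Ground-truth parameters of the fluorescence-parameter surfaces
#'
#' Defines how the PSII fluorescence parameters respond to light, with mild
#' temperature/CO2 modulation. PhiPS2 (actual PSII quantum yield) decays
#' exponentially with PAR; ETR follows the conventional construction
#' ETR = PhiPS2 x PAR x absorptance x PSII fraction; Fv'/Fm' is a compressed
#' power of PhiPS2 so that Fv'/Fm' >= PhiPS2; qP is their ratio; NPQ rises as a
#' Hill function of PAR and declines beyond a photodamage threshold; qN is a
#' saturating transform of NPQ with a deliberately weak coupling (the qN channel
#' carries almost no Pn-related signal, mirroring field observations in which
#' qN correlates with Pn far more weakly than NPQ does).
#'
#' @param phi0 Maximal PSII yield at vanishing light (unitless).
#' @param i_phi PhiPS2 decay scale, umol m-2 s-1.
#' @param leaf_absorptance Leaf absorptance (unitless).
#' @param psii_fraction Fraction of absorbed quanta reaching PSII (unitless).
#' @param npq_max Maximal NPQ (unitless).
#' @param npq_k NPQ half-saturation light, umol m-2 s-1.
#' @param npq_h NPQ Hill exponent (unitless).
#' @param i_damage PAR threshold beyond which NPQ declines, umol m-2 s-1.
#' @param damage_slope Fractional NPQ decline per umol m-2 s-1 above `i_damage`.
#' @param fvpfmp0 Fv'/Fm' at vanishing light (unitless).
#' @param fvpfmp_q Compression exponent linking Fv'/Fm' to PhiPS2, in (0, 1).
#' @param qn0 Baseline qN (unitless).
#' @param qn_gain Gain of the qN coupling to NPQ (unitless, small).
#' @return An object of class `fluor_surface_params`.
#' @export
fluor_surface_params <- function(phi0 = 0.75, i_phi = 1500,
                                 leaf_absorptance = 0.84, psii_fraction = 0.5,
                                 npq_max = 2.5, npq_k = 350, npq_h = 1.4,
                                 i_damage = 1000, damage_slope = 5e-4,
                                 fvpfmp0 = 0.78, fvpfmp_q = 0.6,
                                 qn0 = 0.55, qn_gain = 0.01) {
  stopifnot(phi0 > 0, phi0 < 1, leaf_absorptance > 0, leaf_absorptance <= 1,
            psii_fraction > 0, psii_fraction <= 1, npq_max > 0, npq_k > 0,
            npq_h > 0, i_damage > 0, damage_slope >= 0,
            fvpfmp0 >= phi0, fvpfmp_q > 0, fvpfmp_q < 1, qn_gain >= 0)
  structure(list(phi0 = phi0, i_phi = i_phi,
                 leaf_absorptance = leaf_absorptance,
                 psii_fraction = psii_fraction,
                 npq_max = npq_max, npq_k = npq_k, npq_h = npq_h,
                 i_damage = i_damage, damage_slope = damage_slope,
                 fvpfmp0 = fvpfmp0, fvpfmp_q = fvpfmp_q,
                 qn0 = qn0, qn_gain = qn_gain),
            class = "fluor_surface_params")
}

#' Configuration of the synthetic factorial experiment
#'
#' The default design mirrors a greenhouse multi-factor protocol: 6 temperature
#' levels x 4 CO2 levels x 13 light levels, relative humidity fixed at 50%,
#' three replicate plants per combination — 312 environmental combinations and
#' 936 records in total. Replicate noise is multiplicative Gaussian with a 3%
#' coefficient of variation.
#'
#' @param temp_levels Temperatures, degC; strictly increasing.
#' @param co2_levels CO2 mole fractions, umol mol-1; strictly increasing.
#' @param par_levels Light intensities, umol m-2 s-1; strictly increasing,
#'   non-negative. A level of 0 is supported: fluorescence parameters are
#'   invalid in darkness and are emitted as `NA` with `valid_fluor = FALSE`.
#' @param rh Relative humidity, %, held constant.
#' @param replicates Replicate measurements per grid combination.
#' @param noise_cv Coefficient of variation of the multiplicative replicate
#'   noise (unitless). The additive qN jitter scales with `noise_cv` so that
#'   `noise_cv = 0` yields perfectly identical replicates.
#' @param seed Integer seed making generation reproducible.
#' @param surface_params A [pn_surface_params()] object.
#' @param fluor_params A [fluor_surface_params()] object.
#' @param qn_jitter_sd Additive qN jitter standard deviation at the default
#'   `noise_cv` of 3% (scaled proportionally for other values).
#' @return An object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' nrow(build_factorial_grid(cfg))
generator_config <- function(temp_levels = c(18, 20, 24, 28, 32, 36),
                             co2_levels = c(300, 600, 900, 1200),
                             par_levels = c(20, 50, 100, 200, 300, 500, 700,
                                            900, 1000, 1100, 1200, 1300, 1500),
                             rh = 50, replicates = 3, noise_cv = 0.03,
                             seed = 1L,
                             surface_params = pn_surface_params(),
                             fluor_params = fluor_surface_params(),
                             qn_jitter_sd = 0.05) {
  check_levels <- function(x, name, min_allowed = -Inf) {
    if (length(x) == 0) {
      abort(paste0("`", name, "` must be a non-empty numeric vector."),
            class = "psobp_config_error")
    }
    if (any(diff(x) <= 0)) {
      abort(paste0("`", name, "` must be strictly increasing."),
            class = "psobp_config_error")
    }
    if (any(x < min_allowed)) {
      abort(paste0("`", name, "` must be >= ", min_allowed, "."),
            class = "psobp_config_error")
    }
  }
  check_levels(temp_levels, "temp_levels")
  check_levels(co2_levels, "co2_levels", 0)
  check_levels(par_levels, "par_levels", 0)
  if (replicates < 1) abort("`replicates` must be >= 1.", class = "psobp_config_error")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.", class = "psobp_config_error")
  stopifnot(inherits(surface_params, "pn_surface_params"),
            inherits(fluor_params, "fluor_surface_params"))
  structure(list(temp_levels = temp_levels, co2_levels = co2_levels,
                 par_levels = par_levels, rh = rh, replicates = replicates,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 surface_params = surface_params, fluor_params = fluor_params,
                 qn_jitter_sd = qn_jitter_sd),
            class = "generator_config")
}

#' Full factorial environmental grid
#'
#' Cartesian product of the configured temperature, CO2 and light levels, in
#' deterministic nested order: temperature outermost, CO2 next, light
#' innermost. Replicates are not expanded here.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `tem`, `co2`, `par`, one row per combination.
#' @export
build_factorial_grid <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tidyr::expand_grid(tem = config$temp_levels,
                     co2 = config$co2_levels,
                     par = config$par_levels)
}

#' Noise-free net photosynthetic rate surface
#'
#' @param tem Temperature, degC (vectorised).
#' @param co2 CO2 mole fraction, umol mol-1.
#' @param par PAR, umol m-2 s-1; must be non-negative.
#' @param params A [pn_surface_params()] object.
#' @return Net photosynthetic rate, umol m-2 s-1. At `par = 0` this is `-r_d`
#'   (dark respiration only).
#' @export
#' @examples
#' pn_surface(18, 600, c(0, 300, 990, 1500), pn_surface_params())
pn_surface <- function(tem, co2, par, params = pn_surface_params()) {
  stopifnot(inherits(params, "pn_surface_params"))
  if (any(par < 0)) abort("`par` must be >= 0.", class = "psobp_domain_error")
  light <- params$alpha * par * (1 - params$beta * par) / (1 + params$gamma * par)
  temp_mod <- exp(-((tem - params$t_opt) / params$t_sigma)^2)
  co2_mod <- co2 / (co2 + params$k_c)
  light * temp_mod * co2_mod - params$r_d
}

## mild temperature/CO2 modulation of PSII yield, clamped to [0.9, 1.1]
fluor_modulation <- function(tem, co2) {
  pmin(1.1, pmax(0.9, 1 + 0.05 * (tem - 27) / 9 + 0.05 * (co2 - 750) / 450))
}

#' Noise-free chlorophyll fluorescence parameter surfaces
#'
#' @inheritParams pn_surface
#' @param params A [fluor_surface_params()] object.
#' @return A tibble with columns `qp`, `etr`, `phips2`, `fvpfmp`, `npq`, `qn`.
#'   Requires `par > 0`: fluorescence parameters are undefined in darkness.
#' @export
fluorescence_surface <- function(tem, co2, par, params = fluor_surface_params()) {
  stopifnot(inherits(params, "fluor_surface_params"))
  if (any(par <= 0)) {
    abort("`par` must be > 0; fluorescence parameters are invalid in darkness.",
          class = "psobp_domain_error")
  }
  n <- max(length(tem), length(co2), length(par))
  tem <- rep_len(tem, n); co2 <- rep_len(co2, n); par <- rep_len(par, n)
  m <- fluor_modulation(tem, co2)
  phips2 <- params$phi0 * exp(-par / params$i_phi) * m
  etr <- phips2 * par * params$leaf_absorptance * params$psii_fraction
  fvpfmp <- params$fvpfmp0 * (phips2 / params$phi0)^params$fvpfmp_q
  fvpfmp <- pmin(1, pmax(fvpfmp, phips2))
  qp <- pmin(1, phips2 / fvpfmp)
  hill <- par^params$npq_h / (par^params$npq_h + params$npq_k^params$npq_h)
  damage <- pmax(0, 1 - params$damage_slope * pmax(0, par - params$i_damage))
  npq <- params$npq_max * hill * damage
  qn <- params$qn0 + params$qn_gain * (1 - exp(-npq))
  tibble::tibble(qp = qp, etr = etr, phips2 = phips2, fvpfmp = fvpfmp,
                 npq = npq, qn = qn)
}

#' Generate a synthetic factorial dataset
#'
#' Expands the factorial grid by the configured number of replicates and draws
#' each observed quantity as `surface x (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`, then clips to the physical ranges
#' (`0 <= qp <= 1`, `0 <= phips2 <= fvpfmp <= 1`, `etr >= 0`, `npq >= 0`,
#' `0 <= qn <= 1`). The qN channel additionally receives an independent
#' additive jitter (sd `qn_jitter_sd`, scaled by `noise_cv / 0.03`). Records at
#' `par = 0` carry `NA` fluorescence values and `valid_fluor = FALSE`.
#'
#' Generation is fully reproducible: the same `config` (including its `seed`)
#' gives a byte-identical dataset.
#'
#' @param config A [generator_config()].
#' @return A tibble of class `psobp_dataset` with columns `tem`, `co2`, `par`,
#'   `rh`, `pn`, `qp`, `etr`, `phips2`, `fvpfmp`, `npq`, `qn`, `valid_fluor`,
#'   carrying the config and seed as attributes (`meta`).
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 7))
#' nrow(d)
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  grid <- build_factorial_grid(config)
  full <- tidyr::expand_grid(grid, replicate = seq_len(config$replicates))
  n <- nrow(full)
  lit <- full$par > 0

  pn_true <- pn_surface(full$tem, full$co2, full$par, config$surface_params)
  fl_true <- tibble::tibble(qp = NA_real_, etr = NA_real_, phips2 = NA_real_,
                            fvpfmp = NA_real_, npq = NA_real_, qn = NA_real_)
  fl_true <- fl_true[rep(1, n), ]
  if (any(lit)) {
    fl_true[lit, ] <- fluorescence_surface(full$tem[lit], full$co2[lit],
                                           full$par[lit], config$fluor_params)
  }

  cv <- config$noise_cv
  noisy <- withr::with_seed(config$seed, {
    mult <- function(x) x * (1 + rnorm(n, 0, cv))
    out <- tibble::tibble(
      pn = mult(pn_true),
      qp = mult(fl_true$qp),
      etr = mult(fl_true$etr),
      phips2 = mult(fl_true$phips2),
      fvpfmp = mult(fl_true$fvpfmp),
      npq = mult(fl_true$npq),
      qn = mult(fl_true$qn) + rnorm(n, 0, config$qn_jitter_sd * cv / 0.03)
    )
    out
  })

  # enforce physical ranges after noise
  noisy$qp <- pmin(1, pmax(0, noisy$qp))
  noisy$phips2 <- pmin(1, pmax(0, noisy$phips2))
  noisy$fvpfmp <- pmin(1, pmax(noisy$fvpfmp, noisy$phips2))
  noisy$etr <- pmax(0, noisy$etr)
  noisy$npq <- pmax(0, noisy$npq)
  noisy$qn <- pmin(1, pmax(0, noisy$qn))

  out <- dplyr::bind_cols(
    full[, c("tem", "co2", "par")],
    tibble::tibble(rh = rep(config$rh, n)),
    noisy[, c("pn", "qp", "etr", "phips2", "fvpfmp", "npq", "qn")],
    tibble::tibble(valid_fluor = lit)
  )
  attr(out, "meta") <- list(config = config, seed = config$seed,
                            schema_version = "1.0")
  class(out) <- c("psobp_dataset", class(out))
  out
}

dataset_columns <- c("tem", "co2", "par", "rh", "pn", "qp", "etr", "phips2",
                     "fvpfmp", "npq", "qn", "valid_fluor")

#' Write / read a dataset as annotated CSV
#'
#' The on-disk format is plain UTF-8 CSV with '.' decimal separator, a fixed
#' header naming exactly the dataset columns, preceded by a `#`-prefixed
#' metadata block carrying the schema version, the generation seed and the
#' generator configuration (as JSON). Numeric fields round-trip to full double
#' precision.
#'
#' @param dataset A `psobp_dataset` (or any data frame with the schema columns).
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()` returns
#'   a `psobp_dataset` tibble.
#' @export
write_dataset <- function(dataset, path) {
  missing_cols <- setdiff(dataset_columns, names(dataset))
  if (length(missing_cols) > 0) {
    abort(paste0("Dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "psobp_schema_error")
  }
  meta <- attr(dataset, "meta")
  header <- c("# psobp dataset",
              paste0("# schema_version: ", meta$schema_version %||% "1.0"),
              paste0("# seed: ", meta$seed %||% NA))
  if (!is.null(meta$config)) {
    cfg <- meta$config
    cfg$surface_params <- unclass(cfg$surface_params)
    cfg$fluor_params <- unclass(cfg$fluor_params)
    header <- c(header, paste0("# config: ",
                               jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                                digits = NA)))
  }
  readr::write_lines(header, path)
  body <- dplyr::as_tibble(dataset)[, dataset_columns]
  readr::write_csv(body, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "psobp_schema_error")
  }
  lines <- readr::read_lines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  seed <- NA_integer_
  config <- NULL
  for (ln in meta_lines) {
    if (grepl("^# seed: ", ln)) {
      seed <- suppressWarnings(as.integer(sub("^# seed: ", "", ln)))
    }
    if (grepl("^# config: ", ln)) {
      cfg <- jsonlite::fromJSON(sub("^# config: ", "", ln))
      config <- tryCatch(
        generator_config(
          temp_levels = cfg$temp_levels, co2_levels = cfg$co2_levels,
          par_levels = cfg$par_levels, rh = cfg$rh,
          replicates = cfg$replicates, noise_cv = cfg$noise_cv,
          seed = cfg$seed,
          surface_params = do.call(pn_surface_params, as.list(cfg$surface_params)),
          fluor_params = do.call(fluor_surface_params, as.list(cfg$fluor_params)),
          qn_jitter_sd = cfg$qn_jitter_sd),
        error = function(e) NULL)
    }
  }
  body <- suppressMessages(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character())))
  missing_cols <- setdiff(dataset_columns, names(body))
  if (length(missing_cols) > 0) {
    abort(paste0("File is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "psobp_schema_error")
  }
  extra <- setdiff(names(body), dataset_columns)
  if (length(extra) > 0) {
    abort(paste0("File has unexpected column(s): ",
                 paste(extra, collapse = ", ")),
          class = "psobp_schema_error")
  }
  numeric_cols <- setdiff(dataset_columns, "valid_fluor")
  for (col in numeric_cols) {
    raw <- body[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw == "NA"))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric value in column '", col, "', row ", bad[1],
                   ": '", raw[bad[1]], "'"),
            class = "psobp_schema_error")
    }
    body[[col]] <- val
  }
  body$valid_fluor <- body$valid_fluor %in% c("TRUE", "true", "T", "1")
  out <- body[, dataset_columns]
  attr(out, "meta") <- list(config = config, seed = seed,
                            schema_version = "1.0")
  class(out) <- c("psobp_dataset", class(out))
  out
}

#' Light-response plot of a dataset
#'
#' Net photosynthetic rate against PAR, one panel per CO2 level, coloured by
#' temperature — the conventional light-response-curve view.
#'
#' @param dataset A `psobp_dataset`.
#' @return A ggplot object.
#' @export
plot_light_response <- function(dataset) {
  ggplot2::ggplot(dataset, ggplot2::aes(x = .data$par, y = .data$pn,
                                        colour = factor(.data$tem))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_wrap(~ .data$co2, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "PAR (umol m-2 s-1)", y = "Pn (umol m-2 s-1)",
                  colour = "Tem (degC)") +
    ggplot2::theme_minimal()
}
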