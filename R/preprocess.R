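## Preprocessing: [-1, 1] min-max normalization, Pearson correlation screening
## with significance flags, factor selection, seeded train/validation split.

#' Fit per-feature min-max normalization parameters
#'
#' Records the minimum and maximum of each named feature so that values can be
#' mapped to the interval \[-1, 1\] by `y = 2 (x - xmin) / (xmax - xmin) - 1`
#' and mapped back exactly.
#'
#' @param data A data frame containing the features.
#' @param features Character vector of column names to normalize.
#' @return An object of class `normalization_params`: a tibble with columns
#'   `feature`, `xmin`, `xmax`.
#' @export
#' @examples
#' fit_normalization(data.frame(a = c(2, 4, 6)), "a")
fit_normalization <- function(data, features) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Feature(s) not present: ", paste(missing_cols, collapse = ", ")),
          class = "psobp_schema_error")
  }
  params <- purrr::map_dfr(features, function(f) {
    x <- data[[f]]
    x <- x[!is.na(x)]
    rng <- range(x)
    if (!(rng[2] > rng[1])) {
      abort(paste0("Feature '", f, "' is constant (", rng[1],
                   "); cannot be normalized."),
            class = "psobp_degenerate_feature_error")
    }
    tibble::tibble(feature = f, xmin = rng[1], xmax = rng[2])
  })
  structure(params, class = c("normalization_params", class(params)))
}

norm_lookup <- function(params, feature) {
  i <- match(feature, params$feature)
  if (is.na(i)) {
    abort(paste0("Unknown feature '", feature, "' in normalization params."),
          class = "psobp_schema_error")
  }
  list(xmin = params$xmin[i], xmax = params$xmax[i])
}

#' Map values to \[-1, 1\] and back
#'
#' `normalize()` applies `y = 2 (x - xmin) / (xmax - xmin) - 1`;
#' `denormalize()` inverts it exactly. Values outside the fitted range map
#' outside \[-1, 1\] without clipping (deliberately: validation data may exceed
#' the training range and the model must see that).
#'
#' @param x A numeric vector (with `feature` naming which parameters to use) or
#'   a data frame (every fitted feature column is transformed in place).
#' @param params A `normalization_params` object from [fit_normalization()].
#' @param feature Feature name, required when `x` is a numeric vector.
#' @return Same shape as `x`.
#' @export
normalize <- function(x, params, feature = NULL) {
  stopifnot(inherits(params, "normalization_params"))
  if (is.data.frame(x)) {
    for (f in intersect(params$feature, names(x))) {
      p <- norm_lookup(params, f)
      x[[f]] <- 2 * (x[[f]] - p$xmin) / (p$xmax - p$xmin) - 1
    }
    return(x)
  }
  if (is.null(feature)) abort("`feature` is required for vector input.")
  p <- norm_lookup(params, feature)
  2 * (x - p$xmin) / (p$xmax - p$xmin) - 1
}

#' @rdname normalize
#' @export
denormalize <- function(x, params, feature = NULL) {
  stopifnot(inherits(params, "normalization_params"))
  if (is.data.frame(x)) {
    for (f in intersect(params$feature, names(x))) {
      p <- norm_lookup(params, f)
      x[[f]] <- (x[[f]] + 1) * (p$xmax - p$xmin) / 2 + p$xmin
    }
    return(x)
  }
  if (is.null(feature)) abort("`feature` is required for vector input.")
  p <- norm_lookup(params, feature)
  (x + 1) * (p$xmax - p$xmin) / 2 + p$xmin
}

#' Pearson correlation with significance
#'
#' Computes the Pearson product-moment correlation in its population form,
#' `r = S_xy / (S_x S_y)` with divide-by-n standard deviations and covariance
#' (algebraically identical to the sample n-1 form, since the factors cancel),
#' and a two-sided significance test based on
#' `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#' @param alpha Significance level for the `significant` flag (default 0.01,
#'   bilateral).
#' @param name Optional factor label carried into the result.
#' @return A one-row tibble: `factor`, `r`, `n`, `p_value`, `significant`.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 4, 5, 9))
pearson_cor <- function(x, y, alpha = 0.01, name = NA_character_) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "psobp_domain_error")
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Need at least 3 paired observations.",
                   class = "psobp_domain_error")
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  if (sx == 0 || sy == 0) {
    abort("Correlation undefined: constant input series.",
          class = "psobp_degenerate_feature_error")
  }
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  r <- sxy / (sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  tibble::tibble(factor = name, r = r, n = n, p_value = p,
                 significant = p < alpha)
}

#' Correlation screen of all candidate factors against Pn
#'
#' Correlates each environmental driver (Tem, CO2, Par, RH) and each
#' fluorescence parameter (qP, ETR, PhiPS2, Fv'/Fm', NPQ, qN) with the net
#' photosynthetic rate. Records with `valid_fluor = FALSE` are excluded from
#' the fluorescence correlations. Constant (degenerate) factors — RH in the
#' default design, where humidity is held at 50% — are carried through with
#' `r = NA` and a note instead of an error.
#'
#' @param dataset A `psobp_dataset` (or data frame with the schema columns).
#' @param alpha Significance level for the flag (default 0.01, bilateral).
#' @return A tibble with one row per factor: `factor`, `group` (environmental /
#'   fluorescence), `r`, `n`, `p_value`, `significant`, `note`.
#' @export
correlation_screen <- function(dataset, alpha = 0.01) {
  env_factors <- c("tem", "co2", "par", "rh")
  fluor_factors <- c("qp", "etr", "phips2", "fvpfmp", "npq", "qn")
  need <- c(env_factors, fluor_factors, "pn")
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols) > 0) {
    abort(paste0("Dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "psobp_schema_error")
  }
  screen_one <- function(f, group) {
    d <- dataset
    if (group == "fluorescence" && "valid_fluor" %in% names(d)) {
      d <- d[d$valid_fluor, ]
    }
    res <- tryCatch(
      pearson_cor(d[[f]], d$pn, alpha = alpha, name = f),
      psobp_degenerate_feature_error = function(e) {
        tibble::tibble(factor = f, r = NA_real_, n = nrow(d),
                       p_value = NA_real_, significant = NA)
      })
    res$group <- group
    res$note <- if (is.na(res$r)) "degenerate (constant) factor" else ""
    res
  }
  dplyr::bind_rows(
    purrr::map_dfr(env_factors, screen_one, group = "environmental"),
    purrr::map_dfr(fluor_factors, screen_one, group = "fluorescence")
  )[, c("factor", "group", "r", "n", "p_value", "significant", "note")]
}

#' Select model factors from a correlation screen
#'
#' Keeps factors that are significant at `alpha` and whose absolute correlation
#' with Pn reaches `r_threshold`, ordered by decreasing |r| with stable
#' tie-breaking by input order.
#'
#' @param results A tibble as returned by [correlation_screen()] (or any tibble
#'   with `factor`, `r`, `p_value` columns).
#' @param r_threshold Minimum |r| to retain a factor.
#' @param alpha Significance level (default 0.01).
#' @return Character vector of factor names, strongest first.
#' @export
select_factors <- function(results, r_threshold, alpha = 0.01) {
  if (nrow(results) == 0) abort("`results` must be non-empty.")
  keep <- !is.na(results$r) & results$p_value < alpha &
    abs(results$r) >= r_threshold
  kept <- results[keep, ]
  kept$factor[order(-abs(kept$r))]   # order() is stable: ties keep input order
}

#' Seeded train/validation split
#'
#' Draws a uniform random permutation of `1:n` from a seeded generator; the
#' first `round(fraction * n)` indices form the training set, the rest the
#' validation set.
#'
#' @param n Number of records; must be >= 5.
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return An object of class `split_indices`: list with integer vectors
#'   `train` and `validation` plus the `seed`.
#' @export
#' @examples
#' s <- train_val_split(936, seed = 1)
#' c(length(s$train), length(s$validation))
train_val_split <- function(n, fraction = 0.8, seed = 1L) {
  if (n < 5) abort("`n` must be >= 5.", class = "psobp_domain_error")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(fraction * n)
  structure(list(train = perm[seq_len(n_train)],
                 validation = perm[setdiff(seq_len(n), seq_len(n_train))],
                 seed = as.integer(seed)),
            class = "split_indices")
}
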