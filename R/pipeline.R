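## End-to-end orchestration: dataset -> normalization (train split only) ->
## PSO over flattened weights -> LM/GD fine-tuning -> denormalized predictions
## -> metric tables; plus the BP vs PSO-BP comparison and the auxiliary
## fluorescence-parameter (ETR, NPQ) models.

#' Regression accuracy metrics
#'
#' Mean squared error, mean absolute error, mean relative error and the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot` (SS_tot about the
#' mean of `y_true`). For the relative error, entries with
#' `|y_true| < 1e-9` are excluded and counted.
#'
#' @param y_true,y_pred Aligned numeric vectors, non-empty.
#' @return A one-row tibble: `mse`, `rmse`, `mae`, `mre`, `r2`, `n`,
#'   `n_mre_excluded`.
#' @export
#' @examples
#' evaluate_metrics(c(1, 2, 3), c(2, 2, 2))
evaluate_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must be non-empty and aligned.",
          class = "psobp_domain_error")
  }
  resid <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    abort("R^2 undefined: `y_true` is constant.", class = "psobp_domain_error")
  }
  ok <- abs(y_true) >= 1e-9
  mre <- if (any(ok)) mean(abs(resid[ok]) / abs(y_true[ok])) else NA_real_
  mse <- mean(resid^2)
  tibble::tibble(mse = mse, rmse = sqrt(mse), mae = mean(abs(resid)),
                 mre = mre, r2 = 1 - sum(resid^2) / ss_tot,
                 n = length(y_true), n_mre_excluded = sum(!ok))
}

model_input_defaults <- c("tem", "co2", "par")
fluor_targets <- c("qp", "etr", "phips2", "fvpfmp", "npq", "qn")

#' Fit a photosynthetic-rate (or fluorescence-parameter) prediction model
#'
#' The reference pipeline: split the data 80/20, fit \[-1, 1\] normalization on
#' the training split only, optionally run the particle swarm over the
#' flattened (m, L, 1) weight vector to choose initial weights
#' (`method = "psobp"`), fine-tune with the damped least-squares trainer
#' (default) or plain gradient descent, then report denormalized train and
#' validation metrics.
#'
#' @param data A `psobp_dataset` (or data frame with the schema columns).
#' @param target Response column: `"pn"` (default), `"etr"` or `"npq"` (any
#'   fluorescence column is accepted). Rows with `valid_fluor = FALSE` are
#'   dropped when the target is a fluorescence parameter.
#' @param inputs Input feature columns (default Tem, CO2, Par).
#' @param method `"psobp"` (swarm-chosen initial weights, default) or `"bp"`
#'   (seeded random initial weights).
#' @param split_fraction Training fraction (default 0.8).
#' @param split_seed Seed for the train/validation permutation.
#' @param arch A [network_architecture()]; default (length(inputs), 5, 1).
#' @param train_cfg A [train_config()].
#' @param pso_cfg A [pso_config()] (used when `method = "psobp"`).
#' @param init_seed Seed for the random initial weights when `method = "bp"`.
#' @return An object of class `psobp_fit` with elements `method`, `target`,
#'   `inputs`, `arch`, `weights`, `norm_params`, `split`, `train_result`,
#'   `pso_result` (NULL for `"bp"`), `metrics` (tibble with one row per split,
#'   raw-unit metrics plus `mse_norm`/`rmse_norm` on the normalized scale),
#'   `predictions` (tibble `split`, `observed`, `predicted`).
#' @export
run_psobp <- function(data, target = "pn", inputs = model_input_defaults,
                      method = c("psobp", "bp"), split_fraction = 0.8,
                      split_seed = 1L,
                      arch = network_architecture(m = length(inputs)),
                      train_cfg = train_config(),
                      pso_cfg = pso_config(), init_seed = 1L) {
  method <- match.arg(method)
  if (target %in% inputs) {
    abort("`target` must not be among `inputs`.", class = "psobp_config_error")
  }
  need <- c(inputs, target)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "psobp_schema_error")
  }
  if (target %in% fluor_targets && "valid_fluor" %in% names(data)) {
    data <- data[data$valid_fluor, ]
    if (nrow(data) == 0) {
      abort(paste0("No valid fluorescence records for target '", target, "'."),
            class = "psobp_domain_error")
    }
  }
  data <- data[stats::complete.cases(data[, need]), ]

  split <- train_val_split(nrow(data), fraction = split_fraction,
                           seed = split_seed)
  train_df <- data[split$train, need]
  val_df <- data[split$validation, need]

  # normalization fitted on the training split only (no leakage)
  norm_params <- fit_normalization(train_df, need)
  tr_n <- normalize(train_df, norm_params)
  va_n <- normalize(val_df, norm_params)
  Xtr <- as.matrix(tr_n[, inputs]); Ttr <- as.matrix(tr_n[, target])
  Xva <- as.matrix(va_n[, inputs])

  pso_res <- NULL
  if (method == "psobp") {
    fitness <- make_mse_fitness(arch, Xtr, Ttr)
    pso_res <- pso_optimize(n_params(arch), pso_cfg, fitness)
    w0 <- unflatten_weights(pso_res$position, arch)
  } else {
    w0 <- init_weights(arch, seed = init_seed)
  }
  fit <- nn_train(w0, Xtr, Ttr, train_cfg)

  predict_raw <- function(Xn) {
    yn <- as.vector(nn_forward(fit$weights, Xn))
    denormalize(yn, norm_params, feature = target)
  }
  pred_tr <- predict_raw(Xtr)
  pred_va <- predict_raw(Xva)
  obs_tr <- train_df[[target]]
  obs_va <- val_df[[target]]

  metric_row <- function(split_name, obs, pred, Xn) {
    m <- evaluate_metrics(obs, pred)
    yn <- as.vector(nn_forward(fit$weights, Xn))
    tn <- normalize(obs, norm_params, feature = target)
    m$mse_norm <- mean((yn - tn)^2)
    m$rmse_norm <- sqrt(m$mse_norm)
    dplyr::bind_cols(tibble::tibble(split = split_name), m)
  }
  metrics <- dplyr::bind_rows(metric_row("train", obs_tr, pred_tr, Xtr),
                              metric_row("validation", obs_va, pred_va, Xva))

  structure(list(
    method = method, target = target, inputs = inputs, arch = arch,
    weights = fit$weights, norm_params = norm_params, split = split,
    train_result = fit, pso_result = pso_res, metrics = metrics,
    predictions = tibble::tibble(
      split = rep(c("train", "validation"), c(length(obs_tr), length(obs_va))),
      observed = c(obs_tr, obs_va),
      predicted = c(pred_tr, pred_va)),
    seeds = list(split = split_seed,
                 pso = if (method == "psobp") pso_cfg$seed else NULL,
                 init = if (method == "bp") init_seed else NULL)
  ), class = "psobp_fit")
}

#' Predict from a fitted model
#'
#' @param object A `psobp_fit`.
#' @param newdata Data frame containing the model's input columns (raw units).
#' @param ... Unused.
#' @return Numeric vector of predictions in the target's raw units.
#' @export
predict.psobp_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$inputs, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("`newdata` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "psobp_schema_error")
  }
  Xn <- as.matrix(normalize(newdata[, object$inputs, drop = FALSE],
                            object$norm_params))
  yn <- as.vector(nn_forward(object$weights, Xn))
  denormalize(yn, object$norm_params, feature = object$target)
}

#' @export
print.psobp_fit <- function(x, ...) {
  cat("<psobp_fit> ", toupper(x$method), " model: ", x$target, " ~ ",
      paste(x$inputs, collapse = " + "), "\n", sep = "")
  cat("  architecture: ", x$arch$m, "-", x$arch$L, "-", x$arch$n_out,
      " (", x$arch$hidden_activation, " hidden)\n", sep = "")
  cat("  epochs used: ", x$train_result$epochs_used,
      if (x$train_result$converged) " (goal reached)" else "", "\n", sep = "")
  print(as.data.frame(x$metrics[, c("split", "rmse", "mae", "mre", "r2")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

## epochs to reach the MSE goal from a training trace (Inf if never reached)
epochs_to_goal <- function(train_result, goal) {
  hit <- which(train_result$trace$mse <= goal)
  if (length(hit) == 0) Inf else hit[1]
}

#' Compare plain BP against PSO-BP across seeds
#'
#' Runs both methods with matched total evaluation budgets per seed: every PSO
#' fitness evaluation is one full-batch forward pass, so the plain-BP arm's
#' epoch budget is inflated by `iters x population` equivalent epochs. Both
#' arms train to their error floor (the goal stop is disabled) and
#' epochs-to-goal is then read off the training trace at the reference error
#' level `goal_level` — by default 3e-3 normalized MSE, the order of the
#' expected error level at which hybrid-vs-plain convergence comparisons are
#' conventionally reported. Reports per-seed metrics, median summaries, and a
#' per-metric verdict (which method is better in the median).
#'
#' @param data A `psobp_dataset`.
#' @param seeds Integer vector of at least 3 seeds; each seed drives the split,
#'   swarm and initial weights of its run.
#' @param methods Length-2 character vector of the two arms (default
#'   `c("bp", "psobp")`).
#' @param goal_level Reference normalized-MSE level for the epochs-to-goal
#'   reading (training itself is not stopped at this level).
#' @param target,inputs,arch,train_cfg,pso_cfg As in [run_psobp()].
#' @return An object of class `psobp_comparison`: list with `per_seed` (tibble)
#'   `summary` (median by method) and `verdict` (per-metric better method).
#' @export
compare_methods <- function(data, seeds, methods = c("bp", "psobp"),
                            goal_level = 3e-3,
                            target = "pn", inputs = model_input_defaults,
                            arch = network_architecture(m = length(inputs)),
                            train_cfg = train_config(),
                            pso_cfg = pso_config()) {
  if (length(seeds) < 3) {
    abort("`seeds` must contain at least 3 seeds.", class = "psobp_config_error")
  }
  stopifnot(length(methods) == 2, all(methods %in% c("bp", "psobp")))
  budget_extra <- pso_cfg$max_iters * pso_cfg$population
  runs <- purrr::map_dfr(seeds, function(s) {
    purrr::map_dfr(methods, function(m) {
      tc <- train_cfg
      tc$goal <- 1e-12    # train to the floor; goal_level is read off the trace
      if (m == "bp") {
        # charge the swarm's evaluations to the plain-BP arm
        tc$max_epochs <- as.integer(min(tc$max_epochs + budget_extra, 1e6))
      }
      pc <- pso_cfg; pc$seed <- as.integer(s)
      fit <- run_psobp(data, target = target, inputs = inputs, method = m,
                       split_seed = s, arch = arch, train_cfg = tc,
                       pso_cfg = pc, init_seed = s)
      val <- fit$metrics[fit$metrics$split == "validation", ]
      tibble::tibble(
        seed = s, method = m,
        epochs_to_goal = epochs_to_goal(fit$train_result, goal_level),
        epochs_used = fit$train_result$epochs_used,
        final_train_mse_norm =
          fit$metrics$mse_norm[fit$metrics$split == "train"],
        val_mse = val$mse, val_rmse = val$rmse, val_mae = val$mae,
        val_mre = val$mre, val_r2 = val$r2)
    })
  })
  summary <- runs |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(
      c("epochs_to_goal", "final_train_mse_norm", "val_mse", "val_rmse",
        "val_mae", "val_r2"),
      stats::median), .groups = "drop")
  verdict_for <- function(metric, lower_better = TRUE) {
    v <- summary[[metric]]
    better <- if (lower_better) which.min(v) else which.max(v)
    summary$method[better]
  }
  verdict <- tibble::tibble(
    metric = c("epochs_to_goal", "final_train_mse_norm", "val_mse", "val_r2"),
    better = c(verdict_for("epochs_to_goal"),
               verdict_for("final_train_mse_norm"),
               verdict_for("val_mse"),
               verdict_for("val_r2", lower_better = FALSE)))
  structure(list(per_seed = runs, summary = summary, verdict = verdict),
            class = "psobp_comparison")
}

#' @export
print.psobp_comparison <- function(x, ...) {
  cat("<psobp_comparison> over", length(unique(x$per_seed$seed)), "seeds\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  cat("verdict (median):\n")
  print(as.data.frame(x$verdict), row.names = FALSE)
  invisible(x)
}

#' Fit the Pn, ETR and NPQ prediction models
#'
#' Three PSO-BP models sharing the environmental inputs (Tem, CO2, Par) with
#' the net photosynthetic rate and the two core fluorescence parameters as
#' targets — the auxiliary-verification battery. Model1 predicts Pn, Model2
#' ETR, Model3 NPQ.
#'
#' @param data A `psobp_dataset` with valid fluorescence columns.
#' @param targets Response columns (default `c("pn", "etr", "npq")`).
#' @param seed Seed bundle driving split, swarm and training for every model.
#' @param inputs,train_cfg,pso_cfg As in [run_psobp()].
#' @return A list of class `psobp_fluor_models`: `report` (tibble `model`,
#'   `target`, `split`, `r2`, `rmse`, `rmse_norm`) and `fits` (named list of
#'   `psobp_fit`).
#' @export
fit_fluorescence_models <- function(data, targets = c("pn", "etr", "npq"),
                                    seed = 1L,
                                    inputs = model_input_defaults,
                                    train_cfg = train_config(),
                                    pso_cfg = pso_config()) {
  for (tg in intersect(targets, fluor_targets)) {
    if (!any(data$valid_fluor) || all(is.na(data[[tg]][data$valid_fluor]))) {
      abort(paste0("No valid fluorescence observations in column '", tg, "'."),
            class = "psobp_domain_error")
    }
  }
  pc <- pso_cfg; pc$seed <- as.integer(seed)
  fits <- purrr::map(targets, function(tg) {
    run_psobp(data, target = tg, inputs = inputs, method = "psobp",
              split_seed = seed, train_cfg = train_cfg, pso_cfg = pc)
  })
  names(fits) <- targets
  report <- purrr::imap_dfr(fits, function(fit, tg) {
    idx <- match(tg, targets)
    dplyr::bind_cols(
      tibble::tibble(model = paste0("Model", idx), target = tg,
                     split = fit$metrics$split),
      fit$metrics[, c("r2", "rmse", "rmse_norm")])
  })
  structure(list(report = report, fits = fits), class = "psobp_fluor_models")
}

#' @export
print.psobp_fluor_models <- function(x, ...) {
  cat("<psobp_fluor_models>\n")
  print(as.data.frame(x$report), row.names = FALSE, digits = 4)
  invisible(x)
}
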