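#' Fit a regression forest with dual variable importance
#'
#' Wraps a `randomForest` regression fit (100 trees by default) and returns
#' it with both importance metrics: increase in node purity (the decrease in
#' residual sum of squares from splits on the variable) and percent increase
#' in MSE under out-of-bag permutation of the variable's values. Rows with a
#' missing predictor are dropped (complete-case) and counted; missing
#' responses are not allowed.
#'
#' @param X Data frame of predictors.
#' @param y Numeric response, same length as `nrow(X)`, no missing values.
#' @param n_trees Number of regression trees (default 100).
#' @param seed Integer seed; the fit is reproducible given it.
#' @param n_perm Permutation repeats per tree for the %IncMSE metric
#'   (default 5).
#' @return A list of class `"forest_fit"`: `forest` (the randomForest
#'   object), `response`, `predictors`, `n_trees`, `n_used`, `n_dropped`,
#'   `oob_mse` (final out-of-bag MSE), `oob_mse_by_ntree` (running OOB MSE
#'   as trees are added), `pct_var_explained` (OOB pseudo-R2, percent),
#'   `importance` (data frame `predictor`, `inc_node_purity`, `pct_inc_mse`,
#'   `rank_node_purity`, `rank_pct_inc_mse`), `seed`.
#' @export
fit_forest <- function(X, y, n_trees = 100L, seed = 1L, n_perm = 5L) {
  stopifnot(is.data.frame(X), n_trees >= 1)
  if (any(is.na(y))) stop("response contains missing values")
  if (length(y) != nrow(X)) stop("X and y sizes differ")
  cc <- stats::complete.cases(X)
  n_dropped <- sum(!cc)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  if (nrow(X) < 10) stop("fewer than 10 complete rows: refusing to fit")
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   importance = TRUE, nPerm = n_perm,
                                   keep.inbag = TRUE)
  imp <- randomForest::importance(rf)
  tab <- data.frame(predictor = rownames(imp),
                    inc_node_purity = unname(imp[, "IncNodePurity"]),
                    pct_inc_mse = unname(imp[, "%IncMSE"]),
                    stringsAsFactors = FALSE)
  tab$rank_node_purity <- rank(-tab$inc_node_purity, ties.method = "first")
  tab$rank_pct_inc_mse <- rank(-tab$pct_inc_mse, ties.method = "first")
  out <- list(forest = rf,
              response = deparse(substitute(y)),
              predictors = colnames(X),
              n_trees = n_trees, n_used = nrow(X), n_dropped = n_dropped,
              oob_mse = rf$mse[n_trees],
              oob_mse_by_ntree = rf$mse,
              # constant response: no variance to explain
              pct_var_explained = if (is.finite(rf$rsq[n_trees]))
                100 * rf$rsq[n_trees] else 0,
              importance = tab, seed = seed)
  class(out) <- "forest_fit"
  out
}

#' @export
print.forest_fit <- function(x, ...) {
  cat("Regression forest:", x$n_trees, "trees,", length(x$predictors),
      "predictors,", x$n_used, "rows\n")
  cat(sprintf("  OOB MSE %.4g, %% variance explained %.1f\n",
              x$oob_mse, x$pct_var_explained))
  top <- x$importance[order(x$importance$rank_node_purity), ]
  cat("  top predictors (node purity):",
      paste(utils::head(top$predictor, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a fitted forest
#'
#' @param object A `forest_fit`.
#' @param newdata Data frame with the model's predictor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.forest_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols) > 0)
    stop("missing predictor(s): ", paste(missing_cols, collapse = ", "))
  unname(stats::predict(object$forest,
                        newdata[, object$predictors, drop = FALSE]))
}

# Mean permutation importance over nfor seeded forests; returns a named
# vector over colnames(X).
mean_perm_importance <- function(X, y, n_trees, nfor, seed) {
  imps <- sapply(seq_len(nfor), function(i) {
    fit <- fit_forest(X, y, n_trees = n_trees, seed = seed + i)
    stats::setNames(fit$importance$pct_inc_mse, fit$importance$predictor)
  })
  rowMeans(matrix(imps, nrow = ncol(X),
                  dimnames = list(colnames(X), NULL)))
}

#' Noise-thresholded forward variable selection
#'
#' Two-stage selection in the spirit of permutation-importance forward
#' strategies. Stage 1 (screening): permutation importance is averaged over
#' several seeded forests fitted to the candidates plus an equal number of
#' shuffled-copy noise variables; candidates whose mean importance does not
#' exceed the maximum importance attained by any noise variable are
#' discarded. Stage 2 (forward addition): surviving candidates are added in
#' rank order, and one is kept only when the mean decrease in out-of-bag
#' error it brings exceeds a noise threshold — the mean plus
#' `threshold_mult` standard deviations of the absolute OOB-error changes
#' observed when appending permuted-copy noise variables to the current
#' model.
#'
#' @param X Data frame of candidate predictors (>= 2 columns).
#' @param y Numeric response.
#' @param n_trees Trees per forest during selection (default 50; the final
#'   model is refitted at full size separately).
#' @param nfor Forests averaged per importance/OOB estimate (default 3).
#' @param n_noise Number of permuted-copy noise variables used to estimate
#'   the forward threshold (default 5).
#' @param threshold_mult Multiplier on the noise-change standard deviation
#'   (default 2).
#' @param seed Integer seed.
#' @return A list of class `"selection_result"`: `candidates` (screened,
#'   in rank order), `selected`, `step_decreases` (named OOB-error decrease
#'   for each accepted variable), `threshold`, `screening` (data frame of
#'   mean importances incl. noise variables), `diagnostics`.
#' @export
select_variables <- function(X, y, n_trees = 50L, nfor = 3L, n_noise = 5L,
                             threshold_mult = 2, seed = 1L) {
  if (ncol(X) < 1) stop("need at least 1 candidate predictor")
  cc <- stats::complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  set.seed(seed)

  # stage 1: screening against shuffled-copy noise variables
  Xn <- X
  noise_names <- paste0(".noise_", colnames(X))
  for (j in seq_len(ncol(X)))
    Xn[[noise_names[j]]] <- sample(X[[j]])
  imp <- mean_perm_importance(Xn, y, n_trees, nfor, seed)
  noise_max <- max(imp[noise_names])
  cand_imp <- sort(imp[colnames(X)], decreasing = TRUE)
  kept <- names(cand_imp)[cand_imp > noise_max]
  screening <- data.frame(variable = names(imp),
                          mean_importance = unname(imp),
                          is_noise = names(imp) %in% noise_names,
                          stringsAsFactors = FALSE)
  out <- list(candidates = kept, selected = character(0),
              step_decreases = numeric(0), threshold = NA_real_,
              screening = screening,
              diagnostics = list(noise_max_importance = noise_max,
                                 n_screened_out = ncol(X) - length(kept)))
  class(out) <- "selection_result"
  if (length(kept) == 0) return(out)

  mean_oob <- function(cols, extra = NULL) {
    Xi <- X[, cols, drop = FALSE]
    if (!is.null(extra)) Xi <- cbind(Xi, extra)
    mean(vapply(seq_len(nfor), function(i)
      fit_forest(Xi, y, n_trees = n_trees, seed = seed + 100 + i)$oob_mse,
      numeric(1)))
  }

  # noise threshold: OOB-error variation caused by appending permuted-copy
  # noise variables to the screened-candidate model (the stablest model
  # available at this point)
  base_oob <- mean_oob(kept)
  noise_changes <- vapply(seq_len(n_noise), function(i) {
    extra <- data.frame(.noisecol = sample(X[[sample(ncol(X), 1)]]))
    abs(mean_oob(kept, extra) - base_oob)
  }, numeric(1))
  threshold <- mean(noise_changes) + threshold_mult * stats::sd(noise_changes)
  out$threshold <- threshold

  # forward addition, starting from the null model (mean prediction)
  current_oob <- mean((y - mean(y))^2)
  for (v in kept) {
    trial_oob <- mean_oob(c(out$selected, v))
    dec <- current_oob - trial_oob
    if (dec > threshold) {
      out$selected <- c(out$selected, v)
      out$step_decreases[v] <- dec
      current_oob <- trial_oob
    }
  }
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Forward variable selection\n")
  cat("  screened candidates:", length(x$candidates),
      " selected:", length(x$selected), "\n")
  if (length(x$selected) > 0)
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat("  forward threshold:", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Repeated random-holdout cross-validation of a forest model
#'
#' The protocol runs 99 iterations by default, each withholding a random
#' 10% of the training data, refitting the forest on the remainder and
#' scoring the held-out rows. Reported per iteration: held-out MSE and R2
#' (1 - MSE / variance of held-out responses).
#'
#' @param X Data frame of predictors.
#' @param y Numeric response.
#' @param n_trees Trees per refit (default 100).
#' @param iterations Number of iterations (default 99).
#' @param holdout_fraction Fraction withheld each iteration (default 0.10).
#' @param seed Integer seed.
#' @return A list of class `"cv_result"`: `iterations`, `holdout_fraction`,
#'   `per_iteration` (data frame `iteration`, `mse`, `r_squared`),
#'   `mean_mse`, `sd_mse`, `mean_r_squared`, `sd_r_squared`, `seed`.
#' @export
kfold_cv <- function(X, y, n_trees = 100L, iterations = 99L,
                     holdout_fraction = 0.10, seed = 1L) {
  stopifnot(iterations >= 1, holdout_fraction > 0, holdout_fraction < 1)
  cc <- stats::complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  n <- nrow(X)
  n_hold <- round(n * holdout_fraction)
  if (n_hold < 2) stop("holdout smaller than 2 rows: refusing")
  set.seed(seed)
  res <- data.frame(iteration = seq_len(iterations), mse = NA_real_,
                    r_squared = NA_real_)
  for (i in seq_len(iterations)) {
    hold <- sample(n, n_hold)
    rf <- randomForest::randomForest(x = X[-hold, , drop = FALSE],
                                     y = y[-hold], ntree = n_trees)
    pred <- stats::predict(rf, X[hold, , drop = FALSE])
    res$mse[i] <- mean((y[hold] - pred)^2)
    vy <- mean((y[hold] - mean(y[hold]))^2)
    res$r_squared[i] <- if (vy > 0) 1 - res$mse[i] / vy else
      as.numeric(res$mse[i] == 0)
  }
  out <- list(iterations = iterations, holdout_fraction = holdout_fraction,
              per_iteration = res,
              mean_mse = mean(res$mse), sd_mse = stats::sd(res$mse),
              mean_r_squared = mean(res$r_squared),
              sd_r_squared = stats::sd(res$r_squared), seed = seed)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %d iterations, %.0f%% holdout\n",
              x$iterations, 100 * x$holdout_fraction))
  cat(sprintf("  held-out MSE %.4g (sd %.3g), R2 %.3f (sd %.3f)\n",
              x$mean_mse, x$sd_mse, x$mean_r_squared, x$sd_r_squared))
  invisible(x)
}

#' Partial dependence of the forest response on one predictor
#'
#' The marginal effect of a variable on the response: for each grid value,
#' the predictor is clamped to that value in every training row (all other
#' columns kept at their observed values) and the predictions are averaged.
#' Grid points outside the training range are computed but flagged as
#' extrapolation.
#'
#' @param fit A `forest_fit`.
#' @param predictor Name of a predictor in the fitted model.
#' @param grid Numeric vector of values (length >= 2), or a single integer
#'   `m` to use `m` equally spaced points across the training range.
#' @param X Training predictor table used for the marginalization (the rows
#'   the forest was fitted to).
#' @return Data frame of class `"partial_effect"`: `value`, `effect`,
#'   `extrapolated`.
#' @export
partial_effect <- function(fit, predictor, grid, X) {
  if (!(predictor %in% fit$predictors))
    stop("predictor '", predictor, "' not in the fitted model")
  X <- X[stats::complete.cases(X[fit$predictors]), fit$predictors,
         drop = FALSE]
  rng <- range(X[[predictor]])
  if (length(grid) == 1 && grid >= 2) {
    grid <- seq(rng[1], rng[2], length.out = grid)
  }
  if (length(grid) < 2) stop("need at least 2 grid values")
  eff <- vapply(grid, function(v) {
    Xi <- X
    Xi[[predictor]] <- v
    mean(stats::predict(fit$forest, Xi))
  }, numeric(1))
  out <- data.frame(value = grid, effect = eff,
                    extrapolated = grid < rng[1] | grid > rng[2])
  class(out) <- c("partial_effect", "data.frame")
  out
}
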