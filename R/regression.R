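# Index regression: maps the five window features to a 0-100 index. The
# primary model is a squared-exponential Gaussian process fitted by marginal
# likelihood; robust linear, regression tree and radial SVM comparators are
# provided for benchmarking.

#' Assemble a training set from features and annotations
#'
#' Joins a per-second feature table with the annotation stream, drops seconds
#' whose reference is invalid (sentinel or SQI < 15) or whose features are
#' degenerate, and returns the modelling table.
#'
#' @param features Tibble from [extract_feature_table()].
#' @param annotations Annotation tibble (columns `t_s`, `bis`, `sqi`, `emg`).
#' @param subject_id Label attached to every row.
#' @return Tibble with columns `subject_id`, `t_s`, the five features, `bis`.
#' @export
build_training_set <- function(features, annotations, subject_id = "S1") {
  ann <- dplyr::mutate(annotations, .valid_ref = valid_bis_mask(annotations))
  out <- dplyr::inner_join(features, ann, by = "t_s")
  out <- dplyr::filter(out, !.data$degenerate, .data$.valid_ref)
  dplyr::transmute(out, subject_id = subject_id, t_s = .data$t_s,
                   se = .data$se, fe = .data$fe, pe = .data$pe,
                   hurst_rr = .data$hurst_rr, psd_fea = .data$psd_fea,
                   bis = .data$bis)
}

NDOA_FEATURES <- c("se", "fe", "pe", "hurst_rr", "psd_fea")

.feature_matrix <- function(data) {
  miss <- setdiff(NDOA_FEATURES, names(data))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  as.matrix(data[NDOA_FEATURES])
}

# ---- squared-exponential GP core -------------------------------------------

.sqexp_kernel <- function(X1, X2, ell, sf2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  sf2 * exp(-0.5 * pmax(d2, 0) / ell^2)
}

# Negative log marginal likelihood of (log ell, log sf, log sn).
.gp_nlml <- function(theta, X, y, d2) {
  ell <- exp(theta[1]); sf2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
  n <- nrow(X)
  K <- sf2 * exp(-0.5 * d2 / ell^2) + diag(sn2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

# Analytic gradient of .gp_nlml in (log ell, log sf, log sn).
.gp_nlml_grad <- function(theta, X, y, d2) {
  ell <- exp(theta[1]); sf2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
  n <- nrow(X)
  K0 <- sf2 * exp(-0.5 * d2 / ell^2)
  K <- K0 + diag(sn2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(c(0, 0, 0))
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  Kinv <- chol2inv(ch)
  W <- Kinv - tcrossprod(alpha)  # d nlml/dK = 0.5 * W
  g_ell <- 0.5 * sum(W * (K0 * d2 / ell^2))
  g_sf <- 0.5 * sum(W * (2 * K0))
  g_sn <- 0.5 * sum(diag(W)) * 2 * sn2
  c(g_ell, g_sf, g_sn)
}

.gp_fit <- function(X, y, seed, subset_cap = 2000L, ell0 = NULL) {
  n <- nrow(X)
  idx <- seq_len(n)
  if (n > subset_cap) {
    old <- .Random.seed_save()
    set.seed(as.integer(seed %% .Machine$integer.max))
    idx <- sort(sample.int(n, subset_cap))
    .Random.seed_restore(old)
  }
  Xs <- X[idx, , drop = FALSE]
  ys <- y[idx]
  ybar <- mean(ys)
  yc <- ys - ybar
  sy <- stats::sd(ys)
  if (!is.finite(sy) || sy == 0) sy <- 1
  d2 <- outer(rowSums(Xs^2), rowSums(Xs^2), `+`) - 2 * tcrossprod(Xs)
  d2 <- pmax(d2, 0)
  base_ell <- ell0 %||% sqrt(ncol(X))
  # deterministic multi-start: broad/short length-scales, low/moderate noise
  starts <- list(
    c(log(base_ell), log(sy), log(max(sy / 10, 1e-3))),
    c(log(base_ell / 4), log(sy), log(max(sy / 100, 1e-4))),
    c(log(base_ell * 4), log(sy), log(max(sy / 3, 1e-3)))
  )
  best <- NULL
  for (th0 in starts) {
    opt <- stats::optim(th0, .gp_nlml, gr = .gp_nlml_grad, X = Xs, y = yc,
                        d2 = d2, method = "L-BFGS-B",
                        lower = c(-6, -6, -12), upper = c(8, 12, 10),
                        control = list(maxit = 200))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  opt <- best
  ell <- exp(opt$par[1]); sf2 <- exp(2 * opt$par[2]); sn2 <- exp(2 * opt$par[3])
  K <- .sqexp_kernel(Xs, Xs, ell, sf2) + diag(sn2 + 1e-8, nrow(Xs))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(X = Xs, alpha = alpha, ybar = ybar, ell = ell, sf2 = sf2, sn2 = sn2,
       nlml = opt$value, subset = idx)
}

.gp_predict <- function(gp, X) {
  Ks <- .sqexp_kernel(X, gp$X, gp$ell, gp$sf2)
  drop(Ks %*% gp$alpha) + gp$ybar
}

# ---- model menu -------------------------------------------------------------

#' Fit an index model
#'
#' Standardizes the five features (z-score on the training statistics, stored
#' with the model) and fits the requested regressor:
#' * `"sq_exp_gp"` (default): squared-exponential Gaussian process, kernel
#'   hyperparameters (length-scale, signal and noise standard deviations) set
#'   by Nelder-Mead optimization of the marginal likelihood from a fixed
#'   start; training sets beyond `subset_cap` rows are subsampled (seeded)
#'   before the O(n^3) solve.
#' * `"linear_robust"`: M-estimator linear regression ([MASS::rlm()]).
#' * `"tree"`: regression tree ([rpart::rpart()]).
#' * `"svm_rbf"`: radial-kernel support vector regression ([e1071::svm()]).
#'
#' Predictions from any kind are clamped to `[0, 100]`.
#'
#' @param data Training tibble from [build_training_set()] (needs the five
#'   feature columns and `bis`).
#' @param kind Model kind.
#' @param seed Integer seed (subsampling and any library internals).
#' @param subset_cap GP subset-of-data cap (rows).
#' @param denoise,features The pre-processing configurations to freeze into
#'   the model so streaming uses the identical pipeline.
#' @return An object of class `ndoa_model`.
#' @export
ndoa_fit <- function(data, kind = c("sq_exp_gp", "linear_robust", "tree", "svm_rbf"),
                     seed = 1, subset_cap = 2000L,
                     denoise = denoise_config(), features = feature_config()) {
  kind <- match.arg(kind)
  X <- .feature_matrix(data)
  y <- data$bis
  if (nrow(X) < 20) stop("need >= 20 training rows", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("training data contains NA", call. = FALSE)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) {
    stop("degenerate (zero-variance) feature column: ",
         paste(NDOA_FEATURES[sdev == 0], collapse = ", "), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  if (stats::sd(y) == 0) {
    # constant target: every regressor reduces to the constant predictor
    return(structure(
      list(kind = kind, fit = list(constant = y[1]), center = mu, scale = sdev,
           seed = seed, n_train = nrow(X), denoise = denoise,
           features = features),
      class = "ndoa_model"
    ))
  }
  fit <- switch(
    kind,
    sq_exp_gp = .gp_fit(Z, y, seed = seed, subset_cap = subset_cap),
    linear_robust = MASS::rlm(y ~ ., data = data.frame(Z, y = y), maxit = 50),
    tree = rpart::rpart(y ~ ., data = data.frame(Z, y = y),
                        method = "anova",
                        control = rpart::rpart.control(cp = 0.001, minsplit = 10)),
    svm_rbf = {
      old <- .Random.seed_save()
      set.seed(as.integer(seed %% .Machine$integer.max))
      # features are already standardized; scale y explicitly so a constant
      # target does not break the library's internal scaling
      yc <- mean(y)
      ys <- stats::sd(y)
      if (!is.finite(ys) || ys == 0) ys <- 1
      m <- e1071::svm(Z, (y - yc) / ys, type = "eps-regression",
                      kernel = "radial", scale = FALSE)
      .Random.seed_restore(old)
      list(svm = m, y_center = yc, y_scale = ys)
    }
  )
  structure(
    list(kind = kind, fit = fit, center = mu, scale = sdev, seed = seed,
         n_train = nrow(X), denoise = denoise, features = features),
    class = "ndoa_model"
  )
}

#' Predict the index for new feature rows
#'
#' Applies the stored standardization and the fitted regressor; predictions
#' are clamped to `[0, 100]`. Rows with any missing feature yield `NA` rather
#' than an error.
#'
#' @param object An `ndoa_model`.
#' @param newdata Tibble or matrix with the five feature columns (may be
#'   empty).
#' @param ... Unused.
#' @return Numeric vector of index values (with `NA` for invalid rows).
#' @export
predict.ndoa_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else .feature_matrix(newdata)
  if (nrow(X) == 0) return(numeric(0))
  out <- rep(NA_real_, nrow(X))
  ok <- stats::complete.cases(X) & apply(is.finite(X), 1, all)
  if (!any(ok)) return(out)
  Z <- sweep(sweep(X[ok, , drop = FALSE], 2, object$center), 2, object$scale, "/")
  if (!is.null(object$fit$constant)) {
    out[ok] <- clamp01_100(rep(object$fit$constant, sum(ok)))
    return(out)
  }
  raw <- switch(
    object$kind,
    sq_exp_gp = .gp_predict(object$fit, Z),
    linear_robust = as.numeric(stats::predict(object$fit, newdata = data.frame(Z))),
    tree = stats::predict(object$fit, newdata = data.frame(Z)),
    svm_rbf = as.numeric(stats::predict(object$fit$svm, Z)) * object$fit$y_scale +
      object$fit$y_center
  )
  out[ok] <- clamp01_100(raw)
  out
}

#' @export
print.ndoa_model <- function(x, ...) {
  cat("<ndoa_model>", x$kind, "fitted on", x$n_train, "rows\n")
  if (x$kind == "sq_exp_gp") {
    cat(sprintf("  length-scale %.3f, signal sd %.3f, noise sd %.3f\n",
                x$fit$ell, sqrt(x$fit$sf2), sqrt(x$fit$sn2)))
  }
  invisible(x)
}

#' @rdname ndoa_fit
#' @param x An `ndoa_model`.
#' @export
tidy.ndoa_model <- function(x, ...) {
  switch(
    x$kind,
    sq_exp_gp = tibble::tibble(
      term = c("length_scale", "signal_sd", "noise_sd"),
      estimate = c(x$fit$ell, sqrt(x$fit$sf2), sqrt(x$fit$sn2))
    ),
    linear_robust = tibble::tibble(
      term = names(stats::coef(x$fit)),
      estimate = unname(stats::coef(x$fit))
    ),
    tibble::tibble(term = "kind", estimate = NA_real_)
  )
}

#' @rdname ndoa_fit
#' @export
glance.ndoa_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_train = x$n_train,
                 nlml = if (x$kind == "sq_exp_gp") x$fit$nlml else NA_real_)
}

# ---- metrics and cross-validation ------------------------------------------

#' Goodness-of-fit metrics
#'
#' `r2 = 1 - SS_res/SS_tot` (may be negative for a model worse than the mean
#' predictor), `mse`, `rmse = sqrt(mse)`, and `mae`.
#'
#' @param y Observed reference values.
#' @param f Predicted values, same length (>= 2).
#' @return One-row tibble with `r2`, `rmse`, `mse`, `mae`, `n`.
#' @export
compute_metrics <- function(y, f) {
  stopifnot(length(y) == length(f), length(y) >= 2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero-variance reference: R^2 undefined", call. = FALSE)
  mse <- mean((y - f)^2)
  tibble::tibble(
    r2 = 1 - sum((y - f)^2) / sst,
    rmse = sqrt(mse), mse = mse, mae = mean(abs(y - f)), n = length(y)
  )
}

#' K-fold cross-validation of an index model
#'
#' Seeded fold assignment (row-wise by default, or grouped by subject to
#' avoid within-subject leakage); metrics are pooled over all held-out
#' predictions.
#'
#' @inheritParams ndoa_fit
#' @param folds Number of folds (default 5).
#' @param by_subject Assign whole subjects to folds.
#' @return One-row metrics tibble (see [compute_metrics()]) with a `folds`
#'   column.
#' @export
ndoa_crossvalidate <- function(data, kind = "sq_exp_gp", folds = 5, seed = 1,
                               by_subject = FALSE, subset_cap = 2000L) {
  stopifnot(folds >= 2)
  n <- nrow(data)
  old <- .Random.seed_save()
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (by_subject) {
    subj <- unique(data$subject_id)
    f_of_subj <- sample(rep_len(seq_len(folds), length(subj)))
    fold_id <- f_of_subj[match(data$subject_id, subj)]
  } else {
    fold_id <- sample(rep_len(seq_len(folds), n))
  }
  .Random.seed_restore(old)
  pred <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    if (sum(hold) < 1 || sum(!hold) < 2) stop("fold with too few rows", call. = FALSE)
    m <- ndoa_fit(data[!hold, , drop = FALSE], kind = kind, seed = seed,
                  subset_cap = subset_cap)
    pred[hold] <- predict(m, data[hold, , drop = FALSE])
  }
  out <- compute_metrics(data$bis, pred)
  out$folds <- folds
  out
}

#' Save / load a fitted index model
#'
#' Serializes the model (kind, hyperparameters, standardization vectors,
#' GP inducing subset, frozen pre-processing configuration) so that
#' `predict()` after a round-trip matches the original to floating point.
#'
#' @param model An `ndoa_model`.
#' @param path File path.
#' @return `ndoa_save_model()`: `path`, invisibly. `ndoa_load_model()`: the
#'   model.
#' @export
ndoa_save_model <- function(model, path) {
  stopifnot(inherits(model, "ndoa_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname ndoa_save_model
#' @export
ndoa_load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ndoa_model")) stop("not an ndoa model file", call. = FALSE)
  m
}
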