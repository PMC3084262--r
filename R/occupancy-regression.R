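#' Gaussian imputation of missing occupancy entries
#'
#' Each missing entry of a column is filled with an independent draw from
#' `Normal(column mean, column sd)` computed on that column's observed
#' entries; `n_draws` independently filled matrices are returned. Observed
#' entries are identical across draws.
#'
#' @param x regions x factors numeric matrix, NA = missing.
#' @param n_draws number of filled matrices.
#' @param seed integer seed.
#' @return object of class `imputed_matrix`: list with `draws` (list of
#'   matrices), `base`, `n_draws`, `seed`.
#' @export
impute_missing <- function(x, n_draws = 10L, seed = 1L) {
  x <- as.matrix(x)
  obs_n <- colSums(!is.na(x))
  if (any(obs_n < 2L)) {
    stop("unimputable-column: column '",
         colnames(x)[which(obs_n < 2L)[1]],
         "' has fewer than 2 observed values")
  }
  mu <- colMeans(x, na.rm = TRUE)
  sd_ <- apply(x, 2, stats::sd, na.rm = TRUE)
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(d) {
    filled <- x
    for (j in seq_len(ncol(x))) {
      miss <- which(is.na(x[, j]))
      if (length(miss)) {
        filled[miss, j] <- stats::rnorm(length(miss), mu[j], sd_[j])
      }
    }
    filled
  })
  structure(list(draws = draws, base = x, n_draws = as.integer(n_draws),
                 seed = seed),
            class = "imputed_matrix")
}

# OLS with coefficient standard errors via the QR decomposition; X excludes
# the intercept column (added here)
ols_fit <- function(y, X) {
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) {
    cc <- stats::cor(X)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("collinearity: design is singular; most correlated pair: ",
         colnames(X)[worst[1]], " and ", colnames(X)[worst[2]])
  }
  coef <- drop(qr.coef(qr_, y))
  res <- drop(y - Xi %*% coef)
  df <- nrow(Xi) - ncol(Xi)
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(chol(crossprod(Xi)))
  se <- sqrt(s2 * diag(XtX_inv))
  names(se) <- names(coef)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(coef = coef, se = se, r2 = r2, df = df)
}

#' Univariate screen for positively predictive recruiters
#'
#' Each candidate is regressed alone (simple OLS, complete cases) against
#' co-repressor occupancy; a candidate is retained iff its slope is positive
#' and its slope p-value is below `alpha`.
#'
#' @param y co-repressor occupancy vector.
#' @param X regions x candidates matrix (NA allowed; complete cases per
#'   candidate).
#' @param alpha retention threshold on the slope p-value.
#' @param min_pairs minimum complete pairs; candidates with fewer are skipped
#'   with a warning.
#' @return character vector of retained candidates, with a `screen` attribute
#'   (data.frame: factor, slope, p_value, retained).
#' @export
univariate_screen <- function(y, X, alpha = 0.01, min_pairs = 10L) {
  X <- as.matrix(X)
  res <- lapply(colnames(X), function(f) {
    keep <- !is.na(y) & !is.na(X[, f])
    if (sum(keep) < min_pairs) {
      warning("recruiter '", f, "' skipped: only ", sum(keep),
              " complete pairs")
      return(data.frame(factor = f, slope = NA_real_, p_value = NA_real_,
                        retained = FALSE))
    }
    fit <- stats::lm(y[keep] ~ X[keep, f])
    sm <- summary(fit)$coefficients
    slope <- sm[2, 1]; p <- sm[2, 4]
    data.frame(factor = f, slope = slope, p_value = p,
               retained = slope > 0 && p < alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  out <- res$factor[res$retained]
  attr(out, "screen") <- res
  out
}

#' Fit the multi-recruiter occupancy model with repeated random-subsampling
#' cross-validation
#'
#' For each of `n_splits` random half/half partitions of the regions, an
#' ordinary multiple regression of co-repressor occupancy on the recruiter
#' columns is fitted on one half — averaging coefficient estimates (and their
#' standard errors) over the `n_imputations` Gaussian-filled matrices — and
#' its R-squared evaluated on the held-out half. Final parameters are the
#' mean over the split fits; per-parameter p-values come from the averaged
#' coefficient and the mean per-fit standard error.
#'
#' @param y region-id named co-repressor occupancy vector.
#' @param X regions x recruiters matrix (NA allowed; imputed internally).
#' @param recruiters columns of `X` to include (default all).
#' @param n_splits number of random half-genome partitions.
#' @param n_imputations Gaussian imputation draws per split.
#' @param seed integer seed controlling imputation and partitioning.
#' @param alpha significance threshold used to flag non-significant
#'   parameters.
#' @return object of class `occupancy_model`: intercept, weights, param_p,
#'   param_se, r2_train, r2_heldout, included, nonsignificant, n_splits,
#'   n_imputations, seed.
#' @export
fit_with_cv <- function(y, X, recruiters = colnames(X), n_splits = 5L,
                        n_imputations = 10L, seed = 1L, alpha = 0.01) {
  X <- as.matrix(X)[, recruiters, drop = FALSE]
  n <- length(y)
  stopifnot(n == nrow(X), n >= 50L, length(recruiters) >= 1L)
  imp <- impute_missing(X, n_draws = n_imputations, seed = seed)
  set.seed(seed + 1L)
  p <- length(recruiters) + 1L
  coef_splits <- matrix(0, n_splits, p)
  se_splits <- matrix(0, n_splits, p)
  r2_train <- r2_heldout <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    train <- sort(sample.int(n, floor(n / 2)))
    test <- setdiff(seq_len(n), train)
    coefs <- matrix(0, n_imputations, p)
    ses <- matrix(0, n_imputations, p)
    r2t <- r2h <- numeric(n_imputations)
    for (d in seq_len(n_imputations)) {
      Xd <- imp$draws[[d]]
      fit <- ols_fit(y[train], Xd[train, , drop = FALSE])
      coefs[d, ] <- fit$coef
      ses[d, ] <- fit$se
      r2t[d] <- fit$r2
      yhat <- cbind(1, Xd[test, , drop = FALSE]) %*% fit$coef
      r2h[d] <- 1 - sum((y[test] - yhat)^2) /
        sum((y[test] - mean(y[test]))^2)
    }
    coef_splits[s, ] <- colMeans(coefs)
    se_splits[s, ] <- colMeans(ses)
    r2_train[s] <- mean(r2t)
    r2_heldout[s] <- mean(r2h)
  }
  coef_final <- colMeans(coef_splits)
  se_final <- colMeans(se_splits)
  names(coef_final) <- names(se_final) <- c("(Intercept)", recruiters)
  df <- floor(n / 2) - p
  tval <- coef_final / se_final
  param_p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(
    intercept = unname(coef_final[1]),
    weights = coef_final[-1],
    param_se = se_final[-1],
    param_p = param_p[-1],
    r2_train = mean(r2_train),
    r2_heldout = mean(r2_heldout),
    included = recruiters,
    nonsignificant = recruiters[param_p[-1] > alpha],
    n_splits = as.integer(n_splits),
    n_imputations = as.integer(n_imputations),
    seed = seed
  ), class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf(
    "occupancy_model: %d recruiters, R2 train %.3f / held-out %.3f (%d splits x %d imputations)\n",
    length(x$included), x$r2_train, x$r2_heldout, x$n_splits, x$n_imputations))
  tab <- data.frame(weight = c(x$intercept, x$weights),
                    p_value = c(NA, x$param_p),
                    row.names = c("(Intercept)", x$included))
  print(signif(tab, 3))
  invisible(x)
}

#' Drop non-significant recruiters and refit
#'
#' Removes every recruiter whose pooled p-value exceeds `alpha` and refits
#' the model on the reduced set with [fit_with_cv()] (same split/imputation
#' settings and seed).
#'
#' @param model a fitted `occupancy_model`.
#' @param y,X the data the model was fitted on.
#' @param alpha retention threshold.
#' @return the refitted reduced `occupancy_model` (the input model if nothing
#'   is dropped).
#' @export
drop_nonsignificant <- function(model, y, X, alpha = 0.01) {
  keep <- model$included[model$param_p <= alpha]
  if (length(keep) == 0L) stop("empty-model: all recruiters non-significant")
  if (length(keep) == length(model$included)) return(model)
  fit_with_cv(y, X, recruiters = keep, n_splits = model$n_splits,
              n_imputations = model$n_imputations, seed = model$seed,
              alpha = alpha)
}

#' Partial F-test comparison of nested occupancy models
#'
#' Fits both recruiter sets to the same full data (complete cases over the
#' union of columns) and performs the nested-model partial F-test; reports
#' the R-squared gain of the extended model and the test p-value.
#'
#' @param y co-repressor occupancy vector.
#' @param X recruiter matrix.
#' @param base character vector of the base model's recruiters.
#' @param extended character vector of the extended model's recruiters; must
#'   strictly contain `base`.
#' @return list: delta_r2, f_statistic, df1, df2, p_value, r2_base,
#'   r2_extended.
#' @export
compare_models <- function(y, X, base, extended) {
  if (!all(base %in% extended)) {
    stop("non-nested: base recruiters must be a subset of extended")
  }
  X <- as.matrix(X)[, extended, drop = FALSE]
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  fit_b <- ols_fit(y, X[, base, drop = FALSE])
  if (setequal(base, extended)) {
    return(list(delta_r2 = 0, f_statistic = 0,
                df1 = 0L, df2 = fit_b$df, p_value = 1,
                r2_base = fit_b$r2, r2_extended = fit_b$r2))
  }
  fit_e <- ols_fit(y, X)
  df1 <- length(extended) - length(base)
  df2 <- fit_e$df
  rss_b <- (1 - fit_b$r2); rss_e <- (1 - fit_e$r2)
  f <- ((rss_b - rss_e) / df1) / (rss_e / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(delta_r2 = fit_e$r2 - fit_b$r2, f_statistic = f, df1 = df1, df2 = df2,
       p_value = p, r2_base = fit_b$r2, r2_extended = fit_e$r2)
}

#' Predict co-repressor occupancy from recruiter occupancy
#'
#' `y_hat = intercept + sum_r beta_r x_r` per region. All included
#' recruiters must be present; missing entries should be imputed first.
#'
#' @param object a fitted `occupancy_model`.
#' @param newdata regions x recruiters matrix containing all included
#'   recruiter columns.
#' @param ... unused.
#' @return numeric vector of predictions, named by rownames of `newdata`.
#' @export
predict.occupancy_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing_r <- setdiff(object$included, colnames(newdata))
  if (length(missing_r)) {
    stop("missing-recruiter: ", paste(missing_r, collapse = ", "))
  }
  drop(object$intercept +
         newdata[, object$included, drop = FALSE] %*% object$weights)
}

#' Full regression pipeline on an occupancy dataset
#'
#' Convenience wrapper chaining the stages as they are meant to be run:
#' univariate screening of candidates (positive, significant slope), fitting
#' with repeated random-subsampling cross-validation under Gaussian
#' imputation, and removal of recruiters that are non-significant in the
#' multivariate model.
#'
#' @param dataset an `occupancy_dataset` from [generate_dataset()] (or any
#'   list with `occupancy` matrix and `truth$corepressor`).
#' @param candidates candidate recruiter columns (default: all non-response
#'   columns).
#' @param n_splits,n_imputations,seed,alpha passed to the stages.
#' @return list: model (`occupancy_model`), screened (output of
#'   [univariate_screen()]).
#' @export
fit_occupancy_model <- function(dataset, candidates = NULL, n_splits = 5L,
                                n_imputations = 10L, seed = 1L,
                                alpha = 0.01) {
  resp <- dataset$truth$corepressor
  occ <- dataset$occupancy
  if (is.null(candidates)) candidates <- setdiff(colnames(occ), resp)
  y <- occ[, resp]
  X <- occ[, candidates, drop = FALSE]
  screened <- univariate_screen(y, X, alpha = alpha)
  if (length(screened) == 0L) stop("empty-model: no candidate survived the ",
                                   "univariate screen")
  model <- fit_with_cv(y, X, recruiters = screened, n_splits = n_splits,
                       n_imputations = n_imputations, seed = seed,
                       alpha = alpha)
  model <- drop_nonsignificant(model, y, X, alpha = alpha)
  list(model = model, screened = screened)
}
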