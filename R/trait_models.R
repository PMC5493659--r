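# Trait prediction from the index catalog.
#
# With 1,541 candidate predictors and at most a few hundred plants the
# feature space must be reduced; linear stepwise regression (forward entry
# / backward removal on partial-F p-values) selects a small set of
# effective indices per trait. Model quality is judged by k-fold
# cross-validation with the mean and standard deviation of the per-sample
# absolute percentage errors (MAPE, SD_APE) and the held-out R-squared.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

rss_of <- function(X, y) {
  fit <- lm.fit(X, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

#' Stepwise linear regression (forward entry, backward removal)
#'
#' Classic bidirectional stepwise selection on partial-F p-values: at each
#' forward step the candidate with the smallest entry p-value joins the
#' model if it is below `alpha_enter`; after each entry, included
#' variables whose removal p-value exceeds `alpha_remove` are dropped
#' (largest first). Iteration stops when neither step changes the model.
#' Ties in p-value are broken by the lexicographically smallest feature
#' name, which makes the procedure deterministic and independent of
#' column order. Candidates whose addition would make the design
#' rank-deficient are skipped.
#'
#' @param X feature matrix or data.frame (named columns).
#' @param y numeric response.
#' @param alpha_enter entry significance level (default 0.05).
#' @param alpha_remove removal significance level (default 0.10).
#' @param max_steps safety cap on the number of entry steps.
#' @return object of class `stepwise_model`: selected feature names,
#'   coefficients (with intercept), training R-squared, n.
#' @export
stepwise_lsr <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.10,
                         max_steps = 100L) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X and y sizes differ")
  if (n < 4L) stop("too few samples for stepwise regression (need n >= 4)")
  keep <- apply(X, 2, function(v) sd(v) > 0)
  candidates <- colnames(X)[keep]
  selected <- character(0)
  tss0 <- sum((y - mean(y))^2)
  rss_tol <- 1e-10 * max(tss0, .Machine$double.eps)
  design <- function(feats) cbind(`(Intercept)` = 1, X[, feats, drop = FALSE])
  entry_p <- function(feat) {
    p0 <- length(selected)
    df2 <- n - p0 - 2L
    if (df2 <= 0L) return(NA_real_)
    base <- rss_of(design(selected), y)
    if (base$rss <= rss_tol) return(NA_real_)  # already an exact fit
    fit1 <- rss_of(design(c(selected, feat)), y)
    if (fit1$rank < p0 + 2L) return(NA_real_)  # collinear: blocked
    f <- (base$rss - fit1$rss) / (max(fit1$rss, rss_tol) / df2)
    pf(f, 1, df2, lower.tail = FALSE)
  }
  removal_p <- function(feat) {
    p1 <- length(selected)
    df2 <- n - p1 - 1L
    if (df2 <= 0L) return(0)
    full <- rss_of(design(selected), y)
    red <- rss_of(design(setdiff(selected, feat)), y)
    if (red$rss - full$rss <= rss_tol) return(1)  # removal costs nothing
    f <- (red$rss - full$rss) / (max(full$rss, rss_tol) / df2)
    pf(f, 1, df2, lower.tail = FALSE)
  }
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool) && n - length(selected) - 2L > 0L) {
      pv <- vapply(pool, entry_p, 1)
      ok <- which(!is.na(pv) & pv < alpha_enter)
      if (length(ok)) {
        best <- ok[order(pv[ok], pool[ok])][1]
        selected <- c(selected, pool[best])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(selected)) break
      pv <- vapply(selected, removal_p, 1)
      worst <- which(pv > alpha_remove)
      if (!length(worst)) break
      drop_i <- worst[order(-pv[worst], selected[worst])][1]
      selected <- setdiff(selected, selected[drop_i])
      changed <- TRUE
    }
    if (!changed) break
  }
  fit <- lm.fit(design(selected), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(features = sort(selected),
                 coefficients = coef(fit),
                 r_squared = if (tss > 0) max(0, 1 - rss / tss) else NA_real_,
                 n = n, alpha_enter = alpha_enter, alpha_remove = alpha_remove),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> %d features, R^2 = %.3f (n = %d)\n",
              length(x$features), x$r_squared, x$n))
  if (length(x$features)) cat("  ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a stepwise model
#' @param object a `stepwise_model`.
#' @param newdata matrix/data.frame containing the selected feature columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  co <- object$coefficients
  feats <- setdiff(names(co), "(Intercept)")
  X <- as_feature_matrix(newdata)
  missing <- setdiff(feats, colnames(X))
  if (length(missing)) stop("newdata lacks features: ", paste(missing, collapse = ", "))
  drop(cbind(1, X[, feats, drop = FALSE]) %*% co[c("(Intercept)", feats)])
}

#' k-fold cross-validation of a stepwise trait model
#'
#' Samples are assigned to `k` folds by a seeded uniform permutation. For
#' each fold a stepwise model is fitted on the remaining samples and
#' evaluated on the held-out fold with
#' `MAPE = 100/n * sum(|(Y_i - y_i) / Y_i|)` (observed `Y_i`, predicted
#' `y_i`), the standard deviation of the per-sample absolute percentage
#' errors (SD_APE), and the held-out R-squared. Samples with `Y_i = 0`
#' are excluded from the percentage errors with a warning.
#'
#' @param X feature table.
#' @param y observed trait values.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param ... passed to [stepwise_lsr()].
#' @return object of class `cv_report`: per-fold table (`folds`), pooled
#'   `mape`, `sd_ape`, mean held-out `r_squared`, the per-sample APEs, the
#'   fold assignment and the seed.
#' @export
kfold_cv <- function(X, y, k = 5L, seed = 1L, ...) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, k >= 2L, n >= k)
  assignment <- with_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
  if (any(y == 0)) warning("samples with Y = 0 excluded from percentage errors")
  ape_all <- rep(NA_real_, n)
  folds <- data.frame(fold = seq_len(k), n = NA_integer_, r_squared = NA_real_,
                      mape = NA_real_, sd_ape = NA_real_)
  for (f in seq_len(k)) {
    test <- assignment == f
    model <- stepwise_lsr(X[!test, , drop = FALSE], y[!test], ...)
    pred <- if (length(model$features) == 0L)
      rep(mean(y[!test]), sum(test))
    else predict(model, X[test, , drop = FALSE])
    obs <- y[test]
    ok <- obs != 0
    ape <- abs((obs[ok] - pred[ok]) / obs[ok]) * 100
    ape_all[which(test)[ok]] <- ape
    tss <- sum((obs - mean(obs))^2)
    folds$n[f] <- sum(test)
    folds$r_squared[f] <- if (tss > 0) 1 - sum((obs - pred)^2) / tss else NA_real_
    folds$mape[f] <- mean(ape)
    folds$sd_ape[f] <- sd(ape)
  }
  structure(list(folds = folds,
                 mape = mean(ape_all, na.rm = TRUE),
                 sd_ape = sd(ape_all, na.rm = TRUE),
                 r_squared = mean(folds$r_squared, na.rm = TRUE),
                 ape = ape_all, assignment = assignment, seed = seed, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold: MAPE = %.2f%%, SD_APE = %.2f, mean held-out R^2 = %.3f\n",
              x$k, x$mape, x$sd_ape, x$r_squared))
  invisible(x)
}

#' Wavelength frequency distribution of trait-correlated indices
#'
#' Computes the Pearson correlation of every catalog index with a trait
#' and tallies, per wavelength, how many indices exceed the threshold in
#' absolute value. Band-family indices are tallied at their band
#' wavelength; characteristic indices at their defining window centre.
#' The resulting distribution highlights the spectral regions that carry
#' information about the trait.
#'
#' @param index_table matrix/data.frame, one row per plant, columns named
#'   after catalog indices (extra columns are ignored).
#' @param trait numeric trait vector, one value per row.
#' @param r_threshold absolute correlation cutoff (default 0.3).
#' @param catalog catalog layout, default [index_catalog()].
#' @return data.frame `(wavelength_nm, count)` over the wavelengths with
#'   at least one counted index, sorted by wavelength.
#' @export
correlation_screen <- function(index_table, trait, r_threshold = 0.3,
                               catalog = NULL) {
  X <- as_feature_matrix(index_table)
  trait <- as.numeric(trait)
  stopifnot(nrow(X) == length(trait))
  if (nrow(X) < 3L) stop("need at least 3 samples for a correlation screen")
  if (sd(trait) == 0) stop("trait has zero variance")
  if (is.null(catalog)) catalog <- index_catalog()
  catalog <- catalog[catalog$name %in% colnames(X), , drop = FALSE]
  r <- suppressWarnings(as.vector(cor(X[, catalog$name, drop = FALSE], trait)))
  hit <- !is.na(r) & abs(r) > r_threshold
  wl <- round(catalog$wavelength_nm[hit])
  if (!length(wl)) return(data.frame(wavelength_nm = numeric(0), count = integer(0)))
  tab <- table(wl)
  data.frame(wavelength_nm = as.numeric(names(tab)), count = as.integer(tab))
}

# --- stepwise discriminant analysis --------------------------------------

wilks_lambda <- function(X, labels) {
  # det(within-class scatter) / det(total scatter); NA if singular
  X <- as.matrix(X)
  total <- crossprod(scale(X, scale = FALSE))
  within <- matrix(0, ncol(X), ncol(X))
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    within <- within + crossprod(scale(Xg, scale = FALSE))
  }
  dt <- det(total)
  if (!is.finite(dt) || dt <= .Machine$double.eps) return(NA_real_)
  det(within) / dt
}

#' Stepwise discriminant classification
#'
#' Selects features by stepwise entry on Wilks' lambda partial-F tests
#' (the standard stepwise discriminant analysis), fits a linear
#' discriminant on the selected features and reports the cross-validated
#' confusion matrix and correct rate. Features whose within-class scatter
#' is singular given the current set are skipped.
#'
#' @param X feature table.
#' @param labels class labels (factor or character), e.g. growth stages
#'   or subspecies.
#' @param k CV folds (default 5).
#' @param seed fold-assignment seed.
#' @param alpha_enter,alpha_remove stepwise significance levels.
#' @param max_features cap on selected features.
#' @return list: `features`, `accuracy` (cross-validated correct rate in
#'   \%), `confusion` matrix, per-fold accuracies.
#' @export
discriminant_classify <- function(X, labels, k = 5L, seed = 1L,
                                  alpha_enter = 0.05, alpha_remove = 0.10,
                                  max_features = 20L) {
  X <- as_feature_matrix(X)
  labels <- factor(labels)
  n <- nrow(X); g <- nlevels(labels)
  if (g < 2L) stop("need at least 2 classes")
  if (any(table(labels) < k)) stop("every class needs at least k samples")
  candidates <- colnames(X)[apply(X, 2, function(v) sd(v) > 0)]
  selected <- character(0)
  lambda_of <- function(feats) {
    if (!length(feats)) return(1)
    wilks_lambda(X[, feats, drop = FALSE], labels)
  }
  partial_p <- function(l_old, l_new, p_new) {
    df2 <- n - g - p_new + 1L
    if (df2 <= 0L || is.na(l_new) || l_new <= 0) return(NA_real_)
    f <- (l_old / l_new - 1) * df2 / (g - 1)
    pf(f, g - 1, df2, lower.tail = FALSE)
  }
  repeat {
    changed <- FALSE
    l_cur <- lambda_of(selected)
    pool <- setdiff(candidates, selected)
    if (length(pool) && length(selected) < max_features) {
      pv <- vapply(pool, function(f)
        partial_p(l_cur, lambda_of(c(selected, f)), length(selected) + 1L), 1)
      ok <- which(!is.na(pv) & pv < alpha_enter)
      if (length(ok)) {
        best <- ok[order(pv[ok], pool[ok])][1]
        selected <- c(selected, pool[best])
        changed <- TRUE
      }
    }
    if (length(selected) > 1L) {
      l_cur <- lambda_of(selected)
      pv <- vapply(selected, function(f)
        partial_p(lambda_of(setdiff(selected, f)), l_cur, length(selected)), 1)
      worst <- which(!is.na(pv) & pv > alpha_remove)
      if (length(worst)) {
        drop_i <- worst[order(-pv[worst], selected[worst])][1]
        selected <- setdiff(selected, selected[drop_i])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(selected)) selected <- candidates[1]
  assignment <- with_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- assignment == f
    fit <- MASS::lda(X[!test, selected, drop = FALSE], grouping = labels[!test])
    p <- predict(fit, X[test, selected, drop = FALSE])$class
    pred[test] <- p
    acc[f] <- mean(p == labels[test]) * 100
  }
  list(features = selected,
       accuracy = mean(pred == labels, na.rm = TRUE) * 100,
       confusion = table(observed = labels, predicted = pred),
       fold_accuracy = acc)
}
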