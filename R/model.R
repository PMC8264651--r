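# L1-penalized logistic response models with leave-one-out lambda tuning.
# glmnet does the coordinate-descent fitting; this module wires the LOOCV
# tuning, the misclassification accounting and the tidy reporting.

#' LASSO logistic model with leave-one-out cross-validation
#'
#' Fits an L1-penalized logistic regression of a binary outcome (complete
#' response coded 1) on a covariate matrix, over a descending log-spaced
#' lambda grid starting at the smallest lambda that zeroes every
#' coefficient. Covariates are standardized internally (mean 0, sd 1;
#' intercept unpenalized). `lambda_min` is selected by minimal leave-one-out
#' binomial deviance; the reported model is the full-data fit at that
#' penalty, and the leave-one-out misclassification rate at probability
#' cutoff 0.5 (ties predicted as class 1) is reported alongside.
#'
#' @param x numeric matrix or data frame, patients x covariates.
#' @param y binary outcome vector (0/1); both classes must be present.
#' @param nlambda number of penalties in the grid.
#' @param thresh coordinate-descent convergence tolerance.
#' @param maxit maximum coordinate-descent iterations.
#' @return An object of class `lasso_fit`: list with `coefficients` (named,
#'   nonzero terms plus `(Intercept)`, on the original covariate scale),
#'   `lambda_min`, `loocv_error`, `loocv_deviance`, `lambda`, `cvm`, `n`,
#'   `glmnet_fit` and the training data.
#' @export
lasso_logistic_loocv <- function(x, y, nlambda = 100, thresh = 1e-7,
                                 maxit = 1e5) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  keep <- stats::complete.cases(x) & is.finite(y)
  if (any(!keep)) {
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  if (n < 5) stop("need at least 5 complete observations", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; cannot fit a classifier", call. = FALSE)
  }
  informative <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(informative)) {
    # no usable covariate: intercept-only model
    p1 <- mean(y)
    pred <- as.integer(p1 >= 0.5)
    fit <- list(coefficients = c("(Intercept)" = stats::qlogis(min(max(p1, 1e-12), 1 - 1e-12))),
                lambda_min = Inf, loocv_error = mean(pred != y),
                loocv_deviance = NA_real_, lambda = numeric(), cvm = numeric(),
                n = n, glmnet_fit = NULL, x = x, y = y,
                intercept_only = TRUE)
    class(fit) <- "lasso_fit"
    return(fit)
  }
  xi <- x[, informative, drop = FALSE]
  # lambda grid from the full-data path: descending from the smallest
  # penalty that zeroes every slope
  full <- glmnet::glmnet(xi, y, family = "binomial", nlambda = nlambda,
                         standardize = TRUE, thresh = thresh, maxit = maxit)
  lambda <- full$lambda
  # explicit leave-one-out loop: predicted probability of each held-out
  # patient across the whole penalty grid
  prob <- loocv_probabilities(xi, y, lambda, thresh = thresh, maxit = maxit)
  pc <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  cvm <- colMeans(-2 * (y * log(pc) + (1 - y) * log(1 - pc)))
  lambda_min <- lambda[which.min(cvm)]
  coefs <- stats::coef(full, s = lambda_min, exact = TRUE, x = xi, y = y)[, 1]
  nz <- coefs[coefs != 0 | names(coefs) == "(Intercept)"]
  sel <- which.min(cvm)
  loocv_err <- mean(as.integer(prob[, sel] >= 0.5) != y)
  fit <- list(coefficients = nz, lambda_min = lambda_min,
              loocv_error = loocv_err,
              loocv_deviance = cvm[sel],
              lambda = lambda, cvm = cvm, n = n,
              glmnet_fit = full, x = xi, y = y, intercept_only = FALSE)
  class(fit) <- "lasso_fit"
  fit
}

# n x n_lambda matrix of held-out predicted probabilities; training folds
# degenerating to a single class fall back to the fold prevalence
loocv_probabilities <- function(x, y, lambda, thresh = 1e-7, maxit = 1e5) {
  n <- length(y)
  t(vapply(seq_len(n), function(i) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) {
      return(rep(mean(yi), length(lambda)))
    }
    f <- tryCatch(
      glmnet::glmnet(x[-i, , drop = FALSE], yi, family = "binomial",
                     lambda = lambda, standardize = TRUE,
                     thresh = thresh, maxit = maxit),
      error = function(e) NULL)
    if (is.null(f)) return(rep(mean(yi), length(lambda)))
    p <- stats::predict(f, x[i, , drop = FALSE], s = lambda,
                        type = "response")
    as.numeric(p)
  }, numeric(length(lambda))))
}

# leave-one-out refits at a fixed penalty; prediction at cutoff 0.5 with
# ties assigned to class 1
loocv_misclassification <- function(x, y, lambda, s, thresh = 1e-7,
                                    maxit = 1e5) {
  prob <- loocv_probabilities(x, y, lambda, thresh = thresh, maxit = maxit)
  p_at_s <- prob[, which.min(abs(lambda - s))]
  mean(as.integer(p_at_s >= 0.5) != y)
}

#' Classification error of a fitted LASSO model
#'
#' Fraction misclassified at probability cutoff 0.5 (ties predicted as
#' class 1), either on the supplied data (apparent error) or by leave-one-out
#' refitting at the tuned penalty.
#'
#' @param fit a `lasso_fit`.
#' @param x covariate matrix (defaults to the training matrix).
#' @param y outcome vector (defaults to the training outcome).
#' @param loocv if `TRUE`, refit n times leaving each observation out.
#' @return Misclassification rate in `[0, 1]`.
#' @export
classification_error <- function(fit, x = fit$x, y = fit$y, loocv = FALSE) {
  stopifnot(inherits(fit, "lasso_fit"))
  x <- as.matrix(x)
  if (isTRUE(fit$intercept_only)) {
    pred <- as.integer(mean(fit$y) >= 0.5)
    return(mean(pred != y))
  }
  if (loocv) {
    return(loocv_misclassification(x, y, lambda = fit$lambda,
                                   s = fit$lambda_min))
  }
  p <- as.numeric(stats::predict(fit$glmnet_fit, x, s = fit$lambda_min,
                                 type = "response"))
  mean(as.integer(p >= 0.5) != y)
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> n =", x$n, " lambda_min =", signif(x$lambda_min, 3),
      " LOOCV error =", signif(x$loocv_error, 3), "\n")
  cat("nonzero coefficients:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Tidy a LASSO fit
#'
#' One row per retained (nonzero) term, broom style.
#'
#' @param x a `lasso_fit`.
#' @param ... unused.
#' @return Tibble with columns `term`, `estimate`.
#' @method tidy lasso_fit
#' @export
tidy.lasso_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' Model-level summary of a LASSO fit
#'
#' @param x a `lasso_fit`.
#' @param ... unused.
#' @return One-row tibble: `n`, `n_selected` (nonzero slopes), `lambda_min`,
#'   `loocv_error`, `loocv_deviance`.
#' @method glance lasso_fit
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_selected = sum(names(x$coefficients) != "(Intercept)"),
    lambda_min = x$lambda_min,
    loocv_error = x$loocv_error,
    loocv_deviance = x$loocv_deviance
  )
}

#' Build the covariate matrix of percentage-change features
#'
#' Pivots a long percentage-change feature table (original contour) to a
#' patients x features matrix restricted to the given features.
#'
#' @param change_table tibble with `patient_id`, `feature`, `value`.
#' @param features character vector of feature ids to keep.
#' @param pet_binary optional named (by patient id) 0/1 vector appended as a
#'   `pet_response` covariate.
#' @return Numeric matrix with patient ids as row names.
#' @export
feature_matrix <- function(change_table, features,
                           pet_binary = NULL) {
  wide <- change_table |>
    dplyr::filter(.data$feature %in% features) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "feature",
                       values_from = "value")
  m <- as.matrix(wide[, setdiff(names(wide), "patient_id"), drop = FALSE])
  rownames(m) <- wide$patient_id
  if (!is.null(pet_binary)) {
    m <- cbind(m, pet_response = as.numeric(pet_binary[rownames(m)]))
  }
  m
}
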