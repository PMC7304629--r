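#' Linear score of a candidate binding region
#'
#' S_F = lambda1 * delta_id + lambda2 * delta_a + lambda3 * delta_h + gamma.
#' Positive scores favour a disorder-to-order transition of the region upon
#' binding, negative scores a disorder-to-disorder one.
#'
#' @param features Numeric vector or matrix with (columns) `delta_id`,
#'   `delta_a`, `delta_h`.
#' @param params A `binding_model` or a list with `lambda` (length-3) and
#'   `gamma`.
#' @return Numeric score(s).
#' @export
score_region <- function(features, params) {
  lam <- model_lambda(params); gam <- model_gamma(params)
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  cols <- c("delta_id", "delta_a", "delta_h")
  if (!is.null(colnames(features)) && all(cols %in% colnames(features)))
    features <- features[, cols, drop = FALSE]
  drop(features %*% lam) + gam
}

#' Disorder-to-order probability from a region score
#'
#' The logistic transform p_DO = exp(s) / (1 + exp(s)), evaluated stably for
#' large |s| (via `plogis`). p_DD = 1 - p_DO.
#'
#' @param s Numeric score(s).
#' @return Probabilities in (0, 1).
#' @export
pdo_from_score <- function(s) stats::plogis(s)

model_lambda <- function(params) {
  if (inherits(params, "binding_model")) return(params$coefficients[1:3 + 1])
  as.numeric(params$lambda)
}
model_gamma <- function(params) {
  if (inherits(params, "binding_model")) return(unname(params$coefficients[1]))
  as.numeric(params$gamma)
}

#' Fit the binding-mode scoring function by logistic regression
#'
#' Maximum-likelihood logistic regression of region labels (1 =
#' disorder-to-order, 0 = disorder-to-disorder) on the three local-bias
#' features, fitted by iteratively reweighted least squares (Newton
#' scoring). Convergence is declared when the log-likelihood changes by
#' less than `tol` (default 1e-8), with at most `max_iter` (default 100)
#' iterations. Complete or quasi-complete separation is detected (all
#' fitted probabilities at the boundary); in that case a small L2 ridge
#' (`ridge = 1e-4`) is engaged automatically with a warning so finite
#' coefficients are returned. Context-dependent regions must not be
#' included in the training set; the model discriminates only the two pure
#' binding modes.
#'
#' @param formula Model formula; default `label ~ delta_id + delta_a +
#'   delta_h`.
#' @param data data.frame holding the response and features (e.g. from
#'   [featurize_regions()] or [simulate_training_set()]).
#' @param min_per_class Minimum examples required per class (default 10).
#' @param tol,max_iter IRLS convergence controls.
#' @param ridge L2 penalty used only on detected separation.
#' @param feature_config Metadata list recorded with the model (flank
#'   length, window range, composition statistic, disorder source).
#' @return Object of class `binding_model` with components `coefficients`
#'   (gamma first, then the lambdas), `se`, `vcov`, `loglik`, `iter`,
#'   `converged`, `separation`, `fitted`, `y`, `X`, `feature_config`.
#' @examples
#' set.seed(1)
#' tr <- simulate_training_set(n = 500, lambda = c(2, -1, 0.5), gamma = -0.3)
#' fit <- fit_binding_model(data = tr)
#' coef(fit)
#' @export
fit_binding_model <- function(formula = label ~ delta_id + delta_a + delta_h,
                              data, min_per_class = 10L, tol = 1e-8,
                              max_iter = 100L, ridge = 1e-4,
                              feature_config = default_feature_config()) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  X <- stats::model.matrix(formula, mf)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present (got ", n1, " positives, ", n0,
         " negatives)")
  if (n1 < min_per_class || n0 < min_per_class)
    stop("need >= ", min_per_class, " examples per class")

  irls <- function(pen) {
    beta <- numeric(ncol(X))
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      p <- stats::plogis(eta)
      w <- pmax(p * (1 - p), 1e-10)
      H <- crossprod(X, X * w) + diag(pen, ncol(X))
      g <- crossprod(X, y - p) - pen * beta
      beta <- beta + solve(H, g)
      eta <- drop(X %*% beta)
      # stable log(1+exp(eta)): eta itself for large eta
      lse <- ifelse(eta > 30, eta, log1p(exp(eta)))
      ll <- sum(y * eta - lse) - pen / 2 * sum(beta^2)
      if (is.finite(ll) && abs(ll - ll_old) < tol)
        return(list(beta = beta, ll = ll, iter = it, converged = TRUE))
      ll_old <- ll
    }
    list(beta = beta, ll = ll_old, iter = max_iter, converged = FALSE)
  }

  fit <- irls(0)
  p <- stats::plogis(drop(X %*% fit$beta))
  sep <- all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6)
  if (sep || (!fit$converged && (max(abs(fit$beta)) > 1e4))) {
    warning("complete separation detected; refitting with L2 ridge ", ridge)
    sep <- TRUE
    fit <- irls(ridge)
    p <- stats::plogis(drop(X %*% fit$beta))
  } else if (!fit$converged) {
    warning("IRLS did not converge in ", max_iter,
            " iterations (loglik ", sprintf("%.6g", fit$ll), ")")
  }
  w <- pmax(p * (1 - p), 1e-10)
  H <- crossprod(X, X * w) + diag(if (sep) ridge else 0, ncol(X))
  vc <- solve(H)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 se = sqrt(diag(vc)), vcov = vc,
                 loglik = fit$ll, iter = fit$iter,
                 converged = fit$converged, separation = sep,
                 fitted = p, y = y, X = X,
                 n = length(y), formula = formula,
                 feature_config = feature_config),
            class = "binding_model")
}

#' Default feature-configuration metadata
#'
#' @param flank_len,min_len,max_len,composition_stat,disorder_source
#'   Configuration values recorded with a fitted model so parameters are
#'   never applied to features computed under a different convention.
#' @return Named list.
#' @export
default_feature_config <- function(flank_len = 20L, min_len = 5L,
                                   max_len = 9L,
                                   composition_stat = "topidp",
                                   disorder_source = "builtin-fallback") {
  list(flank_len = flank_len, min_len = min_len, max_len = max_len,
       composition_stat = composition_stat,
       disorder_source = disorder_source)
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Binding-mode logistic scoring model\n")
  cat("  S_F = lambda1*delta_id + lambda2*delta_a + lambda3*delta_h + gamma\n")
  co <- x$coefficients
  cat(sprintf("  gamma   = %+.4f\n", co[1]))
  for (k in 2:length(co))
    cat(sprintf("  %-7s = %+.4f  (%s)\n", paste0("lambda", k - 1), co[k],
                names(co)[k]))
  cat(sprintf("  n = %d, log-likelihood = %.4f, IRLS iterations = %d%s\n",
              x$n, x$loglik, x$iter,
              if (x$separation) " [ridge: separation]" else ""))
  invisible(x)
}

#' @export
summary.binding_model <- function(object, ...) {
  co <- object$coefficients
  z <- co / object$se
  tab <- cbind(Estimate = co, `Std. Error` = object$se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, loglik = object$loglik, n = object$n,
              converged = object$converged, separation = object$separation)
  class(out) <- "summary.binding_model"
  out
}

#' @export
print.summary.binding_model <- function(x, ...) {
  cat("Binding-mode logistic model: n =", x$n,
      " log-likelihood =", sprintf("%.4f", x$loglik), "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (x$separation) cat("Note: separation detected; ridge-regularised fit.\n")
  invisible(x)
}

#' @export
coef.binding_model <- function(object, ...) object$coefficients

#' @export
vcov.binding_model <- function(object, ...) object$vcov

#' @export
logLik.binding_model <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' 95 % Wald confidence intervals for model coefficients
#' @param object A `binding_model`.
#' @param parm Coefficients to include (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @export
confint.binding_model <- function(object, parm = NULL, level = 0.95, ...) {
  co <- object$coefficients; se <- object$se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(co - zq * se, co + zq * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict from a fitted binding-mode model
#'
#' For feature data (`newdata` a data.frame with the bias columns) returns
#' the linear score (`type = "link"`) or the disorder-to-order probability
#' (`type = "response"`, default). When `newdata` is a
#' [protein_sequence()], dispatches to [predict_binding_modes()] and
#' returns a per-residue `binding_profile`.
#'
#' @param object A `binding_model`.
#' @param newdata data.frame of features, or a `protein_sequence`.
#' @param type `"response"` or `"link"`.
#' @param ... Passed on to [predict_binding_modes()] for sequence input.
#' @export
predict.binding_model <- function(object, newdata = NULL,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "protein_sequence"))
    return(predict_binding_modes(newdata, model = object, ...))
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
  } else {
    X <- stats::model.matrix(stats::delete.response(
      stats::terms(object$formula)), newdata)
    eta <- drop(X %*% object$coefficients[colnames(X)])
  }
  eta <- unname(eta)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.binding_model <- function(object,
                                    type = c("deviance", "pearson",
                                             "response"), ...) {
  type <- match.arg(type)
  y <- object$y; p <- object$fitted
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) *
           sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p))))
}

#' Simulate labels from a fitted binding-mode model
#'
#' Draws Bernoulli labels at the fitted (or newdata) probabilities.
#'
#' @param object A `binding_model`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @export
simulate.binding_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Write / read model parameters as JSON
#'
#' The JSON object stores `lambda1..lambda3`, `gamma`, `se`, the
#' `feature_config` metadata and free-form `provenance`; numbers round-trip
#' bit-exactly (written at full precision).
#'
#' @param model A `binding_model` or a params list.
#' @param path Output path.
#' @param provenance Optional list recorded verbatim.
#' @return `path` invisibly (write); params list of class `binding_params`
#'   usable wherever a model is accepted (read).
#' @export
write_model_json <- function(model, path, provenance = list()) {
  lam <- model_lambda(model); gam <- model_gamma(model)
  obj <- list(lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
              gamma = gam,
              feature_config = if (inherits(model, "binding_model"))
                model$feature_config else model$feature_config,
              provenance = provenance)
  if (inherits(model, "binding_model")) obj$se <- unname(model$se)
  # digits = I(17): full IEEE double precision, bit-exact on re-read
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("lambda1", "lambda2", "lambda3", "gamma"))
    if (is.null(obj[[f]])) stop("model JSON missing field '", f, "'")
  structure(list(lambda = c(obj$lambda1, obj$lambda2, obj$lambda3),
                 gamma = obj$gamma,
                 feature_config = obj$feature_config,
                 provenance = obj$provenance),
            class = "binding_params")
}

#' Default packaged model parameters
#'
#' Coefficients fitted on packaged synthetic example regions (see the
#' methods vignette). They demonstrate the pipeline end to end but are NOT
#' the published parametrisation, which was trained on curated structural
#' datasets with an external disorder predictor.
#'
#' @return A `binding_params` list.
#' @export
default_model <- function() {
  read_model_json(system.file("extdata", "default_model.json",
                              package = "bindmode", mustWork = TRUE))
}
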