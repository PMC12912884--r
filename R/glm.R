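# Binomial-logit model of collection probability, fitted by IRLS,
# with AICc selection, McFadden pseudo-R2 and ROC AUC.

.glm_predictors <- c("elevation", "slope", "lulc", "dist_road", "dist_harbour")

#' Specify a candidate model
#'
#' @param predictors character subset of `elevation`, `slope`, `lulc`,
#'   `dist_road`, `dist_harbour`; empty for the null (intercept-only)
#'   model.
#' @param lulc_encoding `"dummy"` (treatment-coded indicators, reference
#'   = agriculture and croplands; recommended) or `"integer"` (a single
#'   coefficient on the 1-6 class code; provided for comparability with
#'   analyses that report one land-cover coefficient, but statistically
#'   questionable for a nominal variable).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(predictors = character(0),
                       lulc_encoding = c("dummy", "integer")) {
  lulc_encoding <- match.arg(lulc_encoding)
  predictors <- unique(predictors)
  bad <- setdiff(predictors, .glm_predictors)
  if (length(bad) > 0) {
    stop(sprintf("unknown predictor(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(predictors = predictors, lulc_encoding = lulc_encoding),
            class = "model_spec")
}

#' Default candidate model set
#'
#' Null model, each single predictor, environment-only
#' (elevation + slope + land cover), accessibility-only (distances to
#' road and harbour), and the full model.
#'
#' @param lulc_encoding passed to [model_spec()].
#' @return named list of `model_spec`s.
#' @export
candidate_specs <- function(lulc_encoding = "dummy") {
  singles <- stats::setNames(
    lapply(.glm_predictors, model_spec, lulc_encoding = lulc_encoding),
    .glm_predictors
  )
  c(
    list(null = model_spec(character(0), lulc_encoding)),
    singles,
    list(
      environment = model_spec(c("elevation", "slope", "lulc"), lulc_encoding),
      accessibility = model_spec(c("dist_road", "dist_harbour"), lulc_encoding),
      full = model_spec(.glm_predictors, lulc_encoding)
    )
  )
}

# Build the design matrix for a spec; continuous predictors stay on
# their raw scale so coefficients are per-unit.
.design_matrix <- function(table, spec, lulc_levels_seen = NULL) {
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (p in spec$predictors) {
    if (p == "lulc") {
      f <- table$lulc
      if (!is.factor(f)) f <- factor(f, levels = lulc_levels())
      if (spec$lulc_encoding == "integer") {
        X <- cbind(X, lulc = as.integer(f))
      } else {
        lev <- if (is.null(lulc_levels_seen)) {
          levels(f)[tabulate(f, nbins = nlevels(f)) > 0]
        } else {
          lulc_levels_seen
        }
        if (any(!(as.character(f) %in% lev))) {
          stop("unseen LULC category in prediction data", call. = FALSE)
        }
        for (l in lev[-1]) {
          col <- as.numeric(f == l)
          X <- cbind(X, col)
          colnames(X)[ncol(X)] <- paste0("lulc_", l)
        }
        attr(X, "lulc_levels_seen") <- lev
      }
    } else {
      X <- cbind(X, table[[p]])
      colnames(X)[ncol(X)] <- p
    }
  }
  X
}

.bernoulli_loglik <- function(y, p) {
  eps <- 1e-12
  sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Fit the binomial-logit collection model by IRLS
#'
#' Maximum-likelihood logistic regression of the presence indicator on
#' the requested predictors, by iteratively reweighted least squares
#' from \eqn{\beta = 0}, converging when the relative deviance change
#' falls below `tol` (with step-halving so deviance never increases).
#' Standard errors come from the inverse Fisher information at the
#' optimum; p-values are two-sided Wald normal.  Continuous predictors
#' are used on their raw scale, so coefficients are per metre / per
#' degree.  Constant predictor columns are dropped with a warning; a fit
#' with any |coefficient| > 15 at convergence is flagged as likely
#' separation.
#'
#' @param table predictor table from [build_model_table()] (columns
#'   `presence` plus the predictors).
#' @param spec a [model_spec()].
#' @param tol relative deviance convergence tolerance (default 1e-8).
#' @param max_iter IRLS iteration cap (default 100).
#' @return object of class `glm_fit`: list with `beta`, `se`, `z`, `p`,
#'   `loglik`, `loglik_null`, `n_obs`, `k`, `aicc`, `mcfadden_r2`,
#'   `auc`, `converged`, `n_iter`, `separation`, `spec`,
#'   `lulc_levels_seen`, `deviance_trace`.
#' @export
fit_logistic <- function(table, spec = model_spec(.glm_predictors),
                         tol = 1e-8, max_iter = 100) {
  y <- table$presence
  if (length(unique(y)) < 2) {
    stop("need at least one presence and one absence", call. = FALSE)
  }
  X <- .design_matrix(table, spec)
  lulc_seen <- attr(X, "lulc_levels_seen")
  # drop constant non-intercept columns
  keep <- c(TRUE, vapply(seq_len(ncol(X) - 1) + 1, function(j) {
    stats::var(X[, j]) > 0
  }, logical(1)))
  if (any(!keep)) {
    warning(sprintf("dropped constant predictor column(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop(sprintf("singular information matrix; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(X); k <- ncol(X)
  beta <- rep(0, k)
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  dev <- -2 * .bernoulli_loglik(y, p)
  trace <- dev
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      p_try <- stats::plogis(eta_try)
      dev_try <- -2 * .bernoulli_loglik(y, p_try)
      if (dev_try <= dev + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    rel_change <- abs(dev - dev_try) / (abs(dev) + 0.1)
    beta <- beta_try; eta <- eta_try; p <- p_try; dev <- dev_try
    trace <- c(trace, dev)
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  w <- pmax(p * (1 - p), 1e-10)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  ll <- -dev / 2
  p_bar <- mean(y)
  ll0 <- .bernoulli_loglik(y, rep(p_bar, n))
  separation <- any(abs(beta) > 15)
  if (separation) warning("possible complete separation: |coefficient| > 15")
  fit <- structure(list(
    beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(zval, colnames(X)),
    p = stats::setNames(pval, colnames(X)),
    loglik = ll, loglik_null = ll0,
    n_obs = n, k = k,
    converged = converged, n_iter = iter,
    separation = separation,
    spec = spec, lulc_levels_seen = lulc_seen,
    fitted = p, response = y,
    deviance_trace = trace
  ), class = "glm_fit")
  fit$aicc <- if (n > k + 1) aicc(fit) else NA_real_
  fit$mcfadden_r2 <- 1 - ll / ll0
  fit$auc <- roc_auc(y, p)
  fit
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Binomial-logit fit: n = %d, k = %d, logLik = %.3f, AICc = %.3f\n",
              x$n_obs, x$k, x$loglik, x$aicc))
  cat(sprintf("McFadden pseudo-R2 = %.4f, ROC AUC = %.4f%s\n",
              x$mcfadden_r2, x$auc,
              if (x$separation) " [separation-flagged]" else ""))
  tab <- data.frame(estimate = x$beta, se = x$se, z = x$z, p = x$p)
  print(format(tab, digits = 4))
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n - k - 1)}.
#'
#' @param fit a `glm_fit`, or a list with `loglik`, `k`, `n_obs`.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  n <- fit$n_obs; k <- fit$k
  if (n <= k + 1) stop("AICc undefined: n_obs <= k + 1", call. = FALSE)
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' McFadden pseudo-R-squared
#'
#' \eqn{1 - \ell_{model}/\ell_{null}}.
#'
#' @param fit fitted model (`glm_fit`).
#' @param null_fit intercept-only fit on the same response.
#' @return pseudo-R2 value.
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  if (null_fit$loglik == 0) stop("null log-likelihood is zero", call. = FALSE)
  1 - fit$loglik / null_fit$loglik
}

#' ROC AUC by the Mann-Whitney rank statistic
#'
#' Midrank tie handling: \eqn{AUC = (R_1 - n_1(n_1+1)/2)/(n_1 n_0)}
#' where \eqn{R_1} is the rank-sum of the positive-class scores.
#' Equivalent to the mean over all (positive, negative) pairs of
#' \eqn{[s_1 > s_0] + \frac{1}{2}[s_1 = s_0]}.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in \eqn{[0, 1]}.
#' @export
roc_auc <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predicted collection probabilities
#'
#' Inverse-logit of the linear predictor for new data.
#'
#' @param fit a `glm_fit`.
#' @param table data frame with the predictors of the fitted spec; a
#'   land-cover category unseen at fit time is an error.
#' @return probabilities in (0, 1).
#' @export
predict_prob <- function(fit, table) {
  X <- .design_matrix(table, fit$spec, lulc_levels_seen = fit$lulc_levels_seen)
  X <- X[, names(fit$beta), drop = FALSE]
  stats::plogis(drop(X %*% fit$beta))
}

#' Fit and rank candidate models by AICc
#'
#' Fits each candidate spec to the same predictor table and orders the
#' results by increasing AICc (ties broken by fewer predictors then by
#' spec name); the minimum-AICc model is flagged best.  A failing fit
#' annotates its row instead of aborting the comparison.
#'
#' @param table predictor table from [build_model_table()].
#' @param specs named list of [model_spec()]s; must include at least 2
#'   (typically [candidate_specs()], which has the null and full models).
#' @return list with `table` (data frame `spec`, `predictors`, `k`,
#'   `aicc`, `delta_aicc`, `mcfadden_r2`, `auc`, `best`, `error`) and
#'   `fits` (named list of `glm_fit`s).
#' @export
compare_models <- function(table, specs = candidate_specs()) {
  if (length(specs) < 2) stop("need at least 2 candidate specs", call. = FALSE)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    stop("specs must be a named list", call. = FALSE)
  }
  fits <- list()
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    res <- tryCatch(fit_logistic(table, sp), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(spec = nm, predictors = paste(sp$predictors, collapse = "+"),
                 k = NA_integer_, aicc = NA_real_, mcfadden_r2 = NA_real_,
                 auc = NA_real_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      fits[[nm]] <<- res
      data.frame(spec = nm, predictors = paste(sp$predictors, collapse = "+"),
                 k = res$k, aicc = res$aicc, mcfadden_r2 = res$mcfadden_r2,
                 auc = res$auc, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  npred <- vapply(specs[tab$spec], function(s) length(s$predictors), integer(1))
  ord <- order(is.na(tab$aicc), tab$aicc, npred, tab$spec)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$aicc - min(tab$aicc, na.rm = TRUE)
  # deterministic single best: first row after ordering by (aicc, npred, name)
  tab$best <- seq_len(nrow(tab)) == 1 & !is.na(tab$aicc[1])
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
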