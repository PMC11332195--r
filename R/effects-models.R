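#' Build a design matrix with sum contrasts and z-scored predictors
#'
#' Constructs the fixed-effects design used throughout: an intercept
#' (representing the grand mean), sum-contrast codes (+1/-1) for two-level
#' factors, z-transformed continuous predictors, and requested interaction
#' columns as elementwise products of the coded columns. For each factor
#' the first level in sort order is coded +1 and the second -1 (so
#' duration 50 -> +1, 500 -> -1; condition "generated" -> +1,
#' "real" -> -1); the coding map is stored and used by [linear_trend()].
#'
#' Continuous predictors are standardized within the rows supplied here -
#' i.e. within the analysis set - unless they already have mean 0 and
#' SD 1 (tolerance 1e-8), in which case they pass through unchanged.
#'
#' @param data Data frame of trials.
#' @param factors Character vector of two-level factor columns.
#' @param continuous Character vector of numeric predictor columns.
#' @param interactions List of character vectors naming 2+ predictors to
#'   multiply (factor names refer to their coded columns).
#' @param participant Optional column name; adds centered indicator
#'   columns for all but the first participant, absorbing per-participant
#'   intercepts in the fixed-effects fit (the package's substitute for
#'   random intercepts).
#' @return Object of class `design_matrix`: list with `x` (numeric
#'   matrix, first column `(Intercept)`), `coding` (per factor, named
#'   vector level -> code), `terms`.
#' @export
build_design <- function(data, factors = character(), continuous = character(),
                         interactions = list(), participant = NULL) {
  assert_cols(data, c(factors, continuous, participant), "trial data")
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  coding <- list()
  for (f in factors) {
    lev <- sort(unique(as.character(data[[f]])))
    if (length(lev) != 2) {
      stopf("factor '%s' has %d levels; only two-level factors are supported",
            f, length(lev))
    }
    code <- setNames(c(1, -1), lev)
    coding[[f]] <- code
    cols[[f]] <- unname(code[as.character(data[[f]])])
  }
  for (cn in continuous) {
    v <- data[[cn]]
    if (!is.numeric(v)) stopf("continuous predictor '%s' is not numeric", cn)
    if (abs(mean(v)) > 1e-8 || abs(sd(v) - 1) > 1e-8) v <- z_transform(v)
    cols[[cn]] <- v
  }
  for (ia in interactions) {
    bad <- setdiff(ia, names(cols))
    if (length(bad)) stopf("interaction references unknown predictor(s): %s",
                           paste(bad, collapse = ", "))
    cols[[paste(ia, collapse = ":")]] <- Reduce(`*`, cols[ia])
  }
  if (!is.null(participant)) {
    ids <- sort(unique(data[[participant]]))
    for (pid in ids[-1]) {
      d <- as.numeric(data[[participant]] == pid)
      cols[[paste0(".p", pid)]] <- d - mean(d)  # centered: intercept stays grand mean
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  structure(list(x = x, coding = coding,
                 terms = list(factors = factors, continuous = continuous,
                              interactions = interactions,
                              participant = participant)),
            class = "design_matrix")
}

new_fit_result <- function(beta, se, statistic, stat_label, p, vcov, family,
                           link, loglik, n, design, note = NULL) {
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), statistic = unname(statistic),
                      p_value = unname(p),
                      ci_lo = unname(beta - 1.96 * se),
                      ci_hi = unname(beta + 1.96 * se),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, stat_label = stat_label, vcov = vcov,
                 family = family, link = link, logLik = loglik, n = n,
                 design = design, note = note),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s regression (%s link), n = %d, logLik = %.2f\n",
              x$family, x$link, x$n, x$logLik))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) round(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

check_design <- function(design, y) {
  stopifnot(inherits(design, "design_matrix"))
  x <- design$x
  if (nrow(x) != length(y)) stopf("design and response lengths differ")
  if (nrow(x) <= ncol(x)) stopf("need more observations than design columns")
  if (qr(x)$rank < ncol(x)) stopf("design matrix is rank deficient")
  x
}

#' Fit a fixed-effects binomial regression with Wald inference
#'
#' Binary-response regression on a [build_design()] matrix, reporting for
#' each coefficient the estimate, its standard error from the inverse
#' Fisher information, the Wald z statistic, two-sided p-value, and a
#' 95% Wald confidence interval (beta +/- 1.96 SE). This is a deliberate
#' fixed-effects simplification of a mixed-effects analysis: participant
#' heterogeneity can be absorbed by passing participant indicator columns,
#' not by random effects.
#'
#' The link is logit by default; a probit link fits threshold responses of
#' an equal-variance Gaussian evidence model on the evidence scale. With
#' `guess > 0` the success probability has a floor,
#' P = guess + (1 - guess) * linkinv(eta), as appropriate for forced-choice
#' accuracy with a chance floor (0.2 for 5-AFC); that model is fit by
#' direct Newton-type maximization of the exact likelihood.
#'
#' @param design A `design_matrix`.
#' @param y Binary response vector (0/1).
#' @param link "logit" or "probit".
#' @param guess Chance floor in \[0, 1).
#' @return A `fit_result`.
#' @export
fit_logistic <- function(design, y, link = c("logit", "probit"), guess = 0) {
  link <- match.arg(link)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  x <- check_design(design, y)
  if (guess < 0 || guess >= 1) stopf("guess must lie in [0, 1)")

  if (guess == 0) {
    fit <- withCallingHandlers(
      glm.fit(x, y, family = binomial(link = link),
              control = list(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        # separation is detected and reported below from the coefficients
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    beta <- coef(fit)
    if (any(abs(beta) > 15)) {
      stopf("perfect separation detected: coefficients diverge")
    }
    w <- fit$weights
    info <- crossprod(x * sqrt(w))
    vcov <- solve(info)
    loglik <- -fit$deviance / 2
  } else {
    linkinv <- if (link == "logit") plogis else pnorm
    dlink <- if (link == "logit") function(e) plogis(e) * (1 - plogis(e)) else
      function(e) stats::dnorm(e)
    nll <- function(b) {
      p <- guess + (1 - guess) * linkinv(drop(x %*% b))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    }
    grad <- function(b) {
      eta <- drop(x %*% b)
      p <- guess + (1 - guess) * linkinv(eta)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      gpart <- (1 - guess) * dlink(eta) * (y / p - (1 - y) / (1 - p))
      -drop(crossprod(x, gpart))
    }
    opt <- optim(rep(0, ncol(x)), nll, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    beta <- setNames(opt$par, colnames(x))
    if (any(abs(beta) > 15)) {
      stopf("perfect separation detected: coefficients diverge")
    }
    hess <- stats::optimHess(beta, nll, grad)
    vcov <- solve(hess)
    loglik <- -opt$value
  }
  se <- sqrt(diag(vcov))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  new_fit_result(beta, se, z, "z", p, vcov, "logistic", link, loglik,
                 length(y), design,
                 note = if (guess > 0) sprintf("chance floor %.2f", guess))
}

#' Fit a fixed-effects linear regression with Wald inference
#'
#' Ordinary least squares on a [build_design()] matrix; t statistics with
#' n - p degrees of freedom and Wald 95% intervals. A residual sum of
#' squares of (numerically) zero yields zero standard errors and a
#' degenerate-fit note.
#'
#' @param design A `design_matrix`.
#' @param y Numeric response.
#' @return A `fit_result`.
#' @export
fit_linear <- function(design, y) {
  y <- as.numeric(y)
  x <- check_design(design, y)
  fit <- lm.fit(x, y)
  beta <- coef(fit)
  n <- length(y); p <- ncol(x)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(vcov))
  degenerate <- rss < 1e-10 * max(1, sum(y^2))
  tstat <- ifelse(se > 0, beta / se, Inf * sign(beta))
  pval <- 2 * pt(-abs(tstat), df = n - p)
  loglik <- -n / 2 * (log(2 * pi) + log(max(rss, .Machine$double.xmin) / n) + 1)
  new_fit_result(beta, se, tstat, "t", pval, vcov, "linear", "identity",
                 loglik, n, design,
                 note = if (degenerate) "degenerate fit: residuals ~ 0")
}

#' Per-level slopes of a continuous predictor from a factor interaction
#'
#' For a model containing a continuous predictor and its interaction with
#' a sum-coded two-level factor, the simple slope at the +1-coded level is
#' beta_cont + beta_int and at the -1 level beta_cont - beta_int, with
#' standard errors from the coefficient covariance
#' (var_c + var_i +/- 2 cov). The average of the two slopes equals the
#' main-effect coefficient exactly, a property of sum coding.
#'
#' @param fit A `fit_result` whose design contains the interaction.
#' @param continuous Name of the continuous predictor.
#' @param by_factor Name of the interacting factor.
#' @return Data frame: level, slope, se, ci_lo, ci_hi.
#' @export
linear_trend <- function(fit, continuous, by_factor) {
  stopifnot(inherits(fit, "fit_result"))
  terms <- fit$coefficients$term
  int_name <- if (paste(by_factor, continuous, sep = ":") %in% terms) {
    paste(by_factor, continuous, sep = ":")
  } else if (paste(continuous, by_factor, sep = ":") %in% terms) {
    paste(continuous, by_factor, sep = ":")
  } else {
    stopf("fit does not contain the %s x %s interaction", continuous, by_factor)
  }
  if (!continuous %in% terms) stopf("fit does not contain '%s'", continuous)
  b <- setNames(fit$coefficients$estimate, terms)
  v <- fit$vcov
  code <- fit$design$coding[[by_factor]]
  if (is.null(code)) stopf("'%s' is not a coded factor in this design", by_factor)
  out <- do.call(rbind, lapply(c(1, -1), function(sgn) {
    slope <- b[continuous] + sgn * b[int_name]
    se <- sqrt(v[continuous, continuous] + v[int_name, int_name] +
                 2 * sgn * v[continuous, int_name])
    data.frame(level = names(code)[code == sgn], slope = unname(slope),
               se = se, ci_lo = unname(slope - 1.96 * se),
               ci_hi = unname(slope + 1.96 * se), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
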