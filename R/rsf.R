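#' Assemble a used-available design
#'
#' Binds used (response 1) and available (response 0) covariate tables,
#' standardizes the covariates on the combined fitting set, and carries the
#' grouping label needed for mixed models.
#'
#' @param used data frame of used points with covariate columns.
#' @param available data frame of available points with the same covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param group_used,group_available optional animal ids per row (defaults:
#'   `used$animal_id` if present; `"pooled"` otherwise).
#' @return list of class `ua_design`: `data` (with `y`, `group`,
#'   standardized covariates), `covariates`, `stats` (standardization
#'   statistics).
#' @export
ua_design <- function(used, available, covariates,
                      group_used = NULL, group_available = NULL) {
  stopifnot(nrow(used) > 0, nrow(available) > 0,
            all(covariates %in% names(used)),
            all(covariates %in% names(available)))
  gu <- if (!is.null(group_used)) as.character(group_used)
        else if ("animal_id" %in% names(used)) as.character(used$animal_id)
        else rep("pooled", nrow(used))
  ga <- if (!is.null(group_available)) as.character(group_available)
        else if ("animal_id" %in% names(available))
          as.character(available$animal_id)
        else rep("pooled", nrow(available))
  dat <- rbind(
    data.frame(y = 1L, group = gu, used[covariates], stringsAsFactors = FALSE),
    data.frame(y = 0L, group = ga, available[covariates],
               stringsAsFactors = FALSE))
  std <- standardize_covariates(dat, covariates)
  structure(list(data = std$z, covariates = covariates, stats = std$stats),
            class = "ua_design")
}

#' Second-order RSF: logistic GLM on a used-available design
#'
#' Maximum-likelihood logistic regression (logit link) of used vs available
#' on the standardized covariates. The intercept only absorbs the
#' used:available sampling ratio and is not interpreted.
#'
#' @param design `ua_design` object.
#' @return list of class `rsf_glm`: `coef`, `se`, `vcov`, `fit` (the `glm`
#'   object), `design`.
#' @export
fit_logistic <- function(design) {
  dat <- design$data
  stopifnot(length(unique(dat$y)) == 2)
  if (length(design$covariates)) {
    X <- as.matrix(dat[design$covariates])
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1) {
      stop("rank-deficient design; aliased column(s): ",
           paste(design$covariates[qr(X)$pivot[-seq_len(qr(X)$rank)]],
                 collapse = ", "))
    }
  }
  rhs <- if (length(design$covariates))
    paste(design$covariates, collapse = " + ") else "1"
  f <- stats::as.formula(paste("y ~", rhs))
  fit <- stats::glm(f, family = stats::binomial(), data = dat)
  if (!fit$converged) stop("logistic fit did not converge")
  if (any(abs(stats::coef(fit)) > 15)) {
    stop("near-complete separation: diverging coefficient(s) ",
         paste(names(which(abs(stats::coef(fit)) > 15)), collapse = ", "))
  }
  structure(list(coef = stats::coef(fit),
                 se = sqrt(diag(stats::vcov(fit))),
                 vcov = stats::vcov(fit), logLik = as.numeric(stats::logLik(fit)),
                 n = nrow(dat), fit = fit, design = design),
            class = "rsf_glm")
}

#' Third-order RSF: random-intercept logistic GLMM
#'
#' Mixed logistic regression with a per-animal normal random intercept,
#' fitted by adaptive Gauss-Hermite quadrature (`nAGQ` nodes; 1 = Laplace)
#' through `lme4::glmer`.
#'
#' @param design `ua_design` object with at least 2 groups.
#' @param nAGQ number of adaptive quadrature nodes (default 9).
#' @return list of class `rsf_glmm`: fixed effects `coef`, `se`, `vcov`,
#'   random-intercept SD `tau`, `logLik`, the `glmer` fit, `design`.
#' @export
fit_logistic_mixed <- function(design, nAGQ = 9) {
  dat <- design$data
  stopifnot(length(unique(dat$group)) >= 2)
  f <- stats::as.formula(paste("y ~",
                               paste(design$covariates, collapse = " + "),
                               "+ (1 | group)"))
  fit <- lme4::glmer(f, family = stats::binomial(), data = dat, nAGQ = nAGQ)
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("GLMM did not converge (optimizer code ", conv, "); messages: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  structure(list(coef = beta, se = sqrt(diag(vc)), vcov = vc,
                 tau = sqrt(unname(unlist(lme4::VarCorr(fit)))[1]),
                 logLik = as.numeric(stats::logLik(fit)), nAGQ = nAGQ,
                 n = nrow(dat), fit = fit, design = design),
            class = "rsf_glmm")
}

#' Marginal log-likelihood of a random-intercept logistic model
#'
#' Integrates the per-group random intercept out of the Bernoulli
#' likelihood with adaptive Gauss-Hermite quadrature: per group the
#' integrand mode is located by Newton steps, and the quadrature rule is
#' recentered and rescaled there. With `adaptive = FALSE` a plain rule
#' centered at zero with scale `tau` is used.
#'
#' @param beta coefficient vector including intercept, ordered as
#'   `(intercept, covariates...)`.
#' @param tau random-intercept standard deviation, `>= 0`.
#' @param y 0/1 response.
#' @param X model matrix *without* intercept column.
#' @param group group id per row.
#' @param nodes number of quadrature nodes (default 25).
#' @param adaptive recenter the rule at the per-group mode (default `TRUE`).
#' @return marginal log-likelihood (scalar).
#' @export
glmm_marginal_loglik <- function(beta, tau, y, X, group, nodes = 25,
                                 adaptive = TRUE) {
  X <- as.matrix(X)
  eta0 <- beta[1] + X %*% beta[-1]
  gh <- gauss_hermite(nodes)
  total <- 0
  for (g in unique(group)) {
    i <- group == g
    yi <- y[i]; ei <- eta0[i]
    # log p(y_g | b) + log phi(b; 0, tau^2) and derivatives
    lf <- function(b) {
      p <- stats::plogis(ei + b)
      sum(stats::dbinom(yi, 1, p, log = TRUE)) +
        stats::dnorm(b, 0, tau, log = TRUE)
    }
    if (adaptive && tau > 0) {
      b <- 0
      for (it in 1:50) {
        p <- stats::plogis(ei + b)
        g1 <- sum(yi - p) - b / tau^2
        g2 <- -sum(p * (1 - p)) - 1 / tau^2
        step <- g1 / g2
        b <- b - step
        if (abs(step) < 1e-12) break
      }
      p <- stats::plogis(ei + b)
      sd_hat <- 1 / sqrt(sum(p * (1 - p)) + 1 / tau^2)
      z <- b + sqrt(2) * sd_hat * gh$x
      lw <- vapply(z, lf, numeric(1)) + gh$x^2 +
        log(sqrt(2) * sd_hat) + log(gh$w)
    } else if (tau > 0) {
      z <- sqrt(2) * tau * gh$x
      lw <- vapply(z, function(b) {
        p <- stats::plogis(ei + b)
        sum(stats::dbinom(yi, 1, p, log = TRUE))
      }, numeric(1)) + log(gh$w) - 0.5 * log(pi)
    } else {
      total <- total + sum(stats::dbinom(yi, 1, stats::plogis(ei), log = TRUE))
      next
    }
    m <- max(lw)
    total <- total + m + log(sum(exp(lw - m)))
  }
  total
}

# Golub-Welsch Gauss-Hermite nodes and weights (physicists' convention:
# integrates f against exp(-x^2))
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(sqrt(pi) * e$vectors[1, ]^2))
}

#' Per-increment odds ratios from standardized RSF coefficients
#'
#' Back-transforms each standardized coefficient to natural units
#' (`beta_raw = beta_std / sd`) and reports the odds ratio over a natural
#' increment (100 m for distance covariates, 10 percentage points for
#' canopy): `OR = exp(increment * beta_raw)`, with a 95% Wald CI transformed
#' the same way. A covariate is flagged significant when the CI excludes 1.
#'
#' @param fit `rsf_glm` or `rsf_glmm` object.
#' @param increments named vector of increments per covariate; defaults to
#'   100 for columns starting with `d_` and 10 for `canopy`.
#' @return data frame of class `odds_report`: `covariate`, `beta_std`, `se`,
#'   `increment`, `or`, `ci_low`, `ci_high`, `significant`.
#' @export
odds_per_increment <- function(fit, increments = NULL) {
  design <- fit$design
  cov_names <- design$covariates
  if (is.null(increments)) {
    increments <- ifelse(grepl("^d_", cov_names), 100, 10)
    names(increments) <- cov_names
  }
  st <- design$stats
  out <- lapply(cov_names, function(cl) {
    b <- fit$coef[[cl]]
    se <- fit$se[[cl]]
    s <- st$sd[st$column == cl]
    inc <- increments[[cl]]
    scale <- inc / s
    ci <- exp((b + c(-1, 1) * 1.96 * se) * scale)
    data.frame(covariate = cl, beta_std = b, se = se, increment = inc,
               or = exp(b * scale), ci_low = ci[1], ci_high = ci[2],
               significant = ci[1] > 1 | ci[2] < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("odds_report", class(out))
  out
}

#' Rank-based AUC (concordance)
#'
#' Fraction of used-available pairs in which the used point scores higher,
#' ties counted one half; equivalent to the area under the ROC curve.
#'
#' @param scores numeric scores (e.g. fitted linear predictors).
#' @param labels 0/1 (or logical) class labels; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a fitted RSF
#' @param fit `rsf_glm` or `rsf_glmm` object.
#' @return rank-based AUC of the fitted linear predictor against the
#'   used/available labels.
#' @export
auc_rsf <- function(fit) {
  dat <- fit$design$data
  X <- as.matrix(dat[fit$design$covariates])
  eta <- drop(fit$coef[1] + X %*% fit$coef[-1])
  auc_rank(eta, dat$y)
}
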