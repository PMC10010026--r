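#' @importFrom stats pnorm qnorm plogis qlogis optim optimHess
NULL

new_pooled_result <- function(log_effect, se, measure, model, n_contributing,
                              alpha, converged = TRUE, diagnostics = NULL) {
  z_crit <- stats::qnorm(1 - alpha / 2)
  z <- if (is.finite(se) && se > 0) log_effect / se else NaN
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else NaN
  structure(list(
    log_effect = log_effect,
    se = se,
    ci_low = log_effect - z_crit * se,
    ci_high = log_effect + z_crit * se,
    p_value = p,
    measure = measure,
    model = model,
    n_contributing = n_contributing,
    alpha = alpha,
    converged = converged,
    diagnostics = diagnostics
  ), class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("pooled %s (%s model): %s = %.4f [%.4f, %.4f], p = %.4g\n",
              x$measure, x$model, x$measure, exp(x$log_effect),
              exp(x$ci_low), exp(x$ci_high), x$p_value))
  cat(sprintf("log scale: %.6f (SE %.6f); %d contributing studies%s\n",
              x$log_effect, x$se, x$n_contributing,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Per-study Peto contribution
#'
#' For a 2x2 table with `a` treatment cases out of `n1` and `c` control
#' cases out of `n2` (`N = n1 + n2`), the Peto method scores the study by
#' the observed-minus-expected treatment cases `O - E = a - (a+c) n1 / N`
#' and the hypergeometric variance
#' `V = (a+c)(N-a-c) n1 n2 / (N^2 (N-1))`. A double-zero study has
#' `O - E = V = 0`: it is invisible to this two-stage engine.
#'
#' @param t_cases,t_n,c_cases,c_n Scalar (or vector) study counts.
#' @return A list of numeric vectors `o_minus_e` and `v`.
#' @export
study_peto_contribution <- function(t_cases, t_n, c_cases, c_n) {
  a <- t_cases; c_ <- c_cases; n1 <- t_n; n2 <- c_n
  N <- n1 + n2
  m1 <- a + c_
  e <- m1 * n1 / N
  v <- m1 * (N - m1) * n1 * n2 / (N^2 * (N - 1))
  list(o_minus_e = a - e, v = v)
}

#' Pool a meta-analysis with the two-stage Peto odds ratio
#'
#' Fixed-effect pooled log OR `sum(O-E) / sum(V)` with standard error
#' `1 / sqrt(sum(V))` and a two-sided normal p-value. No continuity
#' correction is applied anywhere: single-zero studies enter natively and
#' double-zero studies contribute nothing.
#'
#' @param ds A [meta_dataset()].
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `pooled_result` with `measure = "OR"`.
#' @export
peto_pool <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "meta_dataset"))
  contrib <- study_peto_contribution(ds$t_cases, ds$t_n, ds$c_cases, ds$c_n)
  sv <- sum(contrib$v)
  if (sv <= 0) stop("no informative studies: every Peto variance is zero",
                    call. = FALSE)
  so <- sum(contrib$o_minus_e)
  new_pooled_result(
    log_effect = so / sv,
    se = 1 / sqrt(sv),
    measure = "OR", model = "peto",
    n_contributing = sum(contrib$v > 0),
    alpha = alpha
  )
}

#' Pool a meta-analysis with the Mantel-Haenszel risk ratio
#'
#' Pooled RR `sum(a n2 / N) / sum(c n1 / N)` with the Greenland-Robins
#' variance estimator for the log RR. Studies with no cases in either arm
#' contribute zero to every sum. Zero cells enter as zeros; no continuity
#' correction.
#'
#' @inheritParams peto_pool
#' @return A `pooled_result` with `measure = "RR"`.
#' @export
mh_rr_pool <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "meta_dataset"))
  a <- ds$t_cases; c_ <- ds$c_cases; n1 <- ds$t_n; n2 <- ds$c_n
  N <- n1 + n2
  num <- sum(a * n2 / N)
  den <- sum(c_ * n1 / N)
  if (num <= 0 || den <= 0) {
    stop("RR undefined: a pooled arm has no cases; use the OR measure",
         call. = FALSE)
  }
  p_terms <- ((a + c_) * n1 * n2 / N^2) - (a * c_ / N)
  var_log_rr <- sum(p_terms) / (num * den)
  new_pooled_result(
    log_effect = log(num / den),
    se = sqrt(var_log_rr),
    measure = "RR", model = "mh",
    n_contributing = sum(a + c_ > 0),
    alpha = alpha
  )
}

#' Beta-binomial log-likelihood for a one-stage meta-analysis
#'
#' The model treats each arm of each study as one beta-binomial
#' observation: cases `y` out of `n` follow `BetaBin(n, mu, rho)` where
#' `logit(mu) = intercept + effect * treat` (`treat` is 1 for treatment
#' arms, 0 for control) and `rho` in (0,1) is a shared overdispersion
#' parameter (the within-arm beta correlation). Writing
#' `s = (1 - rho) / rho`, the beta shape parameters are `a = mu * s` and
#' `b = (1 - mu) * s`, and each arm contributes
#' `lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)`.
#' Double-zero studies are informative here: their terms depend on the
#' parameters. This function is the single source of truth for the model;
#' the fitting routine and its test oracle both maximize it.
#'
#' @param par Numeric vector `c(intercept, effect, logit_rho)`.
#' @param y,n,treat Parallel vectors over arms: cases, sample sizes, and
#'   the 0/1 treatment indicator.
#' @return The log-likelihood (scalar); `-Inf` when not finite.
#' @export
betabin_loglik <- function(par, y, n, treat) {
  mu <- stats::plogis(par[1] + par[2] * treat)
  rho <- stats::plogis(par[3])
  s <- (1 - rho) / rho
  a <- mu * s
  b <- (1 - mu) * s
  ll <- sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
  if (!is.finite(ll)) -Inf else ll
}

#' Pool a meta-analysis with the one-stage beta-binomial model
#'
#' Maximizes [betabin_loglik()] over the intercept, the treatment effect
#' (a log odds ratio) and the overdispersion, from several deterministic
#' starting points (effect in -1, 0, 1). The parameter space is the box
#' `intercept, effect` in \[-15, 15\] and `logit(rho)` in \[-12, 8\]: the
#' lower overdispersion bound (rho about 6e-6) is the model's binomial
#' limit at realistic sample sizes. The standard error of the effect comes
#' from the observed information matrix; the p-value is a Wald test.
#' Non-convergence is flagged in `converged`, never silently swallowed.
#'
#' @inheritParams peto_pool
#' @return A `pooled_result` with `measure = "OR"`, `model = "betabin"`.
#' @export
betabin_pool <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "meta_dataset"))
  if (nrow(ds) < 2) stop("beta-binomial pooling needs at least 2 studies",
                         call. = FALSE)
  if (sum(ds$t_cases) + sum(ds$c_cases) < 1) {
    stop("beta-binomial pooling needs at least one case overall",
         call. = FALSE)
  }
  y <- c(ds$t_cases, ds$c_cases)
  n <- c(ds$t_n, ds$c_n)
  treat <- c(rep(1, nrow(ds)), rep(0, nrow(ds)))

  p_bar <- max(min(sum(y) / sum(n), 0.99), 1e-4)
  int0 <- stats::qlogis(p_bar)
  starts <- lapply(c(0, -1, 1), function(b) c(int0, b, stats::qlogis(0.05)))

  # logit(rho) is kept above -12: below rho ~ 6e-6 the beta-binomial is
  # numerically indistinguishable from its binomial limit and the lbeta
  # differences lose precision to cancellation
  lower <- c(-15, -15, -12)
  upper <- c(15, 15, 8)
  neg_ll <- function(par) -betabin_loglik(par, y, n, treat)
  fits <- lapply(starts, function(st) {
    tryCatch(
      stats::optim(st, neg_ll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 1000)),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    return(new_pooled_result(NaN, NaN, "OR", "betabin", nrow(ds), alpha,
                             converged = FALSE,
                             diagnostics = "all optimizer starts failed"))
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  # keep the earliest start among ties so the symmetric case stays at 0
  best <- fits[[which(vals <= min(vals) + 1e-9)[1]]]

  converged <- best$convergence == 0
  se <- NaN
  diag_msg <- NULL
  hess <- tryCatch(stats::optimHess(best$par, neg_ll), error = function(e) NULL)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && is.finite(vc[2, 2]) && vc[2, 2] > 0) {
      se <- sqrt(vc[2, 2])
    } else {
      converged <- FALSE
      diag_msg <- "observed information not positive definite"
    }
  } else {
    converged <- FALSE
    diag_msg <- "Hessian evaluation failed"
  }
  if (best$convergence != 0) {
    diag_msg <- paste(c(diag_msg,
                        sprintf("optim convergence code %d", best$convergence)),
                      collapse = "; ")
  }
  res <- new_pooled_result(
    log_effect = best$par[2],
    se = se,
    measure = "OR", model = "betabin",
    n_contributing = nrow(ds),
    alpha = alpha,
    converged = converged,
    diagnostics = diag_msg
  )
  res$loglik <- -best$value
  res$par <- c(intercept = best$par[1], effect = best$par[2],
               logit_rho = best$par[3])
  res
}

#' Pool a dataset with the requested engine
#'
#' Dispatches to [peto_pool()], [mh_rr_pool()] or [betabin_pool()]. Only
#' the pairings the method supports are allowed: Peto and beta-binomial
#' estimate an odds ratio; Mantel-Haenszel estimates a risk ratio (the
#' Peto method cannot produce an RR).
#'
#' @param ds A [meta_dataset()].
#' @param model One of `"peto"`, `"mh"`, `"betabin"`.
#' @param alpha Two-sided significance level.
#' @return A `pooled_result`.
#' @export
pool_meta <- function(ds, model = c("peto", "mh", "betabin"), alpha = 0.05) {
  model <- match.arg(model)
  switch(model,
    peto = peto_pool(ds, alpha),
    mh = mh_rr_pool(ds, alpha),
    betabin = betabin_pool(ds, alpha)
  )
}

#' Direction and significance of a pooled result
#'
#' Direction is the sign of the pooled log-effect (a pooled OR/RR of
#' exactly 1 maps to 0, which downstream change detection never treats as
#' a crossing). Significance is the strict comparison `p < alpha`.
#'
#' @param r A `pooled_result`.
#' @param alpha Two-sided significance level.
#' @return A list with `direction` (-1, 0, or 1) and `significant`
#'   (logical).
#' @export
significance_and_direction <- function(r, alpha = 0.05) {
  stopifnot(inherits(r, "pooled_result"))
  list(direction = sign(r$log_effect),
       significant = is.finite(r$p_value) && r$p_value < alpha)
}
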