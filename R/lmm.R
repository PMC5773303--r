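# Shared dense-likelihood machinery for the spatial mixed model and the
# weighted spatial GLS. Everything is ML; sizes here are a few hundred
# records, so dense Cholesky factorizations are the right tool.

# Cholesky-based Gaussian GLS given a correlation-scale covariance V0
# (V = s2 * V0, s2 profiled out). Returns profiled ML loglik and pieces.
gls_profile <- function(y, X, V0) {
  n <- length(y)
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  # whiten: solve L' u = x  =>  u = backsolve(L, x, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  Xty <- crossprod(Xw, yw)
  beta <- tryCatch(drop(solve(XtX, Xty)), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  r <- yw - Xw %*% beta
  q <- sum(r^2)
  s2 <- q / n
  logdet <- 2 * sum(log(diag(L)))
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) - 0.5 * logdet - 0.5 * n
  list(beta = beta, s2 = s2, loglik = ll, XtX = XtX, L = L)
}

exp_corr <- function(D, rho, jitter = 1e-8) {
  C <- exp(-D / rho)
  diag(C) <- diag(C) + jitter
  C
}

#' Evaluate the spatial mixed-model log-likelihood at given parameters
#'
#' Marginal Gaussian log-density of `y` under mean `X beta` and covariance
#' `V = sigma2_year Z Z' + sigma2_resid C(rho)`, with `Z` the year indicator
#' matrix and `C(rho)_ij = exp(-d_ij / rho)` over Euclidean distance between
#' the supplied coordinates. Used directly by the fitter and available for
#' external verification at arbitrary parameter values.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (with intercept column).
#' @param year per-record collection year (grouping factor).
#' @param coords numeric matrix of per-record coordinates.
#' @param beta fixed effects; `sigma2_year`, `sigma2_resid`, `rho` variance
#'   components and correlation range.
#' @param jitter diagonal ridge keeping the correlation PSD at duplicate
#'   coordinates.
#' @return log-likelihood (scalar).
#' @export
lmm_loglik <- function(y, X, year, coords, beta, sigma2_year, sigma2_resid,
                       rho, jitter = 1e-8) {
  n <- length(y)
  D <- as.matrix(stats::dist(coords))
  Zt <- outer(year, year, `==`) + 0
  V <- sigma2_year * Zt + sigma2_resid * exp_corr(D, rho, jitter)
  L <- chol(V)
  r <- y - drop(X %*% beta)
  rw <- backsolve(L, r, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(rw^2)
}

lmm_term_labels <- c("ffd", "precip", "ffd:precip")

# design matrix from scaled climate columns for a subset of the term set
lmm_design <- function(data, fixed_terms) {
  stopifnot(all(fixed_terms %in% lmm_term_labels))
  if ("ffd:precip" %in% fixed_terms &&
      !all(c("ffd", "precip") %in% fixed_terms))
    stop("interaction requires both main effects")
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  if ("ffd" %in% fixed_terms) X <- cbind(X, ffd = data$scaled_ffd)
  if ("precip" %in% fixed_terms) X <- cbind(X, precip = data$scaled_precip)
  if ("ffd:precip" %in% fixed_terms)
    X <- cbind(X, "ffd:precip" = data$scaled_ffd * data$scaled_precip)
  X
}

lmm_response <- function(data, response) {
  switch(response,
         log_svl_female = ,
         log_svl_male = log(data$svl_mm),
         julian_day = as.numeric(data$julian_day),
         stop("unknown response: ", response))
}

lmm_subset <- function(data, response) {
  switch(response,
         log_svl_female = data[data$sex == "female", , drop = FALSE],
         log_svl_male = data[data$sex == "male", , drop = FALSE],
         julian_day = data,
         stop("unknown response: ", response))
}

#' Fit a climate--trait spatial linear mixed model by ML
#'
#' Fits `y = X beta + u_year + e` where the collection-year intercepts
#' `u_year` have variance `sigma2_year` and the residual `e` is Gaussian with
#' exponential spatial correlation `exp(-d/rho)` (variance `sigma2_resid`)
#' over Euclidean distance between the records' coordinates. `log SVL`
#' responses are fit per sex; Julian day pools sexes. Estimation is full ML:
#' the residual variance is profiled analytically and
#' `(log(sigma2_year/sigma2_resid), log rho)` is optimized by Nelder--Mead
#' from several deterministic starting points spanning the observed distance
#' scale.
#'
#' @param data specimen data.frame with `svl_mm`, `julian_day`, `sex`,
#'   `year`, `scaled_ffd`, `scaled_precip` and the coordinate columns.
#' @param response one of `"log_svl_female"`, `"log_svl_male"`,
#'   `"julian_day"`.
#' @param fixed_terms subset of `c("ffd", "precip", "ffd:precip")`
#'   (`character(0)` for intercept-only); the interaction requires both main
#'   effects.
#' @param coords coordinate column names. Defaults to latitude, longitude and
#'   elevation in native units; set `scale_coords = TRUE` to standardize each
#'   axis to unit SD first (otherwise elevation in metres dominates the
#'   distances).
#' @param scale_coords standardize coordinate axes before distances.
#' @param jitter diagonal ridge on the correlation (duplicate coordinates).
#' @param n_starts number of optimizer starting points (>= 1).
#' @return object of class `lmm_fit`: `beta`, `se_beta`, `vcov_beta`,
#'   `sigma2_year`, `sigma2_resid`, `rho`, `loglik`, `n`, `k`, `aicc`,
#'   `r2_marginal`, `r2_conditional`, `converged`, plus the design pieces.
#' @export
fit_lmm <- function(data, response, fixed_terms = character(0),
                    coords = c("lat", "lon", "elev_m"),
                    scale_coords = FALSE, jitter = 1e-8, n_starts = 5) {
  data <- lmm_subset(data, response)
  n <- nrow(data)
  if (n < 10) stop("need at least 10 records, got ", n)
  if (length(unique(data$year)) < 2) stop("need >= 2 distinct years")
  y <- lmm_response(data, response)
  X <- lmm_design(data, fixed_terms)
  cm <- as.matrix(data[, coords, drop = FALSE])
  if (scale_coords) cm <- scale(cm)
  D <- as.matrix(stats::dist(cm))
  Zt <- outer(data$year, data$year, `==`) + 0

  dpos <- D[upper.tri(D)]
  dmed <- stats::median(dpos[dpos > 0])
  if (!isTRUE(dmed > 0)) dmed <- 1
  starts <- matrix(c(-3, log(dmed),
                     -3, log(0.1 * dmed),
                     0, log(dmed),
                     0, log(0.3 * dmed),
                     -1.5, log(3 * dmed)),
                   ncol = 2, byrow = TRUE)
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]

  obj <- function(par) {
    g <- exp(min(par[1], 20)); rho <- exp(par[2])
    if (!is.finite(g) || !is.finite(rho) || rho <= 0) return(1e10)
    V0 <- g * Zt + exp_corr(D, rho, jitter)
    p <- gls_profile(y, X, V0)
    if (is.null(p) || !is.finite(p$loglik)) return(1e10)
    -p$loglik
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  par <- best$par
  g <- exp(par[1]); rho <- exp(par[2])
  V0 <- g * Zt + exp_corr(D, rho, jitter)
  p <- gls_profile(y, X, V0)
  sigma2_resid <- p$s2
  sigma2_year <- g * p$s2
  vcov_beta <- p$s2 * solve(p$XtX)
  se_beta <- sqrt(diag(vcov_beta))
  kpar <- ncol(X) + 3L
  varF <- stats::var(drop(X %*% p$beta))
  denom <- varF + sigma2_year + sigma2_resid
  fit <- structure(list(
    response = response, fixed_terms = fixed_terms,
    beta = stats::setNames(drop(p$beta), colnames(X)),
    se_beta = stats::setNames(se_beta, colnames(X)),
    vcov_beta = vcov_beta,
    sigma2_year = sigma2_year, sigma2_resid = sigma2_resid, rho = rho,
    loglik = p$loglik, n = n, k = kpar,
    aicc = aicc(p$loglik, kpar, n),
    r2_marginal = varF / denom,
    r2_conditional = (varF + sigma2_year) / denom,
    converged = best$convergence == 0,
    y = y, X = X, year = data$year, coords = cm, jitter = jitter
  ), class = "lmm_fit")
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s ~ %s | n=%d logLik=%.3f AICc=%.3f R2m=%.3f R2c=%.3f\n",
              x$response,
              if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ")
              else "1",
              x$n, x$loglik, x$aicc, x$r2_marginal, x$r2_conditional))
  print(data.frame(estimate = x$beta, se = x$se_beta))
  cat(sprintf("sigma2_year=%.4g sigma2_resid=%.4g rho=%.4g\n",
              x$sigma2_year, x$sigma2_resid, x$rho))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized log-likelihood; `k` parameter count; `n` sample
#'   size (`n > k + 1`).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) stop("AICc needs n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' The five-candidate climate model set
#'
#' All admissible combinations of FFD, precipitation and their interaction,
#' plus an intercept-only model: `{1}, {FFD}, {P}, {FFD+P}, {FFD+P+FFD:P}`.
#'
#' @return named list of term-character vectors.
#' @export
candidate_terms <- function() {
  list("1" = character(0),
       "ffd" = "ffd",
       "precip" = "precip",
       "ffd+precip" = c("ffd", "precip"),
       "ffd*precip" = c("ffd", "precip", "ffd:precip"))
}

#' Fit the full candidate model set
#'
#' @param data,response,... passed to [fit_lmm()].
#' @return named list of `lmm_fit`s, one per member of [candidate_terms()].
#' @export
fit_candidates <- function(data, response, ...) {
  lapply(candidate_terms(), function(tt)
    fit_lmm(data, response, fixed_terms = tt, ...))
}

#' AICc ranking and full model averaging
#'
#' Ranks fits by AICc, computes Akaike weights, and averages coefficients
#' over the substantial-support set (`delta AICc <= delta_max`) with
#' zero-substitution ("full") averaging: a model not containing a term
#' contributes estimate 0 with SE 0. Unconditional SEs follow
#' `sum_i w_i sqrt(se_i^2 + (b_i - b_avg)^2)`; 95% CIs are `+/- 1.96 SE` and
#' a term is flagged significant when its CI excludes zero. Non-converged
#' fits are excluded from the support set with a warning.
#'
#' @param fits list of `lmm_fit` (or `change_gls_fit`) objects on identical
#'   data.
#' @param delta_max support threshold on delta AICc.
#' @return object of class `model_selection`: `table` (model, loglik, k,
#'   aicc, delta, weight), `support` (model names averaged), `averaged`
#'   (term, estimate, se, lower, upper, significant), `best` (name of the
#'   top-ranked model).
#' @export
select_and_average <- function(fits, delta_max = 2) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f)
      if (length(f$fixed_terms)) paste(f$fixed_terms, collapse = "+")
      else "1", "")
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1) stop("fits must share the same data")
  av <- vapply(fits, function(f) f$aicc, 0)
  ll <- vapply(fits, function(f) f$loglik, 0)
  kk <- vapply(fits, function(f) f$k, 0)
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  delta <- av - min(av[conv])
  w <- exp(-delta / 2) * conv
  w <- w / sum(w)
  r2m <- vapply(fits, function(f)
    if (is.null(f$r2_marginal)) NA_real_ else f$r2_marginal, 0)
  r2c <- vapply(fits, function(f)
    if (is.null(f$r2_conditional)) NA_real_ else f$r2_conditional, 0)
  tab <- data.frame(model = names(fits), loglik = ll, k = kk, aicc = av,
                    delta = delta, weight = w,
                    r2_marginal = r2m, r2_conditional = r2c,
                    converged = conv, stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL

  support <- names(fits)[delta <= delta_max]
  if (any(!conv[support])) {
    warning("dropping non-converged fit(s) from the averaging set: ",
            paste(support[!conv[support]], collapse = ", "))
    support <- support[conv[support]]
  }
  if (length(support) == 0) stop("empty averaging set")
  ws <- w[support] / sum(w[support])

  all_terms <- unique(unlist(lapply(fits[support],
                                    function(f) names(f$beta))))
  rows <- lapply(all_terms, function(tm) {
    est <- se <- numeric(length(support))
    for (i in seq_along(support)) {
      f <- fits[[support[i]]]
      j <- match(tm, names(f$beta))
      if (!is.na(j)) { est[i] <- f$beta[j]; se[i] <- f$se_beta[j] }
    }
    b <- sum(ws * est)
    use <- sum(ws * sqrt(se^2 + (est - b)^2))
    data.frame(term = tm, estimate = b, se = use,
               lower = b - 1.96 * use, upper = b + 1.96 * use,
               significant = (b - 1.96 * use > 0) | (b + 1.96 * use < 0),
               stringsAsFactors = FALSE)
  })
  structure(list(table = tab, support = support,
                 averaged = do.call(rbind, rows),
                 best = tab$model[1]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> best:", x$best, "| averaged over:",
      paste(x$support, collapse = ", "), "\n")
  print(x$table, digits = 4)
  print(x$averaged, digits = 4)
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-component decomposition: with `varF` the variance of the
#' fixed-effect linear predictor, `R2m = varF / (varF + sigma2_year +
#' sigma2_resid)` (fixed effects alone) and `R2c = (varF + sigma2_year) /
#' (same)` (fixed plus random).
#'
#' @param fit an `lmm_fit`.
#' @return named vector `c(r2_marginal=, r2_conditional=)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  c(r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional)
}

#' Likelihood ratio test between nested ML fits
#'
#' @param full,reduced `lmm_fit`s on the same data, `reduced` nested in
#'   `full`.
#' @return named vector `c(chi2=, df=, p=)`; `chi2` floored at zero.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$fixed_terms %in% full$fixed_terms) ||
      full$n != reduced$n || full$response != reduced$response)
    stop("models are not nested on the same data")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$k - reduced$k
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
       else if (chi2 <= 1e-12) 1 else NA_real_
  c(chi2 = chi2, df = df, p = p)
}
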