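# Weighted spatial GLS of trait change on proportional climate change:
# second-order polynomial fixed effects, exponential residual correlation
# over (lon, lat), per-point precision weights from the pooled bootstrap SE.

#' Sample random change points from the valid-data mask
#'
#' Uniform without-replacement sample of cells that are inside the range
#' mask and have finite trait-change and climate-change values; each point
#' sits at its cell centre. Deterministic under `seed`.
#'
#' @param chg a `change_map` (per-trait delta and pooled SE).
#' @param prop a `change_rasters` (proportional climate change).
#' @param n number of points (default 484).
#' @param seed integer seed.
#' @param extra_deltas optional named list of further `change_map`s to
#'   extract at the same points (one shared draw for all responses).
#' @return data.frame of class `change_points`: lon, lat, row, col,
#'   delta_trait, prop_dffd, prop_dprecip, pooled_se, weight (normalized
#'   1/pooled_se^2), plus a `delta_<name>`/`se_<name>` pair per extra map.
#' @export
sample_change_points <- function(chg, prop, n = 484, seed = 1L,
                                 extra_deltas = NULL) {
  stopifnot(inherits(chg, "change_map"), inherits(prop, "change_rasters"))
  if (!grid_same(chg$grid, prop$grid)) stop("grids differ")
  ok <- chg$mask & is.finite(chg$delta) & is.finite(chg$pooled_se) &
    is.finite(prop$prop_change$ffd) & is.finite(prop$prop_change$precipitation)
  for (ex in extra_deltas) ok <- ok & is.finite(ex$delta)
  idx <- which(ok)
  if (length(idx) < n)
    stop("only ", length(idx), " valid cells for ", n, " requested points")
  set.seed(seed)
  pick <- if (length(idx) == n) idx else sort(sample(idx, n))
  g <- chg$grid
  row <- ((pick - 1L) %% g$nrow) + 1L
  col <- ((pick - 1L) %/% g$nrow) + 1L
  out <- data.frame(
    lon = g$xll + (col - 0.5) * g$cellsize,
    lat = g$yll + (g$nrow - row + 0.5) * g$cellsize,
    row = row, col = col,
    delta_trait = chg$delta[pick],
    prop_dffd = prop$prop_change$ffd[pick],
    prop_dprecip = prop$prop_change$precipitation[pick],
    pooled_se = chg$pooled_se[pick]
  )
  for (nm in names(extra_deltas)) {
    out[[paste0("delta_", nm)]] <- extra_deltas[[nm]]$delta[pick]
    out[[paste0("se_", nm)]] <- extra_deltas[[nm]]$pooled_se[pick]
  }
  out$weight <- (1 / out$pooled_se^2)
  out$weight <- out$weight / mean(out$weight)
  class(out) <- c("change_points", "data.frame")
  out
}

gls_term_labels <- c("F", "F2", "P", "P2", "F:P")

# polynomial design over raw proportional changes (not re-centred: the
# values are already proportional to pre-warming levels)
gls_design <- function(points, terms) {
  stopifnot(all(terms %in% gls_term_labels))
  if ("F2" %in% terms && !"F" %in% terms)
    stop("quadratic FFD term requires the linear term")
  if ("P2" %in% terms && !"P" %in% terms)
    stop("quadratic precipitation term requires the linear term")
  if ("F:P" %in% terms && !all(c("F", "P") %in% terms))
    stop("interaction requires both linear terms")
  f <- points$prop_dffd; p <- points$prop_dprecip
  X <- matrix(1, nrow(points), 1, dimnames = list(NULL, "(Intercept)"))
  if ("F" %in% terms) X <- cbind(X, F = f)
  if ("F2" %in% terms) X <- cbind(X, F2 = f^2)
  if ("P" %in% terms) X <- cbind(X, P = p)
  if ("P2" %in% terms) X <- cbind(X, P2 = p^2)
  if ("F:P" %in% terms) X <- cbind(X, "F:P" = f * p)
  X
}

#' Weighted spatial GLS of trait change on climate change
#'
#' ML fit of `delta_trait = X beta + e` with covariance
#' `sigma2 * W^(-1/2) C(rho) W^(-1/2)`: `C` the exponential correlogram over
#' (lon, lat) Euclidean distance and `W = diag(weight)` per-point precision,
#' so points mapped with low pooled SE carry more weight. `sigma2` is
#' profiled analytically; `log rho` is optimized by 1-D Nelder--Mead from
#' several deterministic starts.
#'
#' @param points a `change_points` data.frame (or any data.frame with
#'   `lon`, `lat`, `prop_dffd`, `prop_dprecip`, `weight` and the response).
#' @param terms subset of `c("F", "F2", "P", "P2", "F:P")` respecting
#'   marginality (quadratics need their linear term; interaction needs both
#'   linear terms). `character(0)` = intercept-only.
#' @param response column holding the trait change (default `delta_trait`).
#' @param weight_mode `"precision"` (1/se^2, the default) or `"inverse_se"`
#'   (1/se).
#' @param jitter diagonal ridge on the correlation.
#' @return object of class `change_gls_fit` with `beta`, `se_beta`, `lower`,
#'   `upper`, `significant`, `sigma2`, `rho`, `loglik`, `n`, `k`, `aicc`,
#'   `converged`, `fixed_terms`.
#' @export
fit_change_gls <- function(points, terms, response = "delta_trait",
                           weight_mode = c("precision", "inverse_se"),
                           jitter = 1e-8) {
  weight_mode <- match.arg(weight_mode)
  y <- points[[response]]
  X <- gls_design(points, terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("singular design; collinear term(s): ", paste(bad, collapse = ", "))
  }
  n <- length(y)
  w <- if (weight_mode == "precision") points$weight
       else {
         wi <- sqrt(points$weight)   # weight column is 1/se^2-normalized
         wi / mean(wi)
       }
  sw <- 1 / sqrt(w)                  # W^(-1/2) diagonal
  D <- as.matrix(stats::dist(cbind(points$lon, points$lat)))
  dpos <- D[upper.tri(D)]
  dmed <- stats::median(dpos[dpos > 0])
  if (!isTRUE(dmed > 0)) dmed <- 1

  obj <- function(lrho) {
    rho <- exp(lrho)
    V0 <- outer(sw, sw) * exp_corr(D, rho, jitter)
    p <- gls_profile(y, X, V0)
    if (is.null(p) || !is.finite(p$loglik)) return(1e10)
    -p$loglik
  }
  best <- NULL
  for (st in log(dmed * c(0.05, 0.3, 1, 3))) {
    o <- stats::optim(st, obj, method = "Brent",
                      lower = st - 8, upper = st + 8)
    if (is.null(best) || o$value < best$value) best <- o
  }
  rho <- exp(best$par)
  V0 <- outer(sw, sw) * exp_corr(D, rho, jitter)
  p <- gls_profile(y, X, V0)
  vcov_beta <- p$s2 * solve(p$XtX)
  se <- sqrt(diag(vcov_beta))
  kpar <- ncol(X) + 2L
  beta <- stats::setNames(drop(p$beta), colnames(X))
  lower <- beta - 1.96 * se
  upper <- beta + 1.96 * se
  structure(list(
    fixed_terms = terms, response = response,
    beta = beta, se_beta = stats::setNames(se, colnames(X)),
    vcov_beta = vcov_beta,
    lower = lower, upper = upper,
    significant = lower > 0 | upper < 0,
    sigma2 = p$s2, rho = rho,
    loglik = p$loglik, n = n, k = kpar,
    aicc = aicc(p$loglik, kpar, n),
    converged = best$convergence == 0
  ), class = "change_gls_fit")
}

#' @export
print.change_gls_fit <- function(x, ...) {
  cat(sprintf("<change_gls_fit> %s ~ %s | n=%d logLik=%.3f AICc=%.3f rho=%.3g\n",
              x$response,
              if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ")
              else "1",
              x$n, x$loglik, x$aicc, x$rho))
  print(data.frame(estimate = x$beta, lower = x$lower, upper = x$upper,
                   significant = x$significant))
  invisible(x)
}

#' All marginality-respecting polynomial term sets
#'
#' The candidate set over `{F, F2, P, P2, F:P}` in which quadratics imply
#' their linear term and the interaction implies both linear terms; with
#' the intercept-only model, 11 candidates.
#'
#' @param include_intercept_only include the `{1}` model (default TRUE).
#' @return named list of term vectors.
#' @export
gls_candidate_terms <- function(include_intercept_only = TRUE) {
  sets <- list(
    "F" = "F",
    "P" = "P",
    "F+F2" = c("F", "F2"),
    "P+P2" = c("P", "P2"),
    "F+P" = c("F", "P"),
    "F+P+F:P" = c("F", "P", "F:P"),
    "F+F2+P" = c("F", "F2", "P"),
    "F+P+P2" = c("F", "P", "P2"),
    "F+F2+P+P2" = c("F", "F2", "P", "P2"),
    "F+F2+P+P2+F:P" = c("F", "F2", "P", "P2", "F:P")
  )
  if (include_intercept_only) sets <- c(list("1" = character(0)), sets)
  sets
}

#' Enumerate, rank and average the change-GLS candidate set
#'
#' Fits every candidate in [gls_candidate_terms()], ranks by AICc and
#' full-averages the substantial-support set via [select_and_average()].
#' Individual fit failures are collected; averaging proceeds over the
#' successes.
#'
#' @param points a `change_points` data.frame.
#' @param response trait-change column.
#' @param delta_max AICc support threshold.
#' @param ... passed to [fit_change_gls()].
#' @return list: `selection` (a `model_selection`), `fits`, `failed`
#'   (named list of error messages).
#' @export
enumerate_and_average <- function(points, response = "delta_trait",
                                  delta_max = 2, ...) {
  cand <- gls_candidate_terms()
  fits <- list(); failed <- list()
  for (nm in names(cand)) {
    f <- tryCatch(fit_change_gls(points, cand[[nm]], response = response,
                                 ...),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "change_gls_fit")) fits[[nm]] <- f
    else failed[[nm]] <- f
  }
  if (length(fits) < 2) stop("fewer than two candidate fits succeeded")
  list(selection = select_and_average(fits, delta_max = delta_max),
       fits = fits, failed = failed)
}

#' Partial-effect curves from an averaged polynomial fit
#'
#' Fitted trait change along one climate-change axis at fixed conditioning
#' values (low / median / high quantiles) of the other, from the averaged
#' coefficients; the curve for visualizing how e.g. intermediate FFD
#' increases map to the earliest breeding shifts.
#'
#' @param selection a `model_selection` from [enumerate_and_average()].
#' @param points the `change_points` used for fitting.
#' @param axis `"F"` or `"P"`.
#' @param cond_probs quantiles of the conditioning variable.
#' @param length_out curve resolution.
#' @return data.frame: axis value `x`, conditioning label and value,
#'   `fitted`.
#' @export
partial_effects <- function(selection, points, axis = c("F", "P"),
                            cond_probs = c(low = 0.1, median = 0.5,
                                           high = 0.9),
                            length_out = 101) {
  axis <- match.arg(axis)
  est <- stats::setNames(selection$averaged$estimate,
                         selection$averaged$term)
  co <- function(nm) if (nm %in% names(est)) est[[nm]] else 0
  fvals <- points$prop_dffd; pvals <- points$prop_dprecip
  xv <- if (axis == "F") fvals else pvals
  cv <- if (axis == "F") pvals else fvals
  xs <- seq(min(xv), max(xv), length.out = length_out)
  out <- lapply(names(cond_probs), function(lb) {
    cq <- stats::quantile(cv, cond_probs[[lb]], names = FALSE)
    f <- if (axis == "F") xs else cq
    p <- if (axis == "F") cq else xs
    fitted <- co("(Intercept)") + co("F") * f + co("F2") * f^2 +
      co("P") * p + co("P2") * p^2 + co("F:P") * f * p
    data.frame(x = xs, conditioning = lb, cond_value = cq, fitted = fitted)
  })
  do.call(rbind, out)
}
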