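# Thin-plate spline smoothing in 3 coordinates (order m = 2, so the radial
# kernel is phi(r) = -r, conditionally positive definite over the affine
# null space). Implemented via the null-space QR reduction: with T the
# affine basis and T = [Q1 Q2] R, the side condition T'c = 0 gives
# c = Q2 g and (Q2' K Q2 + n*lambda I) g = Q2' y. The matrix Q2' K Q2 is
# eigendecomposed once, making the whole lambda path (and hence GCV search)
# O(n) per candidate lambda.

tps_kernel <- function(D) -D

#' Fit a 3-D thin-plate spline
#'
#' Solves the penalized interpolation system
#' `[K + n lambda I, T; T', 0] [c; d] = [y; 0]` with kernel `phi(r) = -r`
#' over Euclidean distance between internally standardized coordinates
#' (each axis centred and scaled to unit SD, so elevation in metres does not
#' dominate degrees). `lambda = "auto"` picks the smoothing parameter
#' minimizing the GCV score `V(lambda) = n RSS / (n - tr A(lambda))^2` over
#' a log-spaced grid tied to the spectrum of the reduced kernel.
#'
#' @param coords numeric matrix (n x 3) of (lat, lon, elev) or any three
#'   coordinates; n >= 8 unique points, not all coplanar.
#' @param y response vector, length n.
#' @param lambda non-negative smoothing parameter, or `"auto"` for GCV.
#' @param weights optional positive observation weights (e.g. multiplicities
#'   of collapsed replicate observations); the penalized criterion becomes
#'   `sum_i w_i (y_i - f(x_i))^2 + N lambda J(f)` with `N = sum(w)`.
#' @return object of class `tps_fit`: `rbf_coeffs` (c), `affine_coeffs` (d),
#'   `lambda`, `gcv`, `fitted`, `knots` (standardized), standardization
#'   parameters, and the GCV path when auto-selected. Predict with
#'   [predict.tps_fit()].
#' @export
fit_tps <- function(coords, y, lambda = "auto", weights = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n == length(y), ncol(coords) == 3)
  if (n < 8) stop("need at least 8 points for a 3-D thin-plate spline")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  ntot <- sum(weights)
  sw <- sqrt(weights)
  ctr <- colMeans(coords)
  scl <- apply(coords, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(coords, 2, ctr), 2, scl, "/")

  D <- as.matrix(stats::dist(Xs))
  K <- tps_kernel(D)
  Tm <- cbind(1, Xs)
  # weighted problem reduces to the unweighted one after scaling rows and
  # columns by sqrt(w): solve for c~ = sqrt(w) c in the scaled system
  Kw <- K * outer(sw, sw)
  Tw <- Tm * sw
  yw <- y * sw
  qrT <- qr(Tw)
  if (qrT$rank < 4)
    stop("coplanar/degenerate point configuration: affine basis is rank ",
         qrT$rank)
  Q <- qr.Q(qrT, complete = TRUE)
  Q2 <- Q[, 5:n, drop = FALSE]
  B <- crossprod(Q2, Kw %*% Q2)
  B <- (B + t(B)) / 2
  # fast path for a fixed positive lambda: single Cholesky solve of the
  # reduced system (no eigendecomposition, GCV trace not reported)
  if (is.numeric(lambda) && length(lambda) == 1 && lambda > 0 &&
      is.null(attr(lambda, "want_gcv"))) {
    nl <- ntot * lambda
    R <- tryCatch(chol(B + diag(nl, nrow(B))), error = function(e) NULL)
    if (!is.null(R)) {
      zq <- drop(crossprod(Q2, yw))
      g <- backsolve(R, backsolve(R, zq, transpose = TRUE))
      ct <- drop(Q2 %*% g)
      cc <- ct * sw
      d <- qr.coef(qrT, yw - Kw %*% ct - nl * ct)
      fitted <- drop(K %*% cc + Tm %*% d)
      return(structure(list(rbf_coeffs = cc, affine_coeffs = drop(d),
                            lambda = lambda, gcv = NA_real_,
                            fitted = fitted, y = y, weights = weights,
                            knots = Xs, center = ctr, scale = scl,
                            gcv_path = NULL, n = n),
                       class = "tps_fit"))
    }
  }

  eg <- eigen(B, symmetric = TRUE)
  z <- drop(crossprod(eg$vectors, crossprod(Q2, yw)))

  solve_lambda <- function(nl) {
    # nl = ntot * lambda
    g <- z / (eg$values + nl)
    ct <- drop(Q2 %*% (eg$vectors %*% g))     # c~ in the scaled system
    rss <- nl^2 * sum(ct^2)                   # weighted RSS
    tra <- n - nl * sum(1 / (eg$values + nl))
    list(ct = ct, rss = rss, tra = tra,
         gcv = ntot * rss / (ntot - tra)^2)
  }

  path <- NULL
  if (identical(lambda, "auto")) {
    scale0 <- mean(abs(eg$values))
    nl_grid <- scale0 * 10^seq(-8, 2, by = 0.25)
    gcvs <- vapply(nl_grid, function(nl) solve_lambda(nl)$gcv, 0)
    nl <- nl_grid[which.min(gcvs)]
    path <- data.frame(lambda = nl_grid / ntot, gcv = gcvs)
    lambda <- nl / ntot
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    nl <- ntot * lambda
  }

  if (nl == 0) {
    if (any(eg$values < 1e-10 * max(abs(eg$values))))
      stop("duplicate-heavy configuration: exact interpolation is singular; ",
           "use lambda > 0")
    sl <- solve_lambda(0)
  } else sl <- solve_lambda(nl)
  cc <- sl$ct * sw                            # back to c = sqrt(w) c~
  # affine part from the first (scaled) block: Tw d = yw - Kw c~ - nl c~
  d <- qr.coef(qrT, yw - Kw %*% sl$ct - nl * sl$ct)
  fitted <- drop(K %*% cc + Tm %*% d)

  structure(list(rbf_coeffs = cc, affine_coeffs = drop(d),
                 lambda = lambda, gcv = sl$gcv,
                 fitted = fitted, y = y, weights = weights,
                 knots = Xs, center = ctr, scale = scl,
                 gcv_path = path, n = n),
            class = "tps_fit")
}

#' Predict from a thin-plate spline fit
#'
#' @param object a `tps_fit`.
#' @param newcoords matrix (m x 3) in the same native units as the training
#'   coordinates.
#' @param ... unused.
#' @return vector of m predictions.
#' @export
predict.tps_fit <- function(object, newcoords, ...) {
  newcoords <- as.matrix(newcoords)
  Xs <- sweep(sweep(newcoords, 2, object$center), 2, object$scale, "/")
  out <- numeric(nrow(Xs))
  # block over prediction points to bound memory on large grids
  blk <- 2000L
  kn <- object$knots
  for (s in seq(1L, nrow(Xs), by = blk)) {
    e <- min(s + blk - 1L, nrow(Xs))
    xb <- Xs[s:e, , drop = FALSE]
    d2 <- outer(xb[, 1], kn[, 1], `-`)^2 + outer(xb[, 2], kn[, 2], `-`)^2 +
      outer(xb[, 3], kn[, 3], `-`)^2
    out[s:e] <- tps_kernel(sqrt(d2)) %*% object$rbf_coeffs +
      cbind(1, Xs[s:e, , drop = FALSE]) %*% object$affine_coeffs
  }
  drop(out)
}

map_response <- function(records, response) {
  switch(response,
         svl_female = list(data = records[records$sex == "female", ,
                                          drop = FALSE], col = "svl_mm"),
         svl_male = list(data = records[records$sex == "male", ,
                                        drop = FALSE], col = "svl_mm"),
         julian_day = list(data = records, col = "julian_day"),
         stop("unknown map response: ", response))
}

#' Bootstrap thin-plate-spline trait maps
#'
#' Case-resamples the records `B` times; each replicate fits a GCV-smoothed
#' thin-plate spline of the trait on (lat, lon, elev) and predicts every
#' in-mask pixel (cell centres, elevation from the DEM band). Duplicated
#' draws within a replicate are collapsed to unique records with
#' multiplicity weights. Because a case resample carries no pure error at
#' duplicated records, per-replicate GCV tends toward light smoothing; the
#' resulting percentile intervals are wide (conservative) in data-dense
#' areas, which suits the CI-overlap change test downstream. Per pixel the
#' ensemble yields the mean surface, 2.5/97.5 percentile confidence bounds,
#' and the bootstrap SD (`pooled_se`). Per replicate the in-sample r-squared
#' (on the resample) and the out-of-bag mean squared prediction error are
#' recorded. Replicate `b` is seeded deterministically from `seed + b`, so
#' ensembles are reproducible. Replicates with fewer than 8 unique records
#' are redrawn (at most 10 times each) and counted.
#'
#' @param records one period's records (data.frame with `sex`, `svl_mm`,
#'   `julian_day`, `lat`, `lon`, `elev_m`).
#' @param response `"svl_female"`, `"svl_male"` (SVL in mm, sex-filtered) or
#'   `"julian_day"` (sexes pooled, breeding records only upstream).
#' @param grid a [trait_grid()]; `dem` elevation matrix and logical `mask`
#'   matrix on that grid.
#' @param B bootstrap replicates (default 100).
#' @param seed integer; replicate b uses `seed + b`.
#' @return object of class `map_ensemble`: `grid`, `mask`, matrices `mean`,
#'   `lo`, `hi`, `pooled_se` (NA outside mask), `r2_mean`, `r2` (per
#'   replicate), `mspe`, `mspe_mean`, `B`, `seed`, `n_records`, `redraws`.
#' @export
bootstrap_maps <- function(records, response, grid, dem, mask, B = 100,
                           seed = 1L) {
  mr <- map_response(records, response)
  dat <- mr$data
  n <- nrow(dat)
  if (n < 20) stop("need >= 20 records for bootstrap mapping, got ", n)
  stopifnot(B >= 2)
  coords <- as.matrix(dat[, c("lat", "lon", "elev_m")])
  yy <- as.numeric(dat[[mr$col]])

  cc <- grid_centers(grid)
  inmask <- mask[cbind(cc$row, cc$col)] & !is.na(dem[cbind(cc$row, cc$col)])
  px <- cbind(lat = cc$lat[inmask], lon = cc$lon[inmask],
              elev_m = dem[cbind(cc$row, cc$col)][inmask])
  npx <- nrow(px)

  preds <- matrix(NA_real_, B, npx)
  r2 <- mspe <- rep(NA_real_, B)
  redraws <- 0L
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0L
    while (length(unique(idx)) < 8 && tries < 10L) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- tries + 1L
      redraws <- redraws + 1L
    }
    if (length(unique(idx)) < 8)
      stop("could not draw a usable bootstrap replicate (too few unique points)")
    # duplicate draws collapse to unique records with multiplicity weights
    tb <- table(idx)
    uidx <- as.integer(names(tb))
    wts <- as.numeric(tb)
    fit <- fit_tps(coords[uidx, , drop = FALSE], yy[uidx], lambda = "auto",
                   weights = wts)
    preds[b, ] <- predict(fit, px)
    wbar <- sum(wts * fit$y) / sum(wts)
    r2[b] <- 1 - sum(wts * (fit$y - fit$fitted)^2) /
      sum(wts * (fit$y - wbar)^2)
    oob <- setdiff(seq_len(n), uidx)
    if (length(oob) > 0) {
      po <- predict(fit, coords[oob, , drop = FALSE])
      mspe[b] <- mean((yy[oob] - po)^2)
    }
  }

  put <- function(v) {
    m <- matrix(NA_real_, grid$nrow, grid$ncol)
    m[cbind(cc$row[inmask], cc$col[inmask])] <- v
    m
  }
  qs <- apply(preds, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  structure(list(grid = grid, mask = mask,
                 mean = put(colMeans(preds)),
                 lo = put(qs[1, ]), hi = put(qs[2, ]),
                 pooled_se = put(apply(preds, 2, stats::sd)),
                 r2 = r2, r2_mean = mean(r2),
                 mspe = mspe, mspe_mean = mean(mspe, na.rm = TRUE),
                 B = B, seed = seed, n_records = n, response = response,
                 redraws = redraws),
            class = "map_ensemble")
}

#' @export
print.map_ensemble <- function(x, ...) {
  cat(sprintf("<map_ensemble> %s, B=%d, n=%d, mean r2=%.3f, MSPE=%.4g\n",
              x$response, x$B, x$n_records, x$r2_mean, x$mspe_mean))
  invisible(x)
}

#' Trait change map with CI-overlap significance
#'
#' Per pixel: `delta = post mean - pre mean`; the change is significant
#' exactly where the two periods' 95% intervals are disjoint, and treated as
#' zero elsewhere (`delta_masked`). Also emits the pooled SE of the
#' difference, `sqrt(se_pre^2 + se_post^2)`, for downstream precision
#' weighting.
#'
#' @param pre,post `map_ensemble`s on the same grid.
#' @return object of class `change_map`: `grid`, `mask`, `delta`,
#'   `significant` (logical matrix), `delta_masked`, `pooled_se`.
#' @export
change_map <- function(pre, post) {
  stopifnot(inherits(pre, "map_ensemble"), inherits(post, "map_ensemble"))
  if (!grid_same(pre$grid, post$grid)) stop("ensembles are on different grids")
  delta <- post$mean - pre$mean
  significant <- (post$lo > pre$hi) | (post$hi < pre$lo)
  delta_masked <- ifelse(significant, delta, 0)
  delta_masked[is.na(delta)] <- NA
  structure(list(grid = pre$grid, mask = pre$mask,
                 delta = delta, significant = significant,
                 delta_masked = delta_masked,
                 pooled_se = sqrt(pre$pooled_se^2 + post$pooled_se^2)),
            class = "change_map")
}
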