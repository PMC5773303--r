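#' Extract climate at a point for one decade
#'
#' Returns the value of the 5-arc-minute cell containing the point (no
#' interpolation; half-open cell convention, see [cell_index()]).
#'
#' @param stack a `climate_stack`.
#' @param lat,lon point coordinates (vectorized).
#' @param decade decade label (as in `stack$decades$label`) or a calendar
#'   year, which is mapped to the decade whose interval contains it.
#' @param ids optional record ids used in error messages.
#' @return data.frame with columns `ffd`, `temperature`, `precipitation`.
#' @export
extract_at <- function(stack, lat, lon, decade, ids = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  if (is.numeric(decade)) {
    d <- findInterval(decade, stack$decades$start)
    if (any(d < 1 | decade > max(stack$decades$end)))
      stop("year(s) outside the decade coverage")
  } else {
    d <- match(decade, stack$decades$label)
    if (anyNA(d)) stop("unknown decade label(s): ",
                       paste(unique(decade[is.na(d)]), collapse = ", "))
  }
  n <- length(lat)
  d <- rep_len(d, n)
  ij <- cell_index(stack$grid, lon, lat)
  inside <- !is.na(ij$row) & !is.na(ij$col)
  inside[inside] <- stack$mask[cbind(ij$row[inside], ij$col[inside])]
  if (!all(inside)) {
    lab <- if (is.null(ids)) which(!inside) else ids[!inside]
    stop("point(s) outside the range mask: ",
         paste(utils::head(lab, 5), collapse = ", "))
  }
  out <- data.frame(ffd = numeric(n), temperature = numeric(n),
                    precipitation = numeric(n))
  for (dd in unique(d)) {
    sel <- d == dd
    idx <- cbind(ij$row[sel], ij$col[sel])
    out$ffd[sel] <- stack$values$ffd[[dd]][idx]
    out$temperature[sel] <- stack$values$temperature[[dd]][idx]
    out$precipitation[sel] <- stack$values$precipitation[[dd]][idx]
  }
  out
}

#' t statistic of a Pearson correlation
#'
#' `t = r * sqrt(df / (1 - r^2))`, the usual test of a correlation
#' coefficient against zero on `df` degrees of freedom.
#'
#' @param r correlation, `|r| < 1`.
#' @param df degrees of freedom (n - 2), `>= 1`.
#' @return the t statistic (vectorized over `r`).
#' @export
pearson_t <- function(r, df) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  if (any(df < 1)) stop("df must be >= 1")
  r * sqrt(df / (1 - r^2))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor j
#' on all the others (with intercept). Perfectly collinear predictors report
#' `Inf` rather than erroring.
#'
#' @param X numeric matrix or data.frame of predictor columns (>= 2).
#' @return named vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(res^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Centre and scale a column, keeping the transform
#'
#' z-scores with the sample SD (n-1 denominator). The returned transform can
#' be applied to new data so fitted-model coefficients stay interpretable.
#'
#' @param x numeric vector with positive SD.
#' @return list of class `scale_transform`: `z`, `mean`, `sd`, and
#'   `apply(newx)`.
#' @export
center_scale <- function(x) {
  s <- stats::sd(x)
  if (!isTRUE(s > 0)) stop("cannot scale a constant column")
  m <- mean(x)
  structure(list(z = (x - m) / s, mean = m, sd = s,
                 apply = function(newx) (newx - m) / s),
            class = "scale_transform")
}

#' Attach per-record climate with scaling
#'
#' Extracts each record's decadal climate from the stack and adds
#' centred-and-scaled FFD and precipitation columns (transform computed over
#' the supplied records, i.e. the fitting set, and returned for reuse).
#'
#' @param records specimen data.frame with `lat`, `lon`, `year`, `id`.
#' @param stack a `climate_stack`.
#' @param transforms optional list `(ffd=, precip=)` of `scale_transform`s to
#'   reuse (e.g. apply the pre-period scaling to post-period records).
#' @return list: `records` (input + ffd, temperature, precipitation,
#'   scaled_ffd, scaled_precip), `transforms`.
#' @export
record_climate <- function(records, stack, transforms = NULL) {
  cl <- extract_at(stack, records$lat, records$lon, records$year,
                   ids = records$id)
  if (is.null(transforms)) {
    tf_f <- center_scale(cl$ffd)
    tf_p <- center_scale(cl$precipitation)
    transforms <- list(ffd = tf_f, precip = tf_p)
    records$scaled_ffd <- tf_f$z
    records$scaled_precip <- tf_p$z
  } else {
    records$scaled_ffd <- transforms$ffd$apply(cl$ffd)
    records$scaled_precip <- transforms$precip$apply(cl$precipitation)
  }
  records$ffd <- cl$ffd
  records$temperature <- cl$temperature
  records$precipitation <- cl$precipitation
  list(records = records, transforms = transforms)
}

#' Collinearity diagnostics for climate predictors
#'
#' Pairwise Pearson correlations with t statistics, plus VIFs for the
#' temperature+precipitation and FFD+precipitation designs — the diagnostic
#' behind preferring FFD over temperature when the two are nearly collinear
#' proxies for the thermal season.
#'
#' @param climate data.frame with `temperature`, `ffd`, `precipitation`
#'   (per-record values by default; pass per-cell values to diagnose across
#'   cells instead).
#' @param prefer which thermal proxy downstream models should use; FFD by
#'   default (feeding-season length is the mechanistic proxy, and
#'   temperature is nearly collinear with it).
#' @return list: `correlations` (pair, r, df, t), `vif_temp_precip`,
#'   `vif_ffd_precip`, `chosen`.
#' @export
climate_collinearity <- function(climate, prefer = c("ffd", "temperature")) {
  prefer <- match.arg(prefer)
  vars <- c("temperature", "ffd", "precipitation")
  stopifnot(all(vars %in% names(climate)))
  pairs <- utils::combn(vars, 2)
  df <- nrow(climate) - 2
  cors <- apply(pairs, 2, function(p) stats::cor(climate[[p[1]]],
                                                 climate[[p[2]]]))
  corr <- data.frame(pair = apply(pairs, 2, paste, collapse = ":"),
                     r = cors, df = df, t = pearson_t(cors, df))
  v_tp <- vif(climate[, c("temperature", "precipitation")])
  v_fp <- vif(climate[, c("ffd", "precipitation")])
  list(correlations = corr, vif_temp_precip = v_tp, vif_ffd_precip = v_fp,
       chosen = prefer)
}

#' Period means and proportional climate change
#'
#' Per variable and cell: mean over post-cutoff decades minus mean over
#' pre-cutoff decades, divided by the pre-cutoff mean (change proportional
#' to pre-warming levels). Cells whose pre-period mean is zero are masked
#' out and counted.
#'
#' @param stack a `climate_stack`.
#' @param cutoff_year decades ending at or before this year are "pre".
#' @return list of class `change_rasters`: `grid`, `mask`, per-variable
#'   `prop_change` matrices, per-variable `pre_mean`/`post_mean`, and
#'   `n_zero_pre` counts.
#' @export
proportional_change <- function(stack, cutoff_year = 1960) {
  pre <- stack$decades$end <= cutoff_year
  if (!any(pre) || all(pre))
    stop("need at least one decade on each side of the cutoff")
  avg <- function(layers) Reduce(`+`, layers) / length(layers)
  out <- list(grid = stack$grid, mask = stack$mask, prop_change = list(),
              pre_mean = list(), post_mean = list(), n_zero_pre = integer(0))
  for (v in names(stack$values)) {
    pm <- avg(stack$values[[v]][pre])
    qm <- avg(stack$values[[v]][!pre])
    zero <- !is.na(pm) & pm == 0
    if (all(pm[stack$mask] == 0, na.rm = TRUE))
      warning("all-zero pre-period mean for ", v)
    pc <- (qm - pm) / pm
    pc[zero] <- NA
    out$prop_change[[v]] <- pc
    out$pre_mean[[v]] <- pm
    out$post_mean[[v]] <- qm
    out$n_zero_pre[v] <- sum(zero & stack$mask)
  }
  class(out) <- "change_rasters"
  out
}
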