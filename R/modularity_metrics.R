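#' Principal (lead) axis of a flat-map ROI
#'
#' First principal component of the centred, unweighted `(u, v)` cell
#' coordinates of the ROI — its long axis, along which modular banding is
#' assessed. The sign convention fixes a positive u-component (positive
#' v-component if the axis is orthogonal to u). A warning is emitted when
#' the ROI is nearly isotropic (eigenvalue ratio < 1.2), where the lead
#' axis is poorly determined.
#'
#' @param x A [flatten_map()] result, a [flat_cells()] data frame, or a
#'   two-column coordinate matrix.
#' @return Unit-length numeric vector of length 2, with attribute
#'   `eigenvalue_ratio`.
#' @export
principal_axis <- function(x) {
  if (inherits(x, "flat_map")) x <- flat_cells(x)
  if (is.data.frame(x)) x <- cbind(x$u, x$v)
  stopifnot(is.matrix(x), ncol(x) == 2)
  if (nrow(x) < 3) stop("need at least 3 ROI cells")
  cc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[2] <= .Machine$double.eps * ev$values[1])
    stop("degenerate (collinear) ROI")
  ratio <- ev$values[1] / ev$values[2]
  if (ratio < 1.2)
    warning("ROI is nearly isotropic; the lead axis is poorly determined")
  ax <- ev$vectors[, 1]
  if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
  ax <- ax / sqrt(sum(ax^2))
  attr(ax, "eigenvalue_ratio") <- ratio
  ax
}

#' Collapse a flat map along an axis
#'
#' Projects each occupied cell's `(u, v)` centre onto the axis and averages
#' cell values within projection bins, yielding the 1D modularity profile.
#'
#' @param flatmap A [flatten_map()] result.
#' @param axis Unit vector from [principal_axis()]; computed from the map
#'   itself when `NULL`.
#' @param bin_width_mm Projection bin width; must be at least the cell size.
#' @return Object of class `modularity_profile`: data frame with `center`
#'   (mm along the axis), `value`, `n_cells`; attributes `axis` and
#'   `bin_width_mm`. Empty bins are dropped with a warning.
#' @export
collapse_profile <- function(flatmap, axis = NULL,
                             bin_width_mm = flatmap$cell_mm) {
  stopifnot(inherits(flatmap, "flat_map"))
  if (is.null(axis)) axis <- principal_axis(flatmap)
  stopifnot(length(axis) == 2)
  if (bin_width_mm < flatmap$cell_mm - 1e-9)
    stop("bin_width_mm must be at least the cell size")
  cells <- flat_cells(flatmap)
  if (nrow(cells) == 0) stop("flat map has no occupied cells")
  proj <- cells$u * axis[1] + cells$v * axis[2]
  # first bin centred on the smallest projection
  lo <- min(proj) - bin_width_mm / 2
  n_bins <- max(1L, ceiling((max(proj) - lo) / bin_width_mm - 1e-9))
  edges <- lo + (0:n_bins) * bin_width_mm
  bin <- pmin(pmax(findInterval(proj, edges), 1L), n_bins)
  centers <- edges[-length(edges)] + bin_width_mm / 2
  present <- sort(unique(bin))
  if (length(setdiff(seq_len(n_bins), present)))
    warning("empty projection bins dropped")
  value <- tapply(cells$value, bin, mean)
  n_cells <- tapply(cells$value, bin, length)
  out <- data.frame(center = centers[present],
                    value = as.numeric(value),
                    n_cells = as.integer(n_cells))
  attr(out, "axis") <- axis
  attr(out, "bin_width_mm") <- bin_width_mm
  class(out) <- c("modularity_profile", "data.frame")
  out
}

#' Least-squares sinusoid fit to a modularity profile
#'
#' Scans candidate periods between twice the bin width and the profile
#' extent; at each period the amplitude and phase are solved linearly
#' (sine/cosine regression with intercept), and the period minimising the
#' residual sum of squares is kept. A clearly periodic (modular) profile
#' yields a high R-squared; deviation from a sinusoid indicates reduced
#' spatial specificity.
#'
#' @param profile A [collapse_profile()] result with at least 8 bins.
#' @param n_periods Number of candidate periods scanned.
#' @return List with `period` (mm), `amplitude`, `phase` (radians),
#'   `r_squared` (vs the mean-only model), and the scanned `periods`.
#' @export
fit_sinusoid <- function(profile, n_periods = 400L) {
  stopifnot(inherits(profile, "modularity_profile") ||
              is.data.frame(profile))
  x <- profile$center
  y <- profile$value
  if (length(y) < 8) stop("need at least 8 bins to fit a sinusoid")
  bw <- attr(profile, "bin_width_mm")
  if (is.null(bw)) bw <- min(diff(sort(x)))
  extent <- max(x) - min(x)
  periods <- seq(2 * bw, extent, length.out = n_periods)
  tss <- sum((y - mean(y))^2)
  best <- list(rss = Inf)
  for (p in periods) {
    w <- 2 * pi / p
    Xd <- cbind(1, sin(w * x), cos(w * x))
    fit <- stats::lm.fit(Xd, y)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss)
      best <- list(rss = rss, period = p,
                   coef = unname(fit$coefficients))
  }
  a <- best$coef[2]; b <- best$coef[3]
  list(period = best$period,
       amplitude = sqrt(a^2 + b^2),
       phase = atan2(b, a),
       r_squared = if (tss > 0) 1 - best$rss / tss else 0,
       periods = range(periods))
}

#' Voxel sensitivity index
#'
#' How strongly a voxel responds to any visual stimulus: the Euclidean norm
#' of its per-condition t-value vector `(t_RF0, t_RF4)`.
#'
#' @param v Length-2 numeric vector, or an n x 2 matrix of vectors.
#' @return Non-negative scalar (or vector of length n).
#' @export
sensitivity <- function(v) {
  if (is.null(dim(v))) {
    stopifnot(length(v) == 2, all(is.finite(v)))
    return(sqrt(sum(v^2)))
  }
  stopifnot(ncol(v) == 2)
  sqrt(rowSums(v^2))
}

#' Voxel specificity index
#'
#' How well a voxel is tuned to one condition:
#' `1 - acos(vhat . what) / theta_max`, where `vhat` is the voxel's
#' (rectified, by default) unit response vector and `what` the winning
#' reference axis — the unit vector of the larger rectified component. With
#' two conditions the largest possible angle between `vhat` and an axis is
#' 45 degrees, hence `theta_max = 45`. A voxel responding to one condition
#' only scores 1; equal responses to both score 0 (equally tuned = not
#' specific); a zero vector scores 0 by definition. With `rectify = FALSE`
#' raw signed components are normalised instead and the result is clamped
#' to `[0, 1]`.
#'
#' @param v Length-2 numeric vector `(t_RF0, t_RF4)`, or an n x 2 matrix.
#' @param theta_max Scaling angle in degrees (> 0, default 45).
#' @param rectify Rectify negative components at 0 before normalising.
#' @return Scalar (or vector) in `[0, 1]`.
#' @export
specificity <- function(v, theta_max = 45, rectify = TRUE) {
  if (theta_max <= 0) stop("theta_max must be positive")
  single <- is.null(dim(v))
  if (single) v <- matrix(v, 1)
  stopifnot(ncol(v) == 2)
  w <- if (rectify) pmax(v, 0) else v
  nrm <- sqrt(rowSums(w^2))
  winner_big <- w[, 1] >= w[, 2]          # reference axis of the winner
  cosang <- ifelse(winner_big, w[, 1], w[, 2]) / nrm
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  out <- 1 - ang / theta_max
  out[nrm == 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (single) out[1] else out
}

#' Voxelwise sensitivity and specificity maps
#'
#' Applies [sensitivity()] and [specificity()] to the per-condition t maps
#' of one contrast mechanism within an ROI.
#'
#' @param t_rf0,t_rf4 3D t-value arrays on the same grid.
#' @param roi Optional logical 3D mask; voxels outside are NA.
#' @param contrast_tag Label (`"bold"` or `"vaso"`) carried in the result.
#' @param theta_max,rectify Passed to [specificity()].
#' @return Object of class `sens_spec_maps`: 3D arrays `sensitivity` and
#'   `specificity` plus the contrast tag.
#' @export
sens_spec_maps <- function(t_rf0, t_rf4, roi = NULL, contrast_tag = "bold",
                           theta_max = 45, rectify = TRUE) {
  if (!identical(dim(t_rf0), dim(t_rf4))) stop("t-map grids mismatch")
  v <- cbind(as.vector(t_rf0), as.vector(t_rf4))
  sens <- sensitivity(v)
  spec <- specificity(v, theta_max = theta_max, rectify = rectify)
  spec[sens == 0] <- 0
  sens <- array(sens, dim(t_rf0))
  spec <- array(spec, dim(t_rf0))
  if (!is.null(roi)) {
    sens[!roi] <- NA_real_
    spec[!roi] <- NA_real_
  }
  structure(list(sensitivity = sens, specificity = spec,
                 contrast_tag = contrast_tag),
            class = "sens_spec_maps")
}

#' Summary comparison of sensitivity/specificity between contrasts
#'
#' @param bold,vaso [sens_spec_maps()] for the two contrast mechanisms over
#'   the same ROI.
#' @return Data frame with one row per contrast x index: median, quartiles,
#'   range, and voxel count; the per-voxel scatter table is attached as the
#'   `scatter` attribute.
#' @export
compare_contrasts <- function(bold, vaso) {
  stopifnot(inherits(bold, "sens_spec_maps"),
            inherits(vaso, "sens_spec_maps"))
  summarise <- function(m, contrast, index) {
    x <- m[is.finite(m)]
    if (length(x) == 0) stop("empty ROI")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(contrast = contrast, index = index, n = length(x),
               median = q[2], q25 = q[1], q75 = q[3],
               min = min(x), max = max(x), iqr = q[3] - q[1],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    summarise(bold$sensitivity, bold$contrast_tag, "sensitivity"),
    summarise(bold$specificity, bold$contrast_tag, "specificity"),
    summarise(vaso$sensitivity, vaso$contrast_tag, "sensitivity"),
    summarise(vaso$specificity, vaso$contrast_tag, "specificity")
  )
  keep_b <- is.finite(bold$sensitivity)
  keep_v <- is.finite(vaso$sensitivity)
  attr(out, "scatter") <- rbind(
    data.frame(voxel = which(keep_b), contrast = bold$contrast_tag,
               sensitivity = bold$sensitivity[keep_b],
               specificity = bold$specificity[keep_b]),
    data.frame(voxel = which(keep_v), contrast = vaso$contrast_tag,
               sensitivity = vaso$sensitivity[keep_v],
               specificity = vaso$specificity[keep_v])
  )
  out
}
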