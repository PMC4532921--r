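# Gabor fitting of receptive fields: 8-parameter Gabor model, moment
# based initialization, multi-start Nelder-Mead, quality control and
# shape-profile statistics.

#' Evaluate a 2D Gabor function on a square pixel grid
#'
#' G(x, y) = A cos(2 pi f x' + phi) exp(-x'^2 / (2 sx^2) -
#' y'^2 / (2 sy^2)) with (x', y') the coordinates rotated by theta
#' about the center (x0, y0). Pixel coordinates are 1-based, x along
#' rows and y along columns.
#'
#' @param side grid side length in pixels.
#' @param x0,y0 center in pixels.
#' @param A amplitude.
#' @param sigmaX,sigmaY Gaussian envelope widths in pixels (> 0).
#' @param theta orientation in radians.
#' @param f spatial frequency in cycles/pixel (> 0).
#' @param phi phase in radians.
#' @return side x side numeric matrix.
#' @export
gaborImage <- function(side, x0, y0, A, sigmaX, sigmaY, theta, f, phi) {
  g <- expand.grid(x = seq_len(side), y = seq_len(side))
  xp <- (g$x - x0) * cos(theta) + (g$y - y0) * sin(theta)
  yp <- -(g$x - x0) * sin(theta) + (g$y - y0) * cos(theta)
  v <- A * cos(2 * pi * f * xp + phi) *
    exp(-xp^2 / (2 * sigmaX^2) - yp^2 / (2 * sigmaY^2))
  matrix(v, side, side)
}

# Canonicalize (A, phi, theta): A >= 0 via phi -> phi + pi; theta in
# [0, pi) (theta -> theta + pi flips x', absorbed by phi -> -phi);
# phi wrapped to [-pi, pi).
canonicalGabor <- function(p) {
  if (p[["A"]] < 0) {
    p[["A"]] <- -p[["A"]]
    p[["phi"]] <- p[["phi"]] + pi
  }
  p[["sigmaX"]] <- abs(p[["sigmaX"]])
  p[["sigmaY"]] <- abs(p[["sigmaY"]])
  p[["f"]] <- abs(p[["f"]])
  th <- p[["theta"]] %% pi
  # rotating theta by pi negates x'; cos(2 pi f x' + phi) ->
  # cos(2 pi f x' - phi), so flip the phase sign when we wrapped.
  nWraps <- round((p[["theta"]] - th) / pi)
  if (nWraps %% 2 != 0) p[["phi"]] <- -p[["phi"]]
  p[["theta"]] <- th
  p[["phi"]] <- ((p[["phi"]] + pi) %% (2 * pi)) - pi
  p
}

# Moment-based initial guess: center from the centroid of |rf - mean|,
# orientation from the image structure tensor, frequency from the
# radial FFT peak, envelope widths from second moments.
gaborInit <- function(rf) {
  side <- nrow(rf)
  r0 <- rf - mean(rf)
  wAbs <- abs(r0)
  wAbs <- wAbs / max(sum(wAbs), 1e-12)
  g <- expand.grid(x = seq_len(side), y = seq_len(side))
  x0 <- sum(g$x * as.vector(wAbs))
  y0 <- sum(g$y * as.vector(wAbs))
  # structure tensor of the patch
  gx <- r0[c(2:side, side), ] - r0[c(1, 1:(side - 1)), ]
  gy <- r0[, c(2:side, side)] - r0[, c(1, 1:(side - 1))]
  Jxx <- sum(gx^2); Jyy <- sum(gy^2); Jxy <- sum(gx * gy)
  theta <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)  # dominant gradient dir
  # frequency: peak of the radial amplitude spectrum (DC excluded)
  sp <- radialSpectrum(r0, nBins = max(8L, side %/% 2))
  f <- sp$f[which.max(sp$amplitude)]
  f <- min(max(f, 0.02), 0.45)
  sx <- sqrt(sum(((g$x - x0)^2) * as.vector(wAbs)))
  sy <- sqrt(sum(((g$y - y0)^2) * as.vector(wAbs)))
  c(x0 = x0, y0 = y0, A = max(abs(r0)),
    sigmaX = max(sx, 0.5), sigmaY = max(sy, 0.5),
    theta = theta, f = f, phi = 0)
}

gaborResiduals <- function(par, rf) {
  side <- nrow(rf)
  # soft box on the log-scale parameters: keeps sigma in
  # [0.3, 2*side] and f in (0, 0.75] without hard walls
  lsLo <- log(0.3); lsHi <- log(2 * side)
  lfLo <- log(0.005); lfHi <- log(0.75)
  excess <- sum(pmax(0, par[4:5] - lsHi)^2 +
                pmax(0, lsLo - par[4:5])^2) +
    max(0, par[7] - lfHi)^2 + max(0, lfLo - par[7])^2
  par[4:5] <- pmin(pmax(par[4:5], lsLo), lsHi)
  par[7] <- pmin(pmax(par[7], lfLo), lfHi)
  G <- gaborImage(side, par[1], par[2], par[3],
                  exp(par[4]), exp(par[5]), par[6], exp(par[7]),
                  par[8])
  sum((rf - G)^2) + excess * (1 + sum(rf^2))
}

#' Fit a Gabor function to a receptive field
#'
#' Minimizes the sum of squared residuals between the RF and the
#' 8-parameter Gabor by Nelder-Mead, with a moment-based initial guess
#' plus seeded random restarts (perturbed center/orientation/frequency
#' and both phase quadratures). Envelope widths and frequency are
#' optimized on the log scale, keeping them positive. Parameters are
#' returned in canonical ranges (A >= 0, theta in [0, pi), phi in
#' [-pi, pi)).
#'
#' @param rf side x side numeric matrix (non-constant).
#' @param nRestarts number of random restarts beyond the deterministic
#'   starts (default 10).
#' @param seed integer seed for the restarts.
#' @return One-row data.frame with columns x0, y0, A, sigmaX, sigmaY,
#'   theta, f, phi, r2 and converged. If no restart converges, r2 is
#'   -Inf and converged FALSE.
#' @export
fitGabor <- function(rf, nRestarts = 10L, seed = 1L) {
  rf <- as.matrix(rf)
  if (stats::sd(as.vector(rf)) == 0)
    stop("fitGabor: constant receptive field")
  # the Gabor model carries its own DC structure (substantial at low
  # f), so the raw field is fitted; remove ensemble pedestals before
  # calling (cf. the centered reverse-correlation estimate)
  rf0 <- rf
  init <- gaborInit(rf)
  sst <- sum((rf0 - mean(rf0))^2)
  set.seed(as.integer(seed))
  side <- nrow(rf)

  toPar <- function(p) c(p[["x0"]], p[["y0"]], p[["A"]],
                         log(p[["sigmaX"]]), log(p[["sigmaY"]]),
                         p[["theta"]], log(p[["f"]]), p[["phi"]])
  starts <- list(toPar(init),
                 toPar(`[[<-`(init, "phi", pi / 2)),
                 toPar(`[[<-`(init, "theta", init[["theta"]] + pi / 2)))
  for (i in seq_len(nRestarts)) {
    p <- init
    p[["x0"]] <- p[["x0"]] + stats::rnorm(1, sd = side / 8)
    p[["y0"]] <- p[["y0"]] + stats::rnorm(1, sd = side / 8)
    p[["theta"]] <- stats::runif(1, 0, pi)
    p[["f"]] <- exp(log(p[["f"]]) + stats::rnorm(1, sd = 0.4))
    p[["phi"]] <- stats::runif(1, -pi, pi)
    p[["sigmaX"]] <- p[["sigmaX"]] * exp(stats::rnorm(1, sd = 0.3))
    p[["sigmaY"]] <- p[["sigmaY"]] * exp(stats::rnorm(1, sd = 0.3))
    starts[[length(starts) + 1L]] <- toPar(p)
  }

  # cheap exploration pass over every start, full polish on the best
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, gaborResiduals, rf = rf0,
                   method = "Nelder-Mead",
                   control = list(maxit = 600, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(best)) {
    # restart the simplex at its own optimum until the value stops
    # improving; a fresh full-size simplex escapes the shallow
    # valleys where a collapsed one stalls (notably at low f)
    for (polish in 1:6) {
      fit2 <- stats::optim(best$par, gaborResiduals, rf = rf0,
                           method = "Nelder-Mead",
                           control = list(maxit = 2000,
                                          reltol = 1e-12))
      fit2$convergence <- min(best$convergence, fit2$convergence)
      improved <- best$value - fit2$value >
        1e-10 * max(fit2$value, 1)
      best <- fit2
      if (!improved) break
    }
  }
  if (is.null(best))
    return(data.frame(x0 = NA, y0 = NA, A = NA, sigmaX = NA,
                      sigmaY = NA, theta = NA, f = NA, phi = NA,
                      r2 = -Inf, converged = FALSE))
  p <- best$par
  out <- canonicalGabor(list(x0 = p[1], y0 = p[2], A = p[3],
                             sigmaX = exp(p[4]), sigmaY = exp(p[5]),
                             theta = p[6], f = exp(p[7]), phi = p[8]))
  data.frame(x0 = out$x0, y0 = out$y0, A = out$A,
             sigmaX = out$sigmaX, sigmaY = out$sigmaY,
             theta = out$theta, f = out$f, phi = out$phi,
             r2 = 1 - best$value / sst,
             converged = best$convergence == 0)
}

#' Fit Gabors to all columns of a receptive-field matrix
#'
#' @param RF Nv x Nh matrix of vectorized receptive fields (as from
#'   \code{\link{estimateRFs}}).
#' @param side patch side length.
#' @param nRestarts,seed passed to \code{\link{fitGabor}}; the seed is
#'   offset per unit so fits are independent but reproducible.
#' @return data.frame with one row per unit (column \code{unit} plus
#'   the \code{\link{fitGabor}} columns).
#' @export
fitGabors <- function(RF, side, nRestarts = 10L, seed = 1L) {
  res <- lapply(seq_len(ncol(RF)), function(j) {
    rf <- matrix(RF[, j], side, side)
    if (stats::sd(RF[, j]) == 0) {
      f <- data.frame(x0 = NA, y0 = NA, A = NA, sigmaX = NA,
                      sigmaY = NA, theta = NA, f = NA, phi = NA,
                      r2 = -Inf, converged = FALSE)
    } else {
      f <- fitGabor(rf, nRestarts = nRestarts, seed = seed + j)
    }
    cbind(unit = j, f)
  })
  do.call(rbind, res)
}

#' Quality-filter Gabor fits
#'
#' Keeps fits with r2 >= r2Min and, when \code{sanityBounds} is TRUE,
#' whose center lies inside the patch and whose envelope widths do not
#' exceed the patch diagonal.
#'
#' @param fits data.frame of fits (\code{\link{fitGabor}} columns).
#' @param r2Min minimum goodness-of-fit in [0, 1] (default 0.5).
#' @param side patch side length (needed for the sanity bounds).
#' @param sanityBounds apply the geometric sanity checks (default
#'   TRUE).
#' @return The retained rows.
#' @export
qualityFilter <- function(fits, r2Min = 0.5, side = NULL,
                          sanityBounds = TRUE) {
  if (r2Min < 0 || r2Min > 1)
    stop("qualityFilter: r2Min must be in [0, 1]")
  keep <- !is.na(fits$r2) & fits$r2 >= r2Min
  if (sanityBounds) {
    if (is.null(side))
      stop("qualityFilter: side is required when sanityBounds = TRUE")
    diagLen <- sqrt(2) * side
    keep <- keep &
      fits$x0 >= 1 & fits$x0 <= side &
      fits$y0 >= 1 & fits$y0 <= side &
      fits$sigmaX <= diagLen & fits$sigmaY <= diagLen
    keep[is.na(keep)] <- FALSE
  }
  fits[keep, , drop = FALSE]
}

#' Shape profiles (nx, ny) of Gabor fits
#'
#' Envelope widths in units of the sinusoidal wavelength:
#' (nx, ny) = (sigmaX * f, sigmaY * f), dimensionless, plus the aspect
#' ratio. The ratio orientation is configurable; ny/nx is the default.
#'
#' @param fits data.frame of (filtered) Gabor fits.
#' @param ratio "ny/nx" (default) or "nx/ny".
#' @return data.frame with columns \code{unit} (if present),
#'   \code{nx}, \code{ny}, \code{aspectRatio}.
#' @export
shapeProfiles <- function(fits, ratio = c("ny/nx", "nx/ny")) {
  if (nrow(fits) == 0) stop("shapeProfiles: no fits")
  ratio <- match.arg(ratio)
  nx <- fits$sigmaX * fits$f
  ny <- fits$sigmaY * fits$f
  ar <- if (ratio == "ny/nx") ny / nx else nx / ny
  out <- data.frame(nx = nx, ny = ny, aspectRatio = ar)
  if (!is.null(fits$unit)) out <- cbind(unit = fits$unit, out)
  out
}

#' Histogram of aspect ratios
#'
#' @param profiles data.frame from \code{\link{shapeProfiles}}.
#' @param binEdges explicit, increasing bin edges; values outside the
#'   range are counted in the first/last bin so counts always sum to
#'   the number of fits.
#' @return data.frame with columns \code{lower}, \code{upper},
#'   \code{count}; counts sum to \code{nrow(profiles)}.
#' @export
aspectHistogram <- function(profiles,
                            binEdges = seq(0, 5, by = 0.25)) {
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("aspectHistogram: binEdges must be strictly increasing")
  x <- profiles$aspectRatio
  nb <- length(binEdges) - 1L
  idx <- findInterval(x, binEdges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  data.frame(lower = binEdges[-length(binEdges)],
             upper = binEdges[-1],
             count = as.integer(tabulate(idx, nbins = nb)))
}
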