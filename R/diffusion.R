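# Mean-squared displacement and Einstein diffusion coefficients.

#' Unwrap periodic ion coordinates
#'
#' Removes periodic jumps so displacement accumulates across box crossings.
#' Consecutive-frame displacements must stay well below half the box per
#' axis; steps above 0.45 box (the practical detection limit for wrapped
#' input) raise an error suggesting finer time sampling.
#'
#' @param traj a `Trajectory`.
#' @param species ion species label.
#' @return array n_ions x 3 x n_frames of continuous coordinates (A).
#' @export
unwrap_coordinates <- function(traj, species) {
  idx <- species_indices(traj, species)
  nf <- traj$n_frames
  out <- array(NA_real_, c(length(idx), 3L, nf))
  for (k in seq_along(idx)) {
    x <- t(traj$coords[idx[k], , , drop = FALSE][1, , ])  # nf x 3
    if (nf > 1L) {
      steps <- min_image_disp(x[-1L, , drop = FALSE] - x[-nf, , drop = FALSE],
                              traj$box)
      steps <- as_coord_matrix(steps)
      lim <- matrix(0.45 * traj$box, nrow(steps), 3L, byrow = TRUE)
      if (any(abs(steps) >= lim)) {
        stop("per-frame displacement >= 0.45 box for species '", species,
             "'; unwrapping unreliable - use finer time sampling")
      }
      x <- rbind(x[1L, ], sweep(apply(steps, 2, cumsum), 2, x[1L, ], "+"))
    }
    out[k, , ] <- t(x)
  }
  out
}

#' Mean-squared displacement and Einstein diffusion coefficient
#'
#' MSD over all time origins, averaged over ions; `D` is the slope of the
#' linear fit over `fit_window` divided by 6.  The fit is additionally
#' checked by the log-log slope of the MSD: values far from 1 (e.g. ~2 for
#' ballistic motion) set `fit_flagged`.
#'
#' @param unwrapped array from [unwrap_coordinates()] (or an n_frames x 3
#'   matrix for a single particle).
#' @param dt frame interval (ps).
#' @param max_lag largest lag (ps); trace must be at least 5 times longer.
#' @param fit_window `c(lo, hi)` (ps); default `[0.1, 0.5] * max_lag`,
#'   avoiding the ballistic start and the noisy tail.
#' @return object of class `MSDResult`: `lags` (ps), `msd` (A^2),
#'   `n_pairs`, `D` (A^2/ps), `D_cm2_s`, `fit_window`, `fit_r2`,
#'   `loglog_slope`, `fit_flagged`.
#' @export
msd <- function(unwrapped, dt, max_lag, fit_window = NULL) {
  if (length(dim(unwrapped)) == 2L) {
    unwrapped <- array(t(unwrapped), c(1L, 3L, nrow(unwrapped)))
  }
  nf <- dim(unwrapped)[3]
  nion <- dim(unwrapped)[1]
  max_lag_fr <- floor(max_lag / dt)
  if (nf < 5 * max_lag_fr) {
    stop("trace length (", nf, " frames) must be >= 5 * max_lag (",
         5 * max_lag_fr, " frames)")
  }
  lags_fr <- seq_len(max_lag_fr)
  msd_v <- numeric(length(lags_fr))
  npairs <- numeric(length(lags_fr))
  for (li in seq_along(lags_fr)) {
    l <- lags_fr[li]
    d <- unwrapped[, , (1L + l):nf, drop = FALSE] -
         unwrapped[, , 1L:(nf - l), drop = FALSE]
    npairs[li] <- nion * (nf - l)
    msd_v[li] <- sum(d * d) / npairs[li]   # summed over x,y,z
  }
  lags <- lags_fr * dt
  fit_window <- fit_window %||% (c(0.1, 0.5) * max_lag)
  infit <- which(lags >= fit_window[1] & lags <= fit_window[2])
  if (length(infit) < 10L) stop("fewer than 10 lag points in the fit window")
  fit <- lm(msd_v[infit] ~ lags[infit])
  D <- unname(coef(fit)[2]) / 6
  r2 <- summary(fit)$r.squared
  pos <- infit[msd_v[infit] > 0]
  alpha <- if (length(pos) >= 2L) {
    unname(coef(lm(log(msd_v[pos]) ~ log(lags[pos])))[2])
  } else NA_real_
  structure(list(lags = lags, msd = msd_v, n_pairs = npairs,
                 D = max(D, 0), D_cm2_s = max(D, 0) * 1e-4,
                 fit_window = fit_window, fit_r2 = r2,
                 loglog_slope = alpha,
                 fit_flagged = is.na(alpha) || abs(alpha - 1) > 0.3),
            class = "MSDResult")
}

#' @export
print.MSDResult <- function(x, ...) {
  cat(sprintf("<MSDResult> D = %.4g A^2/ps (%.3g cm^2/s), fit [%g, %g] ps, R^2 = %.3f%s\n",
              x$D, x$D_cm2_s, x$fit_window[1], x$fit_window[2], x$fit_r2,
              if (x$fit_flagged) " [FLAGGED: non-diffusive]" else ""))
  invisible(x)
}
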