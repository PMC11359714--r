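# The two classical spatial-interpolation baselines the network is judged
# against: a normalized inverse-distance weighted average over the observed
# electrodes (weights 1/d or 1/d^2 on the planar projection), and a natural
# cubic spline fitted along the electrode row or column through the target.

#' Inverse-distance weighted prediction at one instant
#'
#' Predicts a target electrode's value as the convex combination of the
#' observed values with weights proportional to `d^(-power)`, normalized to
#' sum to one (so the output stays in microvolts and within the observed
#' value range). If any distance is exactly zero the coincident electrode's
#' value is passed through (first such electrode in input order).
#'
#' @param values numeric vector of observed-channel values (microvolts).
#' @param distances non-negative planar distances to the target, same
#'   length as `values`.
#' @param power 1 (reciprocal distance) or 2 (reciprocal squared distance).
#' @return predicted scalar in microvolts.
#' @examples
#' idw_predict(c(1, 2, 3), c(1, 1, 1), power = 1)  # equidistant -> mean
#' @export
idw_predict <- function(values, distances, power = 2) {
  stopifnot(length(values) == length(distances), length(values) >= 1,
            all(is.finite(values)), all(distances >= 0),
            power %in% c(1, 2))
  z <- which(distances == 0)
  if (length(z) > 0) return(values[z[1]])
  w <- distances^(-power)
  sum(w * values) / sum(w)
}

.idw_weights <- function(distances, power) {
  z <- which(distances == 0)
  w <- numeric(length(distances))
  if (length(z) > 0) { w[z[1]] <- 1; return(w) }
  w <- distances^(-power)
  w / sum(w)
}

#' Inverse-distance interpolation of all target channels over time
#'
#' Applies [idw_predict()] independently at every sample instant for every
#' target channel of the split. Weights depend only on geometry, so the
#' per-instant average reduces to one fixed convex weight vector per
#' target.
#'
#' @param rec an `eeg_recording` containing at least the observed channels.
#' @param split a `channel_split`.
#' @param montage the montage defining planar positions.
#' @param power 1 or 2.
#' @return numeric matrix, targets x samples, rownames = target labels.
#' @export
idw_predict_series <- function(rec, split, montage, power = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  obs_idx <- match(montage$names[split$observed], rec$channel_labels)
  if (anyNA(obs_idx)) stop("recording lacks observed channels of the split")
  D <- montage_distances(montage)
  W <- t(vapply(split$targets, function(tg)
    .idw_weights(D[tg, split$observed], power),
    numeric(length(split$observed))))
  out <- W %*% rec$data[obs_idx, , drop = FALSE]
  rownames(out) <- montage$names[split$targets]
  out
}

#' Natural cubic spline interpolant
#'
#' Fits the piecewise-cubic C2 interpolant through the knots with natural
#' boundary conditions (zero second derivative at both ends), solving the
#' standard tridiagonal system for the knot second derivatives.
#'
#' @param knots_x strictly increasing abscissae (>= 3 knots).
#' @param knots_y knot values.
#' @return a function `f(x)` evaluating the spline (vectorized); refuses
#'   to extrapolate outside `range(knots_x)`.
#' @export
natural_cubic_spline <- function(knots_x, knots_y) {
  n <- length(knots_x)
  stopifnot(n >= 3, length(knots_y) == n)
  if (any(diff(knots_x) <= 0)) stop("knot abscissae must be strictly increasing")
  h <- diff(knots_x)
  # tridiagonal system for interior second derivatives (Thomas algorithm)
  m <- n - 2
  a <- h[1:(m)]                      # sub/super diagonals h_i
  diag_ <- 2 * (h[1:m] + h[2:(m + 1)])
  rhs <- 6 * (diff(knots_y)[2:(m + 1)] / h[2:(m + 1)] -
              diff(knots_y)[1:m] / h[1:m])
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- if (m > 1) h[2] / diag_[1] else 0
  dp[1] <- rhs[1] / diag_[1]
  if (m > 1) {
    for (i in 2:m) {
      denom <- diag_[i] - h[i] * cp[i - 1]
      cp[i] <- if (i < m) h[i + 1] / denom else 0
      dp[i] <- (rhs[i] - h[i] * dp[i - 1]) / denom
    }
  }
  M <- numeric(n)  # second derivatives, natural ends = 0
  if (m >= 1) {
    M[m + 1] <- dp[m]
    if (m > 1) for (i in (m - 1):1) M[i + 1] <- dp[i] - cp[i] * M[i + 2]
  }
  force(knots_x); force(knots_y)
  function(x) {
    if (any(x < knots_x[1] - 1e-12 | x > knots_x[n] + 1e-12))
      stop("evaluation outside the knot range (extrapolation refused)")
    i <- findInterval(x, knots_x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    hi <- knots_x[i + 1] - knots_x[i]
    A <- (knots_x[i + 1] - x) / hi
    B <- (x - knots_x[i]) / hi
    A * knots_y[i] + B * knots_y[i + 1] +
      ((A^3 - A) * M[i] + (B^3 - B) * M[i + 1]) * hi^2 / 6
  }
}

#' Build the spline knot line through a target electrode
#'
#' Selects the observed electrodes lying in the same anterior-posterior
#' band (horizontal line) or lateral band (vertical line) as the target,
#' orders them along the line, and assigns abscissae as cumulative planar
#' distances between consecutive knots. The orientation with more observed
#' knots wins; ties go to horizontal. The target's abscissa is its planar
#' distance from the preceding knot added to that knot's abscissa.
#'
#' @param montage an `eeg_montage`.
#' @param split a `channel_split`.
#' @param target target electrode index or label.
#' @param band half-width of the coordinate band (planar units) within
#'   which an electrode counts as on the line.
#' @param orientation force `"horizontal"` or `"vertical"`; `NULL` picks
#'   automatically.
#' @return a `spline_line`: list with `knot_indices`, `abscissae`,
#'   `target_abscissa`, `orientation`.
#' @export
spline_line <- function(montage, split, target, band = 0.15,
                        orientation = NULL) {
  tg <- resolve_channel(montage, target)
  p <- montage$pos2d
  pick <- function(axis_keep, axis_along) {
    cand <- split$observed[abs(p[split$observed, axis_keep] -
                               p[tg, axis_keep]) <= band]
    cand <- setdiff(cand, tg)
    cand[order(p[cand, axis_along])]
  }
  hor <- pick(2, 1)  # same y band, ordered by x
  ver <- pick(1, 2)  # same x band, ordered by y
  if (is.null(orientation))
    orientation <- if (length(ver) > length(hor)) "vertical" else "horizontal"
  knots <- if (orientation == "horizontal") hor else ver
  if (length(knots) < 3)
    stop(sprintf("only %d observed electrodes on the %s line through %s (need >= 3)",
                 length(knots), orientation, montage$names[tg]))
  pts <- p[knots, , drop = FALSE]
  absc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  along <- if (orientation == "horizontal") 1 else 2
  pos <- findInterval(p[tg, along], p[knots, along])
  if (pos < 1 || pos >= length(knots))
    stop("target lies outside the knot span (extrapolation refused)")
  t_absc <- absc[pos] + sqrt(sum((p[tg, ] - pts[pos, ])^2))
  structure(list(knot_indices = knots, abscissae = absc,
                 target_abscissa = t_absc, orientation = orientation),
            class = "spline_line")
}

#' Cubic-spline interpolation of a target channel over time
#'
#' At every sample instant, fits a natural cubic spline over the line's
#' knot values (abscissae = cumulative planar distances) and evaluates it
#' at the target's abscissa. Because the natural-spline fit is linear in
#' the knot values, the per-instant fits collapse to one fixed linear
#' functional of the knot channels, which is what is applied.
#'
#' @param rec an `eeg_recording`.
#' @param split a `channel_split`.
#' @param montage an `eeg_montage`.
#' @param target target electrode index or label.
#' @param line optional precomputed [spline_line()].
#' @return numeric vector of predictions (microvolts), one per sample.
#' @export
spline_predict_series <- function(rec, split, montage, target, line = NULL) {
  if (is.null(line)) line <- spline_line(montage, split, target)
  k <- length(line$knot_indices)
  # linear functional: response of the spline at the target abscissa to
  # each unit knot value
  cvec <- vapply(seq_len(k), function(j) {
    y <- numeric(k); y[j] <- 1
    natural_cubic_spline(line$abscissae, y)(line$target_abscissa)
  }, numeric(1))
  idx <- match(montage$names[line$knot_indices], rec$channel_labels)
  if (anyNA(idx)) stop("recording lacks knot channels of the line")
  drop(cvec %*% rec$data[idx, , drop = FALSE])
}
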