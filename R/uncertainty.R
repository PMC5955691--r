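# Ensemble-uncertainty classification: directional agreement, the
# distance-directional (DDU) and latitudinal (LU) procedures, and their
# combination into a single rating per species projection.

#' Directional agreement among projected shift bearings
#'
#' Each bearing is placed on the unit circle as Cartesian coordinates; the
#' coordinates are averaged and the radius of the mean position from the
#' origin is returned (the mean resultant length of circular statistics).
#' 1 means every projection points the same way; 0 means directions cancel
#' completely (e.g. equal numbers due north and due south).
#'
#' @param bearings_deg bearings in degrees clockwise from north; at least 2
#' @return agreement radius R in \[0, 1\]
#' @examples
#' directional_agreement(rep(45, 16))   # 1
#' directional_agreement(c(0, 180))     # 0
#' directional_agreement(c(0, 90))      # sqrt(0.5)
#' @export
directional_agreement <- function(bearings_deg) {
  if (length(bearings_deg) < 2)
    stop("directional_agreement: at least two bearings required")
  th <- bearings_deg * pi / 180
  r <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  min(r, 1)
}

#' Linear quantile regression of y on x
#'
#' Fits the line minimizing the check (pinball) loss
#' \eqn{\sum_i \rho_\tau(y_i - a - b x_i)} with
#' \eqn{\rho_\tau(u) = u(\tau - 1[u < 0])}.  The objective, profiled over
#' the intercept (whose optimum given a slope is the \eqn{\tau}-quantile of
#' the residuals), is convex and piecewise linear in the slope, so it is
#' minimized by bracketed ternary search followed by an exact
#' order-statistic intercept.  This matches the linear-programming optimum
#' to well below the spacing of the data.
#'
#' @param x,y numeric vectors (finite, equal length, n >= 3)
#' @param tau quantile level in (0, 1)
#' @return list with `intercept`, `slope`, `tau`, `loss` (minimized check
#'   loss), and `fitted` values
#' @export
rq_line <- function(x, y, tau) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            tau > 0, tau < 1)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("rq_line: x and y must be finite")
  check_loss <- function(u) sum(u * (tau - (u < 0)))
  # profiled objective: optimal intercept for slope b is a tau-quantile
  # (type-1 order statistic) of y - b x
  prof <- function(b) {
    r <- y - b * x
    a <- quantile(r, probs = tau, type = 1, names = FALSE)
    check_loss(r - a)
  }
  if (sd(x) == 0) {                       # degenerate: vertical spread only
    a <- quantile(y, probs = tau, type = 1, names = FALSE)
    return(list(intercept = a, slope = 0, tau = tau,
                loss = check_loss(y - a), fitted = rep(a, length(y))))
  }
  b_ls <- coef(lm(y ~ x))[[2]]
  half <- 10 * (sd(y) / sd(x)) + abs(b_ls) + 1
  lo <- b_ls - half
  hi <- b_ls + half
  for (i in seq_len(240)) {               # (2/3)^240 shrink: below eps
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    if (prof(m1) <= prof(m2)) hi <- m2 else lo <- m1
  }
  b <- (lo + hi) / 2
  r <- y - b * x
  a <- quantile(r, probs = tau, type = 1, names = FALSE)
  list(intercept = a, slope = b, tau = tau,
       loss = check_loss(r - a), fitted = a + b * x)
}

# Floor a vector away from zero before taking logs; used for degenerate
# shifts (a centroid that does not move has no defined log-distance).
.log_floor <- function(x, eps) log(pmax(x, eps))

.rate_from_exceedance <- function(exceed95, exceed75) {
  out <- rep("low", length(exceed75))
  out[exceed75] <- "medium"
  out[exceed95] <- "high"
  factor(out, levels = c("low", "medium", "high"))
}

#' Distance-directional uncertainty (DDU) classification
#'
#' Across all species projections within one scenario, the standard
#' deviation of shift distance among GCMs is regressed (ordinary least
#' squares) on the mean shift distance, both on the natural-log scale, to
#' normalize residual errors.  The residual of each species measures how
#' much more (or less) variable its projections are than expected for the
#' distance shifted.  Residuals are paired with directional
#' \emph{disagreement} 1 - R (low agreement among bearings means a more
#' uncertain direction).  A species is rated \code{high} if either metric
#' strictly exceeds that metric's empirical 95th percentile, \code{medium}
#' if either strictly exceeds its 75th percentile (and the species is not
#' high), and \code{low} otherwise.
#'
#' @param stats data frame with one row per species projection and columns
#'   `mean_dist`, `sd_dist` (km) and `agreement_R` in \[0, 1\]
#' @param probs the medium and high percentile levels (defaults 0.75, 0.95)
#' @param eps_dist floor (km) applied to means/SDs before logging
#' @return list: `rating` factor (low/medium/high per row), `residual`,
#'   `disagreement`, `fit` (the log-log lm), and `thresholds`
#' @export
ddu_classify <- function(stats, probs = c(0.75, 0.95), eps_dist = 1) {
  req <- c("mean_dist", "sd_dist", "agreement_R")
  if (!all(req %in% names(stats)))
    stop("ddu_classify: stats needs columns ", paste(req, collapse = ", "))
  if (nrow(stats) < 10)
    stop("ddu_classify: need >= 10 species for stable percentiles")
  lx <- .log_floor(stats$mean_dist, eps_dist)
  ly <- .log_floor(stats$sd_dist, eps_dist)
  fit <- lm(ly ~ lx)
  resid <- unname(ly - fitted(fit))
  # snap numerically-zero residuals (exactly collinear input) to true
  # ties so the strict percentile rule sees them as such
  resid[abs(resid) < 1e-10 * (1 + max(abs(ly)))] <- 0
  disagree <- 1 - stats$agreement_R
  qr_ <- quantile(resid, probs = probs, names = FALSE)
  qd <- quantile(disagree, probs = probs, names = FALSE)
  high <- resid > qr_[2] | disagree > qd[2]
  med <- resid > qr_[1] | disagree > qd[1]
  list(rating = .rate_from_exceedance(high, med),
       residual = resid, disagreement = disagree, fit = fit,
       thresholds = list(residual = setNames(qr_, paste0("p", probs * 100)),
                         disagreement = setNames(qd, paste0("p", probs * 100))))
}

#' Latitudinal uncertainty (LU) classification
#'
#' Across all species projections within one scenario, the standard
#' deviation of the latitudinal centroid shift among GCMs is related to
#' the absolute mean latitudinal shift on the natural-log scale, and
#' linear quantile regressions at the 0.75 and 0.95 levels are fitted with
#' [rq_line()].  Species strictly above the 0.95 line are \code{high}
#' uncertainty, species above the 0.75 line (but not the 0.95 line)
#' \code{medium}, the rest \code{low}.
#'
#' @param stats data frame with columns `mean_dlat` (signed degrees) and
#'   `sd_dlat` (degrees)
#' @param taus medium and high quantile levels (defaults 0.75, 0.95)
#' @param eps_dlat floor (degrees) applied before logging
#' @return list: `rating` factor, `log_mean`, `log_sd`, and `lines`
#'   (fitted [rq_line()] objects, one per tau)
#' @export
lu_classify <- function(stats, taus = c(0.75, 0.95), eps_dlat = 1e-3) {
  req <- c("mean_dlat", "sd_dlat")
  if (!all(req %in% names(stats)))
    stop("lu_classify: stats needs columns ", paste(req, collapse = ", "))
  if (nrow(stats) < 10)
    stop("lu_classify: need >= 10 species for stable quantile lines")
  lx <- .log_floor(abs(stats$mean_dlat), eps_dlat)
  ly <- .log_floor(stats$sd_dlat, eps_dlat)
  lines <- lapply(taus, function(tau) rq_line(lx, ly, tau))
  names(lines) <- paste0("tau", taus * 100)
  eps <- 1e-9 * (1 + max(abs(ly)))      # strict "above", robust to fp ties
  above <- vapply(lines, function(l) ly - l$fitted > eps,
                  logical(length(ly)))
  list(rating = .rate_from_exceedance(above[, 2], above[, 1]),
       log_mean = lx, log_sd = ly, lines = lines)
}

#' Combine DDU and LU ratings
#'
#' A projection rated high by either method has poor model agreement and
#' is rated \code{high} overall; one rated low by both is robust
#' (\code{low}); anything else is \code{medium}.
#'
#' @param ddu,lu factors/characters with levels low/medium/high
#' @return factor with levels low/medium/high (vectorized)
#' @export
combine_ratings <- function(ddu, lu) {
  lv <- c("low", "medium", "high")
  d <- as.character(ddu); l <- as.character(lu)
  if (!all(d %in% lv) || !all(l %in% lv))
    stop("combine_ratings: ratings must be low/medium/high")
  out <- ifelse(d == "high" | l == "high", "high",
                ifelse(d == "low" & l == "low", "low", "medium"))
  factor(out, levels = lv)
}
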