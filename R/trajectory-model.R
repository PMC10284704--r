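# Developmental trajectory regression for normalized social preference.
#
# The closed-state reference curve is fit on a timecourse of one point per
# mouse (age_days, normalized_score).  Candidate model forms are linear,
# cubic B-spline, natural cubic spline and loess; the natural spline with an
# interior knot at P35 and an upper boundary knot at P98 is the default, with
# leave-one-out cross-validation available for model-form selection.

#' Default closed-state developmental trajectory
#'
#' Smooth piecewise-cubic curve used by the synthetic-data generators as the
#' closed-state mean of normalized social preference: elevated in juveniles
#' with a peak near P42, declining to 1.0 at `adult_age` (default P98) and
#' essentially flat thereafter (adults show no net social place preference,
#' so the post/pre ratio centres on 1).
#'
#' The curve is the member of the natural cubic spline family with interior
#' knot P35 and boundary knots P21/`adult_age` whose three coefficients are
#' solved exactly so that it equals `juvenile_level` at P21 (weaning), 1.0
#' at `adult_age`, and has zero slope there.  By the natural boundary
#' condition the curve is linear beyond `adult_age`, so with zero slope it
#' is identically 1.0 for all older ages; in between it declines smoothly
#' with an inflection in the mid-juvenile range (near P42 at the defaults).
#' Within this single-knot spline family a flat adult plateau forces the
#' juvenile limb to be monotone declining — an interior peak is not
#' representable — and because the default trajectory model uses the same
#' family, it is exactly correctly specified for synthetic timecourses,
#' keeping the nested mean-shift test calibrated in null simulations (real
#' data need not be this kind; see the vignette).
#'
#' @param age_days postnatal age(s) in days.
#' @param juvenile_level trajectory value at P21 (normalized preference
#'   units; default 1.4, an elevated juvenile social preference).
#' @param adult_age age at and beyond which the curve equals 1.0 exactly.
#' @return numeric vector of trajectory values.
#' @export
developmental_trajectory <- function(age_days, juvenile_level = 1.4,
                                     adult_age = 98) {
  stopifnot(adult_age > 35, juvenile_level >= 1)
  basis <- function(a) cbind(1, splines::ns(a, knots = 35,
                                            Boundary.knots = c(21, adult_age)))
  eps <- 1e-4
  dbasis_adult <- (basis(adult_age) - basis(adult_age - eps)) / eps
  beta <- solve(rbind(basis(21), basis(adult_age), dbasis_adult),
                c(juvenile_level, 1, 0))
  drop(basis(age_days) %*% beta)
}

#' Spline specification for trajectory models
#'
#' @param interior_knots ages of interior knots (default 35, i.e. P35).
#' @param boundary_knots pair of boundary ages; `NA` entries are filled from
#'   the data range at fit time.  Default `c(NA, 98)`: lower boundary at the
#'   youngest observed age, upper at P98.
#' @return object of class `spline_spec`.
#' @export
spline_spec <- function(interior_knots = 35, boundary_knots = c(NA, 98)) {
  if (anyDuplicated(interior_knots))
    stop("duplicate interior knots", call. = FALSE)
  if (is.unsorted(interior_knots, strictly = TRUE) && length(interior_knots) > 1)
    stop("interior knots must be strictly increasing", call. = FALSE)
  if (length(boundary_knots) != 2L)
    stop("`boundary_knots` must have length 2", call. = FALSE)
  structure(list(interior_knots = as.numeric(interior_knots),
                 boundary_knots = as.numeric(boundary_knots)),
            class = "spline_spec")
}

resolve_boundary <- function(spec, ages) {
  bk <- spec$boundary_knots
  if (is.na(bk[1])) bk[1] <- min(ages)
  if (is.na(bk[2])) bk[2] <- max(ages)
  if (bk[1] >= bk[2]) stop("boundary knots must be increasing", call. = FALSE)
  if (length(spec$interior_knots) &&
      (any(spec$interior_knots <= bk[1]) || any(spec$interior_knots >= bk[2])))
    stop("interior knots must lie strictly inside the boundary knots",
         call. = FALSE)
  bk
}

#' Natural cubic spline basis
#'
#' Cubic spline basis with natural boundary conditions (second derivative zero
#' at the boundary knots, linear beyond them).  With `k` interior knots the
#' basis has `k + 1` columns; the regression intercept is supplied by the
#' fitter, so a fit on this basis has `k + 2` parameters.
#'
#' @param ages numeric vector of evaluation ages.
#' @param spec a [spline_spec()].
#' @return design matrix with one row per age.
#' @export
natural_spline_basis <- function(ages, spec = spline_spec()) {
  if (!length(ages)) stop("`ages` must be non-empty", call. = FALSE)
  bk <- resolve_boundary(spec, ages)
  if (anyDuplicated(c(spec$interior_knots, bk)))
    stop("duplicate knots", call. = FALSE)
  splines::ns(ages, knots = spec$interior_knots, Boundary.knots = bk)
}

model_formula <- function(model_form, spec, ages) {
  bk <- resolve_boundary(spec, ages)
  switch(model_form,
    linear = normalized_score ~ age_days,
    natural_spline = stats::as.formula(sprintf(
      "normalized_score ~ splines::ns(age_days, knots = c(%s), Boundary.knots = c(%s))",
      paste(spec$interior_knots, collapse = ","), paste(bk, collapse = ","))),
    # B-splines are zero outside their boundary; they take the data range
    # (splines::bs default) rather than the P98 boundary used by the
    # natural spline
    bspline = stats::as.formula(sprintf(
      "normalized_score ~ splines::bs(age_days, knots = c(%s), degree = 3)",
      paste(spec$interior_knots, collapse = ","))),
    stop("unknown model_form: ", model_form, call. = FALSE))
}

#' Fit a developmental trajectory model
#'
#' Least-squares fit of normalized social preference against age.  Model forms:
#' \describe{
#'   \item{`natural_spline`}{cubic spline, linear beyond the boundary knots
#'     (default: interior knot P35, upper boundary P98).}
#'   \item{`bspline`}{cubic B-spline with the same interior knots.}
#'   \item{`linear`}{straight line.}
#'   \item{`loess`}{local linear regression with tricube weights
#'     (span `span`).}
#' }
#' Reported fit measures: RMSE (root mean squared residual), \eqn{R^2},
#' adjusted \eqn{R^2}, the overall regression F-test P value (`model_p`;
#' `NA` for loess) and the leave-one-out cross-validation RMSE.
#'
#' @param data data frame with columns `age_days` and `normalized_score`
#'   (e.g. from [timecourse_from_records()]).
#' @param model_form one of `"natural_spline"`, `"linear"`, `"bspline"`,
#'   `"loess"`.
#' @param spec a [spline_spec()] (ignored for linear/loess).
#' @param span loess span (fraction of points in each local fit).
#' @param loocv compute the leave-one-out RMSE at fit time (default `TRUE`;
#'   uses the hat-matrix identity for the linear-in-parameters forms, an
#'   explicit refit loop for loess).
#' @return object of class `trajectory_fit` with components `coefficients`,
#'   `fitted`, `residuals`, `rmse`, `r2`, `adj_r2`, `model_p`, `loocv_rmse`,
#'   `model_form`, `spec`, `n`, `df_model` and the underlying `fit`.
#' @examples
#' tc <- timecourse_from_records(
#'   generate_reference_timecourse(ages = seq(21, 112, by = 7),
#'                                 n_per_age = 10, seed = 1))
#' fit <- fit_trajectory(tc)
#' summary(fit)
#' predict(fit, newdata = data.frame(age_days = c(28, 98)))
#' @export
fit_trajectory <- function(data,
                           model_form = c("natural_spline", "linear",
                                          "bspline", "loess"),
                           spec = spline_spec(), span = 0.75, loocv = TRUE) {
  model_form <- match.arg(model_form)
  check_columns(data, c("age_days", "normalized_score"), "timecourse data")
  data <- as.data.frame(data)
  if (any(!is.finite(data$age_days)) || any(!is.finite(data$normalized_score)))
    stop("non-finite values in timecourse data", call. = FALSE)
  n <- nrow(data)

  if (model_form == "loess") {
    fit <- stats::loess(normalized_score ~ age_days, data = data,
                        span = span, degree = 1, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    fitted_v <- stats::fitted(fit)
    res <- stats::residuals(fit)
    coefs <- NULL
    p_eff <- fit$trace.hat
    model_p <- NA_real_
  } else {
    fml <- model_formula(model_form, spec, data$age_days)
    mm <- stats::model.matrix(fml, data)
    if (n <= ncol(mm))
      stop(sprintf("only %d points for %d parameters: fit is degenerate (no residual degrees of freedom)",
                   n, ncol(mm)), call. = FALSE)
    fit <- stats::lm(fml, data = data)
    if (anyNA(stats::coef(fit)))
      stop("singular design; collinear column(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    fitted_v <- stats::fitted(fit)
    res <- stats::residuals(fit)
    coefs <- stats::coef(fit)
    p_eff <- length(coefs)
    sm <- suppressWarnings(summary(fit))  # perfect fits trip summary.lm
    model_p <- if (is.null(sm$fstatistic)) NA_real_ else
      unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                       lower.tail = FALSE))
  }

  sst <- sum((data$normalized_score - mean(data$normalized_score))^2)
  ssr <- sum(res^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  adj_r2 <- if (sst == 0) 1 else 1 - (1 - r2) * (n - 1) / (n - p_eff)
  obj <- structure(list(
    coefficients = coefs,
    fitted = fitted_v,
    residuals = res,
    rmse = sqrt(mean(res^2)),
    r2 = r2,
    adj_r2 = adj_r2,
    model_p = model_p,
    loocv_rmse = NA_real_,
    model_form = model_form,
    spec = spec,
    span = span,
    n = n,
    df_model = p_eff,
    data = data,
    fit = fit,
    call = match.call()
  ), class = "trajectory_fit")
  if (loocv)
    obj$loocv_rmse <- loocv_rmse(data, model_form, spec = spec, span = span)
  obj
}

#' Leave-one-out cross-validation RMSE
#'
#' Root mean squared leave-one-out prediction error for a trajectory model.
#' For the linear-in-parameters forms the default uses the hat-matrix
#' identity \eqn{e_{(i)} = e_i / (1 - h_{ii})}, which equals the explicit
#' n-refit loop exactly; `method = "explicit"` runs the loop (always used for
#' loess).
#'
#' @inheritParams fit_trajectory
#' @param method `"hat"` (shortcut) or `"explicit"` (refit loop).
#' @return the LOOCV RMSE (a single number).
#' @export
loocv_rmse <- function(data, model_form = "natural_spline",
                       spec = spline_spec(), span = 0.75,
                       method = c("hat", "explicit")) {
  method <- match.arg(method)
  check_columns(data, c("age_days", "normalized_score"), "timecourse data")
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 points for LOOCV", call. = FALSE)

  if (model_form == "loess" || method == "explicit") {
    errs <- vapply(seq_len(n), function(i) {
      train <- data[-i, , drop = FALSE]
      pred <- tryCatch({
        if (model_form == "loess") {
          f <- stats::loess(normalized_score ~ age_days, data = train,
                            span = span, degree = 1,
                            control = stats::loess.control(surface = "direct"))
          stats::predict(f, newdata = data[i, , drop = FALSE])
        } else {
          f <- stats::lm(model_formula(model_form, spec, data$age_days),
                         data = train)
          if (anyNA(stats::coef(f))) stop("singular")
          stats::predict(f, newdata = data[i, , drop = FALSE])
        }
      }, error = function(e)
        stop(sprintf("leave-one-out refit without point %d (age %.3g) failed: %s",
                     i, data$age_days[i], conditionMessage(e)), call. = FALSE))
      data$normalized_score[i] - pred
    }, numeric(1))
    return(sqrt(mean(errs^2)))
  }

  fit <- stats::lm(model_formula(model_form, spec, data$age_days), data = data)
  if (anyNA(stats::coef(fit)))
    stop("singular design in LOOCV", call. = FALSE)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  bad <- which(h > 1 - 1e-10)
  if (length(bad))
    stop(sprintf("leave-one-out refit is singular without point %d (age %.3g, leverage 1)",
                 bad[1L], data$age_days[bad[1L]]), call. = FALSE)
  sqrt(mean((stats::residuals(fit) / (1 - h))^2))
}

#' Candidate knot from the loess inflection point
#'
#' Fits a loess smooth (degree 2) to the timecourse, evaluates it on a dense
#' age grid, and returns the age at which the numerical second derivative
#' changes sign — the inflection of the fitted curve, used as a data-driven
#' candidate for the spline's interior knot.  When the smooth is peaked there
#' are two inflections (one on each flank); the one on the declining flank
#' (the first after the fitted maximum) is returned, since the knot marks the
#' transition from the juvenile peak toward the adult plateau.  The final
#' knot remains a configuration choice (default P35 in [spline_spec()]).
#'
#' @inheritParams fit_trajectory
#' @param grid_n number of grid ages for the inflection search.
#' @return inflection age (single number) with all candidate sign-change ages
#'   in `attr(, "candidates")`.
#' @export
select_knot <- function(data, span = 0.75, grid_n = 512) {
  check_columns(data, c("age_days", "normalized_score"), "timecourse data")
  fit <- stats::loess(normalized_score ~ age_days, data = data, span = span,
                      degree = 2,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(data$age_days), max(data$age_days), length.out = grid_n)
  pred <- stats::predict(fit, newdata = data.frame(age_days = grid))
  d2 <- diff(pred, differences = 2)          # curvature at grid[2:(n-1)]
  # numerical curvature blips far below the curve's real curvature scale are
  # not inflections; look for sign flips across the thresholded signal
  s <- sign(d2) * (abs(d2) >= 0.01 * max(abs(d2)))
  nz <- which(s != 0)
  flip <- which(diff(s[nz]) != 0)
  if (!length(flip))
    stop("loess curve has no inflection on the age grid (monotone curvature); ",
         "supply the interior knot explicitly via spline_spec()",
         call. = FALSE)
  cand <- (grid[nz[flip] + 1L] + grid[nz[flip + 1L] + 1L]) / 2
  peak_age <- grid[which.max(pred)]
  after <- cand[cand > peak_age]
  knot <- if (length(after)) after[1L] else cand[1L]
  structure(knot, candidates = cand)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Developmental trajectory fit (", x$model_form, ")\n", sep = "")
  cat(sprintf("  n = %d points, %s parameters\n", x$n,
              format(signif(x$df_model, 3))))
  cat(sprintf("  rmse = %.4g, R2 = %.4g, adj. R2 = %.4g\n",
              x$rmse, x$r2, x$adj_r2))
  if (!is.na(x$model_p))
    cat(sprintf("  overall regression P = %.4g\n", x$model_p))
  if (!is.na(x$loocv_rmse))
    cat(sprintf("  LOOCV rmse = %.4g\n", x$loocv_rmse))
  invisible(x)
}

#' @export
summary.trajectory_fit <- function(object, ...) {
  print(object)
  if (object$model_form != "loess") {
    cat("\nCoefficients:\n")
    print(stats::coef(summary(object$fit)))
  }
  invisible(object)
}

#' @export
coef.trajectory_fit <- function(object, ...) object$coefficients

#' @export
residuals.trajectory_fit <- function(object, ...) object$residuals

#' @export
fitted.trajectory_fit <- function(object, ...) object$fitted

#' Predict normalized preference at new ages
#'
#' @param object a `trajectory_fit`.
#' @param newdata data frame with an `age_days` column (or a numeric vector of
#'   ages).  Defaults to the training data.
#' @param ... unused.
#' @export
predict.trajectory_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.numeric(newdata)) newdata <- data.frame(age_days = newdata)
  check_columns(newdata, "age_days", "newdata")
  as.numeric(stats::predict(object$fit, newdata = newdata))
}

#' Plot a fitted developmental trajectory
#'
#' Scatter of the timecourse points with the fitted curve and a dashed line at
#' the adult no-preference level 1.0.
#'
#' @param x a `trajectory_fit`.
#' @param n_grid number of ages for the curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_fit <- function(x, n_grid = 200, ...) {
  d <- x$data
  graphics::plot(d$age_days, d$normalized_score,
                 xlab = "Age (postnatal days)",
                 ylab = "Normalized social preference",
                 col = "grey40", pch = 16, ...)
  grid <- seq(min(d$age_days), max(d$age_days), length.out = n_grid)
  graphics::lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  graphics::abline(h = 1, lty = 2, col = "grey60")
  invisible(x)
}

#' Simulate timecourses from a fitted trajectory
#'
#' Draws new normalized-score vectors at the training ages, with Gaussian
#' noise at the fit's residual standard deviation.
#'
#' @param object a `trajectory_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed RNG seed.
#' @param ... unused.
#' @return data frame with one column per simulation.
#' @export
simulate.trajectory_fit <- function(object, nsim = 1, seed = 1, ...) {
  mu <- object$fitted
  sigma <- object$rmse
  with_seed(seed, {
    out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}
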