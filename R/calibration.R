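# Calibration of accelerometer mg cut-points against energy-expenditure
# criteria. Two routes share one machinery: the proposed age-equivalent route
# translates adult MET cut-points to common VO2net cut-points by linear
# regression and inverts each age group's anchored VO2net-vs-mg spline; the
# traditional route inverts each group's MET-vs-mg spline at the same MET
# values. In adults the two coincide by construction.

#' Default MET cut-points per intensity level
#' @return named vector: LPA 1.5, MPA 3.0, VPA 6.0, VVPA 9.0 METs.
#' @export
default_met_cutpoints <- function() c(LPA = 1.5, MPA = 3.0, VPA = 6.0, VVPA = 9.0)

intensity_levels <- function() c("SED", "LPA", "MPA", "VPA", "VVPA")

#' Linear MET-to-VO2net regression on adult calibration points
#'
#' Ordinary least squares of VO2net on MET over adult stage records (stand
#' through the fastest run). Used to translate adult MET cut-points into
#' VO2net cut-points that can then be applied identically to every age group.
#'
#' @param points calibration-point data frame with columns `met`, `vo2_net`
#'   and (unless already subset) `age_group`.
#' @param include_stand include the stand stage record (a valid
#'   (MET ~ 1.2, VO2net = 0) observation); default `TRUE`.
#' @return object of class `met_vo2net_fit` with `slope`, `intercept`.
#' @export
fit_met_vo2net_regression <- function(points, include_stand = TRUE) {
  if ("age_group" %in% names(points)) points <- points[points$age_group == "adults", ]
  if (!include_stand && "stage" %in% names(points))
    points <- points[points$stage != "stand", ]
  if (nrow(points) < 2 || length(unique(points$met)) < 2)
    stop("degenerate design: need at least 2 distinct adult MET values")
  fit <- lm(vo2_net ~ met, data = points)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits warn
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 n = nrow(points), r_squared = r2),
            class = "met_vo2net_fit")
}

#' @export
predict.met_vo2net_fit <- function(object, met, ...) {
  object$intercept + object$slope * met
}

#' @export
print.met_vo2net_fit <- function(x, ...) {
  cat(sprintf("<met_vo2net_fit> VO2net = %.3f * MET %+.3f  (n = %d, R^2 = %.3f)\n",
              x$slope, x$intercept, x$n, x$r_squared))
  invisible(x)
}

#' Derive common VO2net cut-points from the adult regression
#'
#' Evaluates the MET-to-VO2net regression at the MET cut-points. Full
#' precision is kept internally; `reported` carries the 1-decimal values used
#' in human-readable output.
#'
#' @param fit a `met_vo2net_fit`.
#' @param met_cutpoints named MET cut-points (default [default_met_cutpoints()]).
#' @return list with `cutpoints` (full precision, named) and `reported`
#'   (rounded to 1 decimal).
#' @export
derive_vo2net_cutpoints <- function(fit, met_cutpoints = default_met_cutpoints()) {
  cp <- predict(fit, met_cutpoints)
  names(cp) <- names(met_cutpoints)
  list(cutpoints = cp, reported = round_half_up(cp, 1))
}

# decimal round-half-up (round() rounds half to even, and binary storage can
# push x.x5 either way); tiny epsilon absorbs representation error
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

# weighted pool-adjacent-violators: non-decreasing fit minimizing weighted SS
pava_nondecreasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- y; wt <- w; len <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; len[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tw
      wt[m - 1L] <- tw
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = len[seq_len(m)])
}

#' Fit an anchored intensity curve (response vs mg)
#'
#' Cubic smoothing spline of the criterion response (VO2net or MET) on
#' accelerometer mg for one age group and placement, with the intercept forced
#' through the physiological anchor: 0 mg corresponds to 0 VO2net or 1 MET.
#' The anchor is enforced by a pseudo-observation carrying `anchor_weight`
#' times the maximum data weight, and pinned exactly on the evaluation grid.
#'
#' Implementation: a cubic regression spline (mgcv) with basis dimension
#' matched to the number of distinct mg clusters and the smoothing parameter
#' chosen by generalized cross-validation - treadmill data cluster at the
#' protocol speeds, and an unrestricted all-knots natural spline is unstable
#' in the empty regions between clusters. When the data determine the
#' response exactly (few distinct mg values, zero within-cluster spread - the
#' noise-free limit), an exact interpolating cubic spline with FMM end
#' conditions is used instead. Non-monotone fits are projected onto the
#' nearest non-decreasing curve (weighted isotonic regression of the grid
#' predictions, anchor kept fixed).
#'
#' @param mg accelerometer values (mg), at least 5 distinct.
#' @param y criterion response values parallel to `mg`.
#' @param response `"vo2_net"` (anchor 0) or `"met"` (anchor 1).
#' @param age_group,placement labels carried on the fitted object.
#' @param anchor_weight pseudo-observation weight multiplier (default 1000).
#' @param grid_step evaluation grid step in mg (default 1).
#' @return object of class `intensity_curve`: monotone grid predictions,
#'   `predict()` support, and fit `r_squared` against the raw points.
#' @export
fit_intensity_curve <- function(mg, y, response = c("vo2_net", "met"),
                                age_group = NA_character_,
                                placement = NA_character_,
                                anchor_weight = 1000, grid_step = 1) {
  response <- match.arg(response)
  keep <- is.finite(mg) & is.finite(y)
  mg <- mg[keep]; y <- y[keep]
  if (length(unique(mg)) < 5) stop("need at least 5 distinct mg values")
  anchor <- if (response == "vo2_net") 0 else 1
  grid <- seq(0, max(mg), by = grid_step)

  # collapse replicate mg values (protocol stages) to weighted cluster means
  ux <- sort(unique(mg))
  um <- vapply(split(y, match(mg, ux)), mean, numeric(1))
  uw <- as.numeric(table(match(mg, ux)))
  spread <- max(vapply(split(y, match(mg, ux)), function(v) diff(range(v)), numeric(1)))
  yscale <- max(abs(y - anchor), 1e-12)

  if (length(ux) <= 10 && spread <= 1e-8 * yscale) {
    # exact data: interpolate through the cluster means. Locomotion
    # energy-cost curves are power-law-like, so the spline is built in
    # log-log space of the increment above the anchor (exact for power laws,
    # benign otherwise); points at or below the anchor level and the region
    # below the first rising point are joined linearly from the anchor.
    dm <- um - anchor
    pos <- dm > 1e-12 * yscale
    pred <- rep(anchor, length(grid))
    if (sum(pos) >= 4) {
      lsf <- splinefun(log(ux[pos]), log(dm[pos]), method = "fmm")
      x1 <- ux[pos][1]
      up <- grid >= x1
      pred[up] <- anchor + exp(lsf(log(grid[up])))
      mid <- grid > 0 & grid < x1
      pred[mid] <- anchor + dm[pos][1] * grid[mid] / x1
    } else {
      pred <- approx(c(0, ux), c(anchor, um), xout = grid, rule = 2)$y
    }
  } else {
    xx <- c(0, mg); yy <- c(anchor, y)
    ww <- c(anchor_weight * 1, rep(1, length(mg)))
    k <- max(4, min(length(ux), 10))
    # pass 1: GCV smoothing parameter on unit weights
    fit <- mgcv::gam(yy ~ s(xx, k = k, bs = "cr"), weights = ww,
                     method = "GCV.Cp")
    # pass 2: inverse-variance weights - VO2 scatter grows with the response,
    # and unweighted GCV lets the top stages dominate the fit
    mu <- pmax(as.numeric(fitted(fit)) - anchor, 0)
    w2 <- 1 / (0.5 + mu)^2
    w2 <- w2 / max(w2)
    w2[1] <- anchor_weight
    fit <- mgcv::gam(yy ~ s(xx, k = k, bs = "cr"), weights = w2,
                     method = "GCV.Cp")
    # final fit: same basis and smoothing parameter, coefficients constrained
    # to a monotone non-decreasing spline (an unconstrained fit can wiggle in
    # the empty regions between stage clusters, and isotonic projection of a
    # wiggle pools it into a flat stretch exactly where cut-points land)
    pred <- tryCatch({
      dat <- data.frame(xx = xx, yy = yy)
      sm <- mgcv::smoothCon(mgcv::s(xx, k = k, bs = "cr"), dat, knots = NULL)[[1]]
      con <- mgcv::mono.con(sm$xp)
      G <- list(X = sm$X, C = matrix(0, 0, 0), sp = fit$sp, p = sm$xp,
                y = yy, w = w2, Ain = con$A, bin = con$b, S = sm$S, off = 0)
      coefs <- mgcv::pcls(G)
      as.numeric(mgcv::Predict.matrix(sm, data.frame(xx = grid)) %*% coefs)
    }, error = function(e)
      as.numeric(predict(fit, data.frame(xx = grid))))
  }
  pred[1] <- anchor                                            # exact pin
  wts <- rep(1, length(pred)); wts[1] <- 1e9
  pred <- pava_nondecreasing(pred, wts)
  pred[1] <- anchor

  fhat <- approx(grid, pred, xout = mg, rule = 2)$y
  r2 <- 1 - sum((y - fhat)^2) / sum((y - mean(y))^2)

  structure(list(grid = grid, fitted = pred, anchor = anchor,
                 response = response, age_group = age_group,
                 placement = placement, r_squared = r2,
                 mg_range = range(mg), n = length(mg)),
            class = "intensity_curve")
}

#' @export
predict.intensity_curve <- function(object, mg, ...) {
  approx(object$grid, object$fitted, xout = mg, rule = 2)$y
}

#' @export
print.intensity_curve <- function(x, ...) {
  cat(sprintf("<intensity_curve> %s ~ mg, %s/%s, n = %d, R^2 = %.3f, mg in [%g, %g]\n",
              x$response, x$age_group, x$placement, x$n, x$r_squared,
              x$mg_range[1], x$mg_range[2]))
  invisible(x)
}

#' Invert an intensity curve to an mg cut-point
#'
#' Smallest mg on the evaluation grid whose predicted response reaches the
#' criterion cut-point, reported as an integer mg. A cut-point above the
#' curve's maximum is an extrapolation error, never silently extrapolated.
#'
#' @param curve an [fit_intensity_curve()] result.
#' @param cutpoint_value criterion value (VO2net in mL/min/kg, or MET).
#' @return integer mg.
#' @export
invert_to_mg <- function(curve, cutpoint_value) {
  stopifnot(inherits(curve, "intensity_curve"))
  if (cutpoint_value > max(curve$fitted))
    stop(sprintf("cut-point %.3g above the fitted curve maximum %.3g (extrapolation refused)",
                 cutpoint_value, max(curve$fitted)))
  idx <- which(curve$fitted >= cutpoint_value)[1]
  as.integer(round(curve$grid[idx]))
}

#' Assemble the cut-point table
#'
#' Builds the full mg cut-point table over placement x age group x calibration
#' method. The age-equivalent method inverts each group's VO2net curve at the
#' common VO2net cut-points; the traditional method inverts each group's MET
#' curve at the MET cut-points, except in adults where it equals the
#' VO2net-based result by construction (the VO2net cut-points are images of
#' the adult MET cut-points under the adult regression, so the two methods
#' select the same adult operating points).
#'
#' @param curves list of `intensity_curve` objects (any order); each must
#'   carry `age_group`, `placement`, `response`.
#' @param vo2net_cutpoints named VO2net cut-points (mL/min/kg), typically from
#'   [derive_vo2net_cutpoints()]`$cutpoints`.
#' @param met_cutpoints named MET cut-points.
#' @return object of class `cutpoint_table`: a data frame with columns
#'   `placement`, `age_group`, `method`, `level`, `mg`, `r_squared`, plus
#'   attributes `vo2net_cutpoints` and `met_cutpoints`. Inversion failures
#'   leave `NA` cells and mark the table incomplete.
#' @export
build_cutpoint_table <- function(curves, vo2net_cutpoints,
                                 met_cutpoints = default_met_cutpoints()) {
  rows <- list(); errors <- character(0)
  key <- function(g, p, r) paste(g, p, r, sep = "|")
  index <- setNames(curves, vapply(curves, function(cv)
    key(cv$age_group, cv$placement, cv$response), character(1)))

  combos <- unique(do.call(rbind, lapply(curves, function(cv)
    data.frame(age_group = cv$age_group, placement = cv$placement))))
  for (i in seq_len(NROW(combos))) {
    g <- combos$age_group[i]; p <- combos$placement[i]
    for (method in c("vo2net", "met")) {
      if (method == "vo2net" || g == "adults") {
        cv <- index[[key(g, p, "vo2_net")]]
        cps <- vo2net_cutpoints
      } else {
        cv <- index[[key(g, p, "met")]]
        cps <- met_cutpoints
      }
      if (is.null(cv)) { errors <- c(errors, key(g, p, method)); next }
      for (lev in names(cps)) {
        mg <- tryCatch(invert_to_mg(cv, cps[[lev]]), error = function(e) {
          errors <<- c(errors, sprintf("%s/%s/%s/%s: %s", p, g, method, lev,
                                       conditionMessage(e)))
          NA_integer_
        })
        rows[[length(rows) + 1]] <- data.frame(
          placement = p, age_group = g, method = method, level = lev,
          mg = mg, r_squared = cv$r_squared)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(placement = character(0), age_group = character(0),
               method = character(0), level = character(0),
               mg = integer(0), r_squared = numeric(0))
  # ordering check: within placement x group x method, LPA < MPA < VPA < VVPA
  if (nrow(tab)) {
    sp <- split(tab, tab[c("placement", "age_group", "method")], drop = TRUE)
    for (cell in sp) {
      mg <- cell$mg[match(c("LPA", "MPA", "VPA", "VVPA"), cell$level)]
      if (!anyNA(mg) && any(diff(mg) <= 0))
        errors <- c(errors, sprintf("non-increasing cut-points in %s/%s/%s",
                                    cell$placement[1], cell$age_group[1],
                                    cell$method[1]))
    }
  }
  structure(tab, class = c("cutpoint_table", "data.frame"),
            vo2net_cutpoints = vo2net_cutpoints,
            met_cutpoints = met_cutpoints,
            complete = length(errors) == 0, errors = errors)
}

#' Extract the cut-points for one placement, age group and method
#'
#' @param table a [build_cutpoint_table()] result (or equivalent data frame).
#' @param placement `"hip"` or `"thigh"`.
#' @param age_group `"children"`, `"adolescents"` or `"adults"`.
#' @param method `"vo2net"` or `"met"`.
#' @return named numeric vector `c(LPA=, MPA=, VPA=, VVPA=)` of mg thresholds.
#' @export
cutpoints_for <- function(table, placement, age_group, method = c("vo2net", "met")) {
  method <- match.arg(method)
  sel <- table[table$placement == placement & table$age_group == age_group &
                 table$method == method, ]
  if (nrow(sel) == 0)
    stop(sprintf("no cut-points for %s/%s/%s", placement, age_group, method))
  setNames(sel$mg, sel$level)[c("LPA", "MPA", "VPA", "VVPA")]
}

#' Calibrate cut-points from a calibration-point set
#'
#' The full calibration procedure on per-subject per-stage records: adult
#' MET-to-VO2net regression, common VO2net cut-points, anchored splines per
#' age group x placement x response, and cut-point table assembly.
#'
#' @param points calibration points: columns `subject_id`, `age_group`,
#'   `placement`, `stage`, `mg`, `vo2_net`, `met`.
#' @param met_cutpoints named MET cut-points.
#' @param anchor_weight,grid_step passed to [fit_intensity_curve()].
#' @return list with `table` (a `cutpoint_table`), `vo2net_cutpoints` (full
#'   and reported), `regression`, and the fitted `curves`.
#' @export
calibrate_cutpoints <- function(points, met_cutpoints = default_met_cutpoints(),
                                anchor_weight = 1000, grid_step = 1) {
  reg <- fit_met_vo2net_regression(points)
  vcp <- derive_vo2net_cutpoints(reg, met_cutpoints)
  curves <- list()
  for (g in unique(points$age_group)) for (p in unique(points$placement)) {
    sub <- points[points$age_group == g & points$placement == p, ]
    if (nrow(sub) == 0) next
    for (resp in c("vo2_net", "met")) {
      curves[[length(curves) + 1]] <- fit_intensity_curve(
        sub$mg, sub[[resp]], response = resp, age_group = g, placement = p,
        anchor_weight = anchor_weight, grid_step = grid_step)
    }
  }
  tab <- build_cutpoint_table(curves, vcp$cutpoints, met_cutpoints)
  list(table = tab, vo2net_cutpoints = vcp, regression = reg, curves = curves)
}
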