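#' Four-parameter logistic concentration-response curve
#'
#' Constructs a 4PL curve in normalized percent-of-T0 response space:
#' \deqn{f(c) = bottom + \frac{top - bottom}{1 + (c / inflection)^{slope}}}
#' With `slope > 0` the response decreases with concentration from `top`
#' towards `bottom` (the usual shape for a growth-inhibition assay); a
#' negative slope encodes an increasing curve. Parameters are canonicalized
#' so that `top >= bottom` (swapping flips the slope sign).
#'
#' @param bottom Lower asymptote, %T0.
#' @param top Upper asymptote, %T0.
#' @param inflection Inflection concentration (midpoint of the transition), nM.
#' @param slope Hill slope, dimensionless and nonzero.
#' @return An object of class `fourpl_curve`.
#' @examples
#' cv <- fourpl_curve(0, 300, 1000, 1)
#' fourpl_response(cv, c(0, 1000, 30000))
#' @export
fourpl_curve <- function(bottom, top, inflection, slope) {
  if (!is.finite(bottom) || !is.finite(top)) stop("bottom/top must be finite")
  if (!is.finite(inflection) || inflection <= 0) stop("inflection must be a positive finite concentration")
  if (!is.finite(slope) || slope == 0) stop("slope must be finite and nonzero")
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp
    slope <- -slope
  }
  structure(list(bottom = bottom, top = top, inflection = inflection, slope = slope),
            class = "fourpl_curve")
}

#' @export
print.fourpl_curve <- function(x, ...) {
  cat(sprintf("4PL curve: bottom %.4g, top %.4g (%%T0), inflection %.4g nM, slope %.4g\n",
              x$bottom, x$top, x$inflection, x$slope))
  invisible(x)
}

#' Evaluate a 4PL curve
#'
#' @param curve A [fourpl_curve()].
#' @param conc Concentration vector, nM (zero allowed; gives the no-dose asymptote).
#' @return Response in %T0.
#' @export
fourpl_response <- function(curve, conc) {
  stopifnot(inherits(curve, "fourpl_curve"))
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  curve$bottom + (curve$top - curve$bottom) / (1 + (conc / curve$inflection)^curve$slope)
}

# Closed-form inversion without range censoring; NA when the level lies outside
# the open asymptote interval.
.invert_closed <- function(curve, level) {
  b <- curve$bottom; t <- curve$top
  if (!is.finite(level) || level <= b || level >= t) return(NA_real_)
  ratio <- (t - level) / (level - b)
  curve$inflection * ratio^(1 / curve$slope)
}

#' Invert a 4PL curve at a response level
#'
#' Returns the unique concentration at which the monotone fitted curve equals
#' `level`, with explicit censoring: `"unreachable"` when the level lies outside
#' the open `(bottom, top)` asymptote interval, `"gt_max"` when it is attained
#' only above `max_conc` (the value slot then carries `max_conc` as a bound).
#'
#' @param curve A [fourpl_curve()].
#' @param level Target response, %T0.
#' @param max_conc Highest tested concentration, nM (`Inf` disables range
#'   censoring, e.g. for equi-effective-dose lookups).
#' @return A list with `value` (nM) and `censor` (`"none"`, `"gt_max"`,
#'   `"unreachable"`).
#' @examples
#' cv <- fourpl_curve(0, 300, 1000, 1)
#' invert_fourpl(cv, 200)           # 500 nM
#' invert_fourpl(cv, 100)           # 2000 nM
#' invert_fourpl(cv, 350)           # unreachable
#' @export
invert_fourpl <- function(curve, level, max_conc = Inf) {
  x <- .invert_closed(curve, level)
  if (is.na(x)) return(list(value = NA_real_, censor = "unreachable"))
  if (x > max_conc) return(list(value = max_conc, censor = "gt_max"))
  list(value = x, censor = "none")
}

#' Normalized concentration-response data
#'
#' Container for plate data after T0 normalization: responses are percent of
#' the time-of-dosing (T0) measurement, so T0 is 100 by construction and the
#' DMSO (untreated endpoint) level records how much the line grew over the
#' assay.
#'
#' @param conc Strictly increasing positive concentrations, nM.
#' @param response Mean response at each concentration, %T0.
#' @param dmso_level Mean DMSO response, %T0.
#' @param max_tested_conc Highest tested concentration, nM.
#' @return An object of class `normalized_curve_data`.
#' @export
normalized_curve_data <- function(conc, response, dmso_level,
                                  max_tested_conc = max(conc)) {
  if (length(conc) != length(response)) stop("conc and response lengths differ")
  if (any(!is.finite(conc)) || any(conc <= 0)) stop("concentrations must be positive and finite")
  if (is.unsorted(conc, strictly = TRUE)) stop("concentrations must be strictly increasing")
  if (!is.finite(dmso_level) || dmso_level <= 0) stop("dmso_level must be positive")
  structure(list(conc = conc, response = response, dmso_level = dmso_level,
                 max_tested_conc = max_tested_conc),
            class = "normalized_curve_data")
}

#' Normalize raw plate signals to the T0 anchor
#'
#' Responses are expressed as percent of the mean T0 (time-of-dosing) signal;
#' replicate wells at the same concentration are averaged (arithmetic mean)
#' before output, and the DMSO wells give the untreated endpoint level on the
#' same scale.
#'
#' @param conc Concentration of each treated well, nM.
#' @param signal Raw signal of each treated well (positive).
#' @param t0_signals Raw signals of the T0 anchor wells (>= 1 well).
#' @param dmso_signals Raw signals of the DMSO anchor wells (>= 1 well).
#' @return A [normalized_curve_data()].
#' @examples
#' normalize_to_t0(c(10, 100), c(150, 80), t0_signals = c(90, 110),
#'                 dmso_signals = c(280, 320))
#' @export
normalize_to_t0 <- function(conc, signal, t0_signals, dmso_signals) {
  if (length(t0_signals) < 1 || any(!is.finite(t0_signals)) || any(t0_signals <= 0))
    stop("anchor error: need at least one positive T0 well")
  if (length(dmso_signals) < 1 || any(!is.finite(dmso_signals)) || any(dmso_signals <= 0))
    stop("anchor error: need at least one positive DMSO well")
  if (length(conc) != length(signal)) stop("conc and signal lengths differ")
  if (any(!is.finite(signal)) || any(signal <= 0)) stop("treated signals must be positive")
  t0m <- mean(t0_signals)
  resp <- 100 * signal / t0m
  mean_by_conc <- tapply(resp, conc, mean)
  cc <- as.numeric(names(mean_by_conc))
  o <- order(cc)
  normalized_curve_data(cc[o], as.numeric(mean_by_conc)[o],
                        dmso_level = 100 * mean(dmso_signals) / t0m)
}

# Deterministic jitter schedule for fit restarts: (log10 shift applied to the
# inflection start, multiplier applied to the slope start).
.fit_jitters <- list(c(0, 1), c(1, 1), c(-1, 1), c(0, 0.5), c(0, 2), c(1, 0.5))

#' Fit a 4PL curve by least squares
#'
#' Nonlinear least squares in a log-inflection parameterization
#' (`y ~ b + (t-b)/(1 + exp(s*(log(c) - logI)))`), initialized from data
#' quantiles (top = max response, bottom = min response, inflection = the
#' concentration nearest mid-response, slope = 1) with a deterministic schedule
#' of jittered restarts. Degenerate data (no measurable dose effect, fitted
#' span below 1 %T0, or no convergent fit) yields a flagged result rather than
#' an error; downstream metrics are then censored.
#'
#' @param data A [normalized_curve_data()] with at least 4 distinct concentrations.
#' @return An object of class `fourpl_fit`: list with `curve`
#'   ([fourpl_curve()]), `rss`, `converged`, `degenerate`.
#' @export
fit_fourpl <- function(data) {
  stopifnot(inherits(data, "normalized_curve_data"))
  conc <- data$conc; y <- data$response
  if (length(conc) < 4) stop("need at least 4 distinct concentrations to fit a 4PL")
  span <- diff(range(y))
  geo_mid <- exp(mean(log(range(conc))))
  if (!is.finite(span) || span < 1e-8) {
    return(structure(list(curve = fourpl_curve(mean(y) - 0.5, mean(y) + 0.5, geo_mid, 1),
                          rss = 0, converged = FALSE, degenerate = TRUE),
                     class = "fourpl_fit"))
  }
  df <- data.frame(lc = log(conc), y = y)
  t0 <- max(y); b0 <- min(y)
  li0 <- df$lc[which.min(abs(y - (t0 + b0) / 2))]
  s0 <- if (y[1] >= y[length(y)]) 1 else -1
  best <- NULL
  for (j in .fit_jitters) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + (t - b) / (1 + exp(s * (lc - li))),
                        data = df,
                        start = list(b = b0, t = t0, li = li0 + j[1] * log(10),
                                     s = s0 * j[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-15,
                                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    # stop restarting once the fit explains >= 95% of the response variance
    if (isTRUE(fit$convInfo$isConv) && rss <= 0.05 * sum((y - mean(y))^2)) break
  }
  if (is.null(best)) {
    return(structure(list(curve = fourpl_curve(b0, max(t0, b0 + 1), geo_mid, 1),
                          rss = NA_real_, converged = FALSE, degenerate = TRUE),
                     class = "fourpl_fit"))
  }
  cf <- stats::coef(best$fit)
  curve <- fourpl_curve(unname(cf["b"]), unname(cf["t"]),
                        exp(unname(cf["li"])), unname(cf["s"]))
  degenerate <- (curve$top - curve$bottom) < 1
  structure(list(curve = curve, rss = best$rss,
                 converged = isTRUE(best$fit$convInfo$isConv),
                 degenerate = degenerate),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  RSS %.4g; converged %s; degenerate %s\n",
              x$rss, x$converged, x$degenerate))
  invisible(x)
}

#' Growth metrics from a fitted curve
#'
#' Extracts the screen's potency metrics from a fitted 4PL curve and its
#' source data, each with explicit censoring:
#' * `gic50` — concentration at the midpoint of the growth window,
#'   `(dmso_level + 100)/2` %T0;
#' * `gic100` — concentration of complete growth stasis (response = 100 %T0);
#' * `dec50` — concentration of 50% net cell death (response = 50 %T0);
#' * `ymin_minus_t0` — minimum of the fitted curve over the tested
#'   concentration range minus 100 (positive = net growth, negative = net
#'   death).
#'
#' Concentrations attained only beyond the tested range are censored
#' `"gt_max"` (carrying the max tested concentration as a bound); levels
#' outside the fitted asymptotes are `"unreachable"`. A degenerate fit censors
#' all three concentrations (`"degenerate"`, bound = max tested) and sets
#' `ymin_minus_t0 = dmso_level - 100`.
#'
#' @param fit A `fourpl_fit` (or bare [fourpl_curve()], treated as non-degenerate).
#' @param data The [normalized_curve_data()] the curve was fitted to.
#' @return An object of class `growth_metrics`.
#' @examples
#' cv <- fourpl_curve(0, 300, 1000, 1)
#' concs <- 30000 / 3^(9:0)
#' dat <- normalized_curve_data(concs, fourpl_response(cv, concs), dmso_level = 300)
#' growth_metrics(fit_fourpl(dat), dat)
#' @export
growth_metrics <- function(fit, data) {
  stopifnot(inherits(data, "normalized_curve_data"))
  if (inherits(fit, "fourpl_curve")) fit <- list(curve = fit, degenerate = FALSE)
  curve <- fit$curve
  mx <- data$max_tested_conc
  if (isTRUE(fit$degenerate)) {
    cen <- list(value = mx, censor = "degenerate")
    out <- list(gic50 = cen, gic100 = cen, dec50 = cen,
                ymin_minus_t0 = data$dmso_level - 100,
                dmso_level = data$dmso_level, max_tested_conc = mx)
    return(structure(out, class = "growth_metrics"))
  }
  lv <- c(gic50 = (data$dmso_level + 100) / 2, gic100 = 100, dec50 = 50)
  mets <- lapply(lv, function(l) invert_fourpl(curve, l, max_conc = mx))
  ymin <- min(fourpl_response(curve, range(data$conc))) - 100
  structure(c(mets, list(ymin_minus_t0 = ymin,
                         dmso_level = data$dmso_level, max_tested_conc = mx)),
            class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  fmt <- function(m) {
    if (m$censor == "none") sprintf("%.4g nM", m$value)
    else if (m$censor == "gt_max") sprintf("> %.4g nM", m$value)
    else m$censor
  }
  cat(sprintf("gIC50 %s; gIC100 %s; dEC50 %s; Ymin-T0 %.4g %%T0 (DMSO %.4g %%T0)\n",
              fmt(x$gic50), fmt(x$gic100), fmt(x$dec50),
              x$ymin_minus_t0, x$dmso_level))
  invisible(x)
}

#' Aggregate growth metrics across biological replicates
#'
#' Concentration metrics are averaged on the log10 scale (geometric mean)
#' among uncensored replicates; a metric is censored in the aggregate only if
#' it is censored in every replicate (the aggregate then carries the largest
#' replicate bound). Metrics aggregated from a mix of censored and uncensored
#' replicates are flagged `"partial"`. `ymin_minus_t0` and `dmso_level` use
#' the arithmetic mean; `max_tested_conc` the maximum.
#'
#' @param metrics_list Nonempty list of [growth_metrics()] objects.
#' @return A `growth_metrics` object with an added `partial` logical vector.
#' @export
aggregate_replicates <- function(metrics_list) {
  if (length(metrics_list) < 1) stop("need at least one replicate")
  stopifnot(all(vapply(metrics_list, inherits, logical(1), "growth_metrics")))
  agg_one <- function(name) {
    vals <- vapply(metrics_list, function(m) m[[name]]$value, numeric(1))
    cens <- vapply(metrics_list, function(m) m[[name]]$censor, character(1))
    unc <- cens == "none"
    if (any(unc)) {
      list(value = 10^mean(log10(vals[unc])),
           censor = "none", partial = any(!unc))
    } else {
      kind <- if (any(cens == "gt_max")) "gt_max" else cens[1]
      list(value = max(vals, na.rm = TRUE), censor = kind, partial = FALSE)
    }
  }
  mets <- lapply(c(gic50 = "gic50", gic100 = "gic100", dec50 = "dec50"), agg_one)
  partial <- vapply(mets, function(m) m$partial, logical(1))
  mets <- lapply(mets, function(m) m[c("value", "censor")])
  out <- c(mets,
           list(ymin_minus_t0 = mean(vapply(metrics_list, `[[`, numeric(1), "ymin_minus_t0")),
                dmso_level = mean(vapply(metrics_list, `[[`, numeric(1), "dmso_level")),
                max_tested_conc = max(vapply(metrics_list, `[[`, numeric(1), "max_tested_conc")),
                partial = partial))
  structure(out, class = "growth_metrics")
}

# One-row data.frame view of a growth_metrics object (used by fit_panel and IO).
.metrics_row <- function(gm) {
  data.frame(gic50_nM = gm$gic50$value, gic50_censor = gm$gic50$censor,
             gic100_nM = gm$gic100$value, gic100_censor = gm$gic100$censor,
             dec50_nM = gm$dec50$value, dec50_censor = gm$dec50$censor,
             ymin_minus_t0 = gm$ymin_minus_t0, dmso_level = gm$dmso_level,
             max_tested_conc = gm$max_tested_conc,
             stringsAsFactors = FALSE)
}
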