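#' Fixed-ratio combination design
#'
#' @param agent_a,agent_b Agent identifiers (must match plate `agent` labels).
#' @param parts_a,parts_b Positive mixture parts; fractions are
#'   `parts / sum(parts)` (4:1 gives 0.8/0.2).
#' @return An object of class `fixed_ratio_design`.
#' @export
fixed_ratio_design <- function(agent_a, agent_b, parts_a = 4, parts_b = 1) {
  if (parts_a <= 0 || parts_b <= 0) stop("ratio parts must be positive")
  structure(list(agent_a = agent_a, agent_b = agent_b,
                 fraction_a = parts_a / (parts_a + parts_b),
                 fraction_b = parts_b / (parts_a + parts_b)),
            class = "fixed_ratio_design")
}

#' Synergy classification rules
#'
#' Thresholds of the three-tier call: strongly synergistic when the summary CI
#' is below `ci_strong` and both agents shift in potency by at least
#' `fold_strong` at some measured parameter; synergistic when CI is below
#' `ci_synergy` with both fold shifts at least `fold_synergy`; additive
#' otherwise (including CI between `ci_synergy` and 1, and any CI >= 1 — no
#' antagonism tier is defined).
#'
#' @param ci_strong,fold_strong CI and fold-shift thresholds of the strong tier.
#' @param ci_synergy,fold_synergy Thresholds of the synergistic tier.
#' @param same_parameter If `TRUE` (default) both agents must reach the
#'   fold-shift threshold at the same measured parameter (gIC50, gIC100 or
#'   dEC50); if `FALSE` each agent may satisfy it at a different parameter.
#' @return An object of class `synergy_rules`.
#' @export
synergy_rules <- function(ci_strong = 0.44, fold_strong = 5,
                          ci_synergy = 0.78, fold_synergy = 3,
                          same_parameter = TRUE) {
  stopifnot(ci_strong > 0, ci_synergy >= ci_strong, fold_strong >= fold_synergy,
            is.logical(same_parameter))
  structure(list(ci_strong = ci_strong, fold_strong = fold_strong,
                 ci_synergy = ci_synergy, fold_synergy = fold_synergy,
                 same_parameter = same_parameter),
            class = "synergy_rules")
}

#' Mutually non-exclusive combination index
#'
#' \deqn{CI = D_1/Dx_1 + D_2/Dx_2 + (D_1 D_2)/(Dx_1 Dx_2)}
#' where `D1`, `D2` are the component doses of the mixture at an effect level
#' and `Dx1`, `Dx2` the single-agent doses producing the same effect. An
#' unreachable single-agent dose (monotherapy cannot achieve the effect) is
#' passed as `Inf`; its terms contribute 0 and the result is flagged
#' `monotherapy_incapable` — the limit `Dx -> Inf` of the formula.
#'
#' @param d1,d2 Component doses in the mixture, nM (nonnegative, not both 0).
#' @param dx1,dx2 Single-agent equi-effective doses, nM (may be `Inf`).
#' @return List with `ci` and logical `monotherapy_incapable`.
#' @examples
#' combination_index(50, 50, 100, 100)   # sham halves: 0.5 + 0.5 + 0.25 = 1.25
#' combination_index(10, 10, 100, 100)   # 0.1 + 0.1 + 0.01 = 0.21
#' @export
combination_index <- function(d1, d2, dx1, dx2) {
  if (d1 < 0 || d2 < 0) stop("doses must be nonnegative")
  if (d1 == 0 && d2 == 0) stop("at least one component dose must be positive")
  if (dx1 <= 0 || dx2 <= 0) stop("equi-effective doses must be positive (Inf if unreachable)")
  t1 <- if (is.finite(dx1)) d1 / dx1 else 0
  t2 <- if (is.finite(dx2)) d2 / dx2 else 0
  list(ci = t1 + t2 + t1 * t2,
       monotherapy_incapable = !is.finite(dx1) || !is.finite(dx2))
}

#' Three-tier synergy call from per-level CIs and fold shifts
#'
#' The summary CI is the minimum over the available effect levels. The call is
#' `strongly_synergistic` iff summary CI < 0.44 and the fold-shift condition
#' holds at threshold 5; `synergistic` iff summary CI < 0.78 at threshold 3;
#' otherwise `additive` (CI in \[0.78, 1\], CI above 1, or an insufficient
#' fold shift from either single agent).
#'
#' @param ci Numeric vector of per-level CI values (NA = level unavailable).
#' @param fold_a,fold_b Per-level fold shifts in potency from each single
#'   agent (NA where not computable).
#' @param rules A [synergy_rules()].
#' @return One of `"strongly_synergistic"`, `"synergistic"`, `"additive"`.
#' @examples
#' classify_synergy(0.30, 6, 7)            # strongly_synergistic
#' classify_synergy(0.50, 4, 3.2)          # synergistic
#' classify_synergy(0.60, 8, 2)            # additive (one shift < 3)
#' classify_synergy(0.90, 10, 10)          # additive
#' @export
classify_synergy <- function(ci, fold_a, fold_b, rules = synergy_rules()) {
  stopifnot(inherits(rules, "synergy_rules"))
  if (!any(is.finite(ci))) return("additive")
  summary_ci <- min(ci, na.rm = TRUE)
  fold_ok <- function(thr) {
    fa <- ifelse(is.na(fold_a), -Inf, fold_a)
    fb <- ifelse(is.na(fold_b), -Inf, fold_b)
    if (rules$same_parameter) any(fa >= thr & fb >= thr)
    else any(fa >= thr) && any(fb >= thr)
  }
  if (summary_ci < rules$ci_strong && fold_ok(rules$fold_strong))
    return("strongly_synergistic")
  if (summary_ci < rules$ci_synergy && fold_ok(rules$fold_synergy))
    return("synergistic")
  "additive"
}

#' Analyze one fixed-ratio combination experiment
#'
#' Fits 4PL curves to agent A alone, agent B alone and the fixed-ratio
#' mixture (all in total-dose units), then for each effect level defined by
#' the mixture's growth metrics (gIC50 level `(DMSO+100)/2`, gIC100 level 100,
#' dEC50 level 50 %T0) that the mixture attains within its tested range:
#' * splits the total mixture dose into component doses
#'   `D1 = fraction_a * D`, `D2 = fraction_b * D`;
#' * looks up each single agent's equi-effective dose `Dx` by model inversion
#'   at the same response level (extrapolation beyond the tested range is
#'   allowed here; only a level outside an agent's asymptotes makes its term
#'   unreachable);
#' * computes the mutually non-exclusive [combination_index()];
#' * computes fold shifts in potency as each agent's own metric divided by its
#'   per-component concentration in the mixture (only where both are
#'   uncensored).
#'
#' The summary CI is the minimum over available levels and the call follows
#' [classify_synergy()]. A mixture attaining no level is called `additive`
#' with reason `"no attainable effect level"`.
#'
#' @param data_a,data_b,data_mix [normalized_curve_data()] for the two single
#'   agents and the mixture (same line and duration).
#' @param design A [fixed_ratio_design()].
#' @param rules A [synergy_rules()].
#' @return An object of class `combination_result`: list with `levels` (one
#'   row per effect level: total and component doses, Dx values, CI, flags,
#'   fold shifts), `summary_ci`, `call`, `reason`.
#' @export
analyze_combination <- function(data_a, data_b, data_mix, design,
                                rules = synergy_rules()) {
  stopifnot(inherits(design, "fixed_ratio_design"))
  fit_a <- fit_fourpl(data_a)
  fit_b <- fit_fourpl(data_b)
  fit_mix <- fit_fourpl(data_mix)
  met_a <- growth_metrics(fit_a, data_a)
  met_b <- growth_metrics(fit_b, data_b)

  level_names <- c("gic50", "gic100", "dec50")
  levels_mix <- c(gic50 = (data_mix$dmso_level + 100) / 2, gic100 = 100, dec50 = 50)
  rows <- lapply(level_names, function(nm) {
    row <- data.frame(level = nm, level_pct_t0 = levels_mix[[nm]],
                      d_total = NA_real_, d1 = NA_real_, d2 = NA_real_,
                      dx1 = NA_real_, dx2 = NA_real_, ci = NA_real_,
                      monotherapy_incapable = NA,
                      fold_a = NA_real_, fold_b = NA_real_,
                      stringsAsFactors = FALSE)
    if (fit_mix$degenerate) return(row)
    dmix <- invert_fourpl(fit_mix$curve, levels_mix[[nm]],
                          max_conc = data_mix$max_tested_conc)
    if (dmix$censor != "none") return(row)
    d <- dmix$value
    d1 <- design$fraction_a * d
    d2 <- design$fraction_b * d
    dx1 <- if (fit_a$degenerate) Inf else {
      v <- .invert_closed(fit_a$curve, levels_mix[[nm]]); if (is.na(v)) Inf else v
    }
    dx2 <- if (fit_b$degenerate) Inf else {
      v <- .invert_closed(fit_b$curve, levels_mix[[nm]]); if (is.na(v)) Inf else v
    }
    cix <- combination_index(d1, d2, dx1, dx2)
    row$d_total <- d; row$d1 <- d1; row$d2 <- d2
    row$dx1 <- dx1; row$dx2 <- dx2
    row$ci <- cix$ci; row$monotherapy_incapable <- cix$monotherapy_incapable
    # Fold shift: each agent's own potency metric over its in-mixture
    # component concentration at the matching parameter.
    own_a <- met_a[[nm]]; own_b <- met_b[[nm]]
    if (own_a$censor == "none") row$fold_a <- own_a$value / d1
    if (own_b$censor == "none") row$fold_b <- own_b$value / d2
    row
  })
  lev <- do.call(rbind, rows)
  if (!any(is.finite(lev$ci))) {
    return(structure(list(levels = lev, summary_ci = NA_real_,
                          call = "additive",
                          reason = "no attainable effect level",
                          design = design),
                     class = "combination_result"))
  }
  call <- classify_synergy(lev$ci, lev$fold_a, lev$fold_b, rules)
  structure(list(levels = lev, summary_ci = min(lev$ci, na.rm = TRUE),
                 call = call, reason = NA_character_, design = design),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("Combination result: call = %s (summary CI %.3g)\n",
              x$call, x$summary_ci))
  print(x$levels, row.names = FALSE)
  invisible(x)
}
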