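#' Default gene mutation frequencies for the synthetic panel
#'
#' A small pan-cancer marker panel with frequencies in the range typical of
#' large cell-line collections.
#' @return Named numeric vector of per-gene mutation frequencies.
#' @export
default_mutation_freqs <- function() {
  c(TP53 = 0.50, KRAS = 0.25, PIK3CA = 0.20, APC = 0.15, CDKN2A = 0.12,
    PTEN = 0.12, BRAF = 0.10, RB1 = 0.10, ARID1A = 0.10, NF1 = 0.08,
    SMAD4 = 0.08, STK11 = 0.07, CTNNB1 = 0.06, NRAS = 0.05, HRAS = 0.02)
}

.default_tumor_props <- c(heme = 0.17, lung = 0.17, colon = 0.13, breast = 0.13,
                          ovary = 0.11, other = 0.11, pancreas = 0.09, skin = 0.09)

# Integer tumor-type counts summing exactly to n, from the default proportions.
.default_tumor_counts <- function(n) {
  cum <- round(cumsum(.default_tumor_props) * n)
  counts <- diff(c(0L, cum))
  names(counts) <- names(.default_tumor_props)
  counts[counts > 0]
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (length(x) != 1 || !is.finite(x) || x < lower || x > upper ||
      (strict_lower && x <= lower))
    stop(sprintf("invalid configuration: field '%s'", name))
  x
}

#' Configuration for a synthetic single-agent screen
#'
#' Defaults emulate a ~230-line pan-cancer screen: lognormal baseline potency
#' centred on 550 nM (log10 sd 0.8, spanning roughly 13 nM to beyond 29 uM),
#' mutation-linked resistance multipliers applied to the inflection
#' concentration of mutant lines (the default 3x KRAS multiplier reproduces a
#' mutant/WT median potency ratio of about 1650/550 nM), 10-point 3-fold
#' dilutions from 30 uM, and 5% multiplicative measurement noise.
#'
#' @param n_lines Number of cell lines.
#' @param tumor_types Named integer vector of per-type line counts summing to
#'   `n_lines`; `NULL` uses default pan-cancer proportions.
#' @param mutation_freqs Named per-gene mutation frequencies in `[0, 1]`.
#' @param effect_multipliers Named per-gene multiplicative shifts applied to
#'   the inflection concentration of mutant lines for the first agent
#'   (> 1 = resistance). Must be positive.
#' @param baseline_gic50_log10_mean,baseline_gic50_log10_sd Normal parameters
#'   of the log10 inflection concentration (nM).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 disables noise).
#' @param dose_grid List with `top_conc_nM`, `dilution` (> 1) and `n_points`
#'   (>= 4).
#' @param n_replicates Treated wells per concentration.
#' @param n_anchor_wells T0 and DMSO wells per plate.
#' @param agents Character vector of agent names (first agent carries the
#'   mutation-linked multipliers).
#' @param seed Integer seed; identical seed + config gives identical output.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_lines = 230,
                         tumor_types = NULL,
                         mutation_freqs = default_mutation_freqs(),
                         effect_multipliers = c(KRAS = 3),
                         baseline_gic50_log10_mean = log10(550),
                         baseline_gic50_log10_sd = 0.8,
                         noise_cv = 0.05,
                         dose_grid = list(top_conc_nM = 30000, dilution = 3, n_points = 10),
                         n_replicates = 2,
                         n_anchor_wells = 6,
                         agents = "BETi",
                         seed = 1L) {
  .check_scalar(n_lines, "n_lines", lower = 1)
  if (is.null(tumor_types)) tumor_types <- .default_tumor_counts(n_lines)
  if (is.null(names(tumor_types)) || sum(tumor_types) != n_lines)
    stop("invalid configuration: field 'tumor_types' (named counts must sum to n_lines)")
  if (length(mutation_freqs) && (is.null(names(mutation_freqs)) ||
      any(!is.finite(mutation_freqs)) || any(mutation_freqs < 0) || any(mutation_freqs > 1)))
    stop("invalid configuration: field 'mutation_freqs' (named frequencies in [0,1])")
  if (length(effect_multipliers) && (is.null(names(effect_multipliers)) ||
      any(!is.finite(effect_multipliers)) || any(effect_multipliers <= 0)))
    stop("invalid configuration: field 'effect_multipliers' (named positive multipliers)")
  .check_scalar(baseline_gic50_log10_mean, "baseline_gic50_log10_mean")
  .check_scalar(baseline_gic50_log10_sd, "baseline_gic50_log10_sd", lower = 0)
  .check_scalar(noise_cv, "noise_cv", lower = 0)
  .check_scalar(dose_grid$top_conc_nM, "dose_grid$top_conc_nM", lower = 0, strict_lower = TRUE)
  .check_scalar(dose_grid$dilution, "dose_grid$dilution", lower = 1, strict_lower = TRUE)
  .check_scalar(dose_grid$n_points, "dose_grid$n_points", lower = 4)
  .check_scalar(n_replicates, "n_replicates", lower = 1)
  .check_scalar(n_anchor_wells, "n_anchor_wells", lower = 1)
  if (!is.character(agents) || length(agents) < 1)
    stop("invalid configuration: field 'agents'")
  .check_scalar(seed, "seed")
  structure(list(n_lines = as.integer(n_lines), tumor_types = tumor_types,
                 mutation_freqs = mutation_freqs,
                 effect_multipliers = effect_multipliers,
                 baseline_gic50_log10_mean = baseline_gic50_log10_mean,
                 baseline_gic50_log10_sd = baseline_gic50_log10_sd,
                 noise_cv = noise_cv, dose_grid = dose_grid,
                 n_replicates = as.integer(n_replicates),
                 n_anchor_wells = as.integer(n_anchor_wells),
                 agents = agents, seed = as.integer(seed)),
            class = "panel_config")
}

#' Configuration for a fixed-ratio combination titration
#'
#' @param parts_a,parts_b Positive mixture parts (e.g. 4:1).
#' @param psi Synergy parameter: 1 = Loewe-additive; < 1 inflates the
#'   equivalent dose by `1/psi` (synergistic potency gain); > 1 antagonistic.
#' @param duration_days Assay duration, 3 or 6 days.
#' @param seed Integer seed for the plate noise.
#' @return An object of class `combo_config`.
#' @export
combo_config <- function(parts_a = 4, parts_b = 1, psi = 1,
                         duration_days = 6, seed = 1L) {
  .check_scalar(parts_a, "parts_a", lower = 0, strict_lower = TRUE)
  .check_scalar(parts_b, "parts_b", lower = 0, strict_lower = TRUE)
  .check_scalar(psi, "psi", lower = 0, strict_lower = TRUE)
  if (!duration_days %in% c(3, 6))
    stop("invalid configuration: field 'duration_days' (3 or 6)")
  .check_scalar(seed, "seed")
  structure(list(parts_a = parts_a, parts_b = parts_b,
                 fraction_a = parts_a / (parts_a + parts_b),
                 fraction_b = parts_b / (parts_a + parts_b),
                 psi = psi, duration_days = duration_days, seed = as.integer(seed)),
            class = "combo_config")
}

#' Configuration for a synthetic xenograft efficacy study
#'
#' @param n_per_group Animals per group (>= 2).
#' @param v0_mm3 Randomization tumor-volume range, mm^3 (length-2).
#' @param growth_rate_per_day Named per-group exponential growth rates, /day.
#' @param endpoint_volume_mm3 Endpoint volume; must exceed the top of `v0_mm3`.
#' @param measurement_interval_days Days between caliper measurements.
#' @param noise_cv Multiplicative lognormal measurement noise CV.
#' @param max_study_day Final study day (right-censoring time).
#' @param seed Integer seed.
#' @return An object of class `xeno_config`.
#' @export
xeno_config <- function(n_per_group = 10, v0_mm3 = c(100, 200),
                        growth_rate_per_day = c(vehicle = 0.12, treated = 0.06),
                        endpoint_volume_mm3 = 2000,
                        measurement_interval_days = 3.5,
                        noise_cv = 0.1, max_study_day = 60, seed = 1L) {
  .check_scalar(n_per_group, "n_per_group", lower = 2)
  if (length(v0_mm3) != 2 || any(!is.finite(v0_mm3)) || any(v0_mm3 <= 0) ||
      v0_mm3[1] > v0_mm3[2])
    stop("invalid configuration: field 'v0_mm3'")
  if (is.null(names(growth_rate_per_day)) || any(!is.finite(growth_rate_per_day)))
    stop("invalid configuration: field 'growth_rate_per_day' (named finite rates)")
  .check_scalar(endpoint_volume_mm3, "endpoint_volume_mm3",
                lower = max(v0_mm3), strict_lower = TRUE)
  .check_scalar(measurement_interval_days, "measurement_interval_days",
                lower = 0, strict_lower = TRUE)
  .check_scalar(noise_cv, "noise_cv", lower = 0)
  .check_scalar(max_study_day, "max_study_day", lower = 0, strict_lower = TRUE)
  .check_scalar(seed, "seed")
  structure(list(n_per_group = as.integer(n_per_group), v0_mm3 = v0_mm3,
                 growth_rate_per_day = growth_rate_per_day,
                 endpoint_volume_mm3 = endpoint_volume_mm3,
                 measurement_interval_days = measurement_interval_days,
                 noise_cv = noise_cv, max_study_day = max_study_day,
                 seed = as.integer(seed)),
            class = "xeno_config")
}

# Multiplicative lognormal noise factors with unit mean and the given CV.
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

.aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Recurrent-hotspot catalogs for a few well-known genes; everything else gets
# random missense changes plus ~12% ambiguous (frameshift/splice) strings that
# must fall back to gene-level markers.
.pc_catalog <- list(
  KRAS = c("G12D", "G12V", "G12C", "G13D", "Q61H"),
  NRAS = c("Q61K", "Q61R", "G12D"),
  HRAS = c("G12V", "Q61L"),
  BRAF = c("V600E", "V600E", "V600K", "G469A"),
  PIK3CA = c("E545K", "H1047R", "E542K")
)

.random_protein_change <- function(n) {
  kind <- sample(c("missense", "fs", "splice"), n, replace = TRUE,
                 prob = c(0.88, 0.08, 0.04))
  pos <- sample(30:900, n, replace = TRUE)
  ifelse(kind == "missense",
         paste0(sample(.aa, n, replace = TRUE), pos, sample(.aa, n, replace = TRUE)),
         ifelse(kind == "fs", paste0(sample(.aa, n, replace = TRUE), pos, "fs"),
                paste0("X", pos, "_splice")))
}

# Ground truth for a panel: line table, per-line-per-agent true 4PL curves,
# MAF-like mutation table and wide binary mutation matrix. Consumes RNG.
.synth_truth <- function(config) {
  n <- config$n_lines
  lines <- data.frame(
    line_id = sprintf("L%03d", seq_len(n)),
    tumor_type = rep(names(config$tumor_types), times = config$tumor_types),
    stringsAsFactors = FALSE)
  genes <- names(config$mutation_freqs)
  calls <- matrix(0L, n, length(genes), dimnames = list(lines$line_id, genes))
  maf <- NULL
  for (g in genes) {
    calls[, g] <- stats::rbinom(n, 1, config$mutation_freqs[[g]])
    idx <- which(calls[, g] == 1L)
    if (!length(idx)) next
    pc <- if (g %in% names(.pc_catalog))
      sample(.pc_catalog[[g]], length(idx), replace = TRUE)
    else .random_protein_change(length(idx))
    maf <- rbind(maf, data.frame(line_id = lines$line_id[idx], gene = g,
                                 protein_change = pc, stringsAsFactors = FALSE))
  }
  if (is.null(maf))
    maf <- data.frame(line_id = character(), gene = character(),
                      protein_change = character(), stringsAsFactors = FALSE)
  # Untreated growth (top), maximal-effect floor (bottom), Hill slope and T0
  # raw level are line properties shared across agents: the 4PL family is then
  # closed under Loewe mixing, so additive combination plates are exactly 4PL
  # and pipeline deviations from CI = 1 + fA*fB measure synergy, not model
  # misfit.
  top <- stats::runif(n, 150, 400)
  t0_raw <- stats::rlnorm(n, meanlog = log(1000), sdlog = 0.2)
  bottom <- stats::runif(n, 0, 120)
  slope <- stats::runif(n, 0.9, 1.3)
  curves <- NULL
  for (k in seq_along(config$agents)) {
    shift <- if (k == 1 && length(config$effect_multipliers)) {
      planted <- intersect(names(config$effect_multipliers), genes)
      if (length(planted))
        as.numeric(calls[, planted, drop = FALSE] %*%
                     log10(config$effect_multipliers[planted]))
      else 0
    } else 0
    l10 <- stats::rnorm(n, config$baseline_gic50_log10_mean,
                        config$baseline_gic50_log10_sd) + shift
    curves <- rbind(curves, data.frame(
      line_id = lines$line_id, agent = config$agents[k],
      bottom = bottom, top = top, inflection_nM = 10^l10, slope = slope,
      t0_raw = t0_raw, stringsAsFactors = FALSE))
  }
  list(lines = lines, curves = curves, maf = maf, calls = calls)
}

.dose_grid_concs <- function(dose_grid) {
  dose_grid$top_conc_nM / dose_grid$dilution^(dose_grid$n_points - seq_len(dose_grid$n_points))
}

# Raw plate rows for a set of true curves: anchors (T0, DMSO) + treated wells,
# all as T0_raw * response/100 * multiplicative noise. `extra` appends
# constant columns (e.g. per-component concentrations).
.plate_rows <- function(curves, config, responses_at = NULL, agent_label = NULL,
                        extra = NULL) {
  concs <- .dose_grid_concs(config$dose_grid)
  np <- length(concs); nr <- config$n_replicates; nw <- config$n_anchor_wells
  n <- nrow(curves)
  cv <- config$noise_cv
  tt <- curves$tumor_type
  agent <- if (is.null(agent_label)) curves$agent else rep(agent_label, n)

  anchor <- function(role, level_pct) {
    i <- rep(seq_len(n), each = nw)
    data.frame(line_id = curves$line_id[i], tumor_type = tt[i], agent = agent[i],
               conc_nM = 0, conc_A_nM = NA_real_, conc_B_nM = NA_real_,
               replicate = rep(seq_len(nw), times = n),
               signal = curves$t0_raw[i] * level_pct[i] / 100 * .mult_noise(n * nw, cv),
               well_role = role, stringsAsFactors = FALSE)
  }
  t0_block <- anchor("T0", rep(100, n))
  dmso_block <- anchor("DMSO", curves$top)

  i <- rep(seq_len(n), each = np * nr)
  conc_v <- rep(rep(concs, each = nr), times = n)
  if (is.null(responses_at)) {
    resp <- curves$bottom[i] + (curves$top[i] - curves$bottom[i]) /
      (1 + (conc_v / curves$inflection_nM[i])^curves$slope[i])
  } else {
    # responses_at: n x np matrix of true responses at `concs`, line-major
    resp <- rep(as.numeric(t(responses_at)), each = nr)
  }
  treated <- data.frame(
    line_id = curves$line_id[i], tumor_type = tt[i], agent = agent[i],
    conc_nM = conc_v, conc_A_nM = NA_real_, conc_B_nM = NA_real_,
    replicate = rep(rep(seq_len(nr), times = np), times = n),
    signal = curves$t0_raw[i] * resp / 100 * .mult_noise(n * np * nr, cv),
    well_role = "treated", stringsAsFactors = FALSE)
  if (!is.null(extra)) for (col in names(extra)) treated[[col]] <- extra[[col]]
  rbind(t0_block, dmso_block, treated)
}

#' Generate a synthetic single-agent screen
#'
#' Draws a panel of cell lines with independent per-gene mutation calls and
#' true 4PL concentration-response curves whose inflection is multiplied by
#' the configured effect multiplier in mutant lines, then emits raw plate
#' signals (T0/DMSO anchor wells plus replicated treated wells) with
#' multiplicative lognormal noise.
#'
#' @param config A [panel_config()].
#' @return List with `plate` (long-format well table: `line_id`, `tumor_type`,
#'   `agent`, `conc_nM`, `replicate`, `signal`, `well_role`), `truth`
#'   (per-line-per-agent true curve parameters), `mutations` (MAF-like table),
#'   `mutation_calls` (line x gene binary matrix) and `config`.
#' @export
synth_single_agent_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  truth <- .synth_truth(config)
  plate <- .plate_rows(merge_tumor_type(truth$curves, truth$lines), config)
  list(plate = plate, truth = truth$curves, mutations = truth$maf,
       mutation_calls = truth$calls, config = config)
}

merge_tumor_type <- function(curves, lines) {
  curves$tumor_type <- lines$tumor_type[match(curves$line_id, lines$line_id)]
  curves
}

#' Loewe dose-equivalence mixture response
#'
#' Response of a fixed-ratio mixture of two agents at total dose `D`,
#' constructed from the single-agent curves by Loewe dose equivalence: the
#' response level `E` solves
#' \deqn{f_A D / Dx_A(E) + f_B D / Dx_B(E) = \psi}
#' where `Dx(E)` is each agent's equi-effective dose. `psi = 1` is exactly
#' Loewe-additive; `psi < 1` inflates the equivalent dose by `1/psi`
#' (synergy). Solved by bisection on the effect level (monotone one-to-one
#' with the equivalent dose) to a relative bracket width of 1e-12.
#'
#' @param curve_a,curve_b Single-agent [fourpl_curve()]s (decreasing; they
#'   should share the untreated top level).
#' @param fraction_a,fraction_b Mixture fractions, summing to 1.
#' @param total_dose Total mixture dose vector, nM.
#' @param psi Synergy parameter (> 0).
#' @return Mixture response, %T0.
#' @export
loewe_response <- function(curve_a, curve_b, fraction_a, fraction_b,
                           total_dose, psi = 1) {
  stopifnot(inherits(curve_a, "fourpl_curve"), inherits(curve_b, "fourpl_curve"))
  if (abs(fraction_a + fraction_b - 1) > 1e-12 || fraction_a <= 0 || fraction_b <= 0)
    stop("fractions must be positive and sum to 1")
  if (psi <= 0) stop("psi must be positive")
  hi0 <- min(curve_a$top, curve_b$top)
  lo0 <- min(curve_a$bottom, curve_b$bottom)
  q <- function(E, D) {
    dxa <- .invert_closed(curve_a, E)
    dxb <- .invert_closed(curve_b, E)
    ta <- if (is.na(dxa)) 0 else fraction_a * D / dxa
    tb <- if (is.na(dxb)) 0 else fraction_b * D / dxb
    ta + tb
  }
  vapply(total_dose, function(D) {
    if (D == 0) return(hi0)
    lo <- lo0 + 1e-13 * (hi0 - lo0)
    hi <- hi0 - 1e-13 * (hi0 - lo0)
    for (iter in 1:80) {
      mid <- (lo + hi) / 2
      if (q(mid, D) > psi) hi <- mid else lo <- mid
      if ((hi - lo) <= 1e-12 * max(1, abs(hi))) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Generate synthetic fixed-ratio combination plates
#'
#' For each selected line, emits raw plates for agent A alone, agent B alone,
#' and the fixed-ratio mixture, whose true response is built from the
#' ground-truth single-agent curves by Loewe dose equivalence (see
#' [loewe_response()]); with `psi = 1` the mixture is exactly Loewe-additive.
#' The panel config must name exactly two agents.
#'
#' @param config A [panel_config()] with `length(agents) == 2` (seeds the
#'   ground-truth curves).
#' @param combo A [combo_config()] (ratio, synergy parameter, plate-noise seed).
#' @param lines Optional character vector of line ids to include (default all).
#' @return List with `plate` (the three blocks; mixture rows carry `conc_nM` =
#'   total dose plus `conc_A_nM`, `conc_B_nM` per-component concentrations),
#'   `truth`, `mutations`, `mutation_calls`, `combo`, `config`.
#' @export
synth_combination_plates <- function(config, combo, lines = NULL) {
  stopifnot(inherits(config, "panel_config"), inherits(combo, "combo_config"))
  if (length(config$agents) != 2)
    stop("invalid configuration: field 'agents' (combination plates need exactly 2 agents)")
  set.seed(config$seed)
  truth <- .synth_truth(config)
  keep <- if (is.null(lines)) truth$lines$line_id else lines
  if (!all(keep %in% truth$lines$line_id)) stop("unknown line ids in 'lines'")
  curves <- truth$curves[truth$curves$line_id %in% keep, , drop = FALSE]
  curves <- merge_tumor_type(curves, truth$lines)
  ca <- curves[curves$agent == config$agents[1], , drop = FALSE]
  cb <- curves[curves$agent == config$agents[2], , drop = FALSE]
  ca <- ca[order(ca$line_id), , drop = FALSE]
  cb <- cb[order(cb$line_id), , drop = FALSE]

  set.seed(combo$seed)
  plate_a <- .plate_rows(ca, config)
  plate_b <- .plate_rows(cb, config)

  concs <- .dose_grid_concs(config$dose_grid)
  n <- nrow(ca)
  mix_resp <- matrix(NA_real_, n, length(concs))
  for (i in seq_len(n)) {
    cva <- fourpl_curve(ca$bottom[i], ca$top[i], ca$inflection_nM[i], ca$slope[i])
    cvb <- fourpl_curve(cb$bottom[i], cb$top[i], cb$inflection_nM[i], cb$slope[i])
    mix_resp[i, ] <- loewe_response(cva, cvb, combo$fraction_a, combo$fraction_b,
                                    concs, psi = combo$psi)
  }
  mix_label <- paste(config$agents, collapse = "+")
  mix_curves <- ca  # carries line ids, t0_raw, top for anchor wells
  plate_mix <- .plate_rows(mix_curves, config, responses_at = mix_resp,
                           agent_label = mix_label)
  tr <- plate_mix$well_role == "treated"
  plate_mix$conc_A_nM[tr] <- plate_mix$conc_nM[tr] * combo$fraction_a
  plate_mix$conc_B_nM[tr] <- plate_mix$conc_nM[tr] * combo$fraction_b

  list(plate = rbind(plate_a, plate_b, plate_mix),
       truth = curves, mutations = truth$maf, mutation_calls = truth$calls,
       combo = combo, config = config)
}

#' Generate a synthetic xenograft efficacy study
#'
#' Exponential tumor growth `V(t) = V0 exp(rate * t)` with multiplicative
#' lognormal measurement noise, measured every `measurement_interval_days`
#' from randomization (day 0) until the recorded volume first crosses the
#' endpoint or the final study day is reached (right-censored).
#'
#' @param config A [xeno_config()].
#' @return Long data.frame: `animal_id`, `group`, `day`, `volume_mm3`.
#' @export
synth_xenograft <- function(config) {
  stopifnot(inherits(config, "xeno_config"))
  set.seed(config$seed)
  days <- seq(0, config$max_study_day, by = config$measurement_interval_days)
  out <- NULL
  for (g in names(config$growth_rate_per_day)) {
    rate <- config$growth_rate_per_day[[g]]
    for (a in seq_len(config$n_per_group)) {
      v0 <- stats::runif(1, config$v0_mm3[1], config$v0_mm3[2])
      v <- v0 * exp(rate * days) * .mult_noise(length(days), config$noise_cv)
      cross <- which(v >= config$endpoint_volume_mm3)
      keep <- if (length(cross)) seq_len(cross[1]) else seq_along(days)
      out <- rbind(out, data.frame(
        animal_id = sprintf("%s_%02d", g, a), group = g,
        day = days[keep], volume_mm3 = v[keep], stringsAsFactors = FALSE))
    }
  }
  out
}
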