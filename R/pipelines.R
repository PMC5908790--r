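# Normalize one plate block (anchors + treated wells) for a line x agent.
.block_ncd <- function(sub) {
  t0 <- sub$signal[sub$well_role == "T0"]
  dmso <- sub$signal[sub$well_role == "DMSO"]
  tr <- sub[sub$well_role == "treated", , drop = FALSE]
  if (length(t0) < 1 || length(dmso) < 1 || nrow(tr) < 1) return(NULL)
  normalize_to_t0(tr$conc_nM, tr$signal, t0, dmso)
}

#' Fit every line x agent block of a plate table
#'
#' Normalizes each block to its T0 anchor, fits a 4PL curve and extracts
#' growth metrics with explicit censoring. Blocks without anchors are skipped
#' with a warning and counted in the `n_skipped` attribute.
#'
#' @param plate Long-format well table (`line_id`, `agent`, `conc_nM`,
#'   `replicate`, `signal`, `well_role`; optional `tumor_type`).
#' @return Data.frame with one row per line x agent: fitted parameters, fit
#'   diagnostics and metrics with censor columns.
#' @export
fit_panel <- function(plate) {
  need <- c("line_id", "agent", "conc_nM", "signal", "well_role")
  if (!all(need %in% names(plate))) stop("plate must have columns line_id, agent, conc_nM, signal, well_role")
  keys <- unique(plate[, c("line_id", "agent")])
  rows <- vector("list", nrow(keys))
  skipped <- 0L
  for (k in seq_len(nrow(keys))) {
    sub <- plate[plate$line_id == keys$line_id[k] & plate$agent == keys$agent[k], , drop = FALSE]
    ncd <- .block_ncd(sub)
    if (is.null(ncd)) { skipped <- skipped + 1L; next }
    fit <- fit_fourpl(ncd)
    gm <- growth_metrics(fit, ncd)
    info <- data.frame(line_id = keys$line_id[k], agent = keys$agent[k],
                       tumor_type = if ("tumor_type" %in% names(sub)) sub$tumor_type[1] else NA_character_,
                       bottom = fit$curve$bottom, top = fit$curve$top,
                       inflection_nM = fit$curve$inflection, slope = fit$curve$slope,
                       rss = fit$rss, converged = fit$converged,
                       degenerate = fit$degenerate, stringsAsFactors = FALSE)
    rows[[k]] <- cbind(info, .metrics_row(gm))
  }
  if (skipped > 0)
    warning(sprintf("skipped %d block(s) without usable anchor wells", skipped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Single-agent biomarker screen, end to end
#'
#' Chains the dose-response and biomarker stages: fit all plates, resolve
#' censored potencies, build the mutation matrix and screen every gene- and
#' residue-level marker.
#'
#' @param plate Long-format well table (see [fit_panel()]).
#' @param maf MAF-like mutation table (`line_id`, `gene`, `protein_change`).
#' @param agent Agent to screen (default: first agent on the plate).
#' @param min_mutants Minimum mutant lines per tested marker.
#' @return List with `metrics`, `potency`, `mutation_matrix`, `associations`.
#' @export
run_single_agent_screen <- function(plate, maf, agent = NULL, min_mutants = 1) {
  if (is.null(agent)) agent <- plate$agent[1]
  metrics <- fit_panel(plate[plate$agent == agent, , drop = FALSE])
  potency <- resolve_censored_potency(metrics)
  mm <- mutation_matrix(maf, lines = metrics$line_id)
  assoc <- screen_all_markers(mm, potency, min_mutants = min_mutants)
  list(metrics = metrics, potency = potency, mutation_matrix = mm,
       associations = assoc)
}

#' Fixed-ratio combination screen, end to end
#'
#' For every line with the three required blocks (agent A, agent B, mixture
#' labeled `"A+B"`), runs [analyze_combination()] and collects per-level
#' intermediates, the summary CI and the three-tier call.
#'
#' @param plate Long-format combination plate table (see
#'   [synth_combination_plates()] for the layout).
#' @param design A [fixed_ratio_design()].
#' @param rules A [synergy_rules()].
#' @return List with `results` (one row per line per effect level, audit
#'   columns included) and `calls` (line x call table).
#' @export
run_combination_screen <- function(plate, design, rules = synergy_rules()) {
  stopifnot(inherits(design, "fixed_ratio_design"))
  mix_label <- paste(design$agent_a, design$agent_b, sep = "+")
  lines <- unique(plate$line_id)
  res_rows <- list(); call_rows <- list()
  for (id in lines) {
    sub <- plate[plate$line_id == id, , drop = FALSE]
    da <- .block_ncd(sub[sub$agent == design$agent_a, , drop = FALSE])
    db <- .block_ncd(sub[sub$agent == design$agent_b, , drop = FALSE])
    dm <- .block_ncd(sub[sub$agent == mix_label, , drop = FALSE])
    if (is.null(da) || is.null(db) || is.null(dm)) next
    cr <- analyze_combination(da, db, dm, design, rules)
    lev <- cr$levels
    lev$line_id <- id
    lev$summary_ci <- cr$summary_ci
    lev$call <- cr$call
    res_rows[[id]] <- lev
    call_rows[[id]] <- data.frame(line_id = id, call = cr$call,
                                  summary_ci = cr$summary_ci,
                                  reason = cr$reason, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res_rows)
  calls <- do.call(rbind, call_rows)
  rownames(results) <- rownames(calls) <- NULL
  list(results = results, calls = calls)
}
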