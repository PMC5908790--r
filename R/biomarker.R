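#' Parse a protein-change string to its residue group
#'
#' Missense-style strings (reference residue, position, alternate residue or
#' stop) map to a residue key such as `"G12"`; ambiguous notations
#' (frameshift, splice, in-frame indels) return `NA` and fall back to
#' gene-level markers only.
#'
#' @param x Character vector of protein-change strings (e.g. `"G12D"`).
#' @return Character vector of residue keys (`"G12"`) or `NA`.
#' @export
parse_protein_change <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- grepl("^[A-Z][0-9]+[A-Z*]$", x)
  out[ok] <- sub("^([A-Z][0-9]+)[A-Z*]$", "\\1", x[ok])
  out
}

#' Build a mutation matrix from a MAF-like table
#'
#' Produces binary gene-level calls (any protein-changing mutation) and
#' derived residue-level columns keyed `gene_residue` (e.g. `"KRAS_G12"`) for
#' unambiguous missense changes.
#'
#' @param maf Data.frame with columns `line_id`, `gene`, `protein_change`.
#' @param lines Character vector of all panel line ids (lines without
#'   mutations get all-zero rows).
#' @return An object of class `mutation_matrix`: list with `lines`, `genes`,
#'   `calls` (line x gene 0/1 matrix), `residue_groups` (line x gene_residue
#'   0/1 matrix) and `annotations` (the input table plus a `residue` column).
#' @export
mutation_matrix <- function(maf, lines) {
  need <- c("line_id", "gene", "protein_change")
  if (!all(need %in% names(maf))) stop("maf must have columns line_id, gene, protein_change")
  lines <- unique(as.character(lines))
  maf <- maf[maf$line_id %in% lines, , drop = FALSE]
  genes <- sort(unique(as.character(maf$gene)))
  calls <- matrix(0L, length(lines), length(genes), dimnames = list(lines, genes))
  if (nrow(maf)) calls[cbind(maf$line_id, maf$gene)] <- 1L
  maf$residue <- parse_protein_change(maf$protein_change)
  res <- maf[!is.na(maf$residue), , drop = FALSE]
  if (nrow(res)) {
    key <- paste(res$gene, res$residue, sep = "_")
    ukey <- sort(unique(key))
    rg <- matrix(0L, length(lines), length(ukey), dimnames = list(lines, ukey))
    rg[cbind(res$line_id, key)] <- 1L
  } else {
    rg <- matrix(0L, length(lines), 0, dimnames = list(lines, character()))
  }
  structure(list(lines = lines, genes = genes, calls = calls,
                 residue_groups = rg, annotations = maf),
            class = "mutation_matrix")
}

#' Resolve censored potencies to a rankable log10 vector
#'
#' Censored gIC50 values (not attained within the tested range, degenerate
#' fits, or asymptote-unreachable levels) are substituted with the maximum
#' tested concentration — a conservative lower bound on the true gIC50,
#' matching the screen convention of ranking values printed as "> max".
#' Substitutions are flagged; lines with neither a value nor a bound are
#' dropped with a warning.
#'
#' @param metrics Data.frame with columns `line_id`, `gic50_nM`,
#'   `gic50_censor` and `max_tested_conc` (as produced by [fit_panel()]).
#' @return Data.frame with `line_id`, `log10_gic50`, `substituted`.
#' @export
resolve_censored_potency <- function(metrics) {
  need <- c("line_id", "gic50_nM", "gic50_censor", "max_tested_conc")
  if (!all(need %in% names(metrics))) stop("metrics must carry gIC50 value, censor state and max tested concentration")
  val <- ifelse(metrics$gic50_censor == "none", metrics$gic50_nM,
                ifelse(is.finite(metrics$gic50_nM), metrics$gic50_nM,
                       metrics$max_tested_conc))
  drop <- !is.finite(val) | val <= 0
  if (any(drop)) {
    warning(sprintf("dropping %d line(s) with neither a gIC50 value nor a censoring bound", sum(drop)))
  }
  data.frame(line_id = metrics$line_id[!drop],
             log10_gic50 = log10(val[!drop]),
             substituted = metrics$gic50_censor[!drop] != "none",
             stringsAsFactors = FALSE)
}

#' Rank-sum association of one marker with potency
#'
#' Two-sided Wilcoxon rank-sum test comparing log10 gIC50 between mutant and
#' wild-type lines: exact distribution when the combined sample size is at
#' most 20 and there are no ties, normal approximation with continuity and
#' tie correction otherwise. A constant potency vector gives p = 1.
#'
#' @param is_mutant Logical (or 0/1) marker column.
#' @param log10_gic50 Numeric potency vector, same length.
#' @param marker Marker identifier for the output row.
#' @return One-row data.frame (`marker`, `n_mut`, `n_wt`, medians on log10 and
#'   nM scales, `direction`, `p_value`), or `NULL` when either group is empty.
#' @export
wilcoxon_marker_test <- function(is_mutant, log10_gic50, marker = "marker") {
  stopifnot(length(is_mutant) == length(log10_gic50))
  is_mutant <- as.logical(is_mutant)
  keep <- !is.na(is_mutant) & is.finite(log10_gic50)
  x <- log10_gic50[keep & is_mutant]
  y <- log10_gic50[keep & !is_mutant]
  if (length(x) < 1 || length(y) < 1) return(NULL)
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y) <= 20) && !ties
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                             exact = exact, correct = TRUE)$p.value)
  }
  mx <- stats::median(x); my <- stats::median(y)
  data.frame(marker = marker, n_mut = length(x), n_wt = length(y),
             median_log10_mut = mx, median_log10_wt = my,
             median_nM_mut = 10^mx, median_nM_wt = 10^my,
             direction = if (mx > my) "resistance" else if (mx < my) "sensitivity" else "none",
             p_value = p, stringsAsFactors = FALSE)
}

#' Screen all gene- and residue-level markers against potency
#'
#' Runs [wilcoxon_marker_test()] for every gene-level and residue-level
#' marker with at least `min_mutants` mutant and one wild-type line, reports
#' the unadjusted p < 0.05 significance column alongside Benjamini-Hochberg
#' q-values, and sorts ascending by p. Markers failing the group-size
#' requirement are skipped and counted (attribute `n_skipped`).
#'
#' @param mm A [mutation_matrix()].
#' @param potency Data.frame with `line_id`, `log10_gic50` (see
#'   [resolve_censored_potency()]).
#' @param min_mutants Minimum mutant count for a marker to be tested.
#' @return Data.frame of association records with `marker_type`, `q_value`
#'   and `significant` columns; attribute `n_skipped`.
#' @export
screen_all_markers <- function(mm, potency, min_mutants = 1) {
  stopifnot(inherits(mm, "mutation_matrix"))
  common <- intersect(mm$lines, potency$line_id)
  if (length(common) < length(mm$lines) || length(common) < nrow(potency))
    warning("restricting screen to lines present in both the mutation matrix and the potency table")
  pot <- potency$log10_gic50[match(common, potency$line_id)]
  cols <- cbind(mm$calls[common, , drop = FALSE],
                mm$residue_groups[common, , drop = FALSE])
  types <- c(rep("gene", ncol(mm$calls)), rep("residue", ncol(mm$residue_groups)))
  rows <- vector("list", ncol(cols))
  skipped <- 0L
  for (j in seq_len(ncol(cols))) {
    nm <- sum(cols[, j] == 1L)
    if (nm < min_mutants || (length(common) - nm) < 1) { skipped <- skipped + 1L; next }
    rec <- wilcoxon_marker_test(cols[, j] == 1L, pot, marker = colnames(cols)[j])
    if (is.null(rec)) { skipped <- skipped + 1L; next }
    rec$marker_type <- types[j]
    rows[[j]] <- rec
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(marker = character(), n_mut = integer(), n_wt = integer(),
                      median_log10_mut = numeric(), median_log10_wt = numeric(),
                      median_nM_mut = numeric(), median_nM_wt = numeric(),
                      direction = character(), p_value = numeric(),
                      marker_type = character(), q_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- skipped
    return(out)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < 0.05
  out <- out[order(out$p_value, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Exact 2x2 enrichment test
#'
#' Builds the 2x2 table of two paired binary traits and tests association
#' with Fisher's exact test (two-sided p by summing hypergeometric
#' probabilities no larger than that of the observed table). The point
#' estimate is the sample odds ratio, with a Haldane 0.5 correction applied
#' when any cell is zero. A degenerate margin (a trait constant) gives p = 1
#' with a warning.
#'
#' @param x,y Paired binary (logical or 0/1) vectors, or `x` a 2x2 matrix
#'   (`y` ignored).
#' @return List with `table`, `odds_ratio`, `p_value`.
#' @examples
#' enrichment_2x2(matrix(c(5, 0, 0, 5), 2))  # p = 2/252
#' @export
enrichment_2x2 <- function(x, y = NULL) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2, 2)) || any(x < 0)) stop("need a 2x2 table of nonnegative counts")
    tab <- x
  } else {
    x <- as.logical(x); y <- as.logical(y)
    stopifnot(length(x) == length(y))
    keep <- !is.na(x) & !is.na(y)
    tab <- matrix(c(sum(x[keep] & y[keep]), sum(x[keep] & !y[keep]),
                    sum(!x[keep] & y[keep]), sum(!x[keep] & !y[keep])),
                  2, 2, byrow = TRUE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: one trait is constant; p = 1")
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, p_value = p)
}

#' Binary response phenotypes per cell line
#'
#' Derives the screen's binary traits: `net_death` (negative Ymin - T0),
#' `synergy` (combination call synergistic or stronger) and
#' `ras_pathway_mut` (protein-changing mutation in a RAS-family gene, BRAF or
#' NF1).
#'
#' @param metrics Data.frame with `line_id` and `ymin_minus_t0`.
#' @param calls Optional data.frame with `line_id` and `call` from the
#'   combination screen.
#' @param mm Optional [mutation_matrix()].
#' @param ras_genes Genes defining the RAS pathway trait.
#' @return Data.frame with `line_id` and the available trait columns.
#' @export
build_binary_phenotypes <- function(metrics, calls = NULL, mm = NULL,
                                    ras_genes = c("KRAS", "NRAS", "HRAS", "BRAF", "NF1")) {
  out <- data.frame(line_id = metrics$line_id,
                    net_death = metrics$ymin_minus_t0 < 0,
                    stringsAsFactors = FALSE)
  if (!is.null(calls)) {
    out$synergy <- calls$call[match(out$line_id, calls$line_id)] %in%
      c("synergistic", "strongly_synergistic")
  }
  if (!is.null(mm)) {
    g <- intersect(ras_genes, colnames(mm$calls))
    ras <- if (length(g)) rowSums(mm$calls[, g, drop = FALSE]) > 0 else rep(FALSE, length(mm$lines))
    out$ras_pathway_mut <- as.logical(ras[match(out$line_id, mm$lines)])
  }
  out
}
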