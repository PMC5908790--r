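test_that("censored potencies substitute the max tested concentration, flagged", {
  m <- data.frame(line_id = c("a", "b", "c"),
                  gic50_nM = c(550, 29300, NA),
                  gic50_censor = c("none", "gt_max", "degenerate"),
                  max_tested_conc = c(30000, 29300, 29300))
  r <- resolve_censored_potency(m)
  expect_equal(r$log10_gic50, c(log10(550), log10(29300), log10(29300)))
  expect_equal(r$substituted, c(FALSE, TRUE, TRUE))
  # neither value nor bound: dropped with a warning
  m$max_tested_conc[3] <- NA; m$gic50_nM[3] <- NA
  expect_warning(r2 <- resolve_censored_potency(m), "dropping")
  expect_equal(nrow(r2), 2)
})

test_that("rank-sum p-values match exact enumeration", {
  # worked example: mutant {3,4,5} vs WT {1,2} -> p = 0.2
  rec <- wilcoxon_marker_test(c(TRUE, TRUE, TRUE, FALSE, FALSE), c(3, 4, 5, 1, 2))
  expect_equal(rec$p_value, 0.2)
  expect_equal(rec$p_value, wilcox_exact_oracle(c(3, 4, 5), c(1, 2)))
  expect_equal(rec$direction, "resistance")
  # identical multisets: p = 1 by symmetry
  rec2 <- wilcoxon_marker_test(rep(c(TRUE, FALSE), each = 3), rep(c(1, 2, 3), 2))
  expect_equal(rec2$p_value, 1)
  # all mutant/WT partitions of distinct values, n <= 8 (acceptance goes to 10)
  for (n in 2:8) {
    vals <- seq_len(n) + 0.1 * seq_len(n)^2
    for (mask in 1:(2^n - 2)) {
      mut <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      rec <- wilcoxon_marker_test(mut, vals)
      expect_equal(rec$p_value, wilcox_exact_oracle(vals[mut], vals[!mut]),
                   tolerance = 1e-12)
    }
  }
  # constant potency vector: p = 1
  expect_equal(wilcoxon_marker_test(c(TRUE, FALSE, FALSE), rep(2, 3))$p_value, 1)
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  # perfect separation of 5 vs 5: the two extreme tables, p = 2/252
  r <- enrichment_2x2(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(r$p_value, 2 / choose(10, 5))
  expect_equal(r$p_value, fisher_exact_oracle(5, 0, 0, 5))
  # perfectly balanced table
  expect_equal(enrichment_2x2(matrix(2, 2, 2))$p_value, 1)
  # random tables up to N = 30 agree with the enumeration oracle
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    tab <- matrix(cells, 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(enrichment_2x2(tab)$p_value,
                 fisher_exact_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
  }
  # Haldane-corrected odds ratio when a cell is empty
  expect_equal(enrichment_2x2(matrix(c(5, 0, 2, 5), 2, 2, byrow = TRUE))$odds_ratio,
               (5.5 * 5.5) / (0.5 * 2.5))
  expect_warning(rd <- enrichment_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(rd$p_value, 1)
})

test_that("the exact test holds its nominal size under independence", {
  set.seed(23)
  rej <- 0L
  for (i in 1:1000) {
    x <- rbinom(24, 1, 0.4); y <- rbinom(24, 1, 0.5)
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    rej <- rej + (enrichment_2x2(matrix(tab, 2, 2))$p_value < 0.05)
  }
  expect_lte(rej / 1000, 0.05)
})

test_that("protein-change parsing builds residue groups nested in gene calls", {
  expect_equal(parse_protein_change(c("G12D", "V600E", "Q61*", "E55fs", "X123_splice", "p.?")),
               c("G12", "V600", "Q61", NA, NA, NA))
  maf <- data.frame(line_id = c("l1", "l2", "l2", "l3"),
                    gene = c("KRAS", "KRAS", "TP53", "TP53"),
                    protein_change = c("G12D", "G12V", "R175H", "E55fs"))
  mm <- mutation_matrix(maf, lines = c("l1", "l2", "l3", "l4"))
  expect_equal(sort(colnames(mm$residue_groups)), c("KRAS_G12", "TP53_R175"))
  expect_equal(unname(mm$residue_groups[, "KRAS_G12"]), c(1L, 1L, 0L, 0L))
  # ambiguous change contributes to the gene call only
  expect_equal(unname(mm$calls["l3", "TP53"]), 1L)
  # residue implies gene
  expect_true(all(mm$calls[mm$residue_groups[, "KRAS_G12"] == 1, "KRAS"] == 1))
})

test_that("the marker screen ranks a planted resistance gene first and is order-invariant", {
  f <- default_mutation_freqs(); f["KRAS"] <- 0.25
  cfg <- panel_config(n_lines = 80, mutation_freqs = f,
                      effect_multipliers = c(KRAS = 4), noise_cv = 0.02, seed = 5)
  p <- synth_single_agent_panel(cfg)
  scr <- run_single_agent_screen(p$plate, p$mutations)
  genes <- scr$associations[scr$associations$marker_type == "gene", ]
  expect_equal(genes$marker[1], "KRAS")
  expect_equal(genes$direction[1], "resistance")
  expect_true(all(diff(scr$associations$p_value) >= 0))
  expect_true(all(c("q_value", "significant") %in% names(scr$associations)))
  # shuffling line and marker order changes nothing
  perm <- sample(nrow(p$mutations))
  mm2 <- mutation_matrix(p$mutations[perm, ], lines = rev(scr$metrics$line_id))
  assoc2 <- screen_all_markers(mm2, scr$potency[sample(nrow(scr$potency)), ])
  expect_equal(assoc2$marker, scr$associations$marker)
  expect_equal(assoc2$p_value, scr$associations$p_value, tolerance = 1e-12)
})

test_that("a panel with no mutations yields an empty association table", {
  maf <- data.frame(line_id = character(), gene = character(),
                    protein_change = character())
  mm <- mutation_matrix(maf, lines = c("a", "b", "c"))
  pot <- data.frame(line_id = c("a", "b", "c"), log10_gic50 = c(1, 2, 3))
  out <- screen_all_markers(mm, pot)
  expect_equal(nrow(out), 0)
})

test_that("identically-censored potencies make every marker uninformative", {
  maf <- data.frame(line_id = c("a", "c"), gene = "KRAS",
                    protein_change = c("G12D", "G12V"))
  mm <- mutation_matrix(maf, lines = letters[1:6])
  pot <- data.frame(line_id = letters[1:6], log10_gic50 = rep(log10(29300), 6))
  out <- screen_all_markers(mm, pot)
  expect_true(all(out$p_value == 1))
})

test_that("null-screen p-values are stochastically no smaller than uniform", {
  freqs <- stats::setNames(rep(0.15, 200), sprintf("G%03d", 1:200))
  cfg <- panel_config(n_lines = 120, mutation_freqs = freqs,
                      effect_multipliers = stats::setNames(numeric(0), character(0)),
                      noise_cv = 0.02, seed = 77)
  p <- synth_single_agent_panel(cfg)
  scr <- run_single_agent_screen(p$plate, p$mutations)
  pv <- scr$associations$p_value[scr$associations$marker_type == "gene"]
  expect_gte(length(pv), 190)
  # one-sided KS: reject only if the ECDF sits significantly ABOVE uniform
  ks <- suppressWarnings(stats::ks.test(pv, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("binary phenotypes follow the sign, call and pathway rules", {
  metrics <- data.frame(line_id = c("a", "b"), ymin_minus_t0 = c(-12, 30))
  calls <- data.frame(line_id = c("a", "b"),
                      call = c("additive", "strongly_synergistic"))
  maf <- data.frame(line_id = "b", gene = "NF1", protein_change = "D2184G")
  mm <- mutation_matrix(maf, lines = c("a", "b"))
  ph <- build_binary_phenotypes(metrics, calls, mm)
  expect_equal(ph$net_death, c(TRUE, FALSE))
  expect_equal(ph$synergy, c(FALSE, TRUE))
  expect_equal(ph$ras_pathway_mut, c(FALSE, TRUE))  # NF1 alone counts
})
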