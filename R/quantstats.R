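#' Viability as the percentage of live cells
#'
#' @param live,dead non-negative counts; their sum must be positive.
#' @return `100 * live / (live + dead)`.
#' @export
viability_percent <- function(live, dead) {
  check_scalar(live, "live", nonneg = TRUE)
  check_scalar(dead, "dead", nonneg = TRUE)
  if (live + dead == 0) stopf("viability_percent: live + dead must be > 0")
  100 * live / (live + dead)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_gene - Ct_reference`; per gene,
#' `ddCt = mean dCt(exposed) - mean dCt(vehicle)` and the fold change is
#' `2^-ddCt`. Replicate spread is reported as per-replicate folds
#' `2^-(dCt_i - mean dCt vehicle)`, the scheme the summary SEM is computed
#' from.
#'
#' @param table long-format Ct table with columns `sample_id`, `group`
#'   (`vehicle`/`exposed`), `gene`, `ct` (see [generate_ct_table()]).
#' @param reference_gene housekeeping gene; defaults to the table's
#'   `reference_gene` attribute.
#' @return A list with `genes` (per-gene `ddct`, `fold_change`, `fold_sem`,
#'   group sizes) and `replicates` (per-sample folds).
#' @export
ddct_fold_changes <- function(table, reference_gene = attr(table, "reference_gene")) {
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(table)))
  if (is.null(reference_gene)) stopf("a reference gene must be given")
  if (any(!table$group %in% c("vehicle", "exposed")))
    stopf("groups must be 'vehicle' or 'exposed'")
  if (any(table$ct <= 0)) stopf("Ct values must be positive")
  ref <- table[table$gene == reference_gene, ]
  samples <- unique(table$sample_id)
  if (!all(samples %in% ref$sample_id))
    stopf("missing reference-gene Ct for sample(s): %s",
          paste(setdiff(samples, ref$sample_id), collapse = ", "))
  ref_ct <- ref$ct[match(table$sample_id, ref$sample_id)]
  table$dct <- table$ct - ref_ct

  genes <- setdiff(unique(table$gene), reference_gene)
  per_gene <- list(); per_rep <- list()
  for (g in genes) {
    tg <- table[table$gene == g, ]
    dv <- tg$dct[tg$group == "vehicle"]
    de <- tg$dct[tg$group == "exposed"]
    if (!length(dv) || !length(de))
      stopf("gene '%s' is absent from one group", g)
    ddct <- mean(de) - mean(dv)
    rep_fold <- 2^-(tg$dct - mean(dv))
    ef <- rep_fold[tg$group == "exposed"]
    per_gene[[g]] <- data.frame(
      gene = g, n_vehicle = length(dv), n_exposed = length(de),
      ddct = ddct, fold_change = 2^-ddct,
      fold_sem = if (length(ef) > 1) sd(ef) / sqrt(length(ef)) else NA_real_)
    per_rep[[g]] <- data.frame(gene = g, sample_id = tg$sample_id,
                               group = tg$group, fold = rep_fold)
  }
  list(genes = do.call(rbind, c(per_gene, list(make.row.names = FALSE))),
       replicates = do.call(rbind, c(per_rep, list(make.row.names = FALSE))))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' In-house FDR step-up: sort ascending, take `adj_(i) = min_{j >= i}
#' (m * p_(j) / j)` clipped at 1, and return in input order. Guarantees
#' `adj >= p` and preserves the step-up ordering.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) stopf("bh_adjust: empty p-value list")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("bh_adjust: p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  adj_sorted <- pmin(1, rev(cummin(rev(m / seq_len(m) * pvalues[o]))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Differential-expression filter
#'
#' Retains genes satisfying all three printed rules, with strict
#' inequalities throughout:
#' (1) CPM strictly above `cpm_min` in at least `min_samples` samples,
#' (2) BH-adjusted p-value strictly below `alpha`,
#' (3) `log2fc < -lfc_cut` or `log2fc > lfc_cut`.
#' The BH correction is applied to the p-values of genes passing the
#' expression filter (standard edgeR practice); `bh_scope = "all"` corrects
#' over every gene instead.
#'
#' @param table data frame with `gene_id`, CPM columns (`cpm_*`), `log2fc`,
#'   `pvalue` (see [generate_gene_stats()]).
#' @param cpm_min,min_samples expression-filter rule.
#' @param alpha FDR cutoff on the adjusted p-value.
#' @param lfc_cut log2-fold-change cutoff magnitude.
#' @param bh_scope `"filtered"` (default) or `"all"`.
#' @return A list with `table` (input plus `pass_expression`, `adj_pvalue`,
#'   `retained`, `direction`), `retained`, `up`, `down` (gene-id vectors).
#' @export
deg_filter <- function(table, cpm_min = 1, min_samples = 2, alpha = 0.05,
                       lfc_cut = 0.5, bh_scope = c("filtered", "all")) {
  bh_scope <- match.arg(bh_scope)
  cpm_cols <- grep("^cpm_", names(table), value = TRUE)
  if (!length(cpm_cols)) stopf("deg_filter: no cpm_* columns found")
  cpm <- as.matrix(table[, cpm_cols])
  pass_expr <- rowSums(cpm > cpm_min) >= min_samples
  adj <- rep(NA_real_, nrow(table))
  if (bh_scope == "filtered") {
    if (any(pass_expr)) adj[pass_expr] <- bh_adjust(table$pvalue[pass_expr])
  } else {
    adj <- bh_adjust(table$pvalue)
  }
  retained <- pass_expr & !is.na(adj) & adj < alpha &
    (table$log2fc < -lfc_cut | table$log2fc > lfc_cut)
  direction <- ifelse(!retained, NA_character_,
                      ifelse(table$log2fc > lfc_cut, "up", "down"))
  table$pass_expression <- pass_expr
  table$adj_pvalue <- adj
  table$retained <- retained
  table$direction <- direction
  list(table = table,
       retained = table$gene_id[retained],
       up = table$gene_id[retained & direction == "up"],
       down = table$gene_id[retained & direction == "down"])
}

#' Normalize a cytokine concentration to cell counts
#'
#' Converts a supernatant concentration into secreted mass per million
#' cells: `conc * volume / cell_count * 1e6`, in pg per 10^6 cells.
#'
#' @param conc_pg_ml concentration in pg/mL.
#' @param volume_ml supernatant volume in mL.
#' @param cell_count number of cells (positive).
#' @return pg per 10^6 cells (vectorized).
#' @export
normalize_cytokine <- function(conc_pg_ml, volume_ml, cell_count) {
  if (any(conc_pg_ml < 0)) stopf("concentrations must be non-negative")
  if (any(volume_ml <= 0)) stopf("volume must be positive")
  if (any(cell_count <= 0)) stopf("cell count must be positive")
  conc_pg_ml * volume_ml / cell_count * 1e6
}

#' Convert a micromolar concentration to ug/L (ppb)
#'
#' `1 umol/L x M g/mol = M ug/L`, so the conversion is the plain product.
#' The default molar mass is elemental arsenic (74.92 g/mol), under which
#' 1 uM arsenite corresponds to ~75 ug/L (ppb); the formula mass of
#' NaAsO2 (129.91 g/mol) can be supplied instead.
#'
#' @param concentration_uM concentration in umol/L (positive).
#' @param molar_mass_g_mol molar mass in g/mol (positive).
#' @return Concentration in ug/L.
#' @export
molar_to_mass_conc <- function(concentration_uM, molar_mass_g_mol = 74.92) {
  if (any(concentration_uM <= 0) || any(molar_mass_g_mol <= 0))
    stopf("molar_to_mass_conc: inputs must be positive")
  concentration_uM * molar_mass_g_mol
}

#' Two-group and multi-group comparisons
#'
#' Thin wrapper over the standard routines: two-tailed unpaired Student's
#' t-test (pooled variance), Welch's t-test, or one-way ANOVA with Tukey
#' post-hoc comparisons against the first (control) group.
#'
#' @param a numeric vector (first group), or for `method = "anova_tukey"` a
#'   named list of three or more numeric vectors whose first element is the
#'   control group.
#' @param b numeric vector (second group); ignored for the ANOVA path.
#' @param method `"t_unpaired"`, `"welch_t"` or `"anova_tukey"`.
#' @return A list of class `group_comparison` with `statistic`, `pvalue`,
#'   `method`, `group_sizes`, and for the ANOVA path a `tukey` data frame of
#'   comparisons versus the control group.
#' @export
compare_groups <- function(a, b = NULL,
                           method = c("t_unpaired", "welch_t", "anova_tukey")) {
  method <- match.arg(method)
  if (method %in% c("t_unpaired", "welch_t")) {
    if (length(a) < 2L || length(b) < 2L)
      stopf("compare_groups: each group needs >= 2 values")
    ht <- t.test(a, b, var.equal = method == "t_unpaired")
    out <- list(statistic = unname(ht$statistic), pvalue = ht$p.value,
                method = method, group_sizes = c(length(a), length(b)),
                tukey = NULL)
  } else {
    if (!is.list(a) || length(a) < 3L)
      stopf("compare_groups: the ANOVA path needs a list of >= 3 groups")
    if (is.null(names(a)) || any(names(a) == ""))
      names(a) <- paste0("group", seq_along(a))
    df <- data.frame(value = unlist(a, use.names = FALSE),
                     group = factor(rep(names(a), lengths(a)),
                                    levels = names(a)))
    fit <- aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    ctrl <- names(a)[1]
    vs_ctrl <- tk[grepl(paste0("-", ctrl, "$"), rownames(tk)) |
                  grepl(paste0("^", ctrl, "-"), rownames(tk)), , drop = FALSE]
    out <- list(statistic = an[["F value"]][1], pvalue = an[["Pr(>F)"]][1],
                method = method, group_sizes = lengths(a),
                tukey = data.frame(comparison = rownames(vs_ctrl),
                                   diff = vs_ctrl[, "diff"],
                                   p_adj = vs_ctrl[, "p adj"],
                                   row.names = NULL))
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison [%s]: statistic %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$pvalue,
              paste(x$group_sizes, collapse = ", ")))
  if (!is.null(x$tukey)) {
    cat("  Tukey vs control:\n")
    print(x$tukey)
  }
  invisible(x)
}
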