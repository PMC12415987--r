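#' Generate a synthetic qPCR Ct table with planted fold changes
#'
#' Builds a long-format Ct table for a vehicle/exposed comparison. Each gene
#' is assigned a vehicle baseline Ct (reference gene at 18 cycles, targets
#' uniform in 22-28); exposed Ct values are shifted by `-log2(fold_change)`
#' before noise, so the 2^-ddCt estimator recovers the planted fold exactly
#' at zero noise. The reference gene is never shifted.
#'
#' @param genes character vector of gene names.
#' @param fold_changes positive planted fold changes, one per gene; the
#'   reference gene (appended automatically if absent) must have fold 1.
#' @param n_replicates biological replicates per arm.
#' @param ct_noise_sd SD (cycles) of Gaussian measurement noise per Ct.
#' @param seed RNG seed.
#' @param reference_gene housekeeping gene used for normalization.
#' @return A data frame with columns `sample_id`, `group`
#'   (`vehicle`/`exposed`), `gene`, `ct`, carrying the reference gene name in
#'   `attr(, "reference_gene")`.
#' @seealso [ddct_fold_changes()]
#' @export
generate_ct_table <- function(genes, fold_changes, n_replicates,
                              ct_noise_sd = 0, seed = 1L,
                              reference_gene = "GAPDH") {
  stopifnot(is.character(genes), length(genes) >= 1L)
  if (length(fold_changes) != length(genes))
    stopf("one fold change per gene is required")
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
    stopf("fold changes must be positive")
  check_scalar(n_replicates, "n_replicates", positive = TRUE, integer = TRUE)
  check_scalar(ct_noise_sd, "ct_noise_sd", nonneg = TRUE)
  if (!reference_gene %in% genes) {
    genes <- c(genes, reference_gene)
    fold_changes <- c(fold_changes, 1)
  } else if (fold_changes[match(reference_gene, genes)] != 1) {
    stopf("the reference gene must have fold change 1")
  }

  with_seed(seed, {
    baseline <- ifelse(genes == reference_gene, 18, runif(length(genes), 22, 28))
    rows <- expand.grid(rep = seq_len(n_replicates),
                        gene = genes,
                        group = c("vehicle", "exposed"),
                        stringsAsFactors = FALSE)
    gi <- match(rows$gene, genes)
    shift <- ifelse(rows$group == "exposed", -log2(fold_changes[gi]), 0)
    ct <- baseline[gi] + shift +
      if (ct_noise_sd > 0) rnorm(nrow(rows), 0, ct_noise_sd) else 0
    out <- data.frame(sample_id = paste0(rows$group, "_", rows$rep),
                      group = rows$group, gene = rows$gene, ct = ct,
                      stringsAsFactors = FALSE)
    attr(out, "reference_gene") <- reference_gene
    out
  })
}

#' Generate a synthetic per-gene statistics table with planted DEGs
#'
#' Fixture for the differential-expression filter: `n_deg` planted genes get
#' `|log2FC| = |planted_lfc|` (random sign) and p-value `planted_p`; null
#' genes get log2FC near zero and uniform p-values; a fraction of null genes
#' receive CPM < 1 in every sample to exercise the expression filter.
#'
#' @param n_genes total genes.
#' @param n_deg number of planted differentially expressed genes.
#' @param planted_lfc planted log2 fold change magnitude (|value| > 0.5 for
#'   the planted genes to be recoverable by the default filter).
#' @param seed RNG seed.
#' @param n_samples number of CPM columns.
#' @param low_expr_fraction fraction of null genes rendered below the CPM
#'   filter in all samples.
#' @param planted_p p-value assigned to planted genes.
#' @return A data frame with `gene_id`, `cpm_1..cpm_n`, `log2fc`, `pvalue`,
#'   `is_deg_true`.
#' @seealso [deg_filter()]
#' @export
generate_gene_stats <- function(n_genes, n_deg, planted_lfc, seed = 1L,
                                n_samples = 4L, low_expr_fraction = 0.1,
                                planted_p = 1e-6) {
  check_scalar(n_genes, "n_genes", positive = TRUE, integer = TRUE)
  check_scalar(n_deg, "n_deg", nonneg = TRUE, integer = TRUE)
  if (n_deg > n_genes) stopf("'n_deg' must not exceed 'n_genes'")
  check_scalar(planted_lfc, "planted_lfc")
  check_fraction(low_expr_fraction, "low_expr_fraction")

  with_seed(seed, {
    is_deg <- rep(FALSE, n_genes)
    if (n_deg > 0) is_deg[sample.int(n_genes, n_deg)] <- TRUE
    nulls <- which(!is_deg)
    n_low <- min(round(low_expr_fraction * n_genes), length(nulls))
    low <- if (n_low > 0) sample(nulls, n_low) else integer(0)

    cpm <- matrix(rlnorm(n_genes * n_samples, log(50), 1), n_genes, n_samples)
    if (length(low))
      cpm[low, ] <- matrix(runif(length(low) * n_samples, 0, 0.9),
                           length(low), n_samples)
    lfc <- rnorm(n_genes, 0, 0.15)
    lfc[is_deg] <- sample(c(-1, 1), n_deg, replace = TRUE) * abs(planted_lfc)
    p <- runif(n_genes)
    p[is_deg] <- planted_p

    out <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
    for (s in seq_len(n_samples)) out[[paste0("cpm_", s)]] <- cpm[, s]
    out$log2fc <- lfc
    out$pvalue <- p
    out$is_deg_true <- is_deg
    out
  })
}
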