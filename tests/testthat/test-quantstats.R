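test_that("viability is the live percentage of the total", {
  expect_equal(viability_percent(50, 50), 50)
  expect_equal(viability_percent(0, 10), 0)
  expect_equal(viability_percent(75, 25), 75)
  expect_error(viability_percent(0, 0), "> 0")
})

test_that("2^-ddCt reproduces hand arithmetic, the null case, and planted folds", {
  tab <- data.frame(
    sample_id = c("v1", "v1", "e1", "e1"),
    group = c("vehicle", "vehicle", "exposed", "exposed"),
    gene = c("IL6", "GAPDH", "IL6", "GAPDH"),
    ct = c(26, 20, 25, 20))
  res <- ddct_fold_changes(tab, reference_gene = "GAPDH")
  expect_equal(res$genes$ddct, -1)
  expect_equal(res$genes$fold_change, 2)
  # identical groups give fold 1
  null_tab <- generate_ct_table(c("IL6", "IL8"), c(1, 1), 3, 0, seed = 2)
  nres <- ddct_fold_changes(null_tab)
  expect_equal(nres$genes$fold_change, c(1, 1))
  # planted folds recovered exactly at zero noise
  planted <- generate_ct_table(c("a", "b", "c"), c(0.5, 2, 8), 4, 0, seed = 3)
  pres <- ddct_fold_changes(planted)
  expect_equal(sort(pres$genes$fold_change), c(0.5, 2, 8))
  # a sample without a reference Ct is an error
  broken <- tab[tab$gene != "GAPDH" | tab$sample_id != "e1", ]
  expect_error(ddct_fold_changes(broken, reference_gene = "GAPDH"),
               "missing reference")
})

test_that("the in-house BH step-up matches hand cases, the brute-force oracle and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(15)
  for (i in 1:200) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("the DEG filter applies the three printed rules with strict inequalities", {
  tab <- data.frame(gene_id = c("lowexp", "edge", "good", "null"),
                    cpm_1 = c(0.5, 50, 50, 50), cpm_2 = c(0.5, 50, 50, 50),
                    cpm_3 = c(0.5, 50, 50, 50), cpm_4 = c(0.5, 50, 50, 50),
                    log2fc = c(3, 0.5, 1.2, 0.1),
                    pvalue = c(1e-9, 1e-6, 1e-6, 0.9))
  res <- deg_filter(tab)
  # CPM 0.5 everywhere is excluded regardless of p and fold change
  expect_false("lowexp" %in% res$retained)
  # log2fc exactly at the cutoff is excluded
  expect_false("edge" %in% res$retained)
  expect_equal(res$retained, "good")
  expect_equal(res$up, "good")
  # CPM exactly 1 does not pass the strict rule
  tie <- tab["good", ]; tie[, paste0("cpm_", 1:4)] <- 1
  expect_equal(length(deg_filter(tie)$retained), 0)
})

test_that("cytokine normalization follows the pg-per-million-cells arithmetic", {
  expect_equal(normalize_cytokine(100, 1, 1e6), 100)
  expect_equal(normalize_cytokine(100, 1, 2e6), 50)
  expect_equal(normalize_cytokine(483.6, 2, 5e5), 1934.4)
  expect_error(normalize_cytokine(10, 1, 0), "positive")
})

test_that("micromolar-to-ppb conversion is the molar-mass product and linear", {
  expect_equal(molar_to_mass_conc(0.5, 100), 50)
  expect_equal(molar_to_mass_conc(1, 1), 1)
  expect_equal(molar_to_mass_conc(3, 74.92), 3 * molar_to_mass_conc(1, 74.92))
  expect_error(molar_to_mass_conc(-1), "positive")
})

test_that("group comparisons match textbook formulas and are symmetric", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 100)
  pooled <- compare_groups(a, b, "t_unpaired")
  welch <- compare_groups(a, b, "welch_t")
  op <- oracle_t_pooled(a, b); ow <- oracle_t_welch(a, b)
  expect_equal(pooled$pvalue, op$pvalue, tolerance = 1e-7)
  expect_equal(pooled$statistic, op$statistic, tolerance = 1e-7)
  expect_equal(welch$pvalue, ow$pvalue, tolerance = 1e-7)
  expect_false(isTRUE(all.equal(pooled$pvalue, welch$pvalue)))
  # identical groups: statistic 0, p = 1
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), "t_unpaired")
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)
  # two-sided p is invariant to swapping the groups
  expect_equal(compare_groups(b, a, "welch_t")$pvalue, welch$pvalue)
  expect_error(compare_groups(1, c(1, 2), "t_unpaired"), ">= 2")
})

test_that("the ANOVA path reports the F test and Tukey comparisons against the control", {
  set.seed(33)
  groups <- list(control = rnorm(8, 10), low = rnorm(8, 10.2),
                 high = rnorm(8, 14))
  res <- compare_groups(groups, method = "anova_tukey")
  fit <- aov(value ~ group,
             data = data.frame(value = unlist(groups),
                               group = factor(rep(names(groups), lengths(groups)),
                                              levels = names(groups))))
  expect_equal(res$pvalue, summary(fit)[[1]][["Pr(>F)"]][1])
  expect_equal(nrow(res$tukey), 2)
  expect_true(all(grepl("control", res$tukey$comparison)))
  expect_error(compare_groups(list(a = 1:3, b = 1:3), method = "anova_tukey"),
               ">= 3")
})
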