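test_that("spearman_with_fdr matches hand rank computations", {
  df <- rbind(
    data.frame(group = "a", metric = "m", score = 1:5, value = (1:5)^3),
    data.frame(group = "b", metric = "m", score = c(1, 2, 3),
               value = c(2, 1, 3)),
    data.frame(group = "c", metric = "m", score = 1:4, value = rep(7, 4)))
  res <- spearman_with_fdr(df)
  expect_equal(res$r_s[res$group == "a"], 1)            # monotone
  expect_equal(res$r_s[res$group == "b"], 0.5)          # hand ranks
  expect_true(is.na(res$r_s[res$group == "c"]))         # degenerate
  expect_match(res$note[res$group == "c"], "degenerate")
  # FDR family excludes the degenerate row
  ok <- !is.na(res$p)
  expect_equal(res$q[ok], p.adjust(res$p[ok], "BH"))
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-12))
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  base <- spearman_with_fdr(data.frame(group = "g", metric = "m",
                                       score = x, value = y))$r_s
  tr <- spearman_with_fdr(data.frame(group = "g", metric = "m",
                                     score = exp(x), value = y^3 + y))$r_s
  expect_equal(base, tr, tolerance = 1e-12)
})

test_that("rank_test picks the right engine and separates shifted groups", {
  rt <- rank_test(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_identical(rt$test, "wilcoxon_rank_sum")
  expect_lt(rt$p, 0.05)

  set.seed(3)
  g3 <- rep(c("a", "b", "c"), each = 15)
  x3 <- rnorm(45) + ifelse(g3 == "c", 3, 0)
  kt <- rank_test(x3, g3)
  expect_identical(kt$test, "kruskal_wallis")
  expect_lt(kt$p, 0.01)

  expect_error(rank_test(1:4, rep("a", 4)), ">= 2 groups")
  expect_error(rank_test(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("categorical_enrichment reproduces the hand 2x2 chi-square", {
  # table [[20,5],[5,20]]: chi-square statistic 18.0 without correction
  strata <- setNames(rep(c("low", "high"), c(25, 25)), paste0("s", 1:50))
  fac <- setNames(rep(c("neg", "pos", "neg", "pos"), c(20, 5, 5, 20)),
                  paste0("s", 1:50))
  res <- categorical_enrichment(strata, fac)
  expect_identical(res$test, "chi_square")
  expect_equal(res$statistic, 18.0, tolerance = 1e-12)
  expect_lt(res$p, 0.001)
  # row sums of the table equal factor level sizes
  expect_equal(unname(rowSums(res$table)), c(25, 25))

  # small 2x2 takes the Fisher path
  strata2 <- setNames(rep(c("low", "high"), each = 3), paste0("t", 1:6))
  fac2 <- setNames(c("a", "a", "b", "a", "b", "b"), paste0("t", 1:6))
  res2 <- categorical_enrichment(strata2, fac2)
  expect_identical(res2$test, "fisher_exact")

  expect_error(categorical_enrichment(strata, setNames("a", "zz")),
               "no shared sample ids")
})

test_that("coexpression_network thresholds and matches brute force", {
  # planted pairwise correlations via exact construction
  set.seed(5)
  n <- 40
  z <- rnorm(n)
  v <- rbind(g1 = z,
             g2 = 0.6 * z + sqrt(1 - 0.36) * rnorm(n),
             g3 = rnorm(n))
  colnames(v) <- paste0("s", 1:n)
  m <- expression_matrix(v, scale = "log2")
  net <- coexpression_network(m, threshold = 0.4)
  expect_true(all(net$edges$r >= 0.4))
  # brute-force all-pairs oracle
  for (i in 1:2) for (j in (i + 1):3) {
    r <- cor(v[i, ], v[j, ])
    in_net <- any((net$edges$gene1 == rownames(v)[i] &
                   net$edges$gene2 == rownames(v)[j]) |
                  (net$edges$gene1 == rownames(v)[j] &
                   net$edges$gene2 == rownames(v)[i]))
    expect_identical(in_net, r >= 0.4)
    if (in_net) {
      er <- net$edges$r[net$edges$gene1 %in% rownames(v)[c(i, j)] &
                        net$edges$gene2 %in% rownames(v)[c(i, j)]]
      expect_equal(er, r, tolerance = 1e-12)
    }
  }

  # duplicated gene gives an r = 1 edge
  v2 <- rbind(v, g1copy = v["g1", ])
  net2 <- coexpression_network(expression_matrix(v2, scale = "log2"))
  dup <- net2$edges[net2$edges$gene1 %in% c("g1", "g1copy") &
                    net2$edges$gene2 %in% c("g1", "g1copy"), ]
  expect_equal(dup$r, 1, tolerance = 1e-12)

  # raising the threshold never adds edges; constant genes are excluded
  netHi <- coexpression_network(m, threshold = 0.7)
  expect_lte(nrow(netHi$edges), nrow(net$edges))
  v3 <- rbind(v, gc = rep(3, n))
  net3 <- coexpression_network(expression_matrix(v3, scale = "log2"))
  expect_identical(net3$excluded, "gc")
})

test_that("coexpression degrees match a 10-gene brute-force computation", {
  m <- toy_matrix(n_genes = 10, n_samples = 25, seed = 19)
  net <- coexpression_network(m, threshold = 0.15)
  cm <- cor(t(m$values))
  deg <- sapply(rownames(cm), function(g)
    sum(cm[g, setdiff(rownames(cm), g)] >= 0.15))
  expect_equal(unname(net$degrees[names(deg)]), unname(deg))
  expect_equal(nrow(net$edges), sum(cm[upper.tri(cm)] >= 0.15))
})

test_that("qn_scale kernel equals brute-force pairwise enumeration", {
  # documented worked example
  q <- qn_scale(c(1, 2, 3, 4, 100))
  expect_equal(q$kernel, 1)
  expect_equal(q$estimate, 2.2219 * 0.844 * 1, tolerance = 1e-12)

  set.seed(101)
  for (n in c(2, 3, 5, 17, 50, 200)) {
    x <- rnorm(n) * runif(1, 0.5, 5)
    expect_equal(qn_scale(x)$kernel, oracle_qn_kernel(x),
                 tolerance = 1e-12, info = paste("n =", n))
  }
  # large-n selection path agrees with enumeration too
  x <- rnorm(600)
  expect_equal(qn_scale(x)$kernel, oracle_qn_kernel(x), tolerance = 1e-12)

  expect_equal(qn_scale(rep(4, 9))$estimate, 0)
  expect_error(qn_scale(3), "n >= 2")
})

test_that("qn_scale is location-invariant and scale-equivariant", {
  set.seed(7)
  x <- rnorm(60)
  base <- qn_scale(x)$estimate
  expect_equal(qn_scale(x + 123.4)$estimate, base, tolerance = 1e-12)
  expect_equal(qn_scale(-2.5 * x)$estimate, 2.5 * base, tolerance = 1e-12)
})

test_that("drug sensitivity analysis recovers the planted CES-IC50 link", {
  cfg <- sim_config(seed = 5, ic50_slope = 0.5)
  cl <- simulate_celllines(cfg)
  ces <- compute_ces(cl$expression, load_gene_panel("ces14"))
  dsa <- drug_sensitivity_analysis(ces, cl$drugs)
  expect_lt(dsa$quartile_test$p, 0.001)
  pooled <- dsa$spearman[dsa$spearman$group == "pooled", ]
  expect_lt(pooled$r_s, 0)
  expect_lt(pooled$p, 0.001)
  # sensitive = lower IC50 in the top CES quartile
  expect_lt(dsa$quartile_test$median_top, dsa$quartile_test$median_bottom)
})

test_that("Qn exclusion flags injected extreme IC50s", {
  # deterministic part: the injected 100x-median outliers are always flagged
  false_flags <- 0L
  for (seed in 1:10) {
    cl <- simulate_celllines(sim_config(seed = seed))
    ces <- compute_ces(cl$expression, load_gene_panel("ces14"))
    dsa <- drug_sensitivity_analysis(ces, cl$drugs)
    expect_true(all(cl$truth$outlier_ids %in% dsa$excluded))
    false_flags <- false_flags +
      length(setdiff(dsa$excluded, cl$truth$outlier_ids))
  }
  # bulk false flags are rare (expected ~0.4 per replicate of 297 lines)
  expect_lt(false_flags, 10)
  # at the generator's default seed the flags are exactly the injected ids
  cl1 <- simulate_celllines(sim_config(seed = 1))
  ces1 <- compute_ces(cl1$expression, load_gene_panel("ces14"))
  expect_setequal(drug_sensitivity_analysis(ces1, cl1$drugs)$excluded,
                  cl1$truth$outlier_ids)
})

test_that("null drug coupling yields non-significant quartile contrasts", {
  nonsig <- 0L
  reps <- 60
  for (seed in seq_len(reps)) {
    cl <- simulate_celllines(sim_config(seed = 1000 + seed, ic50_slope = 0,
                                        n_cell_lines = 120))
    ces <- compute_ces(cl$expression, load_gene_panel("ces14"))
    dsa <- drug_sensitivity_analysis(ces, cl$drugs)
    if (dsa$quartile_test$p > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig / reps, 0.85)
})
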