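test_that("growth rates reproduce the printed columns after rounding", {
  expect_equal(round(unlist(growth_rates(47.5, 305.0, 1157.0)), 2),
               c(gr2wk = 6.42, gr4wk = 24.36))
  expect_equal(round(growth_rates(49.3, 291.7, 1287.5)$gr4wk, 2), 26.12)
  expect_equal(unlist(growth_rates(10, 10, 10)), c(gr2wk = 1, gr4wk = 1))
  expect_error(growth_rates(0, 1, 2), "bw1")

  panel <- chick_myogenesis()
  ph <- panel$phenotypes
  printed_gr2 <- c(BR = 6.42, WC = 5.92, PRW = 5.91, YC = 2.60,
                   BB = 2.81, OMF = 2.62, LR = 1.88, UG = 2.24)
  printed_gr4 <- c(BR = 24.36, WC = 26.12, PRW = 23.57, YC = 6.15,
                   BB = 6.33, OMF = 4.73, LR = 5.25, UG = 5.42)
  gr <- growth_rates(ph$bw1, ph$bw14, ph$bw28)
  expect_equal(round(gr$gr2wk, 2), unname(printed_gr2[ph$breed]))
  expect_equal(round(gr$gr4wk, 2), unname(printed_gr4[ph$breed]))
})

test_that("NO oxidation rate is the nitrate share of all NO metabolites", {
  expect_equal(no_oxidation_rate(50, 0), 0)
  expect_equal(no_oxidation_rate(100, 100), 50)
  expect_equal(no_oxidation_rate(36.0, 100.0), 100 * 100 / 136, tolerance = 1e-12)
  expect_error(no_oxidation_rate(0, 0), "undefined")
  expect_error(no_oxidation_rate(-1, 5), ">= 0")
})

test_that("the normality gate flags the skewed breed traits", {
  panel <- chick_myogenesis()
  gate <- normality_gate(panel$phenotypes[c("bw1", "bw14", "bw28", "nod")])
  expect_lt(gate$p[gate$variable == "bw28"], 0.05)
  expect_identical(attr(gate, "recommended"), "spearman")

  set.seed(1)
  gate_norm <- normality_gate(list(z = stats::rnorm(50)))
  expect_gt(gate_norm$p, 0.05)
  expect_identical(attr(gate_norm, "recommended"), "pearson")

  gate_const <- normality_gate(list(c = rep(1, 5), z = stats::rnorm(10)))
  expect_true(gate_const$degenerate[gate_const$variable == "c"])
  expect_error(normality_gate(list(x = 1:2)), "fewer than 3")
})

test_that("correlation matrix is symmetric, bounded and rank-invariant", {
  panel <- chick_myogenesis()
  ph <- panel$phenotypes
  rep <- correlation_matrix(ph[c("bw1", "bw14", "bw28", "gr2wk", "gr4wk")])
  expect_true(isSymmetric(rep$rho))
  expect_equal(unname(diag(rep$rho)), rep(1, 5))
  expect_true(all(abs(rep$rho) <= 1 + 1e-12))
  # perfectly monotone pairs
  d <- data.frame(up = 1:6, up2 = (1:6)^3, down = 6:1)
  r2 <- correlation_matrix(d)
  expect_equal(r2$rho["up", "up2"], 1)
  expect_equal(r2$rho["up", "down"], -1)
  # Spearman is invariant under monotone transforms
  dd <- data.frame(a = ph$bw28, b = ph$gr4wk)
  dt <- data.frame(a = log(ph$bw28), b = ph$gr4wk^3)
  expect_equal(correlation_matrix(dd)$rho["a", "b"],
               correlation_matrix(dt)$rho["a", "b"], tolerance = 1e-12)
})

test_that("MGEI correlates negatively with post-hatch growth rate", {
  panel <- chick_myogenesis()
  idx <- breed_rank_fits(panel$expression,
                         intercept_modes = panel$intercept_modes)$indices
  merged <- merge(panel$phenotypes, idx, by = "breed")
  rep <- correlation_matrix(merged[c("mgei", "gr2wk", "gr4wk")])
  expect_lt(rep$rho["mgei", "gr4wk"], 0)
  expect_lt(rep$p["mgei", "gr4wk"], 0.05)
  # cross-check rho against a direct rank computation
  brute <- stats::cor(rank(merged$mgei), rank(merged$gr4wk))
  expect_equal(rep$rho["mgei", "gr4wk"], brute, tolerance = 1e-12)
})

test_that("category ANOVA matches the printed breed-type comparison", {
  panel <- chick_myogenesis()
  idx <- breed_rank_fits(panel$expression,
                         intercept_modes = panel$intercept_modes)$indices
  merged <- merge(panel$phenotypes, idx, by = "breed")
  raw <- category_anova(merged$k_breast, merged$meat_category)
  expect_equal(raw$p, 0.09, tolerance = 0.005 / 0.09)
  ln <- category_anova(merged$k_breast, merged$meat_category,
                       ln_normalize = TRUE)
  expect_equal(ln$p, 0.0244, tolerance = 5e-4 / 0.0244)
  expect_lt(ln$p, 0.05)
  gr <- category_anova(merged$gr4wk, merged$meat_category)
  expect_lt(gr$p, 0.001)
})

test_that("ANOVA F has the textbook identities and invariances", {
  x <- c(5.1, 4.9, 6.0, 5.5, 7.2, 7.9, 6.8, 7.5)
  g <- rep(c("a", "b"), each = 4)
  f <- category_anova(x, g)
  tt <- stats::t.test(x ~ g, var.equal = TRUE)
  expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-12)
  # shift and scale invariance of F
  expect_equal(category_anova(x + 100, g)$F, f$F, tolerance = 1e-12)
  expect_equal(category_anova(3 * x, g)$F, f$F, tolerance = 1e-12)
  # identical group means give F = 0, p = 1
  same <- category_anova(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(category_anova(1:4, rep("a", 4)), "2 categories")
  expect_error(category_anova(1:2, c("a", "b")), "singleton")
})

test_that("FDR annotation adds BH q-values without filtering", {
  d <- data.frame(a = c(1, 3, 2, 5, 4, 6), b = c(2, 1, 4, 3, 6, 5),
                  c = c(6, 4, 5, 2, 3, 1))
  rep <- annotate_fdr(correlation_matrix(d))
  expect_true(isSymmetric(rep$q))
  ut <- upper.tri(rep$p)
  expect_equal(rep$q[ut], stats::p.adjust(rep$p[ut], "BH"))
  expect_true(all(rep$q[ut] >= rep$p[ut] - 1e-12))
})
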