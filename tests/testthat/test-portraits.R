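test_that("the worked arithmetic progression is detected", {
  sets <- detect_arithmetic_sets(c(MSTN = 0.20, MYOD1 = 1.36, TBP = 2.49),
                                 tol = 0.05)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$genes, c("MSTN", "MYOD1", "TBP"))
  expect_equal(sets[[1]]$spread, abs(1.16 - 1.13), tolerance = 1e-12)
})

test_that("AP detection reports maximal sets only", {
  sets <- detect_arithmetic_sets(c(a = 0, b = 1, c = 2, d = 3), tol = 0.01)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$genes, c("a", "b", "c", "d"))
  expect_equal(detect_arithmetic_sets(c(a = 1, b = 2), tol = 0.1), list())
  expect_error(detect_arithmetic_sets(c(a = 1, b = 2, c = 3), tol = 0),
               "tol must be > 0")
})

test_that("AP detection equals brute-force enumeration on random panels", {
  set.seed(11)
  for (i in 1:15) {
    v <- stats::setNames(round(stats::runif(7, 0, 5), 2), paste0("g", 1:7))
    got <- detect_arithmetic_sets(v, tol = 0.1)
    got_idx <- lapply(got, function(s) sort(match(s$genes, names(v))))
    want_idx <- oracle_ap_sets(unname(v), tol = 0.1)
    expect_setequal(lapply(got_idx, paste, collapse = ","),
                    lapply(want_idx, paste, collapse = ","))
  }
})

test_that("collinear detection matches the exhaustive-triples oracle", {
  set.seed(23)
  for (n in c(6, 8, 10)) {
    for (i in 1:8) {
      pts <- random_portrait_points(n)
      for (tol in c(0.01, 0.03)) {
        sets <- detect_collinear_sets(pts, tol = tol)
        got <- member_union(sets)
        expect_equal(got, oracle_collinear_members(pts, tol),
                     info = sprintf("n=%d i=%d tol=%g", n, i, tol))
      }
    }
  }
})

test_that("collinear member unions grow monotonically with tolerance", {
  panel <- chick_myogenesis()
  for (b in c("WC", "YC", "BB")) {
    p <- build_portrait(panel$expression, b, "breast")
    prev <- character(0)
    for (tol in c(0.005, 0.01, 0.015, 0.03, 0.06)) {
      cur <- member_union(detect_collinear_sets(p, tol = tol))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("three collinear points plus an outlier give one set of three", {
  pts <- data.frame(gene = c("a", "b", "c", "d"),
                    x = c(0.1, 0.2, 0.3, 0.9),
                    y = c(1.1, 3.2, 5.3, 9.0))
  sets <- detect_collinear_sets(pts, tol = 0.01)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$genes, c("a", "b", "c"))
  expect_lte(sets[[1]]$max_residual, 0.01)
})

test_that("identity-line clusters count only through their AP subsets", {
  # four points on y = x; only {0, 0.2, 0.4} is an arithmetic progression
  pts <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    y = c(0, 0.2, 0.4, 0.95, 3.31),
                    x = c(0, 0.2, 0.4, 0.95, 0.31))
  sets <- detect_collinear_sets(pts, tol = 0.015, ap_tol = 0.1)
  members <- member_union(sets)
  expect_equal(members, c("a", "b", "c"))
})

test_that("bioconsolidation index has the stated bounds and symmetry", {
  expect_equal(bioconsolidation_index(6, 6, 8), 0.75)
  expect_equal(bioconsolidation_index(0, 5, 8), 0)
  expect_equal(bioconsolidation_index(8, 8, 8), 1)
  expect_error(bioconsolidation_index(9, 2, 8), "counts")
  expect_error(bioconsolidation_index(2, 2, 0), "n_genes")
  for (nb in 0:8) {
    for (nt in 0:8) {
      ind <- bioconsolidation_index(nb, nt, 8)
      expect_true(ind >= 0 && ind <= 1)
      expect_equal(ind, bioconsolidation_index(nt, nb, 8))
      if (nb < 8) expect_lte(ind, bioconsolidation_index(nb + 1, nt, 8))
    }
  }
})

test_that("the White Cornish panel consolidates six genes in each tissue", {
  panel <- chick_myogenesis()
  res <- run_model2(panel$expression, "WC")
  expect_equal(res$n_breast, 6L)
  expect_equal(res$n_thigh, 6L)
  expect_equal(res$n_genes, 8L)
  expect_equal(res$ind, 0.75)
  # the worked AP {MSTN, MYOD1, TBP} is among the breast fractals
  breast_sets <- lapply(res$sets_breast, `[[`, "genes")
  expect_true(any(vapply(breast_sets, function(g) {
    all(c("MSTN", "MYOD1", "TBP") %in% g)
  }, logical(1))))
  expect_error(run_model2(panel$expression[panel$expression$tissue == "breast", ],
                          "WC"), "lacks tissue")
})

test_that("planted portrait panels reach the designed index", {
  full <- generate_portrait_panel(synth_spec("portrait_ap", n_genes = 7,
            params = list(n_members = 8), seed = 3))
  expect_equal(run_model2(full, "b1")$ind, 1)
  none <- generate_portrait_panel(synth_spec("portrait_ap", n_genes = 7,
            params = list(n_members = 0), seed = 5))
  expect_equal(run_model2(none, "b1")$ind, 0)
  six <- generate_portrait_panel(synth_spec("portrait_ap", n_genes = 7,
            params = list(n_members = 6), seed = 7))
  expect_equal(run_model2(six, "b1")$ind, 0.75)
})

test_that("planted APs with non-integer step appear as collinear sets", {
  for (seed in 1:5) {
    tab <- generate_portrait_panel(synth_spec("portrait_ap", n_genes = 7,
             params = list(n_members = 4, common_difference = 1.17),
             seed = seed))
    p <- build_portrait(tab, "b1", "breast")
    sets <- detect_collinear_sets(p)
    members <- member_union(sets)
    expect_equal(members, c("TBP", "g1", "g2", "g3"))
  }
})
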