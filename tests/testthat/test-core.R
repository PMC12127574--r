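test_that("reference statistics use the population divisor over C2 only", {
  m <- matrix(c(2, 4, 6, 9, 9, 9), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  x <- gdgse_expr(m, labels = rep(c("normal", "tumor"), each = 3),
                  reference = "normal")
  st <- reference_stats(x)
  expect_equal(unname(st$mu), 4)
  expect_equal(unname(st$sigma), sqrt(8 / 3))  # not the n-1 estimator
  expect_false(isTRUE(all.equal(unname(st$sigma), sd(c(2, 4, 6)))))
  expect_equal(st$n_ref, 3L)

  m2 <- matrix(c(5, 5, 5, 5, 1), nrow = 1,
               dimnames = list("g1", paste0("s", 1:5)))
  x2 <- gdgse_expr(m2, labels = c(rep("normal", 4), "tumor"),
                   reference = "normal")
  st2 <- reference_stats(x2)
  expect_equal(unname(st2$mu), 5)
  expect_equal(unname(st2$sigma), 0)

  # single reference sample: sigma defined as 0
  m3 <- matrix(c(7, 3), nrow = 1, dimnames = list("g1", c("n1", "t1")))
  x3 <- gdgse_expr(m3, labels = c("normal", "tumor"), reference = "normal")
  st3 <- reference_stats(x3)
  expect_equal(unname(st3$mu), 7)
  expect_equal(unname(st3$sigma), 0)
  expect_equal(st3$n_ref, 1L)
})

test_that("binarization is strict at the threshold and follows mu + sigma", {
  m <- matrix(c(2, 4, 6, 6, 5.6329, 5, 5, 5, 5, 5.0001), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:5)))
  x <- gdgse_expr(m, labels = c(rep("normal", 3), "tumor", "tumor"),
                  reference = "normal")
  bin <- binarize(x)
  # gA: thr = 4 + sqrt(8/3) = 5.63299...; 6 exceeds, 5.6329 does not
  expect_identical(unname(bin["gA", ]), c(1L, 0L))
  # gB: sigma = 0, threshold degenerates to mu; equality maps to 0
  expect_identical(unname(bin["gB", ]), c(0L, 1L))
})

test_that("exact threshold equality maps to 0", {
  m <- matrix(c(1, 3, 3, 3.0000001), nrow = 1,
              dimnames = list("g", paste0("s", 1:4)))
  x <- gdgse_expr(m, labels = c("normal", "normal", "tumor", "tumor"),
                  reference = "normal")
  # mu = 2, sigma = 1, thr = 3
  expect_identical(unname(binarize(x)[1, ]), c(0L, 1L))
})

test_that("set scores count measured members over the chosen denominator", {
  bin <- matrix(c(1L, 1L, 0L, 1L), ncol = 1,
                dimnames = list(c("a", "b", "c", "d"), "s1"))
  sets <- gene_sets(list(S4 = c("a", "b", "c", "d"),
                         S5 = c("a", "b", "c", "d", "missing")))
  fit_m <- score_gene_sets(bin, sets, "measured")
  expect_equal(unname(fit_m$scores["S4", 1]), 0.75)
  expect_equal(unname(fit_m$scores["S5", 1]), 0.75)
  fit_f <- score_gene_sets(bin, sets, "full")
  expect_equal(unname(fit_f$scores["S5", 1]), 3 / 5)
  expect_equal(fit_m$genes_measured[["S5"]], 4L)

  all1 <- matrix(1L, 4, 1, dimnames = dimnames(bin))
  expect_equal(unname(score_gene_sets(all1, sets["S4"])$scores[1, 1]), 1)
  all0 <- matrix(0L, 4, 1, dimnames = dimnames(bin))
  expect_equal(unname(score_gene_sets(all0, sets["S4"])$scores[1, 1]), 0)
})

test_that("sets with no measured members are dropped with a warning", {
  bin <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  sets <- gene_sets(list(OK = c("a", "b"), GONE = c("x", "y")))
  expect_warning(fit <- score_gene_sets(bin, sets), "GONE")
  expect_identical(fit$dropped_sets, "GONE")
  expect_identical(rownames(fit$scores), "OK")
  expect_error(score_gene_sets(bin, gene_sets(list(G = c("x", "y")))),
               "no gene set")
})

test_that("toy fixture scores match the hand computation and the oracle", {
  x <- toy_expr_labeled()
  sets <- read_gmt(toy_file("toy_sets.gmt"))
  fit <- gdgse(x, sets)
  expect_equal(unname(fit$scores["SET_A", ]), c(1, 2 / 3, 0))
  expect_equal(unname(fit$scores["SET_B", ]), c(1, 1 / 3, 2 / 3))
  expect_equal(unname(fit$scores["SET_C", ]), c(1, 1 / 2, 0))
  oracle <- naive_scores(x$values, x$labels, "normal", unclass(sets))
  expect_equal(fit$scores, oracle)
  # full-size denominator divides SET_B by 4 instead of 3
  fit_full <- gdgse(x, sets, denominator_mode = "full")
  expect_equal(unname(fit_full$scores["SET_B", ]), c(3 / 4, 1 / 4, 2 / 4))
})

test_that("C1 duplicating C2 scores the fraction of genes above own mu+sigma", {
  set.seed(21)
  v2 <- matrix(rexp(8 * 4, 0.2), 8,
               dimnames = list(paste0("g", 1:8), paste0("n", 1:4)))
  dup <- v2
  colnames(dup) <- paste0("t", 1:4)
  x <- gdgse_expr(cbind(dup, v2),
                  labels = rep(c("tumor", "normal"), each = 4),
                  reference = "normal")
  sets <- gene_sets(list(ALL = paste0("g", 1:8)))
  fit <- gdgse(x, sets)
  st <- naive_refstats(v2, rep("normal", 4), "normal")
  for (j in 1:4) {
    frac <- mean(v2[, j] > st$mu + st$sigma)
    expect_equal(unname(fit$scores["ALL", j]), frac)
  }
})

test_that("scores are invariant to per-gene shifts and positive rescalings", {
  inst <- random_instance(101)
  x <- gdgse_expr(inst$values, labels = inst$labels, reference = "ref")
  sets <- gene_sets(inst$sets)
  base <- suppressWarnings(gdgse(x, sets))
  set.seed(7)
  shift <- runif(nrow(inst$values), -3, 3)
  scale <- runif(nrow(inst$values), 0.1, 10)
  x_mod <- gdgse_expr(inst$values * scale + shift,
                      labels = inst$labels, reference = "ref")
  expect_equal(suppressWarnings(gdgse(x_mod, sets))$scores, base$scores)
})

test_that("raising one C1 entry never lowers the score of containing sets", {
  inst <- random_instance(55)
  x <- gdgse_expr(inst$values, labels = inst$labels, reference = "ref")
  sets <- gene_sets(inst$sets)
  base <- suppressWarnings(gdgse(x, sets))
  c1 <- which(inst$labels != "ref")
  set.seed(8)
  for (rep in 1:10) {
    g <- sample(rownames(inst$values), 1)
    s <- sample(c1, 1)
    v2 <- inst$values
    v2[g, s] <- v2[g, s] + runif(1, 0, 20)
    x2 <- gdgse_expr(v2, labels = inst$labels, reference = "ref")
    new <- suppressWarnings(gdgse(x2, sets))
    for (nm in rownames(base$scores)) {
      if (g %in% sets[[nm]]) {
        expect_gte(new$scores[nm, colnames(x$values)[s]],
                   base$scores[nm, colnames(x$values)[s]])
      }
    }
  }
})

test_that("sample permutation permutes columns; gene order is irrelevant", {
  inst <- random_instance(77)
  x <- gdgse_expr(inst$values, labels = inst$labels, reference = "ref")
  sets <- gene_sets(inst$sets)
  base <- suppressWarnings(gdgse(x, sets))
  set.seed(3)
  ps <- sample(ncol(inst$values))
  xs <- gdgse_expr(inst$values[, ps], labels = inst$labels[ps],
                   reference = "ref")
  perm_fit <- suppressWarnings(gdgse(xs, sets))
  expect_equal(perm_fit$scores,
               base$scores[, colnames(perm_fit$scores), drop = FALSE])
  pg <- sample(nrow(inst$values))
  xg <- gdgse_expr(inst$values[pg, ], labels = inst$labels, reference = "ref")
  g_fit <- suppressWarnings(gdgse(xg, sets))
  expect_equal(g_fit$scores[rownames(base$scores), , drop = FALSE], base$scores)
})

test_that("gene identifier mismatch between stats and matrix is rejected", {
  x <- toy_expr_labeled()
  st <- reference_stats(x)
  st$gene_ids[1] <- "not_a_gene"
  expect_error(binarize(x, st), "do not match")
})

test_that("one-vs-rest separates a perfectly planted signature", {
  genes <- paste0("g", 1:6)
  cells <- paste0("c", 1:9)
  types <- rep(c("A", "B", "C"), each = 3)
  # non-A cells are constant per gene, so the complement threshold equals
  # that constant and strict inequality maps every non-A cell to 0
  v <- matrix(rep(c(1, 2, 0.5, 1.5, 3, 0.2), 9), 6,
              dimnames = list(genes, cells))
  v[c("g1", "g2"), types == "A"] <- 10
  x <- gdgse_expr(v, labels = types)
  sig <- gene_sets(list(A = c("g1", "g2")))
  fit <- one_vs_rest(x, sig)
  expect_equal(unname(fit$scores["A", types == "A"]), rep(1, 3))
  expect_equal(unname(fit$scores["A", types != "A"]), rep(0, 6))
})

test_that("one-vs-rest matrix matches a brute-force per-type recomputation", {
  set.seed(12)
  genes <- paste0("g", 1:6)
  cells <- paste0("c", 1:9)
  types <- rep(c("A", "B", "C"), each = 3)
  v <- matrix(rexp(54, 0.5), 6, dimnames = list(genes, cells))
  sigs <- list(A = c("g1", "g2"), B = c("g3", "g4"), C = c("g5", "g6", "gZ"))
  x <- gdgse_expr(v, labels = types)
  fit <- one_vs_rest(x, gene_sets(sigs))
  for (t in c("A", "B", "C")) {
    oracle <- naive_scores(v, types, setdiff(c("A", "B", "C"), t),
                           sigs[t], which = "all")
    expect_equal(fit$scores[t, , drop = FALSE], oracle)
  }
})

test_that("one-vs-rest requires at least two cell types", {
  v <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  x <- gdgse_expr(v, labels = c("A", "A"))
  expect_error(one_vs_rest(x, gene_sets(list(A = "g1"))), "at least two")
})

test_that("shuffled cell-type labels give no in-type vs out-type signal", {
  sim <- simulate_single_cell(mode = "cell_types", n_genes = 600,
                              set_size = 20, delta = 3, dropout_rate = 0,
                              n_types = 2, cells_per_type = 100, seed = 31)
  set.seed(32)
  shuffled <- sample(sim$expr$labels)
  x <- gdgse_expr(sim$expr$values, labels = unname(shuffled))
  fit <- one_vs_rest(x, sim$sets)
  sc <- fit$scores["type1", ]
  in_t <- x$labels == "type1"
  diff_obs <- mean(sc[in_t]) - mean(sc[!in_t])
  # permutation null for the mean difference on the same score vector
  null_diff <- replicate(500, {
    p <- sample(in_t)
    mean(sc[p]) - mean(sc[!p])
  })
  expect_lt(abs(diff_obs), max(abs(stats::quantile(null_diff, c(0.005, 0.995)))) + 1e-12)
})

test_that("fold change of means follows its conventions", {
  expect_equal(fold_change_of_means(c(0.8, 0.6, 0.2, 0.3, 0.2),
                                    c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               0.7 / mean(c(0.2, 0.3, 0.2)))
  expect_equal(fold_change_of_means(c(0.4, 0.4, 0.4, 0.4),
                                    c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_identical(fold_change_of_means(c(0.5, 0.5, 0, 0),
                                        c(TRUE, TRUE, FALSE, FALSE)), Inf)
  expect_equal(fold_change_of_means(c(0, 0, 0), c(TRUE, FALSE, FALSE)), 1)
  expect_error(fold_change_of_means(c(1, 2), c(TRUE, TRUE)), "non-empty")
  expect_equal(fold_change_of_means(c(0.8, 0.2, 0.2), c("A", "B", "B"),
                                    in_level = "A"), 4)
})

test_that("expression container rejects malformed input", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(gdgse_expr(m), "duplicate gene")
  m2 <- matrix(c(1, NA, 3, 4), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(gdgse_expr(m2), "missing value")
  expect_silent(x <- gdgse_expr(m2, impute_missing = TRUE))
  expect_equal(x$values["g2", "s1"], 0)
  m3 <- matrix(c(1, Inf, 3, 4), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(gdgse_expr(m3), "non-finite")
  ok <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(gdgse_expr(ok, labels = c("a", "a"), reference = "a"),
               "all samples are in the reference")
  expect_error(gdgse_expr(ok, labels = c("a", "b"), reference = "zz"),
               "available levels")
})
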