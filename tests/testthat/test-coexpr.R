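test_that("rank transform uses mean ranks for ties", {
  expect_equal(rank_transform(c(2, 2, 3)), c(1.5, 1.5, 3))
  expect_equal(rank_transform(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(rank_transform(c(5, 1, 5, 5)), c(3, 1, 3, 3))
  expect_error(rank_transform(c(1, 2)), "3 samples")
  expect_error(rank_transform(c(1, 2, NA)), "non-finite")
})

test_that("correlation distance is 1 - Spearman rho, in [0, 2]", {
  r <- rank_transform(c(3, 1, 4, 1.5, 9))
  expect_equal(correlation_distance(r, r), 0)
  expect_equal(correlation_distance(rank_transform(1:5),
                                    rank_transform(5:1)), 2)
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # symmetry and agreement with stats::cor on random data
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    d1 <- correlation_distance(rank_transform(a), rank_transform(b))
    d2 <- correlation_distance(rank_transform(b), rank_transform(a))
    expect_equal(d1, d2)
    expect_equal(1 - d1, cor(a, b, method = "spearman"))
    expect_true(d1 >= 0 && d1 <= 2)
  }
  expect_error(correlation_distance(c(2, 2, 2), c(1, 2, 3)), "zero rank")
})

test_that("rank matrix rows sum to m(m+1)/2 and embed to unit norm", {
  set.seed(8)
  expr <- random_expr(30, 11, tie = TRUE)
  expr <- rbind(expr, constant = rep(1, 11))
  rm_ <- rank_matrix(expr)
  m <- ncol(expr)
  expect_equal(unname(rowSums(rm_$ranks)), rep(m * (m + 1) / 2, nrow(expr)))
  expect_equal(unname(rowMeans(rm_$embedding)),
               rep(0, nrow(rm_$embedding)))
  expect_equal(unname(sqrt(rowSums(rm_$embedding^2))),
               rep(1, nrow(rm_$embedding)))
  expect_equal(rm_$excluded, "constant")
  expect_false("constant" %in% rm_$feature_ids)
  expect_error(rank_matrix(expr[, 1:2]), "fewer than 3 samples")
})

test_that("a self-query returns the gene itself with rho = 1", {
  set.seed(2)
  expr <- random_expr(1, 10)
  idx <- build_coexpr_index(rank_matrix(expr))
  hit <- query_correlated_genes(rank_transform(expr[1, ]), idx)
  expect_equal(hit$gene_id, "g0001")
  expect_equal(hit$rho, 1)
  expect_equal(hit$distance, 0)
})

test_that("tree-backed queries equal the brute-force Spearman oracle", {
  set.seed(101)
  for (rep in 1:6) {
    expr <- random_expr(sample(50:200, 1), sample(10:30, 1),
                        tie = rep %% 2 == 0)
    idx <- build_coexpr_index(rank_matrix(expr), leaf_size = 5L)
    for (q in 1:5) {
      qvals <- if (q == 1) expr[1, ] else rnorm(ncol(expr))
      k <- sample(c(3L, 10L, 1000L), 1)
      rho_min <- sample(c(0.2, 0.5, 0.8), 1)
      got <- query_correlated_genes(rank_transform(qvals), idx,
                                    k = k, rho_min = rho_min)
      want <- oracle_correlated(qvals, expr, k = k, rho_min = rho_min)
      expect_equal(got$gene_id, want$gene_id)
      expect_equal(got$rho, want$rho, tolerance = 1e-12)
    }
  }
})

test_that("the three search strategies return identical hit sets", {
  set.seed(77)
  expr <- random_expr(120, 15, tie = TRUE)
  qvals <- expr[3, ] + rnorm(15, sd = 0.5)
  for (k in c(5L, 1000L)) {
    h_tree <- find_correlated_genes(qvals, expr, method = "tree", k = k)
    h_pre <- find_correlated_genes(qvals, expr, method = "preranked", k = k)
    h_brut <- find_correlated_genes(qvals, expr, method = "bruteforce", k = k)
    expect_equal(h_tree$gene_id, h_pre$gene_id)
    expect_equal(h_tree$gene_id, h_brut$gene_id)
    expect_equal(h_tree$rho, h_pre$rho, tolerance = 1e-12)
    expect_equal(h_tree$rho, h_brut$rho, tolerance = 1e-12)
    expect_equal(h_tree$distance, 1 - h_tree$rho)
  }
})

test_that("strictly increasing transforms leave query results unchanged", {
  set.seed(13)
  expr <- random_expr(80, 12)
  qvals <- expr[7, ] + rnorm(12, sd = 0.3)
  base <- find_correlated_genes(qvals, expr, method = "tree", rho_min = 0.2)
  transforms <- list(function(x) exp(x), function(x) x^3 + 2 * x,
                     function(x) 5 * x - 7)
  for (f in transforms) {
    expr_t <- expr
    expr_t[7, ] <- f(expr_t[7, ])          # transform one feature
    got <- find_correlated_genes(qvals, expr_t, method = "tree",
                                 rho_min = 0.2)
    expect_equal(got, base)
    # and transforming the query itself
    got_q <- find_correlated_genes(f(qvals), expr, method = "tree",
                                   rho_min = 0.2)
    expect_equal(got_q, base)
  }
})

test_that("query validation rejects bad lengths, rho_min and flat queries", {
  set.seed(4)
  expr <- random_expr(10, 8)
  idx <- build_coexpr_index(rank_matrix(expr))
  expect_error(query_correlated_genes(rank_transform(rnorm(5)), idx),
               "does not match")
  expect_error(query_correlated_genes(rank_transform(expr[1, ]), idx,
                                      rho_min = 1.5), "rho_min")
  expect_error(query_correlated_genes(rank_transform(expr[1, ]), idx,
                                      rho_min = -1), "rho_min")
  expect_error(query_correlated_genes(rep(4.5, 8), idx), "zero rank")
  expect_equal(idx$leaf_size, 5L)   # recorded for run metadata
})

test_that("k-th place rho ties break by gene id for reproducibility", {
  # three genes perfectly correlated with the query, k = 2
  base <- c(1, 2, 3, 4, 5)
  expr <- rbind(gB = base, gA = 2 * base, gC = base + 10,
                gZ = c(5, 4, 3, 2, 1))
  colnames(expr) <- paste0("s", 1:5)
  hits <- find_correlated_genes(base, expr, method = "tree", k = 2L)
  expect_equal(hits$gene_id, c("gA", "gB"))
  expect_equal(hits$rho, c(1, 1))
})
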