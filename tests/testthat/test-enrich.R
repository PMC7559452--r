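test_that("background is the intersection of dataset genes and set members", {
  sets <- list(t1 = c("a", "b"), t2 = c("b", "d"))
  expect_setequal(make_background(c("a", "b", "c"), sets), c("a", "b"))
  expect_error(make_background(c("x", "y"), sets), "empty background")
  expect_error(make_background(character(0), sets), "non-empty")

  # explicit construction: 120 annotated genes, union of sets 100, overlap 80
  genes <- paste0("g", 1:120)
  union_genes <- paste0("g", 41:140)     # 80 of them are annotated
  sets2 <- split(union_genes, rep(1:5, each = 20))
  bg <- make_background(genes, sets2)
  expect_equal(length(bg), 80L)
  expect_setequal(bg, paste0("g", 41:120))
})

test_that("hypergeometric tail matches hand-derived values", {
  # (C(5,3)C(5,1) + C(5,4)C(5,0)) / C(10,4) = 55/210
  expect_equal(hypergeom_tail(3, 5, 4, 10), 55 / 210, tolerance = 1e-12)
  # single-term tail 1/C(10,4)
  expect_equal(hypergeom_tail(4, 4, 4, 10), 1 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 5, 4, 10), 1)
  expect_error(hypergeom_tail(5, 4, 6, 10), "I <= min")
  expect_error(hypergeom_tail(1, 11, 4, 10), "I <= min|M <= T")
  expect_error(hypergeom_tail(1.5, 4, 4, 10), "integers")
})

test_that("hypergeometric tail equals exhaustive enumeration for T <= 12", {
  for (T_ in c(5L, 8L, 12L)) {
    for (M in c(1L, T_ %/% 2, T_ - 1L)) {
      for (N in c(1L, T_ %/% 2, T_)) {
        for (I in unique(c(0L, 1L, min(M, N)))) {
          expect_equal(hypergeom_tail(I, M, N, T_),
                       enum_hyper_tail(I, M, N, T_), tolerance = 1e-12,
                       label = sprintf("tail(I=%d,M=%d,N=%d,T=%d)",
                                       I, M, N, T_))
        }
      }
    }
  }
})

test_that("tail probability is monotone in the overlap count", {
  p_prev <- 0
  for (I in 5:0) {
    p <- hypergeom_tail(I, 6, 5, 14)
    expect_gte(p, p_prev)
    p_prev <- p
  }
})

test_that("pooled p sums counts and reduces to p_S for one dataset", {
  one <- data.frame(I = 3L, M = 5L, N = 4L, T = 10L)
  expect_equal(pooled_p(one), hypergeom_tail(3, 5, 4, 10))
  # two identical datasets pool to the tail at the summed parameters
  two <- rbind(one, one)
  expect_equal(pooled_p(two), hypergeom_tail(6, 10, 8, 20))
  expect_equal(pooled_p(two), enum_hyper_tail(6, 10, 8, 20),
               tolerance = 1e-12)
  # zero overlap everywhere pools to 1
  zeros <- data.frame(I = c(0L, 0L), M = c(5L, 4L), N = c(4L, 3L),
                      T = c(10L, 10L))
  expect_equal(pooled_p(zeros), 1)
  expect_error(pooled_p(one[0, ]), "at least one")
})

test_that("BH adjustment reproduces the hand step-up and its properties", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, manual_bh(p))
    expect_true(all(q >= p))                      # never below the raw p
    expect_true(!is.unsorted(q[order(p)]))        # preserves the p ordering
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("prediction recovers a perfectly co-expressed term", {
  set.seed(21)
  n_samp <- 20
  base <- rnorm(n_samp)
  genes <- paste0("g", sprintf("%02d", 1:40))
  expr <- matrix(rnorm(40 * n_samp), 40, n_samp, dimnames = list(genes, NULL))
  colnames(expr) <- paste0("s", 1:n_samp)
  # genes 1..10: exact monotone copies of the smORF profile
  for (i in 1:10) expr[i, ] <- base * (i / 5) + i
  smorf <- matrix(base, 1, n_samp,
                  dimnames = list("smX", colnames(expr)))
  sets <- list(GOBP_TARGET = genes[1:10], GOBP_OTHER = genes[11:30],
               KEGG_MIXED = genes[c(1:3, 31:40)])
  ds <- list(d1 = list(gene_expr = expr, smorf_expr = smorf))
  res <- predict_functions("smX", ds, sets, k = 1000L, rho_min = 0.99)
  expect_equal(res$term_id[1], "GOBP_TARGET")
  expect_true(res$selected[1])
  expect_equal(res$I_sum[res$term_id == "GOBP_TARGET"], 10L)
  expect_equal(attr(res, "status"), "ok")
  detail <- attr(res, "per_dataset")
  expect_true(all(detail$N == 10L))
  expect_true(all(detail$T == length(make_background(genes, sets))))

  # no gene reaches rho_min -> all p = 1, nothing selected
  smorf_flat <- matrix(rnorm(n_samp) * 1e-2 + 100, 1, n_samp,
                       dimnames = list("smX", colnames(expr)))
  set.seed(99)
  expr_null <- matrix(rnorm(40 * n_samp), 40, n_samp,
                      dimnames = dimnames(expr))
  res_null <- predict_functions(
    "smX", list(d1 = list(gene_expr = expr_null, smorf_expr = smorf_flat)),
    sets, rho_min = 0.999)
  expect_true(all(res_null$p == 1))
  expect_false(any(res_null$selected))
})

test_that("unquantifiable smORFs yield an empty flagged result", {
  expr <- matrix(rnorm(15), 5, 3,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  ds <- list(d1 = list(gene_expr = expr,
                       smorf_expr = expr[0, , drop = FALSE]))
  res <- predict_functions("ghost", ds, list(t1 = c("g1", "g2")))
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "status"), "unquantifiable")
})

test_that("terms outside the background are skipped, not reported at p=1", {
  set.seed(33)
  expr <- random_expr(30, 12)
  smorf <- matrix(expr[1, ], 1, 12, dimnames = list("sm", colnames(expr)))
  sets <- list(GOBP_IN = rownames(expr)[1:10],
               GOBP_OUT = paste0("absent", 1:5))
  res <- predict_functions(
    "sm", list(d1 = list(gene_expr = expr, smorf_expr = smorf)), sets)
  expect_false("GOBP_OUT" %in% res$term_id)
})

test_that("FDR family switch adjusts within collections or jointly", {
  set.seed(55)
  expr <- random_expr(60, 15)
  smorf <- matrix(expr[1, ] + rnorm(15, sd = 0.2), 1, 15,
                  dimnames = list("sm", colnames(expr)))
  sets <- list(GOBP_A = rownames(expr)[1:10], GOBP_B = rownames(expr)[11:25],
               KEGG_A = rownames(expr)[c(1:5, 26:35)],
               KEGG_B = rownames(expr)[36:50])
  ds <- list(d1 = list(gene_expr = expr, smorf_expr = smorf))
  per_coll <- predict_functions("sm", ds, sets, rho_min = 0.3)
  joint <- predict_functions("sm", ds, sets, rho_min = 0.3,
                             fdr_family = "all")
  expect_equal(per_coll$p, joint$p)              # pooled p identical
  for (coll in unique(per_coll$collection)) {
    sel <- per_coll$collection == coll
    expect_equal(per_coll$fdr[sel], bh_fdr(per_coll$p[sel]))
  }
  expect_equal(joint$fdr[order(joint$term_id)],
               bh_fdr(joint$p[order(joint$term_id)]))
  expect_equal(gene_set_collections(c("GOBP_X", "GOCC_X", "GOMF_X",
                                      "KEGG_X", "REACTOME_X", "MY_SET")),
               c("GO-BP", "GO-CC", "GO-MF", "KEGG", "REACTOME", "custom"))
})
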