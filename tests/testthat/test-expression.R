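mini_ct <- function(target_ct, ref_ct = 20, reps = 3L) {
  rows <- list()
  for (s in names(target_ct)) {
    rows[[length(rows) + 1L]] <- data.frame(sample = s, gene = "ref",
                                            ct = rep(ref_ct, reps))
    rows[[length(rows) + 1L]] <- data.frame(sample = s, gene = "tgt",
                                            ct = rep(target_ct[[s]], reps))
  }
  ct_table(do.call(rbind, rows))
}

test_that("ddct closed forms: calibrator is 1, shifts map to powers of two", {
  ct <- mini_ct(c(cal = 24, up = 22, down = 25))
  r <- ddct(ct, "tgt", "ref", "cal")
  expect_equal(r$rel_expr[r$sample == "cal"], 1)
  expect_equal(r$rel_expr[r$sample == "up"], 4)      # ddCt = -2
  expect_equal(r$rel_expr[r$sample == "down"], 0.5)  # target +1, ref fixed
  expect_true(all(r$rel_expr > 0))
})

test_that("ddct requires reference wells in every sample", {
  ct <- mini_ct(c(cal = 24, s2 = 23))
  broken <- ct[!(ct$sample == "s2" & ct$gene == "ref"), ]
  expect_error(ddct(ct_table(broken), "tgt", "ref", "cal"), "normalization")
  expect_error(ddct(ct, "tgt", "ref", "nope"), "calibrator")
})

test_that("ddct is invariant to a constant Ct offset per sample", {
  set.seed(10)
  for (i in 1:20) {
    base <- mini_ct(c(cal = runif(1, 20, 26), s2 = runif(1, 20, 26)))
    shifted <- base
    off <- runif(1, -3, 3)
    shifted$ct[shifted$sample == "s2"] <- shifted$ct[shifted$sample == "s2"] + off
    r0 <- ddct(base, "tgt", "ref", "cal")
    r1 <- ddct(shifted, "tgt", "ref", "cal")
    # the offset cancels in dCt only if it hits target and reference alike
    expect_equal(r1$rel_expr, r0$rel_expr, tolerance = 1e-12)
  }
})

test_that("contrasts compute signed log2 fold changes with direction calls", {
  vals <- matrix(c(5, 5, 7, 5, 5, 5.2), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("trt", "ctl")))
  vals["g2", "trt"] <- 7   # 4x up
  vals["g1", "trt"] <- 5   # equal
  vals["g3", "trt"] <- 3.8 # down beyond threshold
  vals["g3", "ctl"] <- 5.2
  ex <- expression_matrix(vals)
  res <- contrast_matrix(ex, list(t_vs_c = c("trt", "ctl")))
  expect_equal(res$log2fc[res$gene == "g2"], 2)
  expect_equal(res$direction[res$gene == "g2"], "up")
  expect_equal(res$direction[res$gene == "g1"], "unchanged")
  expect_equal(res$direction[res$gene == "g3"], "down")
  # equal columns: everything unchanged
  same <- expression_matrix(cbind(a = c(x = 1, y = 2), b = c(x = 1, y = 2)))
  expect_true(all(contrast_matrix(same, list(k = c("a", "b")))$direction
                  == "unchanged"))
  # masked cells propagate and unknown columns error
  vals2 <- vals; vals2["g1", "trt"] <- NA
  res2 <- contrast_matrix(expression_matrix(vals2), list(t = c("trt", "ctl")))
  expect_equal(res2$direction[res2$gene == "g1"], "missing")
  expect_error(contrast_matrix(ex, list(bad = c("trt", "zzz"))), "unknown")
})

test_that("direction tallies conserve the gene count per contrast", {
  set.seed(2)
  sim <- make_expression(n_genes = 40,
                         plan = data.frame(contrast = "c1", numerator = "n",
                                           denominator = "d", n_up = 5L,
                                           n_down = 3L),
                         noise_sd = 0, missing_frac = 0)
  res <- contrast_matrix(sim$expr, sim$contrasts)
  dc <- direction_counts(res)
  expect_equal(dc$up, 5L)
  expect_equal(dc$down, 3L)
  expect_equal(dc$up + dc$down + dc$unchanged + dc$missing, dc$n)
  expect_equal(dc$n, 40L)
  # all-unchanged input
  res0 <- contrast_matrix(
    expression_matrix(cbind(a = c(g1 = 1, g2 = 2), b = c(g1 = 1, g2 = 2))),
    list(k = c("a", "b")))
  expect_equal(unlist(direction_counts(res0)[, c("up", "down", "unchanged",
                                                 "missing")], use.names = FALSE),
               c(0L, 0L, 2L, 0L))
})

test_that("gene clustering is deterministic and permutation-invariant", {
  vals <- rbind(g1 = c(0, 0, 0), g2 = c(0.01, 0, 0), g3 = c(5, 5, 5),
                g4 = c(-4, 2, 1))
  colnames(vals) <- c("a", "b", "c")
  ex <- expression_matrix(vals)
  cl <- cluster_genes(ex)
  # the near-identical pair merges first
  first <- rownames(vals)[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("g1", "g2"))
  # permuting rows gives the same partition structure
  perm <- expression_matrix(vals[c(3, 1, 4, 2), ])
  cl2 <- cluster_genes(perm)
  expect_equal(sort(cl$hclust$height), sort(cl2$hclust$height))
  part <- function(x, k) {
    g <- stats::cutree(x$hclust, k)
    unname(vapply(split(names(g), g), function(m)
      paste(sort(m), collapse = "+"), character(1)))
  }
  expect_setequal(part(cl, 2), part(cl2, 2))
  # missing handling: drop vs zero-impute
  vals2 <- vals; vals2["g4", "a"] <- NA
  ex2 <- expression_matrix(vals2)
  expect_equal(cluster_genes(ex2)$dropped, "g4")
  expect_equal(length(cluster_genes(ex2, impute_zero = TRUE)$order), 4L)
  expect_error(cluster_genes(expression_matrix(vals[1:2, ][c(FALSE, TRUE), ,
                                                          drop = FALSE])),
               ">= 2")
})
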