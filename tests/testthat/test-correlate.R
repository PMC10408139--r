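test_that("pearson matches the t-formula oracle and flags constants", {
  expect_equal(pearson(1:4, 1:4)$r, 1)
  expect_equal(pearson(1:4, 1:4)$p_value, 0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1))$r, -1)

  res <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  # hand computation: cov = 4/3, sd products give r = 0.8; t on 2 df
  r_hand <- 0.8
  t_hand <- r_hand * sqrt((4 - 2) / (1 - r_hand^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-t_hand, df = 2), tolerance = 1e-12)

  const <- pearson(c(2, 2, 2), c(1, 2, 3))
  expect_false(const$computable)
  expect_true(is.na(const$r))
  expect_error(pearson(1:2, 1:2), "at least 3")

  # affine equivariance
  x <- withr::with_seed(1, rnorm(20)); y <- withr::with_seed(2, rnorm(20))
  expect_equal(pearson(2 * x + 3, y)$r, pearson(x, y)$r, tolerance = 1e-12)
  expect_equal(pearson(-x, y)$r, -pearson(x, y)$r, tolerance = 1e-12)
})

test_that("inter-signature correlation is symmetric and equals a pairwise loop", {
  m <- withr::with_seed(3, matrix(rnorm(4 * 30), 4,
                                  dimnames = list(paste0("S", 1:4),
                                                  paste0("s", 1:30))))
  cc <- inter_signature_correlation(m)
  expect_identical(cc$r, t(cc$r))
  expect_equal(unname(diag(cc$r)), rep(1, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- pearson(m[i, ], m[j, ])
    expect_identical(cc$r[i, j], ref$r)
    expect_identical(cc$p_value[i, j], ref$p_value)
  }

  dup <- rbind(m, S1b = m[1, ])
  expect_equal(inter_signature_correlation(dup)$r["S1", "S1b"], 1)

  # signature and its flipped twin anticorrelate exactly
  expr <- rand_expr(100, 25, seed = 4)
  sig <- rand_signature(expr$gene, 8, 8, seed = 5, name = "sig")
  sc <- score_signatures(expr, list(sig, flip_signature(sig)))
  cc2 <- inter_signature_correlation(sc)
  expect_equal(cc2$r["sig", "sig_flipped"], -1)

  # constant score row reported as not-computable
  m2 <- m; m2[2, ] <- 5
  cc3 <- inter_signature_correlation(m2)
  expect_true(all(is.na(cc3$r[2, -2])))
})

test_that("signatures sharing genes correlate most over a reference cohort", {
  ref <- simulate_reference_cohort(150, 400, seed = 7)
  genes <- ref$gene
  base <- rand_signature(genes[1:300], 20, 20, seed = 1, name = "base")
  shared <- gene_signature("shared", up = c(base$up[1:15], genes[301:305]),
                           down = c(base$down[1:15], genes[306:310]))
  others <- lapply(2:3, function(i) rand_signature(genes[1:300], 20, 20,
                                                   seed = i * 11,
                                                   name = paste0("rand", i)))
  cc <- inter_signature_correlation(
    score_signatures(ref, c(list(base, shared), others)))
  off <- cc$r; diag(off) <- NA
  expect_equal(cc$r["base", "shared"], max(off, na.rm = TRUE))
})

test_that("clustering uses 1 - r with average linkage, deterministically", {
  # identical rows merge first at height 0
  m <- withr::with_seed(9, matrix(rnorm(3 * 20), 3,
                                  dimnames = list(c("a", "b", "c"), NULL)))
  m <- rbind(m, a2 = m[1, ])
  tree <- cluster_signatures(suppressWarnings(cor(t(m))))
  expect_equal(min(tree$height), 0, tolerance = 1e-12)

  # hand-built 4x4 block structure: blocks are the top-level split
  r <- matrix(0, 4, 4, dimnames = list(c("a1", "a2", "b1", "b2"),
                                       c("a1", "a2", "b1", "b2")))
  r[1:2, 1:2] <- 0.9; r[3:4, 3:4] <- 0.9; diag(r) <- 1
  tree2 <- cluster_signatures(r)
  # by hand: a1-a2 and b1-b2 merge at d = 0.1, blocks join at d = 1
  expect_equal(sort(tree2$height), c(0.1, 0.1, 1), tolerance = 1e-12)
  top <- stats::cutree(tree2, k = 2)
  expect_equal(unname(top[c("a1", "a2")]), rep(top[["a1"]], 2))
  expect_equal(unname(top[c("b1", "b2")]), rep(top[["b1"]], 2))
  expect_false(top[["a1"]] == top[["b1"]])

  single <- cluster_signatures(matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_equal(length(single$height), 0)
  r_na <- r; r_na[1, 2] <- r_na[2, 1] <- NA
  expect_error(cluster_signatures(r_na), "drop")
})

test_that("clinical correlations stratify by sex and respect small strata", {
  clin <- tibble::tibble(
    sample_id = sprintf("p%02d", 1:12),
    sex = rep(c("F", "M"), 6),
    gestational_age_weeks = withr::with_seed(1, runif(12, 24, 32)),
    birth_weight_g = withr::with_seed(2, runif(12, 500, 1500)),
    bpd_severity = rep(0:3, each = 3),
    oxygen_28d = rep(c(0L, 1L), each = 6))
  # scores strictly increasing in severity -> r = 1 overall
  sc <- tibble::tibble(signature = "sig", sample_id = clin$sample_id,
                       score = as.numeric(clin$bpd_severity) * 2 + 1e-3 * (1:12))
  rep_all <- clinical_correlation(sc, clin)
  cell <- rep_all[rep_all$variable == "bpd_severity" & rep_all$stratum == "all", ]
  expect_gt(cell$r, 0.999)
  expect_setequal(unique(rep_all$stratum), c("all", "sex=F", "sex=M"))
  expect_setequal(unique(rep_all$variable),
                  c("gestational_age_weeks", "birth_weight_g", "bpd_severity",
                    "oxygen_28d"))

  # misaligned ids are named
  bad <- sc; bad$sample_id[1] <- "zzz"
  expect_error(clinical_correlation(bad, clin), "zzz")

  # a stratum smaller than 3 is reported, not computed
  tiny <- clinical_correlation(sc[1:2, ], clin, stratify_by = "sex")
  expect_true(all(!tiny$computable))
  expect_true(all(is.na(tiny$r)))

  # binary BPD encoding is available
  bin <- clinical_correlation(sc, clin, variables = "bpd_severity",
                              stratify_by = "all", bpd_binary = TRUE)
  expect_lt(bin$r[1], cell$r)
})

test_that("null clinical cohorts give severity correlations centered at zero", {
  g <- simulated_genes(300)
  sig <- gene_signature("s", up = g[1:40], down = g[41:80])
  rs <- vapply(1:8, function(s) {
    cs <- simulate_clinical_cohort(c(10, 10, 10, 10), delta = 0, sig, 300,
                                   seed = s)
    sc <- score_signatures(cs$expression, list(sig))
    pearson(sc$score, cs$clinical$bpd_severity[match(sc$sample_id,
                                                     cs$clinical$sample_id)])$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.1)
})
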