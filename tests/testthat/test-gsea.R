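make_ranked <- function(scores, genes = sprintf("g%03d", seq_along(scores))) {
  rank_genes(tibble::tibble(gene = genes, log2_fc = scores,
                            p_value = rep(0.5, length(scores))),
             metric = "log2_fc")
}

test_that("gene ranking is descending with deterministic lexicographic ties", {
  deg <- tibble::tibble(gene = c("b", "a"), log2_fc = c(-1, 1),
                        p_value = c(0.01, 0.01))
  rk <- rank_genes(deg)
  expect_equal(rk$gene, c("a", "b"))
  expect_equal(rk$score[1], -log10(0.01))

  flat <- tibble::tibble(gene = c("z", "m", "a"), log2_fc = c(2, -3, 1),
                         p_value = rep(1, 3))
  rkf <- rank_genes(flat)
  expect_equal(rkf$score, rep(0, 3))
  expect_equal(rkf$gene, c("a", "m", "z"))
  expect_setequal(attr(rkf, "ties"), c("a", "m", "z"))

  expect_error(rank_genes(tibble::tibble(gene = c("a", "a"),
                                         log2_fc = 1:2,
                                         p_value = c(0.1, 0.2))), "duplicate")
  tiny <- tibble::tibble(gene = "a", log2_fc = 1, p_value = 0)
  expect_true(is.finite(rank_genes(tiny)$score))
})

test_that("enrichment score matches the step-through oracle and its reductions", {
  rk <- make_ranked(c(5, 4, 1, -3, -6))
  hit <- rk$gene %in% rk$gene[c(1, 4)]

  es1 <- enrichment_score(rk, rk$gene[c(1, 4)], weight_exponent = 1)
  expect_equal(es1$es, es_oracle(rk$score, hit, 1), tolerance = 1e-12)
  expect_equal(es1$es, 0.625, tolerance = 1e-12)  # frozen from the oracle

  # weight 0 reduces to the classical KS statistic on ranks
  es0 <- enrichment_score(rk, rk$gene[c(1, 4)], weight_exponent = 0)
  expect_equal(es0$es, es_oracle(rk$score, hit, 0), tolerance = 1e-12)
  F_hit <- cumsum(hit) / sum(hit)
  F_miss <- cumsum(!hit) / sum(!hit)
  ks <- (F_hit - F_miss)[which.max(abs(F_hit - F_miss))]
  expect_equal(es0$es, ks, tolerance = 1e-12)

  # all hits at the top: running sum peaks at exactly 1
  expect_equal(enrichment_score(rk, rk$gene[1:2])$es, 1, tolerance = 1e-12)

  expect_error(enrichment_score(rk, "absent"), "no member")
  expect_error(enrichment_score(rk, rk$gene), "entire")

  # random instances: full running-sum path vs oracle, and |ES| <= 1
  for (s in 1:10) {
    sc <- withr::with_seed(s, sort(rnorm(40), decreasing = TRUE))
    rks <- make_ranked(sc)
    set <- withr::with_seed(s + 50, sample(rks$gene, 7))
    es <- enrichment_score(rks, set)$es
    expect_equal(es, es_oracle(rks$score, rks$gene %in% set), tolerance = 1e-12)
    expect_lte(abs(es), 1)
  }
})

test_that("the O(hits) scorer used for permutations equals the full path", {
  for (s in 1:10) {
    n <- 200
    sc <- withr::with_seed(s, sort(rnorm(n), decreasing = TRUE))
    rks <- make_ranked(sc)
    pos <- withr::with_seed(s + 7, sort(sample.int(n, 15)))
    fast <- oxisig:::es_from_positions(pos, abs(sc[pos]), n)$es
    full <- enrichment_score(rks, rks$gene[pos])$es
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("negating the ranking reverses the list and negates the score", {
  sc <- withr::with_seed(3, round(sort(rnorm(30), decreasing = TRUE), 6))
  rk <- make_ranked(sc)
  rk_neg <- make_ranked(-rev(sc), genes = rev(rk$gene))
  set <- rk$gene[c(2, 5, 9, 20)]
  expect_equal(enrichment_score(rk_neg, set)$es,
               -enrichment_score(rk, set)$es, tolerance = 1e-12)
})

test_that("permutation GSEA is seed-deterministic and finds planted sets", {
  sc <- withr::with_seed(11, sort(rnorm(300, sd = 2), decreasing = TRUE))
  rk <- make_ranked(sc)
  sets <- c(list(planted = rk$gene[1:15]),
            simulate_gene_sets(rk$gene, n_sets = 10, set_size = 15, seed = 1))

  r1 <- gsea_preranked(rk, sets, n_perm = 200, seed = 5)
  r2 <- gsea_preranked(rk, sets, n_perm = 200, seed = 5)
  expect_identical(r1, r2)

  planted <- r1[r1$set == "planted", ]
  expect_equal(planted$p_value, 1 / 201)
  expect_gt(planted$nes, 1)
  expect_lt(planted$fdr_q, 0.25)
  expect_equal(sign(r1$nes), sign(r1$es))
  expect_true(all(r1$fdr_q >= 0 & r1$fdr_q <= 1))

  # permutation count changes only p / NES / q, never ES
  r10 <- gsea_preranked(rk, sets, n_perm = 10, seed = 9)
  expect_equal(r10$es[order(r10$set)], r1$es[order(r1$set)], tolerance = 1e-15)

  expect_error(gsea_preranked(rk, list(tiny = rk$gene[1:2]), n_perm = 10,
                              seed = 1), "size filter")
})

test_that("enrichment scores agree with an independent implementation", {
  sc <- withr::with_seed(21, sort(rnorm(500), decreasing = TRUE))
  rk <- make_ranked(sc)
  stats <- stats::setNames(rk$score, rk$gene)
  for (s in 1:5) {
    set <- withr::with_seed(s + 30, sample(rk$gene, 25))
    ours <- enrichment_score(rk, set)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(rk$gene %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("GMT files round-trip and reject malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4"))
  attr(sets, "description") <- c(setA = "first", setB = "second")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back$setA, sets$setA)
  expect_equal(attr(back, "description")[["setB"]], "second")

  writeLines(c("lonely\tdesc"), f)
  expect_error(read_gmt(f), "line 1")
  writeLines(c("s\td\tg1\tg1\tg2"), f)
  expect_equal(read_gmt(f)$s, c("g1", "g2"))  # silent member dedup
})

test_that("NES matrices keep significant cells only and feed discordance", {
  mk <- function(set, nes, q) {
    structure(tibble::tibble(set = set, size = 10, es = sign(nes), nes = nes,
                             p_value = 0.01, fdr_q = q, leading_edge_size = 5),
              class = c("gsea_result", class(tibble::tibble())))
  }
  res <- list(c1 = mk(c("p1", "p2", "p3"), c(2.1, 1.5, 0.5), c(0.01, 0.5, 0.9)),
              c2 = mk(c("p1", "p2"), c(-1.8, 1.2), c(0.01, 0.01)))
  nes <- nes_matrix(res)
  expect_equal(sort(rownames(nes)), c("p1", "p2"))  # p3 never significant
  expect_true(is.na(nes["p2", "c1"]))
  expect_equal(nes["p1", "c2"], -1.8)

  disc <- discordant_pathways(nes, "c1", "c2")
  expect_equal(disc$pathway, "p1")  # opposite signs, both significant
  expect_equal(disc$nes_gap, 3.9)
  expect_error(discordant_pathways(nes, "c1", "nope"), "unknown contrast")

  both_pos <- nes; both_pos["p1", "c2"] <- 1.8
  expect_equal(nrow(discordant_pathways(both_pos, "c1", "c2")), 0)

  none <- list(c1 = mk("p1", 2, 0.9), c2 = mk("p1", 2, 0.9))
  expect_warning(empty <- nes_matrix(none), "no pathway")
  expect_equal(nrow(empty), 0)
  expect_error(nes_matrix(res[c(1, 1)]), "unique")
})
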