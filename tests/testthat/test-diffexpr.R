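test_that("log2-CPM matches its closed form and is scale invariant at large counts", {
  # one gene, count 0, library size forced to 1e6 via a filler gene
  counts <- tibble::tibble(gene = c("g1", "filler"), s1 = c(0L, 1000000L))
  expr <- cpm_normalize(counts)
  expect_equal(expr$s1[1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  # proportional columns converge to equal normalized values
  withr::with_seed(1, {
    base <- rpois(50, 5e4)
  })
  m <- tibble::tibble(gene = sprintf("g%02d", 1:50), a = base, b = 2L * base)
  e <- cpm_normalize(m)
  expect_equal(e$a, e$b, tolerance = 1e-4)

  expect_error(cpm_normalize(tibble::tibble(gene = "g", s = -1L)), "nonnegative")
  expect_error(cpm_normalize(tibble::tibble(gene = "g", bad = 0L, ok = 5L)),
               "bad")
})

test_that("BH adjustment reproduces hand-derived values and is order invariant", {
  # step-up by hand: all three collapse to 0.03
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (s in 1:5) {
    p <- withr::with_seed(s, runif(40))
    perm <- withr::with_seed(s + 100, sample(40))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
})

test_that("Welch stage matches t.test and handles degenerate genes by policy", {
  expr <- rand_expr(100, 12, seed = 3)
  grp <- rep(c("a", "b"), each = 6)
  deg <- differential_expression(expr, grp)
  m <- oxisig:::as_expr_matrix(expr)
  ref <- apply(m, 1, function(r) t.test(r[7:12], r[1:6])$p.value)
  expect_equal(deg$p_value, unname(ref), tolerance = 1e-12)
  expect_equal(deg$log2_fc,
               unname(rowMeans(m[, 7:12]) - rowMeans(m[, 1:6])),
               tolerance = 1e-12)

  same <- tibble::tibble(gene = c("g1", "g2"), a1 = c(1, 5), a2 = c(2, 5),
                         b1 = c(1, 5), b2 = c(2, 5))
  d2 <- differential_expression(same, c("a", "a", "b", "b"))
  expect_equal(d2$log2_fc, c(0, 0))
  expect_equal(d2$p_value, c(1, 1))

  sep <- tibble::tibble(gene = "g1", a1 = 1, a2 = 1, b1 = 3, b2 = 3)
  d3 <- differential_expression(sep, c("a", "a", "b", "b"))
  expect_equal(d3$p_value, 0)
  expect_true(d3$degenerate)

  expect_error(differential_expression(same, c("a", "b", "b", "b")),
               "at least 2 samples")
  expect_error(differential_expression(same, c("a", "b", "c", "c")), "2 levels")
})

test_that("a single null simulation keeps the false-positive rate at its binomial band", {
  sim <- simulate_mouse_counts(mouse_design(5, 2000), planted_effects(),
                               seed = 21)
  deg <- hyperoxia_contrasts(cpm_normalize(sim$counts), sim$metadata)[["F_KO"]]
  expect_lt(abs(mean(deg$p_value < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
  expect_lte(sum(deg$q_value < 0.05), 3)
})

test_that("signature thresholds are inclusive and monotone", {
  deg <- tibble::tibble(
    gene = c("in_up", "weak_fold", "weak_q", "in_down"),
    log2_fc = c(0.7, 0.5, 3, -0.7),
    p_value = c(0.001, 0.001, 0.02, 0.001),
    q_value = c(0.04, 0.04, 0.06, 0.04))
  sig <- extract_signature(deg, fdr_max = 0.05, min_fold = 1.5)
  expect_setequal(sig$up, "in_up")        # fold 1.62 passes, 1.41 does not
  expect_setequal(sig$down, "in_down")
  expect_equal(sig$provenance$fdr_max, 0.05)
  expect_error(extract_signature(deg, min_fold = 1), "min_fold")

  # relaxing either threshold never removes a gene
  for (s in 1:5) {
    rd <- withr::with_seed(s, tibble::tibble(
      gene = sprintf("g%03d", 1:200), log2_fc = rnorm(200, sd = 1.5),
      p_value = runif(200), q_value = bh_adjust(runif(200))))
    tight <- extract_signature(rd, 0.05, 2)
    loose_q <- extract_signature(rd, 0.2, 2)
    loose_f <- extract_signature(rd, 0.05, 1.2)
    expect_true(all(tight$up %in% loose_q$up) && all(tight$up %in% loose_f$up))
    expect_true(all(tight$down %in% loose_q$down) &&
                  all(tight$down %in% loose_f$down))
  }
})

test_that("signature overlaps agree with a brute-force set oracle", {
  a <- gene_signature("A", up = c("g1", "g2"), down = "g9")
  b <- gene_signature("B", up = c("g2", "g3"), down = "g1")
  tab <- signature_overlaps(list(a, b))
  expect_equal(tab$n_genes[tab$signatures == "A & B" & tab$direction == "up"], 1)
  expect_equal(tab$n_genes[tab$signatures == "A & B" &
                             tab$direction == "opposite"], 1)  # g1 up-in-A, down-in-B
  expect_error(signature_overlaps(list(a, a)), "duplicate")

  genes <- sprintf("g%02d", 1:50)
  sigs <- lapply(1:4, function(i) rand_signature(genes, 8, 8, seed = i,
                                                 name = paste0("S", i)))
  tab <- signature_overlaps(sigs)
  oracle <- overlap_oracle(sigs)
  for (nm in names(oracle)) {
    expect_equal(tab$n_genes[tab$signatures == nm & tab$direction == "up"],
                 oracle[[nm]]$up)
    expect_equal(tab$n_genes[tab$signatures == nm & tab$direction == "down"],
                 oracle[[nm]]$down)
  }
  # opposite counts against direct set arithmetic
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    nm <- paste(paste0("S", i), paste0("S", j), sep = " & ")
    expect_equal(tab$n_genes[tab$signatures == nm & tab$direction == "opposite"],
                 length(intersect(sigs[[i]]$up, sigs[[j]]$down)))
  }
})

test_that("external DEG tables import with header mapping and validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(Symbol = c("a", "b", "c"),
                                  logFC = c(1, -2, 0.2),
                                  PValue = c(0.001, 0.01, 0.6),
                                  FDR = c(0.01, 0.05, 0.7)), f)
  deg <- import_deg_table(f)
  expect_equal(nrow(deg), 3)
  expect_equal(deg$q_value, c(0.01, 0.05, 0.7))
  deg2 <- import_deg_table(f, recompute_q = TRUE)
  expect_equal(deg2$q_value, bh_adjust(c(0.001, 0.01, 0.6)))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "a", log2_fc = 1, p_value = 1.5), f2)
  expect_error(import_deg_table(f2), "\\[0, 1\\]")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "a", p_value = 0.5), f3)
  expect_error(import_deg_table(f3), "log2_fc")
})
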