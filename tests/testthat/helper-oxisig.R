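# shared fixtures and independent oracles, built in code

rand_expr <- function(n_genes, n_samples, seed, prefix = "Gene") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2), n_genes)
    rownames(m) <- sprintf("%s%04d", prefix, seq_len(n_genes))
    colnames(m) <- sprintf("s%03d", seq_len(n_samples))
    oxisig:::expr_tbl(m)
  })
}

rand_signature <- function(genes, n_up, n_down, seed, name = "sig") {
  withr::with_seed(seed, {
    pick <- sample(genes, n_up + n_down)
    gene_signature(name, up = pick[seq_len(n_up)],
                   down = pick[n_up + seq_len(n_down)])
  })
}

# naive per-gene-loop summed z-score, independent of the vectorized path
score_oracle <- function(expr, sigs) {
  df <- as.data.frame(expr)
  genes <- df$gene
  vals <- as.matrix(df[-1])
  z <- matrix(0, nrow(vals), ncol(vals))
  for (g in seq_len(nrow(vals))) {
    x <- vals[g, ]
    s <- sd(x)
    if (s > 0) z[g, ] <- (x - mean(x)) / s
  }
  out <- matrix(0, length(sigs), ncol(vals),
                dimnames = list(vapply(sigs, `[[`, "", "name"), colnames(vals)))
  for (k in seq_along(sigs)) {
    for (s in seq_len(ncol(vals))) {
      tot <- 0
      for (g in sigs[[k]]$up) {
        i <- match(g, genes)
        if (!is.na(i)) tot <- tot + z[i, s]
      }
      for (g in sigs[[k]]$down) {
        i <- match(g, genes)
        if (!is.na(i)) tot <- tot - z[i, s]
      }
      out[k, s] <- tot
    }
  }
  out
}

# step-through running-sum oracle for the weighted KS enrichment score
es_oracle <- function(scores, hit, weight = 1) {
  n <- length(scores)
  k <- sum(hit)
  w <- abs(scores)^weight
  W <- sum(w[hit])
  rs <- 0
  best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) {
      if (W > 0) w[i] / W else 1 / k
    } else {
      -1 / (n - k)
    }
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# brute-force set-operation oracle for signature overlaps
overlap_oracle <- function(sigs) {
  nm <- vapply(sigs, `[[`, "", "name")
  res <- list()
  for (k in 2:length(sigs)) {
    for (idx in utils::combn(length(sigs), k, simplify = FALSE)) {
      up <- sigs[[idx[1]]]$up
      down <- sigs[[idx[1]]]$down
      for (j in idx[-1]) {
        up <- up[up %in% sigs[[j]]$up]
        down <- down[down %in% sigs[[j]]$down]
      }
      res[[paste(nm[idx], collapse = " & ")]] <- list(up = length(up),
                                                      down = length(down))
    }
  }
  res
}

jaccard <- function(a, b) {
  if (!length(union(a, b))) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
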