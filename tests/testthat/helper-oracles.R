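# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (series expansion, exhaustive enumeration, direct linear
# solve) kept free of the package code paths it checks.

# Matrix exponential by 40-term Taylor series with scaling and squaring.
expm_taylor <- function(M, terms = 40) {
  s <- max(0, ceiling(log2(max(1, norm(M, "1")))))
  Ms <- M / 2^s
  acc <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(terms)) {
    term <- term %*% Ms / k
    acc <- acc + term
  }
  if (s > 0) for (i in seq_len(s)) acc <- acc %*% acc
  acc
}

# exp(beta * (A - D)) straight from the definition.
kernel_oracle <- function(A, beta) {
  expm_taylor(beta * (A - diag(rowSums(A))))
}

# All-pairs shortest hop counts by Floyd-Warshall.
floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# Direct linear solve of the RWR steady state, with the same self-loop
# handling for zero-degree columns.
rwr_oracle <- function(A, seed_idx, restart) {
  cs <- colSums(A)
  zero <- cs == 0
  if (any(zero)) {
    diag(A)[zero] <- 1
    cs[zero] <- 1
  }
  W <- sweep(A, 2, cs, "/")
  n <- nrow(A)
  p0 <- numeric(n)
  p0[seed_idx] <- 1 / length(seed_idx)
  as.vector(restart * solve(diag(n) - (1 - restart) * W, p0))
}

# Importance by brute-force pair counting over the kernel.
importance_oracle <- function(K) {
  n <- length(K$node_order)
  comp <- K$component_labels
  pairs <- which(upper.tri(K$K) & outer(comp, comp, "=="), arr.ind = TRUE)
  P <- nrow(pairs)
  I <- matrix(1, n, n, dimnames = dimnames(K$K))
  if (P > 0) {
    vals <- signif(K$K[pairs], 12)           # same tie tolerance as the package
    for (t in seq_len(P)) {
      cg <- sum(vals > vals[t])
      I[pairs[t, 1], pairs[t, 2]] <- (cg + 1) / (P + 1)
      I[pairs[t, 2], pairs[t, 1]] <- (cg + 1) / (P + 1)
    }
    diag(I) <- 1 / (P + 1)
  }
  I
}

# DIR score by explicit nested loops over disease genes and networks.
dir_oracle <- function(g, fam_genes, imps, mode = "linear") {
  num <- 0
  den <- 0
  for (d in fam_genes) {
    ivals <- vapply(imps, function(im) {
      if (g %in% im$node_order && d %in% im$node_order) {
        im$I[g, d]
      } else 1
    }, numeric(1))
    evs <- if (mode == "linear") 1 - ivals else -log10(ivals)
    num <- num + max(evs)
    if (min(ivals) < 1) den <- den + 1
  }
  num / (1 + den)
}

# Meta score by explicit pair enumeration.
q_oracle <- function(fam_genes, imps, mode = "linear") {
  total <- 0
  n_pairs <- 0
  for (i in seq_along(fam_genes)) {
    for (j in seq_along(fam_genes)) {
      if (i >= j) next
      n_pairs <- n_pairs + 1
      ivals <- vapply(imps, function(im) {
        a <- fam_genes[i]; b <- fam_genes[j]
        if (a %in% im$node_order && b %in% im$node_order) im$I[a, b] else 1
      }, numeric(1))
      evs <- if (mode == "linear") 1 - ivals else -log10(ivals)
      total <- total + max(evs)
    }
  }
  total / (1 + n_pairs)
}

# Informativeness by mean-then-log over enumerated pairs.
inf_oracle <- function(imp, fam_genes) {
  vals <- c()
  for (i in seq_along(fam_genes)) {
    for (j in seq_along(fam_genes)) {
      if (i >= j) next
      a <- fam_genes[i]; b <- fam_genes[j]
      vals <- c(vals, if (a %in% imp$node_order && b %in% imp$node_order) {
        imp$I[a, b]
      } else 1)
    }
  }
  -log10(max(mean(vals), 1e-300))
}

# Erdos-Renyi style random gene network (optionally weighted).
random_network <- function(n, p, weighted = FALSE, prefix = "g", name = "rand") {
  genes <- sprintf("%s%03d", prefix, seq_len(n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(ut)) < p
  if (!any(keep)) keep[sample(nrow(ut), 1)] <- TRUE
  w <- if (weighted) stats::runif(sum(keep), 0.1, 1) else 1
  gene_network(data.frame(from = genes[ut[keep, 1]], to = genes[ut[keep, 2]],
                          weight = w, stringsAsFactors = FALSE),
               name = name, nodes = genes)
}

# Wrap a hand-built importance matrix in the class the package expects.
make_importance <- function(I, name = "net", components = NULL) {
  node_order <- rownames(I)
  structure(list(node_order = node_order, I = I, network_name = name,
                 n_connected_pairs = sum(I[upper.tri(I)] < 1),
                 component_labels = components),
            class = "importance_matrix")
}
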