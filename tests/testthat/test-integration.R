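# Importance transform, evidence, DIR score, meta score Q and
# informativeness.

test_that("a single connected pair gets importance 1/2", {
  net <- gene_network(data.frame(from = "a", to = "b"))
  imp <- importance_transform(diffusion_kernel(adjacency(net), beta = 0.1))
  expect_equal(unname(imp$I["a", "b"]), 0.5)
  expect_equal(imp$n_connected_pairs, 1)
})

test_that("the path graph splits importance by kernel-similarity ties", {
  net <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c")))
  K <- diffusion_kernel(adjacency(net), beta = 0.1)
  imp <- importance_transform(K)
  # (a,b) and (b,c) tie as most similar -> I = 1/4; (a,c) -> 3/4
  expect_equal(unname(imp$I["a", "b"]), 0.25)
  expect_equal(unname(imp$I["b", "c"]), 0.25)
  expect_equal(unname(imp$I["a", "c"]), 0.75)
  expect_equal(imp$I, importance_oracle(K))
})

test_that("cross-component and absent pairs have importance exactly 1", {
  net <- gene_network(data.frame(from = c("a", "c"), to = c("b", "d")))
  imp <- importance_transform(diffusion_kernel(adjacency(net), beta = 0.1))
  expect_identical(unname(imp$I["a", "c"]), 1)
  expect_identical(unname(imp$I["b", "d"]), 1)
  expect_lt(imp$I["a", "b"], 1)
  lk <- dirank:::importance_lookup(imp, c("a", "ghost"), c("b", "ghost"))
  expect_identical(unname(lk["ghost", "b"]), 1)
  expect_identical(unname(lk["ghost", "ghost"]), 1)
})

test_that("importance equals brute-force pair counting on random graphs", {
  set.seed(17)
  for (i in 1:6) {
    net <- random_network(sample(6:15, 1), 0.25, weighted = i %% 2 == 0)
    K <- diffusion_kernel(adjacency(net), beta = 0.1)
    imp <- importance_transform(K)
    expect_equal(imp$I, importance_oracle(K), tolerance = 1e-14)
  }
})

test_that("importance is a monotone step function of the kernel", {
  set.seed(19)
  net <- random_network(12, 0.4)
  K <- diffusion_kernel(adjacency(net), beta = 0.1)
  imp <- importance_transform(K)
  comp <- K$component_labels
  ut <- which(upper.tri(K$K) & outer(comp, comp, "=="), arr.ind = TRUE)
  kv <- signif(K$K[ut], 12)                  # the transform's tie resolution
  iv <- imp$I[ut]
  for (s in seq_along(kv)) {
    expect_true(all(iv[kv > kv[s]] < iv[s]))
    expect_true(all(iv[kv == kv[s]] == iv[s]))
  }
  expect_true(all(iv < 1))
  expect_true(all(iv > 0))
})

test_that("importance depends only on kernel ranks, not values", {
  set.seed(43)
  net <- gene_network(random_network(10, 0.5)$edges)  # connected w.h.p.
  K <- diffusion_kernel(adjacency(net), beta = 0.1)
  imp1 <- importance_transform(K)
  # add a constant to every connected-pair similarity; ranks survive
  shift <- K
  same <- outer(K$component_labels, K$component_labels, "==")
  shift$K[same] <- shift$K[same] + 5
  imp2 <- importance_transform(shift)
  expect_equal(imp1$I, imp2$I)
})

test_that("an edgeless network yields all-1 importance with a warning", {
  net <- gene_network(data.frame(), nodes = c("a", "b"))
  K <- diffusion_kernel(adjacency(net), beta = 0.1)
  imp <- expect_warning(importance_transform(K), "no connected pairs")
  expect_true(all(imp$I == 1))
})

test_that("evidence maps importance to non-negative support in both modes", {
  expect_equal(evidence(1), 0)
  expect_equal(evidence(0.2), 0.8)
  expect_equal(evidence(1, mode = "log"), 0)
  expect_equal(evidence(0.01, mode = "log"), 2.0)
  expect_error(evidence(0), "0, 1")
  expect_error(evidence(1.2), "0, 1")
})

test_that("DIR score follows its definition on hand-built importances", {
  genes <- c("g", "d")
  I1 <- matrix(c(0.1, 0.2, 0.2, 0.1), 2, 2, dimnames = list(genes, genes))
  I2 <- matrix(1, 2, 2, dimnames = list(genes, genes))
  imps <- list(make_importance(I1, "n1"), make_importance(I2, "n2"))
  res <- dir_score("g", "d", imps)
  # numerator max(0.8, 0) = 0.8; denominator 1 + 1
  expect_equal(res$dir_score, 0.4)
  expect_equal(res$contributing_count, 1L)
  expect_equal(res$per_disease_gene$best_network, "n1")
})

test_that("a candidate unconnected to every disease gene scores zero", {
  genes <- c("g", "d1", "d2")
  I <- matrix(1, 3, 3, dimnames = list(genes, genes))
  imps <- list(make_importance(I, "n1"))
  expect_equal(dir_score("g", c("d1", "d2"), imps)$dir_score, 0)
})

test_that("DIR and Q match nested-loop oracles on random importances", {
  set.seed(23)
  genes <- sprintf("g%02d", 1:12)
  fam <- genes[1:3]
  cands <- genes[4:12]
  rand_imp <- function(nm, subset) {
    g <- sample(genes, subset)
    I <- matrix(runif(subset^2, 0.01, 1), subset, subset,
                dimnames = list(g, g))
    I[upper.tri(I)] <- t(I)[upper.tri(I)]
    diag(I) <- 0.01
    make_importance(I, nm)
  }
  for (mode in c("linear", "log")) {
    for (rep in 1:5) {
      imps <- list(rand_imp("n1", 10), rand_imp("n2", 8), rand_imp("n3", 12))
      for (g in cands) {
        expect_equal(dir_score(g, fam, imps, evidence_mode = mode)$dir_score,
                     dir_oracle(g, fam, imps, mode), tolerance = 1e-12)
      }
      q <- meta_score(fam, imps, evidence_mode = mode)
      expect_equal(q$q, q_oracle(fam, imps, mode), tolerance = 1e-12)
      expect_equal(q$n_pairs, choose(3, 2))
    }
  }
})

test_that("meta score matches the two-gene closed form and the unconnected limit", {
  genes <- c("d1", "d2")
  I <- matrix(c(0.1, 0.1, 0.1, 0.1), 2, 2, dimnames = list(genes, genes))
  imps <- list(make_importance(I, "n1"))
  expect_equal(meta_score(c("d1", "d2"), imps)$q, 0.9 / 2)
  I1 <- matrix(1, 2, 2, dimnames = list(genes, genes))
  expect_equal(meta_score(c("d1", "d2"), list(make_importance(I1, "n1")))$q, 0)
  expect_error(meta_score("d1", imps), "at least 2")
})

test_that("informativeness is -log10 of the mean pairwise importance", {
  genes <- c("d1", "d2", "d3")
  I <- matrix(0.01, 3, 3, dimnames = list(genes, genes))
  imp <- make_importance(I, "n1")
  expect_equal(informativeness(imp, genes), 2.0)
  # fully unconnected family: mean importance 1 -> informativeness 0
  expect_equal(informativeness(make_importance(
    matrix(1, 3, 3, dimnames = list(genes, genes)), "n1"), genes), 0)
  set.seed(29)
  net <- random_network(15, 0.3)
  imp2 <- importance_transform(diffusion_kernel(adjacency(net), beta = 0.1))
  fam <- sample(imp2$node_order, 5)
  expect_equal(informativeness(imp2, fam), inf_oracle(imp2, fam),
               tolerance = 1e-12)
})

test_that("appending an all-uninformative network changes nothing", {
  set.seed(37)
  net <- random_network(20, 0.2)
  imps <- compute_importances(list(main = net), beta = 0.1)
  blank_genes <- sprintf("g%03d", 1:20)
  blank <- make_importance(matrix(1, 20, 20,
                                  dimnames = list(blank_genes, blank_genes)),
                           "blank")
  fam <- imps$main$node_order[1:4]
  cands <- setdiff(imps$main$node_order, fam)[1:10]
  r1 <- rank_candidates(cands, fam, imps, seed = 5)
  r2 <- rank_candidates(cands, fam, c(imps, list(blank)), seed = 5)
  expect_equal(r1$dir_score, r2$dir_score)
  expect_equal(r1$rank, r2$rank)
  expect_equal(attr(r1, "q"), attr(r2, "q"))
})

test_that("DIR is monotone: decreasing one importance never decreases the score", {
  set.seed(41)
  genes <- c("g", "d1", "d2")
  base <- matrix(runif(9, 0.2, 0.9), 3, 3, dimnames = list(genes, genes))
  base[upper.tri(base)] <- t(base)[upper.tri(base)]
  for (rep in 1:20) {
    imp <- make_importance(base, "n1")
    s0 <- dir_score("g", c("d1", "d2"), list(imp))$dir_score
    lower <- base
    d <- sample(c("d1", "d2"), 1)
    lower["g", d] <- lower[d, "g"] <- base["g", d] * runif(1)
    s1 <- dir_score("g", c("d1", "d2"), list(make_importance(lower, "n1")))$dir_score
    expect_gte(s1, s0 - 1e-12)
  }
})

test_that("DIR is zero exactly when no component is shared in any network", {
  two <- gene_network(data.frame(from = c("a", "c"), to = c("b", "d")))
  imps <- compute_importances(list(n1 = two), beta = 0.1)
  expect_equal(dir_score("a", c("c", "d"), imps)$dir_score, 0)
  bridge <- gene_network(data.frame(from = c("a", "c"), to = c("c", "d")))
  imps2 <- compute_importances(list(n1 = two, n2 = bridge), beta = 0.1)
  expect_gt(dir_score("a", c("c", "d"), imps2)$dir_score, 0)
})

test_that("candidates are ranked descending with mean-rank ties", {
  genes <- c("d", "x", "y", "z")
  I <- matrix(1, 4, 4, dimnames = list(genes, genes))
  I["d", "x"] <- I["x", "d"] <- 0.1
  I["d", "y"] <- I["y", "d"] <- 0.4
  imps <- list(make_importance(I, "n1"))
  ranked <- rank_candidates(c("x", "y", "z"), c("d", "w"), imps,
                            include_q = TRUE)
  cand <- ranked[!ranked$is_q, ]
  expect_equal(cand$gene[order(cand$rank)], c("x", "y", "z"))
  expect_equal(sort(cand$rank), c(1, 2, 3))
  # two present candidates tied at zero share the mean rank
  blank <- make_importance(matrix(1, 4, 4, dimnames = list(genes, genes)), "n1")
  tied <- rank_candidates(c("x", "y"), c("d", "w"), list(blank),
                          include_q = FALSE)
  expect_equal(tied$rank, c(1.5, 1.5))
})

test_that("genes absent from all networks receive uniform random ranks", {
  genes <- c("d1", "d2", sprintf("c%03d", 1:100))
  set.seed(47)
  I <- matrix(runif(102^2, 0.01, 0.99), 102, 102,
              dimnames = list(genes, genes))
  I[upper.tri(I)] <- t(I)[upper.tri(I)]
  diag(I) <- 0.01
  imps <- list(make_importance(I, "n1"))
  cands <- c(sprintf("c%03d", 1:100), "missing")
  r1 <- rank_candidates(cands, c("d1", "d2"), imps, seed = 123)
  r2 <- rank_candidates(cands, c("d1", "d2"), imps, seed = 123)
  expect_identical(r1, r2)                   # seeded-reproducible
  draws <- vapply(1:4000, function(s) {
    r <- rank_candidates(cands, c("d1", "d2"), imps, include_q = FALSE,
                         seed = s)
    r$rank[r$gene == "missing"]
  }, numeric(1))
  expect_true(all(draws %in% 1:101))
  chi <- suppressWarnings(chisq.test(tabulate(draws, 101)))
  expect_gt(chi$p.value, 0.001)
})

test_that("the Q pseudo-row is placed by strict score comparison", {
  genes <- c("d1", "d2", "x", "y")
  I <- matrix(1, 4, 4, dimnames = list(genes, genes))
  I["d1", "d2"] <- I["d2", "d1"] <- 0.5      # Q = 0.5/2 = 0.25
  I["x", "d1"] <- I["d1", "x"] <- 0.05       # x: 0.95/2 = 0.475 > Q
  I["y", "d1"] <- I["d1", "y"] <- 0.9        # y: 0.1/2 = 0.05 < Q
  imps <- list(make_importance(I, "n1"))
  ranked <- rank_candidates(c("x", "y"), c("d1", "d2"), imps)
  expect_equal(attr(ranked, "q"), 0.25)
  expect_equal(attr(ranked, "q_rank"), 2)    # one candidate above Q
  expect_true("Q" %in% ranked$gene)
})
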