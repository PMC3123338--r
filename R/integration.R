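# Cross-network integration: the percentile "importance" transform makes
# diffusion-kernel similarities comparable across heterogeneous networks;
# the DIR score combines, per disease gene, the best evidence over all
# networks; the meta score Q turns the within-family evidence into an
# adaptive declaration threshold; informativeness flags families for which
# a network carries usable signal.

#' Importance (percentile) transform of a diffusion kernel
#'
#' For a pair of genes connected in the network (sharing a component), the
#' importance is one minus the percentile of their kernel similarity among
#' all connected (same-component, unordered) pairs:
#' \code{I = (c + 1) / (P + 1)} where \code{c} counts connected pairs with
#' strictly greater kernel similarity and \code{P} is the total number of
#' connected pairs. Ties share \code{c} (similarities are compared at 12
#' significant digits, so ties forced by graph symmetry are not broken by
#' floating-point noise). Pairs in different components have importance
#' exactly 1. Smaller importance means a stronger relationship, and values
#' are comparable across networks.
#'
#' The +1 smoothing keeps the strongest pair strictly above 0 (so
#' log-evidence stays finite) and every connected pair strictly below 1.
#'
#' @param K a \code{\link{kernel_matrix}}.
#' @param network_name label carried to downstream score breakdowns;
#'   defaults to the kernel's source name.
#' @return object of class \code{importance_matrix}: list with
#'   \code{node_order}, symmetric matrix \code{I} in (0, 1],
#'   \code{network_name}, \code{n_connected_pairs} and
#'   \code{component_labels}. The diagonal is set to the smallest attainable
#'   value \code{1/(P+1)} but is never used in scoring.
#' @export
importance_transform <- function(K, network_name = NULL) {
  stopifnot(inherits(K, "kernel_matrix"))
  if (is.null(network_name)) network_name <- if (!is.null(K$name)) K$name else "network"
  n <- length(K$node_order)
  comp <- K$component_labels
  I <- matrix(1, n, n, dimnames = dimnames(K$K))
  same <- outer(comp, comp, "==")
  ut <- upper.tri(I) & same
  vals <- K$K[ut]
  P <- length(vals)
  if (P == 0) {
    warning("network has no connected pairs; all importance values are 1")
    if (n > 0) diag(I) <- 1
  } else {
    # compare similarities at 12 significant digits so that ties forced by
    # graph symmetry survive floating-point noise in the eigendecomposition
    vals <- signif(vals, 12)
    c_greater <- rank(-vals, ties.method = "min") - 1
    I[ut] <- (c_greater + 1) / (P + 1)
    I[lower.tri(I)] <- t(I)[lower.tri(I)]
    diag(I) <- 1 / (P + 1)
  }
  structure(list(node_order = K$node_order, I = I,
                 network_name = network_name, n_connected_pairs = P,
                 component_labels = comp),
            class = "importance_matrix")
}

#' Evidence carried by an importance value
#'
#' Maps importance (small = strong relationship) to evidence (large =
#' strong). The default linear transform is \code{1 - I}, bounded in
#' [0, 1); the log transform \code{-log10(I)} emphasizes very significant
#' pairs (an importance of 0.01 carries evidence 2). Both give evidence 0
#' to unconnected pairs (\code{I = 1}).
#'
#' @param i_value importance values in (0, 1].
#' @param mode \code{"linear"} (default) or \code{"log"}.
#' @return non-negative evidence values, same shape as \code{i_value}.
#' @export
evidence <- function(i_value, mode = c("linear", "log")) {
  mode <- match.arg(mode)
  if (any(is.na(i_value)) || any(i_value <= 0) || any(i_value > 1)) {
    stop("importance values must lie in (0, 1]")
  }
  if (mode == "linear") 1 - i_value else -log10(i_value)
}

# Importance values for all pairs (a x b) from one network; genes absent
# from the network contribute importance 1 (no evidence).
importance_lookup <- function(imp, genes_a, genes_b) {
  out <- matrix(1, length(genes_a), length(genes_b),
                dimnames = list(genes_a, genes_b))
  ia <- match(genes_a, imp$node_order)
  ib <- match(genes_b, imp$node_order)
  ok_a <- which(!is.na(ia))
  ok_b <- which(!is.na(ib))
  if (length(ok_a) && length(ok_b)) {
    out[ok_a, ok_b] <- imp$I[ia[ok_a], ib[ok_b], drop = FALSE]
  }
  out
}

# Vectorized DIR machinery shared by dir_score() and rank_candidates().
# Returns per-candidate score, contributing count and, per (candidate,
# disease gene), the best network, importance and evidence.
dir_score_table <- function(candidates, fam_genes, importances,
                            evidence_mode = "linear") {
  n_c <- length(candidates)
  n_d <- length(fam_genes)
  best_ev <- matrix(0, n_c, n_d)
  min_i <- matrix(1, n_c, n_d)
  best_net <- matrix(NA_character_, n_c, n_d)
  for (imp in importances) {
    I <- importance_lookup(imp, candidates, fam_genes)
    ev <- evidence(I, mode = evidence_mode)
    upd <- ev > best_ev
    best_net[upd] <- imp$network_name
    best_ev[upd] <- ev[upd]
    min_i <- pmin(min_i, I)
  }
  contributing <- rowSums(min_i < 1)
  score <- rowSums(best_ev) / (1 + contributing)
  list(score = as.numeric(score), contributing = as.integer(contributing),
       best_ev = best_ev, best_net = best_net, min_i = min_i)
}

#' DIR score of a candidate gene against a disease family
#'
#' The data integration rank score sums, over the family's disease genes,
#' the best evidence across networks for the pair (candidate, disease
#' gene), and divides by one plus the number of disease genes actually
#' providing information (those sharing a component with the candidate in
#' at least one network):
#' \deqn{DIR(g, F) = \frac{\sum_{d \in D} \max_n ev(I_n(g, d))}
#'                        {1 + |\{d : \min_n I_n(g, d) < 1\}|}}
#' Taking the max lets each disease gene use its most informative network,
#' so incomplete sources do not dilute the score; the +1 stabilizes scores
#' supported by few disease genes.
#'
#' @param g candidate gene identifier (must not be in the family).
#' @param family a \code{\link{disease_family}} or character vector of
#'   disease genes (the caller removes any held-out gene first).
#' @param importances list of \code{\link{importance_matrix}} objects, one
#'   per network; family genes absent from a network contribute importance
#'   1 there.
#' @param evidence_mode passed to \code{\link{evidence}}.
#' @return object of class \code{dir_result}: list with \code{gene},
#'   \code{dir_score}, \code{contributing_count} and a
#'   \code{per_disease_gene} data frame (disease_gene, best_network,
#'   evidence, min_importance).
#' @export
dir_score <- function(g, family, importances, evidence_mode = "linear") {
  fam_genes <- if (inherits(family, "disease_family")) family$genes else as.character(family)
  if (length(fam_genes) == 0) stop("empty disease family")
  if (g %in% fam_genes) stop("candidate gene is a member of the family; remove it first")
  tab <- dir_score_table(g, fam_genes, importances, evidence_mode)
  breakdown <- data.frame(disease_gene = fam_genes,
                          best_network = as.character(tab$best_net[1, ]),
                          evidence = as.numeric(tab$best_ev[1, ]),
                          min_importance = as.numeric(tab$min_i[1, ]),
                          stringsAsFactors = FALSE)
  structure(list(gene = g, dir_score = tab$score[1],
                 contributing_count = tab$contributing[1],
                 per_disease_gene = breakdown),
            class = "dir_result")
}

#' @export
print.dir_result <- function(x, ...) {
  cat(sprintf("DIR(%s) = %.6g (%d contributing disease gene(s))\n",
              x$gene, x$dir_score, x$contributing_count))
  invisible(x)
}

#' Meta score Q of a disease family
#'
#' Measures how close the family's known disease genes are to one another
#' across all networks, using the identical evidence transform as
#' \code{\link{dir_score}} so that Q is rank-comparable with DIR scores:
#' \deqn{Q_F = \frac{\sum_{i<j} \max_n ev(I_n(d_i, d_j))}{1 + \binom{|D|}{2}}}
#' A candidate scoring above Q is closer to the disease genes than they are
#' to each other on average, which motivates the adaptive Q+1 declaration
#' rule.
#'
#' @param family a \code{\link{disease_family}} or character vector with at
#'   least 2 genes.
#' @param importances list of \code{\link{importance_matrix}} objects.
#' @param evidence_mode passed to \code{\link{evidence}}.
#' @return object of class \code{meta_score}: list with \code{family_id},
#'   \code{q} and \code{n_pairs} = C(|D|, 2).
#' @export
meta_score <- function(family, importances, evidence_mode = "linear") {
  fam_genes <- if (inherits(family, "disease_family")) family$genes else as.character(family)
  fid <- if (inherits(family, "disease_family")) family$family_id else "family"
  if (length(fam_genes) < 2) stop("meta score needs at least 2 disease genes")
  pairs <- utils::combn(fam_genes, 2)
  n_pairs <- ncol(pairs)
  best_ev <- numeric(n_pairs)
  for (imp in importances) {
    I <- importance_lookup(imp, fam_genes, fam_genes)
    iv <- I[cbind(match(pairs[1, ], fam_genes), match(pairs[2, ], fam_genes))]
    best_ev <- pmax(best_ev, evidence(iv, mode = evidence_mode))
  }
  structure(list(family_id = fid, q = sum(best_ev) / (1 + n_pairs),
                 n_pairs = n_pairs),
            class = "meta_score")
}

#' Informativeness of a network for a disease family
#'
#' The negative log10 of the mean pairwise importance among the family's
#' disease genes in one network:
#' \deqn{Inf_n(F) = -\log_{10}\left(\frac{\sum_{i<j} I_n(d_i, d_j)}
#'                                      {\binom{|D|}{2}}\right)}
#' A family whose genes are mutually unconnected has mean importance 1 and
#' informativeness 0; informativeness above 2 (mean importance 0.01 or
#' lower) marks a family for which the network carries strong signal.
#' Family genes absent from the network contribute importance 1.
#'
#' @param importance an \code{\link{importance_matrix}}.
#' @param family a \code{\link{disease_family}} or character vector with at
#'   least 2 genes.
#' @return a single non-negative number (the mean is clamped below at
#'   1e-300 before taking the log).
#' @export
informativeness <- function(importance, family) {
  fam_genes <- if (inherits(family, "disease_family")) family$genes else as.character(family)
  if (length(fam_genes) < 2) stop("informativeness needs at least 2 disease genes")
  I <- importance_lookup(importance, fam_genes, fam_genes)
  vals <- I[upper.tri(I)]
  -log10(max(mean(vals), 1e-300))
}

#' Informativeness table over families and networks
#'
#' @param importances named list of \code{\link{importance_matrix}} objects.
#' @param families list of \code{\link{disease_family}} objects.
#' @return data frame (family_id, network, inf), one row per combination.
#' @export
informativeness_table <- function(importances, families) {
  if (is.null(names(importances)) || any(!nzchar(names(importances)))) {
    names(importances) <- vapply(importances, `[[`, character(1), "network_name")
  }
  rows <- expand.grid(family_id = vapply(families, `[[`, character(1), "family_id"),
                      network = names(importances),
                      stringsAsFactors = FALSE)
  rows$inf <- mapply(function(fid, net) {
    fam <- families[[which(vapply(families, `[[`, character(1), "family_id") == fid)]]
    informativeness(importances[[net]], fam)
  }, rows$family_id, rows$network)
  rows
}

# Assign 1..n rank positions: present genes take the remaining positions in
# score order (desc or asc, ties broken by gene id for determinism), absent
# genes take uniformly random positions. Present tie groups then share the
# mean of their positions. Consumes the current RNG stream.
assign_ranks <- function(genes, score, absent, decreasing = TRUE) {
  n <- length(genes)
  pos <- numeric(n)
  abs_idx <- which(absent)
  rand_pos <- if (length(abs_idx)) sample.int(n, length(abs_idx)) else integer(0)
  pres_idx <- which(!absent)
  if (length(pres_idx)) {
    s <- score[pres_idx]
    o <- pres_idx[order(if (decreasing) -s else s, genes[pres_idx])]
    pos[o] <- setdiff(seq_len(n), rand_pos)
  }
  pos[abs_idx] <- rand_pos
  rank <- pos
  if (length(pres_idx)) {
    grp <- split(pres_idx, score[pres_idx])
    for (g in grp) {
      if (length(g) > 1) rank[g] <- mean(pos[g])
    }
  }
  list(rank = rank, position = pos)
}

#' Rank candidate genes by DIR score
#'
#' Candidates are ranked by descending DIR score; score ties share the mean
#' rank of their tie group. A candidate absent from every network carries
#' no information and is assigned a uniformly random rank among the
#' candidate positions (seeded), mirroring how cross-validation treats
#' disease genes missing from all data sources. When \code{include_q} is
#' TRUE a pseudo-row \code{"Q"} carrying the family's meta score is ranked
#' alongside: its candidate-relative rank is one plus the number of
#' candidates with DIR score strictly greater than Q.
#'
#' @param candidates character vector of genes, disjoint from the family.
#' @param family a \code{\link{disease_family}} (>= 2 genes when
#'   \code{include_q}).
#' @param importances list of \code{\link{importance_matrix}} objects.
#' @param include_q add the Q pseudo-row (default TRUE).
#' @param evidence_mode passed to \code{\link{evidence}}.
#' @param seed optional integer seed for the random ranks of genes absent
#'   from all networks; \code{NULL} uses (and advances) the current RNG
#'   stream.
#' @return data frame (gene, dir_score, rank, position, contributing_count,
#'   assigned_randomly, is_q), sorted by position; Q's row has
#'   \code{is_q = TRUE} and \code{rank}/\code{position} equal to its
#'   candidate-relative rank.
#' @export
rank_candidates <- function(candidates, family, importances,
                            include_q = TRUE, evidence_mode = "linear",
                            seed = NULL) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0) stop("empty candidate list")
  if (anyDuplicated(candidates)) stop("duplicate candidate genes")
  fam_genes <- if (inherits(family, "disease_family")) family$genes else as.character(family)
  if (any(candidates %in% fam_genes)) {
    stop("candidates must be disjoint from the family's disease genes")
  }
  all_nodes <- unique(unlist(lapply(importances, `[[`, "node_order")))
  absent <- !(candidates %in% all_nodes)
  tab <- dir_score_table(candidates, fam_genes, importances, evidence_mode)
  score <- tab$score
  score[absent] <- NA_real_
  rk <- with_seed(seed, assign_ranks(candidates, ifelse(absent, 0, score),
                                     absent, decreasing = TRUE))
  out <- data.frame(gene = candidates,
                    dir_score = score,
                    rank = rk$rank,
                    position = rk$position,
                    contributing_count = tab$contributing,
                    assigned_randomly = absent,
                    is_q = FALSE,
                    stringsAsFactors = FALSE)
  if (include_q) {
    q <- meta_score(family, importances, evidence_mode)$q
    q_rank <- 1 + sum(!is.na(score) & score > q)
    out <- rbind(out, data.frame(gene = "Q", dir_score = q, rank = q_rank,
                                 position = q_rank, contributing_count = NA_integer_,
                                 assigned_randomly = FALSE, is_q = TRUE,
                                 stringsAsFactors = FALSE))
    attr(out, "q") <- q
    attr(out, "q_rank") <- q_rank
  }
  out <- out[order(out$is_q, out$position), ]
  rownames(out) <- NULL
  out
}
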