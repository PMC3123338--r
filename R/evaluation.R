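# Leave-one-out cross-validation harness: control-set construction,
# ranking of each held-out disease gene, ROC/AUC and enrichment summaries,
# adaptive declaration criteria (Top-k, Q+1, Q+1OR10) with TPR/FPR, and a
# degree-preserving rewiring null model.

#' Nearest-neighbor control set for a gene
#'
#' Returns the \code{k} genes located nearest to the target gene on the
#' same chromosome by \code{|start - start_target|}, excluding the target
#' itself and any genes in \code{exclude} (typically the rest of the
#' disease family, so that known positives never enter the control set).
#' Distance ties break by gene id. If fewer than \code{k} genes are
#' available the full set is returned with a warning.
#'
#' @param gene target gene (must be present in \code{positions}).
#' @param positions a \code{\link{gene_positions}} table.
#' @param k number of controls; default 100.
#' @param exclude genes to exclude.
#' @return character vector of control genes.
#' @export
nearest_control_set <- function(gene, positions, k = 100, exclude = character(0)) {
  stopifnot(k >= 1)
  i <- match(gene, positions$gene)
  if (is.na(i)) stop("gene '", gene, "' absent from the position table")
  chrom <- positions$chrom[i]
  start0 <- positions$start[i]
  pool <- positions[positions$chrom == chrom &
                    positions$gene != gene &
                    !(positions$gene %in% exclude), , drop = FALSE]
  if (nrow(pool) == 0) {
    warning("no same-chromosome control genes available for '", gene, "'")
    return(character(0))
  }
  d <- abs(pool$start - start0)
  o <- order(d, pool$gene)
  out <- pool$gene[o][seq_len(min(k, nrow(pool)))]
  if (length(out) < k) {
    warning(sprintf("only %d of %d requested controls available for '%s'",
                    length(out), k, gene))
  }
  out
}

#' Selection criteria for declaring disease susceptibility genes
#'
#' \code{top_k(k)} declares the k best-ranked candidates. \code{q_plus_1()}
#' declares every candidate ranked before the family's meta score Q, or the
#' single first-ranked candidate when none is. \code{q_plus_1_or_10()}
#' applies the Q rule only when Q itself ranks in the candidate-relative
#' top 10, and otherwise falls back to the single first-ranked candidate,
#' guarding against weak families with low Q.
#'
#' @param k number of top candidates to declare.
#' @return an object of class \code{selection_criterion}.
#' @export
top_k <- function(k) {
  stopifnot(k >= 1)
  structure(list(kind = "TOP_K", k = as.integer(k),
                 label = paste0("Top-", k)),
            class = "selection_criterion")
}

#' @rdname top_k
#' @export
q_plus_1 <- function() {
  structure(list(kind = "Q_PLUS_1", label = "Q+1"),
            class = "selection_criterion")
}

#' @rdname top_k
#' @export
q_plus_1_or_10 <- function() {
  structure(list(kind = "Q_PLUS_1_OR_10", label = "Q+1OR10"),
            class = "selection_criterion")
}

#' Declare positives from a ranked candidate table
#'
#' @param ranked output of \code{\link{rank_candidates}}; Q criteria
#'   require the Q pseudo-row.
#' @param criterion a \code{\link{top_k}}, \code{\link{q_plus_1}} or
#'   \code{\link{q_plus_1_or_10}} criterion.
#' @return character vector of declared genes (never includes the Q row).
#' @export
select_positives <- function(ranked, criterion) {
  stopifnot(inherits(criterion, "selection_criterion"))
  cand <- ranked[!ranked$is_q, , drop = FALSE]
  cand <- cand[order(cand$position), , drop = FALSE]
  if (criterion$kind == "TOP_K") {
    return(cand$gene[seq_len(min(criterion$k, nrow(cand)))])
  }
  if (!any(ranked$is_q)) {
    stop("criterion '", criterion$label, "' needs the Q pseudo-row; ",
         "call rank_candidates(include_q = TRUE)")
  }
  q_rank <- ranked$rank[ranked$is_q][1]
  if (criterion$kind == "Q_PLUS_1_OR_10" && q_rank > 10) {
    return(cand$gene[1])
  }
  if (q_rank <= 1) cand$gene[1] else cand$gene[seq_len(min(q_rank - 1, nrow(cand)))]
}

#' Leave-one-out cross-validation of gene prioritization
#'
#' For each disease gene of each family, the gene is held out, a control
#' set is constructed, and the held-out gene is ranked among the controls
#' using the chosen method with the reduced family as the known disease
#' genes. Held-out genes absent from every network used by the method get
#' a uniformly random (seeded) rank among the candidate positions.
#'
#' @param families list of \code{\link{disease_family}} objects.
#' @param networks named list of \code{\link{gene_network}} objects (for
#'   DIR, every network; for single-network methods, the network named by
#'   \code{network} or the first one).
#' @param method \code{"DIR"} (multi-network) or a single-network baseline
#'   \code{"RWR"}, \code{"DK"}, \code{"DN"}, \code{"SP"}.
#' @param controls control-set strategy: \code{"nearest"} (the \code{k}
#'   genes closest to the held-out gene on the same chromosome, requires
#'   \code{positions}), \code{"random"} (\code{n_random} genes drawn from
#'   the union of network nodes), or \code{"genomewide"} (all network genes
#'   excluding the family).
#' @param k nearest-control size; default 100.
#' @param n_random random-control size; default 500.
#' @param positions a \code{\link{gene_positions}} table (nearest controls).
#' @param seed integer seed governing every random draw (control sampling
#'   and random ranks).
#' @param beta diffusion parameter used when kernels are computed here.
#' @param evidence_mode passed to \code{\link{evidence}} (DIR only).
#' @param restart RWR restart probability.
#' @param network name of the network used by single-network methods.
#' @param criteria optional list of selection criteria (DIR only); each
#'   LOOCV run then also records which genes the criterion declares.
#' @param importances optional precomputed list of
#'   \code{\link{importance_matrix}} objects (avoids recomputing kernels
#'   across repeated calls); computed from \code{networks} when NULL.
#' @return object of class \code{dirank_cv}: list with \code{records} (data
#'   frame: family_id, held_out_gene, m, rank, assigned_randomly, method)
#'   and \code{declarations} (data frame: run, family_id, held_out_gene,
#'   criterion, gene; NULL without criteria).
#' @export
loocv <- function(families, networks, method = c("DIR", "RWR", "DK", "DN", "SP"),
                  controls = c("nearest", "random", "genomewide"),
                  k = 100, n_random = 500, positions = NULL, seed = 1,
                  beta = 0.1, evidence_mode = "linear", restart = 0.75,
                  network = NULL, criteria = NULL, importances = NULL) {
  method <- match.arg(method)
  controls <- match.arg(controls)
  if (controls == "nearest" && is.null(positions)) {
    stop("nearest controls require a gene position table")
  }
  if (method == "DIR" && is.null(importances)) {
    importances <- compute_importances(networks, beta = beta)
  }
  single_net <- if (method != "DIR") {
    nm <- if (is.null(network)) 1L else network
    networks[[nm]]
  }
  all_nodes <- if (method == "DIR") {
    unique(unlist(lapply(importances, `[[`, "node_order")))
  } else {
    single_net$nodes
  }
  records <- list()
  declarations <- list()
  run <- 0L
  with_seed(seed, {
    for (fam in families) {
      for (d0 in fam$genes) {
        reduced <- setdiff(fam$genes, d0)
        if (length(reduced) < 1) {
          warning("family '", fam$family_id, "' too small after hold-out; skipped")
          next
        }
        ctrl <- switch(controls,
          nearest = nearest_control_set(d0, positions, k = k,
                                        exclude = fam$genes),
          random = sample(setdiff(all_nodes, fam$genes),
                          min(n_random, length(setdiff(all_nodes, fam$genes)))),
          genomewide = setdiff(all_nodes, fam$genes))
        if (length(ctrl) == 0) {
          warning("no controls for gene '", d0, "'; skipped")
          next
        }
        cand <- c(ctrl, d0)
        run <- run + 1L
        if (method == "DIR") {
          want_q <- !is.null(criteria) && length(reduced) >= 2
          ranked <- rank_candidates(cand, reduced, importances,
                                    include_q = want_q,
                                    evidence_mode = evidence_mode,
                                    seed = NULL)
          row <- ranked[ranked$gene == d0 & !ranked$is_q, ]
          r <- row$rank
          rnd <- row$assigned_randomly
          if (want_q) {
            for (cr in criteria) {
              declared <- select_positives(ranked, cr)
              declarations[[length(declarations) + 1L]] <- data.frame(
                run = run, family_id = fam$family_id, held_out_gene = d0,
                criterion = cr$label, gene = declared,
                stringsAsFactors = FALSE)
            }
          }
        } else {
          st <- single_network_scores(method, single_net, reduced, cand,
                                      beta = beta, restart = restart)
          absent <- is.na(st$score)
          rk <- assign_ranks(st$gene, ifelse(absent, 0, st$score), absent,
                             decreasing = attr(st, "direction") == "desc")
          i0 <- match(d0, st$gene)
          r <- rk$rank[i0]
          rnd <- absent[i0]
        }
        records[[run]] <- data.frame(family_id = fam$family_id,
                                     held_out_gene = d0,
                                     m = length(ctrl), rank = r,
                                     assigned_randomly = rnd,
                                     method = method,
                                     stringsAsFactors = FALSE)
      }
    }
  })
  structure(list(records = do.call(rbind, records),
                 declarations = if (length(declarations)) {
                   do.call(rbind, declarations)
                 } else NULL),
            class = "dirank_cv")
}

#' Compute importance matrices for a set of networks
#'
#' Convenience wrapper: adjacency, diffusion kernel and importance
#' transform for each network, preserving names.
#'
#' @param networks named list of \code{\link{gene_network}} objects.
#' @param beta diffusion parameter.
#' @return named list of \code{\link{importance_matrix}} objects.
#' @export
compute_importances <- function(networks, beta = 0.1) {
  out <- lapply(networks, function(net) {
    importance_transform(diffusion_kernel(adjacency(net), beta = beta))
  })
  if (!is.null(names(networks))) {
    for (nm in names(networks)) out[[nm]]$network_name <- nm
  }
  out
}

#' ROC curve and AUC from LOOCV rank records
#'
#' Each run contributes a rank-based AUC equal to the fraction of its
#' controls ranked below the held-out gene, \code{(m - r + 1)/m}, with ties
#' at half credit already folded into the real-valued rank; the overall AUC
#' is the mean over runs. The ROC curve sweeps rank cutoffs: at cutoff
#' \code{k}, TPR is the fraction of runs with rank <= k and FPR the mean
#' fraction of controls admitted.
#'
#' @param records record data frame from \code{\link{loocv}} (or a
#'   \code{dirank_cv} object).
#' @return list with \code{auc} and a \code{points} data frame
#'   (cutoff, tpr, fpr).
#' @export
roc_auc <- function(records) {
  if (inherits(records, "dirank_cv")) records <- records$records
  stopifnot(nrow(records) >= 1)
  r <- records$rank
  m <- records$m
  auc <- mean((m - r + 1) / m)
  cutoffs <- seq_len(max(m) + 1)
  pts <- data.frame(cutoff = cutoffs,
                    tpr = vapply(cutoffs, function(k) mean(r <= k), numeric(1)),
                    fpr = vapply(cutoffs, function(k) {
                      mean((pmin(k, m + 1) - (r <= k)) / m)
                    }, numeric(1)))
  list(auc = auc, points = pts)
}

#' Enrichment factor of a LOOCV rank
#'
#' Defined as 50 divided by the held-out disease gene's rank, so a
#' first-ranked gene scores 50 and rank 50 scores 1.
#'
#' @param rank rank value(s), >= 1.
#' @return enrichment factor(s).
#' @export
enrichment_factor <- function(rank) {
  if (any(rank < 1)) stop("rank must be at least 1")
  50 / rank
}

#' TPR and FPR of declaration criteria over LOOCV runs
#'
#' TPR is the fraction of runs whose held-out disease gene is declared;
#' FPR is the total number of declared non-disease genes divided by the
#' total number of candidate genes across runs.
#'
#' @param cv a \code{dirank_cv} object from \code{\link{loocv}} run with
#'   \code{criteria}.
#' @return data frame (criterion, tpr, fpr, n_runs).
#' @export
tpr_fpr <- function(cv) {
  stopifnot(inherits(cv, "dirank_cv"))
  if (is.null(cv$declarations)) stop("loocv was run without criteria")
  recs <- cv$records
  out <- lapply(split(cv$declarations, cv$declarations$criterion), function(d) {
    runs <- unique(d$run)
    hit <- vapply(runs, function(rn) {
      held <- d$held_out_gene[d$run == rn][1]
      held %in% d$gene[d$run == rn]
    }, logical(1))
    fp <- vapply(runs, function(rn) {
      held <- d$held_out_gene[d$run == rn][1]
      sum(d$gene[d$run == rn] != held)
    }, numeric(1))
    n_cand <- recs$m[runs] + 1
    data.frame(criterion = d$criterion[1],
               tpr = mean(hit),
               fpr = sum(fp) / sum(n_cand),
               n_runs = length(runs),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary of a cross-validation experiment
#'
#' @param cv a \code{dirank_cv} object.
#' @return object of class \code{cv_summary}: list with \code{n_runs},
#'   \code{auc}, \code{mean_enrichment}, \code{n_first_ranked} (runs with
#'   rank < 1.5), \code{n_top10} (rank < 10.5) and, when declarations are
#'   present, the per-criterion TPR/FPR table.
#' @export
cv_summary <- function(cv) {
  stopifnot(inherits(cv, "dirank_cv"))
  recs <- cv$records
  structure(list(n_runs = nrow(recs),
                 auc = roc_auc(recs)$auc,
                 mean_enrichment = mean(enrichment_factor(recs$rank)),
                 n_first_ranked = sum(recs$rank < 1.5),
                 n_top10 = sum(recs$rank < 10.5),
                 criteria = if (!is.null(cv$declarations)) tpr_fpr(cv) else NULL),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("LOOCV: %d runs | AUC %.3f | enrichment %.1f | first-ranked %d | top-10 %d\n",
              x$n_runs, x$auc, x$mean_enrichment, x$n_first_ranked, x$n_top10))
  if (!is.null(x$criteria)) {
    print(x$criteria, row.names = FALSE)
  }
  invisible(x)
}

#' Degree-preserving network rewiring
#'
#' Randomizes a network by repeated double-edge swaps, rejecting swaps that
#' would create self-loops or duplicate edges, so the degree sequence is
#' preserved exactly. Used as a null model to test whether prioritization
#' performance is driven by the degree bias of well-studied disease genes
#' rather than by meaningful topology. Each surviving edge keeps its weight
#' attached to its first endpoint, so the weight multiset is preserved.
#'
#' @param network a \code{\link{gene_network}}.
#' @param swaps_per_edge attempted swaps per edge (rejections count);
#'   default 10.
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return a rewired \code{gene_network} with identical node set and degree
#'   sequence. Networks admitting no valid swap are returned unchanged with
#'   a warning.
#' @export
rewire_degree_preserving <- function(network, swaps_per_edge = 10, seed = NULL) {
  stopifnot(inherits(network, "gene_network"))
  ed <- network$edges
  ne <- nrow(ed)
  if (ne < 2) {
    warning("network has fewer than 2 edges; returned unchanged")
    return(network)
  }
  from <- ed$from
  to <- ed$to
  weight <- ed$weight
  key <- function(a, b) paste0(pmin(a, b), "\r", pmax(a, b))
  env <- new.env(hash = TRUE, size = ne * 2L)
  for (i in seq_len(ne)) assign(key(from[i], to[i]), TRUE, envir = env)
  attempts <- ceiling(swaps_per_edge * ne)
  swaps <- 0L
  with_seed(seed, {
    pick <- matrix(sample.int(ne, 2L * attempts, replace = TRUE), ncol = 2)
    flip <- stats::runif(attempts) < 0.5
    for (t in seq_len(attempts)) {
      i <- pick[t, 1]; j <- pick[t, 2]
      if (i == j) next
      a <- from[i]; b <- to[i]
      cc <- from[j]; dd <- to[j]
      if (flip[t]) { tmp <- cc; cc <- dd; dd <- tmp }
      # propose (a, dd) and (cc, b)
      if (a == dd || cc == b) next
      k1 <- key(a, dd); k2 <- key(cc, b)
      if (k1 == k2 ||
          exists(k1, envir = env, inherits = FALSE) ||
          exists(k2, envir = env, inherits = FALSE)) next
      rm(list = c(key(a, b), key(cc, dd)), envir = env)
      assign(k1, TRUE, envir = env)
      assign(k2, TRUE, envir = env)
      from[i] <- a; to[i] <- dd
      from[j] <- cc; to[j] <- b
      swaps <- swaps + 1L
    }
  })
  if (swaps == 0L) {
    warning("no valid degree-preserving swap found; returned network unchanged")
    return(network)
  }
  gene_network(data.frame(from = from, to = to, weight = weight,
                          stringsAsFactors = FALSE),
               name = network$name, nodes = network$nodes)
}
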