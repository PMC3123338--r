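# Per-network similarity and distance measures. The diffusion kernel
# K = exp(beta * H), H = A - D, is the package's primary global measure;
# direct-neighbor and shortest-path distances and random walk with restart
# are provided for comparison, mirroring the single-source baselines.

#' Adjacency matrix of a gene network
#'
#' @param network a \code{\link{gene_network}}.
#' @param node_order optional character vector fixing the node order; must
#'   contain every network node. Genes in \code{node_order} but absent from
#'   the network become isolated (all-zero) rows. Default: lexicographic
#'   order of the network's nodes.
#' @return object of class \code{adjacency_matrix}: list with
#'   \code{node_order}, symmetric matrix \code{A} (zero diagonal, edge
#'   weights off-diagonal) and the source \code{name}.
#' @export
adjacency <- function(network, node_order = NULL) {
  stopifnot(inherits(network, "gene_network"))
  if (is.null(node_order)) {
    node_order <- network$nodes           # already sorted
  } else {
    node_order <- as.character(node_order)
    if (anyDuplicated(node_order)) stop("node_order contains duplicates")
    missing <- setdiff(network$nodes, node_order)
    if (length(missing)) {
      stop("node_order is missing network nodes, e.g. ", missing[1])
    }
  }
  n <- length(node_order)
  A <- matrix(0, n, n, dimnames = list(node_order, node_order))
  ed <- network$edges
  if (nrow(ed)) {
    i <- match(ed$from, node_order)
    j <- match(ed$to, node_order)
    A[cbind(i, j)] <- ed$weight
    A[cbind(j, i)] <- ed$weight
  }
  structure(list(node_order = node_order, A = A, name = network$name),
            class = "adjacency_matrix")
}

#' Diffusion kernel of a network
#'
#' Computes \code{K = exp(beta * H)} with \code{H = A - D}, where \code{D}
#' is the diagonal matrix of (weighted) node degrees. Because each row of
#' \code{H} sums to zero, every row of \code{K} sums to one; entries are
#' strictly positive within a connected component and exactly zero across
#' components. The kernel is evaluated per component by dense symmetric
#' eigendecomposition, and cross-component entries are set to exact zero
#' from the component labels rather than left to numerical underflow.
#'
#' @param adj an \code{\link{adjacency_matrix}}.
#' @param beta diffusion parameter, > 0. Larger values diffuse similarity
#'   farther along paths; default 0.1.
#' @return object of class \code{kernel_matrix}: list with
#'   \code{node_order}, symmetric matrix \code{K}, \code{beta},
#'   \code{component_labels} (integer per node) and the source \code{name}.
#' @export
diffusion_kernel <- function(adj, beta = 0.1) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    stop("beta must be a single positive number")
  }
  A <- adj$A
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12))) {
    stop("adjacency matrix must be symmetric")
  }
  n <- nrow(A)
  comp <- component_labels(A)
  K <- matrix(0, n, n, dimnames = dimnames(A))
  deg <- rowSums(A)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) {
      K[idx, idx] <- 1
      next
    }
    H <- A[idx, idx, drop = FALSE]
    diag(H) <- diag(H) - deg[idx]
    e <- eigen(H, symmetric = TRUE)
    Kc <- e$vectors %*% (exp(beta * e$values) * t(e$vectors))
    Kc <- (Kc + t(Kc)) / 2
    K[idx, idx] <- Kc
  }
  structure(list(node_order = adj$node_order, K = K, beta = beta,
                 component_labels = comp, name = adj$name),
            class = "kernel_matrix")
}

# Connected-component labels from an adjacency matrix (edges = nonzero).
component_labels <- function(A) {
  n <- nrow(A)
  if (n == 0) return(integer(0))
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Local pairwise distances on a network
#'
#' \code{DN} (direct neighbor): distance 1 for adjacent genes, a constant 2
#' for all non-adjacent pairs. \code{SP} (shortest path): BFS hop count,
#' with \code{Inf} as the unreachable sentinel. Both treat any positive
#' edge weight as presence (hops, not costs).
#'
#' @param adj an \code{\link{adjacency_matrix}}.
#' @param method \code{"DN"} or \code{"SP"}.
#' @return object of class \code{distance_matrix}: list with
#'   \code{node_order}, symmetric matrix \code{d} (zero diagonal) and
#'   \code{method}.
#' @export
local_distance <- function(adj, method = c("DN", "SP")) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  method <- match.arg(method)
  A <- adj$A
  if (method == "DN") {
    d <- ifelse(A > 0, 1, 2)
    diag(d) <- 0
  } else {
    g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected",
                                             diag = FALSE)
    d <- igraph::distances(g, weights = NA)
    dimnames(d) <- dimnames(A)
  }
  structure(list(node_order = adj$node_order, d = d, method = method),
            class = "distance_matrix")
}

#' Random walk with restart
#'
#' Iterates \code{p <- (1 - r) W p + r p0} until the L1 change falls below
#' \code{tol}, where \code{W} is the column-normalized adjacency matrix and
#' \code{p0} puts equal probability on the seed genes. Zero-degree nodes
#' receive a self-loop before normalization so \code{W} stays
#' column-stochastic and probability mass is conserved.
#'
#' @param adj an \code{\link{adjacency_matrix}}.
#' @param seeds character vector of seed genes; seeds absent from the
#'   network are dropped with a message, and it is an error if none remain.
#' @param restart restart probability \code{r} in (0, 1); default 0.75.
#' @param tol L1 convergence threshold; default 1e-10.
#' @param max_iter iteration cap; default 10000.
#' @return object of class \code{rwr_profile}: list with \code{node_order},
#'   probability vector \code{p} (sums to 1), \code{restart},
#'   \code{iterations} and the final L1 \code{residual}.
#' @export
rwr <- function(adj, seeds, restart = 0.75, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  if (!is.numeric(restart) || restart <= 0 || restart >= 1) {
    stop("restart must be in (0, 1)")
  }
  seeds <- unique(as.character(seeds))
  present <- seeds %in% adj$node_order
  if (any(!present)) {
    message("rwr: dropping ", sum(!present), " seed(s) absent from the network")
  }
  seeds <- seeds[present]
  if (length(seeds) == 0) stop("no seed gene is present in the network")
  A <- adj$A
  cs <- colSums(A)
  zero <- cs == 0
  if (any(zero)) {
    diag(A)[zero] <- 1
    cs[zero] <- 1
  }
  W <- sweep(A, 2, cs, "/")
  n <- length(adj$node_order)
  p0 <- numeric(n)
  p0[match(seeds, adj$node_order)] <- 1 / length(seeds)
  p <- p0
  res <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- (1 - restart) * as.vector(W %*% p) + restart * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) break
  }
  names(p) <- adj$node_order
  structure(list(node_order = adj$node_order, p = p, restart = restart,
                 iterations = iter, residual = res),
            class = "rwr_profile")
}

#' Score candidates against a disease family on a single network
#'
#' Implements the single-source baselines: the relationship between a
#' candidate gene and a disease family is the average distance (DN, SP) or
#' average kernel similarity (DK) between the candidate and the family's
#' genes present in the network, or the candidate's steady-state visiting
#' probability when the family genes seed a random walk with restart (RWR).
#'
#' @param measure one of \code{"DN"}, \code{"SP"}, \code{"DK"},
#'   \code{"RWR"}.
#' @param network a \code{\link{gene_network}}.
#' @param family a \code{\link{disease_family}} (or character vector of
#'   disease genes). Family genes absent from the network are ignored;
#'   candidates must not overlap the family.
#' @param candidates character vector of genes to score; candidates absent
#'   from the network get \code{NA} scores (downstream ranking assigns them
#'   random ranks).
#' @param beta diffusion parameter for \code{DK}.
#' @param restart,tol,max_iter RWR parameters.
#' @return data frame (gene, score) with attributes \code{direction}
#'   (\code{"asc"} for distances, \code{"desc"} for similarities) and
#'   \code{uninformative} (TRUE when no family gene is in the network, in
#'   which case all scores are NA). For SP, unreachable family genes are
#'   excluded from a candidate's average; a candidate unreachable from every
#'   family gene scores \code{Inf} (the worst).
#' @export
single_network_scores <- function(measure = c("DK", "RWR", "DN", "SP"),
                                  network, family, candidates,
                                  beta = 0.1, restart = 0.75,
                                  tol = 1e-10, max_iter = 10000) {
  measure <- match.arg(measure)
  fam_genes <- if (inherits(family, "disease_family")) family$genes else as.character(family)
  candidates <- as.character(candidates)
  if (any(candidates %in% fam_genes)) {
    stop("candidates must be disjoint from the family's disease genes")
  }
  adj <- adjacency(network)
  fam_in <- intersect(fam_genes, adj$node_order)
  direction <- if (measure %in% c("DN", "SP")) "asc" else "desc"
  out <- data.frame(gene = candidates, score = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(fam_in) == 0) {
    attr(out, "direction") <- direction
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  cand_in <- candidates[candidates %in% adj$node_order]
  score <- switch(measure,
    DN = {
      d <- local_distance(adj, "DN")$d
      rowMeans(d[cand_in, fam_in, drop = FALSE])
    },
    SP = {
      d <- local_distance(adj, "SP")$d[cand_in, fam_in, drop = FALSE]
      apply(d, 1, function(row) {
        fin <- row[is.finite(row)]
        if (length(fin) == 0) Inf else mean(fin)
      })
    },
    DK = {
      K <- diffusion_kernel(adj, beta)$K
      rowMeans(K[cand_in, fam_in, drop = FALSE])
    },
    RWR = {
      p <- rwr(adj, seeds = fam_in, restart = restart, tol = tol,
               max_iter = max_iter)$p
      p[cand_in]
    })
  out$score[match(cand_in, out$gene)] <- as.numeric(score)
  attr(out, "direction") <- direction
  attr(out, "uninformative") <- FALSE
  out
}

#' Write a kernel (or other symmetric) matrix to TSV
#' @param K a \code{kernel_matrix}, \code{importance_matrix} or plain list
#'   with \code{node_order} and a square matrix component.
#' @param path output file.
#' @param header_lines optional \code{#}-prefixed provenance lines.
#' @return the path, invisibly.
#' @export
write_kernel_tsv <- function(K, path, header_lines = NULL) {
  m <- if (!is.null(K$K)) K$K else K$I
  write_matrix_tsv(m, K$node_order, path, header_lines = header_lines)
}
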