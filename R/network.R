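#' Construct a gene network
#'
#' A \code{gene_network} is an undirected, weighted graph over gene
#' identifiers; one per data source. Self-loops are dropped and duplicate
#' edges between the same unordered pair are merged, keeping the maximum
#' weight, so construction is idempotent.
#'
#' @param edges data frame with character columns \code{from} and \code{to}
#'   and an optional numeric \code{weight} column (missing weights become 1).
#' @param name label for the data source this network encodes.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers; the node set is always a superset of all edge
#'   endpoints.
#' @return object of class \code{gene_network} with fields \code{name},
#'   \code{nodes} (sorted character vector) and \code{edges} (data frame
#'   \code{from}, \code{to}, \code{weight} with \code{from < to}).
#' @examples
#' net <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                weight = c(1, 0.7)), name = "demo")
#' @export
gene_network <- function(edges, name = "network", nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0) {
    ed <- data.frame(from = character(0), to = character(0),
                     weight = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(name = name, nodes = sort(unique(as.character(nodes))),
                          edges = ed),
                     class = "gene_network"))
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
  if (anyNA(from) || anyNA(to)) stop("edge endpoints must be non-missing strings")
  if (anyNA(weight) || any(!is.finite(weight))) stop("edge weights must be finite numbers")
  if (any(weight <= 0)) stop("edge weights must be positive")
  keep <- from != to
  from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste0(a, "\r", b)
  if (anyDuplicated(key)) {
    w <- tapply(weight, key, max)
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]; key <- key[first]
    weight <- as.numeric(w[key])
  }
  o <- order(a, b)
  ed <- data.frame(from = a[o], to = b[o], weight = weight[o],
                   stringsAsFactors = FALSE)
  rownames(ed) <- NULL
  all_nodes <- sort(unique(c(ed$from, ed$to, as.character(nodes))))
  structure(list(name = name, nodes = all_nodes, edges = ed),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges / nodes of a gene network
#' @param network a \code{gene_network}.
#' @return integer count.
#' @export
n_edges <- function(network) nrow(network$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(network) length(network$nodes)

#' Load a gene network from an edge-list TSV
#'
#' Expects lines \code{gene_a<TAB>gene_b[<TAB>weight]}; \code{#} comment
#' lines and blank lines are ignored, and whitespace-separated files are
#' accepted. Self-loops are deleted and duplicated edges between the same
#' pair of nodes are combined (maximum weight wins); a missing weight
#' column means weight 1.
#'
#' @param path edge-list file.
#' @param name data-source label for the resulting network.
#' @return a \code{gene_network}.
#' @export
load_edge_list <- function(path, name = basename(path)) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) return(gene_network(data.frame(), name = name))
  parts <- strsplit(trimws(dat$lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf < 2)
  if (length(bad)) {
    stop(sprintf("malformed edge at line %d of %s: expected at least 2 fields",
                 dat$numbers[bad[1]], path))
  }
  from <- vapply(parts, `[[`, character(1), 1)
  to <- vapply(parts, `[[`, character(1), 2)
  weight <- rep(1, length(parts))
  has_w <- nf >= 3
  if (any(has_w)) {
    wtxt <- vapply(parts[has_w], `[[`, character(1), 3)
    w <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(w)) {
      bad <- dat$numbers[has_w][which(is.na(w))[1]]
      stop(sprintf("non-numeric weight at line %d of %s", bad, path))
    }
    if (any(w <= 0)) {
      bad <- dat$numbers[has_w][which(w <= 0)[1]]
      stop(sprintf("non-positive weight at line %d of %s", bad, path))
    }
    weight[has_w] <- w
  }
  gene_network(data.frame(from = from, to = to, weight = weight,
                          stringsAsFactors = FALSE), name = name)
}

#' Write a gene network as an edge-list TSV
#'
#' @param network a \code{gene_network}.
#' @param path output file.
#' @param header_lines optional \code{#}-prefixed provenance lines.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(network, path, header_lines = NULL) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(header_lines)) writeLines(header_lines, con)
    ed <- network$edges
    if (nrow(ed)) {
      writeLines(paste(ed$from, ed$to, fmt_num(ed$weight), sep = "\t"), con)
    }
  })
}

#' Build a co-expression network from an expression matrix
#'
#' Genes are linked when their Pearson correlation coefficient across arrays
#' exceeds \code{threshold}; the correlation coefficient becomes the edge
#' weight. The rule is signed (\code{r > threshold}), not applied to
#' \code{|r|}, so strong anti-correlation produces no edge. Genes with zero
#' expression variance produce no edges.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param threshold correlation cutoff in (0, 1); default 0.5.
#' @param name label for the resulting network.
#' @return a \code{gene_network} whose nodes are the genes incident to at
#'   least one supra-threshold correlation.
#' @export
build_coexpression_network <- function(expr, threshold = 0.5, name = "coexpression") {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(expr$arrays) < 2) stop("need at least 2 arrays to correlate")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single value in (0, 1)")
  }
  r <- suppressWarnings(stats::cor(t(expr$values)))
  idx <- which(upper.tri(r) & r > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(gene_network(data.frame(), name = name))
  gene_network(data.frame(from = expr$genes[idx[, 1]],
                          to = expr$genes[idx[, 2]],
                          weight = r[idx],
                          stringsAsFactors = FALSE),
               name = name)
}

#' Build a co-existence network from a gene-set collection
#'
#' Links every pair of genes that co-occur in at least one set (e.g. genes
#' sharing a pathway). Edges are unweighted (weight 1) and co-occurrence in
#' multiple sets still yields a single edge.
#'
#' @param sets a \code{\link{gene_set_collection}}.
#' @param name label for the resulting network.
#' @return a \code{gene_network}; its node set is the union of the input
#'   sets restricted to genes appearing in at least one pair.
#' @export
build_coexistence_network <- function(sets, name = "coexistence") {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (length(sets$sets) == 0) stop("empty gene-set collection")
  pair_from <- character(0)
  pair_to <- character(0)
  for (s in sets$sets) {
    g <- sort(unique(s))
    if (length(g) < 2) next
    p <- utils::combn(g, 2)
    pair_from <- c(pair_from, p[1, ])
    pair_to <- c(pair_to, p[2, ])
  }
  if (length(pair_from) == 0) return(gene_network(data.frame(), name = name))
  gene_network(data.frame(from = pair_from, to = pair_to, weight = 1,
                          stringsAsFactors = FALSE),
               name = name)
}
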