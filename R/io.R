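# Typed containers for the remaining inputs (expression matrices, gene-set
# collections, disease families, gene positions) and their TSV/GMT readers
# and writers.

#' Construct an expression matrix
#'
#' @param values numeric matrix, genes in rows, arrays in columns.
#' @param genes gene identifiers (default rownames); must be unique.
#' @param arrays array identifiers (default colnames).
#' @return object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              arrays = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes)) stop("gene identifiers are required")
  if (is.null(arrays)) arrays <- paste0("array", seq_len(ncol(values)))
  genes <- as.character(genes)
  arrays <- as.character(arrays)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in expression matrix")
  if (ncol(values) < 2) stop("expression matrix needs at least 2 arrays")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("expression values must be finite numbers")
  }
  dimnames(values) <- list(genes, arrays)
  structure(list(genes = genes, arrays = arrays, values = values),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d arrays\n",
              length(x$genes), length(x$arrays)))
  invisible(x)
}

#' Load an expression matrix from TSV
#'
#' First column gene id, header row of array ids, tab-separated numeric
#' values.
#'
#' @param path TSV file.
#' @return an \code{\link{expression_matrix}}.
#' @export
load_expression_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 3) stop("expression TSV needs a gene column and >=2 arrays")
  genes <- df[[1]]
  vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) vals <- matrix(vals, nrow = 1)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value for gene '%s', array '%s'",
                 genes[bad[1]], names(df)[-1][bad[2]]))
  }
  expression_matrix(vals, genes = genes, arrays = names(df)[-1])
}

#' Write an expression matrix as TSV
#' @param expr an \code{\link{expression_matrix}}.
#' @param path output file.
#' @param header_lines optional \code{#}-prefixed provenance lines.
#' @return the path, invisibly.
#' @export
write_expression_matrix <- function(expr, path, header_lines = NULL) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(header_lines)) writeLines(header_lines, con)
    writeLines(paste(c("gene", expr$arrays), collapse = "\t"), con)
    for (i in seq_along(expr$genes)) {
      writeLines(paste(c(expr$genes[i], fmt_num(expr$values[i, ])),
                       collapse = "\t"), con)
    }
  })
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors; names are set ids (unique),
#'   every set non-empty.
#' @param descriptions optional character vector of per-set descriptions.
#' @return object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set ids must be unique and non-missing")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

parse_gmt <- function(path) {
  dat <- read_data_lines(path)
  parts <- strsplit(dat$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", character(1))
  genes <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  list(ids = ids, desc = desc, genes = genes, numbers = dat$numbers)
}

#' Load a gene-set collection from a GMT file
#'
#' Standard GMT: tab-separated set id, description, then member genes.
#'
#' @param path GMT file.
#' @return a \code{\link{gene_set_collection}}.
#' @export
load_gene_sets <- function(path) {
  g <- parse_gmt(path)
  if (anyDuplicated(g$ids)) {
    stop("duplicate set id in ", path, ": ", g$ids[duplicated(g$ids)][1])
  }
  empty <- which(lengths(g$genes) == 0)
  if (length(empty)) {
    stop(sprintf("gene set '%s' (line %d) has no genes",
                 g$ids[empty[1]], g$numbers[empty[1]]))
  }
  sets <- g$genes
  names(sets) <- g$ids
  gene_set_collection(sets, descriptions = g$desc)
}

#' Write a gene-set collection (or disease families) as GMT
#' @param x a \code{gene_set_collection} or list of \code{disease_family}.
#' @param path output file.
#' @param header_lines optional \code{#}-prefixed provenance lines.
#' @return the path, invisibly.
#' @export
write_gmt <- function(x, path, header_lines = NULL) {
  if (inherits(x, "gene_set_collection")) {
    ids <- names(x$sets)
    desc <- x$descriptions
    genes <- x$sets
  } else {
    ids <- vapply(x, `[[`, character(1), "family_id")
    desc <- vapply(x, `[[`, character(1), "category")
    genes <- lapply(x, `[[`, "genes")
  }
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(header_lines)) writeLines(header_lines, con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], desc[i], genes[[i]]), collapse = "\t"), con)
    }
  })
}

#' Construct a disease family
#'
#' A disease family pools phenotypically similar disorders so that each
#' family carries several known disease genes; scoring needs at least one
#' gene pair, so families require two or more genes.
#'
#' @param family_id family identifier.
#' @param genes character vector of known disease genes (>= 2, made unique).
#' @param category optional mechanism label
#'   (\code{monogenic|polygenic|cancer|unknown}).
#' @return object of class \code{disease_family}.
#' @export
disease_family <- function(family_id, genes, category = "unknown") {
  genes <- unique(as.character(genes))
  if (length(genes) < 2) {
    stop("disease family '", family_id, "' needs at least 2 genes")
  }
  if (!category %in% c("monogenic", "polygenic", "cancer", "unknown")) {
    category <- "unknown"
  }
  structure(list(family_id = as.character(family_id), genes = genes,
                 category = category),
            class = "disease_family")
}

#' @export
print.disease_family <- function(x, ...) {
  cat(sprintf("disease_family '%s' (%s): %d genes\n",
              x$family_id, x$category, length(x$genes)))
  invisible(x)
}

#' Load disease families from a GMT file
#'
#' Each line: family id, category (or free-text description), member genes.
#' A description matching \code{monogenic}, \code{polygenic} or \code{cancer}
#' is kept as the family's category. Families with fewer than two genes are
#' skipped with a warning, because every downstream score needs at least one
#' within-family gene pair.
#'
#' @param path GMT file.
#' @return named list of \code{\link{disease_family}} objects.
#' @export
load_disease_families <- function(path) {
  g <- parse_gmt(path)
  if (anyDuplicated(g$ids)) {
    stop("duplicate family id in ", path, ": ", g$ids[duplicated(g$ids)][1])
  }
  fams <- list()
  for (i in seq_along(g$ids)) {
    if (length(g$genes[[i]]) < 2) {
      warning(sprintf("skipping family '%s' (line %d): fewer than 2 genes",
                      g$ids[i], g$numbers[i]), call. = FALSE)
      next
    }
    fams[[g$ids[i]]] <- disease_family(g$ids[i], g$genes[[i]],
                                       category = g$desc[i])
  }
  fams
}

#' Load gene chromosomal positions
#'
#' TSV with columns \code{gene}, \code{chrom}, \code{start} (0-based).
#' Used to build nearest-neighbor control sets on the same chromosome.
#'
#' @param path TSV file.
#' @return data frame of class \code{gene_positions} with one row per gene.
#' @export
load_gene_positions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("gene", "chrom", "start")
  gene_positions(df)
}

#' Construct a gene position table
#' @param df data frame with columns \code{gene}, \code{chrom},
#'   \code{start} (integer, 0-based, >= 0); one row per gene.
#' @return data frame of class \code{gene_positions}.
#' @export
gene_positions <- function(df) {
  stopifnot(all(c("gene", "chrom", "start") %in% names(df)))
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene row in positions: ", df$gene[duplicated(df$gene)][1])
  }
  if (anyNA(df$start) || any(df$start < 0) || any(df$start != round(df$start))) {
    stop("start must be a non-negative integer coordinate")
  }
  rownames(df) <- NULL
  class(df) <- c("gene_positions", "data.frame")
  df
}

#' Write gene positions as TSV
#' @param pos a \code{gene_positions} table.
#' @param path output file.
#' @param header_lines optional \code{#}-prefixed provenance lines.
#' @return the path, invisibly.
#' @export
write_gene_positions <- function(pos, path, header_lines = NULL) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(header_lines)) writeLines(header_lines, con)
    writeLines("gene\tchrom\tstart", con)
    if (nrow(pos)) {
      writeLines(paste(pos$gene, pos$chrom, sprintf("%.0f", pos$start),
                       sep = "\t"), con)
    }
  })
}
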