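# Synthetic fixture generator. Produces the three data-source types with a
# shared planted modular structure -- a planted-partition interaction
# graph, latent-factor block-correlated expression, and module-derived
# pathway sets with dropout -- plus disease families drawn from modules,
# gene positions, and a ground-truth module table. Every pipeline stage is
# testable end to end without any external download.

#' Specification of a synthetic fixture
#'
#' The defaults define the package's reference study conditions: 500 genes
#' in 20 modules of 25; interaction edges with probability 0.2 within and
#' 0.01 between modules; expression over 40 arrays with within-module
#' latent-factor correlation 0.8; pathway sets equal to modules with 10\%
#' per-gene dropout; 10 disease families of 8 genes drawn entirely
#' (purity 1) from one module each.
#'
#' @param n_genes total genes.
#' @param n_modules number of planted modules.
#' @param p_in,p_out within/between-module edge probabilities,
#'   \code{0 <= p_out < p_in <= 1}.
#' @param rho within-module expression correlation via a shared latent
#'   factor, in [0, 1).
#' @param n_arrays expression arrays.
#' @param pathway_dropout fraction of module members omitted per pathway
#'   set.
#' @param n_families number of disease families.
#' @param family_size genes per family (>= 3).
#' @param family_purity fraction of each family drawn from its home
#'   module; the rest are random non-module genes.
#' @param seed master seed; each artifact type derives its own stream so
#'   that regenerating one artifact does not perturb the others.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_genes = 500, n_modules = 20, p_in = 0.2,
                         p_out = 0.01, rho = 0.8, n_arrays = 40,
                         pathway_dropout = 0.1, n_families = 10,
                         family_size = 8, family_purity = 1, seed = 1) {
  stopifnot(n_genes >= n_modules, n_modules >= 1,
            p_out >= 0, p_in <= 1, p_out < p_in,
            rho >= 0, rho < 1, n_arrays >= 2,
            pathway_dropout >= 0, pathway_dropout <= 1,
            n_families >= 1, family_size >= 3,
            family_purity >= 0, family_purity <= 1)
  structure(list(n_genes = n_genes, n_modules = n_modules, p_in = p_in,
                 p_out = p_out, rho = rho, n_arrays = n_arrays,
                 pathway_dropout = pathway_dropout, n_families = n_families,
                 family_size = family_size, family_purity = family_purity,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic fixture bundle
#'
#' Deterministic given the spec's seed. Module assignment is the ground
#' truth shared, noisily, by all three sources. Gene positions place each
#' module's genes contiguously (with random gaps) on chromosomes of about
#' 125 genes, so nearest-k control sets exist and are mostly non-family.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return object of class \code{dir_fixture}: list with \code{spec},
#'   \code{ppi} (\code{gene_network}), \code{expression}
#'   (\code{expression_matrix}), \code{pathways}
#'   (\code{gene_set_collection}), \code{families} (named list of
#'   \code{disease_family}), \code{positions} (\code{gene_positions}) and
#'   \code{truth} (data frame gene, module).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  sub <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, 5L))
  n <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  module <- rep(seq_len(spec$n_modules), length.out = n)
  module <- sort(module)                     # contiguous blocks
  module_size <- tabulate(module, spec$n_modules)
  if (spec$family_size > min(module_size)) {
    stop("family_size exceeds the smallest module size")
  }

  # interaction network: planted-partition graph
  ppi <- with_seed(sub[1], {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- module[ut[, 1]] == module[ut[, 2]]
    p <- ifelse(same, spec$p_in, spec$p_out)
    keep <- stats::runif(nrow(ut)) < p
    gene_network(data.frame(from = genes[ut[keep, 1]],
                            to = genes[ut[keep, 2]],
                            weight = 1, stringsAsFactors = FALSE),
                 name = "ppi")
  })

  # expression: per-module latent factor plus independent noise
  expr <- with_seed(sub[2], {
    f <- matrix(stats::rnorm(spec$n_modules * spec$n_arrays),
                spec$n_modules, spec$n_arrays)
    noise <- matrix(stats::rnorm(n * spec$n_arrays), n, spec$n_arrays)
    vals <- sqrt(spec$rho) * f[module, , drop = FALSE] +
      sqrt(1 - spec$rho) * noise
    expression_matrix(vals, genes = genes,
                      arrays = sprintf("arr%02d", seq_len(spec$n_arrays)))
  })

  # pathways: one set per module with per-gene dropout
  pathways <- with_seed(sub[3], {
    sets <- lapply(seq_len(spec$n_modules), function(m) {
      g <- genes[module == m]
      g[stats::runif(length(g)) >= spec$pathway_dropout]
    })
    names(sets) <- sprintf("path%02d", seq_len(spec$n_modules))
    sets <- sets[lengths(sets) > 0]
    if (length(sets) == 0) {
      sets <- list(path_empty = genes[1])     # degenerate full-dropout spec
    }
    gene_set_collection(sets)
  })

  # disease families: purity-weighted draws from a home module
  families <- with_seed(sub[4], {
    fams <- list()
    for (fi in seq_len(spec$n_families)) {
      home <- ((fi - 1) %% spec$n_modules) + 1
      in_mod <- genes[module == home]
      out_mod <- genes[module != home]
      n_pure <- round(spec$family_purity * spec$family_size)
      n_pure <- min(n_pure, length(in_mod))
      fam_genes <- c(sample(in_mod, n_pure),
                     sample(out_mod, spec$family_size - n_pure))
      fid <- sprintf("fam%02d", fi)
      fams[[fid]] <- disease_family(fid, fam_genes)
    }
    fams
  })

  # positions: module blocks laid contiguously over ~125-gene chromosomes
  positions <- with_seed(sub[5], {
    modules_per_chrom <- max(1, ceiling(125 / max(module_size)))
    chrom_of_module <- ceiling(seq_len(spec$n_modules) / modules_per_chrom)
    chrom <- sprintf("chr%d", chrom_of_module[module])
    start <- numeric(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      start[idx] <- cumsum(sample(1000:10000, length(idx), replace = TRUE))
    }
    gene_positions(data.frame(gene = genes, chrom = chrom, start = start,
                              stringsAsFactors = FALSE))
  })

  structure(list(spec = spec, ppi = ppi, expression = expr,
                 pathways = pathways, families = families,
                 positions = positions,
                 truth = data.frame(gene = genes, module = module,
                                    stringsAsFactors = FALSE)),
            class = "dir_fixture")
}

#' @export
print.dir_fixture <- function(x, ...) {
  cat(sprintf(paste0("dir_fixture (seed %d): %d genes, %d modules | ",
                     "ppi %d edges | %d arrays | %d pathways | %d families\n"),
              x$spec$seed, x$spec$n_genes, x$spec$n_modules,
              n_edges(x$ppi), length(x$expression$arrays),
              length(x$pathways$sets), length(x$families)))
  invisible(x)
}

#' The three analysis networks of a fixture
#'
#' Builds the co-expression and pathway co-existence networks from the
#' fixture's raw artifacts and returns them with the interaction network.
#'
#' @param fixture a \code{dir_fixture}.
#' @param threshold correlation threshold for the co-expression network.
#' @return named list of \code{gene_network}: \code{ppi}, \code{coexpr},
#'   \code{pathway}.
#' @export
fixture_networks <- function(fixture, threshold = 0.5) {
  stopifnot(inherits(fixture, "dir_fixture"))
  list(ppi = fixture$ppi,
       coexpr = build_coexpression_network(fixture$expression,
                                           threshold = threshold,
                                           name = "coexpr"),
       pathway = build_coexistence_network(fixture$pathways,
                                           name = "pathway"))
}

#' Expected difficulty of a fixture
#'
#' Computes the per-family, per-network informativeness table of a fixture,
#' so tests (and users) can check that planted structure translates into
#' signal: high-purity families should be markedly more informative than
#' purity-0 families.
#'
#' @param spec a \code{\link{fixture_spec}} or an already generated
#'   \code{dir_fixture}.
#' @param beta diffusion parameter.
#' @param threshold co-expression correlation threshold.
#' @return data frame (family_id, network, inf).
#' @export
expected_difficulty <- function(spec, beta = 0.1, threshold = 0.5) {
  fixture <- if (inherits(spec, "dir_fixture")) spec else generate_fixture(spec)
  nets <- fixture_networks(fixture, threshold = threshold)
  imps <- compute_importances(nets, beta = beta)
  informativeness_table(imps, fixture$families)
}

#' Write a fixture bundle to disk
#'
#' Emits the plain-text artifacts (\code{ppi.tsv}, \code{expression.tsv},
#' \code{pathways.gmt}, \code{families.gmt}, \code{positions.tsv},
#' \code{truth.tsv}) that round-trip through the package loaders.
#'
#' @param fixture a \code{dir_fixture}.
#' @param dir output directory (created if needed).
#' @param header_lines optional \code{#}-prefixed provenance lines.
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, header_lines = NULL) {
  stopifnot(inherits(fixture, "dir_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             expression = file.path(dir, "expression.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             families = file.path(dir, "families.gmt"),
             positions = file.path(dir, "positions.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_edge_list(fixture$ppi, paths["ppi"], header_lines)
  write_expression_matrix(fixture$expression, paths["expression"], header_lines)
  write_gmt(fixture$pathways, paths["pathways"], header_lines)
  write_gmt(fixture$families, paths["families"], header_lines)
  write_gene_positions(fixture$positions, paths["positions"], header_lines)
  write_table_tsv(fixture$truth, paths["truth"], header_lines)
  invisible(paths)
}
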