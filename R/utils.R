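# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Full-precision numeric formatting so TSV round-trips are exact.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  ints <- which(is.finite(x) & x == round(x) & abs(x) < 1e15)
  out[ints] <- sprintf("%.0f", x[ints])
  out
}

# Write via a temp file in the same directory, then rename, so a failure
# leaves no partial output behind.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(pattern = ".dirank-", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}

# Read the non-comment, non-blank lines of a text file, keeping original
# line numbers for error messages.
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], numbers = which(keep))
}

# Provenance header for every CLI output file.
provenance_header <- function(subcommand, config = list(), seed = NULL) {
  version <- as.character(utils::packageVersion("dirank"))
  cfg <- if (length(config)) {
    paste(vapply(names(config), function(k) {
      paste0(k, "=", paste(as.character(config[[k]]), collapse = ","))
    }, character(1)), collapse = " ")
  } else ""
  c(sprintf("# dirank %s", version),
    sprintf("# subcommand: %s", subcommand),
    sprintf("# config: %s", cfg),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else as.character(seed)))
}

# Symmetric matrix persisted as TSV: first column the node id, header row the
# node order. Round-trips at full double precision.
write_matrix_tsv <- function(m, node_order, path, header_lines = NULL) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(header_lines)) writeLines(header_lines, con)
    writeLines(paste(c("node", node_order), collapse = "\t"), con)
    for (i in seq_along(node_order)) {
      writeLines(paste(c(node_order[i], fmt_num(m[i, ])), collapse = "\t"), con)
    }
  })
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          quote = "", check.names = FALSE, stringsAsFactors = FALSE)
  node_order <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(node_order, node_order)
  list(node_order = node_order, m = m)
}

# Tab-separated table with optional provenance header.
write_table_tsv <- function(df, path, header_lines = NULL) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(header_lines)) writeLines(header_lines, con)
    num <- vapply(df, is.double, logical(1))
    out <- df
    for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}
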