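# Delimited-text I/O for expression matrices, gold-standard edge lists and
# inferred networks. TSV is the default; comma-delimited files are detected
# from the header line. All formats are plain text so runs are inspectable.

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stopf("file is empty: %s", path)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV file with one header row and one identifier column and
#' returns a numeric matrix in samples-by-genes orientation, regardless of
#' how the file is laid out. Expression values are assumed already
#' preprocessed (e.g. log2-transformed intensities); no normalization is
#' applied here.
#'
#' @param path Path to a delimited text file (tab or comma separated; the
#'   separator is detected from the header line).
#' @param orientation Either `"samples_by_genes"` (rows are samples, columns
#'   are genes — the default) or `"genes_by_samples"` (the transpose; gene
#'   identifiers are taken from the first column).
#' @return A numeric matrix with `rownames` = sample identifiers and
#'   `colnames` = gene identifiers (n samples x p genes, n >= 2, p >= 2).
#' @details Duplicate gene identifiers, missing values and non-numeric cells
#'   are rejected with an error naming the offending entry: genes are matched
#'   across species by identifier, so silent duplication or imputation would
#'   corrupt downstream regression.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_by_genes",
                                                   "genes_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sniff_sep(path)
  raw <- read.table(path, sep = sep, header = FALSE, colClasses = "character",
                    check.names = FALSE, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    stopf("expression file must have a header row and an id column: %s", path)
  }
  col_ids <- as.character(raw[1L, -1L])
  row_ids <- as.character(raw[-1L, 1L])
  body <- as.matrix(raw[-1L, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("non-numeric or missing value at data row %d, column '%s' in %s",
          bad[1L], col_ids[bad[2L]], path)
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "genes_by_samples") vals <- t(vals)
  as_expression_matrix(vals)
}

#' Validate a samples-by-genes expression matrix
#'
#' @param values Numeric matrix with sample rownames and gene colnames.
#' @return The validated matrix (invisibly unchanged).
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("expression data must be a numeric matrix")
  }
  if (is.null(colnames(values)) || is.null(rownames(values))) {
    stopf("expression matrix needs sample rownames and gene colnames")
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup) > 0L) {
    stopf("duplicate gene identifier(s): %s", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(values)) stopf("expression matrix contains missing values")
  if (nrow(values) < 2L) stopf("need at least 2 samples, got %d", nrow(values))
  if (ncol(values) < 2L) stopf("need at least 2 genes, got %d", ncol(values))
  values
}

#' Write an expression matrix as TSV (samples by genes)
#'
#' @param m Numeric matrix with sample rownames and gene colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard TF-target edge list
#'
#' Reads a two-column delimited file of directed transcription-factor to
#' target-gene edges and restricts it to a declared gene universe. Self
#' edges and edges with an endpoint outside the universe are dropped (with a
#' warning / reported count) rather than silently kept, because evaluation
#' universes must be explicit.
#'
#' @param path Two-column TSV/CSV (tf, target), with a header row by default.
#' @param gene_universe Character vector of admissible gene identifiers.
#' @param header Does the file start with a header row? Default `TRUE`.
#' @return An object of class `gold_standard`: a list with `tf_ids`,
#'   `edges` (two-column character matrix), `gene_universe` and
#'   `n_dropped` (edges removed during restriction).
#' @export
read_gold_standard <- function(path, gene_universe, header = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = header,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("gold-standard file has no edges: %s", path)
  if (ncol(df) < 2L) stopf("gold-standard file needs two columns (tf, target)")
  gold_standard(as.matrix(df[, 1:2]), gene_universe)
}

#' Construct a gold-standard object from an edge matrix
#'
#' @param edges Two-column character matrix of directed (tf, target) pairs.
#' @param gene_universe Character vector of admissible gene identifiers.
#' @return A `gold_standard` object; see [read_gold_standard()].
#' @export
gold_standard <- function(edges, gene_universe) {
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("tf", "target")))
  n0 <- nrow(edges)
  self <- edges[, 1L] == edges[, 2L]
  if (any(self)) {
    warnf("dropping %d self-edge(s) from gold standard", sum(self))
    edges <- edges[!self, , drop = FALSE]
  }
  known <- edges[, 1L] %in% gene_universe & edges[, 2L] %in% gene_universe
  edges <- edges[known, , drop = FALSE]
  edges <- unique(edges)
  structure(
    list(
      tf_ids = sort(unique(edges[, 1L])),
      edges = edges,
      gene_universe = gene_universe,
      n_dropped = n0 - nrow(edges)
    ),
    class = "gold_standard"
  )
}

#' Write a gold standard as a two-column TSV
#'
#' @param gold A `gold_standard` object.
#' @param path Output path.
#' @export
write_gold_standard <- function(gold, path) {
  write.table(gold$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a network object
#'
#' @param weights Symmetric matrix of partial correlations (zero diagonal).
#' @param adjacency Symmetric binary matrix of retained edges.
#' @param threshold_value Absolute partial-correlation threshold applied.
#' @param gene_ids Gene identifiers (defaults to `colnames(weights)`).
#' @param rho Graphical-lasso penalty that produced the weights (or `NA`).
#' @return An object of class `grn_network`.
#' @export
grn_network <- function(weights, adjacency, threshold_value,
                        gene_ids = colnames(weights), rho = NA_real_) {
  check_symmetric(weights, 1e-10, "weight matrix")
  check_symmetric(adjacency, 0, "adjacency matrix")
  if (any(diag(adjacency) != 0)) stopf("adjacency diagonal must be zero")
  if (any(adjacency == 1 & abs(weights) < threshold_value)) {
    stopf("adjacency retains an edge below the threshold")
  }
  dimnames(weights) <- dimnames(adjacency) <- list(gene_ids, gene_ids)
  structure(
    list(gene_ids = gene_ids, weights = weights, adjacency = adjacency,
         threshold_value = threshold_value, rho = rho),
    class = "grn_network"
  )
}

# Retained edges as a data.frame with gene_a < gene_b lexicographically,
# sorted, so output is byte-stable across runs.
network_edges <- function(net) {
  idx <- which(net$adjacency == 1 & upper.tri(net$adjacency), arr.ind = TRUE)
  a <- net$gene_ids[idx[, 1L]]
  b <- net$gene_ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- net$weights[idx]
  ord <- order(a, b)
  data.frame(gene_a = a[ord], gene_b = b[ord],
             partial_correlation = w[ord], stringsAsFactors = FALSE)
}

#' Write an inferred network as an edge list plus JSON metadata
#'
#' Emits a TSV edge list (`gene_a`, `gene_b`, `partial_correlation`) for
#' retained edges with `gene_a < gene_b` lexicographically, and a JSON
#' sidecar (same path with a `.json` extension) recording the threshold, the
#' glasso penalty, the edge count and the gene identifiers so the network can
#' be reconstructed exactly with [read_network()].
#'
#' @param net A `grn_network` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "grn_network"))
  edges <- network_edges(net)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tpartial_correlation", con)
  if (nrow(edges) > 0L) {
    writeLines(sprintf("%s\t%s\t%.17g", edges$gene_a, edges$gene_b,
                       edges$partial_correlation), con)
  }
  meta_path <- paste0(sub("\\.[^./]*$", "", path), ".json")
  write_json_stable(
    list(threshold_value = net$threshold_value, rho = net$rho,
         n_edges = nrow(edges), gene_ids = net$gene_ids),
    meta_path
  )
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' Reconstructs the adjacency and the retained-edge weights from the TSV edge
#' list and its JSON sidecar. Weights of non-retained pairs are zero (the
#' edge list stores only retained edges).
#'
#' @param path Path to the TSV edge list.
#' @return A `grn_network` object.
#' @export
read_network <- function(path) {
  meta_path <- paste0(sub("\\.[^./]*$", "", path), ".json")
  if (!file.exists(meta_path)) stopf("network metadata not found: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  genes <- as.character(meta$gene_ids)
  p <- length(genes)
  w <- adj <- matrix(0, p, p, dimnames = list(genes, genes))
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric"),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    ia <- match(df$gene_a, genes)
    ib <- match(df$gene_b, genes)
    if (anyNA(ia) || anyNA(ib)) stopf("edge endpoint not in gene_ids metadata")
    w[cbind(ia, ib)] <- w[cbind(ib, ia)] <- df$partial_correlation
    adj[cbind(ia, ib)] <- adj[cbind(ib, ia)] <- 1
  }
  grn_network(w, adj, meta$threshold_value, genes, rho = meta$rho)
}
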