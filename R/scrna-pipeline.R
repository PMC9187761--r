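# Downstream single-cell pipeline: QC filters, log normalisation,
# variability-based gene scores, augmentation of real cells with generated
# cells, and clustering validation.

#' Construct an expression matrix container
#'
#' Light cells x genes container carrying gene names, cell ids, optional
#' per-cell class labels, and a layer tag recording whether the values are
#' raw counts or log-normalised.
#'
#' @param values Numeric cells x genes matrix.
#' @param gene_names,cell_ids Identifiers; default to column/row names or
#'   generated ones.
#' @param labels Optional per-cell class labels.
#' @param layer \code{"counts"} or \code{"lognorm"}.
#' @return An object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, gene_names = NULL, cell_ids = NULL,
                              labels = NULL, layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (!is.matrix(values)) values <- as.matrix(values)
  gene_names <- gene_names %||% colnames(values) %||%
    paste0("gene", seq_len(ncol(values)))
  cell_ids <- cell_ids %||% rownames(values) %||%
    paste0("cell", seq_len(nrow(values)))
  if (length(gene_names) != ncol(values) || length(cell_ids) != nrow(values))
    stop("gene/cell identifier lengths must match the matrix dimensions",
         call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("'labels' must have one entry per cell", call. = FALSE)
  if (layer == "counts" && any(values < 0))
    stop("a counts layer cannot contain negative values", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_names)
  structure(list(values = values, gene_names = gene_names,
                 cell_ids = cell_ids, labels = labels, layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d cells x %d genes (%s layer)%s\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Quality-control filter for cells and genes
#'
#' Keeps cells expressing more than \code{min_genes} genes (non-zero counts),
#' then -- on the retained cells -- keeps genes with a count above
#' \code{min_count} in at least a fraction \code{min_cell_frac} of cells.
#' Cells are filtered before genes, and the filter is idempotent.
#'
#' @param x An \code{"expression_matrix"} with a counts layer.
#' @param min_genes Expressed-gene threshold per cell (default 1000; a cell
#'   must exceed it).
#' @param min_count Count a gene must exceed to be called expressed in a cell
#'   (default 5).
#' @param min_cell_frac Minimum fraction of retained cells in which a gene
#'   must exceed \code{min_count} (default 0.10).
#' @return The filtered \code{"expression_matrix"}.
#' @export
qc_filter <- function(x, min_genes = 1000, min_count = 5, min_cell_frac = 0.10) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$layer != "counts")
    stop("qc_filter expects a counts layer", call. = FALSE)
  keep_cells <- rowSums(x$values > 0) > min_genes
  if (!any(keep_cells))
    stop("no cells survive the expressed-genes filter", call. = FALSE)
  v <- x$values[keep_cells, , drop = FALSE]
  keep_genes <- colMeans(v > min_count) >= min_cell_frac
  if (!any(keep_genes))
    stop("no genes survive the minimum-count filter", call. = FALSE)
  expression_matrix(v[, keep_genes, drop = FALSE],
                    gene_names = x$gene_names[keep_genes],
                    cell_ids = x$cell_ids[keep_cells],
                    labels = x$labels[keep_cells],
                    layer = "counts")
}

#' Log-normalise a counts layer
#'
#' \code{log2(x + 1)} on every entry, optionally after scaling each cell to
#' the median library size. Refuses to run twice (layer-tag guard).
#'
#' @param x An \code{"expression_matrix"} with a counts layer.
#' @param library_size_scale Scale cells to the median library size first
#'   (off by default, so the transform is exactly the documented
#'   log2 pseudo-count step).
#' @return The matrix with layer \code{"lognorm"}.
#' @export
log_normalize <- function(x, library_size_scale = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$layer != "counts")
    stop("log_normalize expects a counts layer (already log-normalised?)",
         call. = FALSE)
  v <- x$values
  if (any(v < 0)) stop("negative values in counts layer", call. = FALSE)
  if (library_size_scale) {
    lib <- rowSums(v)
    if (any(lib == 0)) stop("cells with zero library size", call. = FALSE)
    v <- v * (stats::median(lib) / lib)
  }
  expression_matrix(log2(v + 1), gene_names = x$gene_names,
                    cell_ids = x$cell_ids, labels = x$labels,
                    layer = "lognorm")
}

values_of <- function(x) if (inherits(x, "expression_matrix")) x$values else as.matrix(x)

gene_score_table <- function(score, genes, method) {
  ord <- order(-score, seq_along(score))     # ties towards smaller index
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  structure(data.frame(gene = genes, score = score, rank = rank,
                       stringsAsFactors = FALSE),
            method = method, class = c("gene_score_table", "data.frame"))
}

#' Fano-factor gene score
#'
#' Per-gene variance over mean (unbiased variance, n-1 denominator); genes
#' with zero mean score 0. Higher scores rank first.
#'
#' @param x An \code{"expression_matrix"} or plain cells x genes matrix.
#' @return A \code{"gene_score_table"} data frame (gene, score, rank).
#' @export
fano_factor <- function(x) {
  v <- values_of(x)
  if (nrow(v) < 2L) stop("need at least 2 cells", call. = FALSE)
  mu <- colMeans(v)
  va <- apply(v, 2L, stats::var)
  score <- ifelse(mu > 0, va / mu, 0)
  gene_score_table(score, colnames(v) %||% paste0("gene", seq_len(ncol(v))),
                   "fano")
}

#' Squared-coefficient-of-variation gene score
#'
#' Per-gene variance over squared mean; scale-invariant, so it ranks relative
#' variability. Zero-mean genes score 0.
#'
#' @inheritParams fano_factor
#' @return A \code{"gene_score_table"}.
#' @export
cv2_index <- function(x) {
  v <- values_of(x)
  if (nrow(v) < 2L) stop("need at least 2 cells", call. = FALSE)
  mu <- colMeans(v)
  va <- apply(v, 2L, stats::var)
  score <- ifelse(mu > 0, va / mu^2, 0)
  gene_score_table(score, colnames(v) %||% paste0("gene", seq_len(ncol(v))),
                   "cv2")
}

#' Highly-variable genes by binned standardised dispersion
#'
#' The classical dispersion recipe: per-gene dispersion (variance/mean) is
#' z-scored within equal-frequency bins of the mean expression, removing the
#' mean-dispersion trend; the top \code{n_top} genes by z-score are flagged.
#' Degenerate bins (zero spread) get z-score 0.
#'
#' @param x An \code{"expression_matrix"} (log-normalised layer expected) or
#'   matrix.
#' @param n_bins Number of mean-expression bins (default 20).
#' @param n_top Number of genes to select (default 500).
#' @return A \code{"gene_score_table"} with an extra logical column
#'   \code{selected}.
#' @export
hvg_dispersion <- function(x, n_bins = 20, n_top = 500) {
  v <- values_of(x)
  g <- ncol(v)
  if (g < n_bins) stop("need at least 'n_bins' genes", call. = FALSE)
  mu <- colMeans(v)
  va <- apply(v, 2L, stats::var)
  disp <- ifelse(mu > 0, va / mu, 0)
  bin <- ceiling(rank(mu, ties.method = "first") / (g / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  z <- numeric(g)
  for (b in unique(bin)) {
    in_b <- bin == b
    s <- stats::sd(disp[in_b])
    z[in_b] <- if (is.na(s) || s == 0) 0 else (disp[in_b] - mean(disp[in_b])) / s
  }
  tab <- gene_score_table(z, colnames(v) %||% paste0("gene", seq_len(g)),
                          "hvg_dispersion")
  tab$selected <- tab$rank <= min(n_top, g)
  tab
}

#' Rank genes by a variability score
#'
#' Front end over the three native scores.
#'
#' @param x Expression matrix (cells x genes).
#' @param method \code{"fano"}, \code{"cv2"} or \code{"hvg"}.
#' @param n_top Number of top genes to return.
#' @param ... Passed to \code{\link{hvg_dispersion}}.
#' @return Character vector of the top-ranked gene names.
#' @export
select_genes <- function(x, method = c("fano", "cv2", "hvg"), n_top = 500, ...) {
  method <- match.arg(method)
  tab <- switch(method,
                fano = fano_factor(x),
                cv2 = cv2_index(x),
                hvg = hvg_dispersion(x, n_top = n_top, ...))
  tab$gene[order(tab$rank)][seq_len(min(n_top, nrow(tab)))]
}

#' Augment real cells with generated cells to a sample:feature ratio
#'
#' Generates enough cells from a trained model to bring the total cell count
#' to \code{ratio} times the gene count (HDSS data have far fewer cells than
#' genes; gene selection behaves better once cells outnumber
#' \code{ratio x genes}). Real cells are preserved bit-for-bit; generated
#' cells are appended with a \code{"gen_"} id prefix.
#'
#' @param x An \code{"expression_matrix"}.
#' @param model A fitted \code{"lsh_gan"} over the same genes.
#' @param ratio Target cells / genes ratio (default 1.5).
#' @param seed Integer seed for generation.
#' @return The augmented \code{"expression_matrix"} (layer preserved); when
#'   the target is already met the input is returned with a warning.
#' @export
augment_to_ratio <- function(x, model, ratio = 1.5, seed = 1L) {
  stopifnot(inherits(x, "expression_matrix"), inherits(model, "lsh_gan"))
  c0 <- nrow(x$values)
  g <- ncol(x$values)
  if (model$config$n_features != g)
    stop("model feature dimension does not match the matrix", call. = FALSE)
  target <- ceiling(ratio * g)
  if (target <= c0) {
    warning(sprintf("already at %d cells >= target %d; nothing generated",
                    c0, target))
    return(x)
  }
  gen <- generate_cells(model, target - c0, seed = seed)
  values <- rbind(x$values, gen)
  labels <- if (!is.null(x$labels)) c(x$labels, rep(NA, nrow(gen)))
  expression_matrix(values,
                    gene_names = x$gene_names,
                    cell_ids = c(x$cell_ids, paste0("gen_", seq_len(nrow(gen)))),
                    labels = labels, layer = x$layer)
}

#' Cluster cells on selected genes and score against ground truth
#'
#' Restricts the matrix to the selected genes, clusters the cells (k-means by
#' default, spectral via \code{kernlab}-free normalised-Laplacian embedding is
#' not provided -- \code{"kmeans"} or \code{"spectral"} through
#' \code{stats::kmeans} on a Laplacian eigenmap), and returns agreement with
#' the true labels.
#'
#' @param x An \code{"expression_matrix"} or matrix.
#' @param selected_genes Character vector of gene names (subset of the
#'   matrix's genes) or integer column indices.
#' @param n_clusters Number of clusters.
#' @param truth True per-cell labels.
#' @param method \code{"kmeans"} (default) or \code{"spectral"}.
#' @param seed Integer seed.
#' @return List with \code{ari}, \code{nmi} and the predicted \code{cluster}
#'   vector.
#' @export
cluster_and_score <- function(x, selected_genes, n_clusters, truth,
                              method = c("kmeans", "spectral"), seed = 1L) {
  method <- match.arg(method)
  v <- values_of(x)
  if (is.character(selected_genes)) {
    miss <- setdiff(selected_genes, colnames(v))
    if (length(miss))
      stop(sprintf("unknown gene identifiers: %s",
                   paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
    v <- v[, selected_genes, drop = FALSE]
  } else {
    v <- v[, selected_genes, drop = FALSE]
  }
  if (length(truth) != nrow(v))
    stop("'truth' must have one label per cell", call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  if (method == "spectral") {
    # normalised-Laplacian eigenmap on a Gaussian affinity, then k-means
    d2 <- as.matrix(stats::dist(v))^2
    sig <- stats::median(d2[upper.tri(d2)])
    A <- exp(-d2 / (2 * max(sig, .Machine$double.eps)))
    diag(A) <- 0
    dhalf <- 1 / sqrt(pmax(rowSums(A), .Machine$double.eps))
    L <- t(A * dhalf) * dhalf
    emb <- eigen(L, symmetric = TRUE)$vectors[, seq_len(n_clusters), drop = FALSE]
    emb <- emb / pmax(sqrt(rowSums(emb^2)), .Machine$double.eps)
    v <- emb
  }
  cl <- stats::kmeans(v, centers = n_clusters, nstart = 10)$cluster
  list(ari = mclust::adjustedRandIndex(cl, truth),
       nmi = nmi_score(cl, truth),
       cluster = cl)
}

#' Normalised mutual information between two labelings
#'
#' Mutual information normalised by the geometric mean of the two entropies
#' (in nats); 1 for identical partitions, 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return A number in \code{[0, 1]}.
#' @export
nmi_score <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / outer(pi_, p_j)[pos]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / sqrt(ha * hb)
}

#' Read an expression matrix from a dense CSV/TSV file
#'
#' Cells x genes layout: header row of gene names, first column cell ids;
#' an optional \code{label} column is used as class labels.
#'
#' @param path File path.
#' @param layer Layer tag for the values.
#' @param sep Field separator (\code{","} default; use \code{"\t"} for TSV).
#' @return An \code{"expression_matrix"}.
#' @export
read_expression_csv <- function(path, layer = c("counts", "lognorm"), sep = ",") {
  layer <- match.arg(layer)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  labels <- NULL
  if ("label" %in% colnames(df)) {
    labels <- df[["label"]]
    df <- df[, setdiff(colnames(df), "label"), drop = FALSE]
  }
  expression_matrix(as.matrix(df), labels = labels, layer = layer)
}

#' Write an expression matrix to CSV
#'
#' Mirror of \code{\link{read_expression_csv}}.
#'
#' @param x An \code{"expression_matrix"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_csv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- as.data.frame(x$values, check.names = FALSE)
  if (!is.null(x$labels)) df <- cbind(label = x$labels, df)
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Read an expression matrix from Matrix Market files
#'
#' Expects \code{<stem>.mtx} (cells x genes) with \code{<stem>_rows.tsv}
#' (cell ids, optional \code{label} column) and \code{<stem>_cols.tsv} (gene
#' names) sidecars, as written by \code{\link{write_expression_mtx}}.
#'
#' @param stem Path stem without extension.
#' @param layer Layer tag.
#' @return An \code{"expression_matrix"}.
#' @export
read_expression_mtx <- function(stem, layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rows <- utils::read.table(paste0(stem, "_rows.tsv"), header = TRUE, sep = "\t")
  cols <- utils::read.table(paste0(stem, "_cols.tsv"), header = TRUE, sep = "\t")
  expression_matrix(m, gene_names = as.character(cols[[1L]]),
                    cell_ids = as.character(rows[[1L]]),
                    labels = if ("label" %in% colnames(rows)) rows[["label"]],
                    layer = layer)
}

#' Write an expression matrix as Matrix Market files
#'
#' @param x An \code{"expression_matrix"}.
#' @param stem Output path stem.
#' @return The \code{.mtx} path, invisibly.
#' @export
write_expression_mtx <- function(x, stem) {
  stopifnot(inherits(x, "expression_matrix"))
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), paste0(stem, ".mtx"))
  rows <- data.frame(id = x$cell_ids)
  if (!is.null(x$labels)) rows$label <- x$labels
  utils::write.table(rows, paste0(stem, "_rows.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(name = x$gene_names), paste0(stem, "_cols.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paste0(stem, ".mtx"))
}
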