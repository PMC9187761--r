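#' Build a random-hyperplane hash forest over samples
#'
#' Indexes the rows of \code{X} with \code{n_tables} independent
#' locality-sensitive hash tables. Each table draws \code{hash_bits} random
#' Gaussian projection directions and assigns every sample the bit string of
#' the signs of its projections, so nearby points (small Euclidean angle)
#' collide in the same bucket with high probability.
#'
#' @param X Numeric matrix, samples in rows.
#' @param n_tables Number of independent hash tables (default 8).
#' @param hash_bits Hyperplanes (bits) per table (default 16).
#' @param seed Integer seed fixing the projection directions.
#' @return An object of class \code{"hash_forest"}: the projection matrices,
#'   per-table bit matrices and bucket maps, and the indexed data.
#' @export
build_hash_forest <- function(X, n_tables = 8, hash_bits = 16, seed = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 1L || ncol(X) < 1L || !is.numeric(X))
    stop("'X' must be a non-empty numeric matrix", call. = FALSE)
  n_tables <- check_count(n_tables, "n_tables", min = 1L)
  hash_bits <- check_count(hash_bits, "hash_bits", min = 1L)

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  p <- ncol(X)
  tables <- vector("list", n_tables)
  for (tt in seq_len(n_tables)) {
    proj <- matrix(stats::rnorm(hash_bits * p), hash_bits, p)
    bits <- (X %*% t(proj)) > 0        # n x hash_bits logical
    keys <- apply(bits, 1L, function(b) paste(as.integer(b), collapse = ""))
    tables[[tt]] <- list(proj = proj, bits = bits,
                         buckets = split(seq_len(nrow(X)), keys))
  }
  structure(list(tables = tables, X = X,
                 n_tables = n_tables, hash_bits = hash_bits, seed = seed),
            class = "hash_forest")
}

#' @export
print.hash_forest <- function(x, ...) {
  cat(sprintf("Random-hyperplane hash forest: %d tables x %d bits over %d samples (%d features)\n",
              x$n_tables, x$hash_bits, nrow(x$X), ncol(x$X)))
  invisible(x)
}

# Candidate set for sample i: union of its bucket members over all tables,
# widened by truncating trailing hash bits until at least `need` candidates
# (besides i itself) are available or the buckets cover everything.
forest_candidates <- function(forest, i, need) {
  n <- nrow(forest$X)
  for (depth in seq(forest$hash_bits, 0L)) {
    cand <- logical(n)
    for (tab in forest$tables) {
      if (depth == 0L) { cand[] <- TRUE; break }
      key <- tab$bits[i, seq_len(depth)]
      hit <- rowSums(tab$bits[, seq_len(depth), drop = FALSE] ==
                       matrix(key, n, depth, byrow = TRUE)) == depth
      cand <- cand | hit
    }
    cand[i] <- FALSE
    if (sum(cand) >= need || depth == 0L) return(which(cand))
  }
}

#' Approximate k-nearest-neighbour lists from a hash forest
#'
#' For every indexed sample, gathers candidates from its hash buckets (widened
#' by hash-prefix truncation until at least \code{k} candidates exist), then
#' returns the \code{k} candidates at smallest Euclidean distance. Distance
#' ties are broken towards the smaller sample index.
#'
#' @param forest A \code{"hash_forest"}.
#' @param k Number of neighbours per sample; must be smaller than the number
#'   of indexed samples.
#' @return A list of class \code{"neighbor_list"} with integer matrix
#'   \code{idx} (n x k) and numeric matrix \code{dist} (n x k), rows sorted by
#'   non-decreasing distance.
#' @export
query_knn <- function(forest, k) {
  stopifnot(inherits(forest, "hash_forest"))
  n <- nrow(forest$X)
  k <- check_count(k, "k", min = 1L)
  if (k >= n)
    stop(sprintf("'k' (%d) must be smaller than the number of samples (%d)", k, n),
         call. = FALSE)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    cand <- forest_candidates(forest, i, k)
    d <- sqrt(colSums((t(forest$X[cand, , drop = FALSE]) - forest$X[i, ])^2))
    ord <- order(d, cand)[seq_len(k)]
    idx[i, ] <- cand[ord]
    dst[i, ] <- d[ord]
  }
  structure(list(idx = idx, dist = dst, k = k), class = "neighbor_list")
}

#' Greedy neighbour-discarding subsample of a k-NN graph
#'
#' Visits samples in \code{order}; a sample not previously discarded is
#' selected and all of its listed neighbours are discarded, so the selection
#' is an independent set that covers the k-NN graph greedily.
#'
#' @param neighbors A \code{"neighbor_list"} (or a plain list of integer
#'   neighbour vectors, one per sample).
#' @param order Traversal order; defaults to input row order.
#' @return Integer vector of selected sample indices, in scan order.
#' @export
greedy_subsample <- function(neighbors, order = NULL) {
  nb <- if (inherits(neighbors, "neighbor_list"))
    lapply(seq_len(nrow(neighbors$idx)), function(i) neighbors$idx[i, ])
  else neighbors
  n <- length(nb)
  order <- if (is.null(order)) seq_len(n) else as.integer(order)
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("'order' must be a permutation of all sample indices", call. = FALSE)
  discarded <- logical(n)
  selected <- logical(n)
  out <- integer(0)
  for (i in order) {
    if (discarded[i]) next
    selected[i] <- TRUE
    out <- c(out, i)
    drop <- setdiff(nb[[i]], which(selected))
    discarded[drop] <- TRUE
  }
  out
}

#' LSH greedy subsampling of a data matrix
#'
#' The sampling step feeding the LSH-GAN generator: build a hash forest,
#' extract approximate k-nearest-neighbour lists, and greedily select samples
#' while discarding their neighbours. With \code{t > 1} the whole procedure is
#' re-run on the survivors (hashing and k-NN recomputed), shrinking the
#' subsample further.
#'
#' @param X Numeric matrix, samples in rows; must have more than \code{k} rows.
#' @param k Neighbours discarded per selected sample (default 5).
#' @param t Number of sub-sampling passes (default 1).
#' @param n_tables,hash_bits Hash-forest shape, see \code{\link{build_hash_forest}}.
#' @param seed Integer seed (each pass derives its own projection seed).
#' @param recompute_knn If \code{FALSE}, the k-NN lists of the first pass are
#'   reused (restricted to survivors) instead of being recomputed per pass.
#' @return The selected rows of \code{X}; the original row indices are
#'   attached as \code{attr(, "indices")}.
#' @examples
#' X <- make_gaussian_mixture(n_samples = 30, n_features = 20, seed = 1)$values
#' nrow(lsh_sampling(X, k = 3, t = 1, seed = 1))
#' @export
lsh_sampling <- function(X, k = 5, t = 1, n_tables = 8, hash_bits = 16,
                         seed = 1L, recompute_knn = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  k <- check_count(k, "k", min = 1L)
  t <- check_count(t, "t", min = 1L)
  if (nrow(X) <= k)
    stop("need more samples than 'k' to subsample", call. = FALSE)

  current <- seq_len(nrow(X))
  first_nb <- NULL
  for (pass in seq_len(t)) {
    if (length(current) <= k) {
      warning(sprintf(
        "stopping after %d of %d passes: %d survivors is too few for k = %d",
        pass - 1L, t, length(current), k))
      break
    }
    if (recompute_knn || is.null(first_nb)) {
      forest <- build_hash_forest(X[current, , drop = FALSE],
                                  n_tables = n_tables, hash_bits = hash_bits,
                                  seed = derive_seed(seed, pass))
      nb <- query_knn(forest, k)
      if (is.null(first_nb)) first_nb <- nb
      sel_local <- greedy_subsample(nb)
      current <- current[sel_local]
    } else {
      # fixed-list variant: greedy scan over survivors with the original lists
      alive <- current
      nb_sub <- lapply(alive, function(i) intersect(first_nb$idx[i, ], alive))
      sel_local <- greedy_subsample_global(alive, nb_sub)
      current <- alive[sel_local]
    }
  }
  out <- X[current, , drop = FALSE]
  attr(out, "indices") <- current
  out
}

# Greedy scan where `alive` are original indices and nb_sub holds neighbour
# lists in original-index space.
greedy_subsample_global <- function(alive, nb_sub) {
  pos <- match(seq_len(max(alive)), alive)
  nb_local <- lapply(nb_sub, function(v) pos[v][!is.na(pos[v])])
  greedy_subsample(nb_local)
}
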