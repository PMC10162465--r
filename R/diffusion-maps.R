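#' k-nearest-neighbour search (exact, blockwise)
#'
#' Exact Euclidean kNN by blockwise Gram-matrix evaluation. Used for both
#' bandwidth selection and kernel sparsification so the expensive search is
#' done once per pipeline run.
#'
#' @param x Numeric matrix (points in rows) or a `delay_matrix`.
#' @param k Number of neighbours (self excluded).
#' @param block Number of query points per block (memory/speed trade-off).
#' @return List with `idx` (n x k integer matrix of neighbour indices, nearest
#'   first) and `dist` (n x k Euclidean distances).
#' @export
knn_search <- function(x, k, block = 2048L) {
  if (inherits(x, "delay_matrix")) x <- x$coords
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("`k` must be smaller than the number of points", call. = FALSE)
  r <- rowSums(x^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  starts <- seq(1L, n, by = block)
  for (b in starts) {
    rows <- b:min(b + block - 1L, n)
    g <- x[rows, , drop = FALSE] %*% t(x)
    d2 <- sweep(-2 * g, 2, r, "+") + r[rows]
    for (i in seq_along(rows)) {
      di <- d2[i, ]
      di[rows[i]] <- Inf
      ord <- order(di)[seq_len(k)]
      idx[rows[i], ] <- ord
      dst[rows[i], ] <- sqrt(pmax(di[ord], 0))
    }
  }
  list(idx = idx, dist = dst)
}

#' Data-driven kernel bandwidth
#'
#' The bandwidth is the average, over all points, of the mean distance to
#' their `kmin` nearest neighbours (self excluded).
#'
#' @param dm A `delay_matrix` or a numeric matrix of points in rows.
#' @param kmin Number of nearest neighbours entering the average.
#' @param nn Optional precomputed [knn_search()] result with at least `kmin`
#'   columns.
#' @return Bandwidth `epsilon` (same units as the Euclidean distances).
#' @export
select_epsilon <- function(dm, kmin = 12, nn = NULL) {
  if (is.null(nn)) nn <- knn_search(dm, k = kmin)
  if (ncol(nn$dist) < kmin) stop("`nn` has fewer than `kmin` neighbours", call. = FALSE)
  eps <- mean(nn$dist[, seq_len(kmin)])
  if (eps <= 0) stop("degenerate data: kernel bandwidth is zero", call. = FALSE)
  eps
}

#' Sparse Gaussian-kernel Markov matrix
#'
#' Evaluates the Gaussian kernel `exp(-d^2 / epsilon^2)` on a symmetrized
#' (union rule) kNN graph, then normalizes rows to sum one. The union rule
#' keeps an edge when either endpoint lists the other among its `knn`
#' neighbours, so the kernel matrix is symmetric before normalization.
#'
#' @param dm A `delay_matrix` or a numeric matrix of points in rows.
#' @param epsilon Kernel bandwidth (see [select_epsilon()]).
#' @param knn Neighbourhood size for sparsification.
#' @param nn Optional precomputed [knn_search()] result with at least `knn`
#'   columns.
#' @param squared_bandwidth If `TRUE` (default) the exponent is
#'   `d^2 / epsilon^2`; set `FALSE` for the `d^2 / epsilon` convention used in
#'   part of the diffusion-maps literature.
#' @return An object of class `markov_matrix`: list with the row-stochastic
#'   sparse matrix `P`, the pre-normalization row sums `degree`, and the
#'   hyperparameters.
#' @export
build_markov_matrix <- function(dm, epsilon, knn = 192, nn = NULL,
                                squared_bandwidth = TRUE) {
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  if (is.null(nn)) nn <- knn_search(dm, k = knn)
  if (ncol(nn$idx) < knn) stop("`nn` has fewer than `knn` neighbours", call. = FALSE)
  n <- nrow(nn$idx)
  if (knn >= n) stop("`knn` must be smaller than the number of points", call. = FALSE)

  ii <- rep(seq_len(n), times = knn)
  jj <- as.vector(nn$idx[, seq_len(knn)])
  dd <- as.vector(nn$dist[, seq_len(knn)])
  # canonical undirected edges, deduplicated (union symmetrization)
  p1 <- pmin(ii, jj)
  p2 <- pmax(ii, jj)
  key <- (p1 - 1) * n + p2
  keep <- !duplicated(key)
  p1 <- p1[keep]; p2 <- p2[keep]; dd <- dd[keep]
  denom <- if (squared_bandwidth) epsilon^2 else epsilon
  vv <- exp(-dd^2 / denom)

  kern <- Matrix::sparseMatrix(
    i = c(p1, p2, seq_len(n)),
    j = c(p2, p1, seq_len(n)),
    x = c(vv, vv, rep(1, n)),
    dims = c(n, n)
  )
  degree <- Matrix::rowSums(kern)
  if (any(degree <= 1)) {
    # only the unit diagonal contributes: the point has no usable neighbour
    stop("isolated point in the kernel graph (all neighbour weights underflow)",
         call. = FALSE)
  }
  if (!.is_connected(kern)) {
    warning("kNN kernel graph is disconnected; eigenvectors may mix components")
  }
  P <- Matrix::drop0(Matrix::Diagonal(n, 1 / degree) %*% kern)
  structure(
    list(P = P, degree = degree,
         epsilon = epsilon, knn = knn, n = n,
         squared_bandwidth = squared_bandwidth),
    class = "markov_matrix"
  )
}

# reachability of all nodes from node 1 via sparse matrix-vector products
.is_connected <- function(adj) {
  n <- nrow(adj)
  v <- numeric(n)
  v[1] <- 1
  reached <- 1L
  repeat {
    v <- as.numeric((adj %*% v > 0) | (v > 0))
    s <- sum(v)
    if (s == n) return(TRUE)
    if (s == reached) return(FALSE)
    reached <- s
  }
}

#' Leading eigenpairs of the diffusion Markov matrix
#'
#' Computes the leading eigenpairs of a row-stochastic kernel matrix. For a
#' [build_markov_matrix()] result the solve is performed on the symmetric
#' conjugate `D^{1/2} P D^{-1/2}` for numerical stability and the
#' eigenvectors are mapped back to the Markov (right-eigenvector) convention,
#' so all eigenvalues are real and lie in `[-1, 1]`. Eigenvectors are scaled
#' to unit norm with the sign fixed so the largest-magnitude entry is
#' positive; the leading pair is the Perron pair (eigenvalue 1, constant
#' eigenvector).
#'
#' @param P A `markov_matrix` or a row-stochastic base matrix (dense solves
#'   only, for small problems and tests).
#' @param n_eigs Number of leading eigenpairs to return.
#' @param epsilon,kmin,knn Optional hyperparameter metadata carried into the
#'   result (taken from `P` when it is a `markov_matrix`).
#' @return An object of class `diffusion_basis`: list with `eigvals`
#'   (descending), `eigvecs` (one column per eigenvector, one row per embedded
#'   time index) and the hyperparameters.
#' @export
diffusion_eigendecomposition <- function(P, n_eigs = 150, epsilon = NA_real_,
                                         kmin = NA_integer_, knn = NA_integer_) {
  if (inherits(P, "markov_matrix")) {
    n <- P$n
    n_eigs <- min(n_eigs, n - 1L)
    sq <- sqrt(P$degree)
    S <- Matrix::Diagonal(n, sq) %*% P$P %*% Matrix::Diagonal(n, 1 / sq)
    S <- methods::as((S + Matrix::t(S)) / 2, "dgCMatrix")
    if (n <= 2000) {
      # dense solve: exact, and robust to degenerate eigenvalue pairs that a
      # Krylov solver can miss on perfectly symmetric geometries
      es <- eigen(as.matrix(S), symmetric = TRUE)
      es <- list(values = es$values[seq_len(n_eigs)],
                 vectors = es$vectors[, seq_len(n_eigs), drop = FALSE],
                 nconv = n_eigs)
    } else {
      es <- tryCatch(
        RSpectra::eigs_sym(S, k = n_eigs, which = "LM"),
        error = function(e) stop("diffusion eigensolver failed: ",
                                 conditionMessage(e), call. = FALSE)
      )
      if (es$nconv < n_eigs) {
        stop(sprintf("diffusion eigensolver converged for only %d of %d eigenpairs",
                     es$nconv, n_eigs), call. = FALSE)
      }
    }
    ord <- order(es$values, decreasing = TRUE)
    vals <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE] / sq
    eps <- P$epsilon
    knn_used <- P$knn
  } else {
    P <- as.matrix(P)
    n <- nrow(P)
    n_eigs <- min(n_eigs, n)
    ee <- eigen(P)
    if (is.complex(ee$values) && max(abs(Im(ee$values))) > 1e-8) {
      warning("markov matrix has noticeably complex spectrum; real parts taken")
    }
    vals <- Re(ee$values)
    vecs <- Re(ee$vectors)
    ord <- order(vals, decreasing = TRUE)[seq_len(n_eigs)]
    vals <- vals[ord]
    vecs <- vecs[, ord, drop = FALSE]
    eps <- epsilon
    knn_used <- knn
  }
  # unit norm, sign so the largest-magnitude entry is positive
  for (j in seq_len(ncol(vecs))) {
    v <- vecs[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    vecs[, j] <- v
  }
  if (!all(is.finite(vecs))) stop("non-finite diffusion eigenvectors", call. = FALSE)
  structure(
    list(eigvals = vals, eigvecs = vecs, epsilon = eps,
         kmin = kmin, knn = knn_used),
    class = "diffusion_basis"
  )
}

#' @export
print.diffusion_basis <- function(x, ...) {
  cat(sprintf("<diffusion_basis> %d eigenpairs over %d time samples (epsilon = %.4g)\n",
              length(x$eigvals), nrow(x$eigvecs), x$epsilon))
  invisible(x)
}

#' @export
tidy.diffusion_basis <- function(x, ...) {
  tibble::tibble(index = seq_along(x$eigvals), eigenvalue = x$eigvals)
}
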