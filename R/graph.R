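#' Symmetrized k-nearest-neighbor affinity graph
#'
#' Edge (i, j) is present when i is among the k nearest Euclidean neighbors
#' of j or vice versa; its weight is the Gaussian affinity
#' \eqn{M_{ij} = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))}. The diagonal is zero.
#' The unnormalized graph Laplacian \eqn{L = D - M} (degree matrix
#' \eqn{D_{ii} = \sum_j M_{ij}}) is returned alongside; its quadratic form
#' \eqn{x^\top L x = \tfrac12 \sum_{ij} M_{ij} (x_i - x_j)^2} penalizes label
#' disagreement across edges.
#'
#' @param features Numeric matrix or data frame, rows = samples.
#' @param k Number of nearest neighbors, `1 <= k < N`.
#' @param sigma_graph Gaussian affinity bandwidth; `NULL` (default) uses the
#'   median of the distances actually included as neighbor edges.
#' @return Object of class `"affinity_graph"`: list with `affinity` (M),
#'   `degree` (vector of row sums), `laplacian` (L), `k`, `sigma_graph`.
#' @export
build_affinity <- function(features, k = 5L, sigma_graph = NULL) {
  x <- as_feature_matrix(features)
  N <- nrow(x)
  k <- as.integer(k)
  if (k < 1L || k >= N) stop("'k' must satisfy 1 <= k < N")
  d2 <- sq_dist_matrix(x)
  # neighbor mask: k smallest off-diagonal distances per row
  nb <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i][seq_len(k)]
    nb[i, ord] <- TRUE
  }
  nb <- nb | t(nb)                       # union symmetrization
  if (is.null(sigma_graph)) {
    incl <- sqrt(d2[nb])
    sigma_graph <- stats::median(incl[incl > 0])
    if (!is.finite(sigma_graph) || sigma_graph <= 0) sigma_graph <- 1
  }
  if (sigma_graph <= 0) stop("'sigma_graph' must be positive")
  M <- matrix(0, N, N)
  M[nb] <- exp(-d2[nb] / (2 * sigma_graph^2))
  diag(M) <- 0
  M <- (M + t(M)) / 2
  deg <- rowSums(M)
  L <- diag(deg, N) - M
  structure(list(affinity = M, degree = deg, laplacian = L, k = k,
                 sigma_graph = sigma_graph),
            class = "affinity_graph")
}

#' Label-propagation smoothness loss
#'
#' \eqn{\mathrm{tr}(Y^\top L Y) = \tfrac12 \sum_{ij} M_{ij}
#' \|y_i - y_j\|^2}: zero iff the label matrix is constant on every connected
#' component.
#'
#' @param graph An `"affinity_graph"`.
#' @param labels N x C numeric label matrix.
#' @return Non-negative scalar.
#' @export
label_propagation_loss <- function(graph, labels) {
  stopifnot(inherits(graph, "affinity_graph"))
  Y <- as.matrix(labels)
  if (nrow(Y) != nrow(graph$laplacian)) stop("label row count mismatch")
  v <- sum(Y * (graph$laplacian %*% Y))
  max(v, 0)
}

#' Spectral label update under an orthogonality constraint
#'
#' Solves the relaxed problem \eqn{\min_{Y^\top Y = I} \mathrm{tr}(Y^\top H
#' Y)}: the optimum is spanned by the eigenvectors of the C smallest
#' eigenvalues of (the symmetrized) H, attaining their sum (Ky Fan). The
#' relaxed solution is defined only up to an orthogonal rotation, so it is
#' aligned to the fixed one-hot source block by the Procrustes rotation
#' minimizing \eqn{\|Y_{rel}[src,] R - Y_s\|_F}, then target rows are
#' discretized by row-wise argmax (ties to the lowest class index) and
#' source rows restored to their true one-hot values.
#'
#' @param H N x N (near-)symmetric matrix; symmetrized as \eqn{(H+H^\top)/2}.
#' @param n_classes Number of columns C of the label matrix.
#' @param source_mask Logical length-N vector marking source rows.
#' @param source_onehot n_src x C one-hot matrix of true source labels.
#' @return List with `relaxed` (orthonormal N x C minimizer), `rotated`
#'   (relaxed solution after Procrustes alignment), `discrete` (one-hot N x C
#'   with source rows restored), `labels` (length-N integer labels),
#'   `trace` (sum of the C smallest eigenvalues of H).
#' @export
update_labels <- function(H, n_classes, source_mask, source_onehot) {
  H <- as.matrix(H)
  N <- nrow(H)
  C <- as.integer(n_classes)
  if (ncol(H) != N) stop("'H' must be square")
  if (C < 1L || C > N) stop("'n_classes' out of range")
  Hs <- (H + t(H)) / 2
  eg <- tryCatch(eigen(Hs, symmetric = TRUE),
                 error = function(e)
                   stop("eigen-decomposition of H failed (condition ",
                        "estimate ", format(kappa(Hs)), "): ",
                        conditionMessage(e)))
  # eigen() orders decreasing; the C smallest are the trailing columns
  idx <- seq.int(N, by = -1L, length.out = C)
  Yrel <- eg$vectors[, idx, drop = FALSE]
  tr <- sum(eg$values[idx])

  src <- as.logical(source_mask)
  Ys <- as.matrix(source_onehot)
  if (sum(src) != nrow(Ys)) stop("source mask / one-hot size mismatch")
  # Procrustes: R = UV' from svd(Yrel[src]' Ys) maximizes tr(R' Yrel_s' Ys)
  sv <- svd(crossprod(Yrel[src, , drop = FALSE], Ys))
  R <- sv$u %*% t(sv$v)
  Yrot <- Yrel %*% R

  lab <- apply(Yrot, 1L, function(r) which.max(r))  # ties -> lowest index
  lab[src] <- apply(Ys, 1L, which.max)
  Ydisc <- matrix(0, N, C)
  Ydisc[cbind(seq_len(N), lab)] <- 1
  list(relaxed = Yrel, rotated = Yrot, discrete = Ydisc,
       labels = as.integer(lab), trace = tr)
}

#' Export a graph as an edge list
#'
#' Writes rows `i, j, weight` (upper triangle, nonzero edges) to a delimited
#' text file for inspection.
#'
#' @param graph An `"affinity_graph"`.
#' @param path Output file path.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "affinity_graph"))
  M <- graph$affinity
  up <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
  df <- data.frame(i = up[, 1L], j = up[, 2L],
                   weight = M[up])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
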