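#' Empirical maximum mean discrepancy between two index sets
#'
#' Squared RKHS distance between the empirical kernel mean embeddings of the
#' source and target samples:
#' \deqn{\mathrm{MMD}^2 = \frac{1}{n^2}\sum_{i,i'} K_{ii'} +
#'   \frac{1}{m^2}\sum_{j,j'} K_{jj'} - \frac{2}{nm}\sum_{i,j} K_{ij}.}
#' Clamped at zero against round-off.
#'
#' @param gram A `"gram_matrix"` over the pooled samples.
#' @param source_idx,target_idx Disjoint non-empty integer index vectors into
#'   the pooled samples.
#' @return Non-negative scalar.
#' @export
mmd_empirical <- function(gram, source_idx, target_idx) {
  stopifnot(inherits(gram, "gram_matrix"))
  source_idx <- as.integer(source_idx); target_idx <- as.integer(target_idx)
  if (length(source_idx) == 0L || length(target_idx) == 0L)
    stop("index sets must be non-empty")
  if (length(intersect(source_idx, target_idx)) > 0L)
    stop("index sets must be disjoint")
  K <- gram$values
  n <- length(source_idx); m <- length(target_idx)
  v <- sum(K[source_idx, source_idx]) / n^2 +
       sum(K[target_idx, target_idx]) / m^2 -
       2 * sum(K[source_idx, target_idx]) / (n * m)
  max(v, 0)
}

#' One-cluster-center upper bound on the empirical MMD
#'
#' Relaxes the MMD to a clustering objective with the single center
#' \eqn{\mu = \delta\mu_s + (1-\delta)\mu_t}: returns
#' \eqn{\sum_k \varsigma_k \|\phi(x_k)-\mu\|^2} with fixed memberships
#' \eqn{\varsigma_k = 2/n} for source samples and \eqn{2/m} for target
#' samples, which upper-bounds [mmd_empirical()] for every \eqn{\delta \in
#' [0,1]}: by the squared triangle inequality \eqn{\|\hat\mu_s -
#' \hat\mu_t\|^2 \le 2\|\hat\mu_s - \mu\|^2 + 2\|\hat\mu_t - \mu\|^2} and by
#' Jensen \eqn{\|\hat\mu_s - \mu\|^2 \le \frac{1}{n}\sum_i \|\phi(x_i) -
#' \mu\|^2}. (Weights of order \eqn{1/n^2} — i.e. dropping the factor
#' \eqn{2n} — do *not* dominate the MMD: the package's vignette discusses
#' this correction.)
#'
#' @inheritParams mmd_empirical
#' @param delta Blend weight of the source mean in the cluster center.
#' @return Non-negative scalar.
#' @export
one_cluster_bound <- function(gram, source_idx, target_idx, delta = 0.5) {
  stopifnot(inherits(gram, "gram_matrix"))
  source_idx <- as.integer(source_idx); target_idx <- as.integer(target_idx)
  if (length(source_idx) == 0L || length(target_idx) == 0L)
    stop("index sets must be non-empty")
  n <- length(source_idx); m <- length(target_idx)
  N <- gram$sample_count
  a <- numeric(N)
  a[source_idx] <- delta / n
  a[target_idx] <- (1 - delta) / m
  K <- gram$values
  Ka <- as.vector(K %*% a)
  quad <- sum(a * Ka)
  d <- diag(K) - 2 * Ka + quad     # ||phi(x_k) - mu||^2 for every sample
  d[d < 0] <- 0
  2 * sum(d[source_idx]) / n + 2 * sum(d[target_idx]) / m
}

#' Possibilistic distance objective with fuzzy-entropy regularization
#'
#' Evaluates
#' \deqn{\sum_{c,k} \lambda_{k,c}^2 J_{k,c} + \beta \sum_{c,k}
#'   (\lambda_{k,c}^2 \ln \lambda_{k,c}^2 - \lambda_{k,c}^2)}
#' with the convention \eqn{0 \ln 0 = 0}. `costs` is typically the matrix of
#' squared RKHS mean distances \eqn{d_{k,c}} (the pure distribution-distance
#' objective); adding the per-sample classifier residuals via `residuals`
#' gives the full membership subproblem that [update_memberships()]
#' minimizes. `NA` columns (inactive classes) are skipped.
#'
#' @param memberships N x (C+1) matrix of memberships \eqn{\lambda_{k,c}} in
#'   \eqn{[0,1]}.
#' @param costs N x (C+1) matrix of non-negative costs \eqn{d_{k,c}}.
#' @param beta Positive fuzzy-entropy weight.
#' @param residuals Optional length-N vector of squared classifier residuals
#'   \eqn{e_k}, added to every active column of `costs`.
#' @return Scalar objective value.
#' @export
pddm_objective <- function(memberships, costs, beta, residuals = NULL) {
  lam <- as.matrix(memberships)
  d <- as.matrix(costs)
  if (!all(dim(lam) == dim(d))) stop("membership/cost shapes differ")
  if (!is.numeric(beta) || beta <= 0) stop("'beta' must be positive")
  if (!is.null(residuals)) {
    if (length(residuals) != nrow(d)) stop("residual length mismatch")
    d <- d + residuals          # recycled down each column
  }
  l2 <- lam^2
  ent <- ifelse(l2 > 0, l2 * log(l2) - l2, 0)
  keep <- is.finite(d)
  sum(l2[keep] * d[keep]) + beta * sum(ent[keep])
}

#' Closed-form membership update
#'
#' The membership subproblem
#' \eqn{\min_\lambda \sum \lambda^2 (d_{k,c} + e_k) + \beta(\lambda^2 \ln
#' \lambda^2 - \lambda^2)} decouples over entries; its stationary point in
#' \eqn{(0, 1]} is \eqn{\lambda_{k,c}^2 = \exp(-(d_{k,c} + e_k)/\beta)}.
#' Samples far from a mean, or badly fit by the current classifier, therefore
#' receive exponentially small weight — the mechanism that immunizes the
#' domain alignment against outliers. Exponents below -700 underflow to an
#' exact 0; inactive-class columns (`NA` costs) get membership 0.
#'
#' @param mean_distances N x (C+1) matrix of squared RKHS mean distances.
#' @param residuals Length-N vector of squared classifier residuals
#'   \eqn{e_k} (enters every class column identically); defaults to zeros.
#' @param beta Positive fuzzy-entropy weight.
#' @return N x (C+1) membership matrix with entries in \eqn{[0, 1]}.
#' @export
update_memberships <- function(mean_distances, residuals = NULL, beta) {
  d <- as.matrix(mean_distances)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a positive scalar")
  if (is.null(residuals)) residuals <- numeric(nrow(d))
  if (length(residuals) != nrow(d)) stop("residual length mismatch")
  if (any(residuals < 0) || any(d[is.finite(d)] < 0))
    stop("distances and residuals must be non-negative")
  ex <- -(d + residuals) / beta        # log lambda^2
  lam <- matrix(0, nrow(d), ncol(d))
  ok <- is.finite(ex) & ex > -700
  lam[ok] <- exp(ex[ok] / 2)
  lam
}
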