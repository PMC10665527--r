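#' Explicit feature map for the linear classifier
#'
#' The classifier operates in an explicit feature space so that the row-wise
#' l2,1 penalty is well defined. Two maps are available:
#'
#' * `"identity"`: the raw features (linear classifier with bias).
#' * `"random_fourier"`: a seeded random Fourier feature map
#'   \eqn{z(x) = \sqrt{2/D}\,\cos(x^\top \omega_j + b_j)}, with
#'   \eqn{\omega_j \sim N(0, I/\sigma^2)} and \eqn{b_j \sim U[0, 2\pi]},
#'   approximating the Gaussian kernel of bandwidth `sigma`.
#'
#' A constant-1 bias column is appended by [apply_feature_map()] in either
#' mode.
#'
#' @param type `"identity"` or `"random_fourier"`.
#' @param sigma Gaussian bandwidth matched by the random Fourier map.
#' @param dimension Number of random Fourier features D (default 300).
#' @param seed Integer seed for the random frequencies.
#' @param input_dim Ambient feature dimension d (required for
#'   `"random_fourier"`).
#' @return Object of class `"feature_map"`.
#' @export
feature_map <- function(type = c("identity", "random_fourier"),
                        sigma = 1, dimension = 300L, seed = 1L,
                        input_dim = NULL) {
  type <- match.arg(type)
  fm <- list(type = type)
  if (type == "random_fourier") {
    if (is.null(input_dim)) stop("'input_dim' required for random_fourier")
    if (sigma <= 0) stop("'sigma' must be positive")
    fm$sigma <- sigma
    fm$dimension <- as.integer(dimension)
    fm$seed <- as.integer(seed)
    draws <- with_seed(seed, list(
      omega = matrix(stats::rnorm(input_dim * as.integer(dimension),
                                  sd = 1 / sigma),
                     input_dim, as.integer(dimension)),
      phase = stats::runif(as.integer(dimension), 0, 2 * pi)))
    fm$omega <- draws$omega
    fm$phase <- draws$phase
  }
  structure(fm, class = "feature_map")
}

#' Apply a feature map and append the bias column
#'
#' @param fm A [feature_map()].
#' @param features N x d numeric matrix.
#' @return N x (p+1) matrix whose last column is constant 1.
#' @export
apply_feature_map <- function(fm, features) {
  x <- as_feature_matrix(features)
  z <- switch(fm$type,
    identity = x,
    random_fourier =
      sqrt(2 / fm$dimension) *
        cos(sweep(x %*% fm$omega, 2L, fm$phase, "+"))
  )
  cbind(z, bias = 1)
}

l21_norm <- function(W) sum(sqrt(rowSums(W^2)))

l21_objective <- function(W, X, Y, w, rho) {
  R <- X %*% W - Y
  sum(w * rowSums(R^2)) + rho * l21_norm(W)
}

#' Membership-weighted l2,1-regularized least squares
#'
#' Fits \eqn{\min_W \sum_k \omega_k \|\tilde x_k^\top W - y_k\|^2 +
#' \rho \|W\|_{2,1}} by iteratively reweighted least squares: alternate the
#' closed form \eqn{W = (\tilde X^\top \Omega \tilde X + \rho U)^{-1}
#' \tilde X^\top \Omega Y} with the majorizer refresh
#' \eqn{U_{ii} = 1 / (2\|w^i\| + \epsilon)}. The l2,1 penalty (sum of row
#' norms of W) drives entire feature rows to zero, performing feature
#' selection; the half-quadratic U refresh guarantees a monotonically
#' non-increasing objective. With `rho = 0` and a singular normal matrix the
#' system is solved by pseudo-inverse with a warning.
#'
#' @param features_aug N x (p+1) bias-augmented feature matrix.
#' @param targets N x C numeric target (label) matrix.
#' @param sample_weights Length-N non-negative weights \eqn{\omega_k};
#'   default all ones.
#' @param rho Non-negative l2,1 penalty weight.
#' @param max_irls Maximum IRLS iterations.
#' @param tol Relative objective-change stopping tolerance.
#' @param eps_reg Floor inside the U refresh keeping it finite at zero rows.
#' @return Object of class `"l21_fit"`: list with `weights` (W), `U`
#'   (final diagonal entries), `objective` (per-iteration trace),
#'   `iterations`, `converged`.
#' @export
fit_weighted_l21 <- function(features_aug, targets, sample_weights = NULL,
                             rho = 0, max_irls = 50L, tol = 1e-10,
                             eps_reg = 1e-8) {
  X <- as.matrix(features_aug)
  Y <- as.matrix(targets)
  N <- nrow(X); p <- ncol(X)
  if (nrow(Y) != N) stop("feature/target row mismatch")
  if (is.null(sample_weights)) sample_weights <- rep(1, N)
  w <- as.numeric(sample_weights)
  if (length(w) != N || any(w < 0)) stop("invalid sample weights")
  if (all(w == 0)) stop("at least one sample weight must be positive")
  if (rho < 0) stop("'rho' must be non-negative")

  XtO <- t(X * w)                    # X' Omega
  G <- XtO %*% X                     # X' Omega X
  rhs <- XtO %*% Y

  solve_normal <- function(Gp) {
    out <- tryCatch(solve(Gp, rhs), error = function(e) NULL)
    if (is.null(out)) {
      warning("singular normal matrix; using pseudo-inverse")
      out <- pseudo_solve(Gp, rhs)
    }
    out
  }

  if (rho == 0) {
    W <- solve_normal(G)
    U <- 1 / (2 * sqrt(rowSums(W^2)) + eps_reg)
    obj <- l21_objective(W, X, Y, w, rho)
    return(structure(list(weights = W, U = U, objective = obj,
                          iterations = 1L, converged = TRUE),
                     class = "l21_fit"))
  }

  U <- rep(1, p)
  obj <- numeric(0)
  W <- NULL
  converged <- FALSE
  for (it in seq_len(max_irls)) {
    W <- solve_normal(G + diag(rho * U, p))
    U <- 1 / (2 * sqrt(rowSums(W^2)) + eps_reg)
    obj[it] <- l21_objective(W, X, Y, w, rho)
    if (it > 1L && abs(obj[it] - obj[it - 1L]) <=
          tol * max(1, abs(obj[it - 1L]))) {
      converged <- TRUE
      break
    }
  }
  structure(list(weights = W, U = U, objective = obj,
                 iterations = length(obj), converged = converged),
            class = "l21_fit")
}

# Minimum-norm least-squares solve via SVD.
pseudo_solve <- function(A, B, tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% B))
}

#' Per-sample squared prediction residuals
#'
#' \eqn{e_k = \|\tilde x_k^\top W - y_k\|^2}, the quantity that enters the
#' membership update: badly fit samples are downweighted in the next
#' alignment round.
#'
#' @param fit An `"l21_fit"` (or a bare weight matrix).
#' @param features_aug N x (p+1) bias-augmented features.
#' @param targets N x C target matrix.
#' @return Length-N non-negative vector.
#' @export
squared_residuals <- function(fit, features_aug, targets) {
  W <- if (inherits(fit, "l21_fit")) fit$weights else as.matrix(fit)
  R <- as.matrix(features_aug) %*% W - as.matrix(targets)
  rowSums(R^2)
}

#' Predict class scores and labels from a fitted linear classifier
#'
#' @param object An `"l21_fit"`.
#' @param features_aug Bias-augmented feature matrix.
#' @param ... Unused.
#' @return List with `scores` (N x C) and `labels` (argmax per row, ties to
#'   the lowest class index).
#' @export
predict.l21_fit <- function(object, features_aug, ...) {
  S <- as.matrix(features_aug) %*% object$weights
  list(scores = S, labels = as.integer(apply(S, 1L, which.max)))
}

#' Assemble the spectral-update matrix H
#'
#' Substituting the classifier closed form \eqn{W = \tilde A Y} with
#' \eqn{\tilde A = (\tilde X^\top \Omega \tilde X + \rho U)^{-1}
#' \tilde X^\top \Omega} into the joint objective profiles out W and leaves
#' a quadratic form in Y: with the hat-style predictor \eqn{P = \tilde X
#' \tilde A} and \eqn{B = P - I},
#' \deqn{H = \alpha L + B^\top \Omega B \;(+\; \rho \tilde A^\top U \tilde A),}
#' whose constrained trace minimization is solved by [update_labels()].
#' The optional last term (`exact_profile = TRUE`) is the profiled value of
#' the quadratic penalty majorizer \eqn{\rho\,\mathrm{tr}(W^\top U W)} at
#' \eqn{W = \tilde A Y}; including it makes the label update an exact
#' coordinate-descent step on the joint objective rather than dropping the
#' (small) penalty contribution. In the heavy-penalty limit
#' \eqn{\rho \to \infty}, \eqn{P \to 0} and \eqn{H \to \alpha L + \Omega}
#' either way.
#'
#' @param graph An `"affinity_graph"` over the pooled samples.
#' @param features_aug N x (p+1) bias-augmented features.
#' @param sample_weights Length-N non-negative weights \eqn{\omega_k}.
#' @param alpha Non-negative weight of the Laplacian smoothness term.
#' @param rho Non-negative l2,1 penalty weight.
#' @param U Length-(p+1) diagonal of the IRLS majorizer at the current fit
#'   (take it from [fit_weighted_l21()]); defaults to ones.
#' @param exact_profile Include the profiled penalty term (default `TRUE`).
#' @return N x N symmetric matrix H.
#' @export
assemble_H <- function(graph, features_aug, sample_weights, alpha, rho,
                       U = NULL, exact_profile = TRUE) {
  profile_classifier(graph, features_aug, sample_weights, alpha, rho, U,
                     exact_profile)$H
}

# H together with the profiling matrix A, so the solver can materialize
# W = A Y after the spectral step.
profile_classifier <- function(graph, features_aug, sample_weights, alpha,
                               rho, U = NULL, exact_profile = TRUE) {
  stopifnot(inherits(graph, "affinity_graph"))
  X <- as.matrix(features_aug)
  N <- nrow(X); p <- ncol(X)
  w <- as.numeric(sample_weights)
  if (length(w) != N) stop("weight length mismatch")
  if (is.null(U)) U <- rep(1, p)
  XtO <- t(X * w)
  G <- XtO %*% X + diag(rho * U, p)
  A <- tryCatch(solve(G, XtO), error = function(e) pseudo_solve(G, XtO))
  B <- X %*% A
  diag(B) <- diag(B) - 1            # B = P - I
  H <- alpha * graph$laplacian + crossprod(B * sqrt(w))
  if (exact_profile && rho > 0)
    H <- H + rho * crossprod(A * sqrt(U))
  list(H = (H + t(H)) / 2, A = A)
}

#' Write / read classifier weights as delimited text
#'
#' The first line is a `#`-prefixed header recording the feature map type,
#' bandwidth and seed so a fit can be reloaded unambiguously.
#'
#' @param fit An `"l21_fit"`.
#' @param path File path.
#' @param fm Optional [feature_map()] whose metadata is recorded.
#' @export
write_classifier <- function(fit, path, fm = NULL) {
  hdr <- if (is.null(fm) || fm$type == "identity") "# feature_map=identity"
         else sprintf("# feature_map=random_fourier sigma=%.17g dimension=%d seed=%d",
                      fm$sigma, fm$dimension, fm$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(fit$weights, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_classifier
#' @return `read_classifier` returns a list with `weights` and the parsed
#'   `header` line.
#' @export
read_classifier <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#"))
    stop("not a classifier file: missing header")
  W <- as.matrix(utils::read.table(text = lines[-1L], sep = ","))
  dimnames(W) <- NULL
  list(weights = W, header = sub("^#\\s*", "", lines[1L]))
}
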