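#' Kernel configuration
#'
#' Describes a positive-semidefinite kernel used to embed samples in a
#' reproducing kernel Hilbert space (RKHS). Four families are supported:
#'
#' * `"gaussian"`: \eqn{k(x, y) = \exp(-\|x-y\|^2 / (2 (\sigma/\theta)^2))}.
#'   The divisor `theta >= 1` shrinks the effective bandwidth below `sigma`;
#'   `theta = 1` gives the plain Gaussian kernel.
#' * `"inverse_square_distance"`: \eqn{k(x, y) = 1 / (1 + \sigma \|x-y\|^2)}.
#' * `"laplacian"`: \eqn{k(x, y) = \exp(-\sigma \|x-y\|)}.
#' * `"inverse_distance"`: \eqn{k(x, y) = 1 / (1 + \sigma \|x-y\|)}.
#'
#' For the non-Gaussian families `sigma` multiplies the distance (it acts as
#' an inverse bandwidth) and `theta` is ignored. A multi-kernel configuration
#' is built by passing a list of component configurations in `components`;
#' the resulting Gram matrix is the entrywise sum of the component Grams,
#' which is the Gram matrix of the concatenated feature map
#' \eqn{\tilde\phi(x) = [\phi_1(x); \ldots; \phi_A(x)]}.
#'
#' @param family One of `"gaussian"`, `"inverse_square_distance"`,
#'   `"laplacian"`, `"inverse_distance"`.
#' @param sigma Positive bandwidth (Gaussian) or scale multiplier (others).
#'   `NULL` defers to a data-driven heuristic at Gram construction time
#'   (see [default_sigma()]).
#' @param theta Bandwidth divisor in `[1, theta0]`; Gaussian family only.
#' @param theta0 Upper limit for `theta` (default 10).
#' @param components Optional non-empty list of `kernel_config` objects for
#'   multi-kernel mode; when given, the other arguments are ignored.
#' @return An object of class `"kernel_config"`.
#' @export
kernel_config <- function(family = c("gaussian", "inverse_square_distance",
                                     "laplacian", "inverse_distance"),
                          sigma = NULL, theta = 1, theta0 = 10,
                          components = NULL) {
  if (!is.null(components)) {
    if (!is.list(components) || length(components) == 0L)
      stop("'components' must be a non-empty list of kernel_config objects")
    ok <- vapply(components, inherits, logical(1), "kernel_config")
    if (!all(ok)) stop("all 'components' must be kernel_config objects")
    cfg <- structure(list(family = "multi", components = components),
                     class = "kernel_config")
    return(cfg)
  }
  family <- match.arg(family)
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma <= 0)
      stop("'sigma' must be a positive finite scalar")
  }
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 1 || theta > theta0)
    stop(sprintf("'theta' must lie in [1, %g]", theta0))
  structure(list(family = family, sigma = sigma, theta = theta,
                 theta0 = theta0),
            class = "kernel_config")
}

#' @export
print.kernel_config <- function(x, ...) {
  if (identical(x$family, "multi")) {
    cat("Multi-kernel configuration with", length(x$components),
        "components:\n")
    for (comp in x$components) print(comp)
  } else {
    cat(sprintf("Kernel: %s, sigma = %s, theta = %g\n", x$family,
                if (is.null(x$sigma)) "<data-driven>" else
                  format(x$sigma), x$theta))
  }
  invisible(x)
}

#' Data-driven kernel bandwidth
#'
#' Two heuristics for the Gaussian bandwidth \eqn{\sigma}:
#'
#' * `"mean_norm"`: the square root of the average Euclidean norm of the
#'   samples, multiplied by the class count `C` when `C > 2` (multi-class
#'   problems spread class means further apart, so a wider kernel keeps
#'   cross-class Gram entries informative).
#' * `"median_dist"`: the median of the pairwise Euclidean distances
#'   (the classic median heuristic for kernel two-sample tests).
#'
#' @param features Numeric matrix, rows = samples.
#' @param n_classes Number of classes `C`; used by `"mean_norm"` only.
#' @param method `"mean_norm"` (default) or `"median_dist"`.
#' @return Positive scalar bandwidth.
#' @export
default_sigma <- function(features, n_classes = 2L,
                          method = c("mean_norm", "median_dist")) {
  method <- match.arg(method)
  features <- as_feature_matrix(features)
  if (method == "mean_norm") {
    s <- sqrt(mean(sqrt(rowSums(features^2))))
    if (n_classes > 2L) s <- s * n_classes
  } else {
    dd <- stats::dist(features)
    s <- stats::median(dd[dd > 0])
    if (!is.finite(s) || s <= 0) s <- 1
  }
  if (!is.finite(s) || s <= 0)
    stop("bandwidth heuristic produced a non-positive value; ",
         "supply 'sigma' explicitly")
  s
}

# Coerce a feature table (matrix or data frame of numerics) to a numeric
# matrix, rejecting non-finite values.
as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at row %d, column %d",
                 bad[1L], bad[2L]))
  }
  x
}

# Squared Euclidean distance matrix between rows of x. The diagonal is set
# to an exact zero so kernels of the raw distance keep a unit diagonal.
sq_dist_matrix <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Gram matrix of a kernel over a feature table
#'
#' Evaluates the configured kernel on every sample pair. If `config$sigma`
#' is `NULL` the `"mean_norm"` heuristic of [default_sigma()] is applied with
#' `n_classes` classes. For a multi-kernel configuration the component Grams
#' are summed entrywise (Gram of the concatenated feature map).
#'
#' @param features Numeric matrix or data frame, rows = samples.
#' @param config A [kernel_config()].
#' @param n_classes Class count forwarded to the bandwidth heuristic.
#' @return An object of class `"gram_matrix"`: list with `values` (N x N
#'   symmetric PSD matrix) and `sample_count`.
#' @export
compute_gram <- function(features, config = kernel_config(),
                         n_classes = 2L) {
  x <- as_feature_matrix(features)
  if (nrow(x) == 0L) stop("feature table is empty")
  K <- gram_values(x, config, n_classes)
  K <- (K + t(K)) / 2  # exact symmetry against round-off
  structure(list(values = K, sample_count = nrow(x)),
            class = "gram_matrix")
}

gram_values <- function(x, config, n_classes) {
  if (identical(config$family, "multi")) {
    Ks <- lapply(config$components, gram_values, x = x,
                 n_classes = n_classes)
    return(Reduce(`+`, Ks))
  }
  sigma <- config$sigma
  if (is.null(sigma)) sigma <- default_sigma(x, n_classes)
  d2 <- sq_dist_matrix(x)
  switch(config$family,
    gaussian = {
      eff <- sigma / config$theta
      exp(-d2 / (2 * eff^2))
    },
    inverse_square_distance = 1 / (1 + sigma * d2),
    laplacian = exp(-sigma * sqrt(d2)),
    inverse_distance = 1 / (1 + sigma * sqrt(d2)),
    stop("unknown kernel family: ", config$family)
  )
}

#' Kernel-expansion coefficients of blended domain and class means
#'
#' The whole-domain mean \eqn{\mu_0 = \delta \mu_s + (1-\delta)\mu_t} and the
#' class-conditional means \eqn{\mu_c = \delta \mu_{s,c} + (1-\delta)
#' \mu_{t,c}} (c = 1..C) are all affine combinations of the mapped samples
#' \eqn{\phi(x_k)}; this function returns their coefficient vectors so that
#' RKHS distances can be computed purely through the Gram matrix. Within-class
#' means average over the class members only (weight \eqn{\delta/n_c} per
#' source member of class c, \eqn{(1-\delta)/m_c} per target member). If one
#' domain has no members of a class, the populated side receives full weight;
#' if neither domain has members the class is flagged inactive.
#'
#' @param source_labels Integer labels in 1..C for the n source samples.
#' @param target_labels Integer (pseudo-)labels in 1..C for the m target
#'   samples.
#' @param delta Blend weight in \eqn{[0, 1]} given to the source side.
#' @param n_classes Number of classes C; defaults to the maximum label seen.
#' @return Object of class `"class_means"`: list with `coefficients`
#'   (N x (C+1) matrix; column 1 is the whole-domain mean, column c+1 class
#'   c), `active` (logical length C+1), `delta`, `n_classes`. Rows are
#'   ordered source first, then target.
#' @export
class_mean_coefficients <- function(source_labels, target_labels, delta = 0.5,
                                    n_classes = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1)
    stop("'delta' must lie in [0, 1]")
  src <- as.integer(source_labels)
  tgt <- as.integer(target_labels)
  if (length(src) == 0L || length(tgt) == 0L)
    stop("both domains must contain at least one sample")
  if (any(src < 1L) || any(tgt < 1L)) stop("labels must be positive integers")
  C <- if (is.null(n_classes)) max(src, tgt) else as.integer(n_classes)
  if (C < 1L) stop("need at least one class")
  if (any(src > C) || any(tgt > C)) stop("label exceeds 'n_classes'")
  n <- length(src); m <- length(tgt); N <- n + m
  is_src <- c(rep(TRUE, n), rep(FALSE, m))
  lab <- c(src, tgt)

  A <- matrix(0, N, C + 1L)
  active <- rep(TRUE, C + 1L)
  # column 1: whole-domain mean (delta to the source average, 1-delta target)
  A[is_src, 1L] <- delta / n
  A[!is_src, 1L] <- (1 - delta) / m
  for (c in seq_len(C)) {
    sc <- is_src & lab == c
    tc <- !is_src & lab == c
    nc <- sum(sc); mc <- sum(tc)
    if (nc == 0L && mc == 0L) {
      active[c + 1L] <- FALSE
      next
    }
    if (nc == 0L) {            # only the target side is populated
      A[tc, c + 1L] <- 1 / mc
    } else if (mc == 0L) {     # only the source side is populated
      A[sc, c + 1L] <- 1 / nc
    } else {
      A[sc, c + 1L] <- delta / nc
      A[tc, c + 1L] <- (1 - delta) / mc
    }
  }
  structure(list(coefficients = A, active = active, delta = delta,
                 n_classes = C),
            class = "class_means")
}

#' Squared RKHS distances from every sample to every blended mean
#'
#' Uses the kernel expansion
#' \deqn{\|\phi(x_k) - \mu_c\|^2 = K_{kk} - 2 \sum_j a_{c,j} K_{kj}
#'   + \sum_{i,j} a_{c,i} a_{c,j} K_{ij}}
#' so no explicit feature map is needed. Entries are clamped to 0 after
#' round-off; a value below -1e-10 indicates an inconsistent Gram matrix and
#' raises an error. Columns of inactive classes are filled with `NA`.
#'
#' @param gram A `"gram_matrix"` from [compute_gram()].
#' @param means A `"class_means"` from [class_mean_coefficients()] over the
#'   same N samples.
#' @return N x (C+1) matrix of non-negative distances (column 1 = whole
#'   domain), `NA` for inactive classes.
#' @export
rkhs_mean_distances <- function(gram, means) {
  stopifnot(inherits(gram, "gram_matrix"), inherits(means, "class_means"))
  K <- gram$values
  A <- means$coefficients
  if (nrow(A) != gram$sample_count)
    stop("gram and means were built over different sample counts")
  KA <- K %*% A                      # N x (C+1)
  quad <- colSums(A * KA)            # a_c' K a_c
  D <- diag(K) - 2 * KA + matrix(quad, nrow(A), ncol(A), byrow = TRUE)
  if (any(D[is.finite(D)] < -1e-10))
    stop("negative squared RKHS distance beyond round-off; ",
         "Gram matrix is not PSD")
  D[D < 0] <- 0
  D[, !means$active] <- NA_real_
  D
}
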