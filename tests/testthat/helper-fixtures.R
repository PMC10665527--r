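# Shared fixtures: everything is generated in code under fixed seeds.

random_features <- function(n, d, seed) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# Gram matrix of the linear kernel K = X X', wrapped in the package's
# container so RKHS expansions can be checked against explicit feature-space
# arithmetic (the linear kernel's feature map is the identity).
linear_gram <- function(x) {
  x <- as.matrix(x)
  structure(list(values = tcrossprod(x), sample_count = nrow(x)),
            class = "gram_matrix")
}

# Direct scalar evaluation of the Gaussian kernel entry.
gauss_entry <- function(xi, xj, sigma, theta = 1) {
  exp(-sum((xi - xj)^2) / (2 * (sigma / theta)^2))
}

one_hot_test <- function(labels, C) {
  Y <- matrix(0, length(labels), C)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

# Random orthonormal N x C matrix (QR of a Gaussian draw).
random_orthonormal <- function(N, C) {
  qr.Q(qr(matrix(rnorm(N * C), N, C)))
}

# Small labeled two-domain problem for solver tests.
toy_problem <- function(seed, ...) {
  make_two_domain_blobs(n = 60, m = 60, d = 5, n_classes = 3, seed = seed,
                        ...)
}
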