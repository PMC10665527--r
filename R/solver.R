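#' Control parameters for the C-PDDM solver
#'
#' @param alpha Positive weight of the graph-Laplacian label-smoothness term.
#' @param beta Positive fuzzy-entropy weight in the membership update; larger
#'   values keep memberships closer to 1 (less aggressive downweighting).
#' @param rho Positive weight of the l2,1 classifier penalty.
#' @param delta Blend weight in \eqn{[0,1]} of the source side in the
#'   whole-domain and class means (0.5 treats the domains symmetrically).
#' @param upsilon Fusion weight in \eqn{[0,1]} given to the source-trained
#'   classifier at prediction time (default 0.9: source labels are trusted
#'   prior knowledge, the self-trained target classifier refines them).
#' @param k_neighbors Nearest-neighbor count of the affinity graph; the
#'   customary search grid is `c(3, 5, 10, 15, 17)`.
#' @param kernel A [kernel_config()] for the domain-alignment Gram matrix.
#' @param sigma_graph Affinity bandwidth; `NULL` = median included-edge
#'   distance.
#' @param epsilon Absolute stopping tolerance on the objective trace.
#' @param max_iter Maximum number of alternating iterations Z.
#' @param refresh_pseudo_labels Refresh target pseudo-labels (hence class
#'   means and residual targets) from the discretized label matrix every
#'   iteration (dynamic pseudo-labeling, the default); `FALSE` freezes the
#'   initial pseudo-labels, for ablation.
#' @param map_type Classifier feature space: `"identity"` (linear, exact) or
#'   `"random_fourier"` (Gaussian-kernel approximation with a well-defined
#'   row-sparsity penalty).
#' @param rf_dimension Random Fourier dimension when
#'   `map_type = "random_fourier"`.
#' @param seed Integer seed controlling the random Fourier draw (and any
#'   other solver randomness).
#' @return Object of class `"cpddm_control"`.
#' @export
cpddm_control <- function(alpha = 1, beta = 1, rho = 1, delta = 0.5,
                          upsilon = 0.9, k_neighbors = 5L,
                          kernel = kernel_config(), sigma_graph = NULL,
                          epsilon = 1e-5, max_iter = 50L,
                          refresh_pseudo_labels = TRUE,
                          map_type = c("identity", "random_fourier"),
                          rf_dimension = 300L, seed = 1L) {
  map_type <- match.arg(map_type)
  stopifnot(alpha >= 0, beta > 0, rho >= 0, delta >= 0, delta <= 1,
            upsilon >= 0, upsilon <= 1, k_neighbors >= 1,
            inherits(kernel, "kernel_config"), epsilon > 0, max_iter >= 0)
  structure(list(alpha = alpha, beta = beta, rho = rho, delta = delta,
                 upsilon = upsilon, k_neighbors = as.integer(k_neighbors),
                 kernel = kernel, sigma_graph = sigma_graph,
                 epsilon = epsilon, max_iter = as.integer(max_iter),
                 refresh_pseudo_labels = isTRUE(refresh_pseudo_labels),
                 map_type = map_type, rf_dimension = as.integer(rf_dimension),
                 seed = as.integer(seed)),
            class = "cpddm_control")
}

# Per-sample membership weight: the coefficient the k-th squared residual
# carries in the joint objective is sum_c lambda_{k,c}^2.
membership_weights <- function(lam) rowSums(lam^2)

# Joint objective at a consistent state. `Y` supplies both the smoothness
# term and the residual targets.
cpddm_theta <- function(state, Y) {
  e <- squared_residuals(state$fit, state$Xa, Y)
  pddm_objective(state$lam, state$dist, state$control$beta, residuals = e) +
    state$control$alpha * label_propagation_loss(state$graph, Y) +
    state$control$rho * l21_norm(state$fit$weights)
}

# Recompute blended means and RKHS distances for the current pseudo-labels.
refresh_distances <- function(state) {
  means <- class_mean_coefficients(state$ys, state$pseudo,
                                   delta = state$control$delta,
                                   n_classes = state$C)
  state$means <- means
  state$dist <- rkhs_mean_distances(state$gram, means)
  state
}

#' Initialize the C-PDDM solver state (hot start)
#'
#' A classifier is first fit on the source domain alone and used to
#' pseudo-label the target samples. Blended whole-domain and class means are
#' computed with blend weight `delta`; memberships, the joint classifier and
#' the label matrix are then initialized by one pass of their respective
#' closed-form updates, and the objective is recorded.
#'
#' @param source_features n x d numeric matrix (or data frame).
#' @param source_labels Integer labels 1..C for the source rows.
#' @param target_features m x d numeric matrix.
#' @param control A [cpddm_control()].
#' @return Object of class `"cpddm_state"` holding the memberships,
#'   classifier, label matrices, Gram matrix, graph and the objective trace.
#' @export
cpddm_initialize <- function(source_features, source_labels, target_features,
                             control = cpddm_control()) {
  stopifnot(inherits(control, "cpddm_control"))
  Xs <- as_feature_matrix(source_features)
  Xt <- as_feature_matrix(target_features)
  if (ncol(Xs) != ncol(Xt)) stop("domains differ in feature dimension")
  ys <- as.integer(source_labels)
  if (length(ys) != nrow(Xs)) stop("source label length mismatch")
  C <- max(ys)
  if (C < 2L) stop("need at least two classes")
  if (!setequal(unique(ys), seq_len(C)))
    stop("every class 1..C must appear in the source labels")

  n <- nrow(Xs); m <- nrow(Xt); N <- n + m
  if (control$k_neighbors >= N) stop("'k_neighbors' must be < n + m")
  X <- rbind(Xs, Xt)
  src <- c(rep(TRUE, n), rep(FALSE, m))

  kernel <- control$kernel
  sigma_used <- kernel$sigma
  if (identical(kernel$family, "gaussian") && is.null(kernel$sigma)) {
    sigma_used <- default_sigma(X, n_classes = C)
    kernel$sigma <- sigma_used
  }
  fm <- if (control$map_type == "identity") feature_map("identity")
        else feature_map("random_fourier",
                         sigma = if (is.null(sigma_used)) default_sigma(X, C)
                                 else sigma_used,
                         dimension = control$rf_dimension,
                         seed = control$seed, input_dim = ncol(X))
  Xa <- apply_feature_map(fm, X)
  gram <- compute_gram(X, kernel, n_classes = C)
  graph <- build_affinity(X, k = control$k_neighbors,
                          sigma_graph = control$sigma_graph)

  # hot start: source-only classifier pseudo-labels the target
  src_fit <- fit_weighted_l21(Xa[src, , drop = FALSE], one_hot(ys, C),
                              rho = control$rho)
  pseudo <- predict(src_fit, Xa[!src, , drop = FALSE])$labels
  Ys <- one_hot(ys, C)
  Ydisc <- rbind(Ys, one_hot(pseudo, C))

  state <- structure(list(
    X = X, Xa = Xa, fm = fm, gram = gram, graph = graph,
    n = n, m = m, N = N, C = C, src = src, ys = ys, pseudo = pseudo,
    Ys = Ys, Ydisc = Ydisc, Yrot = NULL,
    control = control, kernel = kernel, source_fit = src_fit,
    iterations = 0L, converged = FALSE,
    trace = data.frame()), class = "cpddm_state")
  state <- refresh_distances(state)

  # one pass of the three closed-form updates; the orthonormal relaxed label
  # matrix (Procrustes-aligned to the source block) becomes the working
  # target so that every later update is a descent step on one objective
  e0 <- squared_residuals(src_fit, Xa, Ydisc)
  state$lam <- update_memberships(state$dist, e0, control$beta)
  omega <- membership_weights(state$lam)
  state$fit <- fit_weighted_l21(Xa, Ydisc, omega, rho = control$rho)
  prof <- profile_classifier(graph, Xa, omega, control$alpha, control$rho,
                             U = state$fit$U)
  upd <- update_labels(prof$H, C, src, Ys)
  state$Ydisc <- upd$discrete
  state$Yrot <- upd$rotated
  state$fit$weights <- prof$A %*% state$Yrot
  if (control$refresh_pseudo_labels) {
    state$pseudo <- upd$labels[!src]
    state <- refresh_distances(state)
  }
  state$trace <- data.frame(
    iter = 0L,
    theta_relaxed = cpddm_theta(state, state$Yrot),
    theta_discrete = cpddm_theta(state, state$Ydisc),
    labels_changed = NA_integer_,
    lambda_q10 = unname(stats::quantile(state$lam[, 1L], 0.10)),
    lambda_q50 = unname(stats::quantile(state$lam[, 1L], 0.50)),
    lambda_q90 = unname(stats::quantile(state$lam[, 1L], 0.90)))
  state
}

#' Run the alternating C-PDDM optimization
#'
#' Repeats the three closed-form updates — memberships, classifier, spectral
#' label matrix — until the absolute change of the joint objective
#' (evaluated with the discretized label matrix, the quantity the algorithm
#' observes) drops below `control$epsilon`, or `control$max_iter` iterations
#' have run. Both the relaxed-label and discretized-label objective values
#' are recorded per iteration.
#'
#' @inheritParams cpddm_initialize
#' @param state Optionally, a pre-built state from [cpddm_initialize()]
#'   (then the feature arguments are ignored).
#' @return A fitted `"cpddm_state"` with `converged`, `iterations` and the
#'   per-iteration `trace` filled in.
#' @export
cpddm_fit <- function(source_features, source_labels, target_features,
                      control = cpddm_control(), state = NULL) {
  if (is.null(state))
    state <- cpddm_initialize(source_features, source_labels,
                              target_features, control)
  stopifnot(inherits(state, "cpddm_state"))
  control <- state$control
  for (z in seq_len(control$max_iter)) {
    prev_theta <- state$trace$theta_discrete[nrow(state$trace)]
    prev_labels <- state$pseudo

    e <- squared_residuals(state$fit, state$Xa, state$Yrot)
    state$lam <- update_memberships(state$dist, e, control$beta)
    omega <- membership_weights(state$lam)
    state$fit <- fit_weighted_l21(state$Xa, state$Yrot, omega,
                                  rho = control$rho)
    prof <- profile_classifier(state$graph, state$Xa, omega, control$alpha,
                               control$rho, U = state$fit$U)
    upd <- update_labels(prof$H, state$C, state$src, state$Ys)
    state$Ydisc <- upd$discrete
    state$Yrot <- upd$rotated
    state$fit$weights <- prof$A %*% state$Yrot
    if (control$refresh_pseudo_labels) {
      state$pseudo <- upd$labels[!state$src]
      state <- refresh_distances(state)
    }

    th_rel <- cpddm_theta(state, state$Yrot)
    th_disc <- cpddm_theta(state, state$Ydisc)
    if (!is.finite(th_rel) || !is.finite(th_disc))
      stop("non-finite objective at iteration ", z,
           "; check kernel bandwidth and 'beta'")
    state$trace <- rbind(state$trace, data.frame(
      iter = z, theta_relaxed = th_rel, theta_discrete = th_disc,
      labels_changed = sum(state$pseudo != prev_labels),
      lambda_q10 = unname(stats::quantile(state$lam[, 1L], 0.10)),
      lambda_q50 = unname(stats::quantile(state$lam[, 1L], 0.50)),
      lambda_q90 = unname(stats::quantile(state$lam[, 1L], 0.90))))
    state$iterations <- z
    if (abs(th_disc - prev_theta) < control$epsilon) {
      state$converged <- TRUE
      break
    }
  }
  state
}

#' Fused source/target prediction for the target domain
#'
#' Refits a source classifier on the source rows (true labels) and a target
#' classifier on the target rows (inferred labels), both weighted by the
#' final memberships so that downweighted outliers keep a small vote, and
#' scores each target sample by \eqn{\upsilon f_s(x) + (1-\upsilon) f_t(x)}.
#'
#' @param state A fitted `"cpddm_state"`.
#' @param upsilon Fusion weight; defaults to the control value.
#' @return List with `labels` (length-m integer predictions), `scores`
#'   (m x C fused score matrix), and the two component fits `fit_source`,
#'   `fit_target`.
#' @export
cpddm_predict <- function(state, upsilon = NULL) {
  stopifnot(inherits(state, "cpddm_state"))
  if (is.null(upsilon)) upsilon <- state$control$upsilon
  stopifnot(upsilon >= 0, upsilon <= 1)
  omega <- membership_weights(state$lam)
  src <- state$src
  rho <- state$control$rho
  fs <- fit_weighted_l21(state$Xa[src, , drop = FALSE], state$Ys,
                         omega[src], rho = rho)
  ft <- fit_weighted_l21(state$Xa[!src, , drop = FALSE],
                         one_hot(state$pseudo, state$C),
                         omega[!src], rho = rho)
  Xt <- state$Xa[!src, , drop = FALSE]
  S <- upsilon * (Xt %*% fs$weights) + (1 - upsilon) * (Xt %*% ft$weights)
  list(labels = as.integer(apply(S, 1L, which.max)), scores = S,
       fit_source = fs, fit_target = ft)
}

#' Accuracy and confusion matrix of a prediction
#'
#' @param predicted,truth Equal-length integer label vectors in 1..C.
#' @param n_classes Class count; defaults to the maximum label seen.
#' @return List with `accuracy` (fraction of matches) and `confusion`
#'   (C x C matrix, rows = true class, columns = predicted class).
#' @export
evaluate_predictions <- function(predicted, truth, n_classes = NULL) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  C <- if (is.null(n_classes)) max(predicted, truth) else
    as.integer(n_classes)
  if (any(predicted < 1L | predicted > C) || any(truth < 1L | truth > C))
    stop("labels must lie in 1..", C)
  conf <- matrix(0L, C, C,
                 dimnames = list(true = seq_len(C), predicted = seq_len(C)))
  for (i in seq_along(truth))
    conf[truth[i], predicted[i]] <- conf[truth[i], predicted[i]] + 1L
  list(accuracy = mean(predicted == truth), confusion = conf)
}

#' Mean-shift MMD alignment baseline
#'
#' The classical non-robust recipe: translate the target domain by the
#' difference of the raw domain means (which aligns the empirical mean
#' embeddings of a linear kernel exactly), then predict with a classifier
#' trained on the source domain only. Outliers shift the source mean, so
#' this baseline degrades when the source is contaminated — the failure mode
#' the possibilistic weighting is designed to avoid.
#'
#' @param source_features,source_labels Labeled source domain.
#' @param target_features Unlabeled target domain.
#' @param rho l2,1 penalty of the source classifier.
#' @return List with `labels` and `scores` for the target rows.
#' @export
mean_shift_baseline <- function(source_features, source_labels,
                                target_features, rho = 1) {
  Xs <- as_feature_matrix(source_features)
  Xt <- as_feature_matrix(target_features)
  ys <- as.integer(source_labels)
  C <- max(ys)
  shift <- colMeans(Xs) - colMeans(Xt)
  Xt_aligned <- sweep(Xt, 2L, shift, "+")
  fit <- fit_weighted_l21(cbind(Xs, 1), one_hot(ys, C), rho = rho)
  S <- cbind(Xt_aligned, 1) %*% fit$weights
  list(labels = as.integer(apply(S, 1L, which.max)), scores = S)
}

#' @export
print.cpddm_state <- function(x, ...) {
  cat(sprintf(
    "C-PDDM state: n = %d source, m = %d target, C = %d classes\n",
    x$n, x$m, x$C))
  cat(sprintf("  iterations: %d (converged: %s)\n", x$iterations,
              x$converged))
  if (nrow(x$trace) > 0L) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  objective (discrete labels): %.6g\n",
                last$theta_discrete))
    cat(sprintf("  whole-domain membership quantiles (q10/q50/q90): %.3g / %.3g / %.3g\n",
                last$lambda_q10, last$lambda_q50, last$lambda_q90))
  }
  invisible(x)
}
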