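#' Seeded two-domain Gaussian-blob generator
#'
#' Generates a labeled source domain and an unlabeled (but ground-truthed)
#' target domain with a controllable covariate shift, far outliers and
#' flipped source labels — the contaminated-domain setting the possibilistic
#' distance metric is built for. The C class means sit on the vertices of a
#' scaled coordinate simplex (`class_separation` times the unit basis
#' vectors e_1..e_C, requiring `d >= n_classes`); both domains draw
#' isotropic unit-variance Gaussians around them, the target after a common
#' translation by a random unit vector times `shift_magnitude`. A fraction
#' of source rows is replaced by far outliers placed at distance
#' `outlier_scale * class_separation` from the centroid of the class means
#' (far from every class), which drags the naive domain mean — the mean
#' shift the membership weighting must absorb. Fractional counts are rounded
#' half away from zero.
#'
#' @param n,m Source and target sample counts (each at least `n_classes`).
#' @param d Feature dimension (at least `n_classes`).
#' @param n_classes Number of classes C.
#' @param class_separation Distance scale between class means (default 4:
#'   clearly separated unit-variance clusters).
#' @param shift_magnitude Length of the source-to-target translation
#'   (default 1).
#' @param outlier_fraction Fraction of source rows replaced by outliers, in
#'   `[0, 1)`.
#' @param outlier_scale Outlier distance in units of `class_separation`
#'   (default 10).
#' @param label_noise_fraction Fraction of source labels flipped uniformly
#'   to a different class, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @return List of class `"synthetic_bundle"`: `source` (list with
#'   `features`, `labels` true labels, `labels_noisy`, `outlier` flag
#'   vector), `target` (list with `features`, `labels` held-out truth),
#'   `ground_truth` (class means, shift vector, generator arguments).
#' @export
make_two_domain_blobs <- function(n = 100L, m = 100L, d = 5L,
                                  n_classes = 3L, class_separation = 4,
                                  shift_magnitude = 1,
                                  outlier_fraction = 0, outlier_scale = 10,
                                  label_noise_fraction = 0, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m); d <- as.integer(d)
  C <- as.integer(n_classes)
  if (C < 2L) stop("need at least two classes")
  if (n < C || m < C) stop("each domain needs at least one sample per class")
  if (d < C) stop("'d' must be at least 'n_classes' for simplex means")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("'outlier_fraction' must lie in [0, 1)")
  if (label_noise_fraction < 0 || label_noise_fraction >= 1)
    stop("'label_noise_fraction' must lie in [0, 1)")
  stopifnot(class_separation > 0, shift_magnitude >= 0, outlier_scale > 0)

  means <- matrix(0, C, d)
  means[cbind(seq_len(C), seq_len(C))] <- class_separation

  with_seed(seed, {
    balanced <- function(total) sample(rep_len(seq_len(C), total))
    ys <- balanced(n)
    yt <- balanced(m)
    Xs <- means[ys, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
    shift_dir <- stats::rnorm(d)
    shift_dir <- shift_dir / sqrt(sum(shift_dir^2))
    shift <- shift_dir * shift_magnitude
    Xt <- means[yt, , drop = FALSE] + matrix(stats::rnorm(m * d), m, d)
    Xt <- sweep(Xt, 2L, shift, "+")

    n_out <- as.integer(round_half_away(outlier_fraction * n))
    outlier <- rep(FALSE, n)
    if (n_out > 0L) {
      idx <- sample(n, n_out)
      outlier[idx] <- TRUE
      centroid <- colMeans(means)
      for (i in idx) {
        dir <- stats::rnorm(d)
        dir <- dir / sqrt(sum(dir^2))
        Xs[i, ] <- centroid + dir * outlier_scale * class_separation
      }
    }

    noisy <- inject_label_noise(ys, label_noise_fraction, C,
                                seed = seed + 1L)

    colnames(Xs) <- colnames(Xt) <- paste0("f", seq_len(d))
    structure(list(
      source = list(features = Xs, labels = ys,
                    labels_noisy = noisy$labels, outlier = outlier),
      target = list(features = Xt, labels = yt),
      ground_truth = list(
        means = means, shift = shift,
        args = list(n = n, m = m, d = d, n_classes = C,
                    class_separation = class_separation,
                    shift_magnitude = shift_magnitude,
                    outlier_fraction = outlier_fraction,
                    outlier_scale = outlier_scale,
                    label_noise_fraction = label_noise_fraction,
                    seed = as.integer(seed)))),
      class = "synthetic_bundle")
  })
}

#' Flip an exact fraction of labels uniformly at random
#'
#' Exactly `round_half_away(fraction * length(labels))` uniformly chosen
#' rows receive a uniformly chosen *different* label in 1..C.
#'
#' @param labels Integer label vector in 1..C.
#' @param fraction Flip fraction in `[0, 1)`.
#' @param n_classes Class count C (at least 2).
#' @param seed Integer seed.
#' @return List with `labels` (noisy vector) and `flipped` (logical mask of
#'   altered rows).
#' @export
inject_label_noise <- function(labels, fraction, n_classes, seed = 1L) {
  labels <- as.integer(labels)
  C <- as.integer(n_classes)
  if (C < 2L) stop("label flipping needs at least two classes")
  if (fraction < 0 || fraction >= 1) stop("'fraction' must lie in [0, 1)")
  n_flip <- as.integer(round_half_away(fraction * length(labels)))
  flipped <- rep(FALSE, length(labels))
  out <- labels
  if (n_flip > 0L) {
    with_seed(seed, {
      idx <- sample(length(labels), n_flip)
      for (i in idx) {
        alternatives <- setdiff(seq_len(C), labels[i])
        out[i] <- if (length(alternatives) == 1L) alternatives else
          sample(alternatives, 1L)
      }
      flipped[idx] <- TRUE
    })
  }
  list(labels = out, flipped = flipped)
}
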