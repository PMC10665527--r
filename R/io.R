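#' Read a delimited feature table
#'
#' Accepts comma- or tab-delimited text (auto-detected from the header
#' line) with one header row of feature names and one row per sample. When
#' `expect_labels = TRUE` an integer column named `label` (1-based class
#' codes) is required and returned separately. Any non-numeric or
#' non-finite cell is rejected with its row and column named.
#'
#' @param path File path.
#' @param expect_labels Require and extract a `label` column.
#' @return List with `features` (numeric matrix with column names),
#'   `labels` (integer vector or `NULL`), `n_classes` (max label or `NULL`),
#'   `sample_ids` (row numbers as character).
#' @export
read_feature_table <- function(path, expect_labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  has_label <- "label" %in% names(df)
  if (expect_labels && !has_label)
    stop("expected a 'label' column in ", path)
  labels <- NULL
  if (has_label) {
    raw <- df[["label"]]
    labels <- suppressWarnings(as.integer(raw))
    if (any(is.na(labels)) || any(labels != as.numeric(raw)) ||
        any(labels < 1L))
      stop("'label' column must contain positive integers")
    df[["label"]] <- NULL
  }
  for (j in seq_along(df)) {
    col <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(col))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric or non-finite value at row %d, column '%s'",
                   bad[1L], names(df)[j]))
    df[[j]] <- col
  }
  features <- as.matrix(df)
  rownames(features) <- NULL
  list(features = features, labels = labels,
       n_classes = if (is.null(labels)) NULL else max(labels),
       sample_ids = as.character(seq_len(nrow(features))))
}

#' Write a feature table (optionally with labels) as CSV
#'
#' @param path Output path.
#' @param features Numeric matrix, rows = samples.
#' @param labels Optional integer label vector, written as a `label` column.
#' @export
write_feature_table <- function(path, features, labels = NULL) {
  x <- as.data.frame(as_feature_matrix(features))
  if (is.null(colnames(features)))
    names(x) <- paste0("f", seq_along(x))
  if (!is.null(labels)) x$label <- as.integer(labels)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-sample predictions with class scores
#'
#' Columns: `id`, `predicted_label`, `score_1` .. `score_C`. An empty
#' prediction set produces a header-only file.
#'
#' @param path Output path.
#' @param sample_ids Character or integer sample identifiers.
#' @param labels Integer predicted labels.
#' @param scores N x C numeric score matrix.
#' @export
write_predictions <- function(path, sample_ids, labels, scores) {
  scores <- as.matrix(scores)
  if (length(sample_ids) != length(labels) ||
      (length(labels) > 0L && nrow(scores) != length(labels)))
    stop("sample_ids, labels and scores disagree in length")
  C <- ncol(scores)
  df <- data.frame(id = as.character(sample_ids),
                   predicted_label = as.integer(labels))
  sc <- as.data.frame(scores)
  names(sc) <- paste0("score_", seq_len(C))
  utils::write.csv(cbind(df, sc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path File path.
#' @return List with `sample_ids`, `labels`, `scores`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sc <- as.matrix(df[, grep("^score_", names(df)), drop = FALSE])
  dimnames(sc) <- NULL
  list(sample_ids = as.character(df$id),
       labels = as.integer(df$predicted_label), scores = sc)
}

#' Write a membership matrix with sample identifiers
#'
#' Column 0 of the membership matrix is the whole-domain membership; the
#' exported file names it `domain` and the class columns `class_1` ..
#' `class_C`, so outlier downweighting can be inspected directly.
#'
#' @param path Output path.
#' @param memberships N x (C+1) membership matrix.
#' @param sample_ids Identifiers for the N rows.
#' @export
write_memberships <- function(path, memberships, sample_ids = NULL) {
  lam <- as.matrix(memberships)
  if (is.null(sample_ids)) sample_ids <- seq_len(nrow(lam))
  df <- data.frame(id = as.character(sample_ids))
  out <- as.data.frame(lam)
  names(out) <- c("domain", paste0("class_", seq_len(ncol(lam) - 1L)))
  utils::write.csv(cbind(df, out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Gram matrix as delimited text (debugging aid)
#'
#' @param gram A `"gram_matrix"`.
#' @param path Output path.
#' @export
write_gram <- function(gram, path) {
  stopifnot(inherits(gram, "gram_matrix"))
  utils::write.table(gram$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Flat key = value solver configuration files
#'
#' `read_solver_config()` parses a plain-text file of `key = value` lines
#' (`#` comments allowed) into a [cpddm_control()]; unknown keys are an
#' error. `write_solver_config()` writes the scalar fields of a control
#' object in the same format. Kernel settings use the keys `kernel_family`,
#' `sigma` and `theta`.
#'
#' @param path File path.
#' @return A `"cpddm_control"`.
#' @export
read_solver_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  opts <- stats::setNames(as.list(vals), keys)

  num <- function(key, default) {
    if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
  }
  known <- c("alpha", "beta", "rho", "delta", "upsilon", "k_neighbors",
             "epsilon", "max_iter", "seed", "kernel_family", "sigma",
             "theta", "sigma_graph", "refresh_pseudo_labels", "map_type",
             "rf_dimension")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  kern <- kernel_config(
    family = if (is.null(opts$kernel_family)) "gaussian" else
      opts$kernel_family,
    sigma = if (is.null(opts$sigma)) NULL else as.numeric(opts$sigma),
    theta = num("theta", 1))
  cpddm_control(
    alpha = num("alpha", 1), beta = num("beta", 1), rho = num("rho", 1),
    delta = num("delta", 0.5), upsilon = num("upsilon", 0.9),
    k_neighbors = num("k_neighbors", 5), kernel = kern,
    sigma_graph = if (is.null(opts$sigma_graph)) NULL else
      as.numeric(opts$sigma_graph),
    epsilon = num("epsilon", 1e-5), max_iter = num("max_iter", 50),
    refresh_pseudo_labels =
      is.null(opts$refresh_pseudo_labels) ||
        tolower(opts$refresh_pseudo_labels) %in% c("true", "1", "yes"),
    map_type = if (is.null(opts$map_type)) "identity" else opts$map_type,
    rf_dimension = num("rf_dimension", 300), seed = num("seed", 1))
}

#' @rdname read_solver_config
#' @param control A `"cpddm_control"` to serialize.
#' @export
write_solver_config <- function(control, path) {
  stopifnot(inherits(control, "cpddm_control"))
  kern <- control$kernel
  lines <- c(
    sprintf("alpha = %.17g", control$alpha),
    sprintf("beta = %.17g", control$beta),
    sprintf("rho = %.17g", control$rho),
    sprintf("delta = %.17g", control$delta),
    sprintf("upsilon = %.17g", control$upsilon),
    sprintf("k_neighbors = %d", control$k_neighbors),
    sprintf("epsilon = %.17g", control$epsilon),
    sprintf("max_iter = %d", control$max_iter),
    sprintf("seed = %d", control$seed),
    sprintf("refresh_pseudo_labels = %s",
            tolower(control$refresh_pseudo_labels)),
    sprintf("map_type = %s", control$map_type),
    sprintf("rf_dimension = %d", control$rf_dimension))
  if (!identical(kern$family, "multi")) {
    lines <- c(lines, sprintf("kernel_family = %s", kern$family))
    if (!is.null(kern$sigma))
      lines <- c(lines, sprintf("sigma = %.17g", kern$sigma))
    lines <- c(lines, sprintf("theta = %.17g", kern$theta))
  }
  if (!is.null(control$sigma_graph))
    lines <- c(lines, sprintf("sigma_graph = %.17g", control$sigma_graph))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest before fitting
#'
#' Records the configuration snapshot, MD5 digests of the input files, the
#' seed and the package version as JSON, so a run can be re-executed and
#' verified bit-for-bit.
#'
#' @param path Manifest output path.
#' @param control A `"cpddm_control"`.
#' @param input_paths Named character vector of input files to digest.
#' @param log_path Optional path of the per-iteration log file.
#' @export
write_run_manifest <- function(path, control, input_paths = character(),
                               log_path = NULL) {
  stopifnot(inherits(control, "cpddm_control"))
  digests <- if (length(input_paths) > 0L)
    as.list(tools::md5sum(input_paths)) else list()
  cfg <- control
  cfg$kernel <- unclass(cfg$kernel)
  manifest <- list(
    package = "cpddm",
    version = as.character(utils::packageVersion("cpddm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = control$seed,
    config = unclass(cfg),
    input_digests = digests,
    log_path = log_path)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Append the per-iteration solver trace to a plain-text log
#'
#' One line per iteration:
#' `iter, theta_relaxed, theta_discrete, labels_changed, lambda_q10,
#' lambda_q50, lambda_q90`.
#'
#' @param state A `"cpddm_state"` with a populated trace.
#' @param path Log file path.
#' @export
write_iteration_log <- function(state, path) {
  stopifnot(inherits(state, "cpddm_state"))
  utils::write.csv(state$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
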