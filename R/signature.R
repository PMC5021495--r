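# Nearest shrunken centroids: minimal discriminating gene-list search.
#
# Per gene i and class k, the standardized centroid difference is
#     d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0)),   m_k = sqrt(1/n_k - 1/n)
# with s_i the pooled within-class sd and s0 the median of the s_i (the
# fuzzing constant). Soft-thresholding |d_ik| by Delta shrinks class
# centroids toward the overall centroid; genes whose every shrunken
# difference is zero drop out of the classifier. The cross-validated Delta
# that attains the smallest misclassification error -- largest Delta (fewest
# genes) among ties -- defines the minimal signature.

nsc_stats <- function(expr, meta) {
  validate_expression(expr)
  sid <- intersect(meta$sample_id, colnames(expr))
  meta <- meta[match(sid, meta$sample_id), , drop = FALSE]
  classes <- sort(unique(meta$group))
  if (length(classes) < 2L) stop("need >= 2 classes")
  n_k <- vapply(classes, function(k) sum(meta$group == k), integer(1))
  if (any(n_k < 2L))
    stop("class with < 2 samples: ",
         paste(classes[n_k < 2L], collapse = ", "))
  n <- length(sid); K <- length(classes)

  x <- expr[, sid, drop = FALSE]
  overall <- rowMeans(x)
  cent <- matrix(0, nrow(x), K, dimnames = list(rownames(x), classes))
  ss <- numeric(nrow(x))
  for (k in seq_len(K)) {
    xk <- x[, meta$group == classes[k], drop = FALSE]
    cent[, k] <- rowMeans(xk)
    ss <- ss + rowSums((xk - cent[, k])^2)
  }
  s_i <- sqrt(ss / (n - K))
  s0 <- stats::median(s_i)
  m_k <- sqrt(1 / n_k - 1 / n)
  d <- sweep(cent - overall, 1, s_i + s0, "/")
  d <- sweep(d, 2, m_k, "/")
  list(classes = classes, n_k = n_k, n = n, overall_centroid = overall,
       class_centroids = cent, s_i = s_i, s0 = s0, m_k = m_k, d = d,
       gene_ids = rownames(x))
}

nsc_shrink <- function(st, delta, prior = c("class", "uniform")) {
  prior <- match.arg(prior)
  d_shr <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  scale <- (st$s_i + st$s0)
  cent_shr <- st$overall_centroid +
    sweep(sweep(d_shr, 2, st$m_k, "*"), 1, scale, "*")
  priors <- if (prior == "class") st$n_k / st$n else
    rep(1 / length(st$classes), length(st$classes))
  names(priors) <- st$classes
  surviving <- st$gene_ids[rowSums(d_shr != 0) > 0]
  structure(list(classes = st$classes,
                 overall_centroid = st$overall_centroid,
                 class_centroids = st$class_centroids,
                 class_centroids_shrunken = cent_shr,
                 d = st$d, d_shrunken = d_shr,
                 s_i = st$s_i, s0 = st$s0, m_k = st$m_k,
                 delta = delta, class_priors = priors,
                 surviving_genes = surviving, gene_ids = st$gene_ids),
            class = "nsc_model")
}

#' Train a nearest-shrunken-centroid classifier
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Metadata with `sample_id`, `group`; every class needs >= 2
#'   samples. Classes are ordered by sorted label; ties in prediction break
#'   toward the earlier class.
#' @param delta Shrinkage threshold (>= 0); `0` leaves centroids unshrunken.
#' @param prior `"class"` (observed frequencies, default) or `"uniform"`.
#' @return Object of class `nsc_model` holding raw and shrunken centroids,
#'   `s_i`, `s0`, `delta`, class priors and `surviving_genes`.
#' @export
nsc_train <- function(expr, meta, delta = 0, prior = c("class", "uniform")) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop("delta must be a single number >= 0")
  nsc_shrink(nsc_stats(expr, meta), delta, prior)
}

#' @export
print.nsc_model <- function(x, ...) {
  cat("nsc_model:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "), delta =", signif(x$delta, 4),
      ",", length(x$surviving_genes), "of", length(x$gene_ids),
      "genes surviving\n")
  invisible(x)
}

#' Classify samples with a shrunken-centroid model
#'
#' Discriminant score for class k:
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log(prior_k)`,
#' summed over surviving genes (non-surviving genes contribute identically
#' to every class and are dropped); the predicted label is the argmin, ties
#' broken by class order.
#'
#' @param model An `nsc_model`.
#' @param expr Expression matrix containing every model gene (error
#'   otherwise).
#' @return List with `labels` (named character vector per sample) and
#'   `scores` (samples x classes matrix of discriminant values).
#' @export
nsc_predict <- function(model, expr) {
  stopifnot(inherits(model, "nsc_model"))
  genes <- if (length(model$surviving_genes)) model$surviving_genes else
    character(0)
  missing <- setdiff(model$gene_ids, rownames(expr))
  if (length(missing))
    stop("expression matrix lacks model gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  K <- length(model$classes)
  ns <- ncol(expr)
  scores <- matrix(0, ns, K, dimnames = list(colnames(expr), model$classes))
  if (length(genes)) {
    x <- expr[genes, , drop = FALSE]
    sc <- (model$s_i[genes] + model$s0)
    for (k in seq_len(K)) {
      ck <- model$class_centroids_shrunken[genes, k]
      scores[, k] <- colSums(((x - ck) / sc)^2)
    }
  }
  scores <- sweep(scores, 2, 2 * log(model$class_priors), "-")
  idx <- apply(scores, 1, which.min)   # first minimum = earliest class
  labels <- model$classes[idx]
  names(labels) <- colnames(expr)
  list(labels = labels, scores = scores)
}

#' Cross-validated shrinkage-threshold selection
#'
#' Stratified n-fold cross-validation over a grid of thresholds. The chosen
#' threshold attains the minimal total CV misclassification count; among
#' ties, the largest threshold (fewest surviving genes) wins -- the smallest
#' gene list with the smallest error. The final model is refit on all data
#' at the chosen threshold.
#'
#' @param expr Expression matrix.
#' @param meta Metadata with `sample_id`, `group`.
#' @param n_folds Number of folds (>= 2, <= smallest class size).
#' @param delta_grid Thresholds to scan; default 30 evenly spaced values
#'   from 0 to `max |d_ik|` of the full-data fit.
#' @param seed Integer seed for the fold assignment (mandatory: CV results
#'   are otherwise irreproducible).
#' @param prior Passed to [nsc_train()].
#' @return Object of class `nsc_cv`: `deltas`, `errors` (folds x deltas
#'   misclassification counts), `total_errors`, `genes_surviving` (full-data
#'   survivor count per delta), `chosen_delta`, `model` (final refit) and
#'   `folds` (named fold assignment).
#' @export
nsc_cv <- function(expr, meta, n_folds = 10, delta_grid = NULL, seed,
                   prior = c("class", "uniform")) {
  prior <- match.arg(prior)
  if (missing(seed)) stop("seed is mandatory for reproducible CV folds")
  st <- nsc_stats(expr, meta)
  if (n_folds < 2L || n_folds > min(st$n_k))
    stop("n_folds must be in [2, smallest class size = ", min(st$n_k), "]")
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(st$d)), length.out = 30)
  delta_grid <- sort(unique(delta_grid))

  sid <- intersect(meta$sample_id, colnames(expr))
  meta <- meta[match(sid, meta$sample_id), , drop = FALSE]
  folds <- integer(nrow(meta))
  names(folds) <- meta$sample_id
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (k in st$classes) {
    idx <- which(meta$group == k)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  # each training split must keep >= 2 samples per class
  for (f in seq_len(n_folds)) {
    tr <- meta[folds != f, , drop = FALSE]
    cnt <- table(factor(tr$group, levels = st$classes))
    if (any(cnt < 2L))
      stop("fold ", f, " infeasible: training split leaves a class with < 2 samples")
  }

  errors <- matrix(0L, n_folds, length(delta_grid))
  for (f in seq_len(n_folds)) {
    tr_ids <- names(folds)[folds != f]
    te_ids <- names(folds)[folds == f]
    st_f <- nsc_stats(expr[, tr_ids, drop = FALSE],
                      meta[meta$sample_id %in% tr_ids, , drop = FALSE])
    truth <- meta$group[match(te_ids, meta$sample_id)]
    for (j in seq_along(delta_grid)) {
      mod <- nsc_shrink(st_f, delta_grid[j], prior)
      pred <- nsc_predict(mod, expr[, te_ids, drop = FALSE])$labels
      errors[f, j] <- sum(pred != truth)
    }
  }
  total <- colSums(errors)
  genes_surviving <- vapply(delta_grid, function(dl)
    sum(rowSums(abs(st$d) > dl) > 0), integer(1))
  chosen <- delta_grid[max(which(total == min(total)))]
  model <- nsc_shrink(st, chosen, prior)
  structure(list(deltas = delta_grid, errors = errors, total_errors = total,
                 genes_surviving = genes_surviving, chosen_delta = chosen,
                 model = model, folds = folds, n_folds = n_folds,
                 seed = seed),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat("nsc_cv:", x$n_folds, "folds,", length(x$deltas),
      "thresholds; chosen delta =", signif(x$chosen_delta, 4),
      "(", length(x$model$surviving_genes), "genes,",
      min(x$total_errors), "CV errors )\n")
  invisible(x)
}

#' Serialize a shrunken-centroid model to JSON
#' @param model An `nsc_model`.
#' @param path Output path.
#' @export
write_nsc_model <- function(model, path) {
  stopifnot(inherits(model, "nsc_model"))
  obj <- list(classes = model$classes,
              delta = model$delta,
              s0 = model$s0,
              class_priors = as.list(model$class_priors),
              surviving_genes = model$surviving_genes,
              overall_centroid = as.list(model$overall_centroid[model$surviving_genes]),
              s_i = as.list(model$s_i[model$surviving_genes]),
              class_centroids_shrunken = apply(
                model$class_centroids_shrunken[model$surviving_genes, ,
                                               drop = FALSE], 2, as.list,
                simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
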