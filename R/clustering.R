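# Hierarchical clustering of samples on a gene subset (typically the
# significant DGE genes) and quantification of how well a target
# disease-activity group separates from the rest when the tree is cut.
#
# The agglomeration is implemented directly (Lance-Williams updates) with a
# pinned tie-break -- among equally close pairs, the pair containing the
# lowest original leaf index merges first -- so trees are identical across
# platforms. The result is a standard "hclust" object, so cutree() and
# plot() work as usual.

#' Agglomerative clustering of samples
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Optional gene subset to cluster on (default: all rows);
#'   intersected with the matrix, must be non-empty.
#' @param distance `"correlation"` (1 - Pearson across genes, the microarray
#'   convention, default) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (the
#'   Ward D2 criterion on the chosen distance).
#' @param scale_genes Standardize each gene (row) to mean 0, sd 1 before
#'   computing sample distances (default `TRUE`, the heatmap convention).
#'   Without it, group shifts shared uniformly by the selected genes are
#'   absorbed into per-sample means and invisible to correlation distance;
#'   zero-variance rows are centered only.
#' @return An object of class `hclust` whose leaves are the samples.
#' @export
cluster_samples <- function(expr, genes = NULL,
                            distance = c("correlation", "euclidean"),
                            linkage = c("average", "complete", "ward"),
                            scale_genes = TRUE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  validate_expression(expr)
  if (is.null(genes)) genes <- rownames(expr)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) stop("gene set has empty intersection with the matrix")
  x <- expr[genes, , drop = FALSE]
  if (isTRUE(scale_genes)) {
    sds <- apply(x, 1, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    x <- (x - rowMeans(x)) / sds
  }
  n <- ncol(x)
  if (n < 2L) stop("need >= 2 samples to cluster")
  d <- if (distance == "euclidean") {
    as.matrix(stats::dist(t(x)))
  } else {
    if (nrow(x) < 2L)
      stop("correlation distance needs >= 2 genes; use distance = 'euclidean'")
    dd <- 1 - stats::cor(x)
    dd[dd < 0] <- 0   # clip tiny negative rounding at r ~ 1
    dd
  }
  tree <- agglomerate(d, linkage, labels = colnames(x))
  tree$dist.method <- distance
  tree
}

# Lance-Williams agglomeration on a full symmetric distance matrix.
# Tie-break: pairs are scanned in order of each cluster's minimum original
# leaf index; the first pair attaining the minimum distance wins.
agglomerate <- function(d, linkage, labels) {
  n <- nrow(d)
  diag(d) <- Inf
  if (linkage == "ward") d <- d^2     # Ward D2 recurrences act on squared d
  size <- rep(1L, n)
  min_leaf <- seq_len(n)              # lowest original leaf in each cluster
  code <- -seq_len(n)                 # hclust merge coding
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    ord <- active[order(min_leaf[active])]
    best <- Inf; bi <- 0L; bj <- 0L
    for (ii in seq_len(length(ord) - 1L)) {
      for (jj in (ii + 1L):length(ord)) {
        a <- ord[ii]; b <- ord[jj]
        if (d[a, b] < best) { best <- d[a, b]; bi <- a; bj <- b }
      }
    }
    merge[s, ] <- sort(c(code[bi], code[bj]),
                       method = "radix")  # negatives (leaves) first
    height[s] <- if (linkage == "ward") sqrt(best) else best

    # Lance-Williams update of distances from the merged cluster to the rest
    others <- setdiff(active, c(bi, bj))
    ni <- size[bi]; nj <- size[bj]
    for (o in others) {
      dio <- d[bi, o]; djo <- d[bj, o]
      newd <- switch(linkage,
        average  = (ni * dio + nj * djo) / (ni + nj),
        complete = max(dio, djo),
        ward     = {
          no <- size[o]
          ((ni + no) * dio + (nj + no) * djo - no * d[bi, bj]) /
            (ni + nj + no)
        })
      d[bi, o] <- newd; d[o, bi] <- newd
    }
    size[bi] <- ni + nj
    min_leaf[bi] <- min(min_leaf[bi], min_leaf[bj])
    code[bi] <- s
    active <- setdiff(active, bj)
  }

  structure(list(merge = merge, height = height,
                 order = tree_order(merge, n), labels = labels,
                 method = linkage, call = match.call()),
            class = "hclust")
}

# leaf ordering for plotting: left-to-right depth-first walk of the merges
tree_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Separation of a sample group under a tree cut
#'
#' Cuts the tree into `k_cut` clusters, finds the cluster holding the most
#' members of `target_group` (ties: lowest cluster id) and reports how many
#' target samples land there -- the "x of N separated" statistic.
#'
#' @param tree An `hclust` over samples (see [cluster_samples()]).
#' @param meta Metadata with `sample_id`, `group` covering the tree leaves.
#' @param target_group Group label to score.
#' @param k_cut Number of clusters to cut into (>= 2, <= number of samples).
#' @return Object of class `cluster_separation` with fields `assignment`,
#'   `majority_cluster`, `separated_count`, `target_group_size`, `k_cut`.
#' @export
separation_score <- function(tree, meta, target_group, k_cut = 2) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k_cut < 2L) stop("k_cut must be >= 2")
  if (k_cut > n) stop("k_cut (", k_cut, ") exceeds number of samples (", n, ")")
  assignment <- stats::cutree(tree, k = k_cut)
  target <- meta$sample_id[meta$group == target_group]
  target <- intersect(target, tree$labels)
  if (!length(target)) stop("target group '", target_group, "' not present")
  counts <- table(factor(assignment[target], levels = seq_len(k_cut)))
  majority <- as.integer(which.max(counts))       # ties -> lowest cluster id
  structure(list(assignment = assignment,
                 majority_cluster = majority,
                 separated_count = as.integer(counts[majority]),
                 target_group = target_group,
                 target_group_size = length(target),
                 k_cut = k_cut),
            class = "cluster_separation")
}

#' @export
print.cluster_separation <- function(x, ...) {
  cat("cluster_separation:", x$separated_count, "/", x$target_group_size,
      "'", x$target_group, "' samples in majority cluster",
      x$majority_cluster, "of", x$k_cut, "\n")
  invisible(x)
}

#' Clustered expression heatmap with group color bar
#'
#' Renders the gene-restricted matrix as a clustered heatmap (samples
#' clustered with the package's own [cluster_samples()] tree so the display
#' matches the separation statistic) with a per-sample group annotation bar.
#'
#' @param expr Expression matrix.
#' @param genes Gene subset to display.
#' @param meta Metadata with `sample_id`, `group`.
#' @param path PNG output path.
#' @param distance,linkage Passed to [cluster_samples()].
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(expr, genes, meta, path,
                           distance = c("correlation", "euclidean"),
                           linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) stop("gene set has empty intersection with the matrix")
  x <- expr[genes, , drop = FALSE]
  tree <- if (ncol(x) >= 2L)
    cluster_samples(expr, genes, distance, linkage) else FALSE
  ann <- data.frame(group = meta$group[match(colnames(x), meta$sample_id)],
                    row.names = colnames(x))
  pheatmap::pheatmap(x,
                     scale = if (nrow(x) >= 2L) "row" else "none",
                     cluster_rows = nrow(x) >= 2L,
                     cluster_cols = tree,
                     annotation_col = ann,
                     show_rownames = nrow(x) <= 60,
                     filename = path, silent = TRUE)
  invisible(path)
}
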