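# Module fingerprints: per gene module, the percentage of member genes with
# significant differential expression, split by direction. This is the
# summary statistic that turns a genome-wide DGE table into an interpretable
# per-module profile (interferon up, ribosomal down, ...).

#' Directional module fingerprint of a DGE table
#'
#' For each module, counts how many member genes fall in the up / down
#' significant sets of `dge` at level `alpha` and expresses the counts as
#' percentages of the module. Module members absent from the DGE table (not
#' measured, or lost in probe collapse) contribute to `n_genes_total` only.
#'
#' @param dge A `dge_table` with `q_bh` filled (see [moderated_t()]).
#' @param modules A [module_set()].
#' @param alpha BH significance threshold in (0, 1).
#' @param denominator `"measured"` (default) divides by the number of module
#'   members present in the DGE table; `"total"` divides by the full module
#'   size. Counts are always reported so either convention can be recomputed.
#' @param contrast_id Optional identifier stored with the fingerprint.
#' @return A `module_fingerprint` data frame with columns `module_id`,
#'   `label`, `n_total`, `n_measured`, `n_up`, `n_down`, `pct_up`,
#'   `pct_down`. Modules with a zero denominator get `NA` percentages.
#' @export
module_fingerprint <- function(dge, modules, alpha = 0.05,
                               denominator = c("measured", "total"),
                               contrast_id = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(modules, "module_set"))
  if (is.null(dge$q_bh) || all(is.na(dge$q_bh)))
    stop("dge table has no q_bh column filled")
  sig <- significant_genes(dge, alpha)
  measured <- dge$gene_id

  n <- length(modules)
  n_total <- lengths(modules$genes)
  n_measured <- integer(n); n_up <- integer(n); n_down <- integer(n)
  for (i in seq_len(n)) {
    mem <- modules$genes[[i]]
    meas <- mem[mem %in% measured]
    n_measured[i] <- length(meas)
    n_up[i] <- sum(meas %in% sig$up)
    n_down[i] <- sum(meas %in% sig$down)
  }
  denom <- if (denominator == "measured") n_measured else n_total
  pct_up <- ifelse(denom > 0, 100 * n_up / denom, NA_real_)
  pct_down <- ifelse(denom > 0, 100 * n_down / denom, NA_real_)

  fp <- data.frame(module_id = modules$module_id, label = modules$label,
                   n_total = n_total, n_measured = n_measured,
                   n_up = n_up, n_down = n_down,
                   pct_up = pct_up, pct_down = pct_down,
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(fp, "contrast_id") <- contrast_id
  attr(fp, "alpha") <- alpha
  attr(fp, "denominator") <- denominator
  class(fp) <- c("module_fingerprint", "data.frame")
  fp
}

#' Fingerprints of several contrasts over one module collection
#'
#' @param dge_tables Named list of `dge_table` objects; names are the
#'   contrast ids, must be unique and non-empty.
#' @param modules A [module_set()] shared by all contrasts.
#' @param alpha BH threshold applied to every contrast.
#' @param denominator Passed to [module_fingerprint()].
#' @return A `fingerprint_grid`: list with `contrast_ids`, `modules` and
#'   `fingerprints` (one [module_fingerprint()] per contrast, in input
#'   order).
#' @export
fingerprint_grid <- function(dge_tables, modules, alpha = 0.05,
                             denominator = c("measured", "total")) {
  denominator <- match.arg(denominator)
  if (!length(dge_tables)) stop("need at least one contrast")
  ids <- names(dge_tables)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("dge_tables must be a named list (names are contrast ids)")
  if (anyDuplicated(ids))
    stop("duplicate contrast id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fps <- lapply(ids, function(id)
    module_fingerprint(dge_tables[[id]], modules, alpha,
                       denominator = denominator, contrast_id = id))
  names(fps) <- ids
  structure(list(contrast_ids = ids, modules = modules, fingerprints = fps,
                 alpha = alpha, denominator = denominator),
            class = "fingerprint_grid")
}

#' Flatten a fingerprint grid to a wide table
#'
#' One row per module, columns `<contrast>.up` / `<contrast>.down` holding
#' the percentages.
#' @param grid A `fingerprint_grid`.
#' @return data.frame.
#' @export
grid_table <- function(grid) {
  stopifnot(inherits(grid, "fingerprint_grid"))
  base <- grid$fingerprints[[1]][, c("module_id", "label")]
  for (id in grid$contrast_ids) {
    fp <- grid$fingerprints[[id]]
    base[[paste0(id, ".up")]] <- fp$pct_up
    base[[paste0(id, ".down")]] <- fp$pct_down
  }
  base
}

#' Render a fingerprint grid
#'
#' Always writes the wide TSV (unavailable cells as `NA`, percentages
#' unrounded); optionally also a heat-grid PNG with up-regulation in red and
#' down-regulation in blue, percentages rounded to integers for display.
#'
#' @param grid A `fingerprint_grid`.
#' @param path TSV output path.
#' @param image_path Optional PNG output path.
#' @return `path`, invisibly.
#' @export
render_grid <- function(grid, path, image_path = NULL) {
  tab <- grid_table(grid)
  out <- tab
  for (cc in setdiff(names(out), c("module_id", "label")))
    out[[cc]] <- num_full(out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(image_path)) {
    m <- as.matrix(tab[, setdiff(names(tab), c("module_id", "label")),
                       drop = FALSE])
    rownames(m) <- tab$module_id
    up_cols <- grepl("\\.up$", colnames(m))
    disp <- round(m)
    signed <- disp
    signed[, !up_cols] <- -disp[, !up_cols]   # down in blue (negative)
    grDevices::png(image_path, width = 200 + 90 * ncol(m),
                   height = 120 + 18 * nrow(m))
    op <- graphics::par(mar = c(6, 6, 2, 1))
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
    graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                    z = t(signed[rev(seq_len(nrow(m))), , drop = FALSE]),
                    zlim = c(-100, 100), col = pal, axes = FALSE,
                    xlab = "", ylab = "")
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 1)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(path)
}
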