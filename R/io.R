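# Readers and writers for the external artifacts the pipeline consumes and
# produces: expression matrices (TSV / GCT 1.2), sample metadata, gene-set
# collections (GMT), differential-expression tables and module fingerprints.
# All loaders validate strictly; malformed input is an error, never a warning.

#' Validate a log2 expression matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix with
#' unique, non-empty gene and sample identifiers and no missing or infinite
#' values. Expression is expected on the log2 scale but the scale itself is
#' not (and cannot be) checked.
#'
#' @param x Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene ids as rownames and sample ids as colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "),
         " (collapse duplicates first, see collapse_duplicate_genes())")
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", rownames(x)[bad[1]],
         "', sample '", colnames(x)[bad[2]], "'")
  }
  invisible(x)
}

#' Collapse duplicate gene rows
#'
#' Microarray matrices often carry several probes per gene. When row ids are
#' not unique, this reduces each duplicated id to a single row.
#'
#' @param x Numeric matrix with rownames (possibly duplicated gene ids).
#' @param rule `"max-mean"` keeps, per gene, the row with the largest mean
#'   intensity (ties: first occurrence); `"mean"` averages the rows;
#'   `"none"` errors on any duplicate.
#' @return Matrix with unique rownames, original first-occurrence row order.
#' @export
collapse_duplicate_genes <- function(x, rule = c("max-mean", "mean", "none")) {
  rule <- match.arg(rule)
  ids <- rownames(x)
  if (!anyDuplicated(ids)) return(x)
  if (rule == "none")
    stop("duplicate gene ids with collapse rule 'none': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep_order <- unique(ids)
  if (rule == "max-mean") {
    rm <- rowMeans(x)
    pick <- vapply(split(seq_along(ids), ids), function(i) i[which.max(rm[i])],
                   integer(1))
    out <- x[pick[keep_order], , drop = FALSE]
  } else {
    out <- do.call(rbind, lapply(split(seq_along(ids), ids)[keep_order],
                                 function(i) colMeans(x[i, , drop = FALSE])))
  }
  rownames(out) <- keep_order
  out
}

#' Read a normalized log2 expression matrix
#'
#' Supports plain TSV (first column gene id, header row of sample ids) and
#' GCT 1.2 (version line `#1.2`, dimension line, then `Name`/`Description`
#' columns). Values must be numeric and finite; duplicate gene rows are
#' collapsed per `collapse`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"gct"`.
#' @param collapse Probe-collapse rule, see [collapse_duplicate_genes()].
#' @return Validated numeric matrix, genes x samples.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            collapse = c("max-mean", "mean", "none")) {
  format <- match.arg(format)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"

  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || trimws(hdr[1]) != "#1.2")
      stop("not a GCT 1.2 file (first line must be '#1.2'): ", path)
    dims <- suppressWarnings(as.integer(strsplit(hdr[2], "\t", fixed = TRUE)[[1]][1:2]))
    if (any(is.na(dims)))
      stop("malformed GCT dimension line in ", path)
    tab <- utils::read.delim(path, skip = 2L, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 3L)
      stop("GCT file must have Name, Description and at least one sample column")
    gene_ids <- tab[[1]]
    header_ids <- names(tab)[-(1:2)]       # before [.data.frame dedupes
    val_cols <- tab[, -(1:2), drop = FALSE]
    names(val_cols) <- header_ids
    if (nrow(tab) != dims[1] || ncol(val_cols) != dims[2])
      stop("GCT dimension line (", dims[1], " x ", dims[2],
           ") does not match data (", nrow(tab), " x ", ncol(val_cols), ")")
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2L)
      stop("expression TSV must have a gene-id column and at least one sample column")
    gene_ids <- tab[[1]]
    header_ids <- names(tab)[-1]           # before [.data.frame dedupes
    val_cols <- tab[, -1, drop = FALSE]
    names(val_cols) <- header_ids
  }

  sample_ids <- colnames(val_cols)
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id in header: ", paste(unique(dup), collapse = ", "))

  vals <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(val_cols[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric or non-finite value for gene '", gene_ids[bad[1]],
           "', sample column '", sample_ids[j], "'")
    vals[, j] <- v
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  vals <- collapse_duplicate_genes(vals, collapse)
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, then one column per sample, full double precision.
#' @param x Validated expression matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene_id = rownames(x),
                   apply(x, 2, num_full), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample metadata table
#'
#' @param path TSV with header; first column sample id, second column group
#'   label (columns named `sample_id` and `group` are used by name when
#'   present).
#' @param groups Optional character vector declaring the admissible group
#'   labels; any other label is an error.
#' @return `data.frame` with character columns `sample_id` and `group`.
#' @export
read_metadata <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("metadata must have at least two columns (sample_id, group)")
  sid <- if ("sample_id" %in% names(tab)) tab[["sample_id"]] else tab[[1]]
  grp <- if ("group" %in% names(tab)) tab[["group"]] else tab[[2]]
  dup <- sid[duplicated(sid)]
  if (length(dup)) stop("duplicate sample_id in metadata: ",
                        paste(unique(dup), collapse = ", "))
  if (!is.null(groups)) {
    bad <- setdiff(unique(grp), groups)
    if (length(bad))
      stop("group label(s) not in declared set: ", paste(bad, collapse = ", "))
  }
  data.frame(sample_id = sid, group = grp, stringsAsFactors = FALSE)
}

#' Construct a gene-module collection
#'
#' A `module_set` is an ordered collection of named gene sets: each module has
#' a unique id (e.g. `"M3.1"`), a free-text label (e.g. `"Interferon"`) and a
#' non-empty set of member gene ids. Modules may share genes.
#'
#' @param module_id Character vector of unique module ids.
#' @param label Character vector of annotation labels (recycled if length 1).
#' @param genes List of character vectors of member gene ids.
#' @return Object of class `module_set`.
#' @export
module_set <- function(module_id, label = module_id, genes) {
  module_id <- as.character(module_id)
  if (length(label) == 1L) label <- rep(label, length(module_id))
  if (anyDuplicated(module_id))
    stop("duplicate module id: ",
         paste(unique(module_id[duplicated(module_id)]), collapse = ", "))
  if (length(genes) != length(module_id) || length(label) != length(module_id))
    stop("module_id, label and genes must have equal length")
  genes <- lapply(genes, function(g) unique(as.character(g)))
  empty <- module_id[lengths(genes) == 0L]
  if (length(empty))
    stop("module with empty gene list: ", paste(empty, collapse = ", "))
  structure(list(module_id = module_id, label = as.character(label),
                 genes = genes),
            class = "module_set")
}

#' @export
length.module_set <- function(x) length(x$module_id)

#' @export
print.module_set <- function(x, ...) {
  cat("module_set with", length(x), "modules,",
      length(unique(unlist(x$genes))), "distinct genes\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %-8s %-20s %d genes\n", x$module_id[i], x$label[i],
                length(x$genes[[i]])))
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one module per line, fields are id,
#' description, then one gene per field. File order is preserved.
#'
#' @param path GMT file path.
#' @return A [module_set()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  short <- ids[lengths(fields) < 3L]
  if (length(short))
    stop("GMT module with empty gene list: ", paste(short, collapse = ", "))
  labels <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  module_set(ids, labels, genes)
}

#' Write a module collection as GMT
#' @param ms A [module_set()].
#' @param path Output path.
#' @export
write_gmt <- function(ms, path) {
  stopifnot(inherits(ms, "module_set"))
  lines <- vapply(seq_along(ms$module_id), function(i)
    paste(c(ms$module_id[i], ms$label[i], ms$genes[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# full-precision decimal rendering so write -> read round-trips bit-exactly
num_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a differential-expression table as TSV
#'
#' Columns, in fixed order: `gene_id`, `log_fc`, `s2`, `t_mod`, `df_total`,
#' `p_raw`, `q_bh`. Numerics are written with 17 significant digits so that
#' [read_dge()] reproduces the table bit-exactly.
#'
#' @param tab A `dge_table` (see [moderated_t()]).
#' @param path Output path.
#' @export
write_dge <- function(tab, path) {
  cols <- c("gene_id", "log_fc", "s2", "t_mod", "df_total", "p_raw", "q_bh")
  stopifnot(all(cols %in% names(tab)))
  out <- data.frame(gene_id = tab$gene_id, lapply(tab[cols[-1]], num_full),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a differential-expression table
#' @param path TSV written by [write_dge()].
#' @return A `dge_table` data frame.
#' @export
read_dge <- function(path) {
  if (!file.exists(path)) stop("DGE file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  cols <- c("gene_id", "log_fc", "s2", "t_mod", "df_total", "p_raw", "q_bh")
  if (!all(cols %in% names(tab))) stop("not a DGE table: ", path)
  tab$gene_id <- as.character(tab$gene_id)
  for (cc in cols[-1]) tab[[cc]] <- as.numeric(tab[[cc]])
  class(tab) <- c("dge_table", "data.frame")
  tab
}

#' Write a module fingerprint
#'
#' TSV columns: `module_id`, `label`, `n_total`, `n_measured`, `n_up`,
#' `n_down`, `pct_up`, `pct_down` (unrounded; unavailable percentages are
#' `NA`). A `.json` path instead writes a structured JSON object carrying the
#' contrast id, alpha and denominator convention alongside the rows.
#'
#' @param fp A `module_fingerprint` (see [module_fingerprint()]).
#' @param path Output path; format chosen by extension (`.json` vs TSV).
#' @export
write_fingerprint <- function(fp, path) {
  stopifnot(inherits(fp, "module_fingerprint"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(contrast_id = attr(fp, "contrast_id"),
                alpha = attr(fp, "alpha"),
                denominator = attr(fp, "denominator"),
                modules = fp)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    out <- data.frame(module_id = fp$module_id, label = fp$label,
                      n_total = fp$n_total, n_measured = fp$n_measured,
                      n_up = fp$n_up, n_down = fp$n_down,
                      pct_up = num_full(fp$pct_up),
                      pct_down = num_full(fp$pct_down),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a module fingerprint TSV
#' @param path TSV written by [write_fingerprint()].
#' @return A `module_fingerprint` data frame (contrast metadata not restored
#'   from plain TSV; use the JSON form to round-trip it).
#' @export
read_fingerprint <- function(path) {
  if (!file.exists(path)) stop("fingerprint file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    fp <- as.data.frame(obj$modules, stringsAsFactors = FALSE)
    attr(fp, "contrast_id") <- obj$contrast_id
    attr(fp, "alpha") <- obj$alpha
    attr(fp, "denominator") <- obj$denominator
  } else {
    fp <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    for (cc in c("n_total", "n_measured", "n_up", "n_down"))
      fp[[cc]] <- as.integer(fp[[cc]])
    for (cc in c("pct_up", "pct_down")) fp[[cc]] <- as.numeric(fp[[cc]])
  }
  fp$module_id <- as.character(fp$module_id)
  fp$label <- as.character(fp$label)
  class(fp) <- c("module_fingerprint", "data.frame")
  fp
}
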