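# End-to-end orchestration: simulate (or load) -> differential expression ->
# module fingerprint -> minimal signature -> clustering separation ->
# enrichment, from a single config, with a content-hash manifest and a
# structured run log so every grid of numbers is auditably reproducible.

pipeline_defaults <- function() {
  list(alpha = 0.05, collapse = "max-mean", seed = 1,
       denominator = "measured",
       clustering = list(distance = "correlation", linkage = "average",
                         k_cut = 2),
       signature = list(n_folds = 10, grid_size = 30),
       heatmap = FALSE)
}

# fill defaults without clobbering user-set sublist entries
merge_config <- function(user, defaults = pipeline_defaults()) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      user[[nm]] <- merge_config(user[[nm]], defaults[[nm]])
  }
  user
}

config_as_plain <- function(config) {
  plain <- config
  if (!is.null(plain$sim_config)) plain$sim_config <- unclass(plain$sim_config)
  plain
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: (1) simulate a synthetic cohort (when
#' `sim_config` is given) or load `expr`/`meta`/`modules` paths; (2)
#' moderated-t DGE per contrast; (3) fingerprint grid; (4) nearest-shrunken-
#' centroid signature with CV on the first contrast; (5) hierarchical
#' clustering of the first contrast's samples on its significant genes, with
#' a separation score for the target group; (6) hypergeometric enrichment of
#' the first contrast's significant genes against the module collection.
#' Every input path is validated before any stage runs; the resolved config
#' is written next to the outputs; the manifest lists each artifact with its
#' md5 and marks the failure point if a stage errors.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `out_dir` (required); either `sim_config` (a [simulation_config()]) or
#'   `expr`/`meta`/`modules` file paths; `contrasts` (list of length-2
#'   character vectors, required); optional `alpha`, `collapse`, `seed`,
#'   `denominator`, `clustering` (`distance`, `linkage`, `k_cut`,
#'   `target_group`), `signature` (`n_folds`, `grid_size`), `heatmap`.
#' @return List with `status` (0 ok, 1 failed), `manifest` (data frame:
#'   stage, path, md5, status) and `artifacts` (named paths), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- merge_config(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$contrasts) || !length(config$contrasts))
    stop("config$contrasts is required (list of c(groupA, groupB))")
  if (!is.list(config$contrasts)) config$contrasts <- list(config$contrasts)

  simulate <- !is.null(config$sim_config)
  if (!simulate) {
    for (f in c("expr", "meta", "modules")) {
      if (is.null(config[[f]]))
        stop("config needs either sim_config or an '", f, "' path")
      if (!file.exists(config[[f]]))
        stop("input file for '", f, "' not found: ", config[[f]],
             " (no stage was run)")
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)

  jsonlite::write_json(config_as_plain(config), pth("config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)

  manifest <- data.frame(stage = character(0), path = character(0),
                         md5 = character(0), status = character(0),
                         stringsAsFactors = FALSE)
  log <- list(seed = config$seed,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("modfinger")),
              stages = list())
  artifacts <- character(0)
  record <- function(stage, paths, status = "ok") {
    md5 <- unname(tools::md5sum(paths))
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, path = basename(paths),
                                  md5 = md5, status = status,
                                  stringsAsFactors = FALSE))
    artifacts <<- c(artifacts, stats::setNames(paths, basename(paths)))
  }
  finish <- function(status, failed_stage = NULL) {
    if (!is.null(failed_stage))
      manifest <<- rbind(manifest,
                         data.frame(stage = failed_stage, path = NA_character_,
                                    md5 = NA_character_, status = "failed",
                                    stringsAsFactors = FALSE))
    utils::write.table(manifest, pth("manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    log$status <<- status
    jsonlite::write_json(log, pth("run_log.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(list(status = status, manifest = manifest,
                   artifacts = artifacts, out_dir = out_dir))
  }

  stage_names <- c("simulate", "dge", "fingerprint", "signature",
                   "cluster", "enrich")
  current <- ""
  res <- tryCatch({
    # -- stage 1: obtain inputs ------------------------------------------
    current <- "simulate"
    t0 <- proc.time()[[3]]
    if (simulate) {
      sim <- simulate_cohorts(config$sim_config)
      expr <- sim$expr; meta <- sim$meta; modules <- sim$modules
      write_expression(expr, pth("expr.tsv"))
      utils::write.table(meta, pth("meta.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_gmt(modules, pth("modules.gmt"))
      tr <- sim$truth
      for (cc in names(tr)) if (is.numeric(tr[[cc]])) tr[[cc]] <- num_full(tr[[cc]])
      utils::write.table(tr, pth("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("simulate", pth(c("expr.tsv", "meta.tsv", "modules.gmt",
                               "truth.tsv")))
    } else {
      expr <- read_expression(config$expr, collapse = config$collapse)
      meta <- read_metadata(config$meta)
      modules <- read_gmt(config$modules)
      record("simulate", c(config$expr, config$meta, config$modules))
    }
    log$stages$simulate <- proc.time()[[3]] - t0

    # -- stage 2: DGE per contrast ---------------------------------------
    current <- "dge"
    t0 <- proc.time()[[3]]
    dges <- list()
    for (ct in config$contrasts) {
      id <- paste0(ct[1], "_vs_", ct[2])
      dges[[id]] <- moderated_t(expr, meta, ct)
      write_dge(dges[[id]], pth(paste0("dge_", id, ".tsv")))
    }
    record("dge", pth(paste0("dge_", names(dges), ".tsv")))
    log$stages$dge <- proc.time()[[3]] - t0

    # -- stage 3: fingerprint grid ---------------------------------------
    current <- "fingerprint"
    t0 <- proc.time()[[3]]
    grid <- fingerprint_grid(dges, modules, alpha = config$alpha,
                             denominator = config$denominator)
    render_grid(grid, pth("fingerprint_grid.tsv"))
    for (id in names(dges))
      write_fingerprint(grid$fingerprints[[id]],
                        pth(paste0("fingerprint_", id, ".json")))
    record("fingerprint", pth(c("fingerprint_grid.tsv",
                                paste0("fingerprint_", names(dges), ".json"))))
    log$stages$fingerprint <- proc.time()[[3]] - t0

    # -- stage 4: minimal signature on the first contrast ----------------
    current <- "signature"
    t0 <- proc.time()[[3]]
    ct1 <- config$contrasts[[1]]
    meta1 <- meta[meta$group %in% ct1, , drop = FALSE]
    expr1 <- expr[, intersect(colnames(expr), meta1$sample_id), drop = FALSE]
    n_folds <- min(config$signature$n_folds,
                   min(table(meta1$group)))
    cv <- nsc_cv(expr1, meta1, n_folds = n_folds, seed = config$seed)
    write_nsc_model(cv$model, pth("nsc_model.json"))
    cvtab <- data.frame(delta = num_full(cv$deltas),
                        total_errors = cv$total_errors,
                        genes_surviving = cv$genes_surviving)
    utils::write.table(cvtab, pth("nsc_cv.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("signature", pth(c("nsc_model.json", "nsc_cv.tsv")))
    log$stages$signature <- proc.time()[[3]] - t0

    # -- stage 5: clustering separation ----------------------------------
    current <- "cluster"
    t0 <- proc.time()[[3]]
    sig1 <- significant_genes(dges[[1]], config$alpha)
    de_genes <- c(sig1$up, sig1$down)
    target <- config$clustering$target_group
    if (is.null(target)) target <- ct1[1]
    if (length(de_genes) >= 2L) {
      tree <- cluster_samples(expr1, de_genes,
                              distance = config$clustering$distance,
                              linkage = config$clustering$linkage)
      sep <- separation_score(tree, meta1, target,
                              k_cut = config$clustering$k_cut)
      septab <- data.frame(target_group = target,
                           separated_count = sep$separated_count,
                           target_group_size = sep$target_group_size,
                           k_cut = sep$k_cut,
                           n_genes = length(de_genes))
      if (isTRUE(config$heatmap))
        render_heatmap(expr1, de_genes, meta1, pth("heatmap.png"),
                       distance = config$clustering$distance,
                       linkage = config$clustering$linkage)
    } else {
      septab <- data.frame(target_group = target, separated_count = NA,
                           target_group_size = sum(meta1$group == target),
                           k_cut = config$clustering$k_cut,
                           n_genes = length(de_genes))
    }
    utils::write.table(septab, pth("separation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    record("cluster", pth(c("separation.tsv",
                            if (isTRUE(config$heatmap) && length(de_genes) >= 2L)
                              "heatmap.png")))
    log$stages$cluster <- proc.time()[[3]] - t0

    # -- stage 6: enrichment of the DE genes -----------------------------
    current <- "enrich"
    t0 <- proc.time()[[3]]
    universe <- rownames(expr)
    if (length(de_genes)) {
      enr <- hypergeometric_enrichment(de_genes, modules, universe)
      write_enrichment(enr, pth("enrichment.tsv"))
    } else {
      writeLines(paste(c("set_id", "set_name", "p_value", "q_bonferroni",
                         "q_bh", "hit_count_query", "hit_count_genome"),
                       collapse = "\t"), pth("enrichment.tsv"))
    }
    record("enrich", pth("enrichment.tsv"))
    log$stages$enrich <- proc.time()[[3]] - t0

    finish(0L)
  }, error = function(e) {
    warning("pipeline failed at stage '", current, "': ",
            conditionMessage(e), call. = FALSE)
    finish(1L, failed_stage = current)
  })
  res
}

#' Reproduce a public-cohort fingerprint column
#'
#' Comparison harness for the public pediatric-lupus expression deposit
#' (GEO accession GSE11909): given the locally obtained series matrix, a
#' sample annotation table carrying treatment status, the module GMT and a
#' reference TSV of published per-module percentages, computes the untreated
#' SLE vs healthy-control fingerprint and writes a side-by-side comparison.
#' No network access is attempted; the deposit is known to be incomplete
#' (several healthy-control U133B chips are missing), so agreement is
#' reported, not asserted.
#'
#' @param expr_path Locally downloaded expression matrix (TSV or GCT).
#' @param meta_path Sample annotation TSV (`sample_id`, `group`) whose group
#'   column encodes treatment status; both contrast labels must be present.
#' @param gmt_path Module definitions (GMT).
#' @param reference_path TSV with columns `module_id`, `pct_up`, `pct_down`
#'   holding the published values to compare against.
#' @param out_path Output TSV of the comparison.
#' @param contrast Length-2 contrast, default
#'   `c("SLE_untreated", "healthy")`.
#' @param alpha BH threshold (default 0.05).
#' @param collapse Probe-collapse rule (default `"max-mean"`).
#' @param accession Accession named in error messages (default `"GSE11909"`).
#' @return List with `fingerprint` and `comparison` (data frame adding
#'   `ref_pct_up`, `ref_pct_down`, `diff_up`, `diff_down`), invisibly.
#' @export
repro_gse11909 <- function(expr_path, meta_path, gmt_path, reference_path,
                           out_path, contrast = c("SLE_untreated", "healthy"),
                           alpha = 0.05, collapse = "max-mean",
                           accession = "GSE11909") {
  if (!file.exists(expr_path))
    stop("expression matrix not found: ", expr_path,
         "\nObtain the ", accession, " series matrix locally (no network ",
         "access is attempted here) and point expr_path at it.")
  for (p in c(meta_path, gmt_path, reference_path))
    if (!file.exists(p)) stop("required input not found: ", p)
  expr <- read_expression(expr_path, collapse = collapse)
  meta <- read_metadata(meta_path)
  missing <- setdiff(contrast, unique(meta$group))
  if (length(missing))
    stop("sample annotation lacks treatment-status group(s): ",
         paste(missing, collapse = ", "),
         " (annotate each ", accession, " sample as one of '",
         paste(contrast, collapse = "', '"), "')")
  modules <- read_gmt(gmt_path)
  dge <- moderated_t(expr, meta, contrast)
  fp <- module_fingerprint(dge, modules, alpha,
                           contrast_id = paste0(contrast[1], "_vs_", contrast[2]))
  ref <- utils::read.delim(reference_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("module_id", "pct_up", "pct_down")
  if (!all(need %in% names(ref)))
    stop("reference TSV must have columns: ", paste(need, collapse = ", "))
  idx <- match(fp$module_id, ref$module_id)
  cmp <- data.frame(module_id = fp$module_id, label = fp$label,
                    pct_up = fp$pct_up, pct_down = fp$pct_down,
                    ref_pct_up = ref$pct_up[idx],
                    ref_pct_down = ref$pct_down[idx],
                    stringsAsFactors = FALSE)
  cmp$diff_up <- cmp$pct_up - cmp$ref_pct_up
  cmp$diff_down <- cmp$pct_down - cmp$ref_pct_down
  utils::write.table(cmp, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(list(fingerprint = fp, comparison = cmp))
}
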