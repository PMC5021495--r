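# Shared fixture builders. Everything is generated in code; nothing binary.

# small deterministic expression matrix
tiny_expr <- function(genes = 3, samples = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(genes * samples, 7, 1), 4), genes, samples,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  m
}

# write an expression matrix as a plain TSV fixture, optionally with
# duplicated gene ids (rows keep the ids given)
write_expr_tsv <- function(m, path, gene_ids = rownames(m)) {
  df <- data.frame(gene_id = gene_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gct <- function(m, path, version = "#1.2", dims = dim(m)) {
  con <- file(path, "w")
  writeLines(c(version, paste(dims[1], dims[2], sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = "na", m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  path
}

# two-group metadata for a matrix whose columns are already group-blocked
two_group_meta <- function(expr, n_a, labels = c("A", "B")) {
  data.frame(sample_id = colnames(expr),
             group = rep(labels, c(n_a, ncol(expr) - n_a)),
             stringsAsFactors = FALSE)
}

# a dge_table built directly from given q and log_fc (for fingerprint tests)
fake_dge <- function(gene_id, log_fc, q_bh) {
  tab <- data.frame(gene_id = gene_id, log_fc = log_fc, s2 = 1,
                    t_mod = log_fc, df_total = 10, p_raw = q_bh,
                    q_bh = q_bh, stringsAsFactors = FALSE)
  class(tab) <- c("dge_table", "data.frame")
  tab
}

# independent hypergeometric upper-tail oracle via log-factorial sums
hyper_tail_oracle <- function(k, K, N, n) {
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  if (k <= lo) return(1)
  xs <- k:hi
  if (!length(xs)) return(0)
  terms <- lchoose_(K, xs) + lchoose_(N - K, n - xs) - lchoose_(N, n)
  exp(terms[1]) * sum(exp(terms - terms[1]))
}

# naive O(n^3) average-linkage agglomeration oracle returning the
# cophenetic distance matrix (independent of the package implementation)
naive_average_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  dd <- d; diag(dd) <- Inf
  while (length(clusters) > 1L) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        v <- mean(d[clusters[[i]], clusters[[j]]])
        if (v < best) { best <- v; bi <- i; bj <- j }
      }
    }
    for (a in clusters[[bi]]) for (b in clusters[[bj]]) {
      coph[a, b] <- best; coph[b, a] <- best
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  coph
}

# diagonal-covariance nearest-standardized-centroid oracle (delta = 0)
naive_nsc_predict <- function(x_train, y_train, x_test, priors = NULL) {
  classes <- sort(unique(y_train))
  n <- length(y_train); K <- length(classes)
  cent <- sapply(classes, function(k)
    rowMeans(x_train[, y_train == k, drop = FALSE]))
  ss <- rep(0, nrow(x_train))
  for (k in classes) {
    xk <- x_train[, y_train == k, drop = FALSE]
    ss <- ss + rowSums((xk - rowMeans(xk))^2)
  }
  s_i <- sqrt(ss / (n - K))
  s0 <- median(s_i)
  if (is.null(priors)) priors <- table(y_train)[classes] / n
  apply(x_test, 2, function(x) {
    sc <- sapply(seq_len(K), function(k)
      sum(((x - cent[, k]) / (s_i + s0))^2) - 2 * log(priors[k]))
    classes[which.min(sc)]
  })
}
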