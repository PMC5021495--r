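# dge: moderation prior, moderated t, BH adjustment, significance partition

test_that("moderation prior handles the degenerate and spread limits", {
  # zero spread: all variances equal -> infinite prior df at that value
  pr <- fit_moderation_prior(rep(0.04, 50), df_resid = 10)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.04)

  # two wildly different variances: spread far exceeds chi-square spread
  pr2 <- fit_moderation_prior(c(1e-4, 10), df_resid = 10)
  expect_true(is.finite(pr2$d0) && pr2$d0 > 0)

  expect_error(fit_moderation_prior(c(0, 0, 0), 4), "zero")
  expect_error(fit_moderation_prior(0.5, 4), "at least 2")
})

test_that("prior estimation agrees with the limma moment fit", {
  skip_if_not_installed("limma")
  set.seed(21)
  for (dfr in c(4, 18)) {
    s2 <- 0.07 * 5 / rchisq(3000, 5) * rchisq(3000, dfr) / dfr
    pr <- fit_moderation_prior(s2, dfr)
    f <- limma::fitFDist(s2, dfr)
    expect_equal(pr$d0, f$df2, tolerance = 1e-6)
    expect_equal(pr$s0_sq, f$scale, tolerance = 1e-6)
  }
})

test_that("moderated t matches limma eBayes on simulated data", {
  skip_if_not_installed("limma")
  sim <- simulate_cohorts(simulation_config(
    400, list(planted_module("M", 40, c(A = 0.8))), c(A = 6, B = 8),
    seed = 31))
  tab <- moderated_t(sim$expr, sim$meta, c("A", "B"))
  design <- stats::model.matrix(~ 0 + factor(sim$meta$group,
                                             levels = c("A", "B")))
  colnames(design) <- c("A", "B")
  fit <- limma::lmFit(sim$expr[, sim$meta$sample_id], design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - B,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(tab$t_mod, unname(fit$t[, 1]), tolerance = 1e-10)
  expect_equal(tab$p_raw, unname(fit$p.value[, 1]), tolerance = 1e-10)
  expect_equal(tab$log_fc, unname(fit$coefficients[, 1]), tolerance = 1e-12)
})

test_that("ordinary-t fallback reproduces the pooled two-sample t-test", {
  # printed 2-gene, 3 vs 3 fixture
  m <- matrix(c(5.1, 5.9, 5.4,  6.8, 7.2, 7.0,
                8.0, 8.1, 7.9,  8.0, 8.2, 7.8),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  meta <- two_group_meta(m, 3)
  tab <- moderated_t(m, meta, c("A", "B"), prior = moderation_prior(0, 1))
  for (g in 1:2) {
    tt <- t.test(m[g, 1:3], m[g, 4:6], var.equal = TRUE)
    expect_equal(tab$t_mod[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p_raw[g], tt$p.value, tolerance = 1e-10)
  }
  expect_identical(tab$df_total, rep(4, 2))

  # property: agreement on random small matrices to 1e-10
  for (seed in 41:43) {
    set.seed(seed)
    nA <- sample(2:5, 1); nB <- sample(2:5, 1); ng <- 20
    x <- matrix(rnorm(ng * (nA + nB)), ng,
                dimnames = list(paste0("g", 1:ng),
                                paste0("s", 1:(nA + nB))))
    meta <- two_group_meta(x, nA)
    tab <- moderated_t(x, meta, c("A", "B"),
                       prior = moderation_prior(0, 1))
    oracle_p <- apply(x, 1, function(v)
      t.test(v[1:nA], v[-(1:nA)], var.equal = TRUE)$p.value)
    expect_equal(tab$p_raw, unname(oracle_p), tolerance = 1e-10)
  }
})

test_that("degenerate and limit cases behave as documented", {
  # identical group means -> t = 0, p = 1
  m <- rbind(g1 = c(1, 2, 3, 2, 1, 3), g2 = c(4, 5, 6, 7, 8, 9))
  colnames(m) <- paste0("s", 1:6)
  meta <- two_group_meta(m, 3)
  tab <- moderated_t(m, meta, c("A", "B"))
  expect_identical(tab$t_mod[1], 0)
  expect_identical(tab$p_raw[1], 1)

  # d0 = Inf: every gene shares s0^2, so |t| order equals |log_fc| order
  sim <- simulate_cohorts(simulation_config(60, list(), c(A = 4, B = 4),
                                            seed = 8))
  tinf <- moderated_t(sim$expr, sim$meta, c("A", "B"),
                      prior = moderation_prior(Inf, 0.09))
  expect_identical(order(abs(tinf$t_mod)), order(abs(tinf$log_fc)))
  expect_identical(unique(tinf$df_total), Inf)

  # errors
  expect_error(moderated_t(sim$expr, sim$meta, c("A", "nope")),
               "unknown group")
  meta_small <- sim$meta[-(1:3), ]
  expect_error(moderated_t(sim$expr, meta_small, c("A", "B")),
               ">= 2 samples")
})

test_that("contrast swap negates effects and preserves p-values", {
  sim <- simulate_cohorts(simulation_config(
    200, list(planted_module("M", 30, c(A = 1))), c(A = 5, B = 5),
    seed = 17))
  ab <- moderated_t(sim$expr, sim$meta, c("A", "B"))
  ba <- moderated_t(sim$expr, sim$meta, c("B", "A"))
  expect_equal(ba$log_fc, -ab$log_fc)
  expect_equal(ba$t_mod, -ab$t_mod)
  expect_equal(ba$p_raw, ab$p_raw)
  # dge_table invariants
  expect_true(all(ab$q_bh >= ab$p_raw))
  nz <- ab$log_fc != 0
  expect_identical(sign(ab$t_mod[nz]), sign(ab$log_fc[nz]))
  expect_identical(order(ab$p_raw), order(-abs(ab$t_mod)))
})

test_that("bh_adjust implements the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)                       # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                                # hand-computed
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))

  for (seed in 51:54) {
    set.seed(seed)
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p))                                # inflation
    expect_true(all(q <= 1))
    perm <- sample(length(p))
    expect_identical(bh_adjust(p[perm]), q[perm])           # permutation eqv
  }
})

test_that("significant_genes partitions by direction", {
  tab <- fake_dge(paste0("g", 1:10),
                  log_fc = c(2, 1, -1, -2, 0.5, -0.5, 3, -3, 0, 1),
                  q_bh  = c(0.01, 0.04, 0.03, 0.2, 0.01, 0.04, 0.9,
                            0.05, 0.01, 0.06))
  sig <- significant_genes(tab, 0.05)
  expect_setequal(sig$up, c("g1", "g2", "g5"))               # enumerated
  expect_setequal(sig$down, c("g3", "g6", "g8"))
  expect_length(intersect(sig$up, sig$down), 0)

  none <- significant_genes(fake_dge("g1", 1, 0.5), 0.05)
  expect_length(none$up, 0)
  expect_length(none$down, 0)

  all_g <- significant_genes(tab, 1)                        # alpha = 1
  expect_setequal(c(all_g$up, all_g$down),
                  tab$gene_id[tab$log_fc != 0])
  expect_error(significant_genes(tab, 0), "alpha")
})
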