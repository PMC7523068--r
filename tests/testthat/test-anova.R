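# Two-way fully-within rm-ANOVA: sums-of-squares partition, sphericity
# diagnostics, GG correction, post-hocs and the retention verdict.

# brute-force decomposition by explicit mean subtraction, independent of
# the implementation's sweep-based formulas
brute_force_partition <- function(Y) {
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  gm <- mean(Y)
  term <- function(f) {
    tot <- 0
    for (i in 1:n) for (j in 1:a) for (k in 1:b) tot <- tot + f(i, j, k)^2
    tot
  }
  mi <- apply(Y, 1, mean); mj <- apply(Y, 2, mean); mk <- apply(Y, 3, mean)
  mij <- apply(Y, c(1, 2), mean); mik <- apply(Y, c(1, 3), mean)
  mjk <- apply(Y, c(2, 3), mean)
  list(
    subj = term(function(i, j, k) mi[i] - gm),
    A = term(function(i, j, k) mj[j] - gm),
    B = term(function(i, j, k) mk[k] - gm),
    AB = term(function(i, j, k) mjk[j, k] - mj[j] - mk[k] + gm),
    AS = term(function(i, j, k) mij[i, j] - mi[i] - mj[j] + gm),
    BS = term(function(i, j, k) mik[i, k] - mi[i] - mk[k] + gm),
    ABS = term(function(i, j, k) Y[i, j, k] - mij[i, j] - mik[i, k] -
                 mjk[j, k] + mi[i] + mj[j] + mk[k] - gm),
    total = term(function(i, j, k) Y[i, j, k] - gm))
}

test_that("sums of squares match the brute-force decomposition and sum to the total", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:8, 1); a <- sample(2:3, 1); b <- sample(2:5, 1)
    Y <- array(rnorm(n * a * b, 10, 3), c(n, a, b))
    fit <- rm_anova_2way(Y)
    bf <- brute_force_partition(Y)
    expect_equal(fit$ss[fit$effect == "session"], bf$A, tolerance = 1e-10)
    expect_equal(fit$ss[fit$effect == "trial"], bf$B, tolerance = 1e-10)
    expect_equal(fit$ss[fit$effect == "session:trial"], bf$AB,
                 tolerance = 1e-10)
    expect_equal(fit$err_ss, c(bf$AS, bf$BS, bf$ABS), tolerance = 1e-10)
    expect_equal(attr(fit, "ss_subjects"), bf$subj, tolerance = 1e-10)
    got_total <- sum(fit$ss) + sum(fit$err_ss) + attr(fit, "ss_subjects")
    expect_equal(got_total, attr(fit, "ss_total"), tolerance = 1e-8)
  }
})

test_that("the ANOVA table agrees with aov's error-stratum decomposition", {
  set.seed(17)
  for (rep in 1:4) {
    n <- 6; a <- 3; b <- 4
    Y <- array(rnorm(n * a * b, 5, 2), c(n, a, b))
    fit <- rm_anova_2way(Y)
    long <- data.frame(
      y = c(Y),
      subj = factor(rep(1:n, a * b)),
      A = factor(rep(rep(1:a, each = n), b)),
      B = factor(rep(1:b, each = n * a)))
    ref <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), long))
    getss <- function(stratum, row)
      ref[[stratum]][[1]][row, c("Sum Sq", "F value", "Pr(>F)")]
    rA <- getss("Error: subj:A", "A")
    expect_equal(fit$ss[1], rA[[1]], tolerance = 1e-8)
    expect_equal(fit$F[1], rA[[2]], tolerance = 1e-8)
    expect_equal(fit$p[1], rA[[3]], tolerance = 1e-8)
    rB <- getss("Error: subj:B", "B")
    expect_equal(fit$ss[2], rB[[1]], tolerance = 1e-8)
    expect_equal(fit$F[2], rB[[2]], tolerance = 1e-8)
    rAB <- getss("Error: subj:A:B", "A:B")
    expect_equal(fit$ss[3], rAB[[1]], tolerance = 1e-8)
    expect_equal(fit$F[3], rAB[[2]], tolerance = 1e-8)
  }
})

test_that("Mauchly W and GG epsilon agree with the multivariate reference", {
  skip_if_not_installed("car")
  set.seed(23)
  for (rep in 1:5) {
    n <- 12; a <- 3; b <- 4
    Y <- array(rnorm(n * a * b), c(n, a, b))
    # induce some non-sphericity
    Y[, , 1] <- Y[, , 1] * 2 + Y[, , 2]
    fit <- rm_anova_2way(Y)
    cells <- matrix(aperm(Y, c(1, 3, 2)), n, a * b)  # session slow, trial fast
    idata <- data.frame(session = factor(rep(1:a, each = b)),
                        trial = factor(rep(1:b, a)))
    av <- car::Anova(stats::lm(cells ~ 1), idata = idata,
                     idesign = ~ session * trial, type = 3)
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    sph <- s$sphericity.tests
    adj <- s$pval.adjustments
    for (eff in c("session", "trial", "session:trial")) {
      i <- which(fit$effect == eff)
      expect_equal(fit$mauchly_w[i], sph[eff, "Test statistic"],
                   tolerance = 1e-6)
      expect_equal(fit$mauchly_p[i], sph[eff, "p-value"], tolerance = 1e-6)
      expect_equal(fit$epsilon_gg[i], adj[eff, "GG eps"], tolerance = 1e-6)
      expect_equal(fit$p_gg[i], adj[eff, "Pr(>F[GG])"], tolerance = 1e-6)
    }
  }
})

test_that("GG epsilon hits its analytic anchors", {
  expect_equal(gg_epsilon(diag(4)), 1)            # spherical
  expect_equal(gg_epsilon(matrix(2.7, 1, 1)), 1)  # k = 2: single contrast
  u <- rnorm(9)
  expect_equal(gg_epsilon(outer(u, u)), 1 / 9)    # rank-1, k = 10 levels
})

test_that("Mauchly's test is calibrated under sphericity and detects AR(1)", {
  expect_equal(mauchly_sphericity(matrix(1, 1, 1), 10)$p, 1)  # k = 2
  set.seed(77)
  # spherical population: p-values approximately uniform
  ps <- replicate(200, {
    Z <- matrix(rnorm(200 * 3), 200, 3)   # contrast scores, identity cov
    mauchly_sphericity(cov(Z), 200)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # strong AR(1) correlation: rejected in the majority of replicates
  k <- 5; rho <- 0.85
  Sigma <- rho^abs(outer(1:k, 1:k, "-"))
  Ct <- svd(diag(k) - 1 / k)$u[, 1:(k - 1)]
  R <- chol(Sigma)
  hits <- replicate(20, {
    X <- matrix(rnorm(30 * k), 30, k) %*% R
    m <- mauchly_sphericity(cov(X %*% Ct), 30)
    m$W < 1 && m$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("F statistics are invariant under shift and positive rescaling", {
  set.seed(2)
  Y <- array(rnorm(5 * 3 * 4, 2, 1), c(5, 3, 4))
  f0 <- rm_anova_2way(Y)
  f1 <- rm_anova_2way(Y + 100)
  f2 <- rm_anova_2way(Y * 3.7)
  expect_equal(f1$F, f0$F, tolerance = 1e-8)
  expect_equal(f2$F, f0$F, tolerance = 1e-8)
  expect_equal(f1$p_reported, f0$p_reported, tolerance = 1e-8)
})

test_that("degenerate designs are refused or flagged", {
  expect_error(rm_anova_2way(array(rnorm(2 * 3 * 4), c(2, 3, 4))),
               "at least 3")
  w <- capture_warnings(rm_anova_2way(array(5, c(4, 3, 4))))
  expect_true(any(grepl("constant", w)))
})

test_that("compound-symmetric data keeps epsilon near 1 and p_GG near p", {
  set.seed(19)
  n <- 40; a <- 3; b <- 4
  subj <- rnorm(n, 0, 2)
  Y <- array(rnorm(n * a * b, 0, 1), c(n, a, b)) + subj  # exchangeable cells
  fit <- rm_anova_2way(Y)
  expect_gt(min(fit$epsilon_gg), 0.85)
  expect_equal(fit$p_gg, fit$p, tolerance = 0.05)
})

make_session_design <- function(n, session_means, b = 5, subj_sd = 1,
                                day_sd = 0.3, noise_sd = 0.3) {
  a <- length(session_means)
  subj <- rnorm(n, 0, subj_sd)
  Y <- array(rnorm(n * a * b, 0, noise_sd), c(n, a, b),
             dimnames = list(paste0("P", 1:n), paste0("S", 1:a),
                             paste0("T", 1:b)))
  day <- matrix(rnorm(n * a, 0, day_sd), n, a)
  for (j in 1:a) Y[, j, ] <- Y[, j, ] + session_means[j] + subj + day[, j]
  Y
}

test_that("Tukey HSD recovers a localized session effect and honors null effects", {
  set.seed(55)
  # exactly identical session means (balanced subject-level offsets):
  # zero contrasts against a nonzero error term, adjusted p of 1
  Ynull <- make_session_design(20, c(5, 5, 5), day_sd = 0, noise_sd = 0)
  off <- rep(c(0.5, -0.5), 10)
  Ynull[, 2, ] <- Ynull[, 1, ] + off
  Ynull[, 3, ] <- Ynull[, 1, ] + rev(off)
  fit0 <- suppressWarnings(rm_anova_2way(Ynull))
  ph0 <- suppressWarnings(posthoc_tukey(fit0, "session"))
  expect_true(all(ph0$p_adj > 0.99))
  # S1 differs from S2 = S3: the retention pattern
  Y <- make_session_design(24, c(10, 8.5, 8.5))
  fit <- rm_anova_2way(Y)
  ph <- posthoc_tukey(fit, "session")
  lab <- paste(ph$level_1, ph$level_2)
  expect_lt(ph$p_adj[lab == "S1 S2"], 0.05)
  expect_lt(ph$p_adj[lab == "S1 S3"], 0.05)
  expect_gt(ph$p_adj[lab == "S2 S3"], 0.05)
})

test_that("two-level Tukey agrees with a sign-permutation oracle", {
  set.seed(91)
  n <- 12
  Y <- array(rnorm(n * 2 * 3, 0, 1), c(n, 2, 3))
  Y[, 2, ] <- Y[, 2, ] + 0.6
  fit <- rm_anova_2way(Y)
  ph <- suppressWarnings(posthoc_tukey(fit, "session", gg_adjust = FALSE))
  # permutation: flip each subject's session labels
  d <- apply(Y[, 2, ], 1, mean) - apply(Y[, 1, ], 1, mean)
  obs <- abs(mean(d))
  perms <- replicate(4000, abs(mean(d * sample(c(-1, 1), n, TRUE))))
  p_perm <- mean(perms >= obs - 1e-12)
  expect_lt(abs(ph$p_adj - p_perm), 0.05)
})

test_that("retention verdicts follow the session contrast structure", {
  set.seed(71)
  # learning then plateau: retained, with learning
  Y <- make_session_design(24, c(10, 8.5, 8.5))
  fit <- rm_anova_2way(Y)
  r <- retention_contrast(fit)
  expect_true(r$retained)
  expect_true(r$learning)
  # continued improvement into the last session: not retained
  Y2 <- make_session_design(24, c(10, 8.5, 7))
  r2 <- retention_contrast(rm_anova_2way(Y2))
  expect_false(r2$retained)
  # null cohort: vacuously retained, no learning
  Y3 <- make_session_design(24, c(8, 8, 8))
  r3 <- retention_contrast(rm_anova_2way(Y3))
  expect_true(r3$retained)
  expect_false(r3$learning)
})

test_that("a pure session effect is detected without inventing trial effects", {
  set.seed(99)
  hits_session <- 0; hits_trial <- 0; nrep <- 40
  for (i in 1:nrep) {
    Y <- make_session_design(30, c(10, 8.8, 8.8), b = 10,
                             day_sd = 0.2, noise_sd = 0.5)
    fit <- rm_anova_2way(Y)
    if (fit$p_reported[fit$effect == "session"] < 0.01)
      hits_session <- hits_session + 1
    if (fit$p_reported[fit$effect == "trial"] < 0.05)
      hits_trial <- hits_trial + 1
  }
  expect_gt(hits_session / nrep, 0.9)
  expect_lt(hits_trial / nrep, 0.2)    # ~nominal 5% false positives
})

test_that("learning_analysis assembles per-parameter results from a table", {
  set.seed(12)
  tbl <- rbind(param_table(make_session_design(12, c(10, 8, 8), b = 4),
                           "TaskTime"),
               param_table(make_session_design(12, c(5, 5, 5), b = 4),
                           "PeakVel"))
  la <- suppressWarnings(learning_analysis(
    tbl, parameters = c("TaskTime", "PeakVel")))
  expect_named(la, c("TaskTime", "PeakVel"))
  expect_true(la$TaskTime$retention$retained)
  expect_true(la$PeakVel$retention$retained)  # vacuous
  expect_null(la$PeakVel$posthoc_session)
})

test_that("build_design drops incomplete subjects and keeps labels", {
  set.seed(3)
  tbl <- param_table(array(rnorm(5 * 3 * 4), c(5, 3, 4)), "HPR")
  tbl$value[tbl$subject == "P2" & tbl$session == 2 & tbl$trial == 1] <- NA
  arr <- suppressMessages(build_design(tbl, "HPR", sessions = 1:3,
                                       trials = 1:4))
  expect_equal(dim(arr), c(4, 3, 4))
  expect_false("P2" %in% dimnames(arr)[[1]])
})
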