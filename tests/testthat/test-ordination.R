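euclid_config <- function(n = 8, p = 3, seed = 61) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", seq_len(n)), NULL))
    x
  })
}

test_that("PCoA reproduces Euclidean configurations exactly", {
  x <- euclid_config()
  d <- stats::dist(x)
  fit <- pcoa_ord(d)
  expect_equal(fit$cailliez_constant, 0)
  coords <- as.matrix(fit$coordinates[, -1])
  expect_equal(as.matrix(stats::dist(coords)), as.matrix(d), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$eigenvalues) <= 1e-9))
  expect_equal(sum(fit$proportion), 1)
  # three collinear points: one axis carries everything
  line <- matrix(c(0, 1, 3), dimnames = list(c("a", "b", "c"), NULL))
  lf <- pcoa_ord(stats::dist(line))
  expect_equal(length(lf$eigenvalues), 1)
  expect_equal(lf$proportion, 1)
})

test_that("the Cailliez correction removes negative eigenvalues", {
  rel <- to_relative_abundance(random_count_table(7, 5, seed = 62, depth = 30))
  d <- bray_curtis(rel)
  raw <- pcoa_ord(d, correction = "none")
  expect_gt(length(raw$negative_eigenvalues), 0) # fixture is non-Euclidean
  fixed <- pcoa_ord(d, correction = "cailliez")
  expect_equal(length(fixed$negative_eigenvalues), 0)
  expect_gt(fixed$cailliez_constant, 0)
  # corrected distances embed exactly
  dc <- cailliez_correct(d)
  expect_equal(pcoa_ord(dc, correction = "none")$negative_eigenvalues,
               numeric(0))
})

test_that("PCoA agrees with the reference implementation", {
  rel <- to_relative_abundance(random_count_table(9, 6, seed = 63, depth = 40))
  d <- bray_curtis(rel)
  mine <- pcoa_ord(d, correction = "cailliez")
  ref <- ape::pcoa(d, correction = "cailliez")
  ref_eig <- ref$values$Corr_eig[ref$values$Corr_eig > 1e-8]
  expect_equal(mine$eigenvalues, ref_eig, tolerance = 1e-8)
})

test_that("PERMANOVA detects perfect separation and partitions variance", {
  m <- matrix(1, 6, 6) - diag(6)
  m[1:3, 1:3] <- 0; m[4:6, 4:6] <- 0; diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       grp = rep(c("x", "y"), each = 3))
  fit <- permanova(m, md, "grp", n_perm = 99, seed = 1)
  tab <- tidy(fit)
  expect_equal(tab$r_squared[tab$term == "grp"], 1, tolerance = 1e-12)
  expect_equal(tab$p_value[tab$term == "grp"], 1 / (99 + 1), tolerance = 1e-3)
  # sequential R2 plus residual sums to one on a multi-term model
  x <- euclid_config(n = 12, seed = 64)
  md2 <- tibble::tibble(sample_id = rownames(x),
                        a = rep(c("u", "v"), 6),
                        b = rep(c("p", "q", "r"), each = 4))
  fit2 <- permanova(stats::dist(x), md2, c("a", "b"), n_perm = 99, seed = 2)
  t2 <- tidy(fit2)
  expect_equal(sum(t2$r_squared[t2$term != "Total"]), 1, tolerance = 1e-9)
  expect_error(permanova(stats::dist(x), md2, "missing_term", 99), "unknown")
  md2$c <- "only_level"
  expect_error(permanova(stats::dist(x), md2, "c", 99), "single level")
})

test_that("PERMANOVA on Euclidean distances matches direct SS partitioning", {
  x <- euclid_config(n = 14, p = 4, seed = 65)
  g <- rep(c("u", "v"), 7)
  md <- tibble::tibble(sample_id = rownames(x), g = g)
  fit <- permanova(stats::dist(x), md, "g", n_perm = 49, seed = 3)
  # classical decomposition from the embedded coordinates
  centred <- scale(x, scale = FALSE)
  ss_total <- sum(centred^2)
  ss_within <- sum(vapply(split(seq_len(14), g), function(idx) {
    sum(scale(x[idx, , drop = FALSE], scale = FALSE)^2)
  }, numeric(1)))
  r2_direct <- 1 - ss_within / ss_total
  expect_equal(tidy(fit)$r_squared[1], r2_direct, tolerance = 1e-10)
})

test_that("dispersion test distinguishes spread, not location", {
  x <- euclid_config(n = 20, p = 2, seed = 66)
  # mirror-image groups: same dispersion
  y <- rbind(x, -x)
  rownames(y) <- paste0("s", 1:40)
  g <- rep(c("a", "b"), each = 20)
  fit <- dispersion_test(stats::dist(y), g, n_perm = 199, seed = 4)
  expect_false(fit$degenerate)
  expect_gt(fit$p_value, 0.05)
  # one group blown up: detected
  z <- rbind(x, 3 * x)
  rownames(z) <- paste0("s", 1:40)
  fit2 <- dispersion_test(stats::dist(z), g, n_perm = 199, seed = 5)
  expect_lt(fit2$p_value, 0.05)
  # identical samples: degenerate, not an error
  m0 <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  fit3 <- dispersion_test(m0, rep(c("a", "b"), 3), n_perm = 49)
  expect_true(fit3$degenerate)
  expect_warning(
    dispersion_test(stats::dist(y), c("solo", g[-1]), n_perm = 49, seed = 1),
    "size 1")
})

test_that("VIF pruning removes collinear predictors in the right order", {
  X <- withr::with_seed(67, {
    data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  })
  clean <- vif_prune(X)
  expect_equal(clean$removed, character(0))
  expect_true(all(clean$vif$vif < 1.5))
  # duplicated column goes first
  dup <- cbind(X, x1copy = X$x1 + withr::with_seed(81, rnorm(40, 0, 1e-8)))
  pruned <- vif_prune(dup)
  expect_equal(length(pruned$removed), 1)
  expect_true(pruned$removed %in% c("x1", "x1copy"))
  # derived predictor trio ends below the threshold
  tri <- cbind(X, x4 = X$x1 + X$x2 + withr::with_seed(82, rnorm(40, 0, 0.05)))
  out <- vif_prune(tri, threshold = 10)
  expect_true(all(out$vif$vif < 10))
  expect_gte(length(out$removed), 1)
})

test_that("the Ezekiel adjustment matches its closed form", {
  expect_equal(adjusted_r2(0.5, 21, 4), 0.375)
  expect_equal(adjusted_r2(1, 30, 3), 1)
  expect_lt(adjusted_r2(0.4, 15, 5), 0.4)
  expect_error(adjusted_r2(0.5, 5, 4), "exceed")
})

test_that("dbRDA recovers a noiseless linear structure", {
  withr::with_seed(68, {
    X <- data.frame(p1 = rnorm(20), p2 = rnorm(20))
    Y <- cbind(2 * X$p1 - X$p2, X$p1 + X$p2, 0.5 * X$p2)
    rownames(Y) <- paste0("s", 1:20)
  })
  fit <- db_rda(stats::dist(Y), X, n_perm = 99, seed = 6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-8)
  # a strong but noisy fit yields a significant overall permutation test
  Yn <- Y + withr::with_seed(72, matrix(rnorm(length(Y), 0, 0.2), nrow(Y)))
  fit2 <- db_rda(stats::dist(Yn), X, n_perm = 99, seed = 6)
  expect_lt(glance(fit2)$p_value, 0.05)
  expect_true(all(fit2$axis_tests$p_value > 0 & fit2$axis_tests$p_value <= 1))
  expect_error(db_rda(stats::dist(Y[1:3, ]), X[1:3, ]), "saturated")
})

test_that("RDA on one response column reduces to linear regression", {
  withr::with_seed(69, {
    X <- data.frame(a = rnorm(25), b = rnorm(25))
    y <- 1.5 * X$a - 0.5 * X$b + rnorm(25, 0, 0.3)
  })
  fit <- rda_fit(data.frame(y = y), X, n_perm = 99, seed = 7)
  lmfit <- summary(lm(scale(y) ~ scale(X$a) + scale(X$b)))
  expect_equal(fit$r_squared, lmfit$r.squared, tolerance = 1e-12)
  # duplicated responses collapse to a single constrained dimension
  fit2 <- rda_fit(data.frame(y1 = y, y2 = y), X, n_perm = 99, seed = 8)
  eig <- fit2$eigenvalues$eigenvalue
  expect_equal(sum(eig > 1e-8 * max(eig)), 1)
})

test_that("RDA recovers the generating predictor's loading", {
  withr::with_seed(70, {
    sal <- rnorm(30)
    noise <- rnorm(30)
    resp <- data.frame(d1 = 0.8 * sal + rnorm(30, 0, 0.2),
                       d2 = 0.8 * sal + rnorm(30, 0, 0.2))
    X <- data.frame(sal = sal, other = noise)
  })
  fit <- rda_fit(resp, X, n_perm = 99, seed = 9)
  bp <- vegan::scores(fit$ordination, display = "bp", choices = 1)
  expect_gt(abs(bp["sal", 1]), abs(bp["other", 1]))
})

test_that("variance partitioning cells solve the commonality system", {
  withr::with_seed(71, {
    g1 <- rnorm(25); g2 <- rnorm(25)
    Y <- cbind(g1 + rnorm(25, 0, .4), g2 + rnorm(25, 0, .4))
    rownames(Y) <- paste0("s", 1:25)
    X <- data.frame(g1 = g1, g2 = g2)
  })
  d <- stats::dist(Y)
  vp <- variance_partition(d, X, groups = list(one = "g1", two = "g2"))
  expect_equal(sum(vp$fractions$fraction), vp$total_adj_r2, tolerance = 1e-9)
  expect_equal(vp$residual, 1 - vp$total_adj_r2, tolerance = 1e-9)
  # orthogonal groups share essentially nothing
  shared <- vp$fractions$fraction[vp$fractions$component == "one:two"]
  expect_lt(abs(shared), 0.05)
  # near-duplicate groups share essentially everything
  X2 <- data.frame(g1 = g1, g1b = g1 + withr::with_seed(83, rnorm(25, 0, 1e-6)))
  vp2 <- variance_partition(d, X2, groups = list(one = "g1", two = "g1b"))
  u <- vp2$fractions$fraction[vp2$fractions$n_groups == 1]
  s <- vp2$fractions$fraction[vp2$fractions$component == "one:two"]
  # unique fractions vanish up to the Ezekiel penalty of the extra predictor
  expect_lt(max(abs(u)), 0.05)
  expect_gt(s, 0.9 * vp2$total_adj_r2)
  expect_error(variance_partition(d, X, groups = list(a = "g1")), "2 to 4")
  expect_error(variance_partition(d, X, groups = list(a = "g1", b = "g1")),
               "disjoint")
})

test_that("tidiers return tibbles with the promised columns", {
  x <- euclid_config()
  p <- pcoa_ord(stats::dist(x))
  expect_tibble(tidy(p)); expect_tibble(glance(p))
  md <- tibble::tibble(sample_id = rownames(x), g = rep(c("a", "b"), 4))
  pm <- permanova(stats::dist(x), md, "g", n_perm = 49, seed = 1)
  expect_named(tidy(pm), c("term", "df", "sum_of_squares", "r_squared",
                           "pseudo_f", "p_value"))
  fit <- db_rda(stats::dist(x), data.frame(z = withr::with_seed(1, rnorm(8))),
                n_perm = 49, seed = 2)
  expect_tibble(tidy(fit))
  expect_named(glance(fit), c("kind", "r_squared", "adj_r_squared", "pseudo_f",
                              "p_value", "n", "n_predictors"))
})
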