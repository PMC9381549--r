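gower_center <- function(A) {
  n <- nrow(A)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

#' Cailliez additive constant and corrected distances
#'
#' `cailliez_constant()` returns the smallest constant c such that adding c
#' to every off-diagonal dissimilarity makes the configuration Euclidean
#' (no negative principal-coordinate eigenvalues), via the standard 2n x 2n
#' companion eigenproblem. Euclidean input gives 0.
#' `cailliez_correct()` applies it.
#'
#' @param d `dist` or symmetric matrix.
#' @param tol eigenvalue tolerance below which the input counts as
#'   Euclidean already.
#' @return a single constant, or for `cailliez_correct()` the corrected
#'   `dist` with the constant attached as attribute `"cailliez_constant"`.
#' @export
cailliez_constant <- function(d, tol = 1e-8) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  G <- gower_center(-0.5 * m^2)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > -tol * max(abs(ev))) return(0)
  d1 <- gower_center(-0.5 * m^2)
  d2 <- gower_center(-0.5 * m)
  B <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  vals <- eigen(B, only.values = TRUE)$values
  max(Re(vals[abs(Im(vals)) < 1e-8]))
}

#' @rdname cailliez_constant
#' @export
cailliez_correct <- function(d, tol = 1e-8) {
  m <- as_dist_matrix(d)
  cc <- cailliez_constant(m, tol)
  if (cc > 0) {
    m <- m + cc
    diag(m) <- 0
  }
  out <- stats::as.dist(m)
  attr(out, "cailliez_constant") <- cc
  out
}

#' Principal coordinates analysis with optional Cailliez correction
#'
#' Gower double-centering of `-0.5 * D^2`, eigendecomposition, coordinates
#' scaled by the square root of the eigenvalues. With
#' `correction = "cailliez"` a non-Euclidean input is first made Euclidean
#' by the additive constant, so all retained eigenvalues are non-negative.
#'
#' @param d `dist` or symmetric matrix of sample dissimilarities.
#' @param correction `"cailliez"` (default) or `"none"`.
#' @return an `eco_pcoa` object: `coordinates` (tibble, `sample_id` +
#'   `Axis1..k`), `eigenvalues`, `proportion` (of the positive eigenvalue
#'   total), `cailliez_constant`, `negative_eigenvalues` (those below zero
#'   when uncorrected).
#' @export
pcoa_ord <- function(d, correction = c("cailliez", "none")) {
  correction <- match.arg(correction)
  m <- as_dist_matrix(d)
  cc <- 0
  if (correction == "cailliez") {
    dc <- cailliez_correct(m)
    cc <- attr(dc, "cailliez_constant")
    m <- as_dist_matrix(dc)
  }
  G <- gower_center(-0.5 * m^2)
  e <- eigen(G, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    nrow = sum(pos))
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = dplyr::bind_cols(tibble(sample_id = rownames(m)),
                                   as_tibble(coords)),
    eigenvalues = e$values[pos],
    proportion = e$values[pos] / sum(e$values[pos]),
    cailliez_constant = cc,
    negative_eigenvalues = e$values[e$values < -tol]
  ), class = "eco_pcoa")
}

#' @export
print.eco_pcoa <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", length(x$eigenvalues),
      "positive axes; Cailliez constant", format(x$cailliez_constant, digits = 4),
      "\n")
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' Sequential (Type-I) partitioning of the distance-matrix sum of squares
#' among metadata terms in the caller's order, with pseudo-F and
#' permutation p-values of the form (1 + exceedances) / (1 + n_perm).
#' Delegates the McArdle-Anderson partitioning to [vegan::adonis2()].
#'
#' @param d `dist` or symmetric matrix.
#' @param metadata data frame with `sample_id` plus the term columns.
#' @param terms character vector of metadata columns, in testing order.
#' @param n_perm permutations (default 999).
#' @param seed optional integer.
#' @return an `eco_permanova` object; [tidy()] gives the per-term table.
#' @export
permanova <- function(d, metadata, terms, n_perm = 999, seed = NULL) {
  m <- as_dist_matrix(d)
  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% names(metadata)) stop("metadata needs 'sample_id'")
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx)) stop("metadata missing sample(s): ",
                       paste(rownames(m)[is.na(idx)], collapse = ", "))
  missing_terms <- setdiff(terms, names(metadata))
  if (length(missing_terms)) stop("unknown term(s): ",
                                  paste(missing_terms, collapse = ", "))
  df <- metadata[idx, terms, drop = FALSE]
  for (tm in terms) {
    v <- df[[tm]]
    if (!is.numeric(v) && length(unique(v)) < 2)
      stop("term '", tm, "' has a single level")
  }
  dd <- stats::as.dist(m)
  fit <- with_seed_(seed, {
    vegan::adonis2(dd ~ ., data = df, permutations = n_perm, by = "terms")
  })
  tab <- as.data.frame(fit)
  out <- tibble(
    term = rownames(tab), df = tab$Df, sum_of_squares = tab$SumOfSqs,
    r_squared = tab$R2, pseudo_f = tab$F, p_value = tab[["Pr(>F)"]]
  )
  structure(list(table = out, terms = terms, n_perm = n_perm),
            class = "eco_permanova")
}

#' @export
print.eco_permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_perm, " permutations)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Homogeneity of multivariate dispersion
#'
#' Distance of each sample to its group centroid in the Cailliez-corrected
#' principal-coordinate space, with a permutation F-test of group-wise
#' dispersion differences (via [vegan::betadisper()]). Groups of size 1 are
#' excluded with a warning; a configuration where every dispersion is zero
#' is reported as degenerate rather than tested.
#'
#' @param d `dist` or symmetric matrix.
#' @param groups group label per sample (in the order of the distance
#'   labels).
#' @param n_perm permutations (default 999).
#' @param seed optional integer.
#' @return an `eco_dispersion` object with elements `distances` (tibble),
#'   `f_statistic`, `p_value`, `degenerate`.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = NULL) {
  m <- as_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  sizes <- table(groups)
  singles <- names(sizes)[sizes == 1]
  if (length(singles)) {
    warning("group(s) of size 1 excluded: ", paste(singles, collapse = ", "))
    keep <- !groups %in% singles
    m <- m[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least two groups of size >= 2")
  if (all(abs(m) < 1e-12)) {
    dists <- tibble(sample_id = rownames(m), group = groups,
                    distance_to_centroid = 0)
    return(structure(list(distances = dists, f_statistic = NA_real_,
                          p_value = NA_real_, degenerate = TRUE),
                     class = "eco_dispersion"))
  }
  dc <- cailliez_correct(m)
  bd <- vegan::betadisper(dc, groups, type = "centroid")
  dists <- tibble(sample_id = rownames(m), group = groups,
                  distance_to_centroid = as.numeric(bd$distances))
  if (all(bd$distances < 1e-12)) {
    return(structure(list(distances = dists, f_statistic = NA_real_,
                          p_value = NA_real_, degenerate = TRUE),
                     class = "eco_dispersion"))
  }
  pt <- with_seed_(seed, vegan::permutest(bd, permutations = n_perm))
  structure(list(distances = dists,
                 f_statistic = pt$tab$F[1L],
                 p_value = pt$tab[["Pr(>F)"]][1L],
                 degenerate = FALSE),
            class = "eco_dispersion")
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - m - 1)` for a model with `m` predictors
#' fitted to `n` observations; the adjustment used for all RDA-type models
#' here.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations.
#' @param m number of predictors.
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n - m - 1 <= 0) stop("adjustment undefined: n must exceed m + 1")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Iterative variance-inflation-factor pruning
#'
#' Computes `VIF_j = 1 / (1 - R2_j)` from regressing each predictor on the
#' others and repeatedly removes the predictor with the highest VIF until
#' all are below `threshold`. Perfectly collinear predictors (infinite VIF)
#' go first.
#'
#' @param predictor_table data frame of numeric predictors.
#' @param threshold VIF ceiling (default 10).
#' @return an `eco_vif` object: `retained`, `removed` (in removal order),
#'   `vif` (tibble of final VIFs).
#' @export
vif_prune <- function(predictor_table, threshold = 10) {
  X <- as.data.frame(predictor_table)
  if (!all(vapply(X, is.numeric, logical(1)))) stop("predictors must be numeric")
  X <- as.data.frame(scale(X))
  removed <- character(0)
  vif_of <- function(X) {
    vapply(names(X), function(j) {
      r2 <- summary(stats::lm(X[[j]] ~ ., data = X[setdiff(names(X), j)]))$r.squared
      if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (ncol(X) > 1) {
    v <- vif_of(X)
    if (max(v) < threshold) break
    worst <- names(X)[which.max(v)]
    removed <- c(removed, worst)
    X <- X[setdiff(names(X), worst)]
  }
  final <- if (ncol(X) > 1) vif_of(X) else setNames(1, names(X))
  structure(list(retained = names(X), removed = removed,
                 vif = tibble(predictor = names(final), vif = as.numeric(final)),
                 threshold = threshold),
            class = "eco_vif")
}

# shared fitting core for dbRDA / RDA wrappers
fit_constrained <- function(ord, n, m, n_perm, seed, predictors, kind) {
  r2 <- ord$CCA$tot.chi / ord$tot.chi
  adj <- adjusted_r2(r2, n, m)
  tests <- with_seed_(seed, {
    overall <- vegan::anova.cca(ord, permutations = n_perm)
    axes <- vegan::anova.cca(ord, by = "axis", permutations = n_perm)
    list(overall = overall, axes = axes)
  })
  ov <- as.data.frame(tests$overall)
  ax <- as.data.frame(tests$axes)
  eig <- ord$CCA$eig
  sc <- vegan::scores(ord, display = "sites",
                      choices = seq_along(eig))
  structure(list(
    ordination = ord, kind = kind,
    r_squared = r2, adj_r_squared = adj, n = n, m = m,
    predictors = predictors,
    eigenvalues = tibble(axis = names(eig), eigenvalue = as.numeric(eig),
                         proportion = as.numeric(eig) / ord$tot.chi),
    overall_test = tibble(pseudo_f = ov$F[1L], p_value = ov[["Pr(>F)"]][1L]),
    axis_tests = tibble(axis = rownames(ax)[seq_along(eig)],
                        pseudo_f = ax$F[seq_along(eig)],
                        p_value = ax[["Pr(>F)"]][seq_along(eig)]),
    site_scores = dplyr::bind_cols(
      tibble(sample_id = rownames(sc)), as_tibble(as.matrix(sc))
    )
  ), class = "eco_dbrda")
}

#' Distance-based redundancy analysis
#'
#' Cailliez-corrected principal coordinates of the dissimilarity matrix are
#' regressed on z-score standardised predictors (all positive axes
#' retained as response, preserving total inertia), with overall and
#' per-axis permutation tests. Fitting is delegated to
#' [vegan::capscale()]; R-squared is constrained over total inertia with
#' the Ezekiel adjustment. Prune collinear predictors with [vif_prune()]
#' first.
#'
#' @param d `dist` or symmetric matrix of sample dissimilarities.
#' @param predictors data frame of numeric predictors (rows in distance
#'   order).
#' @param n_perm permutations (default 1000).
#' @param seed optional integer.
#' @return an `eco_dbrda` object; see [tidy.eco_dbrda()] and
#'   [glance.eco_dbrda()].
#' @export
db_rda <- function(d, predictors, n_perm = 1000, seed = NULL) {
  m_ <- as_dist_matrix(d)
  predictors <- as.data.frame(predictors)
  n <- nrow(m_)
  m <- ncol(predictors)
  if (nrow(predictors) != n) stop("predictor rows must match samples")
  if (m >= n - 1) stop("saturated model: need fewer predictors than n - 1")
  pred_std <- as.data.frame(scale(predictors))
  dd <- stats::as.dist(m_)
  ord <- vegan::capscale(dd ~ ., data = pred_std, add = "cailliez")
  fit_constrained(ord, n, m, n_perm, seed, names(pred_std), kind = "dbRDA")
}

#' Redundancy analysis on numeric response columns
#'
#' Classical RDA of z-scored response variables (e.g. paired free-living
#' versus particle-attached dissimilarities) on z-scored predictors; same
#' statistics and return type as [db_rda()].
#'
#' @param response_table data frame of numeric response columns.
#' @inheritParams db_rda
#' @export
rda_fit <- function(response_table, predictors, n_perm = 1000, seed = NULL) {
  Y <- as.data.frame(response_table)
  if (!all(vapply(Y, is.numeric, logical(1)))) stop("response must be numeric")
  predictors <- as.data.frame(predictors)
  n <- nrow(Y)
  m <- ncol(predictors)
  if (nrow(predictors) != n) stop("predictor rows must match response rows")
  if (m >= n - 1) stop("saturated model: need fewer predictors than n - 1")
  Ys <- as.data.frame(scale(Y))
  # a constant response column carries no variance to explain
  Ys <- Ys[, vapply(Ys, function(x) all(is.finite(x)), logical(1)), drop = FALSE]
  pred_std <- as.data.frame(scale(predictors))
  Ym <- as.matrix(Ys)
  ord <- vegan::rda(Ym ~ ., data = pred_std)
  fit_constrained(ord, n, m, n_perm, seed, names(pred_std), kind = "RDA")
}

#' @export
print.eco_dbrda <- function(x, ...) {
  cat(x$kind, ": R2 = ", format(x$r_squared, digits = 4),
      ", adjusted R2 = ", format(x$adj_r_squared, digits = 4),
      ", overall p = ", format(x$overall_test$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Variance partitioning of a dissimilarity matrix across predictor groups
#'
#' Fits the Cailliez-corrected dbRDA for every non-empty subset of 2-4
#' disjoint predictor groups and decomposes the full-model adjusted
#' R-squared into unique and shared fractions (commonality analysis: the
#' cells solve the inclusion-exclusion system exactly, so they always sum
#' to the full-model adjusted R-squared). Negative fractions are retained
#' in the output; suppress them at display time if desired.
#'
#' @param d `dist` or symmetric matrix.
#' @param predictors data frame holding all predictor columns.
#' @param groups named list (2-4 entries) of disjoint character vectors of
#'   predictor column names.
#' @return an `eco_varpart` object: `fractions` (tibble with `component`,
#'   `groups_involved`, `fraction`), `subset_r2`, `residual`,
#'   `total_adj_r2`.
#' @export
variance_partition <- function(d, predictors, groups) {
  m_ <- as_dist_matrix(d)
  predictors <- as.data.frame(predictors)
  k <- length(groups)
  if (k < 2 || k > 4) stop("need 2 to 4 predictor groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  all_cols <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_cols)) stop("groups must be disjoint")
  if (length(setdiff(all_cols, names(predictors))))
    stop("unknown predictor column(s): ",
         paste(setdiff(all_cols, names(predictors)), collapse = ", "))
  gnames <- names(groups)
  subsets <- purrr::map(seq_len(2^k - 1), function(code) {
    gnames[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
  })
  adj <- vapply(subsets, function(s) {
    cols <- unlist(groups[s], use.names = FALSE)
    fit <- db_rda_r2_only(m_, predictors[, cols, drop = FALSE])
    fit
  }, numeric(1))
  # solve R(S) = sum over cells T with T intersecting S
  ns <- length(subsets)
  M <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    M[i, j] <- as.numeric(length(intersect(subsets[[i]], subsets[[j]])) > 0)
  }
  cells <- solve(M, adj)
  total <- adj[[length(subsets)]] # full model: last subset is all groups
  fractions <- tibble(
    component = vapply(subsets, paste, character(1), collapse = ":"),
    n_groups = lengths(subsets),
    fraction = as.numeric(cells)
  )
  structure(list(
    fractions = fractions,
    subset_r2 = tibble(subset = vapply(subsets, paste, character(1), collapse = "+"),
                       adj_r_squared = adj),
    total_adj_r2 = total,
    residual = 1 - total
  ), class = "eco_varpart")
}

# adjusted R2 of the Cailliez dbRDA without permutation tests (varpart core)
db_rda_r2_only <- function(m_, predictors) {
  pred_std <- as.data.frame(scale(predictors))
  dd <- stats::as.dist(m_)
  ord <- vegan::capscale(dd ~ ., data = pred_std, add = "cailliez")
  adjusted_r2(ord$CCA$tot.chi / ord$tot.chi, nrow(m_), ncol(predictors))
}

#' @export
print.eco_varpart <- function(x, ...) {
  cat("Variance partitioning: total adjusted R2 =",
      format(x$total_adj_r2, digits = 4), "\n")
  print(x$fractions)
  invisible(x)
}
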