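#' Per-sample alpha diversity
#'
#' Richness (taxa with abundance > 0), Shannon entropy in nats on
#' within-sample proportions, and Faith's phylogenetic diversity (total
#' branch length of the subtree spanning the present tips and the root —
#' the rooted PD convention). Empty samples get 0 for all three indices
#' with a message rather than an error.
#'
#' @param table count or relative-abundance matrix (samples x taxa).
#' @param tree rooted `phylo` covering the table's taxa; `NULL` skips
#'   Faith's PD.
#' @return tibble with columns `sample_id`, `richness`, `shannon`,
#'   `faith_pd`.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  table <- validate_count_table(table, integer = FALSE)
  richness <- rowSums(table > 0)
  empty <- richness == 0
  if (any(empty)) message("empty sample(s): ",
                          paste(rownames(table)[empty], collapse = ", "))
  shannon <- ifelse(empty, 0, vegan::diversity(table, index = "shannon"))
  pd <- rep(NA_real_, nrow(table))
  if (!is.null(tree)) {
    al <- align_table_and_tree(table, tree)
    pd <- faith_pd(al$table, al$tree)
  }
  tibble(sample_id = rownames(table), richness = as.integer(richness),
         shannon = as.numeric(shannon), faith_pd = pd)
}

# Rooted Faith's PD per sample; degenerate rows (0 or 1 taxon) handled
# directly, the rest delegated to picante.
faith_pd <- function(table, tree) {
  richness <- rowSums(table > 0)
  pd <- numeric(nrow(table))
  root_depth <- ape::node.depth.edgelength(tree)
  single <- which(richness == 1)
  for (s in single) {
    tip <- which(table[s, ] > 0)
    pd[s] <- root_depth[match(colnames(table)[tip], tree$tip.label)]
  }
  multi <- which(richness >= 2)
  if (length(multi)) {
    res <- picante::pd(table[multi, , drop = FALSE], tree, include.root = TRUE)
    pd[multi] <- res$PD
  }
  pd
}

#' Bray-Curtis dissimilarity between samples
#'
#' Operates on total-sum-scaled rows only: callers must normalise first so
#' the dissimilarity reflects composition, not depth.
#'
#' @param rel_table relative-abundance matrix; every row must sum to 1.
#' @return a `dist` with values in `[0, 1]`.
#' @export
bray_curtis <- function(rel_table) {
  rel_table <- validate_count_table(rel_table, integer = FALSE)
  if (max(abs(rowSums(rel_table) - 1)) > 1e-6)
    stop("rows must sum to 1; total-sum-scale the table first")
  vegan::vegdist(rel_table, method = "bray")
}

#' Patristic distances between all tip pairs
#'
#' Sum of branch lengths along the unique path between each pair of tips.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return symmetric matrix with zero diagonal, tips as dimnames.
#' @export
patristic_distances <- function(tree) {
  tree <- validate_tree(tree)
  stats::cophenetic(tree)
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For samples k and m with relative abundances f,
#' `betaMNTD(k, m) = 0.5 * (sum_i f_ik min_j d(i, j) + sum_j f_jm min_i d(j, i))`
#' where i runs over taxa present in k, j over taxa present in m, and d is
#' the patristic distance. A taxon present in both communities has nearest
#' relative distance 0, so identical communities score 0.
#'
#' @param rel_table relative-abundance matrix; rows sum to 1, no empty rows.
#' @param tree rooted `phylo` covering the table's taxa.
#' @return a `dist` of betaMNTD values.
#' @export
beta_mntd <- function(rel_table, tree) {
  rel_table <- validate_count_table(rel_table, integer = FALSE)
  if (max(abs(rowSums(rel_table) - 1)) > 1e-6)
    stop("rows must sum to 1; total-sum-scale the table first")
  empty <- rownames(rel_table)[rowSums(rel_table > 0) == 0]
  if (length(empty)) stop("empty sample(s): ", paste(empty, collapse = ", "))
  al <- align_table_and_tree(rel_table, tree)
  D <- patristic_distances(al$tree)[colnames(al$table), colnames(al$table)]
  m <- cpp_beta_mntd(D, al$table, seq_len(ncol(al$table)))
  dimnames(m) <- list(rownames(al$table), rownames(al$table))
  stats::as.dist(m)
}
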