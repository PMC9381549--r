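# Shared fixtures and independent oracles, all built in code.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

toy_table <- function() {
  matrix(c(1, 1, 0, 0,
           0, 0, 1, 0,
           0, 0, 1, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C", "D")))
}

random_count_table <- function(n_samples, n_taxa, seed, depth = 200) {
  withr::with_seed(seed, {
    m <- t(stats::rmultinom(n_samples, depth, stats::rlnorm(n_taxa)))
    dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                        paste0("t", seq_len(n_taxa)))
    m
  })
}

# Brute-force betaMNTD: double loop over taxa with tip-tip distances taken
# from ape::dist.nodes (a code path independent of the implementation's
# cophenetic lookup). Deliberately slow and literal.
bmntd_oracle <- function(rel, tree) {
  dn <- ape::dist.nodes(tree)[seq_along(tree$tip.label), seq_along(tree$tip.label)]
  dimnames(dn) <- list(tree$tip.label, tree$tip.label)
  ids <- rownames(rel)
  out <- matrix(0, nrow(rel), nrow(rel), dimnames = list(ids, ids))
  for (k in seq_len(nrow(rel))) for (m in seq_len(nrow(rel))) {
    if (k == m) next
    pk <- colnames(rel)[rel[k, ] > 0]
    pm <- colnames(rel)[rel[m, ] > 0]
    acc <- 0
    for (i in pk) acc <- acc + rel[k, i] * min(dn[i, pm])
    for (j in pm) acc <- acc + rel[m, j] * min(dn[j, pk])
    out[k, m] <- 0.5 * acc
  }
  out
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
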