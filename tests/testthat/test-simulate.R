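test_that("simulated trees are ultrametric, sized and reproducible", {
  tree <- simulate_tree(4, seed = 1)
  expect_equal(length(tree$tip.label), 4)
  depths <- ape::node.depth.edgelength(tree)[1:4]
  expect_true(diff(range(depths)) < 1e-9)
  expect_identical(ape::write.tree(simulate_tree(24, seed = 7)),
                   ape::write.tree(simulate_tree(24, seed = 7)))
  expect_false(identical(ape::write.tree(simulate_tree(24, seed = 7)),
                         ape::write.tree(simulate_tree(24, seed = 8))))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("Brownian niche traits match the closed-form variance", {
  tree2 <- ape::read.tree(text = "(A:2,B:2);")
  # degenerate diffusion
  expect_equal(unname(evolve_niche_traits(tree2, 0, root_value = 3, seed = 1)),
               c(3, 3))
  sims <- vapply(seq_len(4000),
                 function(i) evolve_niche_traits(tree2, 1.5, seed = i)["A"],
                 numeric(1))
  # tip variance = sigma^2 * depth; 4000 reps give ~2.2% relative SE
  expect_equal(stats::var(sims), 1.5^2 * 2, tolerance = 0.07)
})

test_that("Brownian traits carry phylogenetic signal", {
  tree <- simulate_tree(50, seed = 3)
  D <- patristic_distances(tree)
  rhos <- vapply(seq_len(40), function(i) {
    tr <- evolve_niche_traits(tree, 1, seed = 100 + i)
    td <- as.matrix(stats::dist(tr[rownames(D)]))
    stats::cor(D[lower.tri(D)], td[lower.tri(td)], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0)
  expect_gt(mean(rhos > 0), 0.8)
})

test_that("niche conservatism freezes traits within subclades", {
  tree <- simulate_tree(60, seed = 5)
  ctree <- conserve_niches(tree, n_niches = 8)
  tr <- evolve_niche_traits(ctree, 1, seed = 6)
  expect_equal(length(unique(round(tr, 9))), 8)
  # topology and tip set unchanged
  expect_identical(ctree$tip.label, tree$tip.label)
  expect_true(all(ctree$edge.length <= tree$edge.length + 1e-12))
})

test_that("selection sampling follows the Gaussian niche filter", {
  tree <- toy_tree()
  traits <- c(A = 1, B = 2, C = 10, D = 20)
  # E far outside with a tight filter: nearest-trait taxon dominates
  cts <- simulate_selection_communities(tree, traits, c(s1 = 40), sigma_f = 0.5,
                                        depth = 5000, seed = 1)
  expect_gt(cts["s1", "D"] / 5000, 0.99)
  # flat-filter limit recovers the metacommunity
  big <- simulate_selection_communities(tree, traits, c(s1 = 40), sigma_f = 1e6,
                                        depth = 4e6, seed = 2)
  a <- withr::with_seed(2, rlnorm(4))
  expect_lt(max(abs(big[1, ] / 4e6 - a / sum(a))), 1e-3)
  # determinism
  expect_identical(
    simulate_selection_communities(tree, traits, c(s1 = 5, s2 = 9), 2, seed = 3),
    simulate_selection_communities(tree, traits, c(s1 = 5, s2 = 9), 2, seed = 3))
  expect_error(simulate_selection_communities(tree, traits, c(s1 = 5), -1),
               "positive")
})

test_that("neutral communities are exchangeable multinomial draws", {
  tree <- simulate_tree(30, seed = 9)
  cts <- simulate_neutral_communities(tree, 200, depth = 2000, seed = 10)
  a <- withr::with_seed(10, {
    v <- rlnorm(30); v / sum(v)
  })
  prop <- colMeans(sweep(cts, 1, rowSums(cts), "/"))
  se <- sqrt(a * (1 - a) / 2000 / 200)
  expect_true(all(abs(prop - a) < 3 * se + 5e-4))
  # depth -> infinity proxy: two samples nearly identical in composition
  big <- simulate_neutral_communities(tree, 2, depth = 1e6, seed = 11)
  bc <- bray_curtis(to_relative_abundance(big))
  expect_lt(as.numeric(bc), 0.01)
  expect_identical(cts, simulate_neutral_communities(tree, 200, 2000, seed = 10))
})

test_that("dispersal limitation restricts richness and pairwise overlap", {
  tree <- simulate_tree(200, seed = 12)
  cts <- simulate_dispersal_limited(tree, 2000, founders = 5, depth = 100,
                                    seed = 13, sdlog = 0)
  expect_true(all(rowSums(cts > 0) <= 5))
  shared <- vapply(seq_len(1000), function(i) {
    sum(cts[2 * i - 1, ] > 0 & cts[2 * i, ] > 0)
  }, numeric(1))
  expect_equal(mean(shared), 25 / 200, tolerance = 0.10)
  expect_error(simulate_dispersal_limited(tree, 2, founders = 200), "smaller")
})

test_that("planted co-occurrence creates signed correlations at fixed depth", {
  tree <- simulate_tree(40, seed = 14)
  base <- simulate_neutral_communities(tree, 100, depth = 2000, seed = 15)
  groups <- list(plus = colnames(base)[1:6], minus = colnames(base)[7:12])
  expect_identical(plant_cooccurrence(base, groups, 0, seed = 1), base)
  out <- plant_cooccurrence(base, groups, 1, seed = 16, antagonistic = "minus")
  expect_identical(rowSums(out), rowSums(base))
  rel <- to_relative_abundance(out)
  within_plus <- cor(rel[, groups$plus])
  cross <- cor(rel[, groups$plus], rel[, groups$minus])
  expect_gt(mean(within_plus[lower.tri(within_plus)]), 0)
  expect_lt(mean(cross), 0)
  expect_error(plant_cooccurrence(base, groups, 1.5), "\\[0, 1\\]")
})

test_that("assembly scenarios are pure functions of their seed", {
  a <- simulate_assembly_scenario("homogeneous_selection", n_taxa = 60,
                                  n_samples = 6, depth = 500, seed = 2)
  b <- simulate_assembly_scenario("homogeneous_selection", n_taxa = 60,
                                  n_samples = 6, depth = 500, seed = 2)
  expect_identical(a$counts, b$counts)
  v <- simulate_assembly_scenario("variable_selection", n_taxa = 60,
                                  n_samples = 6, depth = 500, seed = 2)
  expect_equal(sort(unique(v$block)), c("A", "B"))
  expect_equal(length(unique(v$env)), 2)
})

test_that("the synthetic estuary survey matches its stated design", {
  sim <- simulate_estuary_dataset(scenario_config(n_taxa = 80, depth = 1000),
                                  seed = 21)
  md <- sim$metadata
  expect_equal(nrow(sim$counts), 90)
  expect_equal(unname(table(md$fraction)[c("FL", "PA")]), c(45L, 45L),
               ignore_attr = TRUE)
  expect_true(all(rowSums(sim$counts) == 1000))
  expect_equal(range(md$salinity), c(0, 34))
  # nutrients follow the conservative dilution line
  expect_lt(cor(md$DIN, md$salinity, method = "spearman"), -0.9)
  expect_lt(cor(md$silicate, md$salinity, method = "spearman"), -0.9)
  expect_tibble(sim$taxonomy)
  expect_true(all(c("Chloroplast") %in% sim$taxonomy$order))
  prov <- attr(sim, "provenance")
  expect_true(is.list(prov) && !is.null(prov$specialist_clade))
  # deterministic under the config seed
  again <- simulate_estuary_dataset(scenario_config(n_taxa = 80, depth = 1000),
                                    seed = 21)
  expect_identical(sim$counts, again$counts)
})

test_that("particle-specialist skew controls FL-PA divergence", {
  profile_gap <- function(skew) {
    sim <- simulate_estuary_dataset(
      scenario_config(n_taxa = 80, depth = 1500, pa_skew = skew), seed = 22)
    rel <- to_relative_abundance(sim$counts)
    md <- sim$metadata
    fl <- colMeans(rel[md$sample_id[md$fraction == "FL"], ])
    pa <- colMeans(rel[md$sample_id[md$fraction == "PA"], ])
    spec <- attr(sim, "provenance")$specialist_clade
    list(cor = cor(fl, pa), ratio = sum(pa[spec]) / max(sum(fl[spec]), 1e-9))
  }
  none <- profile_gap(0)
  some <- profile_gap(1.5)
  expect_gt(none$cor, 0.99)       # no skew: identically distributed fractions
  expect_gt(some$ratio, none$ratio)
  expect_gt(some$ratio, 1.5)
})
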