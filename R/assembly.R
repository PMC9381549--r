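#' Beta nearest taxon index from a tip-shuffle null model
#'
#' For every sample pair, compares the observed abundance-weighted betaMNTD
#' with a null distribution obtained by shuffling taxon identities (name and
#' abundance together) across the tips of the phylogeny, keeping topology
#' and branch lengths fixed. One shared permutation per null draw serves all
#' pairs.
#' `betaNTI = (observed - null mean) / null SD`; values below -2 indicate
#' communities phylogenetically closer than chance (homogeneous selection),
#' above +2 further than chance (variable selection).
#'
#' A pair whose null distribution has zero spread is flagged `degenerate`:
#' its betaNTI is 0 when the observed value equals the null constant and a
#' signed infinity otherwise, and it is excluded from process fractions
#' downstream.
#'
#' @param rel_table relative-abundance matrix (rows sum to 1).
#' @param tree rooted `phylo` covering the table's taxa.
#' @param n_null number of tip-shuffle permutations (convention: 999).
#' @param seed optional integer; fixes the whole permutation stream.
#' @return tibble with one row per unordered pair: `sample_a`, `sample_b`,
#'   `bmntd_obs`, `null_mean`, `null_sd`, `bnti`, `degenerate`.
#' @export
bnti <- function(rel_table, tree, n_null = 999, seed = NULL) {
  stopifnot(n_null >= 1)
  rel_table <- validate_count_table(rel_table, integer = FALSE)
  al <- align_table_and_tree(rel_table, tree)
  taxa <- colnames(al$table)
  D <- patristic_distances(al$tree)[taxa, taxa]
  n <- length(taxa)
  obs <- cpp_beta_mntd(D, al$table, seq_len(n))
  perms <- with_seed_(seed, {
    t(vapply(seq_len(n_null), function(i) sample.int(n), integer(n)))
  })
  nulls <- cpp_bnti_null(D, al$table, perms)
  pairs <- pair_index(nrow(al$table))
  ids <- rownames(al$table)
  sel <- cbind(pairs$i, pairs$j)
  null_mean <- nulls$mean[sel]
  null_sd <- nulls$sd[sel]
  bmntd_obs <- obs[sel]
  degenerate <- null_sd < 1e-12
  z <- ifelse(degenerate,
              ifelse(abs(bmntd_obs - null_mean) < 1e-12, 0,
                     sign(bmntd_obs - null_mean) * Inf),
              (bmntd_obs - null_mean) / null_sd)
  tibble(sample_a = ids[pairs$i], sample_b = ids[pairs$j],
         bmntd_obs = bmntd_obs, null_mean = null_mean, null_sd = null_sd,
         bnti = z, degenerate = degenerate)
}

#' Raup-Crick score on Bray-Curtis from a community null model
#'
#' For each sample pair, null communities are assembled preserving each
#' sample's observed richness and read total: taxa are drawn without
#' replacement with probability proportional to regional occupancy (the
#' fraction of samples each taxon occupies), each drawn taxon receives one
#' read, and the remaining reads are distributed multinomially with
#' probability proportional to regional relative abundance among the drawn
#' taxa. The observed Bray-Curtis is ranked within the null Bray-Curtis
#' distribution (exact ties half-weighted) and rescaled to `[-1, 1]`:
#' `RC = 2 * ((less + 0.5 * ties) / n_null - 0.5)`. Values beyond +0.95 /
#' -0.95 indicate dispersal limitation / homogenizing dispersal.
#'
#' The regional occupancy and abundance pools default to the full input
#' table; `pool` restricts (or widens) them to another table over the same
#' taxa. Pair-level reproducibility comes from a substream derived from
#' `(seed, pair ids)`, so subsets of pairs reproduce the full run.
#'
#' @param count_table integer count matrix (samples x taxa).
#' @param n_null number of null assemblies per pair (convention: 999).
#' @param seed optional integer.
#' @param pairs optional two-column matrix/data frame of sample ids (or a
#'   tibble with `sample_a`, `sample_b`) restricting computation to those
#'   pairs; default all unordered pairs.
#' @param pool optional count matrix defining the regional occupancy and
#'   abundance pools (same taxa as `count_table`).
#' @return tibble: `sample_a`, `sample_b`, `bc_obs`, `rc_bray`.
#' @export
rc_bray <- function(count_table, n_null = 999, seed = NULL, pairs = NULL,
                    pool = NULL) {
  stopifnot(n_null >= 1)
  count_table <- validate_count_table(count_table, integer = TRUE)
  totals <- rowSums(count_table)
  zero <- rownames(count_table)[totals == 0]
  if (length(zero)) stop("zero-total sample(s): ", paste(zero, collapse = ", "))
  ids <- rownames(count_table)
  if (is.null(pairs)) {
    pi_ <- pair_index(nrow(count_table))
    pairs <- cbind(ids[pi_$i], ids[pi_$j])
  } else {
    pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  }
  if (!all(pairs %in% ids)) stop("pair ids not in the table")

  pool <- pool %||% count_table
  if (!identical(colnames(pool), colnames(count_table)))
    stop("pool must cover the same taxa as count_table")
  occupancy <- colMeans(pool > 0)
  reg_abund <- colSums(pool) / sum(pool)
  rel <- sweep(count_table, 1L, totals, "/")
  richness <- rowSums(count_table > 0)
  if (any(richness > sum(occupancy > 0)))
    stop("sample richness exceeds the occupied regional pool")

  rc <- numeric(nrow(pairs))
  bc_obs <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1L]; b <- pairs[p, 2L]
    obs <- sum(abs(rel[a, ] - rel[b, ])) / 2
    bc_obs[p] <- obs
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0(a, "|", b))
    null_bc <- with_seed_(sub_seed, {
      vapply(seq_len(n_null), function(t) {
        xa <- rc_null_draw(occupancy, reg_abund, richness[a], totals[a])
        xb <- rc_null_draw(occupancy, reg_abund, richness[b], totals[b])
        sum(abs(xa / totals[a] - xb / totals[b])) / 2
      }, numeric(1))
    })
    rc[p] <- 2 * ((sum(null_bc < obs) + 0.5 * sum(null_bc == obs)) / n_null - 0.5)
  }
  tibble(sample_a = pairs[, 1L], sample_b = pairs[, 2L],
         bc_obs = bc_obs, rc_bray = rc)
}

# one null community: occupancy-weighted membership draw, one read per
# member, remaining reads by regional relative abundance among members
rc_null_draw <- function(occupancy, reg_abund, k_rich, k_total) {
  draw <- sample.int(length(occupancy), k_rich, prob = occupancy)
  x <- numeric(length(occupancy))
  x[draw] <- 1
  if (k_total > k_rich) {
    x[draw] <- x[draw] + as.vector(rmultinom(1L, k_total - k_rich,
                                             reg_abund[draw]))
  }
  x
}

#' Draw communities from the Raup-Crick null generator
#'
#' Exposes the null assembly process behind [rc_bray()] so its calibration
#' can be studied: communities generated this way should themselves yield
#' `|RC-Bray|` below 0.95 for the vast majority of pairs.
#'
#' @param pool_table count matrix defining the regional pools.
#' @param richness,totals per-community richness and read totals to
#'   preserve (recycled to the same length).
#' @param seed optional integer.
#' @return integer count matrix over the pool's taxa.
#' @export
rc_null_communities <- function(pool_table, richness, totals, seed = NULL) {
  pool_table <- validate_count_table(pool_table, integer = TRUE)
  k <- max(length(richness), length(totals))
  richness <- rep_len(richness, k)
  totals <- rep_len(totals, k)
  stopifnot(all(richness >= 1), all(totals >= richness))
  occupancy <- colMeans(pool_table > 0)
  if (any(richness > sum(occupancy > 0)))
    stop("richness exceeds the occupied regional pool")
  reg_abund <- colSums(pool_table) / sum(pool_table)
  out <- with_seed_(seed, {
    t(vapply(seq_len(k), function(i) {
      rc_null_draw(occupancy, reg_abund, richness[i], totals[i])
    }, numeric(ncol(pool_table))))
  })
  dimnames(out) <- list(paste0("null", seq_len(k)), colnames(pool_table))
  out
}

#' Classify pairwise assembly processes
#'
#' Applies the two-stage threshold rule: `betaNTI > 2` is variable
#' selection, `betaNTI < -2` homogeneous selection; otherwise
#' `RC-Bray > 0.95` is dispersal limitation, `RC-Bray < -0.95` homogenizing
#' dispersal, and the remainder is undominated (drift). All comparisons are
#' strict, so values exactly at a threshold fall through to the next rule.
#' Degenerate pairs (null SD of betaMNTD equal to 0) get an `NA` label and
#' are excluded from process fractions.
#'
#' @param pairwise tibble with columns `bnti`, `rc_bray` and optionally
#'   `degenerate` (as produced by [bnti()] joined with [rc_bray()]).
#' @return the input with a `process` factor column added.
#' @export
classify_assembly <- function(pairwise) {
  stopifnot(all(c("bnti", "rc_bray") %in% names(pairwise)))
  degenerate <- pairwise[["degenerate"]] %||% rep(FALSE, nrow(pairwise))
  stochastic <- abs(pairwise$bnti) <= 2 & !degenerate
  if (any(stochastic & is.na(pairwise$rc_bray)))
    stop("rc_bray required for pairs with |bnti| <= 2")
  lab <- dplyr::case_when(
    degenerate ~ NA_character_,
    pairwise$bnti > 2 ~ "variable_selection",
    pairwise$bnti < -2 ~ "homogeneous_selection",
    pairwise$rc_bray > 0.95 ~ "dispersal_limitation",
    pairwise$rc_bray < -0.95 ~ "homogenizing_dispersal",
    TRUE ~ "undominated"
  )
  pairwise$process <- factor(lab, levels = process_levels())
  pairwise
}

process_levels <- function() {
  c("variable_selection", "homogeneous_selection", "homogenizing_dispersal",
    "dispersal_limitation", "undominated")
}

#' Summarise assembly-process fractions by group
#'
#' @param classified tibble from [classify_assembly()].
#' @param grouping optional vector (length = rows of `classified`) mapping
#'   each pair to a group; `NULL` summarises all pairs together.
#' @return tibble: `group`, `process`, `n`, `fraction`; fractions sum to 1
#'   within each group over non-degenerate pairs. Empty groups are dropped
#'   with a warning.
#' @export
summarize_processes <- function(classified, grouping = NULL) {
  stopifnot("process" %in% names(classified))
  grouping <- grouping %||% rep("all", nrow(classified))
  df <- tibble(group = as.character(grouping), process = classified$process)
  empty <- setdiff(unique(df$group), unique(df$group[!is.na(df$process)]))
  if (length(empty))
    warning("group(s) with no classified pairs omitted: ",
            paste(empty, collapse = ", "))
  df <- df[!is.na(df$process), , drop = FALSE]
  out <- df |>
    dplyr::count(.data$group, .data$process, .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  out[out$group %in% df$group, , drop = FALSE]
}

#' Full pairwise assembly-process analysis
#'
#' Convenience orchestration: total-sum scaling, betaNTI against the
#' tip-shuffle null, RC-Bray for the pairs that need it (those with
#' `|betaNTI| <= 2`, unless `rc_pairs = "all"`), and classification.
#'
#' @param count_table integer count matrix.
#' @param tree rooted `phylo`.
#' @param n_null null replicates for both null models.
#' @param seed optional integer; betaNTI and RC-Bray use derived substreams.
#' @param rc_pairs `"stochastic"` (default) computes RC-Bray only where the
#'   classification needs it; `"all"` computes it for every pair; `"none"`
#'   skips it (the result then has no process labels).
#' @return classified pairwise tibble (see [classify_assembly()]).
#' @export
assembly_analysis <- function(count_table, tree, n_null = 999, seed = NULL,
                              rc_pairs = c("stochastic", "all", "none")) {
  rc_pairs <- match.arg(rc_pairs)
  count_table <- validate_count_table(count_table, integer = TRUE)
  rel <- to_relative_abundance(count_table)
  res <- bnti(rel, tree, n_null = n_null,
              seed = if (is.null(seed)) NULL else derive_seed(seed, "bnti"))
  res$bc_obs <- NA_real_
  res$rc_bray <- NA_real_
  need <- if (rc_pairs == "all") rep(TRUE, nrow(res))
          else if (rc_pairs == "none") rep(FALSE, nrow(res))
          else abs(res$bnti) <= 2 & !res$degenerate
  if (any(need)) {
    rc <- rc_bray(count_table, n_null = n_null,
                  seed = if (is.null(seed)) NULL else derive_seed(seed, "rc"),
                  pairs = res[need, c("sample_a", "sample_b")])
    res$bc_obs[need] <- rc$bc_obs
    res$rc_bray[need] <- rc$rc_bray
  }
  # observed Bray-Curtis is cheap; fill it in for all pairs
  bc <- as.matrix(bray_curtis(rel))
  res$bc_obs <- bc[cbind(res$sample_a, res$sample_b)]
  if (rc_pairs == "none") return(res)
  classify_assembly(res)
}
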