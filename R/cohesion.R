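#' Observed pairwise taxon correlations
#'
#' Pearson correlation of each taxon pair's relative abundances across
#' samples. Constant abundance vectors have no defined correlation; their
#' rows and columns are set to 0 with a warning.
#'
#' @param rel_table relative-abundance matrix (samples x taxa), at least 3
#'   samples, taxa already persistence-filtered.
#' @return taxon x taxon correlation matrix.
#' @export
observed_correlations <- function(rel_table) {
  rel_table <- validate_count_table(rel_table, integer = FALSE)
  if (nrow(rel_table) < 3) stop("need at least 3 samples for correlations")
  safe_cor(rel_table, warn = TRUE)
}

safe_cor <- function(m, warn = FALSE) {
  const <- apply(m, 2L, function(x) sd(x) == 0)
  r <- suppressWarnings(cor(m))
  if (any(const)) {
    if (warn) warning("constant taxon vector(s) set to correlation 0: ",
                      paste(colnames(m)[const], collapse = ", "))
    r[const, ] <- 0
    r[, const] <- 0
  }
  r
}

#' Null-expected taxon correlations from a taxa shuffle
#'
#' Each iteration independently permutes every taxon's abundance vector
#' across samples (destroying all between-taxon dependence while preserving
#' each taxon's marginal distribution), recomputes all pairwise Pearson
#' correlations, and the expected matrix is the mean over iterations.
#'
#' @inheritParams observed_correlations
#' @param iterations number of shuffles (convention: 200).
#' @param seed optional integer.
#' @return taxon x taxon expected-correlation matrix.
#' @export
null_expected_correlations <- function(rel_table, iterations = 200, seed = NULL) {
  stopifnot(iterations >= 1)
  rel_table <- validate_count_table(rel_table, integer = FALSE)
  if (nrow(rel_table) < 3) stop("need at least 3 samples for correlations")
  # shuffle in canonical (sorted taxon id) order so the expectation is
  # exactly invariant to the caller's column ordering
  ord <- order(colnames(rel_table))
  sorted <- rel_table[, ord, drop = FALSE]
  with_seed_(seed, {
    acc <- matrix(0, ncol(sorted), ncol(sorted))
    for (it in seq_len(iterations)) {
      shuf <- apply(sorted, 2L, sample)
      acc <- acc + safe_cor(shuf)
    }
    acc <- acc / iterations
    dimnames(acc) <- list(colnames(sorted), colnames(sorted))
    acc[colnames(rel_table), colnames(rel_table)]
  })
}

#' Per-taxon connectedness from null-corrected correlations
#'
#' Corrected correlation = observed - expected. For each taxon, positive
#' connectedness is the mean of its strictly positive corrected
#' correlations with other taxa (0 if there are none) and negative
#' connectedness the mean of the strictly negative ones. Self-correlations
#' are excluded.
#'
#' @param observed,expected conformable taxon x taxon matrices.
#' @return tibble: `taxon_id`, `pos_connectedness`, `neg_connectedness`.
#' @export
connectedness <- function(observed, expected) {
  stopifnot(identical(dim(observed), dim(expected)))
  corrected <- observed - expected
  diag(corrected) <- NA
  signed_mean <- function(x, positive) {
    v <- x[!is.na(x) & (if (positive) x > 0 else x < 0)]
    if (length(v)) mean(v) else 0
  }
  tibble(
    taxon_id = colnames(observed) %||% paste0("t", seq_len(ncol(observed))),
    pos_connectedness = unname(apply(corrected, 1L, signed_mean, positive = TRUE)),
    neg_connectedness = unname(apply(corrected, 1L, signed_mean, positive = FALSE))
  )
}

#' Per-sample cohesion
#'
#' Positive (negative) cohesion of a sample is the relative-abundance
#' weighted sum of the taxa's positive (negative) connectedness, ranging in
#' `[0, 1]` (`[-1, 0]`). The absolute value of negative cohesion is exposed
#' as well, so "more negative co-occurrence" reads as a larger number.
#'
#' @param rel_table relative-abundance matrix over the connectedness taxa.
#' @param conn tibble from [connectedness()] covering the table's taxa.
#' @return tibble: `sample_id`, `pos_cohesion`, `neg_cohesion`,
#'   `abs_neg_cohesion`.
#' @export
cohesion <- function(rel_table, conn) {
  rel_table <- validate_count_table(rel_table, integer = FALSE)
  if (length(setdiff(colnames(rel_table), conn$taxon_id)))
    stop("connectedness must cover every taxon of the table")
  pos <- setNames(conn$pos_connectedness, conn$taxon_id)[colnames(rel_table)]
  neg <- setNames(conn$neg_connectedness, conn$taxon_id)[colnames(rel_table)]
  tibble(
    sample_id = rownames(rel_table),
    pos_cohesion = as.numeric(rel_table %*% pos),
    neg_cohesion = as.numeric(rel_table %*% neg),
    abs_neg_cohesion = abs(as.numeric(rel_table %*% neg))
  )
}

#' Cohesion pipeline from a raw count table
#'
#' Runs the full null-corrected co-occurrence procedure: total-read
#' prefilter (drop taxa with fewer than `min_total_reads` reads overall),
#' persistence filter (keep taxa present in at least `persistence_cutoff`
#' of samples), total-sum scaling, observed and taxa-shuffle expected
#' correlations, connectedness, and abundance-weighted cohesion. Filter
#' settings and the seed are recorded in the `"provenance"` attribute; the
#' connectedness table rides along as the `"connectedness"` attribute.
#'
#' @param count_table integer count matrix.
#' @param min_total_reads read-count prefilter (default 150).
#' @param persistence_cutoff minimum occupied sample fraction (default 0.1;
#'   presence means count > 0).
#' @param iterations taxa-shuffle iterations (default 200).
#' @param seed optional integer.
#' @return cohesion tibble as from [cohesion()], with attributes.
#' @export
compute_cohesion <- function(count_table, min_total_reads = 150,
                             persistence_cutoff = 0.1, iterations = 200,
                             seed = NULL) {
  count_table <- validate_count_table(count_table, integer = FALSE)
  filtered <- filter_low_prevalence(count_table, min_total_reads)
  persistence <- colMeans(filtered > 0)
  keep <- persistence >= persistence_cutoff
  if (!any(keep)) stop("no taxa survive the persistence filter")
  filtered <- filtered[, keep, drop = FALSE]
  if (nrow(filtered) < 3) stop("need at least 3 samples after filtering")
  rel <- to_relative_abundance(filtered)
  obs <- observed_correlations(rel)
  expd <- null_expected_correlations(rel, iterations = iterations, seed = seed)
  conn <- connectedness(obs, expd)
  out <- cohesion(rel, conn)
  attr(out, "connectedness") <- conn
  attr(out, "provenance") <- list(
    min_total_reads = min_total_reads, persistence_cutoff = persistence_cutoff,
    iterations = iterations, seed = seed, n_taxa_used = ncol(filtered),
    correlation_input = "relative abundance"
  )
  out
}
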