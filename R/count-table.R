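#' Validate a community count table
#'
#' The package's universal input is a numeric matrix of taxon counts with
#' samples as rows and taxa as columns, both axes labelled. This checks the
#' container invariants: unique labels, non-negative (optionally integer)
#' values, at least one sample and one taxon.
#'
#' @param x matrix-like object, samples as rows, taxa as columns.
#' @param integer require whole-number counts (set `FALSE` for relative
#'   abundances).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_count_table <- function(x, integer = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("count table needs at least 1 sample and 1 taxon")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have sample (row) and taxon (column) names")
  dup_s <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_s)) stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  dup_t <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_t)) stop("duplicated taxon id(s): ", paste(unique(dup_t), collapse = ", "))
  if (!is.numeric(x)) stop("counts must be numeric")
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-finite count at sample '", rownames(x)[bad[1L, 1L]],
         "', taxon '", colnames(x)[bad[1L, 2L]], "'")
  }
  if (integer) {
    bad <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-integer count at sample '", rownames(x)[bad[1L, 1L]],
           "', taxon '", colnames(x)[bad[1L, 2L]], "'")
    }
  }
  invisible(x)
}

#' Remove taxa matching taxonomic exclusion patterns
#'
#' Drops taxa whose lineage matches any `(rank, value)` pair, the usual
#' cleanup of chloroplast, mitochondrial, archaeal and eukaryotic reads from
#' a 16S ASV table. Matching is case-insensitive on the whole rank string.
#'
#' @param table count matrix (samples x taxa).
#' @param taxonomy data frame with a `taxon_id` column plus one column per
#'   rank (e.g. `domain` ... `genus`).
#' @param exclude_patterns list of two-element character vectors
#'   `c(rank, value)`.
#' @param strict error when a table taxon is absent from `taxonomy`
#'   (default); `FALSE` keeps unknown taxa.
#' @return the filtered count matrix. Samples are retained even if emptied.
#' @export
filter_by_taxonomy <- function(table, taxonomy, exclude_patterns,
                               strict = TRUE) {
  table <- validate_count_table(table, integer = FALSE)
  taxonomy <- as.data.frame(taxonomy)
  if (!"taxon_id" %in% names(taxonomy)) stop("taxonomy needs a 'taxon_id' column")
  missing <- setdiff(colnames(table), taxonomy$taxon_id)
  if (length(missing) && strict)
    stop("taxa absent from taxonomy: ", paste(missing, collapse = ", "))
  if (!length(exclude_patterns)) return(table)
  drop <- character(0)
  for (pat in exclude_patterns) {
    rank <- pat[[1L]]; value <- pat[[2L]]
    if (!rank %in% names(taxonomy)) stop("unknown taxonomy rank: ", rank)
    hit <- taxonomy$taxon_id[!is.na(taxonomy[[rank]]) &
                               tolower(taxonomy[[rank]]) == tolower(value)]
    drop <- union(drop, hit)
  }
  keep <- setdiff(colnames(table), drop)
  if (!length(keep)) stop("taxonomy filter removed every taxon")
  table[, keep, drop = FALSE]
}

#' Remove low-prevalence taxa by total read count
#'
#' Drops taxa with strictly fewer than `min_total_reads` reads summed over
#' all samples; taxa at exactly the threshold are kept. A summary of the
#' removed-taxon and removed-read fractions is attached as the
#' `"prevalence_report"` attribute (see [prevalence_report()]).
#'
#' @param table count matrix (samples x taxa).
#' @param min_total_reads threshold; the conventional ASV prefilter is 150.
#' @return filtered count matrix with a `prevalence_report` attribute.
#' @export
filter_low_prevalence <- function(table, min_total_reads = 150) {
  table <- validate_count_table(table, integer = FALSE)
  stopifnot(min_total_reads >= 0)
  totals <- colSums(table)
  keep <- totals >= min_total_reads
  if (!any(keep)) stop("prevalence filter removed every taxon")
  out <- table[, keep, drop = FALSE]
  attr(out, "prevalence_report") <- tibble(
    min_total_reads = min_total_reads,
    n_taxa_in = ncol(table),
    n_taxa_removed = sum(!keep),
    removed_taxon_fraction = sum(!keep) / ncol(table),
    removed_read_fraction = 1 - sum(totals[keep]) / sum(totals)
  )
  out
}

#' @rdname filter_low_prevalence
#' @param x a table returned by [filter_low_prevalence()].
#' @export
prevalence_report <- function(x) attr(x, "prevalence_report")

#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's reads to exactly `depth` without replacement
#' (multivariate hypergeometric). Samples with fewer than `depth` reads are
#' dropped with a warning naming them; the dropped ids are attached as the
#' `"dropped_samples"` attribute.
#'
#' @param table integer count matrix (samples x taxa).
#' @param depth reads retained per sample.
#' @param seed optional integer; a fixed seed makes the draw reproducible
#'   without touching the caller's RNG.
#' @return rarefied count matrix (all row sums equal `depth`).
#' @export
rarefy <- function(table, depth, seed = NULL) {
  table <- validate_count_table(table, integer = TRUE)
  stopifnot(depth >= 1)
  totals <- rowSums(table)
  if (all(totals < depth)) stop("rarefaction depth ", depth, " exceeds every sample total")
  dropped <- rownames(table)[totals < depth]
  if (length(dropped)) {
    warning("rarefaction dropped ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  }
  keep <- table[totals >= depth, , drop = FALSE]
  out <- with_seed_(seed, {
    t(apply(keep, 1L, function(x) {
      # draw `depth` read indices without replacement from the pooled reads
      reads <- sample.int(sum(x), depth)
      breaks <- cumsum(x)
      tabulate(findInterval(reads - 1L, c(0, breaks), rightmost.closed = FALSE),
               nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(keep)
  attr(out, "dropped_samples") <- dropped
  out
}

#' Total sum scaling to relative abundances
#'
#' @param table count matrix with strictly positive row totals.
#' @return matrix of per-sample proportions; every row sums to 1.
#' @export
to_relative_abundance <- function(table) {
  table <- validate_count_table(table, integer = FALSE)
  totals <- rowSums(table)
  zero <- rownames(table)[totals == 0]
  if (length(zero)) stop("zero-total sample(s): ", paste(zero, collapse = ", "))
  sweep(table, 1L, totals, "/")
}

#' Align a count table with a phylogeny
#'
#' Prunes the tree to the table's taxa. Every table taxon must be a tip.
#'
#' @param table count matrix (samples x taxa).
#' @param tree rooted `phylo` with the table's taxa among its tips.
#' @return list with elements `table` and `tree`.
#' @export
align_table_and_tree <- function(table, tree) {
  table <- validate_count_table(table, integer = FALSE)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  if (length(setdiff(tree$tip.label, colnames(table))))
    tree <- ape::keep.tip(tree, colnames(table))
  list(table = table, tree = tree)
}
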