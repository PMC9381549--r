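#' Read a count table from a tab-separated file
#'
#' Reads a TSV whose first column holds row ids and whose header names the
#' other axis. On-disk orientation is declared by the caller; in memory the
#' canonical orientation is always samples-as-rows.
#'
#' @param path TSV file, header row present, first column = row ids.
#' @param orientation `"taxa_as_rows"` (the usual ASV-table layout) or
#'   `"samples_as_rows"`.
#' @return validated integer count matrix, samples as rows.
#' @export
read_count_table <- function(path, orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated row id(s) in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  storage.mode(m) <- "double"
  validate_count_table(m, integer = TRUE)
  m
}

#' Write a count table as TSV
#'
#' @param table count matrix, samples as rows.
#' @param path output file.
#' @param orientation on-disk layout, as in [read_count_table()].
#' @param id_column header label of the id column.
#' @export
write_count_table <- function(table, path,
                              orientation = c("taxa_as_rows", "samples_as_rows"),
                              id_column = NULL) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "taxa_as_rows") t(table) else table
  id_column <- id_column %||%
    if (orientation == "taxa_as_rows") "taxon_id" else "sample_id"
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation every phylogenetic metric
#' here relies on: unique tips, branch lengths present and non-negative. A
#' missing root edge length is treated as 0.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick in ", path)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree a `phylo` object to validate in place.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicated tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (!is.null(tree$root.edge) && is.na(tree$root.edge)) tree$root.edge <- 0
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Read sample metadata or a taxonomy table from TSV
#'
#' `read_sample_metadata()` expects a `sample_id` column and, when present,
#' validates the size fraction against `FL`/`PA`. `read_taxonomy()` expects
#' a `taxon_id` column followed by ranked lineage columns.
#'
#' @param path TSV file with a header row.
#' @return a tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(df)) stop("metadata needs a 'sample_id' column")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicated sample id(s) in metadata: ", paste(dup, collapse = ", "))
  if ("fraction" %in% names(df) && !all(df$fraction %in% c("FL", "PA")))
    stop("fraction must be 'FL' or 'PA'")
  df
}

#' @rdname read_sample_metadata
#' @export
read_taxonomy <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE))
  if (!"taxon_id" %in% names(df)) stop("taxonomy needs a 'taxon_id' column")
  df
}

#' Read or write a square distance matrix as TSV
#'
#' Square layout with the sample ids as both header row and first column,
#' interchangeable with common ecology tooling.
#'
#' @param path TSV file.
#' @return `read_distance_matrix()` returns a `dist`.
#' @export
read_distance_matrix <- function(path) {
  raw <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- as.character(raw[[1L]])
  m <- as_dist_matrix(m, arg = path)
  stats::as.dist(m)
}

#' @rdname read_distance_matrix
#' @param d `dist` or symmetric matrix.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as_dist_matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
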