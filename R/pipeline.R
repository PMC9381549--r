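#' Analysis configuration
#'
#' Bundles every knob of the end-to-end pipeline with the field's
#' conventional defaults: 999 null replicates for both assembly null
#' models, 200 taxa-shuffle iterations for cohesion, 999/1000 permutations
#' for PERMANOVA / constrained ordination, a 150-read prevalence prefilter,
#' a 0.1 persistence cutoff, VIF ceiling 10 and the +-2 / +-0.95 assembly
#' thresholds. A seed is mandatory: no silent nondeterminism.
#'
#' @param simulate a [scenario_config()] to generate inputs, or `NULL` to
#'   read them from files.
#' @param table,tree,metadata,taxonomy input paths (used when
#'   `simulate = NULL`).
#' @param orientation on-disk count-table layout (see [read_count_table()]).
#' @param rarefaction_depth reads per sample for rarefaction, or `NULL` to
#'   analyse unrarefied counts (the choice is recorded in the manifest).
#' @param n_null null replicates for betaNTI and RC-Bray.
#' @param cohesion_iterations taxa-shuffle iterations.
#' @param n_perm_permanova,n_perm_rda permutation counts.
#' @param prevalence_min_reads,persistence_cutoff cohesion prefilters.
#' @param vif_threshold collinearity ceiling for predictor pruning.
#' @param exclude_patterns taxonomy exclusion list (rank, value pairs).
#' @param seed integer master seed; each stage derives its own substream.
#' @export
analysis_config <- function(simulate = scenario_config(),
                            table = NULL, tree = NULL, metadata = NULL,
                            taxonomy = NULL,
                            orientation = "taxa_as_rows",
                            rarefaction_depth = NULL,
                            n_null = 999,
                            cohesion_iterations = 200,
                            n_perm_permanova = 999,
                            n_perm_rda = 1000,
                            prevalence_min_reads = 150,
                            persistence_cutoff = 0.1,
                            vif_threshold = 10,
                            exclude_patterns = list(
                              c("domain", "Archaea"), c("domain", "Eukaryota"),
                              c("order", "Chloroplast"), c("family", "Mitochondria")
                            ),
                            seed = 1) {
  if (is.null(seed)) stop("a seed is required")
  stopifnot(n_null >= 1, cohesion_iterations >= 1, n_perm_permanova >= 1,
            n_perm_rda >= 1, prevalence_min_reads >= 0,
            persistence_cutoff >= 0, vif_threshold > 0)
  if (is.null(simulate) && (is.null(table) || is.null(tree) ||
                            is.null(metadata) || is.null(taxonomy)))
    stop("either a simulate block or all four input paths are required")
  structure(as.list(environment()), class = "analysis_config")
}

stage_run <- function(name, expr, env) {
  warns <- character(0)
  res <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) {
      warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  env$warnings <- c(env$warnings, warns)
  env$stages <- c(env$stages, name)
  res
}

#' Run the full assembly-inference pipeline
#'
#' Executes, in order: load or simulate inputs, taxonomy filter, optional
#' rarefaction, alpha diversity, total-sum scaling, beta diversity
#' (Bray-Curtis and betaMNTD), PCoA / PERMANOVA / dispersion tests,
#' pairwise assembly processes (betaNTI, RC-Bray, classification and
#' group summaries within each fraction-date group), cohesion per
#' fraction, dbRDA with VIF pruning and variance partitioning per
#' fraction, the paired FL-PA dissimilarity table, and the RDA of that
#' table on environmental and cohesion predictors. Any stage error aborts
#' with the stage name prefixed.
#'
#' @param config an [analysis_config()].
#' @param output_dir optional directory; when given, every stage output is
#'   written (TSV/JSON) together with `manifest.json` carrying the config
#'   echo, package version, completed stages, collected warnings and md5
#'   hashes of all written files.
#' @return a list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed
  state <- new.env()
  state$warnings <- character(0)
  state$stages <- character(0)

  inputs <- stage_run("load", {
    if (!is.null(config$simulate)) {
      simulate_estuary_dataset(config$simulate, seed = derive_seed(seed, "simulate"))
    } else {
      list(counts = read_count_table(config$table, config$orientation),
           tree = read_tree(config$tree),
           metadata = read_sample_metadata(config$metadata),
           taxonomy = read_taxonomy(config$taxonomy))
    }
  }, state)

  counts <- stage_run("taxonomy_filter", {
    filter_by_taxonomy(inputs$counts, inputs$taxonomy,
                       config$exclude_patterns, strict = FALSE)
  }, state)

  if (!is.null(config$rarefaction_depth)) {
    counts <- stage_run("rarefy", {
      rarefy(counts, config$rarefaction_depth, seed = derive_seed(seed, "rarefy"))
    }, state)
  }
  metadata <- inputs$metadata[inputs$metadata$sample_id %in% rownames(counts), ]
  tree <- stage_run("align", align_table_and_tree(counts, inputs$tree)$tree, state)

  alpha <- stage_run("alpha", alpha_diversity(counts, tree), state)
  rel <- stage_run("relative_abundance", to_relative_abundance(counts), state)
  bc <- stage_run("beta_bray_curtis", bray_curtis(rel), state)
  bmntd <- stage_run("beta_mntd", beta_mntd(rel, tree), state)

  ordinations <- stage_run("ordination", {
    terms <- intersect(c("station", "date", "fraction"), names(metadata))
    disp <- lapply(setNames(terms, terms), function(tm) {
      g <- metadata[[tm]][match(rownames(as_dist_matrix(bc)), metadata$sample_id)]
      dispersion_test(bc, g, n_perm = config$n_perm_permanova,
                      seed = derive_seed(seed, paste0("disp_", tm)))
    })
    list(
      pcoa_bc = pcoa_ord(bc), pcoa_bmntd = pcoa_ord(bmntd),
      permanova_bc = permanova(bc, metadata, terms,
                               n_perm = config$n_perm_permanova,
                               seed = derive_seed(seed, "permanova_bc")),
      permanova_bmntd = permanova(bmntd, metadata, terms,
                                  n_perm = config$n_perm_permanova,
                                  seed = derive_seed(seed, "permanova_bmntd")),
      dispersion = disp
    )
  }, state)

  assembly <- stage_run("assembly", {
    grp_cols <- intersect(c("fraction", "date"), names(metadata))
    key <- do.call(paste, c(metadata[grp_cols], sep = "|"))
    groups <- split(metadata$sample_id, key)
    groups <- groups[lengths(groups) >= 2]
    res <- purrr::imap(groups, function(ids, g) {
      out <- assembly_analysis(counts[ids, , drop = FALSE], tree,
                               n_null = config$n_null,
                               seed = derive_seed(seed, paste0("assembly_", g)))
      out$group <- g
      out
    })
    pairs <- dplyr::bind_rows(res)
    list(pairs = pairs,
         summary = summarize_processes(pairs, pairs$group))
  }, state)

  coh <- stage_run("cohesion", {
    split_ids <- if ("fraction" %in% names(metadata)) {
      split(metadata$sample_id, metadata$fraction)
    } else list(all = metadata$sample_id)
    purrr::imap(split_ids, function(ids, f) {
      compute_cohesion(counts[ids, , drop = FALSE],
                       min_total_reads = config$prevalence_min_reads,
                       persistence_cutoff = config$persistence_cutoff,
                       iterations = config$cohesion_iterations,
                       seed = derive_seed(seed, paste0("cohesion_", f)))
    })
  }, state)

  env_vars <- intersect(c("salinity", "temperature", "DIN", "silicate",
                          "phosphate", "DOP", "SPM", "POM_pct", "POP_pct",
                          "Chla", "Chla_pct", "pheopigments"),
                        names(metadata))
  constrained <- stage_run("dbrda", {
    fractions <- names(coh)
    purrr::map(setNames(fractions, fractions), function(f) {
      ids <- coh[[f]]$sample_id
      md <- metadata[match(ids, metadata$sample_id), ]
      pred <- as.data.frame(md[, env_vars])
      pred$pos_cohesion <- coh[[f]]$pos_cohesion
      pred$abs_neg_cohesion <- coh[[f]]$abs_neg_cohesion
      rownames(pred) <- ids
      pruned <- vif_prune(pred, threshold = config$vif_threshold)
      dsub <- as_dist_matrix(bc)[ids, ids]
      fit <- db_rda(dsub, pred[, pruned$retained, drop = FALSE],
                    n_perm = config$n_perm_rda,
                    seed = derive_seed(seed, paste0("dbrda_", f)))
      groups <- list(
        salinity = intersect("salinity", pruned$retained),
        temperature = intersect("temperature", pruned$retained),
        om_nutrients = intersect(c("SPM", "POM_pct", "Chla", "DOP", "phosphate"),
                                 pruned$retained),
        cohesion = intersect(c("pos_cohesion", "abs_neg_cohesion"),
                             pruned$retained)
      )
      groups <- groups[lengths(groups) > 0]
      vp <- if (length(groups) >= 2) {
        variance_partition(dsub, pred[, pruned$retained, drop = FALSE], groups)
      } else NULL
      list(vif = pruned, fit = fit, varpart = vp)
    })
  }, state)

  flpa <- NULL
  flpa_rda <- NULL
  if ("fraction" %in% names(metadata) && all(c("FL", "PA") %in% metadata$fraction)) {
    flpa <- stage_run("flpa_dissimilarity",
                      flpa_pairwise_dissimilarity(bc, bmntd, metadata), state)
    flpa_rda <- stage_run("flpa_rda", {
      md <- metadata[metadata$fraction == "FL", ]
      key <- paste(md$station, md$date)
      idx <- match(paste(flpa$station, flpa$date), key)
      pred <- as.data.frame(md[idx, env_vars])
      add_coh <- function(tbl, prefix) {
        ids <- md$sample_id[idx]
        j <- match(sub("^FL", prefix, ids), tbl$sample_id)
        tbl[j, c("pos_cohesion", "abs_neg_cohesion")]
      }
      if (all(c("FL", "PA") %in% names(coh))) {
        fl_c <- add_coh(coh$FL, "FL")
        pa_c <- add_coh(coh$PA, "PA")
        pred$FL_pos_cohesion <- fl_c$pos_cohesion
        pred$FL_abs_neg_cohesion <- fl_c$abs_neg_cohesion
        pred$PA_pos_cohesion <- pa_c$pos_cohesion
        pred$PA_abs_neg_cohesion <- pa_c$abs_neg_cohesion
      }
      keep <- stats::complete.cases(pred)
      pruned <- vif_prune(pred[keep, ], threshold = config$vif_threshold)
      rda_fit(flpa[keep, c("bray_curtis", "bmntd")],
              pred[keep, pruned$retained, drop = FALSE],
              n_perm = config$n_perm_rda,
              seed = derive_seed(seed, "flpa_rda"))
    }, state)
  }

  results <- list(
    inputs = inputs, counts = counts, metadata = metadata, tree = tree,
    alpha = alpha, bray_curtis = bc, beta_mntd = bmntd,
    ordination = ordinations, assembly = assembly, cohesion = coh,
    constrained = constrained, flpa = flpa, flpa_rda = flpa_rda
  )
  manifest <- list(
    package_version = as.character(packageVersion("ecoassembly")),
    config = config_echo(config),
    stages = state$stages,
    warnings = state$warnings
  )
  if (!is.null(output_dir)) {
    manifest$hashes <- write_pipeline_outputs(results, manifest, output_dir)
  }
  results$manifest <- manifest
  results
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out$exclude_patterns <- lapply(out$exclude_patterns, paste, collapse = "=")
  out
}

write_pipeline_outputs <- function(results, manifest, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  write_count_table(results$counts, p("counts.tsv"))
  write.table(results$metadata, p("metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(results$tree, p("tree.nwk"))
  write.table(results$alpha, p("alpha_diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_distance_matrix(results$bray_curtis, p("bray_curtis.tsv"))
  write_distance_matrix(results$beta_mntd, p("beta_mntd.tsv"))
  write.table(results$assembly$pairs[, setdiff(names(results$assembly$pairs),
                                               character(0))],
              p("assembly_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(results$assembly$summary, p("assembly_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (f in names(results$cohesion)) {
    write.table(results$cohesion[[f]], p(paste0("cohesion_", f, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(results$flpa)) {
    write.table(results$flpa, p("flpa_dissimilarity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest[c("package_version", "config", "stages",
                                  "warnings")],
                       p("manifest.json"), auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  files <- list.files(output_dir, full.names = TRUE)
  hashes <- tibble(file = basename(files),
                   md5 = as.character(tools::md5sum(files)))
  write.table(hashes, p("hashes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hashes
}

#' Paired free-living versus particle-attached dissimilarity
#'
#' Joins each free-living sample with its particle-attached counterpart by
#' (station, date) and reports their Bray-Curtis and betaMNTD
#' dissimilarities. Unpaired station-dates are skipped with a warning;
#' duplicate pairing keys are an error.
#'
#' @param bc,bmntd `dist` objects over the same samples.
#' @param metadata data frame with `sample_id`, `station`, `date`,
#'   `fraction` (`FL`/`PA`).
#' @return tibble: `station`, `date`, `bray_curtis`, `bmntd`.
#' @export
flpa_pairwise_dissimilarity <- function(bc, bmntd, metadata) {
  mb <- as_dist_matrix(bc)
  mm <- as_dist_matrix(bmntd)
  metadata <- as.data.frame(metadata)
  stopifnot(all(c("sample_id", "station", "date", "fraction") %in% names(metadata)))
  md <- metadata[metadata$sample_id %in% rownames(mb), ]
  key <- paste(md$station, md$date, md$fraction, sep = "|")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) stop("duplicate pairing key(s): ", paste(dup, collapse = ", "))
  wide <- tidyr::pivot_wider(
    tibble(station = md$station, date = md$date, fraction = md$fraction,
           sample_id = md$sample_id),
    names_from = "fraction", values_from = "sample_id"
  )
  if (!all(c("FL", "PA") %in% names(wide)))
    stop("need both FL and PA samples")
  unpaired <- is.na(wide$FL) | is.na(wide$PA)
  if (any(unpaired)) {
    warning("unpaired station-date(s) skipped: ",
            paste(paste(wide$station[unpaired], wide$date[unpaired]),
                  collapse = ", "))
    wide <- wide[!unpaired, ]
  }
  tibble(
    station = wide$station, date = wide$date,
    bray_curtis = mb[cbind(wide$FL, wide$PA)],
    bmntd = mm[cbind(wide$FL, wide$PA)]
  )
}
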