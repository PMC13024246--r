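#' Pipeline configuration
#'
#' Validated parameter bundle for [run_pipeline()]. A single root seed derives
#' per-stage seeds by fixed offsets so one number reproduces the whole run.
#'
#' @param abundance,metadata Paths to the input CSVs (as written by
#'   [write_cohort()]); leave `NULL` when passing a `lipid_cohort` directly to
#'   [run_pipeline()].
#' @param out_dir Output directory.
#' @param alpha Adjusted-p cutoff in (0, 1).
#' @param fc_threshold Fold-change magnitude threshold (>= 1).
#' @param levels Stratification levels for the differential-abundance stage.
#' @param r1,r2,subsample_fraction,max_iter,p_threshold Stability-protocol
#'   parameters (see [stability_protocol()]).
#' @param auc_min,sens_min,spec_min ROC screening gates.
#' @param seed Root seed.
#' @param gene_table Path to a gene-lipid association TSV (`NULL` = packaged).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance = NULL, metadata = NULL,
                            out_dir = tempfile("lipidshift_run_"),
                            alpha = 0.05, fc_threshold = 1,
                            levels = c("species", "class", "total_fa"),
                            r1 = 100, r2 = 100, subsample_fraction = 0.70,
                            max_iter = 100, p_threshold = 0.01,
                            auc_min = 0.80, sens_min = 0.70, spec_min = 0.80,
                            seed = 1L, gene_table = NULL) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1", call. = FALSE)
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  stopifnot(r1 >= 1, r2 >= 1, max_iter >= 0,
            p_threshold > 0, p_threshold < 1,
            auc_min >= 0, auc_min <= 1, sens_min >= 0, sens_min <= 1,
            spec_min >= 0, spec_min <= 1)
  for (f in c(abundance, metadata, gene_table))
    if (!is.null(f) && !file.exists(f))
      stop("file not found: ", f, call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate an abundance/metadata CSV pair
#'
#' Checks sample-id uniqueness, metadata coverage, binary group labels,
#' non-negative values, and that every lipid column name parses (all
#' unparseable names are reported at once, not just the first). Dialect names
#' (Unicode minus, `";2.0"` oxygen suffix) are accepted with a warning and the
#' columns renamed to canonical form.
#'
#' @param abundance_path CSV with first column `sample_id`, one column per
#'   lipid species.
#' @param metadata_path CSV with columns `sample_id` and `group`
#'   (case/control).
#' @return A validated `lipid_cohort`.
#' @export
validate_cohort <- function(abundance_path, metadata_path) {
  ab <- utils::read.csv(abundance_path, check.names = FALSE)
  md <- utils::read.csv(metadata_path, check.names = FALSE)
  if (names(ab)[1] != "sample_id")
    stop("abundance file must have 'sample_id' as its first column", call. = FALSE)
  if (!all(c("sample_id", "group") %in% names(md)))
    stop("metadata file must have columns sample_id and group", call. = FALSE)
  dup <- ab$sample_id[duplicated(ab$sample_id)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  missing_md <- setdiff(ab$sample_id, md$sample_id)
  if (length(missing_md))
    stop("metadata missing sample(s): ", paste(missing_md, collapse = ", "),
         call. = FALSE)
  grp <- md$group[match(ab$sample_id, md$sample_id)]
  if (!all(grp %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'; found: ",
         paste(setdiff(unique(grp), c("case", "control")), collapse = ", "),
         call. = FALSE)

  species <- names(ab)[-1]
  parsed <- lapply(species, function(nm) tryCatch(parse_lipid_name(nm),
                                                  error = function(e) e))
  bad <- vapply(parsed, inherits, logical(1), "error")
  if (any(bad))
    stop("unparseable lipid column name(s): ",
         paste(species[bad], collapse = "; "), call. = FALSE)
  canon <- vapply(parsed, `[[`, character(1), "name")
  normalized <- species[canon != species]
  if (length(normalized))
    warning("normalized dialect lipid name(s): ",
            paste(sprintf("'%s' -> '%s'", normalized,
                          canon[canon != species]), collapse = ", "),
            call. = FALSE)

  m <- as.matrix(ab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric or missing abundance values", call. = FALSE)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', species '%s'",
                 ab$sample_id[idx[1]], canon[idx[2]]), call. = FALSE)
  }
  colnames(m) <- canon
  rownames(m) <- ab$sample_id
  if (anyDuplicated(canon))
    stop("duplicated species after normalization: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "), call. = FALSE)
  structure(list(abundance = m, sample_id = ab$sample_id,
                 group = factor(grp, levels = c("case", "control"))),
            class = "lipid_cohort")
}

.write_tsv <- function(df, path, stage, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# lipidshift %s | stage: %s%s",
                 as.character(utils::packageVersion("lipidshift")), stage,
                 if (length(params))
                   paste0(" | ", paste(names(params), unlist(params),
                                       sep = "=", collapse = " ")) else "")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes annotate -> preprocess -> differential abundance (all configured
#' levels) -> PCA / hierarchical clustering -> stability selection -> ROC on
#' the stable features -> gene-lipid network on the significant species,
#' writing one TSV per stage plus a JSON run manifest (input hashes, seeds,
#' parameters, stage outputs, package version) into `config$out_dir`. Stage
#' seeds are derived from the root seed by fixed offsets. If a stage fails,
#' its partial output is kept with a `.partial` suffix and the error names the
#' stage.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally a `lipid_cohort` already in memory; otherwise the
#'   configured CSV paths are read and validated.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$abundance) || is.null(config$metadata))
      stop("either a cohort or abundance/metadata paths are required", call. = FALSE)
    cohort <- validate_cohort(config$abundance, config$metadata)
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "lipidshift",
                   version = as.character(utils::packageVersion("lipidshift")),
                   seed = seed,
                   stage_seeds = list(stability = seed + 1000L,
                                      layout = seed + 2000L),
                   parameters = config[c("alpha", "fc_threshold", "levels",
                                         "r1", "r2", "subsample_fraction",
                                         "max_iter", "p_threshold", "auc_min",
                                         "sens_min", "spec_min")],
                   inputs = list(),
                   stages = list())
  if (!is.null(config$abundance))
    manifest$inputs <- as.list(tools::md5sum(c(config$abundance, config$metadata)))

  run_stage <- function(name, outfile, fun) {
    path <- file.path(out, outfile)
    res <- tryCatch(fun(path), error = function(e) {
      if (file.exists(path)) file.rename(path, paste0(path, ".partial"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- outfile
    res
  }

  annot <- run_stage("annotate", "annotation.tsv", function(path) {
    a <- annotate_lipids(colnames(cohort$abundance))
    .write_tsv(a, path, "annotate")
    a
  })
  prep <- run_stage("preprocess", "log2_abundance.tsv", function(path) {
    p <- preprocess_abundance(cohort$abundance)
    .write_tsv(data.frame(sample_id = rownames(p$log2), p$log2,
                          check.names = FALSE), path, "preprocess")
    p
  })
  de_list <- run_stage("de", "de_species.tsv", function(path) {
    res <- lapply(config$levels, function(lv)
      de_by_level(cohort, annot, lv, alpha = config$alpha,
                  fc_threshold = config$fc_threshold))
    names(res) <- config$levels
    for (lv in config$levels)
      .write_tsv(res[[lv]], file.path(out, sprintf("de_%s.tsv", lv)), "de",
                 list(level = lv, alpha = config$alpha))
    res
  })
  run_stage("pca", "pca_scores.tsv", function(path) {
    pc <- pca_lipids(prep$log2)
    .write_tsv(data.frame(sample_id = rownames(pc$scores),
                          group = as.character(cohort$group),
                          pc$scores[, 1:min(5, ncol(pc$scores))],
                          check.names = FALSE),
               path, "pca",
               list(pc1 = round(pc$explained_fraction[1], 4),
                    pc2 = round(pc$explained_fraction[2], 4)))
    hc <- hier_cluster(prep$log2)
    .write_tsv(data.frame(sample_order = seq_along(hc$sample_order),
                          sample_id = hc$sample_order),
               file.path(out, "cluster_samples.tsv"), "cluster")
    pc
  })
  stab <- run_stage("stability", "stability.tsv", function(path) {
    st <- stability_protocol(prep$log2, cohort$group, R1 = config$r1,
                             R2 = config$r2,
                             subsample_fraction = config$subsample_fraction,
                             base_seed = seed + 1000L,
                             max_iter = config$max_iter,
                             p_threshold = config$p_threshold)
    .write_tsv(st$table, path, "stability",
               list(r1 = config$r1, r2 = config$r2))
    st
  })
  roc <- run_stage("roc", "roc_report.tsv", function(path) {
    stable <- stab$table$feature[stab$table$stable]
    if (length(stable) == 0L) stable <- colnames(cohort$abundance)
    rep <- roc_report(cohort, stable)
    rep$passes_gates <- rep$feature_id %in%
      screen_biomarkers(rep, config$auc_min, config$sens_min,
                        config$spec_min)$feature_id
    .write_tsv(rep, path, "roc")
    rep
  })
  run_stage("network", "network_edges.tsv", function(path) {
    sig <- de_list[["species"]]
    sig <- sig$feature_id[sig$significant]
    tab <- gene_lipid_table(config$gene_table)
    edges <- filter_generic_nodes(map_lipids_to_genes(sig, tab))
    g <- build_gene_lipid_graph(edges)
    .write_tsv(edges, path, "network")
    .write_tsv(layout_coordinates(g, seed = seed + 2000L),
               file.path(out, "network_nodes.tsv"), "network")
    g
  })

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
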