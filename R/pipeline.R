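# File-based orchestration: configuration with validated defaults, the
# five-stage pipeline (network -> assemble -> score -> associate), and the
# run manifest.

#' Pipeline configuration with validated defaults
#'
#' Collects the file paths and tuning constants of a full run. Every
#' threshold defaults to the pipeline's standard value and is validated up
#' front; a bad configuration is rejected before any stage executes.
#'
#' @param expression Named list (one entry per region) of lists with
#'   `expr` and `meta` TSV paths (see [write_expression()]).
#' @param eqtl Named list (per region) of eQTL catalog TSV paths.
#' @param genotypes Genotype path: PLINK prefix or VCF file.
#' @param genotype_format `"plink-bed"` or `"vcf"`.
#' @param annotation Gene annotation TSV path.
#' @param phenotypes Phenotype/covariate TSV path (`individual_id`,
#'   outcome and covariate columns).
#' @param anchor Named character vector or single id: anchor gene per
#'   region.
#' @param outcomes Character vector of outcome column names.
#' @param sex_col Sex covariate column name (`NULL` to omit).
#' @param pc_cols Principal-component column names (default `PC1..PC3`).
#' @param min_abs_r,min_fold,r2_max,window_kb,prs_p_threshold,top_k
#'   Pipeline thresholds.
#' @param bonferroni_m Bonferroni family size (`NULL`: number of outcomes).
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest.
#' @return A validated list of class `"coex_config"`.
#' @export
pipeline_config <- function(expression, eqtl, genotypes,
                            genotype_format = c("plink-bed", "vcf"),
                            annotation, phenotypes, anchor,
                            outcomes, sex_col = "sex",
                            pc_cols = paste0("PC", 1:3),
                            min_abs_r = 0.5, min_fold = 1.5,
                            r2_max = 0.2, window_kb = 250,
                            prs_p_threshold = 4.912e-5, top_k = 4515,
                            bonferroni_m = NULL, out_dir = tempdir(),
                            seed = 1L) {
  genotype_format <- match.arg(genotype_format)
  .assert_scalar_number(min_abs_r, "min_abs_r", 0, 1)
  .assert_scalar_number(min_fold, "min_fold", 0)
  .assert_scalar_number(r2_max, "r2_max", 0, 1)
  .assert_scalar_number(window_kb, "window_kb", 0)
  .assert_scalar_number(prs_p_threshold, "prs_p_threshold", 0, 1)
  if (!is.null(bonferroni_m)) .assert_scalar_number(bonferroni_m, "bonferroni_m", 1)
  stopifnot(is.list(expression), !is.null(names(expression)),
            is.list(eqtl), setequal(names(expression), names(eqtl)),
            is.character(outcomes), length(outcomes) >= 1)
  regions <- names(expression)
  if (length(anchor) == 1 && is.null(names(anchor))) {
    anchor <- setNames(rep(anchor, length(regions)), regions)
  }
  stopifnot(setequal(names(anchor), regions))
  structure(list(expression = expression, eqtl = eqtl,
                 genotypes = genotypes, genotype_format = genotype_format,
                 annotation = annotation, phenotypes = phenotypes,
                 anchor = anchor, regions = regions, outcomes = outcomes,
                 sex_col = sex_col, pc_cols = pc_cols,
                 min_abs_r = min_abs_r, min_fold = min_fold,
                 r2_max = r2_max, window_kb = window_kb,
                 prs_p_threshold = prs_p_threshold, top_k = top_k,
                 bonferroni_m = bonferroni_m, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "coex_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A validated `"coex_config"`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$anchor <- unlist(raw$anchor)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline from files
#'
#' Executes network construction, variant assembly (per region), scoring,
#' and association in sequence, writing every stage output and a run
#' manifest to the configured output directory. All referenced input files
#' must exist; missing files fail before execution.
#'
#' @param config A [pipeline_config()].
#' @return A list with `manifest`, `networks`, `score_table`,
#'   `association` (data frame: outcome, beta, se, p, p_adj, n), and
#'   `split` (the median-split group table).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "coex_config"))
  paths <- c(unlist(config$expression), unlist(config$eqtl),
             config$annotation, config$phenotypes)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genotypes <- read_genotypes(config$genotypes, config$genotype_format)
  annotation <- read_table(config$annotation, "annotation")
  pheno <- read_table(config$phenotypes, "phenotype")

  networks <- list()
  scores <- list()
  manifest <- list(config = unclass(config)[setdiff(names(config),
                                                    c("expression", "eqtl"))],
                   stages = list())
  for (reg in config$regions) {
    expr <- read_expression(config$expression[[reg]]$expr,
                            config$expression[[reg]]$meta)
    catalog <- read_table(config$eqtl[[reg]], "eqtl")
    net <- build_network(expr, config$anchor[[reg]], reg,
                         min_abs_r = config$min_abs_r,
                         min_fold = config$min_fold)
    pairs <- collect_cis_pairs(net, catalog, annotation)
    harm <- harmonize_alleles(pairs, genotypes$variants)
    dedup <- deduplicate_snp_gene(harm$pairs)
    clump <- ld_clump(dedup, genotypes, r2_max = config$r2_max,
                      window_kb = config$window_kb)
    w <- snp_weights(clump$retained, reg)
    networks[[reg]] <- net
    scores[[reg]] <- compute_region_score(genotypes, w)
    counts <- c(genes_expression = nrow(expr$expr),
                genes_network = nrow(net),
                pairs_catalog = nrow(catalog),
                pairs_collected = nrow(pairs),
                pairs_harmonized = nrow(harm$pairs),
                pairs_deduplicated = nrow(dedup),
                snps_scored = nrow(clump$retained))
    filt <- counts[c("pairs_collected", "pairs_harmonized",
                     "pairs_deduplicated", "snps_scored")]
    stopifnot(all(diff(filt) <= 0))          # counts shrink across filters
    manifest$stages[[reg]] <- as.list(counts)
    write_table(as.data.frame(net), file.path(config$out_dir,
                                              paste0("network_", reg, ".tsv")))
    write_table(clump$retained, file.path(config$out_dir,
                                          paste0("pairs_", reg, ".tsv")))
    write_table(harm$drops, file.path(config$out_dir,
                                      paste0("drops_", reg, ".tsv")))
  }

  score_table <- build_score_table(scores)
  write_table(score_table, file.path(config$out_dir, "scores.tsv"))

  ids <- score_table$individual_id
  pheno <- pheno[match(ids, pheno$individual_id), , drop = FALSE]
  if (anyNA(pheno$individual_id)) {
    stop("phenotype table lacks some scored individuals", call. = FALSE)
  }
  split <- median_split(setNames(score_table$score_combined, ids))

  sex <- if (!is.null(config$sex_col) && config$sex_col %in% names(pheno)) {
    pheno[[config$sex_col]]
  } else {
    NULL
  }
  pcs <- if (length(config$pc_cols) > 0 &&
             all(config$pc_cols %in% names(pheno))) {
    as.matrix(pheno[config$pc_cols])
  } else {
    NULL
  }
  assoc <- do.call(rbind, lapply(config$outcomes, function(oc) {
    if (!oc %in% names(pheno)) stop("outcome column missing: ", oc, call. = FALSE)
    res <- fit_linear_association(pheno[[oc]], score_table$score_combined,
                                  sex = sex, pcs = pcs, outcome_name = oc)
    data.frame(outcome = oc, beta = res$beta, se = res$se, p = res$p,
               n = res$n, stringsAsFactors = FALSE)
  }))
  m <- config$bonferroni_m %||% length(config$outcomes)
  assoc$p_adj <- bonferroni_adjust(assoc$p, m = m)
  write_table(assoc, file.path(config$out_dir, "association.tsv"))
  write_table(split, file.path(config$out_dir, "groups.tsv"))

  manifest$version <- as.character(utils::packageVersion("coexprs"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  list(manifest = manifest, networks = networks, score_table = score_table,
       association = assoc, split = split)
}
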