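# End-to-end driver: simulate -> quantify -> subtype / aberrant ->
# classify -> NMD, with a structured, serializable configuration holding
# every analysis constant in one auditable place.

#' Pipeline configuration
#'
#' All thresholds default to the analysis constants used throughout the
#' package: subtype FDR 5% with a 10% proportion delta; aberrant chi-square
#' and post-hoc FDR 1% each, 10% proportion excess, recurrence cap at 10%
#' of the panel; NMD constants 200 nt / 50 nt / 20 aa; gene detection CPM
#' >= 1 in >= 10 lines; 120-nt probes.
#'
#' @param seed integer seed for the synthetic stages.
#' @param n_cell_lines,n_replicates panel design.
#' @param depth_mean,depth_dispersion,proportion_concentration count-model
#'   parameters (see [sim_design()]).
#' @param alpha,min_delta subtype-association thresholds.
#' @param q_gene,q_pair,min_excess,max_lines aberrant-isoform thresholds
#'   (`max_lines = NULL` means 10% of the panel).
#' @param cpm_threshold,min_lines gene expression filter.
#' @param nmd_min_length,nmd_min_distance,orf_min_aa NMD rule constants.
#' @param probe_len probe window length.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_cell_lines = 40L, n_replicates = 2L,
                            depth_mean = 2000, depth_dispersion = 0.1,
                            proportion_concentration = 200,
                            alpha = 0.05, min_delta = 0.10,
                            q_gene = 0.01, q_pair = 0.01, min_excess = 0.10,
                            max_lines = NULL, cpm_threshold = 1,
                            min_lines = 10L, nmd_min_length = 200L,
                            nmd_min_distance = 50L, orf_min_aa = 20L,
                            probe_len = 120L) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha in (0,1]")
  chk(cfg$q_gene > 0 && cfg$q_gene <= 1, "q_gene in (0,1]")
  chk(cfg$q_pair > 0 && cfg$q_pair <= 1, "q_pair in (0,1]")
  chk(cfg$min_delta >= 0 && cfg$min_delta <= 1, "min_delta in [0,1]")
  chk(cfg$min_excess >= 0 && cfg$min_excess <= 1, "min_excess in [0,1]")
  chk(is.null(cfg$max_lines) || cfg$max_lines >= 1, "max_lines >= 1")
  chk(cfg$n_replicates >= 1, "n_replicates >= 1")
  chk(cfg$nmd_min_length > 0 && cfg$nmd_min_distance > 0 &&
        cfg$orf_min_aa > 0, "NMD constants > 0")
  chk(cfg$probe_len > 0, "probe_len > 0")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return [pipeline_config()] (read) or `path` invisibly (write).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @param cfg a [pipeline_config()].
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  # small deterministic fingerprint of the serialized config
  txt <- yaml::as.yaml(unclass(cfg))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the demonstration pipeline end to end
#'
#' Generates the toy annotation and a count matrix over it (one planted
#' aberrant isoform, one planted subtype-associated isoform), then runs
#' quantification, subtype association, aberrant detection, AS
#' classification of the aberrant isoforms, NMD prediction, and probe
#' design for the panel. Deterministic given the config; every stage is
#' also callable on its own, and stage outputs equal stage-wise
#' invocation.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage tables are written
#'   as TSV along with the config (YAML) and its hash.
#' @return List with `annotation`, `counts`, `abundance`, `proportions`,
#'   `subtype`, `aberrant`, `classification`, `nmd`, `probes`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  ann <- gen_annotation(config$seed)
  design <- demo_design(ann, seed = config$seed,
                        n_cell_lines = config$n_cell_lines,
                        n_replicates = config$n_replicates,
                        depth_mean = config$depth_mean,
                        depth_dispersion = config$depth_dispersion,
                        proportion_concentration =
                          config$proportion_concentration)
  cm <- gen_counts(design)
  ab <- cpm(cm)
  pt <- isoform_proportion(ab)
  subtype <- find_subtype_associated(pt, cm$replicate_map, cm$subtype_map,
                                     alpha = config$alpha,
                                     min_delta = config$min_delta)
  canon <- names(ann$models)[vapply(ann$models, function(m) m$is_canonical,
                                    logical(1))]
  aberrant <- find_aberrant_isoforms(cm, canonical_ids = canon,
                                     q_gene = config$q_gene,
                                     q_pair = config$q_pair,
                                     min_excess = config$min_excess,
                                     max_lines = config$max_lines)
  classification <- if (nrow(aberrant) > 0L)
    classify_isoforms(ann$models, aberrant$isoform_id)
  else classify_isoforms(ann$models)
  nmd <- predict_nmd(ann$models, ann$genome, min_aa = config$orf_min_aa,
                     min_length = config$nmd_min_length,
                     min_distance = config$nmd_min_distance)
  probes <- design_probes(ann$models, ann$genome,
                          probe_len = config$probe_len)
  res <- list(annotation = ann, counts = cm, abundance = ab,
              proportions = pt, subtype = subtype, aberrant = aberrant,
              classification = classification, nmd = nmd, probes = probes,
              config_hash = config_hash(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(ann$models, file.path(out_dir, "annotation.gtf"))
    Biostrings::writeXStringSet(ann$genome, file.path(out_dir, "genome.fa"))
    write_count_matrix(cm, file.path(out_dir, "counts.tsv"),
                       file.path(out_dir, "totals.tsv"),
                       file.path(out_dir, "samples.tsv"))
    wt <- function(df, f) write.table(
      cbind(df, config_hash = res$config_hash), file.path(out_dir, f),
      sep = "\t", quote = FALSE, row.names = FALSE)
    wt(subtype, "subtype_association.tsv")
    wt(aberrant, "aberrant_calls.tsv")
    wt(classification, "classification.tsv")
    wt(nmd, "nmd.tsv")
    wt(probes[, c("gene_id", "chrom", "start", "end", "strand", "name")],
       "probes.tsv")
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  res
}
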