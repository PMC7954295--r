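# End-to-end orchestration: phams -> GCS/GCD -> clustering -> tree /
# NEXUS -> dot plots -> HGT report, from one config, with a
# machine-readable run manifest.

#' Build a pipeline run configuration
#'
#' @param genomes List of `annotated_genome` objects (already loaded),
#'   or `NULL` to load from `genes_tsv` + `fasta`.
#' @param metadata Metadata data.frame, or `NULL` to load from
#'   `metadata_tsv`.
#' @param genes_tsv,fasta,metadata_tsv Input paths used when the
#'   in-memory objects are not supplied.
#' @param out_dir Output directory.
#' @param focal Focal phage for the GCD profile and HGT report;
#'   default the first phage.
#' @param identity_threshold,coverage_threshold Pham thresholds
#'   (percent).
#' @param gcs_threshold Clustering threshold (percent, default 35).
#' @param word_nt,word_aa Dot-plot word sizes (defaults 15 and 5).
#' @param gc_delta,host_min HGT flag thresholds.
#' @param max_per_cluster Representative cap for the exported tree.
#' @param seed Seed recorded in the manifest (any subsampling).
#' @return A list of class `run_config`.
#' @export
run_config <- function(genomes = NULL, metadata = NULL,
                       genes_tsv = NULL, fasta = NULL, metadata_tsv = NULL,
                       out_dir, focal = NULL,
                       identity_threshold = 35, coverage_threshold = 75,
                       gcs_threshold = 35, word_nt = 15, word_aa = 5,
                       gc_delta = 5, host_min = 3,
                       max_per_cluster = 10, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(gcs_threshold >= 0, gcs_threshold <= 100,
            identity_threshold > 0, identity_threshold <= 100,
            coverage_threshold > 0, coverage_threshold <= 100,
            word_nt >= 1, word_aa >= 1)
  if (is.null(genomes) && (is.null(genes_tsv) || is.null(fasta)))
    stop2("supply `genomes` or both `genes_tsv` and `fasta`")
  if (is.null(metadata) && is.null(metadata_tsv))
    stop2("supply `metadata` or `metadata_tsv`")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full shared-gene-content pipeline
#'
#' Executes every stage in dependency order, writes each module's
#' outputs under `out_dir`, and returns (and writes as
#' `manifest.json`) a manifest recording inputs, parameters, per-stage
#' status and headline numbers. A failed stage records its error and
#' downstream stages are skipped; re-running with unchanged inputs and
#' config reproduces identical outputs.
#'
#' @param config A `run_config`.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phamflock")),
    parameters = config[c("identity_threshold", "coverage_threshold",
                          "gcs_threshold", "word_nt", "word_aa",
                          "gc_delta", "host_min", "max_per_cluster", "seed")],
    inputs = list(), stages = list(), results = list())
  failed <- FALSE
  stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(out))
      failed <<- TRUE
      return(NULL)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    out
  }

  io <- stage("io", function() {
    genomes <- config$genomes
    metadata <- config$metadata
    if (is.null(genomes)) {
      manifest$inputs$genes_tsv <<- unname(tools::md5sum(config$genes_tsv))
      manifest$inputs$fasta <<- unname(tools::md5sum(config$fasta))
      tab <- read_genes_tsv(config$genes_tsv)
      meta0 <- if (is.null(metadata)) read_metadata_table(config$metadata_tsv)
               else metadata
      genomes <- lapply(unique(tab$phage_name), function(p) {
        m <- meta0[meta0$phage_name == p, ]
        read_annotated_genome_tsv(config$genes_tsv, config$fasta, phage = p,
                                  host = if (nrow(m)) m$host else "unknown",
                                  original_cluster = if (nrow(m)) m$original_cluster
                                                     else "unassigned")
      })
      names(genomes) <- unique(tab$phage_name)
    }
    if (is.null(metadata)) {
      manifest$inputs$metadata_tsv <<- unname(tools::md5sum(config$metadata_tsv))
      metadata <- read_metadata_table(config$metadata_tsv)
    }
    list(genomes = genomes, metadata = metadata)
  })

  assignment <- stage("phams", function() {
    a <- assign_phams(population_proteins(io$genomes),
                      identity_threshold = config$identity_threshold,
                      coverage_threshold = config$coverage_threshold)
    write_pham_table(a, file.path(config$out_dir, "phams.tsv"))
    a
  })

  stats_out <- stage("gene_content", function() {
    profiles <- pham_profiles(assignment)
    m <- gcs_matrix(profiles)
    write_gcs_csv(m, file.path(config$out_dir, "gcs_matrix.csv"))
    focal <- config$focal %||% names(profiles)[1]
    prof <- gcd_profile(focal, profiles)
    write_gcd_profile_csv(prof, file.path(config$out_dir, "gcd_profile.csv"))
    manifest$results$n_phages <<- length(profiles)
    manifest$results$n_phams <<- length(assignment$phams)
    manifest$results$focal <<- focal
    manifest$results$max_gcd_gap <<- prof$max_gcd_gap
    manifest$results$gap_partner <<- prof$gap_partner
    list(profiles = profiles, matrix = m, gcd = prof)
  })

  partition <- stage("clustering", function() {
    p <- cluster_by_gcs(stats_out$matrix, threshold = config$gcs_threshold)
    write_cluster_report(p, io$metadata, file.path(config$out_dir, "clusters.tsv"))
    manifest$results$n_clusters <<- length(p$members)
    manifest$results$n_singletons <<- sum(p$singleton)
    manifest$results$largest_cluster <<- max(lengths(p$members))
    p
  })

  stage("phylogeny", function() {
    keep <- cluster_representatives(partition, config$max_per_cluster)
    if (length(keep) >= 3L) {
      d <- gcd_distance_matrix(stats_out$profiles[keep])
      tree <- neighbor_joining(d)
      ape::write.tree(tree, file.path(config$out_dir, "gene_content_nj.nwk"))
      export_nexus_distances(d, file.path(config$out_dir, "gcd_distances.nex"))
    }
    NULL
  })

  stage("dotplots", function() {
    ord <- io$genomes[order(names(io$genomes))]
    nt <- concatenated_dotplot(ord, "genome", word = config$word_nt)
    aa <- concatenated_dotplot(ord, "proteome", word = config$word_aa)
    write_dotplot_tsv(nt, file.path(config$out_dir, "dotplot_nt.tsv"))
    write_dotplot_tsv(aa, file.path(config$out_dir, "dotplot_aa.tsv"))
    NULL
  })

  stage("hgt", function() {
    focal <- config$focal %||% names(io$genomes)[1]
    tab <- hgt_evidence_table(io$genomes[[focal]], assignment, io$metadata,
                              gc_delta = config$gc_delta,
                              host_min = config$host_min)
    write_hgt_table(tab, file.path(config$out_dir, "hgt_evidence.tsv"))
    manifest$results$n_hgt_flagged <<- sum(tab$flagged)
    NULL
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
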