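#' Run the full TE census pipeline
#'
#' Composes the independently callable stages — annotation summary, window
#' densities, coverage correction, genome comparison — over a configured
#' set of inputs, writing one provenance-stamped TSV per stage plus a run
#' manifest. Stages whose inputs are not configured are skipped; a stage
#' failure is propagated with the stage label.
#'
#' @param config list with (all optional unless noted):
#'   \describe{
#'     \item{annotations}{path to a RepeatMasker `.out` file (required)}
#'     \item{taxonomy}{path to a taxonomy TSV (default: bundled)}
#'     \item{min_score}{score cutoff, default 250}
#'     \item{chrom_map}{path to a chromosome map TSV (windows stage)}
#'     \item{window_width}{bp, default 50000}
#'     \item{proximal_span}{bp, default 3e6}
#'     \item{alignments}{SAM/BAM/depth-TSV path (correction stage)}
#'     \item{scaffold_lengths}{named vector of scaffold lengths
#'       (correction stage)}
#'     \item{genes}{BED path of gene intervals (reference coverage), or}
#'     \item{ref_cov}{external scalar mean coverage}
#'     \item{assembly_size}{bp, for genome-fraction variants}
#'     \item{genome_table}{path to a genome metadata TSV (comparison stage)}
#'     \item{outdir}{output directory (required)}
#'     \item{seed}{recorded in the manifest}
#'   }
#' @return named list of written file paths and stage results.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$outdir)) stop("config$outdir is required")
  if (is.null(config$annotations)) stop("config$annotations is required")
  if (!file.exists(config$annotations))
    stop("annotation input not found: ", config$annotations)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  min_score <- config$min_score %||% 250
  width <- config$window_width %||% 50000
  span <- config$proximal_span %||% 3e6
  taxonomy <- if (is.null(config$taxonomy)) default_taxonomy() else read_taxonomy(config$taxonomy)

  manifest <- list(parameters = list(min_score = min_score,
                                     window_width = width,
                                     proximal_span = span,
                                     seed = config$seed %||% NA),
                   inputs = config[intersect(names(config),
                     c("annotations", "taxonomy", "chrom_map", "alignments",
                       "genes", "ref_cov", "assembly_size", "genome_table"))])
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  mhash <- substr(unname(tools::md5sum(manifest_path)), 1, 12)
  prov <- list(manifest = mhash, seed = config$seed %||% "none")

  stage <- function(label, code) {
    tryCatch(code, error = function(e)
      stop("stage '", label, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- list(manifest = manifest_path)

  ann <- stage("annotation_io", {
    a <- parse_repeatmasker_out(config$annotations, min_score = min_score,
                                taxonomy = taxonomy)
    resolve_overlaps(a)
  })
  out$category_mass <- file.path(config$outdir, "category_mass.tsv")
  cats <- category_totals(ann)
  write_tsv_prov(cats, out$category_mass, c(prov, list(stage = "annotation_io")))
  out$categories <- cats

  if (!is.null(config$chrom_map)) {
    res <- stage("window_density", {
      cm <- read_chrom_map(config$chrom_map)
      w <- make_windows(cm, width = width, include_partial = FALSE)
      w <- te_bp_per_window(w, ann, cm)
      w <- partition_regions(w, cm, proximal_span = span)
      list(windows = w, stats = region_stats(w))
    })
    out$windows <- file.path(config$outdir, "window_density.tsv")
    write_tsv_prov(res$windows, out$windows, c(prov, list(stage = "window_density")))
    out$region_stats <- file.path(config$outdir, "region_stats.tsv")
    write_tsv_prov(res$stats, out$region_stats, c(prov, list(stage = "window_density")))
  }

  if (!is.null(config$alignments)) {
    res <- stage("coverage_correction", {
      if (is.null(config$scaffold_lengths))
        stop("scaffold_lengths needed with alignments")
      track <- depth_track(config$alignments, config$scaffold_lengths,
                           min_mapq = config$min_mapq %||% 0)
      rc <- if (!is.null(config$genes)) {
        g <- read.table(config$genes, sep = "\t", stringsAsFactors = FALSE)
        mean_feature_coverage(track, data.frame(scaffold = g[[1]],
                                                start = g[[2]], end = g[[3]]))
      } else if (!is.null(config$ref_cov)) {
        reference_coverage(config$ref_cov)
      } else stop("either genes (BED) or ref_cov needed for the correction")
      corrected_mass(track, ann, rc)
    })
    out$correction <- file.path(config$outdir, "correction.tsv")
    write_tsv_prov(res, out$correction,
                   c(prov, list(stage = "coverage_correction",
                                ref_cov = attr(res, "ref_cov")$value,
                                ref_cov_source = attr(res, "ref_cov")$source)))
    out$correction_table <- res
  }

  if (!is.null(config$genome_table)) {
    res <- stage("genome_comparison", {
      g <- read_genome_table(config$genome_table)
      gm <- group_means(g)
      mw <- mann_whitney(g$te_percent[g$seq_method == "Sanger"],
                         g$te_percent[g$seq_method == "NGS"])
      gm$u_statistic <- mw$U
      gm$p_value <- mw$p
      gm$test_method <- mw$method
      gm
    })
    out$comparison <- file.path(config$outdir, "group_comparison.tsv")
    write_tsv_prov(res, out$comparison, c(prov, list(stage = "genome_comparison")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot TE density along chromosomes
#'
#' One panel per chromosome, density per window from the telomere, with
#' the proximal band marked.
#'
#' @param windows window table with `density` (and optionally `region`).
#' @param proximal_span proximal band width in bp.
#' @param chrom_map chromosome map (for the band position).
#' @return a ggplot object.
#' @export
plot_window_density <- function(windows, chrom_map, proximal_span = 3e6) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is needed for plotting")
  cl <- chrom_lengths(validate_chrom_map(chrom_map))
  band <- data.frame(chrom = names(cl),
                     at = as.numeric(cl) - proximal_span)
  band$at[band$at < 0] <- 0
  ggplot2::ggplot(windows, ggplot2::aes(x = (start + end) / 2e6, y = density)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_vline(data = band, ggplot2::aes(xintercept = at / 1e6),
                        colour = "red", linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "chromosome position (Mb, from telomere)",
                  y = "TE density") +
    ggplot2::theme_minimal()
}

#' Bar chart of annotated vs corrected category mass
#'
#' @param correction output of [corrected_mass()] (or a compatible table).
#' @param level which level to show (default `"order"`).
#' @return a ggplot object.
#' @export
plot_correction <- function(correction, level = "order") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is needed for plotting")
  d <- correction[correction$level == level, , drop = FALSE]
  long <- rbind(data.frame(category = d$category, what = "annotated",
                           kb = d$annotated_bp / 1000),
                data.frame(category = d$category, what = "corrected",
                           kb = d$corrected_bp / 1000))
  ggplot2::ggplot(long, ggplot2::aes(x = category, y = kb, fill = what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "kb") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
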