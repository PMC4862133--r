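#' Bundled genome survey table
#'
#' The transcribed survey of TE percentages across 27 publicly available
#' Drosophila genus assemblies (25 species; two D. buzzatii strains and two
#' D. simulans assemblies), each annotated with the same RepBase Insecta
#' library, together with taxonomic placement and sequencing technology
#' group (Sanger vs NGS).
#'
#' @return data frame with columns `species`, `strain`, `subgenus`,
#'   `group`, `subgroup`, `seq_method`, `te_percent`.
#' @export
drosophila_genomes <- function() {
  read_genome_table(system.file("extdata", "drosophila_te_content.tsv",
                                package = "tecensus"))
}

#' Read a genome metadata table
#'
#' @param path TSV with at least `species`, `seq_method`, `te_percent`.
#' @return validated data frame.
#' @export
read_genome_table <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  quote = "", fill = TRUE)
  need <- c("species", "seq_method", "te_percent")
  if (!all(need %in% names(g)))
    stop("genome table needs columns: ", paste(need, collapse = ", "))
  stopifnot(all(g$te_percent >= 0 & g$te_percent <= 100))
  g
}

#' Mean TE percentage per sequencing-technology group
#'
#' @param records genome metadata data frame.
#' @return data frame `seq_method`, `n`, `mean_te_percent` (unrounded;
#'   report at 2 decimals).
#' @export
group_means <- function(records) {
  sp <- split(records$te_percent, records$seq_method)
  data.frame(seq_method = names(sp),
             n = vapply(sp, length, 0L),
             mean_te_percent = vapply(sp, mean, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The exact null distribution is used
#' when both samples have at most 25 observations and the pooled values
#' are tie-free; otherwise the normal approximation with continuity
#' correction. The method actually used is recorded in the result. With
#' all values identical across both groups the test is degenerate: p = 1
#' is reported with a ties warning.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max largest per-group size for the exact distribution.
#' @return list `U` (statistic for `a`), `p`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 25) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1) {
    warning("all values identical across both groups: test degenerate, p = 1")
    return(list(U = length(a) * length(b) / 2, p = 1, method = "degenerate_ties"))
  }
  ties <- any(duplicated(c(a, b)))
  use_exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal_approximation_cc")
}

#' Nx assembly statistics
#'
#' Sorts scaffold lengths in descending order and finds the first scaffold
#' at which the cumulative length reaches `fraction` of the assembly
#' total. The Nx index is that scaffold's rank; the Nx length is its
#' length (N50: half the assembly is in scaffolds at least this long).
#'
#' @param lengths scaffold lengths in bp (non-empty, positive).
#' @param fraction target cumulative fraction in (0,1); 0.5 for N50, 0.9
#'   for N90.
#' @return list `index`, `length`.
#' @export
nx_stats <- function(lengths, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  stopifnot(length(lengths) >= 1, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(s) >= fraction * sum(s))[1]
  list(index = i, length = s[i])
}

#' Paired subgroup comparison of sequencing technologies
#'
#' Descriptive table of subgroups represented in both technology groups:
#' mean TE percent per technology within each such subgroup. No test is
#' attached — the records are not phylogenetically independent, so the
#' pairing is reported descriptively only.
#'
#' @param records genome metadata data frame with a `subgroup` column.
#' @return data frame `subgroup`, `sanger_te_percent`, `ngs_te_percent`.
#' @export
paired_subgroups <- function(records) {
  both <- Filter(function(sg) {
    m <- records$seq_method[records$subgroup == sg]
    all(c("Sanger", "NGS") %in% m)
  }, unique(records$subgroup))
  res <- lapply(both, function(sg) {
    r <- records[records$subgroup == sg, ]
    data.frame(subgroup = sg,
               sanger_te_percent = mean(r$te_percent[r$seq_method == "Sanger"]),
               ngs_te_percent = mean(r$te_percent[r$seq_method == "NGS"]),
               stringsAsFactors = FALSE)
  })
  if (!length(res))
    return(data.frame(subgroup = character(), sanger_te_percent = numeric(),
                      ngs_te_percent = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Bundled TE contribution table
#'
#' The transcribed per-superfamily TE mass table (kb) for the two
#' D. buzzatii assemblies — before (`st1_kb`, `j19_kb`) and after
#' (`st1_corr_kb`, `j19_corr_kb`) the coverage-based correction — and the
#' D. mojavensis assembly (`moj_kb`). Helitron, Maverick, Others and
#' Unknown are single-row orders.
#'
#' @return data frame with columns `order`, `superfamily` and the five kb
#'   columns.
#' @export
te_contribution_table <- function() {
  read.table(system.file("extdata", "te_table1.tsv", package = "tecensus"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE, quote = "")
}
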