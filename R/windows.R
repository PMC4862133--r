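#' Chromosome map utilities
#'
#' A chromosome map orders and orients scaffolds along chromosomes. It is a
#' data frame with columns `scaffold`, `chrom`, `index` (order of the
#' scaffold within its chromosome, counted from the telomere), `orientation`
#' (`forward`/`reverse`) and `length` (bp). Scaffolds are abutted without
#' gap padding, defining a single concatenated chromosome coordinate that
#' starts at the telomere and runs toward the centromere.
#'
#' @param path TSV with the five columns above.
#' @return validated chromosome map data frame.
#' @export
read_chrom_map <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_chrom_map(m)
}

validate_chrom_map <- function(m) {
  need <- c("scaffold", "chrom", "index", "orientation", "length")
  if (!all(need %in% names(m)))
    stop("chromosome map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$scaffold)) stop("duplicated scaffold in chromosome map")
  m$chrom <- as.character(m$chrom)
  m <- m[order(m$chrom, m$index), , drop = FALSE]
  # chromosome-coordinate offset of each scaffold
  m$offset <- stats::ave(m$length, m$chrom, FUN = function(x) cumsum(x) - x)
  rownames(m) <- NULL
  m
}

chrom_lengths <- function(chrom_map) {
  tapply(chrom_map$length, chrom_map$chrom, sum)
}

#' Lay fixed-width windows along chromosomes
#'
#' Breaks each chromosome of the map into consecutive non-overlapping
#' half-open windows of exactly `width` bp. The trailing sub-width window
#' is appended only when `include_partial` is TRUE (plotting mode);
#' statistics use whole windows only.
#'
#' @param chrom_map chromosome map (see [read_chrom_map()]).
#' @param width window width in bp (default 50 kb).
#' @param include_partial keep the final shorter window (default FALSE).
#' @return data frame `chrom`, `start`, `end` (chromosome coordinates),
#'   `is_full`.
#' @export
make_windows <- function(chrom_map, width = 50000, include_partial = FALSE) {
  stopifnot(width > 0)
  if (nrow(chrom_map) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      is_full = logical(), stringsAsFactors = FALSE))
  cl <- chrom_lengths(validate_chrom_map(chrom_map))
  out <- lapply(names(cl), function(ch) {
    len <- cl[[ch]]
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    full <- (ends - starts) == width
    if (!include_partial) { starts <- starts[full]; ends <- ends[full]; full <- full[full] }
    if (!length(starts)) return(NULL)
    data.frame(chrom = ch, start = starts, end = ends, is_full = full,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lift scaffold-coordinate annotations to chromosome coordinates
#'
#' Applies the chromosome map: reverse-oriented scaffolds are flipped
#' (interval `[s,e)` on a scaffold of length L becomes `[L-e, L-s)`) and
#' scaffold offsets added. Annotations on scaffolds absent from the map are
#' skipped with a message reporting the count.
#'
#' @param ann TE annotation data frame (scaffold coordinates).
#' @param chrom_map chromosome map.
#' @return annotation data frame with columns `chrom`, `start`, `end` in
#'   chromosome coordinates (original columns retained).
#' @export
lift_to_chrom <- function(ann, chrom_map) {
  chrom_map <- validate_chrom_map(chrom_map)
  i <- match(ann$scaffold, chrom_map$scaffold)
  miss <- is.na(i)
  if (any(miss))
    message(sum(miss), " annotation(s) on scaffolds absent from the chromosome map were skipped")
  ann <- ann[!miss, , drop = FALSE]
  i <- i[!miss]
  len <- chrom_map$length[i]
  rev <- chrom_map$orientation[i] == "reverse"
  s <- ifelse(rev, len - ann$end, ann$start)
  e <- ifelse(rev, len - ann$start, ann$end)
  ann$chrom <- chrom_map$chrom[i]
  ann$start <- s + chrom_map$offset[i]
  ann$end <- e + chrom_map$offset[i]
  rownames(ann) <- NULL
  ann
}

#' TE base pairs and density per window
#'
#' Intersects overlap-resolved annotations (lifted to chromosome
#' coordinates via the map) with a window set. An annotation spanning a
#' window boundary is split at the boundary and contributes to both
#' windows.
#'
#' @param windows window table from [make_windows()].
#' @param ann TE annotation data frame in scaffold coordinates.
#' @param chrom_map chromosome map.
#' @return `windows` with `te_bp` and `density` (`te_bp` / window length)
#'   columns added.
#' @export
te_bp_per_window <- function(windows, ann, chrom_map) {
  windows$te_bp <- 0
  lifted <- lift_to_chrom(ann, chrom_map)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    a <- lifted[lifted$chrom == ch, , drop = FALSE]
    if (!nrow(a)) next
    wr <- IRanges::IRanges(start = windows$start[wi] + 1, end = windows$end[wi])
    ar <- IRanges::IRanges(start = a$start + 1, end = a$end)
    hits <- IRanges::findOverlaps(wr, ar)
    if (!length(hits)) next
    ov <- IRanges::pintersect(wr[S4Vectors::queryHits(hits)],
                              ar[S4Vectors::subjectHits(hits)])
    bp <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    windows$te_bp[wi[as.integer(names(bp))]] <- as.numeric(bp)
  }
  windows$density <- windows$te_bp / (windows$end - windows$start)
  windows
}

#' Partition windows into proximal and central+distal regions
#'
#' The proximal region of each major chromosome is the `proximal_span` bp
#' nearest the centromere, i.e. the highest chromosome coordinates (windows
#' run telomere to centromere). The dot chromosome (label in `dot_chrom`)
#' is treated as a single region of its own. A chromosome shorter than the
#' span is entirely proximal, with a warning.
#'
#' @param windows window table (chromosome coordinates).
#' @param chrom_map chromosome map.
#' @param proximal_span span of the proximal region in bp (default 3 Mb).
#' @param dot_chrom chromosome label(s) forming their own whole-chromosome
#'   region (default `"6"`).
#' @return `windows` with a `region` column in
#'   `{proximal, central_distal, whole_chromosome_6}`.
#' @export
partition_regions <- function(windows, chrom_map, proximal_span = 3e6,
                              dot_chrom = "6") {
  cl <- chrom_lengths(validate_chrom_map(chrom_map))
  len <- as.numeric(cl[windows$chrom])
  short <- setdiff(names(cl)[cl < proximal_span], dot_chrom)
  if (length(short))
    warning("chromosome(s) shorter than the proximal span, entirely proximal: ",
            paste(short, collapse = ", "))
  region <- ifelse(windows$start >= len - proximal_span, "proximal", "central_distal")
  region[windows$chrom %in% dot_chrom] <- "whole_chromosome_6"
  windows$region <- region
  windows
}

#' Per-chromosome, per-region density summary
#'
#' Mean TE density (percent), sample standard deviation and window count
#' per chromosome and region, using full windows only, plus per-chromosome
#' totals and a pooled `Total` row per region. In the pooled rows the
#' whole-dot-chromosome region is grouped with the proximal windows, as
#' both are the recombination-poor, TE-dense compartments.
#'
#' @param windows windows with `density` and `region` columns.
#' @return data frame `chrom`, `region`, `mean_pct`, `sd_pct`, `n`.
#' @export
region_stats <- function(windows) {
  w <- windows[windows$is_full, , drop = FALSE]
  cell <- function(d) {
    if (!length(d)) return(c(NA_real_, NA_real_, 0))
    c(mean(d) * 100, if (length(d) > 1) sd(d) * 100 else 0, length(d))
  }
  rows <- list()
  for (ch in unique(w$chrom)) {
    for (rg in unique(w$region[w$chrom == ch])) {
      v <- cell(w$density[w$chrom == ch & w$region == rg])
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, region = rg,
        mean_pct = v[1], sd_pct = v[2], n = v[3], stringsAsFactors = FALSE)
    }
    v <- cell(w$density[w$chrom == ch])
    rows[[length(rows) + 1]] <- data.frame(chrom = ch, region = "total",
      mean_pct = v[1], sd_pct = v[2], n = v[3], stringsAsFactors = FALSE)
  }
  pooled_prox <- w$region %in% c("proximal", "whole_chromosome_6")
  for (rg in c("proximal", "central_distal", "total")) {
    sel <- switch(rg, proximal = pooled_prox,
                  central_distal = w$region == "central_distal",
                  total = rep(TRUE, nrow(w)))
    v <- cell(w$density[sel])
    rows[[length(rows) + 1]] <- data.frame(chrom = "Total", region = rg,
      mean_pct = v[1], sd_pct = v[2], n = v[3], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Two-sample Kolmogorov-Smirnov comparison of density samples
#'
#' Two-sided two-sample KS test: D is the maximum gap between the two
#' empirical CDFs, p from the standard exact/asymptotic formula
#' (`stats::ks.test`).
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return list with `D`, `p`, `method`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("ks_compare needs at least 2 observations per sample")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value, method = kt$method)
}

#' All-pairs KS comparison matrix
#'
#' Compares every pair of density samples; p-values are reported raw (the
#' comparison surface) and Holm-adjusted as an extra column.
#'
#' @param samples named list of numeric samples.
#' @return data frame `a`, `b`, `D`, `p`, `p_holm`.
#' @export
ks_matrix <- function(samples) {
  nm <- names(samples)
  pairs <- utils::combn(nm, 2)
  res <- apply(pairs, 2, function(pr) {
    k <- ks_compare(samples[[pr[1]]], samples[[pr[2]]])
    data.frame(a = pr[1], b = pr[2], D = k$D, p = k$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res
}
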