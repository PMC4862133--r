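#' Per-base read depth from alignments
#'
#' Builds one depth vector per scaffold — the number of aligned read bases
#' covering each position — from a SAM/BAM file or from the plain-text
#' depth dialect (TSV with columns `scaffold`, `pos` (1-based), `depth`).
#' Only mapped primary alignments are counted; read bases come from the
#' alignment's M/=/X segments (insertions and clips contribute nothing,
#' deletions add no read base). Multi-mapped placement is kept (no MAPQ
#' filter by default): reads from collapsed repeat copies piling onto the
#' surviving copy are exactly the signal the correction uses. Duplicates
#' are not removed.
#'
#' @param path SAM (`.sam`), BAM (`.bam`) or depth TSV file.
#' @param scaffold_lengths named numeric vector of scaffold lengths.
#' @param min_mapq minimum mapping quality (default 0 = keep all).
#' @return named list of integer depth vectors, one per scaffold in
#'   `scaffold_lengths`; attribute `aligned_bases` holds the total.
#' @export
depth_track <- function(path, scaffold_lengths, min_mapq = 0) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    .depth_from_alignments(path, scaffold_lengths, min_mapq)
  } else {
    .depth_from_tsv(path, scaffold_lengths)
  }
}

.depth_from_alignments <- function(path, scaffold_lengths, min_mapq) {
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  extra <- setdiff(names(hdr), names(scaffold_lengths))
  if (length(extra))
    stop("alignment file refers to scaffold(s) absent from the length table: ",
         paste(extra, collapse = ", "))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  n_unmapped <- Rsamtools::countBam(bam, param = Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records
  if (n_unmapped > 0) message(n_unmapped, " unmapped record(s) skipped")
  cov <- GenomicAlignments::coverage(gal, drop.D.ranges = TRUE)
  track <- lapply(setNames(names(scaffold_lengths), names(scaffold_lengths)), function(sc) {
    len <- as.integer(scaffold_lengths[[sc]])
    if (sc %in% names(cov)) {
      v <- as.integer(cov[[sc]])
      length(v) <- len           # pad with NA then zero-fill
      v[is.na(v)] <- 0L
      v
    } else integer(len)
  })
  structure(track, aligned_bases = sum(vapply(track, sum, 0)))
}

.depth_from_tsv <- function(path, scaffold_lengths) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  need <- c("scaffold", "pos", "depth")
  if (!all(need %in% names(d)))
    stop("depth TSV needs columns: ", paste(need, collapse = ", "))
  extra <- setdiff(unique(d$scaffold), names(scaffold_lengths))
  if (length(extra))
    stop("depth TSV refers to scaffold(s) absent from the length table: ",
         paste(extra, collapse = ", "))
  track <- lapply(setNames(names(scaffold_lengths), names(scaffold_lengths)), function(sc) {
    v <- integer(as.integer(scaffold_lengths[[sc]]))
    di <- d[d$scaffold == sc, , drop = FALSE]
    v[di$pos] <- as.integer(di$depth)
    v
  })
  structure(track, aligned_bases = sum(vapply(track, sum, 0)))
}

#' Write a depth track in the plain-text depth dialect
#'
#' Zero-depth positions are omitted; [depth_track()] restores them.
#'
#' @param track named list of per-scaffold depth vectors.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  rows <- lapply(names(track), function(sc) {
    v <- track[[sc]]
    nz <- which(v > 0)
    if (!length(nz)) return(NULL)
    data.frame(scaffold = sc, pos = nz, depth = v[nz], stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(scaffold = character(), pos = integer(), depth = integer())
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# sum of depth over a set of 0-based half-open intervals (data frame with
# scaffold/start/end)
.depth_sum <- function(track, intervals) {
  if (nrow(intervals) == 0) return(0)
  s <- 0
  for (i in seq_len(nrow(intervals))) {
    v <- track[[intervals$scaffold[i]]]
    if (is.null(v)) stop("interval on scaffold absent from track: ", intervals$scaffold[i])
    s <- s + sum(as.numeric(v[(intervals$start[i] + 1):intervals$end[i]]))
  }
  s
}

#' Mean read coverage over a feature set
#'
#' Reference coverage for the correction: total aligned read bases over the
#' feature positions divided by total feature length. The study design uses
#' gene intervals as the reference — genes are essentially single-copy, so
#' their depth is an unbiased estimate of the true per-copy coverage.
#'
#' @param track depth track from [depth_track()].
#' @param features data frame `scaffold`, `start`, `end` (0-based
#'   half-open), overlap-free (internally `reduce`d to be safe).
#' @return list with `value` (mean depth) and `source = "gene_intervals"`.
#' @export
mean_feature_coverage <- function(track, features) {
  if (nrow(features) == 0 || sum(features$end - features$start) == 0)
    stop("zero total feature length")
  red <- do.call(rbind, lapply(split(features, features$scaffold), function(f) {
    r <- IRanges::reduce(IRanges::IRanges(start = f$start + 1, end = f$end))
    data.frame(scaffold = f$scaffold[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  list(value = .depth_sum(track, red) / sum(red$end - red$start),
       source = "gene_intervals")
}

#' Reference coverage from an external scalar
#'
#' Alternative to [mean_feature_coverage()] when the mean coverage is known
#' from the assembler or sequencing design (e.g. 160x) rather than
#' estimated from gene intervals.
#'
#' @param value mean depth, > 0.
#' @return list with `value` and `source = "external_scalar"`.
#' @export
reference_coverage <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value > 0)
  list(value = value, source = "external_scalar")
}

#' Coverage-based correction of TE abundance
#'
#' The core correction: for each order and superfamily, every aligned read
#' base over a TE-annotated position is added up (`read_mass_bp`) and
#' divided by the reference mean coverage, giving the corrected abundance
#' `corrected_bp` — the TE base count implied by the reads rather than by
#' the (possibly collapsed) assembly. The correction factor is
#' `corrected_bp / annotated_bp`; a factor above 1 means copies are missing
#' from the assembly.
#'
#' @param track depth track.
#' @param ann overlap-resolved TE annotation data frame.
#' @param ref_cov reference coverage list ([mean_feature_coverage()] or
#'   [reference_coverage()]) or a bare positive number.
#' @return data frame `level`, `category`, `order`, `annotated_bp`,
#'   `read_mass_bp`, `corrected_bp`, `factor`, `delta_bp`; includes order
#'   rows, superfamily rows and a `Total` row.
#' @export
corrected_mass <- function(track, ann, ref_cov) {
  if (is.numeric(ref_cov)) ref_cov <- reference_coverage(ref_cov)
  C <- ref_cov$value
  if (!is.numeric(C) || C <= 0) stop("reference coverage must be > 0")
  cats <- category_totals(ann)
  mass_of <- function(sel) .depth_sum(track, ann[sel, c("scaffold", "start", "end"), drop = FALSE])
  cats$read_mass_bp <- NA_real_
  for (i in seq_len(nrow(cats))) {
    sel <- switch(cats$level[i],
                  order = ann$order == cats$category[i],
                  superfamily = ann$superfamily == cats$category[i] & ann$order == cats$order[i],
                  total = rep(TRUE, nrow(ann)))
    cats$read_mass_bp[i] <- mass_of(sel)
  }
  res <- data.frame(level = cats$level, category = cats$category,
                    order = cats$order, annotated_bp = cats$bp,
                    read_mass_bp = cats$read_mass_bp,
                    corrected_bp = cats$read_mass_bp / C,
                    stringsAsFactors = FALSE)
  res$factor <- ifelse(res$annotated_bp > 0, res$corrected_bp / res$annotated_bp, NA_real_)
  res$delta_bp <- res$corrected_bp - res$annotated_bp
  attr(res, "ref_cov") <- ref_cov
  res
}

#' Correct a read mass by a reference coverage
#'
#' Scalar form of the correction: `read_mass / coverage`. Used when the
#' summed read mass over TE positions is already known (e.g. 403.3 Mb of
#' read bases at 22.37x mean gene coverage give 18.0 Mb of TE sequence).
#'
#' @param read_mass_bp summed aligned read bases over the category.
#' @param ref_cov mean reference coverage (x), > 0.
#' @return corrected base count.
#' @export
coverage_correct <- function(read_mass_bp, ref_cov) {
  stopifnot(ref_cov > 0)
  read_mass_bp / ref_cov
}

#' Correction factors from annotated and corrected columns
#'
#' @param annotated,corrected matching numeric vectors of per-category
#'   mass (any unit).
#' @param digits rounding for the reported factor (default 2, matching the
#'   published table convention); internal arithmetic is unrounded.
#' @return numeric vector `corrected/annotated`, `NA` (flagged by warning)
#'   where annotated is zero.
#' @export
correction_factors <- function(annotated, corrected, digits = 2) {
  stopifnot(length(annotated) == length(corrected))
  f <- ifelse(annotated > 0, corrected / annotated, NA_real_)
  if (any(is.na(f) & corrected > 0))
    warning("category with zero annotated mass but positive corrected mass: factor undefined")
  round(f, digits)
}

#' Genome TE fraction under the two genome-size conventions
#'
#' `variant = "gaps"` keeps the assembly size as the genome size, assuming
#' the extra corrected mass lives in intra-scaffold gaps:
#' `corrected / assembly_size x 100`. `variant = "inflate"` instead adds
#' the newly found mass to the genome size:
#' `corrected / (assembly_size + (corrected - annotated)) x 100`.
#'
#' @param corrected_bp corrected total TE mass.
#' @param assembly_size_bp assembly size (> 0).
#' @param annotated_bp annotated TE mass (needed for `"inflate"`).
#' @param variant `"gaps"` (default) or `"inflate"`.
#' @return TE percent of the genome.
#' @export
genome_fraction <- function(corrected_bp, assembly_size_bp,
                            annotated_bp = NULL,
                            variant = c("gaps", "inflate")) {
  variant <- match.arg(variant)
  stopifnot(assembly_size_bp > 0)
  if (variant == "gaps") return(corrected_bp / assembly_size_bp * 100)
  if (is.null(annotated_bp))
    stop("the inflate variant needs the annotated mass to size the delta")
  delta <- corrected_bp - annotated_bp   # may be negative (over-assembly)
  corrected_bp / (assembly_size_bp + delta) * 100
}
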