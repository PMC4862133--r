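#' Parse a RepeatMasker .out annotation file
#'
#' Reads the standard 15-column whitespace-separated RepeatMasker `.out`
#' report (3 header lines, 1-based inclusive query coordinates) into a TE
#' annotation table. Coordinates are converted to 0-based half-open at this
#' boundary; all downstream interval arithmetic uses that convention.
#'
#' Records below `min_score` (Smith-Waterman score) are dropped, matching a
#' RepeatMasker run with `cutoff 250`. Simple repeats, low-complexity and
#' satellite/RNA classes are excluded when `drop_simple` is TRUE (the
#' `nolow`/`norna` convention); TE library curation typically removes them
#' before masking anyway.
#'
#' Records flagged `*` (overlapped by a higher-scoring hit) are retained:
#' overlap policy is applied explicitly by [resolve_overlaps()], not by the
#' parser.
#'
#' @param path path to a `.out` file.
#' @param min_score minimum Smith-Waterman score to retain (default 250).
#' @param taxonomy taxonomy for order/superfamily assignment.
#' @param drop_simple exclude Simple_repeat/Low_complexity/Satellite/RNA
#'   classes (default TRUE).
#' @return a TE annotation data frame with columns `scaffold`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`), `family`,
#'   `superfamily`, `order`, `score`, `divergence`.
#' @export
parse_repeatmasker_out <- function(path, min_score = 250,
                                   taxonomy = default_taxonomy(),
                                   drop_simple = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("annotation file is empty (no header, no records): ", path)
  # skip the header block: standard files carry 2 column-header lines + 1
  # blank; detect records as lines whose first token is numeric
  is_record <- vapply(lines, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    length(tok) >= 14 && grepl("^[0-9]+$", tok[1])
  }, logical(1), USE.NAMES = FALSE)
  rec_lines <- which(is_record)
  if (length(rec_lines) == 0) return(empty_annotation())

  parse_one <- function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    score <- suppressWarnings(as.integer(tok[1]))
    qstart <- suppressWarnings(as.numeric(tok[6]))
    qend <- suppressWarnings(as.numeric(tok[7]))
    if (is.na(score) || is.na(qstart) || is.na(qend))
      stop("malformed record at line ", i, " of ", path, ": non-numeric score/coordinates")
    if (qend < qstart)
      stop("malformed record at line ", i, " of ", path, ": end < start")
    list(score = score, divergence = suppressWarnings(as.numeric(tok[2])),
         scaffold = tok[5], start = qstart - 1, end = qend,
         strand = if (tok[9] %in% c("C", "-")) "-" else "+",
         family = tok[10], classfam = tok[11])
  }
  recs <- lapply(rec_lines, parse_one)
  ann <- data.frame(
    scaffold = vapply(recs, `[[`, "", "scaffold"),
    start = vapply(recs, `[[`, 0, "start"),
    end = vapply(recs, `[[`, 0, "end"),
    strand = vapply(recs, `[[`, "", "strand"),
    family = vapply(recs, `[[`, "", "family"),
    classfam = vapply(recs, `[[`, "", "classfam"),
    score = vapply(recs, function(r) as.numeric(r$score), 0),
    divergence = vapply(recs, `[[`, 0, "divergence"),
    stringsAsFactors = FALSE
  )
  if (drop_simple) {
    low <- grepl("^(Simple_repeat|Low_complexity|Satellite|rRNA|snRNA|scRNA|srpRNA|tRNA|RNA|ARTEFACT)",
                 ann$classfam)
    ann <- ann[!low, , drop = FALSE]
  }
  ann <- ann[ann$score >= min_score, , drop = FALSE]
  if (nrow(ann) == 0) return(empty_annotation())
  # exact repeat-name lookup first, class/family string as fallback
  cl_name <- classify(ann$family, taxonomy)
  cl_class <- classify(ann$classfam, taxonomy)
  use_class <- cl_name$order == "Unknown"
  ann$order <- ifelse(use_class, cl_class$order, cl_name$order)
  ann$superfamily <- ifelse(use_class, cl_class$superfamily, cl_name$superfamily)
  ann$classfam <- NULL
  rownames(ann) <- NULL
  ann[, c("scaffold", "start", "end", "strand", "family", "superfamily",
          "order", "score", "divergence")]
}

empty_annotation <- function() {
  data.frame(scaffold = character(), start = numeric(), end = numeric(),
             strand = character(), family = character(),
             superfamily = character(), order = character(),
             score = numeric(), divergence = numeric(),
             stringsAsFactors = FALSE)
}

#' Write annotations in the RepeatMasker .out dialect
#'
#' Emits the standard 15-column layout (3 header lines, 1-based inclusive
#' coordinates) so that [parse_repeatmasker_out()] round-trips the table.
#' The class/family column is written as `order/superfamily`.
#'
#' @param ann TE annotation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(ann, path) {
  hdr <- c(
    "   SW   perc perc perc  query              position in query              matching          repeat                 position in repeat",
    "score   div. del. ins.  sequence           begin  end          (left)     repeat            class/family       begin  end    (left)     ID",
    "")
  body <- character(0)
  if (nrow(ann)) {
    body <- sprintf("%5d %6.1f  0.0  0.0  %s %10d %10d (0) %s %s %s 1 %d (0) %d",
                    as.integer(round(ann$score)), ann$divergence, ann$scaffold,
                    as.integer(ann$start + 1), as.integer(ann$end),
                    ifelse(ann$strand == "-", "C", "+"),
                    ann$family, paste0(ann$order, "/", ann$superfamily),
                    as.integer(ann$end - ann$start), seq_len(nrow(ann)))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resolve overlapping TE annotations
#'
#' RepeatMasker hits can overlap; summing their lengths would double-count
#' bases. The default `"score"` policy assigns every base to exactly one
#' annotation — the highest-scoring hit covering it, ties broken by earlier
#' start then lexicographic family name — and returns (possibly split)
#' disjoint intervals that retain the winning hit's identity. The
#' `"union"` policy instead merges intervals within each (scaffold, family),
#' a sensitivity variant in which each family's bases are counted once but
#' different families may still overlap.
#'
#' @param ann TE annotation data frame.
#' @param method `"score"` (base-level winner takes all, default) or
#'   `"union"` (per-family interval union).
#' @return annotation data frame; with `"score"`, intervals are pairwise
#'   disjoint within each scaffold and total bp never exceeds the input.
#' @export
resolve_overlaps <- function(ann, method = c("score", "union")) {
  method <- match.arg(method)
  if (nrow(ann) == 0) return(ann)
  out <- lapply(split(ann, ann$scaffold), function(a) {
    if (method == "score") .resolve_score(a) else .resolve_union(a)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.resolve_score <- function(a) {
  ord <- order(-a$score, a$start, a$family)
  a <- a[ord, , drop = FALSE]
  claimed <- IRanges::IRanges()
  pieces <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    ir <- IRanges::IRanges(start = a$start[i] + 1, end = a$end[i])
    keep <- IRanges::setdiff(ir, claimed)
    if (length(keep)) {
      row <- a[rep(i, length(keep)), , drop = FALSE]
      row$start <- IRanges::start(keep) - 1
      row$end <- IRanges::end(keep)
      pieces[[i]] <- row
      claimed <- IRanges::union(claimed, keep)
    }
  }
  do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
}

.resolve_union <- function(a) {
  out <- lapply(split(a, a$family), function(f) {
    red <- IRanges::reduce(IRanges::IRanges(start = f$start + 1, end = f$end))
    data.frame(scaffold = f$scaffold[1],
               start = IRanges::start(red) - 1, end = IRanges::end(red),
               strand = f$strand[1], family = f$family[1],
               superfamily = f$superfamily[1], order = f$order[1],
               score = max(f$score), divergence = f$divergence[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate TE mass per order and superfamily
#'
#' Sums annotated base pairs per superfamily and per order and expresses
#' each category's share of the total TE mass in percent. Input should be
#' overlap-resolved (see [resolve_overlaps()]) so no base is counted twice.
#'
#' @param ann overlap-resolved TE annotation data frame.
#' @return data frame with columns `level` (`order`/`superfamily`),
#'   `category`, `order`, `bp`, `kb`, `share_pct`. All seven orders are
#'   always present (zero mass if absent); a row `level == "total"` carries
#'   the TE total. With no annotations every category is 0 and shares are 0.
#' @export
category_totals <- function(ann) {
  width <- ann$end - ann$start
  by_order <- tapply(width, factor(ann$order, levels = TE_ORDERS), sum, default = 0)
  ord_tab <- data.frame(level = "order", category = TE_ORDERS,
                        order = TE_ORDERS, bp = as.numeric(by_order),
                        stringsAsFactors = FALSE)
  sf_tab <- if (nrow(ann)) {
    agg <- aggregate(list(bp = width),
                     by = list(category = ann$superfamily, order = ann$order),
                     FUN = sum)
    data.frame(level = "superfamily", category = agg$category,
               order = agg$order, bp = agg$bp, stringsAsFactors = FALSE)
  } else {
    data.frame(level = character(), category = character(),
               order = character(), bp = numeric(), stringsAsFactors = FALSE)
  }
  total <- sum(width)
  tot_tab <- data.frame(level = "total", category = "Total", order = "Total",
                        bp = as.numeric(total), stringsAsFactors = FALSE)
  res <- rbind(ord_tab, sf_tab, tot_tab)
  res$kb <- res$bp / 1000
  res$share_pct <- if (total > 0) res$bp / total * 100 else 0
  res
}

#' Order-level summary of a Table-1-style mass table
#'
#' Computes order totals and their shares of the TE total from a
#' superfamily-level kb table such as the bundled [te_contribution_table()].
#'
#' @param tab data frame with columns `order`, `superfamily`, and the kb
#'   column named by `column`.
#' @param column which kb column to summarize.
#' @return data frame (`order`, `kb`, `share_pct`) plus a `Total` row.
#' @export
order_shares <- function(tab, column) {
  kb <- tab[[column]]
  if (is.null(kb)) stop("no column '", column, "' in table")
  by_order <- tapply(kb, factor(tab$order, levels = TE_ORDERS), sum, default = 0)
  total <- sum(kb)
  data.frame(order = c(TE_ORDERS, "Total"),
             kb = c(as.numeric(by_order), total),
             share_pct = c(as.numeric(by_order) / total * 100, 100),
             stringsAsFactors = FALSE)
}
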