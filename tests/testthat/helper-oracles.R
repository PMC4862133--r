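# Brute-force oracles, deliberately independent of the package's
# implementations: per-base loops and full enumeration at tiny n.

# per-base winner-takes-all overlap assignment; returns bp claimed per
# input row (highest score, tie earlier start, tie lexicographic family)
oracle_overlap_bp <- function(ann) {
  bp <- numeric(nrow(ann))
  for (sc in unique(ann$scaffold)) {
    rows <- which(ann$scaffold == sc)
    maxend <- max(ann$end[rows])
    for (b in seq_len(maxend) - 1) {
      cov <- rows[ann$start[rows] <= b & ann$end[rows] > b]
      if (!length(cov)) next
      o <- cov[order(-ann$score[cov], ann$start[cov], ann$family[cov])]
      bp[o[1]] <- bp[o[1]] + 1
    }
  }
  bp
}

# per-base window intersection
oracle_window_bp <- function(windows, intervals) {
  te <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    for (b in seq(windows$start[i], windows$end[i] - 1)) {
      hit <- any(intervals$chrom == windows$chrom[i] &
                 intervals$start <= b & intervals$end > b)
      if (hit) te[i] <- te[i] + 1
    }
  }
  te
}

# max ECDF gap over the pooled support
oracle_ks_D <- function(a, b) {
  support <- sort(unique(c(a, b)))
  max(abs(vapply(support, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- apply(idx, 2, function(k) ustat(pooled[k], pooled[-k]))
  u_obs <- ustat(a, b)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# random annotation table on one scaffold, unique family names so rows are
# individually identifiable
random_annotations <- function(n, scaffold_len = 200, scaffold = "scf") {
  start <- sample.int(scaffold_len - 10, n, replace = TRUE) - 1
  len <- sample(3:40, n, replace = TRUE)
  data.frame(scaffold = scaffold, start = start,
             end = pmin(start + len, scaffold_len),
             strand = "+", family = sprintf("Fam%03d", seq_len(n)),
             superfamily = "Gypsy", order = "LTR",
             score = sample(250:2000, n, replace = TRUE),
             divergence = round(runif(n, 0, 30), 1),
             stringsAsFactors = FALSE)
}
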