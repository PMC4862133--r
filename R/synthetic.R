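#' Configuration for a synthetic collapse world
#'
#' Defines a small "true" genome carrying TE copies from several families,
#' an assembly-collapse plan, and a read-coverage model. Collapse emulates
#' what short-read assemblers do to near-identical repeats: of a family's
#' `n` true copies only `m` survive in the assembly, and reads from all
#' `n` copies pile onto the `m` survivors, inflating their depth in
#' proportion to the number of source copies each survivor absorbs.
#'
#' Defaults describe the world used throughout the test suite: 5 scaffolds
#' of 200 kb, six families spanning the LTR, LINE, TIR and Helitron orders
#' with within-family identities of 0.95-0.99 (recently active families —
#' the ones collapse actually hits), mean coverage 50x and 100-bp reads.
#'
#' @param seed integer RNG seed; everything downstream is deterministic
#'   given the seed.
#' @param scaffolds data frame `scaffold`, `length`.
#' @param families data frame `family`, `order`, `superfamily`,
#'   `unit_len` (>= 50 bp), `n` (true copy number), `m` (copies retained
#'   in the assembly, 1 <= m <= n), `identity` (within-family sequence
#'   identity in \[0,1\]; substitution-only divergence).
#' @param coverage mean read coverage C (x).
#' @param cov_mode `"noiseless"` (expected depth exactly) or `"poisson"`.
#' @param read_len read length in bp.
#' @param genes list `n`, `len`: background single-copy gene intervals
#'   placed in TE-free sequence (the reference-coverage features).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       scaffolds = data.frame(
                         scaffold = paste0("scf", 1:5),
                         length = rep(200000, 5),
                         stringsAsFactors = FALSE),
                       families = data.frame(
                         family = c("GypsyBz1", "CopiaBz1", "JockeyBz1",
                                    "R2Bz", "hATBz1", "ISBu1"),
                         order = c("LTR", "LTR", "LINE", "LINE", "TIR", "Helitron"),
                         superfamily = c("Gypsy", "Copia", "Jockey", "R2",
                                         "hAT", "Helitron"),
                         unit_len = c(5000, 4000, 3000, 2000, 1500, 1200),
                         n = c(8, 4, 6, 4, 10, 12),
                         m = c(2, 4, 3, 1, 5, 4),
                         identity = c(0.98, 0.95, 0.97, 0.99, 0.96, 0.98),
                         stringsAsFactors = FALSE),
                       coverage = 50, cov_mode = c("noiseless", "poisson"),
                       read_len = 100,
                       genes = list(n = 40, len = 2000)) {
  cov_mode <- match.arg(cov_mode)
  if (nrow(families)) {
    stopifnot(all(families$m >= 1), all(families$m <= families$n),
              all(families$unit_len >= 50),
              all(families$identity >= 0 & families$identity <= 1))
    if (sum(families$unit_len * families$n) >= sum(scaffolds$length))
      stop("TE plan exceeds genome: total TE bp must be below total genome bp")
  }
  stopifnot(coverage > 0, read_len >= 1)
  structure(list(seed = seed, scaffolds = scaffolds, families = families,
                 coverage = coverage, cov_mode = cov_mode,
                 read_len = read_len, genes = genes),
            class = "sim_config")
}

# place `count` non-overlapping intervals of length `len` on scaffolds,
# given existing occupancy (list of IRanges per scaffold); returns df and
# updates occupancy by reference semantics (returns both)
.place <- function(count, len, scaffolds, occupied, max_try = 5000) {
  out <- data.frame(scaffold = character(count), start = numeric(count),
                    end = numeric(count), stringsAsFactors = FALSE)
  w <- scaffolds$length / sum(scaffolds$length)
  for (i in seq_len(count)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      si <- sample.int(nrow(scaffolds), 1, prob = w)
      slen <- scaffolds$length[si]
      if (slen < len) next
      s <- sample.int(slen - len + 1, 1) - 1
      cand <- IRanges::IRanges(start = s + 1, end = s + len)
      sc <- scaffolds$scaffold[si]
      if (length(IRanges::findOverlaps(cand, occupied[[sc]])) == 0) {
        occupied[[sc]] <- c(occupied[[sc]], cand)
        out$scaffold[i] <- sc; out$start[i] <- s; out$end[i] <- s + len
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible placement: could not fit all planned intervals; ",
           "reduce copy numbers or lengths")
  }
  list(placed = out, occupied = occupied)
}

.mutate_seq <- function(consensus, identity) {
  bases <- c("A", "C", "G", "T")
  x <- strsplit(consensus, "")[[1]]
  hit <- which(stats::runif(length(x)) < (1 - identity))
  for (i in hit) x[i] <- sample(setdiff(bases, x[i]), 1)
  paste(x, collapse = "")
}

#' Build a synthetic collapse world
#'
#' Generates, deterministically from the seed: a true genome with all
#' `n` copies of each family placed without overlap (each copy mutated
#' from the family consensus at substitution rate `1 - identity`); a
#' collapsed assembly in which the last `n - m` copies of each family are
#' excised, their source reads conceptually absorbed round-robin by the
#' `m` survivors; annotations describing the collapsed assembly only (what
#' a repeat annotator would see); TE-free gene intervals present
#' identically in both genomes; and the ground truth (copy positions,
#' per-survivor multiplicity, per-category true and assembled bp).
#'
#' Substitution-only divergence keeps `true_bp = n x unit_len` and
#' `assembled_bp = m x unit_len` exact, so recovery assertions can be
#' exact.
#'
#' @param config a [sim_config()].
#' @return list with elements `config`, `true_genome` and `assembly`
#'   (named character vectors of scaffold sequences), `annotations` (TE
#'   annotation data frame on the collapsed assembly), `genes` (data frame
#'   `scaffold`, `start`, `end` on the collapsed assembly), `truth`.
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .build_world_impl(config))
}

.build_world_impl <- function(config) {
  scf <- config$scaffolds
  fam <- config$families
  occupied <- setNames(lapply(seq_len(nrow(scf)), function(i) IRanges::IRanges()),
                       scf$scaffold)
  bases <- c("A", "C", "G", "T")
  genome <- setNames(vapply(scf$length, function(l)
    paste(sample(bases, l, replace = TRUE), collapse = ""), ""), scf$scaffold)

  copies <- NULL
  if (nrow(fam)) {
    consensus <- setNames(vapply(fam$unit_len, function(l)
      paste(sample(bases, l, replace = TRUE), collapse = ""), ""), fam$family)
    copy_rows <- list()
    for (f in seq_len(nrow(fam))) {
      pl <- .place(fam$n[f], fam$unit_len[f], scf, occupied)
      occupied <- pl$occupied
      p <- pl$placed
      p$family <- fam$family[f]
      p$copy <- seq_len(nrow(p))
      copy_rows[[f]] <- p
    }
    copies <- do.call(rbind, copy_rows)
    # overlay mutated copy sequences onto the background
    for (i in seq_len(nrow(copies))) {
      fi <- match(copies$family[i], fam$family)
      seqi <- .mutate_seq(consensus[[fam$family[fi]]], fam$identity[fi])
      sc <- copies$scaffold[i]
      substr(genome[[sc]], copies$start[i] + 1, copies$end[i]) <- seqi
    }
  }

  gplan <- config$genes
  genes <- data.frame(scaffold = character(), start = numeric(), end = numeric())
  if (!is.null(gplan) && gplan$n > 0) {
    pl <- .place(gplan$n, gplan$len, scf, occupied)
    occupied <- pl$occupied
    genes <- pl$placed
    genes <- genes[order(genes$scaffold, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }

  # collapse: drop copies m+1..n of each family, excise from the assembly
  if (!is.null(copies)) {
    copies$retained <- copies$copy <= fam$m[match(copies$family, fam$family)]
    # round-robin absorption of dropped copies by the survivors
    copies$multiplicity <- NA_integer_
    for (f in seq_len(nrow(fam))) {
      m <- fam$m[f]; n <- fam$n[f]
      mult <- rep(1L, m)
      if (n > m) {
        extra <- tabulate(((seq_len(n - m) - 1) %% m) + 1, nbins = m)
        mult <- mult + extra
      }
      copies$multiplicity[copies$family == fam$family[f] & copies$retained] <- mult
    }
  }

  assembly <- genome
  shift_of <- function(sc, pos) 0
  if (!is.null(copies) && any(!copies$retained)) {
    dropped <- copies[!copies$retained, , drop = FALSE]
    for (sc in unique(dropped$scaffold)) {
      d <- dropped[dropped$scaffold == sc, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      seqv <- strsplit(assembly[[sc]], "")[[1]]
      del <- unlist(mapply(function(s, e) (s + 1):e, d$start, d$end, SIMPLIFY = FALSE))
      assembly[[sc]] <- paste(seqv[-del], collapse = "")
    }
    drop_by_scaf <- split(dropped, dropped$scaffold)
    shift_of <- function(sc, pos) {
      d <- drop_by_scaf[[sc]]
      if (is.null(d)) return(rep(0, length(pos)))
      vapply(pos, function(p) sum((d$end - d$start)[d$end <= p]), 0)
    }
  }

  ann <- empty_annotation()
  retained <- NULL
  if (!is.null(copies)) {
    retained <- copies[copies$retained, , drop = FALSE]
    if (nrow(retained)) {
      sh <- mapply(function(sc, p) shift_of(sc, p), retained$scaffold, retained$start)
      retained$asm_start <- retained$start - sh
      retained$asm_end <- retained$end - sh
      fi <- match(retained$family, fam$family)
      ann <- data.frame(scaffold = retained$scaffold,
                        start = retained$asm_start, end = retained$asm_end,
                        strand = "+", family = retained$family,
                        superfamily = fam$superfamily[fi], order = fam$order[fi],
                        score = pmax(300, fam$unit_len[fi]),
                        divergence = round((1 - fam$identity[fi]) * 100, 1),
                        stringsAsFactors = FALSE)
      ann <- ann[order(ann$scaffold, ann$start), , drop = FALSE]
      rownames(ann) <- NULL
    }
  }
  if (nrow(genes)) {
    sh <- mapply(function(sc, p) shift_of(sc, p), genes$scaffold, genes$start)
    genes$start <- genes$start - sh
    genes$end <- genes$end - sh
  }

  fam_truth <- if (nrow(fam)) {
    data.frame(family = fam$family, order = fam$order,
               superfamily = fam$superfamily, unit_len = fam$unit_len,
               n = fam$n, m = fam$m,
               true_bp = fam$n * fam$unit_len,
               assembled_bp = fam$m * fam$unit_len,
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(), order = character(),
               superfamily = character(), unit_len = numeric(),
               n = integer(), m = integer(), true_bp = numeric(),
               assembled_bp = numeric(), stringsAsFactors = FALSE)
  }
  truth <- list(
    families = fam_truth,
    true_copies = if (is.null(copies)) NULL else
      copies[, c("family", "copy", "scaffold", "start", "end", "retained")],
    retained = if (is.null(retained) || !nrow(retained)) NULL else
      data.frame(family = retained$family, scaffold = retained$scaffold,
                 start = retained$asm_start, end = retained$asm_end,
                 multiplicity = retained$multiplicity, stringsAsFactors = FALSE)
  )
  list(config = config, true_genome = genome, assembly = assembly,
       annotations = ann, genes = genes, truth = truth)
}

#' Persist a synthetic world to disk
#'
#' Writes the true genome and collapsed assembly as FASTA, annotations in
#' the RepeatMasker `.out` dialect, gene intervals as BED and the ground
#' truth as JSON. Byte-identical across runs with the same config.
#'
#' @param world output of [build_world()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(true_genome = file.path(dir, "true_genome.fasta"),
         assembly = file.path(dir, "assembly.fasta"),
         annotations = file.path(dir, "annotations.out"),
         genes = file.path(dir, "genes.bed"),
         truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(world$true_genome), p["true_genome"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(world$assembly), p["assembly"])
  write_repeatmasker_out(world$annotations, p["annotations"])
  g <- world$genes
  write.table(data.frame(g$scaffold, as.integer(g$start), as.integer(g$end)),
              p["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(world$truth, p["truth"], digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(p)
}

#' Simulate read alignments over the collapsed assembly
#'
#' Reads are conceptually drawn from the true genome at mean coverage C
#' and placed on the collapsed assembly: reads from any of a family's `n`
#' source copies align to its `m` surviving copies, so the expected depth
#' over a survivor is `C x multiplicity`, while single-copy sequence
#' (background and genes) sits at C. `"noiseless"` mode realizes the
#' expected depth exactly (reads tile each scaffold, survivors get
#' `(multiplicity - 1) x C` extra tiled reads); `"poisson"` mode draws
#' Poisson read counts with uniform placement. Extra-copy reads start
#' within the survivor's interval, so per-category read mass is preserved
#' exactly in expectation.
#'
#' The SAM and depth-TSV emissions are generated from the same read set
#' under the same derived seed and therefore agree on every fixture.
#'
#' @param world output of [build_world()].
#' @param format `"depth"` (return the depth track, optionally writing the
#'   TSV dialect) or `"sam"` (write a SAM file).
#' @param path output file (required for `"sam"`; optional TSV for
#'   `"depth"`).
#' @return the depth track (named list of integer vectors) for
#'   `"depth"`; the file path for `"sam"`.
#' @export
simulate_alignments <- function(world, format = c("depth", "sam"), path = NULL) {
  format <- match.arg(format)
  cfg <- world$config
  lens <- vapply(world$assembly, nchar, 0L)
  reads <- with_seed(cfg$seed + 1L, .simulate_reads(world, lens))
  if (format == "depth") {
    track <- .reads_to_depth(reads, lens)
    if (!is.null(path)) {
      write_depth_tsv(track, path)
      return(invisible(track))
    }
    return(track)
  }
  if (is.null(path)) path <- tempfile(fileext = ".sam")
  .write_sam(reads, lens, path)
  path
}

# read set: data.frame(scaffold, start (0-based), len)
.simulate_reads <- function(world, lens) {
  cfg <- world$config
  C <- cfg$coverage; L <- cfg$read_len
  ret <- world$truth$retained
  out <- list()
  tile <- function(sc, s, e, copies) {
    if (copies <= 0 || e <= s) return(NULL)
    starts <- seq(s, e - 1, by = L)
    rl <- pmin(L, e - starts)
    data.frame(scaffold = sc, start = rep(starts, each = copies),
               len = rep(rl, each = copies), stringsAsFactors = FALSE)
  }
  if (cfg$cov_mode == "noiseless") {
    stopifnot(C == round(C))
    for (sc in names(lens)) out[[length(out) + 1]] <- tile(sc, 0, lens[[sc]], C)
    if (!is.null(ret)) for (i in seq_len(nrow(ret))) {
      out[[length(out) + 1]] <- tile(ret$scaffold[i], ret$start[i], ret$end[i],
                                     (ret$multiplicity[i] - 1) * C)
    }
  } else {
    draw <- function(sc, s, e, mean_cov) {
      span <- e - s
      if (span <= 0 || mean_cov <= 0) return(NULL)
      rl <- min(L, span)
      n <- rpois(1, mean_cov * span / rl)
      if (n == 0) return(NULL)
      starts <- s + sample.int(span - rl + 1, n, replace = TRUE) - 1
      data.frame(scaffold = sc, start = starts, len = rl, stringsAsFactors = FALSE)
    }
    for (sc in names(lens)) out[[length(out) + 1]] <- draw(sc, 0, lens[[sc]], C)
    if (!is.null(ret)) for (i in seq_len(nrow(ret))) {
      out[[length(out) + 1]] <- draw(ret$scaffold[i], ret$start[i], ret$end[i],
                                     (ret$multiplicity[i] - 1) * C)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(scaffold = character(), start = numeric(), len = numeric()))
  do.call(rbind, out)
}

.reads_to_depth <- function(reads, lens) {
  track <- lapply(setNames(names(lens), names(lens)), function(sc) {
    r <- reads[reads$scaffold == sc, , drop = FALSE]
    if (!nrow(r)) return(integer(lens[[sc]]))
    cv <- IRanges::coverage(IRanges::IRanges(start = r$start + 1,
                                             end = r$start + r$len),
                            width = lens[[sc]])
    as.integer(cv)
  })
  structure(track, aligned_bases = sum(vapply(track, sum, 0)))
}

.write_sam <- function(reads, lens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  body <- if (nrow(reads)) {
    sprintf("r%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
            seq_len(nrow(reads)), reads$scaffold,
            as.integer(reads$start + 1), as.integer(reads$len))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Ground-truth expectation report for a synthetic world
#'
#' Per family, superfamily, order and in total: true pre-collapse bp,
#' assembled bp, and the expected correction factor
#' `true_bp / assembled_bp` — the oracle against which the coverage-based
#' correction is checked.
#'
#' @param truth the `truth` element of a [build_world()] result.
#' @return data frame `level`, `category`, `true_bp`, `assembled_bp`,
#'   `expected_factor`.
#' @export
truth_report <- function(truth) {
  f <- truth$families
  lvl <- function(level, key) {
    if (!nrow(f)) return(NULL)
    t_bp <- tapply(f$true_bp, f[[key]], sum)
    a_bp <- tapply(f$assembled_bp, f[[key]], sum)
    data.frame(level = level, category = names(t_bp),
               true_bp = as.numeric(t_bp), assembled_bp = as.numeric(a_bp),
               expected_factor = as.numeric(t_bp) / as.numeric(a_bp),
               stringsAsFactors = FALSE)
  }
  tot <- data.frame(level = "total", category = "Total",
                    true_bp = sum(f$true_bp), assembled_bp = sum(f$assembled_bp),
                    expected_factor = if (sum(f$assembled_bp) > 0)
                      sum(f$true_bp) / sum(f$assembled_bp) else NA_real_,
                    stringsAsFactors = FALSE)
  res <- rbind(lvl("family", "family"), lvl("superfamily", "superfamily"),
               lvl("order", "order"), tot)
  rownames(res) <- NULL
  res
}

#' Simulate a chromosome-scale TE annotation landscape
#'
#' Annotation-only companion to [build_world()]: TE density along
#' chromosome-ordered scaffolds is emulated at full chromosome scale
#' without generating sequence, which the window/region analysis never
#' needs. TE intervals are dropped into consecutive 2-kb slots with
#' binomial bp counts at a region-dependent rate: a flat background over
#' the chromosome arms, an enriched pericentromeric band over the
#' `proximal_span` bp nearest the centromere of each major chromosome, and
#' a dense dot chromosome. The default rates (5 %, 16 %, 41 %) mirror the
#' pericentromeric accumulation and dot-chromosome saturation observed in
#' repleta-group genomes.
#'
#' @param seed RNG seed.
#' @param chrom_map chromosome map; default [repleta_like_map()].
#' @param densities list `background`, `proximal`, `dot` of target TE
#'   fractions.
#' @param proximal_span proximal band width in bp (default 3 Mb).
#' @param dot_chrom dot chromosome label (default `"6"`).
#' @param slot slot width in bp.
#' @return list `chrom_map`, `annotations` (scaffold coordinates).
#' @export
simulate_te_landscape <- function(seed = 1, chrom_map = repleta_like_map(),
                                  densities = list(background = 0.05,
                                                   proximal = 0.16,
                                                   dot = 0.41),
                                  proximal_span = 3e6, dot_chrom = "6",
                                  slot = 2000) {
  chrom_map <- validate_chrom_map(chrom_map)
  cl <- chrom_lengths(chrom_map)
  ann <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(chrom_map)), function(i) {
      sc <- chrom_map$scaffold[i]; ch <- chrom_map$chrom[i]
      len <- chrom_map$length[i]; off <- chrom_map$offset[i]
      nslot <- floor(len / slot)
      if (nslot == 0) return(NULL)
      starts <- (seq_len(nslot) - 1) * slot
      chrom_pos <- off + starts          # forward orientation assumed here
      rate <- if (ch %in% dot_chrom) rep(densities$dot, nslot) else
        ifelse(chrom_pos >= cl[[ch]] - proximal_span,
               densities$proximal, densities$background)
      te_len <- rbinom(nslot, slot, rate)
      keep <- te_len > 0
      if (!any(keep)) return(NULL)
      data.frame(scaffold = sc, start = starts[keep],
                 end = starts[keep] + te_len[keep], strand = "+",
                 family = "ISBu1", superfamily = "Helitron",
                 order = "Helitron", score = 1000, divergence = 10,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(ann) <- NULL
  list(chrom_map = chrom_map, annotations = ann)
}

#' A repleta-group-like chromosome map
#'
#' Five major chromosomes (X, 2-5) of 23-27 Mb split into 2-3 mapped
#' scaffolds each, plus a 1.5-Mb dot chromosome — the scale of the mapped
#' N90 scaffold set of a repleta-group assembly.
#'
#' @return chromosome map data frame.
#' @export
repleta_like_map <- function() {
  m <- data.frame(
    scaffold = c("sX1", "sX2", "sX3", "s21", "s22", "s23", "s31", "s32",
                 "s33", "s41", "s42", "s51", "s52", "s61"),
    chrom = c("X", "X", "X", "2", "2", "2", "3", "3", "3", "4", "4",
              "5", "5", "6"),
    index = c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 1, 2, 1),
    orientation = "forward",
    length = c(10e6, 9e6, 8e6, 10e6, 9e6, 7e6, 9e6, 8e6, 8e6, 12e6, 11e6,
               13e6, 11e6, 1.5e6),
    stringsAsFactors = FALSE)
  validate_chrom_map(m)
}
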