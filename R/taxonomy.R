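#' TE taxonomy: family -> (order, superfamily)
#'
#' A taxonomy is a data frame with columns `family`, `superfamily`, `order`
#' mapping repeat (family) names to the Wicker hierarchy. Lookups through
#' [classify()] are total: any name the table does not cover resolves to
#' `("Unknown", "Unknown")`.
#'
#' The default table ships as an editable TSV
#' (`system.file("extdata", "te_taxonomy.tsv", package = "tecensus")`) and
#' covers the superfamilies of the five canonical orders — LTR
#' retrotransposons (BelPao, Copia, ERVK, Gypsy), LINEs (CR1, I, Jockey,
#' L1, L2, LOA, R1, R2, R4, RTE), TIR transposons (hAT, Mutator, Novosib,
#' P, PIF/Harbinger, piggyBack, Tc1/mariner, Transib, TIR other),
#' Helitrons and Mavericks — plus common RepeatMasker aliases (e.g. Pao,
#' TcMar, Polinton) and a small set of non-core classes routed to the
#' "Others" order.
#'
#' @param path TSV with columns family, superfamily, order.
#' @return data frame with columns `family`, `superfamily`, `order`.
#' @export
read_taxonomy <- function(path) {
  tax <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("family", "superfamily", "order")
  if (!all(need %in% names(tax)))
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tax$order), TE_ORDERS)
  if (length(bad))
    stop("taxonomy contains orders outside the recognized set: ", paste(bad, collapse = ", "))
  # every superfamily must map to exactly one order
  per_sf <- tapply(tax$order, tax$superfamily, function(o) length(unique(o)))
  if (any(per_sf > 1))
    stop("superfamilies mapped to more than one order: ",
         paste(names(per_sf)[per_sf > 1], collapse = ", "))
  tax
}

#' @rdname read_taxonomy
#' @export
default_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "te_taxonomy.tsv", package = "tecensus"))
}

# RepeatMasker class aliases seen in the "class/family" column
.class_alias <- c(LTR = "LTR", LINE = "LINE", DNA = "TIR", TIR = "TIR",
                  RC = "Helitron", Helitron = "Helitron",
                  Maverick = "Maverick", Polinton = "Maverick",
                  SINE = "Others", DIRS = "Others", PLE = "Others",
                  Penelope = "Others", Crypton = "Others")

#' Classify a repeat name into (order, superfamily)
#'
#' Resolution is exact-name lookup in the taxonomy first, then the
#' RepeatMasker `class/family` string convention (`"LTR/Gypsy"`,
#' `"DNA/TcMar-Tc1"`): the part after `/` is looked up as a superfamily
#' (hyphenated subfamily suffixes and trailing `?` stripped), and the part
#' before `/` maps the order when the superfamily is unknown. Names that
#' resolve nowhere fall back to `("Unknown", "Unknown")` — the function is
#' total and never errors.
#'
#' @param family character vector of repeat or class/family names.
#' @param taxonomy taxonomy data frame (default [default_taxonomy()]).
#' @return data frame with columns `order`, `superfamily`, one row per input.
#' @examples
#' classify(c("Gypsy", "LTR/Gypsy", "Helitron", "TotallyNovelRepeat"))
#' @export
classify <- function(family, taxonomy = default_taxonomy()) {
  lookup <- function(name) {
    name <- sub("\\?$", "", name)
    i <- match(name, taxonomy$family)
    if (!is.na(i)) return(c(taxonomy$order[i], taxonomy$superfamily[i]))
    # strip hyphenated subfamily suffix: "TcMar-Tc1" -> "TcMar"
    base <- sub("-.*$", "", name)
    i <- match(base, taxonomy$family)
    if (!is.na(i)) return(c(taxonomy$order[i], taxonomy$superfamily[i]))
    if (grepl("/", name, fixed = TRUE)) {
      parts <- strsplit(name, "/", fixed = TRUE)[[1]]
      p1 <- parts[1]; p2 <- paste(parts[-1], collapse = "/")
      # either side may carry the superfamily ("LTR/Gypsy" or "Gypsy/LTR")
      h2 <- lookup(p2)
      if (h2[2] != "Unknown") return(h2)
      h1 <- lookup(p1)
      if (h1[2] != "Unknown") return(h1)
      if (h2[1] != "Unknown") return(c(h2[1], "Unknown"))
      if (h1[1] != "Unknown") return(c(h1[1], "Unknown"))
    } else {
      ord <- .class_alias[name]
      if (!is.na(ord)) return(c(unname(ord), "Unknown"))
    }
    c("Unknown", "Unknown")
  }
  res <- t(vapply(as.character(family), lookup, character(2)))
  data.frame(order = res[, 1], superfamily = res[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}
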