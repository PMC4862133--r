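# in-code fixtures: a hand-written RepeatMasker .out file and a tiny SAM

rm_out_header <- c(
  "   SW   perc perc perc  query      position in query           matching repeat       position in  repeat",
  "score   div. del. ins.  sequence   begin end          (left)   repeat   class/family begin end (left) ID",
  "")

write_rm_fixture <- function(records, path = tempfile(fileext = ".out")) {
  writeLines(c(rm_out_header, records), path)
  path
}

# the canonical single-record fixture: scaf1 101..200 (1-based inclusive),
# Gypsy LTR element, score 1306
rm_record_gypsy <- "1306 15.6 4.3 1.2 scaf1 101 200 (4800) + FamA Gypsy/LTR 1 100 (0) 1"

write_sam_fixture <- function(records, sq, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  writeLines(c(hdr, records), path)
  path
}

sam_line <- function(qname, rname, pos1, cigar, flag = 0, mapq = 60) {
  paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, "*", "*", sep = "\t")
}

tiny_world_config <- function(seed = 3, cov_mode = "noiseless") {
  sim_config(
    seed = seed,
    scaffolds = data.frame(scaffold = c("s1", "s2"),
                           length = c(20000, 15000),
                           stringsAsFactors = FALSE),
    families = data.frame(family = c("FamA", "FamB"),
                          order = c("LTR", "Helitron"),
                          superfamily = c("Gypsy", "Helitron"),
                          unit_len = c(1000, 600), n = c(4, 3), m = c(1, 3),
                          identity = c(0.98, 0.95), stringsAsFactors = FALSE),
    coverage = 5, cov_mode = cov_mode, read_len = 50,
    genes = list(n = 5, len = 500))
}
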