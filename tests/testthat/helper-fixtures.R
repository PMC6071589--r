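# Shared fixtures, all built in code.

rc <- function(x) dualguide:::.revcomp(x)

# Reference with two distinct planted protospacer+PAM motifs on the + strand.
# Guide A occupies [10, 30) with PAM [30, 33) (cut 27); guide B starts at
# `b_start` (cut = b_start + 20 - 3). Filler is repeat-poor pyrimidine text.
two_guide_ref <- function(b_start = 110) {
  proto_a <- "GACTACGTACGATCAGGCTA"
  proto_b <- "TGCAAGGTCATCAGTACGAT"
  filler <- function(n) {
    paste(rep_len(strsplit("CTCTTCCCTT", "")[[1]], n), collapse = "")
  }
  stopifnot(b_start >= 33 + 1)
  ref <- paste0(filler(10), proto_a, "AGG", filler(b_start - 33), proto_b,
                "TGG", filler(40))
  list(ref = ref,
       guide_a = guide_rna("gA", proto_a, "AGG"),
       guide_b = guide_rna("gB", proto_b, "TGG"),
       cut_a = 27L, cut_b = b_start + 20L - 3L)
}

random_ref <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  random_dna(n)
}

# loop-out SD-MMEJ fixture: P1 "GGAC" at [5, 9), template (insert + terminal
# microhomology base "A") directly 3' of it, P2 "GGAC" break-proximal, the
# microhomology counterpart "A" immediately right of the junction.
loopout_fixture <- function(insert = "CTTG") {
  tmpl <- paste0(insert, "A")
  ref <- paste0("CCTTC", "GGAC", tmpl, "TT", "GGAC", "ACCTCCATG")
  cut <- 5L + 4L + nchar(tmpl) + 2L + 4L
  list(ref = ref, cut = cut,
       junction = repair_junction(ref, cut, cut, cut, insert))
}

# decomposition result with an arbitrary spectrum (for threshold-logic tests)
fake_result <- function(spectrum) {
  structure(list(spectrum = spectrum,
                 efficiency = 1 - ifelse("0" %in% names(spectrum),
                                         spectrum[["0"]], 0),
                 r_squared = 1, degenerate = FALSE,
                 config = decomposition_config()),
            class = "decomposition_result")
}

# noiseless trace for a set of (indel alleles, frequencies) on a reference
mixture_trace <- function(ref, cut, alleles, freqs, window = NULL) {
  if (is.null(window)) window <- c(max(0L, cut - 60L), min(nchar(ref), cut + 170L))
  pl <- plant_sample(alleles, freqs)
  synthesize_trace(pl, ref, window, noise_sd = 0)
}

# deletion allele of size k spanning the cut
del_allele <- function(cut, k, left = floor(k / 2)) {
  dualguide:::.allele("ref", cut - left, cut - left + k, "",
                      paste0("d", k))
}

ins_allele <- function(ref, cut, k) {
  # duplicate the k bases 5' of the cut (templated, keeps alphabet realistic)
  ins <- substr(ref, cut - k + 1L, cut)
  dualguide:::.allele("ref", cut, cut, ins, paste0("i", k))
}
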