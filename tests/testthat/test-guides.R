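test_that("guide types follow the position of the starting guanine", {
  # 20 nt starting with G, spacer identical
  expect_equal(classify_guide_type("GGGACTGTTAAGTGCAAGCT",
                                   "GGGACTGTTAAGTGCAAGCT"),
               "GN19_starts_with_G")
  # 20 nt with an extra transcribed G
  expect_equal(classify_guide_type("GTATTGCAGAGAGCCTAAAGA",
                                   "TATTGCAGAGAGCCTAAAGA"),
               "GN20_extra_G")
  # truncated guide, 19 nt protospacer starting with G
  expect_equal(classify_guide_type("GATGAGGAGATATTATCTG",
                                   "GATGAGGAGATATTATCTG"),
               "GN18_tru")
  expect_error(classify_guide_type("AGGACTGTTAAGTGCAAGCT",
                                   "AGGACTGTTAAGTGCAAGCT"),
               "guide type")
})

test_that("the bundled guide table parses and types match its labels", {
  g <- bundled_guides()
  expect_equal(nrow(g$table), 13L)
  map <- c("G-N18" = "GN18_tru", "G-N19" = "GN19_starts_with_G",
           "G-N20" = "GN20_extra_G")
  for (i in seq_len(nrow(g$table))) {
    expect_equal(g$guides[[i]]$guide_type,
                 unname(map[g$table$guide_class[i]]),
                 info = g$table$name[i])
  }
  expect_true(all(grepl("^[ACGT]GG$", g$table$pam)))
})

test_that("protospacer localisation finds exact matches with PAM on both strands", {
  g <- bundled_guides()$guides[["GLB3-3"]]
  ref <- paste0("CCTTCCTTCC", g$protospacer, g$pam, "TTCCTTCCTT")
  hits <- find_protospacer(ref, g)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$strand, "+")
  expect_equal(hits[[1]]$protospacer_start, 10L)

  hits_rc <- find_protospacer(rc(ref), g)
  expect_length(hits_rc, 1L)
  expect_equal(hits_rc[[1]]$strand, "-")

  expect_length(find_protospacer("CCTTCCTTCCTTCCTTCCTTCCTTCC", g), 0L)
  expect_error(find_protospacer("ACGTX", g), "alphabet")
})

test_that("cut sites sit 3 nt 5' of the PAM on the protospacer strand", {
  fx <- two_guide_ref()
  site_a <- find_protospacer(fx$ref, fx$guide_a)[[1]]
  expect_equal(site_a$protospacer_start, 10L)
  expect_equal(site_a$pam_start, 30L)
  expect_equal(cut_site(site_a), 27L)

  # same motif on the - strand with PAM at [7, 10) on +: cut = pam_end + 3
  ref_minus <- paste0("CTCTTCC", rc(paste0(fx$guide_a$protospacer, "AGG")),
                      "CTCTTCCCTT")
  site_m <- find_protospacer(ref_minus, fx$guide_a)[[1]]
  expect_equal(site_m$strand, "-")
  expect_equal(site_m$pam_start, 7L)
  expect_equal(cut_site(site_m), 13L)

  # truncated 19-nt protospacer: cut still pam_start - 3 (+ strand)
  tru <- guide_rna("tru", "GATGAGGAGATATTATCTG", "AGG")
  ref_t <- paste0("CTCTTCCCTT", tru$protospacer, "AGG", "CTCTTCC")
  site_t <- find_protospacer(ref_t, tru)[[1]]
  expect_equal(site_t$pam_start, 10L + 19L)
  expect_equal(cut_site(site_t), 10L + 19L - 3L)
})

test_that("localisation mirrors exactly under reverse complementation", {
  set.seed(101)
  g <- bundled_guides()$guides[["VQ19-6"]]
  for (i in 1:10) {
    ref <- paste0(random_dna(60), g$protospacer, g$pam, random_dna(60))
    L <- nchar(ref)
    h <- find_protospacer(ref, g)
    h_rc <- find_protospacer(rc(ref), g)
    expect_length(h_rc, length(h))
    if (length(h) == 1L && length(h_rc) == 1L) {
      expect_equal(h_rc[[1]]$strand, setdiff(c("+", "-"), h[[1]]$strand))
      expect_equal(h_rc[[1]]$cut, L - h[[1]]$cut)
      # reference substring equals the protospacer, strand-adjusted
      plen <- nchar(g$protospacer)
      seen <- substr(ref, h[[1]]$protospacer_start + 1L,
                     h[[1]]$protospacer_start + plen)
      if (h[[1]]$strand == "-") seen <- rc(seen)
      expect_equal(seen, g$protospacer)
    }
  }
})

test_that("dual-guide deletion prediction is cut-to-cut, symmetric, frame-aware", {
  fx <- two_guide_ref(110)  # cuts 27 and 127
  sa <- find_protospacer(fx$ref, fx$guide_a)[[1]]
  sb <- find_protospacer(fx$ref, fx$guide_b)[[1]]
  pred <- predict_dual_deletion(sa, sb)
  expect_equal(pred$length, 100L)
  expect_equal(pred$interval, c(27L, 127L))
  expect_equal(pred$frame_shift, "frameshift")  # 100 %% 3 == 1

  sym <- predict_dual_deletion(sb, sa)
  expect_equal(sym$length, pred$length)
  expect_equal(sym$interval, pred$interval)

  fx2 <- two_guide_ref(256)  # cuts 27 and 273 -> 246, in frame
  sa2 <- find_protospacer(fx2$ref, fx2$guide_a)[[1]]
  sb2 <- find_protospacer(fx2$ref, fx2$guide_b)[[1]]
  pred2 <- predict_dual_deletion(sa2, sb2)
  expect_equal(pred2$length, 246L)
  expect_equal(pred2$frame_shift, "in_frame")

  expect_error(predict_dual_deletion(sa, sa), "coincide")
  sb_other <- find_protospacer(fx$ref, fx$guide_b, "other")[[1]]
  expect_error(predict_dual_deletion(sa, sb_other), "different references")
})

test_that("guide invariants are enforced at construction", {
  expect_error(guide_rna("x", "GACTACGTACGATCAGGCTA", "ATT"), "NGG")
  expect_error(guide_rna("x", "GACTACGTACG", "AGG"), "18-20")
  g <- guide_rna("x", "GACTACGTACGATCAGGCTA", "NGG")
  expect_equal(g$guide_type, "GN19_starts_with_G")
})
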