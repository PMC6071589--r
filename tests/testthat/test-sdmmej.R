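test_that("a planted loop-out primer repeat is recovered with the printed arithmetic", {
  # p = 4, insert = 4, mh = 1 -> diagnostic direct repeat of 9 bp
  fx <- loopout_fixture("CTTG")
  mechs <- enumerate_sdmmej(fx$junction)
  expect_gt(length(mechs), 0L)
  hit <- Filter(function(m) {
    m$class == "SDMMEJ_loopout" && m$p_len == 4L && m$mh_len == 1L &&
      nchar(m$insertion) == 4L
  }, mechs)
  expect_gte(length(hit), 1L)
  m <- hit[[1]]
  expect_equal(m$repeat_len, 9L)
  expect_equal(nchar(m$elongation), 5L)  # insert + mh
  expect_equal(m$repeat_type, "direct")
  expect_equal(mechanism_product(m, fx$ref), junction_product(fx$junction))

  # p = 4, insert = 2, mh = 1 -> repeat 7, elongation 3
  fx2 <- loopout_fixture("TG")
  hit2 <- Filter(function(m) {
    m$class == "SDMMEJ_loopout" && m$p_len == 4L && m$mh_len == 1L &&
      nchar(m$insertion) == 2L
  }, enumerate_sdmmej(fx2$junction))
  expect_gte(length(hit2), 1L)
  expect_equal(hit2[[1]]$repeat_len, 7L)
  expect_equal(nchar(hit2[[1]]$elongation), 3L)
})

test_that("repeat and elongation arithmetic holds for every reported mechanism", {
  set.seed(201)
  checked <- 0L
  for (i in 1:8) {
    R <- random_dna(90)
    cut <- 45L
    al <- tryCatch(
      simulate_repair_allele(R, cut, sample(c("SDMMEJ_loopout",
                                              "SDMMEJ_snapback"), 1)),
      dualguide_mechanism_unavailable = function(e) NULL)
    if (is.null(al)) next
    j <- as_repair_junction(al, R, cut)
    mechs <- enumerate_sdmmej(j, max_resect = 12)
    expect_gt(length(mechs), 0L)
    for (m in mechs) {
      expect_equal(m$repeat_len, m$mh_len + nchar(m$insertion) + m$p_len)
      expect_equal(nchar(m$elongation), nchar(m$insertion) + m$mh_len)
      # soundness: every mechanism reconstructs the observed product
      expect_equal(mechanism_product(m, R), junction_product(j))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("classification cascade: +1 is cNHEJ, mh-flanked deletion is MMEJ", {
  R <- random_ref(80, 31)
  cut <- 40L
  plus1 <- as_repair_junction(simulate_repair_allele(R, cut, "cNHEJ_plus1"),
                              R, cut)
  expect_equal(classify_junction(plus1)$top_class, "cNHEJ_consistent")

  # 10-bp deletion flanked by a >= 2 bp microhomology (planted "CAGT" pair)
  R2 <- paste0("CTCTTCCCTTCTCTTCCCTTCA", "GT", "CTTCCCTA", "GT",
               "ACCTCCATGACCTCC")
  j_mmej <- repair_junction(R2, 28, 24, 34)
  expect_gte(flanking_microhomology(j_mmej)$length, 2L)
  expect_equal(classify_junction(j_mmej)$top_class, "MMEJ")

  # small deletion without informative microhomology stays cNHEJ-consistent
  j_plain <- repair_junction(paste0("CTCTTCCCTT", "AGCAG", "CCTTGGCCTT"),
                             12, 10, 15)
  expect_equal(flanking_microhomology(j_plain)$length, 0L)
  expect_equal(classify_junction(j_plain)$top_class, "cNHEJ_consistent")
})

test_that("a deletion with templated insertion classifies as loop-out SD-MMEJ", {
  # 30-bp deletion combined with a 2-bp templated insertion (p=4, mh=1)
  del30 <- "TTCCTTCATTCCTTCATTCCTTCATTCCTT"
  ref <- paste0("CCTTC", "GGAC", "TGA", "CTCT", "GGAC", del30, "A",
                "CCTCCATG")
  j <- repair_junction(ref, 30, 20, 50, "TG")
  expect_equal(j$del_end - j$del_start, 30L)
  rep_ <- classify_junction(j)
  expect_equal(rep_$top_class, "SDMMEJ_loopout")
  expect_true(any(vapply(rep_$mechanisms, function(m) {
    m$repeat_len == 7L && m$p_len == 4L
  }, logical(1))))
})

test_that("insertions with no mechanism are unexplained; substitutions are posed as del+ins", {
  # repeat-poor reference, arbitrary non-templated insert
  R <- "CCTTAGCATCGGATCCGTAA"
  j <- repair_junction(R, 10, 8, 13, "AAAA")
  rep_ <- classify_junction(j)
  if (length(rep_$mechanisms) == 0L) {
    expect_equal(rep_$top_class, "unexplained")
  } else {
    expect_true(startsWith(rep_$top_class, "SDMMEJ"))
  }
  # 1-bp substitution = del 1 + ins 1
  j_sub <- repair_junction(R, 10, 9, 10, "A")
  expect_equal(indel_size(j_sub), 0L)
  expect_true(classify_junction(j_sub)$top_class %in%
                c("unexplained", "SDMMEJ_loopout", "SDMMEJ_snapback"))
})

test_that("classification is invariant under reverse-complementing the problem", {
  set.seed(55)
  for (i in 1:6) {
    R <- random_dna(80)
    cut <- 40L
    s <- cut - sample(0:6, 1)
    e <- cut + sample(0:6, 1)
    ins <- if (runif(1) < 0.6) random_dna(sample(1:3, 1)) else ""
    j <- repair_junction(R, cut, s, e, ins)
    if (junction_product(j) == R) next
    a <- classify_junction(j)
    b <- classify_junction(revcomp_junction(j))
    expect_equal(a$top_class, b$top_class)
    expect_equal(length(a$mechanisms), length(b$mechanisms))
    expect_equal(a$flanking_mh_len, b$flanking_mh_len)
  }
})

test_that("enumerator and forward oracle agree on small references", {
  set.seed(91)
  for (i in 1:5) {
    R <- random_dna(60)
    cut <- 30L
    orc <- sdmmej_oracle(R, cut, W = 20, p_max = 4, elong_max = 6,
                         max_resect = 5)
    # completeness: oracle products re-posed as junctions have a mechanism
    idx <- sample(seq_along(orc$events), min(10L, length(orc$events)))
    for (k in idx) {
      ev <- orc$events[[k]]
      j <- repair_junction(R, cut, ev$s, ev$e, ev$ins)
      m <- enumerate_sdmmej(j, W = 20, p_max = 4, max_elong = 6,
                            max_resect = 5, first_only = TRUE)
      expect_gte(length(m), 1L)
    }
    # soundness/equivalence on random junctions
    for (k in 1:8) {
      s <- cut - sample(0:4, 1)
      e <- cut + sample(0:4, 1)
      ins <- if (runif(1) < 0.5) random_dna(sample(1:2, 1)) else ""
      j <- repair_junction(R, cut, s, e, ins)
      if (junction_product(j) == R) next
      m <- enumerate_sdmmej(j, W = 20, p_max = 4, max_elong = 6,
                            max_resect = 5, first_only = TRUE)
      expect_equal(length(m) > 0L, junction_product(j) %in% orc$products)
    }
  }
})

test_that("the oracle refuses oversized references", {
  expect_error(sdmmej_oracle(random_ref(300, 1), 150), "refuses")
})
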