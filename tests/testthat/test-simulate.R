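test_that("+1 repair duplicates the base immediately 5' of the cut", {
  R <- random_ref(100, 1)
  for (cut in c(20L, 50L, 80L)) {
    al <- simulate_repair_allele(R, cut, "cNHEJ_plus1")
    expect_equal(al$del_start, cut)
    expect_equal(al$del_end, cut)
    expect_equal(al$insertion, substr(R, cut, cut))
    expect_equal(al$indel_size, 1L)
  }
})

test_that("cNHEJ deletions span the cut with truncated-geometric sizes", {
  set.seed(2)
  R <- random_dna(200)
  sizes <- integer(300)
  for (i in seq_along(sizes)) {
    al <- simulate_repair_allele(R, 100L, "cNHEJ_del")
    expect_lte(al$del_start, 100L)
    expect_gte(al$del_end, 100L)
    expect_equal(al$insertion, "")
    sizes[i] <- al$del_end - al$del_start
  }
  expect_true(all(sizes >= 1 & sizes <= 50))
  # mean of the truncated geometric (mean 3, max 50) is ~3
  expect_lt(abs(mean(sizes) - 3), 0.6)
})

test_that("MMEJ uses a planted microhomology pair or fails loudly", {
  set.seed(3)
  R <- paste0(random_dna(40), "CTA", random_dna(10), "CTA", random_dna(40))
  cfg <- sim_config(mmej_mh_min = 3)
  al <- simulate_repair_allele(R, 47L, "MMEJ", cfg)
  j <- as_repair_junction(al, R, 47L)
  expect_gte(flanking_microhomology(j)$length, 3L)
  expect_gte(al$truth_mechanism$mh_len, 3L)

  # no long microhomology on a short random reference
  set.seed(4)
  R2 <- random_dna(60)
  expect_error(
    simulate_repair_allele(R2, 30L, "MMEJ", sim_config(mmej_mh_min = 8)),
    class = "dualguide_mechanism_unavailable")
})

test_that("forward-simulated SD-MMEJ alleles carry consistent ground truth", {
  set.seed(6)
  n_ok <- 0L
  for (i in 1:10) {
    R <- random_dna(100)
    al <- tryCatch(simulate_repair_allele(R, 50L, "SDMMEJ_loopout"),
                   dualguide_mechanism_unavailable = function(e) NULL)
    if (is.null(al)) next
    tr <- al$truth_mechanism
    expect_equal(tr$repeat_len, tr$p_len + tr$insert_len + tr$mh_len)
    expect_gte(nchar(al$insertion), 1L)
    expect_gt(al$del_end - al$del_start, nchar(al$insertion))
    n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 5L)
})

test_that("T1 plants have WT, unit-sum frequencies and recorded efficiency", {
  set.seed(8)
  R <- random_dna(400)
  for (i in 1:25) {
    pl <- simulate_t1_plant(R, 200L)
    expect_equal(sum(pl$frequencies), 1, tolerance = 1e-9)
    expect_true(all(pl$frequencies >= 0))
    labs <- vapply(pl$alleles, function(a) a$label, character(1))
    expect_true("WT" %in% labs)
    wt_f <- pl$frequencies[labs == "WT"]
    expect_equal(pl$true_efficiency, 1 - sum(wt_f), tolerance = 1e-12)
    expect_lte(length(pl$alleles), sim_config()$max_alleles)
  }
})

test_that("forced compositions give the expected efficiency", {
  R <- random_ref(300, 9)
  wt_only <- simulate_t1_plant(R, 150L, sim_config(allele_lambda = 0))
  expect_equal(wt_only$true_efficiency, 0)

  half <- plant_sample(list(wt_allele("ref", 150L),
                            simulate_repair_allele(R, 150L, "cNHEJ_plus1")),
                       c(0.5, 0.5))
  expect_equal(half$true_efficiency, 0.5)
})

test_that("mean allele count matches the configured truncated Poisson", {
  set.seed(10)
  R <- random_dna(300)
  cfg <- sim_config()
  n <- 400L
  counts <- replicate(n, length(simulate_t1_plant(R, 150L, cfg)$alleles))
  # analytic expectation of min(1 + Pois(lambda), max) is an upper bound;
  # merging identical repair products (all +1 duplications coincide, small
  # deletions often do) pulls the realised count about one allele below it
  k <- 0:30
  expected <- sum(pmin(1 + k, cfg$max_alleles) * dpois(k, cfg$allele_lambda))
  expect_lt(mean(counts), expected + 0.05)
  expect_gt(mean(counts), expected - 1.3)
  # no mutant draws -> exactly the wild-type allele
  expect_equal(length(simulate_t1_plant(R, 150L,
                                        sim_config(allele_lambda = 0))$alleles),
               1L)
})

test_that("noiseless traces are exact frequency-weighted indicator mixtures", {
  R <- random_ref(300, 12)
  cut <- 150L
  pl <- plant_sample(list(wt_allele("ref", cut),
                          simulate_repair_allele(R, cut, "cNHEJ_plus1")),
                     c(0.5, 0.5))
  tr <- synthesize_trace(pl, R, c(100, 280), noise_sd = 0)
  expect_true(all(tr$heights >= 0))
  expect_equal(dim(tr$heights), c(180L, 4L))
  for (i in seq_len(nrow(tr$heights))) {
    h <- sort(tr$heights[i, tr$heights[i, ] > 0])
    expect_true(isTRUE(all.equal(unname(h), c(0.5, 0.5))) ||
                  isTRUE(all.equal(unname(h), 1)))
  }
  # single WT allele, zero noise: one unit channel per row, matching R
  tw <- synthesize_trace(plant_sample(list(wt_allele("ref", cut)), 1),
                         R, c(0, 300), noise_sd = 0)
  expect_equal(rowSums(tw$heights), rep(1, 300))
  hit <- apply(tw$heights, 1L, function(r) c("A", "C", "G", "T")[r == 1])
  expect_equal(paste(hit, collapse = ""), R)

  expect_error(synthesize_trace(pl, R, c(250, 350)), "window")
})

test_that("T2 families segregate 3:1 for resistance and 1:2:1 at the target", {
  set.seed(13)
  n <- 10000L
  t2 <- simulate_t2_population(c("WT", "mut"), n)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(!t2$resistant) - 0.25), 3 * se)
  null_seg <- t2[!t2$resistant, ]
  tab <- table(factor(null_seg$zygosity, levels = c("WT", "het", "hom")))
  expect_gt(stats::chisq.test(tab, p = c(1, 2, 1) / 4)$p.value, 0.001)
  # homozygous germline transmits only homozygous mutants
  t2h <- simulate_t2_population("mut/mut", 500L)
  expect_true(all(t2h$zygosity == "hom"))
  # two different mutant alleles: 1:2:1 hom/biallelic/hom
  t2b <- simulate_t2_population(c("m1", "m2"), 4000L)
  expect_lt(abs(mean(t2b$zygosity == "biallelic") - 0.5), 0.04)
})
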