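test_that("candidate templates are the shifted reference indicators", {
  R <- random_ref(400, 21)
  cut <- 150L
  cfg <- decomposition_config(max_indel = 10, window_len = 40)
  M <- build_candidate_matrix(R, cut, cfg)
  expect_equal(dim(M), c(160L, 21L))
  w0 <- cut + cfg$window_offset
  base_idx <- c(A = 1, C = 2, G = 3, T = 4)
  ind <- function(shift) {
    v <- numeric(4 * cfg$window_len)
    for (i in seq_len(cfg$window_len)) {
      b <- substr(R, w0 + i - shift, w0 + i - shift)
      v[(i - 1) * 4 + base_idx[[b]]] <- 1
    }
    v
  }
  expect_equal(unname(M[, "0"]), ind(0))   # k = 0: the reference itself
  expect_equal(unname(M[, "-2"]), ind(-2)) # k = -2: reference advanced by 2
  # inserted-base rows of a k = +8 template are uniform 0.25
  k8 <- M[, "8"]
  n_unknown <- 8L - cfg$window_offset
  expect_true(all(k8[seq_len(4 * n_unknown)] == 0.25))

  # distinct shifts over a non-repetitive window are linearly independent
  expect_equal(qr(M)$rank, ncol(M))

  expect_error(build_candidate_matrix(R, 380L, cfg), "window")
})

test_that("noiseless mixtures are recovered exactly", {
  R <- random_ref(400, 22)
  cut <- 150L
  # pure wild type
  res <- decompose_trace(mixture_trace(R, cut, list(wt_allele("ref", cut)), 1),
                         R, cut)
  expect_equal(unname(res$spectrum), 1)
  expect_equal(names(res$spectrum), "0")
  expect_equal(res$efficiency, 0)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)

  # 50/50 WT and +1
  res2 <- decompose_trace(
    mixture_trace(R, cut, list(wt_allele("ref", cut), ins_allele(R, cut, 1)),
                  c(0.5, 0.5)), R, cut)
  expect_equal(spectrum_frequency(res2, 0), 0.5, tolerance = 1e-6)
  expect_equal(spectrum_frequency(res2, 1), 0.5, tolerance = 1e-6)
  expect_equal(res2$efficiency, 0.5, tolerance = 1e-6)

  # 0.4 / 0.35 / 0.25 of {0, -10, +1}
  res3 <- decompose_trace(
    mixture_trace(R, cut, list(wt_allele("ref", cut), del_allele(cut, 10),
                               ins_allele(R, cut, 1)),
                  c(0.4, 0.35, 0.25)), R, cut)
  expect_lt(abs(spectrum_frequency(res3, 0) - 0.4), 1e-3)
  expect_lt(abs(spectrum_frequency(res3, -10) - 0.35), 1e-3)
  expect_lt(abs(spectrum_frequency(res3, 1) - 0.25), 1e-3)
})

test_that("spectra are normalised, bounded by K, and efficiency is monotone", {
  set.seed(23)
  R <- random_dna(400)
  cut <- 150L
  effs <- numeric(0)
  for (f in seq(0.1, 0.9, by = 0.2)) {
    res <- decompose_trace(
      mixture_trace(R, cut, list(wt_allele("ref", cut), del_allele(cut, 7)),
                    c(1 - f, f)), R, cut)
    expect_equal(sum(res$spectrum), 1, tolerance = 1e-6)
    expect_true(all(abs(as.integer(names(res$spectrum))) <= 50))
    effs <- c(effs, res$efficiency)
  }
  expect_true(all(diff(effs) > 0))
})

test_that("degenerate and uncovered traces are rejected", {
  R <- random_ref(400, 24)
  tr0 <- trace_matrix(matrix(0, nrow = 300, ncol = 4), start = 0L)
  expect_error(decompose_trace(tr0, R, 150L), "all-zero")
  short <- trace_matrix(matrix(1, nrow = 20, ncol = 4), start = 0L)
  expect_error(decompose_trace(short, R, 150L), "cover")
})

test_that("random multi-allele noiseless mixtures round-trip within 1e-3", {
  set.seed(25)
  R <- random_dna(420)
  cut <- 160L
  for (rep in 1:5) {
    sizes <- sample(c(-30:-1, 1:4), sample(2:4, 1))
    alleles <- c(list(wt_allele("ref", cut)),
                 lapply(sizes, function(k) {
                   if (k < 0) del_allele(cut, -k) else ins_allele(R, cut, k)
                 }))
    f <- stats::rgamma(length(alleles), 2) + 0.2
    f <- f / sum(f)
    res <- decompose_trace(mixture_trace(R, cut, alleles, f,
                                         window = c(100, 350)), R, cut)
    truth <- c(0, sizes)
    for (i in seq_along(truth)) {
      expect_lt(abs(spectrum_frequency(res, truth[i]) - f[i]), 1e-3)
    }
  }
})

test_that("genotype calls follow the allele-floor threshold scheme", {
  expect_equal(call_genotype(fake_result(c("0" = 1)))$call, "WT")
  het <- call_genotype(fake_result(c("0" = 0.5, "-8" = 0.5)))
  expect_equal(het$call, "heterozygous")
  expect_equal(het$genotype, "-8/WT")
  hom <- call_genotype(fake_result(c("0" = 0.05, "-8" = 0.95)))
  expect_equal(hom$call, "homozygous")
  expect_equal(hom$genotype, "-8/-8")
  bi <- call_genotype(fake_result(c("-8" = 0.55, "1" = 0.45)))
  expect_equal(bi$call, "bi_allelic")
  chi <- call_genotype(fake_result(c("0" = 0.3, "1" = 0.4, "-4" = 0.3)))
  expect_equal(chi$call, "chimeric")
  amb <- call_genotype(fake_result(c("0" = 0.09, "1" = 0.05, "-4" = 0.04,
                                     "-7" = 0.82)), allele_floor = 0.9)
  expect_equal(amb$call, "ambiguous")
})
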