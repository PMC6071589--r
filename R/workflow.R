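# T1 -> T3 selection logic: transgene segregation testing, in-silico PCR
# genotyping, dual-guide band screening and Mendelian genotype expectations.

#' Chi-squared test of antibiotic-resistance segregation
#'
#' Tests observed resistant/sensitive T2 seedling counts against an expected
#' ratio (default 3:1, one hemizygous T-DNA locus) with a Pearson chi-squared
#' test, 1 degree of freedom, no continuity correction by default.
#'
#' @param n_resistant,n_sensitive Seedling counts.
#' @param expected_ratio Length-2 expected ratio, default `c(3, 1)`.
#' @param alpha Significance level for the single-locus call (default 0.05).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List with `chi2`, `p_value`, `single_locus_call` (TRUE when
#'   p >= alpha), `expected` counts, `n`.
#' @export
segregation_test <- function(n_resistant, n_sensitive,
                             expected_ratio = c(3, 1), alpha = 0.05,
                             correct = FALSE) {
  n <- n_resistant + n_sensitive
  if (n < 1) .stop_input("no seedlings counted")
  if (n_resistant < 0 || n_sensitive < 0) .stop_input("negative counts")
  p <- expected_ratio / sum(expected_ratio)
  obs <- c(n_resistant, n_sensitive)
  expd <- n * p
  if (correct) {
    # stats::chisq.test only applies Yates to 2x2 tables, not GOF
    chi2 <- sum((pmax(abs(obs - expd) - 0.5, 0))^2 / expd)
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    ct <- suppressWarnings(stats::chisq.test(obs, p = p))
    chi2 <- unname(ct$statistic)
    pval <- unname(ct$p.value)
  }
  list(chi2 = chi2, p_value = pval,
       single_locus_call = pval >= alpha,
       expected = unname(expd), n = n)
}

#' Primer pair for in-silico PCR
#' @param forward,reverse Primer sequences 5'->3' (each >= 15 nt).
#' @return A `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- .norm_seq(forward, allow_n = FALSE, what = "forward primer")
  reverse <- .norm_seq(reverse, allow_n = FALSE, what = "reverse primer")
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    .stop_input("primers must be at least 15 nt")
  }
  structure(list(forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' In-silico PCR amplicon length on one allele sequence
#'
#' The forward primer must match the + strand exactly and the reverse primer
#' the - strand (i.e. its reverse complement matches the + strand), each at
#' most once; the product length runs from the forward site start to the
#' reverse site end.
#'
#' @param allele_sequence Template sequence (one allele).
#' @param primers A [primer_pair()].
#' @return Integer amplicon length, or `NA_integer_` when a primer is absent
#'   or the orientation yields no product.
#' @export
in_silico_pcr <- function(allele_sequence, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  tmpl <- .norm_seq(allele_sequence, allow_n = TRUE, what = "template")
  f <- .match_starts(tmpl, primers$forward)
  r <- .match_starts(tmpl, .revcomp(primers$reverse))
  if (length(f) > 1L || length(r) > 1L) {
    .stop_input("primer binds multiple sites (%d forward, %d reverse)",
                length(f), length(r))
  }
  if (length(f) == 0L || length(r) == 0L) return(NA_integer_)
  len <- (r + nchar(primers$reverse)) - f
  if (len <= 0L) return(NA_integer_)
  as.integer(len)
}

#' Band-based screening of a dual-guide cohort
#'
#' Runs in-silico PCR over every allele of each plant at or above the
#' band-detection floor and classifies the banding pattern. A WT band is an
#' amplicon within `tolerance` of the wild-type length; a deletion band is
#' one within `tolerance` of `WT length - predicted deletion length`.
#'
#' @param plants List of [plant_sample()]s.
#' @param reference Reference (wild-type) sequence.
#' @param primers A [primer_pair()] flanking the predicted deletion.
#' @param predicted A [predict_dual_deletion()] result.
#' @param floor Minimum allele frequency visible on a gel (default 0.10).
#' @param tolerance Band-size tolerance in bp (default 10).
#' @return data.frame with one row per plant: `plant`, `pattern` (`WT_band`,
#'   `deletion_band`, `both`, `neither`), `n_alleles_visible`.
#' @export
dual_guide_screen <- function(plants, reference, primers, predicted,
                              floor = 0.10, tolerance = 10) {
  stopifnot(inherits(predicted, "predicted_deletion"))
  R <- .norm_seq(reference)
  wt_len <- in_silico_pcr(R, primers)
  if (is.na(wt_len)) .stop_input("primers do not amplify the reference")
  del_len <- wt_len - predicted$length
  rows <- lapply(seq_along(plants), function(i) {
    pl <- plants[[i]]
    keep <- pl$frequencies >= floor
    lens <- vapply(pl$alleles[keep], function(a) {
      in_silico_pcr(allele_sequence(a, R), primers)
    }, integer(1))
    lens <- lens[!is.na(lens)]
    wt_band <- any(abs(lens - wt_len) <= tolerance)
    del_band <- any(abs(lens - del_len) <= tolerance)
    pattern <- if (wt_band && del_band) "both"
      else if (wt_band) "WT_band"
      else if (del_band) "deletion_band"
      else "neither"
    data.frame(plant = i, pattern = pattern,
               n_alleles_visible = sum(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expected T2 genotype yield under Mendelian segregation
#'
#' For a selfed T1 with a single unlinked hemizygous T-DNA locus, 1/4 of T2
#' seedlings are Cas9 null-segregants; among them the target genotype follows
#' 1:2:1 transmission of the parental alleles.
#'
#' @param t1_germline Parental target genotype, e.g. `"WT/mut"`, `"mut/mut"`,
#'   `"WT/WT"`, or `"mut1/mut2"` (two different mutant alleles).
#' @param n_t2 Number of T2 seedlings sown.
#' @return List with `expected_null_segregants`, `genotype_probs` (among
#'   null-segregants) and `expected_counts`.
#' @export
expected_genotype_yield <- function(t1_germline, n_t2) {
  g <- if (length(t1_germline) == 1L) strsplit(t1_germline, "/")[[1L]] else
    t1_germline
  stopifnot(length(g) == 2L, n_t2 >= 1)
  wt <- g == "WT"
  probs <- if (all(wt)) {
    c(WT = 1)
  } else if (sum(wt) == 1L) {
    c(WT = 0.25, het = 0.5, hom = 0.25)
  } else if (g[1] == g[2]) {
    c(hom = 1)
  } else {
    stats::setNames(c(0.25, 0.5, 0.25),
                    c(paste0("hom_", g[1]), "biallelic", paste0("hom_", g[2])))
  }
  n_null <- n_t2 / 4
  list(expected_null_segregants = n_null, genotype_probs = probs,
       expected_counts = probs * n_null)
}
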