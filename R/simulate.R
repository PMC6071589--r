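# Synthetic-data generator: repair alleles under cNHEJ/MMEJ/SD-MMEJ, chimeric
# T1 plant samples, four-channel trace signals and T2 segregating populations,
# all with recorded ground truth. Randomness uses the session RNG; call
# set.seed() for reproducibility.

#' Simulation parameters with documented defaults
#'
#' Defaults emulate the observed somatic repair landscape: +1 insertions are
#' the most frequent outcome, followed by deletions of increasing size, with
#' microhomology-driven deletions at lower levels and rare synthesis-dependent
#' events. T1 plants are chimeric (several alleles per leaf) and T2 families
#' segregate a single hemizygous T-DNA locus.
#'
#' @param mech_probs Named probabilities over repair mechanisms
#'   (`cNHEJ_plus1`, `cNHEJ_del`, `MMEJ`, `SDMMEJ_loopout`,
#'   `SDMMEJ_snapback`); normalised internally.
#' @param del_mean,del_max Truncated-geometric deletion size: mean 3 bp,
#'   maximum 50 bp (the indel range the decomposition also uses).
#' @param mmej_mh_min,mmej_window Minimum microhomology length (2 bp) and
#'   search window on each side of the cut (20 bp) for MMEJ deletions.
#' @param sdmmej_W,sdmmej_p,sdmmej_insert,sdmmej_mh,sdmmej_max_resect SD-MMEJ
#'   forward-simulation bounds: P1 window (30 bp), primer length range,
#'   templated-insert length range, microhomology length range, maximum
#'   resection per side.
#' @param p_dual_deletion With two cut sites, probability that a mutant allele
#'   is the full cut-to-cut fragment deletion.
#' @param allele_lambda,max_alleles Number of alleles per T1 plant is
#'   `1 + Poisson(allele_lambda)` (wild type always present), capped.
#' @param dirichlet_conc Symmetric Dirichlet concentration for allele
#'   frequencies within a plant.
#' @param trace_noise_sd Gaussian noise sd on trace peak heights (heights are
#'   on a 0-1 scale; truncated at 0).
#' @param n_t1,n_t2 Default cohort/family sizes (15 T1 plants; 64 T2 seeds).
#' @return Named list of parameters.
#' @export
sim_config <- function(mech_probs = c(cNHEJ_plus1 = 0.55, cNHEJ_del = 0.30,
                                      MMEJ = 0.10, SDMMEJ_loopout = 0.04,
                                      SDMMEJ_snapback = 0.01),
                       del_mean = 3, del_max = 50,
                       mmej_mh_min = 2, mmej_window = 20,
                       sdmmej_W = 30, sdmmej_p = c(2, 6),
                       sdmmej_insert = c(1, 4), sdmmej_mh = c(1, 2),
                       sdmmej_max_resect = 12,
                       p_dual_deletion = 0.4,
                       allele_lambda = 3, max_alleles = 8,
                       dirichlet_conc = 1,
                       trace_noise_sd = 0.05,
                       n_t1 = 15, n_t2 = 64) {
  stopifnot(all(mech_probs >= 0), sum(mech_probs) > 0,
            del_mean >= 1, del_max >= 1, mmej_mh_min >= 1,
            p_dual_deletion >= 0, p_dual_deletion <= 1,
            dirichlet_conc > 0, trace_noise_sd >= 0)
  list(mech_probs = mech_probs / sum(mech_probs), del_mean = del_mean,
       del_max = del_max, mmej_mh_min = mmej_mh_min,
       mmej_window = mmej_window, sdmmej_W = sdmmej_W, sdmmej_p = sdmmej_p,
       sdmmej_insert = sdmmej_insert, sdmmej_mh = sdmmej_mh,
       sdmmej_max_resect = sdmmej_max_resect,
       p_dual_deletion = p_dual_deletion, allele_lambda = allele_lambda,
       max_alleles = max_alleles, dirichlet_conc = dirichlet_conc,
       trace_noise_sd = trace_noise_sd, n_t1 = n_t1, n_t2 = n_t2)
}

.allele <- function(reference_id, del_start, del_end, insertion, label,
                    truth = NULL) {
  structure(
    list(reference_id = reference_id, del_start = as.integer(del_start),
         del_end = as.integer(del_end), insertion = insertion,
         label = label,
         indel_size = as.integer(nchar(insertion) -
                                   (as.integer(del_end) -
                                      as.integer(del_start))),
         truth_mechanism = truth),
    class = "allele")
}

.allele_label <- function(del, ins) {
  if (del == 0L && ins == 0L) return("WT")
  paste0(if (del > 0L) paste0("d", del), if (ins > 0L) paste0("i", ins))
}

#' Wild-type allele for a reference
#' @param reference_id Reference identifier.
#' @param cut Cut coordinate (stored as the empty interval `[cut, cut)`).
#' @return An `allele` with no sequence change.
#' @export
wt_allele <- function(reference_id = "ref", cut = 0L) {
  .allele(reference_id, cut, cut, "", "WT",
          truth = list(mechanism = "WT"))
}

#' Sequence of an allele on its reference
#' @param allele An `allele`.
#' @param reference The reference sequence.
#' @return Character: `reference[:del_start] + insertion +
#'   reference[del_end:]`.
#' @export
allele_sequence <- function(allele, reference) {
  ref <- .norm_seq(reference)
  paste0(.substr0(ref, 0L, allele$del_start), allele$insertion,
         .substr0(ref, allele$del_end, nchar(ref)))
}

#' Pose a simulated allele as a repair junction
#' @param allele An `allele`.
#' @param reference Reference sequence.
#' @param cut Cut coordinate.
#' @return A [repair_junction()].
#' @export
as_repair_junction <- function(allele, reference, cut) {
  repair_junction(reference, cut, allele$del_start, allele$del_end,
                  allele$insertion)
}

.rtrunc_geom <- function(n, mean, kmax) {
  pr <- stats::dgeom(0:(kmax - 1L), prob = 1 / mean)
  sample.int(kmax, n, replace = TRUE, prob = pr)
}

# All (left-copy end, right-copy start, mh) direct-repeat deletion events
# near the cut: copies R[le-m, le) (left of the break) and R[rs, rs+m)
# (right of it) are equal; repair keeps the left copy and deletes
# [le, rs+m), spanning the cut. The maximal m is kept per position pair.
.mmej_pairs <- function(R, cut, mh_min, window, del_max, mh_cap = 10L) {
  L <- nchar(R)
  out <- list()
  for (le in seq.int(max(mh_min, cut - window), cut)) {
    for (rs in seq.int(cut, min(L - mh_min, cut + window))) {
      mh_best <- 0L
      for (m in mh_min:min(le, L - rs, mh_cap)) {
        if (.substr0(R, le - m, le) == .substr0(R, rs, rs + m)) mh_best <- m
      }
      if (mh_best >= mh_min && rs + mh_best - le <= del_max &&
          rs + mh_best > le) {
        out[[length(out) + 1L]] <- list(le = le, rs = rs, mh = mh_best)
      }
    }
  }
  out
}

#' Simulate one repair allele at a cut site
#'
#' Mechanism semantics: `cNHEJ_plus1` duplicates the base immediately 5' of
#' the cut; `cNHEJ_del` deletes k bases spanning the cut (k truncated
#' geometric); `MMEJ` picks a flanking direct microhomology pair and deletes
#' between the repeats; `SDMMEJ_loopout`/`SDMMEJ_snapback` execute the forward
#' primer-repeat mechanism (choose P1/P2, elongate, anneal at a synthesised
#' microhomology) and record full ground truth.
#'
#' @param reference Reference sequence.
#' @param cut Inter-base cut coordinate.
#' @param mechanism One of `cNHEJ_plus1`, `cNHEJ_del`, `MMEJ`,
#'   `SDMMEJ_loopout`, `SDMMEJ_snapback`.
#' @param config A [sim_config()].
#' @param reference_id Identifier stored on the allele.
#' @return An `allele` with `truth_mechanism` ground truth.
#' @export
simulate_repair_allele <- function(reference, cut, mechanism,
                                   config = sim_config(),
                                   reference_id = "ref") {
  R <- .norm_seq(reference, allow_n = FALSE, what = "reference")
  L <- nchar(R)
  cut <- as.integer(cut)
  if (cut < 1L || cut > L - 1L) .stop_input("cut %d not inside reference", cut)
  mechanism <- match.arg(mechanism, c("cNHEJ_plus1", "cNHEJ_del", "MMEJ",
                                      "SDMMEJ_loopout", "SDMMEJ_snapback"))
  if (mechanism == "cNHEJ_plus1") {
    ins <- .substr0(R, cut - 1L, cut)
    return(.allele(reference_id, cut, cut, ins, "i1",
                   truth = list(mechanism = "cNHEJ_plus1")))
  }
  if (mechanism == "cNHEJ_del") {
    for (try in 1:20) {
      k <- .rtrunc_geom(1L, config$del_mean, config$del_max)
      l <- sample.int(k + 1L, 1L) - 1L
      s <- cut - l
      e <- s + k
      if (s >= 0L && e <= L) {
        return(.allele(reference_id, s, e, "", .allele_label(k, 0L),
                       truth = list(mechanism = "cNHEJ_del", size = k)))
      }
    }
    .stop_input("could not place a cNHEJ deletion inside the reference")
  }
  if (mechanism == "MMEJ") {
    pairs <- .mmej_pairs(R, cut, config$mmej_mh_min, config$mmej_window,
                         config$del_max)
    if (length(pairs) == 0L) {
      stop(errorCondition(
        "no flanking microhomology pair in window; MMEJ unavailable here",
        class = c("dualguide_mechanism_unavailable", "error")))
    }
    pr <- pairs[[sample.int(length(pairs), 1L)]]
    s <- pr$le
    e <- pr$rs + pr$mh
    return(.allele(reference_id, s, e, "", .allele_label(e - s, 0L),
                   truth = list(mechanism = "MMEJ", mh_len = pr$mh)))
  }
  # SD-MMEJ: forward-enumerate feasible events within config bounds, require
  # a templated insertion, and sample one uniformly
  mode <- sub("SDMMEJ_", "", mechanism)
  events <- .sdmmej_forward(R, cut, mode, W = config$sdmmej_W,
                            p_min = config$sdmmej_p[1],
                            p_max = config$sdmmej_p[2],
                            mh_min = config$sdmmej_mh[1],
                            elong_max = config$sdmmej_insert[2] +
                              config$sdmmej_mh[2],
                            max_resect = config$sdmmej_max_resect,
                            min_ins = max(1L, config$sdmmej_insert[1]))
  events <- Filter(function(ev) {
    nchar(ev$ins) <= config$sdmmej_insert[2] &&
      ev$mh_min <= config$sdmmej_mh[2] &&
      ev$mh_max >= config$sdmmej_mh[1] &&
      (ev$e - ev$s) <= config$del_max &&
      (ev$e - ev$s) > nchar(ev$ins)  # net deletion, as observed for this class
  }, events)
  if (length(events) == 0L) {
    stop(errorCondition(
      sprintf("no %s event available within bounds at this cut", mechanism),
      class = c("dualguide_mechanism_unavailable", "error")))
  }
  ev <- events[[sample.int(length(events), 1L)]]
  mh_lo <- max(ev$mh_min, config$sdmmej_mh[1])
  mh_hi <- min(ev$mh_max, config$sdmmej_mh[2])
  mh <- if (mh_hi > mh_lo) sample(mh_lo:mh_hi, 1L) else mh_hi
  .allele(reference_id, ev$s, ev$e, ev$ins,
          .allele_label(ev$e - ev$s, nchar(ev$ins)),
          truth = list(mechanism = mechanism, side = ev$side,
                       p_len = ev$p_len, p1_start = ev$p1_start,
                       mh_len = mh, insert_len = nchar(ev$ins),
                       repeat_len = ev$p_len + nchar(ev$ins) + mh))
}

#' Assemble a plant sample from alleles and frequencies
#'
#' @param alleles List of `allele` objects (a WT allele is added with
#'   frequency 0 if absent).
#' @param frequencies Non-negative weights, one per allele; normalised to sum
#'   to 1.
#' @return A `plant_sample` with `true_efficiency = 1 - freq(WT)`.
#' @export
plant_sample <- function(alleles, frequencies) {
  stopifnot(length(alleles) == length(frequencies), all(frequencies >= 0),
            sum(frequencies) > 0)
  frequencies <- frequencies / sum(frequencies)
  is_wt <- vapply(alleles, function(a) {
    a$del_start == a$del_end && !nzchar(a$insertion)
  }, logical(1))
  if (!any(is_wt)) {
    alleles <- c(alleles, list(wt_allele(alleles[[1]]$reference_id)))
    frequencies <- c(frequencies, 0)
    is_wt <- c(is_wt, TRUE)
  }
  structure(
    list(alleles = alleles, frequencies = frequencies,
         true_efficiency = 1 - sum(frequencies[is_wt])),
    class = "plant_sample")
}

#' @export
print.plant_sample <- function(x, ...) {
  labs <- vapply(x$alleles, function(a) a$label, character(1))
  cat(sprintf("<plant_sample> %d alleles (%s), efficiency %.3f\n",
              length(labs),
              paste(sprintf("%s:%.2f", labs, x$frequencies), collapse = ", "),
              x$true_efficiency))
  invisible(x)
}

#' Simulate a chimeric T1 plant
#'
#' Draws `1 + Poisson(allele_lambda)` alleles (wild type always present),
#' assigns each mutant allele a repair mechanism from the configured mix (with
#' two cut sites, optionally the full cut-to-cut fragment deletion), and
#' Dirichlet-distributed frequencies. Identical repair products are merged.
#'
#' @param reference Reference sequence.
#' @param sites Numeric cut coordinate(s) or list of `guide_site`s (1 or 2).
#' @param config A [sim_config()].
#' @param reference_id Identifier for generated alleles.
#' @return A `plant_sample` with ground truth on every allele.
#' @export
simulate_t1_plant <- function(reference, sites, config = sim_config(),
                              reference_id = "ref") {
  R <- .norm_seq(reference, allow_n = FALSE, what = "reference")
  cuts <- if (is.list(sites)) {
    vapply(sites, cut_site, numeric(1))
  } else {
    as.numeric(sites)
  }
  stopifnot(length(cuts) >= 1L, length(cuts) <= 2L)
  n_mut <- min(stats::rpois(1L, config$allele_lambda),
               config$max_alleles - 1L)
  alleles <- list(wt_allele(reference_id, cuts[1]))
  if (n_mut > 0L) {
    for (i in seq_len(n_mut)) {
      if (length(cuts) == 2L &&
          stats::runif(1) < config$p_dual_deletion) {
        s <- min(cuts)
        e <- max(cuts)
        al <- .allele(reference_id, s, e, "", .allele_label(e - s, 0L),
                      truth = list(mechanism = "dual_deletion"))
      } else {
        cut <- cuts[sample.int(length(cuts), 1L)]
        mech <- sample(names(config$mech_probs), 1L,
                       prob = config$mech_probs)
        al <- tryCatch(
          simulate_repair_allele(R, cut, mech, config, reference_id),
          dualguide_mechanism_unavailable = function(e) {
            simulate_repair_allele(R, cut, "cNHEJ_del", config, reference_id)
          })
      }
      alleles[[length(alleles) + 1L]] <- al
    }
  }
  freqs <- stats::rgamma(length(alleles), shape = config$dirichlet_conc)
  # merge alleles with identical repair products
  key <- vapply(alleles, function(a) {
    paste(a$del_start, a$del_end, a$insertion, sep = ":")
  }, character(1))
  if (anyDuplicated(key)) {
    agg <- tapply(freqs, key, sum)
    first <- !duplicated(key)
    alleles <- alleles[first]
    freqs <- as.numeric(agg[key[first]])
  }
  plant_sample(alleles, freqs)
}

#' Simulate the four-channel trace of a mixed sample
#'
#' The peak height of channel b at trace row i is the summed frequency of the
#' alleles whose sequence carries base b at that read position (alleles
#' shorter or longer than the reference shift the signal downstream of their
#' junction), plus optional Gaussian noise truncated at zero.
#'
#' @param sample A [plant_sample()].
#' @param reference Reference sequence.
#' @param window 0-based half-open `c(start, end)` read window; must lie
#'   within the reference.
#' @param config A [sim_config()] (supplies the default noise sd).
#' @param noise_sd Gaussian noise sd; 0 gives a noiseless indicator mixture.
#' @return A `trace_matrix` (`reference_id`, `start`, L x 4 `heights`).
#' @export
synthesize_trace <- function(sample, reference, window,
                             config = sim_config(),
                             noise_sd = config$trace_noise_sd) {
  R <- .norm_seq(reference, allow_n = FALSE, what = "reference")
  L <- nchar(R)
  w1 <- as.integer(window[1])
  w2 <- as.integer(window[2])
  if (w1 < 0L || w2 > L || w1 >= w2) {
    .stop_input("trace window [%d, %d) outside reference [0, %d)", w1, w2, L)
  }
  n <- w2 - w1
  H <- matrix(0, nrow = n, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  pos <- seq.int(w1 + 1L, w2)  # 1-based read positions
  for (i in seq_along(sample$alleles)) {
    A <- allele_sequence(sample$alleles[[i]], R)
    bases <- substring(A, pos, pos)
    ok <- bases %in% c("A", "C", "G", "T")
    if (any(ok)) {
      idx <- cbind(which(ok), match(bases[ok], c("A", "C", "G", "T")))
      H[idx] <- H[idx] + sample$frequencies[i]
    }
  }
  if (noise_sd > 0) {
    H <- pmax(H + matrix(stats::rnorm(length(H), sd = noise_sd), nrow = n), 0)
  }
  structure(list(reference_id = sample$alleles[[1]]$reference_id,
                 start = w1, heights = H),
            class = "trace_matrix")
}

#' Simulate a T2 family segregating one T-DNA locus and a target mutation
#'
#' The selfed T1 parent is hemizygous for a single T-DNA locus, unlinked to
#' the target gene: each seedling draws 0/1/2 T-DNA copies with probabilities
#' 1/4, 1/2, 1/4 (resistant when > 0, so 3/4 resistant; 1/4 are
#' null-segregants) and a target genotype by independent 1:2:1 transmission
#' of the parental alleles.
#'
#' @param germline Parental target genotype: two allele labels, e.g.
#'   `c("WT", "mut")`, or a string `"WT/mut"`. Use `"WT"` for the wild-type
#'   allele; anything else is a mutant allele label.
#' @param n Number of seedlings.
#' @return A data.frame with `tdna_copies`, `resistant`, `allele_1`,
#'   `allele_2` and `zygosity` (`WT`, `het`, `hom`, `biallelic`).
#' @export
simulate_t2_population <- function(germline, n) {
  if (length(germline) == 1L) germline <- strsplit(germline, "/")[[1L]]
  stopifnot(length(germline) == 2L, n >= 1)
  tdna <- sample(0:2, n, replace = TRUE, prob = c(1, 2, 1) / 4)
  a1 <- sample(germline, n, replace = TRUE)
  a2 <- sample(germline, n, replace = TRUE)
  zyg <- ifelse(a1 == "WT" & a2 == "WT", "WT",
         ifelse(a1 == a2, "hom",
         ifelse(a1 == "WT" | a2 == "WT", "het", "biallelic")))
  data.frame(tdna_copies = tdna, resistant = tdna > 0,
             allele_1 = a1, allele_2 = a2, zygosity = zyg,
             stringsAsFactors = FALSE)
}
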