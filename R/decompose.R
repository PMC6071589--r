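# Indel-spectrum decomposition of a mixed Sanger trace around a cut site.
#
# Downstream of the break, each allele with net indel size k contributes the
# reference signal shifted by k. Over a decomposition window the observed
# four-channel peak heights are therefore (up to noise) a non-negative mixture
# of shifted reference templates; non-negative least squares recovers the
# mixture weights, i.e. the indel spectrum, and 1 - w0 is the editing
# efficiency (fraction of cells not wild type).

#' Decomposition parameters
#'
#' @param max_indel K, largest indel size modelled on either side (default 50,
#'   the detection limit of the approach).
#' @param window_offset First decomposition position, this many bases 3' of
#'   the cut (default 5; the first rows after the break are the noisiest).
#' @param window_len Number of positions decomposed (default 100).
#' @param min_freq Smallest reported spectrum frequency (default 0.005);
#'   smaller weights are zeroed and the spectrum renormalised.
#' @param allele_floor Frequency a spectrum entry needs to count as an allele
#'   in genotype calling (default 0.10).
#' @param min_total Minimum summed frequency of floored alleles for a
#'   confident genotype call (below it the call is `ambiguous`).
#' @return Named list of parameters.
#' @export
decomposition_config <- function(max_indel = 50, window_offset = 5,
                                 window_len = 100, min_freq = 0.005,
                                 allele_floor = 0.10, min_total = 0.7) {
  stopifnot(max_indel >= 1, window_offset >= 0, window_len >= 10,
            min_freq >= 0, min_freq < 1, allele_floor >= 0, allele_floor < 1)
  list(max_indel = as.integer(max_indel),
       window_offset = as.integer(window_offset),
       window_len = as.integer(window_len), min_freq = min_freq,
       allele_floor = allele_floor, min_total = min_total)
}

#' Construct a trace matrix
#' @param heights L x 4 non-negative matrix, channels A, C, G, T.
#' @param start 0-based reference position of the first row.
#' @param reference_id Reference identifier.
#' @return A `trace_matrix`.
#' @export
trace_matrix <- function(heights, start = 0L, reference_id = "ref") {
  heights <- as.matrix(heights)
  if (ncol(heights) != 4L) .stop_input("trace needs 4 channels (A,C,G,T)")
  if (nrow(heights) < 1L) .stop_input("trace is empty")
  if (any(heights < 0)) .stop_input("trace heights must be non-negative")
  colnames(heights) <- c("A", "C", "G", "T")
  structure(list(reference_id = reference_id, start = as.integer(start),
                 heights = heights),
            class = "trace_matrix")
}

#' Shifted-reference candidate basis for decomposition
#'
#' One template per indel size k in `[-K, K]`. At window position i (absolute
#' reference coordinate), the template for shift k is the unit channel vector
#' of the reference base at `i - k`; window positions still covered by
#' inserted (unknown) bases (`i < cut + k`) contribute a uniform 0.25 across
#' the four channels.
#'
#' @param reference Reference sequence.
#' @param cut Inter-base cut coordinate.
#' @param config A [decomposition_config()].
#' @return A `(4 * window_len) x (2K + 1)` matrix; column names are the indel
#'   sizes; rows are window positions blocked by channel (A,C,G,T per
#'   position).
#' @export
build_candidate_matrix <- function(reference, cut,
                                   config = decomposition_config()) {
  R <- .norm_seq(reference, allow_n = TRUE, what = "reference")
  L <- nchar(R)
  K <- config$max_indel
  w0 <- cut + config$window_offset
  wlen <- config$window_len
  if (w0 + wlen + K > L || w0 - K < 0L) {
    .stop_input(
      "decomposition window [%d, %d) +/- K=%d does not fit reference of length %d",
      w0, w0 + wlen, K, L)
  }
  ks <- seq.int(-K, K)
  M <- matrix(0, nrow = 4L * wlen, ncol = length(ks),
              dimnames = list(NULL, as.character(ks)))
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  pos <- seq.int(w0, w0 + wlen - 1L)  # absolute 0-based positions
  for (j in seq_along(ks)) {
    k <- ks[j]
    inserted <- pos < cut + k         # only possible for k > 0
    src <- pos - k
    bases <- substring(R, src + 1L, src + 1L)
    for (i in seq_len(wlen)) {
      row0 <- (i - 1L) * 4L
      if (inserted[i]) {
        M[row0 + 1:4, j] <- 0.25
      } else {
        b <- base_idx[bases[i]]
        if (!is.na(b)) M[row0 + b, j] <- 1
      }
    }
  }
  M
}

#' Decompose a mixed trace into an indel spectrum
#'
#' Row-normalises the trace over the decomposition window, solves a
#' non-negative least squares fit against the shifted-reference basis from
#' [build_candidate_matrix()], normalises the weights to sum to 1, and
#' reports the spectrum, the editing efficiency `1 - w0` and the fit R
#' squared.
#'
#' @param trace A `trace_matrix` covering the decomposition window.
#' @param reference Reference sequence.
#' @param cut Inter-base cut coordinate.
#' @param config A [decomposition_config()].
#' @return A `decomposition_result`: `spectrum` (named vector over indel
#'   sizes with frequency >= `min_freq`), `efficiency`, `r_squared`,
#'   `degenerate` flag.
#' @export
decompose_trace <- function(trace, reference, cut,
                      config = decomposition_config()) {
  stopifnot(inherits(trace, "trace_matrix"))
  R <- .norm_seq(reference, allow_n = TRUE, what = "reference")
  M <- build_candidate_matrix(R, cut, config)
  w0 <- cut + config$window_offset
  wlen <- config$window_len
  first <- w0 - trace$start
  if (first < 0L || first + wlen > nrow(trace$heights)) {
    .stop_input("trace [%d, %d) does not cover decomposition window [%d, %d)",
                trace$start, trace$start + nrow(trace$heights), w0, w0 + wlen)
  }
  H <- trace$heights[seq.int(first + 1L, first + wlen), , drop = FALSE]
  rs <- rowSums(H)
  if (all(rs == 0)) .stop_input("all-zero trace over decomposition window")
  H[rs > 0, ] <- H[rs > 0, , drop = FALSE] / rs[rs > 0]
  y <- as.vector(t(H))  # rows blocked by position, channels A,C,G,T
  fit <- pracma::lsqnonneg(M, y)
  x <- fit$x
  degenerate <- FALSE
  if (sum(x) <= 0) {
    degenerate <- TRUE
    warning("singular decomposition fit; returning all-WT spectrum")
    x[] <- 0
    x[colnames(M) == "0"] <- 1
  }
  w <- x / sum(x)
  resid <- y - as.vector(M %*% x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(resid^2) / ss_tot)) else 0
  names(w) <- colnames(M)
  # drop sub-threshold weights, renormalise
  w[w < config$min_freq] <- 0
  if (sum(w) == 0) {
    degenerate <- TRUE
    w[names(w) == "0"] <- 1
  }
  w <- w / sum(w)
  spectrum <- w[w > 0]
  eff <- 1 - ifelse("0" %in% names(spectrum), spectrum[["0"]], 0)
  structure(
    list(spectrum = spectrum, efficiency = eff, r_squared = r2,
         degenerate = degenerate, max_indel = config$max_indel,
         config = config),
    class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> efficiency %.1f%%, r^2 %.3f\n",
              100 * x$efficiency, x$r_squared))
  top <- sort(x$spectrum, decreasing = TRUE)
  top <- top[seq_len(min(6L, length(top)))]
  cat("  spectrum:",
      paste(sprintf("%s:%.1f%%", names(top), 100 * top), collapse = "  "),
      "\n")
  invisible(x)
}

#' Frequency of one indel size in a decomposition result
#' @param result A `decomposition_result`.
#' @param k Indel size (0 = wild type / substitution-only).
#' @return Frequency in `[0, 1]`.
#' @export
spectrum_frequency <- function(result, k) {
  k <- as.character(k)
  if (k %in% names(result$spectrum)) unname(result$spectrum[k]) else 0
}

#' Call a plant genotype from an indel spectrum
#'
#' Alleles are the spectrum entries at or above `allele_floor`. One allele:
#' `WT` if it is size 0, else `homozygous`. Two alleles: `heterozygous` when
#' one is wild type, else `bi-allelic`. Three or more: `chimeric`. No allele
#' above the floor, or floored alleles summing below `min_total`:
#' `ambiguous`.
#'
#' @param result A `decomposition_result`.
#' @param allele_floor,min_total Thresholds (defaults from the result's
#'   config).
#' @return A `genotype_call`: `call`, `genotype` label (e.g. `"-8/WT"`),
#'   `alleles`, `frequencies`.
#' @export
call_genotype <- function(result, allele_floor = NULL, min_total = NULL) {
  stopifnot(inherits(result, "decomposition_result"))
  if (is.null(allele_floor)) allele_floor <- result$config$allele_floor
  if (is.null(min_total)) min_total <- result$config$min_total
  keep <- result$spectrum >= allele_floor
  alleles <- as.integer(names(result$spectrum))[keep]
  freqs <- unname(result$spectrum[keep])
  o <- order(-freqs)
  alleles <- alleles[o]
  freqs <- freqs[o]
  lab <- function(k) if (k == 0L) "WT" else sprintf("%+d", k)
  call <- if (length(alleles) == 0L || sum(freqs) < min_total) {
    "ambiguous"
  } else if (length(alleles) == 1L) {
    if (alleles == 0L) "WT" else "homozygous"
  } else if (length(alleles) == 2L) {
    if (0L %in% alleles) "heterozygous" else "bi_allelic"
  } else {
    "chimeric"
  }
  genotype <- switch(call,
    WT = "WT/WT",
    homozygous = paste(lab(alleles[1]), lab(alleles[1]), sep = "/"),
    heterozygous = paste(lab(setdiff(alleles, 0L)), "WT", sep = "/"),
    bi_allelic = paste(lab(alleles[1]), lab(alleles[2]), sep = "/"),
    NA_character_)
  structure(list(call = call, genotype = genotype, alleles = alleles,
                 frequencies = freqs),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s%s\n", x$call,
              if (!is.na(x$genotype)) paste0(" (", x$genotype, ")") else ""))
  invisible(x)
}
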