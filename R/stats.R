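# Cohort-level statistics over per-plant decomposition results.

#' Bundle per-plant decomposition results for one guide
#' @param guide_name Guide identifier.
#' @param results Non-empty list of `decomposition_result`s.
#' @return A `guide_cohort`.
#' @export
guide_cohort <- function(guide_name, results) {
  if (length(results) == 0L) .stop_input("cohort for %s is empty", guide_name)
  stopifnot(all(vapply(results, inherits, logical(1),
                       "decomposition_result")))
  structure(list(guide_name = guide_name, results = results),
            class = "guide_cohort")
}

.cohort_efficiencies <- function(cohort) {
  if (inherits(cohort, "guide_cohort")) {
    vapply(cohort$results, function(r) r$efficiency, numeric(1))
  } else if (is.numeric(cohort)) {
    cohort
  } else {
    vapply(cohort, function(r) r$efficiency, numeric(1))
  }
}

#' Efficiency summary of a guide cohort (percent scale)
#'
#' Arithmetic mean and median of per-plant editing efficiencies, the values
#' reported per guide in mutagenesis screens.
#'
#' @param cohort A [guide_cohort()], a list of `decomposition_result`s, or a
#'   numeric vector of efficiencies in `[0, 1]`.
#' @return List with `mean`, `median`, `q1`, `q3` (percent) and `n`.
#' @export
efficiency_summary <- function(cohort) {
  eff <- .cohort_efficiencies(cohort)
  if (length(eff) == 0L) .stop_input("empty cohort")
  q <- stats::quantile(eff, c(0.25, 0.75), names = FALSE)
  list(mean = 100 * mean(eff), median = 100 * stats::median(eff),
       q1 = 100 * q[1], q3 = 100 * q[2], n = length(eff))
}

#' Chimerism index: number of alleles at or above a frequency threshold
#'
#' Counts spectrum entries (including wild type, size 0, by default) with
#' frequency >= `threshold`. A plant is chimeric when the count is >= 3.
#'
#' @param result A `decomposition_result`.
#' @param threshold Frequency floor (default 0.01, i.e. 1%).
#' @param include_wt Count the size-0 entry as an allele (default TRUE).
#' @return Integer allele count.
#' @export
chimerism_index <- function(result, threshold = 0.01, include_wt = TRUE) {
  sp <- result$spectrum
  if (!include_wt) sp <- sp[names(sp) != "0"]
  sum(sp >= threshold)
}

#' Is a plant chimeric (>= 3 alleles at the threshold)?
#' @inheritParams chimerism_index
#' @return Logical.
#' @export
is_chimeric <- function(result, threshold = 0.01, include_wt = TRUE) {
  chimerism_index(result, threshold, include_wt) >= 3L
}

#' Indel incidence matrix across guides
#'
#' For each guide and indel size, the number of plants whose spectrum carries
#' that size at >= `threshold` frequency -- the data behind per-guide indel
#' heat maps.
#'
#' @param cohorts A [guide_cohort()] or list of them.
#' @param threshold Frequency floor (default 0.01).
#' @return Integer matrix, guides x indel sizes (columns sorted numerically,
#'   size 0 included).
#' @export
indel_incidence_matrix <- function(cohorts, threshold = 0.01) {
  if (inherits(cohorts, "guide_cohort")) cohorts <- list(cohorts)
  if (length(cohorts) == 0L) .stop_input("no cohorts supplied")
  per_guide <- lapply(cohorts, function(co) {
    counts <- list()
    for (r in co$results) {
      ks <- names(r$spectrum)[r$spectrum >= threshold]
      for (k in ks) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
    counts
  })
  sizes <- sort(unique(as.integer(unlist(lapply(per_guide, names)))))
  if (length(sizes) == 0L) sizes <- 0L
  M <- matrix(0L, nrow = length(cohorts), ncol = length(sizes),
              dimnames = list(vapply(cohorts, function(co) co$guide_name,
                                     character(1)),
                              as.character(sizes)))
  for (i in seq_along(per_guide)) {
    for (k in names(per_guide[[i]])) {
      M[i, k] <- per_guide[[i]][[k]]
    }
  }
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag recurrent larger deletions
#'
#' Deletions larger than `min_size - 1` bp (default: strictly greater than
#' 6 bp) observed in at least `min_plants` plants of a cohort are flagged;
#' recurrence of a particular deletion size across plants is the
#' microhomology-repair signature.
#'
#' @param matrix Incidence matrix from [indel_incidence_matrix()].
#' @param min_size Minimum deletion size in bp (default 7).
#' @param min_plants Minimum number of plants (default 5).
#' @return data.frame with `guide`, `indel_size`, `n_plants` (zero rows when
#'   nothing is flagged).
#' @export
recurrent_deletions <- function(matrix, min_size = 7, min_plants = 5) {
  sizes <- as.integer(colnames(matrix))
  out <- data.frame(guide = character(0), indel_size = integer(0),
                    n_plants = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(matrix))) {
    for (j in seq_along(sizes)) {
      if (sizes[j] <= -min_size && matrix[i, j] >= min_plants) {
        out <- rbind(out, data.frame(
          guide = rownames(matrix)[i], indel_size = sizes[j],
          n_plants = matrix[i, j], stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-guide summary table (efficiency, median, chimerism)
#'
#' @param cohorts A [guide_cohort()] or list of them.
#' @param chimerism_threshold Frequency floor for the allele count.
#' @return data.frame with one row per guide: `guide`, `n`,
#'   `observed_efficiency` (mean, percent), `efficiency_median` (percent),
#'   `chimerism` (mean alleles >= threshold).
#' @export
cohort_summary_table <- function(cohorts, chimerism_threshold = 0.01) {
  if (inherits(cohorts, "guide_cohort")) cohorts <- list(cohorts)
  rows <- lapply(cohorts, function(co) {
    es <- efficiency_summary(co)
    chim <- mean(vapply(co$results, chimerism_index, numeric(1),
                        threshold = chimerism_threshold))
    data.frame(guide = co$guide_name, n = es$n,
               observed_efficiency = es$mean,
               efficiency_median = es$median, chimerism = chim,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
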