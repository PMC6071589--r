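# Repair junctions: an observed allele described as a deleted interval plus an
# inserted string on a reference, around a known cut site.
#
# Flanking repeats make the placement of a deletion/insertion ambiguous, so
# junctions are stored in a canonical maximally-5'-shifted form; that makes
# the flanking microhomology of a deletion the junction's direct repeat.

#' Construct a repair junction
#'
#' @param reference Reference sequence around the break (character).
#' @param cut Inter-base break coordinate (0-based).
#' @param del_start,del_end Deleted interval, 0-based half-open; equal for a
#'   pure insertion. The interval (as supplied) must span or abut the cut.
#' @param insertion Inserted bases at the junction (possibly "").
#' @param canonicalize Shift the representation maximally 5' (default). The
#'   reconstructed product `reference[:del_start] + insertion +
#'   reference[del_end:]` is invariant under shifting.
#' @return A `repair_junction` object.
#' @export
repair_junction <- function(reference, cut, del_start, del_end,
                            insertion = "", canonicalize = TRUE) {
  ref <- .norm_seq(reference, allow_n = FALSE, what = "reference")
  insertion <- .norm_seq(insertion, allow_n = FALSE, what = "insertion")
  L <- nchar(ref)
  del_start <- as.integer(del_start)
  del_end <- as.integer(del_end)
  cut <- as.integer(cut)
  if (del_start < 0L || del_end > L || del_start > del_end) {
    .stop_input("invalid deleted interval [%d, %d) on reference of length %d",
                del_start, del_end, L)
  }
  if (cut < 0L || cut > L) .stop_input("cut %d outside reference", cut)
  j <- structure(
    list(reference = ref, cut = cut, del_start = del_start,
         del_end = del_end, insertion = insertion),
    class = "repair_junction")
  # some equivalent placement (between the 5'- and 3'-maximal shifts) must
  # span or abut the cut
  jc <- canonicalize_junction(j)
  e3 <- .shift3_end(ref, del_start, del_end, insertion)
  if (jc$del_start > cut || e3 < cut) {
    .stop_input("deleted interval [%d, %d) does not span or abut the cut (%d)",
                del_start, del_end, cut)
  }
  if (canonicalize) jc else j
}

# del_end of the maximally 3'-shifted equivalent placement
.shift3_end <- function(R, s, e, I) {
  L <- nchar(R)
  k <- nchar(I)
  repeat {
    if (e >= L) break
    if (k > 0L) {
      if (substr(I, 1L, 1L) != substr(R, s + 1L, s + 1L)) break
      I <- paste0(substr(I, 2L, k), substr(R, e + 1L, e + 1L))
    } else {
      if (s >= L || substr(R, s + 1L, s + 1L) != substr(R, e + 1L, e + 1L))
        break
    }
    s <- s + 1L
    e <- e + 1L
  }
  e
}

#' Reconstruct the repaired product sequence of a junction
#' @param junction A `repair_junction`.
#' @return Character product `reference[:del_start] + insertion +
#'   reference[del_end:]`.
#' @export
junction_product <- function(junction) {
  stopifnot(inherits(junction, "repair_junction"))
  paste0(.substr0(junction$reference, 0L, junction$del_start),
         junction$insertion,
         .substr0(junction$reference, junction$del_end,
                  nchar(junction$reference)))
}

#' Shift a junction representation maximally 5'
#'
#' A representation `(s-1, e-1, I')` is equivalent to `(s, e, I)` whenever the
#' base entering the junction from the left equals the base leaving it on the
#' right (`I`'s last base, or `reference[e-1]` for pure deletions).
#' Idempotent.
#'
#' @param junction A `repair_junction`.
#' @return The canonical `repair_junction` (same product).
#' @export
canonicalize_junction <- function(junction) {
  stopifnot(inherits(junction, "repair_junction"))
  R <- junction$reference
  s <- junction$del_start
  e <- junction$del_end
  I <- junction$insertion
  k <- nchar(I)
  repeat {
    if (s <= 0L) break
    if (k > 0L) {
      if (substr(I, k, k) != substr(R, e, e)) break
      I <- paste0(substr(R, s, s), substr(I, 1L, k - 1L))
    } else {
      if (e <= 0L || substr(R, s, s) != substr(R, e, e)) break
    }
    s <- s - 1L
    e <- e - 1L
  }
  junction$del_start <- s
  junction$del_end <- e
  junction$insertion <- I
  junction
}

#' Indel size of a junction (insertion length minus deletion length)
#' @param junction A `repair_junction`.
#' @return Integer; negative for net deletions.
#' @export
indel_size <- function(junction) {
  nchar(junction$insertion) - (junction$del_end - junction$del_start)
}

#' Longest microhomology flanking a junction
#'
#' The longest k >= 0 with `reference[del_start : del_start+k] ==
#' reference[del_end : del_end+k]` over the maximally 5'- and (mirrored)
#' 3'-shifted placements of the junction, i.e. the longest direct repeat of
#' which one copy was lost -- the classic MMEJ signature. Taking both
#' orientations makes the value invariant under reverse complementation of
#' the whole problem.
#'
#' @param junction A `repair_junction` (canonicalised internally).
#' @return List with `length` and `sequence` (on the + strand).
#' @export
flanking_microhomology <- function(junction) {
  fwd <- .fmh_one(canonicalize_junction(junction))
  rev <- .fmh_one(revcomp_junction(junction))
  if (rev$length > fwd$length) {
    list(length = rev$length, sequence = .revcomp(rev$sequence))
  } else {
    fwd
  }
}

.fmh_one <- function(junction) {
  R <- junction$reference
  s <- junction$del_start
  e <- junction$del_end
  L <- nchar(R)
  kmax <- min(e - s, L - e)
  k <- 0L
  while (k < kmax && substr(R, s + k + 1L, s + k + 1L) ==
         substr(R, e + k + 1L, e + k + 1L)) {
    k <- k + 1L
  }
  list(length = k, sequence = .substr0(R, s, s + k))
}

#' @export
print.repair_junction <- function(x, ...) {
  cat(sprintf(
    "<repair_junction> cut %d, del [%d, %d) (%d bp), ins '%s' (net %+d)\n",
    x$cut, x$del_start, x$del_end, x$del_end - x$del_start, x$insertion,
    indel_size(x)))
  invisible(x)
}

# All representations (s, e, I) of the junction's product with s <= cut <= e
# and resection bounded by max_resect on each side. A representation is valid
# iff product[:s] == reference[:s], product suffix == reference[e:], and the
# implied insertion length is within [0, max_ins].
.junction_reps <- function(junction, max_resect, max_ins) {
  R <- junction$reference
  c0 <- junction$cut
  L <- nchar(R)
  P <- junction_product(junction)
  nP <- nchar(P)
  mp <- .lcp(P, R)  # max usable s
  ms <- .lcs(P, R)  # max usable (L - e)
  s_lo <- max(0L, c0 - as.integer(max_resect))
  s_hi <- min(mp, c0)
  e_lo <- max(c0, L - ms)
  e_hi <- min(L, c0 + as.integer(max_resect))
  reps <- list()
  if (s_lo > s_hi || e_lo > e_hi) return(reps)
  for (s2 in s_lo:s_hi) {
    for (e2 in e_lo:e_hi) {
      ilen <- nP - s2 - (L - e2)
      if (ilen < 0L || ilen > max_ins) next
      reps[[length(reps) + 1L]] <- list(
        s = s2, e = e2,
        ins = if (ilen > 0L) substr(P, s2 + 1L, s2 + ilen) else "")
    }
  }
  reps
}
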