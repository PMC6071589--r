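# Synthesis-dependent MMEJ (SD-MMEJ) junction analysis.
#
# Model: after end resection at the double-strand break, a "primer repeat"
# (P1 + P2, with P2 break-proximal) anneals intramolecularly -- as a loop-out
# when P1 is a same-strand direct copy of P2, or a snap-back hairpin when P1
# is the reverse complement -- with P1 within W bp of the break. A polymerase
# then elongates the 3' end using the sequence next to P1 as template until a
# microhomology (MH1) has been synthesised whose counterpart (MH2) lies on the
# far side of the break; annealing at MH1/MH2 seals the junction. The repair
# product carries a diagnostic direct (loop-out) or inverted (snap-back)
# repeat of length mh + insert + p, and the synthesised elongation has length
# insert + mh.

# ---- shared low-level scans -------------------------------------------------

# Mechanisms explaining a fixed representation (s, e, I) on the left side of
# the break. Returns a list of mechanism records in + strand coordinates of R.
.sdmmej_scan_left <- function(R, c0, s, e, I, mode, W, p_min, p_max, mh_min,
                              max_elong) {
  L <- nchar(R)
  ilen <- nchar(I)
  out <- list()
  if (ilen > max_elong - mh_min) return(out)
  p_hi <- min(p_max, W, s)
  if (p_hi < p_min) return(out)
  for (p in p_min:p_hi) {
    p2s <- s - p
    P2 <- .substr0(R, p2s, s)
    target <- if (mode == "loopout") P2 else .revcomp(P2)
    a_hi <- if (mode == "loopout") s - p - 1L else s - p
    if (a_hi < 0L) next
    cand <- .match_starts(.substr0(R, 0L, min(L, a_hi + p)), target)
    for (a in cand) {
      if (c0 - a > W) next
      if (mode == "loopout") {
        # insertion must be templated by the bases 3' of P1
        if (a + p + ilen > s) next
        if (ilen > 0L && .substr0(R, a + p, a + p + ilen) != I) next
        t_cap <- min(max_elong - ilen, s - (a + p + ilen), L - e)
      } else {
        if (a - ilen < 0L) next
        if (ilen > 0L && .revcomp(.substr0(R, a - ilen, a)) != I) next
        t_cap <- min(max_elong - ilen, a - ilen, L - e)
      }
      if (t_cap < mh_min) next
      # extend the synthesised microhomology base by base
      mh_max <- 0L
      while (mh_max < t_cap) {
        t <- mh_max + 1L
        synth <- if (mode == "loopout") {
          substr(R, a + p + ilen + t, a + p + ilen + t)
        } else {
          chartr("ACGTN", "TGCAN", substr(R, a - ilen - t + 1L,
                                          a - ilen - t + 1L))
        }
        if (synth != substr(R, e + t, e + t)) break
        mh_max <- t
      }
      if (mh_max < mh_min) next
      for (mh in mh_min:mh_max) {
        mh1 <- if (mode == "loopout") {
          c(a + p + ilen, a + p + ilen + mh)
        } else {
          c(a - ilen - mh, a - ilen)
        }
        elong <- if (mode == "loopout") {
          .substr0(R, a + p, a + p + ilen + mh)
        } else {
          .revcomp(.substr0(R, a - ilen - mh, a))
        }
        out[[length(out) + 1L]] <- list(
          class = paste0("SDMMEJ_", mode), side = "left",
          p_len = p, p1_interval = c(a, a + p), p2_interval = c(p2s, s),
          mh_len = mh, mh1_interval = mh1, mh2_interval = c(e, e + mh),
          insertion = I, elongation = elong,
          repeat_signature = paste0(P2, I, .substr0(R, e, e + mh)),
          repeat_type = if (mode == "loopout") "direct" else "inverted",
          repeat_len = p + ilen + mh,
          del_start = s, del_end = e)
      }
    }
  }
  out
}

# map an interval [x, y) through reverse complementation of a length-L string
.rc_iv <- function(iv, L) c(L - iv[2L], L - iv[1L])

# Right-side mechanisms, by running the left-side scan on the
# reverse-complemented problem and mapping coordinates back.
.sdmmej_scan_right <- function(R, c0, s, e, I, mode, W, p_min, p_max, mh_min,
                               max_elong) {
  L <- nchar(R)
  mechs <- .sdmmej_scan_left(.revcomp(R), L - c0, L - e, L - s, .revcomp(I),
                             mode, W, p_min, p_max, mh_min, max_elong)
  lapply(mechs, function(m) {
    m$side <- "right"
    m$p1_interval <- .rc_iv(m$p1_interval, L)
    m$p2_interval <- .rc_iv(m$p2_interval, L)
    m$mh1_interval <- .rc_iv(m$mh1_interval, L)
    m$mh2_interval <- .rc_iv(m$mh2_interval, L)
    m$insertion <- I
    # elongation is synthesised on the bottom strand; report it 5'->3' as
    # synthesised, and the junction repeat on the + strand
    m$repeat_signature <- .revcomp(m$repeat_signature)
    m$del_start <- s
    m$del_end <- e
    m
  })
}

# ---- enumeration ------------------------------------------------------------

#' Enumerate SD-MMEJ mechanisms explaining a repair junction
#'
#' Exhaustively searches loop-out and snap-back primer repeats on both sides
#' of the break, over every representation of the junction's product whose
#' resection stays within `max_resect` of the cut, and returns each mechanism
#' with its P1/P2/MH coordinates and repeat arithmetic. Every returned
#' mechanism satisfies `repeat_len == mh_len + nchar(insertion) + p_len` and
#' reconstructs the observed product exactly.
#'
#' @param junction A [repair_junction()].
#' @param W Maximum distance (bp) of the P1 start from the break (default 30).
#' @param p_min,p_max Primer-repeat length bounds (p is also capped at `W`).
#' @param mh_min Minimum synthesised microhomology length (default 1; a
#'   single-base microhomology still fits the model).
#' @param max_elong Maximum synthesised length (insert + mh), default 20.
#' @param max_resect Maximum resection considered on each side of the cut
#'   when re-placing the junction (default `W`).
#' @param first_only Stop at the first mechanism found (existence check;
#'   default FALSE).
#' @return List of mechanism records, loop-out before snap-back, longest
#'   diagnostic repeat first; empty list if no mechanism exists.
#' @export
enumerate_sdmmej <- function(junction, W = 30, p_min = 1, mh_min = 1,
                             max_elong = 20, p_max = Inf, max_resect = W,
                             first_only = FALSE) {
  stopifnot(inherits(junction, "repair_junction"))
  R <- junction$reference
  c0 <- junction$cut
  reps <- .junction_reps(junction, max_resect = max_resect,
                         max_ins = max_elong - mh_min)
  out <- list()
  for (r in reps) {
    for (mode in c("loopout", "snapback")) {
      out <- c(out,
               .sdmmej_scan_left(R, c0, r$s, r$e, r$ins, mode, W, p_min,
                                 p_max, mh_min, max_elong),
               .sdmmej_scan_right(R, c0, r$s, r$e, r$ins, mode, W, p_min,
                                  p_max, mh_min, max_elong))
      if (first_only && length(out) > 0L) return(out[1L])
    }
  }
  if (length(out) == 0L) return(out)
  # drop duplicates arising from overlapping representations
  keys <- vapply(out, function(m) {
    paste(m$class, m$side, m$p1_interval[1], m$p1_interval[2],
          m$p2_interval[1], m$p2_interval[2], m$mh1_interval[1],
          m$mh2_interval[1], m$mh_len, m$del_start, m$del_end, sep = ":")
  }, character(1))
  out <- out[!duplicated(keys)]
  loop_first <- vapply(out, function(m) m$class == "SDMMEJ_loopout",
                       logical(1))
  rep_len <- vapply(out, function(m) m$repeat_len, numeric(1))
  p_len <- vapply(out, function(m) m$p_len, numeric(1))
  out[order(-as.integer(loop_first), -rep_len, -p_len)]
}

#' Reconstruct the product implied by an SD-MMEJ mechanism
#' @param mechanism One element of the list returned by [enumerate_sdmmej()].
#' @param reference The reference sequence the mechanism refers to.
#' @return Character product sequence.
#' @export
mechanism_product <- function(mechanism, reference) {
  R <- .norm_seq(reference, allow_n = FALSE, what = "reference")
  paste0(.substr0(R, 0L, mechanism$del_start), mechanism$insertion,
         .substr0(R, mechanism$del_end, nchar(R)))
}

# ---- brute-force forward oracle --------------------------------------------

# Forward-generate every left-side event for one mode. The repaired product
# depends only on (s, e, insertion); a valid microhomology of any length
# implies a valid one of length mh_min (prefix property), so events are
# emitted once per (s, p, a, insert, e) with the feasible mh range
# [mh_min, mh_max] attached. Coordinates are + strand coordinates of R.
.sdmmej_forward_left <- function(R, c0, mode, W, p_min, p_max, mh_min,
                                 elong_max, max_resect, min_ins = 0L) {
  L <- nchar(R)
  out <- list()
  e_all <- c0:min(L, c0 + max_resect)
  for (s in max(0L, c0 - max_resect):c0) {
    p_hi <- min(p_max, W, s)
    if (p_hi < p_min) next
    for (p in p_min:p_hi) {
      P2 <- .substr0(R, s - p, s)
      target <- if (mode == "loopout") P2 else .revcomp(P2)
      a_hi <- if (mode == "loopout") s - p - 1L else s - p
      if (a_hi < 0L) next
      cand <- .match_starts(.substr0(R, 0L, min(L, a_hi + p)), target)
      cand <- cand[c0 - cand <= W]
      for (a in cand) {
        i_cap <- if (mode == "loopout") {
          min(elong_max - mh_min, s - (a + p) - mh_min)
        } else {
          min(elong_max - mh_min, a - mh_min)
        }
        if (i_cap < min_ins) next
        for (ilen in min_ins:i_cap) {
          I <- if (mode == "loopout") {
            .substr0(R, a + p, a + p + ilen)
          } else {
            .revcomp(.substr0(R, a - ilen, a))
          }
          mh_cap <- if (mode == "loopout") {
            min(elong_max - ilen, s - (a + p + ilen))
          } else {
            min(elong_max - ilen, a - ilen)
          }
          if (mh_cap < mh_min) next
          mh0 <- if (mode == "loopout") {
            .substr0(R, a + p + ilen, a + p + ilen + mh_min)
          } else {
            .revcomp(.substr0(R, a - ilen - mh_min, a - ilen))
          }
          es <- e_all[e_all + mh_min <= L]
          if (length(es) == 0L) next
          es <- es[substring(R, es + 1L, es + mh_min) == mh0]
          for (e in es) {
            # extend to the maximal valid microhomology at this e
            mh_max <- mh_min
            while (mh_max < mh_cap && e + mh_max < L) {
              t <- mh_max + 1L
              synth <- if (mode == "loopout") {
                substr(R, a + p + ilen + t, a + p + ilen + t)
              } else {
                chartr("ACGTN", "TGCAN",
                       substr(R, a - ilen - t + 1L, a - ilen - t + 1L))
              }
              if (synth != substr(R, e + t, e + t)) break
              mh_max <- t
            }
            out[[length(out) + 1L]] <- list(
              mode = mode, side = "left", s = s, e = e, ins = I,
              p_len = p, p1_start = a, mh_min = mh_min, mh_max = mh_max,
              repeat_len = p + ilen + mh_min)
          }
        }
      }
    }
  }
  out
}

.sdmmej_forward <- function(R, c0, mode, W, p_min, p_max, mh_min, elong_max,
                            max_resect, min_ins = 0L) {
  L <- nchar(R)
  left <- .sdmmej_forward_left(R, c0, mode, W, p_min, p_max, mh_min,
                               elong_max, max_resect, min_ins)
  right <- .sdmmej_forward_left(.revcomp(R), L - c0, mode, W, p_min, p_max,
                                mh_min, elong_max, max_resect, min_ins)
  right <- lapply(right, function(ev) {
    list(mode = ev$mode, side = "right", s = L - ev$e, e = L - ev$s,
         ins = .revcomp(ev$ins), p_len = ev$p_len,
         p1_start = L - (ev$p1_start + ev$p_len), mh_min = ev$mh_min,
         mh_max = ev$mh_max, repeat_len = ev$repeat_len)
  })
  c(left, right)
}

#' Brute-force forward oracle: all SD-MMEJ products reachable within bounds
#'
#' Forward-simulates every loop-out and snap-back repair event (both sides of
#' the break) within the given bounds and collects the distinct product
#' sequences. Intended as an independent check of [enumerate_sdmmej()] on
#' small references: the enumerator finds a mechanism for a junction if and
#' only if the oracle can generate its product under the same bounds.
#'
#' @param reference Reference sequence (refused above 200 nt; the search is
#'   combinatorial).
#' @param cut Inter-base break coordinate.
#' @param W,p_min,p_max,mh_min,elong_max,max_resect Same meanings and units
#'   as in [enumerate_sdmmej()] (`elong_max` bounds insert + mh).
#' @return A list with `products` (character vector of distinct product
#'   sequences, the unchanged reference excluded) and `events` (one
#'   representative generating event per product).
#' @export
sdmmej_oracle <- function(reference, cut, W = 30, p_max = 6, elong_max = 10,
                          p_min = 1, mh_min = 1, max_resect = W) {
  R <- .norm_seq(reference, allow_n = FALSE, what = "reference")
  if (nchar(R) > 200L) {
    .stop_input("oracle refuses references > 200 nt (combinatorial search)")
  }
  events <- c(
    .sdmmej_forward(R, cut, "loopout", W, p_min, p_max, mh_min, elong_max,
                    max_resect),
    .sdmmej_forward(R, cut, "snapback", W, p_min, p_max, mh_min, elong_max,
                    max_resect))
  prods <- vapply(events, function(ev) {
    paste0(.substr0(R, 0L, ev$s), ev$ins, .substr0(R, ev$e, nchar(R)))
  }, character(1))
  keep <- prods != R & !duplicated(prods)
  list(products = prods[keep], events = events[keep])
}

# ---- classification ---------------------------------------------------------

#' Classification parameters for repair junctions
#'
#' @param W P1 search window from the break, bp. The 30 bp default follows the
#'   binding footprint rationale proposed for the model.
#' @param p_min Minimum primer-repeat length reported (1; filter downstream
#'   on `p_len` if desired).
#' @param mh_min Minimum synthesised microhomology (1 bp qualifies).
#' @param max_elong Maximum synthesised length, insert + mh.
#' @param p_max Maximum primer-repeat length (capped at `W` regardless).
#' @param max_resect Maximum resection per side when re-placing the junction.
#' @param mmej_min_mh Minimum flanking microhomology for a deletion-only
#'   junction to be called MMEJ rather than cNHEJ-consistent (2 bp; a 1-bp
#'   "microhomology" is uninformative).
#' @return Named list of parameters.
#' @export
classifier_config <- function(W = 30, p_min = 1, mh_min = 1, max_elong = 20,
                              p_max = Inf, max_resect = W, mmej_min_mh = 2) {
  stopifnot(W >= 1, p_min >= 1, mh_min >= 1, max_elong >= mh_min,
            mmej_min_mh >= 1)
  list(W = W, p_min = p_min, mh_min = mh_min, max_elong = max_elong,
       p_max = p_max, max_resect = max_resect, mmej_min_mh = mmej_min_mh)
}

#' Classify a repair junction by repair mechanism
#'
#' Decision cascade: a bare +1 insertion is cNHEJ-consistent (the typical
#' staggered-cut fill-in); a deletion without insertion is MMEJ when the
#' flanking microhomology is at least `mmej_min_mh` and cNHEJ-consistent
#' otherwise; a junction with inserted bases is SD-MMEJ when at least one
#' loop-out or snap-back mechanism explains it (loop-out preferred, longest
#' diagnostic repeat first) and unexplained otherwise. All SD-MMEJ mechanisms
#' found are reported even when the top class is cNHEJ/MMEJ, annotated as
#' co-consistent. Substitutions should be posed as an equal-length deletion
#' plus insertion before classification.
#'
#' @param junction A [repair_junction()] with a sequence change.
#' @param config A [classifier_config()].
#' @return A `mechanism_report`: `top_class`, `flanking_mh_len`, `mechanisms`
#'   (possibly empty), `co_consistent` flag, and the search parameters used.
#' @export
classify_junction <- function(junction, config = classifier_config()) {
  stopifnot(inherits(junction, "repair_junction"))
  junction <- canonicalize_junction(junction)
  dlen <- junction$del_end - junction$del_start
  ilen <- nchar(junction$insertion)
  if (dlen == 0L && ilen == 0L) {
    .stop_input("junction has no sequence change; nothing to classify")
  }
  mechs <- enumerate_sdmmej(junction, W = config$W, p_min = config$p_min,
                            mh_min = config$mh_min,
                            max_elong = config$max_elong,
                            p_max = config$p_max,
                            max_resect = config$max_resect)
  fmh <- flanking_microhomology(junction)
  top <- if (ilen == 1L && dlen == 0L) {
    "cNHEJ_consistent"
  } else if (ilen == 0L) {
    if (fmh$length >= config$mmej_min_mh) "MMEJ" else "cNHEJ_consistent"
  } else if (length(mechs) > 0L) {
    mechs[[1L]]$class
  } else {
    "unexplained"
  }
  structure(
    list(junction = junction, top_class = top,
         flanking_mh_len = fmh$length, flanking_mh_seq = fmh$sequence,
         mechanisms = mechs,
         co_consistent = length(mechs) > 0L && !startsWith(top, "SDMMEJ"),
         params = config),
    class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat(sprintf("<mechanism_report> %s (flanking mh %d bp, %d SD-MMEJ mechanism%s)\n",
              x$top_class, x$flanking_mh_len, length(x$mechanisms),
              if (length(x$mechanisms) == 1) "" else "s"))
  if (length(x$mechanisms) > 0) {
    m <- x$mechanisms[[1L]]
    cat(sprintf("  best: %s (%s) p=%d mh=%d insert=%d repeat=%d (%s '%s')\n",
                m$class, m$side, m$p_len, m$mh_len, nchar(m$insertion),
                m$repeat_len, m$repeat_type, m$repeat_signature))
  }
  invisible(x)
}

#' Reverse-complement a whole junction problem
#'
#' Maps reference, cut and deleted interval through reverse complementation;
#' classification is invariant under this transform.
#'
#' @param junction A [repair_junction()].
#' @return The mirrored `repair_junction`.
#' @export
revcomp_junction <- function(junction) {
  stopifnot(inherits(junction, "repair_junction"))
  L <- nchar(junction$reference)
  repair_junction(.revcomp(junction$reference), L - junction$cut,
                  L - junction$del_end, L - junction$del_start,
                  .revcomp(junction$insertion))
}
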