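# Synthetic test loci. Real genomic sequence for the targeted genes is not
# redistributed with the package; these builders produce clearly synthetic
# stand-in loci that embed real guide protospacer+PAM sequences at a designed
# cut-to-cut spacing, so the full localisation -> cut arithmetic -> deletion
# prediction chain can be exercised deterministically and offline.

#' Random DNA string from the session RNG
#' @param n Length in nt.
#' @return Character sequence of A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic locus carrying a dual-guide pair at a designed spacing
#'
#' Plants `guide_a` on the + strand and `guide_b` on the requested strand in
#' a random background so that the two blunt Cas9 cut sites are exactly
#' `cut_distance` bp apart, then verifies that each guide matches the locus
#' exactly once. The result is a synthetic stand-in, not genomic sequence:
#' only the protospacer+PAM content and the cut spacing are real design
#' inputs.
#'
#' @param guide_a,guide_b [guide_rna()] objects.
#' @param cut_distance Designed cut-to-cut distance in bp.
#' @param flank Background flank length on each side (default 150).
#' @param strand_b Strand for `guide_b` (`"+"` or `"-"`).
#' @param seed Deterministic background seed (restored on exit).
#' @param locus_id Identifier for the locus.
#' @return List with `sequence`, `locus_id`, `site_a`, `site_b` (the located
#'   `guide_site`s) and `deletion` (the [predict_dual_deletion()] result).
#' @export
synthetic_locus <- function(guide_a, guide_b, cut_distance, flank = 150,
                            strand_b = "+", seed = 1,
                            locus_id = "synthetic_locus") {
  stopifnot(inherits(guide_a, "guide_rna"), inherits(guide_b, "guide_rna"),
            cut_distance > nchar(guide_b$protospacer) + 10)
  motif_a <- paste0(guide_a$protospacer, guide_a$pam)
  motif_b_plus <- paste0(guide_b$protospacer, guide_b$pam)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (attempt in 0:24) {
    set.seed(seed + attempt)
    pa <- flank
    cut_a <- pa + nchar(guide_a$protospacer) - 3L
    if (strand_b == "+") {
      pb <- cut_a + cut_distance - nchar(guide_b$protospacer) + 3L
      motif_b <- motif_b_plus
    } else {
      pb <- cut_a + cut_distance - 6L  # cut_b = pam_end + 3 = pb + 6
      motif_b <- .revcomp(motif_b_plus)
    }
    if (pb <= pa + nchar(motif_a)) {
      .stop_input("guides overlap at this spacing; increase cut_distance")
    }
    total <- pb + nchar(motif_b) + flank
    seq <- random_dna(total)
    seq <- paste0(.substr0(seq, 0L, pa), motif_a,
                  .substr0(seq, pa + nchar(motif_a), pb), motif_b,
                  .substr0(seq, pb + nchar(motif_b), total))
    sa <- find_protospacer(seq, guide_a, locus_id)
    sb <- find_protospacer(seq, guide_b, locus_id)
    if (length(sa) == 1L && length(sb) == 1L) {
      return(list(sequence = seq, locus_id = locus_id,
                  site_a = sa[[1L]], site_b = sb[[1L]],
                  deletion = predict_dual_deletion(sa[[1L]], sb[[1L]])))
    }
  }
  .stop_input("could not build an unambiguous synthetic locus")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Bundled sgRNA guide table
#'
#' Reads the packaged guide description table (name, guide class,
#' protospacer, PAM, plus pass-through prediction scores and observed T1
#' statistics where available) and returns it as a data.frame alongside
#' parsed [guide_rna()] objects.
#'
#' @return List with `table` (data.frame) and `guides` (named list of
#'   `guide_rna`).
#' @export
bundled_guides <- function() {
  path <- system.file("extdata", "sgRNA_guides.tsv", package = "dualguide")
  read_guides_tsv(path)
}
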