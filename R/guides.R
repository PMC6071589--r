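# Guide parsing, protospacer localisation and cut-site arithmetic.
#
# SpCas9 makes a blunt double-strand break 3 nt 5' of the PAM on the
# protospacer strand. All coordinates are 0-based half-open on the + strand;
# cut sites are inter-base integers (the break lies between cut-1 and cut).

#' Classify an sgRNA by the position of its starting guanine
#'
#' Pol III (AtU6-26) transcription starts on a G, so cloned guides fall in one
#' of three classes: a 20-nt protospacer that itself starts with G
#' (`GN19_starts_with_G`, spacer identical to the protospacer), a 20-nt
#' protospacer with an extra transcribed 5' G (`GN20_extra_G`), or a truncated
#' guide with a 19-nt protospacer starting with G (`GN18_tru`).
#'
#' @param spacer Transcribed guide sequence, 5'->3'.
#' @param protospacer Genomic match of the guide (18-20 nt, without PAM).
#' @return One of `"GN19_starts_with_G"`, `"GN20_extra_G"`, `"GN18_tru"`.
#' @export
#' @examples
#' classify_guide_type("GGGACTGTTAAGTGCAAGCT", "GGGACTGTTAAGTGCAAGCT")
#' classify_guide_type("GTATTGCAGAGAGCCTAAAGA", "TATTGCAGAGAGCCTAAAGA")
classify_guide_type <- function(spacer, protospacer) {
  spacer <- .norm_seq(spacer, allow_n = FALSE, what = "spacer")
  protospacer <- .norm_seq(protospacer, allow_n = FALSE, what = "protospacer")
  pl <- nchar(protospacer)
  if (pl == 20L && spacer == protospacer && startsWith(protospacer, "G")) {
    return("GN19_starts_with_G")
  }
  if (pl == 20L && spacer == paste0("G", protospacer)) {
    return("GN20_extra_G")
  }
  if (pl == 19L && startsWith(spacer, "G") &&
      (spacer == protospacer || spacer == paste0("G", protospacer))) {
    return("GN18_tru")
  }
  .stop_input("spacer/protospacer pair (%d nt protospacer) fits no guide type",
              pl)
}

#' Construct a guide RNA description
#'
#' @param name Guide identifier.
#' @param protospacer Genomic protospacer sequence (18-20 nt, no PAM).
#' @param pam 3-nt PAM; must match NGG.
#' @param spacer Transcribed spacer; if omitted it is inferred (`protospacer`
#'   when that starts with G, otherwise `"G" + protospacer`).
#' @param metadata Optional named list of pass-through annotations (e.g.
#'   predicted efficiency scores).
#' @return A `guide_rna` object.
#' @export
guide_rna <- function(name, protospacer, pam, spacer = NULL,
                      metadata = list()) {
  protospacer <- .norm_seq(protospacer, allow_n = FALSE, what = "protospacer")
  pam <- .norm_seq(pam, allow_n = TRUE, what = "PAM")
  if (nchar(pam) != 3L || !grepl("^[ACGTN]GG$", pam)) {
    .stop_input("PAM '%s' does not match NGG", pam)
  }
  if (!nchar(protospacer) %in% 18:20) {
    .stop_input("protospacer must be 18-20 nt, got %d", nchar(protospacer))
  }
  if (is.null(spacer)) {
    spacer <- if (startsWith(protospacer, "G")) protospacer else
      paste0("G", protospacer)
  }
  type <- classify_guide_type(spacer, protospacer)
  structure(
    list(name = as.character(name), spacer = spacer,
         protospacer = protospacer, pam = pam, guide_type = type,
         metadata = metadata),
    class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s [%s]\n  protospacer: %s  PAM: %s\n",
              x$name, x$guide_type, x$protospacer, x$pam))
  invisible(x)
}

.guide_site <- function(guide, reference_id, strand, protospacer_start,
                        pam_start, cut, reference_length) {
  stopifnot(strand %in% c("+", "-"))
  if (cut < 0L || cut > reference_length) {
    .stop_input("cut site %d outside reference [0, %d]", cut,
                reference_length)
  }
  structure(
    list(guide = guide, reference_id = reference_id, strand = strand,
         protospacer_start = as.integer(protospacer_start),
         pam_start = as.integer(pam_start), cut = as.integer(cut),
         reference_length = as.integer(reference_length)),
    class = "guide_site")
}

#' @export
print.guide_site <- function(x, ...) {
  cat(sprintf("<guide_site> %s on %s (%s) protospacer@%d cut@%d\n",
              x$guide$name, x$reference_id, x$strand, x$protospacer_start,
              x$cut))
  invisible(x)
}

#' Locate a guide's protospacer (plus PAM) on a reference
#'
#' Searches both strands for exact matches of protospacer followed by the PAM
#' (N in the PAM matches any base) and reports strand-aware coordinates mapped
#' to the + strand. More than one hit is not an error; the caller decides how
#' to resolve ambiguity.
#'
#' @param reference Reference sequence (character or `DNAString`), A/C/G/T/N.
#' @param guide A [guide_rna()] object.
#' @param reference_id Identifier stored in the returned sites.
#' @return A list of `guide_site` objects (empty if no match). Each site
#'   carries the blunt cut coordinate, 3 nt 5' of the PAM on the protospacer
#'   strand, as a + strand inter-base position.
#' @export
find_protospacer <- function(reference, guide, reference_id = "ref") {
  if (!inherits(guide, "guide_rna")) .stop_input("guide must be a guide_rna")
  ref <- .norm_seq(reference, allow_n = TRUE, what = "reference")
  L <- nchar(ref)
  plen <- nchar(guide$protospacer)
  pam_re <- paste0("^", gsub("N", "[ACGT]", guide$pam, fixed = TRUE), "$")
  sites <- list()

  for (start in .match_starts(ref, guide$protospacer)) {
    pam_start <- start + plen
    if (pam_start + 3L > L) next
    if (!grepl(pam_re, .substr0(ref, pam_start, pam_start + 3L))) next
    sites[[length(sites) + 1L]] <- .guide_site(
      guide, reference_id, "+", start, pam_start, cut = pam_start - 3L,
      reference_length = L)
  }

  rc <- .revcomp(ref)
  for (m in .match_starts(rc, guide$protospacer)) {
    pam_start_rc <- m + plen
    if (pam_start_rc + 3L > L) next
    if (!grepl(pam_re, .substr0(rc, pam_start_rc, pam_start_rc + 3L))) next
    ps_plus <- L - (m + plen)      # protospacer interval on +: [ps_plus, ps_plus+plen)
    pam_start_plus <- ps_plus - 3L # PAM interval on +: [ps_plus-3, ps_plus)
    sites[[length(sites) + 1L]] <- .guide_site(
      guide, reference_id, "-", ps_plus, pam_start_plus,
      cut = ps_plus + 3L, reference_length = L)
  }
  sites
}

#' Blunt Cas9 cut coordinate of a localised guide
#'
#' @param site A `guide_site` from [find_protospacer()].
#' @return Inter-base + strand coordinate: `pam_start - 3` for + strand sites,
#'   `pam_end + 3` for - strand sites.
#' @export
cut_site <- function(site) {
  if (!inherits(site, "guide_site")) .stop_input("site must be a guide_site")
  site$cut
}

#' Predict the fragment deletion produced by a pair of guides
#'
#' The expected dual-guide deletion is the cut-to-cut interval between the two
#' blunt break points; its length decides whether the remaining sequence is in
#' frame (`length %% 3 == 0`) or frameshifted.
#'
#' @param site_a,site_b `guide_site` objects on the same reference with
#'   distinct cut sites.
#' @param cds_frame Optional, unused placeholder for a coding-frame offset
#'   (frame is judged from the deletion length alone).
#' @return A `predicted_deletion` with fields `length`, `interval`
#'   (0-based half-open on +), and `frame_shift`.
#' @export
predict_dual_deletion <- function(site_a, site_b, cds_frame = NULL) {
  if (!inherits(site_a, "guide_site") || !inherits(site_b, "guide_site")) {
    .stop_input("site_a and site_b must be guide_site objects")
  }
  if (site_a$reference_id != site_b$reference_id) {
    .stop_input("sites are on different references (%s vs %s)",
                site_a$reference_id, site_b$reference_id)
  }
  ca <- site_a$cut
  cb <- site_b$cut
  if (ca == cb) .stop_input("cut sites coincide (%d); no deletion predicted", ca)
  len <- abs(ca - cb)
  structure(
    list(site_a = site_a, site_b = site_b, length = len,
         interval = c(min(ca, cb), max(ca, cb)),
         frame_shift = if (len %% 3L == 0L) "in_frame" else "frameshift"),
    class = "predicted_deletion")
}

#' @export
print.predicted_deletion <- function(x, ...) {
  cat(sprintf("<predicted_deletion> %s + %s: %d bp [%d, %d) %s\n",
              x$site_a$guide$name, x$site_b$guide$name, x$length,
              x$interval[1], x$interval[2], x$frame_shift))
  invisible(x)
}
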