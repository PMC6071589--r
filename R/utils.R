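# Internal string/sequence helpers. All public coordinates in the package are
# 0-based, half-open, + strand canonical; cut sites are inter-base integers.

#' @importFrom Biostrings DNAString reverseComplement readDNAStringSet
#'   writeXStringSet DNAStringSet
NULL

.norm_seq <- function(x, allow_n = TRUE, what = "sequence") {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  }
  x <- toupper(x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x)) {
    stop(sprintf("invalid %s: alphabet must be A/C/G/T%s", what,
                 if (allow_n) "/N" else ""), call. = FALSE)
  }
  x
}

# reverse complement of a plain character string (fast path for short strings)
.revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# 0-based half-open substring
.substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# all (possibly overlapping) exact-match 0-based start positions of pat in text
.match_starts <- function(text, pat) {
  n <- nchar(text)
  m <- nchar(pat)
  if (m == 0L || m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  starts[substring(text, starts, starts + m - 1L) == pat] - 1L
}

# longest common prefix length of two strings
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1L]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1L]]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# longest common suffix length of two strings
.lcs <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "", fixed = TRUE)[[1L]])[seq_len(n)]
  bv <- rev(strsplit(b, "", fixed = TRUE)[[1L]])[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

.stop_input <- function(...) {
  stop(errorCondition(sprintf(...), class = c("dualguide_input_error", "error")))
}
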