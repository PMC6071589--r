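# File formats: FASTA (via Biostrings), the trace-TSV dialect, guide tables,
# deletion predictions (TSV/BED), JSON reports and flat run configuration.

#' Read a FASTA file
#' @param path FASTA file.
#' @return Named character vector of uppercased sequences (A/C/G/T/N).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stop_input("no such file: %s", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) .stop_input("malformed FASTA %s: %s",
                                                  path, conditionMessage(e)))
  if (length(set) == 0L) .stop_input("FASTA %s contains no records", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (s in seqs) .norm_seq(s, allow_n = TRUE, what = "FASTA sequence")
  seqs
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a trace matrix from the trace-TSV dialect
#'
#' Expected header `pos A C G T`; `pos` strictly increasing 0-based
#' positions; heights non-negative (scientific notation accepted).
#'
#' @param path TSV file.
#' @param reference_id Identifier to store.
#' @return A [trace_matrix()].
#' @export
read_trace_tsv <- function(path, reference_id = "ref") {
  if (!file.exists(path)) .stop_input("no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("pos", "A", "C", "G", "T")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    .stop_input("trace TSV %s lacks column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) .stop_input("trace TSV %s is empty", path)
  if (any(diff(df$pos) <= 0)) {
    .stop_input("trace positions must be strictly increasing")
  }
  if (any(diff(df$pos) != 1)) {
    .stop_input("trace positions must be contiguous")
  }
  H <- as.matrix(df[, c("A", "C", "G", "T")])
  if (any(H < 0)) .stop_input("negative trace heights in %s", path)
  trace_matrix(H, start = as.integer(df$pos[1]),
               reference_id = reference_id)
}

#' Write a trace matrix in the trace-TSV dialect
#' @param trace A `trace_matrix`.
#' @param path Output path.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "trace_matrix"))
  df <- data.frame(pos = trace$start + seq_len(nrow(trace$heights)) - 1L,
                   trace$heights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide table (name, protospacer, pam, ...)
#'
#' Tab-separated with at least `name`, `protospacer`, `pam`; any further
#' columns are carried along as pass-through metadata on each guide.
#'
#' @param path TSV file.
#' @return List with `table` (data.frame) and `guides` (named list of
#'   [guide_rna()]).
#' @export
read_guides_tsv <- function(path) {
  if (!file.exists(path)) .stop_input("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "protospacer", "pam")
  if (!all(need %in% names(df))) {
    .stop_input("guide TSV needs columns: %s", paste(need, collapse = ", "))
  }
  guides <- lapply(seq_len(nrow(df)), function(i) {
    meta <- as.list(df[i, setdiff(names(df), need), drop = FALSE])
    guide_rna(df$name[i], df$protospacer[i], df$pam[i], metadata = meta)
  })
  names(guides) <- df$name
  list(table = df, guides = guides)
}

#' Write dual-guide deletion predictions as TSV
#'
#' Coordinates in the TSV are 1-based inclusive (human-readable, labelled);
#' use [write_deletions_bed()] for 0-based half-open intervals.
#'
#' @param predictions List of `predicted_deletion`s.
#' @param path Output path.
#' @export
write_deletions_tsv <- function(predictions, path) {
  rows <- lapply(predictions, function(p) {
    data.frame(reference = p$site_a$reference_id,
               guide_a = p$site_a$guide$name, guide_b = p$site_b$guide$name,
               start_1based = p$interval[1] + 1L, end_1based = p$interval[2],
               length_bp = p$length, frame = p$frame_shift,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write predicted deletion intervals as BED (0-based half-open)
#' @param predictions List of `predicted_deletion`s.
#' @param path Output path.
#' @export
write_deletions_bed <- function(predictions, path) {
  lines <- vapply(predictions, function(p) {
    sprintf("%s\t%d\t%d\t%s+%s\t%d\t.", p$site_a$reference_id,
            p$interval[1], p$interval[2], p$site_a$guide$name,
            p$site_b$guide$name, p$length)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a decomposition result as JSON and its spectrum as TSV
#' @param result A `decomposition_result`.
#' @param json_path,tsv_path Output paths (`NULL` to skip either).
#' @export
write_decomposition <- function(result, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(efficiency = result$efficiency, r_squared = result$r_squared,
           degenerate = result$degenerate,
           spectrum = as.list(result$spectrum)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(indel_size = as.integer(names(result$spectrum)),
                     frequency = unname(result$spectrum))
    utils::write.table(df[order(df$indel_size), ], tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}

#' Read a junction table (reference_id, cut, del_start, del_end, insertion)
#' @param path TSV file.
#' @param references Named character vector of reference sequences.
#' @return List of [repair_junction()]s.
#' @export
read_junctions_tsv <- function(path, references) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reference_id", "cut", "del_start", "del_end", "insertion")
  if (!all(need %in% names(df))) {
    .stop_input("junction TSV needs columns: %s", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    rid <- df$reference_id[i]
    if (!rid %in% names(references)) {
      .stop_input("junction references unknown sequence '%s'", rid)
    }
    ins <- df$insertion[i]
    if (is.na(ins) || ins == "." || ins == "-") ins <- ""
    repair_junction(references[[rid]], df$cut[i], df$del_start[i],
                    df$del_end[i], ins)
  })
}

#' Write / read a flat key=value run configuration
#'
#' @param config Named list of scalar values.
#' @param path File path.
#' @return `read_run_config` returns the named list (numbers parsed back to
#'   numeric); round-trips identically for scalar configs.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    paste0(k, "=", format(config[[k]], digits = 17, scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stop_input("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- list()
  for (pair in kv) {
    val <- pair[2]
    num <- suppressWarnings(as.numeric(val))
    out[[pair[1]]] <- if (!is.na(num)) num else val
  }
  out
}
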