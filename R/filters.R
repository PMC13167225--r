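new_filter_report <- function(rule, rs_in, kept_idx, reason, kept_info = NULL) {
  removed_idx <- setdiff(seq_len(nrow(rs_in)), kept_idx)
  reasons <- if (is.function(reason)) as.character(reason(removed_idx))
             else rep_len(as.character(reason), length(removed_idx))
  if (length(removed_idx) == 0L) reasons <- character(0)
  removed <- data.frame(
    record_id = rs_in$record_id[removed_idx],
    reason = reasons,
    stringsAsFactors = FALSE
  )
  rep <- list(rule = rule,
              n_in = nrow(rs_in),
              n_kept = length(kept_idx),
              n_removed = length(removed_idx),
              removed = removed,
              kept_info = kept_info)
  class(rep) <- "filter_report"
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': %d in, %d kept, %d removed\n",
              x$rule, x$n_in, x$n_kept, x$n_removed))
  if (x$n_removed) print(utils::head(x$removed, 10), row.names = FALSE)
  invisible(x)
}

#' Filter records by ungapped sequence length
#'
#' Keeps records whose ungapped length lies inside a window, by default the
#' 500--658 bp window conventional for usable COI-5P barcodes (658 bp is the
#' full Folmer fragment). Bounds are inclusive; alignment gaps do not count
#' toward length.
#'
#' @param rs A [record_set()].
#' @param min_len,max_len Inclusive bounds on ungapped length (bp).
#' @return A list with elements `records` (the kept [record_set()]) and
#'   `report` (a `filter_report`).
#' @export
filter_by_length <- function(rs, min_len = 500L, max_len = 658L) {
  if (min_len > max_len)
    stop("min_len (", min_len, ") exceeds max_len (", max_len, ")")
  len <- ungapped_length(rs$sequence)
  keep <- which(len >= min_len & len <= max_len)
  rep <- new_filter_report(
    sprintf("length_%d_%d", min_len, max_len), rs, keep,
    reason = function(i) sprintf("ungapped length %d outside [%d, %d]",
                                 len[i], min_len, max_len))
  list(records = rs[keep, ], report = rep)
}

#' Translate a nucleotide sequence under the invertebrate mitochondrial code
#'
#' Translation uses NCBI genetic code table 5 (invertebrate mitochondrial),
#' the appropriate code for insect COI: `TGA` is tryptophan, `AGA`/`AGG`
#' are serine, `ATA` is methionine, and only `TAA`/`TAG` are stops. Codons
#' containing any ambiguity symbol translate to `"X"` and therefore never
#' count as stops. A trailing partial codon is ignored; gaps are stripped
#' before translation.
#'
#' @param sequence A single nucleotide string.
#' @param frame_offset Reading-frame offset: 0, 1 or 2 skipped leading bases.
#' @return The amino-acid string (`"*"` marks a stop codon).
#' @export
translate_dna <- function(sequence, frame_offset = 0L) {
  stopifnot(length(sequence) == 1L, frame_offset %in% 0:2)
  s <- frame_codon_string(gsub("-", "", toupper(sequence), fixed = TRUE),
                          frame_offset)
  if (!nzchar(s)) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode("5"),
    if.fuzzy.codon = "X"))
}

# trim an ungapped sequence to its in-frame, whole-codon part
frame_codon_string <- function(s, frame_offset) {
  s <- substring(s, frame_offset + 1L)
  n <- (nchar(s) %/% 3L) * 3L
  substring(s, 1L, n)
}

# stop-codon counts for all records x 3 frames; vectorized over records
stop_count_matrix <- function(sequences) {
  ung <- gsub("-", "", toupper(sequences), fixed = TRUE)
  gc5 <- Biostrings::getGeneticCode("5")
  out <- matrix(NA_integer_, nrow = length(ung), ncol = 3L,
                dimnames = list(NULL, paste0("frame", 0:2)))
  for (f in 0:2) {
    trimmed <- vapply(ung, frame_codon_string, "", frame_offset = f,
                      USE.NAMES = FALSE)
    nz <- nzchar(trimmed)
    counts <- integer(length(trimmed))
    if (any(nz)) {
      aa <- Biostrings::translate(Biostrings::DNAStringSet(trimmed[nz]),
                                  genetic.code = gc5, if.fuzzy.codon = "X")
      counts[nz] <- Biostrings::vcountPattern("*", aa, fixed = TRUE)
    }
    out[, f + 1L] <- counts
  }
  out
}

#' Screen records for stop codons (NUMT filter)
#'
#' Translates each record's ungapped sequence in all three reading-frame
#' offsets and keeps it if at least one frame is stop-free. BOLD exports do
#' not announce the reading frame, so requiring a single fixed frame would
#' remove genuine barcodes; a sequence with stops in *every* frame, on the
#' other hand, cannot be a functional COI fragment and is the classic
#' signature of a nuclear mitochondrial pseudogene (NUMT). The minimal-stop
#' frame of each kept record is reported in `report$kept_info`.
#'
#' @param rs A [record_set()].
#' @return A list with `records` (kept set) and `report`; `report$kept_info`
#'   is a data frame of `record_id` and chosen `frame`.
#' @export
screen_stop_codons <- function(rs) {
  stops <- stop_count_matrix(rs$sequence)
  minstop <- apply(stops, 1L, min)
  keep <- which(minstop == 0L)
  frame <- max.col(-stops, ties.method = "first") - 1L
  kept_info <- data.frame(record_id = rs$record_id[keep],
                          frame = frame[keep], stringsAsFactors = FALSE)
  rep <- new_filter_report(
    "stop_codons", rs, keep,
    reason = function(i) sprintf("stop codons in all frames (min %d)",
                                 minstop[i]),
    kept_info = kept_info)
  list(records = rs[keep, ], report = rep)
}

#' Remove records named on a curation exclusion list
#'
#' The curation loop never deletes records automatically: non-monophyly and
#' distance anomalies are reviewed (see [intruder_report()]), and the
#' reviewer's decisions arrive here as an explicit list of ids. Unknown ids
#' produce a warning, not an error.
#'
#' @param rs A [record_set()].
#' @param excluded_ids Character vector of record ids to drop.
#' @return A list with `records` (reduced set) and `report` (reason
#'   `"curation"` for each removal).
#' @export
apply_exclusion_list <- function(rs, excluded_ids) {
  excluded_ids <- unique(as.character(excluded_ids))
  unknown <- setdiff(excluded_ids, rs$record_id)
  if (length(unknown))
    warning("exclusion list ids not in record set: ",
            paste(unknown, collapse = ", "))
  keep <- which(!rs$record_id %in% excluded_ids)
  rep <- new_filter_report("exclusion_list", rs, keep, reason = "curation")
  list(records = rs[keep, ], report = rep)
}

#' Write filter reports as a TSV audit trail
#'
#' @param reports A list of `filter_report` objects.
#' @param path Output TSV path (columns rule, record_id, reason).
#' @return Invisibly, the combined data frame.
#' @export
write_filter_reports <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    if (r$n_removed == 0L)
      return(data.frame(rule = character(0), record_id = character(0),
                        reason = character(0)))
    cbind(rule = r$rule, r$removed)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
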