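#' Construct a barcode record set
#'
#' A `record_set` is the central container of the package: a data frame with
#' one row per specimen record, carrying the identifier, species label,
#' optional BIN label, the (possibly aligned) nucleotide sequence and
#' provenance metadata. Sequences use the IUPAC nucleotide alphabet plus
#' `"-"` for alignment gaps.
#'
#' @param record_id Character vector of unique record identifiers.
#' @param species_label Character vector of binomial species labels
#'   (`NA` allowed; such records are carried but flagged downstream).
#' @param sequence Character vector of nucleotide strings over
#'   `A C G T R Y S W K M B D H V N -` (case-insensitive; stored upper case).
#' @param bin_label,country,project Optional per-record metadata (`NA` allowed).
#' @param marker Marker name, by convention `"COI-5P"`.
#' @param aligned Logical; `TRUE` asserts that all sequences have equal
#'   length and columns are homologous sites. Verified when set.
#'
#' @return A data frame of class `record_set` with columns `record_id`,
#'   `species_label`, `bin_label`, `sequence`, `country`, `project`,
#'   `marker`, and an `aligned` attribute.
#' @seealso [read_dataset()], [check_alignment()]
#' @export
record_set <- function(record_id, species_label, sequence,
                       bin_label = NA_character_, country = NA_character_,
                       project = NA_character_, marker = "COI-5P",
                       aligned = FALSE) {
  record_id <- as.character(record_id)
  sequence <- toupper(as.character(sequence))
  n <- length(record_id)
  if (length(sequence) != n)
    stop("record_id and sequence must have the same length")
  if (anyDuplicated(record_id))
    stop("duplicate record ids: ",
         paste(unique(record_id[duplicated(record_id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for record(s): ",
         paste(record_id[!nzchar(sequence)], collapse = ", "))
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", sequence)
  if (any(bad))
    stop("sequence contains non-IUPAC symbols for record(s): ",
         paste(record_id[bad], collapse = ", "))
  rs <- data.frame(
    record_id = record_id,
    species_label = rep_len(as.character(species_label), n),
    bin_label = rep_len(as.character(bin_label), n),
    sequence = sequence,
    country = rep_len(as.character(country), n),
    project = rep_len(as.character(project), n),
    marker = rep_len(as.character(marker), n),
    stringsAsFactors = FALSE
  )
  class(rs) <- c("record_set", "data.frame")
  if (isTRUE(aligned)) rs <- check_alignment(rs) else attr(rs, "aligned") <- FALSE
  rs
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("record_set: %d records, %d species%s\n",
              nrow(x), length(unique(stats::na.omit(x$species_label))),
              if (isTRUE(attr(x, "aligned")))
                sprintf(", aligned (%d columns)", nchar(x$sequence[1]))
              else ", not verified aligned"))
  if (nrow(x)) {
    show <- utils::head(x[, c("record_id", "species_label", "bin_label")], 6)
    show$length <- ungapped_length(utils::head(x$sequence, 6))
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > 6) cat("...\n")
  }
  invisible(x)
}

# subsetting keeps the class and alignment flag
#' @export
`[.record_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("record_id", "sequence") %in% names(out))) {
    class(out) <- c("record_set", "data.frame")
    attr(out, "aligned") <- attr(x, "aligned")
  }
  out
}

#' Ungapped sequence length
#'
#' Number of non-gap symbols in each sequence. Alignment gaps (`"-"`) are
#' artifacts of the alignment, not sequence, so all length-based filtering
#' operates on this quantity.
#'
#' @param sequence Character vector of (possibly gapped) sequences.
#' @return Integer vector of ungapped lengths.
#' @export
ungapped_length <- function(sequence) {
  nchar(gsub("-", "", sequence, fixed = TRUE))
}

#' Verify that a record set is aligned
#'
#' Checks that all sequences have equal (gapped) length and marks the set as
#' aligned. The package does not align sequences itself: inputs are expected
#' pre-aligned (e.g. by the BOLD aligner), and this is the gate that
#' enforces it.
#'
#' @param rs A [record_set()].
#' @return `rs` with the `aligned` attribute set to `TRUE`.
#' @export
check_alignment <- function(rs) {
  if (nrow(rs) == 0L) stop("no records")
  lens <- unique(nchar(rs$sequence))
  if (length(lens) > 1L)
    stop("sequences are not aligned: lengths {",
         paste(sort(lens), collapse = ", "),
         "} differ; supply pre-aligned input")
  attr(rs, "aligned") <- TRUE
  rs
}

is_aligned <- function(rs) isTRUE(attr(rs, "aligned"))

require_aligned <- function(rs) {
  if (!is_aligned(rs))
    stop("record set must be aligned; run check_alignment() first")
  invisible(rs)
}
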