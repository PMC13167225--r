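#' Read a barcode dataset from FASTA plus metadata TSV
#'
#' Reads a BOLD-style export: a FASTA file of COI-5P sequences and a
#' tab-separated metadata table keyed by record id. Every FASTA entry must
#' have a metadata row; metadata rows without a sequence are reported via
#' the `unmatched_metadata` attribute but do not error. Records whose
#' species label is missing are kept and flagged (attribute
#' `missing_species`), never silently dropped.
#'
#' @param fasta_path Path to a FASTA file (single-line or wrapped). The
#'   record id is the first whitespace-delimited token of each header.
#' @param metadata_path Path to a UTF-8 TSV with a header row.
#' @param col_map Named list mapping the canonical column roles
#'   (`record_id`, `species_label`, `bin_label`, `country`, `project`) to
#'   the column names used in the file. Roles absent from the file other
#'   than `record_id` and `species_label` are filled with `NA`.
#' @return A [record_set()] (not yet marked aligned).
#' @export
read_dataset <- function(fasta_path, metadata_path,
                         col_map = list(record_id = "record_id",
                                        species_label = "species_label",
                                        bin_label = "bin_label",
                                        country = "country",
                                        project = "project")) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- utils::read.delim(metadata_path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            fileEncoding = "UTF-8")
  idc <- col_map$record_id
  spc <- col_map$species_label
  if (is.null(idc) || !idc %in% names(meta))
    stop("metadata lacks a record id column ('", idc, "')")
  if (is.null(spc) || !spc %in% names(meta))
    stop("metadata lacks a species_label column ('", spc, "')")
  mid <- as.character(meta[[idc]])
  if (anyDuplicated(mid))
    stop("duplicate metadata ids: ",
         paste(unique(mid[duplicated(mid)]), collapse = ", "))
  orphans <- setdiff(ids, mid)
  if (length(orphans))
    stop("FASTA ids absent from metadata: ", paste(orphans, collapse = ", "))
  row <- match(ids, mid)
  getcol <- function(role) {
    nm <- col_map[[role]]
    if (!is.null(nm) && nm %in% names(meta)) as.character(meta[[nm]])[row]
    else rep(NA_character_, length(ids))
  }
  rs <- record_set(
    record_id = ids,
    species_label = getcol("species_label"),
    sequence = as.character(seqs),
    bin_label = getcol("bin_label"),
    country = getcol("country"),
    project = getcol("project")
  )
  miss <- rs$record_id[is.na(rs$species_label) | !nzchar(rs$species_label)]
  if (length(miss)) {
    warning(length(miss), " record(s) lack a species label: ",
            paste(utils::head(miss, 5), collapse = ", "),
            if (length(miss) > 5) ", ...")
    attr(rs, "missing_species") <- miss
  }
  attr(rs, "unmatched_metadata") <- setdiff(mid, ids)
  rs
}

#' Write a record set as FASTA plus metadata TSV
#'
#' Inverse of [read_dataset()]: emits the sequences (one line each) and the
#' metadata columns in the canonical dialect.
#'
#' @param rs A [record_set()].
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `rs`.
#' @export
write_dataset <- function(rs, fasta_path, metadata_path) {
  x <- Biostrings::DNAStringSet(rs$sequence)
  names(x) <- rs$record_id
  Biostrings::writeXStringSet(x, fasta_path, width = 20000L)
  meta <- rs[, c("record_id", "species_label", "bin_label", "country",
                 "project")]
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(rs)
}
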