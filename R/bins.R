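#' Classify BINs by concordance with species labels
#'
#' Each distinct BIN label is classified as `singleton` (one record —
#' concordance unassessable, and this takes precedence), `concordant`
#' (two or more records, all carrying the same species label) or
#' `discordant` (two or more records spanning several species). Records
#' lacking a species label are counted in `n_records` and flagged via
#' `has_unassigned_records`, but do not enter `species_set`. Records
#' without a BIN are tallied separately (`n_unassigned_records`), never
#' guessed into a cluster.
#'
#' @param rs A [record_set()].
#' @return A list of class `bin_report`: `bins` (per-BIN data frame),
#'   `counts`, `percentages` (of distinct BINs, 2 decimals),
#'   `n_bins`, `n_unassigned_records`.
#' @export
bin_concordance <- function(rs) {
  has_bin <- !is.na(rs$bin_label) & nzchar(rs$bin_label)
  sub <- rs[has_bin, ]
  bins <- sort(unique(sub$bin_label))
  per <- lapply(bins, function(b) {
    rows <- sub[sub$bin_label == b, ]
    spp <- sort(unique(rows$species_label[!is.na(rows$species_label) &
                                            nzchar(rows$species_label)]))
    cls <- if (nrow(rows) == 1L) "singleton"
           else if (length(spp) <= 1L) "concordant"
           else "discordant"
    data.frame(bin_label = b, n_records = nrow(rows),
               n_species = length(spp),
               species_list = paste(spp, collapse = "/"),
               has_unassigned_records = any(is.na(rows$species_label) |
                                              !nzchar(rows$species_label)),
               class = cls, stringsAsFactors = FALSE)
  })
  bins_df <- if (length(per)) do.call(rbind, per) else
    data.frame(bin_label = character(0), n_records = integer(0),
               n_species = integer(0), species_list = character(0),
               has_unassigned_records = logical(0), class = character(0))
  counts <- c(concordant = sum(bins_df$class == "concordant"),
              discordant = sum(bins_df$class == "discordant"),
              singleton = sum(bins_df$class == "singleton"))
  pct <- if (nrow(bins_df)) round(100 * counts / nrow(bins_df), 2) else
    counts * NA_real_
  out <- list(bins = bins_df, counts = counts, percentages = pct,
              n_bins = nrow(bins_df),
              n_unassigned_records = sum(!has_bin))
  class(out) <- "bin_report"
  out
}

#' @export
print.bin_report <- function(x, ...) {
  cat(sprintf("BIN concordance: %d distinct BINs\n", x$n_bins))
  for (cl in names(x$counts))
    cat(sprintf("  %-10s %4d (%.2f%%)\n", cl, x$counts[cl],
                x$percentages[cl]))
  if (x$n_unassigned_records)
    cat(sprintf("  %d record(s) without a BIN label\n",
                x$n_unassigned_records))
  disc <- x$bins[x$bins$class == "discordant", ]
  if (nrow(disc))
    cat("discordant:",
        paste(sprintf("%s (%s)", disc$bin_label, disc$species_list),
              collapse = "; "), "\n")
  invisible(x)
}

#' Per-species BIN multiplicity summary
#'
#' For each species: how many distinct BINs its records fall into, which
#' ones, and whether any of its records lacks a BIN. The summary counts
#' (single-BIN, multi-BIN, no-BIN species) are attached as the `summary`
#' attribute.
#'
#' @param rs A [record_set()].
#' @return A data frame with columns `species`, `n_records`, `n_bins`,
#'   `bins_list`, `has_unassigned_records`.
#' @export
species_bin_summary <- function(rs) {
  has_sp <- !is.na(rs$species_label) & nzchar(rs$species_label)
  sub <- rs[has_sp, ]
  spp <- sort(unique(sub$species_label))
  rows <- lapply(spp, function(s) {
    r <- sub[sub$species_label == s, ]
    b <- unique(r$bin_label[!is.na(r$bin_label) & nzchar(r$bin_label)])
    data.frame(species = s, n_records = nrow(r), n_bins = length(b),
               bins_list = paste(sort(b), collapse = ","),
               has_unassigned_records = any(is.na(r$bin_label) |
                                              !nzchar(r$bin_label)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), n_records = integer(0),
               n_bins = integer(0), bins_list = character(0),
               has_unassigned_records = logical(0))
  attr(out, "summary") <- c(
    single_bin = sum(out$n_bins == 1L),
    multi_bin = sum(out$n_bins > 1L),
    no_bin = sum(out$n_bins == 0L))
  out
}
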