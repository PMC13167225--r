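collapse_list_col <- function(x) {
  vapply(x, function(v) paste(v, collapse = ","), "")
}

write_pass_reports <- function(pass, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # species summary (Table-1 shape)
  sp <- as.data.frame(table(pass$records$species_label),
                      stringsAsFactors = FALSE)
  names(sp) <- c("species", "n_barcodes")
  utils::write.table(sp[order(sp$species), ],
                     file.path(dir, "species_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # anomaly table (Table-2 shape)
  an <- as.data.frame(pass$anomalies)
  an$tied_groups <- collapse_list_col(an$tied_groups)
  an$intra_dmax <- round(an$intra_dmax, 2)
  an$dmin_nn <- round(an$dmin_nn, 2)
  names(an)[names(an) == "group"] <- "species"
  utils::write.table(an, file.path(dir, "anomaly_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_haplotype_table(pass$haplotypes, file.path(dir, "haplotypes.tsv"))
  write_monophyly_report(pass$monophyly, file.path(dir, "monophyly.tsv"))
  utils::write.table(pass$bins$bins, file.path(dir, "bin_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(pass$species_bins),
                     file.path(dir, "species_bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pass$distributions,
                     file.path(dir, "distribution_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_filter_reports(pass$filter_reports,
                       file.path(dir, "filter_report.tsv"))
  ape::write.tree(pass$tree, file.path(dir, "tree.nwk"))
  manifest <- pass$manifest
  if (inherits(pass$richness, "richness_cor"))
    manifest$richness_pearson <- pass$richness[c("r", "n", "p_value")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write the full report bundle of a curation run
#'
#' Emits, per pass, the TSV reports (species summary, anomaly table with
#' monophyly status, haplotype table, monophyly report, BIN report,
#' species-BIN summary, distribution summaries, filter audit trail), the
#' tree used (newick) and a JSON manifest of dataset-level counts; plus,
#' for two-pass runs, a TSV diff of monophyly statuses. Reports contain no
#' timestamps, so re-running an identical configuration reproduces them
#' byte for byte.
#'
#' @param bundle A `barcode_curation` from [curate_barcodes()].
#' @param outdir Output directory (created; must be writable).
#' @return Invisibly, `outdir`.
#' @export
write_reports <- function(bundle, outdir) {
  if (!inherits(bundle, "barcode_curation") || is.null(bundle$pass1))
    stop("empty or invalid bundle; run curate_barcodes() first")
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  write_pass_reports(bundle$pass1, file.path(outdir, "pass1"))
  if (!is.null(bundle$pass2)) {
    write_pass_reports(bundle$pass2, file.path(outdir, "pass2"))
    utils::write.table(bundle$diff, file.path(outdir, "monophyly_diff.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
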