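#' Records usable for haplotype analysis
#'
#' Keeps exactly the records whose aligned sequence consists of unambiguous
#' bases only (`A`, `C`, `G`, `T`). Records carrying IUPAC ambiguity codes,
#' `N`s or alignment gaps cannot be assigned to an exact-match haplotype
#' class and are excluded here (they still count toward sampling effort in
#' [count_haplotypes()]).
#'
#' @param rs An aligned [record_set()].
#' @return The usable subset, still a [record_set()].
#' @export
usable_records <- function(rs) {
  require_aligned(rs)
  rs[grepl("^[ACGT]+$", rs$sequence), ]
}

#' Count distinct haplotypes per species
#'
#' Haplotypes are equivalence classes under exact string equality of the
#' full aligned sequence, computed among usable records (see
#' [usable_records()]) within each group. `n_records` counts all records of
#' the group, usable or not, so it can serve as the sampling-effort axis;
#' `n_usable` counts only those entering haplotype classes.
#'
#' @param rs An aligned [record_set()] (may still contain ambiguous
#'   records; they are excluded from haplotype classes internally).
#' @param group_by `"species"` for per-species counts or `"all"` for a
#'   single pooled group.
#' @return A data frame of class `haplotype_table` with columns `group`,
#'   `n_records`, `n_usable`, `n_haplotypes`; the `members` attribute maps
#'   each group to a list of haplotype member-id vectors.
#' @export
count_haplotypes <- function(rs, group_by = c("species", "all")) {
  group_by <- match.arg(group_by)
  require_aligned(rs)
  grp <- if (group_by == "species") rs$species_label else rep("all", nrow(rs))
  grp[is.na(grp)] <- "<unlabeled>"
  usable <- grepl("^[ACGT]+$", rs$sequence)
  groups <- sort(unique(grp))
  members <- stats::setNames(vector("list", length(groups)), groups)
  tab <- data.frame(group = groups,
                    n_records = NA_integer_,
                    n_usable = NA_integer_,
                    n_haplotypes = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(groups)) {
    in_g <- grp == groups[k]
    use <- in_g & usable
    mem <- split(rs$record_id[use], rs$sequence[use])
    names(mem) <- NULL
    members[[k]] <- mem
    tab$n_records[k] <- sum(in_g)
    tab$n_usable[k] <- sum(use)
    tab$n_haplotypes[k] <- length(mem)
  }
  attr(tab, "members") <- members
  attr(tab, "group_by") <- group_by
  class(tab) <- c("haplotype_table", "data.frame")
  tab
}

#' Correlate haplotype richness with sampling effort
#'
#' Pearson correlation between per-species record counts and haplotype
#' counts, with the usual two-sided p-value from the t transform (via
#' [stats::cor.test()]). In well-sampled barcode libraries richness tracks
#' effort strongly, so a weak correlation is itself a diagnostic.
#'
#' @param table A `haplotype_table` from [count_haplotypes()] at species
#'   grouping.
#' @param effort Which column measures effort: all records
#'   (`"n_records"`, default) or usable records only (`"n_usable"`).
#' @return A list of class `richness_cor` with elements `r`, `n`,
#'   `p_value`.
#' @export
richness_vs_effort <- function(table, effort = c("n_records", "n_usable")) {
  effort <- match.arg(effort)
  x <- table[[effort]]
  y <- table$n_haplotypes
  keep <- x > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 species with records for a defined p-value")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in ", if (stats::var(x) == 0) effort else
         "n_haplotypes", "; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  out <- list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
  class(out) <- "richness_cor"
  out
}

#' @export
print.richness_cor <- function(x, ...) {
  cat(sprintf("richness vs effort: Pearson r = %.4f, N = %d, p = %.3g\n",
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Write a haplotype table as TSV
#'
#' @param table A `haplotype_table`.
#' @param path Output path.
#' @return Invisibly, `table`.
#' @export
write_haplotype_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
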