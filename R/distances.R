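#' Uncorrected p-distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or any non-`ACGT` symbol are
#' excluded (pairwise deletion); the distance is the proportion of
#' mismatches among the remaining compared sites. No multiple-hit
#' correction is applied — for barcode-gap work the raw proportion is the
#' conventional statistic.
#'
#' @param a,b Aligned sequences of equal length (character scalars).
#' @return A list with `distance` (proportion, `NA` if no comparable
#'   sites), `n_sites` (compared sites) and `comparable` (logical).
#' @export
p_distance <- function(a, b) {
  a <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length (", length(a), " vs ",
         length(b), ")")
  acgt <- c("A", "C", "G", "T")
  ok <- a %in% acgt & b %in% acgt
  n <- sum(ok)
  if (n == 0L)
    return(list(distance = NA_real_, n_sites = 0L, comparable = FALSE))
  list(distance = sum(a[ok] != b[ok]) / n, n_sites = n, comparable = TRUE)
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' Computes all unordered pairs of [p_distance()] over an aligned record
#' set. Internally the computation is expressed as indicator-matrix
#' products (one 0/1 matrix per base, one validity matrix), so the result
#' is exactly the naive per-pair site enumeration, evaluated in a handful
#' of BLAS calls; mismatch and compared-site counts are integers, so no
#' floating-point drift separates the two formulations.
#'
#' @param rs An aligned [record_set()] with at least 2 records.
#' @return A list of class `pdist` with `ids`, `d` (symmetric matrix of
#'   proportions, `NA` where a pair shares no comparable site) and `sites`
#'   (matrix of compared-site counts).
#' @export
distance_matrix <- function(rs) {
  require_aligned(rs)
  n <- nrow(rs)
  if (n < 2L) stop("need at least 2 records for a distance matrix")
  M <- do.call(rbind, strsplit(toupper(rs$sequence), "", fixed = TRUE))
  V <- matrix(as.numeric(M %in% c("A", "C", "G", "T")), nrow = n)
  S <- V %*% t(V)   # compared sites per pair
  match <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    Ib <- matrix(as.numeric(M == b), nrow = n)
    match <- match + Ib %*% t(Ib)
  }
  D <- (S - match) / S
  D[S == 0] <- NA_real_
  diag(D) <- ifelse(diag(S) > 0, 0, NA_real_)
  dimnames(D) <- dimnames(S) <- list(rs$record_id, rs$record_id)
  out <- list(ids = rs$record_id, d = D, sites = matrix(as.integer(S), n, n,
              dimnames = dimnames(S)))
  class(out) <- "pdist"
  out
}

#' @export
print.pdist <- function(x, ...) {
  n <- length(x$ids)
  offd <- x$d[upper.tri(x$d)]
  cat(sprintf("pdist: %d records, %d pairs (%d incomparable)\n",
              n, length(offd), sum(is.na(offd))))
  if (any(!is.na(offd)))
    cat(sprintf("  p-distance range %.4f - %.4f\n",
                min(offd, na.rm = TRUE), max(offd, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.matrix.pdist <- function(x, ...) x$d

# normalize a grouping argument into a character vector aligned with dm$ids
resolve_grouping <- function(dm, grouping) {
  if (is.null(names(grouping))) {
    if (length(grouping) != length(dm$ids))
      stop("grouping must be named by record id or match the matrix order")
    g <- as.character(grouping)
  } else {
    miss <- setdiff(dm$ids, names(grouping))
    if (length(miss))
      stop("grouping lacks labels for: ", paste(utils::head(miss, 5),
                                                collapse = ", "))
    g <- as.character(grouping[dm$ids])
  }
  g
}

# convenience: record_set -> named grouping vector
species_grouping <- function(rs) {
  stats::setNames(ifelse(is.na(rs$species_label), "<unlabeled>",
                         rs$species_label), rs$record_id)
}

bin_grouping <- function(rs) {
  g <- stats::setNames(rs$bin_label, rs$record_id)
  g[!is.na(g)]
}

#' Maximum intraspecific distance per group
#'
#' For each group label, the maximum p-distance over within-group pairs,
#' reported in percent. Singleton groups (no within pair) yield `NA`.
#' Incomparable pairs (zero shared sites) are skipped.
#'
#' @param dm A `pdist` from [distance_matrix()].
#' @param grouping Character vector of group labels, named by record id
#'   (or unnamed in matrix order).
#' @return Named numeric vector of intra-group maxima (percent).
#' @export
group_dmax <- function(dm, grouping) {
  g <- resolve_grouping(dm, grouping)
  groups <- sort(unique(g))
  out <- stats::setNames(rep(NA_real_, length(groups)), groups)
  for (gr in groups) {
    idx <- which(g == gr)
    if (length(idx) < 2L) next
    sub <- dm$d[idx, idx]
    vals <- sub[upper.tri(sub)]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[gr] <- 100 * max(vals)
  }
  out
}

#' Nearest-neighbor group and minimum between-group distance
#'
#' For each group, the minimum p-distance from any of its records to any
#' record outside the group (Dmin_NN, in percent), and the group attaining
#' it. Ties on the minimum are broken toward the lexicographically smallest
#' group label; all tied groups are kept in the `tied_groups` list column.
#'
#' @inheritParams group_dmax
#' @return A data frame with columns `group`, `nn_group`, `dmin_nn`
#'   (percent) and list column `tied_groups`.
#' @export
nearest_neighbor <- function(dm, grouping) {
  g <- resolve_grouping(dm, grouping)
  groups <- sort(unique(g))
  if (length(groups) < 2L)
    stop("need at least 2 groups for nearest-neighbor distances")
  out <- data.frame(group = groups, nn_group = NA_character_,
                    dmin_nn = NA_real_, stringsAsFactors = FALSE)
  ties <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    inside <- g == groups[k]
    sub <- dm$d[inside, !inside, drop = FALSE]
    if (all(is.na(sub))) next   # no comparable cross pair
    m <- min(sub, na.rm = TRUE)
    hit_cols <- which(apply(sub, 2L, function(col) any(!is.na(col) & col == m)))
    nn <- sort(unique(g[!inside][hit_cols]))
    out$nn_group[k] <- nn[1]
    out$dmin_nn[k] <- 100 * m
    ties[[k]] <- nn
  }
  out$tied_groups <- ties
  out
}

#' Per-group barcode-gap summary
#'
#' Combines [group_dmax()] and [nearest_neighbor()] into one table per
#' group: record count, maximum intraspecific distance, nearest-neighbor
#' group and distance (all distances in percent).
#'
#' @inheritParams group_dmax
#' @return A data frame of class `group_distance_summary` with columns
#'   `group`, `n`, `intra_dmax`, `nn_group`, `dmin_nn`, `tied_groups`.
#' @export
group_distance_summary <- function(dm, grouping) {
  g <- resolve_grouping(dm, grouping)
  dmax <- group_dmax(dm, grouping)
  nn <- nearest_neighbor(dm, grouping)
  out <- data.frame(group = nn$group,
                    n = as.integer(table(g)[nn$group]),
                    intra_dmax = unname(dmax[nn$group]),
                    nn_group = nn$nn_group,
                    dmin_nn = nn$dmin_nn,
                    stringsAsFactors = FALSE)
  out$tied_groups <- nn$tied_groups
  class(out) <- c("group_distance_summary", "data.frame")
  out
}

#' Flag distance anomalies
#'
#' Two rules define an anomalous group: `NN_below_threshold` when the
#' nearest neighbor is less than `threshold_percent` divergent (default
#' 2%), and `gap_violation` when the distance to the nearest neighbor is
#' smaller than the group's own maximum intraspecific distance (a collapsed
#' barcode gap). Either flag marks the group for manual review.
#'
#' @param summaries A `group_distance_summary` (species grouping).
#' @param threshold_percent Divergence threshold in percent.
#' @return The flagged subset with logical columns `NN_below_threshold`,
#'   `gap_violation`; the full annotated table is in attribute `all`.
#' @export
anomaly_flags <- function(summaries, threshold_percent = 2.0) {
  stopifnot(threshold_percent > 0)
  s <- as.data.frame(summaries)
  s$NN_below_threshold <- !is.na(s$dmin_nn) & s$dmin_nn < threshold_percent
  s$gap_violation <- !is.na(s$intra_dmax) & !is.na(s$dmin_nn) &
    s$dmin_nn < s$intra_dmax
  flagged <- s[s$NN_below_threshold | s$gap_violation, , drop = FALSE]
  rownames(flagged) <- NULL
  attr(flagged, "all") <- s
  attr(flagged, "threshold_percent") <- threshold_percent
  flagged
}

#' Distribution summaries of barcode-gap statistics
#'
#' Five-number-plus-mean summaries (min, Q1, median, Q3, max, mean; linear
#' interpolation quantiles, type 7) of the per-group `intra_dmax` and
#' `dmin_nn` value sets under a species grouping and a BIN grouping —
#' the numbers behind violin/box displays of within- versus between-group
#' divergence. `NA` values (singletons, incomparable groups) are dropped.
#'
#' @param dm A `pdist`.
#' @param grouping_species,grouping_bin Groupings as in [group_dmax()].
#'   `grouping_bin` may cover a subset of records (records without a BIN
#'   are ignored for the BIN categories).
#' @return A data frame with one row per category
#'   (`species_dmax`, `species_dmin_nn`, `bin_dmax`, `bin_dmin_nn`).
#' @export
distribution_summaries <- function(dm, grouping_species, grouping_bin = NULL) {
  summarize <- function(v, category) {
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(category = category, n = 0L, min = NA_real_,
                        q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                        max = NA_real_, mean = NA_real_))
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    data.frame(category = category, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5], mean = mean(v))
  }
  sp <- group_distance_summary(dm, grouping_species)
  out <- rbind(summarize(sp$intra_dmax, "species_dmax"),
               summarize(sp$dmin_nn, "species_dmin_nn"))
  if (!is.null(grouping_bin) && length(unique(grouping_bin)) >= 2L) {
    keep <- dm$ids %in% names(grouping_bin)
    sub <- subset_pdist(dm, keep)
    bn <- group_distance_summary(sub, grouping_bin[sub$ids])
    out <- rbind(out, summarize(bn$intra_dmax, "bin_dmax"),
                 summarize(bn$dmin_nn, "bin_dmin_nn"))
  }
  rownames(out) <- NULL
  out
}

subset_pdist <- function(dm, keep) {
  out <- list(ids = dm$ids[keep], d = dm$d[keep, keep, drop = FALSE],
              sites = dm$sites[keep, keep, drop = FALSE])
  class(out) <- "pdist"
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm A `pdist`.
#' @param path Output path. `NA` (incomparable) entries are written as -1.
#' @return Invisibly, `dm`.
#' @export
write_phylip_dist <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$ids)), con)
  d <- dm$d
  d[is.na(d)] <- -1
  for (i in seq_along(dm$ids))
    writeLines(paste(c(format(dm$ids[i], width = 10),
                       sprintf("%.6f", d[i, ])), collapse = "  "), con)
  invisible(dm)
}
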