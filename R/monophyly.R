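#' Parse a newick tree
#'
#' Thin wrapper over [ape::read.tree()] with stricter error reporting:
#' unbalanced parentheses are located by character position, a missing
#' terminal semicolon is diagnosed, and duplicate tip labels are rejected
#' (monophyly assessment needs tips to identify records uniquely). The tree
#' is kept rooted-as-written: the outermost node of the newick string is
#' the root.
#'
#' @param text A newick string, or `NULL` when `file` is given.
#' @param file Path to a newick file.
#' @return An [ape] `phylo` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L)
    stop("newick parse error: ", depth,
         " unclosed '(' at end-of-input (position ", length(chars), ")")
  if (!endsWith(text, ";"))
    stop("newick parse error: missing terminating ';' at position ",
         nchar(text))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error: malformed tree")
  if (anyDuplicated(tree$tip.label))
    stop("newick parse error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Map tree tips to taxa
#'
#' Resolves each tip label to a taxon name. A metadata mapping (named
#' vector, record id to species label) takes precedence; otherwise
#' composite labels of the form `ProcessID.Taxon_name` are split at the
#' first `"."`. Tips that match neither route are returned in
#' `unresolved`, never guessed.
#'
#' @param tree A `phylo`.
#' @param metadata Optional named character vector (names = tip labels /
#'   record ids, values = taxon names).
#' @param split Separator for composite labels (first occurrence splits).
#' @return A list with `mapping` (named character vector over resolved
#'   tips) and `unresolved` (character vector of tips).
#' @export
map_tips_to_taxa <- function(tree, metadata = NULL, split = ".") {
  tips <- tree$tip.label
  out <- stats::setNames(rep(NA_character_, length(tips)), tips)
  if (!is.null(metadata)) {
    hit <- tips %in% names(metadata)
    out[hit] <- unname(metadata[tips[hit]])
  }
  need <- is.na(out)
  if (any(need)) {
    pos <- regexpr(split, tips[need], fixed = TRUE)
    ok <- pos > 0L
    out[need][ok] <- substring(tips[need][ok], pos[ok] + nchar(split))
  }
  list(mapping = out[!is.na(out)], unresolved = tips[is.na(out)])
}

# tips descending from an internal node (or the tip itself)
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# foreign tips under the MRCA of 'tips'; assumes length(tips) >= 2
intruders_of <- function(tree, tips) {
  mrca <- ape::getMRCA(tree, tips)
  setdiff(clade_tips(tree, mrca), tips)
}

#' Assess per-taxon monophyly on a rooted tree
#'
#' A taxon with two or more tips is monophyletic when the most recent
#' common ancestor (MRCA) of its tips has no descendant tip belonging to
#' another taxon; otherwise those foreign tips are its intruders. Taxa
#' with exactly one tip are singletons (monophyly unassessable) and taxa
#' with no tips are absent. The tree is assessed as rooted-as-read; an
#' optional midpoint rooting is available via [curate_barcodes()] and can
#' change statuses, which is why the default leaves the input untouched.
#'
#' @param tree A rooted `phylo`.
#' @param tip_to_taxon Named character vector mapping tip labels to taxa
#'   (e.g. `map_tips_to_taxa()$mapping`). Tips absent from the mapping are
#'   treated as foreign to every assessed taxon.
#' @param taxa Taxa to assess; defaults to every taxon in the mapping.
#' @return A data frame of class `monophyly_result` with columns `taxon`,
#'   `n_tips`, `status` (one of `monophyletic`, `non_monophyletic`,
#'   `singleton`, `absent`); the `intruders` attribute is a named list of
#'   foreign-tip vectors for the non-monophyletic taxa.
#' @export
assess_monophyly <- function(tree, tip_to_taxon, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(unname(tip_to_taxon)))
  tip_to_taxon <- tip_to_taxon[names(tip_to_taxon) %in% tree$tip.label]
  out <- data.frame(taxon = taxa, n_tips = 0L, status = "absent",
                    stringsAsFactors = FALSE)
  intr <- stats::setNames(vector("list", length(taxa)), taxa)
  for (k in seq_along(taxa)) {
    tips <- names(tip_to_taxon)[tip_to_taxon == taxa[k]]
    out$n_tips[k] <- length(tips)
    if (length(tips) == 0L) next
    if (length(tips) == 1L) { out$status[k] <- "singleton"; next }
    foreign <- intruders_of(tree, tips)
    if (length(foreign)) {
      out$status[k] <- "non_monophyletic"
      intr[[k]] <- foreign
    } else out$status[k] <- "monophyletic"
  }
  attr(out, "intruders") <- intr[!vapply(intr, is.null, TRUE)]
  class(out) <- c("monophyly_result", "data.frame")
  out
}

#' @export
print.monophyly_result <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("monophyletic",
        "non_monophyletic", "singleton", "absent")))
  cat(sprintf(
    "monophyly: %d taxa — %d monophyletic, %d non-monophyletic, %d singleton, %d absent\n",
    nrow(x), tab[1], tab[2], tab[3], tab[4]))
  bad <- x$taxon[x$status == "non_monophyletic"]
  if (length(bad)) cat("non-monophyletic:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

# greedy search for a small removal set restoring monophyly of focal tips.
# Candidates are the focal tips themselves (an outlier member is the usual
# culprit for a mislabel) plus, when the intruder set is small, the
# intruders. Advisory only; capped.
suggest_removals <- function(tree, focal_tips, max_removals = 10L,
                             max_intruder_candidates = 50L) {
  removed <- character(0)
  repeat {
    focal <- setdiff(focal_tips, removed)
    if (length(focal) < 2L) break  # singleton/absent: trivially resolved
    intr <- intruders_of(tree, focal)
    if (length(intr) == 0L) break
    if (length(removed) >= max_removals) break
    # intruder candidates first: a tie between removing an intruder and
    # shrinking the focal set to a singleton resolves toward the intruder
    cands <- sort(focal)
    if (length(intr) <= max_intruder_candidates)
      cands <- c(sort(intr), cands)
    score <- rep(NA_integer_, length(cands))
    for (ci in seq_along(cands)) {
      tip <- cands[ci]
      f2 <- setdiff(focal, tip)
      score[ci] <- if (length(f2) < 2L) 0L else
        length(intruders_of(ape::drop.tip(tree, tip), f2))
      if (score[ci] == 0L) break   # cannot do better; first in sort order
    }
    best <- cands[which.min(score)]
    removed <- c(removed, best)
    tree <- ape::drop.tip(tree, best)
  }
  removed
}

#' Curation table for non-monophyletic taxa
#'
#' One row per non-monophyletic taxon: its intruder tips, their taxa, and
#' a greedily computed suggested removal set (repeatedly remove the single
#' tip whose removal most reduces the intruder count). Suggestions are
#' advisory — actual removals only happen through
#' [apply_exclusion_list()] after manual review, mirroring the two-pass
#' curation loop.
#'
#' @param results A `monophyly_result` from [assess_monophyly()].
#' @param tree The tree the assessment used.
#' @param tip_to_taxon The tip-to-taxon mapping used.
#' @param max_removals Cap on the size of a suggested removal set.
#' @return A data frame with columns `taxon`, `n_tips`, `n_intruders`,
#'   `resolved` (did the suggestion restore monophyly) and list columns
#'   `intruders`, `intruder_taxa`, `suggested_removals`.
#' @export
intruder_report <- function(results, tree, tip_to_taxon,
                            max_removals = 10L) {
  intr <- attr(results, "intruders")
  bad <- results$taxon[results$status == "non_monophyletic"]
  rows <- lapply(bad, function(tx) {
    tips <- names(tip_to_taxon)[tip_to_taxon == tx]
    tips <- intersect(tips, tree$tip.label)
    foreign <- intr[[tx]]
    sugg <- suggest_removals(tree, tips, max_removals = max_removals)
    resolved <- FALSE
    if (length(sugg)) {
      tr2 <- ape::drop.tip(tree, sugg)
      f2 <- setdiff(tips, sugg)
      resolved <- length(f2) < 2L ||
        length(intruders_of(tr2, f2)) == 0L
    }
    data.frame(taxon = tx, n_tips = length(tips),
               n_intruders = length(foreign),
               resolved = resolved,
               intruders = I(list(foreign)),
               intruder_taxa = I(list(sort(unique(unname(
                 tip_to_taxon[intersect(foreign, names(tip_to_taxon))]))))),
               suggested_removals = I(list(sugg)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), n_tips = integer(0),
               n_intruders = integer(0), resolved = logical(0),
               intruders = I(list()), intruder_taxa = I(list()),
               suggested_removals = I(list()))
  rownames(out) <- NULL
  out
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Builds an NJ tree (via [ape::nj()]) as a self-contained fallback when
#' no externally inferred tree is supplied. NJ is exact on additive
#' matrices, which makes it adequate for topology-level checks on
#' simulated libraries; it is not a substitute for model-based inference
#' on real data, and externally supplied trees always take precedence in
#' [curate_barcodes()].
#'
#' NJ estimates an unrooted topology whose stored basal node is an
#' artifact of the agglomeration order; assessed "rooted as read" it can
#' land inside a species cloud and fabricate paraphyly. The returned tree
#' is therefore midpoint-rooted (deterministic, and with short
#' intraspecific branches the midpoint falls between species clades).
#'
#' @param dm A `pdist` with at least 3 records; all pairs must be
#'   comparable.
#' @return A rooted `phylo`.
#' @export
nj_tree <- function(dm) {
  n <- length(dm$ids)
  if (n < 3L) stop("need at least 3 records for neighbor joining")
  if (any(is.na(dm$d)))
    stop("incomparable pairs (no shared sites) present; ",
         "supply an externally built tree instead")
  tr <- ape::nj(structure(dm$d, dimnames = list(dm$ids, dm$ids)))
  phangorn::midpoint(tr)
}

#' Write a monophyly report as TSV
#'
#' @param results A `monophyly_result`.
#' @param path Output path (columns taxon, n_tips, status, intruders).
#' @return Invisibly, the written data frame.
#' @export
write_monophyly_report <- function(results, path) {
  intr <- attr(results, "intruders")
  out <- as.data.frame(results)
  out$intruders <- vapply(out$taxon, function(tx)
    paste(intr[[tx]], collapse = ","), "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
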