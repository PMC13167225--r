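# Independent oracles and fixture builders. These deliberately avoid the
# package's own computational paths: distances by explicit per-site
# enumeration, NJ from the textbook recursion, haplotypes by set arithmetic.

# explicit site-enumeration p-distance over a character vector of sequences:
# returns list(d = proportion matrix, sites = compared-site matrix)
naive_pdist <- function(seqs) {
  n <- length(seqs)
  d <- matrix(NA_real_, n, n)
  s <- matrix(0L, n, n)
  chars <- lapply(seqs, function(x) strsplit(toupper(x), "")[[1]])
  acgt <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- chars[[i]]; b <- chars[[j]]
      mism <- 0L; comp <- 0L
      for (k in seq_along(a)) {
        if (a[k] %in% acgt && b[k] %in% acgt) {
          comp <- comp + 1L
          if (a[k] != b[k]) mism <- mism + 1L
        }
      }
      s[i, j] <- comp
      d[i, j] <- if (comp > 0L) mism / comp else NA_real_
    }
  }
  list(d = d, sites = s)
}

# same contract as naive_pdist, but each pair's sites are enumerated with
# vectorized masks (for the many-alignment equivalence sweep)
naive_pdist_pairwise <- function(seqs) {
  n <- length(seqs)
  chars <- lapply(seqs, function(x) strsplit(toupper(x), "")[[1]])
  acgt <- c("A", "C", "G", "T")
  d <- matrix(NA_real_, n, n); s <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- chars[[i]] %in% acgt & chars[[j]] %in% acgt
      comp <- sum(ok)
      s[i, j] <- s[j, i] <- comp
      val <- if (comp > 0L) sum(chars[[i]][ok] != chars[[j]][ok]) / comp
             else NA_real_
      d[i, j] <- d[j, i] <- val
    }
  }
  list(d = d, sites = s)
}

# textbook neighbor joining (Saitou & Nei / Studier & Keppler Q-criterion),
# lowest-index tie-break; returns an ape::phylo via newick assembly
textbook_nj <- function(d, labels = rownames(d)) {
  n <- nrow(d)
  nodes <- as.list(labels)          # newick fragments
  active <- seq_len(n)
  D <- d
  while (length(active) > 2L) {
    m <- length(active)
    Dsub <- D[active, active]
    r <- rowSums(Dsub)
    Q <- (m - 2) * Dsub - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    ai <- active[i]; aj <- active[j]
    vi <- 0.5 * Dsub[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dsub[i, j] - vi
    newdist <- 0.5 * (D[ai, active] + D[aj, active] - D[ai, aj])
    D <- rbind(cbind(D, 0), 0)
    k <- nrow(D)
    D[k, active] <- newdist
    D[active, k] <- newdist
    D[k, k] <- 0
    nodes[[k]] <- sprintf("(%s:%.10f,%s:%.10f)", nodes[[ai]], vi,
                          nodes[[aj]], vj)
    active <- c(setdiff(active, c(ai, aj)), k)
  }
  i <- active[1]; j <- active[2]
  tre <- sprintf("(%s:%.10f,%s:0);", nodes[[i]], D[i, j], nodes[[j]])
  ape::read.tree(text = tre)
}

# random alignment with injected gaps and ambiguity codes
random_alignment <- function(n, len, gap_rate = 0.05, amb_rate = 0.05) {
  amb <- c("N", "R", "Y", "W", "S", "K", "M")
  vapply(seq_len(n), function(i) {
    x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    u <- runif(len)
    x[u < gap_rate] <- "-"
    x[u >= gap_rate & u < gap_rate + amb_rate] <-
      sample(amb, sum(u >= gap_rate & u < gap_rate + amb_rate),
             replace = TRUE)
    paste(x, collapse = "")
  }, "")
}

# quick aligned record_set from named sequences (names = species labels,
# optionally "species|bin")
toy_records <- function(seqs, ids = sprintf("r%02d", seq_along(seqs))) {
  labs <- names(seqs)
  sp <- sub("\\|.*$", "", labs)
  bin <- ifelse(grepl("|", labs, fixed = TRUE), sub("^.*\\|", "", labs),
                NA_character_)
  record_set(record_id = ids, species_label = sp, sequence = unname(seqs),
             bin_label = bin, aligned = TRUE)
}

# stop-free coding sequence of length len (codon-sampled, no TAA/TAG in
# frame 0); used to build clean COI-like fixtures
clean_coding_seq <- function(len) {
  codons <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                  paste0), c("A","C","G","T"), paste0))
  codons <- setdiff(codons, c("TAA", "TAG"))
  substring(paste(sample(codons, ceiling(len / 3), replace = TRUE),
                  collapse = ""), 1, len)
}
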