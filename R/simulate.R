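#' Configuration for the synthetic library generator
#'
#' Describes a species-structured barcode library: per-species ancestral
#' sequences on a two-level species tree (designated sister pairs as
#' shallow cherries at `inter_divergence`, everything else separated by
#' `deep_multiplier * inter_divergence`), intraspecific haplotype clouds
#' around each ancestor (star model, `theta` expected substitutions per
#' individual), and per-record error processes with known ground truth.
#'
#' Defaults mirror a well-sampled COI-5P reference library: the full
#' 658 bp fragment, ~10% divergence between close congeners, a couple of
#' segregating sites per individual, and a right-skewed sampling effort
#' (zero-truncated negative binomial, mean 24, SD ~31). Error rates
#' default to zero: errors are opt-in.
#'
#' @param n_species Number of species (>= 2).
#' @param sister_pairs List of integer pairs (species indices) forced to be
#'   sister cherries at `inter_divergence`.
#' @param seq_length Alignment length in sites (default 658).
#' @param inter_divergence Expected substitutions per site between sister
#'   species (default 0.10).
#' @param deep_multiplier Multiplier giving the expected divergence between
#'   non-sister species (default 2, i.e. ~20%).
#' @param theta Expected substitutions per individual from its species
#'   ancestor, in sites (default 2).
#' @param n_per_species Either a single integer (fixed sample size per
#'   species), a length-2 vector `c(min, max)` (discrete uniform), or a
#'   list `list(mean =, sd =)` for a zero-truncated negative binomial.
#' @param mislabel,contamination,numt,short,ambiguous Per-record error
#'   probabilities (disjoint classes: each record carries at most one).
#' @param ambiguous_site_rate Within an ambiguous record, per-site
#'   probability of an `N` (at least one site is always hit).
#' @param sharing_pairs List of species-index pairs across which one
#'   haplotype is copied verbatim (barcode sharing).
#' @param seed Integer seed; the generator's only source of randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 40L,
                       sister_pairs = list(),
                       seq_length = 658L,
                       inter_divergence = 0.10,
                       deep_multiplier = 2,
                       theta = 2,
                       n_per_species = list(mean = 24, sd = 30.73),
                       mislabel = 0, contamination = 0, numt = 0,
                       short = 0, ambiguous = 0,
                       ambiguous_site_rate = 0.05,
                       sharing_pairs = list(),
                       seed = 1L) {
  stopifnot(n_species >= 2L, seq_length >= 60L,
            inter_divergence >= 0, deep_multiplier > 0, theta >= 0)
  rates <- c(mislabel = mislabel, contamination = contamination,
             numt = numt, short = short, ambiguous = ambiguous)
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  if (sum(rates) > 1)
    stop("error rates sum to ", sum(rates), " > 1; classes are disjoint")
  chk_pairs <- function(p, what) {
    for (pr in p) {
      if (length(pr) != 2L || any(pr < 1L) || any(pr > n_species) ||
          pr[1] == pr[2])
        stop("invalid ", what, " pair: ", paste(pr, collapse = ","))
    }
    if (anyDuplicated(unlist(p)))
      stop(what, " pairs must not share species")
  }
  chk_pairs(sister_pairs, "sister")
  for (pr in sharing_pairs)
    if (length(pr) != 2L || any(pr < 1L) || any(pr > n_species))
      stop("invalid sharing pair: ", paste(pr, collapse = ","))
  cfg <- list(n_species = as.integer(n_species),
              sister_pairs = lapply(sister_pairs, as.integer),
              seq_length = as.integer(seq_length),
              inter_divergence = inter_divergence,
              deep_multiplier = deep_multiplier,
              theta = theta,
              n_per_species = n_per_species,
              rates = rates,
              ambiguous_site_rate = ambiguous_site_rate,
              sharing_pairs = lapply(sharing_pairs, as.integer),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

# random coding-style root sequence: sampled codon-wise, no TAA/TAG in frame 0
random_root_sequence <- function(len) {
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  codons <- setdiff(codons, c("TAA", "TAG"))
  n_codon <- ceiling(len / 3)
  s <- paste(sample(codons, n_codon, replace = TRUE), collapse = "")
  strsplit(substring(s, 1L, len), "", fixed = TRUE)[[1]]
}

# apply k substitution events at uniform positions, uniform among the other
# three bases, rejecting changes that would create a frame-0 stop codon
# (purifying selection on a coding gene; NUMTs are made separately)
mutate_sequence <- function(seq_chars, k) {
  if (k == 0L) return(seq_chars)
  len <- length(seq_chars)
  positions <- sample.int(len, k, replace = TRUE)
  for (pos in positions) {
    alts <- setdiff(BASES, seq_chars[pos])
    alts <- sample(alts)   # random preference order
    codon_start <- pos - (pos - 1L) %% 3L
    for (b in alts) {
      trial <- seq_chars
      trial[pos] <- b
      if (codon_start + 2L <= len) {
        cod <- paste(trial[codon_start:(codon_start + 2L)], collapse = "")
        if (cod %in% c("TAA", "TAG")) next
      }
      seq_chars <- trial
      break
    }
  }
  seq_chars
}

#' Simulate per-species ancestral sequences
#'
#' Builds the two-level species tree implied by the configuration and
#' drops Jukes-Cantor-style substitutions along each branch: the number of
#' events per branch is Poisson with mean `branch length x seq_length`,
#' each event hits a uniform site and substitutes a uniform different
#' base. Species not in a sister pair attach directly to their group node.
#' Uses the current RNG state; call via [simulate_library()] (which seeds
#' it) for reproducible output.
#'
#' @param cfg A [sim_config()].
#' @return A list with `sequences` (named character vector, one ancestral
#'   sequence per species), `species` (names) and `groups` (integer group
#'   index per species).
#' @export
simulate_ancestors <- function(cfg) {
  L <- cfg$seq_length
  root <- random_root_sequence(L)
  species <- sprintf("Species%03d", seq_len(cfg$n_species))
  group <- seq_len(cfg$n_species)
  for (pr in cfg$sister_pairs) group[pr[2]] <- group[pr[1]]
  deep_events <- L * cfg$inter_divergence * cfg$deep_multiplier / 2
  sister_events <- L * cfg$inter_divergence / 2
  anc <- vector("list", cfg$n_species)
  for (gid in unique(group)) {
    g_anc <- mutate_sequence(root, stats::rpois(1, deep_events))
    members <- which(group == gid)
    for (sp in members) {
      anc[[sp]] <- if (length(members) > 1L)
        mutate_sequence(g_anc, stats::rpois(1, sister_events))
      else g_anc
    }
  }
  list(sequences = stats::setNames(
         vapply(anc, paste, "", collapse = ""), species),
       species = species, groups = group)
}

draw_n_per_species <- function(spec, n_species) {
  if (is.list(spec)) {
    mu <- spec$mean; sdv <- spec$sd
    if (sdv^2 <= mu) stop("ztnb requires sd^2 > mean")
    size <- mu^2 / (sdv^2 - mu)
    vapply(seq_len(n_species), function(i) {
      repeat {
        n <- stats::rnbinom(1, size = size, mu = mu)
        if (n > 0L) return(as.integer(n))
      }
    }, integer(1))
  } else if (length(spec) == 2L) {
    as.integer(sample(seq(spec[1], spec[2]), n_species, replace = TRUE))
  } else {
    rep(as.integer(spec), n_species)
  }
}

#' Simulate individual records around the species ancestors
#'
#' Star model of intraspecific variation: each individual is its species
#' ancestor plus `Poisson(theta)` substitutions at uniform positions.
#' Record ids, species labels and BIN labels (one BIN per true species)
#' are deterministic given the RNG state.
#'
#' @param ancestors Output of [simulate_ancestors()].
#' @param cfg The same [sim_config()].
#' @return A list with `records` (an aligned [record_set()]) and `truth`
#'   (data frame: `record_id`, `true_species`, `observed_species`,
#'   `error_class`, all `"none"` at this stage).
#' @export
simulate_individuals <- function(ancestors, cfg) {
  ns <- draw_n_per_species(cfg$n_per_species, cfg$n_species)
  ids <- list(); seqs <- list(); sp <- list()
  for (k in seq_len(cfg$n_species)) {
    anc_chars <- strsplit(ancestors$sequences[k], "", fixed = TRUE)[[1]]
    kmut <- stats::rpois(ns[k], cfg$theta)
    seqs[[k]] <- vapply(kmut, function(m)
      paste(mutate_sequence(anc_chars, m), collapse = ""), "")
    ids[[k]] <- sprintf("%s_%04d", gsub("Species", "SP",
                                        ancestors$species[k]), seq_len(ns[k]))
    sp[[k]] <- rep(ancestors$species[k], ns[k])
  }
  species <- unlist(sp)
  rs <- record_set(record_id = unlist(ids),
                   species_label = species,
                   sequence = unlist(seqs),
                   bin_label = paste0("BIN:", gsub("Species", "", species)),
                   country = "Simland", project = "SIM",
                   aligned = TRUE)
  truth <- data.frame(record_id = rs$record_id,
                      true_species = species,
                      observed_species = species,
                      error_class = "none",
                      stringsAsFactors = FALSE)
  list(records = rs, truth = truth)
}

# force >=1 stop codon in every reading frame by writing TAA at in-frame
# codon slots until none of the three frames is stop-free
force_all_frame_stops <- function(seq_chars) {
  len <- length(seq_chars)
  has_stop <- function(chars, f) {
    s <- frame_codon_string(paste(chars, collapse = ""), f)
    if (!nzchar(s)) return(TRUE)
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    any(cods %in% c("TAA", "TAG"))
  }
  for (iter in 1:10) {
    open <- which(!vapply(0:2, function(f) has_stop(seq_chars, f), TRUE)) - 1L
    if (!length(open)) break
    for (f in open) {
      n_cod <- (len - f) %/% 3L
      slot <- sample.int(n_cod, 1L)
      start <- f + 3L * (slot - 1L) + 1L
      seq_chars[start:(start + 2L)] <- c("T", "A", "A")
    }
  }
  open <- which(!vapply(0:2, function(f) has_stop(seq_chars, f), TRUE))
  if (length(open)) {
    # deterministic fallback: TAA written once per frame offset
    seq_chars[1:3] <- c("T", "A", "A")
    seq_chars[5:7] <- c("T", "A", "A")
    seq_chars[9:11] <- c("T", "A", "A")
  }
  seq_chars
}

#' Inject operational errors into a simulated library
#'
#' Applies the configured per-record error processes, each mimicking a
#' failure mode seen in public barcode repositories:
#' \describe{
#'   \item{mislabel}{species label swapped to a random other species
#'     (misidentification / data entry); the BIN follows the sequence and
#'     stays with the true species, so a discordant BIN results.}
#'   \item{contamination}{sequence replaced by a copy of a record from
#'     another species; the BIN follows the new sequence.}
#'   \item{numt}{a 1-base deletion with re-padding shifts the frame, then
#'     targeted codon edits guarantee a stop in all three frames; the BIN
#'     is withdrawn (a repository would not assign one).}
#'   \item{short}{sequence truncated below the 500 bp window and gap-padded
#'     to keep the alignment rectangular; BIN withdrawn.}
#'   \item{ambiguous}{bases overwritten with `N` at
#'     `ambiguous_site_rate` (at least one).}
#' }
#' The five classes are disjoint (one uniform draw per record against the
#' cumulative rates). Afterwards, for each `sharing_pairs` entry one
#' error-free record of the second species receives a verbatim copy of a
#' haplotype of the first (class `shared_haplotype`).
#'
#' @param rs,truth Output of [simulate_individuals()].
#' @param cfg The same [sim_config()].
#' @return A list with modified `records` and `truth`; the truth table
#'   gains attribute `sharing_pairs` (species-name pairs).
#' @export
inject_errors <- function(rs, truth, cfg) {
  L <- cfg$seq_length
  species <- sort(unique(truth$true_species))
  rates <- cfg$rates
  cum <- cumsum(rates)
  u <- stats::runif(nrow(rs))
  cls <- rep("none", nrow(rs))
  for (k in rev(seq_along(rates)))
    cls[u < cum[k]] <- names(rates)[k]
  if (sum(rates) > 0 && all(cls == "none"))
    warning("error rates produced zero affected records at this size")
  donor_pool <- which(cls == "none")
  for (i in which(cls != "none")) {
    this_sp <- truth$true_species[i]
    switch(cls[i],
      mislabel = {
        other <- sample(setdiff(species, this_sp), 1L)
        truth$observed_species[i] <- other
        rs$species_label[i] <- other
      },
      contamination = {
        cand <- donor_pool[truth$true_species[donor_pool] != this_sp]
        j <- if (length(cand)) sample(cand, 1L) else
          sample(which(truth$true_species != this_sp), 1L)
        rs$sequence[i] <- rs$sequence[j]
        rs$bin_label[i] <- rs$bin_label[j]
      },
      numt = {
        chars <- strsplit(rs$sequence[i], "", fixed = TRUE)[[1]]
        del <- sample.int(L - 1L, 1L)
        chars <- c(chars[-del], sample(BASES, 1L))   # frameshift + re-pad
        chars <- force_all_frame_stops(chars)
        rs$sequence[i] <- paste(chars, collapse = "")
        rs$bin_label[i] <- NA_character_
      },
      short = {
        keep <- sample(300:499, 1L)
        rs$sequence[i] <- paste0(substring(rs$sequence[i], 1L, keep),
                                 strrep("-", L - keep))
        rs$bin_label[i] <- NA_character_
      },
      ambiguous = {
        chars <- strsplit(rs$sequence[i], "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(L) < cfg$ambiguous_site_rate)
        if (!length(hit)) hit <- sample.int(L, 1L)
        chars[hit] <- "N"
        rs$sequence[i] <- paste(chars, collapse = "")
      })
    truth$error_class[i] <- cls[i]
  }
  share_names <- list()
  for (pr in cfg$sharing_pairs) {
    sp_a <- sprintf("Species%03d", pr[1])
    sp_b <- sprintf("Species%03d", pr[2])
    src <- which(truth$true_species == sp_a & truth$error_class == "none")
    dst <- which(truth$true_species == sp_b & truth$error_class == "none")
    if (!length(src) || !length(dst)) {
      warning("sharing pair (", sp_a, ",", sp_b,
              ") has no eligible records; skipped")
      next
    }
    i <- dst[1]
    rs$sequence[i] <- rs$sequence[src[1]]
    truth$error_class[i] <- "shared_haplotype"
    share_names[[length(share_names) + 1L]] <- c(sp_a, sp_b)
  }
  attr(truth, "sharing_pairs") <- share_names
  list(records = rs, truth = truth)
}

#' Generate a complete synthetic barcode library
#'
#' Seeds the RNG from `cfg$seed` (restoring the caller's RNG state on
#' exit) and runs [simulate_ancestors()], [simulate_individuals()] and
#' [inject_errors()] in sequence. Identical configurations produce
#' byte-identical libraries.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_library`: `records` (aligned
#'   [record_set()]), `truth`, `ancestors`, `config`.
#' @export
simulate_library <- function(cfg) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(cfg$seed)
  anc <- simulate_ancestors(cfg)
  ind <- simulate_individuals(anc, cfg)
  inj <- inject_errors(ind$records, ind$truth, cfg)
  out <- list(records = inj$records, truth = inj$truth, ancestors = anc,
              config = cfg)
  class(out) <- "sim_library"
  out
}

#' Write a synthetic library to disk
#'
#' Emits the FASTA + metadata TSV in the [read_dataset()] dialect, the
#' truth table as TSV, and the configuration (seed included) as a
#' key-value reproducibility header.
#'
#' @param lib A `sim_library`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("library.fasta", "metadata.tsv", "truth.tsv",
                            "sim_config.txt"))
  write_dataset(lib$records, paths[1], paths[2])
  utils::write.table(lib$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- lib$config
  scal <- vapply(cfg, function(x) !is.list(x) && length(x) == 1L, TRUE)
  lines <- c(paste0(names(cfg)[scal], "=",
                    vapply(cfg[scal], as.character, "")),
             paste0("n_per_species=", paste(unlist(cfg$n_per_species),
                                            collapse = ",")),
             paste0("sister_pairs=", paste(vapply(cfg$sister_pairs,
                    paste, "", collapse = "-"), collapse = ";")),
             paste0("sharing_pairs=", paste(vapply(cfg$sharing_pairs,
                    paste, "", collapse = "-"), collapse = ";")))
  writeLines(lines, paths[4])
  invisible(paths)
}
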