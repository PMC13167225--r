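test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_species = 6, n_per_species = 5, mislabel = 0.05,
                    numt = 0.05, seed = 99)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a$records$sequence, b$records$sequence)
  expect_identical(a$records$record_id, b$records$record_id)
  expect_identical(a$truth, b$truth)
  # byte-identical FASTA on repeated runs
  td <- withr::local_tempdir()
  write_library(a, file.path(td, "x"))
  write_library(b, file.path(td, "y"))
  expect_identical(readLines(file.path(td, "x", "library.fasta")),
                   readLines(file.path(td, "y", "library.fasta")))
  # a different seed changes the output
  c2 <- simulate_library(sim_config(n_species = 6, n_per_species = 5,
                                    mislabel = 0.05, numt = 0.05,
                                    seed = 100))
  expect_false(identical(a$records$sequence, c2$records$sequence))
})

test_that("zero interspecific divergence collapses all ancestors", {
  set.seed(71)
  anc <- simulate_ancestors(sim_config(n_species = 5,
                                       inter_divergence = 0, seed = 1))
  expect_length(unique(anc$sequences), 1L)
})

test_that("sister pairs are mutual nearest neighbors in true distances", {
  set.seed(72)
  lib <- simulate_library(sim_config(n_species = 8, n_per_species = 3,
                                     sister_pairs = list(c(1, 2), c(5, 6)),
                                     seed = 8))
  dm <- distance_matrix(lib$records)
  nn <- nearest_neighbor(dm, setNames(lib$records$species_label,
                                      lib$records$record_id))
  expect_equal(nn$nn_group[nn$group == "Species001"], "Species002")
  expect_equal(nn$nn_group[nn$group == "Species002"], "Species001")
  expect_equal(nn$nn_group[nn$group == "Species005"], "Species006")
  expect_equal(nn$nn_group[nn$group == "Species006"], "Species005")
})

test_that("realized sister divergence matches the configured rate", {
  # Monte Carlo: mean realized p-distance between a 2-species cherry over
  # many seeds stays within 3 binomial SDs of the nominal 0.10
  # (multiple hits pull it slightly below)
  cfg0 <- sim_config(n_species = 2, sister_pairs = list(c(1, 2)),
                     inter_divergence = 0.10, seq_length = 658, seed = 1)
  ps <- vapply(1:200, function(s) {
    cfg <- cfg0; cfg$seed <- s
    set.seed(cfg$seed)
    anc <- simulate_ancestors(cfg)
    p_distance(anc$sequences[1], anc$sequences[2])$distance
  }, 1)
  sd_bin <- sqrt(0.10 * 0.90 / 658)
  expect_lt(abs(mean(ps) - 0.10), 3 * sd_bin)
  expect_lt(mean(ps), 0.10 + 1e-9)  # collisions only ever reduce it
})

test_that("theta controls haplotype diversity", {
  cfg0 <- sim_config(n_species = 2, n_per_species = 40, theta = 0, seed = 3)
  lib0 <- simulate_library(cfg0)
  expect_equal(count_haplotypes(lib0$records, "species")$n_haplotypes,
               c(1L, 1L))
  # monotone (in expectation) over seeds: theta 2 vs theta 0.2
  hap_at <- function(theta, seed) {
    cfg <- sim_config(n_species = 2, n_per_species = 40, theta = theta,
                      seed = seed)
    tab <- count_haplotypes(simulate_library(cfg)$records, "species")
    tab$n_haplotypes[tab$group == "Species001"]
  }
  h_low <- vapply(1:20, function(s) hap_at(0.2, s), 1L)
  h_high <- vapply(1:20, function(s) hap_at(2, s), 1L)
  expect_gt(mean(h_high), mean(h_low))
  expect_true(all(h_high > 1 & h_high <= 40))
})

test_that("clean individuals are always stop-free in frame 0", {
  set.seed(73)
  lib <- simulate_library(sim_config(n_species = 10, n_per_species = 10,
                                     theta = 5, seed = 23))
  stops <- vapply(lib$records$sequence, function(s)
    grepl("*", translate_dna(s, 0), fixed = TRUE), TRUE)
  expect_false(any(stops))
})

test_that("error injection honors the truth table classes", {
  cfg <- sim_config(n_species = 10, n_per_species = 10,
                    mislabel = 0.05, contamination = 0.05, numt = 0.05,
                    short = 0.05, ambiguous = 0.05,
                    sharing_pairs = list(c(3, 4)), seed = 77)
  lib <- simulate_library(cfg)
  tr <- lib$truth; rs <- lib$records
  expect_equal(tr$record_id, rs$record_id)
  # mislabel: observed != true, label applied to the record
  mis <- tr$error_class == "mislabel"
  expect_true(all(tr$observed_species[mis] != tr$true_species[mis]))
  expect_equal(rs$species_label[mis], tr$observed_species[mis])
  expect_true(all(tr$observed_species[!mis] == tr$true_species[!mis]))
  # numt: stops in all frames, BIN withdrawn
  numt <- which(tr$error_class == "numt")
  expect_gt(length(numt), 0)
  for (i in numt)
    expect_true(all(vapply(0:2, function(f)
      grepl("*", translate_dna(rs$sequence[i], f), fixed = TRUE), TRUE)))
  expect_true(all(is.na(rs$bin_label[numt])))
  # short: below the window, alignment width preserved by gap padding
  sh <- which(tr$error_class == "short")
  expect_gt(length(sh), 0)
  expect_true(all(ungapped_length(rs$sequence[sh]) < 500))
  expect_true(all(nchar(rs$sequence[sh]) == cfg$seq_length))
  # ambiguous: at least one N
  amb <- which(tr$error_class == "ambiguous")
  expect_true(all(grepl("N", rs$sequence[amb])))
  # sharing: the designated record equals a donor haplotype exactly
  shr <- which(tr$error_class == "shared_haplotype")
  expect_length(shr, 1L)
  expect_equal(tr$true_species[shr], "Species004")
  donors <- rs$sequence[tr$true_species == "Species003"]
  expect_true(rs$sequence[shr] %in% donors)
  # all rates zero leaves the library untouched
  cfg0 <- sim_config(n_species = 4, n_per_species = 4, seed = 5)
  set.seed(1)
  base <- simulate_individuals(simulate_ancestors(cfg0), cfg0)
  out <- inject_errors(base$records, base$truth, cfg0)
  expect_identical(out$records$sequence, base$records$sequence)
  expect_identical(out$truth$error_class, base$truth$error_class)
})

test_that("sampling-effort distributions are honored", {
  set.seed(74)
  cfg <- sim_config(n_species = 200, n_per_species = list(mean = 24,
                                                          sd = 30.73),
                    seq_length = 60, inter_divergence = 0.05, theta = 0,
                    seed = 55)
  lib <- simulate_library(cfg)
  n <- table(lib$truth$true_species)
  expect_true(all(n >= 1))
  expect_gt(mean(n), 15); expect_lt(mean(n), 35)
  expect_gt(sd(n), 15)    # right-skewed, not uniform
  fixed <- simulate_library(sim_config(n_species = 3, n_per_species = 7,
                                       seq_length = 60, seed = 2))
  expect_true(all(table(fixed$truth$true_species) == 7))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(sim_config(mislabel = 0.9, numt = 0.2), "sum")
  expect_error(sim_config(mislabel = -0.1), "rates")
  expect_error(sim_config(sister_pairs = list(c(1, 1))), "pair")
  expect_error(sim_config(n_species = 4, sister_pairs = list(c(1, 9))),
               "pair")
})
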