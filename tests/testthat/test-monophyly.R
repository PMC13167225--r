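test_that("newick parsing keeps structure and rejects malformed input", {
  tr <- parse_newick("((a,b),(c,d));")
  expect_equal(sort(tr$tip.label), c("a", "b", "c", "d"))
  expect_equal(tr$Nnode, 3L)
  tr2 <- parse_newick("((a:1,b:2)90:0.5,c:3);")
  expect_equal(sort(tr2$edge.length), c(0.5, 1, 2, 3))
  expect_equal(tr2$node.label[2], "90")
  expect_error(parse_newick("(a,b"), "end-of-input")
  expect_error(parse_newick("(a,b));"), "position")
  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
})

test_that("tips resolve via composite labels with metadata precedence", {
  tr <- parse_newick("(ABC123.Genus_species,(XYZ9.Other_taxon,plain));")
  m <- map_tips_to_taxa(tr)
  expect_equal(unname(m$mapping["ABC123.Genus_species"]), "Genus_species")
  expect_equal(unname(m$mapping["XYZ9.Other_taxon"]), "Other_taxon")
  expect_equal(m$unresolved, "plain")
  # metadata wins over label parsing and resolves plain tips
  meta <- c("ABC123.Genus_species" = "Metadata_name", plain = "Third_taxon")
  m2 <- map_tips_to_taxa(tr, metadata = meta)
  expect_equal(unname(m2$mapping["ABC123.Genus_species"]), "Metadata_name")
  expect_equal(unname(m2$mapping["plain"]), "Third_taxon")
  expect_length(m2$unresolved, 0)
})

test_that("rooted MRCA monophyly classifies toy topologies", {
  map <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", s1 = "S")
  # clean split
  r <- assess_monophyly(parse_newick("((a1,a2),(b1,b2));"), map)
  expect_equal(r$status[r$taxon == "A"], "monophyletic")
  expect_equal(r$status[r$taxon == "B"], "monophyletic")
  # interleaved clades: both non-monophyletic as rooted
  r2 <- assess_monophyly(parse_newick("((a1,b1),(a2,b2));"), map)
  expect_equal(r2$status[r2$taxon == "A"], "non_monophyletic")
  expect_equal(r2$status[r2$taxon == "B"], "non_monophyletic")
  expect_setequal(attr(r2, "intruders")$A, c("b1", "b2"))
  # nested clade: A monophyletic around its own subclade
  r3 <- assess_monophyly(parse_newick("((a1,(a2,a3)),b1);"), map)
  expect_equal(r3$status[r3$taxon == "A"], "monophyletic")
  # singleton and absent taxa
  r4 <- assess_monophyly(parse_newick("((a1,a2),s1);"), map,
                         taxa = c("A", "S", "Z"))
  expect_equal(r4$status[r4$taxon == "S"], "singleton")
  expect_equal(r4$n_tips[r4$taxon == "S"], 1L)
  expect_equal(r4$status[r4$taxon == "Z"], "absent")
  expect_length(attr(r4, "intruders"), 0)
})

test_that("monophyly status is invariant to child-order rotations", {
  map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  forms <- c("((a1,b1),((a2,b2),c1));", "(((b2,a2),c1),(b1,a1));",
             "((c1,(a2,b2)),(a1,b1));")
  res <- lapply(forms, function(t)
    assess_monophyly(parse_newick(t), map))
  for (r in res[-1])
    expect_equal(setNames(r$status, r$taxon),
                 setNames(res[[1]]$status, res[[1]]$taxon))
})

test_that("assessment agrees with ape::is.monophyletic on random labelings", {
  set.seed(51)
  for (rep in 1:20) {
    tr <- ape::rtree(12)
    map <- setNames(sample(c("A", "B", "C"), 12, replace = TRUE),
                    tr$tip.label)
    res <- assess_monophyly(tr, map)
    for (tx in c("A", "B", "C")) {
      tips <- names(map)[map == tx]
      if (length(tips) < 2) next
      oracle <- ape::is.monophyletic(tr, tips)
      expect_equal(res$status[res$taxon == tx] == "monophyletic", oracle,
                   info = paste("rep", rep, "taxon", tx))
    }
  }
})

test_that("intruder report suggests minimal removals for simple cases", {
  map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", b3 = "B")
  tr <- parse_newick("((a1,a2,b1),(b2,b3));")
  res <- assess_monophyly(tr, map)
  rep <- intruder_report(res, tr, map)
  rowA <- rep[rep$taxon == "A", ]
  expect_equal(rowA$intruders[[1]], "b1")
  expect_equal(rowA$suggested_removals[[1]], "b1")
  expect_true(rowA$resolved)
  # second-round confirmation: dropping the suggestion restores monophyly
  tr2 <- ape::drop.tip(tr, rowA$suggested_removals[[1]])
  res2 <- assess_monophyly(tr2, map[tr2$tip.label])
  expect_equal(res2$status[res2$taxon == "A"], "monophyletic")
})

test_that("a mislabeled record is recovered as the suggested removal", {
  set.seed(52)
  cfg <- sim_config(n_species = 6, n_per_species = 6, theta = 1, seed = 9)
  lib <- simulate_library(cfg)
  rs <- lib$records
  # plant one mislabel by hand: a Species001 record labeled Species004
  victim <- which(rs$species_label == "Species001")[1]
  rs$species_label[victim] <- "Species004"
  dm <- distance_matrix(rs)
  tr <- nj_tree(dm)
  map <- setNames(rs$species_label, rs$record_id)
  res <- assess_monophyly(tr, map)
  expect_equal(sort(res$taxon[res$status == "non_monophyletic"]),
               c("Species001", "Species004"))
  rep <- intruder_report(res, tr, map)
  row1 <- rep[rep$taxon == "Species001", ]
  expect_equal(row1$intruders[[1]], rs$record_id[victim])
  expect_equal(row1$suggested_removals[[1]], rs$record_id[victim])
})

test_that("NJ recovers additive matrices exactly", {
  set.seed(53)
  for (ntax in 4:8) {
    tr <- ape::rtree(ntax)
    d <- ape::cophenetic.phylo(tr)
    ids <- rownames(d)
    dm <- structure(list(ids = ids, d = d,
                         sites = matrix(100L, ntax, ntax)),
                    class = "pdist")
    est <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    # branch lengths: patristic distances reproduce the input exactly
    expect_equal(ape::cophenetic.phylo(est)[ids, ids], d,
                 tolerance = 1e-10)
  }
})

test_that("NJ topology matches an independent textbook implementation", {
  set.seed(54)
  for (rep in 1:5) {
    seqs <- random_alignment(12, 80, gap_rate = 0, amb_rate = 0)
    rs <- record_set(sprintf("t%02d", 1:12), "sp", seqs, aligned = TRUE)
    dm <- distance_matrix(rs)
    est <- nj_tree(dm)
    oracle <- textbook_nj(dm$d, labels = dm$ids)
    expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(oracle)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ degenerate and invalid inputs behave as documented", {
  # all-equal distances: deterministic star-ish resolution, valid tree
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  dm <- structure(list(ids = letters[1:4], d = d,
                       sites = matrix(10L, 4, 4)), class = "pdist")
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, letters[1:4])
  # incomparable pair -> directed error
  d2 <- d; d2[1, 2] <- d2[2, 1] <- NA
  dm2 <- structure(list(ids = letters[1:4], d = d2,
                        sites = matrix(10L, 4, 4)), class = "pdist")
  expect_error(nj_tree(dm2), "incomparable|external")
  expect_error(nj_tree(structure(list(ids = c("a", "b"), d = d[1:2, 1:2],
                                      sites = matrix(5L, 2, 2)),
                                 class = "pdist")), "at least 3")
})
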