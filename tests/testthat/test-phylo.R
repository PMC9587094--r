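test_that("protein distances follow the Kimura correction", {
  aln <- tibble::tibble(
    sequence_id = c("a", "b", "c"),
    aligned = c(strrep("A", 100),
                strrep("A", 100),
                paste0(strrep("C", 10), strrep("A", 90)))
  )
  d <- protein_distance(aln)
  expect_equal(unname(d["a", "b"]), 0)
  # p = 0.1 -> -ln(1 - 0.1 - 0.002)
  expect_equal(unname(d["a", "c"]), -log(1 - 0.1 - 0.2 * 0.01))
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
})

test_that("gaps are handled by pairwise deletion and saturation clamps", {
  aln <- tibble::tibble(
    sequence_id = c("a", "b", "c"),
    aligned = c("AAAA--AA", "AA--AAAA", "CCCC--CC")
  )
  d <- protein_distance(aln)
  # a vs b: only the 4 doubly-ungapped columns count, all matches
  expect_equal(unname(d["a", "b"]), 0)
  # a vs c: 6 comparable columns, all mismatching -> saturated, clamped
  expect_equal(unname(d["a", "c"]), 5)

  disjoint <- tibble::tibble(
    sequence_id = c("a", "b", "c"),
    aligned = c("AA--", "--AA", "AAAA")
  )
  expect_error(protein_distance(disjoint), "no comparable columns")
})

test_that("delete-half jackknife keeps floor(L/2) columns, reproducibly", {
  sim <- simulate_padc_families(small_specs(), seed = 61,
                                include_outgroup = FALSE)
  aln <- sim$alignment
  L <- nchar(aln$aligned[1])
  reps <- jackknife_resample(aln, n_replicates = 5L, seed = 1)
  expect_length(reps, 5L)
  for (r in reps) {
    expect_true(all(nchar(r$aligned) == L %/% 2L))
    expect_equal(r$sequence_id, aln$sequence_id)
  }
  # determinism
  reps2 <- jackknife_resample(aln, n_replicates = 5L, seed = 1)
  expect_identical(reps, reps2)
  expect_false(identical(reps,
                         jackknife_resample(aln, n_replicates = 5L,
                                            seed = 2)))

  # every column is kept in about half the replicates (binomial check:
  # 1000 replicates, 3.2 sigma ~ 0.05).  Column resampling is content
  # agnostic, so a row of 40 unique characters tags the kept columns.
  tags <- c(LETTERS, letters[1:14])
  ids <- tibble::tibble(sequence_id = c("r1", "r2"),
                        aligned = rep(paste(tags, collapse = ""), 2))
  freq <- integer(40)
  reps <- jackknife_resample(ids, n_replicates = 1000L, seed = 7)
  for (r in reps) {
    kept <- strsplit(r$aligned[1], "")[[1]]
    freq[match(kept, tags)] <- freq[match(kept, tags)] + 1L
  }
  expect_true(all(abs(freq / 1000 - 0.5) <= 0.05))
})

test_that("neighbour joining recovers additive trees", {
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- build_tree(d3)
  expect_setequal(t3$tip.label, c("a", "b", "c"))
  # x_a = (d_ab + d_ac - d_bc)/2 = 1, x_b = 2, x_c = 3
  lens <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])],
                   t3$tip.label)
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 2, 3))

  # 4 taxa: recovers the generating topology, judged by an exhaustive
  # least-squares fit over the 3 unrooted topologies
  set.seed(601)
  for (i in 1:5) {
    bl <- runif(5, 0.5, 3)  # a,b | c,d external; internal
    dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    dm["a", "b"] <- dm["b", "a"] <- bl[1] + bl[2]
    dm["c", "d"] <- dm["d", "c"] <- bl[3] + bl[4]
    dm["a", "c"] <- dm["c", "a"] <- bl[1] + bl[5] + bl[3]
    dm["a", "d"] <- dm["d", "a"] <- bl[1] + bl[5] + bl[4]
    dm["b", "c"] <- dm["c", "b"] <- bl[2] + bl[5] + bl[3]
    dm["b", "d"] <- dm["d", "b"] <- bl[2] + bl[5] + bl[4]

    # four-point oracle: the pairing with the smallest sum is the split
    sums <- c(ab_cd = dm["a", "b"] + dm["c", "d"],
              ac_bd = dm["a", "c"] + dm["b", "d"],
              ad_bc = dm["a", "d"] + dm["b", "c"])
    expect_equal(names(which.min(sums)), "ab_cd")

    tree <- build_tree(dm)
    want <- ape::read.tree(text = "((a,b),(c,d));")
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(want)), 0,
                 ignore_attr = TRUE)
  }

  # permuting taxon order leaves the topology unchanged
  perm <- c("c", "a", "d", "b")
  dmp <- dm[perm, perm]
  expect_equal(ape::dist.topo(ape::unroot(build_tree(dmp)),
                              ape::unroot(build_tree(dm))), 0,
               ignore_attr = TRUE)

  expect_warning(
    build_tree(matrix(0, 3, 3,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c")))),
    "star"
  )
})

test_that("NJ recovers all 15 labelled five-taxon topologies", {
  skip_if_not_installed("phangorn")
  topologies <- phangorn::allTrees(5, rooted = FALSE,
                                   tip.label = letters[1:5])
  set.seed(602)
  for (k in seq_along(topologies)) {
    tree <- topologies[[k]]
    tree$edge.length <- runif(nrow(tree$edge), 0.3, 2)
    dm <- ape::cophenetic.phylo(tree)
    rec <- build_tree(dm[letters[1:5], letters[1:5]])
    expect_equal(ape::dist.topo(ape::unroot(rec), ape::unroot(tree)), 0,
                 ignore_attr = TRUE,
                 label = paste("topology", k))
  }
})

test_that("consensus retains majority splits with replicate counts", {
  base <- ape::read.tree(text = "((a,b),(c,d),e);")
  alt <- ape::read.tree(text = "((a,c),(b,d),e);")

  unanimous <- consensus_tree(rep(list(base), 20))
  expect_true(all(unanimous$splits$support == 20L))
  expect_true(all(unanimous$splits$retained))
  expect_equal(clade_support(unanimous, c("a", "b")), 20L)

  mixed <- consensus_tree(c(rep(list(base), 2), list(alt)))
  expect_equal(clade_support(mixed, c("a", "b")), 2L)
  ab <- mixed$splits[purrr::map_lgl(mixed$splits$clade,
                                    function(x) setequal(x, c("c", "d"))), ]
  expect_true(ab$retained)
  # supports never exceed the replicate count
  expect_true(all(mixed$splits$support <= 3L))

  # replicate order does not matter
  mixed2 <- consensus_tree(c(list(alt), rep(list(base), 2)))
  expect_equal(dplyr::arrange(mixed$splits, key),
               dplyr::arrange(mixed2$splits, key))

  # trivial and absent bipartitions
  expect_equal(clade_support(mixed, "a"), 3L)
  expect_equal(clade_support(mixed, c("a", "d")), 0L)
  expect_error(clade_support(mixed, "zz"), "unknown")

  expect_error(
    consensus_tree(list(base, ape::read.tree(text = "((a,b),(c,f),e);"))),
    "leaf set"
  )
})

test_that("outgroup rooting is validated and idempotent", {
  tree <- ape::read.tree(text = "((a,b),(c,d),og);")
  rooted <- root_tree(tree, "og")
  expect_true(ape::is.rooted(rooted))
  kids <- ape::prop.part(rooted)
  expect_true(ape::is.monophyletic(rooted, c("a", "b", "c", "d")))

  again <- root_tree(rooted, "og")
  expect_equal(ape::dist.topo(ape::unroot(again), ape::unroot(rooted)), 0,
               ignore_attr = TRUE)

  # multi-leaf outgroups must form a clade
  expect_silent(root_tree(tree, c("c", "d")))
  expect_error(root_tree(tree, c("a", "c")), "not monophyletic")
  expect_error(root_tree(tree, "nope"), "not present")
})
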