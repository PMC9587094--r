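test_that("bitscores follow the scoring scheme and the bits formula", {
  mat <- blosum62()
  scheme <- default_scoring_scheme()

  # self-alignment of a short peptide: raw score is the diagonal sum
  pep <- "ARNDC"
  raw_expected <- sum(diag(mat[strsplit(pep, "")[[1]], strsplit(pep, "")[[1]]]))
  res <- pairwise_bitscore(pep, pep)
  expect_equal(res$raw_score, raw_expected)
  expect_equal(res$bits,
               (scheme$lambda * raw_expected - log(scheme$K)) / log(2))

  # symmetry: swapped arguments give the identical score
  a <- random_protein(40)
  b <- random_protein(35)
  expect_equal(pairwise_bitscore(a, b), pairwise_bitscore(b, a))

  # self-score maximality under local alignment
  set.seed(501)
  for (i in 1:5) {
    x <- random_protein(50)
    y <- random_protein(50)
    expect_gte(pairwise_bitscore(x, x)$bits, pairwise_bitscore(x, y)$bits)
  }

  expect_error(pairwise_bitscore("", "AAA"), "nonempty")
})

test_that("alignment scores equal the brute-force Gotoh oracle", {
  mat <- blosum62()
  set.seed(502)
  for (i in 1:20) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    expect_equal(pairwise_bitscore(a, b)$raw_score,
                 oracle_local_align(a, b, mat),
                 label = paste("pair", i))
  }
})

test_that("keep_higher_of_pair retains the maximum per unordered pair", {
  scores <- tibble::tibble(
    id_a = c("a", "b", "c"),
    id_b = c("b", "a", "d"),
    bits = c(400, 395, 120)
  )
  res <- keep_higher_of_pair(scores)
  expect_equal(nrow(res), 2L)
  expect_equal(res$bits[res$id_a == "a" & res$id_b == "b"], 400)
  # single directed score is kept as-is
  expect_equal(res$bits[res$id_a == "c" & res$id_b == "d"], 120)
  # idempotent on already-symmetric output
  expect_equal(keep_higher_of_pair(res), res)
})

test_that("SSN edges respect the strict threshold and nest across cutoffs", {
  nodes <- tibble::tibble(sequence_id = letters[1:5],
                          linker_family = c("div7", "div7", "minus4",
                                            "minus4", "plus2"))
  pairs <- tibble::tibble(
    id_a = c("a", "a", "b", "c", "d"),
    id_b = c("b", "c", "c", "d", "e"),
    bits = c(700, 380, 200, 500, 390)
  )
  ssn <- build_ssn(pairs, nodes, threshold = 380)
  # bits == 380 is NOT above the threshold
  expect_equal(nrow(ssn$edges), 3L)
  expect_false(any(ssn$edges$bits <= 380))

  low <- build_ssn(pairs, nodes, threshold = 0)
  high <- build_ssn(pairs, nodes, threshold = 500)
  key <- function(e) paste(e$id_a, e$id_b)
  expect_true(all(key(high$edges) %in% key(ssn$edges)))
  expect_true(all(key(ssn$edges) %in% key(low$edges)))

  # all pairs below threshold: edgeless graph keeps all nodes
  none <- build_ssn(pairs, nodes, threshold = 1e4)
  expect_equal(nrow(none$edges), 0L)
  expect_equal(igraph::vcount(none$graph), 5L)
  comp <- ssn_components(none)
  expect_equal(dplyr::n_distinct(comp$component), 5L)
})

test_that("components are labelled by their smallest member", {
  nodes <- tibble::tibble(sequence_id = c("a", "b", "c", "z"))
  pairs <- tibble::tibble(id_a = c("a", "b"), id_b = c("b", "c"),
                          bits = c(500, 500))
  ssn <- build_ssn(pairs, nodes, threshold = 380)
  comp <- ssn_components(ssn)
  expect_equal(comp$component[comp$sequence_id %in% c("a", "b", "c")],
               rep("a", 3))
  expect_equal(comp$component[comp$sequence_id == "z"], "z")

  # complete graph collapses to one component
  all_pairs <- tibble::tibble(
    id_a = c("a", "a", "a", "b", "b", "c"),
    id_b = c("b", "c", "z", "c", "z", "z"),
    bits = 999
  )
  expect_equal(
    dplyr::n_distinct(ssn_components(build_ssn(all_pairs, nodes))$component),
    1L
  )
})

test_that("cluster concordance scores purity and Rand agreement", {
  clusters <- tibble::tibble(
    sequence_id = sprintf("s%02d", 1:8),
    component = rep(c("c1", "c2"), each = 4)
  )
  labels <- dplyr::mutate(clusters, label = component, component = NULL)
  perfect <- cluster_concordance(clusters, labels)
  expect_equal(perfect$purity, 1.0)
  expect_equal(perfect$rand, 1.0)

  # one cluster containing two equal-sized labels contributes purity 1/2
  mixed <- dplyr::mutate(clusters, component = "c1")
  res <- cluster_concordance(mixed, labels)
  expect_equal(res$purity, 0.5)

  # shuffled labels score strictly below the true labelling
  set.seed(503)
  truth <- tibble::tibble(
    sequence_id = sprintf("t%02d", 1:36),
    component = rep(c("x", "y", "z"), each = 12)
  )
  tlabels <- dplyr::mutate(truth, label = component, component = NULL)
  base <- cluster_concordance(truth, tlabels)$rand
  for (i in 1:10) {
    shuf <- dplyr::mutate(tlabels, label = sample(label))
    expect_lt(cluster_concordance(truth, shuf)$rand, base)
  }
})

test_that("threshold sweeps are monotone in edges and components", {
  sim <- simulate_padc_families(small_specs(), seed = 31,
                                include_outgroup = FALSE)
  pairs <- pairwise_bitscores(sim$sequences)
  nodes <- tibble::tibble(
    sequence_id = sim$truth$sequence_id,
    linker_family = bin_linker_family(sim$truth$rel_linker_len)
  )
  labels <- tibble::tibble(sequence_id = sim$truth$sequence_id,
                           label = sim$truth$family)
  sweep <- threshold_sweep(pairs, nodes, c(100, 380, 800, 2000), labels)
  expect_true(all(diff(sweep$n_edges) <= 0))
  expect_true(all(diff(sweep$n_components) >= 0))
  expect_true(all(sweep$purity >= sweep$purity[1] - 1e-12))
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  sim <- simulate_padc_families(small_specs(), seed = 32,
                                include_outgroup = FALSE)
  pairs <- pairwise_bitscores(sim$sequences)
  nodes <- tibble::tibble(
    sequence_id = sim$truth$sequence_id,
    linker_family = bin_linker_family(sim$truth$rel_linker_len)
  )
  ssn <- build_ssn(pairs, nodes, threshold = 380)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_ssn_graphml(ssn, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(g)$name, nodes$sequence_id)
  expect_equal(igraph::ecount(g), nrow(ssn$edges))
  expect_setequal(igraph::V(g)$linker_family, nodes$linker_family)
  expect_equal(sort(igraph::E(g)$bits), sort(ssn$edges$bits))
})
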