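# Distance phylogenetics with delete-half jackknife support.  The original
# workflow (SEQBOOT / PROTDIST / FITCH / CONSENSE) is reproduced with two
# documented substitutions: Kimura-corrected p-distances in place of
# PROTDIST's default model, and neighbour joining in place of
# Fitch-Margoliash.  Both operate at the clustering level the family-level
# claims need; branch-level support values therefore carry a
# method-substitution caveat.

GAP_RAW <- charToRaw("-")

aln_rows_raw <- function(alignment) {
  if (is.data.frame(alignment)) {
    stopifnot(all(c("sequence_id", "aligned") %in% names(alignment)))
    seqs <- setNames(alignment$aligned, alignment$sequence_id)
  } else {
    stopifnot(is.character(alignment), !is.null(names(alignment)))
    seqs <- alignment
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  lapply(seqs, charToRaw)
}

kimura_protein_d <- function(p, d_max, saturation) {
  if (p >= saturation) return(d_max)
  min(-log(1 - p - 0.2 * p^2), d_max)
}

dist_from_raw <- function(rows, d_max = 5, saturation = 0.85) {
  n <- length(rows)
  labels <- names(rows)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    xi <- rows[[i]]
    gi <- xi != GAP_RAW
    for (j in (i + 1L):n) {
      xj <- rows[[j]]
      ok <- gi & (xj != GAP_RAW)
      m <- sum(ok)
      if (m == 0L) {
        stop("no comparable columns between '", labels[i], "' and '",
             labels[j], "'", call. = FALSE)
      }
      p <- sum(xi[ok] != xj[ok]) / m
      d[i, j] <- d[j, i] <- kimura_protein_d(p, d_max, saturation)
    }
  }
  d
}

#' Kimura-corrected protein distance matrix
#'
#' Pairwise distances `d = -ln(1 - p - 0.2 p^2)` where `p` is the mismatch
#' fraction over columns that are ungapped in both sequences (pairwise
#' deletion).  Saturated pairs (`p >= saturation`) are clamped to `d_max`.
#'
#' @param alignment Tibble (`sequence_id`, `aligned`) or named character
#'   vector of equal-length gapped rows; at least 3 taxa.
#' @param d_max Saturation clamp, substitutions/site (default 5).
#' @param saturation Mismatch fraction at which a pair is treated as
#'   saturated (default 0.85).
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
protein_distance <- function(alignment, d_max = 5, saturation = 0.85) {
  rows <- aln_rows_raw(alignment)
  if (length(rows) < 3L) stop("need at least 3 taxa", call. = FALSE)
  dist_from_raw(rows, d_max = d_max, saturation = saturation)
}

#' Delete-half jackknife sub-alignments
#'
#' Every replicate keeps `floor(L/2)` distinct columns drawn without
#' replacement, in their original order.  Replicate `i` uses its own seed
#' substream (`seed + i`), so partial re-runs reproduce individual
#' replicates.
#'
#' @inheritParams protein_distance
#' @param n_replicates Number of replicates (1000 in the original analysis).
#' @param seed Integer seed.
#' @return List of alignment tibbles (`sequence_id`, `aligned`).
#' @export
jackknife_resample <- function(alignment, n_replicates = 1000L, seed) {
  rows <- aln_rows_raw(alignment)
  L <- length(rows[[1]])
  if (L < 2L) stop("alignment must have at least 2 columns", call. = FALSE)
  ids <- names(rows)
  purrr::map(seq_len(n_replicates), function(i) {
    keep <- jackknife_columns(L, as.integer(seed), i)
    tibble::tibble(
      sequence_id = ids,
      aligned = purrr::map_chr(rows, function(r) rawToChar(r[keep]))
    )
  })
}

jackknife_columns <- function(L, seed, i) {
  withr::with_seed((seed + i) %% .Machine$integer.max,
                   sort(sample.int(L, L %/% 2L)))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Unrooted NJ tree ([ape::nj()]); negative branch-length estimates are
#' clamped to zero.  A degenerate all-zero matrix yields a star tree with a
#' warning.  On an additive matrix NJ recovers the generating topology.
#'
#' @param dm Symmetric distance matrix with taxa dimnames, `n >= 3`.
#' @return An [ape::phylo] tree.
#' @export
build_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L, isSymmetric(unname(dm)))
  taxa <- rownames(dm)
  if (all(dm == 0)) {
    warning("all distances are zero; returning a star tree")
    tree <- ape::read.tree(
      text = paste0("(", paste(taxa, collapse = ","), ");")
    )
    tree$edge.length <- rep(0, nrow(tree$edge))
    return(tree)
  }
  tree <- ape::nj(dm)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Jackknife replicate trees
#'
#' Convenience driver: resamples columns (delete-half), computes
#' Kimura-corrected distances and builds one NJ tree per replicate, without
#' materialising the replicate alignments as strings.
#'
#' @inheritParams jackknife_resample
#' @inheritParams protein_distance
#' @return List of [ape::phylo] trees of length `n_replicates`.
#' @export
jackknife_trees <- function(alignment, n_replicates = 1000L, seed,
                            d_max = 5, saturation = 0.85) {
  rows <- aln_rows_raw(alignment)
  L <- length(rows[[1]])
  purrr::map(seq_len(n_replicates), function(i) {
    keep <- jackknife_columns(L, as.integer(seed), i)
    sub <- lapply(rows, function(r) r[keep])
    build_tree(dist_from_raw(sub, d_max = d_max, saturation = saturation))
  })
}

# --- splits ----------------------------------------------------------------
# A split is represented by the tip set on the side NOT containing the
# reference taxon (the alphabetically first tip); keys are canonical sorted
# label strings.  Two splits are compatible iff their representative sets
# are nested or disjoint.

split_key <- function(labels) paste(sort(labels), collapse = "\r")

tree_splits <- function(tree, taxa) {
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  ref <- taxa[1]
  keys <- character()
  sets <- list()
  for (cl in pp) {
    side <- tips[cl]
    if (ref %in% side) side <- setdiff(taxa, side)
    if (length(side) < 2L || length(side) > length(taxa) - 2L) next
    k <- split_key(side)
    if (!(k %in% keys)) {
      keys <- c(keys, k)
      sets[[length(sets) + 1L]] <- side
    }
  }
  list(keys = keys, sets = sets)
}

splits_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

count_splits <- function(trees, taxa) {
  per_tree <- purrr::map(trees, tree_splits, taxa = taxa)
  all_keys <- unlist(purrr::map(per_tree, "keys"))
  counts <- table(all_keys)
  first_sets <- list()
  for (pt in per_tree) {
    for (i in seq_along(pt$keys)) {
      if (is.null(first_sets[[pt$keys[i]]])) {
        first_sets[[pt$keys[i]]] <- pt$sets[[i]]
      }
    }
  }
  keys <- names(counts)
  tibble::tibble(
    key = keys,
    clade = unname(first_sets[keys]),
    size = purrr::map_int(unname(first_sets[keys]), length),
    support = as.integer(counts)
  )
}

# Build a rooted-at-reference newick string from a laminar family of clades
# (each excluding the reference taxon), labelling internal nodes with
# support counts.
newick_from_clades <- function(clades, supports, taxa) {
  ref <- taxa[1]
  others <- setdiff(taxa, ref)
  ord <- order(-purrr::map_int(clades, length))
  clades <- clades[ord]
  supports <- supports[ord]

  # parent[i] = index of the smallest clade strictly containing clade i
  n_cl <- length(clades)
  parent <- rep(0L, n_cl)
  for (i in seq_len(n_cl)) {
    for (j in seq_len(i - 1L)) {
      # clades are sorted largest first, so the last containing j wins,
      # i.e. the smallest strictly containing clade
      if (all(clades[[i]] %in% clades[[j]])) parent[i] <- j
    }
  }
  tip_parent <- vapply(others, function(t) {
    best <- 0L
    for (i in seq_len(n_cl)) {
      if (t %in% clades[[i]]) best <- i  # clades sorted by decreasing size
    }
    best
  }, integer(1))

  render <- function(node) {
    child_cl <- which(parent == node)
    child_tips <- others[tip_parent == node]
    parts <- c(purrr::map_chr(child_cl, render), child_tips)
    if (node == 0L) {
      paste0("(", paste(c(parts, ref), collapse = ","), ");")
    } else {
      paste0("(", paste(parts, collapse = ","), ")", supports[node])
    }
  }
  render(0L)
}

#' Majority-rule consensus with jackknife supports
#'
#' Counts bipartitions across replicate trees, retains those present in more
#' than half of them and, under the extended rule, greedily adds the
#' remaining splits in order of decreasing frequency whenever they are
#' compatible with the tree built so far.  Support values are raw replicate
#' counts (internal node labels of the returned tree).
#'
#' @param trees List of [ape::phylo] trees on identical leaf sets.
#' @param rule `"extended"` (majority plus greedy compatible fill-in,
#'   default) or `"majority"` (strict > 50\% rule).
#' @param n_replicates Number of replicates the counts refer to; defaults to
#'   `length(trees)`.
#' @return A `padc_consensus` object: `tree` (consensus, rooted at the
#'   alphabetically first tip for representation only), `splits` (tibble of
#'   all observed splits with `support` and `retained`), `n_replicates`,
#'   `rule`.
#' @export
consensus_tree <- function(trees, rule = c("extended", "majority"),
                           n_replicates = length(trees)) {
  rule <- match.arg(rule)
  stopifnot(length(trees) >= 1L)
  taxa <- sort(trees[[1]]$tip.label)
  same <- purrr::map_lgl(trees, function(t) {
    setequal(t$tip.label, taxa)
  })
  if (!all(same)) stop("trees must share one leaf set", call. = FALSE)

  splits <- count_splits(trees, taxa)
  splits <- dplyr::arrange(splits, dplyr::desc(.data$support), .data$key)

  majority <- splits$support > n_replicates / 2
  retained <- majority
  if (rule == "extended") {
    kept <- which(majority)
    for (i in which(!majority)) {
      ok <- all(purrr::map_lgl(kept, function(j) {
        splits_compatible(splits$clade[[i]], splits$clade[[j]])
      }))
      if (ok) {
        kept <- c(kept, i)
        retained[i] <- TRUE
      }
    }
  }
  splits$retained <- retained

  txt <- newick_from_clades(splits$clade[retained],
                            splits$support[retained], taxa)
  tree <- ape::read.tree(text = txt)

  structure(list(tree = tree, splits = splits,
                 n_replicates = as.integer(n_replicates), rule = rule),
            class = "padc_consensus")
}

#' @export
print.padc_consensus <- function(x, ...) {
  cat("<padc_consensus> ", length(x$tree$tip.label), " tips, ",
      sum(x$splits$retained), " internal splits retained (",
      x$rule, " rule, ", x$n_replicates, " replicates)\n", sep = "")
  invisible(x)
}

#' Jackknife support of a clade
#'
#' Number of replicate trees containing the bipartition that separates
#' `leaf_set` from the remaining taxa; 0 when the bipartition was never
#' observed.  Trivial bipartitions (single leaves, their complements, the
#' full set) are supported by every replicate by convention.
#'
#' @param consensus A `padc_consensus` from [consensus_tree()].
#' @param leaf_set Character vector of tip labels.
#' @return Integer support count in `[0, n_replicates]`.
#' @export
clade_support <- function(consensus, leaf_set) {
  stopifnot(inherits(consensus, "padc_consensus"))
  taxa <- sort(consensus$tree$tip.label)
  if (!all(leaf_set %in% taxa)) {
    stop("leaf_set contains unknown tips", call. = FALSE)
  }
  side <- unique(leaf_set)
  if (taxa[1] %in% side) side <- setdiff(taxa, side)
  if (length(side) < 2L || length(side) > length(taxa) - 2L) {
    return(consensus$n_replicates)
  }
  k <- split_key(side)
  hit <- consensus$splits$support[consensus$splits$key == k]
  if (length(hit) == 0L) 0L else as.integer(hit)
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup.
#' For multi-leaf outgroups the outgroup must form a clade of the unrooted
#' tree, otherwise an error is raised.  Re-rooting with the same outgroup is
#' idempotent.
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Tip label or character vector of tip labels.
#' @return A rooted [ape::phylo] tree.
#' @export
root_tree <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(outgroup %in% tree$tip.label)) {
    stop("outgroup tips not present in tree", call. = FALSE)
  }
  if (length(outgroup) > 1L) {
    taxa <- sort(tree$tip.label)
    sp <- tree_splits(tree, taxa)
    side <- outgroup
    if (taxa[1] %in% side) side <- setdiff(taxa, side)
    if (!(split_key(side) %in% sp$keys)) {
      stop("outgroup is not monophyletic in the tree", call. = FALSE)
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' @describeIn consensus_tree Tidy the consensus into its split table
#'   (`clade` list column, `size`, `support`, `retained`).
#' @param x A `padc_consensus`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.padc_consensus <- function(x, ...) {
  dplyr::select(x$splits, "clade", "size", "support", "retained")
}

#' @describeIn consensus_tree One-row summary of the consensus.
#' @exportS3Method generics::glance
glance.padc_consensus <- function(x, ...) {
  kept <- x$splits[x$splits$retained, ]
  tibble::tibble(
    n_tips = length(x$tree$tip.label),
    n_replicates = x$n_replicates,
    n_splits_retained = nrow(kept),
    min_support = if (nrow(kept)) min(kept$support) else NA_integer_,
    mean_support = if (nrow(kept)) mean(kept$support) else NA_real_
  )
}
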