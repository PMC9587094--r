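# Sequence similarity network: pairwise local alignment bitscores, the
# keep-higher-of-pair rule, strict edge thresholding and connected-component
# clustering.  The original analysis used all-vs-all BLAST; here scores come
# from optimal affine-gap alignment under BLOSUM62 with BLAST's default gap
# costs (11/1) and fixed gapped Karlin-Altschul constants, so absolute
# bitscores can deviate slightly from NCBI BLAST (no compositional
# adjustment); the edge threshold is therefore an argument everywhere.

#' Alignment scoring scheme for SSN bitscores
#'
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings;
#'   default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive affine gap penalties; a gap of length
#'   k costs `gap_open + k * gap_extend` (BLAST convention).
#' @param lambda,K Gapped Karlin-Altschul parameters used to convert raw
#'   scores to bits: `bits = (lambda * raw - ln K) / ln 2`.  Defaults are the
#'   standard gapped BLOSUM62/11/1 constants (0.267, 0.041).
#' @param type `"local"` (Smith-Waterman, BLAST-like; default) or
#'   `"global"`.
#' @return A list describing the scheme.
#' @export
default_scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                                   gap_extend = 1, lambda = 0.267,
                                   K = 0.041, type = "local") {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0,
            type %in% c("local", "global"))
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
       lambda = lambda, K = K, type = type)
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

raw_to_bits <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Bitscore of one sequence pair
#'
#' Optimal affine-gap alignment score of the pair under the scheme,
#' converted to bits.  Residues outside the 20-letter alphabet are scored as
#' X.  The score is computed once per unordered pair and is symmetric by
#' construction.
#'
#' @param a,b Protein sequences (single strings).
#' @param scheme Scoring scheme, see [default_scoring_scheme()].
#' @return One-row tibble with `raw_score` and `bits`.
#' @export
pairwise_bitscore <- function(a, b, scheme = default_scoring_scheme()) {
  assert_scalar_string(a, "a")
  assert_scalar_string(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  mat <- get_substitution_matrix(scheme$matrix)
  raw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(clean_aa(a)), Biostrings::AAString(clean_aa(b)),
    substitutionMatrix = mat, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = scheme$type, scoreOnly = TRUE
  )
  tibble::tibble(raw_score = raw, bits = raw_to_bits(raw, scheme))
}

#' All-vs-all bitscores for a table of sequences
#'
#' Computes every unordered pair once (so the keep-higher-of-pair rule is a
#' no-op on these scores, as it should be for a symmetric scorer).
#'
#' @param df Tibble with columns `sequence_id` and `sequence`.
#' @inheritParams pairwise_bitscore
#' @return Tibble `id_a`, `id_b`, `raw_score`, `bits`, one row per unordered
#'   pair, with `id_a < id_b`.
#' @export
pairwise_bitscores <- function(df, scheme = default_scoring_scheme()) {
  stopifnot(all(c("sequence_id", "sequence") %in% names(df)))
  n <- nrow(df)
  if (n < 2L) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          raw_score = numeric(), bits = numeric()))
  }
  mat <- get_substitution_matrix(scheme$matrix)
  seqs <- Biostrings::AAStringSet(
    setNames(clean_aa(df$sequence), df$sequence_id)
  )
  out <- purrr::map(2:n, function(j) {
    raw <- Biostrings::pairwiseAlignment(
      seqs[seq_len(j - 1L)], seqs[[j]],
      substitutionMatrix = mat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, type = scheme$type, scoreOnly = TRUE
    )
    tibble::tibble(id_a = df$sequence_id[seq_len(j - 1L)],
                   id_b = df$sequence_id[j], raw_score = raw)
  })
  out <- dplyr::bind_rows(out)
  swap <- out$id_a > out$id_b
  tmp <- out$id_a[swap]
  out$id_a[swap] <- out$id_b[swap]
  out$id_b[swap] <- tmp
  dplyr::arrange(
    dplyr::mutate(out, bits = raw_to_bits(.data$raw_score, scheme)),
    .data$id_a, .data$id_b
  )
}

#' Keep the higher of a pair of directed scores
#'
#' BLAST reports a bitscore per query-subject direction; per unordered pair
#' only the higher one is kept.  With the package's symmetric scorer this is
#' an idempotent canonicalisation.
#'
#' @param scores Tibble with columns `id_a`, `id_b`, `bits` (and optionally
#'   `raw_score`), possibly containing both directions of a pair.
#' @return One row per unordered pair with the maximum `bits`.
#' @export
keep_higher_of_pair <- function(scores) {
  stopifnot(all(c("id_a", "id_b", "bits") %in% names(scores)))
  scores |>
    dplyr::mutate(
      .a = pmin(.data$id_a, .data$id_b),
      .b = pmax(.data$id_a, .data$id_b)
    ) |>
    dplyr::group_by(.data$.a, .data$.b) |>
    dplyr::slice_max(.data$bits, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(id_a = .data$.a, id_b = .data$.b) |>
    dplyr::select(-".a", -".b") |>
    dplyr::arrange(.data$id_a, .data$id_b)
}

#' Build the sequence similarity network
#'
#' Nodes are all sequences in `node_attrs`; edges are unordered pairs whose
#' bitscore strictly exceeds the threshold (380 bits by default, the cut-off
#' at which the natural PadC families separate by linker length).
#'
#' @param pairs Pair-score tibble from [pairwise_bitscores()] (or
#'   [keep_higher_of_pair()]).
#' @param node_attrs Tibble whose first column is `sequence_id`; remaining
#'   columns (e.g. `linker_family`, `rel_linker_len`, `class_call`,
#'   `taxonomy_class`) become node attributes.
#' @param threshold Bitscore threshold; edges require `bits > threshold`.
#' @return A `padc_ssn` object wrapping an igraph graph, the retained edge
#'   table and the threshold.
#' @export
build_ssn <- function(pairs, node_attrs, threshold = 380) {
  stopifnot(names(node_attrs)[1] == "sequence_id")
  ids <- unique(c(pairs$id_a, pairs$id_b))
  if (!all(ids %in% node_attrs$sequence_id)) {
    stop("node_attrs must cover all ids in pairs", call. = FALSE)
  }
  edges <- pairs |>
    keep_higher_of_pair() |>
    dplyr::filter(.data$bits > threshold, .data$id_a != .data$id_b)
  g <- igraph::graph_from_data_frame(
    dplyr::select(edges, "id_a", "id_b", "bits"),
    directed = FALSE,
    vertices = as.data.frame(node_attrs)
  )
  structure(
    list(graph = g, edges = edges, nodes = node_attrs,
         threshold = threshold),
    class = "padc_ssn"
  )
}

#' @export
print.padc_ssn <- function(x, ...) {
  cat("<padc_ssn> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (bits > ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Connected components of an SSN
#'
#' @param ssn A `padc_ssn` from [build_ssn()].
#' @return Tibble `sequence_id`, `component`, where each component is
#'   labelled by its lexicographically smallest member id.
#' @export
ssn_components <- function(ssn) {
  comp <- igraph::components(ssn$graph)
  member <- tibble::tibble(
    sequence_id = igraph::V(ssn$graph)$name,
    .comp = comp$membership
  )
  labels <- member |>
    dplyr::group_by(.data$.comp) |>
    dplyr::summarise(component = min(.data$sequence_id), .groups = "drop")
  member |>
    dplyr::left_join(labels, by = ".comp") |>
    dplyr::select("sequence_id", "component") |>
    dplyr::arrange(.data$sequence_id)
}

#' Concordance between SSN clusters and linker-family labels
#'
#' Purity is the fraction of nodes whose cluster's majority label matches
#' their own; pairwise agreement is the Rand index between the cluster
#' partition and the label partition.
#'
#' @param clusters Tibble `sequence_id`, `component` (see
#'   [ssn_components()]).
#' @param labels Tibble `sequence_id`, `label`, covering all clustered nodes.
#' @return One-row tibble with `purity` and `rand`.
#' @export
cluster_concordance <- function(clusters, labels) {
  stopifnot(all(c("sequence_id", "component") %in% names(clusters)),
            all(c("sequence_id", "label") %in% names(labels)))
  df <- dplyr::inner_join(clusters, labels, by = "sequence_id")
  if (nrow(df) < nrow(clusters)) {
    stop("labels must cover all clustered nodes", call. = FALSE)
  }
  n <- nrow(df)
  tab <- table(df$component, df$label)
  purity <- sum(apply(tab, 1L, max)) / n

  # Rand index by pair counting from the contingency table
  comb2 <- function(x) x * (x - 1) / 2
  n_pairs <- comb2(n)
  a <- sum(comb2(tab))                       # same cluster, same label
  same_cluster <- sum(comb2(rowSums(tab)))
  same_label <- sum(comb2(colSums(tab)))
  d <- n_pairs - same_cluster - same_label + a
  tibble::tibble(purity = purity, rand = (a + d) / n_pairs)
}

#' Edge, component and purity profile across thresholds
#'
#' @inheritParams build_ssn
#' @param thresholds Ascending numeric vector of bitscore thresholds.
#' @param labels Optional label tibble (`sequence_id`, `label`) for purity;
#'   when `NULL`, purity is `NA`.
#' @return Tibble `threshold`, `n_edges`, `n_components`, `purity`.
#' @export
threshold_sweep <- function(pairs, node_attrs, thresholds, labels = NULL) {
  stopifnot(!is.unsorted(thresholds))
  purrr::map_dfr(thresholds, function(t) {
    ssn <- build_ssn(pairs, node_attrs, threshold = t)
    comp <- ssn_components(ssn)
    purity <- if (is.null(labels)) {
      NA_real_
    } else {
      cluster_concordance(comp, labels)$purity
    }
    tibble::tibble(threshold = t, n_edges = nrow(ssn$edges),
                   n_components = dplyr::n_distinct(comp$component),
                   purity = purity)
  })
}

#' Export an SSN to GraphML
#'
#' @param ssn A `padc_ssn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssn_graphml <- function(ssn, path) {
  igraph::write_graph(ssn$graph, path, format = "graphml")
  invisible(path)
}

#' @describeIn build_ssn Tidy the SSN into its edge table.
#' @param x A `padc_ssn`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.padc_ssn <- function(x, ...) {
  x$edges
}

#' @describeIn build_ssn One-row summary: node, edge and component counts.
#' @exportS3Method generics::glance
glance.padc_ssn <- function(x, ...) {
  comp <- ssn_components(x)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    threshold = x$threshold,
    n_components = dplyr::n_distinct(comp$component)
  )
}

#' @describeIn build_ssn Plot the network with nodes coloured by linker
#'   family (requires a `linker_family` node attribute).
#' @param object A `padc_ssn`.
#' @exportS3Method ggplot2::autoplot
autoplot.padc_ssn <- function(object, ...) {
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- dplyr::mutate(object$nodes, x = lay[, 1], y = lay[, 2])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "sequence_id", xa = "x", ya = "y"),
                     by = c(id_a = "sequence_id")) |>
    dplyr::left_join(dplyr::select(nodes, "sequence_id", xb = "x", yb = "y"),
                     by = c(id_b = "sequence_id"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya,
                   xend = .data$xb, yend = .data$yb),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::theme_void()
  if ("linker_family" %in% names(nodes)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$linker_family),
                            size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
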