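# End-to-end orchestration: sequences -> classification -> linker metrics ->
# registers -> SSN -> jackknife consensus tree -> prevalence report.

#' Default pipeline configuration
#'
#' The stated synthetic world: the six demo linker families of
#' [default_family_specs()], a rooting outgroup, the 380-bit SSN threshold
#' and 200 delete-half jackknife replicates (scaled down from the original
#' 1000 so a desk run finishes in minutes; pass `n_replicates = 1000` for
#' the full analysis).
#'
#' @param families Family specification tibble, or `NULL` when `sequences` /
#'   `alignment` are supplied directly.
#' @param include_outgroup Simulate a motif-free outgroup for rooting.
#' @param threshold_bits SSN edge threshold (bits).
#' @param n_replicates Jackknife replicate count.
#' @param sequences,alignment,anchor_ref Pre-existing inputs: tibbles (or
#'   FASTA paths) plus `list(sequence_id, position)` naming the reference
#'   anchor; only used when `families` is `NULL`.
#' @param min_eal_tail,stabilisers,reference_length Forwarded to the
#'   classification, register and linker stages.
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(families = default_family_specs(),
                            include_outgroup = TRUE,
                            threshold_bits = 380,
                            n_replicates = 200L,
                            sequences = NULL, alignment = NULL,
                            anchor_ref = NULL,
                            min_eal_tail = 150L,
                            stabilisers = default_stabilisers(),
                            reference_length = 28L) {
  list(families = families, include_outgroup = include_outgroup,
       threshold_bits = threshold_bits, n_replicates = n_replicates,
       sequences = sequences, alignment = alignment, anchor_ref = anchor_ref,
       min_eal_tail = min_eal_tail, stabilisers = stabilisers,
       reference_length = reference_length)
}

#' Run the full PadC characterisation pipeline
#'
#' Simulates (or loads) the sequence set, classifies every sequence,
#' computes linker annotations from the alignment-anchored PHY residue,
#' calls heptad registers, builds the bitscore-thresholded SSN over the
#' classified PadC/PadC-EAL members, runs the delete-half jackknife
#' consensus phylogeny over all aligned sequences, and summarises
#' linker-length prevalence.  Every input sequence appears exactly once in
#' the annotation table; stage failures are carried as explicit status
#' values, never dropped.
#'
#' @param config Configuration list, see [pipeline_config()].
#' @param seed Integer seed driving every stochastic stage.
#' @param outdir Optional output directory; when given, annotation /
#'   prevalence / edge TSVs, the GraphML network, the Newick consensus and a
#'   JSON run log are written there.
#' @return A `padc_run` list: `annotations`, `prevalence`, `ssn`,
#'   `components`, `concordance`, `trees` count, `consensus`, `rooted_tree`
#'   (when an outgroup is present), `sim` (when simulated), `config`,
#'   `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed, outdir = NULL) {
  seed <- as.integer(seed)

  if (!is.null(config$families)) {
    sim <- simulate_padc_families(config$families, seed = seed,
                                  include_outgroup = config$include_outgroup)
    sequences <- sim$sequences
    alignment <- sim$alignment
    anchor_ref <- sim$anchor_ref
  } else {
    sim <- NULL
    sequences <- config$sequences
    alignment <- config$alignment
    anchor_ref <- config$anchor_ref
    if (is.character(sequences)) sequences <- read_fasta_tbl(sequences)
    if (is.character(alignment)) {
      alignment <- read_fasta_tbl(alignment, column = "aligned")
    }
    if (is.null(sequences) || is.null(alignment)) {
      stop("config must provide either families or sequences + alignment",
           call. = FALSE)
    }
    if (is.null(anchor_ref) || is.null(anchor_ref$sequence_id) ||
        is.null(anchor_ref$position)) {
      stop("config$anchor_ref must name the reference sequence and its ",
           "1-based anchor position", call. = FALSE)
    }
  }

  cls <- classify_sequences(sequences, min_eal_tail = config$min_eal_tail)
  anchors <- locate_phy_anchor(alignment, anchor_ref$sequence_id,
                               anchor_ref$position)

  members <- sequences |>
    dplyr::left_join(dplyr::select(cls, "sequence_id", "class_call",
                                   "pde_active"),
                     by = "sequence_id") |>
    dplyr::left_join(dplyr::select(anchors, "sequence_id", "anchor_idx",
                                   anchor_status = "status"),
                     by = "sequence_id")

  # linker + registers only make sense for classified members
  is_member <- members$class_call %in% c("PadC", "PadC-EAL")
  link_in <- members[is_member, c("sequence_id", "sequence", "anchor_idx")]
  linkers <- annotate_linkers(link_in,
                              reference_length = config$reference_length)
  reg_in <- dplyr::left_join(
    link_in,
    dplyr::select(linkers, "sequence_id", "dxlt_idx", "rel_linker_len"),
    by = "sequence_id"
  )
  registers <- annotate_registers(reg_in, stabilisers = config$stabilisers)

  annotations <- members |>
    dplyr::left_join(
      dplyr::select(linkers, "sequence_id", "dxlt_idx", "abs_linker_len",
                    "rel_linker_len", "linker_family",
                    linker_status = "status"),
      by = "sequence_id"
    ) |>
    dplyr::left_join(
      dplyr::select(registers, "sequence_id", "phase_scores",
                    "inhibiting_phase", "stimulating_phase",
                    "overwind_breakpoint", "regulatory_class",
                    register_status = "status"),
      by = "sequence_id"
    ) |>
    dplyr::mutate(
      status = dplyr::case_when(
        !(.data$class_call %in% c("PadC", "PadC-EAL")) ~ "not a family member",
        .data$linker_status != "ok" ~ .data$linker_status,
        .data$register_status != "ok" ~ .data$register_status,
        TRUE ~ "ok"
      )
    ) |>
    dplyr::select(-"linker_status", -"register_status")

  prevalence <- prevalence_table(annotations)

  # SSN over classified members only (the network of the family)
  member_tbl <- annotations[is_member, ]
  pairs <- pairwise_bitscores(
    member_tbl[, c("sequence_id", "sequence")]
  )
  node_attrs <- dplyr::select(member_tbl, "sequence_id", "class_call",
                              "linker_family", "rel_linker_len",
                              "taxonomy_class")
  ssn <- build_ssn(pairs, node_attrs, threshold = config$threshold_bits)
  components <- ssn_components(ssn)
  concordance <- cluster_concordance(
    components,
    dplyr::transmute(member_tbl, .data$sequence_id,
                     label = .data$linker_family)
  )

  trees <- jackknife_trees(alignment, n_replicates = config$n_replicates,
                           seed = seed)
  consensus <- consensus_tree(trees, n_replicates = config$n_replicates)
  rooted <- NULL
  outgroup_ids <- setdiff(alignment$sequence_id, member_tbl$sequence_id)
  if (length(outgroup_ids) == 1L) {
    rooted <- root_tree(consensus$tree, outgroup_ids)
  }

  run <- structure(list(
    annotations = annotations,
    prevalence = prevalence,
    pairs = pairs,
    ssn = ssn,
    components = components,
    concordance = concordance,
    consensus = consensus,
    rooted_tree = rooted,
    sim = sim,
    config = config,
    seed = seed
  ), class = "padc_run")

  if (!is.null(outdir)) write_run(run, outdir)
  run
}

flatten_annotations <- function(annotations) {
  annotations |>
    dplyr::mutate(
      phase_scores = purrr::map_chr(.data$phase_scores, function(s) {
        if (all(is.na(s))) NA_character_ else paste(signif(s, 6),
                                                   collapse = ",")
      })
    ) |>
    dplyr::select(-dplyr::any_of(c("missing_motifs", "hits", "sequence")))
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(flatten_annotations(run$annotations),
                   file.path(outdir, "annotations.tsv"))
  readr::write_tsv(run$prevalence, file.path(outdir, "prevalence.tsv"))
  readr::write_tsv(run$ssn$edges, file.path(outdir, "ssn_edges.tsv"))
  readr::write_tsv(run$ssn$nodes, file.path(outdir, "ssn_nodes.tsv"))
  write_ssn_graphml(run$ssn, file.path(outdir, "ssn.graphml"))
  tree <- run$rooted_tree %||% run$consensus$tree
  ape::write.tree(tree, file.path(outdir, "consensus.nwk"))
  log <- list(
    seed = run$seed,
    threshold_bits = run$config$threshold_bits,
    n_replicates = run$config$n_replicates,
    reference_length = run$config$reference_length,
    stabilisers = paste(run$config$stabilisers, collapse = ""),
    package_version = as.character(utils::packageVersion("padctools")),
    r_version = R.version.string
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.padc_run <- function(x, ...) {
  n <- nrow(x$annotations)
  cat("<padc_run> ", n, " sequences; ",
      sum(x$annotations$class_call == "PadC"), " PadC, ",
      sum(x$annotations$class_call == "PadC-EAL"), " PadC-EAL; ",
      dplyr::n_distinct(x$components$component), " SSN components at > ",
      x$config$threshold_bits, " bits; ",
      x$consensus$n_replicates, " jackknife replicates\n", sep = "")
  invisible(x)
}

#' Linker-length prevalence table
#'
#' Counts and within-class fractions of relative linker lengths, reported
#' per class (`PadC`, `PadC-EAL`) and for both classes combined -- the
#' published prevalence figures are ambiguous about that denominator, so
#' both splits are always reported.  Fractions sum to 1 within each class.
#'
#' @param annotations Annotation tibble with `class_call` and
#'   `rel_linker_len` columns (e.g. from [run_pipeline()]).
#' @return Tibble `class`, `rel_linker_len`, `linker_family`, `count`,
#'   `fraction`.
#' @export
prevalence_table <- function(annotations) {
  stopifnot(nrow(annotations) > 0)
  base <- annotations |>
    dplyr::filter(.data$class_call %in% c("PadC", "PadC-EAL"),
                  !is.na(.data$rel_linker_len))
  one <- function(df, label) {
    if (nrow(df) == 0L) return(NULL)
    df |>
      dplyr::count(.data$rel_linker_len, name = "count") |>
      dplyr::mutate(
        class = label,
        linker_family = bin_linker_family(.data$rel_linker_len),
        fraction = .data$count / sum(.data$count)
      ) |>
      dplyr::select("class", "rel_linker_len", "linker_family", "count",
                    "fraction")
  }
  dplyr::bind_rows(
    one(dplyr::filter(base, .data$class_call == "PadC"), "PadC"),
    one(dplyr::filter(base, .data$class_call == "PadC-EAL"), "PadC-EAL"),
    one(base, "combined")
  )
}

#' Fraction of a class with linker lengths divisible by seven
#'
#' @inheritParams prevalence_table
#' @param class `"PadC"`, `"PadC-EAL"` or `"combined"`.
#' @return Single numeric fraction.
#' @export
div7_fraction <- function(annotations, class = "PadC") {
  prev <- prevalence_table(annotations)
  prev <- prev[prev$class == class, ]
  sum(prev$fraction[prev$linker_family == "div7"])
}

#' Bar chart of linker-length prevalence
#'
#' @param prevalence Output of [prevalence_table()].
#' @return A ggplot object: per-class relative frequencies of relative
#'   linker lengths, coloured by linker family.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(
    prevalence,
    ggplot2::aes(x = factor(.data$rel_linker_len), y = .data$fraction,
                 fill = .data$linker_family)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = "relative linker length (residues)",
                  y = "fraction of class", fill = "linker family") +
    ggplot2::theme_minimal()
}

#' @describeIn run_pipeline Tidy a pipeline run into its annotation table
#'   (without raw sequences).
#' @param x A `padc_run`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.padc_run <- function(x, ...) {
  flatten_annotations(x$annotations)
}

#' @describeIn run_pipeline One-row run summary: class counts, SSN
#'   components, cluster purity, consensus support range.
#' @exportS3Method generics::glance
glance.padc_run <- function(x, ...) {
  g <- glance(x$consensus)
  tibble::tibble(
    n_sequences = nrow(x$annotations),
    n_padc = sum(x$annotations$class_call == "PadC"),
    n_padc_eal = sum(x$annotations$class_call == "PadC-EAL"),
    n_non_member = sum(x$annotations$class_call == "non-member"),
    n_components = dplyr::n_distinct(x$components$component),
    purity = x$concordance$purity,
    rand = x$concordance$rand,
    n_replicates = g$n_replicates,
    min_support = g$min_support
  )
}
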