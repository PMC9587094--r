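# Synthetic PadC-like families with planted ground truth.
#
# Templates follow the PadC domain architecture: NTS - PAS/GAF - PHY -
# coiled-coil linker - GGDEF (- EAL-linker - EAL).  Block lengths are
# order-of-magnitude realistic defaults (NTS 30, PAS+GAF 320, PHY 150,
# GGDEF 160, EAL-linker 25, EAL 250); only the domain order is biologically
# fixed.  All essential motifs are planted at known offsets and masked
# against mutation, so classification, linker length and register calls have
# an exact ground truth.

BLOCK_LENGTHS <- c(nts = 30L, pas_gaf = 320L, phy = 150L,
                   ggdef = 160L, eal_linker = 25L, eal = 250L)

HYDROPHOBIC_AD <- c("L", "I", "V", "M")
# polar alphabet for non-slot linker positions; D is excluded so the region
# between anchor and DXLT can never contain a premature D.LT match, N is
# reserved for the planted stimulating register, and A is excluded because it
# counts as a stabiliser and would blur the planted registers
LINKER_POLAR <- c("S", "T", "Q", "E", "K", "R", "G")

REFERENCE_LINKER_LENGTH <- 28L

#' Describe one synthetic PadC family
#'
#' @param family_id Family label (unique within a dataset).
#' @param relative_linker_length Linker length relative to the 28-residue
#'   reference; absolute length is `28 + relative_linker_length` and must be
#'   non-negative.
#' @param has_eal Does the family carry a C-terminal EAL domain (PadC-EAL)?
#' @param pde_active Is the EAL domain catalytically competent?  If `FALSE`
#'   the EAL motif is planted as its degenerate EAF variant and the DDFGTG
#'   motif is scrambled.  Requires `has_eal`.
#' @param n_members Number of sequences to draw from the family template.
#' @param within_divergence Per-site substitution probability applied to
#'   unmasked template positions, in `[0, 1)`.
#' @param taxonomy_class Free-text taxonomy label carried into node/report
#'   attributes.
#' @return One-row tibble (a `FamilySpec` row).
#' @export
family_spec <- function(family_id, relative_linker_length, has_eal = FALSE,
                        pde_active = has_eal, n_members = 10L,
                        within_divergence = 0.15,
                        taxonomy_class = NA_character_) {
  relative_linker_length <- as.integer(relative_linker_length)
  if (REFERENCE_LINKER_LENGTH + relative_linker_length < 0L) {
    stop("relative_linker_length ", relative_linker_length,
         " implies a negative absolute linker length", call. = FALSE)
  }
  if (pde_active && !has_eal) {
    stop("pde_active requires has_eal", call. = FALSE)
  }
  stopifnot(n_members >= 1L, within_divergence >= 0, within_divergence < 1)
  tibble::tibble(
    family_id = as.character(family_id),
    relative_linker_length = relative_linker_length,
    has_eal = has_eal,
    pde_active = pde_active,
    n_members = as.integer(n_members),
    within_divergence = within_divergence,
    taxonomy_class = taxonomy_class
  )
}

#' Default demo families
#'
#' Six families at the linker lengths that dominate the natural PadC set
#' (-7, -4, 0, +2, +7, +14), ten members each at 15\% within-family
#' divergence.  The -7 family is a PadC-EAL with a degenerate (EAF) motif,
#' echoing the naturally occurring PDE-dead -7 PadC-EALs; taxonomy labels
#' follow the classes the linker families are enriched in.
#'
#' @return Tibble of family specifications, one row per family.
#' @export
default_family_specs <- function() {
  dplyr::bind_rows(
    family_spec("fam_m7eal", -7L, has_eal = TRUE, pde_active = FALSE,
                taxonomy_class = "Betaproteobacteria"),
    family_spec("fam_m4", -4L, taxonomy_class = "Actinobacteria"),
    family_spec("fam_0", 0L, taxonomy_class = "Gammaproteobacteria"),
    family_spec("fam_p2", 2L, taxonomy_class = "Gammaproteobacteria"),
    family_spec("fam_p7", 7L, taxonomy_class = "Alphaproteobacteria"),
    family_spec("fam_p14", 14L, taxonomy_class = "Gammaproteobacteria")
  )
}

# heptad frame in phase with the DXLT end of the linker: for 0-based linker
# index i and length n, j(i) = (i - n) mod 7; 'a' positions of phase p sit at
# j == p, 'd' positions at j == p + 3.  The planted inhibiting register
# (phase 0) gets hydrophobics at a/d, the planted stimulating register
# (phase 2) gets Asn at its a/d positions; phases 0 and 2 are the only pair
# for which both planted registers score exactly 1 while all others score
# at most 1/2.
in_frame_linker <- function(n) {
  if (n == 0L) return("")
  j <- (seq_len(n) - 1L - n) %% 7L
  res <- character(n)
  slot_inh <- j %in% c(0L, 3L)
  slot_sti <- j %in% c(2L, 5L)
  res[slot_inh] <- sample(HYDROPHOBIC_AD, sum(slot_inh), replace = TRUE)
  res[slot_sti] <- "N"
  res[!(slot_inh | slot_sti)] <-
    sample(LINKER_POLAR, sum(!(slot_inh | slot_sti)), replace = TRUE)
  paste(res, collapse = "")
}

# Build the linker block for a relative length.  Whole-heptad lengths are
# built directly in frame with the DXLT end; -4 linkers are built as an
# in-frame 28-mer with residues 10..13 deleted (the deletion the overwinding
# model compensates); other frame-breaking lengths insert rel mod 7 polar
# residues at position 10 of an in-frame core.
build_linker_block <- function(relative_linker_length) {
  rel <- as.integer(relative_linker_length)
  n <- REFERENCE_LINKER_LENGTH + rel
  if (n < 0L) {
    stop("negative absolute linker length (", n, ") for relative length ",
         rel, call. = FALSE)
  }
  k <- rel %% 7L
  if (k == 0L) return(in_frame_linker(n))
  if (rel == -4L) {
    x <- strsplit(in_frame_linker(28L), "")[[1]]
    return(paste(x[-(11:14)], collapse = ""))
  }
  core <- strsplit(in_frame_linker(n - k), "")[[1]]
  at <- min(10L, length(core))
  ins <- sample(LINKER_POLAR, k, replace = TRUE)
  paste(c(head(core, at), ins, core[seq_along(core) > at]), collapse = "")
}

build_template_core <- function(spec, max_tries = 100L) {
  # chance motif copies in the random blocks (e.g. a GG[DE]EF between DXLT
  # and the planted one) would shadow the planted truth; rebuild until clean
  for (i in seq_len(max_tries)) {
    tpl <- build_template_once(spec)
    if (sequence_truth_clean(tpl$sequence, tpl)) return(tpl)
  }
  stop("could not build a truth-clean template", call. = FALSE)
}

build_template_once <- function(spec) {
  rel <- spec$relative_linker_length
  bl <- BLOCK_LENGTHS

  nts <- strsplit(random_aa_string(bl[["nts"]]), "")[[1]]
  nts[17] <- "C"  # chromophore-binding cysteine, C17-like
  nts <- paste(nts, collapse = "")

  pas_gaf <- strsplit(random_aa_string(bl[["pas_gaf"]]), "")[[1]]
  dip_off <- 200L
  pas_gaf[dip_off + 1:3] <- c("D", "I", "P")
  pas_gaf <- paste(pas_gaf, collapse = "")

  phy <- strsplit(random_aa_string(bl[["phy"]]), "")[[1]]
  prxsf_off <- 80L
  phy[prxsf_off + 1:5] <- c("P", "R", sample(AA20, 1L), "S", "F")
  phy[bl[["phy"]]] <- "I"  # terminal PHY-helix hydrophobic anchor
  phy <- paste(phy, collapse = "")

  linker <- build_linker_block(rel)
  n_linker <- nchar(linker)

  ggdef <- strsplit(random_aa_string(bl[["ggdef"]]), "")[[1]]
  ggdef[1:4] <- c("D", "S", "L", "T")  # DXLT opens the effector block
  ggdef_motif_off <- bl[["ggdef"]] - 5L
  ggdef[ggdef_motif_off + 1:5] <-
    c("G", "G", sample(c("D", "E"), 1L), "E", "F")
  ggdef <- paste(ggdef, collapse = "")

  blocks <- c(nts = nts, pas_gaf = pas_gaf, phy = phy,
              linker = linker, ggdef = ggdef)

  if (spec$has_eal) {
    eal_linker <- random_aa_string(bl[["eal_linker"]])
    eal <- strsplit(random_aa_string(bl[["eal"]]), "")[[1]]
    eal[1:3] <- c("E", sample(c("A", "I", "L", "V"), 1L),
                  if (spec$pde_active) "L" else "F")
    ddfgtg_off <- 100L
    eal[ddfgtg_off + 1:6] <- if (spec$pde_active) {
      c("D", "D", "F", "G", "T", "G")
    } else {
      c("G", "T", "G", "F", "D", "D")  # scrambled: PDE-dead
    }
    eal <- paste(eal, collapse = "")
    blocks <- c(blocks, eal_linker = eal_linker, eal = eal)
  }

  starts <- cumsum(c(0L, nchar(blocks)))
  names(starts) <- c(names(blocks), "total")
  sequence <- paste(blocks, collapse = "")
  total <- nchar(sequence)

  anchor_idx <- starts[["linker"]] - 1L
  dxlt_idx <- starts[["ggdef"]]

  motif_offsets <- c(
    NTS_CYS = 16L,
    DIP = starts[["pas_gaf"]] + dip_off,
    PRXSF = starts[["phy"]] + prxsf_off,
    DXLT = dxlt_idx,
    GGDEF = starts[["ggdef"]] + ggdef_motif_off
  )
  mask_spans <- list(c(16L, 17L),
                     c(motif_offsets[["DIP"]], motif_offsets[["DIP"]] + 3L),
                     c(motif_offsets[["PRXSF"]], motif_offsets[["PRXSF"]] + 5L),
                     c(anchor_idx, anchor_idx + 1L),
                     c(dxlt_idx, dxlt_idx + 4L),
                     c(motif_offsets[["GGDEF"]], motif_offsets[["GGDEF"]] + 5L))
  if (spec$has_eal) {
    motif_offsets <- c(motif_offsets, EAL = starts[["eal"]])
    ddfgtg_site <- starts[["eal"]] + 100L
    if (spec$pde_active) {
      motif_offsets <- c(motif_offsets, DDFGTG = ddfgtg_site)
    }
    mask_spans <- c(mask_spans,
                    list(c(starts[["eal"]], starts[["eal"]] + 3L),
                         c(ddfgtg_site, ddfgtg_site + 6L)))
  }
  immutable <- logical(total)
  for (sp in mask_spans) {
    immutable[(sp[1] + 1L):sp[2]] <- TRUE
  }

  structure(list(
    family_id = spec$family_id,
    blocks = blocks,
    sequence = sequence,
    motif_offsets = motif_offsets,
    immutable = immutable,
    anchor_idx = anchor_idx,
    dxlt_idx = dxlt_idx,
    linker = linker,
    absolute_linker_length = n_linker,
    relative_linker_length = rel,
    has_eal = isTRUE(spec$has_eal),
    pde_active = isTRUE(spec$pde_active),
    inhibiting_phase = 0L,
    stimulating_phase = 2L,
    block_starts = starts
  ), class = "padc_template")
}

#' Build a family scaffold template
#'
#' Constructs one immutable-masked scaffold for a family: random residues in
#' all blocks, essential motifs planted at fixed offsets (C17-like cysteine,
#' DIP, PRXSF, DXLT opening the effector, GG(D/E)EF, and for PadC-EALs the
#' EAL/EAF and DDFGTG sites), the hydrophobic anchor as the last PHY residue,
#' and a heptad-repeat linker of exactly `28 + relative_linker_length`
#' residues carrying planted inhibiting (phase 0, hydrophobics) and
#' stimulating (phase 2, Asn) registers in frame with the DXLT end.
#'
#' @param spec One-row family specification, see [family_spec()].
#' @param rng_seed Integer seed; templates are deterministic given
#'   `(spec, rng_seed)`.
#' @return A `padc_template` list: `sequence`, per-block strings,
#'   `motif_offsets` (0-based), `immutable` mask, `anchor_idx`, `dxlt_idx`,
#'   planted linker and register phases.
#' @export
build_template <- function(spec, rng_seed) {
  withr::with_seed(as.integer(rng_seed), build_template_core(spec))
}

mutate_core <- function(template, rate) {
  stopifnot(rate >= 0, rate < 1)
  chars <- strsplit(template$sequence, "")[[1]]
  mutable <- which(!template$immutable)
  hit <- mutable[stats::runif(length(mutable)) < rate]
  if (length(hit) > 0L) {
    repl <- sample(AA20, length(hit), replace = TRUE)
    same <- repl == chars[hit]
    while (any(same)) {
      repl[same] <- sample(AA20, sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Mutate a template sequence at unmasked positions
#'
#' Each position with `immutable = FALSE` is substituted with probability
#' `rate` by a uniformly drawn *different* residue; masked (motif and anchor)
#' positions are never altered.
#'
#' @param template A `padc_template` from [build_template()].
#' @param rate Per-site substitution probability in `[0, 1)`.
#' @param rng_seed Integer seed; output is deterministic given the seed.
#' @return The mutated sequence as a single string.
#' @export
mutate_sequence <- function(template, rate, rng_seed) {
  withr::with_seed(as.integer(rng_seed), mutate_core(template, rate))
}

# A mutated member is acceptable when chance substitutions have not planted a
# motif that would shadow the truth: no premature D.LT between anchor and the
# planted DXLT, no premature GG(D/E)EF between DXLT and the planted one, and
# (for PadC-EALs) no premature qualifying E[AILV][LF] before the planted EAL.
sequence_truth_clean <- function(seq, template, min_eal_tail = 150L) {
  d <- locate_all0(seq, "D.LT")
  d <- d$start[d$start > template$anchor_idx]
  if (length(d) == 0L || d[1] != template$dxlt_idx) return(FALSE)
  g <- locate_all0(seq, "GG[DE]EF")
  g <- g$start[g$start > template$dxlt_idx + 3L]
  if (length(g) == 0L || g[1] != template$motif_offsets[["GGDEF"]]) {
    return(FALSE)
  }
  if (template$has_eal) {
    e <- locate_all0(seq, "E[AILV][LF]")
    keep <- e$start > template$motif_offsets[["GGDEF"]] + 4L &
      (nchar(seq) - e$end) >= min_eal_tail
    e <- e$start[keep]
    if (length(e) == 0L || e[1] != template$motif_offsets[["EAL"]]) {
      return(FALSE)
    }
  }
  TRUE
}

draw_member <- function(template, rate, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    s <- mutate_core(template, rate)
    if (sequence_truth_clean(s, template)) return(s)
  }
  stop("could not draw a truth-clean mutated sequence", call. = FALSE)
}

#' Generate a synthetic PadC dataset with ground truth
#'
#' Draws every family from its own independently randomised template (so
#' families are far closer within than between), emits the unaligned
#' sequences, the true column-consistent alignment and a ground-truth table,
#' and optionally appends a motif-free random outgroup sequence of PadC
#' length (an FphA-like stand-in for tree rooting).
#'
#' All blocks except the linker have equal lengths across families, so the
#' true alignment simply pads linkers with leading gap columns to the widest
#' linker and pads EAL-less sequences with trailing gap columns.
#'
#' @param specs Tibble of family specifications ([family_spec()] rows);
#'   family ids must be unique.
#' @param seed Integer seed; the dataset is bitwise reproducible given
#'   `(specs, seed)`.
#' @param include_outgroup Append the outgroup sequence (default `TRUE`).
#' @param outgroup_id Sequence id used for the outgroup.
#' @return A `padc_sim` list: `sequences` (tibble `sequence_id`, `family`,
#'   `taxonomy_class`, `sequence`), `alignment` (tibble `sequence_id`,
#'   `aligned`), `truth` (one row per sequence: class, linker truth, planted
#'   register phases), `anchor_ref` (`list(sequence_id, position)`, 1-based
#'   reference anchor for [locate_phy_anchor()]), `specs`, `seed`.
#' @export
simulate_padc_families <- function(specs = default_family_specs(), seed,
                                   include_outgroup = TRUE,
                                   outgroup_id = "outgroup_FphA_like") {
  if (anyDuplicated(specs$family_id)) {
    stop("family ids must be unique", call. = FALSE)
  }
  seed <- as.integer(seed)

  res <- withr::with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(specs)), function(f) {
      spec <- specs[f, ]
      template <- build_template_core(spec)
      members <- purrr::map_chr(seq_len(spec$n_members), function(m) {
        draw_member(template, spec$within_divergence)
      })
      list(
        template = template,
        tbl = tibble::tibble(
          sequence_id = sprintf("%s_%02d", spec$family_id,
                                seq_len(spec$n_members)),
          family = spec$family_id,
          taxonomy_class = spec$taxonomy_class,
          sequence = members
        )
      )
    })
    out <- NULL
    if (include_outgroup) {
      len <- sum(BLOCK_LENGTHS[c("nts", "pas_gaf", "phy", "ggdef")]) +
        REFERENCE_LINKER_LENGTH
      repeat {
        og <- random_aa_string(len)
        if (classify_family(og)$class_call == "non-member") break
      }
      out <- og
    }
    list(rows = rows, outgroup = out)
  })

  templates <- purrr::map(res$rows, "template")
  sequences <- dplyr::bind_rows(purrr::map(res$rows, "tbl"))
  if (anyDuplicated(sequences$sequence_id)) {
    stop("duplicate sequence ids", call. = FALSE)
  }

  truth <- dplyr::bind_rows(purrr::map2(
    templates, purrr::map(res$rows, "tbl"),
    function(tpl, tbl) {
      tibble::tibble(
        sequence_id = tbl$sequence_id,
        family = tpl$family_id,
        class = if (tpl$has_eal) "PadC-EAL" else "PadC",
        rel_linker_len = tpl$relative_linker_length,
        abs_linker_len = tpl$absolute_linker_length,
        anchor_idx = tpl$anchor_idx,
        dxlt_idx = tpl$dxlt_idx,
        inhibiting_phase = tpl$inhibiting_phase,
        stimulating_phase = tpl$stimulating_phase,
        has_eal = tpl$has_eal,
        pde_active = if (tpl$has_eal) tpl$pde_active else NA,
        taxonomy_class = tbl$taxonomy_class[1]
      )
    }
  ))

  # true alignment: pad linkers with leading gaps to the widest linker,
  # pad EAL-less sequences with trailing gaps over the EAL-linker+EAL columns
  pre_len <- sum(BLOCK_LENGTHS[c("nts", "pas_gaf", "phy")])
  linker_widths <- purrr::map_int(templates, "absolute_linker_length")
  max_linker <- max(c(linker_widths,
                      if (include_outgroup) REFERENCE_LINKER_LENGTH))
  any_eal <- any(purrr::map_lgl(templates, "has_eal"))
  eal_cols <- if (any_eal) {
    sum(BLOCK_LENGTHS[c("eal_linker", "eal")])
  } else {
    0L
  }

  align_one <- function(seq, abs_linker, has_eal) {
    pre <- substr(seq, 1L, pre_len)
    linker <- substr(seq, pre_len + 1L, pre_len + abs_linker)
    rest <- substr(seq, pre_len + abs_linker + 1L, nchar(seq))
    paste0(pre,
           strrep("-", max_linker - abs_linker), linker,
           rest,
           if (!has_eal) strrep("-", eal_cols) else "")
  }

  aligned <- purrr::map2_chr(
    sequences$sequence,
    match(sequences$family, specs$family_id),
    function(s, f) {
      align_one(s, templates[[f]]$absolute_linker_length,
                templates[[f]]$has_eal)
    }
  )
  alignment <- tibble::tibble(sequence_id = sequences$sequence_id,
                              aligned = aligned)

  if (include_outgroup) {
    sequences <- dplyr::bind_rows(
      sequences,
      tibble::tibble(sequence_id = outgroup_id, family = "outgroup",
                     taxonomy_class = "Eurotiomycetes",
                     sequence = res$outgroup)
    )
    alignment <- dplyr::bind_rows(
      alignment,
      tibble::tibble(
        sequence_id = outgroup_id,
        aligned = align_one(res$outgroup, REFERENCE_LINKER_LENGTH, FALSE)
      )
    )
    truth <- dplyr::bind_rows(
      truth,
      tibble::tibble(sequence_id = outgroup_id, family = "outgroup",
                     class = "non-member", rel_linker_len = NA_integer_,
                     abs_linker_len = NA_integer_, anchor_idx = NA_integer_,
                     dxlt_idx = NA_integer_, inhibiting_phase = NA_integer_,
                     stimulating_phase = NA_integer_, has_eal = FALSE,
                     pde_active = NA, taxonomy_class = "Eurotiomycetes")
    )
  }

  structure(list(
    sequences = sequences,
    alignment = alignment,
    truth = truth,
    anchor_ref = list(sequence_id = sequences$sequence_id[1],
                      position = templates[[1]]$anchor_idx + 1L),
    specs = specs,
    seed = seed
  ), class = "padc_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits unaligned FASTA, the true alignment as aligned FASTA, and the
#' ground-truth table as TSV (spec columns first:
#' `sequence_id family class rel_linker_len abs_linker_len anchor_idx
#' dxlt_idx`, followed by the planted register phases and flags).
#'
#' @param sim A `padc_sim` from [simulate_padc_families()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_tbl(sim$sequences, file.path(dir, "sequences.fasta"))
  write_fasta_tbl(sim$alignment, file.path(dir, "alignment.fasta"),
                  column = "aligned")
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
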