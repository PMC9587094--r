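# Linker-length statistic: residues strictly between the conserved
# hydrophobic anchor of the terminal PHY helix and the D of the DXLT motif
# (both endpoints excluded), reported absolutely and relative to the
# 28-residue TsPadC-like reference.

#' Map the reference PHY-helix anchor onto every alignment row
#'
#' Finds the alignment column holding the reference sequence's anchor residue
#' (1-based residue number in the *unaligned* reference, I495-style) and
#' returns, per query row, the 0-based unaligned index of the residue
#' occupying that column.  Queries gapped at the anchor column are reported
#' with status `"anchor not alignable"` rather than dropped.
#'
#' @param alignment Tibble with columns `sequence_id` and `aligned`
#'   (equal-length gapped rows, gap character `-`).
#' @param reference_id Sequence id of the reference row.
#' @param reference_position 1-based residue number of the anchor in the
#'   unaligned reference sequence.
#' @return Tibble `sequence_id`, `anchor_idx` (0-based, `NA` on failure),
#'   `status` (`"ok"` or `"anchor not alignable"`).
#' @export
locate_phy_anchor <- function(alignment, reference_id, reference_position) {
  stopifnot(all(c("sequence_id", "aligned") %in% names(alignment)))
  ref <- alignment$aligned[alignment$sequence_id == reference_id]
  if (length(ref) != 1L) {
    stop("reference sequence '", reference_id, "' not found in alignment",
         call. = FALSE)
  }
  widths <- nchar(alignment$aligned)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  ref_chars <- strsplit(ref, "")[[1]]
  non_gap <- which(ref_chars != "-")
  if (reference_position < 1L || reference_position > length(non_gap)) {
    stop("reference anchor position ", reference_position,
         " outside the reference sequence", call. = FALSE)
  }
  col <- non_gap[reference_position]

  rows <- strsplit(alignment$aligned, "")
  res <- purrr::map(rows, function(ch) {
    if (ch[col] == "-") {
      list(anchor_idx = NA_integer_, status = "anchor not alignable")
    } else {
      list(anchor_idx = sum(ch[seq_len(col)] != "-") - 1L, status = "ok")
    }
  })
  tibble::tibble(
    sequence_id = alignment$sequence_id,
    anchor_idx = purrr::map_int(res, "anchor_idx"),
    status = purrr::map_chr(res, "status")
  )
}

#' Bin relative linker lengths into the paper-style families
#'
#' Lengths divisible by seven (complete heptads) form `div7`; the recurrent
#' non-conforming lengths -4 and +2 form their own families; everything else
#' is `other`.  The modulo is mathematical, so negative multiples of seven
#' (e.g. -7) land in `div7`.
#'
#' @param relative_length Integer vector of relative linker lengths.
#' @return Character vector over `{"div7", "minus4", "plus2", "other"}`.
#' @export
bin_linker_family <- function(relative_length) {
  dplyr::case_when(
    is.na(relative_length) ~ NA_character_,
    relative_length %% 7L == 0L ~ "div7",
    relative_length == -4L ~ "minus4",
    relative_length == 2L ~ "plus2",
    TRUE ~ "other"
  )
}

#' Compute the linker annotation for one sequence
#'
#' The linker length is the number of residues strictly between the anchor
#' residue and the D of the first DXLT motif downstream of the anchor (both
#' endpoints excluded): `absolute = dxlt_idx - anchor_idx - 1`.
#'
#' @param seq Protein sequence (single string).
#' @param anchor_idx 0-based index of the PHY-helix anchor residue, from
#'   [locate_phy_anchor()].
#' @param motifs Motif set providing the DXLT pattern.
#' @param reference_length Absolute linker length of the reference (28).
#' @return One-row tibble: `anchor_idx`, `dxlt_idx` (0-based index of the D),
#'   `abs_linker_len`, `rel_linker_len`, `linker_family`.
#' @export
compute_linker <- function(seq, anchor_idx, motifs = default_motif_set(),
                           reference_length = 28L) {
  assert_scalar_string(seq)
  stopifnot(is.numeric(anchor_idx), !is.na(anchor_idx))
  anchor_idx <- as.integer(anchor_idx)
  hit <- first_match_after(seq, motifs$patterns[["DXLT"]], from0 = anchor_idx)
  if (is.null(hit)) {
    stop("effector start not found: no DXLT downstream of anchor index ",
         anchor_idx, call. = FALSE)
  }
  abs_len <- hit$start - anchor_idx - 1L
  rel_len <- abs_len - as.integer(reference_length)
  tibble::tibble(
    anchor_idx = anchor_idx,
    dxlt_idx = hit$start,
    abs_linker_len = abs_len,
    rel_linker_len = rel_len,
    linker_family = bin_linker_family(rel_len)
  )
}

#' Annotate linker lengths for a table of sequences
#'
#' Vectorised [compute_linker()]; per-sequence failures (missing anchor,
#' missing DXLT) are carried as status rows rather than raised, so pipeline
#' denominators stay explicit.
#'
#' @param df Tibble with columns `sequence_id`, `sequence` and `anchor_idx`
#'   (join the output of [locate_phy_anchor()] first).
#' @inheritParams compute_linker
#' @return Tibble with one row per input row: linker columns plus `status`.
#' @export
annotate_linkers <- function(df, motifs = default_motif_set(),
                             reference_length = 28L) {
  stopifnot(all(c("sequence_id", "sequence", "anchor_idx") %in% names(df)))
  empty <- tibble::tibble(
    anchor_idx = NA_integer_, dxlt_idx = NA_integer_,
    abs_linker_len = NA_integer_, rel_linker_len = NA_integer_,
    linker_family = NA_character_
  )
  rows <- purrr::map2(df$sequence, df$anchor_idx, function(s, a) {
    if (is.na(a)) {
      return(dplyr::mutate(empty, status = "anchor not alignable"))
    }
    out <- tryCatch(
      dplyr::mutate(
        compute_linker(s, a, motifs = motifs,
                       reference_length = reference_length),
        status = "ok"
      ),
      error = function(e) {
        dplyr::mutate(empty, anchor_idx = as.integer(a),
                      status = conditionMessage(e))
      }
    )
    out
  })
  dplyr::bind_cols(tibble::tibble(sequence_id = df$sequence_id),
                   dplyr::bind_rows(rows))
}

#' Length of the linker between the GGDEF and EAL domains
#'
#' Residues strictly between the end of the GG(D/E)EF motif and the start of
#' the EAL/EAF motif (same exclusive-endpoints convention as the sensor
#' linker).  Only defined for PadC-EALs.
#'
#' @param seq Protein sequence.
#' @param call One-row classification from [classify_family()].
#' @return Integer length.
#' @export
eal_linker_length <- function(seq, call) {
  assert_scalar_string(seq)
  if (!identical(call$class_call, "PadC-EAL")) {
    stop("EAL-linker length is only defined for PadC-EALs", call. = FALSE)
  }
  hits <- call$hits[[1]]
  ggdef_end <- hits$end[hits$motif_name == "GGDEF"]
  eal_start <- hits$start[hits$motif_name == "EAL"]
  if (length(ggdef_end) != 1L || length(eal_start) != 1L) {
    stop("missing GGDEF or EAL hit in classification", call. = FALSE)
  }
  as.integer(eal_start - ggdef_end)
}
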