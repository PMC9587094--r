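# Heptad-repeat register calling over the sensor-effector linker.
#
# Phase convention: the heptad frame is anchored at the DXLT end of the
# linker (the structurally conserved wide turn), not at its N-terminus.  For
# a linker of length n and 0-based index i, define j(i) = (i - n) mod 7;
# under phase p the 'a' positions sit at j == p and the 'd' positions at
# j == (p + 3) mod 7.  For linkers whose length is a multiple of seven this
# coincides with counting phases from the N-terminus (j == i mod 7).
# Prepending whole heptads never changes a call.

#' Coiled-coil stabilising residues
#'
#' Hydrophobics plus asparagine, the residues counted as stabilising when
#' they occupy core (a/d) positions of a heptad register.  Alanine's
#' inclusion among the hydrophobics is a judgement call, so the set is an
#' argument everywhere it is used.
#'
#' @return Character vector of one-letter residue codes.
#' @export
default_stabilisers <- function() {
  c("A", "V", "L", "I", "M", "F", "W", "Y", "N")
}

# 0-based a/d slot indices of a phase; optionally with the overwinding
# correction: positions before `breakpoint` are scored in the ancestral
# frame (as if the 4 deleted residues were still present downstream of
# them), i.e. with j shifted by -4 mod 7.
register_slot_idx <- function(n, phase, breakpoint = 0L) {
  i <- seq_len(n) - 1L
  j <- (i - n) %% 7L
  j[i < breakpoint] <- (j[i < breakpoint] - 4L) %% 7L
  p <- phase %% 7L
  which(j == p | j == (p + 3L) %% 7L) - 1L
}

#' Score one heptad register phase over a linker
#'
#' The score is the fraction of a- and d-positions of the given phase that
#' are occupied by stabilising residues, in `[0, 1]`.
#'
#' @param linker_seq Linker sequence (length >= 7).
#' @param phase Integer phase 0-6, counted in frame with the DXLT end.
#' @param stabilisers Stabilising residue set, see [default_stabilisers()].
#' @return Numeric score in `[0, 1]`.
#' @examples
#' score_register(strrep("LAALAAA", 4), 0)
#' @export
score_register <- function(linker_seq, phase,
                           stabilisers = default_stabilisers()) {
  assert_scalar_string(linker_seq, "linker_seq")
  n <- nchar(linker_seq)
  if (n < 7L) stop("linker shorter than 7 residues", call. = FALSE)
  stopifnot(phase %in% 0:6)
  chars <- strsplit(linker_seq, "")[[1]]
  slots <- register_slot_idx(n, phase) + 1L
  mean(chars[slots] %in% stabilisers)
}

score_all_phases <- function(chars, n, stabilisers, breakpoint = 0L) {
  vapply(0:6, function(p) {
    slots <- register_slot_idx(n, p, breakpoint) + 1L
    mean(chars[slots] %in% stabilisers)
  }, numeric(1))
}

#' Overwinding adjustment for -4 linkers
#'
#' A -4 linker is modelled as a complete heptad coil that lost one near-turn
#' of four residues, compensated by local overwinding (a 10-residue stretch
#' spanning 3 helical turns).  Operationally this is a single local phase
#' retardation: for a candidate breakpoint `b`, positions N-terminal of `b`
#' are scored in the ancestral frame (j shifted by -4 mod 7) while positions
#' from `b` onwards stay in frame with the DXLT end.  The breakpoint
#' maximising the combined a/d stabiliser fraction is returned; ties resolve
#' to the smallest breakpoint, then the smallest phase.
#'
#' @inheritParams score_register
#' @return List with `breakpoint` (0-based linker index) and `scores`
#'   (per-phase best adjusted scores, length 7).
#' @export
overwind_adjust <- function(linker_seq, stabilisers = default_stabilisers()) {
  assert_scalar_string(linker_seq, "linker_seq")
  n <- nchar(linker_seq)
  if (n < 10L) stop("linker shorter than 10 residues", call. = FALSE)
  chars <- strsplit(linker_seq, "")[[1]]
  by_b <- vapply(0:n, function(b) {
    score_all_phases(chars, n, stabilisers, breakpoint = b)
  }, numeric(7))  # 7 x (n+1)
  best_per_phase <- apply(by_b, 1L, max)
  overall <- max(best_per_phase)
  hit <- which(by_b == overall, arr.ind = TRUE)  # row = phase+1, col = b+1
  b_best <- min(hit[, "col"]) - 1L
  list(breakpoint = b_best, scores = best_per_phase)
}

#' Predict the regulatory class of a linker-length family
#'
#' Complete heptads (length differences divisible by seven) support register
#' switching and pronounced light-activated upregulation; -4 linkers switch
#' through an overwound coil with smaller dynamic ranges; +2 linkers break
#' the heptad pattern and impair coiled-coil stabilisation; all other
#' lengths are unclassified.
#'
#' @param relative_length Integer vector of relative linker lengths.
#' @return Character vector over `{"switch_capable", "overwound_switch",
#'   "impaired_cc", "unknown"}`.
#' @export
predict_regulatory_class <- function(relative_length) {
  dplyr::case_when(
    is.na(relative_length) ~ NA_character_,
    relative_length %% 7L == 0L ~ "switch_capable",
    relative_length == -4L ~ "overwound_switch",
    relative_length == 2L ~ "impaired_cc",
    TRUE ~ "unknown"
  )
}

#' Call the inhibiting and stimulating registers of a linker
#'
#' Scores all seven phases (DXLT-anchored frame), applies the overwinding
#' model first when `relative_length == -4`, and labels the top-scoring
#' phase "inhibiting" and the runner-up "stimulating".  The labels follow
#' the dark-state convention (the inhibited register is the one observed in
#' dark-state structures); they are naming conventions, not structure
#' predictions.  Ties resolve to the lowest phase index.  The stimulating
#' phase is only called when a second phase has a nonzero score.
#'
#' @inheritParams score_register
#' @param relative_length Relative linker length of the sequence; `-4`
#'   engages the overwinding path.
#' @return One-row tibble: `phase_scores` (list column, numeric length 7),
#'   `inhibiting_phase`, `stimulating_phase`, `overwind_breakpoint` (`NA`
#'   unless the -4 path ran) and `regulatory_class`.
#' @export
call_registers <- function(linker_seq, relative_length,
                           stabilisers = default_stabilisers()) {
  assert_scalar_string(linker_seq, "linker_seq")
  n <- nchar(linker_seq)
  if (n < 7L) stop("linker shorter than 7 residues", call. = FALSE)
  relative_length <- as.integer(relative_length)

  breakpoint <- NA_integer_
  if (!is.na(relative_length) && relative_length == -4L) {
    ow <- overwind_adjust(linker_seq, stabilisers)
    scores <- ow$scores
    breakpoint <- ow$breakpoint
  } else {
    chars <- strsplit(linker_seq, "")[[1]]
    scores <- score_all_phases(chars, n, stabilisers)
  }

  ord <- order(-scores, 0:6)
  inhibiting <- ord[1] - 1L
  stimulating <- if (scores[ord[2]] > 0) ord[2] - 1L else NA_integer_

  tibble::tibble(
    phase_scores = list(scores),
    inhibiting_phase = inhibiting,
    stimulating_phase = stimulating,
    overwind_breakpoint = breakpoint,
    regulatory_class = predict_regulatory_class(relative_length)
  )
}

#' Annotate registers for a table of linker-annotated sequences
#'
#' Extracts each linker (residues strictly between `anchor_idx` and
#' `dxlt_idx`) and runs [call_registers()]; failures (short linkers, missing
#' annotations) are carried as status rows.
#'
#' @param df Tibble with columns `sequence_id`, `sequence`, `anchor_idx`,
#'   `dxlt_idx`, `rel_linker_len` (see [annotate_linkers()]).
#' @inheritParams call_registers
#' @return Tibble with one row per input row: register columns plus `status`.
#' @export
annotate_registers <- function(df, stabilisers = default_stabilisers()) {
  need <- c("sequence_id", "sequence", "anchor_idx", "dxlt_idx",
            "rel_linker_len")
  stopifnot(all(need %in% names(df)))
  empty <- tibble::tibble(
    phase_scores = list(rep(NA_real_, 7)),
    inhibiting_phase = NA_integer_, stimulating_phase = NA_integer_,
    overwind_breakpoint = NA_integer_, regulatory_class = NA_character_
  )
  rows <- purrr::pmap(
    list(df$sequence, df$anchor_idx, df$dxlt_idx, df$rel_linker_len),
    function(s, a, d, rel) {
      if (is.na(a) || is.na(d)) {
        return(dplyr::mutate(empty, status = "no linker annotation"))
      }
      linker <- substr0(s, a + 1L, d)
      tryCatch(
        dplyr::mutate(call_registers(linker, rel, stabilisers), status = "ok"),
        error = function(e) {
          dplyr::mutate(empty, status = conditionMessage(e))
        }
      )
    }
  )
  dplyr::bind_cols(tibble::tibble(sequence_id = df$sequence_id),
                   dplyr::bind_rows(rows))
}
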