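#' Essential PadC motif patterns
#'
#' The motif set that defines membership of the PadC / PadC-EAL family: the
#' chromophore-binding cysteine in the N-terminal segment (C17 in IsPadC), the
#' DIP motif of the GAF cofactor pocket, the PRXSF motif of the PHY tongue,
#' the DXLT wide-turn motif opening the effector, the cyclase-defining
#' GG(D/E)EF motif, the phosphodiesterase EAL (or EXL, X aliphatic) motif with
#' its degenerate EAF variant, and the DDFGTG motif required for PDE activity.
#'
#' Patterns are POSIX regular expressions over the amino-acid alphabet.
#' Wildcard positions (`.`) may match `X`; specific-residue positions cannot.
#'
#' @param nts_window Length of the N-terminal window searched for the
#'   chromophore-binding cysteine (residues).  30 by default, comfortably
#'   covering C17-like positions; how far the cysteine may drift in remote
#'   homologs is not known, so this is exposed rather than hard-coded.
#' @return A list with elements `patterns` (named character vector of regexes)
#'   and `nts_window`.
#' @export
default_motif_set <- function(nts_window = 30L) {
  stopifnot(nts_window >= 1L)
  list(
    patterns = c(
      NTS_CYS = "C",
      DIP = "DIP",
      PRXSF = "PR.SF",
      DXLT = "D.LT",
      GGDEF = "GG[DE]EF",
      EAL = "E[AILV]L",
      EAF_DEGENERATE = "E[AILV]F",
      DDFGTG = "DDFGTG"
    ),
    nts_window = as.integer(nts_window)
  )
}

# all leftmost non-overlapping matches of one regex; 0-based half-open spans
locate_all0 <- function(seq, pattern) {
  m <- stringr::str_locate_all(seq, pattern)[[1]]
  tibble::tibble(
    start = as.integer(m[, 1]) - 1L,
    end = as.integer(m[, 2]),
    matched_text = stringr::str_sub(seq, m[, 1], m[, 2])
  )
}

#' Scan a sequence for the essential PadC motifs
#'
#' Reports all leftmost non-overlapping matches of every motif in `motifs`,
#' ordered by start position.  The NTS cysteine is only searched within the
#' N-terminal window.
#'
#' @param seq Protein sequence (single string, 20-letter alphabet plus X).
#' @param motifs Motif set, see [default_motif_set()].
#' @return Tibble with columns `motif_name`, `start`, `end` (0-based,
#'   half-open) and `matched_text`.
#' @examples
#' scan_motifs("MGCDIPPRFSF")
#' @export
scan_motifs <- function(seq, motifs = default_motif_set()) {
  assert_scalar_string(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  hits <- purrr::imap(as.list(motifs$patterns), function(pat, nm) {
    target <- if (nm == "NTS_CYS") {
      substr(seq, 1L, min(nchar(seq), motifs$nts_window))
    } else {
      seq
    }
    locate_all0(target, pat)
  })
  out <- dplyr::bind_rows(hits, .id = "motif_name")
  dplyr::arrange(out, .data$start, .data$motif_name)
}

# first match of `pattern` with 0-based start > from0 (or >= if inclusive);
# returns one-row tibble or NULL
first_match_after <- function(seq, pattern, from0 = -1L, min_tail = 0L) {
  m <- locate_all0(seq, pattern)
  m <- m[m$start > from0 & (nchar(seq) - m$end) >= min_tail, , drop = FALSE]
  if (nrow(m) == 0L) NULL else m[1L, , drop = FALSE]
}

#' Classify one sequence as PadC, PadC-EAL or non-member
#'
#' A sequence is a PadC when the chromophore-binding cysteine (within the
#' N-terminal window), DIP, PRXSF, DXLT and GG(D/E)EF motifs are all present
#' in that order, and no EAL-domain evidence follows the GGDEF motif.  It is
#' a PadC-EAL when additionally an EAL (or degenerate EAF) motif lies
#' downstream of the GGDEF motif with at least `min_eal_tail` residues behind
#' it -- an EAL motif without a domain's worth of sequence after it is treated
#' as a chance match, not as a phosphodiesterase.  Motifs are located by a
#' chained leftmost search (each motif is the first match downstream of the
#' previous one), which makes the verdict robust to spurious later copies.
#'
#' PDE competence (`pde_active`) is `FALSE` when the EAL position matches the
#' degenerate EAF variant or when the DDFGTG motif is absent downstream of
#' GGDEF, mirroring homologs whose EAL domain is catalytically dead.
#'
#' @inheritParams scan_motifs
#' @param min_eal_tail Minimum number of residues required downstream of an
#'   EAL/EAF match for it to count as EAL-domain evidence (default 150).
#' @return One-row tibble: `class_call` (`"PadC"`, `"PadC-EAL"`,
#'   `"non-member"`), `pde_active` (logical, `NA` unless PadC-EAL),
#'   `missing_motifs` (list column of labels) and `hits` (list column, the
#'   chained motif hits actually used).
#' @export
classify_family <- function(seq, motifs = default_motif_set(),
                            min_eal_tail = 150L) {
  assert_scalar_string(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)

  used <- list()
  missing <- character()
  pos <- -1L

  chain <- c(NTS_CYS = "NTS_CYS", DIP = "DIP", PRXSF = "PRXSF",
             DXLT = "DXLT", GGDEF = "GGDEF")
  for (nm in chain) {
    hit <- if (nm == "NTS_CYS") {
      h <- first_match_after(
        substr(seq, 1L, min(nchar(seq), motifs$nts_window)),
        motifs$patterns[["NTS_CYS"]]
      )
      h
    } else {
      first_match_after(seq, motifs$patterns[[nm]], from0 = pos)
    }
    if (is.null(hit)) {
      missing <- c(missing, nm)
    } else {
      used[[nm]] <- dplyr::mutate(hit, motif_name = nm, .before = 1L)
      pos <- hit$end - 1L  # next motif must start strictly after this one
    }
  }

  core_ok <- length(missing) == 0L
  eal_hit <- NULL
  pde <- NA
  if (core_ok) {
    ggdef_end <- used[["GGDEF"]]$end
    eal_pat <- paste0("(", motifs$patterns[["EAL"]], ")|(",
                      motifs$patterns[["EAF_DEGENERATE"]], ")")
    eal_hit <- first_match_after(seq, eal_pat, from0 = ggdef_end - 1L,
                                 min_tail = min_eal_tail)
    if (!is.null(eal_hit)) {
      used[["EAL"]] <- dplyr::mutate(eal_hit, motif_name = "EAL", .before = 1L)
      is_eal <- grepl(paste0("^", motifs$patterns[["EAL"]], "$"),
                      eal_hit$matched_text)
      ddfgtg <- first_match_after(seq, motifs$patterns[["DDFGTG"]],
                                  from0 = ggdef_end - 1L)
      if (!is.null(ddfgtg)) {
        used[["DDFGTG"]] <- dplyr::mutate(ddfgtg, motif_name = "DDFGTG",
                                          .before = 1L)
      }
      pde <- is_eal && !is.null(ddfgtg)
    }
  }

  class_call <- if (!core_ok) {
    "non-member"
  } else if (is.null(eal_hit)) {
    "PadC"
  } else {
    "PadC-EAL"
  }
  if (class_call != "PadC-EAL") pde <- NA

  tibble::tibble(
    class_call = class_call,
    pde_active = pde,
    missing_motifs = list(missing),
    hits = list(dplyr::bind_rows(used))
  )
}

#' Classify a table of sequences
#'
#' Vectorised [classify_family()] over a tibble of sequences.
#'
#' @param df Tibble with columns `sequence_id` and `sequence`.
#' @inheritParams classify_family
#' @return `df`'s `sequence_id` column joined with the per-sequence
#'   classification columns of [classify_family()].
#' @export
classify_sequences <- function(df, motifs = default_motif_set(),
                               min_eal_tail = 150L) {
  stopifnot(all(c("sequence_id", "sequence") %in% names(df)))
  res <- purrr::map(df$sequence, classify_family, motifs = motifs,
                    min_eal_tail = min_eal_tail)
  dplyr::bind_cols(
    tibble::tibble(sequence_id = df$sequence_id),
    dplyr::bind_rows(res)
  )
}
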