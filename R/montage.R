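# 10-20 scalp montage and the electrode pairs used for coherence.

#' Standard 19-channel 10-20 montage labels
#'
#' Channel order used throughout: Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz,
#' C4, T4, T5, P3, Pz, P4, T6, O1, O2.
#'
#' @return Character vector of 19 channel labels.
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Electrode pairs of interest for coherence analysis
#'
#' Three named sets: `left_intra` (F3-T3, T3-P3, F3-P3), `right_intra`
#' (F4-T4, T4-P4, F4-P4) and `inter` (F3-F4, T3-T4, P3-P4), covering
#' fronto-temporal, temporo-parietal and fronto-parietal coupling within
#' each hemisphere plus homologous interhemispheric pairs.
#'
#' @param which Optional set name (`"left_intra"`, `"right_intra"`,
#'   `"inter"`); default returns all three.
#' @return A tibble with columns `set`, `ch1`, `ch2`.
#' @export
#' @examples
#' pair_sets("inter")
pair_sets <- function(which = c("all", "left_intra", "right_intra", "inter")) {
  which <- match.arg(which)
  tbl <- tibble::tribble(
    ~set,          ~ch1,  ~ch2,
    "left_intra",  "F3",  "T3",
    "left_intra",  "T3",  "P3",
    "left_intra",  "F3",  "P3",
    "right_intra", "F4",  "T4",
    "right_intra", "T4",  "P4",
    "right_intra", "F4",  "P4",
    "inter",       "F3",  "F4",
    "inter",       "T3",  "T4",
    "inter",       "P3",  "P4"
  )
  if (which != "all") tbl <- tbl[tbl$set == which, ]
  tbl
}

# Normalize a channel label to canonical 10-20 capitalization where the
# label is recognizable (case-insensitive, ignoring a "EEG " prefix).
normalize_label <- function(x) {
  canon <- montage_10_20()
  stripped <- sub("^eeg[ _]*", "", trimws(tolower(x)))
  hit <- match(stripped, tolower(canon))
  out <- ifelse(is.na(hit), trimws(x), canon[hit])
  out
}

is_eog_label <- function(x) grepl("eog", tolower(x))
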