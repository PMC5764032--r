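#' Norm metadata for the language/literacy battery
#'
#' Names and norm scales for the 13 language/literacy measures plus
#' performance IQ. Three conventional scale families are used: IQ-type
#' standard scores (mean 100, SD 15), subtest scaled scores (10, 3) and
#' t-scores (50, 10).
#'
#' @return Data frame with columns `measure`, `norm_mean`, `norm_sd`,
#'   `language` (TRUE for the 13 classifier measures, FALSE for performance
#'   IQ).
#' @export
battery_norms <- function() {
  m <- c(vocabulary = "t", verbal_comprehension = "iq",
         sentence_repetition = "scaled", nonword_repetition = "scaled",
         oromotor_sequences = "scaled", picture_naming = "iq",
         digit_naming = "iq", sight_word_efficiency = "iq",
         phonetic_decoding = "iq", reading_accuracy = "iq",
         reading_comprehension = "iq", reading_rate = "iq",
         communication_composite = "iq", performance_iq = "iq")
  scales <- list(iq = c(100, 15), scaled = c(10, 3), t = c(50, 10))
  data.frame(measure = names(m),
             norm_mean = vapply(m, function(s) scales[[s]][1], numeric(1)),
             norm_sd = vapply(m, function(s) scales[[s]][2], numeric(1)),
             language = names(m) != "performance_iq",
             row.names = NULL)
}

#' Classify DLD versus TD from normed scores
#'
#' A measure is flagged when the score falls more than 1 SD below its
#' population norm (strictly below mean − SD; a score exactly at the
#' boundary is not flagged). A child is classified DLD with flags on two or
#' more of the 13 language/literacy measures, and TD with at most one flag.
#'
#' @param scores named numeric vector (or 1-row data frame) holding the 13
#'   language measures.
#' @param norms norm table as returned by [battery_norms()]; only rows with
#'   `language = TRUE` are used.
#' @return List with `n_flags`, `group` (`"DLD"` or `"TD"`) and `flags`
#'   (named logical).
#' @export
classify_dld <- function(scores, norms = battery_norms()) {
  if (is.data.frame(scores)) scores <- unlist(scores[1, , drop = TRUE])
  norms <- norms[norms$language, ]
  missing <- setdiff(norms$measure, names(scores))
  if (length(missing))
    stop("missing measure(s): ", paste(missing, collapse = ", "))
  v <- scores[norms$measure]
  flags <- as.logical(v < norms$norm_mean - norms$norm_sd)
  names(flags) <- norms$measure
  n <- sum(flags)
  list(n_flags = n, group = if (n >= 2) "DLD" else "TD", flags = flags)
}

#' Participant-level exclusion screen
#'
#' Children are excluded for performance IQ more than two SDs below the
#' population mean (IQ < 70; exactly 70 is included), an autism spectrum
#' diagnosis in either twin of the pair, sensorineural hearing loss or a
#' failed hearing test, or a serious medical condition/brain injury.
#'
#' @param performance_iq numeric IQ.
#' @param asd_flag ASD diagnosis in this child *or the co-twin* (exclusion
#'   of one twin for ASD excludes the pair).
#' @param hearing_fail,medical_flag logical flags.
#' @return List with `include` (logical) and `reason` (`NA` if included).
#' @export
exclusion_screen <- function(performance_iq, asd_flag = FALSE,
                             hearing_fail = FALSE, medical_flag = FALSE) {
  if (isTRUE(asd_flag)) return(list(include = FALSE, reason = "ASD in pair"))
  if (isTRUE(hearing_fail)) return(list(include = FALSE, reason = "hearing"))
  if (isTRUE(medical_flag)) return(list(include = FALSE, reason = "medical"))
  if (performance_iq < 70) return(list(include = FALSE, reason = "low IQ"))
  list(include = TRUE, reason = NA_character_)
}
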