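#' Score the adapted Edinburgh Handedness Inventory
#'
#' Ten demonstrated actions are each recorded as `"right"`, `"left"` or
#' `"both"`. One point is awarded for exclusive right-hand use, zero for
#' left-hand use and half a point for both hands, giving a 0-10 score. The
#' score maps linearly onto a laterality index from -100 (extreme left
#' handedness) to +100 (extreme right handedness); a child is categorised
#' right-handed only with an index strictly above 0.
#'
#' @param items character vector of exactly 10 values in
#'   `c("right", "left", "both")`.
#' @return List with `score` (0-10 in half-point steps), `li` (-100..100)
#'   and `right` (logical).
#' @export
score_ehi <- function(items) {
  if (length(items) != 10L)
    stop("EHI requires exactly 10 items, got ", length(items))
  if (!all(items %in% c("right", "left", "both")))
    stop("EHI items must be 'right', 'left' or 'both'")
  score <- sum(c(right = 1, both = 0.5, left = 0)[items])
  li <- (2 * score - 10) * 10
  list(score = score, li = li, right = li > 0)
}

#' Score the Quantification of Hand Preference task
#'
#' The child reaches for three cards at each of seven positions spanning the
#' midline at 30-degree intervals (position 1 far left, 4 midline, 7 far
#' right). One point per right-handed reach gives a 0-21 score; a child is
#' right-handed by this measure only with a score strictly over 10. The
#' position profile (right-reach proportion at each position) captures
#' reluctance to reach across the midline with the preferred hand.
#'
#' @param reaches data frame with columns `position` (integer 1-7, exactly 3
#'   rows each) and `hand` (`"right"` or `"left"`).
#' @return List with `score` (0-21), `right` (logical) and
#'   `position_profile` (7 proportions).
#' @export
score_qhp <- function(reaches) {
  if (!is.data.frame(reaches) || !all(c("position", "hand") %in% names(reaches)))
    stop("reach log must have columns position and hand")
  if (nrow(reaches) != 21L || !all(tabulate(reaches$position, 7) == 3L))
    stop("reach log must contain exactly 3 reaches at each of positions 1-7")
  if (!all(reaches$hand %in% c("right", "left")))
    stop("hand must be 'right' or 'left'")
  r <- reaches$hand == "right"
  profile <- vapply(1:7, function(p) mean(r[reaches$position == p]), numeric(1))
  score <- sum(r)
  list(score = score, right = score > 10, position_profile = profile)
}

#' Code consistency of left hemisphere dominance
#'
#' A child is consistently left dominant only if left-lateralised for
#' language by fTCD *and* right-handed on both handedness measures. The
#' triple codes 1 for left-hemisphere dominance on each measure (for fTCD,
#' 0 codes bilateral or right-lateralised language; for the handedness
#' measures, 0 means less than half of responses were right-handed).
#'
#' @param category fTCD laterality category (`"left"`, `"bilateral"`,
#'   `"right"`).
#' @param ehi_right,qhp_right logical right-handedness flags.
#' @return List with `triple` (named integer vector ftcd/ehi/qhp) and
#'   `consistent` (logical).
#' @export
code_dominance <- function(category, ehi_right, qhp_right) {
  if (is.na(category))
    stop("laterality category missing (unusable fTCD data)")
  stopifnot(category %in% c("left", "bilateral", "right"))
  triple <- c(ftcd = as.integer(category == "left"),
              ehi = as.integer(isTRUE(ehi_right)),
              qhp = as.integer(isTRUE(qhp_right)))
  list(triple = triple, consistent = all(triple == 1L))
}
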