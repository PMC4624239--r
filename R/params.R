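#' Scanning parameters
#'
#' Bundles every tunable of the scanning pipeline with validated defaults.
#' The defaults reproduce the published operating point: +1/-1 match/mismatch
#' scores, 8 nt seeds, a noise threshold equal to the score of a perfect
#' 12-mer, windows the size of the query stepping 25\%, pattern chaining with
#' a 200 nt maximum inter-motif gap and 25 nt shift tolerance, region calling
#' at median + 3*MAD, and the 25 highest predictions reported per query.
#'
#' @param s_p Match score per nucleotide (must be > 0).
#' @param s_q Mismatch score per nucleotide (must be < 0).
#' @param k Minimum seed size in nt.
#' @param noise_word_len Length of the perfect word whose score defines the
#'   noise threshold; motifs scoring below it are discarded unless rescued
#'   by a co-linear pattern.
#' @param window_step_fraction Window step as a fraction of the window size.
#' @param max_distance Maximum inter-motif gap (end-to-start, nt) allowed
#'   when chaining motifs into a pattern.
#' @param max_shift Shift tolerance (nt): semi-minor axis of the elliptical
#'   motif spaces used for pattern detection.
#' @param mad_multiplier Region-calling threshold is
#'   `median + mad_multiplier * MAD` of the window scores.
#' @param top_n Number of ranked predictions reported per query and score
#'   type.
#' @return An object of class `scan_params` (a validated list).
#' @examples
#' p <- scan_params()
#' noise_threshold(p) # 144, the score of a perfect 12-mer
#' @export
scan_params <- function(s_p = 1, s_q = -1, k = 8L, noise_word_len = 12L,
                        window_step_fraction = 0.25, max_distance = 200L,
                        max_shift = 25L, mad_multiplier = 3,
                        top_n = 25L) {
  p <- list(
    s_p = as.numeric(s_p), s_q = as.numeric(s_q), k = as.integer(k),
    noise_word_len = as.integer(noise_word_len),
    window_step_fraction = as.numeric(window_step_fraction),
    max_distance = as.numeric(max_distance),
    max_shift = as.numeric(max_shift),
    mad_multiplier = as.numeric(mad_multiplier),
    top_n = as.integer(top_n)
  )
  stopifnot(
    p$s_p > 0, p$s_q < 0, p$k >= 1L, p$noise_word_len >= p$k,
    p$window_step_fraction > 0, p$window_step_fraction <= 1,
    p$max_distance > 0, p$max_shift > 0, p$mad_multiplier >= 0,
    p$top_n >= 1L
  )
  class(p) <- "scan_params"
  p
}

#' @export
print.scan_params <- function(x, ...) {
  cat("scan_params:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
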