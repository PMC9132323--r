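#' Stimulus colour palette
#'
#' The fixed palette of 20 clearly discernible colours used for all stimuli,
#' plus the white background. Colour indices are stable: colours 1--5 are the
#' diagnostic colours of categories 1--5 (used for the diagnostic patch in the
#' patch experiments, the diagnostic segment in the segment experiments and
#' the global figure colour in the colour experiments); colours 6--20 form the
#' non-diagnostic pool that fills everything else.
#'
#' @return A list with `colours`, a 20 x 3 integer matrix of RGB values in
#'   0--255 (rows are colour indices), and `background`, the background RGB
#'   triple (white).
#' @examples
#' pal <- sb_palette()
#' nrow(pal$colours)
#' @export
sb_palette <- function() {
  cols <- matrix(c(
    230,  25,  75,   #  1 red
     60, 180,  75,   #  2 green
      0, 130, 200,   #  3 blue
    245, 130,  48,   #  4 orange
    145,  30, 180,   #  5 purple
     70, 240, 240,   #  6 cyan
    240,  50, 230,   #  7 magenta
    210, 245,  60,   #  8 lime
    250, 190, 212,   #  9 pink
      0, 128, 128,   # 10 teal
    220, 190, 255,   # 11 lavender
    170, 110,  40,   # 12 brown
    255, 250, 200,   # 13 beige
    128,   0,   0,   # 14 maroon
    170, 255, 195,   # 15 mint
    128, 128,   0,   # 16 olive
    255, 215, 180,   # 17 apricot
      0,   0, 128,   # 18 navy
    128, 128, 128,   # 19 grey
    255, 225,  25),  # 20 yellow
    ncol = 3, byrow = TRUE)
  storage.mode(cols) <- "integer"
  list(colours = cols, background = c(255L, 255L, 255L))
}

# Indices of the diagnostic colours (one per category) and the non-diagnostic pool.
diag_colours <- function() 1:5
nondiag_colours <- function() 6:20

n_categories <- function() 5L
n_colours <- function() 20L
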