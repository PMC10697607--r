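# Appendage control strategies: per-row frequency programs.
#
# The eight rows are controlled in quadrant pairs (one sagittal and one
# tentacular row per body quadrant share a frequency) for the four naturally
# observed strategies; the independent-row subsets deliberately break the
# pairing to probe the full capability of the body plan.

#' Per-row frequency program
#'
#' @param freqs length-8 numeric, beat frequency (Hz) of each row in the
#'   [row_layout()] order (quadrant 1 sagittal, quadrant 1 tentacular,
#'   quadrant 2 sagittal, ...).
#' @param direction +1 forward power stroke, -1 reversed (backward swimming).
#' @param mode_label descriptive label carried through tables and outputs.
#' @return object of class `cteno_program`.
#' @export
row_frequency_program <- function(freqs, direction = 1, mode_label = "custom") {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 8 || any(!is.finite(freqs)) || any(freqs < 0))
    stop("freqs must be 8 finite non-negative frequencies (Hz)")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  structure(list(freqs = freqs, direction = direction,
                 mode_label = mode_label),
            class = "cteno_program")
}

#' @export
print.cteno_program <- function(x, ...) {
  cat(sprintf("Row frequency program [%s], direction %+d\n",
              x$mode_label, x$direction))
  cat("  quadrant:   1    1    2    2    3    3    4    4\n")
  cat("  type:       S    T    S    T    S    T    S    T\n")
  cat(sprintf("  f (Hz):  %s\n", paste(sprintf("%4.3g", x$freqs), collapse = " ")))
  invisible(x)
}

#' Turning-mode frequency assignment
#'
#' Express the four observed control strategies as per-row frequency
#' programs. Rows are driven in quadrant pairs:
#' \describe{
#'   \item{mode1}{one quadrant pair at `f_out`, the diagonally opposite
#'     quadrant pair at `f_in`, the other four rows inactive.}
#'   \item{mode2_sagittal}{the four rows on one side of the sagittal plane at
#'     `f_out`, the other four at `f_in`.}
#'   \item{mode2_tentacular}{split across the tentacular plane instead.}
#'   \item{mode3}{six rows at `f_out`, one quadrant pair at `f_in`.}
#'   \item{mode4}{all eight rows at `f_out` (straight swimming).}
#' }
#'
#' @param mode one of `"mode1"`, `"mode2_sagittal"`, `"mode2_tentacular"`,
#'   `"mode3"`, `"mode4"`.
#' @param f_out outside-of-turn frequency (Hz).
#' @param f_in inside-of-turn frequency (Hz); must satisfy
#'   `f_out > f_in >= 0` for modes 1-3 and is ignored for mode 4.
#' @param direction +1 forward, -1 backward power stroke.
#' @return a [row_frequency_program()].
#' @export
#' @examples
#' assign_mode("mode1", f_out = 30, f_in = 0)$freqs
assign_mode <- function(mode = c("mode1", "mode2_sagittal", "mode2_tentacular",
                                 "mode3", "mode4"),
                        f_out, f_in = 0, direction = 1) {
  mode <- match.arg(mode)
  if (!is.finite(f_out) || f_out < 0) stop("f_out must be >= 0")
  if (mode == "mode4") {
    f_in <- f_out
  } else if (!is.finite(f_in) || !(f_out > f_in && f_in >= 0)) {
    stop("modes 1-3 require f_out > f_in >= 0")
  }
  quadrant <- rep(1:4, each = 2)            # row_layout() order
  z <- rep(0, 8)
  freqs <- switch(mode,
    mode1 = ifelse(quadrant == 1, f_out, ifelse(quadrant == 3, f_in, 0)),
    mode2_sagittal = ifelse(quadrant %in% c(1, 4), f_out, f_in),
    mode2_tentacular = ifelse(quadrant %in% c(1, 2), f_out, f_in),
    mode3 = ifelse(quadrant == 3, f_in, f_out),
    mode4 = z + f_out)
  row_frequency_program(freqs, direction = direction, mode_label = mode)
}

#' Enumerate the turning-mode frequency sweep
#'
#' Cartesian product of the four turning configurations (mode 1, the two
#' mode-2 variants, and mode 3) with the frequency grid `f_out = 2, 4, ...,
#' 34 Hz` and `f_in = 0, 2, ..., f_out - 2 Hz`: 153 pairs per configuration,
#' 612 runs in total.
#'
#' @param direction +1 forward, -1 backward power stroke.
#' @return data.frame with columns `mode`, `f_out`, `f_in`, `direction`.
#' @export
#' @examples
#' nrow(enumerate_sweep())   # 612
enumerate_sweep <- function(direction = 1) {
  modes <- c("mode1", "mode2_sagittal", "mode2_tentacular", "mode3")
  grid <- do.call(rbind, lapply(seq(2, 34, by = 2), function(f_out)
    data.frame(f_out = f_out, f_in = seq(0, f_out - 2, by = 2))))
  out <- do.call(rbind, lapply(modes, function(m)
    cbind(data.frame(mode = m), grid)))
  out$direction <- direction
  out
}

#' Enumerate all independent row subsets
#'
#' One program per non-empty subset of the eight rows, active rows beating at
#' `f`, the rest inactive -- the hypothetical case of fully independent row
#' control (quadrant pairing deliberately not enforced). There are
#' `2^8 - 1 = 255` such subsets.
#'
#' @param f beat frequency of the active rows (Hz).
#' @param direction +1 forward, -1 backward power stroke.
#' @return list of 255 [row_frequency_program()] objects; each carries the
#'   active-row mask as attribute `rows`.
#' @export
#' @examples
#' length(enumerate_subsets(30))   # 255
enumerate_subsets <- function(f = 30, direction = 1) {
  stopifnot(f > 0)
  lapply(seq_len(255), function(mask) {
    active <- bitwAnd(mask, bitwShiftL(1L, 0:7)) > 0L
    p <- row_frequency_program(ifelse(active, f, 0), direction = direction,
                               mode_label = sprintf("subset_%03d", mask))
    attr(p, "rows") <- which(active)
    p
  })
}
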