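# Schematic trajectory archetypes on the canonical differentiation grid.

.CANONICAL_DAYS <- c(-2, 0, 2, 4, 6, 8)

# Eight schematic cluster shapes. Each template is piecewise linear on
# the canonical day grid, normalized to unit amplitude (range <= 1).
# Knot values are fixed package constants chosen so that the
# finite-difference slope-sign sequence (central differences at
# interior days, one-sided at the ends) collapses to the stated
# rise/constant/fall pattern under the grammar of labelPattern() at a
# tolerance of 0.05 on unit amplitude.
.ARCHETYPES <- list(
  `rise-fall-rise-fall`      = list(template = c(0.5, 1.0, 0.0, 0.6, 1.0, 0.0),
                                    pattern = "rise-fall-rise-fall"),
  `rise-constant`            = list(template = c(0, 1, 1, 1, 1, 1),
                                    pattern = "rise-constant"),
  `rise`                     = list(template = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                    pattern = "rise"),
  `constant-fall-constant`   = list(template = c(1, 1, 1, 0, 0, 0),
                                    pattern = "constant-fall-constant"),
  `constant`                 = list(template = c(0, 0, 0, 0, 0, 0),
                                    pattern = "constant"),
  `fall-constant`            = list(template = c(1, 0, 0, 0, 0, 0),
                                    pattern = "fall-constant"),
  `rise-fall-constant-fall`  = list(template = c(0, 1, 0.5, 0.5, 0.5, 0),
                                    pattern = "rise-fall-constant-fall"),
  `rise-constant-fall`       = list(template = c(0, 1, 1, 1, 1, 0),
                                    pattern = "rise-constant-fall")
)

#' Schematic trajectory archetypes
#'
#' The eight schematic expression dynamics used by the synthetic-data
#' generator: rise-fall-rise-fall, rise-constant (rise followed by a
#' plateau/slight decline), rise, constant-fall-constant, constant,
#' fall-constant (drop then plateau), rise-fall-constant-fall and
#' rise-constant-fall. Each archetype carries a unit-amplitude
#' piecewise-linear template on the canonical day grid (-2, 0, 2, 4, 6,
#' 8) whose finite-difference slope-sign sequence reproduces its pattern
#' string under [labelPattern()].
#'
#' @return named list; each element has `template` (6 knot values) and
#'   `pattern` (the grammar string).
#' @examples
#' names(archetypeShapes())
#' archetypeShapes()[["rise"]]$template
#' @export
archetypeShapes <- function() .ARCHETYPES

#' Evaluate an archetype template on an arbitrary day grid
#'
#' Templates are defined on the canonical grid; for other grids the
#' piecewise-linear shape is interpolated over normalized time.
#'
#' @param name archetype name (see [archetypeShapes()]).
#' @param days numeric, strictly increasing day grid.
#' @return numeric template values, one per day.
#' @export
archetypeTemplate <- function(name, days = .CANONICAL_DAYS) {
  if (!name %in% names(.ARCHETYPES)) {
    stop(sprintf("unknown archetype '%s'", name), call. = FALSE)
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop("'days' must be strictly increasing", call. = FALSE)
  }
  tpl <- .ARCHETYPES[[name]]$template
  u <- (days - min(days)) / (max(days) - min(days))
  stats::approx(seq(0, 1, length.out = length(tpl)), tpl, xout = u)$y
}
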