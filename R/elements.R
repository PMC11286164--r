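# Per-element mechanics.
#
# A bundle element is either a straight fibre (fails once its effective
# elongation exceeds its critical strain) or a looped fibre that stores
# hidden length in a series of loops. When a looped fibre reaches the
# opening strain of its smallest unopened loop, the loop unravels: the
# released length acts as slack, the force across the fibre resets, and the
# fibre only re-engages once the hidden length has been straightened.
# Straight fibres may in addition receive slack generated by a coupled
# looped fibre, scaled by a transmission coefficient Cs in (0, 1].
#
# Elements are immutable values: state-changing operations return an updated
# copy (the solver owns the mutable simulation state).

#' Straight bundle element
#'
#' @param id Unique element label.
#' @param rel_diameter Relative diameter (dimensionless, `> 0`). Force scales
#'   with the relative cross-section `rel_diameter^2`.
#' @param law A [constitutive_law()].
#' @param critical_strain Effective elongation beyond which the fibre fails.
#' @param coupling_source Optional character vector of looped-element ids
#'   whose released slack this element can receive.
#' @param Cs Transmission coefficient in `(0, 1]`, the fraction of upstream
#'   slack felt by this element. Ignored without a `coupling_source`.
#' @return An object of classes `straight_element`, `bundle_element`.
#' @export
straight_element <- function(id, rel_diameter, law, critical_strain,
                             coupling_source = NULL, Cs = 1) {
  stopifnot(rel_diameter > 0, critical_strain > 0,
            inherits(law, "constitutive_law"))
  if (!is.null(coupling_source) && (Cs <= 0 || Cs > 1))
    stop("Cs must be in (0, 1] when a coupling source is set")
  structure(
    list(id = as.character(id), rel_diameter = as.numeric(rel_diameter),
         law = law, critical_strain = as.numeric(critical_strain),
         coupling_source = coupling_source, Cs = as.numeric(Cs),
         accumulated_slack = 0, failed = FALSE),
    class = c("straight_element", "bundle_element")
  )
}

#' Looped bundle element
#'
#' A fibre carrying a series of loops. Loops are stored sorted by opening
#' threshold: after every opening the effective elongation resets below zero,
#' so the smallest remaining threshold is necessarily the next reached.
#'
#' @inheritParams straight_element
#' @param loop_thresholds Opening critical strains of the loops (`> 0`).
#' @param hidden_lengths Hidden length released by each loop (`> 0`), aligned
#'   with `loop_thresholds` before sorting.
#' @param post_loop_critical_strain Failure strain of the bare fibre once all
#'   loops are open.
#' @return An object of classes `looped_element`, `bundle_element`.
#' @export
looped_element <- function(id, rel_diameter, law, loop_thresholds,
                           hidden_lengths, post_loop_critical_strain = 0.5) {
  stopifnot(rel_diameter > 0, inherits(law, "constitutive_law"),
            length(loop_thresholds) == length(hidden_lengths),
            post_loop_critical_strain > 0)
  if (length(loop_thresholds) && (any(loop_thresholds <= 0) ||
                                  any(hidden_lengths < 0)))
    stop("loop thresholds must be > 0 and hidden lengths >= 0")
  ord <- order(loop_thresholds)
  structure(
    list(id = as.character(id), rel_diameter = as.numeric(rel_diameter),
         law = law,
         loop_thresholds = as.numeric(loop_thresholds[ord]),
         hidden_lengths = as.numeric(hidden_lengths[ord]),
         next_loop = 1L,
         post_loop_critical_strain = as.numeric(post_loop_critical_strain),
         accumulated_slack = 0, failed = FALSE),
    class = c("looped_element", "bundle_element")
  )
}

#' @export
print.bundle_element <- function(x, ...) {
  kind <- if (inherits(x, "looped_element")) "looped" else "straight"
  cat(sprintf("<%s element '%s'> rel_diameter=%g slack=%g failed=%s\n",
              kind, x$id, x$rel_diameter, x$accumulated_slack, x$failed))
  if (inherits(x, "looped_element"))
    cat(sprintf("  loops: %d open / %d total; post-loop critical strain %g\n",
                x$next_loop - 1L, length(x$loop_thresholds),
                x$post_loop_critical_strain))
  invisible(x)
}

n_unopened_loops <- function(element) {
  if (!inherits(element, "looped_element")) return(0L)
  length(element$loop_thresholds) - element$next_loop + 1L
}

# Critical strain currently governing failure: straight fibres use their own;
# looped fibres cannot fail while loops remain, then fail like a bare fibre.
applicable_critical_strain <- function(element) {
  if (inherits(element, "looped_element")) {
    if (n_unopened_loops(element) > 0L) Inf else element$post_loop_critical_strain
  } else {
    element$critical_strain
  }
}

#' Effective elongation of an element
#'
#' The strain the fibre material actually feels: the external strain minus
#' the element's own accumulated slack minus any upstream slack transmitted
#' through the coupling (`upstream_slack * Cs`). May be negative, in which
#' case the element is slack and carries no force.
#'
#' @param element A bundle element.
#' @param x External (applied) strain, `>= 0`.
#' @param upstream_slack Accumulated slack of the coupled looped source
#'   (0 for uncoupled elements).
#' @return Dimensionless effective elongation (possibly negative).
#' @export
effective_elongation <- function(element, x, upstream_slack = 0) {
  stopifnot(x >= 0, upstream_slack >= 0)
  cs <- if (is.null(element$coupling_source)) 1 else element$Cs
  x - element$accumulated_slack - upstream_slack * cs
}

#' Force carried by an element at a given effective elongation
#'
#' Zero if the element has failed, is slack (`x_e <= 0`), or is past the
#' applicable critical strain (its own for straight fibres, the post-loop
#' critical strain for a looped fibre with all loops open; a looped fibre
#' with unopened loops cannot fail). Otherwise
#' `eval_stress(law, x_e) * rel_diameter^2`, in relative force units.
#'
#' @param element A bundle element.
#' @param x_e Effective elongation (see [effective_elongation()]).
#' @return Relative force (`>= 0`).
#' @export
element_force <- function(element, x_e) {
  if (element$failed || x_e <= 0) return(0)
  if (x_e > applicable_critical_strain(element)) return(0)
  eval_stress(element$law, x_e) * element$rel_diameter^2
}

#' Has an element failed at a given effective elongation?
#'
#' @inheritParams element_force
#' @return `TRUE` iff the element is already failed, or is a straight element
#'   with `x_e` above its critical strain, or a looped element with all loops
#'   open and `x_e` above its post-loop critical strain. Failure is
#'   irreversible; a looped element with unopened loops never fails.
#' @export
element_failed <- function(element, x_e) {
  element$failed || x_e > applicable_critical_strain(element)
}

#' Open the smallest-threshold unopened loop of a looped element
#'
#' Unravelling releases the loop: the accumulated slack grows by
#' `threshold + hidden_length` (mode `"reset"`, the default), so immediately
#' after an opening at threshold the new effective elongation is
#' `-hidden_length` — the force across the fibre resets to zero and the
#' released length must be straightened before the fibre re-engages. Mode
#' `"hidden_only"` adds only the hidden length (a parametric-study variant in
#' which the force does not fully reset).
#'
#' @param element A [looped_element()] with at least one unopened loop.
#' @param x External strain at which the opening occurs (recorded in the
#'   event).
#' @param slack_mode `"reset"` or `"hidden_only"`.
#' @return `list(element = <updated element>, event = <one-row data.frame>)`
#'   with event columns `strain`, `element_id`, `event`, `threshold`,
#'   `hidden_length`.
#' @export
open_next_loop <- function(element, x, slack_mode = c("reset", "hidden_only")) {
  stopifnot(inherits(element, "looped_element"))
  slack_mode <- match.arg(slack_mode)
  if (n_unopened_loops(element) == 0L)
    stop("element '", element$id, "' has no unopened loops")
  i <- element$next_loop
  thr <- element$loop_thresholds[i]
  hid <- element$hidden_lengths[i]
  element$accumulated_slack <- element$accumulated_slack +
    if (slack_mode == "reset") thr + hid else hid
  element$next_loop <- i + 1L
  list(
    element = element,
    event = data.frame(strain = x, element_id = element$id,
                       event = "loop_open", threshold = thr,
                       hidden_length = hid, stringsAsFactors = FALSE)
  )
}
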