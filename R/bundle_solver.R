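# Bundle assembly and the quasi-static displacement-controlled solver.
#
# Under displacement control every surviving element sees the same external
# strain x, so equal load sharing is implicit: "redistribution" after a
# failure is simply the change in the force sum. The solver walks x up a
# regular grid; at each grid point it resolves loop openings and failures to
# a fixed point (an opening changes the slack felt by coupled elements, which
# may trigger further events at the same strain) before recording the total
# force.

#' Assemble bundle elements into a parallel bundle
#'
#' @param elements List of [straight_element()] / [looped_element()] objects
#'   with unique ids; any `coupling_source` must name looped elements present
#'   in the bundle.
#' @return An object of class `fbm_bundle`.
#' @export
bundle <- function(elements) {
  ids <- vapply(elements, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate element ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  looped_ids <- ids[vapply(elements, inherits, TRUE, "looped_element")]
  for (el in elements) {
    bad <- setdiff(el$coupling_source, looped_ids)
    if (length(bad))
      stop("element '", el$id, "': coupling source(s) not a looped element ",
           "in the bundle: ", paste(bad, collapse = ", "))
  }
  names(elements) <- ids
  structure(list(elements = elements), class = "fbm_bundle")
}

#' @export
print.fbm_bundle <- function(x, ...) {
  looped <- vapply(x$elements, inherits, TRUE, "looped_element")
  cat(sprintf("<fbm_bundle> %d elements (%d looped, %d straight), %d loops\n",
              length(x$elements), sum(looped), sum(!looped),
              sum(vapply(x$elements, n_unopened_loops, 0L))))
  invisible(x)
}

#' @export
length.fbm_bundle <- function(x) length(x$elements)

#' Closed-form equal-load-sharing fibre bundle force
#'
#' The classic fibre bundle model: `N` parallel linear fibres of stiffness
#' `k` with failure thresholds distributed with CDF `P` carry, at elongation
#' `x`, the expected force `F = N k x (1 - P(x))`.
#'
#' @param N Number of fibres.
#' @param k Fibre stiffness.
#' @param x Elongation (vectorized, `>= 0`).
#' @param threshold_cdf Either a function `P(x)` or a two-column tabulation
#'   (x, P) which must be monotone in both columns and is interpolated
#'   linearly.
#' @return Force, same length as `x`.
#' @export
classic_fbm_force <- function(N, k, x, threshold_cdf) {
  stopifnot(all(x >= 0))
  P <- if (is.function(threshold_cdf)) {
    threshold_cdf
  } else {
    tab <- as.data.frame(threshold_cdf)
    if (ncol(tab) < 2) stop("threshold_cdf tabulation needs two columns")
    if (is.unsorted(tab[[1]], strictly = TRUE) || is.unsorted(tab[[2]]) ||
        any(tab[[2]] < 0) || any(tab[[2]] > 1))
      stop("invalid CDF tabulation: x must be strictly increasing and P monotone in [0, 1]")
    stats::approxfun(tab[[1]], tab[[2]], rule = 2)
  }
  p <- P(x)
  if (any(diff(p) < -1e-12) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("threshold_cdf is not a valid CDF on the requested points")
  N * k * x * (1 - pmin(pmax(p, 0), 1))
}

## ---- internal vectorized engine ------------------------------------------
# The engine flattens a bundle into parallel vectors so a default-thread
# simulation (~8000 grid steps, 1600 loop events) runs in well under a
# second, and a 10^4-fibre classic bundle is vectorized across elements.

as_engine <- function(b, slack_mode = "reset") {
  els <- b$elements
  n <- length(els)
  ids <- names(els)
  powers <- sort(unique(unlist(lapply(els, function(e) e$law$powers))))
  coefs <- matrix(0, n, length(powers))
  for (i in seq_len(n)) {
    e <- els[[i]]
    coefs[i, match(e$law$powers, powers)] <- e$law$coefficients
  }
  looped <- vapply(els, inherits, TRUE, "looped_element")
  thr <- lapply(els, function(e) if (inherits(e, "looped_element")) e$loop_thresholds else numeric())
  hid <- lapply(els, function(e) if (inherits(e, "looped_element")) e$hidden_lengths else numeric())
  nxt <- vapply(els, function(e) if (inherits(e, "looped_element")) e$next_loop else 1L, 1L)
  nl <- lengths(thr)
  post_xc <- vapply(els, function(e)
    if (inherits(e, "looped_element")) e$post_loop_critical_strain else e$critical_strain, 0)
  # critical strain currently governing failure (Inf while loops remain)
  cur_xc <- ifelse(looped & nxt <= nl, Inf, post_xc)
  coupled <- which(vapply(els, function(e) length(e$coupling_source) > 0, TRUE))
  src <- lapply(els[coupled], function(e) match(e$coupling_source, ids))
  cap <- sum(nl) + n + 8L
  list(
    n = n, ids = ids, d2 = vapply(els, `[[`, 0, "rel_diameter")^2,
    powers = powers, coefs = coefs,
    looped = looped, thr = thr, hid = hid, nxt = nxt, nl = nl,
    post_xc = post_xc, cur_xc = cur_xc,
    slack = vapply(els, `[[`, 0, "accumulated_slack"),
    failed = vapply(els, `[[`, TRUE, "failed"),
    Cs = vapply(els, function(e) if (is.null(e$Cs)) 1 else e$Cs, 0),
    coupled = coupled, src = src,
    slack_mode = slack_mode, max_xe = numeric(n), cascade_cap = cap,
    ev_strain = numeric(cap), ev_id = character(cap), ev_kind = character(cap),
    ev_thr = rep(NA_real_, cap), ev_hid = rep(NA_real_, cap), ev_n = 0L
  )
}

engine_upstream <- function(eng) {
  up <- numeric(eng$n)
  for (j in seq_along(eng$coupled))
    up[eng$coupled[j]] <- eng$Cs[eng$coupled[j]] * max(eng$slack[eng$src[[j]]])
  up
}

engine_record <- function(eng, strain, id, kind, thr = NA_real_, hid = NA_real_) {
  eng$ev_n <- eng$ev_n + 1L
  k <- eng$ev_n
  eng$ev_strain[k] <- strain
  eng$ev_id[k] <- id
  eng$ev_kind[k] <- kind
  eng$ev_thr[k] <- thr
  eng$ev_hid[k] <- hid
  eng
}

# Resolve all events at external strain x to a fixed point, then return the
# post-cascade total force. Openings within one element are necessarily
# sequential (the reset leaves the effective elongation below zero), but an
# opening feeds slack to coupled elements, so passes repeat until quiet.
engine_step <- function(eng, x) {
  iter <- 0L
  repeat {
    xe <- x - eng$slack - engine_upstream(eng)
    changed <- FALSE
    for (i in which(eng$looped & !eng$failed)) {
      j <- eng$nxt[i]
      if (j <= eng$nl[i] && xe[i] >= eng$thr[[i]][j]) {
        t_j <- eng$thr[[i]][j]
        h_j <- eng$hid[[i]][j]
        eng$slack[i] <- eng$slack[i] +
          if (eng$slack_mode == "reset") t_j + h_j else h_j
        eng$nxt[i] <- j + 1L
        if (eng$nxt[i] > eng$nl[i]) eng$cur_xc[i] <- eng$post_xc[i]
        eng <- engine_record(eng, x, eng$ids[i], "loop_open", t_j, h_j)
        changed <- TRUE
      }
    }
    if (changed) { xe <- x - eng$slack - engine_upstream(eng) }
    newly <- which(!eng$failed & xe > eng$cur_xc)
    if (length(newly)) {
      eng$failed[newly] <- TRUE
      for (i in newly) eng <- engine_record(eng, x, eng$ids[i], "element_fail")
      changed <- TRUE
    }
    iter <- iter + 1L
    if (!changed || iter > eng$cascade_cap) break
  }
  xe <- x - eng$slack - engine_upstream(eng)
  engaged <- !eng$failed & xe > 0
  force <- 0
  if (any(engaged)) {
    xi <- xe[engaged]
    stress <- numeric(length(xi))
    for (j in seq_along(eng$powers))
      stress <- stress + eng$coefs[engaged, j] * xi^eng$powers[j]
    force <- sum(stress * eng$d2[engaged])
    eng$max_xe[engaged] <- pmax(eng$max_xe[engaged], xi)
  }
  list(eng = eng, force = force)
}

engine_events <- function(eng) {
  k <- seq_len(eng$ev_n)
  data.frame(strain = eng$ev_strain[k], element_id = eng$ev_id[k],
             event = eng$ev_kind[k], threshold = eng$ev_thr[k],
             hidden_length = eng$ev_hid[k], stringsAsFactors = FALSE)
}

engine_writeback <- function(eng, b) {
  for (i in seq_len(eng$n)) {
    el <- b$elements[[i]]
    el$accumulated_slack <- eng$slack[i]
    el$failed <- eng$failed[i]
    if (inherits(el, "looped_element")) el$next_loop <- eng$nxt[i]
    b$elements[[i]] <- el
  }
  b
}

## ---- public solver surface ------------------------------------------------

#' Total force carried by a bundle at an external strain
#'
#' Stateless: evaluates the force sum at strain `x` for the bundle's current
#' element states (no events are triggered). Each coupled element reads the
#' largest accumulated slack among its coupling sources, scaled by its `Cs`.
#'
#' @param bundle An [bundle()] object.
#' @param x External strain (`>= 0`).
#' @return Total relative force.
#' @export
total_force <- function(bundle, x) {
  stopifnot(inherits(bundle, "fbm_bundle"), x >= 0)
  f <- 0
  for (el in bundle$elements) {
    up <- 0
    if (length(el$coupling_source))
      up <- max(vapply(bundle$elements[el$coupling_source], `[[`, 0,
                       "accumulated_slack"))
    f <- f + element_force(el, effective_elongation(el, x, up))
  }
  f
}

#' Advance a bundle to an external strain, resolving all triggered events
#'
#' Resolves loop openings and element failures at strain `x` to a fixed
#' point (events may enable further events through the slack coupling) and
#' returns the post-cascade force together with the updated bundle.
#'
#' @param bundle An [bundle()] object.
#' @param x External strain; must not be below a strain already applied to
#'   this bundle (quasi-static loading is monotone).
#' @param slack_mode `"reset"` (opening resets the element force) or
#'   `"hidden_only"`.
#' @return `list(force = <number>, events = <data.frame>, bundle = <updated>)`.
#' @export
step_bundle <- function(bundle, x, slack_mode = "reset") {
  stopifnot(inherits(bundle, "fbm_bundle"))
  last <- attr(bundle, "last_strain")
  if (!is.null(last) && x < last)
    stop("non-monotone loading: x = ", x, " after strain ", last)
  eng <- as_engine(bundle, slack_mode)
  st <- engine_step(eng, x)
  out <- engine_writeback(st$eng, bundle)
  attr(out, "last_strain") <- x
  list(force = st$force, events = engine_events(st$eng), bundle = out)
}

#' Quasi-static displacement-controlled simulation of a bundle
#'
#' Steps the external strain from 0 to `x_max` in increments `dx`, resolving
#' events at each grid point, and stops early once every element has failed
#' (from which point the force is identically zero). Deterministic given the
#' bundle: all randomness lives in the sampling that built the bundle.
#'
#' @param bundle An [bundle()] object (in its initial state).
#' @param x_max Largest external strain to apply.
#' @param dx Strain increment (`> 0`). Events are resolved at grid points,
#'   so event strains carry up to one `dx` of grid slop.
#' @param slack_mode `"reset"` or `"hidden_only"` (see [open_next_loop()]).
#' @param seed,fingerprint Optional metadata recorded in the result (the seed
#'   used to build the bundle and the fingerprint of its configuration).
#' @return An object of class `fbm_sim`: a list with `curve` (data.frame
#'   `strain`, `force`), `events` (data.frame `strain`, `element_id`,
#'   `event`, `threshold`, `hidden_length`), `element_max` (named vector of
#'   the maximum effective elongation each element reached while carrying
#'   load), `final_strain` (largest strain with positive force, `NA` if the
#'   curve never loads), `dx`, `x_max`, `slack_mode`, `seed`, `fingerprint`.
#' @export
simulate_bundle <- function(bundle, x_max = 50, dx = 0.005,
                            slack_mode = c("reset", "hidden_only"),
                            seed = NULL, fingerprint = NULL) {
  stopifnot(inherits(bundle, "fbm_bundle"))
  slack_mode <- match.arg(slack_mode)
  if (dx <= 0) stop("dx must be > 0")
  if (x_max <= 0) stop("x_max must be > 0")
  eng <- as_engine(bundle, slack_mode)
  grid <- seq(0, x_max, by = dx)
  forces <- numeric(length(grid))
  used <- length(grid)
  for (s in seq_along(grid)) {
    st <- engine_step(eng, grid[s])
    eng <- st$eng
    forces[s] <- st$force
    if (all(eng$failed)) { used <- s; break }
  }
  curve <- data.frame(strain = grid[seq_len(used)], force = forces[seq_len(used)])
  nz <- which(curve$force > 0)
  structure(
    list(curve = curve, events = engine_events(eng),
         element_max = stats::setNames(eng$max_xe, eng$ids),
         final_strain = if (length(nz)) curve$strain[max(nz)] else NA_real_,
         dx = dx, x_max = x_max, slack_mode = slack_mode,
         seed = seed, fingerprint = fingerprint),
    class = "fbm_sim"
  )
}

#' @export
print.fbm_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "<fbm_sim> %d grid points (dx = %g), final strain %.3f (%.0f%%)\n",
    "  events: %d loop openings, %d element failures; peak force %.4g\n"),
    nrow(x$curve), x$dx, x$final_strain, 100 * x$final_strain,
    sum(x$events$event == "loop_open"), sum(x$events$event == "element_fail"),
    max(x$curve$force)))
  invisible(x)
}

#' Write a simulation result to plain-text files
#'
#' Writes `<prefix>_curve.csv` (readable by [read_curve()]),
#' `<prefix>_events.csv` and a JSON sidecar `<prefix>_meta.json` carrying the
#' seed, configuration fingerprint, per-element maxima and event totals.
#'
#' @param sim An `fbm_sim` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "fbm_sim"))
  paths <- paste0(prefix, c("_curve.csv", "_events.csv", "_meta.json"))
  write_curve(force_curve(sim$curve$strain, sim$curve$force,
                          units = "relative"), paths[1])
  utils::write.csv(sim$events, paths[2], row.names = FALSE)
  meta <- list(
    seed = sim$seed, fingerprint = sim$fingerprint, dx = sim$dx,
    x_max = sim$x_max, slack_mode = sim$slack_mode,
    n_elements = length(sim$element_max),
    n_loop_open = sum(sim$events$event == "loop_open"),
    n_element_fail = sum(sim$events$event == "element_fail"),
    final_strain = sim$final_strain,
    element_max_effective_elongation = as.list(sim$element_max)
  )
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(paths)
}
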