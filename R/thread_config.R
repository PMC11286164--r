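# Thread model configurations: definition, validation, (de)serialization,
# and expansion into a concrete bundle by seeded sampling.
#
# A configuration lists element *groups* (a group = several identical fibres
# up to the random draws) plus global solver settings. Distribution-valued
# fields use the `mean +/- pm` notation: `list(mean = m, pm = h)` means
# uniform on [m - h, m + h]; a bare number is a degenerate (exact) value.

GROUP_KEYS <- c("name", "count", "rel_diameter", "law", "critical_strain",
                "loops", "coupling", "post_loop_critical_strain")
LOOP_KEYS <- c("count", "threshold", "hidden_length")
SETTINGS_KEYS <- c("dx", "x_max", "slack_mode", "post_loop_critical_strain",
                   "seed")

#' Create a thread model configuration
#'
#' @param groups List of group specifications. Each group is a list with
#'   `name`, `count` (fibres in the group), `rel_diameter`, `law` (either
#'   `list(linear = list(E = ...))` or `list(poly = list(c1 = ..., c3 = ...,
#'   ...))`), and optionally `critical_strain` (a number or
#'   `list(mean =, pm =)`), `loops` (`list(count =, threshold = list(mean =,
#'   pm =), hidden_length = list(mean =, pm =))`; loop count is per fibre),
#'   `coupling` (`list(sources = <group names>, Cs = <(0,1]>)`) and
#'   `post_loop_critical_strain`.
#' @param settings Global settings: `dx` (strain increment), `x_max`,
#'   `slack_mode` (`"reset"` or `"hidden_only"`),
#'   `post_loop_critical_strain` (default failure strain of looped fibres
#'   after their last loop opens), `seed`.
#' @return A validated object of class `thread_config`.
#' @seealso [default_kukulcania_config()], [build_bundle()], [load_config()]
#' @export
thread_config <- function(groups, settings = list()) {
  defaults <- list(dx = 0.005, x_max = 50, slack_mode = "reset",
                   post_loop_critical_strain = 0.5, seed = 1L)
  settings <- utils::modifyList(defaults, settings)
  cfg <- structure(list(groups = groups, settings = settings),
                   class = "thread_config")
  validate_config(cfg)
}

#' Default 11-element Kukulcania cribellar thread configuration
#'
#' The configuration of the composite cribellar capture thread of the
#' Southern house spider used throughout: 1 stiff radial carrier line
#' (linear, E = 7 GPa, critical strain 0.2), 2 axial components (cubic
#' strain-stiffening law `0.1 e + 5 e^3`, critical strain 0.5, receiving
#' slack from the undulating fibres with Cs = 0.999), 2 undulating fibres
#' and 6 paracribellar fibres, each carrying 200 loops with opening strains
#' uniform 0.150 +/- 0.145 and hidden lengths uniform 0.038 +/- 0.002.
#' Expands to 11 parallel elements (3 straight + 8 looped) with 1600 loops.
#'
#' @return A `thread_config`.
#' @export
default_kukulcania_config <- function() {
  loopspec <- list(count = 200L,
                   threshold = list(mean = 0.150, pm = 0.145),
                   hidden_length = list(mean = 0.038, pm = 0.002))
  thread_config(list(
    list(name = "radial", count = 1L, rel_diameter = 1,
         law = list(linear = list(E = 7)), critical_strain = 0.2),
    list(name = "axial", count = 2L, rel_diameter = 0.2,
         law = list(poly = list(c1 = 0.1, c3 = 5)), critical_strain = 0.5,
         coupling = list(sources = "uf", Cs = 0.999)),
    list(name = "uf", count = 2L, rel_diameter = 0.175,
         law = list(linear = list(E = 7)), loops = loopspec),
    list(name = "pc", count = 6L, rel_diameter = 0.035,
         law = list(linear = list(E = 7)), loops = loopspec)
  ))
}

## ---- validation -----------------------------------------------------------

is_dist_spec <- function(x)
  is.list(x) && setequal(names(x), c("mean", "pm")) &&
    is.numeric(x$mean) && is.numeric(x$pm)

# number or mean+/-pm -> uniform_pm
as_pm <- function(x) {
  if (is_dist_spec(x)) uniform_pm(x$mean, x$pm)
  else uniform_pm(as.numeric(x), 0)
}

check_dist <- function(x, path, errs, positive_mean = FALSE) {
  if (is_dist_spec(x)) {
    if (x$pm < 0) errs <- c(errs, paste0(path, ".pm: must be >= 0"))
    if (x$mean - x$pm < 0)
      errs <- c(errs, paste0(path, ": support extends below 0 (mean - pm < 0)"))
    if (positive_mean && x$mean <= 0)
      errs <- c(errs, paste0(path, ".mean: must be > 0"))
  } else if (is.numeric(x) && length(x) == 1) {
    if (x < 0 || (positive_mean && x <= 0))
      errs <- c(errs, paste0(path, ": must be ", if (positive_mean) "> 0" else ">= 0"))
  } else {
    errs <- c(errs, paste0(path, ": expected a number or list(mean =, pm =)"))
  }
  errs
}

#' Validate a thread configuration
#'
#' Checks structural and referential integrity (known keys, positive counts
#' and diameters, non-negative distribution supports, coupling sources that
#' resolve to looped groups) and reports every violation with its field
#' path.
#'
#' @param config A `thread_config` (or a bare list with the same shape).
#' @return The config, invisibly, with class `thread_config`.
#' @export
validate_config <- function(config) {
  errs <- character()
  if (!is.list(config$groups) || !length(config$groups))
    stop("config validation failed:\n  groups: at least one group required")
  gnames <- vapply(config$groups, function(g)
    if (is.character(g$name)) g$name else NA_character_, "")
  if (anyNA(gnames)) errs <- c(errs, "groups: every group needs a character `name`")
  if (anyDuplicated(stats::na.omit(gnames)))
    errs <- c(errs, "groups: duplicate group names")
  looped_groups <- gnames[vapply(config$groups, function(g) !is.null(g$loops), TRUE)]
  for (g in config$groups) {
    p <- paste0("groups[", if (is.character(g$name)) g$name else "?", "]")
    unknown <- setdiff(names(g), GROUP_KEYS)
    if (length(unknown))
      errs <- c(errs, paste0(p, ": unknown key(s): ", paste(unknown, collapse = ", ")))
    if (!is.numeric(g$count) || length(g$count) != 1 || g$count < 1 ||
        g$count != round(g$count))
      errs <- c(errs, paste0(p, ".count: must be an integer >= 1"))
    if (!is.numeric(g$rel_diameter) || g$rel_diameter <= 0)
      errs <- c(errs, paste0(p, ".rel_diameter: must be > 0"))
    if (!is.list(g$law) || length(g$law) != 1 ||
        !names(g$law) %in% c("linear", "poly"))
      errs <- c(errs, paste0(p, '.law: expected list(linear = list(E =)) or list(poly = list(c1 =, ...))'))
    else if (names(g$law) == "linear" &&
             (!is.numeric(g$law$linear$E) || g$law$linear$E <= 0))
      errs <- c(errs, paste0(p, ".law.linear.E: must be > 0"))
    if (!is.null(g$critical_strain))
      errs <- check_dist(g$critical_strain, paste0(p, ".critical_strain"),
                         errs, positive_mean = TRUE)
    if (!is.null(g$loops)) {
      lp <- paste0(p, ".loops")
      unknown <- setdiff(names(g$loops), LOOP_KEYS)
      if (length(unknown))
        errs <- c(errs, paste0(lp, ": unknown key(s): ", paste(unknown, collapse = ", ")))
      if (!is.numeric(g$loops$count) || g$loops$count < 0 ||
          g$loops$count != round(g$loops$count))
        errs <- c(errs, paste0(lp, ".count: must be an integer >= 0"))
      if ((g$loops$count %||% 0) > 0) {
        errs <- check_dist(g$loops$threshold, paste0(lp, ".threshold"), errs,
                           positive_mean = TRUE)
        errs <- check_dist(g$loops$hidden_length, paste0(lp, ".hidden_length"),
                           errs)
      }
    }
    if (!is.null(g$coupling)) {
      cp <- paste0(p, ".coupling")
      bad <- setdiff(as.character(g$coupling$sources), looped_groups)
      if (length(bad))
        errs <- c(errs, paste0(cp, ".sources: not a looped group: ",
                               paste(bad, collapse = ", ")))
      cs <- g$coupling$Cs
      if (!is.numeric(cs) || cs <= 0 || cs > 1)
        errs <- c(errs, paste0(cp, ".Cs: must be in (0, 1]"))
    }
  }
  s <- config$settings
  unknown <- setdiff(names(s), SETTINGS_KEYS)
  if (length(unknown))
    errs <- c(errs, paste0("settings: unknown key(s): ",
                           paste(unknown, collapse = ", ")))
  if (!is.numeric(s$dx) || s$dx <= 0) errs <- c(errs, "settings.dx: must be > 0")
  if (!is.numeric(s$x_max) || s$x_max <= 0) errs <- c(errs, "settings.x_max: must be > 0")
  if (!s$slack_mode %in% c("reset", "hidden_only"))
    errs <- c(errs, 'settings.slack_mode: must be "reset" or "hidden_only"')
  if (length(errs))
    stop(errorCondition(
      paste0("config validation failed:\n  ", paste(errs, collapse = "\n  ")),
      class = "loopfbm_validation_error"))
  invisible(structure(config, class = "thread_config"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thread_config <- function(x, ...) {
  cat("<thread_config>", length(x$groups), "groups,",
      sum(vapply(x$groups, function(g) g$count, 0)), "elements; fingerprint",
      config_fingerprint(x), "\n")
  for (g in x$groups)
    cat(sprintf("  %-8s x%-2d rel_diameter %-6g %s\n", g$name, g$count,
                g$rel_diameter,
                if (is.null(g$loops)) "straight" else
                  paste0(g$loops$count, " loops/fibre")))
  invisible(x)
}

## ---- serialization --------------------------------------------------------

# canonical form: stable key order, plain lists, for hashing and round-trips
canonicalize_config <- function(config) {
  canon_num <- function(x) as.numeric(x)
  cg <- lapply(config$groups, function(g) {
    out <- list(name = g$name, count = as.integer(g$count),
                rel_diameter = canon_num(g$rel_diameter))
    lk <- names(g$law)
    out$law <- stats::setNames(list(lapply(g$law[[1]], canon_num)), lk)
    if (!is.null(g$critical_strain))
      out$critical_strain <- if (is_dist_spec(g$critical_strain))
        list(mean = canon_num(g$critical_strain$mean),
             pm = canon_num(g$critical_strain$pm))
      else canon_num(g$critical_strain)
    if (!is.null(g$loops)) {
      thr <- as_pm(g$loops$threshold %||% 0)
      hl <- as_pm(g$loops$hidden_length %||% 0)
      out$loops <- list(
        count = as.integer(g$loops$count),
        threshold = list(mean = thr$mean, pm = thr$halfwidth),
        hidden_length = list(mean = hl$mean, pm = hl$halfwidth))
    }
    if (!is.null(g$coupling))
      out$coupling <- list(sources = as.character(g$coupling$sources),
                           Cs = canon_num(g$coupling$Cs))
    if (!is.null(g$post_loop_critical_strain))
      out$post_loop_critical_strain <- canon_num(g$post_loop_critical_strain)
    out
  })
  s <- config$settings
  list(groups = cg,
       settings = list(dx = canon_num(s$dx), x_max = canon_num(s$x_max),
                       slack_mode = s$slack_mode,
                       post_loop_critical_strain = canon_num(s$post_loop_critical_strain),
                       seed = as.integer(s$seed)))
}

#' Stable fingerprint of a configuration
#'
#' A short hex hash of the canonicalized configuration; it changes iff any
#' field changes. Recorded in simulation outputs so every curve is traceable
#' to its exact configuration.
#'
#' @param config A `thread_config`.
#' @return An 8-character hex string.
#' @export
config_fingerprint <- function(config) {
  json <- jsonlite::toJSON(canonicalize_config(config), auto_unbox = TRUE,
                           digits = NA)
  h <- fnv1a32(as.character(json))
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Read / write thread configurations
#'
#' Configurations are stored as JSON (`.json`) or YAML (`.yml`/`.yaml`);
#' the format is chosen by file extension. `save_config()` followed by
#' `load_config()` reproduces an equivalent configuration (identical
#' fingerprint).
#'
#' @param path File path.
#' @param config A `thread_config`.
#' @return `load_config()`: a validated `thread_config`. `save_config()`:
#'   the path, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("unrecognised config extension (want .json, .yml or .yaml): ", path)
  if (is.null(raw$groups)) stop("config validation failed:\n  groups: missing")
  groups <- lapply(raw$groups, function(g) {
    if (!is.null(g$coupling))
      g$coupling$sources <- as.character(unlist(g$coupling$sources))
    g
  })
  thread_config(groups, raw$settings %||% list())
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "thread_config"))
  canon <- canonicalize_config(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(canon, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(canon, path)
  else stop("unrecognised config extension (want .json, .yml or .yaml): ", path)
  invisible(path)
}

## ---- expansion ------------------------------------------------------------

law_from_spec <- function(spec) {
  if (names(spec) == "linear") linear_law(spec$linear$E)
  else constitutive_law(stats::setNames(
    as.numeric(unlist(spec$poly)),
    sub("^c", "", names(spec$poly))))
}

#' Expand a configuration into a concrete bundle
#'
#' Instantiates every fibre of every group, sampling per-loop opening
#' thresholds, per-loop hidden lengths and (where distribution-valued)
#' per-element critical strains. Each sampled quantity of each element draws
#' from its own substream derived from `seed`, so the draws for one quantity
#' are unaffected by how many values another quantity consumes.
#' Deterministic given `(config, seed)`.
#'
#' @param config A `thread_config`.
#' @param seed Integer seed; defaults to `config$settings$seed`.
#' @return An [bundle()] object.
#' @export
build_bundle <- function(config, seed = NULL) {
  config <- validate_config(config)
  seed <- seed %||% config$settings$seed
  gnames <- vapply(config$groups, `[[`, "", "name")
  # coupling sources name groups; expand to the member element ids of the
  # sources that actually carry loops (a zero-loop source transmits nothing)
  members <- lapply(config$groups, function(g)
    if (!is.null(g$loops) && g$loops$count > 0)
      paste0(g$name, seq_len(g$count)) else character())
  names(members) <- gnames
  elements <- list()
  for (g in config$groups) {
    law <- law_from_spec(g$law)
    for (f in seq_len(g$count)) {
      id <- paste0(g$name, f)
      xc <- if (!is.null(g$critical_strain)) {
        d <- as_pm(g$critical_strain)
        if (d$halfwidth > 0)
          sample_pm(d, 1, substream_seed(seed, id, "critical_strain"))
        else d$mean
      } else NULL
      if (!is.null(g$loops) && g$loops$count > 0) {
        nl <- g$loops$count
        thr <- sample_pm(as_pm(g$loops$threshold), nl,
                         substream_seed(seed, id, "loop_thresholds"))
        hid <- sample_pm(as_pm(g$loops$hidden_length), nl,
                         substream_seed(seed, id, "hidden_lengths"))
        el <- looped_element(
          id, g$rel_diameter, law, thr, hid,
          post_loop_critical_strain = g$post_loop_critical_strain %||%
            xc %||% config$settings$post_loop_critical_strain)
      } else {
        el <- straight_element(
          id, g$rel_diameter, law,
          critical_strain = xc %||% config$settings$post_loop_critical_strain,
          coupling_source = if (!is.null(g$coupling)) {
            src <- unlist(members[as.character(g$coupling$sources)],
                          use.names = FALSE)
            if (length(src)) src else NULL
          },
          Cs = g$coupling$Cs %||% 1)
      }
      elements[[length(elements) + 1L]] <- el
    }
  }
  bundle(elements)
}

#' Simulate a thread configuration end to end
#'
#' Convenience wrapper: validates the configuration, builds the bundle with
#' `seed`, and runs [simulate_bundle()] with the configuration's solver
#' settings (any of which can be overridden).
#'
#' @param config A `thread_config`.
#' @param seed Integer seed (defaults to `config$settings$seed`).
#' @param dx,x_max Optional overrides of the configuration's settings.
#' @return An `fbm_sim` (see [simulate_bundle()]).
#' @export
simulate_thread <- function(config, seed = NULL, dx = NULL, x_max = NULL) {
  config <- validate_config(config)
  seed <- seed %||% config$settings$seed
  b <- build_bundle(config, seed)
  simulate_bundle(b,
                  x_max = x_max %||% config$settings$x_max,
                  dx = dx %||% config$settings$dx,
                  slack_mode = config$settings$slack_mode,
                  seed = seed, fingerprint = config_fingerprint(config))
}

## ---- dotted-path access (used by sweeps) ----------------------------------

resolve_path <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (!length(parts)) stop("empty parameter path")
  if (parts[1] == "settings") {
    if (length(parts) != 2 || !parts[2] %in% SETTINGS_KEYS)
      stop("unresolvable parameter path: ", path)
    return(list(where = "settings", key = parts[2]))
  }
  if (parts[1] == "groups") {
    gnames <- vapply(config$groups, `[[`, "", "name")
    gi <- match(parts[2], gnames)
    if (is.na(gi) || length(parts) < 3)
      stop("unresolvable parameter path: ", path)
    return(list(where = "group", index = gi, rest = parts[-(1:2)]))
  }
  stop("unresolvable parameter path: ", path)
}

#' Get or set a configuration value by dotted path
#'
#' Paths address `settings.<key>` or `groups.<group name>.<field>...`, e.g.
#' `"groups.uf.loops.count"` or `"groups.axial.coupling.Cs"`. Used by
#' [run_sweep()] to vary one parameter across simulations.
#'
#' @param config A `thread_config`.
#' @param path Dotted parameter path.
#' @param value Replacement value.
#' @return `get_config_value()`: the value. `set_config_value()`: the
#'   modified, re-validated config.
#' @export
get_config_value <- function(config, path) {
  loc <- resolve_path(config, path)
  if (loc$where == "settings") return(config$settings[[loc$key]])
  node <- config$groups[[loc$index]]
  for (k in loc$rest) {
    node <- node[[k]]
    if (is.null(node)) stop("unresolvable parameter path: ", path)
  }
  node
}

#' @rdname get_config_value
#' @export
set_config_value <- function(config, path, value) {
  loc <- resolve_path(config, path)
  if (loc$where == "settings") {
    config$settings[[loc$key]] <- value
  } else {
    invisible(get_config_value(config, path)) # errors if path absent
    config$groups[[loc$index]][[loc$rest]] <- value
  }
  validate_config(config)
  config
}
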