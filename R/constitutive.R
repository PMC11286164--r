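# Constitutive laws and the uniform "mean +/- halfwidth" distribution shared
# by all elements of a thread model.

#' Odd-polynomial stress-strain law
#'
#' A constitutive law of the form \eqn{\sigma(\epsilon) = \sum_i c_i
#' \epsilon^i} over odd powers \eqn{i}, with stress in GPa and dimensionless
#' strain. Odd polynomials through the origin with non-negative coefficients
#' cover both laws used for the default thread (linear fibres and the
#' strain-stiffening cubic axial law \eqn{\sigma = 0.1\epsilon + 5\epsilon^3})
#' and are guaranteed monotone non-decreasing on \eqn{\epsilon \ge 0}.
#'
#' @param coefficients Named numeric vector of non-negative coefficients; the
#'   names are the (odd, positive) powers, e.g. `c("1" = 0.1, "3" = 5)`.
#' @return An object of class `constitutive_law` with fields `coefficients`
#'   and `powers`.
#' @seealso [linear_law()], [cubic_law()], [eval_stress()]
#' @examples
#' law <- cubic_law(c1 = 0.1, c3 = 5)
#' eval_stress(law, 0.5) # 0.1 * 0.5 + 5 * 0.5^3
#' @export
constitutive_law <- function(coefficients) {
  if (length(coefficients) == 0 || is.null(names(coefficients)))
    stop("`coefficients` must be a named vector (names = polynomial powers)")
  powers <- suppressWarnings(as.numeric(names(coefficients)))
  if (anyNA(powers) || any(powers < 1) || any(powers %% 2 != 1))
    stop("polynomial powers must be odd positive integers (got: ",
         paste(names(coefficients), collapse = ", "), ")")
  if (any(coefficients < 0))
    stop("coefficients must be non-negative (monotone law)")
  structure(
    list(coefficients = unname(as.numeric(coefficients)), powers = powers),
    class = "constitutive_law"
  )
}

#' @rdname constitutive_law
#' @param E Young's modulus in GPa (slope of the linear law).
#' @export
linear_law <- function(E) constitutive_law(c("1" = E))

#' @rdname constitutive_law
#' @param c1,c3 Linear and cubic coefficients (GPa).
#' @export
cubic_law <- function(c1, c3) constitutive_law(c("1" = c1, "3" = c3))

#' @export
print.constitutive_law <- function(x, ...) {
  terms <- paste0(format(x$coefficients), "*eps^", x$powers)
  cat("<constitutive_law> sigma(eps) =", paste(terms, collapse = " + "),
      "[GPa]\n")
  invisible(x)
}

#' Evaluate a stress-strain law
#'
#' @param law A [constitutive_law()].
#' @param strain Numeric vector of non-negative dimensionless strains. A
#'   negative strain is an error: slack (negative effective elongation)
#'   carries zero force and must be clamped by the caller before asking the
#'   material for a stress.
#' @return Stress in GPa, vectorized over `strain`.
#' @export
eval_stress <- function(law, strain) {
  stopifnot(inherits(law, "constitutive_law"))
  if (any(strain < 0))
    stop("negative strain: a slack element carries zero force; clamp before calling eval_stress()")
  sigma <- numeric(length(strain))
  for (j in seq_along(law$powers))
    sigma <- sigma + law$coefficients[j] * strain^law$powers[j]
  sigma
}

#' Uniform "mean plus/minus halfwidth" distribution
#'
#' The thread model draws every stochastic critical quantity (loop opening
#' strains, loop hidden lengths, optional element critical strains) from a
#' uniform distribution written as `mean +/- halfwidth`, i.e. uniform on
#' `[mean - halfwidth, mean + halfwidth]`.
#'
#' @param mean Dimensionless mean.
#' @param halfwidth Dimensionless halfwidth (`>= 0`); `mean - halfwidth` must
#'   be non-negative since all modelled quantities are strain-like.
#' @return An object of class `uniform_pm`.
#' @examples
#' sample_pm(uniform_pm(0.150, 0.145), 5, seed = 1)
#' @export
uniform_pm <- function(mean, halfwidth = 0) {
  if (halfwidth < 0) stop("halfwidth must be >= 0")
  if (mean - halfwidth < 0)
    stop("support must be non-negative: mean - halfwidth = ", mean - halfwidth)
  structure(list(mean = mean, halfwidth = halfwidth), class = "uniform_pm")
}

#' @export
print.uniform_pm <- function(x, ...) {
  cat("<uniform_pm>", x$mean, "+/-", x$halfwidth, "\n")
  invisible(x)
}

#' Draw reproducible samples from a `uniform_pm` distribution
#'
#' Identical `(dist, n, seed)` triples give bit-identical samples; the
#' caller's RNG state is left untouched.
#'
#' @param dist A [uniform_pm()].
#' @param n Number of draws (`>= 1`).
#' @param seed Integer seed.
#' @return Numeric vector of length `n` in
#'   `[mean - halfwidth, mean + halfwidth]`.
#' @export
sample_pm <- function(dist, n, seed) {
  stopifnot(inherits(dist, "uniform_pm"))
  if (n < 1) stop("n must be >= 1 (got ", n, ")")
  with_seed(seed, stats::runif(n, dist$mean - dist$halfwidth,
                               dist$mean + dist$halfwidth))
}
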