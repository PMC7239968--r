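## Dispersal-kernel registry: the 11 named distance-decay profiles r(d)
## that drive the zero-inflated model mean.  Normalising constants are
## absorbed into the coefficient Q, so each kernel is a bare distance
## profile with a scale `a` (> 0, metres) and, where applicable, a shape
## `b` (> 0).

# guard for kernels with negative powers of d
.d_floor <- 1e-6

kernel_registry <- list(
  "log-sech" = list(
    n_params = 2L,
    fn = function(d, a, b) 1 / ((d / a)^b + (d / a)^(-b))
  ),
  "exponential-power" = list(
    n_params = 2L,
    fn = function(d, a, b) exp(-(d / a)^b)
  ),
  "power-law" = list(
    n_params = 2L,
    fn = function(d, a, b) (1 + d / a)^(-b)
  ),
  "logistic" = list(
    n_params = 2L,
    fn = function(d, a, b) 1 / (1 + (d / a)^b)
  ),
  "2Dt" = list(
    n_params = 2L,
    fn = function(d, a, b) (1 + d^2 / a^2)^(-b)
  ),
  "gamma" = list(
    n_params = 2L,
    fn = function(d, a, b) (d / a)^(b - 1) * exp(-d / a)
  ),
  "WALD" = list(
    n_params = 2L,
    fn = function(d, a, b) d^(-1.5) * exp(-b * (d - a)^2 / (2 * a^2 * d))
  ),
  "Weibull" = list(
    n_params = 2L,
    fn = function(d, a, b) exp(-(d / a)^b) * (d / a)^(b - 1)
  ),
  "negative-exponential" = list(
    n_params = 1L,
    fn = function(d, a, b) exp(-d / a)
  ),
  "log-normal" = list(
    n_params = 2L,
    fn = function(d, a, b) exp(-log(d / a)^2 / (2 * b^2))
  ),
  "Gaussian" = list(
    n_params = 1L,
    fn = function(d, a, b) exp(-(d / a)^2)
  )
)

#' Normalise a kernel name
#'
#' Kernel names are matched case-insensitively and tolerate spaces or
#' underscores in place of hyphens (`"Exponential power"`,
#' `"exponential-power"` and `"exponential_power"` are equivalent; plain
#' `"exponential"` resolves to the negative-exponential kernel).
#'
#' @param name Character scalar.
#' @return The canonical registry name.
#' @export
match_kernel <- function(name) {
  key <- gsub("[ _]", "-", tolower(trimws(name)))
  canon <- names(kernel_registry)
  hit <- match(key, tolower(canon))
  if (is.na(hit) && key %in% c("exponential", "neg.-exponential",
                               "neg-exponential", "exp"))
    hit <- match("negative-exponential", canon)
  if (is.na(hit))
    stop("unknown dispersal kernel: '", name, "'. Known kernels: ",
         paste(canon, collapse = ", "), call. = FALSE)
  canon[hit]
}

#' List the registered dispersal kernels
#'
#' @return A data.frame with columns `name` and `n_params` (1 for the
#'   single-scale negative-exponential and Gaussian kernels, 2 otherwise).
#' @examples
#' list_kernels()
#' @export
list_kernels <- function() {
  data.frame(name = names(kernel_registry),
             n_params = vapply(kernel_registry, `[[`, integer(1), "n_params"),
             row.names = NULL)
}

#' Evaluate a dispersal kernel
#'
#' Computes the distance profile `r(d)` of a named kernel.  All kernels
#' are non-negative and decay to zero at large distance; distances are
#' floored at `1e-6` m to guard the kernels with negative powers of `d`.
#'
#' @param name Kernel name (see [list_kernels()]; matching is tolerant,
#'   see [match_kernel()]).
#' @param d Numeric vector of distances in metres (> 0).
#' @param a Scale parameter, metres (> 0).
#' @param b Shape parameter (> 0); ignored by one-parameter kernels.
#' @return Numeric vector `r(d)`, same length as `d`.
#' @examples
#' evaluate_kernel("Gaussian", d = 2, a = 2)  # exp(-1)
#' @export
evaluate_kernel <- function(name, d, a, b = NULL) {
  name <- match_kernel(name)
  entry <- kernel_registry[[name]]
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("kernel scale 'a' must be a positive number", call. = FALSE)
  if (entry$n_params == 2L) {
    if (is.null(b) || !is.finite(b) || b <= 0)
      stop("kernel '", name, "' requires a positive shape 'b'", call. = FALSE)
  } else b <- 1
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  d <- pmax(d, .d_floor)
  r <- entry$fn(d, a, b)
  pmax(r, 0)
}
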