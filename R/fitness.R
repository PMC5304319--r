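#' Construct a fitness vector
#'
#' A fitness vector holds one strictly positive, finite fitness value
#' \eqn{\phi_j} per node, together with the derived unfitness
#' \eqn{U_j = 1/\phi_j}.  Unfitness is the quantity whose maximum expected
#' exposure the solvers minimise; strict positivity of \eqn{\phi} is what
#' guarantees that every node receives positive attachment probability at
#' the optimum, so values at or below `floor` are rejected rather than
#' clamped.
#'
#' @param phi numeric vector of strictly positive, finite fitness values.
#' @param node_ids optional character vector of unique node identifiers;
#'   defaults to `"n1", "n2", ...`.
#' @param floor smallest admissible fitness (default `1e-12`); values at or
#'   below it are a validation error.
#' @return An object of class `fitness_vector`: a list with elements
#'   `node_id`, `phi`, and `unfitness`.
#' @examples
#' fv <- fitness_vector(c(1, 2, 4))
#' fv$unfitness   # 1.00 0.50 0.25
#' @export
fitness_vector <- function(phi, node_ids = NULL, floor = 1e-12) {
  phi <- as.numeric(phi)
  if (length(phi) == 0L) stop_validation("fitness vector must be non-empty")
  if (anyNA(phi) || any(!is.finite(phi)))
    stop_validation("fitness values must be finite and non-missing")
  if (any(phi <= floor))
    stop_validation("fitness values must be strictly positive (> ", floor,
                    "); offending index: ", which(phi <= floor)[1])
  if (is.null(node_ids)) node_ids <- paste0("n", seq_along(phi))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != length(phi))
    stop_validation("node_ids and phi lengths differ")
  if (anyDuplicated(node_ids))
    stop_validation("node_ids must be unique; duplicated: ",
                    node_ids[anyDuplicated(node_ids)])
  structure(list(node_id = node_ids, phi = phi, unfitness = 1 / phi),
            class = "fitness_vector")
}

#' @export
length.fitness_vector <- function(x) length(x$phi)

#' @export
print.fitness_vector <- function(x, ...) {
  cat(sprintf("<fitness_vector> %d nodes, phi in [%.4g, %.4g]\n",
              length(x), min(x$phi), max(x$phi)))
  invisible(x)
}

#' @export
as.data.frame.fitness_vector <- function(x, ...) {
  data.frame(node_id = x$node_id, fitness = x$phi,
             unfitness = x$unfitness, stringsAsFactors = FALSE)
}

#' Specify a lognormal fitness distribution
#'
#' `scale_mu` and `shape_sigma` are the mean and standard deviation of
#' \eqn{\log\phi} (the usual scale/shape parameterisation of the lognormal).
#'
#' @param n number of nodes to draw (positive integer).
#' @param scale_mu scale parameter (mean of log-fitness), default 0.
#' @param shape_sigma shape parameter (sd of log-fitness), must be > 0.
#' @param seed optional integer seed making the draw reproducible.
#' @return An object of class `lognormal_spec`.
#' @examples
#' sp <- lognormal_spec(n = 12, scale_mu = 0, shape_sigma = 1, seed = 7)
#' @export
lognormal_spec <- function(n, scale_mu = 0, shape_sigma = 1, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_validation("n must be a positive integer")
  if (!is.numeric(scale_mu) || length(scale_mu) != 1L || !is.finite(scale_mu))
    stop_validation("scale_mu must be a finite number")
  if (!is.numeric(shape_sigma) || length(shape_sigma) != 1L ||
      !is.finite(shape_sigma) || shape_sigma <= 0)
    stop_validation("shape_sigma must be > 0")
  structure(list(n = n, scale_mu = scale_mu, shape_sigma = shape_sigma,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "lognormal_spec")
}

#' Sample node fitness from a lognormal distribution
#'
#' @param spec a [lognormal_spec()].
#' @param node_ids optional node identifiers passed to [fitness_vector()].
#' @return A [fitness_vector()] of `spec$n` draws; identical across calls
#'   when `spec$seed` is set.
#' @examples
#' fv <- sample_lognormal_fitness(lognormal_spec(5, 0, 1, seed = 1))
#' @export
sample_lognormal_fitness <- function(spec, node_ids = NULL) {
  if (!inherits(spec, "lognormal_spec"))
    stop_validation("spec must be a lognormal_spec")
  phi <- with_seed(spec$seed,
                   rlnorm(spec$n, meanlog = spec$scale_mu, sdlog = spec$shape_sigma))
  fitness_vector(phi, node_ids = node_ids)
}

#' Compose fitness as a product of node attributes
#'
#' Fitness is modelled as the product of many positive attributes of a node
#' (quality, price, reliability, ...).  When the attributes are numerous and
#' independent, the resulting fitness is approximately lognormal, which is
#' why the samplers and fixtures default to lognormal fitness.
#'
#' @param attributes a numeric matrix (nodes x attributes) or a list with one
#'   numeric vector of attributes per node; all values must be > 0.
#' @param node_ids optional node identifiers.
#' @return A [fitness_vector()] with `phi[j] = prod(attributes[j, ])`.
#' @examples
#' compose_fitness(rbind(c(2, 3), c(1, 1)))$phi   # 6 1
#' @export
compose_fitness <- function(attributes, node_ids = NULL) {
  if (is.matrix(attributes)) attributes <- asplit(attributes, 1)
  if (!is.list(attributes)) stop_validation("attributes must be a matrix or list")
  phi <- vapply(attributes, function(a) {
    a <- as.numeric(a)
    if (length(a) == 0L || anyNA(a) || any(!is.finite(a)) || any(a <= 0))
      stop_validation("all attribute values must be finite and > 0")
    prod(a)
  }, numeric(1))
  fitness_vector(phi, node_ids = node_ids)
}

#' Node unfitness
#'
#' @param fv a [fitness_vector()].
#' @return Numeric vector of unfitness values \eqn{U_j = 1/\phi_j}.
#' @export
unfitness <- function(fv) {
  assert_fitness_vector(fv)
  fv$unfitness
}

assert_fitness_vector <- function(fv) {
  if (!inherits(fv, "fitness_vector"))
    stop_validation("expected a fitness_vector")
  invisible(fv)
}
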