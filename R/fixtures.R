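#' Reference homogeneous fixture: 12 lognormal(0, 1) nodes
#'
#' A small homogeneous node set matching the package's worked example: 12
#' fitness values drawn from a lognormal with scale (mu of log-fitness) 0
#' and shape (sd of log-fitness) 1.
#'
#' @param seed integer seed (required: fixtures are meant to be
#'   reproducible).
#' @param n number of nodes (default 12).
#' @param scale_mu,shape_sigma lognormal parameters (defaults 0 and 1).
#' @return A [fitness_vector()].
#' @export
fixture_homogeneous <- function(seed, n = 12L, scale_mu = 0, shape_sigma = 1) {
  sample_lognormal_fitness(
    lognormal_spec(n, scale_mu, shape_sigma, seed = seed))
}

#' Reference tiered fixture: a four-tier supply chain
#'
#' Four tiers (suppliers, manufacturers, distributors, retailers) of equal
#' size with lognormal fitness of shape 3, 1, 1, 0.1 respectively and zero
#' scale parameter: oligopoly conditions diminishing downstream, with
#' near-perfect competition among retailers.  Adjacency is complete between
#' consecutive tiers.  `nodes_per_tier = 25` gives the 100-node system;
#' `nodes_per_tier = 3` the 12-node one.
#'
#' @param seed integer seed.
#' @param nodes_per_tier size of each tier (default 25).
#' @param scale_mu lognormal scale parameter shared by all tiers.
#' @param shape_sigma per-tier shape parameters, one per tier.
#' @return A [tiered_system()].
#' @export
fixture_tiered <- function(seed, nodes_per_tier = 25L, scale_mu = 0,
                           shape_sigma = c(3, 1, 1, 0.1)) {
  tier_names <- if (length(shape_sigma) == 4L)
    c("supplier", "manufacturer", "distributor", "retailer")
  else paste0("tier", seq_along(shape_sigma))
  tiers <- lapply(seq_along(shape_sigma), function(k) {
    sample_lognormal_fitness(
      lognormal_spec(nodes_per_tier, scale_mu, shape_sigma[k],
                     seed = derive_seed(seed, k)),
      node_ids = paste0(substr(tier_names[k], 1, 1), k, "_", seq_len(nodes_per_tier)))
  })
  tiered_system(tiers, tier_names = tier_names)
}
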