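# Plain-TSV interfaces.  Numbers are serialised with 17 significant digits
# so a write/read round trip is exact in double precision.

fmt17 <- function(x) sprintf("%.17g", x)

#' Read a fitness table
#'
#' Two dialects are accepted, distinguished by the header line:
#' `node_id<TAB>fitness` yields a [fitness_vector()];
#' `node_id<TAB>tier<TAB>fitness` yields a [tiered_system()] whose tiers
#' are ordered by first appearance in the file.  Malformed rows,
#' non-positive fitness, and duplicate ids are rejected with the offending
#' line number.
#'
#' @param path path to a UTF-8 TSV file with a header line.
#' @param adjacency optional path to an adjacency TSV with header
#'   `tier_index<TAB>upstream_node<TAB>downstream_node` listing the allowed
#'   links between tier `tier_index` and tier `tier_index + 1` (tiered
#'   dialect only); omitted pairs of tiers remain completely connected only
#'   if no row mentions them, otherwise exactly the listed links are kept.
#' @return A `fitness_vector` or `tiered_system`.
#' @examples
#' ts <- read_fitness_tsv(system.file("extdata", "supply_chain12_synthetic.tsv",
#'                                    package = "minmaxfit"))
#' tier_minmax_values(ts)
#' @export
read_fitness_tsv <- function(path, adjacency = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop_validation(path, ": no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  tiered <- identical(header, c("node_id", "tier", "fitness"))
  if (!tiered && !identical(header, c("node_id", "fitness")))
    stop_validation(path, " line 1: header must be 'node_id<TAB>fitness' or ",
                    "'node_id<TAB>tier<TAB>fitness'")
  want <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- character(0); tiers <- character(0); fit <- numeric(0)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    line <- i + 1L
    if (length(r) != want)
      stop_validation(path, " line ", line, ": expected ", want,
                      " tab-separated fields, found ", length(r))
    f <- suppressWarnings(as.numeric(r[[want]]))
    if (is.na(f)) stop_validation(path, " line ", line, ": fitness '",
                                  r[[want]], "' is not a number")
    if (!is.finite(f) || f <= 0)
      stop_validation(path, " line ", line, ": fitness must be > 0 and finite")
    ids <- c(ids, r[[1]]); fit <- c(fit, f)
    if (tiered) tiers <- c(tiers, r[[2]])
  }
  if (anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1]
    stop_validation(path, " line ", d + 1L, ": duplicate node_id '", ids[d], "'")
  }
  if (!tiered) return(fitness_vector(fit, node_ids = ids))
  tier_levels <- unique(tiers)
  if (length(tier_levels) < 2L)
    stop_validation(path, ": a tiered file needs at least two distinct tiers")
  fvs <- lapply(tier_levels, function(tl) {
    sel <- tiers == tl
    fitness_vector(fit[sel], node_ids = ids[sel])
  })
  adj <- NULL
  if (!is.null(adjacency))
    adj <- read_adjacency_tsv(adjacency, fvs, tier_levels)
  tiered_system(fvs, adjacency = adj, tier_names = tier_levels)
}

read_adjacency_tsv <- function(path, fvs, tier_levels) {
  df <- read.delim(path, colClasses = c("integer", "character", "character"))
  if (!identical(names(df), c("tier_index", "upstream_node", "downstream_node")))
    stop_validation(path, ": header must be ",
                    "'tier_index<TAB>upstream_node<TAB>downstream_node'")
  K <- length(fvs)
  adj <- vector("list", K - 1L)
  for (k in sort(unique(df$tier_index))) {
    if (k < 1L || k >= K)
      stop_validation(path, ": tier_index ", k, " out of range 1..", K - 1L)
    sub <- df[df$tier_index == k, ]
    up <- match(sub$upstream_node, fvs[[k]]$node_id)
    dn <- match(sub$downstream_node, fvs[[k + 1L]]$node_id)
    if (anyNA(up) || anyNA(dn))
      stop_validation(path, ": unknown node id in adjacency for tier pair ", k)
    M <- matrix(0L, length(fvs[[k]]$node_id), length(fvs[[k + 1L]]$node_id))
    M[cbind(up, dn)] <- 1L
    adj[[k]] <- M
  }
  adj
}

#' Write a fitness table
#'
#' @param x a [fitness_vector()] or [tiered_system()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fitness_tsv <- function(x, path) {
  if (inherits(x, "fitness_vector")) {
    lines <- c("node_id\tfitness",
               paste(x$node_id, fmt17(x$phi), sep = "\t"))
  } else if (inherits(x, "tiered_system")) {
    lines <- "node_id\ttier\tfitness"
    for (k in seq_along(x$tiers)) {
      tk <- x$tiers[[k]]
      lines <- c(lines, paste(tk$node_id, x$tier_names[k], fmt17(tk$phi),
                              sep = "\t"))
    }
  } else stop_validation("x must be a fitness_vector or tiered_system")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a solver result table
#'
#' Columns: `node_id`, `p`, `q`, `p_closed_form` (plus a leading `tier`
#' column for tiered results).
#'
#' @param solution a `minmax_solution`, or a list of them (one per tier, as
#'   returned in `solve_lp_p2(...)$solutions` or `run_a1(...)$solutions`).
#' @param fv the [fitness_vector()] or [tiered_system()] that was solved.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(solution, fv, path) {
  if (inherits(solution, "minmax_solution")) {
    pc <- closed_form_attachment(fv)
    lines <- c("node_id\tp\tq\tp_closed_form",
               paste(solution$node_id, fmt17(solution$p), fmt17(solution$q),
                     fmt17(pc), sep = "\t"))
  } else {
    stopifnot(inherits(fv, "tiered_system"), length(solution) == length(fv$tiers))
    lines <- "tier\tnode_id\tp\tq\tp_closed_form"
    for (k in seq_along(solution)) {
      pc <- closed_form_attachment(fv$tiers[[k]])
      sk <- solution[[k]]
      lines <- c(lines, paste(fv$tier_names[k], sk$node_id, fmt17(sk$p),
                              fmt17(sk$q), fmt17(pc), sep = "\t"))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a convergence trace
#'
#' @param state a `game_state` or `tiered_game_state` returned by
#'   [run_a0()]/[run_a1()] (must carry a `trace`).
#' @param path output path; columns `iteration`, `upper_bound`,
#'   `lower_bound` (tiered traces add a `tier` column).
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(state, path) {
  tr <- state$trace
  if (is.null(tr)) stop_validation("state carries no trace")
  if (is.data.frame(tr)) {
    lines <- c("iteration\tupper_bound\tlower_bound",
               paste(fmt17(tr$iteration), fmt17(tr$upper_bound),
                     fmt17(tr$lower_bound), sep = "\t"))
  } else {
    lines <- "tier\titeration\tupper_bound\tlower_bound"
    for (k in seq_along(tr))
      lines <- c(lines, paste(k, fmt17(tr[[k]]$iteration),
                              fmt17(tr[[k]]$upper_bound),
                              fmt17(tr[[k]]$lower_bound), sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a grown network as edge-list and node-table TSVs
#'
#' @param net a `grown_network`.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`
#'   (`u<TAB>v`) and `<prefix>_nodes.tsv`
#'   (`node_id`, `fitness`, `arrival_order`, `degree`).
#' @return The two paths, invisibly.
#' @export
write_network_tsv <- function(net, prefix) {
  if (!inherits(net, "grown_network")) stop_validation("expected a grown_network")
  ep <- paste0(prefix, "_edges.tsv")
  np <- paste0(prefix, "_nodes.tsv")
  writeLines(c("u\tv", paste(net$edges[, 1], net$edges[, 2], sep = "\t")), ep)
  writeLines(c("node_id\tfitness\tarrival_order\tdegree",
               paste(seq_along(net$degree), fmt17(net$fitness),
                     net$arrival_order, net$degree, sep = "\t")), np)
  invisible(c(ep, np))
}
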