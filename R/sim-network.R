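# Synthetic network inputs: a degree-heterogeneous PPI stand-in, a cohesive
# disease module, and compound target sets at controlled distance from it.

#' Simulate a degree-heterogeneous protein-protein interaction network
#'
#' Grows an undirected simple graph by preferential attachment: the first
#' `edges_per_node` vertices start unconnected, and each subsequent vertex
#' attaches to `edges_per_node` distinct existing vertices sampled with
#' probability proportional to their current degree. The result is connected,
#' has a heavy-tailed degree distribution, and contains exactly
#' `edges_per_node * (n_nodes - edges_per_node)` edges. Vertices are named
#' `P0001`, `P0002`, ... in order of addition.
#'
#' The default attachment count of 2 keeps the typical shortest-path length
#' above 2 hops at desk scale (a few thousand nodes), so set-to-set
#' proximity retains dynamic range instead of saturating as it would on a
#' dense small graph.
#'
#' Real interactomes are far richer than a preferential-attachment graph; this
#' generator reproduces only the property the proximity null is sensitive to —
#' strong degree heterogeneity with a connected core.
#'
#' @param n_nodes Number of proteins (>= 10).
#' @param edges_per_node Attachment count m (< `n_nodes`).
#' @param seed Integer seed; the construction is a pure function of the
#'   arguments including the seed.
#' @return An undirected simple igraph with named vertices.
#' @examples
#' net <- gen_ppi_network(200, 3, seed = 1)
#' igraph::ecount(net)  # 3 * (200 - 3)
#' @export
gen_ppi_network <- function(n_nodes, edges_per_node = 2L, seed = 1L) {
  n <- check_count(n_nodes, "n_nodes", min = 10L)
  m <- check_count(edges_per_node, "edges_per_node", min = 1L)
  if (m >= n) abort_arg("`edges_per_node` must be smaller than `n_nodes`")

  edges <- matrix(0L, nrow = m * (n - m), ncol = 2L)
  with_seed(seed, {
    # endpoint multiset; sampling uniformly from it is degree-proportional
    repeated <- integer(2L * m * (n - m))
    n_rep <- 0L
    targets <- seq_len(m)
    row <- 0L
    for (v in (m + 1L):n) {
      edges[row + seq_len(m), 1L] <- v
      edges[row + seq_len(m), 2L] <- targets
      row <- row + m
      repeated[n_rep + seq_len(2L * m)] <- c(targets, rep.int(v, m))
      n_rep <- n_rep + 2L * m
      pool <- repeated[seq_len(n_rep)]
      uniq <- unique(pool[sample.int(n_rep, n_rep)])
      while (length(uniq) < m) {  # cannot happen once n_rep >= m distinct ids
        uniq <- unique(c(uniq, pool[sample.int(n_rep, 1L)]))
      }
      targets <- uniq[seq_len(m)]
    }
  })
  ids <- sprintf("P%04d", seq_len(n))
  g <- igraph::graph_from_edgelist(
    cbind(ids[edges[, 1L]], ids[edges[, 2L]]), directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))  # defensive; normally 0
  g
}

#' Simulate a cohesive disease module on a network
#'
#' Picks a random start vertex and grows the module by breadth-first
#' expansion, so the induced subgraph is connected by construction (the
#' analogue of a disease-associated seed-protein set occupying a neighborhood
#' of the interactome).
#'
#' @param net An igraph network.
#' @param size Module size (<= vertex count).
#' @param seed Integer seed.
#' @return Character vector of `size` vertex names.
#' @export
gen_disease_module <- function(net, size, seed = 1L) {
  size <- check_count(size, "size", min = 1L)
  n <- igraph::vcount(net)
  if (size > n) abort_arg("`size` exceeds the number of nodes in the network")
  with_seed(seed, {
    start <- sample.int(n, 1L)
    ord <- igraph::bfs(net, root = start, unreachable = FALSE,
                       order = TRUE)$order
    ord <- ord[!is.na(ord)]
    members <- igraph::V(net)$name[ord]
    if (length(members) < size) {
      # start component exhausted: pad from the remaining vertices
      rest <- setdiff(igraph::V(net)$name, members)
      members <- c(members, sample(rest, size - length(members)))
    }
    members[seq_len(size)]
  })
}

#' Simulate a compound screen with planted proximal compounds
#'
#' Generates `n_compounds` compound target sets on `net`. The first
#' `n_planted` compounds ("planted") draw their targets from within graph
#' distance <= 1 of the disease module, so their observed proximity to the
#' module is small by construction. The remaining ("background") compounds
#' draw targets degree-matched to the planted target pool but from outside
#' that pool, so that planted and background compounds differ in placement
#' but not in degree profile. Excluding the module neighborhood from the
#' background draws keeps the ground-truth labels honest: a benchmark
#' "negative" must not be an accidental positive, or recovery rates measure
#' label noise instead of the method.
#'
#' @param net An igraph network.
#' @param module Character vector of module vertex names (non-empty).
#' @param n_compounds Number of compounds.
#' @param targets_per_compound Targets per compound.
#' @param n_planted Number of planted compounds (<= `n_compounds`).
#' @param seed Integer seed.
#' @param min_bin_size Degree-bin size used for degree-matching the
#'   background draws (see [degree_bins()]).
#' @return A list with `target_sets` (named list of character vectors, names
#'   `CPD001`, ...) and `truth` (data.frame with `compound_id` and logical
#'   `planted`).
#' @export
gen_compound_screen <- function(net, module, n_compounds = 50L,
                                targets_per_compound = 10L, n_planted = 1L,
                                seed = 1L, min_bin_size = 100L) {
  if (length(module) == 0L) abort_arg("`module` must be non-empty")
  n_compounds <- check_count(n_compounds, "n_compounds", min = 1L)
  k <- check_count(targets_per_compound, "targets_per_compound", min = 1L)
  n_planted <- check_count(n_planted, "n_planted", min = 0L)
  if (n_planted > n_compounds) abort_arg("`n_planted` exceeds `n_compounds`")
  if (k > igraph::vcount(net)) {
    abort_arg("`targets_per_compound` exceeds the number of nodes")
  }
  module <- intersect(module, igraph::V(net)$name)
  if (length(module) == 0L) abort_arg("`module` has no nodes on the network")

  nbrs <- igraph::ego(net, order = 1L, nodes = module)
  pool <- unique(unlist(lapply(nbrs, function(v) v$name), use.names = FALSE))
  if (length(pool) < k) pool <- igraph::V(net)$name  # degenerate tiny nets
  bins <- degree_bins(net, min_bin_size = min_bin_size, quiet = TRUE)
  # per-bin members outside the module neighborhood, for background draws
  vs <- igraph::V(net)$name
  pool_idx <- match(pool, vs)
  outside <- lapply(bins$members, function(m) setdiff(m, pool_idx))

  ids <- sprintf("CPD%03d", seq_len(n_compounds))
  target_sets <- with_seed(seed, {
    lapply(seq_len(n_compounds), function(i) {
      template <- sample(pool, k)
      if (i <= n_planted) return(template)
      cnt <- tabulate(bins$bin_of[match(template, vs)],
                      nbins = length(bins$members))
      picked <- integer(0)
      for (b in which(cnt > 0L)) {
        mem <- outside[[b]]
        if (length(mem) < cnt[b]) mem <- bins$members[[b]]  # tiny-bin fallback
        picked <- c(picked,
                    if (cnt[b] >= length(mem)) mem
                    else mem[sample.int(length(mem), cnt[b])])
      }
      vs[picked]
    })
  })
  names(target_sets) <- ids
  list(target_sets = target_sets,
       truth = data.frame(compound_id = ids,
                          planted = seq_len(n_compounds) <= n_planted,
                          stringsAsFactors = FALSE))
}
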