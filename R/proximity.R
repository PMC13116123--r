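# Closest-distance network proximity between a compound's target set T and a
# disease module S, with a degree-preserving permutation null:
#
#   d(S,T) = 1/(|S|+|T|) * ( sum_{t in T} min_{s in S} d(s,t)
#                          + sum_{s in S} min_{t in T} d(s,t) )
#   Z      = (d(S,T) - mu) / sigma
#
# where d(s,t) is the unweighted shortest-path length and (mu, sigma) are the
# mean and s.d. of d over permutations in which the node sets are replaced by
# degree-matched random sets. A more negative Z means the targets sit closer
# to the module than chance, given their degrees.

#' Shortest-path distances between two node sets
#'
#' Unweighted hop-count distances computed by breadth-first search from the
#' smaller of the two sets. Nodes absent from the network are dropped and
#' counted, not treated as an error.
#'
#' @param net An igraph network.
#' @param sources,targets Character vectors of vertex names.
#' @return A numeric matrix (rows = sources, cols = targets); unreachable
#'   pairs are `Inf`. Attributes `n_dropped_sources` / `n_dropped_targets`
#'   count nodes not present in the network.
#' @export
shortest_distances <- function(net, sources, targets) {
  vs <- igraph::V(net)$name
  s <- intersect(unique(sources), vs)
  t <- intersect(unique(targets), vs)
  drop_s <- length(unique(sources)) - length(s)
  drop_t <- length(unique(targets)) - length(t)
  if (length(s) == 0L || length(t) == 0L) {
    D <- matrix(numeric(0), nrow = length(s), ncol = length(t),
                dimnames = list(s, t))
  } else if (length(s) <= length(t)) {
    D <- igraph::distances(net, v = s, to = t, algorithm = "unweighted")
  } else {
    D <- t(igraph::distances(net, v = t, to = s, algorithm = "unweighted"))
    dimnames(D) <- list(s, t)
  }
  structure(D, n_dropped_sources = drop_s, n_dropped_targets = drop_t)
}

# Row-wise minima without `apply` overhead (hot path of the permutation loop).
row_mins <- function(D) {
  m <- D[, 1L]
  for (j in seq_len(ncol(D))[-1L]) m <- pmin(m, D[, j])
  m
}

# Core of the proximity statistic, on a precomputed |S| x |T| distance matrix.
# Members with no finite distance to the other set are dropped and counted;
# the denominator shrinks accordingly.
closest_prox_from_matrix <- function(D) {
  if (nrow(D) == 0L || ncol(D) == 0L) {
    return(list(d = NA_real_, n_dropped_S = nrow(D), n_dropped_T = ncol(D),
                reason = "empty set after network intersection"))
  }
  min_t <- row_mins(D)         # per module member, nearest target
  min_s <- row_mins(t(D))      # per target, nearest module member
  keep_s <- is.finite(min_t)
  keep_t <- is.finite(min_s)
  denom <- sum(keep_s) + sum(keep_t)
  if (denom == 0L) {
    return(list(d = NA_real_, n_dropped_S = sum(!keep_s),
                n_dropped_T = sum(!keep_t),
                reason = "no finite distances between the sets"))
  }
  list(d = (sum(min_t[keep_s]) + sum(min_s[keep_t])) / denom,
       n_dropped_S = sum(!keep_s), n_dropped_T = sum(!keep_t), reason = NA_character_)
}

#' Closest-distance proximity between a disease module and a target set
#'
#' Computes the symmetric closest-distance average between node sets `S` and
#' `T` on `net` (see the package vignette for the formula). The value is 0
#' exactly when the two sets, after intersection with the network, are
#' identical. Unreachable members are dropped and counted via attributes
#' `n_dropped_S` / `n_dropped_T`; an invalid computation (a set empty after
#' pruning) returns `NA` with attribute `reason`.
#'
#' @param net An igraph network.
#' @param S Character vector: disease-module node names.
#' @param T Character vector: compound target node names.
#' @return Numeric proximity (>= 0), with drop-count attributes.
#' @examples
#' g <- igraph::make_ring(5, circular = FALSE)
#' igraph::V(g)$name <- LETTERS[1:5]
#' closest_proximity(g, "A", "E")  # 4
#' @export
closest_proximity <- function(net, S, T) {
  D <- shortest_distances(net, S, T)
  res <- closest_prox_from_matrix(D)
  structure(res$d,
            n_dropped_S = res$n_dropped_S + attr(D, "n_dropped_sources"),
            n_dropped_T = res$n_dropped_T + attr(D, "n_dropped_targets"),
            reason = res$reason)
}

#' Partition network nodes into degree bins for degree-preserving sampling
#'
#' Nodes are sorted by degree and contiguous degree groups are merged upward
#' until every bin holds at least `min_bin_size` nodes (a trailing small bin
#' is merged into its predecessor). On graphs too small to support the
#' requested bin size, the size is reduced automatically with a warning.
#'
#' @param net An igraph network.
#' @param min_bin_size Minimum nodes per bin (default 100, the conventional
#'   choice for interactome-scale graphs).
#' @param quiet Suppress the small-graph warning.
#' @return An object of class `degree_bins`: list with `bin_of` (integer bin
#'   index per node, named) and `members` (list of integer vertex indices per
#'   bin).
#' @export
degree_bins <- function(net, min_bin_size = 100L, quiet = FALSE) {
  n <- igraph::vcount(net)
  min_bin_size <- check_count(min_bin_size, "min_bin_size", min = 1L)
  eff <- min(min_bin_size, max(1L, n %/% 4L))
  if (eff < min_bin_size && !quiet) {
    warning(sprintf("graph has only %d nodes; min_bin_size reduced %d -> %d",
                    n, min_bin_size, eff), call. = FALSE)
  }
  deg <- igraph::degree(net)
  groups <- split(seq_len(n), deg)            # ascending degree
  bins <- list()
  cur <- integer(0)
  for (g in groups) {
    cur <- c(cur, g)
    if (length(cur) >= eff) {
      bins[[length(bins) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur)) {
    if (length(bins)) bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    else bins[[1L]] <- cur
  }
  bin_of <- integer(n)
  for (b in seq_along(bins)) bin_of[bins[[b]]] <- b
  names(bin_of) <- igraph::V(net)$name
  structure(list(bin_of = bin_of, members = bins), class = "degree_bins")
}

#' Draw a degree-matched random node set
#'
#' Returns `length(template)` distinct nodes: for each template node, one
#' node sampled uniformly without replacement from that node's degree bin.
#' The draw may overlap the template. This is the permutation scheme behind
#' the proximity null: it preserves the degree profile of the set, so hub
#' bias cannot masquerade as proximity.
#'
#' @param net An igraph network.
#' @param template Character vector of vertex names to match.
#' @param bins Optional precomputed [degree_bins()] object.
#' @param min_bin_size Used when `bins` is not supplied.
#' @return Character vector of sampled vertex names, same length as the
#'   template after intersection with the network. Sampling uses the current
#'   RNG stream; seed it with [with_seed] semantics at the call site (all
#'   package entry points do).
#' @export
degree_matched_sample <- function(net, template, bins = NULL,
                                  min_bin_size = 100L) {
  if (is.null(bins)) bins <- degree_bins(net, min_bin_size, quiet = TRUE)
  idx <- match(intersect(unique(template), names(bins$bin_of)), names(bins$bin_of))
  counts <- tabulate(bins$bin_of[idx], nbins = length(bins$members))
  out <- integer(0)
  for (b in which(counts > 0L)) {
    mem <- bins$members[[b]]
    need <- counts[b]
    if (need >= length(mem)) {
      picked <- mem  # without-replacement exhaustion
    } else {
      picked <- mem[sample.int(length(mem), need)]
    }
    out <- c(out, picked)
  }
  names(bins$bin_of)[out]
}

# Fast internal variant used inside the permutation loop: works on integer
# vertex indices and precomputed per-bin counts.
sample_bins_idx <- function(members, counts) {
  out <- vector("list", length(counts))
  for (b in which(counts > 0L)) {
    mem <- members[[b]]
    out[[b]] <- if (counts[b] >= length(mem)) mem
                else mem[sample.int(length(mem), counts[b])]
  }
  unlist(out, use.names = FALSE)
}

#' Proximity z-score under a degree-preserving permutation null
#'
#' Computes the observed closest-distance proximity `d(S,T)`, then builds its
#' null distribution from `n_perm` permutations in which the node sets are
#' replaced by degree-matched random sets (both sets by default, targets only
#' with `randomize = "targets"`). Reports the z-score, an add-one empirical
#' p-value `(1 + #{d_perm <= d_obs}) / (1 + n_perm)`, and the lower-tail
#' normal-approximation p-value.
#'
#' @param net An igraph network.
#' @param S Disease-module node names.
#' @param T Target-set node names.
#' @param n_perm Number of permutations (1000 by default; a warning is given
#'   below 100).
#' @param seed Integer seed; the result is a pure function of
#'   (network, S, T, n_perm, seed, options).
#' @param min_bin_size Degree-bin size (see [degree_bins()]).
#' @param randomize Replace `"both"` sets or only the `"targets"` under the
#'   null.
#' @param compound_id Optional label carried into the result.
#' @param distance_matrix Optional precomputed all-pairs distance matrix with
#'   vertex-name dimnames (as from `igraph::distances`); supply it when
#'   scoring many compounds on one network.
#' @param bins Optional precomputed [degree_bins()].
#' @return An object of class `proximity_result`: list with `compound_id`,
#'   `d_obs`, `mu`, `sigma`, `z`, `p_empirical`, `p_normal`, `n_perm`,
#'   `seed`, `n_dropped_S`, `n_dropped_T`, `valid`, `reason`. When `sigma`
#'   is 0 the z-score and normal p are `NaN` with a warning.
#' @export
proximity_z <- function(net, S, T, n_perm = 1000L, seed = 1L,
                        min_bin_size = 100L,
                        randomize = c("both", "targets"),
                        compound_id = NA_character_,
                        distance_matrix = NULL, bins = NULL) {
  randomize <- match.arg(randomize)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (n_perm < 100L) {
    warning("n_perm < 100 gives an unstable null; 1000 is conventional",
            call. = FALSE)
  }
  vs <- igraph::V(net)$name
  S0 <- unique(S); T0 <- unique(T)
  Sv <- intersect(S0, vs); Tv <- intersect(T0, vs)
  drop_S <- length(S0) - length(Sv)
  drop_T <- length(T0) - length(Tv)

  invalid <- function(reason) {
    structure(list(compound_id = compound_id, d_obs = NA_real_, mu = NA_real_,
                   sigma = NA_real_, z = NA_real_, p_empirical = NA_real_,
                   p_normal = NA_real_, n_perm = n_perm, seed = seed,
                   n_dropped_S = drop_S, n_dropped_T = drop_T,
                   randomize = randomize, valid = FALSE, reason = reason),
              class = "proximity_result")
  }
  if (length(Sv) == 0L || length(Tv) == 0L) {
    return(invalid("S or T empty after intersection with the network"))
  }

  if (is.null(bins)) bins <- degree_bins(net, min_bin_size, quiet = TRUE)
  if (is.null(distance_matrix) && igraph::vcount(net) <= 5000L) {
    distance_matrix <- igraph::distances(net, algorithm = "unweighted")
  }

  if (!is.null(distance_matrix)) {
    si <- match(Sv, rownames(distance_matrix))
    ti <- match(Tv, colnames(distance_matrix))
    obs <- closest_prox_from_matrix(distance_matrix[si, ti, drop = FALSE])
  } else {
    obs <- closest_prox_from_matrix(shortest_distances(net, Sv, Tv))
  }
  if (is.na(obs$d)) return(invalid(obs$reason))

  cnt_S <- tabulate(bins$bin_of[match(Sv, names(bins$bin_of))],
                    nbins = length(bins$members))
  cnt_T <- tabulate(bins$bin_of[match(Tv, names(bins$bin_of))],
                    nbins = length(bins$members))
  si_fix <- match(Sv, vs)

  d_null <- numeric(n_perm)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      sp <- if (randomize == "both") sample_bins_idx(bins$members, cnt_S) else si_fix
      tp <- sample_bins_idx(bins$members, cnt_T)
      if (!is.null(distance_matrix)) {
        Dp <- distance_matrix[sp, tp, drop = FALSE]
      } else {
        Dp <- shortest_distances(net, vs[sp], vs[tp])
      }
      d_null[i] <- closest_prox_from_matrix(Dp)$d
    }
  })
  d_null <- d_null[!is.na(d_null)]
  mu <- mean(d_null)
  sigma <- stats::sd(d_null)
  if (!is.finite(sigma) || sigma == 0) {
    warning("permutation null is degenerate (sigma = 0); z undefined",
            call. = FALSE)
    z <- NaN; p_norm <- NaN
  } else {
    z <- (obs$d - mu) / sigma
    p_norm <- stats::pnorm(z)
  }
  p_emp <- (1 + sum(d_null <= obs$d)) / (1 + length(d_null))
  structure(list(compound_id = compound_id, d_obs = obs$d, mu = mu,
                 sigma = sigma, z = z, p_empirical = p_emp,
                 p_normal = p_norm, n_perm = n_perm, seed = seed,
                 n_dropped_S = drop_S + obs$n_dropped_S,
                 n_dropped_T = drop_T + obs$n_dropped_T,
                 randomize = randomize, valid = TRUE, reason = NA_character_),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat("Network proximity", if (!is.na(x$compound_id)) paste0("[", x$compound_id, "]"),
      "\n")
  if (!x$valid) {
    cat("  invalid:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  d(S,T) = %.4f   null mu = %.4f, sigma = %.4f (%d perms)\n",
              x$d_obs, x$mu, x$sigma, x$n_perm))
  cat(sprintf("  z = %.3f   p_empirical = %.4g   p_normal = %.4g\n",
              x$z, x$p_empirical, x$p_normal))
  if (x$n_dropped_S + x$n_dropped_T > 0) {
    cat(sprintf("  dropped: %d module node(s), %d target(s)\n",
                x$n_dropped_S, x$n_dropped_T))
  }
  invisible(x)
}

#' Score a whole compound screen against one disease module
#'
#' Convenience wrapper that precomputes the all-pairs distance matrix and the
#' degree bins once, scores every target set with [proximity_z()] (each
#' compound gets an independent child seed derived from `seed`), and returns
#' the ranked table from [rank_compounds()].
#'
#' @param net An igraph network.
#' @param S Disease-module node names.
#' @param target_sets Named list of character vectors (one per compound).
#' @param n_perm,seed,min_bin_size,randomize Passed to [proximity_z()].
#' @return A list with `results` (list of `proximity_result`) and `table`
#'   (the ranked data.frame).
#' @export
screen_proximity <- function(net, S, target_sets, n_perm = 1000L, seed = 1L,
                             min_bin_size = 100L,
                             randomize = c("both", "targets")) {
  randomize <- match.arg(randomize)
  stopifnot(is.list(target_sets), length(target_sets) >= 1L)
  if (is.null(names(target_sets))) {
    names(target_sets) <- sprintf("CPD%03d", seq_along(target_sets))
  }
  bins <- degree_bins(net, min_bin_size, quiet = TRUE)
  D <- if (igraph::vcount(net) <= 5000L) {
    igraph::distances(net, algorithm = "unweighted")
  } else NULL
  results <- lapply(names(target_sets), function(id) {
    proximity_z(net, S, target_sets[[id]], n_perm = n_perm,
                seed = child_seed(seed, id), min_bin_size = min_bin_size,
                randomize = randomize, compound_id = id,
                distance_matrix = D, bins = bins)
  })
  names(results) <- names(target_sets)
  list(results = results, table = rank_compounds(results))
}

#' Rank compounds by proximity z-score
#'
#' Orders valid results ascending by z (lower z = stronger predicted
#' association with the disease module), breaking ties by observed proximity
#' then compound id; invalid results are appended last and flagged. A
#' `significant` column marks empirical p < 0.05.
#'
#' @param results A list of `proximity_result` objects.
#' @return A data.frame, one row per compound.
#' @export
rank_compounds <- function(results) {
  if (inherits(results, "proximity_result")) results <- list(results)
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    data.frame(compound_id = r$compound_id, d_obs = r$d_obs, mu = r$mu,
               sigma = r$sigma, z = r$z, p_empirical = r$p_empirical,
               p_normal = r$p_normal, n_dropped_S = r$n_dropped_S,
               n_dropped_T = r$n_dropped_T, valid = r$valid,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!any(tab$valid)) {
    attr(tab, "status") <- "error: all results invalid"
    return(tab[0L, ])
  }
  tab$significant <- !is.na(tab$p_empirical) & tab$p_empirical < 0.05
  ord <- order(!tab$valid, xtfrm(tab$z), xtfrm(tab$d_obs), tab$compound_id)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  tab
}
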