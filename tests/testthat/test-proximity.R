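test_that("shortest distances match hand-checkable cases", {
  path <- make_path(LETTERS[1:5])
  D <- shortest_distances(path, "A", "E")
  expect_equal(D["A", "E"], 4)
  expect_equal(shortest_distances(path, "C", "C")["C", "C"], 0)
  # absent nodes are dropped and counted, not fatal
  D2 <- shortest_distances(path, c("A", "ZZ"), c("E", "QQ"))
  expect_equal(attr(D2, "n_dropped_sources"), 1)
  expect_equal(attr(D2, "n_dropped_targets"), 1)
  expect_equal(dim(D2), c(1, 1))
})

test_that("set distances agree with an exhaustive Floyd-Warshall oracle", {
  for (i in 1:10) {
    g <- random_graph(30, p = 0.12, seed = i)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    D_oracle <- fw_distances(adj)
    vs <- igraph::V(g)$name
    D_pkg <- shortest_distances(g, vs, vs)
    expect_equal(D_pkg[vs, vs], D_oracle[vs, vs])
  }
})

test_that("closest proximity reproduces forced geometries", {
  path <- make_path(LETTERS[1:5])
  expect_equal(as.numeric(closest_proximity(path, "A", "E")), 4)  # (4+4)/2
  # star: center h, leaves x y z; S = {x,y}, T = {z}
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("h", "x", "y", "z")
  expect_equal(as.numeric(closest_proximity(star, c("x", "y"), "z")), 2)
  # identical sets give exactly zero
  expect_equal(as.numeric(closest_proximity(path, c("B", "C"), c("C", "B"))), 0)
})

test_that("closest proximity equals the brute-force double loop on random graphs", {
  withr::with_seed(99, {
    for (i in 1:30) {
      n <- sample(10:60, 1)
      g <- random_graph(n, p = runif(1, 0.05, 0.3), seed = 1000 + i)
      adj <- as.matrix(igraph::as_adjacency_matrix(g))
      D <- fw_distances(adj)
      vs <- igraph::V(g)$name
      S <- sample(vs, sample(2:6, 1))
      T <- sample(vs, sample(2:6, 1))
      expect_identical(as.numeric(closest_proximity(g, S, T)),
                       brute_closest_proximity(D, S, T))
      # symmetry in the two sets
      expect_identical(as.numeric(closest_proximity(g, S, T)),
                       as.numeric(closest_proximity(g, T, S)))
    }
  })
})

test_that("moving a target closer along a path never increases proximity", {
  path <- make_path(sprintf("V%02d", 1:15))
  S <- c("V01", "V02", "V03")
  d_prev <- Inf
  for (pos in 15:4) {
    d <- as.numeric(closest_proximity(path, S, sprintf("V%02d", pos)))
    expect_lte(d, d_prev)
    d_prev <- d
  }
})

test_that("proximity handles disconnection and empties explicitly", {
  g <- igraph::make_graph(~ A - B, C - D)   # two components
  d <- closest_proximity(g, c("A", "C"), "B")
  # C cannot reach T = {B}: dropped from the S-side sum
  expect_equal(as.numeric(d), (1 + 1) / 2)
  expect_equal(attr(d, "n_dropped_S"), 1)
  bad <- closest_proximity(g, "ZZ", "B")
  expect_true(is.na(as.numeric(bad)))
  expect_match(attr(bad, "reason"), "empty")
})

test_that("degree bins cover all nodes and respect the minimum size", {
  net <- gen_ppi_network(500, 2, seed = 3)
  suppressWarnings(bins <- degree_bins(net, min_bin_size = 50))
  expect_length(bins$bin_of, 500)
  expect_true(all(lengths(bins$members) >= 50))
  expect_setequal(unlist(bins$members), seq_len(500))
  # bins are degree-contiguous: max degree in bin b <= min degree in bin b+1
  deg <- igraph::degree(net)
  ranges <- lapply(bins$members, function(m) range(deg[m]))
  for (b in seq_len(length(ranges) - 1)) {
    expect_lte(ranges[[b]][2], ranges[[b + 1]][1])
  }
  expect_warning(degree_bins(igraph::make_ring(10), min_bin_size = 100),
                 "reduced")
})

test_that("degree-matched sampling is uniform within bins", {
  # regular graph: all degrees equal, one bin; any subset is a legal draw
  ring <- igraph::make_ring(20)
  igraph::V(ring)$name <- sprintf("R%02d", 1:20)
  suppressWarnings(bins <- degree_bins(ring, 5))
  s <- withr::with_seed(1, degree_matched_sample(ring, sprintf("R%02d", 1:4),
                                                 bins = bins))
  expect_length(s, 4)
  expect_length(unique(s), 4)
  # template = all nodes: without-replacement exhaustion returns all nodes
  all_s <- withr::with_seed(2, degree_matched_sample(ring, sprintf("R%02d", 1:20),
                                                     bins = bins))
  expect_setequal(all_s, sprintf("R%02d", 1:20))
  # inclusion frequencies match the exact uniform probability |tmpl n bin|/|bin|
  net <- gen_ppi_network(200, 2, seed = 8)
  suppressWarnings(bins <- degree_bins(net, 40))
  template <- igraph::V(net)$name[c(1:5, 100:104)]
  counts <- setNames(numeric(200), igraph::V(net)$name)
  n_draw <- 4000
  withr::with_seed(7, {
    for (i in seq_len(n_draw)) {
      s <- degree_matched_sample(net, template, bins = bins)
      counts[s] <- counts[s] + 1
    }
  })
  tmpl_bins <- bins$bin_of[template]
  for (b in unique(tmpl_bins)) {
    mem <- igraph::V(net)$name[bins$members[[b]]]
    p_inc <- sum(tmpl_bins == b) / length(mem)
    obs <- counts[mem]
    chi <- sum((obs - n_draw * p_inc)^2 / (n_draw * p_inc * (1 - p_inc)))
    # conservative chi-square bound on per-node inclusion uniformity
    expect_lt(chi, stats::qchisq(0.999, df = length(mem)))
  }
})

test_that("proximity z is reproducible and flags degenerate nulls", {
  net <- gen_ppi_network(300, 2, seed = 5)
  mod <- gen_disease_module(net, 10, seed = 6)
  T <- gen_compound_screen(net, mod, 1, 8, 1, seed = 7)$target_sets[[1]]
  r1 <- proximity_z(net, mod, T, n_perm = 150, seed = 11)
  r2 <- proximity_z(net, mod, T, n_perm = 150, seed = 11)
  expect_identical(r1, r2)
  expect_equal(r1$z, (r1$d_obs - r1$mu) / r1$sigma)
  expect_gte(r1$p_empirical, 1 / (r1$n_perm + 1))
  expect_lte(r1$p_empirical, 1)
  # degenerate: complete graph of 3 nodes, S = T = all nodes -> sigma = 0
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  expect_warning(r0 <- proximity_z(k3, c("a", "b", "c"), c("a", "b", "c"),
                                   n_perm = 100, seed = 1), "degenerate")
  expect_equal(r0$d_obs, 0)
  expect_true(is.nan(r0$z))
  # invalid inputs propagate as invalid results, not errors
  bad <- proximity_z(net, "NOPE", T, n_perm = 100, seed = 1)
  expect_false(bad$valid)
})

test_that("ranking is by z with documented tie-breaks", {
  mk <- function(id, z, d, p = 0.01) {
    structure(list(compound_id = id, d_obs = d, mu = 2, sigma = 1, z = z,
                   p_empirical = p, p_normal = pnorm(z), n_perm = 100,
                   seed = 1, n_dropped_S = 0, n_dropped_T = 0,
                   randomize = "both", valid = TRUE, reason = NA_character_),
              class = "proximity_result")
  }
  res <- list(mk("b", -2.852, 1.5), mk("a", -4.198, 1.2),
              mk("d", -1.0, 2.0, p = 0.2), mk("c", -1.0, 1.0, p = 0.2))
  tab <- rank_compounds(res)
  expect_equal(tab$compound_id, c("a", "b", "c", "d"))
  expect_equal(tab$significant, c(TRUE, TRUE, FALSE, FALSE))
  # permuting the input leaves the ranking unchanged
  tab2 <- rank_compounds(res[c(3, 1, 4, 2)])
  expect_equal(tab2, tab)
  # invalid results go last
  inv <- structure(list(compound_id = "x", d_obs = NA_real_, mu = NA_real_,
                        sigma = NA_real_, z = NA_real_, p_empirical = NA_real_,
                        p_normal = NA_real_, n_perm = 100, seed = 1,
                        n_dropped_S = 0, n_dropped_T = 0, randomize = "both",
                        valid = FALSE, reason = "empty"),
                   class = "proximity_result")
  tab3 <- rank_compounds(c(res, list(inv)))
  expect_equal(tab3$compound_id[5], "x")
})

test_that("the permutation null is its own null in targets mode", {
  # T drawn by the package's own degree-matched sampler must score as noise
  net <- gen_ppi_network(600, 2, seed = 21)
  mod <- gen_disease_module(net, 12, seed = 22)
  D <- igraph::distances(net, algorithm = "unweighted")
  suppressWarnings(bins <- degree_bins(net, 100, quiet = TRUE))
  zs <- numeric(40)
  for (i in seq_len(40)) {
    template <- withr::with_seed(3000 + i,
      sample(igraph::V(net)$name, 8))
    T <- withr::with_seed(4000 + i,
      degree_matched_sample(net, template, bins = bins))
    r <- proximity_z(net, mod, T, n_perm = 300, seed = 5000 + i,
                     randomize = "targets", distance_matrix = D, bins = bins)
    zs[i] <- r$z
  }
  expect_lt(abs(mean(zs)), 0.5)   # loose bound at this replicate count
  expect_gt(stats::sd(zs), 0.6)
  expect_lt(stats::sd(zs), 1.4)
})
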