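test_that("preferential-attachment network has the exact edge count and shape", {
  # m = 1 yields a tree: n - 1 edges, connected, acyclic
  tree <- gen_ppi_network(10, 1, seed = 1)
  expect_equal(igraph::ecount(tree), 9)
  expect_true(igraph::is_connected(tree))

  net <- gen_ppi_network(500, 3, seed = 7)
  expect_equal(igraph::ecount(net), 3 * (500 - 3))
  expect_true(igraph::is_connected(net))
  expect_true(igraph::is_simple(net))
  # heavy tail: the max degree dwarfs the median
  deg <- igraph::degree(net)
  expect_gt(max(deg), 5 * stats::median(deg))
})

test_that("network generation is a pure function of its seed", {
  a <- gen_ppi_network(500, 3, seed = 7)
  b <- gen_ppi_network(500, 3, seed = 7)
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
  c <- gen_ppi_network(500, 3, seed = 8)
  expect_false(identical(igraph::as_edgelist(a), igraph::as_edgelist(c)))
})

test_that("network generator rejects degenerate sizes", {
  expect_error(gen_ppi_network(5, 1), "n_nodes")
  expect_error(gen_ppi_network(10, 10), "edges_per_node")
  expect_error(gen_ppi_network(10, 0), "edges_per_node")
})

test_that("disease module grows by BFS and has the requested cardinality", {
  path <- make_path(LETTERS[1:5])
  # any seed whose random start is A forces {A, B, C}
  for (s in 1:20) {
    mod <- gen_disease_module(path, 3, seed = s)
    expect_length(mod, 3)
    if (mod[1] == "A") expect_setequal(mod, c("A", "B", "C"))
  }
  net <- gen_ppi_network(300, 2, seed = 2)
  for (size in c(1, 10, 50)) {
    mod <- gen_disease_module(net, size, seed = 5)
    expect_length(mod, size)
    # induced subgraph is connected by construction (>= 80% contract)
    sub <- igraph::induced_subgraph(net, mod)
    comp <- igraph::components(sub)
    expect_gte(max(comp$csize) / size, 0.8)
  }
  expect_error(gen_disease_module(net, 301, seed = 1), "exceeds")
})

test_that("compound screen plants targets close to the module", {
  net <- gen_ppi_network(400, 2, seed = 11)
  mod <- gen_disease_module(net, 12, seed = 3)
  scr <- gen_compound_screen(net, mod, n_compounds = 8,
                             targets_per_compound = 6, n_planted = 8,
                             seed = 9)
  expect_true(all(scr$truth$planted))
  # oracle: brute-force distance matrix, each planted target within 1 hop
  adj <- as.matrix(igraph::as_adjacency_matrix(net))
  D <- fw_distances(adj)
  for (T in scr$target_sets) {
    to_module <- sapply(T, function(t) min(D[mod, t]))
    expect_true(all(to_module <= 1))
  }
  # none planted: all labels background
  scr0 <- gen_compound_screen(net, mod, 5, 4, 0, seed = 2)
  expect_false(any(scr0$truth$planted))
  # seeded determinism
  again <- gen_compound_screen(net, mod, 8, 6, 8, seed = 9)
  expect_identical(scr$target_sets, again$target_sets)
  expect_error(gen_compound_screen(net, character(0), 5, 4, 1, seed = 1),
               "non-empty")
})

test_that("planted compounds sit closer to the module than background", {
  # construction guarantee, checked against brute-force distances
  closer <- 0
  for (i in 1:20) {
    net <- gen_ppi_network(300, 2, seed = 100 + i)
    mod <- gen_disease_module(net, 10, seed = 200 + i)
    scr <- gen_compound_screen(net, mod, 10, 8, 5, seed = 300 + i)
    adj <- as.matrix(igraph::as_adjacency_matrix(net))
    D <- fw_distances(adj)
    d <- vapply(scr$target_sets, function(T) {
      brute_closest_proximity(D, mod, T)
    }, numeric(1))
    planted_mean <- mean(d[scr$truth$planted])
    background_mean <- mean(d[!scr$truth$planted])
    closer <- closer + (planted_mean < background_mean)
  }
  expect_gte(closer, 19)
})

test_that("bioactivity table plants the exact violation counts", {
  tab <- gen_bioactivity_table(10, 2, 3, 1, 4, seed = 5)
  expect_equal(nrow(tab$records), 20)
  expect_equal(as.integer(table(tab$truth$violation)[c("clean", "i", "ii", "iii", "iv")]),
               c(10L, 2L, 3L, 1L, 4L))
  clean <- tab$records[tab$truth$violation == "clean", ]
  expect_true(all(is_valid_inchikey(clean$inchikey)))
  expect_true(all(is_valid_uniprot(clean$target_accession)))
  expect_true(all(is_valid_smiles(clean$smiles)))
  expect_true(all(tolower(clean$activity_type) %in%
                  c("ki", "kd", "ic50", "ec50", "potency")))
  # seeded determinism down to the serialized CSV
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(gen_bioactivity_table(5, 1, 1, 1, 1, seed = 3)$records, f1,
            row.names = FALSE)
  write.csv(gen_bioactivity_table(5, 1, 1, 1, 1, seed = 3)$records, f2,
            row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # empty table
  tab0 <- gen_bioactivity_table(0, seed = 1)
  expect_equal(nrow(tab0$records), 0)
})

test_that("fingerprint generator matches its binomial noise model", {
  sim <- gen_fingerprints(10, 10, 512, 0.05, seed = 3)
  expect_equal(dim(sim$fingerprints), c(100, 512))
  expect_true(all(sim$fingerprints %in% 0:1))
  # expected Hamming distance to own prototype = n_bits * flip_prob = 25.6
  ham <- vapply(seq_len(100), function(i) {
    sum(sim$fingerprints[i, ] != sim$prototypes[sim$truth$cluster[i], ])
  }, numeric(1))
  expect_lt(abs(mean(ham) - 512 * 0.05), 3)
  # flip_prob = 0: members identical to the prototype
  pure <- gen_fingerprints(3, 4, 64, 0, seed = 1)
  for (i in seq_len(12)) {
    expect_identical(unname(pure$fingerprints[i, ]),
                     unname(pure$prototypes[pure$truth$cluster[i], ]))
  }
  expect_error(gen_fingerprints(2, 2, 64, 0.5, seed = 1), "flip_prob")
})

test_that("pk profile generator matches its closed forms", {
  sim <- gen_pk_profile(A = 5000, alpha = 2, B = 930, beta = 0.0686,
                        times_h = c(0, 1, 2), noise_cv = 0)
  expect_equal(sim$profile$conc_ng_ml[1], 5930)    # C(0) = A + B
  expect_equal(sim$truth$auc_0_inf, 5000 / 2 + 930 / 0.0686)
  expect_equal(sim$truth$t_half, log(2) / 0.0686)
  # noisy curve is seeded
  n1 <- gen_pk_profile(noise_cv = 0.1, seed = 4)$profile$conc_ng_ml
  n2 <- gen_pk_profile(noise_cv = 0.1, seed = 4)$profile$conc_ng_ml
  expect_identical(n1, n2)
  expect_error(gen_pk_profile(A = 10, alpha = 0.05, B = 5, beta = 0.1),
               "alpha")
})

test_that("cohort generator responds to the hazard coefficient", {
  sim <- gen_cohort(n = 500, seed = 1)
  expect_equal(nrow(sim$cohort), 500)
  # FFQ decomposition reproduces the stored AFVC exactly
  afvc <- vapply(seq_len(20), function(i) {
    compute_afvc(as.numeric(sim$cohort[i, grep("^ffq_times", names(sim$cohort))]),
                 as.numeric(sim$cohort[i, grep("^ffq_grams", names(sim$cohort))]))
  }, numeric(1))
  expect_equal(afvc, sim$cohort$afvc_kg_year[1:20])
  # null hazard coefficient: group incidence difference is pure noise
  diffs <- vapply(1:30, function(i) {
    co <- gen_cohort(n = 400, log_hazard_per_kg = 0, seed = 100 + i)$cohort
    st <- stratify(co)
    st$groups$incidence[st$groups$group == "high"] -
      st$groups$incidence[st$groups$group == "low"]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
  # protective coefficient: high group has lower incidence nearly always
  lower <- vapply(1:25, function(i) {
    co <- gen_cohort(n = 2000, log_hazard_per_kg = -0.01, seed = 500 + i)$cohort
    st <- stratify(co)
    st$groups$incidence[st$groups$group == "high"] <
      st$groups$incidence[st$groups$group == "low"]
  }, logical(1))
  expect_gte(mean(lower), 0.95)
})
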