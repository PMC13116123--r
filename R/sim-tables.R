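# Synthetic bioactivity tables with planted single-criterion violations, and
# binary fingerprint matrices with known cluster structure.

random_inchikey <- function(n) {
  blk <- function(k) {
    apply(matrix(sample(LETTERS, n * k, replace = TRUE), nrow = n), 1L,
          paste, collapse = "")
  }
  paste0(blk(14L), "-", blk(10L), "-", sample(c("N", "O", "M"), n, TRUE))
}

random_uniprot <- function(n) {
  paste0(sample(c("P", "Q", "O"), n, replace = TRUE),
         formatC(sample.int(99999L, n, replace = TRUE), width = 5, flag = "0"))
}

# Syntactically valid SMILES assembled from a safe fragment vocabulary; no
# chemical meaning is intended beyond lexical validity.
random_smiles <- function(n) {
  frags <- c("C", "CC", "CO", "CN", "C(=O)O", "c1ccccc1", "C1CCCCC1",
             "C(C)C", "OC", "N", "CCl", "CBr", "C=C", "C#N")
  vapply(seq_len(n), function(i) {
    paste(sample(frags, sample(2:4, 1L), replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a bioactivity table with planted filter violations
#'
#' Builds a record table in which exactly the requested number of rows
#' violate each inclusion criterion of [filter_bioactivity()], one criterion
#' per row (violations are disjoint by construction), so filter attribution
#' is exactly testable. Clean rows carry a valid InChIKey, a human organism
#' tag, a UniProt-style accession, a lexically valid SMILES, and an activity
#' type from {Ki, Kd, IC50, EC50, potency}.
#'
#' @param n_clean Rows satisfying all criteria.
#' @param n_bad_activity_type Rows violating (i) only.
#' @param n_nonhuman Rows violating (ii) only.
#' @param n_no_uniprot Rows violating (iii) only.
#' @param n_no_smiles Rows violating (iv) only.
#' @param seed Integer seed.
#' @return A list with `records` (data.frame in the input layout of
#'   [filter_bioactivity()]) and `truth` (data.frame with a `violation`
#'   column: `"clean"`, `"i"`, `"ii"`, `"iii"`, or `"iv"` per row).
#' @export
gen_bioactivity_table <- function(n_clean, n_bad_activity_type = 0L,
                                  n_nonhuman = 0L, n_no_uniprot = 0L,
                                  n_no_smiles = 0L, seed = 1L) {
  counts <- c(clean = check_count(n_clean, "n_clean", 0L),
              i = check_count(n_bad_activity_type, "n_bad_activity_type", 0L),
              ii = check_count(n_nonhuman, "n_nonhuman", 0L),
              iii = check_count(n_no_uniprot, "n_no_uniprot", 0L),
              iv = check_count(n_no_smiles, "n_no_smiles", 0L))
  n <- sum(counts)
  lab <- rep(names(counts), counts)
  if (n == 0L) {
    rec <- data.frame(compound_key = character(0), inchikey = character(0),
                      smiles = character(0), target_accession = character(0),
                      organism = character(0), activity_type = character(0),
                      activity_value = numeric(0), activity_units = character(0),
                      stringsAsFactors = FALSE)
    return(list(records = rec,
                truth = data.frame(row = integer(0), violation = character(0),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    rec <- data.frame(
      compound_key = sprintf("CPD%04d", sample.int(max(n, 1L) * 3L, n)),
      inchikey = random_inchikey(n),
      smiles = random_smiles(n),
      target_accession = random_uniprot(n),
      organism = "Homo sapiens",
      activity_type = sample(c("Ki", "Kd", "IC50", "EC50", "Potency"), n, TRUE),
      activity_value = signif(rlnorm(n, log(100), 1.5), 4),
      activity_units = "nM",
      stringsAsFactors = FALSE
    )
    if (n > 0L) {
      bad_i <- lab == "i"
      rec$activity_type[bad_i] <- sample(c("AC50", "Inhibition", "Tm", ""),
                                         sum(bad_i), replace = TRUE)
      bad_ii <- lab == "ii"
      rec$organism[bad_ii] <- sample(c("Rattus norvegicus", "Mus musculus",
                                       "Bos taurus"), sum(bad_ii), TRUE)
      bad_iii <- lab == "iii"
      rec$target_accession[bad_iii] <- sample(c("", "CHEMBL301", "1ABC"),
                                              sum(bad_iii), TRUE)
      bad_iv <- lab == "iv"
      rec$smiles[bad_iv] <- sample(c("", "C1CC(C", "C!!O", "[]C"),
                                   sum(bad_iv), TRUE)
    }
  })
  list(records = rec,
       truth = data.frame(row = seq_len(n), violation = lab,
                          stringsAsFactors = FALSE))
}

#' Simulate a binary fingerprint matrix with planted clusters
#'
#' Each cluster has a random prototype bit-vector; members are the prototype
#' with independent per-bit flips at `flip_prob` (the noise model for
#' structural fingerprints of related compounds).
#'
#' @param n_clusters Number of clusters.
#' @param per_cluster Compounds per cluster.
#' @param n_bits Fingerprint length (>= 8).
#' @param flip_prob Per-bit flip probability, in `[0, 0.5)`; at 0.5 and above
#'   the clusters are information-theoretically unrecoverable, so that is an
#'   error.
#' @param seed Integer seed.
#' @return A list with `fingerprints` (0/1 matrix, rownames `CPD001`, ...),
#'   `truth` (data.frame `compound_id`, `cluster`), and `prototypes`
#'   (n_clusters x n_bits matrix).
#' @export
gen_fingerprints <- function(n_clusters = 10L, per_cluster = 10L,
                             n_bits = 512L, flip_prob = 0.05, seed = 1L) {
  n_clusters <- check_count(n_clusters, "n_clusters")
  per_cluster <- check_count(per_cluster, "per_cluster")
  n_bits <- check_count(n_bits, "n_bits", min = 8L)
  flip_prob <- check_prob(flip_prob, "flip_prob")
  if (flip_prob >= 0.5) {
    abort_arg("`flip_prob` must be < 0.5 (clusters unrecoverable at 0.5)")
  }
  n <- n_clusters * per_cluster
  with_seed(seed, {
    proto <- matrix(rbinom(n_clusters * n_bits, 1L, 0.3),
                    nrow = n_clusters, ncol = n_bits)
    cl <- rep(seq_len(n_clusters), each = per_cluster)
    flips <- matrix(rbinom(n * n_bits, 1L, flip_prob), nrow = n)
    fp <- (proto[cl, , drop = FALSE] + flips) %% 2L
  })
  rownames(fp) <- sprintf("CPD%03d", seq_len(n))
  colnames(fp) <- sprintf("bit%03d", seq_len(n_bits))
  list(fingerprints = fp,
       truth = data.frame(compound_id = rownames(fp), cluster = cl,
                          stringsAsFactors = FALSE),
       prototypes = proto)
}
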