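# Harmonization of compound-protein bioactivity records under four inclusion
# criteria, deduplication by InChIKey, and the bipartite fruit-compound graph.
#
# Criteria, applied in fixed order (a multiply-violating record is reported
# under the first failure):
#   (i)   the activity type is a binding/potency measurement
#         (Ki, Kd, IC50, EC50, potency; synonyms folded, case-insensitive)
#   (ii)  the protein target is a human protein
#   (iii) the target carries a UniProt-style accession
#   (iv)  the compound has a syntactically valid SMILES string

BIOACTIVITY_COLUMNS <- c("compound_key", "inchikey", "smiles",
                         "target_accession", "organism", "activity_type",
                         "activity_value", "activity_units")

# Accepted activity-type spellings -> canonical form. Unknown types fail (i).
ACTIVITY_SYNONYMS <- c(
  "ki" = "Ki", "kd" = "Kd",
  "ic50" = "IC50", "ic 50" = "IC50",
  "ec50" = "EC50", "ec 50" = "EC50",
  "potency" = "potency", "biological potency" = "potency"
)

# Organism spellings treated as human (criterion ii).
HUMAN_ORGANISMS <- c("homo sapiens", "human", "9606")

#' Validate an InChIKey (27-character standard layout)
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_valid_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' Validate a UniProt-style accession
#'
#' Matches the UniProtKB lexical pattern (6- or 10-character accessions).
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_valid_uniprot <- function(x) {
  pat <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
  !is.na(x) & grepl(pat, x)
}

#' Syntactic SMILES validity check
#'
#' A lexical check, not a chemistry engine: the string must consist of legal
#' SMILES tokens (organic-subset and bracket atoms, bonds, branches, ring
#' closures), with balanced parentheses and brackets and every ring-closure
#' digit opened and closed. Semantic canonicalization can be layered on via a
#' cheminformatics toolkit if available; the filter contract only requires
#' rejecting records whose SMILES cannot be parsed at all.
#'
#' @param x Character vector of SMILES strings.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(x) {
  allowed <- c(LETTERS, letters, as.character(0:9), "@", "+", "-", "[", "]",
               "(", ")", "=", "#", "$", "/", "\\", "%", ".", ":", "*")
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!all(chars %in% allowed)) return(FALSE)
    # balanced parentheses / brackets
    for (pair in list(c("(", ")"), c("[", "]"))) {
      depth <- cumsum((chars == pair[1]) - (chars == pair[2]))
      if (any(depth < 0) || depth[length(depth)] != 0) return(FALSE)
    }
    # bracket atoms: isotope? element chirality/hcount/charge
    brackets <- regmatches(s, gregexpr("\\[[^][]*\\]", s))[[1]]
    for (b in brackets) {
      inner <- substr(b, 2L, nchar(b) - 1L)
      if (!grepl("^[0-9]*[A-Za-z][a-z]?[A-Za-z0-9@+-]*$", inner)) return(FALSE)
    }
    # the remainder must be organic-subset atoms, bonds, branches and rings
    bare <- gsub("\\[[^][]*\\]", "A", s)
    rest <- gsub("Cl|Br|[BCNOPSFIbcnops]|A", "", bare)
    if (grepl("[A-Za-z]", rest)) return(FALSE)
    # ring closures: every digit (or %nn label) must open and close
    digits <- regmatches(bare, gregexpr("%[0-9]{2}|[0-9]", bare))[[1]]
    if (length(digits) && any(table(digits) %% 2L != 0L)) return(FALSE)
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Filter bioactivity records under the four inclusion criteria
#'
#' Splits a bioactivity table into accepted records (satisfying all four
#' criteria) and rejected records annotated with the first failing criterion
#' code (`"i"`, `"ii"`, `"iii"`, `"iv"`).
#'
#' @param records A data.frame with columns `compound_key`, `inchikey`,
#'   `smiles`, `target_accession`, `organism`, `activity_type`,
#'   `activity_value`, `activity_units`.
#' @return A list with `accepted` (data.frame, `activity_type` canonicalized)
#'   and `rejected` (data.frame with an extra `reason_code` column).
#' @examples
#' tab <- gen_bioactivity_table(5, 1, 1, 0, 0, seed = 1)$records
#' filter_bioactivity(tab)$rejected$reason_code
#' @export
filter_bioactivity <- function(records) {
  stopifnot(is.data.frame(records))
  check_columns(records, BIOACTIVITY_COLUMNS, "bioactivity table")
  n <- nrow(records)
  if (n == 0L) {
    rej <- records
    rej$reason_code <- character(0)
    return(list(accepted = records, rejected = rej))
  }
  type_key <- tolower(trimws(records$activity_type))
  ok_i <- type_key %in% names(ACTIVITY_SYNONYMS)
  ok_ii <- tolower(trimws(records$organism)) %in% HUMAN_ORGANISMS
  ok_iii <- is_valid_uniprot(trimws(records$target_accession))
  ok_iv <- is_valid_smiles(records$smiles)

  reason <- rep(NA_character_, n)
  reason[!ok_iv] <- "iv"
  reason[!ok_iii] <- "iii"
  reason[!ok_ii] <- "ii"
  reason[!ok_i] <- "i"     # first-failure precedence (i) -> (iv)

  keep <- is.na(reason)
  accepted <- records[keep, , drop = FALSE]
  accepted$activity_type <- unname(ACTIVITY_SYNONYMS[type_key[keep]])
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason_code <- reason[!keep]
  rownames(accepted) <- NULL
  rownames(rejected) <- NULL
  list(accepted = accepted, rejected = rejected)
}

#' Deduplicate accepted records into a compound-target map
#'
#' Keys compounds by InChIKey and collapses records to the unique set of
#' compound-protein pairs; the number of supporting records per pair is kept
#' as provenance. Records without a valid InChIKey are dropped with a
#' message reporting the count.
#'
#' @param accepted Accepted bioactivity records (see [filter_bioactivity()]).
#' @return An object of class `compound_target_map`: list with `entries`
#'   (named list, InChIKey -> character vector of accessions) and `pairs`
#'   (data.frame `inchikey`, `accession`, `support`).
#' @export
dedupe_to_map <- function(accepted) {
  stopifnot(is.data.frame(accepted))
  check_columns(accepted, c("inchikey", "target_accession"), "accepted table")
  ok <- is_valid_inchikey(trimws(accepted$inchikey))
  if (any(!ok)) {
    message(sum(!ok), " record(s) without a valid InChIKey dropped")
  }
  df <- accepted[ok, , drop = FALSE]
  if (nrow(df) == 0L) {
    pairs <- data.frame(inchikey = character(0), accession = character(0),
                        support = integer(0), stringsAsFactors = FALSE)
    return(structure(list(entries = list(), pairs = pairs,
                          n_dropped_no_inchikey = sum(!ok)),
                     class = "compound_target_map"))
  }
  key <- paste(df$inchikey, df$target_accession, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  pairs <- data.frame(inchikey = vapply(parts, `[`, "", 1L),
                      accession = vapply(parts, `[`, "", 2L),
                      support = as.integer(tab), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$inchikey, pairs$accession), , drop = FALSE]
  rownames(pairs) <- NULL
  entries <- split(pairs$accession, pairs$inchikey)
  structure(list(entries = entries, pairs = pairs,
                 n_dropped_no_inchikey = sum(!ok)),
            class = "compound_target_map")
}

#' @export
print.compound_target_map <- function(x, ...) {
  cat("Compound-target map:", length(x$entries), "compound(s),",
      nrow(x$pairs), "unique pair(s)\n")
  if (x$n_dropped_no_inchikey > 0) {
    cat("  dropped (no InChIKey):", x$n_dropped_no_inchikey, "\n")
  }
  invisible(x)
}

#' Write a compound-target map as a pair TSV
#' @param map A `compound_target_map`.
#' @param path Output path; columns inchikey, accession, support.
#' @return `path`, invisibly.
#' @export
write_pair_map <- function(map, path) {
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a pair TSV back into a compound-target map
#' @param path Path written by [write_pair_map()].
#' @return A `compound_target_map`.
#' @export
read_pair_map <- function(path) {
  pairs <- utils::read.delim(path, colClasses = c("character", "character",
                                                  "integer"))
  check_columns(pairs, c("inchikey", "accession", "support"), "pair map")
  structure(list(entries = split(pairs$accession, pairs$inchikey),
                 pairs = pairs, n_dropped_no_inchikey = 0L),
            class = "compound_target_map")
}

#' Build the bipartite fruit-compound network
#'
#' One node per fruit and per compound, an edge wherever a compound occurs in
#' a fruit. Node degree is stored as a vertex attribute for display sizing
#' (a compound found in many fruits draws a large node).
#'
#' @param compounds A data.frame with columns `inchikey`, `display_name`, and
#'   `fruit_sources` (semicolon-separated fruit names).
#' @return A bipartite igraph (`type` TRUE for compounds, FALSE for fruits)
#'   with a `degree` vertex attribute.
#' @export
build_fruit_compound_network <- function(compounds) {
  stopifnot(is.data.frame(compounds))
  check_columns(compounds, c("inchikey", "display_name", "fruit_sources"),
                "compound table")
  sources <- strsplit(as.character(compounds$fruit_sources), ";", fixed = TRUE)
  sources <- lapply(sources, function(s) unique(trimws(s[nzchar(trimws(s))])))
  empty <- lengths(sources) == 0L
  if (any(empty)) {
    abort_arg(paste0("compound(s) with no fruit source: ",
                     paste(compounds$inchikey[empty], collapse = ", ")))
  }
  cpd <- as.character(compounds$display_name)
  el <- do.call(rbind, Map(function(fr, cp) cbind(fr, rep(cp, length(fr))),
                           sources, cpd))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% cpd
  igraph::V(g)$degree <- igraph::degree(g)
  g
}
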