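# Closed-form assay and phenotype indices: kinome percent-of-control and the
# S(35) selectivity score, Seahorse-style respirometry metrics, behavioral
# indices, and the damaged-mitochondria fraction.

#' Kinome percent-of-control
#'
#' `%Ctrl = 100 * (test - positive control) / (negative control - positive
#' control)`. The negative control (DMSO) defines 100% and the positive
#' control (a saturating control inhibitor) defines 0%; lower values mean
#' stronger binding of the test compound. Values outside `[0, 100]` are
#' returned unclipped with attribute `out_of_range`.
#'
#' @param test,pos,neg Signals (any common arbitrary unit); vectorized.
#' @return Numeric percent-of-control values.
#' @examples
#' percent_control(1060, 100, 10100)  # 9.6
#' @export
percent_control <- function(test, pos, neg) {
  if (any(neg == pos)) {
    bad <- which(neg == pos)
    abort_arg(paste0("negative and positive control signals equal for row(s) ",
                     paste(bad, collapse = ", ")))
  }
  out <- 100 * (test - pos) / (neg - pos)
  oor <- out < 0 | out > 100
  if (any(oor)) attr(out, "out_of_range") <- which(oor)
  out
}

#' Kinase selectivity score S(threshold)
#'
#' Fraction of non-mutant kinases in a panel bound below the potency
#' threshold: `S(35) = #{non-mutant kinases with %Ctrl < 35} / #{non-mutant
#' kinases tested}`. Mutant variants are excluded from both numerator and
#' denominator; the hit comparison is strictly below the threshold.
#'
#' @param panel A data.frame with columns `kinase`, `is_mutant` (logical),
#'   `test`, `pos`, `neg` signal columns, or a precomputed `pct_ctrl` column.
#' @param threshold Potency threshold in %Ctrl units (default 35).
#' @return A list with `s_score` (fraction), `n_hits`, `n_tested`, and
#'   `hits` (data.frame of non-mutant hits sorted ascending by %Ctrl).
#' @export
selectivity_score <- function(panel, threshold = 35) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1L)
  check_columns(panel, c("kinase", "is_mutant"), "kinome panel")
  if (!"pct_ctrl" %in% names(panel)) {
    check_columns(panel, c("test", "pos", "neg"), "kinome panel")
    panel$pct_ctrl <- as.numeric(percent_control(panel$test, panel$pos,
                                                 panel$neg))
  }
  nm <- panel[!panel$is_mutant, , drop = FALSE]
  if (nrow(nm) == 0L) abort_arg("panel has no non-mutant kinases")
  hit <- nm$pct_ctrl < threshold
  hits <- nm[hit, c("kinase", "pct_ctrl"), drop = FALSE]
  hits <- hits[order(hits$pct_ctrl), , drop = FALSE]
  rownames(hits) <- NULL
  list(s_score = sum(hit) / nrow(nm), n_hits = sum(hit), n_tested = nrow(nm),
       threshold = threshold, hits = hits)
}

#' Mitochondrial respiration metrics from a Seahorse-style OCR trace
#'
#' Takes the phase means of an oxygen-consumption-rate run with sequential
#' oligomycin / FCCP / rotenone+antimycin A injections and returns the
#' standard derived quantities (all in the input units, typically
#' pmol O2/min):
#' \itemize{
#'   \item basal = basal OCR - non-mitochondrial OCR (post rotenone/AA)
#'   \item ATP-linked = basal OCR - post-oligomycin OCR
#'   \item proton leak = post-oligomycin OCR - non-mitochondrial OCR
#'   \item maximal = post-FCCP OCR - non-mitochondrial OCR
#'   \item spare = maximal - basal
#' }
#' The identity `atp_linked + proton_leak = basal` holds exactly.
#'
#' @param basal_ocr,post_oligomycin,post_fccp,post_rot_aa Phase means; all
#'   four must be present and finite.
#' @return A named list with `basal`, `atp_linked`, `proton_leak`, `maximal`,
#'   `spare`.
#' @export
respiration_metrics <- function(basal_ocr, post_oligomycin, post_fccp,
                                post_rot_aa) {
  vals <- c(basal_ocr, post_oligomycin, post_fccp, post_rot_aa)
  if (length(vals) != 4L || any(!is.finite(vals))) {
    abort_arg("all four phase values must be present and finite")
  }
  basal <- basal_ocr - post_rot_aa
  atp_linked <- basal_ocr - post_oligomycin
  proton_leak <- post_oligomycin - post_rot_aa
  maximal <- post_fccp - post_rot_aa
  list(basal = basal, atp_linked = atp_linked, proton_leak = proton_leak,
       maximal = maximal, spare = maximal - basal)
}

#' Spontaneous alternation fraction (Y-maze)
#'
#' `alternations / (total arm entries - 2)`: of the entries that could have
#' been an alternation (all but the first two), the fraction that were.
#'
#' @param alternations Number of alternations (entries into a different arm
#'   than the previous two).
#' @param total_entries Total arm entries (>= 3).
#' @return Fraction in `[0, 1]`.
#' @export
spontaneous_alternation <- function(alternations, total_entries) {
  if (total_entries < 3) abort_arg("`total_entries` must be >= 3")
  if (alternations < 0 || alternations > total_entries - 2) {
    abort_arg("`alternations` must lie in [0, total_entries - 2]")
  }
  alternations / (total_entries - 2)
}

#' Novel-object recognition index
#'
#' Time spent exploring the novel object as a fraction of total exploration
#' time.
#'
#' @param novel_time,total_time Seconds; `0 <= novel_time <= total_time`,
#'   `total_time > 0`.
#' @return Fraction in `[0, 1]`.
#' @export
recognition_index <- function(novel_time, total_time) {
  if (total_time <= 0) abort_arg("`total_time` must be > 0")
  if (novel_time < 0 || novel_time > total_time) {
    abort_arg("`novel_time` must lie in [0, total_time]")
  }
  novel_time / total_time
}

#' Damaged-mitochondria fraction
#'
#' Damaged mitochondria counted on electron-microscopy images divided by
#' total mitochondria.
#'
#' @param damaged,total Counts; `0 <= damaged <= total`, `total > 0`.
#' @return Fraction in `[0, 1]`.
#' @export
damaged_mito_fraction <- function(damaged, total) {
  if (total <= 0) abort_arg("`total` must be > 0")
  if (damaged < 0 || damaged > total) {
    abort_arg("`damaged` must lie in [0, total]")
  }
  damaged / total
}
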