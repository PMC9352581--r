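#' Tape chemistry configuration
#'
#' Bundles the constants that define one tape design: the repeated monomer,
#' the constant key carried at the 3' end of every insertion (which completes
#' the spacer of the next monomer), the length of the variable insertion
#' barcode, and the number of monomer units on the array.
#'
#' @param monomer DNA string repeated along the array. Default is the 14-nt
#'   HEK3-derived monomer \code{TGATGGTGAGCACG}.
#' @param key constant DNA suffix of every insertion (2-4 nt, default
#'   \code{GGA}).
#' @param barcode_len length in nt of the variable insertion barcode (2-6).
#' @param n_sites number of monomer units (editable sites) on the array.
#' @param name free-text label.
#' @return An object of class \code{tape_config}.
#' @examples
#' cfg <- tape_config(n_sites = 5)           # 5x array, NNGGA insertions
#' cfg3 <- tape_config(barcode_len = 3)      # NNNGGA insertions
#' @export
tape_config <- function(monomer = "TGATGGTGAGCACG", key = "GGA",
                        barcode_len = 2L, n_sites = 5L, name = "TAPE-1") {
  monomer <- toupper(monomer); key <- toupper(key)
  if (!is_dna(monomer) || !is_dna(key)) stop_usage("monomer/key must be DNA (ACGT)")
  if (nchar(key) < 2 || nchar(key) > 4) stop_usage("key must be 2-4 nt")
  if (nchar(monomer) < nchar(key) + 3) stop_usage("monomer must be at least key length + 3")
  barcode_len <- as.integer(barcode_len); n_sites <- as.integer(n_sites)
  if (barcode_len < 2 || barcode_len > 6) stop_usage("barcode_len must be in 2..6")
  if (n_sites < 1) stop_usage("n_sites must be >= 1")
  structure(list(monomer = monomer, key = key, barcode_len = barcode_len,
                 n_sites = n_sites, name = name),
            class = "tape_config")
}

#' @export
print.tape_config <- function(x, ...) {
  cat(sprintf("<tape_config %s: %dx %s | key %s | %d-nt barcodes>\n",
              x$name, x$n_sites, x$monomer, x$key, x$barcode_len))
  invisible(x)
}

#' Single tape state
#'
#' The ordered list of insertion barcodes currently written to one array.
#' Because editing is strictly sequential, the inserts always occupy a prefix
#' of the sites: site i can only be edited once sites 1..i-1 are.
#'
#' @param inserts character vector of insertion barcodes, in temporal
#'   (= physical, 5' to 3') order. May be empty.
#' @param config a \code{\link{tape_config}}.
#' @param target_bc optional tape-identifying barcode 5' of the array
#'   (typically 8 nt; may be "").
#' @return Object of class \code{tape_state}.
#' @export
tape_state <- function(inserts = character(), config = tape_config(),
                       target_bc = "") {
  inserts <- toupper(as.character(inserts))
  if (length(inserts) > config$n_sites)
    stop_usage("more inserts (%d) than sites (%d)", length(inserts), config$n_sites)
  if (length(inserts) && any(nchar(inserts) != config$barcode_len))
    stop_usage("all insertion barcodes must have length %d", config$barcode_len)
  if (!is_dna(target_bc) || (length(inserts) && !is_dna(inserts)))
    stop_usage("barcodes must be DNA (ACGT)")
  structure(list(target_bc = toupper(target_bc), inserts = inserts,
                 config = config),
            class = "tape_state")
}

#' Transfection programme specification
#'
#' An ordered list of epochs; in each epoch one or more barcodes are available
#' at given mixing weights, and each tape gains at most one edit.
#'
#' @param epochs list; each element is a named numeric vector of positive
#'   mixing weights, names being the insertion barcodes available that epoch.
#' @param per_epoch_edit_prob baseline probability that a given (non-full)
#'   tape acquires an edit in one epoch.
#' @return Object of class \code{programme_spec}.
#' @examples
#' # 3 single-barcode epochs, then one 1:3 two-barcode epoch
#' prog <- programme_spec(
#'   list(c(AA = 1), c(CC = 1), c(GG = 1), c(AT = 1, TA = 3)),
#'   per_epoch_edit_prob = 0.1)
#' @export
programme_spec <- function(epochs, per_epoch_edit_prob) {
  if (!is.list(epochs) || !length(epochs)) stop_usage("epochs must be a non-empty list")
  for (ep in epochs) {
    if (!length(ep) || is.null(names(ep)) || any(!nzchar(names(ep))))
      stop_usage("each epoch must be a non-empty named weight vector")
    if (any(!is.finite(ep)) || any(ep <= 0)) stop_usage("mixing weights must be positive")
  }
  bl <- nchar(unlist(lapply(epochs, names)))
  if (length(unique(bl)) != 1) stop_usage("all programme barcodes must share one length")
  if (!is.numeric(per_epoch_edit_prob) || per_epoch_edit_prob < 0 ||
      per_epoch_edit_prob > 1)
    stop_usage("per_epoch_edit_prob must be in [0, 1]")
  structure(list(epochs = epochs, per_epoch_edit_prob = per_epoch_edit_prob,
                 barcode_len = bl[1]),
            class = "programme_spec")
}

#' Per-barcode editing-efficiency map
#'
#' Edit scores are log2-scaled relative efficiencies (0 = neutral): a barcode
#' with score s is written 2^s times as efficiently as a neutral one. Barcodes
#' absent from the map score 0.
#'
#' @param scores named numeric vector of log2 edit scores (may be empty).
#' @return Object of class \code{efficiency_map}.
#' @seealso \code{\link{compute_edit_scores}} to estimate scores from data.
#' @export
efficiency_map <- function(scores = numeric()) {
  if (length(scores)) {
    if (is.null(names(scores)) || any(!nzchar(names(scores))))
      stop_usage("scores must be named by barcode")
    if (any(!is.finite(scores))) stop_usage("edit scores must be finite")
  }
  structure(setNames(as.numeric(scores), names(scores)), class = "efficiency_map")
}

#' Look up edit scores (0 for barcodes not in the map)
#' @param eff an \code{\link{efficiency_map}} or NULL (all-neutral).
#' @param barcodes character vector.
#' @return numeric vector of log2 scores, one per barcode.
#' @export
edit_score <- function(eff, barcodes) {
  if (is.null(eff) || !length(eff)) return(numeric(length(barcodes)))
  s <- unclass(eff)[barcodes]
  s[is.na(s)] <- 0
  unname(s)
}

#' Parameters of a clonal-expansion recording simulation
#'
#' Defaults describe a monoclonal line expanded for 20 doublings while 13
#' integrated tapes (nine 5-site, three 4-site, one 2-site; 59 editable sites
#' in total) record: each tape, at each division, gains one edit with
#' probability 0.154, so that a cell accrues roughly two edits per division
#' (13 x 0.154 ~ 2) and ~40 over the expansion. 19 insertion symbols compete
#' for each edit in proportion to 2^edit_score.
#'
#' @param generations number of synchronous doublings from the founder.
#' @param tape_site_counts integer vector of per-tape site capacities.
#' @param per_tape_per_division_edit_prob per-tape, per-division edit
#'   probability (applied while a tape still has free sites).
#' @param symbols character vector of insertion barcodes (one shared length).
#' @param efficiency an \code{\link{efficiency_map}} over \code{symbols}.
#' @param sample_size number of leaf cells sampled (without replacement).
#' @param seed integer RNG seed; required for reproducibility.
#' @param target_bcs tape-identifying barcodes, one per tape.
#' @return Object of class \code{clone_sim_params}.
#' @export
clone_sim_params <- function(generations = 20L,
                             tape_site_counts = c(rep(5L, 9), rep(4L, 3), 2L),
                             per_tape_per_division_edit_prob = 0.154,
                             symbols = default_symbols(19),
                             efficiency = efficiency_map(),
                             sample_size = 100L,
                             seed = 1L,
                             target_bcs = DEFAULT_TARGETBCS[seq_along(tape_site_counts)]) {
  generations <- as.integer(generations)
  tape_site_counts <- as.integer(tape_site_counts)
  if (generations < 0) stop_usage("generations must be >= 0")
  if (generations > 30) stop_usage("generations > 30 not supported (leaf index overflow)")
  if (!length(tape_site_counts) || any(tape_site_counts < 1))
    stop_usage("tape_site_counts must be positive integers")
  if (length(target_bcs) != length(tape_site_counts))
    stop_usage("need one target_bc per tape")
  p <- per_tape_per_division_edit_prob
  if (p < 0 || p > 1) stop_usage("edit probability must be in [0, 1]")
  if (length(unique(nchar(symbols))) != 1) stop_usage("symbols must share one length")
  if (anyDuplicated(symbols)) stop_usage("symbols must be distinct")
  sample_size <- as.integer(sample_size)
  if (sample_size < 1 || sample_size > 2^generations)
    stop_usage("sample_size must be in 1..2^generations")
  structure(list(generations = generations, tape_site_counts = tape_site_counts,
                 per_tape_per_division_edit_prob = p, symbols = symbols,
                 efficiency = efficiency, sample_size = sample_size,
                 seed = as.integer(seed), target_bcs = target_bcs),
            class = "clone_sim_params")
}

#' Deterministic default insertion-symbol set
#'
#' First \code{n} k-mers over ACGT in lexicographic order; used as the default
#' symbol alphabet in clonal simulations (19 symbols of 3 nt by default,
#' matching an NNN insertion barcode).
#'
#' @param n number of symbols.
#' @param k barcode length in nt.
#' @return character vector of \code{n} distinct k-mers.
#' @export
default_symbols <- function(n = 19, k = 3) {
  if (n > 4^k) stop_usage("at most %d %d-mers exist", 4^k, k)
  all <- do.call(paste0, rev(expand.grid(rep(list(.DNA_BASES), k),
                                         stringsAsFactors = FALSE)))
  sort(all)[seq_len(n)]
}
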