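#' Per-site symbol frequency tables (unigrams)
#'
#' For each site, the normalized frequency of each (whitelisted) symbol among
#' reads edited at that site. Sites map to physical array positions: the j-th
#' insertion of a read sits at the j-th edited site of its pattern.
#'
#' @param parsed a \code{parsed_reads} list.
#' @param n_sites number of sites to tabulate (default: the maximum observed).
#' @param whitelist optional symbol filter applied before normalization.
#' @return list of named numeric vectors, one per site (empty when a site is
#'   never edited).
#' @export
site_unigrams <- function(parsed, n_sites = NULL, whitelist = NULL) {
  valid <- Filter(function(p) isTRUE(p$valid), parsed)
  n_sites <- n_sites %||%
    max(1L, vapply(valid, function(p) length(p$pattern), integer(1)))
  site <- unlist(lapply(valid, function(p) which(p$pattern)))
  sym <- unlist(lapply(valid, `[[`, "inserts"))
  if (!is.null(whitelist)) {
    keep <- sym %in% whitelist
    site <- site[keep]; sym <- sym[keep]
  }
  lapply(seq_len(n_sites), function(s) {
    v <- sym[site == s]
    if (!length(v)) return(setNames(numeric(), character()))
    tab <- table(v)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  })
}

#' Adjacent-site bigram counts
#'
#' counts[a, b] is the number of times symbol a at site i is immediately
#' followed by symbol b at site i+1 (both sites edited), pooled over all
#' adjacent site pairs of all reads. Non-adjacent pairs are never counted.
#' If B was recorded before A, B-A bigrams vastly outnumber A-B bigrams, so
#' this matrix carries the temporal ordering signal.
#'
#' @param parsed a \code{parsed_reads} list.
#' @param symbols optional symbol universe fixing the matrix dimensions
#'   (default: sorted union of observed symbols).
#' @param whitelist optional filter; pairs with a non-whitelisted member are
#'   dropped.
#' @return square numeric matrix of class \code{bigram_matrix}.
#' @export
bigram_counts <- function(parsed, symbols = NULL, whitelist = NULL) {
  valid <- Filter(function(p) isTRUE(p$valid), parsed)
  from <- character(); to <- character()
  pairs <- lapply(valid, function(p) {
    sites <- which(p$pattern)
    if (length(sites) < 2L) return(NULL)
    adj <- which(diff(sites) == 1L)
    if (!length(adj)) return(NULL)
    cbind(p$inserts[adj], p$inserts[adj + 1L])
  })
  pairs <- do.call(rbind, pairs)
  if (!is.null(pairs) && !is.null(whitelist)) {
    keep <- pairs[, 1] %in% whitelist & pairs[, 2] %in% whitelist
    pairs <- pairs[keep, , drop = FALSE]
  }
  symbols <- symbols %||%
    (if (is.null(pairs)) character() else sort(unique(as.vector(pairs))))
  m <- matrix(0, length(symbols), length(symbols),
              dimnames = list(symbols, symbols))
  if (!is.null(pairs) && nrow(pairs)) {
    keep <- pairs[, 1] %in% symbols & pairs[, 2] %in% symbols
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs)) {
      tab <- table(factor(pairs[, 1], symbols), factor(pairs[, 2], symbols))
      m <- m + unclass(tab)
    }
  }
  structure(m, class = c("bigram_matrix", class(m)))
}

#' Row-then-column normalization of a bigram matrix (display only)
#'
#' The swap test in \code{\link{refine_order}} uses raw counts; this
#' normalization (each row scaled to unit sum, then each column) only serves
#' heatmap display parity. The operator order is a fixed convention.
#'
#' @param m a \code{bigram_matrix}.
#' @return normalized matrix.
#' @export
normalize_bigram <- function(m) {
  rs <- rowSums(m); rs[rs == 0] <- 1
  m <- m / rs
  cs <- colSums(m); cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

.as_order <- function(x) {
  if (inherits(x, "event_order")) x$order else as.character(x)
}

#' Initial event order from site-1 unigram frequencies
#'
#' Symbols sorted by descending frequency at the first site: symbols recorded
#' earlier had more opportunity to claim site 1. Ties break lexicographically
#' so the order is deterministic. This initialization alone is generally not
#' correct (efficiency biases distort frequencies); it seeds
#' \code{\link{refine_order}}.
#'
#' @param site1 named numeric vector of site-1 frequencies.
#' @return object of class \code{event_order} (fields: order, converged,
#'   passes_used).
#' @export
initial_order <- function(site1) {
  if (!length(site1)) stop_usage("empty unigram table")
  ord <- names(site1)[order(-site1, names(site1))]
  structure(list(order = ord, converged = NA, passes_used = 0L),
            class = "event_order")
}

#' @export
print.event_order <- function(x, ...) {
  cat(sprintf("<event_order: %s%s>\n", paste(x$order, collapse = " < "),
              if (isTRUE(x$converged)) "" else
                if (isFALSE(x$converged)) " [not converged]" else " [initial]"))
  invisible(x)
}

#' Refine an event order by pairwise bigram swaps
#'
#' Scans adjacent pairs (A before B) from the beginning; whenever
#' counts[B, A] > counts[A, B] - strictly more observations of B immediately
#' before A than the reverse, inconsistent with the current order - the pair
#' is swapped and the pass restarts. Stops at the first pass with no swap, or
#' after \code{max_passes} (default n(n-1)/2 + 1, enough for a full reversal
#' and guaranteeing termination under cyclic inconsistencies). Ties,
#' including 0 vs 0, never swap: the incoming order is the tiebreak.
#'
#' @param init an \code{event_order} or character permutation of the matrix
#'   symbols.
#' @param bg a \code{\link{bigram_counts}} matrix over the same symbols.
#' @param max_passes pass cap; see above.
#' @return an \code{event_order} with \code{converged} and
#'   \code{passes_used} set.
#' @export
refine_order <- function(init, bg, max_passes = NULL) {
  ord <- .as_order(init)
  if (!setequal(ord, rownames(bg)) || length(ord) != nrow(bg))
    stop_usage("order symbols do not match bigram matrix symbols")
  n <- length(ord)
  max_passes <- max_passes %||% (n * (n - 1L) %/% 2L + 1L)
  passes <- 0L
  converged <- FALSE
  while (passes < max_passes) {
    passes <- passes + 1L
    swapped <- FALSE
    for (k in seq_len(max(0L, n - 1L))) {
      a <- ord[k]; b <- ord[k + 1L]
      if (bg[b, a] > bg[a, b]) {
        ord[c(k, k + 1L)] <- c(b, a)
        swapped <- TRUE
        break  # restart the pass from the beginning
      }
    }
    if (!swapped) { converged <- TRUE; break }
  }
  structure(list(order = ord, converged = converged, passes_used = passes),
            class = "event_order")
}

#' Efficiency-corrected within-epoch mixing ratio
#'
#' Recovers the ratio at which two co-introduced barcodes were mixed: total
#' observed counts (summed over all sites) are divided by each barcode's
#' relative efficiency 2^edit_score before taking the ratio, removing the
#' write-efficiency bias from the estimate.
#'
#' @param counts named numeric vector of total insertion counts (see
#'   \code{\link{insert_counts}}).
#' @param eff an \code{\link{efficiency_map}} (NULL = no correction).
#' @param pair character vector of two barcodes (numerator, denominator).
#' @return single numeric ratio.
#' @export
within_epoch_ratio <- function(counts, eff = NULL, pair) {
  if (length(pair) != 2L) stop_usage("pair must name exactly two barcodes")
  miss <- setdiff(pair, names(counts))
  if (length(miss))
    stop_usage("barcode(s) not observed: %s", paste(miss, collapse = ", "))
  corr <- counts[pair] / 2^edit_score(eff, pair)
  if (corr[2] == 0) stop_usage("zero corrected count for denominator %s", pair[2])
  unname(corr[1] / corr[2])
}

#' Combinatorics of event ordering
#'
#' Ordering n events pairwise requires (n^2 + n)/2 ordering rules (all
#' unordered pairs plus reflexives), while the number of candidate
#' permutations grows as n!: the pairwise bigram representation is what keeps
#' decoding tractable.
#'
#' @param n number of events (>= 1).
#' @return list with \code{rules} and \code{permutations} (numeric; exact up
#'   to n = 18, beyond the integer range for n >= 13).
#' @examples
#' ordering_complexity(16)  # 136 rules vs ~21 trillion permutations
#' @export
ordering_complexity <- function(n) {
  if (!is.numeric(n) || n < 1 || n != round(n)) stop_usage("n must be an integer >= 1")
  list(rules = (n^2 + n) / 2, permutations = factorial(n))
}
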