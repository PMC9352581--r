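#' Correct observed tape-identifying barcodes against a whitelist
#'
#' Exact matches pass through; a barcode at Hamming distance 1 from exactly
#' one whitelist member is corrected to it; anything at distance
#' \code{>= drop_at} from every member (or ambiguous) is dropped with a
#' reason. The whitelist should have pairwise Hamming distance >= 3 so that
#' single-substitution correction is unambiguous; a warning is emitted
#' otherwise.
#'
#' @param observed character vector of observed barcodes (one width).
#' @param whitelist approved barcodes, same width.
#' @param drop_at observations at Hamming distance >= drop_at from all
#'   members are dropped (default 2, the conservative reading of "corrected
#'   at 1 mismatch, removed beyond 2").
#' @return data.frame(observed, corrected, reason) where corrected is NA for
#'   dropped barcodes and reason is one of exact/corrected/ambiguous/
#'   too-distant.
#' @export
correct_targetbc <- function(observed, whitelist, drop_at = 2L) {
  if (length(unique(nchar(whitelist))) != 1)
    stop_usage("whitelist barcodes must share one width")
  if (length(whitelist) > 1) {
    dmin <- min(vapply(seq_along(whitelist)[-1], function(i)
      min(hamming_dist(whitelist[seq_len(i - 1L)], whitelist[i])), numeric(1)))
    if (dmin < 3)
      warning("whitelist pairwise Hamming distance < 3: correction may be ambiguous")
  }
  res <- lapply(observed, function(x) {
    if (nchar(x) != nchar(whitelist[1]))
      return(c(NA_character_, "too-distant"))
    d <- hamming_dist(whitelist, x)
    if (any(d == 0)) return(c(whitelist[d == 0][1], "exact"))
    hit <- whitelist[d == 1]
    if (length(hit) == 1 && 1 < drop_at) return(c(hit, "corrected"))
    if (length(hit) > 1) return(c(NA_character_, "ambiguous"))
    c(NA_character_, "too-distant")
  })
  data.frame(observed = observed,
             corrected = vapply(res, `[`, character(1), 1),
             reason = vapply(res, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Collapse UMI-tagged tape reads to per-cell, per-tape consensus
#'
#' Rows carrying the same (cell, tape id, tape sequence) are collapsed to
#' their distinct-UMI count. Groups supported by fewer than \code{min_umis}
#' UMIs in total are dropped as likely ambient/chimeric molecules. When one
#' (cell, tape id) shows conflicting tape sequences, the sequence with the
#' larger UMI count wins; ties drop the whole group since no consensus
#' exists.
#'
#' @param rows data.frame/data.table with columns cell_id, umi, target_bc,
#'   tape.
#' @param min_umis minimum distinct UMIs per (cell, tape id) consensus
#'   (default 2).
#' @return data.table(cell_id, target_bc, tape, n_umis), one row per
#'   retained (cell, tape id).
#' @export
collapse_umis <- function(rows, min_umis = 2L) {
  dt <- data.table::as.data.table(rows)
  need <- c("cell_id", "umi", "target_bc", "tape")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_usage("missing column(s): %s", paste(miss, collapse = ", "))
  umi <- tape <- n_umis <- cell_id <- target_bc <- NULL  # NSE notes
  g <- dt[, list(n_umis = data.table::uniqueN(umi)),
          by = list(cell_id, target_bc, tape)]
  g <- g[g$n_umis >= min_umis]
  data.table::setorder(g, cell_id, target_bc, -n_umis, tape)
  pick <- g[, {
    if (.N == 1L || n_umis[1] > n_umis[2])
      list(tape = tape[1], n_umis = n_umis[1])
    else
      list(tape = character(0), n_umis = integer(0))  # tie: drop group
  }, by = list(cell_id, target_bc)]
  pick[]
}

#' Assemble a complete-case cohort over a fixed tape panel
#'
#' Keeps only cells that carry every tape of the panel exactly once and, when
#' an insertion whitelist is given, whose every insertion is on it; the
#' remainder is dropped with a per-cell reason. Rows violating the sequential
#' prefix property (an edited site after an unedited one) also drop the cell.
#' The result is the unit on which all lineage computations operate.
#'
#' @param records data.frame/data.table with columns cell_id, target_bc and
#'   site1..siteK (empty string or NA = unedited).
#' @param panel character vector of tape ids, in panel order.
#' @param insertbc_whitelist optional whitelist of insertion barcodes.
#' @param capacity integer vector of per-tape site capacities, parallel to
#'   \code{panel}; default: per-tape maximum site column that is non-NA
#'   anywhere in \code{records}.
#' @return Object of class \code{tape_cohort}: cells (ids), inserts
#'   (character matrix cells x total sites, "" = unedited), panel, capacity,
#'   block (site -> tape index), plus a \code{dropped} attribute.
#' @export
select_complete_cells <- function(records, panel, insertbc_whitelist = NULL,
                                  capacity = NULL) {
  dt <- data.table::as.data.table(records)
  site_cols <- grep("^site[0-9]+$", names(dt), value = TRUE)
  site_cols <- site_cols[order(as.integer(sub("site", "", site_cols)))]
  if (!length(site_cols)) stop_usage("no site columns (site1..siteK) found")
  dt <- dt[dt$target_bc %in% panel]

  # a site exists for a tape when any cell has a non-NA entry there ("" =
  # present but unedited, NA = structurally absent on shorter tapes)
  if (is.null(capacity)) {
    capacity <- vapply(panel, function(tb) {
      sub <- dt[dt$target_bc == tb]
      present <- vapply(site_cols, function(sc)
        nrow(sub) > 0 && any(!is.na(sub[[sc]])), logical(1))
      max(c(0L, which(present)))
    }, integer(1))
  }
  for (sc in site_cols) dt[[sc]][is.na(dt[[sc]])] <- ""
  capacity <- setNames(as.integer(capacity), panel)
  if (any(capacity < 1)) stop_usage("could not determine capacity for all panel tapes")

  dropped <- list()
  keep_rows <- list()
  for (cell in unique(dt$cell_id)) {
    sub <- dt[dt$cell_id == cell]
    if (anyDuplicated(sub$target_bc)) { dropped[[cell]] <- "duplicate-tape"; next }
    if (!all(panel %in% sub$target_bc)) { dropped[[cell]] <- "missing-tape"; next }
    sub <- sub[match(panel, sub$target_bc)]
    ok <- TRUE
    for (t in seq_along(panel)) {
      v <- unlist(sub[t, site_cols[seq_len(capacity[t])], with = FALSE],
                  use.names = FALSE)
      edited <- nzchar(v)
      if (any(edited) && !all(which(edited) == seq_len(sum(edited)))) {
        dropped[[cell]] <- "nonsequential"; ok <- FALSE; break
      }
      if (!is.null(insertbc_whitelist) &&
          length(setdiff(v[edited], insertbc_whitelist))) {
        dropped[[cell]] <- "off-whitelist-insert"; ok <- FALSE; break
      }
    }
    if (ok) keep_rows[[cell]] <- sub
  }
  if (!length(keep_rows)) stop_usage("no cells satisfy the completeness filters")

  cells <- names(keep_rows)
  block <- rep(seq_along(panel), capacity)
  inserts <- matrix("", length(cells), sum(capacity),
                    dimnames = list(cells, NULL))
  for (ci in seq_along(cells)) {
    sub <- keep_rows[[ci]]
    vals <- unlist(lapply(seq_along(panel), function(t)
      unlist(sub[t, site_cols[seq_len(capacity[t])], with = FALSE],
             use.names = FALSE)), use.names = FALSE)
    inserts[ci, ] <- vals
  }
  structure(list(cells = cells, inserts = inserts, panel = panel,
                 capacity = unname(capacity), block = block),
            class = "tape_cohort",
            dropped = unlist(dropped) %||% character())
}

#' Build a cohort directly from a cell table (no filtering)
#' @param records as in \code{\link{select_complete_cells}}.
#' @param panel tape ids; default: sorted unique target_bc.
#' @param capacity per-tape capacities; default inferred.
#' @return a \code{tape_cohort}.
#' @export
as_tape_cohort <- function(records, panel = NULL, capacity = NULL) {
  panel <- panel %||% sort(unique(records$target_bc))
  select_complete_cells(records, panel, insertbc_whitelist = NULL,
                        capacity = capacity)
}

#' @export
print.tape_cohort <- function(x, ...) {
  cat(sprintf("<tape_cohort: %d cells | %d tapes | %d editable sites>\n",
              length(x$cells), length(x$panel), ncol(x$inserts)))
  invisible(x)
}

#' Restrict or resample the tape blocks of a cohort
#'
#' Returns the cohort restricted to the given tape indices, in the given
#' order; repeated indices duplicate blocks, which is what the block
#' bootstrap needs.
#'
#' @param cohort a \code{tape_cohort}.
#' @param idx integer vector of tape (block) indices, possibly repeated.
#' @return a \code{tape_cohort}.
#' @export
subset_blocks <- function(cohort, idx) {
  stopifnot(inherits(cohort, "tape_cohort"))
  cols <- unlist(lapply(idx, function(t) which(cohort$block == t)))
  structure(list(cells = cohort$cells,
                 inserts = cohort$inserts[, cols, drop = FALSE],
                 panel = make.unique(cohort$panel[idx]),
                 capacity = cohort$capacity[idx],
                 block = rep(seq_along(idx), cohort$capacity[idx])),
            class = "tape_cohort")
}
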