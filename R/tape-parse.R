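# count mismatches between read[pos..pos+n-1] and ref (both uppercase)
.mm_at <- function(read, pos, ref) {
  n <- nchar(ref)
  chunk <- substr(read, pos, pos + n - 1L)
  if (nchar(chunk) < n) return(n)  # off the end: treat as all-mismatch
  if (chunk == ref) return(0L)
  sum(strsplit(chunk, "", fixed = TRUE)[[1]] != strsplit(ref, "", fixed = TRUE)[[1]])
}

.invalid_read <- function(read_id, read, reason) {
  structure(list(read_id = read_id, read = read, target_bc = NA_character_,
                 inserts = character(), n_monomers_observed = 0L,
                 pattern = logical(), valid = FALSE, reason = reason),
            class = "parsed_read")
}

#' Extract ordered insertions from one tape amplicon read
#'
#' Walks the monomer scaffold from 5' to 3'. Anything before the first
#' key+monomer match is taken as the target barcode; after each monomer the
#' parser accepts either the next monomer copy (site unedited), a
#' barcode_len-mer followed by the key (site edited), or the end of the read.
#' Reads with the wrong key after a putative barcode, a broken scaffold or
#' trailing garbage are flagged invalid with a reason; they are the reads the
#' wrong-key / length-consistency filters remove. Monomer copies may tolerate
#' up to \code{max_monomer_mismatch} substitutions (default 0; at most 1,
#' matching the single-substitution correction used for 14-nt monomers in
#' single-cell data). The key itself must always match exactly.
#'
#' @param read uppercase DNA string.
#' @param config a \code{\link{tape_config}}.
#' @param max_monomer_mismatch 0 or 1.
#' @param read_id optional identifier carried through.
#' @return Object of class \code{parsed_read}: read_id, read, target_bc,
#'   inserts (in physical order), n_monomers_observed, pattern (logical
#'   per-site edited flags), valid, reason.
#' @export
extract_insertions <- function(read, config, max_monomer_mismatch = 0L,
                               read_id = NA_character_) {
  stopifnot(inherits(config, "tape_config"))
  if (max_monomer_mismatch < 0 || max_monomer_mismatch > 1)
    stop_usage("max_monomer_mismatch must be 0 or 1")
  read <- toupper(read)
  M <- config$monomer; K <- config$key; B <- config$barcode_len
  ml <- nchar(M); kl <- nchar(K); L <- nchar(read)

  # locate the scaffold start: first key immediately followed by a monomer
  start <- NA_integer_
  j <- 1L
  limit <- L - kl - ml + 1L
  while (j <= limit) {
    if (substr(read, j, j + kl - 1L) == K &&
        .mm_at(read, j + kl, M) <= max_monomer_mismatch) { start <- j; break }
    j <- j + 1L
  }
  if (is.na(start)) return(.invalid_read(read_id, read, "no-scaffold"))

  target_bc <- substr(read, 1L, start - 1L)
  pos <- start + kl + ml  # just past monomer 1
  nmono <- 1L
  pattern <- logical()
  inserts <- character()
  repeat {
    rem <- L - pos + 1L
    if (rem == 0L) { pattern[nmono] <- FALSE; break }
    if (rem >= ml && .mm_at(read, pos, M) <= max_monomer_mismatch) {
      pattern[nmono] <- FALSE
      nmono <- nmono + 1L
      pos <- pos + ml
      next
    }
    if (rem < B + kl) return(.invalid_read(read_id, read, "truncated"))
    bc <- substr(read, pos, pos + B - 1L)
    if (substr(read, pos + B, pos + B + kl - 1L) != K)
      return(.invalid_read(read_id, read, "wrong-key"))
    pattern[nmono] <- TRUE
    inserts <- c(inserts, bc)
    pos <- pos + B + kl
    rem <- L - pos + 1L
    if (rem == 0L) break
    if (rem >= ml && .mm_at(read, pos, M) <= max_monomer_mismatch) {
      nmono <- nmono + 1L
      pos <- pos + ml
      next
    }
    return(.invalid_read(read_id, read, "bad-scaffold"))
  }
  structure(list(read_id = read_id, read = read, target_bc = target_bc,
                 inserts = inserts, n_monomers_observed = nmono,
                 pattern = pattern, valid = TRUE, reason = NA_character_),
            class = "parsed_read")
}

#' Parse a batch of reads
#' @param reads character vector (names used as read ids when present) or a
#'   \code{tape_state_set}, which is rendered first.
#' @param config a \code{\link{tape_config}}.
#' @param max_monomer_mismatch passed through to
#'   \code{\link{extract_insertions}}.
#' @return list of \code{parsed_read}, class \code{parsed_reads}.
#' @export
parse_reads <- function(reads, config, max_monomer_mismatch = 0L) {
  if (inherits(reads, "tape_state_set")) {
    config <- reads$config
    reads <- render_tapes(reads)
  }
  ids <- names(reads) %||% rep(NA_character_, length(reads))
  out <- lapply(seq_along(reads), function(i)
    extract_insertions(reads[[i]], config, max_monomer_mismatch, ids[[i]]))
  structure(out, class = "parsed_reads")
}

#' Classify a per-site editing pattern
#'
#' \code{unedited} when no site is edited; \code{sequential} when the edited
#' sites form a non-empty prefix of the array (the only patterns a faithful
#' sequential recorder can produce); \code{nonsequential} otherwise. Of the
#' 2^n conceivable patterns on an n-site array, 1 is unedited, n are
#' sequential and 2^n - n - 1 are nonsequential.
#'
#' @param pattern logical vector of per-site edited flags.
#' @return one of \code{"unedited"}, \code{"sequential"},
#'   \code{"nonsequential"}.
#' @export
classify_pattern <- function(pattern) {
  if (!length(pattern)) stop_usage("empty pattern")
  pattern <- as.logical(pattern)
  k <- sum(pattern)
  if (k == 0L) return("unedited")
  if (all(which(pattern) == seq_len(k))) "sequential" else "nonsequential"
}

#' Editing efficiency, sequential error rate and conditional per-site rates
#'
#' Efficiency is the fraction of (valid) reads showing any edit; the
#' sequential error rate is the fraction of edited reads whose pattern is
#' inconsistent with sequential, directional editing. The conditional rate at
#' site i is the fraction of reads edited at site i among reads that observe
#' site i and are edited at every earlier site (for site 1: among all reads) -
#' i.e. the editing rate of a site given that it has been activated.
#'
#' @param parsed a \code{parsed_reads} list (invalid reads are ignored).
#' @return list of class \code{edit_metrics}: efficiency,
#'   sequential_error_rate (NA when no read is edited), per_site_conditional,
#'   read_counts (named: unedited/sequential/nonsequential/invalid), n_reads.
#' @export
editing_metrics <- function(parsed) {
  valid <- Filter(function(p) isTRUE(p$valid), parsed)
  if (!length(valid)) stop_usage("no valid reads")
  cls <- vapply(valid, function(p) classify_pattern(p$pattern), character(1))
  counts <- c(unedited = sum(cls == "unedited"),
              sequential = sum(cls == "sequential"),
              nonsequential = sum(cls == "nonsequential"),
              invalid = length(parsed) - length(valid))
  edited <- counts[["sequential"]] + counts[["nonsequential"]]
  nsite <- max(vapply(valid, function(p) length(p$pattern), integer(1)))
  cond <- rep(NA_real_, nsite)
  for (s in seq_len(nsite)) {
    den <- 0L; num <- 0L
    for (p in valid) {
      if (length(p$pattern) < s) next
      if (s > 1L && !all(p$pattern[seq_len(s - 1L)])) next
      den <- den + 1L
      num <- num + as.integer(p$pattern[s])
    }
    cond[s] <- if (den) num / den else NA_real_
  }
  structure(list(efficiency = edited / length(valid),
                 sequential_error_rate =
                   if (edited) counts[["nonsequential"]] / edited else NA_real_,
                 per_site_conditional = cond,
                 read_counts = counts,
                 n_reads = length(parsed)),
            class = "edit_metrics")
}

#' @export
print.edit_metrics <- function(x, ...) {
  cat(sprintf("<edit_metrics: efficiency %.3f | sequential error %.3f | %d reads>\n",
              x$efficiency, x$sequential_error_rate, x$n_reads))
  invisible(x)
}

#' Whitelist real barcodes from a count spectrum
#'
#' Exhaustive one-dimensional two-means on log10(count+1): every split point
#' of the sorted values is scored by within-cluster sum of squares and the
#' best split's high cluster is returned (deterministic; no random
#' initialisation). Two guards: equal counts return everything, and the low
#' cluster is only discarded when the two cluster means are separated by at
#' least \code{min_separation} decades - otherwise the spectrum is treated as
#' signal-only. Real error tails (counts of 1-10 against signal in the
#' thousands) separate by 2+ decades; legitimate abundance spread between true
#' barcodes rarely reaches one.
#'
#' @param counts named numeric vector (barcode -> read count).
#' @param key optional key sequence; barcodes not ending in it are excluded
#'   before clustering (wrong-key artefact species).
#' @param min_separation minimum gap (decades) between cluster means for the
#'   split to be applied; 0 reproduces plain two-means.
#' @return character vector of whitelisted barcodes.
#' @export
barcode_whitelist <- function(counts, key = NULL, min_separation = 1) {
  if (is.null(names(counts))) stop_usage("counts must be named by barcode")
  if (!is.null(key))
    counts <- counts[endsWith(names(counts), key)]
  if (length(counts) < 2L) return(names(counts))
  x <- log10(counts + 1)
  if (diff(range(x)) == 0) return(names(counts))
  ord <- order(x, names(counts))
  xs <- x[ord]
  n <- length(xs)
  wss <- vapply(seq_len(n - 1L), function(s) {
    lo <- xs[seq_len(s)]; hi <- xs[(s + 1L):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  s <- which.min(wss)
  gap <- mean(xs[(s + 1L):n]) - mean(xs[seq_len(s)])
  if (gap < min_separation) return(names(counts))
  names(counts)[ord][(s + 1L):n]
}

#' Log2 edit scores from insertion frequencies and pool abundances
#'
#' For each replicate, observed insertion counts are normalized to
#' frequencies and compared with the normalized abundances of the
#' corresponding pegRNAs in the plasmid pool:
#' score_b = mean over replicates of log2((f_b + eps) / (a_b + eps)).
#' The pseudofrequency eps defaults to half a count over the replicate's
#' total (0.5/total), keeping scores finite for unobserved barcodes; pass
#' counts rather than pre-normalized frequencies so the total is known.
#'
#' @param insert_freqs named numeric vector of counts (one replicate) or a
#'   list of such vectors (replicates). Barcodes absent from a replicate
#'   count 0.
#' @param abundances named numeric vector of pool abundances covering every
#'   barcode; frequencies are renormalized internally.
#' @param pseudo explicit pseudofrequency; default 0.5/total (or 5e-7 when
#'   the input is already normalized so the total is unknown).
#' @return an \code{\link{efficiency_map}} over \code{names(abundances)}.
#' @export
compute_edit_scores <- function(insert_freqs, abundances, pseudo = NULL) {
  if (!is.list(insert_freqs)) insert_freqs <- list(insert_freqs)
  if (is.null(names(abundances))) stop_usage("abundances must be named")
  a <- abundances / sum(abundances)
  scores <- vapply(insert_freqs, function(x) {
    if (is.null(names(x))) stop_usage("insert frequencies must be named")
    extra <- setdiff(names(x), names(a))
    if (length(extra))
      stop_usage("barcode(s) absent from abundances: %s",
                 paste(extra, collapse = ", "))
    total <- sum(x)
    eps <- pseudo %||% if (total > 1.5) 0.5 / total else 5e-7
    f <- setNames(numeric(length(a)), names(a))
    f[names(x)] <- x / total
    log2((f + eps) / (a + eps))
  }, numeric(length(a)))
  efficiency_map(rowMeans(matrix(scores, nrow = length(a),
                                 dimnames = list(names(a)))))
}

#' Pick one representative read per target barcode
#'
#' For long (12x/20x) arrays prone to contraction, reads sharing a TargetBC
#' derive from one integration; the representative is the read with the most
#' observed monomers (contraction being far more common than expansion), ties
#' broken by most edits, then by lexicographically smallest read sequence for
#' determinism. Invalid reads (broken scaffold, i.e. observed length
#' inconsistent with the insertion count) are excluded first.
#'
#' @param parsed a \code{parsed_reads} list with non-empty target barcodes.
#' @return named list (target_bc -> representative \code{parsed_read}).
#' @export
group_long_reads <- function(parsed) {
  valid <- Filter(function(p) isTRUE(p$valid) && nzchar(p$target_bc), parsed)
  if (!length(valid)) return(structure(list(), names = character()))
  tbc <- vapply(valid, `[[`, character(1), "target_bc")
  out <- lapply(split(valid, tbc), function(grp) {
    nm <- vapply(grp, `[[`, integer(1), "n_monomers_observed")
    ne <- vapply(grp, function(p) length(p$inserts), integer(1))
    rd <- vapply(grp, `[[`, character(1), "read")
    grp[[order(-nm, -ne, rd)[1]]]
  })
  out[sort(names(out))]
}

#' Total insertion counts across all sites
#' @param parsed a \code{parsed_reads} list.
#' @param whitelist optional barcode filter.
#' @return named numeric vector of counts.
#' @export
insert_counts <- function(parsed, whitelist = NULL) {
  ins <- unlist(lapply(Filter(function(p) isTRUE(p$valid), parsed),
                       `[[`, "inserts"))
  if (!is.null(whitelist)) ins <- ins[ins %in% whitelist]
  if (!length(ins)) return(setNames(numeric(), character()))
  tab <- table(ins)
  setNames(as.numeric(tab), names(tab))
}
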