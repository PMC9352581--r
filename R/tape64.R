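.TAPE64_ALPHABET <- c(LETTERS, ".", ",", "?", "!", " ")

#' Build a TAPE64 encoding table
#'
#' Maps a 31-character alphabet (A-Z, four punctuation symbols and
#' whitespace) onto the 64 possible 3-nt insertion barcodes with redundancy:
#' by default every character owns two codes except whitespace, which owns
#' four (30 x 2 + 4 = 64), whitespace being by far the most frequent
#' character in English text. The default assignment walks the 64 3-mers in
#' lexicographic order; an explicit assignment (e.g. a published table) can
#' be supplied instead and is validated.
#'
#' @param assignments optional named list, character -> character vector of
#'   3-nt codes; code sets must be disjoint and cover all 64 3-mers.
#' @return Object of class \code{tape64_table} with fields \code{codes}
#'   (named list), \code{inverse} (named character, code -> character) and
#'   \code{alphabet}.
#' @export
tape64_table <- function(assignments = NULL) {
  if (is.null(assignments)) {
    red <- setNames(rep(2L, length(.TAPE64_ALPHABET)), .TAPE64_ALPHABET)
    red[" "] <- 4L
    codes <- default_symbols(64, 3)
    assignments <- list()
    at <- 1L
    for (ch in .TAPE64_ALPHABET) {
      assignments[[ch]] <- codes[at:(at + red[[ch]] - 1L)]
      at <- at + red[[ch]]
    }
  }
  all_codes <- unlist(assignments, use.names = FALSE)
  if (anyDuplicated(all_codes)) stop_usage("duplicate barcode in encoding table")
  if (length(all_codes) != 64L)
    stop_usage("encoding table must assign exactly 64 codes (got %d)",
               length(all_codes))
  if (any(nchar(all_codes) != 3L) || !is_dna(all_codes))
    stop_usage("codes must be 3-nt DNA")
  inverse <- setNames(rep(names(assignments), lengths(assignments)), all_codes)
  structure(list(codes = assignments, inverse = inverse,
                 alphabet = names(assignments)),
            class = "tape64_table")
}

#' @export
print.tape64_table <- function(x, ...) {
  cat(sprintf("<tape64_table: %d characters over 64 codes>\n", length(x$codes)))
  invisible(x)
}

#' Encode a text message as a transfection plan
#'
#' The message is split into consecutive sets of four characters (the last
#' set may be shorter); each set becomes one transfection epoch in which the
#' four codes are mixed at weights 7:5:3:1, the weight ranking encoding the
#' within-set character order. Repeated characters cycle round-robin through
#' their redundant codes; once a character repeats beyond its redundancy its
#' codes are reused and the extra occurrences become indistinguishable - a
#' deletion error built into the 64-code scheme, not a bug.
#'
#' @param text message restricted to the table's alphabet.
#' @param table a \code{\link{tape64_table}}.
#' @param set_size characters per epoch (default 4).
#' @param weights within-set mixing weights, strictly decreasing (default
#'   7:5:3:1; truncated to the final set's size).
#' @return Object of class \code{message_plan}: list of epochs, each a
#'   data.frame(char, barcode, weight), plus the text.
#' @export
encode_message <- function(text, table = tape64_table(), set_size = 4L,
                           weights = c(7, 5, 3, 1)) {
  stopifnot(inherits(table, "tape64_table"))
  if (length(weights) < set_size || any(diff(weights) >= 0))
    stop_usage("weights must be strictly decreasing and cover set_size")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), table$alphabet)
  if (length(bad))
    stop_usage("unsupported character(s): %s",
               paste(sprintf("'%s'", bad), collapse = ", "))
  seen <- integer(0)
  code_of <- character(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    k <- (seen[ch] %||% 0L)
    if (is.na(k)) k <- 0L
    code_of[i] <- table$codes[[ch]][(k %% length(table$codes[[ch]])) + 1L]
    seen[ch] <- k + 1L
  }
  sets <- split(seq_along(chars), (seq_along(chars) - 1L) %/% set_size)
  epochs <- lapply(sets, function(idx)
    data.frame(char = chars[idx], barcode = code_of[idx],
               weight = weights[seq_along(idx)], stringsAsFactors = FALSE))
  structure(list(epochs = unname(epochs), text = text), class = "message_plan")
}

#' Convert a message plan to a programme specification
#'
#' Duplicate barcodes within one epoch (a character repeated beyond its
#' redundancy inside a single set) have their weights summed.
#'
#' @param plan a \code{\link{encode_message}} result.
#' @param per_epoch_edit_prob per-epoch edit probability for simulation.
#' @return a \code{\link{programme_spec}}.
#' @export
as_programme_spec <- function(plan, per_epoch_edit_prob = 0.1) {
  stopifnot(inherits(plan, "message_plan"))
  epochs <- lapply(plan$epochs, function(ep) {
    w <- tapply(ep$weight, ep$barcode, sum)
    setNames(as.numeric(w), names(w))
  })
  programme_spec(epochs, per_epoch_edit_prob)
}

#' Decode a recorded text message from parsed tapes
#'
#' The decoding pipeline: (1) whitelist the site-1 insertions with
#' \code{\link{barcode_whitelist}}; (2) build the pooled adjacent-site bigram
#' matrix over the whitelist; (3) group barcodes into co-transfection sets by
#' complete-linkage hierarchical clustering of the Euclidean distances
#' between bigram-profile rows (each barcode's outgoing and incoming
#' transition profile), cutting the dendrogram at the smallest number of
#' clusters at which no cluster exceeds \code{set_size} members - a
#' deterministic surrogate for cutting by eye; (4) order the sets by the
#' bigram swap algorithm applied to the set-aggregated bigram matrix; (5)
#' order characters within each set by decreasing efficiency-corrected
#' unigram counts summed across all sites (earlier characters were
#' transfected at higher weight); (6) map barcodes back to characters.
#'
#' @param parsed a \code{parsed_reads} list (3-nt barcode config).
#' @param table a \code{\link{tape64_table}}.
#' @param eff optional \code{\link{efficiency_map}} used for the
#'   within-set correction.
#' @param set_size maximum co-transfection set size (default 4).
#' @param whitelist explicit barcode whitelist (skips step 1).
#' @param min_separation passed to \code{\link{barcode_whitelist}}.
#' @return list with \code{text} and \code{diagnostics} (whitelist, clusters,
#'   cluster order, corrected counts).
#' @export
decode_message <- function(parsed, table = tape64_table(), eff = NULL,
                           set_size = 4L, whitelist = NULL,
                           min_separation = 1) {
  stopifnot(inherits(table, "tape64_table"))
  if (is.null(whitelist)) {
    uni1 <- site_unigrams(parsed, n_sites = 1L)[[1]]
    counts1 <- insert_counts(parsed)
    counts1 <- counts1[names(counts1) %in% names(uni1)]
    whitelist <- barcode_whitelist(counts1, min_separation = min_separation)
  }
  if (!length(whitelist)) stop_usage("empty barcode whitelist")
  whitelist <- sort(whitelist)

  bg <- bigram_counts(parsed, symbols = whitelist)
  n <- length(whitelist)

  # ---- group into co-transfection sets --------------------------------
  if (n > set_size) {
    # per-symbol context distributions: outgoing and incoming transition
    # profiles each normalized to unit sum, so co-transfected symbols look
    # alike regardless of their (weight-driven) abundance
    rs <- rowSums(bg); rs[rs == 0] <- 1
    cs <- colSums(bg); cs[cs == 0] <- 1
    prof <- cbind(bg / rs, t(bg) / cs)
    hc <- hclust(stats::dist(prof, method = "euclidean"), method = "complete")
    for (k in seq_len(n)) {
      cl <- cutree(hc, k)
      if (max(table(cl)) <= set_size) break
    }
  } else cl <- setNames(rep(1L, n), whitelist)
  clusters <- split(names(cl), cl)

  # ---- order the sets --------------------------------------------------
  uni1 <- site_unigrams(parsed, n_sites = 1L, whitelist = whitelist)[[1]]
  site1_of <- vapply(clusters, function(m) sum(uni1[m], na.rm = TRUE), numeric(1))
  agg <- matrix(0, length(clusters), length(clusters),
                dimnames = list(names(clusters), names(clusters)))
  for (ci in names(clusters)) for (cj in names(clusters))
    if (ci != cj)
      agg[ci, cj] <- sum(bg[clusters[[ci]], clusters[[cj]], drop = FALSE])
  init <- names(clusters)[order(-site1_of, names(clusters))]
  cl_order <- refine_order(init, agg)

  # ---- order within sets by corrected unigram counts -------------------
  counts <- insert_counts(parsed, whitelist = whitelist)
  corrected <- counts / 2^edit_score(eff, names(counts))
  decoded <- character()
  within <- list()
  for (ci in cl_order$order) {
    m <- clusters[[ci]]
    cc <- setNames(corrected[m], m)
    cc[is.na(cc)] <- 0
    m <- m[order(-cc, m)]
    within[[ci]] <- m
    decoded <- c(decoded, unname(table$inverse[m]))
  }
  list(text = paste(decoded, collapse = ""),
       diagnostics = list(whitelist = whitelist, clusters = clusters,
                          cluster_order = cl_order, within_order = within,
                          corrected_counts = corrected))
}

#' Score a decoded message against the truth
#'
#' Optimal string alignment (Damerau-Levenshtein with adjacent
#' transpositions, all operations at unit cost) with a deterministic
#' backtrace. In the reported decomposition a substitution counts as one
#' deletion plus one insertion (the truth's character was lost and an
#' unintended one appeared), while a transposition counts once and its two
#' characters are not among the correct ones; so
#' correct + deletions_of_truth + 2*transpositions = nchar(truth).
#'
#' @param truth the intended message.
#' @param decoded the recovered message.
#' @return list of class \code{reconstruction_score}: \code{correct}
#'   (matched and correctly ordered characters), \code{deletions},
#'   \code{insertions}, \code{transpositions}, \code{distance} (the OSA edit
#'   distance).
#' @export
score_reconstruction <- function(truth, decoded) {
  a <- strsplit(truth, "", fixed = TRUE)[[1]]
  b <- strsplit(decoded, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- d[i, j] + (a[i] != b[j])
    del <- d[i, j + 1L] + 1L
    ins <- d[i + 1L, j] + 1L
    best <- min(sub, del, ins)
    if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j])
      best <- min(best, d[i - 1L, j - 1L] + 1L)
    d[i + 1L, j + 1L] <- best
  }
  # deterministic backtrace: match > transposition > substitution > del > ins
  i <- n; j <- m
  ops <- c(match = 0L, trans = 0L, sub = 0L, del = 0L, ins = 0L)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && a[i] == b[j] && d[i + 1L, j + 1L] == d[i, j]) {
      ops["match"] <- ops["match"] + 1L; i <- i - 1L; j <- j - 1L
    } else if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j] &&
               d[i + 1L, j + 1L] == d[i - 1L, j - 1L] + 1L) {
      ops["trans"] <- ops["trans"] + 1L; i <- i - 2L; j <- j - 2L
    } else if (i > 0L && j > 0L && d[i + 1L, j + 1L] == d[i, j] + 1L && a[i] != b[j]) {
      ops["sub"] <- ops["sub"] + 1L; i <- i - 1L; j <- j - 1L
    } else if (i > 0L && d[i + 1L, j + 1L] == d[i, j + 1L] + 1L) {
      ops["del"] <- ops["del"] + 1L; i <- i - 1L
    } else {
      ops["ins"] <- ops["ins"] + 1L; j <- j - 1L
    }
  }
  structure(list(correct = unname(ops["match"]),
                 deletions = unname(ops["del"] + ops["sub"]),
                 insertions = unname(ops["ins"] + ops["sub"]),
                 transpositions = unname(ops["trans"]),
                 distance = d[n + 1L, m + 1L]),
            class = "reconstruction_score")
}

#' @export
print.reconstruction_score <- function(x, ...) {
  cat(sprintf("<reconstruction: %d correct | %d del | %d ins | %d swaps>\n",
              x$correct, x$deletions, x$insertions, x$transpositions))
  invisible(x)
}
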