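# integer-coded view of the insert matrix: 0 = unedited, >0 = symbol id
.code_matrix <- function(cohort) {
  v <- cohort$inserts
  syms <- sort(unique(v[v != ""]))
  m <- matrix(match(v, syms, nomatch = 0L), nrow(v), ncol(v),
              dimnames = dimnames(v))
  list(codes = m, symbols = syms)
}

#' Order-aware count of shared edits between two cells
#'
#' Per tape, sites are scanned from site 1 while both cells carry the
#' identical insertion at every site so far; the scan stops at the first site
#' where either cell is unedited or the insertions differ. Only sites inside
#' this identical prefix count: a matching insertion behind a discordant site
#' presumably arose by coincident writing of the same symbol in unrelated
#' cells and carries no lineage signal, so it is discounted. The counts are
#' summed over the panel's tapes.
#'
#' @param cohort a \code{tape_cohort}.
#' @param i,j cell ids or indices.
#' @return integer count of qualified shared edits.
#' @export
shared_edits_order_aware <- function(cohort, i, j) {
  stopifnot(inherits(cohort, "tape_cohort"))
  a <- cohort$inserts[i, ]; b <- cohort$inserts[j, ]
  eq <- (a == b) & (a != "")
  total <- 0L
  for (t in seq_along(cohort$capacity)) {
    e <- eq[cohort$block == t]
    total <- total + sum(cumprod(e))
  }
  as.integer(total)
}

#' Order-aware distance matrix over a cohort
#'
#' d(i, j) = max_shared - shared(i, j), where max_shared defaults to the
#' total number of editable sites on the panel and shared() is the
#' order-aware count of \code{\link{shared_edits_order_aware}}. The diagonal
#' is set to 0 by convention (self-distance), even though
#' max_shared - shared(i, i) is positive for partially edited cells; only
#' off-diagonal entries feed the tree methods.
#'
#' @param cohort a \code{tape_cohort}.
#' @param max_shared maximum attainable shared-edit count (default
#'   \code{sum(cohort$capacity)}).
#' @return symmetric numeric matrix with cell-id dimnames.
#' @export
distance_matrix <- function(cohort, max_shared = NULL) {
  stopifnot(inherits(cohort, "tape_cohort"))
  max_shared <- max_shared %||% sum(cohort$capacity)
  sh <- shared_matrix(cohort)
  d <- max_shared - sh
  diag(d) <- 0
  d
}

#' All-pairs order-aware shared-edit counts
#' @param cohort a \code{tape_cohort}.
#' @return symmetric integer matrix (diagonal = each cell's own qualified
#'   edit count).
#' @export
shared_matrix <- function(cohort) {
  cm <- .code_matrix(cohort)$codes
  n <- nrow(cm)
  blocks <- lapply(seq_along(cohort$capacity),
                   function(t) which(cohort$block == t))
  sh <- matrix(0L, n, n, dimnames = list(cohort$cells, cohort$cells))
  for (i in seq_len(n)) {
    rows <- i:n
    acc <- integer(length(rows))
    for (cols in blocks) {
      run <- rep(1L, length(rows))
      for (s in cols) {
        run <- run * as.integer(cm[rows, s] == cm[i, s] & cm[i, s] > 0L)
        acc <- acc + run
      }
    }
    sh[i, rows] <- acc
    sh[rows, i] <- acc
  }
  sh
}

#' Build a lineage tree from a distance matrix
#'
#' UPGMA (average-linkage agglomeration; rooted, ultrametric) or classical
#' neighbour joining (unrooted). Leaves are sorted by label before
#' clustering, so equal-distance merge ties resolve to the smallest label
#' pair and the output is reproducible.
#'
#' @param dist symmetric nonnegative matrix (or \code{dist}).
#' @param method \code{"upgma"} or \code{"nj"}.
#' @return an ape \code{phylo}; attribute \code{method} records the choice.
#' @export
build_tree <- function(dist, method = c("upgma", "nj")) {
  method <- match.arg(method)
  m <- as.matrix(dist)
  if (nrow(m) < 2) stop_usage("need at least 2 leaves")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  ord <- order(rownames(m))
  m <- m[ord, ord]
  tr <- if (method == "upgma") {
    ape::as.phylo(hclust(as.dist(m), method = "average"))
  } else {
    ape::nj(as.dist(m))
  }
  attr(tr, "method") <- method
  tr
}

#' Fitch small-parsimony score of a cohort on a tree
#'
#' Characters are the editable sites; states are the insertion identities
#' plus explicit "unedited". Unordered Fitch counting: the score is the
#' minimum total number of state changes over the tree, summed across sites.
#' Non-binary trees are resolved arbitrarily (with a warning) before
#' counting, and unrooted binary trees are traversed from their ape root
#' node; for binary trees the count is exact.
#'
#' @param tree an ape \code{phylo} whose tip labels are the cohort's cells.
#' @param cohort a \code{tape_cohort}.
#' @return integer parsimony score.
#' @export
fitch_parsimony <- function(tree, cohort) {
  stopifnot(inherits(tree, "phylo"), inherits(cohort, "tape_cohort"))
  if (!setequal(tree$tip.label, cohort$cells))
    stop_usage("tree tips do not match cohort cells")
  if (!ape::is.binary(tree)) {
    warning("tree has polytomies: resolving arbitrarily before Fitch counting")
    tree <- ape::multi2di(tree)
  }
  cm <- .code_matrix(cohort)$codes  # 0 = unedited, a state in its own right
  S <- ncol(cm)
  nst <- apply(cm, 2, function(v) length(unique(v)))
  if (any(nst > 31)) stop_usage("more than 31 states at a site")
  # per-site state recoding to bit positions
  bits <- matrix(0L, nrow(cm), S)
  for (s in seq_len(S))
    bits[, s] <- bitwShiftL(1L, match(cm[, s], sort(unique(cm[, s]))) - 1L)
  rownames(bits) <- rownames(cm)

  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  masks <- matrix(0L, n_tip + tree$Nnode, S)
  masks[seq_len(n_tip), ] <- bits[tree$tip.label, , drop = FALSE]
  touched <- logical(n_tip + tree$Nnode)
  touched[seq_len(n_tip)] <- TRUE
  score <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (!touched[p]) {
      masks[p, ] <- masks[ch, ]
      touched[p] <- TRUE
    } else {
      inter <- bitwAnd(masks[p, ], masks[ch, ])
      union_needed <- inter == 0L
      masks[p, ] <- ifelse(union_needed, bitwOr(masks[p, ], masks[ch, ]), inter)
      score <- score + sum(union_needed)
    }
  }
  score
}

#' Block bootstrap support for a lineage tree
#'
#' Sites within one tape are not independent (an edit at site i requires
#' edits at 1..i-1), so resampling is done on whole tapes: each replicate
#' draws the panel's tape blocks with replacement, recomputes the order-aware
#' distance (max shared = the resampled site total) and rebuilds the tree.
#' Support for each internal branch of the reference tree is the percentage
#' of replicates containing the same bipartition of cells.
#'
#' @param cohort a \code{tape_cohort}.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer RNG seed.
#' @param method tree method, as in \code{\link{build_tree}}.
#' @param tree optional reference tree (default: tree of the full cohort).
#' @return the reference tree with node labels set to percent support
#'   (class \code{phylo}); the support vector is attached as attribute
#'   \code{support}.
#' @export
bootstrap_support <- function(cohort, n_reps = 100L, seed = 1L,
                              method = "upgma", tree = NULL) {
  stopifnot(inherits(cohort, "tape_cohort"))
  set.seed(as.integer(seed))
  tree <- tree %||% build_tree(distance_matrix(cohort), method)
  B <- length(cohort$capacity)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(B, B, replace = TRUE)
    sub <- subset_blocks(cohort, idx)
    boots[[r]] <- build_tree(distance_matrix(sub), method)
  }
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(tree, boots, rooted = (method == "upgma"))
  cnt[is.na(cnt)] <- 0
  supp <- 100 * cnt / n_reps
  tree$node.label <- round(supp, 1)
  attr(tree, "support") <- supp
  tree
}

#' Cohort-level recording summaries
#'
#' The descriptive statistics used to characterize a recording cohort:
#' per-tape per-site cumulative edit fractions and their cross-tape means;
#' the mean and variance of edits per cell (Poisson-like accrual makes these
#' roughly equal); the distribution of pairwise differences (sites whose
#' states differ, edited-vs-unedited included); each cell's nearest-neighbour
#' difference; active tapes per cell (tapes still below capacity, i.e. still
#' recording); and the unique-pattern census.
#'
#' @param cohort a \code{tape_cohort}.
#' @return list of class \code{cohort_summary}; see fields in the source.
#' @export
cohort_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "tape_cohort"))
  cm <- .code_matrix(cohort)$codes
  n <- nrow(cm)
  per_tape <- lapply(seq_along(cohort$capacity), function(t)
    colMeans(cm[, cohort$block == t, drop = FALSE] > 0L))
  names(per_tape) <- cohort$panel
  max_sites <- max(cohort$capacity)
  site_means <- vapply(seq_len(max_sites), function(s) {
    has <- which(cohort$capacity >= s)
    mean(vapply(has, function(t) per_tape[[t]][s], numeric(1)))
  }, numeric(1))

  edits <- rowSums(cm > 0L)
  edited_per_tape <- vapply(seq_along(cohort$capacity), function(t)
    rowSums(cm[, cohort$block == t, drop = FALSE] > 0L), numeric(n))
  if (n == 1L) edited_per_tape <- matrix(edited_per_tape, nrow = 1)
  active <- rowSums(sweep(edited_per_tape, 2, cohort$capacity, "<"))

  pair_mean <- pair_sd <- NA_real_
  nn <- rep(NA_real_, n)
  total_shared <- NA_real_
  if (n >= 2) {
    diffs <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      rows <- (i + 1):n
      dd <- rowSums(cm[rows, , drop = FALSE] !=
                      matrix(cm[i, ], length(rows), ncol(cm), byrow = TRUE))
      diffs[i, rows] <- dd
      diffs[rows, i] <- dd
    }
    ut <- diffs[upper.tri(diffs)]
    pair_mean <- mean(ut); pair_sd <- stats::sd(ut)
    diag(diffs) <- NA
    nn <- setNames(apply(diffs, 1, min, na.rm = TRUE), cohort$cells)
    sh <- shared_matrix(cohort)
    total_shared <- sum(sh[upper.tri(sh)])
  }

  structure(list(n_cells = n,
                 per_site_cumulative = per_tape,
                 site_means = site_means,
                 edits_per_cell = edits,
                 edits_mean = mean(edits),
                 edits_var = if (n > 1) var(edits) else 0,
                 pairwise_diff_mean = pair_mean,
                 pairwise_diff_sd = pair_sd,
                 nearest_neighbour = nn,
                 nearest_neighbour_mean = if (n > 1) mean(nn) else NA_real_,
                 active_guides = active,
                 active_guides_mean = mean(active),
                 n_fully_edited = sum(edits == ncol(cm)),
                 n_unique_patterns = nrow(unique(cm)),
                 total_shared_order_aware = total_shared,
                 n_pairs = n * (n - 1) / 2),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0("<cohort_summary: %d cells | edits/cell mean %.1f var %.1f",
                     " | %d unique patterns | mean active tapes %.1f>\n"),
              x$n_cells, x$edits_mean, x$edits_var,
              x$n_unique_patterns, x$active_guides_mean))
  invisible(x)
}
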