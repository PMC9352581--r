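# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately re-derive results by brute force / enumeration and
# never call the code paths they check.

# random tape state under a config (optionally with a target barcode)
random_state <- function(cfg, with_tbc = FALSE) {
  k <- sample(0:cfg$n_sites, 1)
  bases <- c("A", "C", "G", "T")
  ins <- if (k) vapply(seq_len(k), function(i)
    paste(sample(bases, cfg$barcode_len, TRUE), collapse = ""), "") else character()
  tbc <- if (with_tbc) paste(sample(bases, 8, TRUE), collapse = "") else ""
  tape_state(ins, cfg, tbc)
}

# prefix classifier, written independently of classify_pattern
oracle_classify <- function(pattern) {
  if (!any(pattern)) return("unedited")
  first_gap <- match(FALSE, pattern, nomatch = length(pattern) + 1L)
  if (any(pattern[seq_along(pattern) >= first_gap])) "nonsequential" else "sequential"
}

# exhaustive two-partition 1-D two-means (checks that the optimal 2-means
# split is found; contiguity in sorted order is itself part of what we test)
oracle_two_means_high <- function(counts) {
  x <- log10(counts + 1)
  n <- length(x)
  best <- NULL; best_wss <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    wss <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    if (wss < best_wss - 1e-12) { best_wss <- wss; best <- grp }
  }
  hi <- if (mean(x[best]) > mean(x[!best])) best else !best
  sort(names(counts)[hi])
}

# brute-force permutation search: order minimizing total below-diagonal mass
oracle_best_order <- function(bg) {
  syms <- rownames(bg)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  below <- vapply(perms(syms), function(p) {
    m <- bg[p, p]
    sum(m[lower.tri(m)])
  }, numeric(1))
  perms(syms)[[which.min(below)]]
}

# per-site scan oracle for the order-aware shared-edit count
oracle_shared <- function(a, b, block) {
  total <- 0L
  for (t in unique(block)) {
    for (s in which(block == t)) {
      if (a[s] == "" || b[s] == "" || a[s] != b[s]) break
      total <- total + 1L
    }
  }
  total
}

# exhaustive Sankoff: minimum changes over all internal-node labelings
oracle_sankoff <- function(tree, tip_states) {
  stopifnot(ape::is.binary(tree), ape::is.rooted(tree))
  states <- sort(unique(tip_states))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  combos <- expand.grid(rep(list(states), n_int), stringsAsFactors = FALSE)
  node_state <- function(combo, node)
    if (node <= n_tip) tip_states[tree$tip.label[node]] else combo[[node - n_tip]]
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    combo <- combos[r, , drop = TRUE]
    if (n_int == 1) combo <- list(combos[r, 1])
    ch <- sum(vapply(seq_len(nrow(tree$edge)), function(e)
      node_state(combo, tree$edge[e, 1]) != node_state(combo, tree$edge[e, 2]),
      logical(1)))
    best <- min(best, ch)
  }
  best
}

# small cohort straight from an insert matrix (cells x sites)
cohort_from_matrix <- function(m, capacity, panel = NULL) {
  panel <- panel %||% paste0("TB", seq_along(capacity))
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  structure(list(cells = rownames(m), inserts = m, panel = panel,
                 capacity = as.integer(capacity),
                 block = rep(seq_along(capacity), capacity)),
            class = "tape_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 16-epoch single-barcode programme used by ordering tests
programme16 <- function(p = 0.1) {
  syms <- default_symbols(16, 2)
  programme_spec(lapply(syms, function(b) stats::setNames(1, b)), p)
}

mild_efficiency <- function(symbols, seed, sd = 0.5) {
  set.seed(seed)
  efficiency_map(stats::setNames(stats::rnorm(length(symbols), 0, sd), symbols))
}
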