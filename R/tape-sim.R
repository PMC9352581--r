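#' Render a tape state as its DNA sequence
#'
#' The canonical rendering convention: the target barcode, then the key, then
#' for each site the monomer followed, if the site is edited, by its insertion
#' barcode plus the key. Each edit therefore deposits barcode+key at the
#' junction 3' of the monomer it targeted, which is what completes the spacer
#' of the following monomer. Total length is
#' |target_bc| + |key| + n_sites*|monomer| + n_edits*(barcode_len+|key|).
#'
#' @param state a \code{\link{tape_state}}, or a list of insertion barcodes.
#' @param config a \code{\link{tape_config}} (defaults to the state's own).
#' @return single DNA string.
#' @examples
#' cfg <- tape_config(n_sites = 2)
#' render_tape(tape_state(character(), cfg))   # unedited 2x array
#' render_tape(tape_state("CA", cfg))          # one CA+GGA insertion
#' @export
render_tape <- function(state, config = NULL) {
  if (!inherits(state, "tape_state"))
    state <- tape_state(state, config %||% tape_config())
  config <- config %||% state$config
  k <- length(state$inserts)
  if (k && any(nchar(state$inserts) != config$barcode_len))
    stop_usage("insertion barcodes must have length %d", config$barcode_len)
  junction <- rep("", config$n_sites)
  if (k) junction[seq_len(k)] <- paste0(state$inserts, config$key)
  paste0(state$target_bc, config$key,
         paste0(config$monomer, junction, collapse = ""))
}

#' Render many tape states at once
#' @param states a \code{tape_state_set} (e.g. from
#'   \code{\link{simulate_programme}}) or a list of \code{tape_state}s.
#' @return character vector of DNA strings.
#' @export
render_tapes <- function(states) {
  if (inherits(states, "tape_state_set")) {
    cfg <- states$config
    junc <- ifelse(states$inserts == "", "", paste0(states$inserts, cfg$key))
    body <- do.call(paste0, lapply(seq_len(ncol(junc)),
                                   function(j) paste0(cfg$monomer, junc[, j])))
    return(paste0(states$target_bc, cfg$key, body))
  }
  vapply(states, render_tape, character(1))
}

#' Append one edit at the next free site
#'
#' Writes \code{barcode} to the first unedited site. A full tape raises a
#' classed condition (\code{tapewriter_tape_exhausted}): exhaustion is an
#' expected state of a recorder, so callers decide whether it is an error.
#' Simulators treat full tapes as silently inactive.
#'
#' @param state a \code{\link{tape_state}}.
#' @param barcode insertion barcode of the configured length.
#' @return the updated \code{tape_state}.
#' @export
step_edit <- function(state, barcode) {
  stopifnot(inherits(state, "tape_state"))
  if (length(state$inserts) >= state$config$n_sites) {
    cond <- structure(class = c("tapewriter_tape_exhausted", "error", "condition"),
                      list(message = "tape exhausted: all sites already edited",
                           call = sys.call()))
    stop(cond)
  }
  tape_state(c(state$inserts, barcode), state$config, state$target_bc)
}

#' Simulate a multi-epoch transfection programme on a population of tapes
#'
#' Each epoch approximates one transient transfection: a tape that still has a
#' free site gains at most one edit, with the barcode drawn among the epoch's
#' mix in proportion to mix_weight * 2^edit_score. By default the per-epoch
#' edit probability itself is also scaled by the weight-averaged 2^edit_score
#' of the epoch's mix (capped at 1): a low-efficiency pegRNA writes less often
#' overall, not just relative to co-transfected competitors, which is what
#' distorts site-1 unigram frequencies away from the epoch order. Set
#' \code{scale_rate_by_efficiency = FALSE} for a rate that ignores scores.
#'
#' @param prog a \code{\link{programme_spec}}.
#' @param config a \code{\link{tape_config}}.
#' @param n_tapes number of independent arrays.
#' @param eff an \code{\link{efficiency_map}} (NULL = all-neutral).
#' @param seed integer RNG seed.
#' @param scale_rate_by_efficiency see Description.
#' @return A \code{tape_state_set}: list with the config, a character matrix
#'   \code{inserts} (n_tapes x n_sites, "" = unedited) and \code{target_bc}.
#' @export
simulate_programme <- function(prog, config, n_tapes, eff = NULL, seed,
                               scale_rate_by_efficiency = TRUE) {
  stopifnot(inherits(prog, "programme_spec"), inherits(config, "tape_config"))
  if (prog$barcode_len != config$barcode_len)
    stop_usage("programme barcodes (%d nt) incompatible with config barcode_len (%d)",
               prog$barcode_len, config$barcode_len)
  set.seed(as.integer(seed))
  ins <- matrix("", nrow = n_tapes, ncol = config$n_sites)
  ned <- integer(n_tapes)
  for (ep in prog$epochs) {
    bcs <- names(ep)
    w <- as.numeric(ep) * 2^edit_score(eff, bcs)
    p <- prog$per_epoch_edit_prob
    if (scale_rate_by_efficiency) p <- min(1, p * sum(w) / sum(ep))
    hit <- which(runif(n_tapes) < p & ned < config$n_sites)
    if (length(hit)) {
      sym <- if (length(bcs) == 1L) rep(bcs, length(hit)) else
        sample(bcs, length(hit), replace = TRUE, prob = w)
      ins[cbind(hit, ned[hit] + 1L)] <- sym
      ned[hit] <- ned[hit] + 1L
    }
  }
  structure(list(config = config, inserts = ins, target_bc = ""),
            class = "tape_state_set")
}

#' @export
print.tape_state_set <- function(x, ...) {
  cat(sprintf("<tape_state_set: %d tapes x %d sites, %.2f edits/tape>\n",
              nrow(x$inserts), ncol(x$inserts), mean(rowSums(x$inserts != ""))))
  invisible(x)
}

#' Convert a tape_state_set to a list of tape_state objects
#' @param x a \code{tape_state_set}.
#' @return list of \code{\link{tape_state}}.
#' @export
as_tape_states <- function(x) {
  stopifnot(inherits(x, "tape_state_set"))
  lapply(seq_len(nrow(x$inserts)), function(i) {
    v <- x$inserts[i, ]
    tape_state(v[v != ""], x$config, x$target_bc)
  })
}

# one synchronous division step for one cell's tape complement (internal)
.divide_tapes <- function(sites, ned, offsets, capacity, p, symbols, w) {
  active <- ned < capacity
  hit <- which(runif(length(ned)) < p & active)
  if (length(hit)) {
    sym <- if (length(symbols) == 1L) rep(symbols, length(hit)) else
      sample(symbols, length(hit), replace = TRUE, prob = w)
    sites[offsets[hit] + ned[hit] + 1L] <- sym
    ned[hit] <- ned[hit] + 1L
  }
  list(sites = sites, ned = ned)
}

#' Simulate recording during clonal expansion
#'
#' A founder with all-unedited tapes divides synchronously for
#' \code{generations} doublings. At every division each daughter,
#' independently and for each tape that still has free sites, gains one edit
#' with the per-tape per-division probability, the symbol drawn in proportion
#' to 2^edit_score. \code{sample_size} leaves are then sampled uniformly
#' without replacement and returned together with the induced true genealogy.
#' Only the sampled lineages are simulated, so deep trees are cheap; RNG
#' traversal order is fixed (left child first), making output deterministic
#' under the seed.
#'
#' @param params a \code{\link{clone_sim_params}}.
#' @return list with \code{cells} (a data.table: cell_id, target_bc,
#'   site1..siteK, "" = unedited), \code{newick} (true genealogy, branch
#'   lengths in divisions) and \code{tree} (an ape \code{phylo}, NULL when the
#'   sample has a single leaf).
#' @export
simulate_clone <- function(params) {
  stopifnot(inherits(params, "clone_sim_params"))
  G <- params$generations
  caps <- params$tape_site_counts
  offsets <- c(0L, cumsum(caps))[seq_along(caps)]
  total <- sum(caps)
  w <- 2^edit_score(params$efficiency, params$symbols)
  p <- params$per_tape_per_division_edit_prob
  set.seed(params$seed)
  leaves <- sort(sample.int(2^G, params$sample_size) - 1)  # leaf ids, 0-based

  cell_sites <- list()
  cell_ids <- character()
  pad <- max(6L, nchar(as.character(max(leaves))))

  rec <- function(depth, leafset, sites, ned) {
    if (depth == G) {
      id <- sprintf("cell_%0*d", pad, leafset[1])
      cell_ids[[length(cell_ids) + 1L]] <<- id
      cell_sites[[length(cell_sites) + 1L]] <<- sites
      return(list(nwk = id, len = 0))
    }
    bit <- bitwAnd(bitwShiftR(leafset, G - depth - 1L), 1L)
    out <- list()
    for (side in 0:1) {
      sub <- leafset[bit == side]
      if (!length(sub)) next
      st <- .divide_tapes(sites, ned, offsets, caps, p, params$symbols, w)
      out[[length(out) + 1L]] <- rec(depth + 1L, sub, st$sites, st$ned)
    }
    if (length(out) == 2L)
      list(nwk = sprintf("(%s:%d,%s:%d)", out[[1]]$nwk, out[[1]]$len + 1L,
                         out[[2]]$nwk, out[[2]]$len + 1L),
           len = 0L)
    else
      list(nwk = out[[1]]$nwk, len = out[[1]]$len + 1L)
  }

  if (G == 0L) {
    cell_ids <- sprintf("cell_%0*d", pad, 0L)
    cell_sites <- list(rep("", total))
    newick <- paste0(cell_ids, ";")
  } else {
    root <- rec(0L, leaves, rep("", total), integer(length(caps)))
    newick <- paste0(root$nwk, ";")
  }

  mat <- do.call(rbind, cell_sites)
  dt <- data.table::rbindlist(lapply(seq_along(caps), function(t) {
    cols <- (offsets[t] + 1L):(offsets[t] + caps[t])
    d <- data.table::data.table(cell_id = cell_ids,
                                target_bc = params$target_bcs[t])
    for (s in seq_len(max(caps)))
      d[[paste0("site", s)]] <- if (s <= caps[t]) mat[, cols[s]] else NA_character_
    d
  }))
  data.table::setorder(dt, cell_id, target_bc)
  tree <- if (length(cell_ids) >= 2) ape::read.tree(text = newick) else NULL
  list(cells = dt, newick = newick, tree = tree)
}

#' Inject uniform substitution noise into sequences
#'
#' Every base is independently replaced, with probability \code{sub_rate}, by
#' a uniformly drawn different base. Supports vectors of sequences; artifact
#' plumbing for testing error-filtering stages, not an error model of any
#' particular sequencer.
#'
#' @param seq character vector of DNA sequences.
#' @param sub_rate per-base substitution probability in [0, 1].
#' @param seed integer RNG seed.
#' @return character vector of mutated sequences.
#' @export
add_read_noise <- function(seq, sub_rate, seed) {
  if (sub_rate < 0 || sub_rate > 1) stop_usage("sub_rate must be in [0, 1]")
  set.seed(as.integer(seed))
  if (sub_rate == 0) return(seq)
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < sub_rate
    n <- sum(hit)
    if (n) {
      idx <- match(ch[hit], .DNA_BASES)
      ch[hit] <- .DNA_BASES[((idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Size of the joint sequential-editing state space (log10)
#'
#' A tape with m sites under strictly sequential editing with an n-symbol
#' alphabet can be in sum_{k=0..m} n^k distinct states (the k edited sites are
#' always the first k). Independent tapes multiply, so the log10 state count
#' is additive across tapes. Also reports the loose upper bound
#' total_sites * log10(n) that ignores sequentiality.
#'
#' @param site_counts integer vector of per-tape site capacities.
#' @param n_symbols alphabet size (>= 1).
#' @return list with \code{log10_states} (exact) and \code{log10_upper}
#'   (simple bound).
#' @examples
#' state_space_log10(c(rep(5, 9), rep(4, 3), 2), 19)  # ~10^75 joint states
#' @export
state_space_log10 <- function(site_counts, n_symbols) {
  if (n_symbols < 1) stop_usage("n_symbols must be >= 1")
  per_tape <- vapply(site_counts, function(m)
    log10(sum(n_symbols^(0:m))), numeric(1))
  list(log10_states = sum(per_tape),
       log10_upper = sum(site_counts) * log10(n_symbols))
}
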