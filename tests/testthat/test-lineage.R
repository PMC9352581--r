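wl <- DEFAULT_TARGETBCS[1:5]

test_that("correct_targetbc corrects at Hamming 1 and drops beyond", {
  res <- correct_targetbc(c(wl[1], sub("^A", "T", wl[1])), wl)
  expect_identical(res$corrected, c(wl[1], wl[1]))
  expect_identical(res$reason, c("exact", "corrected"))

  two_off <- paste0("TT", substr(wl[1], 3, 8))
  res2 <- correct_targetbc(two_off, wl)
  expect_true(is.na(res2$corrected))
  expect_identical(res2$reason, "too-distant")

  expect_warning(correct_targetbc("AAAAAAAA", c("AAAAAAAT", "AAAAAAAG")),
                 "ambiguous")
})

test_that("collapse_umis enforces UMI support and resolves conflicts", {
  rows <- data.frame(
    cell_id = c("c1", "c2", "c2", "c2", "c3", "c3", "c3", "c3", "c4", "c4"),
    umi = c("u1", "u1", "u2", "u3", "u1", "u2", "u3", "u4", "u1", "u2"),
    target_bc = "TB1",
    tape = c("S", "S", "S", "S", "S1", "S1", "S1", "S2", "Sa", "Sb"),
    stringsAsFactors = FALSE)
  out <- collapse_umis(rows)
  expect_false("c1" %in% out$cell_id)                  # 1 UMI: dropped
  expect_identical(out[out$cell_id == "c2"]$tape, "S") # 3 UMIs: kept
  expect_identical(out[out$cell_id == "c3"]$tape, "S1")# 3 vs 1: majority
  expect_false("c4" %in% out$cell_id)                  # 1 vs 1 after filter
})

test_that("select_complete_cells keeps only whitelisted complete cells", {
  panel <- c("TB1", "TB2")
  rec <- data.frame(
    cell_id = c("a", "a", "b", "c", "c", "d", "d"),
    target_bc = c("TB1", "TB2", "TB1", "TB1", "TB2", "TB1", "TB2"),
    site1 = c("AAA", "CCC", "AAA", "AAA", "ZZZ", "", "AAA"),
    site2 = c("", "GGG", "", "", "", "AAA", ""),
    stringsAsFactors = FALSE)
  co <- select_complete_cells(rec, panel, insertbc_whitelist = c("AAA", "CCC", "GGG"))
  expect_identical(co$cells, "a")                       # complete + clean
  drops <- attr(co, "dropped")
  expect_identical(unname(drops["b"]), "missing-tape")
  expect_identical(unname(drops["c"]), "off-whitelist-insert")
  expect_identical(unname(drops["d"]), "nonsequential")
  expect_identical(co$capacity, c(2L, 2L))

  # no dropout, no whitelist: everything complete is retained
  co2 <- select_complete_cells(rec[rec$cell_id %in% c("a", "c"), ], panel)
  expect_setequal(co2$cells, c("a", "c"))
})

test_that("shared_edits_order_aware counts identical prefixes only", {
  m <- rbind(c1 = c("X", "Y", "", "A", ""),
             c2 = c("Z", "Y", "", "A", ""),
             c3 = c("X", "Y", "", "A", ""))
  co <- cohort_from_matrix(m, capacity = c(3L, 2L))
  # same prefix everywhere: all 3 edits shared
  expect_identical(shared_edits_order_aware(co, "c1", "c3"), 3L)
  # tape 1: site-1 mismatch discounts the site-2 match; tape 2 still counts
  expect_identical(shared_edits_order_aware(co, "c1", "c2"), 1L)

  set.seed(33)
  syms <- c("P", "Q", "R", "")
  for (rep in 1:30) {
    caps <- sample(1:4, sample(2:4, 1), replace = TRUE)
    n <- 4
    mat <- t(vapply(seq_len(n), function(i) {
      unlist(lapply(caps, function(cp) {
        k <- sample(0:cp, 1)
        c(sample(c("P", "Q", "R"), k, TRUE), rep("", cp - k))
      }))
    }, character(sum(caps))))
    co <- cohort_from_matrix(mat, caps)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_identical(shared_edits_order_aware(co, i, j),
                       oracle_shared(mat[i, ], mat[j, ], co$block))
    }
    sh <- shared_matrix(co)
    expect_identical(sh[2, 4], shared_edits_order_aware(co, 2, 4))
    expect_true(isSymmetric(sh))
  }
})

test_that("distance_matrix is max_shared minus shared with a zero diagonal", {
  caps <- c(rep(5L, 9), rep(4L, 3), 2L)
  # two identical cells with 40 edits -> d = 59 - 40 = 19
  row <- unlist(lapply(caps, function(cp) {
    k <- min(cp, 4L)  # 4 edits on 5/4-site tapes, 2 on the 2-site: 4*12+2 = 50
    c(rep("AAA", k), rep("", cp - k))
  }))
  m <- rbind(c1 = row, c2 = row, founder = rep("", sum(caps)))
  m["c2", 3] <- m["c1", 3]
  edits <- sum(m["c1", ] != "")
  co <- cohort_from_matrix(m, caps)
  d <- distance_matrix(co)
  expect_equal(d["c1", "c2"], 59 - edits)
  expect_equal(d["c1", "founder"], 59)
  expect_true(all(diag(d) == 0))
  expect_true(isSymmetric(d))
  # pairwise range invariant: d(i,j) in [59 - min(edits_i, edits_j), 59]
  edits_all <- rowSums(m != "")
  for (i in 1:2) for (j in (i + 1):3)
    expect_true(d[i, j] >= 59 - min(edits_all[i], edits_all[j]) &&
                  d[i, j] <= 59)
})

test_that("build_tree: UPGMA closed form and ultrametricity, NJ exactness", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(d, "upgma")
  bt <- sort(unname(ape::branching.times(tr)))
  expect_equal(bt, c(1, 3))
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))

  # random additive metrics: NJ recovers topology and branch lengths
  set.seed(14)
  for (n in c(4, 6, 8)) {
    true <- ape::rtree(n, br = function(k) runif(k, 1, 5))
    D <- cophenetic(true)
    nj_tr <- build_tree(D, "nj")
    expect_equal(ape::dist.topo(ape::unroot(true), nj_tr)[1], 0)
    expect_equal(cophenetic(nj_tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }

  # UPGMA trees are ultrametric within numerical tolerance
  set.seed(15)
  rd <- matrix(runif(64, 1, 10), 8, 8); rd <- rd + t(rd); diag(rd) <- 0
  rownames(rd) <- colnames(rd) <- paste0("t", 1:8)
  up <- build_tree(rd, "upgma")
  expect_true(ape::is.ultrametric(up, tol = 1e-9))
  expect_error(build_tree(matrix(0, 1, 1)), "2 leaves")
})

test_that("fitch_parsimony equals exhaustive Sankoff on small instances", {
  m2 <- rbind(a = c("X", ""), b = c("X", ""))
  co2 <- cohort_from_matrix(m2, 2L)
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_identical(fitch_parsimony(tr2, co2), 0L)

  m3 <- rbind(a = c("X", "Y", "Z"), b = c("X", "Q", ""))
  expect_identical(fitch_parsimony(ape::read.tree(text = "(a:1,b:1);"),
                                   cohort_from_matrix(m3, 3L)), 2L)

  set.seed(55)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    tips <- letters[seq_len(n)]
    tr <- ape::rtree(n, tip.label = tips)
    sites <- 4
    mat <- matrix(sample(c("P", "Q", "R", ""), n * sites, TRUE), n, sites,
                  dimnames = list(tips, NULL))
    co <- cohort_from_matrix(mat, rep(1L, sites))
    want <- sum(vapply(seq_len(sites), function(s) {
      st <- stats::setNames(mat[, s], tips)
      oracle_sankoff(tr, st)
    }, numeric(1)))
    expect_identical(fitch_parsimony(tr, co), as.integer(want))
  }
})

test_that("block bootstrap gives full support to a deep split", {
  # two clades separated by discordant early edits on every tape
  caps <- rep(3L, 4)
  cladeA <- unlist(lapply(caps, function(cp) c("P", "P", "")))
  cladeB <- unlist(lapply(caps, function(cp) c("Q", "Q", "")))
  jitter <- function(v, i) { v[3 * i] <- "R"; v }
  m <- rbind(a1 = cladeA, a2 = jitter(cladeA, 1), a3 = jitter(cladeA, 2),
             b1 = cladeB, b2 = jitter(cladeB, 1), b3 = jitter(cladeB, 2))
  co <- cohort_from_matrix(m, caps)
  bs <- bootstrap_support(co, n_reps = 50, seed = 9)
  supp <- attr(bs, "support")
  split_node <- ape::getMRCA(bs, c("a1", "a2", "a3"))
  expect_equal(supp[split_node - length(bs$tip.label)], 100)

  bs1 <- bootstrap_support(co, n_reps = 1, seed = 2)
  expect_true(all(attr(bs1, "support") %in% c(0, 100)))
})

test_that("cohort_summaries reports the recording statistics", {
  caps <- c(rep(5L, 9), rep(4L, 3), 2L)
  founder <- cohort_from_matrix(rbind(f1 = rep("", 59), f2 = rep("", 59)), caps)
  s0 <- cohort_summaries(founder)
  expect_equal(s0$edits_mean, 0)
  expect_equal(s0$edits_var, 0)
  expect_equal(s0$active_guides_mean, 13)
  expect_equal(s0$n_unique_patterns, 1)

  sat <- cohort_from_matrix(rbind(s1 = rep("AAA", 59), s2 = rep("AAA", 59)), caps)
  ss <- cohort_summaries(sat)
  expect_equal(ss$active_guides_mean, 0)
  expect_true(all(ss$site_means == 1))
  expect_equal(ss$n_fully_edited, 2)

  m <- rbind(x = c("P", "Q", "", ""), y = c("P", "R", "R", ""))
  sm <- cohort_summaries(cohort_from_matrix(m, c(2L, 2L)))
  expect_equal(sm$pairwise_diff_mean, 2)   # sites 2 and 3 differ
  expect_equal(sm$nearest_neighbour, c(x = 2, y = 2))
  expect_equal(sm$total_shared_order_aware, 1)  # only the site-1 P qualifies
})
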