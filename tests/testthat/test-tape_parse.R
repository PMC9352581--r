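cfg5 <- tape_config(n_sites = 5)
M <- cfg5$monomer; K <- cfg5$key

test_that("extract_insertions flags wrong-key and broken scaffolds", {
  # wrong key TGA after the barcode CA
  bad <- paste0(K, M, "CA", "TGA", M, M, M, M)
  p <- extract_insertions(bad, cfg5)
  expect_false(p$valid)
  expect_identical(p$reason, "wrong-key")

  trunc <- paste0(K, M, "C")
  expect_identical(extract_insertions(trunc, cfg5)$reason, "truncated")
  expect_identical(extract_insertions("ACGTACGTACGT", cfg5)$reason, "no-scaffold")

  # a single monomer substitution is rescued only with tolerance 1
  mut <- paste0(K, M, "CA", K, sub("G", "T", M), M, M, M)
  expect_false(extract_insertions(mut, cfg5)$valid)
  ok <- extract_insertions(mut, cfg5, max_monomer_mismatch = 1)
  expect_true(ok$valid)
  expect_identical(ok$inserts, "CA")
})

test_that("nonsequential physical patterns are recovered as such", {
  # sites 1,2 edited on a 5x array -> XXOOO, sequential
  seq_read <- render_tape(tape_state(c("AC", "GT"), cfg5))
  p <- extract_insertions(seq_read, cfg5)
  expect_identical(p$pattern, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(classify_pattern(p$pattern), "sequential")

  # hand-built OX read: second junction edited, first clean
  ox <- paste0(K, M, M, "CA", K, M, M, M)
  p2 <- extract_insertions(ox, cfg5)
  expect_true(p2$valid)
  expect_identical(p2$pattern[1:2], c(FALSE, TRUE))
  expect_identical(classify_pattern(p2$pattern), "nonsequential")
})

test_that("classify_pattern partitions all patterns like the prefix oracle", {
  for (n in c(2L, 5L, 8L, 12L)) {
    pats <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    cls <- apply(pats, 1, classify_pattern)
    orc <- apply(pats, 1, oracle_classify)
    expect_identical(cls, orc)
    expect_equal(as.integer(table(cls)[c("unedited", "sequential")]),
                 c(1L, n))
    expect_equal(sum(cls == "nonsequential"), 2^n - n - 1)
  }
  expect_error(classify_pattern(logical()), "empty")
})

test_that("editing_metrics implements the efficiency / error-rate formulas", {
  mk <- function(pattern) structure(list(read_id = NA, read = "", target_bc = "",
                                         inserts = rep("AA", sum(pattern)),
                                         n_monomers_observed = length(pattern),
                                         pattern = pattern, valid = TRUE,
                                         reason = NA), class = "parsed_read")
  reads <- c(replicate(6, mk(c(FALSE, FALSE)), simplify = FALSE),
             replicate(3, mk(c(TRUE, FALSE)), simplify = FALSE),
             list(mk(c(FALSE, TRUE))))
  m <- editing_metrics(reads)
  expect_equal(m$efficiency, 0.4)
  expect_equal(m$sequential_error_rate, 0.25)
  expect_equal(sum(m$read_counts), length(reads))

  m0 <- editing_metrics(replicate(5, mk(c(FALSE, FALSE)), simplify = FALSE))
  expect_equal(m0$efficiency, 0)
  expect_true(is.na(m0$sequential_error_rate))

  # conditional rates: 100 reads, 20 edited at site 1, 5 of those at site 2
  reads2 <- c(replicate(80, mk(c(FALSE, FALSE)), simplify = FALSE),
              replicate(15, mk(c(TRUE, FALSE)), simplify = FALSE),
              replicate(5, mk(c(TRUE, TRUE)), simplify = FALSE))
  m2 <- editing_metrics(reads2)
  expect_equal(m2$per_site_conditional, c(0.20, 0.25))
})

test_that("barcode_whitelist matches the exhaustive two-means oracle", {
  expect_setequal(barcode_whitelist(c(A = 1000, B = 900, C = 2, D = 1)),
                  c("A", "B"))
  expect_setequal(barcode_whitelist(c(X = 5000, a = 3, b = 2, c = 1)), "X")
  expect_setequal(barcode_whitelist(c(A = 10, B = 10, C = 10)),
                  c("A", "B", "C"))
  # key-suffix pre-filter
  expect_setequal(
    barcode_whitelist(c(CAGGA = 900, TTGGA = 800, CATGA = 850, AAGGA = 2),
                      key = "GGA"),
    c("CAGGA", "TTGGA"))
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    counts <- stats::setNames(
      round(10^(runif(n, 0, 4))),
      paste0("b", seq_len(n)))
    got <- barcode_whitelist(counts, min_separation = 0)
    expect_setequal(got, oracle_two_means_high(counts))
  }
})

test_that("whitelist recovers exactly the true symbols from a noisy run", {
  # 3-nt barcodes: substitution errors mostly fall outside the 16-symbol set
  syms <- default_symbols(16, 3)
  cfg3 <- tape_config(n_sites = 5, barcode_len = 3)
  prog <- programme_spec(lapply(syms, function(b) stats::setNames(1, b)), 0.25)
  sim <- simulate_programme(prog, cfg3, 12000, seed = 6)
  noisy <- add_read_noise(render_tapes(sim), 0.002, seed = 7)
  parsed <- parse_reads(noisy, cfg3)
  counts <- insert_counts(parsed)
  expect_gt(length(counts), 16)            # noise created error species
  expect_setequal(barcode_whitelist(counts), syms)
})

test_that("compute_edit_scores is a mean log2 enrichment with pseudocounts", {
  ab <- c(AA = 0.25, CC = 0.25, GG = 0.25, TT = 0.25)
  eq <- compute_edit_scores(c(AA = 500, CC = 500, GG = 500, TT = 500), ab)
  expect_equal(unname(unclass(eq)), rep(0, 4), tolerance = 1e-6)

  f2 <- compute_edit_scores(c(AA = 2000, CC = 1000, GG = 1000, TT = 1000), ab)
  expect_equal(unclass(f2)[["AA"]], log2((2 / 5) / (1 / 4)), tolerance = 1e-3)

  # replicate averaging and invariance to common rescaling
  r1 <- c(AA = 100, CC = 300); r2 <- c(AA = 200, CC = 600)
  ab2 <- c(AA = 0.5, CC = 0.5)
  s12 <- compute_edit_scores(list(r1, r2), ab2)
  s11 <- compute_edit_scores(list(r1, r1), ab2)
  expect_equal(unclass(s12)[["CC"]], unclass(s11)[["CC"]], tolerance = 1e-3)

  expect_error(compute_edit_scores(c(AA = 1, NN = 1), ab), "absent")
})

test_that("group_long_reads picks max-monomer, then max-edit representatives", {
  cfg12 <- tape_config(n_sites = 12, barcode_len = 3)
  mk <- function(tbc, n_sites, inserts)
    extract_insertions(render_tape(tape_state(inserts,
                                              tape_config(n_sites = n_sites,
                                                          barcode_len = 3),
                                              target_bc = tbc)),
                       cfg12)
  one <- mk("AAAAAAAA", 12, c("ACT", "CAT"))
  grp <- group_long_reads(list(one))
  expect_identical(grp[["AAAAAAAA"]]$inserts, c("ACT", "CAT"))

  reads <- list(mk("CCCCCCCC", 12, rep("ACT", 3)),
                mk("CCCCCCCC", 9, rep("ACT", 3)),
                mk("CCCCCCCC", 12, rep("GAC", 5)))
  rep_read <- group_long_reads(reads)[["CCCCCCCC"]]
  expect_identical(rep_read$n_monomers_observed, 12L)
  expect_identical(length(rep_read$inserts), 5L)

  # length-inconsistent (truncated) reads never become representatives
  broken <- extract_insertions(substr(reads[[3]]$read, 1, 40), cfg12)
  expect_false(broken$valid)
  grp2 <- group_long_reads(c(reads[2], list(broken)))
  expect_identical(grp2[["CCCCCCCC"]]$n_monomers_observed, 9L)
})
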