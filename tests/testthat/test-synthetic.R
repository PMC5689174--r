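# synthetic-genome module: background composition, the divergence process,
# insertion bookkeeping, truth round-trips, annotation tables

test_that("background genome has forced length, target GC and is seed-deterministic", {
  g <- simulate_background(10000, 0.5, seed = 1)
  expect_equal(Biostrings::width(g), 10000L)
  expect_identical(as.character(g), as.character(simulate_background(10000, 0.5, seed = 1)))
  expect_false(identical(as.character(g), as.character(simulate_background(10000, 0.5, seed = 2))))

  big <- simulate_background(100000, 0.528, seed = 7)
  gc <- sum(Biostrings::letterFrequency(big, c("G", "C"))) / 100000
  expect_lt(abs(gc - 0.528), 3 * sqrt(0.528 * (1 - 0.528) / 100000))

  expect_error(simulate_background(500, 0.5), "1000")
  expect_error(simulate_background(10000, 1.2), "gc_fraction")
})

test_that("age zero leaves the LTR pair identical; transition_fraction = 1 forces transitions", {
  ltr <- substr(unname(as.character(simulate_background(2000, 0.5, seed = 3))), 1, 1000)
  p0 <- age_ltr_pair(ltr, 0, seed = 1)
  expect_identical(p0$ltr5, p0$ltr3)
  expect_identical(p0$ltr5, ltr)

  p1 <- age_ltr_pair(ltr, 2e7, transition_fraction = 1, seed = 2)
  a <- strsplit(p1$ltr5, "")[[1]]; b <- strsplit(p1$ltr3, "")[[1]]
  d <- which(a != b)
  expect_gt(length(d), 0)
  is_transition <- (a[d] == "A" & b[d] == "G") | (a[d] == "G" & b[d] == "A") |
    (a[d] == "C" & b[d] == "T") | (a[d] == "T" & b[d] == "C")
  expect_true(all(is_transition))

  expect_error(age_ltr_pair(ltr, -1), "age_T")
})

test_that("mean pair divergence matches the analytic jump-chain expectation", {
  # calibration at 10 MY on long repeats, then a sweep to 50 MY
  ltr <- as.character(simulate_background(10000, 0.5, seed = 5))
  r <- 1.05e-9
  cases <- list(list(len = 10000L, T = 1e7, reps = 50L),
                list(len = 2000L, T = 2.5e7, reps = 50L),
                list(len = 2000L, T = 5e7, reps = 50L))
  for (cs in cases) {
    seqs <- substr(ltr, 1, cs$len)
    obs <- vapply(seq_len(cs$reps), function(i) {
      p <- age_ltr_pair(seqs, cs$T, rate_r = r, seed = 1000L + i)
      mean(strsplit(p$ltr5, "")[[1]] != strsplit(p$ltr3, "")[[1]])
    }, 0)
    expected <- oracle_expected_mismatch(2 * r * cs$T)
    se <- sqrt(expected * (1 - expected) / (cs$len * cs$reps))
    expect_lt(abs(mean(obs) - expected), 3 * se)
  }
})

test_that("insertion bookkeeping is additive and truth coordinates excise the elements", {
  tmpl <- fx_gypsy_template()
  elen <- nchar(tmpl$ltr_sequence) * 2L + nchar(tmpl$internal_sequence)
  bg <- simulate_background(100000, 0.5, seed = 11)
  sim <- insert_elements(bg, list(tmpl), simulation_config(n_insertions = 3, ages = 0, seed = 12))
  expect_equal(Biostrings::width(sim$genome),
               100000L + 3L * elen + sum(nchar(sim$truth$tsd)))
  gseq <- as.character(sim$genome[[1]])
  for (i in seq_len(nrow(sim$truth))) {
    r <- sim$truth[i, ]
    expect_identical(substr(gseq, r$ltr5_start, r$ltr5_end),
                     substr(gseq, r$ltr3_start, r$ltr3_end))  # age 0: identical LTRs
    expect_identical(substr(gseq, r$start - nchar(r$tsd), r$start - 1L),
                     substr(gseq, r$end + 1L, r$end + nchar(r$tsd)))  # TSD flanks
  }
})

test_that("excised truth LTR pairs show divergence consistent with their age", {
  sim <- fx_small_sim()
  gseq <- as.character(sim$genome[[1]])
  full <- sim$truth[!sim$truth$truncated & !sim$truth$solo, ]
  for (i in seq_len(nrow(full))) {
    r <- full[i, ]
    a <- strsplit(substr(gseq, r$ltr5_start, r$ltr5_end), "")[[1]]
    b <- strsplit(substr(gseq, r$ltr3_start, r$ltr3_end), "")[[1]]
    p <- mean(a != b)
    expected <- 2 * 1.05e-9 * r$age
    expect_lt(abs(p - expected), 3 * sqrt(max(expected, 1 / 350) / 350) + 0.002)
  }
})

test_that("full truncation leaves no element with both LTRs complete", {
  bg <- simulate_background(200000, 0.5, seed = 21)
  sim <- insert_elements(bg, list(fx_gypsy_template()),
                         simulation_config(n_insertions = 6, ages = 1e6,
                                           truncation_fraction = 1, seed = 22))
  both <- !is.na(sim$truth$ltr5_start) & !is.na(sim$truth$ltr3_start)
  expect_false(any(both))
  expect_true(all(sim$truth$truncated))
})

test_that("truth GFF3 round-trips and FASTA/GFF3 output is byte-deterministic", {
  sim <- fx_small_sim()
  d <- withr::local_tempdir()
  gff <- file.path(d, "truth.gff3")
  write_elements_gff3(sim$truth, gff)
  back <- read_elements_gff3(gff)
  for (cc in c("element_id", "seqid", "start", "end", "ltr5_start", "ltr5_end",
               "ltr3_start", "ltr3_end", "family_id", "tsd"))
    expect_equal(back[[cc]], sim$truth[[cc]], ignore_attr = TRUE)
  expect_equal(as.numeric(back$age), sim$truth$age)

  # determinism: regenerate the whole simulation and compare bytes
  bg <- simulate_background(50000, 0.5, seed = 33)
  mk <- function() {
    s <- insert_elements(bg, list(fx_copia_template()),
                         simulation_config(n_insertions = 2, ages = 1e6, seed = 34))
    fa <- file.path(d, "g.fasta"); gf <- file.path(d, "t.gff3")
    write_genome(s$genome, fa); write_elements_gff3(s$truth, gf)
    c(tools::md5sum(fa), tools::md5sum(gf))
  }
  expect_identical(unname(mk()), unname(mk()))
})

test_that("annotation tables realise planted counts exactly", {
  pt <- data.frame(term = c("GO:0030600", "GO:0000001"),
                   count_in_secretome = c(6L, 0L), count_in_genome = c(9L, 5L))
  tabs <- simulate_annotation_tables(14928, 470, pt, seed = 2)
  expect_length(tabs$secreted, 470L)
  g1 <- unique(tabs$gene2go$gene_id[tabs$gene2go$term == "GO:0030600"])
  expect_length(g1, 9L)
  expect_equal(sum(g1 %in% tabs$secreted), 6L)
  g2 <- unique(tabs$gene2go$gene_id[tabs$gene2go$term == "GO:0000001"])
  expect_length(g2, 5L)
  expect_equal(sum(g2 %in% tabs$secreted), 0L)

  tabs2 <- simulate_annotation_tables(14928, 470, pt, seed = 3)
  g1b <- unique(tabs2$gene2go$gene_id[tabs2$gene2go$term == "GO:0030600"])
  expect_length(g1b, 9L)
  expect_equal(sum(g1b %in% tabs2$secreted), 6L)
  expect_false(identical(sort(g1), sort(g1b)))  # same counts, new placement

  expect_error(simulate_annotation_tables(100, 10, data.frame(
    term = "x", count_in_secretome = 9, count_in_genome = 5)), "exceeds")
})
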