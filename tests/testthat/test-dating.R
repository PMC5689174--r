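# dating module: alignment vs exhaustive oracle, trimming, P/Q counting,
# the Kimura 2P closed form, age conversion, burst profiles, recovery

test_that("pair alignment is optimal (exhaustive oracle) and deterministic", {
  id <- strrep("ACGTTGCA", 40)   # identical 320-mers
  a0 <- align_ltr_pair(id, id)
  expect_identical(a0$ltr5, a0$ltr3)
  expect_false(grepl("-", a0$ltr5, fixed = TRUE))

  a1 <- align_ltr_pair("ACGT", "AGT")
  gaps <- sum(strsplit(a1$ltr5, "")[[1]] == "-") + sum(strsplit(a1$ltr3, "")[[1]] == "-")
  expect_equal(gaps, 1L)
  expect_equal(a1$score, oracle_global_score("ACGT", "AGT"))

  set.seed(42)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE), collapse = "")
    expect_equal(align_ltr_pair(x, y)$score, oracle_global_score(x, y),
                 info = paste(x, y))
    expect_identical(align_ltr_pair(x, y), align_ltr_pair(x, y))
  }
  expect_error(align_ltr_pair("", "ACGT"), "empty")
})

test_that("trimming removes exactly the gap/N columns", {
  aln <- structure(list(ltr5 = "ACGTACGTAC", ltr3 = "ACGTACGTAC",
                        score = 0, trimmed = FALSE), class = "rb_pair_alignment")
  expect_identical(trim_alignment(aln)$ltr5, aln$ltr5)

  a <- paste0(strrep("A", 95), "-----")
  b <- strrep("A", 100)
  t1 <- trim_alignment(structure(list(ltr5 = a, ltr3 = b, score = 0, trimmed = FALSE),
                                 class = "rb_pair_alignment"))
  expect_equal(nchar(t1$ltr5), 95L)
  expect_true(t1$trimmed)

  nn <- structure(list(ltr5 = "A-N", ltr3 = "-AN", score = 0, trimmed = FALSE),
                  class = "rb_pair_alignment")
  expect_error(trim_alignment(nn), "uninformative")
})

test_that("P/Q counting matches a brute-force recount on random pairs", {
  mk <- function(a, b) structure(list(ltr5 = a, ltr3 = b, score = 0, trimmed = TRUE),
                                 class = "rb_pair_alignment")
  p <- count_PQ(mk(paste0(strrep("A", 90), "GGGGGG", "CCCC"),
                   paste0(strrep("A", 90), "AAAAAA", "AAAA")))
  expect_equal(p$P, 0.06)
  expect_equal(p$Q, 0.04)
  expect_equal(p$usable_sites, 100L)
  expect_equal(count_PQ(mk("ACGT", "ACGT")), list(P = 0, Q = 0, usable_sites = 4L))

  set.seed(7)
  for (i in 1:10) {
    n <- 200L
    a <- sample(c("A", "C", "G", "T"), n, TRUE)
    b <- sample(c("A", "C", "G", "T"), n, TRUE)
    got <- count_PQ(mk(paste(a, collapse = ""), paste(b, collapse = "")))
    ts <- sum((a == "A" & b == "G") | (a == "G" & b == "A") |
                (a == "C" & b == "T") | (a == "T" & b == "C"))
    tv <- sum(a != b) - ts
    expect_equal(got$P, ts / n)
    expect_equal(got$Q, tv / n)
  }
})

test_that("Kimura 2P matches the closed form, saturates and is monotone", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.1, 0.05), 0.1701812, tolerance = 1e-6)
  expect_equal(kimura2p(0.1, 0.05), oracle_k2p(0.1, 0.05), tolerance = 1e-12)
  expect_error(kimura2p(0.5, 0.1), class = "rb_saturation")
  expect_error(kimura2p(0.3, 0.4), class = "rb_saturation")

  grid <- expand.grid(P = seq(0.005, 0.2, by = 0.02), Q = seq(0.005, 0.15, by = 0.02))
  for (i in seq_len(nrow(grid))) {
    expect_equal(kimura2p(grid$P[i], grid$Q[i]), oracle_k2p(grid$P[i], grid$Q[i]),
                 tolerance = 1e-12)
    # strictly increasing in each argument
    expect_gt(kimura2p(grid$P[i] + 1e-3, grid$Q[i]), kimura2p(grid$P[i], grid$Q[i]))
    expect_gt(kimura2p(grid$P[i], grid$Q[i] + 1e-3), kimura2p(grid$P[i], grid$Q[i]))
  }
  # small-divergence limit K -> P + Q
  for (pq in list(c(0.004, 0.004), c(0.006, 0.002), c(0.002, 0.008))) {
    K <- kimura2p(pq[1], pq[2])
    expect_lt(abs(K - sum(pq)) / sum(pq), 0.02)
  }
})

test_that("age conversion is exact arithmetic in the substitution rate", {
  expect_equal(age_from_k(0), 0)
  expect_equal(age_from_k(0.0105, 1.05e-9), 5e6)
  expect_equal(age_from_k(0.063, 1.05e-9), 3e7)
  expect_error(age_from_k(0.1, 0), "rate_r")
  expect_error(age_from_k(-0.1), "K must")
})

test_that("burst profiles bin half-open, pool old ages and track undatable elements", {
  p <- burst_profile(c(1e6, 2e6, 12e6))
  expect_equal(p$bins$count[1:3], c(2L, 0L, 1L))
  expect_equal(p$n_dated, 3L)

  e <- burst_profile(numeric(0))
  expect_true(all(e$bins$count == 0L))

  pool <- burst_profile(c(5e6, 49e6, 60e6, NA), max_age = 50e6)
  expect_equal(pool$n_undatable, 1L)
  expect_equal(pool$bins$count[10], 2L)  # 49 MY and pooled 60 MY
  expect_equal(sum(pool$bins$count), pool$n_dated)

  expect_equal(burst_profile(c(4.999e6, 5e6))$bins$count[1:2], c(1L, 1L))
  expect_error(burst_profile(1e6, bin_width = 0), "bin_width")
})

test_that("the dating pipeline recovers simulated ages and never goes negative", {
  r <- 1.05e-9
  ltr <- as.character(simulate_background(2000, 0.5, seed = 55))
  ltr <- substr(ltr, 1, 500)
  est <- function(T, n, seed0) vapply(seq_len(n), function(i) {
    pair <- age_ltr_pair(ltr, T, rate_r = r, seed = seed0 + i)
    pq <- count_PQ(trim_alignment(align_ltr_pair(pair$ltr5, pair$ltr3)))
    age_from_k(kimura2p(pq$P, pq$Q), r)
  }, 0)
  ages10 <- est(1e7, 30L, 7000L)
  expect_true(all(ages10 >= 0))
  K <- ages10 * 2 * r
  se <- sd(K) / sqrt(length(K))
  expect_lt(abs(mean(K) - 2 * r * 1e7), 3 * se)  # unbiased under the matched model
})

test_that("date_elements flags degenerate elements instead of failing", {
  g <- setNames(Biostrings::DNAStringSet(paste0(
    strrep("ACGT", 200), strrep("TTTT", 100), strrep("ACGT", 200))), "s")
  el <- data.frame(element_id = c("ok", "noltr"), seqid = "s",
                   start = c(1L, 1L), end = c(500L, 1200L),
                   ltr5_start = c(1L, NA), ltr5_end = c(100L, NA),
                   ltr3_start = c(401L, NA), ltr3_end = c(500L, NA),
                   stringsAsFactors = FALSE)
  d <- date_elements(g, el)
  expect_identical(d$status, c("ok", "no_ltrs"))
  expect_equal(d$T_years[1], 0)
  expect_true(is.na(d$T_years[2]))
})
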