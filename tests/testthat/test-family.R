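# family census: clustering, consensus, copy annotation, Table-style census

test_that("clustering groups aged copies of one template and separates templates", {
  sim <- fx_small_sim()
  det <- fx_small_detected()
  fams <- cluster_copies(det, sim$genome)
  expect_equal(length(fams), 2L)
  expect_equal(sort(vapply(fams, function(f) length(f$members), 0L)), c(4L, 4L))
  # members of one family all descend from one template
  for (f in fams) {
    rows <- f$member_rows
    truth_fam <- vapply(rows, function(i) {
      ov <- pmin(det$end[i], sim$truth$end) - pmax(det$start[i], sim$truth$start)
      sim$truth$family_id[which.max(ov)]
    }, "")
    expect_equal(length(unique(truth_fam)), 1L)
  }

  one <- cluster_copies(det[1, ], sim$genome)
  expect_equal(length(one), 1L)
  expect_identical(one[[1]]$members, det$element_id[1])
})

test_that("consensus building takes the per-column majority over planted mutations", {
  anc <- unname(as.character(simulate_background(1200, 0.5, seed = 81)))
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    paste(ch, collapse = "")
  }
  members <- c(mutate_at(anc, 100), mutate_at(anc, 500), mutate_at(anc, 900))
  g <- setNames(Biostrings::DNAStringSet(paste(members, collapse = "")), "s")
  el <- data.frame(element_id = paste0("e", 1:3), seqid = "s",
                   start = c(1L, 1201L, 2401L), end = c(1200L, 2400L, 3600L),
                   ltr5_start = NA_integer_, ltr5_end = NA_integer_,
                   ltr3_start = NA_integer_, ltr3_end = NA_integer_,
                   stringsAsFactors = FALSE)
  fam <- list(family_id = "FAM_001", members = el$element_id, member_rows = 1:3)
  expect_identical(build_consensus(fam, el, g), anc)  # majority restores the ancestor

  single <- list(family_id = "FAM_002", members = "e1", member_rows = 1L)
  expect_identical(build_consensus(single, el, g), members[1])
})

test_that("copy annotation recovers full, truncated and solo copies with honest fractions", {
  cons <- as.character(simulate_background(5000, 0.5, seed = 82))
  ltr <- substr(cons, 1, 350)
  trunc <- substr(cons, 2001, 5000)   # 60% of the consensus
  bg <- as.character(simulate_background(30000, 0.5, seed = 83))
  g <- setNames(Biostrings::DNAStringSet(paste0(
    substr(bg, 1, 5000), cons,
    substr(bg, 5001, 12000), trunc,
    substr(bg, 12001, 20000), ltr,
    substr(bg, 20001, 30000))), "s")
  hits <- annotate_copies(g, c(FAM_001 = cons))
  expect_equal(nrow(hits), 3L)
  hits <- hits[order(hits$start), ]
  expect_equal(hits$fraction_of_consensus, c(1, 0.6, 0.07), tolerance = 0.02)
  expect_equal(hits$start[1], 5001L)
  expect_equal(hits$end[1], 10000L)

  none <- annotate_copies(setNames(Biostrings::DNAStringSet(substr(bg, 1, 10000)), "x"),
                          c(FAM_001 = cons))
  expect_equal(nrow(none), 0L)
})

test_that("the census arithmetic is exact and unions match the bitmap oracle", {
  copies <- data.frame(seqid = "s",
                       start = c(10001L, 30001L, 60001L),
                       end = c(15000L, 35000L, 65000L), strand = "+",
                       family_id = "FAM_001", identity = 1,
                       cons_start = 1L, cons_end = 5000L,
                       fraction_of_consensus = 1, stringsAsFactors = FALSE)
  g <- simulate_background(100000, 0.5, seed = 84, seq_id = "s")
  q <- quantify(copies, g)
  fam_row <- q[!is.na(q$family_id), ]
  expect_equal(fam_row$n_copies, 3L)
  expect_equal(fam_row$n_full_copies, 3L)
  expect_equal(fam_row$coverage_percent, 15.0)

  # half-overlapping annotations count once
  ov <- data.frame(seqid = "s", start = c(1001L, 1501L), end = c(2000L, 2500L),
                   strand = "+", family_id = "F", identity = 1,
                   cons_start = 1L, cons_end = 1000L, fraction_of_consensus = 1,
                   stringsAsFactors = FALSE)
  expect_equal(quantify(ov, g)$coverage_percent[2], 100 * 1500 / 100000)

  set.seed(99)
  rnd <- data.frame(seqid = "s", start = sample(1:90000, 40), strand = "+",
                    family_id = sample(c("A", "B"), 40, TRUE), identity = 1,
                    cons_start = 1L, cons_end = 100L, fraction_of_consensus = 1,
                    stringsAsFactors = FALSE)
  rnd$end <- rnd$start + sample(100:5000, 40)
  q2 <- quantify(rnd, g, classification = c(A = "Gypsy", B = "Copia"))
  total <- q2[q2$classification == "TOTAL" & !is.na(q2$classification), ]
  expect_equal(total$coverage_percent,
               100 * oracle_union_bp(rnd$start, rnd$end, 100000) / 100000)
  fam_cov <- q2$coverage_percent[!is.na(q2$family_id)]
  expect_lte(total$coverage_percent, sum(fam_cov) + 1e-9)
  for (fam in c("A", "B")) {
    ff <- rnd[rnd$family_id == fam, ]
    expect_equal(q2$coverage_percent[!is.na(q2$family_id) & q2$family_id == fam],
                 100 * oracle_union_bp(ff$start, ff$end, 100000) / 100000)
  }
})

test_that("the full census recovers the planted benchmark within tolerance", {
  bench <- fx_census_benchmark()
  # with solo LTRs and truncated copies planted, stray terminal-repeat pairs
  # can mimic a full element: require the target-site duplication and keep
  # only domain-confirmed candidates (putative autonomous elements) before
  # building families
  det <- detect_ltr_elements(bench$genome, detector_params(require_tsd = TRUE))
  det <- classify_elements(bench$genome, det)
  det <- det[det$superfamily != "unknown", ]
  cen <- census(bench$genome, det)
  expect_equal(length(cen$families), 2L)
  truth <- bench$truth
  # map each consensus family to the template whose members it detected
  for (f in cen$families) {
    rows <- f$member_rows
    tfam <- vapply(rows, function(i) {
      ov <- pmin(det$end[i], truth$end) - pmax(det$start[i], truth$start)
      truth$family_id[which.max(ov)]
    }, "")
    tf <- unique(tfam)
    expect_length(tf, 1L)
    tt <- truth[truth$family_id == tf, ]
    crow <- cen$census[!is.na(cen$census$family_id) &
                         cen$census$family_id == f$family_id, ]
    expect_lte(abs(crow$n_copies - nrow(tt)), 1L)
    truth_cov <- 100 * oracle_union_bp(tt$start, tt$end,
                                       sum(Biostrings::width(bench$genome))) /
      sum(Biostrings::width(bench$genome))
    expect_lt(abs(crow$coverage_percent - truth_cov), 1)
  }
  # determinism
  cen2 <- census(bench$genome, det)
  expect_identical(cen$census, cen2$census)
})
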