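# RT phylogeny: extraction, progressive alignment vs pairwise oracle,
# Poisson distances, NJ consistency on additive matrices, bootstrap, rooting

test_that("RT peptides are extracted verbatim from planted domains", {
  tmpl <- fx_gypsy_template()
  elem <- paste0(tmpl$ltr_sequence, tmpl$internal_sequence, tmpl$ltr_sequence)
  hits <- list(fam1 = scan_domains(elem, fx_library()))
  peps <- extract_rt_peptides(c(fam1 = elem), hits)
  ref <- fx_library()$peptides[[grep("^RT:gypsy", names(fx_library()$peptides))[1]]]
  expect_true(grepl(ref, peps[["fam1"]], fixed = TRUE))

  expect_warning(extract_rt_peptides(c(x = "ACGTACGTACGT"), list(x = hits$fam1[0, ])),
                 "without RT")
})

test_that("progressive alignment: identical inputs gapless; pairwise equals the NW oracle", {
  p <- c(a = "MKVLATREDD", b = "MKVLATREDD", c = "MKVLATREDD")
  aln <- align_peptides(p)
  expect_false(any(grepl("-", aln, fixed = TRUE)))
  expect_identical(unname(nchar(aln)), rep(10L, 3L))

  x <- "MKVLATREDDHEWQNNPLKV"
  y <- "MKVLTREDDHEWQNPLKV"
  a2 <- align_peptides(c(x = x, y = y), max_gap_fraction = 1)
  mat <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(x), Biostrings::AAString(y), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  my_score <- {
    av <- strsplit(a2[["x"]], "")[[1]]; bv <- strsplit(a2[["y"]], "")[[1]]
    e <- new.env(); utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
    B <- e$BLOSUM62
    s <- 0; in_gap <- FALSE
    for (k in seq_along(av)) {
      if (av[k] == "-" || bv[k] == "-") {
        s <- s - 0.5 - if (in_gap) 0 else 10
        in_gap <- TRUE
      } else { s <- s + B[av[k], bv[k]]; in_gap <- FALSE }
    }
    s
  }
  expect_equal(my_score, Biostrings::score(mat))

  # >50% gap columns are trimmed
  p4 <- c(a = "MKVLREDD", b = "MKVLREDD", c = "MKVLREDD", d = "MKVLWWWWWREDD")
  a4 <- align_peptides(p4)
  ch <- do.call(rbind, strsplit(unclass(a4), ""))
  expect_true(all(colMeans(ch == "-") <= 0.5))

  expect_error(align_peptides(c(a = "MKV")), "at least 2")
})

test_that("distances are Poisson-corrected p-distances with exact closed form", {
  rows <- c(a = strrep("A", 10), b = paste0(strrep("A", 9), "W"),
            c = strrep("W", 10))
  D <- distance_matrix(rows)
  expect_equal(D["a", "b"], -log(1 - 0.1))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_identical(D, t(D))
  expect_true(is.infinite(D["a", "c"]))
  expect_error(nj_tree(D), class = "rb_saturation")
})

test_that("NJ exactly recovers additive trees (quartet oracle) and ignores taxon order", {
  skip_if_not_installed("ape")
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    tr$tip.label <- paste0("t", seq_len(n))
    D <- ape::cophenetic.phylo(tr)
    got <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
    # spot-check three random quartets against the four-point condition
    for (q in 1:3) {
      tips <- sample(tr$tip.label, 4)
      expect_identical(tree_quartet_split(got, tips),
                       oracle_quartet_split(D[tips, tips]))
    }
    # permutation invariance
    perm <- sample(rownames(D))
    got2 <- nj_tree(D[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(got2)), 0,
                 ignore_attr = TRUE)
  }
  # 3 taxa: forced star with exact lengths
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_equal(sort(t3$edge.length), c(1, 1, 3))
})

test_that("bootstrap supports are seed-deterministic and saturate on clean signal", {
  # conflict-free alignment: every column is constant or splits the same way
  # (shared K/R columns keep all pairwise p-distances below saturation)
  rows <- c(A1 = strrep("AKAR", 30), A2 = strrep("AKAR", 30),
            B1 = strrep("GKGR", 30), B2 = strrep("GKGR", 30),
            C1 = strrep("WKWR", 30))
  b1 <- bootstrap_support(rows, n_replicates = 50, seed = 5)
  b2 <- bootstrap_support(rows, n_replicates = 50, seed = 5)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] == 1))

  single <- bootstrap_support(rows, n_replicates = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(single$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 1)))
})

test_that("outgroup rooting splits the pendant edge and recovers planted clades", {
  D4 <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 2,
                 8, 8, 2, 0), 4, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D4)
  rooted <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  expect_true(which(rooted$tip.label == "D") %in% kids)
  again <- root_with_outgroup(rooted, "D")
  expect_identical(ape::write.tree(again), ape::write.tree(rooted))
  expect_error(root_with_outgroup(tr, "nope"), "unknown outgroup")

  peps <- fx_rt_peptides()
  aln <- align_peptides(peps)
  tree <- root_with_outgroup(nj_tree(distance_matrix(aln)), "OUT")
  is_mono <- function(tree, tips) ape::is.monophyletic(tree, tips)
  expect_true(is_mono(tree, c("A1", "A2", "A3")))
  expect_true(is_mono(tree, c("B1", "B2", "B3")))
})
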