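# Reverse-transcriptase phylogeny: RT peptide extraction from domain hits,
# an authored progressive aligner (k-mer guide tree + profile-profile
# Needleman-Wunsch with affine gaps under BLOSUM62), Poisson-corrected
# p-distances, neighbor joining (ape's canonical Saitou-Nei implementation,
# negative branches clamped to zero), nonparametric bootstrap supports, and
# outgroup rooting on the midpoint of the outgroup's pendant edge.

#' Extract the reverse-transcriptase peptide of each taxon
#'
#' @param sequences named character vector of element/consensus nucleotide
#'   sequences.
#' @param hits named list of [scan_domains()] tables, parallel to
#'   `sequences`.
#' @return named character vector of RT peptides; taxa without an RT hit
#'   are omitted with a warning.  Internal stop codons are retained as `*`.
#' @export
extract_rt_peptides <- function(sequences, hits) {
  out <- character(0)
  for (nm in names(sequences)) {
    h <- hits[[nm]]
    if (is.null(h) || !nrow(h) || !any(h$domain == "RT")) {
      warning("taxon without RT hit skipped: ", nm, call. = FALSE)
      next
    }
    rt <- h[h$domain == "RT", ]
    best <- rt[which.max(rt$score), ]
    nt <- substr(sequences[[nm]], best$nt_start, best$nt_end)
    d <- Biostrings::DNAString(nt)
    if (best$frame < 0) d <- Biostrings::reverseComplement(d)
    len <- (length(d) %/% 3L) * 3L
    pep <- as.character(Biostrings::translate(Biostrings::subseq(d, 1L, len),
                                              if.fuzzy.codon = "X",
                                              no.init.codon = TRUE))
    out[nm] <- pep
  }
  out
}

aa_profile <- function(rows, alphabet) {
  m <- matrix(0, nrow = length(alphabet), ncol = nchar(rows[1]),
              dimnames = list(alphabet, NULL))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    ok <- ch %in% alphabet
    idx <- cbind(match(ch[ok], alphabet), which(ok))
    m[idx] <- m[idx] + 1
  }
  sweep(m, 2L, length(rows), "/")   # gap mass simply missing from the column
}

# profile-profile global alignment with affine gaps; returns the two column
# index vectors (0 = gap) of the merged alignment
profile_nw <- function(fa, fb, mat, go, ge) {
  S <- t(fa) %*% mat[rownames(fa), rownames(fb)] %*% fb
  la <- ncol(fa); lb <- ncol(fb)
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L); Ix <- M; Iy <- M
  M[1, 1] <- 0
  if (la >= 1L) Ix[2:(la + 1L), 1] <- -(go + ge * seq_len(la))
  if (lb >= 1L) Iy[1, 2:(lb + 1L)] <- -(go + ge * seq_len(lb))
  tbM <- matrix(0L, la + 1L, lb + 1L); tbX <- tbM; tbY <- tbM
  for (i in seq_len(la)) {
    Mi1 <- M[i, ]; Xi1 <- Ix[i, ]; Yi1 <- Iy[i, ]
    Mi <- M[i + 1L, ]; Xi <- Ix[i + 1L, ]; Yi <- Iy[i + 1L, ]
    for (j in seq_len(lb)) {
      # M: diagonal move
      cands <- c(Mi1[j], Xi1[j], Yi1[j])
      w <- which.max(cands)
      Mi[j + 1L] <- cands[w] + S[i, j]; tbM[i + 1L, j + 1L] <- w
      # Ix: gap in B (consume A column i)
      cands <- c(Mi1[j + 1L] - go - ge, Xi1[j + 1L] - ge)
      w <- which.max(cands)
      Xi[j + 1L] <- cands[w]; tbX[i + 1L, j + 1L] <- w
      # Iy: gap in A (consume B column j)
      cands <- c(Mi[j] - go - ge, Yi[j] - ge)
      w <- which.max(cands)
      Yi[j + 1L] <- cands[w]; tbY[i + 1L, j + 1L] <- w
    }
    M[i + 1L, ] <- Mi; Ix[i + 1L, ] <- Xi; Iy[i + 1L, ] <- Yi
  }
  i <- la; j <- lb
  state <- which.max(c(M[la + 1L, lb + 1L], Ix[la + 1L, lb + 1L], Iy[la + 1L, lb + 1L]))
  ca <- integer(0); cb <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      ca <- c(i, ca); cb <- c(j, cb)
      state <- tbM[i + 1L, j + 1L]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ca <- c(i, ca); cb <- c(0L, cb)
      state <- if (tbX[i + 1L, j + 1L] == 2L) 2L else 1L
      i <- i - 1L
    } else {
      ca <- c(0L, ca); cb <- c(j, cb)
      state <- if (tbY[i + 1L, j + 1L] == 2L) 3L else 1L
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  list(ca = ca, cb = cb,
       score = max(M[la + 1L, lb + 1L], Ix[la + 1L, lb + 1L], Iy[la + 1L, lb + 1L]))
}

apply_columns <- function(rows, cols) {
  vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    paste(ifelse(cols == 0L, "-", ch[pmax(cols, 1L)]), collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' Progressive multiple alignment of peptides
#'
#' Guide tree from 3-mer profile distances (average-linkage clustering),
#' then profile-profile global alignment with affine gaps under BLOSUM62.
#' Columns with more than `max_gap_fraction` gaps are removed afterwards.
#'
#' @param peptides named character vector (>= 2 sequences).
#' @param gap_open,gap_extend positive gap costs (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param max_gap_fraction column-removal threshold (default 0.5).
#' @return named character vector of equal-length aligned rows, class
#'   `rb_peptide_alignment`.
#' @export
align_peptides <- function(peptides, gap_open = 10, gap_extend = 0.5,
                           max_gap_fraction = 0.5) {
  n <- length(peptides)
  if (n < 2L) rb_stop("need at least 2 sequences", "rb_value_error")
  mat <- blosum62()
  alphabet <- rownames(mat)
  groups <- lapply(names(peptides), function(nm) setNames(peptides[nm], nm))
  if (n == 2L) {
    order_merge <- matrix(c(-1L, -2L), 1L)
  } else {
    # 3-mer presence (Jaccard) distance for the guide tree
    kmers <- lapply(peptides, function(p) {
      L <- nchar(p)
      if (L < 3L) character(0) else unique(substring(p, 1:(L - 2L), 3:L))
    })
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      u <- length(union(kmers[[i]], kmers[[j]]))
      d <- if (u == 0L) 1 else 1 - length(intersect(kmers[[i]], kmers[[j]])) / u
      D[i, j] <- D[j, i] <- d
    }
    hc <- hclust(as.dist(D), method = "average")
    order_merge <- hc$merge
  }
  merged <- vector("list", nrow(order_merge))
  for (m in seq_len(nrow(order_merge))) {
    pick <- function(v) if (v < 0L) groups[[-v]] else merged[[v]]
    A <- pick(order_merge[m, 1]); B <- pick(order_merge[m, 2])
    fa <- aa_profile(A, alphabet); fb <- aa_profile(B, alphabet)
    nw <- profile_nw(fa, fb, mat, gap_open, gap_extend)
    merged[[m]] <- c(apply_columns(A, nw$ca), apply_columns(B, nw$cb))
  }
  aln <- merged[[length(merged)]][names(peptides)]
  # column trim
  chm <- do.call(rbind, strsplit(aln, ""))
  gap_frac <- colMeans(chm == "-")
  keep <- gap_frac <= max_gap_fraction
  aln <- setNames(apply(chm[, keep, drop = FALSE], 1L, paste, collapse = ""),
                  names(peptides))
  structure(aln, class = "rb_peptide_alignment")
}

#' Poisson-corrected distance matrix from a peptide alignment
#'
#' Pairwise p-distance over mutually ungapped columns, corrected as
#' `d = -ln(1 - p)`; saturated pairs (`p >= 1`) become `Inf`.
#'
#' @param aln named character vector of equal-length aligned rows.
#' @param correction `"poisson"` (default) or `"p"` for the raw p-distance.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  n <- length(aln)
  if (n < 3L) rb_stop("need >= 3 taxa for a distance matrix", "rb_value_error")
  ch <- do.call(rbind, strsplit(unclass(aln), ""))
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    use <- ch[i, ] != "-" & ch[j, ] != "-" & ch[i, ] != "X" & ch[j, ] != "X"
    if (!any(use)) { D[i, j] <- D[j, i] <- Inf; next }
    p <- mean(ch[i, use] != ch[j, use])
    d <- if (correction == "p") p else if (p >= 1) Inf else -log(1 - p)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining (via ape), with negative branch
#' lengths clamped to zero.  Non-finite distances (saturated pairs) raise
#' an error advising taxon removal.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (any(!is.finite(D)))
    rb_stop("non-finite distance (saturated pair): remove the offending taxa",
            "rb_saturation")
  if (nrow(D) < 3L) rb_stop("need >= 3 taxa", "rb_value_error")
  phy <- ape::nj(as.dist(D))
  phy$edge.length[phy$edge.length < 0] <- 0
  phy$edge.length <- phy$edge.length + 0   # normalise -0
  phy
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' fraction of replicates containing its bipartition (stored in
#' `node.label`).
#'
#' @param aln `rb_peptide_alignment` (or named aligned character vector).
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param correction distance correction, see [distance_matrix()].
#' @return `phylo` tree with `node.label` supports in `[0, 1]`.
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L,
                              correction = "poisson") {
  if (n_replicates < 1L) rb_stop("n_replicates must be >= 1", "rb_value_error")
  aln <- setNames(as.character(aln), names(aln))
  ref <- nj_tree(distance_matrix(aln, correction))
  ch <- do.call(rbind, strsplit(aln, ""))
  ncolumns <- ncol(ch)
  trees <- with_seed(seed, lapply(seq_len(n_replicates), function(b) {
    idx <- sample.int(ncolumns, ncolumns, replace = TRUE)
    rows <- setNames(apply(ch[, idx, drop = FALSE], 1L, paste, collapse = ""),
                     rownames(ch))
    tryCatch(nj_tree(distance_matrix(rows, correction)), error = function(e) NULL)
  }))
  trees <- Filter(Negate(is.null), trees)
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- format(round(counts / max(1L, length(trees)), 3))
  # root "clade" of an unrooted tree is not a bipartition; blank it
  ref$node.label[1] <- ""
  ref
}

#' Root a tree on a designated outgroup
#'
#' The root is placed on the outgroup's pendant edge, at its midpoint.
#' Rooting an already-rooted tree on the same outgroup is idempotent.
#'
#' @param tree `phylo` tree.
#' @param outgroup leaf label.
#' @return rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    rb_stop(paste0("unknown outgroup taxon: ", outgroup), "rb_value_error")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tip <- which(rooted$tip.label == outgroup)
  rootnode <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == rootnode)
  pend <- kids[rooted$edge[kids, 2] == tip]
  if (length(pend) == 1L && length(kids) == 2L) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

#' Full reverse-transcriptase phylogeny
#'
#' @param sequences named nucleotide sequences (family consensi or elements).
#' @param hits named list of domain-hit tables from [scan_domains()].
#' @param outgroup optional leaf to root on (e.g. a bundled synthetic
#'   outgroup RT); `NULL` leaves the tree unrooted.
#' @param n_replicates bootstrap replicates.
#' @param seed integer seed.
#' @return list of class `rb_rt_phylo`: `tree` (phylo, with supports),
#'   `alignment`, `distances`.
#' @export
rt_phylogeny <- function(sequences, hits, outgroup = NULL,
                         n_replicates = 100L, seed = 1L) {
  peps <- extract_rt_peptides(sequences, hits)
  if (length(peps) < 3L) rb_stop("need >= 3 taxa with RT hits", "rb_value_error")
  aln <- align_peptides(peps)
  D <- distance_matrix(aln)
  tree <- bootstrap_support(aln, n_replicates = n_replicates, seed = seed)
  if (!is.null(outgroup)) tree <- root_with_outgroup(tree, outgroup)
  structure(list(tree = tree, alignment = aln, distances = D),
            class = "rb_rt_phylo")
}
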