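# Independent oracles used by the unit and acceptance tests.  Each is a
# deliberately naive implementation kept separate from the package code
# paths it checks.

# quadratic scan: all same-strand exact k-mer pairs with spacing in [lo, hi]
oracle_seed_pairs <- function(seq, k, lo, hi) {
  n <- nchar(seq)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  out <- list()
  for (d in lo:hi) {
    i <- starts[starts + d <= n - k + 1L]
    if (!length(i)) next
    hit <- ok[i] & ok[i + d] & kmers[i] == kmers[i + d]
    if (any(hit)) out[[length(out) + 1L]] <- data.frame(pos1 = i[hit], pos2 = i[hit] + d)
  }
  if (!length(out)) return(data.frame(pos1 = integer(0), pos2 = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$pos1, res$pos2), ]
}

# exhaustive global alignment score by recursive enumeration (affine gaps,
# Biostrings convention: a gap of length L costs open + L * extend)
oracle_global_score <- function(a, b, match = 2, mismatch = -3,
                                gap_open = 5, gap_extend = 2) {
  rec <- function(i, j, state) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= nchar(a)) {
      cost <- gap_extend + if (state == "ga") 0 else gap_open
      best <- max(best, -cost + rec(i + 1L, j, "ga"))
    }
    if (j <= nchar(b)) {
      cost <- gap_extend + if (state == "gb") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1L, "gb"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# independent algebraic form of the Kimura 2P distance
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# analytic expected mismatch between two copies after total divergence
# d = 2 * r * T expected substitution events, under the jump chain with
# transition probability tf and the two transversions at (1-tf)/2 each
oracle_expected_mismatch <- function(d, tf = 0.5) {
  bases <- c("A", "G", "C", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  for (b in bases) {
    Q[b, ts_partner[[b]]] <- tf
    tv <- setdiff(bases, c(b, ts_partner[[b]]))
    Q[b, tv] <- (1 - tf) / 2
    Q[b, b] <- -1
  }
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors)
  1 - Re(P[1, 1])
}

# hypergeometric upper tail by plain enumeration (no logs)
oracle_fisher_upper <- function(a, b, c_, d) {
  N <- a + b + c_ + d; K <- a + c_; n <- a + b
  if (K == 0 || n == 0 || K == N || n == N || a == 0) return(1)
  xs <- a:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# base-by-base bitmap coverage oracle
oracle_union_bp <- function(starts, ends, len) {
  bit <- logical(len)
  for (i in seq_along(starts)) bit[starts[i]:ends[i]] <- TRUE
  sum(bit)
}

# four-point-condition quartet split from a distance matrix: returns the
# pairing of taxa 1..4 as a canonical string
oracle_quartet_split <- function(D4) {
  s12 <- D4[1, 2] + D4[3, 4]; s13 <- D4[1, 3] + D4[2, 4]; s14 <- D4[1, 4] + D4[2, 3]
  w <- which.min(c(s12, s13, s14))
  c("12|34", "13|24", "14|23")[w]
}

# which quartet split a tree displays for 4 named tips
tree_quartet_split <- function(tree, tips) {
  sub <- ape::keep.tip(tree, tips)
  sub <- ape::unroot(sub)
  # find the internal edge bipartition
  parts <- ape::prop.part(sub)
  for (p in parts) {
    labs <- attr(parts, "labels")[p]
    if (length(labs) == 2L) {
      idx <- sort(match(labs, tips))
      if (!1L %in% idx) idx <- sort(setdiff(1:4, idx))
      return(paste0(idx[1], idx[2], "|",
                    paste(sort(setdiff(1:4, idx)), collapse = "")))
    }
  }
  # star (unresolved)
  NA_character_
}

# 50% reciprocal-overlap matching of detected vs truth element intervals
match_elements <- function(det, truth) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(nrow(truth))) {
      if (used[j] || det$seqid[i] != truth$seqid[j]) next
      ov <- min(det$end[i], truth$end[j]) - max(det$start[i], truth$start[j]) + 1L
      if (ov <= 0) next
      r <- min(ov / (det$end[i] - det$start[i] + 1L),
               ov / (truth$end[j] - truth$start[j] + 1L))
      if (r >= 0.5) { used[j] <- TRUE; tp <- tp + 1L; break }
    }
  }
  list(tp = tp, recall = tp / nrow(truth), precision = tp / nrow(det))
}
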