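# Insertion-age dating from LTR-pair divergence: global alignment of the two
# terminal repeats, gap/ambiguity trimming, transition/transversion counting,
# the Kimura two-parameter correction K = -1/2 ln[(1-2P-Q) sqrt(1-2Q)], and
# T = K / (2 r) with the fungal substitution rate r = 1.05e-9
# substitutions/site/yr.  Saturated pairs (1-2P-Q <= 0 or 1-2Q <= 0) are
# flagged undatable and excluded from burst profiles rather than clamped.

#' Globally align the two terminal repeats of one element
#'
#' Needleman-Wunsch with the stated scores (defaults +2/-3, gap open 5, gap
#' extend 2; a gap of length L costs `open + L * extend`).  Backed by
#' Biostrings' C implementation, hence deterministic.
#'
#' @param ltr5,ltr3 nucleotide strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring (penalties positive).
#' @return list of class `rb_pair_alignment`: `ltr5`, `ltr3` (equal-length
#'   aligned strings over ACGTN-), `score`, `trimmed` flag.
#' @export
align_ltr_pair <- function(ltr5, ltr3, match = 2, mismatch = -3,
                           gap_open = 5, gap_extend = 2) {
  if (!nchar(ltr5) || !nchar(ltr3)) rb_stop("empty LTR sequence", "rb_value_error")
  sub <- matrix(mismatch, 5, 5, dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(sub) <- match
  sub["N", ] <- mismatch; sub[, "N"] <- mismatch   # N never matches, even N/N
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3),
    type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(ltr5 = as.character(Biostrings::alignedPattern(pa)),
                 ltr3 = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa), trimmed = FALSE),
            class = "rb_pair_alignment")
}

#' Trim an LTR-pair alignment
#'
#' Drops every column containing a gap or an N (a deterministic
#' simplification of trimAl's column filtering), erring toward a
#' conservative site set for the distance estimate.
#'
#' @param aln `rb_pair_alignment`.
#' @return trimmed `rb_pair_alignment` (`trimmed = TRUE`).
#' @export
trim_alignment <- function(aln) {
  a <- strsplit(aln$ltr5, "")[[1]]; b <- strsplit(aln$ltr3, "")[[1]]
  keep <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(keep)) rb_stop("alignment uninformative: no usable columns", "rb_uninformative")
  structure(list(ltr5 = paste(a[keep], collapse = ""),
                 ltr3 = paste(b[keep], collapse = ""),
                 score = aln$score, trimmed = TRUE),
            class = "rb_pair_alignment")
}

#' Count transition and transversion proportions
#'
#' Over usable columns (both bases in ACGT): `P` = transitions/usable
#' (A<->G, C<->T), `Q` = transversions/usable.
#'
#' @param aln trimmed `rb_pair_alignment`.
#' @return list with `P`, `Q`, `usable_sites`.
#' @export
count_PQ <- function(aln) {
  a <- strsplit(aln$ltr5, "")[[1]]; b <- strsplit(aln$ltr3, "")[[1]]
  use <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(use)
  if (n == 0L) rb_stop("no usable sites", "rb_uninformative")
  a <- a[use]; b <- b[use]
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                  (a == "C" & b == "T") | (a == "T" & b == "C"))
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, usable_sites = n)
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`.  Outside the valid domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the divergence is saturated and a
#' classed error (`rb_saturation`) is raised; callers flag the element
#' undatable.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return numeric distance `K >= 0`.
#' @export
#' @examples
#' kimura2p(0, 0)        # 0
#' kimura2p(0.1, 0.05)   # 0.1701812
kimura2p <- function(P, Q) {
  if (P < 0 || Q < 0 || P + Q > 1) rb_stop("P and Q must be proportions", "rb_value_error")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    rb_stop("saturated divergence: Kimura 2P undefined", "rb_saturation")
  -0.5 * log(w1 * sqrt(w2))
}

#' Convert a Kimura 2P distance to an insertion age
#'
#' `T = K / (2 r)`: both terminal repeats diverge, hence the factor 2.
#'
#' @param K Kimura 2P distance (>= 0).
#' @param rate_r substitution rate in substitutions/site/yr (> 0); default
#'   the fungal rate 1.05e-9.
#' @return age in years.
#' @export
#' @examples
#' age_from_k(0.0105, 1.05e-9)  # 5e6 years
age_from_k <- function(K, rate_r = 1.05e-9) {
  if (rate_r <= 0) rb_stop("rate_r must be > 0", "rb_value_error")
  if (K < 0) rb_stop("K must be >= 0", "rb_value_error")
  K / (2 * rate_r)
}

#' Date every element of a candidate table
#'
#' Extracts both terminal repeats of each element with complete LTR
#' intervals, aligns, trims, counts, and converts to years.  Elements with
#' saturated divergence or uninformative alignments are kept with
#' `status != "ok"` and `T_years = NA`.
#'
#' @param genome named `DNAStringSet`.
#' @param elements element data.frame (needs complete ltr5/ltr3 intervals).
#' @param rate_r substitution rate (substitutions/site/yr).
#' @return data.frame: `element_id`, `P`, `Q`, `usable_sites`, `K`,
#'   `T_years`, `status` (`ok` / `saturated` / `uninformative` / `no_ltrs`).
#' @export
date_elements <- function(genome, elements, rate_r = 1.05e-9) {
  out <- lapply(seq_len(nrow(elements)), function(i) {
    r <- elements[i, ]
    base <- data.frame(element_id = r$element_id, P = NA_real_, Q = NA_real_,
                       usable_sites = NA_integer_, K = NA_real_,
                       T_years = NA_real_, status = "no_ltrs",
                       stringsAsFactors = FALSE)
    if (anyNA(c(r$ltr5_start, r$ltr5_end, r$ltr3_start, r$ltr3_end))) return(base)
    s <- as.character(genome[[r$seqid]])
    l5 <- substr(s, r$ltr5_start, r$ltr5_end)
    l3 <- substr(s, r$ltr3_start, r$ltr3_end)
    tryCatch({
      pq <- count_PQ(trim_alignment(align_ltr_pair(l5, l3)))
      base$P <- pq$P; base$Q <- pq$Q; base$usable_sites <- pq$usable_sites
      K <- kimura2p(pq$P, pq$Q)
      base$K <- K; base$T_years <- age_from_k(K, rate_r); base$status <- "ok"
      base
    },
    rb_saturation = function(e) { base$status <- "saturated"; base },
    rb_uninformative = function(e) { base$status <- "uninformative"; base })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Amplification-burst profile
#'
#' Histogram of insertion ages in half-open bins `[i*w, (i+1)*w)` of width
#' `bin_width` (default 5 million years); ages at or beyond `max_age` pool
#' into the last bin; `NA` ages (undatable elements) are excluded but
#' counted in `n_undatable`.
#'
#' @param ages numeric vector of ages in years (may contain `NA`).
#' @param bin_width bin width in years (> 0).
#' @param max_age pooling limit in years.
#' @return list of class `rb_burst_profile`: `bins` (data.frame bin_start,
#'   bin_end, count), `n_dated`, `n_undatable`, `bin_width`.
#' @export
#' @examples
#' burst_profile(c(1e6, 2e6, 12e6))$bins$count  # 2 0 1
burst_profile <- function(ages, bin_width = 5e6, max_age = 50e6) {
  if (bin_width <= 0) rb_stop("bin_width must be > 0", "rb_value_error")
  undat <- sum(is.na(ages))
  a <- ages[!is.na(ages)]
  if (any(a < 0)) rb_stop("negative age", "rb_value_error")
  nbin <- as.integer(ceiling(max_age / bin_width))
  idx <- pmin(a %/% bin_width, nbin - 1L)
  counts <- tabulate(idx + 1L, nbins = nbin)
  structure(list(bins = data.frame(bin_start = (seq_len(nbin) - 1L) * bin_width,
                                   bin_end = seq_len(nbin) * bin_width,
                                   count = counts),
                 n_dated = length(a), n_undatable = undat, bin_width = bin_width),
            class = "rb_burst_profile")
}

#' @export
print.rb_burst_profile <- function(x, ...) {
  cat(sprintf("burst profile: %d dated, %d undatable, bin width %.1f MY\n",
              x$n_dated, x$n_undatable, x$bin_width / 1e6))
  on <- x$bins$count > 0
  for (i in which(on))
    cat(sprintf("  %5.1f-%5.1f MY  %s (%d)\n", x$bins$bin_start[i] / 1e6,
                x$bins$bin_end[i] / 1e6,
                strrep("*", min(60L, x$bins$count[i])), x$bins$count[i]))
  invisible(x)
}
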