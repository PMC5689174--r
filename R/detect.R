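# Structural detection of full-length LTR retrotransposons: exact k-mer seed
# pairs at plausible spacings -> collinear chains -> ungapped X-drop extension
# of the two repeat copies -> TSD-guided boundary refinement -> structural
# filters and exact (weighted-interval-scheduling) overlap resolution.
#
# Same-strand search only: the two LTRs of one element are co-oriented by
# construction, so inverted repeats are never considered.

#' Detector parameters
#'
#' Defaults mirror common LTRharvest-style settings: terminal repeats of
#' 100-1500 bp whose starts are 1-15 kb apart, pair identity >= 0.80,
#' 20-mer seeds, 4-6 bp target-site duplications.
#'
#' @param seed_k exact-match seed length (bp).
#' @param ltr_len_range admissible LTR length range, bp.
#' @param ltr_start_spacing_range admissible distance range between the two
#'   LTR start positions, bp.
#' @param min_ltr_identity minimum identity between the two repeats,
#'   computed over all aligned columns.
#' @param tsd_len_range admissible TSD length range.
#' @param require_tsd drop candidates without a detectable TSD.
#' @param band_width offset tolerance when grouping seeds into chains (bp).
#' @param match,mismatch,xdrop extension scores: match bonus, mismatch
#'   penalty (positive), and the score drop that terminates extension.
#' @return list of class `rb_detector_params`.
#' @export
detector_params <- function(seed_k = 20L, ltr_len_range = c(100L, 1500L),
                            ltr_start_spacing_range = c(1000L, 15000L),
                            min_ltr_identity = 0.80, tsd_len_range = c(4L, 6L),
                            require_tsd = FALSE, band_width = 30L,
                            match = 2L, mismatch = 3L, xdrop = 25L) {
  if (min_ltr_identity <= 0 || min_ltr_identity > 1)
    rb_stop("min_ltr_identity must be in (0, 1]", "rb_value_error")
  if (diff(ltr_len_range) < 0 || diff(ltr_start_spacing_range) < 0)
    rb_stop("ranges must be non-empty", "rb_value_error")
  structure(list(seed_k = as.integer(seed_k),
                 ltr_len_range = as.integer(ltr_len_range),
                 ltr_start_spacing_range = as.integer(ltr_start_spacing_range),
                 min_ltr_identity = min_ltr_identity,
                 tsd_len_range = as.integer(tsd_len_range),
                 require_tsd = isTRUE(require_tsd),
                 band_width = as.integer(band_width),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 xdrop = as.integer(xdrop)),
            class = "rb_detector_params")
}

#' Find same-strand exact k-mer seed pairs
#'
#' Reports every pair of identical k-mers on the same sequence whose start
#' distance lies in the spacing range, each pair once with `pos1 < pos2`.
#' k-mers containing N never match.
#'
#' @param genome named `DNAStringSet`.
#' @param params [detector_params()].
#' @return data.frame with columns `seqid`, `pos1`, `pos2` (1-based k-mer
#'   start positions).
#' @export
find_seed_pairs <- function(genome, params = detector_params()) {
  k <- params$seed_k
  lo <- params$ltr_start_spacing_range[1]; hi <- params$ltr_start_spacing_range[2]
  out <- list()
  for (si in seq_along(genome)) {
    s <- as.character(genome[[si]])
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    dt <- data.table::data.table(kmer = kmers[keep], pos = starts[keep])
    dt <- dt[, if (.N >= 2L) {
      p <- sort(pos)
      idx <- data.table::CJ(i = seq_along(p), j = seq_along(p))[i < j]
      d <- p[idx$j] - p[idx$i]
      ok <- d >= lo & d <= hi
      list(pos1 = p[idx$i][ok], pos2 = p[idx$j][ok])
    }, by = "kmer"]
    if (nrow(dt)) {
      out[[length(out) + 1L]] <- data.frame(seqid = names(genome)[si],
                                            pos1 = dt$pos1, pos2 = dt$pos2,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(0), pos1 = integer(0), pos2 = integer(0)))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$seqid, res$pos1, res$pos2), ]
  rownames(res) <- NULL
  res
}

# Ungapped X-drop extension of two loci in one sequence.  Returns the signed
# extension lengths (left, right) from the given anchor intervals that
# maximise the cumulative match/mismatch score, never crossing sequence
# bounds nor the midpoint between the two loci.
xdrop_extend <- function(chars, a1, b1, a2, b2, match, mismatch, xdrop,
                         left_limit1 = 1L, right_limit2 = NULL) {
  n <- length(chars)
  if (is.null(right_limit2)) right_limit2 <- n
  mid <- (b1 + a2) %/% 2L
  # left extension: compare chars[a1-i] vs chars[a2-i]
  best <- 0; cur <- 0; best_i <- 0L; i <- 1L
  while (a1 - i >= left_limit1 && a2 - i > mid) {
    cur <- cur + if (chars[a1 - i] == chars[a2 - i] &&
                     chars[a1 - i] != "N") match else -mismatch
    if (cur > best) { best <- cur; best_i <- i }
    if (best - cur > xdrop) break
    i <- i + 1L
  }
  left <- best_i
  # right extension: compare chars[b1+i] vs chars[b2+i]
  best <- 0; cur <- 0; best_i <- 0L; i <- 1L
  while (b2 + i <= right_limit2 && b1 + i < mid) {
    cur <- cur + if (chars[b1 + i] == chars[b2 + i] &&
                     chars[b1 + i] != "N") match else -mismatch
    if (cur > best) { best <- cur; best_i <- i }
    if (best - cur > xdrop) break
    i <- i + 1L
  }
  c(left = left, right = best_i)
}

# TSD-guided boundary refinement.  Extension boundaries can overshoot by a
# few bases on chance matches; the target-site duplication pins the exact
# edge.  Candidate boundary shifts are scored by (TSD length - total
# shift): a true TSD viewed from a boundary overshot by d appears truncated
# to length L-d at shift 0, so the true reading always scores at least as
# high as its truncated shadows, while unrelated duplications at large
# shifts are penalised away.  Ties prefer the longer duplication, then the
# smaller shift, deterministically.  Returns list(d5, d3, tsd).
refine_boundaries_tsd <- function(chars, start, end, tsd_len_range, max_shift = 6L) {
  n <- length(chars)
  combos <- expand.grid(d5 = seq(-max_shift, max_shift),
                        d3 = seq(-max_shift, max_shift))
  combos$dist <- abs(combos$d5) + abs(combos$d3)
  combos <- combos[combos$dist <= max_shift, ]
  combos <- combos[order(combos$dist, abs(combos$d5), combos$d5, combos$d3), ]
  best <- list(d5 = 0L, d3 = 0L, tsd = NA_character_, len = 0L)
  best_score <- -Inf
  for (ci in seq_len(nrow(combos))) {
    d5 <- combos$d5[ci]; d3 <- combos$d3[ci]
    s <- start + d5; e <- end + d3
    if (s >= e) next
    for (L in rev(seq(tsd_len_range[1], tsd_len_range[2]))) {
      if (s - L < 1L || e + L > n) next
      left <- chars[(s - L):(s - 1L)]
      right <- chars[(e + 1L):(e + L)]
      if (all(left == right) && !any(left == "N")) {
        sc <- L - combos$dist[ci]
        if (sc > best_score || (sc == best_score && L > best$len)) {
          best <- list(d5 = d5, d3 = d3, tsd = paste(left, collapse = ""), len = L)
          best_score <- sc
        }
        break   # longer L at same shift already checked first
      }
    }
  }
  best
}

#' Extend seed chains into candidate elements
#'
#' Seed pairs are grouped into collinear chains (same offset within
#' `band_width`, positions within the admissible spacing), each chain's two
#' repeat copies are extended outward by ungapped X-drop extension, and the
#' element boundaries are snapped to the best flanking target-site
#' duplication within a +-2 bp window when one exists.  Candidates from
#' chains describing the same repeat are merged (best score kept).
#'
#' @param genome named `DNAStringSet`.
#' @param seed_pairs output of [find_seed_pairs()].
#' @param params [detector_params()].
#' @return candidate element data.frame (element schema plus `ltr_identity`,
#'   `tsd`, `score`).
#' @export
extend_seed_chain <- function(genome, seed_pairs, params = detector_params()) {
  k <- params$seed_k
  cands <- list()
  for (sid in unique(seed_pairs$seqid)) {
    sp <- seed_pairs[seed_pairs$seqid == sid, ]
    chars <- strsplit(as.character(genome[[sid]]), "")[[1]]
    sp$offset <- sp$pos2 - sp$pos1
    sp <- sp[order(sp$offset, sp$pos1), ]
    # split into chains: offset jump > band_width or pos1 jump > max LTR len
    brk <- c(TRUE, diff(sp$offset) > params$band_width |
               abs(diff(sp$pos1)) > params$ltr_len_range[2])
    sp$chain <- cumsum(brk)
    for (ch in unique(sp$chain)) {
      cc <- sp[sp$chain == ch, ]
      a1 <- min(cc$pos1); b1 <- max(cc$pos1) + k - 1L
      a2 <- min(cc$pos2); b2 <- max(cc$pos2) + k - 1L
      ext <- xdrop_extend(chars, a1, b1, a2, b2,
                          params$match, params$mismatch, params$xdrop)
      l5s <- a1 - ext["left"]; l3s <- a2 - ext["left"]
      l5e <- b1 + ext["right"]; l3e <- b2 + ext["right"]
      ref <- refine_boundaries_tsd(chars, l5s, l3e, params$tsd_len_range)
      if (!is.na(ref$tsd)) {
        l5s <- l5s + ref$d5; l3s <- l3s + ref$d5   # keep copies in register
        l3e <- l3e + ref$d3; l5e <- l5e + ref$d3
      }
      if (l5e >= l3s) { clip <- (b1 + a2) %/% 2L
        l5e <- min(l5e, clip); l3s <- max(l3s, clip + 1L) }
      len5 <- l5e - l5s + 1L; len3 <- l3e - l3s + 1L
      ncol <- min(len5, len3)
      m <- sum(chars[l5s:(l5s + ncol - 1L)] == chars[l3s:(l3s + ncol - 1L)] &
                 chars[l5s:(l5s + ncol - 1L)] != "N")
      ident <- m / max(len5, len3)
      cands[[length(cands) + 1L]] <- data.frame(
        seqid = sid, start = l5s, end = l3e,
        ltr5_start = l5s, ltr5_end = l5e, ltr3_start = l3s, ltr3_end = l3e,
        ltr_identity = ident, tsd = ref$tsd,
        score = ident * min(len5, len3), stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) return(empty_candidates())
  out <- do.call(rbind, cands)
  merge_duplicate_candidates(out)
}

empty_candidates <- function() {
  data.frame(element_id = character(0), seqid = character(0),
             start = integer(0), end = integer(0),
             ltr5_start = integer(0), ltr5_end = integer(0),
             ltr3_start = integer(0), ltr3_end = integer(0),
             ltr_identity = numeric(0), tsd = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# Merge candidates whose both repeat intervals overlap >= 50% reciprocally.
merge_duplicate_candidates <- function(cand) {
  cand <- cand[order(cand$seqid, cand$start, cand$end), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cand))) {
      if (i == j || !keep[j] || cand$seqid[i] != cand$seqid[j]) next
      r5 <- reciprocal_overlap(cand$ltr5_start[i], cand$ltr5_end[i],
                               cand$ltr5_start[j], cand$ltr5_end[j])
      r3 <- reciprocal_overlap(cand$ltr3_start[i], cand$ltr3_end[i],
                               cand$ltr3_start[j], cand$ltr3_end[j])
      if (r5 >= 0.5 && r3 >= 0.5) {
        if (cand$score[j] > cand$score[i] ||
            (cand$score[j] == cand$score[i] && j < i)) keep[i] <- FALSE
        else keep[j] <- FALSE
      }
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Detect the target-site duplication flanking a candidate
#'
#' Longest exact match (length within `tsd_len_range`) between the window
#' immediately 5' of the element and the window immediately 3' of it; ties
#' broken toward longer matches.  Elements at a sequence edge have no TSD.
#'
#' @param genome named `DNAStringSet`.
#' @param candidate one-row element data.frame (uses `seqid`, `start`, `end`).
#' @param tsd_len_range length-2 integer range.
#' @return TSD string, or `NA_character_` when absent.
#' @export
detect_tsd <- function(genome, candidate, tsd_len_range = c(4L, 6L)) {
  s <- candidate$start; e <- candidate$end
  chars <- strsplit(as.character(genome[[candidate$seqid]]), "")[[1]]
  for (L in rev(seq(tsd_len_range[1], tsd_len_range[2]))) {
    if (s - L < 1L || e + L > length(chars)) next
    left <- chars[(s - L):(s - 1L)]
    right <- chars[(e + 1L):(e + L)]
    if (all(left == right) && !any(left == "N")) return(paste(left, collapse = ""))
  }
  NA_character_
}

#' Filter and resolve candidate elements
#'
#' Keeps candidates whose repeat lengths, pair identity and (optionally)
#' TSD satisfy the detector parameters, then resolves overlaps exactly by
#' weighted interval scheduling on `score = identity * min(LTR lengths)`
#' (the selected set maximises total score; of two fully overlapping
#' candidates the higher score always survives).  Output is sorted by
#' coordinate and labelled `cand_0001`, ...
#'
#' @param candidates data.frame from [extend_seed_chain()].
#' @param genome named `DNAStringSet` (used to re-check TSDs).
#' @param params [detector_params()].
#' @return filtered candidate data.frame.
#' @export
filter_candidates <- function(candidates, genome, params = detector_params()) {
  if (!nrow(candidates)) return(empty_candidates())
  len5 <- candidates$ltr5_end - candidates$ltr5_start + 1L
  len3 <- candidates$ltr3_end - candidates$ltr3_start + 1L
  ok <- len5 >= params$ltr_len_range[1] & len5 <= params$ltr_len_range[2] &
    len3 >= params$ltr_len_range[1] & len3 <= params$ltr_len_range[2] &
    candidates$ltr_identity >= params$min_ltr_identity
  spacing <- candidates$ltr3_start - candidates$ltr5_start
  ok <- ok & spacing >= params$ltr_start_spacing_range[1] &
    spacing <= params$ltr_start_spacing_range[2]
  if (params$require_tsd) ok <- ok & !is.na(candidates$tsd)
  cand <- candidates[ok, , drop = FALSE]
  if (!nrow(cand)) return(empty_candidates())
  # containment filter: a terminal-repeat pair bracketing a second intact
  # pair is a chimeric pairing across neighbouring insertions (elements do
  # not nest here); drop the outer candidate
  drop <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    inner <- cand$seqid == cand$seqid[i] & seq_len(nrow(cand)) != i &
      cand$start >= cand$start[i] & cand$end <= cand$end[i] &
      (cand$end - cand$start) < (cand$end[i] - cand$start[i]) &
      cand$score >= 0.3 * cand$score[i]
    if (any(inner)) drop[i] <- TRUE
  }
  cand <- cand[!drop, , drop = FALSE]
  if (!nrow(cand)) return(empty_candidates())
  # exact overlap resolution per sequence
  out <- list()
  for (sid in unique(cand$seqid)) {
    cc <- cand[cand$seqid == sid, , drop = FALSE]
    cc <- cc[order(cc$end, cc$start), , drop = FALSE]
    n <- nrow(cc)
    # p[i]: last candidate ending before cc$start[i]
    p <- vapply(seq_len(n), function(i) {
      prev <- which(cc$end < cc$start[i])
      if (length(prev)) max(prev) else 0L
    }, 0L)
    opt <- numeric(n + 1L); take <- logical(n)
    for (i in seq_len(n)) {
      with_i <- cc$score[i] + opt[p[i] + 1L]
      opt[i + 1L] <- max(opt[i], with_i)
    }
    sel <- logical(n); i <- n
    while (i >= 1L) {
      if (cc$score[i] + opt[p[i] + 1L] >= opt[i]) { sel[i] <- TRUE; i <- p[i] }
      else i <- i - 1L
    }
    out[[length(out) + 1L]] <- cc[sel, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seqid, res$start), , drop = FALSE]
  res$element_id <- sprintf("cand_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("element_id", setdiff(names(res), "element_id"))]
}

#' Detect full-length LTR retrotransposons in a genome
#'
#' Convenience wrapper running [find_seed_pairs()], [extend_seed_chain()]
#' and [filter_candidates()].
#'
#' @inheritParams find_seed_pairs
#' @return candidate element data.frame.
#' @export
#' @examples
#' tmpl <- family_template("fam1", "Gypsy", seed = 3)
#' bg <- simulate_background(60000, 0.5, seed = 4)
#' sim <- insert_elements(bg, list(tmpl), simulation_config(n_insertions = 2, ages = 0))
#' det <- detect_ltr_elements(sim$genome)
detect_ltr_elements <- function(genome, params = detector_params()) {
  sp <- find_seed_pairs(genome, params)
  if (!nrow(sp)) return(empty_candidates())
  cand <- extend_seed_chain(genome, sp, params)
  filter_candidates(cand, genome, params)
}
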