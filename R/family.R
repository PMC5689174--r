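# Family census: single-linkage clustering of detected copies (80/80
# convention), star-alignment majority consensus per family, seed-and-extend
# annotation of all genomic copies against the consensus library (two
# passes: the second keeps only families retaining at least one full-length
# copy), and the copies / full-length copies / % coverage census with
# union-based totals.

#' Cluster detected elements into families
#'
#' Single-linkage clustering on pairwise local-alignment identity >=
#' `min_identity` over >= `min_mutual_coverage` of both sequence lengths
#' (the 80/80 convention).  Families are numbered deterministically by the
#' leftmost member coordinate.
#'
#' @param elements element data.frame.
#' @param genome named `DNAStringSet`.
#' @param min_identity minimum pairwise identity.
#' @param min_mutual_coverage minimum aligned fraction of both lengths.
#' @return list of class `rb_family_set`: per family a list with
#'   `family_id`, `members` (element_ids), `member_rows` (indices into
#'   `elements`).
#' @export
cluster_copies <- function(elements, genome, min_identity = 0.80,
                           min_mutual_coverage = 0.80) {
  n <- nrow(elements)
  if (!n) rb_stop("no elements to cluster", "rb_value_error")
  seqs <- vapply(seq_len(n), function(i)
    substr(as.character(genome[[elements$seqid[i]]]),
           elements$start[i], elements$end[i]), "")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  # cheap 12-mer Jaccard prefilter: unrelated sequences share essentially no
  # exact 12-mers, so skip the expensive alignment for them
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 12L) return(character(0))
    unique(substring(s, 1:(L - 11L), 12:L))
  })
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (find(i) == find(j)) next     # single linkage: already connected
    shared <- length(intersect(km[[i]], km[[j]]))
    if (shared < 0.04 * min(length(km[[i]]), length(km[[j]]))) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[i]), Biostrings::DNAString(seqs[j]),
      type = "local", substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
    cov_i <- (Biostrings::end(Biostrings::pattern(pa)) -
                Biostrings::start(Biostrings::pattern(pa)) + 1L) / nchar(seqs[i])
    cov_j <- (Biostrings::end(Biostrings::subject(pa)) -
                Biostrings::start(Biostrings::subject(pa)) + 1L) / nchar(seqs[j])
    ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    if (ident >= min_identity && cov_i >= min_mutual_coverage &&
        cov_j >= min_mutual_coverage) {
      parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  # number families by leftmost member coordinate
  ord <- order(elements$seqid, elements$start)
  fam_of <- integer(n); next_id <- 0L
  for (i in ord) {
    c_i <- comp[i]
    if (!any(fam_of[comp == c_i] > 0L)) { next_id <- next_id + 1L; fam_of[comp == c_i] <- next_id }
  }
  fams <- lapply(seq_len(next_id), function(fi) {
    rows <- which(fam_of == fi)
    list(family_id = sprintf("FAM_%03d", fi),
         members = elements$element_id[rows], member_rows = rows)
  })
  structure(fams, class = "rb_family_set")
}

#' Build a family consensus sequence
#'
#' Star alignment of all members to the longest member; per column the
#' majority base wins, ties resolve to the longest member's base.  The
#' consensus carries no gap characters and has the length of the longest
#' member.
#'
#' @param family one entry of [cluster_copies()] output.
#' @param elements element data.frame.
#' @param genome named `DNAStringSet`.
#' @return consensus nucleotide string.
#' @export
build_consensus <- function(family, elements, genome) {
  rows <- family$member_rows
  seqs <- vapply(rows, function(i)
    substr(as.character(genome[[elements$seqid[i]]]),
           elements$start[i], elements$end[i]), "")
  if (length(seqs) == 1L) return(seqs)
  centre <- which.max(nchar(seqs))
  cen <- seqs[centre]
  Lc <- nchar(cen)
  votes <- matrix(0L, nrow = 5L, ncol = Lc, dimnames = list(c(DNA_BASES, "N"), NULL))
  cen_chars <- strsplit(cen, "")[[1]]
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (m in seq_along(seqs)) {
    if (m == centre) {
      idx <- cbind(match(cen_chars, rownames(votes)), seq_len(Lc))
      votes[idx] <- votes[idx] + 1L
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[m]), Biostrings::DNAString(cen),
      type = "global", substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    cpos <- cumsum(as_ != "-")
    usable <- as_ != "-" & ap %in% rownames(votes)
    idx <- cbind(match(ap[usable], rownames(votes)), cpos[usable])
    votes[idx] <- votes[idx] + 1L
  }
  votes["N", ] <- 0L   # N never wins a column
  best <- apply(votes, 2L, max)
  cons <- vapply(seq_len(Lc), function(j) {
    winners <- rownames(votes)[votes[, j] == best[j] & votes[, j] > 0L]
    if (cen_chars[j] %in% winners || !length(winners)) cen_chars[j] else winners[1]
  }, "")
  paste(cons, collapse = "")
}

# chain k-mer matches of one consensus against one genome strand
chain_consensus_hits <- function(gpos, cpos, k, max_gap = 600L, band = 50L) {
  o <- order(gpos - cpos, gpos)
  gpos <- gpos[o]; cpos <- cpos[o]
  diag <- gpos - cpos
  brk <- c(TRUE, diff(diag) > band | abs(diff(gpos)) > max_gap)
  ch <- cumsum(brk)
  lapply(unique(ch), function(ci) {
    i <- ch == ci
    list(g = c(min(gpos[i]), max(gpos[i]) + k - 1L),
         c = c(min(cpos[i]), max(cpos[i]) + k - 1L))
  })
}

#' Annotate genomic copies of a consensus library
#'
#' Seed-and-extend local matching of each consensus against both genome
#' strands (exact k-mer seeds on collinear chains, ungapped X-drop
#' extension toward the consensus ends); overlapping hits of one family are
#' merged.  `fraction_of_consensus` is the aligned consensus span divided
#' by consensus length (capped at 1).
#'
#' @param genome named `DNAStringSet`.
#' @param consensus_lib named character vector (family_id -> consensus).
#' @param min_identity minimum hit identity.
#' @param min_hit_len minimum hit length in bp.
#' @param seed_k seed k-mer length.
#' @return data.frame: `seqid`, `start`, `end`, `strand`, `family_id`,
#'   `identity`, `fraction_of_consensus`.
#' @export
annotate_copies <- function(genome, consensus_lib, min_identity = 0.80,
                            min_hit_len = 80L, seed_k = 12L) {
  if (!length(consensus_lib)) rb_stop("empty consensus library", "rb_value_error")
  hits <- list()
  for (si in seq_along(genome)) {
    gseq <- as.character(genome[[si]])
    gchars <- strsplit(gseq, "")[[1]]
    ng <- length(gchars)
    gstarts <- seq_len(max(0L, ng - seed_k + 1L))
    gk <- substring(gseq, gstarts, gstarts + seed_k - 1L)
    gidx <- split(gstarts, gk)
    for (fam in names(consensus_lib)) {
      for (strand in c("+", "-")) {
        cons <- consensus_lib[[fam]]
        if (strand == "-")
          cons <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
        cchars <- strsplit(cons, "")[[1]]
        nc <- length(cchars)
        if (nc < seed_k) next
        cstarts <- seq_len(nc - seed_k + 1L)
        ck <- substring(cons, cstarts, cstarts + seed_k - 1L)
        mlist <- gidx[ck]
        has <- !vapply(mlist, is.null, TRUE)
        if (!any(has)) next
        gpos <- unlist(mlist[has], use.names = FALSE)
        cpos <- rep(cstarts[has], lengths(mlist[has]))
        for (chain in chain_consensus_hits(gpos, cpos, seed_k)) {
          g <- chain$g; cc <- chain$c
          # extend along the shared diagonal toward the consensus ends,
          # then keep the maximum-scoring contiguous segment (+2/-3), which
          # trims background picked up beyond a truncated copy's boundary
          # extend along the diagonal anchored at the chain start
          left_room <- min(cc[1] - 1L, g[1] - 1L)
          gs0 <- g[1] - left_room
          cs0 <- cc[1] - left_room
          ge0 <- min(ng, g[1] + (nc - cc[1]))
          if (ge0 < gs0) next
          eq <- gchars[gs0:ge0] == cchars[cs0:(cs0 + ge0 - gs0)] &
            gchars[gs0:ge0] != "N"
          sc <- ifelse(eq, 2, -3)
          # Kadane with segment recovery
          best <- -Inf; cur <- 0; cur_s <- 1L; b_s <- 1L; b_e <- 1L
          for (ii in seq_along(sc)) {
            if (cur <= 0) { cur <- sc[ii]; cur_s <- ii } else cur <- cur + sc[ii]
            if (cur > best) { best <- cur; b_s <- cur_s; b_e <- ii }
          }
          gs <- gs0 + b_s - 1L; ge <- gs0 + b_e - 1L
          cs <- cs0 + b_s - 1L; ce <- cs0 + b_e - 1L
          ident <- mean(eq[b_s:b_e]); len <- ge - gs + 1L
          if (len < min_hit_len || ident < min_identity) next
          cons_span <- if (strand == "+") c(cs, ce) else c(nc - ce + 1L, nc - cs + 1L)
          hits[[length(hits) + 1L]] <- data.frame(
            seqid = names(genome)[si], start = gs, end = ge, strand = strand,
            family_id = fam, identity = ident,
            cons_start = cons_span[1], cons_end = cons_span[2],
            fraction_of_consensus = min(1, (ce - cs + 1L) / nc),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(seqid = character(0), start = integer(0), end = integer(0),
                      strand = character(0), family_id = character(0),
                      identity = numeric(0), cons_start = integer(0),
                      cons_end = integer(0), fraction_of_consensus = numeric(0)))
  h <- do.call(rbind, hits)
  merge_family_hits(h, vapply(consensus_lib, nchar, 0L))
}

# merge overlapping genome intervals of one family.  The merged
# annotation's fraction_of_consensus is its genome width over the consensus
# length: under the indel-free copy model the aligned genome length equals
# the consensus span covered, and (unlike a consensus-side union) it does
# not double-count a solo LTR matching both terminal repeats of the
# consensus.
merge_family_hits <- function(h, cons_len) {
  out <- list()
  for (fam in unique(h$family_id)) for (sid in unique(h$seqid)) {
    hh <- h[h$family_id == fam & h$seqid == sid, , drop = FALSE]
    if (!nrow(hh)) next
    ir <- IRanges::reduce(IRanges::IRanges(hh$start, hh$end))
    for (i in seq_along(ir)) {
      s <- IRanges::start(ir)[i]; e <- IRanges::end(ir)[i]
      inside <- hh$start <= e & hh$end >= s
      cl <- min(hh$cons_start[inside]); cu <- max(hh$cons_end[inside])
      out[[length(out) + 1L]] <- data.frame(
        seqid = sid, start = s, end = e,
        strand = hh$strand[inside][which.max(hh$end[inside] - hh$start[inside])],
        family_id = fam, identity = max(hh$identity[inside]),
        cons_start = cl, cons_end = cu,
        fraction_of_consensus = min(1, (e - s + 1L) / cons_len[[fam]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seqid, res$start, res$family_id), ]
  rownames(res) <- NULL
  res
}

#' Table-4-style census
#'
#' Per family: `n_copies` (merged annotations), `n_full_copies`
#' (annotations covering >= `full_copy_min_fraction` of the consensus) and
#' `coverage_percent` (100 x union of annotated intervals / genome length).
#' Per-classification and TOTAL rows are computed on the union of member
#' intervals, never by summing family coverages.
#'
#' @param copies data.frame from [annotate_copies()].
#' @param genome named `DNAStringSet` (assembly length is the denominator,
#'   N runs included).
#' @param classification optional named character (family_id -> label, e.g.
#'   "Gypsy") used for per-order rows.
#' @param full_copy_min_fraction full-length cutoff (default 0.95).
#' @return data.frame with `family_id`, `classification`, `n_copies`,
#'   `n_full_copies`, `coverage_percent`; per-order and TOTAL rows have
#'   `family_id = NA`.
#' @export
quantify <- function(copies, genome, classification = NULL,
                     full_copy_min_fraction = 0.95) {
  glen <- sum(Biostrings::width(genome))
  union_bp <- function(df) {
    if (!nrow(df)) return(0L)
    sum(vapply(unique(df$seqid), function(sid) {
      dd <- df[df$seqid == sid, ]
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(dd$start, dd$end))))
    }, 0L))
  }
  fams <- sort(unique(copies$family_id))
  rows <- lapply(fams, function(fam) {
    cf <- copies[copies$family_id == fam, ]
    data.frame(family_id = fam,
               classification = unname(classification[fam] %||% NA_character_),
               n_copies = nrow(cf),
               n_full_copies = sum(cf$fraction_of_consensus >= full_copy_min_fraction),
               coverage_percent = 100 * union_bp(cf) / glen,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  extra <- list()
  if (!is.null(classification)) {
    for (cl in sort(unique(stats::na.omit(unname(classification))))) {
      in_cl <- copies$family_id %in% names(classification)[classification == cl]
      cf <- copies[in_cl, ]
      extra[[length(extra) + 1L]] <- data.frame(
        family_id = NA_character_, classification = cl, n_copies = nrow(cf),
        n_full_copies = sum(cf$fraction_of_consensus >= full_copy_min_fraction),
        coverage_percent = 100 * union_bp(cf) / glen, stringsAsFactors = FALSE)
    }
  }
  extra[[length(extra) + 1L]] <- data.frame(
    family_id = NA_character_, classification = "TOTAL", n_copies = nrow(copies),
    n_full_copies = sum(copies$fraction_of_consensus >= full_copy_min_fraction),
    coverage_percent = 100 * union_bp(copies) / glen, stringsAsFactors = FALSE)
  out <- rbind(res, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Full census pipeline for a set of detected elements
#'
#' Clusters elements into families, builds consensi, annotates all genomic
#' copies in two passes (pass 2 keeps families retaining at least one
#' full-length copy), and tabulates the census.
#'
#' @param genome named `DNAStringSet`.
#' @param elements detected element data.frame (optionally classified).
#' @param min_identity,min_mutual_coverage clustering thresholds.
#' @param full_copy_min_fraction full-length cutoff.
#' @return list of class `rb_census`: `families`, `consensus_lib`,
#'   `copies`, `census` (the table), `classification`.
#' @export
census <- function(genome, elements, min_identity = 0.80,
                   min_mutual_coverage = 0.80, full_copy_min_fraction = 0.95) {
  fams <- cluster_copies(elements, genome, min_identity, min_mutual_coverage)
  lib <- vapply(fams, function(f) build_consensus(f, elements, genome), "")
  names(lib) <- vapply(fams, `[[`, "", "family_id")
  classification <- NULL
  if ("superfamily" %in% names(elements)) {
    classification <- vapply(fams, function(f) {
      sf <- elements$superfamily[f$member_rows]
      sf <- sf[!is.na(sf) & sf != "unknown"]
      if (!length(sf)) "unknown" else names(sort(table(sf), decreasing = TRUE))[1]
    }, "")
    names(classification) <- names(lib)
  }
  pass1 <- annotate_copies(genome, lib)
  keep <- vapply(names(lib), function(fam) {
    any(pass1$family_id == fam &
          pass1$fraction_of_consensus >= full_copy_min_fraction)
  }, TRUE)
  lib2 <- lib[keep]
  copies <- if (length(lib2)) annotate_copies(genome, lib2) else pass1[0, ]
  structure(list(families = fams, consensus_lib = lib, copies = copies,
                 census = quantify(copies, genome, classification,
                                   full_copy_min_fraction),
                 classification = classification),
            class = "rb_census")
}
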