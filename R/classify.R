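# Superfamily classification by internal protein-domain order: six-frame
# translation, Smith-Waterman scan against a bundled reference-peptide
# library (BLOSUM62), then the structural rule — reverse transcriptase
# before integrase on the coding strand = Gypsy, integrase first = Copia,
# and a chromodomain downstream of the integrase marks Chromoviridae.
#
# The bundled library is synthetic (seeded random peptides, regenerated by
# data-raw/make_domain_library.R); per-domain score thresholds are frozen at
# the 99th percentile of a Monte-Carlo null of random 3-kb sequences.

DOMAIN_NAMES <- c("GAG", "AP", "RT", "RH", "INT", "CHROMO")

#' Load the bundled (or a user) domain peptide library
#'
#' @param fasta peptide FASTA; entry ids are `DOMAIN:tag` (e.g. `RT:gypsy`).
#' @param thresholds TSV with columns `domain`, `min_score`.
#' @return list of class `rb_domain_library` with `peptides` (named
#'   character) and `min_score` (named numeric per domain).
#' @export
load_domain_library <- function(
    fasta = system.file("extdata", "domain_library_synthetic.fasta",
                        package = "retroburst"),
    thresholds = system.file("extdata", "domain_min_scores_synthetic.tsv",
                             package = "retroburst")) {
  pep <- Biostrings::readAAStringSet(fasta)
  peptides <- setNames(as.character(pep), sub("\\s.*$", "", names(pep)))
  doms <- sub(":.*$", "", names(peptides))
  if (!all(c("AP", "RT", "INT") %in% doms))
    rb_stop("domain library must cover at least AP, RT and INT", "rb_value_error")
  th <- read_tsv(thresholds)
  structure(list(peptides = peptides,
                 min_score = setNames(th$min_score, th$domain)),
            class = "rb_domain_library")
}

#' Six-frame translation
#'
#' Standard genetic code; stop codons are rendered `*`, fuzzy codons
#' (containing N) as `X`.  Frames -1..-3 translate the reverse complement.
#'
#' @param sequence nucleotide string (length >= 3).
#' @return named character vector of six peptides (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
#' @examples
#' six_frame_translate("ATGGCC")[["+1"]]  # "MA"
six_frame_translate <- function(sequence) {
  if (nchar(sequence) < 3L) rb_stop("sequence must be >= 3 nt", "rb_value_error")
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  tr <- function(s, f) {
    sub <- Biostrings::subseq(s, f, f + ((length(s) - f + 1L) %/% 3L) * 3L - 1L)
    if (length(sub) < 3L) return("")
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  c(`+1` = tr(fwd, 1L), `+2` = tr(fwd, 2L), `+3` = tr(fwd, 3L),
    `-1` = tr(rev, 1L), `-2` = tr(rev, 2L), `-3` = tr(rev, 3L))
}

# Map a peptide interval in reading frame f back to nucleotide coordinates
# on the original (forward) sequence.  L = nucleotide length.
frame_to_nt <- function(aa_start, aa_end, frame, L) {
  f <- abs(frame)
  s <- 3L * (aa_start - 1L) + f
  e <- 3L * aa_end + f - 1L
  if (frame > 0) c(s, e) else c(L - e + 1L, L - s + 1L)
}

#' Scan an element for retrotransposon protein domains
#'
#' Local (Smith-Waterman) alignment of each translation frame against each
#' library reference under BLOSUM62; hits at or above the per-domain
#' threshold are reported with nucleotide coordinates mapped back from
#' peptide coordinates; overlapping hits for one domain collapse to the
#' best-scoring one.
#'
#' @param sequence element nucleotide string.
#' @param library [load_domain_library()].
#' @param gap_open,gap_extend positive gap costs.
#' @return data.frame of hits: `domain`, `ref`, `frame`, `nt_start`,
#'   `nt_end`, `cs_start` (start in coding-strand orientation), `score`,
#'   `pident`.
#' @export
scan_domains <- function(sequence, library = load_domain_library(),
                         gap_open = 10, gap_extend = 0.5) {
  if (!length(library$peptides)) rb_stop("empty domain library", "rb_value_error")
  frames <- six_frame_translate(sequence)
  L <- nchar(sequence)
  mat <- blosum62()
  hits <- list()
  for (fr in names(frames)) {
    pepseq <- chartr("*", "X", frames[[fr]])   # stops scored as X in the scan
    if (nchar(pepseq) < 5L) next
    f <- as.integer(fr)
    for (ref in names(library$peptides)) {
      dom <- sub(":.*$", "", ref)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pepseq), Biostrings::AAString(library$peptides[[ref]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_extend)
      sc <- Biostrings::score(pa)
      if (sc < (library$min_score[[dom]] %||% 0)) next
      aa_s <- Biostrings::start(Biostrings::pattern(pa))
      aa_e <- Biostrings::end(Biostrings::pattern(pa))
      nt <- frame_to_nt(aa_s, aa_e, f, L)
      cs <- if (f > 0) nt[1] else L - nt[2] + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        domain = dom, ref = ref, frame = f,
        nt_start = nt[1], nt_end = nt[2], cs_start = cs,
        score = sc, pident = Biostrings::pid(pa, type = "PID1"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(domain = character(0), ref = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0), cs_start = integer(0),
                      score = numeric(0), pident = numeric(0)))
  h <- do.call(rbind, hits)
  # collapse overlapping hits of one domain to the best score
  h <- h[order(h$domain, -h$score), ]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(h)) > i & h$domain == h$domain[i] &
                 interval_overlap(h$nt_start[i], h$nt_end[i],
                                  h$nt_start, h$nt_end) > 0L)
    keep[j] <- FALSE
  }
  h <- h[keep, ]
  h <- h[order(h$cs_start), ]
  rownames(h) <- NULL
  h
}

#' Classify an element from its domain hits
#'
#' The coding strand is the strand of the best reverse-transcriptase hit
#' (or the strand with the highest total score when RT is absent).  On that
#' strand: RT start before INT start = Gypsy, INT before RT = Copia,
#' otherwise unknown; Chromoviridae = Gypsy with a chromodomain hit
#' starting after the integrase.
#'
#' @param hits data.frame from [scan_domains()].
#' @return list of class `rb_classification` with `superfamily`
#'   (`"Gypsy"`/`"Copia"`/`"unknown"`), `chromoviridae` (flag) and
#'   `evidence` (ordered domain names on the coding strand).
#' @export
classify_element <- function(hits) {
  res <- function(sf, chromo, ev) {
    if (chromo && sf != "Gypsy") chromo <- FALSE   # invariant: chromo => Gypsy
    structure(list(superfamily = sf, chromoviridae = chromo, evidence = ev),
              class = "rb_classification")
  }
  if (!nrow(hits)) return(res("unknown", FALSE, character(0)))
  rt <- hits[hits$domain == "RT", ]
  strand <- if (nrow(rt)) sign(rt$frame[which.max(rt$score)]) else {
    plus <- sum(hits$score[hits$frame > 0]); minus <- sum(hits$score[hits$frame < 0])
    if (minus > plus) -1 else 1
  }
  h <- hits[sign(hits$frame) == strand, ]
  h <- h[order(h$cs_start), ]
  ev <- h$domain
  rt_s <- h$cs_start[h$domain == "RT"][1]
  int_s <- h$cs_start[h$domain == "INT"][1]
  if (is.na(rt_s) || is.na(int_s)) return(res("unknown", FALSE, ev))
  sf <- if (rt_s < int_s) "Gypsy" else "Copia"
  chromo_s <- h$cs_start[h$domain == "CHROMO"]
  chromo <- sf == "Gypsy" && length(chromo_s) > 0 && any(chromo_s > int_s)
  res(sf, chromo, ev)
}

#' @export
print.rb_classification <- function(x, ...) {
  cat(sprintf("superfamily: %s%s  [%s]\n", x$superfamily,
              if (x$chromoviridae) " (Chromoviridae)" else "",
              paste(x$evidence, collapse = " > ")))
  invisible(x)
}

#' Classify every element of a candidate table
#'
#' @param genome named `DNAStringSet`.
#' @param elements element data.frame.
#' @param library [load_domain_library()].
#' @return `elements` with added columns `superfamily`, `chromoviridae`,
#'   `domains` (comma-joined evidence), plus the hit table as attribute
#'   `"hits"` (a named list).
#' @export
classify_elements <- function(genome, elements, library = load_domain_library()) {
  sfs <- character(nrow(elements)); chromo <- logical(nrow(elements))
  doms <- character(nrow(elements)); all_hits <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    seq <- substr(as.character(genome[[elements$seqid[i]]]),
                  elements$start[i], elements$end[i])
    h <- scan_domains(seq, library)
    cl <- classify_element(h)
    sfs[i] <- cl$superfamily; chromo[i] <- cl$chromoviridae
    doms[i] <- paste(cl$evidence, collapse = ",")
    all_hits[[i]] <- h
  }
  elements$superfamily <- sfs
  elements$chromoviridae <- chromo
  elements$domains <- doms
  names(all_hits) <- elements$element_id
  attr(elements, "hits") <- all_hits
  elements
}
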