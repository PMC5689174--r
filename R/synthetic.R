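# Synthetic-genome module: genomes carrying LTR-retrotransposon insertions of
# known age, family and structure, plus matching truth annotations and
# gene -> GO tables with planted enrichment.  Ground truth for every
# downstream stage.
#
# Substitution process: per site, a Poisson(rate_r * age_T) number of single
# base substitutions applied sequentially; each substitution is a transition
# with probability transition_fraction (default 0.5, i.e. alpha = 2*beta,
# matching the Kimura 2P estimator downstream) and otherwise one of the two
# transversions uniformly.  Both LTR copies evolve independently, so the
# expected pair divergence is ~ 2 * rate_r * age_T (minus multiple hits).

DNA_BASES <- c("A", "C", "G", "T")
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Simulate a random background genome
#'
#' Bases are drawn independently with P(G) + P(C) = `gc_fraction` (split
#' evenly within each pair), giving a repeat-free substrate for element
#' insertion.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc_fraction target GC content in (0, 1).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param seq_id sequence name.
#' @return named `DNAStringSet` with a single record.
#' @export
#' @examples
#' g <- simulate_background(2000, 0.5, seed = 1)
simulate_background <- function(length, gc_fraction = 0.5, seed = 1L, seq_id = "chr1") {
  if (!is.numeric(length) || length < 1000)
    rb_stop("length must be a number >= 1000", "rb_value_error")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    rb_stop("gc_fraction must be in (0, 1)", "rb_value_error")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                               collapse = ""))
  setNames(Biostrings::DNAStringSet(seq), seq_id)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Reverse-translate a peptide with uniformly random synonymous codons.
reverse_translate <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  aa <- strsplit(peptide, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- by_aa[[a]]
    if (is.null(cods)) rb_stop(paste0("no codon for residue ", a), "rb_value_error")
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

#' Build a family template with a realistic domain layout
#'
#' The internal region embeds reverse-translated copies of the bundled
#' reference peptides in the canonical order: Gypsy templates carry
#' GAG-AP-RT-RH-INT (with an optional chromodomain after the integrase,
#' the Chromoviridae layout); Copia templates carry GAG-AP-INT-RT-RH.
#' Domain segments are separated by random spacers.
#'
#' @param family_id template label.
#' @param superfamily `"Gypsy"` or `"Copia"`.
#' @param ltr_len terminal-repeat length in bp (100-1500).
#' @param chromovirus add a chromodomain after the integrase (Gypsy only).
#' @param seed integer seed.
#' @param library domain library (see [load_domain_library()]).
#' @param spacer_len length of inter-domain spacers in bp.
#' @return object of class `rb_family_template`: list with `family_id`,
#'   `ltr_sequence`, `internal_sequence`, `domain_layout` (data.frame of
#'   domain, start, end on the internal sequence) and `superfamily_truth`.
#' @export
family_template <- function(family_id, superfamily = c("Gypsy", "Copia"),
                            ltr_len = 350L, chromovirus = (superfamily == "Gypsy"),
                            seed = 1L, library = load_domain_library(),
                            spacer_len = 60L) {
  superfamily <- match.arg(superfamily)
  if (ltr_len < 100L || ltr_len > 1500L)
    rb_stop("ltr_len must be in [100, 1500]", "rb_value_error")
  chromovirus <- isTRUE(chromovirus) && superfamily == "Gypsy"
  order <- if (superfamily == "Gypsy") c("GAG", "AP", "RT", "RH", "INT") else
    c("GAG", "AP", "INT", "RT", "RH")
  if (chromovirus) order <- c(order, "CHROMO")
  tag <- tolower(superfamily)
  with_seed(seed, {
    ltr <- random_dna(ltr_len)
    segs <- character(0); layout <- list(); pos <- 0L
    for (dom in order) {
      sp <- random_dna(spacer_len)
      segs <- c(segs, sp); pos <- pos + nchar(sp)
      hit <- grep(paste0("^", dom, ":", tag), names(library$peptides))
      if (!length(hit)) hit <- grep(paste0("^", dom, ":"), names(library$peptides))
      if (!length(hit)) rb_stop(paste0("library lacks domain ", dom), "rb_value_error")
      pep <- library$peptides[[hit[1]]]
      dna <- reverse_translate(pep)
      segs <- c(segs, dna)
      layout[[dom]] <- data.frame(domain = dom, start = pos + 1L,
                                  end = pos + nchar(dna), stringsAsFactors = FALSE)
      pos <- pos + nchar(dna)
    }
    segs <- c(segs, random_dna(spacer_len))
    structure(list(family_id = family_id, ltr_sequence = ltr,
                   internal_sequence = paste(segs, collapse = ""),
                   domain_layout = do.call(rbind, layout),
                   superfamily_truth = superfamily),
              class = "rb_family_template")
  })
}

# Apply the substitution process to one sequence (character scalar).
mutate_dna <- function(seq, lambda, transition_fraction) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- rpois(n, lambda)
  idx <- which(hits > 0L)
  for (i in idx) {
    for (k in seq_len(hits[i])) {
      b <- chars[i]
      chars[i] <- if (runif(1) < transition_fraction) TRANSITION_OF[[b]] else {
        tv <- TRANSVERSIONS_OF[[b]]
        tv[sample.int(2L, 1L)]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Age an LTR pair by independent divergence
#'
#' Both copies start identical and accumulate substitutions independently
#' for `age_T` years at rate `rate_r` (substitutions/site/yr) under the
#' transition-biased process described in the package vignette.
#'
#' @param ltr_sequence character, the ancestral terminal repeat.
#' @param age_T insertion age in years (>= 0).
#' @param rate_r substitution rate per site per year (default 1.05e-9, the
#'   fungal rate used for dating).
#' @param transition_fraction probability that a substitution is a
#'   transition (default 0.5).
#' @param seed integer seed.
#' @return list with elements `ltr5` and `ltr3` (character).
#' @export
age_ltr_pair <- function(ltr_sequence, age_T, rate_r = 1.05e-9,
                         transition_fraction = 0.5, seed = 1L) {
  if (age_T < 0) rb_stop("age_T must be >= 0", "rb_value_error")
  lambda <- rate_r * age_T
  with_seed(seed, list(ltr5 = mutate_dna(ltr_sequence, lambda, transition_fraction),
                       ltr3 = mutate_dna(ltr_sequence, lambda, transition_fraction)))
}

#' Simulation configuration
#'
#' Bundles and validates the knobs of [insert_elements()].  Defaults state
#' the simulated world: the fungal substitution rate 1.05e-9
#' substitutions/site/yr, an unbiased transition fraction of 0.5, no
#' indels, and target-site duplications of 4-6 bp.
#'
#' @param n_insertions insertions per family template.
#' @param ages vector of insertion ages in years, recycled over insertions.
#' @param rate_r substitution rate (substitutions/site/yr).
#' @param transition_fraction transition probability per substitution.
#' @param truncation_fraction fraction of insertions left 5'- or 3'-truncated.
#' @param solo_ltr_fraction fraction of insertions planted as solo LTRs.
#' @param indel_rate per-site indel rate applied to internal regions only
#'   (default 0; LTR pairs stay indel-free so dating is exact).
#' @param seed integer seed.
#' @return list of class `rb_sim_config`.
#' @export
simulation_config <- function(n_insertions = 10L, ages = 5e6, rate_r = 1.05e-9,
                              transition_fraction = 0.5, truncation_fraction = 0,
                              solo_ltr_fraction = 0, indel_rate = 0, seed = 1L) {
  for (f in c(transition_fraction, truncation_fraction, solo_ltr_fraction))
    if (f < 0 || f > 1) rb_stop("fractions must be in [0, 1]", "rb_value_error")
  if (rate_r <= 0) rb_stop("rate_r must be > 0", "rb_value_error")
  if (any(ages < 0)) rb_stop("ages must be >= 0", "rb_value_error")
  structure(list(n_insertions = as.integer(n_insertions), ages = ages,
                 rate_r = rate_r, transition_fraction = transition_fraction,
                 truncation_fraction = truncation_fraction,
                 solo_ltr_fraction = solo_ltr_fraction,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "rb_sim_config")
}

#' Insert LTR-retrotransposon copies into a genome
#'
#' Each insertion duplicates a 4-6 bp target site (TSD) flanking the
#' element, ages the two terminal repeats independently with
#' [age_ltr_pair()], and is recorded in a truth table with exact final
#' coordinates.  Truncated copies lose a uniform 20-80% of the element from
#' the 5' or the 3' end; solo-LTR copies consist of a single aged terminal
#' repeat.  Insertion points are distinct, so elements never overlap.
#'
#' @param genome named `DNAStringSet` background.
#' @param templates list of [family_template()] objects.
#' @param config [simulation_config()].
#' @return list with `genome` (expanded `DNAStringSet`) and `truth`
#'   (element data.frame with family_id, age, tsd, truncated, solo columns).
#' @export
insert_elements <- function(genome, templates, config) {
  stopifnot(inherits(config, "rb_sim_config"))
  if (inherits(templates, "rb_family_template")) templates <- list(templates)
  n_total <- length(templates) * config$n_insertions
  glen <- sum(Biostrings::width(genome))
  if (glen < n_total * 20L + 1000L)
    rb_stop("genome too short to host the requested insertions", "rb_value_error")

  with_seed(config$seed, {
    # plan one row per insertion
    plan <- do.call(rbind, lapply(seq_along(templates), function(ti) {
      data.frame(template = ti,
                 family_id = templates[[ti]]$family_id,
                 age = rep_len(config$ages, config$n_insertions),
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(plan)
    n_solo <- round(config$solo_ltr_fraction * n)
    n_trunc <- round(config$truncation_fraction * (n - n_solo))
    kind <- rep("full", n)
    kind[sample.int(n, n_solo)] <- "solo"
    kind[sample(which(kind == "full"), n_trunc)] <- "trunc"
    plan$kind <- kind
    # choose target sequence (weighted by length) and insertion point
    widths <- Biostrings::width(genome)
    plan$seq_i <- sample.int(length(genome), n, replace = TRUE, prob = widths)
    plan$point <- NA_integer_
    for (si in unique(plan$seq_i)) {
      rows <- which(plan$seq_i == si)
      pts <- sort(sample(seq(10L, widths[si] - 10L), length(rows)))
      plan$point[rows] <- pts
    }
    plan <- plan[order(plan$seq_i, plan$point), ]

    out_seqs <- as.character(genome)
    truth <- list()
    for (si in seq_along(genome)) {
      rows <- which(plan$seq_i == si)
      if (!length(rows)) next
      bg <- as.character(genome[[si]])
      pieces <- character(0); last <- 0L; offset <- 0L
      for (ri in rows) {
        p <- plan$point[ri]
        tmpl <- templates[[plan$template[ri]]]
        tsd_len <- sample(4:6, 1L)
        pair <- list(ltr5 = mutate_dna(tmpl$ltr_sequence, config$rate_r * plan$age[ri],
                                       config$transition_fraction),
                     ltr3 = mutate_dna(tmpl$ltr_sequence, config$rate_r * plan$age[ri],
                                       config$transition_fraction))
        llen <- nchar(tmpl$ltr_sequence)
        internal <- tmpl$internal_sequence
        kind <- plan$kind[ri]
        if (kind == "solo") {
          elem <- pair$ltr5
          l5 <- c(1L, llen); l3 <- c(NA_integer_, NA_integer_)
        } else {
          elem <- paste0(pair$ltr5, internal, pair$ltr3)
          elen0 <- nchar(elem)
          l5 <- c(1L, llen); l3 <- c(elen0 - llen + 1L, elen0)
          if (kind == "trunc") {
            frac <- runif(1, 0.2, 0.8)
            cut <- max(1L, as.integer(round(frac * elen0)))
            if (runif(1) < 0.5) {      # 5' truncation
              elem <- substr(elem, cut + 1L, elen0)
              shift <- cut
              l5 <- if (shift >= llen) c(NA_integer_, NA_integer_) else c(NA_integer_, NA_integer_)
              l3 <- l3 - shift
              if (l3[1] < 1L) l3 <- c(NA_integer_, NA_integer_)
            } else {                   # 3' truncation
              elem <- substr(elem, 1L, elen0 - cut)
              if (l3[2] > nchar(elem)) l3 <- c(NA_integer_, NA_integer_)
              if (l5[2] > nchar(elem)) l5 <- c(NA_integer_, NA_integer_)
            }
          }
        }
        # keep planted boundaries unambiguous: if the background base just
        # before the target site equals the element's last base (or the base
        # just after it equals the element's first base) an equally valid
        # shifted element reading with a different TSD would exist; nudge the
        # insertion point until the boundary is unique
        next_p <- plan$point[rows][match(ri, rows) + 1L]
        p_max <- min(p + 8L, (if (is.na(next_p)) nchar(bg) - 10L else next_p - 2L))
        repeat {
          ambiguous <- substr(bg, p, p) == substr(elem, nchar(elem), nchar(elem)) ||
            substr(bg, p + tsd_len + 1L, p + tsd_len + 1L) == substr(elem, 1L, 1L)
          if (!ambiguous || p >= p_max) break
          p <- p + 1L
        }
        tsd <- substr(bg, p + 1L, p + tsd_len)
        construct <- paste0(elem, tsd)   # genome[..p+tsd_len] | elem | tsd | genome[p+tsd_len+1..]
        pieces <- c(pieces, substr(bg, last + 1L, p + tsd_len), construct)
        elem_start <- p + tsd_len + offset + 1L
        elem_end <- elem_start + nchar(elem) - 1L
        truth[[length(truth) + 1L]] <- data.frame(
          element_id = sprintf("truth_%s_%03d", plan$family_id[ri], ri),
          seqid = names(genome)[si],
          start = elem_start, end = elem_end,
          ltr5_start = if (is.na(l5[1])) NA_integer_ else elem_start + l5[1] - 1L,
          ltr5_end = if (is.na(l5[2])) NA_integer_ else elem_start + l5[2] - 1L,
          ltr3_start = if (is.na(l3[1])) NA_integer_ else elem_start + l3[1] - 1L,
          ltr3_end = if (is.na(l3[2])) NA_integer_ else elem_start + l3[2] - 1L,
          family_id = plan$family_id[ri], age = plan$age[ri], tsd = tsd,
          truncated = kind == "trunc", solo = kind == "solo",
          stringsAsFactors = FALSE)
        offset <- offset + nchar(construct)
        last <- p + tsd_len
      }
      pieces <- c(pieces, substr(bg, last + 1L, nchar(bg)))
      out_seqs[si] <- paste(pieces, collapse = "")
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$seqid, truth$start), ]
    rownames(truth) <- NULL
    list(genome = setNames(Biostrings::DNAStringSet(out_seqs), names(genome)),
         truth = truth)
  })
}

#' Simulate gene -> GO and secretome tables with planted enrichment
#'
#' Produces the two inputs of the enrichment stage: a long gene/term table
#' and a secreted-gene set.  `planted_terms` rows are realised exactly:
#' `count_in_secretome` of the `count_in_genome` genes carrying the term are
#' drawn from the secreted subset.  Remaining background terms are assigned
#' to random genes.
#'
#' @param n_genes genome gene count.
#' @param n_secreted secreted subset size.
#' @param planted_terms data.frame with columns `term`,
#'   `count_in_secretome`, `count_in_genome`.
#' @param seed integer seed.
#' @param n_background_terms number of random background GO terms.
#' @param background_genes_per_term mean genes per background term.
#' @return list with `gene2go` (data.frame gene_id, term) and `secreted`
#'   (character vector of gene ids).
#' @export
simulate_annotation_tables <- function(n_genes, n_secreted, planted_terms,
                                       seed = 1L, n_background_terms = 50L,
                                       background_genes_per_term = 20L) {
  if (n_secreted > n_genes) rb_stop("n_secreted must be <= n_genes", "rb_value_error")
  if (nrow(planted_terms) &&
      any(planted_terms$count_in_secretome > planted_terms$count_in_genome))
    rb_stop("count_in_secretome exceeds count_in_genome", "rb_value_error")
  if (nrow(planted_terms) && any(planted_terms$count_in_secretome > n_secreted))
    rb_stop("count_in_secretome exceeds subset size", "rb_value_error")
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    secreted <- sort(sample(genes, n_secreted))
    rows <- list()
    for (i in seq_len(nrow(planted_terms))) {
      tr <- planted_terms[i, ]
      in_sec <- sample(secreted, tr$count_in_secretome)
      out_sec <- sample(setdiff(genes, secreted),
                        tr$count_in_genome - tr$count_in_secretome)
      rows[[length(rows) + 1L]] <- data.frame(gene_id = c(in_sec, out_sec),
                                              term = tr$term, stringsAsFactors = FALSE)
    }
    for (b in seq_len(n_background_terms)) {
      k <- max(1L, rpois(1, background_genes_per_term))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sample(genes, min(k, n_genes)),
        term = sprintf("GO:%07d", 8000000L + b), stringsAsFactors = FALSE)
    }
    gene2go <- unique(do.call(rbind, rows))
    gene2go <- gene2go[order(gene2go$term, gene2go$gene_id), ]
    rownames(gene2go) <- NULL
    list(gene2go = gene2go, secreted = secreted, genes = genes)
  })
}
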