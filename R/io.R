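# Readers/writers shared by all stages: FASTA (via Biostrings), the element
# GFF3 schema, plain TSV tables, and structural format validation.
#
# Element tables are plain data.frames with one row per element and columns
#   element_id, seqid, start, end, ltr5_start, ltr5_end, ltr3_start,
#   ltr3_end  (1-based, inclusive; NA where a terminal repeat is absent)
# plus any stage-specific metadata columns (family_id, age, tsd, truncated,
# solo, ltr_identity, score, superfamily, chromoviridae, ...).  GFF3 output
# uses a parent LTR_retrotransposon feature with long_terminal_repeat
# children, the single interchange schema for truth and detections alike.

ELEMENT_CORE_COLS <- c("element_id", "seqid", "start", "end",
                       "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")

#' Read a genome FASTA file
#'
#' @param path FASTA file path.
#' @return named `DNAStringSet`; ids must be unique, sequences non-empty.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) rb_stop("duplicate sequence ids in FASTA", "rb_format_error")
  if (any(Biostrings::width(x) == 0L)) rb_stop("empty sequence in FASTA", "rb_format_error")
  x
}

#' Write a genome FASTA file
#' @param genome named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}
gff3_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Write an element table as GFF3
#'
#' Each element becomes a `LTR_retrotransposon` feature carrying metadata
#' columns as attributes; complete terminal repeats become
#' `long_terminal_repeat` children.  Coordinates are written 1-based
#' inclusive per the GFF3 standard.
#'
#' @param elements element data.frame (see package docs for the schema).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path, source = "retroburst") {
  stopifnot(all(ELEMENT_CORE_COLS %in% names(elements)))
  meta_cols <- setdiff(names(elements), c(ELEMENT_CORE_COLS, "strand"))
  lines <- "##gff-version 3"
  fmt_attr <- function(key, val) paste0(key, "=", gff3_escape(as.character(val)))
  for (i in seq_len(nrow(elements))) {
    r <- elements[i, ]
    attrs <- fmt_attr("ID", r$element_id)
    for (mc in meta_cols) {
      v <- r[[mc]]
      if (length(v) == 1L && !is.na(v)) attrs <- c(attrs, fmt_attr(mc, v))
    }
    strand <- if ("strand" %in% names(elements) && !is.na(r$strand)) r$strand else "+"
    lines <- c(lines, paste(r$seqid, source, "LTR_retrotransposon",
                            r$start, r$end, ".", strand, ".",
                            paste(attrs, collapse = ";"), sep = "\t"))
    for (side in c("5", "3")) {
      s <- r[[paste0("ltr", side, "_start")]]; e <- r[[paste0("ltr", side, "_end")]]
      if (!is.na(s) && !is.na(e)) {
        lines <- c(lines, paste(r$seqid, source, "long_terminal_repeat",
                                s, e, ".", strand, ".",
                                paste0("ID=", gff3_escape(r$element_id), ".ltr", side,
                                       ";Parent=", gff3_escape(r$element_id)),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an element GFF3 written by [write_elements_gff3()]
#'
#' @param path GFF3 path.
#' @return element data.frame; attribute values come back as character
#'   except the coordinate columns.
#' @export
read_elements_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(ELEMENT_CORE_COLS)),
                                  ELEMENT_CORE_COLS))
    return(out)
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) rb_stop(sprintf("GFF3 line %d does not have 9 fields", bad[1]), "rb_format_error")
  f <- do.call(rbind, f)
  attrs <- lapply(strsplit(f[, 9], ";", fixed = TRUE), function(a) {
    kv <- strsplit(a, "=", fixed = TRUE)
    setNames(gff3_unescape(vapply(kv, `[`, "", 2L)), vapply(kv, `[`, "", 1L))
  })
  is_parent <- f[, 3] == "LTR_retrotransposon"
  parents <- which(is_parent)
  rows <- lapply(parents, function(i) {
    a <- attrs[[i]]
    id <- a[["ID"]]
    kids <- which(!is_parent & vapply(attrs, function(x) identical(unname(x["Parent"]), id), TRUE))
    ltr <- list(`5` = c(NA_integer_, NA_integer_), `3` = c(NA_integer_, NA_integer_))
    for (k in kids) {
      side <- if (grepl("ltr5$", attrs[[k]][["ID"]])) "5" else "3"
      ltr[[side]] <- as.integer(f[k, 4:5])
    }
    meta <- a[setdiff(names(a), "ID")]
    c(list(element_id = id, seqid = f[i, 1],
           start = as.integer(f[i, 4]), end = as.integer(f[i, 5]),
           ltr5_start = ltr$`5`[1], ltr5_end = ltr$`5`[2],
           ltr3_start = ltr$`3`[1], ltr3_end = ltr$`3`[2],
           strand = f[i, 7]),
      as.list(meta))
  })
  all_names <- unique(unlist(lapply(rows, names)))
  out <- as.data.frame(lapply(setNames(all_names, all_names), function(nm)
    unlist(lapply(rows, function(r) if (is.null(r[[nm]])) NA else r[[nm]]))),
    stringsAsFactors = FALSE)
  for (cc in c("start", "end", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end"))
    out[[cc]] <- as.integer(out[[cc]])
  out
}

#' Write / read a TSV table
#' @param x data.frame.
#' @param path file path.
#' @return `path` invisibly for the writer; a data.frame for the reader.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Structurally validate a data file
#'
#' Checks FASTA (unique ids, legal alphabet), GFF3 (9 fields, start <= end,
#' parent-child integrity), newick (balanced parentheses, labelled leaves)
#' or TSV (rectangular).  The file is never modified.
#'
#' @param path file path.
#' @param format_name one of `"FASTA"`, `"GFF3"`, `"newick"`, `"TSV"`.
#' @return character vector of diagnostics; empty when the file is clean.
#' @export
validate_formats <- function(path, format_name = c("FASTA", "GFF3", "newick", "TSV")) {
  format_name <- match.arg(format_name)
  diags <- character(0)
  ln <- readLines(path, warn = FALSE)
  if (format_name == "FASTA") {
    hd <- grep("^>", ln)
    if (!length(hd)) return("no FASTA header found")
    ids <- sub("\\s.*$", "", sub("^>", "", ln[hd]))
    dup <- ids[duplicated(ids)]
    if (length(dup)) diags <- c(diags, paste0("duplicate sequence id: ", unique(dup)))
    seqs <- ln[-hd]
    bad <- grep("[^ACGTNacgtn]", seqs)
    if (length(bad)) diags <- c(diags, paste0("illegal alphabet in sequence line ", bad[1]))
  } else if (format_name == "GFF3") {
    body <- which(!startsWith(ln, "#") & nzchar(ln))
    ids <- character(0); parents <- character(0)
    for (i in body) {
      f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 9L) { diags <- c(diags, paste0("line ", i, ": expected 9 fields")); next }
      s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
      if (is.na(s) || is.na(e) || s < 1L) diags <- c(diags, paste0("line ", i, ": bad coordinates"))
      else if (e < s) diags <- c(diags, paste0("line ", i, ": end < start"))
      a <- strsplit(f[9], ";", fixed = TRUE)[[1]]
      for (kv in a) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        if (p[1] == "ID") ids <- c(ids, p[2])
        if (p[1] == "Parent") parents <- c(parents, p[2])
      }
    }
    orphan <- setdiff(parents, ids)
    if (length(orphan)) diags <- c(diags, paste0("Parent without ID: ", orphan))
  } else if (format_name == "newick") {
    txt <- paste(ln, collapse = "")
    op <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
    cl <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
    if (op != cl) diags <- c(diags, "unbalanced parentheses")
    if (!grepl(";\\s*$", txt)) diags <- c(diags, "missing terminal semicolon")
    if (grepl("\\(\\s*[,)]", txt)) diags <- c(diags, "unlabelled leaf")
  } else {
    nf <- lengths(strsplit(ln[nzchar(ln)], "\t", fixed = TRUE))
    if (length(unique(nf)) > 1L)
      diags <- c(diags, paste0("ragged TSV: rows have ", paste(unique(nf), collapse = "/"), " fields"))
  }
  diags
}
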