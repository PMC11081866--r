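#' Read a FASTQ file
#'
#' Parses a (optionally gzip-compressed) FASTQ file with Phred+33 quality
#' encoding into a data frame of reads. Each record is validated: the
#' sequence and quality lines must have equal length, the separator line
#' must start with `+`, and bases must be over `{A,C,G,T,N}`. Malformed
#' records raise an error naming the 1-based record index.
#'
#' @param path path to a FASTQ file (`.gz` accepted transparently).
#' @return a data frame with columns `id` (header without the leading `@`),
#'   `seq`, `qual` (Phred+33 string), and `mate` (1, 2 or `NA`, parsed from
#'   a trailing `/1` or `/2` on the id).
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
read_fastq <- function(path) {
  if (!file.exists(path)) {
    bq_stop("bequant_io_error", "FASTQ file not found: %s", path)
  }
  lines <- readLines(path)  # R connections decompress .gz transparently
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), mate = integer(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    bq_stop("bequant_parse_error",
            "truncated FASTQ: %d lines is not a multiple of 4 (record %d incomplete)",
            length(lines), length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  sep <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    bq_stop("bequant_parse_error", "record %d: header does not start with '@'", bad[1])
  }
  bad <- which(!startsWith(sep, "+"))
  if (length(bad)) {
    bq_stop("bequant_parse_error", "record %d: missing '+' separator line", bad[1])
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    bq_stop("bequant_parse_error",
            "record %d: sequence length %d != quality length %d",
            bad[1], nchar(seq[bad[1]]), nchar(qual[bad[1]]))
  }
  bad <- which(nchar(seq) == 0L)
  if (length(bad)) {
    bq_stop("bequant_parse_error", "record %d: empty sequence", bad[1])
  }
  bad <- which(grepl("[^ACGTN]", seq))
  if (length(bad)) {
    bq_stop("bequant_parse_error", "record %d: non-ACGTN base in sequence", bad[1])
  }
  id <- sub("^@", "", hdr)
  mate <- rep(NA_integer_, n)
  mate[endsWith(id, "/1")] <- 1L
  mate[endsWith(id, "/2")] <- 2L
  data.frame(id = id, seq = seq, qual = qual, mate = mate,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns `id`, `seq`, `qual` as returned by
#'   [read_fastq()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    bq_stop("bequant_io_error", "sequence/quality length mismatch on write")
  }
  n <- nrow(reads)
  out <- character(4L * n)
  if (n > 0) {
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$id)
    out[seq(2L, by = 4L, length.out = n)] <- reads$seq
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- reads$qual
  }
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return list of integer vectors of per-base Phred scores.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode Phred scores as a Phred+33 string
#' @param scores integer vector of Phred scores.
#' @return single quality string.
#' @export
phred_encode <- function(scores) {
  intToUtf8(as.integer(scores) + 33L)
}

#' Construct and validate an amplicon specification
#'
#' An `amplicon_spec` describes one targeted locus: the reference amplicon,
#' the protospacer(s) with PAM and strand, the target adenine (the
#' pathogenic position the editor is meant to revert), the coding-sequence
#' anchor used for consequence calls, and the analysis windows. All
#' coordinates are 0-based, half-open on the reference; HGVS c. positions
#' are 1-based.
#'
#' Defaults: the quantification window is the combined interval of all
#' protospacers; the indel window additionally covers the nick site plus
#' minus 3 bp; the nick offset follows canonical SpCas9 nickase geometry
#' (cut between protospacer positions 17 and 18, 3 bp 5' of the PAM) of
#' the first protospacer.
#'
#' @param locus_name locus label.
#' @param reference reference amplicon sequence (plus strand).
#' @param protospacers data frame (or list coercible to one) with columns
#'   `label`, `seq` (5'->3' on its strand), `start` (0-based reference
#'   offset), `strand` (`+`/`-`), `pam`.
#' @param target_adenine 0-based reference offset of the target adenine
#'   (an `A` on the protospacer strand).
#' @param cds optional coding context: a list with `seq` (coding-strand
#'   sequence of the local CDS segment), `c_start` (1-based c. position of
#'   its first base), `anchor_offset` (reference offset of an anchor base),
#'   `anchor_cpos` (its c. position) and `strand` (coding strand on the
#'   reference).
#' @param nick_offset 0-based reference offset just 3' of the nick
#'   (computed from protospacer geometry when `NULL`).
#' @param quant_window,indel_window half-open `c(start, end)` reference
#'   intervals; defaults as described above.
#' @return an object of class `amplicon_spec`.
#' @export
#' @examples
#' spec <- example_amplicon_spec()
#' spec$quant_window
amplicon_spec <- function(locus_name, reference, protospacers,
                          target_adenine, cds = NULL, nick_offset = NULL,
                          quant_window = NULL, indel_window = NULL) {
  reference <- toupper(reference)
  if (grepl("[^ACGTN]", reference)) {
    bq_stop("bequant_spec_error", "reference contains non-ACGTN characters")
  }
  ps <- as.data.frame(protospacers, stringsAsFactors = FALSE)
  need <- c("label", "seq", "start", "strand", "pam")
  if (!all(need %in% names(ps))) {
    bq_stop("bequant_spec_error", "protospacers must have columns %s",
            paste(need, collapse = ", "))
  }
  ps$seq <- toupper(ps$seq)
  ps$start <- as.integer(ps$start)
  rlen <- nchar(reference)

  for (i in seq_len(nrow(ps))) {
    L <- nchar(ps$seq[i])
    s <- ps$start[i]
    if (s < 0 || s + L > rlen) {
      bq_stop("bequant_spec_error",
              "protospacer '%s' [%d, %d) outside reference bounds", ps$label[i], s, s + L)
    }
    slice <- substr(reference, s + 1L, s + L)
    expected <- if (ps$strand[i] == "+") ps$seq[i] else revcomp(ps$seq[i])
    if (slice != expected) {
      bq_stop("bequant_spec_error",
              "protospacer '%s' does not match reference at offset %d on strand %s",
              ps$label[i], s, ps$strand[i])
    }
  }

  union_start <- min(ps$start)
  union_end <- max(ps$start + nchar(ps$seq))

  # which protospacer covers the target adenine sets the relevant strand
  cover <- which(ps$start <= target_adenine & target_adenine < ps$start + nchar(ps$seq))
  proto_strand <- if (length(cover)) ps$strand[cover[1]] else ps$strand[1]
  ref_base <- substr(reference, target_adenine + 1L, target_adenine + 1L)
  want <- if (proto_strand == "+") "A" else "T"
  if (!identical(ref_base, want)) {
    bq_stop("bequant_spec_error",
            "target_adenine at offset %d is '%s' on the reference, not an A on the %s protospacer strand",
            target_adenine, ref_base, proto_strand)
  }

  if (is.null(nick_offset)) {
    s <- ps$start[1]; L <- nchar(ps$seq[1])
    nick_offset <- if (ps$strand[1] == "+") s + L - 3L else s + 3L
  }
  nick_offset <- as.integer(nick_offset)

  if (is.null(quant_window)) quant_window <- c(union_start, union_end)
  if (is.null(indel_window)) {
    indel_window <- c(min(union_start, nick_offset - 3L),
                      max(union_end, nick_offset + 3L))
  }
  quant_window <- as.integer(quant_window)
  indel_window <- as.integer(indel_window)

  for (w in list(quant_window = quant_window, indel_window = indel_window)) {
    if (length(w) != 2L || w[1] < 0 || w[2] > rlen || w[1] >= w[2]) {
      bq_stop("bequant_spec_error", "analysis window [%d, %d) invalid for reference of length %d",
              w[1], w[2], rlen)
    }
  }
  if (!(quant_window[1] <= target_adenine && target_adenine < quant_window[2])) {
    bq_stop("bequant_spec_error", "target_adenine %d outside quant_window [%d, %d)",
            target_adenine, quant_window[1], quant_window[2])
  }
  if (!(indel_window[1] <= nick_offset && nick_offset < indel_window[2])) {
    bq_stop("bequant_spec_error", "nick_offset %d outside indel_window [%d, %d)",
            nick_offset, indel_window[1], indel_window[2])
  }
  if (!(indel_window[1] <= union_start && union_end <= indel_window[2])) {
    bq_stop("bequant_spec_error", "indel_window must cover the deamination (protospacer) interval")
  }

  if (!is.null(cds)) {
    need <- c("seq", "c_start", "anchor_offset", "anchor_cpos", "strand")
    if (!all(need %in% names(cds))) {
      bq_stop("bequant_spec_error", "cds must have fields %s", paste(need, collapse = ", "))
    }
    cds$seq <- toupper(cds$seq)
    cds$c_start <- as.integer(cds$c_start)
    cds$anchor_offset <- as.integer(cds$anchor_offset)
    cds$anchor_cpos <- as.integer(cds$anchor_cpos)
    # every reference base that maps into the supplied CDS segment must agree
    offs <- 0:(rlen - 1L)
    cpos <- if (cds$strand == "+") {
      cds$anchor_cpos + (offs - cds$anchor_offset)
    } else {
      cds$anchor_cpos - (offs - cds$anchor_offset)
    }
    idx <- cpos - cds$c_start + 1L
    inside <- idx >= 1L & idx <= nchar(cds$seq)
    if (any(inside)) {
      ref_b <- strsplit(reference, "", fixed = TRUE)[[1]][inside]
      cds_b <- strsplit(cds$seq, "", fixed = TRUE)[[1]][idx[inside]]
      expect <- if (cds$strand == "+") ref_b else comp_base(ref_b)
      if (!all(cds_b == expect)) {
        bq_stop("bequant_spec_error", "cds segment disagrees with the reference over their overlap")
      }
    }
  }

  structure(list(locus_name = locus_name, reference = reference,
                 protospacers = ps, target_adenine = as.integer(target_adenine),
                 proto_strand = proto_strand, cds = cds,
                 nick_offset = nick_offset, quant_window = quant_window,
                 indel_window = indel_window),
            class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("amplicon_spec '%s': %d bp reference, %d protospacer(s)\n",
              x$locus_name, nchar(x$reference), nrow(x$protospacers)))
  cat(sprintf("  target adenine @%d (%s strand), nick @%d\n",
              x$target_adenine, x$proto_strand, x$nick_offset))
  cat(sprintf("  quant window [%d, %d), indel window [%d, %d)\n",
              x$quant_window[1], x$quant_window[2],
              x$indel_window[1], x$indel_window[2]))
  invisible(x)
}

#' Load an amplicon specification from a YAML file
#'
#' The file holds the fields of [amplicon_spec()]; the reference is given
#' either inline (`reference:`) or as a FASTA path (`reference_fasta:`,
#' optionally `reference_name:` to pick a record).
#'
#' @param path path to the YAML locus configuration.
#' @return a validated `amplicon_spec`.
#' @export
load_amplicon_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg[["reference"]])) {
    if (is.null(cfg[["reference_fasta"]])) {
      bq_stop("bequant_spec_error", "config needs 'reference' or 'reference_fasta'")
    }
    fa_path <- cfg[["reference_fasta"]]
    if (!file.exists(fa_path)) {
      fa_path <- file.path(dirname(path), fa_path)
    }
    fa <- Biostrings::readDNAStringSet(fa_path)
    ref <- if (!is.null(cfg[["reference_name"]])) fa[[cfg[["reference_name"]]]] else fa[[1]]
    cfg[["reference"]] <- as.character(ref)
  }
  ps <- do.call(rbind, lapply(cfg[["protospacers"]], function(p) {
    data.frame(label = p$label, seq = p$seq, start = p$start,
               strand = p$strand, pam = p$pam, stringsAsFactors = FALSE)
  }))
  amplicon_spec(locus_name = cfg[["locus_name"]], reference = cfg[["reference"]],
                protospacers = ps, target_adenine = cfg[["target_adenine"]],
                cds = cfg[["cds"]], nick_offset = cfg[["nick_offset"]],
                quant_window = unlist(cfg[["quant_window"]]),
                indel_window = unlist(cfg[["indel_window"]]))
}

#' Read a sample sheet
#'
#' Tab-separated table with columns `sample_id`, `fastq1`, `locus` and
#' optionally `fastq2` plus free-form group columns (treatment, genotype,
#' sex, tissue, ...).
#'
#' @param path TSV path.
#' @param loci optional named list of `amplicon_spec` objects; when given,
#'   every `locus` entry must resolve.
#' @param check_files require the FASTQ paths to exist (relative paths are
#'   resolved against the sheet's directory).
#' @return data frame of samples.
#' @export
read_sample_sheet <- function(path, loci = NULL, check_files = TRUE) {
  sheet <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "fastq1", "locus")
  if (!all(need %in% names(sheet))) {
    bq_stop("bequant_spec_error", "sample sheet needs columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    bq_stop("bequant_spec_error", "duplicate sample_id: %s",
            sheet$sample_id[duplicated(sheet$sample_id)][1])
  }
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(dirname(path), p))
  }
  sheet$fastq1 <- resolve(sheet$fastq1)
  if ("fastq2" %in% names(sheet)) {
    has2 <- !is.na(sheet$fastq2) & nzchar(sheet$fastq2)
    sheet$fastq2[has2] <- resolve(sheet$fastq2[has2])
  }
  if (check_files) {
    missing <- sheet$fastq1[!file.exists(sheet$fastq1)]
    if (length(missing)) {
      bad <- sheet$sample_id[!file.exists(sheet$fastq1)][1]
      bq_stop("bequant_io_error", "sample '%s': FASTQ not found: %s", bad, missing[1])
    }
  }
  if (!is.null(loci)) {
    unresolved <- setdiff(sheet$locus, names(loci))
    if (length(unresolved)) {
      bq_stop("bequant_spec_error", "locus '%s' not found among provided specs", unresolved[1])
    }
  }
  sheet
}

#' A synthetic demonstration locus
#'
#' Builds a fully synthetic 240-bp amplicon with one 20-nt protospacer
#' (NGG/NGN-compatible PAM `TGG`) embedded in a coding exon, shaped like a
#' recessive-missense correction target: the target adenine (A_2) reverts
#' a His codon (CAC) to Arg (CGC); bystander adenine A_1 is a synonymous
#' third-codon position (CCA->CCG, Pro), while A_3 (TAC->TGC, Tyr->Cys)
#' and A_4 (GAT->GGT, Asp->Gly) are nonsynonymous. No part of this
#' sequence is taken from any genome; it exists so examples and tests have
#' a locus with known codon-level consequences.
#'
#' @return an `amplicon_spec` for the locus `"demo_locus"`.
#' @export
#' @examples
#' example_amplicon_spec()
example_amplicon_spec <- function() {
  upstream <- "ATGTCGTGACCTGGATTCAGCACCGTTGGTCATGGCAGTC"   # offsets 0..40
  left_cds <- paste(c("CTG", "GAG", "AAG", "ATC", "TTC", "GTG", "GAC",
                      "CTG", "AAC", "GTG", "AAG", "ACC", "CTG", "GCT",
                      "GAG", "TTC", "CTC", "GAC", "AAG", "ATC"),
                    collapse = "")                            # offsets 40..100
  proto <- "GCTCCACACGTTTACGGTGA"                             # offsets 100..120
  pam <- "TGG"                                                # offsets 120..123
  right_cds <- paste(c("C", paste(rep(c("ACC", "ATC", "GAG", "CTG",
                                        "TTC", "AAG", "GAC", "GTG"), 4),
                                  collapse = "")),
                     collapse = "")                           # offsets 123..220
  tail_seq <- "GTAAGTACCTGCATGTTCAG"                          # offsets 220..240
  reference <- paste0(upstream, left_cds, proto, pam, right_cds, tail_seq)
  stopifnot(nchar(reference) == 240L)
  cds <- list(seq = substr(reference, 41L, 220L), c_start = 301L,
              anchor_offset = 40L, anchor_cpos = 301L, strand = "+")
  amplicon_spec(
    locus_name = "demo_locus",
    reference = reference,
    protospacers = data.frame(label = "sgRNA_demo", seq = proto,
                              start = 100L, strand = "+", pam = pam,
                              stringsAsFactors = FALSE),
    target_adenine = 107L,
    cds = cds
  )
}
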