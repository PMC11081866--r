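#' Alignment scoring parameters
#'
#' Affine-gap scoring for global alignment of reads to the reference
#' amplicon. A gap of length `k` costs `gap_open + k * gap_extend`.
#' Defaults make a 1-bp indel (-11) preferable to three scattered
#' mismatches (-12 including lost matches), so short indels near the nick
#' are called as indels rather than smeared into substitutions.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend gap extension penalty (<= 0).
#' @param min_identity minimum fraction of matching read bases for an
#'   alignment to be accepted.
#' @param min_overlap minimum ungapped overlap for read-pair merging.
#' @return a list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -2, gap_open = -10,
                         gap_extend = -1, min_identity = 0.6,
                         min_overlap = 10L) {
  if (match <= 0) bq_stop("bequant_param_error", "match reward must be > 0")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0) {
    bq_stop("bequant_param_error", "penalties must be <= 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 min_overlap = as.integer(min_overlap)),
            class = "align_params")
}

#' Merge a read pair by ungapped overlap
#'
#' The reverse-strand mate is reverse-complemented and slid against read 1;
#' the overlap (at least `min_overlap` bases) with the highest score
#' (+1 match, -1 mismatch, N neutral) wins, ties preferring the longer
#' overlap; a pair whose best overlap score is not positive is rejected. At disagreeing overlap positions the base with the higher
#' Phred score is kept (ties keep read 1's call) with that Phred; at
#' agreeing positions qualities are summed and capped.
#'
#' @param r1,r2 single reads: lists or one-row data frames with `id`,
#'   `seq`, `qual` (`r2` in sequencing orientation).
#' @param min_overlap minimum overlap length.
#' @param qual_cap Phred cap for summed qualities (93, the Phred+33
#'   printable maximum).
#' @return a list with `ok`; on success `id`, `seq`, `qual`; on failure a
#'   `reason` code (`"no_overlap"`).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, qual_cap = 93L) {
  res <- merge_pair_cpp(as.character(r1$seq), as.character(r1$qual),
                        as.character(r2$seq), as.character(r2$qual),
                        as.integer(min_overlap), as.integer(qual_cap))
  if (!res$ok) return(list(ok = FALSE, reason = res$reason))
  list(ok = TRUE, id = sub("/[12]$", "", as.character(r1$id)),
       seq = res$seq, qual = res$qual, overlap = res$overlap)
}

#' Merge all pairs of two mate files
#'
#' @param reads1,reads2 data frames from [read_fastq()], row-matched mates.
#' @param min_overlap minimum overlap length.
#' @return list with `merged` (read data frame) and `n_rejected`.
#' @export
merge_read_pairs <- function(reads1, reads2, min_overlap = 10L) {
  if (nrow(reads1) != nrow(reads2)) {
    bq_stop("bequant_io_error", "mate files differ in read count (%d vs %d)",
            nrow(reads1), nrow(reads2))
  }
  out <- vector("list", nrow(reads1))
  rejected <- 0L
  for (i in seq_len(nrow(reads1))) {
    m <- merge_pairs(reads1[i, ], reads2[i, ], min_overlap = min_overlap)
    if (m$ok) out[[i]] <- data.frame(id = m$id, seq = m$seq, qual = m$qual,
                                     mate = NA_integer_, stringsAsFactors = FALSE)
    else rejected <- rejected + 1L
  }
  merged <- do.call(rbind, out)
  if (is.null(merged)) {
    merged <- data.frame(id = character(), seq = character(),
                         qual = character(), mate = integer(),
                         stringsAsFactors = FALSE)
  }
  list(merged = merged, n_rejected = rejected)
}

#' Global alignment of one read against a reference
#'
#' Optimal affine-gap global alignment, end-gap free on the read side (a
#' short read may sit anywhere inside the amplicon without penalty).
#' Orientation is detected: if the reverse complement scores higher the
#' read is flipped and flagged. Indels are left-aligned against the
#' reference after traceback so window membership is independent of
#' traceback internals. Ties resolve deterministically (substitution over
#' deletion over insertion).
#'
#' @param read a single read (list/one-row data frame with `id`, `seq`) or
#'   a plain sequence string.
#' @param ref reference sequence.
#' @param params an [align_params()].
#' @param check_rc test the reverse complement orientation as well.
#' @return object of class `bq_alignment`: `read_id`, `aligned_read`,
#'   `aligned_ref` (equal-length gapped strings), `score`, `identity`,
#'   `rc`, `accepted`, and `ops` (cigar-like data frame).
#' @export
#' @examples
#' a <- global_align("ACGTACGT", "ACGTTACGT")
#' a$ops
global_align <- function(read, ref, params = align_params(), check_rc = TRUE) {
  if (is.character(read)) read <- list(id = "read", seq = read)
  if (nchar(read$seq) == 0L || nchar(ref) == 0L) {
    bq_stop("bequant_align_error", "read and reference must be non-empty")
  }
  res <- align_batch_cpp(toupper(as.character(read$seq)), toupper(ref),
                         params$match, params$mismatch, params$gap_open,
                         params$gap_extend, 0L, 0L, 0L, 0L,
                         params$min_identity, check_rc)
  aln <- list(read_id = as.character(read$id),
              aligned_read = res$aligned_read[1],
              aligned_ref = res$aligned_ref[1],
              score = res$score[1], identity = res$identity[1],
              rc = res$rc[1], accepted = res$accepted[1])
  aln$ops <- alignment_ops(aln$aligned_read, aln$aligned_ref)
  class(aln) <- "bq_alignment"
  aln
}

#' @export
print.bq_alignment <- function(x, ...) {
  cat(sprintf("alignment of '%s': score %.1f, identity %.3f%s%s\n",
              x$read_id, x$score, x$identity,
              if (x$rc) ", reverse-complemented" else "",
              if (!x$accepted) ", REJECTED" else ""))
  cat(" read:", x$aligned_read, "\n ref: ", x$aligned_ref, "\n")
  invisible(x)
}

#' Cigar-like operation list from a gapped alignment pair
#'
#' @param aligned_read,aligned_ref equal-length gapped strings.
#' @return data frame with `op` in `{match, mismatch, ins, del}`, `length`
#'   and `ref_offset` (0-based reference offset where the op starts).
#' @export
alignment_ops <- function(aligned_read, aligned_ref) {
  ar <- strsplit(aligned_read, "", fixed = TRUE)[[1]]
  rf <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  if (length(ar) != length(rf)) {
    bq_stop("bequant_align_error", "gapped strings differ in length")
  }
  type <- ifelse(ar == "-", "del",
                 ifelse(rf == "-", "ins",
                        ifelse(ar == rf & ar != "N", "match", "mismatch")))
  ref_off <- cumsum(rf != "-") - (rf != "-")  # 0-based offset of each column
  r <- rle(type)
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  data.frame(op = r$values, length = r$lengths,
             ref_offset = ref_off[starts], stringsAsFactors = FALSE)
}

#' Align a batch of reads to an amplicon and extract window profiles
#'
#' The workhorse behind quantification: every read is oriented, globally
#' aligned, indel-left-aligned, and reduced to its gapped sequence over
#' the quantification window (deletions `-`, insertions lowercase before
#' the following reference slot, uncovered positions `N`) plus a flag for
#' indels overlapping the indel window. Reads below `min_identity` are
#' rejected and counted.
#'
#' @param reads data frame from [read_fastq()] (or merged pairs).
#' @param spec an [amplicon_spec()].
#' @param params an [align_params()].
#' @param check_rc also test reverse-complement orientation per read.
#' @return data frame with one row per input read: `id`, `score`,
#'   `identity`, `rc`, `accepted`, `window`, `indel_in_window`,
#'   `aligned_read`, `aligned_ref`; attribute `accounting` holds the
#'   read-fate counts.
#' @export
align_reads <- function(reads, spec, params = align_params(), check_rc = TRUE) {
  if (nrow(reads) == 0L) {
    bq_stop("bequant_align_error", "no reads to align")
  }
  res <- align_batch_cpp(toupper(reads$seq), spec$reference,
                         params$match, params$mismatch, params$gap_open,
                         params$gap_extend,
                         spec$quant_window[1], spec$quant_window[2],
                         spec$indel_window[1], spec$indel_window[2],
                         params$min_identity, check_rc)
  out <- data.frame(id = reads$id, score = res$score, identity = res$identity,
                    rc = res$rc, accepted = res$accepted,
                    window = res$window, indel_in_window = res$indel_in_window,
                    aligned_read = res$aligned_read,
                    aligned_ref = res$aligned_ref,
                    stringsAsFactors = FALSE)
  attr(out, "accounting") <- list(total = nrow(out),
                                  aligned = sum(out$accepted),
                                  rejected_low_identity = sum(!out$accepted))
  out
}
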